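# Shared fixtures, built lazily and cached for the session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a clean single-slab acquisition: uniform retarder over the full tissue
# depth, no speckle/noise/PSF, identity instrument
slab_truth <- function(delta = 0.1, theta = 30, dims = c(64L, 8L, 2L),
                       mu = 0.002, backscatter = 1) {
  g <- default_nerve_geometry(dims = dims)
  g$fascicles <- g$fascicles[0, ]
  g$stripes <- g$stripes[0, ]
  g$vessels <- g$vessels[0, ]
  g$backscatter_texture_sd <- 0
  g$surface_z <- 10L
  g$bed$x0 <- 1L; g$bed$x1 <- dims[2]
  g$bed$delta <- delta; g$bed$theta <- theta
  g$bed$mu <- mu; g$bed$backscatter <- backscatter; g$bed$depol <- 0
  g$epineurium[c("mu", "delta", "theta", "backscatter", "depol")] <-
    g$bed[c("mu", "delta", "theta", "backscatter", "depol")]
  build_nerve_truth(g, seed = 1)
}

clean_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_repeats = 1L, snr_db = Inf, speckle = FALSE,
         apply_psf = FALSE, seed = 1L),
    list(...))
  do.call(acq_config, args)
}

# linear retarder Jones matrix; independent oracle used by the tests
oracle_retarder <- function(theta_deg, phi_deg) {
  th2 <- 2 * theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  matrix(c(cos(ph / 2) + 1i * sin(ph / 2) * cos(th2),
           1i * sin(ph / 2) * sin(th2),
           1i * sin(ph / 2) * sin(th2),
           cos(ph / 2) - 1i * sin(ph / 2) * cos(th2)),
         2, 2)
}

# smallest absolute difference between axis angles (deg, mod 180)
axis_err <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, 180 - d, d)
}

# full recovery summary on a phantom: per-fascicle segment retardation,
# calibrated axis and masked attenuation versus ground truth
recovery_summary <- function(truth, cs, jv) {
  fas <- truth$geometry$fascicles
  out <- list()
  for (i in seq_len(nrow(fas))) {
    code <- i
    fm <- truth$label == code
    b <- mask_segment_bounds(fm, min_len = 10L, inset = 3L)
    seg <- segment_retardation(jv, b$z_top, b$z_bottom)
    expe <- matrix(NA_real_, dim(fm)[2], dim(fm)[3])
    for (y in seq_len(dim(fm)[3])) {
      for (x in seq_len(dim(fm)[2])) {
        if (is.finite(b$z_top[x, y])) {
          expe[x, y] <- 2 * sum(truth$delta[b$z_top[x, y]:b$z_bottom[x, y],
                                            x, y]) *
            truth$pitch[["axial"]]
        }
      }
    }
    axc <- apply_axis_calibration(seg$axis, cs$calibration)
    out[[fas$label[i]]] <- list(
      ret_meas = mean(seg$retardation, na.rm = TRUE),
      ret_true = mean(expe, na.rm = TRUE),
      axis_meas = circ_mean_deg180(axc)$mean,
      axis_true = fas$theta[i],
      mu_meas = mean(cs$attenuation[fm & cs$valid], na.rm = TRUE),
      mu_true = mean(truth$mu[fm]) * 1000)
  }
  out
}

# angiography phantom: default geometry with three vessel tubes (cached)
angio_fixture <- function() {
  fixture("angio", {
    g <- default_nerve_geometry(dims = c(160L, 80L, 24L))
    truth <- build_nerve_truth(g, seed = 2)
    raw <- simulate_tomogram(truth, acq_config(n_repeats = 5L, snr_db = 30,
                                               seed = 6L))
    ang <- compute_angio(raw)
    jv <- assemble_jones(raw)
    refl <- compute_reflectance(jv)
    surf <- detect_surface(refl, estimate_noise_floor(refl))
    ef <- project_enface(ang, surf, c(30, 160), 3.5)
    list(truth = truth, raw = raw, ang = ang, surf = surf, ef = ef)
  })
}

# the default-phantom acquisition at study conditions (expensive; cached)
default_recovery <- function() {
  fixture("default_recovery", {
    truth <- build_nerve_truth(seed = 1)
    raw <- simulate_tomogram(truth, acq_config(
      n_repeats = 5L, snr_db = 30,
      system_unitary = random_system_unitary(13L), seed = 7L))
    jv <- assemble_jones(raw)
    cs <- reconstruct_channels(raw, stripe_rois = stripe_masks(truth))
    list(truth = truth, raw = raw, jv = jv, cs = cs,
         summary = recovery_summary(truth, cs, jv))
  })
}
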