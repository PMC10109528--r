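test_that("Jones assembly inverts the probe-state interleave", {
  # identity medium: measured matrix proportional to identity everywhere
  truth <- slab_truth(delta = 0, theta = 0, mu = 0)
  raw <- simulate_tomogram(truth, clean_cfg())
  jv <- assemble_jones(raw)
  zz <- 10:60
  expect_lt(max(Mod(jv$j[zz, , , 2L])), 1e-10)
  expect_lt(max(Mod(jv$j[zz, , , 3L])), 1e-10)
  expect_lt(max(Mod(jv$j[zz, , , 1L] - jv$j[zz, , , 4L])), 1e-10)

  # 30-degree one-way slab: matches the independently built Jones product
  truth2 <- slab_truth(delta = 0.1, theta = 25, mu = 0)
  raw2 <- simulate_tomogram(truth2, clean_cfg())
  jv2 <- assemble_jones(raw2)
  z <- 40L
  n_slabs <- z - truth2$surface_z + 1L
  phi_one_way <- 0.1 * 3.5 * n_slabs
  expected <- oracle_retarder(25, 2 * phi_one_way)  # round trip = 2x one way
  got <- matrix(jv2$j[z, 3, 1, ], 2, 2, byrow = TRUE)
  expect_lt(max(Mod(got - expected)) / max(Mod(expected)), 1e-6)

  # swapping the state columns together with the A-line parity is a no-op
  cfg_sw <- clean_cfg()
  cfg_sw$input_states <- cfg_sw$input_states[, 2:1]
  raw_sw <- raw2
  d <- dim(raw_sw$field)
  swap <- as.vector(rbind(seq(2, d[2], 2), seq(1, d[2], 2)))
  raw_sw$field <- raw_sw$field[, swap, , , , drop = FALSE]
  raw_sw$config <- cfg_sw
  jv_sw <- assemble_jones(raw_sw)
  expect_equal(jv_sw$j, jv2$j, tolerance = 1e-10)

  expect_error(assemble_jones(structure(list(
    field = raw$field,
    config = acq_config(input_states = cbind(c(1, 0), c(2, 0)))),
    class = "raw_acquisition")), "degenerate")
})

test_that("reflectance follows the log law, the floor, and the decay slope", {
  truth <- slab_truth(delta = 0, theta = 0, mu = 0)
  raw <- simulate_tomogram(truth, clean_cfg())
  jv <- assemble_jones(raw)
  r1 <- compute_reflectance(jv)
  jv2 <- jv; jv2$j <- jv$j * 2
  r2 <- compute_reflectance(jv2)
  zz <- 10:60
  expect_equal(r2[zz, , ] - r1[zz, , ], array(20 * log10(2), c(51, 8, 2)),
               tolerance = 1e-9)
  # empty voxels hit the configured floor, not -Inf
  expect_true(all(r1[1:3, , ] == -120))

  # speckle-averaged slope: -2 mu * (10/ln 10) dB per unit depth
  mu <- 0.003
  ts <- slab_truth(delta = 0, theta = 0, mu = mu, dims = c(96L, 64L, 20L))
  rs <- simulate_tomogram(ts, clean_cfg(speckle = TRUE, seed = 5L))
  refl <- compute_reflectance(assemble_jones(rs))
  zz <- 10:90
  prof <- 10 * log10(rowMeans(matrix(10^(refl[zz, , ] / 10), length(zz))))
  slope_db_per_um <- stats::coef(stats::lm(prof ~ zz))[2] / 3.5
  expect_equal(unname(slope_db_per_um), -2 * mu * 10 / log(10),
               tolerance = 0.05)
})

test_that("attenuation estimator matches its closed forms", {
  # geometric halving: mu-hat = ln(2)/2 per pixel at every depth
  n <- 60L
  ii <- array(0.5^(seq_len(n)), c(n, 1, 1))
  mu <- compute_attenuation(ii, dz_um = 1, lateral_smooth = 1L,
                            tail_correct = TRUE, mask_last = 0L)
  expect_equal(as.vector(mu) / 1000, rep(log(2) / 2, n), tolerance = 1e-9)

  # constant A-line: mu-hat_i = ln(1 + 1/(N - i)) / (2 dz), 1-based i
  ii2 <- array(1, c(n, 1, 1))
  mu2 <- compute_attenuation(ii2, dz_um = 1, lateral_smooth = 1L,
                             tail_correct = FALSE, mask_last = 0L)
  i <- seq_len(n - 1L)
  expect_equal(as.vector(mu2)[i] / 1000, log(1 + 1 / (n - i)) / 2,
               tolerance = 1e-12)
  expect_true(is.na(mu2[n, 1, 1]))  # zero tail is masked, not an error

  # scale invariance
  mu3 <- compute_attenuation(ii * 77, dz_um = 1, lateral_smooth = 1L,
                             tail_correct = TRUE, mask_last = 0L)
  expect_equal(mu3, mu, tolerance = 1e-12)
})

test_that("cumulative retardation doubles the one-way slab retardance", {
  # uniform slab, one-way 30 deg in total over 30 slabs
  dims <- c(64L, 8L, 2L)
  delta <- 30 / (30 * 3.5)
  g <- slab_truth(delta = 0, theta = 0, mu = 0.001, dims = dims)$geometry
  g$bed$delta <- 0
  g$slab <- NULL
  # two stacked regions with the same axis: 20 then 10 one-way degrees
  truth <- build_nerve_truth(g, seed = 1)
  z0 <- truth$surface_z
  # 1 deg/px one-way; the reference pixel itself sits at the slab top, so
  # the 20-deg slab spans the 20 pixels below it and the 10-deg slab the
  # next 10
  truth$delta[z0:(z0 + 20), , ] <- 1 / 3.5
  truth$delta[(z0 + 21):(z0 + 30), , ] <- 1 / 3.5
  truth$theta[] <- 40
  raw <- simulate_tomogram(truth, clean_cfg())
  jv <- assemble_jones(raw)
  refl <- compute_reflectance(jv)
  surf <- detect_surface(refl, estimate_noise_floor(refl))
  ret <- compute_retardation(jv, surf, ref_offset = 0L)
  # 60 deg round trip at the bottom of both slabs (oracle: Jones product)
  expect_equal(ret[z0 + 30, 4, 1], 60, tolerance = 1)
  expect_equal(ret[z0 + 20, 4, 1], 40, tolerance = 1)

  # delta = 0 medium stays at zero retardation
  t0 <- slab_truth(delta = 0, theta = 0, mu = 0.001)
  raw0 <- simulate_tomogram(t0, clean_cfg())
  jv0 <- assemble_jones(raw0)
  refl0 <- compute_reflectance(jv0)
  surf0 <- detect_surface(refl0, estimate_noise_floor(refl0))
  ret0 <- compute_retardation(jv0, surf0)
  expect_false(anyNA(ret0[15:55, 2:7, ]))
  expect_lt(max(abs(ret0[15:55, , ]), na.rm = TRUE), 1e-4)
})

test_that("optic axis is recovered, equivariant, and masked when undefined", {
  mk <- function(theta) {
    truth <- slab_truth(delta = 0.2, theta = theta, mu = 0.001)
    raw <- simulate_tomogram(truth, clean_cfg())
    jv <- assemble_jones(raw)
    refl <- compute_reflectance(jv)
    surf <- detect_surface(refl, estimate_noise_floor(refl))
    compute_optic_axis(jv, surf)
  }
  ax0 <- mk(0)
  expect_lt(max(axis_err(ax0[20:40, , ], 0), na.rm = TRUE), 2)
  # rotating the simulated axis rotates the recovered axis equally
  ax30 <- mk(30)
  expect_lt(max(axis_err(ax30[20:40, , ], 30), na.rm = TRUE), 2)
  # 170 deg and -10 deg are the same axis
  expect_equal(mk(170)[20:40, , ], mk(-10 + 180)[20:40, , ], tolerance = 1e-9)
  # delta ~ 0: axis undefined -> masked
  t0 <- slab_truth(delta = 0, theta = 0, mu = 0.001)
  raw0 <- simulate_tomogram(t0, clean_cfg())
  jv0 <- assemble_jones(raw0)
  refl0 <- compute_reflectance(jv0)
  ax_ud <- compute_optic_axis(jv0, detect_surface(refl0,
                                                  estimate_noise_floor(refl0)))
  expect_true(all(is.na(ax_ud[20:40, , ])))
})

test_that("stripe calibration fixes offset and chirality across instruments", {
  fx <- default_recovery()
  cs <- fx$cs
  expect_lt(axis_err(cs$calibration$p0, 0), 2)
  expect_lt(axis_err(cs$calibration$p45, 45), 2)

  # a different instrument unitary yields the same calibrated fascicle axes
  raw2 <- simulate_tomogram(fx$truth, acq_config(
    n_repeats = 5L, snr_db = 30, system_unitary = random_system_unitary(29L),
    seed = 7L))
  jv2 <- assemble_jones(raw2)
  cs2 <- reconstruct_channels(raw2, stripe_rois = stripe_masks(fx$truth))
  s2 <- recovery_summary(fx$truth, cs2, jv2)
  diffs <- sapply(names(s2), function(f)
    axis_err(s2[[f]]$axis_meas, fx$summary[[f]]$axis_meas))
  expect_lt(sqrt(mean(diffs^2)), 3)

  # recalibrating an already calibrated volume is a no-op
  cal2 <- calibrate_optic_axis(cs$axis, stripe_masks(fx$truth))
  sel <- is.finite(cs$axis) & cs$valid
  resid <- axis_err(cal2$axis[sel], cs$axis[sel])
  expect_lt(sqrt(mean(resid^2)), 2.5)

  # indistinguishable stripes are a hard failure
  expect_error(
    calibrate_optic_axis(cs$axis,
                         list(P0 = stripe_masks(fx$truth)$P0,
                              P45 = stripe_masks(fx$truth)$P0)),
    "calibration failure")
})

test_that("DOPU is 1 for uniform states and ~1/sqrt(n) for random ones", {
  truth <- slab_truth(delta = 0.05, theta = 30, mu = 0.001,
                      dims = c(64L, 32L, 4L))
  raw <- simulate_tomogram(truth, clean_cfg(speckle = TRUE, seed = 3L))
  jv <- assemble_jones(raw)
  dopu <- compute_dopu(jv, kernel = c(3L, 9L))
  expect_true(all(dopu[15:55, 6:27, ] > 0.99))   # speckle is a scalar: uniform

  # isotropically random states: E[DOPU] ~ 1/sqrt(n) for an n-voxel kernel
  set.seed(8)
  n_vox <- 63L * 129L * 2L
  jr <- list(j = array(complex(real = rnorm(n_vox * 4),
                               imaginary = rnorm(n_vox * 4)),
                       c(63, 129, 2, 4)),
             dims = c(63L, 129L, 2L), pitch = c(axial = 3.5, lateral = 10))
  class(jr) <- "jones_volume"
  d2 <- compute_dopu(jr, kernel = c(9L, 9L))
  inner <- d2[5:59, 5:125, ]
  expect_equal(mean(inner), 1 / sqrt(81), tolerance = 0.2)

  # a depolarizing region scores lower than a non-depolarizing one
  g <- slab_truth(delta = 0.05, theta = 30, mu = 0.001,
                  dims = c(64L, 32L, 4L))$geometry
  td <- build_nerve_truth(g, seed = 1)
  td$depol[, 17:32, ] <- 0.5
  rawd <- simulate_tomogram(td, clean_cfg(speckle = TRUE, seed = 3L))
  dd <- compute_dopu(assemble_jones(rawd), kernel = c(3L, 9L))
  expect_gt(mean(dd[15:55, 5:12, ]), mean(dd[15:55, 21:28, ]) + 0.1)

  expect_error(compute_dopu(jv, kernel = c(4L, 9L)), "odd")
  expect_error(compute_dopu(jv, kernel = c(3L, 999L)), "larger")
})

test_that("BwOA encodes axis as cyclic hue weighted by local retardance", {
  nz <- 40L; nx <- 10L; ny <- 1L
  d <- c(nz, nx, ny)
  refl <- array(0, d); valid <- array(TRUE, d)
  ret0 <- array(0, d)
  ax <- array(30, d)
  # zero retardance -> zero saturation -> gray (R = G = B)
  rgb0 <- compute_bwoa(ret0, ax, refl, valid, dz_um = 3.5,
                       value_range = c(-10, 10))
  expect_equal(rgb0[, , , 1], rgb0[, , , 2], tolerance = 1e-12)
  expect_equal(rgb0[, , , 2], rgb0[, , , 3], tolerance = 1e-12)

  # axes 0 and 180 produce identical hue
  slope <- array(rep(2 * 0.3 * 3.5 * seq_len(nz), nx * ny), d)
  rgb_a <- compute_bwoa(slope, array(0, d), refl, valid, 3.5,
                        value_range = c(-10, 10))
  rgb_b <- compute_bwoa(slope, array(180, d), refl, valid, 3.5,
                        value_range = c(-10, 10))
  expect_equal(rgb_a, rgb_b, tolerance = 1e-12)

  # saturation grows monotonically with retardance up to the cap
  sats <- sapply(c(0.05, 0.15, 0.3, 0.6), function(dl) {
    cum <- array(rep(2 * dl * 3.5 * seq_len(nz), nx * ny), d)
    rgb <- compute_bwoa(cum, ax, refl, valid, 3.5, sat_cap = 0.4,
                        value_range = c(-10, 10))
    v <- max(rgb[20, 5, 1, ]); m <- min(rgb[20, 5, 1, ])
    (v - m) / v   # HSV saturation recovered from RGB
  })
  expect_true(all(diff(sats) >= -1e-9))
  expect_lt(abs(sats[4] - 1), 1e-9)

  # value channel zeroed outside the validity mask
  valid2 <- valid; valid2[1:10, , ] <- FALSE
  rgbm <- compute_bwoa(slope, ax, refl, valid2, 3.5, value_range = c(-10, 10))
  expect_true(all(rgbm[1:10, , , ] == 0))
})

test_that("channels recover the phantom ground truth at study conditions", {
  fx <- default_recovery()
  s <- fx$summary
  for (f in names(s)) {
    expect_lt(abs(s[[f]]$ret_meas / s[[f]]$ret_true - 1), 0.05)
    expect_lt(axis_err(s[[f]]$axis_meas, s[[f]]$axis_true), 3)
    expect_lt(abs(s[[f]]$mu_meas / s[[f]]$mu_true - 1), 0.10)
  }
  # channel outputs carry no NaN inside the validity mask
  cs <- fx$cs
  expect_true(all(is.finite(cs$reflectance[cs$valid])))
  expect_true(all(is.finite(cs$retardation[cs$valid])))
  expect_true(all(is.finite(cs$dopu[cs$valid])))
})

test_that("retardation and DOPU are invariant to the instrument unitary", {
  truth <- slab_truth(delta = 0.15, theta = 35, mu = 0.001)
  outs <- lapply(c(1L, 2L), function(k) {
    u <- if (k == 1L) diag(2) + 0i else random_system_unitary(41L)
    raw <- simulate_tomogram(truth, clean_cfg(system_unitary = u))
    jv <- assemble_jones(raw)
    refl <- compute_reflectance(jv)
    surf <- detect_surface(refl, estimate_noise_floor(refl))
    list(ret = compute_retardation(jv, surf),
         dopu = compute_dopu(jv, kernel = c(3L, 5L)))
  })
  zz <- 15:55
  expect_equal(outs[[1]]$ret[zz, , ], outs[[2]]$ret[zz, , ],
               tolerance = 1e-6)
  # the probe state physically traverses the fibre, so the in-tissue Stokes
  # trajectory differs slightly between instruments: near-exact, not exact
  expect_lt(max(abs(outs[[1]]$dopu[zz, , ] - outs[[2]]$dopu[zz, , ])), 2e-4)
})
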