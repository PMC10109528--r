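#' Reflectance channel (dB)
#'
#' Total backscattered power summed over the entries of the measured Jones
#' matrix (i.e. over both probe-state response columns), on a decibel scale
#' and floored so empty voxels report the noise floor rather than -Inf.
#'
#' @param jv a `jones_volume`.
#' @param floor_db flooring value in dB.
#' @return array (nz, nx, ny) of reflectance in dB.
#' @export
compute_reflectance <- function(jv, floor_db = -120) {
  p <- Mod(jv$j[, , , 1L])^2 + Mod(jv$j[, , , 2L])^2 +
    Mod(jv$j[, , , 3L])^2 + Mod(jv$j[, , , 4L])^2
  pmax(10 * log10(p), floor_db)
}

#' Estimate the reflectance noise floor from the air gap above the tissue
#'
#' @param refl_db reflectance array.
#' @param top_rows number of shallow rows assumed to be signal-free.
#' @return scalar noise floor (dB).
#' @export
estimate_noise_floor <- function(refl_db, top_rows = 6L) {
  # mean linear power (not median dB): this is the quantity subtracted when
  # correcting intensities for additive noise
  10 * log10(mean(10^(refl_db[seq_len(top_rows), , ] / 10)))
}

#' Detect the tissue surface on each A-line
#'
#' First depth at which reflectance exceeds the noise floor by `rise_db`
#' for `run` consecutive pixels; robust to isolated speckle spikes.
#'
#' @param refl_db reflectance array (nz, nx, ny).
#' @param noise_floor_db scalar noise floor.
#' @param rise_db required rise above the floor (default 10 dB).
#' @param run consecutive-pixel run length (default 3).
#' @return integer matrix (nx, ny); NA where no surface is found.
#' @export
detect_surface <- function(refl_db, noise_floor_db, rise_db = 10, run = 3L) {
  d <- dim(refl_db)
  nz <- d[1]
  cond <- refl_db > noise_floor_db + rise_db
  cnt <- matrix(0L, d[2], d[3])
  surf <- matrix(NA_integer_, d[2], d[3])
  for (z in seq_len(nz)) {
    cz <- matrix(cond[z, , ], d[2], d[3])
    cnt <- ifelse(cz, cnt + 1L, 0L)
    hit <- cnt >= run & is.na(surf)
    surf[hit] <- z - run + 1L
  }
  surf
}

#' Depth-resolved attenuation coefficient
#'
#' Log-form depth-resolved estimator: mu_i = ln(1 + I_i / sum_{j>i} I_j) /
#' (2 dz), exact for discrete exponential decays. The optional tail
#' correction extrapolates the truncated sum beyond the last pixel by
#' fitting a log-linear slope to the deepest valid window, removing the
#' finite-depth bias; it is skipped on A-lines whose signal has already
#' decayed into the noise. A lateral boxcar reduces speckle noise before
#' estimation, and an estimated noise power is subtracted first.
#'
#' @param intensity linear-scale intensity array (nz, nx, ny), >= 0.
#' @param dz_um axial pixel pitch in micrometres.
#' @param noise_power scalar noise power subtracted before estimation.
#' @param lateral_smooth odd boxcar width (pixels) applied along x; 1 = off.
#' @param tail_correct extrapolate the tail sum beyond the imaging depth.
#' @param tail_fit number of deepest pixels used for the tail slope fit.
#' @param mask_last invalidate this many deepest pixels (truncation bias).
#' @return array of attenuation estimates in 1/mm; NA where invalid.
#' @export
compute_attenuation <- function(intensity, dz_um, noise_power = 0,
                                lateral_smooth = 5L, tail_correct = TRUE,
                                tail_fit = 15L, mask_last = 20L) {
  stopifnot(all(intensity >= 0 | is.na(intensity)))
  d <- dim(intensity)
  if (is.null(d)) d <- c(length(intensity), 1L, 1L)
  nz <- d[1]
  arr <- array(intensity, d)
  arr <- pmax(arr - noise_power, 0)
  if (lateral_smooth > 1L && length(d) == 3L && d[2] >= lateral_smooth) {
    for (y in seq_len(d[3])) {
      arr[, , y] <- box_mean_2d(matrix(arr[, , y], nz, d[2]), 1L,
                                as.integer(lateral_smooth))
    }
  }
  m <- matrix(arr, nz, prod(d) / nz)

  # reverse cumulative sum: tail[i] = sum_{j > i} I_j
  tail <- apply(m[rev(seq_len(nz)), , drop = FALSE], 2, cumsum)
  tail <- tail[rev(seq_len(nz)), , drop = FALSE] - m

  if (tail_correct && nz > tail_fit + 2L) {
    win <- (nz - tail_fit + 1L):nz
    lw <- log(m[win, , drop = FALSE])
    ok <- colSums(!is.finite(lw)) == 0L
    zc <- win - mean(win)
    slope <- rep(NA_real_, ncol(m))
    pred_last <- rep(NA_real_, ncol(m))
    if (any(ok)) {
      slope[ok] <- colSums(zc * lw[, ok, drop = FALSE]) / sum(zc^2)
      # fitted (de-speckled) intensity at the deepest pixel
      pred_last[ok] <- colMeans(lw[, ok, drop = FALSE]) +
        slope[ok] * (nz - mean(win))
    }
    qf <- exp(slope)                       # per-pixel decay factor
    usable <- ok & is.finite(qf) & qf > 0 & qf < 0.999
    rem <- numeric(ncol(m))
    rem[usable] <- exp(pred_last[usable]) * qf[usable] / (1 - qf[usable])
    tail <- sweep(tail, 2, rem, `+`)
  }

  mu <- log1p(m / tail) / (2 * dz_um) * 1000   # 1/mm
  mu[tail <= 0] <- NA_real_
  if (mask_last > 0L) mu[(nz - mask_last + 1L):nz, ] <- NA_real_
  array(mu, d)
}

#' Cumulative round-trip phase retardation (degrees)
#'
#' Phase split of the eigenvalues of the surface-relative Jones matrix
#' J(z_surf)^-1 J(z), unwrapped along depth. The relative matrix cancels the
#' instrument unitary by construction, so the output is invariant to fibre
#' birefringence.
#'
#' @param jv a `jones_volume`.
#' @param surface integer matrix (nx, ny) of surface indices, from
#'   [detect_surface()].
#' @param ref_offset pixels below the surface used as the reference plane.
#' @return array (nz, nx, ny) of cumulative round-trip retardation in
#'   degrees; NA above the surface and on A-lines without one.
#' @export
compute_retardation <- function(jv, surface, ref_offset = 2L) {
  polar_fields(jv, surface, ref_offset)$retardation
}

#' Raw (uncalibrated) optic-axis orientation (degrees mod 180)
#'
#' Orientation of the leading eigenvector of the surface-relative Jones
#' matrix, mapped to a linear-retarder axis angle. Masked where the local
#' phase split is too close to 0 or 180 degrees for the eigenvectors to be
#' defined.
#'
#' @inheritParams compute_retardation
#' @param axis_floor_deg degeneracy floor on the folded phase split.
#' @export
compute_optic_axis <- function(jv, surface, ref_offset = 2L,
                               axis_floor_deg = 4) {
  polar_fields(jv, surface, ref_offset, axis_floor_deg)$axis
}

#' Retardation and axis of a depth segment, free of overlayer compounding
#'
#' The cumulative retardation channel compounds non-additively when layers
#' above a structure have a different optic axis. For quantifying one
#' structure (e.g. a fascicle), the segment estimator removes the overlayer:
#' J(z1)^-1 J(z2) is similar to the round-trip matrix of the segment alone,
#' so its eigen phase split is exactly the segment's round-trip retardance
#' 2 * integral(delta dz) and its eigenvector orientation is the segment
#' axis (up to the instrument offset, removed by the stripe calibration).
#'
#' Because speckle enters the Jones matrix as a per-voxel complex scalar, it
#' cancels in the segment matrix up to a global phase; after normalising the
#' matrix to unit determinant (with the sign chosen so the trace — real and
#' positive for a retarder-like segment — stays positive), neighbouring
#' A-lines can be averaged coherently before the eigendecomposition, which
#' suppresses the additive-noise bias of the nonlinear eigenvector step.
#'
#' @param jv a `jones_volume`.
#' @param z_top,z_bottom integer matrices (nx, ny): segment endpoints per
#'   A-line; NA skips the A-line.
#' @param smooth c(kx, ky) odd box kernel for coherent averaging of the
#'   unimodular segment matrix across A-lines; c(1, 1) disables.
#' @return list of (nx, ny) matrices `retardation` (deg, round trip) and
#'   `axis` (deg mod 180, uncalibrated).
#' @export
segment_retardation <- function(jv, z_top, z_bottom, smooth = c(5L, 5L)) {
  j <- jv$j
  nx <- jv$dims[2]; ny <- jv$dims[3]
  ok <- is.finite(z_top) & is.finite(z_bottom)
  idx <- function(zm, k) {
    zi <- ifelse(ok, zm, 1L)
    matrix(j[cbind(as.vector(zi), rep(seq_len(nx), ny),
                   rep(seq_len(ny), each = nx), k)], nx, ny)
  }
  a1 <- idx(z_top, 1L); b1 <- idx(z_top, 2L)
  c1 <- idx(z_top, 3L); d1 <- idx(z_top, 4L)
  a2 <- idx(z_bottom, 1L); b2 <- idx(z_bottom, 2L)
  c2 <- idx(z_bottom, 3L); d2 <- idx(z_bottom, 4L)
  det1 <- a1 * d1 - b1 * c1
  det1[Mod(det1) < 1e-15] <- NA
  n11 <- (d1 * a2 - b1 * c2) / det1
  n12 <- (d1 * b2 - b1 * d2) / det1
  n21 <- (-c1 * a2 + a1 * c2) / det1
  n22 <- (-c1 * b2 + a1 * d2) / det1

  # det-normalise (cancels speckle), sign-align on the trace, then average
  dN <- n11 * n22 - n12 * n21
  s <- sqrt(dN)
  flip <- Re((n11 + n22) / s) < 0
  s[which(flip)] <- -s[which(flip)]
  bad <- !ok | !is.finite(Mod(s)) | Mod(s) < 1e-15
  s[which(bad)] <- 1
  n11 <- n11 / s; n12 <- n12 / s; n21 <- n21 / s; n22 <- n22 / s

  eig <- function(m11, m12, m21, m22) {
    tr <- m11 + m22
    disc <- sqrt(tr^2 - 4 * (m11 * m22 - m12 * m21))
    psi <- Arg((tr + disc) / (tr - disc))
    lu <- (tr + ifelse(psi >= 0, 1, -1) * disc) / 2
    v1a <- m12; v2a <- lu - m11
    v1b <- lu - m22; v2b <- m21
    use_b <- (Mod(v1b)^2 + Mod(v2b)^2) > (Mod(v1a)^2 + Mod(v2a)^2)
    v1 <- ifelse(use_b, v1b, v1a); v2 <- ifelse(use_b, v2b, v2a)
    list(psi = psi,
         axis = wrap180(0.5 * atan2(2 * Re(v1 * Conj(v2)),
                                    Mod(v1)^2 - Mod(v2)^2) * 180 / pi))
  }

  # retardation per column (averaging matrices across columns would shrink
  # the eigen split when axes or overlayers vary within the kernel)
  ret <- abs(eig(n11, n12, n21, n22)$psi) * 180 / pi

  # axis from the coherently averaged matrix (suppresses noise bias of the
  # eigenvector step)
  smooth <- pmin(as.integer(smooth), c(nx, ny))
  smooth <- smooth - (1L - smooth %% 2L)   # force odd, within grid
  if (any(smooth > 1L)) {
    w <- matrix(as.numeric(!bad), nx, ny)
    zero <- function(m) { m[which(bad)] <- 0; m }
    bm <- function(m) box_mean_2d_cplx(matrix(zero(m), nx, ny),
                                       smooth[1], smooth[2])
    wbar <- box_mean_2d(w, smooth[1], smooth[2])
    wbar[wbar < 1e-12] <- NA
    axis <- eig(bm(n11) / wbar, bm(n12) / wbar,
                bm(n21) / wbar, bm(n22) / wbar)$axis
  } else {
    axis <- eig(n11, n12, n21, n22)$axis
  }
  ret[!ok] <- NA_real_; axis[!ok] <- NA_real_
  dim(ret) <- dim(axis) <- c(nx, ny)
  list(retardation = ret, axis = axis)
}

#' Per-A-line depth bounds of a voxel mask, for the segment estimator
#'
#' @param mask logical array (nz, nx, ny).
#' @param min_len minimum run of masked voxels per A-line.
#' @param inset pixels trimmed from both ends (keeps the endpoints clear of
#'   the PSF-blurred boundary).
#' @return list of integer (nx, ny) matrices `z_top`, `z_bottom`.
#' @export
mask_segment_bounds <- function(mask, min_len = 10L, inset = 2L) {
  d <- dim(mask)
  z_top <- matrix(NA_integer_, d[2], d[3])
  z_bottom <- z_top
  for (y in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      zz <- which(mask[, x, y])
      if (length(zz) >= min_len + 2L * inset) {
        z_top[x, y] <- min(zz) + inset
        z_bottom[x, y] <- max(zz) - inset
      }
    }
  }
  list(z_top = z_top, z_bottom = z_bottom)
}

# shared core: build the offset/chirality calibration from stripe axis values
calibration_from_stripe_axes <- function(ax0, ax45) {
  m0 <- circ_mean_deg180(ax0)$mean
  m45 <- circ_mean_deg180(ax45)$mean
  if (!is.finite(m0) || !is.finite(m45)) stop("empty or axis-invalid stripe ROI")
  if (abs(axis_diff_deg(m0, m45)) < 10) {
    stop("calibration failure: stripe axes indistinguishable")
  }
  best <- NULL
  for (s in c(1, -1)) {
    p45 <- wrap180(s * (m45 - m0))
    err <- abs(axis_diff_deg(p45, 45))
    if (is.null(best) || err < best$err) {
      best <- list(offset = m0, chirality = s, err = err,
                   p0 = 0, p45 = p45)
    }
  }
  best$err <- NULL
  best
}

#' Apply a stored stripe calibration to an axis map
#'
#' @param axis axis values (deg mod 180).
#' @param calibration list with `offset` and `chirality` from
#'   [calibrate_optic_axis()].
#' @export
apply_axis_calibration <- function(axis, calibration) {
  wrap180(calibration$chirality * (axis - calibration$offset))
}

#' Calibrate the optic-axis channel against the 0/45-degree stripe phantoms
#'
#' The two rigid reference stripes bracket the tissue; an offset is chosen so
#' the circular mean axis of stripe P0 reads 0 degrees, and the chirality
#' (sign) is chosen so stripe P45 reads +45 rather than -45. The same
#' offset/sign is applied to the whole volume, making axis maps comparable
#' across acquisitions and instruments.
#'
#' @param axis raw axis array (deg mod 180).
#' @param rois list with logical arrays `P0` and `P45` selecting stripe
#'   voxels.
#' @return list with `axis` (calibrated array), `offset`, `chirality`, and
#'   the post-calibration stripe means `p0`, `p45`.
#' @export
calibrate_optic_axis <- function(axis, rois) {
  cal <- calibration_from_stripe_axes(axis[rois$P0], axis[rois$P45])
  out <- apply_axis_calibration(axis, cal)
  cal$p0 <- circ_mean_deg180(out[rois$P0])$mean
  cal$p45 <- circ_mean_deg180(out[rois$P45])$mean
  c(list(axis = out), cal)
}

#' Degree of polarization uniformity
#'
#' Unit Stokes vectors (Q, U, V) of the response to the first probe state are
#' averaged over a small spatial kernel; DOPU is the length of the mean
#' vector, 1 for a locally uniform polarization state and ~1/sqrt(n) for
#' isotropically random states.
#'
#' @param jv a `jones_volume`.
#' @param kernel odd (z, x) kernel size, default 3 x 9.
#' @param state probe state (2-vector) whose response is analysed.
#' @return array (nz, nx, ny) with DOPU in [0, 1].
#' @export
compute_dopu <- function(jv, kernel = c(3L, 9L), state = c(1, 0)) {
  if (any(kernel %% 2 == 0)) stop("kernel dimensions must be odd")
  d <- jv$dims
  if (kernel[1] > d[1] || kernel[2] > d[2]) stop("kernel larger than volume")
  e1 <- jv$j[, , , 1L] * state[1] + jv$j[, , , 2L] * state[2]
  e2 <- jv$j[, , , 3L] * state[1] + jv$j[, , , 4L] * state[2]
  ii <- Mod(e1)^2 + Mod(e2)^2
  eps <- 1e-30
  q <- (Mod(e1)^2 - Mod(e2)^2) / (ii + eps)
  u <- 2 * Re(e1 * Conj(e2)) / (ii + eps)
  v <- -2 * Im(e1 * Conj(e2)) / (ii + eps)
  out <- array(NA_real_, d)
  for (y in seq_len(d[3])) {
    mq <- box_mean_2d(matrix(q[, , y], d[1], d[2]), kernel[1], kernel[2])
    mu_ <- box_mean_2d(matrix(u[, , y], d[1], d[2]), kernel[1], kernel[2])
    mv <- box_mean_2d(matrix(v[, , y], d[1], d[2]), kernel[1], kernel[2])
    out[, , y] <- sqrt(mq^2 + mu_^2 + mv^2)
  }
  pmin(out, 1)
}

# vectorised HSV -> RGB (h, s, v in [0,1]); returns list(r, g, b)
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Birefringence-weighted optic axis composite (RGB)
#'
#' HSV composition: hue encodes the calibrated axis on a cyclic map (0 and
#' 180 degrees are the same colour), saturation the local one-way retardance
#' normalised to `sat_cap`, and value the reflectance mapped to the display
#' range; the value channel is zeroed outside the validity mask, so invalid
#' depths render black.
#'
#' @param retardation cumulative round-trip retardation (deg).
#' @param axis calibrated axis (deg mod 180).
#' @param refl_db reflectance (dB).
#' @param valid logical validity mask.
#' @param dz_um axial pitch (um).
#' @param sat_cap saturation cap in deg/um of one-way retardance.
#' @param value_range reflectance display range (dB); defaults to the 1st and
#'   99.9th percentile of the masked reflectance.
#' @return array (nz, nx, ny, 3) with RGB in [0, 1].
#' @export
compute_bwoa <- function(retardation, axis, refl_db, valid, dz_um,
                         sat_cap = 0.4, value_range = NULL) {
  d <- dim(refl_db)
  # local one-way retardance (deg/um) from the cumulative round-trip slope
  local <- array(0, d)
  local[2:(d[1] - 1), , ] <-
    (retardation[3:d[1], , ] - retardation[1:(d[1] - 2), , ]) / (4 * dz_um)
  local[!is.finite(local)] <- 0
  if (is.null(value_range)) {
    vv <- refl_db[valid & is.finite(refl_db)]
    value_range <- if (length(vv)) stats::quantile(vv, c(0.01, 0.999))
      else range(refl_db, finite = TRUE)
  }
  h <- wrap180(ifelse(is.finite(axis), axis, 0)) / 180
  s <- pmin(pmax(local / sat_cap, 0), 1)
  s[!is.finite(axis)] <- 0
  v <- pmin(pmax((refl_db - value_range[1]) /
                   diff(range(value_range)), 0), 1)
  v[!valid] <- 0
  rgb <- hsv_to_rgb(h, s, v)
  out <- array(0, c(d, 3L))
  out[, , , 1L] <- rgb$r; out[, , , 2L] <- rgb$g; out[, , , 3L] <- rgb$b
  out
}

#' Reconstruct the six PSOCT channels from a raw acquisition
#'
#' Runs the full channel chain: Jones assembly (coherent repeat average),
#' reflectance, noise-floor and surface estimation, depth-resolved
#' attenuation, cumulative retardation and optic axis, DOPU, the
#' polarization-validity mask and, when stripe ROIs are supplied, the
#' 0/45-degree axis calibration and the BwOA composite.
#'
#' @param raw a `raw_acquisition`.
#' @param stripe_rois list of logical stripe masks (see [stripe_masks()]
#'   applied to the generating truth, or segmented on real data); NULL skips
#'   calibration and the axis channel stays in the raw frame.
#' @param dopu_kernel DOPU kernel (z, x).
#' @param dopu_min,refl_margin_db validity-mask thresholds: DOPU floor and
#'   required reflectance rise above the noise floor.
#' @param ... passed to [compute_attenuation()].
#' @return list of class `channel_set`.
#' @export
reconstruct_channels <- function(raw, stripe_rois = NULL,
                                 dopu_kernel = c(3L, 9L),
                                 dopu_min = 0.6, refl_margin_db = 5, ...) {
  jv <- assemble_jones(raw)
  refl <- compute_reflectance(jv)
  floor_db <- estimate_noise_floor(refl)
  surface <- detect_surface(refl, floor_db)
  dz <- raw$pitch[["axial"]]

  lin <- 10^(refl / 10)
  noise_lin <- 10^(floor_db / 10)
  atten <- compute_attenuation(lin, dz, noise_power = noise_lin, ...)

  pf <- polar_fields(jv, surface)
  dopu <- compute_dopu(jv, dopu_kernel)

  # The polarization-valid region is a depth limit, not a voxel sieve: each
  # A-line is valid from the surface down to the first sustained failure of
  # the DOPU / reflectance criteria. (A voxelwise mask would keep only
  # bright-speckle voxels at depth and bias intensity statistics upward.)
  d <- jv$dims
  zidx <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  surf_big <- expand_z(surface, d[1])
  crit <- is.finite(surf_big) & zidx > surf_big &
    refl >= floor_db + refl_margin_db & dopu >= dopu_min
  crit[!is.finite(crit)] <- FALSE
  fail_run <- 3L
  cnt <- matrix(0L, d[2], d[3])
  cutoff <- matrix(d[1] + 1L, d[2], d[3])
  open_col <- matrix(TRUE, d[2], d[3])
  for (z in seq_len(d[1])) {
    below <- matrix(zidx[z, , ] > surf_big[z, , ], d[2], d[3])
    failz <- below & !matrix(crit[z, , ], d[2], d[3])
    cnt <- ifelse(below & open_col, ifelse(failz, cnt + 1L, 0L), cnt)
    hit <- open_col & cnt >= fail_run
    cutoff[hit] <- z - fail_run + 1L
    open_col[hit] <- FALSE
  }
  valid <- is.finite(surf_big) & zidx > surf_big &
    zidx < expand_z(cutoff, d[1])

  # stripe calibration from the segment estimator over the stripe bodies
  # (noise-robust: speckle-cancelled, coherently averaged across A-lines)
  calib <- NULL
  axis <- pf$axis
  if (!is.null(stripe_rois)) {
    b0 <- mask_segment_bounds(stripe_rois$P0, min_len = 6L, inset = 1L)
    b45 <- mask_segment_bounds(stripe_rois$P45, min_len = 6L, inset = 1L)
    s0 <- segment_retardation(jv, b0$z_top, b0$z_bottom)
    s45 <- segment_retardation(jv, b45$z_top, b45$z_bottom)
    calib <- calibration_from_stripe_axes(s0$axis, s45$axis)
    axis <- apply_axis_calibration(pf$axis, calib)
    calib$p45 <- circ_mean_deg180(
      apply_axis_calibration(s45$axis, calib))$mean
    calib$p0 <- circ_mean_deg180(apply_axis_calibration(s0$axis, calib))$mean
  }
  bwoa <- compute_bwoa(pf$retardation, axis, refl, valid, dz)

  out <- list(reflectance = refl, attenuation = atten,
              retardation = pf$retardation, axis = axis,
              dopu = dopu, bwoa = bwoa, valid = valid,
              surface = surface, noise_floor_db = floor_db,
              calibration = calib, pitch = raw$pitch, dims = d)
  class(out) <- "channel_set"
  out
}

#' @export
print.channel_set <- function(x, ...) {
  cat("channel_set:", paste(x$dims, collapse = " x "),
      sprintf("| noise floor %.1f dB | %.1f%% voxels polarization-valid\n",
              x$noise_floor_db, 100 * mean(x$valid)))
  if (!is.null(x$calibration)) {
    cat(sprintf("  axis calibration: offset %.1f deg, chirality %+d (P0 -> %.2f, P45 -> %.2f)\n",
                x$calibration$offset, x$calibration$chirality,
                x$calibration$p0, x$calibration$p45))
  }
  invisible(x)
}
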