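#' Inter-repeat decorrelation angiography
#'
#' Voxelwise 1 - mean over adjacent repeat pairs of the magnitude of the
#' locally averaged normalized complex correlation. Static tissue (frozen
#' speckle) scores ~0; flowing blood decorrelates the speckle between
#' repeats and scores towards 1.
#'
#' @param raw a `raw_acquisition` with >= 2 repeats.
#' @param kernel odd (z, x) averaging kernel for the correlation estimate.
#' @return array (nz, nx, ny) of decorrelation values in [0, 1].
#' @export
compute_angio <- function(raw, kernel = c(3L, 3L)) {
  d <- dim(raw$field)
  nrep <- d[5]
  if (nrep < 2L) stop("angiography needs at least 2 repeats")
  nz <- d[1]; nx <- d[2] %/% 2L; ny <- d[3]
  odd <- seq(1L, d[2], by = 2L)
  acc <- array(0, c(nz, nx, ny))
  eps <- 1e-30
  for (r in seq_len(nrep - 1L)) {
    e1a <- raw$field[, odd, , 1L, r];     e1b <- raw$field[, odd, , 2L, r]
    e2a <- raw$field[, odd, , 1L, r + 1L]; e2b <- raw$field[, odd, , 2L, r + 1L]
    dim(e1a) <- dim(e1b) <- dim(e2a) <- dim(e2b) <- c(nz, nx, ny)
    for (y in seq_len(ny)) {
      num <- box_mean_2d_cplx(
        matrix(e1a[, , y] * Conj(e2a[, , y]) + e1b[, , y] * Conj(e2b[, , y]),
               nz, nx), kernel[1], kernel[2])
      p1 <- box_mean_2d(matrix(Mod(e1a[, , y])^2 + Mod(e1b[, , y])^2, nz, nx),
                        kernel[1], kernel[2])
      p2 <- box_mean_2d(matrix(Mod(e2a[, , y])^2 + Mod(e2b[, , y])^2, nz, nx),
                        kernel[1], kernel[2])
      acc[, , y] <- acc[, , y] + Mod(num) / sqrt(p1 * p2 + eps)
    }
  }
  pmin(pmax(1 - acc / (nrep - 1L), 0), 1)
}

#' En-face average-intensity projection below the tissue surface
#'
#' @param volume array (nz, nx, ny).
#' @param surface integer matrix (nx, ny) of surface indices.
#' @param window_um c(lo, hi) depth window below the surface, micrometres.
#' @param dz_um axial pitch.
#' @return matrix (ny, nx) of class `enface_image` with the depth window and
#'   pitch stored as attributes.
#' @export
project_enface <- function(volume, surface, window_um, dz_um) {
  d <- dim(volume)
  z0 <- round(window_um[1] / dz_um); z1 <- round(window_um[2] / dz_um)
  if (z1 < z0) stop("empty depth window")
  img <- matrix(NA_real_, d[3], d[2])
  for (x in seq_len(d[2])) {
    for (y in seq_len(d[3])) {
      s <- surface[x, y]
      if (!is.finite(s)) next
      zz <- max(1L, s + z0):min(d[1], s + z1)
      if (length(zz) == 0L) next
      img[y, x] <- mean(volume[zz, x, y], na.rm = TRUE)
    }
  }
  structure(img, class = c("enface_image", "matrix"),
            window_um = window_um, dz_um = dz_um)
}

#' Suppress horizontal motion-artifact lines in an en-face image
#'
#' Each row is divided by the ratio of its mean to a running-median-smoothed
#' row-mean profile, flattening single-row intensity jumps while leaving
#' column (vessel) structure untouched.
#'
#' @param img en-face image, rows = slow axis.
#' @param window odd running-median window in rows (>= 3).
#' @return corrected image.
#' @export
remove_motion_lines <- function(img, window = 5L) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  m <- rowMeans(img, na.rm = TRUE)
  if (nrow(img) <= window) return(img)
  msm <- stats::runmed(m, window, endrule = "median")
  fac <- ifelse(abs(msm) > 1e-12, m / msm, 1)
  out <- img / fac
  attributes(out) <- attributes(img)
  out
}

#' Rigid integer-shift co-registration of two en-face images
#'
#' Exhaustively maximises the normalized cross-correlation over integer
#' (dy, dx) shifts and crops both images to the overlap, mirroring a
#' crop-to-overlap tiling strategy. Rotation and scaling are deliberately
#' not corrected.
#'
#' @param fixed,moving en-face images (matrices of equal orientation).
#' @param max_shift largest |shift| searched per axis.
#' @param min_overlap smallest permissible overlap fraction of the fixed
#'   image area.
#' @param ncc_floor peak NCC below which registration is flagged failed.
#' @return list with `shift` = c(dy, dx) to apply to `moving`, `ncc`,
#'   `failed`, and the cropped co-registered `fixed` / `moving` images.
#' @export
register_enface <- function(fixed, moving, max_shift = 20L,
                            min_overlap = 0.25, ncc_floor = 0.2) {
  fill_na <- function(img) {
    if (anyNA(img)) img[is.na(img)] <- mean(img, na.rm = TRUE)
    img
  }
  fixed <- fill_na(unclass(fixed)); moving <- fill_na(unclass(moving))
  nr <- nrow(fixed); nc <- ncol(fixed)
  best <- list(ncc = -Inf, shift = c(0L, 0L))
  for (dy in -max_shift:max_shift) {
    rf <- max(1, 1 + dy):min(nr, nrow(moving) + dy)
    if (length(rf) < 2) next
    for (dx in -max_shift:max_shift) {
      cf <- max(1, 1 + dx):min(nc, ncol(moving) + dx)
      if (length(cf) < 2) next
      if (length(rf) * length(cf) < min_overlap * nr * nc) next
      a <- fixed[rf, cf]
      b <- moving[rf - dy, cf - dx]
      sa <- stats::sd(a); sb <- stats::sd(b)
      if (sa < 1e-12 || sb < 1e-12) next
      ncc <- mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
      if (ncc > best$ncc) best <- list(ncc = ncc, shift = c(dy, dx))
    }
  }
  dy <- best$shift[1]; dx <- best$shift[2]
  rf <- max(1, 1 + dy):min(nr, nrow(moving) + dy)
  cf <- max(1, 1 + dx):min(nc, ncol(moving) + dx)
  # moving[r, c] overlays fixed[r + dy - dy, ...]: the displacement of the
  # moving image relative to the fixed one is -(dy, dx)
  list(shift = -best$shift, ncc = best$ncc,
       failed = !is.finite(best$ncc) || best$ncc < ncc_floor,
       fixed = fixed[rf, cf], moving = moving[rf - dy, cf - dx])
}

#' Vessel diameter as full width at half maximum of a profile cut
#'
#' Samples the image along a segment crossing the vessel, defines the
#' background as the mean of the outer 20% of samples at both ends, and
#' returns the linearly interpolated width at half prominence, scaled to
#' micrometres.
#'
#' @param img en-face image.
#' @param p0,p1 segment endpoints c(row, col) in pixels.
#' @param pitch_um image pixel pitch (um/px, assumed isotropic in-plane).
#' @param oversample profile samples per pixel of segment length.
#' @param min_prominence reject measurements whose peak rises less than this
#'   fraction of the background-subtracted image range above background.
#' @return list with `fwhm_um`, `fwhm_px`, `profile`, `peak`, `background`,
#'   `rejected`.
#' @export
measure_vessel_fwhm <- function(img, p0, p1, pitch_um,
                                oversample = 4L, min_prominence = 0) {
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- max(9L, ceiling(len_px * oversample) + 1L)
  tt <- seq(0, 1, length.out = n)
  rr <- p0[1] + tt * (p1[1] - p0[1])
  cc <- p0[2] + tt * (p1[2] - p0[2])
  prof <- bilinear_sample(img, rr, cc)
  k <- max(1L, floor(0.2 * n / 2))
  bg <- mean(c(prof[seq_len(k)], prof[(n - k + 1L):n]))
  interior <- (k + 1L):(n - k)
  ipk <- interior[which.max(prof[interior])]
  peak <- prof[ipk]
  if (peak - bg <= min_prominence || peak <= bg) {
    return(list(fwhm_um = NA_real_, fwhm_px = NA_real_, profile = prof,
                peak = peak, background = bg, rejected = TRUE))
  }
  half <- bg + (peak - bg) / 2
  cross <- function(idx) {       # linear interpolation to the half level
    for (i in idx) {
      a <- prof[i]; b <- prof[i + 1L]
      lo <- min(a, b); hi <- max(a, b)
      if (half >= lo && half <= hi && a != b) {
        return(i + (half - a) / (b - a))
      }
    }
    NA_real_
  }
  left <- cross(rev(seq_len(ipk - 1L)))
  right <- cross(ipk:(n - 1L))
  if (!is.finite(left) || !is.finite(right)) {
    return(list(fwhm_um = NA_real_, fwhm_px = NA_real_, profile = prof,
                peak = peak, background = bg, rejected = TRUE))
  }
  dt_px <- len_px / (n - 1)
  fw_px <- (right - left) * dt_px
  list(fwhm_um = fw_px * pitch_um, fwhm_px = fw_px, profile = prof,
       peak = peak, background = bg, rejected = FALSE)
}

#' Vessel coverage fraction inside a density ROI
#'
#' Pipeline: percentile contrast rescale, global threshold (Otsu by default,
#' or a fixed empirically chosen value), binary opening then closing for
#' morphological noise reduction, then the percentage of ROI pixels inside
#' the vessel mask.
#'
#' @param img en-face angiogram.
#' @param roi logical matrix, the density ROI.
#' @param threshold "otsu" or a numeric threshold on the rescaled [0,1]
#'   image.
#' @param open_radius,close_radius disc radii (px) of the morphological
#'   opening/closing; 0 disables.
#' @param rescale percentile pair for contrast rescaling.
#' @param filters FALSE skips rescaling and morphology (binary input).
#' @return list with `fraction` (percent), `mask`.
#' @export
compute_vessel_fraction <- function(img, roi = NULL, threshold = "otsu",
                                    open_radius = 1L, close_radius = 1L,
                                    rescale = c(0.01, 0.99), filters = TRUE) {
  x <- unclass(img)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(x), ncol(x))
  if (!any(roi)) stop("empty density ROI")
  if (filters) {
    qq <- stats::quantile(x, rescale, na.rm = TRUE)
    if (diff(qq) < 1e-12) qq <- range(x, na.rm = TRUE) + c(0, 1e-12)
    x <- pmin(pmax((x - qq[1]) / (qq[2] - qq[1]), 0), 1)
  }
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(x, range = c(0, 1))
  } else threshold
  mask <- x > thr
  if (filters) {
    if (open_radius > 0) {
      mask <- EBImage::opening(mask, EBImage::makeBrush(2L * open_radius + 1L,
                                                        "disc")) > 0
    }
    if (close_radius > 0) {
      mask <- EBImage::closing(mask, EBImage::makeBrush(2L * close_radius + 1L,
                                                        "disc")) > 0
    }
  }
  list(fraction = 100 * sum(mask & roi) / sum(roi), mask = mask)
}
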