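#' Presence/absence mask of one immunofluorescence channel
#'
#' Marks pixels whose fluorescence exceeds a background offset, relying on
#' presence rather than brightness so staining-intensity differences between
#' slides do not bias pixel counts.
#'
#' @param img RGB array (h, w, 3): red = myelin (P0), green = axons
#'   (beta-tubulin-III), blue = nuclei (DAPI).
#' @param channel "red", "green" or "blue".
#' @param offset background offset subtracted before the > 0 test (default 0
#'   for noise-free fluorescence); "otsu" derives a threshold from the
#'   channel histogram for real images with background haze.
#' @return logical matrix.
#' @export
mask_channel <- function(img, channel = c("red", "green", "blue"),
                         offset = 0) {
  channel <- match.arg(channel)
  ch <- img[, , match(channel, c("red", "green", "blue"))]
  if (identical(offset, "otsu")) {
    offset <- EBImage::otsu(ch / max(ch, 1e-12), range = c(0, 1)) *
      max(ch, 1e-12)
  }
  ch > offset
}

#' Count mask-positive pixels inside an ROI polygon
#'
#' Pixels count when their centres lie inside the polygon.
#'
#' @param mask logical matrix (rows = y, cols = x).
#' @param roi polygon matrix with columns (x, y) in pixel coordinates.
#' @return integer count.
#' @export
count_pixels <- function(mask, roi) {
  xr <- range(roi[, 1]); yr <- range(roi[, 2])
  xs <- max(1L, floor(xr[1])):min(ncol(mask), ceiling(xr[2]))
  ys <- max(1L, floor(yr[1])):min(nrow(mask), ceiling(yr[2]))
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  inside <- mgcv::in.out(rbind(roi, roi[1, ]), pts)
  pix <- pts[inside, , drop = FALSE]
  sum(mask[cbind(pix[, 2], pix[, 1])])
}

#' Myelin-to-axon pixel-count ratio
#'
#' @param red_count myelin (red) positive-pixel count.
#' @param green_count axon (green) positive-pixel count.
#' @return red/green, or NA when no axon pixels are present.
#' @export
myelin_axon_ratio <- function(red_count, green_count) {
  if (green_count <= 0) return(NA_real_)
  red_count / green_count
}
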