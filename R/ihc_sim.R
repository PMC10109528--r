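#' Default immunofluorescence composition for a three-fascicle section
#'
#' Per-fascicle target positive-pixel fractions for the three channels
#' (red = myelin, green = axons, blue = nuclei). Baseline values reflect a
#' healthy myelin-rich fascicle cross-section.
#'
#' @param dims image height and width (px).
#' @return composition list consumed by [simulate_ihc_image()].
#' @export
default_ihc_composition <- function(dims = c(300L, 360L)) {
  h <- dims[1]; w <- dims[2]
  list(dims = c(h, w),
       fascicles = data.frame(
         label = c("L", "C", "R"),
         cx = w * c(0.25, 0.50, 0.75), cy = h * c(0.5, 0.52, 0.5),
         rx = w * 0.10, ry = h * 0.28,
         red = 0.40, green = 0.30, blue = 0.08,
         stringsAsFactors = FALSE))
}

#' Simulate a noise-free immunofluorescence section with known pixel counts
#'
#' Renders per-fascicle RGB fluorescence with exact target positive-pixel
#' fractions (rounded to whole pixels, hence within 1% absolute of the
#' target) and zero signal outside the tissue, and stores the realised
#' ground-truth counts per ROI and channel.
#'
#' @param composition see [default_ihc_composition()]; fractions per channel
#'   must lie in [0, 1].
#' @param seed RNG seed for pixel placement and intensities.
#' @return list of class `ihc_image` with `img` (h x w x 3 array in [0, 1]),
#'   `rois` (named list of (x, y) polygons) and `truth` (data.frame of
#'   realised counts).
#' @export
simulate_ihc_image <- function(composition = default_ihc_composition(),
                               seed = 1L) {
  fr <- as.matrix(composition$fascicles[c("red", "green", "blue")])
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  h <- composition$dims[1]; w <- composition$dims[2]
  img <- array(0, c(h, w, 3L))
  rois <- list()
  truth <- list()
  set.seed(seed)
  ang <- seq(0, 2 * pi, length.out = 61L)[-61L]
  for (i in seq_len(nrow(composition$fascicles))) {
    f <- composition$fascicles[i, ]
    poly <- cbind(x = f$cx + f$rx * cos(ang), y = f$cy + f$ry * sin(ang))
    rois[[f$label]] <- poly
    xs <- max(1L, floor(f$cx - f$rx)):min(w, ceiling(f$cx + f$rx))
    ys <- max(1L, floor(f$cy - f$ry)):min(h, ceiling(f$cy + f$ry))
    pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
    inside <- pts[mgcv::in.out(rbind(poly, poly[1, ]), pts), , drop = FALSE]
    n <- nrow(inside)
    for (ch in 1:3) {
      target <- f[[c("red", "green", "blue")[ch]]]
      cnt <- round(target * n)
      if (cnt > 0) {
        pick <- inside[sample.int(n, cnt), , drop = FALSE]
        img[cbind(pick[, 2], pick[, 1], ch)] <-
          stats::runif(cnt, 0.3, 1)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        fascicle = f$label, channel = c("red", "green", "blue")[ch],
        count = cnt, roi_px = n, target_fraction = target,
        realized_fraction = cnt / n, stringsAsFactors = FALSE)
    }
  }
  out <- list(img = img, rois = rois, truth = do.call(rbind, truth),
              seed = seed)
  class(out) <- "ihc_image"
  out
}
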