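#' @keywords internal
"_PACKAGE"

# Angles are handled in degrees throughout; axis angles live on the
# half-circle [0, 180) and are averaged in the doubled-angle representation.

wrap180 <- function(theta) {
  out <- theta %% 180
  neg <- which(out < 0)
  out[neg] <- out[neg] + 180
  out
}

#' Circular mean of axis angles (degrees, modulo 180)
#'
#' Doubled-angle resultant mean: angles are mapped to the full circle by
#' doubling, vector-averaged, and halved back. Returns NA when no finite
#' values are supplied.
#'
#' @param theta numeric vector of angles in degrees.
#' @param na.rm drop non-finite values first.
#' @return list with `mean` (degrees in [0,180)) and `resultant` (mean
#'   resultant length in [0,1]).
#' @export
circ_mean_deg180 <- function(theta, na.rm = TRUE) {
  if (na.rm) theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) return(list(mean = NA_real_, resultant = NA_real_))
  z <- mean(exp(2i * theta * pi / 180))
  list(mean = wrap180(Arg(z) * 180 / pi / 2), resultant = Mod(z))
}

# signed smallest difference between two axis angles (deg, result in (-90, 90])
axis_diff_deg <- function(a, b) {
  d <- (a - b) %% 180
  d[d > 90] <- d[d > 90] - 180
  d
}

# standard complex circular Gaussian with unit power E|z|^2 = 1
rcnorm <- function(n) {
  complex(real = stats::rnorm(n, sd = sqrt(0.5)),
          imaginary = stats::rnorm(n, sd = sqrt(0.5)))
}

# deterministic substream derivation; keeps seeds within 32-bit range
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ids) {
    s <- (s * 69069 + as.double(k) * 104729 + 12345) %% 2147483647
  }
  as.integer(s)
}

# 2D box mean with edge renormalisation (kernel kz x kx, both odd)
box_mean_2d <- function(mat, kz, kx) {
  stopifnot(kz %% 2 == 1, kx %% 2 == 1)
  nz <- nrow(mat); nx <- ncol(mat)
  if (kz > nz || kx > nx) stop("kernel larger than image")
  run1 <- function(m, k, along) {
    if (k == 1) return(m)
    h <- (k - 1) / 2
    if (along == 1) {
      cs <- apply(m, 2, cumsum)
      cs <- rbind(matrix(0, 1, ncol(m)), cs)
      i <- seq_len(nrow(m))
      lo <- pmax(i - h, 1); hi <- pmin(i + h, nrow(m))
      (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
    } else {
      t(run1(t(m), k, 1))
    }
  }
  run1(run1(mat, kz, 1), kx, 2)
}

# complex-capable version (applied to Re and Im separately)
box_mean_2d_cplx <- function(mat, kz, kx) {
  complex(real = box_mean_2d(Re(mat), kz, kx),
          imaginary = box_mean_2d(Im(mat), kz, kx)) |>
    matrix(nrow(mat), ncol(mat))
}

# bilinear interpolation of a matrix at fractional (row, col) positions
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
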