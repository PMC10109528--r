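#' Axial point-spread-function width of a Gaussian swept source
#'
#' Round-trip coherence length in air: (2 ln 2 / pi) * lambda0^2 / dlambda.
#'
#' @param lambda0_nm centre wavelength (nm).
#' @param dlambda_nm full spectral bandwidth (nm).
#' @return FWHM of the axial PSF in micrometres.
#' @export
axial_psf_fwhm <- function(lambda0_nm, dlambda_nm) {
  if (any(lambda0_nm <= 0) || any(dlambda_nm <= 0)) {
    stop("wavelength and bandwidth must be positive")
  }
  (2 * log(2) / pi) * lambda0_nm^2 / dlambda_nm / 1000
}

#' Acquisition configuration for the tomogram simulator
#'
#' @param lambda0_nm,dlambda_nm swept-source centre wavelength and bandwidth.
#' @param n_repeats repeated frames per location (>= 2 for angiography).
#' @param snr_db signal-to-noise ratio at the tissue surface; `Inf` disables
#'   additive noise.
#' @param system_unitary 2x2 complex unitary with unit determinant modelling
#'   the fibre birefringence of the instrument, applied on both passes
#'   (measured matrix = t(U) %*% J_roundtrip %*% U).
#' @param input_states 2x2 complex matrix whose columns are the two probe
#'   polarization states interleaved on alternating A-lines. The system does
#'   not prescribe a particular pair; horizontal and 45-degree linear are the
#'   recorded default.
#' @param speckle simulate fully developed speckle (complex circular Gaussian
#'   per scatterer voxel). Disabled for noise-free identity checks.
#' @param apply_psf convolve the complex field axially with the Gaussian PSF.
#' @param seed integer RNG seed.
#' @export
acq_config <- function(lambda0_nm = 1310, dlambda_nm = 110,
                       n_repeats = 5L, snr_db = 30,
                       system_unitary = diag(2) + 0i,
                       input_states = cbind(c(1, 0), c(1, 1) / sqrt(2)),
                       speckle = TRUE, apply_psf = TRUE, seed = 1L) {
  cfg <- list(lambda0_nm = lambda0_nm, dlambda_nm = dlambda_nm,
              n_repeats = as.integer(n_repeats), snr_db = snr_db,
              system_unitary = system_unitary, input_states = input_states,
              speckle = speckle, apply_psf = apply_psf, seed = as.integer(seed))
  class(cfg) <- "acq_config"
  cfg
}

#' Random instrument unitary (fibre circular birefringence)
#'
#' Draws a real rotation by a uniform angle: a unit-determinant unitary whose
#' effect on the recovered optic axis is a rigid offset, the situation the
#' 0/45-degree stripe calibration is designed to undo.
#'
#' @param seed integer seed.
#' @return 2x2 rotation matrix (complex storage mode).
#' @export
random_system_unitary <- function(seed = 1L) {
  set.seed(seed)
  a <- stats::runif(1, -pi / 2, pi / 2)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2) + 0i
}

is_unitary <- function(u, tol = 1e-8) {
  max(Mod(u %*% Conj(t(u)) - diag(2))) < tol
}

# Gaussian convolution of a (nz, nx, ny) array along z, edge-renormalised.
conv_z_gauss <- function(arr, sigma_px) {
  if (sigma_px < 0.15) return(arr)
  r <- max(1L, ceiling(3 * sigma_px))
  w <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  d <- dim(arr)
  nz <- d[1]
  m <- matrix(arr, nz, prod(d[-1]))
  out <- matrix(0 + 0i, nz, ncol(m))
  norm <- numeric(nz)
  for (k in (-r):r) {
    src <- seq_len(nz) + k
    ok <- src >= 1 & src <= nz
    out[ok, ] <- out[ok, ] + w[k + r + 1] * m[src[ok], ]
    norm[ok] <- norm[ok] + w[k + r + 1]
  }
  array(out / norm, d)
}

#' Forward-simulate a polarization-diverse OCT acquisition
#'
#' Each tissue column is modelled as a stack of thin linear-retarder slabs
#' (retardance delta*dz at axis theta). The one-way cumulative Jones matrix
#' is the ordered slab product; reciprocity gives the round-trip matrix as
#' its transpose sandwich, and the instrument contributes
#' t(U) %*% J_rt %*% U. The backscattered amplitude follows
#' sqrt(backscatter) * exp(-integral mu dz), so intensity decays as
#' exp(-2 mu z); fully developed speckle multiplies each voxel by a complex
#' circular Gaussian that is frozen across repeats for static tissue and
#' decorrelates with AR(1) coefficient rho inside vessels. A depolarization
#' fraction mixes in an unpolarized field component. Additive complex
#' Gaussian noise is set by the surface SNR, and the field is blurred axially
#' by the source PSF.
#'
#' Alternating A-lines interleave the two probe states: odd A-line indices
#' (first of each pair) carry input state 1, even indices state 2; both
#' sample the same tissue column.
#'
#' @param truth a `phantom_truth`.
#' @param cfg an `acq_config`.
#' @return list of class `raw_acquisition` with `field` of dimension
#'   (nz, 2*nx A-lines, ny, 2 detection channels, n_repeats), the config and
#'   grid metadata.
#' @export
simulate_tomogram <- function(truth, cfg = acq_config()) {
  if (!is_unitary(cfg$system_unitary)) stop("system matrix is not unitary")
  if (!is.infinite(cfg$snr_db) && cfg$snr_db <= 0) stop("nonpositive SNR")
  if (Mod(det(cfg$input_states)) < 1e-6) stop("degenerate input states")
  nz <- truth$dims[1]; nx <- truth$dims[2]; ny <- truth$dims[3]
  dz <- truth$pitch[["axial"]]
  n <- nz * nx * ny
  nrep <- cfg$n_repeats

  # cumulative one-way Jones matrix down each column (vectorised over x, y)
  phi <- truth$delta * dz * pi / 180          # one-way slab retardance (rad)
  th2 <- 2 * truth$theta * pi / 180
  cph <- cos(phi / 2); sph <- sin(phi / 2)
  sa <- cph + 1i * sph * cos(th2)
  sb <- 1i * sph * sin(th2)
  sd <- cph - 1i * sph * cos(th2)

  dm <- c(nz, nx, ny)
  Ma <- array(0 + 0i, dm); Mb <- Ma; Mc <- Ma; Md <- Ma
  a <- matrix(1 + 0i, nx, ny); b <- matrix(0 + 0i, nx, ny)
  cc <- b; d <- a
  for (z in seq_len(nz)) {
    za <- sa[z, , ]; zb <- sb[z, , ]; zd <- sd[z, , ]
    a2 <- za * a + zb * cc; b2 <- za * b + zb * d
    c2 <- zb * a + zd * cc; d2 <- zb * b + zd * d
    a <- a2; b <- b2; cc <- c2; d <- d2
    Ma[z, , ] <- a; Mb[z, , ] <- b; Mc[z, , ] <- cc; Md[z, , ] <- d
  }

  # round trip (transpose sandwich) then instrument unitary on both passes
  Ra <- Ma * Ma + Mc * Mc
  Rb <- Ma * Mb + Mc * Md
  Rd <- Mb * Mb + Md * Md
  rm(Ma, Mb, Mc, Md)
  U <- cfg$system_unitary
  p11 <- Ra * U[1, 1] + Rb * U[2, 1]; p12 <- Ra * U[1, 2] + Rb * U[2, 2]
  p21 <- Rb * U[1, 1] + Rd * U[2, 1]; p22 <- Rb * U[1, 2] + Rd * U[2, 2]
  s11 <- U[1, 1] * p11 + U[2, 1] * p21
  s12 <- U[1, 1] * p12 + U[2, 1] * p22
  s21 <- U[1, 2] * p11 + U[2, 2] * p21
  s22 <- U[1, 2] * p12 + U[2, 2] * p22
  rm(Ra, Rb, Rd, p11, p12, p21, p22)

  # responses to the two probe states
  e <- cfg$input_states
  EA1 <- s11 * e[1, 1] + s12 * e[2, 1]; EA2 <- s21 * e[1, 1] + s22 * e[2, 1]
  EB1 <- s11 * e[1, 2] + s12 * e[2, 2]; EB2 <- s21 * e[1, 2] + s22 * e[2, 2]
  rm(s11, s12, s21, s22)

  # one-way attenuation -> round-trip intensity decay exp(-2 int mu dz)
  cmu <- apply(truth$mu * dz, c(2, 3), cumsum)
  amp <- sqrt(truth$backscatter) * exp(-cmu)
  f <- truth$depol
  w_pol <- sqrt(1 - f)

  set.seed(derive_seed(cfg$seed, 101L))
  eta <- if (any(f > 0)) {
    list(a1 = array(rcnorm(n), dm), a2 = array(rcnorm(n), dm),
         b1 = array(rcnorm(n), dm), b2 = array(rcnorm(n), dm))
  } else NULL

  i_ref <- mean(truth$backscatter[truth$backscatter > 0])
  sig_n <- if (is.infinite(cfg$snr_db)) 0 else sqrt(i_ref * 10^(-cfg$snr_db / 10))
  sigma_px <- axial_psf_fwhm(cfg$lambda0_nm, cfg$dlambda_nm) / 2.355 / dz

  field <- array(0 + 0i, c(nz, 2L * nx, ny, 2L, nrep))
  g <- NULL
  for (r in seq_len(nrep)) {
    set.seed(derive_seed(cfg$seed, 200L, r))
    if (cfg$speckle) {
      fresh <- array(rcnorm(n), dm)
      g <- if (r == 1L) fresh else truth$rho * g + sqrt(1 - truth$rho^2) * fresh
    } else {
      g <- array(1 + 0i, dm)
    }
    w <- amp * w_pol * g
    fa1 <- w * EA1; fa2 <- w * EA2; fb1 <- w * EB1; fb2 <- w * EB2
    if (!is.null(eta)) {
      wd <- amp * sqrt(f)
      fa1 <- fa1 + wd * eta$a1; fa2 <- fa2 + wd * eta$a2
      fb1 <- fb1 + wd * eta$b1; fb2 <- fb2 + wd * eta$b2
    }
    if (cfg$apply_psf) {
      fa1 <- conv_z_gauss(fa1, sigma_px); fa2 <- conv_z_gauss(fa2, sigma_px)
      fb1 <- conv_z_gauss(fb1, sigma_px); fb2 <- conv_z_gauss(fb2, sigma_px)
    }
    if (sig_n > 0) {
      fa1 <- fa1 + sig_n * rcnorm(n); fa2 <- fa2 + sig_n * rcnorm(n)
      fb1 <- fb1 + sig_n * rcnorm(n); fb2 <- fb2 + sig_n * rcnorm(n)
    }
    odd <- seq(1L, 2L * nx, by = 2L)
    field[, odd, , 1L, r] <- fa1; field[, odd, , 2L, r] <- fa2
    field[, odd + 1L, , 1L, r] <- fb1; field[, odd + 1L, , 2L, r] <- fb2
  }

  raw <- list(field = field, config = cfg, pitch = truth$pitch,
              dims = c(nz, nx, ny), noise_power = sig_n^2)
  class(raw) <- "raw_acquisition"
  raw
}

#' @export
print.raw_acquisition <- function(x, ...) {
  d <- dim(x$field)
  cat(sprintf(
    "raw_acquisition: %d z x %d A-lines x %d frames, %d channels, %d repeats\n",
    d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}
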