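#' Assemble the per-voxel measured Jones matrix from a raw acquisition
#'
#' Pairs the interleaved A-lines (odd index = probe state 1, even = state 2)
#' and solves J_meas = [E_1 | E_2] %*% solve([e_1 | e_2]) at every voxel.
#' Repeats are averaged coherently by default; for angiography pass a single
#' repeat index.
#'
#' @param raw a `raw_acquisition`.
#' @param repeats repeat indices to average (default all).
#' @return list of class `jones_volume` with `j`, a complex array of
#'   dimension (nz, nx pairs, ny, 4) holding (J11, J12, J21, J22).
#' @export
assemble_jones <- function(raw, repeats = NULL) {
  stopifnot(inherits(raw, "raw_acquisition"))
  S <- raw$config$input_states
  if (Mod(det(S)) < 1e-6) stop("degenerate (collinear) input states")
  Sinv <- solve(S)
  d <- dim(raw$field)
  nz <- d[1]; nal <- d[2]; ny <- d[3]
  nx <- nal %/% 2L
  repeats <- repeats %||% seq_len(d[5])
  odd <- seq(1L, nal, by = 2L)

  acc <- array(0 + 0i, c(nz, nx, ny, 4L))
  for (r in repeats) {
    A1 <- raw$field[, odd, , 1L, r, drop = FALSE]
    A2 <- raw$field[, odd, , 2L, r, drop = FALSE]
    B1 <- raw$field[, odd + 1L, , 1L, r, drop = FALSE]
    B2 <- raw$field[, odd + 1L, , 2L, r, drop = FALSE]
    dim(A1) <- dim(A2) <- dim(B1) <- dim(B2) <- c(nz, nx, ny)
    acc[, , , 1L] <- acc[, , , 1L] + A1 * Sinv[1, 1] + B1 * Sinv[2, 1]
    acc[, , , 2L] <- acc[, , , 2L] + A1 * Sinv[1, 2] + B1 * Sinv[2, 2]
    acc[, , , 3L] <- acc[, , , 3L] + A2 * Sinv[1, 1] + B2 * Sinv[2, 1]
    acc[, , , 4L] <- acc[, , , 4L] + A2 * Sinv[1, 2] + B2 * Sinv[2, 2]
  }
  out <- list(j = acc / length(repeats), dims = c(nz, nx, ny),
              pitch = raw$pitch, repeats = repeats)
  class(out) <- "jones_volume"
  out
}

# expand a (nx, ny) matrix to (nz, nx, ny) by replication along depth
expand_z <- function(m, nz) array(rep(m, each = nz), c(nz, dim(m)))

# Relative Jones matrix J(z_surf)^-1 J(z), eigen phase split and eigenvector
# axis, vectorised over the whole volume via the closed-form 2x2 eigensystem.
polar_fields <- function(jv, surface, ref_offset = 2L, axis_floor_deg = 4) {
  j <- jv$j
  nz <- jv$dims[1]; nx <- jv$dims[2]; ny <- jv$dims[3]

  zs <- pmin(pmax(surface + ref_offset, 1L), nz)
  bad_col <- !is.finite(zs)
  zs_idx <- ifelse(bad_col, 1L, zs)
  colgrid <- cbind(as.vector(zs_idx),
                   rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  pick <- function(k) matrix(j[cbind(colgrid, k)], nx, ny)
  a0 <- pick(1L); b0 <- pick(2L); c0 <- pick(3L); d0 <- pick(4L)
  det0 <- a0 * d0 - b0 * c0
  sing <- Mod(det0) < 1e-12
  det0[sing] <- 1
  ia <- expand_z(d0 / det0, nz);  ib <- expand_z(-b0 / det0, nz)
  ic <- expand_z(-c0 / det0, nz); id <- expand_z(a0 / det0, nz)

  r11 <- ia * j[, , , 1L] + ib * j[, , , 3L]
  r12 <- ia * j[, , , 2L] + ib * j[, , , 4L]
  r21 <- ic * j[, , , 1L] + id * j[, , , 3L]
  r22 <- ic * j[, , , 2L] + id * j[, , , 4L]

  tr <- r11 + r22
  dt <- r11 * r22 - r12 * r21
  disc <- sqrt(tr^2 - 4 * dt)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  psi_raw <- Arg(l1 / l2)                       # (-pi, pi]
  folded <- abs(psi_raw)

  # unwrap the folded phase split down each column, starting at the surface;
  # pixels between the surface and the reference plane sit at the reference
  # state and read zero
  psi <- array(NA_real_, c(nz, nx, ny))
  prev <- matrix(0, nx, ny)
  for (z in seq_len(nz)) {
    fz <- matrix(folded[z, , ], nx, ny)
    on <- z >= zs_idx & !bad_col
    pre <- z > (zs_idx - ref_offset) & z < zs_idx & !bad_col
    c1 <- 2 * pi * round((prev - fz) / (2 * pi)) + fz
    c2 <- 2 * pi * round((prev + fz) / (2 * pi)) - fz
    val <- ifelse(abs(c1 - prev) <= abs(c2 - prev), c1, c2)
    val <- pmax(val, 0)
    prev[on] <- val[on]
    pz <- matrix(NA_real_, nx, ny)
    pz[on] <- val[on]
    pz[pre] <- 0
    psi[z, , ] <- pz
  }

  ret_deg <- psi * 180 / pi

  # eigenvector of the eigenvalue with the leading phase
  sgn <- ifelse(psi_raw >= 0, 1, -1)
  lu <- (tr + sgn * disc) / 2
  v1a <- r12;       v2a <- lu - r11
  v1b <- lu - r22;  v2b <- r21
  na2 <- Mod(v1a)^2 + Mod(v2a)^2
  nb2 <- Mod(v1b)^2 + Mod(v2b)^2
  use_b <- nb2 > na2
  v1 <- ifelse(use_b, v1b, v1a)
  v2 <- ifelse(use_b, v2b, v2a)
  q <- Mod(v1)^2 - Mod(v2)^2
  u <- 2 * Re(v1 * Conj(v2))
  axis <- wrap180(0.5 * atan2(u, q) * 180 / pi)
  # past the 180-degree round-trip fold the leading eigenvector is the
  # orthogonal one; use the unwrapped phase to pick the branch
  swap <- (psi %% (2 * pi)) > pi
  axis[which(swap)] <- wrap180(axis[which(swap)] + 90)

  floor_rad <- axis_floor_deg * pi / 180
  axis[pmin(folded, pi - folded) < floor_rad] <- NA_real_
  axis[!is.finite(psi)] <- NA_real_
  if (any(sing)) {
    for (k in which(sing)) {
      xk <- (k - 1L) %% nx + 1L; yk <- (k - 1L) %/% nx + 1L
      ret_deg[, xk, yk] <- NA_real_; axis[, xk, yk] <- NA_real_
    }
  }
  dim(axis) <- c(nz, nx, ny)
  list(retardation = ret_deg, axis = axis,
       folded = folded, surface_ref = zs_idx)
}
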