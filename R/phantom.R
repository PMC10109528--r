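#' Default three-fascicle nerve phantom geometry
#'
#' Builds the geometry description of the digital nerve phantom used
#' throughout the package: a scattering tissue bed holding an epineurium
#' ellipse that contains three disjoint fascicles (labelled L/C/R by
#' proximity to the stimulation lead), a pair of birefringent calibration
#' stripes with optic axes at exactly 0 and 45 degrees flanking the tissue,
#' and epineurial vessels running along the slow axis. All positions scale
#' with the grid so the same description can be rendered at different sizes.
#'
#' Units: pitches in micrometres per pixel, attenuation in 1/um, birefringent
#' retardance in deg/um (one-way), axis angles in degrees on [0, 180).
#'
#' @param dims integer grid (depth z, lateral x in A-line pairs, slow axis y).
#' @param pitch c(axial, lateral) um per pixel.
#' @return a list of class `nerve_geometry`.
#' @export
default_nerve_geometry <- function(dims = c(192L, 96L, 40L),
                                   pitch = c(axial = 3.5, lateral = 10)) {
  nz <- dims[1]; nx <- dims[2]
  fr <- function(f, n) as.integer(round(f * n))
  # keep a clear air gap above the surface: the noise floor is estimated
  # from the shallowest rows
  surface_z <- max(10L, fr(0.065, nz))
  geom <- list(
    dims = as.integer(dims),
    pitch = c(axial = unname(pitch[1]), lateral = unname(pitch[2])),
    surface_z = surface_z,
    # scattering bed below the nerve keeps the attenuation tail exponential
    # backscatter tracks attenuation (constant single-scattering albedo),
    # the regime in which the depth-resolved attenuation estimator is exact
    bed = list(x0 = fr(0.13, nx), x1 = fr(0.88, nx),
               mu = 0.0035, delta = 0.02, theta = 90,
               backscatter = 0.875, depol = 0),
    epineurium = list(cx = fr(0.5, nx), cz = fr(0.5, nz),
                      rx = fr(0.33, nx), rz = fr(0.38, nz),
                      mu = 0.0035, delta = 0.02, theta = 90,
                      backscatter = 0.875, depol = 0),
    fascicles = data.frame(
      label = c("L", "C", "R"),
      cx = fr(c(0.28, 0.50, 0.72), nx),
      cz = fr(c(0.47, 0.49, 0.47), nz),
      rx = fr(c(0.095, 0.095, 0.095), nx),
      rz = fr(c(0.155, 0.165, 0.155), nz),
      delta = c(0.30, 0.25, 0.30),
      theta = c(20, 90, 150),
      mu = c(0.0045, 0.0040, 0.0050),
      backscatter = c(1.125, 1.0, 1.25),
      stringsAsFactors = FALSE),
    stripes = data.frame(
      label = c("P0", "P45"),
      x0 = c(fr(0.03, nx), fr(0.90, nx)),
      x1 = c(fr(0.10, nx), fr(0.97, nx)),
      z0 = c(surface_z + 2L, surface_z + 2L),
      z1 = c(surface_z + 2L + fr(0.10, nz), surface_z + 2L + fr(0.10, nz)),
      delta = c(0.35, 0.35),
      theta = c(0, 45),
      mu = c(0.0035, 0.0035),
      backscatter = c(1.3, 1.3),
      stringsAsFactors = FALSE),
    vessels = data.frame(
      x = fr(c(0.34, 0.50, 0.66), nx),
      z = fr(c(0.20, 0.185, 0.20), nz),
      radius_um = c(22, 28, 22),
      rho = c(0.3, 0.3, 0.3)),
    backscatter_texture_sd = 0.10
  )
  class(geom) <- "nerve_geometry"
  geom
}

label_codes <- c(none = 0L, L = 1L, C = 2L, R = 3L, P0 = 4L, P45 = 5L)

#' Render a ground-truth nerve phantom from a geometry description
#'
#' Produces the voxelwise truth maps the forward simulator consumes and the
#' reconstruction is validated against: backscatter amplitude, attenuation
#' mu (1/um), one-way birefringent retardance delta (deg/um), optic axis
#' theta (deg mod 180), depolarization fraction, flow correlation rho (1 =
#' static) and an integer label map (none/L/C/R/P0/P45). Maps are constant
#' along the slow axis apart from a seeded log-normal backscatter texture.
#'
#' @param geometry a `nerve_geometry`, see [default_nerve_geometry()].
#' @param seed integer seed for the backscatter texture.
#' @return a list of class `phantom_truth`.
#' @export
build_nerve_truth <- function(geometry = default_nerve_geometry(), seed = 1L) {
  g <- geometry
  nz <- g$dims[1]; nx <- g$dims[2]; ny <- g$dims[3]
  dz <- g$pitch[["axial"]]; dx <- g$pitch[["lateral"]]

  zi <- matrix(seq_len(nz), nz, nx)
  xi <- matrix(seq_len(nx), nz, nx, byrow = TRUE)

  mk <- function(val = 0) matrix(val, nz, nx)
  bs <- mk(); mu <- mk(); delta <- mk(); theta <- mk()
  depol <- mk(); rho <- mk(1); lab <- matrix(label_codes["none"], nz, nx)

  in_ellipse <- function(cx, cz, rx, rz) {
    ((xi - cx) / rx)^2 + ((zi - cz) / rz)^2 <= 1
  }

  bed <- g$bed
  bed_m <- xi >= bed$x0 & xi <= bed$x1 & zi >= g$surface_z
  set_region <- function(m, p) {
    bs[m] <<- p$backscatter; mu[m] <<- p$mu; delta[m] <<- p$delta
    theta[m] <<- wrap180(p$theta); depol[m] <<- p$depol %||% 0
  }
  set_region(bed_m, bed)

  epi <- g$epineurium
  epi_m <- in_ellipse(epi$cx, epi$cz, epi$rx, epi$rz) & zi >= g$surface_z
  set_region(epi_m, epi)

  tissue_m <- bed_m | epi_m

  fmasks <- list()
  for (i in seq_len(nrow(g$fascicles))) {
    f <- g$fascicles[i, ]
    m <- in_ellipse(f$cx, f$cz, f$rx, f$rz)
    fmasks[[f$label]] <- m
  }
  for (i in seq_along(fmasks)) {
    for (j in seq_along(fmasks)) {
      if (i < j && any(fmasks[[i]] & fmasks[[j]])) {
        stop("overlapping fascicle ellipses: ",
             names(fmasks)[i], " and ", names(fmasks)[j])
      }
    }
  }
  for (i in seq_len(nrow(g$fascicles))) {
    f <- g$fascicles[i, ]
    m <- fmasks[[f$label]]
    set_region(m, as.list(f))
    depol[m] <- 0
    lab[m] <- label_codes[f$label]
  }

  for (i in seq_len(nrow(g$stripes))) {
    s <- g$stripes[i, ]
    m <- xi >= s$x0 & xi <= s$x1 & zi >= s$z0 & zi <= s$z1
    if (any(m & tissue_m)) stop("calibration stripe overlaps tissue")
    set_region(m, as.list(s))
    lab[m] <- label_codes[s$label]
  }

  if (!is.null(g$vessels) && nrow(g$vessels) > 0) {
    for (i in seq_len(nrow(g$vessels))) {
      v <- g$vessels[i, ]
      m <- (((zi - v$z) * dz)^2 + ((xi - v$x) * dx)^2) <= v$radius_um^2
      m <- m & (tissue_m | lab > 0)
      rho[m] <- v$rho
    }
  }

  ex <- function(m) array(rep(m, ny), c(nz, nx, ny)) # extrude along y
  set.seed(seed)
  texture <- array(exp(stats::rnorm(nz * nx * ny,
                                    sd = g$backscatter_texture_sd %||% 0)),
                   c(nz, nx, ny))
  truth <- list(
    dims = c(nz, nx, ny), pitch = g$pitch, surface_z = g$surface_z,
    backscatter = ex(bs) * texture,
    mu = ex(mu), delta = ex(delta), theta = ex(theta),
    depol = ex(depol), rho = ex(rho), label = ex(lab),
    vessels = g$vessels, geometry = g, seed = seed
  )
  class(truth) <- "phantom_truth"
  truth
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:", paste(x$dims, collapse = " x "),
      sprintf("(z x x-pairs x y), pitch %.1f/%.1f um\n",
              x$pitch[["axial"]], x$pitch[["lateral"]]))
  cat("  labels present:",
      paste(names(label_codes)[label_codes %in% unique(as.vector(x$label))],
            collapse = ", "), "\n")
  invisible(x)
}

#' Logical voxel masks of the two calibration stripes
#'
#' @param truth a `phantom_truth`.
#' @return list with logical arrays `P0` and `P45`.
#' @export
stripe_masks <- function(truth) {
  list(P0 = truth$label == label_codes["P0"],
       P45 = truth$label == label_codes["P45"])
}

#' Fascicle cross-section ROI polygons derived from the phantom truth
#'
#' In study mode fascicle ROIs are drawn by hand; for synthetic cohorts they
#' are derived from the known fascicle ellipses, shrunk towards the centre so
#' boundary voxels blurred by the axial point-spread function stay outside.
#'
#' @param truth a `phantom_truth`.
#' @param shrink radial shrink factor applied to each ellipse (default 0.8).
#' @param n_vertices polygon resolution.
#' @return named list of polygons, each a matrix with columns (x, z) in pixel
#'   coordinates of the cross-sectional frame.
#' @export
fascicle_rois_from_truth <- function(truth, shrink = 0.8, n_vertices = 48L) {
  fas <- truth$geometry$fascicles
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  out <- list()
  for (i in seq_len(nrow(fas))) {
    f <- fas[i, ]
    out[[f$label]] <- cbind(x = f$cx + shrink * f$rx * cos(ang),
                            z = f$cz + shrink * f$rz * sin(ang))
  }
  out
}
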