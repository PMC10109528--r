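# File formats: volumes and en-face images go to multi-page TIFF with a JSON
# sidecar carrying the value scaling, grid metadata and a schema version;
# tabular data goes to CSV with a JSON sidecar. TIFF stores 32-bit samples
# scaled to the [min, max] recorded in the sidecar, so round trips are exact
# to ~2^-32 of the value range.

SCHEMA_VERSION <- "nervoct-1"

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  meta$schema_version <- SCHEMA_VERSION
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar: ", sp)
  meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                   error = function(e) stop("corrupted sidecar ", sp, ": ",
                                            conditionMessage(e)))
  if (!identical(meta$schema_version, SCHEMA_VERSION)) {
    stop("schema mismatch in ", sp, ": found '",
         meta$schema_version %||% "<none>", "', expected '", SCHEMA_VERSION, "'")
  }
  meta
}

#' Write a numeric volume (or image) to scaled 32-bit TIFF plus JSON sidecar
#'
#' Pages index the third dimension. Finite values are mapped to
#' [0.001, 1] of the sample range; the value 0 is reserved to encode
#' non-finite voxels, which the reader restores to NA.
#'
#' @param arr numeric array (nz, nx, ny) or matrix.
#' @param path output .tif path.
#' @param meta extra metadata stored in the sidecar.
#' @export
write_volume_tiff <- function(arr, path, meta = list()) {
  d <- dim(arr)
  if (length(d) == 2L) d <- c(d, 1L)
  a <- array(arr, d)
  na_idx <- !is.finite(a)
  rng <- range(a[!na_idx])
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  scaled <- 0.001 + 0.999 * (a - rng[1]) / (rng[2] - rng[1])
  scaled[na_idx] <- 0
  pages <- lapply(seq_len(d[3]), function(k) matrix(scaled[, , k], d[1], d[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_sidecar(path, c(meta, list(dims = d, vmin = rng[1], vmax = rng[2])))
  invisible(path)
}

#' @rdname write_volume_tiff
#' @return `read_volume_tiff` returns the array with metadata in
#'   `attr(, "meta")`.
#' @export
read_volume_tiff <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- meta$dims
  a <- array(0, d)
  for (k in seq_len(d[3])) a[, , k] <- pages[[k]]
  na_idx <- a < 5e-4
  a <- (a - 0.001) / 0.999 * (meta$vmax - meta$vmin) + meta$vmin
  a[na_idx] <- NA_real_
  if (d[3] == 1L) dim(a) <- d[1:2]
  attr(a, "meta") <- meta
  a
}

#' Write a reconstructed channel set to a directory
#'
#' One TIFF per scalar channel plus sidecars; grid pitch, noise floor,
#' calibration and validity mask are preserved.
#'
#' @param cs a `channel_set`.
#' @param dir output directory (created if needed).
#' @export
write_channelset <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  common <- list(pitch_um = as.list(cs$pitch),
                 noise_floor_db = cs$noise_floor_db,
                 calibration = cs$calibration)
  for (ch in c("reflectance", "attenuation", "retardation", "axis", "dopu")) {
    write_volume_tiff(cs[[ch]], file.path(dir, paste0(ch, ".tif")),
                      c(common, list(channel = ch)))
  }
  write_volume_tiff(cs$valid + 0, file.path(dir, "valid.tif"),
                    c(common, list(channel = "valid")))
  utils::write.csv(data.frame(x = seq_len(nrow(cs$surface)) |>
                                rep(times = ncol(cs$surface)),
                              y = rep(seq_len(ncol(cs$surface)),
                                      each = nrow(cs$surface)),
                              surface = as.vector(cs$surface)),
                   file.path(dir, "surface.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_channelset
#' @export
read_channelset <- function(dir) {
  out <- list()
  for (ch in c("reflectance", "attenuation", "retardation", "axis", "dopu")) {
    out[[ch]] <- read_volume_tiff(file.path(dir, paste0(ch, ".tif")))
  }
  meta <- attr(out$reflectance, "meta")
  out$valid <- read_volume_tiff(file.path(dir, "valid.tif")) > 0.5
  surf <- utils::read.csv(file.path(dir, "surface.csv"))
  out$surface <- matrix(surf$surface, max(surf$x), max(surf$y))
  out$pitch <- unlist(meta$pitch_um)
  out$noise_floor_db <- meta$noise_floor_db
  out$calibration <- meta$calibration
  out$dims <- dim(out$reflectance)
  class(out) <- "channel_set"
  out
}

#' Write/read a tabular record set as CSV plus JSON sidecar
#'
#' @param df data.frame.
#' @param path .csv path.
#' @param schema short schema label recorded in the sidecar.
#' @export
write_table_csv <- function(df, path, schema = "table") {
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, list(schema = schema, n_rows = nrow(df),
                           columns = names(df)))
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path, schema = NULL) {
  meta <- read_sidecar(path)
  if (!is.null(schema) && !identical(meta$schema, schema)) {
    stop("schema mismatch: found '", meta$schema, "', expected '", schema, "'")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an immunofluorescence image and its ROI polygons
#'
#' RGB goes to 8-bit TIFF; ROI vertices to CSV (label, x, y).
#'
#' @param ihc an `ihc_image`.
#' @param tiff_path,roi_path output paths.
#' @export
write_ihc <- function(ihc, tiff_path, roi_path) {
  tiff::writeTIFF(ihc$img, tiff_path, bits.per.sample = 8L)
  rois <- do.call(rbind, lapply(names(ihc$rois), function(lab) {
    data.frame(label = lab, x = ihc$rois[[lab]][, 1], y = ihc$rois[[lab]][, 2])
  }))
  write_table_csv(rois, roi_path, schema = "ihc_rois")
  invisible(tiff_path)
}

#' @rdname write_ihc
#' @export
read_ihc <- function(tiff_path, roi_path) {
  img <- tiff::readTIFF(tiff_path)
  df <- read_table_csv(roi_path, schema = "ihc_rois")
  rois <- lapply(split(df, df$label), function(s) cbind(x = s$x, y = s$y))
  list(img = img, rois = rois)
}
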