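#' Average a block of cross-sectional frames
#'
#' Arithmetic per-pixel mean, or — for the optic-axis channel, whose values
#' live on the 180-degree half-circle — a coherent mean: half the argument of
#' the doubled-angle resultant, masked where the resultant length indicates
#' incoherent axes.
#'
#' @param volume array (nz, nx, ny); frames are indexed by y.
#' @param center centre frame index.
#' @param n odd number of frames to average (default 25).
#' @param mode "arithmetic" or "coherent".
#' @param min_resultant coherent-mode mask threshold on the mean resultant
#'   length.
#' @return matrix (nz, nx).
#' @export
average_frames <- function(volume, center, n = 25L,
                           mode = c("arithmetic", "coherent"),
                           min_resultant = 0.3) {
  mode <- match.arg(mode)
  if (n %% 2 == 0) stop("n must be odd")
  h <- (n - 1L) / 2L
  idx <- (center - h):(center + h)
  if (min(idx) < 1L || max(idx) > dim(volume)[3]) {
    stop("averaging window out of bounds")
  }
  block <- volume[, , idx, drop = FALSE]
  if (mode == "arithmetic") {
    return(apply(block, c(1, 2), mean, na.rm = TRUE))
  }
  z <- exp(2i * block * pi / 180)
  zm <- apply(z, c(1, 2), function(w) mean(w[is.finite(w)]))
  out <- wrap180(Arg(zm) * 180 / pi / 2)
  out[!is.finite(zm) | Mod(zm) < min_resultant] <- NA_real_
  out
}

#' Evenly spaced analysis-region centres across the stimulation span
#'
#' Places k centres at the midpoints of k equal subdivisions of the span,
#' each carrying an n-frame averaging window. Overlapping windows are
#' permitted with a warning when the span is short.
#'
#' @param extent number of frames in the volume.
#' @param span c(lo, hi) frame range of the stimulation region.
#' @param k number of regions (default 5).
#' @param n frames per averaging window.
#' @return integer vector of k centre indices.
#' @export
pick_analysis_regions <- function(extent, span, k = 5L, n = 25L) {
  if (k < 1L) stop("k must be >= 1")
  if (span[1] < 1L || span[2] > extent) stop("span outside volume extent")
  centers <- span[1] + (2 * seq_len(k) - 1) / (2 * k) * (span[2] - span[1])
  centers <- as.integer(round(centers))
  if (k > 1L && min(diff(centers)) < n) {
    warning("analysis windows overlap: span too short for ", k,
            " non-overlapping ", n, "-frame windows")
  }
  centers
}

#' Mean channel value over a fascicle ROI
#'
#' Pixels whose centres fall inside the polygon and pass the validity mask
#' contribute an arithmetic mean (circular mean for the axis channel).
#' Records with too few valid pixels are flagged invalid and excluded from
#' downstream statistics.
#'
#' @param frame matrix (nz, nx) of channel values.
#' @param roi polygon matrix with columns (x, z) in frame pixel coordinates.
#' @param label fascicle label.
#' @param channel channel name; "axis" switches to circular averaging.
#' @param valid optional logical matrix of valid pixels.
#' @param min_valid minimum valid pixel count (default 50).
#' @param animal,group,timepoint,region metadata carried into the record.
#' @return one-row data.frame metric record.
#' @export
extract_fascicle_mean <- function(frame, roi, label, channel,
                                  valid = NULL, min_valid = 50L,
                                  animal = NA, group = NA,
                                  timepoint = NA, region = NA) {
  nz <- nrow(frame); nx <- ncol(frame)
  xr <- range(roi[, 1]); zr <- range(roi[, 2])
  xs <- max(1L, floor(xr[1])):min(nx, ceiling(xr[2]))
  zs <- max(1L, floor(zr[1])):min(nz, ceiling(zr[2]))
  pts <- cbind(rep(xs, each = length(zs)), rep(zs, length(xs)))
  inside <- mgcv::in.out(rbind(roi, roi[1, ]), pts)
  pix <- pts[inside, , drop = FALSE]
  vals <- frame[cbind(pix[, 2], pix[, 1])]
  ok <- is.finite(vals)
  if (!is.null(valid)) ok <- ok & valid[cbind(pix[, 2], pix[, 1])]
  n_ok <- sum(ok)
  value <- if (n_ok >= min_valid) {
    if (channel == "axis") circ_mean_deg180(vals[ok])$mean else mean(vals[ok])
  } else NA_real_
  data.frame(animal = animal, group = group, fascicle = label,
             channel = channel, timepoint = timepoint, region = region,
             value = value, n_valid = n_ok,
             valid = n_ok >= min_valid, stringsAsFactors = FALSE)
}

circ_delta_deg180 <- function(a, b) axis_diff_deg(a, b)

#' Delta-metric table: day-7 change referenced to the day-1 baseline
#'
#' Region values are first averaged per animal and timepoint, each animal
#' contributes (D7 - baseline), and groups are summarised by mean and SD
#' across animals. The axis channel uses circular averaging and the signed
#' smallest circular difference. A derived percent-change-versus-sham column
#' (100 * (delta_group - delta_SC) / |delta_SC|) is included; its
#' normalisation is one defensible reading of percent change against the
#' sham arm and is labelled as derived.
#'
#' @param records metric-record data.frame from [extract_fascicle_mean()]
#'   (columns animal, group, fascicle, channel, timepoint, region, value,
#'   valid).
#' @param baseline,followup timepoint labels (defaults "B" and "D7").
#' @param reference_group reference arm for the derived percent column.
#' @return list with `per_animal` (one delta per animal x fascicle x
#'   channel) and `table` (group x fascicle x channel summary).
#' @export
delta_metric <- function(records, baseline = "B", followup = "D7",
                         reference_group = "SC") {
  r <- records[records$valid & is.finite(records$value), , drop = FALSE]
  agg_mean <- function(df) {
    out <- list()
    for (key in unique(paste(df$animal, df$group, df$fascicle, df$channel,
                             df$timepoint, sep = "\r"))) {
      parts <- strsplit(key, "\r")[[1]]
      sel <- df$animal == parts[1] & df$group == parts[2] &
        df$fascicle == parts[3] & df$channel == parts[4] &
        df$timepoint == parts[5]
      v <- df$value[sel]
      m <- if (parts[4] == "axis") circ_mean_deg180(v)$mean else mean(v)
      out[[key]] <- data.frame(animal = parts[1], group = parts[2],
                               fascicle = parts[3], channel = parts[4],
                               timepoint = parts[5], value = m,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  tp <- agg_mean(r)

  base <- tp[tp$timepoint == baseline, ]
  fup <- tp[tp$timepoint == followup, ]
  key <- function(df) paste(df$animal, df$fascicle, df$channel, sep = "\r")
  m <- match(key(fup), key(base))
  paired <- !is.na(m)
  if (any(!paired)) {
    message(sum(!paired), " record(s) without a matching baseline excluded")
  }
  fup <- fup[paired, ]; base <- base[m[paired], ]
  delta <- ifelse(fup$channel == "axis",
                  circ_delta_deg180(fup$value, base$value),
                  fup$value - base$value)
  per_animal <- data.frame(animal = fup$animal, group = fup$group,
                           fascicle = fup$fascicle, channel = fup$channel,
                           delta = delta, stringsAsFactors = FALSE)

  cells <- unique(per_animal[c("group", "fascicle", "channel")])
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- per_animal$group == cells$group[i] &
      per_animal$fascicle == cells$fascicle[i] &
      per_animal$channel == cells$channel[i]
    d <- per_animal$delta[sel]
    data.frame(cells[i, ], mean = mean(d),
               sd = if (length(d) > 1) stats::sd(d) else NA_real_,
               n = length(d), row.names = NULL)
  }))
  ref_key <- paste(tab$fascicle, tab$channel, sep = "\r")
  ref <- tab[tab$group == reference_group, ]
  mref <- ref$mean[match(ref_key, paste(ref$fascicle, ref$channel, sep = "\r"))]
  tab$pct_vs_ref <- ifelse(abs(mref) > 1e-12,
                           100 * (tab$mean - mref) / abs(mref), NA_real_)
  list(per_animal = per_animal, table = tab)
}

#' Two-factor group statistics on per-animal delta values
#'
#' Two-way (group x fascicle) ANOVA on the per-animal deltas of one channel,
#' followed by Tukey-adjusted pairwise group contrasts within each fascicle.
#' A fully degenerate input (all values identical) reports F = 0, p = 1.
#'
#' @param per_animal data.frame with columns group, fascicle, delta (one
#'   channel; filter before calling), plus animal.
#' @return list with `anova` (data.frame of F tests) and `contrasts`
#'   (data.frame of Tukey-adjusted pairwise group comparisons per fascicle).
#' @export
group_stats <- function(per_animal) {
  dat <- per_animal
  dat$group <- factor(dat$group); dat$fascicle <- factor(dat$fascicle)
  n_animals <- tapply(dat$animal, dat$group, function(a) length(unique(a)))
  if (any(n_animals < 2)) stop("need >= 2 animals per group")
  if (stats::var(dat$delta) < .Machine$double.eps) {
    lev <- levels(dat$group)
    prs <- t(utils::combn(lev, 2))
    return(list(
      anova = data.frame(term = c("group", "fascicle", "group:fascicle"),
                         F = 0, p = 1),
      contrasts = do.call(rbind, lapply(levels(dat$fascicle), function(f) {
        data.frame(fascicle = f, contrast = paste(prs[, 1], "-", prs[, 2]),
                   estimate = 0, p = 1)
      }))))
  }
  fit <- stats::aov(delta ~ group * fascicle, data = dat)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  anova_tab <- data.frame(term = terms[terms != "Residuals"],
                          df = an$Df[terms != "Residuals"],
                          F = an$`F value`[terms != "Residuals"],
                          p = an$`Pr(>F)`[terms != "Residuals"])
  emm <- emmeans::emmeans(fit, ~ group | fascicle, data = dat)
  prs <- summary(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  contrasts <- data.frame(fascicle = prs$fascicle, contrast = prs$contrast,
                          estimate = prs$estimate, se = prs$SE,
                          p = prs$p.value, stringsAsFactors = FALSE)
  list(anova = anova_tab, contrasts = contrasts)
}

#' Repeated-measures statistics for a per-timepoint metric series
#'
#' One value per animal and timepoint (e.g. vessel diameter or vessel
#' fraction): repeated-measures ANOVA with animal as the error stratum,
#' then Tukey-adjusted pairwise timepoint contrasts.
#'
#' @param df data.frame with columns animal, timepoint, value.
#' @return list with `anova` and `contrasts` data.frames.
#' @export
group_stats_timecourse <- function(df) {
  dat <- df
  dat$animal <- factor(dat$animal)
  dat$timepoint <- factor(dat$timepoint)
  if (stats::var(dat$value) < .Machine$double.eps) {
    prs <- t(utils::combn(levels(dat$timepoint), 2))
    return(list(anova = data.frame(term = "timepoint", F = 0, p = 1),
                contrasts = data.frame(contrast = paste(prs[, 1], "-", prs[, 2]),
                                       estimate = 0, p = 1)))
  }
  # blocking on animal is the balanced-design equivalent of the
  # subject-stratum repeated-measures ANOVA and keeps the Tukey machinery
  # on an lm-type fit
  fit <- stats::aov(value ~ animal + timepoint, data = dat)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  i <- which(terms == "timepoint")
  anova_tab <- data.frame(term = "timepoint", df = an$Df[i],
                          F = an$`F value`[i], p = an$`Pr(>F)`[i])
  emm <- emmeans::emmeans(fit, ~ timepoint, data = dat)
  prs <- summary(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  list(anova = anova_tab,
       contrasts = data.frame(contrast = prs$contrast,
                              estimate = prs$estimate, p = prs$p.value))
}
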