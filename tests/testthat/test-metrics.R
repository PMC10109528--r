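test_that("frame averaging is arithmetic for scalars, coherent for axes", {
  vol <- array(0, c(4, 3, 5))
  for (y in 1:5) vol[, , y] <- y  # constant frames 1..5
  expect_equal(average_frames(vol, 2, 3L), matrix(2, 4, 3))

  same <- array(7, c(4, 3, 5))
  expect_equal(average_frames(same, 3, 5L), matrix(7, 4, 3))

  # axis pixels {10, 170}: coherent mean 0, never the arithmetic 90
  ax <- array(0, c(1, 1, 3))
  ax[1, 1, ] <- c(10, 170, 10)
  cm <- average_frames(ax, 2, 3L, mode = "coherent")
  expect_lt(axis_err(cm[1, 1], 0), 4)
  ax2 <- array(c(10, 170), c(1, 1, 2))
  z <- mean(exp(2i * c(10, 170) * pi / 180))
  expect_equal((Arg(z) * 90 / pi) %% 180, 0)  # doubled-angle oracle

  # incoherent axes are masked
  spread <- array(c(0, 60, 120), c(1, 1, 3))
  expect_true(is.na(average_frames(spread, 2, 3L, mode = "coherent")[1, 1]))

  expect_error(average_frames(vol, 1, 3L), "out of bounds")
  expect_error(average_frames(vol, 2, 4L), "odd")
})

test_that("analysis-region centres tile the stimulation span evenly", {
  expect_equal(pick_analysis_regions(400L, c(100, 300), k = 5L, n = 25L),
               c(120L, 160L, 200L, 240L, 280L))
  expect_equal(pick_analysis_regions(400L, c(100, 300), k = 1L, n = 25L),
               200L)
  # symmetric within the span: centres mirror about the span midpoint
  fwd <- pick_analysis_regions(400L, c(100, 300), k = 5L, n = 25L)
  expect_equal(fwd - 100L, rev(300L - fwd))
  expect_warning(pick_analysis_regions(400L, c(100, 140), k = 5L, n = 25L),
                 "overlap")
  expect_error(pick_analysis_regions(50L, c(10, 60), k = 2L), "extent")
})

test_that("fascicle ROI means respect the polygon, mask, and axis circle", {
  frame <- matrix(7, 40, 40)
  sq <- cbind(x = c(10, 30, 30, 10), z = c(10, 10, 30, 30))
  rec <- extract_fascicle_mean(frame, sq, "L", "retardation", min_valid = 10L)
  expect_equal(rec$value, 7)
  expect_true(rec$valid)

  # half 0 / half 10
  frame2 <- matrix(0, 40, 40); frame2[, 21:40] <- 10
  half <- cbind(x = c(11, 31, 31, 11) - 0.5, z = c(10.5, 10.5, 30.5, 30.5))
  rec2 <- extract_fascicle_mean(frame2, half, "L", "attenuation",
                                min_valid = 10L)
  expect_equal(rec2$value, 5)

  # axis channel: circular mean over balanced {10, 170} halves
  frame3 <- matrix(10, 40, 40); frame3[1:20, ] <- 170
  bal <- cbind(x = c(10, 30, 30, 10), z = c(10.5, 10.5, 30.5, 30.5))
  rec3 <- extract_fascicle_mean(frame3, bal, "L", "axis", min_valid = 10L)
  expect_lt(axis_err(rec3$value, 0), 1e-6)

  # too few valid pixels flags the record invalid
  vmask <- matrix(FALSE, 40, 40); vmask[15:16, 15:16] <- TRUE
  rec4 <- extract_fascicle_mean(frame, sq, "L", "retardation",
                                valid = vmask, min_valid = 50L)
  expect_false(rec4$valid)
  expect_true(is.na(rec4$value))
})

make_records <- function(d7_shift = function(g, f) 0, noise = 0) {
  groups <- c(SC = 3L, SL1 = 3L, SL2 = 3L)
  rows <- list()
  set.seed(99)
  for (g in names(groups)) for (i in seq_len(groups[[g]])) {
    for (f in c("L", "C", "R")) for (tp in c("B", "D7")) {
      for (rg in 1:2) {
        base <- 100
        v <- base + (if (tp == "D7") d7_shift(g, f) else 0) +
          stats::rnorm(1, sd = noise)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = paste0(g, i), group = g, fascicle = f,
          channel = "retardation", timepoint = tp, region = rg,
          value = v, n_valid = 100L, valid = TRUE)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("delta metric pairs D7 with baseline per animal and summarises", {
  # D7 identical to baseline: all deltas zero
  r0 <- make_records()
  d0 <- delta_metric(r0)
  expect_true(all(abs(d0$table$mean) < 1e-12))

  # per-animal deltas {1, 2, 3} -> mean 2, sd 1
  r1 <- make_records()
  idx <- r1$timepoint == "D7" & r1$group == "SL1" & r1$fascicle == "C"
  bump <- rep(c(1, 2, 3), each = 2)   # two regions per animal
  r1$value[idx] <- r1$value[idx] + bump
  d1 <- delta_metric(r1)
  cell <- d1$table[d1$table$group == "SL1" & d1$table$fascicle == "C", ]
  expect_equal(cell$mean, 2)
  expect_equal(cell$sd, 1)
  expect_equal(cell$n, 3L)

  # injected -20% drop in (SL2, R) only: that cell reads -20, others ~0
  r2 <- make_records(d7_shift = function(g, f)
    if (g == "SL2" && f == "R") -20 else 0, noise = 0.2)
  d2 <- delta_metric(r2)
  tab <- d2$table
  hot <- tab$group == "SL2" & tab$fascicle == "R"
  expect_lt(abs(tab$mean[hot] - (-20)), 0.6)   # within 3% of the drop
  expect_lt(max(abs(tab$mean[!hot])), 2)       # |delta| < 2% of baseline
  # the derived percent-vs-sham column normalises against the SC cell
  expect_true(is.na(tab$pct_vs_ref[hot]) || abs(tab$pct_vs_ref[hot]) > 100)

  # a missing baseline excludes that animal from the cell
  r3 <- make_records()
  r3 <- r3[!(r3$animal == "SC1" & r3$timepoint == "B"), ]
  expect_message(d3 <- delta_metric(r3), "excluded")
  expect_equal(d3$table$n[d3$table$group == "SC"], rep(2L, 3))
})

test_that("two-way ANOVA and Tukey contrasts match a sums-of-squares oracle", {
  # balanced 2 groups x 3 fascicles, 4 animals per cell
  set.seed(5)
  df <- expand.grid(rep = 1:4, group = c("A", "B"),
                    fascicle = c("L", "C", "R"),
                    stringsAsFactors = FALSE)
  df$animal <- paste0(df$group, df$rep)
  df$delta <- c(3, 4, 5, 4,   6, 7, 6, 7,   2, 3, 2, 3,
                5, 5, 6, 6,   8, 9, 8, 9,   4, 4, 5, 5)
  gs <- group_stats(df)

  # oracle: explicit sums of squares
  gm <- mean(df$delta)
  ssg <- sum(tapply(df$delta, df$group, function(v) length(v) *
                      (mean(v) - gm)^2))
  ssf <- sum(tapply(df$delta, df$fascicle, function(v) length(v) *
                      (mean(v) - gm)^2))
  cellm <- tapply(df$delta, list(df$group, df$fascicle), mean)
  ssc <- 4 * sum((cellm - gm)^2)
  ssi <- ssc - ssg - ssf
  sse <- sum((df$delta - cellm[cbind(df$group, df$fascicle)])^2)
  f_g <- (ssg / 1) / (sse / 18)
  f_f <- (ssf / 2) / (sse / 18)
  f_i <- (ssi / 2) / (sse / 18)
  expect_equal(gs$anova$F[gs$anova$term == "group"], f_g, tolerance = 1e-6)
  expect_equal(gs$anova$F[gs$anova$term == "fascicle"], f_f, tolerance = 1e-6)
  expect_equal(gs$anova$F[gs$anova$term == "group:fascicle"], f_i,
               tolerance = 1e-6)

  # all-identical data: F = 0, p = 1 by contract
  df0 <- df; df0$delta <- 5
  gs0 <- group_stats(df0)
  expect_true(all(gs0$anova$F == 0) && all(gs0$anova$p == 1))
  expect_true(all(gs0$contrasts$p == 1))

  # a huge injected effect is flagged in the right contrast
  dfe <- make_records(d7_shift = function(g, f)
    if (g == "SL2" && f == "R") -30 else 0, noise = 1)
  pa <- delta_metric(dfe)$per_animal
  gse <- group_stats(pa)
  hot <- gse$contrasts$fascicle == "R" &
    grepl("SL2", gse$contrasts$contrast) & grepl("SC", gse$contrasts$contrast)
  expect_lt(gse$contrasts$p[hot], 0.05)
  expect_error(group_stats(pa[pa$animal != "SC1" & pa$animal != "SC2", ]),
               "2 animals")
})

test_that("repeated-measures timecourse statistics flag timepoint effects", {
  set.seed(6)
  tps <- c("B", "S1", "S2", "R1", "R2", "D7")
  df <- expand.grid(animal = paste0("a", 1:6), timepoint = tps,
                    stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df), sd = 0.5) + ifelse(df$timepoint == "D7", 5, 0)
  gs <- group_stats_timecourse(df)
  expect_lt(gs$anova$p, 0.01)
  hot <- grepl("D7", gs$contrasts$contrast) & grepl("\\bB\\b", gs$contrasts$contrast)
  expect_true(any(gs$contrasts$p[hot] < 0.05))

  df0 <- df; df0$value <- 1
  gs0 <- group_stats_timecourse(df0)
  expect_equal(gs0$anova$F, 0)
  expect_equal(gs0$anova$p, 1)
})
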