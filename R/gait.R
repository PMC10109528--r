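# Walking-track composite indices. Coefficient sets follow the rodent
# walking-track literature; they are configuration constants so alternative
# published sets can be swapped in.
sfi_coefficients <- c(pl = -38.3, ts = 109.5, it = 13.3, intercept = -8.8)
tfi_coefficients <- c(pl = -37.2, ts = 104.4, it = 45.6, intercept = -8.8)

walking_track_index <- function(rec, coef) {
  n <- c(rec$NPL, rec$NTS, rec$NIT)
  if (any(!is.finite(n)) || any(n <= 0)) {
    stop("normal-side footprint parameters must be positive")
  }
  coef[["pl"]] * (rec$EPL - rec$NPL) / rec$NPL +
    coef[["ts"]] * (rec$ETS - rec$NTS) / rec$NTS +
    coef[["it"]] * (rec$EIT - rec$NIT) / rec$NIT +
    coef[["intercept"]]
}

#' Sciatic function index (SFI)
#'
#' Footprint-geometry composite of print length (PL), toe spread (TS) and
#' intermediary toe spread (IT), experimental (E, injured side) against
#' normal (N): SFI = -38.3 (EPL-NPL)/NPL + 109.5 (ETS-NTS)/NTS +
#' 13.3 (EIT-NIT)/NIT - 8.8. Approximately -8.8 indicates normal function
#' and -100 complete sciatic injury; ratios make the index scale-invariant.
#'
#' @param rec a `gait_record` or any list with fields EPL, ETS, EIT, NPL,
#'   NTS, NIT (lengths in consistent units).
#' @param coefficients named coefficient vector (pl, ts, it, intercept).
#' @return numeric index.
#' @export
sfi <- function(rec, coefficients = sfi_coefficients) {
  walking_track_index(rec, coefficients)
}

#' Tibial function index (TFI)
#'
#' Same construction as [sfi()] with the tibial coefficient set:
#' TFI = -37.2 (EPL-NPL)/NPL + 104.4 (ETS-NTS)/NTS + 45.6 (EIT-NIT)/NIT - 8.8.
#'
#' @inheritParams sfi
#' @export
tfi <- function(rec, coefficients = tfi_coefficients) {
  walking_track_index(rec, coefficients)
}

#' Summarise Von Frey paw-withdrawal forces
#'
#' @param ipsilateral,contralateral numeric vectors of withdrawal forces
#'   (typically 5 trials per limb).
#' @return list with per-limb mean and SD and the ipsi/contra ratio.
#' @export
von_frey_summary <- function(ipsilateral, contralateral) {
  if (length(ipsilateral) < 1 || length(contralateral) < 1) {
    stop("need at least one valid trial per limb")
  }
  list(ipsi_mean = mean(ipsilateral), ipsi_sd = stats::sd(ipsilateral),
       contra_mean = mean(contralateral), contra_sd = stats::sd(contralateral),
       ratio = mean(ipsilateral) / mean(contralateral))
}

#' Simulate a walking-track footprint record at a given deficit level
#'
#' Normal-side parameters are drawn around configured means; the
#' experimental side shifts towards the injured pattern — longer print,
#' narrower toe spreads — in proportion to the deficit d, with d = 1 tuned
#' so the SFI lands near -100 (complete injury) and d = 0 reproducing the
#' normal side exactly (SFI = -8.8).
#'
#' @param deficit deficit level in [0, 1].
#' @param seed RNG seed.
#' @param animal,timepoint metadata labels.
#' @param means normal-side means c(PL, TS, IT) in mm.
#' @param cv coefficient of variation of the normal-side draw.
#' @return list of class `gait_record`.
#' @export
simulate_gait <- function(deficit, seed = 1L, animal = NA, timepoint = NA,
                          means = c(PL = 28, TS = 14, IT = 7), cv = 0.03) {
  if (deficit < 0 || deficit > 1) stop("deficit must be in [0, 1]")
  set.seed(seed)
  normal <- means * (1 + stats::rnorm(3, sd = cv))
  exper <- c(normal[1] * (1 + 0.40 * deficit),
             normal[2] * (1 - 0.60 * deficit),
             normal[3] * (1 - 0.60 * deficit))
  rec <- list(animal = animal, timepoint = timepoint, deficit = deficit,
              NPL = normal[[1]], NTS = normal[[2]], NIT = normal[[3]],
              EPL = exper[[1]], ETS = exper[[2]], EIT = exper[[3]])
  class(rec) <- "gait_record"
  rec
}
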