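#' Stimulation specification for a study arm
#'
#' Presets mirror the three study arms: sham control SC (0.0 mA / 0 Hz),
#' SL1 (3.4 mA / 50 Hz) and SL2 (6.8 mA / 100 Hz), all with a cathodic-first
#' charge-balanced square wave of 100 us pulse width and 400 us interphase
#' delay delivered through a 0.05 mm diameter hemi-cuff electrode pair with
#' 0.2 mm (positive) and 0.4 mm (negative) deinsulated lengths.
#'
#' @param group "SC", "SL1" or "SL2", or NULL to pass explicit values.
#' @param amplitude_mA,frequency_Hz,pulse_width_us,interphase_us waveform
#'   parameters.
#' @param electrode_diameter_mm,deinsulated_mm_pos,deinsulated_mm_neg
#'   electrode geometry.
#' @return list of class `stim_spec`.
#' @export
stim_spec <- function(group = NULL, amplitude_mA = 0, frequency_Hz = 0,
                      pulse_width_us = 100, interphase_us = 400,
                      electrode_diameter_mm = 0.05,
                      deinsulated_mm_pos = 0.2, deinsulated_mm_neg = 0.4) {
  if (!is.null(group)) {
    group <- toupper(group)
    preset <- switch(group,
                     SC = c(0, 0), SL1 = c(3.4, 50), SL2 = c(6.8, 100),
                     stop("unknown group: ", group))
    amplitude_mA <- preset[1]; frequency_Hz <- preset[2]
  }
  if (amplitude_mA < 0 || frequency_Hz < 0) stop("amplitude/frequency must be >= 0")
  if (pulse_width_us <= 0) stop("pulse width must be positive")
  spec <- list(group = group %||% NA_character_,
               amplitude_mA = amplitude_mA, frequency_Hz = frequency_Hz,
               pulse_width_us = pulse_width_us, interphase_us = interphase_us,
               electrode_diameter_mm = electrode_diameter_mm,
               deinsulated_mm_pos = deinsulated_mm_pos,
               deinsulated_mm_neg = deinsulated_mm_neg)
  class(spec) <- "stim_spec"
  spec
}

#' Shannon-model stimulation dose
#'
#' Charge per phase Q = I * PW, geometric electrode area A = pi * d * L
#' (full lateral cylinder area of the positive 0.2 mm lead), charge density
#' D = Q / A, and the Shannon parameter k = log10(D) + log10(Q) with Q in uC
#' and D in uC/cm^2. Values of k above ~1.85 are associated with tissue
#' damage; frequency does not enter the model.
#'
#' The full-cylinder positive-lead area is the unique simple geometric
#' convention that reproduces both study arms' printed k values from the
#' printed current, pulse width, and electrode dimensions.
#'
#' @param spec a `stim_spec`.
#' @return list with `Q_uC`, `A_cm2`, `D_uC_cm2`, `k`; for a sham spec
#'   (I = 0), `k`, `Q_uC` and `D_uC_cm2` are NA ("not applicable").
#' @export
shannon_k <- function(spec) {
  stopifnot(inherits(spec, "stim_spec"))
  A_cm2 <- pi * spec$electrode_diameter_mm * spec$deinsulated_mm_pos / 100
  if (spec$amplitude_mA <= 0) {
    return(list(Q_uC = NA_real_, A_cm2 = A_cm2, D_uC_cm2 = NA_real_,
                k = NA_real_, applicable = FALSE))
  }
  Q_uC <- spec$amplitude_mA * spec$pulse_width_us * 1e-3  # mA*us = nC -> uC
  D <- Q_uC / A_cm2
  list(Q_uC = Q_uC, A_cm2 = A_cm2, D_uC_cm2 = D,
       k = log10(Q_uC * D), applicable = TRUE)
}

#' Sampled stimulation current waveform
#'
#' Cathodic-first charge-balanced square wave: each period holds -I for one
#' pulse width, 0 for the interphase delay, +I for one pulse width, then 0
#' until the next period. Net charge per period is exactly zero.
#'
#' @param spec a `stim_spec`.
#' @param duration_s trace duration (s).
#' @param fs sample rate (Hz); must resolve the pulse width with >= 10
#'   samples per phase.
#' @return numeric vector of current samples (mA).
#' @export
generate_waveform <- function(spec, duration_s, fs) {
  n_total <- round(duration_s * fs)
  if (spec$amplitude_mA == 0 || spec$frequency_Hz == 0) {
    return(numeric(n_total))
  }
  active_us <- 2 * spec$pulse_width_us + spec$interphase_us
  if (spec$frequency_Hz * active_us > 1e6) stop("invalid spec: phases overlap")
  if (fs * spec$pulse_width_us * 1e-6 < 10) {
    stop("sample rate too low to resolve the pulse width")
  }
  n_period <- round(fs / spec$frequency_Hz)
  n_pw <- round(spec$pulse_width_us * 1e-6 * fs)
  n_gap <- round(spec$interphase_us * 1e-6 * fs)
  period <- numeric(n_period)
  period[seq_len(n_pw)] <- -spec$amplitude_mA
  period[n_pw + n_gap + seq_len(n_pw)] <- spec$amplitude_mA
  rep_len(period, n_total)
}
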