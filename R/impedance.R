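#' Aortic input impedance from an ensemble-averaged beat
#'
#' Treats the averaged beat as one period of a periodic signal and forms
#' the harmonic impedance `Z(k) = P(k) / Q(k)` from the discrete Fourier
#' coefficients of pressure (converted to dyn/cm2) and flow (cm3/s).
#' `Z0`, the zero-frequency modulus, equals mean pressure over mean flow
#' and measures total LV afterload; the characteristic impedance `Zc` is
#' extracted by [characteristic_impedance].  Harmonics whose flow
#' coefficient is below `mask_rel * |Q(1)|` are masked: the near-zero
#' denominator makes their modulus meaningless and they are excluded
#' from the Zc average.
#'
#' @param beat an `ensemble_beat` with pressure and flow.
#' @param mask_rel relative flow-coefficient threshold below which a
#'   harmonic is masked.
#' @param f_lo,f_hi band (Hz) passed on to [characteristic_impedance].
#' @return an object of class `impedance_spectrum`: `f_hz` (harmonic
#'   frequencies, `f_hz[1] = 0`), `modulus_dyn_s_cm5`, `phase_rad`,
#'   `masked` (logical), `z0_dyn_s_cm5`, `zc_dyn_s_cm5`.
#' @export
input_impedance <- function(beat, mask_rel = 1e-6, f_lo = 1, f_hi = 10) {
  if (is.null(beat$p_mmhg) || is.null(beat$q_ml_s)) {
    stop("input impedance needs both pressure and flow traces",
         call. = FALSE)
  }
  p <- convert_units(beat$p_mmhg, "mmHg", "dyn/cm2")
  q <- beat$q_ml_s                       # mL/s == cm3/s
  n <- length(p)
  if (length(q) != n) stop("pressure and flow lengths differ", call. = FALSE)
  if (abs(mean(q)) < .Machine$double.eps * max(abs(q), 1)) {
    stop("impedance undefined: mean flow is zero (Z0 = P/Q at DC)",
         call. = FALSE)
  }
  ph <- stats::fft(p) / n
  qh <- stats::fft(q) / n
  k <- 0:(n %/% 2)
  f <- k * beat$fs_hz / n
  masked <- Mod(qh[k + 1L]) < mask_rel * Mod(qh[2L])
  masked[1L] <- FALSE                    # DC carries Z0
  z <- ph[k + 1L] / qh[k + 1L]
  spec <- structure(
    list(f_hz = f,
         modulus_dyn_s_cm5 = Mod(z),
         phase_rad = Arg(z),
         masked = masked,
         z0_dyn_s_cm5 = Mod(z[1L]),
         zc_dyn_s_cm5 = NA_real_),
    class = "impedance_spectrum")
  spec$zc_dyn_s_cm5 <- characteristic_impedance(spec, f_lo, f_hi)
  spec
}

#' Characteristic impedance as the mean modulus over a frequency band
#'
#' Zc is the pulsatile pressure-to-flow ratio in the absence of wave
#' reflections; from a single periodic beat it is estimated as the
#' unweighted arithmetic mean of the input-impedance moduli at all
#' harmonics of the beat fundamental whose frequency lies in the closed
#' band `[f_lo, f_hi]` Hz (default 1-10 Hz), skipping masked harmonics.
#'
#' @param spectrum an `impedance_spectrum`.
#' @param f_lo,f_hi band limits, Hz.
#' @return Zc in dyn s cm-5.
#' @export
characteristic_impedance <- function(spectrum, f_lo = 1, f_hi = 10) {
  keep <- spectrum$f_hz >= f_lo & spectrum$f_hz <= f_hi &
    spectrum$f_hz > 0 & !spectrum$masked
  if (!any(keep)) {
    stop("no usable harmonic in [", f_lo, ", ", f_hi, "] Hz (fundamental ",
         format(spectrum$f_hz[2L], digits = 4), " Hz)", call. = FALSE)
  }
  mean(spectrum$modulus_dyn_s_cm5[keep])
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  nh <- sum(!x$masked) - 1L
  cat(sprintf("impedance_spectrum: fundamental %.3g Hz, %d usable harmonics\n",
              x$f_hz[2L], nh))
  cat(sprintf("  Z0 = %.1f, Zc = %.1f dyn s cm-5\n",
              x$z0_dyn_s_cm5, x$zc_dyn_s_cm5))
  invisible(x)
}
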