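#' Linear forward/backward pressure wave separation
#'
#' With the diastolic offset removed (`p~ = P - min(P)`), the measured
#' pressure and flow decompose into a forward and a backward travelling
#' wave:
#' \deqn{P_f = (\tilde p + Z_c Q)/2, \qquad P_b = (\tilde p - Z_c Q)/2,}
#' so that `Pf + Pb` reconstructs the offset-free pressure and
#' `(Pf - Pb)/Zc` the flow, exactly.  The reflection magnitude is the
#' ratio of peak-trough amplitudes `RM = |Pb|/|Pf|` and the reflection
#' index `RI = |Pb|/(|Pf| + |Pb|) = RM/(1 + RM)`.
#'
#' Because published tables sometimes reference the forward wave to the
#' absolute pressure level rather than to the diastolic baseline, the
#' result also carries `pf_peak_abs_mmhg` (offset + forward peak); RM and
#' RI always use the peak-trough amplitudes.
#'
#' @param beat an `ensemble_beat` with pressure and flow.
#' @param zc characteristic impedance, dyn s cm-5 (> 0), typically from
#'   [characteristic_impedance].
#' @return an object of class `wave_separation` with `pf_trace_mmhg`,
#'   `pb_trace_mmhg`, `offset_mmhg`, `pf_amp_mmhg`, `pb_amp_mmhg`,
#'   `pf_peak_abs_mmhg`, `rm`, `ri`.
#' @export
separate_waves <- function(beat, zc) {
  if (!is.numeric(zc) || length(zc) != 1L || !is.finite(zc) || zc <= 0) {
    stop("zc must be a single positive number (got ",
         deparse(substitute(zc)), " = ", format(zc), ")", call. = FALSE)
  }
  if (is.null(beat$p_mmhg) || is.null(beat$q_ml_s)) {
    stop("wave separation needs both pressure and flow traces",
         call. = FALSE)
  }
  offset <- min(beat$p_mmhg)
  p_dyn <- convert_units(beat$p_mmhg - offset, "mmHg", "dyn/cm2")
  zq <- zc * beat$q_ml_s
  pf <- convert_units((p_dyn + zq) / 2, "dyn/cm2", "mmHg")
  pb <- convert_units((p_dyn - zq) / 2, "dyn/cm2", "mmHg")
  pf_amp <- max(pf) - min(pf)
  pb_amp <- max(pb) - min(pb)
  structure(
    list(pf_trace_mmhg = pf, pb_trace_mmhg = pb, offset_mmhg = offset,
         pf_amp_mmhg = pf_amp, pb_amp_mmhg = pb_amp,
         pf_peak_abs_mmhg = offset + max(pf),
         rm = pb_amp / pf_amp,
         ri = pb_amp / (pf_amp + pb_amp)),
    class = "wave_separation")
}

#' Reflection index from reflection magnitude
#'
#' The algebraic identity `RI = RM / (1 + RM)` relating the two
#' amplitude-ratio summaries of wave reflection.
#'
#' @param rm reflection magnitude (>= 0).
#' @return reflection index in `[0, 1)`.
#' @examples
#' reflection_index(0.46)  # ~0.32
#' @export
reflection_index <- function(rm) {
  stopifnot(is.numeric(rm), all(rm >= 0))
  rm / (1 + rm)
}

#' @export
print.wave_separation <- function(x, ...) {
  cat(sprintf(paste0("wave_separation: |Pf| %.1f, |Pb| %.1f mmHg ",
                     "(peak-trough); RM %.3f, RI %.3f\n"),
              x$pf_amp_mmhg, x$pb_amp_mmhg, x$rm, x$ri))
  invisible(x)
}
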