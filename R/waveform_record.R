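#' Multichannel physiological waveform recording
#'
#' A `waveform_record` holds uniformly sampled channels (ECG, ascending
#' aortic pressure, LV pressure, aortic flow and/or velocity) together with
#' per-channel unit strings and subject/condition labels.  At least `ecg`,
#' `aop` and one of `flow`/`velocity` must be present for the analysis
#' pipeline to run.
#'
#' @param fs_hz sampling rate in Hz (> 0).
#' @param channels named list of equal-length numeric vectors; recognised
#'   names are `ecg`, `aop`, `lvp`, `flow`, `velocity`.
#' @param units named character vector of unit strings, one per channel.
#'   Defaults are supplied for the recognised channel names.
#' @param subject_id,condition free-text labels.
#' @param t0_s start time of the first sample, seconds.
#' @return an object of class `waveform_record`.
#' @export
waveform_record <- function(fs_hz, channels, units = NULL,
                            subject_id = "unknown", condition = "unknown",
                            t0_s = 0) {
  default_units <- c(ecg = "a.u.", aop = "mmHg", lvp = "mmHg",
                     flow = "mL/s", velocity = "m/s")
  if (is.null(units)) {
    units <- default_units[names(channels)]
    units[is.na(units)] <- "a.u."
    names(units) <- names(channels)
  }
  rec <- structure(
    list(fs_hz = fs_hz, t0_s = t0_s, channels = channels, units = units,
         subject_id = subject_id, condition = condition),
    class = "waveform_record")
  validate_record(rec)
  rec
}

#' Validate a waveform_record
#'
#' Checks structural invariants: positive sampling rate, equal channel
#' lengths, numeric finite samples, mandatory channels present.
#'
#' @param rec a `waveform_record`.
#' @param require_channels character vector of channels that must exist;
#'   the default enforces the pipeline's minimum (`ecg`, `aop`, one of
#'   `flow`/`velocity`).  Use `character(0)` to skip.
#' @return `rec`, invisibly; errors describe the violated invariant.
#' @export
validate_record <- function(rec,
                            require_channels = c("ecg", "aop")) {
  if (!is.list(rec$channels) || length(rec$channels) == 0L) {
    stop("record has no channels", call. = FALSE)
  }
  if (!is.numeric(rec$fs_hz) || length(rec$fs_hz) != 1L || rec$fs_hz <= 0) {
    stop("fs_hz must be a single positive number", call. = FALSE)
  }
  lens <- vapply(rec$channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have equal length (got ",
         paste(paste0(names(lens), "=", lens), collapse = ", "), ")",
         call. = FALSE)
  }
  if (lens[1] == 0L) stop("channels are empty", call. = FALSE)
  for (ch in names(rec$channels)) {
    if (!is.numeric(rec$channels[[ch]])) {
      stop("channel '", ch, "' is not numeric", call. = FALSE)
    }
    if (any(!is.finite(rec$channels[[ch]]))) {
      stop("channel '", ch, "' contains non-finite samples", call. = FALSE)
    }
  }
  missing <- setdiff(require_channels, names(rec$channels))
  if (length(missing) > 0L) {
    stop("missing mandatory channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(require_channels) > 0L &&
      !any(c("flow", "velocity") %in% names(rec$channels))) {
    stop("record must contain at least one of 'flow' or 'velocity'",
         call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat("waveform_record:", x$subject_id, "/", x$condition, "\n")
  cat(sprintf("  %d samples @ %g Hz (%.2f s)\n", n, x$fs_hz, n / x$fs_hz))
  for (ch in names(x$channels)) {
    v <- x$channels[[ch]]
    cat(sprintf("  %-9s [%s] range %.4g .. %.4g\n",
                ch, x$units[[ch]], min(v), max(v)))
  }
  invisible(x)
}

#' Scalar aortic diameter measurement
#'
#' B-mode derived maximum and minimum internal aortic diameters for one
#' subject in one condition.
#'
#' @param dmax_mm,dmin_mm maximum/minimum internal diameter, mm;
#'   `dmax_mm >= dmin_mm > 0` is enforced.
#' @param subject_id,condition labels.
#' @return an object of class `diameter_measurement`.
#' @export
diameter_measurement <- function(dmax_mm, dmin_mm,
                                 subject_id = "unknown",
                                 condition = "unknown") {
  if (!is.finite(dmax_mm) || !is.finite(dmin_mm) || dmin_mm <= 0) {
    stop("diameters must be finite and dmin_mm > 0", call. = FALSE)
  }
  if (dmax_mm < dmin_mm) {
    stop("dmax_mm (", dmax_mm, ") must be >= dmin_mm (", dmin_mm, ")",
         call. = FALSE)
  }
  structure(list(dmax_mm = dmax_mm, dmin_mm = dmin_mm,
                 subject_id = subject_id, condition = condition),
            class = "diameter_measurement")
}
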