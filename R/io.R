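#' Read a multichannel waveform recording from delimited text
#'
#' The on-disk container is delimited text (comma or tab, autodetected),
#' UTF-8, with `#`-prefixed metadata lines (`# key=value`) followed by a
#' header row of channel names and one row per sample.  The sampling rate
#' comes either from a `# fs_hz=...` metadata line or from a `time_s`
#' column, which must be uniform to within 1 ppm.
#'
#' @param path file to read.
#' @param require_channels mandatory channels; defaults to the pipeline
#'   minimum (`ecg`, `aop`, plus one of `flow`/`velocity`).
#' @param interpolate if `TRUE`, non-finite samples are repaired by linear
#'   interpolation (the repair count is reported via `message()`); the
#'   default policy is to reject them.
#' @return a [waveform_record].
#' @export
read_recording <- function(path, require_channels = c("ecg", "aop"),
                           interpolate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  meta <- .parse_meta(lines[meta_idx])
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)

  sep <- if (grepl("\t", body[1])) "\t" else ","
  dat <- utils::read.table(text = paste(body, collapse = "\n"),
                           header = TRUE, sep = sep,
                           check.names = FALSE,
                           stringsAsFactors = FALSE)

  if ("time_s" %in% names(dat)) {
    tt <- dat[["time_s"]]
    dt <- diff(tt)
    if (length(dt) < 1L || any(dt <= 0)) {
      stop("time_s column is not strictly increasing", call. = FALSE)
    }
    if ((max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
      stop("time_s column is not uniform within 1 ppm", call. = FALSE)
    }
    fs <- 1 / stats::median(dt)
    t0 <- tt[1]
    dat[["time_s"]] <- NULL
  } else {
    if (is.null(meta$fs_hz)) {
      stop("no 'time_s' column and no '# fs_hz=' metadata line",
           call. = FALSE)
    }
    fs <- as.numeric(meta$fs_hz)
    t0 <- if (is.null(meta$t0_s)) 0 else as.numeric(meta$t0_s)
  }

  channels <- lapply(dat, as.numeric)
  for (ch in names(channels)) {
    bad <- !is.finite(channels[[ch]])
    if (any(bad)) {
      if (!interpolate) {
        stop("channel '", ch, "' has ", sum(bad), " non-finite sample(s); ",
             "re-read with interpolate = TRUE to repair", call. = FALSE)
      }
      idx <- seq_along(channels[[ch]])
      channels[[ch]] <- stats::approx(idx[!bad], channels[[ch]][!bad],
                                      xout = idx, rule = 2)$y
      message("read_recording: interpolated ", sum(bad),
              " non-finite sample(s) in channel '", ch, "'")
    }
  }

  units <- vapply(names(channels), function(ch) {
    u <- meta[[paste0("unit_", ch)]]
    if (is.null(u)) NA_character_ else u
  }, character(1))
  units[is.na(units)] <- c(ecg = "a.u.", aop = "mmHg", lvp = "mmHg",
                           flow = "mL/s",
                           velocity = "m/s")[names(units)[is.na(units)]]
  units[is.na(units)] <- "a.u."

  rec <- structure(
    list(fs_hz = fs, t0_s = t0, channels = channels, units = units,
         subject_id = meta$subject_id %||% "unknown",
         condition = meta$condition %||% "unknown"),
    class = "waveform_record")
  validate_record(rec, require_channels = require_channels)
  rec
}

#' Write a waveform recording to delimited text
#'
#' Emits the container read by [read_recording]: `# key=value` metadata
#' (sampling rate, labels, per-channel units) followed by comma-separated
#' samples at full double precision, so a read/write round trip is
#' lossless to better than 1e-9 relative.
#'
#' @param rec a valid [waveform_record].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_record(rec, require_channels = character(0))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs_hz=%s", format(rec$fs_hz, digits = 17)),
    sprintf("# t0_s=%s", format(rec$t0_s, digits = 17)),
    sprintf("# subject_id=%s", rec$subject_id),
    sprintf("# condition=%s", rec$condition),
    sprintf("# unit_%s=%s", names(rec$units), unname(rec$units))
  ), con)
  m <- vapply(rec$channels, function(v) format(v, digits = 17,
                                               scientific = TRUE,
                                               trim = TRUE),
              character(length(rec$channels[[1]])))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  writeLines(paste(names(rec$channels), collapse = ","), con)
  writeLines(apply(m, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a table of aortic diameter measurements
#'
#' Plain CSV with a header row and columns `subject_id`, `condition`,
#' `dmax_mm`, `dmin_mm`.
#'
#' @param path CSV file.
#' @return a list of [diameter_measurement] objects.
#' @export
read_diameters <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "dmax_mm", "dmin_mm")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    stop("diameter table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(d)), function(i) {
    diameter_measurement(d$dmax_mm[i], d$dmin_mm[i],
                         subject_id = d$subject_id[i],
                         condition = d$condition[i])
  })
}

#' Read a flat key-value or JSON configuration file
#'
#' Accepts either a JSON object or a flat text file with one `key: value`
#' (or `key=value`) pair per line; `#` lines are comments.  Values that
#' parse as numbers are returned numeric.
#'
#' @param path configuration file.
#' @return a named list.
#' @export
read_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- readLines(path, encoding = "UTF-8")
  first <- trimws(paste(txt, collapse = " "))
  if (startsWith(first, "{")) {
    return(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                              simplifyVector = TRUE))
  }
  txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
  kv <- regmatches(txt, regexec("^\\s*([^:=]+?)\\s*[:=]\\s*(.*?)\\s*$", txt))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop("cannot parse config line(s): ",
         paste(txt[bad], collapse = "; "), call. = FALSE)
  }
  vals <- lapply(kv, function(m) {
    v <- m[3]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 2)
  vals
}

.parse_meta <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- regmatches(lines, regexec("^([^=]+?)\\s*=\\s*(.*)$", lines))
  kv <- kv[vapply(kv, length, integer(1)) == 3L]
  out <- lapply(kv, `[`, 3)
  names(out) <- vapply(kv, `[`, character(1), 2)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
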