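#' Construct a power trace
#'
#' A `power_trace` holds the uniformly sampled power output of a single
#' ergometer test: sample times in seconds from the start of the effort,
#' instantaneous power in watts, and optionally cadence in rpm.  Times must
#' be strictly increasing and uniformly spaced (the constructor rejects
#' traces whose sampling steps deviate from the median step by more than
#' 1\%); power must be finite and non-negative.
#'
#' @param time Numeric vector of sample times (s), strictly increasing,
#'   first value >= 0, nominally uniform.
#' @param power Numeric vector of power samples (W), finite, >= 0.
#' @param cadence Optional numeric vector of cadence samples (rpm).
#' @param fs Sampling rate in Hz.  If `NULL`, inferred as the reciprocal of
#'   the median time step.
#' @return An object of class `power_trace`: a list with elements `time`,
#'   `power`, `cadence` (possibly `NULL`) and `fs`.
#' @examples
#' tr <- power_trace(0:9, rep(250, 10))
#' tr$fs
#' @export
power_trace <- function(time, power, cadence = NULL, fs = NULL) {
  time <- as.double(time)
  power <- as.double(power)
  if (length(time) < 2L) stop_critpow("a power trace needs at least 2 samples")
  if (length(power) != length(time)) {
    stop_critpow("time and power must have the same length")
  }
  if (anyNA(time) || any(!is.finite(time))) stop_critpow("non-finite time values")
  if (time[1L] < 0) stop_critpow("first time must be >= 0")
  dt <- diff(time)
  if (any(dt <= 0)) stop_critpow("non-monotonic time")
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med)) {
    stop_critpow("non-uniform sampling: time steps deviate from the median by more than 1%")
  }
  if (anyNA(power) || any(!is.finite(power))) stop_critpow("non-finite power values")
  if (any(power < 0)) stop_critpow("negative power")
  if (!is.null(cadence)) {
    cadence <- as.double(cadence)
    if (length(cadence) != length(time)) {
      stop_critpow("cadence must have the same length as time")
    }
  }
  if (is.null(fs)) fs <- 1 / med
  if (!is_scalar_number(fs) || fs <= 0) stop_critpow("fs must be a positive number")
  structure(list(time = time, power = power, cadence = cadence, fs = fs),
            class = "power_trace")
}

#' @export
print.power_trace <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<power_trace> %d samples @ %.3g Hz, %.1f-%.1f s\n",
              n, x$fs, x$time[1L], x$time[n]))
  cat(sprintf("  power: %.0f-%.0f W (mean %.1f W)%s\n",
              min(x$power), max(x$power), mean(x$power),
              if (is.null(x$cadence)) "" else ", cadence recorded"))
  invisible(x)
}

#' @export
length.power_trace <- function(x) length(x$time)

#' Construct test metadata
#'
#' Describes the test a [power_trace()] belongs to: the athlete, the test
#' kind (`"3MT"` for the 3-minute all-out test, `"CPT"` for the
#' constant-power plus all-out test), the prescribed power (required for a
#' CPT, absent for a 3MT) and optionally the preferred cadence and session
#' date.
#'
#' @param athlete_id Opaque athlete identifier (string).
#' @param test_kind `"3MT"` or `"CPT"`.
#' @param prescribed_power Prescribed power in W; required (> 0) when
#'   `test_kind = "CPT"`, must be `NULL` for a 3MT.
#' @param preferred_cadence Optional preferred cadence (rpm).
#' @param session_date Optional ISO-8601 date string.
#' @return An object of class `test_meta`.
#' @export
test_meta <- function(athlete_id, test_kind, prescribed_power = NULL,
                      preferred_cadence = NULL, session_date = NULL) {
  athlete_id <- as.character(athlete_id)
  if (length(athlete_id) != 1L || is.na(athlete_id) || !nzchar(athlete_id)) {
    stop_critpow("athlete_id must be a non-empty string")
  }
  if (!is.character(test_kind) || length(test_kind) != 1L ||
      !test_kind %in% c("3MT", "CPT")) {
    stop_critpow("test_kind must be \"3MT\" or \"CPT\"")
  }
  if (test_kind == "CPT") {
    if (!is_scalar_number(prescribed_power) || prescribed_power <= 0) {
      stop_critpow("a CPT requires prescribed_power > 0")
    }
  } else if (!is.null(prescribed_power)) {
    stop_critpow("prescribed_power applies only to a CPT")
  }
  if (!is.null(preferred_cadence) &&
      (!is_scalar_number(preferred_cadence) || preferred_cadence <= 0)) {
    stop_critpow("preferred_cadence must be a positive number")
  }
  if (!is.null(session_date)) session_date <- as.character(session_date)
  structure(list(athlete_id = athlete_id, test_kind = test_kind,
                 prescribed_power = prescribed_power,
                 preferred_cadence = preferred_cadence,
                 session_date = session_date),
            class = "test_meta")
}

#' @export
print.test_meta <- function(x, ...) {
  cat(sprintf("<test_meta> athlete %s, %s%s\n", x$athlete_id, x$test_kind,
              if (is.null(x$prescribed_power)) ""
              else sprintf(" @ %.1f W", x$prescribed_power)))
  invisible(x)
}

# metadata keys written as '# key: value' header lines
.meta_keys <- c("athlete_id", "test_kind", "prescribed_power",
                "preferred_cadence", "session_date", "fs")

#' Write a power trace to CSV
#'
#' Writes the trace as a CSV with columns `time_s`, `power_w` and, when
#' cadence is present, `cadence_rpm`.  Test metadata is stored in
#' `'#'`-prefixed `key: value` header lines so that a single file round-trips
#' through [read_trace()] bit-faithfully (numbers are written with 17
#' significant digits).
#'
#' @param trace A [power_trace()].
#' @param meta A [test_meta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_trace()]
#' @export
write_trace <- function(trace, meta, path) {
  stopifnot(inherits(trace, "power_trace"), inherits(meta, "test_meta"))
  con <- tryCatch(file(path, open = "wt"), error = function(e) {
    stop_critpow("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(
    sprintf("# athlete_id: %s", meta$athlete_id),
    sprintf("# test_kind: %s", meta$test_kind),
    if (!is.null(meta$prescribed_power))
      sprintf("# prescribed_power: %s", num(meta$prescribed_power)),
    if (!is.null(meta$preferred_cadence))
      sprintf("# preferred_cadence: %s", num(meta$preferred_cadence)),
    if (!is.null(meta$session_date))
      sprintf("# session_date: %s", meta$session_date),
    sprintf("# fs: %s", num(trace$fs))
  )
  writeLines(hdr, con)
  cols <- c("time_s", "power_w", if (!is.null(trace$cadence)) "cadence_rpm")
  writeLines(paste(cols, collapse = ","), con)
  body <- if (is.null(trace$cadence)) {
    paste(num(trace$time), num(trace$power), sep = ",")
  } else {
    paste(num(trace$time), num(trace$power), num(trace$cadence), sep = ",")
  }
  writeLines(body, con)
  invisible(path)
}

#' Read a power trace from CSV
#'
#' Reads a trace written by [write_trace()] (or any CSV with columns
#' `time_s`, `power_w` and optional `cadence_rpm`, plus `'#'`-prefixed
#' `key: value` metadata lines).  The file is validated, never repaired:
#' missing required columns, non-monotonic time, negative power, or a CPT
#' without a prescribed power are errors.
#'
#' @param path File path.
#' @return A list with elements `trace` ([power_trace()]) and `meta`
#'   ([test_meta()]).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_critpow("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- m[3L]
  }
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  for (col in c("time_s", "power_w")) {
    if (!col %in% names(dat)) stop_critpow("missing required column '", col, "'")
  }
  kind <- kv[["test_kind"]]
  if (is.null(kind)) stop_critpow("metadata line '# test_kind: ...' missing")
  meta <- test_meta(
    athlete_id = kv[["athlete_id"]] %||% "unknown",
    test_kind = kind,
    prescribed_power = if (!is.null(kv[["prescribed_power"]]))
      as.double(kv[["prescribed_power"]]),
    preferred_cadence = if (!is.null(kv[["preferred_cadence"]]))
      as.double(kv[["preferred_cadence"]]),
    session_date = kv[["session_date"]]
  )
  trace <- power_trace(
    time = dat$time_s, power = dat$power_w,
    cadence = if ("cadence_rpm" %in% names(dat)) dat$cadence_rpm,
    fs = if (!is.null(kv[["fs"]])) as.double(kv[["fs"]])
  )
  list(trace = trace, meta = meta)
}

# Nearest sample index for time t; errors if t is outside the trace or does
# not coincide with a sample time (within numerical tolerance).
.time_index <- function(trace, t, what = "time") {
  if (t < trace$time[1L] - 1e-9 || t > trace$time[length(trace$time)] + 1e-9) {
    stop_critpow(what, " = ", t, " s lies outside the trace")
  }
  i <- which.min(abs(trace$time - t))
  if (abs(trace$time[i] - t) > 0.5 / trace$fs + 1e-9) {
    stop_critpow(what, " = ", t, " s does not coincide with a sample time")
  }
  i
}

# Subset a trace to [t0, t1] (sample-aligned), keeping fs.
.subset_trace <- function(trace, t0, t1) {
  i0 <- .time_index(trace, t0, "t0")
  i1 <- .time_index(trace, t1, "t1")
  if (i1 <= i0) stop_critpow("empty trace window")
  power_trace(trace$time[i0:i1], trace$power[i0:i1],
              cadence = if (!is.null(trace$cadence)) trace$cadence[i0:i1],
              fs = trace$fs)
}
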