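#' Uniformly sampled skin conductance series
#'
#' @param samples numeric vector of conductance values (microsiemens)
#' @param rate sampling rate (Hz), > 0
#' @param t0 time of the first sample (s); sample k (1-based) is at
#'   `t0 + (k - 1) / rate`
#' @return an object of class `conductance_series`
#' @export
conductance_series <- function(samples, rate, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    stop("a conductance series needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("conductance samples must all be finite", call. = FALSE)
  }
  if (!is.finite(rate) || rate <= 0) {
    stop("sampling rate must be finite and > 0", call. = FALSE)
  }
  structure(list(samples = samples, rate = rate, t0 = t0),
            class = "conductance_series")
}

#' @export
print.conductance_series <- function(x, ...) {
  cat(sprintf(
    "<conductance_series> %d samples @ %g Hz (%.1f s from t0 = %g s), range [%.3g, %.3g] uS\n",
    length(x$samples), x$rate, length(x$samples) / x$rate, x$t0,
    min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.conductance_series <- function(x) length(x$samples)

#' Sample times of a conductance series
#' @param series a [conductance_series()]
#' @return numeric vector of times (s)
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "conductance_series"))
  series$t0 + (seq_along(series$samples) - 1) / series$rate
}

#' A labelled analysis epoch
#'
#' @param series a [conductance_series()]
#' @param label condition tag (e.g. "baseline" or "anticipation"), or `NA`
#' @param subject subject identifier, or `NA`
#' @param excluded artifact flag; excluded epochs must carry a `reason`
#' @param reason reason string when `excluded` is `TRUE`
#' @return an object of class `sf_epoch`
#' @export
sf_epoch <- function(series, label = NA_character_, subject = NA_character_,
                     excluded = FALSE, reason = NULL) {
  stopifnot(inherits(series, "conductance_series"))
  if (isTRUE(excluded) && (is.null(reason) || !nzchar(reason))) {
    stop("excluded epochs must carry a reason string", call. = FALSE)
  }
  structure(list(series = series, label = label, subject = subject,
                 excluded = isTRUE(excluded), reason = reason),
            class = "sf_epoch")
}

#' @export
print.sf_epoch <- function(x, ...) {
  cat(sprintf("<sf_epoch> subject %s, label %s%s\n",
              x$subject, x$label,
              if (x$excluded) sprintf(" [EXCLUDED: %s]", x$reason) else ""))
  print(x$series)
  invisible(x)
}

#' Read a conductance series from disk
#'
#' Plain format: one conductance value per line. CSV format: RFC-4180 with
#' a header; the conductance column is named `scl` (case-insensitive) or
#' selected by position via `column`. Lines starting with `#` are treated
#' as comments. Values are assumed to be in microsiemens; use `scale` if
#' your file is in other units.
#'
#' @param path file path
#' @param rate sampling rate of the stored trace (Hz)
#' @param format "auto" (by extension), "plain", or "csv"
#' @param column conductance column name or index for CSV input
#' @param scale multiplicative factor applied to the stored values
#' @param t0 time of the first sample (s)
#' @return a [conductance_series()]
#' @export
read_series <- function(path, rate, format = c("auto", "plain", "csv"),
                        column = "scl", scale = 1, t0 = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "plain"
  }
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  body <- raw[keep]
  if (!length(body)) stop("no data in ", path, call. = FALSE)
  if (format == "plain") {
    vals <- suppressWarnings(as.numeric(trimws(body)))
    if (anyNA(vals)) {
      bad <- lineno[which(is.na(vals))[1]]
      stop(sprintf("non-numeric value on line %d of %s", bad, path),
           call. = FALSE)
    }
  } else {
    con <- textConnection(body)
    on.exit(close(con))
    df <- utils::read.csv(con, stringsAsFactors = FALSE)
    if (is.character(column)) {
      hit <- which(tolower(names(df)) == tolower(column))
      if (!length(hit)) {
        stop(sprintf("no column named '%s' in %s (found: %s)", column, path,
                     paste(names(df), collapse = ", ")), call. = FALSE)
      }
      col <- df[[hit[1]]]
    } else {
      if (column < 1 || column > ncol(df)) {
        stop("column index out of range for ", path, call. = FALSE)
      }
      col <- df[[column]]
    }
    vals <- suppressWarnings(as.numeric(col))
    if (anyNA(vals)) {
      # +1 for the header line within the kept lines
      bad <- lineno[which(is.na(vals))[1] + 1L]
      stop(sprintf("non-numeric value on line %d of %s", bad, path),
           call. = FALSE)
    }
  }
  conductance_series(vals * scale, rate = rate, t0 = t0)
}

#' Write a conductance series to disk
#'
#' @param series a [conductance_series()]
#' @param path output path
#' @param format "plain" (one value per line) or "csv" (columns `t`, `scl`)
#' @param header optional character vector written as leading `#` comments
#' @return `path`, invisibly
#' @export
write_series <- function(series, path, format = c("csv", "plain"),
                         header = NULL) {
  stopifnot(inherits(series, "conductance_series"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (format == "plain") {
    writeLines(sprintf("%.10g", series$samples), con)
  } else {
    writeLines("t,scl", con)
    writeLines(sprintf("%.6f,%.10g", series_times(series), series$samples),
               con)
  }
  invisible(path)
}

#' Zero-phase low-pass filtering and resampling
#'
#' Applies a bidirectional (forward-backward) first-order Butterworth
#' low-pass filter and then decimates to the target rate. The forward and
#' backward passes square the magnitude response, so the effective
#' attenuation at frequency f is \eqn{1 / (1 + (f/f_c)^2)} while the phase
#' is zero. The signal is odd-reflection padded by several filter time
#' constants at each end before filtering so that 60 s epochs carry no edge
#' transient. When the source rate is an integer multiple of the target
#' the trace is decimated (the 5 Hz filter acting as the anti-alias
#' stage); otherwise it is linearly interpolated onto the target grid.
#'
#' @param series a [conductance_series()]
#' @param cutoff filter cut-off frequency (Hz), must be below Nyquist
#' @param target_rate output sampling rate (Hz), at most `series$rate`
#' @return a filtered [conductance_series()] at `target_rate`
#' @export
lowpass_resample <- function(series, cutoff = 5, target_rate = 10) {
  stopifnot(inherits(series, "conductance_series"))
  rate <- series$rate
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= rate / 2) {
    stop(sprintf("cutoff must lie in (0, Nyquist = %g Hz)", rate / 2),
         call. = FALSE)
  }
  if (!is.finite(target_rate) || target_rate <= 0 || target_rate > rate) {
    stop("target_rate must be in (0, series rate]", call. = FALSE)
  }
  x <- series$samples
  n <- length(x)
  bf <- signal::butter(1, cutoff / (rate / 2), type = "low")
  pad <- min(n - 1L, as.integer(ceiling(3 * rate / cutoff)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  yp <- signal::filtfilt(bf, xp)
  y <- yp[(pad + 1):(pad + n)]
  if (target_rate < rate) {
    ratio <- rate / target_rate
    if (abs(ratio - round(ratio)) < 1e-9) {
      y <- y[seq(1, n, by = round(ratio))]
    } else {
      t_old <- (seq_len(n) - 1) / rate
      t_new <- seq(0, t_old[n], by = 1 / target_rate)
      y <- stats::approx(t_old, y, xout = t_new)$y
    }
  }
  conductance_series(y, rate = target_rate, t0 = series$t0)
}

#' Subtract the segment minimum
#'
#' Shifts a trace so that its lowest value is zero, the convention used
#' before model inversion: the generative model predicts a return to zero
#' conductance in the absence of sudomotor input, while recorded traces
#' carry an arbitrary high-pass-filtered baseline.
#'
#' @param x a [conductance_series()] or [sf_epoch()]
#' @return the same class of object, shifted so `min(samples) == 0`
#' @export
baseline_subtract <- function(x) {
  if (inherits(x, "sf_epoch")) {
    x$series <- baseline_subtract(x$series)
    return(x)
  }
  stopifnot(inherits(x, "conductance_series"))
  x$samples <- x$samples - min(x$samples)
  x
}

#' Cut a series into fixed-length epochs
#'
#' Windows are closed-open `[start, start + duration)` in the series' own
#' time coordinates. Each epoch is independently minimum-subtracted,
#' following the segment-wise baseline convention.
#'
#' @param series a [conductance_series()]
#' @param starts epoch start times (s)
#' @param duration epoch length (s), default 60
#' @param labels optional condition tags, recycled against `starts`
#' @param subject optional subject identifier attached to every epoch
#' @return a list of [sf_epoch()] objects
#' @export
segment_epochs <- function(series, starts, duration = 60, labels = NULL,
                           subject = NA_character_) {
  stopifnot(inherits(series, "conductance_series"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  n <- length(series$samples)
  len <- round(duration * series$rate)
  if (!is.null(labels)) labels <- rep_len(labels, length(starts))
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    i0 <- round((s - series$t0) * series$rate) + 1L
    if (i0 < 1L || i0 + len - 1L > n) {
      stop(sprintf("epoch starting at %g s does not fit within the series", s),
           call. = FALSE)
    }
    seg <- conductance_series(series$samples[i0:(i0 + len - 1L)],
                              rate = series$rate, t0 = s)
    sf_epoch(baseline_subtract(seg),
             label = if (is.null(labels)) NA_character_ else labels[i],
             subject = subject)
  })
}
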