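#' Construct a CTG trace
#'
#' A cardiotocogram (CTG) pairs a fetal heart rate (FHR) channel in beats
#' per minute with a uterine contraction (UC) intensity channel in relative
#' units (0--100), sampled at a common rate. Missing samples (transducer
#' dropouts) are represented as `NA`.
#'
#' @param fhr numeric vector of heart-rate samples (bpm); `NA` = missing.
#' @param uc numeric vector of contraction-intensity samples, same length
#'   as `fhr`; `NA` = missing.
#' @param rate sampling rate in samples per second (default 2, the
#'   conventional CTG plotting rate of two points per second).
#' @param label free-text identifier carried into reports.
#' @return An object of class `ctg_trace`: a list with elements `fhr`,
#'   `uc`, `rate`, `label`. Sample `i` (1-based) is at time `(i-1)/rate`
#'   seconds from trace start.
#' @export
#' @examples
#' tr <- ctg_trace(fhr = rep(140, 10), uc = rep(5, 10))
#' tr
ctg_trace <- function(fhr, uc, rate = 2, label = "trace") {
  fhr <- as.numeric(fhr)
  uc <- as.numeric(uc)
  if (length(fhr) != length(uc)) {
    stop("fhr and uc must have equal length", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  if (any(!is.na(fhr) & !is.finite(fhr))) {
    stop("non-missing fhr samples must be finite", call. = FALSE)
  }
  if (any(!is.na(uc) & !is.finite(uc))) {
    stop("non-missing uc samples must be finite", call. = FALSE)
  }
  structure(
    list(fhr = fhr, uc = uc, rate = rate, label = as.character(label)[1L]),
    class = "ctg_trace"
  )
}

#' @export
print.ctg_trace <- function(x, ...) {
  n <- length(x$fhr)
  cat(sprintf(
    "CTG trace '%s': %d samples at %g Hz (%.1f s)\n",
    x$label, n, x$rate, n / x$rate
  ))
  cat(sprintf(
    "  FHR: %d missing; range %s bpm\n",
    sum(is.na(x$fhr)),
    paste(signif(range(x$fhr, na.rm = TRUE), 4), collapse = "-")
  ))
  cat(sprintf(
    "  UC : %d missing; range %s\n",
    sum(is.na(x$uc)),
    paste(signif(range(x$uc, na.rm = TRUE), 4), collapse = "-")
  ))
  invisible(x)
}

#' Times of the samples in a trace
#'
#' @param trace a [ctg_trace()].
#' @return numeric vector of times in seconds from trace start.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$fhr) - 1) / trace$rate
}

#' Read a CTG trace from a delimited text file
#'
#' The format is CSV with a header naming at least `fhr` and `uc` columns
#' (a `t` column, seconds from trace start, is accepted and ignored for
#' reconstruction: samples are taken to be uniformly spaced). An optional
#' leading comment line `# rate: <samples per second>` carries the
#' sampling rate; without it, and without `rate_override`, the rate
#' defaults to 2 samples per second. Blank or unparsable cells become
#' missing samples.
#'
#' @param path file path.
#' @param rate_override optional sampling rate taking precedence over the
#'   file header.
#' @return a [ctg_trace()].
#' @export
read_ctg_trace <- function(path, rate_override = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read trace file '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  rate <- NULL
  hdr <- grep("^#", lines)
  for (i in hdr) {
    m <- regmatches(lines[i], regexec("rate[:=]\\s*([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(m) == 2L) rate <- as.numeric(m[2])
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) {
    stop(sprintf("trace file '%s' has no header row", path), call. = FALSE)
  }
  df <- utils::read.csv(
    textConnection(paste(body, collapse = "\n")),
    stringsAsFactors = FALSE
  )
  names(df) <- tolower(names(df))
  if (!all(c("fhr", "uc") %in% names(df))) {
    stop(sprintf("trace file '%s' lacks fhr/uc columns", path), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  if (!is.null(rate_override)) rate <- rate_override
  if (is.null(rate) || !is.finite(rate)) rate <- 2
  ctg_trace(
    fhr = num(df$fhr), uc = num(df$uc), rate = rate,
    label = sub("\\.[^.]*$", "", basename(path))
  )
}

#' Write a CTG trace to CSV
#'
#' Writes the `# rate:` header line and `t,fhr,uc` columns; missing
#' samples become empty cells. [read_ctg_trace()] on the result recovers
#' every non-missing sample to machine precision.
#'
#' @param trace a [ctg_trace()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_ctg_trace <- function(trace, path) {
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 15, format = "g"))
  lines <- c(
    sprintf("# rate: %s", formatC(trace$rate, digits = 15, format = "g")),
    "t,fhr,uc",
    paste(fmt(trace_times(trace)), fmt(trace$fhr), fmt(trace$uc), sep = ",")
  )
  ok <- tryCatch(
    {
      writeLines(lines, path)
      TRUE
    },
    error = function(e) e,
    warning = function(w) w
  )
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write trace file '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' @export
plot.ctg_trace <- function(x, ...) {
  tt <- trace_times(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tt, x$fhr,
    type = "l", xlab = "time (s)", ylab = "FHR (bpm)",
    main = x$label, ...
  )
  graphics::plot(tt, x$uc,
    type = "l", xlab = "time (s)", ylab = "UC (rel. units)", ...
  )
  invisible(x)
}
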