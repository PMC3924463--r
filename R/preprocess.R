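#' Engine configuration
#'
#' Collects the cleaning, smoothing, baseline and detection parameters in
#' one validated list. All durations are seconds, heights bpm (FHR) or
#' relative units (UC).
#'
#' @param fhr_valid_range length-2 numeric, plausible FHR range in bpm;
#'   samples outside are treated as invalid (e.g. transducer artefact).
#' @param max_gap_s longest run of missing/invalid samples bridged by
#'   linear interpolation; longer runs split the trace into independent
#'   analysis segments.
#' @param smooth_window_s moving-average window for both channels.
#' @param dup_run_max longest tolerated run of exactly repeated FHR
#'   values; longer runs bounded by a jump discontinuity are taken as a
#'   sensor hold and invalidated.
#' @param hold_jump_bpm discontinuity (bpm) at a duplicate run's edge
#'   that marks the run as a sensor hold rather than a genuine flat
#'   rate.
#' @param baseline_window_s horizon over which the FHR baseline and UC
#'   resting tone are estimated.
#' @param min_prominence minimum height of a UC peak above resting tone
#'   to count as a contraction.
#' @param tol UC level tolerance when locating the tone crossings that
#'   bound a contraction cycle.
#' @param return_tol band around the FHR baseline (bpm) within which the
#'   rate counts as "returned to baseline".
#' @param horizon_s how far past the contraction end the nadir of a
#'   linked deceleration may lie.
#' @param shoulder_search_s how far past the deceleration recovery a
#'   shoulder acceleration is sought.
#' @param onset_frac length-2 fraction band of the measured depth over
#'   which the descending limb is fitted when localising the fall onset.
#' @param nadir_band_bpm half-height (bpm) of the nadir plateau whose
#'   centre is reported as the nadir time.
#' @param min_excursion_bpm smallest baseline-to-nadir drop reported as a
#'   candidate deceleration episode at all.
#' @return an object of class `ctg_config` (a named list).
#' @export
ctg_config <- function(fhr_valid_range = c(50, 240), max_gap_s = 15,
                       smooth_window_s = 5, dup_run_max = 10,
                       hold_jump_bpm = 10,
                       baseline_window_s = 600, min_prominence = 10,
                       tol = 2, return_tol = 5, horizon_s = 60,
                       shoulder_search_s = 60,
                       onset_frac = c(0.15, 0.85), nadir_band_bpm = 2,
                       min_excursion_bpm = 2) {
  if (length(fhr_valid_range) != 2L || fhr_valid_range[1] >= fhr_valid_range[2]) {
    stop("fhr_valid_range must be (low, high) with low < high", call. = FALSE)
  }
  if (max_gap_s < 0) stop("max_gap_s must be >= 0", call. = FALSE)
  if (smooth_window_s <= 0) stop("smooth_window_s must be > 0", call. = FALSE)
  structure(list(
    fhr_valid_range = as.numeric(fhr_valid_range),
    max_gap_s = as.numeric(max_gap_s),
    smooth_window_s = as.numeric(smooth_window_s),
    dup_run_max = as.integer(dup_run_max),
    hold_jump_bpm = as.numeric(hold_jump_bpm),
    baseline_window_s = as.numeric(baseline_window_s),
    min_prominence = as.numeric(min_prominence),
    tol = as.numeric(tol),
    return_tol = as.numeric(return_tol),
    horizon_s = as.numeric(horizon_s),
    shoulder_search_s = as.numeric(shoulder_search_s),
    onset_frac = as.numeric(onset_frac),
    nadir_band_bpm = as.numeric(nadir_band_bpm),
    min_excursion_bpm = as.numeric(min_excursion_bpm)
  ), class = "ctg_config")
}

#' Read an engine configuration from a YAML file
#'
#' Keys are the argument names of [ctg_config()]; absent keys take their
#' defaults.
#'
#' @param path YAML file path.
#' @return a [ctg_config()] object.
#' @export
read_ctg_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ctg_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown config keys: %s",
      paste(extra, collapse = ", ")), call. = FALSE)
  }
  do.call(ctg_config, vals[intersect(names(vals), known)])
}

# maximal runs of TRUE; data.frame(start, end) of 1-based indices
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Clean a CTG trace
#'
#' Marks invalid samples (FHR outside the plausible range, UC negative,
#' and sensor-hold runs of more than `dup_run_max` exactly repeated FHR
#' values) as missing, then bridges missing runs no longer than
#' `max_gap_s` by linear interpolation. Longer runs stay missing and
#' split the trace into analysis segments, recorded in the `segments`
#' attribute as a data frame of 1-based sample indices.
#'
#' @param trace a [ctg_trace()].
#' @param config a [ctg_config()].
#' @return the cleaned `ctg_trace` with a `segments` attribute.
#' @export
ctg_clean <- function(trace, config = ctg_config()) {
  stopifnot(inherits(trace, "ctg_trace"))
  n <- length(trace$fhr)
  if (n == 0L) stop("empty trace", call. = FALSE)
  fhr <- trace$fhr
  uc <- trace$uc

  lo <- config$fhr_valid_range[1]
  hi <- config$fhr_valid_range[2]
  fhr[!is.na(fhr) & (fhr < lo | fhr > hi)] <- NA_real_
  uc[!is.na(uc) & uc < 0] <- NA_real_

  # sensor-hold detection: a held reading repeats one exact value longer
  # than dup_run_max and then jumps when the signal resumes; a genuine
  # flat rate joins its neighbours continuously and is left alone
  if (n > 1L) {
    r <- rle(ifelse(is.na(fhr), -Inf, fhr))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hold <- which(is.finite(r$values) & r$lengths > config$dup_run_max)
    for (k in hold) {
      v <- r$values[k]
      jump_in <- starts[k] > 1L &&
        (is.na(fhr[starts[k] - 1L]) ||
          abs(fhr[starts[k] - 1L] - v) > config$hold_jump_bpm)
      jump_out <- ends[k] < n &&
        (is.na(fhr[ends[k] + 1L]) ||
          abs(fhr[ends[k] + 1L] - v) > config$hold_jump_bpm)
      if (jump_in || jump_out) fhr[starts[k]:ends[k]] <- NA_real_
    }
  }

  if (sum(!is.na(fhr)) < 2L) {
    stop("fewer than 2 valid FHR samples after cleaning", call. = FALSE)
  }

  max_gap <- round(config$max_gap_s * trace$rate)
  fhr <- bridge_gaps(fhr, max_gap)
  uc <- bridge_gaps(uc, max_gap)

  out <- ctg_trace(fhr, uc, rate = trace$rate, label = trace$label)
  attr(out, "segments") <- runs_of(!is.na(out$fhr))
  out
}

# linearly interpolate interior NA runs of length <= max_gap
bridge_gaps <- function(x, max_gap) {
  if (!anyNA(x) || max_gap < 1L) return(x)
  gaps <- runs_of(is.na(x))
  n <- length(x)
  for (k in seq_len(nrow(gaps))) {
    s <- gaps$start[k]
    e <- gaps$end[k]
    if (e - s + 1L > max_gap) next
    if (s == 1L || e == n) next # edge gaps cannot be interpolated
    idx <- s:e
    x[idx] <- x[s - 1L] + (x[e + 1L] - x[s - 1L]) * (idx - (s - 1L)) / (e - s + 2L)
  }
  x
}

#' Moving-average smoothing
#'
#' Centered moving average over `round(window_s * rate)` samples (forced
#' odd by adding one when even). Missing samples are excluded from every
#' window's mean; positions that are themselves missing stay missing, so
#' analysis segments are preserved. Windows are clipped at the series
#' ends.
#'
#' @param x numeric vector, `NA` = missing.
#' @param rate samples per second.
#' @param window_s window length in seconds.
#' @return smoothed numeric vector of the same length.
#' @export
ctg_smooth <- function(x, rate, window_s = 5) {
  n <- length(x)
  if (n == 0L) stop("cannot smooth an empty series", call. = FALSE)
  if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
  w <- round(window_s * rate)
  if (w %% 2 == 0) w <- w + 1
  if (w <= 1L) return(x)
  half <- (w - 1L) %/% 2L
  miss <- is.na(x)
  xs <- ifelse(miss, 0, x)
  cs <- cumsum(xs)
  cn <- cumsum(as.numeric(!miss))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  s <- cs[hi] - c(0, cs)[lo]
  k <- cn[hi] - c(0, cn)[lo]
  out <- ifelse(k > 0, s / k, NA_real_)
  out[miss] <- NA_real_
  out
}

# tile [1, n] into baseline windows; short tails (< 60 s) are folded into
# the decision "reuse nearest full-window estimate"
baseline_windows <- function(n, rate, window_s) {
  wlen <- max(1L, round(window_s * rate))
  starts <- seq(1L, n, by = wlen)
  data.frame(start = starts, end = pmin(starts + wlen - 1L, n))
}

#' Estimate the FHR baseline per window
#'
#' The baseline B is the heart-rate level between excursions. Per
#' consecutive window of `window_s` seconds, B is the median of the
#' smoothed FHR samples lying between the window's 10th and 90th
#' percentiles (the trimming discards deceleration nadirs and
#' acceleration peaks), rounded to the nearest 1 bpm. Windows shorter
#' than 60 s, or with no valid samples, reuse the nearest computed
#' estimate.
#'
#' @param trace a cleaned [ctg_trace()] (see [ctg_clean()]).
#' @param window_s estimation window, seconds.
#' @param config a [ctg_config()]; supplies the smoothing window.
#' @return data frame with one row per window: `start_s`, `end_s`
#'   (closed time interval covered) and `b` (bpm).
#' @export
estimate_fhr_baseline <- function(trace, window_s = 600, config = ctg_config()) {
  sm <- ctg_smooth(trace$fhr, trace$rate, config$smooth_window_s)
  est_windows(sm, trace$rate, window_s, function(v) {
    q <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
    round(stats::median(v[v >= q[1] & v <= q[2]]))
  }, what = "FHR baseline")
}

#' Estimate the UC resting tone per window
#'
#' The resting tone is the level the contraction channel returns to
#' between contractions, estimated as the 10th percentile of the smoothed
#' UC samples per window. Window handling as in
#' [estimate_fhr_baseline()].
#'
#' @inheritParams estimate_fhr_baseline
#' @return data frame with `start_s`, `end_s`, `tone`.
#' @export
estimate_uc_tone <- function(trace, window_s = 600, config = ctg_config()) {
  sm <- ctg_smooth(trace$uc, trace$rate, config$smooth_window_s)
  out <- est_windows(sm, trace$rate, window_s, function(v) {
    stats::quantile(v, 0.1, names = FALSE, type = 7)
  }, what = "UC tone")
  names(out)[names(out) == "b"] <- "tone"
  out
}

# shared window-tiling estimator with short/empty-window fallback
est_windows <- function(sm, rate, window_s, f, what) {
  n <- length(sm)
  win <- baseline_windows(n, rate, window_s)
  min_len <- 60 * rate
  vals <- rep(NA_real_, nrow(win))
  full <- logical(nrow(win))
  for (k in seq_len(nrow(win))) {
    v <- sm[win$start[k]:win$end[k]]
    v <- v[!is.na(v)]
    len <- win$end[k] - win$start[k] + 1L
    if (length(v) == 0L) next
    if (len < min_len && nrow(win) > 1L) next # short tail: reuse nearest
    vals[k] <- f(v)
    full[k] <- TRUE
  }
  if (!any(full)) {
    # single short window is still allowed to carry the estimate
    for (k in seq_len(nrow(win))) {
      v <- sm[win$start[k]:win$end[k]]
      v <- v[!is.na(v)]
      if (length(v)) {
        vals[k] <- f(v)
        full[k] <- TRUE
      }
    }
  }
  if (!any(full)) {
    stop(sprintf("no valid samples in any window: cannot estimate %s", what),
      call. = FALSE
    )
  }
  idx_full <- which(full)
  for (k in which(!full)) {
    vals[k] <- vals[idx_full[which.min(abs(idx_full - k))]]
  }
  data.frame(
    start_s = (win$start - 1) / rate,
    end_s = (win$end - 1) / rate,
    b = vals
  )
}

# per-sample lookup of a windowed estimate (column 3) at sample index i
window_value_at <- function(est, t) {
  k <- findInterval(t, est$start_s)
  k[k < 1L] <- 1L
  est[[3L]][k]
}
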