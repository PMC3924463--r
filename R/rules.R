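#' Convert a sample count to seconds
#'
#' At the conventional CTG plotting rate of two points per second, 90
#' samples span 45 seconds and 10 samples span 5 seconds.
#'
#' @param n sample count (>= 0).
#' @param rate samples per second (> 0).
#' @return `n / rate`, seconds.
#' @export
#' @examples
#' samples_to_seconds(90, 2) # 45
samples_to_seconds <- function(n, rate) {
  if (!is.numeric(rate) || any(rate <= 0)) {
    stop("rate must be > 0", call. = FALSE)
  }
  if (any(n < 0)) stop("n must be >= 0", call. = FALSE)
  n / rate
}

symptom_labels <- function() {
  c(
    "Tachycardia", "Bradycardia", "EarlyDeceleration", "LateDeceleration",
    "VariableDecelerationA", "VariableDecelerationB"
  )
}

#' Classify a deceleration episode
#'
#' Evaluates the four deceleration rule sets against the episode's key
#' points. The shared symbols mix time and value semantics, resolved
#' explicitly here: fall time and lags compare key-point times (seconds),
#' depth and shoulder height compare values (bpm). All comparisons are
#' inclusive as conventionally printed, so boundary cases are
#' label-positive. Every satisfied rule set is reported: an episode can
#' legitimately carry several labels (e.g. a V-shaped deceleration with a
#' shoulder satisfies both variable types), which downstream reporting
#' flags as ambiguous.
#'
#' Rule sets (e = episode, c = criteria):
#' \itemize{
#'   \item Early: `hrp.t < uce.t`, `hrp.t - hrs.t >= fall_time_s`,
#'     `hrs.t >= ucs.t + uc_lag_s`, `b - hrp.v >= depth_bpm`.
#'   \item Late: `hrp.t >= uce.t`, `hrp.t - hrs.t >= fall_time_s`,
#'     `b - hrp.v >= depth_bpm`.
#'   \item Variable A: `hrp.t - hrs.t <= fall_time_s`,
#'     `hrs.t >= ucs.t + uc_lag_s`, `b - hrp.v >= depth_bpm`.
#'   \item Variable B: `hrs.t >= ucs.t + uc_lag_s`,
#'     `b - hrp.v >= depth_bpm`, shoulder present with
#'     `hsp.v - b >= shoulder_height_bpm` and
#'     `hse.t - hre.t >= shoulder_lag_s`.
#' }
#'
#' @param episode a `decel_episode` with a linked cycle and baseline.
#' @param criteria a [ctg_criteria()].
#' @return character vector of assigned labels (possibly empty, possibly
#'   several), with attribute `rules`: a data frame with one row per
#'   rule evaluated (`label`, `rule`, `value`, `threshold`, `passed`).
#' @export
classify_decel <- function(episode, criteria = ctg_criteria()) {
  if (is.null(episode$cycle)) {
    stop("episode has no linked uterine contraction cycle", call. = FALSE)
  }
  e <- episode
  c_ <- criteria
  fall <- e$hrp$t - e$hrs$t
  lag <- e$hrs$t - e$cycle$ucs$t
  depth <- e$b - e$hrp$v
  has_sh <- !is.null(e$shoulder)
  sh_h <- if (has_sh) e$shoulder$hsp$v - e$b else NA_real_
  sh_lag <- if (has_sh) e$shoulder$hse$t - e$hre$t else NA_real_

  rows <- list(
    list("EarlyDeceleration", "nadir_before_uce", e$hrp$t, e$cycle$uce$t,
      e$hrp$t < e$cycle$uce$t),
    list("EarlyDeceleration", "fall_time", fall, c_$fall_time_s,
      fall >= c_$fall_time_s),
    list("EarlyDeceleration", "uc_lag", lag, c_$uc_lag_s,
      lag >= c_$uc_lag_s),
    list("EarlyDeceleration", "depth", depth, c_$depth_bpm,
      depth >= c_$depth_bpm),
    list("LateDeceleration", "nadir_after_uce", e$hrp$t, e$cycle$uce$t,
      e$hrp$t >= e$cycle$uce$t),
    list("LateDeceleration", "fall_time", fall, c_$fall_time_s,
      fall >= c_$fall_time_s),
    list("LateDeceleration", "depth", depth, c_$depth_bpm,
      depth >= c_$depth_bpm),
    list("VariableDecelerationA", "fall_time", fall, c_$fall_time_s,
      fall <= c_$fall_time_s),
    list("VariableDecelerationA", "uc_lag", lag, c_$uc_lag_s,
      lag >= c_$uc_lag_s),
    list("VariableDecelerationA", "depth", depth, c_$depth_bpm,
      depth >= c_$depth_bpm),
    list("VariableDecelerationB", "uc_lag", lag, c_$uc_lag_s,
      lag >= c_$uc_lag_s),
    list("VariableDecelerationB", "depth", depth, c_$depth_bpm,
      depth >= c_$depth_bpm),
    list("VariableDecelerationB", "shoulder_height", sh_h,
      c_$shoulder_height_bpm, has_sh && sh_h >= c_$shoulder_height_bpm),
    list("VariableDecelerationB", "shoulder_lag", sh_lag,
      c_$shoulder_lag_s, has_sh && sh_lag >= c_$shoulder_lag_s)
  )
  rules <- data.frame(
    label = vapply(rows, `[[`, character(1), 1L),
    rule = vapply(rows, `[[`, character(1), 2L),
    value = vapply(rows, function(r) as.numeric(r[[3L]]), numeric(1)),
    threshold = vapply(rows, function(r) as.numeric(r[[4L]]), numeric(1)),
    passed = vapply(rows, function(r) isTRUE(r[[5L]]), logical(1)),
    stringsAsFactors = FALSE
  )
  labels <- character(0)
  for (lab in unique(rules$label)) {
    if (all(rules$passed[rules$label == lab])) labels <- c(labels, lab)
  }
  structure(labels, rules = rules)
}

#' Classify a sustained-rate episode
#'
#' High episodes (all samples at or above the tachycardia threshold) are
#' Tachycardia; low episodes Bradycardia. Duration filtering happens
#' upstream in [detect_sustained()].
#'
#' @param episode a `sustained_episode`.
#' @param criteria a [ctg_criteria()] (carried for the rule record).
#' @return a single label string with attribute `rules`.
#' @export
classify_sustained <- function(episode, criteria = ctg_criteria()) {
  lab <- if (identical(episode$kind, "high")) "Tachycardia" else "Bradycardia"
  thr <- if (lab == "Tachycardia") criteria$tachy_bpm else criteria$brady_bpm
  rules <- data.frame(
    label = c(lab, lab),
    rule = c("rate_threshold", "sustained_duration"),
    value = c(episode$extreme_v, episode$duration_s),
    threshold = c(thr, criteria$sustained_min_s),
    passed = c(TRUE, episode$duration_s >= criteria$sustained_min_s),
    stringsAsFactors = FALSE
  )
  structure(lab, rules = rules)
}
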