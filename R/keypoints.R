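#' A named key point on a trace
#'
#' The clinical key points (contraction start/peak/end, fall start,
#' nadir, recovery, shoulder peak/end) each carry both a time and the
#' channel value at that time; rules use one or the other explicitly.
#'
#' @param t time in seconds from trace start.
#' @param v channel value at `t` (bpm for FHR points, relative units for
#'   UC points).
#' @return a list with elements `t` and `v`, class `keypoint`.
#' @export
keypoint <- function(t, v) {
  stopifnot(is.finite(t), t >= 0, is.finite(v))
  structure(list(t = as.numeric(t), v = as.numeric(v)), class = "keypoint")
}

#' @export
print.keypoint <- function(x, ...) {
  cat(sprintf("keypoint: t = %.1f s, v = %.1f\n", x$t, x$v))
  invisible(x)
}

# earliest sample of each plateau that is strictly higher than both
# neighbouring distinct values; NA breaks candidacy
plateau_peaks <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (is.na(x[i])) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && !is.na(x[j + 1L]) && x[j + 1L] == x[i]) j <- j + 1L
    if (!is.na(x[i - 1L]) && j < n && !is.na(x[j + 1L]) &&
      x[i] > x[i - 1L] && x[i] > x[j + 1L]) {
      peaks <- c(peaks, i)
    }
    i <- j + 1L
  }
  peaks
}

#' Detect uterine contraction cycles
#'
#' A contraction peak (UCp) is a sample strictly higher than its two
#' neighbours (plateaus collapse to their earliest sample) rising at
#' least `min_prominence` units above the resting tone. From the peak
#' the cycle start (UCs) and end (UCe) are the nearest earlier and later
#' crossings of the level `tone + tol`. Candidate cycles that share a
#' crossing (no return to tone between two peaks) are split at the
#' valley minimum between them.
#'
#' @param uc smoothed UC sample vector.
#' @param tone UC resting tone: a scalar, or the data frame from
#'   [estimate_uc_tone()].
#' @param rate samples per second.
#' @param config a [ctg_config()] (supplies `min_prominence` and `tol`).
#' @return list of `uc_cycle` objects, each with keypoints `ucs`, `ucp`,
#'   `uce`, sorted by start time and non-overlapping.
#' @export
detect_uc_cycles <- function(uc, tone, rate, config = ctg_config()) {
  n <- length(uc)
  tt <- (seq_len(n) - 1) / rate
  tone_at <- if (is.data.frame(tone)) window_value_at(tone, tt) else rep(tone, n)
  cross <- tone_at + config$tol

  peaks <- plateau_peaks(uc)
  peaks <- peaks[!is.na(uc[peaks]) &
    uc[peaks] >= tone_at[peaks] + config$min_prominence]
  if (length(peaks) == 0L) return(list())

  below <- !is.na(uc) & uc <= cross
  starts <- integer(length(peaks))
  ends <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    s <- which(below[seq_len(p - 1L)])
    starts[k] <- if (length(s)) max(s) else 1L
    e <- which(below[p:n])
    ends[k] <- if (length(e)) p + min(e) - 1L else n
  }

  # split overlapping neighbours at the valley minimum between peaks
  for (k in seq_along(peaks)[-1L]) {
    if (starts[k] < ends[k - 1L]) {
      valley_idx <- peaks[k - 1L]:peaks[k]
      valley <- valley_idx[which.min(uc[valley_idx])]
      ends[k - 1L] <- valley
      starts[k] <- valley
    }
  }

  cycles <- vector("list", length(peaks))
  keep <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    s <- starts[k]; p <- peaks[k]; e <- ends[k]
    if (!(s < p && p < e)) next
    cycles[[k]] <- structure(list(
      ucs = keypoint(tt[s], uc[s]),
      ucp = keypoint(tt[p], uc[p]),
      uce = keypoint(tt[e], uc[e])
    ), class = "uc_cycle")
    keep[k] <- TRUE
  }
  cycles[keep]
}

#' @export
print.uc_cycle <- function(x, ...) {
  cat(sprintf(
    "UC cycle: start %.1f s, peak %.1f s (%.1f), end %.1f s\n",
    x$ucs$t, x$ucp$t, x$ucp$v, x$uce$t
  ))
  invisible(x)
}

#' Extract a candidate deceleration linked to a contraction cycle
#'
#' Scans the smoothed FHR forward from the contraction start, within a
#' horizon extending `horizon_s` past the contraction end, for the
#' deepest excursion below the local baseline. The nadir (HRp) is the
#' centre of the minimum plateau; the fall start (HRs) — the point from
#' which the rate begins its monotone-trend fall — is localised by
#' fitting the raised-cosine fall template to the descending limb
#' (`acos` of the relative depth is linear in time) and taking the
#' fitted baseline intercept; the recovery (HRe) is the first return to
#' within `return_tol` bpm of the baseline after the nadir. Excursions
#' shallower than `min_excursion_bpm` are not reported.
#'
#' @param fhr smoothed FHR sample vector.
#' @param cycle a `uc_cycle` from [detect_uc_cycles()].
#' @param b local FHR baseline in bpm.
#' @param rate samples per second.
#' @param config a [ctg_config()].
#' @return a `decel_episode` (keypoints `hrs`, `hrp`, `hre`, the linked
#'   `cycle`, baseline `b`, `shoulder = NULL`), or `NULL` when no
#'   discernible excursion exists in the search window.
#' @export
extract_decel <- function(fhr, cycle, b, rate, config = ctg_config()) {
  n <- length(fhr)
  i0 <- max(1L, round(cycle$ucs$t * rate) + 1L)
  ih <- round((cycle$uce$t + config$horizon_s) * rate) + 1L
  if (i0 >= n) return(NULL)
  ih <- min(ih, n)

  win <- fhr[i0:ih]
  if (all(is.na(win))) return(NULL)
  ip <- i0 + which.min(win) - 1L
  m <- fhr[ip]
  depth <- b - m
  if (!is.finite(depth) || depth < config$min_excursion_bpm) return(NULL)

  # nadir plateau: contiguous run around the minimum within nadir_band;
  # its centre is a far steadier nadir-time estimate than the raw argmin
  lo_i <- ip
  while (lo_i > i0 && !is.na(fhr[lo_i - 1L]) &&
    fhr[lo_i - 1L] <= m + config$nadir_band_bpm) {
    lo_i <- lo_i - 1L
  }
  hi_i <- ip
  while (hi_i < ih && !is.na(fhr[hi_i + 1L]) &&
    fhr[hi_i + 1L] <= m + config$nadir_band_bpm) {
    hi_i <- hi_i + 1L
  }
  ip_c <- as.integer(round((lo_i + hi_i) / 2))

  # fall onset: the descending limb of a deceleration is modelled as a
  # raised cosine, so acos(1 - 2*relative depth) is linear in time along
  # the limb; fit that line between onset_frac of the depth and read the
  # onset off its baseline intercept (robust to noise, exact at zero)
  f1 <- config$onset_frac[1L]
  f2 <- config$onset_frac[2L]
  j <- lo_i
  while (j > i0 && !is.na(fhr[j - 1L]) &&
    (b - fhr[j - 1L]) > f1 * depth) {
    j <- j - 1L
  }
  limb <- j:lo_i
  frac <- (b - fhr[limb]) / depth
  keep <- !is.na(frac) & frac >= f1 & frac <= f2
  tt <- function(i) (i - 1) / rate
  hrs_t <- NA_real_
  if (sum(keep) >= 3L) {
    u <- tt(limb[keep])
    y <- acos(pmin(1, pmax(-1, 1 - 2 * frac[keep])))
    beta <- stats::cov(u, y) / stats::var(u)
    if (is.finite(beta) && beta > 0) hrs_t <- mean(u) - mean(y) / beta
  }
  if (!is.finite(hrs_t)) hrs_t <- tt(j) # crossing fallback
  hrs_t <- min(max(hrs_t, tt(i0)), tt(ip_c))
  hrs_i <- min(max(round(hrs_t * rate) + 1L, i0), ip_c)

  # recovery: first return to within return_tol of baseline after nadir
  after <- fhr[hi_i:n]
  rec <- which(!is.na(after) & after >= b - config$return_tol)
  if (!length(rec)) return(NULL)
  hre_i <- hi_i + min(rec) - 1L

  structure(list(
    hrs = keypoint(hrs_t, fhr[hrs_i]),
    hrp = keypoint(tt(ip_c), m),
    hre = keypoint(tt(hre_i), fhr[hre_i]),
    shoulder = NULL,
    cycle = cycle,
    b = b
  ), class = "decel_episode")
}

#' @export
print.decel_episode <- function(x, ...) {
  cat(sprintf(
    "Deceleration: fall %.1f s -> nadir %.1f s (%.1f bpm, depth %.1f), recovery %.1f s%s\n",
    x$hrs$t, x$hrp$t, x$hrp$v, x$b - x$hrp$v, x$hre$t,
    if (is.null(x$shoulder)) "" else sprintf(
      "; shoulder peak %.1f s (+%.1f bpm)",
      x$shoulder$hsp$t, x$shoulder$hsp$v - x$b
    )
  ))
  invisible(x)
}

#' Detect a shoulder acceleration after a deceleration
#'
#' Searches the `shoulder_search_s` seconds following the recovery point
#' for a local maximum rising above the baseline. If found, the shoulder
#' peak (HSp) is the highest such maximum and the shoulder end (HSe) the
#' first return to within `return_tol` of the baseline after it;
#' otherwise the episode is returned with the shoulder absent.
#'
#' @param fhr smoothed FHR sample vector.
#' @param episode a `decel_episode` from [extract_decel()].
#' @param b local FHR baseline in bpm.
#' @param rate samples per second.
#' @param config a [ctg_config()].
#' @return the episode, with `shoulder` filled (`hsp`, `hse` keypoints)
#'   or left `NULL`.
#' @export
detect_shoulder <- function(fhr, episode, b, rate, config = ctg_config()) {
  n <- length(fhr)
  i0 <- round(episode$hre$t * rate) + 1L
  ih <- min(n, i0 + round(config$shoulder_search_s * rate))
  if (i0 >= ih) return(episode)

  seg <- fhr[i0:ih]
  peaks <- plateau_peaks(seg)
  peaks <- peaks[!is.na(seg[peaks]) & seg[peaks] > b]
  if (!length(peaks)) return(episode)
  hsp_i <- i0 + peaks[which.max(seg[peaks])] - 1L

  after <- fhr[hsp_i:n]
  rec <- which(!is.na(after) & after <= b + config$return_tol)
  if (!length(rec)) return(episode)
  hse_i <- hsp_i + min(rec) - 1L

  tt <- function(i) (i - 1) / rate
  episode$shoulder <- list(
    hsp = keypoint(tt(hsp_i), fhr[hsp_i]),
    hse = keypoint(tt(hse_i), fhr[hse_i])
  )
  episode
}

#' Detect sustained high/low heart-rate episodes
#'
#' Maximal runs of consecutive samples at or above the tachycardia
#' threshold (kind `"high"`) or at or below the bradycardia threshold
#' (kind `"low"`) lasting at least `sustained_min_s` seconds. Missing
#' samples break runs, so episodes never merge across signal-loss gaps.
#' Run duration is counted as `n_samples / rate`.
#'
#' @param fhr cleaned, smoothed FHR sample vector.
#' @param rate samples per second.
#' @param criteria a [ctg_criteria()].
#' @return list of `sustained_episode` objects with fields `start`,
#'   `end` (times of the first and last sample, seconds), `duration_s`,
#'   `kind` and `extreme_v` (the most extreme bpm in the run).
#' @export
detect_sustained <- function(fhr, rate, criteria = ctg_criteria()) {
  out <- list()
  for (kind in c("high", "low")) {
    flag <- if (kind == "high") {
      !is.na(fhr) & fhr >= criteria$tachy_bpm
    } else {
      !is.na(fhr) & fhr <= criteria$brady_bpm
    }
    rr <- runs_of(flag)
    if (!nrow(rr)) next
    keep <- (rr$end - rr$start + 1L) / rate >= criteria$sustained_min_s
    for (k in which(keep)) {
      idx <- rr$start[k]:rr$end[k]
      out[[length(out) + 1L]] <- structure(list(
        start = (rr$start[k] - 1) / rate,
        end = (rr$end[k] - 1) / rate,
        duration_s = length(idx) / rate,
        kind = kind,
        extreme_v = if (kind == "high") max(fhr[idx]) else min(fhr[idx])
      ), class = "sustained_episode")
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "start"))]
}

#' @export
print.sustained_episode <- function(x, ...) {
  cat(sprintf(
    "Sustained %s rate: %.1f-%.1f s (%.0f s), extreme %.1f bpm\n",
    x$kind, x$start, x$end, x$duration_s, x$extreme_v
  ))
  invisible(x)
}
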