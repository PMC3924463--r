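# Independent oracles and small constructors shared across the suite.
# Oracles deliberately use naive loops, not the package's code paths.

# brute-force centered moving mean: window clipped at the ends, missing
# samples excluded, missing positions stay missing
oracle_moving_mean <- function(x, w) {
  n <- length(x)
  half <- (w - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    win <- x[max(1, i - half):min(n, i + half)]
    win <- win[!is.na(win)]
    out[i] <- mean(win)
  }
  out
}

# exhaustive run-length scan for sustained high/low episodes
oracle_sustained <- function(fhr, rate, tachy = 160, brady = 110,
                             min_s = 180) {
  out <- list()
  for (kind in c("high", "low")) {
    inrun <- FALSE
    start <- NA_integer_
    for (i in seq_len(length(fhr) + 1L)) {
      hit <- i <= length(fhr) && !is.na(fhr[i]) &&
        ((kind == "high" && fhr[i] >= tachy) ||
          (kind == "low" && fhr[i] <= brady))
      if (hit && !inrun) {
        inrun <- TRUE
        start <- i
      } else if (!hit && inrun) {
        inrun <- FALSE
        len <- i - start
        if (len / rate >= min_s) {
          out[[length(out) + 1L]] <- list(
            start = (start - 1) / rate, end = (i - 2) / rate, kind = kind
          )
        }
      }
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "start"))]
}

# direct truth-table evaluation of the four deceleration rule sets,
# written from the threshold inequalities, independent of classify_decel
oracle_decel_labels <- function(hrs_t, hrp_t, hre_t, b, hrp_v,
                                ucs_t, uce_t, hsp_v = NULL, hse_t = NULL,
                                crit = ctg_criteria()) {
  fall <- hrp_t - hrs_t
  lag_ok <- hrs_t >= ucs_t + crit$uc_lag_s
  depth_ok <- b - hrp_v >= crit$depth_bpm
  labs <- character(0)
  if (hrp_t < uce_t && fall >= crit$fall_time_s && lag_ok && depth_ok) {
    labs <- c(labs, "EarlyDeceleration")
  }
  if (hrp_t >= uce_t && fall >= crit$fall_time_s && depth_ok) {
    labs <- c(labs, "LateDeceleration")
  }
  if (fall <= crit$fall_time_s && lag_ok && depth_ok) {
    labs <- c(labs, "VariableDecelerationA")
  }
  if (!is.null(hsp_v) && lag_ok && depth_ok &&
    hsp_v - b >= crit$shoulder_height_bpm &&
    hse_t - hre_t >= crit$shoulder_lag_s) {
    labs <- c(labs, "VariableDecelerationB")
  }
  labs
}

# assemble a decel_episode from bare key-point numbers
make_episode <- function(hrs_t, hrp_t, hre_t, b, hrp_v,
                         ucs_t = 0, ucp_t = NULL, uce_t = 100,
                         hsp_t = NULL, hsp_v = NULL,
                         hse_t = NULL) {
  if (is.null(ucp_t)) ucp_t <- (ucs_t + uce_t) / 2
  shoulder <- NULL
  if (!is.null(hsp_t)) {
    shoulder <- list(
      hsp = keypoint(hsp_t, hsp_v),
      hse = keypoint(hse_t, b)
    )
  }
  structure(list(
    hrs = keypoint(hrs_t, b),
    hrp = keypoint(hrp_t, hrp_v),
    hre = keypoint(hre_t, b),
    shoulder = shoulder,
    cycle = structure(list(
      ucs = keypoint(ucs_t, 5),
      ucp = keypoint(ucp_t, 60),
      uce = keypoint(uce_t, 5)
    ), class = "uc_cycle"),
    b = b
  ), class = "decel_episode")
}

# step-function random trace exercising both rate thresholds and gaps
random_step_fhr <- function(n, rate) {
  x <- numeric(0)
  while (length(x) < n) {
    len <- sample(10:500, 1)
    lvl <- sample(c(
      runif(1, 80, 112), runif(1, 120, 150), runif(1, 158, 190), NA_real_
    ), 1, prob = c(0.3, 0.3, 0.3, 0.1))
    x <- c(x, rep(lvl, len))
  }
  x[seq_len(n)]
}
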