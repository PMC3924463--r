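#' Describe uterine-contraction bells for a synthetic trace
#'
#' Contractions are raised-cosine bells over the resting tone:
#' `amplitude/2 * (1 - cos(2*pi*(t - onset)/duration))` on
#' `[onset, onset + duration]`.
#'
#' @param onset_s bell onset times, seconds.
#' @param duration_s bell durations, seconds.
#' @param amplitude bell heights, relative units.
#' @return data frame with one row per contraction.
#' @export
uc_bells <- function(onset_s, duration_s, amplitude) {
  data.frame(
    onset_s = as.numeric(onset_s),
    duration_s = as.numeric(duration_s),
    amplitude = as.numeric(amplitude)
  )
}

#' Synthetic event constructors
#'
#' Each event injects one abnormality into a synthetic trace.
#' Deceleration events are inverted raised cosines anchored to a
#' contraction cycle: the fall lasts `fall_s` and the recovery mirrors
#' it; the lag (early/variable) is measured from the cycle's analytic
#' start (the crossing of tone + tol), and a late deceleration is
#' positioned by where its nadir falls after the cycle's analytic end.
#' An optional shoulder is a positive raised cosine appended after the
#' recovery. Sustained events are plateaus with 10-s raised-cosine
#' ramps.
#'
#' @param cycle 1-based index into the spec's contraction list.
#' @param depth_bpm deceleration depth below baseline, bpm.
#' @param fall_s fall time (onset to nadir), seconds; a variable
#'   deceleration must have `fall_s <= 30` (V/U shape).
#' @param lag_s fall onset lag after the contraction start, seconds.
#' @param nadir_after_uce_s how far the nadir trails the contraction
#'   end, seconds.
#' @param shoulder_height_bpm,shoulder_duration_s optional shoulder
#'   geometry; both or neither.
#' @param start_s,duration_s,level_bpm sustained-plateau geometry.
#' @return a list describing the event, for `synth_spec(events = ...)`.
#' @name synth_events
NULL

#' @rdname synth_events
#' @export
ev_early_decel <- function(cycle, depth_bpm, fall_s, lag_s) {
  list(
    type = "early_decel", cycle = cycle, depth_bpm = depth_bpm,
    fall_s = fall_s, lag_s = lag_s
  )
}

#' @rdname synth_events
#' @export
ev_late_decel <- function(cycle, depth_bpm, fall_s, nadir_after_uce_s) {
  list(
    type = "late_decel", cycle = cycle, depth_bpm = depth_bpm,
    fall_s = fall_s, nadir_after_uce_s = nadir_after_uce_s
  )
}

#' @rdname synth_events
#' @export
ev_var_decel <- function(cycle, depth_bpm, fall_s, lag_s,
                         shoulder_height_bpm = NULL,
                         shoulder_duration_s = NULL) {
  list(
    type = "var_decel", cycle = cycle, depth_bpm = depth_bpm,
    fall_s = fall_s, lag_s = lag_s,
    shoulder_height_bpm = shoulder_height_bpm,
    shoulder_duration_s = shoulder_duration_s
  )
}

#' @rdname synth_events
#' @export
ev_tachy <- function(start_s, duration_s, level_bpm) {
  list(
    type = "tachy", start_s = start_s, duration_s = duration_s,
    level_bpm = level_bpm
  )
}

#' @rdname synth_events
#' @export
ev_brady <- function(start_s, duration_s, level_bpm) {
  list(
    type = "brady", start_s = start_s, duration_s = duration_s,
    level_bpm = level_bpm
  )
}

#' Specify a synthetic CTG trace
#'
#' @param duration_s trace length, seconds.
#' @param rate samples per second.
#' @param baseline_bpm resting FHR level.
#' @param tone UC resting tone, relative units.
#' @param uc data frame from [uc_bells()] (possibly zero rows).
#' @param events list of events from the `ev_*()` constructors.
#' @param noise_sd_bpm standard deviation of additive Gaussian noise on
#'   the FHR channel.
#' @param dropout_prob per-sample probability of a missing sample,
#'   independently on each channel.
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   traces.
#' @param label trace identifier.
#' @param tol crossing offset used for the analytic cycle anchors; keep
#'   equal to the detection config's `tol`.
#' @return a validated object of class `synth_spec`.
#' @export
synth_spec <- function(duration_s, rate = 2, baseline_bpm = 140, tone = 5,
                       uc = uc_bells(numeric(0), numeric(0), numeric(0)),
                       events = list(), noise_sd_bpm = 0, dropout_prob = 0,
                       seed = 1, label = "synthetic", tol = 2) {
  spec <- structure(list(
    duration_s = as.numeric(duration_s), rate = as.numeric(rate),
    baseline_bpm = as.numeric(baseline_bpm), tone = as.numeric(tone),
    uc = uc, events = events, noise_sd_bpm = as.numeric(noise_sd_bpm),
    dropout_prob = as.numeric(dropout_prob), seed = as.integer(seed),
    label = as.character(label), tol = as.numeric(tol)
  ), class = "synth_spec")
  bad <- character(0)
  for (i in seq_along(events)) {
    ev <- events[[i]]
    msg <- validate_event(ev, spec)
    if (!is.null(msg)) bad <- c(bad, sprintf("event %d (%s): %s", i, ev$type, msg))
  }
  if (length(bad)) {
    stop(paste(c("invalid synthetic spec:", bad), collapse = "\n  "),
      call. = FALSE
    )
  }
  spec
}

validate_event <- function(ev, spec) {
  if (ev$type %in% c("early_decel", "late_decel", "var_decel")) {
    if (is.null(ev$cycle) || ev$cycle < 1 || ev$cycle > nrow(spec$uc)) {
      return("references a non-existent contraction cycle")
    }
    lvl <- spec$baseline_bpm - ev$depth_bpm
    if (lvl < 30 || spec$baseline_bpm > 240) {
      return("nadir level outside the physical range 30-240 bpm")
    }
    if (ev$type == "var_decel") {
      if (ev$fall_s > 30) return("variable deceleration must have fall_s <= 30")
      sh <- !is.null(ev$shoulder_height_bpm)
      if (sh != !is.null(ev$shoulder_duration_s)) {
        return("shoulder needs both height and duration")
      }
    }
    return(NULL)
  }
  if (ev$type %in% c("tachy", "brady")) {
    if (ev$level_bpm < 30 || ev$level_bpm > 240) {
      return("level outside the physical range 30-240 bpm")
    }
    if (ev$start_s < 0 || ev$start_s + ev$duration_s > spec$duration_s) {
      return("plateau extends outside the trace")
    }
    return(NULL)
  }
  "unknown event type"
}

# analytic anchors of bell k: times at which the bell crosses tol above
# the resting tone (what cycle detection localises as UCs/UCe), plus peak
bell_anchors <- function(spec, k) {
  D <- spec$uc$duration_s[k]
  amp <- spec$uc$amplitude[k]
  onset <- spec$uc$onset_s[k]
  frac <- min(1, max(-1, 1 - 2 * spec$tol / amp))
  u0 <- D * acos(frac) / (2 * pi)
  list(ucs = onset + u0, ucp = onset + D / 2, uce = onset + D - u0)
}

raised_cos <- function(t, onset, dur) {
  u <- t - onset
  out <- numeric(length(t))
  inside <- u >= 0 & u <= dur
  out[inside] <- 0.5 * (1 - cos(2 * pi * u[inside] / dur))
  out
}

# local RNG scope so generation never disturbs the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic CTG trace with ground truth
#'
#' Builds the UC channel as raised-cosine contractions over the resting
#' tone and the FHR channel as the baseline plus the injected events,
#' then adds Gaussian noise to the FHR and applies independent per-sample
#' dropout to both channels. The returned ground truth records, per
#' event, the analytic key points and the intended label (plus any label
#' logically entailed by the rule table for that geometry, e.g. a
#' V-shaped type-B variable deceleration also satisfies the type-A
#' rules).
#'
#' @param spec a [synth_spec()].
#' @return list with elements `trace` (a [ctg_trace()]) and `truth` (a
#'   `ctg_truth` list, one entry per event).
#' @export
generate_ctg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$duration_s * spec$rate)
  tt <- (seq_len(n) - 1) / spec$rate

  uc <- rep(spec$tone, n)
  for (k in seq_len(nrow(spec$uc))) {
    uc <- uc + spec$uc$amplitude[k] *
      raised_cos(tt, spec$uc$onset_s[k], spec$uc$duration_s[k])
  }

  fhr <- rep(spec$baseline_bpm, n)
  truth <- vector("list", length(spec$events))
  for (i in seq_along(spec$events)) {
    ev <- spec$events[[i]]
    res <- inject_event(fhr, tt, ev, spec)
    fhr <- res$fhr
    truth[[i]] <- res$truth
  }

  out <- with_seed(spec$seed, {
    f <- fhr
    u <- uc
    if (spec$noise_sd_bpm > 0) f <- f + stats::rnorm(n, 0, spec$noise_sd_bpm)
    if (spec$dropout_prob > 0) {
      f[stats::runif(n) < spec$dropout_prob] <- NA_real_
      u[stats::runif(n) < spec$dropout_prob] <- NA_real_
    }
    list(f = f, u = u)
  })

  list(
    trace = ctg_trace(out$f, out$u, rate = spec$rate, label = spec$label),
    truth = structure(truth, class = "ctg_truth")
  )
}

inject_event <- function(fhr, tt, ev, spec) {
  b <- spec$baseline_bpm
  if (ev$type %in% c("early_decel", "late_decel", "var_decel")) {
    anch <- bell_anchors(spec, ev$cycle)
    hrs_t <- switch(ev$type,
      early_decel = anch$ucs + ev$lag_s,
      var_decel = anch$ucs + ev$lag_s,
      late_decel = anch$uce + ev$nadir_after_uce_s - ev$fall_s
    )
    dur <- 2 * ev$fall_s
    fhr <- fhr - ev$depth_bpm * raised_cos(tt, hrs_t, dur)
    hre_t <- hrs_t + dur
    shoulder <- NULL
    if (ev$type == "var_decel" && !is.null(ev$shoulder_height_bpm)) {
      fhr <- fhr + ev$shoulder_height_bpm *
        raised_cos(tt, hre_t, ev$shoulder_duration_s)
      shoulder <- list(
        hsp = list(t = hre_t + ev$shoulder_duration_s / 2,
          v = b + ev$shoulder_height_bpm),
        hse = list(t = hre_t + ev$shoulder_duration_s, v = b)
      )
    }
    label <- switch(ev$type,
      early_decel = "EarlyDeceleration",
      late_decel = "LateDeceleration",
      var_decel = if (is.null(shoulder)) "VariableDecelerationA"
        else "VariableDecelerationB"
    )
    entailed <- if (identical(label, "VariableDecelerationB") &&
      ev$fall_s <= 30) "VariableDecelerationA" else character(0)
    truth <- list(
      type = ev$type, label = label, entailed = entailed, cycle = ev$cycle,
      hrs = list(t = hrs_t, v = b),
      hrp = list(t = hrs_t + ev$fall_s, v = b - ev$depth_bpm),
      hre = list(t = hre_t, v = b),
      shoulder = shoulder,
      ucs_t = anch$ucs, ucp_t = anch$ucp, uce_t = anch$uce
    )
    return(list(fhr = fhr, truth = truth))
  }
  # sustained plateau with raised-cosine ramps
  ramp <- min(10, ev$duration_s / 4)
  delta <- ev$level_bpm - b
  u <- tt - ev$start_s
  shape <- numeric(length(tt))
  shape[u >= 0 & u < ramp] <-
    0.5 * (1 - cos(pi * u[u >= 0 & u < ramp] / ramp))
  shape[u >= ramp & u <= ev$duration_s - ramp] <- 1
  dn <- u > ev$duration_s - ramp & u <= ev$duration_s
  shape[dn] <- 0.5 * (1 - cos(pi * (ev$duration_s - u[dn]) / ramp))
  fhr <- fhr + delta * shape
  truth <- list(
    type = ev$type,
    label = if (ev$type == "tachy") "Tachycardia" else "Bradycardia",
    entailed = character(0),
    start_t = ev$start_s, end_t = ev$start_s + ev$duration_s,
    level = ev$level_bpm
  )
  list(fhr = fhr, truth = truth)
}

#' Write / read ground-truth annotations as JSON
#'
#' @param truth a `ctg_truth` list from [generate_ctg()].
#' @param path file path.
#' @return `write_ctg_truth()`: `path` invisibly; `read_ctg_truth()`:
#'   the `ctg_truth` list.
#' @export
write_ctg_truth <- function(truth, path) {
  txt <- jsonlite::toJSON(unclass(truth),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  ok <- tryCatch(
    {
      writeLines(txt, path)
      TRUE
    },
    error = function(e) e, warning = function(w) w
  )
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write truth file '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_ctg_truth
#' @export
read_ctg_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(lapply(obj, function(e) {
    e$entailed <- unlist(e$entailed) %||% character(0)
    e
  }), class = "ctg_truth")
}
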