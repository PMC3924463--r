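#' Run the full diagnostic pipeline over a trace
#'
#' Cleans the trace, smooths both channels, estimates the FHR baseline
#' and UC resting tone, extracts contraction cycles and their linked
#' deceleration episodes (with shoulder search), detects sustained
#' high/low rate episodes, applies the six rule sets, and assembles one
#' alert event per (episode, label). Deterministic for fixed inputs.
#'
#' @param trace a [ctg_trace()].
#' @param criteria a [ctg_criteria()].
#' @param config a [ctg_config()].
#' @return an object of class `ctg_diagnosis`: a list with
#'   `trace_label`, `criteria`, `config`, `decels` (list of
#'   `list(episode, labels, rules, ambiguous)`), `sustained` (list of
#'   `list(episode, label)`), `alerts` (data frame `t`, `label`,
#'   `episode_id`, `recipient`, time-ordered), `baseline` and `uc_tone`
#'   window estimates, and `segments`.
#' @export
#' @examples
#' spec <- synth_spec(
#'   duration_s = 300, uc = uc_bells(onset_s = 60, duration_s = 100,
#'   amplitude = 60), events = list(ev_early_decel(1, depth_bpm = 45,
#'   fall_s = 45, lag_s = 10)), seed = 1
#' )
#' sim <- generate_ctg(spec)
#' dx <- ctg_diagnose(sim$trace)
#' dx
ctg_diagnose <- function(trace, criteria = ctg_criteria(),
                         config = ctg_config()) {
  stopifnot(inherits(trace, "ctg_trace"))
  cleaned <- ctg_clean(trace, config)
  segments <- attr(cleaned, "segments")
  rate <- cleaned$rate
  fhr_s <- ctg_smooth(cleaned$fhr, rate, config$smooth_window_s)
  uc_s <- ctg_smooth(cleaned$uc, rate, config$smooth_window_s)
  baseline <- estimate_fhr_baseline(cleaned, config$baseline_window_s, config)
  uc_tone <- estimate_uc_tone(cleaned, config$baseline_window_s, config)

  decels <- list()
  for (s in seq_len(nrow(segments))) {
    idx <- segments$start[s]:segments$end[s]
    seg_uc <- rep(NA_real_, length(uc_s))
    seg_uc[idx] <- uc_s[idx]
    seg_fhr <- rep(NA_real_, length(fhr_s))
    seg_fhr[idx] <- fhr_s[idx]
    cycles <- detect_uc_cycles(seg_uc, uc_tone, rate, config)
    for (cy in cycles) {
      b <- window_value_at(baseline, cy$ucp$t)
      ep <- extract_decel(seg_fhr, cy, b, rate, config)
      if (is.null(ep)) next
      ep <- detect_shoulder(seg_fhr, ep, b, rate, config)
      labels <- classify_decel(ep, criteria)
      decels[[length(decels) + 1L]] <- list(
        episode = ep,
        labels = as.character(labels),
        rules = attr(labels, "rules"),
        ambiguous = length(labels) > 1L
      )
    }
  }

  sustained <- lapply(
    detect_sustained(fhr_s, rate, criteria),
    function(ep) list(
      episode = ep,
      label = as.character(classify_sustained(ep, criteria))
    )
  )

  alerts <- build_alerts(decels, sustained, criteria$patient)
  structure(list(
    trace_label = cleaned$label,
    criteria = criteria,
    config = config,
    decels = decels,
    sustained = sustained,
    alerts = alerts,
    baseline = baseline,
    uc_tone = uc_tone,
    segments = segments
  ), class = "ctg_diagnosis")
}

# one alert per (episode, label), ordered by time
build_alerts <- function(decels, sustained, recipient) {
  rows <- list()
  for (i in seq_along(decels)) {
    for (lab in decels[[i]]$labels) {
      rows[[length(rows) + 1L]] <- data.frame(
        t = decels[[i]]$episode$hrp$t, label = lab,
        episode_id = sprintf("decel-%d", i), recipient = recipient,
        stringsAsFactors = FALSE
      )
    }
  }
  for (i in seq_along(sustained)) {
    rows[[length(rows) + 1L]] <- data.frame(
      t = sustained[[i]]$episode$start, label = sustained[[i]]$label,
      episode_id = sprintf("sustained-%d", i), recipient = recipient,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(
      t = numeric(0), label = character(0), episode_id = character(0),
      recipient = character(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$t, out$episode_id, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ctg_diagnosis <- function(x, ...) {
  cat(sprintf("CTG diagnosis for '%s' (patient '%s')\n",
    x$trace_label, x$criteria$patient))
  cat(sprintf("  %d deceleration episode(s), %d sustained-rate episode(s), %d alert(s)\n",
    length(x$decels), length(x$sustained), nrow(x$alerts)))
  if (nrow(x$alerts)) {
    for (i in seq_len(nrow(x$alerts))) {
      cat(sprintf("  alert: %-22s at %7.1f s  [%s]\n",
        x$alerts$label[i], x$alerts$t[i], x$alerts$episode_id[i]))
    }
  } else {
    cat("  no abnormality detected\n")
  }
  invisible(x)
}

#' @export
summary.ctg_diagnosis <- function(object, ...) {
  x <- object
  cat(sprintf("CTG diagnosis for '%s'\n", x$trace_label))
  cat(sprintf("  baseline windows: %s bpm; UC tone: %s units\n",
    paste(x$baseline$b, collapse = ", "),
    paste(signif(x$uc_tone$tone, 3), collapse = ", ")))
  for (i in seq_along(x$decels)) {
    d <- x$decels[[i]]
    e <- d$episode
    cat(sprintf(
      "  decel-%d: HRs %.1f s, HRp %.1f s (%.1f bpm), HRe %.1f s, B %.0f -> %s%s\n",
      i, e$hrs$t, e$hrp$t, e$hrp$v, e$hre$t, e$b,
      if (length(d$labels)) paste(d$labels, collapse = " + ") else "(no label)",
      if (d$ambiguous) " [ambiguous]" else ""
    ))
  }
  for (i in seq_along(x$sustained)) {
    s <- x$sustained[[i]]
    cat(sprintf("  sustained-%d: %s %.1f-%.1f s -> %s\n",
      i, s$episode$kind, s$episode$start, s$episode$end, s$label))
  }
  invisible(x)
}

#' @export
plot.ctg_diagnosis <- function(x, trace = NULL, ...) {
  if (is.null(trace)) {
    stop("supply the diagnosed ctg_trace via the `trace` argument",
      call. = FALSE)
  }
  tt <- trace_times(trace)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tt, trace$fhr, type = "l", col = "grey50",
    xlab = "time (s)", ylab = "FHR (bpm)", main = x$trace_label, ...)
  for (k in seq_len(nrow(x$baseline))) {
    graphics::segments(x$baseline$start_s[k], x$baseline$b[k],
      x$baseline$end_s[k], x$baseline$b[k], col = "red", lty = 2)
  }
  for (d in x$decels) {
    e <- d$episode
    graphics::points(c(e$hrs$t, e$hrp$t, e$hre$t),
      c(e$hrs$v, e$hrp$v, e$hre$v), col = "blue", pch = 19)
    if (!is.null(e$shoulder)) {
      graphics::points(c(e$shoulder$hsp$t, e$shoulder$hse$t),
        c(e$shoulder$hsp$v, e$shoulder$hse$v), col = "darkgreen", pch = 17)
    }
  }
  graphics::plot(tt, trace$uc, type = "l", col = "grey50",
    xlab = "time (s)", ylab = "UC (rel. units)", ...)
  for (d in x$decels) {
    cy <- d$episode$cycle
    graphics::points(c(cy$ucs$t, cy$ucp$t, cy$uce$t),
      c(cy$ucs$v, cy$ucp$v, cy$uce$v), col = "blue", pch = 19)
  }
  invisible(x)
}

kp_to_list <- function(kp) list(t = kp$t, v = kp$v)
kp_from_list <- function(l) keypoint(l$t, l$v)

decel_to_list <- function(d) {
  e <- d$episode
  list(
    hrs = kp_to_list(e$hrs), hrp = kp_to_list(e$hrp), hre = kp_to_list(e$hre),
    shoulder = if (is.null(e$shoulder)) NULL else list(
      hsp = kp_to_list(e$shoulder$hsp), hse = kp_to_list(e$shoulder$hse)
    ),
    cycle = list(
      ucs = kp_to_list(e$cycle$ucs), ucp = kp_to_list(e$cycle$ucp),
      uce = kp_to_list(e$cycle$uce)
    ),
    b = e$b,
    labels = as.list(d$labels),
    ambiguous = d$ambiguous
  )
}

decel_from_list <- function(l) {
  ep <- structure(list(
    hrs = kp_from_list(l$hrs), hrp = kp_from_list(l$hrp),
    hre = kp_from_list(l$hre),
    shoulder = if (is.null(l$shoulder)) NULL else list(
      hsp = kp_from_list(l$shoulder$hsp), hse = kp_from_list(l$shoulder$hse)
    ),
    cycle = structure(list(
      ucs = kp_from_list(l$cycle$ucs), ucp = kp_from_list(l$cycle$ucp),
      uce = kp_from_list(l$cycle$uce)
    ), class = "uc_cycle"),
    b = l$b
  ), class = "decel_episode")
  list(
    episode = ep, labels = unlist(l$labels) %||% character(0),
    rules = NULL, ambiguous = isTRUE(l$ambiguous)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a diagnosis report as structured JSON
#'
#' The JSON schema shipped at
#' `system.file("extdata", "report-schema.json", package = "ctgdiag")`
#' describes the layout. [read_ctg_report()] on the result reproduces
#' every episode key point and label exactly.
#'
#' @param report a `ctg_diagnosis`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_ctg_report <- function(report, path) {
  stopifnot(inherits(report, "ctg_diagnosis"))
  obj <- list(
    schema = "ctgdiag-report-v1",
    trace_label = report$trace_label,
    criteria = unclass(report$criteria),
    config = unclass(report$config),
    decels = lapply(report$decels, decel_to_list),
    sustained = lapply(report$sustained, function(s) list(
      start = s$episode$start, end = s$episode$end,
      duration_s = s$episode$duration_s, kind = s$episode$kind,
      extreme_v = s$episode$extreme_v, label = s$label
    )),
    alerts = report$alerts,
    baseline = report$baseline,
    uc_tone = report$uc_tone,
    segments = report$segments
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  ok <- tryCatch(
    {
      writeLines(txt, path)
      TRUE
    },
    error = function(e) e, warning = function(w) w
  )
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write report to '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' Read a diagnosis report back from JSON
#'
#' @param path path to a file written by [write_ctg_report()].
#' @return a `ctg_diagnosis` (rule evaluation detail is not serialised
#'   and comes back `NULL`).
#' @export
read_ctg_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "ctgdiag-report-v1")) {
    stop(sprintf("'%s' is not a ctgdiag report", path), call. = FALSE)
  }
  crit_args <- obj$criteria[names(obj$criteria) %in%
    c(criteria_keys(), "patient")]
  df_from <- function(l, cols) {
    if (!length(l)) {
      return(NULL)
    }
    do.call(rbind, lapply(l, function(r) {
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
  }
  alerts <- df_from(obj$alerts, c("t", "label", "episode_id", "recipient"))
  if (is.null(alerts)) {
    alerts <- data.frame(
      t = numeric(0), label = character(0), episode_id = character(0),
      recipient = character(0), stringsAsFactors = FALSE
    )
  }
  structure(list(
    trace_label = obj$trace_label,
    criteria = do.call(ctg_criteria, crit_args),
    config = do.call(ctg_config, lapply(
      obj$config[names(obj$config) %in% names(formals(ctg_config))],
      function(v) unlist(v)
    )),
    decels = lapply(obj$decels, decel_from_list),
    sustained = lapply(obj$sustained, function(s) list(
      episode = structure(list(
        start = s$start, end = s$end, duration_s = s$duration_s,
        kind = s$kind, extreme_v = s$extreme_v
      ), class = "sustained_episode"),
      label = s$label
    )),
    alerts = alerts,
    baseline = df_from(obj$baseline, c("start_s", "end_s", "b")),
    uc_tone = df_from(obj$uc_tone, c("start_s", "end_s", "tone")),
    segments = df_from(obj$segments, c("start", "end"))
  ), class = "ctg_diagnosis")
}

#' Deliver alert events to a consumer
#'
#' Passes every alert of the report to `sink` exactly once, in time
#' order. `sink` is any function accepting one alert (a one-row data
#' frame); a failing call is retried once, then logged via [warning()]
#' and skipped.
#'
#' @param report a `ctg_diagnosis`.
#' @param sink function of one argument consuming an alert event.
#' @return the number of alerts delivered.
#' @export
emit_alerts <- function(report, sink) {
  stopifnot(inherits(report, "ctg_diagnosis"), is.function(sink))
  delivered <- 0L
  for (i in seq_len(nrow(report$alerts))) {
    event <- report$alerts[i, , drop = FALSE]
    ok <- tryCatch(
      {
        sink(event)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      ok <- tryCatch(
        {
          sink(event)
          TRUE
        },
        error = function(e) FALSE
      )
      if (!ok) {
        warning(sprintf(
          "alert '%s' at %.1f s could not be delivered after retry",
          event$label, event$t
        ), call. = FALSE)
        next
      }
    }
    delivered <- delivered + 1L
  }
  delivered
}
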