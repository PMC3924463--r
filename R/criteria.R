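#' Diagnostic criteria set
#'
#' The numeric thresholds behind the six abnormality rules, one instance
#' per patient profile. Defaults are the conventional obstetric values:
#' tachycardia above 160 bpm and bradycardia below 110 bpm sustained for
#' at least three minutes; a deceleration must fall for at least 30 s to
#' count as early/late (at most 30 s for variable type A), start at least
#' 5 s after the contraction onset, and reach a nadir at least 15 bpm
#' below baseline; a type-B variable deceleration additionally needs a
#' post-deceleration "shoulder" acceleration at least 10 bpm above
#' baseline lasting at least 10 s.
#'
#' @param tachy_bpm tachycardia threshold, bpm.
#' @param brady_bpm bradycardia threshold, bpm.
#' @param sustained_min_s minimum duration of a sustained high/low rate
#'   episode, seconds.
#' @param fall_time_s fall-time threshold (onset to nadir), seconds.
#' @param uc_lag_s minimum lag of the heart-rate fall after the
#'   contraction onset, seconds.
#' @param depth_bpm minimum depth of the nadir below baseline, bpm.
#' @param shoulder_height_bpm minimum shoulder peak height above
#'   baseline, bpm.
#' @param shoulder_lag_s minimum shoulder duration after recovery,
#'   seconds.
#' @param patient free-text patient identifier.
#' @return an object of class `ctg_criteria` (a named list).
#' @seealso [read_ctg_criteria()] to load a per-patient XML profile.
#' @export
ctg_criteria <- function(tachy_bpm = 160, brady_bpm = 110,
                         sustained_min_s = 180, fall_time_s = 30,
                         uc_lag_s = 5, depth_bpm = 15,
                         shoulder_height_bpm = 10, shoulder_lag_s = 10,
                         patient = "default") {
  x <- list(
    tachy_bpm = tachy_bpm, brady_bpm = brady_bpm,
    sustained_min_s = sustained_min_s, fall_time_s = fall_time_s,
    uc_lag_s = uc_lag_s, depth_bpm = depth_bpm,
    shoulder_height_bpm = shoulder_height_bpm,
    shoulder_lag_s = shoulder_lag_s
  )
  for (k in names(x)) {
    v <- x[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("criteria threshold '%s' must be strictly positive", k),
        call. = FALSE
      )
    }
    x[[k]] <- as.numeric(v)
  }
  if (x$tachy_bpm <= x$brady_bpm) {
    stop("tachy_bpm must exceed brady_bpm", call. = FALSE)
  }
  x$patient <- as.character(patient)[1L]
  class(x) <- "ctg_criteria"
  x
}

#' @export
print.ctg_criteria <- function(x, ...) {
  cat(sprintf("CTG criteria for patient '%s':\n", x$patient))
  for (k in criteria_keys()) cat(sprintf("  %-20s %g\n", k, x[[k]]))
  invisible(x)
}

criteria_keys <- function() {
  c(
    "tachy_bpm", "brady_bpm", "sustained_min_s", "fall_time_s",
    "uc_lag_s", "depth_bpm", "shoulder_height_bpm", "shoulder_lag_s"
  )
}

# which threshold keys belong under which <symptom> element when writing
criteria_symptom_map <- function() {
  list(
    Tachycardia = c("tachy_bpm", "sustained_min_s"),
    Bradycardia = c("brady_bpm", "sustained_min_s"),
    EarlyDeceleration = c("fall_time_s", "uc_lag_s", "depth_bpm"),
    LateDeceleration = c("fall_time_s", "depth_bpm"),
    VariableDecelerationA = c("fall_time_s", "uc_lag_s", "depth_bpm"),
    VariableDecelerationB = c(
      "uc_lag_s", "depth_bpm", "shoulder_height_bpm", "shoulder_lag_s"
    )
  )
}

#' Read a per-patient criteria profile from XML
#'
#' The dialect groups `<threshold key="..." value="..."/>` elements under
#' `<symptom name="...">` elements inside a root `<criteria patient="...">`.
#' Threshold keys are the field names of [ctg_criteria()]; a key may
#' appear under several symptoms (e.g. `sustained_min_s` under both
#' Tachycardia and Bradycardia) and must then agree. Any key absent from
#' the file takes its default value, with a warning naming it.
#'
#' @param path path to the XML file.
#' @return a [ctg_criteria()] object.
#' @export
read_ctg_criteria <- function(path) {
  doc <- xml2::read_xml(path) # malformed XML errors here
  root <- xml2::xml_name(doc)
  if (!identical(root, "criteria")) {
    stop(sprintf("expected root element <criteria>, found <%s>", root),
      call. = FALSE
    )
  }
  patient <- xml2::xml_attr(doc, "patient")
  if (is.na(patient)) patient <- "default"
  nodes <- xml2::xml_find_all(doc, ".//threshold")
  keys <- xml2::xml_attr(nodes, "key")
  vals <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, "value")))
  seen <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% criteria_keys()) {
      warning(sprintf("ignoring unknown threshold key '%s'", k), call. = FALSE)
      next
    }
    if (is.na(vals[i]) || vals[i] <= 0) {
      stop(sprintf("threshold '%s' must be a strictly positive number", k),
        call. = FALSE
      )
    }
    if (!is.null(seen[[k]]) && seen[[k]] != vals[i]) {
      stop(sprintf("threshold '%s' appears with conflicting values", k),
        call. = FALSE
      )
    }
    seen[[k]] <- vals[i]
  }
  missing_keys <- setdiff(criteria_keys(), names(seen))
  for (k in missing_keys) {
    warning(sprintf("criteria file omits '%s'; using default", k),
      call. = FALSE
    )
  }
  args <- seen
  args$patient <- patient
  do.call(ctg_criteria, args)
}

#' Write a criteria profile as XML
#'
#' Inverse of [read_ctg_criteria()]: every threshold is written under each
#' symptom whose rule set uses it.
#'
#' @param criteria a [ctg_criteria()] object.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_ctg_criteria <- function(criteria, path) {
  doc <- xml2::xml_new_root("criteria", patient = criteria$patient)
  smap <- criteria_symptom_map()
  for (sym in names(smap)) {
    node <- xml2::xml_add_child(doc, "symptom", name = sym)
    for (k in smap[[sym]]) {
      xml2::xml_add_child(node, "threshold",
        key = k,
        value = formatC(criteria[[k]], digits = 15, format = "g")
      )
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
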