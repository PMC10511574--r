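#' pH recording container
#'
#' A \code{ph_trace} holds one ambulatory esophageal pH recording: regularly
#' sampled pH values (each sample covers the half-open interval
#' \code{[time_s, time_s + sample_interval_s)}), posture intervals
#' (upright/supine) jointly covering the recording, and optional meal
#' intervals. Times are seconds from recording start; all intervals are
#' half-open \code{[start, end)}.
#'
#' @param recording_id identifier string.
#' @param time_s strictly increasing sample times (s).
#' @param ph pH values in \code{[0, 9]}.
#' @param sample_interval_s sampling interval (s); default 6 (Bravo-capsule
#'   convention).
#' @param posture data.frame with columns \code{start_s}, \code{end_s},
#'   \code{posture} (\code{"upright"}/\code{"supine"}) covering
#'   \code{[0, duration_s)}; default all-upright.
#' @param meals optional data.frame with \code{start_s}, \code{end_s}.
#' @param duration_s recording duration; default last sample end.
#' @return a validated \code{ph_trace} object.
#' @export
ph_trace <- function(recording_id, time_s, ph, sample_interval_s = 6,
                     posture = NULL, meals = NULL, duration_s = NULL) {
  duration_s <- duration_s %||% (max(time_s) + sample_interval_s)
  if (is.null(posture))
    posture <- data.frame(start_s = 0, end_s = duration_s,
                          posture = "upright", stringsAsFactors = FALSE)
  if (is.null(meals))
    meals <- data.frame(start_s = numeric(0), end_s = numeric(0))
  x <- structure(list(recording_id = as.character(recording_id),
                      time_s = as.numeric(time_s), ph = as.numeric(ph),
                      sample_interval_s = sample_interval_s,
                      posture = posture, meals = meals,
                      duration_s = duration_s),
                 class = "ph_trace")
  validate_ph_trace(x)
  x
}

#' @rdname ph_trace
#' @param x a \code{ph_trace}.
#' @export
validate_ph_trace <- function(x) {
  stopifnot(inherits(x, "ph_trace"))
  t <- x$time_s
  if (length(t) == 0L) stop("empty trace: no samples")
  if (length(t) != length(x$ph)) stop("time_s and ph lengths differ")
  if (any(diff(t) <= 0)) {
    i <- which(diff(t) <= 0)[1]
    stop(sprintf("non-monotone time at sample %d (%.10g followed by %.10g)",
                 i, t[i], t[i + 1]))
  }
  if (t[1] < 0 || max(t) > x$duration_s)
    stop("sample times outside [0, duration_s]")
  if (any(x$ph < 0 | x$ph > 9, na.rm = TRUE) || anyNA(x$ph))
    stop("ph out of range [0, 9]")
  if (x$duration_s < 120) stop("recording shorter than 2 min")
  p <- x$posture[order(x$posture$start_s), , drop = FALSE]
  if (nrow(p) == 0L) stop("posture intervals must cover the recording")
  if (!all(p$posture %in% c("upright", "supine")))
    stop("posture must be 'upright' or 'supine'")
  tol <- 1e-6
  if (abs(p$start_s[1]) > tol || abs(p$end_s[nrow(p)] - x$duration_s) > tol ||
      (nrow(p) > 1 && any(abs(p$start_s[-1] - p$end_s[-nrow(p)]) > tol)))
    stop("posture intervals must be non-overlapping and cover [0, duration_s)")
  m <- x$meals
  if (nrow(m) > 0) {
    m <- m[order(m$start_s), , drop = FALSE]
    if (any(m$start_s < -tol) || any(m$end_s > x$duration_s + tol) ||
        any(m$end_s <= m$start_s) ||
        (nrow(m) > 1 && any(m$start_s[-1] < m$end_s[-nrow(m)] - tol)))
      stop("meal intervals must be non-overlapping and within [0, duration_s)")
  }
  invisible(TRUE)
}

#' @export
print.ph_trace <- function(x, ...) {
  cat(sprintf("<ph_trace %s: %d samples @ %gs, %.2f h, %d posture / %d meal intervals>\n",
              x$recording_id, length(x$time_s), x$sample_interval_s,
              x$duration_s / 3600, nrow(x$posture), nrow(x$meals)))
  invisible(x)
}

#' Read / write pH traces
#'
#' The trace file is comma-delimited with header \code{time_s,ph}; an optional
#' companion annotation file has header \code{start_s,end_s,kind} with kind
#' one of \code{upright}, \code{supine}, \code{meal}. \code{write_trace}
#' emits the canonical form (stable number formatting, annotations sorted by
#' start), so write-read-write round-trips are byte identical.
#'
#' @param path trace file path.
#' @param annotations optional annotation file path.
#' @param recording_id identifier; defaults to the file name.
#' @param sample_interval_s override for the sampling interval; by default
#'   inferred from the median time step.
#' @return \code{read_trace} returns a \code{ph_trace}.
#' @export
read_trace <- function(path, annotations = NULL, recording_id = NULL,
                       sample_interval_s = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L || trimws(lines[1]) != "time_s,ph")
    stop("malformed header: expected 'time_s,ph' in ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  tt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  pp <- suppressWarnings(as.numeric(vapply(parts, function(p) p[2] %||% NA_character_, "")))
  bad <- sort(unique(c(bad, which(is.na(tt) | is.na(pp)))))
  if (length(bad))
    stop("unparseable trace rows at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for header
  posture <- NULL; meals <- NULL
  if (!is.null(annotations)) {
    if (!file.exists(annotations)) stop("annotation file not found: ", annotations)
    ann <- read.csv(annotations, stringsAsFactors = FALSE)
    if (!identical(names(ann), c("start_s", "end_s", "kind")))
      stop("malformed header: expected 'start_s,end_s,kind' in ", annotations)
    if (!all(ann$kind %in% c("upright", "supine", "meal")))
      stop("annotation kind must be upright, supine or meal")
    pos <- ann[ann$kind != "meal", , drop = FALSE]
    if (nrow(pos))
      posture <- data.frame(start_s = pos$start_s, end_s = pos$end_s,
                            posture = pos$kind, stringsAsFactors = FALSE)
    ml <- ann[ann$kind == "meal", c("start_s", "end_s"), drop = FALSE]
    if (nrow(ml)) meals <- ml
  }
  dt <- if (length(tt) > 1) stats::median(diff(tt)) else 6
  ph_trace(recording_id %||% sub("\\.[^.]*$", "", basename(path)),
           tt, pp, sample_interval_s %||% dt, posture, meals)
}

#' @rdname read_trace
#' @param trace a \code{ph_trace}.
#' @param annotations_path optional path for the companion annotation file.
#' @export
write_trace <- function(trace, path, annotations_path = NULL) {
  validate_ph_trace(trace)
  writeLines(c("time_s,ph",
               paste(fmt_num(trace$time_s), fmt_num(trace$ph), sep = ",")),
             path)
  if (!is.null(annotations_path)) {
    ann <- rbind(
      data.frame(start_s = trace$posture$start_s, end_s = trace$posture$end_s,
                 kind = trace$posture$posture, stringsAsFactors = FALSE),
      if (nrow(trace$meals))
        data.frame(start_s = trace$meals$start_s, end_s = trace$meals$end_s,
                   kind = "meal", stringsAsFactors = FALSE))
    ann <- ann[order(ann$start_s, ann$kind), , drop = FALSE]
    writeLines(c("start_s,end_s,kind",
                 paste(fmt_num(ann$start_s), fmt_num(ann$end_s), ann$kind,
                       sep = ",")),
               annotations_path)
  }
  invisible(path)
}

#' Symptom event log
#'
#' Up to three tracked symptoms per recording, each event a (time, symptom)
#' pair; every event's symptom must be among the tracked ones.
#'
#' @param recording_id identifier string.
#' @param tracked_symptoms character vector, 1-3 distinct labels.
#' @param events data.frame with columns \code{time_s}, \code{symptom}
#'   (possibly zero rows).
#' @param duration_s optional recording duration; events must fall inside it.
#' @param strict if TRUE unknown symptom labels are an error, otherwise they
#'   map to category "other" with a warning.
#' @return a \code{symptom_log}.
#' @export
symptom_log <- function(recording_id, tracked_symptoms,
                        events = data.frame(time_s = numeric(0),
                                            symptom = character(0)),
                        duration_s = NULL, strict = FALSE) {
  tracked_symptoms <- as.character(tracked_symptoms)
  if (length(unique(tracked_symptoms)) != length(tracked_symptoms))
    stop("tracked symptoms must be distinct")
  if (length(tracked_symptoms) < 1L || length(tracked_symptoms) > 3L)
    stop("at most 3 tracked symptoms (and at least 1)")
  categories <- symptom_category(tracked_symptoms, strict = strict)
  events <- data.frame(time_s = as.numeric(events$time_s),
                       symptom = as.character(events$symptom),
                       stringsAsFactors = FALSE)
  if (nrow(events)) {
    if (!all(events$symptom %in% tracked_symptoms))
      stop("every event's symptom must be among the tracked symptoms")
    if (any(events$time_s < 0)) stop("event times must be >= 0")
    if (!is.null(duration_s) && any(events$time_s > duration_s))
      stop("event times must be within [0, duration_s]")
    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(recording_id = as.character(recording_id),
                 tracked_symptoms = tracked_symptoms,
                 categories = categories, events = events),
            class = "symptom_log")
}

#' @export
print.symptom_log <- function(x, ...) {
  cat(sprintf("<symptom_log %s: %s; %d events>\n", x$recording_id,
              paste(x$tracked_symptoms, collapse = ", "), nrow(x$events)))
  invisible(x)
}

#' Read / write symptom logs (JSON)
#'
#' @param path JSON file with fields \code{recording_id},
#'   \code{tracked_symptoms} and \code{events} (array of
#'   \code{{time_s, symptom}}).
#' @inheritParams symptom_log
#' @return \code{read_symptom_log} returns a \code{symptom_log}.
#' @export
read_symptom_log <- function(path, duration_s = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("symptom log not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  ev <- raw$events
  if (is.null(ev) || length(ev) == 0L || NROW(ev) == 0L)
    ev <- data.frame(time_s = numeric(0), symptom = character(0))
  symptom_log(raw$recording_id, raw$tracked_symptoms, ev,
              duration_s = duration_s, strict = strict)
}

#' @rdname read_symptom_log
#' @param log a \code{symptom_log}.
#' @export
write_symptom_log <- function(log, path) {
  stopifnot(inherits(log, "symptom_log"))
  obj <- list(recording_id = log$recording_id,
              tracked_symptoms = log$tracked_symptoms,
              events = if (nrow(log$events)) log$events else list())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- cohort tables ----------------------------------------------------------

cohort_columns <- function() c(
  "patient_id", "age", "sex", "bmi", "preop_hrql", "postop_hrql",
  "satisfied", "ppi_free", "fundoplication", "followup_months",
  "demeester", "sap_positive_count", "per_symptom_sap")

#' Read / write cohort tables
#'
#' One row per patient; comma-delimited with the canonical column order
#' \code{patient_id, age, sex, bmi, preop_hrql, postop_hrql, satisfied,
#' ppi_free, fundoplication, followup_months, demeester, sap_positive_count,
#' per_symptom_sap}. Missing values are empty cells; booleans are
#' \code{true}/\code{false}; \code{per_symptom_sap} encodes the tracked
#' symptoms and their SAP flags as \code{"heartburn=1|cough=0"} (flag empty
#' for a not-assessable symptom). \code{sap_positive_count} must equal the
#' number of flags equal to 1.
#'
#' @param path cohort CSV path.
#' @param strict passed to the symptom-label check.
#' @return \code{read_cohort} returns a data.frame with the canonical columns
#'   and proper types.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 na.strings = NULL)
  if (!identical(names(df), cohort_columns()))
    stop("malformed header: expected canonical cohort columns in ", path)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  bool <- function(v) ifelse(v == "", NA, v == "true")
  out <- data.frame(
    patient_id = df$patient_id,
    age = num(df$age), sex = ifelse(df$sex == "", NA, df$sex),
    bmi = num(df$bmi),
    preop_hrql = num(df$preop_hrql), postop_hrql = num(df$postop_hrql),
    satisfied = bool(df$satisfied), ppi_free = bool(df$ppi_free),
    fundoplication = ifelse(df$fundoplication == "", NA, df$fundoplication),
    followup_months = num(df$followup_months),
    demeester = num(df$demeester),
    sap_positive_count = num(df$sap_positive_count),
    per_symptom_sap = df$per_symptom_sap,
    stringsAsFactors = FALSE)
  validate_cohort(out, strict = strict)
  out
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame with the canonical columns.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  fmt <- function(v) {
    if (is.logical(v)) ifelse(is.na(v), "", ifelse(v, "true", "false"))
    else if (is.numeric(v)) fmt_num(v)
    else ifelse(is.na(v), "", as.character(v))
  }
  cols <- cohort_columns()
  m <- vapply(cols, function(cn) fmt(cohort[[cn]]), character(nrow(cohort)))
  if (nrow(cohort) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, cols))
  writeLines(c(paste(cols, collapse = ","),
               apply(m, 1, paste, collapse = ",")),
             path)
  invisible(path)
}

#' @rdname read_cohort
#' @export
validate_cohort <- function(cohort, strict = FALSE) {
  miss <- setdiff(cohort_columns(), names(cohort))
  if (length(miss)) stop("cohort missing column(s): ", paste(miss, collapse = ", "))
  h <- c(cohort$preop_hrql, cohort$postop_hrql)
  if (any(h < 0 | h > 80, na.rm = TRUE))
    stop("hrql totals must be in [0, 80]")
  if (any(!cohort$sex %in% c("female", "male") & !is.na(cohort$sex)))
    stop("sex must be 'female' or 'male'")
  if (any(!cohort$fundoplication %in% c("nissen", "partial") &
          !is.na(cohort$fundoplication)))
    stop("fundoplication must be 'nissen' or 'partial'")
  ps <- parse_per_symptom_sap(cohort$per_symptom_sap, strict = strict)
  npos <- vapply(ps, function(p) sum(p$sap_flag %in% 1), numeric(1))
  bad <- which(!is.na(cohort$sap_positive_count) &
               cohort$sap_positive_count != npos)
  if (length(bad))
    stop("sap_positive_count inconsistent with per_symptom_sap flags for row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

# "heartburn=1|cough=0|nausea=" -> data.frame(symptom, sap_flag (1/0/NA))
parse_per_symptom_sap <- function(s, strict = FALSE) {
  lapply(s, function(one) {
    if (is.na(one) || !nzchar(one))
      return(data.frame(symptom = character(0), sap_flag = numeric(0)))
    kv <- strsplit(strsplit(one, "|", fixed = TRUE)[[1]], "=", fixed = TRUE)
    sym <- vapply(kv, `[`, "", 1)
    flag <- suppressWarnings(as.numeric(vapply(kv, function(p)
      if (length(p) > 1 && nzchar(p[2])) p[2] else NA_character_, "")))
    if (length(sym) > 3L) stop("at most 3 tracked symptoms")
    invisible(symptom_category(sym, strict = strict))
    data.frame(symptom = sym, sap_flag = flag, stringsAsFactors = FALSE)
  })
}

format_per_symptom_sap <- function(symptoms, flags) {
  paste(paste0(symptoms, "=",
               ifelse(is.na(flags), "", as.character(as.integer(flags)))),
        collapse = "|")
}

#' Long view of per-symptom SAP flags
#'
#' Expands the packed \code{per_symptom_sap} column into one row per
#' (patient, tracked symptom) with the SAP flag (1, 0 or NA when not
#' assessable) and the symptom's category.
#'
#' @inheritParams write_cohort
#' @return data.frame with columns \code{patient_id}, \code{symptom},
#'   \code{sap_flag}, \code{category}.
#' @export
cohort_symptom_long <- function(cohort) {
  ps <- parse_per_symptom_sap(cohort$per_symptom_sap)
  n <- vapply(ps, nrow, integer(1))
  out <- do.call(rbind, ps)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(patient_id = character(0), symptom = character(0),
                      sap_flag = numeric(0), category = character(0)))
  out$patient_id <- rep(cohort$patient_id, n)
  out$category <- suppressWarnings(symptom_category(out$symptom))
  out[, c("patient_id", "symptom", "sap_flag", "category")]
}
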