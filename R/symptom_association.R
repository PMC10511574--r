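#' Partition a recording into consecutive windows
#'
#' Tiles \code{[0, duration_s)} with consecutive half-open windows of
#' \code{window_s} seconds (default 120 s, the 2-min periods of the SAP
#' method); the last window is shorter when the duration is not a multiple.
#'
#' @param trace a \code{ph_trace}, or a single numeric duration in seconds.
#' @param window_s window length in seconds.
#' @return a \code{window_grid} with \code{starts}, \code{ends}, \code{n}.
#' @export
partition_windows <- function(trace, window_s = 120) {
  duration <- if (inherits(trace, "ph_trace")) trace$duration_s
              else as.numeric(trace)
  if (duration < window_s)
    stop("recording shorter than one window")
  n <- as.integer(ceiling(duration / window_s - 1e-12))
  starts <- (seq_len(n) - 1) * window_s
  structure(list(window_s = window_s, starts = starts,
                 ends = pmin(starts + window_s, duration),
                 n = n, duration_s = duration),
            class = "window_grid")
}

window_index <- function(grid, times) {
  i <- findInterval(times, grid$starts)
  i[times < 0 | times >= grid$duration_s] <- NA_integer_
  i
}

#' Label reflux-positive windows
#'
#' A window is reflux-positive if either (criterion A) it contains at least
#' \code{sustained_s} seconds of pH below 4 from a single sub-4 run (each
#' sample covering \code{[t, t + interval)}; a run straddling a window
#' boundary counts in every window where its within-window portion reaches
#' \code{sustained_s}), or (criterion B) it contains a sample pair no more
#' than \code{drop_span_s} seconds apart whose pH falls by more than
#' \code{drop_units}. At the default 6-s sampling, criterion B can never fire
#' with \code{drop_span_s = 5}; it is faithful to the stated 5-s rule and
#' becomes active on finer-sampled traces.
#'
#' @param trace a \code{ph_trace}.
#' @param grid the \code{window_grid} partition of the same trace.
#' @param threshold_ph sub-4 criterion threshold.
#' @param sustained_s minimum within-window sub-threshold time (criterion A).
#' @param drop_units,drop_span_s rapid-drop criterion (criterion B).
#' @return logical vector of length \code{grid$n}.
#' @export
label_reflux_windows <- function(trace, grid, threshold_ph = 4.0,
                                 sustained_s = 5, drop_units = 1.0,
                                 drop_span_s = 5) {
  stopifnot(inherits(grid, "window_grid"))
  t <- trace$time_s; ph <- trace$ph; dt <- trace$sample_interval_s
  pos <- logical(grid$n)
  # criterion A: per sub-4 run, flag windows overlapped by >= sustained_s
  below <- ph < threshold_ph
  if (any(below)) {
    r <- rle(below)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    si <- starts[r$values]; ei <- ends[r$values]
    rs <- t[si]; re <- pmin(t[ei] + dt, grid$duration_s)
    for (j in seq_along(rs)) {
      w0 <- window_index(grid, rs[j])
      w1 <- window_index(grid, re[j] - 1e-9)
      w <- w0:w1
      ov <- pmin(re[j], grid$ends[w]) - pmax(rs[j], grid$starts[w])
      pos[w[ov >= sustained_s - 1e-9]] <- TRUE
    }
  }
  # criterion B: pH drop > drop_units between samples <= drop_span_s apart,
  # both samples inside the same window
  n <- length(t)
  wi <- window_index(grid, t)
  k <- 1L
  while (k < n) {
    dtime <- t[(1L + k):n] - t[1L:(n - k)]
    if (min(dtime) > drop_span_s) break
    hit <- dtime <= drop_span_s + 1e-9 &
      (ph[1L:(n - k)] - ph[(1L + k):n]) > drop_units &
      wi[1L:(n - k)] == wi[(1L + k):n]
    pos[unique(wi[which(hit)])] <- TRUE
    k <- k + 1L
  }
  pos
}

#' Label symptom-positive windows
#'
#' A window is symptom-positive for a given symptom if at least one event of
#' that symptom falls inside the half-open window (an event exactly on a
#' boundary belongs to the later window).
#'
#' @param grid a \code{window_grid}.
#' @param log a \code{symptom_log}.
#' @param symptom one tracked symptom label.
#' @return logical vector of length \code{grid$n}.
#' @export
label_symptom_windows <- function(grid, log, symptom) {
  stopifnot(inherits(grid, "window_grid"), inherits(log, "symptom_log"))
  if (!symptom %in% log$tracked_symptoms)
    stop("symptom '", symptom, "' is not tracked in this log")
  v <- logical(grid$n)
  ev <- log$events$time_s[log$events$symptom == symptom]
  wi <- window_index(grid, ev)
  v[wi[!is.na(wi)]] <- TRUE
  v
}

#' Cross-tabulate reflux and symptom window labels
#'
#' @param reflux_vec,symptom_vec logical label vectors of equal length.
#' @return named count vector \code{c(a, b, c, d)}: a = (symptom+, reflux+),
#'   b = (symptom+, reflux-), c = (symptom-, reflux+), d = (symptom-,
#'   reflux-).
#' @export
build_table <- function(reflux_vec, symptom_vec) {
  if (length(reflux_vec) != length(symptom_vec))
    stop("label vectors must have equal length")
  c(a = sum(symptom_vec & reflux_vec),
    b = sum(symptom_vec & !reflux_vec),
    c = sum(!symptom_vec & reflux_vec),
    d = sum(!symptom_vec & !reflux_vec))
}

#' Symptom association probability from a 2x2 window table
#'
#' SAP = (1 - p) x 100 where p is the Fisher exact p-value of the
#' symptom-by-reflux window cross-tabulation; a symptom is SAP-positive when
#' SAP >= 95% (equivalently p <= 0.05). A table with an empty symptom margin
#' forces p = 1 and SAP 0.
#'
#' @param table output of \code{build_table} (or any 2x2 input accepted by
#'   \code{fisher_exact_2x2}).
#' @param alternative sidedness of the exact test; two-sided by default.
#' @return a \code{sap_result} list with \code{table}, \code{p_value},
#'   \code{sap_pct}, \code{positive}.
#' @export
sap <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ft <- fisher_exact_2x2(table, alternative)
  p <- ft$p_value
  pct <- (1 - p) * 100
  structure(list(table = as_2x2(table), p_value = p, sap_pct = pct,
                 positive = pct >= 95 - 1e-9, alternative = alternative),
            class = "sap_result")
}

#' @export
print.sap_result <- function(x, ...) {
  cat(sprintf("SAP %.2f%% (%s p = %.4g) -> %s\n", x$sap_pct, x$alternative,
              x$p_value, if (x$positive) "SAP-positive" else "SAP-negative"))
  invisible(x)
}

#' Symptom index (SI)
#'
#' Percent of symptom events that are reflux-associated: an event counts as
#' associated when any reflux-positive window intersects the \code{lag_s}
#' seconds preceding (and including) the event. SI-positive at >= 50%. With
#' zero events the index is not assessable and reported as NA, not 0.
#'
#' @param grid window grid; \code{reflux_vec} its reflux labels.
#' @param reflux_vec logical reflux-positive labels for \code{grid}.
#' @inheritParams label_symptom_windows
#' @param lag_s association lag in seconds.
#' @return list \code{si_pct}, \code{si_positive}, \code{n_events}.
#' @export
symptom_index <- function(grid, reflux_vec, log, symptom, lag_s = 120) {
  ev <- log$events$time_s[log$events$symptom == symptom]
  if (!symptom %in% log$tracked_symptoms)
    stop("symptom '", symptom, "' is not tracked in this log")
  if (length(ev) == 0L)
    return(list(si_pct = NA_real_, si_positive = NA, n_events = 0L))
  assoc <- vapply(ev, function(tt) {
    lo <- window_index(grid, max(0, tt - lag_s))
    hi <- window_index(grid, min(tt, grid$duration_s - 1e-9))
    any(reflux_vec[lo:hi])
  }, logical(1))
  pct <- 100 * mean(assoc)
  list(si_pct = pct, si_positive = pct >= 50, n_events = length(ev))
}

#' Symptom sensitivity index (SSI)
#'
#' Percent of reflux episodes accompanied by at least one event of the
#' symptom within \code{lag_s} seconds after episode onset (i.e. an event in
#' \code{[onset, offset + lag_s)}). SSI-positive at >= 10%. With zero
#' episodes the index is not assessable (NA).
#'
#' @inheritParams label_symptom_windows
#' @param episodes episode data.frame from \code{detect_reflux_episodes}.
#' @param lag_s association lag in seconds.
#' @return list \code{ssi_pct}, \code{ssi_positive}, \code{n_episodes}.
#' @export
symptom_sensitivity_index <- function(log, symptom, episodes, lag_s = 120) {
  if (!symptom %in% log$tracked_symptoms)
    stop("symptom '", symptom, "' is not tracked in this log")
  if (nrow(episodes) == 0L)
    return(list(ssi_pct = NA_real_, ssi_positive = NA, n_episodes = 0L))
  ev <- log$events$time_s[log$events$symptom == symptom]
  hit <- vapply(seq_len(nrow(episodes)), function(i)
    any(ev >= episodes$onset_s[i] & ev < episodes$offset_s[i] + lag_s),
    logical(1))
  pct <- 100 * mean(hit)
  list(ssi_pct = pct, ssi_positive = pct >= 10, n_episodes = nrow(episodes))
}

#' Full symptom-reflux association analysis for one recording
#'
#' Runs the whole SAP chain for every tracked symptom: window partition,
#' reflux and symptom labels, 2x2 table, Fisher exact SAP, plus SI and SSI.
#' A symptom with zero reported events is flagged not assessable (its SAP is
#' NA, never counted as negative). The patient is SAP-positive if at least
#' one assessable symptom is SAP-positive. An "any-symptom" combined SAP
#' (union of the symptom label vectors) is also reported.
#'
#' @param trace a \code{ph_trace}.
#' @param log the matching \code{symptom_log}.
#' @param window_s window length (s).
#' @param alternative sidedness of the exact test.
#' @param lag_s SI/SSI association lag (s).
#' @param merge_gap_s episode merging gap for the SSI episode list.
#' @inheritParams label_reflux_windows
#' @return an \code{association_summary}: \code{per_symptom} data.frame,
#'   \code{any_symptom} SAP result, \code{patient_sap_positive},
#'   \code{n_sap_positive}, \code{n_assessable}.
#' @export
associate <- function(trace, log, window_s = 120,
                      alternative = c("two_sided", "greater", "less"),
                      threshold_ph = 4.0, sustained_s = 5, drop_units = 1.0,
                      drop_span_s = 5, lag_s = 120, merge_gap_s = 0) {
  alternative <- match.arg(alternative)
  grid <- partition_windows(trace, window_s)
  rvec <- label_reflux_windows(trace, grid, threshold_ph, sustained_s,
                               drop_units, drop_span_s)
  episodes <- detect_reflux_episodes(trace, threshold_ph, merge_gap_s)
  rows <- lapply(log$tracked_symptoms, function(sym) {
    svec <- label_symptom_windows(grid, log, sym)
    n_events <- sum(log$events$symptom == sym)
    si <- symptom_index(grid, rvec, log, sym, lag_s)
    ssi <- symptom_sensitivity_index(log, sym, episodes, lag_s)
    if (n_events == 0L) {
      data.frame(symptom = sym, category = symptom_category(sym),
                 n_events = 0L, a = 0L, b = 0L, c = sum(rvec),
                 d = sum(!rvec), p_value = NA_real_, sap_pct = NA_real_,
                 sap_positive = NA, assessable = FALSE,
                 si_pct = NA_real_, si_positive = NA,
                 ssi_pct = ssi$ssi_pct, ssi_positive = ssi$ssi_positive,
                 stringsAsFactors = FALSE)
    } else {
      tab <- build_table(rvec, svec)
      s <- sap(tab, alternative)
      data.frame(symptom = sym, category = symptom_category(sym),
                 n_events = n_events, a = tab[["a"]], b = tab[["b"]],
                 c = tab[["c"]], d = tab[["d"]], p_value = s$p_value,
                 sap_pct = s$sap_pct, sap_positive = s$positive,
                 assessable = TRUE, si_pct = si$si_pct,
                 si_positive = si$si_positive, ssi_pct = ssi$ssi_pct,
                 ssi_positive = ssi$ssi_positive, stringsAsFactors = FALSE)
    }
  })
  per_symptom <- do.call(rbind, rows)
  any_vec <- Reduce(`|`, lapply(log$tracked_symptoms, function(sym)
    label_symptom_windows(grid, log, sym)))
  any_sap <- sap(build_table(rvec, any_vec), alternative)
  n_pos <- sum(per_symptom$sap_positive, na.rm = TRUE)
  structure(list(recording_id = log$recording_id, per_symptom = per_symptom,
                 any_symptom = any_sap,
                 n_assessable = sum(per_symptom$assessable),
                 n_sap_positive = n_pos,
                 patient_sap_positive = n_pos >= 1L,
                 n_windows = grid$n, n_reflux_windows = sum(rvec)),
            class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat(sprintf("<association_summary %s: %d windows, %d reflux-positive>\n",
              x$recording_id, x$n_windows, x$n_reflux_windows))
  print(x$per_symptom[, c("symptom", "n_events", "p_value", "sap_pct",
                          "sap_positive", "si_pct", "ssi_pct")], digits = 4)
  cat(sprintf("patient SAP-%s (%d of %d assessable symptom(s) positive)\n",
              if (x$patient_sap_positive) "positive" else "negative",
              x$n_sap_positive, x$n_assessable))
  invisible(x)
}
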