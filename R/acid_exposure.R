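#' Detect acid reflux episodes on a pH trace
#'
#' A reflux episode is a maximal run of samples with pH below
#' \code{threshold_ph}; each sample carries the half-open interval
#' \code{[t, t + sample_interval_s)}, so a run of k samples covers k
#' intervals. Runs separated by at most \code{merge_gap_s} of pH at or above
#' threshold are merged (default 0: no merging, since clinical systems differ
#' and no merging rule is universal).
#'
#' @param trace a \code{ph_trace}.
#' @param threshold_ph episode threshold, default 4.0.
#' @param merge_gap_s merge runs separated by gaps of at most this many
#'   seconds.
#' @return data.frame with columns \code{onset_s}, \code{offset_s},
#'   \code{duration_s}, \code{nadir_ph}, sorted by onset.
#' @export
detect_reflux_episodes <- function(trace, threshold_ph = 4.0, merge_gap_s = 0) {
  validate_ph_trace(trace)
  t <- trace$time_s; ph <- trace$ph; dt <- trace$sample_interval_s
  below <- ph < threshold_ph
  if (!any(below))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), nadir_ph = numeric(0)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  si <- starts[r$values]; ei <- ends[r$values]
  onset <- t[si]; offset <- t[ei] + dt
  if (merge_gap_s > 0 && length(onset) > 1L) {
    gap <- onset[-1] - offset[-length(offset)]
    grp <- cumsum(c(TRUE, gap > merge_gap_s))
    onset2 <- tapply(onset, grp, min)
    offset2 <- tapply(offset, grp, max)
    onset <- as.numeric(onset2); offset <- as.numeric(offset2)
  }
  nadir <- vapply(seq_along(onset), function(i)
    min(ph[t >= onset[i] & t < offset[i]]), numeric(1))
  data.frame(onset_s = onset, offset_s = offset,
             duration_s = offset - onset, nadir_ph = nadir)
}

#' Six-component acid-exposure profile
#'
#' Computes the six DeMeester components from a trace and its episode list:
#' percent time pH < 4 total / upright / supine, the number of episodes, the
#' number of episodes lasting at least 5 min, and the longest episode in
#' minutes. A stratum with zero duration (e.g. a recording with no supine
#' time) contributes 0 percent with a warning. Meal intervals are included by
#' default; set \code{exclude_meals} to drop meal-period samples from both
#' numerator and denominator.
#'
#' @inheritParams detect_reflux_episodes
#' @param episodes episode data.frame from \code{detect_reflux_episodes};
#'   recomputed if \code{NULL}.
#' @param exclude_meals drop samples inside meal intervals.
#' @return an \code{acid_profile} list with the six components (composite
#'   score and severity are added by \code{score_trace}).
#' @export
acid_exposure_components <- function(trace, episodes = NULL,
                                     threshold_ph = 4.0,
                                     exclude_meals = FALSE) {
  validate_ph_trace(trace)
  if (is.null(episodes))
    episodes <- detect_reflux_episodes(trace, threshold_ph)
  t <- trace$time_s; ph <- trace$ph; dt <- trace$sample_interval_s
  keep <- rep(TRUE, length(t))
  if (exclude_meals && nrow(trace$meals))
    for (i in seq_len(nrow(trace$meals)))
      keep <- keep & !(t >= trace$meals$start_s[i] & t < trace$meals$end_s[i])
  pos <- trace$posture[order(trace$posture$start_s), , drop = FALSE]
  stratum <- pos$posture[findInterval(t, pos$start_s)]
  below <- ph < threshold_ph
  pct <- function(sel, label) {
    denom <- sum(sel & keep) * dt
    if (denom == 0) {
      warning("zero ", label, " time; percent reported as 0")
      return(0)
    }
    100 * sum(sel & keep & below) * dt / denom
  }
  structure(list(
    pct_time_ph_lt4_total = pct(rep(TRUE, length(t)), "total"),
    pct_time_ph_lt4_upright = pct(stratum == "upright", "upright"),
    pct_time_ph_lt4_supine = pct(stratum == "supine", "supine"),
    n_episodes = nrow(episodes),
    n_episodes_ge_5min = sum(episodes$duration_s >= 300),
    longest_episode_min = if (nrow(episodes)) max(episodes$duration_s) / 60 else 0,
    demeester = NA_real_, severity = NA_character_),
    class = "acid_profile")
}

#' DeMeester reference normals
#'
#' Per-component reference means and standard deviations used by the
#' composite score, plus the abnormality threshold (14.7) and the mild/severe
#' strata bounds. The shipped defaults are the classic Johnson-DeMeester
#' normal-subject values for 24-h monitoring; they are external constants,
#' not derived here, and are fully configurable (48-h recordings in
#' particular may warrant recalibrated episode-count normals).
#'
#' @param means,sds named numeric vectors over the six components
#'   (\code{pct_time_ph_lt4_total}, \code{pct_time_ph_lt4_upright},
#'   \code{pct_time_ph_lt4_supine}, \code{n_episodes},
#'   \code{n_episodes_ge_5min}, \code{longest_episode_min}).
#' @param threshold composite abnormality cutoff (strict \code{>}).
#' @param mild_upper upper bound of the mild stratum (inclusive).
#' @param severe_lower lower bound of the severe stratum (strict \code{>}).
#' @return a \code{demeester_normals} list.
#' @export
demeester_normals <- function(
    means = c(pct_time_ph_lt4_total = 1.51, pct_time_ph_lt4_upright = 2.34,
              pct_time_ph_lt4_supine = 0.63, n_episodes = 19.00,
              n_episodes_ge_5min = 0.84, longest_episode_min = 6.74),
    sds = c(pct_time_ph_lt4_total = 1.36, pct_time_ph_lt4_upright = 2.34,
            pct_time_ph_lt4_supine = 1.43, n_episodes = 12.76,
            n_episodes_ge_5min = 1.18, longest_episode_min = 7.85),
    threshold = 14.7, mild_upper = 20, severe_lower = 50) {
  comp <- names(demeester_components())
  stopifnot(setequal(names(means), comp), setequal(names(sds), comp))
  if (any(sds <= 0)) stop("component sds must be > 0")
  structure(list(means = means[comp], sds = sds[comp], threshold = threshold,
                 mild_upper = mild_upper, severe_lower = severe_lower),
            class = "demeester_normals")
}

demeester_components <- function() c(
  pct_time_ph_lt4_total = "% time pH<4, total",
  pct_time_ph_lt4_upright = "% time pH<4, upright",
  pct_time_ph_lt4_supine = "% time pH<4, supine",
  n_episodes = "no. of episodes",
  n_episodes_ge_5min = "no. of episodes >= 5 min",
  longest_episode_min = "longest episode (min)")

#' DeMeester composite score
#'
#' Each component contributes \code{max(0, (value - mean)/sd + 1)}; the
#' composite is the sum over the six components. With every component at its
#' reference mean the score is exactly 6; the per-component clamp keeps
#' unusually low components from offsetting high ones. The score is monotone
#' non-decreasing in every component.
#'
#' @param profile an \code{acid_profile} (or any list carrying the six
#'   component fields).
#' @param normals a \code{demeester_normals}.
#' @return the composite score (scalar).
#' @export
demeester_score <- function(profile, normals = demeester_normals()) {
  stopifnot(inherits(normals, "demeester_normals"))
  comp <- names(demeester_components())
  v <- vapply(comp, function(k) as.numeric(profile[[k]]), numeric(1))
  if (anyNA(v)) stop("profile is missing component(s)")
  sum(pmax(0, (v - normals$means) / normals$sds + 1))
}

#' Severity strata for the composite score
#'
#' \code{normal} for scores at or below the abnormality threshold (14.7;
#' abnormality is strict \code{> 14.7}), \code{mild} on (14.7, 20],
#' \code{moderate} on (20, 50] and \code{severe} strictly above 50.
#'
#' @param score composite score(s), non-negative.
#' @inheritParams demeester_score
#' @return character vector over \code{normal/mild/moderate/severe}.
#' @export
classify_severity <- function(score, normals = demeester_normals()) {
  stopifnot(all(score >= 0))
  ifelse(score <= normals$threshold, "normal",
    ifelse(score <= normals$mild_upper, "mild",
      ifelse(score <= normals$severe_lower, "moderate", "severe")))
}

#' One-call acid-exposure scoring of a trace
#'
#' Runs episode detection, the six components, the composite score and the
#' severity class.
#'
#' @inheritParams acid_exposure_components
#' @inheritParams detect_reflux_episodes
#' @param normals a \code{demeester_normals}.
#' @return an \code{acid_profile} with \code{demeester} and \code{severity}
#'   filled in, plus the episode list as attribute \code{"episodes"}.
#' @export
score_trace <- function(trace, normals = demeester_normals(),
                        threshold_ph = 4.0, merge_gap_s = 0,
                        exclude_meals = FALSE) {
  eps <- detect_reflux_episodes(trace, threshold_ph, merge_gap_s)
  prof <- acid_exposure_components(trace, eps, threshold_ph, exclude_meals)
  prof$demeester <- demeester_score(prof, normals)
  prof$severity <- classify_severity(prof$demeester, normals)
  attr(prof, "episodes") <- eps
  prof
}

#' @export
print.acid_profile <- function(x, ...) {
  lbl <- demeester_components()
  for (k in names(lbl))
    cat(sprintf("  %-26s %.3g\n", lbl[k], x[[k]]))
  if (!is.na(x$demeester))
    cat(sprintf("  DeMeester score: %.2f (%s)\n", x$demeester, x$severity))
  invisible(x)
}
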