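#' Configuration for the pH-trace simulator
#'
#' The defaults emulate a 48-h Bravo-style recording sampled every 6 s:
#' baseline esophageal pH fluctuating around 6.2 (sd 0.25, so the baseline
#' essentially never dips below 4), acid reflux episodes arriving as a
#' posture-dependent Poisson process (3/h upright, 1/h supine), lognormal
#' episode durations (median 90 s), episode nadir pH uniform on [1.0, 3.5],
#' and a 30-s linear recovery from pH 4 back to baseline after each episode.
#' The recording is assumed to start at 08:00 with supine (recumbent) time
#' 23:00-07:00 each night.
#'
#' @param duration_s recording length (s); default 172800 (48 h).
#' @param sample_interval_s sampling interval (s); default 6.
#' @param baseline_ph_mean,baseline_ph_sd baseline pH noise.
#' @param episode_rate_upright_per_h,episode_rate_supine_per_h episode rates.
#' @param episode_duration_median_s,episode_duration_sigma lognormal episode
#'   duration (median in seconds, log-sd).
#' @param nadir_ph_low,nadir_ph_high uniform nadir range; high must be < 4.
#' @param recovery_s post-episode linear recovery time (s).
#' @param recording_start_clock,supine_start_clock,supine_end_clock "HH:MM"
#'   clock times defining the nightly supine block.
#' @param meals optional data.frame(start_s, end_s) carried as annotations.
#' @param seed integer RNG seed (mandatory: generators are pure functions of
#'   their config).
#' @return a \code{trace_sim_config} list.
#' @export
trace_sim_config <- function(duration_s = 172800, sample_interval_s = 6,
                             baseline_ph_mean = 6.2, baseline_ph_sd = 0.25,
                             episode_rate_upright_per_h = 3,
                             episode_rate_supine_per_h = 1,
                             episode_duration_median_s = 90,
                             episode_duration_sigma = 0.6,
                             nadir_ph_low = 1.0, nadir_ph_high = 3.5,
                             recovery_s = 30,
                             recording_start_clock = "08:00",
                             supine_start_clock = "23:00",
                             supine_end_clock = "07:00",
                             meals = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (duration_s < sample_interval_s) stop("duration shorter than one sample")
  if (nadir_ph_high >= 4) stop("nadir_ph_high must be < 4")
  if (nadir_ph_low > nadir_ph_high) stop("nadir range inverted")
  if (episode_rate_upright_per_h < 0 || episode_rate_supine_per_h < 0)
    stop("episode rates must be >= 0")
  structure(cfg, class = "trace_sim_config")
}

clock_to_s <- function(hhmm) {
  p <- as.numeric(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  if (length(p) != 2 || anyNA(p)) stop("bad clock time: ", hhmm)
  p[1] * 3600 + p[2] * 60
}

# posture intervals for the recording, derived from the nightly schedule
posture_schedule <- function(cfg) {
  start <- clock_to_s(cfg$recording_start_clock)
  s0 <- clock_to_s(cfg$supine_start_clock)
  s1 <- clock_to_s(cfg$supine_end_clock)
  if (s1 <= s0) s1 <- s1 + 86400 else if (s1 - s0 >= 86400)
    stop("inconsistent supine schedule")
  days <- ceiling(cfg$duration_s / 86400) + 1
  sup <- do.call(rbind, lapply(-1:days, function(d) {
    lo <- d * 86400 + s0 - start; hi <- d * 86400 + s1 - start
    c(max(0, lo), min(cfg$duration_s, hi))
  }))
  sup <- sup[sup[, 2] > sup[, 1], , drop = FALSE]
  # complement -> upright
  pts <- sort(unique(c(0, cfg$duration_s, sup)))
  out <- data.frame(start_s = pts[-length(pts)], end_s = pts[-1])
  insup <- vapply(seq_len(nrow(out)), function(i)
    any(out$start_s[i] >= sup[, 1] & out$end_s[i] <= sup[, 2]), logical(1))
  out$posture <- ifelse(insup, "supine", "upright")
  out
}

#' Simulate a pH recording with planted reflux episodes
#'
#' Baseline Gaussian pH noise plus planted episodes: the pH drops to the
#' episode nadir for the episode duration, then recovers linearly from just
#' above 4 to baseline over \code{recovery_s}. Episode onsets and offsets are
#' snapped to the sample grid and the sub-4 extent of each episode is exactly
#' its planted \code{[onset_s, offset_s)} interval, so planted truth can be
#' compared bit-for-bit against detection. Overlapping draws are thinned so
#' consecutive episodes are separated by at least \code{2 * recovery_s}.
#'
#' @param config a \code{trace_sim_config}.
#' @return list with elements \code{trace} (a \code{ph_trace}) and
#'   \code{episodes} (the planted truth: onset_s, offset_s, duration_s,
#'   nadir_ph).
#' @export
simulate_trace <- function(config = trace_sim_config()) {
  stopifnot(inherits(config, "trace_sim_config"))
  cfg <- config
  dt <- cfg$sample_interval_s
  n <- floor(cfg$duration_s / dt)
  duration <- n * dt
  posture <- posture_schedule(cfg)
  posture <- posture[posture$start_s < duration, , drop = FALSE]
  posture$end_s[nrow(posture)] <- duration
  with_seed(cfg$seed, {
    t <- (seq_len(n) - 1) * dt
    ph <- rnorm(n, cfg$baseline_ph_mean, cfg$baseline_ph_sd)
    # posture-dependent Poisson episode onsets
    onsets <- numeric(0); durs <- numeric(0)
    for (i in seq_len(nrow(posture))) {
      len <- posture$end_s[i] - posture$start_s[i]
      rate <- if (posture$posture[i] == "supine")
        cfg$episode_rate_supine_per_h else cfg$episode_rate_upright_per_h
      k <- rpois(1, rate * len / 3600)
      if (k > 0) {
        o <- sort(runif(k, posture$start_s[i], posture$end_s[i]))
        d <- rlnorm(k, log(cfg$episode_duration_median_s),
                    cfg$episode_duration_sigma)
        onsets <- c(onsets, o); durs <- c(durs, d)
      }
    }
    ord <- order(onsets); onsets <- onsets[ord]; durs <- durs[ord]
    # snap to grid; thin so episodes stay well separated
    onsets <- floor(onsets / dt) * dt
    durs <- pmax(dt, round(durs / dt) * dt)
    keep <- logical(length(onsets))
    last_end <- -Inf
    for (j in seq_along(onsets)) {
      if (onsets[j] >= last_end + 2 * cfg$recovery_s &&
          onsets[j] + durs[j] + cfg$recovery_s < duration) {
        keep[j] <- TRUE
        last_end <- onsets[j] + durs[j]
      }
    }
    onsets <- onsets[keep]; durs <- durs[keep]
    nadir <- if (length(onsets))
      runif(length(onsets), cfg$nadir_ph_low, cfg$nadir_ph_high) else numeric(0)
    for (j in seq_along(onsets)) {
      # onsets/durations are grid-aligned, so index ranges are exact
      i0 <- as.integer(onsets[j] / dt)
      idx <- (i0 + 1L):min(n, i0 + as.integer(durs[j] / dt))
      ph[idx] <- pmin(3.9, pmax(0.3,
        nadir[j] + rnorm(length(idx), 0, 0.05)))
      off <- onsets[j] + durs[j]
      r0 <- as.integer(off / dt)
      ridx <- (r0 + 1L):min(n, r0 + as.integer(ceiling(cfg$recovery_s / dt)))
      ridx <- ridx[t[ridx] < off + cfg$recovery_s]
      frac <- (t[ridx] - off) / cfg$recovery_s
      ph[ridx] <- pmax(4.01,
        4.05 + (cfg$baseline_ph_mean - 4.05) * frac +
          rnorm(length(ridx), 0, 0.05))
    }
    ph <- pmin(9, pmax(0, ph))
    trace <- ph_trace(sprintf("sim-%d", cfg$seed), t, ph, dt,
                      posture = posture, meals = cfg$meals,
                      duration_s = duration)
    list(trace = trace,
         episodes = data.frame(onset_s = onsets, offset_s = onsets + durs,
                               duration_s = durs, nadir_ph = nadir))
  })
}

#' Configuration for the symptom-event simulator
#'
#' Symptom-reflux coupling is defined at window level, matching the SAP
#' estimand: each event is placed, with probability \code{coupling}, uniformly
#' inside a randomly chosen reflux-positive 2-min window; otherwise uniformly
#' over the whole recording. \code{coupling = 0} therefore makes events
#' independent of the reflux process, and \code{coupling = 1} puts every
#' event inside a reflux-positive window (when one exists).
#'
#' @param symptoms named integer vector: event count per tracked symptom
#'   (1-3 names).
#' @param coupling probability in [0, 1] that an event is reflux-coupled.
#' @param window_s window length used to define coupling (s).
#' @param seed integer RNG seed.
#' @return a \code{symptom_sim_config} list.
#' @export
symptom_sim_config <- function(symptoms = c(heartburn = 20), coupling = 0.5,
                               window_s = 120, seed = 1) {
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  if (length(symptoms) < 1L || length(symptoms) > 3L || is.null(names(symptoms)))
    stop("symptoms must be a named vector of 1-3 event counts")
  if (any(symptoms < 0)) stop("event counts must be >= 0")
  structure(list(symptoms = symptoms, coupling = coupling,
                 window_s = window_s, seed = seed),
            class = "symptom_sim_config")
}

#' Simulate a symptom event log coupled to a trace
#'
#' @param trace a \code{ph_trace} (typically from \code{simulate_trace}).
#' @param config a \code{symptom_sim_config}.
#' @return a \code{symptom_log}; event counts honor the config exactly.
#' @export
simulate_symptoms <- function(trace, config = symptom_sim_config()) {
  stopifnot(inherits(config, "symptom_sim_config"))
  grid <- partition_windows(trace, config$window_s)
  rvec <- label_reflux_windows(trace, grid)
  posw <- which(rvec)
  with_seed(config$seed, {
    rows <- lapply(names(config$symptoms), function(sym) {
      k <- config$symptoms[[sym]]
      if (k == 0) return(NULL)
      coupled <- rbinom(k, 1, config$coupling) == 1 & length(posw) > 0
      tt <- numeric(k)
      nc <- sum(coupled)
      if (nc > 0) {
        w <- posw[sample.int(length(posw), nc, replace = TRUE)]
        tt[coupled] <- grid$starts[w] +
          runif(nc) * (grid$ends[w] - grid$starts[w])
      }
      tt[!coupled] <- runif(k - nc, 0, grid$duration_s)
      data.frame(time_s = tt, symptom = sym, stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, rows)
    if (is.null(events))
      events <- data.frame(time_s = numeric(0), symptom = character(0))
    symptom_log(trace$recording_id, names(config$symptoms), events,
                duration_s = trace$duration_s)
  })
}

#' Configuration for the surgical-cohort simulator
#'
#' Defaults reproduce the marginals of a ~600-patient antireflux-surgery
#' cohort with abnormal acid exposure: n = 597, 71.4% female, median (IQR)
#' age 59 (49-67), BMI 29.1 (26-33), DeMeester 44.1 (29-62) with 7.4% mild
#' ((14.7, 20]) and 40.7% severe (> 50) strata, preoperative GERD-HRQL 36
#' (21-51), 89.1% Nissen, 72.0% SAP-positive with the 1/2/3-positive-symptom
#' split 221:164:45, base favorable-outcome rate 0.82 with a configurable
#' SAP effect on the log-odds scale (default 0: no effect), satisfaction
#' 87.4% and PPI freedom 91.7% generated so their conjunction is exactly the
#' favorable flag, mean (sd) follow-up 10.5 (8) months, and per-field
#' missingness chosen to reproduce the differing outcome denominators of a
#' real registry (satisfaction ~32%, PPI status ~1.3%, postoperative HRQL
#' ~48% missing).
#'
#' @param n cohort size.
#' @param age_median,age_iqr,bmi_median,bmi_iqr,demeester_median,demeester_iqr
#'   location/spread targets (IQR as length-2 vectors).
#' @param pct_female,pct_nissen,pct_mild,pct_severe,pct_sap_positive percent
#'   marginals (0-100 scale).
#' @param preop_hrql_median,preop_hrql_iqr preoperative HRQL target.
#' @param sap_count_split relative sizes of the 1/2/3 SAP-positive-symptom
#'   groups.
#' @param base_favorable_rate favorable-outcome probability for SAP-negative
#'   patients.
#' @param sap_effect_log_odds added to the favorable log-odds for
#'   SAP-positive patients (default 0, the null).
#' @param satisfaction_rate,ppi_free_rate target marginal outcome rates;
#'   must be at least the favorable rate and jointly feasible.
#' @param postop_hrql_mean,postop_hrql_sd postoperative HRQL distribution.
#' @param followup_mean,followup_sd follow-up months.
#' @param miss_satisfied,miss_ppi_free,miss_postop_hrql per-field
#'   missingness probabilities.
#' @param seed integer RNG seed.
#' @return a \code{cohort_sim_config} list.
#' @export
cohort_sim_config <- function(n = 597,
                              age_median = 59, age_iqr = c(49, 67),
                              pct_female = 71.4,
                              bmi_median = 29.1, bmi_iqr = c(26, 33),
                              demeester_median = 44.1,
                              demeester_iqr = c(29, 62),
                              pct_mild = 7.4, pct_severe = 40.7,
                              preop_hrql_median = 36,
                              preop_hrql_iqr = c(21, 51),
                              pct_nissen = 89.1,
                              base_favorable_rate = 0.82,
                              sap_effect_log_odds = 0,
                              pct_sap_positive = 72.0,
                              sap_count_split = c(221, 164, 45),
                              satisfaction_rate = 0.874,
                              ppi_free_rate = 0.917,
                              postop_hrql_mean = 10.6, postop_hrql_sd = 13.5,
                              followup_mean = 10.5, followup_sd = 8,
                              miss_satisfied = 0.32, miss_ppi_free = 0.013,
                              miss_postop_hrql = 0.48,
                              seed = 1) {
  cfg <- as.list(environment())
  if (n < 1) stop("n must be >= 1")
  pr <- c(pct_female, pct_nissen, pct_mild, pct_severe, pct_sap_positive) / 100
  if (any(pr < 0 | pr > 1)) stop("percent marginals must be in [0, 100]")
  if (pct_mild + pct_severe > 100)
    stop("infeasible marginal combination: pct_mild + pct_severe > 100")
  if (base_favorable_rate <= 0 || base_favorable_rate >= 1)
    stop("base_favorable_rate must be in (0, 1)")
  ps <- (satisfaction_rate - base_favorable_rate) / (1 - base_favorable_rate)
  pp <- (ppi_free_rate - base_favorable_rate) / (1 - base_favorable_rate)
  if (ps < 0 || pp < 0 || ps + pp > 1)
    stop("infeasible marginal combination: satisfaction/PPI rates vs favorable rate")
  if (length(sap_count_split) != 3 || any(sap_count_split < 0))
    stop("sap_count_split must be three non-negative weights")
  structure(cfg, class = "cohort_sim_config")
}

# IQR-matched sd for a normal (or log-normal on the log scale)
iqr_sd <- function(iqr) (iqr[2] - iqr[1]) / (2 * qnorm(0.75))

# symptom tracking weights loosely matching real-world prevalence
.symptom_weights <- c(heartburn = 0.28, regurgitation = 0.17, cough = 0.16,
                      dysphagia = 0.09, chest_pain = 0.08, nausea = 0.07,
                      throat_clearing = 0.07, abdominal_pain = 0.06,
                      globus = 0.02)

#' Simulate a surgical cohort table
#'
#' Draws demographics by quantile matching (normal for age/HRQL, lognormal
#' for BMI; DeMeester from a lognormal truncated within severity strata drawn
#' at the configured mild/moderate/severe mix), assigns per-patient SAP
#' status and tracked symptoms, and generates outcomes from a Bernoulli logit
#' with an SAP main effect only. Satisfaction and PPI freedom are generated
#' so that their conjunction equals the favorable flag while hitting the
#' configured marginal rates; missingness is applied last, independently per
#' outcome field.
#'
#' @param config a \code{cohort_sim_config}.
#' @return a cohort data.frame with the canonical columns (see
#'   \code{\link{read_cohort}}).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  n <- cfg$n
  with_seed(cfg$seed, {
    age <- round(pmin(95, pmax(18,
      rnorm(n, cfg$age_median, iqr_sd(cfg$age_iqr)))))
    sex <- ifelse(runif(n) < cfg$pct_female / 100, "female", "male")
    bmi <- round(rlnorm(n, log(cfg$bmi_median), iqr_sd(log(cfg$bmi_iqr))), 1)
    # DeMeester: severity stratum, then truncated lognormal within it
    sev <- sample(c("mild", "moderate", "severe"), n, replace = TRUE,
                  prob = c(cfg$pct_mild,
                           100 - cfg$pct_mild - cfg$pct_severe,
                           cfg$pct_severe) / 100)
    ml <- log(cfg$demeester_median); sl <- iqr_sd(log(cfg$demeester_iqr))
    lo <- c(mild = 14.7, moderate = 20, severe = 50)[sev]
    hi <- c(mild = 20, moderate = 50, severe = 2000)[sev]
    u <- runif(n, plnorm(lo, ml, sl), plnorm(hi, ml, sl))
    demeester <- round(qlnorm(u, ml, sl), 1)
    # floor of 1: these are symptomatic surgical candidates, never score 0
    preop <- round(pmin(80, pmax(1,
      rnorm(n, cfg$preop_hrql_median, iqr_sd(cfg$preop_hrql_iqr)))))
    postop <- round(pmin(80, pmax(0,
      rnorm(n, cfg$postop_hrql_mean, cfg$postop_hrql_sd))))
    fundo <- ifelse(runif(n) < cfg$pct_nissen / 100, "nissen", "partial")
    followup <- round(pmin(36, pmax(1,
      rnorm(n, cfg$followup_mean, cfg$followup_sd))), 1)
    # SAP status and tracked symptoms
    sap_pos <- runif(n) < cfg$pct_sap_positive / 100
    counts <- integer(n)
    counts[sap_pos] <- sample(1:3, sum(sap_pos), replace = TRUE,
                              prob = cfg$sap_count_split)
    n_tracked <- pmax(counts,
                      sample(1:3, n, replace = TRUE, prob = c(0.15, 0.35, 0.5)))
    per_symptom <- vapply(seq_len(n), function(i) {
      syms <- sample(names(.symptom_weights), n_tracked[i],
                     prob = .symptom_weights)
      flags <- integer(n_tracked[i])
      if (counts[i] > 0)
        flags[sample.int(n_tracked[i], counts[i])] <- 1L
      format_per_symptom_sap(syms, flags)
    }, character(1))
    # outcomes: single Bernoulli logit with an SAP main effect
    pf <- plogis(qlogis(cfg$base_favorable_rate) +
                   cfg$sap_effect_log_odds * sap_pos)
    favorable <- runif(n) < pf
    ps <- (cfg$satisfaction_rate - cfg$base_favorable_rate) /
      (1 - cfg$base_favorable_rate)
    pp <- (cfg$ppi_free_rate - cfg$base_favorable_rate) /
      (1 - cfg$base_favorable_rate)
    cat3 <- sample(c("sat_only", "ppi_only", "neither"), n, replace = TRUE,
                   prob = c(ps, pp, 1 - ps - pp))
    satisfied <- favorable | (cat3 == "sat_only")
    ppi_free <- favorable | (cat3 == "ppi_only")
    satisfied[runif(n) < cfg$miss_satisfied] <- NA
    ppi_free[runif(n) < cfg$miss_ppi_free] <- NA
    postop[runif(n) < cfg$miss_postop_hrql] <- NA
    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = age, sex = sex, bmi = bmi,
      preop_hrql = preop, postop_hrql = postop,
      satisfied = satisfied, ppi_free = ppi_free,
      fundoplication = fundo, followup_months = followup,
      demeester = demeester, sap_positive_count = counts,
      per_symptom_sap = per_symptom,
      stringsAsFactors = FALSE)
    validate_cohort(out)
    out
  })
}
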