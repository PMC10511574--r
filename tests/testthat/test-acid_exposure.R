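test_that("episode detection finds planted runs and honors merge_gap_s", {
  # flat trace far above threshold: nothing to find
  expect_equal(nrow(detect_reflux_episodes(make_trace(rep(6.8, 100)))), 0)
  # 10 consecutive sub-4 samples at 6 s -> one 60-s episode
  ph <- rep(6.8, 100); ph[41:50] <- 3.0
  eps <- detect_reflux_episodes(make_trace(ph))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$duration_s, 60)
  expect_equal(eps$onset_s, 40 * 6)
  expect_equal(eps$nadir_ph, 3.0)
  # two runs 18 s apart: split at merge_gap_s = 0, merged at 30
  ph2 <- rep(6.8, 100); ph2[11:15] <- 3.2; ph2[19:24] <- 3.5
  expect_equal(nrow(detect_reflux_episodes(make_trace(ph2))), 2)
  merged <- detect_reflux_episodes(make_trace(ph2), merge_gap_s = 30)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$nadir_ph, 3.2)
})

test_that("degenerate traces are rejected", {
  tr <- make_trace(rep(6.8, 100))
  tr$ph <- numeric(0); tr$time_s <- numeric(0)
  expect_error(detect_reflux_episodes(tr), "empty trace")
})

test_that("acid exposure components match arithmetic on planted truth", {
  # all-neutral trace: every component zero (supine absent -> warned zero)
  flat <- make_trace(rep(7, 200))
  expect_warning(prof <- acid_exposure_components(flat), "supine")
  expect_equal(prof$pct_time_ph_lt4_total, 0)
  expect_equal(prof$n_episodes, 0)
  expect_equal(prof$longest_episode_min, 0)

  # one 8-min episode entirely supine within a 48-h recording
  n <- 28800; ph <- rep(6.5, n)
  supine <- data.frame(start_s = c(54000, 140400), end_s = c(82800, 169200))
  i0 <- 54000 / 6 + 100
  ph[(i0 + 1):(i0 + 80)] <- 2.5  # 80 samples * 6 s = 480 s
  posture <- data.frame(
    start_s = c(0, 54000, 82800, 140400, 169200),
    end_s = c(54000, 82800, 140400, 169200, 172800),
    posture = c("upright", "supine", "upright", "supine", "upright"))
  tr <- make_trace(ph, posture = posture)
  prof <- acid_exposure_components(tr)
  expect_equal(prof$n_episodes, 1)
  expect_equal(prof$n_episodes_ge_5min, 1)
  expect_equal(prof$longest_episode_min, 8)
  expect_equal(prof$pct_time_ph_lt4_total, 100 * 480 / 172800)
  expect_equal(prof$pct_time_ph_lt4_upright, 0)
  expect_equal(prof$pct_time_ph_lt4_supine, 100 * 480 / 57600)
})

test_that("stratum percentages satisfy the time decomposition", {
  sim <- simulate_trace(trace_sim_config(seed = 31))
  prof <- acid_exposure_components(sim$trace)
  pos <- sim$trace$posture
  up <- sum(pos$end_s[pos$posture == "upright"] - pos$start_s[pos$posture == "upright"])
  sup <- sum(pos$end_s[pos$posture == "supine"] - pos$start_s[pos$posture == "supine"])
  expect_equal(prof$pct_time_ph_lt4_total * (up + sup),
               prof$pct_time_ph_lt4_upright * up +
                 prof$pct_time_ph_lt4_supine * sup,
               tolerance = 1e-9)
})

test_that("episode count and sub-4 time are invariant to finer resampling", {
  sim <- simulate_trace(trace_sim_config(duration_s = 14400, seed = 32))
  tr <- sim$trace
  t2 <- seq(0, tr$duration_s - 3, by = 3)
  ph2 <- tr$ph[pmin(length(tr$ph), floor(t2 / 6) + 1)]
  tr2 <- ph_trace(tr$recording_id, t2, ph2, 3, posture = tr$posture,
                  duration_s = tr$duration_s)
  e1 <- detect_reflux_episodes(tr)
  e2 <- detect_reflux_episodes(tr2)
  expect_equal(nrow(e2), nrow(e1))
  expect_equal(sum(e2$duration_s), sum(e1$duration_s))
})

test_that("DeMeester score follows the clamped z + 1 composite", {
  nm <- demeester_normals()
  prof <- as.list(nm$means)
  expect_equal(demeester_score(prof, nm), 6)  # every term exactly 1
  # with mean >= sd for every component, an all-zero profile clamps to 0
  nm2 <- demeester_normals(means = setNames(rep(2, 6), names(nm$means)),
                           sds = setNames(rep(1, 6), names(nm$sds)))
  zero <- as.list(setNames(rep(0, 6), names(nm$means)))
  expect_equal(demeester_score(zero, nm2), 0)
  # monotone non-decreasing in each component
  base <- as.list(nm$means)
  s0 <- demeester_score(base, nm)
  for (k in names(nm$means)) {
    up <- base; up[[k]] <- up[[k]] + 1
    expect_gte(demeester_score(up, nm), s0)
  }
})

test_that("a heavily loaded simulated trace scores severe, stably by seed", {
  heavy <- function(seed) {
    cfg <- trace_sim_config(episode_rate_upright_per_h = 8,
                            episode_rate_supine_per_h = 6,
                            episode_duration_median_s = 300, seed = seed)
    score_trace(simulate_trace(cfg)$trace)
  }
  for (s in c(101, 102)) {
    prof <- heavy(s)
    expect_gt(prof$demeester, 50)
    expect_equal(prof$severity, "severe")
  }
})

test_that("severity strata reproduce the quoted boundaries", {
  expect_equal(classify_severity(14.7), "normal")
  expect_equal(classify_severity(14.71), "mild")
  expect_equal(classify_severity(17.0), "mild")
  expect_equal(classify_severity(20.0), "mild")
  expect_equal(classify_severity(20.01), "moderate")
  expect_equal(classify_severity(44.1), "moderate")
  expect_equal(classify_severity(50.0), "moderate")
  expect_equal(classify_severity(50.01), "severe")
})

test_that("meal exclusion removes meal time from numerator and denominator", {
  ph <- rep(6.5, 600); ph[101:110] <- 3.0  # sub-4 run at 600-660 s
  meals <- data.frame(start_s = 550, end_s = 700)
  tr <- make_trace(ph, meals = meals)
  with_meals <- suppressWarnings(acid_exposure_components(tr))
  no_meals <- suppressWarnings(acid_exposure_components(tr, exclude_meals = TRUE))
  expect_gt(with_meals$pct_time_ph_lt4_total, 0)
  expect_equal(no_meals$pct_time_ph_lt4_total, 0)  # the run sits in the meal
})
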