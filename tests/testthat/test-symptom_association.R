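test_that("window partition tiles the recording with a ceil rule", {
  g <- partition_windows(172800)
  expect_equal(g$n, 1440)
  expect_equal(g$ends - g$starts, rep(120, 1440))
  g2 <- partition_windows(172830)
  expect_equal(g2$n, 1441)
  expect_equal(g2$ends[1441] - g2$starts[1441], 30)
  expect_equal(partition_windows(120)$n, 1)
  expect_error(partition_windows(119), "shorter than one window")
})

test_that("reflux window labelling implements both criteria", {
  g <- partition_windows(240)
  # constant neutral pH: negative
  expect_false(any(label_reflux_windows(make_trace(rep(6.8, 40)), g)))
  # two consecutive sub-4 samples cover 12 s >= 5 s: positive via A
  ph <- rep(6.8, 40); ph[5:6] <- 3.8
  expect_equal(label_reflux_windows(make_trace(ph), g), c(TRUE, FALSE))
  # single 6.5 -> 5.2 step across a 6-s gap: B needs span >= 6
  ph2 <- rep(6.5, 40); ph2[25:40] <- 5.2
  tr2 <- make_trace(ph2)
  expect_false(any(label_reflux_windows(tr2, g)))
  expect_equal(label_reflux_windows(tr2, g, drop_span_s = 6), c(FALSE, TRUE))
})

test_that("reflux labels agree with a brute-force window scan", {
  set.seed(71)
  for (rep in 1:10) {
    # 20 windows of irregular content; 1-s sampling exercises criterion B
    dt <- sample(c(2, 6), 1)
    n <- 2400 / dt
    ph <- 6 + cumsum(rnorm(n, 0, 0.45))
    ph <- pmin(8.5, pmax(0.5, ph))
    tr <- make_trace(ph, dt = dt)
    g <- partition_windows(tr)
    expect_equal(label_reflux_windows(tr, g),
                 oracle_reflux_labels(tr, g))
  }
})

test_that("symptom window labelling uses half-open windows without multiplicity", {
  g <- partition_windows(600)
  log <- symptom_log("r", c("heartburn", "cough"),
                     data.frame(time_s = c(120, 130, 100, 119.9),
                                symptom = rep("heartburn", 4)))
  v <- label_symptom_windows(g, log, "heartburn")
  expect_equal(v, c(TRUE, TRUE, FALSE, FALSE, FALSE))  # 120 -> later window
  expect_false(any(label_symptom_windows(g, log, "cough")))  # zero events
  expect_error(label_symptom_windows(g, log, "nausea"), "not tracked")
})

test_that("2x2 table construction matches a counting oracle", {
  expect_equal(build_table(c(TRUE, TRUE, FALSE, FALSE),
                           c(TRUE, FALSE, TRUE, FALSE)),
               c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(build_table(rep(TRUE, 4), rep(FALSE, 4))[c("a", "b")],
               c(a = 0, b = 0))
  expect_error(build_table(c(TRUE, FALSE), TRUE), "equal length")
  set.seed(72)
  for (i in 1:20) {
    r <- runif(50) < 0.3; s <- runif(50) < 0.2
    expect_equal(build_table(r, s), oracle_count_table(r, s))
  }
})

test_that("SAP values match full hypergeometric enumeration", {
  s1 <- sap(c(6, 0, 4, 10))
  expect_equal(s1$p_value, 420 / 38760, tolerance = 1e-12)
  expect_equal(s1$sap_pct, (1 - 420 / 38760) * 100, tolerance = 1e-9)
  expect_true(s1$positive)
  s2 <- sap(c(4, 0, 6, 10))
  expect_equal(s2$p_value, 420 / 4845, tolerance = 1e-12)
  expect_false(s2$positive)
  s3 <- sap(c(0, 0, 7, 13))  # empty symptom margin
  expect_equal(s3$p_value, 1)
  expect_equal(s3$sap_pct, 0)
  expect_false(s3$positive)
})

test_that("sap_pct falls as the table rotates away from positive association", {
  # hold margins fixed: move one count from a to b and one from d to c
  tab <- c(a = 8, b = 2, c = 4, d = 16)
  prev <- sap(tab)$sap_pct
  for (k in 1:2) {
    tab <- tab + c(-1, 1, 1, -1)
    cur <- sap(tab)$sap_pct
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("SI and SSI handle full, null and empty association", {
  ph <- rep(6.8, 200)
  ph[c(21:30, 101:110)] <- 3.0  # reflux in windows 2 and 6 (120 s each)
  tr <- make_trace(ph)
  g <- partition_windows(tr)
  rvec <- label_reflux_windows(tr, g)
  eps <- detect_reflux_episodes(tr)
  # all events inside reflux-positive windows
  log1 <- symptom_log("r", "heartburn",
                      data.frame(time_s = c(130, 610), symptom = "heartburn"))
  si1 <- symptom_index(g, rvec, log1, "heartburn")
  expect_equal(si1$si_pct, 100)
  expect_true(si1$si_positive)
  ssi1 <- symptom_sensitivity_index(log1, "heartburn", eps)
  expect_equal(ssi1$ssi_pct, 100)
  # 0 of 4 events reflux-associated (far from both episodes, beyond the lag)
  log2 <- symptom_log("r", "heartburn",
                      data.frame(time_s = c(400, 500, 900, 1000),
                                 symptom = "heartburn"))
  si2 <- symptom_index(g, rvec, log2, "heartburn")
  expect_equal(si2$si_pct, 0)
  expect_false(si2$si_positive)
  ssi2 <- symptom_sensitivity_index(log2, "heartburn", eps)
  expect_equal(ssi2$ssi_pct, 0)
  expect_false(ssi2$ssi_positive)
  # zero events / zero episodes: not assessable, never 0
  log3 <- symptom_log("r", c("heartburn", "cough"),
                      data.frame(time_s = 130, symptom = "heartburn"))
  expect_true(is.na(symptom_index(g, rvec, log3, "cough")$si_pct))
  none <- detect_reflux_episodes(make_trace(rep(7, 200)))
  expect_true(is.na(symptom_sensitivity_index(log1, "heartburn", none)$ssi_pct))
})

test_that("associate aggregates per-symptom results and composes the chain", {
  sim <- simulate_trace(trace_sim_config(duration_s = 14400, seed = 41))
  # heartburn strongly coupled; cough has a couple of events; nausea none
  log <- simulate_symptoms(sim$trace,
                           symptom_sim_config(c(heartburn = 25, cough = 2),
                                              coupling = 1, seed = 42))
  log <- symptom_log(log$recording_id,
                     c(log$tracked_symptoms, "nausea"), log$events,
                     duration_s = sim$trace$duration_s)
  res <- associate(sim$trace, log)
  expect_s3_class(res, "association_summary")
  expect_equal(nrow(res$per_symptom), 3)
  expect_false(res$per_symptom$assessable[res$per_symptom$symptom == "nausea"])
  expect_true(is.na(res$per_symptom$sap_pct[res$per_symptom$symptom == "nausea"]))
  # compositionality: the summary equals the hand-run chain
  g <- partition_windows(sim$trace)
  rvec <- label_reflux_windows(sim$trace, g)
  svec <- label_symptom_windows(g, log, "heartburn")
  manual <- sap(build_table(rvec, svec))
  row <- res$per_symptom[res$per_symptom$symptom == "heartburn", ]
  expect_equal(row$p_value, manual$p_value)
  expect_equal(row$sap_positive, manual$positive)
  expect_equal(res$n_sap_positive,
               sum(res$per_symptom$sap_positive, na.rm = TRUE))
  expect_equal(res$patient_sap_positive, res$n_sap_positive >= 1)
})

test_that("a patient with one positive of three tracked symptoms is SAP-positive", {
  ph <- rep(6.8, 2880)  # 4.8 h
  set.seed(43)
  ridx <- sort(sample(0:143, 30))  # 30 reflux-positive windows
  for (w in ridx) ph[(w * 20 + 1):(w * 20 + 3)] <- 3.2
  tr <- make_trace(ph)
  g <- partition_windows(tr)
  rvec <- label_reflux_windows(tr, g)
  hb <- g$starts[which(rvec)[1:12]] + 5       # all inside reflux windows
  cg <- g$starts[which(!rvec)[1:4]] + 5       # all outside
  log <- symptom_log("r", c("heartburn", "cough", "nausea"),
                     data.frame(time_s = c(hb, cg, 50),
                                symptom = c(rep("heartburn", 12),
                                            rep("cough", 4), "nausea")))
  res <- associate(tr, log)
  ps <- res$per_symptom
  expect_true(ps$sap_positive[ps$symptom == "heartburn"])
  expect_false(ps$sap_positive[ps$symptom == "cough"])
  expect_equal(res$n_sap_positive, sum(ps$sap_positive, na.rm = TRUE))
  expect_true(res$patient_sap_positive)
})
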