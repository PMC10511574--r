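test_that("outcome flags implement the favorable and HRQL definitions", {
  coh <- data.frame(
    patient_id = sprintf("P%d", 1:5),
    preop_hrql = c(36.2, 40, 30, 0, 20),
    postop_hrql = c(10.6, 20, 16, 5, NA),
    satisfied = c(TRUE, TRUE, FALSE, TRUE, NA),
    ppi_free = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_warning(fl <- outcome_flags(coh), "preoperative HRQL of 0")
  expect_equal(fl$favorable, c(TRUE, FALSE, FALSE, TRUE, NA))
  # 70.7% improvement -> TRUE; exactly 50% -> TRUE; 46.7% -> FALSE
  expect_equal(fl$hrql_improved_50, c(TRUE, TRUE, FALSE, NA, NA))
})

test_that("group comparison requires two non-empty groups", {
  coh <- simulate_cohort(cohort_sim_config(n = 60, seed = 91))
  expect_error(compare_groups(coh, grouping = rep("x", nrow(coh))),
               "two groups")
})

test_that("identical groups give p = 1 everywhere", {
  half <- simulate_cohort(cohort_sim_config(n = 80, seed = 92))
  twin <- rbind(half, half)
  grouping <- rep(c("g1", "g2"), each = nrow(half))
  rows <- compare_groups(twin, grouping = grouping)
  expect_true(all(rows$p_value > 1 - 1e-9))
  expect_equal(rows$n1, rows$n2)
})

test_that("SAP-group comparison on a null cohort finds no outcome effect", {
  coh <- simulate_cohort(cohort_sim_config(seed = 93))
  t3 <- compare_groups(coh, variables = refluxsap:::outcome_variables())
  expect_gt(t3$p_value[t3$variable == "favorable"], 0.05)
  # per-variable complete cases give differing denominators
  expect_gt(t3$n1[t3$variable == "ppi_free"], t3$n1[t3$variable == "satisfied"])
})

test_that("SAP-count analysis is consistent with the binary comparison", {
  coh <- simulate_cohort(cohort_sim_config(n = 400, seed = 94))
  cnt <- sap_count_analysis(coh, seed = 95)
  expect_equal(sum(cnt$rates$n), sum(!is.na(outcome_flags(coh)$favorable)))
  # collapsing 1-3 into "positive" reproduces the two-group favorable table
  fav <- outcome_flags(coh)$favorable
  pos <- coh$sap_positive_count >= 1
  ok <- !is.na(fav)
  expect_equal(sum(cnt$rates$n_favorable[cnt$rates$n_sap_positive >= 1]),
               sum(fav[ok & pos]))
  # seeded null cohort: no association across 0/1/2/3
  expect_gt(cnt$test$p_value, 0.05)
  # equal rates by construction -> p ~ 1
  flat <- data.frame(
    patient_id = sprintf("P%d", 1:80),
    preop_hrql = 40, postop_hrql = 10,
    satisfied = rep(c(TRUE, TRUE, TRUE, FALSE), 20),
    ppi_free = TRUE,
    sap_positive_count = rep(0:3, each = 20))
  flat$per_symptom_sap <- ""
  cnt2 <- sap_count_analysis(flat, seed = 96)
  expect_gt(cnt2$test$p_value, 0.9)
})

test_that("symptom-type analysis respects tracking and the taxonomy", {
  coh <- simulate_cohort(cohort_sim_config(n = 300, seed = 97))
  tab <- symptom_type_analysis(coh)
  expect_equal(tab$name[tab$level == "type"],
               c("typical", "atypical", "non_reflux"))
  expect_setequal(tab$name[tab$level == "symptom"], known_symptoms())
  # a symptom tracked by nobody is flagged not assessable
  coh2 <- coh
  coh2$per_symptom_sap <- gsub("globus", "cough", coh2$per_symptom_sap)
  # collapse accidental duplicate cough entries by rebuilding counts
  tab2 <- symptom_type_analysis(coh2)
  expect_false(tab2$assessable[tab2$name == "globus"])
  # denominators never exceed the number of patients tracking the symptom
  long <- cohort_symptom_long(coh)
  for (i in which(tab$level == "symptom" & tab$assessable)) {
    ntrack <- sum(long$symptom == tab$name[i])
    expect_lte(tab$n_pos[i] + tab$n_neg[i], ntrack)
  }
})

test_that("subgroup sweep flags empty groups and matches the global row", {
  coh <- simulate_cohort(cohort_sim_config(seed = 98))
  specs <- c(default_subgroups(),
             list(list(name = "everyone", predicate = function(d) rep(TRUE, nrow(d))),
                  list(name = "nobody", predicate = function(d) rep(FALSE, nrow(d)))))
  sw <- subgroup_sweep(coh, specs, adjust = "holm")
  expect_false(sw$tested[sw$subgroup == "nobody"])
  t3 <- compare_groups(coh, variables = refluxsap:::outcome_variables())
  expect_equal(sw$p_value[sw$subgroup == "everyone"],
               t3$p_value[t3$variable == "favorable"])
  expect_true(all(sw$p_holm >= sw$p_value, na.rm = TRUE))
  # weighted decomposition: male/female rates recombine to the overall rate
  fav <- outcome_flags(coh)$favorable
  overall <- mean(fav, na.rm = TRUE)
  bysex <- tapply(fav, coh$sex, mean, na.rm = TRUE)
  wts <- tapply(!is.na(fav), coh$sex, sum)
  expect_equal(sum(bysex * wts) / sum(wts), overall, tolerance = 1e-12)
})

test_that("report percents equal their numerators over stated denominators", {
  coh <- simulate_cohort(cohort_sim_config(n = 250, seed = 99))
  rep <- suppressWarnings(cohort_report(coh, seed = 100))
  r <- rep$fig1_counts
  expect_equal(r$favorable_pct,
               refluxsap:::round_half_up(100 * r$n_favorable / pmax(1, r$n), 1))
  expect_true(all(r$n <= nrow(coh)))
  sw <- rep$fig2_subgroups
  expect_true(all(sw$n_sap_pos + sw$n_sap_neg <= sw$n))
  sb <- rep$sap_breakdown
  expect_equal(sb$n[1] + sb$n[2], nrow(coh))
  expect_equal(sb$pct, refluxsap:::round_half_up(100 * sb$n / nrow(coh), 1))
})

test_that("the primary comparison detects a real SAP effect at full size", {
  # power sweep: sap_effect_log_odds = 1 at n = 597 over 200 seeds
  rej <- vapply(1:200, function(s) {
    coh <- simulate_cohort(cohort_sim_config(sap_effect_log_odds = 1,
                                             seed = 20000 + s))
    fav <- outcome_flags(coh)$favorable
    pos <- coh$sap_positive_count >= 1
    ok <- !is.na(fav)
    tab <- matrix(c(sum(fav[ok & pos]), sum(!fav[ok & pos]),
                    sum(fav[ok & !pos]), sum(!fav[ok & !pos])), 2)
    fisher_exact_2x2(tab)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("SAP count arithmetic reproduces patient-level totals", {
  sb <- summarize_sap_counts(c(221, 164, 45), n = 597)
  expect_equal(sb$n, c(430, 167))
  expect_equal(sb$pct, c(72.0, 28.0))
  expect_error(summarize_sap_counts(c(300, 300, 45), n = 597))
})
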