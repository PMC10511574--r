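#' Outcome flags for a cohort
#'
#' Favorable outcome is patient satisfaction AND freedom from PPI; it is
#' missing when either component is missing. \code{hrql_improved_50} flags at
#' least a 50% improvement of the GERD-HRQL total score from baseline
#' (boundary inclusive); it is missing when the postoperative score is
#' missing, and missing with a warning when the preoperative score is 0.
#'
#' @param cohort a cohort data.frame (canonical columns) or a single-row
#'   record.
#' @return data.frame with logical columns \code{satisfied}, \code{ppi_free},
#'   \code{favorable}, \code{hrql_improved_50}.
#' @export
outcome_flags <- function(cohort) {
  pre <- cohort$preop_hrql; post <- cohort$postop_hrql
  impr <- ifelse(!is.na(pre) & pre > 0 & !is.na(post),
                 (pre - post) / pre >= 0.5 - 1e-12, NA)
  zero_pre <- !is.na(pre) & pre == 0 & !is.na(post)
  if (any(zero_pre))
    warning("preoperative HRQL of 0: 50%-improvement flag set to missing for ",
            sum(zero_pre), " patient(s)")
  data.frame(satisfied = cohort$satisfied, ppi_free = cohort$ppi_free,
             favorable = cohort$satisfied & cohort$ppi_free,
             hrql_improved_50 = impr)
}

sap_group <- function(cohort) {
  factor(ifelse(cohort$sap_positive_count >= 1, "sap_positive", "sap_negative"),
         levels = c("sap_positive", "sap_negative"))
}

fmt_median_iqr <- function(x) {
  x <- x[!is.na(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.1f (%.0f-%.0f)", q[2], q[1], q[3])
}

fmt_n_pct <- function(k, n) sprintf("%d (%.1f%%)", k, round_half_up(100 * k / n, 1))

# default variable sets for the two-group comparison tables
baseline_variables <- function() list(
  list(name = "age", type = "continuous", value = function(d) d$age),
  list(name = "sex_female", type = "binary", value = function(d) d$sex == "female"),
  list(name = "bmi", type = "continuous", value = function(d) d$bmi),
  list(name = "bmi_gt_30", type = "binary", value = function(d) d$bmi > 30),
  list(name = "demeester", type = "continuous", value = function(d) d$demeester),
  list(name = "mild_reflux", type = "binary",
       value = function(d) d$demeester > 14.7 & d$demeester <= 20),
  list(name = "severe_reflux", type = "binary", value = function(d) d$demeester > 50),
  list(name = "preop_hrql", type = "continuous", value = function(d) d$preop_hrql),
  list(name = "fundoplication_partial", type = "binary",
       value = function(d) d$fundoplication == "partial"))

outcome_variables <- function() list(
  list(name = "favorable", type = "binary",
       value = function(d) outcome_flags(d)$favorable),
  list(name = "satisfied", type = "binary", value = function(d) d$satisfied),
  list(name = "ppi_free", type = "binary", value = function(d) d$ppi_free),
  list(name = "hrql_improved_50", type = "binary",
       value = function(d) suppressWarnings(outcome_flags(d)$hrql_improved_50)))

#' Two-group comparison table (SAP-positive vs SAP-negative)
#'
#' Continuous variables are summarised as median (IQR) and compared with the
#' Mann-Whitney U test; binary variables as n (%) with Fisher's exact test.
#' Each variable uses its own complete cases, and the per-group denominators
#' are reported explicitly.
#'
#' @param cohort cohort data.frame.
#' @param grouping logical/two-level vector of length \code{nrow(cohort)};
#'   default is SAP-positive vs SAP-negative.
#' @param variables list of variable specs (name, type, value function);
#'   defaults to the baseline set.
#' @return data.frame with one row per variable: group summaries,
#'   denominators, test name and p-value.
#' @export
compare_groups <- function(cohort, grouping = sap_group(cohort),
                           variables = baseline_variables()) {
  g <- factor(grouping)
  if (nlevels(g) != 2L)
    stop("grouping must yield exactly two groups, got: ",
         paste(levels(g), collapse = ", "))
  lv <- levels(g)
  if (!all(table(g) > 0)) stop("grouping yields an empty group")
  rows <- lapply(variables, function(v) {
    x <- v$value(cohort)
    ok <- !is.na(x) & !is.na(g)
    x1 <- x[ok & g == lv[1]]; x2 <- x[ok & g == lv[2]]
    if (v$type == "continuous") {
      tst <- mann_whitney_u(x1, x2)
      s1 <- fmt_median_iqr(x1); s2 <- fmt_median_iqr(x2)
    } else {
      tab <- matrix(c(sum(x1), sum(!x1), sum(x2), sum(!x2)), 2)
      tst <- fisher_exact_2x2(tab)
      s1 <- fmt_n_pct(sum(x1), length(x1)); s2 <- fmt_n_pct(sum(x2), length(x2))
    }
    data.frame(variable = v$name, type = v$type,
               group1 = s1, group2 = s2,
               n1 = length(x1), n2 = length(x2),
               test = tst$method, p_value = tst$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group1"] <- lv[1]
  names(out)[names(out) == "group2"] <- lv[2]
  out
}

#' Favorable outcome by number of SAP-positive symptoms
#'
#' Cross-tabulates favorable outcome against the number (0/1/2/3) of
#' SAP-positive symptoms and tests the 2 x k table with the Monte Carlo
#' exact test.
#'
#' @param cohort cohort data.frame.
#' @param n_resamples,seed passed to \code{exact_rxc_test}.
#' @return list with the \code{table}, per-count favorable \code{rates}
#'   data.frame, and \code{test}.
#' @export
sap_count_analysis <- function(cohort, n_resamples = 4000, seed = NULL) {
  fav <- outcome_flags(cohort)$favorable
  cnt <- factor(pmin(cohort$sap_positive_count, 3), levels = 0:3)
  ok <- !is.na(fav)
  tab <- table(favorable = factor(fav[ok], levels = c(FALSE, TRUE)),
               n_sap_positive = cnt[ok])
  keep <- colSums(tab) > 0
  tst <- if (sum(keep) < 2L)
    new_reflux_test(NA_real_, 1, "Monte Carlo exact r x c", sum(tab), mc_se = 0)
  else exact_rxc_test(as.matrix(tab[, keep, drop = FALSE]),
                      n_resamples = n_resamples, seed = seed)
  rates <- data.frame(
    n_sap_positive = as.integer(colnames(tab)),
    n = as.integer(colSums(tab)),
    n_favorable = as.integer(tab["TRUE", ]),
    favorable_pct = round_half_up(
      100 * as.integer(tab["TRUE", ]) / pmax(1, as.integer(colSums(tab))), 1))
  list(table = tab, rates = rates, test = tst)
}

#' Favorable outcome by SAP status per symptom and symptom type
#'
#' For each of the nine individual symptoms and each symptom category
#' (typical/atypical/non-reflux), compares the favorable-outcome rate between
#' patients SAP-positive and SAP-negative for that symptom (category),
#' restricted to patients who tracked it, with Fisher's exact test. A symptom
#' tracked by nobody (or with an empty SAP group) is flagged not assessable.
#'
#' @param cohort cohort data.frame.
#' @return data.frame, one row per category then per symptom.
#' @export
symptom_type_analysis <- function(cohort) {
  long <- cohort_symptom_long(cohort)
  fav <- outcome_flags(cohort)$favorable
  names(fav) <- cohort$patient_id
  one_row <- function(name, level, ids_pos, ids_neg) {
    f1 <- fav[ids_pos]; f2 <- fav[ids_neg]
    f1 <- f1[!is.na(f1)]; f2 <- f2[!is.na(f2)]
    if (length(f1) == 0L || length(f2) == 0L)
      return(data.frame(name = name, level = level, assessable = FALSE,
                        n_pos = length(f1), n_neg = length(f2),
                        fav_pos = NA, fav_neg = NA,
                        fav_pos_pct = NA_real_, fav_neg_pct = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    tst <- fisher_exact_2x2(matrix(c(sum(f1), sum(!f1), sum(f2), sum(!f2)), 2))
    data.frame(name = name, level = level, assessable = TRUE,
               n_pos = length(f1), n_neg = length(f2),
               fav_pos = sum(f1), fav_neg = sum(f2),
               fav_pos_pct = round_half_up(100 * mean(f1), 1),
               fav_neg_pct = round_half_up(100 * mean(f2), 1),
               p_value = tst$p_value, stringsAsFactors = FALSE)
  }
  cat_rows <- lapply(symptom_categories(), function(cc) {
    sub <- long[long$category == cc, , drop = FALSE]
    byp <- tapply(sub$sap_flag %in% 1, sub$patient_id, any)
    one_row(cc, "type", names(byp)[byp], names(byp)[!byp])
  })
  sym_rows <- lapply(known_symptoms(), function(ss) {
    sub <- long[long$symptom == ss, , drop = FALSE]
    one_row(ss, "symptom",
            sub$patient_id[sub$sap_flag %in% 1],
            sub$patient_id[sub$sap_flag %in% 0])
  })
  do.call(rbind, c(cat_rows, sym_rows))
}

#' Default clinical subgroups
#'
#' The nine standard subgroups: age < 40, age >= 70, female, male, BMI >= 30,
#' mild objective reflux (DeMeester in (14.7, 20]), severe objective reflux
#' (> 50), Nissen and partial fundoplication. \code{hrql_split_subgroups}
#' adds the preoperative-HRQL median-split pair for a given cohort.
#'
#' @return list of subgroup specs (\code{name} + \code{predicate}).
#' @export
default_subgroups <- function() list(
  list(name = "age_lt_40", predicate = function(d) d$age < 40),
  list(name = "age_ge_70", predicate = function(d) d$age >= 70),
  list(name = "female", predicate = function(d) d$sex == "female"),
  list(name = "male", predicate = function(d) d$sex == "male"),
  list(name = "bmi_ge_30", predicate = function(d) d$bmi >= 30),
  list(name = "mild_reflux",
       predicate = function(d) d$demeester > 14.7 & d$demeester <= 20),
  list(name = "severe_reflux", predicate = function(d) d$demeester > 50),
  list(name = "nissen", predicate = function(d) d$fundoplication == "nissen"),
  list(name = "partial", predicate = function(d) d$fundoplication == "partial"))

#' @rdname default_subgroups
#' @param cohort cohort data.frame used to compute the median.
#' @export
hrql_split_subgroups <- function(cohort) {
  med <- median(cohort$preop_hrql, na.rm = TRUE)
  list(
    list(name = sprintf("preop_hrql_lt_%g", med),
         predicate = function(d) d$preop_hrql < med),
    list(name = sprintf("preop_hrql_ge_%g", med),
         predicate = function(d) d$preop_hrql >= med))
}

#' Favorable-by-SAP comparison within subgroups
#'
#' Within each subgroup (patients with a missing predicate input are
#' excluded), compares the favorable-outcome rate between SAP-positive and
#' SAP-negative patients with Fisher's exact test. A subgroup with an empty
#' SAP group is flagged untested. Holm adjustment across the sweep is
#' optional.
#'
#' @param cohort cohort data.frame.
#' @param specs list of subgroup specs; default \code{default_subgroups()}.
#' @param adjust \code{"none"} or \code{"holm"}.
#' @return data.frame, one row per subgroup.
#' @export
subgroup_sweep <- function(cohort, specs = default_subgroups(),
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  fav <- outcome_flags(cohort)$favorable
  sg <- sap_group(cohort)
  rows <- lapply(specs, function(sp) {
    inq <- sp$predicate(cohort)
    inq[is.na(inq)] <- FALSE
    ok <- inq & !is.na(fav)
    f1 <- fav[ok & sg == "sap_positive"]; f2 <- fav[ok & sg == "sap_negative"]
    base <- data.frame(subgroup = sp$name, n = sum(inq),
                       n_sap_pos = length(f1), n_sap_neg = length(f2),
                       stringsAsFactors = FALSE)
    if (length(f1) == 0L || length(f2) == 0L) {
      base$fav_pos_pct <- NA_real_; base$fav_neg_pct <- NA_real_
      base$p_value <- NA_real_; base$tested <- FALSE
    } else {
      tst <- fisher_exact_2x2(matrix(c(sum(f1), sum(!f1), sum(f2), sum(!f2)), 2))
      base$fav_pos_pct <- round_half_up(100 * mean(f1), 1)
      base$fav_neg_pct <- round_half_up(100 * mean(f2), 1)
      base$p_value <- tst$p_value; base$tested <- TRUE
    }
    base
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_holm <- p.adjust(out$p_value, "holm")
  out
}

#' Patient-level SAP count arithmetic
#'
#' Given the sizes of the one/two/three SAP-positive-symptom groups and the
#' cohort size, derives the patient-level SAP-positive and SAP-negative
#' counts and percentages (one decimal, half-up rounding).
#'
#' @param counts length-3 vector: patients with exactly 1, 2 and 3
#'   SAP-positive symptoms.
#' @param n cohort size.
#' @return data.frame with rows \code{sap_positive} and \code{sap_negative}.
#' @examples
#' summarize_sap_counts(c(221, 164, 45), n = 597)
#' @export
summarize_sap_counts <- function(counts, n) {
  stopifnot(length(counts) == 3, all(counts >= 0), sum(counts) <= n)
  npos <- sum(counts)
  data.frame(group = c("sap_positive", "sap_negative"),
             n = c(npos, n - npos),
             pct = round_half_up(100 * c(npos, n - npos) / n, 1),
             stringsAsFactors = FALSE)
}

#' Full cohort analysis report
#'
#' Produces the whole analytic battery: a cohort summary (demographics and
#' reflux severity), the baseline and outcome SAP-group comparison tables,
#' the symptom-type/individual-symptom table, the favorable-by-SAP-count
#' breakdown and the subgroup sweep. \code{write_report} exports each table
#' as CSV plus a combined JSON document to a directory.
#'
#' @param cohort cohort data.frame.
#' @param subgroups subgroup specs for the sweep.
#' @param adjust p-adjustment for the sweep.
#' @param n_resamples,seed Monte Carlo settings for the count analysis.
#' @return a \code{cohort_report} list of data.frames.
#' @export
cohort_report <- function(cohort, subgroups = default_subgroups(),
                          adjust = "none", n_resamples = 4000, seed = NULL) {
  fav <- outcome_flags(cohort)$favorable
  counts <- table(factor(pmin(cohort$sap_positive_count, 3), levels = 0:3))
  summary1 <- data.frame(
    characteristic = c("n", "age_median_iqr", "female_n_pct",
                       "bmi_median_iqr", "demeester_median_iqr",
                       "mild_reflux_n_pct", "severe_reflux_n_pct",
                       "preop_hrql_median_iqr", "nissen_n_pct",
                       "favorable_n_pct"),
    value = c(nrow(cohort), fmt_median_iqr(cohort$age),
              fmt_n_pct(sum(cohort$sex == "female"), nrow(cohort)),
              fmt_median_iqr(cohort$bmi), fmt_median_iqr(cohort$demeester),
              fmt_n_pct(sum(cohort$demeester > 14.7 & cohort$demeester <= 20),
                        nrow(cohort)),
              fmt_n_pct(sum(cohort$demeester > 50), nrow(cohort)),
              fmt_median_iqr(cohort$preop_hrql),
              fmt_n_pct(sum(cohort$fundoplication == "nissen"), nrow(cohort)),
              fmt_n_pct(sum(fav, na.rm = TRUE), sum(!is.na(fav)))),
    stringsAsFactors = FALSE)
  cnt <- sap_count_analysis(cohort, n_resamples = n_resamples, seed = seed)
  structure(list(
    table1 = summary1,
    table2 = compare_groups(cohort, variables = baseline_variables()),
    table3 = compare_groups(cohort, variables = outcome_variables()),
    table4_5 = symptom_type_analysis(cohort),
    fig1_counts = cbind(cnt$rates,
                        p_value = c(cnt$test$p_value,
                                    rep(NA, nrow(cnt$rates) - 1))),
    fig2_subgroups = subgroup_sweep(cohort, subgroups, adjust),
    sap_breakdown = summarize_sap_counts(as.integer(counts[2:4]), nrow(cohort))),
    class = "cohort_report")
}

#' @rdname cohort_report
#' @param report a \code{cohort_report}.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(table1 = "table1.csv", table2 = "table2.csv",
             table3 = "table3.csv", table4_5 = "table4.csv",
             fig1_counts = "fig1_counts.csv",
             fig2_subgroups = "fig2_subgroups.csv",
             sap_breakdown = "sap_breakdown.csv")
  for (k in names(files))
    utils::write.csv(report[[k]], file.path(dir, files[k]), row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
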