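# Published summary tables from the ischemic-stroke case-control study that
# this pipeline reimplements, typed in as code so they can serve as inputs
# (the raw plasma lipidomics data were not deposited).

#' Baseline 2x2 contingency counts of the stroke case-control study
#'
#' Counts of the categorical baseline characteristics for the 251 ischemic
#' stroke cases and 251 controls, as published: gender, type 2 diabetes,
#' hypertension, obesity, antihypertensive drug use and hypoglycemic drug
#' use. Each entry is a 2x2 integer matrix with columns `case`/`control`
#' and rows the two exposure levels (for gender: male/female; otherwise
#' yes/no).
#'
#' @return Named list of 2x2 matrices.
#' @seealso [pearson_chi_square()]
#' @export
is_baseline_counts <- function() {
  m2 <- function(a, b, c, d, rows) matrix(
    as.integer(c(a, c, b, d)), 2, 2,
    dimnames = list(rows, c("case", "control")))
  list(
    gender = m2(153, 98, 157, 94, c("male", "female")),
    t2d = m2(70, 18, 251 - 70, 251 - 18, c("yes", "no")),
    hypertension = m2(140, 38, 251 - 140, 251 - 38, c("yes", "no")),
    obesity = m2(33, 9, 251 - 33, 251 - 9, c("yes", "no")),
    antihypertensive = m2(89, 22, 251 - 89, 251 - 22, c("yes", "no")),
    hypoglycemic = m2(46, 11, 251 - 46, 251 - 11, c("yes", "no")))
}

#' Baseline continuous summaries of the stroke case-control study
#'
#' Mean and SD of age and the conventional lipid panel (TC, TG, LDL-C,
#' HDL-C; mmol/L) per group, n = 251 per group, as published.
#'
#' @return Data frame with columns `variable`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`, `n_case`, `n_control`.
#' @seealso [z_from_summary()]
#' @export
is_baseline_summaries <- function() {
  data.frame(
    variable = c("age", "tc", "tg", "ldl_c", "hdl_c"),
    case_mean = c(64.53, 4.82, 1.84, 2.78, 1.05),
    case_sd = c(10.26, 1.85, 1.39, 0.92, 0.79),
    control_mean = c(62.95, 4.10, 1.55, 2.38, 1.19),
    control_sd = c(8.79, 0.81, 0.94, 0.83, 0.73),
    n_case = 251L, n_control = 251L,
    stringsAsFactors = FALSE)
}

#' Published differential-lipid statistics
#'
#' The per-lipid statistics published for the two analysis stages of the
#' study: the 19 lipid species that passed the discovery-stage filter
#' (VIP > 1, P < 0.05, |log2FC| > 1; n = 15/15) and the 15 that remained
#' significant (VIP > 1, P < 0.05) in the comorbidity-free validation
#' subset (n = 111/213). Columns: `feature_id`, `mz` (Da), `rt` (min),
#' `log2fc` (case vs control; positive = up in cases), `vip`, `p`, `q`.
#' The source prints every p-value only as "< 0.001"; they are stored
#' here as 5e-4 (any representative value below the 0.05 threshold is
#' equivalent for filtering). `q` repeats `p` since per-lipid adjusted
#' values were not printed.
#'
#' @param cohort `"discovery"` (19 rows) or `"validation"` (15 rows).
#' @return Data frame of lipid statistics.
#' @seealso [differential_filter()]
#' @export
is_lipid_stats <- function(cohort = c("discovery", "validation")) {
  cohort <- match.arg(cohort)
  p <- 5e-4
  if (cohort == "discovery") {
    df <- data.frame(
      feature_id = c("PE(16:0/16:1)", "DAG(16:0/20:4)", "TAG48:3-FA16:0",
                     "PE(P-18:0/22:4)", "TAG48:3-FA14:0", "PA(18:0/22:4)",
                     "TAG48:3-FA16:1", "TAG48:2-FA14:0", "PG(20:0/16:1)",
                     "DCER(24:1)", "TAG54:3-FA20:2", "PE(P-18:1/22:4)",
                     "DAG(18:2/20:4)", "DAG(16:1/18:2)", "PE(P-18:1/18:2)",
                     "PE(P-16:0/20:5)", "PC(14:0/16:1)", "TAG56:4-FA18:0",
                     "PE(P-18:0/22:6)"),
      mz = c(688.49, 634.50, 810.53, 778.60, 810.53, 751.53, 812.53,
             810.53, 775.55, 650.90, 818.53, 776.60, 658.50, 608.50,
             724.50, 720.50, 704.55, 820.53, 774.50),
      rt = c(12.09, 13.37, 16.64, 13.93, 16.54, 13.21, 17.10, 16.99,
             10.69, 15.35, 17.44, 13.11, 12.46, 12.69, 12.70, 11.78,
             10.65, 17.68, 13.11),
      log2fc = c(-2.52, -2.16, -1.81, 1.77, -1.76, 1.67, -1.55, -1.49,
                 -1.29, -1.26, -1.17, 1.15, -1.10, -1.09, 1.08, 1.08,
                 -1.07, -1.06, 1.034),
      vip = c(1.49, 1.71, 1.07, 2.00, 1.04, 2.00, 1.11, 1.04, 1.36,
              1.23, 1.57, 1.88, 1.51, 1.45, 1.91, 1.13, 1.17, 1.46,
              1.52),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      feature_id = c("PE(16:0/16:1)", "DAG(16:0/20:4)", "TAG48:3-FA16:0",
                     "PE(P-18:0/22:4)", "TAG48:3-FA14:0", "PA(18:0/22:4)",
                     "TAG48:3-FA16:1", "TAG48:2-FA14:0", "PG(20:0/16:1)",
                     "DCER(24:1)", "TAG54:3-FA20:2", "PE(P-18:1/22:4)",
                     "DAG(18:2/20:4)", "DAG(16:1/18:2)", "PE(P-18:0/22:6)"),
      mz = c(688.49, 634.50, 810.53, 778.60, 810.53, 751.53, 812.53,
             810.53, 775.55, 650.90, 818.53, 776.60, 658.50, 608.50,
             774.50),
      rt = c(12.09, 13.37, 16.64, 13.93, 16.54, 13.21, 17.10, 16.99,
             10.69, 15.35, 17.44, 13.11, 12.46, 12.69, 13.11),
      log2fc = c(-2.18, -2.75, -1.55, 2.35, -1.48, 1.42, -1.32, -1.27,
                 -1.16, -1.82, -1.05, 1.02, -0.98, -0.92, 1.68),
      vip = c(1.32, 2.28, 1.05, 2.45, 1.02, 1.85, 1.08, 1.03, 1.21,
              1.67, 1.42, 1.78, 1.35, 1.28, 2.08),
      stringsAsFactors = FALSE)
  }
  df$p <- p
  df$q <- p
  df
}

#' Published panel-weighting coefficients
#'
#' The published comprehensive score-model coefficients and normalized
#' index weights of the 15 validation-stage lipids, ordered by weight as
#' printed. Note the printed weights are rounded and do not renormalize
#' exactly from the printed coefficients; they are used here as inputs
#' to [select_panel()], not as a check of [pca_weighting()].
#'
#' @return Data frame with columns `feature_id`, `coefficient`, `weight`.
#' @export
is_panel_weights <- function() {
  data.frame(
    feature_id = c("PE(P-18:1/22:4)", "PE(16:0/16:1)", "TAG48:3-FA16:1",
                   "DAG(18:2/20:4)", "PE(P-18:0/22:6)", "PE(P-18:0/22:4)",
                   "DCER(24:1)", "TAG48:3-FA16:0", "DAG(16:0/20:4)",
                   "PA(18:0/22:4)", "DAG(16:1/18:2)", "TAG48:2-FA14:0",
                   "TAG48:3-FA14:0", "TAG54:3-FA20:2", "PG(20:0/16:1)"),
    coefficient = c(0.231, 0.220, 0.045, 0.032, 0.012, 0.010, 0.010,
                    0.010, 0.010, 0.009, 0.008, 0.007, 0.007, 0.006,
                    0.005),
    weight = c(0.177, 0.168, 0.035, 0.025, 0.009, 0.008, 0.008, 0.008,
               0.007, 0.007, 0.006, 0.005, 0.005, 0.004, 0.004),
    stringsAsFactors = FALSE)
}

#' Published comorbidity prevalences and subgroup sizes
#'
#' Per-group prevalences of type 2 diabetes, hypertension and obesity and
#' the comorbidity-free subgroup sizes (111 of 251 cases, 213 of 251
#' controls), as published. These are the defaults of [cohort_spec()].
#'
#' @return List with `case` and `control` sublists (`t2d`,
#'   `hypertension`, `obesity`, `comorbidity_free`), each a proportion.
#' @export
is_comorbidity_rates <- function() {
  list(case = list(t2d = 70 / 251, hypertension = 140 / 251,
                   obesity = 33 / 251, comorbidity_free = 111 / 251),
       control = list(t2d = 18 / 251, hypertension = 38 / 251,
                      obesity = 9 / 251, comorbidity_free = 213 / 251))
}
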