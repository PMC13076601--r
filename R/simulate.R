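# Synthetic case-control cohort generator. Emulates the statistical
# structure the downstream analysis assumes: log-normal lipid abundances
# with planted log2 fold changes at the published discovery-stage
# magnitudes, block correlation among PE-plasmalogen and DAG species,
# baseline covariates at the published prevalences and summaries.

#' Specify a synthetic case-control lipidomics cohort
#'
#' Defaults reproduce the published study conditions: the 19 planted
#' log2 fold changes of the discovery-stage differential lipids, 139
#' additional null lipids (158 species total), log2-scale SD 0.5, one
#' positively correlated PE-plasmalogen block (rho = 0.5), a DAG block
#' (within rho = 0.5) negatively correlated with the PE block
#' (rho = -0.3), comorbidity prevalences and conventional-lipid
#' means/SDs from the published baseline table, and comorbidity-free
#' fractions 111/251 (case) and 213/251 (control).
#'
#' @param n_case,n_control group sizes (>= 2).
#' @param effect_table data frame with columns `feature_id`, `log2fc`
#'   giving the planted per-feature effects; defaults to the published
#'   discovery-stage lipids ([is_lipid_stats]`("discovery")`).
#' @param n_null_features number of additional zero-effect lipids.
#' @param sigma_log SD of log2 abundance (> 0).
#' @param block_structure list of blocks, each
#'   `list(features = <ids>, rho = <within-block correlation>)`, plus an
#'   optional attribute-free element `list(between = c(i, j), rho = r)`
#'   giving a cross-block correlation between blocks i and j.
#' @param covariate_prevalences list as [is_comorbidity_rates()].
#' @param lipid_panel_params data frame as [is_baseline_summaries()]
#'   (rows `age`, `tc`, `tg`, `ldl_c`, `hdl_c`).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_case = 15, n_control = 15,
                        effect_table = NULL, n_null_features = 139,
                        sigma_log = 0.5, block_structure = NULL,
                        covariate_prevalences = is_comorbidity_rates(),
                        lipid_panel_params = is_baseline_summaries(),
                        seed = 1L) {
  if (n_case < 2 || n_control < 2) stop("n_case and n_control must be >= 2")
  if (sigma_log <= 0) stop("sigma_log must be > 0")
  if (is.null(effect_table)) {
    tab <- is_lipid_stats("discovery")
    effect_table <- tab[, c("feature_id", "log2fc")]
  }
  stopifnot(all(c("feature_id", "log2fc") %in% names(effect_table)))
  if (n_null_features < 0) stop("n_null_features must be >= 0")
  if (is.null(block_structure)) {
    pe <- grep("^PE\\(P-", effect_table$feature_id, value = TRUE)
    dag <- grep("^DAG\\(", effect_table$feature_id, value = TRUE)
    block_structure <- list(
      list(features = pe, rho = 0.5),
      list(features = dag, rho = 0.5),
      list(between = c(1L, 2L), rho = -0.3))
  }
  for (b in block_structure) {
    if (!is.null(b$rho) && (b$rho <= -1 || b$rho >= 1))
      stop("block correlations must lie in (-1, 1)")
  }
  pr <- covariate_prevalences
  for (g in c("case", "control"))
    for (nm in names(pr[[g]]))
      if (pr[[g]][[nm]] < 0 || pr[[g]][[nm]] > 1)
        stop("covariate probabilities must lie in [0, 1]")
  spec <- structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         effect_table = effect_table,
         n_null_features = as.integer(n_null_features),
         sigma_log = sigma_log, block_structure = block_structure,
         covariate_prevalences = pr,
         lipid_panel_params = lipid_panel_params,
         seed = as.integer(seed)),
    class = "cohort_spec")
  # fail early on a non-PSD implied covariance
  invisible(build_correlation(spec))
  spec
}

# assemble the feature correlation matrix implied by the block structure
build_correlation <- function(spec) {
  ids <- all_feature_ids(spec)
  p <- length(ids)
  R <- diag(p)
  rownames(R) <- colnames(R) <- ids
  blocks <- Filter(function(b) !is.null(b$features), spec$block_structure)
  between <- Filter(function(b) !is.null(b$between), spec$block_structure)
  for (b in blocks) {
    idx <- match(b$features, ids)
    if (anyNA(idx)) stop("block feature not in feature set")
    R[idx, idx] <- b$rho
    diag(R)[idx] <- 1
  }
  for (b in between) {
    i <- match(blocks[[b$between[1]]]$features, ids)
    j <- match(blocks[[b$between[2]]]$features, ids)
    R[i, j] <- b$rho
    R[j, i] <- b$rho
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("block structure implies a non positive semi-definite covariance")
  R
}

all_feature_ids <- function(spec) {
  nulls <- if (spec$n_null_features > 0)
    sprintf("NULL_LIPID_%03d", seq_len(spec$n_null_features)) else character()
  c(spec$effect_table$feature_id, nulls)
}

#' Simulate a case-control lipidomics study
#'
#' Log2 abundance of feature j in sample s is
#' `mu_j + I(case) * delta_j + e_s`, with `e ~ N(0, sigma_log^2 * R)`
#' (R the block correlation matrix) and the abundance `2^(log2 value)`,
#' i.e. log-normal on the natural scale. Baseline levels `mu_j` are drawn
#' once per study (uniform on \[10, 20\] log2 units, typical of LC-MS peak
#' areas). Identical spec + seed gives bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `simulated_study`: `feature_table` (a
#'   [feature_table()], cases first), `metadata` (from
#'   [simulate_covariates()]), `truth` (data frame `feature_id`,
#'   `log2fc`, `differential`).
#' @export
simulate_lipidomics <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- build_correlation(spec)
  ids <- all_feature_ids(spec)
  p <- length(ids)
  n <- spec$n_case + spec$n_control
  delta <- c(spec$effect_table$log2fc, rep(0, spec$n_null_features))
  set.seed(spec$seed)
  mu <- stats::runif(p, 10, 20)
  L <- chol(R + diag(1e-10, p))
  e <- matrix(stats::rnorm(n * p), n, p) %*% L * spec$sigma_log
  grp <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
  log2x <- sweep(e, 2, mu, `+`) +
    outer(as.numeric(grp == "case"), delta)
  values <- 2^log2x
  dimnames(values) <- list(sprintf("S%03d", seq_len(n)), ids)
  ft <- feature_table(values, group = grp)
  meta <- simulate_covariates(spec, sample_ids = rownames(values),
                              group = grp, reseed = FALSE)
  truth <- data.frame(feature_id = ids, log2fc = delta,
                      differential = delta != 0, stringsAsFactors = FALSE)
  structure(list(feature_table = ft, metadata = meta, truth = truth),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("simulated_study\n")
  print(x$feature_table)
  cat(sprintf("  planted differential features: %d of %d\n",
              sum(x$truth$differential), nrow(x$truth)))
  invisible(x)
}

#' Simulate baseline covariates
#'
#' Draws per-sample gender (balanced within group), age and conventional
#' lipids (normal at the published group means/SDs, lipids truncated at
#' zero by redraw), and comorbidity flags. Comorbidities follow the
#' two-stage scheme: an "any comorbidity" indicator is drawn first at
#' `1 - comorbidity_free` per group, then each condition is assigned
#' among comorbid samples with probability `p_condition / p_any` (with
#' hypertension — the condition whose published prevalence equals the
#' comorbid fraction — forced on when no condition was assigned), so both
#' the condition marginals and the comorbidity-free fraction match the
#' published table in expectation.
#'
#' @param spec a [cohort_spec()].
#' @param sample_ids,group optional externally fixed ids/groups (used by
#'   [simulate_lipidomics()] so metadata aligns with the feature table).
#' @param reseed set the RNG from `spec$seed` (default `TRUE`; internal
#'   callers that already seeded pass `FALSE`).
#' @return Metadata data frame (columns of [read_metadata()]).
#' @export
simulate_covariates <- function(spec, sample_ids = NULL, group = NULL,
                                reseed = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (reseed) set.seed(spec$seed)
  if (is.null(group))
    group <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
  n <- length(group)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  pars <- spec$lipid_panel_params
  rownames(pars) <- pars$variable
  rnorm_pos <- function(n, m, s) {
    x <- stats::rnorm(n, m, s)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), m, s)
    x
  }
  draw_group <- function(g, ng) {
    pr <- spec$covariate_prevalences[[g]]
    p_any <- 1 - pr$comorbidity_free
    any_com <- stats::runif(ng) < p_any
    cond <- function(p_marg) {
      z <- rep(FALSE, ng)
      if (p_any > 0)
        z[any_com] <- stats::runif(sum(any_com)) < min(1, p_marg / p_any)
      z
    }
    t2d <- cond(pr$t2d)
    htn <- cond(pr$hypertension)
    ob <- cond(pr$obesity)
    none <- any_com & !(t2d | htn | ob)
    htn[none] <- TRUE   # keep the "any comorbidity" marginal exact
    m <- function(v) pars[v, if (g == "case") "case_mean" else "control_mean"]
    s <- function(v) pars[v, if (g == "case") "case_sd" else "control_sd"]
    data.frame(
      gender = factor(rep_len(c("male", "female"), ng),
                      levels = c("male", "female")),
      age = stats::rnorm(ng, m("age"), s("age")),
      t2d = t2d, hypertension = htn, obesity = ob,
      tc = rnorm_pos(ng, m("tc"), s("tc")),
      tg = rnorm_pos(ng, m("tg"), s("tg")),
      ldl_c = rnorm_pos(ng, m("ldl_c"), s("ldl_c")),
      hdl_c = rnorm_pos(ng, m("hdl_c"), s("hdl_c")),
      stringsAsFactors = FALSE)
  }
  out <- data.frame(sample_id = sample_ids,
                    group = factor(group, levels = c("case", "control")),
                    stringsAsFactors = FALSE)
  covs <- rbind(draw_group("case", sum(group == "case")),
                draw_group("control", sum(group == "control")))
  # rows above are ordered case-then-control; reorder to the group vector
  idx <- integer(n)
  idx[group == "case"] <- seq_len(sum(group == "case"))
  idx[group == "control"] <- sum(group == "case") + seq_len(sum(group == "control"))
  cbind(out, covs[idx, , drop = FALSE], row.names = NULL)
}

#' Inject missing values and a batch shift
#'
#' Sets cells missing completely at random at `missing_rate` and applies
#' an additive log2 offset (`batch_shift`) to a designated second-batch
#' sample subset, for exercising imputation and batch adjustment.
#'
#' @param ft a [feature_table()].
#' @param missing_rate MCAR missingness proportion in \[0, 1).
#' @param batch_shift log2 offset added to batch-2 samples (0 = none).
#' @param batch2_samples sample ids forming batch 2; default the second
#'   half of the table.
#' @param seed RNG seed.
#' @return List: `feature_table` (modified), `batch` (per-sample factor
#'   `"b1"`/`"b2"`).
#' @export
inject_missing_and_batch <- function(ft, missing_rate = 0,
                                     batch_shift = 0,
                                     batch2_samples = NULL, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  set.seed(seed)
  v <- ft$values
  if (is.null(batch2_samples))
    batch2_samples <- ft$sample_ids[seq_len(nrow(v)) > nrow(v) / 2]
  batch <- factor(ifelse(ft$sample_ids %in% batch2_samples, "b2", "b1"))
  if (batch_shift != 0) {
    i2 <- which(batch == "b2")
    v[i2, ] <- v[i2, ] * 2^batch_shift
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(v)) < missing_rate,
                   nrow(v), ncol(v))
    v[drop] <- NA_real_
  }
  list(feature_table = feature_table(v, group = if (is.null(ft$group))
    NULL else as.character(ft$group)), batch = batch)
}

#' Simulate a two-batch expression matrix
#'
#' Gaussian log2 expression (genes x samples) with a planted group effect
#' for a fraction of genes and optional additive per-batch offsets, for
#' exercising the transcriptome screen.
#'
#' @param n_case,n_control samples per group.
#' @param n_genes number of genes.
#' @param de_fraction fraction of genes with a planted effect, in \[0, 1\].
#' @param effect log2 effect size added to cases for DE genes (sign
#'   alternates up/down).
#' @param batch_design `NULL` (single batch) or a list
#'   `list(offset = <log2 shift>, fraction = <share of samples in batch 2,
#'   taken equally from both groups>)`.
#' @param seed RNG seed.
#' @param sigma residual SD of log2 expression.
#' @return List: `matrix` (genes x samples), `groups` (factor),
#'   `batch` (factor), `truth` (data frame `gene`, `log2fc`, `de`).
#' @export
simulate_expression <- function(n_case, n_control, n_genes,
                                de_fraction = 0, effect = 2,
                                batch_design = NULL, seed = 1L,
                                sigma = 1) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  set.seed(seed)
  n <- n_case + n_control
  groups <- factor(rep(c("case", "control"), c(n_case, n_control)),
                   levels = c("case", "control"))
  genes <- sprintf("G%05d", seq_len(n_genes))
  n_de <- round(de_fraction * n_genes)
  delta <- rep(0, n_genes)
  if (n_de > 0)
    delta[seq_len(n_de)] <- effect * rep_len(c(1, -1), n_de)
  base <- stats::runif(n_genes, 4, 12)
  m <- matrix(stats::rnorm(n_genes * n, sd = sigma), n_genes, n,
              dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  m <- m + base + outer(delta, as.numeric(groups == "case"))
  batch <- factor(rep("b1", n), levels = c("b1", "b2"))
  if (!is.null(batch_design)) {
    k_case <- round(batch_design$fraction * n_case)
    k_ctrl <- round(batch_design$fraction * n_control)
    in2 <- c(seq_len(k_case), n_case + seq_len(k_ctrl))
    batch[in2] <- "b2"
    m[, in2] <- m[, in2] + batch_design$offset
  }
  list(matrix = m, groups = groups, batch = batch,
       truth = data.frame(gene = genes, log2fc = delta, de = delta != 0,
                          stringsAsFactors = FALSE))
}
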