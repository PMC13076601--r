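# Differential-lipid filtering, PCA score-coefficient panel weighting,
# composite diagnostic score, and ROC evaluation with DeLong confidence
# intervals.

#' Three-criterion differential-lipid filter
#'
#' Retains lipids with VIP strictly above `vip_min`, univariate p
#' strictly below `p_max`, and (when `abs_log2fc_min` is not `NA`)
#' |log2FC| strictly above `abs_log2fc_min`. Passing `abs_log2fc_min = NA`
#' disables the fold-change criterion — the validation-stage mode
#' (VIP > 1, P < 0.05 only). Row order is preserved.
#'
#' @param records data frame with columns `feature_id`, `log2fc`, `vip`,
#'   `p` (e.g. [is_lipid_stats()] or [lipid_stat_table()]).
#' @param vip_min VIP cutoff (strict >; default 1).
#' @param p_max p-value cutoff (strict <; default 0.05).
#' @param abs_log2fc_min |log2FC| cutoff (strict >), or `NA` to disable.
#' @return The retained rows of `records`.
#' @examples
#' nrow(differential_filter(is_lipid_stats("discovery")))            # 19
#' nrow(differential_filter(is_lipid_stats("validation"),
#'                          abs_log2fc_min = NA))                    # 15
#' @export
differential_filter <- function(records, vip_min = 1, p_max = 0.05,
                                abs_log2fc_min = 1) {
  stopifnot(all(c("feature_id", "log2fc", "vip", "p") %in% names(records)))
  keep <- records$vip > vip_min & records$p < p_max
  if (!is.na(abs_log2fc_min))
    keep <- keep & abs(records$log2fc) > abs_log2fc_min
  message(sprintf(
    "differential_filter: VIP > %g, p < %g%s -> %d of %d retained",
    vip_min, p_max,
    if (is.na(abs_log2fc_min)) "" else sprintf(", |log2FC| > %g", abs_log2fc_min),
    sum(keep), nrow(records)))
  records[keep, , drop = FALSE]
}

#' Per-lipid statistics table from a cohort
#'
#' Builds the per-lipid statistics record (log2FC, VIP, univariate p and
#' BH q) that feeds [differential_filter()]: log2FC is the difference of
#' group means of log2 abundance (case - control); VIP comes from an
#' OPLS-DA fit on the preprocessed table; p from the per-lipid two-sample
#' t test on log2 abundances (the univariate test the discovery screen
#' uses); q from [bh_adjust()].
#'
#' @param ft a grouped [feature_table()] of raw (positive) abundances.
#' @param annotation optional data frame `feature_id`, `mz`, `rt` to join.
#' @param n_ortho orthogonal components for the OPLS-DA fit.
#' @return Data frame with columns `feature_id` (+ `mz`, `rt` if given),
#'   `log2fc`, `vip`, `p`, `q`.
#' @export
lipid_stat_table <- function(ft, annotation = NULL, n_ortho = 1) {
  idx <- split_groups(ft)
  pp <- preprocess(ft, log_base = 2, scaling = "autoscale")
  fit <- oplsda(pp, scale = FALSE, n_ortho = n_ortho)
  vip <- vip_scores(fit)
  logv <- log2(ft$values[, colnames(pp$values), drop = FALSE])
  log2fc <- colMeans(logv[idx$case, , drop = FALSE]) -
    colMeans(logv[idx$control, , drop = FALSE])
  p <- vapply(seq_len(ncol(logv)), function(j)
    two_sample_t(logv[idx$case, j], logv[idx$control, j])$p, 0.0)
  out <- data.frame(feature_id = colnames(logv), log2fc = unname(log2fc),
                    vip = unname(vip), p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation))
    out <- merge(annotation, out, by = "feature_id", sort = FALSE)
  out
}

#' Comorbidity-free subset
#'
#' Drops every sample with type 2 diabetes, hypertension or obesity.
#' Missing comorbidity flags are an error — they must not be silently
#' treated as absent disease.
#'
#' @param metadata metadata data frame with logical `t2d`,
#'   `hypertension`, `obesity` columns.
#' @return List with `case` and `control` character vectors of retained
#'   sample ids.
#' @export
comorbidity_free_subset <- function(metadata) {
  flags <- metadata[, c("t2d", "hypertension", "obesity")]
  if (anyNA(flags))
    stop("comorbidity flags contain missing values; cannot subset")
  free <- !(flags$t2d | flags$hypertension | flags$obesity)
  list(case = metadata$sample_id[free & metadata$group == "case"],
       control = metadata$sample_id[free & metadata$group == "control"])
}

#' PCA score-coefficient weighting of differential lipids
#'
#' The panel-weighting procedure: autoscale the retained lipids, run
#' correlation-matrix PCA, keep components with eigenvalue strictly above
#' `eigen_min`, form score coefficients `c_ij = loading_ij / sqrt(lambda_j)`,
#' average their absolute values across retained components weighted by
#' the components' variance-explained shares, and normalize to weights
#' summing to 1. Absolute coefficients are used because loadings carry
#' arbitrary signs while the published coefficients are all positive.
#'
#' @param ft a [feature_table()] restricted to the retained lipids (raw
#'   abundances; log2 + autoscale applied internally).
#' @param eigen_min eigenvalue retention cutoff (strict >; default 1).
#' @param log_base log transform applied before scaling (default 2;
#'   `"none"` if `ft` is already preprocessed).
#' @return Object of class `panel_weighting`: `retained_components`,
#'   `eigenvalues`, `loadings`, `coefficients` (named, per lipid),
#'   `weights` (named, sum 1), and the source `pca` fit.
#' @export
pca_weighting <- function(ft, eigen_min = 1, log_base = 2) {
  if (ncol(ft$values) < 2) stop("need >= 2 lipids for weighting")
  pp <- preprocess(ft, log_base = log_base, scaling = "autoscale")
  pca <- pca_fit(pp, use_correlation = TRUE)
  keep <- which(pca$eigenvalues > eigen_min)
  if (!length(keep))
    stop("no component has eigenvalue > ", eigen_min,
         "; reduce eigen_min")
  lam <- pca$eigenvalues[keep]
  ve <- lam / sum(pca$eigenvalues)
  coefs <- sweep(pca$loadings[, keep, drop = FALSE], 2, sqrt(lam), `/`)
  coefficient <- drop(abs(coefs) %*% ve) / sum(ve)
  weights <- coefficient / sum(coefficient)
  message(sprintf(
    "pca_weighting: %d component(s) with eigenvalue > %g retained (%.1f%% of variance)",
    length(keep), eigen_min, 100 * sum(ve)))
  structure(list(retained_components = keep,
                 eigenvalues = pca$eigenvalues,
                 loadings = pca$loadings[, keep, drop = FALSE],
                 score_coefficients = coefs,
                 coefficients = coefficient,
                 weights = weights, pca = pca),
            class = "panel_weighting")
}

#' @export
print.panel_weighting <- function(x, ...) {
  cat(sprintf("panel_weighting: %d lipids, %d retained component(s)\n",
              length(x$weights), length(x$retained_components)))
  ord <- order(x$weights, decreasing = TRUE)
  df <- data.frame(coefficient = round(x$coefficients[ord], 4),
                   weight = round(x$weights[ord], 4))
  print(utils::head(df, 10))
  if (length(ord) > 10) cat("  ...\n")
  invisible(x)
}

#' Select the top-weighted diagnostic panel
#'
#' Top `k` lipids by weight, ties broken lexicographically by feature id
#' (logged); reports the panel's cumulative share of total weight as a
#' percentage.
#'
#' @param weighting a [pca_weighting()] result, or a data frame with
#'   columns `feature_id` and `weight` (e.g. [is_panel_weights()]).
#' @param k panel size (default 5).
#' @return List of class `lipid_panel`: `panel` (feature ids, weight
#'   descending), `weights` (their weights), `cumulative_weight_pct`.
#' @examples
#' select_panel(is_panel_weights())$panel
#' @export
select_panel <- function(weighting, k = 5) {
  w <- if (inherits(weighting, "panel_weighting")) weighting$weights
       else stats::setNames(weighting$weight, weighting$feature_id)
  if (k > length(w)) stop("k exceeds the number of lipids")
  ord <- order(-w, names(w))   # weight desc, feature id asc on ties
  if (anyDuplicated(w[ord][seq_len(min(k + 1, length(w)))]))
    message("select_panel: tied weights broken by feature id")
  sel <- ord[seq_len(k)]
  structure(list(panel = names(w)[sel], weights = w[sel],
                 cumulative_weight_pct = 100 * sum(w[sel]) / sum(w)),
            class = "lipid_panel")
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat(sprintf("lipid_panel: %d lipids, %.3f%% of total weight\n",
              length(x$panel), x$cumulative_weight_pct))
  print(round(x$weights, 4))
  invisible(x)
}

#' Composite diagnostic score
#'
#' Weighted sum of autoscaled log2 abundances over the panel lipids,
#' `score_s = sum_i weight_i d_i z_i(s)` (scaling parameters from the
#' full cohort). The weights quantify importance, not direction, so by
#' default each lipid enters with its case-like orientation
#' `d_i = sign(case mean z_i - control mean z_i)` (equivalently the sign
#' of its log2 fold change); otherwise lipids dysregulated in opposite
#' directions cancel. `orient = "global"` instead applies a single sign
#' flip to the whole score when the case mean falls below the control
#' mean. `method = "logistic"` replaces the weighted sum with the linear
#' predictor of a logistic regression of group on the panel z-scores.
#'
#' @param ft a grouped [feature_table()] of raw abundances containing the
#'   panel features.
#' @param weights named weight vector (e.g. `select_panel()$weights`).
#' @param panel feature ids to combine; default `names(weights)`.
#' @param orient `"per_lipid"` (default) or `"global"`; ignored for the
#'   logistic method. Requires group labels; an ungrouped table gets the
#'   raw (unoriented) weighted sum with a warning.
#' @param method `"weighted"` (default) or `"logistic"`.
#' @param log_base log transform before scaling (default 2; `"none"` if
#'   `ft` is already preprocessed).
#' @return Named numeric vector of per-sample scores (higher = more
#'   case-like).
#' @export
composite_score <- function(ft, weights, panel = names(weights),
                            orient = c("per_lipid", "global"),
                            method = c("weighted", "logistic"),
                            log_base = 2) {
  orient <- match.arg(orient)
  method <- match.arg(method)
  miss <- setdiff(panel, ft$feature_ids)
  if (length(miss))
    stop("panel feature(s) absent from table: ", paste(miss, collapse = ", "))
  pp <- preprocess(ft[, panel], log_base = log_base, scaling = "autoscale")
  z <- pp$values[, panel, drop = FALSE]
  if (method == "logistic") {
    if (is.null(ft$group)) stop("logistic scoring needs group labels")
    gfit <- stats::glm.fit(cbind(1, z),
                           as.numeric(ft$group == "case"),
                           family = stats::binomial())
    return(stats::setNames(drop(cbind(1, z) %*% gfit$coefficients),
                           ft$sample_ids))
  }
  if (is.null(ft$group)) {
    warning("no group labels: returning the unoriented weighted sum")
    return(stats::setNames(drop(z %*% weights[panel]), ft$sample_ids))
  }
  idx <- split_groups(ft)
  if (orient == "per_lipid") {
    d <- sign(colMeans(z[idx$case, , drop = FALSE]) -
                colMeans(z[idx$control, , drop = FALSE]))
    d[d == 0] <- 1
    if (any(d < 0))
      message("composite_score: ", sum(d < 0),
              " lipid(s) entered with negative (control-high) orientation")
    score <- drop(z %*% (weights[panel] * d))
  } else {
    score <- drop(z %*% weights[panel])
  }
  if (mean(score[idx$case]) < mean(score[idx$control])) {
    message("composite_score: sign flipped so cases score higher")
    score <- -score
  }
  stats::setNames(score, ft$sample_ids)
}

# ---- ROC ---------------------------------------------------------------

# rank (Mann-Whitney) AUC with ties counted 1/2
rank_auc <- function(scores, is_case) {
  r <- rank(scores)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC via placement values
delong_var <- function(scores, is_case) {
  x <- scores[is_case]; y <- scores[!is_case]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(a) mean(psi(a, y)), 0.0)
  v01 <- vapply(y, function(b) mean(psi(x, b)), 0.0)
  stats::var(v10) / m + stats::var(v01) / n
}

#' ROC evaluation of a diagnostic score
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted 1/2;
#' 95% CI by DeLong (default) or a stratified bootstrap; operating point
#' at the threshold maximizing the Youden index J = Se + Sp - 1 (ties go
#' to the lowest threshold; a sample is called a case when
#' `score >= threshold`).
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels two-class labels; `"case"`/first level = positive.
#' @param ci `"delong"` or `"bootstrap"`.
#' @param seed RNG seed (bootstrap CI only).
#' @param n_boot bootstrap replicates.
#' @return Object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `threshold`, `sensitivity`, `specificity`, `youden`, and `curve`
#'   (data frame `threshold`, `fpr`, `tpr`).
#' @export
roc_evaluate <- function(scores, labels, ci = c("delong", "bootstrap"),
                         seed = 1L, n_boot = 2000) {
  ci <- match.arg(ci)
  if (any(!is.finite(scores))) stop("scores must be finite")
  lab <- if (is.factor(labels)) labels else
    factor(labels, levels = if (all(labels %in% c("case", "control")))
      c("case", "control") else sort(unique(labels)))
  if (nlevels(droplevels(lab)) != 2)
    stop("both classes must be present")
  is_case <- lab == levels(lab)[1]
  auc <- rank_auc(scores, is_case)
  if (ci == "delong") {
    se <- sqrt(delong_var(scores, is_case))
    zc <- stats::qnorm(0.975)
    ci_low <- max(0, auc - zc * se)
    ci_high <- min(1, auc + zc * se)
  } else {
    set.seed(seed)
    i1 <- which(is_case); i0 <- which(!is_case)
    boot <- replicate(n_boot, {
      b <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      rank_auc(scores[b], is_case[b])
    })
    qs <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    ci_low <- qs[1]; ci_high <- qs[2]
  }
  # candidate thresholds: every distinct score (call case when >= thr)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(h) mean(scores[is_case] >= h), 0.0)
  spec <- vapply(thr, function(h) mean(scores[!is_case] < h), 0.0)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]   # sorted ascending -> lowest threshold
  curve <- data.frame(threshold = c(-Inf, thr),
                      fpr = c(1, 1 - spec), tpr = c(1, sens))
  structure(list(auc = auc,
                 ci_low = min(ci_low, auc), ci_high = max(ci_high, auc),
                 ci_method = ci,
                 threshold = thr[best], sensitivity = sens[best],
                 specificity = spec[best],
                 youden = sens[best] + spec[best] - 1,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method))
  cat(sprintf("  Youden-optimal threshold %.4g: Se = %.1f%%, Sp = %.1f%%, J = %.3f\n",
              x$threshold, 100 * x$sensitivity, 100 * x$specificity,
              x$youden))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright",
                   legend = sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Youden index from an operating point
#'
#' `J = sensitivity + specificity - 1`, exactly.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return J in \[-1, 1\].
#' @examples
#' youden_index(0.600, 0.967)  # 0.567
#' @export
youden_index <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  sensitivity + specificity - 1
}

#' End-to-end panel discovery on a cohort
#'
#' Runs the full pipeline on one grouped feature table: per-lipid
#' statistics, three-criterion filter, PCA weighting of the retained
#' lipids, top-k panel selection, composite score, and ROC evaluation.
#'
#' @param ft a grouped [feature_table()] of raw abundances.
#' @param config thresholds from [default_config()] / [read_config()].
#' @param abs_log2fc_min fold-change cutoff (`NA` disables; defaults to
#'   `config$abs_log2fc`).
#' @return List of class `panel_pipeline`: `stats`, `retained`,
#'   `weighting`, `panel`, `scores`, `roc`.
#' @export
discover_panel <- function(ft, config = default_config(),
                           abs_log2fc_min = config$abs_log2fc) {
  stats_tab <- lipid_stat_table(ft)
  retained <- differential_filter(stats_tab, vip_min = config$vip,
                                  p_max = config$p,
                                  abs_log2fc_min = abs_log2fc_min)
  if (nrow(retained) < 2)
    stop("fewer than 2 lipids pass the filter; cannot weight a panel")
  weighting <- pca_weighting(ft[, retained$feature_id],
                             eigen_min = config$eigen_min)
  panel <- select_panel(weighting, k = min(config$panel_size,
                                           nrow(retained)))
  scores <- composite_score(ft, panel$weights)
  roc <- roc_evaluate(scores, ft$group)
  structure(list(stats = stats_tab, retained = retained,
                 weighting = weighting, panel = panel, scores = scores,
                 roc = roc),
            class = "panel_pipeline")
}

#' @export
print.panel_pipeline <- function(x, ...) {
  cat(sprintf("panel_pipeline: %d lipids -> %d retained -> %d-lipid panel\n",
              nrow(x$stats), nrow(x$retained), length(x$panel$panel)))
  cat("  panel:", paste(x$panel$panel, collapse = ", "), "\n")
  print(x$roc)
  invisible(x)
}
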