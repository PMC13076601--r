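test_that("differential filter applies strict criteria in both stages", {
  rec <- data.frame(feature_id = c("a", "b", "c"),
                    log2fc = c(1.2, 2.0, 0.9),
                    vip = c(1.5, 1.0, 1.5),
                    p = c(0.01, 0.01, 0.01))
  out <- suppressMessages(differential_filter(rec))
  expect_equal(out$feature_id, "a")   # b: vip == 1 excluded; c: |fc| < 1

  # validation-stage mode: fold-change criterion disabled
  out2 <- suppressMessages(differential_filter(rec, abs_log2fc_min = NA))
  expect_equal(out2$feature_id, c("a", "c"))

  # order preserved
  rec3 <- rec[c(3, 1, 2), ]
  out3 <- suppressMessages(differential_filter(rec3, abs_log2fc_min = NA))
  expect_equal(out3$feature_id, c("c", "a"))
})

test_that("comorbidity-free subsetting drops any-comorbidity samples and rejects missing flags", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   group = factor(rep(c("case", "control"), each = 3),
                                  levels = c("case", "control")),
                   t2d = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   hypertension = FALSE,
                   obesity = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  sub <- comorbidity_free_subset(md)
  expect_equal(sub$case, c("s1", "s3"))
  expect_equal(sub$control, c("s5", "s6"))   # s4: obesity only -> excluded

  md$t2d[1] <- NA
  expect_error(comorbidity_free_subset(md), "missing")

  # synthetic cohort at the published comorbidity-free fractions
  spec <- cohort_spec(n_case = 251, n_control = 251, seed = 17)
  sub2 <- comorbidity_free_subset(simulate_covariates(spec))
  p1 <- 111 / 251; p2 <- 213 / 251
  expect_lt(abs(length(sub2$case) - 111), 3 * sqrt(251 * p1 * (1 - p1)))
  expect_lt(abs(length(sub2$control) - 213), 3 * sqrt(251 * p2 * (1 - p2)))
})

test_that("PCA weighting follows the stated formula and its symmetries", {
  # brute-force formula oracle on a correlated-block fixture
  set.seed(23)
  n <- 60
  block <- matrix(rnorm(n), n, 6) * 0.9 + matrix(rnorm(n * 6), n, 6) * 0.45
  rest <- matrix(rnorm(n * 9), n, 9)
  m <- 2^(cbind(block, rest) + 12)
  colnames(m) <- sprintf("L%02d", 1:15)
  ft <- feature_table(m)
  w <- suppressMessages(pca_weighting(ft))

  z <- scale(log2(m))
  ed <- eigen(cor(z))
  keep <- which(ed$values > 1)
  lam <- ed$values[keep]
  load <- ed$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), length(lam))
  coefs <- abs(load %*% diag(1 / sqrt(lam), length(lam)))
  ve <- lam / sum(ed$values)
  coef_oracle <- drop(coefs %*% ve) / sum(ve)
  w_oracle <- coef_oracle / sum(coef_oracle)
  expect_equal(unname(w$weights), w_oracle, tolerance = 1e-8)
  expect_equal(w$retained_components, keep)
  # the correlated block occupies the top weight ranks
  expect_true(all(sprintf("L%02d", 1:6) %in%
                    names(sort(w$weights, decreasing = TRUE))[1:6]))

  # weights sum to 1; permuting lipid order permutes weights identically
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  perm <- sample(15)
  w2 <- suppressMessages(pca_weighting(ft[, perm]))
  expect_equal(w2$weights[names(w$weights)], w$weights, tolerance = 1e-9)

  # two independent equal blocks: block-symmetric weights
  set.seed(24)
  b1 <- matrix(rnorm(n), n, 3) + matrix(rnorm(n * 3), n, 3) * 0.5
  b2 <- matrix(rnorm(n), n, 3) + matrix(rnorm(n * 3), n, 3) * 0.5
  ms <- 2^(cbind(b1, b2) + 10)
  colnames(ms) <- paste0("B", 1:6)
  ws <- suppressMessages(pca_weighting(feature_table(ms)))
  expect_lt(abs(sum(ws$weights[1:3]) - sum(ws$weights[4:6])), 0.12)

  # single retained component: weights proportional to |loading|
  one <- matrix(rnorm(n), n, 4) + matrix(rnorm(n * 4), n, 4) * 0.3
  mo <- 2^(one + 10); colnames(mo) <- paste0("S", 1:4)
  wo <- suppressMessages(pca_weighting(feature_table(mo)))
  if (length(wo$retained_components) == 1) {
    l1 <- abs(wo$loadings[, 1])
    expect_equal(unname(wo$weights), unname(l1 / sum(l1)), tolerance = 1e-9)
  }
  expect_error(suppressMessages(
    pca_weighting(feature_table(mo), eigen_min = 100)), "eigen_min")
})

test_that("panel selection reproduces the published five lipids and its arithmetic", {
  sel <- select_panel(is_panel_weights(), k = 5)
  expect_equal(sel$panel,
               c("PE(P-18:1/22:4)", "PE(16:0/16:1)", "TAG48:3-FA16:1",
                 "DAG(18:2/20:4)", "PE(P-18:0/22:6)"))

  w <- data.frame(feature_id = c("a", "b", "c", "d"),
                  weight = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(select_panel(w, k = 2)$cumulative_weight_pct, 70)
  expect_equal(select_panel(w, k = 4)$cumulative_weight_pct, 100)
  expect_error(select_panel(w, k = 5), "exceeds")

  # deterministic lexicographic tie-break
  wt <- data.frame(feature_id = c("zed", "alpha", "mid"),
                   weight = c(0.4, 0.3, 0.3))
  expect_equal(suppressMessages(select_panel(wt, k = 2))$panel,
               c("zed", "alpha"))
})

test_that("composite score reduces correctly in simple cases", {
  ft <- random_table(10, 10, 4, seed = 30)
  z <- scale(log2(ft$values))

  # single-lipid panel with weight 1: the score is that lipid's z (up to sign)
  w1 <- c(f01 = 1)
  s1 <- suppressMessages(composite_score(ft, w1))
  expect_true(max(abs(s1 - z[, "f01"])) < 1e-12 ||
                max(abs(s1 + z[, "f01"])) < 1e-12)

  # equal weights, same orientation: mean z across the panel (up to sign)
  ftc <- ft
  ftc$values[ftc$group == "case", ] <- ftc$values[ftc$group == "case", ] * 4
  zc <- scale(log2(ftc$values))
  weq <- setNames(rep(0.25, 4), colnames(ftc$values))
  se <- suppressMessages(composite_score(ftc, weq))
  expect_equal(unname(se), unname(rowMeans(zc) * 0.25 * 4), tolerance = 1e-12)

  # mixed-direction lipids: per-lipid orientation beats the global flip
  set.seed(31)
  n <- 100
  up <- c(rnorm(n, 1), rnorm(n, 0)); dn <- c(rnorm(n, -1), rnorm(n, 0))
  m <- 2^(cbind(up = up, dn = dn) + 10)
  ftm <- feature_table(m, group = rep(c("case", "control"), each = n))
  wmix <- c(up = 0.5, dn = 0.5)
  s_per <- suppressMessages(composite_score(ftm, wmix))
  s_glo <- suppressMessages(composite_score(ftm, wmix, orient = "global"))
  auc_per <- roc_evaluate(s_per, ftm$group)$auc
  auc_glo <- roc_evaluate(s_glo, ftm$group)$auc
  expect_gt(auc_per, auc_glo)
  expect_gt(auc_per, 0.8)

  expect_error(suppressMessages(composite_score(ft, c(nope = 1))), "absent")
})

test_that("ROC evaluation matches the Mann-Whitney identity and pROC", {
  set.seed(33)
  for (s in 1:5) {
    sc <- rnorm(40) + rep(c(s / 3, 0), each = 20)
    lab <- rep(c("case", "control"), each = 20)
    r <- roc_evaluate(sc, lab)
    u <- unname(wilcox.test(sc[1:20], sc[21:40], exact = FALSE)$statistic)
    expect_equal(r$auc, u / 400, tolerance = 1e-12)
    pr <- pROC::roc(lab, sc, levels = c("control", "case"),
                    direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(c(r$ci_low, r$ci_high), ci[c(1, 3)], tolerance = 1e-6)
  }

  # perfect separation
  rp <- roc_evaluate(c(5, 6, 7, 1, 2, 3), rep(c("case", "control"), each = 3))
  expect_equal(rp$auc, 1)
  expect_equal(rp$youden, 1)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)

  # invariance under strictly increasing transforms
  set.seed(34)
  sc <- rnorm(30); lab <- rep(c("case", "control"), 15)
  r1 <- roc_evaluate(sc, lab)
  r2 <- roc_evaluate(exp(sc), lab)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$sensitivity, r2$sensitivity)
  expect_equal(r1$youden, r2$youden)

  # Youden identity holds exactly at the chosen operating point
  expect_equal(r1$youden, r1$sensitivity + r1$specificity - 1)
  expect_error(roc_evaluate(1:4, rep("case", 4)), "both classes")
})

test_that("DeLong CI covers the null AUC at the nominal rate", {
  set.seed(35)
  cover <- vapply(1:300, function(i) {
    sc <- rnorm(60)
    r <- roc_evaluate(sc, rep(c("case", "control"), 30))
    r$ci_low <= 0.5 && 0.5 <= r$ci_high
  }, TRUE)
  expect_gt(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("the full pipeline discovers the planted panel end to end, reproducibly", {
  spec <- cohort_spec(n_case = 251, n_control = 251, seed = 11)
  study <- simulate_lipidomics(spec)
  res <- suppressMessages(discover_panel(study$feature_table))
  expect_equal(length(res$panel$panel), 5L)
  expect_true(all(res$panel$panel %in%
                    study$truth$feature_id[study$truth$differential]))
  expect_gt(res$roc$auc, 0.8)

  # bit-reproducible under the same spec
  res2 <- suppressMessages(
    discover_panel(simulate_lipidomics(spec)$feature_table))
  expect_identical(res$scores, res2$scores)
  expect_identical(res$roc$auc, res2$roc$auc)
})
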