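test_that("cohort simulation is reproducible and respects the null model", {
  spec <- cohort_spec(seed = 4)
  a <- simulate_lipidomics(spec)
  b <- simulate_lipidomics(spec)
  expect_identical(a$feature_table$values, b$feature_table$values)
  expect_identical(a$metadata, b$metadata)

  # default spec plants exactly the 19 published differential lipids
  expect_equal(sum(a$truth$differential), 19L)
  expect_equal(nrow(a$truth), 158L)

  # all-null spec: every group-mean log2 difference within 3 sigma / sqrt(n)
  null_spec <- cohort_spec(
    n_case = 40, n_control = 40,
    effect_table = data.frame(feature_id = paste0("f", 1:10), log2fc = 0),
    n_null_features = 0, block_structure = list(), seed = 8)
  s <- simulate_lipidomics(null_spec)
  lg <- log2(s$feature_table$values)
  d <- colMeans(lg[s$feature_table$group == "case", ]) -
    colMeans(lg[s$feature_table$group == "control", ])
  expect_true(all(abs(d) < 3 * null_spec$sigma_log * sqrt(2 / 40)))
})

test_that("planted log2 fold changes are recovered empirically", {
  spec <- cohort_spec(
    n_case = 50, n_control = 50,
    effect_table = data.frame(feature_id = "hit", log2fc = 3),
    n_null_features = 4, block_structure = list(),
    sigma_log = 0.2, seed = 13)
  s <- simulate_lipidomics(spec)
  lg <- log2(s$feature_table$values)
  fc <- mean(lg[s$feature_table$group == "case", "hit"]) -
    mean(lg[s$feature_table$group == "control", "hit"])
  expect_gt(fc, 2.5)
  expect_lt(fc, 3.5)
})

test_that("block correlation structure is realised and non-PSD blocks are rejected", {
  spec <- cohort_spec(n_case = 300, n_control = 300, seed = 2)
  s <- simulate_lipidomics(spec)
  lg <- log2(s$feature_table$values)
  # residual (within-group) correlations: remove the group mean shift
  res <- rbind(scale(lg[s$feature_table$group == "case", ], scale = FALSE),
               scale(lg[s$feature_table$group == "control", ], scale = FALSE))
  pe <- grep("^PE\\(P-", colnames(lg), value = TRUE)
  dag <- grep("^DAG\\(", colnames(lg), value = TRUE)
  pe_cor <- cor(res[, pe])
  expect_gt(mean(pe_cor[upper.tri(pe_cor)]), 0.4)
  cross <- cor(res[, pe], res[, dag])
  expect_lt(mean(cross), -0.2)
  nul <- cor(res[, grep("NULL", colnames(lg))[1:10]])
  expect_lt(max(abs(nul[upper.tri(nul)])), 0.3)

  # within-block 0.2 but cross-block 0.9 is impossible (e.g. the contrast
  # (1,1,-1,-1) has negative variance)
  bad <- list(list(features = c("a", "b"), rho = 0.2),
              list(features = c("c", "d"), rho = 0.2),
              list(between = c(1L, 2L), rho = 0.9))
  expect_error(
    cohort_spec(effect_table = data.frame(feature_id = letters[1:4],
                                          log2fc = 0),
                n_null_features = 0, block_structure = bad),
    "positive semi-definite")
})

test_that("covariates match the published prevalences and summaries", {
  # certainty case: prevalence 1 for t2d among cases
  pr <- is_comorbidity_rates()
  pr$case$t2d <- 1; pr$case$comorbidity_free <- 0
  md <- simulate_covariates(cohort_spec(n_case = 40, n_control = 40,
                                        covariate_prevalences = pr,
                                        seed = 3))
  expect_true(all(md$t2d[md$group == "case"]))

  # binomial moments at the published rates, 500 Monte-Carlo replicates
  spec <- cohort_spec(n_case = 251, n_control = 251, seed = 1)
  counts <- vapply(1:500, function(i) {
    spec$seed <- i
    m <- simulate_covariates(spec)
    c(t2d = sum(m$t2d[m$group == "case"]),
      free_case = sum(!(m$t2d | m$hypertension | m$obesity) &
                        m$group == "case"),
      free_ctrl = sum(!(m$t2d | m$hypertension | m$obesity) &
                        m$group == "control"))
  }, c(0, 0, 0))
  p <- 70 / 251
  expect_lt(abs(mean(counts["t2d", ]) - 70), 3 * sqrt(251 * p * (1 - p)))
  expect_lt(abs(mean(counts["free_case", ]) - 111), 3)
  expect_lt(abs(mean(counts["free_ctrl", ]) - 213), 3)

  # conventional lipids centered on the published means
  tc_means <- vapply(1:200, function(i) {
    spec$seed <- i
    m <- simulate_covariates(spec)
    mean(m$tc[m$group == "case"])
  }, 0)
  expect_lt(abs(mean(tc_means) - 4.82), 0.05)
})

test_that("missingness injection and batch shift behave as designed", {
  ft <- random_table(5, 5, 10, seed = 6)
  # identity when rates are zero
  out <- inject_missing_and_batch(ft, 0, 0, seed = 1)
  expect_identical(out$feature_table$values, ft$values)

  # binomial bound on injected NAs: 20 +/- 12 cells on a 10x10 table
  nmiss <- vapply(1:30, function(s)
    sum(is.na(inject_missing_and_batch(ft, 0.2, 0, seed = s
    )$feature_table$values)), 0)
  expect_true(all(nmiss >= 8 & nmiss <= 32))

  # a +2 log2 shift moves batch means by ~2; batch_adjust removes it
  out <- inject_missing_and_batch(ft, 0, 2, seed = 1)
  lg <- t(log2(out$feature_table$values))       # genes x samples
  before <- rowMeans(lg[, out$batch == "b2"]) -
    rowMeans(lg[, out$batch == "b1"])
  adj <- batch_adjust(lg, out$batch)
  after <- rowMeans(adj[, out$batch == "b2"]) -
    rowMeans(adj[, out$batch == "b1"])
  expect_equal(mean(before), 2, tolerance = 0.5)
  expect_lt(max(abs(after)), 1e-10)

  expect_error(inject_missing_and_batch(ft, 1.0), "missing_rate")
})

test_that("planted effects at the published magnitudes are recovered by the filter", {
  # aggregate sensitivity/FPR of the three-criterion filter over
  # discovery-sized replicates (n = 15/15, sigma_log = 0.5)
  n_rep <- 60
  hits <- fps <- 0; n_hit_possible <- n_fp_possible <- 0
  for (r in seq_len(n_rep)) {
    s <- simulate_lipidomics(cohort_spec(seed = 1000 + r))
    tab <- suppressMessages(lipid_stat_table(s$feature_table))
    ret <- suppressMessages(differential_filter(tab))$feature_id
    truth <- s$truth
    hits <- hits + sum(truth$feature_id[truth$differential] %in% ret)
    fps <- fps + sum(truth$feature_id[!truth$differential] %in% ret)
    n_hit_possible <- n_hit_possible + sum(truth$differential)
    n_fp_possible <- n_fp_possible + sum(!truth$differential)
  }
  expect_gte(hits / n_hit_possible, 0.7)
  expect_lte(fps / n_fp_possible, 0.1)
})

test_that("expression simulator supports the screen power and batch-efficacy checks", {
  # null: the joint threshold retains ~0 genes
  sim0 <- simulate_expression(15, 15, 1000, de_fraction = 0, seed = 5)
  deg0 <- suppressMessages(
    deg_filter(moderated_t(sim0$matrix, sim0$groups)))
  expect_lt(deg0$n_up + deg0$n_down, 10)

  # power: planted effect 2 at n = 30/30 recovered with sensitivity > 0.8
  sim1 <- simulate_expression(30, 30, 1000, de_fraction = 0.1, effect = 2,
                              seed = 6)
  deg1 <- suppressMessages(
    deg_filter(moderated_t(sim1$matrix, sim1$groups)))
  found <- c(deg1$up$gene, deg1$down$gene)
  expect_gt(mean(sim1$truth$gene[sim1$truth$de] %in% found), 0.8)

  # batch efficacy: confounding-free offset 3, DEG count within 10% of
  # the no-batch run after adjustment
  simb <- simulate_expression(30, 30, 1000, de_fraction = 0.1, effect = 2,
                              batch_design = list(offset = 3, fraction = 0.5),
                              seed = 6)
  adj <- batch_adjust(simb$matrix, simb$batch)
  degb <- suppressMessages(deg_filter(moderated_t(adj, simb$groups)))
  n_ref <- deg1$n_up + deg1$n_down
  n_adj <- degb$n_up + degb$n_down
  expect_lt(abs(n_adj - n_ref) / n_ref, 0.1)
})
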