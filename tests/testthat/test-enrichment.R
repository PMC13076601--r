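test_that("batch adjustment removes location-scale batch structure", {
  set.seed(1)
  m <- matrix(rnorm(50 * 12, mean = 8), 50, 12)
  batch <- rep(c("b1", "b2"), each = 6)

  # single batch: identity up to floating error
  expect_equal(batch_adjust(m, rep("b1", 12)), m)

  # constant per-gene offset: batch means equalized to ~1e-10
  m2 <- m; m2[, batch == "b2"] <- m2[, batch == "b2"] + 3
  adj <- batch_adjust(m2, batch)
  dmeans <- rowMeans(adj[, batch == "b2"]) - rowMeans(adj[, batch == "b1"])
  expect_lt(max(abs(dmeans)), 1e-10)

  # simulated batch offset: residual between-batch variance fraction < 1%
  sim <- simulate_expression(12, 12, 300, de_fraction = 0,
                             batch_design = list(offset = 3, fraction = 0.5),
                             seed = 3)
  adj2 <- batch_adjust(sim$matrix, sim$batch)
  frac <- vapply(seq_len(nrow(adj2)), function(g) {
    fit <- anova(lm(adj2[g, ] ~ sim$batch))
    fit$`Sum Sq`[1] / sum(fit$`Sum Sq`)
  }, 0)
  expect_lt(max(frac), 0.01)

  # zero-variance block: centered only, with a warning
  m3 <- m; m3[1, batch == "b2"] <- 5
  expect_warning(batch_adjust(m3, batch), "zero variance")
})

test_that("moderated t has the right limits and matches limma", {
  sim <- simulate_expression(8, 8, 400, de_fraction = 0.05, effect = 1.5,
                             seed = 4)
  m <- sim$matrix; g <- sim$groups

  # d0 = 0: ordinary two-sample t for every gene
  r0 <- moderated_t(m, g, d0 = 0)
  t_ord <- apply(m, 1, function(x)
    t.test(x[g == "case"], x[g == "control"], var.equal = TRUE)$statistic)
  expect_equal(r0$t_mod, unname(t_ord), tolerance = 1e-10)

  # d0 = Inf: every gene shrunk fully to s0^2
  rI <- moderated_t(m, g, d0 = Inf)
  se_implied <- r0$log2fc / rI$t_mod
  expect_lt(diff(range(se_implied^2)), 1e-10)

  # estimated prior agrees with limma's empirical Bayes fit
  rE <- moderated_t(m, g)
  design <- model.matrix(~ 0 + g)
  colnames(design) <- c("case", "control")
  lfit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(m, design),
    limma::makeContrasts(case - control, levels = design)))
  # limma's fitFDist differs from plain moment matching in small-sample
  # corrections; agreement is close but not exact
  expect_equal(attr(rE, "d0"), lfit$df.prior, tolerance = 0.05)
  expect_equal(attr(rE, "s0_sq"), lfit$s2.prior, tolerance = 0.02)
  expect_equal(rE$t_mod, unname(lfit$t[, 1]), tolerance = 0.02)
  expect_gt(cor(rE$p, lfit$p.value[, 1]), 0.999)

  # equal residual variances: moderated ranks equal ordinary-t ranks.
  # force every gene's pooled sample variance to exactly 1 by rescaling
  # within-group residuals, then compare orderings.
  meq <- m
  for (gi in seq_len(nrow(meq))) {
    for (lv in levels(g)) {
      cols <- g == lv
      meq[gi, cols] <- scale(m[gi, cols])[, 1] + mean(m[gi, cols])
    }
  }
  req <- moderated_t(meq, g)
  teq <- apply(meq, 1, function(x)
    t.test(x[g == "case"], x[g == "control"], var.equal = TRUE)$statistic)
  expect_equal(order(abs(req$t_mod)), order(abs(teq)))

  # null type-I calibration under the estimated prior
  sim0 <- simulate_expression(10, 10, 2000, de_fraction = 0, seed = 5)
  p0 <- moderated_t(sim0$matrix, sim0$groups)$p
  expect_gt(mean(p0 < 0.05), 0.035)
  expect_lt(mean(p0 < 0.05), 0.065)

  # direction consistent with the fold-change sign
  expect_true(all((rE$log2fc >= 0) == (rE$direction == "up")))
})

test_that("DEG filter applies strict joint thresholds", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.2, 1.0, -1.4, -0.5),
                    t_mod = 0, p = c(0.04, 0.04, 0.002, 0.001),
                    direction = c("up", "up", "down", "down"))
  out <- suppressMessages(deg_filter(rec))
  expect_equal(out$up$gene, "a")          # b excluded: log2fc == 1 (strict)
  expect_equal(out$down$gene, "c")
  expect_equal(out$n_up + out$n_down, 2L)
})

test_that("GSEA running sum matches brute force and its symmetries", {
  scores <- sort(setNames(c(5, 4, 3, 2, 1, -1, -2, -3),
                          paste0("g", 1:8)), decreasing = TRUE)
  gs <- c("g1", "g2", "g3")          # extreme top concentration
  r <- gsea_preranked(scores, gs, n_perm = 200, seed = 1)
  expect_gt(r$es, 0)
  expect_equal(r$es, gsea_es_brute(scores, 1:3), tolerance = 1e-12)
  expect_equal(sort(r$leading_edge), sort(gs))

  # ES bounded in [-1, 1] and negated by reversing the ranked list
  for (s in 1:6) {
    set.seed(s)
    sc <- setNames(rnorm(30), paste0("x", 1:30))
    set <- sample(names(sc), 6)
    a <- gsea_preranked(sc, set, n_perm = 50, seed = s)
    b <- gsea_preranked(-sc, set, n_perm = 50, seed = s)
    expect_lte(abs(a$es), 1)
    expect_equal(b$es, -a$es, tolerance = 1e-12)
    expect_equal(sign(a$nes), sign(a$es))
  }

  # weight_exp = 0: invariant to monotone rescaling of the scores
  sc <- setNames(c(9, 7, 5, 3, 2, 1.5, 1, 0.5), paste0("g", 1:8))
  set <- c("g2", "g5", "g7")
  e1 <- gsea_preranked(sc, set, weight_exp = 0, n_perm = 30, seed = 2)
  e2 <- gsea_preranked(exp(sc), set, weight_exp = 0, n_perm = 30, seed = 2)
  expect_equal(e1$es, e2$es, tolerance = 1e-12)

  # overlap below 3 genes is skipped with a warning
  expect_warning(expect_null(
    gsea_preranked(sc, c("g1", "g2"), n_perm = 10, seed = 1)), "skipped")
})

test_that("exact GSEA permutation p equals exhaustive enumeration over all 56 subsets", {
  scores <- setNames(c(3.2, 2.5, 1.9, 1.2, 0.4, -0.8, -1.6, -2.9),
                     paste0("g", 1:8))
  gs <- c("g1", "g3", "g4")
  r <- gsea_preranked(scores, gs, exact = TRUE)
  expect_equal(r$n_perm, choose(8, 3))

  # independent enumeration with the brute-force running sum
  sorted <- sort(scores, decreasing = TRUE)
  combos <- combn(8, 3)
  es_all <- apply(combos, 2, function(ix) gsea_es_brute(sorted, ix))
  es_obs <- gsea_es_brute(sorted, match(gs, names(sorted)))
  p_exact <- if (es_obs >= 0) sum(es_all >= es_obs) / sum(es_all >= 0)
             else sum(es_all <= es_obs) / sum(es_all <= 0)
  expect_equal(r$es, es_obs, tolerance = 1e-12)
  expect_equal(r$p, p_exact, tolerance = 1e-12)
})

test_that("random gene sets are rarely called enriched under the joint rule", {
  set.seed(10)
  sc <- setNames(rnorm(120), paste0("n", 1:120))
  joint <- vapply(1:300, function(i) {
    gs <- sample(names(sc), 10)
    r <- gsea_preranked(sc, gs, n_perm = 100, seed = 5000 + i)
    abs(r$nes) > 1 && r$p < 0.05
  }, TRUE)
  expect_lte(mean(joint), 0.09)
})

test_that("hypergeometric over-representation matches closed-form counts", {
  # drawing the whole set: p = 1 / C(20, 5)
  universe <- paste0("u", 1:20)
  gs <- universe[1:5]
  r <- ora_hypergeometric(gs, universe, gs)
  expect_equal(r$overlap, 5L)
  expect_equal(r$p, 1 / choose(20, 5), tolerance = 1e-12)

  # certain events: de = set = universe, and zero overlap
  expect_equal(ora_hypergeometric(universe, universe, universe)$p, 1)
  r0 <- ora_hypergeometric(universe[6:10], universe, universe[11:15])
  expect_equal(r0$overlap, 0L)
  expect_equal(r0$p, 1)

  expect_error(ora_hypergeometric(c("zz"), universe, gs), "subset")
})

test_that("gsea_screen and ora_screen assemble per-set tables with BH q-values", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  set.seed(12)
  genes <- paste0("G", 1:60)
  writeLines(c(paste(c("TOP", "d", genes[1:8]), collapse = "\t"),
               paste(c("RAND", "d", sample(genes, 8)), collapse = "\t")),
             tmp)
  sets <- read_gmt(tmp)
  sc <- setNames(seq(3, -3, length.out = 60), genes)
  out <- gsea_screen(sc, sets, n_perm = 200, seed = 3)
  expect_equal(nrow(out), 2L)
  expect_gt(out$nes[out$set_name == "TOP"], 1)
  expect_true(out$selected[out$set_name == "TOP"])
  o2 <- ora_screen(genes[1:10], genes, sets)
  expect_equal(nrow(o2), 2L)
  expect_lt(o2$p[o2$set_name == "TOP"], 0.01)
  expect_true(all(o2$q >= o2$p))
})
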