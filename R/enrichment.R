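# Lightweight transcriptome screen: known-batch location-scale
# adjustment, empirical-Bayes moderated t, the joint DEG threshold,
# preranked GSEA with NES, and hypergeometric over-representation.

#' Location-scale batch adjustment
#'
#' Per gene, each batch's values are standardized to zero mean / unit
#' variance and rescaled to the gene's pooled mean and SD. This removes
#' additive and multiplicative batch offsets when batch labels are known;
#' it is a deliberate, documented simplification relative to surrogate
#' variable estimation, appropriate when the batches are the known data
#' series. A gene with zero variance within some batch is only centered
#' in that batch (warning).
#'
#' @param m numeric matrix, genes x samples.
#' @param batch per-sample batch labels (>= 2 samples per batch).
#' @return Adjusted matrix, same dimensions.
#' @export
batch_adjust <- function(m, batch) {
  m <- as.matrix(m)
  batch <- as.factor(batch)
  if (length(batch) != ncol(m))
    stop("batch must have one label per sample (column)")
  if (any(table(batch) < 2)) stop("each batch needs >= 2 samples")
  if (nlevels(droplevels(batch)) == 1L) return(m)
  out <- m
  pooled_mean <- rowMeans(m)
  # pooled SD: sqrt of the weighted mean of within-batch variances
  wvar <- matrix(0, nrow(m), nlevels(batch))
  wts <- numeric(nlevels(batch))
  for (k in seq_len(nlevels(batch))) {
    cols <- batch == levels(batch)[k]
    wvar[, k] <- apply(m[, cols, drop = FALSE], 1, stats::var)
    wts[k] <- sum(cols) - 1
  }
  pooled_sd <- sqrt(drop(wvar %*% wts) / sum(wts))
  degen <- 0L
  for (k in seq_len(nlevels(batch))) {
    cols <- batch == levels(batch)[k]
    mb <- rowMeans(m[, cols, drop = FALSE])
    sb <- sqrt(wvar[, k])
    zero <- sb == 0 | pooled_sd == 0
    degen <- degen + sum(zero)
    scale_f <- ifelse(zero, 1, pooled_sd / ifelse(sb == 0, 1, sb))
    out[, cols] <- (m[, cols, drop = FALSE] - mb) * scale_f + pooled_mean
  }
  if (degen > 0)
    warning(degen, " gene/batch block(s) had zero variance; centered only")
  out
}

# solve trigamma(x) = y by Newton iteration (y > 0)
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t test
#'
#' Per-gene two-sample comparison with variance shrinkage: the pooled
#' residual variance `s_g^2` (d_g = n - 2 df) is shrunk toward a prior
#' `s_0^2` with d_0 df, `s~^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)`,
#' and the moderated t referred to a t distribution on `d_0 + d_g` df.
#' The prior is estimated by moment matching on the log sample variances
#' (mean/variance of `log s_g^2` against the scaled log-chi-square
#' moments, trigamma-inverse for d_0). `d0` may be forced for the
#' no-shrinkage (`0`) and full-shrinkage (`Inf`) limits.
#'
#' @param m numeric matrix of log2 expression, genes x samples.
#' @param groups two-class per-sample labels; first level (or `"case"`)
#'   is the positive class of the fold change.
#' @param d0 `NULL` (estimate), `0`, `Inf`, or a positive number.
#' @return Data frame: `gene`, `log2fc`, `t_mod`, `p`, `direction`
#'   (`up`/`down`), plus attributes `d0` and `s0_sq`.
#' @export
moderated_t <- function(m, groups, d0 = NULL) {
  m <- as.matrix(m)
  g <- if (is.factor(groups)) groups else
    factor(groups, levels = if (all(groups %in% c("case", "control")))
      c("case", "control") else sort(unique(groups)))
  if (nlevels(droplevels(g)) != 2) stop("groups must have two classes")
  i1 <- g == levels(g)[1]; i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1, stats::var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  if (all(s2 == 0)) stop("all genes have zero variance")
  ok <- s2 > 0
  if (is.null(d0)) {
    # moment matching on z = log s^2 ~ log s0^2 + log(chi^2_dg / dg) shifted
    z <- log(s2[ok])
    e <- z - digamma(dg / 2) + log(dg / 2)
    excess <- stats::var(e) - trigamma(dg / 2)
    if (excess > 0) {
      d0 <- 2 * trigamma_inverse(excess)
      s0_sq <- exp(mean(e) - digamma(d0 / 2) + log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
  } else {
    s0_sq <- exp(mean(log(s2[ok])))
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2))
              else (d0 * s0_sq + dg * s2) / (d0 + dg)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  log2fc <- m1 - m2
  t_mod <- log2fc / se
  df_tot <- if (is.infinite(d0)) Inf else d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_tot)
  out <- data.frame(gene = rownames(m), log2fc = log2fc, t_mod = t_mod,
                    p = p,
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Joint DEG threshold
#'
#' Retains genes with `p < p_max` and `|log2fc| > abs_log2fc_min`
#' (both strict, as published), partitioned by fold-change sign.
#'
#' @param records data frame from [moderated_t()].
#' @param p_max p cutoff (strict <).
#' @param abs_log2fc_min |log2FC| cutoff (strict >).
#' @return List: `up`, `down` (data frames), `n_up`, `n_down`.
#' @export
deg_filter <- function(records, p_max = 0.05, abs_log2fc_min = 1) {
  if (!nrow(records)) stop("records is empty")
  keep <- records$p < p_max & abs(records$log2fc) > abs_log2fc_min
  up <- records[keep & records$log2fc > 0, , drop = FALSE]
  down <- records[keep & records$log2fc < 0, , drop = FALSE]
  message(sprintf("deg_filter: p < %g & |log2FC| > %g -> %d up, %d down",
                  p_max, abs_log2fc_min, nrow(up), nrow(down)))
  list(up = up, down = down, n_up = nrow(up), n_down = nrow(down))
}

# weighted Kolmogorov-Smirnov running sum; returns the signed extremum ES
# and the running-sum vector
gsea_es <- function(scores, hits, weight_exp = 1) {
  n <- length(scores)
  w <- abs(scores)^weight_exp
  nr <- sum(w[hits])
  if (nr == 0) w[hits] <- nr <- 1   # degenerate all-zero scores
  step <- numeric(n)
  step[hits] <- w[hits] / nr
  step[!hits] <- -1 / (n - sum(hits))
  rs <- cumsum(step)
  i <- which.max(abs(rs))
  list(es = rs[i], running = rs)
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted running-sum GSEA on a signed, ranked gene list:
#' increments `|score|^weight_exp / N_R` at set hits, decrements
#' `1 / (N - N_H)` at misses; ES is the signed extremum. The null is the
#' gene-label permutation (random hit positions). NES is ES divided by
#' the mean of same-sign permuted ES; the permutation p is the same-sign
#' tail fraction with +1 smoothing, or exact when `exact = TRUE`
#' (enumerates all hit-position subsets; requires
#' `choose(N, N_H) <= max_exact`).
#'
#' Ties in the ranking are broken by gene symbol (lexicographic) for
#' determinism.
#'
#' @param scores named numeric vector of signed ranking scores (e.g.
#'   moderated t), genes as names; sorted internally, decreasing.
#' @param geneset character vector of member genes (or a list with a
#'   `members` element as from [read_gmt()]).
#' @param weight_exp running-sum weight exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm number of gene-label permutations.
#' @param seed RNG seed.
#' @param exact enumerate all hit subsets instead of sampling.
#' @param max_exact enumeration cap for `exact = TRUE`.
#' @return Object of class `gsea_result`: `es`, `nes`, `p`,
#'   `leading_edge` (gene vector), `n_hits`, `n_perm`; or `NULL` (with a
#'   warning) when the overlap is < 3 genes.
#' @export
gsea_preranked <- function(scores, geneset, weight_exp = 1,
                           n_perm = 1000, seed = 1L, exact = FALSE,
                           max_exact = 2e5) {
  if (is.list(geneset)) geneset <- geneset$members
  if (is.null(names(scores))) stop("scores must be named by gene")
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  genes <- names(scores)
  hits <- genes %in% geneset
  nh <- sum(hits)
  n <- length(scores)
  if (nh < 3) {
    warning("gene set overlaps the ranked list in < 3 genes; skipped")
    return(NULL)
  }
  if (nh == n) stop("gene set covers the whole ranked list")
  obs <- gsea_es(scores, hits, weight_exp)
  es <- obs$es
  # leading edge: hits at or before (after, for negative ES) the extremum
  i_ext <- which.max(abs(obs$running))
  le <- if (es >= 0) genes[hits & seq_len(n) <= i_ext]
        else genes[hits & seq_len(n) >= i_ext]
  # the p-value and NES are computed against the SAME-SIGN portion of the
  # permutation null (Broad convention): the observed ES is a signed
  # extremum, so a tail over the full two-sided null would be
  # anti-conservative by roughly a factor two
  if (exact) {
    combos <- utils::combn(n, nh)
    if (ncol(combos) > max_exact)
      stop("exact enumeration too large; use permutations")
    perm_es <- apply(combos, 2, function(ix) {
      h <- rep(FALSE, n); h[ix] <- TRUE
      gsea_es(scores, h, weight_exp)$es
    })
    same <- if (es >= 0) perm_es >= 0 else perm_es <= 0
    extreme <- if (es >= 0) perm_es >= es else perm_es <= es
    p <- sum(extreme) / sum(same)   # observed subset is enumerated: no smoothing
    n_used <- ncol(combos)
  } else {
    set.seed(seed)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      h <- rep(FALSE, n); h[sample.int(n, nh)] <- TRUE
      gsea_es(scores, h, weight_exp)$es
    }, 0.0)
    same <- if (es >= 0) perm_es >= 0 else perm_es <= 0
    extreme <- if (es >= 0) perm_es >= es else perm_es <= es
    p <- (sum(extreme) + 1) / (sum(same) + 1)
    n_used <- n_perm
  }
  denom <- mean(abs(perm_es[same]))
  nes <- if (is.finite(denom) && denom > 0) es / denom else sign(es) * abs(es)
  structure(list(es = es, nes = nes, p = p, leading_edge = le,
                 n_hits = nh, n_perm = n_used, exact = exact,
                 running = obs$running),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES = %.3f, NES = %.3f, p = %.4g (%s, %d hits)\n",
              x$es, x$nes, x$p,
              if (x$exact) "exact" else sprintf("%d perms", x$n_perm),
              x$n_hits))
  invisible(x)
}

#' Run preranked GSEA over a gene-set collection
#'
#' @param scores named signed ranking scores.
#' @param genesets list of gene sets from [read_gmt()].
#' @param nes_min,p_max selection thresholds (|NES| strict >, p strict <).
#' @param ... passed to [gsea_preranked()].
#' @return Data frame: `set_name`, `es`, `nes`, `p`, `q` (BH), `n_hits`,
#'   `selected`.
#' @export
gsea_screen <- function(scores, genesets, nes_min = 1, p_max = 0.05, ...) {
  res <- lapply(genesets, function(gs)
    gsea_preranked(scores, gs, ...))
  keep <- !vapply(res, is.null, TRUE)
  res <- res[keep]
  out <- data.frame(
    set_name = vapply(genesets[keep], `[[`, "", "name"),
    es = vapply(res, `[[`, 0.0, "es"),
    nes = vapply(res, `[[`, 0.0, "nes"),
    p = vapply(res, `[[`, 0.0, "p"),
    n_hits = vapply(res, `[[`, 0L, "n_hits"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- bh_adjust(out$p)
  out$selected <- abs(out$nes) > nes_min & out$p < p_max
  out
}

#' Hypergeometric over-representation
#'
#' Upper-tail p-value `P(X >= overlap)` for the overlap of a DE gene list
#' with a gene set under hypergeometric sampling from the universe.
#'
#' @param de_genes character vector, subset of `universe`.
#' @param universe character vector of all tested genes (non-empty).
#' @param geneset character vector (or [read_gmt()] entry).
#' @return List: `p`, `overlap`, `expected`, `genes` (the overlapping
#'   symbols).
#' @export
ora_hypergeometric <- function(de_genes, universe, geneset) {
  if (is.list(geneset)) geneset <- geneset$members
  if (!length(universe)) stop("universe must be non-empty")
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe")
  set_in <- intersect(geneset, universe)
  if (!length(set_in)) stop("gene set does not intersect the universe")
  hit <- intersect(de_genes, set_in)
  k <- length(hit)
  p <- stats::phyper(k - 1, length(set_in),
                     length(universe) - length(set_in),
                     length(de_genes), lower.tail = FALSE)
  list(p = p, overlap = k,
       expected = length(de_genes) * length(set_in) / length(universe),
       genes = hit)
}

#' Over-representation across a gene-set collection
#'
#' @inheritParams ora_hypergeometric
#' @param genesets list from [read_gmt()].
#' @return Data frame: `set_name`, `overlap`, `expected`, `p`, `q` (BH).
#' @export
ora_screen <- function(de_genes, universe, genesets) {
  rows <- lapply(genesets, function(gs) {
    r <- ora_hypergeometric(de_genes, universe, gs)
    data.frame(set_name = gs$name, overlap = r$overlap,
               expected = r$expected, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bh_adjust(out$p)
  out
}
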