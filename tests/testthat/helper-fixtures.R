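# Shared fixture builders and independent oracles for the test suite.

# random positive feature table with group labels
random_table <- function(n_case = 6, n_control = 6, p = 8, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  m <- matrix(2^rnorm(n * p, mean = 12), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  feature_table(m, group = rep(c("case", "control"), c(n_case, n_control)))
}

# data whose sample correlation matrix is EXACTLY R: orthonormal centered
# basis times chol(R)
exact_cor_data <- function(R, n, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  Z <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))            # columns orthonormal and mean-zero
  X <- Q %*% chol(R)
  X * sqrt(n - 1)             # unit sample variance per column
}

# independent 1-component PLS oracle (direct formulas, no NIPALS loop)
pls1_oracle <- function(Xtr, ytr, Xte) {
  mu <- colMeans(Xtr); sd <- apply(Xtr, 2, sd); sd[sd == 0] <- 1
  Z <- sweep(sweep(Xtr, 2, mu), 2, sd, `/`)
  yc <- ytr - mean(ytr)
  w <- drop(crossprod(Z, yc)); w <- w / sqrt(sum(w^2))
  t <- drop(Z %*% w)
  b <- sum(t * yc) / sum(t^2)
  Zte <- sweep(sweep(Xte, 2, mu), 2, sd, `/`)
  b * drop(Zte %*% w) + mean(ytr)
}

# brute-force weighted GSEA running sum, written independently of the
# package implementation (indexing loop instead of vectorised cumsum)
gsea_es_brute <- function(scores_sorted, hit_positions, weight_exp = 1) {
  n <- length(scores_sorted)
  nh <- length(hit_positions)
  nr <- sum(abs(scores_sorted[hit_positions])^weight_exp)
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (i %in% hit_positions)
      abs(scores_sorted[i])^weight_exp / nr else -1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# Mann-Whitney U (x side, ties 1/2) by direct pair counting
u_brute <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}
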