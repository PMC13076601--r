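# From-scratch chemometric preprocessing and unsupervised analysis:
# half-minimum imputation, log transform, autoscaling/Pareto scaling,
# correlation-matrix PCA, KMO sampling adequacy, Bartlett's sphericity,
# and the Hotelling T2 confidence ellipse.

#' Preprocess a feature table
#'
#' Metabolomics-convention preprocessing: drop features whose missing
#' fraction exceeds `max_missing_fraction` (with a message), impute the
#' remaining missing cells as half the feature's observed minimum,
#' log-transform, then column-scale. Autoscaled output has zero column
#' means and unit SDs; zero-variance features are dropped under
#' autoscaling with a warning.
#'
#' @param ft a [feature_table()].
#' @param log_base 2, 10, `exp(1)`, or `"none"`.
#' @param scaling `"autoscale"`, `"pareto"`, or `"none"`.
#' @param impute `"half_min"` or `"none"` (then missing cells must be
#'   absent downstream).
#' @param max_missing_fraction drop features missing more than this, in
#'   \[0, 1).
#' @return A [feature_table()] (possibly fewer features), with attribute
#'   `"dropped"` listing removed feature ids.
#' @export
preprocess <- function(ft, log_base = 2,
                       scaling = c("autoscale", "pareto", "none"),
                       impute = c("half_min", "none"),
                       max_missing_fraction = 0.5) {
  scaling <- match.arg(scaling)
  impute <- match.arg(impute)
  if (max_missing_fraction < 0 || max_missing_fraction >= 1)
    stop("max_missing_fraction must lie in [0, 1)")
  v <- ft$values
  missfrac <- colMeans(is.na(v))
  dropped <- character()
  all_missing <- missfrac == 1
  too_missing <- missfrac > max_missing_fraction & !all_missing
  if (any(all_missing)) {
    warning("dropping feature(s) with all values missing: ",
            paste(ft$feature_ids[all_missing], collapse = ", "))
    dropped <- c(dropped, ft$feature_ids[all_missing])
  }
  if (any(too_missing)) {
    message("dropping ", sum(too_missing), " feature(s) above the ",
            max_missing_fraction, " missing-fraction threshold")
    dropped <- c(dropped, ft$feature_ids[too_missing])
  }
  keep <- !(all_missing | too_missing)
  v <- v[, keep, drop = FALSE]
  if (impute == "half_min" && anyNA(v)) {
    for (j in which(colSums(is.na(v)) > 0)) {
      v[is.na(v[, j]), j] <- min(v[, j], na.rm = TRUE) / 2
    }
  }
  if (!identical(log_base, "none")) {
    if (any(v <= 0, na.rm = TRUE))
      stop("log transform requires strictly positive abundances")
    v <- log(v, base = as.numeric(log_base))
  }
  if (scaling != "none") {
    mu <- colMeans(v, na.rm = TRUE)
    sd <- apply(v, 2, stats::sd, na.rm = TRUE)
    if (scaling == "autoscale") {
      zero <- sd == 0
      if (any(zero)) {
        warning("dropping zero-variance feature(s) under autoscaling: ",
                paste(colnames(v)[zero], collapse = ", "))
        dropped <- c(dropped, colnames(v)[zero])
        v <- v[, !zero, drop = FALSE]
        mu <- mu[!zero]; sd <- sd[!zero]
      }
      v <- sweep(sweep(v, 2, mu), 2, sd, `/`)
    } else {
      v <- sweep(sweep(v, 2, mu), 2, sqrt(sd), `/`)
    }
  }
  out <- ft
  out$values <- v
  out$feature_ids <- colnames(v)
  structure(out, dropped = dropped, class = "feature_table")
}

# autoscale a raw numeric matrix, returning scaling parameters for reuse
# on held-out data (used by the CV and composite-score code paths)
autoscale_fit <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

autoscale_apply <- function(m, sc) {
  sweep(sweep(m, 2, sc$mu), 2, sc$sd, `/`)
}

#' Principal component analysis
#'
#' Eigendecomposition of the correlation matrix (default; i.e. PCA of
#' autoscaled data) or the covariance matrix of centered data. Loadings
#' are eigenvectors scaled by sqrt(eigenvalue); scores are the projections
#' of the scaled data on the eigenvectors. Component signs follow the
#' deterministic convention that each component's largest-magnitude
#' loading is positive. Components beyond the matrix rank are retained
#' with eigenvalue ~0 and flagged.
#'
#' @param x a [feature_table()] or numeric matrix (samples x features),
#'   no missing values.
#' @param use_correlation correlation (default) vs covariance matrix.
#' @return Object of class `pca_model`: `eigenvalues`, `loadings`
#'   (features x components, eigenvector * sqrt(lambda)), `eigenvectors`,
#'   `scores` (samples x components), `variance_explained`,
#'   `rank_deficient` (logical per component), `use_correlation`.
#' @export
pca_fit <- function(x, use_correlation = TRUE) {
  m <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (anyNA(m)) stop("pca_fit requires a complete matrix; preprocess() first")
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 samples and >= 2 features")
  ctr <- sweep(m, 2, colMeans(m))
  if (use_correlation) {
    sd <- apply(m, 2, stats::sd)
    if (any(sd == 0)) stop("zero-variance feature; drop before correlation PCA")
    z <- sweep(ctr, 2, sd, `/`)
    S <- stats::cor(m)
  } else {
    z <- ctr
    S <- stats::cov(m)
  }
  ed <- eigen(S, symmetric = TRUE)
  lambda <- pmax(ed$values, 0)
  V <- ed$vectors
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  loadings <- V %*% diag(sqrt(lambda), length(lambda))
  scores <- z %*% V
  dimnames(V) <- dimnames(loadings) <-
    list(colnames(m), paste0("PC", seq_along(lambda)))
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_along(lambda)))
  structure(list(eigenvalues = lambda, loadings = loadings,
                 eigenvectors = V, scores = scores,
                 variance_explained = lambda / sum(lambda),
                 rank_deficient = lambda < 1e-10 * max(lambda),
                 use_correlation = use_correlation),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, n = 5, ...) {
  k <- min(n, length(x$eigenvalues))
  cat(sprintf("pca_model (%s matrix): %d components\n",
              if (x$use_correlation) "correlation" else "covariance",
              length(x$eigenvalues)))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues[1:k]),
                              collapse = " "),
      if (length(x$eigenvalues) > k) "...\n" else "\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained[1:k]),
            collapse = " "),
      if (length(x$eigenvalues) > k) "...\n" else "\n")
  invisible(x)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares raw correlations with anti-image partial correlations:
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum a_ij^2)` over i != j, where
#' `a_ij = -inv(R)_ij / sqrt(inv(R)_ii inv(R)_jj)`. Also returns the
#' per-variable measure of sampling adequacy (same ratio over row sums).
#'
#' @param x a [feature_table()] or numeric matrix (samples x features).
#' @return List: `kmo` (overall, in \[0, 1\]), `msa` (named per-variable).
#' @export
kmo <- function(x) {
  m <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  R <- stats::cor(m)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; reduce the variable set"))
  d <- sqrt(diag(Rinv))
  A <- -Rinv / tcrossprod(d)
  diag(A) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; a2 <- A^2
  list(kmo = sum(r2) / (sum(r2) + sum(a2)),
       msa = stats::setNames(rowSums(r2) / (rowSums(r2) + rowSums(a2)),
                             colnames(m)))
}

#' Bartlett's test of sphericity
#'
#' Tests that the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` df.
#'
#' @param x a [feature_table()] or numeric matrix (samples x features),
#'   with more samples than features and positive-definite correlation.
#' @return An `lp_test` with `method = "bartlett_sphericity"`.
#' @export
bartlett_sphericity <- function(x) {
  m <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  n <- nrow(m); p <- ncol(m)
  if (n <= p) stop("Bartlett's test needs n > p")
  R <- stats::cor(m)
  dt <- determinant(R, logarithm = TRUE)
  if (dt$sign <= 0)
    stop("correlation matrix is not positive definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(dt$modulus)
  df <- p * (p - 1) / 2
  test_result("bartlett_sphericity", chi2,
              stats::pchisq(chi2, df, lower.tail = FALSE), df = df)
}

#' Hotelling T2 confidence ellipse
#'
#' The (1 - alpha) Hotelling T2 ellipse of a two-column score matrix:
#' centered at the score means, axes along the score-covariance
#' eigenvectors with half-lengths `sqrt(lambda_i * c)` where
#' `c = 2 (n - 1) / (n - 2) * F(1 - alpha; 2, n - 2)`.
#'
#' @param scores numeric matrix with exactly 2 columns, >= 3 rows.
#' @param alpha significance level (default 0.05 for the 95% ellipse).
#' @return List: `center`, `axes` (half-lengths, major first), `angle`
#'   (radians, major axis vs x), `inside` (logical per point),
#'   `coverage` (fraction inside).
#' @export
hotelling_ellipse <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns")
  n <- nrow(scores)
  if (n < 3) stop("need >= 3 samples")
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  if (abs(det(S)) < .Machine$double.eps)
    stop("singular score covariance")
  cval <- 2 * (n - 1) / (n - 2) * stats::qf(1 - alpha, 2, n - 2)
  ed <- eigen(S, symmetric = TRUE)
  d <- sweep(scores, 2, ctr)
  t2 <- rowSums((d %*% solve(S)) * d)
  list(center = ctr, axes = sqrt(ed$values * cval),
       angle = atan2(ed$vectors[2, 1], ed$vectors[1, 1]),
       inside = t2 <= cval, coverage = mean(t2 <= cval))
}
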