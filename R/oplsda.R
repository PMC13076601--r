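# Orthogonal partial least squares discriminant analysis (OPLS-DA) for
# two-class metabolomics data: a NIPALS-style fit separating one
# class-predictive component from class-orthogonal variation, with VIP
# scores, stratified cross-validated Q2, and permutation validation.

code_y <- function(y) {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (length(u) != 2) stop("y must have exactly two classes")
    lev <- as.character(c(u[2], u[1]))   # larger value codes +1
    yc <- ifelse(y == u[2], 1, -1)
  } else {
    y <- as.factor(y)
    if (nlevels(y) != 2) stop("y must have exactly two classes")
    lev <- levels(y)
    yc <- ifelse(y == lev[1], 1, -1)
  }
  if (min(table(yc)) < 3) stop("each class needs >= 3 samples")
  list(y = yc, levels = lev)
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis with
#' one predictive component and `n_ortho` orthogonal components, fitted by
#' the deterministic NIPALS-style algorithm (no random initialisation):
#' the class vector is coded +1/-1 and centered; the candidate predictive
#' weight is `w` proportional to `X'y`; each orthogonal weight is the part of the
#' X-loading orthogonal to `w` (`w_o` proportional to `p - (w'p / w'w) w`), whose score
#' `t_o = X w_o` is deflated from X; the final predictive component is
#' extracted from the fully deflated X. `R2Y = 1 - ||y - yhat||^2 / ||y||^2`
#' on the centered class vector.
#'
#' For `n_ortho = 0` the model is exactly a 1-component PLS regression of
#' the coded class on X.
#'
#' @param x a [feature_table()] with group labels, or a numeric matrix
#'   (samples x features).
#' @param y two-class labels (factor/character/two-valued numeric); taken
#'   from `x$group` when `x` is a grouped feature table. The first factor
#'   level is coded +1.
#' @param n_ortho number of orthogonal components (>= 0; default 1).
#' @param scale autoscale columns before fitting (default `TRUE`;
#'   scaling parameters are stored and reused by [predict.oplsda()]).
#' @return An object of class `oplsda`: list with predictive weights `w`
#'   (unit norm), loadings `p_load`, scores `t`, inner coefficient `b`,
#'   orthogonal `w_o`, `p_o`, `t_o` (p x n_ortho / n x n_ortho matrices),
#'   `r2y`, fitted values, scaling parameters, class coding, and
#'   dimensions.
#' @seealso [vip_scores()], [q2_cross_validated()],
#'   [permutation_validate()]
#' @examples
#' study <- simulate_lipidomics(cohort_spec(seed = 7))
#' ft <- preprocess(study$feature_table)
#' fit <- oplsda(ft, scale = FALSE)
#' fit
#' @export
oplsda <- function(x, y = NULL, n_ortho = 1, scale = TRUE) {
  m <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (is.null(y)) {
    if (!inherits(x, "feature_table") || is.null(x$group))
      stop("y is required unless x is a grouped feature_table")
    y <- x$group
  }
  if (anyNA(m)) stop("x must be complete; preprocess() first")
  cy <- code_y(y)
  yc <- cy$y - mean(cy$y)
  if (all(yc == 0)) stop("degenerate class vector")
  sc <- autoscale_fit(m)
  X <- if (scale) autoscale_apply(m, sc)
       else sweep(m, 2, colMeans(m))  # always center
  if (all(abs(X) < .Machine$double.eps)) stop("X has no variance")
  p <- ncol(X); n <- nrow(X)
  W_o <- matrix(0, p, 0); P_o <- matrix(0, p, 0); T_o <- matrix(0, n, 0)
  for (k in seq_len(n_ortho)) {
    w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    pl <- drop(crossprod(X, t)) / sum(t^2)
    w_o <- pl - sum(w * pl) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break   # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  pl <- drop(crossprod(X, t)) / sum(t^2)
  b <- sum(t * yc) / sum(t^2)
  fitted <- b * t
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)
  feat <- colnames(m)
  names(w) <- names(pl) <- feat
  if (ncol(W_o)) rownames(W_o) <- rownames(P_o) <- feat
  structure(list(w = w, p_load = pl, t = t, b = b,
                 w_o = W_o, p_o = P_o, t_o = T_o,
                 r2y = r2y, fitted = fitted, y = yc,
                 y_mean = mean(cy$y), levels = cy$levels,
                 n_ortho = ncol(W_o), scale = scale, scaling = sc,
                 center = colMeans(m), n = n, p = p,
                 feature_ids = feat),
            class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("oplsda: %d samples x %d features, 1 predictive + %d orthogonal component(s)\n",
              x$n, x$p, x$n_ortho))
  cat(sprintf("  R2Y = %.3f\n", x$r2y))
  if (!is.null(x$q2)) cat(sprintf("  Q2  = %.3f\n", x$q2))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  vip <- vip_scores(object)
  structure(list(r2y = object$r2y, q2 = object$q2, n = object$n,
                 p = object$p, n_ortho = object$n_ortho,
                 n_vip_gt1 = sum(vip > 1),
                 top_vip = sort(vip, decreasing = TRUE)[
                   seq_len(min(5, length(vip)))]),
            class = "summary.oplsda")
}

#' @export
print.summary.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: n = %d, features = %d, orthogonal components = %d\n",
              x$n, x$p, x$n_ortho))
  cat(sprintf("  R2Y = %.3f%s\n", x$r2y,
              if (is.null(x$q2)) "" else sprintf(", Q2 = %.3f", x$q2)))
  cat(sprintf("  features with VIP > 1: %d\n", x$n_vip_gt1))
  cat("  top VIP:\n")
  print(round(x$top_vip, 3))
  invisible(x)
}

#' @export
coef.oplsda <- function(object, ...) object$b * object$w

#' @export
fitted.oplsda <- function(object, ...) object$fitted + object$y_mean

#' @export
residuals.oplsda <- function(object, ...) object$y - object$fitted

#' Predict from an OPLS-DA model
#'
#' New data are scaled with the training parameters, orthogonal
#' components are filtered out with the stored `w_o`/`p_o`, and the
#' predictive score is mapped through the inner relation.
#'
#' @param object an [oplsda()] fit.
#' @param newdata matrix or [feature_table()] with the training features.
#' @param type `"response"` (continuous prediction on the +1/-1 scale),
#'   `"class"` (factor with the training levels; threshold 0 on the
#'   centered response), or `"scores"` (list with predictive `t` and
#'   orthogonal `t_o`).
#' @param ... unused.
#' @return Per `type`.
#' @export
predict.oplsda <- function(object, newdata,
                           type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  m <- if (inherits(newdata, "feature_table")) newdata$values
       else as.matrix(newdata)
  if (!is.null(colnames(m)) && !identical(colnames(m), object$feature_ids)) {
    if (!all(object$feature_ids %in% colnames(m)))
      stop("newdata lacks training features")
    m <- m[, object$feature_ids, drop = FALSE]
  }
  X <- if (object$scale) autoscale_apply(m, object$scaling)
       else sweep(m, 2, object$center)
  T_o <- matrix(0, nrow(X), 0)
  for (k in seq_len(object$n_ortho)) {
    t_o <- drop(X %*% object$w_o[, k])
    X <- X - tcrossprod(t_o, object$p_o[, k])
    T_o <- cbind(T_o, t_o)
  }
  t <- drop(X %*% object$w)
  if (type == "scores") return(list(t = t, t_o = T_o))
  resp <- object$b * t
  if (type == "response") return(resp + object$y_mean)
  factor(ifelse(resp > 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' Score plot of an OPLS-DA model
#'
#' Predictive score t1 against the first orthogonal score (or sample
#' index when `n_ortho = 0`), colored by class, with the 95% Hotelling
#' T2 ellipse of all scores.
#'
#' @param x an [oplsda()] fit.
#' @param alpha ellipse significance level.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.oplsda <- function(x, alpha = 0.05, ...) {
  t2 <- if (x$n_ortho > 0) x$t_o[, 1] else seq_along(x$t)
  cls <- ifelse(x$y > 0, x$levels[1], x$levels[2])
  graphics::plot(x$t, t2, col = ifelse(x$y > 0, "firebrick", "steelblue"),
                 pch = 19, xlab = "t1 (predictive)",
                 ylab = if (x$n_ortho > 0) "to1 (orthogonal)" else "index",
                 ...)
  if (x$n_ortho > 0) {
    ell <- hotelling_ellipse(cbind(x$t, t2), alpha = alpha)
    th <- seq(0, 2 * pi, length.out = 200)
    pts <- cbind(ell$axes[1] * cos(th), ell$axes[2] * sin(th))
    rot <- matrix(c(cos(ell$angle), sin(ell$angle),
                    -sin(ell$angle), cos(ell$angle)), 2, 2)
    pts <- pts %*% t(rot)
    graphics::lines(pts[, 1] + ell$center[1], pts[, 2] + ell$center[2],
                    lty = 2)
  }
  graphics::legend("topright", legend = x$levels, pch = 19,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SS_a (w_aj / ||w_a||)^2 / sum_a SS_a)` over the
#' predictive components (`SS_a = b_a^2 t_a' t_a`); with the single
#' predictive component of this model this reduces to
#' `sqrt(p) |w_j| / ||w||`. By construction `mean(VIP^2) = 1`.
#'
#' @param model an [oplsda()] fit.
#' @param ... unused.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model, ...) {
  stopifnot(inherits(model, "oplsda"))
  ss <- model$b^2 * sum(model$t^2)
  if (ss <= 0) stop("degenerate model: zero predictive sum of squares")
  wnorm <- model$w / sqrt(sum(model$w^2))
  sqrt(model$p * wnorm^2)
}

# stratified fold assignment: shuffles within class, deals round-robin
stratified_folds <- function(y, folds) {
  idx <- split(seq_along(y), y)
  assign <- integer(length(y))
  for (cls in idx) {
    cls <- cls[sample.int(length(cls))]
    assign[cls] <- rep_len(seq_len(folds), length(cls))
  }
  assign
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Stratified k-fold cross-validation: per fold the model (including the
#' column scaling) is refitted on the training rows only and the held-out
#' class values predicted; `Q2 = 1 - PRESS / sum (y_test - ybar_train)^2`,
#' pooled over folds. Can be negative for uninformative X.
#'
#' @param x matrix or [feature_table()] (complete).
#' @param y two-class labels (or `NULL` for a grouped feature table).
#' @param n_ortho orthogonal components.
#' @param folds number of folds (>= 2; default 7, the common chemometrics
#'   default).
#' @param seed RNG seed for the fold assignment.
#' @param scale autoscale within each training fold.
#' @return Q2 (scalar).
#' @export
q2_cross_validated <- function(x, y = NULL, n_ortho = 1, folds = 7,
                               seed = 1L, scale = TRUE) {
  m <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (is.null(y)) {
    if (!inherits(x, "feature_table") || is.null(x$group))
      stop("y is required unless x is a grouped feature_table")
    y <- x$group
  }
  if (folds < 2) stop("folds must be >= 2")
  cy <- code_y(y)
  yc <- cy$y
  set.seed(seed)
  fold <- stratified_folds(yc, folds)
  press <- tss <- 0
  for (k in sort(unique(fold))) {
    tr <- fold != k
    if (length(unique(yc[tr])) < 2)
      stop("a training fold lost a class; reduce folds")
    fit <- oplsda(m[tr, , drop = FALSE], yc[tr], n_ortho = n_ortho,
                  scale = scale)
    pred <- predict(fit, m[!tr, , drop = FALSE], type = "response")
    press <- press + sum((yc[!tr] - pred)^2)
    tss <- tss + sum((yc[!tr] - mean(yc[tr]))^2)
  }
  1 - press / tss
}

#' Permutation validation of an OPLS-DA model
#'
#' Recomputes the cross-validated Q2 after each of `n_perm` seeded random
#' permutations of the class labels; the permutation p-value is
#' `(#\{Q2_perm >= Q2_obs\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams q2_cross_validated
#' @param n_perm number of label permutations (default 200; < 20 warns
#'   about p-value resolution).
#' @return List of class `oplsda_permutation`: `q2_observed`, `perm_q2`
#'   (length `n_perm`), `perm_p`, `n_perm`.
#' @export
permutation_validate <- function(x, y = NULL, n_perm = 200, seed = 1L,
                                 n_ortho = 1, folds = 7, scale = TRUE) {
  m <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (is.null(y)) {
    if (!inherits(x, "feature_table") || is.null(x$group))
      stop("y is required unless x is a grouped feature_table")
    y <- x$group
  }
  if (n_perm < 20) warning("n_perm < 20 gives a coarse permutation p")
  yc <- code_y(y)$y
  q2_obs <- q2_cross_validated(m, yc, n_ortho = n_ortho, folds = folds,
                               seed = seed, scale = scale)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(length(yc)), simplify = FALSE)
  perm_q2 <- vapply(seq_len(n_perm), function(i) {
    q2_cross_validated(m, yc[perms[[i]]], n_ortho = n_ortho,
                       folds = folds, seed = seed + i, scale = scale)
  }, 0.0)
  structure(list(q2_observed = q2_obs, perm_q2 = perm_q2,
                 perm_p = (sum(perm_q2 >= q2_obs) + 1) / (n_perm + 1),
                 n_perm = n_perm),
            class = "oplsda_permutation")
}

#' @export
print.oplsda_permutation <- function(x, ...) {
  cat(sprintf("permutation validation (n_perm = %d)\n", x$n_perm))
  cat(sprintf("  observed Q2 = %.3f, max permuted Q2 = %.3f, p = %.4g\n",
              x$q2_observed, max(x$perm_q2), x$perm_p))
  invisible(x)
}
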