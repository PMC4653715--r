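# Phylogenetic generalized least squares under a Brownian-motion
# residual covariance.

#' Phylogenetic generalized least squares regression
#'
#' GLS regression of a species-level response on one or more covariates with
#' the residual covariance fixed at the Brownian-motion expectation C from
#' the phylogeny (no concurrent lambda estimation): beta-hat =
#' (X' C^-1 X)^-1 X' C^-1 y with an intercept column.  Species with a
#' missing response or covariate value are dropped pairwise, and the tree is
#' pruned to the retained set.  The reported `correlation` is the signed
#' square root of the GLS coefficient of determination, sign taken from the
#' slope: sign(beta_slope) * sqrt(1 - RSS_GLS / TSS_GLS), with TSS_GLS the
#' GLS residual sum of squares about the phylogenetic mean.
#'
#' @param y Named numeric response (names = tip labels).
#' @param X Named numeric covariate vector, or a matrix/data frame of
#'   covariates with rownames = tip labels (no intercept column; one is
#'   added).
#' @param tree An [ape::phylo] containing at least the species shared by
#'   `y` and `X`.
#' @return Object of class `pgls_fit`: `beta` (intercept first),
#'   `correlation`, `t_stat`, `p_value` (two-sided, slope coefficients),
#'   `df`, `n_used`, `species`, `sigma2`.
#' @export
pgls_fit <- function(y, X, tree) {
  validate_phylogeny(tree)
  if (is.null(dim(X))) {
    X <- matrix(X, ncol = 1L, dimnames = list(names(X), "x"))
  } else X <- as.matrix(X)
  if (is.null(names(y)) || is.null(rownames(X)))
    stop("y and X must carry species names")
  common <- intersect(intersect(names(y), rownames(X)), tree$tip.label)
  keep <- common[stats::complete.cases(cbind(y[common], X[common, , drop = FALSE])) &
                   is.finite(y[common])]
  p <- ncol(X)
  if (length(keep) < p + 3L)
    stop("fewer than ", p + 3L, " species with complete data")
  tr <- prune_to_taxa(tree, keep)
  yv <- y[tr$tip.label]
  Xm <- cbind(`(Intercept)` = 1, X[tr$tip.label, , drop = FALSE])
  if (qr(Xm)$rank < ncol(Xm)) stop("rank-deficient design matrix")
  C <- ape::vcv.phylo(tr)
  L <- chol(C)
  # whiten: solve(t(L)) %*% . turns GLS into OLS
  wy <- forwardsolve(t(L), yv)
  wX <- forwardsolve(t(L), Xm)
  qrw <- qr(wX)
  beta <- qr.coef(qrw, wy)
  res <- wy - wX %*% beta
  n <- length(yv)
  df <- n - ncol(Xm)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qrw))
  se <- sqrt(sigma2 * diag(XtX_inv))
  t_stat <- beta / se
  p_value <- 2 * stats::pt(-abs(t_stat), df)
  # GLS R^2 about the phylogenetic mean
  w1 <- forwardsolve(t(L), rep(1, n))
  mu <- sum(w1 * wy) / sum(w1^2)
  tss <- sum((wy - mu * w1)^2)
  rss <- sum(res^2)
  r2 <- max(0, 1 - rss / tss)
  slope_sign <- if (ncol(Xm) == 2L) sign(beta[2L]) else 1
  structure(list(beta = stats::setNames(as.numeric(beta), colnames(Xm)),
                 correlation = as.numeric(slope_sign * sqrt(r2)),
                 t_stat = stats::setNames(as.numeric(t_stat), colnames(Xm)),
                 p_value = stats::setNames(as.numeric(p_value), colnames(Xm)),
                 df = df, n_used = n, species = tr$tip.label,
                 sigma2 = sigma2),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (BM residuals), n = ", x$n_used, ", df = ", x$df, "\n", sep = "")
  tab <- data.frame(beta = x$beta, t = x$t_stat, p = x$p_value)
  print(tab, digits = 4)
  cat("correlation (signed sqrt GLS R^2): ",
      format(x$correlation, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$beta
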