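# ML fitting of the six trait-evolution models, information-theoretic
# comparison, phylogenetic signal, ancestral states, the evolutionary rate
# matrix, and multivariate Brownian simulation.

.align_to_tips <- function(x, tree) {
  tips <- tree$tip.label
  if (is.null(names(x))) {
    if (length(x) != length(tips))
      stop("x has no names and its length differs from the tip count")
    names(x) <- tips
    return(x)
  }
  missing <- setdiff(tips, names(x))
  if (length(missing))
    stop("no data for tip(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  x[tips]
}

# Profiled GLS log-likelihood of x ~ N(z0 1, sigma2 V): z0 and sigma2 have
# closed-form ML solutions given V.
.profile_lnl <- function(x, V) {
  n <- length(x)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(list(lnL = -Inf, z0 = NA_real_, sigma2 = NA_real_))
  logdet <- 2 * sum(log(diag(L)))
  one <- rep(1, n)
  iv_x <- backsolve(L, forwardsolve(t(L), x))
  iv_1 <- backsolve(L, forwardsolve(t(L), one))
  z0 <- sum(iv_1 * x) / sum(iv_1 * one)
  if (!is.finite(z0)) return(list(lnL = -Inf, z0 = NA_real_,
                                  sigma2 = NA_real_))
  r <- x - z0
  q <- sum(r * backsolve(L, forwardsolve(t(L), r)))
  sigma2 <- q / n
  if (!is.finite(sigma2) || sigma2 <= 0)
    return(list(lnL = -Inf, z0 = z0, sigma2 = sigma2))
  lnL <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(lnL = lnL, z0 = z0, sigma2 = sigma2)
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits one of six models of continuous trait evolution on a phylogeny by
#' ML: Brownian motion (BM), single-optimum Ornstein-Uhlenbeck (OU, with the
#' root at the optimum and the stationary covariance), white noise (WN, iid
#' normal), Early Burst (EB/ACDC, exponentially time-changing rate, positive
#' rate change allowed), Pagel's delta and Pagel's lambda.  The root state
#' z0 and rate sigma2 are profiled analytically; the remaining scalar
#' parameter is optimised by bounded Brent search restarted from five grid
#' points across its bounds (log-spaced for OU alpha).
#'
#' @param x Named per-species values (names = tip labels), n >= 4.
#' @param tree An [ape::phylo] with branch lengths.
#' @param model One of "BM", "OU", "WN", "EB", "delta", "lambda".
#' @return Object of class `trait_model`: `model`, `sigma2`, `z0`, `param`
#'   (named `alpha_ou`, `a_eb`, `delta` or `lambda`; `NULL` for BM/WN),
#'   `lnL`, `k_params` (2 for BM/WN, 3 otherwise), `AICc`, `n`, `at_bound`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' fit_trait_model(c(A = 2, B = 4, C = 9), tr, "BM")
#' @export
fit_trait_model <- function(x, tree, model = c("BM", "OU", "WN", "EB",
                                               "delta", "lambda")) {
  model <- match.arg(model)
  validate_phylogeny(tree)
  x <- .align_to_tips(x, tree)
  n <- length(x)
  if (n < 4L) stop("need at least 4 species")
  if (any(!is.finite(x))) stop("non-finite trait values")
  C <- ape::vcv.phylo(tree)
  if (any(!is.finite(tryCatch(chol(C), error = function(e) NaN))) &&
      model != "WN")
    stop("singular phylogenetic covariance (duplicate zero-length tips?)")
  Tmax <- max(diag(C))
  param <- NULL; at_bound <- FALSE
  if (model %in% c("BM", "WN")) {
    V <- if (model == "BM") C else diag(n)
    prof <- .profile_lnl(x, V)
    k_params <- 2L
  } else {
    bounds <- model_param_bounds(model, Tmax)
    trans <- if (model == "OU") log else identity
    inv <- if (model == "OU") exp else identity
    lo <- trans(bounds[1L]); hi <- trans(bounds[2L])
    clamp <- function(p) min(max(inv(p), bounds[1L]), bounds[2L])
    obj <- function(p) {
      V <- transform_covariance(C, model, clamp(p))
      v <- -.profile_lnl(x, V)$lnL
      if (!is.finite(v)) v <- .Machine$double.xmax / 2  # numerically infeasible
      v
    }
    grid <- seq(lo, hi, length.out = 5L)
    vals <- vapply(grid, obj, 0)
    best <- Inf; best_p <- grid[which.min(vals)]
    for (i in which(rank(vals, ties.method = "first") <= 2L)) {
      lo_i <- if (i == 1L) lo else grid[i - 1L]
      hi_i <- if (i == 5L) hi else grid[i + 1L]
      op <- stats::optimize(obj, c(lo_i, hi_i), tol = 1e-8)
      if (op$objective < best) { best <- op$objective; best_p <- op$minimum }
    }
    # endpoints can beat interior optima (e.g. lambda-hat = 1)
    for (p in c(lo, hi)) {
      v <- obj(p)
      if (v < best) { best <- v; best_p <- p }
    }
    param <- clamp(best_p)
    at_bound <- min(param - bounds[1L], bounds[2L] - param) <
      1e-6 * diff(bounds)
    prof <- .profile_lnl(x, transform_covariance(C, model, param))
    names(param) <- switch(model, OU = "alpha_ou", EB = "a_eb",
                           delta = "delta", lambda = "lambda")
    k_params <- 3L
  }
  structure(list(model = model, sigma2 = prof$sigma2, z0 = prof$z0,
                 param = param, lnL = prof$lnL, k_params = k_params,
                 AICc = if (n > k_params + 1) aicc(prof$lnL, k_params, n)
                        else NA_real_,
                 n = n,
                 at_bound = at_bound),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("Trait-evolution model ", x$model, " (ML, n = ", x$n, ")\n", sep = "")
  cat("  sigma2 = ", format(x$sigma2, digits = 6),
      ", z0 = ", format(x$z0, digits = 6), sep = "")
  if (!is.null(x$param))
    cat(", ", names(x$param), " = ", format(unname(x$param), digits = 6),
        if (x$at_bound) " (at bound)", sep = "")
  cat("\n  lnL = ", format(x$lnL, digits = 8), ", k = ", x$k_params,
      ", AICc = ", format(x$AICc, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.trait_model <- function(object, ...) {
  structure(object$lnL, df = object$k_params, nobs = object$n,
            class = "logLik")
}

#' @export
coef.trait_model <- function(object, ...) {
  c(sigma2 = object$sigma2, z0 = object$z0, object$param)
}

#' Sample-size corrected Akaike information criterion
#'
#' AICc = 2k - 2 lnL + 2k(k + 1)/(n - k - 1).
#'
#' @param lnL Log-likelihood at the ML estimate.
#' @param k_params Number of free parameters.
#' @param n Sample size; must exceed `k_params + 1`.
#' @return The AICc value.
#' @export
aicc <- function(lnL, k_params, n) {
  if (n <= k_params + 1) stop("n must exceed k_params + 1 for AICc")
  2 * k_params - 2 * lnL + 2 * k_params * (k_params + 1) / (n - k_params - 1)
}

#' Compare fitted models by AICc
#'
#' Computes delta-AICc relative to the best (lowest-AICc) model and Akaike
#' weights w_i = exp(-dAICc_i/2) / sum_j exp(-dAICc_j/2).
#'
#' @param fits A list of [fit_trait_model()] results, or a named numeric
#'   vector of AICc values.
#' @return Object of class `model_comparison`: a data frame with columns
#'   `model`, `lnL` (when available), `AICc`, `dAICc`, `weight`.
#' @export
compare_models <- function(fits) {
  if (is.numeric(fits)) {
    df <- data.frame(model = if (is.null(names(fits)))
      paste0("m", seq_along(fits)) else names(fits),
      lnL = NA_real_, AICc = as.numeric(fits))
  } else {
    if (length(fits) < 2L) stop("need at least two fits")
    df <- data.frame(model = vapply(fits, `[[`, "", "model"),
                     lnL = vapply(fits, `[[`, 0, "lnL"),
                     AICc = vapply(fits, `[[`, 0, "AICc"))
  }
  if (nrow(df) < 2L) stop("need at least two models")
  df$dAICc <- df$AICc - min(df$AICc)
  w <- exp(-df$dAICc / 2)
  df$weight <- w / sum(w)
  class(df) <- c("model_comparison", "data.frame")
  df
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (AICc):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Blomberg's K with permutation test
#'
#' K compares the observed ratio of the non-phylogenetic to the phylogenetic
#' mean squared error, MSE0/MSE, with its Brownian-motion expectation on the
#' tree, so K = 1 is expected under BM, K > 1 indicates more resemblance
#' among close relatives than BM predicts and K < 1 less.  Significance is
#' assessed by permuting tip values: P = (1 + #\{permutations with MSE <=
#' observed MSE\}) / (n_perm + 1).
#'
#' @param x Named per-species values; n >= 4.
#' @param tree An [ape::phylo].
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutations.
#' @return List of class `signal_result` with `K`, `p_value`, `n_perm`.
#' @export
blomberg_k <- function(x, tree, n_perm = 999L, seed = NULL) {
  validate_phylogeny(tree)
  x <- .align_to_tips(x, tree)
  n <- length(x)
  if (n < 4L) stop("need at least 4 species")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (stats::var(x) == 0) stop("zero variance in x")
  C <- ape::vcv.phylo(tree)
  Cinv <- solve(C)
  one <- rep(1, n)
  denom_1C1 <- as.numeric(one %*% Cinv %*% one)
  mse_pair <- function(v) {
    a <- as.numeric(one %*% Cinv %*% v) / denom_1C1
    r <- v - a
    c(mse0 = sum(r^2) / (n - 1),
      mse = as.numeric(r %*% Cinv %*% r) / (n - 1))
  }
  obs <- mse_pair(x)
  expected_ratio <- (sum(diag(C)) - n / denom_1C1) / (n - 1)
  K <- (obs["mse0"] / obs["mse"]) / expected_ratio
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- mse_pair(sample(x))
    if (perm["mse"] <= obs["mse"]) hits <- hits + 1L
  }
  structure(list(K = unname(K), p_value = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  if (!is.null(x$K))
    cat("Blomberg's K = ", format(x$K, digits = 4),
        " (P = ", format(x$p_value, digits = 3), ", ",
        x$n_perm, " permutations)\n", sep = "")
  if (!is.null(x$lambda_hat))
    cat("Pagel's lambda = ", format(x$lambda_hat, digits = 4),
        " (lnL = ", format(x$lnL_lambda, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Pagel's lambda as a phylogenetic-signal measure
#'
#' ML estimate of lambda (0 = star phylogeny / no signal, 1 = Brownian
#' motion) with its log-likelihood, via [fit_trait_model()].
#'
#' @inheritParams blomberg_k
#' @return List of class `signal_result` with `lambda_hat`, `lnL_lambda`
#'   and the underlying `fit`.
#' @export
pagel_lambda_signal <- function(x, tree) {
  fit <- fit_trait_model(x, tree, "lambda")
  structure(list(lambda_hat = unname(fit$param), lnL_lambda = fit$lnL,
                 fit = fit),
            class = "signal_result")
}

#' Ancestral states under Brownian motion
#'
#' GLS/ML reconstruction: the expectation of each internal node conditional
#' on the tip values under BM, anc = z0 + C_nt C_tt^{-1} (x - z0 1), where
#' C_nt holds shared path lengths between internal nodes and tips.  The
#' root estimate equals the profiled GLS root state z0.
#'
#' @param x Named per-species values.
#' @param tree An [ape::phylo].
#' @return Named numeric vector over internal nodes (ape numbering,
#'   n + 1 .. n + Nnode; the first entry is the root).
#' @export
ancestral_states_bm <- function(x, tree) {
  validate_phylogeny(tree)
  x <- .align_to_tips(x, tree)
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  root <- n + 1L
  depth <- D[root, ]
  nodes <- root:(n + tree$Nnode)
  tips <- seq_len(n)
  # shared path length between node a and tip i: (depth_a + depth_i - d_ai)/2
  Cnt <- outer(depth[nodes], depth[tips], `+`) - D[nodes, tips, drop = FALSE]
  Cnt <- Cnt / 2
  Ctt <- ape::vcv.phylo(tree)
  prof <- .profile_lnl(x, Ctt)
  anc <- prof$z0 + as.numeric(Cnt %*% solve(Ctt, x - prof$z0))
  stats::setNames(anc, nodes)
}

#' Evolutionary rate matrix from independent contrasts
#'
#' Estimates the m x m Brownian evolutionary covariance of m traits as the
#' mean outer product of the phylogenetically standardised independent
#' contrasts (divisor n - 1), equivalent to the GLS estimator about the
#' phylogenetic mean.
#'
#' @param X n x m matrix of per-species trait values, rownames = tip labels
#'   (a vector is treated as one trait).
#' @param tree An [ape::phylo].
#' @return Symmetric positive semidefinite m x m matrix.
#' @export
ratematrix <- function(X, tree) {
  validate_phylogeny(tree)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                   dimnames = list(names(X), "trait"))
  X <- as.matrix(X)
  if (is.null(rownames(X))) {
    if (nrow(X) != length(tree$tip.label)) stop("tree/tip mismatch")
    rownames(X) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, rownames(X))
  if (length(missing)) stop("tree/tip mismatch: no data for ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X); m <- ncol(X)
  if (n <= m) warning("fewer species than traits + 1; rate matrix is rank-deficient")
  pics <- apply(X, 2L, function(v) ape::pic(v, tree))
  crossprod(as.matrix(pics)) / (n - 1)
}

#' Simulate multivariate Brownian trait evolution
#'
#' Recursive root-to-tip simulation: each branch adds a zero-mean
#' multivariate normal increment with covariance `R * branch length`.
#'
#' @param tree An [ape::phylo].
#' @param R m x m trait covariance (PSD); a scalar is a 1-trait rate.
#' @param z0 Root state (length m, recycled).
#' @param n_sims Number of replicate simulations.
#' @param seed Optional integer seed; the same seed reproduces the output
#'   exactly.
#' @return Array n_tips x m x n_sims with tip-label rownames.
#' @export
sim_traits <- function(tree, R, z0 = 0, n_sims = 1L, seed = NULL) {
  validate_phylogeny(tree)
  R <- as.matrix(R)
  m <- nrow(R)
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
    stop("R is not positive semidefinite")
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), m) # R = A A'
  z0 <- rep_len(z0, m)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "cladewise")
  E <- nrow(tr$edge)
  Z <- matrix(stats::rnorm(E * n_sims * m), E * n_sims, m) %*% t(A)
  dim(Z) <- c(E, n_sims, m)
  Z <- Z * sqrt(tr$edge.length)          # recycles over sims and traits
  val <- array(0, c(ntip + nnode, n_sims, m))
  val[ntip + 1L, , ] <- rep(z0, each = n_sims)
  for (e in seq_len(E))
    val[tr$edge[e, 2L], , ] <- val[tr$edge[e, 1L], , ] + Z[e, , ]
  out <- val[seq_len(ntip), , , drop = FALSE]
  out <- aperm(out, c(1L, 3L, 2L))
  dimnames(out) <- list(tr$tip.label, colnames(R), NULL)
  out
}
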