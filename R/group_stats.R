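# Canonical variates analysis and permutation Procrustes ANOVA over
# feeding-preference / feeding-mode groupings.

#' Canonical variates analysis
#'
#' Ordination maximising among-group relative to within-group variance: the
#' canonical axes are eigenvectors of W^-1 B, with W the pooled within-group
#' covariance and B the between-group covariance of the group means.  When
#' raw shape coordinates (more variables than can support an invertible W)
#' are supplied they are first projected onto their leading principal
#' components.
#'
#' @param x Observations: an n x p numeric matrix (rows named), a
#'   [species_mean_shapes()] result, or a k x 2 x n array of shapes.
#' @param groups Group label per observation (>= 2 groups, none empty).
#' @param retain Number of leading PCs to keep when projecting raw shape
#'   coordinates; default `min(n - g, 20)`.  Ignored for already
#'   low-dimensional score input.
#' @return Object of class `cva_fit`: `scores` (n x (g - 1)),
#'   `proportions` (percent of among-group variance per axis, summing to
#'   100), `axes` (directions in the analysed space), `groups`,
#'   `retained_pcs`.
#' @export
cva <- function(x, groups, retain = NULL) {
  if (inherits(x, "list") && !is.null(x$shapes)) x <- x$shapes
  if (length(dim(x)) == 3L)
    x <- t(apply(x, 3L, flatten_coords))
  x <- as.matrix(x)
  groups <- as.factor(as.character(groups))
  n <- nrow(x)
  if (length(groups) != n) stop("one group label per observation required")
  g <- nlevels(groups)
  if (g < 2L) stop("need at least two groups")
  if (any(table(groups) < 1L)) stop("empty group")
  retained_pcs <- ncol(x)
  if (ncol(x) >= n - g + 1L) {
    retain <- if (is.null(retain)) min(n - g, 20L) else min(retain, n - g)
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    x <- pc$x[, seq_len(retain), drop = FALSE]
    retained_pcs <- retain
  }
  p <- ncol(x)
  grand <- colMeans(x)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(groups)) {
    xi <- x[groups == lev, , drop = FALSE]
    mi <- colMeans(xi)
    if (nrow(xi) > 1L)
      W <- W + crossprod(sweep(xi, 2L, mi))
    B <- B + nrow(xi) * tcrossprod(mi - grand)
  }
  W <- W / (n - g)
  ew <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ew) < 1e-10 * max(ew))
    stop("singular pooled within-group covariance after retaining ",
         p, " dimensions (deficient dimension ", which.min(ew), ")")
  eg <- eigen(solve(W, B))
  ord <- order(Re(eg$values), decreasing = TRUE)
  naxes <- min(g - 1L, p)
  vals <- pmax(Re(eg$values)[ord][seq_len(naxes)], 0)
  axes <- Re(eg$vectors)[, ord, drop = FALSE][, seq_len(naxes), drop = FALSE]
  scores <- sweep(x, 2L, grand) %*% axes
  colnames(scores) <- paste0("CV", seq_len(naxes))
  structure(list(scores = scores,
                 proportions = 100 * vals / sum(vals),
                 eigenvalues = vals, axes = axes, groups = groups,
                 retained_pcs = retained_pcs),
            class = "cva_fit")
}

#' @export
print.cva_fit <- function(x, ...) {
  cat("CVA: ", nrow(x$scores), " observations, ", nlevels(x$groups),
      " groups, ", ncol(x$scores), " axes (", x$retained_pcs,
      " dims analysed)\n", sep = "")
  cat("  % among-group variance:",
      paste(sprintf("%.1f", x$proportions), collapse = " "), "\n")
  invisible(x)
}

.panova_stats <- function(x, groups) {
  n <- nrow(x)
  grand <- colMeans(x)
  ss_total <- sum(sweep(x, 2L, grand)^2)
  ss_between <- 0
  for (lev in levels(groups)) {
    xi <- x[groups == lev, , drop = FALSE]
    ss_between <- ss_between + nrow(xi) * sum((colMeans(xi) - grand)^2)
  }
  ss_within <- ss_total - ss_between
  g <- nlevels(groups)
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  c(ss_between = ss_between, ss_within = ss_within, ss_total = ss_total,
    df_between = g - 1, df_within = n - g, F = f)
}

#' Procrustes ANOVA with permutation test
#'
#' Goodall-type variance partitioning of shape: sums of squares are squared
#' tangent-space (Euclidean) distances of the flattened aligned coordinates,
#' SS_total about the grand mean and SS_between = sum_g n_g d^2(mean_g,
#' grand mean); F = (SS_B/(g - 1)) / (SS_W/(N - g)).  Significance by
#' unrestricted permutation of group labels: P = (1 + #\{permutations with
#' F >= F_obs\}) / (n_perm + 1).
#'
#' @param x A [gpa()] result, a k x 2 x n array of aligned shapes, or an
#'   n x p score matrix (e.g. ln CS as a one-column matrix for the size
#'   ANOVA).
#' @param groups Factor of group labels, one per observation.
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Optional integer seed.
#' @return Object of class `anova_shape`: SS components, df pair, `F`,
#'   `p_value`, `n_perm`.
#' @export
procrustes_anova <- function(x, groups, n_perm = 999L, seed = NULL) {
  if (inherits(x, "gpa")) x <- x$aligned
  if (length(dim(x)) == 3L) x <- t(apply(x, 3L, flatten_coords))
  x <- as.matrix(x)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 1L)) stop("empty group")
  if (length(groups) != nrow(x)) stop("one group label per observation")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  obs <- .panova_stats(x, groups)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    f <- .panova_stats(x, sample(groups))["F"]
    if (f >= obs["F"]) hits <- hits + 1L
  }
  structure(list(ss_between = unname(obs["ss_between"]),
                 ss_within = unname(obs["ss_within"]),
                 ss_total = unname(obs["ss_total"]),
                 df = unname(obs[c("df_between", "df_within")]),
                 F = unname(obs["F"]),
                 p_value = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm),
            class = "anova_shape")
}

#' @export
print.anova_shape <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA: F_%d,%d = %.3f, P = %.4g (%d permutations)\n",
              x$df[1L], x$df[2L], x$F, x$p_value, x$n_perm))
  cat(sprintf("  SS between %.4g, within %.4g, total %.4g\n",
              x$ss_between, x$ss_within, x$ss_total))
  invisible(x)
}
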