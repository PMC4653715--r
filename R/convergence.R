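# Pairwise distance-contrast analysis: species pairs morphologically more
# similar than Brownian motion predicts given their phylogenetic distance.

.gls_root <- function(X, C) {
  n <- nrow(X)
  Cinv1 <- solve(C, rep(1, n))
  as.numeric(crossprod(Cinv1, X)) / sum(Cinv1)
}

#' Pairwise distance-contrast convergence analysis
#'
#' For every species pair, compares the observed morphological distance (in
#' the retained shape-score space) with the distribution of distances under
#' neutral Brownian evolution on the tree: (1) the evolutionary rate matrix
#' is estimated from the scores; (2) `n_sims` multivariate BM datasets are
#' simulated with that rate matrix and the GLS root state; (3) each pair's
#' simulated-distance sample is bootstrapped (`n_boot` resamples of the
#' simulation replicates) to a per-pair lower 95% threshold (the bootstrap
#' estimate of the 2.5th percentile of that pair's simulated distances);
#' (4) pairs whose observed distance falls below that threshold are flagged
#' convergent.  Under the null about 2.5% of pairs are
#' expected to be flagged.
#'
#' @param species_scores n x m matrix of species mean scores, rownames =
#'   tip labels (a named vector is one trait).
#' @param tree An [ape::phylo].
#' @param exclude Tip labels (e.g. known outliers) pruned from both the
#'   data and the tree before the analysis; an excluded label absent from
#'   the tree is an error.
#' @param n_sims Number of BM simulations (>= 100).
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param seed Optional integer seed; the whole analysis is reproducible
#'   under it.
#' @return Object of class `distance_contrast`: `pairs` (data frame with
#'   `sp1`, `sp2`, `phylo_dist`, `morph_dist`, `sim_mean`, `diff` =
#'   observed - simulated mean, `lower95`, `convergent`),
#'   `convergent_count`, `expected_count` (= 0.025 x pair count), `n_sims`,
#'   `n_boot`.
#' @export
distance_contrast_analysis <- function(species_scores, tree, exclude = NULL,
                                       n_sims = 1000L, n_boot = 1000L,
                                       seed = NULL) {
  validate_phylogeny(tree)
  if (n_sims < 100L) stop("n_sims must be at least 100")
  if (n_boot < 100L) stop("n_boot must be at least 100")
  X <- species_scores
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                   dimnames = list(names(X), "trait"))
  X <- as.matrix(X)
  if (length(exclude)) {
    absent <- setdiff(exclude, tree$tip.label)
    if (length(absent))
      stop("excluded label absent from tree: ", paste(absent, collapse = ", "))
    tree <- prune_to_taxa(tree, setdiff(tree$tip.label, exclude))
    X <- X[setdiff(rownames(X), exclude), , drop = FALSE]
  }
  missing <- setdiff(tree$tip.label, rownames(X))
  if (length(missing)) stop("no scores for tip(s): ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  obs_d <- stats::dist(X)
  if (max(obs_d) < 1e-12)
    warning("all species have identical scores; observed distances are degenerate")
  phy_d <- cophenetic_distances(tree)
  pair_idx <- which(lower.tri(phy_d), arr.ind = TRUE)
  # dist() enumerates pairs column-major over the lower triangle, same order
  sp1 <- rownames(phy_d)[pair_idx[, 1L]]
  sp2 <- rownames(phy_d)[pair_idx[, 2L]]
  if (!is.null(seed)) set.seed(seed)
  R <- ratematrix(X, tree)
  z0 <- .gls_root(X, ape::vcv.phylo(tree))
  sims <- sim_traits(tree, R, z0, n_sims = n_sims)
  npair <- length(obs_d)
  D <- matrix(NA_real_, npair, n_sims)
  for (s in seq_len(n_sims))
    D[, s] <- as.vector(stats::dist(sims[, , s]))
  sim_mean <- rowMeans(D)
  # Per-pair lower 95% threshold of the simulated-distance distribution,
  # bootstrap-estimated: each resample draws n_sims simulation replicates
  # with replacement (jointly for all pairs) and takes its 2.5th percentile;
  # the threshold is the mean over resamples.  Because the resampled values
  # are order statistics of each pair's sorted distances, one shared set of
  # resampled index order statistics serves every pair.
  Dsort <- apply(D, 1L, sort.int)              # n_sims x npair
  h <- (n_sims - 1) * 0.025 + 1
  lo <- floor(h); hi <- ceiling(h); gam <- h - lo
  Jlo <- integer(n_boot); Jhi <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sort.int(sample.int(n_sims, replace = TRUE), method = "radix")
    Jlo[b] <- idx[lo]; Jhi[b] <- idx[hi]
  }
  lower95 <- colMeans((1 - gam) * Dsort[Jlo, , drop = FALSE] +
                        gam * Dsort[Jhi, , drop = FALSE])
  obs <- as.vector(obs_d)
  pairs <- data.frame(sp1 = sp1, sp2 = sp2,
                      phylo_dist = phy_d[pair_idx],
                      morph_dist = obs,
                      sim_mean = sim_mean,
                      diff = obs - sim_mean,
                      lower95 = lower95,
                      convergent = obs < lower95)
  structure(list(pairs = pairs,
                 convergent_count = sum(pairs$convergent),
                 expected_count = 0.025 * npair,
                 n_sims = n_sims, n_boot = n_boot,
                 rate_matrix = R, z0 = z0),
            class = "distance_contrast")
}

#' @export
print.distance_contrast <- function(x, ...) {
  cat("Distance-contrast analysis: ", nrow(x$pairs), " species pairs, ",
      x$n_sims, " BM simulations, ", x$n_boot, " bootstrap resamples\n",
      sep = "")
  cat("  convergent pairs (observed < lower 95% of simulated): ",
      x$convergent_count, " (", format(x$expected_count, digits = 3),
      " expected by chance)\n", sep = "")
  invisible(x)
}
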