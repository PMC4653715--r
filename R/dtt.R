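# Disparity-through-time curves and the morphological disparity index
# against a simulated Brownian-motion null.

#' Disparity of a trait matrix
#'
#' Mean squared pairwise Euclidean distance over all unordered row pairs;
#' 0 for a single row.
#'
#' @param X Numeric matrix (rows = species) or vector (one trait).
#' @return Non-negative scalar.
#' @export
disparity_of <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  m <- nrow(X)
  if (m < 2L) return(0)
  ss <- m * sum(X^2) - sum(colSums(X)^2)
  ss / (m * (m - 1) / 2)
}

# Per-internal-node relative times and the lineages (clades) alive just
# after each divergence; cached tree bookkeeping for dtt.
.dtt_tree_info <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  Tmax <- max(depth[seq_len(n)])
  node_ids <- (n + 1L):nn
  ord <- order(depth[node_ids])
  times <- depth[node_ids][ord] / Tmax
  parent_depth <- depth[tree$edge[, 1L]] / Tmax
  child_depth <- depth[tree$edge[, 2L]] / Tmax
  po_edge <- ape::reorder.phylo(tree, "postorder")$edge
  mcount <- c(rep(1L, n), integer(tree$Nnode))
  for (e in seq_len(nrow(po_edge)))
    mcount[po_edge[e, 1L]] <- mcount[po_edge[e, 1L]] + mcount[po_edge[e, 2L]]
  # lineages crossing the i-th divergence time: edges spanning t, counting
  # an edge that ends exactly at t (the diverging lineage) as one clade
  alive_child <- lapply(seq_along(times), function(i) {
    if (i == 1L) return(n + 1L)          # root slice: the whole clade
    t <- times[i]
    tree$edge[parent_depth < t - 1e-12 & child_depth >= t - 1e-12, 2L]
  })
  list(n = n, n_nodes = nn, times = times, po_edge = po_edge,
       mcount = mcount, alive_child = alive_child, root = n + 1L)
}

# Mean relative subclade disparity at each node time; per-clade disparities
# come from a postorder accumulation of tip sums, so one pass is O(nodes x m).
.dtt_values <- function(X, info) {
  m <- info$mcount
  S <- matrix(0, info$n_nodes, ncol(X))
  S[seq_len(info$n), ] <- X
  Q <- c(rowSums(X^2), numeric(info$n_nodes - info$n))
  for (e in seq_len(nrow(info$po_edge))) {
    p <- info$po_edge[e, 1L]; ch <- info$po_edge[e, 2L]
    S[p, ] <- S[p, ] + S[ch, ]
    Q[p] <- Q[p] + Q[ch]
  }
  npairs <- m * (m - 1) / 2
  disp <- ifelse(m > 1L, (m * Q - rowSums(S^2)) / pmax(npairs, 1), 0)
  total <- disp[info$root]
  if (total <= 0) stop("zero total disparity")
  vapply(info$alive_child, function(ch) mean(disp[ch]) / total, 0)
}

#' Disparity-through-time curve
#'
#' At each internal-node time (relative: 0 = root, 1 = deepest tip) the
#' curve value is the mean, over every lineage crossing that time, of the
#' disparity of the tips descending from that lineage divided by the
#' disparity of the whole clade.  The root value is 1 by construction (the
#' single lineage at the root subtends all tips).
#'
#' @param X Per-species trait matrix (rownames = tip labels) or named vector.
#' @param tree An [ape::phylo] with >= 3 tips.
#' @return List with `times` (relative node times, increasing from 0) and
#'   `observed` (mean relative subclade disparity at each time).
#' @export
dtt_curve <- function(X, tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 3L) stop("tree needs at least 3 tips")
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                   dimnames = list(names(X), "trait"))
  X <- as.matrix(X)
  if (!is.null(rownames(X))) {
    missing <- setdiff(tree$tip.label, rownames(X))
    if (length(missing)) stop("no data for tip(s): ",
                              paste(utils::head(missing, 5L), collapse = ", "))
    X <- X[tree$tip.label, , drop = FALSE]
  } else if (nrow(X) != length(tree$tip.label)) stop("tree/data mismatch")
  info <- .dtt_tree_info(tree)
  list(times = info$times, observed = .dtt_values(X, info))
}

# Integral of a step curve (value holds from each time to the next) over
# [0, cutoff]; the last value extends from the last node time to cutoff.
.step_integral <- function(times, values, cutoff) {
  breaks <- c(times, max(cutoff, times[length(times)]))
  widths <- pmax(pmin(breaks[-1L], cutoff) - pmin(breaks[-length(breaks)], cutoff), 0)
  sum(values * widths)
}

#' Morphological disparity index against a Brownian null
#'
#' Simulates trait evolution `n_sims` times under Brownian motion with the
#' rate matrix estimated from the data ([ratematrix()]) and the GLS root
#' state, computes the disparity-through-time curve of every simulation on
#' the shared node-time grid, and summarises: MDI is the integral of
#' (observed - simulation median) over relative time \[0, cutoff\] treating
#' the curves as step functions between node times; positive MDI means more
#' subclade overlap in morphospace than BM predicts.  The two-sided P value
#' is the proportion of simulations whose own MDI (against the same median)
#' is at least as extreme as the observed MDI in its direction, doubled and
#' capped at 1.
#'
#' @param X Per-species trait matrix (rownames = tip labels) or named
#'   vector (single-axis convenience form).
#' @param tree An [ape::phylo].
#' @param n_sims Number of BM simulations (>= 100).
#' @param cutoff Fraction of relative tree height integrated over, in
#'   (0, 1\]; the default 0.9 guards against tip-ward over-dispersion.
#' @param seed Optional integer seed.
#' @param observed Optional precomputed [dtt_curve()] result for `X` (saves
#'   one pass; recomputed when `NULL`).
#' @return Object of class `dtt_result`: `times`, `observed`, `sim_median`,
#'   `lower`, `upper` (95% envelope), `MDI`, `p_value`, `cutoff`, `n_sims`.
#' @export
mdi <- function(X, tree, n_sims = 1000L, cutoff = 0.9, seed = NULL,
                observed = NULL) {
  validate_phylogeny(tree)
  if (n_sims < 100L) stop("n_sims must be at least 100")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                   dimnames = list(names(X), "trait"))
  X <- as.matrix(X)
  X <- X[tree$tip.label, , drop = FALSE]
  info <- .dtt_tree_info(tree)
  obs <- if (is.null(observed)) .dtt_values(X, info) else observed$observed
  if (!is.null(seed)) set.seed(seed)
  R <- ratematrix(X, tree)
  z0 <- .gls_root(X, ape::vcv.phylo(tree))
  sims <- sim_traits(tree, R, z0, n_sims = n_sims)
  sim_curves <- matrix(NA_real_, n_sims, length(info$times))
  for (s in seq_len(n_sims)) {
    Xs <- sims[, , s, drop = FALSE]
    dim(Xs) <- dim(sims)[1:2]
    sim_curves[s, ] <- .dtt_values(Xs, info)
  }
  med <- apply(sim_curves, 2L, stats::median)
  lower <- apply(sim_curves, 2L, stats::quantile, probs = 0.025, names = FALSE)
  upper <- apply(sim_curves, 2L, stats::quantile, probs = 0.975, names = FALSE)
  MDI <- .step_integral(info$times, obs - med, cutoff)
  sim_mdi <- apply(sim_curves, 1L, function(v)
    .step_integral(info$times, v - med, cutoff))
  p <- if (MDI > 0) mean(sim_mdi >= MDI)
       else if (MDI < 0) mean(sim_mdi <= MDI)
       else 1
  structure(list(times = info$times, observed = obs, sim_median = med,
                 lower = lower, upper = upper, MDI = MDI,
                 p_value = min(1, 2 * p), cutoff = cutoff, n_sims = n_sims),
            class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat("Disparity through time: ", length(x$times), " node times, ",
      x$n_sims, " BM simulations\n", sep = "")
  cat(sprintf("  MDI over [0, %.2g] = %.4f (P = %.4g, two-sided)\n",
              x$cutoff, x$MDI, x$p_value))
  invisible(x)
}
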