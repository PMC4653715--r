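# Shared fixtures and independent oracles, built in code at test time.

three_taxon_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# Random tree with branch lengths (ape::rtree draws uniform lengths).
rtree_bl <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  opercle::validate_phylogeny(ape::rtree(n))
}

# Simulate one univariate BM dataset on a tree via its Cholesky factor --
# an independent route from sim_traits' edge-wise recursion.
bm_sim_chol <- function(tree, sigma2 = 1, z0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv.phylo(tree)
  stats::setNames(z0 + drop(crossprod(chol(sigma2 * C), rnorm(nrow(C)))),
                  rownames(C))
}

# Dense multivariate-normal log-density oracle evaluated at given (z0,
# sigma2): the raw density formula via determinant() and solve(), an
# independent route from the Cholesky-based profiled assembly.
dense_lnl_at <- function(x, V, z0, sigma2) {
  n <- length(x)
  S <- sigma2 * V
  r <- x - z0
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       sum(r * solve(S, r))))
}

# Independent brute-force outline walker: marches the closed polygon
# segment by segment and emits k points at arc positions j * P / k.
walk_outline <- function(pts, k) {
  n <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  P <- sum(seg)
  out <- matrix(NA_real_, k, 2)
  for (j in seq_len(k)) {
    target <- (j - 1) * P / k
    acc <- 0; i <- 1
    while (i <= n && acc + seg[i] < target - 1e-12) {
      acc <- acc + seg[i]; i <- i + 1
    }
    frac <- (target - acc) / seg[i]
    out[j, ] <- closed[i, ] + frac * (closed[i + 1, ] - closed[i, ])
  }
  out
}

# Regular n-gon on a circle (counterclockwise as constructed).
regular_polygon <- function(n, r = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(r * cos(t), r * sin(t))
}

# Arc-length positions of polygon vertices by brute-force segment summation.
arc_positions <- function(pts) {
  closed <- rbind(pts, pts[1L, ])
  c(0, cumsum(sqrt(rowSums(diff(closed)^2))))
}
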