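# Tree covariance construction and the branch-length/covariance transforms
# defining the candidate trait-evolution models.

#' Phylogenetic variance-covariance matrix
#'
#' C[i, j] is the shared path length from the root to the most recent common
#' ancestor of tips i and j; C[i, i] is the root-to-tip distance.  Symmetric
#' and positive semidefinite; the diagonal is constant iff the tree is
#' ultrametric.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @return List of class `phylo_vcv` with `C` (n x n, dimnames = tip labels),
#'   `tip_order` and `T` (maximum tip depth).
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  structure(list(C = C, tip_order = rownames(C), T = max(diag(C))),
            class = "phylo_vcv")
}

#' Patristic (cophenetic) distances between tips
#'
#' d[i, j] = C[i, i] + C[j, j] - 2 C[i, j]; zero diagonal, symmetric.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @return n x n distance matrix with tip-label dimnames.
#' @export
cophenetic_distances <- function(tree) {
  validate_phylogeny(tree)
  ape::cophenetic.phylo(tree)
}

#' Model-specific covariance transforms
#'
#' Applies the branch-length/covariance transform that defines each
#' candidate trait-evolution model to a phylogenetic covariance matrix C:
#'
#' * `lambda`: off-diagonal elements multiplied by lambda (0 = star
#'   phylogeny, 1 = Brownian motion), diagonal unchanged.
#' * `delta`: every element raised to the power delta, then rescaled so the
#'   maximum diagonal equals the original tree height T (node-depth power
#'   transform; delta > 1 concentrates change toward the tips).
#' * `EB` (early burst / ACDC): element-wise (exp(a C) - 1)/a with the
#'   a -> 0 limit C; negative a decelerates, positive a accelerates.
#' * `OU`: stationary Ornstein-Uhlenbeck covariance on the depth matrix,
#'   V[i, j] = exp(-2 alpha (T - C[i, j])) (1 - exp(-2 alpha C[i, j])) /
#'   (2 alpha).
#' * `BM`: C unchanged; `WN`: identity scaled to the tree height's units
#'   (diag of ones).
#'
#' @param C n x n phylogenetic covariance (matrix or [phylo_vcv()] result).
#' @param model One of "BM", "OU", "WN", "EB", "delta", "lambda".
#' @param param Scalar parameter: lambda in \[0, 1\], delta in (0, 100\],
#'   EB a in \[-20/T, 20/T\], OU alpha in \[1e-8, 500\]; ignored for BM/WN.
#' @return Transformed covariance matrix.
#' @export
transform_covariance <- function(C, model = c("BM", "OU", "WN", "EB",
                                              "delta", "lambda"),
                                 param = NULL) {
  model <- match.arg(model)
  if (inherits(C, "phylo_vcv")) C <- C$C
  C <- as.matrix(C)
  Tmax <- max(diag(C))
  bounds <- model_param_bounds(model, Tmax)
  if (model %in% c("BM", "WN")) {
    if (model == "BM") return(C)
    V <- diag(nrow(C))
    dimnames(V) <- dimnames(C)
    return(V)
  }
  if (is.null(param)) stop("model ", model, " needs a parameter")
  if (param < bounds[1L] || param > bounds[2L])
    stop(model, " parameter ", format(param), " outside [",
         format(bounds[1L]), ", ", format(bounds[2L]), "]")
  V <- switch(model,
    lambda = {
      V <- C * param
      diag(V) <- diag(C)
      V
    },
    delta = {
      V <- C^param
      V * (Tmax / max(diag(V)))
    },
    EB = {
      if (abs(param) < 1e-12) C
      else (exp(param * C) - 1) / param
    },
    OU = {
      a <- param
      exp(-2 * a * (Tmax - C)) * (1 - exp(-2 * a * C)) / (2 * a)
    })
  dimnames(V) <- dimnames(C)
  V
}

#' Parameter bounds per trait-evolution model
#'
#' @param model Model name.
#' @param T Tree height (maximum tip depth); enters the EB bound.
#' @return Length-2 numeric vector (lower, upper); `c(NA, NA)` for BM/WN.
#' @export
model_param_bounds <- function(model, T = 1) {
  switch(model,
         lambda = c(0, 1),
         delta = c(1e-5, 100),
         EB = c(-20 / T, 20 / T),
         OU = c(1e-8, 500),
         BM = , WN = c(NA_real_, NA_real_),
         stop("unknown model ", model))
}

#' Prune a phylogeny to a set of tips
#'
#' Induced subtree on `labels`; degree-2 nodes created by the pruning are
#' collapsed with branch lengths merged additively, so patristic distances
#' among the kept tips are preserved.
#'
#' @param tree An [ape::phylo].
#' @param labels Tip labels to keep (subset of the tree's tips).
#' @return Pruned [ape::phylo].
#' @export
prune_to_taxa <- function(tree, labels) {
  validate_phylogeny(tree)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (setequal(labels, tree$tip.label)) return(tree)
  ape::keep.tip(tree, labels)
}

#' Node depths from the root
#'
#' Root depth 0; every other node's depth is its parent's depth plus the
#' connecting branch length.  Optionally scaled by the maximum tip depth so
#' the root maps to 0 and the deepest tip to 1.
#'
#' @param tree An [ape::phylo].
#' @param scale Divide by the maximum tip depth?
#' @return Named numeric vector over tips then internal nodes (ape node
#'   numbering; names for tips are tip labels).
#' @export
node_depths <- function(tree, scale = FALSE) {
  validate_phylogeny(tree)
  d <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  if (scale) d <- d / max(d[seq_len(n)])
  names(d) <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  d
}
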