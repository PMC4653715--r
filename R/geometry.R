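# Outline resampling, Procrustes superimposition and ordination.
# Flattening convention throughout: a k x 2 configuration becomes the
# length-2k vector (x1, y1, x2, y2, ...).

flatten_coords <- function(coords) as.vector(t(coords))

unflatten_coords <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

.center <- function(coords) sweep(coords, 2L, colMeans(coords))

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the points from their
#' centroid; scales linearly with the configuration (CS(c x) = c CS(x)).
#'
#' @param coords Two-column coordinate matrix (>= 1 point).
#' @return Non-negative scalar; 0 for a single point.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  sqrt(sum(.center(coords)^2))
}

signed_area <- function(coords) {
  x <- coords[, 1L]; y <- coords[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Construct a landmark configuration
#'
#' @param coords k x 2 matrix of ordered semilandmarks.
#' @param specimen_id,species_code Identifiers.
#' @param centroid_size Optional pre-computed centroid size; recomputed from
#'   `coords` when missing.
#' @return Object of class `landmark_config`.
#' @export
landmark_config <- function(coords, specimen_id = NA_character_,
                            species_code = NA_character_,
                            centroid_size = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must be k x 2")
  if (is.null(centroid_size)) centroid_size <- centroid_size(coords)
  structure(list(coords = unname(coords), centroid_size = centroid_size,
                 specimen_id = as.character(specimen_id),
                 species_code = as.character(species_code)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration ", x$specimen_id, ": ", nrow(x$coords),
      " points, CS = ", format(x$centroid_size, digits = 6), "\n", sep = "")
  invisible(x)
}

discrete_curvature <- function(pts) {
  n <- nrow(pts)
  prv <- pts[c(n, 1L:(n - 1L)), , drop = FALSE]
  nxt <- pts[c(2L:n, 1L), , drop = FALSE]
  e1 <- pts - prv
  e2 <- nxt - pts
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  cross <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  dot <- rowSums(e1 * e2)
  theta <- atan2(cross, dot)           # exterior turning angle
  abs(theta) / pmax((l1 + l2) / 2, .Machine$double.eps)
}

#' Locate the homologous start point of an outline
#'
#' Returns the index of the vertex with maximal discrete curvature within
#' the dorsal (upper-y) half of the outline, emulating the type II landmark
#' at the maximum of curvature of the dorsal margin used to anchor the
#' semilandmark scheme.  Ties are broken by the lowest index.
#'
#' @param outline An [outline_spec()] (or bare k x 2 matrix) with >= 5 points.
#' @return Integer vertex index into the outline's points.
#' @export
detect_start_point <- function(outline) {
  pts <- if (inherits(outline, "outline_spec")) outline$points else as.matrix(outline)
  n <- nrow(pts)
  if (n < 5L) stop("need at least 5 points to estimate curvature")
  kappa <- discrete_curvature(pts)
  closed <- rbind(pts, pts[1L, ])
  per <- sum(sqrt(rowSums(diff(closed)^2)))
  if (all(kappa < 1e-12) || abs(signed_area(pts)) < 1e-12 * per^2)
    stop("outline is collinear; no dorsal curvature maximum")
  dorsal <- pts[, 2L] > mean(pts[, 2L])
  if (!any(dorsal)) dorsal <- rep(TRUE, n)
  kd <- ifelse(dorsal, kappa, -Inf)
  mx <- max(kd)
  which(kd >= mx - 1e-12 * max(mx, 1))[1L]
}

#' Resample an outline to k equidistant semilandmarks
#'
#' Places `k` points equally spaced by arc length along the piecewise-linear
#' closed curve, traversed clockwise (negative signed area), starting at a
#' homologous start point.
#'
#' @param outline An [outline_spec()].
#' @param k Number of semilandmarks (default 100).
#' @param start `"auto"` to locate the start point with
#'   [detect_start_point()], or a vertex index to use directly.
#' @param max_k Upper bound on `k` (guards against typos).
#' @return A [landmark_config()] with `k` points; its first point is the
#'   start point and its centroid size is computed from the resampled points.
#' @export
resample_outline <- function(outline, k = 100L, start = "auto", max_k = 4096L) {
  if (!inherits(outline, "outline_spec")) stop("outline must be an outline_spec")
  if (k < 3L) stop("k must be at least 3")
  if (k > max_k) stop("k exceeds configured maximum of ", max_k)
  pts <- outline$points
  n <- nrow(pts)
  idx <- if (identical(start, "auto")) detect_start_point(outline) else {
    start <- as.integer(start)
    if (start < 1L || start > n) stop("start index out of range")
    start
  }
  pts <- pts[c(idx:n, seq_len(idx - 1L)), , drop = FALSE]
  if (signed_area(pts) > 0)            # enforce clockwise traversal
    pts <- pts[c(1L, n:2L), , drop = FALSE]
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  per <- cum[n + 1L]
  if (per <= 0) stop("degenerate outline: zero perimeter")
  target <- (seq_len(k) - 1L) * per / k
  seg_idx <- findInterval(target, cum, rightmost.closed = TRUE)
  seg_idx[seg_idx > n] <- n
  frac <- (target - cum[seg_idx]) / pmax(seg[seg_idx], .Machine$double.eps)
  out <- closed[seg_idx, , drop = FALSE] +
    frac * (closed[seg_idx + 1L, , drop = FALSE] - closed[seg_idx, , drop = FALSE])
  landmark_config(out, specimen_id = outline$specimen_id,
                  species_code = outline$species_code)
}

# Optimal rotation (no reflection) aligning X onto M, both centered.
.opt_rotation <- function(X, M) {
  s <- svd(crossprod(X, M))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes alignment
#'
#' Iterative superimposition removing translation (centering), scale
#' (each configuration scaled to unit centroid size) and rotation (orthogonal
#' rotation onto the running consensus, reflections disallowed).  The
#' consensus is re-estimated as the arithmetic mean until its displacement
#' falls below `tol`.
#'
#' @param configs List of [landmark_config()] objects (or k x 2 matrices)
#'   with a common k; at least two.
#' @param tol Convergence tolerance on the consensus displacement
#'   (root summed squared coordinate change).
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return Object of class `gpa` with elements `aligned` (k x 2 x n array),
#'   `mean_shape` (k x 2 consensus), `centroid_sizes` (pre-scaling CS),
#'   `specimen_ids`, `species_codes`, `iterations`, `converged`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2L) stop("need at least two configurations")
  get_coords <- function(cf) if (inherits(cf, "landmark_config")) cf$coords else as.matrix(cf)
  coords <- lapply(configs, get_coords)
  k <- nrow(coords[[1L]])
  if (any(vapply(coords, nrow, 0L) != k)) stop("configurations differ in k")
  n <- length(coords)
  cs <- vapply(coords, centroid_size, 0)
  if (any(cs <= 0)) stop("degenerate configuration with zero centroid size")
  scaled <- lapply(seq_len(n), function(i) .center(coords[[i]]) / cs[i])
  consensus <- scaled[[1L]]
  consensus <- consensus / centroid_size(consensus)
  iterations <- 0L; converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    aligned <- lapply(scaled, function(X) X %*% .opt_rotation(X, consensus))
    new_consensus <- Reduce(`+`, aligned) / n
    new_consensus <- .center(new_consensus)
    new_consensus <- new_consensus / centroid_size(new_consensus)
    shift <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (shift < tol) { converged <- TRUE; scaled <- aligned; break }
    if (iterations >= max_iter) {
      warning("GPA did not converge in ", max_iter, " iterations")
      scaled <- aligned; break
    }
  }
  arr <- array(unlist(scaled), dim = c(k, 2L, n))
  ids <- vapply(configs, function(cf)
    if (inherits(cf, "landmark_config")) cf$specimen_id else NA_character_, "")
  spp <- vapply(configs, function(cf)
    if (inherits(cf, "landmark_config")) cf$species_code else NA_character_, "")
  dimnames(arr) <- list(NULL, c("x", "y"), ids)
  structure(list(aligned = arr,
                 mean_shape = Reduce(`+`, scaled) / n,
                 centroid_sizes = stats::setNames(cs, ids),
                 specimen_ids = ids, species_codes = spp,
                 iterations = iterations, converged = converged),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat("Procrustes alignment: ", dim(x$aligned)[3L], " configurations, k = ",
      dim(x$aligned)[1L], ", ", x$iterations, " iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Root summed squared coordinate difference after centering, scaling both
#' configurations to unit centroid size and optimally rotating one onto the
#' other (reflections disallowed).  Symmetric; zero iff the shapes are
#' related by a similarity transform.
#'
#' @param a,b k x 2 matrices or [landmark_config()] objects with equal k.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  A <- if (inherits(a, "landmark_config")) a$coords else as.matrix(a)
  B <- if (inherits(b, "landmark_config")) b$coords else as.matrix(b)
  if (nrow(A) != nrow(B)) stop("configurations differ in k")
  A <- .center(A); A <- A / centroid_size(A)
  B <- .center(B); B <- B / centroid_size(B)
  sqrt(sum((A %*% .opt_rotation(A, B) - B)^2))
}

.fix_pc_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

.make_shape_space <- function(X, is_form, k) {
  if (nrow(X) < 3L) stop("need at least 3 observations for a PCA")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (sum(Xc^2) < 1e-24) stop("zero total variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- seq_along(ev)
  fx <- .fix_pc_signs(pc$x[, keep, drop = FALSE],
                      pc$rotation[, keep, drop = FALSE])
  structure(list(scores = fx$scores, loadings = fx$loadings,
                 eigenvalues = ev, proportions = ev / sum(ev),
                 center = ctr, k = k, is_form_space = is_form),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(if (x$is_form_space) "Form-space" else "Shape-space",
      " PCA: ", nrow(x$scores), " observations, ",
      length(x$eigenvalues), " axes\n", sep = "")
  p <- utils::head(x$proportions, 5L)
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", p), collapse = " "), "\n")
  invisible(x)
}

#' Principal component analysis of aligned shapes
#'
#' PCA of the covariance of the flattened Procrustes-aligned coordinates.
#' The tangent-space projection is taken as the identity (small-variation
#' assumption).  The shape space has at most min(n - 1, 2k - 4) meaningful
#' dimensions; trailing numerically-zero eigenvalues are retained but carry
#' essentially no variance.  PC signs follow the convention that each axis's
#' largest-magnitude loading is positive.
#'
#' @param alignment A [gpa()] result, or a plain n x 2k score matrix.
#' @return A `shape_space` with scores, loadings, eigenvalues, proportions.
#' @export
shape_pca <- function(alignment) {
  X <- if (inherits(alignment, "gpa")) {
    t(apply(alignment$aligned, 3L, flatten_coords))
  } else as.matrix(alignment)
  k <- if (inherits(alignment, "gpa")) dim(alignment$aligned)[1L] else ncol(X) / 2
  sp <- .make_shape_space(X, is_form = FALSE, k = k)
  if (inherits(alignment, "gpa"))
    rownames(sp$scores) <- alignment$specimen_ids
  sp
}

#' Form-space principal component analysis
#'
#' PCA of the flattened aligned coordinates augmented with the natural
#' logarithm of centroid size, mixing size back into the ordination.
#'
#' @param alignment A [gpa()] result (its retained centroid sizes must all
#'   be positive).
#' @return A `shape_space` with `is_form_space = TRUE`; the final loading row
#'   corresponds to ln CS.
#' @export
form_pca <- function(alignment) {
  if (!inherits(alignment, "gpa")) stop("alignment must be a gpa result")
  if (any(alignment$centroid_sizes <= 0)) stop("centroid sizes must be > 0")
  X <- cbind(t(apply(alignment$aligned, 3L, flatten_coords)),
             lnCS = log(alignment$centroid_sizes))
  sp <- .make_shape_space(X, is_form = TRUE, k = dim(alignment$aligned)[1L])
  rownames(sp$scores) <- alignment$specimen_ids
  sp
}

#' Broken-stick assessment of eigenvalue proportions
#'
#' Expected proportion of variance for axis j of p under the broken-stick
#' null, b_j = (1/p) * sum_{i=j..p} 1/i; an axis is flagged significant when
#' its observed proportion exceeds its broken-stick expectation.  `p` is the
#' number of eigenvalues supplied (pass the axes under consideration).
#'
#' @param eigenvalues Non-negative eigenvalues, not all zero.
#' @return Data frame with observed and expected proportions and a
#'   `significant` flag per axis.
#' @export
broken_stick <- function(eigenvalues) {
  if (length(eigenvalues) == 0L) stop("empty eigenvalue vector")
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  tot <- sum(eigenvalues)
  if (tot <= 0) stop("all eigenvalues are zero")
  p <- length(eigenvalues)
  b <- rev(cumsum(1 / rev(seq_len(p)))) / p
  obs <- eigenvalues / tot
  data.frame(axis = seq_len(p), observed = obs, expected = b,
             significant = obs > b)
}

#' Species mean shapes from an alignment
#'
#' Arithmetic (tangent-space) mean of the aligned coordinates per species,
#' re-centered at the origin, with the arithmetic mean of the retained
#' centroid sizes.
#'
#' @param alignment A [gpa()] result.
#' @param species Character vector of species labels, one per specimen;
#'   defaults to the alignment's recorded `species_codes`.
#' @param levels Optional subset/order of species to return; requesting a
#'   species with zero specimens is an error.
#' @return List with `shapes` (k x 2 x n_species array, dimnames species),
#'   `mean_cs` (named vector) and `n_specimens` (named counts).
#' @export
species_mean_shapes <- function(alignment, species = NULL, levels = NULL) {
  if (!inherits(alignment, "gpa")) stop("alignment must be a gpa result")
  if (is.null(species)) species <- alignment$species_codes
  n <- dim(alignment$aligned)[3L]
  if (length(species) != n) stop("one species label per specimen required")
  if (is.null(levels)) levels <- unique(species)
  missing <- setdiff(levels, species)
  if (length(missing))
    stop("species with zero specimens requested: ", paste(missing, collapse = ", "))
  k <- dim(alignment$aligned)[1L]
  shapes <- array(NA_real_, c(k, 2L, length(levels)),
                  dimnames = list(NULL, c("x", "y"), levels))
  mean_cs <- stats::setNames(numeric(length(levels)), levels)
  nsp <- stats::setNames(integer(length(levels)), levels)
  for (s in levels) {
    idx <- which(species == s)
    m <- apply(alignment$aligned[, , idx, drop = FALSE], c(1L, 2L), mean)
    shapes[, , s] <- .center(m)
    mean_cs[s] <- mean(alignment$centroid_sizes[idx])
    nsp[s] <- length(idx)
  }
  list(shapes = shapes, mean_cs = mean_cs, n_specimens = nsp)
}

#' Shape model along an ordination axis
#'
#' Deforms the mean shape along one PC loading: mean + score * loading,
#' reshaped to k points (the ln CS entry of a form-space loading, if present,
#' is dropped from the reshaped coordinates).
#'
#' @param mean_shape k x 2 matrix (or flattened length-2k vector).
#' @param loading Loading vector over the flattened coordinate space.
#' @param score Scalar score at which to evaluate the model.
#' @return k x 2 coordinate matrix.
#' @export
axis_shape_model <- function(mean_shape, loading, score) {
  m <- if (is.matrix(mean_shape)) flatten_coords(mean_shape) else as.numeric(mean_shape)
  l <- as.numeric(loading)
  if (length(l) == length(m) + 1L) l <- l[seq_along(m)]  # form space: drop lnCS
  if (length(l) != length(m)) stop("loading dimension does not match shape")
  unflatten_coords(m + score * l)
}
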