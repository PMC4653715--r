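# Synthetic study bundles with known ground truth: pure-birth tree,
# opercle-like template outline, smooth deformation basis, latent trait
# evolution, specimen replication, covariates and feeding groups.

#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) tree conditioned on the number of tips, with tip labels
#' `sp0001`, `sp0002`, ... (6-character species codes) and, by default, the
#' height rescaled to 1.
#'
#' @param n_tips Number of tips (>= 3); default matches a 54-species flock.
#' @param birth Speciation rate.
#' @param seed Optional integer seed.
#' @param rescale Rescale so the maximum root-to-tip depth is 1?
#' @return An [ape::phylo].
#' @export
simulate_tree <- function(n_tips = 54L, birth = 1, seed = NULL,
                          rescale = TRUE) {
  if (n_tips < 3L) stop("n_tips must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  tr$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  if (rescale) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / h
  }
  tr
}

#' Opercle-like template outline
#'
#' Deterministic smooth closed curve: an ellipse of the given aspect ratio
#' carrying one localised dorsal bump, so the outline has a unique curvature
#' maximum on its dorsal margin for [detect_start_point()] to anchor on.
#' Points are equally spaced by arc length, traversed clockwise, starting at
#' the bump apex.
#'
#' @param k Number of outline points (>= 20).
#' @param aspect Ellipse height/width ratio.
#' @param notch_depth Relative amplitude of the dorsal bump.
#' @return An [outline_spec()] with `k` points.
#' @export
make_template_outline <- function(k = 100L, aspect = 0.8,
                                  notch_depth = 0.15) {
  if (k < 20L) stop("k must be at least 20")
  nf <- 2048L
  t <- seq(pi / 2, pi / 2 - 2 * pi, length.out = nf + 1L)[-(nf + 1L)]
  bump <- notch_depth * exp(-((t - pi / 2)^2) / (2 * 0.12^2))
  r <- 1 + bump
  pts <- cbind(r * cos(t), aspect * r * sin(t))
  fine <- outline_spec(pts, specimen_id = "template",
                       species_code = "templa")
  cfg <- resample_outline(fine, k = k, start = 1L)
  # iterate to the fixed point of equal-arc resampling at k, so the
  # template itself is resample-idempotent
  for (i in 1:100) {
    nxt <- resample_outline(outline_spec(cfg$coords, "t"), k = k, start = 1L)
    if (max(abs(nxt$coords - cfg$coords)) < 1e-13) { cfg <- nxt; break }
    cfg <- nxt
  }
  outline_spec(cfg$coords, specimen_id = "template", species_code = "templa")
}

#' Orthonormal deformation basis over an outline
#'
#' Builds `d` smooth boundary deformation fields: sinusoidal displacement
#' profiles of increasing frequency applied along the outward normals of the
#' template outline, projected off the similarity-transform directions
#' (translations, rotation, scaling) so the planted axes live in shape space
#' proper, then orthonormalised (QR) in the flattened coordinate space.
#' These play the role of interpretable planted shape axes, in the spirit of
#' the dorsoventral-compression / anteroposterior-extension
#' "dilation-diminution" modes seen in real opercles.
#'
#' @param template An [outline_spec()] (k points).
#' @param d Number of fields (d << 2k).
#' @return 2k x d matrix with orthonormal columns, each orthogonal to the
#'   template's similarity-transform directions.
#' @export
make_deformation_basis <- function(template, d = 4L) {
  pts <- template$points
  k <- nrow(pts)
  if (d >= 2L * k - 4L) stop("too many fields for k points")
  ctr <- .center(pts)
  nxt <- pts[c(2L:k, 1L), ]
  prv <- pts[c(k, 1L:(k - 1L)), ]
  tangent <- nxt - prv
  tangent <- tangent / sqrt(rowSums(tangent^2))
  normal <- cbind(tangent[, 2L], -tangent[, 1L])   # outward for clockwise
  s <- (seq_len(k) - 1L) / k
  # similarity-transform directions: x/y translation, rotation, scaling
  sim <- cbind(flatten_coords(cbind(rep(1, k), 0)),
               flatten_coords(cbind(0, rep(1, k))),
               flatten_coords(cbind(-ctr[, 2L], ctr[, 1L])),
               flatten_coords(ctr))
  fields <- sapply(seq_len(d), function(j) {
    freq <- 1L + ceiling(j / 2)                    # start above translation
    prof <- if (j %% 2L == 1L) cos(2 * pi * freq * s) else sin(2 * pi * freq * s)
    flatten_coords(prof * normal)
  })
  Q <- qr.Q(qr(cbind(sim, fields)))[, ncol(sim) + seq_len(d), drop = FALSE]
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

.default_latent_models <- function() {
  list(list(model = "BM",     sigma2 = 0.0040, param = NULL),
       list(model = "lambda", sigma2 = 0.0020, param = 0.8),
       list(model = "delta",  sigma2 = 0.0010, param = 3),
       list(model = "OU",     sigma2 = 0.0005, param = 2))
}

#' Evolve latent shape dimensions on a tree
#'
#' Each latent dimension evolves under its own model (BM, OU, EB, delta or
#' lambda, via [transform_covariance()]) with root state 0; the species mean
#' shape is the template plus the score-weighted sum of the deformation
#' fields.  Scores large enough to risk a self-intersecting outline
#' (pointwise displacement beyond 45% of the template's RMS radius) are
#' clipped with a warning.
#'
#' @param tree An [ape::phylo].
#' @param template An [outline_spec()].
#' @param basis 2k x d orthonormal field matrix ([make_deformation_basis()]).
#' @param latent_models List of length d; each element a list with `model`,
#'   `sigma2` and (except BM) `param`.
#' @param seed Optional integer seed.
#' @return List with `species_shapes` (k x 2 x n array, dimnames = tips),
#'   `true_scores` (n x d, rownames = tips), `basis`.
#' @export
simulate_shape_evolution <- function(tree, template, basis,
                                     latent_models = .default_latent_models(),
                                     seed = NULL) {
  validate_phylogeny(tree)
  d <- length(latent_models)
  if (d > ncol(basis)) stop("more latent dimensions than basis fields")
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv.phylo(tree)
  n <- nrow(C)
  scores <- matrix(0, n, d, dimnames = list(rownames(C), NULL))
  for (j in seq_len(d)) {
    lm <- latent_models[[j]]
    V <- lm$sigma2 * transform_covariance(C, lm$model, lm$param)
    if (lm$sigma2 > 0)
      scores[, j] <- drop(crossprod(chol(V), stats::rnorm(n)))
  }
  flat_template <- flatten_coords(template$points)
  rms <- sqrt(mean(rowSums(.center(template$points)^2)))
  limit <- 0.45 * rms
  clipped <- FALSE
  k <- nrow(template$points)
  shapes <- array(NA_real_, c(k, 2L, n),
                  dimnames = list(NULL, c("x", "y"), rownames(C)))
  for (i in seq_len(n)) {
    disp <- basis[, seq_len(d), drop = FALSE] %*% scores[i, ]
    mx <- max(sqrt(rowSums(unflatten_coords(disp)^2)))
    if (mx > limit) {
      scores[i, ] <- scores[i, ] * limit / mx
      disp <- disp * limit / mx
      clipped <- TRUE
    }
    shapes[, , i] <- unflatten_coords(flat_template + disp)
  }
  if (clipped)
    warning("some species' deformations were clipped to keep outlines simple")
  list(species_shapes = shapes, true_scores = scores,
       basis = basis[, seq_len(d), drop = FALSE])
}

#' Replicate specimens around species mean shapes
#'
#' Adds independent isotropic coordinate noise (at the scale of the unit
#' mean shape) per specimen and scales each specimen to its centroid size.
#' Species ln CS evolves as Brownian motion on the tree around `ln_cs_mean`,
#' optionally coupled allometrically to a latent dimension; specimen ln CS
#' adds lognormal individual variation.
#'
#' @param species_shapes k x 2 x n array of species mean shapes (dimnames =
#'   species codes).
#' @param tree An [ape::phylo] (for the size Brownian motion).
#' @param n_per_species Integer vector of specimen counts (recycled).
#' @param noise_sd Coordinate noise standard deviation, relative to the mean
#'   shape's scale.
#' @param ln_cs_mean,ln_cs_sigma2 Mean and BM rate of species ln CS.
#' @param cs_individual_sd Specimen-level ln CS standard deviation.
#' @param allometry Optional list(`scores` = per-species latent scores,
#'   `dim` = which latent dimension, `coef` = slope of ln CS on that score).
#' @param seed Optional integer seed.
#' @return List with `specimens` (list of [outline_spec()], TPS-writable),
#'   `species_cs` (named species ln CS means), `counts` (named per-species
#'   specimen totals).
#' @export
generate_specimens <- function(species_shapes, tree, n_per_species = 8L,
                               noise_sd = 0.01, ln_cs_mean = log(50),
                               ln_cs_sigma2 = 0.25, cs_individual_sd = 0.1,
                               allometry = NULL, seed = NULL) {
  if (any(n_per_species < 1L)) stop("n_per_species must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  spp <- dimnames(species_shapes)[[3L]]
  n <- length(spp)
  counts <- stats::setNames(rep_len(as.integer(n_per_species), n), spp)
  C <- ape::vcv.phylo(tree)[spp, spp]
  ln_cs <- ln_cs_mean + drop(crossprod(chol(ln_cs_sigma2 * C), stats::rnorm(n)))
  if (!is.null(allometry))
    ln_cs <- ln_cs + allometry$coef * allometry$scores[spp, allometry$dim]
  names(ln_cs) <- spp
  specimens <- vector("list", sum(counts))
  idx <- 0L
  for (s in spp) {
    base <- species_shapes[, , s]
    for (i in seq_len(counts[s])) {
      idx <- idx + 1L
      shp <- base + matrix(stats::rnorm(length(base), sd = noise_sd),
                           nrow(base), 2L)
      cs_i <- exp(ln_cs[s] + stats::rnorm(1L, sd = cs_individual_sd))
      shp <- .center(shp)
      shp <- shp * (cs_i / centroid_size(shp))
      specimens[[idx]] <- outline_spec(shp,
                                       specimen_id = sprintf("%s_%02d", s, i),
                                       species_code = s)
    }
  }
  list(specimens = specimens, species_ln_cs = ln_cs, counts = counts)
}

.default_covariate_spec <- function() {
  data.frame(
    covariate = c("d13C", "d15N", "grnDa", "grnVa", "mean_rl", "GLTL", "ER"),
    latent_dim = c(1L, 1L, 2L, 2L, 1L, 2L, 2L),
    slope = c(0, 0.8, 0, 0, 0.5, 0.8, -0.8),
    intercept = c(-18, 6, 12, 9, 1.2, 0.9, 1.2),
    resid_sigma2 = c(4, 1, 6, 4, 0.1, 0.04, 0.02),
    link = c("identity", "identity", "count", "count", "identity",
             "exp", "exp"),
    stringsAsFactors = FALSE)
}

#' Generate ecological covariates tied to latent shape dimensions
#'
#' Each covariate is `slope x latent score + Brownian residual` on the tree
#' (plus its intercept); gill-raker counts are rounded with a floor at zero,
#' and ER / GLTL are kept positive by exponentiating the linear predictor.
#' Ground-truth slopes are recorded in the `"truth"` attribute.
#'
#' @param tree An [ape::phylo].
#' @param true_scores n x d latent score matrix (rownames = species).
#' @param covariate_spec Data frame like `.default_covariate_spec()`:
#'   columns `covariate`, `latent_dim`, `slope`, `intercept`,
#'   `resid_sigma2`, `link` (identity/count/exp).
#' @param seed Optional integer seed.
#' @return A [covariate_table()] keyed by species code.
#' @export
generate_covariates <- function(tree, true_scores,
                                covariate_spec = .default_covariate_spec(),
                                seed = NULL) {
  validate_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  spp <- tree$tip.label
  if (any(covariate_spec$latent_dim > ncol(true_scores)))
    stop("unknown latent dimension in covariate_spec")
  C <- ape::vcv.phylo(tree)
  L <- chol(C)
  out <- data.frame(species_code = spp, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(covariate_spec))) {
    cs <- covariate_spec[i, ]
    lin <- cs$intercept + cs$slope * true_scores[spp, cs$latent_dim] +
      drop(crossprod(L, stats::rnorm(length(spp)))) * sqrt(cs$resid_sigma2)
    v <- switch(cs$link,
                identity = lin,
                count = pmax(0, round(lin)),
                exp = exp(lin - cs$intercept + log(cs$intercept)),
                stop("unknown link ", cs$link))
    out[[cs$covariate]] <- as.numeric(v)
  }
  tab <- covariate_table(out)
  attr(tab, "truth") <- covariate_spec
  tab
}

#' Assign species to groups with planted mean-shape shifts
#'
#' Groups are blocks of the tree's (cladewise) tip order or random, and each
#' group receives a mean shift along designated deformation fields; the
#' shifts are returned as score offsets so the caller can add them to the
#' latent scores before building shapes.
#'
#' @param tree An [ape::phylo].
#' @param levels Group labels (n_groups >= 2, at most one per species).
#' @param shift_dims Latent dimensions carrying the group shifts.
#' @param magnitude Scalar or per-group shift magnitude along `shift_dims`.
#' @param method `"clade"` (contiguous blocks of the tip order) or
#'   `"random"`.
#' @param seed Optional integer seed.
#' @return List with `groups` (named factor over species) and
#'   `score_shift` (n x d_max matrix of score offsets; columns are zero
#'   outside `shift_dims`).
#' @export
assign_groups <- function(tree, levels, shift_dims = 1L, magnitude = 0,
                          method = c("clade", "random"), seed = NULL) {
  validate_phylogeny(tree)
  method <- match.arg(method)
  g <- length(levels)
  if (g < 2L) stop("need at least two groups")
  spp <- tree$tip.label
  n <- length(spp)
  if (g > n) stop("more groups than species")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (method == "clade") sort(rep_len(seq_len(g), n))
         else sample(rep_len(seq_len(g), n))
  groups <- stats::setNames(factor(levels[idx], levels = levels), spp)
  magnitude <- rep_len(magnitude, g)
  dmax <- max(shift_dims)
  score_shift <- matrix(0, n, dmax, dimnames = list(spp, NULL))
  # spread group centres symmetrically around zero along each shift dim
  centres <- seq(-1, 1, length.out = g)
  for (j in shift_dims)
    score_shift[, j] <- centres[idx] * magnitude[idx]
  list(groups = groups, score_shift = score_shift)
}

#' Generate a complete synthetic study bundle
#'
#' Mirrors the scale and structure of an outline-morphometric study of a
#' cichlid species flock: 54 species on a pure-birth tree, 416 specimens
#' (5-10 per species), 100-point outlines deformed along latent dimensions
#' with known evolutionary models, seven ecological covariates with known
#' slopes, and 6 feeding-preference plus 7 feeding-mode labels with planted
#' group shifts.
#'
#' @param n_species Number of species.
#' @param n_specimens Total specimen count (distributed 5-10 per species).
#' @param k Semilandmarks per outline.
#' @param latent_models Per-dimension evolutionary models
#'   (see [simulate_shape_evolution()]).
#' @param covariate_spec Covariate ground truth
#'   (see [generate_covariates()]).
#' @param group_magnitude Planted feeding-group shift magnitude (latent
#'   score units).
#' @param noise_sd Specimen digitising noise (unit-shape scale).
#' @param seed Integer seed; the full bundle is reproducible from it.
#' @return Object of class `synthetic_dataset` with `tree`, `template`,
#'   `basis`, `true_params`, `specimens`, `covariates`, `groups`
#'   (feeding_preference, feeding_mode factors) and `species_shapes`,
#'   `true_scores`.
#' @export
make_synthetic_dataset <- function(n_species = 54L, n_specimens = 416L,
                                   k = 100L,
                                   latent_models = .default_latent_models(),
                                   covariate_spec = .default_covariate_spec(),
                                   group_magnitude = 0.06,
                                   noise_sd = 0.01, seed = 1L) {
  set.seed(seed)
  tree <- simulate_tree(n_species)
  template <- make_template_outline(k = k)
  basis <- make_deformation_basis(template, d = length(latent_models))
  grp_pref <- assign_groups(tree, FEEDING_PREFERENCES, shift_dims = 1L,
                            magnitude = group_magnitude)
  grp_mode <- assign_groups(tree, FEEDING_MODES, shift_dims = 2L,
                            magnitude = group_magnitude)
  evo <- simulate_shape_evolution(tree, template, basis, latent_models)
  scores <- evo$true_scores +
    cbind(grp_pref$score_shift[rownames(evo$true_scores), 1L],
          grp_mode$score_shift[rownames(evo$true_scores), 2L],
          matrix(0, n_species, ncol(evo$true_scores) - 2L))
  shapes <- evo$species_shapes
  flat_template <- flatten_coords(template$points)
  for (i in seq_len(n_species))
    shapes[, , i] <- unflatten_coords(flat_template +
                                        evo$basis %*% scores[i, ])
  counts <- rep_len(5:10, n_species)
  counts <- counts[sample.int(n_species)]
  excess <- sum(counts) - n_specimens
  while (excess != 0) {
    i <- sample.int(n_species, 1L)
    if (excess > 0 && counts[i] > 5L) { counts[i] <- counts[i] - 1L; excess <- excess - 1L }
    if (excess < 0 && counts[i] < 10L) { counts[i] <- counts[i] + 1L; excess <- excess + 1L }
  }
  spec <- generate_specimens(shapes, tree, n_per_species = counts,
                             noise_sd = noise_sd,
                             allometry = list(scores = scores, dim = 1L,
                                              coef = 2))
  cov <- generate_covariates(tree, scores, covariate_spec)
  cov$feeding_preference <- factor(
    as.character(grp_pref$groups[cov$species_code]),
    levels = FEEDING_PREFERENCES)
  cov$feeding_mode <- factor(
    as.character(grp_mode$groups[cov$species_code]),
    levels = FEEDING_MODES)
  structure(list(tree = tree, template = template, basis = evo$basis,
                 species_shapes = shapes, true_scores = scores,
                 specimens = spec$specimens,
                 covariates = cov,
                 groups = list(feeding_preference = grp_pref$groups,
                               feeding_mode = grp_mode$groups),
                 true_params = list(latent_models = latent_models,
                                    covariate_spec = covariate_spec,
                                    group_magnitude = group_magnitude,
                                    noise_sd = noise_sd,
                                    species_ln_cs = spec$species_ln_cs,
                                    counts = spec$counts,
                                    seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic study bundle: ", length(x$tree$tip.label), " species, ",
      length(x$specimens), " specimens, k = ", nrow(x$template$points),
      ", seed = ", x$true_params$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits `specimens.tps`, `tree.nwk`, `covariates.csv` and `truth.json`
#' (ground-truth parameters) into a directory.
#'
#' @param dataset A [make_synthetic_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(tps = file.path(dir, "specimens.tps"),
             tree = file.path(dir, "tree.nwk"),
             covariates = file.path(dir, "covariates.csv"),
             truth = file.path(dir, "truth.json"))
  write_tps(dataset$specimens, paths["tps"])
  write_newick(dataset$tree, paths["tree"])
  write_covariates(dataset$covariates, paths["covariates"])
  truth <- dataset$true_params
  truth$true_scores <- unname(split(dataset$true_scores,
                                    row(dataset$true_scores)))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}
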