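test_that("pure-birth trees have the right size, shape and expectations", {
  tr <- simulate_tree(54, seed = 501)
  expect_equal(length(tr$tip.label), 54L)
  expect_true(all(grepl("^sp\\d{4}$", tr$tip.label)))
  depths <- node_depths(tr)[tr$tip.label]
  expect_lt(max(abs(depths - 1)), 1e-9)          # ultrametric, height 1
  expect_error(simulate_tree(2), "at least 3")

  # Yule expectation oracle: lineages through time grow like exp(b t), so
  # the log-lineage regression slope over many replicates recovers b
  b <- 2; n <- 30
  set.seed(502)
  slopes <- replicate(200, {
    t <- simulate_tree(n, birth = b, rescale = FALSE)
    bt <- sort(ape::branching.times(t), decreasing = TRUE)
    depth <- max(bt) - bt
    unname(coef(lm(log(2:n) ~ depth))[2])
  })
  expect_lt(abs(mean(slopes) - b) / b, 0.15)
})

test_that("the template outline is clockwise with one dorsal anchor", {
  tpl <- make_template_outline(k = 100)
  expect_equal(nrow(tpl$points), 100L)
  expect_lt(signed_area(tpl$points), 0)
  # unique dorsal curvature maximum by brute-force scan: the apex beats
  # every other dorsal vertex by a clear margin
  pts <- tpl$points
  kappa <- discrete_curvature(pts)
  dorsal <- which(pts[, 2] > mean(pts[, 2]))
  top2 <- sort(kappa[dorsal], decreasing = TRUE)[1:2]
  expect_gt(top2[1], 1.1 * top2[2])
  expect_equal(which.max(kappa), 1L)
  expect_equal(detect_start_point(tpl), 1L)      # anchored at the apex
  # resampling an equally spaced outline is idempotent
  again <- resample_outline(tpl, k = 100, start = 1)
  expect_lt(max(abs(again$coords - tpl$points)), 1e-9)
  expect_error(make_template_outline(k = 10), "at least 20")
})

test_that("deformation bases are orthonormal planted axes", {
  tpl <- make_template_outline(k = 60)
  B <- make_deformation_basis(tpl, d = 5)
  expect_equal(dim(B), c(120L, 5L))
  G <- crossprod(B)
  expect_lt(max(abs(G - diag(5))), 1e-8)
})

test_that("shape evolution respects its models and plants recoverable axes", {
  tr <- simulate_tree(20, seed = 511)
  tpl <- make_template_outline(k = 40)
  B <- make_deformation_basis(tpl, d = 3)
  # zero variance: every species equals the template
  silent <- lapply(1:3, function(j) list(model = "BM", sigma2 = 0))
  ev0 <- simulate_shape_evolution(tr, tpl, B, silent, seed = 512)
  expect_lt(max(abs(ev0$species_shapes - c(tpl$points))), 1e-12)
  expect_true(all(ev0$true_scores == 0))

  # tip-score covariance follows each model's transformed covariance
  models <- list(list(model = "BM", sigma2 = 0.01),
                 list(model = "lambda", sigma2 = 0.01, param = 0.5))
  C <- ape::vcv.phylo(tr)
  set.seed(513)
  reps <- replicate(4000, simulate_shape_evolution(tr, tpl, B,
                                                   models)$true_scores,
                    simplify = "array")
  for (j in 1:2) {
    emp <- cov(t(reps[, j, ]))
    theo <- models[[j]]$sigma2 *
      transform_covariance(C, models[[j]]$model, models[[j]]$param)
    big <- abs(theo) > 0.3 * max(theo)
    expect_lt(max(abs(emp[big] - theo[big]) / abs(theo[big])), 0.15)
  }

  # PC1 of the generated dataset aligns with the dominant planted field
  dom <- list(list(model = "BM", sigma2 = 0.01),
              list(model = "BM", sigma2 = 0.0005),
              list(model = "BM", sigma2 = 0.0002))
  ev <- simulate_shape_evolution(simulate_tree(40, seed = 514), tpl, B, dom,
                                 seed = 515)
  al <- gpa(lapply(seq_len(40), function(i)
    landmark_config(ev$species_shapes[, , i])))
  sp <- shape_pca(al)
  cosine <- abs(sum(sp$loadings[, 1] * B[, 1]))
  expect_gt(cosine, 0.95)
})

test_that("specimen replication adds controlled noise and records totals", {
  tr <- simulate_tree(8, seed = 521)
  tpl <- make_template_outline(k = 30)
  B <- make_deformation_basis(tpl, d = 2)
  ev <- simulate_shape_evolution(tr, tpl, B,
                                 list(list(model = "BM", sigma2 = 0.003),
                                      list(model = "BM", sigma2 = 0.001)),
                                 seed = 522)
  g0 <- generate_specimens(ev$species_shapes, tr, n_per_species = 3,
                           noise_sd = 0, seed = 523)
  expect_length(g0$specimens, 24L)
  expect_equal(unname(g0$counts), rep(3L, 8))
  # zero noise: specimen shape identical to the species mean shape
  sp1 <- g0$specimens[[1]]
  expect_lt(procrustes_distance(sp1$points,
                                ev$species_shapes[, , sp1$species_code]),
            1e-10)
  # specimen-to-mean shape distance grows monotonically with noise
  meandist <- sapply(c(0.005, 0.02, 0.08), function(ns) {
    g <- generate_specimens(ev$species_shapes, tr, n_per_species = 3,
                            noise_sd = ns, seed = 524)
    mean(sapply(g$specimens, function(s)
      procrustes_distance(s$points, ev$species_shapes[, , s$species_code])))
  })
  expect_true(all(diff(meandist) > 0))
  expect_error(generate_specimens(ev$species_shapes, tr, n_per_species = 0),
               "at least 1")
})

test_that("covariates carry their planted slopes and validate", {
  tr <- simulate_tree(64, seed = 531)
  scores <- matrix(rnorm(64 * 2), 64, 2,
                   dimnames = list(tr$tip.label, NULL))
  spec <- data.frame(covariate = c("d15N", "ER", "grnDa"),
                     latent_dim = c(1L, 2L, 1L),
                     slope = c(0.8, -0.5, 0), intercept = c(6, 1.2, 12),
                     resid_sigma2 = c(0.05, 0.01, 4),
                     link = c("identity", "exp", "count"))
  t1 <- generate_covariates(tr, scores, spec, seed = 532)
  t2 <- generate_covariates(tr, scores, spec, seed = 532)
  expect_identical(t1, t2)                       # same seed, same table
  expect_s3_class(t1, "covariate_table")
  expect_true(all(t1$ER > 0))
  expect_true(all(t1$grnDa >= 0 & t1$grnDa == round(t1$grnDa)))
  # recover the planted d15N slope by PGLS
  y <- setNames(t1$d15N, t1$species_code)
  x <- setNames(scores[t1$species_code, 1], t1$species_code)
  fit <- pgls_fit(y, x, tr)
  expect_gt(fit$beta[2], 0.5)
  expect_lt(fit$beta[2], 1.1)
  bad <- spec; bad$latent_dim[1] <- 9L
  expect_error(generate_covariates(tr, scores, bad, seed = 1), "unknown")
})

test_that("group assignment labels every species once and plants shifts", {
  tr <- simulate_tree(54, seed = 541)
  ga <- assign_groups(tr, FEEDING_PREFERENCES, shift_dims = 1,
                      magnitude = 0.2, seed = 542)
  expect_length(ga$groups, 54L)
  expect_false(anyNA(ga$groups))
  expect_equal(sort(names(ga$groups)), sort(tr$tip.label))
  expect_equal(levels(ga$groups), FEEDING_PREFERENCES)
  expect_error(assign_groups(tr, letters[1:60]), "more groups")
  # planted shifts separate groups in a CVA of the shifted scores
  set.seed(543)
  base <- matrix(rnorm(54 * 3, sd = 0.02), 54, 3,
                 dimnames = list(tr$tip.label, NULL))
  shifted <- base
  shifted[, 1] <- shifted[, 1] + ga$score_shift[rownames(base), 1]
  fit <- cva(shifted, ga$groups[rownames(base)])
  expect_gt(fit$proportions[1], 80)
})

test_that("the full bundle is deterministic and internally consistent", {
  d1 <- make_synthetic_dataset(n_species = 12, n_specimens = 70, k = 40,
                               seed = 9)
  d2 <- make_synthetic_dataset(n_species = 12, n_specimens = 70, k = 40,
                               seed = 9)
  expect_identical(d1$true_scores, d2$true_scores)
  expect_identical(d1$specimens[[5]]$points, d2$specimens[[5]]$points)
  expect_identical(d1$covariates, d2$covariates)
  expect_length(d1$specimens, 70L)
  expect_equal(sum(d1$true_params$counts), 70)
  expect_true(all(table(vapply(d1$specimens, `[[`, "", "species_code")) >= 5))

  # bundle round-trips through the on-disk formats
  dir <- withr::local_tempdir()
  paths <- write_dataset(d1, dir)
  expect_true(all(file.exists(paths)))
  back <- read_tps(paths[["tps"]])
  expect_length(back, 70L)
  expect_lt(max(abs(back[[3]]$points - d1$specimens[[3]]$points)), 1e-9)
  tr <- read_newick(paths[["tree"]])
  expect_setequal(tr$tip.label, d1$tree$tip.label)
  cov <- read_covariates(paths[["covariates"]])
  expect_equal(cov$ER, d1$covariates$ER, tolerance = 1e-6)
})
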