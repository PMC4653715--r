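test_that("model likelihoods agree with a dense multivariate-normal oracle", {
  tr4 <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  x4 <- c(A = 2, B = 4, C = 9, D = 1)
  fit <- fit_trait_model(x4, tr4, "BM")
  C4 <- ape::vcv.phylo(tr4)[names(x4), names(x4)]
  expect_equal(fit$lnL, dense_lnl_at(x4, C4, fit$z0, fit$sigma2),
               tolerance = 1e-8)

  # all six models on a 6-taxon tree, each evaluated at a moderate
  # transform parameter with its profiled z0 / sigma2
  tr6 <- read_newick("(((A:1,B:1):1,(C:1.5,D:0.5):0.5):1,(E:2,F:2):1);")
  set.seed(5)
  x6 <- bm_sim_chol(tr6, sigma2 = 0.5, z0 = 2)
  C6 <- ape::vcv.phylo(tr6)[names(x6), names(x6)]
  params <- list(BM = NULL, WN = NULL, OU = 1.3, EB = 0.8, delta = 2.5,
                 lambda = 0.6)
  for (m in names(params)) {
    V <- if (m == "WN") diag(6) else transform_covariance(C6, m, params[[m]])
    prof <- .profile_lnl(x6, V)
    expect_equal(prof$lnL, dense_lnl_at(x6, V, prof$z0, prof$sigma2),
                 tolerance = 1e-8, label = paste(m, "lnL"))
    # the optimiser never does worse than this fixed parameter
    fit <- fit_trait_model(x6, tr6, m)
    expect_gte(fit$lnL, prof$lnL - 1e-8)
  }
})

test_that("white-noise fit equals the closed-form iid normal MLE", {
  tr <- rtree_bl(12, seed = 61)
  set.seed(62)
  x <- setNames(rnorm(12, 5, 2), tr$tip.label)
  fit <- fit_trait_model(x, tr, "WN")
  n <- 12
  s2 <- sum((x - mean(x))^2) / n
  lnl <- -0.5 * (n * log(2 * pi) + n * log(s2) + n)
  expect_equal(fit$lnL, lnl, tolerance = 1e-8)
  expect_equal(fit$z0, mean(x), tolerance = 1e-10)
  expect_equal(fit$sigma2, s2, tolerance = 1e-10)
})

test_that("nested models recover the BM likelihood at their limits", {
  tr <- rtree_bl(16, seed = 71)
  tru <- ape::compute.brlen(ape::rtree(16), method = "Grafen")  # ultrametric
  set.seed(72)
  for (tree in list(tr, validate_phylogeny(tru))) {
    x <- bm_sim_chol(tree, seed = NULL)
    C <- ape::vcv.phylo(tree)[names(x), names(x)]
    bm <- fit_trait_model(x, tree, "BM")$lnL
    lnl_at <- function(m, p)
      .profile_lnl(x, transform_covariance(C, m, p))$lnL
    expect_equal(lnl_at("lambda", 1), bm, tolerance = 1e-8)
    expect_equal(lnl_at("delta", 1), bm, tolerance = 1e-8)
    expect_equal(lnl_at("EB", 0), bm, tolerance = 1e-8)
  }
  # OU -> BM as alpha -> 0 on an ultrametric tree
  tru <- validate_phylogeny(tru)
  x <- bm_sim_chol(tru, seed = 73)
  Cu <- ape::vcv.phylo(tru)[names(x), names(x)]
  bm <- fit_trait_model(x, tru, "BM")$lnL
  ou <- .profile_lnl(x, transform_covariance(Cu, "OU", 1e-6))$lnL
  expect_lt(abs(ou - bm), 1e-3)
})

test_that("AICc arithmetic matches the published bookkeeping", {
  expect_lt(abs(aicc(80.13, 2, 54) - (-156.00)), 0.05)
  expect_equal(aicc(10, 3, 54) - (2 * 3 - 2 * 10), 24 / 50)
  expect_lt(abs(aicc(10, 3, 1e9) - (2 * 3 - 2 * 10)), 1e-6)
  expect_error(aicc(10, 3, 4), "exceed")
})

test_that("model comparison produces delta-AICc and Akaike weights", {
  cmp <- compare_models(c(BM = -150.81, OU = -155.71, WN = -156.00,
                          delta = -155.74, EB = -155.71, lambda = -155.52))
  expect_equal(min(cmp$dAICc), 0)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-9)
  expect_equal(order(cmp$weight), order(-cmp$AICc))
  expect_equal(round(cmp$weight, 3),
               c(0.017, 0.194, 0.224, 0.196, 0.194, 0.176), tolerance = 1e-9)

  same <- compare_models(rep(-100, 4))
  expect_equal(same$weight, rep(0.25, 4))
  set.seed(81)
  rnd <- compare_models(runif(7, -200, -100))
  expect_equal(sum(rnd$weight), 1, tolerance = 1e-12)
  # invariance to a constant shift of every AICc
  shifted <- compare_models(rnd$AICc + 42)
  expect_equal(shifted$weight, rnd$weight, tolerance = 1e-12)
})

test_that("Blomberg's K is exactly 1 on star trees and matches picante", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(2.5, 8)
  set.seed(91)
  for (r in 1:3) {
    x <- setNames(rnorm(8), star$tip.label)
    expect_equal(blomberg_k(x, star, n_perm = 99)$K, 1, tolerance = 1e-12)
  }
  # independent oracle on random trees
  library(picante)
  for (s in 1:3) {
    tr <- rtree_bl(10, seed = 500 + s)
    x <- bm_sim_chol(tr, seed = 600 + s)
    K_or <- picante::Kcalc(x[tr$tip.label], tr)
    expect_equal(blomberg_k(x, tr, n_perm = 99)$K, as.numeric(K_or),
                 tolerance = 1e-6)
  }
  expect_error(blomberg_k(setNames(rep(1, 8), star$tip.label), star), "variance")
})

test_that("lambda signal distinguishes signal-free from BM data", {
  tr <- rtree_bl(48, seed = 102)
  set.seed(101)
  # star-tree (iid) data carry no signal for the structured tree to find
  lams_star <- replicate(15, {
    x <- setNames(rnorm(48), tr$tip.label)
    pagel_lambda_signal(x, tr)$lambda_hat
  })
  expect_lt(median(lams_star), 0.1)
  lams_bm <- replicate(15, pagel_lambda_signal(bm_sim_chol(tr), tr)$lambda_hat)
  expect_gte(min(lams_bm), 0)
  expect_lte(max(lams_bm), 1)
  expect_gt(median(lams_bm), 0.8)
})

test_that("ancestral state reconstruction matches phytools and the GLS root", {
  tr <- rtree_bl(10, seed = 111)
  x <- setNames(rep(3.2, 10), tr$tip.label)
  anc <- ancestral_states_bm(x, tr)
  expect_equal(unname(anc), rep(3.2, tr$Nnode), tolerance = 1e-10)

  set.seed(112)
  x <- bm_sim_chol(tr)
  anc <- ancestral_states_bm(x, tr)
  prof <- .profile_lnl(x[tr$tip.label], ape::vcv.phylo(tr))
  expect_equal(unname(anc[1]), prof$z0, tolerance = 1e-9)
  library(phytools)
  fa <- phytools::fastAnc(tr, x)
  expect_equal(unname(anc[names(fa)]), as.numeric(fa), tolerance = 1e-6)
})

test_that("rate matrix equals the dense GLS estimator and recovers rates", {
  for (s in 1:3) {
    tr <- rtree_bl(12, seed = 700 + s)
    set.seed(800 + s)
    X <- sapply(1:3, function(j) bm_sim_chol(tr))
    rownames(X) <- tr$tip.label
    R <- ratematrix(X, tr)
    C <- ape::vcv.phylo(tr)
    one <- rep(1, 12)
    Ci <- solve(C)
    z <- as.numeric(crossprod(one, Ci) %*% X) / sum(Ci)
    Xc <- sweep(X, 2, z)
    R_gls <- t(Xc) %*% Ci %*% Xc / (12 - 1)
    expect_lt(max(abs(R - R_gls)), 1e-8)
    expect_true(isSymmetric(R, tol = 1e-10))
  }
  Xconst <- matrix(2, 12, 2, dimnames = list(rtree_bl(12, seed = 703)$tip.label))
  expect_equal(unname(ratematrix(Xconst, rtree_bl(12, seed = 703))),
               matrix(0, 2, 2))
  # recovery of the generating rate
  tr <- rtree_bl(128, seed = 120)
  set.seed(121)
  errs <- replicate(20, abs(ratematrix(bm_sim_chol(tr, sigma2 = 0.7), tr) /
                              0.7 - 1))
  expect_lt(median(errs), 0.25)
})

test_that("BM simulation obeys the process law and is seed-reproducible", {
  tr <- three_taxon_tree()
  R <- matrix(c(1, 0.4, 0.4, 0.5), 2, 2)
  s1 <- sim_traits(tr, R, z0 = c(1, -1), n_sims = 3, seed = 9)
  s2 <- sim_traits(tr, R, z0 = c(1, -1), n_sims = 3, seed = 9)
  expect_identical(s1, s2)

  zero <- tr; zero$edge.length[] <- 0
  sz <- sim_traits(zero, R, z0 = c(1, -1), n_sims = 2, seed = 1)
  expect_equal(unname(sz[, 1, 1]), rep(1, 3))
  expect_equal(unname(sz[, 2, 2]), rep(-1, 3))

  # empirical tip covariance approximates C (x) R
  sims <- sim_traits(tr, R, n_sims = 5000, seed = 33)
  C <- ape::vcv.phylo(tr)[rownames(sims), rownames(sims)]
  for (i in 1:3) for (j in 1:3) for (a in 1:2) for (b in 1:2) {
    expected <- C[i, j] * R[a, b]
    if (abs(expected) > 0.1) {
      emp <- stats::cov(sims[i, a, ], sims[j, b, ])
      expect_lt(abs(emp - expected) / abs(expected), 0.1)
    }
  }
  expect_error(sim_traits(tr, matrix(c(1, 2, 2, 1), 2, 2)), "semidefinite")
})

test_that("white-noise data give white noise the top median Akaike weight", {
  tr <- rtree_bl(54, seed = 131)
  models <- c("BM", "OU", "WN", "EB", "delta", "lambda")
  set.seed(132)
  wts <- replicate(100, {
    x <- setNames(rnorm(54), tr$tip.label)
    cmp <- compare_models(lapply(models, function(m)
      fit_trait_model(x, tr, m)))
    setNames(cmp$weight, cmp$model)
  })
  med <- apply(wts, 1, median)
  expect_equal(names(which.max(med)), "WN")
})
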