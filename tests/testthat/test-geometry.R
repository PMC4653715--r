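test_that("centroid size matches its definition and scales linearly", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(3 * sq), 3 * centroid_size(sq))
  set.seed(3)
  poly <- matrix(rnorm(200), 100, 2)
  ctr <- colMeans(poly)
  oracle <- sqrt(sum(apply(poly, 1, function(p) sum((p - ctr)^2))))
  expect_equal(centroid_size(poly), oracle, tolerance = 1e-12)
  expect_equal(centroid_size(matrix(c(2, 5), 1, 2)), 0)
})

test_that("outline resampling is equidistant, clockwise, start-anchored", {
  sq <- outline_spec(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)), "sq")
  cfg <- resample_outline(sq, k = 4, start = 1)
  expect_equal(cfg$coords[1, ], c(0, 0))
  expect_setequal(apply(round(cfg$coords, 9), 1, paste, collapse = ","),
                  c("0,0", "0,1", "1,1", "1,0"))
  expect_lt(signed_area(cfg$coords), 0)

  # idempotence on an already equally spaced polygon
  k <- 36
  circ <- resample_outline(outline_spec(regular_polygon(k), "c"), k = k,
                           start = 1)
  again <- resample_outline(outline_spec(circ$coords, "c2"), k = k, start = 1)
  expect_lt(max(abs(again$coords - circ$coords)), 1e-9)

  # resampled points sit at arc positions j * P / k of the original curve
  # (independent marching oracle)
  set.seed(9)
  ang <- sort(runif(12, 0, 2 * pi))
  blob <- cbind(cos(ang) * runif(12, 1, 2), sin(ang) * runif(12, 1, 2))
  if (signed_area(blob) > 0) blob <- blob[c(1, 12:2), ]  # clockwise input
  cfg <- resample_outline(outline_spec(blob, "b"), k = 50, start = 1)
  expect_lt(max(abs(cfg$coords - walk_outline(blob, 50))), 1e-9)

  expect_error(resample_outline(sq, k = 2), "at least 3")
  expect_error(resample_outline(sq, k = 99999), "maximum")
})

test_that("start-point detection finds the dorsal curvature maximum", {
  # rounded rectangle with one sharp dorsal notch planted at a known vertex
  t <- seq(0, 2 * pi, length.out = 81)[-81]
  rr <- cbind(1.5 * cos(t), sin(t))
  apex <- which.max(rr[, 2])
  rr[apex, 2] <- rr[apex, 2] + 0.4          # sharp protrusion, dorsal side
  expect_equal(detect_start_point(outline_spec(rr, "rr")), apex)

  # perfect circle: curvature ties resolved to the lowest dorsal index
  circ <- regular_polygon(40)
  idx <- detect_start_point(outline_spec(circ, "c"))
  dorsal <- which(circ[, 2] > mean(circ[, 2]))
  expect_equal(idx, min(dorsal))

  # user-supplied index bypasses detection
  cfg <- resample_outline(outline_spec(rr, "rr"), k = 20, start = 5)
  expect_equal(cfg$coords[1, ], rr[5, ])

  line <- outline_spec(cbind(seq(0, 1, length.out = 6), 0.5), "l")
  expect_error(detect_start_point(line), "collinear")
})

test_that("GPA removes similarity transforms and refuses reflections", {
  set.seed(21)
  base <- regular_polygon(30) + matrix(rnorm(60, sd = 0.1), 30, 2)
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- 3 * base %*% t(R) + matrix(rep(c(5, -2), each = 30), 30, 2)
  al <- gpa(list(landmark_config(base, "a"), landmark_config(moved, "b")))
  expect_true(al$converged)
  expect_lt(sqrt(sum((al$aligned[, , 1] - al$aligned[, , 2])^2)), 1e-10)
  expect_lt(procrustes_distance(base, moved), 1e-10)

  mirror <- base %*% diag(c(-1, 1))
  expect_gt(procrustes_distance(base, mirror), 0.05)

  # aligned configurations are centered with unit centroid size
  cs <- apply(al$aligned, 3, centroid_size)
  expect_lt(max(abs(cs - 1)), 1e-8)
  ctr <- apply(al$aligned, 3, colMeans)
  expect_lt(max(abs(ctr)), 1e-8)
  expect_error(gpa(list(landmark_config(base))), "at least two")
})

test_that("procrustes distance matches a brute-force rotation grid search", {
  tri_a <- rbind(c(0, 0), c(4, 0), c(1, 3))
  tri_b <- rbind(c(0, 0), c(3.2, 0.5), c(0.4, 2.8))
  scale_unit <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / centroid_size(M)
  }
  A <- scale_unit(tri_a); B <- scale_unit(tri_b)
  thetas <- seq(0, 2 * pi, by = 1e-4)
  oracle <- min(vapply(thetas, function(th) {
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    sqrt(sum((A %*% R - B)^2))
  }, 0))
  expect_equal(procrustes_distance(tri_a, tri_b), oracle, tolerance = 1e-6)
  expect_equal(procrustes_distance(tri_a, tri_a), 0)
  expect_equal(procrustes_distance(tri_a, tri_b),
               procrustes_distance(tri_b, tri_a), tolerance = 1e-12)
})

test_that("procrustes distance satisfies the triangle inequality", {
  set.seed(4)
  for (r in 1:25) {
    shapes <- replicate(3, matrix(rnorm(24), 12, 2), simplify = FALSE)
    dab <- procrustes_distance(shapes[[1]], shapes[[2]])
    dbc <- procrustes_distance(shapes[[2]], shapes[[3]])
    dac <- procrustes_distance(shapes[[1]], shapes[[3]])
    expect_lte(dac, dab + dbc + 1e-8)
  }
})

test_that("shape PCA recovers planted structure and reconstructs inputs", {
  set.seed(8)
  tpl <- make_template_outline(k = 40)
  basis <- make_deformation_basis(tpl, d = 3)
  amps <- rnorm(30, sd = 0.08)
  cfgs <- lapply(amps, function(a)
    landmark_config(unflatten_coords(flatten_coords(tpl$points) +
                                       a * basis[, 1])))
  al <- gpa(cfgs)
  sp <- shape_pca(al)
  expect_equal(sum(sp$proportions), 1, tolerance = 1e-9)
  expect_gt(sp$proportions[1], 0.999)
  # zero column means and orthonormal loadings
  expect_lt(max(abs(colMeans(sp$scores))), 1e-9)
  G <- crossprod(sp$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # reconstruction from all PCs
  X <- t(apply(al$aligned, 3, flatten_coords))
  recon <- sweep(sp$scores %*% t(sp$loadings), 2, sp$center, `+`)
  expect_lt(max(abs(recon - X)), 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(3))
    expect_gt(sp$loadings[which.max(abs(sp$loadings[, j])), j], 0)
})

test_that("shape PCA scores are invariant to similarity transforms", {
  set.seed(12)
  cfgs <- lapply(1:8, function(i)
    landmark_config(regular_polygon(15) + matrix(rnorm(30, sd = 0.05), 15, 2),
                    sprintf("s%d", i)))
  sp1 <- shape_pca(gpa(cfgs))
  th <- 1.1; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- lapply(cfgs, function(cf)
    landmark_config(2.5 * cf$coords %*% t(R) + 7, cf$specimen_id))
  sp2 <- shape_pca(gpa(moved))
  for (j in 1:3) {
    cc <- abs(stats::cor(sp1$scores[, j], sp2$scores[, j]))
    expect_gt(cc, 0.999)
  }
})

test_that("form space reduces to shape space at constant size", {
  set.seed(30)
  cfgs <- lapply(1:10, function(i) {
    m <- regular_polygon(12) + matrix(rnorm(24, sd = 0.04), 12, 2)
    m <- m / centroid_size(m)           # constant CS = 1
    landmark_config(m, sprintf("s%d", i))
  })
  al <- gpa(cfgs)
  fs <- form_pca(al)
  ss <- shape_pca(al)
  expect_true(fs$is_form_space)
  expect_equal(sum(fs$proportions), 1, tolerance = 1e-9)
  for (j in 1:3)
    expect_lt(min(max(abs(fs$scores[, j] - ss$scores[, j])),
                  max(abs(fs$scores[, j] + ss$scores[, j]))), 1e-8)

  # dominant size variation loads PC1 on ln CS
  cfgs2 <- lapply(1:10, function(i) {
    m <- regular_polygon(12) + matrix(rnorm(24, sd = 0.01), 12, 2)
    landmark_config(m * 10^runif(1, 0, 1), sprintf("s%d", i))
  })
  fs2 <- form_pca(gpa(cfgs2))
  lncs_row <- nrow(fs2$loadings)
  expect_gt(abs(fs2$loadings[lncs_row, 1]),
            max(abs(fs2$loadings[-lncs_row, 1])))
})

test_that("broken stick expectations match direct summation", {
  bs <- broken_stick(c(5, 3, 1))
  direct <- sapply(1:3, function(j) sum(1 / (j:3)) / 3)
  expect_equal(bs$expected, direct, tolerance = 1e-12)
  expect_equal(bs$expected, c(0.6111, 0.2778, 0.1111), tolerance = 1e-3)
  expect_equal(sum(bs$expected), 1, tolerance = 1e-12)

  bs2 <- broken_stick(c(3, 1, 0))
  expect_equal(bs2$observed, c(0.75, 0.25, 0))
  expect_equal(sum(bs2$significant), 1L)
  expect_error(broken_stick(numeric(0)), "empty")
  expect_error(broken_stick(c(0, 0)), "zero")
})

test_that("species means, GPA idempotence and axis shape models", {
  set.seed(15)
  cfgs <- lapply(1:6, function(i)
    landmark_config(regular_polygon(10) + matrix(rnorm(20, sd = 0.05), 10, 2),
                    sprintf("i%d", i), species_code = c("aaa", "bbb")[1 + i %% 2]))
  al <- gpa(cfgs)
  ms <- species_mean_shapes(al)
  expect_setequal(dimnames(ms$shapes)[[3]], c("aaa", "bbb"))
  idx <- which(al$species_codes == "aaa")
  manual <- apply(al$aligned[, , idx], c(1, 2), mean)
  manual <- sweep(manual, 2, colMeans(manual))
  expect_equal(ms$shapes[, , "aaa"], manual, tolerance = 1e-12)
  expect_equal(ms$mean_cs[["aaa"]], mean(al$centroid_sizes[idx]))
  expect_error(species_mean_shapes(al, levels = c("aaa", "zzz")), "zero specimens")

  # re-running gpa on its own output barely moves the consensus
  al2 <- gpa(lapply(seq_len(dim(al$aligned)[3]), function(i)
    landmark_config(al$aligned[, , i])))
  expect_lt(procrustes_distance(al$mean_shape, al2$mean_shape), 1e-8)

  m <- al$mean_shape
  load <- rep(0, 20); load[3] <- 1
  expect_equal(axis_shape_model(m, load, 0), m)
  up <- axis_shape_model(m, load, 0.5)
  dn <- axis_shape_model(m, load, -0.5)
  expect_equal((up + dn) / 2, m, tolerance = 1e-12)
  expect_equal(flatten_coords(up) - flatten_coords(m), 0.5 * load)
  expect_error(axis_shape_model(m, rep(1, 7), 1), "dimension")
})
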