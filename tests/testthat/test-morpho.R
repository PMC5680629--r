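random_configs <- function(n, k = 16, seed = 1) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(k * 2), k, 2)
    arr <- array(0, c(k, 2, n), dimnames = list(NULL, c("x", "y"),
                                                sprintf("S%03d", 1:n)))
    for (i in 1:n) arr[, , i] <- base + matrix(rnorm(k * 2, 0, 0.1), k, 2)
  })
  arr
}

similarity_transform <- function(m, theta, scale, shift) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(scale * m %*% rot, 2, shift, "+")
}

test_that("TPS files round-trip and malformed records fail loudly", {
  arr <- random_configs(120, seed = 11)
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(arr, path)
  back <- landmark_array(read_tps(path))
  expect_equal(dim(back), dim(arr))
  expect_lt(max(abs(back - arr)), 1e-6)
  expect_identical(dimnames(back)[[3]], dimnames(arr)[[3]])

  # single record
  one <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=fish1"), one)
  cfgs <- read_tps(one)
  expect_length(cfgs, 1)
  expect_equal(nrow(cfgs[[1]]), 3)
  expect_equal(names(cfgs), "fish1")

  # LM count disagrees with coordinate lines: error naming the record
  bad <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=a",
               "LM=16", rep("0 0", 15), "ID=b"), bad)
  expect_error(read_tps(bad), "record 2")

  # missing ID synthesizes one with a warning
  noid <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=2", "0 0", "1 1"), noid)
  expect_warning(cfg2 <- read_tps(noid), "no ID")
  expect_equal(names(cfg2), "specimen_1")
})

test_that("Procrustes superimposition is invariant to similarity transforms", {
  arr <- random_configs(20, seed = 12)
  ref <- generalized_procrustes(arr)
  jittered <- arr
  withr::with_seed(13, for (i in 1:20) {
    jittered[, , i] <- similarity_transform(arr[, , i], runif(1, 0, 2 * pi),
                                            runif(1, 0.2, 5), rnorm(2, 0, 50))
  })
  out <- generalized_procrustes(jittered)
  expect_lt(max(abs(out$aligned - ref$aligned)), 1e-8)
  # aligned configurations sit at the origin with unit centroid size
  rowsums <- apply(out$aligned, 1, function(v) {
    m <- matrix(v, ncol = 2, byrow = TRUE)
    c(abs(colMeans(m)), abs(sum(m^2) - 1))
  })
  expect_lt(max(rowsums), 1e-8)

  # copies of one shape: zero Procrustes variance
  copies <- array(0, c(4, 2, 5))
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  withr::with_seed(14, for (i in 1:5)
    copies[, , i] <- similarity_transform(sq, runif(1, 0, 6), runif(1, .5, 2),
                                          rnorm(2)))
  gc2 <- generalized_procrustes(copies)
  expect_lt(max(apply(gc2$aligned, 2, var)), 1e-16)

  # two triangles differing by a 90 degree rotation are the same shape
  tri <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  g3 <- generalized_procrustes(array(c(tri, similarity_transform(tri, pi / 2, 1, c(0, 0))),
                                     c(3, 2, 2)))
  expect_lt(sum((g3$aligned[1, ] - g3$aligned[2, ])^2), 1e-16)

  expect_error(
    generalized_procrustes(array(c(tri, matrix(1, 3, 2)), c(3, 2, 2))),
    "degenerate")
})

test_that("Procrustes rotation matches a brute-force angle search", {
  t1 <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  t2 <- matrix(c(0, 0, 1, 0, 1, 1), 3, 2, byrow = TRUE)
  g <- generalized_procrustes(array(c(t1, t2), c(3, 2, 2)), tol = 1e-14)
  d_pkg <- sum((g$aligned[1, ] - g$aligned[2, ])^2)

  # independent oracle: grid search over the rotation angle
  pre <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  a <- pre(t1); b <- pre(t2)
  angles <- seq(0, 2 * pi, by = 1e-4)
  d_grid <- min(vapply(angles, function(th) {
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum((a - b %*% rot)^2)
  }, numeric(1)))
  expect_equal(d_pkg, d_grid, tolerance = 1e-4)

  # cross-check the pairwise fit against vegan's Procrustes rotation
  skip_if_not_installed("vegan")
  v <- vegan::procrustes(a, b, scale = FALSE, symmetric = FALSE)
  expect_equal(d_pkg, sum((a - v$Yrot)^2), tolerance = 1e-6)
})

test_that("Burnaby projection is idempotent and removes the nuisance space", {
  withr::with_seed(15, {
    x <- matrix(rnorm(40 * 12), 40, 12)
    f <- matrix(rnorm(12 * 2), 12, 2)
  })
  px <- burnaby_project(x, f)
  expect_lt(max(abs(px %*% f)), 1e-10)               # orthogonality
  expect_lt(max(abs(burnaby_project(px, f) - px)), 1e-10)  # idempotence
  expect_true(all(rowSums(px^2) <= rowSums(x^2) + 1e-12))  # norm non-increasing
  expect_lt(max(abs(burnaby_project(px, f) - px)), 1e-10)
  expect_equal(burnaby_project(px, f), px, tolerance = 1e-10)
  expect_error(burnaby_project(x, cbind(f[, 1], f[, 1])), "rank deficient")
})

test_that("head subset keeps landmarks 1, 2, 12, 13, 15, 16 in order", {
  arr <- random_configs(4, seed = 16)
  h <- head_subset(arr)
  expect_equal(dim(h)[1], 6)
  expect_equal(h[, , 2], arr[c(1, 2, 12, 13, 15, 16), , 2])
  expect_identical(head_subset(h), h)  # subset of subset is the identity
  lst <- head_subset(landmark_list(arr))
  expect_equal(nrow(lst[[1]]), 6)
})

test_that("shape PCA recovers a planted subspace and reconstructs the data", {
  # identical shapes: all eigenvalues zero
  flat <- matrix(rep(rnorm(10), each = 5), 5, 10)
  p0 <- shape_pca(flat)
  expect_lt(max(p0$explained), 1e-12)

  withr::with_seed(17, {
    v <- rnorm(20); v <- v / sqrt(sum(v^2))
    s <- rnorm(300, sd = 2)
    noise <- matrix(rnorm(300 * 20, sd = 0.1), 300, 20)
  })
  x <- outer(s, v) + noise
  p <- shape_pca(x)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  expect_gt(abs(sum(p$loadings[, 1] * v)), 0.95)
  expect_equal(p$explained[1], var(s) / (var(s) + 20 * 0.01),
               tolerance = 0.05)
  # scores x loadings' + center reproduces the input
  recon <- p$scores %*% t(p$loadings) + rep(1, 300) %o% p$center
  expect_lt(max(abs(recon - x)), 1e-8)
  # sign convention: largest-magnitude loading of each PC is positive
  expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))] > 0)))

  expect_error(shape_pca(x[1:2, ]), "at least 3")
})

test_that("size correction returns exact OLS residuals", {
  withr::with_seed(18, {
    tl <- rnorm(50, 199, 9)
    sc <- 0.3 * tl + rnorm(50)
  })
  r <- size_correct(sc, tl)
  expect_lt(abs(mean(r)), 1e-12)
  expect_lt(abs(cor(r, tl)), 1e-12)
  expect_lt(max(abs(size_correct(2 + 0.5 * tl, tl))), 1e-10)
  expect_error(size_correct(sc, rep(199, 50)), "constant")
})

test_that("arching estimation recovers the injected bend and passes the null diagnostic", {
  cfg <- sim_config(seed = 19, n_ponds = 3, n_per_pond = 67)
  ind <- simulate_individuals(cfg)
  lms <- simulate_landmarks(ind, cfg)
  g <- generalized_procrustes(lms)
  basis <- estimate_arching_basis(g)
  expect_equal(sum(basis^2), 1, tolerance = 1e-12)

  # the injected arching direction, projected into shape space
  bases <- anglesel:::shape_deformation_bases(cfg$landmark_template)
  tmpl <- sweep(cfg$landmark_template, 2, colMeans(cfg$landmark_template))
  tmpl <- tmpl / sqrt(sum(tmpl^2))
  inter <- function(a, b) as.vector(rbind(a, b))
  unitv <- function(v) v / sqrt(sum(v^2))
  v <- bases$arch
  for (m in list(inter(rep(1, 16), rep(0, 16)), inter(rep(0, 16), rep(1, 16)),
                 inter(-tmpl[, 2], tmpl[, 1]), inter(tmpl[, 1], tmpl[, 2]))) {
    m <- unitv(m); v <- v - sum(v * m) * m
  }
  v <- unitv(v)
  expect_gt(abs(sum(basis * v)), 0.95)
  # the scores track the injected per-fish arching
  expect_gt(abs(cor(attr(basis, "scores"), attr(lms, "arch_score"))), 0.9)

  # with no arching injected, projection changes PC1 explained variance
  # by far less than 5 percentage points
  cfg0 <- sim_config(seed = 20, n_ponds = 3, n_per_pond = 67, arch_mag = 0)
  ind0 <- simulate_individuals(cfg0)
  g0 <- generalized_procrustes(simulate_landmarks(ind0, cfg0))
  expect_lt(abs(arching_diagnostic(g0)$change_pp), 5)

  # a user-supplied basis is returned unchanged up to normalization
  ub <- matrix(rnorm(32), 32, 1)
  got <- estimate_arching_basis(g, user_basis = ub)
  expect_equal(drop(got), drop(ub) / sqrt(sum(ub^2)))
})

test_that("injected body and head shape scores are recovered end-to-end", {
  cfg <- sim_config(seed = 21, n_ponds = 3, n_per_pond = 67,
                    lm_noise_sd = 0.001)
  ind <- simulate_individuals(cfg)
  lms <- simulate_landmarks(ind, cfg)
  g <- generalized_procrustes(lms)
  proj <- burnaby_project(g$aligned, estimate_arching_basis(g))
  body <- shape_pca(proj)
  expect_gt(abs(cor(body$scores[, 1], ind$z_sb)), 0.9)

  head_pca <- shape_pca(generalized_procrustes(head_subset(lms))$aligned)
  expect_gt(abs(cor(head_pca$scores[, 1], ind$z_sh)), 0.9)

  # a head-only deformation dominates head-subset PCA more than body PCA
  cfg_h <- sim_config(seed = 22, n_ponds = 1, n_per_pond = 100, sb_mag = 0,
                      arch_mag = 0, lm_noise_sd = 0.001)
  ind_h <- simulate_individuals(cfg_h)
  lms_h <- simulate_landmarks(ind_h, cfg_h)
  pc_body <- shape_pca(generalized_procrustes(lms_h)$aligned)
  pc_head <- shape_pca(generalized_procrustes(head_subset(lms_h))$aligned)
  expect_gt(pc_head$explained[1], pc_body$explained[1])
})
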