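make_spectrum <- function(mz, intensity, id = "s1", group = "Control",
                          replicate = 1L) {
  structure(list(sample_id = id, group = group, fraction = "FX2",
                 replicate = replicate, mz = mz, intensity = intensity),
            class = "spectrum")
}

test_that("spectral baseline subtraction removes flats and keeps peaks", {
  mz <- seq(900, 1100, by = 0.1)
  # constant intensity is annihilated
  flat <- make_spectrum(mz, rep(7, length(mz)))
  expect_equal(max(abs(subtract_spectrum_baseline(flat)$intensity)), 0)
  # isolated peaks on a zero baseline survive within 1%
  peaks <- 100 * exp(-((mz - 1000)^2) / (2 * 0.3^2))
  sp <- subtract_spectrum_baseline(make_spectrum(mz, peaks), window_width = 25)
  expect_lt(abs(max(sp$intensity) - 100) / 100, 0.01)
  # a monotone decaying baseline under one peak preserves the apex within 5%
  decay <- 50 * exp(-(mz - 900) / 150)
  sp2 <- subtract_spectrum_baseline(make_spectrum(mz, decay + peaks), 25)
  apex <- max(sp2$intensity[abs(mz - 1000) < 1])
  expect_lt(abs(apex - 100) / 100, 0.05)
  expect_error(subtract_spectrum_baseline(make_spectrum(numeric(0), numeric(0))),
               "empty")
})

test_that("binning follows the half-open convention and conserves intensity", {
  sp <- make_spectrum(c(1000.0, 1000.4, 1500.5), c(2, 3, 7))
  v <- bin_spectrum(sp, bin_width = 1)
  expect_equal(unname(v[101]), 5)   # [1000, 1001) holds both peaks
  expect_equal(unname(v[601]), 7)
  # a point exactly on an edge goes to the higher bin
  edge <- bin_spectrum(make_spectrum(1100, 4), bin_width = 1)
  expect_equal(unname(edge[201]), 4)  # bin [1100, 1101)
  expect_equal(unname(edge[200]), 0)
  # conservation inside [900, 3000)
  set.seed(12)
  mz <- sort(runif(500, 900, 2999.9))
  y <- rexp(500)
  expect_equal(sum(bin_spectrum(make_spectrum(mz, y))), sum(y))
  # brute-force per-point assignment oracle
  v2 <- bin_spectrum(make_spectrum(mz, y), bin_width = 2.5)
  oracle <- numeric(ceiling(2100 / 2.5))
  for (i in seq_along(mz)) {
    k <- floor((mz[i] - 900) / 2.5) + 1
    oracle[k] <- oracle[k] + y[i]
  }
  expect_equal(unname(v2), oracle)
})

test_that("replicate averaging validates grids and averages elementwise", {
  expect_equal(average_replicates(list(c(a = 0, b = 2), c(a = 2, b = 4))),
               c(1, 3))
  expect_equal(average_replicates(list(c(a = 1, b = 2))), c(1, 2))
  expect_error(average_replicates(list(c(a = 1), c(b = 1))), "inconsistent")
})

test_that("scaling centres columns and Pareto divides by root-sd", {
  m <- rbind(c(0, 5, 1), c(4, 5, 1), c(8, 5, 4))
  fm <- structure(list(values = m, sample_ids = paste0("s", 1:3),
                       groups = c("a", "a", "b"), bin_centers = 1:3,
                       scaling_state = "raw"), class = "feature_matrix")
  cen <- scale_features(fm, "mean_center")
  expect_lt(max(abs(colMeans(cen$values))), 1e-12)
  par <- scale_features(fm, "pareto")
  expect_equal(par$values[, 1], (m[, 1] - 4) / sqrt(4))
  # zero-sd column is centred only, no division
  expect_equal(par$values[, 2], c(0, 0, 0))
})

test_that("PCA matches the covariance eigenvalue oracle and reconstructs", {
  set.seed(13)
  m <- matrix(rnorm(10 * 50), 10, 50)
  fm <- structure(list(values = m, sample_ids = paste0("s", 1:10),
                       groups = rep(c("a", "b"), 5), bin_centers = 1:50,
                       scaling_state = "raw"), class = "feature_matrix")
  sc <- scale_features(fm, "mean_center")
  p <- pca_features(sc, n_components = 9)
  ev <- eigen(stats::cov(m))$values[1:9]
  # prcomp sdev^2 equals covariance eigenvalues (n-1 denominator both sides)
  expect_equal(p$explained_variance, ev, tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # orthonormal loadings
  expect_lt(max(abs(crossprod(p$loadings) - diag(9))), 1e-8)
  # full-rank reconstruction
  expect_lt(max(abs(p$scores %*% t(p$loadings) - sc$values)), 1e-8)
  # scores carry the matrix's total variance
  expect_equal(sum(p$explained_variance), sum(apply(sc$values, 2, var)),
               tolerance = 1e-8)
  expect_error(pca_features(sc, 10), "n_components")
  expect_error(pca_features(fm, 2), "scale")
})

test_that("PCA finds a single variance axis when one exists", {
  set.seed(14)
  d <- rnorm(8)
  m <- outer(d, rnorm(30))
  fm <- structure(list(values = m, sample_ids = paste0("s", 1:8),
                       groups = rep(c("a", "b"), 4), bin_centers = 1:30,
                       scaling_state = "raw"), class = "feature_matrix")
  p <- pca_features(scale_features(fm, "mean_center"), n_components = 2)
  expect_gt(p$explained_variance[1] / sum(p$explained_variance), 1 - 1e-10)
})

test_that("discriminant PCA separates planted groups and not shuffled ones", {
  maldi <- simulate_maldi_cohort(n_per_group = 4, seed = 17, n_nuisance = 50)
  fm <- build_feature_matrix(maldi$spectra)
  sc <- scale_features(fm, "pareto")
  dp <- discriminant_pca(sc, n_pcs = 5)
  expect_equal(dp$purity, 1.0)
  expect_false(dp$degenerate)
  expect_error(discriminant_pca(sc, n_pcs = 11), "n_pcs")
  # permutation control: purity near chance for shuffled labels.  A larger
  # cohort is used so nearest-centroid overfit (severe at 4/group) does not
  # dominate the null level.
  maldi2 <- simulate_maldi_cohort(n_per_group = 12, replicates = 1,
                                  seed = 17, n_nuisance = 50)
  sc2 <- scale_features(build_feature_matrix(maldi2$spectra), "pareto")
  set.seed(18)
  purities <- replicate(100, {
    discriminant_pca(sc2, labels = sample(sc2$groups), n_pcs = 5)$purity
  })
  expect_lt(abs(mean(purities) - 1 / 3), 0.25)
})

test_that("two identical groups flag a degenerate discriminant", {
  m <- matrix(rep(rnorm(20), each = 6), 6, 20) +
    matrix(rnorm(120, sd = 1e-8), 6, 20)
  fm <- structure(list(values = m, sample_ids = paste0("s", 1:6),
                       groups = rep(c("a", "b"), 3), bin_centers = 1:20,
                       scaling_state = "raw"), class = "feature_matrix")
  sc <- scale_features(fm, "mean_center")
  expect_warning(dp <- discriminant_pca(sc, n_pcs = 2), "degenerate|singular")
  expect_true(dp$degenerate)
})

test_that("pooled t-test matches the hand-computed example", {
  m <- rbind(1, 2, 3, 4, 5, 6)[, 1, drop = FALSE]
  fm <- structure(list(values = m, sample_ids = paste0("s", 1:6),
                       groups = rep(c("a", "b"), each = 3), bin_centers = 1000,
                       scaling_state = "raw"), class = "feature_matrix")
  r <- differential_t_test(fm, "a", "b")
  expect_equal(r$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$p_value, 0.02131, tolerance = 1e-3)
  expect_equal(r$p_value,
               t.test(1:3, 4:6, var.equal = TRUE)$p.value, tolerance = 1e-12)
})

test_that("t-test handles identical groups and scale invariance", {
  set.seed(19)
  m <- matrix(rnorm(8 * 30), 8, 30)
  m[5:8, ] <- m[1:4, ]
  fm <- structure(list(values = m, sample_ids = paste0("s", 1:8),
                       groups = rep(c("a", "b"), each = 4), bin_centers = 1:30,
                       scaling_state = "raw"), class = "feature_matrix")
  r <- differential_t_test(fm, "a", "b")
  expect_true(all(!r$significant))
  expect_true(all(r$p_value == 1))
  # common rescaling leaves p unchanged
  fm2 <- fm; fm2$values <- fm$values * 37
  set.seed(20)
  fm$values <- matrix(rnorm(8 * 30), 8, 30)
  fm2$values <- fm$values * 37
  expect_equal(differential_t_test(fm2, "a", "b")$p_value,
               differential_t_test(fm, "a", "b")$p_value, tolerance = 1e-12)
})

test_that("pattern classifier reproduces the published pattern grammar", {
  expect_identical(
    classify_pattern(c(Control = 0, `Cerv Ca` = 100, `CIN 2` = 98)),
    "Absent in Control; Cerv Ca = CIN 2")
  expect_identical(
    classify_pattern(c(`CIN 2` = 100, `Cerv Ca` = 40, Control = 10)),
    "CIN 2>Cerv Ca>Control")
  expect_identical(
    classify_pattern(c(Control = 50, `Cerv Ca` = 49, `CIN 2` = 51)),
    "Cerv Ca = CIN 2 = Control")
  expect_identical(
    classify_pattern(c(Control = 100, `Cerv Ca` = 1, `CIN 2` = 2)),
    "Absent in Cerv Ca; Absent in CIN 2; Control")
  expect_identical(classify_pattern(c(a = 0, b = 0)), "Absent in all groups")
})
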