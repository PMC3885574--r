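final_with_group <- function(f, group, id) make_final(f, sample_id = id, group = group)

test_that("group mean/sd curves match a two-pass oracle", {
  set.seed(5)
  fs <- replicate(4, {
    a <- runif(1, 0.3, 0.6); ctr <- runif(1, 60, 64)
    function(t) a * exp(-((t - ctr)^2) / 8)
  })
  scans <- lapply(seq_along(fs), function(i) {
    final_with_group(fs[[i]], "control", paste0("s", i))
  })
  gs <- group_mean_sd(scans)
  mat <- sapply(scans, function(s) s$values)
  expect_lt(max(abs(gs$control$mean_curve - rowMeans(mat))), 1e-12)
  expect_lt(max(abs(gs$control$sd_curve - apply(mat, 1, sd))), 1e-12)
  expect_identical(gs$control$n, 4L)
})

test_that("identical curves give zero sd and opposite curves a zero mean", {
  f <- gaussian_curve(63, 2)
  same <- lapply(1:3, function(i) final_with_group(f, "HSIL", paste0("h", i)))
  expect_equal(group_mean_sd(same)$HSIL$sd_curve,
               rep(0, length(final_grid())))
  # n = 1 group warns and yields sd 0
  expect_warning(one <- group_mean_sd(same[1]), "single sample")
  expect_equal(one$HSIL$sd_curve, rep(0, length(final_grid())))
})

test_that("difference curves subtract the control mean and control is zero", {
  f <- gaussian_curve(62, 2)
  g <- function(t) gaussian_curve(64, 2)(t) + 0.1
  scans <- c(
    lapply(1:2, function(i) final_with_group(f, "control", paste0("c", i))),
    lapply(1:2, function(i) final_with_group(g, "HSIL", paste0("h", i)))
  )
  dc <- difference_vs_control(group_mean_sd(scans))
  expect_equal(dc$control$values, rep(0, length(final_grid())))
  expect_equal(dc$HSIL$values, g(final_grid()) - f(final_grid()),
               tolerance = 1e-12)
  expect_error(difference_vs_control(group_mean_sd(scans[3:4])), "control")
})

test_that("difference curve integral equals the area difference", {
  cohort <- simulate_cohort(default_cohort_specs(n_per_group = 4), seed = 31)
  finals <- process_cohort(cohort)
  gs <- group_mean_sd(finals)
  dc <- difference_vs_control(gs)
  g <- finals[[1]]$temperatures
  tz <- function(y) sum(diff(g) * (y[-1] + y[-length(y)])) / 2
  for (nm in names(dc)) {
    expect_lt(abs(tz(dc[[nm]]$values) -
                    (tz(gs[[nm]]$mean_curve) - tz(gs$control$mean_curve))),
              1e-9)
  }
})

test_that("box summaries follow the closest-rank percentile convention", {
  b <- box_summary(1:100)
  expect_equal(unname(b[c("p25", "p50", "p75")]), c(25.75, 50.5, 75.25))
  expect_equal(unname(b["p5"]), 5.95)
  # ordering invariant and permutation invariance
  expect_true(all(diff(b[c("min", "p1", "p5", "p25", "p50", "p75",
                           "p95", "p99", "max")]) >= 0))
  set.seed(6)
  v <- rnorm(37)
  expect_identical(box_summary(v), box_summary(sample(v)))
  expect_equal(unname(box_summary(rep(2.5, 5))), rep(2.5, 10))
  one <- box_summary(3)
  expect_equal(unname(one[c("min", "p50", "max")]), c(3, 3, 3))
  expect_error(box_summary(numeric(0)), "non-empty")
})

test_that("Mann-Whitney exact p matches the worked case and brute force", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1)
  set.seed(7)
  for (i in 1:100) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    got <- mann_whitney_u(x, y, mode = "exact")$p_value
    expect_identical(got, brute_force_mw_p(x, y))
  }
})

test_that("Mann-Whitney agrees with the stats::wilcox.test oracle", {
  set.seed(8)
  for (i in 1:25) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$u_statistic,
                 unname(wilcox.test(x, y)$statistic))
  }
})

test_that("U statistic symmetry and rank-transform invariance hold", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    expect_equal(mann_whitney_u(x, y)$u_statistic +
                   mann_whitney_u(y, x)$u_statistic,
                 length(x) * length(y))
    # strictly monotone transform of the pooled data leaves p unchanged
    f <- function(v) exp(2 * v) + 1
    expect_identical(mann_whitney_u(x, y)$p_value,
                     mann_whitney_u(f(x), f(y))$p_value)
  }
})

test_that("identical samples and degenerate data give p = 1", {
  x <- c(1.2, 3.4, 5.6)
  expect_equal(mann_whitney_u(x, x)$p_value, 1)
  r <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
})

test_that("tied data fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 4, 4, 5)
  r <- mann_whitney_u(x, y, mode = "auto")
  expect_identical(r$mode_used, "approx")
  expect_equal(r$u_statistic, unname(wilcox.test(x, y, exact = FALSE)$statistic))
  expect_equal(r$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("pairwise tests cover 10 pairs x 8 metrics in the clinical order", {
  set.seed(10)
  met <- do.call(rbind, lapply(clinical_groups(), function(g) {
    data.frame(sample_id = paste0(g, 1:4), group = g,
               area = rnorm(4), width = rnorm(4), height = rnorm(4),
               t_max = rnorm(4), t_fm = rnorm(4), cp_peak1 = rnorm(4),
               cp_peak2 = rnorm(4), ratio = rnorm(4))
  }))
  res <- pairwise_metric_tests(met)
  expect_identical(nrow(res), 80L)
  first_pairs <- res[res$metric == "area", c("group_a", "group_b")]
  expect_identical(first_pairs$group_a[1:4], rep("control", 4))
  expect_identical(first_pairs$group_b[1:4],
                   c("LSIL", "HSIL", "StageI", "StageII_IV"))
  expect_identical(tail(first_pairs, 1)$group_a, "StageI")
  expect_true(all(res$significance_band %in% c("p<0.05", "0.05<=p<0.1", "ns")))
})

test_that("pairwise tests handle a two-group table", {
  met <- data.frame(sample_id = 1:6, group = rep(c("control", "HSIL"), each = 3),
                    area = rnorm(6), width = rnorm(6), height = rnorm(6),
                    t_max = rnorm(6), t_fm = rnorm(6), cp_peak1 = rnorm(6),
                    cp_peak2 = rnorm(6), ratio = rnorm(6))
  res <- pairwise_metric_tests(met)
  expect_identical(nrow(res), 8L)
})
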