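## Group-level thermogram analysis: mean/SD curves, difference-vs-control
## curves, box-chart summaries and pairwise Mann-Whitney U tests.

#' Per-group mean and standard-deviation curves
#'
#' @param scans named list of final-stage thermograms on a common grid.
#' @return named list of `group_summary` lists: `group`, `temperatures`,
#'   `mean_curve`, `sd_curve`, `n`.  Groups with a single sample get an
#'   all-zero sd curve with a warning.
#' @export
group_mean_sd <- function(scans) {
  stop_if_not(length(scans) >= 1, "no thermograms supplied")
  for (s in scans) require_stage(s, "final")
  t0 <- scans[[1]]$temperatures
  groups <- vapply(scans, function(s) s$group, character(1))
  out <- lapply(unique(groups), function(g) {
    members <- scans[groups == g]
    m <- vapply(members, function(s) s$values, numeric(length(t0)))
    m <- matrix(m, nrow = length(t0))
    sd_curve <- if (ncol(m) == 1L) {
      warning(sprintf("group '%s' has a single sample; sd curve set to 0", g))
      rep(0, length(t0))
    } else {
      apply(m, 1L, stats::sd)
    }
    list(group = g, temperatures = t0, mean_curve = rowMeans(m),
         sd_curve = sd_curve, n = ncol(m))
  })
  names(out) <- unique(groups)
  out
}

#' Difference curves of each group's mean thermogram versus control
#'
#' Progressive disease produces a negative difference lobe near the 62 degC
#' main transition and positive lobes at higher temperature.
#'
#' @param summaries output of [group_mean_sd()]; must contain a group
#'   labelled `control`.
#' @param control_label label of the reference group.
#' @return named list of lists: `group`, `temperatures`, `values`.
#' @export
difference_vs_control <- function(summaries, control_label = "control") {
  stop_if_not(control_label %in% names(summaries),
              "no control group among the summaries")
  ctrl <- summaries[[control_label]]$mean_curve
  lapply(summaries, function(s) {
    list(group = s$group, temperatures = s$temperatures,
         values = s$mean_curve - ctrl)
  })
}

#' Box-chart summary of one metric in one group
#'
#' The box-chart convention: box at the 25th/50th/75th percentiles, whiskers
#' at the 5th and 95th, crosses at the 1st and 99th, lines at the minimum
#' and maximum, open square at the mean.  Percentiles use linear
#' interpolation between closest ranks (`stats::quantile` type 7).
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric vector: min, p1, p5, p25, p50, p75, p95, p99, max,
#'   mean.
#' @export
box_summary <- function(values) {
  stop_if_not(length(values) >= 1 && all(is.finite(values)),
              "values must be non-empty and finite")
  q <- stats::quantile(values, c(.01, .05, .25, .50, .75, .95, .99),
                       type = 7, names = FALSE)
  c(min = min(values), p1 = q[1], p5 = q[2], p25 = q[3], p50 = q[4],
    p75 = q[5], p95 = q[6], p99 = q[7], max = max(values),
    mean = mean(values))
}

#' Mann-Whitney U test for unequal medians
#'
#' The U statistic counts pairs with `x > y` (ties count one half).  In
#' `exact` mode the two-sided p-value is computed by enumerating all
#' `choose(n_x + n_y, n_x)` labelings of the pooled sample (requires no
#' ties); `approx` mode uses the normal approximation with tie and
#' continuity corrections; `auto` picks exact enumeration when the labeling
#' count is at most 20,000 and the pooled data are tie-free.
#'
#' @param x,y numeric samples, each non-empty.
#' @param mode one of "auto", "exact", "approx".
#' @return list: `u_statistic`, `p_value`, `mode_used`, `degenerate` (TRUE
#'   when all pooled values are identical, in which case p = 1).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  stop_if_not(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  stop_if_not(all(is.finite(c(x, y))), "samples must be finite")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks for ties
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (length(unique(pooled)) == 1L) {
    return(list(u_statistic = u, p_value = 1, mode_used = "degenerate",
                degenerate = TRUE))
  }
  n_comb <- choose(nx + ny, nx)
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = !has_ties && n_comb <= 20000
  )
  if (use_exact) {
    stop_if_not(!has_ties, "exact mode requires tie-free data")
    ranks <- seq_len(nx + ny)
    combs <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(ranks[combs], nrow = nx)) - nx * (nx + 1) / 2
    dev <- abs(u - nx * ny / 2)
    p <- sum(abs(us - nx * ny / 2) >= dev - 1e-9) / n_comb
    return(list(u_statistic = u, p_value = p, mode_used = "exact",
                degenerate = FALSE))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  stop_if_not(sigma2 > 0, "degenerate variance in normal approximation")
  z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sigma2)
  if (u == mu) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u_statistic = u, p_value = p, mode_used = "approx", degenerate = FALSE)
}

significance_band <- function(p) {
  if (p < 0.05) "p<0.05" else if (p < 0.1) "0.05<=p<0.1" else "ns"
}

#' Pairwise Mann-Whitney tests of every metric across all group pairs
#'
#' One test per metric per unordered group pair, ordered with the control
#' group first and then by disease severity (the clinical-group order), i.e.
#' control vs LSIL, control vs HSIL, ..., Stage I vs Stage II-IV.  Raw
#' p-values are reported by default; Benjamini-Hochberg adjustment is
#' available but off by default, matching the convention of reporting
#' unadjusted pairwise p-values.
#'
#' @param metrics data.frame from [compute_metric_table()] (columns
#'   `group` plus metric columns).
#' @param metric_cols metric column names; default the eight metrics.
#' @param mode passed to [mann_whitney_u()].
#' @param adjust if TRUE, add a BH-adjusted `p_adj` column.
#' @return data.frame: metric, group_a, group_b, u_statistic, p_value,
#'   significance_band (and optionally p_adj).
#' @export
pairwise_metric_tests <- function(metrics,
                                  metric_cols = c("area", "width", "height",
                                                  "t_max", "t_fm", "cp_peak1",
                                                  "cp_peak2", "ratio"),
                                  mode = "auto", adjust = FALSE) {
  present <- intersect(clinical_groups(), unique(metrics$group))
  extra <- setdiff(unique(metrics$group), clinical_groups())
  groups <- c(present, sort(extra))
  counts <- table(metrics$group)[groups]
  empty <- groups[is.na(counts) | counts == 0]
  if (length(empty)) {
    warning("skipping empty group(s): ", paste(empty, collapse = ", "))
    groups <- setdiff(groups, empty)
  }
  stop_if_not(length(groups) >= 2, "need at least two non-empty groups")
  pairs <- utils::combn(groups, 2)
  rows <- list()
  for (m in metric_cols) {
    for (k in seq_len(ncol(pairs))) {
      ga <- pairs[1, k]; gb <- pairs[2, k]
      res <- mann_whitney_u(metrics[[m]][metrics$group == ga],
                            metrics[[m]][metrics$group == gb], mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group_a = ga, group_b = gb,
        u_statistic = res$u_statistic, p_value = res$p_value,
        significance_band = significance_band(res$p_value),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Median/quartile table of every metric per group
#'
#' @param metrics data.frame from [compute_metric_table()].
#' @param metric_cols metric column names.
#' @return data.frame: metric, group, n, median, lq, uq (type-7 quartiles).
#' @export
group_metric_table <- function(metrics,
                               metric_cols = c("area", "width", "height",
                                               "t_max", "t_fm", "cp_peak1",
                                               "cp_peak2", "ratio")) {
  groups <- intersect(clinical_groups(), unique(metrics$group))
  rows <- list()
  for (m in metric_cols) {
    for (g in groups) {
      v <- metrics[[m]][metrics$group == g]
      q <- stats::quantile(v, c(.25, .5, .75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = g, n = length(v),
        median = q[2], lq = q[1], uq = q[3], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
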