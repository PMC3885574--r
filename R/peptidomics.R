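## MALDI-TOF peptidome pipeline: spectral baseline subtraction, m/z binning,
## replicate averaging, scaling, PCA / discriminant PCA, differential
## t-tests and group abundance pattern calls.

## Rolling minimum over a centred window of k points, O(n), via the block
## prefix/suffix cummin construction (no rolling-window package available).
rolling_min <- function(x, k) {
  n <- length(x)
  k <- max(1L, min(as.integer(k), n))
  if (k == 1L) return(x)
  nblocks <- ceiling(n / k)
  pad <- nblocks * k - n
  xp <- c(x, rep(Inf, pad))
  m <- matrix(xp, nrow = k)                 # one block per column
  left <- as.vector(apply(m, 2L, cummin))   # prefix minima within block
  right <- as.vector(apply(m[k:1, , drop = FALSE], 2L, cummin)[k:1, ])
  ## window of k points starting at i: min(right[i], left[i + k - 1])
  starts <- seq_len(n - k + 1L)
  w <- pmin(right[starts], left[starts + k - 1L])
  ## centre the window; clamp at the edges
  half <- (k - 1L) %/% 2L
  idx <- pmin(pmax(seq_len(n) - half, 1L), n - k + 1L)
  w[idx]
}

## Moving average with edge-replicated padding (vectorised via filter).
rolling_mean <- function(x, k) {
  n <- length(x)
  k <- max(1L, min(as.integer(k), n))
  if (k %% 2L == 0L) k <- k + 1L          # centred window
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1L):(half + n)]
}

#' Subtract the chemical baseline from a MALDI spectrum
#'
#' The baseline is estimated by a moving minimum over `window_width` Th
#' followed by moving-average smoothing over the same width, then
#' subtracted; negative residues are clipped to zero.
#'
#' @param spectrum a `spectrum` object (fields `mz`, `intensity`, ...).
#' @param window_width baseline window, Th (default 25).
#' @return the spectrum with baseline-subtracted intensities.
#' @export
subtract_spectrum_baseline <- function(spectrum, window_width = 25) {
  stop_if_not(window_width > 0, "window_width must be positive")
  stop_if_not(length(spectrum$mz) >= 1, "empty spectrum")
  step <- if (length(spectrum$mz) > 1) spectrum$mz[2] - spectrum$mz[1] else 1
  k <- max(3L, as.integer(round(window_width / step)))
  base <- rolling_mean(rolling_min(spectrum$intensity, k), k)
  spectrum$intensity <- pmax(spectrum$intensity - base, 0)
  spectrum
}

#' Bin a spectrum onto a fixed m/z grid
#'
#' Intensities are summed into half-open bins `[edge, edge + width)`
#' spanning `range`; a point exactly on an edge goes to the higher bin.
#' Points outside the range are discarded.
#'
#' @param spectrum a `spectrum` object.
#' @param bin_width bin width, Th (default 1).
#' @param range m/z range (default `c(900, 3000)`).
#' @return named numeric vector of bin intensities; names are bin centres.
#' @export
bin_spectrum <- function(spectrum, bin_width = 1, range = c(900, 3000)) {
  stop_if_not(bin_width > 0, "bin_width must be positive")
  n_bins <- ceiling((range[2] - range[1]) / bin_width)
  idx <- floor((spectrum$mz - range[1]) / bin_width) + 1L
  keep <- idx >= 1L & idx <= n_bins & spectrum$mz >= range[1] &
    spectrum$mz < range[1] + n_bins * bin_width
  v <- numeric(n_bins)
  if (any(keep)) {
    agg <- tapply(spectrum$intensity[keep], idx[keep], sum)
    v[as.integer(names(agg))] <- as.numeric(agg)
  }
  names(v) <- range[1] + (seq_len(n_bins) - 0.5) * bin_width
  v
}

#' Average replicate feature vectors of one sample
#'
#' Signal is averaged across the replicate spots, elementwise.
#'
#' @param vectors list of equally-binned numeric vectors.
#' @return numeric vector.
#' @export
average_replicates <- function(vectors) {
  stop_if_not(length(vectors) >= 1, "no replicates supplied")
  len <- unique(vapply(vectors, length, integer(1)))
  stop_if_not(length(len) == 1L, "inconsistent bin grids across replicates")
  nm <- names(vectors[[1]])
  for (v in vectors[-1]) {
    stop_if_not(identical(names(v), nm), "inconsistent bin grids across replicates")
  }
  rowMeans(matrix(unlist(vectors), nrow = len))
}

#' Build the samples x bins feature matrix from a spectrum collection
#'
#' Applies baseline subtraction and binning to every spectrum, then averages
#' the replicate spots of each sample.
#'
#' @param spectra list of `spectrum` objects.
#' @param bin_width,range binning parameters (see [bin_spectrum()]).
#' @param baseline_window baseline window, Th; `NULL` skips baseline
#'   subtraction.
#' @return a `feature_matrix` list: `values` (samples x bins matrix),
#'   `sample_ids`, `groups`, `bin_centers`, `scaling_state = "raw"`.
#' @export
build_feature_matrix <- function(spectra, bin_width = 1,
                                 range = c(900, 3000),
                                 baseline_window = 25) {
  stop_if_not(length(spectra) >= 1, "no spectra supplied")
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  groups <- vapply(spectra, function(s) s$group, character(1))
  binned <- lapply(spectra, function(s) {
    if (!is.null(baseline_window)) s <- subtract_spectrum_baseline(s, baseline_window)
    bin_spectrum(s, bin_width, range)
  })
  uids <- unique(ids)
  rows <- lapply(uids, function(id) average_replicates(binned[ids == id]))
  values <- do.call(rbind, rows)
  rownames(values) <- uids
  colnames(values) <- names(binned[[1]])
  structure(list(values = values, sample_ids = uids,
                 groups = groups[match(uids, ids)],
                 bin_centers = as.numeric(names(binned[[1]])),
                 scaling_state = "raw"),
            class = "feature_matrix")
}

#' Scale a feature matrix prior to PCA
#'
#' `mean_center` subtracts column means; `pareto` additionally divides each
#' column by the square root of its standard deviation (columns with zero
#' sd are left centred only) — the usual compromise between no scaling and
#' unit-variance scaling for MS intensity data.
#'
#' @param fm a `feature_matrix`.
#' @param method "mean_center" or "pareto".
#' @return the feature matrix with updated `values` and `scaling_state`.
#' @export
scale_features <- function(fm, method = c("pareto", "mean_center")) {
  method <- match.arg(method)
  stop_if_not(nrow(fm$values) >= 2, "need at least 2 samples to scale")
  v <- sweep(fm$values, 2L, colMeans(fm$values))
  if (method == "pareto") {
    s <- apply(fm$values, 2L, stats::sd)
    pos <- s > 0
    v[, pos] <- sweep(v[, pos, drop = FALSE], 2L, sqrt(s[pos]), "/")
  }
  fm$values <- v
  fm$scaling_state <- method
  fm
}

#' Principal component analysis of a scaled feature matrix
#'
#' Components come from the singular value decomposition of the scaled
#' matrix; loading signs are fixed so the largest-magnitude loading of each
#' component is positive, making results deterministic.
#'
#' @param fm a scaled `feature_matrix` (`scaling_state != "raw"`).
#' @param n_components number of components; at most `min(samples - 1, bins)`.
#' @return list: `scores` (samples x components), `loadings`
#'   (bins x components), `explained_variance` (per component),
#'   `total_variance`.
#' @export
pca_features <- function(fm, n_components = 2) {
  stop_if_not(fm$scaling_state != "raw", "scale the matrix before PCA")
  n <- nrow(fm$values)
  p <- ncol(fm$values)
  stop_if_not(n_components >= 1 && n_components <= min(n - 1, p),
              "n_components must be at most min(samples - 1, bins)")
  pc <- stats::prcomp(fm$values, center = FALSE, scale. = FALSE)
  k <- seq_len(n_components)
  load <- pc$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    sign(load[which.max(abs(load[, j])), j])
  }, numeric(1))
  load <- sweep(load, 2L, flip, "*")
  scores <- sweep(pc$x[, k, drop = FALSE], 2L, flip, "*")
  list(scores = scores, loadings = load,
       explained_variance = pc$sdev[k]^2,
       total_variance = sum(pc$sdev^2))
}

#' Discriminant PCA (PCA followed by Fisher LDA on the scores)
#'
#' The feature matrix is reduced to `n_pcs` principal components and Fisher
#' linear discriminant axes are computed on the scores; samples are placed
#' in the (up to) two-dimensional discriminant space and assigned to the
#' nearest group centroid.  A singular within-group scatter matrix is
#' ridge-regularised with a warning.
#'
#' @param fm a scaled `feature_matrix`.
#' @param labels group label per sample (defaults to the matrix's `groups`).
#' @param n_pcs number of principal components retained; must be below
#'   `samples - number of groups`.
#' @param ridge regularisation added to the within-scatter diagonal when it
#'   is singular, as a fraction of its mean diagonal.
#' @return list: `scores` (samples x up to 2 discriminant axes), `labels`,
#'   `centroids`, `assigned`, `purity` (fraction of samples whose nearest
#'   centroid is their own group), `degenerate` (TRUE when the between-group
#'   scatter vanishes).
#' @export
discriminant_pca <- function(fm, labels = fm$groups, n_pcs = 5,
                             ridge = 1e-6) {
  groups <- unique(labels)
  stop_if_not(length(groups) >= 2, "need at least 2 groups")
  stop_if_not(all(table(labels) >= 2), "each group needs at least 2 samples")
  n <- nrow(fm$values)
  stop_if_not(n_pcs < n - length(groups),
              "n_pcs must be below samples - number of groups")
  pc <- pca_features(fm, n_components = n_pcs)
  x <- pc$scores
  mu <- colMeans(x)
  sw <- matrix(0, n_pcs, n_pcs)
  sb <- matrix(0, n_pcs, n_pcs)
  for (g in groups) {
    xg <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    cg <- sweep(xg, 2L, mg)
    sw <- sw + crossprod(cg)
    sb <- sb + nrow(xg) * tcrossprod(mg - mu)
  }
  degenerate <- sum(diag(sb)) < 1e-12 * max(1, sum(diag(sw)))
  if (degenerate) warning("between-group scatter is degenerate")
  if (rcond(sw) < 1e-12) {
    warning("within-group scatter is singular; applying ridge regularisation")
    sw <- sw + diag(ridge * mean(diag(sw)) + 1e-12, n_pcs)
  }
  ev <- eigen(solve(sw, sb))
  k <- min(2L, length(groups) - 1L, n_pcs)
  w <- Re(ev$vectors[, seq_len(k), drop = FALSE])
  scores <- x %*% w
  colnames(scores) <- paste0("DA", seq_len(k))
  centroids <- do.call(rbind, lapply(groups, function(g) {
    colMeans(scores[labels == g, , drop = FALSE])
  }))
  rownames(centroids) <- groups
  d2 <- vapply(groups, function(g) {
    rowSums(sweep(scores, 2L, centroids[g, ])^2)
  }, numeric(n))
  assigned <- groups[max.col(-d2)]
  list(scores = scores, labels = labels, centroids = centroids,
       assigned = assigned, purity = mean(assigned == labels),
       degenerate = degenerate)
}

#' Differential t-tests of every m/z bin between two groups
#'
#' Unpaired, two-tailed Student's t-test with pooled variance on the
#' replicate-averaged bin intensities; bins with p < `alpha` are flagged
#' significant.  Bins with zero variance in both groups and equal means get
#' p = 1.
#'
#' @param fm a `feature_matrix` (raw intensities).
#' @param group_a,group_b the two group labels to compare.
#' @param labels group label per sample (defaults to the matrix's `groups`).
#' @param alpha significance level (default 0.05).
#' @return data.frame: mz_bin, comparison, mean_a, mean_b, t_statistic,
#'   p_value, significant.
#' @export
differential_t_test <- function(fm, group_a, group_b, labels = fm$groups,
                                alpha = 0.05) {
  ia <- labels == group_a
  ib <- labels == group_b
  stop_if_not(sum(ia) >= 2 && sum(ib) >= 2,
              "each group needs at least 2 samples")
  xa <- fm$values[ia, , drop = FALSE]
  xb <- fm$values[ib, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2L, stats::var)
  vb <- apply(xb, 2L, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, (ma - mb) / se, ifelse(ma == mb, 0, Inf * sign(ma - mb)))
  df <- na + nb - 2
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df),
              ifelse(tstat == 0, 1, 0))
  p[se == 0 & ma == mb] <- 1
  data.frame(
    mz_bin = fm$bin_centers,
    comparison = paste(group_a, "vs", group_b),
    mean_a = ma, mean_b = mb,
    t_statistic = as.numeric(tstat), p_value = as.numeric(p),
    significant = as.numeric(p) < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call a group abundance pattern from group mean intensities
#'
#' Groups whose mean falls below `absence_threshold` times the maximum group
#' mean are reported as `"Absent in <G>"`.  The remaining groups are ordered
#' by decreasing mean; adjacent groups whose means differ by less than
#' `fold_tolerance` on the log2 scale are joined by `"="` (ties printed in
#' case-insensitive alphabetical order), others by `">"`.
#'
#' @param group_means named numeric vector of group mean intensities.
#' @param absence_threshold relative absence cut-off (default 0.05).
#' @param fold_tolerance log2-fold tolerance for `"="` (default 0.5).
#' @return pattern string; the degenerate all-absent case returns
#'   `"Absent in all groups"`.
#' @export
classify_pattern <- function(group_means, absence_threshold = 0.05,
                             fold_tolerance = 0.5) {
  stop_if_not(length(group_means) >= 2, "need at least 2 groups")
  stop_if_not(!is.null(names(group_means)), "group means must be named")
  top <- max(group_means)
  if (top <= 0) return("Absent in all groups")
  absent <- names(group_means)[group_means < absence_threshold * top]
  present <- group_means[!names(group_means) %in% absent]
  ord <- order(-present)
  nm <- names(present)[ord]
  mv <- present[ord]
  ## split the ordered groups into "=" runs
  runs <- list(1L)
  if (length(mv) > 1) {
    for (i in 2L:length(mv)) {
      tied <- abs(log2(mv[i - 1] / max(mv[i], 1e-300))) < fold_tolerance
      if (tied) {
        runs[[length(runs)]] <- c(runs[[length(runs)]], i)
      } else {
        runs[[length(runs) + 1L]] <- i
      }
    }
  }
  ci_sort <- function(v) v[order(tolower(v), method = "radix")]
  chain <- paste(vapply(runs, function(ix) {
    paste(ci_sort(nm[ix]), collapse = " = ")
  }, character(1)), collapse = ">")
  parts <- character(0)
  if (length(absent)) {
    parts <- paste("Absent in", ci_sort(absent))
  }
  paste(c(parts, chain), collapse = "; ")
}

#' Differential peptide table with pattern calls
#'
#' Runs [differential_t_test()] for every unordered group pair and adds a
#' pattern call per bin from the group mean intensities.  Only bins
#' significant in at least one comparison are returned by default.
#'
#' @param fm a `feature_matrix`.
#' @param labels group label per sample.
#' @param alpha significance level.
#' @param all_bins if TRUE, return every bin.
#' @param ... passed to [classify_pattern()].
#' @return data.frame: mz_bin, min_p, n_significant_pairs, pattern.
#' @export
differential_peptide_table <- function(fm, labels = fm$groups, alpha = 0.05,
                                       all_bins = FALSE, ...) {
  groups <- unique(labels)
  pairs <- utils::combn(groups, 2)
  pmat <- sapply(seq_len(ncol(pairs)), function(k) {
    differential_t_test(fm, pairs[1, k], pairs[2, k], labels, alpha)$p_value
  })
  pmat <- matrix(pmat, nrow = length(fm$bin_centers))
  means <- vapply(groups, function(g) {
    colMeans(fm$values[labels == g, , drop = FALSE])
  }, numeric(length(fm$bin_centers)))
  patterns <- vapply(seq_along(fm$bin_centers), function(i) {
    classify_pattern(stats::setNames(means[i, ], groups), ...)
  }, character(1))
  out <- data.frame(
    mz_bin = fm$bin_centers,
    min_p = apply(pmat, 1L, min),
    n_significant_pairs = rowSums(pmat < alpha),
    pattern = patterns,
    stringsAsFactors = FALSE
  )
  if (!all_bins) out <- out[out$n_significant_pairs > 0, ]
  out
}
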