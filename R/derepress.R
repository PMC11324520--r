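## derepress: TMM normalization, fold-change ECDFs, DTS permutation test ---

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample normalization factors computed by the TMM method
#' (weighted trimmed mean of log2 relative-expression ratios against the
#' reference sample whose upper-quartile count fraction is closest to the
#' mean), delegated to edgeR's implementation of the published algorithm.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts Genes x samples matrix or data.frame of raw counts (>= 2
#'   samples, each with positive total).
#' @param logratio_trim Trim fraction on M-values (default 0.3).
#' @param abs_trim Trim fraction on A-values (default 0.05).
#' @return Named numeric factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  m <- as.matrix(counts)
  if (ncol(m) < 2L) stopf("TMM needs at least two samples")
  if (any(colSums(m) <= 0)) stopf("every sample must have a positive total")
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  stats::setNames(as.numeric(f), colnames(m))
}

#' Normalize counts and drop weakly expressed genes
#'
#' Normalized counts are raw counts divided by the effective library-size
#' scaling (TMM factor x library size, rescaled so the mean effective size
#' is 1, keeping values on the count scale). Unexpressed genes (zero in
#' every sample) and genes whose normalized count falls below
#' `min_norm_count` in ANY sample are removed.
#'
#' @param counts Genes x samples raw counts.
#' @param factors Output of [tmm_factors()] (computed if NULL).
#' @param min_norm_count Threshold (default 50); a gene needs normalized
#'   count >= this in every sample to be retained.
#' @return list: `norm` (normalized matrix of retained genes), `factors`,
#'   `effective_libsize`, `n_removed`.
#' @export
normalize_and_filter <- function(counts, factors = NULL,
                                 min_norm_count = 50) {
  m <- as.matrix(counts)
  m <- m[rowSums(m) > 0, , drop = FALSE]          # unexpressed genes
  if (is.null(factors)) factors <- tmm_factors(m)
  eff <- colSums(m) * factors[colnames(m)]
  norm <- sweep(m, 2L, eff / mean(eff), "/")
  keep <- rowSums(norm < min_norm_count) == 0L
  list(norm = norm[keep, , drop = FALSE], factors = factors,
       effective_libsize = eff,
       n_removed = sum(!keep))
}

#' Per-group log2 fold changes and their ECDF curves
#'
#' Per gene, log2 of the ratio of mean normalized expression in the test
#' samples over the control samples; genes are then split into the target
#' and background groups and each group's empirical cumulative
#' distribution is returned as sorted (value, cumulative fraction) pairs.
#'
#' @param norm Normalized matrix (from [normalize_and_filter()]).
#' @param target_set,background_set Gene identifier vectors; genes absent
#'   from the matrix are skipped with a message.
#' @param test_samples,control_samples Column names of the two conditions.
#' @return list: `target_lfc`, `background_lfc` (named numeric),
#'   `ecdf_target`, `ecdf_background` (data.frames `value`, `frac`).
#' @export
fold_change_ecdf <- function(norm, target_set, background_set,
                             test_samples, control_samples) {
  stopifnot(all(test_samples %in% colnames(norm)),
            all(control_samples %in% colnames(norm)))
  lfc <- log2(rowMeans(norm[, test_samples, drop = FALSE]) /
                rowMeans(norm[, control_samples, drop = FALSE]))
  grab <- function(set, lab) {
    set <- as_ids(set)
    missing <- setdiff(set, rownames(norm))
    if (length(missing))
      message(sprintf("%d %s gene(s) absent from the matrix; skipped",
                      length(missing), lab))
    lfc[intersect(set, rownames(norm))]
  }
  t_lfc <- grab(target_set, "target")
  b_lfc <- grab(background_set, "background")
  if (!length(t_lfc) || !length(b_lfc))
    stopf("both groups must be non-empty after filtering")
  ecdf_pairs <- function(v) {
    s <- sort(v)
    data.frame(value = s, frac = seq_along(s) / length(s))
  }
  list(target_lfc = t_lfc, background_lfc = b_lfc,
       ecdf_target = ecdf_pairs(t_lfc),
       ecdf_background = ecdf_pairs(b_lfc))
}

## DTS statistic -----------------------------------------------------------

# Precompute the pieces of the DTS integral that do not depend on labels:
# distinct pooled values, the interval widths between consecutive distinct
# values, the pooled ECDF H at each distinct value, and the reweighting
# 1 / sqrt(H (1 - H)) with boundary intervals (H in {0, 1}) zeroed.
dts_precompute <- function(pooled) {
  ord <- order(pooled)
  sorted <- pooled[ord]
  n <- length(sorted)
  last <- which(diff(sorted) != 0)          # last index of each distinct value
  last <- c(last, n)
  vals <- sorted[last]
  m <- length(vals)
  if (m < 2L)
    return(list(ord = ord, last = last, w = numeric(0), n = n))
  dt_ <- diff(vals)                          # widths of [t_i, t_i+1)
  H <- last[-m] / n                          # pooled ECDF at t_i
  w <- ifelse(H <= 0 | H >= 1, 0, dt_ / sqrt(H * (1 - H)))
  list(ord = ord, last = last, w = w, n = n)
}

dts_stat_from_labels <- function(labx, pre, nx, ny) {
  if (length(pre$w) == 0L) return(0)
  zx <- cumsum(labx[pre$ord]) / nx          # E_x at sorted positions
  zy <- cumsum(!labx[pre$ord]) / ny
  i <- pre$last[-length(pre$last)]
  sum(abs(zx[i] - zy[i]) * pre$w)
}

#' DTS two-sample statistic
#'
#' A reweighted integral of the distance between the two empirical
#' cumulative distributions: over consecutive distinct pooled order
#' statistics \eqn{t_{(i)} < t_{(i+1)}}, sums
#' \eqn{|E_x(t_{(i)}) - E_y(t_{(i)})| (t_{(i+1)} - t_{(i)}) /
#' \sqrt{H(t_{(i)})(1 - H(t_{(i)}))}}, with H the pooled ECDF and boundary
#' intervals (H at 0 or 1) contributing nothing. The statistic is invariant
#' to adding a constant to both samples and scales linearly with a common
#' positive scale factor.
#'
#' @param x,y Numeric samples.
#' @return The statistic (>= 0).
#' @export
dts_stat <- function(x, y) {
  pre <- dts_precompute(c(x, y))
  dts_stat_from_labels(c(rep(TRUE, length(x)), rep(FALSE, length(y))),
                       pre, length(x), length(y))
}

#' DTS permutation test
#'
#' Significance of the [dts_stat()] statistic by label permutation. When
#' all distinct splits are no more numerous than `n_perm`
#' (\eqn{C(n_x+n_y, n_x) \le n\_perm}), the exact permutation distribution
#' is enumerated and the p-value is the exact tail fraction; otherwise
#' `n_perm` random label permutations are drawn and the add-one Monte
#' Carlo estimator \eqn{(1 + \#\{S^* \ge S\}) / (1 + n\_perm)} is used so
#' the p-value is never zero.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @param n_perm Permutations (default 2000).
#' @param seed Optional seed for the permutation stream.
#' @return list: `statistic`, `p.value`, `method` (`"exact"` or
#'   `"monte-carlo"`), `n_perm` (splits actually evaluated), `seed`.
#' @export
#' @examples
#' dts_test(c(1, 2, 3), c(4, 5, 6), seed = 1)  # exact p = 0.1
dts_test <- function(x, y, n_perm = 2000L, seed = NULL) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  pre <- dts_precompute(pooled)
  obs <- dts_stat_from_labels(c(rep(TRUE, nx), rep(FALSE, ny)), pre, nx, ny)
  if (length(pre$w) == 0L)                   # degenerate all-equal input
    return(list(statistic = 0, p.value = 1, method = "degenerate",
                n_perm = 0L, seed = seed))
  n_splits <- suppressWarnings(choose(n, nx))
  if (is.finite(n_splits) && n_splits <= n_perm) {
    idx <- combn(n, nx)
    stats_all <- apply(idx, 2L, function(ii) {
      lab <- logical(n); lab[ii] <- TRUE
      dts_stat_from_labels(lab, pre, nx, ny)
    })
    p <- mean(stats_all >= obs - 1e-12)
    return(list(statistic = obs, p.value = p, method = "exact",
                n_perm = ncol(idx), seed = seed))
  }
  run <- function() {
    count <- 0L
    for (b in seq_len(n_perm)) {
      lab <- logical(n)
      lab[sample.int(n, nx)] <- TRUE
      if (dts_stat_from_labels(lab, pre, nx, ny) >= obs - 1e-12)
        count <- count + 1L
    }
    (1 + count) / (1 + n_perm)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(statistic = obs, p.value = p, method = "monte-carlo",
       n_perm = n_perm, seed = seed)
}
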