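#' Unpaired permutation test
#'
#' Shuffles subjects between two groups: at each iteration the pooled rows
#' are randomly split into two pseudo-groups of the original sizes and the
#' statistic recomputed, giving the permuted null of the group difference.
#' Two-tailed p-value with add-one correction:
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm)`.
#'
#' @param stat_fn function of two row-matrices (the two pseudo-groups)
#'   returning a scalar — typically a difference of a graph parameter
#'   computed on each group's network (see [network_stat()]); the whole
#'   network pipeline is recomputed per pseudo-group.
#' @param group_a,group_b numeric matrices, one row per subject.
#' @param n_perm number of label shuffles (default 10000).
#' @param seed integer seed.
#' @return Object of class `perm_result`: list with `observed`,
#'   `null_values`, `p_two_tailed`, `n_permutations`, `exhaustive = FALSE`,
#'   `seed`.
#' @export
unpaired_permutation_test <- function(stat_fn, group_a, group_b,
                                      n_perm = 10000L, seed = 1L) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  na <- nrow(group_a); nb <- nrow(group_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  observed <- stat_fn(group_a, group_b)
  pooled <- rbind(group_a, group_b)
  set.seed(seed)
  null_values <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(na + nb, na)
    tryCatch(stat_fn(pooled[idx, , drop = FALSE],
                     pooled[-idx, , drop = FALSE]),
             error = function(e) stop("statistic failed at permutation ", i,
                                      ": ", conditionMessage(e)))
  }, numeric(1))
  p <- (1 + sum(abs(null_values) >= abs(observed))) / (1 + n_perm)
  structure(list(observed = observed, null_values = null_values,
                 p_two_tailed = p, n_permutations = as.integer(n_perm),
                 exhaustive = FALSE, seed = as.integer(seed)),
            class = "perm_result")
}

#' Exhaustive paired (sign-flip) permutation test
#'
#' For n paired observations (e.g. the two ages of the same subjects), all
#' 2^n within-pair label swaps are enumerated; with 12 pairs that is 4096
#' relabelings. The identity pattern is one of them, so the exact two-tailed
#' p-value is `#\{|null| >= |observed|\} / 2^n` (never zero).
#'
#' @param stat_fn function of two row-matrices (timepoint-1 rows,
#'   timepoint-2 rows, row i paired) returning a scalar.
#' @param x1,x2 numeric matrices with one row per pair member.
#' @param max_pairs enumeration cap (default 20; beyond it the 2^n blow-up
#'   calls for a sampled test instead).
#' @return A `perm_result` with `exhaustive = TRUE` and
#'   `n_permutations = 2^n`.
#' @export
paired_permutation_test <- function(stat_fn, x1, x2, max_pairs = 20L) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (nrow(x1) != nrow(x2)) stop("x1 and x2 must have the same rows (pairs)")
  n <- nrow(x1)
  if (n > max_pairs)
    stop("2^", n, " exceeds the exhaustive enumeration cap (", max_pairs,
         " pairs); use a sampled sign-flip test instead")
  n_perm <- 2L^n
  null_values <- numeric(n_perm)
  for (mask in 0:(n_perm - 1L)) {
    flip <- as.logical(bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask))
    a <- x1; b <- x2
    a[flip, ] <- x2[flip, , drop = FALSE]
    b[flip, ] <- x1[flip, , drop = FALSE]
    null_values[mask + 1L] <- stat_fn(a, b)
  }
  observed <- null_values[1L]           # mask 0 = identity pattern
  p <- sum(abs(null_values) >= abs(observed)) / n_perm
  structure(list(observed = observed, null_values = null_values,
                 p_two_tailed = p, n_permutations = n_perm,
                 exhaustive = TRUE, seed = NA_integer_),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.6g, p = %.4g (%s, %d perms)\n",
              x$observed, x$p_two_tailed,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' Bootstrap distribution of a statistic
#'
#' Resamples subjects (rows) with replacement at the original sample size
#' and recomputes the statistic per resample, e.g. the 100-bootstrap
#' distributions behind per-group violin plots of volume entropy and global
#' efficiency.
#'
#' @param stat_fn function of a row-matrix returning a scalar.
#' @param rows numeric matrix, one row per subject.
#' @param n_boot number of resamples (default 100).
#' @param seed integer seed.
#' @return numeric vector of length `n_boot`.
#' @export
bootstrap_distribution <- function(stat_fn, rows, n_boot = 100L, seed = 1L) {
  rows <- as.matrix(rows)
  if (nrow(rows) == 0) stop("no rows to resample")
  set.seed(seed)
  vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(rows), nrow(rows), replace = TRUE)
    tryCatch(stat_fn(rows[idx, , drop = FALSE]),
             error = function(e) stop("statistic failed at resample ", i,
                                      ": ", conditionMessage(e)))
  }, numeric(1))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at target rate q: sort p-values ascending, find the
#' largest k with `p_(k) <= k q / m`, reject hypotheses 1..k. Implemented
#' through [stats::p.adjust]`(method = "BH")`; the rejection set is always a
#' prefix of the sorted p-values and shrinks as q decreases.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return Object of class `fdr_result`: list with `pvalues`, `q`,
#'   `adjusted`, `rejected` (logical mask, input order) and `threshold`
#'   (largest rejected raw p, or `NA` if none).
#' @export
benjamini_hochberg <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  rejected <- adjusted <= q
  structure(list(pvalues = pvalues, q = q, adjusted = adjusted,
                 rejected = rejected,
                 threshold = if (any(rejected)) max(pvalues[rejected])
                             else NA_real_),
            class = "fdr_result")
}

#' Named graph-parameter statistics for permutation tests
#'
#' Builds a two-group difference statistic that recomputes the entire
#' network pipeline per (pseudo-)group: rows -> subject matrix -> positive
#' correlations -> distances -> the requested graph parameter. Registered
#' parameters: `gcc_threshold`, `global_efficiency`, `volume_entropy`,
#' `modularization` (needs `region_set`), `sld` (needs `pair`, a length-2
#' label vector).
#'
#' @param parameter statistic name.
#' @param schema the `roi_schema` the row matrices conform to.
#' @param region_set region-set name or label vector (for `modularization`).
#' @param pair length-2 ROI label vector (for `sld`).
#' @param gms_mode,gms_adjacency options passed to [gms_analysis()] when
#'   `parameter = "volume_entropy"`.
#' @return `network_stat`: function `(rows_a, rows_b) -> scalar` (difference
#'   a - b); `network_feature`: function `(rows) -> scalar` for one group.
#' @export
network_stat <- function(parameter = c("gcc_threshold", "global_efficiency",
                                       "volume_entropy", "modularization",
                                       "sld"),
                         schema = default_roi_schema(), region_set = NULL,
                         pair = NULL, gms_mode = "filtration",
                         gms_adjacency = "nonbacktracking") {
  f <- network_feature(parameter, schema, region_set, pair,
                       gms_mode, gms_adjacency)
  function(a, b) f(a) - f(b)
}

#' @rdname network_stat
#' @export
network_feature <- function(parameter = c("gcc_threshold",
                                          "global_efficiency",
                                          "volume_entropy", "modularization",
                                          "sld"),
                            schema = default_roi_schema(), region_set = NULL,
                            pair = NULL, gms_mode = "filtration",
                            gms_adjacency = "nonbacktracking") {
  parameter <- match.arg(parameter)
  if (parameter == "modularization" && is.null(region_set))
    stop("modularization needs a region_set")
  if (parameter == "sld" &&
      (is.null(pair) || length(pair) != 2))
    stop("sld needs a pair of ROI labels")
  function(rows) {
    d <- distance_matrix(subject_matrix(rows, schema = schema))
    switch(parameter,
           gcc_threshold = gcc_threshold(d),
           global_efficiency = global_efficiency(d),
           volume_entropy = gms_analysis(d, mode = gms_mode,
                                         adjacency = gms_adjacency)$h,
           modularization = modularization_score(minimum_spanning_tree(d),
                                                 region_set, schema,
                                                 warn_ties = FALSE),
           sld = single_linkage_matrix(d)[pair[1], pair[2]])
  }
}

#' Write a permutation result as JSON
#' @param x a `perm_result`.
#' @param path output path.
#' @param keep_null include the full null distribution (default FALSE).
#' @export
write_perm_json <- function(x, path, keep_null = FALSE) {
  out <- list(observed = x$observed, p_two_tailed = x$p_two_tailed,
              n_permutations = x$n_permutations, exhaustive = x$exhaustive,
              seed = x$seed)
  if (keep_null) out$null_values <- x$null_values
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
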