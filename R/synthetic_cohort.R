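#' Cohort configuration for the synthetic activity generator
#'
#' Describes a paired two-group (control / ADHD-model), two-timepoint
#' (childhood / entry-of-puberty) design. Per (group, age) cell a target
#' correlation matrix over the schema's ROIs is assembled as
#' baseline + block overwrites + effect deltas, repaired to positive
#' semi-definite by eigenvalue clipping if needed; subject activity is drawn
#' from a multivariate Gaussian with that correlation structure. Subjects
#' are paired across ages through a shared latent factor with correlation
#' `across_age_corr`, so paired tests have genuine pairing to exploit.
#'
#' @param n_subjects_per_group subjects per group (default 12, matching a
#'   12 + 12 paired design).
#' @param groups,ages character vectors naming the two groups and two ages.
#' @param baseline_correlation background correlation between all ROI pairs,
#'   in `[0, 1)`.
#' @param blocks list of `list(rois =, r =)` entries: within-block pairs get
#'   target correlation `r` (overwrites baseline). `rois` may be a region-set
#'   name or a label vector.
#' @param effect_deltas list of `list(group =, age =, rois =, delta =)`
#'   entries: additive correlation change applied to all pairs within `rois`
#'   for that (group, age) cell. Used to emulate e.g. limbic-cortical
#'   strengthening with age, or left-lateralized strengthening in one group.
#' @param across_age_corr latent subject-level correlation between the two
#'   ages, in `[0, 1]` (default 0.5).
#' @param mean_uptake,noise_sd marginal mean and SD of the (globally
#'   normalized) activity values; they do not affect correlations.
#' @param repair_tol maximum entrywise deviation tolerated between the
#'   requested targets and the PSD-repaired matrix before failing.
#' @param seed integer seed used by [generate_roi_activity()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group = 12,
                          groups = c("control", "adhd"),
                          ages = c("wk4", "wk6"),
                          baseline_correlation = 0.1,
                          blocks = list(),
                          effect_deltas = list(),
                          across_age_corr = 0.5,
                          mean_uptake = 1,
                          noise_sd = 0.1,
                          repair_tol = 0.1,
                          seed = 1L) {
  stopifnot(n_subjects_per_group >= 3, length(groups) == 2, length(ages) == 2)
  if (baseline_correlation < 0 || baseline_correlation >= 1)
    stop("baseline_correlation must be in [0, 1)")
  for (b in blocks)
    if (is.null(b$rois) || is.null(b$r) || b$r < 0 || b$r >= 1)
      stop("each block needs rois and a correlation target r in [0, 1)")
  if (across_age_corr < 0 || across_age_corr > 1)
    stop("across_age_corr must be in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 groups = groups, ages = ages,
                 baseline_correlation = baseline_correlation,
                 blocks = blocks, effect_deltas = effect_deltas,
                 across_age_corr = across_age_corr,
                 mean_uptake = mean_uptake, noise_sd = noise_sd,
                 repair_tol = repair_tol, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default study-design configuration
#'
#' The design the workflow emulates: 12 subjects per group, paired wk4/wk6
#' timepoints, memory and reward-motivation blocks moderately coherent at
#' baseline, and four developmental effects — a whole-brain strengthening
#' with age in both groups (larger in controls, so the GCC forms earlier at
#' the older age and earlier in controls than in the ADHD-model group), a
#' memory-system (limbic-cortical) strengthening that is full-sized in
#' controls but partial in the ADHD-model group, a reward-motivation gain
#' in controls only, and a left-lateralized cortical strengthening specific
#' to the older ADHD-model group.
#'
#' @param seed integer seed.
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L) {
  whole_brain <- default_roi_schema()$labels
  cohort_config(
    n_subjects_per_group = 12,
    baseline_correlation = 0.10,
    blocks = list(list(rois = "memory", r = 0.35),
                  list(rois = "reward_motivation", r = 0.35)),
    effect_deltas = list(
      list(group = "control", age = "wk4", rois = whole_brain, delta = 0.05),
      list(group = "control", age = "wk6", rois = whole_brain, delta = 0.17),
      list(group = "adhd", age = "wk6", rois = whole_brain, delta = 0.08),
      list(group = "control", age = "wk6", rois = "memory", delta = 0.20),
      list(group = "control", age = "wk6", rois = "reward_motivation",
           delta = 0.12),
      list(group = "adhd", age = "wk6", rois = "memory", delta = 0.08),
      list(group = "adhd", age = "wk6", rois = "left_cortex", delta = 0.20)),
    seed = seed)
}

#' Assemble the target correlation matrix for one (group, age) cell
#'
#' Baseline everywhere off-diagonal, then block overwrites, then additive
#' effect deltas for entries matching the cell; off-diagonals clamped to
#' `[0, 0.95]`; eigenvalue-clipping PSD repair. Fails if the repair moves
#' any entry by more than `repair_tol`, naming the worst-hit block.
#'
#' @param config a `cohort_config`.
#' @param schema an `roi_schema`.
#' @param group,age cell selectors (members of `config$groups` / `config$ages`).
#' @return p x p correlation-target matrix with unit diagonal.
#' @export
target_correlation <- function(config, schema, group, age) {
  stopifnot(inherits(config, "cohort_config"), inherits(schema, "roi_schema"))
  p <- length(schema$labels)
  R <- matrix(config$baseline_correlation, p, p,
              dimnames = list(schema$labels, schema$labels))
  set_pairs <- function(R, rois, f) {
    idx <- match(resolve_region_set(schema, rois), schema$labels)
    if (length(idx) >= 2) {
      sub <- R[idx, idx]
      sub[] <- f(sub)
      R[idx, idx] <- sub
    }
    R
  }
  for (b in config$blocks)
    R <- set_pairs(R, b$rois, function(x) b$r)
  for (e in config$effect_deltas)
    if (identical(e$group, group) && identical(e$age, age))
      R <- set_pairs(R, e$rois, function(x) x + e$delta)
  R <- pmin(pmax(R, 0), 0.95)
  diag(R) <- 1
  repaired <- nearest_psd_correlation(R)
  dev <- abs(repaired - R)
  if (max(dev) > config$repair_tol) {
    worst <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    blk <- "baseline"
    for (b in config$blocks) {
      lab <- resolve_region_set(schema, b$rois)
      if (all(schema$labels[worst] %in% lab))
        blk <- if (is.character(b$rois) && length(b$rois) == 1) b$rois else "custom block"
    }
    stop(sprintf(paste0("target correlation for (%s, %s) is not positive ",
                        "semi-definite within repair tolerance %.3g ",
                        "(worst deviation %.3g at %s-%s, block: %s)"),
                 group, age, config$repair_tol, max(dev),
                 schema$labels[worst[1]], schema$labels[worst[2]], blk))
  }
  repaired
}

# Eigenvalue-clipping PSD repair, rescaled back to unit diagonal.
nearest_psd_correlation <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  M <- stats::cov2cor(M)
  dimnames(M) <- dimnames(R)
  (M + t(M)) / 2
}

#' Generate paired two-group, two-age subject-by-ROI activity
#'
#' Draws, per group, paired multivariate-Gaussian activity at the two ages:
#' the age-specific targets are met exactly in population (symmetric
#' square-root factor per cell) and subjects are linked across ages through
#' a shared latent draw with correlation `across_age_corr`. Row `i` of a
#' group's two matrices is the same subject at the two ages.
#'
#' @param config a `cohort_config`.
#' @param schema an `roi_schema`.
#' @return Named list of [subject_matrix()] objects, names `"<group>.<age>"`.
#' @export
generate_roi_activity <- function(config, schema = default_roi_schema()) {
  stopifnot(inherits(config, "cohort_config"))
  p <- length(schema$labels)
  n <- config$n_subjects_per_group
  rho <- config$across_age_corr
  out <- list()
  set.seed(config$seed)
  for (g in config$groups) {
    ids <- sprintf("%s_%02d", g, seq_len(n))
    A <- lapply(config$ages, function(a) {
      S <- target_correlation(config, schema, g, a)
      e <- eigen(S, symmetric = TRUE)
      e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    })
    Z1 <- matrix(stats::rnorm(n * p), n, p)
    Z2 <- matrix(stats::rnorm(n * p), n, p)
    E <- list(Z1, rho * Z1 + sqrt(1 - rho^2) * Z2)
    for (k in 1:2) {
      X <- config$mean_uptake + config$noise_sd * (E[[k]] %*% A[[k]])
      out[[paste(g, config$ages[k], sep = ".")]] <-
        subject_matrix(X, subject_ids = ids, schema = schema)
    }
  }
  out
}
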