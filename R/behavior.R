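#' Default behavioral parameters per strain
#'
#' Means and SDs per behavioral test per strain, calibrated to the study
#' values for the selected ADHD-model (SHR) and control (WKY) animals:
#' marble burying 12.5 +/- 2.6 vs 2.8 +/- 2.1 marbles; open-field distance
#' 5.0 +/- 1.5 vs 3.6 +/- 1.3 m; delay discounting 12.8 +/- 8.2 vs
#' 35.8 +/- 33.3 % choice of the larger delayed reward.
#'
#' @return Nested list `params[[strain]][[test]] = list(mean, sd)` with
#'   strains `SHR`, `WKY` and tests `mbt`, `oft`, `ddt`.
#' @export
default_behavior_params <- function() {
  list(SHR = list(mbt = list(mean = 12.5, sd = 2.6),
                  oft = list(mean = 5.0, sd = 1.5),
                  ddt = list(mean = 12.8, sd = 8.2)),
       WKY = list(mbt = list(mean = 2.8, sd = 2.1),
                  oft = list(mean = 3.6, sd = 1.3),
                  ddt = list(mean = 35.8, sd = 33.3)))
}

# Inverse-CDF sampler for a normal truncated to [lo, hi].
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(a + stats::runif(n) * (b - a), mean, sd)
}

# Expectation of a [lo,hi]-truncated normal with latent (mu, sd).
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# Expectation of round(X) for X truncated-normal on [lo, hi] (integer grid).
rounded_truncnorm_mean <- function(mu, sd, lo, hi) {
  ks <- seq(ceiling(lo), floor(hi))
  z <- stats::pnorm(lo, mu, sd)
  w <- stats::pnorm(hi, mu, sd) - z
  cell <- function(k) {
    (stats::pnorm(pmin(k + 0.5, hi), mu, sd) -
       stats::pnorm(pmax(k - 0.5, lo), mu, sd)) / w
  }
  sum(ks * vapply(ks, cell, numeric(1)))
}

# Latent location giving the requested expectation after truncation (and
# rounding, when `rounded`). Root-found so configured means are the means
# actually realised in large samples, not just the pre-truncation location.
calibrate_location <- function(target, sd, lo, hi, rounded = FALSE) {
  if (sd == 0) return(target)
  f <- if (rounded) {
    function(mu) rounded_truncnorm_mean(mu, sd, lo, hi) - target
  } else {
    function(mu) truncnorm_mean(mu, sd, lo, hi) - target
  }
  stats::uniroot(f, lower = target - 8 * sd, upper = target + 8 * sd,
                 tol = 1e-10)$root
}

#' Generate synthetic behavioral records
#'
#' Draws per-rat scores for the three phenotyping tests from truncated
#' normal distributions: marble-burying count (rounded to an integer and
#' bounded by the 15 marbles of the 3 x 5 grid), open-field distance
#' (nonnegative, meters) and the delay-discounting score (bounded to
#' `[0, 100]` %). The latent location of each distribution is calibrated so
#' the post-truncation expectation equals the configured mean.
#'
#' The delay-discounting column `ddt_small_reward_pct` stores the task's
#' standard score — the mean percentage of choices of the larger, delayed
#' reward at the longer delays — so LOW values indicate a preference for
#' small immediate rewards (more impulsive). Selection logic reverses it
#' accordingly (see [select_adhd_phenotype()]).
#'
#' @param n_shr,n_wky number of ADHD-model (SHR) and control (WKY) rats.
#' @param params per-strain mean/SD list, see [default_behavior_params()].
#' @param seed integer seed.
#' @param n_marbles marbles presented in the burying test (default 15).
#' @return `data.frame` with columns `rat_id`, `strain`, `mbt_count`,
#'   `oft_distance`, `ddt_small_reward_pct`.
#' @export
generate_behavior <- function(n_shr, n_wky,
                              params = default_behavior_params(),
                              seed = 1L, n_marbles = 15L) {
  for (s in c("SHR", "WKY")) for (t in c("mbt", "oft", "ddt"))
    if (params[[s]][[t]]$sd < 0)
      stop("negative SD for ", s, " ", t)
  set.seed(seed)
  draw_strain <- function(strain, n, prefix) {
    if (n == 0L) return(NULL)
    p <- params[[strain]]
    mu_mbt <- calibrate_location(p$mbt$mean, p$mbt$sd, 0, n_marbles,
                                 rounded = TRUE)
    mu_oft <- calibrate_location(p$oft$mean, p$oft$sd, 0, Inf)
    mu_ddt <- calibrate_location(p$ddt$mean, p$ddt$sd, 0, 100)
    data.frame(
      rat_id = sprintf("%s_%04d", prefix, seq_len(n)),
      strain = strain,
      mbt_count = as.integer(pmin(pmax(
        round(rtruncnorm(n, mu_mbt, p$mbt$sd, 0, n_marbles)), 0), n_marbles)),
      oft_distance = rtruncnorm(n, mu_oft, p$oft$sd, 0, Inf),
      ddt_small_reward_pct = rtruncnorm(n, mu_ddt, p$ddt$sd, 0, 100),
      stringsAsFactors = FALSE)
  }
  rbind(draw_strain("SHR", n_shr, "shr"),
        draw_strain("WKY", n_wky, "wky"))
}

#' Select ADHD-phenotype rats by lower-quartile exclusion
#'
#' From the SHR (ADHD-model candidate) records, excludes rats falling in the
#' lower quartile of any (rule `"union"`, default) or all (rule
#' `"intersection"`) of the three ADHD-direction scores: marble-burying
#' count, open-field distance, and impulsivity `100 - ddt_small_reward_pct`
#' (the delay-discounting score reversed so that higher always means more
#' ADHD-like). "Lower quartile" means strictly below the 25th percentile
#' (linear-interpolation quantile); ties at the cutoff are retained. Control
#' (WKY) rats are never returned.
#'
#' @param records behavioral `data.frame` as from [generate_behavior()].
#' @param rule `"union"` (excluded if in the lower quartile of ANY test) or
#'   `"intersection"` (excluded only if in the lower quartile of ALL tests).
#' @return Character vector of selected SHR `rat_id`s.
#' @export
select_adhd_phenotype <- function(records, rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  shr <- records[records$strain == "SHR", , drop = FALSE]
  if (nrow(shr) == 0) stop("no SHR records to select from")
  if (nrow(shr) < 4)
    stop("need at least 4 SHR records for quartile-based selection, got ",
         nrow(shr))
  scores <- cbind(mbt = shr$mbt_count,
                  oft = shr$oft_distance,
                  imp = 100 - shr$ddt_small_reward_pct)
  below <- sapply(colnames(scores), function(j) {
    scores[, j] < stats::quantile(scores[, j], 0.25, type = 7)
  })
  excluded <- if (rule == "union") apply(below, 1, any) else apply(below, 1, all)
  shr$rat_id[!excluded]
}
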