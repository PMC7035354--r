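mean_diff <- function(a, b) mean(a) - mean(b)

test_that("exchangeable groups give a p-value near 1", {
  set.seed(1)
  x <- matrix(rnorm(40), 10)
  pr <- unpaired_permutation_test(mean_diff, x, x, n_perm = 500, seed = 2)
  expect_equal(pr$observed, 0)
  expect_gt(pr$p_two_tailed, 0.9)
})

test_that("sampled unpaired p matches exact enumeration on tiny groups", {
  set.seed(3)
  a <- matrix(rnorm(4, mean = 1), 2)
  b <- matrix(rnorm(4), 2)
  exact_null <- exact_unpaired_null(mean_diff, a, b)   # all 6 splits
  obs <- mean_diff(a, b)
  p_exact <- mean(abs(exact_null) >= abs(obs))
  pr <- unpaired_permutation_test(mean_diff, a, b, n_perm = 4000, seed = 9)
  expect_lt(abs(pr$p_two_tailed - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
})

test_that("sampled permutation tests are reproducible under a seed", {
  set.seed(4)
  a <- matrix(rnorm(24), 6)
  b <- matrix(rnorm(24, 0.5), 6)
  p1 <- unpaired_permutation_test(mean_diff, a, b, n_perm = 200, seed = 7)
  p2 <- unpaired_permutation_test(mean_diff, a, b, n_perm = 200, seed = 7)
  expect_identical(p1$null_values, p2$null_values)
  p3 <- unpaired_permutation_test(mean_diff, a, b, n_perm = 200, seed = 8)
  expect_false(identical(p3$null_values, p1$null_values))
})

test_that("p-value follows the add-one sampled rule", {
  set.seed(5)
  a <- matrix(rnorm(20, 3), 5)
  b <- matrix(rnorm(20), 5)
  pr <- unpaired_permutation_test(mean_diff, a, b, n_perm = 99, seed = 1)
  expect_equal(pr$p_two_tailed,
               (1 + sum(abs(pr$null_values) >= abs(pr$observed))) / 100)
  expect_gt(pr$p_two_tailed, 0)
})

test_that("statistic failures propagate with the permutation index", {
  bad <- local({
    calls <- 0
    function(a, b) {
      calls <<- calls + 1
      if (calls == 3) stop("boom")
      0
    }
  })
  expect_error(unpaired_permutation_test(bad, matrix(1:4, 2),
                                         matrix(5:8, 2),
                                         n_perm = 10, seed = 1),
               "permutation 2")
})

test_that("paired test enumerates all sign patterns exhaustively", {
  set.seed(6)
  x1 <- matrix(rnorm(10), 5)
  x2 <- matrix(rnorm(10, 1), 5)
  pr <- paired_permutation_test(mean_diff, x1, x2)
  expect_true(pr$exhaustive)
  expect_equal(pr$n_permutations, 32)
  expect_equal(pr$null_values[1], pr$observed)
  # observed appears exactly once as the identity pattern (continuous data)
  expect_equal(sum(pr$null_values == pr$observed), 1)
  # null symmetric about 0 for this antisymmetric statistic
  expect_lt(abs(mean(pr$null_values)), 1e-12)
  expect_lt(abs(sum(pr$null_values^3)), 1e-10)
})

test_that("single pair gives p in {0.5, 1} and the cap triggers", {
  pr <- paired_permutation_test(mean_diff, matrix(1, 1, 2), matrix(3, 1, 2))
  expect_equal(pr$n_permutations, 2)
  expect_true(pr$p_two_tailed %in% c(0.5, 1))
  expect_error(paired_permutation_test(mean_diff, matrix(0, 21, 1),
                                       matrix(1, 21, 1)),
               "cap")
})

test_that("exhaustive paired p equals the sign-flip t-test logic by hand", {
  # differences 1, 2, 4: |sum| of flipped differences; observed sum 7 is
  # the unique maximum together with its mirror -7 -> p = 2/8
  x2 <- matrix(c(1, 2, 4), 3, 1)
  x1 <- matrix(0, 3, 1)
  pr <- paired_permutation_test(function(a, b) sum(b - a), x1, x2)
  expect_equal(pr$p_two_tailed, 2 / 8)
})

test_that("bootstrap resamples subjects with replacement, reproducibly", {
  x <- matrix(rnorm(60), 20)
  bs1 <- bootstrap_distribution(function(r) mean(r), x, n_boot = 100,
                                seed = 11)
  bs2 <- bootstrap_distribution(function(r) mean(r), x, n_boot = 100,
                                seed = 11)
  expect_length(bs1, 100)
  expect_identical(bs1, bs2)
  const <- matrix(2, 8, 3)
  expect_equal(bootstrap_distribution(function(r) mean(r), const,
                                      n_boot = 25, seed = 1),
               rep(2, 25))
})

test_that("bootstrap SE of the mean approximates sd/sqrt(n)", {
  set.seed(12)
  x <- matrix(rnorm(400), 400)
  bs <- bootstrap_distribution(function(r) mean(r), x, n_boot = 2000,
                               seed = 13)
  expect_lt(abs(sd(bs) - sd(x) / sqrt(400)) / (sd(x) / sqrt(400)), 0.15)
})

test_that("Benjamini-Hochberg reproduces the hand-worked step-up", {
  res <- benjamini_hochberg(c(0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_identical(res$rejected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$threshold, 0.02)
  expect_identical(benjamini_hochberg(rep(1, 5))$rejected, rep(FALSE, 5))
  expect_identical(benjamini_hochberg(0.04, q = 0.05)$rejected, TRUE)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH rejections are a prefix of the sorted p-values, monotone in q", {
  set.seed(14)
  for (i in 1:20) {
    p <- runif(30)^2
    r5 <- benjamini_hochberg(p, q = 0.05)
    r1 <- benjamini_hochberg(p, q = 0.01)
    ord <- order(p)
    rej_sorted <- r5$rejected[ord]
    if (any(rej_sorted))
      expect_true(all(rej_sorted[seq_len(max(which(rej_sorted)))]))
    expect_true(all(!r1$rejected | r5$rejected))
  }
})

test_that("BH controls empirical FDR on uniform nulls", {
  set.seed(15)
  fdp <- vapply(1:1000, function(i) {
    res <- benjamini_hochberg(runif(20), q = 0.05)
    as.numeric(any(res$rejected))    # all nulls: any rejection is false
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(fdp), 0.05 + 3 * se)
})

test_that("network statistics plug into the permutation machinery", {
  sch <- tiny_schema(5, sets = list(mod = sprintf("r%02d", 1:3)))
  set.seed(16)
  a <- matrix(rnorm(60), 12)
  b <- matrix(rnorm(60), 12)
  for (param in c("gcc_threshold", "global_efficiency")) {
    sf <- network_stat(param, sch)
    pr <- unpaired_permutation_test(sf, a, b, n_perm = 30, seed = 3)
    expect_true(is.finite(pr$observed))
    expect_length(pr$null_values, 30)
  }
  sfm <- network_stat("modularization", sch, region_set = "mod")
  expect_true(is.finite(sfm(a, b)))
  sfs <- network_stat("sld", sch, pair = c("r01", "r04"))
  expect_true(is.finite(sfs(a, b)))
  expect_error(network_stat("modularization", sch), "region_set")
  expect_error(network_stat("sld", sch), "pair")
})
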