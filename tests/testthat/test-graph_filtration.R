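test_that("filtration of the 4-node example reproduces hand merges", {
  dend <- single_linkage_merges(toy4_distance())
  expect_equal(dend$heights, c(0.2, 0.3, 0.5))
  expect_setequal(dend$merges[[1]]$a, "A")
  expect_setequal(dend$merges[[1]]$b, "B")
  expect_setequal(dend$merges[[3]]$a, c("A", "B"))
  expect_setequal(dend$merges[[3]]$b, c("C", "D"))
  expect_equal(gcc_threshold(dend), 0.5)
})

test_that("beta0-curve is the component count step function", {
  dend <- single_linkage_merges(toy4_distance())
  curve <- beta0_curve(dend)
  expect_equal(curve$beta0[1], 4)                 # below first merge
  expect_equal(beta0_at(curve, 0.25), 3)          # {A,B},{C},{D}
  expect_equal(beta0_at(curve, 0), 4)
  expect_equal(beta0_at(curve, 1), 1)
  expect_equal(beta0_at(curve, 0.5), 1)           # right-continuous at GCC
  expect_true(all(diff(curve$beta0) <= 0))
  expect_true(all(diff(curve$threshold) > 0))
})

test_that("SLM of the example reads off the merge tree", {
  s <- single_linkage_matrix(single_linkage_merges(toy4_distance()))
  expect_equal(unname(s["A", "B"]), 0.2)
  expect_equal(unname(s["C", "D"]), 0.3)
  for (x in c("A", "B")) for (y in c("C", "D"))
    expect_equal(unname(s[x, y]), 0.5)
  expect_equal(diag(unclass(s)), rep(0, 4), ignore_attr = TRUE)
})

test_that("two nodes: single merge at their distance", {
  d <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  dend <- single_linkage_merges(d)
  expect_equal(dend$heights, 0.4)
  expect_equal(gcc_threshold(dend), 0.4)
  expect_equal(unname(single_linkage_matrix(dend)["A", "B"]), 0.4)
})

test_that("filtration is equivariant under node permutation", {
  d <- rand_distance_matrix(7, seed = 44)
  perm <- sample(7)
  dp <- d[perm, perm]
  s1 <- single_linkage_matrix(single_linkage_merges(d))
  s2 <- single_linkage_matrix(single_linkage_merges(dp))
  expect_equal(s2[rownames(d), rownames(d)], unclass(s1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("SLM equals minimax path distances and hclust cophenetic", {
  for (seed in 1:25) {
    d <- rand_distance_matrix(sample(4:8, 1), seed = 700 + seed)
    s <- single_linkage_matrix(single_linkage_merges(d))
    expect_equal(unclass(s), minimax_oracle(d), tolerance = 1e-12)
    coph <- as.matrix(cophenetic(hclust(as.dist(d), method = "single")))
    expect_equal(unclass(s), coph[rownames(s), colnames(s)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("every SLM is ultrametric and bounded by d", {
  for (seed in 1:10) {
    d <- rand_distance_matrix(8, seed = 900 + seed)
    s <- single_linkage_matrix(single_linkage_merges(d))
    expect_lte(ultrametric_violation(unclass(s)), 1e-12)
    expect_true(all(unclass(s) <= d + 1e-12))
  }
})

test_that("disconnected networks are rejected", {
  d <- toy4_distance()
  d[c("A", "B"), c("C", "D")] <- Inf
  d[c("C", "D"), c("A", "B")] <- Inf
  expect_error(single_linkage_merges(d), "disconnected")
})

test_that("SLM contrast is the elementwise difference, antisymmetric", {
  a <- single_linkage_matrix(single_linkage_merges(rand_distance_matrix(6, 1)))
  b <- single_linkage_matrix(single_linkage_merges(rand_distance_matrix(6, 2)))
  expect_true(all(unclass(sld_contrast(a, a)) == 0))
  expect_equal(unclass(sld_contrast(a, b)), -unclass(sld_contrast(b, a)))
  dimnames(b) <- list(letters[1:6], letters[1:6])
  expect_error(sld_contrast(a, b), "different node sets")
})

test_that("a contrast differing in one merge is nonzero exactly on the split", {
  d1 <- toy4_distance()
  d2 <- toy4_distance()
  d2["B", "C"] <- d2["C", "B"] <- 0.6       # move only the final merge
  s1 <- single_linkage_matrix(single_linkage_merges(d1))
  s2 <- single_linkage_matrix(single_linkage_merges(d2))
  diff <- unclass(sld_contrast(s2, s1))
  split_pairs <- as.matrix(expand.grid(c("A", "B"), c("C", "D")))
  for (k in seq_len(nrow(split_pairs)))
    expect_equal(unname(diff[split_pairs[k, 1], split_pairs[k, 2]]), 0.1)
  expect_equal(unname(diff["A", "B"]), 0)
  expect_equal(unname(diff["C", "D"]), 0)
})

test_that("newick export preserves cophenetic structure", {
  d2 <- matrix(c(0, .4, .4, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(dendrogram_to_newick(single_linkage_merges(d2)),
               "(A:0.2,B:0.2);")
  d <- rand_distance_matrix(7, seed = 77)
  dend <- single_linkage_merges(d)
  phy <- ape::read.tree(text = dendrogram_to_newick(dend))
  coph <- ape::cophenetic.phylo(phy)
  s <- single_linkage_matrix(dend)
  expect_equal(coph[rownames(s), colnames(s)], unclass(s),
               tolerance = 1e-8, ignore_attr = TRUE)
  # ultrametric tree: all leaves equidistant from root
  depths <- ape::node.depth.edgelength(phy)[seq_len(7)]
  expect_lt(diff(range(depths)), 1e-8)
})

test_that("beta0-curves shift left as connectivity strengthens", {
  sch <- tiny_schema(8, sets = list(all = sprintf("r%02d", 1:8)))
  gcc_at <- function(r, seed) {
    cfg <- cohort_config(n_subjects_per_group = 12,
                         baseline_correlation = 0,
                         blocks = list(list(rois = "all", r = r)),
                         seed = seed)
    m <- generate_roi_activity(cfg, sch)[["control.wk4"]]
    gcc_threshold(distance_matrix(m))
  }
  lo <- vapply(1:20, function(s) gcc_at(0.1, 5000 + s), numeric(1))
  hi <- vapply(1:20, function(s) gcc_at(0.8, 5000 + s), numeric(1))
  expect_lt(mean(hi), mean(lo))
})
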