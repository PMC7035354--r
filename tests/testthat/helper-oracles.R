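# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own algorithms: minimax distances
# by Floyd-Warshall-style relaxation, spanning trees by exhaustive
# enumeration, permutation nulls by explicit enumeration.

rand_distance_matrix <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(0, p, p)
  d[upper.tri(d)] <- runif(p * (p - 1) / 2, 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(sprintf("n%02d", 1:p), sprintf("n%02d", 1:p))
  d
}

# Minimax path distances: for each pair, the minimum over all paths of the
# maximum edge weight, by repeated max-relaxation (Floyd-Warshall variant).
minimax_oracle <- function(d) {
  s <- unclass(d)
  p <- nrow(s)
  for (k in seq_len(p))
    for (i in seq_len(p))
      s[i, ] <- pmin(s[i, ], pmax(s[i, k], s[k, ]))
  diag(s) <- 0
  s
}

# Exhaustive minimum spanning-tree weight: try every (p-1)-subset of edges.
mst_weight_oracle <- function(d) {
  p <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[ut]
  best <- Inf
  for (sel in asplit(combn(nrow(ut), p - 1), 2)) {
    g <- igraph::graph_from_edgelist(ut[sel, , drop = FALSE], directed = FALSE)
    if (igraph::vcount(g) < p) next
    if (igraph::is_connected(g) && igraph::ecount(g) == p - 1)
      best <- min(best, sum(w[sel]))
  }
  best
}

# All distinct two-group splits of 1..(na+nb) into sizes na, nb.
exact_unpaired_null <- function(stat_fn, a, b) {
  n <- nrow(a) + nrow(b)
  pooled <- rbind(a, b)
  idx <- combn(n, nrow(a))
  apply(idx, 2, function(i)
    stat_fn(pooled[i, , drop = FALSE], pooled[-i, , drop = FALSE]))
}

ultrametric_violation <- function(s) {
  p <- nrow(s)
  worst <- 0
  for (i in 1:p) for (j in 1:p) for (k in 1:p)
    worst <- max(worst, s[i, k] - max(s[i, j], s[j, k]))
  worst
}

toy4_distance <- function() {
  d <- matrix(0.9, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.3
  d["B", "C"] <- d["C", "B"] <- 0.5
  diag(d) <- 0
  d
}

complete_distance <- function(p, len = 1) {
  d <- matrix(len, p, p,
              dimnames = list(LETTERS[1:p], LETTERS[1:p]))
  diag(d) <- 0
  d
}

tiny_schema <- function(p, sets = list()) {
  roi_schema(sprintf("r%02d", 1:p), region_sets = sets)
}

random_subject_matrix <- function(n, schema, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subject_matrix(matrix(rnorm(n * length(schema$labels)), n),
                 schema = schema)
}
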