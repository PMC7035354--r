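#' Minimum spanning tree of a distance network
#'
#' Kruskal's algorithm over the finite distances, scanning candidate edges
#' in ascending `(weight, i, j)` order so equal-weight ties break
#' deterministically by node index. The MST is the minimum edge set whose
#' pairwise minimax distances reproduce the single-linkage matrix of the
#' full network. Ties among edge weights can make the MST (and hence
#' modularization scores) non-unique; the returned tree records whether any
#' tie exists so downstream scoring can warn.
#'
#' @param d a `distance_matrix`.
#' @return Object of class `mst`: list with `edges`
#'   (`data.frame(from, to, weight)`, p-1 rows), `labels`, and
#'   `weight_ties` (logical).
#' @export
minimum_spanning_tree <- function(d) {
  d <- validate_distance(d)
  labs <- rownames(d)
  p <- length(labs)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- unclass(d)[ut]
  keep <- is.finite(w)
  ut <- ut[keep, , drop = FALSE]
  w <- w[keep]
  ord <- order(w, ut[, 1], ut[, 2])
  parent <- seq_len(p)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  sel <- integer(0)
  for (e in ord) {
    if (length(sel) == p - 1L) break
    ra <- find(ut[e, 1]); rb <- find(ut[e, 2])
    if (ra == rb) next
    parent[rb] <- ra
    sel <- c(sel, e)
  }
  if (length(sel) < p - 1L)
    stop("network is disconnected; no spanning tree exists")
  edges <- data.frame(from = labs[ut[sel, 1]], to = labs[ut[sel, 2]],
                      weight = w[sel], stringsAsFactors = FALSE)
  structure(list(edges = edges[order(edges$weight), ], labels = labs,
                 weight_ties = anyDuplicated(signif(w, 12)) > 0L),
            class = "mst")
}

#' @export
print.mst <- function(x, ...) {
  cat("minimum spanning tree:", length(x$labels), "nodes,",
      nrow(x$edges), "edges, total weight",
      format(sum(x$edges$weight), digits = 5),
      if (x$weight_ties) "(weight ties present)" else "", "\n")
  invisible(x)
}

#' Modularization score of a region set on an MST
#'
#' The number of tree edges with BOTH endpoints inside the named region set
#' — the study's measure of how modularized (directly interconnected) a
#' functional system such as the memory-related or reward-motivation-related
#' regions is on the backbone of the network. Bounded by
#' `min(|S| - 1, p - 1)`, attained exactly when the set induces a connected
#' subtree.
#'
#' @param t an `mst`.
#' @param region_set a region-set name in the schema or a vector of labels.
#' @param schema optional `roi_schema` used to resolve a set name.
#' @param warn_ties warn when the underlying network had tied edge weights
#'   (the MST, and hence this count, may then be non-unique).
#' @return integer edge count.
#' @export
modularization_score <- function(t, region_set, schema = NULL,
                                 warn_ties = TRUE) {
  stopifnot(inherits(t, "mst"))
  labs <- if (!is.null(schema)) resolve_region_set(schema, region_set)
          else region_set
  unknown <- setdiff(labs, t$labels)
  if (length(unknown))
    stop("unknown ROI labels: ", paste(unknown, collapse = ", "))
  if (warn_ties && t$weight_ties)
    warning("edge-weight ties present: the MST and its modularization ",
            "score may not be unique")
  sum(t$edges$from %in% labs & t$edges$to %in% labs)
}

#' Export an MST as a tab-separated edge list
#' @param t an `mst`.
#' @param path output path.
#' @export
write_mst <- function(t, path) {
  utils::write.table(t$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Minimax distances along a tree
#'
#' For each node pair the maximum edge weight on the (unique) tree path.
#' Used to verify the MST/SLM equivalence: on the MST of `d` these equal
#' the single-linkage matrix of `d`.
#'
#' @param t an `mst`.
#' @return p x p symmetric matrix.
#' @export
mst_minimax <- function(t) {
  p <- length(t$labels)
  g <- igraph::graph_from_data_frame(t$edges, directed = FALSE,
                                     vertices = t$labels)
  s <- matrix(0, p, p, dimnames = list(t$labels, t$labels))
  for (i in seq_len(p - 1)) {
    paths <- igraph::shortest_paths(g, from = t$labels[i],
                                    to = t$labels[(i + 1):p],
                                    output = "epath", weights = NA)$epath
    for (k in seq_along(paths)) {
      j <- i + k
      s[i, j] <- s[j, i] <- max(igraph::E(g)$weight[paths[[k]]])
    }
  }
  s
}
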