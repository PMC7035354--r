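#' Single-linkage merge structure of a distance network (graph filtration)
#'
#' Thresholding a distance matrix at increasing values yields a nested
#' sequence of binary graphs; connected components merge as the threshold
#' grows. Each merge event joins the two components at their single-linkage
#' distance (SLD): the minimum inter-component distance. This function runs
#' the filtration by a Kruskal-style sweep with a union-find structure,
#' processing candidate edges in ascending `(distance, i, j)` order so ties
#' are resolved deterministically (tie order affects only merge narration,
#' never the resulting SLDs).
#'
#' @param d a `distance_matrix` (symmetric, zero diagonal; `Inf` allowed for
#'   dropped pairs).
#' @return Object of class `sl_dendrogram`: list with `labels`, `merges`
#'   (list of `list(a, b, sld)` — the two component label sets and the merge
#'   distance, nondecreasing), `heights` (the p-1 SLDs) and `hmerge`
#'   (an [stats::hclust]-style merge matrix used for tree export).
#' @export
single_linkage_merges <- function(d) {
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
  members <- as.list(seq_len(p))
  last_merge <- integer(p)            # 0 = singleton leaf
  merges <- vector("list", p - 1L)
  hmerge <- matrix(0L, p - 1L, 2L)
  heights <- numeric(p - 1L)
  k <- 0L
  for (e in ord) {
    if (k == p - 1L) break
    ra <- find(ut[e, 1]); rb <- find(ut[e, 2])
    if (ra == rb) next
    k <- k + 1L
    merges[[k]] <- list(a = labs[members[[ra]]], b = labs[members[[rb]]],
                        sld = w[e])
    hmerge[k, ] <- c(if (last_merge[ra] == 0L) -ra else last_merge[ra],
                     if (last_merge[rb] == 0L) -rb else last_merge[rb])
    heights[k] <- w[e]
    parent[rb] <- ra
    members[[ra]] <- c(members[[ra]], members[[rb]])
    last_merge[ra] <- k
  }
  if (k < p - 1L)
    stop("network is disconnected: filtration produced only ", k,
         " merges for ", p, " nodes (infinite distances isolate a part)")
  structure(list(labels = labs, merges = merges, heights = heights,
                 hmerge = hmerge),
            class = "sl_dendrogram")
}

validate_distance <- function(d) {
  d <- if (inherits(d, "distance_matrix")) d else
    structure(as.matrix(d), class = c("distance_matrix", "matrix"))
  m <- unclass(d)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- sprintf("n%02d", seq_len(nrow(m)))
    attr(d, "dimnames") <- dimnames(m)
  }
  if (any(abs(m - t(m)) > 1e-12, na.rm = TRUE))
    stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix must have zero diagonal")
  if (any(m[is.finite(m)] < 0)) stop("distances must be nonnegative")
  d
}

#' @export
print.sl_dendrogram <- function(x, ...) {
  cat("single-linkage dendrogram:", length(x$labels), "nodes,",
      length(x$merges), "merges, GCC threshold",
      format(max(x$heights), digits = 4), "\n")
  invisible(x)
}

#' beta0-curve of a filtration
#'
#' The number of connected components beta0 as a step function of the
#' distance threshold: starts at p below the first merge, drops by one at
#' every merge SLD, reaches 1 at the GCC threshold. Evaluated exactly at
#' the merge thresholds (piecewise-constant, right-continuous:
#' `beta0(t) = p - #\{merges with sld <= t\}`).
#'
#' @param dend an `sl_dendrogram` (or a `distance_matrix`, filtrated first).
#' @return `data.frame(threshold, beta0)` of class `beta0_curve`; the first
#'   row is `(0, p)` (assuming all off-diagonal distances positive).
#' @export
beta0_curve <- function(dend) {
  dend <- as_dendrogram(dend)
  p <- length(dend$labels)
  th <- unique(dend$heights)
  b0 <- vapply(th, function(t) p - sum(dend$heights <= t), numeric(1))
  structure(data.frame(threshold = c(0, th), beta0 = c(p, b0)),
            class = c("beta0_curve", "data.frame"))
}

#' Evaluate a beta0-curve at arbitrary thresholds
#' @param curve a `beta0_curve`.
#' @param t numeric thresholds.
#' @return integer beta0 values.
#' @export
beta0_at <- function(curve, t) {
  vapply(t, function(x) curve$beta0[max(which(curve$threshold <= x))],
         numeric(1))
}

as_dendrogram <- function(x) {
  if (inherits(x, "sl_dendrogram")) x else single_linkage_merges(x)
}

#' Single-linkage matrix (SLM)
#'
#' The p x p matrix whose (x, y) entry is the SLD of the merge event that
#' first places x and y in one connected component. The SLM is an
#' ultrametric (`s_ik <= max(s_ij, s_jk)`) and satisfies `s <= d`
#' elementwise; it equals the minimax path distance of the weighted network.
#'
#' @param dend an `sl_dendrogram` (or a `distance_matrix`).
#' @return p x p symmetric matrix of class `slm`, zero diagonal.
#' @export
single_linkage_matrix <- function(dend) {
  dend <- as_dendrogram(dend)
  p <- length(dend$labels)
  s <- matrix(0, p, p, dimnames = list(dend$labels, dend$labels))
  for (m in dend$merges)
    s[m$a, m$b] <- s[m$b, m$a] <- m$sld
  structure(s, class = c("slm", "matrix"))
}

#' GCC birth threshold
#'
#' The minimum threshold at which the filtration has a single connected
#' component containing all nodes (the giant connected component): the
#' maximum single-linkage merge distance.
#'
#' @param dend an `sl_dendrogram` (or a `distance_matrix`).
#' @return scalar threshold.
#' @export
gcc_threshold <- function(dend) {
  dend <- as_dendrogram(dend)
  max(dend$heights)
}

#' Elementwise SLM contrast
#'
#' Difference `a - b` of two single-linkage matrices over the same node set
#' (e.g. the later minus the earlier age of a group: negative entries mean
#' the pair merged earlier, i.e. connected more strongly, at the later age).
#'
#' @param a,b `slm` matrices with identical labels.
#' @return p x p antisymmetric-under-swap difference matrix.
#' @export
sld_contrast <- function(a, b) {
  if (!identical(dimnames(a), dimnames(b)))
    stop("SLMs are over different node sets")
  structure(unclass(a) - unclass(b), class = c("slm_contrast", "matrix"))
}

#' Dendrogram export: hclust and Newick
#'
#' `as_hclust` converts the merge structure to a [stats::hclust] object
#' (merge heights = SLDs); `dendrogram_to_newick` writes a Newick string
#' whose leaf-to-leaf cophenetic distances equal the SLDs (midpoint branch
#' lengths: each subtree root sits at half its merge height).
#'
#' @param dend an `sl_dendrogram`.
#' @return `as_hclust`: an `hclust`; `dendrogram_to_newick`: a Newick string
#'   (invisibly, if written to `path`).
#' @export
as_hclust <- function(dend) {
  stopifnot(inherits(dend, "sl_dendrogram"))
  structure(list(merge = dend$hmerge, height = dend$heights,
                 order = hclust_leaf_order(dend$hmerge),
                 labels = dend$labels, method = "single",
                 call = match.call(), dist.method = "sqrt(1-r)"),
            class = "hclust")
}

hclust_leaf_order <- function(hmerge) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(hmerge[k, 1]), walk(hmerge[k, 2]))
  }
  walk(nrow(hmerge))
}

#' @rdname as_hclust
#' @param path optional output file; when `NULL` the string is returned.
#' @export
dendrogram_to_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(as_hclust(dend))
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a beta0-curve as CSV
#' @param curve a `beta0_curve`.
#' @param path output path.
#' @export
write_beta0_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
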