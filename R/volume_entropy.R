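#' Weighted graph for the generalized Markov system
#'
#' An undirected graph with positive edge lengths over the schema's nodes,
#' carrying the derived directed edge space (each undirected edge as two
#' ordered pairs). The GMS works on the q = 2m directed edges.
#'
#' @param edges `data.frame(from, to, length)` of undirected edges.
#' @param nodes character vector of node labels (defaults to the labels
#'   appearing in `edges`).
#' @return Object of class `weighted_graph`: list with `nodes`, `edges`,
#'   and `normalized` flag.
#' @export
weighted_graph <- function(edges, nodes = NULL) {
  stopifnot(all(c("from", "to", "length") %in% names(edges)))
  if (any(edges$length <= 0))
    stop("all edge lengths must be positive (a zero distance means r = 1; ",
         "perturb upstream)")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("duplicate undirected edges")
  structure(list(nodes = as.character(nodes),
                 edges = data.frame(from = as.character(edges$from),
                                    to = as.character(edges$to),
                                    length = edges$length,
                                    stringsAsFactors = FALSE),
                 normalized = FALSE),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("weighted graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "undirected edges (q =", 2 * nrow(x$edges), "directed),",
      if (x$normalized) "volume-normalized" else "unnormalized", "\n")
  invisible(x)
}

#' Extract the GCC-supporting graph from a distance matrix
#'
#' The graph on which information flow is quantified once the filtration
#' has produced a giant connected component. Modes: `"filtration"`
#' (default) keeps every edge with distance at or below the GCC birth
#' threshold — the binary graph at the moment the GCC forms; `"mst"` keeps
#' only the spanning-tree edges (degenerate for non-backtracking entropy:
#' trees carry no closed non-backtracking paths); `"full"` keeps all finite
#' edges.
#'
#' @param d a `distance_matrix`.
#' @param mode `"filtration"`, `"mst"` or `"full"`.
#' @return A [weighted_graph()] with lengths equal to the distances.
#' @export
extract_gcc_graph <- function(d, mode = c("filtration", "mst", "full")) {
  mode <- match.arg(mode)
  d <- validate_distance(d)
  labs <- rownames(d)
  if (mode == "mst") {
    t <- minimum_spanning_tree(d)
    return(weighted_graph(data.frame(from = t$edges$from, to = t$edges$to,
                                     length = t$edges$weight), labs))
  }
  thr <- if (mode == "filtration") gcc_threshold(d) else Inf
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- unclass(d)[ut]
  keep <- is.finite(w) & w <= thr
  weighted_graph(data.frame(from = labs[ut[keep, 1]],
                            to = labs[ut[keep, 2]],
                            length = w[keep]), labs)
}

#' Normalize graph volume to the GMS convention
#'
#' Scales all lengths by one constant so the total edge weight equals 2
#' over the directed edge space (each undirected length counted twice;
#' convention `"directed2"`, default) or over the undirected edges
#' (`"undirected2"`). Volume entropy computed after normalization is
#' invariant to any uniform rescaling of the input distances.
#'
#' @param g a `weighted_graph`.
#' @param convention `"directed2"` or `"undirected2"`.
#' @return The rescaled `weighted_graph`, flagged as normalized.
#' @export
normalize_volume <- function(g, convention = c("directed2", "undirected2")) {
  convention <- match.arg(convention)
  stopifnot(inherits(g, "weighted_graph"))
  total <- sum(g$edges$length)            # undirected total
  target <- if (convention == "directed2") 1 else 2
  g$edges$length <- g$edges$length * (target / total)
  g$normalized <- TRUE
  g$convention <- convention
  g
}

# Directed edge table: each undirected edge as two ordered (tail, head)
# pairs; `rev` indexes the opposite orientation.
directed_edges <- function(g) {
  m <- nrow(g$edges)
  data.frame(tail = c(g$edges$from, g$edges$to),
             head = c(g$edges$to, g$edges$from),
             length = rep(g$edges$length, 2),
             rev = c(m + seq_len(m), seq_len(m)),
             stringsAsFactors = FALSE)
}

# Sparse q x q pattern of the edge-succession relation a_ef.
edge_adjacency <- function(g, adjacency = c("nonbacktracking", "successor")) {
  adjacency <- match.arg(adjacency)
  de <- directed_edges(g)
  q <- nrow(de)
  by_tail <- split(seq_len(q), de$tail)
  ii <- jj <- vector("list", q)
  for (e in seq_len(q)) {
    succ <- by_tail[[de$head[e]]]
    if (adjacency == "nonbacktracking") succ <- succ[succ != de$rev[e]]
    ii[[e]] <- rep.int(e, length(succ))
    jj[[e]] <- succ
  }
  list(A = Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                                dims = c(q, q)),
       edges = de)
}

#' Edge-transition matrix L(h)
#'
#' The q x q matrix `L(h)[e, f] = a_ef * exp(-h * l(f))` over directed
#' edges, where `a_ef = 1` when edge f can succeed edge e (head of e is the
#' tail of f) — excluding the immediate reversal of e under the default
#' non-backtracking adjacency. At `h = 0` it is the binary edge-adjacency
#' matrix.
#'
#' @param g a (normalized) `weighted_graph`.
#' @param h nonnegative decay constant.
#' @param adjacency `"nonbacktracking"` (default) or `"successor"`
#'   (reversal allowed).
#' @return Sparse `Matrix` of dimension q x q with an `edges` attribute
#'   (the directed edge table defining row/column order).
#' @export
edge_transition_matrix <- function(g, h,
                                   adjacency = c("nonbacktracking",
                                                 "successor")) {
  ea <- edge_adjacency(g, adjacency)
  L <- ea$A %*% Matrix::Diagonal(x = exp(-h * ea$edges$length))
  attr(L, "edges") <- ea$edges
  L
}

# Spectral radius (Perron root) of a nonnegative matrix via power iteration
# on M + I (the unit shift makes every recurrent class primitive). Returns
# the radius and the limiting nonnegative vector.
power_radius <- function(M, tol = 1e-13, max_iter = 50000L) {
  q <- nrow(M)
  v <- rep(1 / q, q)
  lam <- NA_real_
  for (i in seq_len(max_iter)) {
    w <- as.numeric(M %*% v) + v
    s <- sum(w)
    if (s == 0) return(list(radius = 0, vector = v, iter = i))
    w <- w / s
    if (i > 5 && abs(s - 1 - lam) <= tol * max(1, abs(lam)) &&
        max(abs(w - v)) <= 1e-12) {
      return(list(radius = s - 1, vector = w, iter = i))
    }
    lam <- s - 1
    v <- w
  }
  list(radius = lam, vector = v, iter = max_iter, converged = FALSE)
}

#' Volume entropy of a weighted graph
#'
#' The unique `h >= 0` at which the spectral radius of the edge-transition
#' matrix `L(h)` equals 1. The radius is continuous and strictly decreasing
#' in `h` on connected non-tree graphs, so the root is found by bracketed
#' bisection (bracket grown geometrically) refined to `|radius - 1|` within
#' tolerance. The graph must be volume-normalized first; entropy is then
#' invariant to uniform rescaling of the raw distances.
#'
#' @param g a normalized `weighted_graph`.
#' @param adjacency see [edge_transition_matrix()].
#' @param tol tolerance on `radius(L(h)) - 1` (default 1e-12; the solve
#'   errors if it cannot reach 1e-9).
#' @return scalar `h`, with attributes `radius` (achieved radius) and
#'   `iterations`.
#' @export
volume_entropy <- function(g, adjacency = c("nonbacktracking", "successor"),
                           tol = 1e-12) {
  adjacency <- match.arg(adjacency)
  stopifnot(inherits(g, "weighted_graph"))
  if (!g$normalized)
    stop("normalize the graph volume first (normalize_volume)")
  p <- length(g$nodes)
  m <- nrow(g$edges)
  if (adjacency == "nonbacktracking" && m == p - 1L)
    stop("degenerate: a tree has no closed non-backtracking paths, so the ",
         "edge-transition radius is 0 for every h; use mode = 'filtration' ",
         "(or adjacency = 'successor')")
  ea <- edge_adjacency(g, adjacency)
  lam <- function(h) {
    power_radius(ea$A %*% Matrix::Diagonal(x = exp(-h * ea$edges$length)))$radius
  }
  f0 <- lam(0) - 1
  if (f0 < 0)
    stop("spectral radius at h = 0 is ", format(f0 + 1, digits = 6),
         " < 1: volume entropy would be negative (graph too sparse)")
  lo <- 0; flo <- f0
  hi <- 1
  fhi <- lam(hi) - 1
  grow <- 0L
  while (fhi > 0) {
    lo <- hi; flo <- fhi
    hi <- hi * 2
    fhi <- lam(hi) - 1
    grow <- grow + 1L
    if (grow > 60L) stop("failed to bracket the volume-entropy root")
  }
  # bisection with a secant step when it stays inside the bracket
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- if (is.finite(flo) && flo != fhi) {
      cand <- lo - flo * (hi - lo) / (fhi - flo)
      if (cand > lo && cand < hi) cand else (lo + hi) / 2
    } else (lo + hi) / 2
    fm <- lam(mid) - 1
    if (abs(fm) <= tol || (hi - lo) < 1e-15 * max(1, hi) || it >= 200L) {
      if (abs(fm) > 1e-9)
        stop("volume-entropy solve did not reach tolerance: |radius - 1| = ",
             format(abs(fm), digits = 3))
      return(structure(mid, radius = fm + 1, iterations = it))
    }
    if (fm > 0) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
}

#' Stationary edge capacities and node capacities
#'
#' At the volume-entropy root, `L(h)` has leading eigenvalue 1; its
#' nonnegative leading right eigenvector z (Perron-Frobenius), normalized
#' to sum 1, is the stationary state of the q directed edges. Reshaped into
#' the p x p edge-capacity matrix `Z[v, w] = z(v -> w)`, it yields the
#' afferent (column-sum), efferent (row-sum) and net (afferent - efferent)
#' node capacities; net capacities always sum to zero.
#'
#' Simplicity of the leading eigenvalue is certified through the strongly
#' connected components of the edge-succession digraph: if more than one
#' recurrent component attains the spectral radius the stationary state is
#' not unique and an error identifies them; if the digraph is connected but
#' not strongly (dangling degree-1 vertices), a warning notes that
#' capacities concentrate on the recurrent core.
#'
#' @param g a normalized `weighted_graph`.
#' @param h the volume entropy (from [volume_entropy()]).
#' @param adjacency see [edge_transition_matrix()].
#' @return Object of class `gms_result`: list with `h`, `Z` (p x p matrix),
#'   `afferent`, `efferent`, `net` (named length-p vectors), `z_edges`
#'   (directed edge table with capacity column), `adjacency`,
#'   `volume_convention`.
#' @export
edge_capacity <- function(g, h, adjacency = c("nonbacktracking",
                                              "successor")) {
  adjacency <- match.arg(adjacency)
  stopifnot(inherits(g, "weighted_graph"), g$normalized)
  ea <- edge_adjacency(g, adjacency)
  L <- ea$A %*% Matrix::Diagonal(x = exp(-h * ea$edges$length))
  eg <- igraph::graph_from_adjacency_matrix(ea$A > 0, mode = "directed")
  comp <- igraph::components(eg, mode = "strong")
  if (comp$no > 1L) {
    big <- which(comp$csize > 1L)
    radii <- vapply(big, function(k) {
      idx <- which(comp$membership == k)
      power_radius(L[idx, idx, drop = FALSE])$radius
    }, numeric(1))
    top <- max(radii)
    attaining <- sum(radii >= top - 1e-9 * max(1, top))
    if (attaining > 1L)
      stop("leading eigenvalue of L(h) is not simple: ", attaining,
           " recurrent edge components attain the spectral radius ",
           format(top, digits = 6), "; the stationary state is not unique")
    warning("edge-succession digraph is not strongly connected (",
            comp$no, " components); stationary capacities concentrate ",
            "on the recurrent core")
  }
  pr <- power_radius(L)
  z <- pr$vector
  resid <- max(abs(as.numeric(L %*% z) - pr$radius * z))
  if (resid > 1e-8)
    stop("stationary state did not converge (residual ",
         format(resid, digits = 3), ")")
  z <- pmax(z, 0)
  z <- z / sum(z)
  p <- length(g$nodes)
  Z <- matrix(0, p, p, dimnames = list(g$nodes, g$nodes))
  Z[cbind(match(ea$edges$tail, g$nodes), match(ea$edges$head, g$nodes))] <- z
  afferent <- colSums(Z)
  efferent <- rowSums(Z)
  structure(list(h = as.numeric(h), Z = Z,
                 afferent = afferent, efferent = efferent,
                 net = afferent - efferent,
                 z_edges = data.frame(from = ea$edges$tail,
                                      to = ea$edges$head,
                                      length = ea$edges$length,
                                      z = z, stringsAsFactors = FALSE),
                 adjacency = adjacency,
                 volume_convention = g$convention),
            class = "gms_result")
}

#' @export
print.gms_result <- function(x, ...) {
  cat("GMS result: h =", format(x$h, digits = 6), "on",
      length(x$afferent), "nodes /", nrow(x$z_edges), "directed edges (",
      x$adjacency, ",", x$volume_convention, ")\n")
  top <- order(-abs(x$net))[1:min(5, length(x$net))]
  cat("largest |net| capacities:",
      paste(sprintf("%s=%+.4f", names(x$net)[top], x$net[top]),
            collapse = " "), "\n")
  invisible(x)
}

#' Full GMS analysis of a distance network
#'
#' Extracts the GCC-supporting graph, normalizes its volume, solves for the
#' volume entropy and computes the stationary edge/node capacities.
#'
#' @param d a `distance_matrix`.
#' @param mode graph extraction mode, see [extract_gcc_graph()].
#' @param adjacency see [edge_transition_matrix()].
#' @param convention see [normalize_volume()].
#' @return A `gms_result` (with the extracted graph attached as `graph`).
#' @export
gms_analysis <- function(d, mode = c("filtration", "mst", "full"),
                         adjacency = c("nonbacktracking", "successor"),
                         convention = c("directed2", "undirected2")) {
  g <- normalize_volume(extract_gcc_graph(d, match.arg(mode)),
                        match.arg(convention))
  h <- volume_entropy(g, match.arg(adjacency))
  res <- edge_capacity(g, as.numeric(h), match.arg(adjacency))
  res$graph <- g
  res
}

#' Global efficiency of a weighted network
#'
#' Mean inverse weighted shortest-path length over ordered node pairs
#' (Latora-Marchiori): `E = mean_{i != j} 1 / l_ij` with `l_ij` the
#' shortest-path distance on the full weighted distance graph (or, when
#' `graph = "gcc"`, on the filtration graph at the GCC threshold).
#'
#' @param d a `distance_matrix`.
#' @param graph `"full"` (default) or `"gcc"`.
#' @return scalar efficiency.
#' @export
global_efficiency <- function(d, graph = c("full", "gcc")) {
  graph <- match.arg(graph)
  d <- validate_distance(d)
  g <- extract_gcc_graph(d, if (graph == "full") "full" else "filtration")
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$from, to = g$edges$to,
               weight = g$edges$length),
    directed = FALSE, vertices = g$nodes)
  sp <- igraph::distances(ig, weights = igraph::E(ig)$weight)
  off <- sp[row(sp) != col(sp)]
  mean(1 / off)
}

#' Write a GMS result as JSON / capacities as CSV
#' @param res a `gms_result`.
#' @param path output path.
#' @export
write_gms_json <- function(res, path) {
  jsonlite::write_json(
    list(h = res$h,
         volume_convention = res$volume_convention,
         adjacency = res$adjacency,
         capacities = data.frame(node = names(res$afferent),
                                 afferent = unname(res$afferent),
                                 efferent = unname(res$efferent),
                                 net = unname(res$net)),
         edges = res$z_edges[, c("from", "to", "z")]),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_gms_json
#' @export
write_capacities_csv <- function(res, path) {
  utils::write.csv(data.frame(node = names(res$afferent),
                              afferent = unname(res$afferent),
                              efferent = unname(res$efferent),
                              net = unname(res$net)),
                   path, row.names = FALSE)
  invisible(path)
}
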