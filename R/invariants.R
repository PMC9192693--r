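#' Combinatorial invariants entering the null-model moments
#'
#' Computes everything the second-order moment formulas need from the bare
#' graph: the degree sequence and its histogram, the number pi3 of
#' (not-necessarily-induced) P3 subgraphs — paths on three nodes, i.e.
#' wedges — the number of 2K2 subgraphs (pairs of disjoint edges), and the
#' common-neighbor table of non-adjacent node pairs at distance two. The
#' identities pi3 = sum_v C(deg v, 2) and 2K2 = C(m,2) - pi3 are used; wedges
#' are enumerated from adjacency lists in O(sum deg^2) so the computation
#' scales to large sparse graphs. All counts are held in doubles as exact
#' integers (well below 2^53 at any realistic scale).
#'
#' @param graph a [colored_graph()].
#' @return An object of class `graph_invariants` with fields `n`, `m`,
#'   `degrees` (named integer), `degree_histogram` (named count by degree
#'   value), `pi3`, `two_k2`, and `dist2_common`, a data frame with columns
#'   `u`, `v`, `common` listing each non-adjacent pair (u < v by position)
#'   with at least one common neighbor.
#' @examples
#' g <- colored_graph(rbind(c("a","b"), c("b","c")),
#'                    c(a = "1", b = "1", c = "2"))
#' inv <- graph_invariants(g)
#' inv$pi3      # 1 wedge
#' inv$two_k2   # 0
#' @export
graph_invariants <- function(graph) {
  stopifnot(inherits(graph, "colored_graph"))
  deg <- .degrees(graph)
  pi3 <- sum(as.numeric(deg) * (as.numeric(deg) - 1) / 2)
  m <- graph$m
  two_k2 <- m * (m - 1) / 2 - pi3

  hist_tab <- table(deg)
  degree_histogram <- stats::setNames(as.integer(hist_tab), names(hist_tab))

  dist2 <- .dist2_table(graph)

  structure(list(
    n = graph$n, m = m, degrees = deg,
    degree_histogram = degree_histogram,
    pi3 = pi3, two_k2 = two_k2,
    dist2_common = dist2
  ), class = "graph_invariants")
}

#' @export
print.graph_invariants <- function(x, ...) {
  cat(sprintf("graph_invariants: n = %d, m = %d, pi3 = %.0f, 2K2 = %.0f, %d distance-2 pairs\n",
              x$n, x$m, x$pi3, x$two_k2, nrow(x$dist2_common)))
  invisible(x)
}

# wedge enumeration: for each center, all pairs of its neighbors; the
# multiplicity of an unordered pair equals its common-neighbor count.
.dist2_table <- function(graph) {
  n <- graph$n
  adj <- .adj_list(graph)
  keys <- vector("list", n)
  for (w in seq_len(n)) {
    nb <- adj[[w]]
    d <- length(nb)
    if (d < 2) next
    nb <- sort(nb)
    # all unordered pairs (a, b), a < b, of neighbors of w
    idx <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
    a <- nb[idx[, 1]]; b <- nb[idx[, 2]]
    keys[[w]] <- (a - 1) * n + b
  }
  keys <- unlist(keys, use.names = FALSE)
  if (is.null(keys) || length(keys) == 0)
    return(data.frame(u = integer(), v = integer(), common = integer()))
  tab <- table(keys)
  key <- as.numeric(names(tab))
  cnt <- as.integer(tab)
  u <- (key - 1) %/% n + 1
  v <- (key - 1) %% n + 1
  # remove adjacent pairs (wedge endpoints joined by an edge = triangles)
  ekey <- (graph$edge_i - 1) * n + graph$edge_j
  keep <- !(key %in% ekey)
  data.frame(u = as.integer(u[keep]), v = as.integer(v[keep]),
             common = cnt[keep])
}

#' Count P3 subgraphs (wedges)
#'
#' @param graph a [colored_graph()].
#' @return `sum_v C(deg(v), 2)` as a double holding an exact integer.
#' @export
count_p3 <- function(graph) {
  deg <- as.numeric(.degrees(graph))
  sum(deg * (deg - 1) / 2)
}

#' Count 2K2 subgraphs (disjoint edge pairs)
#'
#' @param graph a [colored_graph()].
#' @return `C(m, 2) - pi3` as a double holding an exact integer.
#' @export
count_2k2 <- function(graph) {
  m <- graph$m
  m * (m - 1) / 2 - count_p3(graph)
}

#' Common-neighbor counts of non-adjacent node pairs
#'
#' @param graph a [colored_graph()].
#' @return Data frame with node labels `u`, `v` and `common`, one row per
#'   unordered non-adjacent pair with at least one common neighbor.
#' @export
dist2_common_neighbors <- function(graph) {
  d2 <- .dist2_table(graph)
  data.frame(u = graph$nodes[d2$u], v = graph$nodes[d2$v], common = d2$common,
             stringsAsFactors = FALSE)
}
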