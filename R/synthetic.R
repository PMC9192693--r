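#' Planted-partition colored graph
#'
#' Generates a node-colored random graph with a planted community structure:
#' every intra-class node pair is an edge independently with probability
#' `p_in`, every inter-class pair with `p_out`. `p_in > p_out` plants
#' homophily, `p_in < p_out` heterophily, and `p_in == p_out` is an
#' Erdos-Renyi graph whose coloring carries no signal — the null case used
#' for calibration. Isolated nodes are retained (pass the result through
#' [build_colored_graph()] to drop them).
#'
#' @param sizes named integer vector of class sizes (names are color labels).
#' @param p_in,p_out edge probabilities within / between classes.
#' @param seed optional seed.
#' @return A [colored_graph()].
#' @examples
#' g <- planted_partition(c(a = 10, b = 10), p_in = 0.8, p_out = 0.1, seed = 1)
#' diag(edge_zscore_matrix(g))
#' @export
planted_partition <- function(sizes, p_in, p_out, seed = NULL) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1, all(sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(sizes))) names(sizes) <- letters[seq_along(sizes)]
  n <- sum(sizes)
  width <- max(4, nchar(as.character(n)))
  nodes <- sprintf(paste0("v%0", width, "d"), seq_len(n))
  coloring <- stats::setNames(rep(names(sizes), times = sizes), nodes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- coloring[idx[, 1]] == coloring[idx[, 2]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(nrow(idx)) < p
  edges <- cbind(nodes[idx[keep, 1]], nodes[idx[keep, 2]])
  colored_graph(edges, coloring)
}

#' The two monochromatic contrast graphs with equal edge counts
#'
#' For an integer p >= 2, builds the pair of graphs showing that equal
#' intra-class edge counts can coexist with very different isolation: graph A
#' is the disjoint union of a complete graph K_p and 2p isolated nodes; graph
#' B is the disjoint union of K_(p-1), a star K_(1, p-1) and p isolated
#' nodes. Both carry a single color. For every p the two edge counts are
#' equal — C(p,2) = C(p-1,2) + (p-1) — while A has exactly twice as many
#' isolated nodes as B.
#'
#' @param p integer >= 2.
#' @param color the single color label used (default `"i"`).
#' @return List with elements `A` and `B`, both [colored_graph()]s.
#' @examples
#' pair <- example1_pair(3)
#' pair$A$m == pair$B$m                      # TRUE
#' sum(observed_isolated_counts(pair$A)) /
#'   sum(observed_isolated_counts(pair$B))   # 2
#' @export
example1_pair <- function(p, color = "i") {
  stopifnot(p >= 2, p == round(p))
  complete_edges <- function(nodes) {
    if (length(nodes) < 2) return(matrix(character(), ncol = 2))
    idx <- which(upper.tri(matrix(0, length(nodes), length(nodes))), arr.ind = TRUE)
    cbind(nodes[idx[, 1]], nodes[idx[, 2]])
  }
  # A = K_p + Kbar_{2p}
  a_k <- sprintf("k%03d", 1:p)
  a_iso <- sprintf("z%03d", 1:(2 * p))
  A <- colored_graph(complete_edges(a_k),
                     stats::setNames(rep(color, 3 * p), c(a_k, a_iso)))
  # B = K_{p-1} + K_{1,p-1} + Kbar_p
  b_k <- sprintf("k%03d", 1:(p - 1))
  b_hub <- "h001"
  b_leaf <- sprintf("s%03d", 1:(p - 1))
  b_iso <- sprintf("z%03d", 1:p)
  star <- cbind(rep(b_hub, p - 1), b_leaf)
  B <- colored_graph(rbind(complete_edges(b_k), star),
                     stats::setNames(rep(color, 3 * p - 1),
                                     c(b_k, b_hub, b_leaf, b_iso)))
  list(A = A, B = B)
}
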