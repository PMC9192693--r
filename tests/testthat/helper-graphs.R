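# fixtures and independent brute-force oracles shared across test files

path_graph <- function(colors = c(a = "1", b = "1", c = "2")) {
  nodes <- names(colors)
  edges <- cbind(nodes[-length(nodes)], nodes[-1])
  colored_graph(edges, colors)
}

# Erdos-Renyi colored graph; coloring balanced over s colors (uses the
# current RNG stream, so wrap calls in withr::with_seed / set.seed)
random_colored_graph <- function(n, p = 0.4, s = 2) {
  nodes <- sprintf("n%03d", seq_len(n))
  cols <- as.character(rep_len(seq_len(s), n))
  coloring <- setNames(sample(cols), nodes)
  if (n >= 2) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(idx)) < p
    edges <- cbind(nodes[idx[keep, 1]], nodes[idx[keep, 2]])
  } else edges <- matrix(character(), ncol = 2)
  colored_graph(edges, coloring)
}

random_colored_graph_mono <- function(n, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- random_colored_graph(n, p, s = 1)
  g
}

# graph from an edge subset bitmask over the C(n,2) possible pairs,
# nodes colored arbitrarily (caller recolors via profiles)
graph_from_mask <- function(n, mask_bits) {
  nodes <- sprintf("n%d", seq_len(n))
  coloring <- setNames(rep("1", n), nodes)
  if (n >= 2) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- mask_bits[seq_len(nrow(idx))] == 1L
    edges <- cbind(nodes[idx[keep, 1]], nodes[idx[keep, 2]])
  } else edges <- matrix(character(), ncol = 2)
  colored_graph(edges, coloring)
}

# brute-force P3 / 2K2 oracle: classify every pair of edges as sharing an
# endpoint (wedge) or disjoint
brute_edge_pair_counts <- function(graph) {
  m <- graph$m
  wedges <- 0; disjoint <- 0
  if (m >= 2) {
    for (e1 in 1:(m - 1)) for (e2 in (e1 + 1):m) {
      a <- c(graph$edge_i[e1], graph$edge_j[e1])
      b <- c(graph$edge_i[e2], graph$edge_j[e2])
      if (length(intersect(a, b)) > 0) wedges <- wedges + 1
      else disjoint <- disjoint + 1
    }
  }
  list(pi3 = wedges, two_k2 = disjoint)
}

# brute-force distance-2 common-neighbor oracle via the adjacency matrix
brute_dist2 <- function(graph) {
  n <- graph$n
  A <- matrix(0, n, n)
  A[cbind(graph$edge_i, graph$edge_j)] <- 1
  A <- A + t(A)
  CN <- A %*% A
  out <- list()
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (A[u, v] == 0 && CN[u, v] > 0)
      out[[length(out) + 1]] <- c(u, v, CN[u, v])
  }
  if (length(out) == 0)
    return(data.frame(u = integer(), v = integer(), common = integer()))
  out <- do.call(rbind, out)
  data.frame(u = out[, 1], v = out[, 2], common = out[, 3])
}

# partitions of n into at most `parts` positive parts (distinct class-size
# multisets); returned as a list of named count vectors
profiles_up_to <- function(n, parts = 3) {
  res <- list()
  rec <- function(rest, maxpart, acc) {
    if (rest == 0) {
      res[[length(res) + 1]] <<- acc
      return(invisible(NULL))
    }
    if (length(acc) == parts) return(invisible(NULL))
    for (p in min(rest, maxpart):1) rec(rest - p, p, c(acc, p))
  }
  rec(n, n, integer())
  lapply(res, function(cnt) setNames(cnt, as.character(seq_along(cnt))))
}

# exact closed-form moments (rational) for every statistic of (graph, profile)
analytic_exact_moments <- function(graph, counts, inv = graph_invariants(graph)) {
  s <- length(counts)
  n <- graph$n; m <- graph$m
  out <- list()
  for (i in seq_len(s)) for (j in i:s) {
    same <- i == j
    out[[paste0("m:", i, "|", j)]] <- list(
      mean = expected_edge_count(n, m, counts[i], if (same) NULL else counts[j],
                                 same, exact = TRUE),
      var = edge_count_variance(n, m, inv$pi3, counts[i],
                                if (same) NULL else counts[j], same,
                                exact = TRUE))
  }
  for (i in seq_len(s)) {
    out[[paste0("l:", i)]] <- list(
      mean = expected_isolated(graph, inv, counts[i], exact = TRUE),
      var = isolated_variance(graph, inv, counts[i], exact = TRUE))
  }
  out
}

# relabel a colored graph's coloring so that test profiles apply: assign the
# first c_1 nodes color "1", next c_2 color "2", ... in node order
with_profile <- function(graph, counts) {
  coloring <- setNames(rep(names(counts), times = counts), graph$nodes)
  colored_graph(cbind(graph$nodes[graph$edge_i], graph$nodes[graph$edge_j]),
                coloring)
}
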