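#' Falling power
#'
#' The falling r-th power a^(r) = a (a-1) ... (a-r+1), with a^(0) = 1. It
#' replaces the ordinary power wherever nodes are drawn without replacement;
#' the product is 0 as soon as a factor crosses zero.
#'
#' @param a integer base.
#' @param r nonnegative integer exponent.
#' @return The exact product as a double.
#' @examples
#' falling_power(5, 2)  # 20
#' falling_power(3, 0)  # 1
#' falling_power(2, 4)  # 0
#' @export
falling_power <- function(a, r) {
  stopifnot(length(a) == 1, length(r) == 1, r >= 0, r == round(r))
  if (r == 0) return(1)
  ks <- 0:(r - 1)
  if (any(a - ks <= 0)) return(0)
  prod(a - ks)
}

# numerically stable falling-power ratio a^(r)/b^(r) = prod (a-k)/(b-k):
# each factor lies in [0, 1] when a <= b, so no overflow at any scale.
.falling_ratio <- function(a, b, r) {
  if (r == 0) return(1)
  ks <- 0:(r - 1)
  if (any(a - ks <= 0)) return(0)
  if (any(b - ks <= 0)) stop("falling-power ratio denominator crosses zero")
  prod((a - ks) / (b - ks))
}

#' Observed per-color-pair edge counts
#'
#' Classifies every edge by the unordered pair of endpoint colors and counts
#' in a single pass.
#'
#' @param graph a [colored_graph()].
#' @return Symmetric s x s matrix `m[i, j]` of (i, j)-edge counts, with
#'   dimnames the sorted color labels. The upper triangle (i <= j) carries the
#'   counts; the matrix is symmetrized for convenience.
#' @export
observed_edge_counts <- function(graph) {
  cols <- graph$colors
  s <- length(cols)
  out <- matrix(0, s, s, dimnames = list(cols, cols))
  if (graph$m > 0) {
    ci <- match(graph$color[graph$nodes[graph$edge_i]], cols)
    cj <- match(graph$color[graph$nodes[graph$edge_j]], cols)
    lo <- pmin(ci, cj); hi <- pmax(ci, cj)
    tab <- table(factor(lo, levels = 1:s), factor(hi, levels = 1:s))
    out <- matrix(as.numeric(tab), s, s, dimnames = list(cols, cols))
    out <- out + t(out) - diag(diag(out), nrow = s)
  }
  out
}

#' Expected per-pair edge count under the recoloring null
#'
#' Expected number of (i, j)-edges under a uniformly random recoloring with
#' the same profile: `m * c_i^(2) / n^(2)` on the diagonal and
#' `2 m c_i c_j / n^(2)` off it (falling powers).
#'
#' @param n,m node and edge counts of the graph.
#' @param c_i,c_j class sizes (ignore `c_j` when `same_color`).
#' @param same_color `TRUE` for the intra-class (diagonal) case.
#' @param exact return an exact [rat()] instead of a double.
#' @return Expected count (double, or `rat` when `exact`).
#' @export
expected_edge_count <- function(n, m, c_i, c_j = NULL, same_color = TRUE,
                                exact = FALSE) {
  .check_moment_args(n, m, c_i, c_j, same_color)
  if (exact) {
    if (same_color) return(rat(m) * .rat_falling_ratio(c_i, n, 2))
    return(rat(2 * m) * rat(c_i * c_j) / rat(n * (n - 1)))
  }
  if (same_color) m * .falling_ratio(c_i, n, 2)
  else 2 * m * c_i * c_j / (n * (n - 1))
}

.check_moment_args <- function(n, m, c_i, c_j, same_color) {
  stopifnot(n >= 2, m >= 0, c_i >= 1, c_i <= n)
  if (!same_color) {
    if (is.null(c_j)) stop("c_j required when same_color = FALSE")
    stopifnot(c_j >= 1, c_i + c_j <= n)
  }
  invisible(NULL)
}

#' Variance of a per-pair edge count under the recoloring null
#'
#' Exact closed-form variance of the number of (i, j)-edges under a uniformly
#' random recoloring. The graph enters only through n, m and pi3 (the wedge
#' count): wedges determine the covariance of indicator pairs sharing a node,
#' disjoint edge pairs (2K2's, numbering C(m,2) - pi3) the rest.
#'
#' Intra-class case:
#' \deqn{\sigma^2_{ii} = \bar m(1-\bar m) + 2\{(c^{(3)}/n^{(3)} -
#'   c^{(4)}/n^{(4)})\pi_3 + (c^{(4)}/n^{(4)})\binom{m}{2}\}}
#' with \eqn{\bar m = m c^{(2)}/n^{(2)}}; the inter-class case replaces the
#' falling-power brackets by their mixed-color analogues.
#'
#' @inheritParams expected_edge_count
#' @param pi3 wedge count of the graph (see [count_p3()]).
#' @param method `"closed_form"` evaluates the variance formula directly;
#'   `"covariance"` evaluates the equivalent sum-of-covariances decomposition
#'   (used as an internal cross-check — the two must agree).
#' @return Variance (double, or `rat` when `exact`).
#' @export
edge_count_variance <- function(n, m, pi3, c_i, c_j = NULL, same_color = TRUE,
                                exact = FALSE,
                                method = c("closed_form", "covariance")) {
  method <- match.arg(method)
  .check_moment_args(n, m, c_i, c_j, same_color)
  stopifnot(pi3 >= 0, pi3 <= m * (m - 1) / 2)
  mm2 <- m * (m - 1) / 2                      # C(m, 2)

  fr <- if (exact) .rat_falling_ratio else .falling_ratio
  num <- function(x) if (exact) rat(x) else x

  if (same_color) {
    p <- fr(c_i, n, 2)                        # per-edge success prob c^(2)/n^(2)
    mbar <- num(m) * p
    padj <- fr(c_i, n, 3)                     # both wedge edges intra-class
    pdis <- fr(c_i, n, 4)                     # both disjoint edges intra-class
  } else {
    p <- num(2) * num(c_i * c_j) / num(n * (n - 1))
    mbar <- num(m) * p
    # (c_i c_j^(2) + c_i^(2) c_j) / n^(3); at n = 2 no wedge exists and the
    # numerator vanishes with the denominator, so the term is 0
    padj <- if (n < 3) num(0)
      else (num(c_i * c_j) * num(c_j - 1) + num(c_i * c_j) * num(c_i - 1)) /
        (num(n) * num(n - 1) * num(n - 2))
    # 4 c_i^(2) c_j^(2) / n^(4), assembled from bounded ratio products;
    # a disjoint (i,j)-edge pair needs 4 distinct nodes, so it is 0 for n < 4
    pdis <- if (n < 4) num(0) else num(4) * fr(c_i, n, 2) * fr(c_j, n - 2, 2)
  }

  if (method == "closed_form") {
    v <- mbar * (num(1) - mbar) +
      num(2) * ((padj - pdis) * num(pi3) + pdis * num(mm2))
  } else {
    # var = sum of indicator variances + pairwise covariances
    v <- num(m) * p * (num(1) - p) +
      num(2) * (num(pi3) * (padj - p * p) + num(mm2 - pi3) * (pdis - p * p))
  }
  v
}

#' Per-color-pair moment table of edge counts
#'
#' Observed counts, null expectations, variances, observed/expected ratios
#' (the relative intra-/inter-community densities) and z-scores for every
#' unordered color pair. Ratios and z-scores are `NA` where the null
#' expectation (resp. standard deviation) is zero — degenerate cells, e.g. a
#' singleton class on the diagonal — never silently 0.
#'
#' @param graph a [colored_graph()].
#' @param invariants optional precomputed [graph_invariants()].
#' @return Data frame (class `edge_moment_table`) with one row per unordered
#'   color pair (i <= j): `color_i`, `color_j`, `observed`, `expected`,
#'   `variance`, `ratio`, `zscore`.
#' @examples
#' g <- colored_graph(rbind(c("a","b"), c("b","c")),
#'                    c(a = "1", b = "1", c = "2"))
#' edge_moment_table(g)
#' @export
edge_moment_table <- function(graph, invariants = NULL) {
  if (is.null(invariants)) {
    pi3 <- count_p3(graph)
  } else pi3 <- invariants$pi3
  prof <- color_profile(graph)
  cols <- names(prof$counts)
  s <- prof$s
  obs <- observed_edge_counts(graph)
  rows <- list()
  k <- 0L
  for (i in seq_len(s)) for (j in i:s) {
    same <- i == j
    e <- expected_edge_count(graph$n, graph$m, prof$counts[i],
                             if (same) NULL else prof$counts[j], same)
    v <- edge_count_variance(graph$n, graph$m, pi3, prof$counts[i],
                             if (same) NULL else prof$counts[j], same)
    v <- max(v, 0)   # clip float round-off on exact-zero cases
    o <- obs[i, j]
    k <- k + 1L
    rows[[k]] <- data.frame(
      color_i = cols[i], color_j = cols[j],
      observed = o, expected = e, variance = v,
      ratio = if (e > 0) o / e else NA_real_,
      zscore = if (v > 0) (o - e) / sqrt(v) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("edge_moment_table", "data.frame")
  out
}

#' Observed/expected density ratios
#'
#' Extracts the relative intra-community densities (omega, diagonal) and
#' inter-community densities (eta, off-diagonal) from an edge moment table.
#'
#' @param table an [edge_moment_table()].
#' @return List with `omega` (named vector by color) and `eta` (symmetric
#'   matrix, `NA` diagonal-excluded cells left as computed).
#' @export
homophily_ratios <- function(table) {
  cols <- sort(unique(c(table$color_i, table$color_j)))
  s <- length(cols)
  eta <- matrix(NA_real_, s, s, dimnames = list(cols, cols))
  omega <- stats::setNames(rep(NA_real_, s), cols)
  for (r in seq_len(nrow(table))) {
    i <- match(table$color_i[r], cols); j <- match(table$color_j[r], cols)
    if (i == j) omega[i] <- table$ratio[r]
    else eta[i, j] <- eta[j, i] <- table$ratio[r]
  }
  list(omega = omega, eta = eta)
}

#' z-score matrix of intra- and inter-community edge counts
#'
#' The symmetric s x s matrix Z whose (i, j) entry standardizes the observed
#' (i, j)-edge count against its null mean and standard deviation. Diagonal
#' entries score intra-community density (homophily); off-diagonal entries
#' score inter-community density (heterophily). Cells with zero null variance
#' are `NA`.
#'
#' @param graph a [colored_graph()].
#' @param invariants optional precomputed [graph_invariants()].
#' @return Symmetric numeric matrix with color-label dimnames.
#' @export
edge_zscore_matrix <- function(graph, invariants = NULL) {
  tab <- edge_moment_table(graph, invariants)
  cols <- sort(unique(c(tab$color_i, tab$color_j)))
  s <- length(cols)
  Z <- matrix(NA_real_, s, s, dimnames = list(cols, cols))
  for (r in seq_len(nrow(tab))) {
    i <- match(tab$color_i[r], cols); j <- match(tab$color_j[r], cols)
    Z[i, j] <- Z[j, i] <- tab$zscore[r]
  }
  Z
}
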