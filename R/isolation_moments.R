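#' Observed per-color isolated-node counts
#'
#' A node v is i-isolated when g(v) = i and no neighbor of v has color i; the
#' count l_i measures how dispersed class i is. Degree-zero nodes of color i
#' are always i-isolated.
#'
#' @param graph a [colored_graph()].
#' @return Named integer vector, one entry per color.
#' @export
observed_isolated_counts <- function(graph) {
  cols <- graph$colors
  adj <- .adj_list(graph)
  ci <- match(unname(graph$color), cols)     # color index per node position
  out <- stats::setNames(integer(length(cols)), cols)
  for (v in seq_len(graph$n)) {
    if (!any(ci[adj[[v]]] == ci[v])) out[ci[v]] <- out[ci[v]] + 1L
  }
  out
}

#' Null distribution of the number of same-colored nodes in a set
#'
#' Under a uniformly random recoloring with profile counts summing to n, the
#' number of nodes of color i falling in a fixed t-element node set follows a
#' hypergeometric law Hyp(n, c_i, t): the binomial with falling powers in
#' place of ordinary powers. Choosing the set to be a node's neighborhood
#' gives the null distribution of its same-colored-neighbor count. The pmf is
#' computed exactly in rational arithmetic from the falling-power form
#' C(t, h) c_i^(h) (n - c_i)^(t-h) / n^(t).
#'
#' @param n total node count.
#' @param c_i class size, 1 <= c_i <= n.
#' @param t set size, 0 <= t <= n.
#' @return Object of class `neighbor_color_distribution`: fields `n`, `c_i`,
#'   `t`, `support` (integer vector h), `prob` (numeric, sums to 1), and
#'   `prob_rat` (list of exact [rat()] masses while the reduced coefficients
#'   are exactly representable, i.e. C(n, t) < 2^52; `NULL` beyond that, where
#'   the stable floating-point path alone is returned).
#' @examples
#' neighbor_color_pmf(3, 2, 1)$prob   # 1/3, 2/3
#' @export
neighbor_color_pmf <- function(n, c_i, t) {
  stopifnot(n >= 1, c_i >= 1, c_i <= n, t >= 0, t <= n)
  h <- max(0, t - (n - c_i)):min(t, c_i)
  # stable double path: C(t,h) * prod (c-k)/(n-k) * prod (n-c-j)/(n-h-j),
  # every trailing factor in [0, 1]
  prob <- vapply(h, function(hh) {
    p1 <- if (hh == 0) 1 else prod((c_i - 0:(hh - 1)) / (n - 0:(hh - 1)))
    r <- t - hh
    p2 <- if (r == 0) 1 else prod((n - c_i - 0:(r - 1)) / (n - hh - 0:(r - 1)))
    choose(t, hh) * p1 * p2
  }, 0)
  # exact rational path via the reduced hypergeometric ratio
  # C(c,h) C(n-c,t-h) / C(n,t) (equal to the falling-power form), available
  # while the coefficients stay exactly representable
  prob_rat <- NULL
  den <- round(choose(n, t))
  if (den <= .RAT_MAX) {
    prob_rat <- lapply(h, function(hh)
      rat(round(choose(c_i, hh)) * round(choose(n - c_i, t - hh)), den))
    tot <- Reduce(`+`, prob_rat)
    if (!(tot == rat(1))) stop("internal error: pmf does not sum to 1")
    prob <- vapply(prob_rat, rat_num, 0)
  }
  structure(list(
    n = n, c_i = c_i, t = t,
    support = as.integer(h),
    prob = prob,
    prob_rat = prob_rat
  ), class = "neighbor_color_distribution")
}

#' @export
print.neighbor_color_distribution <- function(x, ...) {
  cat(sprintf("Hyp(n = %d, c_i = %d, t = %d) neighbor-color pmf\n",
              x$n, x$c_i, x$t))
  print(stats::setNames(x$prob, x$support))
  invisible(x)
}

# f(d) = (n - c)^(d) / (n - 1)^(d), the survival factor of one node of
# degree d; returned for all d in `degs` via one cumulative product.
.isolation_factor <- function(n, c_i, degs, shift = 1) {
  # shift = 1 gives denominator (n-1)^(d), shift = 2 gives (n-2)^(b)
  dmax <- max(degs, 0)
  f <- numeric(dmax + 1)
  f[1] <- 1
  if (dmax > 0) {
    k <- 0:(dmax - 1)
    numer <- n - c_i - k
    denom <- n - shift - k
    ratio <- ifelse(numer <= 0, 0, numer / denom)
    # once a numerator factor crosses zero the product stays zero; any later
    # zero/negative denominator is unreachable because c_i >= shift there
    bad <- numer > 0 & denom <= 0
    if (any(bad)) stop("falling-power ratio denominator crosses zero")
    f[-1] <- cumprod(ratio)
  }
  f[degs + 1]
}

#' Expected number of i-isolated nodes under the recoloring null
#'
#' E(L^i) = (c_i / n) * sum_v (n - c_i)^(deg v) / (n - 1)^(deg v). Grouped by
#' the degree histogram, one falling-power ratio per distinct degree.
#'
#' @param graph a [colored_graph()].
#' @param invariants optional precomputed [graph_invariants()].
#' @param c_i class size, 1 <= c_i <= n.
#' @param exact return an exact [rat()] (direct per-node sum in rational
#'   arithmetic) instead of a double.
#' @return Expected count (double, or `rat` when `exact`).
#' @export
expected_isolated <- function(graph, invariants = NULL, c_i, exact = FALSE) {
  if (is.null(invariants)) invariants <- graph_invariants(graph)
  n <- invariants$n
  stopifnot(c_i >= 1, c_i <= n)
  if (exact) {
    acc <- rat(0)
    for (d in as.numeric(invariants$degrees))
      acc <- acc + .rat_falling_ratio(n - c_i, n - 1, d)
    return(rat(c_i, n) * acc)
  }
  if (n == 1) return(as.numeric(c_i == 1))
  dh <- invariants$degree_histogram
  degs <- as.integer(names(dh))
  f <- .isolation_factor(n, c_i, degs, shift = 1)
  (c_i / n) * sum(as.numeric(dh) * f)
}

#' Variance of the number of i-isolated nodes under the recoloring null
#'
#' var(L^i) = E(1 - E) + (c_i^(2)/n^(2)) * S, where S sums
#' (n - c_i)^(b(u,v)) / (n - 2)^(b(u,v)) over *ordered* non-adjacent pairs
#' (each unordered pair twice) and b(u, v) = |N(u) u N(v)|. Note E(1 - E) can
#' be negative when E > 1 — it is not a Bernoulli variance — while the total
#' is always nonnegative.
#'
#' The default `"grouped"` method evaluates S as
#' (all ordered pairs, from the degree histogram) - (adjacent pairs) -
#' (distance-2 correction), costing O(sum deg^2 + D^2) with D the number of
#' distinct degrees; `"naive"` loops over all ordered non-adjacent pairs with
#' explicit neighborhood unions and is the reference implementation.
#'
#' @inheritParams expected_isolated
#' @param method `"grouped"` (efficient) or `"naive"` (reference).
#' @param exact return an exact [rat()] via the direct rational pair sum.
#' @return Variance (double, or `rat` when `exact`).
#' @export
isolated_variance <- function(graph, invariants = NULL, c_i,
                              method = c("grouped", "naive"), exact = FALSE) {
  method <- match.arg(method)
  if (is.null(invariants)) invariants <- graph_invariants(graph)
  n <- invariants$n
  stopifnot(n >= 2, c_i >= 1, c_i <= n)
  if (exact) {
    E <- expected_isolated(graph, invariants, c_i, exact = TRUE)
    if (c_i < 2) return(E * (rat(1) - E))
    adj <- .adj_list(graph)
    S <- rat(0)
    for (u in seq_len(n - 1)) for (v in (u + 1):n) {
      if (v %in% adj[[u]]) next
      b <- length(union(adj[[u]], adj[[v]]))
      S <- S + rat(2) * .rat_falling_ratio(n - c_i, n - 2, b)
    }
    return(E * (rat(1) - E) + .rat_falling_ratio(c_i, n, 2) * S)
  }
  E <- expected_isolated(graph, invariants, c_i)
  if (c_i < 2) {
    S <- 0
    coef <- 0
  } else {
    coef <- .falling_ratio(c_i, n, 2)
    S <- if (method == "grouped") .pair_sum_grouped(graph, invariants, c_i)
         else .pair_sum_naive(graph, c_i)
  }
  v <- E * (1 - E) + coef * S
  if (v < 0 && v > -1e-9) v <- 0
  v
}

.pair_sum_grouped <- function(graph, invariants, c_i) {
  n <- invariants$n
  deg <- as.numeric(invariants$degrees)
  dh <- invariants$degree_histogram
  degs <- as.integer(names(dh))
  cnt <- as.numeric(dh)
  # f at every b we may need: sums of two degrees, minus common neighbors
  bmax <- 2 * max(degs, 0)
  fall <- .isolation_factor(n, c_i, 0:bmax, shift = 2)
  f <- function(b) fall[b + 1]

  # term 1: all ordered pairs u != v, from the degree histogram
  pair_f <- outer(degs, degs, `+`)
  t_all <- sum(outer(cnt, cnt) * f(pair_f)) - sum(cnt * f(2 * degs))

  # term 2: ordered adjacent pairs
  du <- deg[graph$edge_i]; dv <- deg[graph$edge_j]
  t_adj <- if (graph$m > 0) 2 * sum(f(du + dv)) else 0

  # term 3: distance-2 pairs, replace f(du+dv) by f(du+dv-common)
  d2 <- invariants$dist2_common
  t_d2 <- 0
  if (nrow(d2) > 0) {
    b_naive <- deg[d2$u] + deg[d2$v]
    b_true <- b_naive - d2$common
    t_d2 <- 2 * sum(f(b_naive) - f(b_true))
  }
  t_all - t_adj - t_d2
}

.pair_sum_naive <- function(graph, c_i) {
  n <- graph$n
  adj <- .adj_list(graph)
  S <- 0
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (v %in% adj[[u]]) next
    b <- length(union(adj[[u]], adj[[v]]))
    stopifnot(b <= n - 2)
    S <- S + 2 * .falling_ratio(n - c_i, n - 2, b)
  }
  S
}

#' Per-color moment table of isolated-node counts
#'
#' Observed counts, null expectations, variances and z-scores of the number
#' of i-isolated nodes, one row per color. z is `NA` where the null variance
#' is zero.
#'
#' @param graph a [colored_graph()].
#' @param invariants optional precomputed [graph_invariants()].
#' @return Data frame (class `isolation_moment_table`) with columns `color`,
#'   `observed`, `expected`, `variance`, `zscore`.
#' @export
isolation_moment_table <- function(graph, invariants = NULL) {
  if (is.null(invariants)) invariants <- graph_invariants(graph)
  prof <- color_profile(graph)
  obs <- observed_isolated_counts(graph)
  cols <- names(prof$counts)
  expd <- vapply(cols, function(cc)
    expected_isolated(graph, invariants, prof$counts[cc]), 0)
  varr <- vapply(cols, function(cc)
    isolated_variance(graph, invariants, prof$counts[cc]), 0)
  out <- data.frame(
    color = cols,
    observed = as.numeric(obs[cols]),
    expected = expd,
    variance = varr,
    zscore = ifelse(varr > 0, (as.numeric(obs[cols]) - expd) / sqrt(varr),
                    NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("isolation_moment_table", "data.frame")
  out
}

#' z-scores of per-color isolated-node counts
#'
#' The vector z0 standardizing each observed l_i against its null moments;
#' strongly negative entries indicate concentrated homophily (fewer isolated
#' nodes than a random recoloring would leave).
#'
#' @inheritParams isolation_moment_table
#' @return Named numeric vector (NA where the null variance is zero).
#' @export
isolation_zscores <- function(graph, invariants = NULL) {
  tab <- isolation_moment_table(graph, invariants)
  stats::setNames(tab$zscore, tab$color)
}
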