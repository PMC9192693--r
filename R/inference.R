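#' U-values: distribution-free significance bounds from z-scores
#'
#' The U-value of a z-score is z^-2: by the two-sided Chebyshev inequality it
#' bounds from above the p-value of the observed deviation under the null,
#' with no distributional assumption. Undefined or zero z-scores give a
#' vacuous bound, reported as `NA` (or clamped to 1 on request).
#'
#' @param z numeric vector or matrix of z-scores (`NA` allowed).
#' @param clamp if `TRUE`, cap values at 1 and report vacuous cells as 1.
#' @return Array of the same shape as `z`.
#' @examples
#' u_values(c(2, 10))        # 0.25, 0.01
#' u_values(0, clamp = TRUE) # 1
#' @export
u_values <- function(z, clamp = FALSE) {
  u <- ifelse(is.na(z) | z == 0, NA_real_, z^-2)
  if (clamp) u <- pmin(ifelse(is.na(u), 1, u), 1)
  u
}

#' Chebyshev / Cantelli tail bound for a z-score
#'
#' Two-sided bound z^-2, or the one-sided Cantelli bound (1 + z^2)^-1, both
#' clamped to 1.
#'
#' @param z numeric z-score(s).
#' @param one_sided use Cantelli's one-sided inequality.
#' @return Probability bound(s) in (0, 1].
#' @examples
#' tail_bound(3)                  # 1/9
#' tail_bound(3, one_sided = TRUE) # 0.1
#' @export
tail_bound <- function(z, one_sided = FALSE) {
  b <- if (one_sided) 1 / (1 + z^2) else ifelse(z == 0, Inf, z^-2)
  pmin(1, b)
}

#' Declare homophilic / heterophilic cells at a significance level
#'
#' One-directional test: a cell is declared positive when its z-score reaches
#' the Chebyshev threshold 1/sqrt(alpha) (no correction) or sqrt(h/alpha)
#' under Bonferroni over the h tested cells — equivalent to the individual
#' level alpha/h. Positive diagonal cells are labelled `homophilic`,
#' off-diagonal ones `heterophilic`; all other defined cells, including
#' arbitrarily negative z-scores, are `not-significant`, and cells with
#' undefined z are `undefined`. With h = s^2 the Bonferroni threshold equals
#' the literal s/sqrt(alpha) form sometimes quoted for s simultaneous
#' diagonal tests; pass `n_tests` to pin h explicitly.
#'
#' @param Z symmetric z-score matrix (color-labelled dimnames).
#' @param z0 optional isolated-node z-score vector; assessed the same
#'   one-directional way and returned under `$isolation`.
#' @param alpha significance level in (0, 1).
#' @param correction `"none"` or `"bonferroni"`.
#' @param family which cells the (corrected) family contains: `"diagonal"`
#'   (the s intra-class tests) or `"all"` (all s(s+1)/2 unordered cells).
#' @param n_tests optional explicit h overriding the family size.
#' @return List with `calls` (character matrix over Z), `isolation`
#'   (character vector, if `z0` given), `threshold`, `alpha`, `correction`,
#'   `n_tests`.
#' @export
assess <- function(Z, z0 = NULL, alpha = 0.05,
                   correction = c("none", "bonferroni"),
                   family = c("diagonal", "all"), n_tests = NULL) {
  correction <- match.arg(correction)
  family <- match.arg(family)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  s <- nrow(Z)
  h <- if (!is.null(n_tests)) n_tests
       else if (correction == "none") 1
       else if (family == "diagonal") s
       else s * (s + 1) / 2
  thr <- if (correction == "none") 1 / sqrt(alpha) else sqrt(h / alpha)

  calls <- matrix("not-significant", s, s, dimnames = dimnames(Z))
  calls[is.na(Z)] <- "undefined"
  pos <- !is.na(Z) & Z >= thr
  calls[pos] <- "heterophilic"
  diag_pos <- diag(pos)
  for (i in seq_len(s)) {
    if (is.na(Z[i, i])) calls[i, i] <- "undefined"
    else calls[i, i] <- if (diag_pos[i]) "homophilic" else "not-significant"
  }
  out <- list(calls = calls, threshold = thr, alpha = alpha,
              correction = correction, n_tests = h)
  if (!is.null(z0)) {
    iso <- ifelse(is.na(z0), "undefined",
                  ifelse(z0 >= thr, "significant", "not-significant"))
    names(iso) <- names(z0)
    out$isolation <- iso
  }
  out
}

# upper-triangle cell labels of an s x s matrix, in row-major label order
.upper_cells <- function(Z) {
  s <- nrow(Z)
  cells <- list()
  k <- 0L
  for (i in seq_len(s)) for (j in i:s) {
    k <- k + 1L
    cells[[k]] <- c(i, j)
  }
  cells
}

#' Largest jointly significant cell set q(alpha)
#'
#' Among a candidate cell set Q, finds the largest subset whose summed
#' U-values stay within the joint level alpha (the family-wise error budget),
#' by greedily adding cells in ascending z^-2 — which maximizes cardinality.
#' Cells with undefined or non-positive z contribute a vacuous bound >= 1 and
#' are never selected at alpha < 1. q(alpha) can be 0. Ties are broken by
#' cell position order, so the construction is deterministic.
#'
#' @param Z symmetric z-score matrix.
#' @param Q optional candidate cells: a two-column matrix of (row, col)
#'   indices with row <= col. Default: all upper-triangle cells.
#' @param alpha joint significance level.
#' @return List with `q` (cardinality) and `cells` (matrix of selected
#'   (row, col) index pairs, possibly zero rows).
#' @export
q_alpha <- function(Z, Q = NULL, alpha) {
  if (is.null(Q)) {
    Q <- do.call(rbind, .upper_cells(Z))
  }
  z <- Z[cbind(Q[, 1], Q[, 2])]
  u <- ifelse(is.na(z) | z <= 0, Inf, z^-2)
  ord <- order(u, Q[, 1], Q[, 2])
  csum <- cumsum(u[ord])
  take <- which(csum <= alpha)
  q <- if (length(take)) max(take) else 0L
  list(q = as.integer(q),
       cells = Q[ord[seq_len(q)], , drop = FALSE])
}

#' Cells exceeding a z threshold: J(lambda)
#'
#' The set of upper-triangle cells (i <= j) with z strictly greater than
#' lambda. The family of these sets over all lambda conveys the same
#' information as q(alpha) over all alpha.
#'
#' @param Z symmetric z-score matrix.
#' @param lam threshold.
#' @return Two-column matrix of (row, col) index pairs.
#' @export
j_lambda <- function(Z, lam) {
  cells <- .upper_cells(Z)
  keep <- vapply(cells, function(ij) {
    z <- Z[ij[1], ij[2]]
    !is.na(z) && z > lam
  }, TRUE)
  out <- do.call(rbind, cells[keep])
  if (is.null(out)) out <- matrix(integer(), ncol = 2)
  out
}

#' Multidimensional Chebyshev bound
#'
#' For a d-dimensional random vector with standardized marginals,
#' Pr(||X|| >= t) <= d / t^2 (Markov on ||X||^2), clamped to 1.
#'
#' @param d dimension (positive integer).
#' @param t positive threshold.
#' @return Probability bound.
#' @export
multidim_bound <- function(d, t) {
  stopifnot(d >= 1, t > 0)
  pmin(1, d / t^2)
}

#' Global homophily index in [0, 1]
#'
#' max(0, 1 - s / ||diag(Z)||^2): one minus the multidimensional Chebyshev
#' bound on observing diagonal z-scores at least this extreme, clamped to
#' [0, 1]. Comparable across networks sharing a color set, in the spirit of a
#' modularity score. Undefined diagonal entries are excluded with s reduced
#' accordingly.
#'
#' @param Z symmetric z-score matrix.
#' @return Scalar in [0, 1] (0 when every diagonal entry is undefined).
#' @export
global_homophily_index <- function(Z) {
  d <- diag(Z)
  d <- d[!is.na(d)]
  s_eff <- length(d)
  if (s_eff == 0) return(0)
  ss <- sum(d^2)
  if (ss == 0) return(0)
  max(0, 1 - s_eff / ss)
}

#' Full homophily report for a colored graph
#'
#' Runs the whole pipeline: invariants, edge and isolation moment tables,
#' z-score arrays Z and z0, U-values, density ratios, significance calls at
#' the requested level, and the global homophily index.
#'
#' @param graph a [colored_graph()].
#' @param alpha significance level for the calls.
#' @param correction,family,n_tests passed to [assess()].
#' @return Object of class `homophily_report`: fields `Z`, `z0`, `U`, `U0`,
#'   `ratios`, `calls`, `isolation_calls`, `global_index`, `edge_table`,
#'   `isolation_table`, `metadata` (n, m, s, profile, pi3, alpha, correction,
#'   threshold).
#' @examples
#' g <- planted_partition(c(a = 8, b = 8), p_in = 0.9, p_out = 0.05, seed = 1)
#' rep <- homophily_report(g)
#' rep$global_index
#' @export
homophily_report <- function(graph, alpha = 0.05,
                             correction = c("none", "bonferroni"),
                             family = c("diagonal", "all"), n_tests = NULL) {
  correction <- match.arg(correction)
  family <- match.arg(family)
  inv <- graph_invariants(graph)
  prof <- color_profile(graph)
  etab <- edge_moment_table(graph, inv)
  itab <- isolation_moment_table(graph, inv)
  cols <- names(prof$counts)
  s <- prof$s
  Z <- matrix(NA_real_, s, s, dimnames = list(cols, cols))
  for (r in seq_len(nrow(etab))) {
    i <- match(etab$color_i[r], cols); j <- match(etab$color_j[r], cols)
    Z[i, j] <- Z[j, i] <- etab$zscore[r]
  }
  z0 <- stats::setNames(itab$zscore, itab$color)
  a <- assess(Z, z0, alpha = alpha, correction = correction,
              family = family, n_tests = n_tests)
  structure(list(
    Z = Z, z0 = z0,
    U = u_values(Z), U0 = u_values(z0),
    ratios = homophily_ratios(etab),
    calls = a$calls, isolation_calls = a$isolation,
    global_index = global_homophily_index(Z),
    edge_table = etab, isolation_table = itab,
    metadata = list(n = graph$n, m = graph$m, s = s,
                    profile = prof$counts, pi3 = inv$pi3,
                    two_k2 = inv$two_k2,
                    alpha = alpha, correction = correction,
                    threshold = a$threshold, n_tests = a$n_tests)
  ), class = "homophily_report")
}

#' @export
print.homophily_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("homophily_report: n = %d, m = %d, s = %d\n", md$n, md$m, md$s))
  cat(sprintf("  alpha = %g (%s, threshold %.3f)\n",
              md$alpha, md$correction, md$threshold))
  cat(sprintf("  global homophily index: %.4f\n", x$global_index))
  cat("  diagonal z-scores:\n")
  print(round(diag(x$Z), 3))
  cat("  isolation z-scores:\n")
  print(round(x$z0, 3))
  invisible(x)
}
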