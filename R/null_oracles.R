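#' Number of colorings with a given profile
#'
#' The multinomial coefficient n! / (c_1! ... c_s!): the size of the null
#' sample space of recolorings.
#'
#' @param profile a [color_profile()] (or named class-size vector).
#' @return Exact count as a double.
#' @examples
#' count_colorings(color_profile(c(a = 2, b = 1)))  # 3
#' @export
count_colorings <- function(profile) {
  if (!inherits(profile, "color_profile")) profile <- color_profile(profile)
  cnt <- profile$counts
  rem <- profile$n
  out <- 1
  for (ci in cnt) {
    out <- out * choose(rem, ci)
    rem <- rem - ci
  }
  out
}

# all distinct colorings with the given counts, as a K x n integer matrix of
# color indices (columns = node positions)
.all_colorings <- function(counts) {
  n <- sum(counts)
  rec <- function(remaining, positions) {
    live <- which(remaining > 0)
    if (length(positions) == 0) return(matrix(integer(), nrow = 1, ncol = 0))
    res <- list()
    for (col in live) {
      r2 <- remaining
      r2[col] <- r2[col] - 1L
      sub <- rec(r2, positions[-1])
      res[[length(res) + 1]] <- cbind(rep.int(col, nrow(sub)), sub)
    }
    do.call(rbind, res)
  }
  out <- rec(as.integer(counts), seq_len(n))
  colnames(out) <- NULL
  out
}

# all m_{i,j} (i <= j) and l_i statistics for a K x n matrix of colorings;
# returns a K x (npairs + s) matrix with named columns "m:i|j" and "l:i"
.coloring_stats <- function(graph, colmat, s) {
  K <- nrow(colmat)
  pairs <- list()
  for (i in seq_len(s)) for (j in i:s) pairs[[length(pairs) + 1]] <- c(i, j)
  out <- matrix(0, K, length(pairs) + s)
  nm <- character(length(pairs) + s)
  if (graph$m > 0) {
    cu <- colmat[, graph$edge_i, drop = FALSE]
    cv <- colmat[, graph$edge_j, drop = FALSE]
  }
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    nm[k] <- paste0("m:", i, "|", j)
    if (graph$m > 0) {
      hit <- (cu == i & cv == j) | (cu == j & cv == i)
      out[, k] <- rowSums(hit)
    }
  }
  adj <- .adj_list(graph)
  for (i in seq_len(s)) {
    iso <- matrix(TRUE, K, graph$n)
    for (v in seq_len(graph$n)) {
      nb <- adj[[v]]
      if (length(nb))
        iso[, v] <- rowSums(colmat[, nb, drop = FALSE] == i) == 0
    }
    li <- rowSums((colmat == i) & iso)
    out[, length(pairs) + i] <- li
    nm[length(pairs) + i] <- paste0("l:", i)
  }
  colnames(out) <- nm
  out
}

#' Exact null distribution by enumeration
#'
#' Enumerates every coloring with the given profile (distinct multiset
#' permutations, not all n! orderings), computes every per-pair edge count
#' and per-color isolated-node count, and returns their exact joint samples
#' and exact rational moments. This is the independent ground truth the
#' closed-form moments are validated against.
#'
#' @param graph a [colored_graph()] (only its structure is used; its own
#'   coloring is ignored).
#' @param profile a [color_profile()]; class sizes must sum to the node
#'   count. Defaults to the graph's own profile.
#' @param cap refuse to enumerate more than this many colorings.
#' @return Object of class `null_distribution` with `source = "exact"`,
#'   `n_colorings`, `stats` (K x nstat integer matrix, one row per coloring,
#'   columns named `m:i|j` / `l:i` by color index in label order), `colors`
#'   (label vector the indices refer to), and `moments`: a data frame with
#'   exact rational `mean` and `var` (list columns of [rat()]) plus numeric
#'   `mean_num`, `var_num`.
#' @export
enumerate_null <- function(graph, profile = color_profile(graph), cap = 1e6) {
  if (!inherits(profile, "color_profile")) profile <- color_profile(profile)
  if (profile$n != graph$n) stop("profile does not sum to the node count")
  K <- count_colorings(profile)
  if (K > cap)
    stop("profile admits ", format(K), " colorings > cap = ", cap,
         "; use monte_carlo_null() instead")
  colmat <- .all_colorings(profile$counts)
  stats <- .coloring_stats(graph, colmat, profile$s)
  Kr <- rat(nrow(stats))
  moments <- lapply(colnames(stats), function(cn) {
    x <- stats[, cn]
    mu <- rat(sum(x)) / Kr
    ex2 <- rat(sum(x * x)) / Kr
    list(mean = mu, var = ex2 - mu * mu)
  })
  structure(list(
    source = "exact",
    n_colorings = nrow(stats),
    colors = names(profile$counts),
    stats = stats,
    moments = data.frame(
      stat = colnames(stats),
      mean_num = vapply(moments, function(mo) rat_num(mo$mean), 0),
      var_num = vapply(moments, function(mo) rat_num(mo$var), 0),
      stringsAsFactors = FALSE
    ),
    moments_rat = moments
  ), class = "null_distribution")
}

#' Draw one uniformly random coloring with a given profile
#'
#' An unbiased shuffle of the color multiset assigned positionally: every
#' coloring with the profile is equally likely. Uses R's RNG stream, so
#' `set.seed()` gives reproducibility.
#'
#' @param nodes node identifiers (or a node count).
#' @param profile a [color_profile()] (or named class-size vector).
#' @return Named character vector node -> color label.
#' @export
sample_coloring <- function(nodes, profile) {
  if (!inherits(profile, "color_profile")) profile <- color_profile(profile)
  if (length(nodes) == 1 && is.numeric(nodes)) nodes <- as.character(seq_len(nodes))
  if (length(nodes) != profile$n) stop("profile does not sum to the node count")
  labels <- rep(names(profile$counts), times = profile$counts)
  stats::setNames(sample(labels), nodes)
}

#' Empirical null moments by Monte Carlo recoloring
#'
#' Recolors the graph `reps` times uniformly at random with the given profile
#' and summarizes every per-pair edge count and per-color isolated-node
#' count: empirical mean and variance with standard errors (the variance SE
#' uses the fourth central moment, valid without normality).
#'
#' @inheritParams enumerate_null
#' @param reps number of recolorings (>= 2).
#' @param seed optional seed for reproducibility.
#' @param chunk internal batch size for the vectorized statistic pass.
#' @return Object of class `null_distribution` with `source = "monte_carlo"`,
#'   `reps`, `seed`, and `moments`: data frame with `stat`, `mean`, `se_mean`,
#'   `var`, `se_var`.
#' @export
monte_carlo_null <- function(graph, profile = color_profile(graph),
                             reps = 1e4, seed = NULL, chunk = 2000) {
  if (!inherits(profile, "color_profile")) profile <- color_profile(profile)
  if (profile$n != graph$n) stop("profile does not sum to the node count")
  stopifnot(reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  s <- profile$s
  base <- rep(seq_len(s), times = profile$counts)
  stats <- NULL
  done <- 0
  while (done < reps) {
    k <- min(chunk, reps - done)
    colmat <- t(vapply(seq_len(k), function(i) sample(base), integer(graph$n)))
    st <- .coloring_stats(graph, colmat, s)
    stats <- rbind(stats, st)
    done <- done + k
  }
  mu <- colMeans(stats)
  va <- apply(stats, 2, stats::var)
  K <- nrow(stats)
  se_mean <- sqrt(va / K)
  # SE of the sample variance: sqrt((m4 - (K-3)/(K-1) s^4) / K)
  se_var <- vapply(seq_along(mu), function(j) {
    x <- stats[, j]
    m4 <- mean((x - mu[j])^4)
    v <- max(m4 - (K - 3) / (K - 1) * va[j]^2, 0)
    sqrt(v / K)
  }, 0)
  structure(list(
    source = "monte_carlo", reps = K, seed = seed,
    colors = names(profile$counts),
    moments = data.frame(stat = colnames(stats), mean = unname(mu),
                         se_mean = unname(se_mean), var = unname(va),
                         se_var = unname(se_var), stringsAsFactors = FALSE)
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution (%s%s)\n", x$source,
              if (x$source == "exact") sprintf(", %d colorings", x$n_colorings)
              else sprintf(", %d reps", x$reps)))
  print(utils::head(x$moments, 12))
  invisible(x)
}

#' Compare closed-form moments against a null oracle
#'
#' Convenience validation: computes the closed-form mean and variance of
#' every statistic and compares with an exact enumeration (when the number of
#' colorings is within `cap`) or a Monte Carlo run. Exact comparisons must
#' agree to numerical round-off; Monte Carlo comparisons are scored in
#' standard-error units.
#'
#' @param graph a [colored_graph()].
#' @param cap enumeration cap (see [enumerate_null()]).
#' @param reps Monte Carlo recolorings used when enumeration is infeasible.
#' @param seed seed for the Monte Carlo path.
#' @return Data frame with one row per statistic: closed-form and oracle
#'   means/variances plus either absolute differences (`exact`) or
#'   standard-error distances (`monte_carlo`), and a logical `ok` column
#'   (exact: agreement to 1e-9 relative; MC: within 4 SE).
#' @export
validate_null_moments <- function(graph, cap = 1e5, reps = 1e4, seed = NULL) {
  prof <- color_profile(graph)
  inv <- graph_invariants(graph)
  cols <- names(prof$counts)
  s <- prof$s
  analytic <- list()
  for (i in seq_len(s)) for (j in i:s) {
    same <- i == j
    analytic[[paste0("m:", i, "|", j)]] <- c(
      expected_edge_count(graph$n, graph$m, prof$counts[i],
                          if (same) NULL else prof$counts[j], same),
      edge_count_variance(graph$n, graph$m, inv$pi3, prof$counts[i],
                          if (same) NULL else prof$counts[j], same))
  }
  for (i in seq_len(s)) {
    analytic[[paste0("l:", i)]] <- c(
      expected_isolated(graph, inv, prof$counts[i]),
      isolated_variance(graph, inv, prof$counts[i]))
  }
  an <- do.call(rbind, analytic)

  if (count_colorings(prof) <= cap) {
    orc <- enumerate_null(graph, prof, cap = cap)
    om <- orc$moments
    idx <- match(rownames(an), om$stat)
    dmean <- abs(an[, 1] - om$mean_num[idx])
    dvar <- abs(an[, 2] - om$var_num[idx])
    tolm <- 1e-9 * pmax(1, abs(an[, 1]))
    tolv <- 1e-9 * pmax(1, abs(an[, 2]))
    data.frame(stat = rownames(an), source = "exact",
               mean_analytic = an[, 1], mean_oracle = om$mean_num[idx],
               var_analytic = an[, 2], var_oracle = om$var_num[idx],
               dev_mean = dmean, dev_var = dvar,
               ok = dmean <= tolm & dvar <= tolv,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    orc <- monte_carlo_null(graph, prof, reps = reps, seed = seed)
    om <- orc$moments
    idx <- match(rownames(an), om$stat)
    zm <- abs(an[, 1] - om$mean[idx]) / pmax(om$se_mean[idx], 1e-12)
    zv <- abs(an[, 2] - om$var[idx]) / pmax(om$se_var[idx], 1e-12)
    data.frame(stat = rownames(an), source = "monte_carlo",
               mean_analytic = an[, 1], mean_oracle = om$mean[idx],
               var_analytic = an[, 2], var_oracle = om$var[idx],
               dev_mean = zm, dev_var = zv,
               ok = zm <= 4 & zv <= 4,
               row.names = NULL, stringsAsFactors = FALSE)
  }
}
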