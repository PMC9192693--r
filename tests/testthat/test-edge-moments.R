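# frozen expected values below (2/3, 4/3, 2/9) were computed by enumerating
# the three colorings of the path a-b-c with profile (2, 1) by hand:
# m11 in {1, 0, 1}, m12 in {1, 2, 1}

test_that("falling powers follow the sampling-without-replacement convention", {
  expect_equal(falling_power(5, 2), 20)
  expect_equal(falling_power(3, 0), 1)
  expect_equal(falling_power(2, 4), 0)
  expect_equal(falling_power(4, 4), 24)
})

test_that("observed per-pair edge counts are exact single-pass tallies", {
  g <- path_graph(c(a = "1", b = "2", c = "1"))
  obs <- observed_edge_counts(g)
  expect_equal(obs["1", "1"], 0)
  expect_equal(obs["1", "2"], 2)

  g <- path_graph(c(a = "1", b = "1", c = "2"))
  obs <- observed_edge_counts(g)
  expect_equal(obs["1", "1"], 1)
  expect_equal(obs["1", "2"], 1)

  mono <- random_colored_graph_mono(10, p = 0.5, seed = 3)
  expect_equal(observed_edge_counts(mono)["1", "1"], mono$m)
})

test_that("expected edge counts match the enumeration of the 3-path", {
  expect_equal(expected_edge_count(3, 2, 2, same_color = TRUE), 2 / 3)
  expect_equal(expected_edge_count(3, 2, 2, 1, same_color = FALSE), 4 / 3)
  expect_equal(expected_edge_count(10, 7, 1, same_color = TRUE), 0)
  expect_error(expected_edge_count(3, 2, 3, 1, same_color = FALSE))
})

test_that("edge-count variances match the enumeration of the 3-path", {
  expect_equal(edge_count_variance(3, 2, 1, 2, same_color = TRUE), 2 / 9)
  expect_equal(edge_count_variance(3, 2, 1, 2, 1, same_color = FALSE), 2 / 9)
  # constant coloring: zero variance, exactly
  expect_equal(edge_count_variance(6, 5, 4, 6, same_color = TRUE), 0)
})

test_that("closed-form variance equals its covariance decomposition", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    m <- sample(1:min(60, n * (n - 1) / 2), 1)
    pi3 <- sample(0:floor(m * (m - 1) / 2), 1)
    ci <- sample(1:(n - 1), 1)
    cj <- sample(1:(n - ci), 1)
    a <- edge_count_variance(n, m, pi3, ci, same_color = TRUE)
    b <- edge_count_variance(n, m, pi3, ci, same_color = TRUE,
                             method = "covariance")
    expect_equal(a, b, tolerance = 1e-12)
    a <- edge_count_variance(n, m, pi3, ci, cj, same_color = FALSE)
    b <- edge_count_variance(n, m, pi3, ci, cj, same_color = FALSE,
                             method = "covariance")
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("expected counts conserve the total edge mass, exactly", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    m <- sample(1:200, 1)
    s <- sample(2:5, 1)
    counts <- as.vector(stats::rmultinom(1, n - s, rep(1, s))) + 1
    tot <- rat(0)
    for (i in seq_len(s)) for (j in i:s) {
      same <- i == j
      tot <- tot + expected_edge_count(n, m, counts[i],
                                       if (same) NULL else counts[j],
                                       same, exact = TRUE)
    }
    expect_true(tot == rat(m))
  }
})

test_that("ratios are observed/expected with degenerate cells flagged", {
  g <- path_graph(c(a = "1", b = "1", c = "2"))
  tab <- edge_moment_table(g)
  r <- homophily_ratios(tab)
  expect_equal(unname(r$omega["1"]), 1 / (2 / 3) * 1)
  expect_true(is.na(r$omega["2"]))   # singleton class: expected 0
  expect_equal(r$eta["1", "2"], 1 / (4 / 3))

  mono <- random_colored_graph_mono(8, p = 0.6, seed = 5)
  expect_equal(unname(homophily_ratios(edge_moment_table(mono))$omega), 1)
})

test_that("z-score matrix matches the enumerated moments and flags zero-variance cells", {
  g <- path_graph(c(a = "1", b = "1", c = "2"))
  Z <- edge_zscore_matrix(g)
  expect_equal(Z["1", "1"], (1 - 2 / 3) / sqrt(2 / 9))
  expect_equal(Z["1", "2"], (1 - 4 / 3) / sqrt(2 / 9))
  expect_equal(Z["1", "1"], 1 / sqrt(2), tolerance = 1e-12)
  expect_true(is.na(Z["2", "2"]))
  expect_equal(Z, t(Z))

  mono <- random_colored_graph_mono(8, p = 0.6, seed = 5)
  expect_true(is.na(edge_zscore_matrix(mono)[1, 1]))
})

test_that("z-scores are equivariant under color relabeling", {
  set.seed(13)
  g <- random_colored_graph(14, p = 0.35, s = 3)
  Z <- edge_zscore_matrix(g)
  relabel <- c("1" = "q", "2" = "a", "3" = "m")
  g2 <- colored_graph(cbind(g$nodes[g$edge_i], g$nodes[g$edge_j]),
                      setNames(relabel[g$color], names(g$color)))
  Z2 <- edge_zscore_matrix(g2)
  perm <- relabel[rownames(Z)]
  expect_equal(unname(Z2[perm, perm]), unname(Z))
})
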