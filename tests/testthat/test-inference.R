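test_that("U-values are reciprocal squared z-scores with vacuous cells flagged", {
  expect_equal(u_values(c(2, 10)), c(0.25, 0.01))
  expect_true(is.na(u_values(0)))
  expect_equal(u_values(0, clamp = TRUE), 1)
  expect_equal(u_values(c(0.5, NA), clamp = TRUE), c(1, 1))
})

test_that("Chebyshev and Cantelli tail bounds clamp to 1", {
  expect_equal(tail_bound(3), 1 / 9)
  expect_equal(tail_bound(3, one_sided = TRUE), 0.1)
  expect_equal(tail_bound(0.5), 1)
  expect_equal(tail_bound(0), 1)
})

test_that("declaration procedure is one-directional with the right thresholds", {
  Z <- matrix(c(5, -8, -8, 2), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  a <- assess(Z, alpha = 0.05, correction = "none")
  expect_equal(a$threshold, 1 / sqrt(0.05), tolerance = 1e-12)
  expect_equal(a$calls["a", "a"], "homophilic")
  expect_equal(a$calls["b", "b"], "not-significant")
  # an extreme negative off-diagonal is still not declared
  expect_equal(a$calls["a", "b"], "not-significant")

  b <- assess(Z, alpha = 0.05, correction = "bonferroni", family = "diagonal")
  expect_equal(b$threshold, sqrt(2 / 0.05), tolerance = 1e-12)
  expect_equal(b$calls["a", "a"], "not-significant")

  # the s/sqrt(alpha) threshold form corresponds to h = s^2 tests
  c2 <- assess(Z, alpha = 0.05, correction = "bonferroni", n_tests = 4)
  expect_equal(c2$threshold, 2 / sqrt(0.05), tolerance = 1e-12)

  Zna <- Z; Zna[2, 2] <- NA
  expect_equal(assess(Zna, alpha = 0.05)$calls["b", "b"], "undefined")
  expect_error(assess(Z, alpha = 0), "alpha")
  expect_error(assess(Z, alpha = 1), "alpha")
})

test_that("declaration at level alpha coincides with the two-sided tail bound test", {
  set.seed(31)
  for (rep in 1:20) {
    z <- runif(1, 0.1, 12)
    Z <- matrix(z, 1, 1, dimnames = list("a", "a"))
    alpha <- runif(1, 0.01, 0.5)
    called <- assess(Z, alpha = alpha)$calls[1, 1] == "homophilic"
    expect_equal(called, tail_bound(z) <= alpha)
  }
})

test_that("q(alpha) greedily maximizes the jointly significant cell count", {
  Z <- diag(c(10, 10))
  dimnames(Z) <- list(c("a", "b"), c("a", "b"))
  Q <- rbind(c(1, 1), c(2, 2))
  expect_equal(q_alpha(Z, Q, alpha = 0.02)$q, 2L)
  expect_equal(q_alpha(Z, Q, alpha = 0.015)$q, 1L)
  expect_equal(q_alpha(Z, Q, alpha = 0.005)$q, 0L)

  # monotone in alpha, and Q(alpha) is J(lambda) n Q for some lambda
  set.seed(37)
  for (rep in 1:10) {
    s <- 4
    Z <- matrix(runif(s * s, -3, 15), s, s)
    Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
    dimnames(Z) <- list(letters[1:s], letters[1:s])
    alphas <- sort(runif(5, 0.001, 0.8))
    qs <- vapply(alphas, function(a) q_alpha(Z, alpha = a)$q, 0L)
    expect_true(all(diff(qs) >= 0))

    sel <- q_alpha(Z, alpha = alphas[3])
    if (sel$q > 0) {
      zs <- Z[sel$cells]
      lam <- min(zs) - 1e-9
      J <- j_lambda(Z, lam)
      jkey <- paste(J[, 1], J[, 2])
      skey <- paste(sel$cells[, 1], sel$cells[, 2])
      expect_true(all(skey %in% jkey))
    }
  }
})

test_that("J(lambda) uses strict exceedance on upper-triangle cells", {
  Z <- diag(c(3, 7)); dimnames(Z) <- list(c("a", "b"), c("a", "b"))
  J <- j_lambda(Z, 5)
  expect_equal(nrow(J), 1)
  expect_equal(unname(J[1, ]), c(2, 2))
  expect_equal(nrow(j_lambda(Z, max(Z))), 0)   # strict: the max is excluded
  expect_equal(nrow(j_lambda(Z, -Inf)), 3)     # all defined upper cells
})

test_that("multidimensional bound is d/t^2 clamped to 1", {
  expect_equal(multidim_bound(3, 3), 1 / 3)
  expect_equal(multidim_bound(19, sqrt(19)), 1)
  expect_equal(multidim_bound(1, 10), 0.01)
})

test_that("global homophily index lies in [0,1] and handles degeneracies", {
  Z <- diag(c(2, 2)); dimnames(Z) <- list(c("a", "b"), c("a", "b"))
  expect_equal(global_homophily_index(Z), 1 - 2 / 8)
  expect_equal(global_homophily_index(diag(c(0, 0))), 0)
  expect_equal(global_homophily_index(matrix(1, 1, 1)), 0)
  # undefined diagonal entries reduce the effective dimension
  Zna <- diag(c(2, NA, 2))
  expect_equal(global_homophily_index(Zna), 1 - 2 / 8)
  # permutation invariance
  set.seed(41)
  Z <- matrix(runif(16, -2, 20), 4, 4); Z <- (Z + t(Z)) / 2
  p <- sample(4)
  expect_equal(global_homophily_index(Z[p, p]), global_homophily_index(Z))
})

test_that("full report assembles consistent arrays and metadata", {
  g <- planted_partition(c(a = 10, b = 10, c = 10), 0.6, 0.05, seed = 9)
  rep <- homophily_report(g, alpha = 0.05)
  expect_equal(dim(rep$Z), c(3, 3))
  expect_equal(rep$Z, t(rep$Z))
  expect_equal(names(rep$z0), c("a", "b", "c"))
  expect_equal(rep$U, u_values(rep$Z))
  expect_true(all(diag(rep$calls) == "homophilic"))
  expect_gt(rep$global_index, 0.5)
  expect_equal(rep$metadata$n, 30)
  expect_equal(sum(rep$edge_table$observed), g$m)
})
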