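test_that("node-color reader handles plain tables, isoform merging and class merging", {
  f <- withr::local_tempfile()
  writeLines(c("a\tJ", "b\tK"), f)
  expect_equal(read_node_colors(f), c(a = "J", b = "K"))

  # isoforms with conflicting functions collapse to the fallback class
  writeLines(c("jhp0681_1\tJ", "jhp0681_2\tK"), f)
  expect_equal(read_node_colors(f, isoform_merge = TRUE), c(jhp0681 = "X"))

  # isoforms agreeing on function keep it
  writeLines(c("p1_1\tJ", "p1_2\tJ"), f)
  expect_equal(read_node_colors(f, isoform_merge = TRUE), c(p1 = "J"))

  # class merging applied after isoform merging
  writeLines(c("a\tR", "b\tS", "c\tJ"), f)
  expect_equal(read_node_colors(f, merge_map = c(R = "X", S = "X")),
               c(a = "X", b = "X", c = "J"))

  # conflicting duplicate of a non-isoform node is an error
  writeLines(c("a\tJ", "a\tK"), f)
  expect_error(read_node_colors(f), "conflicting")

  writeLines(character(), f)
  expect_error(read_node_colors(f), "empty")
})

test_that("edge reader applies the confidence cutoff inclusively and drops loops", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb\t900", "b\tc\t300"), f)
  expect_equal(read_edge_list(f), cbind("a", "b"))

  # 700 itself is kept (inclusive threshold)
  writeLines(c("a\tb\t700", "b\tc\t699"), f)
  expect_equal(read_edge_list(f), cbind("a", "b"))

  writeLines("a\ta\t999", f)
  expect_equal(nrow(read_edge_list(f)), 0)

  writeLines(c("a\tb\t900", "bad-row"), f)
  expect_error(read_edge_list(f), "line 2")

  writeLines(c("a\tb\tnot-a-number"), f)
  expect_error(read_edge_list(f), "non-numeric")
})

test_that("directed input keeps only mutual pairs, idempotently", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb", "b\ta", "a\tc"), f)
  e1 <- read_edge_list(f, directed_mutual = TRUE)
  expect_equal(e1, cbind("a", "b"))

  # symmetrization of an already-symmetric list is a no-op
  writeLines(c("a\tb", "b\ta", "b\tc", "c\tb"), f)
  e2 <- read_edge_list(f, directed_mutual = TRUE)
  writeLines(c(paste(e2[, 1], e2[, 2], sep = "\t"),
               paste(e2[, 2], e2[, 1], sep = "\t")), f)
  expect_equal(read_edge_list(f, directed_mutual = TRUE), e2)
})

test_that("builder drops isolated nodes, prunes empty classes and validates colors", {
  g <- build_colored_graph(c(a = "1", b = "1", c = "2"), cbind("a", "b"))
  expect_equal(g$n, 2)
  expect_equal(g$m, 1)
  expect_equal(g$colors, "1")

  g2 <- build_colored_graph(c(a = "1", b = "2"), cbind("a", "b"))
  expect_equal(color_profile(g2)$counts, c("1" = 1L, "2" = 1L))

  expect_error(build_colored_graph(c(a = "1"), cbind("a", "b")), "without a color")
  expect_error(build_colored_graph(c(a = "1", b = "1"),
                                   matrix(character(), ncol = 2)), "empty")

  # keeping isolated nodes is possible for null-model work
  g3 <- build_colored_graph(c(a = "1", b = "1", c = "2"), cbind("a", "b"),
                            drop_isolated = FALSE)
  expect_equal(g3$n, 3)
  expect_equal(sum(color_profile(g3)$counts), g3$n)
})

test_that("constructor rejects non-simple graphs and partial colorings", {
  expect_error(colored_graph(cbind("a", "a"), c(a = "1")), "self-loop")
  expect_error(colored_graph(rbind(c("a", "b"), c("b", "a")),
                             c(a = "1", b = "1")), "duplicate edge")
  expect_error(colored_graph(cbind("a", "b"), c(a = "1")), "without a color")
  expect_error(colored_graph(cbind("a", "b"), c(a = "1", b = NA)), "total")
})

test_that("age binning uses half-open intervals with fallback for junk values", {
  got <- bin_ages(c(u1 = "17", u2 = "18", u3 = "104", u4 = "", u5 = "59",
                    u6 = "60", u7 = "abc", u8 = "12", u9 = "11"))
  expect_equal(unname(got),
               c("C", "D", "X", "X", "F", "X", "X", "C", "X"))
  expect_error(bin_ages(c(a = 20), bins = list(A = c(10, 25), B = c(20, 30))),
               "overlapping")
})

test_that("profile is computed in lexicographic color order and covers all nodes", {
  g <- path_graph(c(a = "1", b = "1", c = "2"))
  p <- color_profile(g)
  expect_equal(p$counts, c("1" = 2L, "2" = 1L))
  expect_equal(p$n, g$n)

  k3 <- colored_graph(rbind(c("a", "b"), c("a", "c"), c("b", "c")),
                      c(a = "1", b = "1", c = "1"))
  expect_equal(color_profile(k3)$counts, c("1" = 3L))

  # generated contrast graph: the denser construction has 3p nodes in class i
  ex <- example1_pair(3)
  expect_equal(color_profile(ex$A)$counts, c(i = 9L))
})

test_that("graphs round-trip through the two text formats", {
  set.seed(42)
  g <- random_colored_graph(12, p = 0.3, s = 3)
  ef <- withr::local_tempfile(); cf <- withr::local_tempfile()
  write_colored_graph(g, ef, cf)
  g2 <- build_colored_graph(read_node_colors(cf), read_edge_list(ef),
                            drop_isolated = FALSE)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$color, g$color)
  expect_equal(g2$edge_i, g$edge_i)
  expect_equal(g2$edge_j, g$edge_j)
})
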