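#' Node-colored simple undirected graphs
#'
#' A `colored_graph` is the pair (G, g): a simple undirected graph G together
#' with a total coloring g assigning one categorical label ("color") to each
#' node. The coloring is surjective onto the color set carried by the object:
#' every color class is nonempty. Node identifiers and color labels are opaque
#' strings; all outputs are keyed by label. Colors are ordered
#' lexicographically, so matrices and vectors derived from a graph have a
#' reproducible layout.
#'
#' @param edges a two-column character matrix or data frame of edges, one row
#'   per edge (possibly zero rows). Self-loops and duplicate edges are errors:
#'   the graph must be simple.
#' @param coloring a named character vector mapping every node identifier to
#'   its color. Every edge endpoint must appear; nodes without incident edges
#'   are kept.
#' @return An object of class `colored_graph` with fields `nodes` (sorted
#'   identifiers), `color` (named character vector), `colors` (sorted color
#'   levels), `edge_i`/`edge_j` (integer endpoint indices, i < j), `n`, `m`.
#' @examples
#' g <- colored_graph(rbind(c("a", "b"), c("b", "c")),
#'                    c(a = "1", b = "1", c = "2"))
#' g$n; g$m
#' @seealso [build_colored_graph()] for the file-oriented builder that drops
#'   isolated nodes, [color_profile()] for the class-size vector.
#' @export
colored_graph <- function(edges, coloring) {
  if (is.null(names(coloring)) || any(!nzchar(names(coloring))))
    stop("coloring must be a named vector (node -> color)")
  if (anyDuplicated(names(coloring)))
    stop("duplicate node in coloring")
  if (anyNA(coloring)) stop("coloring must be total: NA color found")
  coloring <- vapply(coloring, as.character, "", USE.NAMES = TRUE)
  nodes <- sort(names(coloring))
  coloring <- coloring[nodes]

  edges <- .as_edge_matrix(edges)
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge set")
    miss <- setdiff(c(edges[, 1], edges[, 2]), nodes)
    if (length(miss))
      stop("edge endpoint(s) without a color: ", paste(miss, collapse = ", "))
  }
  i <- match(edges[, 1], nodes)
  j <- match(edges[, 2], nodes)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (anyDuplicated(cbind(i, j))) stop("duplicate edge in edge set")
  ord <- order(i, j)

  structure(list(
    nodes = nodes,
    color = coloring,
    colors = sort(unique(unname(coloring))),
    edge_i = i[ord], edge_j = j[ord],
    n = length(nodes), m = length(i)
  ), class = "colored_graph")
}

.as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0)
    return(matrix(character(), ncol = 2))
  if (!is.matrix(edges) || ncol(edges) != 2)
    stop("edges must be a 2-column matrix or data frame")
  mode(edges) <- "character"
  edges
}

#' @export
print.colored_graph <- function(x, ...) {
  cat(sprintf("colored_graph: %d nodes, %d edges, %d colors (%s)\n",
              x$n, x$m, length(x$colors),
              paste(utils::head(x$colors, 8), collapse = ", ")))
  invisible(x)
}

# adjacency list as integer vectors indexed by node position
.adj_list <- function(g) {
  adj <- vector("list", g$n)
  for (k in seq_len(g$n)) adj[[k]] <- integer()
  if (g$m > 0) {
    from <- c(g$edge_i, g$edge_j)
    to <- c(g$edge_j, g$edge_i)
    adj <- split(to, factor(from, levels = seq_len(g$n)))
    adj <- lapply(adj, as.integer)
  }
  adj
}

.degrees <- function(g) {
  d <- integer(g$n)
  if (g$m > 0) {
    t1 <- tabulate(g$edge_i, g$n)
    t2 <- tabulate(g$edge_j, g$n)
    d <- t1 + t2
  }
  names(d) <- g$nodes
  d
}

#' Color profile of a colored graph
#'
#' The profile is the integer vector c = (c_1, ..., c_s) of color class sizes,
#' ordered lexicographically by color label. It is the only attribute
#' information the recoloring null model retains: two colorings with the same
#' profile induce the same null distribution on every statistic.
#'
#' @param x a `colored_graph`, or a bare named integer vector of class sizes
#'   (names are color labels).
#' @return An object of class `color_profile` with fields `counts` (named
#'   integer vector, sorted by label), `s` and `n`.
#' @examples
#' g <- colored_graph(rbind(c("a", "b"), c("b", "c")),
#'                    c(a = "1", b = "1", c = "2"))
#' color_profile(g)$counts
#' @export
color_profile <- function(x) {
  if (inherits(x, "colored_graph")) {
    counts <- table(factor(x$color, levels = x$colors))
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    if (is.null(names(x))) stop("profile vector must be named by color label")
    counts <- x[order(names(x))]
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (any(counts < 1)) stop("every color class must be nonempty")
  structure(list(counts = counts, s = length(counts), n = sum(counts)),
            class = "color_profile")
}

#' @export
print.color_profile <- function(x, ...) {
  cat(sprintf("color_profile: n = %d, s = %d\n", x$n, x$s))
  print(x$counts)
  invisible(x)
}

#' Read a node-color table
#'
#' Reads a two-column delimited text file mapping node identifiers to color
#' labels, with the merging conventions used for STRING-style protein files:
#' identifiers that differ only by a trailing `_<integer>` suffix denote
#' isoforms of the same protein and can be collapsed to one node, and whole
#' color classes can be relabelled (e.g. the poorly-characterized classes R
#' and S folded into X).
#'
#' @param path path to a delimited text file with columns node, color.
#' @param sep field delimiter (default tab).
#' @param isoform_merge if `TRUE`, identifiers differing only by a trailing
#'   `_<integer>` suffix are merged into the base identifier; when the merged
#'   rows disagree on color the merged node receives `fallback`.
#' @param merge_map optional named character vector mapping old color labels to
#'   new ones, applied after isoform merging.
#' @param fallback color label assigned to isoform-merged nodes with
#'   conflicting colors (default `"X"`).
#' @return A named character vector node -> color.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tJ", "b\tK"), f)
#' read_node_colors(f)
#' @export
read_node_colors <- function(path, sep = "\t", isoform_merge = FALSE,
                             merge_map = NULL, fallback = "X") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty node-color file: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop("malformed node-color row at line ", bad[1], " of ", path)
  node <- vapply(parts, function(p) trimws(p[1]), "")
  col <- vapply(parts, function(p) trimws(p[2]), "")

  if (isoform_merge) {
    base <- sub("_[0-9]+$", "", node)
  } else {
    base <- node
  }
  out <- character(0)
  for (b in unique(base)) {
    cols <- unique(col[base == b])
    if (length(cols) > 1) {
      if (!isoform_merge || all(node[base == b] == b))
        stop("conflicting colors for node '", b, "'")
      # isoforms disagreeing on function: fold into the fallback class
      cols <- fallback
    }
    out[b] <- cols
  }
  if (!is.null(merge_map)) {
    hit <- out %in% names(merge_map)
    out[hit] <- unname(merge_map[out[hit]])
  }
  out
}

#' Read an edge list
#'
#' Reads a 2- or 3-column delimited text file of edges. When a weight column
#' is present, edges below the confidence threshold are dropped (the STRING
#' convention: scores in [0, 999], high-confidence cutoff 700, inclusive).
#' When the input is a directed friendship list, `directed_mutual` keeps the
#' unordered pair {u, v} only if both directions (u, v) and (v, u) occur.
#' Self-loops are dropped and duplicates collapsed.
#'
#' @param path path to the edge file.
#' @param sep field delimiter (default tab).
#' @param weight_threshold minimum weight kept, applied only when a third
#'   column exists (default 700); use `-Inf` to keep everything.
#' @param directed_mutual if `TRUE`, treat rows as directed arcs and keep only
#'   mutual pairs.
#' @return A two-column character matrix of unordered edges.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb\t900", "b\tc\t300"), f)
#' read_edge_list(f)          # keeps only a-b
#' @export
read_edge_list <- function(path, sep = "\t", weight_threshold = 700,
                           directed_mutual = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(matrix(character(), ncol = 2))
  parts <- strsplit(lines, sep, fixed = TRUE)
  len <- vapply(parts, length, 0L)
  bad <- which(len < 2L | len > 3L)
  if (length(bad))
    stop("malformed edge row at line ", lineno[bad[1]], " of ", path)
  u <- vapply(parts, function(p) trimws(p[1]), "")
  v <- vapply(parts, function(p) trimws(p[2]), "")
  has_w <- len == 3L
  if (any(has_w) && !all(has_w))
    stop("malformed edge row at line ", lineno[which(has_w != has_w[1])[1]],
         " of ", path, " (inconsistent weight column)")
  if (all(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(parts, function(p) trimws(p[3]), "")))
    if (anyNA(w))
      stop("malformed edge row at line ", lineno[which(is.na(w))[1]], " of ",
           path, " (non-numeric weight)")
    sel <- w >= weight_threshold
    u <- u[sel]; v <- v[sel]
  }
  drop <- u == v
  u <- u[!drop]; v <- v[!drop]
  if (directed_mutual) {
    arcs <- unique(paste(u, v, sep = "\r"))
    rev_arcs <- paste(v, u, sep = "\r")
    mutual <- paste(u, v, sep = "\r") %in% arcs & rev_arcs %in% arcs
    u <- u[mutual]; v <- v[mutual]
  }
  if (length(u) == 0) return(matrix(character(), ncol = 2))
  a <- pmin(u, v); b <- pmax(u, v)
  keyed <- !duplicated(paste(a, b, sep = "\r"))
  cbind(a[keyed], b[keyed])
}

#' Assemble a colored graph from a coloring and an edge set
#'
#' Combines a node-color map and an edge set into a [colored_graph()]. Every
#' edge endpoint must be colored. By default nodes of degree zero are removed
#' before the color profile is taken — the convention used when preprocessing
#' both protein-interaction and social-network inputs — and color classes
#' emptied by the removal disappear from the color set.
#'
#' @param colors named character vector node -> color.
#' @param edges two-column character matrix of unordered edges.
#' @param drop_isolated drop degree-zero nodes (default `TRUE`).
#' @return A `colored_graph`.
#' @export
build_colored_graph <- function(colors, edges, drop_isolated = TRUE) {
  edges <- .as_edge_matrix(edges)
  ends <- unique(c(edges[, 1], edges[, 2]))
  miss <- setdiff(ends, names(colors))
  if (length(miss))
    stop("edge endpoint(s) without a color: ", paste(miss, collapse = ", "))
  if (drop_isolated) colors <- colors[names(colors) %in% ends]
  if (length(colors) == 0) stop("resulting graph is empty")
  colored_graph(edges, colors)
}

#' Bin numeric ages into categorical classes
#'
#' Maps free-text age values to age-class colors using disjoint half-open
#' intervals [lo, hi). Values that are missing, non-numeric, or outside every
#' bin (implausible declared ages) are assigned the fallback class. The
#' default bins are the Pokec-style classes C [12,18), D [18,25), E [25,40),
#' F [40,60), with fallback X.
#'
#' @param ages named vector (node -> declared age, free text or numeric).
#' @param bins named list of `c(lo, hi)` half-open intervals.
#' @param fallback_label class for unbinnable values (default `"X"`).
#' @return Named character vector node -> age class.
#' @examples
#' bin_ages(c(u1 = "17", u2 = "104", u3 = ""))
#' @export
bin_ages <- function(ages,
                     bins = list(C = c(12, 18), D = c(18, 25),
                                 E = c(25, 40), F = c(40, 60)),
                     fallback_label = "X") {
  lo <- vapply(bins, `[`, 0, 1)
  hi <- vapply(bins, `[`, 0, 2)
  if (any(hi <= lo)) stop("bin with hi <= lo")
  ord <- order(lo)
  if (any(lo[ord][-1] < hi[ord][-length(ord)])) stop("overlapping bins")
  val <- suppressWarnings(as.numeric(ages))
  out <- rep(fallback_label, length(ages))
  for (k in seq_along(bins)) {
    inb <- !is.na(val) & val >= lo[k] & val < hi[k]
    out[inb] <- names(bins)[k]
  }
  names(out) <- names(ages)
  out
}

#' Write a colored graph to its two text files
#'
#' Inverse of the reader pair: writes the node-color table and the edge list
#' in the same delimited formats [read_node_colors()] and [read_edge_list()]
#' accept, so a graph round-trips identically.
#'
#' @param graph a `colored_graph`.
#' @param edge_path,color_path output file paths.
#' @param sep field delimiter.
#' @return Invisibly, `c(edge_path, color_path)`.
#' @export
write_colored_graph <- function(graph, edge_path, color_path, sep = "\t") {
  writeLines(paste(graph$nodes, unname(graph$color), sep = sep), color_path)
  writeLines(paste(graph$nodes[graph$edge_i], graph$nodes[graph$edge_j],
                   sep = sep), edge_path)
  invisible(c(edge_path, color_path))
}
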