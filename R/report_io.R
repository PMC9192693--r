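#' Render a z-score matrix as a heat map
#'
#' Entries are clipped to `clip`, then mapped through the translated
#' logarithm v -> log(v - lo + 1), so the color resolution concentrates where
#' z-scores are small while extreme diagonal values stay on scale. Cells with
#' positive z are drawn in greens, negative in pinks, undefined cells in
#' neutral grey; axes are labelled by color label.
#'
#' @param Z symmetric z-score matrix with dimnames.
#' @param clip length-2 interval the values are cut to (e.g. `c(-10, 60)` for
#'   a protein-network scale, `c(-100, 100)` for a large social network).
#' @param file output path; the device is chosen by extension (`.png` or
#'   `.pdf`). `NULL` draws on the current device.
#' @param main plot title.
#' @return Invisibly, `file`.
#' @export
render_heatmap <- function(Z, clip = c(-10, 60), file = NULL,
                           main = "edge z-scores") {
  stopifnot(length(clip) == 2, clip[1] < clip[2])
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 900, height = 800),
           pdf = grDevices::pdf(file, width = 8, height = 7),
           stop("unsupported heat-map format: .", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  lo <- clip[1]; hi <- clip[2]
  V <- pmin(pmax(Z, lo), hi)
  tr <- function(v) log(v - lo + 1)
  s <- nrow(Z)
  ramp_neg <- grDevices::colorRampPalette(c("#8c0a50", "#f7c8e0"))(64)
  ramp_pos <- grDevices::colorRampPalette(c("#d9f0d3", "#00441b"))(64)
  cell_col <- matrix("#bbbbbb", s, s)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    v <- V[i, j]
    if (is.na(v)) next
    if (Z[i, j] < 0) {
      u <- (tr(v) - tr(lo)) / max(tr(0) - tr(lo), .Machine$double.eps)
      cell_col[i, j] <- ramp_neg[pmax(1, pmin(64, ceiling(u * 64)))]
    } else {
      u <- (tr(v) - tr(0)) / max(tr(hi) - tr(0), .Machine$double.eps)
      cell_col[i, j] <- ramp_pos[pmax(1, pmin(64, 1 + floor(u * 63)))]
    }
  }
  op <- graphics::par(mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NULL, xlim = c(0.5, s + 0.5), ylim = c(0.5, s + 0.5),
                 xlab = "", ylab = "", axes = FALSE, main = main, asp = 1)
  for (i in seq_len(s)) for (j in seq_len(s))
    graphics::rect(j - 0.5, s - i + 0.5, j + 0.5, s - i + 1.5,
                   col = cell_col[i, j], border = "white")
  graphics::axis(1, at = seq_len(s), labels = colnames(Z), las = 2, tick = FALSE)
  graphics::axis(2, at = s:1, labels = rownames(Z), las = 2, tick = FALSE)
  invisible(file)
}

#' Write a homophily report to files
#'
#' Serializes a [homophily_report()] into a directory: labelled CSV tables
#' (Z matrix, z0 vector, U-values, ratios, calls, moment tables), a JSON
#' summary with the metadata and global index, and optionally a heat map.
#' Outputs are deterministic: identical inputs give byte-identical CSV/JSON.
#'
#' @param report a [homophily_report()].
#' @param dir output directory (created if needed).
#' @param heatmap if `TRUE`, also writes `heatmap.png`.
#' @param clip clip interval passed to [render_heatmap()].
#' @return Invisibly, the vector of files written.
#' @export
write_homophily_report <- function(report, dir, heatmap = FALSE,
                                   clip = c(-10, 60)) {
  stopifnot(inherits(report, "homophily_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  wcsv <- function(obj, path, rn = FALSE) {
    utils::write.csv(obj, path, row.names = rn, quote = FALSE)
    path
  }
  files <- c(
    wcsv(report$Z, fp("Z.csv"), rn = TRUE),
    wcsv(data.frame(color = names(report$z0), zscore = report$z0),
         fp("z0.csv")),
    wcsv(report$U, fp("U_values.csv"), rn = TRUE),
    wcsv(data.frame(color = names(report$ratios$omega),
                    omega = report$ratios$omega), fp("omega.csv")),
    wcsv(report$ratios$eta, fp("eta.csv"), rn = TRUE),
    wcsv(report$calls, fp("calls.csv"), rn = TRUE),
    wcsv(report$edge_table, fp("edge_moments.csv")),
    wcsv(report$isolation_table, fp("isolation_moments.csv"))
  )
  meta <- report$metadata
  meta$profile <- as.list(meta$profile)
  json <- jsonlite::toJSON(list(
    metadata = meta,
    global_index = report$global_index,
    isolation_calls = as.list(report$isolation_calls)
  ), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, fp("report.json"))
  files <- c(files, fp("report.json"))
  if (heatmap) {
    render_heatmap(report$Z, clip = clip, file = fp("heatmap.png"))
    files <- c(files, fp("heatmap.png"))
  }
  invisible(files)
}

#' End-to-end pipeline for a directed friendship network with declared ages
#'
#' Reproduces the preprocessing used for Pokec-style social-network inputs:
#' keep only mutual (symmetric) friendship pairs, bin declared ages into the
#' default age classes with fallback X for missing or implausible values,
#' drop isolated nodes, and report the per-class node and intra-class edge
#' counts together with the squared-degree sum that governs the cost of the
#' isolation statistics.
#'
#' @param relationship_path directed edge list (2 columns, tab-separated).
#' @param age_path node profile table (tab-separated; node id in the first
#'   column, free-text age in `age_column`).
#' @param age_column 1-based column index of the declared age (2 for a plain
#'   two-column table; 8 for a SNAP-style full profile dump).
#' @param bins,fallback_label passed to [bin_ages()].
#' @return List with `graph` (the [colored_graph()]), `class_nodes`,
#'   `class_edges` (named vectors), `n`, `m`, `squared_degree_sum`.
#' @export
social_age_pipeline <- function(relationship_path, age_path, age_column = 2,
                                bins = list(C = c(12, 18), D = c(18, 25),
                                            E = c(25, 40), F = c(40, 60)),
                                fallback_label = "X") {
  edges <- read_edge_list(relationship_path, directed_mutual = TRUE,
                          weight_threshold = -Inf)
  # tolerant read: a missing age field is legitimate (fallback class)
  lines <- readLines(age_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ages_tab <- stats::setNames(
    vapply(parts, function(p)
      if (length(p) >= age_column) trimws(p[age_column]) else "", ""),
    vapply(parts, function(p) trimws(p[1]), ""))
  colors <- bin_ages(ages_tab, bins = bins, fallback_label = fallback_label)
  g <- build_colored_graph(colors, edges, drop_isolated = TRUE)
  prof <- color_profile(g)
  obs <- observed_edge_counts(g)
  deg <- .degrees(g)
  list(graph = g,
       class_nodes = prof$counts,
       class_edges = stats::setNames(diag(obs), colnames(obs)),
       n = g$n, m = g$m,
       squared_degree_sum = sum(as.numeric(deg)^2))
}
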