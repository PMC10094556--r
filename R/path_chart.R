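#' Build a (closed) path chart
#'
#' Nodes are the m units, the activity, and optionally an independent error
#' term; edges are the m direct paths unit -> activity (weighted by
#' \eqn{b_j^*}, always drawn) and the unit <-> unit correlation paths
#' (weighted by \eqn{r_{jt}}). To keep charts readable only correlation
#' paths with \eqn{|r_{jt}|} at or above `include_threshold` are kept, and
#' each kept edge is banded: `strong` when \eqn{|r| \ge} `band_bounds[1]`
#' (drawn red), `medium` when between the bounds (orange), `weak` otherwise
#' (gray). With `include_threshold = 0` and the error node the chart is
#' completely closed.
#'
#' @param corr a [correlation_structure()].
#' @param decomp the matching `path_decomposition`.
#' @param include_threshold keep correlation edges with `|r| >=` this,
#'   in [0, 1]; default 0.7.
#' @param band_bounds descending pair (strong, medium) of band boundaries;
#'   bounds below `include_threshold` are clipped up to it.
#' @param include_error draw the independent error node and its edge to the
#'   activity; default `TRUE`.
#' @return object of class `path_chart` with `units`, `activity`,
#'   `direct_edges` (unit, b_star), `corr_edges` (from, to, r, band),
#'   `include_threshold`, `band_bounds`, `include_error`.
#' @export
build_path_chart <- function(corr, decomp, include_threshold = 0.7,
                             band_bounds = c(0.85, 0.75),
                             include_error = TRUE) {
  stopifnot(inherits(corr, "correlation_structure"),
            inherits(decomp, "path_decomposition"))
  if (!is.numeric(include_threshold) || length(include_threshold) != 1L ||
      include_threshold < 0 || include_threshold > 1) {
    pathsar_abort("`include_threshold` must lie in [0, 1]",
                  "pathsar_config_error")
  }
  if (length(band_bounds) != 2L || band_bounds[1L] < band_bounds[2L]) {
    pathsar_abort("`band_bounds` must be a descending pair",
                  "pathsar_config_error")
  }
  band_bounds <- pmax(band_bounds, include_threshold)
  units <- corr$units
  m <- length(units)

  from <- character(0); to <- character(0); r <- numeric(0)
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      for (t in seq(j + 1L, m)) {
        rj <- corr$r_xx[j, t]
        if (abs(rj) >= include_threshold) {
          from <- c(from, units[j]); to <- c(to, units[t]); r <- c(r, rj)
        }
      }
    }
  }
  band <- ifelse(abs(r) >= band_bounds[1L], "strong",
                 ifelse(abs(r) >= band_bounds[2L], "medium", "weak"))
  structure(
    list(units = units,
         activity = decomp$activity,
         direct_edges = data.frame(unit = units,
                                   b_star = unname(decomp$direct),
                                   stringsAsFactors = FALSE),
         corr_edges = data.frame(from = from, to = to, r = r, band = band,
                                 stringsAsFactors = FALSE),
         include_threshold = include_threshold,
         band_bounds = band_bounds,
         include_error = include_error),
    class = "path_chart")
}

#' @export
print.path_chart <- function(x, ...) {
  cat(sprintf("<path_chart> %d units -> '%s'; %d correlation edges (|r| >= %g)%s\n",
              length(x$units), x$activity, nrow(x$corr_edges),
              x$include_threshold,
              if (x$include_error) "; error node" else ""))
  invisible(x)
}

band_color <- c(strong = "red", medium = "orange", weak = "gray")

dot_quote <- function(x) sprintf("\"%s\"", gsub("\"", "\\\\\"", x))

#' Export a path chart as DOT text
#'
#' Correlation edges are styled undirected (`dir=both`, the double-arrow
#' convention for correlation paths), direct edges point at the activity
#' node. Node order follows the input column order, so the output is
#' byte-stable for identical charts. Edge labels carry r / b* rounded to 4
#' decimals.
#'
#' @param chart a [build_path_chart()] result.
#' @param path optional file to write; when `NULL` the DOT text is returned.
#' @return the DOT text, one string, invisibly when written to `path`.
#' @export
export_chart_dot <- function(chart, path = NULL) {
  stopifnot(inherits(chart, "path_chart"))
  q <- dot_quote
  lines <- c("digraph path_chart {",
             "  rankdir=LR;",
             "  node [shape=box];")
  lines <- c(lines,
             sprintf("  %s;", vapply(chart$units, q, character(1L))),
             sprintf("  %s [shape=ellipse];", q(chart$activity)))
  if (chart$include_error) {
    lines <- c(lines, sprintf("  %s [shape=plaintext];", q("error")))
  }
  for (i in seq_len(nrow(chart$corr_edges))) {
    e <- chart$corr_edges[i, ]
    lines <- c(lines, sprintf(
      "  %s -> %s [dir=both, color=%s, label=\"%.4f\"];",
      q(e$from), q(e$to), band_color[[e$band]], e$r))
  }
  for (i in seq_len(nrow(chart$direct_edges))) {
    e <- chart$direct_edges[i, ]
    lines <- c(lines, sprintf(
      "  %s -> %s [label=\"%.4f\"];",
      q(e$unit), q(chart$activity), e$b_star))
  }
  if (chart$include_error) {
    lines <- c(lines, sprintf("  %s -> %s;", q("error"), q(chart$activity)))
  }
  lines <- c(lines, "}")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Export a path chart as GraphML
#'
#' Same nodes and edges as [export_chart_dot()], with `weight` and `band`
#' edge attributes, for consumption by general graph tooling.
#'
#' @inheritParams export_chart_dot
#' @return the GraphML text, invisibly when written to `path`.
#' @export
export_chart_graphml <- function(chart, path = NULL) {
  stopifnot(inherits(chart, "path_chart"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  node <- function(id) sprintf("    <node id=\"%s\"/>", esc(id))
  edge <- function(a, b, w, band, directed) {
    sprintf(paste0("    <edge source=\"%s\" target=\"%s\" directed=\"%s\">",
                   "<data key=\"weight\">%.10g</data>",
                   "<data key=\"band\">%s</data></edge>"),
            esc(a), esc(b), if (directed) "true" else "false", w, band)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
             "  <key id=\"weight\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>",
             "  <key id=\"band\" for=\"edge\" attr.name=\"band\" attr.type=\"string\"/>",
             "  <graph edgedefault=\"directed\">",
             vapply(chart$units, node, character(1L)),
             node(chart$activity))
  if (chart$include_error) lines <- c(lines, node("error"))
  for (i in seq_len(nrow(chart$corr_edges))) {
    e <- chart$corr_edges[i, ]
    lines <- c(lines, edge(e$from, e$to, e$r, e$band, directed = FALSE))
  }
  for (i in seq_len(nrow(chart$direct_edges))) {
    e <- chart$direct_edges[i, ]
    lines <- c(lines, edge(e$unit, chart$activity, e$b_star, "direct",
                           directed = TRUE))
  }
  if (chart$include_error) {
    lines <- c(lines, edge("error", chart$activity, 1, "error", directed = TRUE))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
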