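#' Export a network for Cytoscape
#'
#' Writes the co-occurrence network in two forms: GraphML with all node and
#' edge attributes, and a three-column tab-separated edge list
#' (source, interaction, target) where the interaction is `"pp"` for a
#' positive-correlation edge and `"np"` for a negative one, loadable as a
#' Cytoscape SIF file.
#'
#' @param g an `igraph` network as produced by [build_network()].
#' @param path_graphml output path for GraphML, or NULL to skip.
#' @param path_edgelist output path for the SIF-style edge list, or NULL.
#' @return invisibly, the paths written.
#' @export
write_network <- function(g, path_graphml = NULL, path_edgelist = NULL) {
  stopifnot(igraph::is_igraph(g))
  if (!is.null(path_graphml)) {
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  if (!is.null(path_edgelist)) {
    if (igraph::ecount(g) > 0) {
      ends <- igraph::as_edgelist(g, names = TRUE)
      sgn <- igraph::edge_attr(g, "sign")
      if (is.null(sgn)) sgn <- rep(1, nrow(ends))
      df <- data.frame(source = ends[, 1],
                       interaction = ifelse(sgn >= 0, "pp", "np"),
                       target = ends[, 2], stringsAsFactors = FALSE)
    } else {
      df <- data.frame(source = character(), interaction = character(),
                       target = character())
    }
    utils::write.table(df, path_edgelist, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml = path_graphml, edgelist = path_edgelist))
}

#' Read a network back from GraphML
#'
#' @param path a GraphML file written by [write_network()] (or any GraphML).
#' @return an `igraph` object.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Round half away from zero
#'
#' Fixed-precision rounding used for report files, where exact halves round
#' up in magnitude (2.7875 -> 2.788) rather than to the nearest even digit
#' as base `round()` does.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Write a topology report (plus optional partition and roles) to disk
#'
#' Emits a key/value TSV with one row per topological index, numeric values
#' rounded half-up to three decimals, and optionally companion tables for
#' the module partition and the Zi-Pi node roles.
#'
#' @param report a `topology_report` from [topology_stats()].
#' @param path output path for the key/value report.
#' @param partition optional `module_partition`; written to
#'   `<path>.modules.tsv`.
#' @param roles optional node-role data frame from [zi_pi()]; written to
#'   `<path>.roles.tsv`.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path, partition = NULL, roles = NULL) {
  vals <- unlist(report)
  out <- vapply(seq_along(vals), function(i) {
    v <- vals[[i]]
    if (is.numeric(v) && is.finite(v) && v != floor(v))
      format(round_half_up(v, 3), nsmall = 3)
    else as.character(v)
  }, character(1))
  df <- data.frame(index = names(vals), value = out, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(partition)) {
    pdf <- data.frame(node = names(partition$membership),
                      module = unname(partition$membership))
    utils::write.table(pdf, paste0(path, ".modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(roles)) {
    utils::write.table(roles, paste0(path, ".roles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a key/value report written by [write_report()]
#'
#' @param path report file path.
#' @return a named list; values parsed as numeric where possible.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  vals <- lapply(df$value, function(v) {
    if (is.na(v)) return(NA)
    suppressWarnings(n <- as.numeric(v))
    if (is.na(n) && v != "NA" && v != "NaN") v else n
  })
  stats::setNames(vals, df$index)
}
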