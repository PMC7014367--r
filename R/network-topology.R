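#' Build the co-occurrence network at a similarity threshold
#'
#' Draws an undirected edge between two OTUs whenever their similarity
#' `|r|` is at or above the threshold. Each edge carries the correlation
#' sign (+1 cooperative / -1 competitive) and the similarity value.
#' OTUs left without any edge are dropped: the network node set consists
#' of connected taxa only, which is why reported node counts are far
#' smaller than the number of OTUs entering the correlation step.
#'
#' @param sim a `similarity_matrix` from [pearson_similarity()].
#' @param t threshold in (0, 1).
#' @param taxonomy optional named character vector of taxonomy labels,
#'   attached as a node attribute where names match OTU ids.
#' @return an `igraph` with vertex attrs `name`, `node_kind` (and
#'   `taxonomy` if given), edge attrs `sign` and `similarity`, and graph
#'   attr `threshold`.
#' @export
build_network <- function(sim, t, taxonomy = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"), t > 0, t < 1)
  S <- sim$S
  idx <- which(S >= t & upper.tri(S), arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop(sprintf("threshold %.3f leaves no edges (max similarity %.3f); lower it",
                 t, max(S)))
  ids <- sim$otu_ids
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      sign = sim$signs[idx], similarity = S[idx],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$node_kind <- "otu"
  if (!is.null(taxonomy)) {
    igraph::V(g)$taxonomy <- unname(taxonomy[igraph::V(g)$name])
  }
  g$threshold <- t
  g
}

#' Topological index panel of a network
#'
#' Computes the standard descriptive panel of a molecular ecological
#' network: node and link counts, average degree (`avgK = 2L/N`), average
#' Watts-Strogatz clustering coefficient (nodes of degree < 2 contribute
#' 0), average geodesic distance over connected pairs, density, Krackhardt
#' connectedness (fraction of node pairs joined by some path), the R^2 of
#' the power-law fit to the degree distribution, and — when a partition is
#' supplied — the number of modules and Newman modularity.
#'
#' @param g an `igraph` network.
#' @param partition optional `module_partition` from [detect_modules()].
#' @return object of class `topology_report`: a named list of indices.
#' @export
topology_stats <- function(g, partition = NULL) {
  n <- igraph::vcount(g)
  l <- igraph::ecount(g)
  if (n == 0) stop("empty graph")
  avg_k <- 2 * l / n
  cc <- igraph::transitivity(g, type = "localundirected")
  cc[!is.finite(cc)] <- 0
  avg_cc <- mean(cc)
  if (n == 1) {
    warning("single-node graph: average path distance undefined, reported as 0")
    avg_pd <- 0
    connectivity <- 1
  } else {
    d <- igraph::distances(g)
    finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
    avg_pd <- if (length(finite)) mean(finite) else 0
    comp <- igraph::components(g)
    connectivity <- sum(choose(comp$csize, 2)) / choose(n, 2)
  }
  density <- if (n > 1) 2 * l / (n * (n - 1)) else 0
  r2 <- degree_powerlaw_r2(g)
  structure(list(
    nodes = n, links = l, avg_degree = avg_k, avg_clustering = avg_cc,
    avg_path_distance = avg_pd, density = density,
    connectivity = connectivity,
    n_modules = if (is.null(partition)) NA_integer_ else length(partition$sizes),
    modularity = if (is.null(partition)) NA_real_ else partition$modularity,
    powerlaw_r2 = r2,
    threshold = if (is.null(g$threshold)) NA_real_ else g$threshold
  ), class = c("topology_report", "list"))
}

#' @export
print.topology_report <- function(x, ...) {
  cat("topology_report\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.numeric(v) && is.finite(v)) format(round_half_up(v, 3)) else as.character(v)))
  }
  invisible(x)
}

#' R-squared of the power-law fit to the degree distribution
#'
#' Ordinary least squares of `log10(frequency)` on `log10(degree)` over
#' the observed degree-frequency histogram (zero-frequency degrees
#' excluded). High R^2 is conventionally read as evidence of scale-free
#' structure.
#'
#' @param g an `igraph` network.
#' @return R^2 in \[0, 1\], or NaN (with a warning) when fewer than 3
#'   distinct positive degrees are present.
#' @export
degree_powerlaw_r2 <- function(g) {
  deg <- igraph::degree(g)
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab))
  nk <- as.numeric(tab)
  if (length(k) < 3) {
    warning("fewer than 3 distinct degrees; power-law R^2 undefined")
    return(NaN)
  }
  fit <- stats::lm(log10(nk) ~ log10(k))
  summary(fit)$r.squared
}
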