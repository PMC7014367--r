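#' Detect network modules by greedy modularity maximization
#'
#' Partitions the network into modules with the Clauset-Newman-Moore fast
#' greedy algorithm on the unweighted, unsigned graph. Disconnected
#' components are handled natively (each ends up in its own module or
#' modules). The algorithm is deterministic for a fixed node ordering; the
#' `seed` argument is accepted for interface uniformity with the
#' stochastic stages but has no effect here.
#'
#' @param g an `igraph` network.
#' @param method currently only `"greedy"`.
#' @param seed unused; kept so all pipeline stages share a signature.
#' @return object of class `module_partition`: list with `membership`
#'   (named integer vector), `sizes` (module sizes) and `modularity`
#'   (Newman Q of the partition).
#' @export
detect_modules <- function(g, method = "greedy", seed = NULL) {
  method <- match.arg(method, "greedy")
  stopifnot(igraph::vcount(g) > 0)
  g0 <- strip_weights(g)
  cl <- igraph::cluster_fast_greedy(g0, weights = NULL)
  memb <- stats::setNames(as.integer(igraph::membership(cl)), igraph::V(g)$name)
  q <- igraph::modularity(g0, memb)
  # guard against greedy merges stopping at a negative-Q tie (e.g. a clique):
  # the one-module-per-component partition has Q >= 0 and is the floor
  comp <- stats::setNames(as.integer(igraph::components(g0)$membership),
                          igraph::V(g)$name)
  q_comp <- igraph::modularity(g0, comp)
  if (q_comp > q) {
    memb <- comp
    q <- q_comp
  }
  structure(list(membership = memb,
                 sizes = as.integer(table(memb)),
                 modularity = q),
            class = "module_partition")
}

# strip weight-like edge attributes so community detection is unweighted
strip_weights <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d nodes, Q = %.3f\n",
              length(x$sizes), length(x$membership), x$modularity))
  invisible(x)
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' Classifies each node's topological role in the modular network.
#' `Zi` is the z-score of the node's within-module degree relative to the
#' other members of its module (0 when the module has fewer than 3 nodes
#' or zero within-degree variance); `Pi = 1 - sum_s (k_is / k_i)^2` where
#' `k_is` counts the node's links into module `s`. Nodes are labelled by
#' the conventional quadrants of the Z-P plane: module hubs
#' (`Zi >= z_threshold`), connectors (`Pi >= p_threshold`), network hubs
#' (both) and peripherals (neither). With the default thresholds 2.5 and
#' 0.62, module hubs and connectors are the "critical species" of the
#' network.
#'
#' @param g an `igraph` network.
#' @param partition a `module_partition` from [detect_modules()].
#' @param z_threshold Zi cutoff (default 2.5, inclusive).
#' @param p_threshold Pi cutoff (default 0.62, inclusive).
#' @return data frame with one row per node: `node`, `module`, `degree`,
#'   `within_degree`, `Zi`, `Pi`, `role` and (when present in the graph)
#'   `taxonomy`.
#' @export
zi_pi <- function(g, partition, z_threshold = 2.5, p_threshold = 0.62) {
  memb <- partition$membership[igraph::V(g)$name]
  if (anyNA(memb)) stop("partition does not cover every network node")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(adj)
  mods <- sort(unique(memb))
  # k_is: links of node i into module s
  k_is <- sapply(mods, function(s) rowSums(adj[, memb == s, drop = FALSE]))
  if (is.null(dim(k_is))) k_is <- matrix(k_is, nrow = 1)
  within <- k_is[cbind(seq_along(memb), match(memb, mods))]
  zi <- numeric(length(memb))
  for (s in mods) {
    in_s <- memb == s
    if (sum(in_s) >= 3) {
      mu <- mean(within[in_s])
      sdv <- stats::sd(within[in_s])
      if (sdv > 0) zi[in_s] <- (within[in_s] - mu) / sdv
    }
  }
  pi_v <- 1 - rowSums((k_is / deg)^2)
  role <- classify_role(zi, pi_v, z_threshold, p_threshold)
  out <- data.frame(node = igraph::V(g)$name, module = unname(memb),
                    degree = unname(deg), within_degree = unname(within),
                    Zi = unname(zi), Pi = unname(pi_v), role = role,
                    stringsAsFactors = FALSE)
  tax <- igraph::vertex_attr(g, "taxonomy")
  if (!is.null(tax)) out$taxonomy <- tax
  rownames(out) <- NULL
  out
}

#' Classify nodes in the Z-P plane
#'
#' Deterministic role assignment from a node's within-module degree
#' z-score and among-module connectivity. Both thresholds are inclusive:
#' a node exactly at `Zi = 2.5` is a hub, one exactly at `Pi = 0.62` a
#' connector.
#'
#' @param zi,pi numeric vectors of equal length.
#' @param z_threshold,p_threshold role cutoffs (defaults 2.5 and 0.62).
#' @return character vector: `"peripheral"`, `"connector"`,
#'   `"module hub"` or `"network hub"`.
#' @export
classify_role <- function(zi, pi, z_threshold = 2.5, p_threshold = 0.62) {
  ifelse(zi >= z_threshold & pi >= p_threshold, "network hub",
  ifelse(zi >= z_threshold, "module hub",
  ifelse(pi >= p_threshold, "connector", "peripheral")))
}

#' Count critical species by role
#'
#' @param roles data frame from [zi_pi()].
#' @return named integer vector `c(n_module_hubs, n_connectors,
#'   n_network_hubs)`.
#' @export
count_critical_species <- function(roles) {
  c(n_module_hubs = sum(roles$role == "module hub"),
    n_connectors = sum(roles$role == "connector"),
    n_network_hubs = sum(roles$role == "network hub"))
}

#' Module eigengenes
#'
#' Summarizes each sufficiently large module by the first principal
#' component of its members' standardized abundance profiles: rows of the
#' log-abundance matrix belonging to the module are z-scored across
#' samples and the first right singular vector (one value per sample) is
#' the module eigengene, sign-oriented to correlate positively with the
#' module's mean standardized profile. Modules below `min_module_size`
#' nodes are skipped, mirroring the convention of analysing only modules
#' with more than 5 nodes.
#'
#' @param partition a `module_partition`.
#' @param log_abundance matrix of log abundances with OTU rownames and
#'   sample colnames (from [log_transform()]).
#' @param min_module_size smallest module to summarize (default 6).
#' @return object of class `module_eigengenes`: list with `eigengenes`
#'   (samples x modules matrix of unit-norm eigengenes) and
#'   `variance_explained` (named vector).
#' @export
module_eigengene <- function(partition, log_abundance, min_module_size = 6) {
  memb <- partition$membership
  mods <- sort(unique(memb))
  egs <- list()
  ve <- c()
  for (s in mods) {
    members <- names(memb)[memb == s]
    if (length(members) < min_module_size) next
    members <- intersect(members, rownames(log_abundance))
    sub <- log_abundance[members, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("module %s has no variable members; skipped", s))
      next
    }
    z <- t(scale(t(sub)))
    sv <- svd(z)
    eg <- sv$v[, 1]
    if (stats::cor(eg, colMeans(z)) < 0) eg <- -eg
    egs[[as.character(s)]] <- eg
    ve[as.character(s)] <- sv$d[1]^2 / sum(sv$d^2)
  }
  if (!length(egs)) {
    warning(sprintf("no module reaches min_module_size = %d", min_module_size))
    return(structure(list(eigengenes = NULL, variance_explained = ve),
                     class = "module_eigengenes"))
  }
  E <- do.call(cbind, egs)
  rownames(E) <- colnames(log_abundance)
  colnames(E) <- paste0("M", names(egs))
  structure(list(eigengenes = E, variance_explained = ve),
            class = "module_eigengenes")
}

#' @export
print.module_eigengenes <- function(x, ...) {
  if (is.null(x$eigengenes)) cat("module_eigengenes: none\n")
  else cat(sprintf("module_eigengenes: %d modules x %d samples\n",
                   ncol(x$eigengenes), nrow(x$eigengenes)))
  invisible(x)
}

#' Hierarchy of module eigengenes
#'
#' Average-linkage hierarchical clustering of module eigengenes with
#' dissimilarity `1 - Pearson correlation`; the standard display of how
#' modules relate across samples.
#'
#' @param eigengenes a `module_eigengenes` object or samples x modules
#'   matrix.
#' @param newick_path optional path; the dendrogram is also written as a
#'   Newick tree.
#' @return an `hclust` object (single-leaf case: NULL with a message).
#' @export
eigengene_hierarchy <- function(eigengenes, newick_path = NULL) {
  E <- if (inherits(eigengenes, "module_eigengenes")) eigengenes$eigengenes else eigengenes
  if (is.null(E) || ncol(E) < 2) {
    message("fewer than 2 eigengenes; hierarchy is trivial")
    return(NULL)
  }
  d <- stats::as.dist(1 - stats::cor(E))
  hc <- stats::hclust(d, method = "average")
  if (!is.null(newick_path)) {
    ape::write.tree(ape::as.phylo(hc), file = newick_path)
  }
  hc
}
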