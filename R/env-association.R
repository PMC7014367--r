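#' Mantel test between community structure and an environmental factor
#'
#' Correlates the community dissimilarity structure with the distance
#' structure of a single environmental factor. Community distance is
#' Bray-Curtis on per-sample relative abundances (the amplicon
#' convention); the factor is z-scored and its distance is Euclidean
#' (absolute difference). The Mantel statistic `r` is the Pearson
#' correlation of the two condensed distance vectors, and significance is
#' assessed one-sided by permuting sample labels of the factor distance
#' matrix: `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`.
#'
#' @param community an [otu_table] (taxa x samples).
#' @param env_factor numeric vector, one value per sample, in the same
#'   sample order as the table's columns (names checked when present).
#' @param n_perm number of permutations (default 999, minimum 99).
#' @param seed RNG seed for the permutations.
#' @param community_distance `"bray"` (default) or `"euclidean-log"`
#'   (Euclidean on log10(count + 1)).
#' @return object of class `mantel_result`: list with `r`, `p`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(community, env_factor, n_perm = 999, seed = 1,
                        community_distance = c("bray", "euclidean-log")) {
  community_distance <- match.arg(community_distance)
  m <- unclass(as.matrix(community))
  ns <- ncol(m)
  if (ns < 4) stop("need at least 4 samples for a Mantel test")
  if (n_perm < 99) stop("use at least 99 permutations")
  if (length(env_factor) != ns) stop("factor length must equal number of samples")
  if (!is.null(names(env_factor)) && !is.null(colnames(m))) {
    if (!all(colnames(m) %in% names(env_factor)))
      stop("sample names of factor and community do not match")
    env_factor <- env_factor[colnames(m)]
  }
  if (stats::sd(env_factor) == 0) stop("environmental factor is constant")
  dc_mat <- as.matrix(community_dist(m, community_distance))
  z <- as.numeric(scale(env_factor))
  df_mat <- abs(outer(z, z, "-"))
  lower <- lower.tri(dc_mat)
  dc <- dc_mat[lower]
  r_obs <- stats::cor(dc, df_mat[lower])
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(ns)
    if (stats::cor(dc, df_mat[p, p][lower]) >= r_obs) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (1 + exceed) / (n_perm + 1),
                 n_permutations = n_perm, seed = seed),
            class = "mantel_result")
}

community_dist <- function(m, method) {
  if (method == "bray") {
    rel <- sweep(m, 2, colSums(m), "/")
    vegan::vegdist(t(rel), method = "bray")
  } else {
    stats::dist(t(log10(m + 1)))
  }
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_permutations))
  invisible(x)
}

#' Mantel tests for every factor of an environment table
#'
#' @param community an [otu_table].
#' @param env an [env_table] with the same samples.
#' @param n_perm,seed,community_distance passed to [mantel_test()]; the
#'   seed is offset per factor so permutation streams are independent.
#' @return data frame with columns `factor`, `r`, `p`.
#' @export
mantel_panel <- function(community, env, n_perm = 999, seed = 1,
                         community_distance = "bray") {
  env <- align_samples(env, sample_ids(community))
  res <- lapply(seq_len(ncol(env)), function(j) {
    mt <- mantel_test(community, env[, j], n_perm = n_perm, seed = seed + j,
                      community_distance = community_distance)
    data.frame(factor = colnames(env)[j], r = mt$r, p = mt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

align_samples <- function(env, samples) {
  if (!all(samples %in% rownames(env)))
    stop("environment table is missing samples present in the OTU table")
  unclass(env)[samples, , drop = FALSE]
}

#' Module-environment correlation heatmap table
#'
#' Pearson correlation between each module eigengene and each
#' environmental factor, with the two-sided t-test p-value and a
#' significance mask at `alpha`. This is the table behind the
#' module-environment heatmaps: it asks which environmental gradients the
#' coherent abundance pattern of each module follows.
#'
#' @param eigengenes a `module_eigengenes` object (or samples x modules
#'   matrix).
#' @param env an [env_table] sharing the eigengenes' samples.
#' @param alpha significance level for the mask (default 0.05).
#' @return object of class `module_env_heatmap`: list of matrices `r`,
#'   `p` (modules x factors) and logical `significant`.
#' @export
module_env_heatmap <- function(eigengenes, env, alpha = 0.05) {
  E <- if (inherits(eigengenes, "module_eigengenes")) eigengenes$eigengenes else eigengenes
  if (is.null(E)) stop("no eigengenes to correlate")
  ev <- align_samples(env, rownames(E))
  nm <- ncol(E); nf <- ncol(ev)
  r <- matrix(NA_real_, nm, nf, dimnames = list(colnames(E), colnames(ev)))
  p <- r
  for (i in seq_len(nm)) for (j in seq_len(nf)) {
    if (stats::sd(ev[, j]) == 0) next
    ct <- stats::cor.test(E[, i], ev[, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  if (anyNA(r)) warning("constant factor column(s); correlations undefined there")
  structure(list(r = r, p = p, significant = !is.na(p) & p < alpha,
                 alpha = alpha),
            class = "module_env_heatmap")
}

#' @export
print.module_env_heatmap <- function(x, ...) {
  cat(sprintf("module_env_heatmap: %d modules x %d factors, %d significant at alpha = %g\n",
              nrow(x$r), ncol(x$r), sum(x$significant), x$alpha))
  invisible(x)
}

#' Combined species-environment network
#'
#' Builds an RMT-style correlation network over the most abundant taxa
#' together with the environmental factors as additional nodes: the top
#' `top_k` rows by total abundance are log10(count + 1)-transformed, the
#' factors are z-scored, the stacked matrix is correlated across samples
#' and thresholded exactly as the species-only network. Node attribute
#' `node_kind` distinguishes `"otu"` from `"env_factor"`.
#'
#' @param tab an [otu_table], typically aggregated to genus level.
#' @param env an [env_table] with the same samples.
#' @param threshold similarity threshold in (0, 1).
#' @param top_k number of most abundant taxa to include (default 50; all
#'   taxa, with a warning, if fewer are available).
#' @return an `igraph` with `node_kind` vertex attribute and signed edges.
#' @export
combined_env_network <- function(tab, env, threshold, top_k = 50) {
  stopifnot(inherits(tab, "otu_table"))
  m <- unclass(tab)
  ev <- align_samples(env, colnames(m))
  if (top_k > nrow(m)) {
    warning(sprintf("only %d taxa available; using all", nrow(m)))
    top_k <- nrow(m)
  }
  top <- order(rowSums(m), decreasing = TRUE)[seq_len(top_k)]
  la <- log10(m[top, , drop = FALSE] + 1)
  ez <- t(scale(ev))  # factors x samples, z-scored per factor
  stacked <- rbind(la, ez)
  sim <- pearson_similarity(stacked)
  tax <- taxonomy(tab)
  g <- build_network(sim, threshold, taxonomy = tax)
  igraph::V(g)$node_kind <- ifelse(igraph::V(g)$name %in% colnames(ev),
                                   "env_factor", "otu")
  g
}
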