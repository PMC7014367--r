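#' Filter OTUs by total abundance and prevalence
#'
#' Keeps OTUs whose summed count across samples is at least `min_total` and
#' which are present (count > 0) in at least a fraction `min_prevalence` of
#' samples. Row order is preserved. Major-OTU selection of this kind (e.g.
#' a minimum summed count over the replicate samples) is the usual first
#' step of RMT network construction, as only consistently detected taxa
#' carry a meaningful correlation signal.
#'
#' @param x an [otu_table].
#' @param min_total minimum summed count across samples (default 0).
#' @param min_prevalence minimum fraction of samples with a non-zero count
#'   (default 0.5, i.e. present in at least half the samples).
#' @return the filtered [otu_table].
#' @export
filter_otus <- function(x, min_total = 0, min_prevalence = 0.5) {
  stopifnot(inherits(x, "otu_table"), min_total >= 0,
            min_prevalence >= 0, min_prevalence <= 1)
  m <- unclass(x)
  keep <- rowSums(m) >= min_total &
    rowMeans(m > 0) >= min_prevalence
  if (!any(keep))
    stop(sprintf("filtering removed all OTUs (%d before, 0 after); lower min_total/min_prevalence",
                 nrow(m)))
  tax <- taxonomy(x)
  otu_table(m[keep, , drop = FALSE],
            taxonomy = if (is.null(tax)) NULL else tax[keep])
}

#' Log-transform abundances
#'
#' Elementwise `log10(count + 1)`; the pseudocount maps absent OTUs (0) to
#' 0 and leaves the transform monotone.
#'
#' @param x an [otu_table] or non-negative matrix.
#' @return numeric matrix of the same shape.
#' @export
log_transform <- function(x) {
  m <- unclass(as.matrix(x))
  if (any(m < 0)) stop("abundances must be non-negative")
  attr(m, "taxonomy") <- NULL
  log10(m + 1)
}

#' Pearson similarity matrix between OTUs
#'
#' Correlates every pair of rows (OTUs) across samples and separates the
#' correlation into a magnitude and a sign: the similarity matrix `S`
#' holds `|r|` with a zero diagonal, and `signs` holds `sign(r)`. The
#' magnitude is what the RMT threshold acts on; the sign is carried to the
#' network edges (positive = co-occurrence, negative = exclusion).
#'
#' Constant rows have undefined correlations and are dropped with a
#' warning.
#'
#' @param x numeric matrix, rows = OTUs, columns = samples (usually the
#'   output of [log_transform()]).
#' @return an object of class `similarity_matrix`: list with `S`, `signs`,
#'   and `otu_ids`.
#' @export
pearson_similarity <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("need at least 3 samples to estimate correlations")
  if (is.null(rownames(x))) rownames(x) <- paste0("OTU_", seq_len(nrow(x)))
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant row(s) with undefined correlation",
                    sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 variable OTUs remain")
  r <- stats::cor(t(x))
  r[!is.finite(r)] <- 0
  S <- abs(r)
  diag(S) <- 0
  signs <- sign(r)
  diag(signs) <- 0
  signs[S == 0] <- 0
  structure(list(S = S, signs = signs, otu_ids = rownames(x)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d OTUs, max |r| = %.3f\n",
              length(x$otu_ids), max(x$S)))
  invisible(x)
}
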