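#' Alpha-diversity indices
#'
#' Per-sample diversity estimators conventionally reported for amplicon
#' data: Shannon entropy, (Gini-)Simpson, and the non-parametric richness
#' estimators Chao1 and ACE. `shannon()`, `simpson()`, `chao1()` and
#' `ace()` operate on a single sample's count vector; [diversity_panel()]
#' applies all of them to every sample of an [otu_table].
#'
#' Shannon and Simpson are computed via [vegan::diversity()]; Chao1 and ACE
#' via [vegan::estimateR()]. Chao1 uses the bias-corrected form
#' `S_obs + F1(F1 - 1) / (2 (F2 + 1))`, stable when there are no
#' doubletons; ACE partitions species at `rare_cutoff` (abundance <= 10) and
#' inflates the rare-class richness by its sample coverage and coefficient
#' of variation.
#'
#' @param counts non-negative numeric vector of abundances for one sample.
#' @param base logarithm base for Shannon (default natural log).
#' @param inverse if TRUE return inverse Simpson `1 / sum(p^2)` instead of
#'   the Gini-Simpson `1 - sum(p^2)`.
#' @return a single numeric value.
#' @examples
#' shannon(c(10, 10, 10, 10))  # log(4)
#' simpson(c(10, 10))          # 0.5
#' chao1(c(1, 1, 2, 5))        # 4.5
#' @name diversity-indices
NULL

check_counts <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative with no NA")
  if (sum(counts) == 0) stop("all counts are zero")
  invisible(counts)
}

check_integer_counts <- function(counts) {
  check_counts(counts)
  if (any(counts != floor(counts)))
    stop("richness estimators need integer counts; round or rarefy first")
  invisible(counts)
}

#' @rdname diversity-indices
#' @export
shannon <- function(counts, base = exp(1)) {
  check_counts(counts)
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' @rdname diversity-indices
#' @export
simpson <- function(counts, inverse = FALSE) {
  check_counts(counts)
  idx <- if (inverse) "invsimpson" else "simpson"
  as.numeric(vegan::diversity(counts, index = idx))
}

#' @rdname diversity-indices
#' @export
chao1 <- function(counts) {
  check_integer_counts(counts)
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname diversity-indices
#' @param rare_cutoff abundance at or below which a species counts as
#'   "rare" for ACE (default 10, the standard choice).
#' @export
ace <- function(counts, rare_cutoff = 10) {
  check_integer_counts(counts)
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(as.numeric(length(counts)))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE sample coverage is zero (all rare species are singletons); falling back to Chao1")
    return(chao1(counts))
  }
  fk <- vapply(seq_len(rare_cutoff), function(k) sum(rare == k), numeric(1))
  gamma2 <- max(0, s_rare / c_ace * sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Per-sample alpha-diversity panel
#'
#' @param x an [otu_table] of integer counts.
#' @param shannon_base logarithm base for Shannon.
#' @param simpson_inverse use inverse Simpson instead of Gini-Simpson.
#' @return data frame with one row per sample: `sample`, `observed_otus`,
#'   `shannon`, `simpson`, `chao1`, `ace`.
#' @export
diversity_panel <- function(x, shannon_base = exp(1), simpson_inverse = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  res <- lapply(sample_ids(x), function(s) {
    v <- unclass(x)[, s]
    data.frame(sample = s,
               observed_otus = sum(v > 0),
               shannon = shannon(v, base = shannon_base),
               simpson = simpson(v, inverse = simpson_inverse),
               chao1 = chao1(v),
               ace = ace(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
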