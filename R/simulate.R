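#' Simulate an OTU table with planted correlated modules
#'
#' Generates the statistical structure the RMT pipeline assumes: groups of
#' OTUs ("planted modules") whose log10 abundances share a latent Gaussian
#' factor per sample, plus independent log-normal noise, exponentiated and
#' multinomially sampled to integer counts at a fixed sequencing depth.
#' Within a module, the latent log-abundance correlation between any two
#' members is `within_corr`; across modules the population correlation is
#' zero (finite-sample correlations of ~|0.2| remain at the default 10
#' samples, emulating noise correlations in small replicate designs).
#'
#' The latent log10 abundance of OTU i in module m at sample s is
#' `mu_i + a * g_m(s) + noise_sd * e_is` with
#' `a = noise_sd * sqrt(within_corr / (1 - within_corr))`, so the shared
#' fraction of variance is exactly `within_corr`. Baseline abundances
#' `mu_i` are drawn once per OTU from N(2.5, 0.4) (log10 scale), giving a
#' realistic spread of rare and dominant taxa.
#'
#' @param n_otus number of OTUs.
#' @param n_samples number of replicate samples (default 10, a typical
#'   replicated pot/plot design).
#' @param n_modules number of planted modules; OTUs are split as evenly as
#'   possible.
#' @param within_corr latent within-module Pearson correlation in (0, 1).
#' @param noise_sd SD of the independent log10 noise (default 0.3).
#' @param depth multinomial sequencing depth per sample (default 20000).
#' @param seed RNG seed; identical inputs reproduce identical tables.
#' @return list with `otu` (an [otu_table] of integer counts) and `truth`
#'   (class `synthetic_truth`: planted `module` per OTU, the latent
#'   `factors` matrix (modules x samples), the pre-sampling
#'   `log_abundance` matrix, and the generator parameters).
#' @export
simulate_community <- function(n_otus = 80, n_samples = 10, n_modules = 4,
                               within_corr = 0.9, noise_sd = 0.3,
                               depth = 20000, seed = 1) {
  stopifnot(n_modules <= n_otus, within_corr > 0, within_corr < 1,
            noise_sd >= 0, depth > 0)
  set.seed(seed)
  module <- rep(seq_len(n_modules), length.out = n_otus)
  module <- sort(module)
  factors <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
  a <- if (noise_sd > 0) noise_sd * sqrt(within_corr / (1 - within_corr)) else 0.3
  mu <- stats::rnorm(n_otus, mean = 2.5, sd = 0.4)
  eps <- matrix(stats::rnorm(n_otus * n_samples, sd = noise_sd), n_otus, n_samples)
  z <- mu + a * factors[module, , drop = FALSE] + eps
  lam <- 10^z
  expected <- depth * sweep(lam, 2, colSums(lam), "/")
  if (mean(expected < 1) > 0.5)
    warning("expected counts are below 1 for most OTUs; increase depth or lower abundance spread")
  counts <- sapply(seq_len(n_samples), function(s) {
    stats::rmultinom(1, size = depth, prob = lam[, s])
  })
  rownames(counts) <- sprintf("OTU_%03d", seq_len(n_otus))
  colnames(counts) <- sprintf("S%02d", seq_len(n_samples))
  otu <- otu_table(counts)
  dimnames(z) <- dimnames(counts)
  truth <- structure(list(
    module = stats::setNames(module, rownames(counts)),
    factors = factors,
    log_abundance = z,
    params = list(n_otus = n_otus, n_samples = n_samples,
                  n_modules = n_modules, within_corr = within_corr,
                  noise_sd = noise_sd, depth = depth, seed = seed)),
    class = "synthetic_truth")
  list(otu = otu, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic_truth: %d OTUs in %d modules, %d samples, within_corr = %g, seed = %d\n",
              p$n_otus, p$n_modules, p$n_samples, p$within_corr, p$seed))
  invisible(x)
}

#' Simulate environmental factors coupled to planted modules
#'
#' Each factor is either coupled to one planted module — its per-sample
#' value is `beta * g_m(s) + noise` where `g_m` is that module's latent
#' factor — or pure noise. The default layout mimics a soil panel where
#' pH, EC, OM and AK track community modules while NN, AN and AP do not.
#'
#' @param truth a `synthetic_truth` from [simulate_community()].
#' @param couplings named list mapping factor name to `c(module, beta)`;
#'   factors named in `noise_factors` (or any factor not listed) are pure
#'   noise. The default (NULL) couples pH, EC, OM, AK to modules 1, 2, 1, 3
#'   with beta 1, clamped to the number of planted modules.
#' @param noise_factors character vector of uncoupled factor names.
#' @param noise_sd SD of the factor noise (default 0.5).
#' @param seed RNG seed.
#' @return an [env_table] (samples x factors).
#' @export
simulate_env <- function(truth, couplings = NULL,
                         noise_factors = c("NN", "AN", "AP"),
                         noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  nmod <- nrow(truth$factors)
  ns <- ncol(truth$factors)
  if (is.null(couplings)) {
    couplings <- list(pH = c(1, 1), EC = c(min(2, nmod), 1),
                      OM = c(1, 1), AK = c(min(3, nmod), 1))
  }
  for (cp in couplings) {
    if (cp[1] > nmod) stop("coupling references a module that was not planted")
  }
  names_all <- c(names(couplings), noise_factors)
  vals <- sapply(names_all, function(f) {
    noise <- stats::rnorm(ns, sd = noise_sd)
    if (f %in% names(couplings)) {
      cp <- couplings[[f]]
      cp[2] * truth$factors[cp[1], ] + noise
    } else noise
  })
  rownames(vals) <- sprintf("S%02d", seq_len(ns))
  env_table(vals)
}

#' Simulate a dense and a sparse community condition
#'
#' Produces the paired design the pipeline is meant to contrast: a
#' "dense" condition (many strongly correlated modules, emulating a
#' long-established dryland community) and a "sparse" condition (fewer,
#' more weakly correlated modules, emulating a recently disturbed paddy
#' community). Run through the pipeline at a common similarity threshold,
#' the dense condition should yield more network nodes, more links and a
#' higher average degree.
#'
#' @param params_dense,params_sparse lists of [simulate_community()]
#'   arguments for the two conditions. Defaults: dense = 120 OTUs in 6
#'   modules at within_corr 0.9; sparse = 80 OTUs in 3 modules at
#'   within_corr 0.65 (a disturbed community engages fewer taxa in fewer,
#'   weaker associations); both 10 samples.
#' @param seed base RNG seed (the sparse condition uses `seed + 1000`,
#'   environment tables `seed + 2000/3000`; all below 2^31 for any small
#'   seed).
#' @return list with elements `dense` and `sparse`, each a list of `otu`,
#'   `env`, `truth`.
#' @export
simulate_two_conditions <- function(params_dense = list(n_otus = 120,
                                                        n_modules = 6,
                                                        within_corr = 0.9),
                                    params_sparse = list(n_otus = 80,
                                                         n_modules = 3,
                                                         within_corr = 0.65),
                                    seed = 1) {
  dense <- do.call(simulate_community, c(params_dense, list(seed = seed)))
  sparse <- do.call(simulate_community, c(params_sparse, list(seed = seed + 1000)))
  env_d <- simulate_env(dense$truth, seed = seed + 2000)
  env_s <- simulate_env(sparse$truth, seed = seed + 3000)
  list(dense = list(otu = dense$otu, env = env_d, truth = dense$truth),
       sparse = list(otu = sparse$otu, env = env_s, truth = sparse$truth))
}

#' Serialize / restore the ground truth of a simulation
#'
#' @param truth a `synthetic_truth`.
#' @param path output path (plain-text key/value + tables).
#' @return `read_truth()` returns a `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- truth$params
  writeLines(sprintf("#param %s %s", names(p), vapply(p, format, character(1))), con)
  writeLines(sprintf("#module %s %d", names(truth$module), truth$module), con)
  for (i in seq_len(nrow(truth$factors))) {
    writeLines(paste0("#factor ", i, " ",
                      paste(format(truth$factors[i, ], digits = 17), collapse = " ")), con)
  }
  for (i in seq_len(nrow(truth$log_abundance))) {
    writeLines(paste0("#labund ", rownames(truth$log_abundance)[i], " ",
                      paste(format(truth$log_abundance[i, ], digits = 17), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  parse_tok <- function(prefix) {
    sel <- startsWith(lines, prefix)
    strsplit(sub(paste0(prefix, " "), "", lines[sel]), " +")
  }
  pp <- parse_tok("#param")
  params <- stats::setNames(lapply(pp, function(x) {
    v <- paste(x[-1], collapse = " ")
    suppressWarnings(n <- as.numeric(v)); if (is.na(n)) v else n
  }), vapply(pp, `[`, character(1), 1))
  mm <- parse_tok("#module")
  module <- stats::setNames(as.integer(vapply(mm, `[`, character(1), 2)),
                            vapply(mm, `[`, character(1), 1))
  ff <- parse_tok("#factor")
  factors <- do.call(rbind, lapply(ff, function(x) as.numeric(x[-1])))
  ll <- parse_tok("#labund")
  labund <- do.call(rbind, lapply(ll, function(x) as.numeric(x[-1])))
  rownames(labund) <- vapply(ll, `[`, character(1), 1)
  colnames(labund) <- sprintf("S%02d", seq_len(ncol(labund)))
  structure(list(module = module, factors = factors, log_abundance = labund,
                 params = params),
            class = "synthetic_truth")
}
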