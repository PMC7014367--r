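#' Eigenvalues of the thresholded similarity matrix
#'
#' Applies a hard threshold `t` to the similarity matrix: entries with
#' `|r| < t` are zeroed, rows/columns left with no surviving off-diagonal
#' entry are removed, the diagonal is set to 1 (correlation-matrix
#' convention) and the eigenvalues of the resulting real symmetric matrix
#' are returned in ascending order. Numerically duplicate eigenvalues
#' (within `1e-8`) are collapsed, since zero spacings would otherwise
#' dominate the spacing distribution and trivially mimic Poisson
#' statistics at d -> 0.
#'
#' @param sim a `similarity_matrix` from [pearson_similarity()], or a
#'   symmetric numeric matrix of similarities.
#' @param t threshold in (0, 1).
#' @param min_eigenvalues minimum number of distinct eigenvalues required
#'   for a spacing analysis; fewer flags the result as unusable.
#' @return ascending numeric vector of distinct eigenvalues, with
#'   attributes `n_retained` (matrix order after pruning) and `enough`
#'   (TRUE if at least `min_eigenvalues` distinct values).
#' @export
thresholded_eigenvalues <- function(sim, t, min_eigenvalues = 30) {
  stopifnot(t > 0, t < 1)
  S <- if (inherits(sim, "similarity_matrix")) sim$S else as.matrix(sim)
  A <- S
  A[A < t] <- 0
  diag(A) <- 0
  keep <- rowSums(A > 0) > 0
  if (!any(keep)) {
    out <- numeric(0)
    attr(out, "n_retained") <- 0L
    attr(out, "enough") <- FALSE
    return(out)
  }
  A <- A[keep, keep, drop = FALSE]
  diag(A) <- 1
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  # collapse numerically duplicate eigenvalues
  if (length(ev) > 1) ev <- ev[c(TRUE, diff(ev) > 1e-8)]
  attr(ev, "n_retained") <- sum(keep)
  attr(ev, "enough") <- length(ev) >= min_eigenvalues
  ev
}

#' Spectral unfolding to unit mean spacing
#'
#' Rescales an ordered spectrum so that its local mean level spacing is 1,
#' the prerequisite for comparing a nearest-neighbour spacing distribution
#' (NNSD) against the universal Poisson and GOE forms. The smooth part of
#' the cumulative spectral density is estimated by a cubic smoothing
#' spline fitted to the empirical CDF points (lambda_i, i/n); the unfolded
#' levels are `e_i = n * CDF_hat(lambda_i)` and the returned spacings are
#' their first differences.
#'
#' If the fitted CDF is non-monotone at the eigenvalues, the fit is
#' retried with fewer effective degrees of freedom.
#'
#' @param eigs ascending numeric vector of distinct eigenvalues.
#' @param df starting effective degrees of freedom for the spline.
#' @return numeric vector of `length(eigs) - 1` spacings with mean ~ 1.
#' @export
unfold_spectrum <- function(eigs, df = 10) {
  n <- length(eigs)
  if (n < 5) stop("too few eigenvalues to unfold")
  if (is.unsorted(eigs)) stop("eigenvalues must be ascending")
  ecdf_y <- seq_len(n) / n
  for (d in seq(min(df, n - 1), 4, by = -1)) {
    fit <- stats::smooth.spline(eigs, ecdf_y, df = d)
    e <- n * stats::predict(fit, eigs)$y
    if (!is.unsorted(e, strictly = FALSE) && all(diff(e) >= 0)) {
      return(diff(e))
    }
  }
  stop("could not fit a monotone smooth spectral density; spectrum too irregular")
}

#' Test spacings against Poisson and GOE nearest-neighbour forms
#'
#' Bins the unfolded spacings into equal-width bins on \[0, 3\] (spacings
#' beyond 3 fall in the last bin) and computes chi-square goodness-of-fit
#' statistics against the two universal spacing densities:
#' Poisson `P(d) = exp(-d)` and the GOE Wigner surmise
#' `P(d) = (pi d / 2) exp(-pi d^2 / 4)`. The spectrum is declared Poisson
#' (`poisson_ok`) when the Poisson chi-square is smaller than the GOE one
#' and its goodness-of-fit p-value exceeds `alpha`.
#'
#' @param spacings unfolded spacings from [unfold_spectrum()].
#' @param n_bins number of histogram bins on \[0, 3\] (default 30). Reduced
#'   automatically (with a warning) if more than 20% of bins have expected
#'   count below 1.
#' @param alpha significance level of the Poisson goodness-of-fit test.
#' @return list with `chi2_poisson`, `chi2_goe`, `p_poisson`, `p_goe`,
#'   `n_bins_used` and the logical `poisson_ok`.
#' @export
nnsd_test <- function(spacings, n_bins = 30, alpha = 0.05) {
  n <- length(spacings)
  if (n < 10) stop("too few spacings for a spacing-distribution test")
  if (stats::sd(spacings) == 0) {
    warning("degenerate spacings with zero variance; not Poisson")
    return(list(chi2_poisson = Inf, chi2_goe = Inf, p_poisson = 0,
                p_goe = 0, n_bins_used = n_bins, poisson_ok = FALSE))
  }
  cdf_pois <- function(d) 1 - exp(-d)
  cdf_goe <- function(d) 1 - exp(-pi * d^2 / 4)
  nb <- n_bins
  repeat {
    br <- seq(0, 3, length.out = nb + 1)
    p_pois <- diff(cdf_pois(br))
    p_goe <- diff(cdf_goe(br))
    # last bin absorbs the tail beyond 3
    p_pois[nb] <- p_pois[nb] + (1 - cdf_pois(3))
    p_goe[nb] <- p_goe[nb] + (1 - cdf_goe(3))
    e_pois <- n * p_pois
    if (mean(e_pois < 1) <= 0.2 || nb <= 5) break
    nb <- max(5, ceiling(nb / 2))
    warning(sprintf("expected bin counts too small; reducing to %d bins", nb))
  }
  cuts <- c(br[seq_len(nb)], Inf)
  obs <- tabulate(findInterval(pmax(spacings, 0), cuts,
                               rightmost.closed = FALSE), nbins = nb)
  chi2_poisson <- sum((obs - n * p_pois)^2 / (n * p_pois))
  chi2_goe <- sum((obs - n * p_goe)^2 / (n * p_goe))
  p_poisson <- stats::pchisq(chi2_poisson, df = nb - 1, lower.tail = FALSE)
  p_goe <- stats::pchisq(chi2_goe, df = nb - 1, lower.tail = FALSE)
  list(chi2_poisson = chi2_poisson, chi2_goe = chi2_goe,
       p_poisson = p_poisson, p_goe = p_goe, n_bins_used = nb,
       poisson_ok = (chi2_poisson < chi2_goe) && (p_poisson > alpha))
}

#' Scan similarity thresholds for the GOE-to-Poisson transition
#'
#' Evaluates the NNSD test over an ascending grid of candidate thresholds
#' and selects the smallest threshold at which the eigenvalue spacing
#' distribution of the thresholded similarity matrix is Poisson — the RMT
#' criterion that the surviving correlations reflect modular (non-random)
#' community structure rather than noise. A user-supplied `threshold`
#' bypasses the automatic choice but the scan table can still be
#' requested.
#'
#' @param sim a `similarity_matrix`.
#' @param t_min,t_max,step scan grid (defaults 0.30 to 0.99 by 0.01).
#' @param min_eigenvalues minimum distinct eigenvalues for a usable test.
#' @param n_bins,alpha passed to [nnsd_test()].
#' @param threshold optional manual threshold; recorded as chosen without
#'   consulting the scan.
#' @param run_scan if FALSE and `threshold` is given, skip the grid
#'   entirely.
#' @return object of class `spectral_scan`: list with `scan` (data frame
#'   over the grid), `chosen_threshold`, and `auto` (TRUE if chosen by the
#'   scan).
#' @export
scan_thresholds <- function(sim, t_min = 0.30, t_max = 0.99, step = 0.01,
                            min_eigenvalues = 30, n_bins = 30, alpha = 0.05,
                            threshold = NULL, run_scan = TRUE) {
  grid <- seq(t_min, t_max, by = step)
  scan <- NULL
  if (run_scan || is.null(threshold)) {
    rows <- lapply(grid, function(t) {
      ev <- thresholded_eigenvalues(sim, t, min_eigenvalues = min_eigenvalues)
      if (!attr(ev, "enough")) {
        return(data.frame(threshold = t, n_retained = attr(ev, "n_retained"),
                          n_eigenvalues = length(ev), chi2_poisson = NA,
                          chi2_goe = NA, p_poisson = NA, poisson_ok = FALSE,
                          skipped = TRUE))
      }
      sp <- tryCatch(unfold_spectrum(ev), error = function(e) NULL)
      if (is.null(sp)) {
        return(data.frame(threshold = t, n_retained = attr(ev, "n_retained"),
                          n_eigenvalues = length(ev), chi2_poisson = NA,
                          chi2_goe = NA, p_poisson = NA, poisson_ok = FALSE,
                          skipped = TRUE))
      }
      ts <- suppressWarnings(nnsd_test(sp, n_bins = n_bins, alpha = alpha))
      data.frame(threshold = t, n_retained = attr(ev, "n_retained"),
                 n_eigenvalues = length(ev),
                 chi2_poisson = ts$chi2_poisson, chi2_goe = ts$chi2_goe,
                 p_poisson = ts$p_poisson, poisson_ok = ts$poisson_ok,
                 skipped = FALSE)
    })
    scan <- do.call(rbind, rows)
  }
  if (!is.null(threshold)) {
    chosen <- threshold
    auto <- FALSE
  } else {
    ok <- scan$poisson_ok & !scan$skipped
    if (!any(ok))
      stop("no threshold in the grid passes the Poisson NNSD test; lower min_eigenvalues or supply a manual threshold")
    chosen <- scan$threshold[which(ok)[1]]
    auto <- TRUE
  }
  structure(list(scan = scan, chosen_threshold = chosen, auto = auto),
            class = "spectral_scan")
}

#' @export
print.spectral_scan <- function(x, ...) {
  cat(sprintf("spectral_scan: chosen threshold %.3f (%s)\n",
              x$chosen_threshold, if (x$auto) "automatic" else "manual"))
  if (!is.null(x$scan))
    cat(sprintf("  grid of %d thresholds, %d usable, %d Poisson-ok\n",
                nrow(x$scan), sum(!x$scan$skipped), sum(x$scan$poisson_ok)))
  invisible(x)
}

#' Write the threshold scan table as TSV
#'
#' @param x a `spectral_scan`.
#' @param path output path.
#' @export
write_scan <- function(x, path) {
  utils::write.table(x$scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
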