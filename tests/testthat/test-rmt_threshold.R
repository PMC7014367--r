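test_that("thresholded eigenvalues match the 2x2 closed form", {
  S <- matrix(c(0, 0.9, 0.9, 0), 2, 2)
  ev <- thresholded_eigenvalues(sim_from_matrix(S), 0.8, min_eigenvalues = 2)
  # [[1, .9], [.9, 1]] has eigenvalues 1 +/- 0.9
  expect_equal(as.numeric(ev), c(0.1, 1.9), tolerance = 1e-12)
  expect_equal(attr(ev, "n_retained"), 2)
})

test_that("a matrix with no surviving off-diagonal entries is flagged", {
  S <- matrix(0.2, 4, 4); diag(S) <- 0
  ev <- thresholded_eigenvalues(sim_from_matrix(S), 0.5)
  expect_length(ev, 0)
  expect_false(attr(ev, "enough"))
})

test_that("eigenvalues of a random thresholded similarity are real and ascending", {
  set.seed(3)
  x <- matrix(rnorm(200), 20, 10)
  sim <- pearson_similarity(x)
  ev <- thresholded_eigenvalues(sim, 0.4, min_eigenvalues = 5)
  expect_true(is.numeric(ev) && !is.complex(ev))
  expect_false(is.unsorted(ev))
})

test_that("unfolding yields unit mean spacing", {
  # uniform spectrum: spacings all ~ 1
  sp <- unfold_spectrum(seq(0, 1, length.out = 100))
  expect_equal(mean(sp), 1, tolerance = 0.05)
  expect_lt(max(abs(sp - 1)), 0.25)
  # GOE sample of size 200
  set.seed(1)
  M <- matrix(rnorm(200 * 200), 200)
  G <- (M + t(M)) / sqrt(2 * 200)
  ev <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  sp <- unfold_spectrum(ev)
  expect_gt(mean(sp), 0.95)
  expect_lt(mean(sp), 1.05)
})

test_that("unfolding is invariant to affine rescaling of the spectrum", {
  set.seed(2)
  ev <- sort(rnorm(150))
  expect_equal(unfold_spectrum(2 * ev + 3), unfold_spectrum(ev),
               tolerance = 1e-6)
})

test_that("nnsd_test discriminates Poisson from Wigner spacings", {
  set.seed(42)
  pois <- nnsd_test(rexp(500))
  expect_true(pois$poisson_ok)
  expect_lt(pois$chi2_poisson, pois$chi2_goe)
  set.seed(42)
  wig <- nnsd_test(rwigner(500))
  expect_false(wig$poisson_ok)
  expect_lt(wig$chi2_goe, wig$chi2_poisson)
})

test_that("degenerate spacings are rejected with a warning", {
  expect_warning(res <- nnsd_test(rep(1, 100)), "degenerate")
  expect_false(res$poisson_ok)
})

test_that("auto-scan on a planted-module community picks a block-preserving threshold", {
  sim <- simulate_community(seed = 1)
  S <- pearson_similarity(log_transform(sim$otu))
  sc <- scan_thresholds(S)
  expect_s3_class(sc, "spectral_scan")
  expect_true(sc$auto)
  expect_gte(sc$chosen_threshold, 0.5)
  expect_lte(sc$chosen_threshold, 0.9)
  memb <- sim$truth$module[S$otu_ids]
  within <- S$S[outer(memb, memb, "==") & upper.tri(S$S)]
  expect_gt(mean(within >= sc$chosen_threshold), 0.9)
})

test_that("a manual threshold bypasses the scan", {
  sim <- simulate_community(n_otus = 40, seed = 2)
  S <- pearson_similarity(log_transform(sim$otu))
  sc <- scan_thresholds(S, threshold = 0.88, run_scan = FALSE)
  expect_equal(sc$chosen_threshold, 0.88)
  expect_false(sc$auto)
  expect_null(sc$scan)
})

test_that("retained eigenvalue counts are non-increasing across the grid", {
  sim <- simulate_community(n_otus = 50, seed = 5)
  S <- pearson_similarity(log_transform(sim$otu))
  sc <- scan_thresholds(S, t_min = 0.3, t_max = 0.95, step = 0.05,
                        min_eigenvalues = 10)
  expect_true(all(diff(sc$scan$n_retained) <= 0))
})

test_that("scan is deterministic and avoids t_min on noise, prefers low t on near-diagonal structure", {
  # noise correlation matrices: dense low-threshold graphs look GOE,
  # so the chooser moves well above the grid floor
  for (s in 1:5) {
    set.seed(s)
    S <- pearson_similarity(matrix(rnorm(100 * 10), 100, 10))
    sc <- scan_thresholds(S)
    expect_gt(sc$chosen_threshold, 0.45)
    sc2 <- scan_thresholds(S)
    expect_identical(sc$scan, sc2$scan)
  }
  # sparse incoherent similarities: spectrum is Poisson-like immediately
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 120
    S <- matrix(0, n, n)
    on <- sample(which(upper.tri(S)), round(0.01 * n * (n - 1) / 2))
    S[on] <- runif(length(on), 0.35, 0.6)
    S <- S + t(S)
    sc <- scan_thresholds(sim_from_matrix(S))
    expect_lte(sc$chosen_threshold, 0.45)
  }
})
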