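test_that("Mantel r is 1 when the factor distance mirrors community distance", {
  v <- c(0, 1, 2, 3, 5, 8)
  counts <- matrix(10^v - 1, nrow = 1,
                   dimnames = list("O1", paste0("S", 1:6)))
  tab <- otu_table(counts)
  mt <- mantel_test(tab, v, n_perm = 99, seed = 1,
                    community_distance = "euclidean-log")
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_lte(mt$p, 0.05)
})

test_that("Mantel statistic matches vegan's implementation", {
  set.seed(21)
  sim <- simulate_community(n_otus = 25, seed = 21)
  env_v <- rnorm(10)
  mt <- mantel_test(sim$otu, env_v, n_perm = 99, seed = 2)
  m <- unclass(sim$otu)
  rel <- sweep(m, 2, colSums(m), "/")
  dc <- vegan::vegdist(t(rel), "bray")
  df_ <- dist(scale(env_v))
  ref <- vegan::mantel(dc, df_, permutations = 99)
  expect_equal(mt$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Mantel r is invariant to consistent sample reordering and p is seeded", {
  sim <- simulate_community(n_otus = 20, seed = 4)
  env_v <- setNames(rnorm(10), sample_ids(sim$otu))
  mt1 <- mantel_test(sim$otu, env_v, n_perm = 199, seed = 9)
  perm <- sample(10)
  m2 <- otu_table(unclass(sim$otu)[, perm])
  mt2 <- mantel_test(m2, env_v[perm], n_perm = 199, seed = 9)
  expect_equal(mt1$r, mt2$r, tolerance = 1e-12)
  mt3 <- mantel_test(sim$otu, env_v, n_perm = 199, seed = 9)
  expect_identical(mt1$p, mt3$p)
  expect_gte(mt1$p, 1 / 200)
})

test_that("Mantel preconditions are enforced", {
  sim <- simulate_community(n_otus = 10, n_samples = 3, seed = 1)
  expect_error(mantel_test(sim$otu, rnorm(3)), "4 samples")
  sim2 <- simulate_community(n_otus = 10, seed = 1)
  expect_error(mantel_test(sim2$otu, rep(1, 10)), "constant")
  expect_error(mantel_test(sim2$otu, rnorm(10), n_perm = 10), "99")
})

test_that("mantel_panel runs every factor of an env table", {
  sim <- simulate_community(n_otus = 30, n_modules = 2, seed = 12)
  env <- simulate_env(sim$truth, seed = 13)
  res <- mantel_panel(sim$otu, env, n_perm = 99, seed = 3)
  expect_setequal(res$factor, colnames(env))
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("module-environment heatmap recovers an exact factor copy", {
  set.seed(31)
  E <- matrix(rnorm(30), 10, 3,
              dimnames = list(paste0("S", 1:10), paste0("M", 1:3)))
  ev <- cbind(pH = E[, 1], EC = rnorm(10))
  rownames(ev) <- rownames(E)
  hm <- module_env_heatmap(E, env_table(ev))
  expect_equal(hm$r["M1", "pH"], 1, tolerance = 1e-10)
  expect_lt(hm$p["M1", "pH"], 1e-8)
  expect_true(hm$significant["M1", "pH"])
  # negating a factor flips its correlation column exactly
  ev2 <- ev; ev2[, "EC"] <- -ev2[, "EC"]
  hm2 <- module_env_heatmap(E, env_table(ev2))
  expect_equal(hm2$r[, "EC"], -hm$r[, "EC"], tolerance = 1e-12)
  expect_equal(hm2$p[, "EC"], hm$p[, "EC"], tolerance = 1e-12)
})

test_that("white-noise factors yield null-like heatmap p-values", {
  set.seed(41)
  ps <- replicate(30, {
    E <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("S", 1:10), c("M1", "M2")))
    ev <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("S", 1:10), "X"))
    module_env_heatmap(E, suppressWarnings(env_table(ev)))$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("combined species-environment network links factors to matching taxa", {
  sim <- simulate_community(n_otus = 30, n_modules = 2, seed = 17)
  m <- unclass(sim$otu)
  # factor identical to one genus log profile
  target <- log10(m[1, ] + 1)
  ev <- cbind(pH = target, EC = rnorm(10))
  rownames(ev) <- colnames(m)
  env <- env_table(ev)
  g <- combined_env_network(sim$otu, env, threshold = 0.9, top_k = 20)
  expect_true(igraph::are_adjacent(g, rownames(m)[1], "pH"))
  eid <- igraph::get_edge_ids(g, c(rownames(m)[1], "pH"))
  expect_equal(igraph::E(g)$sign[eid], 1)
  kinds <- igraph::V(g)$node_kind
  expect_setequal(unique(kinds), c("otu", "env_factor"))
  # asking for more taxa than available falls back to all, with a warning
  expect_warning(combined_env_network(sim$otu, env, threshold = 0.9, top_k = 50),
                 "using all")
})

test_that("dropping environment rows reproduces the taxa-only subnetwork", {
  sim <- simulate_community(n_otus = 25, n_modules = 2, seed = 23)
  env <- simulate_env(sim$truth, seed = 24)
  thr <- 0.7
  g_full <- combined_env_network(sim$otu, env, threshold = thr, top_k = 25)
  otus <- igraph::V(g_full)$name[igraph::V(g_full)$node_kind == "otu"]
  sub <- igraph::induced_subgraph(g_full, otus)
  S <- pearson_similarity(log_transform(sim$otu))
  g_taxa <- build_network(S, thr)
  key <- function(g) sort(apply(igraph::as_edgelist(g), 1,
                                function(e) paste(sort(e), collapse = "|")))
  expect_identical(key(sub), key(g_taxa))
})
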