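two_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("n", 1:10)
  g
}

test_that("greedy modularity separates two joined cliques", {
  g <- two_cliques()
  part <- detect_modules(g)
  expect_length(part$sizes, 2)
  memb <- part$membership
  expect_length(unique(memb[paste0("n", 1:5)]), 1)
  expect_length(unique(memb[paste0("n", 6:10)]), 1)
  # the clique split is the best 2-partition: Q matches the Newman formula
  expect_equal(part$modularity, brute_modularity(adj_of(g), memb),
               tolerance = 1e-12)
})

test_that("a single clique is one module with Q = 0", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- paste0("n", 1:6)
  part <- detect_modules(g)
  expect_length(part$sizes, 1)
  expect_equal(part$modularity, 0, tolerance = 1e-12)
})

test_that("reported Q equals independent recomputation on random graphs", {
  for (s in 1:10) {
    g <- random_test_graph(sample(6:14, 1), p = 0.35, seed = 300 + s)
    part <- detect_modules(g)
    expect_equal(part$modularity,
                 brute_modularity(adj_of(g), part$membership[igraph::V(g)$name]),
                 tolerance = 1e-10)
  }
})

test_that("Pi and Zi follow their defining formulas", {
  # star: center c linked to 4 leaves, each leaf in its own module
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("c", paste0("l", 1:4))
  part <- structure(list(membership = c(c = 1L, l1 = 1L, l2 = 2L, l3 = 3L, l4 = 4L),
                         sizes = c(2L, 1L, 1L, 1L), modularity = NA_real_),
                    class = "module_partition")
  roles <- zi_pi(g, part)
  pc <- roles[roles$node == "c", ]
  expect_equal(pc$Pi, 1 - 4 * (1 / 4)^2)
  expect_equal(pc$role, "connector")   # Pi = 0.75 >= 0.62, Zi = 0
  # every leaf has a single link, so Pi = 1 - (1/1)^2 = 0
  expect_true(all(roles$Pi[roles$node != "c"] == 0))
})

test_that("nodes with all links inside their module have Pi = 0", {
  g <- two_cliques()
  part <- detect_modules(g)
  roles <- zi_pi(g, part)
  inner <- roles[!roles$node %in% c("n1", "n6"), ]
  expect_true(all(inner$Pi == 0))
})

test_that("role boundaries are inclusive and deterministic", {
  expect_equal(classify_role(2.5, 0.1), "module hub")
  expect_equal(classify_role(3.0, 0.1), "module hub")
  expect_equal(classify_role(1.0, 0.62), "connector")
  expect_equal(classify_role(2.5, 0.62), "network hub")
  expect_equal(classify_role(2.4999, 0.6199), "peripheral")
})

test_that("Zi is a z-score within modules of size >= 3", {
  for (s in 1:5) {
    g <- random_test_graph(14, p = 0.4, seed = 400 + s)
    part <- detect_modules(g)
    roles <- zi_pi(g, part)
    bz <- brute_zi_pi(adj_of(g), part$membership[igraph::V(g)$name])
    expect_equal(roles$Zi, bz$zi, tolerance = 1e-10)
    expect_equal(roles$Pi, bz$pi, tolerance = 1e-10)
    for (m in unique(roles$module)) {
      sub <- roles$Zi[roles$module == m]
      if (length(sub) >= 3 && sd(roles$within_degree[roles$module == m]) > 0) {
        expect_equal(mean(sub), 0, tolerance = 1e-10)
        expect_equal(sd(sub), 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("role assignment is invariant to node relabeling", {
  g <- two_cliques()
  part <- detect_modules(g)
  r1 <- zi_pi(g, part)
  perm <- sample(10)
  g2 <- igraph::permute(g, perm)
  part2 <- detect_modules(g2)
  r2 <- zi_pi(g2, part2)
  r2 <- r2[match(r1$node, r2$node), ]
  expect_equal(r1$Zi, r2$Zi, tolerance = 1e-12)
  expect_equal(r1$Pi, r2$Pi, tolerance = 1e-12)
  expect_equal(r1$role, r2$role)
})

test_that("critical species counts partition the non-peripheral nodes", {
  g <- two_cliques()
  roles <- zi_pi(g, detect_modules(g))
  counts <- count_critical_species(roles)
  expect_equal(sum(counts), sum(roles$role != "peripheral"))
  roles$role <- "peripheral"
  expect_equal(unname(count_critical_species(roles)), c(0L, 0L, 0L))
})

test_that("a planted hub is classified as a module hub", {
  # one clique-ish module with a dominant star center plus a second module
  g <- igraph::make_star(12, mode = "undirected", center = 1)
  g <- igraph::add_edges(g, c(2, 3, 4, 5, 6, 7))   # some periphery links
  h <- igraph::make_full_graph(5)
  g <- igraph::disjoint_union(g, h)
  g <- igraph::add_edges(g, c(2, 13))
  igraph::V(g)$name <- paste0("n", 1:17)
  part <- detect_modules(g)
  roles <- zi_pi(g, part)
  expect_equal(roles$role[roles$node == "n1"], "module hub")
})

test_that("module eigengenes summarize coherent modules", {
  # module of identical rows: first component carries all variance
  prof <- sin(1:10)
  m <- rbind(matrix(rep(prof, 6), 6, byrow = TRUE) + 0,
             matrix(rnorm(60), 6))
  rownames(m) <- paste0("O", 1:12)
  colnames(m) <- paste0("S", 1:10)
  part <- structure(list(membership = setNames(rep(1:2, each = 6), rownames(m)),
                         sizes = c(6L, 6L), modularity = NA_real_),
                    class = "module_partition")
  eig <- module_eigengene(part, m)
  expect_equal(unname(eig$variance_explained["1"]), 1, tolerance = 1e-10)
  z <- as.numeric(scale(prof))
  expect_equal(abs(cor(eig$eigengenes[, "M1"], z)), 1, tolerance = 1e-10)
  # sign convention: positively correlated with the module mean profile
  expect_gt(cor(eig$eigengenes[, "M1"], z), 0)
  expect_equal(sum(eig$eigengenes[, "M1"]^2), 1, tolerance = 1e-12)
})

test_that("two orthogonal half-modules split variance evenly", {
  a <- rep(c(1, -1), 5); b <- rep(c(1, 1, -1, -1), length.out = 10)
  m <- rbind(matrix(rep(a, 3), 3, byrow = TRUE),
             matrix(rep(b, 3), 3, byrow = TRUE))
  m <- m + matrix(rnorm(60, sd = 1e-6), 6)
  rownames(m) <- paste0("O", 1:6); colnames(m) <- paste0("S", 1:10)
  part <- structure(list(membership = setNames(rep(1L, 6), rownames(m)),
                         sizes = 6L, modularity = NA_real_),
                    class = "module_partition")
  eig <- module_eigengene(part, m)
  expect_equal(unname(eig$variance_explained["1"]), 0.5, tolerance = 1e-3)
})

test_that("modules at or below five nodes are excluded by default", {
  m <- matrix(rnorm(110), 11, 10,
              dimnames = list(paste0("O", 1:11), paste0("S", 1:10)))
  part <- structure(list(membership = setNames(c(rep(1L, 5), rep(2L, 6)), rownames(m)),
                         sizes = c(5L, 6L), modularity = NA_real_),
                    class = "module_partition")
  eig <- module_eigengene(part, m)
  expect_identical(colnames(eig$eigengenes), "M2")
})

test_that("eigengene hierarchy reflects pairwise correlation structure", {
  set.seed(6)
  e1 <- rnorm(10); e1 <- e1 / sqrt(sum(e1^2))
  E <- cbind(M1 = e1, M2 = e1, M3 = -e1)
  hc <- eigengene_hierarchy(E)
  expect_equal(min(hc$height), 0, tolerance = 1e-12)   # identical pair merges first
  expect_equal(max(hc$height), 2, tolerance = 1e-12)   # anti-correlated joins at 1-(-1)
  # three eigengenes with known correlations: check against manual average linkage
  set.seed(7)
  x <- rnorm(10); y <- rnorm(10); z2 <- 0.9 * x + 0.1 * rnorm(10)
  E2 <- cbind(A = x, B = z2, C = y)
  hc2 <- eigengene_hierarchy(E2)
  d <- 1 - cor(E2)
  expect_equal(hc2$height[1], min(d[upper.tri(d)]), tolerance = 1e-12)
  first_pair <- sort(hc2$merge[1, ])
  expect_equal(first_pair, c(-2, -1))  # A and B merge first
  # average linkage height of the final merge
  expect_equal(hc2$height[2], mean(c(d["A", "C"], d["B", "C"])), tolerance = 1e-12)
  # newick serialization round-trips leaf names
  f <- withr::local_tempfile(fileext = ".nwk")
  eigengene_hierarchy(E2, newick_path = f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})

test_that("planted modules are recovered with high adjusted Rand index", {
  ok <- sapply(1:10, function(s) {
    sim <- simulate_community(seed = s)
    S <- pearson_similarity(log_transform(sim$otu))
    g <- build_network(S, 0.8)
    part <- detect_modules(g)
    ari(part$membership, sim$truth$module[names(part$membership)])
  })
  expect_gte(sum(ok >= 0.8), 8)
})
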