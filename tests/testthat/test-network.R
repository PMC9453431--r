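test_that("fold changes are anchored to the control mean", {
  design <- make_design(c(0, 5), n_replicates = 2)
  m <- matrix(c(10, 10, 30, 50), nrow = 1,
              dimnames = list("g1", design$sample_id))
  fc <- fold_change_matrix(m, design, pseudocount = 1)
  expect_equal(unname(fc[1, 1:2]), c(0, 0))          # controls at their mean
  expect_equal(unname(fc[1, 3]), log2(31 / 11))
  # pseudocount -> 0 limit: x = 3 x control mean gives log2 3
  fc0 <- fold_change_matrix(m, design, pseudocount = 1e-9)
  expect_equal(unname(fc0[1, 3]), log2(3), tolerance = 1e-6)
  expect_error(fold_change_matrix(m, make_design(c(0, 5), 2)[c(1, 3, 4), ]),
               ">= 2 control")
})

test_that("fold changes are invariant to depth after normalization", {
  ds <- simulate_experiment(seed = 9, n_genes = 80, n_ahr = 10,
                            n_sensitive = 5, n_high = 5)
  cts <- filter_low_counts(ds$counts)
  f1 <- fold_change_matrix(normalize_counts(cts), ds$design)
  doubled <- cts * 2L
  f2 <- fold_change_matrix(normalize_counts(doubled) / 2, ds$design)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("CV selection keeps varying genes with deterministic ties", {
  design <- make_design(c(0, 5), n_replicates = 2)
  fc <- rbind(flat = rep(0, 4), wiggly = c(0, 0, 2, -2))
  colnames(fc) <- design$sample_id
  expect_identical(rownames(select_top_cv(fc, 1)), "wiggly")
  expect_identical(dim(select_top_cv(fc, 2)), dim(fc))
  tie <- rbind(b_gene = c(0, 1, 0, 1), a_gene = c(0, 1, 0, 1))
  expect_identical(rownames(select_top_cv(tie, 1)), "a_gene")
  expect_error(select_top_cv(fc, 5), "n_top_cv")
})

test_that("planted-module genes rank high in CV on synthetic data", {
  ds <- simulate_experiment(seed = 10, n_genes = 300, n_ahr = 30,
                            n_sensitive = 30, n_high = 30)
  cts <- filter_low_counts(ds$counts)
  fc <- fold_change_matrix(normalize_counts(cts), ds$design)
  kept <- rownames(select_top_cv(fc, nrow(fc) %/% 10))
  ahr <- intersect(ds$truths$gene_id[ds$truths$klass == "ahr_module"],
                   rownames(fc))
  expect_gte(mean(ahr %in% kept), 0.8)
})

test_that("tree-ensemble weights are normalized, deterministic and signal-bearing", {
  set.seed(20)
  n <- 30
  base <- rnorm(n)
  fc <- rbind(pairA = base + rnorm(n, 0, 0.05),
              pairB = base + rnorm(n, 0, 0.05),
              matrix(rnorm(28 * n), 28,
                     dimnames = list(sprintf("noise%02d", 1:28), NULL)))
  colnames(fc) <- sprintf("s%02d", 1:n)
  cfg <- network_config(n_trees = 150, seed = 3)
  W <- infer_network(fc, cfg)
  cs <- colSums(W)
  expect_true(all(abs(cs - 1) < 1e-9 | cs == 0))
  expect_true(all(diag(W) == 0))
  # the correlated pair dominates each other's incoming importance
  expect_identical(rownames(W)[which.max(W[, "pairA"])], "pairB")
  expect_identical(rownames(W)[which.max(W[, "pairB"])], "pairA")
  expect_identical(W, infer_network(fc, cfg))
  # permuting the sample order of all rows together changes nothing
  perm <- sample(n)
  expect_identical(W, infer_network(fc[, perm], cfg))
  # a zero-variance target receives no incoming weight
  fc2 <- rbind(fc, flat = rep(1, n))
  expect_equal(sum(infer_network(fc2, cfg)[, "flat"]), 0)
})

test_that("thresholding is strictly greater-than and tracks isolates", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W["a", "b"] <- 0.0086; W["b", "a"] <- 0.00861; W["a", "c"] <- 0.002
  net <- threshold_network(W, network_config())
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$source, "b")
  expect_identical(net$isolated, "c")
  none <- threshold_network(W, network_config(edge_cutoff = 1))
  expect_equal(nrow(none$edges), 0L)
  all_pos <- threshold_network(W, network_config(edge_cutoff = 1e-9))
  expect_equal(nrow(all_pos$edges), 3L)
})

test_that("greedy modularity separates two weakly joined cliques", {
  ids <- c(sprintf("x%d", 1:5), sprintf("y%d", 1:5))
  W <- matrix(0, 10, 10, dimnames = list(ids, ids))
  W[1:5, 1:5] <- 0.5; W[6:10, 6:10] <- 0.5; diag(W) <- 0
  W["x1", "y1"] <- 0.02
  net <- detect_modules(threshold_network(W, network_config(edge_cutoff = 0.01)))
  expect_equal(length(unique(net$modules)), 2L)
  expect_equal(length(unique(net$modules[sprintf("x%d", 1:5)])), 1L)
  expect_equal(length(unique(net$modules[sprintf("y%d", 1:5)])), 1L)
  expect_gt(net$modularity, 0)
  empty <- threshold_network(W, network_config(edge_cutoff = 1))
  expect_error(detect_modules(empty), "no edges")
})

test_that("centralities match direct formulas and brute-force enumeration", {
  ids <- c("hub", "l1", "l2", "l3", "l4")
  W <- matrix(0, 5, 5, dimnames = list(ids, ids))
  W["hub", c("l1", "l2", "l3", "l4")] <- 0.5
  star <- centralities(threshold_network(W, network_config(edge_cutoff = 0.1)))
  cs <- star$centrality
  expect_equal(cs$degree[cs$gene_id == "hub"], 4L)
  expect_equal(cs$betweenness[cs$gene_id == "hub"], 1)
  expect_equal(cs$betweenness[cs$gene_id == "l1"], 0)

  ids <- c("A", "B", "C")
  P <- matrix(0, 3, 3, dimnames = list(ids, ids))
  P["A", "B"] <- 0.5; P["B", "C"] <- 0.5
  path <- centralities(threshold_network(P, network_config(edge_cutoff = 0.1)))
  expect_equal(path$centrality$betweenness[path$centrality$gene_id == "B"], 1)
  expect_equal(path$centrality$degree[path$centrality$gene_id == "B"], 2L)

  set.seed(30)
  for (trial in 1:5) {
    n <- sample(6:12, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.45)
    adj <- adj + t(adj)
    if (any(rowSums(adj) == 0)) next
    ids <- sprintf("n%02d", 1:n)
    W <- adj * 0.5; dimnames(W) <- list(ids, ids)
    net <- centralities(threshold_network(W, network_config(edge_cutoff = 0.1)))
    got <- net$centrality[match(ids, net$centrality$gene_id), ]
    expect_equal(got$degree, rowSums(adj > 0), ignore_attr = TRUE)
    expect_equal(got$betweenness, brute_betweenness(adj), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("edge arithmetic reproduces the printed network bookkeeping", {
  expect_equal(possible_edge_count(178), 31506)
  expect_equal(possible_edge_count(2), 2)
  expect_equal(possible_edge_count(8000), 63992000)
  expect_error(possible_edge_count(1), "at least 2")
  expect_equal(retained_fraction(4678, 8000), 0.007)
  expect_equal(retained_fraction(possible_edge_count(50), 50), 100)
  expect_equal(retained_fraction(0, 50), 0)
  expect_error(retained_fraction(10, 3), "more edges")
})

test_that("a planted co-expressed module is recovered from counts", {
  ds <- simulate_experiment(seed = 3, n_genes = 200, n_ahr = 25,
                            n_sensitive = 20, n_high = 20)
  cts <- filter_low_counts(ds$counts)
  cfg <- network_config(n_top_cv = 100, n_trees = 150, seed = 9)
  net <- build_network(cts, ds$design, cfg)
  truth_mod <- ds$truths$gene_id[ds$truths$klass == "ahr_module"]
  inmod <- net$modules[names(net$modules) %in% truth_mod]
  best <- as.integer(names(which.max(table(inmod))))
  det <- module_genes(net, best)
  jac <- length(intersect(det, truth_mod)) / length(union(det, truth_mod))
  expect_gte(jac, 0.6)
  # modularity of the partition beats all-singletons (which scores <= 0)
  expect_gt(net$modularity, 0)
})
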