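test_that("zero-fraction filter applies the at-least-25% rule exactly", {
  m <- matrix(5L, nrow = 3, ncol = 32,
              dimnames = list(c("zeros8", "zeros7", "dense"), NULL))
  m["zeros8", 1:8] <- 0L
  m["zeros7", 1:7] <- 0L
  out <- filter_low_counts(m, dge_config())
  expect_identical(rownames(out), c("zeros7", "dense"))
  allzero <- matrix(0L, 1, 32, dimnames = list("allzero", NULL))
  expect_warning(filter_low_counts(allzero), "all genes removed")
})

test_that("case-colliding gene names are averaged and lowercased", {
  m <- matrix(c(2, 4, 7, 1, 2, 6), nrow = 3,
              dimnames = list(c("Cyp1a", "cyp1a", "sox9b"), c("s1", "s2")))
  out <- aggregate_case_collisions(m)
  expect_setequal(rownames(out), c("cyp1a", "sox9b"))
  expect_equal(out["cyp1a", ], c(s1 = 3, s2 = 1.5))
  expect_equal(out["sox9b", ], c(s1 = 7, s2 = 6))
  three <- matrix(c(1, 2, 6), 3, 1, dimnames = list(c("A", "a", "A "), "s"))
  rownames(three) <- c("abc", "Abc", "ABC")
  expect_equal(unname(aggregate_case_collisions(three)[1, 1]), 3)
  expect_identical(aggregate_case_collisions(m[3, , drop = FALSE]),
                   m[3, , drop = FALSE])
})

test_that("size factors follow the median-of-ratios closed forms", {
  m <- matrix(rpois(50, 40) + 1, nrow = 25, ncol = 2)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3))
  doubled <- cbind(m[, 1], 2 * m[, 1])
  expect_equal(unname(size_factors(doubled)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)
  allz <- matrix(0L, 4, 3); allz[1, 1] <- 5L
  expect_error(size_factors(allz), "filter")
})

test_that("BH adjustment matches brute force and the reference routine", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("NB Wald recovers a strong induced gene and respects nulls", {
  design <- std_design()
  tr <- make_gene_truths(200, 0, 0, 0, baseline_range = c(100, 1000), seed = 21)
  # plant a cyp1a-like induced gene
  tr$emax[1] <- 9.6; tr$ec50[1] <- 4; tr$hill_n[1] <- 1.5
  tr$baseline_mean[1] <- 500; tr$dispersion[1] <- 0.02
  tr$klass[1] <- "ahr_module"
  cts <- filter_low_counts(generate_counts(design, tr, seed = 22,
                                           module_rho = 0))
  res <- nb_wald(cts, design)
  top <- res[res$gene_id == tr$gene_id[1] & res$concentration == 50, ]
  expect_lt(top$padj, 0.05)
  truth_lfc <- hill_log2fc(50, 9.6, 4, 1.5)
  expect_lt(abs(top$log2fc - truth_lfc), 0.5)
  expect_true(all(res$padj >= res$p - 1e-12))
  expect_identical(res$is_deg, res$padj < 0.05)
  # a constant gene never moves
  cts2 <- rbind(cts, flatgene = rep(100L, ncol(cts)))
  res2 <- nb_wald(cts2, design)
  expect_true(all(abs(res2$log2fc[res2$gene_id == "flatgene"]) < 0.2))
})

test_that("DEG counts increase with simulated effect size", {
  design <- std_design()
  ndeg <- vapply(c(0, 2, 6), function(emax) {
    tr <- make_gene_truths(150, 0, 0, 0, baseline_range = c(100, 800),
                           seed = 31)
    tr$emax[1:40] <- emax; tr$ec50[1:40] <- 5; tr$hill_n[1:40] <- 2
    cts <- filter_low_counts(generate_counts(design, tr, seed = 32,
                                             module_rho = 0))
    sum(nb_wald(cts, design)$is_deg, na.rm = TRUE)
  }, numeric(1))
  expect_true(ndeg[1] <= ndeg[2] && ndeg[2] <= ndeg[3])
  expect_gt(ndeg[3], ndeg[1])
})

test_that("the teratogenic/non-teratogenic partition is a true partition", {
  res <- data.frame(
    gene_id = c("A", "B", "B", "C"),
    concentration = c(8, 8, 20, 20),
    log2fc = 1, se = 1, p = 0.001, padj = 0.001, is_deg = TRUE)
  extra <- data.frame(gene_id = "D", concentration = 50, log2fc = 0, se = 1,
                      p = 0.9, padj = 0.9, is_deg = FALSE)
  part <- deg_partition(rbind(res, extra), teratogenic_concs = c(20, 50))
  expect_identical(part$nonteratogenic_only, "A")
  expect_identical(part$overlap, "B")
  expect_identical(part$teratogenic_only, "C")
  all3 <- c(part$nonteratogenic_only, part$overlap, part$teratogenic_only)
  expect_false(anyDuplicated(all3) > 0)
  none <- deg_partition(extra, teratogenic_concs = 50)
  expect_equal(lengths(none), c(nonteratogenic_only = 0L, overlap = 0L,
                                teratogenic_only = 0L))
  expect_error(deg_partition(res, teratogenic_concs = 99), "subset")
})

test_that("gene classes land in the expected partition compartments", {
  ds <- simulate_experiment(seed = 6, n_genes = 400, n_ahr = 40,
                            n_sensitive = 40, n_high = 40)
  cts <- filter_low_counts(ds$counts)
  res <- nb_wald(cts, ds$design)
  part <- deg_partition(res, teratogenic_concs = c(20, 50))
  kl <- setNames(ds$truths$klass, ds$truths$gene_id)
  sens_called <- intersect(ds$truths$gene_id[ds$truths$klass == "sensitive"],
                           unlist(part))
  high_called <- intersect(ds$truths$gene_id[ds$truths$klass == "high_only"],
                           unlist(part))
  expect_gte(mean(sens_called %in% c(part$nonteratogenic_only, part$overlap)),
             0.8)
  expect_gte(mean(high_called %in% part$teratogenic_only), 0.8)
})
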