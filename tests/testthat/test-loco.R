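make_loco_fixture <- function(seed = 3, n_genes = 90, n_ahr = 12) {
  ds <- simulate_experiment(seed = seed, n_genes = n_genes, n_ahr = n_ahr,
                            n_sensitive = 0, n_high = 0)
  cts <- filter_low_counts(ds$counts)
  fc <- fold_change_matrix(normalize_counts(cts), ds$design)
  mod <- intersect(ds$truths$gene_id[ds$truths$klass == "ahr_module"],
                   rownames(fc))
  list(ds = ds, fc = fc, mod = mod)
}

test_that("LOCO reproduces the full network and covers every concentration", {
  fx <- make_loco_fixture()
  cfg <- network_config(n_trees = 100, seed = 5)
  loco <- loco_networks(fx$fc, fx$ds$design, fx$mod, cfg)
  expect_equal(length(loco$reduced), 7L)
  expect_identical(sort(as.numeric(names(loco$reduced))),
                   c(0.205, 0.512, 1.28, 3.2, 8, 20, 50))
  W <- infer_network(fx$fc, cfg)
  expect_identical(loco$full, W[sort(fx$mod), sort(fx$mod)])
  expect_error(loco_networks(fx$fc, fx$ds$design, fx$mod, cfg, leave_out = 0),
               "control")
  m <- length(fx$mod)
  rt <- edge_weight_ratios(loco)
  expect_equal(nrow(rt), m * (m - 1))
})

test_that("ratio cells follow the full/reduced conventions", {
  genes <- c("a", "b", "c")
  full <- matrix(c(0, 0.02, 0, 0.01, 0, 0, 0, 0.03, 0), 3, byrow = TRUE,
                 dimnames = list(genes, genes))
  red <- full / 2; red["a", "b"] <- 0; red["c", "b"] <- 0.03
  loco <- list(full = full, reduced = list(`8` = red, `20` = full))
  rt <- edge_weight_ratios(loco)
  get <- function(s, t, col) rt[rt$source == s & rt$target == t, col]
  expect_equal(get("a", "b", "ratio_8"), Inf)       # reduced hit zero
  expect_equal(get("b", "a", "ratio_8"), 2)
  expect_equal(get("c", "b", "ratio_8"), 1)         # unchanged
  expect_equal(get("a", "c", "ratio_8"), 1)         # both zero
  expect_true(all(rt$ratio_20 == 1))
})

test_that("edge classification encodes consistent and progressive loss", {
  mk_row <- function(id, ratios) {
    r <- as.data.frame(as.list(ratios))
    names(r) <- paste0("ratio_", c(0.512, 1.28, 3.2, 8, 20, 50, 100))
    cbind(data.frame(source = id, target = "t", w_full = 0.01), r)
  }
  rt <- rbind(mk_row("asc", c(1.1, 1.2, 1.3, 1.5, 1.8, 2.0, 2.4)),
              mk_row("flat", rep(1, 7)),
              mk_row("high_notmono", c(1.5, 1.2, 1.3, 1.5, 1.8, 2.0, 2.4)),
              mk_row("inf_cell", c(1.1, 1.2, 1.3, 1.5, 1.8, 2.0, Inf)))
  class(rt) <- c("loco_ratio_table", "data.frame")
  cls <- classify_edges(rt)
  g <- function(id) cls[cls$source == id, ]
  expect_true(g("asc")$consistently_higher && g("asc")$progressive_loss)
  expect_false(g("flat")$consistently_higher || g("flat")$progressive_loss)
  expect_true(g("high_notmono")$consistently_higher)
  expect_false(g("high_notmono")$progressive_loss)
  expect_true(g("inf_cell")$consistently_higher)   # eligible but flagged
  expect_true(g("inf_cell")$has_undefined)
  expect_false(g("inf_cell")$progressive_loss)
  expect_true(all(cls$consistently_higher[cls$progressive_loss]))
  # tau relaxation admits the near-monotone profile
  cls2 <- classify_edges(rt, tau_threshold = 0.5)
  expect_true(cls2[cls2$source == "high_notmono", "progressive_loss"])
})

test_that("planted-module edges are enriched for concentration responsiveness", {
  higher_mod <- 0; n_mod <- 0; higher_null <- 0; n_null <- 0
  for (s in 1:3) {
    fx <- make_loco_fixture(seed = s, n_genes = 40, n_ahr = 10)
    nulls <- head(setdiff(rownames(fx$fc), fx$mod), 10)
    cfg <- network_config(n_trees = 100, seed = s)
    loco <- loco_networks(fx$fc, fx$ds$design, c(fx$mod, nulls), cfg)
    cls <- classify_edges(edge_weight_ratios(loco))
    inmod <- cls$source %in% fx$mod & cls$target %in% fx$mod
    innull <- cls$source %in% nulls & cls$target %in% nulls
    higher_mod <- higher_mod + sum(cls$consistently_higher[inmod])
    n_mod <- n_mod + sum(inmod)
    higher_null <- higher_null + sum(cls$consistently_higher[innull])
    n_null <- n_null + sum(innull)
  }
  tab <- matrix(c(higher_mod, n_mod - higher_mod,
                  higher_null, n_null - higher_null), 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = "greater")
  expect_gt(ft$estimate, 1)
  expect_lt(ft$p.value, 0.05)
})
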