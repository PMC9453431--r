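cfg_fast <- bmc_config(n_permutations = 199, n_boot = 60, seed = 4)

test_that("Williams trend test hits its boundary cases", {
  design <- std_design()
  flat <- williams_trend(rep(3.2, 32), design, cfg_fast)
  expect_equal(flat$p, 1); expect_false(flat$passes)

  x <- rep(1:8, each = 4) + rnorm(32, 0, 0.005)
  up <- williams_trend(x, design, cfg_fast, seed = 1)
  expect_lte(up$p, 2 / (cfg_fast$n_permutations + 1))
  expect_identical(up$direction, "up")
  down <- williams_trend(-x, design, cfg_fast, seed = 1)
  expect_identical(down$direction, "down")
  expect_equal(abs(down$statistic), abs(up$statistic))
  expect_equal(down$p, up$p)
  expect_error(williams_trend(1:8, make_design(c(0, 5), 4), cfg_fast), ">= 3")
})

test_that("each model family reproduces data generated from itself", {
  dose <- rep(dilution_series(50, 0.4, 7), each = 4)
  gen <- list(
    linear = function(d) 1 + 0.2 * d,
    poly2 = function(d) 1 + 0.3 * d - 0.004 * d^2,
    power = function(d) 0.5 + 0.05 * d^1.6,
    hill = function(d) 1 + hill_log2fc(d, 8, 5, 2),
    exp4 = function(d) 2 * (3 - 2 * exp(-0.2 * d))
  )
  set.seed(10)
  for (fam in names(gen)) {
    y <- gen[[fam]](dose) + rnorm(length(dose), 0, 0.05)
    f <- fit_family(dose, y, fam, bmc_config())
    expect_true(is.finite(f$aic))
    expect_lt(max(abs(predict(f) - gen[[fam]](dose))), 0.2)
    expect_gt(f$gof_p, 0.01)
  }
  # noiseless linear: essentially exact
  f <- fit_family(dose, 2 + 0.3 * dose, "linear", bmc_config())
  expect_lt(f$sigma, 1e-8)
})

test_that("hill parameters are recovered within 15% at the 8x4 design", {
  dose <- rep(dilution_series(50, 0.4, 7), each = 4)
  set.seed(12)
  y <- 1 + hill_log2fc(dose, 8, 5, 2) + rnorm(length(dose), 0, 0.1)
  f <- fit_family(dose, y, "hill", bmc_config())
  expect_lt(abs(f$params[["v"]] / 8 - 1), 0.15)
  expect_lt(abs(f$params[["k"]] / 5 - 1), 0.15)
  expect_lt(abs(f$params[["n"]] / 2 - 1), 0.15)
})

test_that("AIC penalizes overparameterization and obeys the tie order", {
  dose <- rep(dilution_series(50, 0.4, 7), each = 4)
  set.seed(13)
  y <- 2 + 0.3 * dose + rnorm(length(dose), 0, 0.5)
  cfg <- bmc_config()
  expect_lt(fit_family(dose, y, "linear", cfg)$aic,
            fit_family(dose, y, "poly2", cfg)$aic)
})

test_that("model selection applies the Hill-k flag rule", {
  mk <- function(family, aic, k = NULL, gof = 0.5) {
    structure(list(family = family, aic = aic, gof_p = gof,
                   params = if (!is.null(k)) c(g = 0, v = 1, k = k, n = 1)),
              class = "drc_fit")
  }
  cfg <- bmc_config()
  # flagged hill replaced by next adequate model
  sel <- select_model(list(mk("hill", 5, k = 0.05), mk("linear", 8)),
                      lowest_positive_dose = 0.205, cfg)
  expect_identical(sel$family, "linear")
  # k above one-third of the lowest positive dose: not flagged
  sel <- select_model(list(mk("hill", 5, k = 0.3), mk("linear", 8)), 0.205, cfg)
  expect_identical(sel$family, "hill")
  expect_false(sel$hill_flagged)
  # flagged hill retained when no alternative fits adequately
  sel <- select_model(list(mk("hill", 5, k = 0.05), mk("linear", 8, gof = 0.001)),
                      0.205, cfg)
  expect_identical(sel$family, "hill")
  expect_true(sel$hill_flagged)
  # plain AIC choice
  sel <- select_model(list(mk("linear", 10), mk("poly2", 12)), 0.205, cfg)
  expect_identical(sel$family, "linear")
  # nothing converged
  sel <- select_model(list(mk("linear", Inf), mk("poly2", Inf)), 0.205, cfg)
  expect_true(sel$selection_undefined)
})

test_that("BMC solves the linear closed form and flags flat fits", {
  dose <- rep(dilution_series(50, 0.4, 7), each = 4)
  cfg <- bmc_config()
  f <- compute_bmc(fit_family(dose, 1 + 2 * dose, "linear", cfg), 1, cfg, 50,
                   n_boot = 0)
  expect_equal(f$bmc, 1.349 / 2, tolerance = 1e-6)
  set.seed(14)
  flat <- compute_bmc(fit_family(dose, rnorm(length(dose), 5, 0.01), "linear",
                                 cfg), 1, cfg, 50, n_boot = 0)
  expect_true(flat$removed_above_max)
  expect_true(is.na(flat$bmc))
})

test_that("root-finding agrees with an exhaustive grid scan", {
  dose <- rep(dilution_series(50, 0.4, 7), each = 4)
  cfg <- bmc_config()
  set.seed(15)
  y <- 1 + hill_log2fc(dose, 8, 5, 2) + rnorm(length(dose), 0, 0.1)
  sel <- select_model(fit_all_families(dose, y, cfg), 0.205, cfg)
  sel <- compute_bmc(sel, sel$sigma, cfg, 50, n_boot = 0)
  expect_lt(sel$bmc, 5)  # well under the half-max concentration
  g0 <- predict_drc(sel$family, sel$params, 0)
  grid <- seq(0, 50, by = 50 / 1e5)
  scan <- grid[which(abs(predict_drc(sel$family, sel$params, grid) - g0) >=
                       sel$bmr)[1]]
  expect_lt(abs(scan - sel$bmc) / scan, 0.01)
})

test_that("bootstrap interval brackets the BMC and covers truth reasonably", {
  dose <- rep(dilution_series(50, 0.4, 7), each = 4)
  cfg <- bmc_config()
  truth_bmc <- local({  # true curve crossing at sigma = 0.1
    g <- function(d) hill_log2fc(d, 8, 5, 2) - 1.349 * 0.1
    uniroot(g, c(0.01, 50))$root
  })
  cover <- 0; runs <- 8
  for (s in 1:runs) {
    set.seed(100 + s)
    y <- 1 + hill_log2fc(dose, 8, 5, 2) + rnorm(length(dose), 0, 0.1)
    sel <- select_model(fit_all_families(dose, y, cfg), 0.205, cfg)
    sel <- compute_bmc(sel, sel$sigma, cfg, 50, n_boot = 100, seed = s)
    expect_lte(sel$bmdl, sel$bmc)
    expect_lte(sel$bmc, sel$bmdu)
    if (!is.na(sel$bmdl) && sel$bmdl <= truth_bmc && truth_bmc <= sel$bmdu)
      cover <- cover + 1
  }
  expect_gte(cover / runs, 0.75)
})

test_that("negating responses leaves selection and BMC unchanged", {
  dose <- rep(dilution_series(50, 0.4, 7), each = 4)
  cfg <- bmc_config()
  set.seed(16)
  y <- 1 + hill_log2fc(dose, 6, 8, 3) + rnorm(length(dose), 0, 0.15)
  a <- select_model(fit_all_families(dose, y, cfg), 0.205, cfg)
  b <- select_model(fit_all_families(dose, -y, cfg), 0.205, cfg)
  expect_identical(a$family, b$family)
  expect_equal(a$aic, b$aic, tolerance = 1e-6)
  a <- compute_bmc(a, a$sigma, cfg, 50, n_boot = 0)
  b <- compute_bmc(b, b$sigma, cfg, 50, n_boot = 0)
  expect_equal(a$bmc, b$bmc, tolerance = 1e-4)
})

test_that("the gated pipeline never fits genes failing the trend test", {
  design <- std_design()
  set.seed(17)
  expr <- rbind(
    responsive = 5 + hill_log2fc(design$concentration, 4, 5, 2) +
      rnorm(32, 0, 0.1),
    null1 = rnorm(32, 5, 0.3), null2 = rnorm(32, 5, 0.3),
    null3 = rnorm(32, 5, 0.3))
  out <- bmc_pipeline(expr, design, cfg_fast, n_boot = 30)
  tab <- out$table
  expect_true(tab$passes[tab$gene_id == "responsive"])
  expect_true(all(is.na(tab$bmc[!tab$passes])))
  expect_identical(names(out$records), tab$gene_id[tab$passes])
  expect_output(print(out), "trend gate")
})

test_that("gene-set medians summarize only modeled, in-range genes", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    bmc = c(2, 5, 8, NA, 1),
                    bmdl = c(1, 3, 6, NA, 0.5),
                    bmdu = c(3, 7, 10, NA, 2),
                    removed_above_max = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- geneset_bmc(tab, c("a", "b", "c", "d", "e"))
  expect_equal(out$median_bmc, 5)
  expect_equal(out$n_modeled, 3L)
  expect_warning(out2 <- geneset_bmc(tab, "d"), "no gene")
  expect_true(is.na(out2$median_bmc))
})
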