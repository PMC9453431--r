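#' phenanchor: concentration-response transcriptomics with phenotypic anchoring
#'
#' Pipeline for analysing an 8-point concentration-series RNA-seq experiment
#' against a morphological screen: differential expression, trend-gated
#' benchmark concentration (BMC) modeling, co-expression network inference,
#' leave-one-concentration-out network perturbation, and anchoring of
#' transcriptomic BMCs to a phenotype dose-response.
#'
#' @importFrom stats aggregate approx ave coef cor dbinom dnbinom dist
#'   cutree hclust lm lowess median optim optimize pf phyper plogis pnorm
#'   pt predict qchisq quantile rbinom rnbinom rnorm runif sd setNames
#'   trigamma uniroot var logLik
#' @importFrom utils head read.delim write.table
#' @keywords internal
"_PACKAGE"

#' Geometric dilution series with a zero control
#'
#' Builds the exposure series used throughout: a top concentration scaled
#' down repeatedly by a constant factor, rounded to significant figures,
#' with the 0 (vehicle control) concentration prepended.
#'
#' @param top Highest concentration (µM), positive.
#' @param factor Dilution factor, strictly between 0 and 1.
#' @param n_levels Number of non-zero levels (>= 1).
#' @param sig_figs Significant figures for rounding (default 3).
#' @return Ascending numeric vector of length `n_levels + 1`, starting at 0.
#' @examples
#' dilution_series(50, 0.4, 7) # 0, 0.205, 0.512, 1.28, 3.2, 8, 20, 50
#' @export
dilution_series <- function(top, factor, n_levels, sig_figs = 3) {
  if (!is.numeric(top) || length(top) != 1L || top <= 0)
    stop("`top` must be a single positive concentration")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor >= 1)
    stop("`factor` must lie strictly in (0, 1)")
  if (n_levels < 1) stop("`n_levels` must be >= 1")
  concs <- signif(top * factor^((n_levels - 1):0), sig_figs)
  out <- c(0, concs)
  if (any(diff(out) <= 0))
    stop("rounded series is not strictly increasing; increase `sig_figs`")
  out
}

#' Hill-shaped log2 fold change at a concentration
#'
#' Ground-truth response curve of the generator:
#' `emax * d^n / (ec50^n + d^n)`, zero at `d = 0`.
#'
#' @param d Concentration(s), µM, non-negative.
#' @param emax Asymptotic log2 fold change (sign gives direction).
#' @param ec50 Concentration of half-maximal response, µM.
#' @param hill_n Hill coefficient (> 0).
#' @return Numeric vector of log2 fold changes.
#' @export
hill_log2fc <- function(d, emax, ec50, hill_n) {
  stopifnot(all(d >= 0), ec50 > 0, hill_n > 0)
  dn <- d^hill_n
  out <- emax * dn / (ec50^hill_n + dn)
  out[d == 0] <- 0
  out
}

#' Ground-truth gene table for the synthetic generator
#'
#' Four gene classes mimic the structure the analysis assumes: a co-regulated
#' xenobiotic-response ("AHR-like") module whose half-maximal concentrations
#' sit near the phenotype threshold, sensitive genes responding well below it,
#' genes responding only at the top (teratogenic) concentrations, and null
#' genes. Dispersion is the NB alpha with variance `mu + alpha * mu^2`.
#'
#' @param n_genes Total genes (default 2000).
#' @param n_ahr,n_sensitive,n_high Class sizes (defaults 100 each; the
#'   remainder are null genes).
#' @param baseline_range Range of baseline mean counts, sampled log-uniformly.
#' @param dispersion_range Range of NB dispersion alpha, sampled log-uniformly.
#' @param seed Integer seed.
#' @return data.frame with one row per gene: `gene_id`, `klass`, `emax`,
#'   `ec50`, `hill_n`, `baseline_mean`, `dispersion`, `module_id`.
#' @export
make_gene_truths <- function(n_genes = 2000, n_ahr = 100, n_sensitive = 100,
                             n_high = 100, baseline_range = c(20, 2000),
                             dispersion_range = c(0.005, 0.5), seed = 1) {
  n_null <- n_genes - n_ahr - n_sensitive - n_high
  if (n_null < 0) stop("class sizes exceed `n_genes`")
  set.seed(seed)
  klass <- rep(c("ahr_module", "sensitive", "high_only", "null"),
               c(n_ahr, n_sensitive, n_high, n_null))
  n <- length(klass)
  gene_id <- sprintf("g%05d_%s", seq_len(n), klass)
  emax <- numeric(n)
  ec50 <- rep(1, n)
  hill_n <- rep(1, n)
  i <- klass == "ahr_module"
  # induced battery, all up; steep curves with half-max near 10 uM place the
  # expression benchmark concentrations near the teratogenicity threshold
  emax[i] <- runif(sum(i), 3, 10)
  ec50[i] <- runif(sum(i), 8, 12)
  hill_n[i] <- runif(sum(i), 3, 5)
  i <- klass == "sensitive"
  emax[i] <- runif(sum(i), 2, 6) * sample(c(-1, 1), sum(i), replace = TRUE)
  ec50[i] <- runif(sum(i), 0.2, 0.8)
  hill_n[i] <- runif(sum(i), 1, 2)
  i <- klass == "high_only"
  emax[i] <- runif(sum(i), 3, 8) * sample(c(-1, 1), sum(i), replace = TRUE)
  ec50[i] <- runif(sum(i), 30, 60)
  hill_n[i] <- runif(sum(i), 3, 6)
  data.frame(
    gene_id = gene_id, klass = klass, emax = emax, ec50 = ec50,
    hill_n = hill_n,
    baseline_mean = exp(runif(n, log(baseline_range[1]), log(baseline_range[2]))),
    dispersion = exp(runif(n, log(dispersion_range[1]), log(dispersion_range[2]))),
    module_id = ifelse(klass == "ahr_module", 1L, NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Experiment design for a replicated concentration series
#'
#' @param concentrations Concentration per level (µM); must contain 0 exactly
#'   once (the control).
#' @param n_replicates Replicate pools per concentration (default 4).
#' @return data.frame with `sample_id`, `concentration`, `replicate`,
#'   `is_control`.
#' @export
make_design <- function(concentrations = dilution_series(50, 0.4, 7),
                        n_replicates = 4) {
  if (sum(concentrations == 0) != 1L)
    stop("`concentrations` must contain the control concentration 0 exactly once")
  if (n_replicates < 2) stop("each concentration needs >= 2 replicates")
  concentrations <- sort(concentrations)
  d <- expand.grid(replicate = seq_len(n_replicates),
                   concentration = concentrations,
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[, c("concentration", "replicate")]
  d$sample_id <- sprintf("c%s_r%d", sub("\\.", "p", format(d$concentration, trim = TRUE)),
                         d$replicate)
  d$is_control <- d$concentration == 0
  rownames(d) <- NULL
  d[, c("sample_id", "concentration", "replicate", "is_control")]
}

#' Simulate a negative-binomial count matrix from gene truths
#'
#' For gene g and sample s at concentration d, counts are drawn NB with mean
#' `baseline_mean * 2^(hill_log2fc(d) + b)` where `b` is a latent per-sample
#' deviate shared by all genes of a module (inducing within-module
#' co-expression of strength roughly `module_rho`) and 0 otherwise; NB
#' variance is `mu + dispersion * mu^2`.
#'
#' @param design Output of [make_design()].
#' @param truths Output of [make_gene_truths()].
#' @param seed Integer seed (fixed seed gives bit-identical output).
#' @param module_rho Target within-module log-expression correlation in
#'   `[0, 1)` (default 0.6).
#' @return Integer matrix, genes x samples, with dimnames.
#' @export
generate_counts <- function(design, truths, seed = 1, module_rho = 0.6) {
  stopifnot(nrow(truths) >= 1, module_rho >= 0, module_rho < 1)
  set.seed(seed)
  n_g <- nrow(truths); n_s <- nrow(design)
  lfc <- vapply(seq_len(n_g), function(g)
    hill_log2fc(design$concentration, truths$emax[g], truths$ec50[g],
                truths$hill_n[g]), numeric(n_s))
  log2mu <- t(lfc) + log2(truths$baseline_mean)  # genes x samples
  for (m in unique(truths$module_id[!is.na(truths$module_id)])) {
    gi <- which(!is.na(truths$module_id) & truths$module_id == m)
    if (module_rho > 0 && length(gi) > 1) {
      # shared latent deviate scaled so var_b / (var_b + v_nb) ~ module_rho,
      # with v_nb the class-average NB variance on the log2 scale
      v_nb <- mean(1 / truths$baseline_mean[gi] + truths$dispersion[gi]) / log(2)^2
      sd_b <- sqrt(module_rho / (1 - module_rho) * v_nb)
      b <- rnorm(n_s, 0, sd_b)
      log2mu[gi, ] <- sweep(log2mu[gi, , drop = FALSE], 2, b, "+")
    }
  }
  mu <- 2^log2mu
  counts <- matrix(rnbinom(n_g * n_s, mu = mu, size = rep(1 / truths$dispersion, n_s)),
                   nrow = n_g, ncol = n_s)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truths$gene_id, design$sample_id)
  counts
}

#' Ground-truth phenotype dose-response parameters
#'
#' Defaults encode a teratogenicity curve with half-maximal incidence at
#' 16.5 µM and slope 2, whose 10%-added-risk concentration is 5.5 µM.
#'
#' @param ec50 Half-maximal concentration, µM.
#' @param hill_slope Log-logistic slope (> 0).
#' @param background Background incidence probability in `[0, 1)`.
#' @return Object of class `phenotype_truth`.
#' @export
phenotype_truth <- function(ec50 = 16.5, hill_slope = 2, background = 0) {
  stopifnot(ec50 > 0, hill_slope > 0, background >= 0, background < 1)
  structure(list(ec50 = ec50, hill_slope = hill_slope, background = background),
            class = "phenotype_truth")
}

#' Log-logistic incidence curve
#'
#' `P(d) = bg + (1 - bg) / (1 + (ec50/d)^h)`, with `P(0) = bg`.
#'
#' @param d Concentrations (µM).
#' @param ec50,hill_slope,background Curve parameters.
#' @return Incidence probabilities.
#' @export
loglogistic_incidence <- function(d, ec50, hill_slope, background = 0) {
  p <- ifelse(d > 0, 1 / (1 + (ec50 / d)^hill_slope), 0)
  background + (1 - background) * p
}

#' Simulate a morphology screen
#'
#' Draws per-concentration affected counts from a binomial with log-logistic
#' incidence. The default `n_per_conc` of 36 matches a three-plate screen of
#' 12 embryos per plate pooled per concentration.
#'
#' @param concentrations Tested concentrations (µM).
#' @param n_per_conc Animals exposed per concentration (default 36).
#' @param truth A [phenotype_truth()] object.
#' @param seed Integer seed.
#' @param endpoint,group Labels stored in the table.
#' @return data.frame phenotype table: `concentration`, `endpoint`, `group`,
#'   `n_exposed`, `n_affected`.
#' @export
simulate_phenotypes <- function(concentrations, n_per_conc = 36,
                                truth = phenotype_truth(), seed = 1,
                                endpoint = "any_effect", group = "wild_type") {
  stopifnot(n_per_conc >= 1)
  set.seed(seed)
  p <- loglogistic_incidence(concentrations, truth$ec50, truth$hill_slope,
                             truth$background)
  data.frame(concentration = concentrations, endpoint = endpoint, group = group,
             n_exposed = n_per_conc,
             n_affected = rbinom(length(concentrations), n_per_conc, p),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic experiment
#'
#' Bundles design, gene truths, counts, phenotype screen and the phenotype
#' ground truth under a single seed (fanned out per component so the pieces
#' are individually reproducible).
#'
#' @param seed Integer master seed.
#' @param n_genes,n_ahr,n_sensitive,n_high Passed to [make_gene_truths()].
#' @param concentrations Exposure series (default 0.4x geometric from 50 µM).
#' @param n_replicates Replicates per concentration.
#' @param module_rho Within-module correlation target.
#' @param pheno_concentrations Concentrations of the morphology screen
#'   (default the definitive screen levels `{0,1,5,20,35,50,65,100}`).
#' @param n_per_conc Animals per screen concentration.
#' @return Object of class `synthetic_dataset`: list with `counts`, `design`,
#'   `truths`, `phenotype`, `phenotype_truth`, `seed`.
#' @export
simulate_experiment <- function(seed = 1, n_genes = 2000, n_ahr = 100,
                                n_sensitive = 100, n_high = 100,
                                concentrations = dilution_series(50, 0.4, 7),
                                n_replicates = 4, module_rho = 0.6,
                                pheno_concentrations = c(0, 1, 5, 20, 35, 50, 65, 100),
                                n_per_conc = 36) {
  design <- make_design(concentrations, n_replicates)
  truths <- make_gene_truths(n_genes, n_ahr, n_sensitive, n_high,
                             seed = derive_seed(seed, "truths"))
  counts <- generate_counts(design, truths,
                            seed = derive_seed(seed, "counts"),
                            module_rho = module_rho)
  ptruth <- phenotype_truth()
  pheno <- simulate_phenotypes(pheno_concentrations, n_per_conc, ptruth,
                               seed = derive_seed(seed, "phenotype"))
  structure(list(counts = counts, design = design, truths = truths,
                 phenotype = pheno, phenotype_truth = ptruth, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic concentration-response experiment (seed", x$seed, ")\n")
  cat(sprintf("  %d genes x %d samples; concentrations (uM): %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$concentration), collapse = ", ")))
  cat(sprintf("  gene classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$truths$klass)),
                            table(x$truths$klass)), collapse = ", ")))
  cat(sprintf("  phenotype truth: EC50 %.1f uM, slope %.1f, background %.2f\n",
              x$phenotype_truth$ec50, x$phenotype_truth$hill_slope,
              x$phenotype_truth$background))
  invisible(x)
}

#' Derive a component seed from a master seed
#'
#' Deterministic fan-out so that adding a stage does not perturb the random
#' streams of other stages. Result is a non-negative integer below 2^31.
#'
#' @param seed Integer master seed.
#' @param label Component name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 10007 + h * 131) %% 2147483647)
}
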