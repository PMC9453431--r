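#' Configuration for differential expression calling
#'
#' @param zero_fraction_cutoff Genes with a zero count in at least this
#'   fraction of samples are removed (default 0.25, i.e. 8 of 32).
#' @param alpha Adjusted-p significance threshold for DEG calls.
#' @param pseudocount Pseudocount used where logs of counts are needed.
#' @return List of class `dge_config`.
#' @export
dge_config <- function(zero_fraction_cutoff = 0.25, alpha = 0.05,
                       pseudocount = 1) {
  stopifnot(alpha > 0, alpha < 1, pseudocount > 0)
  structure(list(zero_fraction_cutoff = zero_fraction_cutoff, alpha = alpha,
                 pseudocount = pseudocount), class = "dge_config")
}

#' Remove low-abundance genes by zero fraction
#'
#' Drops genes whose count is zero in at least `zero_fraction_cutoff` of the
#' samples (so with 32 samples and the default 0.25, zeros in 8 or more
#' samples remove the gene; 7 keep it).
#'
#' @param counts Gene x sample count matrix.
#' @param cfg A [dge_config()].
#' @return Filtered count matrix.
#' @export
filter_low_counts <- function(counts, cfg = dge_config()) {
  zf <- rowMeans(counts == 0)
  keep <- zf < cfg$zero_fraction_cutoff
  if (!any(keep)) warning("all genes removed by the zero-fraction filter")
  counts[keep, , drop = FALSE]
}

#' Aggregate gene identifiers colliding up to capitalization
#'
#' Rows whose identifiers are identical except for case are replaced by
#' their arithmetic mean and the identifier is lowercased.
#'
#' @param mat Numeric matrix with gene identifiers as rownames (or supplied
#'   via `gene_ids`).
#' @param gene_ids Optional identifier vector overriding rownames.
#' @return Matrix with case-insensitively unique, lowercased-where-merged
#'   rownames.
#' @export
aggregate_case_collisions <- function(mat, gene_ids = rownames(mat)) {
  stopifnot(!is.null(gene_ids), length(gene_ids) == nrow(mat))
  lower <- tolower(gene_ids)
  dup <- lower %in% lower[duplicated(lower)]
  if (!any(dup)) { rownames(mat) <- gene_ids; return(mat) }
  keep <- mat[!dup, , drop = FALSE]
  rownames(keep) <- gene_ids[!dup]
  merged <- rowsum(mat[dup, , drop = FALSE], lower[dup]) /
    as.vector(table(lower[dup])[sort(unique(lower[dup]))])
  out <- rbind(keep, merged)
  out[order(match(tolower(rownames(out)), unique(lower))), , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' nonzero counts in every sample, of the ratio of the sample's count to the
#' gene's geometric mean across samples.
#'
#' @param counts Gene x sample count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no gene has nonzero counts in every sample; filter low counts first")
  sf <- apply(logc[ok, , drop = FALSE], 2, function(x) exp(median(x - loggeo[ok])))
  sf
}

#' Normalize counts by size factors
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors (default computed by [size_factors()]).
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf, "/")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values.
#' @return Vector of adjusted p-values (monotone-enforced, capped at 1).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m <= 1L) return(pmin(p, 1))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- cummin(m / (m:1) * p[o])
  pmin(adj, 1)[ro]
}

# Cox-Reid adjusted NB profile likelihood for the dispersion. With a group
# indicator design the adjustment term 0.5*log det(X'WX) is the sum over
# groups of the log summed working weights w = mu/(1 + alpha*mu); without it
# the ML dispersion is biased low because the fitted group means consume
# one df per group.
nb_loglik_alpha <- function(log_alpha, k, mu, group_int) {
  a <- exp(log_alpha)
  w <- mu / (1 + a * mu)
  cr <- 0.5 * sum(log(rowsum(w, group_int)))
  -sum(dnbinom(k, mu = mu, size = 1 / a, log = TRUE)) + cr
}

#' Gene-wise NB dispersion with trend shrinkage
#'
#' Cox-Reid adjusted maximum-likelihood dispersion per gene given group
#' fitted means, then a log-log lowess trend of dispersion on base mean, and
#' an empirical-Bayes shrink of each gene's log dispersion toward the trend:
#' the final estimate maximizes the adjusted likelihood plus a log-normal
#' prior centered on the trend whose width is the observed spread of the
#' gene-wise estimates minus their sampling variance. Genes far from the
#' trend are therefore shrunk only weakly. Floored at 1e-8.
#'
#' @param counts Filtered count matrix.
#' @param design Experiment design (see [make_design()]).
#' @param sf Size factors.
#' @return data.frame with `gene_id`, `base_mean`, `alpha_mle`, `alpha_trend`,
#'   `alpha` (final, shrunken).
#' @export
estimate_dispersions <- function(counts, design, sf = size_factors(counts)) {
  group <- factor(design$concentration)
  base_mean <- rowMeans(normalize_counts(counts, sf))
  g_levels <- levels(group)
  # group fitted means on the normalized scale: sum(counts) / sum(sf)
  qmat <- vapply(g_levels, function(g) {
    j <- group == g
    rowSums(counts[, j, drop = FALSE]) / sum(sf[j])
  }, numeric(nrow(counts)))
  gint <- as.integer(group)
  alpha_mle <- vapply(seq_len(nrow(counts)), function(i) {
    mu <- qmat[i, gint] * sf
    if (all(counts[i, ] == 0)) return(1e-8)
    exp(optimize(nb_loglik_alpha, c(log(1e-8), log(30)), k = counts[i, ],
                 mu = pmax(mu, 1e-8), group_int = gint)$minimum)
  }, numeric(1))
  use <- base_mean > 0 & alpha_mle > 1e-7
  alpha_trend <- rep(max(median(alpha_mle[use]), 1e-8), nrow(counts))
  if (sum(use) >= 10) {
    lo <- lowess(log(base_mean[use]), log(alpha_mle[use]), f = 0.5)
    alpha_trend <- exp(approx(lo$x, lo$y, xout = log(pmax(base_mean, min(base_mean[use]))),
                              rule = 2)$y)
  }
  # prior width: spread of the gene-wise log estimates around the trend,
  # less the approximate sampling variance of a log dispersion estimate
  s2_samp <- trigamma((nrow(design) - length(g_levels)) / 2)
  resid_lt <- log(alpha_mle[use]) - log(alpha_trend[use])
  s2_prior <- max(var(resid_lt) - s2_samp, 0.1)
  alpha <- vapply(seq_len(nrow(counts)), function(i) {
    if (all(counts[i, ] == 0)) return(1e-8)
    mu <- pmax(qmat[i, gint] * sf, 1e-8)
    post <- function(la) nb_loglik_alpha(la, counts[i, ], mu, gint) +
      (la - log(alpha_trend[i]))^2 / (2 * s2_prior)
    exp(optimize(post, c(log(1e-8), log(30)))$minimum)
  }, numeric(1))
  alpha <- pmax(alpha, 1e-8)
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             alpha_mle = alpha_mle, alpha_trend = alpha_trend, alpha = alpha,
             stringsAsFactors = FALSE)
}

#' NB Wald differential expression versus control
#'
#' Per gene, fits a negative-binomial GLM (log link) with a concentration
#' group factor and log size-factor offset, using the shrunken gene-wise
#' dispersion from [estimate_dispersions()], and reports a Wald test of each
#' non-control concentration against control. Log2 fold changes are the GLM
#' natural-log coefficients rescaled to log2; p-values are adjusted by
#' Benjamini-Hochberg across genes within each concentration.
#'
#' @param counts Filtered count matrix (genes x samples).
#' @param design Experiment design matching the columns.
#' @param cfg A [dge_config()].
#' @return data.frame of class `deg_results`: `gene_id`, `concentration`,
#'   `log2fc`, `se`, `p`, `padj`, `is_deg`.
#' @export
nb_wald <- function(counts, design, cfg = dge_config()) {
  stopifnot(ncol(counts) == nrow(design))
  group <- factor(design$concentration)
  if (min(table(group)) < 2) stop("need >= 2 replicates per concentration")
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, design, sf)
  off <- log(sf)
  concs <- as.numeric(levels(group))[-1]
  X <- stats::model.matrix(~group)
  res <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    k <- counts[i, ]
    if (all(k == 0)) {
      res[[i]] <- data.frame(gene_id = rownames(counts)[i], concentration = concs,
                             log2fc = 0, se = NA_real_, p = 1,
                             stringsAsFactors = FALSE)
      next
    }
    fam <- MASS::negative.binomial(theta = 1 / disp$alpha[i])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, k, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || any(!is.finite(coef(fit)))) {
      res[[i]] <- data.frame(gene_id = rownames(counts)[i], concentration = concs,
                             log2fc = 0, se = NA_real_, p = 1,
                             stringsAsFactors = FALSE)
      next
    }
    # Wald: covariance from the weighted least-squares at convergence
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(V)) {
      res[[i]] <- data.frame(gene_id = rownames(counts)[i], concentration = concs,
                             log2fc = 0, se = NA_real_, p = 1,
                             stringsAsFactors = FALSE)
      next
    }
    beta <- coef(fit)[-1]
    se <- sqrt(diag(V))[-1]
    z <- beta / se
    # t reference with residual df: a small-sample correction over the
    # asymptotic normal, since the dispersion is estimated from few replicates
    res[[i]] <- data.frame(gene_id = rownames(counts)[i], concentration = concs,
                           log2fc = beta / log(2), se = se / log(2),
                           p = 2 * stats::pt(-abs(z), df = ncol(counts) - ncol(X)),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$padj <- NA_real_
  for (cc in concs) {
    j <- out$concentration == cc
    out$padj[j] <- bh_adjust(out$p[j])
  }
  out$is_deg <- out$padj < cfg$alpha
  class(out) <- c("deg_results", "data.frame")
  out
}

#' Partition DEGs by teratogenic versus non-teratogenic concentrations
#'
#' Splits the union of all per-concentration DEG sets into genes significant
#' only at non-teratogenic concentrations, only at teratogenic ones, or both.
#'
#' @param results Output of [nb_wald()].
#' @param teratogenic_concs Concentrations considered teratogenic (µM),
#'   default `c(20, 50)`.
#' @return List of class `deg_partition` with character vectors
#'   `nonteratogenic_only`, `overlap`, `teratogenic_only`.
#' @export
deg_partition <- function(results, teratogenic_concs = c(20, 50)) {
  tested <- unique(results$concentration)
  if (!all(teratogenic_concs %in% tested))
    stop("`teratogenic_concs` must be a subset of tested concentrations")
  degs <- results[results$is_deg %in% TRUE, , drop = FALSE]
  terat <- unique(degs$gene_id[degs$concentration %in% teratogenic_concs])
  nonterat <- unique(degs$gene_id[!degs$concentration %in% teratogenic_concs])
  structure(list(
    nonteratogenic_only = sort(setdiff(nonterat, terat)),
    overlap = sort(intersect(nonterat, terat)),
    teratogenic_only = sort(setdiff(terat, nonterat))
  ), class = c("deg_partition", "list"))
}

#' @export
print.deg_partition <- function(x, ...) {
  cat("DEG partition by teratogenicity of the calling concentration\n")
  cat(sprintf("  non-teratogenic only: %d\n  overlap: %d\n  teratogenic only: %d\n",
              length(x$nonteratogenic_only), length(x$overlap),
              length(x$teratogenic_only)))
  invisible(x)
}
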