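#' Ward clustering of fold-change profiles
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance) of per-gene
#' mean log2 fold-change profiles across concentrations. Cluster labels are
#' deterministic: clusters are numbered by increasing mean profile value
#' (ties by smallest member gene id).
#'
#' @param fc_profiles Gene x concentration matrix of mean log2 fold changes.
#' @param k Number of clusters (default 6).
#' @return List of class `ward_clusters`: `labels` (named integer vector),
#'   `hclust` (the dendrogram), `centroids`.
#' @export
ward_cluster <- function(fc_profiles, k = 6) {
  if (nrow(fc_profiles) < 2) stop("need >= 2 genes")
  if (k > nrow(fc_profiles)) stop("`k` exceeds the number of genes")
  hc <- hclust(dist(fc_profiles), method = "ward.D2")
  raw <- cutree(hc, k = k)
  cent <- vapply(seq_len(k), function(cl)
    mean(fc_profiles[raw == cl, , drop = FALSE]), numeric(1))
  first <- vapply(seq_len(k), function(cl)
    min(rownames(fc_profiles)[raw == cl]), character(1))
  ord <- order(cent, first)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- setNames(relabel[raw], rownames(fc_profiles))
  centroids <- t(vapply(seq_len(k), function(cl)
    colMeans(fc_profiles[labels == cl, , drop = FALSE]),
    numeric(ncol(fc_profiles))))
  structure(list(labels = labels, hclust = hc, centroids = centroids, k = k),
            class = "ward_clusters")
}

#' Per-concentration mean log2 fold-change profiles
#'
#' Averages the per-replicate fold-change matrix within each non-control
#' concentration, the representation used for profile clustering.
#'
#' @param fc Per-replicate fold-change matrix (see [fold_change_matrix()]).
#' @param design Experiment design.
#' @return Gene x concentration matrix (non-control concentrations,
#'   ascending).
#' @export
mean_fc_profiles <- function(fc, design) {
  concs <- sort(unique(design$concentration[!design$is_control]))
  out <- vapply(concs, function(cc)
    rowMeans(fc[, design$concentration == cc, drop = FALSE]),
    numeric(nrow(fc)))
  colnames(out) <- as.character(concs)
  out
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided upper-tail hypergeometric test of each term's overlap with a
#' query gene set against a background, Benjamini-Hochberg adjusted across
#' terms. Term genes outside the background are ignored.
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param terms Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @return data.frame: `term_id`, `k_overlap`, `K_term`, `n_query`,
#'   `N_background`, `p`, `padj`.
#' @export
hypergeometric_enrichment <- function(query, terms, background) {
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background))
    stop("`query` must be a subset of `background`")
  if (length(query) == 0) {
    warning("empty query gene set")
    return(data.frame(term_id = character(0), k_overlap = integer(0),
                      K_term = integer(0), n_query = integer(0),
                      N_background = integer(0), p = numeric(0),
                      padj = numeric(0), stringsAsFactors = FALSE))
  }
  N <- length(background); n <- length(query)
  rows <- lapply(names(terms), function(tid) {
    tg <- intersect(unique(terms[[tid]]), background)
    K <- length(tg)
    k <- length(intersect(tg, query))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, k_overlap = k, K_term = K, n_query = n,
               N_background = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out[order(out$p, out$term_id), ]
}

#' Anchor a module's transcriptomic BMC to the phenotype BMC
#'
#' Compares the gene-set median BMC (with its BMDL/BMDU interval) to the
#' phenotype benchmark concentration, reporting their ratio and whether the
#' transcriptomic interval covers the phenotype threshold.
#'
#' @param set_bmc Output of [geneset_bmc()].
#' @param phenotype_bmc Output of [phenotype_bmc()] (or a list with `bmc`).
#' @param module_id Module label for the report.
#' @return List of class `anchor_report`: `module_id`, `median_bmc`,
#'   `median_bmdl`, `median_bmdu`, `n_modeled`, `phenotype_bmc`,
#'   `bmc_ratio`, `interval_overlaps_phenotype`, `complete`.
#' @export
anchor_report <- function(set_bmc, phenotype_bmc, module_id = NA) {
  pb <- phenotype_bmc$bmc
  mb <- set_bmc$median_bmc
  complete <- is.finite(pb %||% NA_real_) && is.finite(mb %||% NA_real_)
  ratio <- if (complete) mb / pb else NA_real_
  overlaps <- if (complete && is.finite(set_bmc$median_bmdl) &&
                  is.finite(set_bmc$median_bmdu))
    set_bmc$median_bmdl <= pb && pb <= set_bmc$median_bmdu else NA
  structure(list(module_id = module_id, median_bmc = mb,
                 median_bmdl = set_bmc$median_bmdl,
                 median_bmdu = set_bmc$median_bmdu,
                 n_modeled = set_bmc$n_modeled, phenotype_bmc = pb,
                 bmc_ratio = ratio, interval_overlaps_phenotype = overlaps,
                 complete = complete), class = "anchor_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.anchor_report <- function(x, ...) {
  cat("Phenotypic anchoring report\n")
  if (!x$complete) cat("  (partial: a BMC was undefined)\n")
  cat(sprintf("  module %s: median BMC %.3g uM [BMDL %.3g, BMDU %.3g], %d genes modeled\n",
              as.character(x$module_id), x$median_bmc, x$median_bmdl,
              x$median_bmdu, x$n_modeled))
  cat(sprintf("  phenotype BMC %.3g uM; module/phenotype ratio %.3g; interval covers phenotype: %s\n",
              x$phenotype_bmc, x$bmc_ratio,
              as.character(x$interval_overlaps_phenotype)))
  invisible(x)
}
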