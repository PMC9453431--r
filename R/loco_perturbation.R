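#' Leave-one-concentration-out network re-inference
#'
#' For every non-control concentration, re-infers the network after removing
#' that concentration's replicate columns (same seed, same gene set) and
#' extracts all ordered-pair weights among the module genes — above and below
#' the edge cutoff alike; no thresholding is applied. The full-data inference
#' is recomputed with the identical seed, so it matches the network stage
#' exactly and ratio variation reflects data removal, not ensemble noise.
#'
#' @param fc Fold-change matrix used for network inference (the LOCO runs
#'   subset its columns).
#' @param design Experiment design matching `fc` columns.
#' @param module_genes Genes of the module under study (subset of `fc` rows).
#' @param cfg A [network_config()].
#' @param leave_out Concentrations to leave out (default: every non-control
#'   concentration). Requesting the control is an error, as the fold-change
#'   reference would vanish.
#' @return List of class `loco_networks`: `full` (module weight matrix from
#'   all samples), `reduced` (named list of module weight matrices, one per
#'   left-out concentration), `module_genes`, `leave_out`.
#' @export
loco_networks <- function(fc, design, module_genes, cfg = network_config(),
                          leave_out = NULL) {
  stopifnot(all(module_genes %in% rownames(fc)))
  concs <- sort(unique(design$concentration[!design$is_control]))
  if (is.null(leave_out)) leave_out <- concs
  if (any(leave_out == 0) || any(design$is_control[design$concentration %in% leave_out]))
    stop("the control concentration cannot be left out: it is the fold-change basis")
  if (!all(leave_out %in% concs)) stop("`leave_out` must be tested non-control concentrations")
  module_genes <- sort(module_genes)
  full_W <- infer_network(fc, cfg)[module_genes, module_genes]
  reduced <- lapply(leave_out, function(cc) {
    keep <- design$concentration != cc
    if (sum(keep) < 3) stop("fewer than 3 samples remain after removal")
    infer_network(fc[, keep, drop = FALSE], cfg)[module_genes, module_genes]
  })
  names(reduced) <- as.character(leave_out)
  structure(list(full = full_W, reduced = reduced,
                 module_genes = module_genes, leave_out = leave_out),
            class = "loco_networks")
}

#' Full/reduced edge-weight ratio table
#'
#' One row per ordered gene pair within the module, one column per left-out
#' concentration; cell = full-data weight over reduced-data weight. A ratio
#' above one means the edge was weaker once that concentration's data were
#' removed, i.e. the edge depends on that concentration. A zero reduced
#' weight with positive full weight is recorded as `Inf` (a separate class,
#' not clamped); both zero gives 1.
#'
#' @param loco A `loco_networks` object (or a list with `full` and `reduced`
#'   matrices over the same genes).
#' @return data.frame of class `loco_ratio_table`: `source`, `target`,
#'   `w_full`, then one `ratio_<conc>` column per left-out concentration.
#' @export
edge_weight_ratios <- function(loco) {
  genes <- rownames(loco$full)
  pairs <- which(row(loco$full) != col(loco$full))
  src <- genes[row(loco$full)[pairs]]
  tgt <- genes[col(loco$full)[pairs]]
  wf <- loco$full[pairs]
  out <- data.frame(source = src, target = tgt, w_full = wf,
                    stringsAsFactors = FALSE)
  for (cc in names(loco$reduced)) {
    wr <- loco$reduced[[cc]][pairs]
    ratio <- ifelse(wr == 0, ifelse(wf == 0, 1, Inf), wf / wr)
    out[[paste0("ratio_", cc)]] <- ratio
  }
  ord <- order(out$source, out$target)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("loco_ratio_table", "data.frame")
  out
}

#' Classify edges by their LOCO ratio profile
#'
#' `consistently_higher`: every defined ratio exceeds one (pairs with any
#' infinite cell remain eligible but are flagged `has_undefined`).
#' `progressive_loss`: consistently higher with all ratios finite and
#' strictly increasing with the left-out concentration's rank (Kendall tau
#' against the concentration order at least `tau_threshold`; 1 = strict
#' monotone increase). `progressive_loss` implies `consistently_higher`.
#'
#' @param ratio_table Output of [edge_weight_ratios()].
#' @param conc_order Ascending left-out concentrations (default: parsed from
#'   the ratio column names).
#' @param tau_threshold Kendall tau needed for progressive loss (default 1).
#' @return data.frame: `source`, `target`, `consistently_higher`,
#'   `progressive_loss`, `has_undefined`, `kendall_tau`.
#' @export
classify_edges <- function(ratio_table, conc_order = NULL, tau_threshold = 1) {
  rc <- grep("^ratio_", names(ratio_table), value = TRUE)
  concs <- as.numeric(sub("^ratio_", "", rc))
  if (is.null(conc_order)) conc_order <- sort(concs)
  stopifnot(setequal(conc_order, concs))
  rc <- rc[match(conc_order, concs)]
  R <- as.matrix(ratio_table[, rc, drop = FALSE])
  undef <- !is.finite(R)
  higher <- vapply(seq_len(nrow(R)), function(i) {
    ri <- R[i, ]
    all(ri[is.finite(ri)] > 1) && any(is.finite(ri))
  }, logical(1))
  tau <- rep(NA_real_, nrow(R))
  fin <- rowSums(undef) == 0
  comp <- fin & apply(R, 1, function(r) length(unique(r)) > 1)
  tau[comp] <- apply(R[comp, , drop = FALSE], 1, function(r)
    cor(seq_along(r), r, method = "kendall"))
  tau[fin & !comp] <- 0
  prog <- higher & fin & !is.na(tau) & tau >= tau_threshold
  data.frame(source = ratio_table$source, target = ratio_table$target,
             consistently_higher = higher, progressive_loss = prog,
             has_undefined = rowSums(undef) > 0, kendall_tau = tau,
             stringsAsFactors = FALSE)
}

#' Summary counts of a LOCO edge classification
#'
#' @param classification Output of [classify_edges()].
#' @return List: `n_edges`, `n_consistently_higher`, `n_progressive_loss`.
#' @export
loco_summary <- function(classification) {
  list(n_edges = nrow(classification),
       n_consistently_higher = sum(classification$consistently_higher),
       n_progressive_loss = sum(classification$progressive_loss))
}
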