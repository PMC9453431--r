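#' Configuration for co-expression network inference
#'
#' @param n_top_cv Genes kept by coefficient of variation (default 8000).
#' @param edge_cutoff Importance threshold above which an edge is retained
#'   (default 0.0086, strict inequality).
#' @param n_trees Trees per target-gene ensemble (default 500).
#' @param candidate_features Candidate features per split: `"sqrt"` (default)
#'   or an integer.
#' @param seed Seed for the tree ensembles.
#' @return List of class `network_config`.
#' @export
network_config <- function(n_top_cv = 8000, edge_cutoff = 0.0086,
                           n_trees = 500, candidate_features = "sqrt",
                           seed = 1) {
  stopifnot(edge_cutoff > 0, n_trees >= 1)
  structure(list(n_top_cv = n_top_cv, edge_cutoff = edge_cutoff,
                 n_trees = n_trees, candidate_features = candidate_features,
                 seed = seed), class = "network_config")
}

#' Per-replicate log2 fold changes against the control mean
#'
#' Every sample, including each control replicate, is expressed as
#' `log2((x + pseudocount) / mean_over_controls(x + pseudocount))`, so the
#' control columns average to roughly zero per gene by construction.
#'
#' @param norm_expr Gene x sample matrix of normalized expression.
#' @param design Experiment design.
#' @param pseudocount Added before the ratio (default 1).
#' @return Matrix of log2 fold changes, same shape as `norm_expr`.
#' @export
fold_change_matrix <- function(norm_expr, design, pseudocount = 1) {
  ctrl <- design$is_control
  if (sum(ctrl) < 2) stop("need >= 2 control replicates")
  ref <- rowMeans(norm_expr[, ctrl, drop = FALSE] + pseudocount)
  log2(sweep(norm_expr + pseudocount, 1, ref, "/"))
}

#' Keep the genes with highest coefficient of variation
#'
#' CV is computed on linear-scale ratios (`2^fc`) as SD over |mean| of each
#' gene's row; log-scale fold changes have near-zero means that make the CV
#' unstable. Ties are broken lexicographically by gene id so selection is
#' deterministic.
#'
#' @param fc Fold-change matrix (see [fold_change_matrix()]).
#' @param n_top_cv Number of genes to keep.
#' @return Subset of `fc`, highest-CV genes first.
#' @export
select_top_cv <- function(fc, n_top_cv) {
  stopifnot(n_top_cv <= nrow(fc))
  ratio <- 2^fc
  cv <- apply(ratio, 1, sd) / abs(rowMeans(ratio))
  cv[!is.finite(cv)] <- 0
  ord <- order(-cv, rownames(fc))
  fc[ord[seq_len(n_top_cv)], , drop = FALSE]
}

#' Tree-ensemble network inference
#'
#' For each target gene, a random-forest regression of its fold-change row
#' on all other genes' rows scores every regressor by total variance
#' reduction (impurity importance). Each target's incoming importances are
#' normalized to sum to one, giving a directed weight for every ordered gene
#' pair. Zero-variance targets receive all-zero incoming weights. The
#' per-target ensembles are seeded deterministically from `cfg$seed` and the
#' target's position, so identical inputs give identical weights.
#'
#' @param fc Fold-change matrix (genes x samples), >= 2 genes, >= 3 samples.
#' @param cfg A [network_config()].
#' @return Square weight matrix W (source x target), zero diagonal, each
#'   column summing to 1 (or 0).
#' @export
infer_network <- function(fc, cfg = network_config()) {
  stopifnot(nrow(fc) >= 2, ncol(fc) >= 3)
  genes <- rownames(fc)
  p <- length(genes)
  mtry <- if (identical(cfg$candidate_features, "sqrt"))
    max(1L, floor(sqrt(p - 1))) else as.integer(cfg$candidate_features)
  W <- matrix(0, p, p, dimnames = list(genes, genes))
  # canonical sample order: the ensembles bootstrap rows, so sorting by
  # sample name makes the weights invariant to the input column order
  if (!is.null(colnames(fc)))
    fc <- fc[, order(colnames(fc)), drop = FALSE]
  X <- t(fc)
  colnames(X) <- paste0("v", seq_len(p))  # safe names for ranger
  for (j in seq_len(p)) {
    y <- X[, j]
    if (var(y) == 0) next
    rf <- ranger::ranger(
      x = X[, -j, drop = FALSE], y = y, num.trees = cfg$n_trees,
      mtry = min(mtry, p - 1L), importance = "impurity",
      seed = derive_seed(cfg$seed, paste0("target", j)), num.threads = 1,
      min.node.size = 5, verbose = FALSE)
    imp <- pmax(rf$variable.importance, 0)
    s <- sum(imp)
    if (s > 0) W[-j, j] <- imp / s
  }
  W
}

#' Threshold a weight matrix into a network
#'
#' Retains ordered pairs with weight strictly above the cutoff. Nodes left
#' without any edge are dropped from the graph but reported.
#'
#' @param weights Square weight matrix from [infer_network()].
#' @param cfg A [network_config()].
#' @return Object of class `coexpression_network`: directed igraph `graph`,
#'   `edges` data.frame (source, target, weight), `isolated` nodes,
#'   `n_genes` the pre-threshold node count, and the cutoff.
#' @export
threshold_network <- function(weights, cfg = network_config()) {
  idx <- which(weights > cfg$edge_cutoff, arr.ind = TRUE)
  edges <- data.frame(source = rownames(weights)[idx[, 1]],
                      target = colnames(weights)[idx[, 2]],
                      weight = weights[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  connected <- unique(c(edges$source, edges$target))
  isolated <- setdiff(rownames(weights), connected)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = sort(connected))
  structure(list(graph = g, edges = edges, isolated = sort(isolated),
                 n_genes = nrow(weights), edge_cutoff = cfg$edge_cutoff,
                 modules = NULL, centrality = NULL),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("Co-expression network: %d of %d genes connected, %d directed edges (cutoff %g)\n",
              igraph::vcount(x$graph), x$n_genes, nrow(x$edges),
              x$edge_cutoff))
  cat(sprintf("  retained fraction: %s%% of possible ordered pairs\n",
              format(retained_fraction(nrow(x$edges), x$n_genes))))
  if (!is.null(x$modules))
    cat(sprintf("  modules: %d (sizes %s)\n", length(unique(x$modules)),
                paste(sort(table(x$modules), decreasing = TRUE),
                      collapse = ", ")))
  invisible(x)
}

#' @export
plot.coexpression_network <- function(x, ...) {
  g <- igraph::as_undirected(x$graph, mode = "collapse",
                             edge.attr.comb = list(weight = "sum"))
  col <- if (!is.null(x$modules))
    grDevices::rainbow(max(3, length(unique(x$modules))))[
      as.integer(factor(x$modules[igraph::V(g)$name]))] else "steelblue"
  plot(g, vertex.color = col, vertex.size = 6, vertex.label = NA, ...)
  invisible(x)
}

#' Greedy modularity module detection
#'
#' Clauset-Newman-Moore greedy modularity maximization (igraph fastgreedy) on
#' the undirected weighted projection of the network, with weights of
#' reciprocal edges summed. Modules are relabeled 1, 2, ... by decreasing
#' size (ties by smallest member gene id) so labels are deterministic.
#'
#' @param net A `coexpression_network`.
#' @return `net` with a named `modules` vector (gene -> module id).
#' @export
detect_modules <- function(net) {
  if (nrow(net$edges) == 0) stop("network has no edges")
  g <- igraph::as_undirected(net$graph, mode = "collapse",
                             edge.attr.comb = list(weight = "sum"))
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  first <- vapply(split(names(memb), memb), min, character(1))
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), first)
  relabel <- integer(length(sizes)); relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- setNames(relabel[as.integer(memb)], names(memb))
  net$modules <- out
  net$modularity <- igraph::modularity(cl)
  net
}

#' Genes of one module
#'
#' @param net A `coexpression_network` after [detect_modules()].
#' @param module_id Module label.
#' @return Character vector of gene ids, sorted.
#' @export
module_genes <- function(net, module_id) {
  if (is.null(net$modules)) stop("run detect_modules() first")
  sort(names(net$modules)[net$modules == module_id])
}

#' Degree and betweenness centralities
#'
#' Degree counts distinct neighbours regardless of edge direction;
#' betweenness is the fraction of shortest paths through each node on the
#' unweighted undirected projection, normalized by `(n-1)(n-2)/2`.
#'
#' @param net A `coexpression_network`.
#' @return `net` with a `centrality` data.frame (`gene_id`, `degree`,
#'   `betweenness`).
#' @export
centralities <- function(net) {
  g <- igraph::as_undirected(net$graph, mode = "collapse")
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = TRUE)
  net$centrality <- data.frame(gene_id = igraph::V(g)$name,
                               degree = as.integer(deg),
                               betweenness = as.numeric(btw),
                               stringsAsFactors = FALSE)
  net
}

#' Number of possible directed edges among n genes
#'
#' Ordered pairs: `n * (n - 1)`; 178 genes give 31,506.
#'
#' @param n_genes Number of genes (>= 2).
#' @return Integer count.
#' @export
possible_edge_count <- function(n_genes) {
  if (n_genes < 2) stop("need at least 2 genes")
  as.numeric(n_genes) * (n_genes - 1)
}

#' Percentage of possible edges retained after thresholding
#'
#' @param n_edges Retained edge count.
#' @param n_genes Gene count.
#' @param sig_figs Significant figures of the reported percentage (default 1).
#' @return Percentage (e.g. 0.007 for 4,678 of 8,000 x 7,999).
#' @export
retained_fraction <- function(n_edges, n_genes, sig_figs = 1) {
  total <- possible_edge_count(n_genes)
  if (n_edges > total) stop("more edges than ordered pairs")
  signif(100 * n_edges / total, sig_figs)
}

#' End-to-end network construction from a count matrix
#'
#' Normalizes, computes per-replicate fold changes, selects high-CV genes,
#' infers the tree-ensemble network, thresholds it, detects modules and
#' computes centralities.
#'
#' @param counts Filtered count matrix.
#' @param design Experiment design.
#' @param cfg A [network_config()].
#' @param pseudocount Fold-change pseudocount.
#' @return A `coexpression_network` with `weights` (full matrix), modules
#'   and centralities, plus the selected fold-change matrix as `fc`.
#' @export
build_network <- function(counts, design, cfg = network_config(),
                          pseudocount = 1) {
  norm <- normalize_counts(counts)
  fc <- fold_change_matrix(norm, design, pseudocount)
  fc <- select_top_cv(fc, min(cfg$n_top_cv, nrow(fc)))
  W <- infer_network(fc, cfg)
  net <- threshold_network(W, cfg)
  if (nrow(net$edges) > 0) {
    net <- detect_modules(net)
    net <- centralities(net)
  }
  net$weights <- W
  net$fc <- fc
  net
}
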