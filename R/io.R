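#' Write a count matrix as TSV
#'
#' First column `gene_id`, then one column per sample. Lines starting with
#' `#` carry metadata and are skipped on read.
#'
#' @param counts Gene x sample matrix.
#' @param path Output path.
#' @param metadata Optional named character vector written as `# key: value`.
#' @export
write_counts_tsv <- function(counts, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s: %s", names(metadata), metadata), con)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count matrix TSV
#'
#' @param path Input path (format of [write_counts_tsv()]).
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be `gene_id`: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ncomment <- length(grep("^#", readLines(path, n = 200)))
    stop(sprintf("non-count value at line %d, column `%s` of %s",
                 bad[1, 1] + 1 + ncomment, colnames(m)[bad[1, 2]], path))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Write / read an experiment design TSV
#'
#' @param design Design data.frame (see [make_design()]).
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "concentration", "replicate", "is_control")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design file missing columns: ", paste(miss, collapse = ", "))
  d$is_control <- as.logical(d$is_control)
  if (sum(unique(d$concentration[d$is_control])) != 0 ||
      length(unique(d$concentration[d$is_control])) != 1)
    stop("exactly one control concentration equal to 0 is required")
  d
}

#' Write / read a phenotype table TSV
#'
#' @param pheno Phenotype table (see [simulate_phenotypes()]).
#' @param path File path.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("concentration", "endpoint", "n_exposed", "n_affected")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("phenotype file missing columns: ", paste(miss, collapse = ", "))
  bad <- which(d$n_affected > d$n_exposed | d$n_affected < 0)
  if (length(bad)) stop("n_affected out of range at line ", bad[1] + 1, " of ", path)
  d
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one term per line, tab-separated `term<TAB>description<TAB>`
#' genes. Duplicate term names: the last occurrence wins, with a warning.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) stop("malformed GMT line ", short[1], " of ", path)
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    warning("duplicate GMT terms (last occurrence kept): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  sets[!duplicated(ids, fromLast = TRUE)][unique(ids)]
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional term descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
}

#' Export a network's edge list, SIF and GraphML
#'
#' @param net A `coexpression_network`.
#' @param edge_path,sif_path,graphml_path Output paths (`NULL` skips).
#' @export
write_network <- function(net, edge_path = NULL, sif_path = NULL,
                          graphml_path = NULL) {
  if (!is.null(edge_path))
    write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(sif_path))
    writeLines(sprintf("%s\tcoexpression\t%s", net$edges$source,
                       net$edges$target), sif_path)
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  invisible(net)
}

#' Read an edge-list TSV
#'
#' @param path File with columns `source`, `target`, `weight`.
#' @return data.frame.
#' @export
read_edge_list <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("source", "target", "weight")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("edge list missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Write a JSON report
#'
#' @param x A list (e.g. an `anchor_report` or pipeline manifest).
#' @param path Output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full analysis pipeline
#'
#' Executes differential expression, trend-gated BMC modeling, network
#' inference with module detection, the LOCO perturbation of the most
#' responsive planted-scale module, phenotype dose-response fitting and the
#' anchoring report, writing each stage's outputs and a manifest (with file
#' hashes and the seed) under `outdir`. Stage seeds are fanned out from the
#' global seed so inserting a stage does not perturb the others. If the
#' phenotype table is missing, anchoring is skipped with a warning and the
#' other stages complete.
#'
#' @param counts Filtered or raw count matrix (the zero-fraction filter and
#'   case-collision aggregation are applied here).
#' @param design Experiment design.
#' @param outdir Output directory (created if needed).
#' @param phenotype Optional phenotype table.
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @param teratogenic_concs Concentrations treated as teratogenic.
#' @param seed Global seed.
#' @param dge_cfg,bmc_cfg,net_cfg Stage configurations.
#' @param n_boot Bootstrap draws per gene for BMDL/BMDU.
#' @param loco_module Module id for the LOCO stage (default 1, the largest).
#' @return The manifest, invisibly (list of stage outputs and file hashes).
#' @export
run_pipeline <- function(counts, design, outdir, phenotype = NULL,
                         gene_sets = NULL, teratogenic_concs = c(20, 50),
                         seed = 1, dge_cfg = dge_config(),
                         bmc_cfg = NULL, net_cfg = NULL, n_boot = 200,
                         loco_module = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(bmc_cfg)) bmc_cfg <- bmc_config(seed = derive_seed(seed, "bmc"))
  if (is.null(net_cfg))
    net_cfg <- network_config(n_top_cv = min(8000, nrow(counts)),
                              seed = derive_seed(seed, "network"))
  manifest <- list(seed = seed, stages = list(), files = list(),
                   status = "complete")
  meta <- c(package = "phenanchor", seed = as.character(seed))

  counts <- aggregate_case_collisions(counts)
  counts <- filter_low_counts(round(counts), dge_cfg)

  # dge
  deg <- nb_wald(counts, design, dge_cfg)
  write.table(deg, file.path(outdir, "deg_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  part <- deg_partition(deg, teratogenic_concs)
  write_json_report(part, file.path(outdir, "deg_partition.json"))
  manifest$stages$dge <- list(n_genes = nrow(counts),
                              n_deg = length(unique(deg$gene_id[deg$is_deg])))

  # trend + bmc
  expr <- log2(normalize_counts(counts) + dge_cfg$pseudocount)
  bmc <- bmc_pipeline(expr, design, bmc_cfg, n_boot = n_boot)
  write.table(bmc$table, file.path(outdir, "bmc_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$bmc <- list(n_pass_trend = sum(bmc$table$passes),
                              n_modeled = sum(!is.na(bmc$table$bmc)))

  # network
  net <- build_network(counts, design, net_cfg)
  write_network(net, edge_path = file.path(outdir, "edges.tsv"),
                sif_path = file.path(outdir, "network.sif"),
                graphml_path = file.path(outdir, "network.graphml"))
  if (!is.null(net$modules))
    write.table(data.frame(gene_id = names(net$modules),
                           module = net$modules),
                file.path(outdir, "modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(net$centrality))
    write.table(net$centrality, file.path(outdir, "centralities.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$network <- list(n_edges = nrow(net$edges),
                                  n_modules = length(unique(net$modules)))

  # loco on the chosen module
  mod_genes <- tryCatch(module_genes(net, loco_module), error = function(e) NULL)
  if (!is.null(mod_genes) && length(mod_genes) >= 3) {
    loco <- loco_networks(net$fc, design, mod_genes, net_cfg)
    ratios <- edge_weight_ratios(loco)
    cls <- classify_edges(ratios)
    write.table(ratios, file.path(outdir, "loco_ratios.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cls, file.path(outdir, "loco_classification.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_json_report(loco_summary(cls), file.path(outdir, "loco_summary.json"))
    manifest$stages$loco <- loco_summary(cls)
  } else {
    manifest$stages$loco <- list(skipped = "module too small or absent")
  }

  # enrichment of the teratogenic-only DEG set
  if (!is.null(gene_sets)) {
    enr <- hypergeometric_enrichment(
      intersect(part$teratogenic_only, rownames(counts)), gene_sets,
      rownames(counts))
    write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$enrichment <- list(n_terms = nrow(enr),
                                       n_sig = sum(enr$padj < 0.05))
  }

  # phenotype + anchoring
  if (!is.null(phenotype)) {
    pfit <- fit_loglogistic(phenotype)
    pbmc <- phenotype_bmc(pfit)
    write_json_report(c(coef(pfit), list(ec50_ci = pfit$ec50_ci,
                                         bmc = pbmc$bmc, bmdl = pbmc$bmdl)),
                      file.path(outdir, "phenotype_fit.json"))
    sb <- geneset_bmc(bmc$table, if (!is.null(mod_genes)) mod_genes
                      else bmc$table$gene_id)
    anchor <- anchor_report(sb, pbmc, module_id = loco_module)
    write_json_report(anchor, file.path(outdir, "anchor_report.json"))
    manifest$stages$anchor <- list(module_median_bmc = sb$median_bmc,
                                   phenotype_bmc = pbmc$bmc,
                                   ratio = anchor$bmc_ratio)
  } else {
    warning("no phenotype table: anchoring skipped")
    manifest$stages$anchor <- list(skipped = "phenotype table missing")
  }

  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  write_json_report(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}
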