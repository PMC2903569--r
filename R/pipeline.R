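#' Pipeline configuration
#'
#' Bundles every tunable parameter of the three-stage protocol. All
#' numeric parameters must be positive; the configuration is serialized
#' verbatim into the run-metadata JSON for provenance.
#'
#' @param gap_bp proximity-merging distance in base pairs (default 2000).
#' @param variance_target PCA explained-variance target (default 0.99).
#' @param k_max largest cluster count scanned per region (default 8).
#' @param min_region_size smallest region that undergoes spectral
#'   clustering (default 3).
#' @param window_bp association window in base pairs (default 20000).
#' @param m_perm permutations per association (default 10000).
#' @param alpha raw p-value threshold for the gene ranking (default 0.05).
#' @param log_base logarithm base of the input expression values
#'   (default 2).
#' @param seed global integer seed; all per-region and per-association
#'   sub-seeds derive from it.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(gap_bp = 2000, variance_target = 0.99,
                            k_max = 8, min_region_size = 3,
                            window_bp = 20000, m_perm = 10000,
                            alpha = 0.05, log_base = 2, seed = 1) {
  cfg <- list(gap_bp = gap_bp, variance_target = variance_target,
              k_max = k_max, min_region_size = min_region_size,
              window_bp = window_bp, m_perm = m_perm, alpha = alpha,
              log_base = log_base, seed = seed)
  num <- unlist(cfg[c("gap_bp", "variance_target", "k_max",
                      "min_region_size", "window_bp", "m_perm", "alpha",
                      "log_base")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all numeric pipeline parameters must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Run the full three-stage protocol
#'
#' Executes read -> harmonize -> normalize -> reduce -> associate ->
#' score/rank, writes the result tables and run metadata to
#' \code{out_dir}, and returns all intermediate artifacts. The run is
#' deterministic given the configuration seed: repeating it produces
#' byte-identical output files.
#'
#' Outputs written: \code{clusters.tsv} (per-site region and cluster
#' assignment with the selected sigma, k and compactness),
#' \code{associations.tsv} (all scored associations),
#' \code{ranked_genes.tsv} (genes passing the p-value filter, best
#' association each, descending R), and \code{run_metadata.json}
#' (configuration, stage counts, drop counts).
#'
#' @param meth_path path to the methylation TSV
#'   (see \code{\link{read_methylation}}).
#' @param expr_path path to the expression TSV
#'   (see \code{\link{read_expression}}).
#' @param out_dir output directory, created if needed; \code{NULL} skips
#'   writing.
#' @param config a \code{\link{pipeline_config}}.
#' @param subtype optional named character vector of subtype labels
#'   (names = cell lines) used only in reporting.
#' @return Invisibly, a list of class \code{pipeline_run}: \code{panel},
#'   \code{methylation}, \code{expression} (normalized),
#'   \code{reduction}, \code{associations} (scored), \code{genes}
#'   (per-gene best associations, unfiltered), \code{ranked} (filtered
#'   ranking), \code{counts}, \code{config}, \code{out_dir}.
#' @export
run_pipeline <- function(meth_path, expr_path, out_dir = NULL,
                         config = pipeline_config(), subtype = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  meth <- stage("read_methylation", read_methylation(meth_path))
  expr <- stage("read_expression", read_expression(expr_path))
  panel <- stage("harmonize", {
    p <- harmonize_panels(meth$panel, expr$panel)
    if (!is.null(subtype)) {
      lab <- unname(subtype[p$cell_lines])
      lab[is.na(lab)] <- "unknown"
      p <- cell_panel(p$cell_lines, lab)
    }
    p
  })
  meth <- subset_to_panel(meth, panel)
  expr <- subset_to_panel(expr, panel)
  expr <- stage("normalize_expression",
                normalize_expression(expr, config$log_base))
  red <- stage("reduce", reduce_methylation(
    meth, gap = config$gap_bp, variance_target = config$variance_target,
    k_max = config$k_max, min_region_size = config$min_region_size,
    seed = config$seed))
  assoc <- stage("associate",
                 associate_clusters(red, expr, window = config$window_bp))
  scored <- stage("rank", score_associations(assoc, red, expr,
                                             m_perm = config$m_perm,
                                             seed = config$seed))
  genes <- best_gene_associations(scored)
  ranked <- rank_genes(scored, alpha = config$alpha)

  counts <- list(n_cell_lines = length(panel),
                 n_sites = nrow(meth$sites),
                 n_sites_dropped = meth$dropped,
                 n_regions = nrow(red$regions),
                 n_clusters = nrow(red$clusters),
                 compression_pct =
                   100 * (1 - nrow(red$clusters) / nrow(meth$sites)),
                 pca_components =
                   if (is.null(red$pca)) NA_integer_ else red$pca$n_kept,
                 n_associations = nrow(assoc),
                 n_scored = nrow(scored),
                 n_ranked_genes = nrow(ranked))
  message(sprintf(
    "pipeline: %d sites -> %d regions -> %d clusters (%.1f%% compression); %d associations; %d ranked genes",
    counts$n_sites, counts$n_regions, counts$n_clusters,
    counts$compression_pct, counts$n_associations, counts$n_ranked_genes))

  run <- structure(list(panel = panel, methylation = meth,
                        expression = expr, reduction = red,
                        associations = scored, genes = genes,
                        ranked = ranked, counts = counts, config = config,
                        out_dir = out_dir),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    site_table <- merge(red$assignments,
                        red$clusters[, c("representative_id", "sigma", "k",
                                         "compactness")],
                        by = "representative_id", sort = FALSE)
    site_table <- site_table[order(site_table$site_id),
                             c("region_id", "site_id", "cluster",
                               "representative_id", "sigma", "k",
                               "compactness")]
    write_tsv(site_table, file.path(out_dir, "clusters.tsv"))
    write_tsv(scored, file.path(out_dir, "associations.tsv"))
    ranked_out <- ranked[, c("gene", "R", "p_value", "q_value", "a", "b",
                             "c", "n_used", "representative_id",
                             "probeset_id")]
    names(ranked_out)[names(ranked_out) == "n_used"] <- "n_cell_lines"
    write_tsv(ranked_out, file.path(out_dir, "ranked_genes.tsv"))
    jsonlite::write_json(
      list(config = unclass(config), counts = counts,
           skipped_associations = attr(scored, "skipped")),
      file.path(out_dir, "run_metadata.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %s\n", nm,
                format(x$counts[[nm]], digits = 6)))
  invisible(x)
}

#' Per-gene scatter data for reporting
#'
#' Emits, for every ranked gene, the (methylation, expression, fitted
#' expression) triplet per cell line of its best association -- the data
#' behind the standard expression-versus-methylation scatter with the
#' fitted curve overlaid. When the panel carries subtype labels a
#' \code{subtype} column is included, enabling subtype-stratified plots.
#'
#' @param run a \code{pipeline_run}.
#' @param path optional TSV output path.
#' @return Data frame: \code{gene}, \code{assoc_id}, \code{cell_line},
#'   (\code{subtype}), \code{M}, \code{E}, \code{E_fit}, \code{R},
#'   \code{p_value}. Empty (with a notice) when no gene was ranked.
#' @export
pipeline_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "pipeline_run"))
  ranked <- run$ranked
  has_sub <- !is.null(run$panel$subtype)
  if (nrow(ranked) == 0L) {
    message("pipeline_report: no significant genes; empty report")
    out <- data.frame(gene = character(), assoc_id = character(),
                      cell_line = character(), M = numeric(),
                      E = numeric(), E_fit = numeric(), R = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
    if (has_sub) out$subtype <- character(0)
  } else {
    rows <- lapply(seq_len(nrow(ranked)), function(i) {
      M <- run$reduction$representatives[ranked$representative_id[i], ]
      E <- run$expression$profiles[ranked$probeset_id[i], ]
      df <- data.frame(gene = ranked$gene[i],
                       assoc_id = ranked$assoc_id[i],
                       cell_line = run$panel$cell_lines,
                       M = unname(M), E = unname(E),
                       E_fit = unname(sigmoid_curve(M, ranked$a[i],
                                                    ranked$b[i],
                                                    ranked$c[i])),
                       R = ranked$R[i], p_value = ranked$p_value[i],
                       stringsAsFactors = FALSE)
      if (has_sub)
        df$subtype <- unname(run$panel$subtype)
      df
    })
    out <- do.call(rbind, rows)
  }
  if (!is.null(path)) write_tsv(out, path)
  out
}
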