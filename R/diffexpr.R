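#' Analysis configuration
#'
#' Central container for the thresholds used across the pipeline.
#'
#' @param fc_threshold Fold-change cut for direction calls; a gene is
#'   called down/up when |log2FC| >= log2(fc_threshold). Default 1.5.
#' @param strong_down_cut log2FC ceiling for the "most downregulated"
#'   table; a gene qualifies when log2FC < this in every cell line.
#'   Default -0.9.
#' @param pseudocount Abundance pseudocount added to both condition means
#'   before the ratio, stabilising genes near zero. Default 1.
#' @param alpha Two-sided significance level for the cohort screen.
#'   Default 0.05.
#' @param min_expressed_samples Prevalence filter for the cohort screen: a
#'   miRNA is kept when detected (abundance > 0) in more than this many
#'   patients. Default 300.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(fc_threshold = 1.5, strong_down_cut = -0.9,
                            pseudocount = 1, alpha = 0.05,
                            min_expressed_samples = 300) {
  stopifnot(fc_threshold > 1, pseudocount >= 0, alpha > 0, alpha < 1,
            min_expressed_samples >= 0)
  structure(
    list(fc_threshold = fc_threshold, strong_down_cut = strong_down_cut,
         pseudocount = pseudocount, alpha = alpha,
         min_expressed_samples = min_expressed_samples),
    class = "analysis_config")
}

#' Per-gene log2 fold change for one cell line
#'
#' log2FC = log2((mean mimic + eps) / (mean NC + eps)), computed on the
#' normalized abundance scale. With one sample per condition (a common
#' mimic-transfection design) the means are the single samples; the
#' pseudocount keeps the ratio defined at zero abundance.
#'
#' @param expr Genes-by-samples numeric matrix (row names = gene ids).
#' @param meta Data frame with `sample_id`, `cell_line`, `condition`
#'   (`"mimic"`/`"NC"`).
#' @param cell_line Cell line to compute.
#' @param pseudocount Non-negative pseudocount (default 1).
#' @return Named numeric vector of log2 fold changes.
#' @export
compute_log2fc <- function(expr, meta, cell_line, pseudocount = 1) {
  m <- meta[meta$cell_line == cell_line, , drop = FALSE]
  mimic <- m$sample_id[m$condition == "mimic"]
  nc <- m$sample_id[m$condition == "NC"]
  if (length(mimic) == 0L || length(nc) == 0L) {
    stop(sprintf("cell line '%s' needs at least one mimic and one NC sample",
                 cell_line))
  }
  mu_m <- rowMeans(expr[, mimic, drop = FALSE])
  mu_n <- rowMeans(expr[, nc, drop = FALSE])
  log2((mu_m + pseudocount) / (mu_n + pseudocount))
}

#' Fold-change table across all cell lines
#'
#' One row per gene with log2FC and a direction call per cell line:
#' `down` when log2FC <= -log2(fc_threshold), `up` when
#' log2FC >= +log2(fc_threshold), else `unchanged`.
#'
#' @inheritParams compute_log2fc
#' @param config An [analysis_config()].
#' @return Data frame: `gene_id`, then `log2fc_<line>` and `call_<line>`
#'   per cell line; attribute `"cell_lines"` records the line order.
#' @export
fold_change_table <- function(expr, meta, config = analysis_config()) {
  lines <- sort(unique(meta$cell_line))
  cut <- log2(config$fc_threshold)
  out <- data.frame(gene_id = rownames(expr), stringsAsFactors = FALSE)
  for (cl in lines) {
    lfc <- compute_log2fc(expr, meta, cl, config$pseudocount)
    call <- ifelse(lfc <= -cut, "down", ifelse(lfc >= cut, "up", "unchanged"))
    out[[paste0("log2fc_", cl)]] <- unname(lfc)
    out[[paste0("call_", cl)]] <- unname(call)
  }
  attr(out, "cell_lines") <- lines
  out
}

fc_cell_lines <- function(fc) {
  lines <- attr(fc, "cell_lines")
  if (is.null(lines)) lines <- sub("^log2fc_", "",
                                   grep("^log2fc_", names(fc), value = TRUE))
  lines
}

#' Genes regulated in the same direction in every cell line
#'
#' @param fc Fold-change table from [fold_change_table()].
#' @return List with character vectors `shared_down` and `shared_up`
#'   (disjoint by construction).
#' @export
call_shared_regulated <- function(fc) {
  lines <- fc_cell_lines(fc)
  calls <- as.matrix(fc[paste0("call_", lines)])
  list(
    shared_down = fc$gene_id[rowSums(calls == "down") == length(lines)],
    shared_up = fc$gene_id[rowSums(calls == "up") == length(lines)])
}

#' Table of the most strongly downregulated shared genes
#'
#' Keeps genes that are shared-down and below `strong_down_cut` in every
#' cell line, sorts by mean log2FC ascending (strongest knockdown first),
#' and joins the per-gene site summary when provided.
#'
#' @param fc Fold-change table from [fold_change_table()].
#' @param site_summary Optional per-gene summary from [summarize_sites()].
#' @param strong_down_cut log2FC ceiling (default -0.9).
#' @return Data frame, strongest knockdown first.
#' @export
top_downregulated <- function(fc, site_summary = NULL,
                              strong_down_cut = -0.9) {
  lines <- fc_cell_lines(fc)
  lfc <- as.matrix(fc[paste0("log2fc_", lines)])
  shared_down <- call_shared_regulated(fc)$shared_down
  keep <- fc$gene_id %in% shared_down &
    rowSums(lfc < strong_down_cut) == length(lines)
  out <- fc[keep, c("gene_id", paste0("log2fc_", lines)), drop = FALSE]
  out$mean_log2fc <- rowMeans(as.matrix(out[paste0("log2fc_", lines)]))
  out <- out[order(out$mean_log2fc), , drop = FALSE]
  if (!is.null(site_summary)) {
    out <- merge(out, site_summary, by = "gene_id", all.x = TRUE,
                 sort = FALSE)
    out$total_sites[is.na(out$total_sites)] <- 0L
    out <- out[order(out$mean_log2fc), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
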