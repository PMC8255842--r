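#' Fraction of regulated genes that carry at least one seed site
#'
#' @param genes Character vector of gene ids (typically the shared-down
#'   set); genes absent from the summary count as zero sites.
#' @param site_summary Per-gene summary from [summarize_sites()].
#' @return Proportion in [0, 1].
#' @export
site_presence_fraction <- function(genes, site_summary) {
  if (length(genes) == 0L) stop("empty gene set: fraction undefined")
  totals <- site_summary$total_sites[match(genes, site_summary$gene_id)]
  totals[is.na(totals)] <- 0L
  mean(totals >= 1L)
}

#' Binding-mode and binding-region distributions
#'
#' Mode proportions are over all sites; region proportions are over CDS
#' and 3'UTR sites only (junction sites and, by default, 5'UTR sites are
#' excluded from the headline denominator).
#'
#' @param sites Site data frame from [scan_transcripts()].
#' @param include_5utr Count 5'UTR sites in the region distribution
#'   (default FALSE).
#' @return List with named numeric vectors `mode_distribution` (over the
#'   site types present, summing to 1) and `region_distribution`.
#' @export
mode_and_region_distributions <- function(sites, include_5utr = FALSE) {
  if (nrow(sites) == 0L) stop("no sites: distributions undefined")
  mode <- table(factor(sites$site_type, levels = SITE_TYPES))
  mode <- mode / sum(mode)
  regions <- c("CDS", "3UTR")
  if (include_5utr) regions <- c("5UTR", regions)
  in_denom <- sites$region %in% regions
  if (!any(in_denom)) {
    region <- stats::setNames(rep(NA_real_, length(regions)), regions)
  } else {
    region <- table(factor(sites$region[in_denom], levels = regions))
    region <- region / sum(region)
  }
  list(mode_distribution = c(unclass(mode)),
       region_distribution = c(unclass(region)))
}

#' Correlation between fold change and seed-site count
#'
#' Spearman rank correlation (two-sided) of per-gene log2FC against the
#' number of seed sites, computed within a stated gene set (typically the
#' shared-down genes). Constant site counts make the rank correlation
#' undefined; the result is then flagged not-applicable.
#'
#' @param fc Fold-change table from [fold_change_table()].
#' @param site_summary Per-gene summary from [summarize_sites()]; genes
#'   absent count as zero sites.
#' @param cell_line Which cell line's log2FC to use.
#' @param genes Gene ids to include (default: all genes in `fc`).
#' @return List: `rho`, `p`, `n`, `applicable`.
#' @export
fc_sitecount_correlation <- function(fc, site_summary, cell_line,
                                     genes = fc$gene_id) {
  keep <- fc$gene_id %in% genes
  lfc <- fc[[paste0("log2fc_", cell_line)]][keep]
  ids <- fc$gene_id[keep]
  counts <- site_summary$total_sites[match(ids, site_summary$gene_id)]
  counts[is.na(counts)] <- 0L
  ok <- is.finite(lfc)
  lfc <- lfc[ok]; counts <- counts[ok]
  if (length(lfc) < 3L) stop("need at least 3 genes with defined values")
  if (length(unique(counts)) < 2L || length(unique(lfc)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = length(lfc),
                applicable = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(lfc, counts, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(lfc),
       applicable = TRUE)
}

#' Hypergeometric pathway over-representation
#'
#' For each gene set, tests whether the selected genes overlap it more
#' than expected under random draws from the universe: with universe size
#' N, pathway membership K (restricted to the universe), selection size n
#' and overlap k, the one-sided p is the upper tail P(X >= k) of the
#' hypergeometric distribution. Benjamini-Hochberg adjustment is applied
#' across the tested pathways. Pathways with zero members in the universe
#' are skipped with a message.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector, the gene universe (e.g. all genes in
#'   the expression table).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @return Data frame sorted by p: `pathway_id`, `K`, `k`, `N`, `n`, `p`,
#'   `q`.
#' @export
pathway_overrepresentation <- function(selected, universe, gene_sets) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(gene_sets) == 0L) stop("empty gene-set collection")
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(gene_sets[[id]], universe)
    K <- length(members)
    if (K == 0L) {
      message(sprintf("skipping pathway '%s': no overlap with universe", id))
      return(NULL)
    }
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, K = K, k = k, N = N, n = n, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no pathway overlaps the universe")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$pathway_id), , drop = FALSE]
}

#' Full target-preference report
#'
#' Bundles the headline targeting-preference statistics for a regulated
#' gene set: site-presence fraction, binding-mode and binding-region
#' distributions, and the per-cell-line fold-change/site-count
#' correlations.
#'
#' @param shared_down Character vector of shared-down gene ids.
#' @param sites Site table from [scan_transcripts()] (restricted
#'   internally to `shared_down` genes).
#' @param fc Fold-change table from [fold_change_table()].
#' @param include_5utr Passed to [mode_and_region_distributions()].
#' @return List: `fraction_with_sites`, `mode_distribution`,
#'   `region_distribution`, `correlations` (one entry per cell line).
#' @export
preference_report <- function(shared_down, sites, fc,
                              include_5utr = FALSE) {
  sites <- sites[sites$gene_id %in% shared_down, , drop = FALSE]
  summary <- summarize_sites(sites, genes = shared_down)
  frac <- site_presence_fraction(shared_down, summary)
  dist <- if (nrow(sites) > 0L) {
    mode_and_region_distributions(sites, include_5utr = include_5utr)
  } else {
    list(mode_distribution = NULL, region_distribution = NULL)
  }
  lines <- fc_cell_lines(fc)
  cors <- lapply(lines, function(cl) {
    tryCatch(
      fc_sitecount_correlation(fc, summary, cl, genes = shared_down),
      error = function(e) list(rho = NA_real_, p = NA_real_,
                               n = length(shared_down),
                               applicable = FALSE))
  })
  names(cors) <- lines
  list(fraction_with_sites = frac,
       mode_distribution = dist$mode_distribution,
       region_distribution = dist$region_distribution,
       correlations = cors)
}
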