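#' Run the full target-preference and cohort-screen pipeline
#'
#' Orchestrates the stages end to end: seed-site scan, mimic-vs-NC fold
#' changes with cross-cell-line intersection, target-preference report
#' (with optional pathway over-representation), and the cohort biomarker
#' screen. Every stage writes its TSV outputs under `out_dir` and the
#' headline quantities are collected into a machine-readable
#' `summary.json`. In demo mode (no input paths) all inputs are generated
#' by the synthetic module under `seed`, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param out_dir Output directory (created if needed; must not be an
#'   input location).
#' @param mirna A [mature_mirna()] or sequence string (demo default: the
#'   miR-194 guide).
#' @param transcripts Data frame of transcripts (see
#'   [load_transcriptome()]) or `NULL` for synthetic.
#' @param expr,meta Expression matrix and sample metadata, or `NULL` for
#'   synthetic.
#' @param cohort List with `expr` and `clinical` (see
#'   [simulate_cohort()]) or `NULL` for synthetic.
#' @param gene_sets Named list of gene sets for over-representation, or
#'   `NULL` to skip (demo mode builds synthetic sets).
#' @param config An [analysis_config()].
#' @param min_expressed_frac When the cohort prevalence cutoff should
#'   scale with cohort size, the fraction of patients used (default 0.75;
#'   ignored when `config$min_expressed_samples` is below the cohort
#'   size).
#' @param seed Integer seed for the synthetic stages.
#' @param n_genes Number of synthetic genes in demo mode (default 200).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(out_dir,
                         mirna = mature_mirna("miR-194",
                                              "UGUAACAGCAACUCCAUGUGGA"),
                         transcripts = NULL, expr = NULL, meta = NULL,
                         cohort = NULL, gene_sets = NULL,
                         config = analysis_config(),
                         min_expressed_frac = 0.75,
                         seed = 1, n_genes = 200, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                           sprintf(...))
  mirna <- as_mature_mirna(mirna)
  synthetic <- is.null(transcripts) || is.null(expr) || is.null(cohort)

  if (is.null(transcripts)) {
    say("simulating transcriptome (%d genes, seed %d)", n_genes, seed)
    sim_tx <- simulate_transcriptome(mirna, n_genes = n_genes, seed = seed)
    transcripts <- sim_tx$transcripts
  }

  say("scanning %d transcripts for %s seed sites",
      nrow(transcripts), mirna$id)
  sites <- scan_transcripts(mirna, transcripts)
  write_sites_tsv(sites, file.path(out_dir, "sites.tsv"))
  summary_tab <- summarize_sites(sites, genes = transcripts$gene_id)
  utils::write.table(summary_tab, file.path(out_dir, "site_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (is.null(expr) || is.null(meta)) {
    say("simulating mimic/NC experiment")
    # site-bearing genes (scanned == planted for synthetic input) are the
    # knockdown targets
    sim_de <- simulate_mimic_experiment(
      sites, gene_ids = transcripts$gene_id, seed = seed + 1L)
    expr <- sim_de$expr
    meta <- sim_de$meta
  }
  fc <- fold_change_table(expr, meta, config)
  shared <- call_shared_regulated(fc)
  utils::write.table(fc, file.path(out_dir, "fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(shared$shared_down, file.path(out_dir, "shared_down.txt"))
  writeLines(shared$shared_up, file.path(out_dir, "shared_up.txt"))
  top <- top_downregulated(fc, summary_tab, config$strong_down_cut)
  utils::write.table(top, file.path(out_dir, "top_downregulated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("shared regulated sets: %d down, %d up",
      length(shared$shared_down), length(shared$shared_up))

  pref <- if (length(shared$shared_down) > 0) {
    preference_report(shared$shared_down, sites, fc)
  } else NULL

  ora <- NULL
  if (is.null(gene_sets) && synthetic) {
    gene_sets <- with_seed(seed + 2L, {
      universe <- transcripts$gene_id
      sets <- lapply(1:10, function(i) {
        sample(universe,
               min(length(universe), max(5, round(length(universe) / 10))))
      })
      names(sets) <- sprintf("SET%02d", 1:10)
      sets
    })
  }
  if (!is.null(gene_sets) && length(shared$shared_down) > 0) {
    ora <- pathway_overrepresentation(
      shared$shared_down, transcripts$gene_id, gene_sets)
    utils::write.table(ora, file.path(out_dir, "overrepresentation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (is.null(cohort)) {
    say("simulating clinical cohort")
    cohort <- simulate_cohort(seed = seed + 3L)
  }
  n_pat <- ncol(cohort$expr)
  min_expr <- min(config$min_expressed_samples,
                  floor(min_expressed_frac * n_pat))
  say("screening %d miRNAs across %d patients (prevalence cutoff %d)",
      nrow(cohort$expr), n_pat, min_expr)
  screen <- screen_cohort(cohort$expr, cohort$clinical,
                          alpha = config$alpha,
                          min_expressed_samples = min_expr)
  utils::write.table(screen$associations,
                     file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screen$calls, file.path(out_dir, "biomarker_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vv <- volcano_and_venn(screen$associations)
  for (e in names(vv$volcano)) {
    utils::write.table(
      vv$volcano[[e]], file.path(out_dir, sprintf("volcano_%s.tsv", e)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  venn_named <- lapply(vv$venn, as.list)
  jsonlite::write_json(venn_named, file.path(out_dir, "venn_counts.json"),
                       auto_unbox = TRUE, digits = NA)

  summary <- list(
    mirna = mirna$id,
    data_source = if (synthetic) "synthetic" else "user-supplied",
    n_transcripts = nrow(transcripts),
    n_sites = nrow(sites),
    shared_down = length(shared$shared_down),
    shared_up = length(shared$shared_up),
    n_top_downregulated = nrow(top),
    fraction_with_sites = if (is.null(pref)) NULL else
      pref$fraction_with_sites,
    mode_distribution = if (is.null(pref)) NULL else
      as.list(pref$mode_distribution),
    region_distribution = if (is.null(pref)) NULL else
      as.list(pref$region_distribution),
    correlations = if (is.null(pref)) NULL else
      pref$correlations,
    top_pathway = if (is.null(ora)) NULL else
      list(pathway_id = ora$pathway_id[1], p = ora$p[1], q = ora$q[1]),
    cohort = list(
      n_patients = n_pat,
      n_mirnas_screened = length(unique(screen$calls$mirna_id)),
      n_oncogenic = sum(screen$calls$class == "oncogenic"),
      n_suppressor = sum(screen$calls$class == "suppressor"),
      promising = sort(screen$calls$mirna_id[screen$calls$promising]),
      venn = venn_named))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("pipeline complete; summary written to %s",
      file.path(out_dir, "summary.json"))
  invisible(summary)
}
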