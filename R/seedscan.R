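#' Canonical site-type and region labels
#'
#' `SITE_TYPES` are the three canonical seed-match classes in increasing
#' match length / priority order used throughout the package;
#' `SITE_REGIONS` the transcript regions a site can fall in.
#' @name site-vocab
NULL

#' @rdname site-vocab
#' @export
SITE_TYPES <- c("7mer-A1", "7mer-m8", "8mer")

#' @rdname site-vocab
#' @export
SITE_REGIONS <- c("5UTR", "CDS", "3UTR", "junction")

#' Construct a transcript model
#'
#' A spliced transcript sequence with its coding span in transcript
#' coordinates. Coordinates are 0-based half-open: the 5'UTR is
#' `[0, cds_start)`, the CDS `[cds_start, cds_end)` and the 3'UTR
#' `[cds_end, length)`; the three regions partition the transcript.
#' Noncoding input (no CDS span) is rejected: the analyses here are defined
#' on coding transcripts only.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param sequence 5'->3' nucleotide string (DNA or RNA alphabet).
#' @param cds_start,cds_end CDS span, 0-based half-open.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, sequence,
                             cds_start, cds_end) {
  if (is.null(cds_start) || is.null(cds_end) ||
      is.na(cds_start) || is.na(cds_end)) {
    stop("noncoding transcripts (missing CDS span) are not supported")
  }
  seq <- normalize_rna(sequence)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  n <- nchar(seq)
  if (!(cds_start >= 0L && cds_start < cds_end && cds_end <= n)) {
    stop(sprintf(
      "invalid CDS span [%d, %d) for transcript %s of length %d",
      cds_start, cds_end, transcript_id, n))
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         sequence = seq, cds_start = cds_start, cds_end = cds_end),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (gene %s), %d nt; 5'UTR [0,%d) CDS [%d,%d) 3'UTR [%d,%d)\n",
    x$transcript_id, x$gene_id, nchar(x$sequence),
    x$cds_start, x$cds_start, x$cds_end, x$cds_end, nchar(x$sequence)))
  invisible(x)
}

#' Derive target-side seed-match patterns from a mature miRNA
#'
#' The three canonical site types are defined by complementarity to the
#' miRNA seed, read on the target strand 5'->3':
#' \itemize{
#'   \item 7mer-A1: reverse complement of miRNA positions 2-7, followed by
#'     a literal adenosine opposite miRNA position 1;
#'   \item 7mer-m8: reverse complement of miRNA positions 2-8;
#'   \item 8mer: reverse complement of positions 2-8 plus the literal A.
#' }
#' The position-1 adenosine is a literal target A regardless of the
#' identity of miRNA position 1 (the canonical convention).
#'
#' @param mirna A [mature_mirna()] (or a bare sequence string).
#' @return Named character vector of length 3 with names
#'   `c("7mer-A1", "7mer-m8", "8mer")`, RNA alphabet.
#' @examples
#' build_seed_patterns(mature_mirna("miR-194", "UGUAACAGCAACUCCAUGUGGA"))
#' @export
build_seed_patterns <- function(mirna) {
  mirna <- as_mature_mirna(mirna)
  seed27 <- substr(mirna$sequence, 2L, 7L)
  seed28 <- substr(mirna$sequence, 2L, 8L)
  c("7mer-A1" = paste0(revcomp_rna(seed27), "A"),
    "7mer-m8" = revcomp_rna(seed28),
    "8mer"    = paste0(revcomp_rna(seed28), "A"))
}

#' Classify one 8-nt target window against seed-match patterns
#'
#' Longest-match priority 8mer > 7mer-m8 > 7mer-A1 assigns each window at
#' most one type, so a full 8mer is never double-counted as its nested
#' 7mers.
#'
#' @param window Length-8 nucleotide string (target strand, 5'->3').
#' @param patterns Output of [build_seed_patterns()].
#' @return One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, or `NA_character_`
#'   when the window matches no pattern.
#' @export
classify_window <- function(window, patterns) {
  window <- normalize_rna(window)
  if (nchar(window) != 8L) stop("window must be exactly 8 nt")
  if (window == patterns[["8mer"]]) return("8mer")
  if (substr(window, 1L, 7L) == patterns[["7mer-m8"]]) return("7mer-m8")
  if (substr(window, 2L, 8L) == patterns[["7mer-A1"]]) return("7mer-A1")
  NA_character_
}

empty_sites_df <- function() {
  data.frame(
    transcript_id = character(), gene_id = character(),
    start = integer(), length = integer(),
    site_type = character(), region = character(),
    stringsAsFactors = FALSE)
}

site_region <- function(start0, len, cds_start, cds_end) {
  end0 <- start0 + len
  if (end0 <= cds_start) return("5UTR")
  if (start0 >= cds_end) return("3UTR")
  if (start0 >= cds_start && end0 <= cds_end) return("CDS")
  "junction"
}

#' Locate the region of a seed site within a transcript
#'
#' The region is the one containing the whole matched window; windows that
#' straddle a region boundary are labelled `"junction"` and excluded from
#' the CDS/3'UTR headline distributions.
#'
#' @param site A one-row data frame (or list) with 0-based `start` and
#'   `length`, as produced by [find_seed_sites()].
#' @param transcript A [transcript_model()].
#' @return One of `"5UTR"`, `"CDS"`, `"3UTR"`, `"junction"`.
#' @export
annotate_site_region <- function(site, transcript) {
  start0 <- as.integer(site$start)
  len <- as.integer(site$length)
  n <- nchar(transcript$sequence)
  if (is.na(start0) || is.na(len) || start0 < 0L || start0 + len > n) {
    stop("site coordinates fall outside the transcript")
  }
  site_region(start0, len, transcript$cds_start, transcript$cds_end)
}

#' Find all canonical seed-match sites in one transcript
#'
#' Slides an 8-nt window over the transcript and classifies each window
#' with [classify_window()]'s longest-match priority. A 7mer-A1 call
#' starts at the first matched base (window offset 1); 7mer sites whose
#' span lies inside a reported 8mer span are dropped, so an 8mer is never
#' additionally reported as its nested 7mers. Only the sense strand is
#' scanned and no G:U wobble is allowed.
#'
#' @param mirna A [mature_mirna()] (or sequence string).
#' @param transcript A [transcript_model()].
#' @return Data frame with one row per site: `transcript_id`, `gene_id`,
#'   `start` (0-based), `length` (7 or 8), `site_type`, `region`; sorted
#'   by `start`. Transcripts shorter than 8 nt yield zero rows.
#' @examples
#' tx <- transcript_model("CCND1-3utr", "CCND1", "GGGGTGTTACAGGGG", 0, 4)
#' find_seed_sites("UGUAACAGCAACUCCAUGUGGA", tx)
#' @export
find_seed_sites <- function(mirna, transcript) {
  mirna <- as_mature_mirna(mirna)
  stopifnot(inherits(transcript, "transcript_model"))
  patterns <- build_seed_patterns(mirna)
  seq <- transcript$sequence
  n <- nchar(seq)
  empty <- empty_sites_df()
  if (n < 8L) return(empty)

  idx <- seq_len(n - 7L)                       # 1-based window starts
  win <- substring(seq, idx, idx + 7L)
  is8 <- win == patterns[["8mer"]]
  ism8 <- !is8 & substring(seq, idx, idx + 6L) == patterns[["7mer-m8"]]
  isa1 <- !is8 & !ism8 &
    substring(seq, idx + 1L, idx + 7L) == patterns[["7mer-A1"]]

  start0 <- c(idx[is8] - 1L, idx[ism8] - 1L, idx[isa1])
  len <- c(rep(8L, sum(is8)), rep(7L, sum(ism8)), rep(7L, sum(isa1)))
  type <- c(rep("8mer", sum(is8)), rep("7mer-m8", sum(ism8)),
            rep("7mer-A1", sum(isa1)))
  if (length(start0) == 0L) return(empty)

  # drop 7mer spans nested within an 8mer span
  if (any(len == 8L) && any(len == 7L)) {
    s8 <- start0[len == 8L]
    keep <- vapply(seq_along(start0), function(i) {
      if (len[i] == 8L) return(TRUE)
      !any(start0[i] >= s8 & start0[i] + 7L <= s8 + 8L)
    }, logical(1))
    start0 <- start0[keep]; len <- len[keep]; type <- type[keep]
  }

  ord <- order(start0, -len)
  start0 <- start0[ord]; len <- len[ord]; type <- type[ord]
  region <- vapply(seq_along(start0), function(i) {
    site_region(start0[i], len[i], transcript$cds_start, transcript$cds_end)
  }, character(1))

  data.frame(
    transcript_id = transcript$transcript_id,
    gene_id = transcript$gene_id,
    start = start0, length = len,
    site_type = type, region = region,
    stringsAsFactors = FALSE)
}

#' Scan a set of transcripts for seed sites
#'
#' @param mirna A [mature_mirna()] (or sequence string).
#' @param transcripts Either a list of [transcript_model()] objects or a
#'   data frame with columns `transcript_id`, `gene_id`, `sequence`,
#'   `cds_start`, `cds_end`.
#' @return Data frame of sites as in [find_seed_sites()], concatenated.
#' @export
scan_transcripts <- function(mirna, transcripts) {
  mirna <- as_mature_mirna(mirna)
  if (is.data.frame(transcripts)) {
    transcripts <- lapply(seq_len(nrow(transcripts)), function(i) {
      with(transcripts[i, ], transcript_model(
        transcript_id, gene_id, sequence, cds_start, cds_end))
    })
  }
  out <- lapply(transcripts, function(tx) find_seed_sites(mirna, tx))
  if (length(out) == 0L) return(empty_sites_df())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize seed sites per gene
#'
#' Aggregates a site table into one row per gene with the total site count
#' and counts broken down by site type and by region, plus compact labels
#' in the style `"7mer-A1 (3); 8mer (1)"`. Type counts and region counts
#' each sum to the total.
#'
#' @param sites Site data frame from [find_seed_sites()] /
#'   [scan_transcripts()].
#' @param genes Optional character vector of gene ids to include even when
#'   they carry zero sites.
#' @return Data frame with columns `gene_id`, `total_sites`, one
#'   `n_<type>` column per site type, one `n_<region>` column per region,
#'   and `type_label` / `region_label`.
#' @export
summarize_sites <- function(sites, genes = NULL) {
  all_genes <- union(genes, unique(sites$gene_id))
  type_cols <- paste0("n_", gsub("-", "_", SITE_TYPES))
  region_cols <- paste0("n_", SITE_REGIONS)
  if (length(all_genes) == 0L) {
    out <- data.frame(gene_id = character(), total_sites = integer(),
                      stringsAsFactors = FALSE)
    out[type_cols] <- lapply(type_cols, function(x) integer())
    out[region_cols] <- lapply(region_cols, function(x) integer())
    out$type_label <- character()
    out$region_label <- character()
    return(out)
  }
  rows <- lapply(all_genes, function(g) {
    s <- sites[sites$gene_id == g, , drop = FALSE]
    tc <- vapply(SITE_TYPES, function(t) sum(s$site_type == t), integer(1))
    rc <- vapply(SITE_REGIONS, function(r) sum(s$region == r), integer(1))
    row <- data.frame(gene_id = g, total_sites = nrow(s),
                      stringsAsFactors = FALSE)
    row[type_cols] <- as.list(tc)
    row[region_cols] <- as.list(rc)
    row$type_label <- count_label(tc)
    row$region_label <- count_label(rc)
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$gene_id), , drop = FALSE]
}

count_label <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return("")
  paste(sprintf("%s (%d)", names(counts), counts), collapse = "; ")
}
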