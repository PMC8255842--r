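#' Read sequences from a FASTA file
#'
#' Accepts DNA or RNA spelling; sequences are normalized to the RNA
#' alphabet on construction of downstream objects, not here.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("[[:space:]].*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta_sequences <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a transcript region-annotation table
#'
#' Tab-separated with columns `transcript_id`, `gene_id`, `cds_start`,
#' `cds_end` (CDS span 0-based half-open in transcript coordinates).
#' Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_transcript_annotation <- function(path) {
  ann <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0) {
    stop(sprintf("annotation %s lacks column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  ann
}

#' Assemble transcript models from a FASTA file and an annotation table
#'
#' @param fasta Path to transcript FASTA.
#' @param annotation Path to annotation TSV
#'   (see [read_transcript_annotation()]) or an equivalent data frame.
#' @return Data frame with columns `transcript_id`, `gene_id`, `sequence`,
#'   `cds_start`, `cds_end`, suitable for [scan_transcripts()].
#' @export
load_transcriptome <- function(fasta, annotation) {
  seqs <- read_fasta_sequences(fasta)
  ann <- if (is.data.frame(annotation)) annotation else
    read_transcript_annotation(annotation)
  unknown <- setdiff(ann$transcript_id, names(seqs))
  if (length(unknown) > 0) {
    stop(sprintf("annotation refers to transcripts absent from FASTA: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  data.frame(
    transcript_id = ann$transcript_id,
    gene_id = ann$gene_id,
    sequence = unname(seqs[ann$transcript_id]),
    cds_start = ann$cds_start,
    cds_end = ann$cds_end,
    stringsAsFactors = FALSE)
}

#' Write a seed-site table with 1-based inclusive coordinates
#'
#' Internally all coordinates are 0-based half-open; written reports use
#' 1-based inclusive `start_1based`/`end_1based`.
#'
#' @param sites Site data frame from [scan_transcripts()].
#' @param path Output TSV path.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- data.frame(
    transcript_id = sites$transcript_id,
    gene_id = sites$gene_id,
    start_1based = sites$start + 1L,
    end_1based = sites$start + sites$length,
    site_type = sites$site_type,
    region = sites$region,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression table
#'
#' First column is the gene id; remaining columns are samples with
#' non-negative normalized abundances (TPM-like).
#'
#' @param path TSV file.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  m
}

#' Write a genes-by-samples expression matrix as TSV
#' @param mat Numeric matrix with row names.
#' @param path Output path.
#' @param id_col Name of the identifier column (default `"gene_id"`).
#' @export
write_expression_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (`sample_id`, `cell_line`, `condition`)
#' @param path TSV file.
#' @return Data frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "condition")
  if (!all(need %in% names(meta))) {
    stop("sample metadata needs columns sample_id, cell_line, condition")
  }
  bad <- setdiff(unique(meta$condition), c("mimic", "NC"))
  if (length(bad) > 0) {
    stop(sprintf("unknown condition label(s): %s", paste(bad, collapse = ", ")))
  }
  meta
}

#' Read a clinical table
#'
#' Columns: `sample_id`, `os_days` (overall survival, days), `os_event`
#' (0 censored / 1 death), `t_stage` (1-4), `p_stage` (1-4), `m_stage`
#' (0/1); missing values as NA.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_clinical_tsv <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sample_id", "os_days", "os_event", "t_stage", "p_stage",
            "m_stage")
  missing <- setdiff(need, names(cl))
  if (length(missing) > 0) {
    stop(sprintf("clinical table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  cl
}

#' Read gene sets in GMT format
#'
#' Each line: set id, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line (need id, description, >=1 gene): %s",
                   substr(ln, 1, 60)))
    }
    unique(parts[-c(1, 2)])
  })
  names(sets) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, "na", sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
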