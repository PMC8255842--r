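#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, strips whitespace, converts T to U, and checks that only
#' A/C/G/U remain. All sequence input in the package passes through this,
#' so DNA and RNA spellings of the same sequence are interchangeable.
#'
#' @param x Character scalar, a nucleotide sequence (DNA or RNA alphabet).
#' @return Character scalar over {A,C,G,U}.
#' @export
normalize_rna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- gsub("[[:space:]]", "", toupper(x))
  x <- chartr("T", "U", x)
  if (grepl("[^ACGU]", x)) {
    stop("sequence contains characters outside the A/C/G/U (or T) alphabet")
  }
  x
}

#' Reverse complement of an RNA string
#' @param x Character scalar over {A,C,G,U}.
#' @return Character scalar, the reverse complement (also RNA alphabet).
#' @export
revcomp_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Construct a mature miRNA
#'
#' A mature miRNA is a named 5'->3' sequence; its nucleotides 2-8 (the seed
#' region) drive canonical target recognition. Sequences shorter than 8 nt
#' cannot define the three canonical site types and are rejected.
#'
#' @param id miRNA identifier (e.g. `"miR-194"`).
#' @param sequence 5'->3' nucleotide string; T is accepted and normalized
#'   to U, case-insensitive.
#' @return An object of class `mature_mirna` with elements `id` and
#'   `sequence`.
#' @examples
#' mature_mirna("miR-194", "UGUAACAGCAACUCCAUGUGGA")
#' @export
mature_mirna <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_rna(sequence)
  if (nchar(seq) < 8L) {
    stop("mature miRNA must be at least 8 nt to define seed positions 1-8")
  }
  structure(list(id = id, sequence = seq), class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat(sprintf("<mature_mirna> %s  5'-%s-3' (%d nt)\n",
              x$id, x$sequence, nchar(x$sequence)))
  invisible(x)
}

as_mature_mirna <- function(x) {
  if (inherits(x, "mature_mirna")) return(x)
  if (is.character(x) && length(x) == 1L) return(mature_mirna("miRNA", x))
  stop("expected a mature_mirna object or a single sequence string")
}
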