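# Independent brute-force oracles and small fixture builders.

MIR194_GUIDE <- "UGUAACAGCAACUCCAUGUGGA"

# reverse complement by explicit per-base lookup (independent of the
# package's chartr-based implementation)
oracle_revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  chars <- strsplit(x, "")[[1]]
  paste(comp[rev(chars)], collapse = "")
}

oracle_patterns <- function(mirna_seq) {
  mirna_seq <- chartr("T", "U", toupper(gsub("\\s", "", mirna_seq)))
  s27 <- substr(mirna_seq, 2, 7)
  s28 <- substr(mirna_seq, 2, 8)
  list(a1 = paste0(oracle_revcomp(s27), "A"),
       m8 = oracle_revcomp(s28),
       mer8 = paste0(oracle_revcomp(s28), "A"))
}

# window-by-window brute force with 8mer > 7mer-m8 > 7mer-A1 priority and
# the nested-7mer drop; returns start (0-based), length, site_type
oracle_scan <- function(mirna_seq, tx_seq) {
  p <- oracle_patterns(mirna_seq)
  tx_seq <- chartr("T", "U", toupper(tx_seq))
  n <- nchar(tx_seq)
  out <- data.frame(start = integer(), length = integer(),
                    site_type = character(), stringsAsFactors = FALSE)
  if (n < 8) return(out)
  for (i in 1:(n - 7)) {
    w <- substr(tx_seq, i, i + 7)
    if (w == p$mer8) {
      out <- rbind(out, data.frame(start = i - 1L, length = 8L,
                                   site_type = "8mer"))
    } else if (substr(w, 1, 7) == p$m8) {
      out <- rbind(out, data.frame(start = i - 1L, length = 7L,
                                   site_type = "7mer-m8"))
    } else if (substr(w, 2, 8) == p$a1) {
      out <- rbind(out, data.frame(start = i, length = 7L,
                                   site_type = "7mer-A1"))
    }
  }
  if (nrow(out) > 0) {
    eights <- out[out$length == 8L, , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (j in seq_len(nrow(out))) {
      if (out$length[j] == 7L && nrow(eights) > 0) {
        nested <- any(out$start[j] >= eights$start &
                        out$start[j] + 7L <= eights$start + 8L)
        if (nested) keep[j] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$start, -out$length), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# hypergeometric upper tail by exhaustive enumeration of all draws
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K elements are the pathway
  mean(hits >= k)
}

toy_transcript <- function(seq, cds_start = 0, cds_end = 4,
                           id = "tx", gene = "g") {
  transcript_model(id, gene, seq, cds_start, cds_end)
}

# association rows with prescribed signs, for classifier unit tests
fake_records <- function(mirna_id, survival, t, p, m) {
  sig <- function(s) if (s == "0") 0.5 else 0.01
  rbind(
    data.frame(mirna_id = mirna_id, endpoint = "survival",
               effect = 1, sign = survival, p = sig(survival),
               n_used = 100L, applicable = TRUE),
    data.frame(mirna_id = mirna_id, endpoint = "T_stage",
               effect = 1, sign = t, p = sig(t), n_used = 100L,
               applicable = TRUE),
    data.frame(mirna_id = mirna_id, endpoint = "P_stage",
               effect = 1, sign = p, p = sig(p), n_used = 100L,
               applicable = TRUE),
    data.frame(mirna_id = mirna_id, endpoint = "M_stage",
               effect = 1, sign = m, p = sig(m), n_used = 100L,
               applicable = TRUE))
}
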