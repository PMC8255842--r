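test_that("seed patterns derive from miRNA positions 1-8 as target-strand matches", {
  pat <- build_seed_patterns(mature_mirna("miR-194", MIR194_GUIDE))
  expect_equal(pat[["7mer-A1"]], "UGUUACA")   # DNA form TGTTACA
  expect_equal(pat[["7mer-m8"]], "CUGUUAC")
  expect_equal(pat[["8mer"]], "CUGUUACA")

  hom <- build_seed_patterns(mature_mirna("hom", "AAAAAAAA"))
  expect_equal(unname(hom), c("UUUUUUA", "UUUUUUU", "UUUUUUUA"))

  # structural identities hold for arbitrary miRNAs
  for (i in 1:20) {
    p <- build_seed_patterns(mature_mirna("r", random_rna(22)))
    expect_equal(p[["8mer"]], paste0(p[["7mer-m8"]], "A"))
    expect_equal(substr(p[["8mer"]], 2, 8), p[["7mer-A1"]])
  }

  expect_error(mature_mirna("short", "ACGUACG"), "at least 8")
  expect_equal(build_seed_patterns("ugua acagcaacuccauGUGGA")[["8mer"]],
               "CUGUUACA")  # whitespace/case/alphabet normalization
})

test_that("window classification follows the 8mer > 7mer-m8 > 7mer-A1 priority", {
  pat <- build_seed_patterns(MIR194_GUIDE)
  expect_equal(classify_window("CUGUUACA", pat), "8mer")
  expect_equal(classify_window("CUGUUACG", pat), "7mer-m8")
  expect_equal(classify_window("GUGUUACA", pat), "7mer-A1")
  expect_true(is.na(classify_window("GGGGGGGG", pat)))
  expect_error(classify_window("CUGUUAC", pat), "8 nt")
})

test_that("the printed wild-type heptamer gives one 3'UTR 7mer-A1 site and the mutant none", {
  wt <- toy_transcript("GGGGTGTTACAGGGG", id = "CCND1-3utr", gene = "CCND1")
  sites <- find_seed_sites(MIR194_GUIDE, wt)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$site_type, "7mer-A1")
  expect_equal(sites$region, "3UTR")
  expect_equal(sites$start, 4L)

  mut <- toy_transcript("GGGGAAAAACAGGGG")
  expect_equal(nrow(find_seed_sites(MIR194_GUIDE, mut)), 0L)
})

test_that("scanning handles 8mer detection, short input, and alphabet idempotence", {
  pass <- toy_transcript("CACAUGGAGUUGCUGUUACAUU")
  sites <- find_seed_sites(MIR194_GUIDE, pass)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$site_type, "8mer")
  expect_equal(sites$start, 12L)

  expect_equal(nrow(find_seed_sites(MIR194_GUIDE,
                                    toy_transcript("ACGUACGUA", 0, 4))), 0L)

  # DNA spelling scans identically to its RNA form
  dna <- toy_transcript("CACATGGAGTTGCTGTTACATT")
  expect_equal(find_seed_sites(MIR194_GUIDE, dna)[, -1],
               sites[, -1])
})

test_that("site regions are assigned by full containment with junction fallback", {
  tx <- toy_transcript(random_rna(30), 5, 15)
  expect_equal(annotate_site_region(list(start = 20, length = 7), tx), "3UTR")
  expect_equal(annotate_site_region(list(start = 10, length = 8), tx),
               "junction")
  expect_equal(annotate_site_region(list(start = 6, length = 8), tx), "CDS")
  expect_equal(annotate_site_region(list(start = 0, length = 5), tx), "5UTR")
  expect_error(annotate_site_region(list(start = 25, length = 8), tx),
               "outside")
})

test_that("per-gene summaries conserve totals across type and region breakdowns", {
  sites <- data.frame(
    transcript_id = "t1", gene_id = "IL6ST",
    start = c(10L, 30L, 50L, 70L), length = c(7L, 7L, 7L, 8L),
    site_type = c("7mer-A1", "7mer-A1", "7mer-A1", "8mer"),
    region = "3UTR", stringsAsFactors = FALSE)
  s <- summarize_sites(sites)
  expect_equal(s$total_sites, 4L)
  expect_equal(s$n_7mer_A1, 3L)
  expect_equal(s$n_8mer, 1L)
  expect_equal(s$n_3UTR, 4L)
  expect_equal(s$type_label, "7mer-A1 (3); 8mer (1)")

  empty <- summarize_sites(sites[0, ])
  expect_equal(nrow(empty), 0L)

  with_zero <- summarize_sites(sites, genes = c("IL6ST", "OTHER"))
  expect_equal(with_zero$total_sites[with_zero$gene_id == "OTHER"], 0L)

  # conservation on random site tables
  for (i in 1:10) {
    n <- sample(1:12, 1)
    rs <- data.frame(
      transcript_id = "t", gene_id = "g",
      start = seq_len(n) * 20L, length = 7L,
      site_type = sample(SITE_TYPES, n, replace = TRUE),
      region = sample(SITE_REGIONS, n, replace = TRUE),
      stringsAsFactors = FALSE)
    s <- summarize_sites(rs)
    expect_equal(s$n_7mer_A1 + s$n_7mer_m8 + s$n_8mer, s$total_sites)
    expect_equal(s$n_5UTR + s$n_CDS + s$n_3UTR + s$n_junction,
                 s$total_sites)
  }
})

test_that("scanning agrees with the window-by-window brute force on random inputs", {
  set.seed(11)
  for (i in 1:200) {
    mir <- random_rna(sample(18:24, 1))
    len <- sample(8:500, 1)
    tx_seq <- random_rna(len)
    cds_start <- sample(0:(len - 2), 1)
    cds_end <- sample((cds_start + 1):len, 1)
    tx <- transcript_model("t", "g", tx_seq, cds_start, cds_end)
    got <- find_seed_sites(mir, tx)
    want <- oracle_scan(mir, tx_seq)
    expect_equal(got$start, want$start)
    expect_equal(got$length, want$length)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("no reported 7mer is nested inside a reported 8mer", {
  # a seed whose 7mer-A1 and 7mer-m8 patterns coincide (A-homopolymer
  # target side) makes every 8mer occurrence also match both 7mers in the
  # flanking windows; only the 8mer must survive
  tx <- toy_transcript("GGAAAAAAAAGG", 0, 2)
  sites <- find_seed_sites("AUUUUUUUGG", tx)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$site_type, "8mer")
  expect_equal(sites$start, 2L)

  set.seed(12)
  # seed-rich miRNA/background make overlapping matches likely
  for (i in 1:50) {
    mir <- paste0("A", paste(sample(c("A", "U"), 21, replace = TRUE),
                             collapse = ""))
    tx <- transcript_model("t", "g", random_rna(300), 10, 150)
    sites <- find_seed_sites(mir, tx)
    if (nrow(sites) < 2) next
    s8 <- sites[sites$length == 8, , drop = FALSE]
    s7 <- sites[sites$length == 7, , drop = FALSE]
    if (nrow(s8) == 0 || nrow(s7) == 0) next
    for (j in seq_len(nrow(s7))) {
      expect_false(any(s7$start[j] >= s8$start &
                         s7$start[j] + 7 <= s8$start + 8))
    }
  }
})

test_that("invalid transcript models are rejected", {
  expect_error(transcript_model("t", "g", "ACGUACGU", NA, NA), "noncoding")
  expect_error(transcript_model("t", "g", "ACGUACGU", 5, 3), "invalid CDS")
  expect_error(transcript_model("t", "g", "ACGUACGU", 0, 20), "invalid CDS")
  expect_error(transcript_model("t", "g", "ACGXACGU", 0, 4), "alphabet")
})
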