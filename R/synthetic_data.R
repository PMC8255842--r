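#' Evaluate code under a fixed, restored RNG state
#'
#' Runs `code` with a Mersenne-Twister stream seeded at `seed` and
#' restores the caller's RNG state afterwards, so generation is a pure
#' function of its arguments.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Default per-gene site plan
#'
#' Draws, per gene, whether it carries seed sites and their
#' types/regions. Defaults emulate a mimic-transfection target set:
#' 60% of genes carry at least one site, 1-3 sites per target gene, the
#' three canonical site types near-equally likely, and 86% of sites in
#' the 3'UTR versus 14% in the CDS.
#'
#' @param n_genes Number of genes.
#' @param p_target Probability a gene carries sites (default 0.6).
#' @param count_probs Probabilities of 1, 2, 3 sites given a target
#'   (default `c(0.6, 0.3, 0.1)`).
#' @param type_probs Named probabilities over site types (default equal).
#' @param region_probs Named probabilities over planting regions (default
#'   `c("3UTR" = 0.86, "CDS" = 0.14)`).
#' @return Data frame with one row per planned site: `gene`, `site_type`,
#'   `region` (genes without sites are absent).
#' @export
default_site_plan <- function(n_genes, p_target = 0.6,
                              count_probs = c(0.6, 0.3, 0.1),
                              type_probs = c("7mer-A1" = 1/3,
                                             "7mer-m8" = 1/3,
                                             "8mer" = 1/3),
                              region_probs = c("3UTR" = 0.86,
                                               "CDS" = 0.14)) {
  is_target <- stats::runif(n_genes) < p_target
  rows <- lapply(which(is_target), function(g) {
    k <- sample(seq_along(count_probs), 1, prob = count_probs)
    data.frame(
      gene = g,
      site_type = sample(names(type_probs), k, replace = TRUE,
                         prob = type_probs),
      region = sample(names(region_probs), k, replace = TRUE,
                      prob = region_probs),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

random_background <- function(len, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  sample(names(probs), len, replace = TRUE, prob = probs)
}

# resample every window that matches a seed pattern until none remains
scrub_matches <- function(chars, patterns, gc, max_iter = 100) {
  seq_str <- paste(chars, collapse = "")
  for (iter in seq_len(max_iter)) {
    hits <- pattern_hits(seq_str, patterns)
    if (length(hits) == 0L) return(strsplit(seq_str, "")[[1]])
    for (h in hits) {
      span <- h:min(h + 7L, nchar(seq_str))
      repl <- random_background(length(span), gc)
      substr(seq_str, span[1], span[length(span)]) <-
        paste(repl, collapse = "")
    }
  }
  stop("could not scrub accidental seed matches from background sequence")
}

# 1-based start positions of any occurrence of any pattern (incl. the A1
# heptamer anywhere, so scrubbed backgrounds carry no detectable site)
pattern_hits <- function(seq_str, patterns) {
  hits <- integer()
  for (p in unique(patterns)) {
    from <- 1L
    repeat {
      i <- regexpr(p, substr(seq_str, from, nchar(seq_str)), fixed = TRUE)
      if (i == -1L) break
      hits <- c(hits, from + as.integer(i) - 1L)
      from <- from + as.integer(i)
    }
  }
  sort(unique(hits))
}

plant_site <- function(chars, type, region, patterns, cds_start, cds_end,
                       occupied) {
  len <- if (type == "8mer") 8L else 7L
  pat <- patterns[[type]]
  n <- length(chars)
  bounds <- switch(region,
                   "5UTR" = c(0L, cds_start),
                   "CDS" = c(cds_start, cds_end),
                   "3UTR" = c(cds_end, n))
  lo <- bounds[1]; hi <- bounds[2] - len          # 0-based start range
  if (type == "7mer-A1") lo <- max(lo, 1L)        # needs a preceding base
  if (type != "7mer-A1") hi <- min(hi, n - 8L)    # needs a trailing base
  if (hi < lo) return(NULL)
  cand <- lo:hi
  # keep one spacer base around existing plants so spans stay distinct
  free <- vapply(cand, function(s) {
    !any(occupied >= s - 8L & occupied <= s + len)
  }, logical(1))
  cand <- cand[free]
  if (length(cand) == 0L) return(NULL)
  s <- if (length(cand) == 1L) cand else sample(cand, 1L)
  chars[(s + 1L):(s + len)] <- strsplit(pat, "")[[1]]
  if (type == "7mer-m8" && s + len < n && chars[s + len + 1L] == "A") {
    chars[s + len + 1L] <- "G"                    # would upgrade to 8mer
  }
  list(chars = chars, start = s, length = len)
}

#' Generate a synthetic transcriptome with planted seed sites
#'
#' Builds random-background transcripts for a given miRNA, scrubbing the
#' background of accidental seed matches by rejection, then plants sites
#' of chosen type and region at recorded positions. Each transcript is
#' re-scanned after planting and regenerated if the detected sites differ
#' from the plan, so the returned truth table is exhaustive: scanning the
#' output recovers exactly the planted sites.
#'
#' @param mirna A [mature_mirna()] (or sequence string).
#' @param n_genes Number of genes (one transcript each; default 200).
#' @param site_plan Data frame `gene`, `site_type`, `region` as from
#'   [default_site_plan()]; `NULL` (default) draws one under the default
#'   plan.
#' @param len_range Transcript length bounds, uniform (default 300-1500).
#' @param utr5_frac,cds_frac Fractions of the transcript given to the
#'   5'UTR and CDS (defaults 0.1 and 0.5; the remainder is 3'UTR).
#' @param gc GC content of the background (default 0.5).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List: `transcripts` (data frame `transcript_id`, `gene_id`,
#'   `sequence`, `cds_start`, `cds_end`), `truth` (planted sites with
#'   `gene_id`, `transcript_id`, `start`, `length`, `site_type`,
#'   `region`), and `mirna`.
#' @export
simulate_transcriptome <- function(mirna, n_genes = 200, site_plan = NULL,
                                   len_range = c(300, 1500),
                                   utr5_frac = 0.1, cds_frac = 0.5,
                                   gc = 0.5, seed = 1) {
  mirna <- as_mature_mirna(mirna)
  patterns <- build_seed_patterns(mirna)
  with_seed(seed, {
    if (is.null(site_plan)) site_plan <- default_site_plan(n_genes)
    if (is.null(site_plan)) {
      site_plan <- data.frame(gene = integer(), site_type = character(),
                              region = character(), stringsAsFactors = FALSE)
    }
    tx_rows <- vector("list", n_genes)
    truth_rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("G%04d", g)
      tx_id <- sprintf("T%04d", g)
      plan <- site_plan[site_plan$gene == g, , drop = FALSE]
      for (attempt in 1:50) {
        len <- sample(len_range[1]:len_range[2], 1L)
        cds_start <- as.integer(round(utr5_frac * len))
        cds_end <- as.integer(cds_start + round(cds_frac * len))
        if (cds_start < 1L) cds_start <- 1L
        if (cds_end <= cds_start) cds_end <- cds_start + 1L
        if (cds_end >= len) cds_end <- len - 1L
        chars <- scrub_matches(random_background(len, gc), patterns, gc)
        planted <- NULL
        occupied <- integer()
        ok <- TRUE
        if (nrow(plan) > 0L) {
          for (i in seq_len(nrow(plan))) {
            res <- plant_site(chars, plan$site_type[i], plan$region[i],
                              patterns, cds_start, cds_end, occupied)
            if (is.null(res)) { ok <- FALSE; break }
            chars <- res$chars
            occupied <- c(occupied, res$start)
            planted <- rbind(planted, data.frame(
              gene_id = gene_id, transcript_id = tx_id,
              start = res$start, length = res$length,
              site_type = plan$site_type[i], region = plan$region[i],
              stringsAsFactors = FALSE))
          }
        }
        if (!ok) next
        tx <- transcript_model(tx_id, gene_id, paste(chars, collapse = ""),
                               cds_start, cds_end)
        found <- find_seed_sites(mirna, tx)
        want <- if (is.null(planted)) {
          empty_sites_df()
        } else {
          planted[order(planted$start),
                  c("transcript_id", "gene_id", "start", "length",
                    "site_type", "region")]
        }
        same <- nrow(found) == nrow(want) &&
          (nrow(found) == 0L ||
             all(found$start == want$start & found$length == want$length &
                   found$site_type == want$site_type &
                   found$region == want$region))
        if (same) {
          tx_rows[[g]] <- data.frame(
            transcript_id = tx_id, gene_id = gene_id,
            sequence = tx$sequence, cds_start = cds_start,
            cds_end = cds_end, stringsAsFactors = FALSE)
          truth_rows[[g]] <- planted
          break
        }
      }
      if (is.null(tx_rows[[g]])) {
        stop(sprintf("could not realise the site plan for gene %d", g))
      }
    }
    list(
      transcripts = do.call(rbind, c(tx_rows, list(make.row.names = FALSE))),
      truth = {
        tr <- truth_rows[!vapply(truth_rows, is.null, logical(1))]
        if (length(tr) == 0L) {
          df <- empty_sites_df()
          df[, c("gene_id", "transcript_id", "start", "length",
                 "site_type", "region")]
        } else {
          do.call(rbind, c(tr, list(make.row.names = FALSE)))
        }
      },
      mirna = mirna)
  })
}

#' Simulate a paired mimic / negative-control expression experiment
#'
#' Two cell lines, each with mimic and negative-control (NC) samples.
#' NC abundance is log-normal per gene; the mimic abundance multiplies it
#' by `2^(delta * e + noise)` where `e` is 1 for any site-bearing gene
#' under saturation (effect independent of site count, the regime in
#' which fold change should not correlate with site count) or the site
#' count otherwise, and `noise ~ N(0, sigma)` per gene, cell line and
#' replicate.
#'
#' @param truth Planted-site truth table from [simulate_transcriptome()]
#'   (or any data frame with `gene_id` rows, one per site).
#' @param gene_ids All gene ids in the experiment (site-free genes
#'   included).
#' @param cell_lines Cell-line labels (default `c("line1", "line2")`).
#' @param delta Per-target knockdown in log2 units (default -1).
#' @param sigma SD of the log2 noise (default 0.1).
#' @param saturation Effect independent of site count (default TRUE).
#' @param n_reps Replicates per cell line and condition (default 1).
#' @param base_meanlog,base_sdlog Log-normal parameters of the NC
#'   abundance (defaults log(100) and 0.6, a well-expressed TPM range).
#' @param seed Integer seed.
#' @return List: `expr` (genes x samples matrix), `meta` (data frame
#'   `sample_id`, `cell_line`, `condition`), `truth` (per-gene
#'   `gene_id`, `site_count`, `is_target`).
#' @export
simulate_mimic_experiment <- function(truth, gene_ids,
                                      cell_lines = c("line1", "line2"),
                                      delta = -1, sigma = 0.1,
                                      saturation = TRUE, n_reps = 1,
                                      base_meanlog = log(100),
                                      base_sdlog = 0.6, seed = 1) {
  counts <- table(factor(truth$gene_id, levels = gene_ids))
  site_count <- as.integer(counts)
  e <- if (saturation) as.numeric(site_count > 0) else site_count
  n_genes <- length(gene_ids)
  with_seed(seed, {
    cols <- list()
    meta <- NULL
    for (cl in cell_lines) {
      nc_mu <- matrix(
        stats::rlnorm(n_genes * n_reps, base_meanlog, base_sdlog),
        nrow = n_genes)
      noise <- matrix(stats::rnorm(n_genes * n_reps, 0, sigma),
                      nrow = n_genes)
      for (r in seq_len(n_reps)) {
        nc_id <- sprintf("%s_NC_%d", cl, r)
        mm_id <- sprintf("%s_mimic_%d", cl, r)
        cols[[nc_id]] <- nc_mu[, r]
        cols[[mm_id]] <- nc_mu[, r] * 2^(delta * e + noise[, r])
        meta <- rbind(meta, data.frame(
          sample_id = c(nc_id, mm_id), cell_line = cl,
          condition = c("NC", "mimic"), stringsAsFactors = FALSE))
      }
    }
    expr <- do.call(cbind, cols)
    rownames(expr) <- gene_ids
    list(expr = expr, meta = meta,
         truth = data.frame(gene_id = gene_ids, site_count = site_count,
                            is_target = site_count > 0,
                            stringsAsFactors = FALSE))
  })
}

#' Default planted-effect plan for a synthetic cohort
#'
#' Four suppressor-pattern and four oncogenic-pattern miRNAs (mirroring a
#' small panel of promising biomarkers) among null miRNAs. Effect sizes
#' are per standard deviation of expression and were fixed by a power
#' calculation so that each endpoint detects a planted effect with at
#' least ~80% power in a cohort of a few hundred patients.
#'
#' @param n_null Number of null miRNAs (default 22, for 30 total).
#' @param log_hr Log hazard ratio per expression SD (default 0.45).
#' @param stage_shift Ordinal-logit shift per expression SD (default 0.8).
#' @param m_shift Metastasis-logit shift per expression SD (default 1.1).
#' @return Data frame `mirna_id`, `class`, `log_hr`, `stage_shift`,
#'   `m_shift` (signed per class; null rows are zero).
#' @export
default_cohort_plan <- function(n_null = 22, log_hr = 0.45,
                                stage_shift = 0.8, m_shift = 1.1) {
  planted <- data.frame(
    mirna_id = c(sprintf("supp-%d", 1:4), sprintf("onco-%d", 1:4)),
    class = rep(c("suppressor", "oncogenic"), each = 4),
    stringsAsFactors = FALSE)
  orient <- ifelse(planted$class == "oncogenic", 1, -1)
  planted$log_hr <- orient * log_hr
  planted$stage_shift <- orient * stage_shift
  planted$m_shift <- orient * m_shift
  nulls <- data.frame(
    mirna_id = sprintf("null-%02d", seq_len(n_null)),
    class = "none", log_hr = 0, stage_shift = 0, m_shift = 0,
    stringsAsFactors = FALSE)
  rbind(planted, nulls)
}

#' Simulate a clinical cohort with planted miRNA-outcome associations
#'
#' Expression is Gaussian on the log2-TPM scale. Survival times are
#' exponential with a per-patient hazard `lambda0 * exp(sum_j log_hr_j *
#' z_ij)` over the planted miRNAs (oncogenic: positive log HR, higher
#' expression hastens death); censoring is independent exponential at the
#' requested rate. T and pathological stages are cut from an ordinal
#' logistic latent shifted by the planted stage effects; M stage is
#' Bernoulli on a logit shifted by the planted metastasis effects.
#'
#' @param n_patients Cohort size (default 391, a TCGA-scale gastric
#'   cohort).
#' @param plan Planted-effect table (see [default_cohort_plan()]).
#' @param censoring Approximate censoring probability (default 0.35); a
#'   value >= 1 censors every patient.
#' @param median_days Baseline median survival in days (default 1000).
#' @param expr_mean,expr_sd Location and scale of the log2-TPM expression
#'   (defaults 6 and 1.5).
#' @param m_base Baseline metastasis prevalence (default 0.12).
#' @param seed Integer seed.
#' @return List: `expr` (miRNAs x patients log2-TPM matrix), `clinical`
#'   (data frame `sample_id`, `os_days`, `os_event`, `t_stage`,
#'   `p_stage`, `m_stage`), `truth` (the plan).
#' @export
simulate_cohort <- function(n_patients = 391,
                            plan = default_cohort_plan(),
                            censoring = 0.35, median_days = 1000,
                            expr_mean = 6, expr_sd = 1.5,
                            m_base = 0.12, seed = 1) {
  n_mir <- nrow(plan)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_mir * n_patients), nrow = n_mir,
                dimnames = list(plan$mirna_id, NULL))
    expr <- expr_mean + expr_sd * z
    colnames(expr) <- sprintf("P%04d", seq_len(n_patients))

    lp_surv <- drop(crossprod(z, plan$log_hr))
    lambda0 <- log(2) / median_days
    t_true <- stats::rexp(n_patients, rate = lambda0 * exp(lp_surv))
    if (censoring >= 1) {
      os_days <- stats::rexp(n_patients, rate = lambda0)
      os_event <- rep(0L, n_patients)
    } else if (censoring <= 0) {
      os_days <- t_true
      os_event <- rep(1L, n_patients)
    } else {
      c_rate <- lambda0 * censoring / (1 - censoring)
      c_time <- stats::rexp(n_patients, rate = c_rate)
      os_days <- pmin(t_true, c_time)
      os_event <- as.integer(t_true <= c_time)
    }

    cut_stage <- function(shift) {
      latent <- drop(crossprod(z, shift)) + stats::rlogis(n_patients)
      cuts <- stats::quantile(latent, probs = c(0.25, 0.60, 0.85))
      as.integer(cut(latent, c(-Inf, cuts, Inf), labels = FALSE))
    }
    t_stage <- cut_stage(plan$stage_shift)
    p_stage <- cut_stage(plan$stage_shift)
    lp_m <- stats::qlogis(m_base) + drop(crossprod(z, plan$m_shift))
    m_stage <- stats::rbinom(n_patients, 1, stats::plogis(lp_m))

    clinical <- data.frame(
      sample_id = colnames(expr),
      os_days = pmax(os_days, 1e-3),
      os_event = os_event,
      t_stage = t_stage, p_stage = p_stage, m_stage = m_stage,
      stringsAsFactors = FALSE)
    list(expr = expr, clinical = clinical, truth = plan)
  })
}
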