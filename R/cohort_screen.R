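#' Prevalence filter for cohort miRNAs
#'
#' Keeps miRNAs detected (abundance above zero) in more than
#' `min_expressed_samples` patients; rarely-detected miRNAs give unstable
#' median splits and rank tests.
#'
#' @param expr miRNAs-by-patients numeric matrix (log2-TPM-like).
#' @param min_expressed_samples Strict lower bound on the number of
#'   patients with non-zero abundance (default 300).
#' @return Matrix restricted to the retained miRNAs.
#' @export
filter_mirnas <- function(expr, min_expressed_samples = 300) {
  keep <- rowSums(expr > 0, na.rm = TRUE) > min_expressed_samples
  expr[keep, , drop = FALSE]
}

assoc_record <- function(mirna_id, endpoint, effect, sign, p, n_used,
                         applicable = TRUE) {
  data.frame(mirna_id = mirna_id, endpoint = endpoint,
             effect = effect, sign = sign, p = p, n_used = n_used,
             applicable = applicable, stringsAsFactors = FALSE)
}

na_record <- function(mirna_id, endpoint, n_used) {
  assoc_record(mirna_id, endpoint, NA_real_, "0", NA_real_, n_used,
               applicable = FALSE)
}

#' Survival association of one miRNA (median-split log-rank)
#'
#' Patients are dichotomized at the median expression (ties go to the low
#' group: high means strictly above the median), compared with the
#' log-rank test. The sign is "+" when the high-expression group has the
#' longer estimated median survival (higher expression favorable), "-"
#' when shorter, and "0" when p >= alpha. When a group's median survival
#' is not reached, direction falls back to the observed-vs-expected death
#' ratio of the high group. The effect is the signed -log10 p.
#'
#' @param x Numeric expression vector (one miRNA across patients).
#' @param time Survival time in days (> 0).
#' @param event Event indicator (1 death, 0 censored).
#' @param alpha Significance level (default 0.05).
#' @param mirna_id Identifier used in the output (default "miRNA").
#' @return One-row data frame: `mirna_id`, `endpoint`, `effect`, `sign`,
#'   `p`, `n_used`, `applicable`.
#' @export
survival_association <- function(x, time, event, alpha = 0.05,
                                 mirna_id = "miRNA") {
  ok <- is.finite(x) & is.finite(time) & !is.na(event) & time > 0
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  n <- length(x)
  if (n < 4L || sum(event) < 1L) {
    return(na_record(mirna_id, "survival", n))
  }
  high <- x > stats::median(x)
  if (sum(high) < 2L || sum(!high) < 2L) {
    return(na_record(mirna_id, "survival", n))
  }
  group <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  med <- summary(fit)$table[, "median"]
  direction <- if (!anyNA(med) && med["group=high"] != med["group=low"]) {
    if (med["group=high"] > med["group=low"]) 1 else -1
  } else {
    # deaths deficit in the high group => favorable
    if (sd$obs[2] < sd$exp[2]) 1 else -1
  }
  sign <- if (p < alpha) if (direction > 0) "+" else "-" else "0"
  effect <- direction * -log10(max(p, .Machine$double.xmin))
  assoc_record(mirna_id, "survival", effect, sign, p, n)
}

#' Ordinal stage association of one miRNA (Spearman)
#'
#' Spearman rank correlation of expression against the ordinal stage
#' (T stage or pathological stage coded 1-4; sub-stages collapsed to the
#' integer). Sign is the sign of rho when p < alpha, else "0"; the effect
#' is the signed -log10 p.
#'
#' @param x Numeric expression vector.
#' @param stage Ordinal stage per patient (NA allowed).
#' @param endpoint Label, e.g. `"T_stage"` or `"P_stage"`.
#' @inheritParams survival_association
#' @return One-row association data frame (see [survival_association()]).
#' @export
stage_association <- function(x, stage, endpoint = "T_stage",
                              alpha = 0.05, mirna_id = "miRNA") {
  ok <- is.finite(x) & is.finite(stage)
  x <- x[ok]; stage <- stage[ok]
  n <- length(x)
  if (n < 3L || length(unique(stage)) < 2L || length(unique(x)) < 2L) {
    return(na_record(mirna_id, endpoint, n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, stage, method = "spearman", exact = FALSE))
  p <- ct$p.value
  rho <- unname(ct$estimate)
  sign <- if (is.finite(p) && p < alpha) if (rho > 0) "+" else "-" else "0"
  effect <- sign(rho) * -log10(max(p, .Machine$double.xmin))
  assoc_record(mirna_id, endpoint, effect, sign, p, n)
}

#' Metastasis association of one miRNA (Mann-Whitney)
#'
#' Two-sided Mann-Whitney U test of expression between M0 and M1
#' patients. Sign is "+" when median expression is higher in M1 and
#' p < alpha, "-" for the reverse, else "0".
#'
#' @param x Numeric expression vector.
#' @param m_stage Metastasis status per patient (0/1, NA allowed).
#' @inheritParams survival_association
#' @return One-row association data frame.
#' @export
metastasis_association <- function(x, m_stage, alpha = 0.05,
                                   mirna_id = "miRNA") {
  ok <- is.finite(x) & !is.na(m_stage)
  x <- x[ok]; m <- m_stage[ok]
  n <- length(x)
  x0 <- x[m == 0]; x1 <- x[m == 1]
  if (length(x0) < 1L || length(x1) < 1L) {
    return(na_record(mirna_id, "M_stage", n))
  }
  # exact U distribution when sample sizes are small and tie-free,
  # normal approximation otherwise (wilcox.test's default policy)
  wt <- suppressWarnings(stats::wilcox.test(x1, x0))
  p <- wt$p.value
  dmed <- stats::median(x1) - stats::median(x0)
  if (!is.finite(p)) return(na_record(mirna_id, "M_stage", n))
  sign <- if (p < alpha && dmed != 0) if (dmed > 0) "+" else "-" else "0"
  effect <- sign(dmed) * -log10(max(p, .Machine$double.xmin))
  assoc_record(mirna_id, "M_stage", effect, sign, p, n)
}

#' Classify one miRNA from its four signed associations
#'
#' The oncogenic pattern is: higher expression associates with worse
#' outcome (survival "-", stage "+", M "+"); the suppressor pattern is
#' the mirror image. A miRNA is classified when at least two endpoints
#' are significant, all significant signs fit one pattern, and none
#' contradicts it; contradictory significant signs yield class "none"
#' with a conflict flag. It is "promising" when all three endpoint groups
#' (survival; T or pathological stage; M stage) are significant with
#' consistent signs.
#'
#' @param records Data frame of association rows for one miRNA covering
#'   endpoints `survival`, `T_stage`, `P_stage`, `M_stage` (rows flagged
#'   not-applicable count as non-significant).
#' @return One-row data frame: `mirna_id`, `class`
#'   (`oncogenic`/`suppressor`/`none`), `n_significant`,
#'   `endpoints_significant`, `promising`, `conflict`.
#' @export
classify_biomarker <- function(records) {
  stopifnot(length(unique(records$mirna_id)) == 1L)
  need <- c("survival", "T_stage", "P_stage", "M_stage")
  missing <- setdiff(need, records$endpoint)
  if (length(missing) > 0) {
    stop(sprintf("missing endpoint record(s): %s",
                 paste(missing, collapse = ", ")))
  }
  sgn <- function(e) records$sign[match(e, records$endpoint)]
  # orientation votes: +1 oncogenic-consistent, -1 suppressor-consistent
  vote <- c(
    survival = switch(sgn("survival"), "-" = 1, "+" = -1, 0),
    T_stage = switch(sgn("T_stage"), "+" = 1, "-" = -1, 0),
    P_stage = switch(sgn("P_stage"), "+" = 1, "-" = -1, 0),
    M_stage = switch(sgn("M_stage"), "+" = 1, "-" = -1, 0))
  n_sig <- sum(vote != 0)
  conflict <- any(vote > 0) && any(vote < 0)
  class <- "none"
  if (!conflict && n_sig >= 2L) {
    if (any(vote > 0)) class <- "oncogenic"
    if (any(vote < 0)) class <- "suppressor"
  }
  groups_sig <- c(vote["survival"] != 0,
                  vote["T_stage"] != 0 || vote["P_stage"] != 0,
                  vote["M_stage"] != 0)
  promising <- !conflict && class != "none" && all(groups_sig)
  data.frame(
    mirna_id = records$mirna_id[1],
    class = class,
    n_significant = n_sig,
    endpoints_significant = paste(
      records$endpoint[match(names(vote)[vote != 0], records$endpoint)],
      collapse = ";"),
    promising = promising,
    conflict = conflict,
    stringsAsFactors = FALSE)
}

#' Screen a cohort for prognostic miRNAs
#'
#' Runs the four signed association tests for every miRNA passing the
#' prevalence filter, then classifies each as oncogenic-pattern,
#' suppressor-pattern, or neither.
#'
#' @param expr miRNAs-by-patients matrix (log2-TPM-like); columns must
#'   match `clinical$sample_id`.
#' @param clinical Clinical data frame (see [read_clinical_tsv()]).
#' @param alpha Significance level (default 0.05).
#' @param min_expressed_samples Prevalence cutoff (default 300); set 0 to
#'   keep all miRNAs.
#' @return List: `associations` (long data frame, one row per miRNA x
#'   endpoint) and `calls` (one row per miRNA, Table-style signs plus the
#'   classification).
#' @export
screen_cohort <- function(expr, clinical, alpha = 0.05,
                          min_expressed_samples = 300) {
  stopifnot(all(c("sample_id", "os_days", "os_event", "t_stage",
                  "p_stage", "m_stage") %in% names(clinical)))
  idx <- match(colnames(expr), clinical$sample_id)
  if (anyNA(idx)) stop("expression columns missing from the clinical table")
  cl <- clinical[idx, , drop = FALSE]
  expr <- filter_mirnas(expr, min_expressed_samples)
  if (nrow(expr) == 0L) stop("no miRNA passes the prevalence filter")
  assoc <- lapply(rownames(expr), function(id) {
    x <- expr[id, ]
    rbind(
      survival_association(x, cl$os_days, cl$os_event, alpha, id),
      stage_association(x, cl$t_stage, "T_stage", alpha, id),
      stage_association(x, cl$p_stage, "P_stage", alpha, id),
      metastasis_association(x, cl$m_stage, alpha, id))
  })
  associations <- do.call(rbind, c(assoc, list(make.row.names = FALSE)))
  calls <- do.call(rbind, c(
    lapply(assoc, classify_biomarker), list(make.row.names = FALSE)))
  signs <- do.call(rbind, lapply(assoc, function(a) {
    data.frame(
      mirna_id = a$mirna_id[1],
      survival_sign = a$sign[a$endpoint == "survival"],
      t_stage_sign = a$sign[a$endpoint == "T_stage"],
      p_stage_sign = a$sign[a$endpoint == "P_stage"],
      m_stage_sign = a$sign[a$endpoint == "M_stage"],
      stringsAsFactors = FALSE)
  }))
  calls <- merge(signs, calls, by = "mirna_id", sort = TRUE)
  list(associations = associations, calls = calls)
}

#' Volcano tables and Venn membership counts
#'
#' Builds, per endpoint, a volcano table (signed effect, -log10 p,
#' significance flag) and, per direction class, the three-way Venn counts
#' over the endpoint groups survival / stage (T or pathological) / M.
#' The "unfavorable" Venn collects oncogenic-direction significance
#' (survival "-", stage "+", M "+"); the "favorable" Venn the mirror.
#'
#' @param associations Long association table from [screen_cohort()].
#' @return List: `volcano` (named list of per-endpoint data frames) and
#'   `venn` (list `unfavorable`/`favorable`, each a named count vector
#'   over the 7 Venn regions, names like `"survival&stage&M"`).
#' @export
volcano_and_venn <- function(associations) {
  stopifnot(nrow(associations) > 0)
  endpoints <- unique(associations$endpoint)
  volcano <- lapply(endpoints, function(e) {
    a <- associations[associations$endpoint == e, , drop = FALSE]
    data.frame(mirna_id = a$mirna_id, effect = a$effect,
               neglog10_p = -log10(a$p), sign = a$sign,
               significant = a$sign != "0", stringsAsFactors = FALSE)
  })
  names(volcano) <- endpoints
  wide <- function(e) {
    a <- associations[associations$endpoint == e, , drop = FALSE]
    stats::setNames(a$sign, a$mirna_id)
  }
  ids <- unique(associations$mirna_id)
  sv <- wide("survival")[ids]
  ts <- wide("T_stage")[ids]
  ps <- wide("P_stage")[ids]
  ms <- wide("M_stage")[ids]
  venn_counts <- function(in_surv, in_stage, in_m) {
    regions <- c("survival", "stage", "M", "survival&stage",
                 "survival&M", "stage&M", "survival&stage&M")
    member <- cbind(surv = in_surv, stage = in_stage, m = in_m)
    counts <- c(
      sum(member[, 1] & !member[, 2] & !member[, 3]),
      sum(!member[, 1] & member[, 2] & !member[, 3]),
      sum(!member[, 1] & !member[, 2] & member[, 3]),
      sum(member[, 1] & member[, 2] & !member[, 3]),
      sum(member[, 1] & !member[, 2] & member[, 3]),
      sum(!member[, 1] & member[, 2] & member[, 3]),
      sum(member[, 1] & member[, 2] & member[, 3]))
    stats::setNames(counts, regions)
  }
  venn <- list(
    unfavorable = venn_counts(sv == "-", ts == "+" | ps == "+", ms == "+"),
    favorable = venn_counts(sv == "+", ts == "-" | ps == "-", ms == "-"))
  list(volcano = volcano, venn = venn)
}
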