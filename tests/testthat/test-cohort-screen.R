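test_that("the prevalence filter keeps miRNAs detected in more than the cutoff", {
  expr <- rbind(
    common = c(rep(1, 350), rep(0, 41)),
    rare = c(rep(1, 10), rep(0, 381)))
  expect_equal(rownames(filter_mirnas(expr, 300)), "common")
  expect_equal(nrow(filter_mirnas(expr, 0)), 2L)
  expect_equal(nrow(filter_mirnas(expr, 350)), 0L)  # strict inequality
})

test_that("survival association signs follow the median-split direction", {
  # identical curves in both groups: null
  x <- rep(c(1, 2), each = 20)
  time <- rep(c(100, 200, 300, 400), 10)
  event <- rep(1, 40)
  r <- survival_association(x, time, event)
  expect_equal(r$p, 1, tolerance = 1e-9)
  expect_equal(r$sign, "0")

  # planted hazard ratio 2 for low expressors: high expression favorable
  set.seed(41)
  n <- 300
  x <- rnorm(n)
  rate <- ifelse(x > median(x), 0.001, 0.002)
  time <- rexp(n, rate)
  r <- survival_association(x, time, rep(1, n))
  expect_equal(r$sign, "+")
  expect_lt(r$p, 0.05)
  expect_gt(r$effect, 0)

  # all censored: not applicable
  r_na <- survival_association(x, time, rep(0, n))
  expect_false(r_na$applicable)
  expect_equal(r_na$sign, "0")
})

test_that("planted survival effects are detected in most replicates", {
  hits <- vapply(1:50, function(i) {
    set.seed(400 + i)
    n <- 300
    x <- rnorm(n)
    rate <- ifelse(x > median(x), 0.001, 0.002)  # hazard ratio 2 for low
    time <- rexp(n, rate)
    cens <- rexp(n, 0.0005)
    r <- survival_association(x, pmin(time, cens),
                              as.integer(time <= cens))
    r$sign == "+" && r$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("stage association is signed Spearman with degenerate handling", {
  stage <- rep(1:4, each = 10)
  x <- stage + seq(0, 0.9, length.out = 40)  # strictly increasing
  r <- stage_association(x, stage)
  expect_equal(r$sign, "+")
  expect_lt(r$p, 0.05)

  r_const <- stage_association(x, rep(2, 40))
  expect_false(r_const$applicable)

  # type-I error control on permuted stage
  set.seed(42)
  false_pos <- vapply(1:200, function(i) {
    stage_association(rnorm(300), sample(rep(1:4, 75)))$sign != "0"
  }, logical(1))
  expect_lte(mean(false_pos), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("metastasis association uses the exact Mann-Whitney on small tie-free data", {
  x0 <- 1:10
  x1 <- 11:20
  r <- metastasis_association(c(x0, x1), rep(c(0, 1), each = 10))
  expect_equal(r$sign, "+")
  # fully separated samples: two-sided exact p = 2 / choose(20, 10)
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)

  r_null <- metastasis_association(rep(1:10, 2), rep(c(0, 1), each = 10))
  expect_equal(r_null$sign, "0")

  r_na <- metastasis_association(1:10, rep(0, 10))
  expect_false(r_na$applicable)
})

test_that("biomarker classification reproduces the signed-pattern logic", {
  # suppressor worked example: survival +, both stages -, M -
  supp <- classify_biomarker(fake_records("miR-194", "+", "-", "-", "-"))
  expect_equal(supp$class, "suppressor")
  expect_true(supp$promising)

  # oncogenic worked example: survival -, both stages +, M +
  onco <- classify_biomarker(fake_records("miR-100", "-", "+", "+", "+"))
  expect_equal(onco$class, "oncogenic")
  expect_true(onco$promising)

  none <- classify_biomarker(fake_records("m", "0", "0", "0", "0"))
  expect_equal(none$class, "none")
  expect_false(none$promising)

  # two significant endpoints suffice for a class but not for promising
  partial <- classify_biomarker(fake_records("m", "-", "+", "0", "0"))
  expect_equal(partial$class, "oncogenic")
  expect_false(partial$promising)

  one_only <- classify_biomarker(fake_records("m", "-", "0", "0", "0"))
  expect_equal(one_only$class, "none")

  conflict <- classify_biomarker(fake_records("m", "-", "-", "0", "0"))
  expect_equal(conflict$class, "none")
  expect_true(conflict$conflict)

  expect_error(classify_biomarker(fake_records("m", "+", "-", "-", "-")[1:3, ]),
               "missing endpoint")
})

test_that("negating expression flips every sign and preserves every p-value", {
  co <- simulate_cohort(n_patients = 200, seed = 43)
  cl <- co$clinical
  for (id in c("supp-1", "onco-1", "null-01")) {
    x <- co$expr[id, ]
    flip <- list(
      list(survival_association(x, cl$os_days, cl$os_event),
           survival_association(-x, cl$os_days, cl$os_event)),
      list(stage_association(x, cl$t_stage),
           stage_association(-x, cl$t_stage)),
      list(metastasis_association(x, cl$m_stage),
           metastasis_association(-x, cl$m_stage)))
    for (pair in flip) {
      expect_equal(pair[[1]]$p, pair[[2]]$p, tolerance = 1e-9)
      expect_equal(pair[[1]]$sign,
                   chartr("+-", "-+", pair[[2]]$sign))
    }
  }
})

test_that("screening a synthetic cohort recovers the planted pattern classes", {
  co <- simulate_cohort(n_patients = 300, seed = 44)
  sc <- screen_cohort(co$expr, co$clinical, min_expressed_samples = 0)
  calls <- sc$calls
  planted <- co$truth[co$truth$class != "none", ]
  got <- calls$class[match(planted$mirna_id, calls$mirna_id)]
  expect_gte(mean(got == planted$class), 0.8)
  expect_equal(nrow(calls), nrow(co$truth))
  expect_equal(nrow(sc$associations), 4L * nrow(co$truth))
  # missing clinical fields reduce n_used without crashing
  cl2 <- co$clinical
  cl2$t_stage[1:50] <- NA
  sc2 <- screen_cohort(co$expr, cl2, min_expressed_samples = 0)
  a2 <- sc2$associations
  expect_true(all(a2$n_used[a2$endpoint == "T_stage"] == 250))
})

test_that("volcano tables and Venn counts partition significant miRNAs", {
  co <- simulate_cohort(n_patients = 300,
                        plan = default_cohort_plan(n_null = 10),
                        seed = 45)
  sc <- screen_cohort(co$expr, co$clinical, min_expressed_samples = 0)
  vv <- volcano_and_venn(sc$associations)
  expect_named(vv$volcano, c("survival", "T_stage", "P_stage", "M_stage"))
  expect_true(all(vv$venn$favorable >= 0))
  # suppressors land in the favorable side, oncogenic in the unfavorable
  fav3 <- vv$venn$favorable[["survival&stage&M"]]
  unf3 <- vv$venn$unfavorable[["survival&stage&M"]]
  prom <- sc$calls[sc$calls$promising, ]
  expect_equal(fav3, sum(prom$class == "suppressor"))
  expect_equal(unf3, sum(prom$class == "oncogenic"))

  # a single fully-significant suppressor sits in the 3-way intersection
  single <- data.frame(
    mirna_id = "m1",
    endpoint = c("survival", "T_stage", "P_stage", "M_stage"),
    effect = c(2, -2, -2, -2), sign = c("+", "-", "-", "-"),
    p = 0.001, n_used = 100L, applicable = TRUE,
    stringsAsFactors = FALSE)
  vv1 <- volcano_and_venn(single)
  expect_equal(vv1$venn$favorable[["survival&stage&M"]], 1)
  expect_equal(sum(vv1$venn$unfavorable), 0)
})
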