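test_that("contingency construction rounds control counts and corrects zeros", {
  t1 <- build_contingency(2, 80, 0.0008, 2468)
  expect_equal(unname(t1$raw), c(2, 78, 2, 2466))
  expect_false(t1$corrected)

  t2 <- build_contingency(13, 80, 0.0644, 2468)
  expect_equal(t2$raw[["c"]], 159)
  expect_false(t2$corrected)

  t3 <- build_contingency(2, 80, 0, 12020)
  expect_true(t3$corrected)
  expect_equal(c(t3$a, t3$b, t3$c, t3$d), c(2.5, 78.5, 0.5, 12020.5))

  t4 <- build_contingency(0, 60, 0.0004, 2468)
  expect_true(t4$corrected)
  expect_equal(c(t4$a, t4$b, t4$c, t4$d), c(0.5, 60.5, 1.5, 2467.5))

  expect_error(build_contingency(1, 10, 0.5, 0), "positive")
})

test_that("odds ratios and Woolf CIs reproduce the regression values", {
  o <- odds_ratio_ci(build_contingency(2, 80, 0, 12020))
  expect_equal(round(o$or, 4), 765.6369)
  expect_equal(round(o$ci_low, 4), 36.4590)
  expect_equal(round(o$ci_high, 4), 16078.3238)
  expect_equal(round(o$z, 3), 4.275)

  o2 <- odds_ratio_ci(list(a = 1, b = 79, c = 2081, d = 11791,
                           corrected = FALSE))
  expect_equal(round(o2$or, 4), 0.0717)

  o3 <- odds_ratio_ci(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(o3$or, 1)
  expect_equal(o3$ci_low * o3$ci_high, 1, tolerance = 1e-12)

  expect_error(odds_ratio_ci(list(a = 0, b = 10, c = 10, d = 10)),
               "zero cell")
})

test_that("transposing case and control inverts the OR and swaps the CI", {
  set.seed(42)
  for (i in 1:20) {
    cells <- sample(1:200, 4)
    t <- list(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    tt <- list(a = cells[3], b = cells[4], c = cells[1], d = cells[2])
    o <- odds_ratio_ci(t); ot <- odds_ratio_ci(tt)
    expect_equal(ot$or, 1 / o$or)
    expect_equal(ot$ci_low, 1 / o$ci_high)
    expect_equal(ot$ci_high, 1 / o$ci_low)
  }
})

test_that("chi-square matches the closed form and chisq.test", {
  set.seed(7)
  for (i in 1:20) {
    cells <- sample(1:100, 4)
    t <- list(raw = c(a = cells[1], b = cells[2], c = cells[3],
                      d = cells[4]))
    plain <- chi_square_2x2(t, yates = FALSE)
    expect_equal(plain$chi2,
                 oracle_chi2_closed_form(cells[1], cells[2], cells[3],
                                         cells[4]))
    m <- matrix(cells, 2, 2, byrow = TRUE)
    expect_equal(plain$p,
                 suppressWarnings(chisq.test(m, correct = FALSE)$p.value))
    yat <- chi_square_2x2(t, yates = TRUE)
    expect_equal(yat$p,
                 suppressWarnings(chisq.test(m, correct = TRUE)$p.value))
  }
  flat <- chi_square_2x2(list(raw = c(a = 10, b = 10, c = 10, d = 10)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  degen <- chi_square_2x2(list(raw = c(a = 0, b = 0, c = 5, d = 5)))
  expect_false(degen$defined)
  expect_true(is.na(degen$p))
})

test_that("carrier-trait tables reproduce the published p-values", {
  # autoimmune comorbidity 5/8 vs 6/32 and female 8/8 vs 24/32, Yates
  p1 <- chi_square_2x2(list(raw = c(a = 5, b = 3, c = 6, d = 26)),
                       yates = TRUE)$p
  expect_equal(round(p1, 3), 0.042)
  p2 <- chi_square_2x2(list(raw = c(a = 8, b = 0, c = 24, d = 8)),
                       yates = TRUE)$p
  expect_equal(round(p2, 2), 0.28)
})

test_that("one-sample proportion Z test matches the frozen oracle values", {
  # two-sided normal p-values computed independently (scipy.stats.norm)
  expect_equal(one_sample_proportion_z(1, 80, 0.001)$p, 0.0011366,
               tolerance = 1e-4)
  expect_equal(one_sample_proportion_z(2, 80, 0.093)$p, 0.0362462,
               tolerance = 1e-4)
  eq <- one_sample_proportion_z(8, 80, 0.1)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_error(one_sample_proportion_z(1, 80, 0), "strictly between")
  expect_error(one_sample_proportion_z(1, 80, 1), "strictly between")
})

test_that("BH adjustment matches hand arithmetic and is well-behaved", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))

  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    # permutation invariance
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
    # monotone: larger raw p never maps to smaller adjusted p
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
  # families adjust independently
  p <- c(0.01, 0.02, 0.03, 0.01)
  fam <- c("x", "x", "x", "y")
  expect_equal(bh_adjust(p, fam), c(0.03, 0.03, 0.03, 0.01))
})

test_that("associate_allele_set runs the full per-locus analysis", {
  coh <- mg_reference_cohort()
  panel <- romanian_panel_lowres()
  res <- associate_allele_set(count_alleles(coh, "B", 1), panel)
  expect_s3_class(res, "hla_assoc")
  expect_equal(res$allele, sort(res$allele))
  # union of case and panel alleles: B*14 is panel-only, B*47 in both
  expect_true(all(c("B*14", "B*47", "B*08") %in% res$allele))
  b47 <- res[res$allele == "B*47", ]
  expect_true(b47$corrected)
  expect_true(b47$yates)
  expect_equal(round(b47$or, 4), 765.6369)
  b08 <- res[res$allele == "B*08", ]
  expect_false(b08$yates)  # smallest raw cell is 12
  expect_true(all(res$p_bh >= res$p - 1e-12, na.rm = TRUE))

  expect_error(associate_allele_set(count_alleles(coh, "B", 1),
                                    romanian_panel_highres()),
               "resolution")

  # equal frequencies give OR ~ 1 and a large p
  eq_counts <- allele_count_table(
    data.frame(allele = c("B*07", "B*08"), count = c(50, 50)),
    locus = "B", resolution = 1, n_subjects = 50)
  eq_panel <- frequency_panel(
    data.frame(locus = "B", allele = c("B*07", "B*08"),
               frequency = c(0.5, 0.5), n_alleles = 10000),
    resolution = 1)
  eq <- associate_allele_set(eq_counts, eq_panel)
  expect_equal(eq$or, c(1, 1), tolerance = 1e-12)
  expect_true(all(eq$p > 0.9))
})

test_that("carrier-phenotype comparison flags degenerate traits", {
  coh <- mg_reference_cohort()
  traits <- list(
    autoimmune_comorbidity = function(m) m$autoimmune,
    always = function(m) rep(TRUE, nrow(m))
  )
  cmp <- compare_carrier_phenotypes(coh, "B*40", traits)
  expect_equal(round(cmp$p[cmp$trait == "autoimmune_comorbidity"], 3),
               0.042)
  expect_true(cmp$degenerate[cmp$trait == "always"])
  expect_true(is.na(cmp$p[cmp$trait == "always"]))
  expect_error(
    compare_carrier_phenotypes(coh, "A*80", traits), "at least one carrier")
})

test_that("uncorrected chi-square holds its nominal type-I error", {
  # case and control counts drawn from the same frequency; 1000 replicates
  set.seed(2026)
  p0 <- 0.3
  rej <- vapply(1:1000, function(i) {
    a <- rbinom(1, 80, p0)
    c_ <- rbinom(1, 2000, p0)
    t <- list(raw = c(a = a, b = 80 - a, c = c_, d = 2000 - c_))
    chi_square_2x2(t, yates = FALSE)$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Woolf CIs cover an injected odds ratio at ~95%", {
  set.seed(1234)
  p <- 0.06
  q <- 3 * p / (1 - p) / (1 + 3 * p / (1 - p))  # case freq for OR 3
  n_case <- 1000  # 500 subjects
  covered <- vapply(1:400, function(i) {
    a <- rbinom(1, n_case, q)
    cc <- rbinom(1, 12020, p)
    t <- build_contingency(a, n_case, cc / 12020, 12020)
    o <- odds_ratio_ci(t)
    o$ci_low <= 3 && 3 <= o$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("p-value rendering matches the report convention", {
  expect_equal(format_pvalue(c(0.0008, 9e-6, NA)),
               c("0.0008", "<0.00001", "NA"))
})
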