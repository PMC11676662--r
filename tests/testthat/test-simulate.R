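two_locus_spec <- function(n = 100) {
  simulation_spec(list(A = c("A*01" = 0.7, "A*02" = 0.3),
                       B = c("B*07" = 0.5, "B*08" = 0.3, "B*35" = 0.2)),
                  n_subjects = n)
}

test_that("sampling is seed-reproducible and spec-validated", {
  spec <- two_locus_spec()
  c1 <- sample_cohort(spec, seed = 9)
  c2 <- sample_cohort(spec, seed = 9)
  expect_identical(c1, c2)
  c3 <- sample_cohort(spec, seed = 10)
  expect_false(identical(c1, c3))
  # untouched loci stay untyped
  expect_true(all(is.na(c1$C_1)))

  expect_error(simulation_spec(list(A = c("A*01" = 0.7)), 10), "sum to")
  expect_error(simulation_spec(list(A = c("A*01" = 1)), 0), "positive")
})

test_that("sampled allele frequencies match the spec within binomial error", {
  spec <- two_locus_spec(n = 1000)
  coh <- sample_cohort(spec, seed = 101)
  ct <- count_alleles(coh, "A", 1)
  f <- ct$frequency[ct$allele == "A*01"]
  expect_lt(abs(f - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))
})

test_that("pair_excess forces the requested disequilibrium", {
  spec <- simulation_spec(
    list(B = c("B*07" = 0.5, "B*08" = 0.3, "B*35" = 0.2)),
    n_subjects = 4000,
    pair_excess = data.frame(locus = "B", allele1 = "B*07",
                             allele2 = "B*35", d_pct = 4))
  coh <- sample_cohort(spec, seed = 77)
  pt <- genotype_pair_frequencies(coh, "B", 1)
  ct <- count_alleles(coh, "B", 1)
  ld <- ld_coefficient(pt, ct, "B*07", "B*35")
  # the empirical LD coefficient recovers the forced excess up to
  # binomial noise at n = 4000
  expect_equal(ld$d_pct, 4, tolerance = 0.6)

  bad <- simulation_spec(
    list(B = c("B*07" = 0.5, "B*08" = 0.3, "B*35" = 0.2)),
    n_subjects = 10,
    pair_excess = data.frame(locus = "B", allele1 = "B*07",
                             allele2 = "B*35", d_pct = 95))
  expect_error(sample_cohort(bad, seed = 1), "infeasible")
})

test_that("inject_case_effect solves the odds equation", {
  panel <- romanian_panel_lowres()
  spec <- simulation_spec(list(B = c("B*07" = 0.5, "B*08" = 0.3,
                                     "B*35" = 0.2)), 100)
  s1 <- inject_case_effect(spec, "B", "B*08", 1, panel)
  expect_equal(s1$freqs$B[["B*08"]], 0.06)  # panel frequency
  s2 <- inject_case_effect(spec, "B", "B*08", 2.75,
                           frequency_panel(data.frame(
                             locus = "B", allele = "B*08",
                             frequency = 0.06, n_alleles = 12020), 1))
  # q solving q/(1-q) = 2.75 * 0.06/0.94 (odds algebra): 0.149322
  expect_equal(s2$freqs$B[["B*08"]], 0.149322, tolerance = 1e-5)
  expect_equal(sum(s2$freqs$B), 1)
  expect_error(inject_case_effect(spec, "B", "B*08", 0, panel),
               "positive finite")
})

test_that("injected effects are recovered through the association path", {
  panel <- frequency_panel(
    data.frame(locus = "B", allele = c("B*08", "B*07"),
               frequency = c(0.06, 0.94), n_alleles = 12020), 1)
  spec <- simulation_spec(list(B = c("B*07" = 0.94, "B*08" = 0.06)), 500)
  spec <- inject_case_effect(spec, "B", "B*08", 3, panel)
  covered <- vapply(1:60, function(i) {
    coh <- sample_cohort(spec, seed = 300 + i)
    res <- associate_allele_set(count_alleles(coh, "B", 1), panel)
    row <- res[res$allele == "B*08", ]
    row$ci_low <= 3 && 3 <= row$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.85)
})

test_that("the reference cohort builder matches the frozen file", {
  built <- mg_reference_cohort()
  frozen <- read_cohort(hlacc_file("mg_cohort_synthetic.tsv"))
  expect_identical(as.data.frame(built), as.data.frame(frozen))
  # regenerating with any seed is byte-identical (fully deterministic)
  tmp1 <- withr::local_tempfile(); tmp2 <- withr::local_tempfile()
  write_cohort(mg_reference_cohort(seed = 1), tmp1)
  write_cohort(mg_reference_cohort(seed = 99), tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
})

test_that("reference cohort metadata matches the published mix", {
  coh <- mg_reference_cohort()
  expect_equal(as.integer(table(coh$sex)[c("F", "M")]), c(32L, 8L))
  expect_equal(as.integer(table(coh$onset_class)[c("MGj", "EOMG", "LOMG")]),
               c(3L, 23L, 14L))
  expect_equal(as.integer(table(coh$serotype)[c("RAchPos", "MuSKPos",
                                              "dSNMG")]), c(30L, 1L, 9L))
  expect_equal(as.integer(table(coh$mgfa_max)[c("I", "IIA", "IIB", "IIIB",
                                              "V")]), c(5L, 14L, 11L, 2L, 8L))
  expect_equal(sum(coh$autoimmune), 11L)
  expect_equal(as.integer(table(coh$thymic_status)[c("normal_ct", "thymoma",
                                                   "follicular_hyperplasia")]),
               c(22L, 9L, 9L))
  expect_equal(sum(coh$titin_ryr == "titin_only"), 1L)
  expect_equal(sum(coh$titin_ryr == "titin_and_ryr"), 2L)
  # carrier trait split
  carr <- carrier_flags(coh, "B*40")
  expect_equal(sum(coh$autoimmune[carr]), 5L)
  expect_equal(sum(coh$sex[carr] == "F"), 8L)
  expect_equal(sum(coh$onset_class[carr] == "EOMG"), 6L)
})
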