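test_that("the bundled cohort file loads and round-trips", {
  coh <- read_cohort(hlacc_file("mg_cohort_synthetic.tsv"))
  expect_s3_class(coh, "hla_cohort")
  expect_equal(nrow(coh), 40L)
  # one subject untyped at DQB1 -> allele denominator 78 downstream
  expect_equal(attr(count_alleles(coh, "DQB1"), "denominator"), 78L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, tmp)
  expect_identical(read_cohort(tmp), coh)
  # CSV dialect
  tmpc <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, tmpc, sep = ",")
  expect_identical(read_cohort(tmpc, sep = ","), coh)
})

test_that("homozygous pairs are representable", {
  coh <- tiny_cohort(A_1 = "A*02:01", A_2 = "A*02:01")
  ct <- count_alleles(coh, "A", 2)
  expect_equal(ct$count[ct$allele == "A*02:01"], 2L)
})

test_that("defective cohort files are refused", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("subject_id",
                     paste0(rep(HLA_LOCI, each = 2), "_", 1:2),
                     "sex", "age_at_onset", "onset_class", "mgfa_max",
                     "serotype", "thymic_status", "autoimmune",
                     "titin_ryr"), collapse = "\t"), tmp)
  expect_error(read_cohort(tmp), "empty cohort")

  base <- as.data.frame(tiny_cohort(A_1 = c("A*01", "A*02"),
                                    A_2 = c("A*03", "A*02")))
  dup <- base; dup$subject_id <- c("S01", "S01")
  expect_error(as_hla_cohort(dup), "duplicate subject_id")

  half <- base; half$A_2[1] <- NA
  expect_error(as_hla_cohort(half), "half-typed A")

  wrong <- base; wrong$A_1[1] <- "B*08"
  expect_error(as_hla_cohort(wrong), "in the A columns")

  bad_age <- base; bad_age$onset_class <- "LOMG"  # age 30 in helper
  expect_error(as_hla_cohort(bad_age), "onset_class inconsistent")
})

test_that("subgroup selection filters on metadata and carriers", {
  coh <- mg_reference_cohort()
  expect_message(rach <- select_subgroup(coh, serotype == "RAchPos"),
                 "30 of 40")
  expect_equal(nrow(rach), 30L)
  dsn <- suppressMessages(select_subgroup(coh, serotype == "dSNMG"))
  expect_equal(nrow(dsn), 9L)
  musk <- suppressMessages(select_subgroup(coh, serotype == "MuSKPos"))
  # serotypes partition the cohort
  expect_equal(nrow(rach) + nrow(dsn) + nrow(musk), nrow(coh))
  expect_equal(nrow(suppressMessages(select_subgroup(coh, TRUE))), 40L)
  carr <- suppressMessages(select_subgroup(coh, carrier = "B*40"))
  expect_equal(nrow(carr), 8L)
  expect_error(suppressMessages(select_subgroup(coh, nonsense == 1)))
})

test_that("frequency panels read with unit normalization", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "locus\tallele\tfrequency\tfrequency_unit\tn\tn_unit",
    "B\tB*08\t6.00\tpercent\t6010\tindividuals",
    "B\tB*47\t0\tpercent\t6010\tindividuals",
    "A\tA*01\t0.12\tfraction\t11516\talleles"), tmp)
  p <- read_frequency_panel(tmp, 1L)
  expect_equal(panel_frequency(p, "B", "B*08"), 0.06)
  expect_equal(panel_n_alleles(p, "B"), 12020)
  expect_equal(panel_n_alleles(p, "A"), 11516)
  # explicit zero entries are retained
  expect_true("B*47" %in% p$allele)
  expect_equal(panel_frequency(p, "B", "B*47"), 0)
  # absent allele -> 0; absent locus -> error
  expect_equal(panel_frequency(p, "B", "B*73"), 0)
  expect_error(panel_n_alleles(p, "DQB1"), "absent from panel")
})

test_that("ambiguous or invalid panels are refused", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tfrequency\tfrequency_unit\tn\tn_unit",
               "B\tB*08\t6.00\tfraction\t6010\tindividuals"), tmp)
  expect_error(read_frequency_panel(tmp, 1L), "refuse to guess")
  writeLines(c("locus\tallele\tfrequency\tfrequency_unit\tn\tn_unit",
               "B\tB*08\t6.00\tpercent\t6010\tindividuals",
               "B\tB*44:27\t0.00\tpercent\t6010\tindividuals"), tmp)
  expect_error(read_frequency_panel(tmp, 1L), "mixed resolutions|not at 1")
  # per-locus frequency sum above 1 + tolerance
  bad <- data.frame(locus = "A", allele = c("A*01", "A*02"),
                    frequency = c(0.6, 0.5), n_alleles = 100)
  expect_error(frequency_panel(bad, 1L), "sum to")
})

test_that("the bundled panels match their builders", {
  p1 <- read_frequency_panel(hlacc_file("panel_romania_2digit.tsv"), 1L)
  b1 <- romanian_panel_lowres()
  expect_equal(p1$allele, b1$allele)
  expect_equal(p1$frequency, b1$frequency)
  expect_equal(p1$n_alleles, b1$n_alleles)
  p2 <- read_frequency_panel(hlacc_file("panel_romania_4digit.tsv"), 2L)
  b2 <- romanian_panel_highres()
  expect_equal(p2$frequency, b2$frequency)
  # the high-resolution panel has no DQB1 locus: skipped, never imputed
  expect_false("DQB1" %in% panel_loci(p2))
})
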