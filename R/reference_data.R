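# Bundled reference inputs: the synthetic study-shaped cohort, the two
# Romanian reference frequency panels, national scalar frequencies and
# control genotype-pair tables. All are constructed in code from published
# summary tables; the raw genotypes were never deposited, so the cohort is
# a synthetic completion of the published marginals (see the methods
# vignette for what is and is not pinned down).

# Published two-digit MG genotype pairs per locus, one subject per entry
# (the DRB1 pair DRB1*10-DRB1*15 replaces a printed DRB1*03-DRB1*15 entry
# that is inconsistent with the published allele marginals; see vignette).
mg_pairs_A <- function() {
  c("01|01", "01|02", "01|02", "01|02", "01|02", "01|03", "01|03",
    "01|03", "01|24", "01|24", "01|32", "01|32", "02|02", "02|02",
    "02|02", "02|02", "02|02", "02|03", "02|11", "02|24", "02|24",
    "02|24", "02|24", "02|24", "02|24", "02|25", "02|26", "02|26",
    "02|29", "02|30", "02|32", "03|32", "03|33", "11|24", "23|68",
    "24|24", "24|25", "25|33", "26|26", "31|32")
}

# B*40-carrying pairs first: subjects 1..8 are the carriers.
mg_pairs_B <- function() {
  c("08|40", "18|40", "18|40", "35|40", "35|40", "40|47", "40|47",
    "40|51",
    "07|35", "07|35", "07|44", "08|15", "08|18", "08|18", "08|35",
    "08|38", "08|39", "08|44", "08|44", "08|51", "08|55", "08|73",
    "13|27", "13|35", "13|51", "15|18", "18|38", "18|39", "18|44",
    "18|51", "27|35", "27|51", "27|57", "35|44", "35|44", "35|51",
    "35|52", "38|57", "44|51", "51|58")
}

mg_pairs_DRB1 <- function() {
  c("01|03", "01|07", "01|07", "01|11", "01|11", "01|14", "01|14",
    "01|15", "01|16", "03|11", "03|14", "03|14", "03|16", "03|16",
    "03|16", "03|16", "04|13", "04|15", "04|15", "04|15", "04|16",
    "04|16", "04|16", "07|11", "07|11", "07|14", "07|15", "10|14",
    "10|15", "11|11", "11|12", "11|15", "11|15", "11|16", "11|16",
    "11|16", "11|16", "14|15", "14|16", "15|16")
}

# C and DQB1 pair structure is not published; pair the published allele
# counts deterministically (greedy: largest remaining count against the
# next largest, homozygous only when one allele exceeds all others
# combined).
greedy_pairs <- function(counts) {
  counts <- counts[counts > 0]
  n_pairs <- sum(counts) / 2
  stopifnot(n_pairs == round(n_pairs))
  out <- character(n_pairs)
  for (k in seq_len(n_pairs)) {
    ord <- order(-counts, names(counts))
    top <- ord[1L]
    mate <- if (counts[top] > sum(counts[-top])) top else ord[2L]
    a <- names(counts)[top]; b <- names(counts)[mate]
    out[k] <- paste(min(a, b), max(a, b), sep = "|")
    counts[top] <- counts[top] - 1L
    counts[mate] <- counts[mate] - 1L
    counts <- counts[counts > 0]
  }
  sort(out)
}

mg_pairs_C <- function() {
  greedy_pairs(c("01" = 4, "02" = 8, "03" = 6, "04" = 8, "05" = 1,
                 "06" = 9, "07" = 25, "12" = 10, "14" = 2, "15" = 5,
                 "16" = 2))
}

mg_pairs_DQB1 <- function() {
  greedy_pairs(c("02" = 11, "03" = 23, "05" = 33, "06" = 11))
}

split_pairs <- function(keys, locus) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  list(a1 = paste0(locus, "*", vapply(parts, `[`, "", 1L)),
       a2 = paste0(locus, "*", vapply(parts, `[`, "", 2L)))
}

#' Deterministic synthetic cohort reproducing the published marginals
#'
#' Builds the 40-subject myasthenia gravis cohort whose two-digit allele
#' counts, genotype-pair tables (HLA-A, -B, -DRB1), demographic mix and
#' B*40 carrier/non-carrier trait split equal the published summary
#' tables. HLA-C and -DQB1 pairs, and the joint assignment of loci to
#' subjects, are not pinned down by those tables and are completed
#' deterministically. Subjects 1-8 are the B*40 carriers; subject 40 is
#' untyped at DQB1 (the locus denominator is 78 alleles over 39
#' subjects).
#'
#' @param seed accepted for interface symmetry with [sample_cohort()];
#'   the construction is fully deterministic and ignores it.
#' @return an `hla_cohort` of 40 subjects typed at two-digit resolution.
#' @export
mg_reference_cohort <- function(seed = 1L) {
  A <- split_pairs(mg_pairs_A(), "A")
  B <- split_pairs(mg_pairs_B(), "B")
  C <- split_pairs(mg_pairs_C(), "C")
  DR <- split_pairs(mg_pairs_DRB1(), "DRB1")
  DQ <- split_pairs(mg_pairs_DQB1(), "DQB1")
  # B pairs fix subject identity (carriers first); the other loci are
  # assigned in their listed order
  df <- data.frame(
    subject_id = sprintf("MG%02d", 1:40),
    A_1 = A$a1, A_2 = A$a2,
    B_1 = B$a1, B_2 = B$a2,
    C_1 = C$a1, C_2 = C$a2,
    DRB1_1 = DR$a1, DRB1_2 = DR$a2,
    DQB1_1 = c(DQ$a1, NA), DQB1_2 = c(DQ$a2, NA),
    stringsAsFactors = FALSE
  )
  df$sex <- c(rep("F", 32), rep("M", 8))
  df$onset_class <- c(rep("EOMG", 6), "LOMG", "MGj",        # carriers 1-8
                      "MGj", "MGj", rep("EOMG", 17),        # 9-27
                      rep("LOMG", 13))                      # 28-40
  df$age_at_onset <- c(20, 24, 28, 32, 36, 45, 60, 10,
                       8, 15,
                       c(19, 21, 23, 25, 27, 29, 31, 33, 35, 37, 39, 41,
                         43, 45, 47, 48, 49),
                       seq(50, 74, by = 2))
  df$mgfa_max <- c(rep("IIA", 3), rep("IIB", 3), "V", "V",  # carriers
                   rep("I", 5), rep("IIA", 11), rep("IIB", 8),
                   rep("IIIB", 2), rep("V", 6))
  df$autoimmune <- FALSE
  df$autoimmune[c(1:4, 8, 9, 10, 11, 12, 13, 14)] <- TRUE
  df$thymic_status <- "normal_ct"
  df$thymic_status[c(1:3, 16:21)] <- "thymoma"
  df$thymic_status[c(4, 22:29)] <- "follicular_hyperplasia"
  df$serotype <- "RAchPos"
  df$serotype[c(9, 33:40)] <- "dSNMG"
  df$serotype[32] <- "MuSKPos"
  df$titin_ryr <- "none"
  df$titin_ryr[15] <- "titin_only"
  df$titin_ryr[c(30, 31)] <- "titin_and_ryr"
  as_hla_cohort(df)
}

#' Bundled Romanian reference frequency panels
#'
#' `romanian_panel_lowres()` is the two-digit ("allele group") panel over
#' all five loci (A n = 5758, B n = 6010, C n = 1612, DRB1 n = 6936,
#' DQB1 n = 3328 typed individuals; allele denominators are twice that).
#' `romanian_panel_highres()` is the four-digit (protein level) panel of
#' 1234 individuals over A, B, C and DRB1 only (no DQB1 locus: pipelines
#' must skip, not impute, absent loci); it carries only the published
#' entries, which is valid because panels may omit alleles.
#'
#' @return an `hla_freq_panel`.
#' @export
romanian_panel_lowres <- function() {
  e <- function(locus, n_ind, ...) {
    v <- c(...)
    data.frame(locus = locus,
               allele = paste0(locus, "*", names(v)),
               frequency = unname(v) / 100,
               n_alleles = 2L * n_ind, stringsAsFactors = FALSE)
  }
  entries <- rbind(
    e("A", 5758, "01" = 12, "02" = 26, "03" = 9, "11" = 8, "23" = 3,
      "24" = 12, "25" = 3, "26" = 5, "29" = 2, "30" = 2, "31" = 2,
      "32" = 4, "33" = 3, "36" = 4, "68" = 3),
    e("B", 6010, "07" = 5, "08" = 6, "13" = 3, "14" = 2, "15" = 3,
      "18" = 10, "27" = 4, "35" = 14, "38" = 3, "39" = 3, "40" = 5,
      "41" = 2, "44" = 8, "47" = 0, "49" = 2, "50" = 2, "51" = 9,
      "52" = 4, "53" = 2, "55" = 2, "56" = 1, "57" = 1, "58" = 2,
      "73" = 0, "78" = 3),
    e("C", 1612, "01" = 5, "02" = 7, "03" = 7, "04" = 15, "05" = 3,
      "06" = 9, "07" = 26, "08" = 3, "12" = 13, "14" = 3, "15" = 5,
      "16" = 3, "17" = 1),
    e("DRB1", 6936, "01" = 8, "03" = 11, "04" = 9, "07" = 7, "08" = 2,
      "10" = 1, "11" = 19, "12" = 2, "13" = 15, "14" = 7, "15" = 9,
      "16" = 10),
    e("DQB1", 3328, "02" = 21, "03" = 29, "04" = 2, "05" = 30, "06" = 18)
  )
  frequency_panel(entries, resolution = 1L, name = "Romania 2-digit")
}

#' @rdname romanian_panel_lowres
#' @export
romanian_panel_highres <- function() {
  al <- c("A*02:07" = 0.04, "A*02:08" = 0.04, "A*02:27" = 0.04,
          "A*02:36" = 0.00, "A*03:97" = 0.04, "A*24:18" = 0.04,
          "A*68:18N" = 0.04, "A*74:01" = 0.04, "A*80:01" = 0.04,
          "B*15:09" = 0.04, "B*15:39" = 0.04, "B*15:73" = 0.04,
          "B*35:14" = 0.04, "B*39:10" = 0.04, "B*39:31" = 0.04,
          "B*44:04" = 0.04, "B*44:27" = 0.00, "B*47:27" = 0.00,
          "B*51:02" = 0.05, "B*53:01" = 0.04, "B*57:02" = 0.08,
          "C*08:01" = 0.04, "C*12:12" = 0.04, "C*15:06" = 0.04,
          "DRB1*01:11" = 0.04, "DRB1*11:11" = 0.04, "DRB1*11:33" = 0.04,
          "DRB1*11:39" = 0.04, "DRB1*11:43" = 0.04, "DRB1*13:22" = 0.04,
          "DRB1*14:06" = 0.04, "DRB1*14:54" = 0.00, "DRB1*16:01" = 6.44)
  entries <- data.frame(
    locus = hla_locus(names(al)), allele = names(al),
    frequency = unname(al) / 100, n_alleles = 2L * 1234L,
    stringsAsFactors = FALSE
  )
  frequency_panel(entries, resolution = 2L, name = "Romania 4-digit")
}

#' National scalar allele frequencies
#'
#' The whole-population frequencies used by the one-sample proportion Z
#' test screen.
#'
#' @return named numeric vector of fractions, names are two-digit allele
#'   names.
#' @export
national_allele_frequencies <- function() {
  c("A*11" = 0.093, "B*08" = 0.077, "B*40" = 0.050, "B*47" = 0.006,
    "B*73" = 0.001, "DRB1*13" = 0.105, "DRB1*16" = 0.096)
}

#' Control genotype-pair tables (synthetic completion)
#'
#' The published control pair tables list only the pairs observed in the
#' case cohort, so they are partial (frequencies do not sum to 100%). The
#' HLA-B table additionally carries one synthetic entry, B*15-B*35 at
#' 2.70% (10/371), completing a pair whose disequilibrium the study
#' reports without printing its frequency.
#'
#' @param locus "A", "B" or "DRB1".
#' @return a partial `hla_pair_freqs` (`complete = FALSE`).
#' @export
control_pair_table <- function(locus = c("A", "B", "DRB1")) {
  locus <- match.arg(locus)
  tabs <- list(
    A = list(n = 373L, pct = c(
      "01|01" = 2.41, "01|02" = 10.46, "01|03" = 1.61, "01|24" = 4.29,
      "01|32" = 0.80, "02|02" = 6.97, "02|03" = 6.43, "02|11" = 4.02,
      "02|24" = 6.17, "02|25" = 1.34, "02|26" = 2.95, "02|29" = 0.00,
      "02|30" = 1.07, "02|32" = 2.14, "03|32" = 0.54, "03|33" = 0.00,
      "11|24" = 0.80, "23|68" = 0.00, "24|24" = 1.88, "24|25" = 1.61,
      "25|33" = 0.00, "26|26" = 0.00, "31|32" = 0.80)),
    B = list(n = 371L, pct = c(
      "07|35" = 1.62, "07|44" = 1.35, "08|15" = 0.27, "08|18" = 2.70,
      "08|35" = 1.89, "08|38" = 0.27, "08|39" = 0.81, "08|40" = 1.08,
      "08|44" = 1.08, "08|51" = 1.35, "08|55" = 0.00, "08|73" = 0.00,
      "13|27" = 0.00, "13|35" = 0.81, "13|51" = 1.35, "15|18" = 1.89,
      "15|35" = 2.70, "18|38" = 1.08, "18|39" = 0.27, "18|40" = 1.35,
      "18|44" = 2.16, "18|51" = 2.70, "27|35" = 0.81, "27|51" = 0.54,
      "27|57" = 0.27, "35|40" = 1.62, "35|44" = 2.16, "35|51" = 2.16,
      "35|52" = 1.35, "38|57" = 0.27, "40|47" = 0.00, "40|51" = 0.81,
      "44|51" = 1.35, "51|58" = 0.27)),
    DRB1 = list(n = 134L, pct = c(
      "01|03" = 3.73, "01|07" = 0.75, "01|11" = 2.24, "01|14" = 0.75,
      "01|15" = 0.75, "01|16" = 0.75, "03|11" = 2.99, "03|14" = 2.24,
      "03|15" = 2.99, "03|16" = 2.24, "04|13" = 2.99, "04|15" = 1.49,
      "04|16" = 1.49, "07|11" = 5.22, "07|14" = 0.75, "07|15" = 0.75,
      "10|14" = 0.00, "11|11" = 2.99, "11|12" = 0.75, "11|15" = 4.48,
      "11|16" = 5.22, "14|15" = 0.00, "14|16" = 2.99, "15|16" = 2.24))
  )
  t <- tabs[[locus]]
  p <- split_pairs(names(t$pct), locus)
  pair_table(
    data.frame(allele1 = p$a1, allele2 = p$a2,
               frequency = unname(t$pct) / 100, stringsAsFactors = FALSE),
    locus = locus, resolution = 1L, n_subjects = t$n, complete = FALSE
  )
}

#' Complete control DRB1 pair table for the HWE direction check
#'
#' The published control DRB1 pair list covers only the pairs seen in
#' cases (68 of 134 control subjects). This synthetic completion keeps
#' the printed pair counts verbatim and allocates the remaining 66
#' subjects over the unlisted genotype classes by largest-remainder
#' rounding of their Hardy-Weinberg expectations under the two-digit
#' panel frequencies.
#'
#' @return a complete `hla_pair_freqs` over 134 subjects.
#' @export
control_drb1_pair_table_synthetic <- function() {
  partial <- control_pair_table("DRB1")
  listed <- data.frame(allele1 = partial$allele1, allele2 = partial$allele2,
                       count = as.integer(round(partial$frequency * 134)),
                       stringsAsFactors = FALSE)
  panel <- romanian_panel_lowres()
  dr <- panel[panel$locus == "DRB1", ]
  f <- stats::setNames(dr$frequency, dr$allele)
  al <- names(f)
  k <- length(al)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  a1 <- pmin(al[idx[, 1L]], al[idx[, 2L]])
  a2 <- pmax(al[idx[, 1L]], al[idx[, 2L]])
  prob <- ifelse(idx[, 1L] == idx[, 2L], f[idx[, 1L]]^2,
                 2 * f[idx[, 1L]] * f[idx[, 2L]])
  key <- paste(a1, a2, sep = "|")
  lkey <- paste(listed$allele1, listed$allele2, sep = "|")
  open <- !(key %in% lkey)
  remaining <- 134L - sum(listed$count)
  w <- prob[open] / sum(prob[open])
  raw <- w * remaining
  cnt <- floor(raw)
  short <- remaining - sum(cnt)
  if (short > 0) {
    bump <- order(-(raw - cnt), key[open])[seq_len(short)]
    cnt[bump] <- cnt[bump] + 1L
  }
  extra <- data.frame(allele1 = a1[open], allele2 = a2[open],
                      count = as.integer(cnt), stringsAsFactors = FALSE)
  all_pairs <- rbind(listed, extra)
  all_pairs <- all_pairs[all_pairs$count > 0, ]
  pair_table(all_pairs, locus = "DRB1", resolution = 1L,
             n_subjects = 134L, complete = TRUE)
}

#' Path to a bundled data file
#' @param name file name under the package's `extdata` directory; empty
#'   lists the available files.
#' @return file path(s).
#' @export
hlacc_file <- function(name = "") {
  if (!nzchar(name)) {
    return(dir(system.file("extdata", package = "hlacc")))
  }
  path <- system.file("extdata", name, package = "hlacc")
  if (!nzchar(path)) stop("no bundled file '", name, "'", call. = FALSE)
  path
}
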