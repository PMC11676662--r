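# Independent oracles used across tests.

# Pearson chi-square closed form for a 2x2 with integer cells.
oracle_chi2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# BH step-up by hand: sort ascending, p_(i) * m / i, enforce monotone
# from the largest down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Textbook biallelic HWE chi-square (3 genotype classes, 1 df).
oracle_hwe_biallelic <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  e <- c(n * p^2, 2 * n * p * q, n * q^2)
  o <- c(n_aa, n_ab, n_bb)
  sum((o - e)^2 / e)
}

# A tiny cohort data.frame with sensible metadata defaults; genotype
# columns supplied as named vectors like A_1 = c(...), loci omitted stay
# untyped.
tiny_cohort <- function(..., n = NULL) {
  cols <- list(...)
  if (is.null(n)) n <- length(cols[[1L]])
  df <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (loc in hlacc::HLA_LOCI) {
    for (k in 1:2) {
      nm <- paste0(loc, "_", k)
      df[[nm]] <- if (!is.null(cols[[nm]])) cols[[nm]] else NA_character_
    }
  }
  df$sex <- "F"
  df$age_at_onset <- 30
  df$onset_class <- "EOMG"
  df$mgfa_max <- "IIA"
  df$serotype <- "RAchPos"
  df$thymic_status <- "normal_ct"
  df$autoimmune <- FALSE
  df$titin_ryr <- "none"
  for (nm in intersect(names(cols), names(df))) {
    if (!grepl("_[12]$", nm)) df[[nm]] <- cols[[nm]]
  }
  as_hla_cohort(df)
}

# Published two-digit case allele counts (the regression marginals the
# bundled fixture must reproduce).
published_mg_counts <- function() {
  list(
    A = c("A*01" = 13, "A*02" = 28, "A*03" = 6, "A*11" = 2, "A*23" = 1,
          "A*24" = 12, "A*25" = 3, "A*26" = 4, "A*29" = 1, "A*30" = 1,
          "A*31" = 1, "A*32" = 5, "A*33" = 2, "A*68" = 1),
    B = c("B*07" = 3, "B*08" = 12, "B*13" = 3, "B*15" = 2, "B*18" = 9,
          "B*27" = 4, "B*35" = 11, "B*38" = 3, "B*39" = 2, "B*40" = 8,
          "B*44" = 7, "B*47" = 2, "B*51" = 8, "B*52" = 1, "B*55" = 1,
          "B*57" = 2, "B*58" = 1, "B*73" = 1),
    C = c("C*01" = 4, "C*02" = 8, "C*03" = 6, "C*04" = 8, "C*05" = 1,
          "C*06" = 9, "C*07" = 25, "C*12" = 10, "C*14" = 2, "C*15" = 5,
          "C*16" = 2),
    DRB1 = c("DRB1*01" = 9, "DRB1*03" = 8, "DRB1*04" = 7, "DRB1*07" = 6,
             "DRB1*10" = 2, "DRB1*11" = 14, "DRB1*12" = 1, "DRB1*13" = 1,
             "DRB1*14" = 8, "DRB1*15" = 10, "DRB1*16" = 14),
    DQB1 = c("DQB1*02" = 11, "DQB1*03" = 23, "DQB1*05" = 33,
             "DQB1*06" = 11)
  )
}
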