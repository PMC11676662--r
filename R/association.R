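# Case-vs-reference and within-cohort association statistics.

#' Build a 2x2 allele-copy contingency table
#'
#' Rows are case/control, columns are copies of the allele vs all other
#' copies. The control carried-copy count is reconstructed from the panel
#' frequency as `round(freq * control_denominator)` to the nearest integer
#' (ties round half up). If any raw cell is zero, 0.5 is added to all four
#' cells (Haldane-Anscombe) for odds-ratio purposes and the table is
#' flagged `corrected`; the raw integer cells are kept for the chi-square
#' test.
#'
#' @param case_count allele copies among cases.
#' @param case_denominator total case allele copies (2 x typed subjects).
#' @param control_freq control allele frequency as a fraction.
#' @param control_denominator total control allele copies.
#' @return object of class `hla_contingency`: list with analysis cells
#'   `a`, `b`, `c`, `d`, integer `raw` cells, and `corrected` flag.
#' @export
build_contingency <- function(case_count, case_denominator, control_freq,
                              control_denominator) {
  stopifnot(case_count >= 0, case_count <= case_denominator,
            control_freq >= 0, control_freq <= 1)
  if (control_denominator <= 0) {
    stop("control_denominator must be positive", call. = FALSE)
  }
  cc <- floor(control_freq * control_denominator + 0.5)  # half rounds up
  raw <- c(a = case_count, b = case_denominator - case_count,
           c = cc, d = control_denominator - cc)
  corrected <- any(raw == 0)
  cells <- if (corrected) raw + 0.5 else raw
  structure(list(a = cells[["a"]], b = cells[["b"]], c = cells[["c"]],
                 d = cells[["d"]], raw = raw, corrected = corrected),
            class = "hla_contingency")
}

#' @export
print.hla_contingency <- function(x, ...) {
  cat("2x2 allele table", if (x$corrected) "(Haldane-Anscombe corrected)",
      "\n")
  print(matrix(c(x$a, x$c, x$b, x$d), 2, 2,
               dimnames = list(c("case", "control"), c("allele", "other"))))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval and Wald Z
#'
#' OR = ad/bc on the analysis cells (corrected cells when the raw table
#' had a zero). The CI is the Woolf logit interval
#' `exp(log(OR) +/- z * SE)` with `SE = sqrt(1/a + 1/b + 1/c + 1/d)`; the
#' Z statistic is `log(OR)/SE` with a two-sided normal p-value. At the
#' default alpha the conventional two-decimal quantile 1.96 is used (this
#' is what desk calculators print); other alphas use `qnorm(1 - alpha/2)`.
#'
#' @param t an `hla_contingency`.
#' @param alpha two-sided significance level for the CI.
#' @return list with `or`, `ci_low`, `ci_high`, `z`, `p`.
#' @export
odds_ratio_ci <- function(t, alpha = 0.05) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    stop("zero cell reached odds_ratio_ci uncorrected; ",
         "build_contingency applies the correction", call. = FALSE)
  }
  or <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(sum(1 / cells))
  zq <- if (identical(alpha, 0.05)) 1.96 else stats::qnorm(1 - alpha / 2)
  z <- log(or) / se
  list(or = or,
       ci_low = exp(log(or) - zq * se),
       ci_high = exp(log(or) + zq * se),
       z = abs(z),
       p = 2 * stats::pnorm(-abs(z)))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Runs on the raw integer cells, with 1 degree of freedom. With
#' `yates = TRUE` each `|observed - expected|` is reduced by 0.5 (floored
#' at 0) before squaring. A zero row or column margin makes the statistic
#' undefined; a flagged NA result is returned rather than an error.
#'
#' @param t an `hla_contingency` (or a list with a `raw` vector a,b,c,d).
#' @param yates apply the Yates continuity correction.
#' @return list with `chi2`, `p`, `yates`, and `defined` (FALSE when a
#'   margin is zero).
#' @export
chi_square_2x2 <- function(t, yates = FALSE) {
  o <- matrix(t$raw, 2, 2, byrow = TRUE)  # rows case/control
  rs <- rowSums(o); cs <- colSums(o); n <- sum(o)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_, yates = yates,
                defined = FALSE))
  }
  e <- outer(rs, cs) / n
  dev <- abs(o - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       yates = yates, defined = TRUE)
}

#' One-sample proportion Z test
#'
#' Compares an observed proportion `x/n` against a reference proportion
#' `p0` using the normal approximation with the null variance
#' `p0 (1 - p0) / n`; two-sided.
#'
#' @param x observed count.
#' @param n number of trials (allele copies).
#' @param p0 reference proportion, strictly inside (0, 1).
#' @return list with `estimate`, `z`, `p`.
#' @export
one_sample_proportion_z <- function(x, n, p0) {
  stopifnot(n > 0, x >= 0, x <= n)
  if (p0 <= 0 || p0 >= 1) {
    stop("p0 must lie strictly between 0 and 1", call. = FALSE)
  }
  phat <- x / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  list(estimate = phat, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up FDR adjustment applied independently inside each family (here:
#' locus x resolution x case group). Output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param family optional grouping vector of the same length; NULL treats
#'   all p-values as one family.
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (is.null(family)) family <- rep(1L, length(p))
  stopifnot(length(family) == length(p))
  out <- p
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

#' Associate a case allele set with a reference panel
#'
#' One test per allele present in either the case count table or the
#' panel (at the shared locus and resolution): chi-square on the raw 2x2
#' (Yates when the smallest raw cell is below `yates_threshold`, the
#' "rare allele" rule), odds ratio with Woolf CI and Wald Z on the
#' (zero-cell corrected) cells, and BH adjustment across the allele
#' family.
#'
#' @param case_counts an `hla_allele_counts`.
#' @param panel an `hla_freq_panel` with a matching resolution and
#'   covering the locus.
#' @param yates_threshold minimum raw cell count below which the Yates
#'   correction is applied.
#' @param alpha CI significance level.
#' @return data.frame of class `hla_assoc`, one row per allele ordered by
#'   name: `allele`, `case_count`, `case_freq`, `control_freq`, `yates`,
#'   `chi2`, `p`, `p_bh`, `corrected`, `or`, `ci_low`, `ci_high`, `z_or`,
#'   `p_or`.
#' @export
associate_allele_set <- function(case_counts, panel, yates_threshold = 5,
                                 alpha = 0.05) {
  locus <- attr(case_counts, "locus")
  if (attr(case_counts, "resolution") != attr(panel, "resolution")) {
    stop("case table resolution ", attr(case_counts, "resolution"),
         " does not match panel resolution ", attr(panel, "resolution"),
         call. = FALSE)
  }
  panel_entries <- panel[panel$locus == locus, , drop = FALSE]
  if (nrow(panel_entries) == 0L) {
    stop("locus ", locus, " absent from panel '", attr(panel, "name"), "'",
         call. = FALSE)
  }
  alleles <- sort(union(case_counts$allele, panel_entries$allele))
  case_denom <- attr(case_counts, "denominator")
  ctrl_denom <- panel_n_alleles(panel, locus)
  rows <- lapply(alleles, function(al) {
    a <- if (al %in% case_counts$allele) {
      case_counts$count[case_counts$allele == al]
    } else 0L
    cf <- panel_frequency(panel, locus, al)
    t <- build_contingency(a, case_denom, cf, ctrl_denom)
    yates <- min(t$raw) < yates_threshold
    chi <- chi_square_2x2(t, yates = yates)
    orr <- odds_ratio_ci(t, alpha = alpha)
    data.frame(allele = al, case_count = a, case_freq = a / case_denom,
               control_freq = cf, yates = yates, chi2 = chi$chi2,
               p = chi$p, corrected = t$corrected, or = orr$or,
               ci_low = orr$ci_low, ci_high = orr$ci_high, z_or = orr$z,
               p_or = orr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  out <- out[, c("allele", "case_count", "case_freq", "control_freq",
                 "yates", "chi2", "p", "p_bh", "corrected", "or",
                 "ci_low", "ci_high", "z_or", "p_or")]
  structure(out, locus = locus, resolution = attr(panel, "resolution"),
            case_denominator = case_denom, control_denominator = ctrl_denom,
            class = c("hla_assoc", "data.frame"))
}

#' Compare phenotype traits between carriers and non-carriers
#'
#' For each trait, builds the 2x2 carrier-status x trait table over the
#' cohort and applies the chi-square test with the Yates correction
#' (cohorts this size always have small cells). Traits where every
#' subject is positive or every subject is negative are flagged
#' degenerate and get no p-value.
#'
#' @param cohort an `hla_cohort`.
#' @param allele allele whose carriers are compared.
#' @param traits named list of predicate functions; each receives the
#'   cohort data.frame and returns one logical per subject.
#' @return data.frame of class `hla_carrier_cmp`: `trait`,
#'   `carriers_pos`, `carriers_n`, `noncarriers_pos`, `noncarriers_n`,
#'   `chi2`, `p`, `degenerate`.
#' @export
compare_carrier_phenotypes <- function(cohort, allele, traits) {
  stopifnot(is.list(traits), length(traits) > 0,
            !is.null(names(traits)), all(nzchar(names(traits))))
  carrier <- carrier_flags(cohort, allele)
  if (!any(carrier) || all(carrier)) {
    stop("carrier comparison needs at least one carrier and one ",
         "non-carrier of ", allele, call. = FALSE)
  }
  meta <- as.data.frame(cohort)
  rows <- lapply(names(traits), function(nm) {
    flag <- traits[[nm]](meta)
    if (!is.logical(flag) || length(flag) != nrow(meta)) {
      stop("trait '", nm, "' must yield one logical per subject",
           call. = FALSE)
    }
    flag[is.na(flag)] <- FALSE
    tab <- list(raw = c(a = sum(carrier & flag),
                        b = sum(carrier & !flag),
                        c = sum(!carrier & flag),
                        d = sum(!carrier & !flag)))
    degenerate <- all(flag) || !any(flag)
    chi <- if (degenerate) list(chi2 = NA_real_, p = NA_real_) else {
      chi_square_2x2(tab, yates = TRUE)
    }
    data.frame(trait = nm, carriers_pos = sum(carrier & flag),
               carriers_n = sum(carrier),
               noncarriers_pos = sum(!carrier & flag),
               noncarriers_n = sum(!carrier), chi2 = chi$chi2, p = chi$p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, allele = allele,
            class = c("hla_carrier_cmp", "data.frame"))
}

#' Render a p-value the way the report tables do
#'
#' Four decimals, with values below 1e-5 shown as `"<0.00001"`.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-5, "<0.00001", sprintf("%.4f", p)))
}

#' Export association results as TSV mirroring the report layout
#' @param x an `hla_assoc`.
#' @param path file path.
#' @export
write_assoc_table <- function(x, path) {
  df <- data.frame(
    allele = x$allele,
    case_pct = sprintf("%.2f", 100 * x$case_freq),
    control_pct = sprintf("%.2f", 100 * x$control_freq),
    p = format_pvalue(x$p),
    p_bh = format_pvalue(x$p_bh),
    OR = sprintf("%.4f", x$or),
    ci_low = sprintf("%.4f", x$ci_low),
    ci_high = sprintf("%.4f", x$ci_high),
    Z = sprintf("%.3f", x$z_or),
    p_or = format_pvalue(x$p_or),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
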