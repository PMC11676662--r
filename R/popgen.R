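# Hardy-Weinberg equilibrium and within-locus linkage disequilibrium.

#' Hardy-Weinberg equilibrium chi-square for a multi-allelic locus
#'
#' Expected genotype counts come from the observed allele frequencies:
#' `n p_i^2` for homozygotes and `2 n p_i p_j` for heterozygotes. Genotype
#' classes with expected count below `min_expected` are pooled into a
#' single class before the chi-square is computed. Degrees of freedom are
#' `(#classes after pooling - 1) - (#alleles - 1)`, floored at 1.
#'
#' @param pairs an `hla_pair_freqs` (complete genotype-pair table).
#' @param freqs optional `hla_allele_counts` supplying the allele
#'   frequencies; defaults to marginalizing `pairs`.
#' @param min_expected pooling threshold for rare genotype classes.
#' @return object of class `hla_hwe`: list with `locus`, `chi2`, `df`,
#'   `p`, `n_classes`, `n_pooled`, `pooled_classes`.
#' @export
hwe_test <- function(pairs, freqs = NULL, min_expected = 1.0) {
  n <- attr(pairs, "n_subjects")
  if (is.null(n) || n < 5L) {
    stop("HWE test needs at least 5 subjects", call. = FALSE)
  }
  if (is.null(freqs)) freqs <- allele_counts_from_pairs(pairs)
  al <- freqs$allele[freqs$frequency > 0]
  p <- freqs$frequency[freqs$frequency > 0]
  k <- length(al)
  if (k < 2L) stop("HWE not testable with fewer than 2 alleles",
                   call. = FALSE)
  # all k(k+1)/2 unordered genotype classes
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  exp_cnt <- ifelse(i == j, n * p[i]^2, 2 * n * p[i] * p[j])
  a1 <- pmin(al[i], al[j]); a2 <- pmax(al[i], al[j])
  key <- paste(a1, a2, sep = "|")
  obs <- stats::setNames(rep(0, length(key)), key)
  pk <- paste(pairs$allele1, pairs$allele2, sep = "|")
  known <- pk %in% key
  if (any(!known)) {
    stop("pair table contains alleles absent from the frequency table: ",
         pk[!known][1L], call. = FALSE)
  }
  obs[pk] <- pairs$count
  pool <- exp_cnt < min_expected
  if (all(pool)) stop("all genotype classes fall below min_expected",
                      call. = FALSE)
  obs_kept <- obs[!pool]; exp_kept <- exp_cnt[!pool]
  if (any(pool)) {
    obs_kept <- c(obs_kept, pooled = sum(obs[pool]))
    exp_kept <- c(exp_kept, sum(exp_cnt[pool]))
  }
  chi2 <- sum((obs_kept - exp_kept)^2 / exp_kept)
  df <- max(1L, (length(obs_kept) - 1L) - (k - 1L))
  structure(list(locus = attr(pairs, "locus"), chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
                 n_classes = length(obs_kept), n_pooled = sum(pool),
                 pooled_classes = key[pool]),
            class = "hla_hwe")
}

#' @export
print.hla_hwe <- function(x, ...) {
  cat("HWE chi-square, locus ", x$locus, ": chi2 = ",
      sprintf("%.3f", x$chi2), ", df = ", x$df, ", p = ",
      format_pvalue(x$p), " (", x$n_pooled,
      " rare classes pooled)\n", sep = "")
  invisible(x)
}

#' Within-locus linkage-disequilibrium coefficient
#'
#' D (percent scale) is the observed genotype-pair frequency P_XY minus
#' the product of the two allele frequencies P_X * P_Y. Note the
#' deliberate absence of the heterozygote factor 2 in the expectation:
#' the coefficient measures excess over the plain frequency product, so
#' it is not the HWE expectation used by [hwe_test()].
#'
#' @param pairs an `hla_pair_freqs` (may be partial).
#' @param freqs an `hla_allele_counts` (or any table accepted by
#'   [allele_frequency()]) giving P_X and P_Y.
#' @param allele1,allele2 the pair (order irrelevant).
#' @return data.frame row of class `hla_ld`: `allele1`, `allele2`,
#'   `observed_pct`, `expected_pct`, `d_pct`.
#' @export
ld_coefficient <- function(pairs, freqs, allele1, allele2) {
  a1 <- parse_hla(allele1)$allele; a2 <- parse_hla(allele2)$allele
  lo <- min(a1, a2); hi <- max(a1, a2)
  px <- allele_frequency(freqs, lo); py <- allele_frequency(freqs, hi)
  if (px == 0 || py == 0) {
    stop("allele ", if (px == 0) lo else hi,
         " absent from the frequency table", call. = FALSE)
  }
  hit <- pairs$allele1 == lo & pairs$allele2 == hi
  obs <- if (any(hit)) pairs$frequency[hit][1L] else 0
  out <- data.frame(allele1 = lo, allele2 = hi,
                    observed_pct = 100 * obs,
                    expected_pct = 100 * px * py,
                    d_pct = 100 * obs - 100 * px * py,
                    stringsAsFactors = FALSE)
  structure(out, locus = attr(pairs, "locus"),
            class = c("hla_ld", "data.frame"))
}

#' Scan all observed pairs for linkage disequilibrium above a threshold
#'
#' @param pairs an `hla_pair_freqs`.
#' @param freqs allele frequency table for the same locus/resolution.
#' @param threshold_pct keep pairs with `d_pct >= threshold_pct`.
#' @return `hla_ld` data.frame sorted by decreasing `d_pct`, ties broken
#'   by pair name.
#' @export
ld_scan <- function(pairs, freqs, threshold_pct) {
  loc <- attr(pairs, "locus")
  # pairs whose allele has frequency 0 in the reference table have no
  # defined expectation and are skipped
  testable <- vapply(seq_len(nrow(pairs)), function(r) {
    allele_frequency(freqs, pairs$allele1[r]) > 0 &&
      allele_frequency(freqs, pairs$allele2[r]) > 0
  }, TRUE)
  pairs <- pairs[testable, , drop = FALSE]
  empty <- data.frame(allele1 = character(0), allele2 = character(0),
                      observed_pct = numeric(0), expected_pct = numeric(0),
                      d_pct = numeric(0), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    ld_coefficient(pairs, freqs, pairs$allele1[r], pairs$allele2[r])
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[out$d_pct >= threshold_pct, , drop = FALSE]
  out <- out[order(-out$d_pct, out$allele1, out$allele2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, locus = loc, class = c("hla_ld", "data.frame"))
}
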