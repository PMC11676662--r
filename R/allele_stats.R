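# Allele counting and within-locus genotype-pair tables.

locus_alleles <- function(cohort, locus) {
  a1 <- cohort[[paste0(locus, "_1")]]
  a2 <- cohort[[paste0(locus, "_2")]]
  typed <- !is.na(a1) & !is.na(a2)
  list(a1 = a1[typed], a2 = a2[typed], n = sum(typed))
}

#' Count alleles at a locus
#'
#' Each typed subject contributes two allele copies (homozygotes are
#' counted twice), so the denominator is 2 x the number of subjects typed
#' at the locus. Counts are keyed on names truncated to the requested
#' resolution.
#'
#' @param cohort an `hla_cohort`.
#' @param locus one of [HLA_LOCI].
#' @param resolution 1 (allele group) or 2 (protein level); truncating to
#'   a resolution the typing does not carry is an error.
#' @return data.frame of class `hla_allele_counts` with columns `allele`,
#'   `count`, `frequency`, ordered by allele name, and attributes `locus`,
#'   `resolution`, `denominator`, `n_subjects`.
#' @export
count_alleles <- function(cohort, locus, resolution = 1L) {
  stopifnot(locus %in% HLA_LOCI)
  g <- locus_alleles(cohort, locus)
  if (g$n == 0L) {
    stop("no subject typed at locus ", locus, call. = FALSE)
  }
  alleles <- hla_truncate(c(g$a1, g$a2), resolution)
  tab <- table(alleles)
  allele_count_table(
    data.frame(allele = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE),
    locus = locus, resolution = resolution, n_subjects = g$n
  )
}

#' Construct an allele-count table directly from counts
#'
#' Used for tables not derived from a cohort (e.g. marginalized pair
#' tables or externally stated counts).
#'
#' @param df data.frame with columns `allele`, `count`.
#' @param locus,resolution locus tag and field resolution.
#' @param n_subjects number of typed subjects (denominator is
#'   `2 * n_subjects`).
#' @return an `hla_allele_counts`.
#' @export
allele_count_table <- function(df, locus, resolution, n_subjects) {
  stopifnot(all(c("allele", "count") %in% names(df)))
  df <- as.data.frame(df)[, c("allele", "count")]
  df$allele <- parse_hla(df$allele)$allele
  denom <- 2L * n_subjects
  if (sum(df$count) != denom) {
    stop("allele counts sum to ", sum(df$count), ", expected denominator ",
         denom, call. = FALSE)
  }
  df <- df[order(df$allele), ]
  rownames(df) <- NULL
  df$frequency <- df$count / denom
  structure(df, locus = locus, resolution = as.integer(resolution),
            denominator = denom, n_subjects = as.integer(n_subjects),
            class = c("hla_allele_counts", "data.frame"))
}

#' Frequency of one allele in a count table
#' @param counts an `hla_allele_counts`.
#' @param allele allele name.
#' @return fraction (0 when absent).
#' @export
allele_frequency <- function(counts, allele) {
  allele <- parse_hla(allele)$allele
  hit <- counts$allele == allele
  if (!any(hit)) return(0)
  counts$frequency[hit][1L]
}

#' Collapse a count table to a lower resolution
#' @param counts an `hla_allele_counts` at resolution 2.
#' @param resolution target resolution (must not exceed the current one).
#' @return an `hla_allele_counts` at the target resolution.
#' @export
collapse_counts <- function(counts, resolution = 1L) {
  cur <- attr(counts, "resolution")
  if (resolution > cur) {
    stop("cannot raise resolution from ", cur, " to ", resolution,
         call. = FALSE)
  }
  key <- hla_truncate(counts$allele, resolution)
  agg <- tapply(counts$count, key, sum)
  allele_count_table(
    data.frame(allele = names(agg), count = as.integer(agg),
               stringsAsFactors = FALSE),
    locus = attr(counts, "locus"), resolution = resolution,
    n_subjects = attr(counts, "n_subjects")
  )
}

#' Within-locus genotype-pair frequencies
#'
#' Tabulates each subject's unordered allele pair at one locus (the
#' "haplotypes" of the study design: genotype pairs, not gametic
#' haplotypes). Pair keys are sorted lexicographically; homozygous pairs
#' are keyed (x, x).
#'
#' @inheritParams count_alleles
#' @return data.frame of class `hla_pair_freqs` with columns `allele1`,
#'   `allele2`, `count`, `frequency`, and attributes `locus`,
#'   `resolution`, `n_subjects`.
#' @export
genotype_pair_frequencies <- function(cohort, locus, resolution = 1L) {
  stopifnot(locus %in% HLA_LOCI)
  g <- locus_alleles(cohort, locus)
  if (g$n == 0L) stop("no subject typed at locus ", locus, call. = FALSE)
  a1 <- hla_truncate(g$a1, resolution)
  a2 <- hla_truncate(g$a2, resolution)
  key <- paste(pmin(a1, a2), pmax(a1, a2), sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  pair_table(
    data.frame(allele1 = vapply(parts, `[`, "", 1L),
               allele2 = vapply(parts, `[`, "", 2L),
               count = as.integer(tab), stringsAsFactors = FALSE),
    locus = locus, resolution = resolution, n_subjects = g$n
  )
}

#' Construct a genotype-pair table from explicit pair counts
#'
#' @param df data.frame with columns `allele1`, `allele2` and either
#'   `count` (subjects) or `frequency` (fractions).
#' @param locus,resolution locus tag and field resolution.
#' @param n_subjects number of subjects.
#' @param complete when TRUE (tables covering the whole cohort),
#'   frequencies must sum to 1; partial tables (e.g. only the pairs a
#'   report prints) pass `complete = FALSE`.
#' @return an `hla_pair_freqs`.
#' @export
pair_table <- function(df, locus, resolution, n_subjects, complete = TRUE) {
  stopifnot(all(c("allele1", "allele2") %in% names(df)))
  df <- as.data.frame(df)
  df$allele1 <- parse_hla(df$allele1)$allele
  df$allele2 <- parse_hla(df$allele2)$allele
  swap <- df$allele1 > df$allele2
  tmp <- df$allele1[swap]; df$allele1[swap] <- df$allele2[swap]
  df$allele2[swap] <- tmp
  if (anyDuplicated(paste(df$allele1, df$allele2))) {
    stop("duplicate genotype pair in table", call. = FALSE)
  }
  if (!("count" %in% names(df))) {
    stopifnot("frequency" %in% names(df))
    df$count <- df$frequency * n_subjects
    near_int <- max(abs(df$count - round(df$count))) <= 1e-6
    if (complete && !near_int) {
      stop("pair frequencies are not multiples of 1/n_subjects",
           call. = FALSE)
    }
    # partial tables from printed (rounded) percentages keep fractional
    # counts; complete tables are integer subject counts
    if (near_int) df$count <- as.integer(round(df$count))
  }
  if (complete && sum(df$count) != n_subjects) {
    stop("pair counts sum to ", sum(df$count), ", expected ", n_subjects,
         call. = FALSE)
  }
  df <- df[order(df$allele1, df$allele2), c("allele1", "allele2", "count")]
  rownames(df) <- NULL
  df$frequency <- df$count / n_subjects
  structure(df, locus = locus, resolution = as.integer(resolution),
            n_subjects = as.integer(n_subjects), complete = complete,
            class = c("hla_pair_freqs", "data.frame"))
}

#' Marginalize a pair table into allele counts
#'
#' Each pair contributes its two members (homozygotes twice); on a
#' complete table this reproduces [count_alleles()] exactly.
#'
#' @param pairs an `hla_pair_freqs` with `complete = TRUE`.
#' @return an `hla_allele_counts`.
#' @export
allele_counts_from_pairs <- function(pairs) {
  if (!isTRUE(attr(pairs, "complete"))) {
    stop("marginalization requires a complete pair table", call. = FALSE)
  }
  alleles <- c(rep(pairs$allele1, pairs$count), rep(pairs$allele2, pairs$count))
  tab <- table(alleles)
  allele_count_table(
    data.frame(allele = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE),
    locus = attr(pairs, "locus"), resolution = attr(pairs, "resolution"),
    n_subjects = attr(pairs, "n_subjects")
  )
}

#' Carrier status of an allele
#'
#' A subject carries an allele when either member of their pair truncates
#' to it (homozygotes count once).
#'
#' @param cohort an `hla_cohort`.
#' @param allele allele name at one- or two-field resolution.
#' @return named logical vector over subject_id; FALSE for subjects
#'   untyped at the allele's locus.
#' @export
carrier_flags <- function(cohort, allele) {
  p <- parse_hla(allele)
  a1 <- cohort[[paste0(p$locus, "_1")]]
  a2 <- cohort[[paste0(p$locus, "_2")]]
  typed <- !is.na(a1) & !is.na(a2)
  out <- rep(FALSE, nrow(cohort))
  if (any(typed)) {
    t1 <- hla_truncate(a1[typed], p$resolution)
    t2 <- hla_truncate(a2[typed], p$resolution)
    out[typed] <- t1 == p$allele | t2 == p$allele
  }
  names(out) <- cohort$subject_id
  out
}

#' Export a count or pair table as TSV
#' @param x an `hla_allele_counts` or `hla_pair_freqs`.
#' @param path file path.
#' @export
write_stats_table <- function(x, path) {
  df <- as.data.frame(x)
  df$frequency_pct <- round(100 * df$frequency, 2)
  df$frequency <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
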