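# Cohort genotype tables and reference frequency panels.

COHORT_ALLELE_COLS <- as.vector(t(outer(HLA_LOCI, 1:2, paste, sep = "_")))

COHORT_META_COLS <- c("sex", "age_at_onset", "onset_class", "mgfa_max",
                      "serotype", "thymic_status", "autoimmune", "titin_ryr")

COHORT_COLS <- c("subject_id", COHORT_ALLELE_COLS, COHORT_META_COLS)

ONSET_CLASSES <- c("MGj", "EOMG", "LOMG")
MGFA_CLASSES <- c("I", "IIA", "IIB", "IIIA", "IIIB", "IVA", "IVB", "V")
SEROTYPES <- c("RAchPos", "MuSKPos", "dSNMG")
THYMIC_STATUS <- c("normal_ct", "thymoma", "follicular_hyperplasia")
TITIN_RYR <- c("none", "titin_only", "titin_and_ryr")

#' Construct a cohort object
#'
#' A cohort is a data.frame with one row per subject: `subject_id`, two
#' allele columns per locus (`A_1`, `A_2`, ..., `DQB1_2`; both NA when the
#' subject is untyped at that locus) and the clinical metadata columns
#' `sex` (F/M), `age_at_onset` (years), `onset_class` (MGj/EOMG/LOMG with
#' the 50-year early/late threshold), `mgfa_max`, `serotype`
#' (RAchPos/MuSKPos/dSNMG), `thymic_status`, `autoimmune` (logical) and
#' `titin_ryr`.
#'
#' @param df data.frame carrying the columns above.
#' @param validate check allele names, half-typed loci and metadata levels.
#' @return the data.frame with class `hla_cohort`.
#' @export
as_hla_cohort <- function(df, validate = TRUE) {
  missing_cols <- setdiff(COHORT_COLS, names(df))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, COHORT_COLS]
  if (validate) validate_cohort(df)
  for (loc in HLA_LOCI) {
    for (k in 1:2) {
      col <- paste0(loc, "_", k)
      typed <- !is.na(df[[col]])
      if (any(typed)) df[[col]][typed] <- parse_hla(df[[col]][typed])$allele
    }
  }
  class(df) <- c("hla_cohort", "data.frame")
  df
}

validate_cohort <- function(df) {
  if (nrow(df) == 0L) stop("cohort has no subjects", call. = FALSE)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1L], call. = FALSE)
  }
  for (loc in HLA_LOCI) {
    a1 <- df[[paste0(loc, "_1")]]
    a2 <- df[[paste0(loc, "_2")]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      stop("half-typed ", loc, " locus for subject ",
           df$subject_id[half][1L], call. = FALSE)
    }
    typed <- !is.na(a1)
    if (any(typed)) {
      p <- parse_hla(c(a1[typed], a2[typed]))
      if (any(p$locus != loc)) {
        stop("allele '", p$allele[p$locus != loc][1L],
             "' in the ", loc, " columns", call. = FALSE)
      }
    }
  }
  chk <- function(col, levels) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% levels)
    if (any(bad)) {
      stop("invalid ", col, " value '", df[[col]][bad][1L], "'",
           call. = FALSE)
    }
  }
  chk("sex", c("F", "M")); chk("onset_class", ONSET_CLASSES)
  chk("mgfa_max", MGFA_CLASSES); chk("serotype", SEROTYPES)
  chk("thymic_status", THYMIC_STATUS); chk("titin_ryr", TITIN_RYR)
  # onset class must agree with age at onset: juvenile < 18, early < 50,
  # late >= 50
  ok <- is.na(df$onset_class) | is.na(df$age_at_onset) |
    (df$onset_class == "MGj" & df$age_at_onset < 18) |
    (df$onset_class == "EOMG" & df$age_at_onset >= 18 &
       df$age_at_onset < 50) |
    (df$onset_class == "LOMG" & df$age_at_onset >= 50)
  if (any(!ok)) {
    stop("onset_class inconsistent with age_at_onset for subject ",
         df$subject_id[!ok][1L], call. = FALSE)
  }
  invisible(df)
}

#' Read a cohort genotype table
#'
#' Canonical format is TSV with the columns documented in
#' [as_hla_cohort()]; blank allele cells mark a locus as untyped for that
#' subject (blank in one of the two cells only is an error).
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) or `","` for CSV.
#' @return an `hla_cohort`.
#' @export
read_cohort <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  df$age_at_onset <- as.numeric(df$age_at_onset)
  df$autoimmune <- as.logical(df$autoimmune)
  as_hla_cohort(df)
}

#' Write a cohort genotype table
#' @param cohort an `hla_cohort`.
#' @param path file path.
#' @param sep field separator.
#' @export
write_cohort <- function(cohort, path, sep = "\t") {
  utils::write.table(as.data.frame(cohort), path, sep = sep,
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Select an analysis subgroup
#'
#' Filters a cohort on its metadata, e.g.
#' `select_subgroup(cohort, serotype == "dSNMG")`, or on carrier status of
#' an allele via the `carrier` argument.
#'
#' @param cohort an `hla_cohort`.
#' @param expr predicate over metadata columns, evaluated per subject
#'   (unquoted expression).
#' @param carrier optional allele name; keeps carriers (or non-carriers
#'   with `negate = TRUE`) of that allele at its own resolution.
#' @param negate invert the selection.
#' @return the filtered `hla_cohort`; subgroup size reported via message.
#' @export
select_subgroup <- function(cohort, expr, carrier = NULL, negate = FALSE) {
  keep <- rep(TRUE, nrow(cohort))
  if (!missing(expr)) {
    e <- substitute(expr)
    keep <- eval(e, as.data.frame(cohort), parent.frame())
    if (is.logical(keep) && length(keep) == 1L) {
      keep <- rep(keep, nrow(cohort))
    }
    if (!is.logical(keep) || length(keep) != nrow(cohort)) {
      stop("subgroup predicate must yield one logical per subject",
           call. = FALSE)
    }
    keep[is.na(keep)] <- FALSE
  }
  if (!is.null(carrier)) keep <- keep & carrier_flags(cohort, carrier)
  if (negate) keep <- !keep
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(cohort)
  message("subgroup: ", nrow(out), " of ", nrow(cohort), " subjects")
  out
}

#' Construct a reference frequency panel
#'
#' A panel holds, per locus, reference-population allele frequencies
#' (fractions) and the total allele count (2 x typed individuals). Panels
#' may omit rare alleles, so per-locus frequencies must sum to at most
#' 1 + 0.02; loci may be absent entirely.
#'
#' @param entries data.frame with columns `locus`, `allele`, `frequency`
#'   (fraction in `[0, 1]`) and `n_alleles` (total allele count for that
#'   locus).
#' @param resolution 1 (allele group) or 2 (protein level); all entries
#'   must have this resolution.
#' @param name panel label.
#' @return data.frame of class `hla_freq_panel` with attributes `name` and
#'   `resolution`.
#' @export
frequency_panel <- function(entries, resolution, name = "panel") {
  stopifnot(all(c("locus", "allele", "frequency", "n_alleles") %in%
                  names(entries)))
  entries <- as.data.frame(entries)
  p <- parse_hla(entries$allele)
  entries$allele <- p$allele
  if (any(p$locus != entries$locus)) {
    stop("allele '", p$allele[p$locus != entries$locus][1L],
         "' does not match its locus column", call. = FALSE)
  }
  if (any(p$resolution != resolution)) {
    stop("mixed resolutions in panel: '",
         p$allele[p$resolution != resolution][1L], "' is not at ",
         resolution, " field(s)", call. = FALSE)
  }
  if (any(entries$frequency < 0 | entries$frequency > 1)) {
    stop("panel frequency outside [0, 1]", call. = FALSE)
  }
  sums <- tapply(entries$frequency, entries$locus, sum)
  if (any(sums > 1.02)) {
    stop("panel frequencies for locus ",
         names(sums)[sums > 1.02][1L], " sum to ",
         round(max(sums), 4), " > 1.02", call. = FALSE)
  }
  if (any(entries$n_alleles <= 0)) {
    stop("panel n_alleles must be positive", call. = FALSE)
  }
  structure(entries, name = name, resolution = as.integer(resolution),
            class = c("hla_freq_panel", "data.frame"))
}

#' Read a reference frequency panel
#'
#' Expects a delimited file with columns `locus`, `allele`, `frequency`,
#' `frequency_unit` (`fraction` or `percent`), `n`, `n_unit`
#' (`individuals` or `alleles`). Frequencies are normalized to fractions;
#' `n` given as individuals is doubled to an allele count. A frequency
#' above 1 without an explicit `percent` unit is refused rather than
#' guessed.
#'
#' @param path file path.
#' @param resolution expected field resolution of all entries (1 or 2).
#' @param name panel label (defaults to the file name).
#' @param sep field separator.
#' @return an `hla_freq_panel`.
#' @export
read_frequency_panel <- function(path, resolution, name = basename(path),
                                 sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("locus", "allele", "frequency", "frequency_unit", "n", "n_unit")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("panel file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(df$frequency_unit %in% c("fraction", "percent"))) {
    stop("frequency_unit must be 'fraction' or 'percent'", call. = FALSE)
  }
  if (any(df$frequency_unit == "fraction" & df$frequency > 1)) {
    stop("frequency > 1 declared as fraction; refuse to guess units",
         call. = FALSE)
  }
  freq <- ifelse(df$frequency_unit == "percent", df$frequency / 100,
                 df$frequency)
  if (!all(df$n_unit %in% c("individuals", "alleles"))) {
    stop("n_unit must be 'individuals' or 'alleles'", call. = FALSE)
  }
  n_alleles <- ifelse(df$n_unit == "individuals", 2L * df$n, df$n)
  frequency_panel(
    data.frame(locus = df$locus, allele = df$allele, frequency = freq,
               n_alleles = n_alleles, stringsAsFactors = FALSE),
    resolution = resolution, name = name
  )
}

#' Look up panel frequency and allele-count denominator
#'
#' @param panel an `hla_freq_panel`.
#' @param locus locus tag.
#' @param allele optional allele name; when given, returns its frequency
#'   (0 for alleles the panel omits).
#' @return for `panel_frequency`, a single frequency; for
#'   `panel_n_alleles`, the locus total allele count (error if the locus
#'   is absent from the panel).
#' @export
panel_frequency <- function(panel, locus, allele) {
  allele <- parse_hla(allele)$allele
  hit <- panel$locus == locus & panel$allele == allele
  if (!any(hit)) return(0)
  panel$frequency[hit][1L]
}

#' @rdname panel_frequency
#' @export
panel_n_alleles <- function(panel, locus) {
  hit <- panel$locus == locus
  if (!any(hit)) {
    stop("locus ", locus, " absent from panel '", attr(panel, "name"), "'",
         call. = FALSE)
  }
  panel$n_alleles[hit][1L]
}

#' Loci present in a panel
#' @param panel an `hla_freq_panel`.
#' @return character vector of locus tags.
#' @export
panel_loci <- function(panel) unique(panel$locus)
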