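
#' Parse HLA allele names
#'
#' Parses allele names of the form `<locus>*<f1>[:<f2>[:...]][suffix]`,
#' e.g. `"B*44:27"`, `"A*68:18N"`, `"DRB1*16"`. Only the five loci in
#' [HLA_LOCI] are accepted. Names with more than two colon-separated fields
#' are accepted on input and truncated to two fields (all analyses here use
#' at most protein-level, "four-digit", resolution); an expression suffix is
#' kept only when no field carrying it is dropped.
#'
#' @param x character vector of allele names.
#' @return A data.frame of class `hla_alleles` with columns `allele`
#'   (canonical string), `locus`, `field1`, `field2` (NA at one-field
#'   resolution), `suffix` (NA when absent) and `resolution` (number of
#'   fields retained, 1 or 2).
#' @examples
#' parse_hla(c("B*44:27", "A*68:18N", "DRB1*16"))
#' @export
parse_hla <- function(x) {
  if (length(x) == 0L || !is.character(x)) {
    stop("allele names must be a non-empty character vector", call. = FALSE)
  }
  if (anyNA(x) || any(!nzchar(x))) {
    stop("allele name is empty or NA", call. = FALSE)
  }
  m <- regmatches(x, regexec("^([A-Za-z0-9]+)\\*(.+)$", x))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("malformed allele name (missing '*'): '", x[bad][1L], "'",
         call. = FALSE)
  }
  locus <- vapply(m, `[`, "", 2L)
  rest <- vapply(m, `[`, "", 3L)
  unknown <- !(locus %in% HLA_LOCI)
  if (any(unknown)) {
    stop("unknown HLA locus '", locus[unknown][1L], "' in '",
         x[unknown][1L], "'", call. = FALSE)
  }
  suffix <- rep(NA_character_, length(x))
  has_suf <- grepl("[A-Za-z]$", rest)
  suffix[has_suf] <- substring(rest[has_suf], nchar(rest[has_suf]))
  bad_suf <- has_suf & !(suffix %in% HLA_SUFFIXES)
  if (any(bad_suf)) {
    stop("unknown expression suffix '", suffix[bad_suf][1L], "' in '",
         x[bad_suf][1L], "'", call. = FALSE)
  }
  body <- ifelse(has_suf, substring(rest, 1L, nchar(rest) - 1L), rest)
  fields <- strsplit(body, ":", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 1L && all(grepl("^[0-9]+$", f))
  }, TRUE)
  if (any(!ok)) {
    stop("non-numeric field in allele name '", x[!ok][1L], "'",
         call. = FALSE)
  }
  nf <- lengths(fields)
  # six/eight-digit names collapse to two fields; suffix dropped with the
  # deeper fields it annotated
  suffix[nf > 2L] <- NA_character_
  f1 <- vapply(fields, function(f) as.integer(f[1L]), 1L)
  f2 <- vapply(fields, function(f) {
    if (length(f) >= 2L) as.integer(f[2L]) else NA_integer_
  }, 1L)
  res <- ifelse(is.na(f2), 1L, 2L)
  out <- data.frame(
    allele = hla_format(locus, f1, f2, suffix),
    locus = locus, field1 = f1, field2 = f2, suffix = suffix,
    resolution = res, stringsAsFactors = FALSE
  )
  class(out) <- c("hla_alleles", "data.frame")
  out
}

#' Serialize HLA allele components to canonical strings
#'
#' Fields are zero-padded to a minimum width of 2 (`"B*08"`, not `"B*8"`).
#'
#' @param locus,field1 locus tag and first numeric field.
#' @param field2 second field or NA.
#' @param suffix expression suffix letter or NA.
#' @return character vector of canonical names.
#' @export
hla_format <- function(locus, field1, field2 = NA_integer_,
                       suffix = NA_character_) {
  pad <- function(v) formatC(v, width = 2L, flag = "0")
  out <- paste0(locus, "*", pad(field1))
  two <- !is.na(field2)
  out[two] <- paste0(out[two], ":", pad(field2[two]))
  suf <- !is.na(suffix) & two
  out[suf] <- paste0(out[suf], suffix[suf])
  out[!is.na(suffix) & !two] <- paste0(out[!is.na(suffix) & !two],
                                       suffix[!is.na(suffix) & !two])
  out
}

#' Truncate allele names to a lower field resolution
#'
#' Collapses protein-level ("four-digit") names to allele-group
#' ("two-digit") names, e.g. `"DRB1*14:54"` to `"DRB1*14"`. The expression
#' suffix is dropped whenever the field it annotates is dropped. Requesting
#' more fields than a name carries is an error: precision is never
#' invented.
#'
#' @param x character vector of allele names.
#' @param fields target number of fields (1 or 2).
#' @return character vector of truncated canonical names.
#' @examples
#' hla_truncate("DRB1*14:54", 1)  # "DRB1*14"
#' hla_truncate("B*08", 1)        # identity
#' @export
hla_truncate <- function(x, fields) {
  stopifnot(length(fields) == 1L, fields %in% c(1L, 2L))
  p <- parse_hla(x)
  short <- p$resolution < fields
  if (any(short)) {
    stop("cannot truncate '", p$allele[short][1L], "' to ", fields,
         " fields: only ", p$resolution[short][1L], " available",
         call. = FALSE)
  }
  if (fields == 2L) return(p$allele)
  hla_format(p$locus, p$field1)
}

#' Locus of each allele name
#' @param x character vector of allele names.
#' @return character vector of locus tags.
#' @export
hla_locus <- function(x) parse_hla(x)$locus

#' Resolution (number of fields) of each allele name
#' @param x character vector of allele names.
#' @return integer vector, 1 or 2.
#' @export
hla_resolution <- function(x) parse_hla(x)$resolution
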