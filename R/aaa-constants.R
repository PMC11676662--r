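#' @keywords internal
"_PACKAGE"

#' HLA loci covered by the package
#'
#' The five classical loci typed in the cohort: class I A, B, C and
#' class II DRB1, DQB1.
#' @export
HLA_LOCI <- c("A", "B", "C", "DRB1", "DQB1")

# Expression-variant suffix letters admitted at the end of an allele name.
HLA_SUFFIXES <- c("N", "L", "S", "C", "A", "Q")
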