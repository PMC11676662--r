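# Seeded synthetic cohort generators.

# Default metadata generator settings: the demographic mix of the study
# cohort (proportions of 40 subjects).
DEFAULT_META_PROBS <- list(
  sex = c(F = 0.80, M = 0.20),
  serotype = c(RAchPos = 0.75, MuSKPos = 0.025, dSNMG = 0.225),
  onset_class = c(MGj = 0.075, EOMG = 0.575, LOMG = 0.35),
  mgfa_max = c(I = 0.125, IIA = 0.35, IIB = 0.275, IIIB = 0.05, V = 0.20),
  thymic_status = c(normal_ct = 0.55, thymoma = 0.225,
                    follicular_hyperplasia = 0.225),
  autoimmune = 0.275
)

#' Specify a synthetic cohort simulation
#'
#' Subjects are drawn i.i.d.; at each locus the two alleles are drawn
#' independently from the locus frequencies (Hardy-Weinberg), unless a
#' `pair_excess` entry shifts probability mass onto a specific unordered
#' pair (forcing within-locus disequilibrium of a target size).
#'
#' @param freqs named list (by locus) of named numeric allele-frequency
#'   vectors, each summing to 1 (tolerance 1e-6).
#' @param n_subjects cohort size (> 0).
#' @param pair_excess optional data.frame `locus, allele1, allele2, d_pct`
#'   adding `d_pct` percentage points to the pair's HWE probability; the
#'   remaining pairs are rescaled. Infeasible excesses error at sampling.
#' @param meta_probs metadata category probabilities; defaults mirror the
#'   study cohort's demographics.
#' @return list of class `hla_sim_spec`.
#' @export
simulation_spec <- function(freqs, n_subjects, pair_excess = NULL,
                            meta_probs = DEFAULT_META_PROBS) {
  if (n_subjects <= 0) stop("n_subjects must be positive", call. = FALSE)
  stopifnot(is.list(freqs), length(freqs) > 0,
            all(names(freqs) %in% HLA_LOCI))
  for (loc in names(freqs)) {
    f <- freqs[[loc]]
    if (is.null(names(f)) || any(f < 0)) {
      stop("frequencies for locus ", loc,
           " must be a named non-negative vector", call. = FALSE)
    }
    if (abs(sum(f) - 1) > 1e-6) {
      stop("frequencies for locus ", loc, " sum to ", sum(f), ", not 1",
           call. = FALSE)
    }
    names(freqs[[loc]]) <- parse_hla(names(f))$allele
  }
  if (!is.null(pair_excess)) {
    stopifnot(all(c("locus", "allele1", "allele2", "d_pct") %in%
                    names(pair_excess)))
  }
  structure(list(freqs = freqs, n_subjects = as.integer(n_subjects),
                 pair_excess = pair_excess, meta_probs = meta_probs),
            class = "hla_sim_spec")
}

# Unordered-pair probability table for one locus under HWE, optionally
# tilted by the spec's pair_excess entries.
pair_distribution <- function(f, excess = NULL) {
  al <- names(f)
  k <- length(al)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  a1 <- pmin(al[idx[, 1L]], al[idx[, 2L]])
  a2 <- pmax(al[idx[, 1L]], al[idx[, 2L]])
  prob <- ifelse(idx[, 1L] == idx[, 2L], f[idx[, 1L]]^2,
                 2 * f[idx[, 1L]] * f[idx[, 2L]])
  if (!is.null(excess) && nrow(excess)) {
    excess$allele1 <- parse_hla(excess$allele1)$allele
    excess$allele2 <- parse_hla(excess$allele2)$allele
    key <- paste(a1, a2, sep = "|")
    tkey <- paste(pmin(excess$allele1, excess$allele2),
                  pmax(excess$allele1, excess$allele2), sep = "|")
    hit <- match(tkey, key)
    if (anyNA(hit)) {
      stop("pair_excess names alleles absent from the locus frequencies",
           call. = FALSE)
    }
    # d_pct is on the LD-coefficient scale: the target pair frequency is
    # the allele-frequency product plus d, so the sampled cohort shows
    # P_XY - P_X * P_Y ~= d_pct points
    i1 <- match(excess$allele1, al); i2 <- match(excess$allele2, al)
    target <- f[i1] * f[i2] + excess$d_pct / 100
    if (any(target < 0 | target > 1)) {
      stop("infeasible pair_excess: target pair probability outside [0,1]",
           call. = FALSE)
    }
    rest <- setdiff(seq_along(prob), hit)
    scale <- (1 - sum(target)) / sum(prob[rest])
    if (scale < 0) {
      stop("infeasible pair_excess: excess mass exceeds 1", call. = FALSE)
    }
    prob[rest] <- prob[rest] * scale
    prob[hit] <- target
  }
  data.frame(allele1 = a1, allele2 = a2, prob = prob,
             stringsAsFactors = FALSE)
}

#' Sample a synthetic cohort
#'
#' Fully reproducible given `spec` and `seed` (a single integer seed
#' drives all loci and metadata draws).
#'
#' @param spec an `hla_sim_spec`.
#' @param seed integer seed.
#' @return an `hla_cohort` with subject ids `sim001`, `sim002`, ...
#' @export
sample_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "hla_sim_spec"))
  n <- spec$n_subjects
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  df <- data.frame(
    subject_id = sprintf("sim%03d", seq_len(n)), stringsAsFactors = FALSE
  )
  for (loc in HLA_LOCI) {
    col1 <- paste0(loc, "_1"); col2 <- paste0(loc, "_2")
    if (is.null(spec$freqs[[loc]])) {
      df[[col1]] <- NA_character_; df[[col2]] <- NA_character_
      next
    }
    ex <- spec$pair_excess
    if (!is.null(ex)) ex <- ex[ex$locus == loc, , drop = FALSE]
    pd <- pair_distribution(spec$freqs[[loc]], ex)
    pick <- sample.int(nrow(pd), n, replace = TRUE, prob = pd$prob)
    df[[col1]] <- pd$allele1[pick]
    df[[col2]] <- pd$allele2[pick]
  }
  mp <- spec$meta_probs
  draw <- function(pr) names(pr)[sample.int(length(pr), n, replace = TRUE,
                                            prob = pr)]
  df$sex <- draw(mp$sex)
  df$onset_class <- draw(mp$onset_class)
  # ages drawn inside the band the onset class dictates
  df$age_at_onset <- ifelse(
    df$onset_class == "MGj", sample(5:17, n, replace = TRUE),
    ifelse(df$onset_class == "EOMG", sample(18:49, n, replace = TRUE),
           sample(50:80, n, replace = TRUE)))
  df$mgfa_max <- draw(mp$mgfa_max)
  df$serotype <- draw(mp$serotype)
  df$thymic_status <- draw(mp$thymic_status)
  df$autoimmune <- stats::runif(n) < mp$autoimmune
  df$titin_ryr <- "none"
  as_hla_cohort(df)
}

#' Inject a case-control allele effect into a simulation spec
#'
#' Sets the case frequency q of one allele so its odds are `target_or`
#' times the panel odds: `q/(1-q) = OR * p/(1-p)`. The other alleles at
#' the locus are rescaled to keep the frequencies summing to 1.
#'
#' @param spec an `hla_sim_spec`.
#' @param locus,allele the risk allele.
#' @param target_or target odds ratio (> 0, finite).
#' @param panel an `hla_freq_panel` supplying the reference frequency p.
#' @return the modified `hla_sim_spec`.
#' @export
inject_case_effect <- function(spec, locus, allele, target_or, panel) {
  stopifnot(inherits(spec, "hla_sim_spec"))
  if (!is.finite(target_or) || target_or <= 0) {
    stop("target_or must be a positive finite odds ratio", call. = FALSE)
  }
  p <- panel_frequency(panel, locus, allele)
  if (p <= 0 || p >= 1) {
    stop("panel frequency for ", allele, " must be inside (0, 1)",
         call. = FALSE)
  }
  odds <- target_or * p / (1 - p)
  q <- odds / (1 + odds)
  f <- spec$freqs[[locus]]
  if (is.null(f)) stop("locus ", locus, " absent from spec", call. = FALSE)
  al <- parse_hla(allele)$allele
  if (!(al %in% names(f))) f[al] <- 0
  rest <- setdiff(names(f), al)
  f[rest] <- f[rest] * (1 - q) / sum(f[rest])
  f[al] <- q
  spec$freqs[[locus]] <- f
  spec
}
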