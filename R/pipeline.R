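# Study workflow orchestration and report exports.

cohort_locus_resolution <- function(cohort, locus) {
  g <- locus_alleles(cohort, locus)
  if (g$n == 0L) return(0L)
  min(parse_hla(c(g$a1, g$a2))$resolution)
}

#' Default carrier-comparison trait set
#'
#' The demographic, clinical and thymic traits compared between carriers
#' and non-carriers: sex, onset class, MGFA severity (including bulbar
#' involvement, IIB/IIIB), autoimmune comorbidity and thymic pathology.
#' @return named list of predicate functions for
#'   [compare_carrier_phenotypes()].
#' @export
default_traits <- function() {
  list(
    female = function(m) m$sex == "F",
    EOMG = function(m) m$onset_class == "EOMG",
    LOMG = function(m) m$onset_class == "LOMG",
    MGj = function(m) m$onset_class == "MGj",
    mgfa_I = function(m) m$mgfa_max == "I",
    mgfa_IIA = function(m) m$mgfa_max == "IIA",
    mgfa_V = function(m) m$mgfa_max == "V",
    bulbar = function(m) m$mgfa_max %in% c("IIB", "IIIB"),
    autoimmune_comorbidity = function(m) m$autoimmune,
    thymoma = function(m) m$thymic_status == "thymoma",
    follicular_hyperplasia =
      function(m) m$thymic_status == "follicular_hyperplasia"
  )
}

#' Default study configuration
#'
#' Returns the configuration run_study() uses when fields are omitted:
#' the bundled synthetic cohort and Romanian panels, B*40 as the carrier
#' allele, Yates threshold 5, alpha 0.05, LD thresholds 4 (cases) and 2
#' (controls), BH families per locus.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest (the bundled inputs
#'   are deterministic).
#' @return named list.
#' @export
default_study_config <- function(out_dir = tempfile("hlacc_run_"),
                                 seed = 1L) {
  list(
    cohort = NULL, panel_lowres = NULL, panel_highres = NULL,
    national = NULL, carrier_allele = "B*40",
    groups = list(total = NULL, RAchPos = "RAchPos", dSNMG = "dSNMG"),
    min_group_size = 2L, yates_threshold = 5, alpha = 0.05,
    ld_threshold_case = 4, ld_threshold_control = 2,
    pair_loci = c("A", "B", "DRB1"),
    out_dir = out_dir, seed = as.integer(seed)
  )
}

#' Read a study configuration from YAML
#' @param path YAML file; keys as in [default_study_config()].
#' @return config list merged over the defaults.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_study_config()
  base[names(cfg)] <- cfg
  base
}

load_or <- function(x, loader, default) {
  if (is.null(x)) default else loader(x)
}

#' Run the full association study workflow
#'
#' Stages, in order: (1) one-sample proportion Z tests of cohort allele
#' frequencies against the national scalar frequencies; (2) two-digit
#' association of each analysis group (total cohort, anti-AChR-positive,
#' double-seronegative; groups below `min_group_size` are skipped with a
#' logged reason, which excludes the single MuSK-positive subject) against
#' the low-resolution panel, per locus, BH-corrected per locus family;
#' (3) the same at four-digit resolution against the high-resolution
#' panel when the cohort typing carries two fields (skipped otherwise);
#' (4) carrier-phenotype comparison for `carrier_allele`; (5) genotype
#' pair tables, HWE tests and LD scans per pair locus, for the cohort
#' and the bundled control pair tables. Each stage writes a TSV under
#' `out_dir` and the whole run writes a JSON manifest with parameters,
#' seed and a stage log.
#'
#' @param config list as produced by [default_study_config()] or
#'   [read_study_config()]; NULL input fields fall back to the bundled
#'   reference data.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_study <- function(config = default_study_config()) {
  cfg <- default_study_config()
  cfg[names(config)] <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log <<- c(log, msg)
  }
  cohort <- load_or(cfg$cohort, read_cohort, mg_reference_cohort())
  panel1 <- load_or(cfg$panel_lowres,
                    function(p) read_frequency_panel(p, 1L),
                    romanian_panel_lowres())
  panel2 <- load_or(cfg$panel_highres,
                    function(p) read_frequency_panel(p, 2L),
                    romanian_panel_highres())
  national <- if (is.null(cfg$national)) national_allele_frequencies() else {
    tab <- utils::read.table(cfg$national, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stats::setNames(ifelse(tab$frequency_unit == "percent",
                           tab$frequency / 100, tab$frequency), tab$allele)
  }
  note("cohort: ", nrow(cohort), " subjects")
  results <- list()

  # stage 1: national-frequency Z screen
  zrows <- lapply(names(national), function(al) {
    p <- parse_hla(al)
    counts <- count_alleles(cohort, p$locus, p$resolution)
    x <- counts$count[match(p$allele, counts$allele)]
    x <- if (is.na(x)) 0L else x
    zt <- one_sample_proportion_z(x, attr(counts, "denominator"),
                                  national[[al]])
    data.frame(allele = p$allele, count = x,
               n = attr(counts, "denominator"), cohort_freq = zt$estimate,
               national_freq = national[[al]], z = zt$z, p = zt$p,
               stringsAsFactors = FALSE)
  })
  results$national_z <- do.call(rbind, zrows)
  utils::write.table(results$national_z,
                     file.path(cfg$out_dir, "national_z_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("stage national_z: ", nrow(results$national_z), " alleles")

  # stages 2-3: association per group x resolution
  groups <- lapply(cfg$groups, function(g) {
    if (is.null(g)) cohort else {
      suppressMessages(select_subgroup(cohort, serotype == g))
    }
  })
  for (res in 1:2) {
    panel <- if (res == 1L) panel1 else panel2
    key <- paste0("assoc_", res, "digit")
    results[[key]] <- list()
    for (gname in names(groups)) {
      grp <- groups[[gname]]
      if (nrow(grp) < cfg$min_group_size) {
        note("stage ", key, "/", gname, ": skipped (n = ", nrow(grp),
             " below minimum ", cfg$min_group_size, ")")
        next
      }
      per_locus <- list()
      for (loc in intersect(HLA_LOCI, panel_loci(panel))) {
        if (cohort_locus_resolution(grp, loc) < res) {
          note("stage ", key, "/", gname, "/", loc,
               ": skipped (typing below ", res, "-field resolution)")
          next
        }
        counts <- count_alleles(grp, loc, res)
        per_locus[[loc]] <- associate_allele_set(
          counts, panel, yates_threshold = cfg$yates_threshold,
          alpha = cfg$alpha)
      }
      if (length(per_locus)) {
        results[[key]][[gname]] <- per_locus
        combined <- do.call(rbind, lapply(per_locus, as.data.frame))
        utils::write.table(
          combined, file.path(cfg$out_dir,
                              paste0(key, "_", gname, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        note("stage ", key, "/", gname, ": ", nrow(combined), " tests (n = ",
             nrow(grp), " subjects)")
      }
    }
  }

  # stage 4: carrier phenotype comparison
  results$carriers <- compare_carrier_phenotypes(cohort, cfg$carrier_allele,
                                                 default_traits())
  utils::write.table(as.data.frame(results$carriers),
                     file.path(cfg$out_dir, "carrier_phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("stage carriers: ", cfg$carrier_allele, ", ",
       sum(carrier_flags(cohort, cfg$carrier_allele)), " carriers")

  # stage 5: pair tables, HWE, LD
  results$pairs <- list(); results$hwe <- list(); results$ld <- list()
  for (loc in cfg$pair_loci) {
    pt <- genotype_pair_frequencies(cohort, loc, 1L)
    results$pairs[[loc]] <- pt
    write_stats_table(pt, file.path(cfg$out_dir,
                                    paste0("pairs_", loc, ".tsv")))
    results$hwe[[loc]] <- hwe_test(pt)
    freqs <- count_alleles(cohort, loc, 1L)
    results$ld[[loc]] <- ld_scan(pt, freqs, cfg$ld_threshold_case)
    ctrl <- control_pair_table(loc)
    results$ld[[paste0(loc, "_control")]] <-
      ld_scan(ctrl, panel1[panel1$locus == loc, ], cfg$ld_threshold_control)
    note("stage popgen/", loc, ": HWE p = ",
         format_pvalue(results$hwe[[loc]]$p), ", ",
         nrow(results$ld[[loc]]), " case pairs above LD threshold")
  }
  ld_all <- do.call(rbind, lapply(names(results$ld), function(nm) {
    cbind(table = nm, as.data.frame(results$ld[[nm]]))
  }))
  utils::write.table(ld_all, file.path(cfg$out_dir, "ld_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hwe_df <- do.call(rbind, lapply(names(results$hwe), function(nm) {
    h <- results$hwe[[nm]]
    data.frame(locus = nm, chi2 = h$chi2, df = h$df, p = h$p,
               pooled = h$n_pooled)
  }))
  utils::write.table(hwe_df, file.path(cfg$out_dir, "hwe_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 6: heatmap matrix (cases vs bundled control pair tables)
  hm <- heatmap_matrix(
    stats::setNames(lapply(cfg$pair_loci,
                           function(l) results$pairs[[l]]), cfg$pair_loci),
    stats::setNames(lapply(cfg$pair_loci, control_pair_table),
                    cfg$pair_loci))
  utils::write.table(cbind(row = rownames(hm), as.data.frame(hm)),
                     file.path(cfg$out_dir, "heatmap_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$heatmap <- hm

  manifest <- list(
    package = "hlacc",
    version = as.character(utils::packageVersion("hlacc")),
    seed = cfg$seed,
    parameters = cfg[c("carrier_allele", "min_group_size",
                       "yates_threshold", "alpha", "ld_threshold_case",
                       "ld_threshold_control", "pair_loci")],
    n_subjects = nrow(cohort),
    stages = log,
    outputs = dir(cfg$out_dir)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Frequency matrix for heatmap rendering
#'
#' Rows are genotype pairs ("A*02-A*24") followed by individual alleles;
#' one column per group; values are percent frequencies (0 for absent
#' pairs). Over the pair rows of a complete table each column sums to
#' 100. Rendering (e.g. with pheatmap) is left to the caller.
#'
#' @param case_pairs,control_pairs named lists (by locus) of
#'   `hla_pair_freqs` for the two groups.
#' @return numeric matrix with columns `case` and `control`.
#' @export
heatmap_matrix <- function(case_pairs, control_pairs) {
  stopifnot(identical(names(case_pairs), names(control_pairs)))
  blocks <- lapply(names(case_pairs), function(loc) {
    cp <- case_pairs[[loc]]; kp <- control_pairs[[loc]]
    keys <- sort(union(paste(cp$allele1, cp$allele2, sep = "-"),
                       paste(kp$allele1, kp$allele2, sep = "-")))
    get <- function(tab, keys) {
      k <- paste(tab$allele1, tab$allele2, sep = "-")
      out <- 100 * tab$frequency[match(keys, k)]
      out[is.na(out)] <- 0
      out
    }
    pair_block <- cbind(case = get(cp, keys), control = get(kp, keys))
    rownames(pair_block) <- keys
    ca <- allele_counts_from_pairs(cp)
    al_keys <- ca$allele
    al_block <- cbind(case = 100 * ca$frequency,
                      control = rep(NA_real_, nrow(ca)))
    rownames(al_block) <- al_keys
    rbind(pair_block, al_block)
  })
  do.call(rbind, blocks)
}
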