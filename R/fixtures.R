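#' Load the packaged validation-cohort tables
#'
#' Three TSVs summarizing a 40-family clinical validation cohort of couples at
#' risk for autosomal recessive disorders (beta- and alpha-thalassemia,
#' methylmalonic acidemia, phenylketonuria, ARPKD and DFNB1A):
#' `"families"` — per-family disease, gene, parental/fetal genotypes,
#' gestational age and plasma fetal fraction (percent); `"phase_blocks"` — the
#' phase block spanning the target gene for each parent (interval, size in kb,
#' SNP count); `"nipd"` — informative-SNP counts, confidence scores (percent)
#' and the noninvasive vs. invasive diagnosis per parental allele. In the
#' genotype columns `N` denotes the normal allele, `NC` a no-call and `NA` a
#' parent excluded by phasing failure; variant alleles appear under their HGVS
#' names.
#'
#' @param which One of `"families"`, `"phase_blocks"`, `"nipd"`.
#' @return A `data.frame`.
#' @export
load_cohort_table <- function(which = c("families", "phase_blocks", "nipd")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("cohort_", which, ".tsv"),
                   package = "haplonipt")
  utils::read.delim(f, stringsAsFactors = FALSE, na.strings = "NA")
}

# map a reported allele string to the P/N/NO_CALL/NA code space
code_allele <- function(x) {
  ifelse(is.na(x) | x == "NA", "NA",
         ifelse(x == "N", "N", ifelse(x == "NC", "NO_CALL", "P")))
}

#' Cohort fetal-fraction summary
#'
#' @param families The `"families"` cohort table (default: packaged fixture).
#' @return `list(mean_pct, min_pct, max_pct, n)` of plasma fetal fractions.
#' @export
fetal_fraction_summary <- function(families = load_cohort_table("families")) {
  ff <- families$ff_pct
  list(mean_pct = mean(ff), min_pct = min(ff), max_pct = max(ff),
       n = length(ff))
}

#' Cohort phase-block summary
#'
#' @param blocks The `"phase_blocks"` cohort table (default: packaged fixture).
#' @return `list(min_snps, max_snps, mean_snps, n_blocks, mean_size_kb)` over
#'   the per-parent gene-spanning phase blocks.
#' @export
phase_block_summary <- function(blocks = load_cohort_table("phase_blocks")) {
  list(min_snps = min(blocks$n_snps), max_snps = max(blocks$n_snps),
       mean_snps = mean(blocks$n_snps), n_blocks = nrow(blocks),
       mean_size_kb = mean(blocks$block_size_kb))
}

#' Cohort diagnosis summary
#'
#' Recomputes the headline cohort results from the per-family table through
#' the package's own call-combination machinery: parental haplotype calls
#' resolved, concordance of the noninvasive against the invasive diagnosis,
#' and the affected/carrier/normal breakdown.
#'
#' @param nipd The `"nipd"` cohort table (default: packaged fixture).
#' @return `list(n_families, n_parental_haplotypes, n_called_both,
#'   n_concordant, n_no_call_families, n_affected, n_carrier, n_normal)`.
#' @export
nipd_summary <- function(nipd = load_cohort_table("nipd")) {
  reports <- data.frame(family_id = nipd$family,
                        mat_call = code_allele(nipd$nipd_mat),
                        pat_call = code_allele(nipd$nipd_pat),
                        stringsAsFactors = FALSE)
  truth <- data.frame(family_id = nipd$family,
                      mat_true = code_allele(nipd$invasive_mat),
                      pat_true = code_allele(nipd$invasive_pat),
                      stringsAsFactors = FALSE)
  ct <- concordance_table(reports, truth)
  list(n_families = nrow(nipd),
       n_parental_haplotypes = sum(!is.na(nipd$cs_mat_pct)) +
                               sum(!is.na(nipd$cs_pat_pct)),
       n_called_both = ct$n_called_both,
       n_concordant = ct$n_concordant,
       n_no_call_families = ct$n_no_call_families,
       n_affected = unname(ct$categories["AFFECTED"]),
       n_carrier = unname(ct$categories["CARRIER"]),
       n_normal = unname(ct$categories["NORMAL"]))
}

#' Parse a weeks+days gestational-age string
#'
#' `"12+4"` means 12 weeks 4 days = 12 + 4/7 weeks.
#'
#' @param ga Character vector like `"12+4"` or `"18"`.
#' @return Gestational age in decimal weeks.
#' @export
parse_gestational_age <- function(ga) {
  parts <- strsplit(as.character(ga), "+", fixed = TRUE)
  vapply(parts, function(p) {
    w <- as.numeric(p[1L])
    if (length(p) > 1L) w + as.numeric(p[2L]) / 7 else w
  }, 0)
}
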