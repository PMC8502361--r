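#' Run the full noninvasive diagnosis pipeline for one family
#'
#' Phasing (barcode-graph assembly when barcode observations are available,
#' otherwise the phased-diplotype bypass) -> pathogenic-variant anchoring ->
#' informative-SNP classification -> fetal-fraction estimation -> per-parent
#' Viterbi decoding -> rule-based allele calls -> Monte-Carlo confidence
#' scores -> fetal genotype category.
#'
#' @param config A list. Either simulated input, `sim = simulate_family(...)`
#'   (or `sim_args =` a list of arguments for [simulate_family()]), or file
#'   input, `files = list(mother_vcf, father_vcf, plasma, map)` with phased
#'   single-sample VCFs whose pathogenic sites carry the `PATHOGENIC` INFO
#'   flag. Optional fields: `family_id`, `gene_interval` (required for file
#'   input), `ff` (overrides estimation), `replicates` (default 1000),
#'   `cs_threshold` (0.99), `eps` (0.005), `min_support`/`min_margin` (2/2,
#'   barcode phasing), `min_depth` (50, ff estimation), `seed`, `out` (path
#'   for a JSON report).
#' @return A `family_report` list: family_id, ff, per-parent calls (allele,
#'   rule allele, reason, confidence score, decision, number of informative
#'   SNPs), genotype category, and for simulated input the truth alleles and a
#'   concordance flag.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  replicates <- config$replicates %||% 1000L
  threshold <- config$cs_threshold %||% 0.99
  eps <- config$eps %||% 0.005
  min_support <- config$min_support %||% 2L
  min_margin <- config$min_margin %||% 2L
  min_depth <- config$min_depth %||% 50L

  if (!is.null(config$sim) || !is.null(config$sim_args)) {
    sim <- config$sim %||% do.call(simulate_family, config$sim_args)
    panel <- sim$panel; mother <- sim$mother; father <- sim$father
    plasma <- sim$plasma; map <- sim$map
    gene_interval <- config$gene_interval %||% sim$gene_interval
    variant_idx <- list(mat = match(sim$pathogenic$mother$pos, panel$pos),
                        pat = match(sim$pathogenic$father$pos, panel$pos))
    barcode_obs <- sim$barcode_obs
    truth_alleles <- true_inherited_alleles(sim)
  } else if (!is.null(config$files)) {
    mother <- read_phased_vcf(config$files$mother_vcf)
    father <- read_phased_vcf(config$files$father_vcf)
    panel <- mother$panel
    raw <- read_plasma_tsv(config$files$plasma)
    at <- match(panel$pos, raw$pos)
    plasma <- data.frame(chrom = panel$chrom, pos = panel$pos,
                         ref_count = ifelse(is.na(at), 0L, raw$ref_count[at]),
                         alt_count = ifelse(is.na(at), 0L, raw$alt_count[at]),
                         stringsAsFactors = FALSE)
    map <- read_genetic_map_tsv(config$files$map)
    gene_interval <- config$gene_interval
    if (is.null(gene_interval)) stop("gene_interval is required for file input")
    variant_idx <- list(
      mat = which(mother$panel$is_pathogenic &
                    genotype_codes(mother) == 1L)[1L],
      pat = which(father$panel$is_pathogenic &
                    genotype_codes(father) == 1L)[1L])
    barcode_obs <- NULL
    truth_alleles <- NULL
  } else stop("config must provide sim, sim_args or files")

  hap_pair_for <- function(dip, obs, v_idx) {
    if (is.null(obs)) return(hap_pair_from_diplotype(dip))
    het <- which(genotype_codes(dip) == 1L)
    ev <- build_allele_barcode_graph(obs, het, panel)
    blocks <- assemble_phase_blocks(ev, het, panel, min_support, min_margin)
    anchor_pathogenic_variant(blocks, panel, v_idx, dip = dip,
                              parent_id = dip$sample_id)
  }
  hp_mat <- hap_pair_for(mother, barcode_obs$mat, variant_idx$mat)
  hp_pat <- hap_pair_for(father, barcode_obs$pat, variant_idx$pat)

  informative <- classify_informative_snps(mother, father, hp_mat, hp_pat)
  ff <- config$ff %||%
    as.numeric(estimate_fetal_fraction(plasma, informative, mother,
                                       min_depth = min_depth))
  hc <- extract_haplotype_counts(plasma, informative)

  decode_parent <- function(parent, hap_pair) {
    rows <- hc[hc$parent == parent, , drop = FALSE]
    out <- list(parent = parent, n_informative = nrow(rows),
                rule_allele = "NO_CALL", allele = "NO_CALL",
                cs = NA_real_, decision = NA_character_, reason = NULL)
    # a singleton anchor block contains the variant but links it to no other
    # SNP, so it cannot support dosage analysis: treat as phasing failure
    if (!isTRUE(hap_pair$covered) || length(hap_pair$snp_index) < 2L) {
      out$allele <- "NA"; out$rule_allele <- "NA"
      out$reason <- "phasing failed: no usable block covers the pathogenic variant"
      return(out)
    }
    if (nrow(rows) == 0L) {
      out$reason <- "no informative SNPs"
      return(out)
    }
    path <- viterbi_decode(rows, ff, map, eps = eps)
    rc <- call_fetal_allele(path, gene_interval)
    out$rule_allele <- rc$allele
    out$reason <- rc$reason
    out$segments <- nrow(path$segments)
    if (rc$allele %in% c("P", "N")) {
      cs <- confidence_score(rows, ff, rc$allele, map, gene_interval,
                             replicates = replicates, threshold = threshold,
                             eps = eps,
                             seed = sample.int(.Machine$integer.max, 1L))
      out$cs <- cs$cs
      out$decision <- cs$decision
      out$allele <- if (cs$decision == "CALL") rc$allele else "NO_CALL"
      if (cs$decision == "NO_CALL") out$reason <- "confidence score below threshold"
    }
    out
  }
  mat <- decode_parent("mat", hp_mat)
  pat <- decode_parent("pat", hp_pat)

  report <- list(
    family_id = config$family_id %||% "SIM01",
    gene_interval = gene_interval, ff = ff,
    mat_call = mat, pat_call = pat,
    genotype_category = classify_fetal_genotype(mat$allele, pat$allele))
  if (!is.null(truth_alleles)) {
    report$truth <- truth_alleles
    report$concordant_with_truth <-
      mat$allele %in% c("P", "N") && pat$allele %in% c("P", "N") &&
      mat$allele == truth_alleles$mat && pat$allele == truth_alleles$pat
  }
  class(report) <- "family_report"
  if (!is.null(config$out)) {
    jsonlite::write_json(unclass(report), config$out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.family_report <- function(x, ...) {
  cat(sprintf("<family_report> %s: %s (ff = %.3f)\n  mat: %s (CS %s, %d SNPs)\n  pat: %s (CS %s, %d SNPs)\n",
              x$family_id, x$genotype_category, x$ff,
              x$mat_call$allele, format(x$mat_call$cs), x$mat_call$n_informative,
              x$pat_call$allele, format(x$pat_call$cs), x$pat_call$n_informative))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
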