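#' Classify SNPs by trio-free parental genotype configuration
#'
#' A site heterozygous in the mother and homozygous in the father powers the
#' maternal inheritance analysis (`MAT_INFORMATIVE`); the opposite
#' configuration powers the paternal analysis (`PAT_INFORMATIVE`); everything
#' else — both het, both hom, or missing — is `UNINFORMATIVE`.
#'
#' When the het parent's P/N haplotype labels are available the subtype records
#' which haplotype the hom parent's allele matches:
#' `father_hom_P` / `father_hom_N` for maternal-informative sites and
#' `mother_hom_P` / `mother_hom_N` for paternal-informative ones. The subtype
#' fixes the expected plasma dosage under each inheritance state (see
#' [expected_allele_fraction()]). `p_hap_allele` is the het parent's
#' pathogenic-linked allele at the site (NA outside covered phase blocks).
#'
#' @param mother,father [diplotype()]s over the same panel.
#' @param mother_hap,father_hap Optional `haplotype_pair`s from
#'   [anchor_pathogenic_variant()] or [hap_pair_from_diplotype()].
#' @return `data.frame(snp_index, chrom, pos, ref, alt, category, subtype,
#'   p_hap_allele)`.
#' @export
classify_informative_snps <- function(mother, father, mother_hap = NULL,
                                      father_hap = NULL) {
  p <- mother$panel
  gm <- genotype_codes(mother)
  gf <- genotype_codes(father)
  if (anyNA(gm) || anyNA(gf)) {
    warning(sprintf("%d site(s) with missing genotypes treated as uninformative",
                    sum(is.na(gm) | is.na(gf))))
  }
  category <- rep("UNINFORMATIVE", nrow(p))
  category[!is.na(gm) & !is.na(gf) & gm == 1L & gf %in% c(0L, 2L)] <- "MAT_INFORMATIVE"
  category[!is.na(gm) & !is.na(gf) & gf == 1L & gm %in% c(0L, 2L)] <- "PAT_INFORMATIVE"

  subtype <- rep(NA_character_, nrow(p))
  p_hap <- rep(NA_character_, nrow(p))
  fill <- function(rows, hap_pair, hom_codes, who) {
    if (is.null(hap_pair) || !isTRUE(hap_pair$covered)) return()
    at <- match(rows, hap_pair$snp_index)
    ok <- !is.na(at)
    rows <- rows[ok]; at <- at[ok]
    a <- hap_pair$P_alleles[at]
    hom_allele <- ifelse(hom_codes[rows] == 0L, p$ref[rows], p$alt[rows])
    subtype[rows] <<- ifelse(hom_allele == a,
                             paste0(who, "_hom_P"), paste0(who, "_hom_N"))
    p_hap[rows] <<- a
  }
  fill(which(category == "MAT_INFORMATIVE"), mother_hap, gf, "father")
  fill(which(category == "PAT_INFORMATIVE"), father_hap, gm, "mother")
  data.frame(snp_index = seq_len(nrow(p)), chrom = p$chrom, pos = p$pos,
             ref = p$ref, alt = p$alt, category = category, subtype = subtype,
             p_hap_allele = p_hap, stringsAsFactors = FALSE)
}

#' Estimate the fetal fraction from paternal-specific plasma alleles
#'
#' At paternal-informative sites the mother is homozygous, so any read carrying
#' the allele she lacks is (error aside) of fetal origin; its plasma fraction q
#' is f/2 when the fetus inherited the paternal-specific allele and ~0
#' otherwise. The estimator is ff = 2 * median(q) over the signal sites.
#' Because a father-heterozygous site carries the specific allele in only about
#' half of fetuses, q values are first split into signal/background clusters by
#' a deterministic 2-means (centers initialized at min(q) and max(q)); the
#' split is honoured only when the cluster gap exceeds twice the summed
#' within-cluster spreads — real bimodality — so site sets that are purely
#' signal (obligate-carrier sites) or purely background are not artificially
#' divided.
#'
#' @param counts Plasma counts (`chrom, pos, ref_count, alt_count`), rows
#'   parallel to the panel.
#' @param informative Output of [classify_informative_snps()].
#' @param mother The maternal [diplotype()] (identifies the allele she lacks).
#' @param min_depth Minimum plasma depth for a site to qualify.
#' @param q_max Sites with q above this are discarded as likely genotyping
#'   errors.
#' @param estimator `"median"` (robust default) or `"mean"`.
#' @param min_ff Estimates below this abort with an error (no detectable fetal
#'   signal); supply the fetal fraction explicitly in that case.
#' @return The estimated fetal fraction (numeric scalar) with attribute
#'   `n_sites`, the number of signal sites used.
#' @export
estimate_fetal_fraction <- function(counts, informative, mother,
                                    min_depth = 50L, q_max = 0.4,
                                    estimator = c("median", "mean"),
                                    min_ff = 0.01) {
  estimator <- match.arg(estimator)
  gm <- genotype_codes(mother)
  rows <- which(informative$category == "PAT_INFORMATIVE" & gm %in% c(0L, 2L))
  if (length(rows) == 0L)
    stop("no paternal-informative sites; supply the fetal fraction explicitly")
  depth <- counts$ref_count[rows] + counts$alt_count[rows]
  spec <- ifelse(gm[rows] == 0L, counts$alt_count[rows], counts$ref_count[rows])
  q <- spec / depth
  keep <- depth >= min_depth & is.finite(q) & q <= q_max
  q <- q[keep]; depth <- depth[keep]
  if (length(q) == 0L)
    stop("no paternal-informative site meets min_depth; supply the fetal fraction explicitly")

  qq <- q
  if (length(q) >= 4L && stats::sd(q) > 0) {
    km <- stats::kmeans(q, centers = matrix(c(min(q), max(q)), ncol = 1))
    hi <- which.max(km$centers)
    gap <- abs(diff(range(km$centers)))
    wsd <- vapply(1:2, function(g) {
      x <- q[km$cluster == g]
      if (length(x) > 1L) stats::sd(x) else 0
    }, 0)
    # a 2-means split of a unimodal cloud gives gap ~1.6 sd vs summed
    # within-cluster spreads ~2.4 sd, so this accepts only real bimodality
    n_hi <- sum(km$cluster == hi)
    if (gap > 2 * sum(wsd) && n_hi >= max(2L, ceiling(0.1 * length(q))))
      qq <- q[km$cluster == hi]
  }
  ff <- 2 * if (estimator == "median") stats::median(qq) else mean(qq)
  if (ff < min_ff)
    stop(sprintf("estimated fetal fraction %.4f is below %.3f (no detectable fetal signal); supply it explicitly",
                 ff, min_ff))
  ff <- min(ff, 0.999)
  attr(ff, "n_sites") <- length(qq)
  ff
}

#' Extract per-haplotype plasma counts at informative SNPs
#'
#' Relabels ref/alt plasma counts into counts of the pathogenic-linked (P) and
#' normal (N) haplotype alleles of the relevant parent. Sites whose het parent
#' lacks P/N labels (outside any covered phase block) are dropped with a
#' logged count; total depth is conserved over the retained sites.
#'
#' @param counts Plasma counts, rows parallel to the panel.
#' @param informative Output of [classify_informative_snps()].
#' @return `data.frame(snp_index, chrom, pos, parent, category, subtype,
#'   p_count, n_count, depth)` with `parent` in `{"mat", "pat"}`.
#' @export
extract_haplotype_counts <- function(counts, informative) {
  rows <- which(informative$category != "UNINFORMATIVE")
  covered <- rows[!is.na(informative$p_hap_allele[rows])]
  dropped <- length(rows) - length(covered)
  if (dropped > 0L)
    message(sprintf("%d informative SNP(s) outside covered phase blocks dropped", dropped))
  p_is_alt <- informative$p_hap_allele[covered] == informative$alt[covered]
  p_count <- ifelse(p_is_alt, counts$alt_count[covered], counts$ref_count[covered])
  n_count <- ifelse(p_is_alt, counts$ref_count[covered], counts$alt_count[covered])
  data.frame(snp_index = covered,
             chrom = informative$chrom[covered], pos = informative$pos[covered],
             parent = ifelse(informative$category[covered] == "MAT_INFORMATIVE",
                             "mat", "pat"),
             category = informative$category[covered],
             subtype = informative$subtype[covered],
             p_count = as.integer(p_count), n_count = as.integer(n_count),
             depth = as.integer(p_count + n_count), stringsAsFactors = FALSE)
}
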