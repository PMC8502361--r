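#' Construct a SNP marker panel
#'
#' A panel is the ordered set of biallelic SNP markers over the target region:
#' the gene of interest plus the flanking megabase of highly heterozygous SNPs
#' used for haplotype phasing and relative haplotype dosage.
#'
#' @param chrom Chromosome name (recycled).
#' @param pos 1-based base-pair positions, strictly increasing.
#' @param ref_allele,alt_allele Single-character allele codes; must differ per site.
#' @param is_pathogenic Logical flag marking the disease-variant site(s); by
#'   convention the pathogenic allele is the ALT allele at a flagged site.
#' @return A `data.frame` of class `snp_panel` with columns
#'   `chrom, pos, ref, alt, is_pathogenic`.
#' @export
snp_panel <- function(chrom, pos, ref_allele, alt_allele, is_pathogenic = FALSE) {
  pos <- as.integer(pos)
  n <- length(pos)
  if (n < 1L) stop("a panel needs at least one SNP")
  if (n > 1L && any(diff(pos) <= 0L)) stop("SNP positions must be strictly increasing")
  chrom <- rep_len(as.character(chrom), n)
  ref_allele <- rep_len(as.character(ref_allele), n)
  alt_allele <- rep_len(as.character(alt_allele), n)
  is_pathogenic <- rep_len(as.logical(is_pathogenic), n)
  if (any(ref_allele == alt_allele)) stop("ref and alt alleles must differ at every site")
  structure(
    data.frame(chrom = chrom, pos = pos, ref = ref_allele, alt = alt_allele,
               is_pathogenic = is_pathogenic, stringsAsFactors = FALSE),
    class = c("snp_panel", "data.frame")
  )
}

#' Construct a parental diplotype
#'
#' An ordered pair of haplotypes over a [snp_panel()]. When `phased` is TRUE the
#' hap1/hap2 labels are consistent across all sites, i.e. `hap1` is one physical
#' chromosome. `pathogenic_hap` records which haplotype carries the pathogenic
#' allele for carrier parents.
#'
#' @param sample_id Sample identifier, e.g. `"mother"`.
#' @param panel A [snp_panel()].
#' @param hap1,hap2 Character vectors of alleles, one per panel SNP; each must
#'   equal the site's ref or alt allele.
#' @param phased Logical; whether hap labels are chromosome-consistent.
#' @param pathogenic_hap 1, 2 or NA: index of the haplotype carrying the variant.
#' @return An object of class `diplotype`.
#' @export
diplotype <- function(sample_id, panel, hap1, hap2, phased = TRUE,
                      pathogenic_hap = NA_integer_) {
  if (nrow(panel) != length(hap1) || length(hap1) != length(hap2))
    stop("hap1/hap2 must have one allele per panel SNP")
  ok <- (hap1 == panel$ref | hap1 == panel$alt) &
        (hap2 == panel$ref | hap2 == panel$alt)
  if (!all(ok)) stop("haplotype alleles must match the panel ref/alt alleles")
  structure(list(sample_id = sample_id, panel = panel,
                 hap1 = as.character(hap1), hap2 = as.character(hap2),
                 phased = isTRUE(phased),
                 pathogenic_hap = as.integer(pathogenic_hap)),
            class = "diplotype")
}

#' @export
print.diplotype <- function(x, ...) {
  g <- genotype_codes(x)
  cat(sprintf("<diplotype> %s: %d SNPs (%d het), %s, pathogenic hap: %s\n",
              x$sample_id, length(x$hap1), sum(g == 1L),
              if (x$phased) "phased" else "unphased",
              ifelse(is.na(x$pathogenic_hap), "none", x$pathogenic_hap)))
  invisible(x)
}

#' Genotype dosage codes of a diplotype
#'
#' @param dip A [diplotype()].
#' @return Integer vector: number of ALT alleles per site (0, 1 or 2).
#' @export
genotype_codes <- function(dip) {
  as.integer(dip$hap1 == dip$panel$alt) + as.integer(dip$hap2 == dip$panel$alt)
}

# allele of haplotype `hap_index[i]` at SNP i (vectorized)
hap_alleles <- function(dip, hap_index) {
  ifelse(hap_index == 1L, dip$hap1, dip$hap2)
}

#' Derive the P/N haplotype pair directly from a phased diplotype
#'
#' The phased-VCF bypass: when a parent's haplotypes are already phased across
#' the whole panel (e.g. read from a phased VCF with a known pathogenic phase),
#' the pathogenic-linked (P) and normal (N) haplotypes are obtained by labeling
#' rather than barcode-graph assembly.
#'
#' @param dip A phased [diplotype()] with `pathogenic_hap` set.
#' @return A `haplotype_pair` covering every panel SNP.
#' @export
hap_pair_from_diplotype <- function(dip) {
  if (!dip$phased) stop("diplotype must be phased")
  if (is.na(dip$pathogenic_hap)) stop("pathogenic_hap must be set to label P and N")
  # a panel may flag both parents' variant sites; the carrier must be het at
  # its own (at least one flagged site)
  path_site <- which(dip$panel$is_pathogenic)
  if (length(path_site) >= 1L && !any(genotype_codes(dip)[path_site] == 1L))
    stop("carrier parent must be heterozygous at its pathogenic site")
  P <- if (dip$pathogenic_hap == 1L) dip$hap1 else dip$hap2
  N <- if (dip$pathogenic_hap == 1L) dip$hap2 else dip$hap1
  structure(list(parent_id = dip$sample_id, covered = TRUE,
                 snp_index = seq_len(nrow(dip$panel)),
                 P_alleles = P, N_alleles = N,
                 chrom = dip$panel$chrom[1L],
                 start = min(dip$panel$pos), end = max(dip$panel$pos)),
            class = "haplotype_pair")
}
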