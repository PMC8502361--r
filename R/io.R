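#' Write a phased diplotype as VCF 4.2
#'
#' Emits one sample with phased GT (`|` separator, `/` if unphased) and a PS
#' phase-set tag. Pathogenic sites are marked with a `PATHOGENIC` INFO flag so
#' round-tripping preserves the panel annotation.
#'
#' @param dip A [diplotype()].
#' @param path Output file path.
#' @param phase_set Integer phase-set id(s); defaults to the first SNP position.
#' @param pathogenic_pos Positions to flag `PATHOGENIC`. A shared panel may
#'   flag both parents' variant sites; a single-sample VCF should flag only
#'   this sample's own (default: flagged sites where the sample is
#'   heterozygous).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(dip, path, phase_set = NULL,
                             pathogenic_pos = NULL) {
  p <- dip$panel
  n <- nrow(p)
  if (is.null(phase_set)) phase_set <- rep(p$pos[1L], n)
  phase_set <- rep_len(as.integer(phase_set), n)
  sep <- if (dip$phased) "|" else "/"
  g1 <- as.integer(dip$hap1 == p$alt)
  g2 <- as.integer(dip$hap2 == p$alt)
  if (is.null(pathogenic_pos))
    pathogenic_pos <- p$pos[p$is_pathogenic & genotype_codes(dip) == 1L]
  info <- ifelse(p$pos %in% pathogenic_pos, "PATHOGENIC", ".")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=haplonipt",
    "##INFO=<ID=PATHOGENIC,Number=0,Type=Flag,Description=\"Pathogenic variant site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    sprintf("##contig=<ID=%s>", unique(p$chrom)),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", dip$sample_id)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:PS\t%d%s%d:%d",
                  p$chrom, p$pos, p$ref, p$alt, info, g1, sep, g2, phase_set)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a (phased) single-sample VCF into a diplotype
#'
#' @param path VCF file path (plain text).
#' @param pathogenic_hap Optional haplotype index carrying the pathogenic allele;
#'   if omitted it is derived from sites flagged `PATHOGENIC` in INFO (the
#'   haplotype carrying the ALT allele there).
#' @return A [diplotype()] whose panel marks `PATHOGENIC`-flagged sites.
#' @export
read_phased_vcf <- function(path, pathogenic_hap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (ncol(gt) != 1L) stop("expected a single-sample VCF")
  sample_id <- colnames(gt)[1L]
  gt <- gt[, 1L]
  phased <- all(grepl("|", gt, fixed = TRUE))
  parts <- strsplit(gt, "[|/]")
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  if (anyNA(a1) || anyNA(a2)) stop("missing genotypes in VCF")
  info <- if ("INFO" %in% colnames(fix)) fix[, "INFO"] else rep(".", nrow(fix))
  panel <- snp_panel(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"],
                     is_pathogenic = grepl("PATHOGENIC", info))
  hap1 <- ifelse(a1 == "1", panel$alt, panel$ref)
  hap2 <- ifelse(a2 == "1", panel$alt, panel$ref)
  if (is.null(pathogenic_hap)) {
    ps <- which(panel$is_pathogenic)
    pathogenic_hap <- if (length(ps) >= 1L && phased) {
      i <- ps[1L]
      if (hap1[i] == panel$alt[i]) 1L else if (hap2[i] == panel$alt[i]) 2L else NA_integer_
    } else NA_integer_
  }
  diplotype(sample_id, panel, hap1, hap2, phased = phased,
            pathogenic_hap = pathogenic_hap)
}

#' Write / read the barcode observation table
#'
#' TSV dialect with columns `barcode, chrom, pos, allele` (truth columns
#' `molecule_id` and `hap`, when present, are preserved for testing).
#'
#' @param obs Barcode observation `data.frame` from [simulate_linked_reads()].
#' @param path File path.
#' @return `path` (write) or the observation `data.frame` (read).
#' @export
write_barcode_tsv <- function(obs, path) {
  cols <- intersect(c("barcode", "chrom", "pos", "allele", "molecule_id", "hap"),
                    names(obs))
  utils::write.table(obs[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_tsv
#' @param panel The [snp_panel()] the observations refer to; positions are
#'   matched back to panel indices.
#' @export
read_barcode_tsv <- function(path, panel) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  obs$snp_index <- match(obs$pos, panel$pos)
  if (anyNA(obs$snp_index)) stop("barcode table contains positions absent from the panel")
  obs
}

#' Write / read maternal plasma allele counts
#'
#' TSV dialect with columns `chrom, pos, ref_count, alt_count`.
#'
#' @param counts Plasma counts `data.frame`.
#' @param path File path.
#' @return `path` (write) or the counts `data.frame` (read).
#' @export
write_plasma_tsv <- function(counts, path) {
  utils::write.table(counts[, c("chrom", "pos", "ref_count", "alt_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plasma_tsv
#' @export
read_plasma_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a genetic map as TSV (`chrom, pos, cM`)
#'
#' @param map A [genetic_map()].
#' @param path File path.
#' @return `path` (write) or a [genetic_map()] (read).
#' @export
write_genetic_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("chrom", "pos", "cM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map_tsv
#' @export
read_genetic_map_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  genetic_map(pos = d$pos, cM = d$cM, chrom = d$chrom[1L])
}
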