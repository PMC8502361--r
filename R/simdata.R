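#' Simulate phased parental diplotypes over a target region
#'
#' Generates a SNP panel emulating a capture design — the disease gene plus
#' highly heterozygous SNPs across the flanking megabases — and phased mother
#' and father diplotypes. Each parent is an obligate heterozygous carrier at its
#' own pathogenic site (the pathogenic allele is the ALT allele there); its
#' genotype at the other parent's variant site follows `het_rate` like any
#' background site.
#'
#' @param n_snps Total number of panel SNPs (including the pathogenic sites).
#' @param region_length Region length in bp.
#' @param het_rate Per-site probability that a parent is heterozygous
#'   (non-carrier genotypes at a variant site follow the same rate).
#' @param pathogenic_spec List with elements `mother` and `father`, each a list
#'   `list(pos =, hap =)` giving the variant position (inside the region) and
#'   which haplotype (1 or 2) carries it.
#' @param chrom Chromosome name.
#' @param region_start First bp of the region.
#' @param seed Optional integer seed.
#' @return `list(panel, mother, father)`.
#' @export
simulate_parental_diplotypes <- function(n_snps, region_length = 2e6,
                                         het_rate = 0.6,
                                         pathogenic_spec = list(
                                           mother = list(pos = NULL, hap = 1L),
                                           father = list(pos = NULL, hap = 1L)),
                                         chrom = "chr1", region_start = 1e6,
                                         seed = NULL) {
  if (n_snps < 2L) stop("n_snps must be at least 2")
  if (het_rate <= 0 || het_rate > 1) stop("het_rate must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  region_start <- as.integer(region_start)
  region_end <- region_start + as.integer(region_length) - 1L
  centre <- region_start + as.integer(region_length %/% 2)
  if (is.null(pathogenic_spec$mother$pos)) pathogenic_spec$mother$pos <- centre - 10000L
  if (is.null(pathogenic_spec$father$pos)) pathogenic_spec$father$pos <- centre + 10000L
  ppos <- c(mother = as.integer(pathogenic_spec$mother$pos),
            father = as.integer(pathogenic_spec$father$pos))
  if (any(ppos < region_start | ppos > region_end))
    stop("pathogenic position outside the simulated region")

  n_bg <- n_snps - length(unique(ppos))
  cand <- setdiff(seq.int(region_start, region_end), unique(ppos))
  pos <- sort(c(sample(cand, n_bg), unique(ppos)))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  panel <- snp_panel(chrom, pos, ref, alt, is_pathogenic = pos %in% ppos)

  draw_parent <- function(id, own_pos, own_hap) {
    het <- stats::runif(n_snps) < het_rate
    hom_alt <- !het & stats::runif(n_snps) < 0.5
    alt_on_hap1 <- stats::runif(n_snps) < 0.5
    hap1 <- ifelse(het, ifelse(alt_on_hap1, panel$alt, panel$ref),
                   ifelse(hom_alt, panel$alt, panel$ref))
    hap2 <- ifelse(het, ifelse(alt_on_hap1, panel$ref, panel$alt),
                   ifelse(hom_alt, panel$alt, panel$ref))
    i <- match(own_pos, panel$pos)
    if (own_hap == 1L) { hap1[i] <- panel$alt[i]; hap2[i] <- panel$ref[i] }
    else               { hap1[i] <- panel$ref[i]; hap2[i] <- panel$alt[i] }
    diplotype(id, panel, hap1, hap2, phased = TRUE,
              pathogenic_hap = as.integer(own_hap))
  }
  mother <- draw_parent("mother", ppos["mother"], pathogenic_spec$mother$hap)
  father <- draw_parent("father", ppos["father"], pathogenic_spec$father$hap)
  list(panel = panel, mother = mother, father = father)
}

#' Simulate barcoded linked-read allele observations
#'
#' Emulates linked-read library preparation: high-molecular-weight molecules are
#' drawn from the two parental haplotypes with truncated-exponential lengths
#' (an exponential of mean `molecule_len_mean` conditioned on exceeding
#' `min_molecule_len`, realized as floor + exponential by memorylessness),
#' partitioned into barcodes holding `molecules_per_partition` molecules each,
#' and sheared into allele-level observations: each SNP a molecule covers is
#' observed independently with probability `obs_prob`, and the observed allele
#' is flipped to the other allele of the site with probability `error_rate`.
#' The molecule count is chosen so the mean number of observations per SNP is
#' approximately `target_depth`. Truth columns `molecule_id` and `hap` are
#' retained for testing only.
#'
#' @param dip A [diplotype()].
#' @param molecule_len_mean Mean of the exponential length component (bp).
#' @param min_molecule_len Lower truncation of molecule length (bp); default
#'   50 kb, the usual HMW size floor.
#' @param molecules_per_partition Molecules sharing one barcode.
#' @param target_depth Desired mean observations per SNP.
#' @param error_rate Per-observation allele error probability, in [0, 0.5).
#' @param obs_prob Per-SNP observation probability within a covering molecule.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns
#'   `barcode, snp_index, chrom, pos, allele, molecule_id, hap`.
#' @export
simulate_linked_reads <- function(dip, molecule_len_mean = 5e4,
                                  min_molecule_len = 5e4,
                                  molecules_per_partition = 10L,
                                  target_depth = 100, error_rate = 0.001,
                                  obs_prob = 0.2, seed = NULL) {
  if (molecule_len_mean <= 0) stop("molecule_len_mean must be positive")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  p <- dip$panel
  span <- max(p$pos) - min(p$pos) + 1
  mean_len <- min_molecule_len + molecule_len_mean
  n_mol <- ceiling(target_depth * (span + mean_len) / (obs_prob * mean_len))
  len <- min_molecule_len + stats::rexp(n_mol, rate = 1 / molecule_len_mean)
  start <- stats::runif(n_mol, min = min(p$pos) - len, max = max(p$pos))
  hap <- sample(1:2, n_mol, replace = TRUE)
  perm <- sample.int(n_mol)
  bc <- integer(n_mol)
  bc[perm] <- ceiling(seq_len(n_mol) / molecules_per_partition)

  # SNP indices covered per molecule, via interval lookup on the sorted panel
  lo <- findInterval(start, p$pos) + 1L
  hi <- findInterval(start + len - 1, p$pos)
  keep <- hi >= lo
  if (!any(keep)) {
    warning("no molecule covers any SNP; returning an empty observation table")
    return(data.frame(barcode = character(0), snp_index = integer(0),
                      chrom = character(0), pos = integer(0),
                      allele = character(0), molecule_id = integer(0),
                      hap = integer(0), stringsAsFactors = FALSE))
  }
  idx <- which(keep)
  n_cov <- hi[idx] - lo[idx] + 1L
  mol <- rep(idx, n_cov)
  snp <- sequence(n_cov, from = lo[idx])
  obs_keep <- stats::runif(length(snp)) < obs_prob
  mol <- mol[obs_keep]; snp <- snp[obs_keep]
  if (length(snp) == 0L) {
    warning("no SNP observations generated; returning an empty observation table")
    return(data.frame(barcode = character(0), snp_index = integer(0),
                      chrom = character(0), pos = integer(0),
                      allele = character(0), molecule_id = integer(0),
                      hap = integer(0), stringsAsFactors = FALSE))
  }
  src <- ifelse(hap[mol] == 1L, dip$hap1[snp], dip$hap2[snp])
  flip <- stats::runif(length(snp)) < error_rate
  other <- ifelse(src == p$alt[snp], p$ref[snp], p$alt[snp])
  allele <- ifelse(flip, other, src)
  data.frame(barcode = sprintf("BX%06d", bc[mol]), snp_index = snp,
             chrom = p$chrom[snp], pos = p$pos[snp], allele = allele,
             molecule_id = mol, hap = hap[mol], stringsAsFactors = FALSE)
}

#' Simulate the fetal genome by recombination-aware parental transmission
#'
#' For each parent the transmitted haplotype starts from a uniformly chosen
#' chromosome and switches between adjacent SNPs with probability equal to the
#' Haldane recombination fraction of the genetic-map distance.
#'
#' @param mother,father Phased [diplotype()]s over the same panel.
#' @param map A [genetic_map()] covering the region.
#' @param recombination Logical; FALSE forces zero crossovers.
#' @param ff True fetal fraction in (0, 1), carried as ground truth (default
#'   0.132, a typical early-second-trimester value).
#' @param seed Optional integer seed.
#' @return `list(fetal_mat_hap, fetal_pat_hap, crossovers, true_ff, seed)`;
#'   `crossovers` is a `data.frame(parent, interval, pos_left, pos_right)`.
#' @export
simulate_fetal_genome <- function(mother, father, map, recombination = TRUE,
                                  ff = 0.132, seed = NULL) {
  if (!mother$phased || !father$phased) stop("parental diplotypes must be phased")
  if (ff <= 0 || ff >= 1) stop("ff must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  pos <- mother$panel$pos
  k <- length(pos)
  cm <- interpolate_cM(map, pos)
  d <- pmax(diff(cm), 0)
  r <- if (recombination) haldane_r(d) else rep(0, max(k - 1L, 0L))
  transmit <- function(parent_label) {
    h0 <- sample(1:2, 1L)
    sw <- if (k > 1L) stats::rbinom(k - 1L, 1L, r) else integer(0)
    hap <- ((h0 - 1L + cumsum(c(0L, sw))) %% 2L) + 1L
    xo <- which(sw == 1L)
    list(hap = hap,
         crossovers = data.frame(parent = rep(parent_label, length(xo)),
                                 interval = xo, pos_left = pos[xo],
                                 pos_right = pos[xo + 1L],
                                 stringsAsFactors = FALSE))
  }
  tm <- transmit("mat"); tp <- transmit("pat")
  structure(list(fetal_mat_hap = tm$hap, fetal_pat_hap = tp$hap,
                 crossovers = rbind(tm$crossovers, tp$crossovers),
                 true_ff = ff, seed = seed),
            class = "sim_truth")
}

#' Simulate maternal plasma allele counts
#'
#' Per SNP the sequencing depth is Poisson around `depth_mean`; each read
#' derives from the maternal genome with probability 1 - f (its two alleles
#' equally likely) or from the fetal genome with probability f, and the read's
#' allele is flipped with probability `error_rate`. Counts are drawn from the
#' exact closed-form per-read mixture probability, so allele counts always sum
#' to the drawn depth.
#'
#' @param mother,father Phased [diplotype()]s.
#' @param sim_truth A [simulate_fetal_genome()] result (supplies the inherited
#'   haplotypes and the true fetal fraction).
#' @param depth_mean Mean plasma depth per SNP.
#' @param error_rate Per-read allele error probability.
#' @param seed Optional integer seed.
#' @return `data.frame(chrom, pos, ref_count, alt_count)`.
#' @export
simulate_plasma_counts <- function(mother, father, sim_truth, depth_mean = 200,
                                   error_rate = 0.001, seed = NULL) {
  f <- sim_truth$true_ff
  if (f <= 0 || f >= 1) stop("true_ff must be in (0, 1)")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- mother$panel
  k <- nrow(p)
  mat_allele <- hap_alleles(mother, sim_truth$fetal_mat_hap)
  pat_allele <- hap_alleles(father, sim_truth$fetal_pat_hap)
  mother_alt <- genotype_codes(mother) / 2
  fetal_alt <- (as.integer(mat_allele == p$alt) + as.integer(pat_allele == p$alt)) / 2
  p_alt <- (1 - f) * mother_alt + f * fetal_alt
  p_obs <- p_alt * (1 - error_rate) + (1 - p_alt) * error_rate
  depth <- stats::rpois(k, depth_mean)
  alt <- stats::rbinom(k, depth, p_obs)
  data.frame(chrom = p$chrom, pos = p$pos, ref_count = depth - alt,
             alt_count = alt, stringsAsFactors = FALSE)
}

#' True transmitted parental alleles at the pathogenic sites
#'
#' @param sim A [simulate_family()] result.
#' @return `list(mat =, pat =)` with values `"P"` or `"N"`: whether the fetus
#'   inherited each parent's pathogenic-linked haplotype.
#' @export
true_inherited_alleles <- function(sim) {
  i_m <- match(sim$pathogenic$mother$pos, sim$panel$pos)
  i_p <- match(sim$pathogenic$father$pos, sim$panel$pos)
  list(
    mat = if (sim$truth$fetal_mat_hap[i_m] == sim$mother$pathogenic_hap) "P" else "N",
    pat = if (sim$truth$fetal_pat_hap[i_p] == sim$father$pathogenic_hap) "P" else "N"
  )
}

#' Simulate a complete family: panel, parents, fetus, plasma, optional barcodes
#'
#' Convenience wrapper wiring the four generators into the study design the
#' downstream pipeline expects: a ~2 Mb panel centred on a 50 kb gene interval
#' containing both parental pathogenic sites, a uniform 1 cM/Mb genetic map,
#' a recombined fetal genome and plasma counts at the given fetal fraction.
#'
#' @param n_snps,region_length,het_rate,chrom,region_start Passed to
#'   [simulate_parental_diplotypes()].
#' @param ff True fetal fraction.
#' @param depth_mean,plasma_error Passed to [simulate_plasma_counts()].
#' @param recombination Passed to [simulate_fetal_genome()].
#' @param cM_per_Mb Uniform map rate.
#' @param gene_halfwidth Half-width of the gene interval around the region
#'   centre (bp).
#' @param linked_reads If TRUE also simulate barcode observation tables for
#'   both parents (slower).
#' @param lr_args List of overrides for [simulate_linked_reads()].
#' @param pathogenic_hap_mother,pathogenic_hap_father Haplotype carrying each
#'   parent's variant.
#' @param seed Optional integer seed governing every stage.
#' @return A list with elements `panel, mother, father, truth, plasma, map,
#'   gene_interval, pathogenic, barcode_obs` (the last NULL unless
#'   `linked_reads`).
#' @export
simulate_family <- function(n_snps = 300L, region_length = 2e6, het_rate = 0.6,
                            ff = 0.132, depth_mean = 200, plasma_error = 0.001,
                            recombination = TRUE, cM_per_Mb = 1,
                            gene_halfwidth = 25000L, chrom = "chr1",
                            region_start = 1e6, linked_reads = FALSE,
                            lr_args = list(), pathogenic_hap_mother = 1L,
                            pathogenic_hap_father = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centre <- as.integer(region_start + region_length %/% 2)
  pathogenic <- list(mother = list(pos = centre - 10000L,
                                   hap = pathogenic_hap_mother),
                     father = list(pos = centre + 10000L,
                                   hap = pathogenic_hap_father))
  par <- simulate_parental_diplotypes(n_snps, region_length, het_rate,
                                      pathogenic, chrom, region_start)
  map <- uniform_genetic_map(chrom, region_start,
                             region_start + region_length - 1, cM_per_Mb)
  truth <- simulate_fetal_genome(par$mother, par$father, map,
                                 recombination = recombination, ff = ff)
  plasma <- simulate_plasma_counts(par$mother, par$father, truth,
                                   depth_mean = depth_mean,
                                   error_rate = plasma_error)
  barcode_obs <- NULL
  if (linked_reads) {
    barcode_obs <- list(
      mat = do.call(simulate_linked_reads, c(list(dip = par$mother), lr_args)),
      pat = do.call(simulate_linked_reads, c(list(dip = par$father), lr_args)))
  }
  list(panel = par$panel, mother = par$mother, father = par$father,
       truth = truth, plasma = plasma, map = map,
       gene_interval = c(centre - gene_halfwidth, centre + gene_halfwidth),
       pathogenic = pathogenic, barcode_obs = barcode_obs)
}
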