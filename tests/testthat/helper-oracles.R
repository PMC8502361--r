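# Independent oracles, deliberately naive: plain loops and exhaustive
# enumeration, sharing no code with the implementation paths they check.

# maximum path log-probability of the 2-state chain by enumerating all 2^k paths
brute_force_path_loglik <- function(leP, leN, r) {
  k <- length(leP)
  best <- -Inf
  for (m in 0:(2^k - 1)) {
    s <- as.integer(intToBits(m))[seq_len(k)]  # 1 = state P
    ll <- log(0.5) + sum(ifelse(s == 1L, leP, leN))
    if (k > 1L) ll <- ll + sum(ifelse(diff(s) != 0L, log(r), log(1 - r)))
    if (ll > best) best <- ll
  }
  best
}

# per-barcode recount of pairwise cis/trans evidence
recount_evidence <- function(obs, het_index, panel) {
  obs <- obs[obs$snp_index %in% het_index, , drop = FALSE]
  out <- list()
  for (bc in unique(obs$barcode)) {
    o <- obs[obs$barcode == bc, , drop = FALSE]
    snps <- sort(unique(o$snp_index))
    codes <- sapply(snps, function(s) {
      a <- o$allele[o$snp_index == s]
      n_alt <- sum(a == panel$alt[s])
      if (2 * n_alt == length(a)) return(NA)   # tie
      2 * n_alt > length(a)
    })
    keep <- !is.na(codes)
    snps <- snps[keep]; codes <- codes[keep]
    if (length(snps) < 2) next
    for (x in seq_len(length(snps) - 1)) {
      for (y in seq(x + 1, length(snps))) {
        key <- paste(snps[x], snps[y])
        e <- out[[key]]
        if (is.null(e)) e <- c(i = snps[x], j = snps[y], cis = 0, trans = 0)
        if (codes[x] == codes[y]) e["cis"] <- e["cis"] + 1
        else e["trans"] <- e["trans"] + 1
        out[[key]] <- e
      }
    }
  }
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# total evidence satisfied by a phase assignment phi over a pair-evidence table
evidence_score <- function(phi, evidence, members) {
  s <- 0
  for (r in seq_len(nrow(evidence))) {
    i <- match(evidence$i[r], members); j <- match(evidence$j[r], members)
    if (is.na(i) || is.na(j)) next
    s <- s + if (phi[i] == phi[j]) evidence$cis[r] else evidence$trans[r]
  }
  s
}

# best achievable satisfied-evidence score over all 2^k phasings
exhaustive_best_score <- function(evidence, members) {
  k <- length(members)
  best <- -Inf
  for (m in 0:(2^k - 1)) {
    phi <- as.integer(intToBits(m))[seq_len(k)]
    best <- max(best, evidence_score(phi, evidence, members))
  }
  best
}

# a small panel with evenly spaced SNPs, A->G at every site
toy_panel <- function(n, start = 1e6, step = 1e4, pathogenic = integer(0)) {
  pos <- start + step * (seq_len(n) - 1)
  snp_panel("chr1", pos, "A", "G", is_pathogenic = seq_len(n) %in% pathogenic)
}

# diplotype from 0/1 codes per haplotype (1 = ALT)
toy_diplotype <- function(id, panel, h1, h2, pathogenic_hap = NA_integer_) {
  diplotype(id, panel,
            ifelse(h1 == 1, panel$alt, panel$ref),
            ifelse(h2 == 1, panel$alt, panel$ref),
            phased = TRUE, pathogenic_hap = pathogenic_hap)
}

# an informative-SNP design table for HMM-level tests
toy_design <- function(n, depth, category = "MAT_INFORMATIVE",
                       subtype = "father_hom_P", start = 1e6, step = 1e4) {
  data.frame(pos = start + step * (seq_len(n) - 1),
             category = rep_len(category, n), subtype = rep_len(subtype, n),
             depth = rep_len(depth, n), stringsAsFactors = FALSE)
}

# counts object from a design + a state vector, drawn at the model's dosage
draw_counts <- function(design, states, ff, eps = 0.005) {
  frac <- expected_allele_fraction(states, design$category, design$subtype,
                                   ff, eps)
  p <- rbinom(nrow(design), design$depth, frac)
  data.frame(snp_index = seq_len(nrow(design)), chrom = "chr1",
             pos = design$pos, parent = "mat", category = design$category,
             subtype = design$subtype, p_count = p,
             n_count = design$depth - p, depth = design$depth,
             stringsAsFactors = FALSE)
}
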