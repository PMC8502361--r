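#' Pairwise allele co-occurrence evidence from barcodes
#'
#' Barcodes tie short-fragment observations back to their long source molecule,
#' so two heterozygous SNPs observed under one barcode carry phase evidence.
#' For every SNP pair sharing at least one barcode, `cis` counts barcodes whose
#' majority alleles at the two sites have the same ref/alt polarity and `trans`
#' the opposite. Per-barcode majority voting absorbs partition collisions
#' (two molecules of opposite haplotype in one gel bead); exact ties at a site
#' are dropped for that barcode.
#'
#' @param obs Barcode observation table ([simulate_linked_reads()] dialect):
#'   columns `barcode, snp_index, allele`.
#' @param het_index Indices of heterozygous panel sites to phase.
#' @param panel The [snp_panel()].
#' @return `data.frame(i, j, cis, trans)` with `i < j` (panel indices); pairs
#'   with no shared barcode are absent.
#' @export
build_allele_barcode_graph <- function(obs, het_index, panel) {
  if (nrow(obs) == 0L) stop("observation table is empty")
  keep <- obs$snp_index %in% het_index
  empty <- data.frame(i = integer(0), j = integer(0),
                      cis = integer(0), trans = integer(0))
  if (!any(keep)) return(empty)
  DT <- data.table::data.table(barcode = obs$barcode[keep],
                               snp_index = obs$snp_index[keep],
                               code = obs$allele[keep] ==
                                 panel$alt[obs$snp_index[keep]])
  agg <- DT[, list(n_alt = sum(code), n = .N), by = c("barcode", "snp_index")]
  agg <- agg[agg$n_alt * 2L != agg$n, ]          # drop per-barcode ties
  agg$code <- agg$n_alt * 2L > agg$n
  agg <- agg[, c("barcode", "snp_index", "code")]
  pr <- merge(agg, agg, by = "barcode", allow.cartesian = TRUE,
              suffixes = c(".x", ".y"))
  pr <- pr[pr$snp_index.x < pr$snp_index.y, ]
  if (nrow(pr) == 0L) return(empty)
  ev <- pr[, list(cis = sum(code.x == code.y), trans = sum(code.x != code.y)),
           by = c("snp_index.x", "snp_index.y")]
  out <- data.frame(i = ev$snp_index.x, j = ev$snp_index.y,
                    cis = as.integer(ev$cis), trans = as.integer(ev$trans))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Assemble phase blocks by greedy 2-coloring of the evidence graph
#'
#' Heterozygous sites are visited left to right. A site joins the current block
#' when its net evidence against already-phased members is decisive: total
#' shared-barcode support at least `min_support` and orientation margin
#' `|cis-like - trans-like|` at least `min_margin`; otherwise a new block
#' starts. Within a block the orientation maximizing agreement is taken; an
#' exact orientation tie (possible only when `min_margin = 0`) is resolved
#' toward consistency with the nearest upstream member.
#'
#' @param evidence Output of [build_allele_barcode_graph()].
#' @param het_index Heterozygous site indices (any order).
#' @param panel The [snp_panel()].
#' @param min_support Minimum total evidence to join a block.
#' @param min_margin Minimum orientation margin to join a block.
#' @param max_pair_gap Evidence from SNP pairs farther apart than this (bp) is
#'   ignored: barcodes hold several molecules, so distant pairs share barcodes
#'   mostly through different molecules, contributing symmetric cis/trans
#'   noise. Default 200 kb, on the scale of the longest HMW molecules.
#' @return List of `phase_block` objects: `block_id, chrom, start, end,
#'   snp_index, phase, hap1, hap2, n_snps, support`. `phase[i] = 0` puts the
#'   ALT allele of member i on hap1. Isolated sites become singleton blocks;
#'   block intervals are disjoint by construction.
#' @export
assemble_phase_blocks <- function(evidence, het_index, panel,
                                  min_support = 2L, min_margin = 2L,
                                  max_pair_gap = 2e5) {
  if (min_support < 1L) stop("min_support must be at least 1")
  if (nrow(evidence) > 0L) {
    gap <- abs(panel$pos[evidence$j] - panel$pos[evidence$i])
    evidence <- evidence[gap <= max_pair_gap, , drop = FALSE]
  }
  ord <- het_index[order(panel$pos[het_index])]
  adj <- vector("list", nrow(panel))
  if (nrow(evidence) > 0L) {
    for (r in seq_len(nrow(evidence))) {
      i <- evidence$i[r]; j <- evidence$j[r]
      e <- c(evidence$cis[r], evidence$trans[r])
      adj[[i]] <- rbind(adj[[i]], c(j, e))
      adj[[j]] <- rbind(adj[[j]], c(i, e))
    }
  }
  blocks <- list()
  members <- integer(0); phase <- integer(0); support <- integer(0)
  flush <- function() {
    if (length(members) == 0L) return()
    b <- list(block_id = length(blocks) + 1L,
              chrom = panel$chrom[members[1L]],
              start = min(panel$pos[members]), end = max(panel$pos[members]),
              snp_index = members, phase = phase,
              hap1 = ifelse(phase == 0L, panel$alt[members], panel$ref[members]),
              hap2 = ifelse(phase == 0L, panel$ref[members], panel$alt[members]),
              n_snps = length(members), support = support)
    blocks[[length(blocks) + 1L]] <<- structure(b, class = "phase_block")
  }
  for (s in ord) {
    if (length(members) == 0L) {
      members <- s; phase <- 0L; support <- 0L
      next
    }
    nb <- adj[[s]]
    w0 <- 0; w1 <- 0
    if (!is.null(nb)) {
      hit <- match(nb[, 1L], members)
      use <- which(!is.na(hit))
      for (u in use) {
        ph <- phase[hit[u]]
        cis <- nb[u, 2L]; trans <- nb[u, 3L]
        if (ph == 0L) { w0 <- w0 + cis; w1 <- w1 + trans }
        else          { w0 <- w0 + trans; w1 <- w1 + cis }
      }
    }
    total <- w0 + w1; margin <- abs(w0 - w1)
    if (total >= min_support && margin >= min_margin) {
      if (w0 != w1) {
        ph_new <- if (w0 > w1) 0L else 1L
      } else {
        # orientation tie: follow the nearest upstream member's pair evidence
        hit <- match(nb[, 1L], members)
        use <- which(!is.na(hit))
        near <- use[which.max(panel$pos[nb[use, 1L]])]
        ph_m <- phase[hit[near]]
        ph_new <- if (nb[near, 2L] >= nb[near, 3L]) ph_m else 1L - ph_m
      }
      members <- c(members, s); phase <- c(phase, ph_new)
      support <- c(support, as.integer(total))
    } else {
      flush()
      members <- s; phase <- 0L; support <- 0L
    }
  }
  flush()
  blocks
}

#' @export
print.phase_block <- function(x, ...) {
  cat(sprintf("<phase_block %d> %s:%d-%d, %d SNPs\n",
              x$block_id, x$chrom, x$start, x$end, x$n_snps))
  invisible(x)
}

#' Link phase blocks through overlapping SNPs
#'
#' Blocks from two assemblies over the same panel are merged when they share at
#' least `min_shared` phased heterozygous SNPs and the shared sites vote a
#' consistent relative orientation (majority); a 50:50 orientation vote leaves
#' the blocks unmerged with a warning. Merging repeats to a fixed point so
#' chains of overlaps collapse.
#'
#' @param blocks_a,blocks_b Lists of `phase_block`s over one panel.
#' @param panel The [snp_panel()] (used to rebuild hap alleles after merging).
#' @param min_shared Minimum overlapping phased SNPs to merge (default 2).
#' @return A list of `phase_block`s, renumbered, sorted by start position.
#' @export
merge_blocks_by_overlap <- function(blocks_a, blocks_b, panel, min_shared = 2L) {
  pool <- c(blocks_a, blocks_b)
  if (length(pool) <= 1L) return(renumber_blocks(pool, panel))
  alive <- rep(TRUE, length(pool))
  repeat {
    merged_any <- FALSE
    for (a in seq_along(pool)) {
      if (!alive[a]) next
      for (b in seq_along(pool)) {
        if (b <= a || !alive[b]) next
        A <- pool[[a]]; B <- pool[[b]]
        shared <- intersect(A$snp_index, B$snp_index)
        if (length(shared) < min_shared) next
        pa <- A$phase[match(shared, A$snp_index)]
        pb <- B$phase[match(shared, B$snp_index)]
        same <- sum(pa == pb); diff <- length(shared) - same
        if (same == diff) {
          warning(sprintf("blocks %d/%d share %d SNPs with a 50:50 orientation vote; not merged",
                          A$block_id, B$block_id, length(shared)))
          next
        }
        flip <- diff > same
        new_idx <- setdiff(B$snp_index, shared)
        add_phase <- B$phase[match(new_idx, B$snp_index)]
        if (flip) add_phase <- 1L - add_phase
        add_sup <- B$support[match(new_idx, B$snp_index)]
        members <- c(A$snp_index, new_idx)
        o <- order(members)
        A$snp_index <- members[o]
        A$phase <- c(A$phase, add_phase)[o]
        A$support <- c(A$support, add_sup)[o]
        A$start <- min(A$start, B$start); A$end <- max(A$end, B$end)
        A$n_snps <- length(A$snp_index)
        pool[[a]] <- A
        alive[b] <- FALSE
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  renumber_blocks(pool[alive], panel)
}

# re-derive hap alleles from phase, renumber and sort blocks by start
renumber_blocks <- function(blocks, panel) {
  if (length(blocks) == 0L) return(blocks)
  blocks <- blocks[order(vapply(blocks, function(b) b$start, 0))]
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    b$block_id <- k
    b$hap1 <- ifelse(b$phase == 0L, panel$alt[b$snp_index], panel$ref[b$snp_index])
    b$hap2 <- ifelse(b$phase == 0L, panel$ref[b$snp_index], panel$alt[b$snp_index])
    blocks[[k]] <- b
  }
  blocks
}

#' Anchor the pathogenic variant to label P and N haplotypes
#'
#' Finds the phase block containing the variant site and labels the haplotype
#' carrying the variant allele as P (pathogenic-linked) and the other as N.
#' When no block covers the site, phasing has failed for this parent and
#' `covered = FALSE` is returned: downstream dosage analysis must be skipped.
#'
#' @param blocks List of `phase_block`s.
#' @param panel The [snp_panel()].
#' @param variant_index Panel index of the pathogenic site.
#' @param variant_allele The pathogenic allele (default: the site's ALT).
#' @param dip Optional [diplotype()] used to verify the carrier is heterozygous
#'   at the variant site.
#' @param parent_id Label stored on the result.
#' @return A `haplotype_pair`: `parent_id, covered, snp_index, P_alleles,
#'   N_alleles, chrom, start, end, block_id`.
#' @export
anchor_pathogenic_variant <- function(blocks, panel, variant_index,
                                      variant_allele = NULL, dip = NULL,
                                      parent_id = NA_character_) {
  if (variant_index < 1L || variant_index > nrow(panel))
    stop("variant site is not in the panel")
  if (is.null(variant_allele)) variant_allele <- panel$alt[variant_index]
  if (!variant_allele %in% c(panel$ref[variant_index], panel$alt[variant_index]))
    stop("variant allele does not match the panel alleles at the site")
  if (!is.null(dip) && genotype_codes(dip)[variant_index] != 1L)
    stop("variant site is homozygous in this parent; a carrier must be heterozygous")
  hit <- which(vapply(blocks, function(b) variant_index %in% b$snp_index, TRUE))
  if (length(hit) == 0L) {
    return(structure(list(parent_id = parent_id, covered = FALSE,
                          snp_index = integer(0), P_alleles = character(0),
                          N_alleles = character(0), chrom = panel$chrom[1L],
                          start = NA_integer_, end = NA_integer_,
                          block_id = NA_integer_),
                     class = "haplotype_pair"))
  }
  b <- blocks[[hit[1L]]]
  at <- match(variant_index, b$snp_index)
  hap1 <- ifelse(b$phase == 0L, panel$alt[b$snp_index], panel$ref[b$snp_index])
  hap2 <- ifelse(b$phase == 0L, panel$ref[b$snp_index], panel$alt[b$snp_index])
  p_is_hap1 <- hap1[at] == variant_allele
  structure(list(parent_id = parent_id, covered = TRUE,
                 snp_index = b$snp_index,
                 P_alleles = if (p_is_hap1) hap1 else hap2,
                 N_alleles = if (p_is_hap1) hap2 else hap1,
                 chrom = b$chrom, start = b$start, end = b$end,
                 block_id = b$block_id),
            class = "haplotype_pair")
}

#' Phase-block summary statistics
#'
#' N50 is the largest length L such that blocks of length >= L cover at least
#' half the total phased span.
#'
#' @param blocks Non-empty list of `phase_block`s.
#' @param gene_interval Optional `c(start, end)`; `snps_in_anchor_block` is the
#'   SNP count of the block whose interval contains it (0 when none does).
#' @return `list(n50_length, longest_block, total_blocks, snps_in_anchor_block)`.
#' @export
phase_block_stats <- function(blocks, gene_interval = NULL) {
  if (length(blocks) == 0L) stop("no phase blocks")
  len <- vapply(blocks, function(b) b$end - b$start + 1, 0)
  sl <- sort(len, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= sum(sl) / 2)[1L]]
  anchor <- 0L
  if (!is.null(gene_interval)) {
    hit <- which(vapply(blocks, function(b)
      b$start <= gene_interval[1L] && b$end >= gene_interval[2L], TRUE))
    if (length(hit) >= 1L) anchor <- blocks[[hit[1L]]]$n_snps
  }
  structure(list(n50_length = n50, longest_block = max(len),
                 total_blocks = length(blocks),
                 snps_in_anchor_block = anchor),
            class = "phase_block_stats")
}
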