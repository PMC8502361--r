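make_obs <- function(barcode, snp_index, allele, panel) {
  data.frame(barcode = barcode, snp_index = snp_index,
             chrom = panel$chrom[snp_index], pos = panel$pos[snp_index],
             allele = allele, stringsAsFactors = FALSE)
}

test_that("pairwise barcode evidence counts cis and trans support", {
  panel <- toy_panel(4)
  obs <- make_obs("BX1", c(1L, 2L), c(panel$alt[1], panel$alt[2]), panel)
  ev <- build_allele_barcode_graph(obs, 1:4, panel)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$cis, 1L)
  expect_equal(ev$trans, 0L)

  # a ref/alt pair under one barcode is trans
  obs2 <- rbind(obs, make_obs("BX2", c(1L, 3L),
                              c(panel$ref[1], panel$alt[3]), panel))
  ev2 <- build_allele_barcode_graph(obs2, 1:4, panel)
  expect_equal(ev2$trans[ev2$i == 1 & ev2$j == 3], 1L)
  expect_error(build_allele_barcode_graph(obs[0, ], 1:4, panel), "empty")
})

test_that("evidence graph equals a brute-force per-barcode recount", {
  sim <- simulate_parental_diplotypes(25L, region_length = 2e5, het_rate = 0.9,
                                      seed = 31,
                                      pathogenic_spec = list(
                                        mother = list(pos = 1010000L, hap = 1L),
                                        father = list(pos = 1020000L, hap = 1L)))
  obs <- simulate_linked_reads(sim$mother, molecule_len_mean = 5e4,
                               min_molecule_len = 3e4,
                               molecules_per_partition = 2L, target_depth = 6,
                               error_rate = 0.02, obs_prob = 0.7, seed = 32)
  expect_lte(length(unique(obs$barcode)), 80L)
  het <- which(genotype_codes(sim$mother) == 1L)
  ev <- build_allele_barcode_graph(obs, het, sim$panel)
  oracle <- recount_evidence(obs, het, sim$panel)
  expect_equal(nrow(ev), nrow(oracle))
  expect_equal(ev$i, as.integer(oracle$i))
  expect_equal(ev$j, as.integer(oracle$j))
  expect_equal(ev$cis, as.integer(oracle$cis))
  expect_equal(ev$trans, as.integer(oracle$trans))
})

test_that("error-free connected evidence assembles one truth-matching block", {
  for (s in c(41, 42, 43)) {
    sim <- simulate_parental_diplotypes(60L, region_length = 6e5, het_rate = 1,
                                        seed = s,
                                        pathogenic_spec = list(
                                          mother = list(pos = 1300000L, hap = 1L),
                                          father = list(pos = 1310000L, hap = 1L)))
    obs <- simulate_linked_reads(sim$mother, molecule_len_mean = 1e5,
                                 molecules_per_partition = 1L,
                                 target_depth = 30, error_rate = 0,
                                 obs_prob = 0.8, seed = s + 1)
    het <- which(genotype_codes(sim$mother) == 1L)
    ev <- build_allele_barcode_graph(obs, het, sim$panel)
    expect_true(all(ev$trans == 0L | ev$cis == 0L))  # 2-colorable
    blocks <- assemble_phase_blocks(ev, het, sim$panel)
    expect_equal(length(blocks), 1L)
    b <- blocks[[1]]
    match1 <- all(b$hap1 == sim$mother$hap1[b$snp_index])
    match2 <- all(b$hap1 == sim$mother$hap2[b$snp_index])
    expect_true(match1 || match2)  # truth up to a global flip
  }
})

test_that("an evidence gap forces a block boundary", {
  panel <- toy_panel(10)
  # barcodes span 1-5 and 6-10, never across
  obs <- rbind(
    make_obs(rep(sprintf("L%d", 1:8), each = 5), rep(1:5, 8),
             panel$alt[rep(1:5, 8)], panel),
    make_obs(rep(sprintf("R%d", 1:8), each = 5), rep(6:10, 8),
             panel$alt[rep(6:10, 8)], panel))
  ev <- build_allele_barcode_graph(obs, 1:10, panel)
  blocks <- assemble_phase_blocks(ev, 1:10, panel)
  expect_gte(length(blocks), 2L)
  bounds <- vapply(blocks, function(b) b$end, 0)
  expect_true(panel$pos[5] %in% bounds)  # boundary between SNP 5 and 6
  # block intervals never overlap
  starts <- vapply(blocks, function(b) b$start, 0)
  o <- order(starts)
  expect_true(all(head(sort(bounds), -1) < starts[o][-1]))
})

test_that("greedy assembly attains the exhaustive best satisfied-evidence score", {
  panel <- toy_panel(6)
  # chain evidence with one noisy pair
  ev <- data.frame(i = 1:5, j = 2:6, cis = c(5, 5, 5, 5, 5),
                   trans = c(0, 1, 0, 2, 0))
  blocks <- assemble_phase_blocks(ev, 1:6, panel, min_support = 2L,
                                  min_margin = 2L)
  expect_equal(length(blocks), 1L)
  score <- evidence_score(blocks[[1]]$phase, ev, blocks[[1]]$snp_index)
  expect_equal(score, exhaustive_best_score(ev, 1:6))
})

test_that("block merging links overlapping consistent blocks and leaves the rest", {
  panel <- toy_panel(10)
  mk <- function(idx, phase) {
    structure(list(block_id = 1L, chrom = "chr1", start = min(panel$pos[idx]),
                   end = max(panel$pos[idx]), snp_index = idx, phase = phase,
                   hap1 = ifelse(phase == 0, panel$alt[idx], panel$ref[idx]),
                   hap2 = ifelse(phase == 0, panel$ref[idx], panel$alt[idx]),
                   n_snps = length(idx), support = rep(5L, length(idx))),
              class = "phase_block")
  }
  a <- mk(1:5, c(0L, 1L, 0L, 0L, 1L))
  # b overlaps on 3:5 with globally flipped but consistent orientation
  b <- mk(3:8, c(1L, 1L, 0L, 0L, 1L, 0L))
  merged <- merge_blocks_by_overlap(list(a), list(b), panel)
  expect_equal(length(merged), 1L)
  expect_equal(merged[[1]]$snp_index, 1:8)
  expect_equal(merged[[1]]$start, panel$pos[1])
  expect_equal(merged[[1]]$end, panel$pos[8])
  # orientation resolved toward a's frame
  expect_equal(merged[[1]]$phase[1:5], a$phase)

  disj <- merge_blocks_by_overlap(list(mk(1:3, c(0L, 0L, 1L))),
                                  list(mk(7:9, c(1L, 0L, 0L))), panel)
  expect_equal(length(disj), 2L)

  # 50:50 orientation vote refuses to merge
  c1 <- mk(1:4, c(0L, 0L, 1L, 1L))
  c2 <- mk(3:6, c(1L, 0L, 0L, 0L))  # shared 3,4: one same, one different
  expect_warning(res <- merge_blocks_by_overlap(list(c1), list(c2), panel),
                 "50:50")
  expect_equal(length(res), 2L)
})

test_that("pathogenic anchoring labels P/N, flags failures, and is involutive", {
  panel <- toy_panel(6, pathogenic = 3L)
  blocks <- assemble_phase_blocks(
    data.frame(i = 1:5, j = 2:6, cis = rep(6, 5), trans = rep(0, 5)),
    1:6, panel)
  hp <- anchor_pathogenic_variant(blocks, panel, 3L)
  expect_true(hp$covered)
  expect_identical(hp$P_alleles[hp$snp_index == 3L], panel$alt[3])
  expect_true(all(sort(c(hp$P_alleles[1], hp$N_alleles[1])) ==
                  sort(c(panel$ref[1], panel$alt[1]))))
  hp2 <- anchor_pathogenic_variant(blocks, panel, 3L)
  expect_identical(hp$P_alleles, hp2$P_alleles)

  # variant outside every block: phasing failure, analysis must be skipped
  hp_none <- anchor_pathogenic_variant(list(), panel, 3L)
  expect_false(hp_none$covered)
  expect_length(hp_none$snp_index, 0L)

  hom <- toy_diplotype("m", panel, rep(0, 6), rep(0, 6))
  expect_error(anchor_pathogenic_variant(blocks, panel, 3L, dip = hom),
               "homozygous")
})

test_that("phase-block statistics follow the N50 definition", {
  mk <- function(start, end, n) {
    structure(list(block_id = 1L, chrom = "chr11", start = start, end = end,
                   snp_index = integer(n), phase = integer(n),
                   n_snps = n), class = "phase_block")
  }
  single <- phase_block_stats(list(mk(100, 1099, 10)))
  expect_equal(single$n50_length, 1000)
  expect_equal(single$longest_block, 1000)

  three <- phase_block_stats(list(mk(0, 99999, 5), mk(200000, 399999, 5),
                                  mk(500000, 799999, 7)),
                             gene_interval = c(600000, 700000))
  expect_equal(three$n50_length, 300000)
  expect_equal(three$total_blocks, 3L)
  expect_equal(three$snps_in_anchor_block, 7L)

  # a published gene-spanning block: chr11:4249489-6238960 is 1989.5 kb
  pub <- phase_block_stats(list(mk(4249489, 6238960, 2367)))
  expect_equal(round(pub$longest_block / 1000, 1), 1989.5)
})

test_that("phase-block N50 grows with molecule length", {
  n50_at <- function(mlen, seed) {
    sim <- simulate_parental_diplotypes(80L, region_length = 8e5, het_rate = 1,
                                        seed = seed,
                                        pathogenic_spec = list(
                                          mother = list(pos = 1400000L, hap = 1L),
                                          father = list(pos = 1410000L, hap = 1L)))
    obs <- simulate_linked_reads(sim$mother, molecule_len_mean = mlen,
                                 min_molecule_len = 1e4,
                                 molecules_per_partition = 1L,
                                 target_depth = 12, error_rate = 0,
                                 obs_prob = 0.35, seed = seed + 1)
    het <- which(genotype_codes(sim$mother) == 1L)
    ev <- build_allele_barcode_graph(obs, het, sim$panel)
    phase_block_stats(assemble_phase_blocks(ev, het, sim$panel))$n50_length
  }
  short <- vapply(1:10, function(s) n50_at(2e4, 100 + s), 0)
  long <- vapply(1:10, function(s) n50_at(1.2e5, 100 + s), 0)
  expect_gte(median(long), median(short))
})
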