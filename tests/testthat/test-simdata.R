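test_that("parental diplotype generator honours het_rate, carrier placement and seed", {
  ps <- list(mother = list(pos = 1500000L, hap = 1L),
             father = list(pos = 1600000L, hap = 2L))
  sim <- simulate_parental_diplotypes(10L, region_length = 1e6, het_rate = 1,
                                      pathogenic_spec = ps, seed = 3)
  expect_equal(nrow(sim$panel), 10L)
  expect_true(all(genotype_codes(sim$mother) == 1L))
  expect_true(all(genotype_codes(sim$father) == 1L))
  expect_identical(sim$mother$pathogenic_hap, 1L)
  expect_identical(sim$father$pathogenic_hap, 2L)
  i_m <- match(1500000L, sim$panel$pos)
  expect_identical(sim$mother$hap1[i_m], sim$panel$alt[i_m])
  i_f <- match(1600000L, sim$panel$pos)
  expect_identical(sim$father$hap2[i_f], sim$panel$alt[i_f])

  again <- simulate_parental_diplotypes(10L, region_length = 1e6, het_rate = 1,
                                        pathogenic_spec = ps, seed = 3)
  expect_identical(sim, again)

  bad <- list(mother = list(pos = 99L, hap = 1L), father = list(pos = 1.6e6, hap = 1L))
  expect_error(simulate_parental_diplotypes(10L, region_length = 1e6,
                                            pathogenic_spec = bad),
               "outside")
})

test_that("linked-read generator respects error-free and single-molecule partitions", {
  sim <- simulate_parental_diplotypes(60L, region_length = 5e5, het_rate = 0.8,
                                      seed = 7,
                                      pathogenic_spec = list(
                                        mother = list(pos = 1200000L, hap = 1L),
                                        father = list(pos = 1300000L, hap = 1L)))
  obs <- simulate_linked_reads(sim$mother, molecule_len_mean = 8e4,
                               molecules_per_partition = 1L, target_depth = 30,
                               error_rate = 0, obs_prob = 0.5, seed = 8)
  expect_gt(nrow(obs), 0L)
  src <- ifelse(obs$hap == 1L, sim$mother$hap1[obs$snp_index],
                sim$mother$hap2[obs$snp_index])
  expect_identical(obs$allele, src)
  # one barcode <-> one molecule
  expect_true(all(tapply(obs$molecule_id, obs$barcode,
                         function(x) length(unique(x))) == 1L))
  # determinism
  obs2 <- simulate_linked_reads(sim$mother, molecule_len_mean = 8e4,
                                molecules_per_partition = 1L, target_depth = 30,
                                error_rate = 0, obs_prob = 0.5, seed = 8)
  expect_identical(obs, obs2)
})

test_that("mean observed molecule span tracks the length model", {
  sim <- simulate_parental_diplotypes(200L, region_length = 2e6, het_rate = 1,
                                      seed = 1,
                                      pathogenic_spec = list(
                                        mother = list(pos = 1990000L, hap = 1L),
                                        father = list(pos = 2990000L, hap = 1L)))
  spans <- numeric(0)
  for (s in 1:20) {
    obs <- simulate_linked_reads(sim$mother, molecule_len_mean = 5e4,
                                 target_depth = 100, error_rate = 0, seed = s)
    sp <- tapply(obs$pos, obs$molecule_id, function(x) diff(range(x)))
    spans <- c(spans, sp[tapply(obs$pos, obs$molecule_id, length) >= 2])
  }
  m <- mean(spans)
  expect_gt(m, 25000)   # within a factor 2 of the 50 kb length scale
  expect_lt(m, 100000)
})

test_that("fetal genome generator: crossover behaviour follows the genetic map", {
  panel <- toy_panel(101)
  mo <- toy_diplotype("mother", panel, rep(1, 101), rep(0, 101), 1L)
  fa <- toy_diplotype("father", panel, rep(0, 101), rep(1, 101), 2L)

  flat <- genetic_map(pos = range(panel$pos), cM = c(0, 0))
  tr <- simulate_fetal_genome(mo, fa, flat, recombination = TRUE, seed = 5)
  expect_equal(nrow(tr$crossovers), 0L)
  expect_equal(length(unique(tr$fetal_mat_hap)), 1L)

  steep <- genetic_map(pos = panel$pos, cM = seq(0, 100, by = 1))  # 1 cM/interval
  off <- simulate_fetal_genome(mo, fa, steep, recombination = FALSE, seed = 6)
  expect_equal(length(unique(off$fetal_mat_hap)), 1L)

  # 100 intervals at 1 cM: expected crossovers/parent = 100 * r(1 cM) ~ 0.99
  set.seed(42)
  n_xo <- vapply(1:2000, function(i) {
    t <- simulate_fetal_genome(mo, fa, steep, recombination = TRUE)
    sum(t$crossovers$parent == "mat")
  }, 0)
  expect_gt(mean(n_xo), 0.9)
  expect_lt(mean(n_xo), 1.1)

  unph <- diplotype("m", panel, mo$hap1, mo$hap2, phased = FALSE)
  expect_error(simulate_fetal_genome(unph, fa, flat), "phased")
})

test_that("plasma counts reproduce the closed-form mixture fractions", {
  n <- 6L
  panel <- toy_panel(n)
  flat <- genetic_map(pos = range(panel$pos), cM = c(0, 0))

  # mother hom-ref, father het with ALT on hap1; fetus inherits paternal hap1
  mo <- toy_diplotype("mother", panel, rep(0, n), rep(0, n))
  fa <- toy_diplotype("father", panel, rep(1, n), rep(0, n))
  truth <- list(fetal_mat_hap = rep(1L, n), fetal_pat_hap = rep(1L, n),
                crossovers = data.frame(), true_ff = 0.2, seed = NULL)
  cts <- simulate_plasma_counts(mo, fa, truth, depth_mean = 1e5,
                                error_rate = 0, seed = 9)
  depth <- cts$ref_count + cts$alt_count
  frac <- sum(cts$alt_count) / sum(depth)
  se <- sqrt(0.1 * 0.9 / sum(depth))
  expect_lt(abs(frac - 0.10), 3 * se)   # f/2 at f = 0.2

  # mother het (ALT on inherited hap1), father hom-alt, f = 0.1 -> (1+f)/2
  mo2 <- toy_diplotype("mother", panel, rep(1, n), rep(0, n))
  fa2 <- toy_diplotype("father", panel, rep(1, n), rep(1, n))
  truth2 <- list(fetal_mat_hap = rep(1L, n), fetal_pat_hap = rep(1L, n),
                 crossovers = data.frame(), true_ff = 0.1, seed = NULL)
  cts2 <- simulate_plasma_counts(mo2, fa2, truth2, depth_mean = 1e5,
                                 error_rate = 0, seed = 10)
  d2 <- cts2$ref_count + cts2$alt_count
  frac2 <- sum(cts2$alt_count) / sum(d2)
  expect_lt(abs(frac2 - 0.55), 3 * sqrt(0.55 * 0.45 / sum(d2)))

  # vanishing fetal fraction at a maternal het site -> 0.5
  truth3 <- list(fetal_mat_hap = rep(1L, n), fetal_pat_hap = rep(1L, n),
                 crossovers = data.frame(), true_ff = 1e-6, seed = NULL)
  cts3 <- simulate_plasma_counts(mo2, fa, truth3, depth_mean = 1e5,
                                 error_rate = 0, seed = 11)
  d3 <- cts3$ref_count + cts3$alt_count
  expect_lt(abs(sum(cts3$alt_count) / sum(d3) - 0.5),
            3 * sqrt(0.25 / sum(d3)))

  # conservation and determinism
  expect_true(all(cts$ref_count >= 0 & cts$alt_count >= 0))
  cts_again <- simulate_plasma_counts(mo, fa, truth, depth_mean = 1e5,
                                      error_rate = 0, seed = 9)
  expect_identical(cts, cts_again)
})

test_that("family simulator is deterministic and internally consistent", {
  a <- simulate_family(n_snps = 80, seed = 13)
  b <- simulate_family(n_snps = 80, seed = 13)
  expect_identical(a, b)
  expect_equal(sum(a$panel$is_pathogenic), 2L)
  expect_true(all(a$plasma$pos == a$panel$pos))
  expect_true(a$gene_interval[1] < a$gene_interval[2])
  ta <- true_inherited_alleles(a)
  expect_true(ta$mat %in% c("P", "N") && ta$pat %in% c("P", "N"))
})
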