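#' Expected plasma fraction of the P-haplotype allele
#'
#' Closed forms from the cfDNA mixture: a fraction 1 - f of plasma derives from
#' the mother (her two alleles equally represented) and f from the fetus (its
#' maternal and paternal alleles equally represented). With state = which
#' haplotype of the analyzed parent the fetus inherited, the expected fraction
#' of the P-hap allele is:
#'
#' * maternal-informative, father homozygous for the P allele:
#'   state P -> (1+f)/2, state N -> 1/2
#' * maternal-informative, father homozygous for the N allele:
#'   state P -> 1/2, state N -> (1-f)/2
#' * paternal-informative, mother homozygous for the N allele:
#'   state P -> f/2, state N -> 0
#' * paternal-informative, mother homozygous for the P allele:
#'   state P -> 1, state N -> 1 - f/2
#'
#' Values are clamped into `[eps, 1 - eps]`: sequencing error makes an absent
#' allele observable at rate ~eps, and the clamp leaves interior fractions
#' untouched.
#'
#' @param state `"P"` or `"N"` (vectorized).
#' @param category `"MAT_INFORMATIVE"` or `"PAT_INFORMATIVE"`.
#' @param subtype `"father_hom_P"`, `"father_hom_N"`, `"mother_hom_P"` or
#'   `"mother_hom_N"`.
#' @param ff Fetal fraction in (0, 1).
#' @param eps Sequencing-error floor for absent alleles (default 0.005).
#' @return Expected P-allele fraction(s) in (0, 1).
#' @export
expected_allele_fraction <- function(state, category, subtype, ff, eps = 0.005) {
  if (any(ff <= 0 | ff >= 1)) stop("ff must be in (0, 1)")
  n <- max(length(state), length(category), length(subtype))
  state <- rep_len(state, n); category <- rep_len(category, n)
  subtype <- rep_len(subtype, n)
  key <- paste(category, subtype, state, sep = ":")
  val <- rep(NA_real_, n)
  val[key == "MAT_INFORMATIVE:father_hom_P:P"] <- (1 + ff) / 2
  val[key == "MAT_INFORMATIVE:father_hom_P:N"] <- 1 / 2
  val[key == "MAT_INFORMATIVE:father_hom_N:P"] <- 1 / 2
  val[key == "MAT_INFORMATIVE:father_hom_N:N"] <- (1 - ff) / 2
  val[key == "PAT_INFORMATIVE:mother_hom_N:P"] <- ff / 2
  val[key == "PAT_INFORMATIVE:mother_hom_N:N"] <- 0
  val[key == "PAT_INFORMATIVE:mother_hom_P:P"] <- 1
  val[key == "PAT_INFORMATIVE:mother_hom_P:N"] <- 1 - ff / 2
  if (anyNA(val))
    stop("unrecognized (state, category, subtype) combination: ",
         paste(unique(key[is.na(val)]), collapse = ", "))
  pmin(pmax(val, eps), 1 - eps)
}

#' Binomial emission log-probability
#'
#' Log-probability of observing `p_count` P-allele reads out of
#' `p_count + n_count` at the state's expected P fraction. A zero-depth site
#' carries no information and contributes 0.
#'
#' @param p_count,n_count Non-negative read counts (vectorized).
#' @param expected_p_fraction Expected P-allele fraction in (0, 1).
#' @return Log-probabilities.
#' @export
emission_logprob <- function(p_count, n_count, expected_p_fraction) {
  if (any(p_count < 0 | n_count < 0)) stop("counts must be non-negative")
  if (any(expected_p_fraction <= 0 | expected_p_fraction >= 1))
    stop("expected fraction must be in (0, 1)")
  depth <- p_count + n_count
  out <- stats::dbinom(p_count, depth, expected_p_fraction, log = TRUE)
  out[depth == 0] <- 0
  out
}

# switch probability between adjacent SNPs at genetic distance d_cM
recombination_fraction <- function(d_cM, r_min = 1e-8,
                                   map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d_cM < 0)) stop("genetic distance must be non-negative")
  r <- if (map_function == "haldane") haldane_r(d_cM) else kosambi_r(d_cM)
  pmax(r, r_min)
}

#' HMM transition matrix between adjacent SNPs
#'
#' The switch probability is the recombination fraction of the inter-SNP
#' genetic distance (Haldane by default), floored at `r_min` so co-located
#' SNPs never produce -Inf log transitions.
#'
#' @param d_cM Genetic distance in centimorgan (scalar, non-negative).
#' @param r_min Floor on the recombination fraction.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return 2x2 matrix, rows = from-state (P, N), columns = to-state; rows sum
#'   to 1.
#' @export
transition_matrix <- function(d_cM, r_min = 1e-8,
                              map_function = c("haldane", "kosambi")) {
  r <- recombination_fraction(d_cM, r_min, map_function)
  matrix(c(1 - r, r, r, 1 - r), nrow = 2, byrow = TRUE,
         dimnames = list(c("P", "N"), c("P", "N")))
}

# Vectorized Viterbi over R parallel instances of the same 2-state chain.
# leP/leN: R x k log-emission matrices; r: length k-1 switch probabilities.
# Ties in backtracking prefer the stay predecessor; a final-state tie prefers P.
# Returns states as an R x k logical matrix (TRUE = P) and per-row log-lik.
viterbi_core <- function(leP, leN, r) {
  R <- nrow(leP); k <- ncol(leP)
  dpP <- log(0.5) + leP[, 1L]
  dpN <- log(0.5) + leN[, 1L]
  ptrP <- ptrN <- matrix(FALSE, R, max(k - 1L, 0L))
  if (k > 1L) {
    lst <- log1p(-r); lsw <- log(r)
    for (t in seq_len(k - 1L)) {
      sPs <- dpP + lst[t]; sPx <- dpN + lsw[t]
      sNs <- dpN + lst[t]; sNx <- dpP + lsw[t]
      stayP <- sPs >= sPx; stayN <- sNs >= sNx
      ptrP[, t] <- stayP; ptrN[, t] <- stayN
      dpP <- ifelse(stayP, sPs, sPx) + leP[, t + 1L]
      dpN <- ifelse(stayN, sNs, sNx) + leN[, t + 1L]
    }
  }
  isP <- matrix(FALSE, R, k)
  cur <- dpP >= dpN
  isP[, k] <- cur
  if (k > 1L) {
    for (t in rev(seq_len(k - 1L))) {
      stay <- ifelse(cur, ptrP[, t], ptrN[, t])
      cur <- ifelse(stay, cur, !cur)
      isP[, t] <- cur
    }
  }
  list(isP = isP, loglik = pmax(dpP, dpN))
}

# collapse a state vector into maximal constant segments with bp intervals
states_to_segments <- function(states, pos) {
  rl <- rle(states)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  data.frame(state = rl$values, start_idx = starts, end_idx = ends,
             start_pos = pos[starts], end_pos = pos[ends],
             n_snps = rl$lengths, stringsAsFactors = FALSE)
}

#' Viterbi decoding of the fetal inherited haplotype
#'
#' Two-state HMM over one parent's informative SNPs: states P/N (which parental
#' haplotype the fetus inherited), uniform initial probabilities, binomial
#' emissions at the state's expected plasma dosage and genetic-map transition
#' probabilities. Backtracking ties are broken toward the no-switch
#' predecessor, biasing against spurious recombination events.
#'
#' @param hap_counts One parent's rows of [extract_haplotype_counts()], sorted
#'   by position.
#' @param ff Fetal fraction in (0, 1).
#' @param map A [genetic_map()].
#' @param eps Error floor for [expected_allele_fraction()].
#' @param r_min Recombination-fraction floor.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @return A `haplotype_path`: `parent, states, segments, log_likelihood, pos`.
#' @export
viterbi_decode <- function(hap_counts, ff, map, eps = 0.005, r_min = 1e-8,
                           map_function = c("haldane", "kosambi")) {
  if (nrow(hap_counts) == 0L) stop("no informative SNPs to decode")
  if (is.unsorted(hap_counts$pos)) hap_counts <- hap_counts[order(hap_counts$pos), ]
  fP <- expected_allele_fraction("P", hap_counts$category, hap_counts$subtype,
                                 ff, eps)
  fN <- expected_allele_fraction("N", hap_counts$category, hap_counts$subtype,
                                 ff, eps)
  leP <- matrix(emission_logprob(hap_counts$p_count, hap_counts$n_count, fP),
                nrow = 1L)
  leN <- matrix(emission_logprob(hap_counts$p_count, hap_counts$n_count, fN),
                nrow = 1L)
  d <- pmax(diff(interpolate_cM(map, hap_counts$pos)), 0)
  r <- recombination_fraction(d, r_min, map_function)
  v <- viterbi_core(leP, leN, r)
  states <- ifelse(v$isP[1L, ], "P", "N")
  structure(list(parent = hap_counts$parent[1L], states = states,
                 segments = states_to_segments(states, hap_counts$pos),
                 log_likelihood = v$loglik[1L], pos = hap_counts$pos),
            class = "haplotype_path")
}

#' @export
print.haplotype_path <- function(x, ...) {
  cat(sprintf("<haplotype_path> parent %s: %d SNPs, %d segment(s), logL %.2f\n",
              x$parent, length(x$states), nrow(x$segments), x$log_likelihood))
  invisible(x)
}

# call rule applied to a plain state vector (shared by path objects and the
# batched confidence-score simulation)
call_from_states <- function(states, pos, gene_interval) {
  if (gene_interval[1L] < pos[1L] || gene_interval[2L] > pos[length(pos)])
    return(list(allele = "NO_CALL", reason = "gene interval not covered by informative SNPs"))
  seg <- states_to_segments(states, pos)
  spans <- seg$start_pos <= gene_interval[1L] & seg$end_pos >= gene_interval[2L]
  if (sum(spans) == 1L)
    return(list(allele = seg$state[spans], reason = "single haplotype segment spans the gene"))
  list(allele = "NO_CALL", reason = "haplotype segment boundary inside the target gene")
}

#' Rule-based fetal allele call at the pathogenic site
#'
#' The decoded path is reduced to maximal constant-state segments and the call
#' is the state of the unique segment whose bp interval contains the whole
#' gene interval. This realizes the three call rules: a single spanning segment
#' is called; with two segments the one spanning the gene is called; a segment
#' boundary falling inside the gene — possible fetal recombination at the
#' critical locus — yields NO_CALL, as does a gene interval outside the span of
#' the informative SNPs. More than two segments are handled by the same
#' unique-spanning-segment test.
#'
#' @param path A `haplotype_path` from [viterbi_decode()].
#' @param gene_interval `c(start, end)` in bp.
#' @return `list(allele, reason)` with `allele` in `{"P", "N", "NO_CALL"}`.
#' @export
call_fetal_allele <- function(path, gene_interval) {
  call_from_states(path$states, path$pos, gene_interval)
}
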