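#' Monte-Carlo confidence score for a parental haplotype call
#'
#' Simulates `replicates` plasma datasets under the called inheritance state —
#' binomial draws at each informative SNP's expected dosage, at the observed
#' per-SNP depths and the estimated fetal fraction — re-runs Viterbi decoding
#' and the rule-based call on each, and reports the fraction of replicates that
#' reproduce the called allele. The score therefore reflects the design power
#' of the instance (fetal fraction, depth, informative-SNP count and spacing),
#' not the observed counts themselves.
#'
#' @param design The decoded instance's informative-SNP table: columns
#'   `pos, category, subtype, depth` (one parent's rows of
#'   [extract_haplotype_counts()] qualify). If `depth_profile` is supplied with
#'   a different number of sites than `design`, depths are resampled from it
#'   with replacement, preserving depth heterogeneity.
#' @param ff Fetal fraction in (0, 1).
#' @param called_state `"P"` or `"N"`: the state whose recovery is scored.
#' @param map A [genetic_map()].
#' @param gene_interval `c(start, end)` in bp.
#' @param replicates Number of Monte-Carlo replicates (at least 100; default
#'   1000).
#' @param threshold No-call threshold on the score (default 0.99).
#' @param eps,r_min,map_function Passed to the emission/transition model.
#' @param depth_profile Optional vector of depths to resample.
#' @param seed Optional integer seed.
#' @return A `cs_result`: `list(cs, replicates, threshold, decision, seed)`
#'   with `decision = "NO_CALL"` iff `cs < threshold`.
#' @export
confidence_score <- function(design, ff, called_state, map, gene_interval,
                             replicates = 1000L, threshold = 0.99,
                             eps = 0.005, r_min = 1e-8,
                             map_function = c("haldane", "kosambi"),
                             depth_profile = NULL, seed = NULL) {
  if (replicates < 100L) stop("replicates must be at least 100")
  if (ff <= 0) stop("ff must be positive")
  if (!called_state %in% c("P", "N")) stop("called_state must be 'P' or 'N'")
  if (!is.null(seed)) set.seed(seed)
  if (is.unsorted(design$pos)) design <- design[order(design$pos), ]
  k <- nrow(design)
  if (k == 0L) stop("empty design: no informative SNPs")
  depth <- design$depth
  if (!is.null(depth_profile) && length(depth_profile) != k)
    depth <- sample(depth_profile, k, replace = TRUE)

  fC <- expected_allele_fraction(called_state, design$category, design$subtype,
                                 ff, eps)
  fP <- expected_allele_fraction("P", design$category, design$subtype, ff, eps)
  fN <- expected_allele_fraction("N", design$category, design$subtype, ff, eps)
  R <- as.integer(replicates)
  pc <- matrix(stats::rbinom(R * k, size = rep(depth, each = R),
                             prob = rep(fC, each = R)), nrow = R)
  D <- matrix(rep(depth, each = R), nrow = R)
  leP <- stats::dbinom(pc, D, matrix(rep(fP, each = R), nrow = R), log = TRUE)
  leN <- stats::dbinom(pc, D, matrix(rep(fN, each = R), nrow = R), log = TRUE)
  leP[D == 0] <- 0; leN[D == 0] <- 0

  d <- pmax(diff(interpolate_cM(map, design$pos)), 0)
  r <- recombination_fraction(d, r_min, match.arg(map_function))
  v <- viterbi_core(leP, leN, r)

  # fast path: replicates decoded to a single segment need no interval logic
  n_switch <- if (k > 1L) rowSums(v$isP[, -1L, drop = FALSE] !=
                                  v$isP[, -k, drop = FALSE]) else rep(0L, R)
  gene_ok <- gene_interval[1L] >= design$pos[1L] &&
             gene_interval[2L] <= design$pos[k]
  called <- character(R)
  single <- n_switch == 0L
  called[single] <- if (gene_ok) ifelse(v$isP[single, 1L], "P", "N") else "NO_CALL"
  for (i in which(!single)) {
    st <- ifelse(v$isP[i, ], "P", "N")
    called[i] <- call_from_states(st, design$pos, gene_interval)$allele
  }
  cs <- mean(called == called_state)
  structure(list(cs = cs, replicates = R, threshold = threshold,
                 decision = apply_no_call(cs, threshold), seed = seed),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("<cs_result> CS = %.4f (%d replicates, threshold %.2f) -> %s\n",
              x$cs, x$replicates, x$threshold, x$decision))
  invisible(x)
}

#' Apply the no-call threshold to a confidence score
#'
#' A call stands only when the confidence score reaches the threshold; a score
#' strictly below it is a no-call (the boundary value itself remains callable).
#'
#' @param cs Confidence score in `[0, 1]`.
#' @param threshold No-call threshold (default 0.99).
#' @return `"CALL"` or `"NO_CALL"`.
#' @export
apply_no_call <- function(cs, threshold = 0.99) {
  if (is.na(cs) || cs < 0 || cs > 1) stop("cs must be in [0, 1]")
  if (cs < threshold) "NO_CALL" else "CALL"
}
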