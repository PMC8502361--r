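#' Combine the two parental calls into a fetal genotype category
#'
#' For an autosomal recessive disorder with one pathogenic variant per carrier
#' parent: both P alleles inherited -> AFFECTED; exactly one -> CARRIER;
#' neither -> NORMAL. When exactly one parental allele is unavailable
#' (NO_CALL or not applicable after a phasing failure) the result is PARTIAL;
#' when both are unavailable, NO_CALL.
#'
#' @param mat_call,pat_call `"P"`, `"N"`, `"NO_CALL"` or `"NA"`/`NA`.
#' @return One of `"AFFECTED", "CARRIER", "NORMAL", "PARTIAL", "NO_CALL"`.
#' @export
classify_fetal_genotype <- function(mat_call, pat_call) {
  norm <- function(x) if (is.na(x)) "NA" else as.character(x)
  m <- norm(mat_call); p <- norm(pat_call)
  avail <- c(m, p) %in% c("P", "N")
  if (all(avail)) {
    n_p <- sum(c(m, p) == "P")
    return(c("NORMAL", "CARRIER", "AFFECTED")[n_p + 1L])
  }
  if (sum(avail) == 1L) "PARTIAL" else "NO_CALL"
}

#' Concordance of fetal calls against ground truth
#'
#' @param reports `data.frame` with columns `family_id, mat_call, pat_call`
#'   (values `"P"/"N"/"NO_CALL"/"NA"`).
#' @param truth `data.frame` with columns `family_id, mat_true, pat_true`
#'   (values `"P"/"N"`). Families absent from `truth` are excluded with a
#'   message.
#' @return `list(n_families, n_called_both, n_concordant, n_no_call_families,
#'   categories)` where `categories` is a named count vector over the genotype
#'   categories. A family counts as no-call when either allele is unavailable.
#' @export
concordance_table <- function(reports, truth) {
  cats <- c(AFFECTED = 0L, CARRIER = 0L, NORMAL = 0L, PARTIAL = 0L, NO_CALL = 0L)
  if (nrow(reports) == 0L)
    return(list(n_families = 0L, n_called_both = 0L, n_concordant = 0L,
                n_no_call_families = 0L, categories = cats))
  hit <- match(reports$family_id, truth$family_id)
  if (anyNA(hit)) {
    message(sprintf("%d famil(ies) missing from truth excluded", sum(is.na(hit))))
    reports <- reports[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  called <- function(x) !is.na(x) & x %in% c("P", "N")
  both <- called(reports$mat_call) & called(reports$pat_call)
  conc <- both & reports$mat_call == truth$mat_true[hit] &
          reports$pat_call == truth$pat_true[hit]
  for (i in seq_len(nrow(reports))) {
    cat_i <- classify_fetal_genotype(reports$mat_call[i], reports$pat_call[i])
    cats[cat_i] <- cats[cat_i] + 1L
  }
  list(n_families = nrow(reports), n_called_both = sum(both),
       n_concordant = sum(conc), n_no_call_families = sum(!both),
       categories = cats)
}
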