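#' Construct a genetic map
#'
#' Ordered (bp, cM) anchor pairs; genetic positions of arbitrary bp coordinates
#' are obtained by piecewise-linear interpolation, and queries outside the anchor
#' range are extrapolated with the local recombination rate of the nearest
#' terminal segment.
#'
#' @param pos Base-pair positions of the anchors.
#' @param cM Genetic positions in centimorgan, non-decreasing in `pos`.
#' @param chrom Chromosome name.
#' @return A `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(pos, cM, chrom = "chr1") {
  if (length(pos) != length(cM) || length(pos) < 1L)
    stop("pos and cM must be equal-length, non-empty")
  o <- order(pos)
  pos <- as.numeric(pos[o]); cM <- as.numeric(cM[o])
  if (length(pos) > 1L && any(diff(cM) < 0)) stop("cM must be non-decreasing in bp")
  structure(data.frame(chrom = chrom, pos = pos, cM = cM),
            class = c("genetic_map", "data.frame"))
}

#' Interpolate genetic positions
#'
#' @param map A [genetic_map()].
#' @param pos Base-pair positions to query.
#' @return Numeric cM positions.
#' @export
interpolate_cM <- function(map, pos) {
  p <- map$pos; g <- map$cM
  m <- length(p)
  if (m == 1L) return(rep(g, length(pos)))
  res <- stats::approx(p, g, xout = pos, rule = 2, ties = "ordered")$y
  lo <- pos < p[1L]; hi <- pos > p[m]
  if (any(lo)) res[lo] <- g[1L] + (g[2L] - g[1L]) / (p[2L] - p[1L]) * (pos[lo] - p[1L])
  if (any(hi)) res[hi] <- g[m] + (g[m] - g[m - 1L]) / (p[m] - p[m - 1L]) * (pos[hi] - p[m])
  res
}

#' Haldane map function
#'
#' Converts a genetic distance in cM to a recombination fraction under the
#' no-interference (Haldane) model: r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cM Genetic distance(s) in centimorgan, non-negative.
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("genetic distance must be non-negative")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Kosambi map function
#'
#' Interference-aware alternative to [haldane_r()]: r = tanh(2d/100)/2.
#'
#' @inheritParams haldane_r
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
kosambi_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("genetic distance must be non-negative")
  tanh(2 * d_cM / 100) / 2
}

#' Build a constant-rate genetic map over a region
#'
#' @param chrom Chromosome name.
#' @param start,end Region bounds in bp.
#' @param cM_per_Mb Uniform recombination rate (default 1 cM/Mb, the genome-wide
#'   human average).
#' @return A [genetic_map()] with two anchors.
#' @export
uniform_genetic_map <- function(chrom, start, end, cM_per_Mb = 1) {
  genetic_map(pos = c(start, end), cM = c(0, (end - start) / 1e6 * cM_per_Mb),
              chrom = chrom)
}
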