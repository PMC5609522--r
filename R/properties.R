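# Physico-chemical protein properties: molecular weight, isoelectric point and
# hydropathy-based transmembrane segment prediction.

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Average residue masses (Da); a free chain adds one water.
AA_MASS_AVG <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
WATER_MASS <- 18.01524

# Side-chain / termini pKa sets for isoelectric point calculation.
PKA_SETS <- list(
  emboss = list(
    nterm = 8.6, cterm = 3.6,
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)),
  bjellqvist = list(
    nterm = 7.5, cterm = 3.55,
    positive = c(K = 10.0, R = 12.0, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)))

#' Molecular weight of a protein
#'
#' Sums average residue masses plus one water, mirroring the usual
#' protein-parameter convention (average, not monoisotopic, masses).
#'
#' @param sequence residue string (one-letter codes).
#' @return Molecular weight in kDa.
#' @examples
#' compute_mw("G") * 1000  # 75.07 Da
#' @export
compute_mw <- function(sequence) {
  s <- validate_sequence(sequence)
  residues <- strsplit(s, "")[[1]]
  (sum(AA_MASS_AVG[residues]) + WATER_MASS) / 1000
}

# Net charge of a peptide at a given pH (Henderson-Hasselbalch over the
# termini and D, E, C, Y, K, R, H side chains).
peptide_charge <- function(sequence, ph, pka_set = "emboss") {
  s <- validate_sequence(sequence)
  pka <- if (is.list(pka_set)) pka_set else PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]]
  counts <- table(factor(strsplit(s, "")[[1]], levels = AA_ALPHABET))
  pos <- 1 / (1 + 10^(ph - pka$nterm)) +
    sum(counts[names(pka$positive)] / (1 + 10^(ph - pka$positive)))
  neg <- 1 / (1 + 10^(pka$cterm - ph)) +
    sum(counts[names(pka$negative)] / (1 + 10^(pka$negative - ph)))
  pos - neg
}

#' Isoelectric point of a protein
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge crosses zero by
#' bisection on \[0, 14\].
#'
#' @param sequence residue string.
#' @param pka_set `"emboss"` (default) or `"bjellqvist"`, or a custom list
#'   with elements `nterm`, `cterm`, `positive`, `negative`.
#' @param tol bisection tolerance in pH units.
#' @return Isoelectric point (pH units).
#' @export
compute_pi <- function(sequence, pka_set = "emboss", tol = 1e-4) {
  s <- validate_sequence(sequence)
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peptide_charge(s, mid, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Predict transmembrane segments from hydropathy
#'
#' Sliding-window mean Kyte-Doolittle hydropathy; maximal runs of window
#' centers at or above `threshold` become segments. Runs shorter than
#' `min_span` are discarded, then surviving runs separated by fewer than
#' `merge_gap` residues are merged. A deliberately simple stand-in for a
#' full topology predictor: segment counts, not boundaries, are the intended
#' use.
#'
#' @param sequence residue string.
#' @param window odd window width (residues).
#' @param threshold hydropathy-units threshold for the window mean.
#' @param min_span minimum run length (residues) kept.
#' @param merge_gap runs closer than this many residues are merged.
#' @return Integer matrix with columns `start`, `end`: 0-based half-open
#'   intervals, sorted and non-overlapping.
#' @export
predict_tm_segments <- function(sequence, window = 19, threshold = 1.6,
                                min_span = 15, merge_gap = 3) {
  s <- validate_sequence(sequence)
  if (window <= 0 || window %% 2 == 0)
    stop("window must be a positive odd integer")
  n <- nchar(s)
  if (window > n)
    stop("window exceeds sequence length")
  h <- KYTE_DOOLITTLE[strsplit(s, "")[[1]]]
  hw <- (window - 1) / 2
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centers <- (hw + 1):(n - hw)
  above <- means[centers] >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_span
  segs <- cbind(start = centers[starts[keep]] - 1L,   # 0-based half-open
                end   = centers[ends[keep]])
  if (nrow(segs) > 1) {
    merged <- segs[1, , drop = FALSE]
    for (i in 2:nrow(segs)) {
      if (segs[i, "start"] - merged[nrow(merged), "end"] < merge_gap)
        merged[nrow(merged), "end"] <- segs[i, "end"]
      else
        merged <- rbind(merged, segs[i, , drop = FALSE])
    }
    segs <- merged
  }
  storage.mode(segs) <- "integer"
  segs
}
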