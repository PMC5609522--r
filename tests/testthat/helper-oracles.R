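# Independent test oracles (deliberately naive implementations, kept separate
# from the package code paths they check) and shared fixtures.

# Affine-gap global alignment score by explicit Gotoh dynamic programming:
# a gap of length L costs open + L * ext.
oracle_align_score <- function(a, b, submat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Exhaustive window-by-window NPA scan.
oracle_npa_scan <- function(sequence, third = c("A", "S", "T", "L", "V")) {
  ch <- strsplit(sequence, "")[[1]]
  pos <- integer(); trip <- character()
  for (i in seq_len(max(0, length(ch) - 2))) {
    if (ch[i] == "N" && ch[i + 1] == "P" && ch[i + 2] %in% third) {
      pos <- c(pos, i - 1L)
      trip <- c(trip, paste(ch[i:(i + 2)], collapse = ""))
    }
  }
  data.frame(position = pos, triplet = trip, stringsAsFactors = FALSE)
}

# Residue-by-residue mass summation from an independently restated table
# (ExPASy average residue masses).
oracle_mw_da <- function(sequence) {
  tab <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
           C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
           H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
           M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
           T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  total <- 18.01524
  for (ch in strsplit(sequence, "")[[1]]) total <- total + tab[[ch]]
  total
}

# Position-by-position pattern match (loop form).
oracle_match_count <- function(sdp, allowed) {
  n <- 0L
  for (i in 1:9)
    if (!is.na(sdp[i]) && sdp[i] %in% allowed[[i]]) n <- n + 1L
  n
}

random_peptide <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                             "H", "I", "K", "L", "M", "N",
                                             "P", "Q", "R", "S", "T", "V",
                                             "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Shared synthetic fixtures, generated once per test run.
fixture_env <- new.env(parent = emptyenv())

fixture_proteome <- function() {
  if (is.null(fixture_env$proteome))
    fixture_env$proteome <- make_proteome(n_aqp = 10, n_decoy = 40, seed = 7)
  fixture_env$proteome
}

fixture_anchor <- function() {
  if (is.null(fixture_env$anchor))
    fixture_env$anchor <- load_anchor()
  fixture_env$anchor
}

fixture_scaffolds <- function() {
  if (is.null(fixture_env$scaffolds))
    fixture_env$scaffolds <- subgroup_scaffolds()
  fixture_env$scaffolds
}
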