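# Proteome screening: dual NPA-like motifs, transmembrane helix count,
# length bounds and global-alignment identity to a reference panel.

#' Scan a sequence for NPA-like motifs
#'
#' Finds all occurrences of Asn-Pro-X where X is one of the third-position
#' variants observed in plant aquaporins (A, S, T, L, V by default), left to
#' right.
#'
#' @param sequence residue string.
#' @param third allowed third-position residues.
#' @return data.frame with `position` (0-based index of the triplet start)
#'   and `triplet`, sorted by position.
#' @export
scan_npa_motifs <- function(sequence, third = c("A", "S", "T", "L", "V")) {
  s <- validate_sequence(sequence)
  pattern <- paste0("NP[", paste(third, collapse = ""), "]")
  m <- gregexpr(pattern, s)[[1]]
  if (m[1] == -1L)
    return(data.frame(position = integer(), triplet = character(),
                      stringsAsFactors = FALSE))
  data.frame(position = as.integer(m) - 1L,
             triplet = substring(s, m, m + 2L),
             stringsAsFactors = FALSE)
}

#' Default screening thresholds
#'
#' @param npa_min minimum number of NPA-like hits.
#' @param npa_spacing allowed distance range (residues) between some pair of
#'   hits; the default 60-180 reflects the spacing of the two NPA loops in
#'   the six-transmembrane hourglass fold.
#' @param tm_min minimum predicted transmembrane segment count.
#' @param length_range allowed protein length range (residues).
#' @param identity_floor minimum global-alignment identity to the closest
#'   reference aquaporin.
#' @param tm_args arguments forwarded to [predict_tm_segments()].
#' @return Named list of thresholds.
#' @export
screen_thresholds <- function(npa_min = 2L, npa_spacing = c(60L, 180L),
                              tm_min = 4L, length_range = c(200L, 400L),
                              identity_floor = 0.30, tm_args = list()) {
  list(npa_min = npa_min, npa_spacing = npa_spacing, tm_min = tm_min,
       length_range = length_range, identity_floor = identity_floor,
       tm_args = tm_args)
}

#' Screen a proteome for aquaporin candidates
#'
#' A candidate passes when it carries at least `npa_min` NPA-like motifs with
#' some pair spaced inside `npa_spacing`, at least `tm_min` predicted
#' transmembrane segments, a length inside `length_range`, and a best global
#' alignment identity to the reference panel of at least `identity_floor`.
#' Failed filters are enumerated in `fail_reasons`.
#'
#' @param fasta path to a protein FASTA file, or an `AAStringSet`, or a named
#'   character vector of sequences.
#' @param refs reference aquaporins (named character vector or `AAStringSet`).
#' @param thresholds list from [screen_thresholds()].
#' @return data.frame with one row per protein: `protein_id`, `length`,
#'   `n_npa`, `npa_positions`, `tm_count`, `best_ref_identity`, `passed`,
#'   `fail_reasons` (semicolon-joined, empty when passed).
#' @export
screen_proteome <- function(fasta, refs, thresholds = screen_thresholds()) {
  seqs <- as_sequences(fasta)
  refs <- as_sequences(refs)
  if (length(refs) == 0L) stop("reference panel must be non-empty")
  if (length(seqs) == 0L) {
    warning("empty proteome: no candidates to screen")
    return(data.frame(protein_id = character(), length = integer(),
                      n_npa = integer(), npa_positions = character(),
                      tm_count = integer(), best_ref_identity = numeric(),
                      passed = logical(), fail_reasons = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(seqs), function(id) {
    s <- validate_sequence(seqs[[id]], paste0("sequence '", id, "'"))
    hits <- scan_npa_motifs(s)
    tm <- do.call(predict_tm_segments, c(list(s), thresholds$tm_args))
    ident <- max(align_identities(s, refs))
    reasons <- character()
    if (nrow(hits) < thresholds$npa_min) {
      reasons <- c(reasons, "npa_count")
    } else if (nrow(hits) >= 2L) {
      gaps <- as.vector(dist(hits$position))
      if (!any(gaps >= thresholds$npa_spacing[1] &
               gaps <= thresholds$npa_spacing[2]))
        reasons <- c(reasons, "npa_spacing")
    }
    if (nrow(tm) < thresholds$tm_min) reasons <- c(reasons, "tm_count")
    if (nchar(s) < thresholds$length_range[1] ||
        nchar(s) > thresholds$length_range[2])
      reasons <- c(reasons, "length")
    if (ident < thresholds$identity_floor) reasons <- c(reasons, "ref_identity")
    data.frame(protein_id = id, length = nchar(s), n_npa = nrow(hits),
               npa_positions = paste(hits$position, collapse = ","),
               tm_count = nrow(tm), best_ref_identity = ident,
               passed = length(reasons) == 0L,
               fail_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Coerce FASTA path / AAStringSet / named character into a named character
# vector of sequences.
as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x)))
    x <- readAAStringSet(x)
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x)) || any(names(x) == ""))
      stop("sequences must be named")
    return(x)
  }
  stop("cannot interpret input as protein sequences")
}
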