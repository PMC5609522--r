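# Anchor alignment and diagnostic-residue extraction: a candidate is globally
# aligned to the annotated anchor and the residues in the anchor's diagnostic
# columns are read off the alignment.

#' Default alignment scoring parameters
#'
#' BLOSUM62 with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_ext`).
#'
#' @param matrix substitution matrix name available in Biostrings, or a
#'   numeric matrix.
#' @param gap_open,gap_ext affine gap penalties (positive costs).
#' @return Named list of parameters.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_ext = 0.5) {
  list(matrix = matrix, gap_open = gap_open, gap_ext = gap_ext)
}

# cache for named substitution matrices shipped with Biostrings
.matrix_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name) {
  if (is.null(.matrix_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .matrix_cache[[name]] <- get(name, envir = e)
  }
  .matrix_cache[[name]]
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' Biostrings. Deterministic for fixed inputs and parameters.
#'
#' @param query,subject residue strings; `subject` may also be an anchor list
#'   from [load_anchor()] (its sequence is used).
#' @param params scoring parameters from [align_params()].
#' @param query_id,subject_id identifiers carried into the result.
#' @return An `aqp_alignment` list: `query_id`, `anchor_id`, `aligned_query`,
#'   `aligned_anchor` (equal-length gapped strings), `score` and `identity`
#'   (matching columns / alignment length).
#' @export
global_align <- function(query, subject, params = align_params(),
                         query_id = "query", subject_id = "subject") {
  if (is.list(subject) && !is.null(subject$sequence)) {
    subject_id <- subject$anchor_id
    subject <- subject$sequence
  }
  q <- validate_sequence(query, "query")
  s <- validate_sequence(subject, "subject")
  mat <- params$matrix
  if (is.character(mat)) mat <- substitution_matrix(mat)
  pa <- pairwiseAlignment(AAString(q), AAString(s),
                          substitutionMatrix = mat,
                          gapOpening = params$gap_open,
                          gapExtension = params$gap_ext,
                          type = "global")
  structure(list(query_id = query_id, anchor_id = subject_id,
                 aligned_query = as.character(Biostrings::pattern(pa)),
                 aligned_anchor = as.character(Biostrings::subject(pa)),
                 score = score(pa),
                 identity = Biostrings::nmatch(pa) / Biostrings::nchar(pa)),
            class = "aqp_alignment")
}

# Identities of one query against many references in a single vectorized
# alignment call (matching columns / alignment length, as in global_align).
align_identities <- function(query, refs, params = align_params()) {
  mat <- params$matrix
  if (is.character(mat)) mat <- substitution_matrix(mat)
  pa <- pairwiseAlignment(AAStringSet(refs), AAString(query),
                          substitutionMatrix = mat,
                          gapOpening = params$gap_open,
                          gapExtension = params$gap_ext,
                          type = "global")
  setNames(Biostrings::nmatch(pa) / Biostrings::nchar(pa), names(refs))
}

#' @export
print.aqp_alignment <- function(x, ...) {
  cat("Global alignment", x$query_id, "vs", x$anchor_id,
      sprintf("(score %.2f, identity %.3f)\n", x$score, x$identity))
  invisible(x)
}

#' Extract the diagnostic residue profile from an anchor alignment
#'
#' For every diagnostic anchor column, returns the query residue aligned to
#' it, or a gap. NPA triplets are assembled from their three columns; a
#' triplet containing any gap is reported missing (NA). A gap at a diagnostic
#' column is never substituted by a neighboring residue.
#'
#' @param alignment `aqp_alignment` of a query against the anchor.
#' @param anchor anchor list from [load_anchor()].
#' @return An `aqp_profile` list: `query_id`, `npa_lb`, `npa_le` (3-character
#'   strings or NA), `arr` (named H2/H5/LE1/LE2), `froger` (P1-P5), `sdp`
#'   (SDP1-SDP9; NA marks a gap) and `provenance` (named map from label to
#'   0-based query index, or `"gap"`).
#' @export
extract_profile <- function(alignment, anchor) {
  if (!inherits(alignment, "aqp_alignment"))
    stop("alignment must come from global_align()")
  if (alignment$anchor_id != anchor$anchor_id)
    stop("alignment anchor '", alignment$anchor_id,
         "' does not match anchor '", anchor$anchor_id, "'")
  ac <- strsplit(alignment$aligned_anchor, "")[[1]]
  qc <- strsplit(alignment$aligned_query, "")[[1]]
  # alignment column of each anchor residue, and query index at each column
  anchor_cols <- which(ac != "-")
  query_index <- cumsum(qc != "-") - 1L
  labels <- names(anchor$columns)
  residues <- character(length(labels))
  provenance <- character(length(labels))
  for (i in seq_along(labels)) {
    col <- anchor_cols[anchor$columns[i] + 1L]
    ch <- qc[col]
    if (ch == "-") {
      residues[i] <- NA_character_
      provenance[i] <- "gap"
    } else {
      residues[i] <- ch
      provenance[i] <- as.character(query_index[col])
    }
  }
  names(residues) <- labels
  names(provenance) <- labels
  triplet <- function(group) {
    r <- residues[paste0(group, 1:3)]
    if (anyNA(r)) NA_character_ else paste(r, collapse = "")
  }
  structure(list(
    query_id = alignment$query_id,
    npa_lb = triplet("NPA_LB"),
    npa_le = triplet("NPA_LE"),
    arr = residues[c("H2", "H5", "LE1", "LE2")],
    froger = residues[paste0("P", 1:5)],
    sdp = residues[paste0("SDP", 1:9)],
    provenance = provenance), class = "aqp_profile")
}

#' @export
print.aqp_profile <- function(x, ...) {
  cat("Residue profile for", x$query_id, "\n",
      " NPA:", x$npa_lb, "/", x$npa_le, "\n",
      " ar/R:", paste(x$arr, collapse = "-"), "\n",
      " Froger:", paste(x$froger, collapse = "-"), "\n",
      " SDP:", paste(x$sdp, collapse = "-"), "\n")
  invisible(x)
}

#' Cross-check alignment-derived NPA triplets against motif-scan hits
#'
#' Verifies that each NPA triplet read off the anchor alignment is also found
#' by the direct motif scan at the same query position; disagreement flags
#' the corresponding loop.
#'
#' @param profile `aqp_profile` for a query.
#' @param npa_hits data.frame from [scan_npa_motifs()] on the same query.
#' @return Character vector of flags (`"NPA_LB"`, `"NPA_LE"`); empty when
#'   consistent.
#' @export
cross_check_npa <- function(profile, npa_hits) {
  flags <- character()
  for (loop in c("LB", "LE")) {
    triplet <- profile[[paste0("npa_", tolower(loop))]]
    if (is.na(triplet)) next
    pos <- profile$provenance[[paste0("NPA_", loop, "1")]]
    ok <- pos != "gap" &&
      any(npa_hits$position == as.integer(pos) & npa_hits$triplet == triplet)
    if (!ok) flags <- c(flags, paste0("NPA_", loop))
  }
  flags
}

#' Tabulate residue profiles
#'
#' Flattens a list of profiles into the familiar per-gene residue table
#' (NPA_LB, NPA_LE, H2, H5, LE1, LE2, P1-P5, SDP1-SDP9).
#'
#' @param profiles list of `aqp_profile` objects.
#' @return data.frame with one row per profile.
#' @export
profile_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    data.frame(query_id = p$query_id, npa_lb = p$npa_lb, npa_le = p$npa_le,
               t(p$arr), t(setNames(p$froger, paste0("P", 1:5))),
               t(setNames(p$sdp, paste0("SDP", 1:9))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
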