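# The annotated anchor: a PIP2-type aquaporin sequence with hand-annotated
# diagnostic columns. Candidate profiles are read off a global alignment to
# this anchor, so the sidecar's column map is the normative definition of all
# diagnostic positions (NPA loops, ar/R filter, Froger P1-P5, urea-type
# SDP1-SDP9). The packaged anchor is a constructed (synthetic) sequence laid
# out on the canonical six-transmembrane hourglass topology; any annotated
# anchor with the same label set may be substituted.

ANCHOR_LABELS <- c(paste0("NPA_LB", 1:3), paste0("NPA_LE", 1:3),
                   "H2", "H5", "LE1", "LE2", paste0("P", 1:5),
                   paste0("SDP", 1:9))

# Hydrophobic alphabet used for transmembrane blocks; hydrophilic alphabet for
# loops and termini. Loops deliberately exclude N and P so that the only
# NPA-like motifs in the anchor are the two planted ones.
TM_ALPHABET   <- c("A", "I", "L", "V", "F", "M")
LOOP_ALPHABET <- c("G", "S", "T", "D", "E", "Q", "K", "R", "H", "Y")

#' Construct the synthetic PIP2-type anchor
#'
#' Deterministically builds the packaged anchor: six 25-residue hydrophobic
#' transmembrane blocks joined by hydrophilic loops, with NPA motifs planted
#' on loops B and E and all diagnostic columns set to the canonical PIP2
#' values (ar/R F-H-T-R, Froger Q-S-A-F-W, urea-type SDPs H-P-F-L-L-P-G-G-N).
#'
#' @return A list with `anchor_id`, `sequence`, `columns` (named 0-based
#'   residue indices for every diagnostic label) and `tm_blocks` (0-based
#'   half-open intervals of the planted transmembrane blocks).
#' @export
build_anchor <- function() {
  segs <- c(
    nterm = "MSKEEDVRGEYGHQSTDKGE",
    tm1   = "ILVFILVFLIVFLIVLFIVLFIVLI",
    loopA = "GDRSTGGEHKQDSTAGHE",
    tm2   = "LIVFLIVFILVFLFIVLIVFLIVFL",
    loopB = "TSGKEGDSNPAGGSTHETSGKE",
    tm3   = "VLIFVLIFLVIFLIVFLVIFLIVFL",
    loopC = "GDSTEKHGQSTDGEHKGS",
    tm4   = "ILVFILFVLIVFLIVFILVFLIVLF",
    loopD = "GERSTDGKHSTE",
    tm5   = "FLIVFLIVFLIVFLIVFLIVFLIVF",
    loopE = "GDSNPAGTGRSGSQSAGESTKDGEHSTGKE",
    tm6   = "VLIFVLIFVLIFLIVFLIVFLIVFI",
    cterm = "GSDFEWKSTEGDHKETSG")
  lens <- nchar(segs)
  offset <- setNames(cumsum(c(0, lens[-length(lens)])), names(segs))
  at <- function(seg, k) unname(offset[seg] + k)   # 0-based index into anchor
  columns <- c(
    NPA_LB1 = at("loopB", 8), NPA_LB2 = at("loopB", 9), NPA_LB3 = at("loopB", 10),
    NPA_LE1 = at("loopE", 3), NPA_LE2 = at("loopE", 4), NPA_LE3 = at("loopE", 5),
    H2  = at("tm2", 12), H5 = at("tm5", 12),
    LE1 = at("loopE", 7), LE2 = at("loopE", 9),
    P1 = at("loopC", 8), P2 = at("loopE", 12), P3 = at("loopE", 15),
    P4 = at("cterm", 3), P5 = at("cterm", 5),
    SDP1 = at("loopA", 4), SDP2 = at("loopA", 8), SDP3 = at("loopB", 2),
    SDP4 = at("loopB", 15), SDP5 = at("loopC", 3), SDP6 = at("loopC", 12),
    SDP7 = at("loopD", 4), SDP8 = at("loopE", 18), SDP9 = at("loopE", 22))
  columns <- setNames(as.integer(columns), names(columns))
  seq_chars <- strsplit(paste(segs, collapse = ""), "")[[1]]
  planted <- c(NPA_LB1 = "N", NPA_LB2 = "P", NPA_LB3 = "A",
               NPA_LE1 = "N", NPA_LE2 = "P", NPA_LE3 = "A",
               H2 = "F", H5 = "H", LE1 = "T", LE2 = "R",
               P1 = "Q", P2 = "S", P3 = "A", P4 = "F", P5 = "W",
               SDP1 = "H", SDP2 = "P", SDP3 = "F", SDP4 = "L", SDP5 = "L",
               SDP6 = "P", SDP7 = "G", SDP8 = "G", SDP9 = "N")
  seq_chars[columns[names(planted)] + 1L] <- planted
  sequence <- paste(seq_chars, collapse = "")

  tm_names <- paste0("tm", 1:6)
  tm_blocks <- cbind(start = unname(offset[tm_names]),
                     end   = unname(offset[tm_names] + lens[tm_names]))
  storage.mode(tm_blocks) <- "integer"

  anchor <- list(anchor_id = "PIP2_anchor_synthetic",
                 sequence = sequence,
                 columns = columns,
                 tm_blocks = tm_blocks)
  stopifnot(nrow(scan_npa_motifs(sequence)) == 2L,
            !anyDuplicated(names(columns)),
            all(columns < nchar(sequence)))
  anchor
}

#' Write an anchor to FASTA plus JSON sidecar
#'
#' @param anchor anchor list as returned by [build_anchor()] or [load_anchor()].
#' @param fasta_path,sidecar_path output file paths.
#' @export
write_anchor <- function(anchor, fasta_path, sidecar_path) {
  seqs <- AAStringSet(setNames(anchor$sequence, anchor$anchor_id))
  writeXStringSet(seqs, fasta_path)
  write_json(list(anchor_id = anchor$anchor_id,
                  columns = as.list(anchor$columns)),
             sidecar_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(fasta_path)
}

#' Load an annotated anchor
#'
#' Reads the anchor sequence (FASTA) and its JSON sidecar mapping every
#' diagnostic label to a 0-based residue index, then validates the
#' annotation: all labels present, all indices inside the sequence, and the
#' loop-B NPA columns strictly before the loop-E NPA columns.
#'
#' @param fasta_path,sidecar_path paths; defaults are the packaged synthetic
#'   PIP2-type anchor.
#' @return Anchor list with `anchor_id`, `sequence`, `columns`.
#' @export
load_anchor <- function(fasta_path = aqp_extdata("anchor_pip2_synthetic.fasta"),
                        sidecar_path = aqp_extdata("anchor_pip2_synthetic_columns.json")) {
  seqs <- readAAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("anchor FASTA must contain exactly one record")
  sidecar <- read_json(sidecar_path, simplifyVector = TRUE)
  columns <- unlist(sidecar$columns)
  absent <- setdiff(ANCHOR_LABELS, names(columns))
  if (length(absent))
    stop("anchor sidecar lacks label(s): ", paste(absent, collapse = ", "))
  columns <- columns[ANCHOR_LABELS]
  sequence <- validate_sequence(as.character(seqs[[1]]), "anchor sequence")
  if (any(columns >= nchar(sequence)) || any(columns < 0))
    stop("anchor sidecar indexes outside the sequence")
  if (max(columns[paste0("NPA_LB", 1:3)]) >= min(columns[paste0("NPA_LE", 1:3)]))
    stop("loop-B NPA columns must precede loop-E NPA columns")
  list(anchor_id = sidecar$anchor_id %||% names(seqs)[1],
       sequence = sequence,
       columns = columns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
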