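# Curated reference tables: the aquaporin catalog, per-gene diagnostic
# residues, substrate SDP patterns and observed SDP residues.

FAMILIES <- c("PIP", "TIP", "NIP", "SIP", "XIP")

# "BvPIP2;3" -> "PIP2" (subgroup) / "PIP" (family); any species prefix before
# the family token is ignored, so the helpers also apply to non-beet names.
gene_subgroup <- function(gene) {
  m <- regmatches(gene, regexec("(PIP|TIP|NIP|SIP|XIP)([0-9]*)", gene))
  vapply(m, function(x) {
    if (length(x) == 0L) NA_character_ else paste0(x[2], x[3])
  }, character(1))
}

gene_family <- function(gene) {
  sub("[0-9]*$", "", gene_subgroup(gene))
}

#' Load the aquaporin catalog
#'
#' Reads a tab-separated catalog of family members (one row per protein or
#' transcript) and validates it. The packaged sugar beet catalog is used when
#' `path` is omitted.
#'
#' @param path TSV file with columns `family`, `gene`, `transcript_tag`,
#'   `gene_code`, `gene_id`, `length`, `mw`, `pi`, `tmh`.
#' @return A `data.frame` with one row per entry plus a `label` column
#'   (gene name with the ASCII-normalized transcript tag appended).
#' @export
load_catalog <- function(path = aqp_extdata("bvaqp_catalog.tsv")) {
  cat <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(transcript_tag = "character"))
  required <- c("family", "gene", "gene_id", "length", "mw", "pi", "tmh")
  missing <- setdiff(required, names(cat))
  if (length(missing))
    stop("catalog lacks required columns: ", paste(missing, collapse = ", "))
  if (!"transcript_tag" %in% names(cat)) cat$transcript_tag <- ""
  cat$transcript_tag[is.na(cat$transcript_tag)] <- ""
  cat$label <- paste0(cat$gene, cat$transcript_tag)
  if (nrow(cat) == 0L) return(cat)
  dup <- cat$label[duplicated(cat$label)]
  if (length(dup))
    stop("duplicate gene name(s) in catalog: ", paste(unique(dup), collapse = ", "))
  pref <- gene_family(cat$gene)
  bad <- !pref %in% FAMILIES
  if (any(bad))
    stop("unparseable family prefix in gene name(s): ",
         paste(cat$gene[bad], collapse = ", "))
  if (any(pref != cat$family))
    stop("family column disagrees with gene-name prefix for: ",
         paste(cat$gene[pref != cat$family], collapse = ", "))
  if (any(cat$length <= 0)) stop("non-positive protein length in catalog")
  if (any(cat$pi <= 0 | cat$pi >= 14)) stop("pI outside (0, 14) in catalog")
  cat
}

#' Per-family tallies of a catalog
#'
#' @param catalog data frame from [load_catalog()].
#' @param level `"transcript"` counts every row; `"gene"` collapses
#'   transcript variants of one gene to a single entry.
#' @return Named integer vector over PIP, TIP, NIP, SIP, XIP.
#' @export
family_tally <- function(catalog, level = c("transcript", "gene")) {
  level <- match.arg(level)
  genes <- if (level == "gene") unique(catalog$gene) else catalog$label
  fam <- if (level == "gene") catalog$family[match(genes, catalog$gene)] else catalog$family
  tab <- table(factor(fam, levels = FAMILIES))
  setNames(as.integer(tab), FAMILIES)
}

# Split a slash-delimited residue set ("F/I/L/T") into a validated vector.
parse_residue_set <- function(cell) {
  res <- strsplit(gsub("\\s", "", cell), "/")[[1]]
  if (!length(res) || any(!res %in% AA_ALPHABET))
    stop("invalid residue set: '", cell, "'")
  res
}

#' Load substrate SDP patterns
#'
#' Each pattern names a substrate and gives nine allowed-residue sets, one per
#' specificity-determining position SDP1-SDP9.
#'
#' @param path TSV with columns `substrate`, `class`, `sdp1`..`sdp9`.
#' @param include_novel also return patterns flagged `novel` (single-position
#'   family-specific variants); by default only the six typical patterns.
#' @return List of patterns; each is a list with `substrate`, `class` and
#'   `allowed` (list of nine residue-set vectors).
#' @export
load_patterns <- function(path = aqp_extdata("substrate_patterns.tsv"),
                          include_novel = FALSE) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sdp_cols <- paste0("sdp", 1:9)
  if (!all(sdp_cols %in% names(tab)))
    stop("pattern table must have nine positions (columns sdp1..sdp9)")
  if (!include_novel) tab <- tab[tab$class == "typical", , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(i) {
    allowed <- lapply(sdp_cols, function(col) parse_residue_set(tab[[col]][i]))
    if (length(allowed) != 9L) stop("pattern must have exactly nine positions")
    list(substrate = tab$substrate[i], class = tab$class[i], allowed = allowed)
  })
}

#' Load observed per-protein SDP residues
#'
#' The curated table of SDP residues printed per protein under each substrate
#' heading. Positions are substrate-specific, so one protein may appear under
#' several substrates with different residues.
#'
#' @param path TSV with columns `substrate`, `label`, `sdp1`..`sdp9`.
#' @return data.frame, one row per (substrate, protein) observation.
#' @export
load_sdp_observations <- function(path = aqp_extdata("sdp_observations.tsv")) {
  obs <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sdp_cols <- paste0("sdp", 1:9)
  if (!all(c("substrate", "label", sdp_cols) %in% names(obs)))
    stop("observation table lacks required columns")
  for (col in sdp_cols) {
    bad <- !obs[[col]] %in% AA_ALPHABET
    if (any(bad))
      stop("invalid residue in observation table: ",
           paste(obs[[col]][bad], collapse = ", "))
  }
  obs
}

#' Serialize a catalog back to TSV
#'
#' Inverse of [load_catalog()]; loading the written file reproduces the
#' catalog (round-trip identity).
#'
#' @param catalog data frame from [load_catalog()].
#' @param path output file.
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog[, setdiff(names(catalog), "label"), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the per-gene diagnostic residue table
#'
#' NPA triplets on loops B and E, the ar/R quartet (H2, H5, LE1, LE2) and
#' Froger positions P1-P5 for every catalog member. Cells left blank in the
#' curated source are NA.
#'
#' @param path TSV with columns `label`, `subfamily`, `npa_lb`, `npa_le`,
#'   `h2`, `h5`, `le1`, `le2`, `p1`..`p5`.
#' @return data.frame keyed by `label`.
#' @export
load_residues <- function(path = aqp_extdata("bvaqp_residues.tsv")) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             na.strings = "NA")
}
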