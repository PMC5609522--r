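# Genome context: locus-tag parsing, chromosome distribution, tandem
# duplication detection, exon counts and exon-skipping (alternative splicing)
# detection.

LOCUS_TAG_RE <- "^Bv([1-9])(g|ug|TE)([0-9]{6})_([a-z]{4})\\.t([0-9]+)$"

#' Parse a structured locus tag
#'
#' Locus tags encode chromosome, scaffold status and position rank, e.g.
#' `Bv9g210030_ixem.t1`: chromosome 9, locus number 210030 (numbers step by
#' 10 along the chromosome), four-letter gene code, transcript 1. Scheme
#' flags: `g` placed scaffold, `ug` unplaced-in-chromosome scaffold (flag
#' `u`), `TE` transposable-element-associated annotation.
#'
#' @param raw locus tag string.
#' @return A `locus_tag` list: `raw`, `chromosome` (integer), `scaffold_flags`
#'   (subset of `"u"`, `"TE"`), `locus_number`, `short_code`,
#'   `transcript_index`, `scheme` (the literal tag scheme).
#' @export
parse_locus_tag <- function(raw) {
  m <- regmatches(raw, regexec(LOCUS_TAG_RE, raw))[[1]]
  if (length(m) == 0L)
    stop("unparseable locus tag: '", raw, "'")
  scheme <- m[3]
  flags <- switch(scheme, g = character(), ug = "u", TE = "TE")
  structure(list(raw = raw,
                 chromosome = as.integer(m[2]),
                 scaffold_flags = flags,
                 locus_number = as.integer(m[4]),
                 short_code = m[5],
                 transcript_index = as.integer(m[6]),
                 scheme = scheme),
            class = "locus_tag")
}

#' Re-render a parsed locus tag
#'
#' Inverse of [parse_locus_tag()]: rendering a parsed tag reproduces the raw
#' string.
#'
#' @param tag `locus_tag` list.
#' @return The locus tag string.
#' @export
render_locus_tag <- function(tag) {
  sprintf("Bv%d%s%06d_%s.t%d", tag$chromosome, tag$scheme,
          tag$locus_number, tag$short_code, tag$transcript_index)
}

#' Chromosome distribution of a catalog
#'
#' @param catalog data frame from [load_catalog()] (needs a `gene_id`
#'   column of parseable locus tags).
#' @return Named integer vector of counts for chromosomes 1-9 (zeros
#'   included).
#' @export
chromosome_distribution <- function(catalog) {
  counts <- setNames(integer(9), paste0("chr", 1:9))
  if (nrow(catalog) == 0L) return(counts)
  chrs <- vapply(catalog$gene_id, function(id)
    parse_locus_tag(id)$chromosome, integer(1))
  tab <- table(factor(chrs, levels = 1:9))
  setNames(as.integer(tab), paste0("chr", 1:9))
}

#' Detect tandem-duplicated gene pairs
#'
#' Two catalog members form a high-confidence tandem pair when they share
#' chromosome and subgroup, their locus tags use the same scheme, and their
#' locus numbers differ by at most `max_gap` numbering steps (tags step by
#' 10). Same-subgroup same-chromosome pairs whose tags use different schemes
#' (so locus numbers are not comparable) are reported as low-confidence
#' candidates rather than dropped. Transcript variants of one gene (same gene
#' name) are never paired.
#'
#' @param catalog data frame from [load_catalog()].
#' @param max_gap maximum separation in locus-number steps.
#' @return data.frame: `gene_a`, `gene_b` (alphabetical), `chromosome`,
#'   `separation` (steps; NA for low-confidence pairs), `confidence`.
#' @export
find_tandem_pairs <- function(catalog, max_gap = 2L) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      chromosome = integer(), separation = integer(),
                      confidence = character(), stringsAsFactors = FALSE)
  if (nrow(catalog) < 2L) return(empty)
  tags <- lapply(catalog$gene_id, parse_locus_tag)
  sub <- gene_subgroup(catalog$gene)
  rows <- list()
  for (i in seq_len(nrow(catalog) - 1L)) {
    for (j in (i + 1L):nrow(catalog)) {
      if (catalog$gene[i] == catalog$gene[j]) next  # transcripts of one gene
      if (sub[i] != sub[j]) next
      ti <- tags[[i]]; tj <- tags[[j]]
      if (ti$chromosome != tj$chromosome) next
      pair <- sort(c(catalog$label[i], catalog$label[j]))
      if (ti$scheme == tj$scheme) {
        steps <- abs(ti$locus_number - tj$locus_number) / 10
        if (steps <= max_gap)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_a = pair[1], gene_b = pair[2],
            chromosome = ti$chromosome, separation = as.integer(steps),
            confidence = "high", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = pair[1], gene_b = pair[2],
          chromosome = ti$chromosome, separation = NA_integer_,
          confidence = "low", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$chromosome, out$gene_a), , drop = FALSE]
}

#' Read gene models from a GFF3 file
#'
#' Imports gene / mRNA / exon features and assembles per-gene models with
#' transcript exon chains. Coordinates stay 1-based inclusive as in GFF3.
#'
#' @param path GFF3 file.
#' @return Named list of gene models; each has `gene_id`, `chromosome`,
#'   `start`, `end`, `strand` and `transcripts` (named list of exon
#'   data.frames with `start`, `end`, sorted by genomic position).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  models <- list()
  for (k in seq_len(nrow(genes))) {
    gid <- genes$ID[k]
    model <- list(gene_id = gid,
                  chromosome = as.character(genes$seqnames[k]),
                  start = genes$start[k], end = genes$end[k],
                  strand = as.character(genes$strand[k]),
                  transcripts = list())
    tr <- mrnas[vapply(mrnas$Parent, function(p) gid %in% p, logical(1)), ,
                drop = FALSE]
    for (t in seq_len(nrow(tr))) {
      tid <- tr$ID[t]
      ex <- exons[vapply(exons$Parent, function(p) tid %in% p, logical(1)), ,
                  drop = FALSE]
      ex <- ex[order(ex$start), c("start", "end"), drop = FALSE]
      rownames(ex) <- NULL
      if (any(ex$start < model$start | ex$end > model$end))
        stop("exon outside gene bounds in transcript ", tid)
      model$transcripts[[tid]] <- ex
    }
    models[[gid]] <- model
  }
  models
}

#' Exon counts per transcript
#'
#' @param models GFF3 path or gene-model list from [read_gene_models()].
#' @return Named integer vector: exon count per transcript id.
#' @export
exon_counts <- function(models) {
  if (is.character(models)) models <- read_gene_models(models)
  counts <- integer()
  for (model in models)
    for (tid in names(model$transcripts))
      counts[tid] <- nrow(model$transcripts[[tid]])
  counts
}

#' Detect exon-skipping events between transcripts of a gene
#'
#' For each transcript pair, reports an exon-skipping event when one exon
#' chain equals the other with exactly one internal exon removed (shared
#' exons must match coordinates exactly). Distinct chains not related by a
#' single internal-exon removal are reported as kind `"other"`. The skipped
#' exon ordinal is 1-based in the longer chain, counted in transcription
#' order (strand-aware).
#'
#' @param model one gene model from [read_gene_models()].
#' @return data.frame: `gene_id`, `transcript_a` (longer), `transcript_b`,
#'   `kind`, `skipped_exon_index` (NA unless exon skipping).
#' @export
detect_exon_skipping <- function(model) {
  empty <- data.frame(gene_id = character(), transcript_a = character(),
                      transcript_b = character(), kind = character(),
                      skipped_exon_index = integer(), stringsAsFactors = FALSE)
  tids <- names(model$transcripts)
  if (length(tids) < 2L) return(empty)
  rows <- list()
  for (pair in utils::combn(tids, 2, simplify = FALSE)) {
    a <- model$transcripts[[pair[1]]]
    b <- model$transcripts[[pair[2]]]
    if (nrow(a) < nrow(b)) { tmp <- a; a <- b; b <- tmp; pair <- rev(pair) }
    chain_a <- paste(a$start, a$end, sep = "-")
    chain_b <- paste(b$start, b$end, sep = "-")
    if (identical(chain_a, chain_b)) next
    kind <- "other"
    skipped <- NA_integer_
    if (nrow(a) == nrow(b) + 1L && nrow(a) >= 3L) {
      for (k in 2:(nrow(a) - 1L)) {        # internal exons only
        if (identical(chain_a[-k], chain_b)) {
          kind <- "exon_skipping"
          skipped <- if (model$strand == "-") nrow(a) - k + 1L else k
          break
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = model$gene_id, transcript_a = pair[1], transcript_b = pair[2],
      kind = kind, skipped_exon_index = skipped, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
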