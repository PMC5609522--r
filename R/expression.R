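# Expression profiling from an RPKM matrix: log2 heatmap values, stress
# fold-change classes, tissue breadth and pseudogene-candidate flags.

CONDITIONS <- c("control", "salt", "heat")

#' Build a validated expression matrix
#'
#' @param rpkm non-negative numeric matrix, genes in rows, samples in
#'   columns (dimnames required).
#' @param samples data.frame with columns `sample_id`, `organ`, `condition`
#'   (one of control/salt/heat), one row per matrix column.
#' @return An `aqp_expression` list with `rpkm`, `samples`, `genes`.
#' @export
expression_matrix <- function(rpkm, samples) {
  rpkm <- as.matrix(rpkm)
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  if (is.null(rownames(rpkm)) || is.null(colnames(rpkm)))
    stop("rpkm matrix needs gene and sample dimnames")
  required <- c("sample_id", "organ", "condition")
  if (!all(required %in% names(samples)))
    stop("sample metadata needs columns: ", paste(required, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(rpkm)) ||
      nrow(samples) != ncol(rpkm))
    stop("sample metadata does not match matrix columns")
  bad <- setdiff(unique(samples$condition), CONDITIONS)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  samples <- samples[match(colnames(rpkm), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(rpkm = rpkm, samples = samples, genes = rownames(rpkm)),
            class = "aqp_expression")
}

#' Read an RPKM matrix and sample metadata from TSV
#'
#' @param rpkm_path genes x samples TSV, first column gene ids, header row
#'   sample ids.
#' @param meta_path sample metadata TSV (`sample_id`, `organ`, `condition`).
#' @return `aqp_expression` object.
#' @export
read_rpkm <- function(rpkm_path, meta_path) {
  tab <- read.delim(rpkm_path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  rpkm <- as.matrix(tab[, -1, drop = FALSE])
  rownames(rpkm) <- tab[[1]]
  meta <- read.delim(meta_path, comment.char = "#", stringsAsFactors = FALSE)
  expression_matrix(rpkm, meta)
}

#' Heatmap-ready log2 expression values
#'
#' @param em `aqp_expression`.
#' @param pseudocount added before the log (must be positive).
#' @return Matrix of `log2(RPKM + pseudocount)`, gene/sample order preserved.
#' @export
heatmap_matrix <- function(em, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2(em$rpkm + pseudocount)
}

#' Stress-response log2 fold changes
#'
#' Per-gene `log2((treated + p) / (control + p))` with class UP (> 0),
#' DOWN (< 0) or UNCHANGED (0); `strong` flags responses beyond
#' `strong_cut` in absolute value.
#'
#' @param em `aqp_expression`.
#' @param treated_sample,control_sample sample ids.
#' @param pseudocount pseudocount (positive).
#' @param strong_cut absolute log2 fold-change threshold for a strong
#'   response (default 1, i.e. two-fold).
#' @return data.frame: `gene_id`, `condition` (of the treated sample),
#'   `log2fc`, `class`, `strong`.
#' @export
stress_response <- function(em, treated_sample, control_sample,
                            pseudocount = 1, strong_cut = 1) {
  for (s in c(treated_sample, control_sample))
    if (!s %in% colnames(em$rpkm)) stop("sample not in matrix: ", s)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  lfc <- log2((em$rpkm[, treated_sample] + pseudocount) /
              (em$rpkm[, control_sample] + pseudocount))
  cls <- ifelse(lfc > 0, "UP", ifelse(lfc < 0, "DOWN", "UNCHANGED"))
  cond <- em$samples$condition[em$samples$sample_id == treated_sample]
  data.frame(gene_id = em$genes, condition = cond, log2fc = unname(lfc),
             class = unname(cls), strong = unname(abs(lfc) > strong_cut),
             stringsAsFactors = FALSE)
}

#' Expression breadth across organs
#'
#' Counts, for each gene, the organs (control condition) in which it is
#' detected at or above `detect_floor`. A gene below the floor in every
#' sample of the matrix (any condition) is flagged silent — a pseudogene
#' candidate; detection in exactly one organ flags organ-specific
#' expression.
#'
#' @param em `aqp_expression`.
#' @param detect_floor RPKM detection threshold (>= 0).
#' @return data.frame: `gene_id`, `n_organs`, `detected_organs`
#'   (comma-joined), `expressed_everywhere`, `organ_specific`, `silent`.
#' @export
expression_breadth <- function(em, detect_floor = 1) {
  if (detect_floor < 0) stop("detect_floor must be >= 0")
  ctrl <- em$samples$sample_id[em$samples$condition == "control"]
  organs <- unique(em$samples$organ[em$samples$condition == "control"])
  detected <- sapply(organs, function(org) {
    ids <- intersect(ctrl, em$samples$sample_id[em$samples$organ == org])
    apply(em$rpkm[, ids, drop = FALSE] >= detect_floor, 1, any)
  })
  if (is.null(dim(detected))) detected <- matrix(detected, nrow = 1)
  n_organs <- rowSums(detected)
  data.frame(
    gene_id = em$genes,
    n_organs = as.integer(n_organs),
    detected_organs = apply(detected, 1, function(z)
      paste(sort(organs[z]), collapse = ",")),
    expressed_everywhere = n_organs == length(organs),
    organ_specific = n_organs == 1L,
    silent = apply(em$rpkm < detect_floor, 1, all),
    stringsAsFactors = FALSE)
}
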