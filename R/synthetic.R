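# Deterministic synthetic-data generator: planted-residue aquaporin
# proteomes with decoys, gene annotations with tandem pairs and a
# skipped-exon transcript pair, and RPKM matrices with planted response
# classes. Every output is a pure function of its seed; ground truth is
# returned alongside the data.

SUBGROUPS <- c("PIP1", "PIP2", "TIP1", "TIP2", "TIP3", "TIP4", "TIP5",
               "NIP1", "NIP4", "NIP5", "NIP6", "NIP7",
               "SIP1", "SIP2", "XIP1")

# internal seed for scaffold construction (scaffolds are fixed constants,
# independent of the user-facing seed)
.SCAFFOLD_SEED <- 20170919L

# Representative catalog member whose diagnostic residues are planted into
# each subgroup scaffold.
subgroup_representative <- function(subgroup) {
  reps <- c(PIP1 = "BvPIP1;1", PIP2 = "BvPIP2;1", TIP1 = "BvTIP1;1",
            TIP2 = "BvTIP2;1", TIP3 = "BvTIP3;1", TIP4 = "BvTIP4;1",
            TIP5 = "BvTIP5;1", NIP1 = "BvNIP1;1", NIP4 = "BvNIP4;1",
            NIP5 = "BvNIP5;1", NIP6 = "BvNIP6;1", NIP7 = "BvNIP7;1",
            SIP1 = "BvSIP1;1alpha", SIP2 = "BvSIP2;1", XIP1 = "BvXIP1;1")
  unname(reps[subgroup])
}

# The 24-residue planting vector (anchor column labels -> residues) for a
# subgroup: NPA/arR/Froger from the curated residue table, SDPs from the
# curated observations (urea preferred, then H2O2/boric/NH3; anchor defaults
# where the subgroup has no printed SDP row).
subgroup_planting <- function(subgroup,
                              residues = load_residues(),
                              observations = load_sdp_observations(),
                              anchor = build_anchor()) {
  label <- subgroup_representative(subgroup)
  row <- residues[residues$label == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("no residue row for ", label)
  froger <- unlist(row[paste0("p", 1:5)])
  if (anyNA(froger)) stop("representative row has missing Froger positions")
  sdp <- NULL
  for (substrate in c("urea", "H2O2", "boric_acid", "NH3")) {
    hit <- observations[observations$substrate == substrate &
                          observations$label == label, , drop = FALSE]
    if (nrow(hit) == 1L) {
      sdp <- unlist(hit[paste0("sdp", 1:9)])
      break
    }
  }
  if (is.null(sdp)) {
    seq_chars <- strsplit(anchor$sequence, "")[[1]]
    sdp <- seq_chars[anchor$columns[paste0("SDP", 1:9)] + 1L]
  }
  plant <- c(strsplit(row$npa_lb, "")[[1]], strsplit(row$npa_le, "")[[1]],
             row$h2, row$h5, row$le1, row$le2, froger, sdp)
  setNames(as.character(plant), ANCHOR_LABELS)
}

# Substitute a fraction of non-diagnostic positions. Transmembrane positions
# stay within the hydrophobic alphabet so topology is preserved; loop
# positions stay within the N/P-free hydrophilic alphabet so no spurious NPA
# motifs arise. Uses the current RNG state.
mutate_positions <- function(chars, rate, anchor) {
  n <- length(chars)
  in_tm <- logical(n)
  for (b in seq_len(nrow(anchor$tm_blocks)))
    in_tm[(anchor$tm_blocks[b, "start"] + 1L):anchor$tm_blocks[b, "end"]] <- TRUE
  mutable <- setdiff(seq_len(n), anchor$columns + 1L)
  hit <- mutable[runif(length(mutable)) < rate]
  for (i in hit) {
    pool <- if (in_tm[i]) TM_ALPHABET else LOOP_ALPHABET
    chars[i] <- sample(setdiff(pool, chars[i]), 1)
  }
  chars
}

#' Subgroup scaffold sequences
#'
#' One synthetic consensus-like sequence per subfamily subgroup, built by
#' diverging the anchor at 15% of its non-diagnostic positions (fixed
#' internal seed) and planting the subgroup's curated diagnostic residues.
#' Scaffolds serve as the labeled reference panel for screening and
#' classification and as the parents of planted proteome sequences.
#'
#' @param anchor anchor list ([build_anchor()] by default so scaffolds do not
#'   depend on installed data files).
#' @return List with `sequences` (named character vector, one per subgroup),
#'   `plantings` (per-subgroup diagnostic residue vectors), `tm_blocks`, and
#'   `panel` (data.frame id/family/subgroup/name for classifier use).
#' @export
subgroup_scaffolds <- function(anchor = build_anchor()) {
  residues <- load_residues()
  observations <- load_sdp_observations()
  seqs <- character()
  plantings <- list()
  for (k in seq_along(SUBGROUPS)) {
    sg <- SUBGROUPS[k]
    plant <- subgroup_planting(sg, residues, observations, anchor)
    chars <- strsplit(anchor$sequence, "")[[1]]
    chars <- withr::with_seed(.SCAFFOLD_SEED + k,
                              mutate_positions(chars, 0.15, anchor))
    chars[anchor$columns + 1L] <- plant[names(anchor$columns)]
    seqs[paste0("REF_", sg)] <- paste(chars, collapse = "")
    plantings[[sg]] <- plant
  }
  list(sequences = seqs, plantings = plantings, tm_blocks = anchor$tm_blocks,
       panel = data.frame(id = names(seqs),
                          family = sub("[0-9]+$", "", SUBGROUPS),
                          subgroup = SUBGROUPS,
                          name = vapply(SUBGROUPS, subgroup_representative,
                                        character(1)),
                          stringsAsFactors = FALSE))
}

# planting vector -> profile-shaped ground truth
planting_to_profile <- function(plant) {
  list(npa_lb = paste(plant[paste0("NPA_LB", 1:3)], collapse = ""),
       npa_le = paste(plant[paste0("NPA_LE", 1:3)], collapse = ""),
       arr = plant[c("H2", "H5", "LE1", "LE2")],
       froger = plant[paste0("P", 1:5)],
       sdp = plant[paste0("SDP", 1:9)])
}

#' Generate a synthetic proteome with planted aquaporins and decoys
#'
#' Planted aquaporins are subgroup scaffolds mutated everywhere except the
#' diagnostic columns; decoys are random sequences scrubbed of NPA-like
#' motifs (so they cannot satisfy the dual-NPA screen). Output is
#' bit-for-bit reproducible under a fixed seed.
#'
#' @param n_aqp,n_decoy counts of planted aquaporins and decoys.
#' @param mutation_rate per-position substitution probability outside the
#'   diagnostic columns (0 to 0.2).
#' @param seed RNG seed (required).
#' @return List with `proteome` (`AAStringSet`) and `truth`: `planted_aqps`
#'   (per id: subgroup, profile, tm_intervals), `decoys` (ids), `scaffolds`.
#' @export
make_proteome <- function(n_aqp = 10L, n_decoy = 40L, mutation_rate = 0.05,
                          seed) {
  if (missing(seed)) stop("seed is required")
  if (mutation_rate < 0 || mutation_rate > 0.2)
    stop("mutation_rate must be in [0, 0.2]")
  anchor <- build_anchor()
  scaf <- subgroup_scaffolds(anchor)
  withr::with_seed(seed, {
    planted <- list()
    seqs <- character()
    for (i in seq_len(n_aqp)) {
      sg <- SUBGROUPS[(i - 1L) %% length(SUBGROUPS) + 1L]
      id <- sprintf("AQP%03d_%s", i, sg)
      chars <- strsplit(scaf$sequences[paste0("REF_", sg)], "")[[1]]
      chars <- mutate_positions(chars, mutation_rate, anchor)
      seqs[id] <- paste(chars, collapse = "")
      planted[[id]] <- list(subgroup = sg,
                            profile = planting_to_profile(scaf$plantings[[sg]]),
                            tm_intervals = scaf$tm_blocks)
    }
    decoys <- character()
    for (i in seq_len(n_decoy)) {
      id <- sprintf("DECOY%03d", i)
      len <- sample(180:350, 1)
      chars <- sample(AA_ALPHABET, len, replace = TRUE)
      s <- scrub_npa(paste(chars, collapse = ""))
      decoys[id] <- s
      seqs[id] <- s
    }
    list(proteome = AAStringSet(seqs),
         truth = list(planted_aqps = planted, decoys = names(decoys),
                      scaffolds = scaf))
  })
}

# Remove all NPA-like motifs from a sequence (decoy post-processing).
scrub_npa <- function(sequence) {
  repeat {
    hits <- scan_npa_motifs(sequence)
    if (nrow(hits) == 0L) return(sequence)
    substr(sequence, hits$position[1] + 2L, hits$position[1] + 2L) <- "G"
  }
}

#' Generate a synthetic gene annotation (GFF3) with planted genome context
#'
#' Seven genes following the subfamily exon-count conventions (PIP 4 exons,
#' TIP 3, NIP 5, SIP 3, XIP 2), two tandem pairs at adjacent locus numbers,
#' and one gene carrying a transcript pair in which the second exon is
#' skipped.
#'
#' @param seed RNG seed (required).
#' @return List with `gff` (character vector of GFF3 lines), `catalog`
#'   (mini catalog data.frame for context analyses) and `truth`
#'   (`tandem_pairs`, `splicing_events`, `exon_convention`).
#' @export
make_annotation <- function(seed) {
  if (missing(seed)) stop("seed is required")
  spec <- data.frame(
    gene = c("SynPIP2;1", "SynPIP2;2", "SynNIP4;1", "SynNIP4;2",
             "SynTIP1;1", "SynSIP1;1", "SynXIP1;1"),
    family = c("PIP", "PIP", "NIP", "NIP", "TIP", "SIP", "XIP"),
    chromosome = c(9L, 9L, 2L, 2L, 7L, 2L, 9L),
    locus = c(210020L, 210030L, 27660L, 27680L, 176430L, 35790L, 217040L),
    strand = c("+", "+", "-", "-", "+", "+", "-"),
    n_exons = c(4L, 4L, 5L, 5L, 3L, 3L, 2L),
    stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    codes <- replicate(nrow(spec),
                       paste(sample(letters, 4, replace = TRUE), collapse = ""))
    gff <- "##gff-version 3"
    catalog <- list()
    skip_gene <- NULL
    for (k in seq_len(nrow(spec))) {
      base <- sprintf("Bv%dg%06d_%s", spec$chromosome[k], spec$locus[k],
                      codes[k])
      chrom <- paste0("chr", spec$chromosome[k])
      exon_len <- sample(120:400, spec$n_exons[k], replace = TRUE)
      intron_len <- if (spec$n_exons[k] > 1)
        sample(80:300, spec$n_exons[k] - 1L, replace = TRUE) else integer()
      start <- spec$locus[k] * 50L + sample(0:40, 1)
      starts <- start + cumsum(c(0L, head(exon_len, -1) + intron_len))
      ends <- starts + exon_len - 1L
      gid <- base
      t1 <- paste0(base, ".t1")
      feat <- function(type, s, e, id, parent = NULL) {
        attrs <- paste0("ID=", id)
        if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
        paste(chrom, "aqpkit", type, s, e, ".", spec$strand[k], ".", attrs,
              sep = "\t")
      }
      gff <- c(gff, feat("gene", starts[1], ends[length(ends)], gid),
               feat("mRNA", starts[1], ends[length(ends)], t1, gid))
      for (e in seq_along(starts))
        gff <- c(gff, feat("exon", starts[e], ends[e],
                           paste0(t1, ".exon", e), t1))
      if (spec$gene[k] == "SynSIP1;1") {
        # second transcript skipping the internal second exon
        t2 <- paste0(base, ".t2")
        gff <- c(gff, feat("mRNA", starts[1], ends[length(ends)], t2, gid))
        for (e in c(1L, 3L))
          gff <- c(gff, feat("exon", starts[e], ends[e],
                             paste0(t2, ".exon", e), t2))
        skip_gene <- gid
      }
      catalog[[k]] <- data.frame(
        family = spec$family[k], gene = spec$gene[k], transcript_tag = "",
        gene_code = codes[k], gene_id = t1, length = 250L, mw = 27,
        pi = 7, tmh = 6L, label = spec$gene[k], stringsAsFactors = FALSE)
    }
    truth <- list(
      tandem_pairs = data.frame(
        gene_a = c("SynNIP4;1", "SynPIP2;1"),
        gene_b = c("SynNIP4;2", "SynPIP2;2"),
        stringsAsFactors = FALSE),
      splicing_events = data.frame(
        gene_id = skip_gene,
        transcript_a = paste0(skip_gene, ".t1"),
        transcript_b = paste0(skip_gene, ".t2"),
        kind = "exon_skipping", skipped_exon_index = 2L,
        stringsAsFactors = FALSE),
      exon_convention = setNames(spec$n_exons, spec$gene))
    list(gff = gff, catalog = do.call(rbind, catalog), truth = truth)
  })
}

#' Generate a synthetic RPKM matrix with planted response classes
#'
#' Baseline expression is log-normal; one gene is silent in every sample
#' (pseudogene-like), one is expressed in a single organ, and the remaining
#' genes cycle through salt/heat response classes with 4-fold (strong) or
#' 1.5-fold (weak) effects. Noise is multiplicative log-normal with standard
#' deviation `sigma` on the log scale.
#'
#' @param n_genes number of genes.
#' @param organs organ panel (one control sample each); stress samples
#'   `leaf_salt` and `leaf_heat` are added against the `leaf` control.
#' @param seed RNG seed (required).
#' @param sigma multiplicative noise (log-scale sd; 0 gives exact fold
#'   changes).
#' @param strong_fc,weak_fc planted fold changes.
#' @return List with `em` (`aqp_expression`) and `truth` (data.frame
#'   `gene_id`, `label`).
#' @export
make_expression <- function(n_genes = 28L,
                            organs = c("seedling", "root", "leaf",
                                       "inflorescence", "seed"),
                            seed, sigma = 0.1,
                            strong_fc = 4, weak_fc = 1.5) {
  if (missing(seed)) stop("seed is required")
  stopifnot("leaf" %in% organs, n_genes >= 3L)
  classes <- c("up_salt_strong", "down_salt_strong",
               "up_heat_strong", "down_heat_strong",
               "up_salt_weak", "down_salt_weak", "flat")
  labels <- c("silent", "organ_specific",
              classes[(seq_len(n_genes - 2L) - 1L) %% length(classes) + 1L])
  genes <- sprintf("gene%03d", seq_len(n_genes))
  specific_organ <- if ("inflorescence" %in% organs) "inflorescence" else
    setdiff(organs, "leaf")[1]
  samples <- data.frame(
    sample_id = c(organs, "leaf_salt", "leaf_heat"),
    organ = c(organs, "leaf", "leaf"),
    condition = c(rep("control", length(organs)), "salt", "heat"),
    stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    baseline <- rlnorm(n_genes, meanlog = log(30), sdlog = 0.4)
    noise <- function(n) if (sigma == 0) rep(1, n) else rlnorm(n, 0, sigma)
    rpkm <- matrix(0, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
    for (g in seq_len(n_genes)) {
      lab <- labels[g]
      if (lab == "silent") next
      base_by_sample <- rep(baseline[g], nrow(samples))
      if (lab == "organ_specific")
        base_by_sample[samples$organ != specific_organ] <- 0
      fc <- rep(1, nrow(samples))
      fc[samples$sample_id == "leaf_salt"] <- switch(
        lab, up_salt_strong = strong_fc, down_salt_strong = 1 / strong_fc,
        up_salt_weak = weak_fc, down_salt_weak = 1 / weak_fc, 1)
      fc[samples$sample_id == "leaf_heat"] <- switch(
        lab, up_heat_strong = strong_fc, down_heat_strong = 1 / strong_fc, 1)
      vals <- base_by_sample * fc * noise(nrow(samples))
      rpkm[g, ] <- ifelse(base_by_sample == 0, 0, vals)
    }
    list(em = expression_matrix(rpkm, samples),
         truth = data.frame(gene_id = genes, label = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Write an expression matrix and its sample metadata to TSV
#'
#' @param em `aqp_expression`.
#' @param rpkm_path,meta_path output files (readable by [read_rpkm()]).
#' @export
write_expression <- function(em, rpkm_path, meta_path) {
  tab <- data.frame(gene_id = em$genes, em$rpkm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, rpkm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(rpkm_path)
}
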