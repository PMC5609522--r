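# Distance-based subfamily classification: pairwise-identity distance matrix,
# in-house neighbor-joining, clade-based subfamily assignment and column
# bootstrap.

#' Pairwise distance matrix from sequences
#'
#' Distances are 1 minus global-alignment identity (simple p-distance over
#' alignment columns, no substitution-model correction).
#'
#' @param records named character vector or `AAStringSet` of sequences.
#' @param params alignment scoring parameters ([align_params()]).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
build_distance_matrix <- function(records, params = align_params()) {
  seqs <- as_sequences(records)
  if (length(seqs) < 2L) stop("need at least two records")
  if (anyDuplicated(names(seqs)))
    stop("duplicate ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    ident <- align_identities(seqs[[i]], seqs[(i + 1):n], params)
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- 1 - ident
  }
  d
}

#' Neighbor-joining tree
#'
#' Classical neighbor-joining agglomeration. Ties on the Q-criterion are
#' broken by the lowest (i, j) index pair, making the output deterministic;
#' negative branch lengths are clamped to zero.
#'
#' @param dm symmetric distance matrix with dimnames (taxon ids).
#' @return Unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm) ||
      !isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3L) stop("need at least three taxa")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  # newick fragment per active node
  frag <- ids
  d <- dm
  bl <- function(x) sprintf("%.10g", max(0, x))
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (i, j), i < j, among minima
    best <- which(q == min(q[upper.tri(q)]), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(vi), frag[j], bl(vj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    d <- d2
  }
  d12 <- d[1, 2]; d13 <- d[1, 3]; d23 <- d[2, 3]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1], bl(b1), frag[2], bl(b2), frag[3], bl(b3))
  read.tree(text = newick)
}

# All non-trivial bipartitions of an unrooted tree, canonicalized as the
# sorted tip set on the side NOT containing the alphabetically first tip.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  ref <- sort(tips)[1]
  desc <- descendant_tips(tree)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(ntip))
  splits <- lapply(internal, function(node) {
    side <- desc[[node]]
    if (ref %in% side) side <- setdiff(tips, side)
    sort(side)
  })
  splits <- splits[vapply(splits, function(s)
    length(s) >= 2 && length(s) <= ntip - 2, logical(1))]
  unique(splits)
}

# tip labels descending from every node (index = node number)
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(nnode)))
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  root <- ntip + 1L
  # iterative post-order: resolve a node once all children are resolved
  stack <- root
  while (length(stack)) {
    node <- stack[length(stack)]
    ch <- children[[node]]
    unresolved <- ch[vapply(ch, function(x) is.null(desc[[x]]), logical(1))]
    if (length(unresolved)) {
      stack <- c(stack, unresolved)
    } else {
      desc[[node]] <- unlist(desc[ch], use.names = FALSE)
      stack <- stack[-length(stack)]
    }
  }
  desc
}

#' Assign a query to a subfamily from its tree placement
#'
#' The query's family/subgroup is the unanimous label of its smallest
#' enclosing clade that contains reference taxa; if that clade is mixed, the
#' nearest reference (smallest distance) decides and the method is recorded
#' as `"nearest_ref"`. The proposed name numbers the query after the
#' subgroup's existing members.
#'
#' @param query_id tip id of the query in `tree` and `dm`.
#' @param tree `phylo` tree containing the query and the panel.
#' @param refs labeled panel: data.frame with columns `id`, `subgroup` and
#'   optionally `name` (existing gene names used for numbering).
#' @param dm distance matrix over the same ids.
#' @param prefix species prefix used in the proposed name.
#' @return data.frame row: `query_id`, `family`, `subgroup`, `proposed_name`,
#'   `support` (identity to the nearest reference of the assigned subgroup),
#'   `method` (`"nj_clade"` or `"nearest_ref"`).
#' @export
assign_subfamily <- function(query_id, tree, refs, dm, prefix = "Bv") {
  if (nrow(refs) == 0L) stop("reference panel is empty")
  if (!query_id %in% tree$tip.label) stop("query not in tree: ", query_id)
  ref_ids <- refs$id
  sides <- tree_query_sides(tree, query_id)
  sides <- sides[order(vapply(sides, length, integer(1)))]
  subgroup <- NA_character_
  method <- "nearest_ref"
  for (side in sides) {
    present <- intersect(side, ref_ids)
    if (!length(present)) next
    labs <- unique(refs$subgroup[match(present, ref_ids)])
    if (length(labs) == 1L) {
      subgroup <- labs
      method <- "nj_clade"
    }
    break
  }
  if (is.na(subgroup)) {
    dq <- dm[query_id, ref_ids]
    subgroup <- refs$subgroup[which.min(dq)]
  }
  members <- refs[refs$subgroup == subgroup, , drop = FALSE]
  support <- 1 - min(dm[query_id, members$id])
  existing <- if (!is.null(refs$name)) {
    suffix <- sub(paste0("^", prefix, subgroup, ";"), "", members$name)
    suppressWarnings(as.integer(sub("[^0-9].*$", "", suffix)))
  } else integer()
  k <- if (length(existing) && any(!is.na(existing)))
    max(existing, na.rm = TRUE) + 1L else nrow(members) + 1L
  data.frame(query_id = query_id,
             family = sub("[0-9].*$", "", subgroup),
             subgroup = subgroup,
             proposed_name = paste0(prefix, subgroup, ";", k),
             support = support, method = method,
             stringsAsFactors = FALSE)
}

# For a query tip, the "other side" tip sets of every split, i.e. the members
# of each enclosing clade of the query (query excluded).
tree_query_sides <- function(tree, query_id) {
  tips <- tree$tip.label
  desc <- descendant_tips(tree)
  ntip <- length(tips)
  nodes <- setdiff(seq_len(ntip + tree$Nnode), which(tips == query_id))
  sides <- lapply(nodes, function(node) {
    side <- desc[[node]]
    if (!query_id %in% side) side <- setdiff(tips, side)
    setdiff(side, query_id)
  })
  unique(sides[vapply(sides, length, integer(1)) > 0])
}

#' Column-bootstrap support for a neighbor-joining tree
#'
#' Sequences are projected onto the anchor's coordinate system (the residue
#' aligned to each anchor position, or a gap), anchor columns are resampled
#' with replacement, and a neighbor-joining tree is built per replicate from
#' p-distances. Support of each internal edge of the full-data tree is the
#' fraction of replicate trees containing the same bipartition.
#'
#' @param records named sequences (character vector or `AAStringSet`).
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed; the same seed reproduces the supports exactly.
#' @param anchor anchor list used for the column projection.
#' @return List with `tree` (the full-data NJ tree, `node.label` carrying
#'   supports) and `support` (data.frame of splits and support fractions).
#' @export
bootstrap_support <- function(records, replicates = 100L, seed = 1L,
                              anchor = load_anchor()) {
  if (replicates < 1L) stop("replicates must be >= 1")
  seqs <- as_sequences(records)
  mat <- anchor_projection(seqs, anchor)
  ref_tree <- nj_tree(pdist_matrix(mat))
  ref_splits <- tree_splits(ref_tree)
  counts <- numeric(length(ref_splits))
  withr::with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      bt <- nj_tree(pdist_matrix(mat[, cols, drop = FALSE]))
      bs <- tree_splits(bt)
      for (k in seq_along(ref_splits))
        if (any(vapply(bs, identical, logical(1), ref_splits[[k]])))
          counts[k] <- counts[k] + 1
    }
  })
  support <- counts / replicates
  # attach supports as internal node labels of the reference tree
  ref_tree$node.label <- rep("", ref_tree$Nnode)
  desc <- descendant_tips(ref_tree)
  ntip <- length(ref_tree$tip.label)
  ref <- sort(ref_tree$tip.label)[1]
  for (node in (ntip + 1):(ntip + ref_tree$Nnode)) {
    side <- desc[[node]]
    if (ref %in% side) side <- setdiff(ref_tree$tip.label, side)
    side <- sort(side)
    hit <- which(vapply(ref_splits, identical, logical(1), side))
    if (length(hit))
      ref_tree$node.label[node - ntip] <- sprintf("%.3f", support[hit])
  }
  list(tree = ref_tree,
       support = data.frame(
         split = vapply(ref_splits, paste, character(1), collapse = ","),
         support = support, stringsAsFactors = FALSE))
}

# Project sequences onto anchor columns: one row per sequence, one column per
# anchor residue; "-" where nothing aligns.
anchor_projection <- function(seqs, anchor) {
  L <- nchar(anchor$sequence)
  mat <- matrix("-", length(seqs), L,
                dimnames = list(names(seqs), NULL))
  for (id in names(seqs)) {
    al <- global_align(seqs[[id]], anchor, query_id = id)
    ac <- strsplit(al$aligned_anchor, "")[[1]]
    qc <- strsplit(al$aligned_query, "")[[1]]
    mat[id, ] <- qc[ac != "-"]
  }
  mat
}

# p-distance between rows of a residue matrix (gap columns excluded pairwise;
# distance 1 when no column is comparable).
pdist_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 1
    }
  }
  d
}
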