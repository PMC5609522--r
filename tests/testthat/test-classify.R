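test_that("distance matrices are symmetric, zero-diagonal, order-invariant", {
  scaf <- fixture_scaffolds()
  seqs <- scaf$sequences[1:4]
  dm <- build_distance_matrix(seqs)
  expect_true(isSymmetric(dm))
  expect_equal(unname(diag(dm)), rep(0, 4))
  expect_true(all(dm >= 0 & dm <= 1))
  # identical sequences at distance zero
  two <- c(a = seqs[[1]], b = seqs[[1]])
  expect_equal(build_distance_matrix(two)["a", "b"], 0)
  # element-wise recomputation by the alignment route
  al <- global_align(seqs[[2]], seqs[[3]])
  expect_equal(dm[2, 3], 1 - al$identity)
  # permutation invariance
  dm2 <- build_distance_matrix(seqs[c(3, 1, 4, 2)])
  expect_equal(dm2[rownames(dm), colnames(dm)], dm)
  expect_error(build_distance_matrix(setNames(seqs[c(1, 1)], c("x", "x"))),
               "duplicate")
})

test_that("neighbor joining recovers additive trees exactly (n <= 8)", {
  skip_if_not_installed("ape")
  set.seed(42)
  for (n in c(4:8)) {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
    dm <- ape::cophenetic.phylo(tr)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    my <- nj_tree(dm)
    # tree metric equality against the generating tree
    expect_lt(max(abs(ape::cophenetic.phylo(my)[rownames(dm), colnames(dm)] -
                        dm)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr), my), 0,
                 ignore_attr = TRUE)
  }
})

test_that("three-taxon trees solve the closed-form branch lengths", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["a"]], 1)   # (d_ab + d_ac - d_bc) / 2
  expect_equal(bl[["b"]], 2)
  expect_equal(bl[["c"]], 3)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|three")
  asym <- dm; asym[1, 2] <- 9
  expect_error(nj_tree(asym), "symmetric")
})

test_that("star-like equal distances still yield the oracle total length", {
  n <- 5
  dm <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(dm) <- 0
  tr <- nj_tree(dm)
  # any resolution is acceptable; total length must equal the star optimum
  # (every tip at height 1/2, internal edges collapsed)
  expect_equal(sum(tr$edge.length), n / 2, tolerance = 1e-9)
})

test_that("subfamily assignment is exact on planted queries", {
  gen <- make_proteome(n_aqp = 20, n_decoy = 0, mutation_rate = 0.1,
                       seed = 11)
  scaf <- gen$truth$scaffolds
  seqs <- c(as.character(gen$proteome), scaf$sequences)
  dm <- build_distance_matrix(seqs)
  tree <- nj_tree(dm)
  hits <- 0L
  for (id in names(gen$truth$planted_aqps)) {
    asg <- assign_subfamily(id, tree, scaf$panel, dm)
    if (asg$subgroup == gen$truth$planted_aqps[[id]]$subgroup)
      hits <- hits + 1L
    expect_equal(asg$family, sub("[0-9]+$", "", asg$subgroup))
  }
  expect_equal(hits, 20L)
})

test_that("a query identical to a reference gets its subgroup with support 1", {
  scaf <- fixture_scaffolds()
  seqs <- c(QUERY = unname(scaf$sequences[["REF_PIP2"]]),
            scaf$sequences[c("REF_PIP1", "REF_PIP2", "REF_TIP1",
                             "REF_NIP5", "REF_SIP1")])
  dm <- build_distance_matrix(seqs)
  tree <- nj_tree(dm)
  panel <- scaf$panel[scaf$panel$id %in% names(seqs), ]
  asg <- assign_subfamily("QUERY", tree, panel, dm)
  expect_equal(asg$subgroup, "PIP2")
  expect_equal(asg$family, "PIP")
  expect_equal(asg$support, 1.0)
  # the proposed name numbers after the existing subgroup members
  expect_equal(asg$proposed_name, "BvPIP2;2")
  expect_error(assign_subfamily("QUERY", tree, panel[0, ], dm), "empty")
})

test_that("assignment is invariant to reference panel order", {
  gen <- make_proteome(n_aqp = 3, n_decoy = 0, mutation_rate = 0.08,
                       seed = 19)
  scaf <- gen$truth$scaffolds
  seqs <- c(as.character(gen$proteome), scaf$sequences)
  dm <- build_distance_matrix(seqs)
  tree <- nj_tree(dm)
  id <- names(gen$truth$planted_aqps)[1]
  a1 <- assign_subfamily(id, tree, scaf$panel, dm)
  a2 <- assign_subfamily(id, tree,
                         scaf$panel[rev(seq_len(nrow(scaf$panel))), ], dm)
  expect_equal(a1$subgroup, a2$subgroup)
  expect_equal(a1$support, a2$support)
})

test_that("bootstrap supports are reproducible and bounded", {
  anchor <- fixture_anchor()
  base <- anchor$sequence
  set.seed(3)
  loop_cols_a <- setdiff(46:62, anchor$columns + 1)
  loop_cols_b <- setdiff(136:152, anchor$columns + 1)
  mutate_at <- function(cols) {
    ch <- strsplit(base, "")[[1]]
    for (i in cols)
      ch[i] <- sample(setdiff(aqpkit:::LOOP_ALPHABET, ch[i]), 1)
    paste(ch, collapse = "")
  }
  recs <- c(A1 = mutate_at(loop_cols_a), A2 = mutate_at(loop_cols_a),
            A3 = mutate_at(loop_cols_a), B1 = mutate_at(loop_cols_b),
            B2 = mutate_at(loop_cols_b), B3 = mutate_at(loop_cols_b))
  bs <- bootstrap_support(recs, replicates = 100, seed = 5, anchor = anchor)
  # the clean two-clade split is strongly supported
  sep <- bs$support$support[bs$support$split %in% c("A1,A2,A3", "B1,B2,B3")]
  expect_gte(max(sep), 0.95)
  # determinism under the seed
  bs2 <- bootstrap_support(recs, replicates = 100, seed = 5, anchor = anchor)
  expect_identical(bs$support, bs2$support)
  # one replicate gives all-or-nothing supports
  bs1 <- bootstrap_support(recs, replicates = 1, seed = 9, anchor = anchor)
  expect_true(all(bs1$support$support %in% c(0, 1)))
})
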