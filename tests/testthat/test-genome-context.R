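test_that("locus tags parse and re-render exactly", {
  t1 <- parse_locus_tag("Bv9g210030_ixem.t1")
  expect_equal(t1$chromosome, 9L)
  expect_equal(t1$locus_number, 210030L)
  expect_equal(t1$short_code, "ixem")
  expect_equal(t1$transcript_index, 1L)
  expect_length(t1$scaffold_flags, 0L)
  t2 <- parse_locus_tag("Bv7ug180930_kzkq.t1")
  expect_equal(t2$chromosome, 7L)
  expect_equal(t2$scaffold_flags, "u")
  t3 <- parse_locus_tag("Bv6TE021760_gkiq.t1")
  expect_equal(t3$chromosome, 6L)
  expect_equal(t3$scaffold_flags, "TE")
  for (raw in c("Bv9g210030_ixem.t1", "Bv7ug180930_kzkq.t1",
                "Bv6TE021760_gkiq.t1", "Bv1g004510_fpur.t1"))
    expect_identical(render_locus_tag(parse_locus_tag(raw)), raw)
  expect_error(parse_locus_tag("AT1G01620.1"), "AT1G01620")
})

test_that("chromosome distribution matches the curated catalog", {
  cat_df <- load_catalog()
  dist <- chromosome_distribution(cat_df)
  expect_equal(dist, c(chr1 = 2L, chr2 = 7L, chr3 = 3L, chr4 = 0L,
                       chr5 = 3L, chr6 = 2L, chr7 = 3L, chr8 = 2L,
                       chr9 = 6L))
  expect_equal(sum(dist), nrow(cat_df))
  empty <- chromosome_distribution(cat_df[0, ])
  expect_true(all(empty == 0L))
})

test_that("tandem pairs recover the known duplication events", {
  cat_df <- load_catalog()
  pairs <- find_tandem_pairs(cat_df)
  key <- paste(pairs$gene_a, pairs$gene_b)
  high <- key[pairs$confidence == "high"]
  expect_setequal(high, c("BvPIP1;1 BvPIP1;2", "BvNIP4;1 BvNIP4;2",
                          "BvNIP6;2 BvNIP6;3", "BvPIP2;2 BvPIP2;3"))
  # the NIP5 pair spans two tag schemes (TE vs g): low confidence only
  expect_true("BvNIP5;1 BvNIP5;2" %in% key[pairs$confidence == "low"])
  expect_false("BvNIP5;1 BvNIP5;2" %in% high)
  # the two SIP1;1 transcripts are adjacent tags of one gene, not a pair
  expect_false(any(grepl("SIP1;1", key)))
  # invariance to catalog shuffling
  shuffled <- cat_df[rev(seq_len(nrow(cat_df))), ]
  expect_equal(find_tandem_pairs(shuffled), pairs, ignore_attr = TRUE)
  expect_equal(nrow(find_tandem_pairs(cat_df[1, , drop = FALSE])), 0L)
})

test_that("exon counts follow the annotation", {
  ann <- make_annotation(seed = 4)
  gff <- tempfile(fileext = ".gff3")
  writeLines(ann$gff, gff)
  counts <- exon_counts(gff)
  # generator convention: PIP 4, NIP 5, TIP 3, SIP 3, XIP 2 exons
  lab <- ann$catalog$gene[match(sub("\\.t[0-9]+$", ".t1", names(counts)),
                                ann$catalog$gene_id)]
  t1 <- grepl("\\.t1$", names(counts))
  expect_equal(unname(counts[t1]),
               unname(ann$truth$exon_convention[lab[t1]]))
  xip <- ann$catalog$gene_id[ann$catalog$gene == "SynXIP1;1"]
  expect_equal(unname(counts[xip]), 2L)
  # the skipped-exon transcript has one exon fewer
  sk <- ann$truth$splicing_events
  expect_equal(unname(counts[sk$transcript_b]),
               unname(counts[sk$transcript_a]) - 1L)
})

test_that("exons outside gene bounds are rejected", {
  gff <- c("##gff-version 3",
           "chr1\ttest\tgene\t100\t500\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t100\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chr1\ttest\texon\t100\t200\t.\t+\t.\tID=e1;Parent=g1.t1",
           "chr1\ttest\texon\t400\t600\t.\t+\t.\tID=e2;Parent=g1.t1")
  tmp <- tempfile(fileext = ".gff3")
  writeLines(gff, tmp)
  expect_error(read_gene_models(tmp), "outside gene bounds")
})

test_that("exon skipping is detected from coordinate-equal chains", {
  model <- list(gene_id = "g", chromosome = "chr1", start = 1, end = 2000,
                strand = "+",
                transcripts = list(
                  t1 = data.frame(start = c(1, 500, 1500),
                                  end = c(200, 700, 1700)),
                  t2 = data.frame(start = c(1, 1500), end = c(200, 1700))))
  ev <- detect_exon_skipping(model)
  expect_equal(ev$kind, "exon_skipping")
  expect_equal(ev$skipped_exon_index, 2L)
  expect_equal(ev$transcript_a, "t1")
  # identical chains: no event
  model$transcripts$t2 <- model$transcripts$t1
  expect_equal(nrow(detect_exon_skipping(model)), 0L)
  # two internal differences: kind "other"
  model$transcripts <- list(
    t1 = data.frame(start = c(1, 500, 900, 1500),
                    end = c(200, 700, 1100, 1700)),
    t2 = data.frame(start = c(1, 510, 910, 1500),
                    end = c(200, 700, 1100, 1700)))
  ev2 <- detect_exon_skipping(model)
  expect_equal(ev2$kind, "other")
  expect_true(is.na(ev2$skipped_exon_index))
})

test_that("minus-strand skipped ordinals count in transcription order", {
  model <- list(gene_id = "g", chromosome = "chr1", start = 1, end = 2000,
                strand = "-",
                transcripts = list(
                  t1 = data.frame(start = c(1, 500, 1500),
                                  end = c(200, 700, 1700)),
                  t2 = data.frame(start = c(1, 1500), end = c(200, 1700))))
  ev <- detect_exon_skipping(model)
  # genomic middle exon is still the second exon read 3'-to-5'
  expect_equal(ev$skipped_exon_index, 2L)
})

test_that("the synthetic annotation round-trips through detection", {
  ann <- make_annotation(seed = 8)
  gff <- tempfile(fileext = ".gff3")
  writeLines(ann$gff, gff)
  models <- read_gene_models(gff)
  events <- do.call(rbind, lapply(models, detect_exon_skipping))
  expect_equal(nrow(events), 1L)
  expect_equal(events$kind, "exon_skipping")
  expect_equal(events$skipped_exon_index,
               ann$truth$splicing_events$skipped_exon_index)
  pairs <- find_tandem_pairs(ann$catalog)
  expect_equal(pairs[, c("gene_a", "gene_b")],
               ann$truth$tandem_pairs[order(ann$truth$tandem_pairs$gene_a), ],
               ignore_attr = TRUE)
})
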