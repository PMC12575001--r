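# Dataset builder: splitting, filtering, labeling, segmentation, container.

test_that("human chromosome split reproduces the fixed partition", {
  chroms <- data.frame(name = paste0("chr", c(1:22, "X", "Y")),
                       length = rep(1000, 24))
  sp <- split_chromosomes(chroms, method = "human")
  expect_setequal(sp$test, paste0("chr", c(1, 3, 5, 7, 9)))
  expect_setequal(sp$train, paste0("chr", c(2, 4, 6, 8, 10:22, "X", "Y")))
  # bare names (no chr prefix) accepted
  sp2 <- split_chromosomes(data.frame(name = c("1", "3", "2"),
                                      length = c(1, 1, 1)), method = "human")
  expect_setequal(sp2$test, c("1", "3"))
  expect_error(
    split_chromosomes(data.frame(name = c("chr1", "scaffold_7"),
                                 length = c(1, 1)), method = "human"),
    "scaffold_7")
})

test_that("random split accumulates to the training fraction, reproducibly", {
  chroms <- data.frame(name = letters[1:6],
                       length = c(100, 200, 300, 150, 250, 100))
  s1 <- split_chromosomes(chroms, "random", 0.8, seed = 4)
  s2 <- split_chromosomes(chroms, "random", 0.8, seed = 4)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0L)
  expect_setequal(c(s1$train, s1$test), chroms$name)
  train_len <- sum(chroms$length[chroms$name %in% s1$train])
  expect_gte(train_len, 0.8 * sum(chroms$length))
  # two equal chromosomes at fraction 0.5: one each
  eq <- split_chromosomes(data.frame(name = c("a", "b"),
                                     length = c(10, 10)), "random", 0.5,
                          seed = 1)
  expect_length(eq$train, 1L)
  expect_length(eq$test, 1L)
  # single chromosome: train takes it, empty test warns
  expect_warning(
    one <- split_chromosomes(data.frame(name = "a", length = 10), "random",
                             0.8, seed = 1),
    "empty")
  expect_equal(one$train, "a")
  expect_length(one$test, 0L)
})

test_that("pseudogene filtering removes the listed biotypes only", {
  mk <- function(id, bt) spliceml:::new_gene_model(id, "c", 1, 10, "+", bt,
                                                   list())
  genes <- list(mk("a", "protein_coding"), mk("b", "processed_pseudogene"),
                mk("c", "pseudogene"), mk("d", "transcribed_pseudogene"),
                mk("e", "lncRNA"))
  kept <- filter_pseudogenes(genes)
  expect_setequal(vapply(kept, `[[`, "", "gene_id"), c("a", "e"))
  expect_length(filter_pseudogenes(list()), 0L)
})

test_that("splice-site labeling follows the exonic-base convention", {
  lg <- tiny_labeled_gene()
  # donor on last base of exon 1 (0-based 9), acceptor on first base of
  # exon 2 (0-based 24)
  expect_equal(lg$donor_positions, 9L)
  expect_equal(lg$acceptor_positions, 24L)
  expect_equal(which(lg$labels == 2L) - 1L, 9L)
  expect_equal(which(lg$labels == 1L) - 1L, 24L)
  expect_equal(length(lg$labels), nchar(lg$sequence))
})

test_that("canonical-only labeling keeps GT-AG/GC-AG/AT-AC and drops others", {
  mk_seq <- function(d5, a3) paste0("ATGGCCAAAG", d5, "AAGTTTTTTT", a3,
                                    "GCCTAGGA")
  tx <- spliceml:::new_transcript("t1", cbind(c(1, 25), c(10, 32)), "+")
  for (pair in list(c("GT", "AG"), c("GC", "AG"), c("AT", "AC"))) {
    lg <- label_splice_sites(tx, mk_seq(pair[1], pair[2]), 1L, 32L, "+",
                             canonical_only = TRUE)
    expect_length(lg$donor_positions, 1L)
  }
  lg_nc <- label_splice_sites(tx, mk_seq("CT", "AC"), 1L, 32L, "+",
                              canonical_only = TRUE)
  expect_length(lg_nc$donor_positions, 0L)
  expect_length(lg_nc$acceptor_positions, 0L)
  # without the filter all introns are labeled
  lg_all <- label_splice_sites(tx, mk_seq("CT", "AC"), 1L, 32L, "+",
                               canonical_only = FALSE)
  expect_length(lg_all$donor_positions, 1L)
  # single-exon transcript: no labels
  tx1 <- spliceml:::new_transcript("t1", cbind(1, 32), "+")
  lg1 <- label_splice_sites(tx1, mk_seq("GT", "AG"), 1L, 32L, "+")
  expect_true(all(lg1$labels == 0L))
  # 3-exon transcript with GT..AG introns: 2 donors + 2 acceptors
  seq3 <- paste0("AAAAAAAAAG", "GTTTTTTTAG", "GAAAAAAAAG", "GTTTTTTTAG",
                 "GAAAAAAAAA")
  tx3 <- spliceml:::new_transcript("t3", cbind(c(1, 21, 41), c(10, 30, 50)),
                                   "+")
  lg3 <- label_splice_sites(tx3, seq3, 1L, 50L, "+", canonical_only = TRUE)
  expect_length(lg3$donor_positions, 2L)
  expect_length(lg3$acceptor_positions, 2L)
  # overlapping exons error
  txo <- spliceml:::new_transcript("t1", cbind(c(1, 25), c(10, 32)), "+")
  txo$exons <- cbind(c(1, 8), c(10, 32))
  expect_error(label_splice_sites(txo, mk_seq("GT", "AG"), 1L, 32L, "+"),
               "overlap")
})

test_that("segmentation tiles genes with ceil(L/core) windows and padding", {
  mk <- function(L) structure(
    list(gene_id = "g", sequence = rand_dna(L, seed = L),
         labels = integer(L), donor_positions = integer(0),
         acceptor_positions = integer(0)), class = "labeled_gene")
  # the worked example: 22,000 nt -> 5 segments
  sg <- segment_gene(mk(22000))
  expect_equal(dim(sg$X), c(5L, 15000L, 4L))
  expect_equal(dim(sg$Y), c(5L, 5000L, 3L))
  # final core window holds 2000 real bases
  expect_equal(sum(rowSums(matrix(sg$X[5, 5001:10000, ], ncol = 4))), 2000)
  expect_equal(sum(sg$Y[5, , ]), 2000)
  # exactly one segment at L = core
  expect_equal(dim(segment_gene(mk(5000))$X)[1], 1L)
  # L = 5001: two segments, second core has 1 real base
  sg2 <- segment_gene(mk(5001))
  expect_equal(dim(sg2$X)[1], 2L)
  expect_equal(sum(sg2$Y[2, , ]), 1)
  expect_error(segment_gene(mk(0)), "zero-length")
})

test_that("non-padding label rows across segments reconstruct the gene", {
  spec <- synthetic_spec(n_chromosomes = 1L, chrom_length = 40000L,
                         n_genes = 4L, seed = 3L)
  gen <- generate_genome(spec)
  genome <- read_genome(gen$fasta)
  for (gm in parse_annotation(gen$gff)) {
    lg <- label_splice_sites(select_canonical(gm),
                             extract_gene_sequence(genome, gm),
                             gm$start, gm$end, strand = gm$strand)
    sg <- segment_gene(lg)
    # sum over segments of real (one-hot) Y rows equals gene length
    expect_equal(sum(sg$Y), nchar(lg$sequence))
    # label counts in Y match the labeled gene
    expect_equal(sum(sg$Y[, , 3]), length(lg$donor_positions))
    expect_equal(sum(sg$Y[, , 2]), length(lg$acceptor_positions))
  }
})

test_that("dataset container round-trips losslessly in batched groups", {
  mk <- function(id, L) structure(
    list(gene_id = id, sequence = rand_dna(L), labels = integer(L),
         donor_positions = integer(0), acceptor_positions = integer(0)),
    class = "labeled_gene")
  spliceml:::with_seed(8, {
    genes <- lapply(seq_len(7), function(i) mk(paste0("g", i),
                                               sample(200:900, 1)))
  })
  ds <- encode_dataset(genes, core = 100L, flank = 50L)
  f <- tempfile(fileext = ".rds")
  write_dataset(ds, f, batch_size = 3L)
  back <- read_dataset(f)
  expect_equal(back$n_batches, 3L)  # ceiling(7 / 3)
  expect_equal(length(back$genes), 7L)
  for (i in seq_along(genes)) {
    expect_identical(back$genes[[i]]$X, ds$genes[[i]]$X)
    expect_identical(back$genes[[i]]$Y, ds$genes[[i]]$Y)
  }
  # empty dataset: valid file with zero groups
  f0 <- tempfile(fileext = ".rds")
  write_dataset(encode_dataset(list()), f0)
  expect_equal(read_dataset(f0)$n_batches, 0L)
  # corrupt file errors with the missing key
  f_bad <- tempfile(fileext = ".rds")
  saveRDS(list(whatever = 1), f_bad)
  expect_error(read_dataset(f_bad), "format")
})
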