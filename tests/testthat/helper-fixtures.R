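# Shared fixtures, generated in code at test time.

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else spliceml:::with_seed(seed, draw())
}

# Small multi-gene GFF3 + FASTA pair written to a temp dir.
# Two protein-coding genes (one with 2 transcripts), one lncRNA, one
# processed pseudogene.
tiny_annotation <- function(dir = tempfile("anno_")) {
  dir.create(dir)
  chrom <- rand_dna(4000, seed = 42)
  fa <- file.path(dir, "g.fa")
  writeLines(c(">chrT", chrom), fa)
  gff <- file.path(dir, "a.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\tsrc\tgene\t101\t1100\t.\t+\t.\tID=g1;gene_biotype=protein_coding",
    "chrT\tsrc\tmRNA\t101\t1100\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrT\tsrc\texon\t101\t400\t.\t+\t.\tID=g1.t1.e1;Parent=g1.t1",
    "chrT\tsrc\texon\t701\t1100\t.\t+\t.\tID=g1.t1.e2;Parent=g1.t1",
    "chrT\tsrc\tmRNA\t101\t1000\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chrT\tsrc\texon\t101\t400\t.\t+\t.\tID=g1.t2.e1;Parent=g1.t2",
    "chrT\tsrc\texon\t701\t1000\t.\t+\t.\tID=g1.t2.e2;Parent=g1.t2",
    "chrT\tsrc\tgene\t1501\t2500\t.\t-\t.\tID=g2;gene_biotype=protein_coding",
    "chrT\tsrc\tmRNA\t1501\t2500\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chrT\tsrc\texon\t1501\t1800\t.\t-\t.\tID=g2.t1.e1;Parent=g2.t1",
    "chrT\tsrc\texon\t2101\t2500\t.\t-\t.\tID=g2.t1.e2;Parent=g2.t1",
    "chrT\tsrc\tgene\t2701\t3200\t.\t+\t.\tID=g3;gene_biotype=lncRNA",
    "chrT\tsrc\tlnc_RNA\t2701\t3200\t.\t+\t.\tID=g3.t1;Parent=g3",
    "chrT\tsrc\texon\t2701\t3200\t.\t+\t.\tID=g3.t1.e1;Parent=g3.t1",
    "chrT\tsrc\tgene\t3301\t3700\t.\t+\t.\tID=g4;gene_biotype=processed_pseudogene",
    "chrT\tsrc\tmRNA\t3301\t3700\t.\t+\t.\tID=g4.t1;Parent=g4",
    "chrT\tsrc\texon\t3301\t3700\t.\t+\t.\tID=g4.t1.e1;Parent=g4.t1"),
    gff)
  list(fasta = fa, gff = gff, dir = dir)
}

# Labeled gene with a hand-built sequence: exon1(10) GT..intron(14)..AG exon2(8).
# Donor at 0-based 9, acceptor at 24.
tiny_labeled_gene <- function() {
  seq <- paste0("ATGGCCAAAG", "GTAAGTTTTTTTAG", "GCCTAGGA")
  tx <- spliceml:::new_transcript("t1", cbind(c(1, 25), c(10, 32)), "+")
  label_splice_sites(tx, seq, gene_start = 1L, gene_end = 32L, strand = "+",
                     gene_id = "tiny")
}

# A small untrained model shared across inference tests.
small_model <- function(flank = 80L, channels = 8L, seed = 99L) {
  init_model(build_config(flank, channels = channels), seed = seed)
}

# A model whose outputs ignore the input (all conv weights zero): constant
# logits, useful for exactness properties.
constant_model <- function(flank = 80L, channels = 4L) {
  m <- small_model(flank, channels, seed = 1L)
  zero <- function(l) { l$W[] <- 0; l }
  m$params$conv_in <- zero(m$params$conv_in)
  m$params$skip0 <- zero(m$params$skip0)
  m$params$units <- lapply(m$params$units, function(u) {
    u$conv1 <- zero(u$conv1); u$conv2 <- zero(u$conv2); u
  })
  m$params$skips <- lapply(m$params$skips, zero)
  m$params$conv_out <- zero(m$params$conv_out)
  m
}

# Random logits whose labels are drawn from softmax(logits): calibrated by
# construction.
calibrated_logits <- function(n, seed = 1L, scale = 2) {
  spliceml:::with_seed(seed, {
    z <- matrix(rnorm(n * 3, sd = scale), n, 3)
    p <- spliceml:::softmax_rows(z)
    y <- vapply(seq_len(n), function(i) sample(3L, 1L, prob = p[i, ]), 0L)
    list(logits = z, labels = y)
  })
}

# Cache one small synthetic genome per session for IO-level tests.
syn_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_chromosomes = 2L, chrom_length = 30000L,
                             n_genes = 6L, seed = 7L)
      cache <<- generate_genome(spec)
    }
    cache
  }
})
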