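# Window planning, track prediction, site calling, variant delta scores.

test_that("window plans tile the sequence exactly with edge padding", {
  # one core: pads flank/2 on each side
  p1 <- plan_windows(5000, 80)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$left_pad, 40L)
  expect_equal(p1$right_pad, 40L)
  # 12,000 bases, flank 80 -> 3 windows; third core covers [10000, 12000)
  p3 <- plan_windows(12000, 80)
  expect_equal(nrow(p3), 3L)
  expect_equal(p3$core_start, c(0L, 5000L, 10000L))
  expect_equal(p3$core_end[3], 12000L)
  expect_gt(p3$right_pad[3], 0L)
  # degenerate single-base sequence
  pd <- plan_windows(1, 80)
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$core_end - pd$core_start, 1L)
  # cores tile exactly once for assorted lengths
  for (L in c(1, 4999, 5000, 5001, 23456)) {
    pl <- plan_windows(L, 400)
    expect_equal(pl$core_start[1], 0L)
    expect_equal(pl$core_end[nrow(pl)], L)
    if (nrow(pl) > 1) {
      expect_equal(pl$core_start[-1], pl$core_end[-nrow(pl)])
    }
    expect_true(all(pl$left_pad + (pl$seq_end - pl$seq_start) +
                      pl$right_pad == 5000 + 400))
  }
})

test_that("prediction covers every base and averages ensembles", {
  m <- small_model()
  seq <- rand_dna(7500, 12)
  tr <- predict_track(m, seq)
  expect_equal(tr$length, 7500L)
  expect_length(tr$donor, 7500L)
  expect_true(all(abs(tr$none + tr$acceptor + tr$donor - 1) < 1e-6))
  # k identical models give the same track as one
  tr5 <- predict_track(list(m, m, m, m, m), seq)
  expect_equal(tr5$donor, tr$donor, tolerance = 1e-12)
  # two different models: track is the mean
  m2 <- small_model(seed = 123)
  tr_ab <- predict_track(list(m, m2), seq)
  tr_b <- predict_track(m2, seq)
  expect_equal(tr_ab$donor, (tr$donor + tr_b$donor) / 2, tolerance = 1e-12)
  expect_error(predict_track(m, ""), "empty")
  expect_error(predict_track(list(m, small_model(400, channels = 4L)), seq),
               "flanking size")
})

test_that("chunked and whole-sequence prediction agree everywhere", {
  m <- small_model()
  for (seed in c(1, 2)) {
    seq <- rand_dna(9000, seed)
    whole <- predict_track(m, seq)
    chunked <- predict_track(m, seq, split_threshold = 2500L)
    expect_lt(max(abs(whole$donor - chunked$donor)), 1e-4)
    expect_lt(max(abs(whole$acceptor - chunked$acceptor)), 1e-4)
  }
})

test_that("site calling emits BED records above threshold", {
  tr <- structure(list(none = c(0.2, 0.95, 0.4), acceptor = c(0.1, 0.02, 0.55),
                       donor = c(0.7, 0.03, 0.05), length = 3L),
                  class = "prediction_track")
  cs <- call_sites(tr, threshold = 0.5, seq_name = "chr9", offset = 100L)
  expect_equal(nrow(cs$donor), 1L)
  expect_equal(cs$donor$start, 100L)
  expect_equal(cs$donor$end, 101L)
  expect_equal(cs$donor$score, 0.7)
  expect_equal(cs$acceptor$start, 102L)
  # all below threshold -> empty; threshold 0 -> everything
  expect_equal(nrow(call_sites(tr, 0.96)$donor), 0L)
  expect_equal(nrow(call_sites(tr, 0)$donor), 3L)
})

test_that("delta scores implement the four max-difference channels", {
  # hand example: a_ref/a_alt arrays
  a_ref <- c(0.1, 0.9, 0.3); a_alt <- c(0.8, 0.2, 0.3)
  d0 <- rep(0, 3)
  ds <- delta_scores(a_ref, a_alt, d0, d0)
  expect_equal(ds$DS_AG, 0.7)  # max(a_alt - a_ref)
  expect_equal(ds$DS_AL, 0.7)  # max(a_ref - a_alt)
  expect_equal(ds$DP_AG, -1L)
  expect_equal(ds$DP_AL, 0L)
  # alt = ref -> all zeros
  z <- delta_scores(a_ref, a_ref, d0, d0)
  expect_equal(c(z$DS_AG, z$DS_AL, z$DS_DG, z$DS_DL), rep(0, 4))
  # ref/alt swap exchanges gain and loss exactly
  spliceml:::with_seed(3, {
    ar <- runif(101); aa <- runif(101); dr <- runif(101); da <- runif(101)
    f <- delta_scores(ar, aa, dr, da)
    s <- delta_scores(aa, ar, da, dr)
    expect_identical(f$DS_AG, s$DS_AL)
    expect_identical(f$DS_AL, s$DS_AG)
    expect_identical(f$DS_DG, s$DS_DL)
    expect_identical(f$DS_DL, s$DS_DG)
    expect_true(all(unlist(f[1:4]) >= 0 & unlist(f[1:4]) <= 1))
  })
})

test_that("variant eligibility enforces the gene/end/deletion rules", {
  gene <- spliceml:::new_gene_model("g", "chr1", 1000, 3000, "+",
                                    "protein_coding", list())
  ok <- variant_eligibility(list(CHROM = "chr1", POS = 2000, REF = "G",
                                 ALT = "A"), list(gene), 100000, 80)
  expect_true(ok$eligible)
  out <- variant_eligibility(list(CHROM = "chr1", POS = 5000, REF = "G",
                                  ALT = "A"), list(gene), 100000, 80)
  expect_false(out$eligible)
  expect_match(out$reason, "outside gene")
  # deletion of 150 bases with distance 50 is skipped (150 > 100)
  del <- variant_eligibility(list(CHROM = "chr1", POS = 2000,
                                  REF = strrep("A", 151), ALT = "A"),
                             list(gene), 100000, 80, distance = 50)
  expect_false(del$eligible)
  expect_match(del$reason, "deletion")
  near_end <- variant_eligibility(list(CHROM = "chr1", POS = 2000, REF = "G",
                                       ALT = "A"), list(gene), 2040, 80)
  expect_false(near_end$eligible)
})

test_that("variant scoring aligns arrays and respects swap symmetry", {
  m <- small_model()
  chrom <- rand_dna(3000, 77)
  genome <- genome_from_strings(c(c1 = chrom))
  gene <- spliceml:::new_gene_model("g", "c1", 500, 2500, "+",
                                    "protein_coding", list())
  pos <- 1500L
  ref <- substr(chrom, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- list(CHROM = "c1", POS = pos, REF = ref, ALT = alt)
  ds <- score_variant(m, genome, v, gene, distance = 50L)
  expect_true(all(unlist(ds[1:4]) >= 0))
  expect_true(all(abs(unlist(ds[5:8])) <= 50))
  # identical alt: all DS zero
  ds0 <- score_variant(m, genome, list(CHROM = "c1", POS = pos, REF = ref,
                                       ALT = ref), gene)
  expect_equal(c(ds0$DS_AG, ds0$DS_AL, ds0$DS_DG, ds0$DS_DL), rep(0, 4))
  # swap symmetry through the full scoring path (mutate the genome)
  chrom_alt <- chrom
  substr(chrom_alt, pos, pos) <- alt
  genome_alt <- genome_from_strings(c(c1 = chrom_alt))
  ds_sw <- score_variant(m, genome_alt, list(CHROM = "c1", POS = pos,
                                             REF = alt, ALT = ref), gene)
  expect_equal(ds$DS_AG, ds_sw$DS_AL, tolerance = 1e-10)
  expect_equal(ds$DS_DG, ds_sw$DS_DL, tolerance = 1e-10)
  # ref mismatch errors
  expect_error(score_variant(m, genome, list(CHROM = "c1", POS = pos,
                                             REF = alt, ALT = ref), gene),
               "mismatch")
  # multi-base deletion aligns without index errors
  del_ref <- substr(chrom, pos, pos + 11)
  ds_del <- score_variant(m, genome, list(CHROM = "c1", POS = pos,
                                          REF = del_ref,
                                          ALT = substr(del_ref, 1, 1)), gene)
  expect_true(all(is.finite(unlist(ds_del[1:4]))))
  # insertion too
  ds_ins <- score_variant(m, genome, list(CHROM = "c1", POS = pos, REF = ref,
                                          ALT = paste0(ref, "ACGTAC")), gene)
  expect_true(all(is.finite(unlist(ds_ins[1:4]))))
})

test_that("VCF annotation preserves records and augments the header", {
  m <- small_model(channels = 6L)
  chrom <- rand_dna(3000, 55)
  genome <- genome_from_strings(c(c1 = chrom))
  gene <- spliceml:::new_gene_model("g", "c1", 500, 2500, "+",
                                    "protein_coding", list())
  pos <- 1200L
  ref <- substr(chrom, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  vin <- tempfile(fileext = ".vcf"); vout <- tempfile(fileext = ".vcf")
  write_vcf(data.frame(CHROM = c("c1", "c1"), POS = c(pos, 2900L),
                       ID = c("in_gene", "intergenic"),
                       REF = c(ref, substr(chrom, 2900, 2900)),
                       ALT = c(alt, "A" )), vin, contigs = c(c1 = 3000L))
  summary <- annotate_vcf(vin, vout, genome, list(gene), m)
  expect_equal(nrow(summary), 2L)
  expect_equal(summary$eligible, c(TRUE, FALSE))
  out <- readLines(vout)
  expect_true(any(grepl("##INFO=<ID=SpliceDelta", out)))
  body <- out[!grepl("^#", out)]
  expect_length(body, 2L)
  expect_true(grepl("SpliceDelta=", body[1]))
  expect_false(grepl("SpliceDelta=", body[2]))
  # empty body: valid output with augmented header
  v0 <- tempfile(fileext = ".vcf"); v0o <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), v0)
  s0 <- annotate_vcf(v0, v0o, genome, list(gene), m)
  expect_null(s0)
  expect_true(any(grepl("SpliceDelta", readLines(v0o))))
  # malformed record errors with its number
  vb <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "c1\tnotanumber\tx\tA\tC\t.\t.\t."), vb)
  expect_error(annotate_vcf(vb, tempfile(), genome, list(gene), m),
               "record 1")
})
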