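# Seeded synthetic mini-genome generator: multi-exon protein-coding genes with
# canonical (GT-AG, GC-AG, AT-AC) introns, polypyrimidine tracts upstream of
# acceptors, planted near-consensus decoy sites, and matched FASTA + GFF3 +
# truth tables + VCF variants. Every downstream module is testable against the
# recorded ground truth without any external data.

# Splice-motif model (sense strand, 0-based offsets relative to the junction):
#   donor:    exon ...  M A G | G T R A G T ... intron   (M = A/C, R = A/G)
#   acceptor: intron ... <polypyrimidine tract> Y A G | G ... exon
# The donor label sits on the last exonic base, the acceptor label on the
# first exonic base of the downstream exon (the package-wide convention, see
# `label_splice_sites`).

DONOR_EXON_CONS <- c("M", "A", "G")            # last 3 exonic bases
DONOR_INTRON_CONS <- c("G", "T", "R", "A", "G", "T")  # first 6 intronic bases
ACCEPTOR_INTRON_CONS <- c("Y", "A", "G")       # last 3 intronic bases
ACCEPTOR_EXON_CONS <- c("G")                   # first exonic base

sample_iupac <- function(code) {
  switch(code,
         A = "A", C = "C", G = "G", T = "T",
         M = sample(c("A", "C"), 1L),
         R = sample(c("A", "G"), 1L),
         Y = sample(c("C", "T"), 1L),
         stop("unknown code ", code))
}

#' Specification of a synthetic genome
#'
#' Defaults describe the toy-genome study conditions used throughout the test
#' suite: a 2 Mb genome (8 chromosomes of 250 kb) carrying 80 multi-exon
#' protein-coding genes with strong splice consensus motifs.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Total number of genes, spread evenly over chromosomes.
#' @param exon_count_range Inclusive range the per-gene exon count is drawn
#'   from (uniformly).
#' @param exon_length_range,intron_length_range Uniform length ranges (bases).
#' @param consensus_strength Probability that each degenerate/extended
#'   consensus position carries a consensus base (core dinucleotides are
#'   always exact).
#' @param polypyrimidine_length Length of the C/T tract upstream of each
#'   acceptor.
#' @param gc_ag_fraction,at_ac_fraction Fractions of introns whose boundary
#'   dinucleotides are GC-AG (U2 minor) or AT-AC (U12), respectively; the
#'   remainder are GT-AG.
#' @param noncanonical_fraction Fraction of introns planted with a
#'   non-canonical boundary (CT-GC), which the `canonical_only` labeling
#'   filter must drop.
#' @param decoys_per_gene Number of near-consensus (Hamming distance 1) decoy
#'   splice motifs planted in intron interiors per gene.
#' @param background_gc GC content of intergenic/background sequence.
#' @param seed Integer seed; identical specs produce byte-identical outputs.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chromosomes = 8L,
                           chrom_length = 250000L,
                           n_genes = 80L,
                           exon_count_range = c(5L, 9L),
                           exon_length_range = c(120L, 300L),
                           intron_length_range = c(150L, 450L),
                           consensus_strength = 1,
                           polypyrimidine_length = 12L,
                           gc_ag_fraction = 0.05,
                           at_ac_fraction = 0.02,
                           noncanonical_fraction = 0,
                           decoys_per_gene = 1L,
                           background_gc = 0.42,
                           seed = 1L) {
  stopifnot(n_chromosomes >= 1L, chrom_length > 0L, n_genes >= 1L,
            all(exon_length_range > 0L), all(intron_length_range > 0L),
            gc_ag_fraction + at_ac_fraction + noncanonical_fraction <= 1,
            consensus_strength >= 0, consensus_strength <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

rand_bases <- function(n, gc = 0.42) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

sample_consensus <- function(codes, strength, gc) {
  vapply(codes, function(cd) {
    if (stats::runif(1) <= strength) sample_iupac(cd)
    else sample(c("A", "C", "G", "T"), 1L)
  }, "")
}

# Build one gene on the sense strand. Returns the sequence plus 0-based local
# exon intervals, splice-site positions, intron classes and decoy records.
build_gene_seq <- function(spec) {
  k <- sample(seq(spec$exon_count_range[1L], spec$exon_count_range[2L]), 1L)
  exon_len <- sample(seq(spec$exon_length_range[1L], spec$exon_length_range[2L]),
                     k, replace = TRUE)
  intron_len <- if (k > 1L)
    sample(seq(spec$intron_length_range[1L], spec$intron_length_range[2L]),
           k - 1L, replace = TRUE) else integer(0)
  tract <- spec$polypyrimidine_length
  stopifnot(all(intron_len >= tract + 20L))

  cls_pool <- c("GT-AG", "GC-AG", "AT-AC", "noncanonical")
  cls_p <- c(1 - spec$gc_ag_fraction - spec$at_ac_fraction -
               spec$noncanonical_fraction,
             spec$gc_ag_fraction, spec$at_ac_fraction,
             spec$noncanonical_fraction)
  intron_cls <- if (k > 1L) sample(cls_pool, k - 1L, replace = TRUE, prob = cls_p)
    else character(0)

  pieces <- character(0)
  exons <- matrix(0L, nrow = k, ncol = 2L)  # 0-based half-open local
  donors <- integer(0); acceptors <- integer(0)
  decoys <- list()
  pos <- 0L
  for (i in seq_len(k)) {
    ex <- rand_bases(exon_len[i], spec$background_gc)
    if (i > 1L) {  # acceptor consensus at exon start
      substr(ex, 1L, 1L) <- sample_consensus(ACCEPTOR_EXON_CONS,
                                             spec$consensus_strength,
                                             spec$background_gc)
    }
    if (i < k) {   # donor consensus at exon end
      tailcons <- paste(sample_consensus(DONOR_EXON_CONS,
                                         spec$consensus_strength,
                                         spec$background_gc), collapse = "")
      substr(ex, exon_len[i] - 2L, exon_len[i]) <- tailcons
    }
    pieces <- c(pieces, ex)
    exons[i, ] <- c(pos, pos + exon_len[i])
    if (i < k) donors <- c(donors, pos + exon_len[i] - 1L)
    if (i > 1L) acceptors <- c(acceptors, pos)
    pos <- pos + exon_len[i]

    if (i < k) {
      cls <- intron_cls[i]
      head5 <- paste(sample_consensus(DONOR_INTRON_CONS,
                                      spec$consensus_strength,
                                      spec$background_gc), collapse = "")
      substr(head5, 1L, 2L) <- switch(cls, "GT-AG" = "GT", "GC-AG" = "GC",
                                      "AT-AC" = "AT", "noncanonical" = "CT")
      tail3 <- paste(c(strrep("", 0),
                       sample(c("C", "T"), tract, replace = TRUE),
                       sample_consensus(ACCEPTOR_INTRON_CONS,
                                        spec$consensus_strength,
                                        spec$background_gc)), collapse = "")
      end2 <- switch(cls, "GT-AG" = "AG", "GC-AG" = "AG",
                     "AT-AC" = "AC", "noncanonical" = "GC")
      substr(tail3, nchar(tail3) - 1L, nchar(tail3)) <- end2
      mid_len <- intron_len[i] - nchar(head5) - nchar(tail3)
      intron <- paste0(head5, rand_bases(mid_len, spec$background_gc), tail3)

      # plant decoys: a consensus donor motif with one mismatch, at a random
      # position in the intron interior, kept >= 45 nt away from the real
      # boundary motifs so decoys do not sit inside a real site's context
      n_dec <- spec$decoys_per_gene
      if (n_dec > 0L && mid_len > 100L && i == 1L) {
        for (d in seq_len(min(n_dec, 1L))) {
          motif <- c(vapply(DONOR_EXON_CONS, sample_iupac, ""),
                     vapply(DONOR_INTRON_CONS, sample_iupac, ""))
          mm_at <- 5L                      # the R position of GTRAGT
          consensus_base <- motif[mm_at + 1L]
          alt_pool <- setdiff(c("A", "C", "G", "T"),
                              c(consensus_base, "A", "G"))
          motif[mm_at + 1L] <- sample(alt_pool, 1L)
          off <- nchar(head5) + sample(40L:(mid_len - 49L), 1L)
          substr(intron, off + 1L, off + 9L) <- paste(motif, collapse = "")
          # local position of the would-be donor label (last "exonic" base)
          decoys[[length(decoys) + 1L]] <- list(
            kind = "donor",
            label_local = pos + off + 2L,
            mismatch_local = pos + off + mm_at,
            consensus_base = consensus_base)
        }
      }
      pieces <- c(pieces, intron)
      pos <- pos + intron_len[i]
    }
  }
  list(seq = paste(pieces, collapse = ""), exons = exons, donors = donors,
       acceptors = acceptors, intron_classes = intron_cls, decoys = decoys)
}

#' Generate a synthetic genome
#'
#' Places genes without overlap on both strands of background sequence and
#' writes matched FASTA + GFF3 files plus a truth table recording every
#' planted splice site.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `fasta`, `gff` (file paths), `truth` (data.frame: one row
#'   per gene with genomic exon intervals, donor/acceptor positions, intron
#'   classes), `decoys` (data.frame of planted near-consensus sites), and
#'   `spec`.
#' @export
generate_genome <- function(spec, dir = tempfile("syn_genome_")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    n_chr <- spec$n_chromosomes
    per_chr <- diff(round(seq(0, spec$n_genes, length.out = n_chr + 1L)))
    chrom_names <- sprintf("chrS%02d", seq_len(n_chr))
    margin <- 2000L; gap_min <- 500L; gap_max <- 1500L

    fasta_seqs <- character(n_chr)
    gff_lines <- c("##gff-version 3")
    truth <- list(); decoy_rows <- list()
    gene_counter <- 0L

    for (ci in seq_len(n_chr)) {
      cursor <- margin
      segs <- character(0)  # alternating background / gene sequence
      last_end <- 0L
      for (gi in seq_len(per_chr[ci])) {
        gene_counter <- gene_counter + 1L
        g <- build_gene_seq(spec)
        L <- nchar(g$seq)
        gap <- sample(gap_min:gap_max, 1L)
        start0 <- cursor + gap            # 0-based genomic start
        if (start0 + L > spec$chrom_length - margin) {
          stop("genes cannot be placed without overlap on ", chrom_names[ci],
               "; use longer chromosomes or fewer genes")
        }
        strand <- sample(c("+", "-"), 1L)
        gene_id <- sprintf("SYNG%04d", gene_counter)
        tx_id <- paste0(gene_id, ".t1")

        genomic_seq <- if (strand == "-") revcomp(g$seq) else g$seq
        segs <- c(segs, rand_bases(start0 - last_end, spec$background_gc),
                  genomic_seq)
        last_end <- start0 + L
        cursor <- last_end

        # local (0-based, sense) -> genomic (1-based) coordinate maps
        loc2gen <- function(p) {
          if (strand == "+") start0 + p + 1L else start0 + (L - 1L - p) + 1L
        }
        ex_g <- t(apply(g$exons, 1L, function(e) {
          a <- loc2gen(e[1L]); b <- loc2gen(e[2L] - 1L)
          sort(c(a, b))
        }))
        ex_g <- ex_g[order(ex_g[, 1L]), , drop = FALSE]
        gstart <- start0 + 1L; gend <- start0 + L

        gff_lines <- c(gff_lines,
          sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=protein_coding",
                  chrom_names[ci], gstart, gend, strand, gene_id),
          sprintf("%s\tsynthetic\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                  chrom_names[ci], gstart, gend, strand, tx_id, gene_id),
          sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                  chrom_names[ci], ex_g[, 1L], ex_g[, 2L], strand,
                  tx_id, seq_len(nrow(ex_g)), tx_id))

        truth[[gene_id]] <- data.frame(
          gene_id = gene_id, chrom = chrom_names[ci], strand = strand,
          start = gstart, end = gend,
          n_exons = nrow(g$exons),
          exon_starts = paste(ex_g[, 1L], collapse = ","),
          exon_ends = paste(ex_g[, 2L], collapse = ","),
          donor_local = paste(g$donors, collapse = ","),
          acceptor_local = paste(g$acceptors, collapse = ","),
          donor_genomic = paste(vapply(g$donors, loc2gen, 0L), collapse = ","),
          acceptor_genomic = paste(vapply(g$acceptors, loc2gen, 0L), collapse = ","),
          intron_classes = paste(g$intron_classes, collapse = ","),
          stringsAsFactors = FALSE)

        for (dc in g$decoys) {
          decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
            gene_id = gene_id, chrom = chrom_names[ci], strand = strand,
            kind = dc$kind,
            label_genomic = loc2gen(dc$label_local),
            mismatch_genomic = loc2gen(dc$mismatch_local),
            consensus_base = dc$consensus_base,
            stringsAsFactors = FALSE)
        }
      }
      segs <- c(segs, rand_bases(spec$chrom_length - last_end,
                                 spec$background_gc))
      fasta_seqs[ci] <- paste(segs, collapse = "")
    }

    names(fasta_seqs) <- chrom_names
    fasta_path <- file.path(dir, "genome.fa")
    gff_path <- file.path(dir, "annotation.gff3")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(fasta_seqs), fasta_path)
    writeLines(gff_lines, gff_path)
    truth_df <- do.call(rbind, truth); rownames(truth_df) <- NULL
    decoy_df <- if (length(decoy_rows)) do.call(rbind, decoy_rows) else
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), kind = character(0),
                 label_genomic = integer(0), mismatch_genomic = integer(0),
                 consensus_base = character(0))
    write_tsv_plain(truth_df, file.path(dir, "truth.tsv"), col.names = TRUE)

    list(fasta = fasta_path, gff = gff_path, dir = dir,
         truth = truth_df, decoys = decoy_df, spec = spec)
  })
}

# Parse comma-packed integer columns of the truth table.
truth_positions <- function(truth_row, what = c("donor_genomic",
                                                "acceptor_genomic",
                                                "donor_local",
                                                "acceptor_local")) {
  what <- match.arg(what)
  v <- truth_row[[what]]
  if (!nzchar(v)) return(integer(0))
  as.integer(strsplit(v, ",", fixed = TRUE)[[1L]])
}

#' Plant a splice-disrupting or cryptic-gain variant
#'
#' `donor_loss` / `acceptor_loss` mutate the invariant boundary dinucleotide
#' of a planted intron; `cryptic_gain` converts a planted near-consensus decoy
#' into a full consensus site. The returned record names the delta-score
#' channel expected to dominate.
#'
#' @param genome A `genome_seq` holding the synthetic genome.
#' @param truth Truth table from [generate_genome()].
#' @param kind One of `"donor_loss"`, `"acceptor_loss"`, `"cryptic_gain"`.
#' @param decoys Decoy table from [generate_genome()] (needed for
#'   `cryptic_gain`).
#' @param seed Integer seed for site selection.
#' @return List with `variant` (data.frame CHROM/POS/ID/REF/ALT, 1-based),
#'   `expected_channel`, and `gene_id`.
#' @export
plant_variant <- function(genome, truth, kind = c("donor_loss",
                                                  "acceptor_loss",
                                                  "cryptic_gain"),
                          decoys = NULL, seed = 1L) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "cryptic_gain") {
      if (is.null(decoys) || nrow(decoys) == 0L) {
        stop("no eligible decoy site for cryptic_gain")
      }
      row <- decoys[sample(nrow(decoys), 1L), ]
      pos <- row$mismatch_genomic
      ref <- genome_residues(genome, row$chrom, pos - 1L, pos)
      alt <- if (row$strand == "+") row$consensus_base else
        chartr("ACGT", "TGCA", row$consensus_base)
      expected <- if (row$kind == "donor") "DS_DG" else "DS_AG"
      gene_id <- row$gene_id
    } else {
      wanted <- if (kind == "donor_loss") "donor_genomic" else "acceptor_genomic"
      multi <- truth[truth$n_exons > 1L, ]
      if (nrow(multi) == 0L) stop("no eligible multi-exon gene")
      row <- multi[sample(nrow(multi), 1L), ]
      sites <- truth_positions(row, wanted)
      site <- sites[sample(length(sites), 1L)]
      # boundary dinucleotide: donor -> intron base +1 (the G of GT, sense),
      # acceptor -> intron base -1 (the G of AG, sense)
      sense_off <- if (kind == "donor_loss") 1L else -1L
      gen_off <- if (row$strand == "+") sense_off else -sense_off
      pos <- site + gen_off
      ref <- genome_residues(genome, row$chrom, pos - 1L, pos)
      alt_sense <- "A"  # G -> A kills both GT and AG motifs
      if (ref == (if (row$strand == "+") "G" else "C")) {
        alt <- if (row$strand == "+") alt_sense else
          chartr("ACGT", "TGCA", alt_sense)
      } else {
        # GC-AG / AT-AC boundary variants: just swap to a purine change
        alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
      }
      expected <- if (kind == "donor_loss") "DS_DL" else "DS_AL"
      gene_id <- row$gene_id
    }
    if (alt == ref) stop("planted variant equals the reference base")
    list(variant = data.frame(CHROM = row$chrom, POS = pos,
                              ID = paste0(kind, "_", gene_id),
                              REF = ref, ALT = alt, stringsAsFactors = FALSE),
         expected_channel = expected, gene_id = gene_id)
  })
}

#' Write variant records as a minimal VCF file
#'
#' @param variants data.frame with CHROM, POS, ID, REF, ALT columns.
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$CHROM, variants$POS, variants$ID,
                  variants$REF, variants$ALT)
  writeLines(c(hdr, body), path)
  invisible(path)
}
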