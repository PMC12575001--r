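# Genome FASTA / GFF-GTF annotation input, gene models, one-hot encoding.
#
# Coordinate conventions: annotation files are 1-based inclusive (GFF/GTF);
# positions handed to the encoder/labeler are 0-based; BED output is 0-based
# half-open.

#' Read a genome FASTA file
#'
#' Loads a (multi-)FASTA into an indexed genome object. Sequence names are
#' truncated at the first whitespace, matching common FASTA header usage.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome_seq` supporting [genome_residues()].
#' @export
read_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  structure(list(seqs = set), class = "genome_seq")
}

#' Build a genome object from named character sequences
#'
#' @param seqs Named character vector of sequences.
#' @return A `genome_seq` object.
#' @export
genome_from_strings <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  structure(list(seqs = Biostrings::DNAStringSet(vapply(seqs, normalize_seq, ""))),
            class = "genome_seq")
}

#' Sequence lengths of a genome
#' @param genome A `genome_seq` object.
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

#' Extract residues from a genome interval
#'
#' Returns the bases of the half-open, 0-based interval `[start, end)` of the
#' named sequence, normalized to the A/C/G/T/N alphabet.
#'
#' @param genome A `genome_seq` object.
#' @param name Sequence (chromosome) name.
#' @param start,end 0-based half-open interval, `0 <= start <= end <= length`.
#' @return Character scalar of length `end - start`.
#' @export
genome_residues <- function(genome, name, start, end) {
  if (!name %in% names(genome$seqs)) {
    stop("sequence '", name, "' not found in genome")
  }
  len <- length(genome$seqs[[name]])
  if (start < 0 || end < start || end > len) {
    stop("interval [", start, ",", end, ") out of bounds for '", name,
         "' (length ", len, ")")
  }
  if (end == start) return("")
  normalize_seq(as.character(Biostrings::subseq(genome$seqs[[name]],
                                                start + 1L, end)))
}

# --- gene models --------------------------------------------------------

new_transcript <- function(transcript_id, exons, strand) {
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, exons = exons, strand = strand),
            class = "transcript")
}

new_gene_model <- function(gene_id, seq_name, start, end, strand, biotype,
                           transcripts) {
  stopifnot(start <= end)
  structure(list(gene_id = gene_id, seq_name = seq_name, start = start,
                 end = end, strand = strand, biotype = biotype,
                 transcripts = transcripts),
            class = "gene_model")
}

#' Spliced (exonic) length of a transcript
#' @param tx A `transcript`.
#' @return Total exon length in bases.
#' @export
spliced_length <- function(tx) {
  sum(tx$exons[, 2L] - tx$exons[, 1L] + 1L)
}

# Detect annotation dialect from attribute syntax: GFF3 uses key=value,
# GTF uses key "value";
sniff_gff_dialect <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    if (grepl("^#", ln) || !nzchar(ln)) next
    attr_field <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(attr_field) < 9L) break
    a <- attr_field[9L]
    if (grepl("\\w+ +\"", a)) return("gtf")
    if (grepl("=", a, fixed = TRUE)) return("gff3")
    break
  }
  "gff3"
}

# Cheap structural validation so malformed lines are reported by number.
validate_gff_lines <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield < 8L]
  if (length(bad)) {
    stop("unparseable annotation line ", bad[1L], " in ", path,
         " (expected 9 tab-separated fields)")
  }
  invisible(TRUE)
}

#' Parse a GFF3/GTF annotation into gene models
#'
#' Resolves the gene -> transcript/mRNA -> exon hierarchy (via `ID`/`Parent`
#' in GFF3 or `gene_id`/`transcript_id` in GTF) and returns one gene model per
#' gene passing the biotype filter. Biotype is resolved from the
#' `gene_biotype` attribute, then `biotype`, then the feature type itself
#' (a bare `gene` feature defaults to protein_coding; `pseudogene`,
#' `lnc_RNA`, ... keep their type as biotype).
#'
#' @param gff_path Path to a GFF3 or GTF file.
#' @param biotype_filter `"protein-coding"` (default) or `"all"`.
#' @return List of `gene_model` objects.
#' @export
parse_annotation <- function(gff_path,
                             biotype_filter = c("protein-coding", "all")) {
  biotype_filter <- match.arg(biotype_filter)
  validate_gff_lines(gff_path)
  dialect <- sniff_gff_dialect(gff_path)
  gr <- rtracklayer::import(gff_path, format = if (dialect == "gtf") "gtf" else "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  get_col <- function(nm) if (nm %in% names(md)) as.character(md[[nm]]) else
    rep(NA_character_, length(gr))

  gene_like <- grepl("gene$", type) | type == "gene"
  tx_like <- type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA",
                         "primary_transcript", "pseudogenic_transcript")
  exon_like <- type == "exon"

  gene_biotype <- get_col("gene_biotype")
  biotype_attr <- get_col("biotype")
  resolve_biotype <- function(i) {
    if (!is.na(gene_biotype[i])) return(gene_biotype[i])
    if (!is.na(biotype_attr[i])) return(biotype_attr[i])
    if (type[i] == "gene") "protein_coding" else type[i]
  }

  if (dialect == "gff3") {
    ids <- get_col("ID")
    parents <- md$Parent
    parent1 <- vapply(seq_along(gr), function(i) {
      p <- parents[[i]]
      if (length(p)) as.character(p[1L]) else NA_character_
    }, "")
    gene_idx <- which(gene_like)
    gene_ids <- ids[gene_idx]
    tx_idx <- which(tx_like & parent1 %in% gene_ids)
    tx_ids <- ids[tx_idx]
    exon_idx <- which(exon_like & parent1 %in% tx_ids)
    tx_of_exon <- parent1[exon_idx]
    gene_of_tx <- stats::setNames(parent1[tx_idx], tx_ids)
  } else {
    gid <- get_col("gene_id")
    tid <- get_col("transcript_id")
    gene_idx <- which(gene_like)
    gene_ids <- gid[gene_idx]
    tx_idx <- which(tx_like)
    tx_ids <- tid[tx_idx]
    exon_idx <- which(exon_like & tid %in% tx_ids)
    tx_of_exon <- tid[exon_idx]
    gene_of_tx <- stats::setNames(gid[tx_idx], tx_ids)
  }

  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))

  genes <- list()
  for (j in seq_along(gene_idx)) {
    i <- gene_idx[j]
    gid_j <- gene_ids[j]
    bt <- resolve_biotype(i)
    if (biotype_filter == "protein-coding" &&
        !bt %in% c("protein_coding", "protein-coding")) {
      next
    }
    my_tx_ids <- names(gene_of_tx)[gene_of_tx == gid_j]
    txs <- list()
    for (t_id in my_tx_ids) {
      e <- exon_idx[tx_of_exon == t_id]
      if (!length(e)) next
      ex <- cbind(start = starts[e], end = ends[e])
      txs[[t_id]] <- new_transcript(t_id, ex, strands[i])
    }
    if (!length(txs)) {
      warning("gene ", gid_j, " has no exon-bearing transcript; skipped")
      next
    }
    genes[[gid_j]] <- new_gene_model(
      gene_id = gid_j, seq_name = chroms[i], start = starts[i], end = ends[i],
      strand = strands[i], biotype = bt, transcripts = txs)
  }
  unname(genes)
}

#' Select the canonical transcript of a gene
#'
#' The transcript with the largest spliced (exonic) length is canonical; ties
#' are broken by the lexicographically smallest transcript ID.
#'
#' @param gene A `gene_model` with at least one transcript.
#' @return A `transcript`.
#' @export
select_canonical <- function(gene) {
  stopifnot(length(gene$transcripts) >= 1L)
  lens <- vapply(gene$transcripts, spliced_length, numeric(1))
  ids <- vapply(gene$transcripts, `[[`, "", "transcript_id")
  best <- which(lens == max(lens))
  gene$transcripts[[best[order(ids[best])][1L]]]
}

#' Extract the sense-strand sequence of a gene
#'
#' Forward slice of the genome for `+` genes; reverse complement for `-`.
#'
#' @param genome A `genome_seq`.
#' @param gene A `gene_model`.
#' @return Character scalar of length `end - start + 1`.
#' @export
extract_gene_sequence <- function(genome, gene) {
  len <- genome_lengths(genome)[[gene$seq_name]]
  if (is.null(len) || gene$start < 1L || gene$end > len) {
    stop("gene ", gene$gene_id, " interval [", gene$start, ",", gene$end,
         "] out of bounds on ", gene$seq_name)
  }
  s <- genome_residues(genome, gene$seq_name, gene$start - 1L, gene$end)
  if (gene$strand == "-") revcomp(s) else s
}

# --- one-hot encoding ---------------------------------------------------

#' One-hot encode a nucleotide sequence
#'
#' A=\[1,0,0,0\], C=\[0,1,0,0\], G=\[0,0,1,0\], T/U=\[0,0,0,1\]; N and any
#' other symbol encode as \[0,0,0,0\]. Input is normalized first
#' (lowercase uppercased, U->T, IUPAC codes -> N).
#'
#' @param seq Character scalar.
#' @return Numeric matrix `nchar(seq) x 4`, channel order A,C,G,T.
#' @export
one_hot_encode <- function(seq) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  m <- matrix(0, nrow = n, ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  if (n == 0L) return(m)
  idx <- match(charToRaw(seq), charToRaw("ACGT"))
  keep <- which(!is.na(idx))
  m[cbind(keep, idx[keep])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot_encode()]: all-zero rows decode to N.
#'
#' @param m Numeric matrix with 4 columns (A,C,G,T).
#' @return Character scalar.
#' @export
one_hot_decode <- function(m) {
  if (nrow(m) == 0L) return("")
  bases <- c("A", "C", "G", "T")
  out <- bases[max.col(m, ties.method = "first")]
  out[rowSums(m) == 0] <- "N"
  paste(out, collapse = "")
}
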