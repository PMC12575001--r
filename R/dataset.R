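# Dataset construction: chromosome train/test splitting, pseudogene and
# paralog removal, splice-site labeling, fixed-window segmentation, and the
# batched dataset container (the `create-data` stage).

# Canonical intron boundary dinucleotide pairs (U2 major/minor + U12).
CANONICAL_INTRON_PAIRS <- c("GT-AG", "GC-AG", "AT-AC")

# Splice-label position convention, used consistently by labeling, BED
# output, evaluation, and ISM site selection: the donor label sits on the
# last exonic base upstream of the intron, the acceptor label on the first
# exonic base downstream of it.
SPLICE_LABEL_CONVENTION <- "exonic"

#' Split chromosomes into training and test sets
#'
#' `method = "human"` reproduces the fixed human partition (test chromosomes
#' 1, 3, 5, 7, 9; everything else trains). `method = "random"` shuffles
#' chromosomes with the given seed and accumulates them into the training set
#' until the cumulative length reaches `train_fraction` of the total; the
#' remainder becomes the test set.
#'
#' @param chromosomes data.frame with columns `name` and `length`.
#' @param method `"random"` (default) or `"human"`.
#' @param train_fraction Training proportion in (0,1); default 0.8.
#' @param seed Integer seed for the random method.
#' @return List with character vectors `train` and `test`.
#' @export
split_chromosomes <- function(chromosomes, method = c("random", "human"),
                              train_fraction = 0.8, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)),
            !anyDuplicated(chromosomes$name), all(chromosomes$length > 0),
            train_fraction > 0, train_fraction < 1)
  nm <- as.character(chromosomes$name)
  if (method == "human") {
    core <- sub("^chr", "", nm)
    test_keys <- c("1", "3", "5", "7", "9")
    train_keys <- c(as.character(c(2, 4, 6, 8, 10:22)), "X", "Y")
    unmatched <- nm[!core %in% c(test_keys, train_keys)]
    if (length(unmatched)) {
      stop("human split method cannot place chromosome(s): ",
           paste(unmatched, collapse = ", "))
    }
    return(list(train = nm[core %in% train_keys],
                test = nm[core %in% test_keys]))
  }
  with_seed(seed, {
    ord <- sample(length(nm))
    nm_s <- nm[ord]; len_s <- chromosomes$length[ord]
    total <- sum(as.numeric(len_s))
    cum <- cumsum(as.numeric(len_s))
    n_train <- which(cum >= train_fraction * total)[1L]
    train <- nm_s[seq_len(n_train)]
    test <- setdiff(nm_s, train)
    if (!length(test)) {
      warning("test set is empty: all chromosomes were needed to reach the ",
              "training fraction")
    }
    list(train = train, test = test)
  })
}

#' Remove pseudogenes from a gene collection
#'
#' Drops genes whose feature type or biotype is `pseudogene`,
#' `transcribed_pseudogene`, or `processed_pseudogene`.
#'
#' @param genes List of `gene_model` objects.
#' @return Filtered list.
#' @export
filter_pseudogenes <- function(genes) {
  bad <- c("pseudogene", "transcribed_pseudogene", "processed_pseudogene")
  Filter(function(g) !(g$biotype %in% bad), genes)
}

# --- paralog removal ----------------------------------------------------

# Shared k-mer set of a sequence (both orientations collapsed to the
# lexicographically smaller of k-mer / reverse complement).
canonical_kmers <- function(seq, k = 15L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

kmer_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

minimap2_available <- function() {
  nzchar(Sys.which("minimap2"))
}

# Align test sequences to training sequences with minimap2 (asm20 preset,
# tolerating ~20% divergence). Returns per-alignment identity
# (matches / alignment block length) and query coverage.
minimap2_hits <- function(test_seqs, train_seqs) {
  if (!minimap2_available()) {
    stop("minimap2 not found on PATH; use backend = \"kmer\" for the ",
         "built-in k-mer containment fallback")
  }
  td <- tempfile("paralog_"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "test.fa"); tf <- file.path(td, "train.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(test_seqs), qf)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(train_seqs), tf)
  paf <- file.path(td, "hits.paf")
  status <- system2("minimap2", c("-x", "asm20", "-c", "--secondary=yes",
                                  shQuote(tf), shQuote(qf)),
                    stdout = paf, stderr = FALSE)
  if (!identical(status, 0L)) {
    stop("minimap2 failed (exit ", status, "); use backend = \"kmer\" for ",
         "the built-in fallback")
  }
  lines <- readLines(paf)
  if (!length(lines)) {
    return(data.frame(test_id = character(0), train_id = character(0),
                      identity = numeric(0), coverage = numeric(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    test_id = vapply(f, `[[`, "", 1L),
    train_id = vapply(f, `[[`, "", 6L),
    identity = vapply(f, function(x) as.numeric(x[10L]) / as.numeric(x[11L]), 0),
    coverage = vapply(f, function(x)
      (as.numeric(x[4L]) - as.numeric(x[3L])) / as.numeric(x[2L]), 0),
    stringsAsFactors = FALSE)
}

#' Remove test genes paralogous to training genes
#'
#' Aligns each test gene sequence against the training sequences and drops
#' any test gene with an alignment whose identity and query coverage both
#' strictly exceed the thresholds. The default backend is minimap2 with the
#' high-divergence `asm20` preset; the `"kmer"` backend is a built-in 15-mer
#' containment fallback (Jaccard >= 0.8 is treated as exceeding both
#' thresholds).
#'
#' @param test_genes,train_genes Named lists of `labeled_gene` objects (or any
#'   lists with `gene_id` and `sequence` fields).
#' @param min_identity,min_coverage Thresholds in (0,1\]; default 0.8 each.
#' @param backend `"auto"` (minimap2 if available, else kmer), `"minimap2"`,
#'   or `"kmer"`.
#' @return List with `kept` (filtered test list) and `report` (data.frame of
#'   removals: test_id, train_id, identity, coverage).
#' @export
remove_paralogs <- function(test_genes, train_genes,
                            min_identity = 0.8, min_coverage = 0.8,
                            backend = c("auto", "minimap2", "kmer")) {
  backend <- match.arg(backend)
  if (backend == "auto") {
    backend <- if (minimap2_available()) "minimap2" else "kmer"
  }
  get_seq <- function(g) g$sequence
  get_id <- function(g) g$gene_id
  test_ids <- vapply(test_genes, get_id, "")
  stopifnot(all(nzchar(vapply(test_genes, get_seq, ""))) || !length(test_genes))

  if (!length(test_genes) || !length(train_genes)) {
    return(list(kept = test_genes,
                report = data.frame(test_id = character(0),
                                    train_id = character(0),
                                    identity = numeric(0),
                                    coverage = numeric(0))))
  }

  if (backend == "minimap2") {
    hits <- minimap2_hits(
      stats::setNames(vapply(test_genes, get_seq, ""), test_ids),
      stats::setNames(vapply(train_genes, get_seq, ""),
                      vapply(train_genes, get_id, "")))
    drop_hits <- hits[hits$identity > min_identity &
                        hits$coverage > min_coverage, , drop = FALSE]
  } else {
    train_km <- lapply(train_genes, function(g) canonical_kmers(get_seq(g)))
    rows <- list()
    for (i in seq_along(test_genes)) {
      tk <- canonical_kmers(get_seq(test_genes[[i]]))
      for (j in seq_along(train_genes)) {
        jc <- kmer_jaccard(tk, train_km[[j]])
        if (jc >= 0.8) {
          rows[[length(rows) + 1L]] <- data.frame(
            test_id = test_ids[i], train_id = get_id(train_genes[[j]]),
            identity = jc, coverage = jc, stringsAsFactors = FALSE)
        }
      }
    }
    drop_hits <- if (length(rows)) do.call(rbind, rows) else
      data.frame(test_id = character(0), train_id = character(0),
                 identity = numeric(0), coverage = numeric(0))
  }
  removed <- unique(drop_hits$test_id)
  list(kept = test_genes[!test_ids %in% removed], report = drop_hits)
}

# --- splice-site labeling -----------------------------------------------

#' Label splice sites on a gene sequence
#'
#' Each intron of the transcript contributes a donor label on the last exonic
#' base upstream of it and an acceptor label on the first exonic base
#' downstream of it. With `canonical_only`, an intron is labeled only if its
#' terminal dinucleotides are GT-AG, GC-AG, or AT-AC.
#'
#' @param transcript A `transcript` (genomic 1-based exon intervals).
#' @param gene_sequence Sense-strand gene sequence.
#' @param gene_start,gene_end 1-based genomic gene interval the sequence was
#'   extracted from.
#' @param strand `"+"` or `"-"`.
#' @param canonical_only Restrict labels to canonical boundary motifs.
#' @param gene_id Identifier carried into the result.
#' @return A `labeled_gene`: `sequence`, integer `labels` (0 none,
#'   1 acceptor, 2 donor), 0-based `donor_positions` / `acceptor_positions`.
#' @export
label_splice_sites <- function(transcript, gene_sequence, gene_start, gene_end,
                               strand = transcript$strand,
                               canonical_only = FALSE,
                               gene_id = transcript$transcript_id) {
  L <- nchar(gene_sequence)
  ex <- transcript$exons
  if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L])) {
    stop("overlapping exons in transcript ", transcript$transcript_id)
  }
  # genomic 1-based -> gene-local 0-based sense coordinates
  if (strand == "+") {
    loc <- cbind(ex[, 1L] - gene_start, ex[, 2L] - gene_start)
  } else {
    loc <- cbind(gene_end - ex[, 2L], gene_end - ex[, 1L])
  }
  loc <- loc[order(loc[, 1L]), , drop = FALSE]
  if (any(loc < 0L) || any(loc >= L)) {
    stop("transcript ", transcript$transcript_id,
         " exons fall outside the gene interval")
  }
  labels <- integer(L)
  donors <- integer(0); acceptors <- integer(0)
  if (nrow(loc) > 1L) {
    for (i in seq_len(nrow(loc) - 1L)) {
      don <- loc[i, 2L]          # last exonic base (0-based)
      acc <- loc[i + 1L, 1L]     # first exonic base of next exon
      intron_start <- don + 1L; intron_end <- acc - 1L
      if (intron_end < intron_start) next
      d5 <- substr(gene_sequence, intron_start + 1L, intron_start + 2L)
      a3 <- substr(gene_sequence, intron_end, intron_end + 1L)
      pair <- paste0(d5, "-", a3)
      if (canonical_only && !pair %in% CANONICAL_INTRON_PAIRS) next
      labels[don + 1L] <- 2L
      labels[acc + 1L] <- 1L
      donors <- c(donors, don)
      acceptors <- c(acceptors, acc)
    }
  }
  structure(list(gene_id = gene_id, sequence = gene_sequence, labels = labels,
                 donor_positions = donors, acceptor_positions = acceptors),
            class = "labeled_gene")
}

# --- segmentation -------------------------------------------------------

#' Segment a labeled gene into fixed training windows
#'
#' The gene is tiled with `ceil(L / core)` core windows of `core` bases;
#' each window is extended by `flank` bases of context on both sides.
#' Positions beyond the gene are N-padded (all-zero rows) in X and padding
#' rows (\[0,0,0\]) in Y.
#'
#' @param gene A `labeled_gene`.
#' @param core Core window size (default 5000).
#' @param flank Context on each side during dataset creation (default 5000).
#' @return List with `X` (array `segments x (core + 2*flank) x 4`), `Y`
#'   (array `segments x core x 3`), and `gene_id`.
#' @export
segment_gene <- function(gene, core = 5000L, flank = 5000L) {
  stopifnot(core > 0L, flank > 0L)
  L <- nchar(gene$sequence)
  if (L == 0L) stop("cannot segment a zero-length gene")
  n_seg <- as.integer(ceiling(L / core))
  pad_right <- n_seg * core + flank - L
  padded <- one_hot_encode(paste0(strrep("N", flank), gene$sequence,
                                  strrep("N", pad_right)))
  width <- core + 2L * flank
  X <- array(0, dim = c(n_seg, width, 4L))
  Y <- array(0, dim = c(n_seg, core, 3L))
  ylab <- matrix(0, nrow = L, ncol = 3L)
  ylab[cbind(seq_len(L), gene$labels + 1L)] <- 1
  for (i in seq_len(n_seg)) {
    s <- (i - 1L) * core
    X[i, , ] <- padded[(s + 1L):(s + width), ]
    core_real <- min(core, L - s)
    if (core_real > 0L) {
      Y[i, seq_len(core_real), ] <- ylab[(s + 1L):(s + core_real), ]
    }
  }
  list(gene_id = gene$gene_id, X = X, Y = Y)
}

# --- dataset container --------------------------------------------------

#' Assemble an encoded dataset from labeled genes
#'
#' @param genes List of `labeled_gene` objects.
#' @param core,flank Segmentation parameters (see [segment_gene()]).
#' @return An `encoded_dataset`: list of per-gene segment blocks.
#' @export
encode_dataset <- function(genes, core = 5000L, flank = 5000L) {
  structure(list(genes = lapply(genes, segment_gene, core = core,
                                flank = flank),
                 core = core, flank = flank),
            class = "encoded_dataset")
}

#' Write / read an encoded dataset
#'
#' The on-disk container concatenates genes into stacked X/Y groups of
#' `batch_size` genes each (default 100) with a gene index, and round-trips
#' losslessly. Files are native R serialization (`.rds`).
#'
#' @param ds An `encoded_dataset`.
#' @param path Output file path.
#' @param batch_size Genes per stacked group.
#' @return `path` invisibly (`write_dataset`); the dataset (`read_dataset`).
#' @export
write_dataset <- function(ds, path, batch_size = 100L) {
  stopifnot(inherits(ds, "encoded_dataset"), batch_size >= 1L)
  n <- length(ds$genes)
  n_batches <- if (n == 0L) 0L else as.integer(ceiling(n / batch_size))
  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    gs <- ds$genes[idx]
    segs <- vapply(gs, function(g) dim(g$X)[1L], 0L)
    X <- do.call(abind1, lapply(gs, `[[`, "X"))
    Y <- do.call(abind1, lapply(gs, `[[`, "Y"))
    batches[[b]] <- list(X = X, Y = Y,
                         gene_ids = vapply(gs, `[[`, "", "gene_id"),
                         segments_per_gene = segs)
  }
  saveRDS(list(format = "spliceml-dataset", version = 1L,
               core = ds$core, flank = ds$flank, batches = batches),
          path)
  invisible(path)
}

# Bind arrays along the first dimension.
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  total <- sum(vapply(parts, function(p) dim(p)[1L], 0L))
  out <- array(0, dim = c(total, d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1L]
    if (n > 0L) out[(at + 1L):(at + n), , ] <- p
    at <- at + n
  }
  out
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt dataset file ", path, ": ", conditionMessage(e))
  })
  if (!identical(obj$format, "spliceml-dataset")) {
    stop("corrupt dataset file ", path, ": missing key 'format'")
  }
  genes <- list()
  for (b in obj$batches) {
    at <- 0L
    for (i in seq_along(b$gene_ids)) {
      n <- b$segments_per_gene[i]
      genes[[length(genes) + 1L]] <- list(
        gene_id = b$gene_ids[i],
        X = b$X[(at + 1L):(at + n), , , drop = FALSE],
        Y = b$Y[(at + 1L):(at + n), , , drop = FALSE])
      at <- at + n
    }
  }
  structure(list(genes = genes, core = obj$core, flank = obj$flank,
                 n_batches = length(obj$batches)),
            class = "encoded_dataset")
}

# --- create-data pipeline -----------------------------------------------

#' Build train/test splice-site datasets from FASTA + GFF
#'
#' End-to-end dataset creation: parse annotation, filter biotypes and
#' pseudogenes, pick the canonical transcript per gene, extract sense-strand
#' sequences, label splice sites, split chromosomes, optionally remove test
#' paralogs, segment, and write the two dataset files plus a removal report.
#'
#' @param genome_fasta,annotation_gff Input file paths.
#' @param output_dir Output directory.
#' @param biotype `"protein-coding"` or `"all"`.
#' @param split_method `"random"` or `"human"`.
#' @param train_fraction Training proportion for the random split.
#' @param remove_paralogs Drop test genes paralogous to training genes.
#' @param min_identity,min_coverage Paralog thresholds.
#' @param paralog_backend See [remove_paralogs()].
#' @param canonical_only Restrict labels to canonical intron motifs.
#' @param write_fasta Also dump train/test gene sequences as FASTA.
#' @param seed Integer seed (chromosome shuffling).
#' @return List with dataset paths, per-split labeled genes, and label counts.
#' @export
create_data <- function(genome_fasta, annotation_gff, output_dir,
                        biotype = c("protein-coding", "all"),
                        split_method = c("random", "human"),
                        train_fraction = 0.8,
                        remove_paralogs = FALSE,
                        min_identity = 0.8, min_coverage = 0.8,
                        paralog_backend = "auto",
                        canonical_only = FALSE,
                        write_fasta = FALSE,
                        seed = 1L) {
  biotype <- match.arg(biotype)
  split_method <- match.arg(split_method)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_genome(genome_fasta)
  genes <- parse_annotation(annotation_gff, biotype_filter = biotype)
  genes <- filter_pseudogenes(genes)

  labeled <- lapply(genes, function(g) {
    tx <- select_canonical(g)
    seq <- extract_gene_sequence(genome, g)
    lg <- label_splice_sites(tx, seq, g$start, g$end, strand = g$strand,
                             canonical_only = canonical_only,
                             gene_id = g$gene_id)
    lg$seq_name <- g$seq_name
    lg
  })

  chroms <- data.frame(name = names(genome_lengths(genome)),
                       length = unname(genome_lengths(genome)))
  split <- split_chromosomes(chroms, method = split_method,
                             train_fraction = train_fraction, seed = seed)
  chrom_of <- vapply(labeled, `[[`, "", "seq_name")
  train_genes <- labeled[chrom_of %in% split$train]
  test_genes <- labeled[chrom_of %in% split$test]

  report <- data.frame(test_id = character(0), train_id = character(0),
                       identity = numeric(0), coverage = numeric(0))
  if (isTRUE(remove_paralogs) && length(test_genes)) {
    pr <- remove_paralogs(test_genes, train_genes,
                          min_identity = min_identity,
                          min_coverage = min_coverage,
                          backend = paralog_backend)
    test_genes <- pr$kept
    report <- pr$report
  }

  train_ds <- encode_dataset(train_genes)
  test_ds <- encode_dataset(test_genes)
  train_path <- file.path(output_dir, "dataset_train.rds")
  test_path <- file.path(output_dir, "dataset_test.rds")
  write_dataset(train_ds, train_path)
  write_dataset(test_ds, test_path)
  write_tsv_plain(report, file.path(output_dir, "paralog_removal.tsv"),
                  col.names = TRUE)
  if (isTRUE(write_fasta)) {
    for (side in c("train", "test")) {
      gs <- if (side == "train") train_genes else test_genes
      if (length(gs)) {
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(stats::setNames(
            vapply(gs, `[[`, "", "sequence"),
            vapply(gs, `[[`, "", "gene_id"))),
          file.path(output_dir, paste0("genes_", side, ".fa")))
      }
    }
  }
  count_labels <- function(gs) c(
    donor = sum(vapply(gs, function(g) length(g$donor_positions), 0L)),
    acceptor = sum(vapply(gs, function(g) length(g$acceptor_positions), 0L)))
  list(train_path = train_path, test_path = test_path,
       train_genes = train_genes, test_genes = test_genes,
       split = split, paralog_report = report,
       label_counts = list(train = count_labels(train_genes),
                           test = count_labels(test_genes)))
}
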