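# Windowed, ensemble-averaged prediction over sequences with BED output, and
# VCF variant annotation with splice delta scores.

#' Plan prediction windows over a sequence
#'
#' Tiles the sequence with non-overlapping 5000 nt cores; each window adds
#' `flank/2` context on both sides (windows therefore overlap), N-padding
#' where context runs past the sequence ends. Sequences longer than
#' `split_threshold` are processed in chunks that overlap by `flank/2` so
#' padding never touches interior cores; the chunking affects memory use
#' only, never the scores.
#'
#' @param seq_len Sequence length in bases (> 0).
#' @param flank Model flanking size.
#' @param core Core size (default 5000).
#' @param split_threshold Maximum chunk length (default 1,500,000).
#' @return A `window_plan`: data.frame with columns `core_start`, `core_end`
#'   (0-based half-open), `seq_start`, `seq_end` (clipped context interval),
#'   `left_pad`, `right_pad`, `chunk`.
#' @export
plan_windows <- function(seq_len, flank, core = 5000L,
                         split_threshold = 1500000L) {
  stopifnot(seq_len > 0L, flank >= 2L, flank %% 2L == 0L)
  half <- flank %/% 2L
  width <- core + flank
  n <- as.integer(ceiling(seq_len / core))
  rows <- lapply(seq_len(n) - 1L, function(i) {
    cs <- i * core
    ce <- min(cs + core, seq_len)
    ws <- cs - half
    we <- cs + core + half
    ss <- max(0L, ws); se <- min(seq_len, we)
    data.frame(core_start = cs, core_end = ce,
               seq_start = ss, seq_end = se,
               left_pad = ss - ws, right_pad = we - se,
               chunk = (cs %/% max(split_threshold, core)) + 1L)
  })
  plan <- do.call(rbind, rows)
  stopifnot(all(plan$left_pad + (plan$seq_end - plan$seq_start) +
                  plan$right_pad == width))
  structure(plan, class = c("window_plan", "data.frame"),
            flank = flank, core = core, seq_len = seq_len)
}

#' Predict per-base splice probabilities for a sequence
#'
#' Runs each window of the plan through every model, averages the
#' probabilities across models (deep-ensemble averaging), and concatenates
#' the window cores so every input base receives a score.
#'
#' @param models A `splice_model` or list of models sharing one flanking
#'   size.
#' @param seq Nucleotide sequence (character scalar).
#' @param split_threshold See [plan_windows()].
#' @return A `prediction_track`: list with numeric vectors `none`,
#'   `acceptor`, `donor` of length `nchar(seq)`.
#' @export
predict_track <- function(models, seq, split_threshold = 1500000L) {
  models <- as_model_list(models)
  if (!nchar(seq)) stop("cannot predict on an empty sequence")
  seq <- normalize_seq(seq)
  flank <- models[[1L]]$config$flank
  L <- nchar(seq)
  plan <- plan_windows(L, flank, split_threshold = split_threshold)
  acc <- numeric(L); don <- numeric(L); none <- numeric(L)
  for (w in seq_len(nrow(plan))) {
    r <- plan[w, ]
    body <- if (r$seq_end > r$seq_start)
      substr(seq, r$seq_start + 1L, r$seq_end) else ""
    win_seq <- paste0(strrep("N", r$left_pad), body, strrep("N", r$right_pad))
    x <- one_hot_encode(win_seq)
    p <- NULL
    for (m in models) {
      pm <- model_forward(m, x)
      p <- if (is.null(p)) pm else p + pm
    }
    p <- p / length(models)
    # model output row j corresponds to window position flank/2 + j, i.e.
    # core offset j
    n_core <- r$core_end - r$core_start
    idx <- (r$core_start + 1L):(r$core_end)
    none[idx] <- p[seq_len(n_core), 1L]
    acc[idx] <- p[seq_len(n_core), 2L]
    don[idx] <- p[seq_len(n_core), 3L]
  }
  structure(list(none = none, acceptor = acc, donor = don, length = L),
            class = "prediction_track")
}

as_model_list <- function(models) {
  if (inherits(models, "splice_model")) models <- list(models)
  stopifnot(length(models) >= 1L)
  flanks <- vapply(models, function(m) m$config$flank, 0L)
  if (length(unique(flanks)) != 1L) {
    stop("all ensemble models must share one flanking size; got ",
         paste(unique(flanks), collapse = ", "))
  }
  models
}

#' Call splice sites from a prediction track
#'
#' Emits one BED record (0-based half-open, single-base intervals) per
#' position whose probability exceeds the threshold; the score column carries
#' the probability. `offset` maps sequence-relative positions to genomic
#' coordinates when predictions were made on an extracted gene locus.
#'
#' @param track A `prediction_track`.
#' @param threshold Probability threshold (default 0.5).
#' @param seq_name Chromosome/sequence name for the BED records.
#' @param offset 0-based genomic offset added to positions.
#' @param strand Strand field for the BED records.
#' @return List with data.frames `donor` and `acceptor` (chrom, start, end,
#'   name, score, strand).
#' @export
call_sites <- function(track, threshold = 0.5, seq_name = "seq",
                       offset = 0L, strand = ".") {
  one <- function(scores, label) {
    hit <- which(scores > threshold)
    data.frame(chrom = rep(seq_name, length(hit)),
               start = offset + hit - 1L, end = offset + hit,
               name = if (length(hit))
                 paste0(label, "_", seq_along(hit)) else character(0),
               score = scores[hit], strand = rep(strand, length(hit)),
               stringsAsFactors = FALSE)
  }
  list(donor = one(track$donor, "donor"), acceptor = one(track$acceptor,
                                                         "acceptor"))
}

#' Write BED records
#' @param bed data.frame as produced by [call_sites()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_bed <- function(bed, path) {
  write_tsv_plain(bed, path)
  invisible(path)
}

# --- variant delta scores -----------------------------------------------

#' Delta scores from aligned reference/alternate score arrays
#'
#' Given acceptor and donor probability arrays over the same window of
#' reference coordinates for the reference and alternate alleles, the four
#' delta scores are the maxima `DS_AG = max(a_alt - a_ref)`,
#' `DS_AL = max(a_ref - a_alt)`, `DS_DG = max(d_alt - d_ref)`,
#' `DS_DL = max(d_ref - d_alt)`, clamped at 0. Each delta position is the
#' offset of the maximum relative to the variant (ties: smallest absolute
#' offset, then upstream).
#'
#' @param a_ref,a_alt,d_ref,d_alt Numeric arrays of equal length.
#' @param offsets Integer offsets of the array positions relative to the
#'   variant (default symmetric around 0).
#' @return A `delta_scores` list: DS_AG, DS_AL, DS_DG, DS_DL, DP_AG, DP_AL,
#'   DP_DG, DP_DL.
#' @export
delta_scores <- function(a_ref, a_alt, d_ref, d_alt,
                         offsets = seq_along(a_ref) -
                           (length(a_ref) + 1L) %/% 2L) {
  stopifnot(length(a_ref) == length(a_alt),
            length(d_ref) == length(d_alt),
            length(a_ref) == length(d_ref),
            length(offsets) == length(a_ref))
  pick <- function(diff) {
    mx <- max(diff)
    if (mx <= 0) return(list(ds = 0, dp = 0L))
    at <- which(diff == mx)
    at <- at[order(abs(offsets[at]), offsets[at])][1L]
    list(ds = mx, dp = offsets[at])
  }
  ag <- pick(a_alt - a_ref); al <- pick(a_ref - a_alt)
  dg <- pick(d_alt - d_ref); dl <- pick(d_ref - d_alt)
  structure(list(DS_AG = ag$ds, DS_AL = al$ds, DS_DG = dg$ds, DS_DL = dl$ds,
                 DP_AG = ag$dp, DP_AL = al$dp, DP_DG = dg$dp, DP_DL = dl$dp),
            class = "delta_scores")
}

#' Check whether a variant is eligible for delta-score annotation
#'
#' Ineligible: outside every annotated gene, closer than `flank` to a
#' chromosome end, or a deletion longer than `2 * distance`.
#'
#' @param variant List/row with `CHROM`, `POS` (1-based), `REF`, `ALT`.
#' @param genes List of `gene_model` objects.
#' @param chrom_len Length of the variant's chromosome.
#' @param flank Model flanking size.
#' @param distance Scoring window half-width.
#' @return List with `eligible` (logical), `reason` (NA when eligible), and
#'   `gene` (the containing gene model or NULL).
#' @export
variant_eligibility <- function(variant, genes, chrom_len, flank,
                                distance = 50L) {
  pos <- as.integer(variant$POS)
  hit <- NULL
  for (g in genes) {
    if (g$seq_name == variant$CHROM && pos >= g$start && pos <= g$end) {
      hit <- g; break
    }
  }
  if (is.null(hit)) {
    return(list(eligible = FALSE, reason = "outside gene", gene = NULL))
  }
  if (pos <= flank || pos > chrom_len - flank) {
    return(list(eligible = FALSE, reason = "too close to chromosome end",
                gene = hit))
  }
  del_len <- nchar(variant$REF) - nchar(variant$ALT)
  if (del_len > 2L * distance) {
    return(list(eligible = FALSE, reason = "deletion longer than 2x distance",
                gene = hit))
  }
  list(eligible = TRUE, reason = NA_character_, gene = hit)
}

#' Score a variant's effect on splicing
#'
#' Builds reference and alternate sequences centered on the variant with full
#' genomic flanking context, collects acceptor/donor probabilities over the
#' `2*distance + 1` positions around the variant (aligned to reference
#' coordinates; inserted positions are skipped and deleted positions take the
#' score at the deletion junction), and returns the four delta scores and
#' positions. Scoring runs on the gene's sense strand.
#'
#' @param models Model or ensemble (see [predict_track()]).
#' @param genome A `genome_seq`.
#' @param variant List/row with `CHROM`, `POS` (1-based), `REF`, `ALT`.
#' @param gene The containing `gene_model` (determines the strand).
#' @param distance Window half-width (default 50: 101 positions scored).
#' @return A `delta_scores` object.
#' @export
score_variant <- function(models, genome, variant, gene, distance = 50L) {
  models <- as_model_list(models)
  flank <- models[[1L]]$config$flank
  half <- flank %/% 2L
  chrom <- variant$CHROM
  pos0 <- as.integer(variant$POS) - 1L             # 0-based
  ref <- toupper(variant$REF); alt <- toupper(variant$ALT)
  rlen <- nchar(ref); alen <- nchar(alt)
  clen <- genome_lengths(genome)[[chrom]]

  obs <- genome_residues(genome, chrom, pos0, min(pos0 + rlen, clen))
  if (!identical(obs, ref)) {
    stop("reference allele mismatch at ", chrom, ":", pos0 + 1L,
         " (VCF says ", ref, ", genome has ", obs, ")")
  }

  w_start <- pos0 - distance - half
  w_end <- pos0 + rlen + distance + half
  pad_l <- max(0L, -w_start); pad_r <- max(0L, w_end - clen)
  body <- genome_residues(genome, chrom, max(0L, w_start), min(clen, w_end))
  ref_seq <- paste0(strrep("N", pad_l), body, strrep("N", pad_r))
  var_at <- pos0 - w_start                         # 0-based offset in ref_seq
  alt_seq <- paste0(substr(ref_seq, 1L, var_at),
                    alt,
                    substr(ref_seq, var_at + rlen + 1L, nchar(ref_seq)))

  minus <- identical(gene$strand, "-")
  score_arrays <- function(s) {
    if (minus) s <- revcomp(s)
    p <- model_ensemble_probs(models, one_hot_encode(s))
    if (minus) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    p  # rows now indexed in forward (plus-strand) orientation
  }
  p_ref <- score_arrays(ref_seq)   # rows cover ref_seq positions half..(n-half)
  p_alt <- score_arrays(alt_seq)

  # probability of forward position i (0-based in ref_seq) = row i - half + 1
  ref_row <- function(i) i - half + 1L
  offs <- (-distance):(distance)
  n_off <- length(offs)
  a_ref <- d_ref <- a_alt <- d_alt <- numeric(n_off)
  shift <- alen - rlen
  for (k in seq_len(n_off)) {
    o <- offs[k]
    i_ref <- var_at + o
    a_ref[k] <- p_ref[ref_row(i_ref), 2L]
    d_ref[k] <- p_ref[ref_row(i_ref), 3L]
    # map the reference coordinate into the alternate sequence
    i_alt <- if (o < 0L) i_ref
      else if (o < rlen && o >= alen) var_at + alen - 1L  # deleted: junction
      else if (o < rlen) i_ref                            # within both alleles
      else i_ref + shift                                  # downstream
    i_alt <- min(max(i_alt, 0L), nchar(alt_seq) - 1L)
    a_alt[k] <- p_alt[ref_row(i_alt), 2L]
    d_alt[k] <- p_alt[ref_row(i_alt), 3L]
  }
  delta_scores(a_ref, a_alt, d_ref, d_alt, offsets = offs)
}

# Ensemble-averaged probabilities for a single one-hot matrix.
model_ensemble_probs <- function(models, x) {
  p <- NULL
  for (m in models) {
    pm <- model_forward(m, x)
    if (!is.null(m$temperature)) {
      pm <- scale_probs(model_logits(m, x), m$temperature)
    }
    p <- if (is.null(p)) pm else p + pm
  }
  p / length(models)
}

#' Annotate a VCF with splice delta scores
#'
#' Preserves all input records; eligible records gain an INFO field
#' `SpliceDelta=ALT|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL` and the
#' header gains its definition. Ineligible records pass through unchanged.
#'
#' @param vcf_in,vcf_out Input/output VCF paths (plain text).
#' @param genome A `genome_seq`.
#' @param genes List of `gene_model` objects (the annotation).
#' @param models Model or ensemble.
#' @param distance Scoring window half-width.
#' @return data.frame summary: one row per record with eligibility and
#'   scores.
#' @export
annotate_vcf <- function(vcf_in, vcf_out, genome, genes, models,
                         distance = 50L) {
  models <- as_model_list(models)
  flank <- models[[1L]]$config$flank
  lines <- readLines(vcf_in)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]; body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  info_def <- paste0(
    "##INFO=<ID=SpliceDelta,Number=.,Type=String,Description=",
    "\"Splice delta scores: ALT|DS_AG|DS_AL|DS_DG|DS_DL|",
    "DP_AG|DP_AL|DP_DG|DP_DL\">")
  chrom_line <- grepl("^#CHROM", hdr)
  if (!any(chrom_line)) stop("malformed VCF: no #CHROM header line")
  hdr <- append(hdr, info_def, after = which(chrom_line)[1L] - 1L)

  out_body <- character(length(body))
  rows <- list()
  lens <- genome_lengths(genome)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[2L])))) {
      stop("malformed VCF record ", i, " in ", vcf_in)
    }
    v <- list(CHROM = f[1L], POS = as.integer(f[2L]), REF = f[4L],
              ALT = f[5L])
    el <- variant_eligibility(v, genes, lens[[v$CHROM]] %||% 0L, flank,
                              distance)
    if (el$eligible) {
      ds <- score_variant(models, genome, v, el$gene, distance)
      tag <- sprintf("SpliceDelta=%s|%.4f|%.4f|%.4f|%.4f|%d|%d|%d|%d",
                     v$ALT, ds$DS_AG, ds$DS_AL, ds$DS_DG, ds$DS_DL,
                     ds$DP_AG, ds$DP_AL, ds$DP_DG, ds$DP_DL)
      f[8L] <- if (f[8L] %in% c(".", "")) tag else paste0(f[8L], ";", tag)
      rows[[i]] <- data.frame(CHROM = v$CHROM, POS = v$POS, eligible = TRUE,
                              reason = NA_character_,
                              DS_AG = ds$DS_AG, DS_AL = ds$DS_AL,
                              DS_DG = ds$DS_DG, DS_DL = ds$DS_DL)
    } else {
      rows[[i]] <- data.frame(CHROM = v$CHROM, POS = v$POS, eligible = FALSE,
                              reason = el$reason,
                              DS_AG = NA_real_, DS_AL = NA_real_,
                              DS_DG = NA_real_, DS_DL = NA_real_)
    }
    out_body[i] <- paste(f, collapse = "\t")
  }
  writeLines(c(hdr, out_body), vcf_out)
  do.call(rbind, rows)
}
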