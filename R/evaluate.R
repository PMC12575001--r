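# Model-quality metrics (top-k accuracy, confusion metrics, AUPRC) and
# in-silico mutagenesis: per-base importance profiles, batch motif matrices,
# and profile concordance.

#' Top-k accuracy for a splice-site class
#'
#' Takes the `k * n_true` highest-scoring positions of a class and returns
#' the fraction of them that are annotated sites. Ties at the cutoff are
#' included with the denominator unchanged (default), or resolved by stable
#' truncation.
#'
#' @param scores Numeric vector of per-position scores for the class.
#' @param true_sites Integer vector of 0-based true-site positions.
#' @param k Multiplier (default 1).
#' @param ties `"all"` (include all score-tied positions at the cutoff) or
#'   `"truncate"`.
#' @return Fraction in \[0, 1\], or `NA` when there are no true sites.
#' @export
topk_accuracy <- function(scores, true_sites, k = 1,
                          ties = c("all", "truncate")) {
  ties <- match.arg(ties)
  n_true <- length(true_sites)
  if (n_true == 0L) return(NA_real_)
  n_take <- min(round(k * n_true), length(scores))
  ord <- order(scores, decreasing = TRUE)
  if (ties == "all") {
    cutoff <- scores[ord[n_take]]
    taken <- which(scores >= cutoff)
  } else {
    taken <- ord[seq_len(n_take)]
  }
  sum((taken - 1L) %in% true_sites) / (k * n_true)
}

# Step-wise average precision over a ranked list (no interpolation).
average_precision <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  n_pos <- sum(pos)
  if (n_pos == 0L) return(NA_real_)
  tp <- cumsum(pos)
  precision <- tp / seq_along(pos)
  sum(precision[pos]) / n_pos
}

#' Per-class confusion metrics and AUPRC
#'
#' One-vs-rest at the score threshold: `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, F1 their harmonic mean,
#' `accuracy = (TP+TN)/total`; AUPRC by step-wise average precision over the
#' ranked positions.
#'
#' @param scores `(N, 3)` probability matrix (none, acceptor, donor).
#' @param labels Integer labels (0 none, 1 acceptor, 2 donor).
#' @param threshold Score threshold (default 0.5); a position is called
#'   positive for a class when its score exceeds it.
#' @return data.frame with one row per class (acceptor, donor): tp, fp, fn,
#'   tn, accuracy, precision, recall, f1, auprc. Undefined ratios are `NA`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(nrow(scores) == length(labels))
  out <- list()
  for (cls in c(1L, 2L)) {  # acceptor, donor
    sc <- scores[, cls + 1L]
    truth <- labels == cls
    called <- sc > threshold
    tp <- sum(called & truth); fp <- sum(called & !truth)
    fn <- sum(!called & truth); tn <- sum(!called & !truth)
    precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      class = c("acceptor", "donor")[cls],
      tp = tp, fp = fp, fn = fn, tn = tn,
      accuracy = (tp + tn) / length(truth),
      precision = precision, recall = recall, f1 = f1,
      auprc = average_precision(sc, truth))
  }
  do.call(rbind, out)
}

# Score of a single site (0-based position, class "acceptor"/"donor") within
# a sequence, using ensemble-averaged probabilities over a minimal context.
site_score <- function(models, seq, site_pos, site_class) {
  flank <- models[[1L]]$config$flank
  half <- flank %/% 2L
  L <- nchar(seq)
  s <- site_pos - half; e <- site_pos + half
  body <- substr(seq, max(0L, s) + 1L, min(L, e + 1L))
  ctx <- paste0(strrep("N", max(0L, -s)), body, strrep("N", max(0L, e - L + 1L)))
  p <- model_ensemble_probs(models, one_hot_encode(ctx))
  p[1L, if (site_class == "acceptor") 2L else 3L]
}

#' In-silico mutagenesis importance profile around a splice site
#'
#' Substitutes each position in a window centered on the site with each of
#' the four bases, re-scores the site, and records the score drop. The
#' importance at a position is `S_ref - mean(S_A, S_C, S_G, S_T)` (the
#' reference base's "substitution" scores `S_ref` itself); it may be
#' negative when mutations increase the site score.
#'
#' @param models Model or ensemble.
#' @param seq Sequence containing the site (real genomic context preferred
#'   over N-padding).
#' @param site_pos 0-based position of the labeled site.
#' @param site_class `"acceptor"` or `"donor"`.
#' @param window Half-width of the mutated window in bases.
#' @return An `ism_profile`: list with `positions` (0-based), `importance`,
#'   `drops` (`(2*window+1) x 4` matrix of `S_ref - S_base`), `s_ref`,
#'   `site_pos`, `site_class`.
#' @export
ism_importance <- function(models, seq, site_pos,
                           site_class = c("acceptor", "donor"), window = 40L) {
  site_class <- match.arg(site_class)
  models <- as_model_list(models)
  seq <- normalize_seq(seq)
  L <- nchar(seq)
  if (site_pos - window < 0L || site_pos + window >= L) {
    stop("ISM window exceeds the sequence; provide more flanking context")
  }
  bases <- c("A", "C", "G", "T")
  positions <- (site_pos - window):(site_pos + window)
  s_ref <- site_score(models, seq, site_pos, site_class)
  scores <- matrix(NA_real_, length(positions), 4L,
                   dimnames = list(NULL, bases))
  for (pi in seq_along(positions)) {
    p <- positions[pi]
    ref_base <- substr(seq, p + 1L, p + 1L)
    for (b in bases) {
      if (b == ref_base) {
        scores[pi, b] <- s_ref
      } else {
        mut <- seq
        substr(mut, p + 1L, p + 1L) <- b
        scores[pi, b] <- site_score(models, mut, site_pos, site_class)
      }
    }
  }
  importance <- s_ref - rowMeans(scores)
  structure(list(positions = positions, importance = importance,
                 drops = s_ref - scores, s_ref = s_ref,
                 site_pos = site_pos, site_class = site_class),
            class = "ism_profile")
}

#' Mean mutational score-drop matrix across splice sites
#'
#' Averages, across center-aligned sites, the raw decrease in the central
#' site's score caused by each point substitution at each position; the
#' result is a position x base matrix suitable for sequence-logo rendering.
#'
#' @param models Model or ensemble.
#' @param sites List of site records: each a list with `seq` (sequence of
#'   length `seq_len` with the splice motif at the midpoint), `site_pos`
#'   (0-based site position within `seq`), and `class`.
#' @param shown_window Number of central positions to return (default 80).
#' @return `(shown_window, 4)` matrix of mean score drops (columns A,C,G,T).
#' @export
motif_matrix <- function(models, sites, shown_window = 80L) {
  if (!length(sites)) stop("no sites supplied")
  models <- as_model_list(models)
  half <- shown_window %/% 2L
  acc <- NULL
  for (s in sites) {
    prof <- ism_importance(models, s$seq, s$site_pos, s$class, window = half)
    d <- prof$drops[seq_len(shown_window), , drop = FALSE]
    acc <- if (is.null(acc)) d else acc + d
  }
  acc / length(sites)
}

#' Pearson correlation between two ISM importance profiles
#'
#' @param a,b `ism_profile` objects (or numeric vectors) with equal window
#'   lengths.
#' @return Pearson correlation coefficient.
#' @export
profile_correlation <- function(a, b) {
  va <- if (inherits(a, "ism_profile")) a$importance else a
  vb <- if (inherits(b, "ism_profile")) b$importance else b
  stopifnot(length(va) == length(vb))
  stats::cor(va, vb)
}
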