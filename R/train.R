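# Model training and transfer learning: masked per-position losses, learning
# rate schedulers, decoupled-weight-decay Adam (AdamW), validation split,
# early stopping, and parameter-group freezing for fine-tuning.

LOG_EPS <- 1e-12

# Coerce predictions/targets to a list of (N x 3) matrices.
as_mat_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(x)
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[1L]), function(i) matrix(x[i, , ],
                                                          ncol = dim(x)[3L])))
  }
  stop("expected a matrix, 3-d array, or list of matrices")
}

# Shared masked-loss core; returns value and (optionally) d(loss)/d(logits).
masked_loss <- function(pred, target, gamma = NULL, want_grad = FALSE) {
  ps <- as_mat_list(pred); ys <- as_mat_list(target)
  stopifnot(length(ps) == length(ys))
  n_scored <- sum(vapply(ys, function(y) sum(rowSums(y) > 0), 0))
  if (n_scored == 0) {
    warning("all target positions are padding; loss is 0")
    return(list(value = 0,
                grads = if (want_grad) lapply(ps, function(p)
                  matrix(0, nrow(p), ncol(p))) else NULL))
  }
  total <- 0
  grads <- if (want_grad) vector("list", length(ps)) else NULL
  for (i in seq_along(ps)) {
    p <- ps[[i]]; y <- ys[[i]]
    mask <- rowSums(y) > 0
    pt <- rowSums(p * y)
    pt_c <- pmax(pt, LOG_EPS)
    if (is.null(gamma)) {
      l <- -log(pt_c)
      # fused softmax + cross-entropy: dL/dz = p - y; the 1/pt and pt
      # factors cancel analytically, so saturated positions keep their
      # full gradient
      term <- -1
    } else {
      l <- -(1 - pt)^gamma * log(pt_c)
      # dL/dz_c = [gamma (1-pt)^(gamma-1) log(pt) pt - (1-pt)^gamma]
      #           * (y_c - p_c); finite as pt -> 0
      term <- gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt_c) * pt -
        (1 - pt)^gamma
    }
    total <- total + sum(l[mask])
    if (want_grad) {
      g <- (y - p) * term / n_scored
      g[!mask, ] <- 0
      grads[[i]] <- g
    }
  }
  list(value = total / n_scored, grads = grads)
}

#' Per-position categorical cross-entropy loss
#'
#' Mean over non-padding positions of `-sum_class I_class * log(P_class)`.
#' Padding rows (all-zero targets) contribute nothing.
#'
#' @param pred Predicted class probabilities: `(N, 3)` matrix, `(b, N, 3)`
#'   array, or list of matrices; rows sum to 1.
#' @param target Matching one-hot targets; all-zero rows mark padding.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(pred, target) {
  masked_loss(pred, target)$value
}

#' Per-position focal loss
#'
#' Cross-entropy modulated by `(1 - P_class)^gamma`, down-weighting
#' well-classified positions; `gamma = 0` reduces exactly to
#' [cross_entropy_loss()].
#'
#' @inheritParams cross_entropy_loss
#' @param gamma Focusing exponent (default 2).
#' @return Non-negative scalar.
#' @export
focal_loss <- function(pred, target, gamma = 2) {
  stopifnot(gamma >= 0)
  masked_loss(pred, target, gamma = gamma)$value
}

#' Training configuration
#'
#' @param loss `"cross_entropy"` or `"focal"`.
#' @param gamma Focal exponent (default 2).
#' @param lr Initial learning rate (default 1e-3).
#' @param scheduler `"multistep"` (0.5 decay at every epoch from the sixth
#'   onward) or `"cosine_warm_restarts"` (`T_0 = 5`, `T_mult = 1`,
#'   `eta_min = 1e-5`).
#' @param epochs Maximum epochs (default 10).
#' @param patience Early-stopping patience on validation loss (default 2).
#' @param val_fraction Fraction of training windows held out for validation
#'   (default 0.1).
#' @param batch_size Windows per optimizer step (default 4).
#' @param weight_decay Decoupled weight decay (default 0.01).
#' @param seed Integer seed: validation split, shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(loss = c("cross_entropy", "focal"), gamma = 2,
                         lr = 1e-3,
                         scheduler = c("multistep", "cosine_warm_restarts"),
                         epochs = 10L, patience = 2L, val_fraction = 0.1,
                         batch_size = 4L, weight_decay = 0.01, seed = 1L) {
  loss <- match.arg(loss); scheduler <- match.arg(scheduler)
  stopifnot(gamma >= 0, val_fraction > 0, val_fraction < 1, patience >= 1L)
  if (epochs < 1L) stop("at least one training epoch is required")
  structure(list(loss = loss, gamma = gamma, lr = lr, scheduler = scheduler,
                 T_0 = 5L, T_mult = 1L, eta_min = 1e-5,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Multistep: `lr * 0.5^(number of milestones passed)` with milestones at
#' epochs 6, 7, 8, ... Cosine warm restarts: cosine interpolation between
#' `lr` and `eta_min` with restart period `T_0` (fractional epochs are
#' evaluated on the continuous schedule).
#'
#' @param config A `train_config`.
#' @param epoch Epoch index (>= 1; may be fractional for the cosine curve).
#' @return Learning rate.
#' @export
scheduler_lr <- function(config, epoch) {
  stopifnot(epoch >= 1)
  if (config$scheduler == "multistep") {
    config$lr * 0.5^max(0, floor(epoch) - 5)
  } else {
    t_cur <- (epoch - 1) %% config$T_0
    config$eta_min + (config$lr - config$eta_min) *
      (1 + cos(pi * t_cur / config$T_0)) / 2
  }
}

# --- AdamW --------------------------------------------------------------

# Recursively update every numeric leaf of `params` with the matching leaf of
# `grads` (NULL grad = frozen, skipped). `state` mirrors the structure.
adamw_update <- function(params, grads, state, lr, wd, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.numeric(p)) {
      if (is.null(s)) s <- list(m = p * 0, v = p * 0)
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
      return(list(p = p, s = s))
    }
    if (is.list(p)) {
      if (is.null(s)) s <- vector("list", length(p))
      for (nm in seq_along(p)) {
        # conv layers carry K/dil integers; only touch leaves with grads
        gnm <- if (!is.null(names(p)) && !is.null(names(g)))
          g[[names(p)[nm]]] else g[[nm]]
        if (is.null(gnm)) next
        r <- walk(p[[nm]], gnm, s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      return(list(p = p, s = s))
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

# Drop gradients of frozen parameter groups. Group order (for `last_k`):
# conv_in, skip0, units 1..n, skips 1..m, conv_out.
mask_grads <- function(grads, trainable_groups) {
  if (!"conv_in" %in% trainable_groups) grads["conv_in"] <- list(NULL)
  if (!"skip0" %in% trainable_groups) grads["skip0"] <- list(NULL)
  for (i in seq_along(grads$units)) {
    if (!paste0("unit_", i) %in% trainable_groups) {
      grads$units[i] <- list(NULL)
    }
  }
  for (j in seq_along(grads$skips)) {
    if (!paste0("skip_", j) %in% trainable_groups) {
      grads$skips[j] <- list(NULL)
    }
  }
  if (!"conv_out" %in% trainable_groups) grads["conv_out"] <- list(NULL)
  grads
}

group_names <- function(params) {
  c("conv_in", "skip0", paste0("unit_", seq_along(params$units)),
    paste0("skip_", seq_along(params$skips)), "conv_out")
}

# Extract training windows (X trimmed to 5000 + flank centered on the core,
# Y as-is) from an encoded dataset.
dataset_windows <- function(ds, flank) {
  stopifnot(inherits(ds, "encoded_dataset"))
  ds_flank <- ds$flank %||% 5000L
  core <- ds$core %||% 5000L
  if (flank > 2L * ds_flank) {
    stop("dataset context (", ds_flank, " per side) is too small for ",
         "flanking size ", flank)
  }
  lo <- ds_flank - flank %/% 2L
  xs <- list(); ys <- list()
  for (g in ds$genes) {
    for (s in seq_len(dim(g$X)[1L])) {
      xs[[length(xs) + 1L]] <-
        matrix(g$X[s, (lo + 1L):(lo + core + flank), ], ncol = 4L)
      ys[[length(ys) + 1L]] <- matrix(g$Y[s, , ], ncol = 3L)
    }
  }
  list(X = xs, Y = ys)
}

#' Train a splice model
#'
#' AdamW optimization with a seeded 90/10 train/validation window split,
#' per-epoch scheduler learning rates, and early stopping when validation
#' loss fails to improve for `patience` consecutive epochs. Returns the
#' weights of the best validation epoch.
#'
#' @param model An initialized `splice_model`.
#' @param train_ds An `encoded_dataset` (from [encode_dataset()] /
#'   [read_dataset()]).
#' @param config A [train_config()].
#' @param trainable_groups Character vector of trainable parameter groups
#'   (default: all). Used by [transfer_model()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint) and `log` (per-epoch
#'   data.frame: epoch, lr, train_loss, val_loss, best).
#' @export
train_model <- function(model, train_ds, config = train_config(),
                        trainable_groups = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "splice_model"), inherits(config, "train_config"))
  if (!length(train_ds$genes)) stop("training dataset is empty")
  all_groups <- group_names(model$params)
  if (is.null(trainable_groups)) trainable_groups <- all_groups
  # frozen units keep running batch-norm statistics fixed
  model$trainable <- paste0("unit_", seq_along(model$params$units)) %in%
    trainable_groups

  win <- dataset_windows(train_ds, model$config$flank)
  n <- length(win$X)
  if (n < 2L) stop("need at least 2 windows to split train/validation")
  gamma <- if (config$loss == "focal") config$gamma else NULL

  opt_state <- NULL; t_step <- 0L
  log_rows <- list()
  best_val <- Inf; best_model <- model; best_epoch <- 0L; since_best <- 0L

  with_seed(config$seed, {
    val_idx <- sample(n, max(1L, round(config$val_fraction * n)))
    tr_idx <- setdiff(seq_len(n), val_idx)

    val_loss_of <- function(m) {
      out <- model_forward_core(m, win$X[val_idx], training = FALSE)
      masked_loss(out$probs, win$Y[val_idx], gamma = gamma)$value
    }

    for (epoch in seq_len(config$epochs)) {
      lr <- scheduler_lr(config, epoch)
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0L
      for (b0 in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        out <- model_forward_core(model, win$X[idx], training = TRUE,
                                  cache = TRUE)
        model <- out$model  # refreshed batch-norm running statistics
        lg <- masked_loss(out$probs, win$Y[idx], gamma = gamma,
                          want_grad = TRUE)
        if (!is.finite(lg$value)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        grads <- model_backward(model, out$cache, lg$grads)
        grads <- mask_grads(grads, trainable_groups)
        t_step <- t_step + 1L
        upd <- adamw_update(model$params, grads, opt_state, lr,
                            config$weight_decay, t_step)
        model$params <- upd$p; opt_state <- upd$s
        ep_loss <- ep_loss + lg$value * length(idx); ep_n <- ep_n + length(idx)
      }
      vl <- val_loss_of(model)
      improved <- vl < best_val
      if (improved) {
        best_val <- vl; best_model <- model; best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                      train_loss = ep_loss / max(ep_n, 1L),
                                      val_loss = vl, best = improved)
      if (verbose) {
        message(sprintf("epoch %d lr %.2e train %.4f val %.4f%s", epoch, lr,
                        ep_loss / max(ep_n, 1L), vl,
                        if (improved) " *" else ""))
      }
      if (since_best >= config$patience) break
    }
  })
  log <- do.call(rbind, log_rows)
  attr(log, "seed") <- config$seed
  attr(log, "best_epoch") <- best_epoch
  attr(log, "loss_reduction") <- "mean over non-padding positions"
  list(model = best_model, log = log)
}

#' Fine-tune a pretrained model on a new dataset
#'
#' Loads pretrained weights, freezes all parameter groups except the selected
#' ones, and trains as [train_model()]. Frozen units also keep their
#' batch-norm running statistics fixed.
#'
#' @param pretrained A `splice_model` or checkpoint path.
#' @param target_ds Target-species `encoded_dataset`.
#' @param unfreeze `"all"` or `"last_k"`.
#' @param k With `unfreeze = "last_k"`: number of trailing parameter groups
#'   to train (the output projection is the last group; `k = 0` trains
#'   nothing and returns the pretrained weights unchanged).
#' @param config A [train_config()].
#' @param flank Optional expected flanking size; mismatch with the checkpoint
#'   is an error.
#' @param verbose Print progress.
#' @return As [train_model()].
#' @export
transfer_model <- function(pretrained, target_ds,
                           unfreeze = c("all", "last_k"), k = NULL,
                           config = train_config(), flank = NULL,
                           verbose = FALSE) {
  unfreeze <- match.arg(unfreeze)
  model <- if (is.character(pretrained)) load_checkpoint(pretrained) else
    pretrained
  stopifnot(inherits(model, "splice_model"))
  if (!is.null(flank) && model$config$flank != flank) {
    stop("pretrained checkpoint has flanking size ", model$config$flank,
         " but ", flank, " was requested")
  }
  groups <- group_names(model$params)
  trainable <- if (unfreeze == "all") groups else {
    stopifnot(!is.null(k), k >= 0L)
    if (k == 0L) character(0) else utils::tail(groups, k)
  }
  if (!length(trainable)) {
    log <- data.frame(epoch = integer(0), lr = numeric(0),
                      train_loss = numeric(0), val_loss = numeric(0),
                      best = logical(0))
    return(list(model = model, log = log))
  }
  train_model(model, target_ds, config, trainable_groups = trainable,
              verbose = verbose)
}
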