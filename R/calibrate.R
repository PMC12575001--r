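# Class-wise temperature scaling of model logits, with NLL/ECE diagnostics
# and reliability curves. A vector T = (T_none, T_acceptor, T_donor) divides
# each class's logit before the softmax; T is fitted by minimizing NLL on a
# validation set with the base model weights frozen.

TEMPERATURE_BOUNDS <- c(0.05, 5.0)

#' Apply temperature scaling to logits
#'
#' Divides the logit of class c by `T[c]` and renormalizes with the softmax.
#' `T = c(1, 1, 1)` is the identity.
#'
#' @param logits `(N, 3)` matrix of raw scores.
#' @param temperature Numeric vector of 3 positive temperatures.
#' @return `(N, 3)` matrix of calibrated probabilities.
#' @export
scale_probs <- function(logits, temperature) {
  stopifnot(is.matrix(logits), ncol(logits) == length(temperature))
  if (any(temperature <= 0)) stop("temperatures must be positive")
  softmax_rows(sweep(logits, 2L, temperature, "/"))
}

#' Negative log-likelihood of probabilistic predictions
#'
#' `-(1/N) * sum_i sum_c I_{i,c} log p_{i,c}` over scored positions; equal to
#' the categorical cross-entropy.
#'
#' @param probs `(N, C)` probability matrix.
#' @param labels Integer class labels in `1..C`, or an `(N, C)` one-hot
#'   matrix (all-zero rows excluded as padding).
#' @return Non-negative scalar.
#' @export
nll <- function(probs, labels) {
  y <- as_onehot(labels, ncol(probs))
  cross_entropy_loss(probs, y)
}

as_onehot <- function(labels, C) {
  if (is.matrix(labels)) return(labels)
  y <- matrix(0, length(labels), C)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

#' Fit a class-wise temperature vector
#'
#' Gradient-based minimization of the validation NLL with respect to the
#' temperature vector (base weights fixed): Adam at learning rate 0.01,
#' plateau-driven learning-rate reduction (factor 0.1, patience 2), early
#' stopping at minimum improvement 1e-6 over 2 epochs, temperatures clamped
#' to \[0.05, 5\]. Initialization is T = 1.
#'
#' @param logits `(N, 3)` matrix of validation logits.
#' @param labels Integer labels (1 = none, 2 = acceptor, 3 = donor) or
#'   one-hot matrix; at least 2 classes must be present.
#' @param lr Initial Adam learning rate.
#' @param max_epochs Optimization cap.
#' @return Numeric temperature vector of length 3 with attributes
#'   `nll_before` and `nll_after`.
#' @export
fit_temperature <- function(logits, labels, lr = 0.01, max_epochs = 500L) {
  y <- as_onehot(labels, ncol(logits))
  present <- colSums(y) > 0
  if (sum(present) < 2L) {
    stop("temperature fitting requires at least 2 classes in the labels")
  }
  n <- nrow(logits)
  Tv <- rep(1, ncol(logits))
  nll_of <- function(Tv) nll(scale_probs(logits, Tv), y)
  nll0 <- nll_of(Tv)

  m <- v <- numeric(length(Tv))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- Tv; best_nll <- nll0
  plateau <- 0L; stall <- 0L; cur_lr <- lr
  prev <- nll0
  for (t in seq_len(max_epochs)) {
    p <- scale_probs(logits, Tv)
    # d NLL / d T_c = mean_i (p_ic - y_ic) * (-z_ic / T_c^2)
    g <- colSums((p - y) * sweep(logits, 2L, -1 / Tv^2, "*")) / n
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    Tv <- Tv - cur_lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
    Tv <- pmin(pmax(Tv, TEMPERATURE_BOUNDS[1L]), TEMPERATURE_BOUNDS[2L])
    cur <- nll_of(Tv)
    if (cur < best_nll) { best_nll <- cur; best <- Tv }
    if (prev - cur < 1e-6) {
      stall <- stall + 1L
      plateau <- plateau + 1L
    } else {
      stall <- 0L; plateau <- 0L
    }
    if (plateau >= 2L && cur_lr > 1e-6) {
      cur_lr <- cur_lr * 0.1; plateau <- 0L
    }
    if (stall >= 2L && t > 10L) break
    prev <- cur
  }
  structure(best, nll_before = nll0, nll_after = best_nll)
}

#' Expected calibration error
#'
#' Partitions predictions into `M` uniform-width bins on the predicted-class
#' confidence and returns `sum_m (|B_m|/N) * |acc(B_m) - conf(B_m)|`. 0 is
#' perfect calibration.
#'
#' @param probs `(N, C)` probability matrix.
#' @param labels Integer labels in `1..C` or one-hot matrix.
#' @param M Number of bins (default 30).
#' @return Scalar in \[0, 1\].
#' @export
ece <- function(probs, labels, M = 30L) {
  y <- as_onehot(labels, ncol(probs))
  keep <- rowSums(y) > 0
  probs <- probs[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  pred <- max.col(probs, ties.method = "first")
  conf <- probs[cbind(seq_len(nrow(probs)), pred)]
  correct <- y[cbind(seq_len(nrow(y)), pred)] == 1
  bin <- pmin(pmax(ceiling(conf * M), 1L), M)
  N <- length(conf)
  out <- 0
  for (b in unique(bin)) {
    in_b <- bin == b
    out <- out + sum(in_b) / N * abs(mean(correct[in_b]) - mean(conf[in_b]))
  }
  out
}

#' Reliability curve with normal-approximation confidence intervals
#'
#' Per class (one-vs-rest), bins the predicted class probability into `M`
#' uniform bins and reports the mean predicted probability, the empirical
#' positive frequency, and its 95% CI
#' (`SE = sqrt(p(1-p)/n)`, `CI = [max(p - 1.96 SE, 0), min(p + 1.96 SE, 1)]`).
#'
#' @inheritParams ece
#' @return data.frame with columns class, bin, n, mean_pred, emp_freq, se,
#'   ci_lower, ci_upper.
#' @export
reliability_curve <- function(probs, labels, M = 30L) {
  y <- as_onehot(labels, ncol(probs))
  keep <- rowSums(y) > 0
  probs <- probs[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  z <- 1.96
  rows <- list()
  classes <- colnames(probs) %||% paste0("class", seq_len(ncol(probs)))
  for (c in seq_len(ncol(probs))) {
    pc <- probs[, c]; yc <- y[, c] == 1
    bin <- pmin(pmax(ceiling(pc * M), 1L), M)
    for (b in sort(unique(bin))) {
      in_b <- bin == b
      n <- sum(in_b)
      phat <- mean(yc[in_b])
      se <- sqrt(phat * (1 - phat) / n)
      rows[[length(rows) + 1L]] <- data.frame(
        class = classes[c], bin = b, n = n,
        mean_pred = mean(pc[in_b]), emp_freq = phat, se = se,
        ci_lower = max(phat - z * se, 0), ci_upper = min(phat + z * se, 1))
    }
  }
  do.call(rbind, rows)
}

#' Calibrate a trained splice model
#'
#' Pools per-position logits and labels across validation windows (padding
#' excluded), fits the class-wise temperature vector, and returns the model
#' with the temperature embedded plus a calibration report.
#'
#' @param model A trained `splice_model`.
#' @param val_ds An `encoded_dataset` used as the calibration set.
#' @param M Reliability/ECE bins (default 30).
#' @param max_positions Optional cap on pooled positions (memory guard).
#' @return List with `model` (temperature embedded), `temperature`, and
#'   `report` (NLL/ECE before and after, reliability curves).
#' @export
calibrate_model <- function(model, val_ds, M = 30L, max_positions = NULL) {
  win <- dataset_windows(val_ds, model$config$flank)
  logit_list <- model_forward_core(model, win$X, training = FALSE)$logits
  Z <- do.call(rbind, logit_list)
  Y <- do.call(rbind, win$Y)
  keep <- rowSums(Y) > 0
  Z <- Z[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  if (!is.null(max_positions) && nrow(Z) > max_positions) {
    idx <- seq_len(max_positions)
    Z <- Z[idx, , drop = FALSE]; Y <- Y[idx, , drop = FALSE]
  }
  Tv <- fit_temperature(Z, Y)
  p_before <- softmax_rows(Z)
  p_after <- scale_probs(Z, as.numeric(Tv))
  report <- list(
    temperature = as.numeric(Tv),
    nll_before = attr(Tv, "nll_before"), nll_after = attr(Tv, "nll_after"),
    ece_before = ece(p_before, Y, M), ece_after = ece(p_after, Y, M),
    reliability_before = reliability_curve(p_before, Y, M),
    reliability_after = reliability_curve(p_after, Y, M),
    n_positions = nrow(Z))
  model$temperature <- as.numeric(Tv)
  list(model = model, temperature = as.numeric(Tv), report = report)
}
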