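# Dilated residual convolutional splice-site model.
#
# The network mirrors the classic splice-prediction residual CNN: an initial
# 1x1 convolution projects the 4-channel one-hot input to `channels` features;
# residual units (batch norm -> leaky ReLU -> dilated conv, twice,
# pre-activation order) enlarge the receptive field; after every fourth unit a
# 1x1 "skip" convolution merges features into an accumulator; the accumulator
# is cropped by CL/2 per side and projected to 3 output channels with a
# per-position softmax. All layers (forward and backward) are implemented on
# BLAS-backed matrix products, so models train on CPU without an external
# deep-learning framework.

SUPPORTED_FLANKS <- c(80L, 400L, 2000L, 10000L)

#' Build a model configuration for a flanking size
#'
#' Kernel-size (W) and dilation (AR) vectors per flanking size:
#' 80: W=11 x4, AR=1 x4; 400: W=11 x8, AR=\[1 x4, 4 x4\];
#' 2000: W=\[11 x8, 21 x4\], AR=\[1 x4, 4 x4, 10 x4\];
#' 10000: W=\[11 x8, 21 x4, 41 x4\], AR=\[1 x4, 4 x4, 10 x4, 25 x4\].
#'
#' @param flank Flanking size in nucleotides; one of 80, 400, 2000, 10000.
#' @param channels Feature width of the residual trunk (default 32).
#' @param negative_slope Leaky-ReLU slope (default 0.1).
#' @return A `splice_config` with fields `flank`, `W`, `AR`, `channels`,
#'   `negative_slope`, `bn_eps`, `bn_momentum`.
#' @export
build_config <- function(flank, channels = 32L, negative_slope = 0.1) {
  if (!flank %in% SUPPORTED_FLANKS) {
    stop("unsupported flanking size ", flank, "; valid values: ",
         paste(SUPPORTED_FLANKS, collapse = ", "))
  }
  cfg <- switch(as.character(flank),
    "80" = list(W = rep(11L, 4L), AR = rep(1L, 4L)),
    "400" = list(W = rep(11L, 8L), AR = c(rep(1L, 4L), rep(4L, 4L))),
    "2000" = list(W = c(rep(11L, 8L), rep(21L, 4L)),
                  AR = c(rep(1L, 4L), rep(4L, 4L), rep(10L, 4L))),
    "10000" = list(W = c(rep(11L, 8L), rep(21L, 4L), rep(41L, 4L)),
                   AR = c(rep(1L, 4L), rep(4L, 4L), rep(10L, 4L),
                          rep(25L, 4L))))
  structure(list(flank = as.integer(flank), W = cfg$W, AR = cfg$AR,
                 channels = as.integer(channels),
                 negative_slope = negative_slope,
                 bn_eps = 1e-5, bn_momentum = 0.1),
            class = "splice_config")
}

#' Total cropping length of a configuration
#'
#' `CL = 2 * sum(AR_i * (W_i - 1))`, the amount by which the network output is
#' shorter than its input; equals the flanking size for the four standard
#' configurations.
#'
#' @param config A `splice_config` (or any list with `W` and `AR`).
#' @return Cropping length in nucleotides.
#' @export
cropping_length <- function(config) {
  stopifnot(length(config$W) == length(config$AR))
  as.integer(2L * sum(config$AR * (config$W - 1L)))
}

# --- primitive layers ---------------------------------------------------

# Unfold a (L x Cin) matrix into the (L x K*Cin) im2col matrix for a
# zero-padded "same" 1-D convolution with odd kernel K and dilation dil.
im2col <- function(x, K, dil) {
  L <- nrow(x); Cin <- ncol(x)
  out <- matrix(0, L, K * Cin)
  half <- (K + 1L) %/% 2L
  for (k in seq_len(K)) {
    off <- (k - half) * dil
    i1 <- max(1L, 1L - off); i2 <- min(L, L - off)
    if (i1 <= i2) {
      out[i1:i2, ((k - 1L) * Cin + 1L):(k * Cin)] <-
        x[(i1 + off):(i2 + off), , drop = FALSE]
    }
  }
  out
}

# Fold a (L x K*Cin) gradient back onto the (L x Cin) input.
col2im <- function(dcol, L, Cin, K, dil) {
  dx <- matrix(0, L, Cin)
  half <- (K + 1L) %/% 2L
  for (k in seq_len(K)) {
    off <- (k - half) * dil
    j1 <- max(1L, 1L + off); j2 <- min(L, L + off)
    if (j1 <= j2) {
      dx[j1:j2, ] <- dx[j1:j2, ] +
        dcol[(j1 - off):(j2 - off), ((k - 1L) * Cin + 1L):(k * Cin),
             drop = FALSE]
    }
  }
  dx
}

# Columnwise recycling helpers (faster than sweep(): no aperm).
col_mul <- function(m, v) m * rep(v, each = nrow(m))
col_add <- function(m, v) m + rep(v, each = nrow(m))

# Convolution forward over a batch list of (L x Cin) matrices.
conv_fwd <- function(xs, layer) {
  lapply(xs, function(x) .conv1d_fwd_cpp(x, layer$W, layer$b, layer$K,
                                         layer$dil))
}

# Convolution backward: returns list(dxs, dW, db).
conv_bwd <- function(xs, dys, layer, need_dx = TRUE) {
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  db <- numeric(length(layer$b))
  dxs <- if (need_dx) vector("list", length(xs)) else NULL
  for (i in seq_along(xs)) {
    r <- .conv1d_bwd_cpp(xs[[i]], dys[[i]], layer$W, layer$K, layer$dil,
                         need_dx)
    dW <- dW + r$dW
    db <- db + as.numeric(r$db)
    if (need_dx) dxs[[i]] <- r$dx
  }
  list(dxs = dxs, dW = dW, db = db)
}

# Batch norm forward over a batch list; statistics pool all samples/positions.
bn_fwd <- function(xs, p, training, update_stats = TRUE,
                   momentum = 0.1, eps = 1e-5) {
  xm <- do.call(rbind, xs)
  n <- nrow(xm)
  if (training && n > 1L) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v[v < 0] <- 0
    if (update_stats) {
      p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
      p$run_var <- (1 - momentum) * p$run_var + momentum * v * n / (n - 1L)
    }
  } else {
    mu <- p$run_mean; v <- p$run_var
  }
  invstd <- 1 / sqrt(v + eps)
  aff <- .bn_affine_cpp(xm, mu, invstd, p$gamma, p$beta)
  rows <- vapply(xs, nrow, 0L)
  split_rows <- function(m) {
    out <- vector("list", length(rows)); at <- 0L
    for (i in seq_along(rows)) {
      out[[i]] <- m[(at + 1L):(at + rows[i]), , drop = FALSE]
      at <- at + rows[i]
    }
    out
  }
  list(ys = split_rows(aff$y),
       cache = list(xhat = aff$xhat, invstd = invstd,
                    rows = rows, split = split_rows),
       p = p)
}

bn_bwd <- function(dys, p, cache) {
  dy <- do.call(rbind, dys)
  xhat <- cache$xhat; n <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- col_mul(dy, p$gamma)
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * xhat)
  dx <- col_add(dxhat, -mean_dxhat) - col_mul(xhat, mean_dxhat_xhat)
  dx <- col_mul(dx, cache$invstd)
  list(dxs = cache$split(dx), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(xs, slope) {
  lapply(xs, function(x) .lrelu_fwd_cpp(x, slope))
}

lrelu_bwd <- function(dys, xs, slope) {
  Map(function(dy, x) .lrelu_bwd_cpp(dy, x, slope), dys, xs)
}

# --- model construction -------------------------------------------------

kaiming_w <- function(fan_in, cout, slope) {
  gain <- sqrt(2 / (1 + slope^2))
  matrix(stats::rnorm(fan_in * cout, sd = gain / sqrt(fan_in)), fan_in, cout)
}

new_conv <- function(cin, cout, K, dil, slope) {
  list(W = kaiming_w(K * cin, cout, slope), b = numeric(cout),
       K = as.integer(K), dil = as.integer(dil))
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

#' Initialize a splice model
#'
#' Kaiming fan-in initialization for convolutions; unit scale / zero shift for
#' batch-norm layers. Seedable for reproducibility.
#'
#' @param config A `splice_config` from [build_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `splice_model`.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "splice_config"))
  C <- config$channels; a <- config$negative_slope
  n_units <- length(config$W)
  with_seed(seed, {
    params <- list(
      conv_in = new_conv(4L, C, 1L, 1L, a),
      skip0 = new_conv(C, C, 1L, 1L, a),
      units = lapply(seq_len(n_units), function(i) {
        list(bn1 = new_bn(C),
             conv1 = new_conv(C, C, config$W[i], config$AR[i], a),
             bn2 = new_bn(C),
             conv2 = new_conv(C, C, config$W[i], config$AR[i], a))
      }),
      skips = lapply(seq_len(n_units %/% 4L), function(j)
        new_conv(C, C, 1L, 1L, a)),
      conv_out = new_conv(C, 3L, 1L, 1L, a))
    structure(list(config = config, params = params,
                   trainable = rep(TRUE, n_units),
                   version = 1L),
              class = "splice_model")
  })
}

# Full forward pass. `batch` is a list of (L x 4) matrices (lengths may
# differ only when B = 1 effectively; batched training uses equal lengths).
# Returns probs/logits per sample; with cache = TRUE also every intermediate
# needed by model_backward.
model_forward_core <- function(model, batch, training = FALSE, cache = FALSE) {
  p <- model$params; cfg <- model$config
  a <- cfg$negative_slope
  crop <- cropping_length(cfg) %/% 2L
  cc <- if (cache) new.env(parent = emptyenv()) else NULL

  x <- conv_fwd(batch, p$conv_in)
  if (cache) cc$x_in <- batch
  skip <- conv_fwd(x, p$skip0)
  if (cache) cc$x0 <- x
  xs_at_skip <- list()
  unit_caches <- vector("list", length(p$units))

  for (i in seq_along(p$units)) {
    u <- p$units[[i]]
    upd <- training && model$trainable[i]
    b1 <- bn_fwd(x, u$bn1, training = upd, momentum = cfg$bn_momentum,
                 eps = cfg$bn_eps)
    model$params$units[[i]]$bn1 <- b1$p
    r1 <- lrelu_fwd(b1$ys, a)
    c1 <- conv_fwd(r1, u$conv1)
    b2 <- bn_fwd(c1, u$bn2, training = upd, momentum = cfg$bn_momentum,
                 eps = cfg$bn_eps)
    model$params$units[[i]]$bn2 <- b2$p
    r2 <- lrelu_fwd(b2$ys, a)
    c2 <- conv_fwd(r2, u$conv2)
    x_new <- Map(`+`, x, c2)
    if (cache) {
      unit_caches[[i]] <- list(x = x, b1 = b1$cache, y1 = b1$ys, r1 = r1,
                               c1 = c1, b2 = b2$cache, y2 = b2$ys, r2 = r2)
    }
    x <- x_new
    if (i %% 4L == 0L && (i %/% 4L) <= length(p$skips)) {
      skip <- Map(`+`, skip, conv_fwd(x, p$skips[[i %/% 4L]]))
      xs_at_skip[[i %/% 4L]] <- if (cache) x else NULL
    }
  }
  cropped <- lapply(skip, function(s) {
    L <- nrow(s)
    if (L <= 2L * crop) stop("input length must exceed the flanking size (",
                             cfg$flank, ")")
    s[(crop + 1L):(L - crop), , drop = FALSE]
  })
  logits <- conv_fwd(cropped, p$conv_out)
  probs <- lapply(logits, softmax_rows)
  if (cache) {
    cc$unit_caches <- unit_caches; cc$xs_at_skip <- xs_at_skip
    cc$cropped <- cropped; cc$crop <- crop
  }
  list(probs = probs, logits = logits, cache = cc, model = model)
}

# Backward pass; dlogits is a list matching logits. Returns gradients in the
# same structure as model$params.
model_backward <- function(model, cc, dlogits) {
  p <- model$params; cfg <- model$config
  a <- cfg$negative_slope
  crop <- cc$crop
  zero_like <- function(xs) lapply(xs, function(x) matrix(0, nrow(x), ncol(x)))

  g <- list(units = vector("list", length(p$units)),
            skips = vector("list", length(p$skips)))

  co <- conv_bwd(cc$cropped, dlogits, p$conv_out)
  g$conv_out <- list(W = co$dW, b = co$db)
  # un-crop the skip gradient
  dskip <- Map(function(dc, xc) {
    L <- nrow(xc) + 2L * crop
    m <- matrix(0, L, ncol(dc))
    m[(crop + 1L):(L - crop), ] <- dc
    m
  }, co$dxs, cc$cropped)

  dx <- zero_like(dskip)
  for (i in rev(seq_along(p$units))) {
    if (i %% 4L == 0L && (i %/% 4L) <= length(p$skips)) {
      j <- i %/% 4L
      sb <- conv_bwd(cc$xs_at_skip[[j]], dskip, p$skips[[j]])
      g$skips[[j]] <- list(W = sb$dW, b = sb$db)
      dx <- Map(`+`, dx, sb$dxs)
    }
    u <- p$units[[i]]; uc <- cc$unit_caches[[i]]
    # residual: dx flows both into the unit and straight through
    c2b <- conv_bwd(uc$r2, dx, u$conv2)
    dr2 <- lrelu_bwd(c2b$dxs, uc$y2, a)
    b2b <- bn_bwd(dr2, u$bn2, uc$b2)
    c1b <- conv_bwd(uc$r1, b2b$dxs, u$conv1)
    dr1 <- lrelu_bwd(c1b$dxs, uc$y1, a)
    b1b <- bn_bwd(dr1, u$bn1, uc$b1)
    g$units[[i]] <- list(
      bn1 = list(gamma = b1b$dgamma, beta = b1b$dbeta),
      conv1 = list(W = c1b$dW, b = c1b$db),
      bn2 = list(gamma = b2b$dgamma, beta = b2b$dbeta),
      conv2 = list(W = c2b$dW, b = c2b$db))
    dx <- Map(`+`, dx, b1b$dxs)
  }
  s0 <- conv_bwd(cc$x0, dskip, p$skip0)
  g$skip0 <- list(W = s0$dW, b = s0$db)
  dx <- Map(`+`, dx, s0$dxs)
  ci <- conv_bwd(cc$x_in, dx, p$conv_in, need_dx = FALSE)
  g$conv_in <- list(W = ci$dW, b = ci$db)
  g
}

#' Run the forward pass of a splice model
#'
#' Deterministic inference-mode forward (batch-norm running statistics, no
#' stochastic layers). Accepts variable input lengths: the output is always
#' `input length - flank` positions.
#'
#' @param model A `splice_model`.
#' @param batch One-hot input: a `(n, len, 4)` array, a single `(len, 4)`
#'   matrix, or a list of `(len, 4)` matrices.
#' @return For array/matrix input, a `(n, len - flank, 3)` array of
#'   per-position class probabilities (none, acceptor, donor); for list
#'   input, a list of `(len - flank, 3)` matrices.
#' @export
model_forward <- function(model, batch) {
  as_list <- batch_as_list(batch)
  for (x in as_list$xs) {
    if (ncol(x) != 4L) stop("input must have 4 channels (A,C,G,T)")
  }
  out <- model_forward_core(model, as_list$xs, training = FALSE)
  as_list$rebuild(out$probs)
}

# Normalize the accepted batch shapes to a list of matrices plus a rebuilder.
batch_as_list <- function(batch) {
  if (is.list(batch)) {
    list(xs = batch, rebuild = identity)
  } else if (is.matrix(batch)) {
    list(xs = list(batch), rebuild = function(ps) ps[[1L]])
  } else if (is.array(batch) && length(dim(batch)) == 3L) {
    n <- dim(batch)[1L]
    xs <- lapply(seq_len(n), function(i) {
      matrix(batch[i, , ], ncol = dim(batch)[3L])
    })
    list(xs = xs, rebuild = function(ps) {
      out <- array(0, dim = c(n, nrow(ps[[1L]]), ncol(ps[[1L]])))
      for (i in seq_len(n)) out[i, , ] <- ps[[i]]
      out
    })
  } else stop("unsupported batch type")
}

#' Raw (pre-softmax) logits of a splice model
#'
#' @inheritParams model_forward
#' @return As [model_forward()], but unnormalized logits.
#' @export
model_logits <- function(model, batch) {
  as_list <- batch_as_list(batch)
  out <- model_forward_core(model, as_list$xs, training = FALSE)
  as_list$rebuild(out$logits)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the configuration, all weights and batch-norm running
#' statistics, an optional calibration temperature vector, and a format
#' version.
#'
#' @param model A `splice_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (`save_checkpoint`); the model
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "splice_model"))
  saveRDS(list(format = "spliceml-checkpoint", version = model$version,
               config = unclass(model$config), params = model$params,
               trainable = model$trainable,
               temperature = model$temperature %||% NULL),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "spliceml-checkpoint")) {
    stop("not a spliceml checkpoint: ", path)
  }
  structure(list(config = structure(obj$config, class = "splice_config"),
                 params = obj$params, trainable = obj$trainable,
                 temperature = obj$temperature, version = obj$version),
            class = "splice_model")
}
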