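# Model construction and forward-pass properties.

test_that("configurations match the four-architecture table", {
  c80 <- build_config(80)
  expect_length(c80$W, 4L)
  expect_true(all(c80$W == 11) && all(c80$AR == 1))
  c400 <- build_config(400)
  expect_equal(c400$W, rep(11L, 8L))
  expect_equal(c400$AR, c(rep(1L, 4), rep(4L, 4)))
  c2000 <- build_config(2000)
  expect_equal(c2000$W, c(rep(11L, 8), rep(21L, 4)))
  expect_equal(c2000$AR, c(rep(1L, 4), rep(4L, 4), rep(10L, 4)))
  c10k <- build_config(10000)
  expect_equal(c10k$W, c(rep(11L, 8), rep(21L, 4), rep(41L, 4)))
  expect_equal(c10k$AR, c(rep(1L, 4), rep(4L, 4), rep(10L, 4), rep(25L, 4)))
  expect_error(build_config(123), "80, 400, 2000, 10000")
})

test_that("cropping length is twice the dilation-weighted kernel sum", {
  for (f in c(80L, 400L, 2000L, 10000L)) {
    expect_equal(cropping_length(build_config(f)), f)
  }
  expect_equal(cropping_length(list(W = 11L, AR = 1L)), 20L)
  expect_equal(cropping_length(list(W = c(1L, 11L), AR = c(7L, 2L))), 40L)
})

test_that("skip merges sit after every fourth residual unit", {
  m80 <- small_model(80)
  expect_length(m80$params$units, 4L)
  expect_length(m80$params$skips, 1L)
  m10k <- init_model(build_config(10000, channels = 2L), seed = 1)
  expect_length(m10k$params$units, 16L)
  expect_length(m10k$params$skips, 4L)
})

test_that("forward output is (n, len - flank, 3) with unit row sums", {
  m <- small_model()
  x <- array(0, dim = c(2, 5080, 4))
  x[1, , ] <- one_hot_encode(rand_dna(5080, 1))
  x[2, , ] <- one_hot_encode(rand_dna(5080, 2))
  p <- model_forward(m, x)
  expect_equal(dim(p), c(2L, 5000L, 3L))
  expect_true(max(abs(rowSums(matrix(p, ncol = 3)) - 1)) < 1e-6)
  # all-N input still yields distributions
  pN <- model_forward(m, one_hot_encode(strrep("N", 200)))
  expect_true(max(abs(rowSums(pN) - 1)) < 1e-6)
  # deterministic in inference mode
  expect_identical(model_forward(m, x), model_forward(m, x))
  # variable-length inference
  for (L in c(81L, 200L, 1234L)) {
    expect_equal(nrow(model_forward(m, one_hot_encode(rand_dna(L, L)))),
                 L - 80L)
  }
  expect_error(model_forward(m, matrix(0, 100, 3)), "4 channels")
  expect_error(model_forward(m, one_hot_encode(rand_dna(80, 1))),
               "exceed")
})

test_that("compiled convolution kernels match the im2col reference", {
  spliceml:::with_seed(6, {
    for (cfg in list(c(K = 1L, dil = 1L), c(K = 11L, dil = 1L),
                     c(K = 21L, dil = 10L))) {
      x <- matrix(rnorm(300 * 6), 300, 6)
      W <- matrix(rnorm(cfg["K"] * 6 * 5), cfg["K"] * 6, 5)
      b <- rnorm(5)
      ref <- spliceml:::im2col(x, cfg["K"], cfg["dil"]) %*% W
      ref <- sweep(ref, 2, b, "+")
      got <- spliceml:::.conv1d_fwd_cpp(x, W, b, cfg["K"], cfg["dil"])
      expect_lt(max(abs(ref - got)), 1e-12)
      dy <- matrix(rnorm(300 * 5), 300, 5)
      r <- spliceml:::.conv1d_bwd_cpp(x, dy, W, cfg["K"], cfg["dil"], TRUE)
      expect_lt(max(abs(r$dW -
                          crossprod(spliceml:::im2col(x, cfg["K"],
                                                      cfg["dil"]), dy))),
                1e-12)
      expect_lt(max(abs(r$dx -
                          spliceml:::col2im(dy %*% t(W), 300L, 6L,
                                            cfg["K"], cfg["dil"]))), 1e-12)
      expect_equal(as.numeric(r$db), colSums(dy))
    }
  })
})

test_that("model gradients match central finite differences", {
  m <- init_model(build_config(80, channels = 4L), seed = 5)
  spliceml:::with_seed(19, {
    xs <- list(one_hot_encode(rand_dna(120)), one_hot_encode(rand_dna(120)))
    ys <- lapply(1:2, function(i) {
      y <- matrix(0, 40, 3); y[cbind(1:40, sample(3, 40, TRUE))] <- 1; y
    })
  })
  for (gamma in list(NULL, 2)) {
    lf <- function(mod) {
      o <- spliceml:::model_forward_core(mod, xs, training = TRUE)
      spliceml:::masked_loss(o$probs, ys, gamma = gamma[[1]])$value
    }
    o <- spliceml:::model_forward_core(m, xs, training = TRUE, cache = TRUE)
    lg <- spliceml:::masked_loss(o$probs, ys, gamma = gamma[[1]],
                                 want_grad = TRUE)
    gr <- spliceml:::model_backward(m, o$cache, lg$grads)
    checks <- list(c("conv_in", "W", 3), c("skip0", "W", 5),
                   c("conv_out", "b", 1))
    for (ck in checks) {
      eps <- 1e-6
      mp <- m; mm <- m
      mp$params[[ck[1]]][[ck[2]]][as.integer(ck[3])] <-
        mp$params[[ck[1]]][[ck[2]]][as.integer(ck[3])] + eps
      mm$params[[ck[1]]][[ck[2]]][as.integer(ck[3])] <-
        mm$params[[ck[1]]][[ck[2]]][as.integer(ck[3])] - eps
      num <- (lf(mp) - lf(mm)) / (2 * eps)
      expect_lt(abs(num - gr[[ck[1]]][[ck[2]]][as.integer(ck[3])]), 1e-6)
    }
    # a batch-norm parameter and a dilated-conv weight inside a unit
    for (ck in list(list(1L, "bn1", "gamma", 2L), list(3L, "conv2", "W", 11L))) {
      eps <- 1e-6
      mp <- m; mm <- m
      mp$params$units[[ck[[1]]]][[ck[[2]]]][[ck[[3]]]][ck[[4]]] <-
        mp$params$units[[ck[[1]]]][[ck[[2]]]][[ck[[3]]]][ck[[4]]] + eps
      mm$params$units[[ck[[1]]]][[ck[[2]]]][[ck[[3]]]][ck[[4]]] <-
        mm$params$units[[ck[[1]]]][[ck[[2]]]][[ck[[3]]]][ck[[4]]] - eps
      num <- (lf(mp) - lf(mm)) / (2 * eps)
      expect_lt(abs(num - gr$units[[ck[[1]]]][[ck[[2]]]][[ck[[3]]]][ck[[4]]]),
                1e-6)
    }
  }
})

test_that("initialization is seed-reproducible and checkpoints round-trip", {
  a <- init_model(build_config(80, channels = 6L), seed = 42)
  b <- init_model(build_config(80, channels = 6L), seed = 42)
  expect_identical(a$params, b$params)
  c <- init_model(build_config(80, channels = 6L), seed = 43)
  expect_false(identical(a$params, c$params))
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(a, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, a$params)
  expect_equal(back$config$flank, 80L)
  x <- one_hot_encode(rand_dna(300, 9))
  expect_identical(model_forward(back, x), model_forward(a, x))
})
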