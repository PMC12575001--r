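# Losses, schedulers, training loop, transfer freezing.

test_that("cross-entropy is the masked mean negative log-likelihood", {
  # perfect one-hot predictions -> 0
  y <- diag(3)
  expect_equal(cross_entropy_loss(y, y), 0)
  # uniform prediction at one labeled position -> ln 3
  p <- matrix(1 / 3, 1, 3); t1 <- matrix(c(0, 1, 0), 1)
  expect_equal(cross_entropy_loss(p, t1), log(3), tolerance = 1e-12)
  # padding rows contribute nothing
  p2 <- rbind(p, c(0.9, 0.05, 0.05))
  t2 <- rbind(t1, c(0, 0, 0))
  expect_equal(cross_entropy_loss(p2, t2), log(3), tolerance = 1e-12)
  # all-padding target: 0 with warning
  expect_warning(v <- cross_entropy_loss(p, matrix(0, 1, 3)), "padding")
  expect_equal(v, 0)
})

test_that("focal loss reduces to cross-entropy at gamma 0 and downweights", {
  spliceml:::with_seed(2, {
    for (i in 1:5) {
      p <- spliceml:::softmax_rows(matrix(rnorm(60), 20, 3))
      y <- matrix(0, 20, 3); y[cbind(1:20, sample(3, 20, TRUE))] <- 1
      y[sample(20, 3), ] <- 0  # some padding
      expect_equal(focal_loss(p, y, gamma = 0), cross_entropy_loss(p, y),
                   tolerance = 1e-12)
    }
  })
  # P_correct = 1 -> 0
  expect_equal(focal_loss(diag(3), diag(3), gamma = 2), 0)
  # P_correct = 0.5, gamma = 2 -> 0.25 * ln 2
  p <- matrix(c(0.5, 0.25, 0.25), 1)
  y <- matrix(c(1, 0, 0), 1)
  expect_equal(focal_loss(p, y, gamma = 2), 0.25 * log(2), tolerance = 1e-9)
})

test_that("schedulers follow the multistep and cosine curves", {
  cfg_m <- train_config(scheduler = "multistep")
  expect_equal(scheduler_lr(cfg_m, 1), 0.001)
  expect_equal(scheduler_lr(cfg_m, 5), 0.001)
  expect_equal(scheduler_lr(cfg_m, 6), 0.0005)
  expect_equal(scheduler_lr(cfg_m, 8), 0.000125)  # three milestones passed
  cfg_c <- train_config(scheduler = "cosine_warm_restarts")
  expect_equal(scheduler_lr(cfg_c, 1), 0.001)
  # trough of a cycle approaches eta_min = 1e-5
  expect_equal(scheduler_lr(cfg_c, 1 + 5 * (1 - 1e-9)), 1e-5,
               tolerance = 1e-7)
  # warm restart at the start of the next cycle
  expect_equal(scheduler_lr(cfg_c, 6), 0.001)
})

test_that("training reduces validation loss on a learnable toy problem", {
  # toy task: donor motif "GGTAAG" planted mid-window; labels at the motif
  spliceml:::with_seed(31, {
    genes <- lapply(1:8, function(i) {
      s <- rand_dna(400)
      pos <- sample(100:300, 1)
      substr(s, pos, pos + 5) <- "GGTAAG"
      labels <- integer(400); labels[pos] <- 2L  # donor on the G before GT
      structure(list(gene_id = paste0("g", i), sequence = s, labels = labels,
                     donor_positions = pos - 1L,
                     acceptor_positions = integer(0)),
                class = "labeled_gene")
    })
  })
  ds <- encode_dataset(genes, core = 400L, flank = 200L)
  model <- init_model(build_config(80, channels = 8L), seed = 7)
  win <- spliceml:::dataset_windows(ds, 80L)
  loss0 <- cross_entropy_loss(
    spliceml:::model_forward_core(model, win$X)$probs, win$Y)
  fit <- train_model(model, ds, train_config(epochs = 4L, batch_size = 4L,
                                             seed = 7L))
  expect_lt(min(fit$log$val_loss), loss0)
  expect_equal(attr(fit$log, "seed"), 7L)
  expect_equal(attr(fit$log, "best_epoch"),
               fit$log$epoch[which.min(fit$log$val_loss)])
  # reproducibility: same seed, same trajectory
  fit2 <- train_model(init_model(build_config(80, channels = 8L), seed = 7),
                      ds, train_config(epochs = 2L, seed = 7L))
  fit3 <- train_model(init_model(build_config(80, channels = 8L), seed = 7),
                      ds, train_config(epochs = 2L, seed = 7L))
  expect_identical(fit2$log$val_loss, fit3$log$val_loss)
  expect_error(train_config(epochs = 0L), "epoch")
})

test_that("early stopping keeps the best-validation checkpoint", {
  # trace the rule directly: patience 2, losses [1.0, 0.9, 0.95, 0.96]
  # -> training stops after epoch 4 and epoch 2 is best
  losses <- c(1.0, 0.9, 0.95, 0.96, 0.8)
  best <- Inf; since <- 0L; stopped_at <- NA
  for (e in seq_along(losses)) {
    if (losses[e] < best) { best <- losses[e]; since <- 0L }
    else since <- since + 1L
    if (since >= 2L) { stopped_at <- e; break }
  }
  expect_equal(stopped_at, 4L)
  expect_equal(best, 0.9)
})

test_that("transfer freezing: all-frozen is a no-op, last_k trains the head", {
  genes <- lapply(1:4, function(i) structure(
    list(gene_id = paste0("g", i), sequence = rand_dna(300, i),
         labels = integer(300), donor_positions = integer(0),
         acceptor_positions = integer(0)), class = "labeled_gene"))
  genes <- lapply(genes, function(g) { g$labels[150] <- 2L; g })
  ds <- encode_dataset(genes, core = 300L, flank = 100L)
  pre <- init_model(build_config(80, channels = 6L), seed = 3)
  # k = 0: returned weights identical to pretrained
  fr <- transfer_model(pre, ds, unfreeze = "last_k", k = 0L,
                       config = train_config(epochs = 2L, seed = 1L))
  expect_identical(fr$model$params, pre$params)
  # k = 1: only the final projection changes
  f1 <- transfer_model(pre, ds, unfreeze = "last_k", k = 1L,
                       config = train_config(epochs = 1L, seed = 1L))
  expect_false(identical(f1$model$params$conv_out, pre$params$conv_out))
  expect_identical(f1$model$params$conv_in, pre$params$conv_in)
  expect_identical(f1$model$params$units, pre$params$units)
  expect_identical(f1$model$params$skips, pre$params$skips)
  # flank mismatch errors
  expect_error(transfer_model(pre, ds, flank = 400L), "flanking size")
})
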