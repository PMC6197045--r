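test_that("the learning-rate schedule halves every period", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 3e-4)
  expect_equal(lr_schedule(100, cfg), 1.5e-4)
  expect_equal(lr_schedule(250, cfg), 7.5e-5)
  # closed form across a long sweep
  e <- 0:1000
  expect_equal(lr_schedule(e, cfg), 3e-4 * 0.5^(e %/% 100))
  cfg2 <- train_config(base_lr = 0.01, lr_halving_period_epochs = 10)
  expect_equal(lr_schedule(25, cfg2), 0.01 * 0.25)
})

test_that("sgd_step gradients match central finite differences", {
  # miniature network: 8 x 1 input, one block, no dropout (oracle gate)
  sp <- network_spec(input_len = 8L, input_channels = 1L,
                     blocks = list(c(3L, 2L)), fc_width = 4L,
                     dropout = 0, n_classes = 3L)
  p <- init_network(sp, 21)
  # shrink the weights so the softmax is far from saturation: near-zero
  # gradients would drown the finite-difference oracle in rounding noise
  p$blocks[[1]]$f <- p$blocks[[1]]$f * 0.4
  p$fc1$W <- p$fc1$W * 0.4
  p$fc2$W <- p$fc2$W * 0.4
  set.seed(21)
  X <- array(rnorm(8), c(8, 1, 1))
  y <- 2L
  fwd <- harcnn:::net_forward(X, p, cache = TRUE)
  sx <- harcnn:::softmax_xent(fwd$logits, y)
  g <- harcnn:::net_backward(sx$dlogits, p, fwd$cache)

  spots <- list(
    list(function(q) q$blocks[[1]]$f[2, 1, 1, 2],
         function(q, v) { q$blocks[[1]]$f[2, 1, 1, 2] <- v; q },
         g$blocks[[1]]$f[2, 1, 1, 2]),
    list(function(q) q$blocks[[1]]$b[1],
         function(q, v) { q$blocks[[1]]$b[1] <- v; q },
         g$blocks[[1]]$b[1]),
    list(function(q) q$fc1$W[3, 2],
         function(q, v) { q$fc1$W[3, 2] <- v; q }, g$fc1$W[3, 2]),
    list(function(q) q$fc2$W[1, 3],
         function(q, v) { q$fc2$W[1, 3] <- v; q }, g$fc2$W[1, 3]),
    list(function(q) q$fc2$b[2],
         function(q, v) { q$fc2$b[2] <- v; q }, g$fc2$b[2]))
  for (s in spots) {
    num <- oracle_num_grad(p, X, y, s[[1]], s[[2]])
    expect_lt(abs(s[[3]] - num) / max(abs(num), 1e-6), 1e-4)
  }
})

test_that("sgd_step respects lr = 0, descends, and flags divergence", {
  sp <- network_spec(input_len = 8L, input_channels = 1L,
                     blocks = list(c(3L, 2L)), fc_width = 4L,
                     dropout = 0, n_classes = 3L)
  p <- init_network(sp, 3)
  p$classes <- c("WS", "JR", "NA")
  set.seed(3)
  # bare window stand-ins: the tiny 8 x 1 geometry is not a valid 128 x 3
  # domain window, so plain lists with $values / $label are used
  batch <- lapply(1:4, function(i) {
    list(values = matrix(rnorm(8), 8, 1),
         label = sample(c("WS", "JR", "NA"), 1))
  })

  cfg <- train_config(momentum = 0, weight_decay = 0)
  s0 <- sgd_step(p, batch, lr = 0, cfg)
  expect_identical(s0$params$fc1$W, p$fc1$W)
  expect_identical(s0$params$blocks[[1]]$f, p$blocks[[1]]$f)

  # plain gradient descent decreases the loss for a small lr
  s1 <- sgd_step(p, batch, lr = 1e-2, cfg)
  s2 <- sgd_step(s1$params, batch, 1e-2, cfg, s1$state)
  expect_lte(s2$loss, s1$loss)

  # blowing up the weights must raise the divergence signal
  p_bad <- p
  p_bad$fc2$W[] <- 1e308
  expect_error(sgd_step(p_bad, batch, 1e-2, cfg),
               class = "harcnn_divergence")
})

test_that("early stopping fires at the first positive smoothed slope", {
  expect_null(detect_early_stop(seq(2, 1, length.out = 30), 5))
  expect_identical(detect_early_stop(c(1.0, 0.8, 0.7, 0.75, 0.9), 1), 3L)
  expect_null(detect_early_stop(rep(1, 20), 5))        # zero slope: no stop
  expect_null(detect_early_stop(c(1, 0.9), 5))         # too few epochs
  # smoothing suppresses a one-epoch blip
  blip <- c(1, 0.9, 0.8, 0.85, 0.7, 0.65, 0.6, 0.55, 0.5, 0.45)
  expect_null(detect_early_stop(blip, 3))
  expect_identical(detect_early_stop(blip, 1), 3L)
})

test_that("training on a separable toy descends and is reproducible", {
  b <- toy_bundle(seed = 8)
  folds <- make_folds(b, 2L)
  cfg <- train_config(base_lr = 3e-3, max_epochs = 5L, batch_size = 32L,
                      rng_seed = 13)
  fit <- train_network(b, folds, 1L, cfg, spec = toy_spec(3L))
  expect_identical(nrow(fit$history), 5L)
  expect_identical(fit$history$lr, rep(3e-3, 5))
  # smoothed (window-2) training loss is non-increasing on separable data
  sm <- stats::filter(fit$history$train_loss, rep(0.5, 2), sides = 1)[-1]
  expect_true(all(diff(sm) < 1e-6))

  fit2 <- train_network(b, folds, 1L, cfg, spec = toy_spec(3L))
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params$fc2$W, fit2$params$fc2$W)

  expect_error(train_network(b, folds, 3L, cfg, spec = toy_spec(3L)),
               class = "harcnn_bad_value")
})

test_that("cross-validation partitions the bundle exactly once", {
  b <- toy_bundle(seed = 15)
  cfg <- train_config(base_lr = 3e-3, max_epochs = 3L, batch_size = 32L,
                      rng_seed = 4)
  cv <- cross_validate(b, cfg, k = 2L, spec = toy_spec(3L))
  expect_length(cv$matrices, 2L)
  # conservation: each window validated exactly once
  expect_identical(sum(cv$pooled), length(b$windows))
  per_class_true <- rowSums(cv$pooled)
  expect_identical(as.integer(per_class_true[names(table(b$labels))]),
                   as.integer(table(b$labels)[names(table(b$labels))]))
  expect_identical(Reduce(`+`, cv$matrices), cv$pooled)
})
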