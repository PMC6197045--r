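test_that("conv_layer matches the brute-force oracle", {
  # identity 1x1 filter
  x <- array(rnorm(12), c(4, 1, 3))
  f_id <- array(0, c(1, 1, 3, 3))
  for (d in 1:3) f_id[1, 1, d, d] <- 1
  expect_equal(conv_layer(x, f_id), x, tolerance = 1e-12)

  # hand-computed column: (1,2,3,4) * (1,1) -> (3,5,7)
  xc <- array(c(1, 2, 3, 4), c(4, 1, 1))
  fc <- array(c(1, 1), c(2, 1, 1, 1))
  expect_equal(as.vector(conv_layer(xc, fc)), c(3, 5, 7))

  # random instances against nested loops, several shapes
  set.seed(11)
  shapes <- list(list(c(10, 1, 3), c(3, 1, 3, 5)),
                 list(c(12, 1, 4), c(4, 1, 4, 6)),
                 list(c(8, 5, 2), c(3, 2, 2, 4)))
  for (sh in shapes) {
    x <- array(rnorm(prod(sh[[1]])), sh[[1]])
    f <- array(rnorm(prod(sh[[2]])), sh[[2]])
    b <- rnorm(sh[[2]][4])
    expect_equal(conv_layer(x, f, b), oracle_conv(x, f, b),
                 tolerance = 1e-9)
  }

  # depth mismatch
  expect_error(conv_layer(array(0, c(5, 1, 2)), array(0, c(2, 1, 3, 1))),
               class = "harcnn_bad_shape")
})

test_that("max_pool takes exclusive maxima and drops remainders", {
  col <- function(v) array(v, c(length(v), 1, 1))
  expect_equal(as.vector(max_pool(col(c(1, 3, 2, 4)))), c(3, 4))
  expect_equal(as.vector(max_pool(col(c(5, 1, 4, 2, 9)))), c(5, 4))
  expect_equal(as.vector(max_pool(col(rep(7, 6)))), rep(7, 3))
  # per-channel independence on a random tensor vs plain apply oracle
  set.seed(2)
  x <- array(rnorm(12 * 1 * 3), c(12, 1, 3))
  got <- max_pool(x)
  for (d in 1:3) {
    expect_equal(as.vector(got[, 1, d]),
                 apply(matrix(x[, 1, d], nrow = 2), 2, max))
  }
})

test_that("relu and softmax honour their contracts", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(relu(-(1:5)), rep(0, 5))
  x <- abs(rnorm(10))
  expect_equal(relu(x), x)

  expect_equal(softmax(rep(0, 10)), rep(0.1, 10))
  expect_equal(softmax(log(c(1, 3))), c(0.25, 0.75))
  s <- rnorm(10)
  expect_equal(softmax(s), softmax(s + 42))
  # simplex under large shifts (max-subtraction stability)
  p <- softmax(c(1000, 970, 985, 990 + rnorm(7)))
  expect_true(all(p > 0 & p < 1))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(softmax(c(1, Inf)))
})

test_that("the published layer-shape chain is asserted at construction", {
  sp <- network_spec()
  expect_identical(sp$shape_chain, c(122L, 61L, 56L, 28L, 24L, 12L))
  expect_identical(sp$flat_len, 1296L)
  expect_identical(vapply(sp$filter_shapes, `[`, integer(1), 4),
                   c(72L, 144L, 108L))
  # depths are read from the incoming tensor
  expect_identical(vapply(sp$filter_shapes, `[`, integer(1), 3),
                   c(3L, 72L, 144L))
  expect_error(network_spec(input_len = 4L), class = "harcnn_bad_shape")
})

test_that("forward is a deterministic probability distribution", {
  sp <- toy_spec(10L)
  p <- init_network(sp, 5)
  w <- new_window(matrix(rnorm(128 * 3), 128, 3), "WS", "s")
  pr <- forward(w, p)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_identical(pr, forward(w, p))   # dropout off: bit-reproducible

  # zero weights -> exactly uniform, and prediction ties break to WS
  pz <- p
  for (i in seq_along(pz$blocks)) pz$blocks[[i]]$f[] <- 0
  pz$fc1$W[] <- 0; pz$fc2$W[] <- 0
  expect_equal(unname(forward(w, pz)), rep(0.1, 10))
  expect_identical(predict_activity(w, pz), "WS")

  expect_error(forward(matrix(0, 64, 3), p), class = "harcnn_bad_shape")
})

test_that("forward equals the composition of the public layer ops", {
  # dual route: fast batched path vs conv_layer/max_pool/relu/softmax
  sp <- network_spec()
  p <- init_network(sp, 3)
  w <- matrix(rnorm(128 * 3), 128, 3)
  a <- array(w, c(128, 1, 3))
  for (i in 1:3) {
    a <- relu(max_pool(conv_layer(a, p$blocks[[i]]$f, p$blocks[[i]]$b), 2, 1))
  }
  flat <- as.vector(aperm(a, c(1, 3, 2)))
  z <- drop((drop(flat %*% p$fc1$W) + p$fc1$b) %*% p$fc2$W) + p$fc2$b
  expect_equal(unname(forward(w, p)), softmax(z), tolerance = 1e-12)
})

test_that("compiled batched kernels agree with the plain-R reference route", {
  set.seed(19)
  for (r in 1:8) {
    H <- sample(6:24, 1); B <- sample(1:6, 1); D <- sample(1:5, 1)
    h <- sample(2:min(5, H - 1), 1); C <- sample(1:7, 1)
    X <- array(rnorm(H * B * D), c(H, B, D))
    f <- array(rnorm(h * D * C), c(h, 1, D, C))
    b <- rnorm(C)
    fw <- harcnn:::conv1d_fwd(X, f, b, cache = TRUE)
    expect_equal(fw$Y, harcnn:::conv1d_fwd_r(X, f, b), tolerance = 1e-12)
    dY <- array(rnorm(length(fw$Y)), dim(fw$Y))
    bw <- harcnn:::conv1d_bwd(dY, f, fw)
    ref <- harcnn:::conv1d_bwd_r(dY, f, X)
    expect_equal(bw$dX, ref$dX, tolerance = 1e-12)
    expect_equal(bw$df, ref$df, tolerance = 1e-12)
    expect_equal(bw$db, ref$db, tolerance = 1e-12)

    # pooling: forward maxima and a gradient that routes to the argmax only
    if (H %% 2 == 0) {
      pf <- harcnn:::pool1d_fwd(X, 2L)
      o <- seq(1, H - 1, 2)
      expect_equal(pf$Y,
                   pmax(X[o, , , drop = FALSE], X[o + 1, , , drop = FALSE]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      dY <- array(rnorm(length(pf$Y)), dim(pf$Y))
      bx <- harcnn:::pool1d_bwd(dY, pf, 2L)
      expect_equal(sum(bx), sum(dY), tolerance = 1e-9)
      expect_lte(sum(bx != 0), length(dY))
    }
  }
})

test_that("zero_one_loss complements accuracy", {
  expect_identical(zero_one_loss("WS", "WS"), 0L)
  expect_identical(zero_one_loss("WS", "WF"), 1L)
  preds <- c("WS", "JR", "NA", "NA")
  truths <- c("WS", "JR", "WS", "NA")
  expect_equal(mean(zero_one_loss(preds, truths)),
               1 - mean(preds == truths))
})

test_that("parameter containers round-trip with shape validation", {
  p <- init_network(toy_spec(3L), 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(p, f)
  q <- load_network(f)
  expect_identical(q$blocks[[1]]$f, p$blocks[[1]]$f)
  expect_identical(q$seed, 9L)
  # corrupt a shape: loading must fail
  p_bad <- p
  p_bad$fc1$W <- p_bad$fc1$W[, -1]
  expect_error(save_network(p_bad, f), class = "harcnn_bad_shape")
})
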