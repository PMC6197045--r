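# Layer primitives. Public single-tensor operations (conv_layer, max_pool,
# relu, softmax) share one batched im2col engine with the training path, so
# the oracle tests on the public ops cover the code the network actually
# runs.
#
# Tensors are numeric arrays indexed (height, width, depth); batched
# internals add a trailing batch index. Convolution is "valid" (no padding),
# stride 1: output height H - H' + 1, width W - W' + 1. Pooling areas are
# exclusive (stride = pool size); a trailing remainder is dropped.

# base im2col index matrix: rows ordered (i'' fast, then j''), columns
# ordered (i' fast, then j', then d). Adding (b-1)*H*W*D gives batch b.
im2col_index <- function(H, W, D, h, w) {
  H2 <- H - h + 1L
  W2 <- W - w + 1L
  rowbase <- as.vector(outer(0:(H2 - 1L), (0:(W2 - 1L)) * H, "+"))
  colbase <- as.vector(outer(outer(0:(h - 1L), (0:(w - 1L)) * H, "+"),
                             (0:(D - 1L)) * (H * W), "+"))
  list(A = outer(rowbase, colbase, "+") + 1L, H2 = H2, W2 = W2)
}

# X: (H, W, D, B) array -> list(M, ...) with M ((H2*W2*B) x (h*w*D)),
# rows grouped batch-major.
im2col <- function(X, h, w) {
  d <- dim(X)
  ix <- im2col_index(d[1], d[2], d[3], h, w)
  B <- d[4]
  if (B == 1L) {
    M <- matrix(X[ix$A], nrow(ix$A), ncol(ix$A))
  } else {
    big <- ix$A[rep(seq_len(nrow(ix$A)), B), , drop = FALSE] +
      rep((0:(B - 1L)) * prod(d[1:3]), each = nrow(ix$A))
    M <- matrix(X[big], nrow(big), ncol(big))
    ix$A_big <- big
  }
  ix$M <- M
  ix
}

conv_fwd <- function(X, f, b, cache = FALSE) {
  dX <- dim(X); df <- dim(f)
  if (df[3] != dX[3]) {
    stop_harcnn("harcnn_bad_shape",
                "filter depth %d does not match input depth %d", df[3], dX[3])
  }
  if (df[1] > dX[1] || df[2] > dX[2]) {
    stop_harcnn("harcnn_bad_shape", "filter spatial extent exceeds input")
  }
  ic <- im2col(X, df[1], df[2])
  Wmat <- matrix(f, prod(df[1:3]), df[4])
  Y <- ic$M %*% Wmat
  Y <- sweep(Y, 2L, b, "+")
  B <- dX[4]
  # rows are (i'' fast, j'', batch); columns d'' -> (H2, W2, B, D'') then
  # permute to (H2, W2, D'', B)
  dim(Y) <- c(ic$H2, ic$W2, B, df[4])
  Y <- aperm(Y, c(1L, 2L, 4L, 3L))
  if (cache) list(Y = Y, ic = ic, dims_in = dX) else list(Y = Y)
}

conv_bwd <- function(dY, f, cache) {
  df <- dim(f)
  B <- dim(dY)[4]
  dYm <- aperm(dY, c(1L, 2L, 4L, 3L))
  dim(dYm) <- c(cache$ic$H2 * cache$ic$W2 * B, df[4])
  Wmat <- matrix(f, prod(df[1:3]), df[4])
  dW <- crossprod(cache$ic$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, Wmat)
  dXflat <- numeric(prod(cache$dims_in))
  A <- if (B == 1L) cache$ic$A else cache$ic$A_big
  for (cc in seq_len(ncol(A))) {
    idx <- A[, cc]
    dXflat[idx] <- dXflat[idx] + dM[, cc]
  }
  dim(dW) <- df
  list(dX = array(dXflat, cache$dims_in), df = dW, db = db)
}

pool_fwd <- function(X, ph, pw) {
  d <- dim(X)
  H2 <- d[1] %/% ph
  W2 <- d[2] %/% pw
  if (H2 < 1L || W2 < 1L) {
    stop_harcnn("harcnn_bad_shape", "pool area exceeds input extent")
  }
  Y <- array(-Inf, c(H2, W2, d[3], d[4]))
  win <- array(1L, c(H2, W2, d[3], d[4]))
  for (jp in seq_len(pw)) {
    cols <- (seq_len(W2) - 1L) * pw + jp
    for (ip in seq_len(ph)) {
      rows <- (seq_len(H2) - 1L) * ph + ip
      cand <- X[rows, cols, , , drop = FALSE]
      upd <- cand > Y
      Y[upd] <- cand[upd]
      win[upd] <- (jp - 1L) * ph + ip
    }
  }
  list(Y = Y, win = win, dims_in = d)
}

pool_bwd <- function(dY, cache, ph, pw) {
  d <- cache$dims_in
  H2 <- dim(dY)[1]; W2 <- dim(dY)[2]
  dX <- array(0, d)
  for (jp in seq_len(pw)) {
    cols <- (seq_len(W2) - 1L) * pw + jp
    for (ip in seq_len(ph)) {
      rows <- (seq_len(H2) - 1L) * ph + ip
      sel <- cache$win == (jp - 1L) * ph + ip
      sub <- dX[rows, cols, , , drop = FALSE]
      sub[sel] <- sub[sel] + dY[sel]
      dX[rows, cols, , ] <- sub
    }
  }
  dX
}

#' Convolution layer (valid, stride 1)
#'
#' Each output element is the bias plus the triple sum over the filter's
#' height, width and depth of filter x input products.
#'
#' @param input Numeric array `(H, W, D)`.
#' @param filters Numeric array `(H', W', D, D'')`; depth must match input.
#' @param bias Numeric vector of length `D''` (default zeros).
#' @return Array `(H - H' + 1, W - W' + 1, D'')`.
#' @export
conv_layer <- function(input, filters, bias = numeric(dim(filters)[4])) {
  input <- as_tensor3(input)
  stopifnot(length(dim(filters)) == 4L, length(bias) == dim(filters)[4])
  dim(input) <- c(dim(input), 1L)
  out <- conv_fwd(input, filters, bias)$Y
  array(out, dim(out)[1:3])
}

#' Exclusive max pooling
#'
#' Non-overlapping maxima over `pool_h x pool_w` areas per depth channel;
#' trailing rows/columns that do not fill an area are dropped
#' (`floor` rule).
#'
#' @param input Numeric array `(H, W, D)`.
#' @param pool_h,pool_w Pool area (defaults 2, 1).
#' @return Array `(floor(H/pool_h), floor(W/pool_w), D)`.
#' @export
max_pool <- function(input, pool_h = 2L, pool_w = 1L) {
  input <- as_tensor3(input)
  stopifnot(pool_h >= 1L, pool_w >= 1L)
  dim(input) <- c(dim(input), 1L)
  out <- pool_fwd(input, as.integer(pool_h), as.integer(pool_w))$Y
  array(out, dim(out)[1:3])
}

#' Rectified linear activation
#'
#' @param input Numeric array or vector.
#' @return `max(0, input)` elementwise, shape preserved.
#' @export
relu <- function(input) {
  pmax(input, 0)
}

#' Numerically stable softmax
#'
#' Computed with max-subtraction; entries lie in (0, 1) and sum to 1.
#'
#' @param scores Numeric vector of finite scores.
#' @return Probability vector of the same length.
#' @export
softmax <- function(scores) {
  stopifnot(is.numeric(scores), all(is.finite(scores)))
  z <- exp(scores - max(scores))
  z / sum(z)
}

## ---- fast 1-D path --------------------------------------------------------
# The network itself is 1-D (W = 1 throughout), so the training loop uses a
# dedicated layout (H, B, D) -- batch in the middle. The memory-bound
# pieces (im2col gather, col2im scatter, pooling) are compiled (src/), and
# the big matrix products run in R on BLAS. conv1d_fwd_r / conv1d_bwd_r are
# plain-R reference implementations of the same arithmetic, kept for the
# dual-route tests.

# X: (H, B, D); f: (h, 1, D, C) filter bank
conv1d_fwd <- function(X, f, b, cache = FALSE) {
  d <- dim(X); df <- dim(f)
  M <- cpp_im2col1d(X, d[1], d[2], d[3], df[1])
  Y <- M %*% matrix(f, df[1] * df[3], df[4])
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(d[1] - df[1] + 1L, d[2], df[4])
  if (cache) list(Y = Y, M = M, dims_in = d) else list(Y = Y)
}

conv1d_bwd <- function(dY, f, cache) {
  df <- dim(f)
  d <- cache$dims_in
  C <- df[4]
  dYm <- dY
  dim(dYm) <- c(length(dY) %/% C, C)
  dW <- crossprod(cache$M, dYm)
  dim(dW) <- df
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, matrix(f, df[1] * df[3], C))
  list(dX = cpp_col2im1d(dM, d[1], d[2], d[3], df[1]), df = dW, db = db)
}

# reference route: shift-and-multiply, no compiled code
conv1d_fwd_r <- function(X, f, b) {
  d <- dim(X); df <- dim(f)
  h <- df[1]; D <- df[3]; C <- df[4]
  H2 <- d[1] - h + 1L; B <- d[2]
  Y <- matrix(rep(b, each = H2 * B), H2 * B, C)
  for (ii in seq_len(h)) {
    Xs <- X[ii:(ii + H2 - 1L), , , drop = FALSE]
    dim(Xs) <- c(H2 * B, D)
    Y <- Y + Xs %*% matrix(f[ii, 1L, , ], D, C)
  }
  dim(Y) <- c(H2, B, C)
  Y
}

conv1d_bwd_r <- function(dY, f, X) {
  d <- dim(X); df <- dim(f)
  h <- df[1]; D <- df[3]; C <- df[4]
  H2 <- dim(dY)[1]; B <- d[2]
  dYm <- dY
  dim(dYm) <- c(H2 * B, C)
  dW <- array(0, df)
  dX <- array(0, d)
  for (ii in seq_len(h)) {
    rows <- ii:(ii + H2 - 1L)
    Xs <- X[rows, , , drop = FALSE]
    dim(Xs) <- c(H2 * B, D)
    dW[ii, 1L, , ] <- crossprod(Xs, dYm)
    dM <- tcrossprod(dYm, matrix(f[ii, 1L, , ], D, C))
    dim(dM) <- c(H2, B, D)
    dX[rows, , ] <- dX[rows, , , drop = FALSE] + dM
  }
  list(dX = dX, df = dW, db = colSums(dYm))
}

pool1d_fwd <- function(X, ph) {
  d <- dim(X)
  out <- cpp_pool1d_fwd(X, d[1], d[2], d[3], as.integer(ph))
  list(Y = out$Y, win = out$win, dims_in = d)
}

pool1d_bwd <- function(dY, cache, ph) {
  d <- cache$dims_in
  cpp_pool1d_bwd(dY, cache$win, d[1], d[2], d[3], as.integer(ph))
}

# coerce vectors / matrices to (H, W, D) arrays for the public ops
as_tensor3 <- function(x) {
  if (is.null(dim(x))) {
    x <- array(as.double(x), c(length(x), 1L, 1L))
  } else if (length(dim(x)) == 2L) {
    x <- array(as.double(x), c(dim(x), 1L))
  } else if (length(dim(x)) != 3L) {
    stop_harcnn("harcnn_bad_shape", "expected a rank-3 tensor")
  }
  if (!all(is.finite(x))) {
    stop_harcnn("harcnn_bad_value", "tensor contains non-finite entries")
  }
  x
}
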