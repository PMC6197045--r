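# Network geometry and parameter initialization.
#
# The classifier is a 1-D convolutional network over 128 x 1 x 3 windows:
# three blocks of (valid convolution, stride 1) -> (exclusive 2 x 1 max
# pool) -> ReLU, then flatten -> fully-connected 256 -> dropout 0.5 ->
# fully-connected n_classes -> softmax. Filter banks default to
# 7x1x3x72, 6x1x?x144 and 5x1x?x108; the depth of blocks 2 and 3 is taken
# from the incoming tensor (72 and 144 channels) since filters must span the
# full channel depth for the shapes to compose. The resulting spatial chain
# is 128 -> 122 -> 61 -> 56 -> 28 -> 24 -> 12, flattened to 12 * 108 = 1296.

#' Network specification
#'
#' @param input_len Window length (default 128).
#' @param input_channels Sensor axes (default 3).
#' @param blocks List of `c(filter_h, out_channels)` per convolution block;
#'   default `list(c(7, 72), c(6, 144), c(5, 108))`. Filter depth always
#'   equals the incoming channel count.
#' @param pool_h Max-pool height (exclusive areas, default 2).
#' @param fc_width Fully-connected width (default 256).
#' @param dropout Dropout rate at the penultimate layer (default 0.5).
#' @param n_classes Output classes (default 10).
#' @return Object of class `har_network_spec` including the derived
#'   `shape_chain` (spatial size after every conv and pool) and `flat_len`.
#' @export
#' @examples
#' network_spec()$shape_chain   # 122 61 56 28 24 12
network_spec <- function(input_len = 128L, input_channels = 3L,
                         blocks = list(c(7L, 72L), c(6L, 144L), c(5L, 108L)),
                         pool_h = 2L, fc_width = 256L, dropout = 0.5,
                         n_classes = 10L) {
  stopifnot(input_len >= 1, input_channels >= 1, length(blocks) >= 1,
            pool_h >= 1, fc_width >= 1, dropout >= 0, dropout < 1,
            n_classes >= 2)
  h <- input_len
  depth <- input_channels
  chain <- integer(0)
  shapes <- list()
  for (bl in blocks) {
    fh <- as.integer(bl[[1]]); out <- as.integer(bl[[2]])
    if (fh > h) {
      stop_harcnn("harcnn_bad_shape",
                  "filter height %d exceeds incoming spatial size %d", fh, h)
    }
    h <- h - fh + 1L
    chain <- c(chain, h)
    shapes[[length(shapes) + 1L]] <- c(fh, 1L, depth, out)
    h <- h %/% pool_h
    chain <- c(chain, h)
    depth <- out
  }
  if (h < 1L) stop_harcnn("harcnn_bad_shape", "network collapses to zero size")
  structure(
    list(input_len = as.integer(input_len),
         input_channels = as.integer(input_channels),
         filter_shapes = shapes, pool_h = as.integer(pool_h),
         fc_width = as.integer(fc_width), dropout = dropout,
         n_classes = as.integer(n_classes),
         shape_chain = chain, flat_len = h * depth),
    class = "har_network_spec"
  )
}

#' Initialize network parameters
#'
#' Variance-scaled (He) Gaussian weights, zero biases, with the seed
#' recorded so any parameter set can be regenerated exactly.
#'
#' @param spec A [network_spec()].
#' @param seed Integer RNG seed.
#' @return Object of class `har_network_params`: per-block filter banks
#'   (`f` 4-D array, `b` bias vector), fully-connected layers `fc1`/`fc2`,
#'   the embedded `spec`, `seed` and a format `version`.
#' @export
init_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "har_network_spec"))
  with_seed(seed, {
    blocks <- lapply(spec$filter_shapes, function(sh) {
      fan_in <- prod(sh[1:3])
      list(f = array(stats::rnorm(prod(sh), sd = sqrt(2 / fan_in)), dim = sh),
           b = numeric(sh[4]))
    })
    fc1 <- list(
      W = matrix(stats::rnorm(spec$flat_len * spec$fc_width,
                              sd = sqrt(2 / spec$flat_len)),
                 spec$flat_len, spec$fc_width),
      b = numeric(spec$fc_width))
    fc2 <- list(
      W = matrix(stats::rnorm(spec$fc_width * spec$n_classes,
                              sd = sqrt(2 / spec$fc_width)),
                 spec$fc_width, spec$n_classes),
      b = numeric(spec$n_classes))
    structure(
      list(spec = spec, seed = as.integer(seed), version = "harcnn-params-1",
           blocks = blocks, fc1 = fc1, fc2 = fc2),
      class = "har_network_params"
    )
  })
}

validate_params <- function(params) {
  stopifnot(inherits(params, "har_network_params"))
  spec <- params$spec
  for (i in seq_along(spec$filter_shapes)) {
    if (!identical(dim(params$blocks[[i]]$f),
                   as.integer(spec$filter_shapes[[i]]))) {
      stop_harcnn("harcnn_bad_shape", "block %d filter bank has wrong shape", i)
    }
    if (length(params$blocks[[i]]$b) != spec$filter_shapes[[i]][4]) {
      stop_harcnn("harcnn_bad_shape", "block %d bias has wrong length", i)
    }
  }
  if (!identical(dim(params$fc1$W), c(spec$flat_len, spec$fc_width)) ||
      !identical(dim(params$fc2$W), c(spec$fc_width, spec$n_classes))) {
    stop_harcnn("harcnn_bad_shape", "fully-connected shapes inconsistent")
  }
  invisible(params)
}

#' Save / load network parameters
#'
#' Parameters are stored as a versioned serialized container embedding the
#' spec and initialization seed; [load_network()] validates all shapes.
#'
#' @param params A `har_network_params` object.
#' @param path Destination / source file path.
#' @return `save_network()` returns `path` invisibly; `load_network()` the
#'   validated parameters.
#' @export
save_network <- function(params, path) {
  validate_params(params)
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  params <- readRDS(path)
  if (!identical(params$version, "harcnn-params-1")) {
    stop_harcnn("harcnn_bad_value", "unknown parameter container version")
  }
  validate_params(params)
  params
}
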