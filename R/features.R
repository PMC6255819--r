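#' Layer specifications
#'
#' Constructors for the three layer kinds of the configurable feature
#' hierarchy. Convolutions use odd square kernels with same-size padding
#' (zero by default, circular available for shift-invariance experiments);
#' pooling floor-divides the spatial dimensions; dense layers flatten their
#' input.
#'
#' @param out_channels Number of output channels / units (>= 1).
#' @param kernel Odd kernel side in pixels.
#' @param activation `"relu"` or `"none"`.
#' @param mode Pooling mode, `"avg"` (default) or `"max"`.
#' @param size Pooling window and stride.
#' @return A `layer_spec` list.
#' @export
conv_layer <- function(out_channels, kernel = 3L, activation = "relu") {
  if (!is_count(out_channels, 1)) abort_param("`out_channels` must be a positive integer")
  if (!is_count(kernel, 1) || kernel %% 2 == 0)
    abort_param("`kernel` must be odd and >= 1")
  activation <- match.arg(activation, c("relu", "none"))
  structure(list(kind = "conv", out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), activation = activation),
            class = "layer_spec")
}

#' @rdname conv_layer
#' @export
pool_layer <- function(mode = "avg", size = 2L) {
  mode <- match.arg(mode, c("avg", "max"))
  if (!is_count(size, 2)) abort_param("pool `size` must be an integer >= 2")
  structure(list(kind = "pool", mode = mode, size = as.integer(size)),
            class = "layer_spec")
}

#' @rdname conv_layer
#' @export
dense_layer <- function(out_channels, activation = "relu") {
  if (!is_count(out_channels, 1)) abort_param("`out_channels` must be a positive integer")
  activation <- match.arg(activation, c("relu", "none"))
  structure(list(kind = "dense", out_channels = as.integer(out_channels),
                 activation = activation),
            class = "layer_spec")
}

#' Network configuration
#'
#' An ordered stack of [conv_layer()], [pool_layer()] and [dense_layer()]
#' specs plus the bookkeeping needed to build deterministic weights.
#' `gram_layers` names the layers whose (spatial) outputs feed the texture
#' statistics; they must precede any dense layer.
#'
#' @param layers List of `layer_spec` objects.
#' @param input_channels Channels of the input image (1 for grayscale).
#' @param weight_seed Integer seed that fully determines the weights.
#' @param gram_layers Integer indices into `layers`.
#' @param padding `"zero"` (default) or `"circular"` convolution padding.
#' @return A `network_config` object.
#' @export
#' @examples
#' cfg <- desk_net_config()
#' count_weight_layers(cfg)
network_config <- function(layers, input_channels = 1L, weight_seed = 1L,
                           gram_layers = integer(), padding = "zero") {
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec")))
    abort_param("`layers` must be a nonempty list of layer_spec objects")
  padding <- match.arg(padding, c("zero", "circular"))
  kinds <- vapply(layers, `[[`, "", "kind")
  first_dense <- match("dense", kinds, nomatch = length(kinds) + 1L)
  if (any(which(kinds != "dense") > first_dense))
    abort_param("dense layers must come after all conv/pool layers")
  gram_layers <- as.integer(gram_layers)
  if (any(gram_layers < 1 | gram_layers > length(layers)))
    abort_param("`gram_layers` indices out of range")
  if (any(kinds[gram_layers] == "dense"))
    abort_param("`gram_layers` must reference layers with spatial feature maps")
  structure(list(layers = layers, input_channels = as.integer(input_channels),
                 weight_seed = as.integer(weight_seed),
                 gram_layers = gram_layers, padding = padding),
            class = "network_config")
}

#' Default desk-scale architecture
#'
#' Three 3x3 convolutions (8, 16, 32 channels, relu) separated by 2x2 average
#' pools; texture statistics are taken from all three post-activation conv
#' outputs. Small enough to synthesize on one CPU in seconds while still
#' giving a hierarchy of receptive-field sizes.
#'
#' @param weight_seed Seed for the weights.
#' @param padding Convolution padding mode.
#' @return A [network_config()].
#' @export
desk_net_config <- function(weight_seed = 1L, padding = "zero") {
  network_config(
    layers = list(conv_layer(8), pool_layer("avg"), conv_layer(16),
                  pool_layer("avg"), conv_layer(32)),
    input_channels = 1L, weight_seed = weight_seed,
    gram_layers = c(1L, 3L, 5L), padding = padding)
}

#' Count weight-bearing layers in a configuration
#'
#' Conv and dense layers carry weights; pooling does not.
#' @param config A [network_config()].
#' @return Integer count.
#' @export
count_weight_layers <- function(config) {
  sum(vapply(config$layers, `[[`, "", "kind") %in% c("conv", "dense"))
}

#' Build a network with deterministic seeded weights
#'
#' Conv filter banks are drawn from a zero-mean Gaussian with standard
#' deviation `1/sqrt(fan_in)` (`fan_in = in_channels * kernel^2`) in a single
#' seeded sweep over the layers; biases start at zero. Dense-layer weights
#' are a deterministic function of `(weight_seed, layer index, fan_in)`
#' materialised at forward time, because their fan-in depends on the input
#' resolution. Identical config and seed give bit-identical weights.
#'
#' @param config A [network_config()].
#' @return A `texture_net` object.
#' @export
#' @examples
#' net <- build_network(desk_net_config())
build_network <- function(config) {
  if (!inherits(config, "network_config")) abort_param("`config` must be a network_config")
  layers <- vector("list", length(config$layers))
  in_ch <- config$input_channels
  with_seed(config$weight_seed, {
    for (i in seq_along(config$layers)) {
      sp <- config$layers[[i]]
      if (sp$kind == "conv") {
        fan_in <- in_ch * sp$kernel^2
        W <- matrix(rnorm(sp$out_channels * fan_in, sd = 1 / sqrt(fan_in)),
                    nrow = sp$out_channels)
        layers[[i]] <- c(sp, list(W = W, b = numeric(sp$out_channels),
                                  in_channels = in_ch))
        in_ch <- sp$out_channels
      } else if (sp$kind == "pool") {
        layers[[i]] <- c(sp, list(in_channels = in_ch))
      } else { # dense: weights deferred until fan-in is known
        layers[[i]] <- c(sp, list(W = NULL, b = NULL))
        in_ch <- sp$out_channels
      }
    }
  })
  structure(list(config = config, layers = layers, head = NULL),
            class = "texture_net")
}

# ---- internal conv engine ---------------------------------------------------

# Patch matrix for same-size convolution: rows enumerate (channel, dx, dy)
# with dy fastest; columns enumerate spatial positions column-major.
im2col <- function(x, k, pad_mode) {
  h <- dim(x)[1]; w <- dim(x)[2]; cch <- dim(x)[3]
  p <- (k - 1L) / 2L
  if (pad_mode == "circular" && p > 0) {
    idx_r <- ((seq_len(h + 2 * p) - p - 1) %% h) + 1
    idx_c <- ((seq_len(w + 2 * p) - p - 1) %% w) + 1
    xp <- x[idx_r, idx_c, , drop = FALSE]
  } else {
    xp <- array(0, c(h + 2 * p, w + 2 * p, cch))
    xp[p + seq_len(h), p + seq_len(w), ] <- x
  }
  X <- matrix(0, cch * k * k, h * w)
  row <- 0L
  for (cc in seq_len(cch)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    row <- row + 1L
    X[row, ] <- xp[dy + seq_len(h), dx + seq_len(w), cc]
  }
  X
}

# Adjoint of im2col: scatter-add patch-gradients back onto the input raster.
col2im <- function(dX, h, w, cch, k, pad_mode) {
  p <- (k - 1L) / 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  dxp <- array(0, c(hp, wp, cch))
  row <- 0L
  for (cc in seq_len(cch)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    row <- row + 1L
    dxp[dy + seq_len(h), dx + seq_len(w), cc] <-
      dxp[dy + seq_len(h), dx + seq_len(w), cc] + matrix(dX[row, ], h, w)
  }
  if (pad_mode == "circular" && p > 0) {
    idx_r <- ((seq_len(hp) - p - 1) %% h) + 1
    idx_c <- ((seq_len(wp) - p - 1) %% w) + 1
    out <- array(0, c(h, w, cch))
    for (cc in seq_len(cch)) for (i in seq_len(hp)) {
      tmp <- numeric(w)
      for (j in seq_len(wp)) tmp[idx_c[j]] <- tmp[idx_c[j]] + dxp[i, j, cc]
      out[idx_r[i], , cc] <- out[idx_r[i], , cc] + tmp
    }
    out
  } else {
    dxp[p + seq_len(h), p + seq_len(w), , drop = FALSE]
  }
}

dense_weights <- function(net, i, fan_in) {
  sp <- net$layers[[i]]
  with_seed(derive_seed(net$config$weight_seed, i, fan_in), {
    list(W = matrix(rnorm(sp$out_channels * fan_in, sd = 1 / sqrt(fan_in)),
                    nrow = sp$out_channels),
         b = numeric(sp$out_channels))
  })
}

pool_slices <- function(x, size) {
  h2 <- floor(dim(x)[1] / size); w2 <- floor(dim(x)[2] / size)
  idx <- list()
  for (dy in 0:(size - 1L)) for (dx in 0:(size - 1L)) {
    idx[[length(idx) + 1L]] <- list(r = seq_len(h2) * size - size + 1L + dy,
                                    c = seq_len(w2) * size - size + 1L + dx)
  }
  list(h2 = h2, w2 = w2, idx = idx)
}

# Forward pass keeping per-layer inputs and outputs for backpropagation.
forward_cache <- function(net, x) {
  pad <- net$config$padding
  inputs <- vector("list", length(net$layers))
  outputs <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    inputs[[i]] <- x
    if (ly$kind == "conv") {
      h <- dim(x)[1]; w <- dim(x)[2]
      X <- im2col(x, ly$kernel, pad)
      Z <- ly$W %*% X + ly$b
      if (ly$activation == "relu") Z <- pmax(Z, 0)
      x <- array(t(Z), c(h, w, ly$out_channels))
    } else if (ly$kind == "pool") {
      ps <- pool_slices(x, ly$size)
      if (ps$h2 < 1 || ps$w2 < 1) abort_input("feature map too small to pool")
      acc <- NULL
      for (s in ps$idx) {
        sl <- x[s$r, s$c, , drop = FALSE]
        acc <- if (is.null(acc)) sl else if (ly$mode == "avg") acc + sl else pmax(acc, sl)
      }
      x <- if (ly$mode == "avg") acc / length(ps$idx) else acc
    } else { # dense
      v <- as.vector(x)
      wb <- dense_weights(net, i, length(v))
      z <- drop(wb$W %*% v + wb$b)
      if (ly$activation == "relu") z <- pmax(z, 0)
      x <- z
    }
    outputs[[i]] <- x
  }
  list(inputs = inputs, outputs = outputs)
}

# Reverse pass. `grad_at` is a list mapping layer index -> gradient w.r.t.
# that layer's output; gradients are accumulated downwards. Returns the
# gradient w.r.t. the input image and, optionally, per-layer weight grads.
backward_pass <- function(net, cache, grad_at, weight_grads = FALSE) {
  pad <- net$config$padding
  nL <- length(net$layers)
  g <- NULL
  dW <- if (weight_grads) vector("list", nL) else NULL
  db <- if (weight_grads) vector("list", nL) else NULL
  for (i in rev(seq_len(nL))) {
    ly <- net$layers[[i]]
    out <- cache$outputs[[i]]
    if (!is.null(grad_at[[as.character(i)]])) {
      inj <- grad_at[[as.character(i)]]
      g <- if (is.null(g)) inj else g + inj
    }
    if (is.null(g)) next
    inp <- cache$inputs[[i]]
    if (ly$kind == "conv") {
      h <- dim(inp)[1]; w <- dim(inp)[2]
      gm <- t(matrix(g, h * w, ly$out_channels))
      if (ly$activation == "relu") {
        om <- t(matrix(out, h * w, ly$out_channels))
        gm <- gm * (om > 0)
      }
      X <- im2col(inp, ly$kernel, pad)
      if (weight_grads) {
        dW[[i]] <- gm %*% t(X)
        db[[i]] <- rowSums(gm)
      }
      g <- col2im(t(ly$W) %*% gm, h, w, ly$in_channels, ly$kernel, pad)
    } else if (ly$kind == "pool") {
      ps <- pool_slices(inp, ly$size)
      dx <- array(0, dim(inp))
      if (ly$mode == "avg") {
        for (s in ps$idx) dx[s$r, s$c, ] <- dx[s$r, s$c, ] + g / length(ps$idx)
      } else {
        used <- array(FALSE, dim(out))
        for (s in ps$idx) {
          sl <- inp[s$r, s$c, , drop = FALSE]
          sel <- (sl == out) & !used
          contrib <- array(0, dim(out)); contrib[sel] <- g[sel]
          dx[s$r, s$c, ] <- dx[s$r, s$c, ] + contrib
          used <- used | sel
        }
      }
      g <- dx
    } else { # dense
      v <- as.vector(inp)
      wb <- dense_weights(net, i, length(v))
      gg <- as.vector(g)
      if (ly$activation == "relu") gg <- gg * (out > 0)
      if (weight_grads) {
        dW[[i]] <- outer(gg, v)
        db[[i]] <- gg
      }
      g <- array(drop(crossprod(wb$W, gg)), dim(inp))
    }
  }
  list(dinput = g, dW = dW, db = db)
}

as_input_array <- function(net, image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (length(dim(image)) != 3)
    abort_input("image must be a matrix or h x w x c array")
  if (dim(image)[3] != net$config$input_channels)
    abort_input(sprintf("image has %d channel(s) but network expects %d",
                        dim(image)[3], net$config$input_channels))
  image
}

#' Feed an image forward through a network
#'
#' Computes the post-activation feature maps of every layer in order. Conv
#' and pool outputs are `h x w x channels` arrays; dense outputs are vectors.
#' The pass is fully deterministic.
#'
#' @param network A [build_network()] object.
#' @param image Numeric matrix (grayscale) or `h x w x c` array with values
#'   in `[0, 1]`.
#' @return A `feature_stack`: list of per-layer outputs with attributes
#'   `gram_layers` and `input_dim`.
#' @export
#' @examples
#' net <- build_network(desk_net_config())
#' fs <- forward(net, matrix(0.5, 16, 16))
#' length(fs)
forward <- function(network, image) {
  if (!inherits(network, "texture_net")) abort_param("`network` must be a texture_net")
  x <- as_input_array(network, image)
  assert_gray01(matrix(x, dim(x)[1]), "image")
  cache <- forward_cache(network, x)
  structure(cache$outputs,
            gram_layers = network$config$gram_layers,
            input_dim = dim(x), class = "feature_stack")
}

#' @export
print.texture_net <- function(x, ...) {
  kinds <- vapply(x$layers, `[[`, "", "kind")
  cat(sprintf("<texture_net> %d layers (%d weight-bearing), padding %s, seed %d%s\n",
              length(kinds), sum(kinds %in% c("conv", "dense")),
              x$config$padding, x$config$weight_seed,
              if (!is.null(x$head)) ", fine-tuned head" else ""))
  invisible(x)
}
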