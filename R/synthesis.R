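#' Gram matrix of a feature map
#'
#' For a layer with `N` channels observed at `M` spatial positions, the Gram
#' matrix is the raw (unnormalised) co-activation matrix
#' `G_ij = sum_k F_ik F_jk`: the inner products between channel activation
#' vectors. It summarises the layer's texture statistics while discarding
#' spatial layout, so any spatial permutation of the positions leaves it
#' unchanged.
#'
#' @param feature_map Either an `N x M` matrix (channels by positions) or an
#'   `h x w x N` feature array as produced by [forward()].
#' @return A symmetric positive semidefinite `N x N` matrix.
#' @export
#' @examples
#' gram_matrix(rbind(c(1, 2), c(0, 1)))
gram_matrix <- function(feature_map) {
  Fm <- as_channel_matrix(feature_map)
  if (!nrow(Fm) || !ncol(Fm)) abort_input("feature map must be nonempty")
  if (any(!is.finite(Fm))) abort_input("feature map contains non-finite values")
  tcrossprod(Fm)
}

as_channel_matrix <- function(feature_map) {
  if (is.matrix(feature_map)) return(feature_map)
  if (is.array(feature_map) && length(dim(feature_map)) == 3) {
    d <- dim(feature_map)
    return(t(matrix(feature_map, d[1] * d[2], d[3])))
  }
  abort_input("feature map must be an N x M matrix or h x w x N array")
}

#' Gram statistics of an image under a network
#'
#' Runs a forward pass and computes the Gram matrix of every configured gram
#' layer. The set of per-layer Gram matrices is the texture summary that the
#' synthesis objective matches.
#'
#' @param network A [build_network()] object.
#' @param image Grayscale matrix in `[0, 1]`.
#' @param source_id Optional identifier recorded in the result.
#' @return A `gram_set`: list with `grams` (per-layer matrices), `N`, `M`
#'   (channel and position counts) and `layers` (layer indices).
#' @export
#' @examples
#' net <- build_network(desk_net_config())
#' gs <- gram_set(net, matrix(runif(32 * 32), 32))
#' vapply(gs$grams, nrow, 0L)
gram_set <- function(network, image, source_id = NULL) {
  fs <- forward(network, image)
  layers <- attr(fs, "gram_layers")
  if (!length(layers)) abort_param("network config has no gram_layers")
  grams <- vector("list", length(layers))
  N <- integer(length(layers)); M <- integer(length(layers))
  for (j in seq_along(layers)) {
    Fm <- as_channel_matrix(fs[[layers[j]]])
    grams[[j]] <- tcrossprod(Fm)
    N[j] <- nrow(Fm); M[j] <- ncol(Fm)
  }
  structure(list(grams = grams, N = N, M = M, layers = layers,
                 source_id = source_id),
            class = "gram_set")
}

check_same_structure <- function(a, b) {
  if (!inherits(a, "gram_set") || !inherits(b, "gram_set"))
    abort_structure("arguments must be gram_set objects")
  if (length(a$grams) != length(b$grams) || any(a$N != b$N) || any(a$M != b$M))
    abort_structure("gram sets have mismatched layer structure")
}

resolve_weights <- function(weights, n_layers) {
  if (is.null(weights)) weights <- rep(1 / n_layers, n_layers)
  if (length(weights) != n_layers)
    abort_structure("`weights` length must match the number of gram layers")
  if (any(weights < 0) || all(weights == 0))
    abort_param("layer weights must be nonnegative and not all zero")
  weights
}

#' Gram-matching objective
#'
#' The synthesis loss between two Gram sets:
#' `L = sum_l w_l / (4 N_l^2 M_l^2) * sum_ij (G_ij - A_ij)^2`,
#' an L2 norm on corresponding Gram elements with the conventional
#' `1/(4 N^2 M^2)` per-layer normalisation so that layers of different size
#' contribute on comparable scales. Zero iff all matrices agree (for
#' positive weights).
#'
#' @param grams,target `gram_set` objects with matching structure.
#' @param weights Per-layer nonnegative weights; default uniform
#'   `1/n_layers`.
#' @return Nonnegative scalar.
#' @export
synthesis_loss <- function(grams, target, weights = NULL) {
  check_same_structure(grams, target)
  w <- resolve_weights(weights, length(grams$grams))
  loss <- 0
  for (l in seq_along(grams$grams)) {
    d <- grams$grams[[l]] - target$grams[[l]]
    loss <- loss + w[l] * sum(d^2) / (4 * grams$N[l]^2 * grams$M[l]^2)
  }
  loss
}

#' Exact pixel gradient of the Gram-matching objective
#'
#' Hand-derived backpropagation of [synthesis_loss()] composed with
#' [gram_set()] with respect to every pixel of `image`. At each gram layer
#' the feature-space gradient is `w_l / (N_l^2 M_l^2) * (G - A) F` (using the
#' symmetry of `G - A`); these are injected into a reverse pass through the
#' conv/pool/relu stack.
#'
#' @param network A `texture_net`.
#' @param image Grayscale matrix in `[0, 1]`.
#' @param target Target `gram_set` (same network).
#' @param weights Per-layer weights as in [synthesis_loss()].
#' @return Numeric matrix of the same size as `image`.
#' @export
loss_gradient <- function(network, image, target, weights = NULL) {
  x <- as_input_array(network, image)
  cache <- forward_cache(network, x)
  layers <- network$config$gram_layers
  w <- resolve_weights(weights, length(layers))
  grad_at <- list()
  for (j in seq_along(layers)) {
    feat <- cache$outputs[[layers[j]]]
    d <- dim(feat)
    Fm <- t(matrix(feat, d[1] * d[2], d[3]))
    G <- tcrossprod(Fm)
    N <- nrow(Fm); M <- ncol(Fm)
    if (any(dim(target$grams[[j]]) != N) || target$M[j] != M)
      abort_structure("target gram set does not match this image/network")
    dF <- (w[j] / (N^2 * M^2)) * ((G - target$grams[[j]]) %*% Fm)
    grad_at[[as.character(layers[j])]] <- array(t(dF), d)
  }
  bw <- backward_pass(network, cache, grad_at, weight_grads = FALSE)
  matrix(bw$dinput, dim(x)[1], dim(x)[2])
}

#' Options controlling texture synthesis
#'
#' @param max_iters Maximum gradient-descent iterations (>= 1).
#' @param tol Stop when the loss falls to or below this value.
#' @param init_seed Seed for the white-noise initialisation.
#' @param layer_weights Per-layer loss weights (default uniform).
#' @param step_init Initial step size for the first iteration.
#' @param armijo_c Sufficient-decrease constant.
#' @param shrink Backtracking shrink factor.
#' @param max_backtracks Halvings tried per iteration before stalling out.
#' @param init_image Optional matrix used instead of white noise (test hook
#'   and warm starts).
#' @return A `synthesis_options` list.
#' @export
synthesis_options <- function(max_iters = 500L, tol = 1e-6, init_seed = 1L,
                              layer_weights = NULL, step_init = 1.0,
                              armijo_c = 1e-4, shrink = 0.5,
                              max_backtracks = 40L, init_image = NULL) {
  if (!is_count(max_iters, 1)) abort_param("`max_iters` must be an integer >= 1")
  if (!is.numeric(tol) || tol < 0) abort_param("`tol` must be nonnegative")
  structure(list(max_iters = as.integer(max_iters), tol = tol,
                 init_seed = as.integer(init_seed),
                 layer_weights = layer_weights, step_init = step_init,
                 armijo_c = armijo_c, shrink = shrink,
                 max_backtracks = as.integer(max_backtracks),
                 init_image = init_image),
            class = "synthesis_options")
}

#' Synthesize a texture metamer of an image
#'
#' Starting from seeded uniform white noise on `[0, 1]`, minimises the
#' Gram-matching objective against the original's Gram set by projected
#' steepest descent: each iteration backtracks the step size (Armijo
#' sufficient decrease, evaluated after clamping pixels to `[0, 1]`) until
#' the post-projection loss decreases, so the recorded loss trajectory is
#' non-increasing. The accepted step size is doubled as the next trial step.
#' Stops at `max_iters`, at `tol`, or when no decreasing step exists. The
#' result matches the original's texture statistics while remaining
#' pixel-wise different from it.
#'
#' @param network A `texture_net`.
#' @param original Grayscale matrix in `[0, 1]`.
#' @param opts A [synthesis_options()] object.
#' @return A `synthesis_result`: `image`, `loss_trajectory` (loss at
#'   initialisation and after each accepted iteration), `iterations_run`,
#'   `init_seed`, `target` (the original's `gram_set`).
#' @export
#' @examples
#' net <- build_network(desk_net_config())
#' ph <- generate_phantom(phantom_params("cancer", 32, 32, seed = 3))
#' res <- synthesize(net, ph$image, synthesis_options(max_iters = 25))
#' res$loss_trajectory[1] > res$loss_trajectory[length(res$loss_trajectory)]
synthesize <- function(network, original, opts = synthesis_options()) {
  assert_gray01(original, "original")
  target <- gram_set(network, original)
  h <- nrow(original); w <- ncol(original)
  x <- if (!is.null(opts$init_image)) {
    assert_gray01(opts$init_image, "init_image")
    opts$init_image
  } else {
    with_seed(opts$init_seed, matrix(runif(h * w), h, w))
  }
  weights <- opts$layer_weights
  loss_of <- function(img) synthesis_loss(gram_set(network, img), target, weights)
  cur_loss <- loss_of(x)
  if (!is.finite(cur_loss)) abort_numeric("non-finite loss at initialisation")
  traj <- cur_loss
  iters <- 0L
  step <- opts$step_init
  while (iters < opts$max_iters && cur_loss > opts$tol) {
    g <- loss_gradient(network, x, target, weights)
    if (any(!is.finite(g)))
      abort_numeric(sprintf("non-finite gradient at iteration %d", iters + 1L))
    accepted <- FALSE
    t_try <- step
    for (bt in seq_len(opts$max_backtracks)) {
      x_new <- clamp01(x - t_try * g)
      decrease <- sum((x - x_new)^2) / max(t_try, .Machine$double.eps)
      new_loss <- loss_of(x_new)
      if (!is.finite(new_loss))
        abort_numeric(sprintf("non-finite loss at iteration %d", iters + 1L))
      if (new_loss <= cur_loss - opts$armijo_c * decrease) {
        x <- x_new; cur_loss <- new_loss
        step <- t_try * 2
        accepted <- TRUE
        break
      }
      t_try <- t_try * opts$shrink
    }
    if (!accepted) break # no decreasing step within budget: stalled/converged
    iters <- iters + 1L
    traj[iters + 1L] <- cur_loss
  }
  structure(list(image = x, loss_trajectory = traj, iterations_run = iters,
                 init_seed = opts$init_seed, target = target,
                 final_loss = cur_loss),
            class = "synthesis_result")
}

#' Distance between two Gram sets
#'
#' The uniform-weight synthesis loss between two Gram sets; symmetric, zero
#' iff the sets coincide. Used as the evaluation metric for class-recovery
#' checks.
#'
#' @param a,b `gram_set` objects with matching structure.
#' @return Nonnegative scalar.
#' @export
gram_distance <- function(a, b) {
  synthesis_loss(a, b, weights = NULL)
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat(sprintf("<synthesis_result> %dx%d px, %d iterations, loss %.3g -> %.3g (seed %d)\n",
              nrow(x$image), ncol(x$image), x$iterations_run,
              x$loss_trajectory[1], x$final_loss, x$init_seed))
  invisible(x)
}
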