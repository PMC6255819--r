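final_feature_dim <- function(net, img) {
  x <- as_input_array(net, img)
  out <- forward_cache(net, x)$outputs[[length(net$layers)]]
  if (is.null(dim(out))) length(out) else dim(out)[3]
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fine-tune a network on a phantom cohort
#'
#' Miniature supervised adaptation: a linear softmax head is attached to the
#' global-average-pooled final feature layer and the head plus all conv
#' weights are trained by full-batch gradient descent on the multinomial
#' cross-entropy of the cohort's class labels. Each epoch is accepted only if
#' it does not increase the training loss (the step size is halved, up to 30
#' times, until it does not), so the final loss never exceeds the initial
#' loss and the procedure is deterministic given the seed.
#'
#' @param network A [build_network()] object.
#' @param cohort List of `phantom` objects covering at least 2 classes.
#' @param epochs Number of full-batch epochs (>= 1).
#' @param lr Gradient-descent step size; `lr = 0` leaves weights unchanged.
#' @param seed Seed for the head initialisation.
#' @return The updated `texture_net`, with the trained head in `$head` and a
#'   numeric attribute `loss_trajectory` (initial loss followed by the loss
#'   after each epoch).
#' @export
#' @examples
#' net <- build_network(desk_net_config())
#' cohort <- generate_cohort(2, size = 32, seed = 1)
#' tuned <- finetune_features(net, cohort, epochs = 2, lr = 0.05, seed = 1)
finetune_features <- function(network, cohort, epochs, lr, seed = 1L) {
  if (!inherits(network, "texture_net")) abort_param("`network` must be a texture_net")
  if (!is_count(epochs, 1)) abort_param("`epochs` must be an integer >= 1")
  if (!is.numeric(lr) || lr < 0) abort_param("`lr` must be a nonnegative number")
  labels <- vapply(cohort, `[[`, "", "class_label")
  classes <- phantom_classes[phantom_classes %in% unique(labels)]
  if (length(classes) < 2)
    abort_degenerate("cohort must contain at least 2 classes")
  y <- match(labels, classes)
  n <- length(cohort)
  images <- lapply(cohort, function(p) as_input_array(network, p$image))
  C <- final_feature_dim(network, images[[1]])
  K <- length(classes)
  head <- with_seed(seed, list(
    W = matrix(rnorm(K * C, sd = 1 / sqrt(C)), nrow = K),
    b = numeric(K), classes = classes))
  net <- network

  eval_batch <- function(net, head, want_grads = FALSE) {
    nL <- length(net$layers)
    caches <- lapply(images, function(x) forward_cache(net, x))
    P <- t(vapply(caches, function(cc) {
      out <- cc$outputs[[nL]]
      if (is.null(dim(out))) as.vector(out) else apply(out, 3, mean)
    }, numeric(C)))
    logits <- P %*% t(head$W) + matrix(head$b, n, K, byrow = TRUE)
    pr <- softmax_rows(logits)
    loss <- -mean(log(pmax(pr[cbind(seq_len(n), y)], 1e-12)))
    if (!want_grads) return(list(loss = loss))
    # gradients of the mean cross-entropy w.r.t. head and conv parameters
    dlogit <- pr
    dlogit[cbind(seq_len(n), y)] <- dlogit[cbind(seq_len(n), y)] - 1
    dlogit <- dlogit / n
    gW_head <- t(dlogit) %*% P
    gb_head <- colSums(dlogit)
    dP <- dlogit %*% head$W
    gW <- vector("list", nL); gb <- vector("list", nL)
    for (i in seq_len(n)) {
      out <- caches[[i]]$outputs[[nL]]
      if (is.null(dim(out))) {
        dfeat <- array(dP[i, ], length(out))
      } else {
        M <- prod(dim(out)[1:2])
        dfeat <- array(rep(dP[i, ] / M, each = M), dim(out))
      }
      bw <- backward_pass(net, caches[[i]],
                          stats::setNames(list(dfeat), as.character(nL)),
                          weight_grads = TRUE)
      for (l in seq_len(nL)) {
        if (!is.null(bw$dW[[l]])) {
          gW[[l]] <- if (is.null(gW[[l]])) bw$dW[[l]] else gW[[l]] + bw$dW[[l]]
          gb[[l]] <- if (is.null(gb[[l]])) bw$db[[l]] else gb[[l]] + bw$db[[l]]
        }
      }
    }
    list(loss = loss, gW_head = gW_head, gb_head = gb_head, gW = gW, gb = gb)
  }

  cur <- eval_batch(net, head, want_grads = TRUE)
  traj <- cur$loss
  for (ep in seq_len(epochs)) {
    lr_eff <- lr
    accepted <- FALSE
    for (try in seq_len(31L)) {
      cand_net <- net
      cand_head <- head
      for (l in seq_along(net$layers)) {
        if (!is.null(cur$gW[[l]])) {
          cand_net$layers[[l]]$W <- net$layers[[l]]$W - lr_eff * cur$gW[[l]]
          cand_net$layers[[l]]$b <- net$layers[[l]]$b - lr_eff * cur$gb[[l]]
        }
      }
      cand_head$W <- head$W - lr_eff * cur$gW_head
      cand_head$b <- head$b - lr_eff * cur$gb_head
      cand <- eval_batch(cand_net, cand_head, want_grads = FALSE)
      if (cand$loss <= cur$loss) {
        net <- cand_net; head <- cand_head
        cur <- if (ep < epochs) eval_batch(net, head, want_grads = TRUE)
               else cand
        traj[ep + 1L] <- cand$loss
        accepted <- TRUE
        break
      }
      lr_eff <- lr_eff / 2
    }
    if (!accepted) traj[ep + 1L] <- cur$loss # step rejected; parameters kept
  }
  net$head <- head
  attr(net, "loss_trajectory") <- traj
  net
}

#' Predict phantom classes with a fine-tuned network
#'
#' @param network A `texture_net` carrying a head from [finetune_features()].
#' @param phantoms List of `phantom` objects (or bare image matrices).
#' @return Character vector of predicted class labels.
#' @export
predict_phantom_class <- function(network, phantoms) {
  if (is.null(network$head)) abort_input("network has no fine-tuned head")
  head <- network$head
  vapply(phantoms, function(p) {
    img <- if (inherits(p, "phantom")) p$image else p
    x <- as_input_array(network, img)
    out <- forward_cache(network, x)$outputs[[length(network$layers)]]
    f <- if (is.null(dim(out))) as.vector(out) else apply(out, 3, mean)
    head$classes[which.max(drop(head$W %*% f + head$b))]
  }, "")
}
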