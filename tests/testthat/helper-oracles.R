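# Independent oracles used by the tests. Each re-derives a quantity by a
# different route than the package (brute force, explicit enumeration), so
# agreement is evidence, not tautology.

# Stack-based 8-connected flood fill; returns count and a label matrix
# (labelling order unspecified -- compare partitions, not label values).
flood_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] != 0 && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              mask[ni, nj] != 0 && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            stack[[length(stack) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  list(count = cur, labels = lab)
}

# Spatial sizes per layer from the stated shape arithmetic: same-size conv,
# floor-division pooling.
shape_oracle <- function(config, h, w) {
  out <- list()
  for (i in seq_along(config$layers)) {
    sp <- config$layers[[i]]
    if (sp$kind == "pool") { h <- floor(h / sp$size); w <- floor(w / sp$size) }
    out[[i]] <- c(h, w)
  }
  out
}

# Naive agglomerative average linkage on a dissimilarity matrix; ties broken
# by the lowest-index pair. Returns merge heights in order and the member
# sets at each merge.
average_linkage_oracle <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merged_sets <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(a, b) }
    }
    heights <- c(heights, best_d)
    merged_sets[[length(merged_sets) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, sets = merged_sets)
}

# Leaf sets present in an hclust-style merge table, in merge order.
merge_leaf_sets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    members <- integer(0)
    for (m in merge[i, ]) {
      members <- c(members, if (m < 0) -m else sets[[m]])
    }
    sets[[i]] <- sort(members)
  }
  sets
}

# Central finite differences of the synthesis loss w.r.t. each pixel.
# The difference quotient is only a valid derivative oracle where the loss is
# smooth on [x-h, x+h]; a pixel whose perturbation flips any relu unit on or
# off crosses a kink, so such pixels are flagged invalid rather than compared.
fd_gradient <- function(net, img, target, h = 1e-3) {
  g <- matrix(0, nrow(img), ncol(img))
  valid <- matrix(TRUE, nrow(img), ncol(img))
  relu_pattern <- function(x) lapply(forward(net, x), function(f) f > 0)
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    up <- img; up[i, j] <- img[i, j] + h
    dn <- img; dn[i, j] <- img[i, j] - h
    g[i, j] <- (synthesis_loss(gram_set(net, up), target) -
                synthesis_loss(gram_set(net, dn), target)) / (2 * h)
    valid[i, j] <- identical(relu_pattern(up), relu_pattern(dn))
  }
  list(g = g, valid = valid)
}

# Max relative disagreement between analytic and finite-difference gradients
# over the pixels where the oracle is valid.
fd_rel_error <- function(net, img, target, h = 1e-3) {
  fd <- fd_gradient(net, img, target, h)
  ana <- loss_gradient(net, img, target)
  max(abs(ana - fd$g)[fd$valid]) / max(abs(fd$g))
}

make_test_phantom <- function(class_label, size = 32, seed = 1) {
  generate_phantom(phantom_params(class_label, size, size, seed = seed))
}
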