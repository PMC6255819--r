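test_that("gram_matrix matches the explicit double summation", {
  # N=2, M=2: channel 1 = (1,2), channel 2 = (0,1)
  Fm <- rbind(c(1, 2), c(0, 1))
  expect_equal(gram_matrix(Fm), rbind(c(5, 2), c(2, 1)))
  expect_equal(gram_matrix(matrix(0, 3, 4)), matrix(0, 3, 3))
  # spatial permutation invariance
  Fm2 <- matrix(runif(5 * 12), 5)
  perm <- sample(12)
  expect_equal(gram_matrix(Fm2), gram_matrix(Fm2[, perm]))
  expect_error(gram_matrix(matrix(numeric(0), 0, 0)),
               class = "mammetamer_input_error")
})

test_that("gram matrices are symmetric and positive semidefinite", {
  set.seed(31)
  for (k in 1:50) {
    Fm <- matrix(rnorm(8 * 20), 8)
    G <- gram_matrix(Fm)
    expect_equal(G, t(G))
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(G)))
  }
})

test_that("gram_set records layer sizes and is shift-invariant under periodic padding", {
  net <- build_network(desk_net_config())
  img <- matrix(runif(32 * 32), 32)
  gs <- gram_set(net, img)
  expect_equal(vapply(gs$grams, nrow, 0L), c(8L, 16L, 32L))
  expect_equal(gs$M, c(32L * 32L, 16L * 16L, 8L * 8L))
  expect_identical(gs, gram_set(net, img))

  pnet <- build_network(desk_net_config(padding = "circular"))
  toy <- matrix(runif(64), 8, 8)
  shifted <- toy[c(5:8, 1:4), c(5:8, 1:4)] # circular shift by the total pool stride
  g1 <- gram_set(pnet, toy)
  g2 <- gram_set(pnet, shifted)
  for (l in 1:3) expect_equal(g1$grams[[l]], g2$grams[[l]], tolerance = 1e-10)
})

test_that("synthesis_loss matches hand computation and is linear in weights", {
  g <- structure(list(grams = list(rbind(c(5, 2), c(2, 1))), N = 2L, M = 2L,
                      layers = 1L, source_id = NULL), class = "gram_set")
  z <- structure(list(grams = list(matrix(0, 2, 2)), N = 2L, M = 2L,
                      layers = 1L, source_id = NULL), class = "gram_set")
  # (25+4+4+1) / (4 * 4 * 4) = 34/64
  expect_equal(synthesis_loss(g, z, weights = 1), 0.53125)
  expect_equal(synthesis_loss(g, g), 0)
  net <- build_network(desk_net_config())
  a <- gram_set(net, matrix(runif(256), 16))
  b <- gram_set(net, matrix(runif(256), 16))
  w <- c(0.2, 0.5, 0.3)
  expect_equal(synthesis_loss(a, b, 2 * w), 2 * synthesis_loss(a, b, w))
  expect_error(synthesis_loss(a, z), class = "mammetamer_structure_error")
})

test_that("the analytic pixel gradient matches central finite differences", {
  net <- build_network(desk_net_config())
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(runif(64, 0.15, 0.85), 8, 8)
    target <- gram_set(net, matrix(runif(64, 0.15, 0.85), 8, 8))
    expect_lte(fd_rel_error(net, img, target), 1e-4)
  }
  # gradient vanishes at the target and scales linearly with the loss weight
  img <- matrix(runif(64, 0.2, 0.8), 8, 8)
  self_target <- gram_set(net, img)
  expect_equal(max(abs(loss_gradient(net, img, self_target))), 0)
  other <- gram_set(net, matrix(runif(64, 0.2, 0.8), 8, 8))
  g1 <- loss_gradient(net, img, other, weights = c(1, 1, 1))
  g2 <- loss_gradient(net, img, other, weights = c(2, 2, 2))
  expect_equal(g2, 2 * g1)
})

test_that("synthesis is deterministic, monotone, and fixed at its target", {
  net <- build_network(desk_net_config())
  ph <- make_test_phantom("cancer", 32, 7)
  # init forced to the original: immediate fixed point
  res0 <- synthesize(net, ph$image,
                     synthesis_options(max_iters = 10, init_image = ph$image))
  expect_equal(res0$iterations_run, 0)
  expect_equal(res0$loss_trajectory, 0)
  expect_identical(res0$image, ph$image)

  opts <- synthesis_options(max_iters = 60, init_seed = 4)
  r1 <- synthesize(net, ph$image, opts)
  r2 <- synthesize(net, ph$image, opts)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$loss_trajectory, r2$loss_trajectory)
  expect_true(all(diff(r1$loss_trajectory) <= 0))
  expect_gte(min(r1$image), 0)
  expect_lte(max(r1$image), 1)
})

test_that("synthesized phantoms recover the Gram statistics of their original", {
  net <- build_network(desk_net_config())
  for (seed in c(3, 14)) {
    ph <- make_test_phantom("cancer", 32, seed)
    res <- synthesize(net, ph$image,
                      synthesis_options(max_iters = 300, tol = 1e-12,
                                        init_seed = seed))
    expect_lte(res$final_loss / res$loss_trajectory[1], 0.01)
    # pixel-wise novel yet statistically matched (the metamer property)
    expect_gt(mean(abs(res$image - ph$image)), 0.05)
  }
})

test_that("gram_distance is a symmetric premetric consistent with direct loss", {
  net <- build_network(desk_net_config())
  imgs <- lapply(c(2, 5, 9), function(s) make_test_phantom("benign", 32, s)$image)
  gs <- lapply(imgs, function(i) gram_set(net, i))
  expect_equal(gram_distance(gs[[1]], gs[[1]]), 0)
  expect_equal(gram_distance(gs[[1]], gs[[2]]), gram_distance(gs[[2]], gs[[1]]))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(gram_distance(gs[[i]], gs[[j]]),
                 synthesis_loss(gs[[i]], gs[[j]]))
  }
})
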