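test_that("Experiment-1 schedules are balanced, covering, and reproducible", {
  stim <- stimulus_set()
  sched <- make_schedule(stim, 10, experiment = 1, seed = 3)
  counts <- table(sched$stim_a)
  expect_length(counts, 8)
  expect_true(all(counts >= 10))
  expect_equal(mean(sched$truth_synth), 0.5) # exact 50-50 truth balance
  expect_identical(sched, make_schedule(stim, 10, experiment = 1, seed = 3))
  expect_false(identical(sched$stim_a,
                         make_schedule(stim, 10, 1, seed = 4)$stim_a))
})

test_that("Experiment-2 schedules enumerate all unordered pairs incl. identical", {
  stim <- stimulus_set()
  sched <- make_schedule(stim, 10, experiment = 2, seed = 3)
  expect_equal(nrow(sched), (8 * 9 / 2) * 10)
  key <- paste(pmin(sched$stim_a, sched$stim_b),
               pmax(sched$stim_a, sched$stim_b))
  expect_true(all(table(key) >= 10))
  expect_true(any(sched$stim_a == sched$stim_b)) # both/neither-original trials
  expect_error(make_schedule(stimulus_set()[0, ], 10, 1),
               class = "mammetamer_input_error")
})

test_that("SDT observers behave as their parameters dictate", {
  stim <- stimulus_set(1)
  big <- make_schedule(stim, 5000, 1, seed = 1) # 10,000 trials
  tab <- simulate_observer(big, observer_chance(seed = 9))
  rate <- mean(tab$response)
  expect_gte(rate, 0.48); expect_lte(rate, 0.52)

  sched <- make_schedule(stimulus_set(), 10, 1, seed = 2)
  sharp <- simulate_observer(sched, observer_sdt(6, 3, seed = 5))
  expect_gt(mean(sharp$response[sharp$truth_synth]), 0.95)
  expect_lt(mean(sharp$response[!sharp$truth_synth]), 0.05)

  # observer kind must match the experiment
  expect_error(simulate_observer(sched, observer_rater()),
               class = "mammetamer_input_error")
  sched2 <- make_schedule(stimulus_set(), 2, 2, seed = 2)
  expect_error(simulate_observer(sched2, observer_chance()),
               class = "mammetamer_input_error")

  # noiseless rater reproduces its latent dissimilarities exactly
  quiet <- simulate_observer(sched2, observer_rater(10, 40, 70, sigma = 0))
  info <- quiet[quiet$stim_a == "O1" & quiet$stim_b == "S1", ]
  expect_true(all(info$response == 10))
  expect_true(all(quiet$response[quiet$stim_a == quiet$stim_b] == 0))
})

test_that("d-prime matches quantile oracles and validates its input", {
  expect_equal(dprime_from_rates(0.8413, 0.5), 1.000, tolerance = 1e-3)
  # corrected ceiling performance: h=10, f=0, n=10 per class
  expect_equal(qnorm(10.5 / 11) - qnorm(0.5 / 11), 3.381, tolerance = 1e-3)
  tab <- tibble::tibble(
    subject = "s1", experiment = 1L, trial = 1:20,
    stim_a = rep(c("O1", "S1"), each = 10), stim_b = NA, pair_a = "P1",
    pair_b = NA, truth_synth = rep(c(FALSE, TRUE), each = 10),
    response = rep(c(FALSE, TRUE, FALSE, TRUE), each = 5), rt = NA_real_)
  res <- dprime(tab)
  expect_equal(res$h, 5); expect_equal(res$f, 5)
  expect_equal(res$dprime, 0) # equal corrected rates
  expect_equal(res$H_star, 5.5 / 11)
  res10 <- dprime(dplyr::mutate(tab, response = truth_synth))
  expect_equal(res10$dprime, qnorm(10.5 / 11) - qnorm(0.5 / 11))
  # tn_vs_miss is the complementary description of the same counts
  expect_equal(dprime(tab, "tn_vs_miss")$dprime, res$dprime)
  # a cell without both trial classes is degenerate
  broken <- tab[tab$truth_synth, ]
  expect_error(dprime(broken), class = "mammetamer_degenerate_error")
})

test_that("d-prime recovery: estimates track true sensitivity", {
  stim <- stimulus_set(1)
  sched <- make_schedule(stim, 200, 1, seed = 7) # 200 trials per class
  for (delta in c(0, 0.5, 1, 2)) {
    est <- vapply(1:200, function(i) {
      tab <- simulate_observer(sched,
        observer_sdt(delta, delta / 2, seed = derive_seed(5000, delta * 10, i)))
      dprime(tab)$dprime
    }, 0)
    expect_lte(abs(mean(est) - delta), 0.15)
  }
})

test_that("chance observers at the study design give near-zero median d-prime", {
  stim <- stimulus_set()
  sched <- make_schedule(stim, 10, 1, seed = 11)
  per_pair <- replicate(40, NULL, simplify = FALSE)
  vals <- list()
  for (r in 1:40) {
    panel <- simulate_panel(sched, lapply(1:14, function(i)
      observer_chance(seed = derive_seed(600, r, i))))
    vals[[r]] <- dprime(panel)
  }
  all_cells <- dplyr::bind_rows(vals)
  med <- dplyr::summarise(dplyr::group_by(all_cells, pair_id),
                          m = median(dprime))
  expect_true(all(abs(med$m) <= 0.2))
})

test_that("RDM construction pools, symmetrises and checks coverage", {
  tab <- tibble::tibble(
    subject = "s1", experiment = 2L, trial = 1:5,
    stim_a = c("A", "B", "A", "A", "B"), stim_b = c("B", "A", "B", "A", "B"),
    pair_a = NA, pair_b = NA, truth_synth = NA,
    response = c(10, 20, 30, 0, 0), rt = NA_real_)
  r <- build_rdm(tab)
  expect_equal(r["A", "B"], 20) # mean of {10, 20, 30}, both orders pooled
  expect_equal(r["B", "A"], 20)
  expect_equal(diag(r), c(A = 0, B = 0))

  sched <- make_schedule(stimulus_set(), 3, 2, seed = 5)
  quiet <- simulate_observer(sched, observer_rater(10, 40, 70, sigma = 0))
  r2 <- build_rdm(quiet)
  expect_equal(r2, t(r2))
  expect_true(all(r2 >= 0 & r2 <= 100))
  expect_equal(r2["O1", "S1"], 10)
  expect_equal(r2["O1", "O2"], 40) # same class, not twins
  expect_equal(r2["O1", "O3"], 70) # different class
  # missing pair coverage is an error naming the pairs
  expect_error(build_rdm(quiet[quiet$stim_a != "O1" | quiet$stim_b != "O2", ]),
               class = "mammetamer_coverage_error")
})

test_that("RDM estimates converge to the latent structure as ratings grow", {
  stim <- stimulus_set()
  info_err <- vapply(c(10, 1000), function(n) {
    sched <- make_schedule(stim, n, 2, seed = 21)
    tab <- simulate_observer(sched, observer_rater(10, 40, 70, sigma = 10,
                                                   seed = 77))
    r <- build_rdm(tab)
    quiet <- simulate_observer(make_schedule(stim, 1, 2, seed = 1),
                               observer_rater(10, 40, 70, sigma = 0))
    d <- build_rdm(quiet)
    max(abs(r - d)[upper.tri(r)])
  }, 0)
  expect_lt(info_err[2], info_err[1])
  expect_lt(info_err[2], 2) # 1000 ratings pin each entry to ~0.3 SE
})

test_that("RDM congruity is calibrated and detects shared structure", {
  stim <- stimulus_set()
  quiet <- simulate_observer(make_schedule(stim, 1, 2, seed = 1),
                             observer_rater(10, 40, 70, sigma = 0))
  base <- build_rdm(quiet)
  self <- rdm_congruity(base, base, n_perm = 199, seed = 1)
  expect_equal(self$rho, 1)
  expect_lte(self$p, 0.05)

  # power: two noisy panels sharing the latent structure
  sched <- make_schedule(stim, 10, 2, seed = 2)
  hits <- vapply(1:100, function(i) {
    a <- build_rdm(simulate_observer(sched, observer_rater(sigma = 5,
      seed = derive_seed(900, 1, i))))
    b <- build_rdm(simulate_observer(sched, observer_rater(sigma = 5,
      seed = derive_seed(900, 2, i))))
    rdm_congruity(a, b, n_perm = 199, seed = i)$p
  }, 0)
  expect_gte(mean(hits <= 0.05), 0.95)

  # null calibration: independent RDMs give roughly uniform p
  ps <- vapply(1:200, function(i) {
    mk <- function(s) {
      m <- matrix(0, 8, 8, dimnames = list(rownames(base), rownames(base)))
      vals <- withr::with_seed(s, runif(28, 0, 100))
      m[upper.tri(m)] <- vals
      m + t(m)
    }
    rdm_congruity(mk(derive_seed(700, 1, i)), mk(derive_seed(700, 2, i)),
                  n_perm = 199, seed = i)$p
  }, 0)
  expect_gte(mean(ps), 0.4)
  expect_lte(mean(ps), 0.6)
})

test_that("hierarchical clustering merges twins first and matches the oracle", {
  stim <- stimulus_set()
  quiet <- simulate_observer(make_schedule(stim, 1, 2, seed = 1),
                             observer_rater(10, 40, 70, sigma = 0))
  r <- build_rdm(quiet)
  tree <- hca(r)
  sets <- merge_leaf_sets(tree$merge)
  twin_sets <- lapply(1:4, function(k) sort(match(c(sprintf("O%d", k),
    sprintf("S%d", k)), tree$labels)))
  # the first four merges are exactly the original/synthesized twins
  expect_setequal(lapply(sets[1:4], identity), twin_sets)
  expect_true(all(diff(tree$height) >= -1e-12))

  # heights agree with the brute-force average-linkage oracle
  set.seed(12)
  d <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  d[upper.tri(d)] <- runif(15, 1, 100)
  d <- d + t(d)
  tr <- hca(structure(d, class = c("rdm", "matrix")))
  oracle <- average_linkage_oracle(d)
  expect_equal(tr$height, oracle$heights, tolerance = 1e-12)
  expect_equal(merge_leaf_sets(tr$merge), oracle$sets)

  # two conditions: a single merge at their dissimilarity
  d2 <- matrix(c(0, 42, 42, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- hca(structure(d2, class = c("rdm", "matrix")))
  expect_equal(t2$height, 42)
  expect_match(linkage_newick(t2), "x|y")
})

test_that("the paired rating comparison behaves at its boundary cases", {
  stim <- stimulus_set()
  sched <- make_schedule(stim, 2, 2, seed = 3)
  # perfectly symmetric (noiseless) raters: t = 0
  panel <- simulate_panel(sched, lapply(1:3, function(i)
    observer_rater(10, 40, 70, sigma = 0, seed = i)))
  res <- paired_rating_test(panel, stim)
  expect_equal(res$t, 0)
  expect_equal(res$df, 2)

  # hand-built subjects with differences {+1, -1}: t = 0, df = 1
  mk_subj <- function(id, x, y) tibble::tibble(
    subject = id, experiment = 2L, trial = 1:4,
    stim_a = c("O1", "S1", "O1", "O2"), stim_b = c("O2", "S2", "S2", "S1"),
    pair_a = NA, pair_b = NA, truth_synth = NA,
    response = c(x, y, 40, 40), rt = NA_real_)
  two <- dplyr::bind_rows(mk_subj("s1", 43, 40), mk_subj("s2", 40, 43))
  stim2 <- stimulus_set(2)
  res2 <- paired_rating_test(two, stim2)
  expect_equal(res2$t, 0)
  expect_equal(res2$df, 1)

  # constant nonzero differences: refuse to fabricate an infinite t
  three <- dplyr::bind_rows(mk_subj("s1", 46, 40), mk_subj("s2", 46, 40),
                            mk_subj("s3", 46, 40))
  expect_error(paired_rating_test(three, stim2),
               class = "mammetamer_degenerate_error")
  expect_error(paired_rating_test(mk_subj("s1", 43, 40), stim2),
               class = "mammetamer_degenerate_error")
})
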