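#' Define a stimulus set of original/synthesized image pairs
#'
#' @param n_pairs Number of original/synthesized pairs (default 4, two
#'   healthy and two cancerous, as in the source study design).
#' @param class_labels Diagnostic class per pair; recycled to `n_pairs`.
#' @return A `stimulus_set` tibble with columns `pair_id`, `original_id`,
#'   `synth_id`, `class_label`.
#' @export
#' @examples
#' stimulus_set()
stimulus_set <- function(n_pairs = 4L,
                         class_labels = c("normal", "normal", "cancer", "cancer")) {
  if (!is_count(n_pairs, 1)) abort_param("`n_pairs` must be a positive integer")
  cls <- rep_len(class_labels, n_pairs)
  out <- tibble::tibble(
    pair_id = sprintf("P%d", seq_len(n_pairs)),
    original_id = sprintf("O%d", seq_len(n_pairs)),
    synth_id = sprintf("S%d", seq_len(n_pairs)),
    class_label = cls)
  class(out) <- c("stimulus_set", class(out))
  out
}

stimulus_ids <- function(stimuli) c(stimuli$original_id, stimuli$synth_id)

stim_info <- function(stimuli) {
  tibble::tibble(
    stim_id = c(stimuli$original_id, stimuli$synth_id),
    pair_id = rep(stimuli$pair_id, 2),
    class_label = rep(stimuli$class_label, 2),
    synthesized = rep(c(FALSE, TRUE), each = nrow(stimuli)))
}

#' Build a trial schedule for Experiment 1 or 2
#'
#' Experiment 1 (one image per trial, synthesized-or-not judgement): every
#' image appears exactly `min_presentations` times, so exactly half of all
#' trials present a synthesized image. Experiment 2 (pair per trial,
#' 0-100 dissimilarity rating): every unordered pair of images, including
#' identical-image pairs (so "both", "either" and "neither original" trial
#' types all occur), appears `min_presentations` times. Trial order is a
#' seeded uniform shuffle.
#'
#' @param stimuli A [stimulus_set()].
#' @param min_presentations Minimum presentations per image (Exp 1) or per
#'   unordered pair (Exp 2); default 10.
#' @param experiment 1 or 2.
#' @param seed Shuffle seed.
#' @return A `trial_schedule` tibble with columns `experiment`, `trial`,
#'   `stim_a`, `stim_b` (`NA` in Experiment 1), `pair_a`, `pair_b`,
#'   `truth_synth` (`NA` in Experiment 2); the stimulus set and seed are
#'   carried as attributes.
#' @export
#' @examples
#' sched <- make_schedule(stimulus_set(), 10, experiment = 1, seed = 1)
#' mean(sched$truth_synth)  # exactly 0.5
make_schedule <- function(stimuli, min_presentations = 10L, experiment = 1L,
                          seed = 1L) {
  if (!inherits(stimuli, "stimulus_set") || nrow(stimuli) < 1)
    abort_input("`stimuli` must be a nonempty stimulus_set")
  if (!is_count(min_presentations, 1))
    abort_param("`min_presentations` must be a positive integer")
  if (!experiment %in% c(1L, 2L)) abort_param("`experiment` must be 1 or 2")
  info <- stim_info(stimuli)
  if (experiment == 1L) {
    base <- info[rep(seq_len(nrow(info)), each = min_presentations), ]
    sched <- tibble::tibble(
      experiment = 1L, stim_a = base$stim_id, stim_b = NA_character_,
      pair_a = base$pair_id, pair_b = NA_character_,
      truth_synth = base$synthesized)
  } else {
    ids <- info$stim_id
    prs <- expand.grid(a = seq_along(ids), b = seq_along(ids))
    prs <- prs[prs$a <= prs$b, ]
    prs <- prs[rep(seq_len(nrow(prs)), each = min_presentations), ]
    sched <- tibble::tibble(
      experiment = 2L, stim_a = ids[prs$a], stim_b = ids[prs$b],
      pair_a = info$pair_id[prs$a], pair_b = info$pair_id[prs$b],
      truth_synth = NA)
  }
  ord <- with_seed(seed, sample.int(nrow(sched)))
  sched <- sched[ord, ]
  sched$trial <- seq_len(nrow(sched))
  sched <- sched[, c("experiment", "trial", "stim_a", "stim_b",
                     "pair_a", "pair_b", "truth_synth")]
  attr(sched, "stimuli") <- stimuli
  attr(sched, "seed") <- as.integer(seed)
  attr(sched, "min_presentations") <- as.integer(min_presentations)
  class(sched) <- c("trial_schedule", class(sched))
  sched
}

#' Simulated observer models
#'
#' `observer_sdt()` is the standard equal-variance signal-detection observer
#' for Experiment 1: on each trial, internal evidence
#' `x ~ Normal(delta * is_synthesized, 1)` is compared to criterion `c`;
#' the response is "synthesized" iff `x > c`. `observer_chance()` is the
#' special case `delta = 0, c = 0` (responses independent of image
#' identity). `observer_rater()` is the latent-dissimilarity rater for
#' Experiment 2: the rating of a pair is
#' `clamp(D + Normal(0, sigma), 0, 100)` where `D` is 0 for identical
#' images, `d_pair` for an original and its synthesized twin, `d_class` for
#' same-class non-twins and `d_diff` otherwise.
#'
#' @param delta True sensitivity (d-prime) of the SDT observer.
#' @param criterion Decision criterion `c`.
#' @param d_pair,d_class,d_diff Latent dissimilarities on the 0-100 scale.
#' @param sigma Rating noise standard deviation (>= 0).
#' @param seed Observer seed.
#' @return An `observer_model` list.
#' @export
observer_sdt <- function(delta, criterion = 0, seed = 1L) {
  if (!is.numeric(delta) || !is.numeric(criterion))
    abort_param("`delta` and `criterion` must be numeric")
  structure(list(kind = "sdt", delta = delta, criterion = criterion,
                 seed = as.integer(seed)), class = "observer_model")
}

#' @rdname observer_sdt
#' @export
observer_chance <- function(seed = 1L) observer_sdt(0, 0, seed)

#' @rdname observer_sdt
#' @export
observer_rater <- function(d_pair = 10, d_class = 40, d_diff = 70,
                           sigma = 5, seed = 1L) {
  if (sigma < 0) abort_param("`sigma` must be nonnegative")
  structure(list(kind = "rater", d_pair = d_pair, d_class = d_class,
                 d_diff = d_diff, sigma = sigma, seed = as.integer(seed)),
            class = "observer_model")
}

latent_dissimilarity <- function(observer, stim_a, stim_b, info) {
  ia <- match(stim_a, info$stim_id); ib <- match(stim_b, info$stim_id)
  same <- stim_a == stim_b
  twin <- !same & info$pair_id[ia] == info$pair_id[ib]
  same_class <- !same & !twin & info$class_label[ia] == info$class_label[ib]
  ifelse(same, 0,
         ifelse(twin, observer$d_pair,
                ifelse(same_class, observer$d_class, observer$d_diff)))
}

#' Simulate one observer over a trial schedule
#'
#' @param schedule A [make_schedule()] trial schedule.
#' @param observer An [observer_sdt()], [observer_chance()] or
#'   [observer_rater()] model matching the experiment.
#' @param subject_id Subject label recorded in the table.
#' @return A `response_table` tibble: `subject`, `experiment`, `trial`,
#'   `stim_a`, `stim_b`, `pair_a`, `pair_b`, `truth_synth`, `response`
#'   (logical for Experiment 1, numeric 0-100 for Experiment 2), `rt`
#'   (recorded but always `NA`; reaction times are not modelled).
#' @export
#' @examples
#' sched <- make_schedule(stimulus_set(), 10, experiment = 1, seed = 1)
#' tab <- simulate_observer(sched, observer_chance(seed = 2), "s1")
simulate_observer <- function(schedule, observer, subject_id = "s1") {
  if (!inherits(schedule, "trial_schedule"))
    abort_input("`schedule` must come from make_schedule()")
  if (!inherits(observer, "observer_model"))
    abort_param("`observer` must be an observer_model")
  exper <- schedule$experiment[1]
  if (exper == 1L && observer$kind != "sdt")
    abort_input("Experiment 1 requires an sdt/chance observer")
  if (exper == 2L && observer$kind != "rater")
    abort_input("Experiment 2 requires a rater observer")
  n <- nrow(schedule)
  resp <- with_seed(observer$seed, {
    if (exper == 1L) {
      evidence <- rnorm(n, mean = observer$delta * schedule$truth_synth, sd = 1)
      evidence > observer$criterion
    } else {
      info <- stim_info(attr(schedule, "stimuli"))
      D <- latent_dissimilarity(observer, schedule$stim_a, schedule$stim_b, info)
      pmin(pmax(D + rnorm(n, 0, observer$sigma), 0), 100)
    }
  })
  out <- tibble::tibble(
    subject = subject_id, experiment = exper, trial = schedule$trial,
    stim_a = schedule$stim_a, stim_b = schedule$stim_b,
    pair_a = schedule$pair_a, pair_b = schedule$pair_b,
    truth_synth = schedule$truth_synth, response = resp, rt = NA_real_)
  attr(out, "stimuli") <- attr(schedule, "stimuli")
  class(out) <- c("response_table", class(out))
  out
}

#' Simulate a panel of observers
#'
#' @param schedule A trial schedule.
#' @param observers List of observer models; subjects are named `s1, s2, ...`
#'   unless the list is named.
#' @return A combined `response_table`.
#' @export
simulate_panel <- function(schedule, observers) {
  nms <- names(observers) %||% sprintf("s%d", seq_along(observers))
  if (is.null(names(observers))) names(observers) <- nms
  out <- dplyr::bind_rows(purrr::imap(observers, function(obs, nm)
    simulate_observer(schedule, obs, nm)))
  attr(out, "stimuli") <- attr(schedule, "stimuli")
  class(out) <- c("response_table", class(out))
  out
}

#' d-prime from corrected hit and false-alarm rates
#'
#' `dprime_from_rates()` applies the defining formula
#' `d' = qnorm(H) - qnorm(F)` directly to (already corrected) rates; it is
#' the uncorrected entry point used to bypass the log-linear correction.
#'
#' @param H,F Hit and false-alarm rates in (0, 1).
#' @return Numeric d-prime.
#' @export
dprime_from_rates <- function(H, F) {
  if (any(H <= 0 | H >= 1 | F <= 0 | F >= 1))
    abort_input("rates must lie strictly in (0, 1)")
  qnorm(H) - qnorm(F)
}

#' Signal-detection sensitivity per subject and image pair
#'
#' For each (subject, pair) cell of an Experiment-1 response table, computes
#' the log-linear-corrected hit rate `H* = (h + 0.5) / (n_s + 1)` and
#' false-alarm rate `F* = (f + 0.5) / (n_o + 1)` and
#' `d' = qnorm(H*) - qnorm(F*)`. The log-linear correction keeps d-prime
#' finite at ceiling/floor performance. The `tn_vs_miss` variant applies the
#' same formula to the corrected true-negative rate
#' `(n_o - f + 0.5) / (n_o + 1)` versus the corrected miss rate
#' `(n_s - h + 0.5) / (n_s + 1)`.
#'
#' @param table An Experiment-1 `response_table`.
#' @param variant `"hits_vs_fa"` (default) or `"tn_vs_miss"`.
#' @return A `dprime_result` tibble: `subject`, `pair_id`, `h`, `f`, `n_s`,
#'   `n_o`, `H_star`, `F_star`, `dprime`, `variant`.
#' @export
#' @examples
#' sched <- make_schedule(stimulus_set(), 10, experiment = 1, seed = 1)
#' simulate_observer(sched, observer_chance(2)) |> dprime()
dprime <- function(table, variant = c("hits_vs_fa", "tn_vs_miss")) {
  variant <- match.arg(variant)
  if (!all(table$experiment == 1L))
    abort_input("`table` must contain Experiment-1 trials only")
  cells <- table |>
    dplyr::group_by(.data$subject, pair_id = .data$pair_a) |>
    dplyr::summarise(
      n_s = sum(.data$truth_synth), n_o = sum(!.data$truth_synth),
      h = sum(.data$truth_synth & .data$response),
      f = sum(!.data$truth_synth & .data$response), .groups = "drop")
  bad <- cells[cells$n_s < 1 | cells$n_o < 1, ]
  if (nrow(bad))
    abort_degenerate(sprintf(
      "missing trial class for subject/pair: %s",
      paste(sprintf("%s/%s", bad$subject, bad$pair_id), collapse = ", ")))
  if (variant == "hits_vs_fa") {
    cells$H_star <- (cells$h + 0.5) / (cells$n_s + 1)
    cells$F_star <- (cells$f + 0.5) / (cells$n_o + 1)
  } else {
    cells$H_star <- (cells$n_o - cells$f + 0.5) / (cells$n_o + 1) # corrected TN rate
    cells$F_star <- (cells$n_s - cells$h + 0.5) / (cells$n_s + 1) # corrected miss rate
  }
  cells$dprime <- qnorm(cells$H_star) - qnorm(cells$F_star)
  cells$variant <- variant
  class(cells) <- c("dprime_result", class(cells))
  cells
}

#' Representational dissimilarity matrix from Experiment-2 ratings
#'
#' Entry (i, j) is the mean rating over all trials presenting the unordered
#' pair `{i, j}` (both presentation orders pooled); the matrix is symmetric
#' with diagonal 0 by convention.
#'
#' @param table An Experiment-2 `response_table` covering every unordered
#'   pair of distinct conditions at least once.
#' @return An `rdm`: a symmetric numeric matrix with condition labels as
#'   dimnames and entries in `[0, 100]`.
#' @export
build_rdm <- function(table) {
  if (!all(table$experiment == 2L))
    abort_input("`table` must contain Experiment-2 trials only")
  stimuli <- attr(table, "stimuli")
  conds <- if (!is.null(stimuli)) stimulus_ids(stimuli) else
    sort(unique(c(table$stim_a, table$stim_b)))
  k <- length(conds)
  m <- matrix(0, k, k, dimnames = list(conds, conds))
  cnt <- matrix(0L, k, k)
  ia <- match(table$stim_a, conds); ib <- match(table$stim_b, conds)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  for (t in seq_along(lo)) {
    m[lo[t], hi[t]] <- m[lo[t], hi[t]] + table$response[t]
    cnt[lo[t], hi[t]] <- cnt[lo[t], hi[t]] + 1L
  }
  miss <- which(upper.tri(cnt) & cnt == 0, arr.ind = TRUE)
  if (nrow(miss))
    abort_coverage(sprintf(
      "unrated pairs: %s",
      paste(sprintf("{%s, %s}", conds[miss[, 1]], conds[miss[, 2]]),
            collapse = ", ")))
  mean_ut <- ifelse(cnt > 0, m / pmax(cnt, 1L), 0)
  out <- mean_ut + t(mean_ut)
  diag(out) <- 0
  dimnames(out) <- list(conds, conds)
  structure(out, class = c("rdm", "matrix"))
}

#' Congruity of two RDMs by a label-permutation test
#'
#' Computes the Spearman rank correlation between the upper triangles of two
#' RDMs over the same conditions, and a one-sided permutation p-value
#' obtained by jointly permuting the condition labels (rows and columns) of
#' `b`: `p = (1 + #\{rho_perm >= rho_obs\}) / (n_perm + 1)`.
#'
#' @param a,b `rdm` matrices over the same condition set.
#' @param n_perm Number of label permutations (>= 100; default 1000).
#' @param seed Permutation seed.
#' @return A `rdm_congruity` tibble with `rho`, `p`, `n_perm`.
#' @export
rdm_congruity <- function(a, b, n_perm = 1000L, seed = 1L) {
  if (!is.matrix(a) || !is.matrix(b)) abort_structure("`a` and `b` must be matrices")
  if (is.null(rownames(a)) || is.null(rownames(b)) ||
      !setequal(rownames(a), rownames(b)))
    abort_structure("RDMs must share the same condition labels")
  if (!is_count(n_perm, 100)) abort_param("`n_perm` must be an integer >= 100")
  b <- b[rownames(a), rownames(a)]
  ut <- upper.tri(a)
  rho_obs <- cor(a[ut], b[ut], method = "spearman")
  k <- nrow(a)
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(k)
      bp <- b[pm, pm]
      if (cor(a[ut], bp[ut], method = "spearman") >= rho_obs) hits <- hits + 1L
    }
    hits
  })
  out <- tibble::tibble(rho = rho_obs, p = (1 + count) / (n_perm + 1),
                        n_perm = as.integer(n_perm))
  class(out) <- c("rdm_congruity", class(out))
  out
}

#' Hierarchical clustering of an RDM
#'
#' Agglomerative average-linkage clustering of the conditions by their
#' dissimilarities, as a quantitative dendrogram of perceptual structure.
#'
#' @param rdm An `rdm` matrix.
#' @return A `linkage_tree`: list wrapping the `hclust` object with `merge`,
#'   `height`, `labels` and a cophenetic-distance accessor via
#'   [cophenetic_distances()].
#' @export
hca <- function(rdm) {
  if (!is.matrix(rdm)) abort_structure("`rdm` must be a matrix")
  hc <- hclust(as.dist(rdm), method = "average")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 hclust = hc),
            class = "linkage_tree")
}

#' @rdname hca
#' @param tree A `linkage_tree`.
#' @export
cophenetic_distances <- function(tree) {
  as.matrix(cophenetic(tree$hclust))
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d conditions, %d merges, heights %.3g..%.3g\n",
              length(x$labels), nrow(x$merge),
              min(x$height), max(x$height)))
  invisible(x)
}

#' Newick serialisation of a linkage tree
#'
#' @param tree A `linkage_tree` from [hca()].
#' @return A single Newick string.
#' @export
linkage_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree$hclust))
}

#' Paired comparison of ratings for originals vs synthesized twins
#'
#' Per subject, takes the mean Experiment-2 rating of all pairs involving an
#' original image minus the mean rating of all pairs involving a synthesized
#' image, excluding original/synthesized twin pairs and identical-image
#' pairs from both sides, then tests the subject-level differences against
#' zero with a two-sided paired t-test (`df = n_subjects - 1`). Constant
#' nonzero differences (zero variance) raise a degenerate-input error
#' rather than returning an infinite statistic.
#'
#' @param table An Experiment-2 `response_table` with >= 2 subjects.
#' @param stimuli The [stimulus_set()] used (defaults to the one attached to
#'   `table`).
#' @return A `paired_rating_test` tibble: `t`, `p`, `df`, `n_subjects`,
#'   `mean_diff`.
#' @export
paired_rating_test <- function(table, stimuli = attr(table, "stimuli")) {
  if (!all(table$experiment == 2L))
    abort_input("`table` must contain Experiment-2 trials only")
  if (is.null(stimuli)) abort_input("no stimulus set available")
  info <- stim_info(stimuli)
  ia <- match(table$stim_a, info$stim_id)
  ib <- match(table$stim_b, info$stim_id)
  identical_pair <- table$stim_a == table$stim_b
  twin <- !identical_pair & info$pair_id[ia] == info$pair_id[ib]
  keep <- !identical_pair & !twin
  has_orig <- keep & (!info$synthesized[ia] | !info$synthesized[ib])
  has_syn <- keep & (info$synthesized[ia] | info$synthesized[ib])
  subjects <- unique(table$subject)
  if (length(subjects) < 2) abort_degenerate("need at least 2 subjects")
  diffs <- vapply(subjects, function(s) {
    sel <- table$subject == s
    mean(table$response[sel & has_orig]) - mean(table$response[sel & has_syn])
  }, 0)
  n <- length(diffs)
  sdd <- sd(diffs)
  if (sdd == 0 && mean(diffs) != 0)
    abort_degenerate("subject differences are constant and nonzero; t is undefined")
  tt <- if (sdd == 0) 0 else mean(diffs) / (sdd / sqrt(n))
  p <- if (sdd == 0) 1 else 2 * pt(-abs(tt), df = n - 1)
  out <- tibble::tibble(t = tt, p = p, df = n - 1L, n_subjects = n,
                        mean_diff = mean(diffs))
  class(out) <- c("paired_rating_test", class(out))
  out
}
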