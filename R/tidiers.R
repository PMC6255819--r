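#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a d-prime result
#'
#' `tidy()` returns the per-(subject, pair) table; `glance()` summarises
#' sensitivity across cells (mean, median, min, max d-prime).
#'
#' @param x A `dprime_result` from [dprime()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dprime_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.dprime_result
#' @export
glance.dprime_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    mean_dprime = mean(x$dprime),
    median_dprime = median(x$dprime),
    min_dprime = min(x$dprime),
    max_dprime = max(x$dprime),
    variant = x$variant[1])
}

#' Tidy an RDM into long format
#'
#' @param x An `rdm` matrix.
#' @param ... Unused.
#' @return A tibble with `condition_a`, `condition_b`, `dissimilarity`.
#' @export
tidy.rdm <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    condition_a = rep(rownames(m), times = ncol(m)),
    condition_b = rep(colnames(m), each = nrow(m)),
    dissimilarity = as.vector(m))
}

#' @export
glance.rdm_congruity <- function(x, ...) tibble::as_tibble(x)

#' Tidy a linkage tree's merge table
#'
#' @param x A `linkage_tree` from [hca()].
#' @param ... Unused.
#' @return A tibble with one row per merge: `merge1`, `merge2` (negative
#'   values index original conditions, positive values earlier merges) and
#'   `height`.
#' @export
tidy.linkage_tree <- function(x, ...) {
  tibble::tibble(merge1 = x$merge[, 1], merge2 = x$merge[, 2],
                 height = x$height)
}

#' Tidy a synthesis result's loss trajectory
#'
#' @param x A `synthesis_result` from [synthesize()].
#' @param ... Unused.
#' @return A tibble with `iteration` (0 = initialisation) and `loss`.
#' @export
tidy.synthesis_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$loss_trajectory) - 1L,
                 loss = x$loss_trajectory)
}

#' @rdname tidy.synthesis_result
#' @export
glance.synthesis_result <- function(x, ...) {
  tibble::tibble(
    iterations_run = x$iterations_run,
    initial_loss = x$loss_trajectory[1],
    final_loss = x$final_loss,
    loss_ratio = x$final_loss / x$loss_trajectory[1],
    init_seed = x$init_seed)
}
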