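#' @importFrom rlang abort %||% .data
#' @importFrom stats rnorm runif fft qnorm pnorm sd cor as.dist hclust cophenetic pt median
#' @keywords internal
"_PACKAGE"

# Error helpers. Every user-facing failure carries a subclass so callers (and
# the CLI) can branch on the kind of problem rather than on message text.
mm_abort <- function(message, class) {
  rlang::abort(message, class = c(paste0("mammetamer_", class), "mammetamer_error"))
}

abort_param     <- function(msg) mm_abort(msg, "param_error")
abort_input     <- function(msg) mm_abort(msg, "input_error")
abort_structure <- function(msg) mm_abort(msg, "structure_error")
abort_degenerate<- function(msg) mm_abort(msg, "degenerate_error")
abort_numeric   <- function(msg) mm_abort(msg, "numerical_error")
abort_io        <- function(msg) mm_abort(msg, "io_error")
abort_coverage  <- function(msg) mm_abort(msg, "coverage_error")

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

#' Derive a child seed from a master seed
#'
#' Deterministic, platform-stable fan-out of one master seed into independent
#' child seeds, used throughout the package so that a single seed reproduces a
#' whole cohort, schedule or pipeline run. The scheme is a fixed-modulus
#' linear hash: starting from `master mod m`, each index `i` updates
#' `s <- (s * 1000003 + i * 1009 + 1) mod m` with `m = 2147483629` (a prime
#' below 2^31). All intermediate products stay below 2^53, so the arithmetic
#' is exact in double precision on every platform.
#'
#' @param master Integer master seed.
#' @param ... Additional non-negative integer indices (e.g. class index,
#'   replicate index).
#' @return A single integer seed in `[1, 2147483628]`.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483629
  if (!is.numeric(master) || length(master) != 1 || !is.finite(master))
    abort_param("`master` must be a single finite number")
  s <- abs(as.numeric(master)) %% m
  for (i in idx) {
    s <- (s * 1000003 + abs(as.numeric(i)) * 1009 + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x) && x >= min
}

assert_gray <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    abort_input(sprintf("`%s` must be a numeric matrix", what))
  if (any(!is.finite(image)))
    abort_input(sprintf("`%s` contains non-finite values", what))
  invisible(image)
}

assert_gray01 <- function(image, what = "image", tol = 1e-8) {
  assert_gray(image, what)
  if (min(image) < -tol || max(image) > 1 + tol)
    abort_input(sprintf("`%s` values must lie in [0, 1]", what))
  invisible(image)
}

# Separable Gaussian blur with replicate (edge-clamp) borders. Kernel is
# truncated at 4 sigma and renormalised, so constant images are fixed points
# and the operator commutes with 90-degree rotations.
gauss_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(image))))
}
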