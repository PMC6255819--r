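#' Diagnostic classes of the phantom generator
#'
#' The four radiologically motivated categories emulated by the synthetic
#' phantoms: background-only tissue, an obviously benign smooth disc, an
#' ambiguous fuzzy-edged mass, and a cluster of bright microcalcification-like
#' blobs.
#' @export
phantom_classes <- c("normal", "benign_no_callback", "benign", "cancer")

#' Parameters for a single synthetic phantom
#'
#' Bundles and validates everything [generate_phantom()] needs. The background
#' is an isotropic power-law Gaussian random field (power spectrum
#' proportional to `1/f^beta`), a standard stand-in for mammographic tissue
#' texture; lesions are superposed on top per class. All lesion geometry
#' values are generator stand-ins, not measurements of real lesions.
#'
#' @param class_label One of [phantom_classes].
#' @param height,width Image size in pixels, at least 32.
#' @param background_exponent Spectral slope beta of the background field.
#' @param blob_count Integer range `c(lo, hi)` of microcalcification blobs
#'   (cancer class only).
#' @param blob_sigma Range of blob Gaussian sigma in pixels (cancer class).
#' @param contrast Peak lesion contrast added to the background, in `(0, 1]`.
#'   Defaults per class: 0.10 (benign_no_callback), 0.18 (benign),
#'   0.35 (cancer).
#' @param seed Integer seed; the phantom is a pure function of its parameters.
#' @return A `phantom_params` list.
#' @export
#' @examples
#' p <- phantom_params("cancer", 64, 64, seed = 7)
phantom_params <- function(class_label,
                           height = 128, width = 128,
                           background_exponent = 3.0,
                           blob_count = c(5L, 15L),
                           blob_sigma = c(1, 2),
                           contrast = NULL,
                           seed = 1L) {
  class_label <- match.arg(class_label, phantom_classes)
  if (!is_count(height, 32) || !is_count(width, 32))
    abort_param("`height` and `width` must be integers >= 32")
  if (length(blob_count) != 2 || blob_count[2] < blob_count[1] || blob_count[1] < 1)
    abort_param("`blob_count` must be a nonempty integer range c(lo, hi)")
  if (is.null(contrast)) {
    contrast <- switch(class_label,
      normal = 0, benign_no_callback = 0.10, benign = 0.18, cancer = 0.35)
  }
  if (class_label != "normal" && (contrast <= 0 || contrast > 1))
    abort_param("`contrast` must lie in (0, 1]")
  if (!is.numeric(background_exponent) || background_exponent < 0)
    abort_param("`background_exponent` must be a nonnegative number")
  structure(
    list(class_label = class_label, height = as.integer(height),
         width = as.integer(width),
         background_exponent = background_exponent,
         blob_count = as.integer(blob_count), blob_sigma = blob_sigma,
         contrast = contrast, seed = as.integer(seed)),
    class = "phantom_params")
}

# Isotropic Gaussian random field with power spectrum ~ 1/f^beta, rescaled to
# [0.2, 0.8]. Built in the Fourier domain: white Gaussian noise filtered by
# f^(-beta/2) amplitude, DC removed.
power_law_field <- function(h, w, beta) {
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1) / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1) / w
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- f
  amp[f > 0] <- f[f > 0]^(-beta / 2)
  amp[f == 0] <- 0
  noise <- matrix(rnorm(h * w), h, w)
  field <- Re(fft(fft(noise) * amp, inverse = TRUE)) / (h * w)
  rng <- range(field)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, h, w))
  0.2 + 0.6 * (field - rng[1]) / diff(rng)
}

disc_mask <- function(h, w, cy, cx, radius) {
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  (d2 <= radius^2) * 1L
}

#' Generate one synthetic mammogram-like phantom
#'
#' Deterministically renders a phantom from its parameters: a power-law
#' background rescaled to `[0.2, 0.8]`, plus class-specific lesion features.
#' `normal` is background only (empty ROI mask); `benign_no_callback` adds a
#' smooth disc (radius 8-12 px); `benign` adds one fuzzy-edged Gaussian mass
#' (sigma 6-10 px, mask radius 2 sigma); `cancer` adds a cluster of small
#' bright Gaussian blobs inside a 12 px disc, whose extent is the mask.
#' Lesion extents are capped at `floor(min(height, width)/2) - 2` so the ROI
#' always fits small images. Pixels are clamped to `[0, 1]` after
#' superposition.
#'
#' @param params A [phantom_params()] object.
#' @return A `phantom`: list with `image` (numeric matrix in `[0,1]`),
#'   `roi_mask` (0/1 integer matrix, one 8-connected component for non-normal
#'   classes), `class_label`, and `seed`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params("cancer", 64, 64, seed = 7))
#' range(ph$image)
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params"))
    params <- do.call(phantom_params, as.list(params))
  h <- params$height; w <- params$width
  cap <- floor(min(h, w) / 2) - 2
  with_seed(params$seed, {
    img <- power_law_field(h, w, params$background_exponent)
    mask <- matrix(0L, h, w)
    if (params$class_label != "normal") {
      extent <- switch(params$class_label,
        benign_no_callback = min(runif(1, 8, 12), cap),
        benign = 2 * min(runif(1, 6, 10), cap / 2),
        cancer = min(12, cap))
      margin <- ceiling(extent) + 1
      cy <- round_half_up(runif(1, margin + 1, h - margin))
      cx <- round_half_up(runif(1, margin + 1, w - margin))
      yy <- outer(seq_len(h) - cy, rep(1, w))
      xx <- outer(rep(1, h), seq_len(w) - cx)
      if (params$class_label == "benign_no_callback") {
        # smooth disc: sigmoid edge of ~1.5 px width
        d <- sqrt(yy^2 + xx^2)
        img <- img + params$contrast / (1 + exp((d - extent) / 0.75))
        mask <- disc_mask(h, w, cy, cx, extent)
      } else if (params$class_label == "benign") {
        sig <- extent / 2
        img <- img + params$contrast * exp(-(yy^2 + xx^2) / (2 * sig^2))
        mask <- disc_mask(h, w, cy, cx, extent)
      } else {
        counts <- seq(params$blob_count[1], params$blob_count[2])
        n_blob <- counts[sample.int(length(counts), 1)]
        for (b in seq_len(n_blob)) {
          theta <- runif(1, 0, 2 * pi)
          rad <- extent * sqrt(runif(1))
          by <- cy + rad * sin(theta); bx <- cx + rad * cos(theta)
          bs <- runif(1, params$blob_sigma[1], params$blob_sigma[2])
          img <- img + params$contrast *
            exp(-((yy - (by - cy))^2 + (xx - (bx - cx))^2) / (2 * bs^2))
        }
        mask <- disc_mask(h, w, cy, cx, extent)
      }
    }
    structure(
      list(image = clamp01(img), roi_mask = mask,
           class_label = params$class_label, seed = params$seed,
           params = params),
      class = "phantom")
  })
}

#' Generate a balanced cohort of phantoms
#'
#' Produces `n_per_class` phantoms for each of the four diagnostic classes
#' (so `4 * n_per_class` in total), with per-phantom seeds fanned out from
#' the master seed via [derive_seed()].
#'
#' @param n_per_class Number of phantoms per class (>= 1).
#' @param size Square image side in pixels.
#' @param seed Master seed.
#' @param ... Passed on to [phantom_params()] (e.g. `background_exponent`).
#' @return A list of `phantom` objects, classes in [phantom_classes] order,
#'   replicates within class.
#' @export
#' @examples
#' cohort <- generate_cohort(2, size = 64, seed = 1)
#' table(vapply(cohort, `[[`, "", "class_label"))
generate_cohort <- function(n_per_class, size = 64, seed = 1L, ...) {
  if (!is_count(n_per_class, 1)) abort_param("`n_per_class` must be a positive integer")
  out <- vector("list", 4L * n_per_class)
  k <- 0L
  for (ci in seq_along(phantom_classes)) {
    for (ri in seq_len(n_per_class)) {
      k <- k + 1L
      out[[k]] <- generate_phantom(phantom_params(
        phantom_classes[ci], height = size, width = size,
        seed = derive_seed(seed, ci, ri), ...))
    }
  }
  out
}

#' Tabular manifest of a phantom cohort
#'
#' @param cohort A list of `phantom` objects.
#' @return A tibble with one row per phantom: `id`, `class_label`, `height`,
#'   `width`, `seed`, `roi_pixels`.
#' @export
cohort_manifest <- function(cohort) {
  tibble::tibble(
    id = sprintf("phantom_%03d", seq_along(cohort)),
    class_label = vapply(cohort, `[[`, "", "class_label"),
    height = vapply(cohort, function(p) nrow(p$image), 0L),
    width = vapply(cohort, function(p) ncol(p$image), 0L),
    seed = vapply(cohort, `[[`, 0L, "seed"),
    roi_pixels = vapply(cohort, function(p) sum(p$roi_mask), 0L)
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, %dx%d px, seed %d, ROI pixels %d\n",
              x$class_label, nrow(x$image), ncol(x$image), x$seed,
              sum(x$roi_mask)))
  invisible(x)
}
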