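#' 8-connected components of a binary mask
#'
#' Labels the foreground (nonzero) pixels of a mask into 8-connected
#' components. Labels are assigned in raster-scan order (row-major): the
#' component containing the first foreground pixel encountered scanning rows
#' top-to-bottom, left-to-right within a row, gets label 1, and so on.
#'
#' @param mask Binary matrix (0/1, or logical).
#' @return List with `count` (number of components) and `labels` (integer
#'   matrix, 0 = background).
#' @export
#' @examples
#' m <- matrix(0L, 5, 5); m[1, 1] <- 1L; m[2, 2] <- 1L; m[4, 5] <- 1L
#' connected_components(m)$count  # diagonal pixels join under 8-connectivity
connected_components <- function(mask) {
  if (!is.matrix(mask)) abort_input("`mask` must be a matrix")
  fg <- which(mask != 0)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(fg)) return(list(count = 0L, labels = labels))
  h <- nrow(mask); w <- ncol(mask)
  r <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  pos <- match(fg, fg) # identity; index of each fg pixel in fg order
  lut <- integer(h * w); lut[fg] <- seq_along(fg)
  edges <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nr <- r + dr; nc <- cc + dc
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    nb <- (nc[ok] - 1L) * h + nr[ok]
    hit <- lut[nb] > 0
    if (any(hit)) {
      edges <- rbind(edges, cbind(pos[ok][hit], lut[nb][hit]))
    }
  }
  g <- igraph::graph_from_edgelist(rbind(cbind(seq_along(fg), seq_along(fg)),
                                         edges), directed = FALSE)
  memb <- igraph::components(g)$membership[seq_along(fg)]
  # renumber by first appearance in row-major order
  ord <- order(r, cc)
  first_seen <- memb[ord][!duplicated(memb[ord])]
  relabel <- integer(max(memb)); relabel[first_seen] <- seq_along(first_seen)
  labels[fg] <- relabel[memb]
  list(count = length(first_seen), labels = labels)
}

pvm_record <- function(crop, source_id, class_label, center, provenance) {
  structure(list(crop = crop, source_id = source_id,
                 class_label = class_label, center = center,
                 provenance = provenance),
            class = "pvm_record")
}

pvm_skip <- function(reason, source_id = NULL) {
  structure(list(reason = reason, source_id = source_id), class = "pvm_skip")
}

#' @export
print.pvm_record <- function(x, ...) {
  cat(sprintf("<pvm_record> %dx%d crop at (%d, %d), class %s, provenance %s\n",
              nrow(x$crop), ncol(x$crop), x$center[1], x$center[2],
              x$class_label %||% "?", x$provenance))
  invisible(x)
}

#' @export
print.pvm_skip <- function(x, ...) {
  cat(sprintf("<pvm_skip> reason: %s\n", x$reason))
  invisible(x)
}

#' Extract an ROI-centered partial-view patch
#'
#' Centers a `w x w` square on the (rounded, half-up) centroid of the single
#' ROI component and crops it. Mirrors the source study's patch rules: the
#' extraction is skipped, with a machine-readable reason, if the mask has
#' more than one 8-connected component (`multiple_rois`), if the square
#' would exceed the image bounds (`out_of_bounds`; no padding — fabricated
#' tissue is worse than a skip), or if any ROI pixel falls outside the
#' square (`roi_outside_square`). Reasons are checked in that order. All
#' indices are 1-based; the square spans rows `r0 .. r0 + w - 1` with
#' `r0 = center_row - floor(w/2)` (likewise columns).
#'
#' @param image Grayscale matrix.
#' @param mask Binary ROI mask of the same shape; must be nonempty.
#' @param w Patch side in pixels (>= 2).
#' @param class_label Diagnostic class recorded in the result.
#' @param source_id Optional provenance identifier.
#' @return A `pvm_record` (provenance `"roi"`) or a `pvm_skip`.
#' @export
extract_pvm_roi <- function(image, mask, w, class_label = NULL,
                            source_id = NULL) {
  assert_gray(image)
  if (!is.matrix(mask) || any(dim(mask) != dim(image)))
    abort_input("`mask` must be a matrix with the same shape as `image`")
  if (!any(mask != 0)) abort_input("`mask` is empty")
  if (!is_count(w, 2)) abort_param("`w` must be an integer >= 2")
  comp <- connected_components(mask)
  if (comp$count != 1) return(pvm_skip("multiple_rois", source_id))
  idx <- which(mask != 0)
  rr <- ((idx - 1L) %% nrow(mask)) + 1L
  cc <- ((idx - 1L) %/% nrow(mask)) + 1L
  center <- c(round_half_up(mean(rr)), round_half_up(mean(cc)))
  r0 <- center[1] - floor(w / 2); c0 <- center[2] - floor(w / 2)
  if (r0 < 1 || c0 < 1 || r0 + w - 1 > nrow(image) || c0 + w - 1 > ncol(image))
    return(pvm_skip("out_of_bounds", source_id))
  if (any(rr < r0 | rr > r0 + w - 1 | cc < c0 | cc > c0 + w - 1))
    return(pvm_skip("roi_outside_square", source_id))
  pvm_record(image[r0:(r0 + w - 1), c0:(c0 + w - 1)], source_id, class_label,
             center, "roi")
}

#' Intensity center-surround saliency map
#'
#' A single-channel conspicuity map in the Itti-Koch spirit, reduced to the
#' intensity channel (the only meaningful one for grayscale mammograms):
#' `S = smooth(sum_{s in {1,2,4}} maxnorm(|G_s * I - G_{4s} * I|))` with
#' Gaussian blurs `G`, each center-surround difference max-normalised before
#' summing, final smoothing sigma 2, and the result normalised to maximum 1
#' unless identically zero. A constant image maps to the zero map.
#'
#' @param image Grayscale matrix at least 32 x 32.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
saliency_map <- function(image) {
  assert_gray(image)
  if (nrow(image) < 32 || ncol(image) < 32)
    abort_input("image must be at least 32 x 32 for saliency computation")
  # maps whose peak is at floating-point noise level are treated as flat
  maxnorm <- function(m) {
    mx <- max(m)
    if (mx > 1e-12) m / mx else matrix(0, nrow(m), ncol(m))
  }
  s <- matrix(0, nrow(image), ncol(image))
  for (sig in c(1, 2, 4)) {
    s <- s + maxnorm(abs(gauss_blur(image, sig) - gauss_blur(image, 4 * sig)))
  }
  maxnorm(gauss_blur(s, 2))
}

# Row-major-first index among a set of flat indices of a matrix.
rowmajor_first <- function(idx, h) {
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  idx[order(rr, cc)][1L]
}

#' Extract a saliency-centered partial-view patch
#'
#' For images without an ROI (the normal class), centers the patch on the
#' most salient pixel within the most salient region: the 8-connected
#' component of pixels with saliency at least `0.9 * max` that contains the
#' global argmax (ties broken by smallest row-major index). The square is
#' clamped (shifted) to lie inside the image, so a patch is always produced.
#'
#' @inheritParams extract_pvm_roi
#' @return A `pvm_record` with provenance `"saliency"`.
#' @export
extract_pvm_salient <- function(image, w, class_label = NULL,
                                source_id = NULL) {
  assert_gray(image)
  if (!is_count(w, 2)) abort_param("`w` must be an integer >= 2")
  if (nrow(image) < w || ncol(image) < w)
    abort_input("image is smaller than the requested patch")
  s <- saliency_map(image)
  h <- nrow(s)
  smax <- max(s)
  argmax <- rowmajor_first(which(s == smax), h)
  region <- connected_components(s >= 0.9 * smax)
  lab <- region$labels[argmax]
  in_region <- which(region$labels == lab & s == smax)
  best <- rowmajor_first(in_region, h)
  center <- c(((best - 1L) %% h) + 1L, ((best - 1L) %/% h) + 1L)
  r0 <- min(max(center[1] - floor(w / 2), 1L), nrow(image) - w + 1L)
  c0 <- min(max(center[2] - floor(w / 2), 1L), ncol(image) - w + 1L)
  pvm_record(image[r0:(r0 + w - 1), c0:(c0 + w - 1)], source_id, class_label,
             center, "saliency")
}

#' Extract patches from a whole phantom cohort
#'
#' Applies [extract_pvm_roi()] to non-normal phantoms and
#' [extract_pvm_salient()] to normal ones, collecting records and skips.
#'
#' @param cohort List of `phantom` objects.
#' @param w Patch side in pixels.
#' @return List with `records` (list of `pvm_record`) and `skips` (list of
#'   `pvm_skip`), plus a `manifest` tibble summarising both.
#' @export
extract_cohort_pvms <- function(cohort, w) {
  records <- list(); skips <- list(); rows <- list()
  for (i in seq_along(cohort)) {
    ph <- cohort[[i]]
    id <- sprintf("phantom_%03d", i)
    res <- if (ph$class_label == "normal") {
      extract_pvm_salient(ph$image, w, ph$class_label, id)
    } else {
      extract_pvm_roi(ph$image, ph$roi_mask, w, ph$class_label, id)
    }
    if (inherits(res, "pvm_skip")) {
      skips[[length(skips) + 1L]] <- res
      rows[[length(rows) + 1L]] <- tibble::tibble(
        source_id = id, class_label = ph$class_label, status = "skip",
        reason = res$reason, center_row = NA_integer_, center_col = NA_integer_,
        provenance = NA_character_)
    } else {
      records[[length(records) + 1L]] <- res
      rows[[length(rows) + 1L]] <- tibble::tibble(
        source_id = id, class_label = ph$class_label, status = "ok",
        reason = NA_character_, center_row = res$center[1],
        center_col = res$center[2], provenance = res$provenance)
    }
  }
  list(records = records, skips = skips, manifest = dplyr::bind_rows(rows))
}
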