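test_that("connected component labelling agrees with the flood-fill oracle", {
  m <- matrix(0L, 5, 5)
  expect_equal(connected_components(m)$count, 0)
  m[1:2, 1:2] <- 1L; m[4:5, 4:5] <- 1L
  expect_equal(connected_components(m)$count, 2)
  # diagonal touch joins under 8-connectivity
  d <- matrix(0L, 4, 4); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_equal(connected_components(d)$count, 1)
  expect_equal(flood_components(d)$count, 1)
  # random masks: counts and partitions match the oracle
  set.seed(8)
  for (k in 1:10) {
    rm <- matrix(rbinom(20 * 20, 1, 0.3), 20)
    got <- connected_components(rm)
    want <- flood_components(rm)
    expect_equal(got$count, want$count)
    # same partition: labels must be a relabelling of the oracle's
    tab <- table(got$labels[rm == 1], want$labels[rm == 1])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("ROI extraction crops the centred square and skips per the rules", {
  img <- matrix(runif(256 * 256), 256)
  # single small ROI at center: crop contains all ROI pixels
  mask <- matrix(0L, 256, 256); mask[120:136, 124:140] <- 1L
  rec <- extract_pvm_roi(img, mask, 64, "cancer")
  expect_s3_class(rec, "pvm_record")
  expect_identical(dim(rec$crop), c(64L, 64L))
  expect_equal(rec$center, c(128, 132))
  expect_equal(rec$provenance, "roi")
  # crop content matches the source square
  expect_equal(rec$crop, img[96:159, 100:163])

  # elongated ROI wider than the square
  wide <- matrix(0L, 256, 256); wide[128, 50:200] <- 1L
  sk <- extract_pvm_roi(img, wide, 64, "benign")
  expect_s3_class(sk, "pvm_skip")
  expect_equal(sk$reason, "roi_outside_square")

  # two components
  multi <- matrix(0L, 256, 256); multi[10:12, 10:12] <- 1L; multi[200:202, 200:202] <- 1L
  expect_equal(extract_pvm_roi(img, multi, 64)$reason, "multiple_rois")

  # square would leave the image
  corner <- matrix(0L, 256, 256); corner[2:4, 2:4] <- 1L
  expect_equal(extract_pvm_roi(img, corner, 64)$reason, "out_of_bounds")

  expect_error(extract_pvm_roi(img, matrix(0L, 256, 256), 64),
               class = "mammetamer_input_error")

  # the three skip reasons are mutually exclusive and exhaustive over a
  # constructed suite
  suite <- list(mask, wide, multi, corner)
  outcomes <- vapply(suite, function(m) {
    r <- extract_pvm_roi(img, m, 64)
    if (inherits(r, "pvm_skip")) r$reason else "ok"
  }, "")
  expect_setequal(outcomes, c("ok", "roi_outside_square", "multiple_rois",
                              "out_of_bounds"))
})

test_that("saliency maps highlight contrast and transform predictably", {
  expect_true(all(saliency_map(matrix(0.4, 48, 48)) == 0))

  img <- matrix(0.3, 64, 64)
  yy <- outer(1:64 - 20, rep(1, 64)); xx <- outer(rep(1, 64), 1:64 - 45)
  img <- img + 0.5 * exp(-(yy^2 + xx^2) / (2 * 3^2))
  s <- saliency_map(img)
  expect_gte(min(s), 0); expect_lte(max(s), 1)
  am <- which(s == max(s), arr.ind = TRUE)[1, ]
  expect_lte(sqrt(sum((am - c(20, 45))^2)), 3)

  rot90 <- function(m) t(m[nrow(m):1, ])
  expect_equal(saliency_map(rot90(img)), rot90(saliency_map(img)),
               tolerance = 1e-10)

  expect_error(saliency_map(matrix(0.5, 16, 16)),
               class = "mammetamer_input_error")
})

test_that("saliency-centred crops stay in bounds and honour tie-breaks", {
  # flat image: argmax tie-break forces the top-left anchored crop
  flat <- matrix(0.5, 100, 100)
  rec <- extract_pvm_salient(flat, 64, "normal")
  expect_identical(dim(rec$crop), c(64L, 64L))
  expect_equal(rec$center, c(1L, 1L))
  expect_equal(rec$provenance, "saliency")

  # blob near a corner: crop clamps inside the image and contains the blob
  img <- matrix(0.3, 100, 100)
  yy <- outer(1:100 - 8, rep(1, 100)); xx <- outer(rep(1, 100), 1:100 - 90)
  img <- img + 0.4 * exp(-(yy^2 + xx^2) / (2 * 2^2))
  rec2 <- extract_pvm_salient(img, 64, "normal")
  expect_identical(dim(rec2$crop), c(64L, 64L))
  expect_lte(abs(rec2$center[1] - 8), 3)
  expect_lte(abs(rec2$center[2] - 90), 3)

  expect_error(extract_pvm_salient(matrix(0.5, 40, 40), 64),
               class = "mammetamer_input_error")
})

test_that("cohort extraction routes classes to the right provenance and crop size", {
  # fuzz over seeded phantoms: every returned crop is exactly w x w
  for (rep in 1:25) {
    coh <- generate_cohort(2, 64, 700 + rep) # 8 phantoms per replicate
    res <- extract_cohort_pvms(coh, 32)
    for (rec in res$records) {
      expect_identical(dim(rec$crop), c(32L, 32L))
      if (rec$class_label == "normal") expect_equal(rec$provenance, "saliency")
      else expect_equal(rec$provenance, "roi")
    }
    # all normals must yield a record (clamped saliency crops always fit)
    norm_rows <- res$manifest[res$manifest$class_label == "normal", ]
    expect_true(all(norm_rows$status == "ok"))
    # non-normal skips can only come from the stated rules
    skips <- res$manifest[res$manifest$status == "skip", ]
    expect_true(all(skips$reason %in%
      c("multiple_rois", "out_of_bounds", "roi_outside_square")))
  }
})
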