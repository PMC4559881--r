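# a tiny solid-colour image from stain amounts, shared by several tests
stain_patch <- function(h_amt, d_amt, nr = 8, nc = 8) {
  stains <- rbind(h = c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2)),
                  d = c(0.268, 0.570, 0.776) / sqrt(sum(c(0.268, 0.570, 0.776)^2)))
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3)
    img[, , ch] <- 10^(-(h_amt * stains["h", ch] + d_amt * stains["d", ch]))
  img
}

test_that("colour deconvolution separates the stain basis", {
  # pure DAB pixel: DAB channel carries (essentially all of) the OD
  pure_d <- color_deconvolve(stain_patch(0, 1))
  expect_true(all(pure_d$dab >= 0.95 * (pure_d$dab + pure_d$hematoxylin)))
  expect_equal(mean(pure_d$dab), 1, tolerance = 1e-6)

  # white pixels: both channels zero
  white <- color_deconvolve(array(1, c(4, 4, 3)))
  expect_equal(max(white$dab), 0)
  expect_equal(max(white$hematoxylin), 0)

  # saturated black pixels: finite, never NaN
  black <- color_deconvolve(array(0, c(4, 4, 3)))
  expect_true(all(is.finite(black$dab)) && all(is.finite(black$hematoxylin)))

  # two-stain mixture: recombining the amounts reproduces the OD image
  mix <- stain_patch(0.4, 0.7)
  dec <- color_deconvolve(mix)
  stains <- amyloidpkpd:::hdab_stain_vectors()
  recon <- array(0, dim(mix))
  for (ch in 1:3)
    recon[, , ch] <- dec$amounts[, , 1] * stains["hematoxylin", ch] +
                     dec$amounts[, , 2] * stains["dab", ch] +
                     dec$amounts[, , 3] * stains["residual", ch]
  expect_equal(recon, -log10(mix), tolerance = 1e-3)
})

test_that("nuclei detection: blank channel, planted disks, fixture F1", {
  blank <- detect_nuclei(matrix(0, 64, 64))
  expect_equal(blank$n, 0)
  expect_false(any(blank$mask))

  g <- gen_section_image(n_large = 0, n_small = 0, n_granules = 0,
                         n_nuclei = 50, dims = c(512, 512), seed = 1)
  dec <- color_deconvolve(g$image)
  nuc <- detect_nuclei(dec$hematoxylin)
  expect_equal(nuc$n, 50)

  # standard fixture, seed 0: pixelwise F1 of the nuclei mask >= 0.9
  gs <- gen_section_image(seed = 0)
  nd <- detect_nuclei(color_deconvolve(gs$image)$hematoxylin)
  tp <- sum(nd$mask & gs$truth$nuclei_mask)
  f1 <- 2 * tp / (sum(nd$mask) + sum(gs$truth$nuclei_mask))
  expect_gte(f1, 0.9)
})

test_that("deposit segmentation rejects granules and recovers pixel sets", {
  blank <- segment_deposits(matrix(0, 128, 128))
  expect_equal(nrow(blank$objects), 0)

  # planted disks of ~10/100/500/1500 px: the 10 px disk is rejected
  dab <- matrix(0, 256, 256)
  centres <- list(c(40, 40), c(40, 200), c(128, 128), c(210, 60))
  areas <- c(10, 100, 500, 1500)
  for (i in 1:4) {
    px <- amyloidpkpd:::disk_pixels(centres[[i]][1], centres[[i]][2],
                                    areas[i], 256, 256)
    dab[px] <- 1
  }
  seg <- segment_deposits(dab)
  expect_equal(nrow(seg$objects), 3)
  expect_equal(seg$n_rejected, 1)
  expect_true(all(sort(seg$objects$area_px) > 25))

  # noiseless fixture: recovered pixel sets equal the planted masks
  g <- gen_section_image(n_large = 3, n_small = 6, n_granules = 10,
                         n_nuclei = 20, dims = c(512, 512), seed = 3)
  dec <- color_deconvolve(g$image)
  nuc <- detect_nuclei(dec$hematoxylin)
  seg2 <- segment_deposits(dec$dab, nuc$exclusion)
  truth_retained <- g$truth$deposit_labels %in%
    g$truth$deposits$id[g$truth$deposits$category != "granule"]
  expect_equal(unname(seg2$labels > 0), matrix(truth_retained, 512, 512))
})

test_that("size classification follows the printed category rules", {
  nuc_mask <- matrix(FALSE, 300, 300)
  nuc_mask[amyloidpkpd:::disk_pixels(150, 40, 100, 300, 300)] <- TRUE

  dab <- matrix(0, 300, 300)
  dab[amyloidpkpd:::disk_pixels(60, 220, 1500, 300, 300)] <- 1   # large
  dab[amyloidpkpd:::disk_pixels(220, 220, 500, 300, 300)] <- 1   # small, far
  # nucleus r ~ 5.6 px, deposit r ~ 9.8 px: centre distance 19 px leaves a
  # ~3.6 px boundary gap, inside the 5 px nuclear vicinity
  dab[amyloidpkpd:::disk_pixels(150, 59, 300, 300, 300)] <- 1    # next to nucleus
  seg <- segment_deposits(dab)
  obj <- classify_deposits(seg, nuc_mask)
  obj <- obj[order(obj$area_px), ]
  expect_equal(obj$category, c("intracellular", "small_plaque", "large_plaque"))
  expect_true(obj$near_nucleus[1])

  # categories partition all retained objects
  g <- gen_section_image(n_intracellular = 5, seed = 6)
  q <- quantify_section(g$image, g$roi_mask)
  expect_equal(sum(q$counts), nrow(q$objects))
  expect_true(all(q$objects$category %in%
                  c("intracellular", "small_plaque", "large_plaque")))
  total_components <- sum(q$counts) + q$n_rejected
  expect_equal(total_components,
               nrow(g$truth$deposits))   # rejected + retained = planted
})

test_that("area fraction: exact fractions, invariances, empty ROI", {
  half <- matrix(0L, 10, 10); half[, 1:5] <- 1L
  roi <- matrix(TRUE, 10, 10)
  expect_equal(area_fraction(half, roi), 50)
  expect_equal(area_fraction(matrix(0L, 10, 10), roi), 0)
  expect_error(area_fraction(half, matrix(FALSE, 10, 10)), "empty ROI")

  # translation and 90-degree rotation of image + ROI leave it unchanged
  g <- gen_section_image(n_large = 2, n_small = 5, n_granules = 5,
                         n_nuclei = 10, dims = c(384, 384), seed = 8)
  q <- quantify_section(g$image, g$roi_mask)
  rot_img <- array(0, c(384, 384, 3))
  for (ch in 1:3) rot_img[, , ch] <- t(g$image[384:1, , ch])
  q_rot <- quantify_section(rot_img, g$roi_mask)
  expect_equal(q_rot$area_fraction_pct, q$area_fraction_pct)
  expect_equal(sort(q_rot$objects$area_px), sort(q$objects$area_px))
})

test_that("glia cluster counting: blank, planted truth, scale invariance", {
  roi <- matrix(TRUE, 128, 128)
  expect_equal(count_glia_clusters(matrix(0.2, 128, 128), roi), 0L)

  g <- gen_section_image(n_glia = c(gfap = 12, iba1 = 7), seed = 5)
  expect_equal(count_glia_clusters(g$gfap, g$roi_mask), 12L)
  expect_equal(count_glia_clusters(g$iba1, g$roi_mask), 7L)
  # positive rescaling leaves the count unchanged
  expect_equal(count_glia_clusters(g$gfap * 37.5, g$roi_mask), 12L)
})

test_that("pathology correlation: exact fit, formula oracle, permutation null", {
  x <- c(0.1, 0.3, 0.5, 0.8, 1.2)
  y <- 3 + 20 * x
  r <- correlate_pathology(x, y)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$slope, 20, tolerance = 1e-10)
  expect_equal(r$intercept, 3, tolerance = 1e-10)

  set.seed(1)
  xr <- runif(12); yr <- 2 * xr + rnorm(12, 0, 0.3)
  rr <- correlate_pathology(xr, yr)
  expect_equal(rr$r2, oracle_r2(xr, yr), tolerance = 1e-12)
  expect_true(all(rr$ci_band$lwr <= rr$ci_band$fit &
                  rr$ci_band$fit <= rr$ci_band$upr))

  # shuffled pairs: r2 collapses to the 1/(n-1) null scale
  set.seed(0)
  n <- 12
  null_r2 <- replicate(30, {
    correlate_pathology(runif(n), sample(yr, n, replace = TRUE))$r2
  })
  expect_lt(median(null_r2), 5 / (n - 1))

  expect_error(correlate_pathology(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate_pathology(1:2, 1:2), "at least 3")
})
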