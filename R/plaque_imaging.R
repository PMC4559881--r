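#' @title H-DAB plaque and glia-cluster quantification
#' @description Brightfield immunohistochemistry quantification: optical
#'   density colour deconvolution of hematoxylin/DAB stains, nuclei
#'   detection with an exclusion zone, adaptive thresholding of DAB
#'   deposits, rejection of sub-threshold granules, three-way size
#'   classification (intracellular / small plaque / large plaque), ROI
#'   area fraction, fluorescence glia-cluster counting and the
#'   plaque-load-versus-glia correlation. Images are plain R arrays
#'   indexed `[row, col(, channel)]`, intensities in `[0, 1]` (8-bit input
#'   is rescaled on entry).
#' @name plaque_imaging
NULL

# standard H-DAB stain OD vectors (unit length, RGB order)
hdab_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  h <- h / sqrt(sum(h^2)); d <- d / sqrt(sum(d^2))
  r <- c(h[2] * d[3] - h[3] * d[2],   # residual = h x d, completes the basis
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  rbind(hematoxylin = h, dab = d, residual = r / sqrt(sum(r^2)))
}

as_rgb01 <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L)
    stop("expected an RGB image array [row, col, channel]")
  img <- image[, , 1:3, drop = FALSE]
  if (max(img) > 1) img <- img / 255
  img
}

#' Colour deconvolution of an H-DAB brightfield image
#'
#' Converts RGB transmitted intensity to optical density
#' (`OD = -log10(I)`, intensities clipped to at least 1/255 so saturated
#' black pixels yield a finite OD, never NaN) and projects each pixel onto
#' the hematoxylin and DAB stain vectors by inverting the stain matrix.
#' Negative stain amounts (off-basis noise) are clipped to 0.
#'
#' @param image RGB array `[row, col, 3]`, values in `[0, 1]` or 8-bit.
#' @param stains 3x3 stain matrix (rows = unit OD vectors); defaults to
#'   the standard hematoxylin/DAB basis completed by their cross product.
#' @return List with matrices `hematoxylin` and `dab` (per-pixel stain
#'   amounts, OD units) and the full `amounts` array.
#' @export
color_deconvolve <- function(image, stains = hdab_stain_vectors()) {
  img <- as_rgb01(image)
  od <- -log10(pmax(img, 1 / 255))
  dm <- dim(od)
  odm <- matrix(od, ncol = 3L)           # pixels x RGB
  amounts <- odm %*% solve(stains)       # pixels x stains
  amounts[amounts < 0] <- 0
  out <- array(amounts, c(dm[1L], dm[2L], 3L))
  list(hematoxylin = out[, , 1L], dab = out[, , 2L], amounts = out)
}

# Otsu threshold of a numeric vector (256-bin histogram over its range)
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(Inf)   # constant: nothing above
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1L]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1L] + k / nbins * diff(r)
}

# 8-connected labelling: 4-connected bwlabel plus a diagonal merge pass
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),     # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))     # up-right
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(n)
  findroot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- findroot(pairs[k, 1L]); b <- findroot(pairs[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), findroot, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0
}

#' Detect nuclei in the hematoxylin channel
#'
#' Thresholds the hematoxylin OD channel (Otsu by default), fills holes,
#' removes components below a minimum size, and returns both the nuclei
#' mask and its dilated exclusion zone (the "nuclear vicinity" within
#' which brown objects are not counted as free plaques). A blank channel
#' yields an empty mask, not an error.
#'
#' @param hematoxylin_od Matrix of hematoxylin stain amounts.
#' @param threshold OD cutoff; default Otsu on the channel.
#' @param min_size Minimum nucleus area in pixels (default 20).
#' @param vicinity Dilation radius in pixels for the exclusion zone
#'   (default 5).
#' @return List with logical matrices `mask` and `exclusion`, and `n`
#'   (number of detected nuclei).
#' @export
detect_nuclei <- function(hematoxylin_od, threshold = NULL,
                          min_size = 20L, vicinity = 5L) {
  if (is.null(threshold)) threshold <- otsu_threshold(as.vector(hematoxylin_od))
  mask <- hematoxylin_od > threshold
  if (!any(mask))
    return(list(mask = mask, exclusion = mask, n = 0L))
  mask <- EBImage::fillHull(mask * 1) > 0
  lab <- label8(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_size)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  list(mask = mask, exclusion = dilate_mask(mask, vicinity),
       n = length(keep))
}

#' Segment DAB-stained deposits by adaptive thresholding
#'
#' Local mean-offset thresholding of the DAB OD channel (boxcar window,
#' default 101 px): a pixel is foreground where its OD exceeds the local
#' mean by more than `offset`. Pixels inside the nuclei exclusion zone are
#' removed from the candidates before labelling, components are labelled
#' with 8-connectivity, and objects smaller than `min_area` px are
#' rejected as unspecific granules.
#'
#' @param dab_od Matrix of DAB stain amounts.
#' @param nuclei_exclusion Optional logical matrix (from
#'   [detect_nuclei()]) of pixels to exclude.
#' @param window Odd boxcar side length in pixels (default 101).
#' @param offset OD offset above the local mean (default 0.1).
#' @param min_area Granule rejection floor in pixels (default 25).
#' @return List with `labels` (integer matrix, 0 = background),
#'   `objects` (data frame: `label`, `area_px`, `centroid_row`,
#'   `centroid_col`) and `n_rejected` (granules removed).
#' @export
segment_deposits <- function(dab_od, nuclei_exclusion = NULL,
                             window = 101L, offset = 0.1, min_area = 25L) {
  if (window %% 2L == 0L) stop("`window` must be odd")
  kern <- matrix(1 / window^2, window, window)
  local_mean <- EBImage::filter2(dab_od, kern)
  mask <- dab_od > local_mean + offset
  if (!is.null(nuclei_exclusion)) mask <- mask & !nuclei_exclusion
  lab <- label8(mask)
  n_all <- max(lab)
  if (n_all == 0L)
    return(list(labels = lab,
                objects = data.frame(label = integer(), area_px = integer(),
                                     centroid_row = numeric(),
                                     centroid_col = numeric()),
                n_rejected = 0L))
  areas <- tabulate(lab[lab > 0L], n_all)
  keep <- which(areas >= min_area)
  lab[!(lab %in% keep)] <- 0L
  remap <- match(lab[lab > 0L], keep)
  lab[lab > 0L] <- remap
  idx <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[lab > 0L]
  objects <- data.frame(
    label = seq_along(keep),
    area_px = as.integer(areas[keep]),
    centroid_row = as.numeric(tapply(idx[, 1L], lv, mean)),
    centroid_col = as.numeric(tapply(idx[, 2L], lv, mean)))
  list(labels = lab, objects = objects,
       n_rejected = n_all - length(keep))
}

#' Classify segmented deposits into the three size categories
#'
#' Applies, in order: intracellular if the area lies in `[25, 200]` px or
#' the object touches the nuclear vicinity (nuclei mask dilated by
#' `vicinity` px); large plaque if the area exceeds 1000 px; small plaque
#' for areas in `(200, 1000]` px sufficiently detached from nuclei. Both
#' class bounds are closed on the upper end (an area of exactly 200 px is
#' intracellular, exactly 1000 px a small plaque).
#'
#' @param segmentation Result of [segment_deposits()].
#' @param nuclei_mask Logical nuclei matrix (un-dilated).
#' @param vicinity Nuclear vicinity radius in pixels (default 5).
#' @return The `objects` data frame with `near_nucleus` and `category`
#'   (`"intracellular"`, `"small_plaque"`, `"large_plaque"`) columns.
#' @export
classify_deposits <- function(segmentation, nuclei_mask, vicinity = 5L) {
  objects <- segmentation$objects
  lab <- segmentation$labels
  if (nrow(objects) == 0L) {
    objects$near_nucleus <- logical()
    objects$category <- character()
    return(objects)
  }
  zone <- dilate_mask(nuclei_mask, vicinity)
  overlap <- lab[zone & lab > 0L]
  objects$near_nucleus <- objects$label %in% unique(overlap)
  a <- objects$area_px
  objects$category <- ifelse(
    (a >= 25 & a <= 200) | objects$near_nucleus, "intracellular",
    ifelse(a > 1000, "large_plaque", "small_plaque"))
  objects
}

#' Percent of the ROI covered by classified deposits
#'
#' @param labels Integer label matrix from [segment_deposits()] (or any
#'   mask; non-zero pixels count as deposit).
#' @param roi_mask Logical matrix, same shape, with at least one `TRUE`
#'   pixel.
#' @return `100 * deposit pixels within ROI / ROI pixels`.
#' @export
area_fraction <- function(labels, roi_mask) {
  if (!any(roi_mask)) stop("empty ROI")
  if (!all(dim(labels) == dim(roi_mask))) stop("shape mismatch")
  100 * sum(labels > 0 & roi_mask) / sum(roi_mask)
}

#' Count glia clusters in a single-channel fluorescence image
#'
#' Otsu threshold computed from the ROI pixels only, 8-connected
#' labelling, and a minimum cluster area. The count is invariant to
#' rescaling the intensities by a positive constant because the threshold
#' is derived from the image's own histogram. A blank (constant) channel
#' returns 0.
#'
#' @param channel_image Numeric matrix (any positive scale).
#' @param roi_mask Logical matrix, same shape, non-empty.
#' @param min_area_px Minimum cluster area in pixels (default 20).
#' @return Integer cluster count.
#' @export
count_glia_clusters <- function(channel_image, roi_mask = NULL,
                                min_area_px = 20L) {
  if (is.null(roi_mask))
    roi_mask <- matrix(TRUE, nrow(channel_image), ncol(channel_image))
  if (!any(roi_mask)) stop("empty ROI")
  thr <- otsu_threshold(channel_image[roi_mask])
  mask <- channel_image > thr & roi_mask
  if (!any(mask)) return(0L)
  lab <- label8(mask)
  areas <- tabulate(lab[lab > 0L])
  sum(areas >= min_area_px)
}

#' Correlate plaque burden with glia-cluster counts across animals
#'
#' Pearson correlation with a least-squares line and a pointwise 95 %
#' confidence band, the standard presentation for pathology-versus-
#' inflammation scatter plots.
#'
#' @param x Per-animal plaque area fractions (percent).
#' @param y Per-animal glia cluster counts.
#' @param band_points Number of grid points for the confidence band.
#' @return List: `r2`, `p` (two-sided), `slope`, `intercept`, `ci_band`
#'   (data frame `x`, `fit`, `lwr`, `upr`), `n`.
#' @export
correlate_pathology <- function(x, y, band_points = 50L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  grid <- data.frame(x = seq(min(x), max(x), length.out = band_points))
  band <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = 0.95)
  list(r2 = unname(ct$estimate)^2, p = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       ci_band = data.frame(x = grid$x, fit = band[, "fit"],
                            lwr = band[, "lwr"], upr = band[, "upr"]),
       n = length(x))
}

#' Quantify one stained section end to end
#'
#' Runs colour deconvolution, nuclei detection, adaptive deposit
#' segmentation, granule rejection, size classification and ROI area
#' fraction in sequence, returning the per-section summary used for group
#' comparisons.
#'
#' @param image RGB array `[row, col, 3]`.
#' @param roi_mask Logical matrix; defaults to the whole frame.
#' @param vicinity Nuclear vicinity radius (px).
#' @param window,offset Adaptive threshold parameters
#'   (see [segment_deposits()]).
#' @param min_area Granule rejection floor (px).
#' @return A `section_quant` list: `area_fraction_pct`, `counts` (named:
#'   intracellular, small_plaque, large_plaque), `objects` data frame,
#'   `n_nuclei`, `n_rejected`, `labels`.
#' @export
quantify_section <- function(image, roi_mask = NULL, vicinity = 5L,
                             window = 101L, offset = 0.1, min_area = 25L) {
  img <- as_rgb01(image)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dim(img)[1L], dim(img)[2L])
  decon <- color_deconvolve(img)
  nuc <- detect_nuclei(decon$hematoxylin, vicinity = vicinity)
  seg <- segment_deposits(decon$dab, nuclei_exclusion = nuc$exclusion,
                          window = window, offset = offset,
                          min_area = min_area)
  objects <- classify_deposits(seg, nuc$mask, vicinity = vicinity)
  counts <- vapply(c("intracellular", "small_plaque", "large_plaque"),
                   function(k) sum(objects$category == k), integer(1))
  structure(
    list(area_fraction_pct = area_fraction(seg$labels, roi_mask),
         counts = counts, objects = objects,
         n_nuclei = nuc$n, n_rejected = seg$n_rejected,
         labels = seg$labels),
    class = "section_quant")
}

#' @export
print.section_quant <- function(x, ...) {
  cat(sprintf(
    "<section_quant> area fraction %.3f %%; intracellular %d, small %d, large %d (%d nuclei, %d granules rejected)\n",
    x$area_fraction_pct, x$counts[["intracellular"]],
    x$counts[["small_plaque"]], x$counts[["large_plaque"]],
    x$n_nuclei, x$n_rejected))
  invisible(x)
}
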