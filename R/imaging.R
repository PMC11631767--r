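## Co-localization coefficients and puncta morphometry. Connected components
## use 8-connectivity; perimeters use the 4-direction Crofton estimator, so
## circularity 4*pi*A/P^2 of digitized disks approaches 1 with radius.

#' Pearson co-localization coefficient
#'
#' Sample correlation of the two channels' pixel intensities over a mask.
#'
#' @param channel_a,channel_b Numeric matrices of identical shape.
#' @param mask Optional logical matrix restricting the pixels used.
#' @return Correlation in [-1, 1]; `NA` with attribute `flagged = TRUE`
#'   (and a warning) when either channel has zero variance in the mask.
#' @export
pearson_coloc <- function(channel_a, channel_b, mask = NULL) {
  stopifnot(is.matrix(channel_a), is.matrix(channel_b),
            identical(dim(channel_a), dim(channel_b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  stopifnot(identical(dim(mask), dim(channel_a)))
  if (!any(mask)) stop("mask is empty")
  a <- channel_a[mask]; b <- channel_b[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a channel; Pearson coefficient undefined")
    return(structure(NA_real_, flagged = TRUE))
  }
  stats::cor(a, b)
}

#' Manders overlap coefficients
#'
#' `M1` is the fraction of channel-A intensity residing in pixels where
#' channel B is above its threshold; `M2` is the symmetric quantity.
#' Default thresholds are Otsu per channel within the mask.
#'
#' @inheritParams pearson_coloc
#' @param thresholds Optional numeric `c(t_a, t_b)`; pixels strictly above
#'   threshold count as supra-threshold.
#' @return List with `M1`, `M2` (each in [0, 1]) and `thresholds`; `NA`
#'   components flagged when a channel has zero total intensity.
#' @export
manders_coloc <- function(channel_a, channel_b, mask = NULL, thresholds = NULL) {
  stopifnot(is.matrix(channel_a), is.matrix(channel_b),
            identical(dim(channel_a), dim(channel_b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  if (!any(mask)) stop("mask is empty")
  a <- channel_a[mask]; b <- channel_b[mask]
  if (is.null(thresholds)) {
    thresholds <- c(otsu_threshold(a), otsu_threshold(b))
  }
  stopifnot(length(thresholds) == 2L, all(thresholds >= 0))
  sa <- sum(a); sb <- sum(b)
  M1 <- if (sa > 0) sum(a[b > thresholds[2]]) / sa else {
    warning("channel A has zero total intensity"); structure(NA_real_, flagged = TRUE)
  }
  M2 <- if (sb > 0) sum(b[a > thresholds[1]]) / sb else {
    warning("channel B has zero total intensity"); structure(NA_real_, flagged = TRUE)
  }
  list(M1 = M1, M2 = M2, thresholds = thresholds)
}

#' Otsu threshold of an intensity sample
#'
#' Thin wrapper around `EBImage::otsu()` operating on any numeric sample
#' (values are histogrammed over their own range).
#'
#' @param x Numeric vector or matrix of intensities.
#' @param levels Histogram levels (default 256).
#' @return Threshold on the original intensity scale.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(matrix(v, nrow = 1), range = rng, levels = levels)
}

#' Label connected components (8-connectivity)
#'
#' Iterative minimum-label propagation over the 8-neighborhood. Diagonal
#' contacts join components, matching the particle-analysis convention.
#'
#' @param mask Logical matrix of foreground pixels.
#' @return Integer matrix of labels (0 = background, components numbered
#'   from 1 in raster order of their first pixel).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    r_src <- seq_len(nr) - dr; c_src <- seq_len(nc) - dc
    r_ok <- r_src >= 1 & r_src <= nr; c_ok <- c_src >= 1 & c_src <= nc
    out[r_ok, c_ok] <- m[r_src[r_ok], c_src[c_ok]]
    out
  }
  cur <- matrix(Inf, nr, nc)
  cur[mask] <- matrix(seq_len(nr * nc), nr, nc)[mask]  # initial label = linear index
  repeat {
    nxt <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nxt <- pmin(nxt, shift(cur, dr, dc))
    }
    nxt[!mask] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  out <- matrix(0L, nr, nc)
  vals <- cur[mask]
  out[mask] <- as.integer(match(vals, sort(unique(vals))))
  out
}

## 4-direction Crofton perimeter of a binary mask, in pixel units.
## Histogram of 2x2 neighborhood configurations of the zero-padded mask,
## weighted by the standard integral-geometry LUT.
.crofton_coefs <- {
  s2 <- sqrt(2)
  c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
    0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
    pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
    pi / 4, pi / 2, 0, 0)
}

#' Crofton perimeter of a binary mask
#'
#' Integral-geometry perimeter estimate from 2x2 pixel configuration
#' counts using four line directions; unbiased for smooth shapes, unlike
#' raw boundary-pixel counting.
#'
#' @param mask Logical matrix (the object is `TRUE`).
#' @return Perimeter in pixel units.
#' @export
crofton_perimeter <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(0L, nr + 2L, nc + 2L)
  P[2:(nr + 1), 2:(nc + 1)] <- mask * 1L
  ## 2x2 window at (i, j): current, left, up, up-left
  i <- 2:(nr + 2); j <- 2:(nc + 2)
  code <- P[i, j] + 4L * P[i, j - 1L] + 2L * P[i - 1L, j] + 8L * P[i - 1L, j - 1L]
  h <- tabulate(as.vector(code) + 1L, nbins = 16L)
  sum(.crofton_coefs * h)
}

#' Detect puncta with circularity and size filters
#'
#' Threshold (Otsu by default, within an optional cell mask), label
#' 8-connected components, and retain those with circularity strictly
#' above `min_circularity` and area strictly above `min_area_um2`.
#' Circularity is `4*pi*area/perimeter^2` with the Crofton perimeter.
#'
#' @param image Numeric intensity matrix.
#' @param pixel_size_um Microns per pixel (> 0).
#' @param threshold Numeric threshold; pixels strictly above are
#'   foreground. If `NULL`, Otsu's method is used.
#' @param mask Optional logical cell mask restricting detection and the
#'   Otsu sample.
#' @param min_area_um2 Area cutoff in square microns (default 1).
#' @param min_circularity Circularity cutoff (default 0.5).
#' @param ratio_field Optional numeric matrix; per-component mean ratio is
#'   reported from it.
#' @return An object of class `puncta_set`: `components` (all components
#'   with `label`, `area_um2`, `perimeter_um`, `circularity`, centroid,
#'   `mean_ratio`, `retained`), `labels` (label matrix of retained puncta),
#'   `threshold`, `method`, `n_retained`.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[(row(img) - 32)^2 + (col(img) - 32)^2 <= 8^2] <- 1
#' detect_puncta(img, pixel_size_um = 0.2)$n_retained # one 1.6-um-radius disk
#' @export
detect_puncta <- function(image, pixel_size_um, threshold = NULL, mask = NULL,
                          min_area_um2 = 1.0, min_circularity = 0.5,
                          ratio_field = NULL) {
  stopifnot(is.matrix(image), is.numeric(pixel_size_um), pixel_size_um > 0)
  method <- if (is.null(threshold)) "otsu" else "manual"
  sample_px <- if (is.null(mask)) image else image[mask]
  if (is.null(threshold)) threshold <- otsu_threshold(sample_px)
  fg <- image > threshold
  if (!is.null(mask)) fg <- fg & mask
  lab <- label_components(fg)
  n <- max(lab)
  comp <- data.frame(label = integer(0), area_um2 = numeric(0),
                     perimeter_um = numeric(0), circularity = numeric(0),
                     centroid_row = numeric(0), centroid_col = numeric(0),
                     mean_ratio = numeric(0), retained = logical(0))
  if (n > 0) {
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      m <- lab == k
      area <- sum(m) * pixel_size_um^2
      per <- crofton_perimeter(m) * pixel_size_um
      circ <- if (per > 0) 4 * pi * area / per^2 else NA_real_
      rows[[k]] <- data.frame(
        label = k, area_um2 = area, perimeter_um = per, circularity = circ,
        centroid_row = mean(row(m)[m]), centroid_col = mean(col(m)[m]),
        mean_ratio = if (is.null(ratio_field)) NA_real_ else mean(ratio_field[m]),
        retained = is.finite(circ) && circ > min_circularity && area > min_area_um2)
    }
    comp <- do.call(rbind, rows)
  }
  keep_lab <- lab
  keep_lab[!(lab %in% comp$label[comp$retained])] <- 0L
  structure(list(components = comp, labels = keep_lab, threshold = threshold,
                 method = method, n_retained = sum(comp$retained),
                 pixel_size_um = pixel_size_um),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf(
    "Puncta set: %d/%d components retained (circularity > 0.5, area > 1 um^2)\n",
    x$n_retained, nrow(x$components)))
  cat(sprintf("  threshold %.4g (%s), pixel size %.3g um\n",
              x$threshold, x$method, x$pixel_size_um))
  invisible(x)
}

#' Ratio statistics in punctate versus diffuse regions
#'
#' @param ratio_field Numeric matrix of pixel-wise ratios.
#' @param puncta_mask Logical matrix of punctate pixels (or a label matrix;
#'   nonzero = puncta). Must lie within `cell_mask`.
#' @param cell_mask Logical matrix of the analyzed cell.
#' @return List with `mean_ratio_puncta`, `mean_ratio_diffuse` (`NA` and
#'   flagged when the diffuse region is empty), and `per_punctum` means
#'   when a label matrix was supplied.
#' @export
region_ratio_stats <- function(ratio_field, puncta_mask, cell_mask) {
  stopifnot(is.matrix(ratio_field), identical(dim(ratio_field), dim(cell_mask)))
  labels <- NULL
  if (is.numeric(puncta_mask) || is.integer(puncta_mask)) {
    labels <- puncta_mask
    puncta_mask <- puncta_mask > 0
  }
  stopifnot(is.logical(puncta_mask), is.logical(cell_mask))
  if (any(puncta_mask & !cell_mask)) stop("puncta_mask must lie within cell_mask")
  diffuse <- cell_mask & !puncta_mask
  mp <- if (any(puncta_mask)) mean(ratio_field[puncta_mask]) else NA_real_
  md <- if (any(diffuse)) mean(ratio_field[diffuse]) else {
    warning("diffuse region is empty")
    structure(NA_real_, flagged = TRUE)
  }
  per <- NULL
  if (!is.null(labels) && max(labels) > 0) {
    per <- vapply(seq_len(max(labels)), function(k) {
      px <- labels == k
      if (any(px)) mean(ratio_field[px]) else NA_real_
    }, numeric(1))
  }
  list(mean_ratio_puncta = mp, mean_ratio_diffuse = md, per_punctum = per)
}
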