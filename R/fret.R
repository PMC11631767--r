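## Ratiometric FRET quantification. A channel stack holds time-ordered 2-D
## frames per named channel; traces are per-cell ratio timecourses anchored
## at the frame immediately preceding stimulation.

#' Multi-channel fluorescence image stack
#'
#' @param channels Named list of 3-D numeric arrays `[rows, cols, frames]`.
#'   Conventional names: `donor` (donor excitation/emission), `fret`
#'   (donor excitation, acceptor emission), `acceptor` (direct acceptor).
#' @param pixel_size_um Microns per pixel (> 0).
#' @param stim_frame 1-based index of the first post-stimulus frame.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = 1, stim_frame = 2L) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3L)) {
    stop("each channel must be a 3-D array [rows, cols, frames]")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all channels must share the same dimensions")
  }
  nf <- dims[[1]][3]
  stopifnot(stim_frame >= 2L, stim_frame <= nf)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 stim_frame = as.integer(stim_frame)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Channel stack: %dx%d px, %d frames, channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel size %.3g um, stimulus at frame %d\n",
              x$pixel_size_um, x$stim_frame))
  invisible(x)
}

#' Region of interest over the frame grid
#'
#' @param mask Logical matrix matching the frame shape; must be non-empty.
#' @param kind `"cell"` or `"background"` (background ROIs must be cell-free).
#' @param label Identifier.
#' @return An object of class `roi`.
#' @export
make_roi <- function(mask, kind = c("cell", "background"), label = "roi") {
  kind <- match.arg(kind)
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(mask = mask, kind = kind, label = label), class = "roi")
}

#' Subtract cell-free background from every frame and channel
#'
#' Subtracts the per-frame, per-channel mean intensity of a cell-free
#' region. Values may go slightly negative after subtraction; they are kept
#' as-is for ratio computation (negative denominators are flagged
#' downstream, not clipped).
#'
#' @param stack A [channel_stack()].
#' @param bg_roi An [make_roi()] of kind `"background"`.
#' @return A background-subtracted `channel_stack`.
#' @export
background_subtract <- function(stack, bg_roi) {
  stopifnot(inherits(stack, "channel_stack"), inherits(bg_roi, "roi"))
  if (bg_roi$kind != "background") stop("bg_roi must have kind 'background'")
  out <- stack
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    for (t in seq_len(dim(arr)[3])) {
      fr <- arr[, , t]
      arr[, , t] <- fr - mean(fr[bg_roi$mask])
    }
    out$channels[[ch]] <- arr
  }
  out
}

#' Per-cell FRET ratio timecourse
#'
#' Computes the raw ratio `R_t` as the mean FRET-channel intensity within
#' the ROI divided by the mean donor-channel intensity, per frame, on a
#' background-subtracted stack. The basal ratio `R0` is the ratio at the
#' frame immediately preceding stimulation.
#'
#' @param stack Background-subtracted [channel_stack()].
#' @param cell_roi An [make_roi()] of kind `"cell"`.
#' @param numerator,denominator Channel names forming the ratio
#'   (default FRET / donor, the yellow-over-cyan orientation; swap to
#'   invert).
#' @return An object of class `fret_trace`: `R` (per-frame ratio, `NA`
#'   where the denominator mean was non-positive), `R0`, `stim_frame`,
#'   `n_undefined`, `label`.
#' @export
ratio_trace <- function(stack, cell_roi, numerator = "fret", denominator = "donor") {
  stopifnot(inherits(stack, "channel_stack"), inherits(cell_roi, "roi"))
  if (cell_roi$kind != "cell") stop("cell_roi must have kind 'cell'")
  stopifnot(numerator %in% names(stack$channels),
            denominator %in% names(stack$channels))
  num <- stack$channels[[numerator]]
  den <- stack$channels[[denominator]]
  nf <- dim(num)[3]
  R <- numeric(nf)
  for (t in seq_len(nf)) {
    d <- mean(den[, , t][cell_roi$mask])
    R[t] <- if (d <= 0) NA_real_ else mean(num[, , t][cell_roi$mask]) / d
  }
  n_undef <- sum(is.na(R))
  if (n_undef > 0.2 * nf) {
    stop(sprintf("ratio undefined in %d/%d frames (> 20%%)", n_undef, nf))
  }
  anchor <- stack$stim_frame - 1L
  structure(list(R = R, R0 = R[anchor], stim_frame = stack$stim_frame,
                 n_undefined = n_undef, label = cell_roi$label),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("FRET trace '%s': %d frames, R0 = %.4g, R range %.4g..%.4g\n",
              x$label, length(x$R), x$R0,
              min(x$R, na.rm = TRUE), max(x$R, na.rm = TRUE)))
  invisible(x)
}

#' Normalize a set of FRET traces
#'
#' Three normalizations used for biosensor timecourses:
#' * `"r0"` — each trace divided by its own basal ratio (`R/R0`); the
#'   anchor frame maps exactly to 1.
#' * `"minmax"` — the pooled dataset's lowest and highest ratios map to
#'   0 and 1.
#' * `"ref_min"` — the dataset is shifted so the pooled minimum (attained
#'   in the reference condition, i.e. the condition with the largest
#'   decrease) maps to 0; all values become non-negative.
#'
#' @param traces List of [ratio_trace()] outputs.
#' @param mode One of `"r0"`, `"minmax"`, `"ref_min"`.
#' @param conditions Optional character vector (one per trace) used by
#'   `"ref_min"` to report which condition attains the dataset minimum.
#' @return The list of traces, each with `normalized` values and
#'   `norm_mode` set. For `"ref_min"` the attribute `"reference_condition"`
#'   names the condition attaining the minimum.
#' @export
normalize_traces <- function(traces, mode = c("r0", "minmax", "ref_min"),
                             conditions = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(traces), length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "fret_trace")))
  pooled <- unlist(lapply(traces, `[[`, "R"))
  out <- traces
  if (mode == "r0") {
    for (i in seq_along(out)) {
      out[[i]]$normalized <- out[[i]]$R / out[[i]]$R0
      out[[i]]$norm_mode <- "r0"
    }
  } else if (mode == "minmax") {
    lo <- min(pooled, na.rm = TRUE); hi <- max(pooled, na.rm = TRUE)
    if (hi - lo <= .Machine$double.eps * max(abs(hi), 1)) {
      stop("degenerate dataset range; min-max normalization undefined")
    }
    for (i in seq_along(out)) {
      out[[i]]$normalized <- (out[[i]]$R - lo) / (hi - lo)
      out[[i]]$norm_mode <- "minmax"
    }
  } else {
    lo <- min(pooled, na.rm = TRUE)
    ref <- NA_character_
    if (!is.null(conditions)) {
      stopifnot(length(conditions) == length(traces))
      mins <- vapply(traces, function(tr) min(tr$R, na.rm = TRUE), numeric(1))
      ref <- conditions[which.min(mins)]
    }
    for (i in seq_along(out)) {
      out[[i]]$normalized <- out[[i]]$R - lo
      out[[i]]$norm_mode <- "ref_min"
    }
    attr(out, "reference_condition") <- ref
  }
  out
}

#' Signal-to-noise ratio of a biosensor trace
#'
#' Maximum post-stimulus ratio change (`R_t - R0`) divided by the sample
#' standard deviation of the ratio over a pre-stimulus baseline window.
#'
#' @param trace A [ratio_trace()] output.
#' @param baseline_window Integer frame indices, all pre-stimulus, length
#'   at least 3.
#' @return SNR; `Inf` with attribute `flagged = TRUE` when the baseline is
#'   exactly constant.
#' @export
trace_snr <- function(trace, baseline_window) {
  stopifnot(inherits(trace, "fret_trace"),
            is.numeric(baseline_window), length(baseline_window) >= 3L,
            all(baseline_window >= 1), all(baseline_window < trace$stim_frame))
  s <- stats::sd(trace$R[baseline_window], na.rm = TRUE)
  post <- trace$R[trace$stim_frame:length(trace$R)]
  delta <- max(post - trace$R0, na.rm = TRUE)
  if (s == 0) return(structure(Inf, flagged = TRUE))
  delta / s
}

#' Exclude over-bright cells by the 3-standard-deviation rule
#'
#' Cells whose direct-acceptor intensity exceeds the population mean by
#' strictly more than three standard deviations are excluded (too-bright
#' overexpressors). A cell at exactly mean + 3 s.d. is kept.
#'
#' @param acceptor_intensities Named numeric vector of per-cell mean
#'   direct-acceptor intensities (>= 3 cells for exclusion to apply).
#' @return A list with `kept`, `excluded` (names or indices), `threshold`,
#'   `rule`. With fewer than 3 cells, QC is skipped with a warning.
#' @export
qc_exclude <- function(acceptor_intensities) {
  x <- acceptor_intensities
  ids <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
  if (length(x) < 3L) {
    warning("fewer than 3 cells; brightness QC skipped")
    return(list(kept = ids, excluded = character(0), threshold = NA_real_,
                rule = "skipped (<3 cells)"))
  }
  thr <- mean(x) + 3 * stats::sd(x)
  out <- x > thr  # strict inequality: exactly mean + 3 s.d. is kept
  list(kept = ids[!out], excluded = ids[out], threshold = thr,
       rule = "acceptor intensity > mean + 3 s.d. (strict)")
}

#' Pixel-wise ratio image with pseudocolor rendering
#'
#' Divides a background-subtracted FRET frame by the donor frame pixel by
#' pixel, masking non-positive donor pixels, and renders the ratio with a
#' spectral lookup table for display. The numeric field is returned
#' alongside the rendering.
#'
#' @param fret_frame,donor_frame Numeric matrices of identical shape.
#' @param range Optional display range `c(lo, hi)`; defaults to the finite
#'   ratio range.
#' @param n_colors Colors in the lookup table.
#' @return A list: `ratio` (matrix, `NA` at masked pixels), `n_masked`,
#'   `rgb` (rows x cols x 3 array in [0,1]), `range`.
#' @export
ratio_image <- function(fret_frame, donor_frame, range = NULL, n_colors = 256L) {
  stopifnot(is.matrix(fret_frame), is.matrix(donor_frame))
  if (!identical(dim(fret_frame), dim(donor_frame))) {
    stop("frame shapes differ")
  }
  ratio <- fret_frame / donor_frame
  ratio[donor_frame <= 0] <- NA_real_
  n_masked <- sum(donor_frame <= 0)
  finite <- ratio[is.finite(ratio)]
  if (is.null(range)) {
    range <- if (length(finite)) base::range(finite) else c(0, 1)
  }
  pal <- grDevices::colorRamp(c("black", "blue", "cyan", "green", "yellow",
                                "red", "white"))
  scaled <- (ratio - range[1]) / max(range[2] - range[1], .Machine$double.eps)
  scaled <- pmin(pmax(scaled, 0), 1)
  rgbv <- matrix(0, length(ratio), 3)
  ok <- !is.na(scaled)
  if (any(ok)) rgbv[ok, ] <- pal(scaled[ok]) / 255
  rgb_arr <- array(rgbv, dim = c(dim(ratio), 3))
  list(ratio = ratio, n_masked = n_masked, rgb = rgb_arr, range = range)
}

#' Write a pseudocolored ratio image to PNG
#'
#' @param ri Output of [ratio_image()].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_ratio_png <- function(ri, path) {
  png::writePNG(ri$rgb, path)
  invisible(path)
}

#' Export FRET traces as a tidy CSV table
#'
#' @param traces List of [ratio_trace()] outputs (optionally normalized).
#' @param path CSV path.
#' @param time_step_s Seconds per frame for the `time_s` column.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, time_step_s = 1) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = tr$label, frame = seq_along(tr$R),
               time_s = (seq_along(tr$R) - 1) * time_step_s,
               R = tr$R, R_over_R0 = tr$R / tr$R0,
               normalized = if (is.null(tr$normalized)) NA_real_ else tr$normalized,
               mode = if (is.null(tr$norm_mode)) NA_character_ else tr$norm_mode)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
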