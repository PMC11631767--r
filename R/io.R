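## Plain-text interfaces: YAML/JSON configs for switch parameters and
## mutation libraries, CSV dose-response tables, multi-page TIFF channel
## stacks with a JSON sidecar carrying metadata and the intensity scale.

.read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

.conc_to_molar <- function(x) {
  ## accepts a bare number (molar) or list(value=, unit="nM"|"uM"|"mM"|"M")
  if (is.list(x)) {
    unit <- tolower(x$unit %||% "m")
    mult <- switch(unit, m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9, pm = 1e-12,
                   stop("unknown concentration unit: ", x$unit))
    as.numeric(x$value) * mult
  } else {
    as.numeric(x)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read switch parameters, totals and mutation library from a config file
#'
#' YAML or JSON with top-level keys `params` (`dG_close`, `Kd_key`,
#' `Kd_target`, optional `temperature_K`), optional `totals` (`C_tot`,
#' `K_tot`, `T_tot`) and optional `mutations` (list of `name`,
#' `interface`, `ddG`). Concentrations are molar by default; any
#' concentration may instead be given as `{value: 50, unit: nM}`.
#'
#' @param path Config path (`.yaml`/`.yml`/`.json`).
#' @return List with `params` ([switch_params()]), `totals`
#'   ([switch_totals()] or `NULL`), `mutations` (list of
#'   [mutation_effect()]).
#' @export
read_switch_config <- function(path) {
  cfg <- .read_config(path)
  if (is.null(cfg$params)) stop("config missing 'params' block")
  p <- cfg$params
  params <- switch_params(as.numeric(p$dG_close),
                          .conc_to_molar(p$Kd_key),
                          .conc_to_molar(p$Kd_target),
                          as.numeric(p$temperature_K %||% 298.15))
  totals <- NULL
  if (!is.null(cfg$totals)) {
    totals <- switch_totals(.conc_to_molar(cfg$totals$C_tot),
                            .conc_to_molar(cfg$totals$K_tot),
                            .conc_to_molar(cfg$totals$T_tot %||% 0))
  }
  mutations <- list()
  if (!is.null(cfg$mutations)) {
    ml <- cfg$mutations
    if (is.data.frame(ml)) ml <- split(ml, seq_len(nrow(ml)))
    mutations <- lapply(ml, function(e) {
      mutation_effect(as.character(e$name), as.character(e$interface),
                      as.numeric(e$ddG))
    })
    names(mutations) <- NULL
  }
  list(params = params, totals = totals, mutations = mutations)
}

#' Write a dose-response table to CSV
#'
#' Columns `dose_M`, `signal`, and `ratio` when present.
#'
#' @param dr A [dose_response()] object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(dr, path) {
  stopifnot(inherits(dr, "dose_response"))
  utils::write.csv(as.data.frame(dr), path, row.names = FALSE)
  invisible(path)
}

#' Write a channel stack to multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major (`frame 1: all channels, frame 2: ...`).
#' TIFF float samples live in [0, 1], so intensities are divided by the
#' stack maximum; the scale factor, channel order, pixel size and stimulus
#' frame are recorded in `<path>.json` and restored on read. Ratio
#' quantities are unaffected by the common scale.
#'
#' @param stack A [channel_stack()].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  chn <- names(stack$channels)
  nt <- dim(stack$channels[[1]])[3]
  scale <- max(1e-12, vapply(stack$channels, max, numeric(1)))
  pages <- list()
  for (t in seq_len(nt)) {
    for (ch in chn) {
      pages[[length(pages) + 1L]] <- pmax(stack$channels[[ch]][, , t], 0) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channels = chn, n_frames = nt, scale = scale,
         pixel_size_um = stack$pixel_size_um, stim_frame = stack$stim_frame),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a channel stack written by [write_channel_stack()]
#'
#' @param path TIFF path (its `.json` sidecar must sit alongside).
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  chn <- meta$channels
  nchan <- length(chn)
  d <- dim(pages[[1]])
  channels <- stats::setNames(lapply(chn, function(ch) {
    array(0, c(d[1], d[2], meta$n_frames))
  }), chn)
  k <- 1L
  for (t in seq_len(meta$n_frames)) {
    for (ch in chn) {
      channels[[ch]][, , t] <- pages[[k]] * meta$scale
      k <- k + 1L
    }
  }
  channel_stack(channels, pixel_size_um = meta$pixel_size_um,
                stim_frame = meta$stim_frame)
}

#' Read ROI masks from a JSON polygon or label description
#'
#' JSON with `shape = c(rows, cols)` and a list `rois` of objects, each
#' with `label`, `kind`, and either `rect = [r0, r1, c0, c1]` (inclusive)
#' or polygon `rows`/`cols` vertex vectors (point-in-polygon rasterized).
#'
#' @param path JSON path.
#' @return List of [make_roi()] objects.
#' @export
read_rois_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nr <- spec$shape[[1]]; nc <- spec$shape[[2]]
  lapply(spec$rois, function(r) {
    mask <- matrix(FALSE, nr, nc)
    if (!is.null(r$rect)) {
      rc <- unlist(r$rect)
      mask[rc[1]:rc[2], rc[3]:rc[4]] <- TRUE
    } else {
      ry <- unlist(r$rows); cx <- unlist(r$cols)
      pts_r <- as.vector(row(mask)); pts_c <- as.vector(col(mask))
      inside <- .point_in_polygon(pts_r, pts_c, ry, cx)
      mask[inside] <- TRUE
    }
    make_roi(mask, r$kind, r$label)
  })
}

## even-odd ray casting
.point_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vc[i] > pc) != (vc[j] > pc)) &
      (pr < (vr[j] - vr[i]) * (pc - vc[i]) / (vc[j] - vc[i]) + vr[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
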