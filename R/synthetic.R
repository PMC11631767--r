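## Synthetic-data generators. Every input the analysis modules consume can
## be produced here with known ground truth, bit-reproducible from
## (config, seed), so the whole toolkit is testable offline.

#' Configuration for the synthetic microscopy generator
#'
#' Describes a two-channel (plus direct-acceptor) ratiometric timelapse:
#' elliptical cells on a dark background, a per-cell ratio step at the
#' stimulus frame, optional bright circular puncta with a ratio multiplier,
#' and a signal-proportional noise model.
#'
#' @param image_size Pixels per side, `c(rows, cols)` or scalar.
#' @param pixel_size_um Microns per pixel.
#' @param n_frames,stim_frame Frame count and 1-based first post-stimulus
#'   frame.
#' @param n_cells Number of cells (placed on a non-overlapping grid).
#' @param cell_axes_um Ellipse semi-axes in microns, `c(a, b)`.
#' @param donor_level Mean donor intensity inside cells (arbitrary units,
#'   kept in (0, 1) so stacks round-trip through TIFF).
#' @param bg_level Additive background level present everywhere.
#' @param baseline_ratio True FRET/donor ratio before stimulation.
#' @param step_amplitude Added to the ratio from `stim_frame` on (scalar or
#'   one per cell).
#' @param puncta_per_cell,puncta_radius_um,puncta_ratio_multiplier Puncta
#'   count per cell, radius, and multiplicative ratio contrast.
#' @param noise_cv Signal-proportional noise coefficient of variation.
#' @param noise_floor Additive Gaussian noise s.d. (intensity units).
#' @param acceptor_scale Per-cell direct-acceptor brightness scale (scalar
#'   or one per cell); use an outlying value to plant an over-bright cell.
#' @param seed Integer seed (required).
#' @return A `microscopy_sim_config` list.
#' @export
microscopy_sim_config <- function(image_size = 192L, pixel_size_um = 0.2,
                                  n_frames = 20L, stim_frame = 10L,
                                  n_cells = 4L, cell_axes_um = c(7, 5),
                                  donor_level = 0.4, bg_level = 0.05,
                                  baseline_ratio = 1.0, step_amplitude = 0.10,
                                  puncta_per_cell = 0L, puncta_radius_um = 1.0,
                                  puncta_ratio_multiplier = 1.5,
                                  noise_cv = 0.02, noise_floor = 0.0,
                                  acceptor_scale = 1.0, seed) {
  if (missing(seed)) stop("seed is required")
  image_size <- rep_len(as.integer(image_size), 2L)
  stopifnot(all(image_size > 0), pixel_size_um > 0, n_frames >= 2L,
            stim_frame >= 2L, stim_frame <= n_frames, n_cells >= 1L,
            all(cell_axes_um > 0), donor_level > 0, noise_cv >= 0,
            noise_floor >= 0, puncta_per_cell >= 0L)
  if (puncta_per_cell > 0 && puncta_radius_um >= min(cell_axes_um)) {
    stop("puncta radius must be smaller than the cell minor axis")
  }
  structure(list(
    image_size = image_size, pixel_size_um = pixel_size_um,
    n_frames = as.integer(n_frames), stim_frame = as.integer(stim_frame),
    n_cells = as.integer(n_cells), cell_axes_um = cell_axes_um,
    donor_level = donor_level, bg_level = bg_level,
    baseline_ratio = baseline_ratio,
    step_amplitude = rep_len(step_amplitude, n_cells),
    puncta_per_cell = as.integer(puncta_per_cell),
    puncta_radius_um = puncta_radius_um,
    puncta_ratio_multiplier = puncta_ratio_multiplier,
    noise_cv = noise_cv, noise_floor = noise_floor,
    acceptor_scale = rep_len(acceptor_scale, n_cells),
    seed = as.integer(seed)), class = "microscopy_sim_config")
}

#' Simulate a ratiometric microscopy timelapse with ground truth
#'
#' Cells are ellipses on a grid; the donor channel is drawn per cell, the
#' FRET channel is donor times the local true ratio, the acceptor channel
#' is donor times a per-cell brightness scale. Noise multiplies each pixel
#' by `(1 + noise_cv * eps)` and adds `noise_floor * eps'`.
#'
#' @param config A [microscopy_sim_config()].
#' @return A list: `stack` ([channel_stack()]), and `truth` holding
#'   `cell_labels` (label matrix), `cell_rois`, `bg_roi`, `puncta_labels`
#'   (label matrix, stable over time), `ratio_traces` (per cell per frame
#'   true body ratio), `acceptor_means` (noise-free per-cell acceptor
#'   intensity), `puncta_table`, and the `config`.
#' @export
simulate_microscopy <- function(config) {
  stopifnot(inherits(config, "microscopy_sim_config"))
  set.seed(config$seed)
  nr <- config$image_size[1]; nc <- config$image_size[2]
  ps <- config$pixel_size_um
  ax <- config$cell_axes_um / ps  # semi-axes in pixels

  ## grid placement: as square a grid as fits n_cells
  ncol_g <- ceiling(sqrt(config$n_cells))
  nrow_g <- ceiling(config$n_cells / ncol_g)
  if (2 * ax[1] > nc / ncol_g - 2 || 2 * ax[2] > nr / nrow_g - 2) {
    stop("cells do not fit the image grid; enlarge image_size or shrink cells")
  }
  rowv <- matrix(rep(seq_len(nr), nc), nr, nc)
  colv <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  cell_labels <- matrix(0L, nr, nc)
  puncta_labels <- matrix(0L, nr, nc)
  puncta_rows <- list()
  rp <- config$puncta_radius_um / ps
  for (k in seq_len(config$n_cells)) {
    gi <- (k - 1) %/% ncol_g; gj <- (k - 1) %% ncol_g
    cy <- (gi + 0.5) * nr / nrow_g
    cx <- (gj + 0.5) * nc / ncol_g
    inside <- ((rowv - cy) / ax[2])^2 + ((colv - cx) / ax[1])^2 <= 1
    cell_labels[inside] <- k
    if (config$puncta_per_cell > 0) {
      ## puncta on a ring well inside the cell, non-overlapping by spacing
      for (q in seq_len(config$puncta_per_cell)) {
        ang <- 2 * pi * (q - 1) / config$puncta_per_cell
        py <- cy + 0.5 * ax[2] * sin(ang)
        px <- cx + 0.5 * ax[1] * cos(ang)
        pm <- (rowv - py)^2 + (colv - px)^2 <= rp^2
        pid <- (k - 1L) * config$puncta_per_cell + q
        puncta_labels[pm & inside] <- pid
        puncta_rows[[pid]] <- data.frame(
          cell = k, punctum = q, label = pid,
          radius_um = config$puncta_radius_um,
          area_um2 = sum(pm & inside) * ps^2,
          ratio_multiplier = config$puncta_ratio_multiplier)
      }
    }
  }
  bg_mask <- cell_labels == 0L
  ## reserve a clean corner strip as the nominal background ROI
  bg_roi_mask <- matrix(FALSE, nr, nc)
  bg_roi_mask[1:max(2L, nr %/% 16L), 1:max(2L, nc %/% 16L)] <- TRUE
  bg_roi_mask <- bg_roi_mask & bg_mask

  donor_base <- matrix(0, nr, nc)
  acceptor_base <- matrix(0, nr, nc)
  for (k in seq_len(config$n_cells)) {
    donor_base[cell_labels == k] <- config$donor_level
    acceptor_base[cell_labels == k] <- config$donor_level * config$acceptor_scale[k]
  }

  mk_noise <- function(base) {
    base * (1 + config$noise_cv * stats::rnorm(length(base))) +
      config$noise_floor * stats::rnorm(length(base))
  }

  nt <- config$n_frames
  donor <- array(0, c(nr, nc, nt))
  fret <- array(0, c(nr, nc, nt))
  acceptor <- array(0, c(nr, nc, nt))
  traces <- expand.grid(cell = seq_len(config$n_cells), frame = seq_len(nt))
  traces$true_ratio <- NA_real_
  for (t in seq_len(nt)) {
    ratio_field <- matrix(0, nr, nc)
    for (k in seq_len(config$n_cells)) {
      r_body <- config$baseline_ratio +
        if (t >= config$stim_frame) config$step_amplitude[k] else 0
      ratio_field[cell_labels == k] <- r_body
      traces$true_ratio[traces$cell == k & traces$frame == t] <- r_body
    }
    if (config$puncta_per_cell > 0) {
      pm <- puncta_labels > 0
      ratio_field[pm] <- ratio_field[pm] * config$puncta_ratio_multiplier
    }
    donor[, , t] <- matrix(mk_noise(donor_base), nr, nc) + config$bg_level
    fret[, , t] <- matrix(mk_noise(donor_base * ratio_field), nr, nc) + config$bg_level
    acceptor[, , t] <- matrix(mk_noise(acceptor_base), nr, nc) + config$bg_level
  }

  stack <- channel_stack(list(donor = donor, fret = fret, acceptor = acceptor),
                         pixel_size_um = ps, stim_frame = config$stim_frame)
  cell_rois <- lapply(seq_len(config$n_cells), function(k) {
    make_roi(cell_labels == k, "cell", label = sprintf("cell_%02d", k))
  })
  acceptor_means <- vapply(seq_len(config$n_cells), function(k) {
    mean(acceptor_base[cell_labels == k])
  }, numeric(1))
  names(acceptor_means) <- sprintf("cell_%02d", seq_len(config$n_cells))
  list(stack = stack,
       truth = list(
         cell_labels = cell_labels,
         cell_rois = cell_rois,
         bg_roi = make_roi(bg_roi_mask, "background", "bg"),
         puncta_labels = puncta_labels,
         puncta_table = if (length(puncta_rows)) do.call(rbind, puncta_rows) else NULL,
         ratio_traces = traces,
         acceptor_means = acceptor_means,
         config = config))
}

#' Configuration for the dose-response generator
#'
#' @param params True [switch_params()].
#' @param totals [switch_totals()] template (Cage and Key totals).
#' @param doses Ascending dose grid (molar).
#' @param n_replicates Replicates per dose.
#' @param cv Lognormal measurement coefficient of variation.
#' @param seed Integer seed (required).
#' @return A `dose_sim_config` list.
#' @export
dose_sim_config <- function(params, totals,
                            doses = 10^seq(-9.5, -6, by = 0.5),
                            n_replicates = 3L, cv = 0.05, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(params, "switch_params"), inherits(totals, "switch_totals"),
            cv >= 0, n_replicates >= 1L)
  structure(list(params = params, totals = totals, doses = doses,
                 n_replicates = as.integer(n_replicates), cv = cv,
                 seed = as.integer(seed)), class = "dose_sim_config")
}

#' Simulate noisy dose-response replicates with known parameters
#'
#' Evaluates the equilibrium key-bound fraction at each dose and multiplies
#' by lognormal noise of the configured CV, independently per replicate.
#'
#' @param config A [dose_sim_config()].
#' @return List with `data` (`dose_M`, `replicate`, `signal`), `true_curve`
#'   (deterministic [dose_response()]), and `params`.
#' @export
simulate_dose_response <- function(config) {
  stopifnot(inherits(config, "dose_sim_config"))
  set.seed(config$seed)
  dr <- dose_response(config$params, config$totals, config$doses)
  sdlog <- sqrt(log(1 + config$cv^2))
  rows <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    data.frame(dose_M = dr$dose_M, replicate = r,
               signal = dr$signal *
                 exp(stats::rnorm(nrow(dr), -sdlog^2 / 2, sdlog)))
  }))
  list(data = rows, true_curve = dr, params = config$params)
}

#' Configuration for the proteomics generator
#'
#' @param n_proteins Number of proteins.
#' @param conditions Named integer vector: replicates per condition, e.g.
#'   `c(granule = 4, untargeted = 4)`.
#' @param baseline_mean,baseline_sd Per-protein mean log2 intensity
#'   distribution (MaxQuant-like raw intensities near 2^26).
#' @param rep_sd Within-group replicate s.d. in log2 units.
#' @param n_enriched Number of planted enriched proteins.
#' @param effect_log2 Planted log2 enrichment in the first condition.
#' @param missing Missingness model: `list(type = "logistic", max_p,
#'   center_quantile, scale)` (probability rising as intensity falls) or
#'   `list(type = "threshold", quantile)` (censor below an intensity
#'   quantile) or `list(type = "none")`.
#' @param n_contaminant,n_reverse,n_only_site Planted flagged rows
#'   (appended beyond `n_proteins`).
#' @param seed Integer seed (required).
#' @return A `proteomics_sim_config` list.
#' @export
proteomics_sim_config <- function(n_proteins = 1000L,
                                  conditions = c(granule = 4L, untargeted = 4L),
                                  baseline_mean = 26, baseline_sd = 2,
                                  rep_sd = 0.5, n_enriched = 50L,
                                  effect_log2 = 2,
                                  missing = list(type = "none"),
                                  n_contaminant = 0L, n_reverse = 0L,
                                  n_only_site = 0L, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_proteins >= 1L, length(conditions) >= 2L,
            !is.null(names(conditions)), n_enriched <= n_proteins,
            rep_sd >= 0, is.list(missing), missing$type %in%
              c("none", "logistic", "threshold"))
  structure(list(n_proteins = as.integer(n_proteins), conditions = conditions,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 rep_sd = rep_sd, n_enriched = as.integer(n_enriched),
                 effect_log2 = effect_log2, missing = missing,
                 n_contaminant = as.integer(n_contaminant),
                 n_reverse = as.integer(n_reverse),
                 n_only_site = as.integer(n_only_site),
                 seed = as.integer(seed)), class = "proteomics_sim_config")
}

#' Simulate a proximity-labeling intensity table with ground truth
#'
#' Draws per-protein baseline log2 intensities, adds the planted
#' enrichment to the first condition for a random enriched subset, applies
#' intensity-dependent censoring, optionally plants flagged rows, and
#' returns both an in-memory [intensity_matrix()] and (optionally) a
#' MaxQuant-dialect TSV readable by [load_protein_table()].
#'
#' @param config A [proteomics_sim_config()].
#' @param path Optional TSV output path.
#' @return List with `matrix` (raw-scale [intensity_matrix()]),
#'   `sample_sheet`, `truth` (`enriched` protein names, `mean_log2`,
#'   `missing_fraction`), and `path` if written.
#' @export
simulate_proteomics <- function(config, path = NULL) {
  stopifnot(inherits(config, "proteomics_sim_config"))
  set.seed(config$seed)
  np <- config$n_proteins
  reps <- config$conditions
  samples <- do.call(rbind, lapply(names(reps), function(cn) {
    data.frame(sample = sprintf("%s_%d", cn, seq_len(reps[[cn]])),
               condition = cn, replicate = seq_len(reps[[cn]]))
  }))
  ns <- nrow(samples)
  prot <- sprintf("P%04d", seq_len(np))
  mu <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)
  enriched <- sort(sample(np, config$n_enriched))
  lmat <- matrix(stats::rnorm(np * ns, 0, config$rep_sd), np, ns) + mu
  target <- samples$condition == names(reps)[1]
  lmat[enriched, target] <- lmat[enriched, target] + config$effect_log2

  miss <- matrix(FALSE, np, ns)
  mm <- config$missing
  if (mm$type == "logistic") {
    center <- stats::quantile(lmat, mm$center_quantile)
    pmiss <- mm$max_p * stats::plogis((center - lmat) / mm$scale)
    miss <- matrix(stats::runif(np * ns) < pmiss, np, ns)
  } else if (mm$type == "threshold") {
    miss <- lmat < stats::quantile(lmat, mm$quantile)
  }
  raw <- 2^lmat
  raw[miss] <- NA_real_

  nflag <- config$n_contaminant + config$n_reverse + config$n_only_site
  flags <- data.frame(potential_contaminant = logical(np),
                      reverse = logical(np),
                      only_identified_by_site = logical(np))
  if (nflag > 0) {
    extra_mu <- stats::rnorm(nflag, config$baseline_mean, config$baseline_sd)
    extra <- matrix(stats::rnorm(nflag * ns, 0, config$rep_sd), nflag, ns) + extra_mu
    raw <- rbind(raw, 2^extra)
    prot <- c(prot, sprintf("FLAG%03d", seq_len(nflag)))
    flags <- rbind(flags, data.frame(
      potential_contaminant = rep(c(TRUE, FALSE, FALSE),
                                  c(config$n_contaminant, config$n_reverse,
                                    config$n_only_site)),
      reverse = rep(c(FALSE, TRUE, FALSE),
                    c(config$n_contaminant, config$n_reverse,
                      config$n_only_site)),
      only_identified_by_site = rep(c(FALSE, FALSE, TRUE),
                                    c(config$n_contaminant, config$n_reverse,
                                      config$n_only_site))))
  }
  rownames(raw) <- prot
  m <- intensity_matrix(raw, samples, flags, log2 = FALSE)

  written <- NULL
  if (!is.null(path)) {
    tab <- data.frame(`Protein IDs` = prot, check.names = FALSE)
    vals <- raw
    vals[is.na(vals)] <- 0  # MaxQuant writes 0 for not-detected
    for (j in seq_len(ns)) tab[[paste("Intensity", samples$sample[j])]] <- vals[, j]
    tab[["Potential contaminant"]] <- ifelse(flags$potential_contaminant, "+", "")
    tab[["Reverse"]] <- ifelse(flags$reverse, "+", "")
    tab[["Only identified by site"]] <- ifelse(flags$only_identified_by_site, "+", "")
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- path
  }
  list(matrix = m, sample_sheet = samples,
       truth = list(enriched = prot[enriched], mean_log2 = mu,
                    missing_fraction = mean(miss),
                    target_condition = names(reps)[1]),
       path = written)
}
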