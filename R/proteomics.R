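## Perseus-style processing of proximity-labeling intensity tables:
## flag filtering -> log2 median centering -> replicate correlation QC ->
## downshifted-normal imputation -> Welch differential enrichment.

.FLAG_COLS <- c(potential_contaminant = "Potential contaminant",
                reverse = "Reverse",
                only_identified_by_site = "Only identified by site")

#' Protein-by-sample intensity matrix
#'
#' Container for a proximity-labeling proteomics dataset. Zeros in raw
#' intensity columns are missing values (below detection), per the
#' MaxQuant convention.
#'
#' @param values Numeric matrix (proteins x samples), `NA` for missing.
#' @param samples Data frame with columns `sample`, `condition`,
#'   `replicate` matching the matrix columns.
#' @param flags Logical data frame with columns `potential_contaminant`,
#'   `reverse`, `only_identified_by_site` (one row per protein).
#' @param log2 Whether `values` are on the log2 scale.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, samples, flags = NULL, log2 = FALSE) {
  stopifnot(is.matrix(values), is.data.frame(samples),
            nrow(samples) == ncol(values),
            all(c("sample", "condition", "replicate") %in% names(samples)))
  if (is.null(flags)) {
    flags <- data.frame(potential_contaminant = logical(nrow(values)),
                        reverse = logical(nrow(values)),
                        only_identified_by_site = logical(nrow(values)))
  }
  stopifnot(nrow(flags) == nrow(values))
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples, flags = flags,
                 log2 = log2, normalized = FALSE,
                 imputed_mask = matrix(FALSE, nrow(values), ncol(values)),
                 qc_excluded = stats::setNames(rep(FALSE, nrow(samples)),
                                               samples$sample)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("Intensity matrix: %d proteins x %d samples (%s scale%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2" else "raw",
              if (x$normalized) ", median-centered" else ""))
  cat(sprintf("  missing: %d cells, imputed: %d cells, QC-excluded samples: %d\n",
              sum(is.na(x$values)), sum(x$imputed_mask), sum(x$qc_excluded)))
  cat(sprintf("  flagged rows: %d contaminant, %d reverse, %d only-by-site\n",
              sum(x$flags$potential_contaminant), sum(x$flags$reverse),
              sum(x$flags$only_identified_by_site)))
  invisible(x)
}

#' @export
summary.intensity_matrix <- function(object, ...) {
  cat("Per-sample summary\n")
  df <- data.frame(sample = object$samples$sample,
                   condition = object$samples$condition,
                   replicate = object$samples$replicate,
                   n_observed = colSums(!is.na(object$values)),
                   median = apply(object$values, 2, stats::median, na.rm = TRUE),
                   qc_excluded = unname(object$qc_excluded))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Load a MaxQuant-style proteinGroups table
#'
#' Reads a tab-separated proteinGroups-dialect table: intensity columns
#' named `Intensity <sample>`, flag columns marked with `"+"`. Zero
#' intensities become missing values; intensities stay on the raw scale
#' until [normalize_log2_median()].
#'
#' @param path TSV path.
#' @param sample_sheet Data frame with columns `sample`, `condition`,
#'   `replicate`; each `sample` must match an `Intensity <sample>` column
#'   (or an exact column name).
#' @param id_col Column holding protein identifiers (default
#'   `"Protein IDs"`, falling back to `"Majority protein IDs"`).
#' @return An [intensity_matrix()].
#' @export
load_protein_table <- function(path, sample_sheet, id_col = "Protein IDs") {
  stopifnot(file.exists(path), is.data.frame(sample_sheet),
            all(c("sample", "condition", "replicate") %in% names(sample_sheet)))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- character(0)
  col_for <- function(s) {
    for (cand in c(paste("Intensity", s), s)) {
      if (cand %in% names(tab)) return(cand)
    }
    missing_cols <<- c(missing_cols, paste("Intensity", s))
    NA_character_
  }
  cols <- vapply(sample_sheet$sample, col_for, character(1))
  absent_flags <- setdiff(unname(.FLAG_COLS), names(tab))
  missing_cols <- c(missing_cols, absent_flags)
  if (length(missing_cols)) {
    stop("required columns absent from table: ",
         paste(missing_cols, collapse = "; "))
  }
  vals <- as.matrix(tab[, cols, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[vals == 0] <- NA_real_  # zero intensity = below detection
  flags <- data.frame(lapply(.FLAG_COLS, function(cn) {
    v <- as.character(tab[[cn]])
    v[is.na(v)] <- ""    # fully empty flag columns read as NA
    trimws(v) == "+"
  }))
  names(flags) <- names(.FLAG_COLS)
  if (!id_col %in% names(tab) && "Majority protein IDs" %in% names(tab)) {
    id_col <- "Majority protein IDs"
  }
  rn <- if (id_col %in% names(tab)) as.character(tab[[id_col]]) else
    sprintf("protein_%d", seq_len(nrow(tab)))
  rownames(vals) <- make.unique(rn)
  intensity_matrix(vals, sample_sheet, flags, log2 = FALSE)
}

#' Remove flagged rows
#'
#' Drops potential contaminants, reverse (decoy) hits, and proteins
#' identified only by modified (biotinylated) site.
#'
#' @param m An [intensity_matrix()].
#' @return Filtered matrix; attribute `"removed"` holds per-flag counts
#'   (a row carrying several flags is removed, and counted in total, once).
#' @export
filter_flags <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  fl <- m$flags
  drop <- fl$potential_contaminant | fl$reverse | fl$only_identified_by_site
  counts <- c(potential_contaminant = sum(fl$potential_contaminant),
              reverse = sum(fl$reverse),
              only_identified_by_site = sum(fl$only_identified_by_site),
              total_removed = sum(drop))
  m$values <- m$values[!drop, , drop = FALSE]
  m$flags <- fl[!drop, , drop = FALSE]
  m$imputed_mask <- m$imputed_mask[!drop, , drop = FALSE]
  attr(m, "removed") <- counts
  m
}

#' Log2-transform and median-center each sample column
#'
#' Raw intensities are log2-transformed, then each column's median (over
#' observed cells) is subtracted, leaving every column with median zero.
#' Idempotent: centering an already-centered matrix changes nothing.
#'
#' @param m An [intensity_matrix()].
#' @return Normalized matrix (`log2 = TRUE`, `normalized = TRUE`).
#' @export
normalize_log2_median <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  v <- m$values
  if (!m$log2) {
    if (any(v <= 0, na.rm = TRUE)) stop("raw intensities must be positive")
    v <- log2(v)
  }
  meds <- apply(v, 2, stats::median, na.rm = TRUE)
  if (any(is.na(meds))) {
    stop("column(s) entirely missing: ",
         paste(colnames(v)[is.na(meds)], collapse = ", "))
  }
  m$values <- sweep(v, 2, meds)
  m$log2 <- TRUE
  m$normalized <- TRUE
  m
}

#' Replicate correlation quality control
#'
#' Within each experiment (condition), computes pairwise Pearson
#' correlations over mutually observed proteins, assigns each replicate its
#' mean pairwise r, and excludes replicates whose mean r deviates from the
#' experiment-wide mean of those values by more than `max_dev`. A single,
#' non-iterative pass; exclusion requires at least 3 replicates.
#'
#' @param m A normalized [intensity_matrix()].
#' @param max_dev Maximum allowed deviation of a replicate's mean pairwise
#'   r from the experiment mean (default 0.25).
#' @return List with `matrix` (QC flags set in `qc_excluded`) and `report`
#'   (per-replicate mean r, deviation, excluded).
#' @export
replicate_qc <- function(m, max_dev = 0.25) {
  stopifnot(inherits(m, "intensity_matrix"))
  rep_rows <- list()
  excl <- m$qc_excluded
  for (cond in unique(m$samples$condition)) {
    idx <- which(m$samples$condition == cond)
    if (length(idx) < 2L) next
    sub <- m$values[, idx, drop = FALSE]
    cc <- stats::cor(sub, use = "pairwise.complete.obs")
    mean_r <- (rowSums(cc, na.rm = TRUE) - 1) / (length(idx) - 1)
    dev <- abs(mean_r - mean(mean_r))
    can_exclude <- length(idx) >= 3L
    if (!can_exclude) {
      warning(sprintf("condition '%s' has %d replicates; QC reported but no exclusion",
                      cond, length(idx)))
    }
    out <- can_exclude & dev > max_dev
    excl[idx] <- excl[idx] | out
    rep_rows[[cond]] <- data.frame(
      sample = m$samples$sample[idx], condition = cond,
      mean_r = unname(mean_r), deviation = unname(dev),
      excluded = unname(out))
  }
  m$qc_excluded <- excl
  list(matrix = m, report = do.call(rbind, c(rep_rows, make.row.names = FALSE)))
}

#' Impute missing values from a downshifted normal distribution
#'
#' Missing-not-at-random imputation: for each sample, missing cells are
#' drawn from a normal distribution with mean `sample mean - downshift *
#' sample s.d.` and standard deviation `width * sample s.d.`, statistics
#' taken over that sample's observed values. Downshift and width are thus
#' in units of the per-sample standard deviation (the convention of the
#' Perseus imputation these defaults mirror: downshift 1.8, width 0.2).
#'
#' @param m A normalized [intensity_matrix()].
#' @param downshift Downshift in per-sample s.d. units (default 1.8).
#' @param width Imputed-distribution width in s.d. units (default 0.2).
#' @param seed Integer seed; the imputation is fully reproducible from it.
#' @return Matrix with missing cells filled and `imputed_mask` set.
#'   Samples with fewer than 2 observed values are skipped and listed in
#'   attribute `"skipped_samples"`.
#' @export
impute_mnar <- function(m, downshift = 1.8, width = 0.2, seed) {
  stopifnot(inherits(m, "intensity_matrix"), !missing(seed))
  set.seed(as.integer(seed))
  skipped <- character(0)
  for (j in seq_len(ncol(m$values))) {
    obs <- m$values[, j][!is.na(m$values[, j])]
    miss <- which(is.na(m$values[, j]))
    if (length(miss) == 0L) next
    if (length(obs) < 2L) {
      skipped <- c(skipped, colnames(m$values)[j])
      next
    }
    mu <- mean(obs); s <- stats::sd(obs)
    m$values[miss, j] <- stats::rnorm(length(miss),
                                      mean = mu - downshift * s,
                                      sd = width * s)
    m$imputed_mask[miss, j] <- TRUE
  }
  if (length(skipped)) {
    warning("imputation skipped for sample(s) with <2 observed values: ",
            paste(skipped, collapse = ", "))
    attr(m, "skipped_samples") <- skipped
  }
  m
}

#' Differential enrichment between two conditions
#'
#' Per protein: difference of condition means on the log2 scale, a test of
#' that difference, and Benjamini-Hochberg adjustment across tested
#' proteins. QC-excluded samples are ignored.
#'
#' The default `"moderated"` method is limma's empirical-Bayes moderated
#' t-test, which shares variance information across proteins; at the
#' replicate depths typical of labeling proteomics (3-4 per condition) a
#' per-protein Welch test has only ~6 degrees of freedom and too little
#' power to rank genuine several-fold enrichments reliably, whereas the
#' moderated test does. A plain Welch two-sample t-test (`"welch"`) and a
#' label-permutation test on the Welch statistic (`"permutation"`) are
#' available behind the flag.
#'
#' @param m A processed [intensity_matrix()] (log2 scale).
#' @param condition_a,condition_b Condition labels; log2FC is A minus B.
#' @param method `"moderated"` (default), `"welch"` or `"permutation"`.
#' @param n_perm Permutations for `method = "permutation"`.
#' @param seed Seed for the permutation method.
#' @return An `enrichment_result` data frame (`protein`, `log2FC`, `t`,
#'   `p`, `q`) sorted by `q` then descending `|log2FC|`; attribute
#'   `"n_skipped"` counts proteins with insufficient replication.
#' @export
differential_enrichment <- function(m, condition_a, condition_b,
                                    method = c("moderated", "welch", "permutation"),
                                    n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(m, "intensity_matrix"))
  keep <- !m$qc_excluded
  ia <- which(m$samples$condition == condition_a & keep)
  ib <- which(m$samples$condition == condition_b & keep)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("need >= 2 retained replicates per condition")
  }
  n <- nrow(m$values)
  ids <- rownames(m$values)
  if (is.null(ids)) ids <- sprintf("protein_%d", seq_len(n))
  res <- data.frame(protein = ids,
                    log2FC = NA_real_, t = NA_real_, p = NA_real_)
  skipped <- 0L
  if (method == "moderated") {
    grp <- factor(c(rep("a", length(ia)), rep("b", length(ib))),
                  levels = c("a", "b"))
    design <- stats::model.matrix(~ 0 + grp)
    colnames(design) <- levels(grp)
    vals <- m$values[, c(ia, ib), drop = FALSE]
    enough <- rowSums(!is.na(vals[, grp == "a", drop = FALSE])) >= 2L &
      rowSums(!is.na(vals[, grp == "b", drop = FALSE])) >= 2L
    skipped <- sum(!enough)
    if (any(enough)) {
      fit <- limma::lmFit(vals[enough, , drop = FALSE], design)
      fit <- limma::contrasts.fit(
        fit, limma::makeContrasts(a - b, levels = design))
      fit <- limma::eBayes(fit)
      res$log2FC[enough] <- fit$coefficients[, 1]
      res$t[enough] <- fit$t[, 1]
      res$p[enough] <- fit$p.value[, 1]
    }
    tested <- !is.na(res$p)
    res$q <- NA_real_
    res$q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
    res <- res[order(res$q, -abs(res$log2FC)), ]
    rownames(res) <- NULL
    return(structure(res, class = c("enrichment_result", "data.frame"),
                     n_skipped = skipped, method = method,
                     conditions = c(condition_a, condition_b)))
  }
  for (i in seq_len(n)) {
    xa <- m$values[i, ia]; xb <- m$values[i, ib]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) { skipped <- skipped + 1L; next }
    res$log2FC[i] <- mean(xa) - mean(xb)
    if (stats::sd(c(xa, xb)) == 0) { res$t[i] <- 0; res$p[i] <- 1; next }
    tt <- stats::t.test(xa, xb, var.equal = FALSE)
    res$t[i] <- unname(tt$statistic)
    res$p[i] <- tt$p.value
  }
  if (method == "permutation") {
    set.seed(as.integer(seed))
    vals <- m$values[, c(ia, ib), drop = FALSE]
    na_len <- length(ia)
    tstat <- function(cols) {
      xa <- vals[, cols, drop = FALSE]
      xb <- vals[, setdiff(seq_len(ncol(vals)), cols), drop = FALSE]
      ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
      va <- apply(xa, 1, stats::var, na.rm = TRUE)
      vb <- apply(xb, 1, stats::var, na.rm = TRUE)
      (ma - mb) / sqrt(va / rowSums(!is.na(xa)) + vb / rowSums(!is.na(xb)))
    }
    t_obs <- tstat(seq_len(na_len))
    exceed <- rep(0L, n)
    for (b in seq_len(n_perm)) {
      cols <- sample(ncol(vals), na_len)
      exceed <- exceed + as.integer(abs(tstat(cols)) >= abs(t_obs))
    }
    res$p <- ifelse(is.na(res$p), NA_real_, (exceed + 1) / (n_perm + 1))
  }
  tested <- !is.na(res$p)
  res$q <- NA_real_
  res$q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res <- res[order(res$q, -abs(res$log2FC)), ]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            n_skipped = skipped, method = method,
            conditions = c(condition_a, condition_b))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("Differential enrichment (%s): %s vs %s, %d tested, %d skipped\n",
              attr(x, "method"), cond[1], cond[2],
              sum(!is.na(x$p)), attr(x, "n_skipped")))
  cat(sprintf("  q < 0.05: %d proteins\n", sum(x$q < 0.05, na.rm = TRUE)))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
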