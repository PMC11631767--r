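# Fixtures are built in code: either tiny matrices assembled by hand or
# tables written by the proteomics generator.

tiny_matrix <- function(values, conds, flags = NULL) {
  ns <- ncol(values)
  samples <- data.frame(sample = colnames(values), condition = conds,
                        replicate = ave(seq_len(ns), conds, FUN = seq_along))
  intensity_matrix(values, samples, flags, log2 = TRUE)
}

test_that("MaxQuant-dialect tables parse with zeros as missing and flags set", {
  cfg <- proteomics_sim_config(n_proteins = 10, conditions = c(a = 3L, b = 3L),
                               n_enriched = 0, effect_log2 = 0,
                               n_reverse = 2L, seed = 31)
  f <- withr::local_tempfile(fileext = ".txt")
  sim <- simulate_proteomics(cfg, f)
  m <- load_protein_table(f, sim$sample_sheet)
  expect_identical(dim(m$values), c(12L, 6L))   # 10 proteins + 2 planted decoys
  expect_identical(sum(m$flags$reverse), 2L)
  expect_identical(sum(m$flags$potential_contaminant), 0L)
  expect_false(m$log2)

  # a zero intensity is missing, not log of zero
  tab <- utils::read.delim(f, check.names = FALSE)
  tab[["Intensity a_1"]][1] <- 0
  f2 <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(tab, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- load_protein_table(f2, sim$sample_sheet)
  expect_true(is.na(m2$values[1, "a_1"]))

  # absent required columns are named in the error
  tab$Reverse <- NULL
  tab[["Intensity a_1"]] <- NULL
  f3 <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(tab, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_protein_table(f3, sim$sample_sheet), "Intensity a_1")
  expect_error(load_protein_table(f3, sim$sample_sheet), "Reverse")
})

test_that("flag filtering drops contaminants, decoys and only-by-site rows once", {
  vals <- matrix(2^rnorm(100 * 4, 25), 100, 4,
                 dimnames = list(sprintf("P%03d", 1:100), c("a_1", "a_2", "b_1", "b_2")))
  flags <- data.frame(potential_contaminant = rep(FALSE, 100),
                      reverse = FALSE, only_identified_by_site = FALSE)
  flags$potential_contaminant[1:3] <- TRUE
  flags$reverse[4:5] <- TRUE
  flags$only_identified_by_site[6] <- TRUE
  m <- tiny_matrix(vals, c("a", "a", "b", "b"), flags)
  mf <- filter_flags(m)
  expect_identical(nrow(mf$values), 94L)
  expect_identical(unname(attr(mf, "removed")["total_removed"]), 6L)

  # overlapping flags remove (and count) the row once
  flags2 <- flags
  flags2$reverse[1] <- TRUE   # row 1 is both contaminant and reverse
  mo <- filter_flags(tiny_matrix(vals, c("a", "a", "b", "b"), flags2))
  expect_identical(nrow(mo$values), 94L)
  expect_identical(unname(attr(mo, "removed")["total_removed"]), 6L)

  # no flags: identity
  m0 <- filter_flags(tiny_matrix(vals, c("a", "a", "b", "b")))
  expect_identical(nrow(m0$values), 100L)
})

test_that("median centering normalizes each column and is idempotent", {
  vals <- matrix(c(2, 4, 8,  16, 16, 16,  2, NA, 8), 3, 3,
                 dimnames = list(NULL, c("a_1", "a_2", "b_1")))
  m <- intensity_matrix(vals, data.frame(sample = colnames(vals),
                                         condition = c("a", "a", "b"),
                                         replicate = c(1, 2, 1)))
  mn <- normalize_log2_median(m)
  expect_equal(unname(mn$values[, 1]), c(-1, 0, 1))   # log2 {1,2,3} centered
  expect_equal(unname(mn$values[, 2]), c(0, 0, 0))
  expect_equal(unname(mn$values[, 3]), c(-1, NA, 1))  # missing cells ignored
  expect_lt(max(abs(apply(mn$values, 2, median, na.rm = TRUE))), 1e-9)

  mn2 <- normalize_log2_median(mn)
  expect_equal(mn2$values, mn$values)

  bad <- m; bad$values[, 2] <- NA
  expect_error(normalize_log2_median(bad), "entirely missing")
})

test_that("replicate QC excludes a decorrelated replicate in a single pass", {
  set.seed(41)
  base <- rnorm(400, 0, 1)
  good <- sapply(1:3, function(i) base + rnorm(400, 0, 0.1))
  colnames(good) <- paste0("a_", 1:3)
  m <- tiny_matrix(good, rep("a", 3))
  qc <- replicate_qc(m)
  expect_false(any(qc$matrix$qc_excluded))

  vals <- cbind(good[, 1:2], a_3 = rnorm(400))   # third replicate independent
  qc2 <- replicate_qc(tiny_matrix(vals, rep("a", 3)))
  expect_identical(names(which(qc2$matrix$qc_excluded)), "a_3")
  expect_true(all(qc2$report$deviation[qc2$report$sample != "a_3"] <= 0.25))

  expect_warning(qc3 <- replicate_qc(tiny_matrix(good[, 1:2], rep("a", 2))),
                 "no exclusion")
  expect_false(any(qc3$matrix$qc_excluded))
})

test_that("downshifted imputation matches its stated distribution and is reproducible", {
  set.seed(51)
  obs <- rnorm(2e4, 0, 1)
  vals <- matrix(c(obs, rep(NA_real_, 1e4)), ncol = 1,
                 dimnames = list(NULL, "s_1"))
  m <- intensity_matrix(vals, data.frame(sample = "s_1", condition = "x",
                                         replicate = 1), log2 = TRUE)
  mi <- impute_mnar(m, downshift = 1.8, width = 0.2, seed = 99)
  imp <- mi$values[mi$imputed_mask]
  expect_identical(length(imp), 10000L)
  expect_equal(mean(imp), mean(obs) - 1.8 * sd(obs), tolerance = 0.02)
  expect_equal(sd(imp), 0.2 * sd(obs), tolerance = 0.01 / (0.2 * sd(obs)))
  # observed cells never overwritten
  expect_equal(mi$values[!mi$imputed_mask], obs)

  mi2 <- impute_mnar(m, seed = 99)
  expect_identical(mi$values, mi2$values)

  m_none <- intensity_matrix(matrix(obs[1:10], ncol = 1,
                                    dimnames = list(NULL, "s_1")),
                             data.frame(sample = "s_1", condition = "x",
                                        replicate = 1), log2 = TRUE)
  expect_identical(impute_mnar(m_none, seed = 1)$values, m_none$values)

  sparse <- intensity_matrix(matrix(c(1, NA, NA), ncol = 1,
                                    dimnames = list(NULL, "s_1")),
                             data.frame(sample = "s_1", condition = "x",
                                        replicate = 1), log2 = TRUE)
  expect_warning(ms <- impute_mnar(sparse, seed = 1), "skipped")
  expect_identical(attr(ms, "skipped_samples"), "s_1")
})

test_that("enrichment statistics behave on degenerate and planted inputs", {
  # identical conditions: log2FC 0 and q near 1
  set.seed(61)
  half <- matrix(rnorm(50 * 3, 25, 0.3), 50, 3)
  vals <- cbind(half, half)
  colnames(vals) <- c(paste0("a_", 1:3), paste0("b_", 1:3))
  m <- tiny_matrix(vals, rep(c("a", "b"), each = 3))
  de <- differential_enrichment(m, "a", "b", method = "welch")
  expect_true(all(abs(de$log2FC) < 1e-12))
  expect_true(all(de$p == 1))

  # single protein: BH equals the raw p-value
  one <- matrix(c(25.1, 25.3, 24.9, 26.0, 26.3, 26.1), 1, 6,
                dimnames = list("P1", colnames(vals)))
  de1 <- differential_enrichment(tiny_matrix(one, rep(c("a", "b"), each = 3)),
                                 "a", "b", method = "welch")
  expect_equal(de1$q, de1$p)

  # planted enrichment recovered by the moderated default
  cfg <- proteomics_sim_config(n_proteins = 400, n_enriched = 20, seed = 71,
                               missing = list(type = "none"))
  sim <- simulate_proteomics(cfg)
  mm <- normalize_log2_median(sim$matrix)
  dem <- differential_enrichment(mm, "granule", "untargeted")
  hits <- dem$protein[!is.na(dem$q) & dem$q < 0.05]
  expect_gte(mean(sim$truth$enriched %in% hits), 0.9)
  expect_lte(mean(!(hits %in% sim$truth$enriched)), 0.10)

  # permutation flag produces p-values concordant with Welch ranking
  dep <- differential_enrichment(mm, "granule", "untargeted",
                                 method = "permutation", n_perm = 200, seed = 5)
  top_perm <- dep$protein[seq_len(30)]
  expect_gt(mean(sim$truth$enriched %in% top_perm), 0.9)
})
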