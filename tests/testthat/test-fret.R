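# Small hand-built stacks keep the arithmetic transparent; generator-driven
# recovery lives in test-synthetic.R and the pipeline checks.

stack_from <- function(donor, fret, stim_frame = 2L) {
  channel_stack(list(donor = donor, fret = fret), pixel_size_um = 1,
                stim_frame = stim_frame)
}

test_that("background subtraction removes the per-frame cell-free mean", {
  donor <- array(100, c(4, 4, 2))
  fret <- array(100, c(4, 4, 2))
  fret[1:2, 1:2, 1] <- 10   # bg region mean 10 in frame 1
  fret[1:2, 1:2, 2] <- 20   # and 20 in frame 2
  bg_mask <- matrix(FALSE, 4, 4); bg_mask[1:2, 1:2] <- TRUE
  bg <- make_roi(bg_mask, "background", "bg")
  st <- background_subtract(stack_from(donor, fret), bg)
  expect_equal(st$channels$fret[4, 4, 1], 90)
  expect_equal(st$channels$fret[4, 4, 2], 80)
  expect_equal(st$channels$donor[4, 4, 1], 0)  # whole-frame-constant channel

  full_bg <- make_roi(matrix(TRUE, 4, 4), "background")
  st2 <- background_subtract(stack_from(array(7, c(4, 4, 2)),
                                        array(7, c(4, 4, 2))), full_bg)
  expect_true(all(st2$channels$donor == 0))

  expect_error(background_subtract(stack_from(donor, fret),
                                   make_roi(matrix(TRUE, 4, 4), "cell")),
               "background")
})

test_that("ratio traces divide channel means and anchor R0 pre-stimulus", {
  donor <- array(rep(c(2, 2, 2, 2), each = 16), c(4, 4, 4))
  fret <- 2 * donor
  cell <- make_roi(matrix(TRUE, 4, 4), "cell", "c1")
  tr <- ratio_trace(stack_from(donor, fret, stim_frame = 3L), cell)
  expect_equal(tr$R, rep(2, 4))
  expect_equal(tr$R0, 2)

  # ratio invariant to a common positive scaling of both channels
  tr2 <- ratio_trace(stack_from(donor * 37.5, fret * 37.5, 3L), cell)
  expect_equal(tr2$R, tr$R)

  expect_error(ratio_trace(stack_from(array(0, c(4, 4, 4)), fret, 3L), cell),
               "> 20%")
})

test_that("normalization modes: R/R0 anchor, pooled min-max, reference minimum", {
  mk_trace <- function(R, stim = 2L, label = "t") {
    structure(list(R = R, R0 = R[stim - 1L], stim_frame = stim,
                   n_undefined = 0L, label = label), class = "fret_trace")
  }
  const <- mk_trace(rep(1.7, 5))
  n <- normalize_traces(list(const), "r0")
  expect_equal(n[[1]]$normalized, rep(1, 5))

  stepped <- mk_trace(c(1.0, 1.0, 1.2, 1.3, 1.3), stim = 3L)
  n <- normalize_traces(list(stepped), "r0")
  expect_equal(n[[1]]$normalized[2], 1)  # anchor frame maps exactly to 1

  mm <- normalize_traces(list(mk_trace(c(1.0, 1.5, 2.0))), "minmax")
  expect_equal(mm[[1]]$normalized, c(0, 0.5, 1))
  pooled <- normalize_traces(list(mk_trace(c(1.0, 1.2, 1.4)),
                                  mk_trace(c(1.1, 1.6, 1.8))), "minmax")
  all_vals <- unlist(lapply(pooled, `[[`, "normalized"))
  expect_equal(min(all_vals), 0)
  expect_equal(max(all_vals), 1)
  expect_error(normalize_traces(list(const), "minmax"), "degenerate")

  rm <- normalize_traces(list(mk_trace(c(1.4, 1.3, 1.2)),
                              mk_trace(c(1.4, 1.1, 0.9))),
                         "ref_min", conditions = c("DMSO", "Ce+Y"))
  expect_equal(min(unlist(lapply(rm, `[[`, "normalized"))), 0)
  expect_true(all(unlist(lapply(rm, `[[`, "normalized")) >= 0))
  expect_identical(attr(rm, "reference_condition"), "Ce+Y")
})

test_that("SNR is max post-stimulus change over baseline spread", {
  base <- c(1.00, 1.01, 0.99, 1.00, 1.01)
  tr <- structure(list(R = c(base, 1.10, 1.08), R0 = base[5], stim_frame = 6L,
                       n_undefined = 0L, label = "t"), class = "fret_trace")
  expect_equal(trace_snr(tr, 1:5), (1.10 - 1.01) / stats::sd(base))

  flat <- structure(list(R = c(rep(1, 5), 1.1), R0 = 1, stim_frame = 6L,
                         n_undefined = 0L, label = "t"), class = "fret_trace")
  s <- trace_snr(flat, 1:5)
  expect_true(is.infinite(s))
  expect_true(attr(s, "flagged"))

  # pure-noise traces: mean SNR tracks a brute-force Monte-Carlo estimate of
  # E[max of post-stimulus deviations / baseline s.d.] under the same design
  set.seed(33)
  n_base <- 8L; n_post <- 10L; sims <- 400L
  snrs <- replicate(sims, {
    R <- rnorm(n_base + n_post, 1, 0.01)
    tr <- structure(list(R = R, R0 = R[n_base], stim_frame = n_base + 1L,
                         n_undefined = 0L, label = "x"), class = "fret_trace")
    trace_snr(tr, 1:n_base)
  })
  mc <- replicate(4000, {
    x <- rnorm(n_base + n_post)
    max(x[(n_base + 1):(n_base + n_post)] - x[n_base]) / sd(x[1:n_base])
  })
  expect_equal(mean(snrs), mean(mc), tolerance = 0.1)
})

test_that("brightness QC excludes strictly above mean + 3 s.d.", {
  expect_identical(qc_exclude(rep(5, 8))$excluded, character(0))

  set.seed(9)
  others <- rnorm(19, 10, 1)
  outlier <- mean(others) + 5 * sd(others)
  res <- qc_exclude(stats::setNames(c(others, outlier),
                                    paste0("c", 1:20)))
  expect_identical(res$excluded, "c20")

  # strict inequality: just below the self-consistent boundary is kept,
  # just above is excluded; exact ties (zero-spread population) are kept
  boundary <- uniroot(function(v) {
    x <- c(others, v); v - mean(x) - 3 * sd(x)
  }, c(10, 1e4), tol = 1e-10)$root
  expect_identical(qc_exclude(c(others, boundary * 0.999))$excluded, character(0))
  expect_identical(qc_exclude(c(others, boundary * 1.001))$excluded, "20")

  expect_warning(qc_exclude(c(1, 2)), "skipped")
})

test_that("ratio images mask zero-donor pixels and recover region contrast", {
  donor <- matrix(2, 8, 8)
  expect_equal(ratio_image(donor, donor)$ratio, matrix(1, 8, 8))

  donor0 <- donor; donor0[1:2, 1] <- 0
  ri <- ratio_image(donor0 * 1.5, donor0)
  expect_identical(ri$n_masked, 2L)
  expect_identical(sum(is.na(ri$ratio)), 2L)
  expect_true(all(ri$ratio[!is.na(ri$ratio)] == 1.5))

  expect_error(ratio_image(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")

  # punctum at ratio 1.5 on a body at 1.0
  donor <- matrix(10, 32, 32)
  ratio_true <- matrix(1, 32, 32)
  punctum <- (row(donor) - 16)^2 + (col(donor) - 16)^2 <= 16
  ratio_true[punctum] <- 1.5
  ri <- ratio_image(donor * ratio_true, donor)
  expect_equal(mean(ri$ratio[punctum]), 1.5, tolerance = 0.01)
  expect_equal(mean(ri$ratio[!punctum]), 1.0, tolerance = 0.01)
  expect_identical(dim(ri$rgb), c(32L, 32L, 3L))
})
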