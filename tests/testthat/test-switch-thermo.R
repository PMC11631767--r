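test_that("state weights follow the five-state scheme", {
  sp <- switch_params(0, 1e-6, 1e-7)
  w <- state_weights(sp, K_free = 0, T_free = 0)
  expect_equal(unname(w), c(1, 1, 0, 0, 0))
  expect_equal(unname(state_weights(sp, 0, 0, normalize = TRUE)["closed"]), 0.5)

  # target weight equals the open reference when T_free = Kd_target
  w <- state_weights(sp, K_free = 0, T_free = 1e-7)
  expect_equal(unname(w["target"]), unname(w["open"]))

  # closed-state weight is a hand-evaluated Boltzmann factor at -2 kcal/mol
  sp2 <- switch_params(-2, 1e-6, 1e-7)
  rt <- 1.987204259e-3 * 298.15
  expect_equal(unname(state_weights(sp2, 0, 0)["closed"]), exp(2 / rt))
  p <- state_weights(sp2, 0, 0, normalize = TRUE)
  expect_equal(unname(p["closed"]), exp(2 / rt) / (exp(2 / rt) + 1))
  expect_equal(sum(p), 1)

  expect_error(state_weights(sp, -1e-9, 0), "free concentrations")
})

test_that("dilute limit reproduces the closed-form populations", {
  sp <- switch_params(-1.5, 2e-6, 5e-8)
  tot <- switch_totals(1e-15, 3e-7, 8e-8)
  eq <- solve_equilibrium(sp, tot)
  expect_equal(eq$K_free, tot$K_tot, tolerance = 1e-6)
  expect_equal(eq$T_free, tot$T_tot, tolerance = 1e-6)
  expected <- state_weights(sp, tot$K_tot, tot$T_tot, normalize = TRUE)
  expect_equal(eq$P, expected, tolerance = 1e-6)
})

test_that("solved equilibria conserve mass and match the brute-force oracle", {
  set.seed(101)
  for (i in 1:25) {
    inst <- random_switch_instance()
    sp <- switch_params(inst$dG, inst$KdK, inst$KdT)
    eq <- solve_equilibrium(sp, switch_totals(inst$Ctot, inst$Ktot, inst$Ttot))
    expect_lt(eq$residual_K, 1e-9)
    expect_lt(eq$residual_T, 1e-9)
    orc <- oracle_equilibrium(inst$dG, inst$KdK, inst$KdT,
                              inst$Ctot, inst$Ktot, inst$Ttot)
    expect_equal(unname(eq$P), orc$P, tolerance = 1e-6)
  }
})

test_that("signal limits: no key, and the open-cage binary binding limit", {
  sp <- switch_params(-2, 1e-6, 1e-7)
  expect_equal(switch_signal(sp, switch_totals(1e-6, 0, 1e-7)), 0)
  ro <- readout_model(1, 2)
  expect_equal(switch_ratio(sp, switch_totals(1e-6, 0, 1e-7), ro), 1)

  # latch never closes, no target, dilute cage: simple Key binding isotherm
  sp_open <- switch_params(50, 1e-6, 1e-7)
  K <- 3e-7
  sig <- switch_signal(sp_open, switch_totals(1e-15, K, 0))
  expect_equal(sig, (K / 1e-6) / (1 + K / 1e-6), tolerance = 1e-6)
})

test_that("signal is monotone in target, key and key affinity", {
  sp <- switch_params(-2, 1e-6, 1e-8)
  doses <- c(0, 10^seq(-10, -6, by = 0.5))
  dr <- dose_response(sp, switch_totals(1e-7, 1e-7, 0), doses)
  expect_true(all(diff(dr$signal) > 0))  # strictly increasing in T_tot
  expect_true(all(dr$signal >= 0 & dr$signal <= 1))

  sig_K <- vapply(10^seq(-9, -6, by = 0.5), function(K) {
    switch_signal(sp, switch_totals(1e-7, K, 1e-8))
  }, numeric(1))
  expect_true(all(diff(sig_K) > 0))

  sig_KdK <- vapply(10^seq(-8, -5, by = 0.5), function(kd) {
    switch_signal(switch_params(-2, kd, 1e-8), switch_totals(1e-7, 1e-7, 1e-8))
  }, numeric(1))
  expect_true(all(diff(sig_KdK) < 0))
})

test_that("dose-response spans the basal-to-plateau gap over a wide grid", {
  sp <- switch_params(-2, 1e-7, 1e-8)
  tot <- switch_totals(1e-9, 1e-7, 0)  # dilute cage: no target depletion
  dr1 <- dose_response(sp, tot, 0)
  expect_identical(nrow(dr1), 1L)
  expect_equal(dr1$signal, switch_signal(sp, switch_totals(1e-9, 1e-7, 0)))

  doses <- c(0, 10^seq(log10(1e-8) - 3, log10(1e-8) + 3, by = 0.25))
  dr <- dose_response(sp, tot, doses)
  # the sampled range covers at least 90% of the basal..plateau gap
  basal <- dr$signal[1]
  gap_sampled <- max(dr$signal) - basal
  plateau <- switch_signal(sp, switch_totals(1e-9, 1e-7, 1e-2))
  expect_gt(gap_sampled, 0.9 * (plateau - basal))
})

test_that("dynamic range is max-minus-basal and non-negative", {
  sp <- switch_params(-2, 1e-7, 1e-8)
  tot <- switch_totals(1e-9, 1e-7, 0)
  dr <- dose_response(sp, tot, c(0, 10^seq(-10, -5, by = 1)),
                      readout = readout_model(1, 2))
  expect_gte(dynamic_range(dr), 0)
  expect_equal(dynamic_range(dr),
               dr$signal[nrow(dr)] - dr$signal[1])
  expect_equal(dynamic_range(dr, "ratio"),
               dr$ratio[nrow(dr)] - dr$ratio[1])

  flat <- structure(data.frame(dose_M = c(0, 1e-8, 1e-7),
                               signal = rep(0.2, 3)),
                    class = c("dose_response", "data.frame"))
  expect_equal(dynamic_range(flat), 0)
  arith <- structure(data.frame(dose_M = c(0, 1e-7), signal = c(0.1, 0.6)),
                     class = c("dose_response", "data.frame"))
  expect_equal(dynamic_range(arith), 0.5)
  no_basal <- structure(data.frame(dose_M = c(1e-9, 1e-7), signal = c(0.1, 0.6)),
                        class = c("dose_response", "data.frame"))
  expect_error(dynamic_range(no_basal), "zero dose")
})

test_that("ec50 locates a constructed symmetric sigmoid and flags flat curves", {
  d <- 10^seq(-10, -4, by = 0.25)
  sig <- 0.1 + 0.5 * d / (d + 1e-7)   # half-rise exactly at 1e-7 M
  dr <- structure(data.frame(dose_M = c(0, d), signal = c(0.1, sig)),
                  class = c("dose_response", "data.frame"))
  expect_equal(log10(ec50(dr)), -7, tolerance = 0.25 / 7)

  flat <- structure(data.frame(dose_M = c(0, 1e-8), signal = c(0.2, 0.2)),
                    class = c("dose_response", "data.frame"))
  expect_warning(e <- ec50(flat), "degenerate")
  expect_true(is.na(e))
  expect_true(attr(e, "flagged"))
})

test_that("latch weakening shifts the half-maximal dose lower", {
  tot <- switch_totals(1e-9, 1e-7, 0)
  doses <- c(0, 10^seq(-11, -5, by = 0.25))
  dr_tight <- dose_response(switch_params(-2, 1e-7, 1e-8), tot, doses)
  dr_weak <- dose_response(switch_params(0, 1e-7, 1e-8), tot, doses)
  expect_lt(ec50(dr_weak), ec50(dr_tight))
  # weakened latch also has higher background, the high-basal phenotype
  expect_gt(dr_weak$signal[1], dr_tight$signal[1])
})

test_that("mutation effects act additively on the named interface", {
  sp <- switch_params(-2, 1e-6, 1e-7)
  expect_equal(apply_mutations(sp, list()), sp)

  rt <- rt_kcal()
  m10 <- mutation_effect("K_x10", "key", rt * log(10))
  expect_equal(apply_mutations(sp, list(m10))$Kd_key, 1e-5)

  two <- list(mutation_effect("L1", "latch", 0.7),
              mutation_effect("L2", "latch", 0.4))
  expect_equal(apply_mutations(sp, two)$dG_close, -2 + 1.1)
  expect_error(mutation_effect("bad", "cage", 1))
})

test_that("latch weakening raises background; key weakening lowers both ends", {
  tot0 <- switch_totals(1e-7, 1e-7, 0)
  tot_sat <- switch_totals(1e-7, 1e-7, 1e-5)
  set.seed(202)
  for (i in 1:20) {
    inst <- random_switch_instance()
    sp <- switch_params(inst$dG, inst$KdK, inst$KdT)
    lw <- apply_mutations(sp, list(mutation_effect("L", "latch", 1)))
    kw <- apply_mutations(sp, list(mutation_effect("K", "key", 1)))
    expect_gt(switch_signal(lw, tot0), switch_signal(sp, tot0))
    expect_lt(switch_signal(kw, tot0), switch_signal(sp, tot0))
    expect_lt(switch_signal(kw, tot_sat), switch_signal(sp, tot_sat))
  }
})

test_that("exhaustive tuning matches an independent enumeration", {
  sp <- switch_params(-1, 1e-7, 1e-8)
  tot <- switch_totals(1e-7, 1e-7, 0)
  window <- c(1e-9, 1e-7)

  expect_identical(tune_switch(sp, tot, list(), window, 1)$selected, character(0))

  # one helpful key-weakening effect under a cap excluding the unmutated sensor
  bg0 <- switch_signal(sp, switch_totals(tot$C_tot, tot$K_tot, 0))
  helper <- mutation_effect("K_helper", "key", 1.5)
  spw <- apply_mutations(sp, list(helper))
  bgw <- switch_signal(spw, switch_totals(tot$C_tot, tot$K_tot, 0))
  cap <- (bgw + bg0) / 2   # between the two backgrounds
  res <- tune_switch(sp, tot, list(helper), window, cap)
  expect_identical(res$selected, "K_helper")
  expect_true(res$feasible)

  # independent enumeration oracle over a small random library
  set.seed(7)
  lib <- lapply(1:6, function(i) {
    mutation_effect(sprintf("m%02d", i), sample(c("latch", "key"), 1),
                    stats::runif(1, -0.5, 1.5))
  })
  cap <- 0.15
  best_obj <- -Inf; best <- NULL
  for (k in 0:length(lib)) {
    combos <- utils::combn(length(lib), k, simplify = FALSE)
    for (cc in combos) {
      p <- apply_mutations(sp, lib[cc])
      bg <- switch_signal(p, switch_totals(tot$C_tot, tot$K_tot, 0))
      if (bg > cap) next
      obj <- switch_signal(p, switch_totals(tot$C_tot, tot$K_tot, window[2])) -
        switch_signal(p, switch_totals(tot$C_tot, tot$K_tot, window[1]))
      nm <- paste(sort(vapply(lib[cc], function(e) e$name, character(1))),
                  collapse = "+")
      better <- obj > best_obj + 1e-15 ||
        (abs(obj - best_obj) <= 1e-15 && !is.null(best) &&
           (length(cc) < length(best$cc) ||
              (length(cc) == length(best$cc) && nm < best$nm)))
      if (is.null(best) || better) {
        best_obj <- obj; best <- list(cc = cc, nm = nm)
      }
    }
  }
  res <- tune_switch(sp, tot, lib, window, cap)
  expect_identical(res$selected,
                   sort(vapply(lib[best$cc], function(e) e$name, character(1))))
  expect_equal(res$objective, best_obj, tolerance = 1e-9)

  # infeasible cap returns best effort, flagged
  res_inf <- tune_switch(sp, tot, lib, window, background_cap = -1)
  expect_false(res_inf$feasible)
})
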