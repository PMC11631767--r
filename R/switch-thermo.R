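## Five cage states (single-cage partition function):
##   S1 closed           w = exp(-dG_close/RT)   (latch in groove, TBD occluded)
##   S2 open, empty      w = 1                   (reference state)
##   S3 open, target     w = T_free/Kd_target
##   S4 key, no target   w = K_free/Kd_key       (false-positive state)
##   S5 key + target     w = (K_free/Kd_key) * (T_free/Kd_target)
## The closed cage binds neither key nor target; key and target bind
## independently once the latch is open.

.STATE_NAMES <- c("closed", "open", "target", "key", "key_target")

#' Unnormalized statistical weights of the five cage states
#'
#' @param params A [switch_params()] object.
#' @param K_free Free Key concentration (molar, >= 0).
#' @param T_free Free target concentration (molar, >= 0).
#' @param normalize If `TRUE`, return probabilities summing to 1.
#' @return Named numeric vector of length 5 over states
#'   `closed`, `open`, `target`, `key`, `key_target`.
#' @examples
#' sp <- switch_params(0, 1e-6, 1e-7)
#' state_weights(sp, K_free = 0, T_free = 0) # (1, 1, 0, 0, 0)
#' @export
state_weights <- function(params, K_free, T_free, normalize = FALSE) {
  stopifnot(inherits(params, "switch_params"),
            is.numeric(K_free), length(K_free) == 1L,
            is.numeric(T_free), length(T_free) == 1L)
  if (K_free < 0 || T_free < 0) stop("free concentrations must be >= 0")
  rt <- rt_kcal(params$temperature_K)
  a <- K_free / params$Kd_key
  b <- T_free / params$Kd_target
  w <- c(exp(-params$dG_close / rt), 1, b, a, a * b)
  names(w) <- .STATE_NAMES
  if (normalize) w / sum(w) else w
}

## Vectorized equilibrium engine. All arguments recycled to a common length.
## Returns list of vectors. Damped fixed point on the substitution form
##   K_free = K_tot / (1 + C_tot * (1 + b) / (Kd_key * Z))
## (guaranteed in (0, K_tot]); falls back to nested bisection for any
## instance that has not converged.
.solve_eq_vec <- function(dG, KdK, KdT, Ctot, Ktot, Ttot, temperature_K = 298.15,
                          tol = 1e-12, max_iter = 10000L) {
  n <- max(length(dG), length(KdK), length(KdT),
           length(Ctot), length(Ktot), length(Ttot))
  dG <- rep_len(dG, n); KdK <- rep_len(KdK, n); KdT <- rep_len(KdT, n)
  Ctot <- rep_len(Ctot, n); Ktot <- rep_len(Ktot, n); Ttot <- rep_len(Ttot, n)
  rt <- .R_KCAL * temperature_K
  wc <- exp(-dG / rt)

  Kf <- Ktot
  Tf <- Ttot
  damp <- 0.5
  iter <- 0L
  repeat {
    iter <- iter + 1L
    a <- Kf / KdK
    b <- Tf / KdT
    Z <- wc + 1 + b + a + a * b
    Kf_new <- Ktot / (1 + Ctot * (1 + b) / (KdK * Z))
    Tf_new <- Ttot / (1 + Ctot * (1 + a) / (KdT * Z))
    Kf_upd <- (1 - damp) * Kf + damp * Kf_new
    Tf_upd <- (1 - damp) * Tf + damp * Tf_new
    delta <- pmax(abs(Kf_upd - Kf) / pmax(Ktot, 1e-300),
                  abs(Tf_upd - Tf) / pmax(Ttot, 1e-300))
    Kf <- Kf_upd; Tf <- Tf_upd
    if (all(delta < tol) || iter >= max_iter) break
  }

  a <- Kf / KdK; b <- Tf / KdT
  Z <- wc + 1 + b + a + a * b
  res_K <- abs(Ktot - Kf - Ctot * a * (1 + b) / Z) / pmax(Ktot, 1e-300)
  res_T <- abs(Ttot - Tf - Ctot * b * (1 + a) / Z) / pmax(Ttot, 1e-300)
  bad <- which(res_K > 1e-10 | res_T > 1e-10)
  for (i in bad) {
    s <- .solve_eq_bisect(wc[i], KdK[i], KdT[i], Ctot[i], Ktot[i], Ttot[i])
    Kf[i] <- s[1]; Tf[i] <- s[2]
  }
  a <- Kf / KdK; b <- Tf / KdT
  Z <- wc + 1 + b + a + a * b
  list(
    K_free = Kf, T_free = Tf,
    P = cbind(closed = wc / Z, open = 1 / Z, target = b / Z,
              key = a / Z, key_target = a * b / Z),
    residual_K = abs(Ktot - Kf - Ctot * a * (1 + b) / Z) / pmax(Ktot, 1e-300),
    residual_T = abs(Ttot - Tf - Ctot * b * (1 + a) / Z) / pmax(Ttot, 1e-300),
    iterations = iter
  )
}

## Nested bisection fallback: outer root in K_free, inner root in T_free.
## Both balance functions are strictly increasing in their own variable.
.solve_eq_bisect <- function(wc, KdK, KdT, Ctot, Ktot, Ttot) {
  tsolve <- function(Kf) {
    if (Ttot == 0) return(0)
    g <- function(Tf) {
      a <- Kf / KdK; b <- Tf / KdT
      Z <- wc + 1 + b + a + a * b
      Tf + Ctot * b * (1 + a) / Z - Ttot
    }
    lo <- 0; hi <- Ttot
    for (j in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  if (Ktot == 0) return(c(0, tsolve(0)))
  f <- function(Kf) {
    Tf <- tsolve(Kf)
    a <- Kf / KdK; b <- Tf / KdT
    Z <- wc + 1 + b + a + a * b
    Kf + Ctot * a * (1 + b) / Z - Ktot
  }
  lo <- 0; hi <- Ktot
  for (j in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  Kf <- (lo + hi) / 2
  c(Kf, tsolve(Kf))
}

#' Solve the coupled binding equilibrium at finite concentrations
#'
#' Finds free Key and target concentrations satisfying mass balance
#' `K_tot = K_free + C_tot * (P(key) + P(key_target))` and
#' `T_tot = T_free + C_tot * (P(target) + P(key_target))`, where the state
#' probabilities come from [state_weights()]. The solution is unique because
#' each balance equation is monotone in its own free concentration. A damped
#' fixed-point iteration is used, with a nested-bisection fallback for any
#' instance that fails to reach tolerance.
#'
#' @param params A [switch_params()] object.
#' @param totals A [switch_totals()] object.
#' @param tol Relative convergence tolerance on free concentrations.
#' @param max_iter Maximum fixed-point iterations.
#' @return A list with `K_free`, `T_free`, named probability vector `P`
#'   over the five cage states, `signal` (key-bound fraction), relative
#'   mass-balance residuals, and iteration count.
#' @examples
#' sp <- switch_params(-2, 1e-6, 1e-7)
#' eq <- solve_equilibrium(sp, switch_totals(1e-6, 1e-6, 1e-7))
#' eq$signal
#' @export
solve_equilibrium <- function(params, totals, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(params, "switch_params"), inherits(totals, "switch_totals"))
  s <- .solve_eq_vec(params$dG_close, params$Kd_key, params$Kd_target,
                     totals$C_tot, totals$K_tot, totals$T_tot,
                     temperature_K = params$temperature_K,
                     tol = tol, max_iter = max_iter)
  if (s$residual_K[1] > 1e-9 || s$residual_T[1] > 1e-9) {
    stop(sprintf(
      "equilibrium solver did not converge: relative residuals %.3g (Key), %.3g (target)",
      s$residual_K[1], s$residual_T[1]))
  }
  P <- s$P[1, ]
  list(K_free = s$K_free[1], T_free = s$T_free[1], P = P,
       signal = unname(P["key"] + P["key_target"]),
       residual_K = s$residual_K[1], residual_T = s$residual_T[1],
       iterations = s$iterations)
}

#' Key-bound fraction of cages at equilibrium
#'
#' The readout-generating quantity: the equilibrium fraction of cages with
#' Key bound (false-positive plus ternary states).
#'
#' @inheritParams solve_equilibrium
#' @return Key-bound fraction in [0, 1].
#' @export
switch_signal <- function(params, totals) {
  solve_equilibrium(params, totals)$signal
}

#' FRET-like ratio at equilibrium
#'
#' @inheritParams solve_equilibrium
#' @param readout A [readout_model()] mapping occupancy linearly to a ratio.
#' @return Ratio `R_min + (R_max - R_min) * signal`.
#' @export
switch_ratio <- function(params, totals, readout) {
  stopifnot(inherits(readout, "readout_model"))
  readout$R_min + (readout$R_max - readout$R_min) * switch_signal(params, totals)
}

#' Dose-response curve over a target concentration grid
#'
#' Evaluates the equilibrium key-bound fraction at each total target
#' concentration in `doses`, holding Cage and Key totals fixed.
#'
#' @param params A [switch_params()] object.
#' @param totals A [switch_totals()] object; its `T_tot` is ignored.
#' @param doses Ascending vector of total target concentrations (molar).
#' @param readout Optional [readout_model()]; adds a `ratio` column.
#' @return A `dose_response` data frame with columns `dose_M`, `signal`
#'   and (if `readout` given) `ratio`.
#' @examples
#' sp <- switch_params(-2, 1e-6, 1e-8)
#' dr <- dose_response(sp, switch_totals(1e-6, 1e-6, 0),
#'                     doses = c(0, 10^seq(-10, -6, by = 1)))
#' dynamic_range(dr)
#' @export
dose_response <- function(params, totals, doses, readout = NULL) {
  stopifnot(inherits(params, "switch_params"), inherits(totals, "switch_totals"),
            is.numeric(doses), length(doses) >= 1L, !is.unsorted(doses, strictly = TRUE))
  if (any(doses < 0)) stop("doses must be >= 0")
  s <- .solve_eq_vec(params$dG_close, params$Kd_key, params$Kd_target,
                     totals$C_tot, totals$K_tot, doses,
                     temperature_K = params$temperature_K)
  if (any(s$residual_K > 1e-9 | s$residual_T > 1e-9)) {
    stop("equilibrium solver did not converge for at least one dose")
  }
  out <- data.frame(dose_M = doses,
                    signal = s$P[, "key"] + s$P[, "key_target"])
  if (!is.null(readout)) {
    stopifnot(inherits(readout, "readout_model"))
    out$ratio <- readout$R_min + (readout$R_max - readout$R_min) * out$signal
  }
  structure(out, class = c("dose_response", "data.frame"),
            params = params, totals = totals)
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response: %d doses, signal %.4g .. %.4g\n",
              nrow(x), min(x$signal), max(x$signal)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.dose_response <- function(x, ...) {
  d <- x$dose_M
  pos <- d > 0
  plot(d[pos], x$signal[pos], log = "x", type = "b",
       xlab = "total target (M)", ylab = "key-bound fraction", ...)
  if (any(!pos)) abline(h = x$signal[!pos][1], lty = 3)
  invisible(x)
}

#' Dynamic range of a dose-response curve
#'
#' Maximum response minus basal response, following the convention that
#' dynamic range equals the stimulated readout minus the basal readout.
#'
#' @param dr A [dose_response()] object containing a zero dose, or a basal
#'   value supplied via `basal`.
#' @param value `"signal"` or `"ratio"` column to use.
#' @param basal Optional basal response overriding the zero-dose entry.
#' @return Response at the maximum dose minus basal response.
#' @export
dynamic_range <- function(dr, value = c("signal", "ratio"), basal = NULL) {
  value <- match.arg(value)
  stopifnot(inherits(dr, "dose_response"), nrow(dr) >= 1L)
  if (value == "ratio" && is.null(dr$ratio)) stop("no ratio column; attach a readout_model")
  y <- dr[[value]]
  if (is.null(basal)) {
    i0 <- which(dr$dose_M == 0)
    if (length(i0) == 0L) stop("no zero dose present and no `basal` supplied")
    basal <- y[i0[1]]
  }
  y[which.max(dr$dose_M)] - basal
}

#' Half-maximal effective concentration of a dose-response curve
#'
#' Dose at half-maximal rise above basal, by monotone linear interpolation
#' on log10 dose. The basal point is the zero-dose response (or the lowest
#' dose if zero is absent); the plateau is the response at the maximum dose.
#'
#' @param dr A [dose_response()] object.
#' @param value Column to use (`"signal"` or `"ratio"`).
#' @return The EC50 in molar, or `NA` (with a warning and attribute
#'   `flagged = TRUE`) if the curve does not cross half-maximum.
#' @export
ec50 <- function(dr, value = c("signal", "ratio")) {
  value <- match.arg(value)
  stopifnot(inherits(dr, "dose_response"))
  y <- dr[[value]]
  d <- dr$dose_M
  basal <- y[1]
  plateau <- y[length(y)]
  gap <- plateau - basal
  if (!is.finite(gap) || gap <= .Machine$double.eps * max(abs(y), 1)) {
    warning("dose-response gap is degenerate; EC50 undefined")
    return(structure(NA_real_, flagged = TRUE))
  }
  half <- basal + gap / 2
  pos <- which(d > 0)
  ld <- log10(d[pos]); yy <- y[pos]
  above <- which(yy >= half)
  if (length(above) == 0L) {
    warning("curve does not reach half-maximum; EC50 undefined")
    return(structure(NA_real_, flagged = TRUE))
  }
  i <- above[1]
  if (i == 1L) return(10^ld[1])
  frac <- (half - yy[i - 1]) / (yy[i] - yy[i - 1])
  10^(ld[i - 1] + frac * (ld[i] - ld[i - 1]))
}

#' Tune a switch to a target concentration window by exhaustive search
#'
#' Enumerates every subset of a mutation library (additive per-interface
#' ddG effects, see [apply_mutations()]) and selects the subset maximizing
#' `signal(T_hi) - signal(T_lo)` subject to the background constraint
#' `signal(0) <= background_cap`. Ties are broken by fewer mutations, then
#' lexicographically on sorted mutation names.
#'
#' @param params Starting [switch_params()].
#' @param totals A [switch_totals()]; `T_tot` is ignored.
#' @param effects List of [mutation_effect()] objects (at most 20).
#' @param window Numeric `c(T_lo, T_hi)` target concentration window (molar),
#'   `T_lo < T_hi`.
#' @param background_cap Maximum allowed signal at zero target.
#' @return A `switch_tuning` list: `selected` (mutation names), `params`
#'   (tuned parameters), `objective`, `background`, `feasible`, and a
#'   per-subset `report` data frame.
#' @export
tune_switch <- function(params, totals, effects, window, background_cap) {
  stopifnot(inherits(params, "switch_params"), inherits(totals, "switch_totals"),
            is.list(effects), length(effects) <= 20L,
            is.numeric(window), length(window) == 2L, window[1] < window[2],
            is.numeric(background_cap), length(background_cap) == 1L)
  m <- length(effects)
  nm <- vapply(effects, function(e) e$name, character(1))
  iface <- vapply(effects, function(e) e$interface, character(1))
  ddg <- vapply(effects, function(e) e$ddG, numeric(1))
  rt <- rt_kcal(params$temperature_K)

  n_sub <- 2L^m
  inc <- matrix(FALSE, n_sub, max(m, 1L))
  if (m > 0) {
    for (j in seq_len(m)) {
      inc[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) != 0L
    }
  }
  d_latch <- if (m > 0) as.vector(inc %*% ifelse(iface == "latch", ddg, 0)) else 0
  d_key   <- if (m > 0) as.vector(inc %*% ifelse(iface == "key", ddg, 0)) else 0
  dG <- params$dG_close + d_latch
  KdK <- params$Kd_key * exp(d_key / rt)

  sig_at <- function(Ttot) {
    s <- .solve_eq_vec(dG, KdK, params$Kd_target, totals$C_tot, totals$K_tot,
                       Ttot, temperature_K = params$temperature_K)
    s$P[, "key"] + s$P[, "key_target"]
  }
  bg <- sig_at(0)
  obj <- sig_at(window[2]) - sig_at(window[1])
  nmut <- if (m > 0) rowSums(inc) else rep(0L, n_sub)
  namekey <- vapply(seq_len(n_sub), function(i) {
    paste(sort(nm[inc[i, seq_len(m)]]), collapse = "+")
  }, character(1))

  feasible_mask <- bg <= background_cap
  pick_from <- function(idx) {
    o <- order(-obj[idx], nmut[idx], namekey[idx])
    idx[o[1]]
  }
  feasible <- any(feasible_mask)
  best <- if (feasible) pick_from(which(feasible_mask)) else pick_from(seq_len(n_sub))
  sel <- nm[inc[best, seq_len(m)]]
  structure(list(
    selected = sort(sel),
    params = apply_mutations(params, effects[inc[best, seq_len(m)]]),
    objective = obj[best],
    background = bg[best],
    feasible = feasible,
    report = data.frame(subset = namekey, n_mutations = nmut,
                        background = bg, objective = obj,
                        feasible = feasible_mask)
  ), class = "switch_tuning")
}

#' @export
print.switch_tuning <- function(x, ...) {
  cat("Switch tuning (exhaustive subset search)\n")
  cat("  selected :", if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  objective: %.4g  background: %.4g  %s\n",
              x$objective, x$background,
              if (x$feasible) "feasible" else "INFEASIBLE cap (best effort)"))
  invisible(x)
}
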