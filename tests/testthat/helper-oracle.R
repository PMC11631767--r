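# Independent brute-force oracle for the coupled binding equilibrium.
# Coarse-to-fine grid refinement on each mass-balance equation, written
# without reference to the package solver. Used to validate populations.

oracle_rt <- 1.987204259e-3 * 298.15

oracle_weights <- function(dG, KdK, KdT, Kf, Tf) {
  c(exp(-dG / oracle_rt), 1, Tf / KdT, Kf / KdK, (Kf / KdK) * (Tf / KdT))
}

# refine the root of increasing function g (vectorized) on [lo, hi] by
# repeated 11-point grid bracketing; each round shrinks the bracket 10x
.grid_root <- function(g, lo, hi, rounds = 20) {
  for (r in seq_len(rounds)) {
    xs <- seq(lo, hi, length.out = 11)
    gs <- g(xs)
    i <- which(gs > 0)[1]
    if (is.na(i)) return(hi)
    if (i == 1) return(lo)
    lo <- xs[i - 1]; hi <- xs[i]
  }
  (lo + hi) / 2
}

oracle_equilibrium <- function(dG, KdK, KdT, Ctot, Ktot, Ttot) {
  wc <- exp(-dG / oracle_rt)
  bound_T <- function(Kf, Tf) {
    Z <- wc + 1 + Tf / KdT + Kf / KdK + (Kf / KdK) * (Tf / KdT)
    Ctot * ((Tf / KdT) * (1 + Kf / KdK)) / Z
  }
  bound_K <- function(Kf, Tf) {
    Z <- wc + 1 + Tf / KdT + Kf / KdK + (Kf / KdK) * (Tf / KdT)
    Ctot * ((Kf / KdK) * (1 + Tf / KdT)) / Z
  }
  solve_T <- function(Kf) {
    if (Ttot == 0) return(0)
    .grid_root(function(Tf) Tf + bound_T(Kf, Tf) - Ttot, 0, Ttot)
  }
  Kf <- if (Ktot == 0) 0 else
    .grid_root(function(Kf) {
      vapply(Kf, function(k) k + bound_K(k, solve_T(k)) - Ktot, numeric(1))
    }, 0, Ktot)
  Tf <- solve_T(Kf)
  w <- oracle_weights(dG, KdK, KdT, Kf, Tf)
  list(K_free = Kf, T_free = Tf, P = w / sum(w))
}

# random parameter draw used by oracle-equivalence and sweep tests
random_switch_instance <- function() {
  list(dG = stats::runif(1, -4, 2),
       KdK = 10^stats::runif(1, -8, -5),
       KdT = 10^stats::runif(1, -9, -6),
       Ctot = 10^stats::runif(1, -8, -5),
       Ktot = 10^stats::runif(1, -8, -5),
       Ttot = 10^stats::runif(1, -9, -6))
}
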