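#' @keywords internal
"_PACKAGE"

## Gas constant in kcal/(mol K); RT = 0.593 kcal/mol at 298.15 K.
.R_KCAL <- 1.987204259e-3

#' Thermal energy RT in kcal/mol
#'
#' @param temperature_K Temperature in kelvin.
#' @return RT in kcal/mol (0.593 at 298.15 K).
#' @export
rt_kcal <- function(temperature_K = 298.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  .R_KCAL * temperature_K
}

#' Switch energetic parameters
#'
#' Defines the three tunable interactions of a two-component LOCKR switch:
#' the intramolecular latch:cage interaction (closing free energy), the
#' Key:cage interaction (dissociation constant of Key binding the open
#' groove), and the target interaction with the latch-embedded binding
#' domain (dissociation constant).
#'
#' @param dG_close Free energy of latch closing, G(closed) - G(open), in
#'   kcal/mol. Negative values favor the closed (dark) state.
#' @param Kd_key Dissociation constant (molar) of Key binding the open cage.
#' @param Kd_target Dissociation constant (molar) of target binding the
#'   exposed target-binding domain.
#' @param temperature_K Temperature in kelvin (default 298.15).
#' @return An object of class `switch_params`.
#' @examples
#' sp <- switch_params(dG_close = -2, Kd_key = 1e-6, Kd_target = 1e-7)
#' sp
#' @export
switch_params <- function(dG_close, Kd_key, Kd_target, temperature_K = 298.15) {
  stopifnot(
    is.numeric(dG_close), length(dG_close) == 1L, is.finite(dG_close) || dG_close == Inf,
    is.numeric(Kd_key), length(Kd_key) == 1L, Kd_key > 0,
    is.numeric(Kd_target), length(Kd_target) == 1L, Kd_target > 0,
    is.numeric(temperature_K), length(temperature_K) == 1L, temperature_K > 0
  )
  structure(
    list(dG_close = dG_close, Kd_key = Kd_key, Kd_target = Kd_target,
         temperature_K = temperature_K),
    class = "switch_params"
  )
}

#' @export
print.switch_params <- function(x, ...) {
  cat("LOCKR switch parameters\n")
  cat(sprintf("  dG_close : %+.3f kcal/mol (latch:cage closing)\n", x$dG_close))
  cat(sprintf("  Kd_key   : %.3g M (key:cage)\n", x$Kd_key))
  cat(sprintf("  Kd_target: %.3g M (target:TBD)\n", x$Kd_target))
  cat(sprintf("  T        : %.2f K (RT = %.4f kcal/mol)\n",
              x$temperature_K, rt_kcal(x$temperature_K)))
  invisible(x)
}

#' Total component concentrations
#'
#' @param C_tot Total Cage concentration (molar).
#' @param K_tot Total Key concentration (molar).
#' @param T_tot Total target concentration (molar).
#' @return An object of class `switch_totals`.
#' @export
switch_totals <- function(C_tot, K_tot, T_tot) {
  stopifnot(
    is.numeric(C_tot), length(C_tot) == 1L, C_tot >= 0,
    is.numeric(K_tot), length(K_tot) == 1L, K_tot >= 0,
    is.numeric(T_tot), length(T_tot) == 1L, T_tot >= 0
  )
  structure(list(C_tot = C_tot, K_tot = K_tot, T_tot = T_tot),
            class = "switch_totals")
}

#' @export
print.switch_totals <- function(x, ...) {
  cat(sprintf("Totals: Cage %.3g M, Key %.3g M, target %.3g M\n",
              x$C_tot, x$K_tot, x$T_tot))
  invisible(x)
}

#' Linear readout model mapping key-bound fraction to a ratio
#'
#' @param R_min Ratio at zero key-bound fraction.
#' @param R_max Ratio at full key-bound fraction.
#' @return An object of class `readout_model`.
#' @export
readout_model <- function(R_min, R_max) {
  stopifnot(is.numeric(R_min), is.numeric(R_max),
            length(R_min) == 1L, length(R_max) == 1L,
            R_min > 0, R_max > R_min)
  structure(list(R_min = R_min, R_max = R_max), class = "readout_model")
}

#' Interface-destabilizing mutation effect
#'
#' A named free-energy perturbation applied to one of the switch's two
#' tunable protein:protein interfaces. Positive `ddG` weakens the named
#' interface: a latch effect raises `dG_close` (less closing), a key effect
#' scales `Kd_key` by `exp(ddG/RT)` (weaker key binding).
#'
#' @param name Identifier for the mutation.
#' @param interface `"latch"` or `"key"`.
#' @param ddG Destabilization in kcal/mol (positive weakens).
#' @return An object of class `mutation_effect`.
#' @export
mutation_effect <- function(name, interface, ddG) {
  interface <- match.arg(interface, c("latch", "key"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(ddG), length(ddG) == 1L, is.finite(ddG))
  structure(list(name = name, interface = interface, ddG = ddG),
            class = "mutation_effect")
}

#' Apply mutation effects to switch parameters
#'
#' Effects are additive per interface: latch effects add their ddG to
#' `dG_close`; key effects multiply `Kd_key` by `exp(ddG/RT)` (equivalently
#' add ddG to the key binding free energy).
#'
#' @param params A [switch_params()] object.
#' @param effects A list of [mutation_effect()] objects (possibly empty).
#' @return A new `switch_params` object.
#' @examples
#' sp <- switch_params(-2, 1e-6, 1e-7)
#' weaker_key <- mutation_effect("K1", "key", ddG = rt_kcal() * log(10))
#' apply_mutations(sp, list(weaker_key))$Kd_key / sp$Kd_key # 10
#' @export
apply_mutations <- function(params, effects) {
  stopifnot(inherits(params, "switch_params"), is.list(effects))
  rt <- rt_kcal(params$temperature_K)
  dG <- params$dG_close
  kdk <- params$Kd_key
  for (e in effects) {
    if (!inherits(e, "mutation_effect")) {
      stop("all elements of `effects` must be mutation_effect objects")
    }
    if (e$interface == "latch") {
      dG <- dG + e$ddG
    } else if (e$interface == "key") {
      kdk <- kdk * exp(e$ddG / rt)
    } else {
      stop("unknown interface: ", e$interface)
    }
  }
  switch_params(dG, kdk, params$Kd_target, params$temperature_K)
}
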