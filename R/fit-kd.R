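#' Refit the target dissociation constant from dose-response data
#'
#' Least-squares fit of `Kd_target` (on a log10 scale) to observed
#' key-bound-fraction measurements across a target titration, holding the
#' remaining switch parameters fixed at their supplied values. One-dimensional
#' golden-section/parabolic search via [stats::optimize()].
#'
#' @param data Data frame with columns `dose_M` and `signal` (replicate rows
#'   allowed).
#' @param params [switch_params()] holding the fixed parameters; its
#'   `Kd_target` is used only as a fallback search-interval center.
#' @param totals [switch_totals()]; `T_tot` is ignored.
#' @param interval Optional log10 search interval for `Kd_target`; defaults
#'   to the dosed range widened by four decades on each side.
#' @return An object of class `kd_fit` with methods `print`, `coef`,
#'   `predict`, and `plot`. `coef()` returns the fitted `Kd_target` (molar).
#' @examples
#' sp <- switch_params(-2, 1e-6, 1e-8)
#' tot <- switch_totals(1e-6, 1e-6, 0)
#' dr <- dose_response(sp, tot, c(0, 10^seq(-10, -6, 0.5)))
#' fit <- fit_kd_target(data.frame(dose_M = dr$dose_M, signal = dr$signal), sp, tot)
#' coef(fit)
#' @export
fit_kd_target <- function(data, params, totals, interval = NULL) {
  stopifnot(is.data.frame(data), all(c("dose_M", "signal") %in% names(data)),
            inherits(params, "switch_params"), inherits(totals, "switch_totals"))
  if (nrow(data) < 3L) stop("need at least 3 observations")
  if (is.null(interval)) {
    pos <- data$dose_M[data$dose_M > 0]
    if (length(pos) == 0L) stop("need at least one positive dose")
    interval <- c(log10(min(pos)) - 4, log10(max(pos)) + 4)
  }
  doses <- data$dose_M
  obs <- data$signal
  sse <- function(lkd) {
    s <- .solve_eq_vec(params$dG_close, params$Kd_key, 10^lkd,
                       totals$C_tot, totals$K_tot, doses,
                       temperature_K = params$temperature_K)
    pred <- s$P[, "key"] + s$P[, "key_target"]
    sum((obs - pred)^2)
  }
  opt <- stats::optimize(sse, interval = interval, tol = 1e-6)
  kd <- 10^opt$minimum
  fitted_params <- switch_params(params$dG_close, params$Kd_key, kd,
                                 params$temperature_K)
  structure(list(Kd_target = kd, sse = opt$objective, data = data,
                 params = fitted_params, totals = totals,
                 interval_log10 = interval),
            class = "kd_fit")
}

#' @export
coef.kd_fit <- function(object, ...) c(Kd_target = object$Kd_target)

#' @export
print.kd_fit <- function(x, ...) {
  cat("Target-affinity refit (1-D least squares on log10 Kd)\n")
  cat(sprintf("  Kd_target: %.4g M   SSE: %.4g   n = %d\n",
              x$Kd_target, x$sse, nrow(x$data)))
  invisible(x)
}

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  doses <- if (is.null(newdata)) sort(unique(object$data$dose_M)) else newdata$dose_M
  dr <- dose_response(object$params, object$totals, sort(doses))
  dr$signal[match(doses, dr$dose_M)]
}

#' @export
plot.kd_fit <- function(x, ...) {
  d <- x$data
  pos <- d$dose_M > 0
  plot(d$dose_M[pos], d$signal[pos], log = "x",
       xlab = "total target (M)", ylab = "key-bound fraction", ...)
  grid_d <- 10^seq(log10(min(d$dose_M[pos])), log10(max(d$dose_M[pos])), length.out = 50)
  lines(grid_d, predict(x, data.frame(dose_M = grid_d)))
  invisible(x)
}

#' @export
residuals.kd_fit <- function(object, ...) {
  object$data$signal - predict(object, object$data)
}
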