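#' Coincidence factor between two spike trains
#'
#' The chance-corrected fraction of coincident spikes,
#' `Gamma = (N_c - <N_c>) / (N_d + N_m) * 2 / (1 - 2 nu Delta)`,
#' where `N_d` and `N_m` are the reference and prediction spike counts,
#' `N_c` the number of coincidences within `delta`, and
#' `<N_c> = 2 nu N_d delta` the count expected from a Poisson process firing
#' at the prediction's rate `nu`. `Gamma = 1` only if every spike coincides;
#' a Poisson prediction at the reference rate scores 0 on average. The
#' definition is asymmetric: `nu` is always the prediction train's rate.
#'
#' Coincidences are counted by greedy in-order one-to-one matching (each
#' spike used at most once); for this interval structure greedy matching
#' attains the maximum bipartite matching.
#'
#' @param reference Reference [spike_train()] (the detailed model).
#' @param prediction Predicted [spike_train()] (the reduced model).
#' @param delta Coincidence window (ms).
#' @return An object of class `gamma_result` with fields `gamma`, `n_coinc`,
#'   `expected_nc`, `n_ref`, `n_pred`, `nu` (/ms), `delta`.
#' @examples
#' a <- spike_train(c(10, 50, 90), 100)
#' coincidence_factor(a, a)$gamma  # exactly 1
#' @export
coincidence_factor <- function(reference, prediction, delta = 4) {
  stopifnot(inherits(reference, "spike_train"),
            inherits(prediction, "spike_train"))
  duration <- reference$duration
  if (duration <= 0) abort("duration must be > 0")
  n_d <- length(reference$times)
  n_m <- length(prediction$times)
  nu <- n_m / prediction$duration
  corr <- 1 - 2 * nu * delta
  if (corr <= 0)
    abort(sprintf("degenerate rate: 1 - 2 nu delta = %.3g <= 0", corr))
  n_c <- count_coincidences_cpp(reference$times, prediction$times, delta)
  expected <- 2 * nu * n_d * delta
  gamma <- if (n_d + n_m == 0) NA_real_ else
    (n_c - expected) / (n_d + n_m) * 2 / corr
  structure(list(gamma = gamma, n_coinc = n_c, expected_nc = expected,
                 n_ref = n_d, n_pred = n_m, nu = nu, delta = delta),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> Gamma = %.3f (N_c = %d, N_ref = %d, N_pred = %d, delta = %g ms)\n",
              x$gamma, x$n_coinc, x$n_ref, x$n_pred, x$delta))
  invisible(x)
}

#' @export
tidy.gamma_result <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, n_coinc = x$n_coinc,
                 expected_nc = x$expected_nc, n_ref = x$n_ref,
                 n_pred = x$n_pred, nu = x$nu, delta = x$delta)
}

#' Interspike-interval statistics
#'
#' Firing rate, coefficient of variation of the ISIs, and the lag-1 serial
#' ISI correlation `rho_1 = <ISI_i ISI_(i+1) - <ISI>^2> / <ISI^2 - <ISI>^2>`
#' (plug-in autocorrelation with the global ISI mean). Fields that need more
#' spikes than available (cv: >= 3 spikes; rho1: >= 4 spikes and nonzero ISI
#' variance) are returned as `NA` rather than fabricated.
#'
#' @param train A [spike_train()].
#' @return An object of class `isi_stats` with fields `rate` (Hz), `cv`,
#'   `rho1`, `n_isi`.
#' @export
isi_stats <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  x <- diff(train$times)
  n <- length(x)
  cv <- if (n >= 2) sd(x) / mean(x) else NA_real_
  rho1 <- NA_real_
  if (n >= 3) {
    m <- mean(x)
    den <- mean(x^2) - m^2
    if (den > 0) rho1 <- (mean(x[-n] * x[-1]) - m^2) / den
  }
  structure(list(rate = firing_rate(train), cv = cv, rho1 = rho1, n_isi = n),
            class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  cat(sprintf("<isi_stats> rate = %.3f Hz, cv = %s, rho1 = %s (n_isi = %d)\n",
              x$rate, format(x$cv, digits = 3), format(x$rho1, digits = 3),
              x$n_isi))
  invisible(x)
}

#' @export
tidy.isi_stats <- function(x, ...) {
  tibble::tibble(rate = x$rate, cv = x$cv, rho1 = x$rho1, n_isi = x$n_isi)
}
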