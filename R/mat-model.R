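#' Multi-timescale threshold kernel
#'
#' The post-spike threshold kernel of the adaptive threshold model:
#' `H_u(t) = alpha_0 e^(-t/tau_m) + alpha_M e^(-t/tau_p) +
#' alpha_AHP (e^(-t/tau_ca) - e^(-t/tau_s))` for `t > 0` and 0 for
#' `t <= 0`. The fast term shares the membrane time constant; the M term
#' decays with the p-gate time constant evaluated at the mean subthreshold
#' voltage; the AHP term is a difference of exponentials at the Ca2+ and
#' s-gate time constants, so it starts at zero and has an interior maximum.
#'
#' @param alpha_0 Fast weight (mV).
#' @param tau_m Fast time constant = membrane time constant (ms).
#' @param alpha_M Slow M-type weight (mV).
#' @param tau_p M-term time constant (ms); 150 ms corresponds to a mean
#'   subthreshold voltage near -70 mV.
#' @param alpha_AHP AHP pair weight (mV).
#' @param tau_ca,tau_s AHP pair time constants (ms); must differ when
#'   `alpha_AHP != 0`.
#' @return An object of class `threshold_kernel`.
#' @examples
#' k <- threshold_kernel(alpha_0 = 35.5, tau_m = 10, alpha_M = 4.1, tau_p = 150)
#' kernel_eval(k, c(-5, 0, 10))
#' @export
threshold_kernel <- function(alpha_0, tau_m = 10, alpha_M = 0, tau_p = 150,
                             alpha_AHP = 0, tau_ca = 200, tau_s = 50) {
  if (any(c(tau_m, tau_p, tau_ca, tau_s) <= 0))
    abort("kernel time constants must be > 0")
  if (alpha_AHP != 0 && tau_ca == tau_s)
    abort("tau_ca and tau_s must differ when alpha_AHP != 0")
  structure(list(alpha_0 = alpha_0, tau_m = tau_m, alpha_M = alpha_M,
                 tau_p = tau_p, alpha_AHP = alpha_AHP, tau_ca = tau_ca,
                 tau_s = tau_s),
            class = "threshold_kernel")
}

#' @export
print.threshold_kernel <- function(x, ...) {
  cat(sprintf("<threshold_kernel> alpha_0 = %.3g mV (tau_m = %g ms)", x$alpha_0, x$tau_m))
  if (x$alpha_M != 0)
    cat(sprintf("; alpha_M = %.3g mV (tau_p = %g ms)", x$alpha_M, x$tau_p))
  if (x$alpha_AHP != 0)
    cat(sprintf("; alpha_AHP = %.3g mV (tau_Ca = %g, tau_s = %g ms)",
                x$alpha_AHP, x$tau_ca, x$tau_s))
  cat("\n")
  invisible(x)
}

#' Evaluate a threshold kernel
#'
#' @param kernel A [threshold_kernel()].
#' @param t Times since spike (ms), vectorized.
#' @return Kernel values (mV); exactly 0 for `t <= 0`.
#' @export
kernel_eval <- function(kernel, t) {
  out <- ifelse(t > 0,
                kernel$alpha_0 * exp(-t / kernel$tau_m) +
                  kernel$alpha_M * exp(-t / kernel$tau_p) +
                  kernel$alpha_AHP * (exp(-t / kernel$tau_ca) -
                                        exp(-t / kernel$tau_s)),
                0)
  as.numeric(out)
}

# Non-zero (alpha, tau) exponential pairs for the simulation core.
.kernel_terms <- function(kernel) {
  alpha <- c(kernel$alpha_0, kernel$alpha_M, kernel$alpha_AHP, -kernel$alpha_AHP)
  tau <- c(kernel$tau_m, kernel$tau_p, kernel$tau_ca, kernel$tau_s)
  keep <- alpha != 0
  if (!any(keep)) keep[1] <- TRUE
  list(alpha = alpha[keep], tau = tau[keep])
}

#' Parameters of the adaptive threshold (MAT) model
#'
#' The reduced neuron: a non-resetting leaky integrator
#' `du/dt = -u/tau_m + I_ex/C_m` that emits a spike whenever `u` reaches the
#' adaptive threshold `theta_u(t) = theta_inf + sum_k H_u(t - t_k)`; `u` is
#' never reset.
#'
#' @param theta_inf Resting threshold `theta_u^inf` (mV, relative to the
#'   effective resting potential).
#' @param kernel A [threshold_kernel()].
#' @param tau_m Membrane time constant (ms).
#' @param C_m Capacitance (uF/cm^2).
#' @param refractory Absolute refractory period (ms); prevents re-crossing
#'   on consecutive grid points since `u` does not reset.
#' @return An object of class `mat_params`.
#' @export
mat_params <- function(theta_inf, kernel, tau_m = 10, C_m = 1.0,
                       refractory = 2) {
  if (tau_m <= 0) abort("tau_m must be > 0")
  if (refractory < 0) abort("refractory must be >= 0")
  stopifnot(inherits(kernel, "threshold_kernel"))
  structure(list(theta_inf = theta_inf, kernel = kernel, tau_m = tau_m,
                 C_m = C_m, refractory = refractory), class = "mat_params")
}

#' @export
print.mat_params <- function(x, ...) {
  cat(sprintf("<mat_params> theta_inf = %.3g mV, tau_m = %g ms, refractory = %g ms\n",
              x$theta_inf, x$tau_m, x$refractory))
  print(x$kernel)
  invisible(x)
}

#' Simulate the adaptive threshold model
#'
#' Exact exponential integration of the subthreshold dynamics (the update is
#' exact for piecewise-constant input, so spike times depend on `dt` only
#' through threshold-crossing detection at grid points). The threshold is
#' maintained as one decaying accumulator per kernel exponential, giving
#' O(1) cost per step regardless of spike count.
#'
#' @param params A [mat_params()] object.
#' @param stimulus Numeric current vector (uA/cm^2) or tibble with `t`,
#'   `I_ex`.
#' @param dt Time step (ms) when `stimulus` is a bare vector.
#' @param u0 Initial potential (mV); default 0 (rest).
#' @param record Keep the `u` and `theta_u` series.
#' @return A list with `spikes` (a [spike_train()]); when `record = TRUE`
#'   also `trace`, a tibble with `t`, `u`, `theta`.
#' @examples
#' k <- threshold_kernel(alpha_0 = 35, tau_m = 10)
#' m <- mat_params(theta_inf = 30, kernel = k)
#' simulate_mat(m, rep(5, 40000))$spikes
#' @export
simulate_mat <- function(params, stimulus, dt = 0.025, u0 = 0,
                         record = FALSE) {
  if (is.data.frame(stimulus)) {
    I <- stimulus$I_ex
    tt <- stimulus$t
    if (length(tt) > 1) dt <- tt[2] - tt[1]
  } else {
    I <- as.numeric(stimulus)
    tt <- seq_along(I) * dt - dt
  }
  km <- .kernel_terms(params$kernel)
  res <- mat_sim_cpp(I, dt, params$tau_m, params$C_m, params$theta_inf,
                     km$alpha, km$tau, params$refractory, u0, record)
  duration <- dt * (length(I) - 1)
  out <- list(spikes = spike_train(res$spike_times, max(duration, dt)))
  if (record)
    out$trace <- tibble::tibble(t = tt, u = res$u, theta = res$theta)
  out
}
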