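#' Constant current with a delta pulse
#'
#' The pulse protocol: a constant holding current `I_c` plus a Dirac delta of
#' charge `q_c` at time `t_p`. On the discrete grid the delta is realized as
#' a single sample of extra amplitude `q_c / dt` at the grid point nearest
#' `t_p`, so the integrated injected charge is exactly `q_c`. When probing
#' protocols need an instantaneous voltage jump instead, the same charge is
#' applied as `V -> V + q_c / C_m` inside the probe itself.
#'
#' The pulse charge that lifts the membrane from a holding potential `V_c`
#' to -45 mV is `q_c = C_m * (-45 - V_c)` (see [pulse_charge()]).
#'
#' @param I_c Constant current (uA/cm^2).
#' @param q_c Pulse charge (nC/cm^2; numerically mV * uF/cm^2).
#' @param t_p Pulse time (ms).
#' @param duration Total stimulus length (ms).
#' @param dt Grid step (ms).
#' @return A tibble with columns `t`, `I_ex`; the constant component is kept
#'   in `attr(, "I_const")` and the pulse location in `attr(, "t_p")`.
#' @export
pulse_current <- function(I_c, q_c, t_p, duration, dt = 0.025) {
  if (dt <= 0 || duration <= 0) abort("dt and duration must be > 0")
  tt <- seq(0, duration, by = dt)
  if (t_p < 0 || t_p > duration) abort("t_p outside the stimulus window")
  I <- rep(I_c, length(tt))
  ip <- which.min(abs(tt - t_p))
  I[ip] <- I[ip] + q_c / dt
  out <- tibble::tibble(t = tt, I_ex = I)
  attr(out, "I_const") <- I_c
  attr(out, "t_p") <- tt[ip]
  attr(out, "dt") <- dt
  out
}

#' Pulse charge for a target depolarization to -45 mV
#'
#' @param V_c Holding voltage (mV).
#' @param C_m Membrane capacitance (uF/cm^2).
#' @return Charge in nC/cm^2.
#' @export
pulse_charge <- function(V_c, C_m = 1.0) C_m * (-45 - V_c)

#' Ornstein-Uhlenbeck input current
#'
#' Colored-noise current with mean `mu`, stationary SD `sigma` and
#' correlation time `tau_syn`, generated by the exact discretization
#' `I(t+dt) = mu + (I(t) - mu) e^(-dt/tau_syn) +
#' sigma sqrt(1 - e^(-2 dt/tau_syn)) xi`, with `I(0) ~ N(mu, sigma^2)`.
#' The exact update has no time-step bias, so tuned rates do not depend
#' on `dt`.
#'
#' @param mu Mean current (uA/cm^2).
#' @param sigma Stationary SD (uA/cm^2).
#' @param duration Length (ms).
#' @param tau_syn Correlation time (ms).
#' @param dt Grid step (ms).
#' @param seed Optional integer; when given, the series is reproducible and
#'   the global RNG state is left untouched.
#' @return A tibble with `t`, `I_ex` and attributes `I_const = mu`, `dt`.
#' @export
ou_current <- function(mu, sigma, duration, tau_syn = 2, dt = 0.025,
                       seed = NULL) {
  if (duration <= 0) abort("duration must be > 0")
  if (sigma < 0 || tau_syn <= 0) abort("sigma >= 0 and tau_syn > 0 required")
  n <- length(seq(0, duration, by = dt))
  gen <- function() {
    if (sigma == 0) return(rep(mu, n))
    a <- exp(-dt / tau_syn)
    b <- sigma * sqrt(1 - a^2)
    x0 <- rnorm(1, 0, sigma)
    dev <- stats::filter(b * rnorm(n), a, method = "recursive", init = x0)
    mu + as.numeric(dev)
  }
  I <- if (is.null(seed)) gen() else .with_seed(seed, gen())
  out <- tibble::tibble(t = seq(0, duration, by = dt), I_ex = I)
  attr(out, "I_const") <- mu
  attr(out, "dt") <- dt
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring the global state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Holding current for a target membrane potential
#'
#' Bisects on the constant current until the steady-state voltage matches
#' `V_c` within `tol`. Spiking at a trial current is treated as overshoot,
#' so targets above the spike threshold raise an error.
#'
#' @param params A [conductance_params()] object.
#' @param V_c Target holding voltage (mV), below the spike threshold.
#' @param tol Voltage tolerance (mV).
#' @param bracket Initial current interval (uA/cm^2).
#' @param dt Integration step (ms).
#' @return The holding current `I_c` (uA/cm^2).
#' @export
tune_holding_current <- function(params, V_c, tol = 0.05,
                                 bracket = c(-5, 5), dt = 0.025) {
  steady_V <- function(I) {
    st <- tryCatch(steady_state(params, I_c = I, dt = dt),
                   error = function(e) NULL)
    if (is.null(st)) Inf else st[["V"]]  # spiking counts as "too high"
  }
  lo <- bracket[1]; hi <- bracket[2]
  v_lo <- steady_V(lo); v_hi <- steady_V(hi)
  if (!is.finite(v_lo) || v_lo > V_c)
    abort(sprintf("V_c = %g below reach of bracket", V_c))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- steady_V(mid)
    if (is.finite(v) && abs(v - V_c) < tol) return(mid)
    if (v > V_c) hi <- mid else lo <- mid
  }
  abort(sprintf("V_c = %g mV unreachable without spiking", V_c))
}

#' Tune the OU mean current for a target firing rate
#'
#' Bisects on `mu` (with `sigma` slaved to `mu` by `sigma_rule`) until the
#' detailed model fires within `tol` (relative) of `target_rate`.
#'
#' @param params A [conductance_params()] object.
#' @param target_rate Target firing rate (Hz).
#' @param sigma_rule `"sigma=mu"` (moderate noise) or `"sigma=2mu"` (high
#'   noise).
#' @param duration Simulation length per trial (ms).
#' @param seed RNG seed for the OU realizations (the same realization shape
#'   is reused across trial `mu` values).
#' @param tol Relative rate tolerance.
#' @param bracket Initial `mu` interval (uA/cm^2).
#' @param dt Time step (ms).
#' @return The tuned `mu`; the achieved rate is in `attr(, "rate")`.
#' @export
tune_mean_for_rate <- function(params, target_rate,
                               sigma_rule = c("sigma=mu", "sigma=2mu"),
                               duration = 20000, seed = 1, tol = 0.1,
                               bracket = c(0.2, 8), dt = 0.025) {
  sigma_rule <- match.arg(sigma_rule)
  if (target_rate <= 0) abort("target_rate must be > 0")
  k <- if (sigma_rule == "sigma=mu") 1 else 2
  rest <- steady_state(params, I_c = 0, dt = dt)
  rate_at <- function(mu) {
    stim <- ou_current(mu, k * mu, duration, dt = dt, seed = seed)
    tr <- simulate_neuron(params, stim, dt = dt, init = rest)
    firing_rate(detect_spikes(tr))
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (r_lo > target_rate || r_hi < target_rate)
    abort(sprintf(paste0("bracket failure: rates [%.3g, %.3g] Hz at mu in ",
                         "[%g, %g] do not bracket target %g Hz"),
                  r_lo, r_hi, lo, hi, target_rate))
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_rate) <= tol * target_rate) {
      return(structure(mid, rate = r, sigma = k * mid))
    }
    if (r > target_rate) hi <- mid else lo <- mid
  }
  abort("rate tuning did not converge; noisy rate estimate may be non-monotone")
}

#' Printed input parameters of the spike-prediction protocol
#'
#' The six (mu, sigma) pairs per neuron used for the coincidence-factor
#' evaluation: three moderately noisy inputs (`sigma = mu`) and three highly
#' noisy inputs (`sigma = 2 mu`), targeting 5, 10 and 20 Hz.
#'
#' @param neuron `"M"` for the M-current neuron (g_M = 0.2) or `"AHP"` for
#'   the AHP neuron (g_AHP = 0.2).
#' @return A tibble with columns `input` ("M"/"H"), `target_rate`, `mu`,
#'   `sigma`.
#' @export
evaluation_inputs <- function(neuron = c("M", "AHP")) {
  neuron <- match.arg(neuron)
  if (neuron == "M") {
    mu <- c(1.98, 2.45, 3.24, 1.33, 1.65, 2.22)
    sg <- c(1.98, 2.45, 3.24, 2.66, 3.30, 4.44)
  } else {
    mu <- c(1.84, 2.15, 2.75, 1.28, 1.58, 2.10)
    sg <- c(1.84, 2.15, 2.75, 2.56, 3.16, 4.20)
  }
  tibble::tibble(input = rep(c("M", "H"), each = 3),
                 target_rate = rep(c(5, 10, 20), 2),
                 mu = mu, sigma = sg)
}
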