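#' Holding-plus-pulse protocol with full state recording
#'
#' The standard probing protocol: hold the neuron at `V_c` with a tuned
#' constant current, then at `t_p` inject the pulse charge
#' `q_c = C_m (-45 - V_c)` as an instantaneous voltage shift to -45 mV,
#' which evokes exactly one spike. The full state (voltage, gates, Ca2+,
#' per-ion currents) is recorded so that any instant of the protocol can
#' serve as a threshold-probe starting point.
#'
#' @param params A [conductance_params()] object.
#' @param V_c Holding voltage (mV).
#' @param t_p Pulse time (ms).
#' @param post Recording length after the pulse (ms).
#' @param dt Time step (ms).
#' @return A list of class `probe_protocol`: `trace` (with currents, gates),
#'   `params`, `I_c`, `V_c`, `t_p`, `spike_time` (first 0 mV upward
#'   crossing), `dt`.
#' @export
evoked_spike_protocol <- function(params, V_c = -70, t_p = 200, post = 600,
                                  dt = 0.025) {
  I_c <- tune_holding_current(params, V_c, dt = dt)
  init <- steady_state(params, I_c = I_c, dt = dt)
  nA <- round(t_p / dt)
  trA <- simulate_neuron(params, rep(I_c, nA + 1), dt = dt, init = init,
                         record_currents = TRUE, record_gates = TRUE)
  stA <- attr(trA, "final_state")
  stA[["V"]] <- stA[["V"]] + pulse_charge(V_c, params$C_m) / params$C_m
  nB <- round(post / dt)
  trB <- simulate_neuron(params, rep(I_c, nB + 1), dt = dt, init = stA,
                         record_currents = TRUE, record_gates = TRUE)
  trB$t <- trB$t + t_p
  trace <- dplyr::bind_rows(trA[-nrow(trA), ], trB)
  attr(trace, "dt") <- dt
  class(trace) <- c("neuron_trace", class(tibble::tibble()))
  sp <- detect_spikes(trace)
  spike_time <- sp$times[sp$times >= t_p][1]
  structure(list(trace = trace, params = params, I_c = I_c, V_c = V_c,
                 t_p = t_p, spike_time = spike_time, dt = dt),
            class = "probe_protocol")
}

# Full state vector at grid time t0 (requires gate recording in the trace).
.state_at <- function(protocol, t0) {
  tr <- protocol$trace
  i <- which.min(abs(tr$t - t0))
  st <- c(V = tr$V[i], m = tr$m[i], h = tr$h[i], n = tr$n[i], p = tr$p[i],
          q = tr$q[i], r = tr$r[i], s = tr$s[i], Ca = tr$Ca[i])
  st
}

#' Instantaneous spike threshold by bisection
#'
#' The spike threshold at a given state is the lowest voltage `c` such that
#' instantaneously shifting `V -> c` (gates and Ca2+ untouched) triggers a
#' spike within the observation horizon. `c` is bisected over `interval`:
#' when the trial shift spikes the upper end moves down, otherwise the lower
#' end moves up, until the interval is narrower than `tol`.
#'
#' @param params A [conductance_params()] object.
#' @param state A full state vector (from [steady_state()] or a recorded
#'   protocol).
#' @param I_c Constant background current during the probe (uA/cm^2).
#' @param horizon Observation window for a spike (ms).
#' @param interval Initial voltage bracket (mV).
#' @param tol Termination width (mV).
#' @param level Spike detection level (mV).
#' @param dt Time step (ms).
#' @return A list of class `threshold_sample`: `theta_V` (mV), `q_min`
#'   (nC/cm^2), `V_pre` (mV). `theta_V = V_pre + q_min / C_m`.
#' @export
instantaneous_threshold <- function(params, state, I_c = 0, horizon = 50,
                                    interval = c(-80, 0), tol = 1e-4,
                                    level = 0, dt = 0.025) {
  pv <- .param_vec(params)
  st <- as.numeric(state)
  spikes_at <- function(cc)
    hh_first_crossing_cpp(pv, st, cc, I_c, horizon, dt, level) >= 0
  a <- interval[1]; b <- interval[2]
  if (spikes_at(a) || !spikes_at(b))
    abort(sprintf(paste0("bisection bracket failure: ends of [%g, %g] do not ",
                         "separate spiking from non-spiking"), a, b))
  while (b - a > tol) {
    cc <- (a + b) / 2
    if (spikes_at(cc)) b <- cc else a <- cc
  }
  theta <- (a + b) / 2
  V_pre <- state[["V"]]
  structure(list(theta_V = theta, q_min = params$C_m * (theta - V_pre),
                 V_pre = V_pre),
            class = "threshold_sample")
}

#' @export
print.threshold_sample <- function(x, ...) {
  cat(sprintf("<threshold_sample> theta_V = %.4f mV (V_pre = %.2f, q_min = %.3f nC/cm^2)\n",
              x$theta_V, x$V_pre, x$q_min))
  invisible(x)
}

#' Post-spike threshold recovery curve
#'
#' Evokes a single spike with the holding-plus-pulse protocol and measures
#' the instantaneous threshold at a set of lags after the spike. In
#' adaptation-free neurons the curve plateaus within tens of ms; slow K+
#' currents keep the threshold elevated for hundreds of ms.
#'
#' @param params A [conductance_params()] object.
#' @param lags Probe lags after the evoked spike (ms), increasing.
#' @param V_c Holding voltage (mV).
#' @param protocol Optionally a precomputed [evoked_spike_protocol()] (its
#'   `post` window must cover `max(lags) + 1` ms).
#' @inheritParams instantaneous_threshold
#' @return A tibble with `lag`, `theta_V`, `q_min`, `V_pre`.
#' @export
postspike_threshold_curve <- function(params, lags, V_c = -70,
                                      protocol = NULL, horizon = 50,
                                      tol = 1e-4, dt = 0.025) {
  if (is.null(protocol))
    protocol <- evoked_spike_protocol(params, V_c = V_c,
                                      post = max(lags) + horizon + 20,
                                      dt = dt)
  if (is.na(protocol$spike_time))
    abort("the pulse protocol did not evoke a spike")
  rows <- purrr::map(lags, function(lag) {
    st <- .state_at(protocol, protocol$spike_time + lag)
    th <- instantaneous_threshold(params, st, I_c = protocol$I_c,
                                  horizon = horizon, tol = tol, dt = dt)
    tibble::tibble(lag = lag, theta_V = th$theta_V, q_min = th$q_min,
                   V_pre = th$V_pre)
  })
  dplyr::bind_rows(rows)
}

#' Spike-triggered slow K+ current
#'
#' The deviation of a slow ionic current from its holding baseline after a
#' single evoked spike: `eta_ion(t) = I_ion(t_onset + t) - I_ion(holding)`,
#' with the spike onset taken at the pulse time. Fast Na+/Kd/Ca transients
#' die out within a few ms, so the analysis window conventionally starts
#' 4 ms after onset.
#'
#' @param params A [conductance_params()] object.
#' @param ion `"M"` or `"AHP"`.
#' @param V_c Holding voltage (mV).
#' @param window Analysis window after spike onset (ms), default `c(4, 500)`.
#' @param dt Time step (ms).
#' @param protocol Optional precomputed [evoked_spike_protocol()].
#' @return A tibble with `t` (ms after onset) and `eta` (uA/cm^2), with
#'   attributes `v_bar` (mean voltage over the window, mV), `delta_p`,
#'   `delta_Ca` (per-spike increments measured 4 ms post-onset), `ion`,
#'   `tau_slow` (the fixed-form slow time constant(s) implied by `params`
#'   and `v_bar`).
#' @export
spike_triggered_current <- function(params, ion = c("M", "AHP"), V_c = -70,
                                    window = c(4, 500), dt = 0.025,
                                    protocol = NULL) {
  ion <- match.arg(ion)
  if (is.null(protocol))
    protocol <- evoked_spike_protocol(params, V_c = V_c,
                                      post = window[2] + 20, dt = dt)
  tr <- protocol$trace
  t_on <- protocol$t_p
  col <- if (ion == "M") "I_M" else "I_AHP"
  i_pre <- max(which(tr$t < t_on))
  baseline <- tr[[col]][i_pre]
  sel <- tr$t >= t_on + window[1] & tr$t <= t_on + window[2]
  sp <- detect_spikes(tr)
  extra <- sp$times[sp$times > t_on + 1 & sp$times <= t_on + window[2]]
  if (length(extra) > 1)
    abort("second spike inside the analysis window contaminates eta")
  out <- tibble::tibble(t = tr$t[sel] - t_on, eta = tr[[col]][sel] - baseline)
  v_bar <- mean(tr$V[sel])
  i4 <- which.min(abs(tr$t - (t_on + 4)))
  delta_p <- tr$p[i4] - tr$p[i_pre]
  delta_Ca <- tr$Ca[i4] - tr$Ca[i_pre]
  attr(out, "ion") <- ion
  attr(out, "v_bar") <- v_bar
  attr(out, "delta_p") <- delta_p
  attr(out, "delta_Ca") <- delta_Ca
  attr(out, "tau_slow") <- if (ion == "M")
    c(tau = tau_p(v_bar, params$tau_max)) else
      c(tau_ca = params$tau_Ca, tau_s = 1 / params$beta_s)
  out
}

#' Fit the fixed-form kernel component to an extracted series
#'
#' Least-squares fit of `a e^(-t/tau)` (M-type) or
#' `a (e^(-t/tau_ca) - e^(-t/tau_s))` (AHP-type) to a spike-triggered
#' current or threshold-variation series. With fixed time constants the
#' amplitude is the closed-form linear least-squares solution; with
#' `free_taus = TRUE` the time constant(s) are fitted too, by nonlinear
#' least squares started from the fixed values.
#'
#' @param series A two-column data frame: time since spike (ms) and value
#'   (uA/cm^2 for eta, mV for h). Output of [spike_triggered_current()] or
#'   [threshold_variation()].
#' @param ion `"M"` or `"AHP"`; defaults to the series' `ion` attribute.
#' @param taus Fixed time constants: single value for M, `c(tau_ca, tau_s)`
#'   for AHP; defaults to the series' `tau_slow` attribute.
#' @param free_taus Also fit the time constants.
#' @param component `"eta"` (current) or `"h"` (threshold variation); only
#'   recorded in the result.
#' @return A list of class `kernel_component_fit`: `ion`, `component`,
#'   `amplitude`, `tau_slow`, `v_bar`, `delta`, `rms_residual`.
#' @export
fit_eta <- function(series, ion = NULL, taus = NULL, free_taus = FALSE,
                    component = "eta") {
  if (is.null(ion)) ion <- attr(series, "ion")
  ion <- match.arg(ion, c("M", "AHP"))
  if (is.null(taus)) taus <- attr(series, "tau_slow")
  if (is.null(taus)) abort("taus must be supplied (no tau_slow attribute)")
  tt <- series[[1]]
  y <- series[[2]]
  basis <- function(tau) {
    if (ion == "M") exp(-tt / tau[1])
    else exp(-tt / tau[1]) - exp(-tt / tau[2])
  }
  if (free_taus) {
    df <- data.frame(tt = tt, y = y)
    a0 <- sum(y * basis(taus)) / sum(basis(taus)^2)
    fit <- if (ion == "M") {
      .nls_fit(y ~ a * exp(-tt / tau), df,
               list(a = a0, tau = unname(taus[1])))
    } else {
      .nls_fit(y ~ a * (exp(-tt / tau1) - exp(-tt / tau2)), df,
               list(a = a0, tau1 = unname(taus[1]), tau2 = unname(taus[2])))
    }
    cf <- coef(fit)
    a <- cf[["a"]]
    taus <- if (ion == "M") c(tau = cf[["tau"]]) else
      c(tau_ca = cf[["tau1"]], tau_s = cf[["tau2"]])
    if (any(taus <= 0)) abort("fit failure: negative fitted time constant")
    resid <- y - stats::predict(fit)
  } else {
    b <- basis(taus)
    a <- sum(y * b) / sum(b * b)
    resid <- y - a * b
  }
  structure(list(ion = ion, component = component, amplitude = a,
                 tau_slow = taus, v_bar = attr(series, "v_bar"),
                 delta = c(delta_p = attr(series, "delta_p"),
                           delta_Ca = attr(series, "delta_Ca")),
                 rms_residual = sqrt(mean(resid^2))),
            class = "kernel_component_fit")
}

.nls_fit <- function(formula, data, start) {
  if (requireNamespace("minpack.lm", quietly = TRUE))
    minpack.lm::nlsLM(formula, data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  else
    stats::nls(formula, data = data, start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
}

#' @export
print.kernel_component_fit <- function(x, ...) {
  cat(sprintf("<kernel_component_fit> %s (%s): amplitude = %.4g, tau = %s ms, rms = %.3g\n",
              x$component, x$ion, x$amplitude,
              paste(signif(x$tau_slow, 4), collapse = "/"), x$rms_residual))
  invisible(x)
}

#' @export
tidy.kernel_component_fit <- function(x, ...) {
  tibble::tibble(ion = x$ion, component = x$component,
                 amplitude = x$amplitude,
                 tau1 = unname(x$tau_slow[1]),
                 tau2 = if (length(x$tau_slow) > 1) unname(x$tau_slow[2]) else NA_real_,
                 v_bar = x$v_bar %||% NA_real_,
                 rms_residual = x$rms_residual)
}

#' Post-spike threshold variation attributable to one slow current
#'
#' The difference between the post-spike threshold curves of a neuron with
#' the slow conductance under study and the matched neuron without it,
#' `h_ion(lag) = theta_V^with(lag) - theta_V^without(lag)`, with each
#' neuron's pre-spike (holding) threshold subtracted first, so that `h`
#' isolates the spike-triggered threshold change and decays to zero. (The
#' tonically active fraction of the slow current shifts the resting
#' threshold of the two neurons by a constant that belongs to
#' `theta_V^inf`, not to the kernel.)
#'
#' @param params_with,params_without [conductance_params()] differing only
#'   in the slow conductance under study.
#' @param lags Probe lags after the evoked spike (ms).
#' @param V_c Holding voltage (mV).
#' @param dt Time step (ms).
#' @param ... Passed to [postspike_threshold_curve()].
#' @return A tibble with `lag`, `h`, `theta_with`, `theta_without`;
#'   attributes as in [spike_triggered_current()] when derivable.
#' @export
threshold_variation <- function(params_with, params_without, lags,
                                V_c = -70, dt = 0.025, ...) {
  rest_theta <- function(params) {
    Ic <- tune_holding_current(params, V_c, dt = dt)
    st <- steady_state(params, I_c = Ic, dt = dt)
    instantaneous_threshold(params, st, I_c = Ic, dt = dt)$theta_V
  }
  cw <- postspike_threshold_curve(params_with, lags, V_c = V_c, dt = dt, ...)
  co <- postspike_threshold_curve(params_without, lags, V_c = V_c, dt = dt, ...)
  dw <- cw$theta_V - rest_theta(params_with)
  do <- co$theta_V - rest_theta(params_without)
  out <- tibble::tibble(lag = lags, h = dw - do,
                        theta_with = cw$theta_V, theta_without = co$theta_V)
  ion <- if (params_with$g_M != params_without$g_M) "M" else "AHP"
  attr(out, "ion") <- ion
  attr(out, "tau_slow") <- if (ion == "M")
    c(tau = tau_p(mean(cw$V_pre), params_with$tau_max)) else
      c(tau_ca = params_with$tau_Ca, tau_s = 1 / params_with$beta_s)
  out
}

#' Reset-rule statistics of the spike waveform
#'
#' Measures the effective spike width `w_sp` and per-spike voltage change
#' `delta_V` used by the reduction's reset rule `t -> t + w_sp`,
#' `V -> V + delta_V`. The onset is the pulse time (where the voltage is
#' shifted to -45 mV); the spike is considered over when the fast
#' repolarization has finished, i.e. at the first post-peak sample where the
#' downstroke has flattened to less than 1 mV/ms (the slow
#' afterhyperpolarization is an order of magnitude flatter).
#'
#' @param protocol An [evoked_spike_protocol()] result.
#' @return A list with `w_sp` (ms), `delta_V` (mV), `t_peak`, `V_peak`.
#' @export
spike_waveform_stats <- function(protocol) {
  tr <- protocol$trace
  t_on <- protocol$t_p
  i_on <- which.min(abs(tr$t - t_on))
  sel <- which(tr$t >= t_on & tr$t <= t_on + 20)
  i_peak <- sel[which.max(tr$V[sel])]
  V <- tr$V
  dt <- protocol$dt
  nmax <- nrow(tr) - 1
  i <- i_peak
  while (i < nmax && (V[i + 1] - V[i]) / dt >= -1) i <- i + 1  # enter downstroke
  while (i < nmax && (V[i + 1] - V[i]) / dt < -1) i <- i + 1   # ride until flat
  w_sp <- tr$t[i] - t_on
  delta_V <- V[i] - V[i_on]
  list(w_sp = w_sp, delta_V = delta_V, t_peak = tr$t[i_peak],
       V_peak = V[i_peak])
}

#' Scaling predictor for the slow kernel weights
#'
#' The reduction predicts the slow threshold weights up to a common
#' proportionality constant: `alpha_M ~ g_M (v_bar - E_K) delta_p / tau_max`
#' and `alpha_AHP ~ g_AHP (v_bar - E_K) delta_Ca tau_Ca tau_s /
#' (tau_Ca - tau_s)`. Useful for comparing fitted weights across parameter
#' grids, not for absolute prediction.
#'
#' @param ion `"M"` or `"AHP"`.
#' @param params A [conductance_params()] object.
#' @param v_bar Mean post-spike voltage (mV).
#' @param delta Per-spike gate increment `delta_p` (M) or Ca2+ increment
#'   `delta_Ca` in uM (AHP).
#' @return The unnormalized predictor (arbitrary units).
#' @export
alpha_scaling_predictor <- function(ion = c("M", "AHP"), params, v_bar,
                                    delta) {
  ion <- match.arg(ion)
  if (ion == "M") {
    if (delta <= 0 || delta > 1) abort("delta_p must lie in (0, 1]")
    params$g_M * (v_bar - params$E_K) * delta / (params$tau_max * 1000)
  } else {
    tau_s <- 1 / params$beta_s
    if (abs(params$tau_Ca - tau_s) < 1e-9)
      abort("singular: tau_Ca equals the s-gate time constant")
    if (delta <= 0) abort("delta_Ca must be > 0")
    params$g_AHP * (v_bar - params$E_K) * delta *
      params$tau_Ca * tau_s / (params$tau_Ca - tau_s)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
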