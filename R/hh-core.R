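.GATES <- c("m", "h", "n", "p", "q", "r", "s")

#' Voltage- and calcium-dependent gate kinetics
#'
#' Opening (`alpha`) and closing (`beta`) rates of the seven gating variables.
#' Removable singularities in the rational rate functions (e.g. the Na+
#' activation rate at V = -45 mV) are evaluated by their analytic limits.
#' The p-gate rates are derived from its equilibrium value and voltage-
#' dependent time constant; the s-gate opening rate is proportional to the
#' intracellular Ca2+ concentration.
#'
#' @param gate One of `"m"`, `"h"`, `"n"`, `"p"`, `"q"`, `"r"`, `"s"`.
#' @param V Membrane voltage(s), mV.
#' @param Ca Ca2+ concentration (uM); only the s-gate depends on it.
#' @param params A [conductance_params()] object (supplies `tau_max`, `beta_s`).
#' @return A tibble with columns `gate`, `V`, `alpha`, `beta` (rates in /ms).
#' @examples
#' gate_rates("m", V = -45)  # evaluated at the removable singularity
#' @export
gate_rates <- function(gate, V, Ca = NULL, params = conductance_params()) {
  gate <- match.arg(gate, .GATES)
  if (is.null(Ca)) Ca <- params$Ca_inf
  stopifnot(all(is.finite(V)))
  m <- gate_rates_cpp(.param_vec(params), as.numeric(V), as.numeric(Ca))
  gi <- match(gate, .GATES)
  tibble::tibble(gate = gate, V = as.numeric(V),
                 alpha = m[, gi], beta = m[, 7 + gi])
}

# Equilibrium value of every gate at (V, Ca): alpha/(alpha+beta)
.gate_steady <- function(V, Ca, params) {
  m <- gate_rates_cpp(.param_vec(params), V, Ca)
  a <- m[1, 1:7]
  b <- m[1, 8:14]
  setNames(a / (a + b), .GATES)
}

#' p-gate time constant and equilibrium activation
#'
#' The M-current gate relaxes with `tau_p(V) = tau_max / (3.3 e^((V+35)/20)
#' + e^(-(V+35)/20))` toward `p_inf(V) = 1 / (1 + e^(-(V+35)/10))`.
#'
#' @param V Voltage (mV), vectorized.
#' @param tau_max Time-constant scale in seconds.
#' @return `tau_p()`: time constant in ms; `p_inf()`: dimensionless.
#' @export
tau_p <- function(V, tau_max = 1.0) {
  1000 * tau_max / (3.3 * exp((V + 35) / 20) + exp(-(V + 35) / 20))
}

#' @rdname tau_p
#' @export
p_inf <- function(V) 1 / (1 + exp(-(V + 35) / 10))

#' Neuron state vector
#'
#' A full instantaneous state: voltage, the seven gates, and the Ca2+
#' concentration. Gates default to their equilibrium at (`V`, `Ca`).
#'
#' @param V Voltage (mV).
#' @param Ca Ca2+ concentration (uM).
#' @param params A [conductance_params()] object.
#' @param gates Optional named vector overriding the equilibrium gates.
#' @return Named numeric vector `c(V, m, h, n, p, q, r, s, Ca)`.
#' @export
neuron_state <- function(V = -70, Ca = NULL, params = conductance_params(),
                         gates = NULL) {
  if (is.null(Ca)) Ca <- params$Ca_inf
  g <- .gate_steady(V, Ca, params)
  if (!is.null(gates)) g[names(gates)] <- gates
  if (any(g < 0 | g > 1)) abort("gate values must lie in [0, 1]")
  if (Ca < 0) abort("Ca must be >= 0")
  c(V = V, g, Ca = Ca)
}

#' Relax the neuron to its steady state under a constant current
#'
#' Integrates the model under constant current `I_c` until every state
#' derivative falls below `tol`. The current must be subthreshold: a spike
#' during relaxation is an error.
#'
#' @param params A [conductance_params()] object.
#' @param I_c Constant current (uA/cm^2).
#' @param V_init Starting voltage (mV); gates start at equilibrium for it.
#' @param dt Integration step (ms).
#' @param max_ms Relaxation budget (ms).
#' @param tol Convergence tolerance on the largest state derivative
#'   (mV/ms for V, /ms for gates, uM/ms for Ca).
#' @return A named state vector as from [neuron_state()].
#' @export
steady_state <- function(params = conductance_params(), I_c = 0,
                         V_init = NULL, dt = 0.025, max_ms = 20000,
                         tol = 1e-7) {
  if (is.null(V_init)) V_init <- params$E_L + I_c / max(params$g_L, 1e-6)
  init <- neuron_state(V = V_init, params = params)
  res <- hh_relax_cpp(.param_vec(params), I_c, dt, init, max_ms, tol)
  if (res$spiked)
    abort(sprintf("current I_c = %g is not subthreshold: spike during relaxation", I_c))
  if (!res$converged)
    abort(sprintf("no steady state within %g ms (tol %g)", max_ms, tol))
  setNames(as.numeric(res$state), c("V", .GATES, "Ca"))
}

#' Simulate the conductance-based neuron
#'
#' Forward-Euler integration of the full model under an arbitrary injected
#' current. The default initial condition is the steady state at the
#' stimulus's constant component (stimuli built by [pulse_current()] carry
#' it; otherwise 0 is assumed), so protocols start from rest.
#'
#' @param params A [conductance_params()] object.
#' @param stimulus Either a numeric vector of currents (uA/cm^2), one per
#'   grid point, or a tibble with columns `t` and `I_ex`.
#' @param dt Time step (ms). Ignored when `stimulus` carries its own grid.
#' @param init Initial state (named vector from [neuron_state()] or
#'   [steady_state()]); `NULL` relaxes to steady state first.
#' @param record_currents,record_gates Record per-ion currents / gating
#'   variables and Ca2+ alongside the voltage.
#' @return A `neuron_trace` tibble with columns `t`, `I_ex`, `V` and,
#'   optionally, `I_L`, `I_Na`, `I_Kd`, `I_M`, `I_Ca`, `I_AHP` and the gate
#'   and `Ca` series. The time step is stored in `attr(, "dt")`.
#' @examples
#' stim <- pulse_current(I_c = 0, q_c = 0, t_p = 1, duration = 50, dt = 0.025)
#' tr <- simulate_neuron(neuron_noadapt(), stim)
#' @export
simulate_neuron <- function(params, stimulus, dt = 0.025, init = NULL,
                            record_currents = FALSE, record_gates = FALSE) {
  if (is.data.frame(stimulus)) {
    tt <- stimulus$t
    I <- stimulus$I_ex
    if (length(tt) > 1) dt <- tt[2] - tt[1]
  } else {
    I <- as.numeric(stimulus)
    tt <- seq_along(I) * dt - dt
  }
  if (dt <= 0) abort("dt must be > 0")
  if (is.null(init)) {
    I0 <- attr(stimulus, "I_const")
    if (is.null(I0)) I0 <- 0
    init <- steady_state(params, I_c = I0, dt = dt)
  }
  res <- hh_sim_cpp(.param_vec(params), I, dt, init,
                    record_currents, record_gates)
  out <- tibble::tibble(t = tt, I_ex = I, V = res$V)
  if (record_currents) {
    cn <- c("I_L", "I_Na", "I_Kd", "I_M", "I_Ca", "I_AHP")
    for (k in seq_along(cn)) out[[cn[k]]] <- res$currents[, k]
  }
  if (record_gates) {
    gn <- c(.GATES, "Ca")
    for (k in seq_along(gn)) out[[gn[k]]] <- res$gates[, k]
  }
  attr(out, "dt") <- dt
  attr(out, "final_state") <- setNames(as.numeric(res$final_state),
                                       c("V", .GATES, "Ca"))
  class(out) <- c("neuron_trace", class(tibble::tibble()))
  out
}

#' Spike trains
#'
#' A spike train is a strictly increasing vector of spike times within an
#' observation window.
#'
#' @param times Spike times (ms), strictly increasing.
#' @param duration Observation length (ms).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (length(times) && (is.unsorted(times, strictly = TRUE)))
    abort("spike times must be strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    abort("spike times must lie within [0, duration]")
  if (duration <= 0) abort("duration must be > 0")
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g ms (%.2f Hz)\n",
              length(x$times), x$duration, 1000 * length(x$times) / x$duration))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Detect spikes in a voltage trace
#'
#' A spike time is the upward crossing of `level` (default 0 mV), located by
#' linear interpolation between samples. Crossings closer than `debounce` to
#' the previous accepted spike are discarded, so one action potential yields
#' one spike.
#'
#' @param trace A `neuron_trace` tibble (or any tibble with `t` and `V`).
#' @param level Detection level (mV).
#' @param debounce Minimal separation between detected spikes (ms).
#' @return A [spike_train()].
#' @export
detect_spikes <- function(trace, level = 0, debounce = 2) {
  V <- trace$V
  tt <- trace$t
  if (!length(V)) abort("empty trace")
  up <- which(V[-length(V)] <= level & V[-1] > level)
  times <- tt[up] + (level - V[up]) / (V[up + 1] - V[up]) * (tt[up + 1] - tt[up])
  if (length(times) > 1) {
    # debounce against the last *kept* spike, not just the previous crossing
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= debounce) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  duration <- tt[length(tt)] - tt[1]
  spike_train(times, max(duration, if (length(times)) max(times) else 0))
}

#' Firing rate of a spike train
#' @param train A [spike_train()].
#' @return Rate in Hz.
#' @export
firing_rate <- function(train) 1000 * length(train$times) / train$duration
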