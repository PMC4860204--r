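#' Closed-form membrane filtering of an exponential current
#'
#' The contribution of an exponential spike-triggered current
#' `a e^(-t/tau)` to the effective threshold kernel is its convolution with
#' the membrane filter `e^(-t/tau_m) / C_m`, which evaluates to
#' `a tau tau_m / (C_m (tau - tau_m)) (e^(-t/tau) - e^(-t/tau_m))`
#' (and `a t e^(-t/tau_m) / C_m` in the degenerate case `tau = tau_m`).
#'
#' @param a Current amplitude (uA/cm^2).
#' @param tau Current decay time (ms).
#' @param tau_m Membrane time constant (ms).
#' @param C_m Capacitance (uF/cm^2).
#' @param t Times (ms), vectorized.
#' @return Filtered contribution (mV).
#' @export
filtered_exponential <- function(a, tau, tau_m, C_m, t) {
  if (abs(tau - tau_m) < 1e-9) return(a * t * exp(-t / tau_m) / C_m)
  a * tau * tau_m / (C_m * (tau - tau_m)) * (exp(-t / tau) - exp(-t / tau_m))
}

#' Assemble the theory-driven threshold kernel
#'
#' Combines the three measured ingredients of the reduction into an
#' effective threshold kernel: (i) the reset term
#' `-delta_V e^(-(t - w_sp)/tau_m)` from the spike waveform, (ii) the
#' membrane-filtered spike-triggered currents, and (iii) the direct
#' threshold variations `h_ion(t)`. The exact assembled kernel is then
#' projected by least squares (on a dense time grid) onto the
#' multi-timescale parametric family, yielding `alpha_0` and the slow
#' weight.
#'
#' @param eta_fits List of [fit_eta()] results for spike-triggered currents
#'   (component `"eta"`).
#' @param h_fits List of [fit_eta()] results for threshold variations
#'   (component `"h"`).
#' @param waveform List with `w_sp` (ms) and `delta_V` (mV), from
#'   [spike_waveform_stats()].
#' @param tau_m Membrane time constant (ms).
#' @param C_m Capacitance (uF/cm^2).
#' @param t_grid Projection grid (ms).
#' @return A [threshold_kernel()]; `attr(, "projection_rms")` reports the
#'   residual of the family projection, `attr(, "exact")` the assembled
#'   kernel as a function of `t`.
#' @export
assemble_theory_kernel <- function(eta_fits = list(), h_fits = list(),
                                   waveform, tau_m = 10, C_m = 1,
                                   t_grid = seq(0.5, 800, by = 0.5)) {
  if (is.null(waveform$w_sp) || is.null(waveform$delta_V))
    abort("waveform must supply w_sp and delta_V")
  if (inherits(eta_fits, "kernel_component_fit")) eta_fits <- list(eta_fits)
  if (inherits(h_fits, "kernel_component_fit")) h_fits <- list(h_fits)
  exact <- function(t) {
    out <- -waveform$delta_V * exp(-(t - waveform$w_sp) / tau_m)
    for (f in eta_fits) {
      if (f$ion == "M") {
        out <- out + filtered_exponential(f$amplitude, f$tau_slow[[1]],
                                          tau_m, C_m, t)
      } else {
        out <- out +
          filtered_exponential(f$amplitude, f$tau_slow[[1]], tau_m, C_m, t) -
          filtered_exponential(f$amplitude, f$tau_slow[[2]], tau_m, C_m, t)
      }
    }
    for (f in h_fits) {
      if (f$ion == "M") {
        out <- out + f$amplitude * exp(-t / f$tau_slow[[1]])
      } else {
        out <- out + f$amplitude * (exp(-t / f$tau_slow[[1]]) -
                                      exp(-t / f$tau_slow[[2]]))
      }
    }
    out
  }
  fits <- c(eta_fits, h_fits)
  ion <- if (length(fits)) fits[[1]]$ion else "none"
  y <- exact(t_grid)
  X1 <- exp(-t_grid / tau_m)
  if (ion == "none") {
    co <- sum(y * X1) / sum(X1^2)
    kern <- threshold_kernel(alpha_0 = co, tau_m = tau_m)
    resid <- y - co * X1
  } else if (ion == "M") {
    taus <- fits[[1]]$tau_slow
    X2 <- exp(-t_grid / taus[[1]])
    fit <- lm(y ~ 0 + X1 + X2)
    kern <- threshold_kernel(alpha_0 = coef(fit)[[1]], tau_m = tau_m,
                             alpha_M = coef(fit)[[2]], tau_p = taus[[1]])
    resid <- stats::residuals(fit)
  } else {
    taus <- fits[[1]]$tau_slow
    X2 <- exp(-t_grid / taus[[1]]) - exp(-t_grid / taus[[2]])
    fit <- lm(y ~ 0 + X1 + X2)
    kern <- threshold_kernel(alpha_0 = coef(fit)[[1]], tau_m = tau_m,
                             alpha_AHP = coef(fit)[[2]],
                             tau_ca = taus[[1]], tau_s = taus[[2]])
    resid <- stats::residuals(fit)
  }
  attr(kern, "projection_rms") <- sqrt(mean(resid^2))
  attr(kern, "exact") <- exact
  kern
}

#' Probe-based reduction of one neuron
#'
#' Runs the full probing pipeline for a neuron with one slow K+ current:
#' evoked-spike protocol, spike-triggered current extraction and fit,
#' threshold-variation fit against the matched neuron without the slow
#' conductance, waveform statistics, and theory-kernel assembly.
#'
#' @param params A [conductance_params()] with exactly one of `g_M`,
#'   `g_AHP` positive.
#' @param lags Lags for the threshold-variation curve (ms).
#' @param V_c Holding voltage (mV).
#' @param dt Time step (ms).
#' @param include_h Also probe the threshold variation (the slowest step);
#'   when `FALSE` the kernel uses the filtered current and reset term only.
#' @return A list of class `probe_reduction`: `kernel`, `eta_fit`, `h_fit`
#'   (or `NULL`), `waveform`, `increments` (`delta_p`, `delta_Ca`),
#'   `v_bar`.
#' @export
reduce_by_probe <- function(params, lags = c(20, 40, 80, 150, 250, 400),
                            V_c = -70, dt = 0.025, include_h = TRUE) {
  ion <- if (params$g_M > 0 && params$g_AHP == 0) "M"
  else if (params$g_AHP > 0 && params$g_M == 0) "AHP"
  else abort("params must have exactly one slow conductance positive")
  protocol <- evoked_spike_protocol(params, V_c = V_c,
                                    post = max(520, max(lags) + 80), dt = dt)
  eta <- spike_triggered_current(params, ion, V_c = V_c, protocol = protocol,
                                 dt = dt)
  eta_fit <- fit_eta(eta, component = "eta")
  h_fit <- NULL
  if (include_h) {
    p0 <- if (ion == "M") conductance_params(g_M = 0, g_AHP = params$g_AHP,
                                             C_m = params$C_m, g_L = params$g_L,
                                             g_Na = params$g_Na, g_Kd = params$g_Kd,
                                             g_Ca = params$g_Ca, tau_Ca = params$tau_Ca,
                                             beta_s = params$beta_s)
    else conductance_params(g_M = params$g_M, g_AHP = 0, C_m = params$C_m,
                            g_L = params$g_L, g_Na = params$g_Na,
                            g_Kd = params$g_Kd, g_Ca = params$g_Ca,
                            tau_max = params$tau_max)
    h <- threshold_variation(params, p0, lags, V_c = V_c, dt = dt)
    h_fit <- fit_eta(h, component = "h")
  }
  wf <- spike_waveform_stats(protocol)
  kern <- assemble_theory_kernel(eta_fits = list(eta_fit),
                                 h_fits = if (is.null(h_fit)) list() else list(h_fit),
                                 waveform = wf,
                                 tau_m = params$C_m / params$g_L,
                                 C_m = params$C_m)
  structure(list(kernel = kern, eta_fit = eta_fit, h_fit = h_fit,
                 waveform = wf,
                 increments = c(delta_p = attr(eta, "delta_p"),
                                delta_Ca = attr(eta, "delta_Ca")),
                 v_bar = attr(eta, "v_bar")),
            class = "probe_reduction")
}

#' Fit the adaptive threshold model by coincidence-factor maximization
#'
#' Given an input current and the reference spike train of the detailed
#' neuron, optimizes the free threshold parameters (`theta_inf`, `alpha_0`,
#' and the slow weight) by Nelder-Mead maximization of the coincidence
#' factor. The structural parameters stay fixed: `tau_m`, `C_m`, the M-term
#' time constant `tau_p` (from the mean subthreshold voltage of the
#' training trace when available), and the AHP pair (`tau_ca`, `tau_s`).
#' Because the objective is piecewise constant in the parameters, several
#' jittered restarts are used and the best is kept.
#'
#' @param stimulus Training current: numeric vector or tibble with `I_ex`.
#' @param spikes Reference [spike_train()] aligned with `stimulus`.
#' @param slow `"M"`, `"AHP"` or `"none"`: which slow kernel term is free.
#' @param test_stimulus,test_spikes Optional held-out data for `gamma_test`.
#' @param tau_m,C_m Fixed subthreshold parameters.
#' @param tau_p M-term time constant (ms); default 150 unless `v_bar` given.
#' @param v_bar Mean subthreshold voltage (mV) used to evaluate the p-gate
#'   time constant; overrides `tau_p`.
#' @param tau_max p-gate scale (s) used with `v_bar`.
#' @param tau_ca,tau_s Fixed AHP time constants (ms).
#' @param delta Coincidence window (ms).
#' @param dt Time step (ms).
#' @param refractory MAT refractory period (ms).
#' @param init Starting point `c(theta_inf, alpha_0, alpha_slow)` (mV).
#' @param restarts Number of jittered Nelder-Mead restarts.
#' @param jitter Relative jitter of the restarts' starting points.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param seed Seed for the restart jitter (local RNG).
#' @return An object of class `mat_fit` with elements `params`
#'   ([mat_params()]), `gamma_train`, `gamma_test`, `restarts` (per-restart
#'   tibble), `slow`, `delta`.
#' @export
fit_mat <- function(stimulus, spikes, slow = c("M", "AHP", "none"),
                    test_stimulus = NULL, test_spikes = NULL,
                    tau_m = 10, C_m = 1.0, tau_p = NULL, v_bar = NULL,
                    tau_max = 1.0, tau_ca = 200, tau_s = 50, delta = 4,
                    dt = 0.025, refractory = 2,
                    init = c(30, 35, 3), restarts = 5, jitter = 0.5,
                    maxit = 250, seed = 1) {
  slow <- match.arg(slow)
  I <- if (is.data.frame(stimulus)) stimulus$I_ex else as.numeric(stimulus)
  if (is.data.frame(stimulus) && nrow(stimulus) > 1)
    dt <- stimulus$t[2] - stimulus$t[1]
  if (length(spikes$times) == 0)
    abort("unfittable: no spikes in the training data")
  if (is.null(tau_p)) tau_p <- if (!is.null(v_bar))
    tau_p(v_bar, tau_max) else 150
  build <- function(th) {
    kern <- switch(slow,
      M = threshold_kernel(alpha_0 = th[2], tau_m = tau_m, alpha_M = th[3],
                           tau_p = tau_p),
      AHP = threshold_kernel(alpha_0 = th[2], tau_m = tau_m,
                             alpha_AHP = th[3], tau_ca = tau_ca,
                             tau_s = tau_s),
      none = threshold_kernel(alpha_0 = th[2], tau_m = tau_m))
    mat_params(theta_inf = th[1], kernel = kern, tau_m = tau_m, C_m = C_m,
               refractory = refractory)
  }
  gamma_of <- function(th, I_use, sp_use) {
    mp <- tryCatch(build(th), error = function(e) NULL)
    if (is.null(mp)) return(-10)
    pred <- simulate_mat(mp, I_use, dt = dt)$spikes
    g <- tryCatch(coincidence_factor(sp_use, pred, delta = delta)$gamma,
                  error = function(e) -10)
    if (!is.finite(g)) -10 else g
  }
  n_free <- if (slow == "none") 2 else 3
  x0 <- init[seq_len(n_free)]
  runs <- .with_seed(seed, {
    purrr::map(seq_len(restarts), function(r) {
      start <- if (r == 1) x0 else x0 * (1 + runif(n_free, -jitter, jitter))
      opt <- optim(start, gamma_of, I_use = I, sp_use = spikes,
                   method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = maxit))
      list(par = opt$par, gamma = opt$value, start = start)
    })
  })
  gtr <- vapply(runs, function(r) r$gamma, numeric(1))
  best <- runs[[which.max(gtr)]]
  mp <- build(best$par)
  restab <- tibble::tibble(restart = seq_len(restarts),
                           gamma_train = gtr,
                           best_so_far = cummax(gtr))
  gamma_test <- NA_real_
  test_result <- NULL
  if (!is.null(test_stimulus) && !is.null(test_spikes)) {
    I2 <- if (is.data.frame(test_stimulus)) test_stimulus$I_ex else
      as.numeric(test_stimulus)
    pred <- simulate_mat(mp, I2, dt = dt)$spikes
    test_result <- coincidence_factor(test_spikes, pred, delta = delta)
    gamma_test <- test_result$gamma
  }
  structure(list(params = mp, gamma_train = max(gtr),
                 gamma_test = gamma_test, test_result = test_result,
                 restarts = restab, slow = slow, delta = delta,
                 tau_p = tau_p, dt = dt),
            class = "mat_fit")
}

#' @export
print.mat_fit <- function(x, ...) {
  cat(sprintf("<mat_fit> slow = %s: Gamma_train = %.3f, Gamma_test = %s\n",
              x$slow, x$gamma_train,
              ifelse(is.na(x$gamma_test), "NA", sprintf("%.3f", x$gamma_test))))
  print(x$params)
  invisible(x)
}

#' @export
tidy.mat_fit <- function(x, ...) {
  k <- x$params$kernel
  alpha_slow <- switch(x$slow, M = k$alpha_M, AHP = k$alpha_AHP, none = NA_real_)
  tau_slow <- switch(x$slow, M = k$tau_p, AHP = k$tau_ca, none = NA_real_)
  tibble::tibble(
    term = c("theta_inf", "alpha_0", "alpha_slow"),
    estimate = c(x$params$theta_inf, k$alpha_0, alpha_slow),
    unit = "mV",
    fixed_tau = c(NA, k$tau_m, tau_slow))
}

#' @export
glance.mat_fit <- function(x, ...) {
  tibble::tibble(gamma_train = x$gamma_train, gamma_test = x$gamma_test,
                 slow = x$slow, delta = x$delta,
                 n_restarts = nrow(x$restarts))
}

# Deterministic per-condition seed derived from a user seed (kept < 2^31).
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Spike-prediction evaluation protocol
#'
#' The full validation pipeline for one neuron type: for each of the six
#' printed (mu, sigma) input conditions, simulate the detailed model for
#' `duration` ms under independent train and test OU currents, fit the
#' reduced model on the training spike train, and score the test prediction
#' by the coincidence factor.
#'
#' @param neuron `"M"` (g_M = 0.2, g_AHP = 0) or `"AHP"` (g_AHP = 0.2,
#'   g_M = 0).
#' @param duration Train and test length (ms) per condition.
#' @param dt Time step (ms).
#' @param seed Master seed; per-condition stream seeds are derived from it.
#' @param conditions Input table (defaults to [evaluation_inputs()]).
#' @param restarts,maxit Optimizer effort per condition (see [fit_mat()]).
#' @param delta Coincidence window (ms).
#' @param g Slow conductance of the detailed neuron (mS/cm^2).
#' @return A tibble with one row per condition: the inputs, detailed-model
#'   rates, fitted threshold parameters and train/test coincidence factors.
#'   The fitted `mat_fit` objects are attached as `attr(, "fits")`.
#' @export
run_evaluation_protocol <- function(neuron = c("M", "AHP"),
                                    duration = 50000, dt = 0.025, seed = 1,
                                    conditions = NULL, restarts = 4,
                                    maxit = 250, delta = 4, g = 0.2) {
  neuron <- match.arg(neuron)
  params <- if (neuron == "M") neuron_im(g_M = g) else neuron_ahp(g_AHP = g)
  if (is.null(conditions)) conditions <- evaluation_inputs(neuron)
  rest <- steady_state(params, I_c = 0, dt = dt)
  fits <- vector("list", nrow(conditions))
  rows <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    mu <- conditions$mu[i]; sg <- conditions$sigma[i]
    I_tr <- ou_current(mu, sg, duration, dt = dt,
                       seed = .derive_seed(seed, 2 * i - 1))
    I_te <- ou_current(mu, sg, duration, dt = dt,
                       seed = .derive_seed(seed, 2 * i))
    tr <- simulate_neuron(params, I_tr, dt = dt, init = rest)
    sp_tr <- detect_spikes(tr)
    v_bar <- mean(tr$V[tr$V < -40])
    te <- simulate_neuron(params, I_te, dt = dt, init = rest)
    sp_te <- detect_spikes(te)
    fit <- fit_mat(I_tr, sp_tr, slow = neuron,
                   test_stimulus = I_te, test_spikes = sp_te,
                   v_bar = if (neuron == "M") v_bar else NULL,
                   tau_max = params$tau_max, tau_ca = params$tau_Ca,
                   tau_s = 1 / params$beta_s, delta = delta, dt = dt,
                   restarts = restarts, maxit = maxit,
                   seed = .derive_seed(seed, 1000 + i))
    k <- fit$params$kernel
    rows[[i]] <- tibble::tibble(
      input = conditions$input[i], target_rate = conditions$target_rate[i],
      mu = mu, sigma = sg,
      rate_train = firing_rate(sp_tr), rate_test = firing_rate(sp_te),
      v_bar = v_bar, tau_p = fit$tau_p,
      theta_inf = fit$params$theta_inf, alpha_0 = k$alpha_0,
      alpha_slow = if (neuron == "M") k$alpha_M else k$alpha_AHP,
      gamma_train = fit$gamma_train, gamma_test = fit$gamma_test)
    fits[[i]] <- fit
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  attr(out, "neuron") <- neuron
  out
}
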