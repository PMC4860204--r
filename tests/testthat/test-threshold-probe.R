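# One probing protocol per neuron is shared across the tests in this file.
p_im <- neuron_im(g_M = 0.1)
p_ahp <- neuron_ahp(g_AHP = 0.2)
prot_im <- evoked_spike_protocol(p_im, V_c = -70, post = 520)
prot_ahp <- evoked_spike_protocol(p_ahp, V_c = -70, post = 520)

test_that("threshold bisection brackets the spiking transition", {
  leak <- conductance_params(g_Na = 0, g_Kd = 0, g_M = 0, g_Ca = 0, g_AHP = 0)
  st <- steady_state(leak, 0)
  expect_error(instantaneous_threshold(leak, st), "bracket")
  st0 <- steady_state(p_im, prot_im$I_c)
  th <- instantaneous_threshold(p_im, st0, I_c = prot_im$I_c)
  # postcondition: epsilon above the threshold spikes, epsilon below does not
  pv <- matreduce:::.param_vec(p_im)
  above <- matreduce:::hh_first_crossing_cpp(pv, st0, th$theta_V + 0.01,
                                             prot_im$I_c, 50, 0.025, 0)
  below <- matreduce:::hh_first_crossing_cpp(pv, st0, th$theta_V - 0.01,
                                             prot_im$I_c, 50, 0.025, 0)
  expect_gte(above, 0)
  expect_lt(below, 0)
  # q_min/theta_V identity
  expect_equal(th$theta_V, th$V_pre + th$q_min / p_im$C_m, tolerance = 1e-10)
  # noiseless probe is deterministic
  th2 <- instantaneous_threshold(p_im, st0, I_c = prot_im$I_c)
  expect_equal(th$theta_V, th2$theta_V, tolerance = 1e-3)
})

test_that("post-spike threshold decays fast without adaptation, slowly with I_M", {
  p0 <- neuron_noadapt()
  prot0 <- evoked_spike_protocol(p0, V_c = -70, post = 520)
  lags <- c(30, 50, 200, 400)
  c0 <- postspike_threshold_curve(p0, lags, protocol = prot0)
  cM <- postspike_threshold_curve(p_im, lags, protocol = prot_im)
  plateau0 <- c0$theta_V[c0$lag == 400]
  plateauM <- cM$theta_V[cM$lag == 400]
  # adaptation-free threshold is within 0.5 mV of its plateau by 50 ms
  expect_lt(abs(c0$theta_V[c0$lag == 50] - plateau0), 0.5)
  # the M-current keeps the threshold elevated at 200 ms
  expect_gt(cM$theta_V[cM$lag == 200] - plateauM,
            c0$theta_V[c0$lag == 200] - plateau0)
})

test_that("spike-triggered currents have the predicted exponential structure", {
  # zero conductance: identically zero series
  eta0 <- spike_triggered_current(p_im, "AHP", protocol = prot_im)
  expect_true(all(abs(eta0$eta) < 1e-10))
  # eta_M is log-linear over [10, 300] ms
  etaM <- spike_triggered_current(p_im, "M", protocol = prot_im)
  sel <- etaM$t >= 10 & etaM$t <= 300
  fit <- lm(log(etaM$eta[sel]) ~ etaM$t[sel])
  expect_gt(summary(fit)$r.squared, 0.98)
  # eta_AHP peaks near the double-exponential optimum
  etaA <- spike_triggered_current(p_ahp, "AHP", protocol = prot_ahp)
  t_peak_pred <- log(200 / 50) * 200 * 50 / (200 - 50)
  expect_lt(abs(etaA$t[which.max(etaA$eta)] - t_peak_pred), 15)
})

test_that("fit_eta recovers known components and scales with the conductances", {
  # self-consistency on a pure synthetic exponential
  tt <- seq(4, 500, by = 0.5)
  synth <- tibble::tibble(t = tt, eta = 0.7 * exp(-tt / 150))
  f <- fit_eta(synth, ion = "M", taus = c(tau = 120), free_taus = TRUE)
  expect_equal(f$amplitude, 0.7, tolerance = 0.01)
  expect_equal(unname(f$tau_slow[1]), 150, tolerance = 0.01)
  # amplitude ratios track g_M at 1:2:4
  amps <- vapply(c(0.05, 0.1, 0.2), function(g) {
    fit_eta(spike_triggered_current(neuron_im(g_M = g), "M"))$amplitude
  }, numeric(1))
  expect_equal(amps[2] / amps[1], 2, tolerance = 0.2)
  expect_equal(amps[3] / amps[1], 4, tolerance = 0.2 * 4)
  # doubling tau_Ca doubles the fitted slow time constant
  eta2 <- spike_triggered_current(neuron_ahp(g_AHP = 0.2, tau_Ca = 400), "AHP")
  f2 <- fit_eta(eta2, free_taus = TRUE)
  expect_equal(unname(f2$tau_slow[["tau_ca"]]), 400, tolerance = 0.1)
})

test_that("threshold variation isolates the slow current's contribution", {
  lags <- c(20, 50, 100, 180, 300, 420)
  # identical parameter sets give identically zero h
  h0 <- threshold_variation(p_im, p_im, lags = c(30, 120))
  expect_true(all(abs(h0$h) < 2e-4))
  # h_M follows b_M e^(-t/tau_p(v_bar)) closely
  hM <- threshold_variation(p_im, neuron_noadapt(), lags = lags)
  fM <- fit_eta(hM, component = "h")
  ss_tot <- sum((hM$h - mean(hM$h))^2)
  basis <- exp(-lags / fM$tau_slow[[1]])
  ss_res <- sum((hM$h - fM$amplitude * basis)^2)
  expect_gt(1 - ss_res / ss_tot, 0.95)
  # h_AHP is non-monotone with an interior hump
  hA <- threshold_variation(p_ahp, neuron_noadapt(), lags = lags)
  i_max <- which.max(hA$h)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(lags))
})

test_that("eta/h extraction commutes with zeroing the other conductance", {
  lags <- c(30, 80, 150, 300)
  base_with <- conductance_params(g_M = 0.1, g_AHP = 0.05)
  base_without <- conductance_params(g_M = 0, g_AHP = 0.05)
  h_mixed <- threshold_variation(base_with, base_without, lags = lags)
  h_pure <- threshold_variation(p_im, neuron_noadapt(), lags = lags)
  expect_equal(max(h_mixed$h), max(h_pure$h), tolerance = 0.1)
})

test_that("scaling predictor is linear in the conductance and guards edge cases", {
  p1 <- alpha_scaling_predictor("M", neuron_im(0.1), v_bar = -70, delta = 0.08)
  p2 <- alpha_scaling_predictor("M", neuron_im(0.2), v_bar = -70, delta = 0.08)
  expect_equal(p2 / p1, 2, tolerance = 1e-12)
  sing <- neuron_ahp(0.2, beta_s = 1 / 200, tau_Ca = 200)
  expect_error(alpha_scaling_predictor("AHP", sing, -70, 0.05), "singular")
  expect_error(alpha_scaling_predictor("M", neuron_im(0.1), -70, 1.5), "delta_p")
})
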