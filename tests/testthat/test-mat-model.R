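test_that("threshold kernel evaluates its closed form and vanishes for t <= 0", {
  k <- threshold_kernel(alpha_0 = 35.5, tau_m = 10, alpha_M = 4.1, tau_p = 150)
  expect_equal(kernel_eval(k, -5), 0)
  expect_equal(kernel_eval(k, 0), 0)
  expect_equal(kernel_eval(k, 10), 35.5 * exp(-1) + 4.1 * exp(-10 / 150),
               tolerance = 1e-12)
  # AHP pair cancels at t -> 0+
  ka <- threshold_kernel(alpha_0 = 0, alpha_AHP = 2, tau_ca = 200, tau_s = 50)
  expect_lt(abs(kernel_eval(ka, 1e-6)), 1e-6)
  expect_error(threshold_kernel(1, alpha_AHP = 1, tau_ca = 50, tau_s = 50),
               "differ")
})

test_that("subthreshold MAT integration is exact and linear", {
  m <- mat_params(30, threshold_kernel(alpha_0 = 35, tau_m = 10))
  # constant input below rheobase: no spikes, u converges to I0 tau_m
  sim <- simulate_mat(m, rep(2, 40000), record = TRUE)
  expect_length(sim$spikes$times, 0)
  expect_equal(tail(sim$trace$u, 1), 2 * 10, tolerance = 1e-6)
  # superposition of responses (disable spiking with a huge threshold)
  big <- mat_params(1e9, threshold_kernel(alpha_0 = 35, tau_m = 10))
  I1 <- ou_current(1, 1, 500, seed = 1)$I_ex
  I2 <- ou_current(0.5, 2, 500, seed = 2)$I_ex
  u1 <- simulate_mat(big, I1, record = TRUE)$trace$u
  u2 <- simulate_mat(big, I2, record = TRUE)$trace$u
  u12 <- simulate_mat(big, I1 + I2, record = TRUE)$trace$u
  expect_equal(u12, u1 + u2, tolerance = 1e-9)
  expect_error(simulate_mat(m, c(1, NaN, 1)), "non-finite")
})

test_that("asymptotic firing of the fast-only model matches the closed form", {
  m <- mat_params(29, threshold_kernel(alpha_0 = 35, tau_m = 10))
  sim <- simulate_mat(m, rep(6.4, 400000))
  isi <- diff(sim$spikes$times)
  T_analytic <- 1000 / fi_closed_form(29, 35, 10, 6.4)
  expect_lt(abs(tail(isi, 1) - T_analytic), 0.025 + 1e-9)
})

test_that("slow kernels adapt the ISI sequence onto the periodic fixed point", {
  m <- mat_params(30, threshold_kernel(alpha_0 = 35, tau_m = 10,
                                       alpha_M = 6, tau_p = 150))
  sim <- simulate_mat(m, rep(5, 400000))
  isi <- diff(sim$spikes$times)
  expect_gt(length(isi), 5)
  # monotone lengthening (threshold fatigue accumulates), up to grid jitter
  expect_true(all(diff(isi) >= -0.025 - 1e-9))
  T_star <- fi_adaptive(m, 5)$T
  expect_equal(tail(isi, 1), T_star, tolerance = 0.025 / T_star + 2e-3)
})

test_that("threshold accumulators equal the explicit sum over past spikes", {
  m <- mat_params(25, threshold_kernel(alpha_0 = 30, tau_m = 10, alpha_M = 3,
                                       tau_p = 150, alpha_AHP = 2,
                                       tau_ca = 200, tau_s = 50))
  stim <- ou_current(4, 3, 2000, seed = 9)
  sim <- simulate_mat(m, stim, record = TRUE)
  expect_gt(length(sim$spikes$times), 10)
  idx <- seq(1, nrow(sim$trace), by = 997)
  tt <- sim$trace$t[idx]
  oracle <- vapply(tt, function(x) {
    past <- sim$spikes$times[sim$spikes$times < x - 1e-12]
    m$theta_inf + sum(kernel_eval(m$kernel, x - past))
  }, numeric(1))
  expect_equal(sim$trace$theta[idx], oracle, tolerance = 1e-9)
})

test_that("spike times are dt-robust for deterministic inputs", {
  m <- mat_params(30, threshold_kernel(alpha_0 = 35, tau_m = 10,
                                       alpha_M = 4, tau_p = 150))
  s1 <- simulate_mat(m, rep(4.5, 400000), dt = 0.025)$spikes$times
  s2 <- simulate_mat(m, rep(4.5, 100000), dt = 0.1)$spikes$times
  n <- min(length(s1), length(s2))
  expect_gt(n, 20)
  # subthreshold integration is dt-exact; only crossing quantization differs,
  # so early spikes agree to the coarse grid and the ISIs stay locked
  expect_lt(max(abs(s1[1:8] - s2[1:8])), 0.21)
  expect_lt(abs(tail(diff(s1), 1) - tail(diff(s2), 1)), 0.11)
})
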