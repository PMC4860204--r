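test_that("eta_T_inf sums the kernel over an infinite periodic history", {
  k <- threshold_kernel(alpha_0 = 35, tau_m = 10)
  # hand value at t = T = 100
  expect_equal(eta_T_inf(k, 100, 100), 35 * exp(-10) / (1 - exp(-10)),
               tolerance = 1e-12)
  # long-period limit reduces to the kernel itself
  kf <- threshold_kernel(30, 10, alpha_M = 3, tau_p = 150, alpha_AHP = 2,
                         tau_ca = 200, tau_s = 50)
  expect_equal(eta_T_inf(kf, 1e7, 25), kernel_eval(kf, 25), tolerance = 1e-9)
  # brute-force series oracle: sum H_u(t + j T) over j = 0..10^4
  T_per <- 80
  for (t in c(5, 40, 80)) {
    brute <- sum(kernel_eval(kf, t + (0:10000) * T_per))
    expect_equal(eta_T_inf(kf, T_per, t), brute, tolerance = 1e-8)
  }
  expect_error(eta_T_inf(k, -1, 1), "period")
})

test_that("closed-form f-I curve matches hand values and edges", {
  expect_equal(fi_closed_form(29, 35, 10, 6.4), 100 / log(2), tolerance = 1e-10)
  expect_equal(fi_closed_form(29, 35, 10, 2.8), 0)
  # rate decays (logarithmically) toward 0 as the drive approaches rheobase
  expect_lt(fi_closed_form(29, 35, 10, 2.9 + 1e-9),
            fi_closed_form(29, 35, 10, 2.9 + 1e-3))
  expect_lt(fi_closed_form(29, 35, 10, 2.9 + 1e-3),
            fi_closed_form(29, 35, 10, 3))
})

test_that("the periodic-solution root coincides with the closed form when slow weights vanish", {
  m <- mat_params(29, threshold_kernel(alpha_0 = 35, tau_m = 10))
  for (I0 in c(3.5, 5, 6.4, 12)) {
    sol <- fi_adaptive(m, I0)
    expect_equal(sol$f, fi_closed_form(29, 35, 10, I0), tolerance = 1e-6)
    expect_lt(abs(sol$residual), 1e-6)
  }
  # subthreshold input: silent solution, not an error
  expect_equal(fi_adaptive(m, 2)$f, 0)
})

test_that("analytic rates match simulated asymptotic rates within 2 percent", {
  set.seed(31)
  for (rep in 1:8) {
    kern <- threshold_kernel(alpha_0 = runif(1, 25, 45), tau_m = 10,
                             alpha_M = runif(1, 0.5, 5),
                             tau_p = runif(1, 100, 300))
    m <- mat_params(runif(1, 25, 35), kern)
    for (f_target in c(6, 15, 35)) {
      I0 <- current_for_rate(m, f_target)
      sol <- fi_adaptive(m, I0)
      sim <- simulate_mat(m, rep(I0, 240000))  # 6 s, past adaptation
      isi <- tail(diff(sim$spikes$times), 3)
      expect_equal(mean(1000 / isi), sol$f, tolerance = 0.02)
    }
  }
})

test_that("f increases monotonically with the input current", {
  m <- mat_params(31, threshold_kernel(36, 10, alpha_M = 1.6, tau_p = 150))
  fc <- fi_curve(m, c(3.2, 12), n = 30)
  expect_true(all(diff(fc$f) > 0))
})

test_that("noise sensitivity matches a finite-difference threshold perturbation", {
  m <- mat_params(29, threshold_kernel(alpha_0 = 35, tau_m = 10))
  I0 <- current_for_rate(m, 12)
  # the drive-threshold gap shrinks like e^(-T/tau_m), so the perturbation
  # must stay well inside it for the linearization to hold
  du <- 1e-5
  ns <- noise_sensitivity(m, I0, delta_u = du)
  expect_lt(ns$slope, 0)
  # lowering theta_inf by delta_u advances the spike: compare the periods
  m2 <- mat_params(29 - du, threshold_kernel(alpha_0 = 35, tau_m = 10))
  dT_fd <- fi_adaptive(m2, I0)$T - fi_adaptive(m, I0)$T
  expect_equal(ns$delta_T, dT_fd, tolerance = 0.05)
})

test_that("a potential kick injected near a spike shifts the next ISI as predicted", {
  m <- mat_params(30, threshold_kernel(alpha_0 = 35, tau_m = 10,
                                       alpha_M = 1.6, tau_p = 150))
  I0 <- current_for_rate(m, 25)
  sol <- fi_adaptive(m, I0)
  dt <- 0.025
  n <- 240000
  base <- simulate_mat(m, rep(I0, n), dt = dt)$spikes$times
  k_ref <- length(base) - 2
  t_kick <- base[k_ref] + sol$T - 1   # 1 ms before the expected next spike
  gain <- m$tau_m * (1 - exp(-dt / m$tau_m)) / m$C_m
  delta_u <- 0.1
  I <- rep(I0, n)
  I[round(t_kick / dt) + 1] <- I0 + delta_u / gain
  pert <- simulate_mat(m, I, dt = dt)$spikes$times
  shift <- pert[k_ref + 1] - base[k_ref + 1]
  # the kick decays for ~1 ms before the crossing
  delta_eff <- delta_u * exp(-(base[k_ref + 1] - t_kick) / m$tau_m)
  predicted <- delta_eff / sol$slope
  expect_equal(shift, predicted, tolerance = 0.1 + dt / abs(predicted))
})

test_that("slow K+ kernels shape the dispersion-rate profile differentially", {
  m_none <- mat_params(29, threshold_kernel(35, 10))
  m_M <- mat_params(31, threshold_kernel(36, 10, alpha_M = 1.6, tau_p = 150))
  m_AHP <- mat_params(30, threshold_kernel(34, 10, alpha_AHP = 2.6,
                                           tau_ca = 200, tau_s = 100))
  disp <- function(m, f) {
    noise_sensitivity(m, current_for_rate(m, f))$delta_T_over_T
  }
  rates <- c(2, 3, 5, 10, 20)
  d_none <- vapply(rates, function(f) disp(m_none, f), numeric(1))
  d_M <- vapply(rates, function(f) disp(m_M, f), numeric(1))
  d_AHP <- vapply(rates, function(f) disp(m_AHP, f), numeric(1))
  # the M-current suppresses dispersion across the whole range
  expect_true(all(d_M < d_none))
  # the AHP current suppresses strongly only at low rates ...
  expect_lt(d_AHP[rates == 3] / d_none[rates == 3], 1e-3)
  # ... and its advantage is gone at 20 Hz where the M-current still helps
  expect_gt(d_AHP[rates == 20] / d_none[rates == 20], 0.5)
  expect_lt(d_M[rates == 20], d_AHP[rates == 20])
})
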