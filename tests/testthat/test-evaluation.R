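test_that("coincidence factor is 1 for self-prediction and 0 for silence", {
  a <- spike_train(sort(runif(40, 0, 10000)), 10000)
  self <- coincidence_factor(a, a)
  expect_identical(self$n_coinc, length(a$times))
  expect_equal(self$gamma, 1, tolerance = 1e-12)
  empty <- coincidence_factor(a, spike_train(numeric(0), 10000))
  expect_equal(empty$gamma, 0)
  # degenerate prediction rate: 1 - 2 nu delta <= 0
  dense <- spike_train(seq(1, 1000, by = 3), 1000)
  expect_error(coincidence_factor(a, dense, delta = 4), "degenerate")
})

test_that("Poisson predictions score at chance level", {
  set.seed(1203)
  ref <- spike_train(sort(runif(100, 0, 20000)), 20000)
  gammas <- replicate(100, {
    n <- rpois(1, 100)
    pred <- spike_train(sort(runif(n, 0, 20000)), 20000)
    coincidence_factor(ref, pred)$gamma
  })
  se <- sd(gammas) / sqrt(length(gammas))
  expect_lt(abs(mean(gammas)), 3 * se + 1e-9)
})

test_that("greedy matching attains the maximum bipartite matching", {
  set.seed(77)
  for (trial in 1:40) {
    n1 <- sample(0:12, 1)
    n2 <- sample(0:12, 1)
    a <- sort(runif(n1, 0, 50))
    b <- sort(runif(n2, 0, 50))
    greedy <- matreduce:::count_coincidences_cpp(a, b, 4)
    expect_identical(greedy, brute_force_matching(a, b, 4))
  }
})

test_that("gamma is shift-invariant but deliberately asymmetric", {
  a <- spike_train(c(10, 52, 101, 160, 240), 300)
  b <- spike_train(c(12, 60, 99, 200), 300)
  g0 <- coincidence_factor(a, b)$gamma
  shift <- function(tr, s) spike_train(tr$times + s, tr$duration)
  expect_equal(coincidence_factor(shift(a, 37), shift(b, 37))$gamma, g0,
               tolerance = 1e-12)
  # nu comes from the prediction train, so swapping the roles changes Gamma
  g_swapped <- coincidence_factor(b, a)$gamma
  expect_false(isTRUE(all.equal(g0, g_swapped)))
})

test_that("ISI statistics flag undefined quantities instead of fabricating", {
  per <- spike_train(seq(100, 1000, by = 100), 1000)
  s <- isi_stats(per)
  expect_equal(s$cv, 0)
  expect_true(is.na(s$rho1))  # zero variance
  two <- isi_stats(spike_train(c(1, 5), 10))
  expect_true(is.na(two$cv))
})

test_that("iid exponential ISIs give cv = 1 and rho1 = 0", {
  set.seed(8)
  isi <- rexp(1e4, rate = 1 / 50)
  tr <- spike_train(cumsum(isi), sum(isi) + 1)
  s <- isi_stats(tr)
  expect_equal(s$cv, 1, tolerance = 0.03)
  expect_lt(abs(s$rho1), 0.03)
})

test_that("the slow-K+ reduced model generates negative ISI correlations", {
  k <- threshold_kernel(36, 10, alpha_M = 1.6, tau_p = 150)
  m <- mat_params(31, k)
  stim <- ou_current(4, 2, 60000, seed = 3)
  s <- isi_stats(simulate_mat(m, stim)$spikes)
  expect_lt(s$rho1, 0)
})
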