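# Shared oracles and fixtures, built in code at test time.

# Maximum bipartite matching between two spike trains under |a - b| <= delta,
# by exhaustive recursion (tractable for n <= 12); independent of the greedy
# counter used by the package.
brute_force_matching <- function(a, b, delta) {
  match_from <- function(i, used) {
    if (i > length(a)) return(0L)
    best <- match_from(i + 1L, used)
    for (j in seq_along(b)) {
      if (!used[j] && abs(a[i] - b[j]) <= delta) {
        used[j] <- TRUE
        best <- max(best, 1L + match_from(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  match_from(1L, logical(length(b)))
}

# Threshold of the MAT model by explicit summation over the spike history.
brute_force_theta <- function(params, spike_times, t) {
  vapply(t, function(tt) {
    params$theta_inf + sum(kernel_eval(params$kernel, tt - spike_times))
  }, numeric(1))
}

# Small deterministic triangle wave crossing `level` upward at known times.
triangle_trace <- function(dt = 0.01) {
  tt <- seq(0, 30, by = dt)
  V <- 10 * sin(2 * pi * tt / 10) - 2   # upward crossings of 0 where sin = 0.2
  tibble::tibble(t = tt, V = V)
}

# Lazily-computed, cached results of the heavy evaluation protocols so the
# acceptance blocks can share one run.
.protocol_cache <- new.env(parent = emptyenv())
protocol_results <- function(neuron, duration = 50000, seed = 101) {
  key <- paste0(neuron, "_", duration, "_", seed)
  if (is.null(.protocol_cache[[key]])) {
    .protocol_cache[[key]] <- run_evaluation_protocol(
      neuron, duration = duration, seed = seed, restarts = 4)
  }
  .protocol_cache[[key]]
}
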