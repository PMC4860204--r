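#' Read and write traces, spike trains and fitted models as plain text
#'
#' Traces are columnar CSV (`t,V,I_ex[,...]`) with a JSON sidecar
#' (`<path>.json`) recording units, the time step and optional provenance.
#' Numeric columns are written with shortest round-trip precision, so a
#' write-read cycle reproduces the values exactly. Spike trains are one
#' time (ms) per line with a `# duration:` header. Fitted MAT parameters
#' are flat JSON.
#'
#' @param trace A trace tibble (from [simulate_neuron()] or compatible).
#' @param path Output file.
#' @param meta Optional named list merged into the sidecar.
#' @return `write_*`: the path, invisibly. `read_*`: the object.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace <- function(trace, path, meta = list()) {
  readr::write_csv(as.data.frame(trace), path, progress = FALSE)
  sidecar <- c(list(units = list(t = "ms", V = "mV", I = "uA/cm^2",
                                 Ca = "uM"),
                    dt = attr(trace, "dt"),
                    columns = names(trace)),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  # base strtod parsing is exact to the last ulp, unlike the fast approximate
  # float path some readers take; exactness matters for bitwise round-trips
  out <- tibble::as_tibble(utils::read.csv(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$dt)) attr(out, "dt") <- as.numeric(meta$dt)
  } else if (nrow(out) > 1) {
    attr(out, "dt") <- out$t[2] - out$t[1]
  }
  class(out) <- c("neuron_trace", class(tibble::tibble()))
  out
}

#' @rdname trace_io
#' @param train A [spike_train()].
#' @export
write_spike_train <- function(train, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration: %s",
                     format(train$duration, digits = 17)), con)
  writeLines(format(train$times, digits = 17, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  dur_line <- lines[hdr][grepl("duration:", lines[hdr])]
  if (!length(dur_line)) abort(sprintf("%s: missing '# duration:' header", path))
  duration <- as.numeric(sub(".*duration:\\s*", "", dur_line[1]))
  body <- lines[!hdr & nzchar(trimws(lines))]
  times <- suppressWarnings(as.numeric(body))
  if (anyNA(times)) {
    bad <- which(!hdr & nzchar(trimws(lines)))[which(is.na(times))[1]]
    abort(sprintf("%s: cannot parse spike time at line %d", path, bad))
  }
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE)) {
    bad <- which(diff(times) <= 0)[1]
    abort(sprintf("%s: non-monotone spike times at line %d", path,
                  which(!hdr)[bad + 1]))
  }
  spike_train(times, duration)
}

#' @rdname trace_io
#' @param params A [mat_params()] object.
#' @export
write_mat_params <- function(params, path, meta = list()) {
  k <- params$kernel
  obj <- c(list(theta_inf = params$theta_inf, tau_m = params$tau_m,
                C_m = params$C_m, refractory = params$refractory,
                alpha_0 = k$alpha_0, alpha_M = k$alpha_M, tau_p = k$tau_p,
                alpha_AHP = k$alpha_AHP, tau_ca = k$tau_ca,
                tau_s = k$tau_s),
           meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_mat_params <- function(path) {
  o <- jsonlite::read_json(path)
  kern <- threshold_kernel(alpha_0 = o$alpha_0, tau_m = o$tau_m,
                           alpha_M = o$alpha_M, tau_p = o$tau_p,
                           alpha_AHP = o$alpha_AHP, tau_ca = o$tau_ca,
                           tau_s = o$tau_s)
  mat_params(theta_inf = o$theta_inf, kernel = kern, tau_m = o$tau_m,
             C_m = o$C_m, refractory = o$refractory)
}

#' Seeded fixture bundle for the standard protocols
#'
#' Regenerates, from code and a single seed, the data sets the analyses
#' rest on: (a) rectangular-current responses of the three reference
#' neurons (adaptation-free, M-current, AHP); (b) the six-condition OU
#' train/test current pairs for the spike-prediction protocol (currents
#' only -- traces are simulated on demand); (c) a synthetic data set
#' generated by a known MAT model for parameter-recovery checks. The same
#' seed always yields bit-identical fixtures.
#'
#' @param seed Master seed.
#' @param eval_duration Duration of the evaluation currents (ms).
#' @param recovery_duration Duration of the MAT-recovery stimulus (ms).
#' @param dt Time step (ms).
#' @return A named list with elements `rectangular`, `evaluation`,
#'   `mat_recovery` and the generating `seed`.
#' @export
generate_fixtures <- function(seed = 1, eval_duration = 5000,
                              recovery_duration = 20000, dt = 0.025) {
  rect_stim <- function(amp) {
    tt <- seq(0, 1500, by = dt)
    out <- tibble::tibble(t = tt, I_ex = ifelse(tt >= 200 & tt <= 1300, amp, 0))
    attr(out, "I_const") <- 0
    attr(out, "dt") <- dt
    out
  }
  rectangular <- list(
    noadapt = simulate_neuron(neuron_noadapt(), rect_stim(2.5), dt = dt),
    im = simulate_neuron(neuron_im(g_M = 0.1), rect_stim(3.2), dt = dt),
    ahp = simulate_neuron(neuron_ahp(g_AHP = 0.2), rect_stim(3.1), dt = dt))
  make_eval <- function(neuron, base) {
    cond <- evaluation_inputs(neuron)
    cond$train <- purrr::map(seq_len(nrow(cond)), function(i)
      ou_current(cond$mu[i], cond$sigma[i], eval_duration, dt = dt,
                 seed = .derive_seed(seed, base + 2 * i - 1)))
    cond$test <- purrr::map(seq_len(nrow(cond)), function(i)
      ou_current(cond$mu[i], cond$sigma[i], eval_duration, dt = dt,
                 seed = .derive_seed(seed, base + 2 * i)))
    cond
  }
  true_kernel <- threshold_kernel(alpha_0 = 35, tau_m = 10, alpha_M = 4,
                                  tau_p = 150)
  true_mat <- mat_params(theta_inf = 30, kernel = true_kernel)
  rec_stim <- ou_current(3.2, 3.2, recovery_duration, dt = dt,
                         seed = .derive_seed(seed, 9001))
  rec_spikes <- simulate_mat(true_mat, rec_stim, dt = dt)$spikes
  list(rectangular = rectangular,
       evaluation = list(M = make_eval("M", 100), AHP = make_eval("AHP", 300)),
       mat_recovery = list(true_params = true_mat, stimulus = rec_stim,
                           spikes = rec_spikes),
       seed = seed)
}

#' One-call reduction pipeline
#'
#' Drives simulate -> fit -> evaluate from a single flat configuration:
#' generates the OU input pair, simulates the detailed neuron, fits the
#' reduced model on the training half and scores the test half. All
#' randomness derives from `config$seed`, and the returned artifact records
#' the configuration, so a rerun reproduces identical numbers.
#'
#' @param config Named list with required fields `neuron` ("M" or "AHP"),
#'   `mu`, `sigma`, `duration` (ms), `seed`; optional `dt` (0.025),
#'   `g` (0.2), `restarts` (4), `maxit` (250), `delta` (4), `out_dir`
#'   (when set, the fitted model, spike trains and gamma table are written
#'   there as text).
#' @return A list of class `pipeline_result`: `fit` (a `mat_fit`), `gamma`
#'   (tibble), `rates`, `config`, `log` (stage timings).
#' @export
run_pipeline <- function(config) {
  required <- c("neuron", "mu", "sigma", "duration", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing))
    abort(sprintf("config is missing required fields: %s",
                  paste(missing, collapse = ", ")))
  config <- modifyList(list(dt = 0.025, g = 0.2, restarts = 4, maxit = 250,
                            delta = 4, out_dir = NULL), config)
  if (!config$neuron %in% c("M", "AHP")) abort("neuron must be 'M' or 'AHP'")
  tic <- function() Sys.time()
  log <- list()
  params <- if (config$neuron == "M") neuron_im(g_M = config$g) else
    neuron_ahp(g_AHP = config$g)
  t0 <- tic()
  I_tr <- ou_current(config$mu, config$sigma, config$duration, dt = config$dt,
                     seed = .derive_seed(config$seed, 1))
  I_te <- ou_current(config$mu, config$sigma, config$duration, dt = config$dt,
                     seed = .derive_seed(config$seed, 2))
  rest <- steady_state(params, 0, dt = config$dt)
  tr <- simulate_neuron(params, I_tr, dt = config$dt, init = rest)
  te <- simulate_neuron(params, I_te, dt = config$dt, init = rest)
  sp_tr <- detect_spikes(tr)
  sp_te <- detect_spikes(te)
  log$simulate <- as.numeric(difftime(tic(), t0, units = "secs"))
  if (length(sp_tr$times) == 0)
    abort("stage 'simulate' produced no training spikes; increase mu")
  t0 <- tic()
  fit <- fit_mat(I_tr, sp_tr, slow = config$neuron,
                 test_stimulus = I_te, test_spikes = sp_te,
                 v_bar = if (config$neuron == "M") mean(tr$V[tr$V < -40]) else NULL,
                 tau_ca = params$tau_Ca, tau_s = 1 / params$beta_s,
                 delta = config$delta, dt = config$dt,
                 restarts = config$restarts, maxit = config$maxit,
                 seed = .derive_seed(config$seed, 3))
  log$fit <- as.numeric(difftime(tic(), t0, units = "secs"))
  gamma <- tibble::tibble(mu = config$mu, sigma = config$sigma,
                          rate_train = firing_rate(sp_tr),
                          rate_test = firing_rate(sp_te),
                          gamma_train = fit$gamma_train,
                          gamma_test = fit$gamma_test)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mat_params(fit$params, file.path(config$out_dir, "mat.json"),
                     meta = list(seed = config$seed,
                                 neuron = config$neuron,
                                 gamma_train = fit$gamma_train,
                                 gamma_test = fit$gamma_test))
    write_spike_train(sp_tr, file.path(config$out_dir, "train.spk"))
    write_spike_train(sp_te, file.path(config$out_dir, "test.spk"))
    readr::write_csv(gamma, file.path(config$out_dir, "gamma.csv"))
  }
  structure(list(fit = fit, gamma = gamma,
                 rates = c(train = firing_rate(sp_tr),
                           test = firing_rate(sp_te)),
                 config = config,
                 log = tibble::tibble(stage = names(log),
                                      seconds = unlist(log))),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s neuron, mu = %g, sigma = %g\n",
              x$config$neuron, x$config$mu, x$config$sigma))
  print(x$gamma)
  invisible(x)
}
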