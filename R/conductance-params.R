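#' Biophysical parameters of the conductance-based neuron
#'
#' Builds the full parameter set of the single-compartment conductance-based
#' model: leak, transient Na+, delayed-rectifier K+, muscarinic K+ (M-current,
#' gate p), high-threshold Ca2+, and Ca2+-activated K+ (AHP current, gate s)
#' conductances, plus the intracellular Ca2+ dynamics feeding the s-gate. The
#' defaults are the standard cortical parameter set used throughout the
#' package.
#'
#' All quantities are handled internally in ms, mV, uA/cm^2, uF/cm^2,
#' mS/cm^2 and uM. The only unit conversion at this boundary is `tau_max`,
#' which is conventionally quoted in seconds.
#'
#' @param C_m Membrane capacitance (uF/cm^2).
#' @param g_L,g_Na,g_Kd,g_M,g_Ca,g_AHP Maximal conductances (mS/cm^2).
#' @param E_L,E_Na,E_K,E_Ca Reversal potentials (mV).
#' @param tau_max Scale of the p-gate (M-current) time constant, in seconds.
#' @param beta_s Inactivation rate of the AHP s-gate (/ms).
#' @param tau_Ca Intracellular Ca2+ relaxation time constant (ms).
#' @param Ca_inf Equilibrium Ca2+ concentration (uM).
#' @param F Faraday constant (C/mol).
#'
#' @return An object of class `conductance_params` (a named list).
#' @examples
#' p <- conductance_params(g_M = 0.2, g_AHP = 0)  # M-current neuron
#' @export
conductance_params <- function(C_m = 1.0, g_L = 0.1, g_Na = 50.0, g_Kd = 5.0,
                               g_M = 0.1, g_Ca = 0.001, g_AHP = 0.2,
                               E_L = -80, E_Na = 50, E_K = -90, E_Ca = 120,
                               tau_max = 1.0, beta_s = 0.02, tau_Ca = 200,
                               Ca_inf = 0.05, F = 9.6485e4) {
  p <- list(C_m = C_m, g_L = g_L, g_Na = g_Na, g_Kd = g_Kd, g_M = g_M,
            g_Ca = g_Ca, g_AHP = g_AHP, E_L = E_L, E_Na = E_Na, E_K = E_K,
            E_Ca = E_Ca, tau_max = tau_max, beta_s = beta_s, tau_Ca = tau_Ca,
            Ca_inf = Ca_inf, F = F)
  conds <- c("g_L", "g_Na", "g_Kd", "g_M", "g_Ca", "g_AHP")
  if (any(vapply(p[conds], function(x) x < 0, logical(1))))
    abort("conductances must be >= 0")
  if (tau_max <= 0 || beta_s <= 0 || tau_Ca <= 0)
    abort("tau_max, beta_s and tau_Ca must be > 0")
  if (C_m <= 0) abort("C_m must be > 0")
  structure(p, class = "conductance_params")
}

#' Convenience parameter sets for the three reference neurons
#'
#' The adaptation-free neuron (`g_M = g_AHP = 0`), the M-current neuron
#' (`g_AHP = 0`) and the AHP neuron (`g_M = 0`).
#'
#' @param g_M,g_AHP Maximal slow K+ conductance (mS/cm^2).
#' @param ... Further overrides passed to [conductance_params()].
#' @return A `conductance_params` object.
#' @export
neuron_im <- function(g_M = 0.2, ...) {
  conductance_params(g_M = g_M, g_AHP = 0, ...)
}

#' @rdname neuron_im
#' @export
neuron_ahp <- function(g_AHP = 0.2, ...) {
  conductance_params(g_M = 0, g_AHP = g_AHP, ...)
}

#' @rdname neuron_im
#' @export
neuron_noadapt <- function(...) {
  conductance_params(g_M = 0, g_AHP = 0, ...)
}

#' @export
print.conductance_params <- function(x, ...) {
  cat("<conductance_params>\n")
  cat(sprintf("  C_m = %g uF/cm^2; g (mS/cm^2): L=%g Na=%g Kd=%g M=%g Ca=%g AHP=%g\n",
              x$C_m, x$g_L, x$g_Na, x$g_Kd, x$g_M, x$g_Ca, x$g_AHP))
  cat(sprintf("  E (mV): L=%g Na=%g K=%g Ca=%g\n", x$E_L, x$E_Na, x$E_K, x$E_Ca))
  cat(sprintf("  tau_max = %g s; beta_s = %g /ms; tau_Ca = %g ms; Ca_inf = %g uM\n",
              x$tau_max, x$beta_s, x$tau_Ca, x$Ca_inf))
  invisible(x)
}

# Flat parameter vector consumed by the C++ core; tau_max converted to ms.
.param_vec <- function(params) {
  stopifnot(inherits(params, "conductance_params"))
  c(params$C_m, params$g_L, params$g_Na, params$g_Kd, params$g_M,
    params$g_Ca, params$g_AHP, params$E_L, params$E_Na, params$E_K,
    params$E_Ca, params$tau_max * 1000, params$beta_s, params$tau_Ca,
    params$Ca_inf, params$F)
}
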