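# Network simulation front end over the compiled stochastic Heun
# integrators.

#' Simulation configuration
#'
#' @param dt Integration step in seconds (default 0.06).
#' @param duration Total simulated time in seconds (default 4000).
#' @param transient Initial epoch discarded before analysis, seconds
#'   (default 500).
#' @param noise_amplitude Half-width of the uniform noise, so draws are
#'   uniform on `[-noise_amplitude, noise_amplitude]` (default 0.3).
#' @param noise_convention `"sqrt_dt"` (default) scales each noise draw by
#'   `sqrt(dt)` (diffusion reading); `"dt"` scales by `dt` (literal
#'   ODE-term reading).
#' @param seed Integer seed for initial conditions and noise.
#' @param model_kind `"phase"` (delayed Kuramoto) or `"limit_cycle"`
#'   (delayed Hopf normal form).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.06, duration = 4000, transient = 500,
                       noise_amplitude = 0.3,
                       noise_convention = c("sqrt_dt", "dt"),
                       seed = 1L,
                       model_kind = c("phase", "limit_cycle")) {
  noise_convention <- match.arg(noise_convention)
  model_kind <- match.arg(model_kind)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (transient < 0 || transient >= duration) {
    stop("need 0 <= transient < duration", call. = FALSE)
  }
  if (noise_amplitude < 0) stop("`noise_amplitude` must be >= 0", call. = FALSE)
  structure(
    list(
      dt = dt, duration = duration, transient = transient,
      noise_amplitude = noise_amplitude,
      noise_convention = noise_convention,
      seed = as.integer(seed), model_kind = model_kind
    ),
    class = "sim_config"
  )
}

#' Simulate a delayed oscillator network
#'
#' Integrates the delayed Kuramoto phase model or the delayed Hopf
#' limit-cycle model with the stochastic Heun scheme. The coupling term of
#' oscillator `j` is `C/N * sum_n w_jn sin(phi_n(t - tau_jn) - phi_j)`
#' (phase) or `C/N * sum_n w_jn (z_n(t - tau_jn) - z_j)` (limit cycle);
#' pairwise delays come from [scale_delays()] applied to the network's
#' path lengths with global delay `tau`. Initial phases are uniform on
#' `[0, 2 pi)`; initial limit-cycle states uniform in the complex unit
#' disk; the pre-history is held constant at the initial state. The
#' retained trajectory holds the observable (`sin(phi_j)` or `Re(z_j)`)
#' at every step after the transient.
#'
#' @param network A `model_network` (see [derive_model_inputs()]).
#' @param params A `regional_parameters` with frequencies `f` (Hz) and,
#'   for the limit-cycle model, amplitudes `a`.
#' @param C Global coupling strength, `>= 0`.
#' @param tau Global delay in seconds, `>= 0`.
#' @param config A `sim_config`.
#' @return A `sim_run` with the retained `observable` matrix
#'   (`(duration - transient)/dt` rows x N columns) and the run metadata.
#' @export
simulate_network <- function(network, params, C, tau, config = sim_config()) {
  stopifnot(inherits(network, "model_network"))
  if (C < 0) stop("`C` must be >= 0", call. = FALSE)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  n <- network$n_regions
  if (length(params$f) != n) {
    stop("`params$f` length must match the number of regions", call. = FALSE)
  }
  dsteps <- scale_delays(network$lengths, tau, config$dt, network$convention)
  wc <- (C / n) * network$weights
  n_total <- as.integer(round(config$duration / config$dt))
  n_trans <- as.integer(round(config$transient / config$dt))
  sqrtdt <- config$noise_convention == "sqrt_dt"

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  res <- if (config$model_kind == "phase") {
    sim_phase_cpp(
      params$f, wc, dsteps, config$dt, n_total, n_trans,
      config$noise_amplitude, sqrtdt
    )
  } else {
    if (length(params$a) != n) {
      stop("`params$a` length must match the number of regions", call. = FALSE)
    }
    sim_hopf_cpp(
      params$f, params$a, wc, dsteps, config$dt, n_total, n_trans,
      config$noise_amplitude, sqrtdt
    )
  }
  if (isTRUE(res$diverged)) {
    stop(
      sprintf(
        "simulation diverged at step %d for (tau = %g, C = %g)",
        res$step, tau, C
      ),
      call. = FALSE
    )
  }
  structure(
    list(
      observable = res$observable,
      imag = res$imag,
      model_kind = config$model_kind,
      C = C, tau = tau, dt = config$dt,
      transient = config$transient, seed = config$seed
    ),
    class = "sim_run"
  )
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "<sim_run: %s model, %d regions, %d retained steps (dt = %g s), tau = %g, C = %g>\n",
    x$model_kind, ncol(x$observable), nrow(x$observable), x$dt, x$tau, x$C
  ))
  invisible(x)
}

#' Simulated functional connectivity of a run
#'
#' Pairwise Pearson correlation of the retained observables; the simulated
#' analogue of an empirical FC matrix (symmetric, unit diagonal).
#'
#' @param run A `sim_run`, or a time-by-region numeric matrix.
#' @return `N x N` correlation matrix.
#' @export
compute_sfc <- function(run) {
  x <- if (inherits(run, "sim_run")) run$observable else run
  if (!is.matrix(x) || nrow(x) < 3) {
    stop("need a trajectory with at least 3 retained steps", call. = FALSE)
  }
  sds <- apply(x, 2, pop_sd)
  if (any(sds == 0)) {
    stop(
      sprintf(
        "constant signal in region(s) %s: correlation undefined",
        paste(which(sds == 0), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  fc <- cor(x)
  diag(fc) <- 1
  (fc + t(fc)) / 2
}
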