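# Personalized model derivation: coupling weights from streamline counts,
# delays from path lengths, natural frequencies from BOLD spectra, Hopf
# amplitudes from BOLD fluctuation magnitudes.

#' Normalize streamline counts into coupling weights
#'
#' Weights are `w_jn = k_jn / <k_jn>`, where `<.>` is the ensemble average
#' over the entire zero-diagonal `N x N` matrix (dividing by `N^2`;
#' `convention = "offdiag"` divides by `N (N - 1)` instead). The diagonal
#' stays zero (no self-connections) and the mean of the output under the
#' same convention is exactly 1.
#'
#' @param counts Symmetric nonnegative `N x N` matrix with zero diagonal.
#' @param convention Averaging convention, `"full"` (default) or
#'   `"offdiag"`.
#' @return Weight matrix of the same shape.
#' @export
#' @examples
#' k <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3)
#' normalize_weights(k)
normalize_weights <- function(counts, convention = c("full", "offdiag")) {
  convention <- match.arg(convention)
  stopifnot_symmetric_zero_diag(counts, "counts")
  if (any(counts < 0)) stop("`counts` must be nonnegative", call. = FALSE)
  mu <- matrix_mean(counts, convention)
  if (mu == 0) stop("all-zero `counts`: weights are degenerate", call. = FALSE)
  w <- counts / mu
  diag(w) <- 0
  w
}

#' Convert path lengths and a global delay into integer delay steps
#'
#' Pairwise delays are `tau_jn = tau_global * L_jn / <L_jn>` with the same
#' averaging convention as the weights, then discretized to integration
#' steps by round-half-to-even of `tau_jn / dt`.
#'
#' @param lengths Symmetric nonnegative `N x N` matrix (mm), zero diagonal.
#' @param tau_global Global (average) delay in seconds, `>= 0`.
#' @param dt Integration step in seconds.
#' @param convention Averaging convention (see [normalize_weights()]).
#' @return Integer matrix of delay step counts, zero diagonal.
#' @export
#' @examples
#' L <- matrix(10, 3, 3); diag(L) <- 0
#' scale_delays(L, tau_global = 2, dt = 0.06)
scale_delays <- function(lengths, tau_global, dt,
                         convention = c("full", "offdiag")) {
  convention <- match.arg(convention)
  stopifnot_symmetric_zero_diag(lengths, "lengths")
  if (tau_global < 0) stop("`tau_global` must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  n <- nrow(lengths)
  if (tau_global == 0) {
    return(matrix(0L, n, n))
  }
  mu <- matrix_mean(lengths, convention)
  if (mu == 0) {
    stop("all-zero `lengths` with positive `tau_global`: delays are degenerate",
      call. = FALSE
    )
  }
  tau <- tau_global * lengths / mu
  steps <- matrix(as.integer(round(tau / dt)), n, n) # round half to even
  diag(steps) <- 0L
  steps
}

#' Extract natural frequencies from BOLD spectra
#'
#' Per region, the frequency of the largest periodogram ordinate within
#' the band (default 0.01-0.1 Hz), computed from a single no-taper FFT
#' periodogram of the mean-removed concatenated signal. Frequencies below
#' and above the band are discarded before taking the maximum.
#'
#' @param bold A `bold_dataset`.
#' @param band Length-2 numeric, lower and upper band edge in Hz.
#' @return Numeric vector of in-band frequencies, one per region (Hz).
#' @export
extract_natural_frequencies <- function(bold, band = c(0.01, 0.1)) {
  stopifnot(inherits(bold, "bold_dataset"))
  x <- bold$concatenated
  n_t <- nrow(x)
  freqs <- seq_len(floor(n_t / 2)) / (n_t * bold$tr)
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) {
    stop(
      sprintf(
        "no Fourier bin falls within [%g, %g] Hz: signal too short (%d samples at TR = %g s)",
        band[1], band[2], n_t, bold$tr
      ),
      call. = FALSE
    )
  }
  apply(x, 2, function(sig) {
    spec <- Mod(stats::fft(sig - mean(sig)))[seq_len(floor(n_t / 2)) + 1]^2
    fb <- freqs[in_band]
    fb[which.max(spec[in_band])]
  })
}

#' Calibrate Hopf amplitude parameters from BOLD fluctuation magnitudes
#'
#' Per-region temporal standard deviations `s_j` of the concatenated
#' signal are affinely standardized so that over parcels the mean is 0.5
#' and the population standard deviation is 0.4:
#' `a_j = 0.5 + 0.4 (s_j - mean(s)) / sd(s)`. Negative `a_j` are allowed
#' and put the oscillator in the subcritical (noise-driven) regime. If all
#' regions have identical fluctuation magnitude the calibration is
#' degenerate; every `a_j` is set to 0.5 with a warning.
#'
#' @param bold A `bold_dataset` with at least 2 regions.
#' @param target_mean,target_sd Calibration moments (defaults 0.5, 0.4).
#' @return Numeric amplitude vector `a`, same region order as the input.
#' @export
calibrate_amplitudes <- function(bold, target_mean = 0.5, target_sd = 0.4) {
  stopifnot(inherits(bold, "bold_dataset"))
  x <- bold$concatenated
  if (ncol(x) < 2) stop("need at least 2 regions", call. = FALSE)
  s <- apply(x, 2, pop_sd)
  sds <- pop_sd(s)
  if (sds == 0) {
    warning("all regions have identical BOLD SD; returning constant amplitudes")
    return(rep(target_mean, length(s)))
  }
  target_mean + target_sd * (s - mean(s)) / sds
}

#' Derive all personalized model inputs from a subject bundle
#'
#' Bundles weights, path lengths, natural frequencies, and Hopf amplitudes
#' into the model network and regional parameters that
#' [simulate_network()] consumes.
#'
#' @param bundle A `subject_bundle`.
#' @param convention Matrix averaging convention (see
#'   [normalize_weights()]).
#' @param band Frequency band for [extract_natural_frequencies()].
#' @return A list with elements `network` (class `model_network`: `weights`,
#'   `lengths`, `n_regions`, `mean_length`, `convention`) and `params`
#'   (class `regional_parameters`: `f`, `a`).
#' @export
derive_model_inputs <- function(bundle, convention = c("full", "offdiag"),
                                band = c(0.01, 0.1)) {
  convention <- match.arg(convention)
  stopifnot(inherits(bundle, "subject_bundle"))
  w <- normalize_weights(bundle$connectome$counts, convention)
  lengths <- bundle$connectome$lengths
  network <- structure(
    list(
      weights = w,
      lengths = lengths,
      n_regions = nrow(w),
      mean_length = matrix_mean(lengths, convention),
      convention = convention
    ),
    class = "model_network"
  )
  params <- structure(
    list(
      f = extract_natural_frequencies(bundle$bold, band),
      a = calibrate_amplitudes(bundle$bold)
    ),
    class = "regional_parameters"
  )
  list(network = network, params = params)
}

#' @export
print.model_network <- function(x, ...) {
  cat(sprintf(
    "<model_network: %d regions, mean weight %.3f (%s convention), mean length %.1f mm>\n",
    x$n_regions, matrix_mean(x$weights, x$convention), x$convention,
    x$mean_length
  ))
  invisible(x)
}

#' @export
print.regional_parameters <- function(x, ...) {
  cat(sprintf(
    "<regional_parameters: %d regions, f in [%.3f, %.3f] Hz, a mean %.2f sd %.2f>\n",
    length(x$f), min(x$f), max(x$f), mean(x$a), pop_sd(x$a)
  ))
  invisible(x)
}
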