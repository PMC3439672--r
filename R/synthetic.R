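# Synthetic lipid-mixing assay traces.
#
# The in vitro readout being emulated is FRET-based lipid mixing: donor
# dequenching fluorescence rises as labeled v-SNARE liposomes fuse with
# unlabeled t-SNARE liposomes. The generator drives a normalized
# dequenching signal with the simulated fusion level and adds Gaussian
# measurement noise, so every downstream analysis stage can be exercised
# end to end without any external data.

#' Generate a synthetic lipid-mixing fluorescence trace
#'
#' Simulates the model at the given SM dose, normalizes the fusion level
#' (fraction of v-SNARE in fused species), adds i.i.d. Gaussian noise and
#' clamps into \code{[0, 1 - 1e-6]} so that the fusion-round transform
#' stays defined. Deterministic under \code{seed}.
#'
#' @param model,rates Model and rate set (defaults: the model's own rates).
#' @param sm_dose Initial SM concentration (uM).
#' @param duration Trace duration (s).
#' @param sample_interval Sampling interval (s).
#' @param noise_sd Noise standard deviation on the normalized signal,
#'   \code{>= 0}.
#' @param seed Integer seed.
#' @param scan_species SM species name (default: detected).
#' @return An \code{ssnm_assay_trace}: \code{times}, \code{fluorescence},
#'   plus the generating \code{noise_sd}, \code{seed}, model name and dose.
#' @examples
#' tr <- generate_assay_trace(yeast_ssnm(), sm_dose = 4.5, duration = 200,
#'                            sample_interval = 10, noise_sd = 0.01, seed = 1)
#' @export
generate_assay_trace <- function(model, rates = rate_set(model), sm_dose,
                                 duration = 2000, sample_interval = 10,
                                 noise_sd = 0.01, seed = 1L,
                                 scan_species = NULL) {
  stopifnot(noise_sd >= 0, duration > 0, sample_interval > 0)
  if (is.null(scan_species)) scan_species <- sm_species(model)
  times <- seq(0, duration, by = sample_interval)
  tr <- simulate_ode(model, rates, t_end = duration,
                     y0 = stats::setNames(sm_dose, scan_species),
                     n_points = length(times))
  f <- fusion_level(tr)
  set.seed(seed)
  noisy <- f + stats::rnorm(length(f), mean = 0, sd = noise_sd)
  noisy <- pmin(pmax(noisy, 0), 1 - 1e-6)
  structure(list(times = times, fluorescence = noisy,
                 noise_sd = noise_sd, seed = seed,
                 model = model$name, sm_dose = sm_dose),
            class = "ssnm_assay_trace")
}

#' @export
print.ssnm_assay_trace <- function(x, ...) {
  cat(sprintf("synthetic lipid-mixing trace: model '%s', SM %g uM, %d samples, noise sd %g, seed %d\n",
              x$model, x$sm_dose, length(x$times), x$noise_sd, x$seed))
  invisible(x)
}

#' Fusion-round transform of normalized fluorescence
#'
#' Converts a normalized lipid-mixing signal \code{f} in \code{[0, 1)} to
#' rounds of fusion, \code{-log(1 - f)} -- the Poisson-rounds convention of
#' the lipid-mixing literature: if each vesicle undergoes a Poisson number
#' of fusion events, the dequenched fraction is \code{1 - exp(-rounds)}.
#' Strictly increasing and convex on \code{[0, 1)}; 0 at \code{f = 0}.
#'
#' @param f Numeric vector or \code{ssnm_assay_trace}.
#' @return Numeric vector of fusion rounds.
#' @examples
#' fluorescence_to_rounds(1 - exp(-1))  # exactly 1
#' @export
fluorescence_to_rounds <- function(f) {
  if (inherits(f, "ssnm_assay_trace")) f <- f$fluorescence
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1))
    stop("fluorescence must lie in [0, 1) for the fusion-round transform")
  -log1p(-f)
}

#' End-to-end parameter-recovery fixture
#'
#' Draws one LHS-perturbed rate set around the motif's defaults, simulates
#' its fusion dose-response, and produces a noisy copy of the table
#' (Gaussian, sd 0.01, clamped to \code{[0, 1)}). Classification of the
#' noisy table must match the noiseless one; the bundle serves as an
#' end-to-end regression fixture.
#'
#' @param motif Catalog motif name (see \code{\link{ssnm_motif}}).
#' @param seed Integer seed (drives both the rate draw and the noise).
#' @param values Scan grid (uM).
#' @param noise_sd Noise standard deviation (default 0.01).
#' @param t_max Readout horizon (s).
#' @return List: \code{model}, \code{rates} (perturbed),
#'   \code{dose_response} (clean), \code{noisy_fusion},
#'   \code{classification_clean}, \code{classification_noisy}, \code{seed}.
#' @export
make_recovery_fixture <- function(motif, seed = 1L,
                                  values = seq(0, 6, by = 0.5),
                                  noise_sd = 0.01, t_max = 5000) {
  model <- ssnm_motif(motif)
  rates <- lhs_sample(rate_set(model), n = 1, variance_fraction = 0.30,
                      seed = seed)[[1L]]
  dr <- dose_response(model, rates, sm_species(model), values, t_max = t_max)
  set.seed(seed + 1L)
  noisy <- pmin(pmax(dr$fusion + stats::rnorm(length(dr$fusion), 0, noise_sd),
                     0), 1 - 1e-6)
  noisy_dr <- dr
  noisy_dr$fusion <- noisy
  # classification tolerance chosen at 3 * noise sd so measurement noise is
  # absorbed without masking the motif-scale fusion differences
  tol <- max(1e-3, 3 * noise_sd)
  list(model = model, rates = rates, dose_response = dr,
       noisy_fusion = noisy,
       classification_clean = classify_response(dr, tol),
       classification_noisy = classify_response(noisy_dr, tol),
       seed = seed)
}
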