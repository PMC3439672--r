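# Dose-response shape classification, optimum SM dose ("bifurcation point"),
# Latin hypercube parameter robustness, overexpression scenarios and
# comparative motif reports.

#' Classify the shape of a dose-response curve
#'
#' Labels a scanned steady-state fusion curve as
#' \code{monotonic_increasing} (hyperbolic, yeast-like: every successive
#' difference \code{>= -tolerance} and total increase \code{> tolerance}),
#' \code{monotonic_decreasing} (symmetric), \code{biphasic} (neuronal-like
#' "bifurcation": rises by more than the tolerance before its maximum and
#' falls by more than the tolerance after it), or \code{flat}. At equal
#' maxima the smallest dose wins (deterministic reporting).
#'
#' @param dr An \code{ssnm_dose_response} (or list with \code{doses} and
#'   \code{fusion}), at least 5 scan points.
#' @param tolerance Fusion-level tolerance (default 1e-3).
#' @return An \code{ssnm_classification}: fields \code{shape},
#'   \code{argmax_dose}, \code{max_fusion}, \code{tolerance}.
#' @examples
#' dr <- list(doses = 0:5, fusion = c(.1, .3, .5, .6, .65, .67))
#' classify_response(dr)$shape  # monotonic_increasing
#' @export
classify_response <- function(dr, tolerance = 1e-3) {
  f <- dr$fusion
  doses <- dr$doses
  if (length(f) < 5L) stop("classification needs at least 5 scan points")
  d <- diff(f)
  imax <- which.max(f)          # first maximum: smallest dose wins
  rise <- f[imax] - f[1L]
  fall <- f[imax] - f[length(f)]
  shape <-
    if (all(d >= -tolerance) && (f[length(f)] - f[1L]) > tolerance) {
      "monotonic_increasing"
    } else if (all(d <= tolerance) && (f[1L] - f[length(f)]) > tolerance) {
      "monotonic_decreasing"
    } else if (rise > tolerance && fall > tolerance) {
      "biphasic"
    } else {
      "flat"
    }
  structure(list(shape = shape, argmax_dose = doses[imax],
                 max_fusion = f[imax], tolerance = tolerance),
            class = "ssnm_classification")
}

#' @export
print.ssnm_classification <- function(x, ...) {
  cat(sprintf("dose-response shape: %s (argmax %g uM, max fusion %.4f)\n",
              x$shape, x$argmax_dose, x$max_fusion))
  invisible(x)
}

#' Locate the SM dose maximizing plateau fusion
#'
#' Grid-scans plateau fusion over \code{[lo, hi]} at the stated resolution,
#' then refines around the grid argmax by golden-section search in the
#' two-cell bracket. For the wildtype neuronal motif this locates the
#' "bifurcation point": the interior optimum at stoichiometric equality of
#' SM and syntaxin. For monotone motifs it returns the appropriate scan
#' bound.
#'
#' @inheritParams dose_response
#' @param scan_species Species to scan (default: the model's SM monomer,
#'   detected as the species whose name ends in \code{"SM"}).
#' @param lo,hi Scan bounds (uM), \code{lo < hi}.
#' @param resolution Grid step (uM), \code{> 0}; the result is accurate to
#'   about one resolution.
#' @param refine Run golden-section refinement after the grid scan.
#' @return List: \code{optimum} (uM), \code{fusion} at the optimum,
#'   \code{grid_argmax} (uM), and the scan \code{dose_response}.
#' @export
find_optimum_sm <- function(model, rates = rate_set(model),
                            scan_species = NULL, lo = 0, hi = 6,
                            resolution = 0.05, refine = TRUE,
                            t_max = 5000, epsilon = 1e-6) {
  stopifnot(lo < hi, resolution > 0)
  if (is.null(scan_species)) scan_species <- sm_species(model)
  values <- seq(lo, hi, by = resolution)
  if (abs(values[length(values)] - hi) > 1e-12) values <- c(values, hi)
  dr <- dose_response(model, rates, scan_species, values,
                      t_max = t_max, epsilon = epsilon)
  i <- which.max(dr$fusion)
  grid_opt <- dr$doses[i]
  obj <- function(x) {
    plateau_readout(model, rates,
                    y0 = stats::setNames(x, scan_species),
                    t_max = t_max, epsilon = epsilon)$fusion
  }
  if (refine && i > 1L && i < length(values)) {
    o <- stats::optimize(obj, lower = dr$doses[i - 1L],
                         upper = dr$doses[i + 1L],
                         maximum = TRUE, tol = resolution / 4)
    list(optimum = o$maximum, fusion = o$objective, grid_argmax = grid_opt,
         dose_response = dr)
  } else {
    list(optimum = grid_opt, fusion = dr$fusion[i], grid_argmax = grid_opt,
         dose_response = dr)
  }
}

# The SM monomer of a catalog-style model: the monomer species whose name
# ends in "SM".
sm_species <- function(model) {
  mono <- names(model$species)[vapply(model$species,
                                      function(s) s$role == "monomer",
                                      logical(1))]
  hit <- grep("SM$", mono, value = TRUE)
  if (length(hit) != 1L)
    stop("cannot identify a unique SM monomer; pass scan_species explicitly")
  hit
}

#' Latin hypercube samples around a nominal rate set
#'
#' Each rate constant (every nonzero \code{kf} and \code{kr}) is an
#' independent dimension sampled uniformly on
#' \code{[(1 - v) k, (1 + v) k]} with Latin hypercube stratification:
#' exactly one sample falls in each of the \code{n} equal-width strata of
#' every dimension. Zero rates (irreversible reactions) stay exactly zero.
#' Reproducible under \code{seed}.
#'
#' @param nominal Named list: label -> \code{c(kf = , kr = )}.
#' @param n Number of samples, \code{>= 1}.
#' @param variance_fraction Half-width \code{v} of the relative sampling
#'   interval, \code{0 <= v < 1} (the published analysis used 0.30).
#' @param seed Integer seed.
#' @return List of \code{n} rate sets shaped like \code{nominal}.
#' @examples
#' s <- lhs_sample(default_rates("yeast"), n = 5,
#'                 variance_fraction = 0.3, seed = 1)
#' @export
lhs_sample <- function(nominal, n, variance_fraction = 0.30, seed = 1L) {
  stopifnot(n >= 1, variance_fraction >= 0, variance_fraction < 1)
  labels <- names(nominal)
  k <- unlist(lapply(nominal, function(x) c(x[["kf"]], x[["kr"]])))
  d <- length(k)
  set.seed(seed)
  U <- lhs::randomLHS(n, d)
  lapply(seq_len(n), function(i) {
    vals <- unname(k * (1 - variance_fraction) +
                     k * 2 * variance_fraction * U[i, ])
    out <- vector("list", length(labels))
    names(out) <- labels
    for (j in seq_along(labels))
      out[[j]] <- c(kf = vals[2 * j - 1L], kr = vals[2 * j])
    out
  })
}

#' Parameter-robustness analysis by Latin hypercube sampling
#'
#' Draws \code{n} rate sets around the nominal values (each constant varied
#' within \code{+/- variance_fraction}, uniform, LHS-stratified), classifies
#' the fusion dose-response under each, and reports the fraction of samples
#' preserving the nominal shape label. Individual integrator failures are
#' recorded per sample (shape \code{NA}, counted as not preserved), never
#' fatal. Fully reproducible under \code{(n, variance_fraction, seed)}.
#'
#' @inheritParams dose_response
#' @inheritParams lhs_sample
#' @param scan_species Scanned species (default: the model's SM monomer).
#' @param values Scan grid (uM); default \code{seq(0, 6, by = 0.5)}.
#' @param tolerance Classification tolerance.
#' @return An \code{ssnm_robustness}: \code{n}, \code{variance_fraction},
#'   \code{seed}, \code{nominal_shape}, \code{shapes} (per sample, NA on
#'   failure), \code{errors}, \code{preservation_fraction}.
#' @export
robustness_analysis <- function(model, nominal = rate_set(model), n = 50,
                                variance_fraction = 0.30, seed = 1L,
                                scan_species = NULL,
                                values = seq(0, 6, by = 0.5),
                                t_max = 5000, epsilon = 1e-6,
                                tolerance = 1e-3) {
  if (is.null(scan_species)) scan_species <- sm_species(model)
  nominal_dr <- dose_response(model, nominal, scan_species, values,
                              t_max = t_max, epsilon = epsilon)
  nominal_shape <- classify_response(nominal_dr, tolerance)$shape
  samples <- lhs_sample(nominal, n, variance_fraction, seed)
  shapes <- character(n)
  errors <- vector("list", n)
  for (i in seq_len(n)) {
    shapes[i] <- tryCatch({
      dr <- dose_response(model, samples[[i]], scan_species, values,
                          t_max = t_max, epsilon = epsilon)
      classify_response(dr, tolerance)$shape
    }, error = function(e) {
      errors[[i]] <<- conditionMessage(e)
      NA_character_
    })
  }
  structure(list(n = n, variance_fraction = variance_fraction, seed = seed,
                 nominal_shape = nominal_shape, shapes = shapes,
                 errors = errors,
                 preservation_fraction =
                   sum(shapes == nominal_shape, na.rm = TRUE) / n),
            class = "ssnm_robustness")
}

#' @export
print.ssnm_robustness <- function(x, ...) {
  cat(sprintf("LHS robustness: n = %d, variance +/-%d%%, seed %d\n",
              x$n, round(100 * x$variance_fraction), x$seed))
  cat(sprintf("  nominal shape %s preserved in %.1f%% of samples\n",
              x$nominal_shape, 100 * x$preservation_fraction))
  invisible(x)
}

#' Outcome of an SM overexpression scenario
#'
#' Compares plateau fusion at a baseline SM concentration against
#' \code{baseline_sm * fold_increase}. On the biphasic neuronal motif the
#' same overexpression manipulation can increase fusion (if the final dose
#' stays below the bifurcation point) or decrease it (if it overshoots) --
#' the model's reconciliation of conflicting overexpression experiments.
#'
#' @inheritParams plateau_readout
#' @param baseline_sm Baseline SM concentration (uM), \code{>= 0}.
#' @param fold_increase Overexpression factor, \code{>= 1}.
#' @param scan_species SM species (default: detected).
#' @param tolerance Fusion difference below which the outcome is
#'   \code{"unchanged"}.
#' @return List: \code{outcome} in \code{{"increased", "decreased",
#'   "unchanged"}}, \code{fusion_baseline}, \code{fusion_overexpressed}.
#' @examples
#' \donttest{
#' overexpression_outcome(neuronal_ssnm(), baseline_sm = 2,
#'                        fold_increase = 1.5)$outcome  # "increased"
#' }
#' @export
overexpression_outcome <- function(model, rates = rate_set(model),
                                   baseline_sm, fold_increase,
                                   scan_species = NULL, tolerance = 1e-3,
                                   t_max = 5000, epsilon = 1e-6) {
  stopifnot(baseline_sm >= 0, fold_increase >= 1)
  if (is.null(scan_species)) scan_species <- sm_species(model)
  f0 <- plateau_readout(model, rates,
                        y0 = stats::setNames(baseline_sm, scan_species),
                        t_max = t_max, epsilon = epsilon)$fusion
  f1 <- plateau_readout(model, rates,
                        y0 = stats::setNames(baseline_sm * fold_increase,
                                             scan_species),
                        t_max = t_max, epsilon = epsilon)$fusion
  outcome <- if (f1 - f0 > tolerance) "increased"
             else if (f0 - f1 > tolerance) "decreased"
             else "unchanged"
  list(outcome = outcome, fusion_baseline = f0, fusion_overexpressed = f1)
}

#' Compare dose-responses of several motifs on a common grid
#'
#' @param motifs Named list of \code{ssnm_model} objects, or of lists with
#'   fields \code{model} and \code{rates}; at least 2.
#' @param values Common scan grid (uM).
#' @param tolerance Classification tolerance.
#' @inheritParams dose_response
#' @return An \code{ssnm_comparison}: \code{table} (data.frame, dose column
#'   plus one fusion column per motif) and \code{classifications} (named
#'   character vector of shape labels).
#' @export
compare_motifs <- function(motifs, values = seq(0, 6, by = 0.25),
                           tolerance = 1e-3, t_max = 5000, epsilon = 1e-6) {
  if (length(motifs) < 2L)
    stop("compare_motifs needs at least 2 motifs")
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    stop("motifs must be a named list")
  drs <- lapply(motifs, function(m) {
    if (inherits(m, "ssnm_model")) m <- list(model = m, rates = rate_set(m))
    dose_response(m$model, m$rates, sm_species(m$model), values,
                  t_max = t_max, epsilon = epsilon)
  })
  tab <- data.frame(dose = values)
  for (nm in names(drs)) tab[[nm]] <- drs[[nm]]$fusion
  cls <- vapply(drs, function(d) classify_response(d, tolerance)$shape,
                character(1))
  structure(list(table = tab, classifications = cls,
                 dose_responses = drs),
            class = "ssnm_comparison")
}

#' @export
print.ssnm_comparison <- function(x, ...) {
  cat("SSNM motif comparison:\n")
  for (nm in names(x$classifications))
    cat(sprintf("  %-20s %s (max fusion %.3f)\n", nm, x$classifications[[nm]],
                max(x$table[[nm]])))
  invisible(x)
}
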