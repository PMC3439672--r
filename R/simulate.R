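# Deterministic and stochastic simulation of SSNM models, fusion readout,
# plateau detection and dose-response scanning.

new_trajectory <- function(times, conc, model, rates, kind) {
  structure(list(times = times, conc = conc, model = model, rates = rates,
                 kind = kind),
            class = "ssnm_trajectory")
}

#' @export
print.ssnm_trajectory <- function(x, ...) {
  cat(sprintf("SSNM %s trajectory of model '%s': %d time points over [0, %g] s, %d species\n",
              x$kind, x$model$name, length(x$times), max(x$times), ncol(x$conc)))
  f <- fusion_level(x)
  cat(sprintf("  final fusion level: %.4f\n", f[length(f)]))
  invisible(x)
}

#' Deterministic simulation of a reaction-network model
#'
#' Integrates the mass-action ODEs with a stiff-capable variable-step solver
#' (\code{deSolve}'s \code{lsoda}, which switches automatically between
#' Adams and BDF methods) and reports the solution on a dense regular grid.
#'
#' @param model A valid \code{ssnm_model}.
#' @param rates Rate set (default: the model's own rates).
#' @param t_end Final time (s), \code{> 0}.
#' @param y0 Optional named initial-concentration override (uM); defaults to
#'   the model's initial concentrations.
#' @param rtol,atol Relative / absolute integration tolerances
#'   (defaults 1e-6 and 1e-9 uM).
#' @param n_points Number of equally spaced reporting points (default 500).
#' @return An \code{ssnm_trajectory}: fields \code{times} (s) and
#'   \code{conc} (time x species matrix, uM).
#' @examples
#' tr <- simulate_ode(yeast_ssnm(sm0 = 4.5), t_end = 100)
#' tail(fusion_level(tr), 1)
#' @export
simulate_ode <- function(model, rates = rate_set(model), t_end,
                         y0 = NULL, rtol = 1e-6, atol = 1e-9,
                         n_points = 500L) {
  stopifnot(t_end > 0)
  rhs <- build_mass_action_rhs(model, rates)
  init <- model$initial
  if (!is.null(y0)) init[names(y0)] <- y0
  times <- seq(0, t_end, length.out = n_points)
  sol <- deSolve::ode(y = init, times = times,
                      func = function(t, y, parms) list(rhs(y)),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("ODE integration failed at t = %g (istate = %d); last state: %s",
                 max(sol[, "time"]), attr(sol, "istate")[1L],
                 paste(sprintf("%s=%.3g", names(init), sol[nrow(sol), -1L]),
                       collapse = ", ")))
  conc <- unname(sol[, -1L, drop = FALSE])
  dimnames(conc) <- list(NULL, names(init))
  new_trajectory(times = sol[, "time"], conc = conc, model = model,
                 rates = rates, kind = "ODE")
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates the chemical master equation with the direct stochastic
#' simulation algorithm. Concentrations are converted to copy numbers with
#' the volume scale \code{omega} (molecules per uM); mass-action propensities
#' use the standard falling-factorial combinatorics. This serves as an
#' independent oracle for the ODE route: ensemble means converge to the ODE
#' solution as \code{omega} grows.
#'
#' @inheritParams simulate_ode
#' @param omega Volume scale, molecules per uM (\code{>= 1}).
#' @param seed Optional integer seed (R RNG) for reproducibility.
#' @param n_points Number of reporting points (default 100).
#' @return An \code{ssnm_trajectory} with \code{conc} = copy numbers / omega.
#' @examples
#' tr <- simulate_stochastic(yeast_ssnm(sm0 = 4.5), t_end = 10,
#'                           omega = 100, seed = 1)
#' @export
simulate_stochastic <- function(model, rates = rate_set(model), t_end,
                                omega, seed = NULL, y0 = NULL,
                                n_points = 100L) {
  stopifnot(omega >= 1, t_end > 0)
  v <- validate_model(model)
  if (length(v)) stop("model has validation violations; see validate_model()")
  rates <- check_rates(model, rates)
  if (!is.null(seed)) set.seed(seed)
  init <- model$initial
  if (!is.null(y0)) init[names(y0)] <- y0
  st <- stoich_matrices(model)
  kf <- vapply(names(model$reactions), function(lb) rates[[lb]][["kf"]], numeric(1))
  kr <- vapply(names(model$reactions), function(lb) rates[[lb]][["kr"]], numeric(1))
  x0 <- round(init * omega)
  times <- seq(0, t_end, length.out = n_points)
  counts <- ssa_direct_cpp(st$R, st$P, kf, kr, x0, omega, times)
  conc <- counts / omega
  colnames(conc) <- names(init)
  new_trajectory(times = times, conc = conc, model = model, rates = rates,
                 kind = "SSA")
}

#' Fusion level of a trajectory
#'
#' The fusion level at a time point is the fraction of the model's readout
#' moiety (conventionally the v-SNARE) residing in fused species:
#' \code{sum over fused species of moiety count * concentration} divided by
#' the total readout moiety. Dimensionless, in [0, 1], and non-decreasing in
#' time because fusion reactions are irreversible.
#'
#' @param trajectory An \code{ssnm_trajectory}.
#' @param model Model the trajectory came from (default: stored reference).
#' @return Numeric vector, one fusion level per time point.
#' @export
fusion_level <- function(trajectory, model = trajectory$model) {
  prot <- model$readout_moiety
  M <- moiety_matrix(model)
  if (!prot %in% colnames(M)) stop("unknown readout moiety '", prot, "'")
  w_all <- M[, prot]
  fused <- vapply(model$species, function(s) s$role == "fused", logical(1))
  w_fused <- w_all * fused
  total <- drop(trajectory$conc[1L, , drop = FALSE] %*% w_all)
  if (total <= 0)
    stop("total readout moiety ('", prot, "') is zero; fusion level undefined")
  as.numeric(trajectory$conc[, names(w_fused), drop = FALSE] %*% w_fused) / total
}

#' Plateau ("steady-state") fusion readout
#'
#' Integrates the model and reports the fusion level once its time
#' derivative falls below \code{epsilon} (the operational steady state of a
#' system whose fusion step is irreversible: the true t -> infinity limit is
#' dose-independent, so the biologically meaningful readout is the plateau
#' on the simulated time scale). If the plateau criterion is not met by
#' \code{t_max}, the fusion level at \code{t_max} is returned and flagged.
#'
#' @inheritParams simulate_ode
#' @param t_max Integration horizon (s), default 5000.
#' @param epsilon Plateau slope threshold (fusion units per second),
#'   default 1e-6.
#' @param n_points Reporting-grid size used for slope detection.
#' @return List with fields \code{fusion} (level at readout), \code{time}
#'   (readout time, s), \code{plateau_met} (logical), and the trajectory.
#' @examples
#' plateau_readout(yeast_ssnm(sm0 = 4.5))$fusion
#' @export
plateau_readout <- function(model, rates = rate_set(model), y0 = NULL,
                            t_max = 5000, epsilon = 1e-6,
                            rtol = 1e-6, atol = 1e-9, n_points = 500L) {
  stopifnot(epsilon > 0, t_max > 0)
  tr <- simulate_ode(model, rates, t_end = t_max, y0 = y0,
                     rtol = rtol, atol = atol, n_points = n_points)
  f <- fusion_level(tr)
  dt <- diff(tr$times)
  slope <- diff(f) / dt
  idx <- which(slope < epsilon)
  if (length(idx)) {
    i <- idx[1L] + 1L
    list(fusion = f[i], time = tr$times[i], plateau_met = TRUE,
         trajectory = tr)
  } else {
    n <- length(f)
    list(fusion = f[n], time = tr$times[n], plateau_met = FALSE,
         trajectory = tr)
  }
}

#' Steady-state fusion versus dose of a scanned species
#'
#' Runs \code{\link{plateau_readout}} for each value of the scanned species
#' (all other initial concentrations held at the model's defaults); runs are
#' independent, so the result is order-invariant.
#'
#' @inheritParams plateau_readout
#' @param scan_species Species whose initial concentration is scanned
#'   (e.g. \code{"nSM"}).
#' @param values Strictly increasing scan values (uM), at least 3.
#' @return An \code{ssnm_dose_response}: fields \code{species},
#'   \code{doses}, \code{fusion}, \code{readout_time}, \code{plateau_met}.
#' @examples
#' dr <- dose_response(yeast_ssnm(), scan_species = "ySM",
#'                     values = c(0, 1.5, 3, 4.5, 6), t_max = 2000)
#' @export
dose_response <- function(model, rates = rate_set(model), scan_species,
                          values, t_max = 5000, epsilon = 1e-6,
                          rtol = 1e-6, atol = 1e-9, n_points = 500L) {
  if (!scan_species %in% names(model$species))
    stop("scan species '", scan_species, "' is not in the model")
  if (length(values) < 3L || any(diff(values) <= 0))
    stop("scan values must be strictly increasing with at least 3 points")
  res <- lapply(values, function(v) {
    y0 <- stats::setNames(v, scan_species)
    p <- plateau_readout(model, rates, y0 = y0, t_max = t_max,
                         epsilon = epsilon, rtol = rtol, atol = atol,
                         n_points = n_points)
    p[c("fusion", "time", "plateau_met")]
  })
  structure(list(species = scan_species,
                 doses = as.numeric(values),
                 fusion = vapply(res, `[[`, numeric(1), "fusion"),
                 readout_time = vapply(res, `[[`, numeric(1), "time"),
                 plateau_met = vapply(res, `[[`, logical(1), "plateau_met"),
                 model = model$name),
            class = "ssnm_dose_response")
}

#' @export
print.ssnm_dose_response <- function(x, ...) {
  cat(sprintf("SSNM dose-response: model '%s', %s scanned over [%g, %g] uM (%d points)\n",
              x$model, x$species, min(x$doses), max(x$doses), length(x$doses)))
  cat(sprintf("  fusion range [%.4f, %.4f], argmax at %g uM\n",
              min(x$fusion), max(x$fusion), x$doses[which.max(x$fusion)]))
  invisible(x)
}

#' @export
as.data.frame.ssnm_dose_response <- function(x, ...) {
  data.frame(dose = x$doses, fusion = x$fusion,
             readout_time = x$readout_time, plateau_met = x$plateau_met)
}
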