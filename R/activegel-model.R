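#' Effective viscosity of the active gel at pore radius R
#'
#' The opening pore couples the layer's material viscosity to actin turnover
#' and to the density dependence of the net gel stress, giving a pore-size
#' dependent effective viscosity
#' \deqn{\eta_{eff}(R) = \eta + (\eta - 2 \rho_0 \tau_a \zeta) R^2 / R_L^2.}
#' For a passive actin layer (`zeta < 0`) the correction exceeds `eta`
#' (densification stiffens the layer); for an actomyosin layer (`zeta > 0`)
#' myosin fluidizes it and the effective viscosity drops below the passive
#' value.
#'
#' @param params a [gel_params()] object.
#' @param R pore radius, m (vectorized); must satisfy `0 <= R <= R_L`.
#' @param floor_frac error floor: an effective viscosity at or below
#'   `floor_frac * eta` signals an unphysical parameter combination (the
#'   reduced law is a lubrication-type early-phase approximation and a
#'   near-zero or negative effective viscosity is outside its validity).
#' @return effective viscosity, Pa s (same length as `R`).
#' @export
effective_viscosity <- function(params, R, floor_frac = 0.01) {
  params <- validate_gel_params(params)
  if (!all(is.finite(R))) stop("R must be finite")
  if (any(R < 0 | R > params$R_L)) stop("R must lie in [0, R_L]")
  eff <- params$eta +
    (params$eta - 2 * params$rho0 * params$tau_a * params$zeta) *
      R^2 / params$R_L^2
  if (any(eff <= floor_frac * params$eta))
    stop("effective viscosity at or below ", floor_frac,
         "*eta: unphysical parameter combination (zeta too large ",
         "relative to eta / (2 rho0 tau_a))")
  eff
}

#' Rate of pore opening in the reduced active-gel law
#'
#' Early-phase force balance at the pore edge:
#' \deqn{dR/dt = [(\sigma_0 + 2 f_{adh} R_L / 3) R - 2\gamma] / \eta_{eff}(R).}
#' The membrane tension term resists opening; contractile active stress and
#' adhesion drive it. Positive values mean the pore opens.
#'
#' @inheritParams effective_viscosity
#' @return signed rate dR/dt, m/s (vectorized over `R`).
#' @export
pore_opening_rate <- function(params, R) {
  params <- validate_gel_params(params)
  eff <- effective_viscosity(params, R)
  ((params$sigma0 + 2 * params$f_adh * params$R_L / 3) * R -
     2 * params$gamma) / eff
}

#' Critical pore radius for expansion
#'
#' Pores larger than \eqn{R_c = 6\gamma / (3\sigma_0 + 2 f_{adh} R_L)} open;
#' smaller pores reseal. `R_c` is the unstable fixed point of the reduced
#' law and may exceed `R_L`, in which case no pore can open.
#'
#' @param params a [gel_params()] object with `3*sigma0 + 2*f_adh*R_L > 0`.
#' @return critical radius, m.
#' @export
critical_radius <- function(params) {
  params <- validate_gel_params(params)
  denom <- 3 * params$sigma0 + 2 * params$f_adh * params$R_L
  if (denom <= 0)
    stop("3*sigma0 + 2*f_adh*R_L must be > 0: no finite critical radius")
  6 * params$gamma / denom
}

#' Critical adhesive force density for a pore of given initial size to open
#'
#' Inverts the critical-radius relation: returns the adhesive force density
#' at which the critical radius equals `R_init`, i.e.
#' \eqn{(6\gamma/R_{init} - 3\sigma_0) / (2 R_L)}, clamped at 0 when the
#' active stress alone suffices to open the pore.
#'
#' @param params a [gel_params()] object.
#' @param R_init initial pore radius, m; must be > 0.
#' @return adhesive force density, N/m^3.
#' @export
critical_adhesion <- function(params, R_init) {
  params <- validate_gel_params(params)
  if (!is.finite(R_init) || R_init <= 0) stop("R_init must be > 0")
  pmax(0, (6 * params$gamma / R_init - 3 * params$sigma0) / (2 * params$R_L))
}

#' Pore radius trajectory container
#'
#' @param times times, s, strictly increasing.
#' @param radii pore radii, m, within `[0, R_L]`.
#' @param terminated logical: did the trajectory stop on reaching `R_L`
#'   (rupture complete) or 0 (resealed)?
#' @param R_L contact radius used, m (optional, for validation).
#' @return an object of class `pore_trajectory` with fields `times`, `radii`,
#'   `terminated`.
#' @export
pore_trajectory <- function(times, radii, terminated = FALSE, R_L = NULL) {
  if (length(times) != length(radii))
    stop("times and radii must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(radii)))
    stop("times and radii must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(radii < 0)) stop("radii must be >= 0")
  if (!is.null(R_L) && any(radii > R_L * (1 + 1e-9)))
    stop("radii must be <= R_L")
  structure(list(times = as.numeric(times), radii = as.numeric(radii),
                 terminated = isTRUE(terminated)),
            class = "pore_trajectory")
}

#' @export
print.pore_trajectory <- function(x, ...) {
  cat(sprintf("Pore trajectory: %d samples, t in [%g, %g] s, R in [%g, %g] m%s\n",
              length(x$times), min(x$times), max(x$times),
              min(x$radii), max(x$radii),
              if (x$terminated) " (terminated)" else ""))
  invisible(x)
}

#' Write / read a pore trajectory as CSV
#'
#' CSV with header `t_s,R_m,terminated` (the flag is repeated on every row).
#'
#' @param traj a [pore_trajectory()].
#' @param path file path.
#' @return `read_pore_trajectory()` returns a [pore_trajectory()];
#'   the writer returns `path` invisibly.
#' @export
write_pore_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pore_trajectory"))
  df <- data.frame(t_s = traj$times, R_m = traj$radii,
                   terminated = traj$terminated)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pore_trajectory
#' @export
read_pore_trajectory <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "R_m") %in% names(df)))
    stop("expected columns t_s,R_m in ", path)
  pore_trajectory(df$t_s, df$R_m,
                  terminated = isTRUE(as.logical(df$terminated[1])))
}

#' Integrate the reduced pore-opening law
#'
#' Numerically integrates `dR/dt = pore_opening_rate(params, R)` from
#' `R_init` over `t_grid` with an adaptive solver (`deSolve::lsodar`,
#' rtol 1e-8, atol 1e-12 m). Integration stops, and the `terminated` flag is
#' set, when the pore reaches the contact radius `R_L` (rupture complete) or
#' closes to 0; root finding locates the stopping time. A pore started
#' exactly at the critical radius is returned as a constant trajectory.
#'
#' @param params a [gel_params()] object.
#' @param R_init initial pore radius, m, in `(0, R_L)`.
#' @param t_grid output times, s, strictly increasing, starting at the pore
#'   nucleation time (taken as t = 0 if `t_grid[1] == 0`).
#' @param rtol,atol integrator tolerances.
#' @return a [pore_trajectory()]. Output times beyond the stopping event are
#'   dropped; the event time and radius are appended as the final sample.
#' @export
simulate_pore <- function(params, R_init, t_grid, rtol = 1e-8, atol = 1e-12) {
  params <- validate_gel_params(params)
  if (!is.finite(R_init) || R_init <= 0 || R_init >= params$R_L)
    stop("R_init must lie strictly inside (0, R_L)")
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least 2 points")
  # guard the eta_eff floor over the whole radius range up front
  effective_viscosity(params, c(0, params$R_L))

  rhs <- function(t, y, parms) {
    R <- min(max(y[1], 0), params$R_L)
    list(pore_opening_rate(params, R))
  }
  root <- function(t, y, parms) c(y[1] - params$R_L, y[1])
  sol <- deSolve::lsodar(y = c(R = R_init), times = t_grid, func = rhs,
                         rootfunc = root, rtol = rtol, atol = atol)
  attr_diag <- attributes(sol)
  if (!is.null(attr_diag$istate) && attr_diag$istate[1] < 0)
    stop("integration failed (stiff failure) near t = ",
         signif(max(sol[, "time"]), 6), " s")
  times <- sol[, "time"]
  radii <- pmin(pmax(sol[, "R"], 0), params$R_L)
  terminated <- !is.null(attr_diag$iroot) && any(attr_diag$iroot != 0)
  # lsodar can return a duplicated terminal time; drop it
  keep <- c(TRUE, diff(times) > 0)
  pore_trajectory(times[keep], radii[keep], terminated = terminated,
                  R_L = params$R_L)
}

#' Classify the pore regime of a parameter set at a probe radius
#'
#' @param params a [gel_params()] object.
#' @param R probe radius, m.
#' @param tol rate magnitude below which the pore is considered stalled, m/s.
#' @return one of `"seals"`, `"opens_to_rupture"`, `"stalls"`.
#' @export
pore_regime <- function(params, R, tol = 1e-18) {
  rate <- pore_opening_rate(params, R)
  if (abs(rate) <= tol) "stalls" else if (rate > 0) "opens_to_rupture" else "seals"
}

#' Fixed-point analysis of the reduced law
#'
#' @param params a [gel_params()] object.
#' @param R_probe radius at which the regime is probed, m (defaults to
#'   the geometric mean of `R_c` and `R_L` when `R_c < R_L`, else `R_L/2`).
#' @return a list with `R_c` (unstable fixed point, m), `stable_radius`
#'   (`R_L` in the opening regime, 0 in the sealing regime, `R_probe` when
#'   stalled) and `regime`.
#' @export
fixed_points <- function(params, R_probe = NULL) {
  params <- validate_gel_params(params)
  R_c <- critical_radius(params)
  if (is.null(R_probe))
    R_probe <- if (R_c < params$R_L) sqrt(R_c * params$R_L) else params$R_L / 2
  regime <- pore_regime(params, R_probe)
  stable <- switch(regime,
                   opens_to_rupture = params$R_L,
                   seals = 0,
                   stalls = R_probe)
  list(R_c = R_c, stable_radius = stable, regime = regime)
}

#' Phase diagram of pore fate over adhesion and initial radius
#'
#' Labels each `(f_adh, R)` grid point by the sign of the reduced opening
#' rate and returns the unstable fixed-point curve `R_c(f_adh)` separating
#' sealing from opening; in the opening regime the stable fixed point is the
#' contact radius `R_L`.
#'
#' @param params a [gel_params()] object (its `f_adh` is overridden by the
#'   grid values).
#' @param f_adh_grid adhesive force densities, N/m^3, non-empty.
#' @param R_grid pore radii, m, non-empty, within `[0, R_L]`.
#' @return a list with `regime` (character matrix, radii in rows),
#'   `R_c` (vector along `f_adh_grid`, m) and the grids.
#' @export
phase_diagram <- function(params, f_adh_grid, R_grid) {
  params <- validate_gel_params(params)
  if (length(f_adh_grid) == 0L || length(R_grid) == 0L)
    stop("grids must be non-empty")
  if (any(f_adh_grid < 0)) stop("f_adh_grid must be >= 0")
  if (any(R_grid < 0 | R_grid > params$R_L))
    stop("R_grid must lie within [0, R_L]")
  lab <- matrix(NA_character_, nrow = length(R_grid),
                ncol = length(f_adh_grid),
                dimnames = list(NULL, NULL))
  R_c <- numeric(length(f_adh_grid))
  for (j in seq_along(f_adh_grid)) {
    pj <- params
    pj$f_adh <- f_adh_grid[j]
    pj <- validate_gel_params(pj)
    R_c[j] <- critical_radius(pj)
    for (i in seq_along(R_grid))
      lab[i, j] <- pore_regime(pj, R_grid[i])
  }
  list(regime = lab, R_c = R_c, f_adh_grid = f_adh_grid, R_grid = R_grid,
       stable_radius = params$R_L)
}
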