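#' Azimuthally symmetric actin field on the annulus between pore and contact line
#'
#' Node-centred uniform radial grid from the pore edge `R` to the contact
#' radius `R_L`, carrying the normalized actin density `rho` and the radial
#' velocity `v`.
#'
#' @param R pore radius, m.
#' @param R_L contact radius, m; `R_L > R`.
#' @param n number of grid nodes (>= 8).
#' @param rho normalized density on the grid: scalar (recycled) or length-n
#'   vector, >= 0.
#' @param v radial velocity on the grid, m/s (scalar or length-n).
#' @return object of class `radial_field` with fields `r`, `rho`, `v`, `R`,
#'   `R_L`, `h` (grid spacing).
#' @export
radial_field <- function(R, R_L, n = 200, rho = 1, v = 0) {
  if (!is.finite(R) || !is.finite(R_L) || R < 0 || R_L <= R)
    stop("need 0 <= R < R_L")
  if (n < 8) stop("n must be >= 8")
  r <- seq(R, R_L, length.out = n)
  rho <- rep_len(rho, n)
  v <- rep_len(v, n)
  if (any(rho < 0)) stop("rho must be >= 0")
  structure(list(r = r, rho = rho, v = v, R = R, R_L = R_L,
                 h = r[2] - r[1]),
            class = "radial_field")
}

# cell areas of the finite-volume tessellation implied by the node grid:
# interior nodes own [r - h/2, r + h/2], boundary nodes own half cells.
.cell_areas <- function(field) {
  r <- field$r; h <- field$h; n <- length(r)
  lo <- pmax(r - h / 2, field$R)
  hi <- pmin(r + h / 2, field$R_L)
  pi * (hi^2 - lo^2)
}

#' Total gel mass of a radial field
#'
#' Discrete mass \eqn{\int \rho \, 2\pi r \, dr} consistent with the
#' finite-volume tessellation used by [advance_density()].
#'
#' @param field a [radial_field()].
#' @return mass in units of (normalized density) x m^2.
#' @export
field_mass <- function(field) {
  sum(field$rho * .cell_areas(field))
}

#' Quasi-static radial force balance for the gel velocity
#'
#' Solves the linear two-point boundary-value problem
#' \deqn{\eta (v'' + v'/r - v/r^2) + \partial_r[\sigma_0 + \zeta(\rho-\rho_0)]
#'   = \Gamma v - f_{adh}}
#' on the current grid, with the constitutive stress linearized about the
#' reference density. Boundary conditions are prescribed total radial stress
#' \eqn{\eta v' + \sigma_0 + \zeta(\rho - \rho_0)} at both ends: a
#' membrane-tension pull `edge_stress` at the pore edge and zero (slip) at
#' the contact line. By default the edge stress is `C_edge / R`, where the
#' coefficient `C_edge` is anchored once per simulation so the
#' uniform-density limit reproduces the reduced opening law (see
#' [anchor_edge_coef()]).
#'
#' @param field a [radial_field()] (its `rho` enters the forcing).
#' @param params a [gel_params()] object; `Gamma` must be > 0 (with friction
#'   absent and stress conditions at both ends the system is singular and is
#'   reported as such).
#' @param edge_stress total radial stress imposed at the pore edge, Pa.
#' @return velocity on the grid, m/s.
#' @export
solve_velocity <- function(field, params, edge_stress) {
  stopifnot(inherits(field, "radial_field"))
  params <- validate_gel_params(params)
  if (params$Gamma <= 0)
    stop("singular system: Gamma = 0 with stress conditions at both ends")
  r <- field$r; h <- field$h; n <- length(r)
  eta <- params$eta; zeta <- params$zeta
  drho <- c(0, (field$rho[3:n] - field$rho[1:(n - 2)]) / (2 * h), 0)
  drho[1] <- (field$rho[2] - field$rho[1]) / h
  drho[n] <- (field$rho[n] - field$rho[n - 1]) / h

  A <- matrix(0, n, n)
  b <- numeric(n)
  i <- 2:(n - 1)
  A[cbind(i, i - 1)] <- eta * (1 / h^2 - 1 / (2 * h * r[i]))
  A[cbind(i, i)] <- eta * (-2 / h^2 - 1 / r[i]^2) - params$Gamma
  A[cbind(i, i + 1)] <- eta * (1 / h^2 + 1 / (2 * h * r[i]))
  b[i] <- -params$f_adh - zeta * drho[i]

  # stress BCs, second-order one-sided derivatives
  # eta v'(R)  = edge_stress - sigma0 - zeta (rho_1 - rho0)
  A[1, 1:3] <- eta * c(-3, 4, -1) / (2 * h)
  b[1] <- edge_stress - params$sigma0 - zeta * (field$rho[1] - params$rho0)
  # eta v'(R_L) = -sigma0 - zeta (rho_n - rho0)
  A[n, (n - 2):n] <- eta * c(1, -4, 3) / (2 * h)
  b[n] <- -params$sigma0 - zeta * (field$rho[n] - params$rho0)

  # row equilibration: entries span many orders when the annulus is thin
  s <- pmax(apply(abs(A), 1, max), .Machine$double.xmin)
  v <- tryCatch(solve(A / s, b / s),
                error = function(e) stop("velocity BVP is singular: ",
                                         conditionMessage(e)))
  as.numeric(v)
}

#' Anchor the pore-edge stress coefficient against the reduced law
#'
#' The exact boundary stress exerted by the retracting membrane at the pore
#' edge is modelled as `C_edge / R` (a membrane-tension-type term). The
#' coefficient is fixed by requiring that at uniform reference density the
#' edge velocity of the field model equals the reduced opening law
#' ([pore_opening_rate()]) at the current radius; the edge speed is linear
#' in the imposed stress, so the anchor is a two-solve closed form.
#'
#' @param params a [gel_params()] object.
#' @param R pore radius at which to anchor, m.
#' @param n grid nodes used for the anchoring solves.
#' @return coefficient `C_edge`, N/m (the imposed edge stress is
#'   `C_edge / R`).
#' @export
anchor_edge_coef <- function(params, R, n = 200) {
  params <- validate_gel_params(params)
  field <- radial_field(R, params$R_L, n = n, rho = params$rho0)
  target <- pore_opening_rate(params, R)
  v0 <- solve_velocity(field, params, edge_stress = 0)[1]
  v1 <- solve_velocity(field, params, edge_stress = 1)[1]
  if (abs(v1 - v0) < .Machine$double.eps)
    stop("edge speed insensitive to edge stress; cannot anchor")
  s_star <- (target - v0) / (v1 - v0)
  s_star * R
}

#' Advance the actin density one step on the moving domain
#'
#' Conservative first-order upwind finite-volume update of the continuity
#' equation \eqn{\partial_t \rho + \nabla\cdot(\rho v) = -(\rho-\rho_0)/\tau_a}
#' in radial geometry, in arbitrary Lagrangian--Eulerian form: grid faces
#' move affinely with the pore edge (the edge is material, no-slip, so the
#' advective flux through it vanishes identically) and the turnover term is
#' applied as an exact exponential sub-step. The domain is remapped to
#' `[R + v(R) dt, R_L]`; because the mesh motion is affine the grid stays
#' uniform and the update is exactly mass-conservative up to boundary fluxes
#' and turnover.
#'
#' @param field a [radial_field()] whose `v` is the current velocity.
#' @param dt time step, s; must satisfy the CFL condition
#'   `max |v - v_mesh| * dt <= 0.5 h`.
#' @param params a [gel_params()] object (only `tau_a`, `rho0` enter).
#' @param outer `"closed"` (no gel crosses the contact line; default) or
#'   `"open"` (upwind outflow at the contact line).
#' @param turnover set `FALSE` to switch the turnover sub-step off (for
#'   mass-conservation audits).
#' @return the advanced [radial_field()] (velocity carried over unchanged;
#'   re-solve before the next step).
#' @export
advance_density <- function(field, dt, params, outer = c("closed", "open"),
                            turnover = TRUE) {
  stopifnot(inherits(field, "radial_field"))
  outer <- match.arg(outer)
  params <- validate_gel_params(params)
  r <- field$r; h <- field$h; n <- length(r)
  v <- field$v; rho <- field$rho
  Rdot <- v[1]                               # no-slip: edge is material
  span <- field$R_L - field$R
  v_mesh <- Rdot * (field$R_L - r) / span

  rel <- v - v_mesh
  if (max(abs(rel)) * dt > 0.5 * h * (1 + 1e-12))
    stop("CFL violation: max|v - v_mesh|*dt = ",
         signif(max(abs(rel)) * dt, 4), " > 0.5*h = ", signif(0.5 * h, 4))

  # interior faces at node midpoints
  rf <- (r[-n] + r[-1]) / 2
  vf <- (rel[-n] + rel[-1]) / 2
  rho_up <- ifelse(vf >= 0, rho[-n], rho[-1])
  flux <- 2 * pi * rf * rho_up * vf          # mass per time through face

  areas <- .cell_areas(field)
  m <- rho * areas
  dm <- numeric(n)
  dm[1] <- -flux[1]                          # inner boundary flux is 0
  dm[2:(n - 1)] <- flux[1:(n - 2)] - flux[2:(n - 1)]
  dm[n] <- flux[n - 1]
  if (outer == "open") {
    out_v <- rel[n]
    if (out_v > 0) dm[n] <- dm[n] - 2 * pi * field$R_L * rho[n] * out_v
  }
  m_new <- m + dt * dm

  R_new <- field$R + Rdot * dt
  if (R_new < 0 || R_new >= field$R_L)
    stop("pore edge left the domain during the step; reduce dt")
  new <- radial_field(R_new, field$R_L, n = n, rho = 0, v = v)
  rho_new <- m_new / .cell_areas(new)
  if (any(rho_new < -1e-12 * max(abs(rho_new), 1)))
    stop("negative density after update: advection unstable")
  rho_new <- pmax(rho_new, 0)
  if (turnover)
    rho_new <- params$rho0 + (rho_new - params$rho0) * exp(-dt / params$tau_a)
  new$rho <- rho_new
  new
}

# exponential decay length of the velocity magnitude away from the pore edge
.decay_length <- function(field) {
  w <- abs(field$v - field$v[length(field$v)])
  wmax <- max(w)
  if (!is.finite(wmax) || wmax <= 0) return(NA_real_)
  # contiguous run rightwards from the peak while above exp(-3) of the peak
  start <- which.max(w)
  keep <- start
  for (j in seq(start + 1L, length(w))) {
    if (j > length(w) || w[j] <= wmax * exp(-3) || w[j] <= 0) break
    keep <- c(keep, j)
  }
  if (length(keep) < 4) return(NA_real_)
  fit <- stats::lm(log(w[keep]) ~ field$r[keep])
  slope <- stats::coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  as.numeric(-1 / slope)
}

#' Moving-boundary simulation of the coupled density and velocity fields
#'
#' Alternates the quasi-static velocity solve ([solve_velocity()]), the
#' conservative density advance ([advance_density()]) and the edge motion
#' `dR/dt = v(R)` (no-slip: the pore edge is material). The pore-edge stress
#' coefficient is anchored once at initialization ([anchor_edge_coef()]) and
#' then frozen, so the early-time edge speed matches the reduced law while
#' later dynamics are governed by the full fields (density pile-up at the
#' edge feeds back on the force balance through `zeta`).
#'
#' @param params a [gel_params()] object.
#' @param R_init initial pore radius, m, in `(0, R_L)`.
#' @param t_end simulated time horizon, s.
#' @param n grid nodes.
#' @param n_out number of recorded output frames (evenly spaced in time).
#' @param R_stop_frac integration stops (flag `terminated`) once
#'   `R >= R_stop_frac * R_L`.
#' @param cfl CFL number for the advection step (<= 0.5).
#' @param outer outer mass boundary, see [advance_density()].
#' @param store_fields keep the full [radial_field()] at each output frame.
#' @return object of class `field_trajectory`: `times`, `R`, `mean_density`
#'   (area-averaged density over the annulus, units of rho0), `flow_peak`
#'   (max |v|, m/s), `decay_length` (fitted exponential decay length of the
#'   edge flow, m), `edge_speed` (m/s), `C_edge` (anchored coefficient, N/m),
#'   `terminated`, and optionally `fields`.
#' @export
simulate_fields <- function(params, R_init, t_end, n = 200, n_out = 40,
                            R_stop_frac = 0.95, cfl = 0.4,
                            outer = c("closed", "open"),
                            store_fields = FALSE) {
  params <- validate_gel_params(params)
  outer <- match.arg(outer)
  if (R_init <= 0 || R_init >= params$R_L)
    stop("R_init must lie strictly inside (0, R_L)")
  if (t_end <= 0) stop("t_end must be > 0")

  C_edge <- anchor_edge_coef(params, R_init, n = n)
  field <- radial_field(R_init, params$R_L, n = n, rho = params$rho0)
  t_out <- seq(0, t_end, length.out = n_out + 1)

  rec <- list(times = numeric(0), R = numeric(0), mean_density = numeric(0),
              flow_peak = numeric(0), decay_length = numeric(0),
              edge_speed = numeric(0), fields = list())
  record <- function(t, field) {
    rec$times <<- c(rec$times, t)
    rec$R <<- c(rec$R, field$R)
    rec$mean_density <<- c(rec$mean_density,
                           field_mass(field) / sum(.cell_areas(field)) /
                             params$rho0)
    rec$flow_peak <<- c(rec$flow_peak, max(abs(field$v)))
    rec$decay_length <<- c(rec$decay_length, .decay_length(field))
    rec$edge_speed <<- c(rec$edge_speed, field$v[1])
    if (store_fields) rec$fields[[length(rec$fields) + 1L]] <<- field
  }

  t <- 0
  field$v <- solve_velocity(field, params, edge_stress = C_edge / field$R)
  record(t, field)
  next_out <- 2L
  terminated <- FALSE
  max_steps <- 200000L
  for (step in seq_len(max_steps)) {
    if (t >= t_end || terminated || next_out > length(t_out)) break
    Rdot <- field$v[1]
    span <- field$R_L - field$R
    v_mesh <- Rdot * (field$R_L - field$r) / span
    vmax <- max(abs(field$v - v_mesh))
    dt_cfl <- if (vmax > 0) cfl * field$h / vmax else t_end / n_out
    dt <- min(dt_cfl, params$tau_a / 10, t_out[next_out] - t, t_end - t)
    dt <- max(dt, 1e-12)
    field <- advance_density(field, dt, params, outer = outer)
    t <- t + dt
    field$v <- solve_velocity(field, params, edge_stress = C_edge / field$R)
    if (abs(t - t_out[next_out]) < 1e-9 * max(t_out[next_out], 1)) {
      record(t, field)
      next_out <- next_out + 1L
    }
    if (field$R >= R_stop_frac * params$R_L) {
      terminated <- TRUE
      if (abs(t - rec$times[length(rec$times)]) > 1e-12) record(t, field)
    }
  }
  structure(c(rec, list(C_edge = C_edge, terminated = terminated,
                        params = params)),
            class = "field_trajectory")
}

#' @export
print.field_trajectory <- function(x, ...) {
  cat(sprintf(
    "Field trajectory: %d frames, t in [%g, %g] s, R %g -> %g m%s\n",
    length(x$times), min(x$times), max(x$times), x$R[1],
    x$R[length(x$R)], if (x$terminated) " (terminated)" else ""))
  invisible(x)
}

#' Export a field-trajectory summary as CSV
#'
#' One row per recorded frame with columns
#' `t_s,R_m,mean_density,flow_peak_m_s,decay_length_m,edge_speed_m_s`.
#'
#' @param ft a `field_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_summary <- function(ft, path) {
  stopifnot(inherits(ft, "field_trajectory"))
  df <- data.frame(t_s = ft$times, R_m = ft$R,
                   mean_density = ft$mean_density,
                   flow_peak_m_s = ft$flow_peak,
                   decay_length_m = ft$decay_length,
                   edge_speed_m_s = ft$edge_speed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
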