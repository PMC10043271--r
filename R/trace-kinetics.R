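#' Time series container for radius / intensity traces
#'
#' @param t times, s, strictly increasing.
#' @param y values (m for radii, arbitrary units for intensity).
#' @param label free-text label.
#' @param units free-text units of `y`.
#' @return object of class `time_series`.
#' @export
time_series <- function(t, y, label = "", units = "") {
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("t and y must be finite")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(list(t = as.numeric(t), y = as.numeric(y),
                 label = label, units = units),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Time series '%s': %d samples, t in [%g, %g] s%s\n",
              x$label, length(x$t), min(x$t), max(x$t),
              if (nzchar(x$units)) paste0(", units ", x$units) else ""))
  invisible(x)
}

#' Write / read a trace as CSV (`t_s,value`)
#' @param ts a [time_series()].
#' @param path file path.
#' @return the reader returns a [time_series()]; the writer returns `path`
#'   invisibly.
#' @export
write_time_series <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  utils::write.csv(data.frame(t_s = ts$t, value = ts$y), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_series
#' @export
read_time_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "value") %in% names(df)))
    stop("expected columns t_s,value in ", path)
  time_series(df$t_s, df$value, label = basename(path))
}

.fit_result <- function(model_name, estimates, se, rms, converged) {
  structure(list(model_name = model_name, estimates = estimates,
                 se = se, residual_rms = rms, converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit '%s'%s, residual RMS %.4g\n", x$model_name,
              if (x$converged) "" else " (NOT converged)", x$residual_rms))
  est <- data.frame(estimate = x$estimates, se = x$se)
  print(est)
  invisible(x)
}

#' Pore-opening timescale from a radius trace
#'
#' Least-squares fit of the saturating exponential
#' \eqn{R(t) = R_\infty - (R_\infty - R_0) e^{-(t - t_0)/\tau}} with
#' `R_0`, `R_inf` and `tau` free and `t_0` fixed at the first sample; the
#' pore saturates at the contact radius, so the saturating form is the
#' default. A growing-exponential variant
#' \eqn{R(t) = R_0 e^{(t - t_0)/\tau}} is available with `form = "growing"`.
#'
#' @param ts a [time_series()] of non-negative radii with at least 6 points.
#' @param form `"saturating"` (default) or `"growing"`.
#' @return a `fit_result` with estimates `R0`, `R_inf` (saturating only) and
#'   `tau` (s) with asymptotic standard errors.
#' @export
fit_pore_radius <- function(ts, form = c("saturating", "growing")) {
  stopifnot(inherits(ts, "time_series"))
  form <- match.arg(form)
  if (length(ts$t) < 6) stop("need at least 6 points")
  if (any(ts$y < 0)) stop("radii must be non-negative")
  t0 <- ts$t[1]
  tt <- ts$t - t0
  y <- ts$y
  if (stats::sd(y) == 0) stop("fit did not converge: constant trace")
  rng <- diff(range(y))
  if (form == "saturating") {
    start <- list(R_inf = max(y) + 0.05 * rng, R0 = y[1],
                  tau = max(tt[which(y >= y[1] + 0.63 * (max(y) - y[1]))][1],
                            diff(range(tt)) / 10, na.rm = TRUE))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ R_inf - (R_inf - R0) * exp(-tt / tau),
                        start = start,
                        lower = c(R_inf = 0, R0 = 0, tau = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("fit did not converge: ",
                               conditionMessage(e)))
  } else {
    start <- list(R0 = max(y[1], 1e-12), tau = diff(range(tt)) / 3)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ R0 * exp(tt / tau), start = start,
                        lower = c(R0 = 0, tau = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("fit did not converge: ",
                               conditionMessage(e)))
  }
  est <- stats::coef(fit)
  if (est[["tau"]] <= 0) stop("negative or zero fitted tau")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  .fit_result(paste0(form, "_exponential"), est, se,
              sqrt(mean(stats::resid(fit)^2)), fit$convInfo$isConv)
}

#' Standard pore-opening timescale protocol for a parameter set
#'
#' Integrates the reduced law from `R_init` until rupture, extends the trace
#' with the physical plateau at the contact radius (after rupture completes
#' the pore equals the contact area, as in the measured traces), resamples
#' uniformly, and fits the saturating exponential. This is the package's
#' fixed measurement protocol for the model timescale tau.
#'
#' @param params a [gel_params()] object.
#' @param R_init initial pore radius, m (default 0.5 um, a spontaneous pore
#'   just above the critical radius at the shipped defaults).
#' @param n_points samples in the fitted trace.
#' @param plateau_factor plateau duration as a multiple of the opening time.
#' @param max_t give up if rupture has not completed by this time, s.
#' @return list with `tau` (s), `fit` (the `fit_result`), and `trace`
#'   (the fitted [time_series()]).
#' @export
pore_timescale <- function(params, R_init = 5e-7, n_points = 200,
                           plateau_factor = 1, max_t = 10000) {
  params <- validate_gel_params(params)
  traj <- simulate_pore(params, R_init,
                        t_grid = seq(0, max_t, length.out = 4001))
  if (!traj$terminated)
    stop("pore did not rupture within max_t = ", max_t, " s")
  t_rupt <- max(traj$times)
  tt <- seq(0, t_rupt * (1 + plateau_factor), length.out = n_points)
  yy <- stats::approx(traj$times, traj$radii, xout = tt, rule = 2)$y
  trace <- time_series(tt, yy, label = "pore radius", units = "m")
  fit <- fit_pore_radius(trace)
  list(tau = unname(fit$estimates[["tau"]]), fit = fit, trace = trace)
}

#' Normalize a pore-opening timescale to the bare-liposome timescale
#'
#' @param tau timescale, s.
#' @param tau_BL bare (empty) liposome timescale, s; > 0.
#' @return dimensionless ratio `tau / tau_BL`.
#' @export
normalize_tau <- function(tau, tau_BL) {
  if (!is.finite(tau_BL) || tau_BL <= 0) stop("tau_BL must be > 0")
  tau / tau_BL
}

#' Actin turnover time from a centre-depletion intensity trace
#'
#' Detects the onset of depolymerization as the last time the smoothed trace
#' is within 2 percent of its running maximum, then fits
#' \eqn{I(t) = I_\infty + (I_0 - I_\infty) e^{-(t - t_{onset})/\tau_a}} on
#' the samples from the onset onwards.
#'
#' @param ts a [time_series()] of intensities with a decreasing trend.
#' @param onset_frac onset rule: last time within `onset_frac` of the
#'   running maximum (default 0.02).
#' @param smooth_k running-mean half-width for the onset detection, samples.
#' @return a `fit_result` with estimates `I0`, `I_inf`, `tau_a` (s) and the
#'   detected `onset` time stored as attribute `"onset"`.
#' @export
fit_center_depletion <- function(ts, onset_frac = 0.02, smooth_k = 4) {
  stopifnot(inherits(ts, "time_series"))
  if (length(ts$t) < 6) stop("need at least 6 points")
  # running median: a running mean lets single noise spikes inflate the
  # running maximum, which then never re-enters the onset band
  k <- min(2 * smooth_k + 1, length(ts$y) - (1 - length(ts$y) %% 2))
  sm <- as.numeric(stats::runmed(ts$y, max(3, k - (1 - k %% 2))))
  if (stats::coef(stats::lm(sm ~ ts$t))[2] >= 0)
    stop("trace is rising; expected a decaying depletion trace")
  runmax <- cummax(sm)
  near_max <- sm >= (1 - onset_frac) * runmax
  onset_idx <- max(which(near_max))
  if (onset_idx > length(ts$t) - 5) onset_idx <- max(1L, length(ts$t) - 5L)

  # refine the onset by profiling a plateau-then-exponential model over
  # candidate onsets around the detected one: the threshold rule alone is
  # biased under noise (the running maximum drifts upward), whereas the
  # changepoint least-squares profile is not
  n <- length(ts$t)
  span <- max(2L, ceiling(n / 16))
  cand <- unique(pmin(pmax(onset_idx + seq(-span, span, length.out = 9L),
                           1L), n - 5L))
  cand <- as.integer(round(cand))
  last_err <- NULL
  profile_fit <- function(cand) {
  best <- NULL
  yy <- ts$y
  for (ci in cand) {
    t0 <- ts$t[ci]
    ttc <- pmax(ts$t - t0, 0)
    start <- list(I_inf = min(yy), I0 = max(sm),
                  tau_a = max(diff(range(ts$t)) / 4, 1e-9))
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ I_inf + (I0 - I_inf) * exp(-ttc / tau_a),
                        start = start,
                        lower = c(I_inf = -Inf, I0 = -Inf, tau_a = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse, t0 = t0, ci = ci)
  }
  best
  }
  best <- profile_fit(cand)
  if (is.null(best))
    stop("fit did not converge for any candidate onset",
         if (!is.null(last_err)) paste0(" (", last_err, ")") else "")
  # second pass at single-sample resolution around the coarse optimum
  step <- max(1L, as.integer(round(diff(range(cand)) / 8)))
  fine <- unique(pmin(pmax(seq(best$ci - step, best$ci + step), 1L),
                      n - 5L))
  best_fine <- profile_fit(setdiff(fine, best$ci))
  if (!is.null(best_fine) && best_fine$sse < best$sse) best <- best_fine
  fit <- best$fit
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  out <- .fit_result("center_depletion_exponential", est, se,
                     sqrt(mean(stats::resid(fit)^2)), fit$convInfo$isConv)
  attr(out, "onset") <- best$t0
  out
}

#' Normalize an intensity trace to a baseline window (density fold change)
#'
#' @param ts a [time_series()].
#' @param baseline_window `c(t_min, t_max)` in s; the mean of `y` over this
#'   window (which must be > 0) is the normalization.
#' @return a [time_series()] of fold change (dimensionless).
#' @export
density_fold <- function(ts, baseline_window) {
  stopifnot(inherits(ts, "time_series"))
  if (length(baseline_window) != 2L) stop("baseline_window must be c(t0, t1)")
  sel <- ts$t >= baseline_window[1] & ts$t <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- mean(ts$y[sel])
  if (base <= 0) stop("baseline mean must be > 0")
  time_series(ts$t, ts$y / base, label = paste0(ts$label, " (fold)"),
              units = "rho/rho0")
}

#' Kymograph container
#'
#' @param intensity matrix, rows = time lines, columns = positions.
#' @param pixel_size m per pixel.
#' @param frame_interval s per time line.
#' @return object of class `kymograph`.
#' @export
kymograph <- function(intensity, pixel_size, frame_interval) {
  intensity <- as.matrix(intensity)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "kymograph")
}

#' Cumulative displacement and displacement gradient from a kymograph
#'
#' One-dimensional particle-image velocimetry: per consecutive pair of time
#' lines, windowed normalized cross-correlation (default window 8 px, 50
#' percent overlap) with parabolic sub-pixel peak refinement yields the
#' incremental displacement per window; cumulative displacement `U(x, t)` is
#' the time sum and the displacement gradient is the central difference of
#' `U` on the window-centre grid.
#'
#' @param kymo a [kymograph()] with at least 16 px in x and 3 time lines.
#' @param window correlation window, px.
#' @param overlap window overlap fraction.
#' @param max_shift largest integer lag searched, px.
#' @param min_peak windows whose correlation peak falls below this value are
#'   flagged (their increment is set to NA and carried forward).
#' @return list with `x` (window centres, m), `t` (s, one per time line
#'   starting at the second), `U` (matrix, m), `dUdx` (matrix,
#'   dimensionless), `peak_cor` (matrix of correlation peaks), and the pixel
#'   calibration.
#' @export
displacement_gradient <- function(kymo, window = 8, overlap = 0.5,
                                  max_shift = 6, min_peak = 0.5) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$intensity
  nt <- nrow(img); nx <- ncol(img)
  if (nx < 16) stop("kymograph must be at least 16 px wide")
  if (nt < 3) stop("kymograph must have at least 3 time lines")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq(1L, nx - window + 1L, by = step)
  xc <- starts + (window - 1) / 2

  ncc_shift <- function(a_line, b_line, x0) {
    w1 <- a_line[x0:(x0 + window - 1L)]
    if (stats::sd(w1) == 0) return(c(NA_real_, NA_real_))
    lags <- -max_shift:max_shift
    cc <- rep(-Inf, length(lags))
    for (k in seq_along(lags)) {
      lo <- x0 + lags[k]; hi <- lo + window - 1L
      if (lo < 1L || hi > nx) next
      w2 <- b_line[lo:hi]
      if (stats::sd(w2) == 0) next
      cc[k] <- stats::cor(w1, w2)
    }
    kbest <- which.max(cc)
    if (!is.finite(cc[kbest])) return(c(NA_real_, NA_real_))
    shift <- lags[kbest]
    if (cc[kbest] < 1 - 1e-9 &&      # exact match needs no refinement
        kbest > 1 && kbest < length(lags) &&
        is.finite(cc[kbest - 1]) && is.finite(cc[kbest + 1])) {
      denom <- cc[kbest - 1] - 2 * cc[kbest] + cc[kbest + 1]
      if (denom < 0)
        shift <- shift + 0.5 * (cc[kbest - 1] - cc[kbest + 1]) / denom
    }
    c(shift, cc[kbest])
  }

  npair <- nt - 1L
  inc <- matrix(NA_real_, npair, length(starts))
  pk <- matrix(NA_real_, npair, length(starts))
  for (ti in seq_len(npair)) {
    for (wi in seq_along(starts)) {
      res <- ncc_shift(img[ti, ], img[ti + 1L, ], starts[wi])
      inc[ti, wi] <- res[1]
      pk[ti, wi] <- res[2]
    }
  }
  flagged <- !is.finite(pk) | pk < min_peak
  inc[flagged] <- NA_real_
  # universal-median outlier validation: a window whose increment deviates
  # from the local median of its row by more than 1 px is replaced by it
  if (ncol(inc) >= 5) {
    for (ti in seq_len(npair)) {
      row <- inc[ti, ]
      ok <- is.finite(row)
      if (sum(ok) < 3) next
      med <- stats::runmed(ifelse(ok, row, stats::median(row[ok])), 5)
      bad <- ok & abs(row - med) > 1
      row[bad] <- med[bad]
      inc[ti, ] <- row
    }
  }
  inc_filled <- inc
  inc_filled[is.na(inc_filled)] <- 0
  U <- apply(inc_filled, 2, cumsum)
  if (npair == 1L) U <- matrix(U, nrow = 1L)
  U <- U * kymo$pixel_size
  dx <- diff(xc)[1] * kymo$pixel_size
  dUdx <- t(apply(U, 1, function(u) {
    n <- length(u)
    c(u[2] - u[1], (u[3:n] - u[1:(n - 2)]) / 2, u[n] - u[n - 1]) / dx
  }))
  list(x = xc * kymo$pixel_size,
       t = (seq_len(npair)) * kymo$frame_interval,
       U = U, dUdx = dUdx, peak_cor = pk, flagged = flagged,
       pixel_size = kymo$pixel_size, frame_interval = kymo$frame_interval)
}

#' Fit the reduced active-gel law to a measured pore-radius trace
#'
#' Nonlinear least squares over [simulate_pore()] outputs: the chosen free
#' parameters are adjusted so the integrated reduced law matches the trace
#' (radii beyond rupture are held at the contact radius). Reports the fitted
#' values, the myosin layer tension `sigma0 * d`, and the fluidization
#' diagnostic curve \eqn{\eta_{eff}(t) / \eta_{eff}(\zeta = 0)} along the
#' fitted trajectory.
#'
#' @param ts a [time_series()] pore-radius trace, m; the first sample is the
#'   initial radius.
#' @param params a [gel_params()] object supplying the fixed parameters and
#'   the starting values of the free ones.
#' @param free character subset of
#'   `c("eta", "sigma0", "zeta", "f_adh", "gamma")`.
#' @return a `fit_result` whose estimates are the free parameters, plus
#'   components `sigma_a_d` (N/m), `eta_eff_ratio` (a [time_series()]),
#'   `identifiable` (FALSE when the approximate covariance is singular) and
#'   `params` (the full fitted parameter set).
#' @export
fit_model_to_trace <- function(ts, params,
                               free = c("sigma0", "zeta")) {
  stopifnot(inherits(ts, "time_series"))
  params <- validate_gel_params(params)
  allowed <- c("eta", "sigma0", "zeta", "f_adh", "gamma")
  if (!all(free %in% allowed))
    stop("free must be a subset of ", paste(allowed, collapse = ", "))
  R_init <- ts$y[1]
  if (R_init <= 0 || R_init >= params$R_L)
    stop("first trace sample must be a radius inside (0, R_L)")
  tt <- ts$t - ts$t[1]

  predict_trace <- function(theta) {
    p <- params
    for (nm in names(theta)) p[[nm]] <- theta[[nm]]
    p <- tryCatch(validate_gel_params(p), error = function(e) NULL)
    if (is.null(p)) return(NULL)
    traj <- tryCatch(
      simulate_pore(p, R_init, t_grid = unique(c(0, tt[tt > 0]))),
      error = function(e) NULL)
    if (is.null(traj)) return(NULL)
    stats::approx(traj$times, traj$radii, xout = tt, rule = 2)$y
  }
  resid_fn <- function(par) {
    pred <- predict_trace(as.list(par))
    if (is.null(pred)) return(rep(1e3 * params$R_L, length(tt)))
    pred - ts$y
  }
  start <- unlist(params[free])
  lower <- c(eta = 1e-6, sigma0 = -Inf, zeta = -Inf, f_adh = 0,
             gamma = 0)[free]
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- stats::coef(fit)
  hess <- fit$hessian
  identifiable <- TRUE
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  cov_try <- tryCatch({
    dof <- max(length(tt) - length(est), 1)
    s2 <- fit$deviance / dof
    covm <- solve(hess) * 2 * s2
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) NULL)
  if (is.null(cov_try) || any(!is.finite(cov_try))) {
    identifiable <- FALSE
  } else {
    se <- cov_try
  }
  p_fit <- params
  for (nm in names(est)) p_fit[[nm]] <- est[[nm]]
  p_fit <- validate_gel_params(p_fit)
  pred <- predict_trace(as.list(est))
  eff <- effective_viscosity(p_fit, pmin(pred, p_fit$R_L))
  p0 <- p_fit; p0$zeta <- 0
  eff0 <- effective_viscosity(validate_gel_params(p0),
                              pmin(pred, p_fit$R_L))
  out <- .fit_result("active_gel_pore_law", est, se,
                     sqrt(fit$deviance / length(tt)),
                     fit$info %in% 1:4)
  out$sigma_a_d <- p_fit$sigma0 * p_fit$d
  out$eta_eff_ratio <- time_series(ts$t, eff / eff0,
                                   label = "eta_eff/eta_eff(zeta=0)")
  out$identifiable <- identifiable
  out$params <- p_fit
  out
}

.p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}

#' Two-sided Welch t-test between two groups
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `statistic`, `p_value`, `df`, `stars` (significance
#'   convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#' @export
group_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (equal) 0 else Inf,
                p_value = if (equal) 1 else 0,
                df = NA_real_, stars = if (equal) "n.s." else "***"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), stars = .p_stars(tt$p.value))
}

#' Fisher exact test on a 2x2 prevalence table
#'
#' Exact two-sided p-value obtained by summing hypergeometric probabilities
#' no larger than that of the observed table (conditional on the margins).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `p_value` and `stars`.
#' @export
prevalence_compare <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margins")
  p <- stats::fisher.test(table)$p.value
  list(p_value = p, stars = .p_stars(p))
}
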