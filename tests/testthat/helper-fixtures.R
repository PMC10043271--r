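# shared fixtures and independent oracles

# fixed-step RK4 integration of the reduced opening law; independent of
# simulate_pore's adaptive path
rk4_pore <- function(params, R_init, t_grid) {
  f <- function(R) {
    R <- min(max(R, 0), params$R_L)
    pore_opening_rate(params, R)
  }
  R <- numeric(length(t_grid))
  R[1] <- R_init
  for (i in seq_len(length(t_grid) - 1)) {
    h <- t_grid[i + 1] - t_grid[i]
    y <- R[i]
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    R[i + 1] <- min(max(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0),
                    params$R_L)
  }
  R
}

# brute-force two-sided Fisher p: sum all hypergeometric probabilities not
# exceeding that of the observed table, conditioning on the margins
fisher_bruteforce <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); s <- sum(tab[, 1])
  support <- max(0, s - n):min(m, s)
  probs <- stats::dhyper(support, m, n, s)
  p_obs <- stats::dhyper(tab[1, 1], m, n, s)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random valid parameter draw for property tests
random_gel_params <- function() {
  gel_params(eta = stats::runif(1, 50, 5000),
             Gamma = stats::runif(1, 1e13, 1e15),
             sigma0 = stats::runif(1, 0, 5),
             zeta = stats::runif(1, -2, 2),
             tau_a = stats::runif(1, 20, 300),
             gamma = stats::runif(1, 1e-7, 1e-4),
             f_adh = stats::runif(1, 1e5, 5e7),
             R_L = stats::runif(1, 5e-6, 3e-5),
             d = 1e-7)
}

# disk mask centred on a generated movie frame, eroded by `erode` metres
movie_disk_mask <- function(frame, R_liposome, erode = 0) {
  n <- nrow(frame$intensity)
  cxy <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  sqrt((xs - cxy)^2 + (ys - cxy)^2) <= R_liposome / frame$pixel_size -
    erode / frame$pixel_size
}

# detection scoring against a planted-feature truth table
match_detections <- function(det, truth, tol) {
  if (nrow(truth) == 0) return(list(recall = NA, precision = NA))
  recall <- mean(vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(det) == 0) return(Inf)
    min(sqrt((det$x_m - truth$x_m[i])^2 + (det$y_m - truth$y_m[i])^2))
  }, numeric(1)) < tol)
  precision <- if (nrow(det) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(det)), function(i) {
      min(sqrt((truth$x_m - det$x_m[i])^2 + (truth$y_m - det$y_m[i])^2))
    }, numeric(1)) < tol)
  }
  list(recall = recall, precision = precision)
}

# scenario used for the (sigma0, zeta) recovery suite: active-stress
# dominated so both parameters are identifiable (see vignette)
recovery_params <- function() {
  gel_params(eta = 300, Gamma = 2.5e14, sigma0 = 1, zeta = 1, tau_a = 100,
             gamma = 2e-7, f_adh = 1e5, R_L = 1e-5, d = 1e-7)
}
recovery_tgrid <- function() seq(0, 2200, length.out = 250)

# rebuild a gel_params object with some fields replaced
with_params <- function(p, ...) {
  do.call(gel_params, utils::modifyList(unclass(p), list(...)))
}
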