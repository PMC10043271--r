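# run code under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scene configuration for the liposome movie generator
#'
#' All randomness in a generated scene is a pure function of `seed`: the
#' global random stream is split deterministically per feature, so repeated
#' calls are bit-identical.
#'
#' @param seed integer seed fixing all randomness.
#' @param pixel_size m per pixel (default 0.1 um).
#' @param frame_interval s between frames.
#' @param R_liposome contact radius, m.
#' @param n_frames number of frames.
#' @param noise_model `"gaussian"` (read noise, sd = `noise_sd` of the unit
#'   dynamic range) or `"poisson"` (shot noise with `gain` expected counts
#'   at unit intensity).
#' @param noise_sd Gaussian noise sd, fraction of dynamic range.
#' @param gain Poisson gain, counts at unit intensity.
#' @param n_spots number of peripheral actin spots.
#' @param spot_snr spot peak amplitude over noise sd.
#' @param spot_diam spot FWHM diameter, m.
#' @param ring_width width of the peripheral annulus holding the spots, m.
#' @param spot_margin clearance between spot centres and the contact line, m.
#' @param psf_sigma Gaussian point-spread sd applied to every clean frame, m
#'   (single-Gaussian optics model).
#' @param n_blisters number of dark brightfield blisters.
#' @param blister_radii radius range `c(min, max)` of blisters, m.
#' @param tau_a centre-depletion time constant, s.
#' @param depletion_floor terminal fraction of the initial interior
#'   intensity.
#' @param pore_trajectory optional `field_trajectory` (with stored fields)
#'   rendered as an opening dark pore advecting the layer intensity.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(seed, pixel_size = 1e-7, frame_interval = 5,
                         R_liposome = 1e-5, n_frames = 12,
                         noise_model = c("gaussian", "poisson"),
                         noise_sd = 0.05, gain = 400,
                         n_spots = 10, spot_snr = 5, spot_diam = 1e-6,
                         ring_width = 2e-6, spot_margin = 1e-6, psf_sigma = 1.5e-7,
                         n_blisters = 0, blister_radii = c(1e-6, 2e-6),
                         tau_a = 100, depletion_floor = 0.2,
                         pore_trajectory = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.finite(seed), pixel_size > 0, frame_interval > 0,
            R_liposome > 0, n_frames >= 1, noise_sd >= 0, gain > 0,
            n_spots >= 0, spot_snr > 0, spot_diam > 0, ring_width > 0,
            spot_margin >= 0, n_blisters >= 0, tau_a > 0,
            depletion_floor >= 0, depletion_floor < 1)
  if (ring_width + spot_margin >= R_liposome)
    stop("spot annulus does not fit inside the liposome")
  stopifnot(psf_sigma >= 0)
  structure(list(seed = as.integer(seed), pixel_size = pixel_size,
                 frame_interval = frame_interval, R_liposome = R_liposome,
                 n_frames = as.integer(n_frames), noise_model = noise_model,
                 noise_sd = noise_sd, gain = gain,
                 n_spots = as.integer(n_spots), spot_snr = spot_snr,
                 spot_diam = spot_diam, ring_width = ring_width,
                 spot_margin = spot_margin, psf_sigma = psf_sigma,
                 n_blisters = as.integer(n_blisters),
                 blister_radii = blister_radii, tau_a = tau_a,
                 depletion_floor = depletion_floor,
                 pore_trajectory = pore_trajectory),
            class = "scene_config")
}

.apply_noise <- function(img, cfg) {
  if (cfg$noise_model == "gaussian") {
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_sd),
                          nrow(img))
  } else {
    img <- matrix(stats::rpois(length(img), pmax(img, 0) * cfg$gain),
                  nrow(img)) / cfg$gain
  }
  pmax(img, 0)
}

#' Noisy pore-radius trace from the reduced model, with ground truth
#'
#' Runs [simulate_pore()] and adds i.i.d. Gaussian noise of the stated sd.
#'
#' @param params a [gel_params()] object.
#' @param R_init initial pore radius, m.
#' @param t_grid output times, s.
#' @param noise_sd noise sd: metres for `noise_type = "additive"`, or a
#'   fraction of the current radius for `noise_type = "relative"` (the
#'   natural model for a radius measured from images, whose uncertainty
#'   scales with the object size). 0 gives the clean trajectory resampled.
#' @param seed integer seed.
#' @param noise_type `"additive"` or `"relative"`.
#' @return list with `trace` (a [time_series()]) and `truth` (list with the
#'   clean trajectory, parameters, `R_init`, `noise_sd`, `seed`).
#' @export
gen_pore_trace <- function(params, R_init, t_grid, noise_sd = 0, seed = 1,
                           noise_type = c("additive", "relative")) {
  params <- validate_gel_params(params)
  noise_type <- match.arg(noise_type)
  traj <- simulate_pore(params, R_init, t_grid)
  clean <- stats::approx(traj$times, traj$radii, xout = t_grid, rule = 2)$y
  noisy <- if (noise_sd > 0) {
    .with_seed(seed, {
      eps <- stats::rnorm(length(clean), 0, noise_sd)
      if (noise_type == "relative") clean * (1 + eps) else clean + eps
    })
  } else clean
  list(trace = time_series(t_grid, pmax(noisy, 0), label = "pore radius",
                           units = "m"),
       truth = list(trajectory = traj, clean = clean, params = params,
                    R_init = R_init, noise_sd = noise_sd,
                    noise_type = noise_type, seed = seed))
}

#' Synthetic liposome movie with known ground truth
#'
#' Renders a disk liposome on a dark background with, per the configuration:
#' peripheral actin spots (Gaussian blobs of FWHM `spot_diam`, logistic
#' onset at per-spot times drawn uniformly over the first 60 percent of the
#' movie), brightfield blisters (dark smoothed disks) with actin enrichment
#' spreading around their rims as a logistic angular wave, interior
#' intensity depleting exponentially with time constant `tau_a`, and
#' optionally an opening pore whose dark interior and advected layer
#' intensity are taken from a stored [simulate_fields()] trajectory. Noise
#' is added last.
#'
#' @param cfg a [scene_config()].
#' @return list with `actin` and `brightfield` (lists of [image_frame()])
#'   and `truth` (spot table, blister table, wave parameters, `tau_a`,
#'   `center`, `R_liposome`, and the pore trajectory when present).
#' @export
gen_liposome_movie <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  ps <- cfg$pixel_size
  R_px <- cfg$R_liposome / ps
  npx <- 2L * ceiling(R_px * 1.15) + 1L
  cx <- (npx + 1) / 2
  xs <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
  ys <- matrix(seq_len(npx), npx, npx)
  rr <- sqrt((xs - cx)^2 + (ys - cx)^2)     # px from centre
  disk <- rr <= R_px
  center_m <- c(cx, cx) * ps
  times <- (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval

  # rejection-sample positions with a minimum pairwise separation so that
  # planted features stay resolvable; deterministic under the seed
  .place <- function(n, draw_xy, min_sep, max_try = 500) {
    xs_ <- numeric(0); ys_ <- numeric(0)
    tries <- 0
    while (length(xs_) < n && tries < max_try * n) {
      tries <- tries + 1
      p <- draw_xy()
      if (length(xs_) == 0 ||
          all(sqrt((xs_ - p[1])^2 + (ys_ - p[2])^2) >= min_sep)) {
        xs_ <- c(xs_, p[1]); ys_ <- c(ys_, p[2])
      }
    }
    if (length(xs_) < n)
      stop("feature overflow: cannot place ", n,
           " features at the requested separation")
    cbind(xs_, ys_)
  }

  .with_seed(cfg$seed, {
    # feature draws, one block per feature type (deterministic split)
    sp_xy <- .place(cfg$n_spots, function() {
      r <- stats::runif(1, cfg$R_liposome - cfg$spot_margin - cfg$ring_width,
                        cfg$R_liposome - cfg$spot_margin)
      th <- stats::runif(1, 0, 2 * pi)
      center_m + r * c(cos(th), sin(th))
    }, min_sep = 1.3 * cfg$spot_diam)
    spot_onset <- stats::runif(cfg$n_spots, 0, 0.6 * max(times, 1))
    bl_xy <- .place(cfg$n_blisters, function() {
      r <- stats::runif(1, 0.15, 0.72) * cfg$R_liposome
      th <- stats::runif(1, 0, 2 * pi)
      center_m + r * c(cos(th), sin(th))
    }, min_sep = 2 * cfg$blister_radii[2] + 1e-6)
    bl_r <- stats::runif(cfg$n_blisters, cfg$blister_radii[1],
                         cfg$blister_radii[2])
    bl_wave_th0 <- stats::runif(cfg$n_blisters, 0, 2 * pi)

    spots <- data.frame(x_m = sp_xy[, 1], y_m = sp_xy[, 2],
                        r_m = sqrt((sp_xy[, 1] - center_m[1])^2 +
                                     (sp_xy[, 2] - center_m[2])^2),
                        onset_s = spot_onset)
    blisters <- data.frame(x_m = bl_xy[, 1], y_m = bl_xy[, 2],
                           radius_m = bl_r, wave_theta0 = bl_wave_th0)

    sigma_spot <- cfg$spot_diam / 2.355 / ps   # FWHM -> sd, px
    # compensate the PSF attenuation so the rendered peak / noise sd is
    # exactly the configured SNR
    psf_att <- sigma_spot^2 / (sigma_spot^2 + (cfg$psf_sigma / ps)^2)
    amp_spot <- cfg$spot_snr * max(cfg$noise_sd, 0.02) / psf_att
    wave_speed <- pi / max(times[length(times)], 1)   # rad/s, half turn
    tau_rise <- max(cfg$frame_interval, 1)

    ft <- cfg$pore_trajectory
    if (!is.null(ft) && length(ft$fields) == 0)
      stop("pore_trajectory must be simulated with store_fields = TRUE")

    actin <- vector("list", cfg$n_frames)
    bright <- vector("list", cfg$n_frames)
    for (k in seq_len(cfg$n_frames)) {
      t <- times[k]
      interior <- cfg$depletion_floor +
        (1 - cfg$depletion_floor) * exp(-t / cfg$tau_a)
      img <- matrix(0, npx, npx)
      img[disk] <- interior
      if (!is.null(ft)) {
        fi <- which.min(abs(ft$times - t))
        fld <- ft$fields[[fi]]
        rm_ <- rr * ps
        img[disk] <- stats::approx(fld$r, fld$rho, xout = rm_[disk],
                                   yleft = 0, yright = fld$rho[length(fld$rho)]
                                   )$y * interior
        img[rm_ < fld$R] <- 0
      }
      # spots with logistic onset
      for (s in seq_len(cfg$n_spots)) {
        on <- 1 / (1 + exp(-(t - spot_onset[s]) / tau_rise))
        if (on < 1e-3) next
        sx <- spots$x_m[s] / ps; sy <- spots$y_m[s] / ps
        lo_x <- max(1L, floor(sx - 4 * sigma_spot))
        hi_x <- min(npx, ceiling(sx + 4 * sigma_spot))
        lo_y <- max(1L, floor(sy - 4 * sigma_spot))
        hi_y <- min(npx, ceiling(sy + 4 * sigma_spot))
        gx <- (lo_x:hi_x - sx)^2
        gy <- (lo_y:hi_y - sy)^2
        img[lo_y:hi_y, lo_x:hi_x] <- img[lo_y:hi_y, lo_x:hi_x] +
          amp_spot * on * exp(-outer(gy, gx, "+") / (2 * sigma_spot^2))
      }
      bf <- matrix(0.5, npx, npx)
      bf[disk] <- 1
      # blisters: dark brightfield disks + actin wave at their rims
      for (b in seq_len(cfg$n_blisters)) {
        bxd <- xs - blisters$x_m[b] / ps
        byd <- ys - blisters$y_m[b] / ps
        bd <- sqrt(bxd^2 + byd^2)
        r_b <- blisters$radius_m[b] / ps
        edge <- 1 / (1 + exp((bd - r_b) / 0.8))   # smoothed disk
        bf <- bf - 0.6 * edge
        dth <- (atan2(byd, bxd) - bl_wave_th0[b]) %% (2 * pi)
        dth <- pmin(dth, 2 * pi - dth)
        wave <- 1 / (1 + exp((dth - wave_speed * t) / 0.15))
        rim <- exp(-(bd - r_b)^2 / (2 * (1e-6 / ps / 2.355)^2))
        img <- img + 0.5 * interior * rim * wave
      }
      img[!disk] <- 0.02
      if (cfg$psf_sigma > 0) {
        sig_psf <- cfg$psf_sigma / ps
        img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                                   sigma = sig_psf)))
        bf <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(bf)),
                                                  sigma = sig_psf)))
      }
      actin[[k]] <- image_frame(.apply_noise(img, cfg), ps,
                                channel = "actin", time = t)
      bright[[k]] <- image_frame(.apply_noise(pmax(bf, 0), cfg), ps,
                                 channel = "brightfield", time = t)
    }
    list(actin = actin, brightfield = bright,
         truth = list(spots = spots, blisters = blisters,
                      tau_a = cfg$tau_a,
                      depletion_floor = cfg$depletion_floor,
                      wave_speed = wave_speed, center = center_m,
                      R_liposome = cfg$R_liposome,
                      pore_trajectory = cfg$pore_trajectory,
                      times = times))
  })
}

#' Kymograph of advected actin texture from a field trajectory, with truth
#'
#' Material markers seeded uniformly over the initial annulus are advected
#' with the trajectory's velocity fields; each time line renders the local
#' density modulated by Gaussian splats at the marker positions, zero inside
#' the pore, plus Gaussian noise.
#'
#' @param field_traj a `field_trajectory` from [simulate_fields()] with
#'   `store_fields = TRUE`.
#' @param noise_sd Gaussian noise sd (intensity units).
#' @param seed integer seed.
#' @param pixel_size m per pixel along x.
#' @param n_markers number of texture markers.
#' @param texture_amp splat amplitude relative to the density signal.
#' @return list with `kymo` (a [kymograph()]), and `truth` (marker tracks
#'   matrix [time x marker] in m, edge radius `R` per time line, times).
#' @export
gen_kymograph <- function(field_traj, noise_sd = 0.02, seed = 1,
                          pixel_size = 1e-7, n_markers = 30,
                          texture_amp = 1) {
  stopifnot(inherits(field_traj, "field_trajectory"))
  if (length(field_traj$fields) == 0)
    stop("field trajectory must be simulated with store_fields = TRUE")
  times <- field_traj$times
  nt <- length(times)
  R_L <- field_traj$fields[[1]]$R_L
  R0 <- field_traj$fields[[1]]$R
  .with_seed(seed, {
    X <- matrix(NA_real_, nt, n_markers)
    X[1, ] <- sort(stats::runif(n_markers, R0, R_L))
    for (k in seq_len(nt - 1)) {
      fld <- field_traj$fields[[k]]
      dt_full <- times[k + 1] - times[k]
      nsub <- max(1L, ceiling(dt_full / 1))
      x <- X[k, ]
      for (s in seq_len(nsub)) {
        vv <- stats::approx(fld$r, fld$v, xout = pmin(pmax(x, fld$R), R_L),
                            rule = 2)$y
        x <- pmin(x + vv * dt_full / nsub, R_L)
      }
      X[k + 1, ] <- x
    }
    xg <- seq(0, R_L, by = pixel_size)
    sig <- 1.5 * pixel_size
    img <- matrix(0, nt, length(xg))
    for (k in seq_len(nt)) {
      fld <- field_traj$fields[[k]]
      rho_x <- stats::approx(fld$r, fld$rho, xout = xg, yleft = 0,
                             yright = fld$rho[length(fld$rho)])$y
      rho_x[xg < fld$R] <- 0
      tex <- rep(0, length(xg))
      for (m in seq_len(n_markers)) {
        tex <- tex + exp(-(xg - X[k, m])^2 / (2 * sig^2))
      }
      img[k, ] <- rho_x * (1 + texture_amp * tex)
    }
    if (noise_sd > 0)
      img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                               nt), 0)
    # Eulerian displacement truth: time integral of v at each fixed x
    U_eul <- matrix(0, nt, length(xg))
    for (k in seq_len(nt - 1)) {
      fld <- field_traj$fields[[k]]
      vv <- stats::approx(fld$r, fld$v, xout = xg, rule = 2)$y
      vv[xg < fld$R] <- 0
      U_eul[k + 1, ] <- U_eul[k, ] + vv * (times[k + 1] - times[k])
    }
    list(kymo = kymograph(img, pixel_size, mean(diff(times))),
         truth = list(markers = X, R = field_traj$R, times = times,
                      x_grid = xg, U_eulerian = U_eul))
  })
}

#' Synthetic traction map with known rim tension
#'
#' Radially inward-pointing stress confined to a rim band inside the contact
#' boundary, with magnitude chosen so that the literal rim-tension readout
#' ([rim_tension()], mean peripheral stress times marching-squares
#' perimeter) returns `target_tension` exactly in the noise-free limit.
#' The default band (3.5 um) is wider than the usual 1--3 um analysis rim so
#' the mean peripheral stress is well defined for any analysis band inside
#' it.
#'
#' @param target_tension rim tension to encode, N/m.
#' @param R_contact contact radius, m.
#' @param rim_width stress band width, m; must be < `R_contact`.
#' @param noise_sd_pa Gaussian noise sd added to each stress component, Pa.
#' @param seed integer seed.
#' @param pixel_size m per pixel.
#' @return list with `tmap` (a [traction_map()]) and `truth` (list with
#'   `target_tension`, `stress_magnitude` Pa, `perimeter` m).
#' @export
gen_traction_map <- function(target_tension, R_contact, rim_width = 3.5e-6,
                             noise_sd_pa = 0, seed = 1, pixel_size = 2e-7) {
  if (rim_width >= R_contact)
    stop("infeasible geometry: rim_width must be < R_contact")
  if (target_tension < 0) stop("target_tension must be >= 0")
  ps <- pixel_size
  R_px <- R_contact / ps
  npx <- 2L * ceiling(R_px * 1.3) + 1L
  cx <- (npx + 1) / 2
  xs <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
  ys <- matrix(seq_len(npx), npx, npx)
  rr <- sqrt((xs - cx)^2 + (ys - cx)^2)
  mask <- rr <= R_px
  perim <- .mask_perimeter(t(mask) * 1, ps)
  mag <- target_tension / perim
  band <- mask & (R_px - rr) * ps <= rim_width
  ux <- ifelse(rr > 0, -(xs - cx) / pmax(rr, 1e-9), 0)
  uy <- ifelse(rr > 0, -(ys - cx) / pmax(rr, 1e-9), 0)
  sx <- mag * ux * band
  sy <- mag * uy * band
  .with_seed(seed, {
    if (noise_sd_pa > 0) {
      sx <- sx + matrix(stats::rnorm(length(sx), 0, noise_sd_pa), npx)
      sy <- sy + matrix(stats::rnorm(length(sy), 0, noise_sd_pa), npx)
    }
    list(tmap = traction_map(sx, sy, ps, mask),
         truth = list(target_tension = target_tension,
                      stress_magnitude = mag, perimeter = perim,
                      center = c(cx, cx) * ps, R_contact = R_contact,
                      rim_width = rim_width))
  })
}
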