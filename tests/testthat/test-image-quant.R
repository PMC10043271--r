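make_disk_frame <- function(npx = 161, R_px = 60, value = 1, ps = 1e-7,
                            channel = "actin") {
  xs <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
  ys <- matrix(seq_len(npx), npx, npx)
  img <- matrix(0, npx, npx)
  img[(xs - (npx + 1) / 2)^2 + (ys - (npx + 1) / 2)^2 <= R_px^2] <- value
  image_frame(img, ps, channel = channel)
}

test_that("radial profile is flat inside a disk and peaks on a ring", {
  fr <- make_disk_frame()
  ctr <- c(81, 81) * 1e-7
  prof <- radial_profile(fr, ctr)
  inside <- prof$intensity[prof$r_m < 50 * 1e-7]
  expect_true(all(abs(inside - 1) < 1e-9))
  expect_lt(prof$intensity[prof$r_m > 70 * 1e-7][1], 0.1)
  # ring fixture: peak within 1 px of the planted radius
  npx <- 161
  xs <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
  ys <- matrix(seq_len(npx), npx, npx)
  rr <- sqrt((xs - 81)^2 + (ys - 81)^2)
  ring <- image_frame(exp(-(rr - 40)^2 / 8), 1e-7, channel = "actin")
  prof_r <- radial_profile(ring, ctr)
  expect_lt(abs(prof_r$r_m[which.max(prof_r$intensity)] - 40e-7), 1e-7)
  # rotating the image 90 degrees leaves the profile unchanged within 0.5%
  rot <- image_frame(t(ring$intensity)[npx:1, ], 1e-7, channel = "actin")
  prof_rot <- radial_profile(rot, ctr)
  expect_lt(max(abs(prof_rot$intensity - prof_r$intensity)) /
              max(prof_r$intensity), 0.005)
  expect_error(radial_profile(fr, c(1, 1) * 1e-3), "outside")
})

test_that("angular profile resolves azimuthal structure", {
  npx <- 161
  xs <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
  ys <- matrix(seq_len(npx), npx, npx)
  rr <- sqrt((xs - 81)^2 + (ys - 81)^2)
  # azimuthally uniform ring: flat profile
  ring <- image_frame(exp(-(rr - 40)^2 / 32), 1e-7, channel = "actin")
  ap <- angular_profile(ring, c(81, 81) * 1e-7, 40e-7)
  expect_lt(diff(range(ap$intensity)) / mean(ap$intensity), 0.01)
  # point source at theta = 0: peak at 0 with symmetric decay
  th <- atan2(ys - 81, xs - 81)
  blob <- exp(-(rr - 40)^2 / 8) * exp(-th^2 / 0.1)
  ap2 <- angular_profile(image_frame(blob, 1e-7, channel = "actin"),
                         c(81, 81) * 1e-7, 40e-7)
  expect_equal(ap2$theta_deg[which.max(ap2$intensity)], 0)
  expect_equal(ap2$intensity[ap2$theta_deg == 10],
               ap2$intensity[ap2$theta_deg == 350], tolerance = 0.05)
  expect_error(angular_profile(ring, c(81, 81) * 1e-7, 120e-7), "exits")
})

test_that("blister detection: planted disks, blank frames, offset invariance", {
  cfg <- scene_config(seed = 9, n_frames = 3, n_spots = 0, n_blisters = 7,
                      noise_sd = 0.02, R_liposome = 1.6e-5)
  mv <- gen_liposome_movie(cfg)
  bl <- detect_blisters(mv$brightfield[[2]])
  truth <- mv$truth$blisters
  expect_equal(nrow(bl), 7)
  sc <- match_detections(bl, truth, tol = 1e-6)
  expect_gte(sc$recall, 6 / 7)
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((bl$x_m - truth$x_m[i])^2 + (bl$y_m - truth$y_m[i])^2)
    j <- which.min(d)
    expect_lt(abs(bl$radius_m[j] - truth$radius_m[i]) / truth$radius_m[i],
              0.15)
  }
  # blank frame: empty set
  blank <- image_frame(matrix(0.8, 64, 64), 1e-7, channel = "brightfield")
  expect_equal(nrow(detect_blisters(blank)), 0)
  # a global intensity offset does not change the count (bandpass removes it)
  off <- mv$brightfield[[2]]
  off$intensity <- off$intensity + 0.3
  expect_equal(nrow(detect_blisters(off)), nrow(bl))
  expect_error(detect_blisters(make_disk_frame(channel = "actin")),
               "brightfield")
})

test_that("spot detection: recall and precision at SNR 5, gain invariance", {
  cfg <- scene_config(seed = 7, n_frames = 10, n_spots = 10, spot_snr = 5,
                      n_blisters = 0)
  mv <- gen_liposome_movie(cfg)
  fr <- mv$actin[[10]]
  mask <- movie_disk_mask(fr, cfg$R_liposome, erode = 0.3e-6)
  sp <- detect_spots(fr, mask = mask)
  sc <- match_detections(sp, mv$truth$spots, tol = 0.75e-6)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.9)
  # doubling the global gain leaves detections unchanged (MAD-relative)
  fr2 <- fr
  fr2$intensity <- 2 * fr$intensity
  sp2 <- detect_spots(fr2, mask = mask)
  expect_equal(nrow(sp2), nrow(sp))
  expect_equal(sort(sp2$x_m), sort(sp$x_m), tolerance = 1e-9)
  # blank frame: empty
  blank <- image_frame(matrix(1, 64, 64), 1e-7, channel = "actin")
  expect_equal(nrow(detect_spots(blank)), 0)
})

test_that("spot-ring width recovers the planted annulus", {
  cfg <- scene_config(seed = 13, n_frames = 8, n_spots = 14, spot_snr = 8,
                      ring_width = 2e-6, spot_margin = 1e-6, n_blisters = 0)
  mv <- gen_liposome_movie(cfg)
  fr <- mv$actin[[8]]
  mask <- movie_disk_mask(fr, cfg$R_liposome, erode = 0.3e-6)
  sp <- detect_spots(fr, mask = mask)
  srw <- spot_ring_width(sp, mv$truth$center, cfg$R_liposome)
  # spots span [margin, margin + ring]; w is the 95th percentile of the
  # inward distance, so close to margin + ring
  expect_lt(abs(srw$w - 3e-6) / 3e-6, 0.25)
  expect_equal(srw$w_over_R, srw$w / cfg$R_liposome)
  # all spots at the contact line give w near zero
  synth <- data.frame(x_m = mv$truth$center[1] +
                        cfg$R_liposome * cos(1:6),
                      y_m = mv$truth$center[2] + cfg$R_liposome * sin(1:6))
  srw0 <- spot_ring_width(synth, mv$truth$center, cfg$R_liposome)
  expect_lt(srw0$w, 1e-8)
  expect_error(spot_ring_width(synth[1:2, ], mv$truth$center,
                               cfg$R_liposome), "3 spots")
})

test_that("pore radius extraction tracks the simulated opening", {
  p <- liposome_params("actin")
  ft <- simulate_fields(p, R_init = 1.5e-6, t_end = 150, n = 150,
                        n_out = 10, R_stop_frac = 0.8, store_fields = TRUE)
  cfg <- scene_config(seed = 5, n_frames = length(ft$fields),
                      frame_interval = mean(diff(ft$times)),
                      n_spots = 0, n_blisters = 0, noise_sd = 0.03,
                      pore_trajectory = ft)
  mv <- gen_liposome_movie(cfg)
  rs <- pore_radius_series(mv$actin, center = mv$truth$center,
                           R_liposome = cfg$R_liposome)
  truth_R <- stats::approx(ft$times, ft$R, xout = rs$t, rule = 2)$y
  expect_lt(max(abs(rs$y - truth_R) / truth_R), 0.05)
  # monotone ground truth gives a monotone estimate
  expect_true(all(diff(rs$y) > 0))
  # frame without a pore raises
  flat <- image_frame(matrix(1, 161, 161) +
                        matrix(stats::rnorm(161^2, 0, 0.02), 161), 1e-7,
                      channel = "actin")
  expect_error(pore_radius_series(list(flat), center = c(80, 80) * 1e-7,
                                  R_liposome = 6e-6), "no dark pore")
})

test_that("rim tension: construction value, zero map, rim-width robustness", {
  g <- gen_traction_map(1.4e-4, R_contact = 1.1e-5, noise_sd_pa = 0,
                        seed = 1)
  expect_equal(rim_tension(g$tmap), 1.4e-4, tolerance = 0.01)
  # the implied uniform rim stress is at the pascal scale
  expect_equal(g$truth$stress_magnitude, 2, tolerance = 0.05)
  # robustness across analysis rim widths 1-3 um
  for (w in c(1e-6, 2e-6, 3e-6)) {
    expect_equal(rim_tension(g$tmap, w_rim = w), 1.4e-4, tolerance = 0.05)
  }
  # zero stress gives zero tension
  z <- traction_map(matrix(0, 64, 64), matrix(0, 64, 64), 2e-7,
                    {
                      m <- matrix(FALSE, 64, 64)
                      m[20:44, 20:44] <- TRUE
                      m
                    })
  expect_equal(rim_tension(z, w_rim = 2e-6), 0)
  # the alternative reading (integrated force over perimeter) is close on a
  # uniform rim but is a distinct estimator
  alt <- rim_tension(g$tmap, w_rim = 3e-6, method = "force_per_perimeter")
  expect_gt(alt, 0)
  expect_error(rim_tension(traction_map(matrix(0, 8, 8), matrix(0, 8, 8),
                                        1e-7, matrix(FALSE, 8, 8))),
               "empty")
})

test_that("geometric outputs scale linearly with the pixel calibration", {
  for (ps in c(1e-7, 2e-7)) {
    cfg <- scene_config(seed = 3, pixel_size = ps, n_frames = 4,
                        n_spots = 6, spot_snr = 8, n_blisters = 0)
    mv <- gen_liposome_movie(cfg)
    fr <- mv$actin[[4]]
    mask <- movie_disk_mask(fr, cfg$R_liposome, erode = 0.3e-6)
    sp <- detect_spots(fr, mask = mask)
    sc <- match_detections(sp, mv$truth$spots, tol = 0.75e-6)
    expect_gte(sc$recall, 0.8)
  }
})

test_that("image stacks round-trip through TIFF with sidecar calibration", {
  cfg <- scene_config(seed = 21, n_frames = 3, n_spots = 3, n_blisters = 0)
  mv <- gen_liposome_movie(cfg)
  f <- tempfile(fileext = ".tif")
  write_image_stack(mv$actin, f)
  back <- read_image_stack(f)
  expect_equal(length(back), 3)
  expect_equal(back[[1]]$pixel_size, cfg$pixel_size)
  expect_equal(back[[2]]$time, mv$actin[[2]]$time)
  expect_lt(max(abs(back[[3]]$intensity - mv$actin[[3]]$intensity)),
            diff(range(mv$actin[[3]]$intensity)) / 1000)
  # missing sidecar is a hard error, no silent default calibration
  f2 <- tempfile(fileext = ".tif")
  file.copy(f, f2)
  expect_error(read_image_stack(f2), "sidecar")
})
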