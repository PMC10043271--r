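#' Calibrated image frame
#'
#' Intensity grid with physical pixel calibration. Coordinate convention:
#' pixel centres sit at integer pixel coordinates `(x = column, y = row)`,
#' origin at the top-left pixel; physical coordinates are pixel coordinates
#' times `pixel_size`, and all detections are reported in metres.
#'
#' @param intensity non-negative matrix (rows = y, columns = x).
#' @param pixel_size m per pixel; > 0.
#' @param channel one of `"actin"`, `"myosin"`, `"membrane"`, `"brightfield"`.
#' @param time acquisition time, s.
#' @return object of class `image_frame`.
#' @export
image_frame <- function(intensity, pixel_size,
                        channel = c("actin", "myosin", "membrane",
                                    "brightfield"),
                        time = 0) {
  channel <- match.arg(channel)
  intensity <- as.matrix(intensity)
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 channel = channel, time = time),
            class = "image_frame")
}

# bilinear sampling at pixel coordinates (x = column, y = row), clamped
.bilinear <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

#' Rotationally averaged radial intensity profile
#'
#' Samples the intensity along `n_rays` equally spaced rays from the centre
#' by bilinear interpolation and averages per 1-px radial bin.
#'
#' @param frame an [image_frame()].
#' @param center `c(x, y)` centre in metres; must lie inside the frame.
#' @param n_rays number of rays (default 360).
#' @param r_max largest radius sampled, m (default: distance to the nearest
#'   frame border).
#' @return data.frame with `r_m` (bin radius, m) and `intensity`.
#' @export
radial_profile <- function(frame, center, n_rays = 360, r_max = NULL) {
  stopifnot(inherits(frame, "image_frame"))
  ps <- frame$pixel_size
  cx <- center[1] / ps; cy <- center[2] / ps
  ny <- nrow(frame$intensity); nx <- ncol(frame$intensity)
  if (cx < 1 || cx > nx || cy < 1 || cy > ny)
    stop("center lies outside the frame")
  r_max_px <- min(cx - 1, nx - cx, cy - 1, ny - cy)
  if (!is.null(r_max)) r_max_px <- min(r_max_px, r_max / ps)
  radii <- seq(0, floor(r_max_px), by = 1)
  theta <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  prof <- vapply(radii, function(rr) {
    mean(.bilinear(frame$intensity, cx + rr * cos(theta),
                   cy + rr * sin(theta)))
  }, numeric(1))
  data.frame(r_m = radii * ps, intensity = prof)
}

#' Angular intensity profile along a circle
#'
#' Samples the intensity at `step_deg` steps along a circle by bilinear
#' interpolation, e.g. around a blister rim to follow wave-like actin
#' recruitment.
#'
#' @param frame an [image_frame()].
#' @param center `c(x, y)` circle centre, m.
#' @param radius circle radius, m; the circle must stay inside the frame.
#' @param step_deg angular step, degrees (default 1).
#' @return data.frame with `theta_deg` and `intensity`.
#' @export
angular_profile <- function(frame, center, radius, step_deg = 1) {
  stopifnot(inherits(frame, "image_frame"))
  ps <- frame$pixel_size
  cx <- center[1] / ps; cy <- center[2] / ps
  r_px <- radius / ps
  ny <- nrow(frame$intensity); nx <- ncol(frame$intensity)
  if (cx - r_px < 1 || cx + r_px > nx || cy - r_px < 1 || cy + r_px > ny)
    stop("circle exits the frame")
  theta <- seq(0, 360 - step_deg, by = step_deg)
  rad <- theta * pi / 180
  data.frame(theta_deg = theta,
             intensity = .bilinear(frame$intensity, cx + r_px * cos(rad),
                                   cy + r_px * sin(rad)))
}

#' Angular fraction of a profile above half-maximum
#'
#' Spread metric for wave-like recruitment: the fraction of angular samples
#' whose intensity exceeds the midpoint between the profile's minimum and
#' maximum.
#'
#' @param intensity angular intensity samples.
#' @return fraction in `[0, 1]`.
#' @export
angular_fraction_above_halfmax <- function(intensity) {
  if (length(intensity) == 0) stop("empty profile")
  half <- min(intensity) + 0.5 * diff(range(intensity))
  mean(intensity >= half)
}

#' Detect blisters (dark disks) in a brightfield frame
#'
#' Difference-of-Gaussians bandpass at the blister scales, Otsu threshold on
#' the dark-going response, connected components filtered by circularity and
#' equivalent diameter.
#'
#' @param frame an [image_frame()] with `channel = "brightfield"`.
#' @param diam_range accepted equivalent-diameter range, m.
#' @param circularity minimum circularity (`4 pi area / perimeter^2`).
#' @param scales difference-of-Gaussians smoothing scales, m.
#' @return data.frame (class `blister_set`) with `x_m`, `y_m`, `radius_m`,
#'   `area_m2`; zero rows when nothing is detected.
#' @export
detect_blisters <- function(frame, diam_range = c(0.5e-6, 10e-6),
                            circularity = 0.7,
                            scales = c(1e-6, 5e-6)) {
  stopifnot(inherits(frame, "image_frame"))
  if (frame$channel != "brightfield")
    stop("detect_blisters expects a brightfield frame")
  img <- frame$intensity
  if (length(img) == 0) stop("empty frame")
  ps <- frame$pixel_size
  empty0 <- data.frame(x_m = numeric(0), y_m = numeric(0),
                       radius_m = numeric(0), area_m2 = numeric(0))
  class(empty0) <- c("blister_set", class(empty0))
  if (stats::sd(img) == 0) return(empty0)
  # clamp the smoothing scales so the Gaussian kernel fits the frame
  max_sig <- (min(dim(img)) - 1) / 8
  s1 <- min(scales[1] / ps / 2, max_sig / 2)
  s2 <- min(scales[2] / ps / 2, max_sig)
  im <- EBImage::Image(t(img))          # EBImage is column-major x,y
  bp <- EBImage::gblur(im, sigma = s1) - EBImage::gblur(im, sigma = s2)
  neg <- pmax(-EBImage::imageData(bp), 0)
  empty <- data.frame(x_m = numeric(0), y_m = numeric(0),
                      radius_m = numeric(0), area_m2 = numeric(0))
  class(empty) <- c("blister_set", class(empty))
  if (max(neg) <= 0) return(empty)
  th <- EBImage::otsu(EBImage::Image(neg / max(neg)))
  mask <- EBImage::bwlabel(EBImage::Image((neg / max(neg)) > th))
  if (max(mask) == 0) return(empty)
  sh <- EBImage::computeFeatures.shape(mask)
  mom <- EBImage::computeFeatures.moment(mask)
  area_px <- sh[, "s.area"]
  perim <- pmax(sh[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area_px / perim^2, 1)
  r_eq <- sqrt(area_px / pi) * ps
  keep <- which(circ >= circularity &
                  (2 * r_eq) >= diam_range[1] & (2 * r_eq) <= diam_range[2])
  # refine each radius on the raw image: local threshold halfway between
  # the blister core and the surrounding background (the bandpass response
  # distorts sizes)
  ny <- nrow(img); nx <- ncol(img)
  refine <- function(cx, cy, r0) {
    m <- ceiling(3 * r0)
    x1 <- max(1, floor(cx - m)); x2 <- min(nx, ceiling(cx + m))
    y1 <- max(1, floor(cy - m)); y2 <- min(ny, ceiling(cy + m))
    loc <- img[y1:y2, x1:x2]
    dx <- matrix(seq(x1, x2), nrow(loc), ncol(loc), byrow = TRUE) - cx
    dy <- matrix(seq(y1, y2), nrow(loc), ncol(loc)) - cy
    dd <- sqrt(dx^2 + dy^2)
    core <- dd <= pmax(0.5 * r0, 1)
    ring <- dd >= 1.6 * r0 & dd <= 2.8 * r0
    if (!any(core) || !any(ring)) return(r0)
    th <- (mean(loc[core]) + stats::median(loc[ring])) / 2
    dark <- loc < th & dd <= 1.6 * r0
    if (!any(dark)) return(r0)
    sqrt(sum(dark) / pi)
  }
  r_ref <- vapply(keep, function(i) {
    refine(mom[i, "m.cx"], mom[i, "m.cy"], r_eq[i] / ps) * ps
  }, numeric(1))
  out <- data.frame(x_m = mom[keep, "m.cx"] * ps,
                    y_m = mom[keep, "m.cy"] * ps,
                    radius_m = r_ref,
                    area_m2 = pi * r_ref^2)
  class(out) <- c("blister_set", class(out))
  rownames(out) <- NULL
  out
}

#' Detect peripheral actin spots
#'
#' Local maxima of a Laplacian-of-Gaussian-type (difference-of-Gaussians)
#' response at the spot scale, kept when the response exceeds `k_mad` robust
#' deviations (MAD) of the response and separated by at least `min_sep`.
#' The MAD-relative threshold makes detection invariant to global gain and
#' the bandpass removes additive offsets.
#'
#' @param frame an [image_frame()] with `channel = "actin"`.
#' @param spot_diam nominal spot diameter, m (default 1 um).
#' @param k_mad prominence threshold in MADs of the response.
#' @param min_sep minimum centre separation, m.
#' @param mask optional logical matrix (same shape as the frame) restricting
#'   candidate maxima, e.g. the liposome footprint eroded away from the
#'   contact-line edge response; the response MAD is then computed within
#'   the mask.
#' @return data.frame (class `spot_set`) with `x_m`, `y_m`, `intensity`,
#'   `response`.
#' @export
detect_spots <- function(frame, spot_diam = 1e-6, k_mad = 5,
                         min_sep = 0.5e-6, mask = NULL) {
  stopifnot(inherits(frame, "image_frame"))
  if (frame$channel != "actin")
    stop("detect_spots expects an actin frame")
  ps <- frame$pixel_size
  img <- frame$intensity
  empty <- data.frame(x_m = numeric(0), y_m = numeric(0),
                      intensity = numeric(0), response = numeric(0))
  class(empty) <- c("spot_set", class(empty))
  sigma <- max(spot_diam / ps / 2.8, 0.6)
  if (!is.null(mask)) {
    mask <- as.matrix(mask) > 0
    if (!all(dim(mask) == dim(img))) stop("mask must match the frame shape")
    if (!any(mask)) return(empty)
    # suppress structures outside the detection region (e.g. the contact
    # line edge) before band-passing: inpaint with the in-mask median
    img_w <- img
    img_w[!mask] <- stats::median(img[mask])
    mask_t <- t(mask)
  } else {
    img_w <- img
    mask_t <- NULL
  }
  im <- EBImage::Image(t(img_w))
  resp <- EBImage::imageData(EBImage::gblur(im, sigma = sigma) -
                               EBImage::gblur(im, sigma = 1.6 * sigma))
  mad_r <- if (is.null(mask_t)) stats::mad(resp) else stats::mad(resp[mask_t])
  if (!is.finite(mad_r) || mad_r == 0) return(empty)
  sep_px <- max(1L, as.integer(round(min_sep / ps)))
  brush <- EBImage::makeBrush(2L * sep_px + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(resp), brush))
  is_max <- resp >= dil & resp > k_mad * mad_r
  if (!is.null(mask_t)) is_max <- is_max & mask_t
  idx <- which(is_max, arr.ind = TRUE)   # resp is x-major: rows = x
  if (nrow(idx) == 0) return(empty)
  # drop border maxima (half the spot must fit)
  b <- ceiling(sigma)
  ok <- idx[, 1] > b & idx[, 1] <= nrow(resp) - b &
    idx[, 2] > b & idx[, 2] <= ncol(resp) - b
  idx <- idx[ok, , drop = FALSE]
  if (nrow(idx) == 0) return(empty)
  out <- data.frame(x_m = idx[, 1] * ps, y_m = idx[, 2] * ps,
                    intensity = img[cbind(idx[, 2], idx[, 1])],
                    response = resp[idx])
  out <- out[order(-out$response), ]
  rownames(out) <- NULL
  class(out) <- c("spot_set", class(out))
  out
}

#' Spot-ring width at the liposome periphery
#'
#' Peripheral spots are those lying in the outer half of the contact disk
#' (radial position at least `0.5 * R_liposome`). The ring width `w` is the
#' 95th percentile of their inward distance from the contact line.
#'
#' @param spots a `spot_set` (from [detect_spots()]) with at least 3 spots.
#' @param center contact-disk centre `c(x, y)`, m.
#' @param R_liposome contact radius, m.
#' @return list with `w` (m), `w_over_R`, `n_peripheral`.
#' @export
spot_ring_width <- function(spots, center, R_liposome) {
  if (nrow(spots) < 3) stop("need at least 3 spots")
  d <- sqrt((spots$x_m - center[1])^2 + (spots$y_m - center[2])^2)
  peripheral <- d >= 0.5 * R_liposome
  if (!any(peripheral)) stop("no peripheral spots")
  w <- unname(stats::quantile(R_liposome - d[peripheral], 0.95))
  list(w = w, w_over_R = w / R_liposome, n_peripheral = sum(peripheral))
}

#' Pore radius extraction from a fluorescence movie
#'
#' Per frame, intensities inside the liposome disk are split into a dark
#' (pore) and a bright (layer) population (2-means); the frame is
#' thresholded at the midpoint between the population centres, the largest
#' dark connected component inside the disk is taken as the pore and its
#' equivalent-circle radius reported. Frames whose populations are not
#' separated (no pore) raise an error unless `skip_missing = TRUE`.
#'
#' @param frames list of [image_frame()] (fluorescence).
#' @param center liposome centre `c(x, y)`, m.
#' @param R_liposome contact radius, m.
#' @param min_contrast minimum separation of the two intensity populations,
#'   as a fraction of the bright centre, for a pore to be declared.
#' @param skip_missing drop frames without a pore instead of erroring.
#' @return a [time_series()] of pore radius (m) against frame times.
#' @export
pore_radius_series <- function(frames, center, R_liposome,
                               min_contrast = 0.5, skip_missing = FALSE) {
  if (length(frames) == 0) stop("no frames")
  times <- vapply(frames, function(f) f$time, numeric(1))
  radii <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    ps <- f$pixel_size
    ny <- nrow(f$intensity); nx <- ncol(f$intensity)
    xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE) * ps
    ys <- matrix(seq_len(ny), ny, nx) * ps
    disk <- (xs - center[1])^2 + (ys - center[2])^2 <= R_liposome^2
    vals <- f$intensity[disk]
    rng <- range(vals)
    if (diff(rng) <= 0) {
      if (skip_missing) next
      stop("no dark pore component found in frame ", k)
    }
    # robust population centres: the pore interior is the extreme dark
    # tail (a small pore is a tiny pixel fraction and must not be swamped
    # by layer brightness variation, so plain 2-means is not used)
    lo <- stats::quantile(vals, 0.002, names = FALSE)
    hi <- stats::median(vals[vals > stats::quantile(vals, 0.25)])
    if ((hi - lo) < min_contrast * max(hi, 1e-12)) {
      if (skip_missing) next
      stop("no dark pore component found in frame ", k)
    }
    th <- (lo + hi) / 2
    dark <- f$intensity < th & disk
    lab <- EBImage::bwlabel(EBImage::Image(t(dark)))
    if (max(lab) == 0) {
      if (skip_missing) next
      stop("no dark pore component found in frame ", k)
    }
    areas <- tabulate(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
    radii[k] <- sqrt(max(areas) * ps^2 / pi)
  }
  keep <- !is.na(radii)
  if (!any(keep)) stop("no frames with a detectable pore")
  time_series(times[keep], radii[keep], label = "pore radius", units = "m")
}

#' Traction map container
#'
#' @param stress_x,stress_y 2D matrices of substrate stress components, Pa.
#' @param pixel_size m per pixel.
#' @param contact_mask logical matrix marking the contact footprint;
#'   must be non-empty for rim operations.
#' @return object of class `traction_map`.
#' @export
traction_map <- function(stress_x, stress_y, pixel_size, contact_mask) {
  stress_x <- as.matrix(stress_x); stress_y <- as.matrix(stress_y)
  contact_mask <- as.matrix(contact_mask)
  if (!all(dim(stress_x) == dim(stress_y)) ||
      !all(dim(stress_x) == dim(contact_mask)))
    stop("stress components and mask must share dimensions")
  if (any(!is.finite(stress_x)) || any(!is.finite(stress_y)))
    stop("stresses must be finite")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(stress_x = stress_x, stress_y = stress_y,
                 pixel_size = pixel_size,
                 contact_mask = contact_mask > 0),
            class = "traction_map")
}

# marching-squares perimeter of the largest contour of a binary mask, m
.mask_perimeter <- function(mask, pixel_size) {
  cl <- grDevices::contourLines(x = seq_len(nrow(mask)),
                                y = seq_len(ncol(mask)),
                                z = mask * 1, levels = 0.5)
  if (length(cl) == 0) stop("mask has no boundary")
  len <- vapply(cl, function(cc) {
    sum(sqrt(diff(c(cc$x, cc$x[1]))^2 + diff(c(cc$y, cc$y[1]))^2))
  }, numeric(1))
  max(len) * pixel_size
}

#' Rim tension from a traction map
#'
#' Membrane tension at the contact line, read out from the stress
#' accumulation at the rim: the mean peripheral stress magnitude (over the
#' band of pixels within `w_rim` inside the mask boundary) multiplied by the
#' contact perimeter (marching-squares contour length). This is the literal
#' printed readout; a physically alternative reading -- the integrated rim
#' force magnitude divided by the perimeter -- is available with
#' `method = "force_per_perimeter"`.
#'
#' @param tmap a [traction_map()] with a non-empty contact mask.
#' @param w_rim rim band width, m (default 2 um).
#' @param method `"literal"` (default) or `"force_per_perimeter"`.
#' @return tension, N/m.
#' @export
rim_tension <- function(tmap, w_rim = 2e-6,
                        method = c("literal", "force_per_perimeter")) {
  stopifnot(inherits(tmap, "traction_map"))
  method <- match.arg(method)
  if (!any(tmap$contact_mask)) stop("contact mask is empty")
  ps <- tmap$pixel_size
  dm <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(t(tmap$contact_mask) * 1)))
  band <- t(dm) * ps <= w_rim & t(dm) > 0
  if (!any(band)) stop("empty rim band")
  mag <- sqrt(tmap$stress_x^2 + tmap$stress_y^2)
  perim <- .mask_perimeter(t(tmap$contact_mask) * 1, ps)
  if (method == "literal") {
    mean(mag[band]) * perim
  } else {
    sum(mag[band]) * ps^2 / perim
  }
}
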