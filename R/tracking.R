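#' Bright-field frame sequence of a falling spheroid
#'
#' @param frames 3D array `[y, x, frame]` of grayscale intensities, or a
#'   list of equally sized matrices.
#' @param timestamps acquisition times in seconds, strictly increasing.
#' @param pixel_size um per pixel.
#' @param polarity `"dark"` if the spheroid is darker than the background
#'   (bright-field absorption, the usual case) or `"bright"`.
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, timestamps, pixel_size,
                           polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (is.list(frames)) {
    dm <- dim(frames[[1]])
    ss_check(all(vapply(frames, function(f) identical(dim(f), dm), logical(1))),
             "all frames must have the same shape")
    frames <- array(unlist(frames), c(dm, length(frames)))
  }
  ss_check(is.array(frames) && length(dim(frames)) == 3,
           "`frames` must be a [y, x, frame] array")
  n <- dim(frames)[3]
  ss_check(n >= 5, "a sequence needs at least 5 frames")
  ss_check(length(timestamps) == n, "one timestamp per frame required")
  ss_check(all(diff(timestamps) > 0), "timestamps must be strictly increasing")
  ss_check(is.numeric(pixel_size) && pixel_size > 0, "pixel_size must be > 0")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 pixel_size = pixel_size, polarity = polarity),
            class = "frame_sequence")
}

# All candidate components of one frame (already polarity-normalized so the
# object is dark). Returns centroids/radii for components passing the area
# floor, ordered by area; flags whether each touches the frame border.
frame_components <- function(frame, min_area = 20) {
  rng <- range(frame)
  if (rng[1] == rng[2]) return(NULL)
  u <- (frame - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(u, range = c(0, 1))
  mask <- u < thr
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(NULL)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) return(NULL)
  dm <- dim(frame)
  bg <- modal_value(u[!mask])
  out <- lapply(keep, function(id) {
    sel <- lab == id
    idx <- which(sel, arr.ind = TRUE)
    border <- any(idx[, 1] %in% c(1L, dm[1])) || any(idx[, 2] %in% c(1L, dm[2]))
    # contrast weight ~ partial pixel coverage of an absorbing object; a
    # narrow ring around the mask captures anti-aliased edge pixels
    ring <- EBImage::dilate(sel * 1, EBImage::makeBrush(3, "box")) > 0
    w <- pmax(bg - u, 0) * ring
    tot <- sum(w)
    cy <- sum(w * row(frame)) / tot
    cx <- sum(w * col(frame)) / tot
    fg <- modal_value(u[sel])
    contrast <- max(bg - fg, .Machine$double.eps)
    area_cov <- min(tot / contrast, sum(ring))  # coverage-weighted area, px
    list(x = cx, y = cy, radius = sqrt(area_cov / pi), area = sizes[id],
         border = border)
  })
  out[order(vapply(out, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Detect the spheroid in a single bright-field frame
#'
#' Otsu global threshold honoring the polarity, largest connected
#' component, contrast-weighted (sub-pixel) centroid, and equivalent-circle
#' radius from the partial-coverage-weighted area. The detection is invalid
#' when the component touches the frame border or its area is below 20 px.
#'
#' @param frame 2D intensity matrix.
#' @param polarity `"dark"` or `"bright"`.
#' @param pixel_size um per pixel (carried through; positions are returned
#'   in pixels).
#' @return list `x`, `y` (pixel coordinates, origin top-left, y down),
#'   `radius` (pixels), `valid`.
#' @export
detect_spheroid <- function(frame, polarity = "dark", pixel_size = 1) {
  ss_check(is.matrix(frame) && all(is.finite(frame)),
           "`frame` must be a finite 2D matrix")
  f <- if (identical(polarity, "bright")) max(frame) - frame else frame
  comps <- frame_components(f)
  if (is.null(comps))
    return(list(x = NA_real_, y = NA_real_, radius = NA_real_, valid = FALSE))
  c1 <- comps[[1]]
  list(x = c1$x, y = c1$y, radius = c1$radius, valid = !c1$border)
}

#' Track a spheroid through a frame sequence
#'
#' Per-frame detection with nearest-neighbor continuity: among the
#' candidate components of each frame the one closest to the previous
#' accepted position is followed, gated at 3x the running median
#' frame-to-frame displacement. Gaps of up to 2 frames are linearly
#' interpolated and flagged.
#'
#' @param seq a [frame_sequence()].
#' @return object of class `spheroid_track`: `x`, `y` (px), `radius` (px),
#'   `valid`, `interpolated` (all per frame).
#' @export
track_spheroid <- function(seq) {
  ss_check(inherits(seq, "frame_sequence"), "`seq` must be a frame_sequence")
  n <- dim(seq$frames)[3]
  x <- y <- r <- rep(NA_real_, n)
  valid <- interpolated <- logical(n)
  last <- NULL
  steps <- numeric()
  for (k in seq_len(n)) {
    f <- seq$frames[, , k]
    if (identical(seq$polarity, "bright")) f <- max(f) - f
    comps <- frame_components(f)
    if (is.null(comps)) next
    pick <- NULL
    if (is.null(last)) {
      if (!comps[[1]]$border) pick <- comps[[1]]
    } else {
      d <- vapply(comps, function(cc)
        sqrt((cc$x - last[1])^2 + (cc$y - last[2])^2), numeric(1))
      gate <- if (length(steps) >= 2) 3 * stats::median(steps) else Inf
      j <- which.min(d)
      if (d[j] <= max(gate, 3) && !comps[[j]]$border) pick <- comps[[j]]
    }
    if (!is.null(pick)) {
      x[k] <- pick$x; y[k] <- pick$y; r[k] <- pick$radius; valid[k] <- TRUE
      if (!is.null(last)) steps <- c(steps, sqrt((pick$x - last[1])^2 +
                                                   (pick$y - last[2])^2))
      last <- c(pick$x, pick$y)
    }
  }
  if (sum(valid) < 3)
    ss_stop("fewer than 3 valid detections in the sequence",
            "spherosed_tracking_error")
  # interpolate interior gaps of <= 2 frames
  vidx <- which(valid)
  for (g in which(!valid)) {
    if (g < min(vidx) || g > max(vidx)) next
    lo <- max(vidx[vidx < g]); hi <- min(vidx[vidx > g])
    if (hi - lo - 1 <= 2) {
      w <- (seq$timestamps[g] - seq$timestamps[lo]) /
        (seq$timestamps[hi] - seq$timestamps[lo])
      x[g] <- (1 - w) * x[lo] + w * x[hi]
      y[g] <- (1 - w) * y[lo] + w * y[hi]
      r[g] <- (1 - w) * r[lo] + w * r[hi]
      valid[g] <- TRUE; interpolated[g] <- TRUE
    }
  }
  structure(list(x = x, y = y, radius = r, valid = valid,
                 interpolated = interpolated),
            class = "spheroid_track")
}

# Robust per-point noise scale of 3-point local slopes, from second
# differences of the positions (a second difference of a smooth trend is
# ~0, so this isolates the measurement noise).
slope_noise_scale <- function(yv, tv) {
  if (length(yv) < 4) return(0)
  d2 <- diff(yv, differences = 2)
  sig_y <- stats::mad(d2) / sqrt(6)
  dt <- stats::median(diff(tv))
  sqrt(2) * sig_y / (2 * dt)
}

#' Fit the terminal velocity over the steady window of a track
#'
#' Local 3-point slopes of vertical position vs time are screened for a
#' terminal plateau: the steady window is the longest suffix of the track
#' whose local slopes all deviate from the suffix median slope by at most
#' `max(5%% of the median slope, 3.5 x the estimated slope noise)`; the
#' noise floor (estimated robustly from second differences) keeps the 5%%
#' rule, which is exact for noiseless tracks, usable on noisy centroids.
#' Ordinary least squares over the window gives the velocity.
#'
#' @param track a [track_spheroid()] result.
#' @param timestamps per-frame times (s).
#' @param pixel_size um per pixel.
#' @return object of class `velocity_fit`: `v` (m/s, positive = falling),
#'   `se` (m/s), `r2`, `window` (first/last frame index used).
#' @export
fit_velocity <- function(track, timestamps, pixel_size) {
  ok <- track$valid
  ss_check(sum(ok) >= 3, "need at least 3 valid frames")
  yv <- track$y[ok] * pixel_size * 1e-6   # m
  tv <- timestamps[ok]
  n <- length(yv)
  if (n < 3)
    ss_stop("no terminal plateau of length >= 3", "spherosed_fit_error")
  # central 3-point local slopes at interior points
  sl <- (yv[3:n] - yv[1:(n - 2)]) / (tv[3:n] - tv[1:(n - 2)])
  m <- length(sl)
  noise <- slope_noise_scale(yv, tv)
  start <- NA_integer_
  for (k in seq_len(m)) {
    win <- sl[k:m]
    med <- stats::median(win)
    tol <- max(0.05 * abs(med), 3.5 * noise)
    if (all(abs(win - med) <= tol)) { start <- k; break }
  }
  if (is.na(start) || (m - start + 1) < 1 || (n - start) < 2)
    ss_stop("no terminal plateau of length >= 3", "spherosed_fit_error")
  idx <- start:n    # frames covered by the accepted slopes
  if (length(idx) < 3)
    ss_stop("no terminal plateau of length >= 3", "spherosed_fit_error")
  fit <- stats::lm(yv[idx] ~ tv[idx])
  sm <- suppressWarnings(summary(fit))  # noiseless tracks fit exactly
  v <- unname(stats::coef(fit)[2])
  se <- unname(sm$coefficients[2, 2])
  r2 <- if (is.null(sm$r.squared) || is.nan(sm$r.squared)) 1 else sm$r.squared
  frames_used <- which(ok)[idx]
  structure(list(v = v, se = se, r2 = r2,
                 window = c(min(frames_used), max(frames_used))),
            class = "velocity_fit")
}

#' Measure a spheroid from a fall video
#'
#' Composes tracking, velocity fitting, radius estimation (median of valid
#' per-frame radii), density inversion, mass/weight computation, and the
#' Reynolds guard into one per-spheroid biophysical measurement.
#'
#' @param seq a [frame_sequence()].
#' @param fluid a [fluid_medium()].
#' @param chan a [channel_geometry()].
#' @param config optional list: `wall_correction` (FALSE),
#'   `reynolds_threshold` (0.5), `min_r2` (0.99).
#' @return a [biophysical_measurement()].
#' @export
measure_spheroid <- function(seq, fluid, chan, config = list()) {
  cfg <- utils::modifyList(list(wall_correction = FALSE,
                                reynolds_threshold = 0.5, min_r2 = 0.99),
                           config)
  trk <- track_spheroid(seq)
  fit <- fit_velocity(trk, seq$timestamps, seq$pixel_size)
  r_px <- stats::median(trk$radius[trk$valid], na.rm = TRUE)
  r_um <- r_px * seq$pixel_size
  rho <- invert_density(fit$v, r_um * 1e-6, fluid, chan,
                        wall_correction = cfg$wall_correction)
  flags <- character()
  if (fit$r2 < cfg$min_r2) flags <- c(flags, "poor_plateau")
  biophysical_measurement(
    terminal_velocity = fit$v, velocity_se = fit$se,
    diameter_um = 2 * r_um, mass_density_kg_m3 = rho,
    fluid = fluid, chan = chan, n_repetitions = 1L, qc_flags = flags,
    reynolds_threshold = cfg$reynolds_threshold)
}

#' Average repeated fall measurements of one spheroid
#'
#' Arithmetic mean of density, mass, buoyant weight, diameter and velocity
#' across repetitions; the velocity standard error is pooled as
#' `sqrt(sum(se_i^2)) / k`; QC flags are unioned.
#'
#' @param measurements list of [biophysical_measurement()] objects.
#' @return a single `biophysical_measurement` with `n_repetitions` set.
#' @export
aggregate_repetitions <- function(measurements) {
  ss_check(is.list(measurements) && length(measurements) >= 1,
           "need at least one measurement")
  ss_check(all(vapply(measurements, inherits, logical(1),
                      "biophysical_measurement")),
           "all elements must be biophysical measurements")
  k <- length(measurements)
  g <- function(f) vapply(measurements, `[[`, numeric(1), f)
  out <- measurements[[1]]
  out$terminal_velocity <- mean(g("terminal_velocity"))
  out$velocity_se <- sqrt(sum(g("velocity_se")^2)) / k
  out$diameter <- mean(g("diameter"))
  out$mass_density <- mean(g("mass_density"))
  out$mass <- mean(g("mass"))
  out$buoyant_weight <- mean(g("buoyant_weight"))
  out$reynolds <- mean(g("reynolds"))
  out$n_repetitions <- sum(vapply(measurements, `[[`, integer(1),
                                  "n_repetitions"))
  out$qc_flags <- Reduce(union, lapply(measurements, `[[`, "qc_flags"))
  out
}
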