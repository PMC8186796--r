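# Seeded ground-truth generators for every pipeline input: fall videos,
# cleared-spheroid nuclei stacks, cohort tables and fluorescence standard
# curves. Every generator is a pure function of (scenario, seed): the RNG
# state is localized and restored, so identical calls give identical output.

#' Scenario for a synthetic falling-spheroid video
#'
#' @param true_density spheroid mass density (kg/m^3).
#' @param true_radius_um spheroid radius (um).
#' @param fluid a [fluid_medium()]. @param chan a [channel_geometry()].
#' @param fps frames per second; if `NULL`, chosen so the terminal fall
#'   advances ~2.5 px per frame.
#' @param n_frames number of frames (>= 5).
#' @param pixel_size_um um per pixel.
#' @param noise_sigma_px per-frame Gaussian jitter of the rendered disk
#'   center (px), i.e. centroid noise.
#' @param intensity_noise additive Gaussian pixel-intensity noise SD
#'   (intensity units, background = 1, disk contrast = `contrast`).
#' @param contrast disk darkness relative to background, in (0, 1].
#' @param v0 initial velocity (m/s).
#' @return list of class `fall_scenario`.
#' @export
fall_scenario <- function(true_density = 1050, true_radius_um = 100,
                          fluid = fluid_medium(), chan = channel_geometry(),
                          fps = NULL, n_frames = 40, pixel_size_um = 2,
                          noise_sigma_px = 0, intensity_noise = 0,
                          contrast = 0.6, v0 = 0) {
  ss_check(true_density > 0 && true_radius_um > 0, "density and radius must be > 0")
  ss_check(n_frames >= 5, "need at least 5 frames")
  ss_check(pixel_size_um > 0 && contrast > 0 && contrast <= 1,
           "pixel size must be > 0 and contrast in (0, 1]")
  ss_check(noise_sigma_px >= 0 && intensity_noise >= 0, "noise must be >= 0")
  structure(list(true_density = true_density, true_radius_um = true_radius_um,
                 fluid = fluid, chan = chan, fps = fps, n_frames = n_frames,
                 pixel_size_um = pixel_size_um, noise_sigma_px = noise_sigma_px,
                 intensity_noise = intensity_noise, contrast = contrast,
                 v0 = v0), class = "fall_scenario")
}

# Anti-aliased dark disk on a unit background: pixel value
# 1 - contrast * coverage, coverage approximated by the clamped signed
# distance from the pixel center to the circle edge (exact to first order,
# and integrating to the true disk area), so sub-pixel centroid truth is
# meaningful.
render_disk <- function(ny, nx, cy, cx, r_px, contrast) {
  d <- sqrt(outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`))
  coverage <- pmin(pmax(r_px - d + 0.5, 0), 1)
  1 - contrast * coverage
}

#' Generate a synthetic fall video with ground truth
#'
#' The trajectory comes from the transient settling model
#' ([settle_ode()]); each frame renders an anti-aliased dark disk at the
#' (sub-pixel) true position plus optional centroid jitter and pixel
#' noise. The frame is sized to contain the whole fall with a margin; an
#' explicit `frame_height_px` that cuts the fall short raises a
#' `frame_too_short` error.
#'
#' @param scenario a [fall_scenario()].
#' @param seed integer seed.
#' @param frame_height_px optional fixed frame height (px).
#' @return list: `seq` (a [frame_sequence()]), `truth` (list with
#'   `density`, `radius_um`, `diameter_um`, `terminal_velocity`, `mass_ug`,
#'   `buoyant_weight_nN`, `y_px` per-frame true centers).
#' @export
gen_fall_video <- function(scenario, seed = 1, frame_height_px = NULL) {
  sc <- scenario
  ss_check(inherits(sc, "fall_scenario"), "`scenario` must be a fall_scenario")
  sph <- spheroid_physics(sc$true_radius_um * 1e-6, sc$true_density)
  v_term <- terminal_velocity(sph, sc$fluid, sc$chan)
  ss_check(v_term > 0, "scenario must sink (density above the fluid's)")
  r_px <- sc$true_radius_um / sc$pixel_size_um
  fps <- sc$fps
  if (is.null(fps)) {
    # ~2.5 px advance per frame, but never so fast that the sequence fails
    # to span the inertial transient (>= 25 relaxation times total)
    fps <- v_term / (2.5 * sc$pixel_size_um * 1e-6)
    tau <- relaxation_time(sph, sc$fluid, sc$chan)
    fps <- min(fps, sc$n_frames / (25 * tau))
  }
  times <- (seq_len(sc$n_frames) - 1) / fps
  traj <- settle_ode(sph, sc$fluid, sc$chan, v0 = sc$v0, times = times)
  y_px_true <- traj$y / (sc$pixel_size_um * 1e-6)
  margin <- 4
  y0 <- r_px + margin + 1
  ny_needed <- ceiling(y0 + max(y_px_true) + r_px + margin)
  if (!is.null(frame_height_px)) {
    # require >= 5 frames with the disk fully inside the fixed frame
    inside <- y0 + y_px_true + r_px + 1 <= frame_height_px
    if (sum(inside) < 5)
      ss_stop("spheroid exits the frame before 5 steady frames",
              "spherosed_frame_too_short")
    ny <- frame_height_px
  } else ny <- ny_needed
  nx <- ceiling(2 * r_px + 2 * (margin + 1) + 2)
  with_local_seed(seed, {
    jit <- matrix(0, sc$n_frames, 2)
    if (sc$noise_sigma_px > 0)
      jit <- matrix(stats::rnorm(2 * sc$n_frames, 0, sc$noise_sigma_px),
                    ncol = 2)
    frames <- array(0, c(ny, nx, sc$n_frames))
    cx <- nx / 2
    for (k in seq_len(sc$n_frames)) {
      f <- render_disk(ny, nx, y0 + y_px_true[k] + jit[k, 1],
                       cx + jit[k, 2], r_px, sc$contrast)
      if (sc$intensity_noise > 0)
        f <- f + matrix(stats::rnorm(length(f), 0, sc$intensity_noise),
                        nrow = ny)
      frames[, , k] <- quantize16(f)
    }
    mw <- mass_and_weight(sc$true_density, sc$true_radius_um * 1e-6,
                          sc$fluid, sc$chan$gravity)
    list(seq = frame_sequence(frames, times, sc$pixel_size_um, "dark"),
         truth = list(density = sc$true_density,
                      radius_um = sc$true_radius_um,
                      diameter_um = 2 * sc$true_radius_um,
                      terminal_velocity = v_term,
                      mass_ug = mw$mass_ug,
                      buoyant_weight_nN = mw$buoyant_weight_nN,
                      y_px = y0 + y_px_true, fps = fps))
  })
}

#' Scenario for a synthetic cleared-spheroid nuclei stack
#'
#' @param spheroid_radius_um spheroid radius (um).
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_um mean nucleus radius (um).
#' @param nucleus_radius_sd_um SD of nucleus radii (um).
#' @param min_separation_um minimum center-to-center distance (um).
#' @param voxel_size_um um per voxel `(y, x, z)`; default lateral 0.7, z 1
#'   (z-step 1 um as in confocal deep imaging; lateral binned for speed).
#' @param psf_sigma_um Gaussian PSF sigma `(y, x, z)` in um.
#' @param peak_snr peak signal-to-noise ratio of a nucleus over the noise.
#' @param background_level additive background intensity (nucleus peak = 1).
#' @param body_level dim diffuse intensity of the spheroid body (tissue
#'   autofluorescence / residual stain), as a fraction of nucleus peak.
#' @return list of class `stack_scenario`.
#' @export
stack_scenario <- function(spheroid_radius_um = 18, n_nuclei = 50,
                           nucleus_radius_um = 2, nucleus_radius_sd_um = 0.15,
                           min_separation_um = 4,
                           voxel_size_um = c(y = 0.7, x = 0.7, z = 1),
                           psf_sigma_um = c(y = 0.25, x = 0.25, z = 0.7),
                           peak_snr = 10, background_level = 0.1,
                           body_level = 0.08) {
  ss_check(spheroid_radius_um > 0 && nucleus_radius_um > 0,
           "radii must be > 0")
  ss_check(n_nuclei >= 0, "n_nuclei must be >= 0")
  ss_check(peak_snr > 0, "peak_snr must be > 0")
  # rejection-sampling feasibility: exclusion spheres must fit loosely
  half_sep <- min_separation_um / 2
  packing <- n_nuclei * half_sep^3 /
    (spheroid_radius_um + half_sep)^3
  ss_check(packing <= 0.25,
           "n_nuclei not placeable at min_separation within the sphere")
  structure(list(spheroid_radius_um = spheroid_radius_um, n_nuclei = n_nuclei,
                 nucleus_radius_um = nucleus_radius_um,
                 nucleus_radius_sd_um = nucleus_radius_sd_um,
                 min_separation_um = min_separation_um,
                 voxel_size_um = voxel_size_um, psf_sigma_um = psf_sigma_um,
                 peak_snr = peak_snr, background_level = background_level,
                 body_level = body_level), class = "stack_scenario")
}

# Rejection-sample n centers inside a sphere of radius R with pairwise
# minimum separation; errors after a bounded number of attempts.
sample_centers <- function(n, R, min_sep, max_attempts = 20000L) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      ss_stop("nucleus placement failed: density too high",
              "spherosed_density_too_high")
    p <- stats::runif(3, -R, R)
    if (sum(p^2) > R^2) next
    if (placed > 0) {
      d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2)
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
  }
  pts
}

#' Generate a synthetic nuclei stack with ground truth
#'
#' Nucleus centers are rejection-sampled inside the spheroid at the
#' requested minimum separation; each nucleus is rendered as an
#' anti-aliased solid ball, superimposed on a dim spheroid body, convolved
#' with a Gaussian PSF, and degraded with Poisson photon noise plus
#' Gaussian read noise scaled to the stated peak SNR. A matching 2D
#' bright-field image (absorbing disk over a bright background) is
#' rendered for the optical-density readout.
#'
#' @param scenario a [stack_scenario()].
#' @param seed integer seed.
#' @return list: `nuclear` ([image_stack3d()]), `brightfield` (2D matrix),
#'   `truth` (centers in um and voxels, count, spheroid radius/volume,
#'   bright-field absorbance and area).
#' @export
gen_nuclei_stack <- function(scenario, seed = 1) {
  sc <- scenario
  ss_check(inherits(sc, "stack_scenario"), "`scenario` must be a stack_scenario")
  vs <- sc$voxel_size_um
  R <- sc$spheroid_radius_um
  pad <- 2 * sc$nucleus_radius_um + 2
  extent <- R + pad
  dm <- c(ceiling(2 * extent / vs[1]), ceiling(2 * extent / vs[2]),
          ceiling(2 * extent / vs[3]))
  ctr_um <- dm / 2 * vs  # stack center in um (y, x, z)
  with_local_seed(seed, {
    centers <- sample_centers(sc$n_nuclei, R - sc$nucleus_radius_um,
                              sc$min_separation_um)
    radii <- if (sc$n_nuclei > 0)
      pmax(stats::rnorm(sc$n_nuclei, sc$nucleus_radius_um,
                        sc$nucleus_radius_sd_um),
           0.5 * sc$nucleus_radius_um) else numeric(0)
    ax <- lapply(1:3, function(a) (seq_len(dm[a]) - 0.5) * vs[a] - ctr_um[a])
    # dim spheroid body (absent when the scenario has no cells at all:
    # a zero-nucleus scenario is a background-only field)
    clean <- array(0, dm)
    if (sc$n_nuclei > 0) {
      d_body <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
      clean <- sc$body_level * pmin(pmax((R - d_body) / min(vs) + 0.5, 0), 1)
    }
    # anti-aliased solid balls
    for (i in seq_len(sc$n_nuclei)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]; cz <- centers[i, 3]
      d <- sqrt(outer(outer((ax[[1]] - cy)^2, (ax[[2]] - cx)^2, `+`),
                      (ax[[3]] - cz)^2, `+`))
      cov <- pmin(pmax((radii[i] - d) / min(vs) + 0.5, 0), 1)
      clean <- pmax(clean, cov)
    }
    blurred <- gauss3d(clean, sc$psf_sigma_um / vs) + sc$background_level
    peak <- max(blurred)
    scale <- sc$peak_snr^2 / peak        # photons per intensity unit
    noisy <- stats::rpois(length(blurred), pmax(blurred, 0) * scale) / scale +
      stats::rnorm(length(blurred), 0, 0.25 * peak / sc$peak_snr)
    stack <- array(pmax(noisy, 0), dm)
    # bright-field: absorbing disk over unit background
    bf_px <- vs[2]
    nyx <- c(dm[1], dm[2])
    d2d <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
    absorb <- 0.5 * pmin(pmax((R - d2d) / bf_px + 0.5, 0), 1)
    bf <- quantize16(10^(-absorb) *
                       (1 + stats::rnorm(prod(nyx), 0, 0.003)))
    dim(bf) <- nyx
    vox_centers <- if (sc$n_nuclei > 0)
      sweep(sweep(centers, 2, ctr_um, `+`), 2, vs, `/`) else centers
    list(nuclear = image_stack3d(stack, vs, "nuclear"),
         brightfield = bf,
         truth = list(centers_um = centers, centers_vox = vox_centers,
                      count = sc$n_nuclei, radii_um = radii,
                      spheroid_radius_um = R,
                      volume_um3 = 4 / 3 * pi * R^3,
                      bf_absorbance = 0.5, bf_pixel_size_um = bf_px,
                      bf_area_um2 = pi * R^2))
  })
}

#' Scenario for a synthetic measurement cohort
#'
#' Defaults emulate a treated-spheroid study: under treatment the mass
#' density rises while weight and diameter fall, identically in live and
#' fixed samples (fixation-neutral); per-cell spread follows typical
#' sedimentation-assay repeatability.
#'
#' @param means named list `condition -> c(density, weight, diameter)`
#'   cell means (g/cm^3, ug, um).
#' @param sds per-parameter SDs `c(density, weight, diameter)`.
#' @param n_per_cell spheroids per (condition x state) cell.
#' @param fixed_offset added to every fixed-state mean (0 = fixation has
#'   no effect).
#' @param outliers list `list(count =, offset_sd =)`: per cell, how many
#'   values are displaced by `offset_sd` SDs (ground-truth outliers).
#' @return list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(
    means = list(CTRL = c(density = 1.048, weight = 4.4, diameter = 200),
                 CZB250 = c(density = 1.056, weight = 3.6, diameter = 185),
                 CZB500 = c(density = 1.060, weight = 3.2, diameter = 175)),
    sds = c(density = 0.003, weight = 0.35, diameter = 8),
    n_per_cell = 15, fixed_offset = c(density = 0, weight = 0, diameter = 0),
    outliers = list(count = 0, offset_sd = 6)) {
  ss_check(n_per_cell >= 4, "need n >= 4 per cell")
  ss_check(all(sds > 0), "sds must be > 0")
  ss_check(all(COHORT_CONDITIONS %in% names(means)),
           "means must cover CTRL, CZB250, CZB500")
  structure(list(means = means, sds = sds, n_per_cell = n_per_cell,
                 fixed_offset = fixed_offset, outliers = outliers),
            class = "cohort_scenario")
}

#' Generate a synthetic cohort table with ground truth
#'
#' Gaussian draws per (condition x state x parameter) cell; optional
#' outliers displaced by a stated number of SDs are injected and recorded
#' in the ground truth.
#'
#' @param scenario a [cohort_scenario()].
#' @param seed integer seed.
#' @return list: `table` (a [cohort_table()]), `truth` (cell means/sds and
#'   injected outlier values per cell).
#' @export
gen_cohort <- function(scenario, seed = 1) {
  sc <- scenario
  ss_check(inherits(sc, "cohort_scenario"), "`scenario` must be a cohort_scenario")
  with_local_seed(seed, {
    rows <- NULL
    injected <- list()
    id <- 0L
    for (st in COHORT_STATES) {
      for (cond in COHORT_CONDITIONS) {
        for (par in COHORT_PARAMETERS) {
          mu <- sc$means[[cond]][[par]] +
            (if (st == "fixed") sc$fixed_offset[[par]] else 0)
          sd <- sc$sds[[par]]
          v <- stats::rnorm(sc$n_per_cell, mu, sd)
          n_out <- sc$outliers$count
          if (n_out > 0) {
            # one-sided high outliers (doublet/debris-like artifacts);
            # jittered so injected values are distinct
            pick <- seq_len(n_out)
            v[pick] <- mu + sc$outliers$offset_sd * sd *
              (1 + 0.02 * (pick - 1))
            injected[[paste(cond, st, par, sep = ".")]] <- v[pick]
          }
          rows <- rbind(rows, data.frame(
            spheroid_id = sprintf("%s_%s_%03d", cond, st,
                                  id + seq_along(v)),
            condition = cond, state = st, parameter = par, value = v))
        }
        id <- id + sc$n_per_cell
      }
    }
    list(table = suppressWarnings(cohort_table(rows)),
         truth = list(means = sc$means, sds = sc$sds,
                      fixed_offset = sc$fixed_offset, outliers = injected))
  })
}

#' Generate a synthetic fluorescence standard-curve table
#'
#' @param slope,intercept true line `fluorescence = slope * conc + intercept`.
#' @param noise_sd Gaussian noise on the fluorescence readings.
#' @param n number of standards (>= 3), equally spaced concentrations.
#' @param seed integer seed.
#' @param conc_max largest standard concentration.
#' @return data.frame with columns `concentration`, `fluorescence`.
#' @export
gen_standard_curve <- function(slope, intercept, noise_sd = 0, n = 8,
                               seed = 1, conc_max = 10) {
  ss_check(n >= 3, "need at least 3 standards")
  ss_check(noise_sd >= 0, "noise_sd must be >= 0")
  with_local_seed(seed, {
    conc <- seq(0, conc_max, length.out = n)
    f <- slope * conc + intercept + stats::rnorm(n, 0, noise_sd)
    data.frame(concentration = conc, fluorescence = f)
  })
}
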