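# small helper: an anti-aliased solid ball on an isotropic grid
ball_stack <- function(dm, center, r, amplitude = 1) {
  ax <- lapply(dm, seq_len)
  d <- sqrt(outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2,
                        `+`), (ax[[3]] - center[3])^2, `+`))
  amplitude * pmin(pmax(r - d + 0.5, 0), 1)
}

test_that("Richardson-Lucy with a delta PSF is the identity", {
  set.seed(3)
  a <- array(runif(20^3), c(20, 20, 20))
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  expect_equal(richardson_lucy(a, delta, 5), a, tolerance = 1e-10)
})

test_that("Richardson-Lucy sharpens blurred blobs and conserves intensity", {
  ax <- 1:32
  b1 <- exp(-0.5 * outer(outer((ax - 12)^2, (ax - 16)^2, `+`),
                         (ax - 16)^2, `+`) / 4)
  b2 <- exp(-0.5 * outer(outer((ax - 21)^2, (ax - 16)^2, `+`),
                         (ax - 16)^2, `+`) / 4)
  truth <- array(b1 + b2, c(32, 32, 32))
  psf <- gaussian_psf(c(1, 1, 1), na = 0.8, wavelength_um = 1.2)
  blurred <- pmax(spherosed:::fft_convolve(truth, psf), 0)
  dec <- richardson_lucy(blurred, psf, 20)
  valley <- function(x) (x[12, 16, 16] + x[21, 16, 16]) / 2 - x[16, 16, 16]
  expect_gt(valley(dec), valley(blurred))      # contrast strictly increases
  expect_lt(abs(sum(dec) / sum(blurred) - 1), 0.01)
  expect_gte(min(dec), 0)
  expect_error(richardson_lucy(blurred - 1, psf, 2),
               class = "spherosed_validation_error")
  expect_error(richardson_lucy(blurred, psf * 2, 2),
               class = "spherosed_validation_error")
})

test_that("z-alignment recovers injected per-slice drifts within 0.5 px", {
  ax <- 1:40
  blob <- exp(-0.5 * outer((ax - 20)^2, (ax - 18)^2, `+`) / 16) +
    0.6 * exp(-0.5 * outer((ax - 12)^2, (ax - 27)^2, `+`) / 9)
  base <- array(rep(blob, 8), c(40, 40, 8))
  drift <- cbind(cumsum(c(0, rep(0.8, 7))), cumsum(c(0, rep(-0.5, 7))))
  shifted <- base
  for (z in 2:8)
    shifted[, , z] <- spherosed:::shift2d_subpix(base[, , z],
                                                 drift[z, 1], drift[z, 2])
  al <- align_z(shifted)
  expect_lt(max(abs(al$shifts - drift)), 0.5)
  # unshifted stack: all shifts (numerically) zero
  al0 <- align_z(base)
  expect_lt(max(abs(al0$shifts)), 1e-6)
})

test_that("z-alignment of pure noise is bounded and flagged low-confidence", {
  set.seed(8)
  nz <- array(rnorm(40 * 40 * 5), c(40, 40, 5))
  al <- align_z(nz, max_shift = 5)
  expect_true(all(abs(al$shifts) <= 5 * 4))
  expect_true(any(al$low_confidence))
})

test_that("denoising respects physical units and reduces noise variance", {
  set.seed(4)
  vs <- c(y = 0.5, x = 0.5, z = 2)
  a <- array(rnorm(24^3), c(24, 24, 24))
  expect_identical(denoise_stack(a, 0, vs), a)
  sm <- denoise_stack(a, 1, vs)
  expect_lt(var(as.vector(sm)), var(as.vector(a)))
  # anisotropic voxels: same physical sigma spreads less along the coarse z
  delta <- array(0, c(25, 25, 25)); delta[13, 13, 13] <- 1
  g <- denoise_stack(delta, 2, vs)
  spread <- function(ax) {
    w <- apply(g, ax, sum)
    sqrt(sum(w * (1:25 - 13)^2))
  }
  expect_gt(spread(1), 2 * spread(3))  # 4 vox lateral sigma vs 1 vox axial
})

test_that("3D spot detection finds every well-separated nucleus", {
  sc <- stack_scenario(n_nuclei = 30, min_separation_um = 8,
                       peak_snr = 50)
  g <- gen_nuclei_stack(sc, seed = 6)
  vs <- sc$voxel_size_um
  seeds <- detect_spots3d(denoise_stack(g$nuclear$voxels, 0.3, vs), vs,
                          nucleus_diameter_um = 4)
  expect_identical(nrow(seeds), 30L)
  # every seed within one voxel (per axis) of a true center
  for (i in seq_len(nrow(seeds))) {
    d <- abs(sweep(g$truth$centers_vox, 2,
                   as.numeric(seeds[i, c("y", "x", "z")]), `-`))
    expect_lte(min(apply(d, 1, max)), 1.05)
  }
})

test_that("spot detection handles empty stacks and near-merged pairs", {
  empty <- array(0, c(12, 12, 12))
  expect_identical(nrow(detect_spots3d(empty, c(1, 1, 1), 4)), 0L)
  # two nuclei closer than the separation floor: never more than 2 seeds
  two <- ball_stack(c(24, 24, 12), c(10, 12, 6), 2.5) +
    ball_stack(c(24, 24, 12), c(13, 12, 6), 2.5)
  seeds <- detect_spots3d(two, c(1, 1, 1), 5)
  expect_lte(nrow(seeds), 2L)
  expect_gte(nrow(seeds), 1L)
})

test_that("region growing recovers a single nucleus volume", {
  stk <- ball_stack(c(24, 24, 24), c(12, 12, 12), 4) + 0.01
  seeds <- data.frame(y = 12, x = 12, z = 12)
  seg <- grow_regions(stk, seeds, c(1, 1, 1))
  expect_identical(seg$count, 1L)
  true_vol <- 4 / 3 * pi * 4^3
  expect_lt(abs(sum(seg$labels == 1L) - true_vol) / true_vol, 0.2)
})

test_that("touching nuclei split at the intensity valley", {
  stk <- pmax(ball_stack(c(30, 24, 16), c(11, 12, 8), 4),
              ball_stack(c(30, 24, 16), c(19, 12, 8), 4))
  seeds <- data.frame(y = c(11, 19), x = c(12, 12), z = c(8, 8))
  seg <- grow_regions(stk, seeds, c(1, 1, 1))
  expect_identical(seg$count, 2L)
  # split plane near the geometric valley (y = 15)
  lab1_y <- which(seg$labels == 1L, arr.ind = TRUE)[, 1]
  lab2_y <- which(seg$labels == 2L, arr.ind = TRUE)[, 1]
  expect_lt(max(lab1_y), 17)
  expect_gt(min(lab2_y), 13)
})

test_that("label smoothing removes spurs and never raises the count", {
  lab <- array(0L, c(16, 16, 16))
  lab[6:11, 6:11, 6:11] <- 1L
  lab[12:15, 8, 8] <- 1L              # one-voxel-thick spur
  seg <- structure(list(labels = lab, seeds = NULL, count = 1L),
                   class = "nuclei_segmentation")
  sm <- smooth_labels(seg, c(1, 1, 1), radius_um = 1)
  expect_lte(sm$count, 1L)
  expect_identical(sum(sm$labels[13:15, 8, 8]), 0L)  # spur gone
  expect_gt(sum(sm$labels == 1L), 100)               # body kept
  # radius 0 is the identity
  expect_identical(smooth_labels(seg, c(1, 1, 1), 0)$labels, lab)
})

test_that("erosion-splitting separates a dumbbell but not a solid ball", {
  dumb <- (ball_stack(c(32, 20, 20), c(9, 10, 10), 5) >= 1) |
    (ball_stack(c(32, 20, 20), c(23, 10, 10), 5) >= 1)
  dumb[15:18, 10, 10] <- TRUE          # thin neck
  lab <- array(0L, dim(dumb)); lab[dumb] <- 1L
  seg <- structure(list(labels = lab, seeds = NULL, count = 1L),
                   class = "nuclei_segmentation")
  sep <- separate_objects(seg, 2)
  expect_identical(sep$count, 2L)
  # a solid ball survives unsplit
  ball <- ball_stack(c(20, 20, 20), c(10, 10, 10), 6) >= 1
  lab2 <- array(0L, dim(ball)); lab2[ball] <- 1L
  seg2 <- structure(list(labels = lab2, seeds = NULL, count = 1L),
                    class = "nuclei_segmentation")
  expect_identical(separate_objects(seg2, 2)$count, 1L)
  # erosion_count 0 is the identity
  expect_identical(separate_objects(seg, 0)$labels, lab)
})

test_that("counting applies the volume floor monotonically", {
  lab <- array(0L, c(12, 12, 12))
  lab[2:5, 2:5, 2:5] <- 1L     # 64 voxels
  lab[9, 9, 9] <- 2L           # 1 voxel
  seg <- structure(list(labels = lab, seeds = NULL, count = 2L),
                   class = "nuclei_segmentation")
  expect_identical(count_nuclei(seg, c(1, 1, 1), min_volume_um3 = 0.5), 2L)
  expect_identical(count_nuclei(seg, c(1, 1, 1), min_volume_um3 = 5), 1L)
  expect_identical(count_nuclei(seg, c(1, 1, 1), min_volume_um3 = 100), 0L)
  empty <- structure(list(labels = array(0L, c(4, 4, 4)), seeds = NULL,
                          count = 0L), class = "nuclei_segmentation")
  expect_identical(count_nuclei(empty, c(1, 1, 1)), 0L)
})

test_that("spheroid volume: sphere formula and voxelized ball agree", {
  expect_equal(spheroid_volume(method = "equivalent_sphere",
                               diameter_um = 100),
               523598.7756, tolerance = 1e-9)
  ball <- ball_stack(c(68, 68, 68), c(34.5, 34.5, 34.5), 30)
  v <- spheroid_volume(ball, c(1, 1, 1), method = "mask")
  truth <- 4 / 3 * pi * 30^3
  expect_lt(abs(v - truth) / truth, 0.02)
  expect_error(spheroid_volume(method = "mask"),
               class = "spherosed_validation_error")
})

test_that("nuclear density is the exact count-to-volume ratio", {
  expect_equal(nuclei_density(50, 523598.8), 9.549297e-5, tolerance = 1e-6)
  expect_identical(nuclei_density(0, 100), 0)
  expect_error(nuclei_density(10, 0), class = "spherosed_validation_error")
})

test_that("optical density matches the flat-disk closed form", {
  px <- 1
  r_px <- sqrt(1000 / pi)       # disk area 1000 um^2 at 1 um/px
  bg <- 0.8
  d <- sqrt(outer((1:80 - 40.2)^2, (1:80 - 39.7)^2, `+`))
  img <- matrix(bg, 80, 80)
  img[d <= r_px] <- bg / 10     # absorbance exactly 1 inside
  od <- optical_density(img, px)
  expect_equal(od$modal_absorbance, 1, tolerance = 0.01)
  expect_equal(od$od, od$modal_absorbance / od$area_um2, tolerance = 1e-12)
  expect_equal(od$area_um2, 1000, tolerance = 0.03)
  # a darker disk of equal area has larger OD
  img2 <- img; img2[d <= r_px] <- bg / 100
  expect_gt(optical_density(img2, px)$od, od$od)
  expect_error(optical_density(matrix(0.5, 50, 50), px),
               class = "spherosed_no_spheroid")
})

test_that("full quantification is deterministic and ordered by design", {
  ctrl_sc <- stack_scenario(spheroid_radius_um = 15, n_nuclei = 24)
  trt_sc <- stack_scenario(spheroid_radius_um = 11, n_nuclei = 16)
  ctrl <- gen_nuclei_stack(ctrl_sc, seed = 41)
  trt <- gen_nuclei_stack(trt_sc, seed = 42)
  q_ctrl <- quantify_nuclei(ctrl$nuclear, brightfield = ctrl$brightfield)
  q_trt <- quantify_nuclei(trt$nuclear, brightfield = trt$brightfield)
  # the generated "treated-like" spheroid is smaller, less populated, denser
  expect_lt(q_trt$count, q_ctrl$count)
  expect_lt(q_trt$volume, q_ctrl$volume)
  expect_gt(q_trt$density, q_ctrl$density)
  # density = count / volume holds exactly
  expect_identical(q_ctrl$density, q_ctrl$count / q_ctrl$volume)
  expect_identical(q_trt$density, q_trt$count / q_trt$volume)
  # determinism
  q_again <- quantify_nuclei(ctrl$nuclear, brightfield = ctrl$brightfield)
  expect_identical(q_again$count, q_ctrl$count)
  expect_identical(q_again$volume, q_ctrl$volume)
  # missing bright-field: absent, not zero
  expect_true(is.na(quantify_nuclei(trt$nuclear)$optical_density))
})

test_that("counts are stable under voxel-size refinement", {
  mk <- function(vs) {
    sc <- stack_scenario(spheroid_radius_um = 9, n_nuclei = 8,
                         min_separation_um = 5.5,
                         voxel_size_um = vs)
    g <- gen_nuclei_stack(sc, seed = 19)
    quantify_nuclei(g$nuclear, params = list(align = FALSE))$count
  }
  coarse <- mk(c(y = 1, x = 1, z = 1))
  fine <- mk(c(y = 0.5, x = 0.5, z = 0.5))
  expect_lte(abs(coarse - fine) / max(fine, 1), 0.05)
})
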