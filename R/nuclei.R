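#' Build a 3D image stack object
#'
#' @param voxels 3D numeric array, dimensions `[y, x, z]`.
#' @param voxel_size voxel size in micrometers, named `c(y =, x =, z =)` or
#'   an unnamed length-3 vector in that order. Typical confocal acquisition:
#'   lateral 0.21 um/pixel, z-step 1 um.
#' @param channel one of `"nuclear"`, `"actin"`, `"brightfield"`.
#' @return object of class `image_stack3d` with fields `voxels`,
#'   `voxel_size`, `channel`.
#' @export
image_stack3d <- function(voxels, voxel_size, channel = "nuclear") {
  ss_check(is.array(voxels) && length(dim(voxels)) == 3,
           "`voxels` must be a 3D array [y, x, z]")
  ss_check(dim(voxels)[3] >= 3, "a stack needs at least 3 z-slices")
  voxel_size <- as.numeric(voxel_size)
  ss_check(length(voxel_size) == 3 && all(voxel_size > 0),
           "`voxel_size` must be 3 positive sizes (y, x, z) in um")
  names(voxel_size) <- c("y", "x", "z")
  channel <- match.arg(channel, c("nuclear", "actin", "brightfield"))
  structure(list(voxels = voxels, voxel_size = voxel_size, channel = channel),
            class = "image_stack3d")
}

as_voxels <- function(stack) {
  if (inherits(stack, "image_stack3d")) stack$voxels else stack
}

#' Gaussian model of a confocal point spread function
#'
#' An analytic stand-in for a measured PSF, parameterized by numerical
#' aperture and emission wavelength: lateral sigma `0.21 lambda / NA`,
#' axial sigma `0.66 lambda n / NA^2` (refractive index `n`), sampled on
#' the voxel grid and normalized to unit sum.
#'
#' @param voxel_size um per voxel, `(y, x, z)`.
#' @param na numerical aperture (default 1.05, a silicone-immersion
#'   deep-imaging objective).
#' @param wavelength_um emission wavelength (default 0.461, DAPI emission).
#' @param refractive_index mounting-medium index (default 1.46).
#' @return 3D kernel array summing to 1.
#' @export
gaussian_psf <- function(voxel_size, na = 1.05, wavelength_um = 0.461,
                         refractive_index = 1.46) {
  sig_lat <- 0.21 * wavelength_um / na
  sig_ax <- 0.66 * wavelength_um * refractive_index / na^2
  sig_um <- c(y = sig_lat, x = sig_lat, z = sig_ax)
  sig_vox <- sig_um / voxel_size
  half <- pmax(ceiling(3 * sig_vox), 1)
  g <- expand.grid(dy = -half[1]:half[1], dx = -half[2]:half[2],
                   dz = -half[3]:half[3])
  k <- exp(-0.5 * ((g$dy / sig_vox[1])^2 + (g$dx / sig_vox[2])^2 +
                     (g$dz / sig_vox[3])^2))
  arr <- array(k, dim = 2 * half + 1)
  arr / sum(arr)
}

#' Richardson-Lucy deconvolution of a 3D stack
#'
#' Standard multiplicative iterations
#' `e <- e * conv(obs / conv(e, psf), psf_mirrored)`; nonnegativity is
#' preserved and total intensity is conserved (circular boundary).
#'
#' @param stack 3D array or [image_stack3d()] (nonnegative intensities).
#' @param psf 3D kernel normalized to unit sum.
#' @param iterations number of update rounds (>= 1).
#' @return deconvolved array of the same dimensions.
#' @export
richardson_lucy <- function(stack, psf, iterations = 10) {
  v <- as_voxels(stack)
  ss_check(all(v >= 0), "input intensities must be nonnegative")
  ss_check(is.array(psf) && length(dim(psf)) == 3, "`psf` must be a 3D array")
  ss_check(abs(sum(psf) - 1) < 1e-6, "`psf` must be normalized to unit sum")
  ss_check(iterations >= 1, "`iterations` must be >= 1")
  psf_m <- psf[rev(seq_len(dim(psf)[1])), rev(seq_len(dim(psf)[2])),
               rev(seq_len(dim(psf)[3])), drop = FALSE]
  dim(psf_m) <- dim(psf)
  eps <- .Machine$double.eps
  est <- v
  for (i in seq_len(iterations)) {
    blur <- pmax(fft_convolve(est, psf), 0)
    ratio <- v / (blur + eps)
    est <- est * pmax(fft_convolve(ratio, psf_m), 0)
  }
  pmax(est, 0)
}

# Sub-pixel 2D translation by bilinear interpolation, zero padding.
shift2d_subpix <- function(m, dy, dx) {
  iy <- floor(dy); ix <- floor(dx)
  fy <- dy - iy; fx <- dx - ix
  s <- function(a, oy, ox) {
    arr <- array(a, c(dim(a), 1))
    arr_shift(arr, c(oy, ox, 0), fill = 0)[, , 1]
  }
  (1 - fy) * (1 - fx) * s(m, iy, ix) +
    fy * (1 - fx) * s(m, iy + 1, ix) +
    (1 - fy) * fx * s(m, iy, ix + 1) +
    fy * fx * s(m, iy + 1, ix + 1)
}

# Lateral offset of slice b relative to slice a by FFT cross-correlation,
# peak restricted to +/- max_shift, refined to sub-pixel by local DFT
# upsampling of the correlation surface around the integer peak.
xcorr_shift <- function(a, b, max_shift = 10, upsample = 20) {
  dm <- dim(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  F <- stats::fft(b0) * Conj(stats::fft(a0))
  cc <- Re(stats::fft(F, inverse = TRUE)) / length(a0)
  lag <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  ly <- lag(seq_len(dm[1]), dm[1]); lx <- lag(seq_len(dm[2]), dm[2])
  ok <- outer(abs(ly) <= max_shift, abs(lx) <= max_shift)
  cc_ok <- cc; cc_ok[!ok] <- -Inf
  pk <- which(cc_ok == max(cc_ok), arr.ind = TRUE)[1, ]
  # quality: normalized cross-correlation at the peak, in [0, 1]
  qual <- max(cc_ok) / (sqrt(sum(a0^2) * sum(b0^2)) + .Machine$double.eps)
  # evaluate cc on a fine grid within +/- 1 px of the integer peak:
  # cc(u) = (1/N) sum_k F[k] exp(2 pi i (ky uy / ny + kx ux / nx))
  uy <- ly[pk[1]] + seq(-1, 1, by = 1 / upsample)
  ux <- lx[pk[2]] + seq(-1, 1, by = 1 / upsample)
  ey <- exp(2i * pi * outer(ly, uy) / dm[1])
  ex <- exp(2i * pi * outer(lx, ux) / dm[2])
  fine <- Re(t(ey) %*% F %*% ex) / length(a0)
  fpk <- which(fine == max(fine), arr.ind = TRUE)[1, ]
  list(shift = c(dy = uy[fpk[1]], dx = ux[fpk[2]]), quality = qual)
}

#' Align the slices of a stack along z
#'
#' Estimates the lateral offset of every slice relative to its predecessor
#' by cross-correlation, accumulates the offsets, and shifts each slice
#' back with sub-pixel bilinear interpolation. Slice pairs whose
#' correlation peak is weak (pure noise, empty slices) get zero shift and
#' are flagged low-confidence.
#'
#' @param stack 3D array or [image_stack3d()].
#' @param max_shift largest per-slice offset searched, pixels.
#' @param min_quality minimum normalized cross-correlation at the peak
#'   (in `[0, 1]`) to accept an estimated shift.
#' @return list: `stack` (aligned array), `shifts` (nz x 2 matrix of
#'   cumulative y/x shifts applied, slice 1 = 0), `low_confidence`
#'   (logical per slice).
#' @export
align_z <- function(stack, max_shift = 10, min_quality = 0.3) {
  v <- as_voxels(stack)
  nz <- dim(v)[3]
  ss_check(nz >= 2, "need at least 2 slices to align")
  rel <- matrix(0, nz, 2)
  lowc <- logical(nz)
  for (k in 2:nz) {
    a <- v[, , k - 1]; b <- v[, , k]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) { lowc[k] <- TRUE; next }
    est <- xcorr_shift(a, b, max_shift)
    if (est$quality < min_quality) { lowc[k] <- TRUE; next }
    rel[k, ] <- est$shift
  }
  cum <- apply(rel, 2, cumsum)
  out <- v
  for (k in 2:nz) {
    if (any(cum[k, ] != 0))
      out[, , k] <- shift2d_subpix(v[, , k], -cum[k, 1], -cum[k, 2])
  }
  list(stack = out, shifts = cum, low_confidence = lowc)
}

#' Gaussian denoising with a physical bandwidth
#'
#' @param stack 3D array or [image_stack3d()].
#' @param sigma_um isotropic physical smoothing scale (um); converted
#'   per-axis to voxels via `voxel_size`, so anisotropic voxels get an
#'   anisotropic kernel.
#' @param voxel_size um per voxel `(y, x, z)`.
#' @return smoothed array.
#' @export
denoise_stack <- function(stack, sigma_um, voxel_size) {
  v <- as_voxels(stack)
  ss_check(sigma_um >= 0, "sigma must be >= 0")
  if (sigma_um == 0) return(v)
  gauss3d(v, sigma_um / voxel_size)
}

#' Detect nucleus centers in 3D (scale-matched Laplacian of Gaussian)
#'
#' Bright-spot detection: the stack is smoothed at the blob-matched scale
#' `sigma = r_nucleus / sqrt(3)`, the negated spacing-aware Laplacian is
#' taken as the blob response, and 26-connected local maxima above
#' `threshold_rel` of the global maximum response are kept, greedily
#' enforcing a minimum center separation of 0.7 nucleus diameters.
#'
#' @param stack 3D array or [image_stack3d()].
#' @param voxel_size um per voxel `(y, x, z)`.
#' @param nucleus_diameter_um expected nucleus diameter (um).
#' @param threshold_rel relative response threshold in (0, 1].
#' @return data.frame of seed voxel coordinates `y, x, z` (1-based) with a
#'   `response` column, ordered by decreasing response.
#' @export
detect_spots3d <- function(stack, voxel_size, nucleus_diameter_um,
                           threshold_rel = 0.25) {
  v <- as_voxels(stack)
  ss_check(nucleus_diameter_um > 0, "nucleus diameter must be > 0")
  sig_um <- nucleus_diameter_um / 2 / sqrt(3)
  sm <- gauss3d(v, sig_um / voxel_size)
  resp <- -laplace3d(sm, voxel_size)
  # absolute noise floor: in a blob-free stack every local maximum is a
  # noise fluctuation, and a threshold relative to the global maximum
  # would promote them all to seeds
  noise_scale <- stats::mad(resp)
  resp[resp < 0] <- 0
  if (max(resp) <= 0) return(data.frame(y = integer(), x = integer(),
                                        z = integer(), response = numeric()))
  thr <- max(threshold_rel * max(resp), 6 * noise_scale)
  cand <- which(local_maxima3d(resp) & resp >= thr)
  if (length(cand) == 0) return(data.frame(y = integer(), x = integer(),
                                           z = integer(), response = numeric()))
  dm <- dim(v)
  idx <- arrayInd(cand, dm)
  ord <- order(resp[cand], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  rsp <- resp[cand][ord]
  pos_um <- sweep(idx, 2, voxel_size, `*`)
  min_sep <- 0.7 * nucleus_diameter_um
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- colSums((t(pos_um[keep, , drop = FALSE]) - pos_um[i, ])^2)
    if (min(d2) >= min_sep^2) keep[i] <- TRUE
  }
  data.frame(y = idx[keep, 1], x = idx[keep, 2], z = idx[keep, 3],
             response = rsp[keep])
}

#' Grow detected centers to nucleus regions (seeded 3D watershed)
#'
#' Seeds are flooded outward through descending smoothed intensity,
#' restricted to the foreground mask (Otsu threshold on the stack), so
#' touching nuclei split at the intensity valley between them.
#'
#' @param stack 3D array or [image_stack3d()].
#' @param seeds data.frame with voxel columns `y, x, z` (as from
#'   [detect_spots3d()]).
#' @param voxel_size um per voxel.
#' @param smooth_sigma_um pre-flood smoothing scale (um).
#' @return object of class `nuclei_segmentation`: `labels` (integer array,
#'   0 = background), `seeds`, `count`.
#' @export
grow_regions <- function(stack, seeds, voxel_size, smooth_sigma_um = 0.5) {
  v <- as_voxels(stack)
  ss_check(is.data.frame(seeds) && nrow(seeds) >= 1,
           "at least one seed is required")
  mask <- v > otsu_threshold(v)
  sm <- if (smooth_sigma_um > 0) gauss3d(v, smooth_sigma_um / voxel_size) else v
  seed_lab <- array(0L, dim(v))
  for (i in seq_len(nrow(seeds)))
    seed_lab[seeds$y[i], seeds$x[i], seeds$z[i]] <- i
  # a seed just outside the mask still claims its own voxel
  mask <- mask | seed_lab > 0L
  lab <- watershed_flood(sm, seed_lab, mask)
  relabel_segmentation(lab, seeds)
}

relabel_segmentation <- function(lab, seeds = NULL) {
  ids <- sort(unique(lab[lab > 0L]))
  out <- array(0L, dim(lab))
  out[lab > 0L] <- match(lab[lab > 0L], ids)
  structure(list(labels = out, seeds = seeds, count = length(ids)),
            class = "nuclei_segmentation")
}

# Bounding box of a label, padded, as index lists.
label_bbox <- function(lab, id, pad) {
  w <- which(lab == id)
  idx <- arrayInd(w, dim(lab))
  lapply(1:3, function(ax) {
    max(1, min(idx[, ax]) - pad[ax]):min(dim(lab)[ax], max(idx[, ax]) + pad[ax])
  })
}

#' Morphological smoothing of nucleus labels
#'
#' Opens then closes every label with a ball of physical radius
#' `radius_um` (converted per-axis to voxels, rounded, at least 1 voxel
#' when the radius is positive), removing spurs and pinholes. Labels are
#' processed independently so the label count never increases.
#'
#' @param seg a `nuclei_segmentation`.
#' @param voxel_size um per voxel.
#' @param radius_um ball radius (um); default 0.332.
#' @return smoothed `nuclei_segmentation`.
#' @export
smooth_labels <- function(seg, voxel_size, radius_um = 0.332) {
  ss_check(radius_um >= 0, "radius must be >= 0")
  if (radius_um == 0) return(seg)
  lab <- seg$labels
  r_vox <- pmax(round(radius_um / voxel_size), 1)
  off <- ball_offsets(r_vox)
  out <- array(0L, dim(lab))
  for (id in seq_len(max(lab, 0L))) {
    if (!any(lab == id)) next
    bb <- label_bbox(lab, id, pad = 2 * r_vox)
    sub <- lab[bb[[1]], bb[[2]], bb[[3]], drop = FALSE] == id
    dim(sub) <- lengths(bb)
    opened <- dilate_mask(erode_mask(sub, off), off)
    closed <- erode_mask(dilate_mask(opened, off), off)
    tgt <- out[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
    dim(tgt) <- lengths(bb)
    tgt[closed & tgt == 0L] <- id
    out[bb[[1]], bb[[2]], bb[[3]]] <- tgt
  }
  relabel_segmentation(out, seg$seeds)
}

#' Split fused labels by repeated erosion
#'
#' Each label is eroded `erosion_count` times (6-neighborhood); if the
#' eroded core falls apart into several connected components, every
#' component is grown back within the original label footprint and becomes
#' its own label. A label whose core stays connected (or erodes away
#' entirely) is left unchanged.
#'
#' @param seg a `nuclei_segmentation`.
#' @param erosion_count number of erosion passes (>= 0); 0 is the identity.
#' @param min_core_vox eroded components smaller than this many voxels are
#'   treated as noise specks, not separate cores (default 4).
#' @return `nuclei_segmentation` with possibly more labels.
#' @export
separate_objects <- function(seg, erosion_count = 2, min_core_vox = 4) {
  ss_check(erosion_count >= 0, "erosion_count must be >= 0")
  if (erosion_count == 0) return(seg)
  lab <- seg$labels
  out <- array(0L, dim(lab))
  nxt <- 1L
  for (id in seq_len(max(lab, 0L))) {
    if (!any(lab == id)) next
    bb <- label_bbox(lab, id, pad = c(1, 1, 1))
    sub <- lab[bb[[1]], bb[[2]], bb[[3]], drop = FALSE] == id
    dim(sub) <- lengths(bb)
    core <- sub
    for (i in seq_len(erosion_count)) core <- erode_mask(core, NEIGH6)
    comps <- if (any(core)) cc3d(core) else array(0L, dim(core))
    if (max(comps) > 1) {
      sizes <- tabulate(comps[comps > 0L], nbins = max(comps))
      keep <- which(sizes >= min_core_vox)
      comps[!(comps %in% keep)] <- 0L
      if (length(keep))
        comps[comps > 0L] <- match(comps[comps > 0L], keep)
    }
    ncomp <- max(comps)
    if (ncomp <= 1) {
      pieces <- array(0L, dim(sub)); pieces[sub] <- 1L
      ncomp <- 1L
    } else {
      pieces <- geodesic_fill(comps, sub)
      pieces[sub & pieces == 0L] <- 1L  # unreachable remainder -> first piece
    }
    tgt <- out[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
    dim(tgt) <- lengths(bb)
    sel <- pieces > 0L & tgt == 0L
    tgt[sel] <- nxt - 1L + pieces[sel]
    out[bb[[1]], bb[[2]], bb[[3]]] <- tgt
    nxt <- nxt + ncomp
  }
  relabel_segmentation(out, seg$seeds)
}

#' Count nuclei above a debris volume floor
#'
#' @param seg a `nuclei_segmentation`.
#' @param voxel_size um per voxel.
#' @param min_volume_um3 smallest label volume counted as a nucleus
#'   (default 5 um^3, a conservative debris floor).
#' @return integer count.
#' @export
count_nuclei <- function(seg, voxel_size, min_volume_um3 = 5) {
  lab <- seg$labels
  if (max(lab) == 0L) return(0L)
  voxvol <- prod(voxel_size)
  vols <- tabulate(lab[lab > 0L], nbins = max(lab)) * voxvol
  sum(vols >= min_volume_um3)
}

#' Whole-spheroid foreground mask of a stack
#'
#' Strong Gaussian smoothing (so individual nuclei blur into the spheroid
#' body), Otsu threshold, largest 6-connected component, morphological
#' closing.
#'
#' @param stack 3D array or [image_stack3d()].
#' @param voxel_size um per voxel.
#' @param smooth_sigma_um smoothing scale before thresholding (um).
#' @return logical 3D array.
#' @export
spheroid_mask <- function(stack, voxel_size, smooth_sigma_um = 1.5) {
  v <- as_voxels(stack)
  sm <- if (smooth_sigma_um > 0) gauss3d(v, smooth_sigma_um / voxel_size) else v
  mask <- sm > otsu_threshold(sm)
  if (!any(mask)) return(mask)
  # refine to a half-maximum boundary: Otsu can land between the dim body
  # and the bright nuclei; the midpoint of the modal inside and outside
  # intensities puts the surface where the smoothed profile crosses 50%
  thr <- (modal_value(sm[mask]) + modal_value(sm[!mask])) / 2
  mask <- sm > thr
  if (!any(mask)) return(mask)
  lab <- cc3d(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  biggest <- lab == which.max(sizes)
  off <- ball_offsets(pmax(round(2 / voxel_size), 1))  # ~2 um closing ball
  erode_mask(dilate_mask(biggest, off), off)
}

#' Spheroid volume from a 3D mask or an equivalent-sphere diameter
#'
#' @param stack 3D array or [image_stack3d()] (for `method = "mask"`
#'   when no `mask` is given).
#' @param voxel_size um per voxel.
#' @param method `"mask"` (voxel count x voxel volume of the whole-spheroid
#'   mask) or `"equivalent_sphere"` (`pi/6 d^3`).
#' @param diameter_um diameter for the equivalent-sphere method.
#' @param mask optional precomputed logical mask.
#' @return volume in um^3.
#' @export
spheroid_volume <- function(stack = NULL, voxel_size = NULL,
                            method = c("mask", "equivalent_sphere"),
                            diameter_um = NULL, mask = NULL) {
  method <- match.arg(method)
  if (method == "equivalent_sphere") {
    ss_check(!is.null(diameter_um) && diameter_um > 0,
             "`diameter_um` is required for the equivalent-sphere method")
    return(pi / 6 * diameter_um^3)
  }
  if (is.null(mask)) {
    ss_check(!is.null(stack), "supply a stack or a mask")
    mask <- spheroid_mask(stack, voxel_size)
  }
  n <- sum(mask)
  ss_check(n > 0, "empty spheroid mask", "spherosed_pipeline_error")
  n * prod(voxel_size)
}

#' Volumetric nuclear density
#'
#' @param count nuclei count. @param volume spheroid volume (um^3).
#' @return nuclei per um^3.
#' @export
nuclei_density <- function(count, volume) {
  ss_check(is.numeric(volume) && volume > 0, "volume must be > 0")
  count / volume
}

#' Bright-field optical density of a spheroid
#'
#' The spheroid is segmented as the largest dark connected component
#' (Otsu); per-pixel absorbance is `A = -log10(I / I_bg)` with `I_bg` the
#' modal background intensity; the optical density is the modal absorbance
#' inside the mask divided by the mask area in um^2.
#'
#' @param brightfield 2D intensity matrix.
#' @param pixel_size um per pixel.
#' @return list: `od` (per um^2), `area_um2`, `modal_absorbance`.
#' @export
optical_density <- function(brightfield, pixel_size) {
  ss_check(is.matrix(brightfield), "`brightfield` must be a 2D matrix")
  v <- brightfield
  if (min(v) == max(v))
    ss_stop("no spheroid detectable in a uniform image", "spherosed_no_spheroid")
  thr <- otsu_threshold(v)
  mask <- v < thr
  if (!any(mask))
    ss_stop("no dark component found", "spherosed_no_spheroid")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  mask <- lab == which.max(sizes)
  if (sum(mask) < 20)
    ss_stop("largest dark component is below the minimum area",
            "spherosed_no_spheroid")
  i_bg <- modal_value(v[!mask])
  eps <- .Machine$double.eps
  absorb <- -log10(pmax(v, eps) / max(i_bg, eps))
  a_mode <- modal_value(absorb[mask])
  area <- sum(mask) * pixel_size^2
  list(od = a_mode / area, area_um2 = area, modal_absorbance = a_mode)
}

#' Full 3D nuclei quantification of a cleared spheroid
#'
#' Runs the chain denoise -> z-align -> (optional Richardson-Lucy) ->
#' bright-spot detection -> seeded region growing -> label smoothing ->
#' erosion-based separation -> counting, plus spheroid volume from the
#' 3D mask, volumetric nuclear density, and bright-field optical density
#' when a bright-field image is supplied.
#'
#' @param nuclear nuclear-channel stack ([image_stack3d()] or 3D array).
#' @param voxel_size um per voxel (taken from the stack object if absent).
#' @param brightfield optional 2D bright-field matrix.
#' @param params list of tunables: `nucleus_diameter_um` (4),
#'   `threshold_rel` (0.25), `denoise_sigma_um` (0.3), `align` (TRUE),
#'   `deconvolve` (FALSE), `rl_iterations` (8), `smooth_radius_um` (0.332),
#'   `erosion_count` (2), `min_volume_um3` (5), `volume_method` ("mask").
#' @return object of class `nuclei_quantification`: `count`, `volume`
#'   (um^3), `density` (um^-3), `optical_density` (um^-2 or `NA`), plus the
#'   intermediate `segmentation` and `seeds`.
#' @export
quantify_nuclei <- function(nuclear, voxel_size = NULL, brightfield = NULL,
                            params = list()) {
  if (inherits(nuclear, "image_stack3d") && is.null(voxel_size))
    voxel_size <- nuclear$voxel_size
  ss_check(!is.null(voxel_size), "voxel_size is required")
  p <- utils::modifyList(list(
    nucleus_diameter_um = 4, threshold_rel = 0.25, denoise_sigma_um = 0.3,
    align = TRUE, deconvolve = FALSE, rl_iterations = 8,
    smooth_radius_um = 0.332, erosion_count = 2, min_core_vox = 4,
    min_volume_um3 = 5,
    volume_method = "mask", brightfield_pixel_size = NULL), params)
  v <- as_voxels(nuclear)
  v <- denoise_stack(v, p$denoise_sigma_um, voxel_size)
  if (isTRUE(p$align)) v <- align_z(v)$stack
  if (isTRUE(p$deconvolve))
    v <- richardson_lucy(pmax(v, 0), gaussian_psf(voxel_size),
                         iterations = p$rl_iterations)
  seeds <- detect_spots3d(v, voxel_size, p$nucleus_diameter_um,
                          p$threshold_rel)
  count <- 0L
  seg <- NULL
  if (nrow(seeds) > 0) {
    seg <- grow_regions(v, seeds, voxel_size)
    seg <- smooth_labels(seg, voxel_size, p$smooth_radius_um)
    seg <- separate_objects(seg, p$erosion_count, p$min_core_vox)
    count <- count_nuclei(seg, voxel_size, p$min_volume_um3)
  }
  volume <- spheroid_volume(v, voxel_size, method = "mask")
  od <- NA_real_
  if (!is.null(brightfield)) {
    px <- p$brightfield_pixel_size
    if (is.null(px)) px <- voxel_size[["x"]]
    od <- optical_density(brightfield, px)$od
  }
  structure(list(count = count, volume = volume,
                 density = nuclei_density(count, volume),
                 optical_density = od, segmentation = seg, seeds = seeds),
            class = "nuclei_quantification")
}

#' @export
print.nuclei_quantification <- function(x, ...) {
  cat("Cleared-spheroid nuclei quantification\n")
  cat(sprintf("  nuclei count:      %d\n", x$count))
  cat(sprintf("  spheroid volume:   %.4g um^3\n", x$volume))
  cat(sprintf("  nuclear density:   %.4g um^-3\n", x$density))
  if (!is.na(x$optical_density))
    cat(sprintf("  optical density:   %.4g um^-2\n", x$optical_density))
  invisible(x)
}
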