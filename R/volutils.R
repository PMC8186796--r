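# Vectorized 3D array primitives for the nuclei pipeline.
#
# Stacks are arrays dim c(ny, nx, nz), i.e. [y, x, z]; voxel sizes travel as
# named vectors c(y=, x=, z=) in micrometers. All neighborhood operations use
# integer shifts of whole arrays, so they stay vectorized in R; iterative
# propagation (connected components, watershed flooding, geodesic fill)
# converges in O(object diameter) sweeps, which is cheap for blob-like
# objects such as nuclei and spheroid masks.

# Shift a 3D array by integer offsets (dy, dx, dz), padding with `fill`.
arr_shift <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    if (d[i] >= 0) {
      if (d[i] >= dm[i]) return(out)
      src[[i]] <- seq_len(dm[i] - d[i])
      dst[[i]] <- seq_len(dm[i] - d[i]) + d[i]
    } else {
      if (-d[i] >= dm[i]) return(out)
      src[[i]] <- seq_len(dm[i] + d[i]) - d[i]
      dst[[i]] <- seq_len(dm[i] + d[i])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

NEIGH6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

# Offsets of a (possibly anisotropic) ellipsoidal ball with semi-axes
# `r_vox = c(y, x, z)` in voxels. Always contains the origin.
ball_offsets <- function(r_vox) {
  r <- pmax(r_vox, 0)
  ri <- floor(r)
  g <- expand.grid(dy = -ri[1]:ri[1], dx = -ri[2]:ri[2], dz = -ri[3]:ri[3])
  keep <- (g$dy / max(r[1], .5))^2 + (g$dx / max(r[2], .5))^2 +
    (g$dz / max(r[3], .5))^2 <= 1 + 1e-9
  g <- g[keep, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) c(g$dy[i], g$dx[i], g$dz[i]))
}

erode_mask <- function(mask, offsets) {
  out <- mask
  for (d in offsets) {
    if (all(d == 0)) next
    out <- out & arr_shift(mask, d, fill = FALSE)
  }
  out
}

dilate_mask <- function(mask, offsets) {
  out <- mask
  for (d in offsets) {
    if (all(d == 0)) next
    out <- out | arr_shift(mask, d, fill = FALSE)
  }
  out
}

# 6-connected components of a logical 3D array. Returns an integer array
# (0 = background) with labels 1..n in order of first (column-major) voxel.
cc3d <- function(mask) {
  dm <- dim(mask)
  lab <- array(Inf, dm)
  lab[mask] <- which(mask)
  repeat {
    new <- lab
    for (d in NEIGH6) {
      sh <- arr_shift(lab, d, fill = Inf)
      new <- pmin(new, sh)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, dm)
  vals <- lab[mask]
  out[mask] <- as.integer(factor(vals, levels = unique(sort(vals))))
  out
}

# Seeded watershed by descending-intensity level flooding: labels grow from
# seeds into `mask`, brightest voxels first, so touching blobs split at the
# intensity valley between them. 6-connectivity; deterministic tie-breaking
# by fixed neighbor order.
watershed_flood <- function(intensity, seed_lab, mask, n_levels = 64L) {
  dm <- dim(intensity)
  lab <- seed_lab
  lab[!mask] <- 0L
  vals <- intensity[mask & lab == 0L]
  if (length(vals) == 0) return(lab)
  thresholds <- rev(seq(min(vals), max(vals), length.out = n_levels))
  for (thr in thresholds) {
    active <- mask & intensity >= thr
    repeat {
      frontier <- active & lab == 0L
      if (!any(frontier)) break
      assigned <- FALSE
      newlab <- lab
      for (d in NEIGH6) {
        sh <- arr_shift(lab, d, fill = 0L)
        take <- frontier & newlab == 0L & sh > 0L
        if (any(take)) { newlab[take] <- sh[take]; assigned <- TRUE }
      }
      if (!assigned) break
      lab <- newlab
    }
  }
  lab
}

# Propagate existing labels to every voxel of `footprint` by geodesic
# dilation (approximate nearest-core assignment); used to re-grow split
# label cores back to the original object footprint.
geodesic_fill <- function(lab, footprint) {
  lab[!footprint] <- 0L
  repeat {
    frontier <- footprint & lab == 0L
    if (!any(frontier)) break
    newlab <- lab
    assigned <- FALSE
    for (d in NEIGH6) {
      sh <- arr_shift(lab, d, fill = 0L)
      take <- frontier & newlab == 0L & sh > 0L
      if (any(take)) { newlab[take] <- sh[take]; assigned <- TRUE }
    }
    if (!assigned) break   # disconnected remainder: leave unlabeled
    lab <- newlab
  }
  lab
}

# --- FFT filtering -------------------------------------------------------

# Circular 3D convolution with a separable Gaussian of per-axis sigma (in
# voxels). Implemented as a product of 1D frequency responses of sampled
# Gaussian kernels, so total mass is exactly preserved.
gauss3d <- function(a, sigma_vox) {
  dm <- dim(a)
  fa <- stats::fft(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dm[ax]
    half <- floor(min(n / 2, max(1, ceiling(4 * s))))
    k1 <- stats::dnorm(-half:half, sd = s)
    k1 <- k1 / sum(k1)
    kv <- numeric(n)
    idx <- ((-half:half) %% n) + 1
    for (j in seq_along(k1)) kv[idx[j]] <- kv[idx[j]] + k1[j]
    fk <- stats::fft(kv)
    shape <- c(1, 1, 1); shape[ax] <- n
    fa <- fa * array(rep(fk, each = prod(dm[seq_len(ax - 1)])),
                     dm)[seq_len(prod(dm))]
    dim(fa) <- dm
  }
  Re(stats::fft(fa, inverse = TRUE)) / prod(dm)
}

# Circular convolution of a stack with an arbitrary kernel whose center is
# at floor(dim/2)+1 (fftshift convention).
fft_convolve <- function(a, kernel) {
  dm <- dim(a)
  kd <- dim(kernel)
  ss_check(all(kd <= dm), "kernel must not exceed the stack size")
  pk <- array(0, dm)
  pk[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kernel
  ctr <- floor(kd / 2)
  for (ax in 1:3) {
    perm <- seq_len(dm[ax])
    shifted <- ((perm - 1 + ctr[ax]) %% dm[ax]) + 1
    idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    idx[[ax]] <- shifted
    pk <- pk[idx[[1]], idx[[2]], idx[[3]]]
    dim(pk) <- dm
  }
  Re(stats::fft(stats::fft(a) * stats::fft(pk), inverse = TRUE)) / prod(dm)
}

# Spacing-aware 7-point discrete Laplacian (units: intensity / um^2).
laplace3d <- function(a, voxel_size) {
  out <- array(0, dim(a))
  for (ax in 1:3) {
    d <- c(0, 0, 0); d[ax] <- 1
    h2 <- voxel_size[ax]^2
    # replicate edge values so the Laplacian vanishes on flat regions at
    # the boundary instead of spiking
    fwd <- arr_shift(a, d, fill = 0); bwd <- arr_shift(a, -d, fill = 0)
    edge_f <- arr_shift(array(1, dim(a)), d, fill = 0) == 0
    edge_b <- arr_shift(array(1, dim(a)), -d, fill = 0) == 0
    fwd[edge_f] <- a[edge_f]; bwd[edge_b] <- a[edge_b]
    out <- out + (fwd + bwd - 2 * a) / h2
  }
  out
}

# Logical array of 26-connected local maxima (strictly >= all neighbors,
# > at least one).
local_maxima3d <- function(a) {
  ge_all <- array(TRUE, dim(a))
  gt_any <- array(FALSE, dim(a))
  for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    sh <- arr_shift(a, c(dy, dx, dz), fill = -Inf)
    ge_all <- ge_all & (a >= sh)
    gt_any <- gt_any | (a > sh)
  }
  ge_all & gt_any
}
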