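#' Gridding reconstruction configuration
#'
#' @param kernel_width Kaiser-Bessel kernel width in grid cells.
#' @param oversampling Grid oversampling factor.
#' @param dcf Density compensation: `"pipe"` (iterative Pipe-Menon, default)
#'   or `"radial"` (analytic `|k| * d|k|` weights).
#' @param dcf_iterations Iterations for the Pipe-Menon scheme.
#' @return An object of class `gridding_config`.
#' @export
gridding_config <- function(kernel_width = 4, oversampling = 1.5,
                            dcf = c("pipe", "radial"), dcf_iterations = 25) {
  assert_that(oversampling >= 1, "oversampling must be >= 1")
  assert_that(kernel_width >= 2, "kernel_width must be >= 2")
  structure(list(kernel_width = kernel_width, oversampling = oversampling,
                 dcf = match.arg(dcf), dcf_iterations = dcf_iterations),
            class = "gridding_config")
}

# Kaiser-Bessel kernel (unnormalized), u in grid cells, |u| <= W/2.
kb_beta <- function(width, os) {
  pi * sqrt(width^2 / os^2 * (os - 0.5)^2 - 0.8)   # Beatty et al. choice
}

kb_kernel <- function(u, width, beta) {
  t <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- t > 0
  out[ok] <- besselI(beta * sqrt(t[ok]), 0)
  out
}

# Fourier transform of the KB kernel at image position fraction q = x/N_os
# (1D, same normalization as kb_kernel integrated over grid cells).
kb_kernel_ft <- function(q, width, beta) {
  arg2 <- (pi * width * q)^2 - beta^2
  out <- ifelse(arg2 > 0, sin(sqrt(pmax(arg2, 0))) / sqrt(pmax(arg2, 1e-300)),
                sinh(sqrt(pmax(-arg2, 0))) / sqrt(pmax(-arg2, 1e-300)))
  out * width
}

# Sparse gridding (convolution interpolation) operator for a set of 2D
# k-space points, in grid-cell units. Returns a dgCMatrix mapping sample
# values to the oversampled grid (N_os^2 x n_points).
gridding_operator <- function(kx, ky, dk_grid, n_os, width, beta) {
  u <- kx / dk_grid + n_os / 2    # 0-based fractional grid coords
  v <- ky / dk_grid + n_os / 2
  hw <- width / 2
  offs <- seq(-ceiling(hw), ceiling(hw))
  no <- length(offs)
  n_pts <- length(u)
  iu <- floor(u); iv <- floor(v)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (du in offs) for (dv in offs) {
    gu <- iu + du; gv <- iv + dv
    wu <- kb_kernel(gu - u, width, beta)
    wv <- kb_kernel(gv - v, width, beta)
    w <- wu * wv
    keep <- w > 0 & gu >= 0 & gu < n_os & gv >= 0 & gv < n_os
    if (!any(keep)) next
    rows <- c(rows, gu[keep] + n_os * gv[keep] + 1)
    cols <- c(cols, which(keep))
    vals <- c(vals, w[keep])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(n_os^2, n_pts))
}

# Density compensation for the combined interleaf set (2D points).
# "radial": w = |k| * d|k| along the readout (annulus area elements),
# normalized per interleaf; "pipe": Pipe-Menon iteration w <- w / (C C^T w)
# using the gridding kernel, then scaled to physical k-space area elements
# via the kernel's area integral.
compute_dcf <- function(traj, config, A = NULL, dk_grid = NULL) {
  k2 <- rbind_interleaves(traj)
  r <- sqrt(k2[, 1]^2 + k2[, 2]^2)
  n_int <- dim(traj$k)[3]; n_samp <- traj$n_samples
  rbase <- sqrt(traj$k[, 1, 1]^2 + traj$k[, 2, 1]^2)
  dr <- c(diff(rbase), 0)
  dr[length(dr)] <- dr[length(dr) - 1]
  w0 <- pmax(rbase * dr, 0)
  # center sample: disk of radius dr/2
  w0[1] <- (dr[1] / 2)^2 / 2
  w0 <- w0 * 2 * pi / n_int            # annulus share of one interleaf
  w <- rep(w0, n_int)
  if (config$dcf == "pipe") {
    beta <- kb_beta(config$kernel_width, config$oversampling)
    for (it in seq_len(config$dcf_iterations)) {
      dens <- as.numeric(Matrix::crossprod(A, A %*% w))
      w <- w / pmax(dens, 1e-12)
    }
    # the iteration uses grid-then-degrid (kernel autocorrelation), so the
    # converged weights are area elements divided by dk^2 * (int ker)^4 in
    # 2D; rescale back to physical k-space area elements
    uu <- seq(-config$kernel_width / 2, config$kernel_width / 2, length.out = 513)
    k1 <- kb_kernel(uu, config$kernel_width, beta)
    w <- w * (sum(k1) * diff(uu)[1])^4 * dk_grid^2
  }
  w
}

rbind_interleaves <- function(traj) {
  n_int <- dim(traj$k)[3]
  do.call(rbind, lapply(seq_len(n_int), function(m) traj$k[, , m]))
}

# Centered 2D inverse DFT on the oversampled grid with the half-voxel image
# offset handled by pre-multiplying sample phases; returns the cropped
# central n x n image. G is the gridded k-space (n_os x n_os), already
# containing the fftshift-convention data (k index g - n_os/2).
grid_ifft_crop <- function(G, n, n_os) {
  # move k = (g - n_os/2) to FFT order, transform, move image back
  G <- G[c((n_os / 2 + 1):n_os, 1:(n_os / 2)),
         c((n_os / 2 + 1):n_os, 1:(n_os / 2))]
  img <- stats::fft(G, inverse = TRUE)
  img <- img[c((n_os / 2 + 1):n_os, 1:(n_os / 2)),
             c((n_os / 2 + 1):n_os, 1:(n_os / 2))]
  off <- (n_os - n) / 2
  img[(off + 1):(off + n), (off + 1):(off + n)]
}

#' Gridding reconstruction of binned spiral k-space
#'
#' Standard convolution gridding per cardiac frame and flow segment:
#' density compensation, Kaiser-Bessel convolution onto an oversampled
#' Cartesian grid, inverse FFT in-plane, deapodization by the kernel
#' transform, explicit inverse DFT along the slice encodes, and cropping of
#' the slice-oversampled region. For a `cartesian_trajectory` the
#' reconstruction reduces to the exact inverse DFT.
#'
#' @param binned A `binned_kspace` from [bin_samples()], or for single-frame
#'   use a complex array shaped like its `k` element (with the trajectory
#'   passed separately).
#' @param traj The trajectory that produced the samples (defaults to the one
#'   stored in `binned`).
#' @param config A [gridding_config()].
#' @return An object of class `segment_images`: complex array
#'   `[nx, ny, n_slices, 4, n_frames]` plus geometry metadata.
#' @export
grid_reconstruct <- function(binned, traj = NULL, config = gridding_config()) {
  stopifnot(inherits(binned, "binned_kspace"))
  traj <- traj %||% binned$trajectory
  if (!is.null(traj$params) && dim(binned$k)[1] != traj$n_samples)
    stop_ctx("trajectory does not match the sample layout",
             class = "spiral4d_traj_mismatch")
  params <- traj$params
  n <- params$matrix; vox <- params$voxel
  n_sl <- params$n_slices_recon; n_kz <- traj$n_kz
  n_int <- dim(traj$k)[3]
  nf <- binned$n_frames
  n_os <- 2 * ceiling(config$oversampling * n / 2)
  dk_grid <- 1 / (n_os * vox)
  beta <- kb_beta(config$kernel_width, config$oversampling)
  k2 <- rbind_interleaves(traj)
  A <- gridding_operator(k2[, 1], k2[, 2], dk_grid, n_os,
                         config$kernel_width, beta)
  w <- compute_dcf(traj, config, A = A, dk_grid = dk_grid)
  # half-voxel image offset folded into the sample phases: the shifted data
  # correspond to an object on the integer-centered grid
  shift2 <- exp(2i * pi * (k2[, 1] + k2[, 2]) * vox / 2)
  qx <- ((seq_len(n) - 1) - n / 2) / n_os
  deap <- kb_kernel_ft(qx, config$kernel_width, beta)
  deap2 <- outer(deap, deap)
  scale <- vox^2                          # k-space area elements -> voxel values
  # slice direction: exact inverse DFT with half-voxel offset, crop to n_sl
  zoff <- (n_kz - n_sl) / 2
  zs <- axis_coords(n_kz, params$slice_thickness)[(zoff + 1):(zoff + n_sl)]
  Wz <- exp(2i * pi * (traj$kz %o% zs)) / n_kz        # n_kz x n_sl inverse
  out <- array(complex(real = 0), dim = c(n, n, n_sl, 4, nf))
  for (f in seq_len(nf)) for (sg in 1:4) {
    hybrid <- array(complex(real = 0), dim = c(n, n, n_kz))
    for (kz in seq_len(n_kz)) {
      s <- w * shift2 * as.vector(binned$k[, , kz, sg, f])
      gs <- as.numeric(A %*% Re(s)) + 1i * as.numeric(A %*% Im(s))
      G <- matrix(gs, n_os, n_os)
      img <- grid_ifft_crop(G, n, n_os)
      hybrid[, , kz] <- img * scale / deap2
    }
    dim(hybrid) <- c(n * n, n_kz)
    out[, , , sg, f] <- array(hybrid %*% Wz, dim = c(n, n, n_sl))
  }
  structure(list(images = out, voxel_size = c(vox, vox, params$slice_thickness),
                 frame_duration = binned$frame_duration,
                 venc = binned$venc %||% params$venc, params = params),
            class = "segment_images")
}

#' Exact Cartesian reconstruction (inverse DFT)
#'
#' Reference reconstruction for fully sampled Cartesian data: exact inverse
#' DFT in-plane and along slice encodes, with the same voxel-center
#' convention and slice-oversampling crop as the gridding path.
#'
#' @param kdata Complex array `[n, n_lines, n_kz, ...]` of Cartesian samples
#'   (trailing dimensions preserved).
#' @param traj A [cartesian_trajectory()].
#' @return Complex array with in-plane/slice dims replaced by image dims.
#' @export
cartesian_reconstruct <- function(kdata, traj) {
  stopifnot(inherits(traj, "cartesian_trajectory"))
  params <- traj$params
  n <- params$matrix; vox <- params$voxel
  n_sl <- params$n_slices_recon; n_kz <- traj$n_kz
  d <- dim(kdata)
  stopifnot(d[1] == n, d[2] == n, d[3] == n_kz)
  rest <- if (length(d) > 3) prod(d[-(1:3)]) else 1
  dim(kdata) <- c(n, n, n_kz, rest)
  xs <- axis_coords(n, vox)
  idx <- seq_len(n) - 1 - floor(n / 2)
  kx <- idx / params$fov
  # put lines back in frequency order
  line_pos <- match(idx, traj$order)
  Wx <- exp(2i * pi * (xs %o% kx)) / n
  zoff <- (n_kz - n_sl) / 2
  zs <- axis_coords(n_kz, params$slice_thickness)[(zoff + 1):(zoff + n_sl)]
  Wz <- exp(2i * pi * (traj$kz %o% zs)) / n_kz
  out <- array(complex(real = 0), dim = c(n, n, n_sl, rest))
  for (r in seq_len(rest)) {
    vol <- kdata[, line_pos, , r, drop = FALSE]
    dim(vol) <- c(n, n, n_kz)
    hybrid <- array(complex(real = 0), dim = c(n, n, n_kz))
    for (kz in seq_len(n_kz))
      hybrid[, , kz] <- Wx %*% vol[, , kz] %*% t(Wx)
    dim(hybrid) <- c(n * n, n_kz)
    out[, , , r] <- array(hybrid %*% Wz, dim = c(n, n, n_sl))
  }
  dim(out) <- c(n, n, n_sl, if (length(d) > 3) d[-(1:3)] else NULL)
  out
}

#' Convert segment images to velocity maps
#'
#' Four-point phase-difference processing: per voxel and frame,
#' `v_d = venc * arg(S_d * conj(S_ref)) / pi` for each encoded direction,
#' with the reference segment's modulus as the magnitude image. Velocities
#' beyond venc wrap (no unwrapping is attempted).
#'
#' @param segments A `segment_images` object from [grid_reconstruct()], or a
#'   complex array `[nx, ny, nz, 4, n_frames]`.
#' @param venc Velocity encoding, cm/s (taken from the object if present).
#' @param voxel_size,frame_duration Geometry metadata when a bare array is
#'   given.
#' @return A [velocity_series()].
#' @export
phase_difference_velocity <- function(segments, venc = NULL,
                                      voxel_size = NULL,
                                      frame_duration = NULL) {
  if (inherits(segments, "segment_images")) {
    venc <- venc %||% segments$venc
    voxel_size <- voxel_size %||% segments$voxel_size
    frame_duration <- frame_duration %||% segments$frame_duration
    segments <- segments$images
  }
  d <- dim(segments)
  assert_that(length(d) == 5 && d[4] == 4,
              "segment images must be [x, y, z, 4, frames]")
  venc_m <- venc / 100
  nf <- d[5]
  magnitude <- array(0, dim = d[c(1:3, 5)])
  v <- array(0, dim = c(d[1:3], nf, 3))
  for (f in seq_len(nf)) {
    ref <- segments[, , , 1, f]
    magnitude[, , , f] <- Mod(ref)
    for (ci in 1:3)
      v[, , , f, ci] <- venc_m * Arg(segments[, , , ci + 1, f] * Conj(ref)) / pi
  }
  velocity_series(magnitude, v, voxel_size, frame_duration, venc)
}

#' Signal-to-noise ratio map and ROI statistics
#'
#' SNR map as magnitude divided by the standard deviation of a signal-free
#' noise image.
#'
#' @param magnitude 3D magnitude volume.
#' @param noise 3D volume from a signal-free acquisition (same units).
#' @param roi Logical 3D array selecting the region of interest.
#' @return List with `mean`, `sd` of SNR over the ROI, the noise `sigma`,
#'   and the full SNR `map`.
#' @export
compute_snr <- function(magnitude, noise, roi) {
  sigma <- stats::sd(as.numeric(noise))
  if (!is.finite(sigma) || sigma <= 0)
    stop_ctx("noise volume has zero variance", class = "spiral4d_zero_noise")
  map <- magnitude / sigma
  vals <- map[as.logical(roi)]
  list(mean = mean(vals), sd = stats::sd(vals), sigma = sigma, map = map)
}
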