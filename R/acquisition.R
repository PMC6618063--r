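#' Navigator respiratory-gating configuration
#'
#' Readouts are accepted only when the tracked diaphragm position lies
#' inside an acceptance window: a tight window for the central fraction of
#' slice encodes (by |kz| rank) and a wider one for the k-space periphery.
#'
#' @param inner_window Full width of the acceptance window for central
#'   slice encodes, mm.
#' @param outer_window Full width for peripheral slice encodes, mm.
#' @param central_fraction Fraction of slice encodes (smallest |kz|) that
#'   use the inner window.
#' @return An object of class `navigator_config`.
#' @export
navigator_config <- function(inner_window = 4, outer_window = 7,
                             central_fraction = 0.25) {
  assert_that(inner_window <= outer_window, "inner window must be <= outer")
  assert_that(central_fraction > 0 && central_fraction <= 1,
              "central_fraction must be in (0, 1]")
  assert_that(inner_window > 0, "windows must be positive")
  structure(list(inner_window = inner_window, outer_window = outer_window,
                 central_fraction = central_fraction),
            class = "navigator_config")
}

#' Navigator accept/reject decision
#'
#' @param position Navigator (diaphragm) position, mm, relative to the
#'   window center. Vectorized.
#' @param slice_encode Slice-encode index (1-based).
#' @param nav A [navigator_config()].
#' @param n_slice_encodes Total number of slice encodes.
#' @return Logical: accepted.
#' @export
navigator_accept <- function(position, slice_encode, nav, n_slice_encodes) {
  central <- central_slice_encodes(n_slice_encodes, nav$central_fraction)
  window <- ifelse(slice_encode %in% central, nav$inner_window,
                   nav$outer_window)
  abs(position) <= window / 2
}

# slice-encode indices whose |kz| rank puts them in the central fraction
central_slice_encodes <- function(n_kz, fraction) {
  kz_order <- order(abs(seq_len(n_kz) - 1 - floor(n_kz / 2)))
  n_central <- max(1, round(fraction * n_kz))
  sort(kz_order[seq_len(n_central)])
}

#' Sinusoidal respiratory trace
#'
#' @param amplitude Peak displacement, mm.
#' @param period Breathing period, ms.
#' @param phase Phase offset, rad.
#' @return A function of absolute time (ms) returning position (mm).
#' @export
respiratory_trace <- function(amplitude = 5, period = 4000, phase = 0) {
  force(amplitude); force(period); force(phase)
  function(t) amplitude * sin(2 * pi * t / period + phase)
}

#' Simulate a velocity-encoded stack-of-spirals acquisition
#'
#' Samples the analytic phantom's k-space along the designed trajectory over
#' many cardiac cycles. Per slice encode, all interleaves are acquired
#' before the next slice encode; one k-space line occupies a full beat, with
#' heart-phase slots advancing every `n_flow_segments * TR` and the four
#' flow segments (reference, x, y, z encoding) acquired in succession within
#' each slot. The signal of a readout is the non-uniform DFT, at the
#' trajectory coordinates, of the complex image
#' `m(r) * exp(i * pi * v_d(r, t) / venc)` frozen at the readout's center
#' time; complex white Gaussian noise is added per sample. Beats whose
#' navigator position falls outside the acceptance window are rejected and
#' the line is immediately re-acquired in the next beat.
#'
#' @param field A [make_phantom()] flow field.
#' @param traj A [design_spiral_interleaf()] trajectory.
#' @param params The [sequence_params()] used for the trajectory.
#' @param rr_seq RR-interval sequence, ms (e.g. [sample_rr_intervals()]);
#'   must be long enough to cover rejections.
#' @param nav A [navigator_config()], or `NULL` to accept everything.
#' @param resp A respiratory trace function of absolute time (ms), or `NULL`.
#' @param seed Seed for the measurement noise.
#' @param min_efficiency Error out if the navigator acceptance efficiency
#'   falls below this floor.
#' @return An object of class `kspace_samples`: complex `samples`
#'   `[n_samples, n_readouts]`, per-readout `events` data frame (interleaf,
#'   kz_index, segment 1=ref/2=x/3=y/4=z, slot, t_abs, t_since_r, rr,
#'   accepted, row), per-beat `beats` data frame (rr, nav_position,
#'   accepted, interleaf, kz_index), `rr_used`, the trajectory, `venc`,
#'   `noise_sd` and `seed`.
#' @export
simulate_acquisition <- function(field, traj, params, rr_seq,
                                 nav = navigator_config(),
                                 resp = respiratory_trace(),
                                 seed = NULL, min_efficiency = 0.05) {
  stopifnot(inherits(field, "flow_field"),
            inherits(traj, "spiral_trajectory"),
            inherits(params, "sequence_params"))
  venc_m <- params$venc / 100
  if (field$peak_speed > venc_m)
    warning("phantom peak speed ", signif(field$peak_speed, 3),
            " m/s exceeds venc ", venc_m, " m/s: velocity will wrap")
  n <- params$matrix; vox <- params$voxel
  n_sl <- params$n_slices_recon
  n_kz <- traj$n_kz; n_int <- dim(traj$k)[3]; n_samp <- traj$n_samples
  # object grid: the central n_sl slices of the oversampled slice slab
  xs <- axis_coords(n, vox); ys <- xs
  zs_full <- axis_coords(n_kz, params$slice_thickness)
  zoff <- (n_kz - n_sl) / 2
  zs <- zs_full[(zoff + 1):(zoff + n_sl)]
  gg2 <- expand.grid(x = xs, y = ys)
  gg3 <- expand.grid(x = xs, y = ys, z = zs)
  mag3 <- field$magnitude(gg3$x, gg3$y, gg3$z)          # n*n*n_sl
  uv <- field$unit_velocity(gg3$x, gg3$y, gg3$z)        # m/s per unit flux
  # background phase offsets from the phantom spec, per encoded component
  bgoff <- matrix(0, length(mag3), 3)
  bp <- field$spec$background_poly
  if (!is.null(bp)) {
    geo <- list(dim = c(n, n, n_sl),
                voxel_size = c(vox, vox, params$slice_thickness))
    basis <- poly4_design(geo)
    for (ci in 1:3) {
      beta <- bp[[c("vx", "vy", "vz")[ci]]] %||% numeric(0)
      if (length(beta))
        bgoff[, ci] <- basis %*% c(beta, numeric(35 - length(beta)))
    }
  }
  phi_unit <- pi * uv / venc_m        # phase per unit flux, per component
  phi_bg <- pi * bgoff / venc_m
  # per-interleaf in-plane NUDFT matrices
  enc <- vector("list", n_int)
  for (m in seq_len(n_int)) {
    ph <- traj$k[, 1, m] %o% gg2$x + traj$k[, 2, m] %o% gg2$y
    enc[[m]] <- exp(-2i * pi * ph)
  }
  zph <- exp(-2i * pi * (traj$kz %o% zs))               # n_kz x n_sl
  slot_len <- params$n_flow_segments * params$tr
  rrm <- field$spec$rr_mean
  lines <- expand.grid(interleaf = seq_len(n_int), kz_index = seq_len(n_kz))
  # slice-encode outer loop ("all interleaves before the next slice encode")
  lines <- lines[order(lines$kz_index, lines$interleaf), ]
  with_seed(seed, {
    beats <- list(); events <- list(); samp_cols <- list()
    t_abs <- 0; bi <- 0; li <- 1; row <- 0
    nvx <- n * n
    while (li <= nrow(lines)) {
      bi <- bi + 1
      if (bi > length(rr_seq))
        stop_ctx("rr_seq exhausted after ", bi - 1, " beats (",
                 li - 1, "/", nrow(lines), " lines acquired); supply more ",
                 "beats or widen the navigator window",
                 class = "spiral4d_rr_exhausted")
      rr <- rr_seq[bi]
      il <- lines$interleaf[li]; kzi <- lines$kz_index[li]
      pos <- if (is.null(resp)) 0 else resp(t_abs)
      acc <- if (is.null(nav)) TRUE else
        navigator_accept(pos, kzi, nav, n_kz)
      beats[[bi]] <- data.frame(beat = bi, rr = rr, nav_position = pos,
                                accepted = acc, interleaf = il,
                                kz_index = kzi)
      if (acc) {
        # the TR train runs continuously until the next R wave; the final
        # slot may be partial (fewer than 4 segments acquired)
        n_slots <- max(1L, ceiling(rr / slot_len))
        t_slots <- (seq_len(n_slots) - 1) * slot_len
        # readout-center times of the 4 segments within each slot
        t_seg <- outer((1:4 - 0.5) * params$tr, t_slots, "+")  # 4 x n_slots
        q <- field$waveform(field$norm_time(as.vector(t_seg), rr))
        zw <- zph[kzi, ]
        mz <- mag3 * rep(zw, each = nvx)
        img_ref2 <- rowSums(matrix(mz, nvx, n_sl))      # z-collapsed, ref
        rhs <- matrix(complex(real = 0), nvx, 4 * n_slots)
        for (s in seq_len(n_slots)) {
          rhs[, (s - 1) * 4 + 1] <- img_ref2
          for (d in 1:3) {
            qi <- q[(s - 1) * 4 + d + 1]
            phi <- (phi_unit[, d] * qi + phi_bg[, d])
            imgc <- mz * complex(argument = phi)
            rhs[, (s - 1) * 4 + 1 + d] <- rowSums(matrix(imgc, nvx, n_sl))
          }
        }
        keep <- as.vector(t_seg) < rr     # segments cut short by the R wave
        rhs <- rhs[, keep, drop = FALSE]
        sig <- enc[[il]] %*% rhs                        # n_samp x n_kept
        noise <- field$spec$noise_sd * field$spec$magnitude_fluid
        if (noise > 0)
          sig <- sig + matrix(complex(real = stats::rnorm(length(sig), 0, noise),
                                      imaginary = stats::rnorm(length(sig), 0, noise)),
                              nrow(sig))
        nr <- sum(keep)
        events[[bi]] <- data.frame(
          beat = bi, interleaf = il, kz_index = kzi,
          slot = rep(seq_len(n_slots), each = 4)[keep],
          segment = rep(1:4, n_slots)[keep],
          t_abs = t_abs + as.vector(t_seg)[keep],
          t_since_r = as.vector(t_seg)[keep], rr = rr, accepted = TRUE,
          row = row + seq_len(nr))
        samp_cols[[bi]] <- sig
        row <- row + nr
        li <- li + 1
      }
      t_abs <- t_abs + rr
    }
    beats <- do.call(rbind, beats)
    eff <- mean(beats$accepted)
    if (eff < min_efficiency)
      stop_ctx("navigator acceptance efficiency ", signif(eff, 3),
               " below floor ", min_efficiency,
               class = "spiral4d_low_efficiency")
    events <- do.call(rbind, events)
    samples <- do.call(cbind, samp_cols)
    structure(list(samples = samples, events = events, beats = beats,
                   rr_used = beats$rr[beats$accepted],
                   trajectory = traj, params = params, venc = params$venc,
                   noise_sd = field$spec$noise_sd, seed = seed,
                   efficiency = eff),
              class = "kspace_samples")
  })
}

#' @exportS3Method print kspace_samples
print.kspace_samples <- function(x, ...) {
  cat("k-space sample set: ", ncol(x$samples), " readouts of ",
      nrow(x$samples), " samples\n  ", nrow(x$beats), " beats (",
      sum(x$beats$accepted), " accepted, efficiency ",
      signif(x$efficiency, 3), ")\n", sep = "")
  invisible(x)
}

#' Actual scan time of a simulated acquisition
#'
#' @param samples A `kspace_samples` object.
#' @return List with `beats` (total heartbeats consumed, including
#'   navigator rejections), `accepted`, `nominal` (beats that would be
#'   needed at 100% efficiency), `ratio_to_nominal` and `minutes` at the
#'   mean RR.
#' @export
actual_scan_time <- function(samples) {
  stopifnot(inherits(samples, "kspace_samples"))
  total <- nrow(samples$beats)
  nominal <- sum(samples$beats$accepted)
  list(beats = total, accepted = nominal, nominal = nominal,
       ratio_to_nominal = if (nominal > 0) total / nominal else NA_real_,
       minutes = total * mean(samples$beats$rr) / 60000)
}
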