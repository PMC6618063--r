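#' Retrospective gating configuration
#'
#' @param n_frames Number of reconstructed cardiac frames.
#' @param t_sys Systole duration in ms, or if `t_sys_frac` is given, ignored.
#' @param t_sys_frac Systole duration as a fraction of the mean RR interval
#'   (used when `t_sys` is `NULL`).
#' @param rule Binning rule. `"linear"` (default) distributes each readout
#'   between the two nearest frame centers with linear weights, the
#'   interpolating sort that combines the acquired cycles into an arbitrary
#'   number of frames without re-weighting the cardiac cycle; `"nearest"`
#'   assigns each readout wholly to the frame bin containing it. With slot
#'   spacing close to the frame width, nearest-bin assignment warps the
#'   effective time axis and biases time-integrated quantities (net volume)
#'   by several percent; linear weighting removes that bias.
#' @param fill How to complete bins that received no data: `"interp"`
#'   interpolates linearly in time between the nearest filled frames of the
#'   same line and segment (cyclic), `"nearest"` copies the nearest filled
#'   frame, `"none"` leaves them empty (error downstream if any line has no
#'   data at all).
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(n_frames = 40, t_sys = NULL, t_sys_frac = 0.4,
                          rule = c("linear", "nearest"),
                          fill = c("interp", "nearest", "none")) {
  assert_that(n_frames >= 1, "n_frames must be >= 1")
  if (is.null(t_sys))
    assert_that(t_sys_frac > 0 && t_sys_frac < 1,
                "t_sys_frac must be in (0, 1)")
  else assert_that(t_sys > 0, "t_sys must be positive")
  structure(list(n_frames = n_frames, t_sys = t_sys,
                 t_sys_frac = t_sys_frac, rule = match.arg(rule),
                 fill = match.arg(fill)),
            class = "gating_config")
}

#' Map a time within a beat onto the average cardiac cycle
#'
#' All cardiac cycles are normalized to one average cycle: systole is kept
#' constant (times up to `t_sys` are unchanged) and diastole is stretched or
#' compressed linearly so that the beat's end maps to the end of the average
#' cycle.
#'
#' @param t Time since the R wave, ms (0 <= t < rr). Vectorized.
#' @param rr RR interval of the containing beat, ms.
#' @param rr_mean Mean RR interval of the acquisition, ms.
#' @param t_sys Systole duration, ms (must be < rr and < rr_mean).
#' @return Normalized time in \[0, rr_mean).
#' @examples
#' normalize_cardiac_time(750, rr = 1200, rr_mean = 900, t_sys = 300)  # 600
#' @export
normalize_cardiac_time <- function(t, rr, rr_mean, t_sys) {
  if (any(rr <= t_sys) || rr_mean <= t_sys)
    stop_ctx("systole duration t_sys must be shorter than every RR interval",
             class = "spiral4d_domain")
  assert_that(all(t >= 0 & t < rr), "t must satisfy 0 <= t < rr")
  out <- ifelse(t <= t_sys, t,
                t_sys + (t - t_sys) * (rr_mean - t_sys) / (rr - t_sys))
  pmin(out, rr_mean * (1 - 1e-12))
}

#' Bin acquired readouts into cardiac frames
#'
#' Maps every accepted readout onto the normalized average cycle, assigns it
#' to the nearest of `n_frames` equal bins (`floor(t_norm / frame_width)`),
#' and averages complex samples that land in the same
#' (frame, segment, interleaf, slice-encode) bin. Bins left empty are
#' reported and, under the default policy, borrowed from the nearest filled
#' frame of the same line.
#'
#' @param samples A `kspace_samples` object from [simulate_acquisition()].
#' @param config A [gating_config()].
#' @return An object of class `binned_kspace`: complex array `k`
#'   `[n_samples, n_interleaves, n_kz, 4, n_frames]`, integer `hits`
#'   `[n_interleaves, n_kz, 4, n_frames]`, `fill_fraction` (raw, before
#'   borrowing), `borrowed` count, `rr_mean`, `t_sys`, `n_frames`,
#'   `frame_duration` and the trajectory.
#' @export
bin_samples <- function(samples, config = gating_config()) {
  stopifnot(inherits(samples, "kspace_samples"),
            inherits(config, "gating_config"))
  ev <- samples$events[samples$events$accepted, ]
  assert_that(nrow(ev) > 0, "no accepted readouts to bin")
  rr_mean <- mean(samples$rr_used)
  t_sys <- config$t_sys %||% (config$t_sys_frac * rr_mean)
  nf <- config$n_frames
  tn <- normalize_cardiac_time(ev$t_since_r, ev$rr, rr_mean, t_sys)
  fd <- rr_mean / nf
  if (config$rule == "nearest") {
    contrib_ev <- seq_len(nrow(ev))
    contrib_fr <- pmin(pmax(floor(tn / fd), 0), nf - 1) + 1L
    contrib_w <- rep(1, nrow(ev))
  } else {
    # linear weights to the two nearest frame centers, cyclic in the cycle
    u <- tn / fd - 0.5
    f0 <- floor(u); w1 <- u - f0
    contrib_ev <- rep(seq_len(nrow(ev)), 2L)
    contrib_fr <- c((f0 %% nf) + 1L, ((f0 + 1) %% nf) + 1L)
    contrib_w <- c(1 - w1, w1)
    keep <- contrib_w > 1e-12
    contrib_ev <- contrib_ev[keep]; contrib_fr <- contrib_fr[keep]
    contrib_w <- contrib_w[keep]
  }
  traj <- samples$trajectory
  n_samp <- traj$n_samples; n_int <- dim(traj$k)[3]; n_kz <- traj$n_kz
  k <- array(complex(real = 0), dim = c(n_samp, n_int, n_kz, 4, nf))
  hits <- array(0L, dim = c(n_int, n_kz, 4, nf))
  weight <- array(0, dim = c(n_int, n_kz, 4, nf))
  lin <- as.integer((contrib_fr - 1) * (n_int * n_kz * 4) +
                      (ev$segment[contrib_ev] - 1) * (n_int * n_kz) +
                      (ev$kz_index[contrib_ev] - 1) * n_int +
                      ev$interleaf[contrib_ev])
  ord <- order(lin)
  sm <- samples$samples[, ev$row, drop = FALSE]
  for (grp in split(seq_along(lin)[ord], lin[ord])) {
    e <- contrib_ev[grp]; i1 <- e[1]
    fr1 <- contrib_fr[grp[1]]
    ww <- contrib_w[grp]
    kidx <- cbind(seq_len(n_samp), ev$interleaf[i1], ev$kz_index[i1],
                  ev$segment[i1], fr1)
    k[kidx] <- as.vector(sm[, e, drop = FALSE] %*% ww) / sum(ww)
    hits[ev$interleaf[i1], ev$kz_index[i1], ev$segment[i1], fr1] <- length(grp)
    weight[ev$interleaf[i1], ev$kz_index[i1], ev$segment[i1], fr1] <- sum(ww)
  }
  fill_fraction <- mean(hits > 0)
  borrowed <- 0L
  if (config$fill != "none" && fill_fraction < 1) {
    for (il in seq_len(n_int)) for (kz in seq_len(n_kz)) for (sg in 1:4) {
      got <- which(hits[il, kz, sg, ] > 0)
      if (!length(got))
        stop_ctx("line (interleaf ", il, ", kz ", kz, ", segment ", sg,
                 ") has no accepted samples", class = "spiral4d_empty_line")
      for (f in which(hits[il, kz, sg, ] == 0)) {
        dcyc <- pmin(abs(got - f), nf - abs(got - f))
        if (config$fill == "interp" && length(got) >= 2) {
          # nearest filled frame on each side (cyclic), inverse-distance
          # weighted: linear interpolation of the line in cardiac time
          dfwd <- (got - f) %% nf; dfwd[dfwd == 0] <- nf
          dbwd <- (f - got) %% nf; dbwd[dbwd == 0] <- nf
          nxt <- got[which.min(dfwd)]; prv <- got[which.min(dbwd)]
          dn <- min(dfwd); dp <- min(dbwd)
          k[, il, kz, sg, f] <- (dn * k[, il, kz, sg, prv] +
                                   dp * k[, il, kz, sg, nxt]) / (dn + dp)
        } else {
          src <- got[which.min(dcyc)]
          k[, il, kz, sg, f] <- k[, il, kz, sg, src]
        }
        borrowed <- borrowed + 1L
      }
    }
  } else if (config$fill == "none") {
    for (il in seq_len(n_int)) for (kz in seq_len(n_kz)) for (sg in 1:4)
      if (!any(hits[il, kz, sg, ] > 0))
        stop_ctx("line (interleaf ", il, ", kz ", kz, ", segment ", sg,
                 ") has no accepted samples", class = "spiral4d_empty_line")
  }
  if (borrowed > 0)
    message("bin_samples: completed ", borrowed, " empty bins (",
            signif(100 * (1 - fill_fraction), 3),
            "% of bins) by ", config$fill, " fill")
  structure(list(k = k, hits = hits, fill_fraction = fill_fraction,
                 borrowed = borrowed, rr_mean = rr_mean, t_sys = t_sys,
                 n_frames = nf, frame_duration = rr_mean / nf,
                 trajectory = traj, venc = samples$venc),
            class = "binned_kspace")
}

#' @exportS3Method print binned_kspace
print.binned_kspace <- function(x, ...) {
  cat("Binned k-space: ", x$n_frames, " frames x 4 segments, ",
      dim(x$k)[2], " interleaves x ", dim(x$k)[3], " slice encodes\n",
      "  raw fill fraction ", signif(x$fill_fraction, 4), ", borrowed ",
      x$borrowed, " bins; mean RR ", signif(x$rr_mean, 4), " ms, systole ",
      signif(x$t_sys, 4), " ms\n", sep = "")
  invisible(x)
}
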