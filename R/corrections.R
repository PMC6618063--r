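#' Degree-4 spatial polynomial design matrix of a volume
#'
#' All 35 monomials `x^i y^j z^k` with `i + j + k <= 4`, evaluated at voxel
#' centers with each coordinate normalized to \[-1, 1\] over the volume
#' extent (for conditioning). Column order: by total degree, then
#' lexicographic in (i, j, k).
#'
#' @param series A [velocity_series()] (only its geometry is used), or a
#'   list with `dim` (length 3) and `voxel_size`.
#' @return Matrix with `prod(dim)` rows and 35 columns.
#' @export
poly4_design <- function(series) {
  d <- if (inherits(series, "velocity_series")) dim(series$magnitude)[1:3]
       else series$dim
  vox <- series$voxel_size
  norm1 <- function(n, dl) {
    x <- axis_coords(n, dl)
    if (max(abs(x)) > 0) x / max(abs(x)) else x
  }
  gg <- expand.grid(x = norm1(d[1], vox[1]), y = norm1(d[2], vox[2]),
                    z = norm1(d[3], vox[3]))
  pows <- poly4_powers()
  out <- matrix(1, nrow(gg), nrow(pows))
  for (j in seq_len(nrow(pows)))
    out[, j] <- gg$x^pows[j, 1] * gg$y^pows[j, 2] * gg$z^pows[j, 3]
  colnames(out) <- apply(pows, 1, function(p)
    paste0("x", p[1], "y", p[2], "z", p[3]))
  out
}

poly4_powers <- function() {
  pw <- expand.grid(i = 0:4, j = 0:4, k = 0:4)
  pw <- pw[rowSums(pw) <= 4, ]
  as.matrix(pw[order(rowSums(pw), pw$i, pw$j, pw$k), ])
}

#' Detect static tissue by low temporal variance
#'
#' A voxel is static when its temporal SD of speed is at or below the given
#' percentile of the SD distribution over voxels with adequate signal, and
#' its (time-averaged) magnitude is at or above the floor.
#'
#' @param series A [velocity_series()] with at least 2 frames.
#' @param sd_percentile Percentile (0-100) of the speed-SD distribution used
#'   as the variance threshold.
#' @param magnitude_floor Minimum magnitude, as a fraction of the maximum
#'   time-averaged magnitude.
#' @return An object of class `static_mask`: logical 3D array `mask` plus
#'   the thresholds used.
#' @export
detect_static_tissue <- function(series, sd_percentile = 25,
                                 magnitude_floor = 0.1) {
  stopifnot(inherits(series, "velocity_series"))
  d <- dim(series$magnitude)
  assert_that(d[4] >= 2, "static-tissue detection needs >= 2 frames")
  mag <- apply(series$magnitude, 1:3, mean)
  floor_abs <- magnitude_floor * max(mag)
  above <- mag >= floor_abs
  if (!any(above))
    stop_ctx("magnitude floor is above every voxel's signal",
             class = "spiral4d_empty_mask")
  speed <- sqrt(series$v[, , , , 1]^2 + series$v[, , , , 2]^2 +
                  series$v[, , , , 3]^2)
  dim(speed) <- c(prod(d[1:3]), d[4])
  sdv <- array(apply(speed, 1, stats::sd), dim = d[1:3])
  thr <- stats::quantile(sdv[above], sd_percentile / 100, names = FALSE)
  mask <- above & sdv <= thr
  if (!any(mask))
    stop_ctx("static-tissue mask is empty at the given thresholds",
             class = "spiral4d_empty_mask")
  structure(list(mask = mask, sd_threshold = thr,
                 magnitude_floor = floor_abs,
                 sd_percentile = sd_percentile), class = "static_mask")
}

#' Fit the eddy-current background model to static tissue
#'
#' Ordinary least squares of the time-averaged velocity of masked voxels on
#' the degree-4 spatial basis, independently per velocity component. One
#' time-invariant polynomial per component models the slowly varying
#' eddy-current phase offset.
#'
#' @param series A [velocity_series()].
#' @param mask A `static_mask` from [detect_static_tissue()], or a logical
#'   3D array.
#' @return An object of class `background_model`: a `35 x 3` coefficient
#'   matrix (columns vx, vy, vz) in m/s on the normalized basis.
#' @export
fit_background <- function(series, mask) {
  stopifnot(inherits(series, "velocity_series"))
  if (inherits(mask, "static_mask")) mask <- mask$mask
  idx <- which(as.logical(mask))
  assert_that(length(idx) >= 35,
              "need >= 35 static voxels to resolve the degree-4 basis")
  basis <- poly4_design(series)[idx, , drop = FALSE]
  qrb <- qr(basis)
  if (qrb$rank < ncol(basis))
    stop_ctx("degree-4 basis is rank deficient on the static mask",
             class = "spiral4d_rank_deficient")
  vbar <- apply(series$v, c(1, 2, 3, 5), mean)   # time-averaged velocity
  dim(vbar) <- c(prod(dim(series$magnitude)[1:3]), 3)
  coef <- qr.coef(qrb, vbar[idx, , drop = FALSE])
  dimnames(coef) <- list(colnames(poly4_design(series)), c("vx", "vy", "vz"))
  structure(list(coefficients = coef, n_voxels = length(idx)),
            class = "background_model")
}

#' @exportS3Method print background_model
print.background_model <- function(x, ...) {
  cat("Degree-4 background velocity model fitted on", x$n_voxels,
      "static voxels\n  constant terms (m/s):",
      paste(signif(x$coefficients[1, ], 3), collapse = ", "), "\n")
  invisible(x)
}

#' Subtract the fitted background offset from a series
#'
#' Evaluates the polynomial model over the volume and subtracts it from
#' every frame of each velocity component; magnitude is untouched.
#'
#' @param series A [velocity_series()].
#' @param model A `background_model` from [fit_background()].
#' @return The corrected series.
#' @export
subtract_background <- function(series, model) {
  stopifnot(inherits(series, "velocity_series"),
            inherits(model, "background_model"))
  d <- dim(series$magnitude)
  basis <- poly4_design(series)
  for (ci in 1:3) {
    off <- array(basis %*% model$coefficients[, ci], dim = d[1:3])
    for (f in seq_len(d[4]))
      series$v[, , , f, ci] <- series$v[, , , f, ci] - off
  }
  series
}

#' Evaluate a background model over a series geometry
#'
#' @param model A `background_model`.
#' @param series The series providing the voxel grid.
#' @return 4D array `[nx, ny, nz, 3]` of offsets, m/s.
#' @export
evaluate_background <- function(model, series) {
  d <- dim(series$magnitude)
  basis <- poly4_design(series)
  array(basis %*% model$coefficients, dim = c(d[1:3], 3))
}
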