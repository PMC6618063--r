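#' Vessel cross-section plane segmentation
#'
#' An axis-aligned plane through the volume with an in-plane lumen mask and
#' a unit normal along one coordinate axis.
#'
#' @param mask Logical 3D array marking lumen voxels of the plane (non-zero
#'   only on one slice along the normal axis).
#' @param normal Unit normal, e.g. `c(0, 1, 0)`; must be axis-aligned.
#' @param pixel_area Area of one in-plane pixel, mm^2.
#' @return An object of class `plane_segmentation`.
#' @export
plane_segmentation <- function(mask, normal, pixel_area) {
  assert_that(abs(sqrt(sum(normal^2)) - 1) < 1e-9, "|normal| must be 1")
  assert_that(sum(normal != 0) == 1, "normal must be axis-aligned")
  assert_that(any(mask), "plane mask is empty")
  assert_that(pixel_area > 0, "pixel_area must be positive")
  structure(list(mask = as.logical(mask) & TRUE, dim = dim(mask),
                 mask_idx = which(as.logical(mask)), normal = normal,
                 pixel_area = pixel_area), class = "plane_segmentation")
}

#' Helper: plane through a phantom limb
#'
#' Builds a [plane_segmentation()] for the inlet or outlet tube of the
#' U-bend phantom at a given y position, on the grid of a series.
#'
#' @param field A [make_phantom()] object.
#' @param series The [velocity_series()] whose grid the plane lives on.
#' @param which `"inlet"` or `"outlet"`.
#' @param y_plane y position of the plane, mm (defaults to halfway up the
#'   limb).
#' @param dilate_mm Radial margin added to the lumen radius when masking
#'   (captures partial-volume spill of the reconstructed flow), mm.
#' @return A `plane_segmentation` whose normal points along the expected
#'   flow direction (`(0, -1, 0)` for the inlet, `(0, 1, 0)` for the
#'   outlet), so flow curves are positive.
#' @export
phantom_plane <- function(field, series, which = c("inlet", "outlet"),
                          y_plane = NULL, dilate_mm = 0) {
  which <- match.arg(which)
  spec <- field$spec
  y_plane <- y_plane %||% (spec$mouth_y + spec$tube_length / 2)
  co <- series_coords(series)
  jy <- which.min(abs(co$y - y_plane))
  xc <- if (which == "inlet") spec$loop_radius else -spec$loop_radius
  d <- dim(series$magnitude)[1:3]
  gg <- expand.grid(x = co$x, z = co$z)
  in_lumen <- sqrt((gg$x - xc)^2 + gg$z^2) <= spec$tube_radius + dilate_mm
  mask <- array(FALSE, dim = d)
  mask[, jy, ] <- array(in_lumen, dim = c(d[1], d[3]))
  plane_segmentation(mask, c(0, if (which == "inlet") -1 else 1, 0),
                     pixel_area = series$voxel_size[1] * series$voxel_size[3])
}

#' Volume flow rate through a plane, per cardiac frame
#'
#' `Q(frame) = sum over mask of (v . n) * pixel_area`, in ml/s.
#'
#' @param series A [velocity_series()].
#' @param plane A [plane_segmentation()].
#' @return Numeric vector, ml/s per frame.
#' @export
flow_rate_curve <- function(series, plane) {
  stopifnot(inherits(series, "velocity_series"),
            inherits(plane, "plane_segmentation"))
  d <- dim(series$magnitude)
  if (!all(plane$dim == d[1:3]))
    stop_ctx("plane does not lie inside the volume grid",
             class = "spiral4d_plane_mismatch")
  nf <- d[4]
  ax <- which(plane$normal != 0)
  sgn <- plane$normal[ax]
  nvox <- prod(d[1:3])
  sapply(seq_len(nf), function(f) {
    vn <- series$v[, , , f, ax][plane$mask_idx] * sgn
    # m/s * mm^2 = mm^3/ms = ml/s
    sum(vn * plane$pixel_area)
  })
}

#' Net volume per cardiac cycle from a flow-rate curve
#'
#' Rectangle-rule integral over the frames of one cycle.
#'
#' @param q Flow-rate curve, ml/s per frame.
#' @param frame_duration Frame duration, ms.
#' @return Net volume, ml.
#' @export
net_volume <- function(q, frame_duration) {
  sum(q) * frame_duration / 1000
}

#' Peak flow rate and peak velocity in a plane
#'
#' Peak flow rate is the maximum of the flow-rate curve; peak velocity is
#' the maximum through-plane speed over frames and mask pixels.
#'
#' @inheritParams flow_rate_curve
#' @return List with `peak_flow_rate` (ml/s) and `peak_velocity` (m/s).
#' @export
peaks <- function(series, plane) {
  q <- flow_rate_curve(series, plane)
  d <- dim(series$magnitude)
  ax <- which(plane$normal != 0)
  pv <- 0
  for (f in seq_len(d[4]))
    pv <- max(pv, abs(series$v[, , , f, ax][plane$mask_idx]))
  list(peak_flow_rate = max(q), peak_velocity = pv)
}

#' Full plane-flow quantification
#'
#' @inheritParams flow_rate_curve
#' @return An object of class `flow_result`: `q` (ml/s per frame),
#'   `net_volume` (ml), `peak_flow_rate` (ml/s), `peak_velocity` (m/s),
#'   `frame_duration` (ms), and a tidy `curve` data frame.
#' @export
quantify_flow <- function(series, plane) {
  q <- flow_rate_curve(series, plane)
  pk <- peaks(series, plane)
  structure(list(q = q, net_volume = net_volume(q, series$frame_duration),
                 peak_flow_rate = pk$peak_flow_rate,
                 peak_velocity = pk$peak_velocity,
                 frame_duration = series$frame_duration,
                 curve = data.frame(
                   frame = seq_along(q),
                   time_ms = (seq_along(q) - 0.5) * series$frame_duration,
                   flow_ml_s = q)),
            class = "flow_result")
}

#' @exportS3Method print flow_result
print.flow_result <- function(x, ...) {
  cat("Plane flow: net volume ", signif(x$net_volume, 4), " ml/cycle, peak ",
      signif(x$peak_flow_rate, 4), " ml/s, peak velocity ",
      signif(x$peak_velocity, 3), " m/s (", length(x$q), " frames)\n",
      sep = "")
  invisible(x)
}

#' @export
plot.flow_result <- function(x, ...) {
  graphics::plot(x$curve$time_ms, x$curve$flow_ml_s, type = "b", pch = 16,
                 xlab = "time in cycle (ms)", ylab = "flow rate (ml/s)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
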