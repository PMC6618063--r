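#' Time-resolved velocity volume series
#'
#' Container for reconstructed (or ground-truth) 4D flow data: a magnitude
#' volume and three velocity-component volumes per cardiac frame.
#'
#' @param magnitude 4D array `[nx, ny, nz, n_frames]`, arbitrary units.
#' @param v 5D array `[nx, ny, nz, n_frames, 3]` of velocity in m/s
#'   (components x, y, z).
#' @param voxel_size Voxel edge lengths in mm, length 3.
#' @param frame_duration Duration of one cardiac frame, ms.
#' @param venc Velocity encoding of the originating acquisition, cm/s.
#' @return An object of class `velocity_series`.
#' @export
velocity_series <- function(magnitude, v, voxel_size, frame_duration, venc) {
  dm <- dim(magnitude); dv <- dim(v)
  assert_that(length(dm) == 4, "magnitude must be a 4D array [x, y, z, frame]")
  assert_that(length(dv) == 5 && all(dv[1:4] == dm) && dv[5] == 3,
              "v must be [x, y, z, frame, 3] matching magnitude")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "voxel_size must be 3 positive lengths (mm)")
  assert_that(frame_duration > 0 && venc > 0,
              "frame_duration and venc must be positive")
  structure(list(magnitude = magnitude, v = v, voxel_size = voxel_size,
                 frame_duration = frame_duration, venc = venc),
            class = "velocity_series")
}

#' @exportS3Method print velocity_series
print.velocity_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat("velocity_series: ", paste(d[1:3], collapse = " x "), " voxels (",
      paste(signif(x$voxel_size, 3), collapse = " x "), " mm), ",
      d[4], " frames @ ", signif(x$frame_duration, 4), " ms, venc ",
      x$venc, " cm/s\n", sep = "")
  invisible(x)
}

#' @export
dim.velocity_series <- function(x) dim(x$magnitude)

# voxel-center coordinate vectors (mm) of a series/array geometry
series_coords <- function(series) {
  d <- dim(series$magnitude)
  list(x = axis_coords(d[1], series$voxel_size[1]),
       y = axis_coords(d[2], series$voxel_size[2]),
       z = axis_coords(d[3], series$voxel_size[3]))
}
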