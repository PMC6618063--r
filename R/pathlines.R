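#' Chamber segmentations for pathline analysis
#'
#' End-diastolic and end-systolic chamber masks with labeled boundary
#' regions on the end-systolic surface: the inlet (e.g. mitral) region, the
#' outlet (e.g. aortic) region, and everything else counting as wall
#' (myocardium).
#'
#' @param ed_mask Logical 3D array: chamber at end diastole.
#' @param es_mask Logical 3D array: chamber at end systole.
#' @param inlet_region,outlet_region Logical 3D arrays labeling the
#'   boundary-region voxels.
#' @param ed_frame,es_frame Frame indices of end diastole / end systole.
#' @return An object of class `chamber_segmentations`.
#' @export
chamber_segmentations <- function(ed_mask, es_mask, inlet_region,
                                  outlet_region, ed_frame, es_frame) {
  assert_that(any(ed_mask) && any(es_mask), "chamber masks must be non-empty")
  assert_that(ed_frame != es_frame, "ED and ES frames must differ")
  structure(list(ed_mask = ed_mask, es_mask = es_mask,
                 inlet_region = inlet_region, outlet_region = outlet_region,
                 ed_frame = ed_frame, es_frame = es_frame),
            class = "chamber_segmentations")
}

# Quadrilinear (x, y, z, t) velocity interpolation with periodic wrapping in
# time over the cycle. pos: n x 3 matrix (mm); t scalar (ms). Returns n x 3
# velocities (m/s); positions outside the volume get zero velocity and
# oob = TRUE.
interp_velocity <- function(series, pos, t) {
  d <- dim(series$magnitude)
  vox <- series$voxel_size
  nt <- d[4]
  period <- nt * series$frame_duration
  # fractional voxel indices (1-based; voxel centers at axis_coords)
  fx <- pos[, 1] / vox[1] + d[1] / 2 + 0.5
  fy <- pos[, 2] / vox[2] + d[2] / 2 + 0.5
  fz <- pos[, 3] / vox[3] + d[3] / 2 + 0.5
  oob <- fx < 1 | fx > d[1] | fy < 1 | fy > d[2] | fz < 1 | fz > d[3]
  fx <- pmin(pmax(fx, 1), d[1]); fy <- pmin(pmax(fy, 1), d[2])
  fz <- pmin(pmax(fz, 1), d[3])
  ix <- pmin(floor(fx), d[1] - 1); iy <- pmin(floor(fy), d[2] - 1)
  iz <- pmin(floor(fz), d[3] - 1)
  wx <- fx - ix; wy <- fy - iy; wz <- fz - iz
  tt <- (t / series$frame_duration - 0.5) %% nt     # frame-center convention
  it <- floor(tt)
  wt <- tt - it
  f0 <- (it %% nt) + 1L; f1 <- ((it + 1) %% nt) + 1L
  n <- nrow(pos)
  out <- matrix(0, n, 3)
  nvox <- prod(d[1:3])
  base <- (iz - 1) * d[1] * d[2] + (iy - 1) * d[1] + ix   # linear idx (1-based)
  for (ci in 1:3) {
    v0 <- series$v[, , , f0, ci, drop = FALSE]; dim(v0) <- c(nvox, length(1))
    v1 <- series$v[, , , f1, ci, drop = FALSE]; dim(v1) <- c(nvox, length(1))
    acc <- numeric(n)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
        (if (dz) wz else 1 - wz)
      idx <- base + dx + dy * d[1] + dz * d[1] * d[2]
      acc <- acc + w * ((1 - wt) * v0[idx, 1] + wt * v1[idx, 1])
    }
    out[, ci] <- acc
  }
  out[oob, ] <- 0
  attr(out, "oob") <- oob
  out
}

#' One classical Runge-Kutta step through the velocity field
#'
#' Fourth-order Runge-Kutta with quadrilinear spatiotemporal interpolation;
#' `dt` may be negative for backward tracing. Positions leaving the volume
#' see zero velocity and are flagged, not raised as errors.
#'
#' @param series A [velocity_series()].
#' @param pos `n x 3` matrix of positions, mm.
#' @param t Current time, ms (periodic over the cycle).
#' @param dt Step length, ms (default 5).
#' @return `n x 3` matrix of updated positions with attribute `oob`.
#' @export
rk4_step <- function(series, pos, t, dt = 5) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  # velocities in m/s = mm/ms, dt in ms -> displacement in mm
  k1 <- interp_velocity(series, pos, t)
  k2 <- interp_velocity(series, pos + dt / 2 * k1, t + dt / 2)
  k3 <- interp_velocity(series, pos + dt / 2 * k2, t + dt / 2)
  k4 <- interp_velocity(series, pos + dt * k3, t + dt)
  new_pos <- pos + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  attr(new_pos, "oob") <- attr(k1, "oob")
  new_pos
}

#' Trace pathlines through the time-resolved field
#'
#' Integrates each seed from `t0` to `t1` (backward when `t1 < t0`) in RK4
#' steps, recording positions and, against the chamber mask, boundary
#' crossings with the label of the nearest labeled surface region.
#'
#' @param series A [velocity_series()].
#' @param seeds `n x 3` matrix of seed positions, mm.
#' @param t0,t1 Start and end times, ms (cycle time; may exceed the cycle,
#'   periodicity is applied).
#' @param dt Step length magnitude, ms.
#' @param segs Optional [chamber_segmentations()]; when given, chamber-exit
#'   crossings are recorded.
#' @param carried_volume Volume carried by each pathline, ml (scalar or
#'   vector).
#' @return An object of class `pathline_set`: `positions`
#'   `[n_steps + 1, n, 3]`, `times`, `exit` data frame (pathline, step,
#'   region in inlet/outlet/wall, position), `carried_volume`, flags.
#' @export
trace_pathlines <- function(series, seeds, t0, t1, dt = 5, segs = NULL,
                            carried_volume = 1) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  n <- nrow(seeds)
  dt <- abs(dt) * sign(t1 - t0)
  n_steps <- ceiling(abs(t1 - t0) / abs(dt) - 1e-9)
  pos <- seeds
  times <- t0 + (0:n_steps) * dt
  if (n_steps > 0) times[n_steps + 1] <- t1
  positions <- array(NA_real_, dim = c(n_steps + 1, n, 3))
  positions[1, , ] <- pos
  oob_flag <- rep(FALSE, n)
  inside_prev <- if (!is.null(segs)) mask_lookup(segs$es_mask, series, pos)
  exit_rec <- list()
  if (n_steps > 0) for (s in seq_len(n_steps)) {
    step_dt <- times[s + 1] - times[s]
    newp <- rk4_step(series, pos, times[s], step_dt)
    oob_flag <- oob_flag | attr(newp, "oob")
    if (!is.null(segs)) {
      inside_now <- mask_lookup(segs$es_mask, series, newp)
      crossed <- which(inside_prev & !inside_now)
      if (length(crossed)) {
        lab <- label_crossing(segs, series, newp[crossed, , drop = FALSE])
        exit_rec[[length(exit_rec) + 1]] <- data.frame(
          pathline = crossed, step = s, time = times[s + 1], region = lab,
          x = newp[crossed, 1], y = newp[crossed, 2], z = newp[crossed, 3])
      }
      inside_prev <- inside_now
    }
    pos <- newp
    positions[s + 1, , ] <- pos
  }
  exit <- if (length(exit_rec)) do.call(rbind, exit_rec)
  else data.frame(pathline = integer(0), step = integer(0),
                  time = numeric(0), region = character(0),
                  x = numeric(0), y = numeric(0), z = numeric(0))
  # first exit per pathline is the one that counts
  exit <- exit[!duplicated(exit$pathline), , drop = FALSE]
  structure(list(positions = positions, times = times, seeds = seeds,
                 exit = exit, oob = oob_flag,
                 carried_volume = rep(carried_volume, length.out = n)),
            class = "pathline_set")
}

# nearest-voxel mask membership of positions
mask_lookup <- function(mask, series, pos) {
  d <- dim(mask)
  vox <- series$voxel_size
  ix <- round(pos[, 1] / vox[1] + d[1] / 2 + 0.5)
  iy <- round(pos[, 2] / vox[2] + d[2] / 2 + 0.5)
  iz <- round(pos[, 3] / vox[3] + d[3] / 2 + 0.5)
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  out <- rep(FALSE, nrow(pos))
  out[ok] <- mask[cbind(ix[ok], iy[ok], iz[ok])]
  out
}

# Label a crossing point by the nearest labeled boundary voxel: inlet,
# outlet, or wall when neither is within reach (1.5 voxel diagonals).
label_crossing <- function(segs, series, pts) {
  co <- series_coords(series)
  vox_diag <- sqrt(sum(series$voxel_size^2))
  lab_pts <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    cbind(co$x[idx[, 1]], co$y[idx[, 2]], co$z[idx[, 3]])
  }
  inlet_xyz <- lab_pts(segs$inlet_region)
  outlet_xyz <- lab_pts(segs$outlet_region)
  nearest_d <- function(p, xyz) {
    if (!nrow(xyz)) return(Inf)
    min(sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2))
  }
  apply(pts, 1, function(p) {
    din <- nearest_d(p, inlet_xyz); dout <- nearest_d(p, outlet_xyz)
    if (min(din, dout) > 1.5 * vox_diag) "wall"
    else if (din <= dout) "inlet" else "outlet"
  })
}

#' Classify pathlines into the four flow components
#'
#' Combines a forward trace (end diastole through systole to end systole)
#' and a backward trace (end diastole back through diastole to the previous
#' end systole): a pathline that entered through the inlet region and leaves
#' through the outlet is direct flow; entered but not left, retained inflow;
#' left but not entered, delayed ejection; neither, residual volume. Any
#' wall crossing discards the pathline. Volumes accumulate the carried
#' volumes; inflow = direct + retained, outflow = direct + delayed.
#'
#' @param fwd `pathline_set` traced forward from ED to ES.
#' @param bwd `pathline_set` traced backward from ED to the previous ES.
#' @param segs The [chamber_segmentations()] used for tracing.
#' @return An object of class `flow_components`: volumes in ml for
#'   `direct`, `retained_inflow`, `delayed_ejection`, `residual`, `inflow`,
#'   `outflow`, `discarded`, `discarded_fraction`, `total`, plus the
#'   per-pathline classification.
#' @export
classify_pathlines <- function(fwd, bwd, segs) {
  stopifnot(inherits(fwd, "pathline_set"), inherits(bwd, "pathline_set"))
  n <- nrow(fwd$seeds)
  assert_that(nrow(bwd$seeds) == n, "forward/backward seed sets differ")
  vol <- fwd$carried_volume
  left_lab <- entered_lab <- rep(NA_character_, n)
  left_lab[fwd$exit$pathline] <- fwd$exit$region
  entered_lab[bwd$exit$pathline] <- bwd$exit$region
  discarded <- (!is.na(left_lab) & left_lab == "wall") |
    (!is.na(entered_lab) & entered_lab == "wall")
  entered <- !is.na(entered_lab) & entered_lab == "inlet" & !discarded
  left <- !is.na(left_lab) & left_lab == "outlet" & !discarded
  class_of <- ifelse(discarded, "discarded",
                     ifelse(entered & left, "direct",
                            ifelse(entered, "retained_inflow",
                                   ifelse(left, "delayed_ejection",
                                          "residual"))))
  vsum <- function(sel) sum(vol[sel])
  direct <- vsum(class_of == "direct")
  retained <- vsum(class_of == "retained_inflow")
  delayed <- vsum(class_of == "delayed_ejection")
  residual <- vsum(class_of == "residual")
  disc <- vsum(discarded)
  structure(list(direct = direct, retained_inflow = retained,
                 delayed_ejection = delayed, residual = residual,
                 inflow = direct + retained, outflow = direct + delayed,
                 discarded = disc,
                 discarded_fraction = disc / sum(vol), total = sum(vol),
                 classification = class_of),
            class = "flow_components")
}

#' @exportS3Method print flow_components
print.flow_components <- function(x, ...) {
  cat("Flow components (ml): direct ", signif(x$direct, 3), ", retained ",
      signif(x$retained_inflow, 3), ", delayed ",
      signif(x$delayed_ejection, 3), ", residual ", signif(x$residual, 3),
      "\n  inflow ", signif(x$inflow, 3), ", outflow ",
      signif(x$outflow, 3), ", discarded ",
      signif(100 * x$discarded_fraction, 3), "%\n", sep = "")
  invisible(x)
}

#' Flow components from stated component volumes
#'
#' Builds a `flow_components` object from direct / retained-inflow /
#' delayed-ejection / residual volumes (e.g. values reported for a clinical
#' examination), deriving inflow and outflow from the additivity
#' identities.
#'
#' @param direct,retained_inflow,delayed_ejection,residual Volumes, ml.
#' @return A `flow_components` object.
#' @export
flow_components <- function(direct, retained_inflow, delayed_ejection,
                            residual = 0) {
  total <- direct + retained_inflow + delayed_ejection + residual
  structure(list(direct = direct, retained_inflow = retained_inflow,
                 delayed_ejection = delayed_ejection, residual = residual,
                 inflow = direct + retained_inflow,
                 outflow = direct + delayed_ejection,
                 discarded = 0, discarded_fraction = 0, total = total,
                 classification = NULL),
            class = "flow_components")
}

#' Mass-conservation check of a pathline decomposition
#'
#' In an incompressible chamber the pathline-based inflow must equal the
#' outflow; their difference is a sensitive quality measure of the velocity
#' data.
#'
#' @param components A `flow_components` object.
#' @return List with `inflow`, `outflow`, `difference` (ml) and
#'   `relative_difference`.
#' @export
conservation_check <- function(components) {
  stopifnot(inherits(components, "flow_components"))
  list(inflow = components$inflow, outflow = components$outflow,
       difference = components$inflow - components$outflow,
       relative_difference = if (components$inflow != 0)
         (components$inflow - components$outflow) / components$inflow
       else 0)
}

#' Seed positions for pathline release
#'
#' One seed per chamber voxel center by default, optionally subdivided
#' `k^3`-fold; each seed carries voxel volume / seeds-per-voxel.
#'
#' @param mask Logical 3D chamber mask (end diastole).
#' @param series The series providing the grid.
#' @param subdivide Per-axis subdivision factor k.
#' @return List with `seeds` (`n x 3`, mm) and `carried_volume` (ml each).
#' @export
seed_chamber <- function(mask, series, subdivide = 1) {
  co <- series_coords(series)
  idx <- which(mask, arr.ind = TRUE)
  base <- cbind(co$x[idx[, 1]], co$y[idx[, 2]], co$z[idx[, 3]])
  vox <- series$voxel_size
  if (subdivide > 1) {
    offs <- expand.grid(
      x = (seq_len(subdivide) - 0.5) / subdivide - 0.5,
      y = (seq_len(subdivide) - 0.5) / subdivide - 0.5,
      z = (seq_len(subdivide) - 0.5) / subdivide - 0.5)
    seeds <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
      sweep(base, 2, -as.numeric(offs[i, ]) * vox)))
  } else seeds <- base
  carried <- prod(vox) / subdivide^3 / 1000   # mm^3 -> ml
  list(seeds = seeds, carried_volume = carried)
}

#' Run the full pathline decomposition of a chamber
#'
#' Seeds the end-diastolic chamber, traces forward through systole and
#' backward through diastole, and classifies the four components.
#'
#' @param series A [velocity_series()] covering one cycle.
#' @param segs A [chamber_segmentations()].
#' @param dt RK4 step length, ms.
#' @param subdivide Seed subdivision factor.
#' @return A `flow_components` object with the traced sets attached as
#'   attributes `fwd` and `bwd`.
#' @export
pathline_decomposition <- function(series, segs, dt = 5, subdivide = 1) {
  nt <- dim(series$magnitude)[4]
  period <- nt * series$frame_duration
  t_ed <- 0                                  # R wave = end diastole
  t_es <- (segs$es_frame - 0.5) * series$frame_duration
  sd <- seed_chamber(segs$ed_mask, series, subdivide)
  fwd <- trace_pathlines(series, sd$seeds, t_ed, t_es, dt = dt, segs = segs,
                         carried_volume = sd$carried_volume)
  # backward: from ED (= period, end of previous cycle) back to previous ES
  bwd <- trace_pathlines(series, sd$seeds, period, t_es, dt = dt,
                         segs = segs, carried_volume = sd$carried_volume)
  out <- classify_pathlines(fwd, bwd, segs)
  attr(out, "fwd") <- fwd
  attr(out, "bwd") <- bwd
  out
}
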