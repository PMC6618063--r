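test_that("RK4 is exact for a uniform steady field", {
  ser <- uniform_series(c(0.3, -0.2, 0.1), n = 16, vox = 2.8, n_sl = 8)
  pos <- matrix(c(0, 0, 0, 5, -3, 2), ncol = 3, byrow = TRUE)
  out <- rk4_step(ser, pos, t = 50, dt = 5)
  expect_equal(out[, 1], pos[, 1] + 0.3 * 5, tolerance = 1e-12)
  expect_equal(out[, 2], pos[, 2] - 0.2 * 5, tolerance = 1e-12)
  expect_equal(out[, 3], pos[, 3] + 0.1 * 5, tolerance = 1e-12)
  # reversibility in a steady field
  back <- rk4_step(ser, out, t = 55, dt = -5)
  expect_lt(max(abs(back - pos)), 1e-6)
})

test_that("rigid rotation closes the circular orbit within 0.1%", {
  omega <- 2 * pi / 600          # one revolution per 600 ms
  ser <- rotation_series(omega)
  r0 <- 12
  pos <- matrix(c(r0, 0, 0), ncol = 1 + 2)
  dt <- 5
  n_steps <- 600 / dt
  p <- pos
  max_drift <- 0
  for (s in seq_len(n_steps)) {
    p <- rk4_step(ser, p, t = (s - 1) * dt, dt = dt)
    drift <- abs(sqrt(p[1]^2 + p[2]^2) - r0)
    max_drift <- max(max_drift, drift)
  }
  # per-step radius drift bounded by the (omega dt)^5 truncation scale
  expect_lt(max_drift / r0, n_steps * (omega * dt)^5)
  expect_lt(sqrt((p[1] - r0)^2 + p[2]^2) / r0, 0.001)
})

test_that("zero field leaves every pathline stationary", {
  ser <- uniform_series(c(0, 0, 0), n = 16, vox = 2.8, n_sl = 8)
  seeds <- matrix(runif(30, -10, 10), ncol = 3)
  mask <- array(TRUE, dim = c(16, 16, 8))
  segs <- chamber_segmentations(mask, mask,
                                array(FALSE, dim = dim(mask)),
                                array(FALSE, dim = dim(mask)), 2, 1)
  ps <- trace_pathlines(ser, seeds, 0, 100, dt = 5, segs = segs)
  expect_equal(ps$positions[21, , ], seeds)
  expect_equal(nrow(ps$exit), 0)
})

test_that("out-of-volume trajectories terminate with a flag, not an error", {
  ser <- uniform_series(c(1, 0, 0), n = 8, vox = 2.8, n_sl = 4)
  seeds <- matrix(c(9, 0, 0), ncol = 3)   # near +x edge, moving +x
  ps <- trace_pathlines(ser, seeds, 0, 100, dt = 5)
  expect_true(ps$oob[1])
})

test_that("step halving changes phantom trajectories by under 0.1 voxel", {
  f <- make_phantom(phantom_spec())
  ser <- rasterize_phantom(f, matrix = 64, voxel = 2.8, n_slices = 8,
                           n_frames = 20)
  masks <- phantom_masks(f, matrix = 64, voxel = 2.8, n_slices = 8)
  idx <- which(masks$chamber, arr.ind = TRUE)
  co <- list(x = axis_coords_t(64, 2.8), y = axis_coords_t(64, 2.8),
             z = axis_coords_t(8, 2.8))
  set.seed(9)
  pick <- idx[sample(nrow(idx), 40), ]
  seeds <- cbind(co$x[pick[, 1]], co$y[pick[, 2]], co$z[pick[, 3]])
  p5 <- trace_pathlines(ser, seeds, 0, 360, dt = 5)
  p25 <- trace_pathlines(ser, seeds, 0, 360, dt = 2.5)
  dpos <- sqrt(rowSums((p5$positions[dim(p5$positions)[1], , ] -
                          p25$positions[dim(p25$positions)[1], , ])^2))
  expect_lt(max(dpos), 0.1 * 2.8)
})

test_that("volume bookkeeping closes exactly and identities hold", {
  f <- make_phantom(phantom_spec())
  ser <- rasterize_phantom(f, matrix = 64, voxel = 2.8, n_slices = 8,
                           n_frames = 20)
  masks <- phantom_masks(f, matrix = 64, voxel = 2.8, n_slices = 8)
  segs <- chamber_segmentations(masks$chamber, masks$chamber,
                                masks$inlet_mouth, masks$outlet_mouth,
                                ed_frame = 20, es_frame = 8)
  comp <- pathline_decomposition(ser, segs)
  expect_equal(comp$direct + comp$retained_inflow + comp$delayed_ejection +
                 comp$residual + comp$discarded, comp$total,
               tolerance = 1e-9)
  expect_equal(comp$inflow, comp$direct + comp$retained_inflow)
  expect_equal(comp$outflow, comp$direct + comp$delayed_ejection)
  # components are all exercised by the phantom
  expect_gt(comp$direct, 0)
  expect_gt(comp$retained_inflow, 0)
  expect_gt(comp$delayed_ejection, 0)
  expect_gt(comp$residual, 0)
  cc <- conservation_check(comp)
  expect_lt(abs(cc$relative_difference), 0.05)
  # inflow and outflow each approximate half the cycle volume of the
  # rigid flow-through chamber
  expect_lt(abs(cc$inflow - 12.5) / 12.5, 0.1)
})

test_that("closed static chamber is pure residual volume", {
  ser <- uniform_series(c(0, 0, 0), n = 16, vox = 2.8, n_sl = 8, nf = 4)
  mask <- array(FALSE, dim = c(16, 16, 8)); mask[6:10, 6:10, 3:6] <- TRUE
  inlet <- array(FALSE, dim = dim(mask)); inlet[6, 6:10, 3:6] <- TRUE
  outlet <- array(FALSE, dim = dim(mask)); outlet[10, 6:10, 3:6] <- TRUE
  segs <- chamber_segmentations(mask, mask, inlet, outlet, 4, 2)
  comp <- pathline_decomposition(ser, segs)
  expect_equal(comp$inflow, 0)
  expect_equal(comp$outflow, 0)
  expect_equal(comp$residual, comp$total)
})

test_that("reported component volumes satisfy the clinical identities", {
  tbl <- patient_flow_table()
  c1 <- flow_components(tbl$direct[1], tbl$retained_inflow[1],
                        tbl$delayed_ejection[1], tbl$residual[1])
  expect_equal(c1$inflow, 56)       # 17 + 39
  expect_equal(c1$inflow, tbl$inflow[1])
  expect_equal(c1$outflow, 57)      # 17 + 40, as reported
  c2 <- flow_components(tbl$direct[2], tbl$retained_inflow[2],
                        tbl$delayed_ejection[2], tbl$residual[2])
  expect_equal(c2$outflow, 58)      # 36 + 22
  c3 <- flow_components(tbl$direct[3], tbl$retained_inflow[3],
                        tbl$delayed_ejection[3], tbl$residual[3])
  expect_equal(c3$inflow, 114)      # 66 + 48
  # conservation difference from the reported patient-3 numbers
  cc <- conservation_check(flow_components(66, 48, 45))
  expect_equal(conservation_check(c3)$inflow -
                 tbl$outflow[3], 3)  # 114 - 111
})
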