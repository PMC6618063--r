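test_that("timing formulas reproduce the protocol table values", {
  expect_equal(nominal_temporal_resolution(sequence_params(tr = 12)), 48)
  expect_equal(nominal_temporal_resolution(
    sequence_params(tr = 5.8, te = 3.4, segmentation_factor = 2)), 46.4)
  expect_equal(nominal_temporal_resolution(sequence_params(tr = 10)), 40)
  expect_equal(nominal_scan_time(sequence_params(n_slices_recon = 36)), 460)
  expect_equal(nominal_scan_time(sequence_params(n_slices_recon = 40)), 510)
  expect_equal(nominal_scan_time(
    sequence_params(n_interleaves = 1, n_slices_recon = 1,
                    slice_oversampling = 0)), 1)
})

test_that("designed spiral satisfies hardware and sampling invariants", {
  limits <- gradient_limits(33, 180, 10)
  for (par in list(sequence_params(),                     # full protocol
                   small_params())) {                     # desk scale
    tr <- design_spiral_interleaf(par, limits)
    n_int <- dim(tr$k)[3]
    # starts at the k-space center
    for (m in seq_len(n_int)) expect_equal(tr$k[1, , m], c(0, 0))
    # gradient amplitude and slew within limits, sample-wise
    dt <- tr$raster_time / 1000
    for (m in seq_len(n_int)) {
      g <- tr$g[, , m]
      expect_lte(max(sqrt(g[, 1]^2 + g[, 2]^2)), limits$max_gradient)
      sl <- rbind(g[1, ], diff(g)) / dt
      expect_lte(max(sqrt(sl[, 1]^2 + sl[, 2]^2)), limits$max_slew * 1.001)
    }
    # kmax reached within 1%
    r <- sqrt(tr$k[, 1, 1]^2 + tr$k[, 2, 1]^2)
    expect_lt(abs(max(r) / tr$kmax - 1), 0.01)
    # readout fits the prescribed duration
    expect_lte(tr$readout_time, par$readout_duration)
    # rotational symmetry to machine precision
    for (m in seq_len(n_int)) {
      a <- tr$angles[m]
      rot <- cbind(cos(a) * tr$k[, 1, 1] - sin(a) * tr$k[, 2, 1],
                   sin(a) * tr$k[, 1, 1] + cos(a) * tr$k[, 2, 1])
      expect_lt(max(abs(rot - tr$k[, , m])), 1e-12)
    }
  }
})

test_that("fully sampled core meets the Nyquist criterion", {
  par <- sequence_params()
  tr <- design_spiral_interleaf(par, density = density_profile(0.2, 1))
  r <- sqrt(tr$k[, 1, 1]^2 + tr$k[, 2, 1]^2)
  th <- atan2(tr$k[, 2, 1], tr$k[, 1, 1])
  th_un <- th + 2 * pi * cumsum(c(0, diff(th) < -pi))
  # adjacent-turn radial spacing of the combined set <= n_int / FOV
  rs <- stats::approxfun(th_un, r, rule = 2)
  probe <- seq(0, max(th_un) - 2 * pi, length.out = 200)
  spacing <- rs(probe + 2 * pi) - rs(probe)
  expect_lte(max(spacing), par$n_interleaves / par$fov * 1.02)
})

test_that("uniform-density radii match an independent fine-raster oracle", {
  par <- sequence_params(matrix = 32, fov = 32 * 2.8, n_interleaves = 2,
                         readout_duration = 12)
  limits <- gradient_limits(33, 180, 10)
  tr <- design_spiral_interleaf(par, limits, density_profile(1, 1))
  # oracle: forward-Euler integration of the slew/amplitude-limited
  # Archimedean dynamics at 100x finer steps, written independently
  cc <- par$n_interleaves / (2 * pi * par$fov)
  vmax <- 0.995 * 0.042577478518 * limits$max_gradient
  amax <- 0.995 * 0.042577478518 * limits$max_slew
  dt <- limits$raster_time / 1000 / 100
  th <- 0; om <- 0; rr <- 0
  s_or <- 0; arc <- c(0); rad <- c(0)
  while (rr < tr$kmax) {
    a_re <- -rr * om^2; a_im <- 2 * cc * om^2
    b_re <- cc; b_im <- rr
    b2 <- b_re^2 + b_im^2
    ab <- a_re * b_re + a_im * b_im
    disc <- ab^2 - b2 * ((a_re^2 + a_im^2) - amax^2)
    tdd <- if (disc <= 0) -ab / b2 else (-ab + sqrt(disc)) / b2
    ff <- sqrt(cc^2 + rr^2)
    if (om * ff >= vmax) tdd <- min(tdd, -om^2 * (rr * cc / ff) / ff)
    om <- om + tdd * dt
    th <- th + om * dt
    rnew <- cc * th
    s_or <- s_or + sqrt(cc^2 + rr^2) * om * dt
    rr <- rnew
    arc <- c(arc, s_or); rad <- c(rad, rr)
  }
  # radius as a function of arc length, compared where both defined
  r_design <- sqrt(tr$k[, 1, 1]^2 + tr$k[, 2, 1]^2)
  s_design <- cumsum(c(0, sqrt(diff(tr$k[, 1, 1])^2 + diff(tr$k[, 2, 1])^2)))
  oracle_at <- stats::approxfun(arc, rad, rule = 2)
  sel <- s_design > 0.1 * max(s_design)    # skip the stiff launch
  rel <- abs(r_design[sel] - oracle_at(s_design[sel])) / tr$kmax
  expect_lt(max(rel), 0.01)
})

test_that("infeasible readout durations raise a typed error", {
  par <- sequence_params(readout_duration = 0.3)
  expect_error(design_spiral_interleaf(par),
               class = "spiral4d_infeasible_readout")
})

test_that("cartesian trajectory enumerates lines per the ordering scheme", {
  par <- sequence_params(matrix = 4, fov = 4 * 2.8)
  tr <- cartesian_trajectory(par, ordering = "linear")
  expect_equal(dim(tr$k), c(4, 2, 4))
  expect_equal(tr$order, c(-2, -1, 0, 1))
  # low-high: brute-force enumeration sorted by |ky| then ky
  trc <- cartesian_trajectory(par, ordering = "low_high")
  idx <- c(-2, -1, 0, 1)
  expect_equal(trc$order, idx[order(abs(idx), idx)])
  full <- cartesian_trajectory(sequence_params())
  expect_equal(dim(full$k)[3], 100)
  # every line holds the same kx samples
  expect_equal(full$k[, 1, 1], full$k[, 1, 57])
})

test_that("parameter validation rejects inconsistent protocols", {
  expect_error(sequence_params(n_flow_segments = 3), class = "spiral4d_invalid")
  expect_error(sequence_params(slice_oversampling = -0.1),
               class = "spiral4d_invalid")
  expect_error(gradient_limits(max_slew = 0), class = "spiral4d_invalid")
  expect_error(density_profile(taper_to = 0.5), class = "spiral4d_invalid")
})
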