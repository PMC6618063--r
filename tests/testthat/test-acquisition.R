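test_that("DC sample of the reference segment equals the voxel sum", {
  ks <- small_acquisition()
  ev <- ks$events
  tr <- small_trajectory()
  kz0 <- which(abs(tr$kz) < 1e-12)
  i <- which(ev$interleaf == 1 & ev$kz_index == kz0 & ev$segment == 1)[1]
  dc <- ks$samples[1, ev$row[i]]
  f <- make_phantom(small_spec())
  xs <- axis_coords_t(32, 2.8)
  zs <- axis_coords_t(4, 2.8)
  gg <- expand.grid(x = xs, y = xs, z = zs)
  expect_equal(Mod(dc), sum(f$magnitude(gg$x, gg$y, gg$z)),
               tolerance = 1e-6)
})

test_that("samples match a brute-force direct-DFT oracle", {
  ks <- small_acquisition()
  ev <- ks$events
  tr <- small_trajectory()
  f <- make_phantom(small_spec())
  xs <- axis_coords_t(32, 2.8)
  zs <- axis_coords_t(4, 2.8)
  gg <- expand.grid(x = xs, y = xs, z = zs)
  mag <- f$magnitude(gg$x, gg$y, gg$z)
  uv <- f$unit_velocity(gg$x, gg$y, gg$z)
  venc_m <- 1.2
  set.seed(99)
  probe_ev <- sample(which(ev$segment != 1), 5)
  for (i in probe_ev) {
    e <- ev[i, ]
    q <- f$flux(e$t_since_r, e$rr)
    phi <- pi * uv[, e$segment - 1] * q / venc_m
    img <- mag * exp(1i * phi) *
      exp(-2i * pi * tr$kz[e$kz_index] * gg$z)
    for (s in sample(tr$n_samples, 10)) {
      oracle <- sum(img * exp(-2i * pi * (tr$k[s, 1, e$interleaf] * gg$x +
                                            tr$k[s, 2, e$interleaf] * gg$y)))
      expect_equal(ks$samples[s, e$row], oracle,
                   tolerance = 1e-5)
    }
  }
})

test_that("navigator windows follow the central/outer split", {
  nav <- navigator_config(4, 7, 0.25)
  expect_true(navigator_accept(0, 1, nav, 12))
  # central slice encode: half-window 2 mm
  n_kz <- 12
  central <- order(abs(seq_len(n_kz) - 1 - floor(n_kz / 2)))[1:3]
  expect_false(navigator_accept(2.5, central[1], nav, n_kz))
  expect_true(navigator_accept(2.5, setdiff(seq_len(n_kz), central)[1],
                               nav, n_kz))
  expect_false(navigator_accept(3.6, setdiff(seq_len(n_kz), central)[1],
                                nav, n_kz))
})

test_that("acceptance fraction matches the arcsine closed form", {
  nav <- navigator_config(4, 7, 0.25)
  amp <- 5            # 10 mm peak-to-peak
  trace <- respiratory_trace(amplitude = amp, period = 4000)
  tt <- seq(0, 4000, length.out = 40001)[-1]
  pos <- trace(tt)
  frac <- function(w) mean(abs(pos) <= w / 2)
  expected <- function(w) 2 / pi * asin(pmin(w / 2 / amp, 1))
  expect_lt(abs(frac(4) - expected(4)), 0.02)
  expect_lt(abs(frac(7) - expected(7)), 0.02)
  # and the same fractions through the accept decision itself
  n_kz <- 8
  central <- sort(order(abs(seq_len(n_kz) - 1 - floor(n_kz / 2)))[1:2])
  acc_central <- mean(navigator_accept(pos, central[1], nav, n_kz))
  acc_outer <- mean(navigator_accept(pos, setdiff(1:n_kz, central)[1], nav, n_kz))
  expect_lt(abs(acc_central - expected(4)), 0.02)
  expect_lt(abs(acc_outer - expected(7)), 0.02)
})

test_that("identical seeds give bit-identical sample sets", {
  f <- make_phantom(small_spec(noise_sd = 1))
  tr <- small_trajectory()
  rr <- sample_rr_intervals(900, 30, 300, seed = 5)
  a <- simulate_acquisition(f, tr, small_params(), rr, seed = 6)
  b <- simulate_acquisition(f, tr, small_params(), rr, seed = 6)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
  c <- simulate_acquisition(f, tr, small_params(), rr, seed = 7)
  expect_false(identical(a$samples, c$samples))
})

test_that("every line is acquired despite navigator rejections", {
  f <- make_phantom(small_spec(resp_amplitude = 5))
  tr <- small_trajectory()
  rr <- sample_rr_intervals(900, 30, 2000, seed = 5)
  ks <- simulate_acquisition(f, tr, small_params(), rr,
                             nav = navigator_config(),
                             resp = respiratory_trace(5, 4000), seed = 6)
  got <- unique(ks$events[, c("interleaf", "kz_index")])
  expect_equal(nrow(got), 6 * tr$n_kz)
  expect_lt(ks$efficiency, 1)
  st <- actual_scan_time(ks)
  expect_equal(st$accepted, 6 * tr$n_kz)
  expect_gt(st$beats, st$accepted)
  expect_equal(st$ratio_to_nominal, st$beats / st$accepted)
})

test_that("scan time equals nominal when nothing is rejected", {
  ks <- small_acquisition()
  st <- actual_scan_time(ks)
  expect_equal(st$beats, st$nominal)
  expect_equal(st$ratio_to_nominal, 1)
})

test_that("a fifty-percent-efficiency trace doubles the scan time", {
  f <- make_phantom(small_spec(resp_amplitude = 5))
  tr <- small_trajectory()
  rr <- sample_rr_intervals(900, 0, 3000, seed = 5)
  # square-wave trace inside the window exactly half the time
  sq <- function(t) ifelse((t %/% 900) %% 2 == 0, 0, 50)
  ks <- simulate_acquisition(f, tr, small_params(), rr,
                             nav = navigator_config(), resp = sq, seed = 6)
  st <- actual_scan_time(ks)
  expect_lt(abs(st$ratio_to_nominal - 2), 0.2)
})
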