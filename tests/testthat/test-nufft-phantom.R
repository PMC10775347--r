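test_that("NUFFT matches brute-force DFT summation", {
  set.seed(3)
  n <- 16
  x <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), rep(n, 3))
  co <- matrix(runif(500 * 3, -8, 8), 500, 3)
  s0 <- ndft_type2(x, co, n)
  pl <- nufft_plan(co, n, oversamp = 2, width = 8)
  expect_lt(max(Mod(nufft_type2(x, pl) - s0)) / max(Mod(s0)), 1e-5)
  # the faster pipeline settings stay within simulation-grade accuracy
  pl2 <- nufft_plan(co, n, oversamp = 1.5, width = 5)
  expect_lt(max(Mod(nufft_type2(x, pl2) - s0)) / max(Mod(s0)), 2e-3)
})

test_that("type-1 is the exact adjoint of type-2", {
  set.seed(8)
  n <- 12
  x <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), rep(n, 3))
  co <- matrix(runif(300 * 3, -6, 6), 300, 3)
  pl <- nufft_plan(co, n, oversamp = 1.5, width = 6)
  y <- complex(real = rnorm(300), imaginary = rnorm(300))
  lhs <- sum(Conj(y) * nufft_type2(x, pl))
  rhs <- sum(Conj(nufft_type1(y, pl)) * x)
  scale <- sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2))
  expect_lt(Mod(lhs - rhs) / scale, 1e-5)
})

test_that("energy is preserved through an oversampled Cartesian transform", {
  set.seed(9)
  n <- 12
  x <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), rep(n, 3))
  co <- as.matrix(expand.grid(-6:5, -6:5, -6:5))
  pl <- nufft_plan(co, n, oversamp = 2, width = 8)
  s <- nufft_type2(x, pl)
  # Parseval: ||F x||^2 = N^3 ||x||^2 on the full integer grid
  expect_equal(sum(Mod(s)^2) / (n^3 * sum(Mod(x)^2)), 1, tolerance = 1e-3)
})

test_that("trajectories outside the Nyquist box are rejected", {
  co <- matrix(c(10, 0, 0), 1, 3)
  expect_error(nufft_plan(co, 16), "Nyquist")
})

test_that("phantom generation is seed-reproducible with valid maps", {
  p1 <- make_phantom(24, seed = 11)
  p2 <- make_phantom(24, seed = 11)
  expect_identical(p1$t1_map, p2$t1_map)
  expect_identical(p1$mwf_map, p2$mwf_map)
  expect_identical(p1$b0_map, p2$b0_map)
  expect_true(all(p1$mwf_map >= 0 & p1$mwf_map <= 1))
  expect_true(all(p1$mwf_map[p1$tissue_label != 3L] == 0))
  p3 <- make_phantom(24, seed = 12)
  expect_false(identical(p1$mwf_map, p3$mwf_map))
})

test_that("rasterized label fractions match the analytic geometry", {
  ph <- make_phantom(32, seed = 7)
  fr <- expected_volume_fractions(ph)
  obs <- vapply(0:3, function(l) mean(ph$tissue_label == l), 0)
  expect_true(all(abs(fr - obs) < 0.02))
})

test_that("voxel time series is the stated two-pool mixture", {
  p <- small_protocol()
  ph <- make_phantom(16, seed = 2,
                     config = list(b1_range = c(1, 1),
                                   b0_amplitude_hz = 0))
  # force a pure-tissue and a pure-myelin voxel
  wmv <- which(ph$tissue_label == 3L)
  ph$mwf_map[wmv[1]] <- 0
  ph$mwf_map[wmv[2]] <- 1
  ph$pd_map[wmv[2]] <- 1
  ts <- voxel_timeseries(ph, p)
  ev <- protocol_events(p)
  s_tis <- as.vector(epg_simulate(ev, 750, 60, 1, te = p$te, n_groups = 4))
  s_mye <- as.vector(epg_simulate(ev, 120, 20, 1, te = p$te, n_groups = 4))
  i1 <- match(wmv[1], ts$voxel_index)
  i2 <- match(wmv[2], ts$voxel_index)
  expect_equal(ts$signals[i1, ], ph$pd_map[wmv[1]] * s_tis,
               tolerance = 1e-12)
  expect_equal(ts$signals[i2, ], s_mye, tolerance = 1e-12)
  # pointwise linearity in the myelin fraction
  i3 <- which(ph$mwf_map[ts$voxel_index] > 0 &
                ph$tissue_label[ts$voxel_index] == 3L)[3]
  f <- ph$mwf_map[ts$voxel_index[i3]]
  pd <- ph$pd_map[ts$voxel_index[i3]]
  expect_equal(ts$signals[i3, ],
               pd * (f * s_mye + (1 - f) * s_tis), tolerance = 1e-12)
})

test_that("k-space of a centered point object has flat magnitude", {
  p <- small_protocol()
  shape <- c(16L, 16L, 16L)
  ph <- make_phantom(16, seed = 3, config = list(b0_amplitude_hz = 0))
  ctr <- 16 %/% 2 + 1
  idx <- ((ctr - 1) * 16 + (ctr - 1)) * 16 + ctr
  ts <- list(signals = matrix(1, 1, 80), voxel_index = idx, shape = shape)
  sp <- design_spiral(fov = 16, resolution = 1, undersampling = 2,
                      vd_edge_factor = 2)
  sch <- tgas_schedule(2, 80)
  sens <- array(1 + 0i, c(shape, 1))
  kd <- sample_kspace(ts, ph, p, sch, sp, sens, noise_sigma = 0,
                      oversamp = 2, width = 6)
  mags <- Mod(kd$samples[, 1, 1])
  expect_lt(max(abs(mags - 1)), 1e-3)
})

test_that("noise realizations are seed-deterministic", {
  p <- small_protocol()
  shape <- c(16L, 16L, 16L)
  ph <- make_phantom(16, seed = 3)
  ts <- voxel_timeseries(ph, p)
  sp <- design_spiral(fov = 16, resolution = 1, undersampling = 2,
                      vd_edge_factor = 2)
  sch <- tgas_schedule(2, 80)
  sens <- coil_sensitivities(16, 2)
  k1 <- sample_kspace(ts, ph, p, sch, sp, sens, noise_sigma = 0.01, seed = 5)
  k2 <- sample_kspace(ts, ph, p, sch, sp, sens, noise_sigma = 0.01, seed = 5)
  expect_identical(k1$samples, k2$samples)
  k3 <- sample_kspace(ts, ph, p, sch, sp, sens, noise_sigma = 0.01, seed = 6)
  expect_false(identical(k1$samples, k3$samples))
})

test_that("the configured forward model passes an adjoint test", {
  tiny <- make_tiny_kdata(seed = 21, M = 400, n_t = 8, K = 2)
  cf <- matrix(complex(real = rnorm(512 * 2), imaginary = rnorm(512 * 2)),
               512, 2)
  s <- forward_operator(cf, tiny$basis, tiny$kdata, tiny$sens,
                        oversamp = 2, width = 6)
  y <- array(complex(real = rnorm(length(s)),
                     imaginary = rnorm(length(s))), dim(s))
  xb <- adjoint_operator(y, tiny$basis, tiny$kdata, tiny$sens,
                         oversamp = 2, width = 6)
  lhs <- sum(Conj(y) * s)
  rhs <- sum(Conj(xb) * cf)
  scale <- sqrt(sum(Mod(cf)^2)) * sqrt(sum(Mod(y)^2))
  expect_lt(Mod(lhs - rhs) / scale, 1e-5)
})
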