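test_that("map fitting is self-consistent on projected noiseless atoms", {
  d <- small_dictionary()
  b <- compute_basis(d, 14)
  set.seed(17)
  shape <- c(4L, 4L, 2L)
  nv <- prod(shape)
  picks <- sample(which(d$index$b1 == 1.0), nv, replace = TRUE)
  cf <- d$atoms[picks, ] %*% b$phi            # nv x K projections
  cmaps <- list(c = array(cf, c(shape, 14L)))
  qm <- fit_maps(cmaps, b, d, b1_map = array(1, shape),
                 myelin_correction = FALSE)
  expect_equal(as.vector(qm$t1_map), d$index$t1[picks])
  expect_equal(as.vector(qm$t2_map), d$index$t2[picks])
  expect_equal(as.vector(qm$pd_map), rep(1, nv), tolerance = 1e-3)
  # scaling the coefficients scales PD only
  qm3 <- fit_maps(list(c = array(3 * cf, c(shape, 14L))), b, d,
                  b1_map = array(1, shape), myelin_correction = FALSE)
  expect_equal(as.vector(qm3$pd_map), rep(3, nv), tolerance = 1e-3)
  expect_equal(qm3$t1_map, qm$t1_map)
  expect_equal(qm3$t2_map, qm$t2_map)
  expect_equal(qm3$vista_image, 3 * qm$vista_image, tolerance = 1e-9)
  # the myelin-corrected path is transparent for long-T1 (nulled) atoms
  longp <- sample(which(d$index$b1 == 1.0 & d$index$t1 >= 750), nv,
                  replace = TRUE)
  cfl <- d$atoms[longp, ] %*% b$phi
  qml <- fit_maps(list(c = array(cfl, c(shape, 14L))), b, d,
                  b1_map = array(1, shape), myelin_correction = TRUE)
  # the tiny residual ViSTa amplitude of nulled atoms may move the match
  # by at most one grid step
  expect_lt(max(abs(as.vector(qml$t1_map) - d$index$t1[longp]) /
                  d$index$t1[longp]), 0.08)
  expect_lt(max(abs(as.vector(qml$t2_map) - d$index$t2[longp]) /
                  pmax(d$index$t2[longp], 10)), 0.12)
  expect_equal(as.vector(qml$pd_map), rep(1, nv), tolerance = 2e-2)
})

test_that("fitting without a B1 map warns and proceeds at B1 = 1", {
  d <- small_dictionary()
  b <- compute_basis(d, 14)
  cf <- d$atoms[5, , drop = FALSE] %*% b$phi
  cmaps <- list(c = array(rep(cf, 8), c(2L, 2L, 2L, 14L)))
  expect_warning(fit_maps(cmaps, b, d), "B1")
})

test_that("myelin reference from the dictionary matches direct simulation", {
  d <- small_dictionary()
  mref <- myelin_reference(d)
  expect_true(all(mref$s_myelin > 0 & mref$s_myelin < 1))
  direct <- myelin_reference(NULL, protocol = d$protocol,
                             b1_values = d$grid$b1_values)
  expect_equal(mref$s_myelin, direct$s_myelin, tolerance = 1e-10)
})

test_that("MWF formula is exact, clipped, and scale invariant", {
  mref <- structure(list(b1_values = 1, s_myelin = 0.4),
                    class = "myelin_reference")
  shape <- c(4L, 4L, 4L)
  pd <- array(1, shape)
  # zero ViSTa signal: zero MWF
  expect_true(all(compute_mwf(array(0, shape), pd, mref) == 0))
  # pure myelin voxel: vista = pd * s_myelin gives MWF 1
  mwf <- compute_mwf(array(0.4, shape), pd, mref)
  expect_equal(as.vector(mwf), rep(1, 64), tolerance = 1e-12)
  # joint rescaling of pd and vista leaves MWF unchanged
  v <- array(runif(64, 0, 0.4), shape)
  m1 <- compute_mwf(v, pd, mref)
  m2 <- compute_mwf(2 * v, 2 * pd, mref)
  expect_equal(m1, m2, tolerance = 1e-12)
  # clipping to [0, 1]
  m3 <- compute_mwf(array(10, shape), pd, mref)
  expect_true(all(m3 <= 1 & m3 >= 0))
  # low-PD voxels are treated as background
  pd2 <- pd; pd2[1, 1, 1] <- 1e-6
  m4 <- compute_mwf(v, pd2, mref)
  expect_equal(m4[1, 1, 1], 0)
})

test_that("contrast synthesis nulls and orders signals correctly", {
  shape <- c(2L, 2L, 1L)
  t1 <- array(c(4000, 750, 1300, 120), shape)
  t2 <- array(c(2000, 60, 75, 20), shape)
  pd <- array(1, shape)
  # FLAIR with TI = T1_CSF ln 2 nulls CSF
  fl <- synthesize_contrast(t1, t2, pd, "flair", tr = Inf, te = 80,
                            ti = 4000 * log(2))
  expect_lt(abs(fl[1, 1, 1]), 1e-6)
  expect_gt(abs(fl[2, 1, 1]), 1e-3)
  # T2-weighted signal strictly decreases with TE at fixed pd and T1
  s <- vapply(c(20, 60, 120), function(te)
    synthesize_contrast(t1, t2, pd, "t2w", tr = 6000, te = te)[2, 1, 1], 0)
  expect_true(all(diff(s) < 0))
  # DIR nulls both targeted tissues via the package's own root solver
  nt <- dir_null_times(4000, 1300)
  expect_lt(nt$residual, 1e-10)
  di <- synthesize_contrast(t1, t2, pd, "dir", tr = Inf, te = 10,
                            ti = nt$ti, ti2 = nt$ti2)
  expect_lt(abs(di[1, 1, 1]), 1e-4)       # CSF
  expect_lt(abs(di[1, 2, 1]), 1e-4)       # GM
  expect_gt(abs(di[2, 1, 1]), 1e-3)       # WM survives
  expect_error(synthesize_contrast(t1, t2, pd, "stir"))
})

test_that("quantitative maps round trip through NIfTI within float32", {
  qm <- structure(list(t1_map = array(runif(64, 100, 3000), c(4, 4, 4)),
                       t2_map = array(runif(64, 10, 300), c(4, 4, 4)),
                       pd_map = array(runif(64), c(4, 4, 4)),
                       vista_image = array(runif(64, 0, 0.3), c(4, 4, 4)),
                       mwf_map = array(runif(64, 0, 0.2), c(4, 4, 4))),
                  class = "quant_maps")
  dir <- tempfile()
  write_quant_maps(qm, dir, voxel_size = 1)
  back <- read_quant_maps(dir)
  expect_equal(back$t1_map, qm$t1_map, tolerance = 1e-6)
  expect_equal(back$mwf_map, qm$mwf_map, tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
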