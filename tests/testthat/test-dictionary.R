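test_that("grid validation and atom enumeration behave as specified", {
  expect_error(dict_grid(t1_values = c(100, 100, 200)), "duplicate")
  expect_error(dict_grid(t1_values = numeric(0)), "empty")
  g <- dict_grid()
  ga <- grid_atoms(g)
  n_pairs <- sum(outer(g$t1_values, g$t2_values, ">=") )
  expect_equal(nrow(ga), n_pairs * length(g$b1_values))
  expect_true(all(ga$t2 <= ga$t1))
})

test_that("a singleton dictionary equals the direct simulation", {
  p <- vista_protocol()
  g <- dict_grid(t1_values = 750, t2_values = 60, b1_values = 1.0)
  d <- build_dictionary(g, p)
  s <- simulate_evolution(p, tissue_params(750, 60))
  expect_equal(as.vector(d$atoms[1, ]), s$values, tolerance = 1e-12)
})

test_that("temporal basis is orthonormal with monotone energy capture", {
  d <- small_dictionary()
  b <- compute_basis(d, 14)
  expect_lt(max(abs(crossprod(b$phi) - diag(14))), 1e-10)
  efs <- vapply(c(1, 3, 5, 10, 14, 20), function(k)
    compute_basis(d, k)$energy_fraction, 0)
  expect_true(all(diff(efs) >= -1e-12))
  full <- compute_basis(d, min(dim(d$atoms)))
  expect_equal(full$energy_fraction, 1, tolerance = 1e-10)
  expect_error(compute_basis(d, 0), "out of range")
})

test_that("subspace projection residuals match the retained energy", {
  d <- small_dictionary()
  # energy-weighted (RMS) relative residual equals sqrt(1 - energy) exactly
  res_by_k <- vapply(c(5, 14), function(k) {
    b <- compute_basis(d, k)
    proj <- d$atoms %*% b$phi %*% t(b$phi)
    sqrt(sum((d$atoms - proj)^2) / sum(d$norms^2))
  }, 0)
  b14 <- compute_basis(d, 14)
  expect_lt(res_by_k[2], sqrt(1 - b14$energy_fraction) + 1e-8)
  expect_lt(res_by_k[2], res_by_k[1])
})

test_that("matching recovers scaled atoms, rejects bad B1, flags background", {
  d <- small_dictionary()
  i <- 137
  m <- match_voxel(2.5 * d$atoms[i, ], d, d$index$b1[i])
  expect_equal(c(m$t1, m$t2), c(d$index$t1[i], d$index$t2[i]))
  expect_equal(m$pd_scale, 2.5, tolerance = 1e-9)
  expect_error(match_voxel(d$atoms[1, ], d, 0.4), "outside")
  bg <- match_voxel(rep(0, ncol(d$atoms)), d)
  expect_true(bg$background)
  expect_equal(c(bg$t1, bg$t2, bg$pd_scale), c(0, 0, 0))
})

test_that("noiseless self-match is exact over the small dictionary", {
  d <- small_dictionary()
  b <- compute_basis(d, 14)
  for (bv in d$grid$b1_values) {
    sub <- which(d$index$b1 == bv)
    A <- d$atoms[sub, , drop = FALSE]
    sc <- abs(A %*% t(A)) / d$norms[sub]
    hit <- max.col(t(sc), ties.method = "first")
    expect_identical(hit, seq_along(sub))
  }
})

test_that("matching survives noise at SNR 30 within one grid step", {
  d <- small_dictionary()
  i <- which(d$index$t1 == 120 & d$index$t2 == 20 & d$index$b1 == 0.9)
  a <- d$atoms[i, ]
  sigma <- max(abs(a)) / 30
  set.seed(123)
  ok <- 0
  t1v <- d$grid$t1_values; t2v <- d$grid$t2_values
  step_t1 <- diff(t1v)[findInterval(120, t1v)]
  step_t2 <- diff(t2v)[findInterval(20, t2v)]
  for (trial in 1:100) {
    y <- a + rnorm(length(a), 0, sigma)
    m <- match_voxel(y, d, 0.9)
    if (abs(m$t1 - 120) <= step_t1 && abs(m$t2 - 20) <= step_t2) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("dictionary construction is deterministic and round trips", {
  p <- vista_protocol()
  g <- dict_grid(t1_values = c(100, 500), t2_values = c(20, 60),
                 b1_values = c(0.9, 1.0))
  d1 <- build_dictionary(g, p)
  d2 <- build_dictionary(g, p)
  expect_identical(d1$atoms, d2$atoms)
  f <- tempfile(fileext = ".rds")
  b <- compute_basis(d1, 4)
  write_dictionary(d1, f, basis = b)
  obj <- read_dictionary(f)
  expect_identical(obj$dict$atoms, d1$atoms)
  expect_identical(obj$basis$phi, b$phi)
  expect_true(file.exists(paste0(f, ".json")))
})

test_that("coefficient-space batch matching agrees with direct matching", {
  d <- small_dictionary()
  b <- compute_basis(d, 14)
  set.seed(7)
  picks <- sample(nrow(d$atoms), 25)
  cf <- t(d$atoms[picks, ] %*% b$phi)      # K x n signals (projected atoms)
  res <- match_coefficients(cf, d, b, b1 = d$index$b1[picks])
  direct <- vapply(seq_along(picks), function(j) {
    s <- as.vector(b$phi %*% cf[, j])
    m <- match_voxel(s, d, d$index$b1[picks[j]])
    c(m$t1, m$t2)
  }, c(0, 0))
  expect_equal(res$t1, direct[1, ])
  expect_equal(res$t2, direct[2, ])
})
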