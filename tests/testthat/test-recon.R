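test_that("MFI weights represent bin frequencies exactly and improve with bins", {
  tau <- 1.8 + seq(0, 6, 0.01)
  b0 <- seq(-40, 40, length.out = 64)
  mf <- mfi_weights(b0, tau, mfi_bins = 6)
  # a voxel at a bin frequency gets the unit selector
  j <- 3
  row <- which.min(abs(mf$freqs - mf$bin_freqs[j]))
  sel <- mf$coeffs[row, ]
  unit <- rep(0, 6); unit[j] <- 1
  expect_lt(max(Mod(sel - unit)), 1e-8)
  # error decreases monotonically with the number of bins
  errs <- vapply(2:12, function(nb) mfi_weights(b0, tau, nb)$max_err, 0)
  expect_true(all(diff(errs) <= 1e-10))
  # degenerate zero field: single passthrough bin
  mf0 <- mfi_weights(array(0, c(4, 4, 4)), tau, 4)
  expect_equal(length(mf0$bin_freqs), 1L)
  expect_equal(mf0$max_err, 0)
})

test_that("forward operator is linear and respects degenerate off-resonance", {
  tiny <- make_tiny_kdata(seed = 31, M = 300, n_t = 6, K = 2)
  nv <- prod(tiny$shape)
  z <- matrix(0i, nv, 2)
  expect_true(all(forward_operator(z, tiny$basis, tiny$kdata, tiny$sens) == 0))
  c1 <- matrix(complex(real = rnorm(nv * 2), imaginary = rnorm(nv * 2)), nv, 2)
  c2 <- matrix(complex(real = rnorm(nv * 2), imaginary = rnorm(nv * 2)), nv, 2)
  s1 <- forward_operator(c1, tiny$basis, tiny$kdata, tiny$sens)
  s2 <- forward_operator(c2, tiny$basis, tiny$kdata, tiny$sens)
  s12 <- forward_operator(c1 + c2, tiny$basis, tiny$kdata, tiny$sens)
  expect_lt(max(Mod(s12 - s1 - s2)), 1e-10 * max(Mod(s1)))
  # with b0 = 0 the MFI phase model is the identity
  geom_tau <- tiny$kdata$te + tiny$kdata$tau_offsets_ms
  mf0 <- mfi_weights(tiny$kdata$b0_map, geom_tau, 4)
  s_mfi <- forward_operator(c1, tiny$basis, tiny$kdata, tiny$sens, mfi = mf0)
  expect_lt(max(Mod(s_mfi - s1)), 1e-8 * max(Mod(s1)))
  # rank mismatch is rejected
  expect_error(forward_operator(c1[, 1, drop = FALSE], tiny$basis,
                                tiny$kdata, tiny$sens), "mismatch")
})

test_that("LLR prox matches a dense SVD oracle and shrinks nuclear norm", {
  set.seed(13)
  d <- c(6L, 6L, 6L, 4L)
  x <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  expect_identical(llr_prox(x, 0), x)
  th <- 0.8
  y <- llr_prox(x, th, block_edge = 6L)      # single block
  m <- matrix(x, ncol = 4)
  sv <- svd(m)
  oracle <- sv$u %*% (pmax(sv$d - th, 0) * t(Conj(sv$v)))
  expect_lt(max(Mod(matrix(y, ncol = 4) - oracle)), 1e-8)
  nuc <- function(a) sum(svd(matrix(a, ncol = 4))$d)
  y2 <- llr_prox(x, th, block_edge = 3L, shift = c(1L, 2L, 0L))
  expect_lt(nuc(y2), nuc(x))
  expect_error(llr_prox(x, th, block_edge = 12L), "block larger")
})

test_that("gradient of the weighted data term matches the adjoint formula", {
  tiny <- make_tiny_kdata(seed = 41, M = 400, n_t = 6, K = 2)
  nv <- prod(tiny$shape)
  set.seed(2)
  w <- runif(tiny$M, 0.5, 2)
  cf <- matrix(complex(real = rnorm(nv * 2), imaginary = rnorm(nv * 2)), nv, 2)
  dir <- matrix(complex(real = rnorm(nv * 2), imaginary = rnorm(nv * 2)), nv, 2)
  fobj <- function(cc) {
    r <- forward_operator(cc, tiny$basis, tiny$kdata, tiny$sens,
                          oversamp = 2, width = 6) - tiny$kdata$samples
    0.5 * sum(rep(w, prod(dim(r)[2:3])) * Mod(r)^2)
  }
  r0 <- forward_operator(cf, tiny$basis, tiny$kdata, tiny$sens,
                         oversamp = 2, width = 6) - tiny$kdata$samples
  g <- adjoint_operator(r0, tiny$basis, tiny$kdata, tiny$sens, weights = w,
                        oversamp = 2, width = 6)
  eps <- 1e-4
  num <- (fobj(cf + eps * dir) - fobj(cf - eps * dir)) / (2 * eps)
  ana <- Re(sum(Conj(g) * dir))
  expect_lt(abs(num - ana) / abs(ana), 1e-5)
})

test_that("lambda = 0 reconstruction matches a dense normal-equation solve", {
  tiny <- make_tiny_kdata(seed = 5)         # 8^3, K = 3, 2000 samples
  cfg <- recon_config(lambda_llr = 0, n_iter = 60, precond_degree = 4,
                      use_dcf = FALSE, oversamp = 2, width = 6)
  rec <- subspace_recon(tiny$kdata, tiny$sens, tiny$basis, cfg)
  # dense oracle: assemble H and b explicitly from the high-accuracy
  # operators and solve the normal equations directly
  nv <- prod(tiny$shape); K <- tiny$K
  tk <- vistamrf:::build_toeplitz_kernels(
    tiny$kdata, tiny$basis$phi, rep(1, tiny$M), 2, 6L)
  H <- matrix(0i, nv * K, nv * K)
  for (j in seq_len(nv * K)) {
    e <- matrix(0i, nv, K); e[j] <- 1
    H[, j] <- as.vector(vistamrf:::apply_normal_op(e, tk, tiny$sens,
                                                   tiny$shape))
  }
  b <- adjoint_operator(tiny$kdata$samples, tiny$basis, tiny$kdata,
                        tiny$sens, oversamp = 2, width = 6)
  cdense <- solve(H, as.vector(b))
  chat <- as.vector(matrix(rec$c, ncol = K))
  relerr <- sqrt(sum(Mod(chat - cdense)^2) / sum(Mod(cdense)^2))
  expect_lt(relerr, 1e-4)
})

test_that("fully sampled lambda = 0 recon recovers the time series", {
  # oversampled Cartesian sampling, single flat coil, no noise: the
  # subspace solution reproduces the ground-truth evolutions
  p <- small_protocol()
  ph <- make_phantom(16, seed = 4,
                     config = list(b1_range = c(1, 1), b0_amplitude_hz = 0))
  ts <- voxel_timeseries(ph, p)
  # basis spanning exactly the phantom's evolutions
  ev <- protocol_events(p)
  pool <- epg_simulate(ev, c(120, 750, 1300, 4000), c(20, 60, 75, 2000),
                       rep(1, 4), te = p$te, n_groups = 4)
  sv <- svd(t(pool))
  K <- 4L
  basis <- structure(list(phi = sv$u[, 1:K], k = K,
                          singular_values = sv$d),
                     class = "temporal_basis")
  n_t <- ncol(ts$signals)
  co <- as.matrix(expand.grid(-8:7, -8:7, -8:7))
  shape <- c(16L, 16L, 16L)
  sens <- array(1 + 0i, c(shape, 1))
  kdata <- structure(list(samples = array(0i, c(nrow(co), n_t, 1)),
                          coords3d = co, tau_offsets_ms = rep(0, nrow(co)),
                          shape = shape, voxel_size = 1, fov = 16, te = p$te,
                          noise_sigma = 0, seed = 1,
                          b0_map = array(0, shape),
                          b1_map = array(1, shape), protocol_hash = "c"),
                     class = "kspace_dataset")
  x <- array(0i, shape)
  for (t in seq_len(n_t)) {
    x[] <- 0i
    x[ts$voxel_index] <- ts$signals[, t]
    pl <- nufft_plan(co, 16, oversamp = 2, width = 6)
    kdata$samples[, t, 1] <- nufft_type2(x, pl)
  }
  cfg <- recon_config(lambda_llr = 0, n_iter = 30, precond_degree = 4,
                      use_dcf = FALSE, oversamp = 2, width = 6)
  rec <- subspace_recon(kdata, sens, basis, cfg)
  xhat <- matrix(rec$c, ncol = K) %*% t(basis$phi)   # nvox x n_t
  truth <- matrix(0, prod(shape), n_t)
  truth[ts$voxel_index, ] <- ts$signals
  nrmse <- sqrt(sum(Mod(xhat - truth)^2) / sum(truth^2))
  expect_lt(nrmse, 0.01)
})

test_that("reconstruction is deterministic and objective non-increasing", {
  tiny <- make_tiny_kdata(seed = 51, M = 800, n_t = 10, K = 2)
  cfg <- recon_config(lambda_llr = "auto", llr_block = 4L, n_iter = 8,
                      precond_degree = 2, use_dcf = FALSE,
                      oversamp = 1.5, width = 5)
  r1 <- subspace_recon(tiny$kdata, tiny$sens, tiny$basis, cfg)
  r2 <- subspace_recon(tiny$kdata, tiny$sens, tiny$basis, cfg)
  expect_identical(r1$c, r2$c)
  expect_gt(r1$lambda, 0)
  tr <- r1$objective_trace
  expect_lte(tail(tr, 1), tr[1])
})

test_that("polynomial preconditioning accelerates convergence", {
  tiny <- make_tiny_kdata(seed = 5)
  base <- recon_config(lambda_llr = 0, n_iter = 40, precond_degree = 0,
                       use_dcf = FALSE, oversamp = 2, width = 6)
  rec0 <- subspace_recon(tiny$kdata, tiny$sens, tiny$basis, base)
  pre <- recon_config(lambda_llr = 0, n_iter = 20, precond_degree = 4,
                      use_dcf = FALSE, oversamp = 2, width = 6)
  rec1 <- subspace_recon(tiny$kdata, tiny$sens, tiny$basis, pre)
  target <- tail(rec0$objective_trace, 1)    # objective after 40 iterations
  expect_lte(min(rec1$objective_trace), target)
})
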