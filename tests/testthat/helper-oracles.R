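# Independent oracles used by the test suite.  These deliberately do not
# share code paths with the package implementation.

# Brute-force isochromat Bloch simulator over the same event vocabulary as
# the EPG engine: `n_iso` isochromats uniformly dephased by one full cycle
# per gradient-spoiling event.  Returns the complex mean transverse signal
# at each excitation (decayed to TE).
bloch_simulate <- function(events, t1, t2, b1 = 1, te = 0, n_iso = 2000,
                           n_groups = 1) {
  theta <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  rot <- exp(1i * theta)
  mxy <- complex(n_iso)
  mz <- rep(1, n_iso)
  e2te <- exp(-te / t2)
  n_read <- sum(events$op == 4L)
  out <- complex(n_read * n_groups)
  ir <- 0L
  for (g in seq_len(n_groups)) {
    for (e in seq_len(nrow(events))) {
      op <- events$op[e]
      if (op == 1L) {
        mz <- -mz
      } else if (op == 2L) {
        mxy[] <- 0i; mz[] <- 0
      } else if (op == 3L) {
        tau <- events$param[e]
        mxy <- mxy * exp(-tau / t2)
        mz <- 1 + (mz - 1) * exp(-tau / t1)
      } else if (op == 4L) {
        al <- b1 * events$param[e] * pi / 180
        my <- Im(mxy); mx <- Re(mxy)
        my2 <- cos(al) * my + sin(al) * mz
        mz <- -sin(al) * my + cos(al) * mz
        mxy <- complex(real = mx, imaginary = my2)
        ir <- ir + 1L
        out[ir] <- mean(mxy) * e2te
      } else if (op == 5L) {
        mxy <- mxy * rot
      }
    }
  }
  out
}

# events of a plain gradient-spoiled (FISP) subsequence
fisp_events <- function(fa_train, tr) {
  n <- length(fa_train)
  data.frame(op = rep(c(4L, 3L, 5L), n),
             param = as.vector(rbind(fa_train, tr, 0)))
}

# spherical-cap discrepancy of a set of unit vectors against uniform area
cap_discrepancy <- function(normals, n_caps = 300, cap_deg = 30,
                            seed = 42) {
  set.seed(seed)
  u <- matrix(rnorm(n_caps * 3), n_caps)
  u <- u / sqrt(rowSums(u^2))
  co <- cos(cap_deg * pi / 180)
  area <- (1 - co) / 2
  max(abs(colMeans(tcrossprod(normals, u) > co) - area))
}

# spherical Fibonacci points: the golden-means reference schedule
fibonacci_normals <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  th <- 2 * pi * i * 0.38196601125
  cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
}

schedule_normals <- function(sch) {
  t(apply(sch$rotations, 3, function(m) m %*% c(0, 0, 1)))
}

# well-posed tiny subspace instance: random 3D coordinates shared by all
# time points (k-space cube fully covered), random orthonormal basis
make_tiny_kdata <- function(seed = 5, shape = 8L, n_t = 20L, K = 3L,
                            M = 2000L, n_coils = 2L, b0 = NULL) {
  set.seed(seed)
  shape <- rep_len(as.integer(shape), 3L)
  co3 <- matrix(runif(M * 3, -shape[1] / 2, shape[1] / 2), M, 3)
  phi <- qr.Q(qr(matrix(rnorm(n_t * K), n_t)))
  basis <- structure(list(phi = phi, k = K, singular_values = rep(1, K)),
                     class = "temporal_basis")
  sens <- coil_sensitivities(shape, n_coils)
  kdata <- structure(list(
    samples = array(0i, c(M, n_t, n_coils)), coords3d = co3,
    tau_offsets_ms = seq(0, 3, length.out = M),
    shape = shape, voxel_size = 1, fov = shape[1], te = 1.8,
    noise_sigma = 0, seed = seed,
    b0_map = if (is.null(b0)) array(0, shape) else b0,
    b1_map = array(1, shape), protocol_hash = "tiny"),
    class = "kspace_dataset")
  nvox <- prod(shape)
  ctrue <- matrix(complex(real = rnorm(nvox * K),
                          imaginary = rnorm(nvox * K)), nvox, K)
  kdata$samples <- forward_operator(ctrue, basis, kdata, sens,
                                    oversamp = 2, width = 6)
  list(kdata = kdata, basis = basis, sens = sens, ctrue = ctrue,
       shape = shape, K = K, M = M)
}

# small dictionary shared across test files (memoised)
.fixture_env <- new.env(parent = emptyenv())

small_protocol <- function() {
  vista_protocol(n_vista_blocks = 2L, n_vista_timepoints_per_block = 10L,
                 n_mrf_timepoints = 60L, mrf_inversion_index = 20L,
                 fa_train = default_fa_train("ramp", 80L))
}

small_dictionary <- function() {
  if (is.null(.fixture_env$small_dict)) {
    g <- dict_grid(t1_values = c(seq(60, 300, 20), seq(350, 1500, 50)),
                   t2_values = c(seq(10, 100, 5), 150, 200),
                   b1_values = c(0.85, 0.9, 0.95, 1.0, 1.05))
    .fixture_env$small_dict <- build_dictionary(g, vista_protocol())
  }
  .fixture_env$small_dict
}

# full default dictionary + basis, built once and shared by the
# acceptance-level tests
full_dictionary <- function() {
  if (is.null(.fixture_env$full_dict)) {
    .fixture_env$full_dict <- build_dictionary(dict_grid(), vista_protocol())
  }
  .fixture_env$full_dict
}

full_basis <- function() {
  if (is.null(.fixture_env$full_basis)) {
    .fixture_env$full_basis <- compute_basis(full_dictionary(), 14L)
  }
  .fixture_env$full_basis
}
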