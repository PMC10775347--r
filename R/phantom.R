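#' Digital two-compartment brain phantom
#'
#' Nested-ellipsoid brain-like geometry: an outer CSF shell, a gray-matter
#' shell, a white-matter core and two ventricular CSF cavities, on a
#' centered grid.  Each voxel carries a tissue pool (t1/t2/pd per label) and
#' — inside white matter — a myelin-water fraction drawn from a smooth
#' random field in [0.05, 0.18].  B0 (Hz) and B1+ (dimensionless) are
#' spatially smooth low-order polynomial fields.  Fully reproducible from
#' the seed.
#'
#' @param shape matrix size (scalar or length-3, >= 16 per axis).
#' @param seed integer seed.
#' @param config optional overrides: list with any of `t1` (named ms),
#'   `t2`, `pd`, `mwf_range`, `b0_amplitude_hz`, `b1_range`,
#'   `radii` (fractions of the half-FOV for head/brain/wm boundaries).
#' @return object of class `digital_phantom` with per-voxel arrays
#'   `tissue_label` (0 bg, 1 csf, 2 gm, 3 wm), `t1_map`, `t2_map`, `pd_map`,
#'   `mwf_map`, `b0_map`, `b1_map`, plus `shape`, `seed`, `config`.
#' @export
make_phantom <- function(shape = 32, seed = 1L, config = list()) {
  shape <- rep_len(as.integer(shape), 3L)
  if (any(shape < 16)) stop("shape must be >= 16 per axis")
  cfg <- utils::modifyList(list(
    t1 = c(csf = 4000, gm = 1300, wm = 750),
    t2 = c(csf = 2000, gm = 75, wm = 60),
    pd = c(csf = 1.00, gm = 0.86, wm = 0.77),
    mwf_range = c(0.05, 0.18),
    b0_amplitude_hz = 30,
    b1_range = c(0.9, 1.1),
    radii = c(head = 0.92, brain = 0.80, wm = 0.62),
    ventricle_radius = 0.16
  ), config)

  set.seed(seed)
  ax <- lapply(shape, function(n) (seq_len(n) - 1 - n %/% 2) / (n / 2))
  X <- array(rep(ax[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)

  jit <- function() 1 + stats::runif(3, -0.04, 0.04)
  rh <- cfg$radii["head"] * jit()
  rb <- cfg$radii["brain"] * jit()
  rw <- cfg$radii["wm"] * jit()
  e <- function(r, cx = c(0, 0, 0), squash = c(1, 1, 1)) {
    ((X - cx[1]) / (r[1] * squash[1]))^2 +
      ((Y - cx[2]) / (r[2] * squash[2]))^2 +
      ((Z - cx[3]) / (r[3] * squash[3]))^2
  }
  lab <- array(0L, shape)
  lab[e(rh) <= 1] <- 1L                              # CSF shell
  lab[e(rb, squash = c(1, 0.95, 0.9)) <= 1] <- 2L    # gray matter
  lab[e(rw, squash = c(1, 0.9, 0.85)) <= 1] <- 3L    # white matter
  vr <- cfg$ventricle_radius
  for (sgn in c(-1, 1)) {                            # ventricles
    lab[e(rep(vr, 3), cx = c(0.22 * sgn, 0.05, 0.1),
          squash = c(1, 1.6, 1.2)) <= 1 & lab == 3L] <- 1L
  }

  pick <- function(tab) {
    m <- array(0, shape)
    m[lab == 1L] <- tab["csf"]; m[lab == 2L] <- tab["gm"]
    m[lab == 3L] <- tab["wm"]
    m
  }
  t1 <- pick(cfg$t1); t2 <- pick(cfg$t2); pd <- pick(cfg$pd)

  smooth_field <- function(lo, hi) {
    # random low-order polynomial, rescaled into [lo, hi]
    co <- stats::rnorm(10)
    f <- co[1] + co[2] * X + co[3] * Y + co[4] * Z + co[5] * X * Y +
      co[6] * X * Z + co[7] * Y * Z + co[8] * X^2 + co[9] * Y^2 + co[10] * Z^2
    rng <- range(f)
    lo + (hi - lo) * (f - rng[1]) / (rng[2] - rng[1])
  }
  mwf <- array(0, shape)
  mf <- smooth_field(0, 1)
  wmv <- lab == 3L
  if (any(wmv)) {
    # rescale over the WM voxels so WM spans the configured range
    fw <- mf[wmv]
    rngw <- range(fw)
    span <- if (diff(rngw) > 0) (fw - rngw[1]) / diff(rngw) else 0.5
    mwf[wmv] <- cfg$mwf_range[1] + diff(cfg$mwf_range) * span
  }
  b0 <- smooth_field(-cfg$b0_amplitude_hz, cfg$b0_amplitude_hz)
  b1 <- smooth_field(cfg$b1_range[1], cfg$b1_range[2])

  structure(list(shape = shape, tissue_label = lab, t1_map = t1,
                 t2_map = t2, pd_map = pd, mwf_map = mwf,
                 b0_map = b0, b1_map = b1, seed = as.integer(seed),
                 config = cfg),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  n <- prod(x$shape)
  cat("digital_phantom:", paste(x$shape, collapse = "x"), "voxels, seed",
      x$seed, "\n")
  for (l in 0:3) {
    cat(sprintf("  %-4s %5.1f%%\n", c("bg", "csf", "gm", "wm")[l + 1],
                100 * sum(x$tissue_label == l) / n))
  }
  invisible(x)
}

#' Smooth complex coil sensitivities
#'
#' Low-order complex polynomial fields for `n_coils` elements arranged
#' around the object, each with a linear + quadratic magnitude profile
#' toward its position and a smooth linear phase; deterministic.
#'
#' @param shape matrix size (scalar or length-3).
#' @param n_coils number of coils (default 8).
#' @return object of class `coil_sens`: complex array
#'   `shape x n_coils`.
#' @export
coil_sensitivities <- function(shape = 32, n_coils = 8L) {
  shape <- rep_len(as.integer(shape), 3L)
  ax <- lapply(shape, function(n) (seq_len(n) - 1 - n %/% 2) / (n / 2))
  X <- array(rep(ax[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  S <- array(0i, c(shape, n_coils))
  for (j in seq_len(n_coils)) {
    al <- 2 * pi * (j - 1) / n_coils
    u <- X * cos(al) + Y * sin(al) + 0.15 * Z * ((-1)^j)
    mag <- 0.45 + 0.45 * u + 0.22 * u^2
    ph <- 0.9 * (Y * cos(al) - X * sin(al)) + al / 3
    S[, , , j] <- mag * exp(1i * ph)
  }
  structure(S, class = "coil_sens")
}

#' Two-compartment per-voxel signal evolutions
#'
#' For every non-background voxel,
#' `signal = pd * (mwf * S(120, 20, b1) + (1 - mwf) * S(t1, t2, b1))`
#' with `S` the EPG evolution at the voxel's B1+ (no exchange or
#' magnetization transfer).  B1 is quantized to `b1_step` for batching.
#'
#' @param phantom a [make_phantom()] phantom.
#' @param protocol a [vista_protocol()].
#' @param myelin_t1,myelin_t2 myelin-water pool relaxation times (ms).
#' @param b1_step quantization of the B1 map for EPG batching.
#' @param n_settle_groups,n_orders EPG settings.
#' @return list with `signals` (matrix `n_nonbackground x n_timepoints`),
#'   `voxel_index` (linear indices into the phantom arrays), `shape`.
#' @export
voxel_timeseries <- function(phantom, protocol, myelin_t1 = 120,
                             myelin_t2 = 20, b1_step = 0.0025,
                             n_settle_groups = 3L, n_orders = 40L) {
  stopifnot(inherits(phantom, "digital_phantom"))
  validate_protocol(protocol)
  vox <- which(phantom$tissue_label > 0L)
  b1q <- round(phantom$b1_map[vox] / b1_step) * b1_step
  key <- paste(phantom$t1_map[vox], phantom$t2_map[vox], b1q)
  uk <- !duplicated(key)
  ut1 <- phantom$t1_map[vox][uk]; ut2 <- phantom$t2_map[vox][uk]
  ub1 <- b1q[uk]
  ukey <- key[uk]
  ev <- protocol_events(protocol)
  tis <- epg_simulate(ev, ut1, ut2, ub1, te = protocol$te,
                      n_orders = n_orders, n_groups = n_settle_groups + 1L)
  ub1m <- sort(unique(ub1))
  mye <- epg_simulate(ev, rep(myelin_t1, length(ub1m)),
                      rep(myelin_t2, length(ub1m)), ub1m, te = protocol$te,
                      n_orders = n_orders, n_groups = n_settle_groups + 1L)
  ti <- match(key, ukey)
  mi <- match(b1q, ub1m)
  mwf <- phantom$mwf_map[vox]
  pd <- phantom$pd_map[vox]
  signals <- (pd * mwf) * mye[mi, , drop = FALSE] +
    (pd * (1 - mwf)) * tis[ti, , drop = FALSE]
  list(signals = signals, voxel_index = vox, shape = phantom$shape)
}

# linear-interpolation time-segmentation weights for off-resonance:
# returns segment times tau (ms) and a M x L weight matrix over sample times
time_segments <- function(times_ms, n_segments) {
  if (n_segments < 2) {
    return(list(tau = mean(range(times_ms)),
                w = matrix(1, length(times_ms), 1)))
  }
  tau <- seq(min(times_ms), max(times_ms), length.out = n_segments)
  w <- matrix(0, length(times_ms), n_segments)
  dt <- diff(tau)[1]
  j <- pmin(pmax(floor((times_ms - tau[1]) / dt) + 1, 1), n_segments - 1)
  fr <- (times_ms - tau[j]) / dt
  w[cbind(seq_along(j), j)] <- 1 - fr
  w[cbind(seq_along(j), j + 1)] <- fr
  list(tau = tau, w = w)
}

#' Simulate undersampled multi-coil spiral-projection k-space
#'
#' Forward model per time point: coil sensitivities, off-resonance phase
#' accrual `exp(2 pi i b0 (TE + t_sample))` (piecewise-linear time
#' segmentation of the readout), non-uniform Fourier transform at the
#' TGAS-rotated spiral coordinates of every acquisition group, plus seeded
#' complex Gaussian noise (standard deviation `noise_sigma` per real and
#' imaginary component).
#'
#' @param ts result of [voxel_timeseries()].
#' @param phantom the phantom (supplies b0 and geometry).
#' @param protocol the sequence protocol (TE).
#' @param schedule a [tgas_schedule()] with `n_tr_per_group` equal to the
#'   number of time points.
#' @param spiral a [design_spiral()] readout; its `fov` must equal
#'   `shape * voxel_size`.
#' @param sens a [coil_sensitivities()] array.
#' @param noise_sigma complex noise standard deviation per component.
#' @param seed noise seed.
#' @param voxel_size voxel edge in mm (with `shape` defines the FOV).
#' @param oversamp,width NUFFT accuracy parameters.
#' @param n_time_segments off-resonance time segments (`"auto"`: one per
#'   0.05 cycles of maximum accrual, at least 2).
#' @return object of class `kspace_dataset`.
#' @export
sample_kspace <- function(ts, phantom, protocol, schedule, spiral, sens,
                          noise_sigma = 0, seed = 1L, voxel_size = 1,
                          oversamp = 1.25, width = 5L,
                          n_time_segments = "auto") {
  shape <- ts$shape
  n_t <- ncol(ts$signals)
  if (schedule$n_tr_per_group != n_t) {
    stop("schedule n_tr_per_group must equal the number of time points")
  }
  fov <- shape[1] * voxel_size
  kmax_box <- max(abs(spiral$k_samples)) * fov
  if (kmax_box > shape[1] / 2 + 1e-9) {
    stop("trajectory outside the Nyquist box of the phantom grid")
  }
  tau_all <- protocol$te + spiral$times_ms
  if (identical(n_time_segments, "auto")) {
    acc <- max(abs(phantom$b0_map)) * diff(range(tau_all)) / 1000
    n_time_segments <- max(2L, ceiling(acc / 0.1))
  }
  seg <- time_segments(tau_all, n_time_segments)
  L <- length(seg$tau)
  n_coil <- dim(sens)[4]
  n_g <- schedule$n_groups
  m_arm <- nrow(spiral$k_samples)

  vox <- ts$voxel_index
  b0v <- phantom$b0_map[vox]
  samples <- array(0i, c(m_arm * n_g, n_t, n_coil))

  # one prototype plan supplies the grid geometry; per-time-point plans
  # only swap coordinates
  pl0 <- nufft_plan(matrix(0, 1, 3), shape, oversamp = oversamp,
                    width = width)
  ng <- pl0$ng
  # linear indices of the phantom voxels in the padded grid + apodization
  ai <- arrayInd(vox, shape)
  gidx <- pl0$embed[[1]][ai[, 1]] +
    (pl0$embed[[2]][ai[, 2]] - 1L) * ng[1] +
    (pl0$embed[[3]][ai[, 3]] - 1L) * ng[1] * ng[2]
  av <- pl0$apod[[1]][ai[, 1]] * pl0$apod[[2]][ai[, 2]] *
    pl0$apod[[3]][ai[, 3]]
  # spatial modulators per (coil, segment), restricted to the support
  mods <- vector("list", n_coil * L)
  for (cc in seq_len(n_coil)) {
    sv <- sens[, , , cc][vox]
    for (l in seq_len(L)) {
      mods[[(cc - 1) * L + l]] <- sv * exp(2i * pi * b0v * seg$tau[l] / 1000)
    }
  }
  g <- array(0i, ng)
  beta <- mean(pl0$beta)
  for (t in seq_len(n_t)) {
    co <- do.call(rbind, lapply(seq_len(n_g), function(gg) {
      rotate_spiral(spiral, schedule$rotations[, , (gg - 1) * n_t + t]) * fov
    }))
    if (max(abs(co)) > shape[1] / 2 + 1e-9) {
      stop("trajectory outside the Nyquist box of the phantom grid")
    }
    cgrid <- t(co * rep(ng / shape, each = nrow(co)))
    wseg <- seg$w[rep(seq_len(m_arm), n_g), , drop = FALSE]
    base <- ts$signals[, t] / av
    for (cc in seq_len(n_coil)) {
      acc <- complex(m_arm * n_g)
      for (l in seq_len(L)) {
        g[gidx] <- base * mods[[(cc - 1) * L + l]]
        G <- fft(g)
        acc <- acc + wseg[, l] *
          kb_interp3_cpp(as.vector(G), ng, cgrid, pl0$width, beta)
      }
      samples[, t, cc] <- acc
    }
    g[gidx] <- 0i
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    nsl <- m_arm * n_g * n_t
    for (cc in seq_len(n_coil)) {   # per-coil chunks bound the memory peak
      samples[, , cc] <- samples[, , cc] +
        complex(real = rnorm(nsl, 0, noise_sigma),
                imaginary = rnorm(nsl, 0, noise_sigma))
    }
  }
  structure(list(samples = samples, spiral = spiral, schedule = schedule,
                 shape = shape, voxel_size = voxel_size, fov = fov,
                 te = protocol$te, noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 b0_map = phantom$b0_map, b1_map = phantom$b1_map,
                 protocol_hash = protocol_hash(protocol)),
            class = "kspace_dataset")
}

#' @export
print.kspace_dataset <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "kspace_dataset: %d samples/arm x %d groups, %d time points, %d coils\n",
    nrow(x$spiral$k_samples), x$schedule$n_groups, d[2], d[3]))
  cat(sprintf("  matrix %s, voxel %g mm, noise sigma %g, seed %d\n",
              paste(x$shape, collapse = "x"), x$voxel_size, x$noise_sigma,
              x$seed))
  invisible(x)
}

#' Write / read the k-space container
#'
#' Serialized RDS payload with a JSON sidecar manifest (schema version,
#' shapes, seed, noise level, protocol hash).
#'
#' @param kdata a [sample_kspace()] dataset.
#' @param path output `.rds` path.
#' @export
write_kspace <- function(kdata, path) {
  stopifnot(inherits(kdata, "kspace_dataset"))
  saveRDS(list(schema = "vistamrf-kspace-1", kdata = kdata), path)
  d <- dim(kdata$samples)
  jsonlite::write_json(list(schema = "vistamrf-kspace-1",
                            n_samples = d[1], n_timepoints = d[2],
                            n_coils = d[3],
                            shape = kdata$shape, seed = kdata$seed,
                            noise_sigma = kdata$noise_sigma,
                            protocol_hash = kdata$protocol_hash),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "vistamrf-kspace-1")) {
    stop("not a vistamrf k-space container")
  }
  obj$kdata
}

#' Analytic volume fractions of the phantom geometry
#'
#' Expected voxel fractions of each label from the ellipsoid volumes of the
#' same seeded geometry, for validating the rasterized label histogram.
#'
#' @param phantom a [make_phantom()] result.
#' @return named vector of expected fractions (bg/csf/gm/wm).
#' @export
expected_volume_fractions <- function(phantom) {
  cfg <- phantom$config
  set.seed(phantom$seed)
  jit <- function() 1 + stats::runif(3, -0.04, 0.04)
  rh <- cfg$radii["head"] * jit()
  rb <- cfg$radii["brain"] * jit() * c(1, 0.95, 0.9)
  rw <- cfg$radii["wm"] * jit() * c(1, 0.9, 0.85)
  vol <- function(r) pi / 6 * prod(r)      # ellipsoid volume / full box
  vv <- 2 * vol(rep(cfg$ventricle_radius, 3) * c(1, 1.6, 1.2))
  c(bg = 1 - vol(rh), csf = vol(rh) - vol(rb) + vv,
    gm = vol(rb) - vol(rw), wm = vol(rw) - vv)
}
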