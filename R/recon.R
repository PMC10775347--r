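#' Reconstruction configuration
#'
#' @param lambda_llr locally-low-rank regularization weight; `"auto"` sets
#'   it to 0.01 x the largest casorati singular value of the zero-filled
#'   adjoint reconstruction.
#' @param llr_block cubic block edge in voxels.
#' @param n_iter FISTA iterations.
#' @param precond_degree Chebyshev polynomial preconditioner degree
#'   (0 = off).
#' @param use_dcf apply Pipe-Menon density-compensation weights in the data
#'   term.
#' @param dcf_power exponent on the density-compensation weights (1 = full
#'   compensation, best conditioning; smaller values trade convergence
#'   speed against less noise amplification at sparsely sampled high
#'   frequencies).
#' @param mfi_bins off-resonance correction bins (0 = off); applied as
#'   conjugate-phase multi-frequency demodulation of the adjoint data term.
#' @param step_size `"auto"` (power-iteration Lipschitz estimate x 0.95) or
#'   a numeric value.
#' @param random_shift_seed seed of the per-iteration cyclic LLR block
#'   shifts.
#' @param oversamp,width gridding accuracy of the reconstruction operators.
#' @param toeplitz_factor embedding grid factor of the Toeplitz normal
#'   operator (2 = exact; smaller trades PSF-tail aliasing at the image
#'   edges for speed).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(lambda_llr = "auto", llr_block = 8L, n_iter = 30L,
                         precond_degree = 4L, use_dcf = TRUE, mfi_bins = 0L,
                         step_size = "auto", random_shift_seed = 1L,
                         oversamp = 1.25, width = 5L, toeplitz_factor = 2,
                         dcf_power = 1) {
  if (is.numeric(lambda_llr) && lambda_llr < 0) stop("lambda_llr must be >= 0")
  if (llr_block < 2) stop("llr_block must be >= 2")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(lambda_llr = lambda_llr, llr_block = as.integer(llr_block),
                 n_iter = as.integer(n_iter),
                 precond_degree = as.integer(precond_degree),
                 use_dcf = use_dcf, mfi_bins = as.integer(mfi_bins),
                 step_size = step_size,
                 random_shift_seed = as.integer(random_shift_seed),
                 oversamp = oversamp, width = as.integer(width),
                 toeplitz_factor = toeplitz_factor,
                 dcf_power = dcf_power),
            class = "recon_config")
}

#' Multi-frequency interpolation (MFI) weights for off-resonance
#'
#' Bin frequencies span the off-resonance range; per-voxel least-squares
#' coefficients approximate `exp(2 pi i f tau)` over the readout times by a
#' combination of the bin phase functions.
#'
#' @param b0_map off-resonance values (Hz), any shape.
#' @param readout_times_ms sample times tau (ms, including TE).
#' @param mfi_bins number of bins (>= 2 unless the field is identically
#'   zero, which degenerates to a single passthrough bin).
#' @param freq_step quantization of voxel frequencies (Hz) for the
#'   coefficient table.
#' @return list with `bin_freqs` (Hz), `coeffs` (`n_freqs x bins` complex
#'   table), `freqs` (table row frequencies), `voxel_bin` (function mapping
#'   frequencies to table rows), `max_err` (worst-case approximation error
#'   of a unit phasor).
#' @export
mfi_weights <- function(b0_map, readout_times_ms, mfi_bins,
                        freq_step = 0.5) {
  rng <- range(b0_map)
  if (diff(rng) == 0 && rng[1] == 0) {
    f <- 0
    return(list(bin_freqs = 0,
                coeffs = matrix(1 + 0i, 1, 1), freqs = 0,
                voxel_bin = function(fr) rep(1L, length(fr)),
                max_err = 0))
  }
  if (mfi_bins < 2) stop("mfi_bins must be >= 2 when off-resonance is present")
  bf <- seq(rng[1], rng[2], length.out = mfi_bins)
  tau <- readout_times_ms / 1000
  E <- exp(2i * pi * outer(tau, bf))           # M x bins
  freqs <- seq(floor(rng[1] / freq_step), ceiling(rng[2] / freq_step)) * freq_step
  Tg <- exp(2i * pi * outer(tau, freqs))       # M x n_freqs
  # least squares via QR (the bin phasors grow collinear for many bins)
  co <- t(qr.coef(qr(E), Tg))
  co[is.na(co)] <- 0
  resid <- Tg - E %*% t(co)
  max_err <- max(sqrt(colSums(Mod(resid)^2) / length(tau)))
  voxel_bin <- function(fr) {
    pmin(pmax(round((fr - freqs[1]) / freq_step) + 1L, 1L), length(freqs))
  }
  list(bin_freqs = bf, coeffs = co, freqs = freqs, voxel_bin = voxel_bin,
       max_err = max_err)
}

# geometry bundle: per-timepoint 3D coordinates in cycles/FOV.  A dataset
# may carry explicit coordinates in `coords3d` (matrix shared by all time
# points, or a list per time point); otherwise they are rebuilt from the
# spiral readout and the rotation schedule.
recon_geometry <- function(kdata) {
  n_t <- dim(kdata$samples)[2]
  if (!is.null(kdata$coords3d)) {
    co <- kdata$coords3d
    first <- if (is.list(co)) co[[1]] else co
    return(list(n_t = n_t, n_g = 1L, m_arm = nrow(first),
                tau_ms = kdata$te + kdata$tau_offsets_ms %||%
                  rep(0, nrow(first)),
                coords_t = if (is.list(co)) function(t) co[[t]]
                           else function(t) co))
  }
  n_g <- kdata$schedule$n_groups
  list(n_t = n_t, n_g = n_g,
       m_arm = nrow(kdata$spiral$k_samples),
       tau_ms = kdata$te + kdata$spiral$times_ms,
       coords_t = function(t) {
         do.call(rbind, lapply(seq_len(n_g), function(g) {
           rotate_spiral(kdata$spiral,
                         kdata$schedule$rotations[, , (g - 1) * n_t + t]) *
             kdata$fov
         }))
       })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Explicit subspace forward operator
#'
#' Predicts k-space from coefficient maps: per time point `t`,
#' `x_t = sum_k phi[t, k] c_k`, multiplied by coil sensitivities and the MFI
#' off-resonance phase model, then transformed at the time point's rotated
#' spiral coordinates.  Linear in `c`.  This explicit path is used for
#' simulation-grade checks and small problems; [subspace_recon()] uses a
#' Toeplitz-embedded normal operator instead.
#'
#' @param cf complex matrix `n_voxels x K` of coefficient maps.
#' @param basis a [compute_basis()] basis (its first `K` columns are used).
#' @param kdata a [sample_kspace()] dataset supplying geometry.
#' @param sens coil sensitivity array.
#' @param mfi optional [mfi_weights()] result (`NULL` = no off-resonance
#'   model).
#' @param oversamp,width gridding accuracy.
#' @return complex array shaped like `kdata$samples`.
#' @export
forward_operator <- function(cf, basis, kdata, sens, mfi = NULL,
                             oversamp = 1.5, width = 6L) {
  geom <- recon_geometry(kdata)
  shape <- kdata$shape
  K <- ncol(cf)
  if (K != basis$k) stop("coefficient / basis rank mismatch")
  phi <- basis$phi
  n_coil <- dim(sens)[4]
  out <- array(0i, dim(kdata$samples))
  nb <- if (is.null(mfi)) 1L else length(mfi$bin_freqs)
  if (!is.null(mfi)) {
    cvox <- mfi$coeffs[mfi$voxel_bin(as.vector(kdata$b0_map)), , drop = FALSE]
  }
  x <- array(0i, shape)
  for (t in seq_len(geom$n_t)) {
    pl <- nufft_plan(geom$coords_t(t), shape, oversamp = oversamp,
                     width = width)
    xt <- array(as.vector(cf %*% phi[t, ]), shape)
    for (cc in seq_len(n_coil)) {
      xs <- xt * sens[, , , cc]
      if (is.null(mfi)) {
        out[, t, cc] <- nufft_type2(xs, pl)
      } else {
        acc <- complex(geom$m_arm * geom$n_g)
        for (j in seq_len(nb)) {
          x[] <- xs * array(cvox[, j], shape)
          dem <- exp(2i * pi * mfi$bin_freqs[j] *
                       rep(geom$tau_ms, geom$n_g) / 1000)
          acc <- acc + dem * nufft_type2(x, pl)
        }
        out[, t, cc] <- acc
      }
    }
  }
  out
}

#' Explicit subspace adjoint operator
#'
#' Exact adjoint of [forward_operator()] (with conjugate MFI demodulation
#' when an off-resonance model is supplied), optionally with per-sample
#' weights.
#'
#' @param samples complex array shaped like `kdata$samples`.
#' @param weights optional per-sample weight vector (length samples/arm x
#'   groups) applied before the adjoint.
#' @inheritParams forward_operator
#' @return complex matrix `n_voxels x K`.
#' @export
adjoint_operator <- function(samples, basis, kdata, sens, mfi = NULL,
                             weights = NULL, oversamp = 1.5, width = 6L) {
  geom <- recon_geometry(kdata)
  shape <- kdata$shape
  K <- basis$k
  phi <- basis$phi
  n_coil <- dim(sens)[4]
  nvox <- prod(shape)
  out <- matrix(0i, nvox, K)
  nb <- if (is.null(mfi)) 1L else length(mfi$bin_freqs)
  if (!is.null(mfi)) {
    cvox <- Conj(mfi$coeffs[mfi$voxel_bin(as.vector(kdata$b0_map)), ,
                            drop = FALSE])
    tau <- if (length(geom$tau_ms) == geom$m_arm) {
      rep(geom$tau_ms, geom$n_g)
    } else geom$tau_ms
    dems <- lapply(seq_len(nb), function(j) {
      exp(-2i * pi * mfi$bin_freqs[j] * tau / 1000)
    })
  }
  sconj <- lapply(seq_len(n_coil), function(cc) Conj(as.vector(sens[, , , cc])))
  for (t in seq_len(geom$n_t)) {
    pl <- nufft_plan(geom$coords_t(t), shape, oversamp = oversamp,
                     width = width)
    xt <- complex(nvox)
    for (cc in seq_len(n_coil)) {
      s <- samples[, t, cc]
      if (!is.null(weights)) s <- s * weights
      if (is.null(mfi)) {
        xb <- as.vector(nufft_type1(s, pl))
      } else {
        xb <- complex(nvox)
        for (j in seq_len(nb)) {
          xb <- xb + cvox[, j] * as.vector(nufft_type1(dems[[j]] * s, pl))
        }
      }
      xt <- xt + xb * sconj[[cc]]
    }
    out <- out + outer(xt, phi[t, seq_len(K)])
  }
  out
}

#' Locally-low-rank proximal operator
#'
#' Partitions the coefficient volume (after a cyclic shift) into cubic
#' blocks, soft-thresholds the singular values of each block's casorati
#' matrix (block voxels x K), and reassembles.
#'
#' @param c4 4D array `(x, y, z, K)`, real or complex.
#' @param threshold soft-threshold level (>= 0).
#' @param block_edge cubic block edge; must not exceed any spatial
#'   dimension.
#' @param shift length-3 integer cyclic shift applied before blocking.
#' @return array of the same shape.
#' @export
llr_prox <- function(c4, threshold, block_edge = 8L, shift = c(0L, 0L, 0L)) {
  if (threshold < 0) stop("threshold must be >= 0")
  d <- dim(c4)
  if (threshold == 0) return(c4)
  if (any(block_edge > d[1:3])) stop("block larger than volume")
  sh <- function(x, s) if (s %% length(x) == 0) x else
    c(x[(s %% length(x) + 1):length(x)], x[1:(s %% length(x))])
  i1 <- sh(seq_len(d[1]), shift[1])
  i2 <- sh(seq_len(d[2]), shift[2])
  i3 <- sh(seq_len(d[3]), shift[3])
  x <- c4[i1, i2, i3, , drop = FALSE]
  starts <- function(n) unique(pmin(seq(1L, n, by = block_edge), n - block_edge + 1L))
  for (s1 in starts(d[1])) for (s2 in starts(d[2])) for (s3 in starts(d[3])) {
    b1 <- s1:(s1 + block_edge - 1); b2 <- s2:(s2 + block_edge - 1)
    b3 <- s3:(s3 + block_edge - 1)
    blk <- x[b1, b2, b3, , drop = FALSE]
    m <- matrix(blk, ncol = d[4])
    sv <- svd(m)
    dshr <- pmax(sv$d - threshold, 0)
    m2 <- sv$u %*% (dshr * t(Conj(sv$v)))
    x[b1, b2, b3, ] <- array(m2, dim(blk))
  }
  inv <- function(idx) order(idx)
  x[inv(i1), inv(i2), inv(i3), , drop = FALSE]
}

# Toeplitz kernel stack of the weighted subspace normal operator:
# H_{kl} = sum_t phi[t,k] phi[t,l] PSF_t on the embedding grid
# (`factor` x image grid; 2 is exact, smaller factors trade edge aliasing
# of the PSF tail for speed).
build_toeplitz_kernels <- function(kdata, basis_bal, weights, oversamp,
                                   width, factor = 2, verbose = FALSE) {
  geom <- recon_geometry(kdata)
  shape <- kdata$shape
  K <- ncol(basis_bal)
  n2 <- as.integer(ceiling(factor * shape / 2) * 2)
  pairs <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  P <- nrow(pairs)
  pair_idx <- matrix(0L, K, K)
  for (p in seq_len(P)) {
    pair_idx[pairs[p, 1], pairs[p, 2]] <- p
    pair_idx[pairs[p, 2], pairs[p, 1]] <- p
  }
  kern <- complex(prod(n2) * P)
  dim(kern) <- c(prod(n2), P)
  scale <- n2 / shape
  for (t in seq_len(geom$n_t)) {
    co2 <- geom$coords_t(t) * rep(scale, each = geom$m_arm * geom$n_g)
    pl <- nufft_plan(co2, n2, oversamp = oversamp, width = width)
    psf <- as.vector(nufft_type1(as.complex(weights), pl))
    psi <- basis_bal[t, pairs[, 1]] * basis_bal[t, pairs[, 2]]
    rank1_acc_cpp(kern, psf, psi)
  }
  # wrap (centered -> FFT order) and transform each kernel
  embed <- lapply(1:3, function(d) {
    r <- seq_len(n2[d]) - 1 - n2[d] %/% 2
    (r %% n2[d]) + 1L
  })
  g <- array(0i, n2)
  for (p in seq_len(P)) {
    g[embed[[1]], embed[[2]], embed[[3]]] <- array(kern[, p], n2)
    kern[, p] <- as.vector(fft(g))
  }
  list(kern = kern, pair_idx = pair_idx, n2 = n2)
}

# weighted normal operator via Toeplitz embedding; cmat n_vox x K complex
apply_normal_op <- function(cmat, tk, sens, shape) {
  K <- ncol(cmat)
  n2 <- tk$n2
  n_coil <- dim(sens)[4]
  idx1 <- seq_len(shape[1]); idx2 <- seq_len(shape[2]); idx3 <- seq_len(shape[3])
  out <- matrix(0i, nrow(cmat), K)
  g <- array(0i, n2)
  F <- matrix(0i, prod(n2), K)
  for (cc in seq_len(n_coil)) {
    sc <- as.vector(sens[, , , cc])
    xs <- cmat * sc
    for (k in seq_len(K)) {
      g[] <- 0i
      g[idx1, idx2, idx3] <- array(xs[, k], shape)
      F[, k] <- fft(g)
    }
    F2 <- toeplitz_mac_cpp(F, tk$kern, tk$pair_idx)
    for (k in seq_len(K)) {
      h <- fft(array(F2[, k], n2), inverse = TRUE)
      out[, k] <- out[, k] +
        as.vector(h[idx1, idx2, idx3]) * (Conj(sc) / prod(n2))
    }
  }
  out
}

# Chebyshev polynomial approximation of 1/x on [a, b], applied to the
# operator: returns p(H) g via Clenshaw recurrence with `deg + 1` terms.
cheb_inverse_coeffs <- function(deg, a, b) {
  j <- 0:deg
  nodes <- cos(pi * (j + 0.5) / (deg + 1))
  xv <- (nodes + 1) / 2 * (b - a) + a
  fv <- 1 / xv
  co <- vapply(0:deg, function(k) {
    2 / (deg + 1) * sum(fv * cos(k * pi * (j + 0.5) / (deg + 1)))
  }, 0)
  co[1] <- co[1] / 2
  list(coeffs = co, a = a, b = b)
}

apply_cheb <- function(g, Hfun, cheb) {
  a <- cheb$a; b <- cheb$b; co <- cheb$coeffs
  deg <- length(co) - 1
  # Clenshaw on the shifted operator y = (2H - (a+b)) / (b-a)
  opy <- function(v) (2 * Hfun(v) - (a + b) * v) / (b - a)
  bk1 <- 0 * g; bk2 <- 0 * g
  for (k in seq(deg, 1)) {
    bk <- 2 * opy(bk1) - bk2 + co[k + 1] * g
    bk2 <- bk1; bk1 <- bk
  }
  opy(bk1) - bk2 + co[1] * g
}

#' Subspace reconstruction with locally-low-rank regularization
#'
#' Solves `min_c 1/2 || W^(1/2) (A c - k) ||^2 + lambda ||c||_LLR` by FISTA,
#' where `A` is the (basis-balanced) subspace forward operator and `W`
#' optional Pipe-Menon density-compensation weights.  The weighted normal
#' operator is applied through precomputed Toeplitz kernels on the doubled
#' grid (no per-iteration regridding); an optional Chebyshev polynomial
#' preconditioner (built from a power-iteration spectrum estimate) is
#' applied to the gradient.  When `mfi_bins > 0` the adjoint data term is
#' conjugate-phase demodulated with [mfi_weights()].  Momentum restarts on
#' objective increase keep the reported objective trace non-increasing up
#' to the restart tolerance; divergence (objective above 10x initial)
#' aborts.
#'
#' @param kdata a [sample_kspace()] dataset (or container read back).
#' @param sens coil sensitivities.
#' @param basis a [compute_basis()] temporal basis.
#' @param config a [recon_config()].
#' @param verbose print per-iteration objectives.
#' @return object of class `coef_maps`: list with `c` (4D array x,y,z,K in
#'   the unbalanced basis convention), `objective_trace`, `lambda`,
#'   `basis_hash`, `config`.
#' @export
subspace_recon <- function(kdata, sens, basis, config = recon_config(),
                           verbose = FALSE) {
  shape <- kdata$shape
  K <- basis$k
  geom <- recon_geometry(kdata)
  nvox <- prod(shape)

  # basis balancing: scale columns by normalized singular values so one
  # soft-threshold level suits all coefficient components; bypassed for
  # unregularized solves where it would only worsen conditioning
  sv <- basis$singular_values[seq_len(K)]
  sb <- if (identical(config$lambda_llr, 0) || identical(config$lambda_llr, 0L)) {
    rep(1, K)
  } else sv / sv[1]
  phi_bal <- basis$phi %*% diag(sb, K)
  basis_bal <- structure(list(phi = phi_bal, k = K,
                              singular_values = basis$singular_values),
                         class = "temporal_basis")

  # density compensation from the first time point's arm union (the arm
  # geometry is rotation-equivalent across time points)
  weights <- if (config$use_dcf) {
    pipe_menon_dcf(geom$coords_t(1), shape)^(config$dcf_power %||% 1)
  } else rep(1, geom$m_arm * geom$n_g)

  mfi <- if (config$mfi_bins > 0) {
    mfi_weights(kdata$b0_map, geom$tau_ms, config$mfi_bins)
  } else NULL

  # right-hand side b = A^H W k (conjugate-phase demodulated when MFI on)
  b <- adjoint_operator(kdata$samples, basis_bal, kdata, sens, mfi = mfi,
                        weights = weights, oversamp = config$oversamp,
                        width = config$width)

  tk <- build_toeplitz_kernels(kdata, phi_bal, weights, config$oversamp,
                               config$width,
                               factor = config$toeplitz_factor %||% 2)
  Hfun <- function(cm) apply_normal_op(cm, tk, sens, shape)

  # Lipschitz estimate by power iteration
  set.seed(config$random_shift_seed)
  v <- matrix(complex(real = rnorm(nvox * K), imaginary = rnorm(nvox * K)),
              nvox, K)
  v <- v / sqrt(sum(Mod(v)^2))
  L <- 1
  for (i in 1:6) {
    w <- Hfun(v)
    L <- sqrt(sum(Mod(w)^2))
    v <- w / L
  }

  cheb <- if (config$precond_degree > 0) {
    cheb_inverse_coeffs(config$precond_degree, 0.05 * L, 1.05 * L)
  } else NULL
  grad_map <- function(g) if (is.null(cheb)) g / L else apply_cheb(g, Hfun, cheb)
  # effective gradient scale seen by the prox: 1/L for the plain iteration,
  # the spectrum-averaged polynomial value for the preconditioned one
  grad_scale <- if (is.null(cheb)) 1 / L else
    log(cheb$b / cheb$a) / (cheb$b - cheb$a)

  step <- if (identical(config$step_size, "auto")) {
    if (is.null(cheb)) 0.95 else {
      # spectral radius of P H by power iteration
      v2 <- v; Lp <- 1
      for (i in 1:4) {
        w2 <- apply_cheb(Hfun(v2), Hfun, cheb)
        Lp <- sqrt(sum(Mod(w2)^2)); v2 <- w2 / Lp
      }
      0.95 / Lp
    }
  } else config$step_size

  # lambda: 0.01 x largest casorati singular value of the zero-filled
  # adjoint (balanced convention)
  lambda <- config$lambda_llr
  if (identical(lambda, "auto")) {
    blk <- array(b, c(shape, K))
    m <- matrix(blk, ncol = K)
    lambda <- 0.01 * svd(crossprod(Conj(m), m))$d[1]^0.5
  }

  set.seed(config$random_shift_seed)
  cmat <- matrix(0i, nvox, K)
  y <- cmat
  tacc <- 1
  obj <- function(cm, Hc) {
    f <- 0.5 * Re(sum(Conj(cm) * Hc)) - Re(sum(Conj(b) * cm))
    f
  }
  trace <- numeric(config$n_iter + 1)
  Hy <- matrix(0i, nvox, K)      # H of the zero start
  f0 <- obj(y, Hy)
  trace[1] <- f0
  c_prev <- cmat
  Hc_prev <- matrix(0i, nvox, K)
  f_prev <- f0
  for (it in seq_len(config$n_iter)) {
    g <- Hy - b
    z <- y - step * grad_map(g)
    if (lambda > 0) {
      shift <- sample.int(config$llr_block, 3, replace = TRUE) - 1L
      z4 <- llr_prox(array(z, c(shape, K)), lambda * step * grad_scale,
                     config$llr_block, shift)
      cmat <- matrix(z4, ncol = K)
    } else {
      cmat <- z
    }
    Hc <- Hfun(cmat)
    f <- obj(cmat, Hc)
    if (is.na(f) || f - f0 > 10 * abs(f0) + 10) {
      stop("subspace_recon diverged: objective grew by more than 10x")
    }
    if (f > f_prev) {
      # adaptive restart: drop momentum
      tacc <- 1
      y <- cmat
      Hy <- Hc
    } else {
      t_next <- (1 + sqrt(1 + 4 * tacc^2)) / 2
      mom <- (tacc - 1) / t_next
      y <- cmat + mom * (cmat - c_prev)
      Hy <- Hc + mom * (Hc - Hc_prev)   # linearity of H
      tacc <- t_next
    }
    c_prev <- cmat
    Hc_prev <- Hc
    f_prev <- min(f_prev, f)
    trace[it + 1] <- f
    if (verbose) cat(sprintf("iter %3d  objective %.6g\n", it, f))
  }
  # return unbalanced-basis coefficients: x = phi_bal c_bal = phi (sb * c)
  cub <- sweep(cmat, 2, sb, "*")
  structure(list(c = array(cub, c(shape, K)),
                 c_balanced = array(cmat, c(shape, K)),
                 objective_trace = trace, lambda = lambda,
                 step = step, lipschitz = L,
                 weights = weights, config = config),
            class = "coef_maps")
}

#' @export
print.coef_maps <- function(x, ...) {
  d <- dim(x$c)
  cat(sprintf("coef_maps: %dx%dx%d x %d coefficients, lambda %.3g\n",
              d[1], d[2], d[3], d[4], x$lambda))
  cat(sprintf("  objective %.4g -> %.4g in %d iterations\n",
              x$objective_trace[1], tail(x$objective_trace, 1),
              length(x$objective_trace) - 1))
  invisible(x)
}
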