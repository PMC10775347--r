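#' Non-uniform FFT plan (3D Kaiser-Bessel gridding)
#'
#' Type-2 (image -> non-Cartesian samples) evaluates
#' `s(k) = sum_r x[r] exp(-2 pi i k . r / N)` with voxel indices `r`
#' centered on the grid; type-1 is its exact adjoint.  Coordinates are in
#' cycles/FOV units (so `k` equal to an integer lies on a Cartesian grid
#' line, and `|k_d| <= N_d / 2` is the Nyquist box).
#'
#' @param coords `M x 3` matrix of k-space coordinates in cycles/FOV.
#' @param n image matrix size (scalar or length-3).
#' @param oversamp grid oversampling factor.
#' @param width kernel width in oversampled grid units.
#' @return object of class `nufft_plan`.
#' @export
nufft_plan <- function(coords, n, oversamp = 1.5, width = 6L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be M x 3")
  n <- rep_len(as.integer(n), 3L)
  if (any(abs(coords) > rep(n / 2, each = nrow(coords)) + 1e-9)) {
    stop("trajectory extends outside the Nyquist box")
  }
  ng <- as.integer(ceiling(oversamp * n / 2) * 2)  # even oversampled dims
  os_eff <- ng / n
  beta <- pi * sqrt((width / os_eff * (os_eff - 0.5))^2 - 0.8)
  # oversampled-grid coordinates (wrapped in C++)
  cg <- t(coords * rep(ng / n, each = nrow(coords)))
  apod <- lapply(1:3, function(d) {
    r <- seq_len(n[d]) - 1 - n[d] %/% 2
    kb_ft(r / ng[d], width, beta[d])
  })
  embed <- lapply(1:3, function(d) {
    r <- seq_len(n[d]) - 1 - n[d] %/% 2
    (r %% ng[d]) + 1L
  })
  structure(list(coords = coords, cgrid = cg, n = n, ng = ng,
                 width = as.integer(width), beta = beta,
                 apod = apod, embed = embed, m = nrow(coords)),
            class = "nufft_plan")
}

# continuous Fourier transform of the Kaiser-Bessel kernel of full width
# `width`, evaluated at frequency f (cycles per grid sample)
kb_ft <- function(f, width, beta) {
  q2 <- beta^2 - (pi * width * f)^2
  out <- numeric(length(f))
  pos <- q2 > 0
  q <- sqrt(abs(q2))
  out[pos] <- sinh(q[pos]) / q[pos]
  out[!pos] <- sin(q[!pos]) / q[!pos]
  out[q == 0] <- 1
  out * width / besselI(beta, 0)
}

deapodize <- function(x, plan) {
  n <- plan$n
  x / (rep(plan$apod[[1]], times = n[2] * n[3]) *
       rep(rep(plan$apod[[2]], each = n[1]), times = n[3]) *
       rep(plan$apod[[3]], each = n[1] * n[2]))
}

#' Evaluate the NUFFT (type 2: image to samples)
#'
#' @param x complex (or numeric) 3D array of the plan's matrix size.
#' @param plan a [nufft_plan()].
#' @return complex vector of samples, one per trajectory point.
#' @export
nufft_type2 <- function(x, plan) {
  n <- plan$n; ng <- plan$ng
  x <- deapodize(as.array(x), plan)
  g <- array(0i, ng)
  g[plan$embed[[1]], plan$embed[[2]], plan$embed[[3]]] <- x
  G <- fft(g)
  kb_interp3_cpp(as.vector(G), ng, plan$cgrid, plan$width, mean(plan$beta))
}

#' Adjoint NUFFT (type 1: samples to image)
#'
#' Exact adjoint of [nufft_type2()].
#'
#' @param s complex sample vector.
#' @param plan a [nufft_plan()].
#' @return complex 3D array of the plan's matrix size.
#' @export
nufft_type1 <- function(s, plan) {
  ng <- plan$ng
  g <- kb_spread3_cpp(as.complex(s), ng, plan$cgrid, plan$width,
                      mean(plan$beta))
  G <- fft(array(g, ng), inverse = TRUE)
  x <- G[plan$embed[[1]], plan$embed[[2]], plan$embed[[3]]]
  deapodize(x, plan)
}

#' Direct discrete Fourier summation (oracle-grade, O(M N^3))
#'
#' Brute-force evaluation of the same transform as [nufft_type2()]; intended
#' for validation on tiny problems.
#'
#' @inheritParams nufft_type2
#' @param coords `M x 3` coordinates in cycles/FOV.
#' @param n matrix size (scalar or length 3).
#' @export
ndft_type2 <- function(x, coords, n) {
  n <- rep_len(as.integer(n), 3L)
  r1 <- seq_len(n[1]) - 1 - n[1] %/% 2
  r2 <- seq_len(n[2]) - 1 - n[2] %/% 2
  r3 <- seq_len(n[3]) - 1 - n[3] %/% 2
  M <- nrow(coords)
  out <- complex(M)
  for (m in seq_len(M)) {
    p1 <- exp(-2i * pi * coords[m, 1] * r1 / n[1])
    p2 <- exp(-2i * pi * coords[m, 2] * r2 / n[2])
    p3 <- exp(-2i * pi * coords[m, 3] * r3 / n[3])
    ph <- outer(outer(p1, p2), p3)
    out[m] <- sum(x * ph)
  }
  out
}

# batched 3D FFT over the 4th dimension of a 4D array, via mvfft along each
# spatial dimension (R's fft is applied to all volumes at once)
batch_fft3 <- function(x, inverse = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  # dim 1
  dim(x) <- c(d[1], prod(d[2:4]))
  x <- mvfft(x, inverse = inverse)
  dim(x) <- d
  # dim 2
  x <- aperm(x, c(2, 1, 3, 4))
  dp <- dim(x)
  dim(x) <- c(dp[1], prod(dp[2:4]))
  x <- mvfft(x, inverse = inverse)
  dim(x) <- dp
  x <- aperm(x, c(2, 1, 3, 4))
  # dim 3
  x <- aperm(x, c(3, 2, 1, 4))
  dp <- dim(x)
  dim(x) <- c(dp[1], prod(dp[2:4]))
  x <- mvfft(x, inverse = inverse)
  dim(x) <- dp
  aperm(x, c(3, 2, 1, 4))
}
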