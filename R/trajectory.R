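#' Design a constrained variable-density spiral-out readout
#'
#' Time-stepped design at the dwell resolution: the k-space speed is limited
#' by the gradient amplitude, the slew-rate ramp, and the curvature of the
#' spiral (centripetal slew), so the trajectory is slew-limited near the
#' center and amplitude-limited outside.  The spiral reaches
#' `k_max = 1 / (2 resolution)`; the radial spacing between turns grows
#' linearly from `undersampling / fov` at the center to
#' `vd_edge_factor * undersampling / fov` at the edge (one arm per TR;
#' through-plane encoding comes from the rotation schedule).
#'
#' @param fov field of view in mm.
#' @param resolution nominal resolution in mm.
#' @param dwell sample dwell time in microseconds.
#' @param gmax maximum gradient amplitude, mT/m.
#' @param smax maximum slew rate, T/m/s.
#' @param max_duration maximum readout duration in ms.
#' @param undersampling in-plane undersampling factor at the k-space center
#'   (turn spacing in units of 1/fov).
#' @param vd_edge_factor variable-density ratio of edge to center spacing.
#' @return object of class `spiral_readout`: `k_samples` (`M x 2`,
#'   cycles/mm), `times_ms` (from readout start), `dwell_us`, `duration_ms`,
#'   constraint audit fields (`gmax_used`, `smax_used`).
#' @export
design_spiral <- function(fov = 220, resolution = 1, dwell = 10,
                          gmax = 40, smax = 100, max_duration = 6.8,
                          undersampling = 8, vd_edge_factor = 5) {
  if (fov <= 0 || resolution <= 0) stop("fov and resolution must be positive")
  gam <- 0.042577                      # cycles/mm/ms per mT/m
  kmax <- 1 / (2 * resolution)         # cycles/mm
  s0 <- undersampling / fov            # center turn spacing, cycles/mm
  dt <- dwell / 1000                   # ms
  vmax <- gam * gmax                   # cycles/mm/ms
  amax <- gam * smax                   # cycles/mm/ms^2
  safety <- 0.995

  # design against a derated slew limit so the discrete waveform audit
  # stays below smax despite the curvature linearization
  amax_d <- 0.88 * amax
  spacing <- function(r) s0 * (1 + (vd_edge_factor - 1) * r / kmax)
  r <- 0; phi <- 0; v <- 0; t <- 0
  nmax <- ceiling(max_duration / dt) + 1L
  kx <- numeric(nmax); ky <- numeric(nmax)
  i <- 0L
  while (r < kmax) {
    i <- i + 1L
    if (i > nmax) {
      stop(sprintf(
        "spiral infeasible: k_max %.3f cycles/mm not reached within %.2f ms under gmax=%g, smax=%g",
        kmax, max_duration, gmax, smax))
    }
    kx[i] <- r * cos(phi)
    ky[i] <- r * sin(phi)
    rp <- spacing(r) / (2 * pi)        # dr/dphi
    dk_dphi <- sqrt(r^2 + rp^2)
    kappa <- (r^2 + 2 * rp^2) / dk_dphi^3
    v_curv <- sqrt(amax_d / kappa)
    # keep the azimuthal step small near the center so the discrete
    # waveform tracks the continuous curve (bounds the audit slew)
    v_step <- 0.3 * dk_dphi / dt
    v <- min(vmax, v + amax_d * dt, v_curv, v_step) * safety
    dphi <- v * dt / dk_dphi
    phi <- phi + dphi
    r <- r + rp * dphi
    t <- t + dt
  }
  k <- cbind(kx[seq_len(i)], ky[seq_len(i)])
  times <- (seq_len(i) - 1) * dt
  g <- diff(rbind(0, k)) / dt / gam    # mT/m (first step ramps from origin)
  slew <- diff(rbind(0, g)) / dt       # mT/m/ms = T/m/s
  structure(list(k_samples = k, times_ms = times, dwell_us = dwell,
                 duration_ms = t, fov = fov, resolution = resolution,
                 gmax = gmax, smax = smax, undersampling = undersampling,
                 vd_edge_factor = vd_edge_factor,
                 gmax_used = max(sqrt(rowSums(g^2))),
                 smax_used = max(sqrt(rowSums(slew^2)))),
            class = "spiral_readout")
}

#' @export
print.spiral_readout <- function(x, ...) {
  cat(sprintf("spiral_readout: %d samples, %.2f ms, kmax %.3f cycles/mm\n",
              nrow(x$k_samples), x$duration_ms, max(sqrt(rowSums(x$k_samples^2)))))
  cat(sprintf("  constraints: |G| %.1f/%.1f mT/m, slew %.1f/%.1f T/m/s\n",
              x$gmax_used, x$gmax, x$smax_used, x$smax))
  invisible(x)
}

rot_axis <- function(axis, deg) {
  th <- deg * pi / 180
  c <- cos(th); s <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
         y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
         z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3))
}

#' Tiny-golden-angle-shuffling (TGAS) rotation schedule
#'
#' Within an acquisition group, successive TRs advance by the tiny golden
#' angle about the group's primary axis; the primary axis cycles x -> y -> z
#' across groups.  Each group's base orientation tilts the readout plane so
#' that the circle traced by the plane normals sits at a golden-means
#' stratified latitude (uniform in the cosine of the polar angle from the
#' group axis) with a golden azimuthal offset — shuffling the circle
#' families over the sphere for near-uniform angular coverage.  Fully
#' deterministic.
#'
#' @param n_groups number of acquisition groups.
#' @param n_tr_per_group TRs (spiral arms) per group.
#' @param increment_deg tiny golden angle in degrees (default 23.628).
#' @return object of class `rotation_schedule`: `rotations` (3 x 3 x n
#'   array, TR-major within group), `group`, `tr`, `axis`, `increment_deg`.
#' @export
tgas_schedule <- function(n_groups, n_tr_per_group, increment_deg = 23.628) {
  if (n_groups < 1 || n_tr_per_group < 1) stop("counts must be >= 1")
  axes <- c("x", "y", "z")
  # 2D golden means (generalized Fibonacci) driving the per-group shuffle
  phi2 <- c(0.4656, 0.6823)
  n <- n_groups * n_tr_per_group
  R <- array(0, c(3, 3, n))
  grp <- integer(n); tr <- integer(n); ax <- character(n)
  idx <- 0L
  for (g in seq_len(n_groups)) {
    a <- axes[((g - 1L) %% 3L) + 1L]
    u <- (g * phi2[1]) %% 1
    theta <- acos(1 - 2 * u) * 180 / pi   # polar angle from the group axis
    phi0 <- 360 * ((g * phi2[2]) %% 1)    # azimuthal offset about it
    base <- switch(a,
      x = rot_axis("x", phi0) %*% rot_axis("y", 90 - theta),
      y = rot_axis("y", phi0) %*% rot_axis("x", theta - 90),
      z = rot_axis("z", phi0) %*% rot_axis("y", theta))
    for (i in seq_len(n_tr_per_group)) {
      idx <- idx + 1L
      R[, , idx] <- rot_axis(a, (i - 1) * increment_deg) %*% base
      grp[idx] <- g; tr[idx] <- i; ax[idx] <- a
    }
  }
  structure(list(rotations = R, group = grp, tr = tr, axis = ax,
                 increment_deg = increment_deg,
                 n_groups = n_groups, n_tr_per_group = n_tr_per_group),
            class = "rotation_schedule")
}

#' @export
print.rotation_schedule <- function(x, ...) {
  cat(sprintf("rotation_schedule: %d groups x %d TRs, increment %.3f deg\n",
              x$n_groups, x$n_tr_per_group, x$increment_deg))
  invisible(x)
}

#' Rotate a 2D spiral readout into 3D sample coordinates
#'
#' @param spiral a [design_spiral()] readout.
#' @param rotation 3x3 rotation matrix.
#' @return `M x 3` matrix of 3D k-space coordinates (cycles/mm).
#' @export
rotate_spiral <- function(spiral, rotation) {
  k3 <- cbind(spiral$k_samples, 0)
  k3 %*% t(rotation)
}

#' Pipe-Menon iterative density compensation
#'
#' Iterates `w <- w / (G G^H w)` where `G G^H` is the sample-domain
#' autocorrelation of the gridding operator — the weighted sample density
#' smoothed by an isotropic (radially symmetric) Kaiser-Bessel kernel, so
#' the weights are exactly invariant under global rotations of the sample
#' set.  At the fixed point the kernel-smoothed weighted density is one
#' everywhere; a uniform-density Cartesian set receives uniform weights.
#'
#' @param coords `M x 3` sample coordinates in cycles/FOV units.
#' @param n matrix size (scalar or length 3) defining the Nyquist box
#'   (kernel radius is `width / 2` in these grid units).
#' @param n_iter iterations (default 30).
#' @param width kernel diameter in grid units.
#' @param beta Kaiser-Bessel shape parameter.
#' @return positive weight vector of length `M`.
#' @export
pipe_menon_dcf <- function(coords, n, n_iter = 30, width = 4L, beta = 9.5) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty sample set")
  n <- rep_len(as.numeric(n), 3L)
  if (any(abs(coords) > rep(n / 2, each = nrow(coords)) + 0.5)) {
    stop("sample coordinates outside the Nyquist box")
  }
  cg <- t(coords)
  dens <- function(w) pm_density_cpp(cg, w, width / 2, beta, n)
  w <- rep(1, nrow(coords))
  eps <- 1e-12
  for (it in seq_len(n_iter)) {
    d <- dens(w)
    bad <- d <= eps * max(d)
    if (any(bad)) {
      warning("zero-valued intermediate density guarded with epsilon")
      d[bad] <- eps * max(d)
    }
    w <- w / d
  }
  w
}
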