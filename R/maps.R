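#' Myelin-water reference signal per B1+ value
#'
#' The B1-corrected, EPG-simulated ViSTa time-point signal of nominal
#' myelin water (T1/T2 = 120/20 ms) at unit proton density, one value per
#' dictionary B1 grid point.  Units: a 90 degree tip of fully recovered Mz
#' equals 1.
#'
#' @param dict a [build_dictionary()] dictionary whose grid contains the
#'   myelin anchor, or `NULL` to simulate directly.
#' @param protocol protocol used when simulating directly.
#' @param b1_values B1 grid when simulating directly.
#' @param myelin_t1,myelin_t2 nominal myelin-water relaxation times (ms).
#' @return object of class `myelin_reference`: list with `b1_values`,
#'   `s_myelin` (positive, < 1).
#' @export
myelin_reference <- function(dict = NULL, protocol = vista_protocol(),
                             b1_values = seq(0.70, 1.20, 0.05),
                             myelin_t1 = 120, myelin_t2 = 20) {
  if (!is.null(dict)) {
    vi <- timepoint_kinds(dict$protocol)$vista_index
    sel <- which(dict$index$t1 == myelin_t1 & dict$index$t2 == myelin_t2)
    if (length(sel) == 0) stop("dictionary grid lacks the myelin anchor")
    b1v <- dict$index$b1[sel]
    s <- abs(dict$atoms[sel, vi])
  } else {
    ev <- protocol_events(protocol)
    sig <- epg_simulate(ev, rep(myelin_t1, length(b1_values)),
                        rep(myelin_t2, length(b1_values)), b1_values,
                        te = protocol$te, n_orders = 40L, n_groups = 4L)
    vi <- timepoint_kinds(protocol)$vista_index
    b1v <- b1_values
    s <- abs(sig[, vi])
  }
  if (any(s <= 0) || any(s >= 1)) {
    stop("myelin reference signal outside (0, 1); check the protocol")
  }
  structure(list(b1_values = b1v, s_myelin = s), class = "myelin_reference")
}

# trilinear resampling of a 3D array onto a target shape (normalized
# coordinates aligned at the volume faces)
resample_linear <- function(x, target_shape) {
  d <- dim(x)
  target_shape <- rep_len(as.integer(target_shape), 3L)
  if (all(d == target_shape)) return(x)
  g <- function(n_from, n_to) {
    if (n_to == 1) return(rep(1, 1))
    seq(1, n_from, length.out = n_to)
  }
  c1 <- g(d[1], target_shape[1]); c2 <- g(d[2], target_shape[2])
  c3 <- g(d[3], target_shape[3])
  i1 <- pmin(floor(c1), d[1] - 1); f1 <- c1 - i1
  i2 <- pmin(floor(c2), d[2] - 1); f2 <- c2 - i2
  i3 <- pmin(floor(c3), d[3] - 1); f3 <- c3 - i3
  out <- array(0, target_shape)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- outer(outer(if (a) f1 else 1 - f1, if (b) f2 else 1 - f2),
               if (cc) f3 else 1 - f3)
    out <- out + w * x[i1 + a, i2 + b, i3 + cc]
  }
  out
}

#' Quantitative map fitting from subspace coefficient maps
#'
#' Per voxel, the reconstructed time series `phi c` is matched against the
#' B1-restricted dictionary (see [match_coefficients()]); the ViSTa image is
#' the magnitude of the first ViSTa time point `|phi[vista, ] c|`.
#'
#' With `myelin_correction = TRUE` (the default) the method's own mechanism
#' is used before matching: because the double-inversion preparation nulls
#' the long-T1 tissue pools at the ViSTa time point, the complex ViSTa
#' amplitude divided by the unit-PD myelin-water signal estimates the
#' myelin pool amplitude, whose evolution is subtracted from the series so
#' that the single-pool dictionary sees only the tissue pool.  The reported
#' PD is then the total-water amplitude (tissue + myelin pools), which is
#' the `I(PD)` entering the MWF definition.  This removes the strong T1/T2
#' bias that direct single-pool matching of two-pool voxels incurs (the
#' ViSTa blocks are myelin-dominant by sequence design).  The correction
#' assumes tissue pools are nulled at the ViSTa point, i.e. tissue T1 well
#' above ~600 ms; for dictionary-pure short-T1 inputs use
#' `myelin_correction = FALSE`.
#'
#' @param cmaps a [subspace_recon()] result (or any 4D coefficient array
#'   wrapped in `list(c = ...)`).
#' @param basis the temporal basis used in the reconstruction.
#' @param dict the matching dictionary.
#' @param b1_map B1+ map; resampled to the coefficient grid by linear
#'   interpolation when shapes differ.  `NULL` proceeds with B1 = 1 and a
#'   warning.
#' @param myelin_correction subtract the ViSTa-derived myelin-pool
#'   evolution before matching and report total-water PD.
#' @param myelin_t1,myelin_t2 nominal myelin-water relaxation times (ms)
#'   used by the correction.
#' @return object of class `quant_maps` (without `mwf_map`; see
#'   [compute_mwf()]): `t1_map`, `t2_map`, `pd_map`, `vista_image`,
#'   `b1_map_used`, `score_map`.
#' @export
fit_maps <- function(cmaps, basis, dict, b1_map = NULL,
                     myelin_correction = TRUE,
                     myelin_t1 = 120, myelin_t2 = 20) {
  carr <- cmaps$c
  d <- dim(carr)
  shape <- d[1:3]; K <- d[4]
  if (K != basis$k) stop("coefficient / basis rank mismatch")
  if (is.null(b1_map)) {
    warning("no B1+ map supplied; matching without B1 correction (B1 = 1)")
    b1_map <- array(1, shape)
  } else {
    b1_map <- resample_linear(b1_map, shape)
  }
  cmat <- matrix(carr, ncol = K)               # nvox x K
  vi <- timepoint_kinds(dict$protocol)$vista_index
  v_c <- as.vector(cmat %*% basis$phi[vi, ])   # complex ViSTa amplitude
  vista <- abs(v_c)

  b1v <- dict$grid$b1_values
  b1_near_idx <- vapply(as.vector(b1_map),
                        function(b) which.min(abs(b1v - b)), 0L)
  pd_myelin <- NULL
  if (myelin_correction) {
    sel <- which(dict$index$t1 == myelin_t1 & dict$index$t2 == myelin_t2)
    if (length(sel) != length(b1v)) {
      warning("dictionary lacks the myelin anchor; matching without ",
              "myelin correction")
      myelin_correction <- FALSE
    } else {
      sel <- sel[match(b1v, dict$index$b1[sel])]
      s_my_v <- dict$atoms[sel, vi]            # ViSTa signal per B1
      psi_my <- dict$atoms[sel, , drop = FALSE] %*% basis$phi  # n_b1 x K
      a_m <- v_c / s_my_v[b1_near_idx]         # complex myelin amplitude
      cmat <- cmat - a_m * psi_my[b1_near_idx, , drop = FALSE]
      pd_myelin <- Mod(a_m)
    }
  }
  m <- match_coefficients(t(cmat), dict, basis, b1 = as.vector(b1_map))
  pd <- m$pd_scale
  if (!is.null(pd_myelin)) pd <- pd + pd_myelin
  structure(list(t1_map = array(m$t1, shape),
                 t2_map = array(m$t2, shape),
                 pd_map = array(pd, shape),
                 vista_image = array(vista, shape),
                 b1_map_used = b1_map,
                 score_map = array(m$score, shape)),
            class = "quant_maps")
}

#' @export
print.quant_maps <- function(x, ...) {
  d <- dim(x$t1_map)
  cat("quant_maps:", paste(d, collapse = "x"), "\n")
  nz <- x$pd_map > 0
  if (any(nz)) {
    cat(sprintf("  t1 median %.0f ms, t2 median %.1f ms, pd median %.3f\n",
                median(x$t1_map[nz]), median(x$t2_map[nz]),
                median(x$pd_map[nz])))
  }
  if (!is.null(x$mwf_map)) {
    cat(sprintf("  mwf median (nonzero) %.3f\n",
                median(x$mwf_map[x$mwf_map > 0])))
  }
  invisible(x)
}

#' Myelin-water fraction from the ViSTa image and the PD map
#'
#' `MWF = I(ViSTa) / (I(PD) * S(myelin_water))` with the B1-corrected
#' myelin-water reference signal.  Voxels whose PD falls below 1% of the
#' robust maximum are set to zero; the result is clipped to [0, 1].
#'
#' @param vista_image,pd_map volumes in the same reconstruction units.
#' @param myelin_ref a [myelin_reference()].
#' @param b1_map B1+ map (resampled if needed); `NULL` = 1.
#' @param pd_floor_frac background threshold as a fraction of the robust
#'   (99th percentile) PD maximum.
#' @return mwf array in [0, 1].
#' @export
compute_mwf <- function(vista_image, pd_map, myelin_ref, b1_map = NULL,
                        pd_floor_frac = 0.01) {
  stopifnot(inherits(myelin_ref, "myelin_reference"))
  if (any(myelin_ref$s_myelin <= 0)) stop("non-positive myelin reference")
  shape <- dim(pd_map)
  if (is.null(b1_map)) b1_map <- array(1, shape)
  else b1_map <- resample_linear(b1_map, shape)
  b1v <- myelin_ref$b1_values
  idx <- vapply(as.vector(b1_map), function(b) which.min(abs(b1v - b)), 0L)
  smy <- array(myelin_ref$s_myelin[idx], shape)
  floor_pd <- pd_floor_frac * quantile(pd_map[pd_map > 0], 0.99,
                                       names = FALSE)
  if (!length(floor_pd) || is.na(floor_pd)) floor_pd <- Inf
  mwf <- array(0, shape)
  ok <- pd_map > floor_pd
  mwf[ok] <- vista_image[ok] / (pd_map[ok] * smy[ok])
  pmin(pmax(mwf, 0), 1)
}

mz_recursion <- function(t1, scheme, tr) {
  # steady-state longitudinal magnetization before the preparation of each
  # cycle; scheme is a list of c(type, par): inv, delay(par ms),
  # sat, readout_loss(par = cos(alpha) per excitation is folded upstream)
  mz <- rep(1, length(t1))
  n_cycles <- if (is.infinite(tr)) 1L else 60L
  for (cyc in seq_len(n_cycles)) {
    m <- mz
    for (st in scheme) {
      if (st$type == "inv") m <- -m
      else if (st$type == "sat") m <- 0 * m
      else if (st$type == "delay") {
        e <- exp(-st$par / t1)
        m <- 1 + (m - 1) * e
      } else if (st$type == "scale") m <- m * st$par
    }
    mz <- m
  }
  mz
}

#' Synthesize contrast-weighted images from quantitative maps
#'
#' Bloch-simulated steady-state signal equations: spin-echo T1w/T2w
#' `pd (1 - exp(-TR/T1)) exp(-TE/T2)`; inversion-prepared contrasts
#' (MPRAGE, FLAIR, DIR) by discrete longitudinal-magnetization recursion
#' over the preparation scheme followed by the readout factor.
#'
#' @param t1_map,t2_map,pd_map quantitative volumes (ms / ms / a.u.).
#' @param contrast one of `"t1w"`, `"t2w"`, `"mprage"`, `"flair"`, `"dir"`.
#' @param tr,te repetition/echo time in ms (`tr = Inf` = full recovery).
#' @param ti first (or only) inversion delay, ms.
#' @param ti2 second inversion delay (DIR: inversion-to-readout), ms.
#' @param flip_angle readout excitation in degrees (gradient-echo readouts).
#' @return signal image (same shape as inputs).
#' @export
synthesize_contrast <- function(t1_map, t2_map, pd_map,
                                contrast = c("t1w", "t2w", "mprage",
                                             "flair", "dir"),
                                tr = Inf, te = 10, ti = NULL, ti2 = NULL,
                                flip_angle = 9) {
  contrast <- match.arg(contrast)
  shape <- dim(pd_map)
  t1 <- pmax(as.vector(t1_map), 1e-6)
  t2 <- pmax(as.vector(t2_map), 1e-6)
  pd <- as.vector(pd_map)
  sig <- switch(contrast,
    t1w = ,
    t2w = {
      trr <- if (is.infinite(tr)) Inf else tr
      e1 <- if (is.infinite(trr)) 0 else exp(-trr / t1)
      pd * (1 - e1) * exp(-te / t2)
    },
    mprage = {
      if (is.null(ti)) stop("mprage needs ti")
      scheme <- list(list(type = "inv"), list(type = "delay", par = ti))
      mz <- mz_recursion(t1, c(scheme,
        if (!is.infinite(tr)) list(list(type = "scale",
                                        par = cos(flip_angle * pi / 180)),
                                   list(type = "delay", par = tr - ti))),
        tr)
      # magnetization at TI after the (steady-state) inversion
      mz_ti <- local({
        m <- if (is.infinite(tr)) rep(1, length(t1)) else mz
        m <- -m
        1 + (m - 1) * exp(-ti / t1)
      })
      pd * mz_ti * sin(flip_angle * pi / 180) * exp(-te / t2)
    },
    flair = {
      if (is.null(ti)) stop("flair needs ti")
      mz0 <- if (is.infinite(tr)) rep(1, length(t1)) else
        mz_recursion(t1, list(list(type = "inv"),
                              list(type = "delay", par = ti),
                              list(type = "scale", par = 0),
                              list(type = "delay", par = tr - ti)), tr)
      mz_ti <- 1 + (-mz0 - 1) * exp(-ti / t1)
      pd * mz_ti * exp(-te / t2)
    },
    dir = {
      if (is.null(ti) || is.null(ti2)) stop("dir needs ti and ti2")
      mz0 <- if (is.infinite(tr)) rep(1, length(t1)) else
        mz_recursion(t1, list(list(type = "inv"),
                              list(type = "delay", par = ti),
                              list(type = "inv"),
                              list(type = "delay", par = ti2),
                              list(type = "scale", par = 0),
                              list(type = "delay", par = tr - ti - ti2)), tr)
      m <- -mz0
      m <- 1 + (m - 1) * exp(-ti / t1)
      m <- -m
      m <- 1 + (m - 1) * exp(-ti2 / t1)
      pd * m * exp(-te / t2)
    })
  array(sig, shape)
}

#' Inversion delays nulling two tissues in a DIR preparation
#'
#' Solves (Newton iteration with analytic Jacobian, full-recovery cycle)
#' for the delays `(ti, ti2)` such that
#' `1 - 2 exp(-ti2/T1) + 2 exp(-(ti + ti2)/T1) = 0` for both target T1s.
#'
#' @param t1_a,t1_b target longitudinal relaxation times (ms).
#' @return list `(ti, ti2, residual)`.
#' @export
dir_null_times <- function(t1_a, t1_b) {
  f <- function(p) {
    vapply(c(t1_a, t1_b), function(T1) {
      1 - 2 * exp(-p[2] / T1) + 2 * exp(-(p[1] + p[2]) / T1)
    }, 0)
  }
  J <- function(p) {
    do.call(rbind, lapply(c(t1_a, t1_b), function(T1) {
      c(-2 / T1 * exp(-(p[1] + p[2]) / T1),
        2 / T1 * exp(-p[2] / T1) - 2 / T1 * exp(-(p[1] + p[2]) / T1))
    }))
  }
  p <- c(max(t1_a, t1_b) * 0.8, min(t1_a, t1_b) * log(2))
  for (i in 1:100) {
    r <- f(p)
    if (max(abs(r)) < 1e-12) break
    p <- p - solve(J(p), r)
    p <- pmax(p, 1)
  }
  list(ti = p[1], ti2 = p[2], residual = max(abs(f(p))))
}
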