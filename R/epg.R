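#' Tissue parameter set
#'
#' @param t1,t2 relaxation times in ms (`t2 <= t1`).
#' @param pd proton density (equilibrium magnetization scale).
#' @param b1 transmit field scale applied to excitation flip angles
#'   (inversions and saturations are modeled as adiabatic, hence
#'   B1-insensitive).
#' @param off_resonance off-resonance in Hz.  It does not change the
#'   magnitude of the gradient-spoiled EPG signal and is carried for the
#'   phantom forward model.
#' @return object of class `tissue_params`.
#' @export
tissue_params <- function(t1, t2, pd = 1, b1 = 1, off_resonance = 0) {
  if (any(t1 <= 0) || any(t2 <= 0)) stop("relaxation times must be positive")
  if (any(t2 > t1)) stop("t2 must not exceed t1")
  if (any(pd < 0)) stop("pd must be non-negative")
  if (any(b1 < 0.5 | b1 > 1.5)) stop("b1 must lie in [0.5, 1.5]")
  structure(list(t1 = t1, t2 = t2, pd = pd, b1 = b1,
                 off_resonance = off_resonance),
            class = "tissue_params")
}

#' Reference tissue anchors
#'
#' Myelin water (T1/T2 = 120/20 ms), white matter (750/60 ms), gray matter
#' (1300/75 ms) and CSF (4000/2000 ms, a package default for simulation).
#'
#' @param name one of `"myelin"`, `"wm"`, `"gm"`, `"csf"`.
#' @param ... passed to [tissue_params()] (e.g. `pd`, `b1`).
#' @export
reference_tissue <- function(name = c("myelin", "wm", "gm", "csf"), ...) {
  name <- match.arg(name)
  v <- switch(name,
    myelin = c(120, 20), wm = c(750, 60), gm = c(1300, 75),
    csf = c(4000, 2000))
  tissue_params(t1 = v[1], t2 = v[2], ...)
}

#' Low-level EPG simulation over an explicit event list
#'
#' Runs the extended-phase-graph recursion (constant RF phase, one
#' gradient-spoiling shift per SHIFT event, ideal inversion and saturation
#' pulses) for a batch of atoms.  Signal units: a 90 degree excitation of a
#' fully recovered Mz with `pd = 1` gives signal 1 before TE decay; each
#' readout reports the F0 state decayed to the echo time.
#'
#' @param events data.frame with `op`, `param` (see [protocol_events()]).
#' @param t1,t2,b1 vectors of equal length (one entry per atom), ms / ms /
#'   dimensionless.
#' @param te echo time in ms.
#' @param n_orders EPG truncation: highest retained dephasing order.
#' @param n_groups number of repetitions of the event list.
#' @param keep_groups how many trailing repetitions to return readouts for.
#' @return matrix `n_atoms x (n_readouts * keep_groups)` of real signal
#'   amplitudes (sign carries the phase of the constant-phase signal).
#' @export
epg_simulate <- function(events, t1, t2, b1 = rep(1, length(t1)), te = 0,
                         n_orders = 40L, n_groups = 1L, keep_groups = 1L) {
  stopifnot(length(t1) == length(t2), length(t1) == length(b1))
  if (any(t1 <= 0) || any(t2 <= 0)) stop("relaxation times must be positive")
  if (keep_groups > n_groups) stop("keep_groups must not exceed n_groups")
  epg_simulate_cpp(as.integer(events$op), as.numeric(events$param),
                   as.numeric(t1), as.numeric(t2), as.numeric(b1),
                   te, as.integer(n_orders), as.integer(n_groups),
                   as.integer(keep_groups))
}

#' Simulate a per-tissue ViSTa-MRF signal evolution
#'
#' Runs the EPG recursion over `n_settle_groups + 1` repetitions of the full
#' acquisition group and returns the evolution of the final repetition.  The
#' trailing saturation + TD of each group drives the longitudinal
#' magnetization into its cyclic steady state, so a few settle groups
#' suffice (see [steady_state_check()]).
#'
#' @param protocol a [vista_protocol()].
#' @param tissue a [tissue_params()].
#' @param n_settle_groups settle repetitions before the reported group
#'   (default 3).
#' @param n_orders EPG truncation order.
#' @return object of class `signal_evolution`: list with `values` (length
#'   `n_timepoints`, scaled by `pd`), `timepoint_kind`, `vista_index`.
#' @export
simulate_evolution <- function(protocol, tissue, n_settle_groups = 3L,
                               n_orders = 40L) {
  validate_protocol(protocol)
  stopifnot(inherits(tissue, "tissue_params"))
  if (n_settle_groups < 1) stop("n_settle_groups must be >= 1")
  ev <- protocol_events(protocol)
  sig <- epg_simulate(ev, tissue$t1, tissue$t2, tissue$b1, te = protocol$te,
                      n_orders = n_orders,
                      n_groups = n_settle_groups + 1L, keep_groups = 1L)
  kinds <- timepoint_kinds(protocol)
  structure(list(values = as.numeric(sig[1, ]) * tissue$pd,
                 timepoint_kind = kinds$kind,
                 vista_index = kinds$vista_index,
                 tissue = tissue),
            class = "signal_evolution")
}

#' @export
print.signal_evolution <- function(x, ...) {
  cat("signal_evolution:", length(x$values), "time points, ViSTa index",
      x$vista_index, "\n")
  cat(sprintf("  |ViSTa signal| = %.4f, max |signal| = %.4f\n",
              abs(x$values[x$vista_index]), max(abs(x$values))))
  invisible(x)
}

#' Steady-state convergence of the ViSTa signal across acquisition groups
#'
#' Reports the relative change of the first ViSTa time-point signal between
#' the last two simulated groups.
#'
#' @inheritParams simulate_evolution
#' @param tolerance convergence threshold on the relative change (strict
#'   inequality).
#' @return list with `converged` (logical) and `relative_change`.
#' @export
steady_state_check <- function(protocol, tissue, n_settle_groups = 3L,
                               tolerance = 1e-3, n_orders = 40L) {
  validate_protocol(protocol)
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (n_settle_groups < 1) stop("n_settle_groups must be >= 1")
  ev <- protocol_events(protocol)
  sig <- epg_simulate(ev, tissue$t1, tissue$t2, tissue$b1, te = protocol$te,
                      n_orders = n_orders,
                      n_groups = n_settle_groups + 1L, keep_groups = 2L)
  n_read <- ncol(sig) / 2L
  vi <- timepoint_kinds(protocol)$vista_index
  s_prev <- sig[1, vi]
  s_last <- sig[1, n_read + vi]
  denom <- max(abs(s_prev), .Machine$double.eps)
  rc <- abs(s_last - s_prev) / denom
  list(converged = rc < tolerance, relative_change = rc)
}
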