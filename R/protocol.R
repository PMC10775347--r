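#' ViSTa-MRF sequence protocol
#'
#' Describes the timing and flip-angle train of one ViSTa-MRF acquisition
#' group: `n_vista_blocks` double-inversion-prepared ViSTa blocks of
#' `n_vista_timepoints_per_block` gradient-spoiled (FISP) readouts each,
#' followed by one FISP-MRF block of `n_mrf_timepoints` readouts with a rest
#' period and an inversion pulse inserted at `mrf_inversion_index` (0-based).
#' Each ViSTa block except the last ends with a saturation pulse and a
#' recovery delay `td`; the group itself also ends with saturation + `td`,
#' which drives the short-T1 longitudinal magnetization into a steady state
#' across groups.
#'
#' Timing convention: `ti1` is the delay from the first to the second
#' inversion and `ti2` the delay from the second inversion to the first
#' readout of the block.  With the default `ti1` = 560 ms, `ti2` = 220 ms and
#' a saturation-recovery start (`td` = 380 ms), longitudinal magnetization of
#' both white matter (T1 = 750 ms) and gray matter (T1 = 1300 ms) crosses
#' zero at the first readout, leaving only the short-T1 myelin-water pool —
#' the "ViSTa signal".
#'
#' @param ti1,ti2 double-inversion delays in ms.
#' @param td saturation-recovery delay in ms.
#' @param tr,te repetition and echo time in ms.
#' @param n_vista_blocks,n_vista_timepoints_per_block,n_mrf_timepoints block
#'   structure counts.
#' @param mrf_inversion_index 0-based MRF time-point index before which the
#'   rest period and inversion are inserted.
#' @param mrf_rest_duration rest before the MRF inversion, ms.
#' @param fa_train flip angles in degrees, one per readout
#'   (`n_vista_blocks * n_vista_timepoints_per_block + n_mrf_timepoints`
#'   values).  Defaults to the packaged CRLB-optimized train.
#' @param rf_phase constant RF phase in degrees (the FISP convention used
#'   here; only constant-phase trains are supported).
#' @return An object of class `vista_protocol`.
#' @export
vista_protocol <- function(ti1 = 560, ti2 = 220, td = 380, tr = 12, te = 1.8,
                           n_vista_blocks = 8, n_vista_timepoints_per_block = 20,
                           n_mrf_timepoints = 500, mrf_inversion_index = 200,
                           mrf_rest_duration = 1000, fa_train = NULL,
                           rf_phase = 0) {
  n_tp <- n_vista_blocks * n_vista_timepoints_per_block + n_mrf_timepoints
  if (is.null(fa_train)) {
    fa_train <- default_fa_train("optimized", n_tp)
  }
  p <- structure(list(
    ti1 = ti1, ti2 = ti2, td = td, tr = tr, te = te,
    n_vista_blocks = as.integer(n_vista_blocks),
    n_vista_timepoints_per_block = as.integer(n_vista_timepoints_per_block),
    n_mrf_timepoints = as.integer(n_mrf_timepoints),
    mrf_inversion_index = as.integer(mrf_inversion_index),
    mrf_rest_duration = mrf_rest_duration,
    fa_train = as.numeric(fa_train),
    rf_phase = rf_phase
  ), class = "vista_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "vista_protocol"))
  n_tp <- p$n_vista_blocks * p$n_vista_timepoints_per_block + p$n_mrf_timepoints
  if (length(p$fa_train) != n_tp) {
    stop("fa_train must have ", n_tp, " angles, got ", length(p$fa_train))
  }
  if (any(p$fa_train < 0 | p$fa_train > 90)) {
    stop("flip angles must lie in [0, 90] degrees")
  }
  if (!(p$te < p$tr)) stop("te must be smaller than tr")
  if (!(p$ti2 < p$ti1)) stop("ti2 must be smaller than ti1")
  if (any(c(p$ti1, p$ti2, p$td, p$tr) <= 0)) stop("timings must be positive")
  if (p$mrf_inversion_index < 0 || p$mrf_inversion_index >= p$n_mrf_timepoints) {
    stop("mrf_inversion_index out of range")
  }
  invisible(p)
}

#' Flip-angle trains bundled with the package
#'
#' `"optimized"` is the CRLB-optimized train shipped in `inst/extdata`
#' (produced by [optimize_fa()] for the default protocol and target tissues);
#' `"constant35"` is a flat 35-degree reference train; `"ramp"` is a simple
#' non-optimized baseline with a linear ramp in the ViSTa blocks and
#' sinusoidal lobes in the MRF block.
#'
#' @param kind one of `"optimized"`, `"constant35"`, `"ramp"`.
#' @param n_timepoints train length.
#' @return Numeric vector of flip angles in degrees.
#' @export
default_fa_train <- function(kind = c("optimized", "constant35", "ramp"),
                             n_timepoints = 660L) {
  kind <- match.arg(kind)
  if (kind == "optimized") {
    path <- system.file("extdata", "fa_train_optimized.txt", package = "vistamrf")
    if (nzchar(path) && file.exists(path)) {
      fa <- read_fa_train(path)
      if (length(fa) == n_timepoints) return(fa)
    }
    # fall back to the ramp baseline when the packaged train does not apply
    kind <- "ramp"
  }
  if (kind == "constant35") return(rep(35, n_timepoints))
  # ramp baseline: assumes the default 8 x 20 + 500 layout when possible
  if (n_timepoints == 660L) {
    vista <- rep(seq(10, 70, length.out = 20), 8)
    lobe <- function(n, lo, hi) lo + (hi - lo) * sin(pi * seq_len(n) / (n + 1))
    mrf <- c(lobe(250, 5, 70), lobe(250, 5, 55))
    c(vista, mrf)
  } else {
    5 + 60 * abs(sin(pi * seq_len(n_timepoints) / 120))
  }
}

#' Compile a protocol into the EPG event list of one acquisition group
#'
#' Events are (opcode, parameter) pairs consumed by the EPG engine:
#' 1 = inversion (ideal Z -> -Z), 2 = saturation (all states zeroed),
#' 3 = delay in ms, 4 = excitation + readout at TE (parameter = nominal flip
#' angle in degrees), 5 = one gradient-spoiling state shift.  Each readout TR
#' expands to PULSE, DELAY(tr), SHIFT.
#'
#' @param p a [vista_protocol()].
#' @return data.frame with columns `op`, `param`.
#' @export
protocol_events <- function(p) {
  validate_protocol(p)
  ops <- integer(0); pars <- numeric(0)
  add <- function(o, v = 0) { ops <<- c(ops, o); pars <<- c(pars, v) }
  fa <- p$fa_train
  i <- 1L
  for (blk in seq_len(p$n_vista_blocks)) {
    add(1L); add(3L, p$ti1)   # first inversion, TI1
    add(1L); add(3L, p$ti2)   # second inversion, TI2
    for (j in seq_len(p$n_vista_timepoints_per_block)) {
      add(4L, fa[i]); add(3L, p$tr); add(5L)
      i <- i + 1L
    }
    if (blk < p$n_vista_blocks) { add(2L); add(3L, p$td) }
  }
  for (j in seq_len(p$n_mrf_timepoints)) {
    if (j - 1L == p$mrf_inversion_index) { add(3L, p$mrf_rest_duration); add(1L) }
    add(4L, fa[i]); add(3L, p$tr); add(5L)
    i <- i + 1L
  }
  add(2L); add(3L, p$td)      # inter-group saturation + recovery
  data.frame(op = ops, param = pars)
}

#' Time-point labels and the ViSTa index
#'
#' @param p a [vista_protocol()].
#' @return list with `kind` (character vector `"vista"`/`"mrf"` per time
#'   point) and `vista_index` (1-based index of the first ViSTa time point).
#' @export
timepoint_kinds <- function(p) {
  nv <- p$n_vista_blocks * p$n_vista_timepoints_per_block
  list(kind = c(rep("vista", nv), rep("mrf", p$n_mrf_timepoints)),
       vista_index = 1L)
}

#' Sequence timing model
#'
#' Sums the modeled intervals of one acquisition group (inversions and
#' saturations are treated as instantaneous).  The printed protocol-level
#' group time of 19 s is larger than this sum (~18.2 s with the default
#' timings) because RF pulse durations, spoilers and rewinders are not part
#' of the timing model; `nominal_group_seconds` carries that protocol-level
#' value for scan-time arithmetic.
#'
#' @param p a [vista_protocol()].
#' @return list with `group_ms` (modeled), `nominal_group_seconds` (19),
#'   and the per-segment breakdown.
#' @export
group_duration <- function(p) {
  validate_protocol(p)
  prep <- p$ti1 + p$ti2
  vista_ms <- p$n_vista_blocks * (prep + p$n_vista_timepoints_per_block * p$tr) +
    (p$n_vista_blocks - 1) * p$td
  mrf_ms <- p$n_mrf_timepoints * p$tr + p$mrf_rest_duration
  end_ms <- p$td
  list(group_ms = vista_ms + mrf_ms + end_ms,
       nominal_group_seconds = 19,
       vista_ms = vista_ms, mrf_ms = mrf_ms, intergroup_ms = end_ms)
}

#' Total scan time for a multi-group acquisition
#'
#' @param n_groups number of acquisition groups.
#' @param group_seconds seconds per group; defaults to the nominal
#'   protocol-level 19 s (see [group_duration()] for the modeled value and
#'   the documented gap).
#' @return scan time in minutes.
#' @export
scan_time_minutes <- function(n_groups, group_seconds = 19) {
  n_groups * group_seconds / 60
}

#' Per-slice acquisition time of the standard (non-MRF) ViSTa sequence
#'
#' One fully sampled slice needs `n_interleaves` repetitions of the
#' double-inversion preparation, each lasting TI1 + TI2 + TD.
#'
#' @param p a [vista_protocol()] supplying the timings.
#' @param n_interleaves spiral interleaves per slice.
#' @return time in seconds.
#' @export
standard_vista_slice_seconds <- function(p, n_interleaves = 48) {
  n_interleaves * (p$ti1 + p$ti2 + p$td) / 1000
}

#' @export
print.vista_protocol <- function(x, ...) {
  n_tp <- length(x$fa_train)
  cat("ViSTa-MRF protocol:", x$n_vista_blocks, "ViSTa blocks x",
      x$n_vista_timepoints_per_block, "+", x$n_mrf_timepoints, "MRF =",
      n_tp, "time points\n")
  cat(sprintf("  TI1/TI2/TD = %g/%g/%g ms, TR/TE = %g/%g ms\n",
              x$ti1, x$ti2, x$td, x$tr, x$te))
  cat(sprintf("  MRF rest %g ms + inversion before point %d\n",
              x$mrf_rest_duration, x$mrf_inversion_index))
  cat(sprintf("  FA train: %.1f..%.1f deg (first %.1f)\n",
              min(x$fa_train), max(x$fa_train), x$fa_train[1]))
  gd <- group_duration(x)
  cat(sprintf("  modeled group duration %.2f s (nominal %g s)\n",
              gd$group_ms / 1000, gd$nominal_group_seconds))
  invisible(x)
}

#' Read / write protocol configuration files
#'
#' Protocols are stored as YAML key/value files (durations in ms, angles in
#' degrees); the flip-angle train is stored separately as a plain-text file
#' with one angle per line (see [write_fa_train()]).
#'
#' @param p a [vista_protocol()].
#' @param path file path.
#' @param fa_path optional path for the flip-angle train; defaults to
#'   `<path>` with extension `.fa.txt`.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns a [vista_protocol()].
#' @export
write_protocol <- function(p, path, fa_path = NULL) {
  validate_protocol(p)
  if (is.null(fa_path)) fa_path <- paste0(sub("\\.ya?ml$", "", path), ".fa.txt")
  fields <- p[setdiff(names(p), "fa_train")]
  fields$fa_train_file <- basename(fa_path)
  fields$units <- "durations: ms; angles: degrees"
  yaml::write_yaml(fields, path)
  write_fa_train(p$fa_train, fa_path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path, fa_path = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(fa_path)) {
    fa_path <- file.path(dirname(path), y$fa_train_file)
  }
  fa <- read_fa_train(fa_path)
  vista_protocol(ti1 = y$ti1, ti2 = y$ti2, td = y$td, tr = y$tr, te = y$te,
                 n_vista_blocks = y$n_vista_blocks,
                 n_vista_timepoints_per_block = y$n_vista_timepoints_per_block,
                 n_mrf_timepoints = y$n_mrf_timepoints,
                 mrf_inversion_index = y$mrf_inversion_index,
                 mrf_rest_duration = y$mrf_rest_duration,
                 fa_train = fa, rf_phase = y$rf_phase)
}

#' Plain-text flip-angle train files (one angle in degrees per line)
#'
#' @param fa numeric vector of flip angles in degrees.
#' @param path file path.
#' @export
write_fa_train <- function(fa, path) {
  writeLines(formatC(fa, digits = 10, format = "g"), path)
  invisible(path)
}

#' @rdname write_fa_train
#' @export
read_fa_train <- function(path) {
  as.numeric(readLines(path))
}
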