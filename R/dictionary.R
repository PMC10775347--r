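#' Dictionary parameter grid
#'
#' Default grids resolve the myelin-water anchor (120/20 ms) finely and span
#' brain-tissue relaxation times: t1 in \{60:10:300, 320:20:1000,
#' 1050:50:3000\} ms, t2 in \{10:2:100, 105:5:300, 320:20:500\} ms, B1+ in
#' 0.70:0.05:1.20.  Pairs with t2 > t1 are excluded.
#'
#' @param t1_values,t2_values,b1_values strictly increasing grids.
#' @return object of class `dict_grid`.
#' @export
dict_grid <- function(t1_values = c(seq(60, 300, 10), seq(320, 1000, 20),
                                    seq(1050, 3000, 50)),
                      t2_values = c(seq(10, 100, 2), seq(105, 300, 5),
                                    seq(320, 500, 20)),
                      b1_values = seq(0.70, 1.20, 0.05)) {
  for (v in list(t1_values, t2_values, b1_values)) {
    if (length(v) == 0) stop("empty grid")
    if (any(duplicated(v))) stop("duplicate grid values requested")
    if (is.unsorted(v, strictly = TRUE)) stop("grids must be strictly increasing")
  }
  structure(list(t1_values = as.numeric(t1_values),
                 t2_values = as.numeric(t2_values),
                 b1_values = as.numeric(b1_values)),
            class = "dict_grid")
}

#' Enumerate grid atoms (t2 <= t1 only)
#' @param grid a [dict_grid()].
#' @return data.frame with columns `t1`, `t2`, `b1`, ordered b1-major then
#'   t1 then t2 (deterministic atom indexing).
#' @export
grid_atoms <- function(grid) {
  stopifnot(inherits(grid, "dict_grid"))
  tt <- expand.grid(t2 = grid$t2_values, t1 = grid$t1_values,
                    KEEP.OUT.ATTRS = FALSE)
  tt <- tt[tt$t2 <= tt$t1, c("t1", "t2")]
  out <- do.call(rbind, lapply(grid$b1_values, function(b) {
    cbind(tt, b1 = b)
  }))
  rownames(out) <- NULL
  out
}

#' Build the ViSTa-MRF dictionary by EPG simulation
#'
#' One steady-state EPG evolution per grid point at `pd = 1`.  Deterministic
#' given inputs (no randomness in this module).
#'
#' @param grid a [dict_grid()].
#' @param protocol a [vista_protocol()].
#' @param n_settle_groups settle repetitions (see [simulate_evolution()]).
#' @param n_orders EPG truncation order.
#' @return object of class `vista_dictionary`: list with `atoms`
#'   (`n_atoms x n_timepoints` matrix), `index` (data.frame t1/t2/b1),
#'   `norms`, `grid`, `protocol`.
#' @export
build_dictionary <- function(grid, protocol, n_settle_groups = 3L,
                             n_orders = 40L) {
  stopifnot(inherits(grid, "dict_grid"))
  validate_protocol(protocol)
  idx <- grid_atoms(grid)
  ev <- protocol_events(protocol)
  atoms <- epg_simulate(ev, idx$t1, idx$t2, idx$b1, te = protocol$te,
                        n_orders = n_orders,
                        n_groups = n_settle_groups + 1L, keep_groups = 1L)
  norms <- sqrt(rowSums(atoms^2))
  if (any(norms == 0)) stop("dictionary contains an all-zero atom")
  structure(list(atoms = atoms, index = idx, norms = norms,
                 grid = grid, protocol = protocol),
            class = "vista_dictionary")
}

#' @export
print.vista_dictionary <- function(x, ...) {
  cat("vista_dictionary:", nrow(x$atoms), "atoms x", ncol(x$atoms),
      "time points\n")
  cat("  t1:", length(x$grid$t1_values), "values; t2:",
      length(x$grid$t2_values), "values; b1:",
      length(x$grid$b1_values), "values\n")
  invisible(x)
}

#' Temporal subspace basis of a dictionary
#'
#' Left singular vectors of the (time x atoms) matrix, computed from the
#' 660 x 660 Gram matrix of the unnormalized atoms; `energy_fraction` is the
#' cumulative squared-singular-value fraction captured by the first `k`
#' components.
#'
#' @param dict a [vista_dictionary()][build_dictionary].
#' @param k subspace rank (default 14).
#' @return object of class `temporal_basis`: list with `phi`
#'   (`n_timepoints x k`, orthonormal), `singular_values` (all), `k`,
#'   `energy_fraction`.
#' @export
compute_basis <- function(dict, k = 14L) {
  stopifnot(inherits(dict, "vista_dictionary"))
  n_t <- ncol(dict$atoms)
  if (k < 1 || k > min(nrow(dict$atoms), n_t)) stop("k out of range")
  G <- crossprod(dict$atoms)           # time x time Gram
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  sv <- sqrt(ev)
  phi <- eg$vectors[, seq_len(k), drop = FALSE]
  # fix sign convention: largest-magnitude element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(phi[, j]))
    if (phi[i, j] < 0) phi[, j] <- -phi[, j]
  }
  structure(list(phi = phi, singular_values = sv, k = as.integer(k),
                 energy_fraction = sum(ev[seq_len(k)]) / sum(ev)),
            class = "temporal_basis")
}

#' @export
print.temporal_basis <- function(x, ...) {
  cat(sprintf("temporal_basis: %d x %d, energy fraction %.6f\n",
              nrow(x$phi), x$k, x$energy_fraction))
  invisible(x)
}

# index range of the b1 sub-dictionary nearest to b1_local
b1_subdict <- function(dict, b1_local) {
  b1v <- dict$grid$b1_values
  pad <- 0.025 + 1e-12
  if (b1_local < min(b1v) - pad || b1_local > max(b1v) + pad) {
    stop("b1_local outside dictionary support [",
         min(b1v) - 0.025, ", ", max(b1v) + 0.025, "]")
  }
  b1n <- b1v[which.min(abs(b1v - b1_local))]
  which(dict$index$b1 == b1n)
}

#' Match one voxel signal against the B1-restricted sub-dictionary
#'
#' Restricts atoms to the B1 grid value nearest `b1_local` and returns the
#' arg-max of the normalized inner product `|<signal, atom>| / ||atom||`
#' (ties broken toward the lowest atom index).  The proton-density scale is
#' `Re(<signal, atom>) / ||atom||^2` at the winner.
#'
#' @param signal numeric or complex vector of length `n_timepoints`.
#' @param dict a dictionary from [build_dictionary()].
#' @param b1_local local transmit scale; must lie within half a grid step of
#'   the dictionary's B1 range.
#' @return list `(t1, t2, pd_scale, score)`; an all-zero signal is flagged
#'   as background with `t1 = t2 = pd_scale = 0`.
#' @export
match_voxel <- function(signal, dict, b1_local = 1) {
  stopifnot(inherits(dict, "vista_dictionary"))
  if (length(signal) != ncol(dict$atoms)) stop("signal length mismatch")
  if (all(signal == 0)) {
    return(list(t1 = 0, t2 = 0, pd_scale = 0, score = 0, background = TRUE))
  }
  sub <- b1_subdict(dict, b1_local)
  ip <- as.vector(dict$atoms[sub, , drop = FALSE] %*% signal)
  score <- Mod(ip) / dict$norms[sub]
  w <- which.max(score)          # which.max returns the first (lowest index) max
  i <- sub[w]
  list(t1 = dict$index$t1[i], t2 = dict$index$t2[i],
       pd_scale = Re(ip[w]) / dict$norms[i]^2, score = score[w],
       background = FALSE)
}

#' Batch dictionary matching in the temporal subspace
#'
#' Matches many voxel signals given as subspace coefficients: for signals
#' `s = phi %*% cf` the inner products `<s, atom>` equal
#' `<cf, t(phi) %*% atom>`, so matching runs in the `k`-dimensional
#' coefficient space with the full-signal atom norms.  Voxels are grouped by
#' their nearest B1 grid value.
#'
#' @param cf `k x n_voxels` matrix (real or complex) of subspace
#'   coefficients.
#' @param dict dictionary from [build_dictionary()].
#' @param basis a [compute_basis()] result whose `phi` spans the signals.
#' @param b1 per-voxel B1 values (length `n_voxels` or scalar).
#' @param chunk voxels per BLAS block.
#' @return list of vectors `t1`, `t2`, `pd_scale`, `score`.
#' @export
match_coefficients <- function(cf, dict, basis, b1 = 1, chunk = 1024L) {
  stopifnot(inherits(dict, "vista_dictionary"), inherits(basis, "temporal_basis"))
  k <- nrow(basis$phi); stopifnot(nrow(cf) == basis$k)
  nv <- ncol(cf)
  b1 <- rep_len(b1, nv)
  atoms_k <- dict$atoms %*% basis$phi          # n_atoms x k
  t1 <- t2 <- pdsc <- score <- numeric(nv)
  b1v <- dict$grid$b1_values
  b1_near <- b1v[pmin(pmax(findInterval(b1, (b1v[-1] + b1v[-length(b1v)]) / 2) + 1, 1), length(b1v))]
  cplx <- is.complex(cf)
  for (bv in unique(b1_near)) {
    vox <- which(b1_near == bv)
    sub <- which(dict$index$b1 == bv)
    A <- atoms_k[sub, , drop = FALSE]
    nrm <- dict$norms[sub]
    for (st in seq(1, length(vox), by = chunk)) {
      vv <- vox[st:min(st + chunk - 1, length(vox))]
      C <- cf[, vv, drop = FALSE]
      ip <- if (cplx) (A %*% Re(C)) + 1i * (A %*% Im(C)) else A %*% C
      sc <- Mod(ip) / nrm
      w <- max.col(t(sc), ties.method = "first")
      pick <- cbind(w, seq_along(vv))
      t1[vv] <- dict$index$t1[sub[w]]
      t2[vv] <- dict$index$t2[sub[w]]
      pdsc[vv] <- Re(ip[pick]) / nrm[w]^2
      score[vv] <- sc[pick]
    }
  }
  list(t1 = t1, t2 = t2, pd_scale = pdsc, score = score)
}

#' Write / read a dictionary + basis container
#'
#' Self-describing serialized container (RDS payload plus a JSON sidecar
#' manifest recording the schema version, grid sizes and a protocol hash).
#'
#' @param dict dictionary; `basis` optional.
#' @param path output path (`.rds`).
#' @param basis optional [compute_basis()] result stored alongside.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path, basis = NULL) {
  stopifnot(inherits(dict, "vista_dictionary"))
  obj <- list(schema = "vistamrf-dictionary-1", dict = dict, basis = basis)
  saveRDS(obj, path)
  manifest <- list(schema = obj$schema,
                   n_atoms = nrow(dict$atoms),
                   n_timepoints = ncol(dict$atoms),
                   n_t1 = length(dict$grid$t1_values),
                   n_t2 = length(dict$grid$t2_values),
                   n_b1 = length(dict$grid$b1_values),
                   k = if (!is.null(basis)) basis$k else NULL,
                   protocol_hash = protocol_hash(dict$protocol))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "vistamrf-dictionary-1")) {
    stop("not a vistamrf dictionary container")
  }
  obj
}

protocol_hash <- function(p) {
  s <- paste(vapply(p[setdiff(names(p), "fa_train")], function(x)
    paste(format(x, digits = 12), collapse = ","), ""), collapse = ";")
  s <- paste(s, paste(format(p$fa_train, digits = 12), collapse = ","), sep = "|")
  # small rolling hash; stable across sessions
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%d", h)
}
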