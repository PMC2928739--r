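# Normalized cross-correlations of residue fluctuations (dynamic
# cross-correlation maps) and time-delayed orientational autocorrelations of
# virtual C-alpha backbone bond vectors.

#' Dynamic cross-correlation matrix of residue fluctuations
#'
#' Computes the normalized equal-time correlation
#' `C_ij = <dR_i . dR_j> / sqrt(<dR_i^2> <dR_j^2>)`, where
#' `dR_i(t) = R_i(t) - <R_i>` is the fluctuation of residue i about its mean
#' position over the analyzed frames. Values lie in `[-1, 1]`: +1 fully
#' correlated, -1 fully anti-correlated. Global rigid-body motion must be
#' removed first, otherwise the statistic is dominated by overall
#' rotation; by default every analyzed frame is superposed on `fit_mask`
#' (set `fit_mask = NULL` only for pre-aligned trajectories).
#'
#' @param traj a [trajectory()].
#' @param fit_mask residues to superpose each frame on before computing
#'   fluctuations (default: all residues). `NA` skips alignment.
#' @param measure_mask residues to include in the matrix (default all).
#' @param window optional `(start, end]` time window (ns); `NULL` uses the
#'   whole trajectory.
#' @param exclude_equilibration drop frames flagged as equilibration?
#' @param global_mean if `TRUE`, fluctuations are taken about the mean over
#'   *all* usable frames rather than the window-local mean.
#' @return matrix of class `"correlation_matrix"` with `chain:resno`
#'   dimnames; residues with zero positional variance give `NA` rows/columns
#'   (never a silent 0). Attributes record the window and alignment mask.
#' @export
cross_correlation_matrix <- function(traj, fit_mask = NULL,
                                     measure_mask = NULL, window = NULL,
                                     exclude_equilibration = TRUE,
                                     global_mean = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  measure_mask <- as_selection(measure_mask, top)
  align <- !(length(fit_mask) == 1L && is.na(fit_mask[1]))
  if (align) fit_mask <- as_selection(fit_mask, top)
  all_usable <- usable_frames(traj, exclude_equilibration)
  frames <- usable_frames(traj, exclude_equilibration, window)
  if (length(frames) < 2L) {
    stop("window contains fewer than 2 usable frames")
  }
  work <- if (global_mean) all_usable else frames
  flat <- matrix(0, length(work), 3L * nrow(top))
  if (align) {
    ref <- matrix(traj$coords[work[1], , ], ncol = 3L)
    for (k in seq_along(work)) {
      cc <- matrix(traj$coords[work[k], , ], ncol = 3L)
      sp <- kabsch_superpose(cc, ref, fit_mask)
      flat[k, ] <- as.vector(t(apply_superposition(cc, sp)))
    }
  } else {
    flat <- flatten_frames(traj, frames = work)
  }
  mu <- colMeans(flat)
  keep <- match(frames, work)
  ctr <- sweep(flat[keep, , drop = FALSE], 2L, mu)
  n <- nrow(top)
  xi <- seq(1L, 3L * n, 3L)
  num <- crossprod(ctr[, xi]) + crossprod(ctr[, xi + 1L]) +
    crossprod(ctr[, xi + 2L])
  num <- num / length(frames)
  v <- diag(num)
  zero <- v <= 0 | v < 1e-300
  denom <- sqrt(outer(v, v))
  C <- num / denom
  C[zero, ] <- NA_real_
  C[, zero] <- NA_real_
  C <- (C + t(C)) / 2          # kill floating-point asymmetry
  C <- C[measure_mask, measure_mask, drop = FALSE]
  labs <- residue_labels(top)[measure_mask]
  dimnames(C) <- list(labs, labs)
  attr(C, "window") <- if (is.null(window)) "whole" else window
  attr(C, "alignment_mask") <- if (align) as.integer(fit_mask) else NULL
  attr(C, "frames_used") <- length(frames)
  class(C) <- c("correlation_matrix", "matrix", "array")
  C
}

#' @export
print.correlation_matrix <- function(x, ...) {
  w <- attr(x, "window")
  wtxt <- if (identical(w, "whole")) "whole trajectory" else
    sprintf("(%g, %g] ns", w[1], w[2])
  cat(sprintf("cross-correlation matrix: %d x %d residues, %s, %d frames\n",
              nrow(x), ncol(x), wtxt, attr(x, "frames_used")))
  invisible(x)
}

#' @export
plot.correlation_matrix <- function(x, ...) {
  m <- unclass(x)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)),
                  m[, rev(seq_len(ncol(m)))], zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "residue", ylab = "residue", ...)
  invisible(x)
}

#' Time-windowed cross-correlation matrices
#'
#' One [cross_correlation_matrix()] per time window (windows may come from a
#' clustering-derived segmentation of the trajectory, and may overlap). If
#' two residue blocks are named, the pairwise contrast between windows is
#' summarized as the mean absolute difference of the matrices restricted to
#' `block_a x block_b` — a single number quantifying how much the coupling
#' between the two regions changed between windows.
#'
#' @inheritParams cross_correlation_matrix
#' @param windows list of `(start, end]` pairs (ns).
#' @param block_a,block_b optional residue selections naming the two blocks
#'   to contrast across windows.
#' @return list with `matrices` (one per window) and, when blocks are given,
#'   `block_contrast`: a `windows x windows` matrix of mean absolute
#'   block-restricted differences.
#' @export
windowed_correlations <- function(traj, windows, fit_mask = NULL,
                                  measure_mask = NULL, block_a = NULL,
                                  block_b = NULL,
                                  exclude_equilibration = TRUE,
                                  global_mean = FALSE) {
  if (!is.list(windows) || length(windows) == 0L) {
    stop("'windows' must be a non-empty list of (start, end] pairs")
  }
  mats <- lapply(windows, function(w) {
    cross_correlation_matrix(traj, fit_mask = fit_mask,
                             measure_mask = measure_mask, window = w,
                             exclude_equilibration = exclude_equilibration,
                             global_mean = global_mean)
  })
  names(mats) <- vapply(windows, function(w)
    sprintf("(%g,%g]", w[1], w[2]), "")
  out <- list(matrices = mats)
  if (!is.null(block_a) && !is.null(block_b)) {
    sel <- as_selection(measure_mask, traj$topology)
    a <- match(as_selection(block_a, traj$topology), sel)
    b <- match(as_selection(block_b, traj$topology), sel)
    if (anyNA(a) || anyNA(b)) {
      stop("contrast blocks must lie inside the measure mask")
    }
    nw <- length(mats)
    contrast <- matrix(0, nw, nw, dimnames = list(names(mats), names(mats)))
    for (i in seq_len(nw)) for (j in seq_len(nw)) {
      contrast[i, j] <- mean(abs(mats[[i]][a, b] - mats[[j]][a, b]),
                             na.rm = TRUE)
    }
    out$block_contrast <- contrast
  }
  out
}

#' Virtual backbone bond vectors of one frame
#'
#' The virtual backbone bond vector `M_i` is the unit vector from the
#' C-alpha of residue i-1 to the C-alpha of residue i. Vectors are computed
#' within chains only; pairs spanning a chain boundary are omitted.
#'
#' @param coords `residues x 3` coordinate matrix.
#' @param top the matching [topology()].
#' @return `bonds x 3` matrix of unit vectors with a `bonds` attribute: a
#'   data frame (`chain`, `from_index`, `to_index`, `label`).
#' @export
bond_vectors <- function(coords, top) {
  stopifnot(inherits(top, "topology"))
  if (nrow(coords) != nrow(top)) stop("coordinates do not match topology")
  off <- chain_offsets(top)
  if (any(off$end - off$start < 1L)) {
    stop("every chain needs at least 2 residues for bond vectors")
  }
  from <- unlist(lapply(seq_len(nrow(off)), function(i)
    seq(off$start[i], off$end[i] - 1L)))
  to <- from + 1L
  v <- coords[to, , drop = FALSE] - coords[from, , drop = FALSE]
  len <- sqrt(rowSums(v * v))
  if (any(len <= 1e-12)) {
    k <- which(len <= 1e-12)[1]
    stop("zero-length bond between ", residue_labels(top)[from[k]], " and ",
         residue_labels(top)[to[k]])
  }
  m <- v / len
  labs <- paste(residue_labels(top)[from], residue_labels(top)[to],
                sep = "->")
  attr(m, "bonds") <- data.frame(chain = top$chain[from], from_index = from,
                                 to_index = to, label = labs,
                                 stringsAsFactors = FALSE)
  rownames(m) <- labs
  m
}

#' Time-delayed autocorrelations of the virtual backbone bond vectors
#'
#' For each virtual bond `M_i`, computes `<M_i(t) . M_i(t + tau)>`, averaged
#' over all usable frame pairs `(t, t + tau)`, for each requested delay tau.
#' At `tau = 0` the value is 1 for every bond; as tau grows, bonds with free
#' orientational motion decorrelate while restricted bonds stay near 1.
#' The statistic is computed on the raw (unaligned) coordinates: bond
#' vectors are internal directions and per-frame realignment would distort
#' their orientational dynamics. A sensible upper delay is slightly more
#' than half the usable span; beyond that the average runs over too few
#' frame pairs.
#'
#' @param traj a [trajectory()] with uniformly spaced frames.
#' @param delays numeric vector of delays tau (ns); each must be a
#'   nonnegative multiple of the frame spacing and leave at least 2 frame
#'   pairs.
#' @param exclude_equilibration drop frames flagged as equilibration?
#' @return matrix of class `"bond_autocorrelation"`, `bonds x delays`, with
#'   the bond table and delay grid as attributes.
#' @export
bond_autocorrelation <- function(traj, delays,
                                 exclude_equilibration = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  frames <- usable_frames(traj, exclude_equilibration)
  if (length(frames) < 3L) stop("need at least 3 usable frames")
  tt <- traj$times[frames]
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop("usable frames are not uniformly spaced in time")
  }
  dt <- dt[1]
  delays <- as.numeric(delays)
  if (any(delays < 0)) stop("delays must be nonnegative")
  lags <- delays / dt
  if (any(abs(lags - round(lags)) > 1e-6)) {
    bad <- delays[abs(lags - round(lags)) > 1e-6][1]
    stop("delay ", bad, " ns is not a multiple of the frame spacing ",
         dt, " ns")
  }
  lags <- as.integer(round(lags))
  if (any(length(frames) - lags < 2L)) {
    bad <- delays[length(frames) - lags < 2L][1]
    stop("delay ", bad, " ns leaves fewer than 2 frame pairs")
  }
  # bond unit vectors for every usable frame
  top <- traj$topology
  b0 <- bond_vectors(matrix(traj$coords[frames[1], , ], ncol = 3L), top)
  nb <- nrow(b0)
  M <- array(0, c(length(frames), nb, 3L))
  M[1, , ] <- b0
  for (k in seq_along(frames)[-1L]) {
    M[k, , ] <- bond_vectors(matrix(traj$coords[frames[k], , ], ncol = 3L),
                             top)
  }
  out <- matrix(0, nb, length(lags))
  for (j in seq_along(lags)) {
    L <- lags[j]
    t0 <- seq_len(length(frames) - L)
    dots <- M[t0, , 1, drop = FALSE] * M[t0 + L, , 1, drop = FALSE] +
      M[t0, , 2, drop = FALSE] * M[t0 + L, , 2, drop = FALSE] +
      M[t0, , 3, drop = FALSE] * M[t0 + L, , 3, drop = FALSE]
    out[, j] <- colMeans(matrix(dots, length(t0), nb))
  }
  dimnames(out) <- list(rownames(b0), sprintf("tau=%g", delays))
  attr(out, "delays") <- delays
  attr(out, "bonds") <- attr(b0, "bonds")
  class(out) <- c("bond_autocorrelation", "matrix", "array")
  out
}

#' @export
print.bond_autocorrelation <- function(x, ...) {
  cat(sprintf("bond-vector autocorrelation: %d bonds x %d delays (%s ns)\n",
              nrow(x), ncol(x),
              paste(attr(x, "delays"), collapse = ", ")))
  invisible(x)
}

#' @export
plot.bond_autocorrelation <- function(x, ...) {
  d <- attr(x, "delays")
  graphics::matplot(seq_len(nrow(x)), unclass(x), type = "l", lty = 1,
                    ylim = c(-1, 1), xlab = "virtual bond",
                    ylab = "autocorrelation", ...)
  graphics::legend("bottomleft", legend = sprintf("tau = %g ns", d),
                   col = seq_along(d), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
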