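# Optimal rigid-body superposition (Kabsch) and chain-pivot RMSD analyses.
#
# The pivot idiom: superpose a complex on one chain (fit mask) and measure
# the RMSD of another (measure mask). Distinct masks expose quaternary
# (relative-orientation) changes that self-aligned RMSD hides.

#' Kabsch superposition of two C-alpha coordinate sets
#'
#' Finds the proper rotation and translation minimizing the mass-unweighted
#' RMSD between `mobile` and `reference` over the residues in `fit_mask`.
#' Reflections are forbidden: the returned rotation has determinant +1.
#'
#' @param mobile,reference `residues x 3` coordinate matrices on a common
#'   topology.
#' @param fit_mask selection of residues to fit on (default: all). At least 3
#'   non-collinear residues are required.
#' @return object of class `"superposition"`: list with `rotation` (3x3),
#'   `translation` (length 3) and `rmsd` (Angstrom, over the fit mask). The
#'   aligned mobile is `mobile %*% rotation + translation` (rows are points);
#'   see [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, reference, fit_mask = NULL) {
  if (!is.matrix(mobile) || !is.matrix(reference) ||
      ncol(mobile) != 3L || ncol(reference) != 3L ||
      nrow(mobile) != nrow(reference)) {
    stop("'mobile' and 'reference' must be residue x 3 matrices of equal size")
  }
  if (is.null(fit_mask)) fit_mask <- seq_len(nrow(mobile))
  idx <- sort(unique(as.integer(fit_mask)))
  if (any(idx < 1L) || any(idx > nrow(mobile))) {
    stop("fit mask indices out of range")
  }
  if (length(idx) < 3L) stop("fit mask must contain at least 3 residues")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2L, pbar); Qc <- sweep(Q, 2L, qbar)
  sv <- svd(crossprod(Pc, Qc))
  # collinear/degenerate fit sets leave the rotation underdetermined
  if (sv$d[2] <= 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate (collinear or coincident) fit configuration")
  }
  s <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  tvec <- qbar - as.vector(pbar %*% R)
  d <- Pc %*% R - Qc
  structure(list(rotation = R, translation = tvec,
                 rmsd = sqrt(mean(rowSums(d * d)))),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.6g A over fit mask\n", x$rmsd))
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation:", sprintf("%.6g", x$translation), "\n")
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param coords `n x 3` coordinate matrix.
#' @param sp a `"superposition"` from [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  stopifnot(inherits(sp, "superposition"))
  sweep(coords %*% sp$rotation, 2L, sp$translation, "+")
}

# plain RMSD between congruent coordinate sets over a mask
coord_rmsd <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- seq_len(nrow(a))
  d <- a[mask, , drop = FALSE] - b[mask, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

#' Per-frame RMSD with independent fit and measure masks
#'
#' For each frame: superpose on `fit_mask`, then report the RMSD over
#' `measure_mask`. With `fit_mask == measure_mask` this is the ordinary
#' self-aligned RMSD; with distinct masks it is the chain-pivot RMSD (e.g.
#' fit the complex on one chain, measure the displacement of the other),
#' which is sensitive to changes in relative chain orientation.
#'
#' @param traj a [trajectory()].
#' @param reference `residues x 3` reference coordinates on the same
#'   topology.
#' @param fit_mask,measure_mask residue selections ([select_residues()]);
#'   both default to all residues.
#' @return data frame of class `"rmsd_series"` with columns `time` (ns) and
#'   `rmsd` (Angstrom).
#' @export
rmsd_timeseries <- function(traj, reference, fit_mask = NULL,
                            measure_mask = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  fit_mask <- as_selection(fit_mask, traj$topology)
  measure_mask <- as_selection(measure_mask, traj$topology)
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    cc <- matrix(traj$coords[f, , ], ncol = 3L)
    sp <- kabsch_superpose(cc, reference, fit_mask)
    out[f] <- coord_rmsd(apply_superposition(cc, sp), reference,
                         measure_mask)
  }
  structure(data.frame(time = traj$times, rmsd = out),
            class = c("rmsd_series", "data.frame"))
}

#' @export
plot.rmsd_series <- function(x, ...) {
  plot(x$time, x$rmsd, type = "l", xlab = "time (ns)", ylab = "RMSD (A)",
       ...)
  invisible(x)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @inheritParams rmsd_timeseries
#' @return a [trajectory()] with every frame superposed on `reference` over
#'   `fit_mask`; topology, times and equilibration marker unchanged. The
#'   operation is idempotent.
#' @export
align_trajectory <- function(traj, reference, fit_mask = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  fit_mask <- as_selection(fit_mask, traj$topology)
  coords <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    cc <- matrix(coords[f, , ], ncol = 3L)
    sp <- kabsch_superpose(cc, reference, fit_mask)
    coords[f, , ] <- apply_superposition(cc, sp)
  }
  trajectory(traj$topology, coords, times = traj$times,
             equilibration_end = traj$equilibration_end)
}
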