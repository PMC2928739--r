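#' Conformational trajectory of a C-alpha model
#'
#' Container for a trajectory: an array of `frames x residues x 3` C-alpha
#' coordinates (in Angstrom) bound to a [topology()], with per-frame times in
#' nanoseconds and an equilibration marker. Frames at or before
#' `equilibration_end` are flagged as equilibration, never deleted; analysis
#' functions skip them when asked to.
#'
#' @param top a [topology()].
#' @param coords numeric array `frames x residues x 3`, or a single
#'   `residues x 3` matrix for a one-frame trajectory.
#' @param times numeric vector of frame times (ns), strictly increasing. If
#'   `NULL`, computed as `(0:(frames-1)) * frame_interval`.
#' @param frame_interval frame spacing in ns used when `times` is `NULL`.
#' @param equilibration_end time (ns); frames with `time <= equilibration_end`
#'   are flagged as equilibration. Must be `>= 0`.
#' @return An object of class `"trajectory"`: a list with elements
#'   `topology`, `coords`, `times`, `equilibration_end`.
#' @export
trajectory <- function(top, coords, times = NULL, frame_interval = 1,
                       equilibration_end = 0) {
  stopifnot(inherits(top, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("'coords' must be a frames x residues x 3 array")
  }
  if (dim(coords)[2] != nrow(top)) {
    stop("coordinate residue dimension (", dim(coords)[2],
         ") does not match topology (", nrow(top), ")")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  nf <- dim(coords)[1]
  if (nf == 0L) stop("trajectory has no frames")
  if (is.null(times)) {
    if (!is.finite(frame_interval) || frame_interval <= 0) {
      stop("'frame_interval' must be positive")
    }
    times <- (seq_len(nf) - 1) * frame_interval
  }
  times <- as.numeric(times)
  if (length(times) != nf) stop("'times' length differs from frame count")
  if (nf > 1L && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  if (!is.finite(equilibration_end) || equilibration_end < 0) {
    stop("'equilibration_end' must be >= 0")
  }
  structure(list(topology = top, coords = coords, times = times,
                 equilibration_end = equilibration_end),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf(
    "trajectory: %d frames x %d residues, %.4g..%.4g ns (equilibration <= %.4g ns: %d frames)\n",
    nf, nrow(x$topology), x$times[1], x$times[nf], x$equilibration_end,
    sum(x$times <= x$equilibration_end)))
  print(x$topology)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[1]
}

#' Indices of usable (analysis) frames
#'
#' The frames downstream statistics average over: post-equilibration frames,
#' optionally restricted to a time window `(start, end]`.
#'
#' @param traj a [trajectory()].
#' @param exclude_equilibration drop frames with
#'   `time <= equilibration_end`? (With the default marker of 0, no frame
#'   is flagged.)
#' @param window optional length-2 numeric `(start, end]` in ns.
#' @return integer vector of frame indices (possibly empty).
#' @export
usable_frames <- function(traj, exclude_equilibration = TRUE, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  keep <- rep(TRUE, n_frames(traj))
  if (exclude_equilibration && traj$equilibration_end > 0) {
    keep <- traj$times > traj$equilibration_end
  }
  if (!is.null(window)) {
    if (length(window) != 2L || !all(is.finite(window)) ||
        window[2] <= window[1]) {
      stop("'window' must be a finite (start, end] pair with end > start")
    }
    keep <- keep & traj$times > window[1] & traj$times <= window[2]
  }
  which(keep)
}

#' Extract one frame's coordinates
#' @param traj a [trajectory()].
#' @param i frame index.
#' @return `residues x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  i <- as.integer(i)
  if (length(i) != 1L || i < 1L || i > n_frames(traj)) {
    stop("frame index out of range")
  }
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(residue_labels(traj$topology), c("x", "y", "z")))
}

#' Keep every k-th frame of a trajectory
#' @param traj a [trajectory()].
#' @param stride positive integer; keep frames `1, 1+stride, ...`.
#' @return strided [trajectory()] (times and equilibration marker preserved).
#' @export
stride_frames <- function(traj, stride) {
  stopifnot(inherits(traj, "trajectory"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be a positive integer")
  keep <- seq(1L, n_frames(traj), by = stride)
  trajectory(traj$topology, traj$coords[keep, , , drop = FALSE],
             times = traj$times[keep],
             equilibration_end = traj$equilibration_end)
}

# frames x (3n) matrix of a selection's coordinates, residue-major
# (x1,y1,z1,x2,...) ordering so a row reshapes to an n x 3 matrix by row
flatten_frames <- function(traj, sel = NULL, frames = NULL) {
  sel <- as_selection(sel, traj$topology)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  cc <- traj$coords[frames, sel, , drop = FALSE]
  nf <- length(frames); n <- length(sel)
  out <- matrix(0, nf, 3L * n)
  out[, seq(1L, 3L * n, by = 3L)] <- cc[, , 1]
  out[, seq(2L, 3L * n, by = 3L)] <- cc[, , 2]
  out[, seq(3L, 3L * n, by = 3L)] <- cc[, , 3]
  out
}

unflatten_frame <- function(row) {
  matrix(row, ncol = 3L, byrow = TRUE)
}
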