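# Per-residue mean-square fluctuations and inter-residue distance series.

#' Per-residue mean-square fluctuations
#'
#' Computes `msf_i = < |R_i(t) - <R_i>|^2 >` over usable frames, after
#' superposing every frame on `fit_mask` (minus `exclude_mask`). Aligning on
#' a single chain avoids the inflated fluctuations that a whole-complex
#' alignment produces when the quaternary structure drifts; highly flexible
#' segments (e.g. a disordered terminal tail) can be excluded from the fit
#' via `exclude_mask`. Frames are aligned to the first usable frame; the mean
#' position is then taken over the same usable frames.
#'
#' @param traj a [trajectory()].
#' @param fit_mask residues to superpose on (default all); `NA` skips the
#'   per-frame alignment entirely (for pre-aligned trajectories, or when
#'   fluctuations about the raw frame coordinates are wanted). Note that
#'   fitting necessarily absorbs a small part of the true fluctuation into
#'   the removed rigid-body modes.
#' @param measure_mask residues to report (default all).
#' @param exclude_equilibration drop frames flagged as equilibration?
#' @param exclude_mask residues removed from both the fit and the report
#'   (e.g. a flexible tail); `NULL` for none.
#' @return data frame of class `"fluct_profile"` with columns `index`,
#'   `chain`, `resno`, `label`, `msf` (Angstrom^2); attributes `frames_used`
#'   and `fit_mask`.
#' @export
mean_square_fluctuations <- function(traj, fit_mask = NULL,
                                     measure_mask = NULL,
                                     exclude_equilibration = TRUE,
                                     exclude_mask = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  align <- !(length(fit_mask) == 1L && is.na(fit_mask[1]))
  if (align) fit_mask <- as_selection(fit_mask, top)
  measure_mask <- as_selection(measure_mask, top)
  fit_eff <- if (align) as.integer(fit_mask) else integer(0)
  if (!is.null(exclude_mask)) {
    exclude_mask <- as_selection(exclude_mask, top)
    if (align) {
      fit_eff <- setdiff(fit_eff, exclude_mask)
      if (length(fit_eff) == 0L) {
        stop("exclude_mask removes every residue of the fit mask")
      }
    }
    measure_mask <- setdiff(measure_mask, exclude_mask)
    if (length(measure_mask) == 0L) {
      stop("exclude_mask removes every residue of the measure mask")
    }
  }
  frames <- usable_frames(traj, exclude_equilibration)
  if (length(frames) < 2L) {
    stop("need at least 2 usable frames for fluctuations")
  }
  if (align) {
    ref <- matrix(traj$coords[frames[1], , ], ncol = 3L)
    flat <- matrix(0, length(frames), 3L * nrow(top))
    for (k in seq_along(frames)) {
      cc <- matrix(traj$coords[frames[k], , ], ncol = 3L)
      sp <- kabsch_superpose(cc, ref, fit_eff)
      flat[k, ] <- as.vector(t(apply_superposition(cc, sp)))
    }
  } else {
    flat <- flatten_frames(traj, frames = frames)
  }
  ctr <- sweep(flat, 2L, colMeans(flat))
  ssq <- colMeans(ctr * ctr)
  per_res <- ssq[seq(1L, length(ssq), 3L)] + ssq[seq(2L, length(ssq), 3L)] +
    ssq[seq(3L, length(ssq), 3L)]
  idx <- as.integer(measure_mask)
  out <- data.frame(index = idx, chain = top$chain[idx],
                    resno = top$resno[idx],
                    label = residue_labels(top)[idx],
                    msf = per_res[idx], stringsAsFactors = FALSE)
  attr(out, "frames_used") <- length(frames)
  attr(out, "fit_mask") <- fit_eff
  class(out) <- c("fluct_profile", "data.frame")
  out
}

#' @export
plot.fluct_profile <- function(x, ...) {
  plot(seq_len(nrow(x)), x$msf, type = "l", xlab = "residue",
       ylab = "msf (A^2)", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(nrow(x)), labels = x$resno)
  # dashed separators between chains
  br <- which(diff(as.integer(factor(x$chain, levels = unique(x$chain)))) != 0)
  if (length(br) > 0) graphics::abline(v = br + 0.5, lty = 2)
  invisible(x)
}

#' Inter-residue / inter-region distance time series
#'
#' Distance per usable frame between two selections, either between two
#' single C-alpha atoms or between the unweighted centroids of the two
#' selections' C-alpha coordinates (a C-alpha approximation to
#' centre-of-mass distances).
#'
#' @param traj a [trajectory()].
#' @param selection_a,selection_b residue selections; in `"calpha"` mode each
#'   must contain exactly one residue.
#' @param mode `"calpha"` (atom-to-atom) or `"centroid"`
#'   (centroid-to-centroid).
#' @param exclude_equilibration drop frames flagged as equilibration?
#' @return data frame of class `"distance_series"` with columns `time`,
#'   `distance` (Angstrom); attribute `mean` holds the time average.
#' @export
distance_timeseries <- function(traj, selection_a, selection_b,
                                mode = c("calpha", "centroid"),
                                exclude_equilibration = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  mode <- match.arg(mode)
  a <- as_selection(selection_a, traj$topology)
  b <- as_selection(selection_b, traj$topology)
  if (mode == "calpha" && (length(a) != 1L || length(b) != 1L)) {
    stop("'calpha' mode requires single-residue selections")
  }
  frames <- usable_frames(traj, exclude_equilibration)
  if (length(frames) == 0L) stop("no usable frames")
  pa <- apply(traj$coords[frames, a, , drop = FALSE], c(1L, 3L), mean)
  pb <- apply(traj$coords[frames, b, , drop = FALSE], c(1L, 3L), mean)
  d <- sqrt(rowSums((pa - pb)^2))
  out <- data.frame(time = traj$times[frames], distance = d)
  attr(out, "mean") <- mean(d)
  attr(out, "mode") <- mode
  class(out) <- c("distance_series", "data.frame")
  out
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance series (%s): %d frames, mean %.4f A\n",
              attr(x, "mode"), nrow(x), attr(x, "mean")))
  invisible(x)
}
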