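# Conformational clustering (radius-seeded k-means, RMSD-to-centroid metric)
# and joined-ensemble principal component analysis.

# Align each trajectory's frames to fit_reference over fit_mask, extract the
# analysis selection, and return the joined flattened frames plus provenance.
join_aligned_frames <- function(trajs, fit_reference, fit_mask, selection,
                                exclude_equilibration = TRUE) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (is.null(names(trajs)) || any(names(trajs) == "")) {
    names(trajs) <- paste0("trajectory_", seq_along(trajs))
  }
  top <- trajs[[1]]$topology
  sel <- as_selection(selection, top)
  for (tr in trajs) {
    if (nrow(tr$topology) != nrow(top)) {
      stop("trajectories do not share a congruent topology")
    }
  }
  frames <- list(); src <- integer(0); tms <- numeric(0)
  for (i in seq_along(trajs)) {
    tr <- align_trajectory(trajs[[i]], fit_reference, fit_mask)
    use <- usable_frames(tr, exclude_equilibration)
    if (length(use) == 0L) next
    frames[[length(frames) + 1L]] <- flatten_frames(tr, sel, use)
    src <- c(src, rep(i, length(use)))
    tms <- c(tms, tr$times[use])
  }
  if (length(frames) == 0L) stop("no usable frames in any trajectory")
  list(X = do.call(rbind, frames), source = src, times = tms,
       names = names(trajs), selection = sel, n_res = length(sel))
}

# RMSD between flattened conformations and a set of flattened centroids:
# euclidean distance / sqrt(n_res)
rmsd_to_centroids <- function(X, centroids, n_res) {
  d2 <- outer(rowSums(X^2), rowSums(centroids^2), "+") -
    2 * X %*% t(centroids)
  d2[d2 < 0] <- 0
  sqrt(d2 / n_res)
}

#' Radius-seeded k-means clustering of conformations
#'
#' Clusters the joined usable frames of one or more trajectories with
#' k-means, using the coordinate RMSD of the analysis selection to the
#' cluster centroid as the similarity measure. The number of clusters is
#' controlled by `radius`: seeding scans the frames in order and founds a
#' new centroid whenever a frame lies farther than `radius` from every
#' existing one (so larger radii yield fewer clusters). Lloyd iterations
#' then alternate nearest-centroid assignment (ties to the lowest cluster
#' index) with coordinate-mean centroid updates until assignments are
#' stable; empty clusters are dropped. All frames are first superposed on a
#' fixed reference conformation, never re-aligned to moving centroids.
#'
#' @param trajs a [trajectory()] or (possibly named) list of trajectories
#'   sharing one topology.
#' @param fit_reference `residues x 3` reference coordinates used for the
#'   one-off alignment.
#' @param fit_mask residues to superpose on.
#' @param radius RMSD seeding radius in Angstrom (> 0).
#' @param seed integer seed; only consumed when `shuffle = TRUE`.
#' @param max_iter maximum Lloyd iterations.
#' @param selection residues whose coordinates are clustered (default all).
#' @param exclude_equilibration drop frames flagged as equilibration?
#' @param shuffle if `TRUE`, frames are scanned in a seeded random order
#'   during seeding (assignment and occupancies are unaffected by order
#'   once centroids converge). Default `FALSE`: fully deterministic.
#' @return object of class `"cluster_model"`: list with `centroids` (list of
#'   `n x 3` matrices), `assignments` (per-source-trajectory integer
#'   vectors), `occupancy` (source x cluster percentage matrix, rows sum to
#'   100), `timeline` (per-source data frames of `(time, cluster)`),
#'   `radius`, `objective` (per-iteration sum of squared member-to-centroid
#'   RMSDs), and the aligned frames used for fitting.
#' @export
cluster_conformations <- function(trajs, fit_reference, fit_mask = NULL,
                                  radius, seed = 1L, max_iter = 100L,
                                  selection = NULL,
                                  exclude_equilibration = TRUE,
                                  shuffle = FALSE) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("'radius' must be a positive number (Angstrom)")
  }
  jn <- join_aligned_frames(trajs, fit_reference, fit_mask, selection,
                            exclude_equilibration)
  X <- jn$X
  nf <- nrow(X)
  order_idx <- seq_len(nf)
  if (shuffle) {
    order_idx <- withr::with_seed(as.integer(seed), sample.int(nf))
  }
  # stage 1: greedy radius seeding in scan order
  cent_rows <- order_idx[1]
  for (f in order_idx[-1L]) {
    d <- rmsd_to_centroids(X[f, , drop = FALSE],
                           X[cent_rows, , drop = FALSE], jn$n_res)
    if (min(d) > radius) cent_rows <- c(cent_rows, f)
  }
  centroids <- X[cent_rows, , drop = FALSE]
  # stage 2: Lloyd iterations
  assign_prev <- rep(0L, nf)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- rmsd_to_centroids(X, centroids, jn$n_res)
    assign_cur <- max.col(-D, ties.method = "first")
    objective <- c(objective, sum(D[cbind(seq_len(nf), assign_cur)]^2))
    keep <- sort(unique(assign_cur))
    if (length(keep) < nrow(centroids)) {
      assign_cur <- match(assign_cur, keep)
      centroids <- centroids[keep, , drop = FALSE]
    }
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
    for (k in seq_len(nrow(centroids))) {
      centroids[k, ] <- colMeans(X[assign_cur == k, , drop = FALSE])
    }
  }
  k <- nrow(centroids)
  n_src <- length(jn$names)
  occupancy <- matrix(0, n_src, k,
                      dimnames = list(jn$names, paste0("cluster_", 1:k)))
  assignments <- vector("list", n_src)
  timeline <- vector("list", n_src)
  names(assignments) <- names(timeline) <- jn$names
  for (s in seq_len(n_src)) {
    rows <- jn$source == s
    if (!any(rows)) next
    assignments[[s]] <- assign_cur[rows]
    timeline[[s]] <- data.frame(time = jn$times[rows],
                                cluster = assign_cur[rows])
    occupancy[s, ] <- 100 * tabulate(assign_cur[rows], k) / sum(rows)
  }
  structure(list(centroids = lapply(seq_len(k), function(i)
                   unflatten_frame(centroids[i, ])),
                 assignments = assignments, occupancy = occupancy,
                 timeline = timeline, radius = radius,
                 objective = objective, frames = X, source = jn$source,
                 times = jn$times, selection = jn$selection,
                 n_res = jn$n_res, iterations = it),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "conformational clustering: %d cluster(s), radius %.3g A, %d frames, %d iteration(s)\n",
    length(x$centroids), x$radius, nrow(x$frames), x$iterations))
  cat("occupancy (% of each source ensemble):\n")
  print(round(x$occupancy, 2))
  invisible(x)
}

#' @export
plot.cluster_model <- function(x, ...) {
  ns <- length(x$timeline)
  op <- graphics::par(mfrow = c(ns, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (s in seq_len(ns)) {
    tl <- x$timeline[[s]]
    plot(tl$time, tl$cluster, pch = 20, cex = 0.5, xlab = "time (ns)",
         ylab = "cluster", yaxt = "n",
         ylim = c(0.5, length(x$centroids) + 0.5),
         main = names(x$timeline)[s], ...)
    graphics::axis(2, at = seq_along(x$centroids))
  }
  invisible(x)
}

#' Cluster the joined ensemble of two trajectories
#'
#' Fits one [cluster_conformations()] model on the concatenated usable
#' frames of two trajectories so their conformational spaces are directly
#' comparable: the occupancy table has one row per source ensemble (both
#' rows sum to 100%), and the membership timeline records which cluster each
#' ensemble visits over time. An ensemble confined to one basin concentrates
#' in a single cluster; a more mobile ensemble spreads over several.
#'
#' @param traj_a,traj_b two trajectories sharing a topology.
#' @inheritParams cluster_conformations
#' @return a `"cluster_model"` (see [cluster_conformations()]) whose
#'   occupancy matrix and timeline have one row/entry per input trajectory.
#' @export
joined_ensemble_analysis <- function(traj_a, traj_b, fit_reference,
                                     fit_mask = NULL, radius, seed = 1L,
                                     selection = NULL,
                                     exclude_equilibration = TRUE, ...) {
  trajs <- list(traj_a, traj_b)
  nm <- c(deparse(substitute(traj_a)), deparse(substitute(traj_b)))
  names(trajs) <- make.unique(nm)
  cluster_conformations(trajs, fit_reference, fit_mask = fit_mask,
                        radius = radius, seed = seed,
                        selection = selection,
                        exclude_equilibration = exclude_equilibration, ...)
}

#' Representative (medoid) structures of a cluster model
#'
#' For each cluster, the member frame with the smallest RMSD to the cluster
#' centroid; ties go to the earliest frame in scan order. These medoids are
#' actual sampled conformations (centroids are coordinate means and need
#' not be), suitable for downstream structural comparisons.
#'
#' @param model a `"cluster_model"`.
#' @return list, one entry per cluster: `source` (trajectory name),
#'   `time` (ns), `rmsd_to_centroid` (A) and `coords` (`n x 3`).
#' @export
representative_structures <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  assign_all <- integer(nrow(model$frames))
  pos <- 1L
  for (s in seq_along(model$assignments)) {
    a <- model$assignments[[s]]
    assign_all[model$source == s] <- a
  }
  out <- list()
  for (k in seq_along(model$centroids)) {
    members <- which(assign_all == k)
    if (length(members) == 0L) {
      warning("cluster ", k, " is empty; skipped")
      next
    }
    cen <- matrix(as.vector(t(model$centroids[[k]])), nrow = 1L)
    d <- rmsd_to_centroids(model$frames[members, , drop = FALSE], cen,
                           model$n_res)
    best <- members[which.min(d)]   # which.min -> earliest on ties
    out[[paste0("cluster_", k)]] <- list(
      source = names(model$assignments)[model$source[best]],
      time = model$times[best], rmsd_to_centroid = min(d),
      coords = unflatten_frame(model$frames[best, ]))
  }
  out
}

#' Principal component analysis of a joined conformational ensemble
#'
#' Eigendecomposition of the `3N x 3N` covariance of the selected C-alpha
#' coordinates over the joined usable frames of one or more trajectories,
#' after superposing every frame on a fixed reference (same convention as
#' [cluster_conformations()]). The proportion of each eigenvalue in the
#' eigenvalue sum is the fraction of total positional variance that PC
#' explains; cumulative proportions are also stored for axis annotation.
#'
#' @inheritParams cluster_conformations
#' @return object of class `"pca_model"`: list with `mean` (flattened mean
#'   conformation), `eigenvectors` (`3N x k` orthonormal columns),
#'   `eigenvalues` (A^2, nonincreasing), `proportions`, `cumulative`,
#'   `selection`, plus the alignment convention (`fit_reference`,
#'   `fit_mask`).
#' @export
pca_fit <- function(trajs, fit_reference, fit_mask = NULL,
                    selection = NULL, exclude_equilibration = TRUE) {
  jn <- join_aligned_frames(trajs, fit_reference, fit_mask, selection,
                            exclude_equilibration)
  X <- jn$X
  if (nrow(X) < 2L) stop("need at least 2 usable frames for PCA")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0)
  k <- min(nrow(X) - 1L, ncol(X))
  eig <- (sv$d^2 / (nrow(X) - 1L))[seq_len(k)]
  eig[eig < 0] <- 0
  vecs <- sv$v[, seq_len(k), drop = FALSE]
  colnames(vecs) <- paste0("PC", seq_len(k))
  structure(list(mean = mu, eigenvectors = vecs, eigenvalues = eig,
                 proportions = eig / sum(eig),
                 cumulative = cumsum(eig) / sum(eig),
                 selection = jn$selection, fit_reference = fit_reference,
                 fit_mask = fit_mask, n_frames = nrow(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("ensemble PCA: %d frames, %d components\n", x$n_frames,
              length(x$eigenvalues)))
  k <- min(5L, length(x$eigenvalues))
  cat("leading eigenvalues (A^2):",
      sprintf("%.4g", x$eigenvalues[1:k]), "\n")
  cat("variance proportions:    ",
      sprintf("%.3f", x$proportions[1:k]), "\n")
  cat("cumulative:              ",
      sprintf("%.3f", x$cumulative[1:k]), "\n")
  invisible(x)
}

#' Project conformations onto fitted principal components
#'
#' Aligns the trajectory with the model's convention, mean-centers the
#' selected coordinates with the model mean, and takes dot products with the
#' requested eigenvectors. Projections are in Angstrom.
#'
#' @param traj a [trajectory()] congruent with the model's topology.
#' @param model a `"pca_model"` from [pca_fit()].
#' @param components integer indices of the PCs to project on.
#' @param exclude_equilibration drop frames flagged as equilibration?
#' @return data frame with `time` plus one `PCk` column per requested
#'   component.
#' @export
pca_project <- function(traj, model, components = c(1L, 2L),
                        exclude_equilibration = TRUE) {
  stopifnot(inherits(model, "pca_model"), inherits(traj, "trajectory"))
  components <- as.integer(components)
  if (any(components < 1L | components > ncol(model$eigenvectors))) {
    stop("component index out of range 1..", ncol(model$eigenvectors))
  }
  tr <- align_trajectory(traj, model$fit_reference, model$fit_mask)
  use <- usable_frames(tr, exclude_equilibration)
  X <- flatten_frames(tr, model$selection, use)
  proj <- sweep(X, 2L, model$mean) %*%
    model$eigenvectors[, components, drop = FALSE]
  out <- data.frame(time = tr$times[use], proj)
  names(out) <- c("time", paste0("PC", components))
  out
}
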