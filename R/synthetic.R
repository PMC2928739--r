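# Synthetic trajectories with planted, analytically known statistical
# structure. Each generator emulates one regime of interest: stationary
# Gaussian fluctuations with a planted residue-residue correlation structure
# (optionally Ornstein-Uhlenbeck in time), rotational diffusion of backbone
# bond vectors, a rigid-body reorientation of one chain mid-trajectory, and
# multi-basin ensembles with planted cluster occupancies. All randomness
# flows from the spec's seed through one seeded generator per trajectory;
# nothing consumes the caller's global RNG state.

#' Idealized helical C-alpha reference trace
#'
#' An alpha-helix-like trace (radius 2.3 A, rise 1.5 A, 100 degrees per
#' residue; successive C-alpha spacing approximately 3.8 A), one helix per
#' chain, chains laid side by side. An idealized geometry rather than a real
#' protein, so planted statistics have closed forms and no external files
#' are needed.
#'
#' @param chains named integer vector: residues per chain, e.g.
#'   `c(A = 20, B = 15)`.
#' @param spacing distance between chain axes (A).
#' @return list with `topology` and `coords` (`residues x 3`).
#' @export
helix_reference <- function(chains = c(A = 20L), spacing = 30) {
  if (is.null(names(chains)) || any(names(chains) == "")) {
    names(chains) <- LETTERS[seq_along(chains)]
  }
  coords <- NULL; ch <- character(0); rn <- integer(0)
  for (i in seq_along(chains)) {
    n <- as.integer(chains[i])
    t <- seq_len(n) - 1L
    cc <- cbind(2.3 * cos(t * 100 * pi / 180) + (i - 1L) * spacing,
                2.3 * sin(t * 100 * pi / 180),
                1.5 * t)
    coords <- rbind(coords, cc)
    ch <- c(ch, rep(names(chains)[i], n))
    rn <- c(rn, seq_len(n))
  }
  top <- topology(ch, rn)
  dimnames(coords) <- list(residue_labels(top), c("x", "y", "z"))
  list(topology = top, coords = coords)
}

#' Specification of a synthetic trajectory
#'
#' Validated container consumed by the four generators. Only the fields a
#' given generator uses need to be meaningful; everything is checked at
#' construction where possible (positive-semidefiniteness of the planted
#' correlation structure, basin weights summing to 1, positive spreads).
#'
#' @param chains named integer vector of residues per chain.
#' @param frames number of frames.
#' @param frame_interval frame spacing, ns.
#' @param seed integer seed; identical (spec, seed) gives bit-identical
#'   trajectories.
#' @param variances isotropic per-residue displacement variance, A^2 per
#'   axis (scalar or one value per residue).
#' @param blocks optional list of planted correlation blocks, each
#'   `list(members = <residue indices>, rho = <correlation>,
#'   window = <NULL or (start, end] ns>)`: all pairs of distinct members are
#'   correlated at `rho` (a common-factor structure, positive semidefinite
#'   for `0 <= rho <= 1`). A `window` restricts the block to frames inside
#'   it (white temporal model only).
#' @param temporal `"white"` (independent frames) or `"ou"`
#'   (Ornstein-Uhlenbeck relaxation).
#' @param theta OU relaxation time, ns; displacement autocorrelation decays
#'   as `exp(-tau / theta)` exactly on the frame grid.
#' @param D rotational diffusion coefficient, rad^2/ns (bond-vector
#'   generator).
#' @param events optional list of one rigid-body event:
#'   `list(time = <ns>, chain = <id>, angle = <deg>, axis = <3-vector>,
#'   translation = <3-vector A>)`.
#' @param basins optional list of basins, each `list(offset = <A>,
#'   spread = <A>, weight = <probability>)`; weights must sum to 1.
#' @param equilibration_end equilibration marker passed to the output
#'   trajectory, ns.
#' @return validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(chains = c(A = 20L), frames = 1000L,
                           frame_interval = 0.1, seed = 1L,
                           variances = 0.25, blocks = NULL,
                           temporal = c("white", "ou"), theta = 1,
                           D = 0.1, events = NULL, basins = NULL,
                           equilibration_end = 0) {
  temporal <- match.arg(temporal)
  frames <- as.integer(frames)
  if (frames < 1L) stop("'frames' must be positive")
  if (frame_interval <= 0) stop("'frame_interval' must be positive")
  n <- sum(as.integer(chains))
  if (length(variances) == 1L) variances <- rep(variances, n)
  if (length(variances) != n) {
    stop("'variances' must be scalar or one value per residue")
  }
  if (any(variances < 0)) stop("'variances' must be nonnegative")
  if (temporal == "ou" && theta <= 0) stop("'theta' must be positive")
  if (D < 0) stop("'D' must be nonnegative")
  if (!is.null(blocks)) {
    for (b in blocks) {
      if (is.null(b$members) || is.null(b$rho)) {
        stop("each block needs 'members' and 'rho'")
      }
      if (any(b$members < 1L | b$members > n)) {
        stop("block members out of residue range")
      }
      if (!is.null(b$window) && temporal == "ou") {
        stop("windowed correlation blocks require the white temporal model")
      }
    }
    # planted structure must be a valid correlation matrix
    ok <- tryCatch({
      chol(block_correlation(n, blocks, active = rep(TRUE,
                                                     length(blocks))) +
             diag(1e-10, n))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("planted block correlation structure is not positive ",
                  "semidefinite")
  }
  if (!is.null(basins)) {
    w <- vapply(basins, function(b) b$weight, 0)
    if (abs(sum(w) - 1) > 1e-8) stop("basin weights must sum to 1")
    sp <- vapply(basins, function(b) b$spread, 0)
    if (any(sp <= 0)) stop("basin spreads must be positive")
  }
  if (!is.null(events)) {
    span <- (frames - 1L) * frame_interval
    for (e in events) {
      if (is.null(e$time) || e$time <= 0 || e$time >= span) {
        stop("event time must lie strictly inside the trajectory span")
      }
      if (is.null(e$chain)) stop("event must name a chain")
    }
  }
  structure(list(chains = chains, frames = frames,
                 frame_interval = frame_interval, seed = as.integer(seed),
                 variances = variances, blocks = blocks,
                 temporal = temporal, theta = theta, D = D,
                 events = events, basins = basins,
                 equilibration_end = equilibration_end),
            class = "synthetic_spec")
}

# n x n correlation matrix: identity plus common-factor blocks.
# 'active' flags which blocks apply (time-windowed blocks switch off).
block_correlation <- function(n, blocks, active) {
  C <- diag(n)
  for (i in seq_along(blocks)) {
    if (!active[i]) next
    m <- blocks[[i]]$members
    C[m, m] <- blocks[[i]]$rho
  }
  diag(C) <- 1
  C
}

# upper-triangular factor of the planted residue covariance (per axis)
planted_chol <- function(spec, active) {
  n <- length(spec$variances)
  C <- block_correlation(n, spec$blocks, active)
  sd <- sqrt(spec$variances)
  S <- C * outer(sd, sd)
  if (all(S == 0)) return(matrix(0, n, n))
  chol(S + diag(1e-12 * max(diag(S)), n))
}

#' Gaussian fluctuation trajectory with planted correlation structure
#'
#' Frames fluctuate about the helical reference with isotropic per-residue
#' variances and the spec's planted block correlations, independently per
#' Cartesian axis. With `temporal = "ou"`, displacements evolve by the exact
#' autoregressive Ornstein-Uhlenbeck update with factor
#' `exp(-frame_interval / theta)`, so the displacement autocorrelation at
#' delay tau is `exp(-tau / theta)` exactly on the frame grid. Blocks with a
#' `window` are active only for frames inside it (white model), planting a
#' mid-run correlation switch.
#'
#' @param spec a [synthetic_spec()] with no events and no basins.
#' @return a [trajectory()].
#' @export
generate_gaussian_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$events) || !is.null(spec$basins)) {
    stop("gaussian generator takes a spec without events or basins")
  }
  ref <- helix_reference(spec$chains)
  n <- nrow(ref$coords)
  nf <- spec$frames
  times <- (seq_len(nf) - 1L) * spec$frame_interval
  # frames grouped by which windowed blocks are active
  act <- matrix(TRUE, nf, max(1L, length(spec$blocks)))
  if (!is.null(spec$blocks)) {
    for (i in seq_along(spec$blocks)) {
      w <- spec$blocks[[i]]$window
      if (!is.null(w)) act[, i] <- times > w[1] & times <= w[2]
    }
  }
  coords <- array(0, c(nf, n, 3L))
  withr::with_seed(spec$seed, {
    if (spec$temporal == "white") {
      grp <- apply(act, 1L, paste, collapse = "")
      for (g in unique(grp)) {
        rows <- which(grp == g)
        U <- planted_chol(spec, act[rows[1], ])
        for (ax in 1:3) {
          coords[rows, , ax] <- matrix(stats::rnorm(length(rows) * n),
                                       length(rows), n) %*% U
        }
      }
    } else {
      U <- planted_chol(spec, rep(TRUE, max(1L, length(spec$blocks))))
      phi <- exp(-spec$frame_interval / spec$theta)
      for (ax in 1:3) {
        x <- as.vector(stats::rnorm(n) %*% U)
        coords[1, , ax] <- x
        innov_scale <- sqrt(1 - phi^2)
        for (f in seq_len(nf)[-1L]) {
          x <- phi * x + innov_scale * as.vector(stats::rnorm(n) %*% U)
          coords[f, , ax] <- x
        }
      }
    }
  })
  for (ax in 1:3) coords[, , ax] <- sweep(coords[, , ax], 2L,
                                          ref$coords[, ax], "+")
  trajectory(ref$topology, coords, times = times,
             equilibration_end = spec$equilibration_end)
}

# 3x3 rotation matrix about a unit axis (column convention: p' = R p)
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) * cos(angle) + sin(angle) * K +
    (1 - cos(angle)) * outer(axis, axis)
}

# rotate rows of M (B x 3) by rotation vectors W (B x 3), Rodrigues form
rotate_rows <- function(M, W) {
  th <- sqrt(rowSums(W * W))
  k <- W / ifelse(th > 0, th, 1)
  kxm <- cbind(k[, 2] * M[, 3] - k[, 3] * M[, 2],
               k[, 3] * M[, 1] - k[, 1] * M[, 3],
               k[, 1] * M[, 2] - k[, 2] * M[, 1])
  kdm <- rowSums(k * M)
  M * cos(th) + kxm * sin(th) + k * kdm * (1 - cos(th))
}

#' Bond-vector rotational diffusion trajectory
#'
#' A single chain whose successive-C-alpha bond directions evolve by
#' isotropic rotational diffusion: at each step every bond is rotated by a
#' random rotation vector with per-axis variance `2 * D * frame_interval`.
#' Coordinates are rebuilt by chaining 3.8 A bonds from the origin. The
#' rank-1 orientational autocorrelation of each bond then decays as
#' `exp(-2 D tau)`, giving a closed-form target for
#' [bond_autocorrelation()].
#'
#' @param spec a [synthetic_spec()] with a single chain.
#' @param D rotational diffusion coefficient, rad^2/ns; defaults to
#'   `spec$D`.
#' @return a [trajectory()].
#' @export
generate_rotational_diffusion_bonds <- function(spec, D = spec$D) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$chains) != 1L) {
    stop("rotational-diffusion generator takes a single chain")
  }
  if (D < 0) stop("'D' must be nonnegative")
  n <- as.integer(spec$chains[1])
  if (n < 2L) stop("need at least 2 residues")
  nb <- n - 1L
  nf <- spec$frames
  sd_step <- sqrt(2 * D * spec$frame_interval)
  coords <- array(0, c(nf, n, 3L))
  withr::with_seed(spec$seed, {
    # isotropic initial directions
    M <- matrix(stats::rnorm(nb * 3L), nb, 3L)
    M <- M / sqrt(rowSums(M * M))
    for (f in seq_len(nf)) {
      if (f > 1L && sd_step > 0) {
        W <- matrix(stats::rnorm(nb * 3L, sd = sd_step), nb, 3L)
        M <- rotate_rows(M, W)
        M <- M / sqrt(rowSums(M * M))
      }
      coords[f, , ] <- rbind(c(0, 0, 0), apply(3.8 * M, 2L, cumsum))
    }
  })
  top <- topology(rep(names(spec$chains)[1] %||% "A", n), seq_len(n))
  trajectory(top, coords, times = (seq_len(nf) - 1L) * spec$frame_interval,
             equilibration_end = spec$equilibration_end)
}

#' Rigid-body reorientation event trajectory
#'
#' Two or more chains fluctuate (white isotropic noise) about the helical
#' reference; at the planted event time, the target chain's reference is
#' rigidly rotated about its centroid and translated, emulating a
#' mid-trajectory change in quaternary structure. Each chain's internal
#' geometry is statistically unchanged across the event, so self-aligned
#' RMSD stays flat while cross-chain pivot RMSD steps up by the analytic
#' RMSD of the planted transform.
#'
#' @param spec a [synthetic_spec()] with `>= 2` chains and exactly one
#'   event.
#' @return a [trajectory()]; the transformed per-chain reference is stored
#'   in the `"planted"` attribute.
#' @export
generate_rotation_event <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$chains) < 2L) stop("need at least 2 chains")
  if (is.null(spec$events) || length(spec$events) != 1L) {
    stop("spec must carry exactly one event")
  }
  ev <- spec$events[[1]]
  ref <- helix_reference(spec$chains)
  top <- ref$topology
  off <- chain_offsets(top)
  if (!ev$chain %in% off$chain) stop("event chain not in topology")
  rows <- which(top$chain == ev$chain)
  axis <- ev$axis %||% c(0, 0, 1)
  axis <- axis / sqrt(sum(axis^2))
  angle <- (ev$angle %||% 30) * pi / 180
  shift <- ev$translation %||% c(0, 0, 0)
  ctr <- colMeans(ref$coords[rows, , drop = FALSE])
  R <- rotation_matrix(axis, angle)
  post_ref <- ref$coords
  post_ref[rows, ] <- sweep(sweep(ref$coords[rows, , drop = FALSE], 2L,
                                  ctr) %*% t(R), 2L, ctr + shift, "+")
  nf <- spec$frames
  times <- (seq_len(nf) - 1L) * spec$frame_interval
  n <- nrow(top)
  sd_ax <- sqrt(spec$variances)
  coords <- array(0, c(nf, n, 3L))
  withr::with_seed(spec$seed, {
    for (f in seq_len(nf)) {
      base <- if (times[f] > ev$time) post_ref else ref$coords
      coords[f, , ] <- base + matrix(stats::rnorm(3L * n), n, 3L) * sd_ax
    }
  })
  out <- trajectory(top, coords, times = times,
                    equilibration_end = spec$equilibration_end)
  attr(out, "planted") <- list(event = ev, pre_reference = ref$coords,
                               post_reference = post_ref)
  out
}

# orthonormal basis of rigid-body modes (3 translations + 3 linearized
# rotations) of a reference, as columns of a 3n x 6 matrix
rigid_modes <- function(ref) {
  n <- nrow(ref)
  ctr <- sweep(ref, 2L, colMeans(ref))
  modes <- matrix(0, 3L * n, 6L)
  for (ax in 1:3) {
    m <- matrix(0, n, 3L); m[, ax] <- 1
    modes[, ax] <- as.vector(t(m))
  }
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    m <- cbind(e[2] * ctr[, 3] - e[3] * ctr[, 2],
               e[3] * ctr[, 1] - e[1] * ctr[, 3],
               e[1] * ctr[, 2] - e[2] * ctr[, 1])
    modes[, 3L + ax] <- as.vector(t(m))
  }
  qr.Q(qr(modes))
}

#' Multi-basin conformational ensemble with planted occupancies
#'
#' Each frame is drawn from one of several basins chosen by the planted
#' weights; within a basin, frames scatter isotropically about the basin
#' center with the given spread (expected RMSD from the center). Basin
#' centers are the reference plus mutually orthogonal random displacement
#' fields that are also orthogonal to all rigid-body modes, so the planted
#' offsets survive superposition: basin i sits at RMSD `offset_i` from the
#' reference and basins i, j are separated by
#' `sqrt(offset_i^2 + offset_j^2)`.
#'
#' @param spec a [synthetic_spec()] with a basin list.
#' @param weights optional list of per-trajectory weight vectors; each
#'   produces one output trajectory sampled with those occupancies (basin
#'   geometry shared). Defaults to the single weight vector in
#'   `spec$basins`.
#' @return a [trajectory()], or a list of them when `weights` has several
#'   entries. The basin centers and per-frame basin labels are stored in
#'   the `"planted"` attribute.
#' @export
generate_multibasin_ensemble <- function(spec, weights = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$basins)) stop("spec has no basins")
  ref <- helix_reference(spec$chains)
  n <- nrow(ref$coords)
  nb <- length(spec$basins)
  if (is.null(weights)) {
    weights <- list(vapply(spec$basins, function(b) b$weight, 0))
  }
  for (w in weights) {
    if (length(w) != nb || abs(sum(w) - 1) > 1e-8) {
      stop("each weight vector must have one weight per basin, summing to 1")
    }
  }
  out <- withr::with_seed(spec$seed, {
    rigid <- rigid_modes(ref$coords)
    basis <- rigid
    centers <- vector("list", nb)
    for (k in seq_len(nb)) {
      v <- stats::rnorm(3L * n)
      v <- v - basis %*% crossprod(basis, v)
      v <- v / sqrt(sum(v^2))
      basis <- cbind(basis, v)
      offs <- spec$basins[[k]]$offset %||% 0
      centers[[k]] <- as.vector(t(ref$coords)) + v * offs * sqrt(n)
    }
    lapply(weights, function(w) {
      nf <- spec$frames
      lab <- sample.int(nb, nf, replace = TRUE, prob = w)
      coords <- array(0, c(nf, n, 3L))
      for (f in seq_len(nf)) {
        sp <- spec$basins[[lab[f]]]$spread
        coords[f, , ] <- unflatten_frame(centers[[lab[f]]]) +
          matrix(stats::rnorm(3L * n, sd = sp / sqrt(3)), n, 3L)
      }
      tr <- trajectory(ref$topology, coords,
                       times = (seq_len(nf) - 1L) * spec$frame_interval,
                       equilibration_end = spec$equilibration_end)
      attr(tr, "planted") <- list(
        centers = lapply(centers, unflatten_frame),
        basin_sequence = lab, weights = w)
      tr
    })
  })
  if (length(out) == 1L) out[[1]] else out
}
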