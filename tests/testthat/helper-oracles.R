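# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the package internals.

# naive double-loop normalized cross-correlation on raw frame coordinates
# coords: frames x residues x 3 (assumed already free of global motion)
naive_cross_correlation <- function(coords) {
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  dR <- sweep(coords, c(2, 3), mu)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (f in seq_len(nf)) s <- s + sum(dR[f, i, ] * dR[f, j, ])
      C[i, j] <- s / nf
    }
  }
  d <- sqrt(diag(C))
  C / outer(d, d)
}

# naive double-loop time-delayed bond-vector autocorrelation
# returns bonds x delays matrix; lags in frames
naive_bond_autocorrelation <- function(coords, lags) {
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  nb <- n - 1L
  M <- array(0, c(nf, nb, 3L))
  for (f in seq_len(nf)) {
    for (b in seq_len(nb)) {
      v <- coords[f, b + 1L, ] - coords[f, b, ]
      M[f, b, ] <- v / sqrt(sum(v * v))
    }
  }
  out <- matrix(0, nb, length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]
    for (b in seq_len(nb)) {
      s <- 0
      for (t in seq_len(nf - L)) s <- s + sum(M[t, b, ] * M[t + L, b, ])
      out[b, k] <- s / (nf - L)
    }
  }
  out
}

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)
rot_y <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0,
                              sin(b), 0, cos(b)), 3, 3)

# grid-search minimum RMSD over rotations (zyz Euler angles, successive
# refinement); translation handled by centering, which is optimal for any
# fixed rotation
grid_search_rmsd <- function(P, Q, levels = 6L, points = 9L) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  ctr <- c(0, pi / 2, 0)
  hw <- c(pi, pi / 2, pi)
  best <- Inf
  for (lev in seq_len(levels)) {
    ga <- ctr[1] + seq(-hw[1], hw[1], length.out = points)
    gb <- ctr[2] + seq(-hw[2], hw[2], length.out = points)
    gg <- ctr[3] + seq(-hw[3], hw[3], length.out = points)
    for (a in ga) for (b in gb) for (g in gg) {
      R <- rot_z(a) %*% rot_y(b) %*% rot_z(g)
      v <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
      if (v < best) { best <- v; ctr <- c(a, b, g) }
    }
    hw <- hw * 2 / (points - 1)
  }
  best
}

# apply a global proper rigid transform (row-vector convention) to every
# frame of a trajectory
transform_trajectory <- function(traj, R, shift = c(0, 0, 0)) {
  coords <- traj$coords
  for (f in seq_len(dim(coords)[1])) {
    coords[f, , ] <- sweep(matrix(coords[f, , ], ncol = 3) %*% t(R), 2,
                           shift, "+")
  }
  trajectory(traj$topology, coords, times = traj$times,
             equilibration_end = traj$equilibration_end)
}

random_rotation <- function() {
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
  ensdyn:::rotation_matrix(v, stats::runif(1, 0.2, 2.8))
}

# write a toy single-model PDB with given atom records (list of lists with
# elety, resname, chain, resno, xyz, and optional alt/occ)
write_toy_pdb <- function(path, atoms) {
  lines <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00",
            i, sprintf(" %-3s", a$elety), a$alt %||% " ", a$resname %||% "ALA",
            a$chain, a$resno, a$xyz[1], a$xyz[2], a$xyz[3], a$occ %||% 1)
  }, "")
  writeLines(c(lines, "END"), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small gaussian trajectory spec used in several files
quick_gaussian <- function(n = 8L, frames = 60L, seed = 1L, ...) {
  generate_gaussian_trajectory(synthetic_spec(
    chains = c(A = n), frames = frames, frame_interval = 0.1,
    seed = seed, variances = 0.25, ...))
}
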