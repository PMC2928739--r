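test_that("identical and opposite displacement sequences give +1 / -1", {
  top <- topology(rep("A", 3), 1:3)
  nf <- 20
  set.seed(2)
  disp <- rnorm(nf)
  arr <- array(0, c(nf, 3, 3))
  base <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  for (f in seq_len(nf)) {
    arr[f, , ] <- base
    arr[f, 1, 2] <- disp[f]
    arr[f, 2, 2] <- disp[f]      # identical to residue 1
    arr[f, 3, 2] <- -disp[f]     # exactly opposite
  }
  tr <- trajectory(top, arr, frame_interval = 0.1)
  C <- cross_correlation_matrix(tr, fit_mask = NA)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_equal(C[1, 3], -1, tolerance = 1e-12)
  expect_equal(diag(C), setNames(rep(1, 3), rownames(C)),
               tolerance = 1e-9)
})

test_that("the matrix is symmetric, bounded, and PSD from a common mean", {
  tr <- quick_gaussian(n = 9L, frames = 80L, seed = 31L,
                       blocks = list(list(members = 2:5, rho = 0.6)))
  C <- cross_correlation_matrix(tr, fit_mask = NA)
  expect_lt(max(abs(C - t(C))), 1e-12)
  expect_true(all(C >= -1 - 1e-9 & C <= 1 + 1e-9))
  expect_gt(min(eigen(unclass(C), symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
})

test_that("zero-variance residues are reported missing, never zero", {
  top <- topology(rep("A", 4), 1:4)
  nf <- 10
  arr <- array(0, c(nf, 4, 3))
  set.seed(3)
  base <- helix_reference(c(A = 4L))$coords
  for (f in seq_len(nf)) {
    arr[f, , ] <- base
    arr[f, 1:3, ] <- arr[f, 1:3, ] + matrix(rnorm(9, sd = 0.5), 3, 3)
  }
  tr <- trajectory(top, arr, frame_interval = 0.1)
  C <- cross_correlation_matrix(tr, fit_mask = NA)
  expect_true(all(is.na(C[4, ])))
  expect_true(all(is.na(C[, 4])))
  expect_false(anyNA(C[1:3, 1:3]))
})

test_that("optimized map agrees with the naive double-loop oracle", {
  tr <- quick_gaussian(n = 10L, frames = 100L, seed = 41L,
                       blocks = list(list(members = c(1:3, 7:9),
                                          rho = 0.5)))
  C <- cross_correlation_matrix(tr, fit_mask = NA)
  oracle <- naive_cross_correlation(tr$coords)
  expect_lt(max(abs(unclass(C) - oracle)), 1e-10)
})

test_that("a planted block correlation is recovered and shrinks with frames", {
  a <- 3:6; b <- 12:15
  recover <- function(frames) {
    tr <- generate_gaussian_trajectory(synthetic_spec(
      chains = c(A = 20L), frames = frames, frame_interval = 0.1,
      seed = 11L, variances = 0.25,
      blocks = list(list(members = c(a, b), rho = 0.8))))
    C <- cross_correlation_matrix(tr, fit_mask = NA)
    # entry-level RMS recovery error over planted and null regions
    c(inter = mean(C[a, b]), outside = mean(abs(C[17:20, 8:10])),
      rms = sqrt(mean(c((C[a, b] - 0.8)^2, C[17:20, 8:10]^2))))
  }
  r5000 <- recover(5000L)
  expect_equal(unname(r5000["inter"]), 0.8, tolerance = 0.05 / 0.8)
  expect_lt(unname(r5000["outside"]), 0.05)
  r500 <- recover(500L)
  expect_lt(r5000["rms"], r500["rms"])
})

test_that("windowed maps recover a planted mid-run correlation switch", {
  a <- 3:6; b <- 12:15
  tr <- generate_gaussian_trajectory(synthetic_spec(
    chains = c(A = 20L), frames = 4000L, frame_interval = 0.1,
    seed = 4L, variances = 0.25,
    blocks = list(list(members = c(a, b), rho = 0.8,
                       window = c(0, 200)))))
  wc <- windowed_correlations(tr, list(c(0, 200), c(200, 400)),
                              fit_mask = NA, block_a = a, block_b = b)
  expect_equal(mean(wc$matrices[[1]][a, b]), 0.8, tolerance = 0.07 / 0.8)
  expect_lt(abs(mean(wc$matrices[[2]][a, b])), 0.07)
  expect_gt(wc$block_contrast[1, 2], 0.5)
  expect_equal(diag(wc$block_contrast),
               setNames(c(0, 0), rownames(wc$block_contrast)))
  # one window spanning everything equals the whole-trajectory matrix
  whole <- cross_correlation_matrix(tr, fit_mask = NA)
  one <- windowed_correlations(tr, list(c(-1, 400)), fit_mask = NA)
  expect_equal(unclass(one$matrices[[1]]), unclass(whole),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(windowed_correlations(tr, list()), "non-empty")
  expect_error(
    cross_correlation_matrix(tr, fit_mask = NA, window = c(900, 1000)),
    "fewer than 2")
})

test_that("bond vectors are unit length, ordered, and chain-bounded", {
  top <- topology(c(rep("A", 4), rep("B", 3)), c(1:4, 1:3))
  cc <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(3.8, 3.8, 3.8),
              c(30, 0, 0), c(33.8, 0, 0), c(33.8, 3.8, 0))
  m <- bond_vectors(cc, top)
  expect_equal(nrow(m), 5L)  # 3 in chain A + 2 in chain B
  expect_equal(unname(sqrt(rowSums(m^2))), rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(m[1, ]), c(1, 0, 0))
  b <- attr(m, "bonds")
  expect_false(any(b$from_index == 4 & b$to_index == 5))
  # coincident successive residues are an error naming the pair
  cc2 <- cc; cc2[2, ] <- cc2[1, ]
  expect_error(bond_vectors(cc2, top), "zero-length.*A:1.*A:2")
})

test_that("autocorrelation is 1 at zero delay and for pure translation", {
  tr <- generate_rotational_diffusion_bonds(synthetic_spec(
    chains = c(A = 8L), frames = 100L, frame_interval = 0.1, seed = 1L,
    D = 0.4))
  ac <- bond_autocorrelation(tr, delays = c(0, 0.5))
  expect_equal(unname(ac[, 1]), rep(1, nrow(ac)), tolerance = 1e-12)
  # rigid translation: directions never change
  ref <- helix_reference(c(A = 6L))
  arr <- array(0, c(20, 6, 3))
  shift <- matrix(c(0.5, 0.2, -0.1), 6, 3, byrow = TRUE)
  for (f in 1:20) arr[f, , ] <- ref$coords + (f - 1) * shift
  trans <- trajectory(ref$topology, arr, frame_interval = 0.1)
  ac2 <- bond_autocorrelation(trans, delays = c(0, 0.5, 1))
  expect_equal(unname(as.vector(ac2)), rep(1, length(ac2)),
               tolerance = 1e-12)
})

test_that("optimized autocorrelation matches the naive double-loop oracle", {
  tr <- generate_rotational_diffusion_bonds(synthetic_spec(
    chains = c(A = 10L), frames = 100L, frame_interval = 0.1, seed = 5L,
    D = 0.8))
  ac <- bond_autocorrelation(tr, delays = c(0, 0.3, 1.2))
  oracle <- naive_bond_autocorrelation(tr$coords, c(0L, 3L, 12L))
  expect_lt(max(abs(unclass(ac) - oracle)), 1e-10)
  expect_true(all(ac >= -1 - 1e-9 & ac <= 1 + 1e-9))
})

test_that("rotational diffusion decays as exp(-2 D tau)", {
  delays <- c(0, 0.2, 0.5, 1)
  for (D in c(0.25, 0.5)) {
    tr <- generate_rotational_diffusion_bonds(synthetic_spec(
      chains = c(A = 10L), frames = 5000L, frame_interval = 0.02,
      seed = 3L), D = D)
    ac <- bond_autocorrelation(tr, delays = delays)
    expect_lt(max(abs(colMeans(ac) - exp(-2 * D * delays))), 0.03)
  }
})

test_that("the statistic is computed on raw coordinates", {
  tr <- generate_rotational_diffusion_bonds(synthetic_spec(
    chains = c(A = 8L), frames = 300L, frame_interval = 0.1, seed = 7L,
    D = 0.6))
  ac <- bond_autocorrelation(tr, delays = c(0, 1, 3))
  # invariant under one global (time-independent) rigid transform ...
  set.seed(4)
  moved <- transform_trajectory(tr, random_rotation(), c(10, -5, 3))
  expect_equal(unclass(bond_autocorrelation(moved, delays = c(0, 1, 3))),
               unclass(ac), tolerance = 1e-9)
  # ... but per-frame realignment changes it, so raw coordinates matter
  aligned <- align_trajectory(tr, frame_coords(tr, 1))
  ac_al <- bond_autocorrelation(aligned, delays = c(0, 1, 3))
  expect_gt(max(abs(ac_al - ac)), 0.01)
  expect_equal(unclass(ac),
               naive_bond_autocorrelation(tr$coords, c(0L, 10L, 30L)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("incommensurate or oversized delays are rejected", {
  tr <- generate_rotational_diffusion_bonds(synthetic_spec(
    chains = c(A = 5L), frames = 50L, frame_interval = 0.1, seed = 2L,
    D = 0.1))
  expect_error(bond_autocorrelation(tr, delays = 0.25),
               "not a multiple")
  expect_error(bond_autocorrelation(tr, delays = 4.9),
               "fewer than 2 frame pairs")
  expect_error(bond_autocorrelation(tr, delays = -1), "nonnegative")
})
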