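test_that("identical spec and seed give bit-identical trajectories", {
  s <- function() synthetic_spec(chains = c(A = 10L), frames = 40L,
                                 seed = 77L, variances = 0.3,
                                 temporal = "ou", theta = 0.5)
  t1 <- generate_gaussian_trajectory(s())
  t2 <- generate_gaussian_trajectory(s())
  expect_identical(t1$coords, t2$coords)
  # generators never touch the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_gaussian_trajectory(s()))
  expect_identical(rnorm(3), before)
})

test_that("zero covariance gives a static trajectory", {
  tr <- generate_gaussian_trajectory(synthetic_spec(
    chains = c(A = 7L), frames = 10L, seed = 1L, variances = 0))
  expect_equal(max(abs(sweep(tr$coords, c(2, 3),
                             tr$coords[1, , ]))), 0)
})

test_that("planted variance and OU relaxation are recovered empirically", {
  theta <- 0.5
  dt <- 0.1
  tr <- generate_gaussian_trajectory(synthetic_spec(
    chains = c(A = 10L), frames = 5000L, frame_interval = dt,
    seed = 8L, variances = 0.25, temporal = "ou", theta = theta))
  ref <- helix_reference(c(A = 10L))$coords
  disp <- sweep(tr$coords, c(2, 3), ref)
  v <- mean(apply(disp, c(2, 3), stats::var))
  expect_equal(v, 0.25, tolerance = 0.05)
  # lag-k autocorrelation of displacements approximates exp(-k dt / theta)
  for (k in c(1L, 5L, 10L)) {
    x <- disp[, 4, 1]
    ac <- stats::cor(x[seq_len(5000 - k)], x[seq_len(5000 - k) + k])
    expect_lt(abs(ac - exp(-k * dt / theta)), 0.05)
  }
})

test_that("invalid planted structures are rejected at spec validation", {
  expect_error(synthetic_spec(chains = c(A = 5L),
                              basins = list(list(offset = 1, spread = 0.1,
                                                 weight = 0.7))),
               "sum to 1")
  expect_error(synthetic_spec(chains = c(A = 5L),
                              basins = list(list(offset = 1, spread = 0,
                                                 weight = 1))),
               "positive")
  expect_error(synthetic_spec(chains = c(A = 5L), variances = -1),
               "nonnegative")
  expect_error(synthetic_spec(chains = c(A = 5L), D = -0.1),
               "nonnegative")
  expect_error(synthetic_spec(chains = c(A = 6L), frames = 10L,
                              events = list(list(time = 99, chain = "A"))),
               "inside the trajectory span")
  expect_error(synthetic_spec(chains = c(A = 6L), temporal = "ou",
                              blocks = list(list(members = 1:3, rho = 0.5,
                                                 window = c(0, 1)))),
               "white temporal model")
})

test_that("rotational diffusion is frozen at D = 0 and speeds up with D", {
  frozen <- generate_rotational_diffusion_bonds(synthetic_spec(
    chains = c(A = 8L), frames = 50L, frame_interval = 0.1, seed = 2L,
    D = 0))
  ac <- bond_autocorrelation(frozen, delays = c(0, 1, 2))
  expect_equal(unname(as.vector(ac)), rep(1, length(ac)),
               tolerance = 1e-9)
  decay_at_1 <- vapply(c(0.1, 0.4, 1), function(D) {
    tr <- generate_rotational_diffusion_bonds(synthetic_spec(
      chains = c(A = 8L), frames = 2000L, frame_interval = 0.05,
      seed = 4L), D = D)
    mean(bond_autocorrelation(tr, delays = 1)[, 1])
  }, 0)
  expect_true(all(diff(decay_at_1) < 0))
  # successive C-alpha spacing is the canonical 3.8 A
  cc <- frame_coords(frozen, 1)
  expect_equal(unname(sqrt(rowSums(diff(cc)^2))), rep(3.8, 7),
               tolerance = 1e-9)
})

test_that("a zero-angle event leaves the RMSD series statistically flat", {
  spec <- synthetic_spec(chains = c(A = 10L, B = 8L), frames = 300L,
                         frame_interval = 0.1, seed = 6L,
                         variances = 0.04,
                         events = list(list(time = 15, chain = "B",
                                            angle = 0, axis = c(0, 0, 1),
                                            translation = c(0, 0, 0))))
  tr <- generate_rotation_event(spec)
  pl <- attr(tr, "planted")
  expect_equal(pl$pre_reference, pl$post_reference)
  rs <- rmsd_timeseries(tr, pl$pre_reference,
                        fit_mask = select_residues(tr$topology, "A"),
                        measure_mask = select_residues(tr$topology, "B"))
  tt <- stats::t.test(rs$rmsd[rs$time <= 15], rs$rmsd[rs$time > 15])
  expect_gt(tt$p.value, 0.01)
})

test_that("multibasin weights drive per-trajectory sampling", {
  spec <- synthetic_spec(
    chains = c(A = 10L), frames = 800L, seed = 3L,
    basins = list(list(offset = 2, spread = 0.3, weight = 0.5),
                  list(offset = 2, spread = 0.3, weight = 0.5)))
  trs <- generate_multibasin_ensemble(spec,
                                      weights = list(c(1, 0), c(0.3, 0.7)))
  expect_equal(length(trs), 2L)
  lab2 <- attr(trs[[2]], "planted")$basin_sequence
  expect_equal(mean(lab2 == 1), 0.3, tolerance = 0.1)
  expect_true(all(attr(trs[[1]], "planted")$basin_sequence == 1))
  # basin geometry is shared across the output trajectories
  expect_equal(attr(trs[[1]], "planted")$centers,
               attr(trs[[2]], "planted")$centers)
  expect_error(generate_multibasin_ensemble(spec, weights = list(c(2, 0))),
               "summing to 1")
})

test_that("basin offsets survive superposition by construction", {
  spec <- synthetic_spec(
    chains = c(A = 16L), frames = 10L, seed = 13L,
    basins = list(list(offset = 3, spread = 1e-6, weight = 1)))
  tr <- generate_multibasin_ensemble(spec)
  ref <- helix_reference(c(A = 16L))$coords
  rs <- rmsd_timeseries(tr, ref)
  expect_equal(mean(rs$rmsd), 3, tolerance = 0.01)
})
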