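ref20 <- helix_reference(c(A = 20L))

three_basins <- function(frames = 1000L, seed = 5L, weights = NULL) {
  spec <- synthetic_spec(
    chains = c(A = 20L), frames = frames, frame_interval = 0.1,
    seed = seed,
    basins = list(list(offset = 3, spread = 0.5, weight = 0.5),
                  list(offset = 3, spread = 0.5, weight = 0.15),
                  list(offset = 4.5, spread = 0.5, weight = 0.35)))
  generate_multibasin_ensemble(spec, weights = weights)
}

test_that("an ensemble of identical frames forms one full cluster", {
  arr <- array(rep(ref20$coords, each = 10), c(10, 20, 3))
  tr <- trajectory(ref20$topology, arr, frame_interval = 0.1)
  cm <- cluster_conformations(tr, ref20$coords, radius = 1.7)
  expect_equal(length(cm$centroids), 1L)
  expect_equal(unname(cm$occupancy[1, 1]), 100)
})

test_that("planted basin occupancies are recovered at the planted radius", {
  tr <- three_basins()
  cm <- cluster_conformations(tr, ref20$coords, radius = 1.7, seed = 1)
  expect_equal(length(cm$centroids), 3L)
  occ <- sort(cm$occupancy[1, ], decreasing = TRUE)
  expect_lt(max(abs(occ - c(50, 35, 15))), 3)
  expect_equal(sum(cm$occupancy[1, ]), 100, tolerance = 1e-6)
  # every frame sits with its nearest centroid
  cen <- do.call(rbind, lapply(cm$centroids, function(m) as.vector(t(m))))
  D <- ensdyn:::rmsd_to_centroids(cm$frames, cen, cm$n_res)
  expect_equal(max.col(-D, ties.method = "first"),
               unname(cm$assignments[[1]]))
})

test_that("cluster count is nonincreasing over the radius grid", {
  tr <- three_basins()
  counts <- vapply(c(1.5, 1.7, 2, 10), function(r)
    length(cluster_conformations(tr, ref20$coords,
                                 radius = r)$centroids), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[4], 1L)
})

test_that("the k-means objective never increases across iterations", {
  tr <- three_basins(seed = 8L)
  cm <- cluster_conformations(tr, ref20$coords, radius = 1.0)
  expect_true(all(diff(cm$objective) <= 1e-9))
})

test_that("clustering is exactly reproducible and matches Lloyd k-means", {
  tr <- three_basins(frames = 300L)
  cm1 <- cluster_conformations(tr, ref20$coords, radius = 1.7, seed = 3)
  cm2 <- cluster_conformations(tr, ref20$coords, radius = 1.7, seed = 3)
  expect_identical(cm1$assignments, cm2$assignments)
  expect_identical(cm1$centroids, cm2$centroids)
  # same seeding handed to stats::kmeans (Lloyd) gives the same partition:
  # RMSD-to-centroid is euclidean distance / sqrt(n), so assignments agree
  X <- cm1$frames
  km <- suppressWarnings(stats::kmeans(
    X, centers = do.call(rbind, lapply(
      cm1$centroids, function(m) as.vector(t(m)))),
    iter.max = 1, algorithm = "Lloyd"))
  expect_equal(unname(km$cluster), unname(cm1$assignments[[1]]))
})

test_that("joined ensembles share clusters and occupancy rows sum to 100", {
  tr <- three_basins(frames = 400L)
  cm <- joined_ensemble_analysis(tr, tr, ref20$coords, radius = 1.7)
  expect_equal(nrow(cm$occupancy), 2L)
  expect_equal(cm$occupancy[1, ], cm$occupancy[2, ])
  expect_equal(unname(rowSums(cm$occupancy)), c(100, 100),
               tolerance = 1e-6)
  expect_equal(length(cm$timeline), 2L)
})

test_that("one confined and one spread ensemble reproduce planted rows", {
  trs <- three_basins(frames = 1000L, seed = 12L,
                      weights = list(c(0.98, 0.01, 0.01),
                                     c(0.5, 0.15, 0.35)))
  cm <- cluster_conformations(list(bound = trs[[1]], free = trs[[2]]),
                              ref20$coords, radius = 1.7)
  expect_equal(length(cm$centroids), 3L)
  # map clusters to planted basins by centroid-to-center distance
  centers <- attr(trs[[1]], "planted")$centers
  perm <- vapply(cm$centroids, function(cen)
    which.min(vapply(centers, function(ctr)
      sqrt(mean(rowSums((cen - ctr)^2))), 0)), 0L)
  expect_setequal(perm, 1:3)
  # recovered rows match the realized basin draws near-exactly ...
  freq <- function(tr) 100 * tabulate(
    attr(tr, "planted")$basin_sequence, 3)[perm] / 1000
  expect_lt(max(abs(cm$occupancy["bound", ] - freq(trs[[1]]))), 0.5)
  expect_lt(max(abs(cm$occupancy["free", ] - freq(trs[[2]]))), 0.5)
  # ... and the planted weights up to sampling noise
  expect_lt(max(abs(cm$occupancy["bound", ] -
                      100 * c(0.98, 0.01, 0.01)[perm])), 3)
  expect_lt(max(abs(cm$occupancy["free", ] -
                      100 * c(0.5, 0.15, 0.35)[perm])), 3.5)
})

test_that("ensembles confined to disjoint basins do not share clusters", {
  trs <- three_basins(frames = 300L, seed = 9L,
                      weights = list(c(1, 0, 0), c(0, 0.4, 0.6)))
  cm <- cluster_conformations(list(a = trs[[1]], b = trs[[2]]),
                              ref20$coords, radius = 1.7)
  both <- cm$occupancy[1, ] > 0 & cm$occupancy[2, ] > 0
  expect_false(any(both))
})

test_that("representative structures are medoids with earliest-frame ties", {
  tr <- three_basins(frames = 200L)
  cm <- cluster_conformations(tr, ref20$coords, radius = 1.7)
  med <- representative_structures(cm)
  expect_equal(length(med), length(cm$centroids))
  for (k in seq_along(med)) {
    cen <- matrix(as.vector(t(cm$centroids[[k]])), nrow = 1)
    members <- which(cm$assignments[[1]] == k)
    d <- ensdyn:::rmsd_to_centroids(
      cm$frames[members, , drop = FALSE], cen, cm$n_res)
    expect_equal(med[[k]]$rmsd_to_centroid, min(d), tolerance = 1e-12)
    # planted geometry: medoid lies within the basin spread of a center
    cdist <- vapply(attr(tr, "planted")$centers, function(ctr)
      sqrt(mean(rowSums((med[[k]]$coords - ctr)^2))), 0)
    expect_lt(min(cdist), 3 * 0.5)
  }
  # tie rule: all frames equidistant -> earliest wins
  arr <- array(rep(ref20$coords, each = 4), c(4, 20, 3))
  arr[2, 1, 1] <- arr[2, 1, 1] + 1
  arr[3, 1, 1] <- arr[3, 1, 1] - 1
  tr2 <- trajectory(ref20$topology, arr, frame_interval = 0.1)
  cm2 <- cluster_conformations(tr2, ref20$coords, radius = 50)
  med2 <- representative_structures(cm2)
  expect_equal(med2$cluster_1$time, 0)
})

test_that("single-direction variation loads entirely on PC1", {
  n <- 12L
  ref <- helix_reference(c(A = n))
  u <- ensdyn:::rigid_modes(ref$coords)
  set.seed(6)
  v <- rnorm(3 * n); v <- v - u %*% crossprod(u, v)
  v <- v / sqrt(sum(v^2))
  nf <- 100L
  z <- rnorm(nf)
  arr <- array(0, c(nf, n, 3))
  for (f in seq_len(nf)) {
    arr[f, , ] <- ref$coords + matrix(z[f] * v, ncol = 3, byrow = TRUE)
  }
  tr <- trajectory(ref$topology, arr, frame_interval = 0.1)
  pm <- pca_fit(tr, ref$coords)
  expect_equal(pm$proportions[1], 1, tolerance = 1e-9)
  expect_gt(abs(sum(pm$eigenvectors[, 1] * v)), 0.999)
})

test_that("planted two-mode variances give 0.8/0.2 proportions", {
  n <- 15L
  ref <- helix_reference(c(A = n))
  basis <- ensdyn:::rigid_modes(ref$coords)
  set.seed(10)
  u <- rnorm(3 * n); u <- u - basis %*% crossprod(basis, u)
  u <- u / sqrt(sum(u^2)); basis <- cbind(basis, u)
  w <- rnorm(3 * n); w <- w - basis %*% crossprod(basis, w)
  w <- w / sqrt(sum(w^2))
  nf <- 2000L
  z1 <- rnorm(nf, sd = 2); z2 <- rnorm(nf, sd = 1)
  arr <- array(0, c(nf, n, 3))
  for (f in seq_len(nf)) {
    arr[f, , ] <- ref$coords +
      matrix(z1[f] * u + z2[f] * w, ncol = 3, byrow = TRUE)
  }
  tr <- trajectory(ref$topology, arr, frame_interval = 0.1)
  pm <- pca_fit(tr, ref$coords)
  expect_lt(max(abs(pm$proportions[1:2] - c(0.8, 0.2))), 0.03)
  expect_equal(pm$cumulative[length(pm$cumulative)], 1, tolerance = 1e-9)
  # eigenvalues nonincreasing, eigenvectors orthonormal
  expect_true(all(diff(pm$eigenvalues) <= 1e-9))
  G <- crossprod(pm$eigenvectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
})

test_that("eigenvalue sum equals total variance; projection reconstructs", {
  tr <- quick_gaussian(n = 8L, frames = 60L, seed = 19L)
  ref <- helix_reference(c(A = 8L))$coords
  pm <- pca_fit(tr, ref)
  al <- align_trajectory(tr, ref)
  X <- ensdyn:::flatten_frames(al, frames = usable_frames(al))
  expect_equal(sum(pm$eigenvalues), sum(apply(X, 2, stats::var)),
               tolerance = 1e-8)
  # full-rank projection reconstructs the centered coordinates
  proj <- pca_project(tr, pm,
                      components = seq_along(pm$eigenvalues))
  Xc <- sweep(X, 2, pm$mean)
  back <- as.matrix(proj[, -1]) %*% t(pm$eigenvectors)
  expect_lt(max(abs(back - Xc)), 1e-8)
  # the mean conformation projects to the origin
  one <- trajectory(tr$topology, ensdyn:::unflatten_frame(pm$mean),
                    frame_interval = 0.1, equilibration_end = 0)
  p0 <- pca_project(one, pm, components = 1:2,
                    exclude_equilibration = FALSE)
  expect_equal(unname(unlist(p0[1, c("PC1", "PC2")])), c(0, 0),
               tolerance = 1e-8)
})

test_that("two basins separate in the PC1/PC2 plane by the planted offset", {
  spec <- synthetic_spec(
    chains = c(A = 20L), frames = 600L, frame_interval = 0.1, seed = 14L,
    basins = list(list(offset = 3, spread = 0.4, weight = 0.5),
                  list(offset = 3, spread = 0.4, weight = 0.5)))
  tr <- generate_multibasin_ensemble(spec)
  pm <- pca_fit(tr, ref20$coords)
  proj <- pca_project(tr, pm)
  lab <- attr(tr, "planted")$basin_sequence
  c1 <- colMeans(proj[lab == 1, c("PC1", "PC2")])
  c2 <- colMeans(proj[lab == 2, c("PC1", "PC2")])
  # separation of basin centers: sqrt(3^2 + 3^2) * sqrt(n_res) in 3N space
  planted <- sqrt(3^2 + 3^2) * sqrt(20)
  expect_equal(sqrt(sum((c1 - c2)^2)), planted, tolerance = 0.05)
  expect_error(pca_project(tr, pm, components = 9999L), "out of range")
})

test_that("invalid clustering inputs are hard errors", {
  tr <- three_basins(frames = 50L)
  expect_error(cluster_conformations(tr, ref20$coords, radius = -1),
               "positive")
  expect_error(cluster_conformations(tr, ref20$coords, radius = 0),
               "positive")
})
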