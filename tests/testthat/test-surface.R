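# a 5x5x5 volume with unit voxels at the origin, wrapped as one frame
unit_vol <- function(values) {
  arr <- array(values, dim = c(5, 5, 5, 1))
  structure(list(data = arr, affine = diag(4), TR_s = 1),
            class = "volume_ts")
}
# mesh whose vertices are probe points (faces only used for validity)
probe_mesh <- function(pts) cortical_mesh(pts, matrix(1:3, 1))

test_that("trilinear sampling interpolates exactly at and between voxel centers", {
  vals <- array(0, c(5, 5, 5))
  vals[3, 3, 3] <- 7
  vals[4, 3, 3] <- 9
  vol <- unit_vol(vals)
  pts <- rbind(c(2, 2, 2),      # voxel [3,3,3] center (0-based world = index)
               c(2.5, 2, 2),    # midpoint between two centers
               c(0, 0, 0))
  sts <- sample_volume_to_surface(vol, probe_mesh(pts))
  expect_equal(as.numeric(sts$data), c(7, (7 + 9) / 2, 0))
})

test_that("a spatially constant volume samples to a constant surface", {
  vol <- unit_vol(rep(4.25, 125))
  pts <- rbind(c(1.2, 2.7, 3.1), c(0.4, 0.1, 3.9), c(2, 2, 2))
  sts <- sample_volume_to_surface(vol, probe_mesh(pts))
  expect_equal(as.numeric(sts$data), rep(4.25, 3))
})

test_that("vertices outside the volume are reported by id", {
  vol <- unit_vol(rep(0, 125))
  pts <- rbind(c(2, 2, 2), c(9, 0, 0), c(1, 1, 1))
  expect_error(sample_volume_to_surface(vol, probe_mesh(pts)), "2")
})

test_that("smoothing preserves constants and is the identity at fwhm 0", {
  mesh <- make_synthetic_mesh(1, 10)
  const <- structure(list(data = matrix(3.3, 4, 42), TR_s = 1.5),
                     class = "surface_ts")
  expect_equal(surface_smooth(const, mesh, fwhm_mm = 8)$data, const$data)
  set.seed(1)
  rnd <- structure(list(data = matrix(rnorm(2 * 42), 2, 42), TR_s = 1.5),
                   class = "surface_ts")
  expect_identical(surface_smooth(rnd, mesh, 0)$data, rnd$data)
})

test_that("sparse iterated smoothing matches a dense matrix-power oracle", {
  mesh <- make_synthetic_mesh(2, 40)   # 162 vertices
  lambda <- 0.5
  fwhm <- 10
  # dense oracle assembled independently from edge lengths
  adj <- vertex_adjacency(mesh)
  V <- 162
  W <- matrix(0, V, V)
  h <- mean(adj$lengths)
  for (e in seq_len(nrow(adj$edges))) {
    i <- adj$edges[e, 1]; j <- adj$edges[e, 2]
    w <- exp(-adj$lengths[e]^2 / (2 * h^2))
    W[i, j] <- w; W[j, i] <- w
  }
  P <- W / rowSums(W)
  M <- (1 - lambda) * diag(V) + lambda * P
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  n_iter <- ceiling(sigma^2 / (lambda * h^2))
  Mk <- diag(V)
  for (i in seq_len(n_iter)) Mk <- Mk %*% M
  impulse <- matrix(0, 1, V); impulse[1, 17] <- 1
  sts <- structure(list(data = impulse, TR_s = 1.5), class = "surface_ts")
  got <- surface_smooth(sts, mesh, fwhm, lambda = lambda)$data
  # smoothing a field x is x -> M x, so the impulse response is column 17
  expect_lt(max(abs(as.numeric(got) - Mk[, 17])), 1e-10)
})

test_that("smoothing obeys the maximum principle and shrinks variance", {
  mesh <- make_synthetic_mesh(2, 30)
  set.seed(7)
  X <- matrix(rnorm(3 * 162), 3, 162)
  sts <- structure(list(data = X, TR_s = 1.5), class = "surface_ts")
  sm <- surface_smooth(sts, mesh, 6)$data
  for (f in 1:3) {
    expect_gte(min(sm[f, ]), min(X[f, ]))
    expect_lte(max(sm[f, ]), max(X[f, ]))
    expect_lt(var(sm[f, ]), var(X[f, ]))
  }
})

test_that("degenerate patch partitions behave as identity and pooling", {
  mesh <- make_synthetic_mesh(1, 10)   # 42 vertices
  id <- build_patch_partition(mesh, 42)
  expect_equal(id$assignment, 1:42)
  one <- build_patch_partition(mesh, 1)
  expect_equal(one$assignment, rep(1L, 42))
  big <- build_patch_partition(mesh, 1000)  # clipped to V
  expect_equal(big$K, 42)
})

test_that("farthest-point centers match an exhaustive max-min search", {
  mesh <- make_synthetic_mesh(0, 10)   # icosahedron
  g <- cortexstress:::mesh_graph(mesh)
  D <- igraph::distances(g)
  part <- build_patch_partition(mesh, 2, start_vertex = 1)
  # second center: vertex at maximal graph distance from vertex 1
  expect_equal(D[1, part$centers[2]], max(D[1, ]))
  # three centers: brute-force over all candidates for the third pick
  part3 <- build_patch_partition(mesh, 3, start_vertex = 1)
  dmin <- pmin(D[part3$centers[1], ], D[part3$centers[2], ])
  expect_equal(dmin[part3$centers[3]], max(dmin))
})

test_that("patch assignment is a partition covering every vertex", {
  mesh <- make_synthetic_mesh(2, 30)
  part <- build_patch_partition(mesh, 40)
  expect_length(part$assignment, 162)
  counts <- tabulate(part$assignment, nbins = 40)
  expect_equal(sum(counts), 162)
  expect_true(all(counts > 0))
  # centers belong to their own patch
  expect_equal(part$assignment[part$centers], 1:40)
})

test_that("patch features average vertices within patches", {
  sts <- structure(list(data = matrix(c(1, 3, 5), 1, 3), TR_s = 1),
                   class = "surface_ts")
  part <- structure(list(centers = c(1L, 3L),
                         assignment = c(1L, 1L, 2L), K = 2L),
                    class = "patch_partition")
  expect_equal(as.numeric(patch_features(sts, part)), c(2, 5))
  # identity partition reproduces vertex values
  idp <- structure(list(centers = 1:3, assignment = 1:3, K = 3L),
                   class = "patch_partition")
  expect_equal(as.numeric(patch_features(sts, idp)), c(1, 3, 5))
  # single patch gives the global mean
  onep <- structure(list(centers = 1L, assignment = rep(1L, 3), K = 1L),
                    class = "patch_partition")
  expect_equal(as.numeric(patch_features(sts, onep)), 3)
})

test_that("ANOVA F ranking matches direct sum-of-squares computation", {
  # two groups A=(1,2), B=(5,6): F = 32
  X <- cbind(f1 = c(1, 2, 5, 6))
  labels <- c(1, 1, 2, 2)
  sel <- select_features(X, labels, 1)
  expect_equal(unname(attr(sel, "F_stat")), 32)
  # cross-check against R's aov on the same toy
  f_aov <- summary(aov(X[, 1] ~ factor(labels)))[[1]]$`F value`[1]
  expect_equal(unname(attr(sel, "F_stat")), f_aov)
})

test_that("feature ranking places label copies first and constants last", {
  set.seed(3)
  labels <- rep(1:4, each = 3)
  X <- cbind(noise1 = rnorm(12), exact = labels, const = rep(2, 12),
             noise2 = rnorm(12))
  sel <- select_features(X, labels, 4)
  expect_equal(sel[1], 2L)               # within-group variance 0 -> F = Inf
  expect_equal(sel[4], 3L)               # constant -> F = 0, ranked last
  f <- unname(attr(sel, "F_stat"))
  expect_equal(f[3], 0)
  expect_true(is.infinite(f[2]))
})

test_that("feature ranking is invariant to per-feature affine rescaling", {
  set.seed(11)
  labels <- rep(1:8, each = 3)
  X <- matrix(rnorm(24 * 10), 24, 10) + labels
  s1 <- select_features(X, labels, 10)
  X2 <- sweep(sweep(X, 2, runif(10, 0.1, 5), "*"), 2, runif(10, -3, 3), "+")
  s2 <- select_features(X2, labels, 10)
  expect_equal(as.integer(s1), as.integer(s2))
})

test_that("feature ranking requires two samples per class", {
  expect_error(select_features(cbind(1:3), c(1, 1, 2), 1), "fewer than 2")
})
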