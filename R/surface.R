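#' Sample a 4D volume onto a cortical mesh
#'
#' Maps each vertex through the inverse voxel-to-world affine and
#' interpolates the volume trilinearly at the resulting (0-based) voxel
#' coordinate, per frame. This realizes gray-matter sampling: only
#' intensities at the surface of interest enter the analysis.
#'
#' @param vol a `volume_ts` (4D `data`, 4x4 `affine`, `TR_s`).
#' @param mesh a [cortical_mesh] in the volume's world space (mm).
#' @return A `surface_ts`: list with `data` (frames x vertices), `TR_s`.
#' @export
sample_volume_to_surface <- function(vol, mesh) {
  dims <- dim(vol$data)
  stopifnot(length(dims) == 4)
  nvox <- prod(dims[1:3])
  W <- trilinear_weights(mesh$vertices, vol$affine, dims[1:3])
  X <- vol$data
  dim(X) <- c(nvox, dims[4])
  out <- t(as.matrix(W %*% X))
  structure(list(data = out, TR_s = vol$TR_s), class = "surface_ts")
}

# Sparse V x nvox trilinear interpolation operator for points in world mm.
trilinear_weights <- function(points, affine, dims3) {
  ijk <- t(solve(affine) %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
  bad <- which(apply(ijk, 1, function(p)
    any(p < 0 | p > dims3 - 1)))
  if (length(bad) > 0)
    stop(sprintf("vertices outside volume bounds: %s%s",
                 paste(utils::head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) sprintf(" (and %d more)",
                                               length(bad) - 10) else ""))
  i0 <- pmin(floor(ijk), matrix(rep(dims3 - 2, each = nrow(ijk)), ncol = 3))
  i0 <- pmax(i0, 0)
  fr <- ijk - i0
  n <- nrow(points)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- 1 + (i0[, 1] + dx) + dims3[1] * ((i0[, 2] + dy) +
            dims3[2] * (i0[, 3] + dz))
    rows <- c(rows, seq_len(n)); cols <- c(cols, lin); vals <- c(vals, w)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(n, prod(dims3)))
}

# Row-normalized Gaussian-edge-weight neighbor-average operator P and the
# (lambda, n_iter) calibration for a requested FWHM. One diffusion step
# x <- (1 - lambda) x + lambda P x spreads variance by about lambda * h^2
# along the mesh (h = mean edge length), so n_iter = ceil(sigma^2 /
# (lambda h^2)) with sigma = fwhm / sqrt(8 ln 2). lambda is fixed at 0.5.
smoothing_operator <- function(mesh, adj = NULL) {
  if (is.null(adj)) adj <- vertex_adjacency(mesh)
  h <- mean(adj$lengths)
  w <- exp(-adj$lengths^2 / (2 * h^2))
  V <- adj$n_vertices
  P <- Matrix::sparseMatrix(i = c(adj$edges[, 1], adj$edges[, 2]),
                            j = c(adj$edges[, 2], adj$edges[, 1]),
                            x = c(w, w), dims = c(V, V))
  rs <- Matrix::rowSums(P)
  isolated <- rs == 0
  rs[isolated] <- 1
  P <- Matrix::Diagonal(x = 1 / rs) %*% P
  if (any(isolated))
    P <- P + Matrix::Diagonal(x = as.numeric(isolated))
  list(P = P, mean_edge = h)
}

#' Smooth a surface time series along the cortical manifold
#'
#' Iterative graph diffusion restricted to mesh edges: each step replaces a
#' vertex value by a convex combination of itself and the Gaussian-weighted
#' average of its neighbors. Smoothing therefore follows the folded surface
#' rather than cutting through volume space. `fwhm_mm = 0` returns the
#' input unchanged. The operator preserves constants and obeys the maximum
#' principle (outputs stay within the input's range).
#'
#' @param sts a `surface_ts` (frames x vertices).
#' @param mesh the [cortical_mesh] the series lives on.
#' @param fwhm_mm requested smoothing extent (full width at half maximum,
#'   mm), >= 0.
#' @param lambda per-step mixing weight in (0, 1]; default 0.5.
#' @return A smoothed `surface_ts`.
#' @export
surface_smooth <- function(sts, mesh, fwhm_mm, lambda = 0.5) {
  stopifnot(fwhm_mm >= 0, lambda > 0, lambda <= 1)
  if (fwhm_mm == 0) return(sts)
  adj <- vertex_adjacency(mesh)
  g <- mesh_graph(mesh, adj)
  if (igraph::count_components(g) > 1)
    warning("mesh is disconnected; smoothing within components")
  op <- smoothing_operator(mesh, adj)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  n_iter <- ceiling(sigma^2 / (lambda * op$mean_edge^2))
  X <- sts$data
  Pt <- Matrix::t(op$P)
  for (i in seq_len(n_iter))
    X <- (1 - lambda) * X + lambda * as.matrix(X %*% Pt)
  structure(list(data = X, TR_s = sts$TR_s), class = "surface_ts")
}

#' Partition mesh vertices into patches by farthest-point sampling
#'
#' Selects `K_base` patch centers by iterative farthest-point sampling under
#' graph-geodesic distance (edge lengths as weights), starting from
#' `start_vertex`, then assigns every vertex to its nearest center (ties go
#' to the lower patch id, i.e. the earlier-selected center). Averaging
#' within these quasi-uniform patches is the downsampling half of the
#' blur-and-downsample dimensionality reduction.
#'
#' @param mesh a [cortical_mesh].
#' @param K_base number of patches (clipped to the vertex count).
#' @param start_vertex 1-based index of the first center (default 1).
#' @return A `patch_partition`: list with `centers` (vertex ids, one per
#'   patch), `assignment` (integer patch id per vertex), `K`.
#' @export
build_patch_partition <- function(mesh, K_base, start_vertex = 1) {
  stopifnot(K_base >= 1)
  V <- nrow(mesh$vertices)
  K <- min(K_base, V)
  if (K == V) {
    return(structure(list(centers = seq_len(V), assignment = seq_len(V),
                          K = V), class = "patch_partition"))
  }
  g <- mesh_graph(mesh)
  centers <- integer(K)
  centers[1] <- as.integer(start_vertex)
  d <- as.numeric(igraph::distances(g, v = centers[1]))
  assignment <- rep(1L, V)
  for (k in seq_len(K - 1)) {
    nxt <- which.max(d)   # ties: lowest vertex id
    centers[k + 1] <- nxt
    dn <- as.numeric(igraph::distances(g, v = nxt))
    closer <- dn < d      # strict: ties keep the earlier (lower) patch id
    assignment[closer] <- k + 1L
    d[closer] <- dn[closer]
  }
  structure(list(centers = centers, assignment = assignment, K = K),
            class = "patch_partition")
}

#' Average a surface time series within patches
#'
#' Collapses the per-vertex series to one feature per patch (the unweighted
#' mean over the patch's vertices), per frame. Feature order follows patch
#' id order.
#'
#' @param sts a `surface_ts`.
#' @param partition a [build_patch_partition] result covering all vertices.
#' @return A numeric matrix, frames x K, with attribute `TR_s`.
#' @export
patch_features <- function(sts, partition) {
  V <- ncol(sts$data)
  stopifnot(length(partition$assignment) == V)
  M <- Matrix::sparseMatrix(i = seq_len(V), j = partition$assignment, x = 1,
                            dims = c(V, partition$K))
  cnt <- Matrix::colSums(M)
  if (any(cnt == 0)) stop("empty patch in partition")
  M <- M %*% Matrix::Diagonal(x = 1 / cnt)
  out <- as.matrix(sts$data %*% M)
  colnames(out) <- sprintf("f%04d", seq_len(partition$K))
  attr(out, "TR_s") <- sts$TR_s
  out
}

#' Rank features by one-way ANOVA F against the stress label
#'
#' Scores every feature by the classical one-way F statistic of feature
#' value against the 8-class label, computed on training samples only, and
#' returns the top `K_sub` feature indices in descending F order (ties:
#' lower feature id first). The F statistic is invariant to per-feature
#' affine rescaling, so ranking does not depend on feature units.
#'
#' @param X training feature matrix (samples x features).
#' @param labels integer labels (1-8), one per row of `X`.
#' @param K_sub number of features to keep (default all).
#' @return Integer vector of feature indices, length `K_sub`, with the full
#'   F vector as attribute `F_stat`.
#' @export
select_features <- function(X, labels, K_sub = ncol(X)) {
  stopifnot(K_sub >= 1, K_sub <= ncol(X), nrow(X) == length(labels))
  counts <- table(labels)
  if (any(counts < 2))
    stop(sprintf("class %s has fewer than 2 training samples",
                 names(counts)[which(counts < 2)[1]]))
  n <- nrow(X)
  k <- length(counts)
  if (k < 2) stop("need at least 2 classes to rank features")
  gm <- colMeans(X)
  ssb <- numeric(ncol(X))
  ssw <- numeric(ncol(X))
  for (g in names(counts)) {
    rows <- labels == as.numeric(g)
    mg <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (mg - gm)^2
    ssw <- ssw + colSums((X[rows, , drop = FALSE] -
                            matrix(mg, nrow = sum(rows), ncol = ncol(X),
                                   byrow = TRUE))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  tot <- ssb + ssw
  f[tot <= 1e-12 * pmax(gm^2, 1)] <- 0     # constant feature: no information
  f[ssw == 0 & ssb > 0] <- Inf
  ord <- order(-f, seq_along(f))
  structure(ord[seq_len(K_sub)], F_stat = f)
}
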