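#' Triangulated cortical surface mesh
#'
#' A `cortical_mesh` stores vertex coordinates in world millimetres together
#' with a triangle index list. It is the geometric substrate for
#' volume-to-surface sampling, manifold smoothing and patch downsampling.
#' For simulation work a closed icosphere stands in for the gray-white
#' interface surface that a segmentation pipeline would normally provide.
#'
#' @param vertices numeric matrix, V x 3, vertex coordinates in mm.
#' @param faces integer matrix, F x 3, 1-based vertex indices per triangle.
#' @return An object of class `cortical_mesh` with elements `vertices` and
#'   `faces`.
#' @export
cortical_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Unit icosahedron with a fixed, deterministic vertex ordering.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# One loop-style subdivision pass: each edge gains a midpoint vertex
# (projected back to the unit sphere), each face splits into four.
# Midpoints are created in face-scan order, which fixes the vertex ordering.
subdivide_sphere <- function(vertices, faces) {
  key <- function(a, b) paste(min(a, b), max(a, b))
  cache <- new.env(hash = TRUE, parent = emptyenv())
  verts <- vertices
  midpoint <- function(a, b) {
    k <- key(a, b)
    id <- cache[[k]]
    if (!is.null(id)) return(id)
    m <- (verts[a, ] + verts[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    id <- nrow(verts)
    cache[[k]] <- id
    id
  }
  newf <- matrix(0L, nrow = 4 * nrow(faces), ncol = 3)
  for (i in seq_len(nrow(faces))) {
    a <- faces[i, 1]; b <- faces[i, 2]; c3 <- faces[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
    newf[4 * i - 3, ] <- c(a, ab, ca)
    newf[4 * i - 2, ] <- c(b, bc, ab)
    newf[4 * i - 1, ] <- c(c3, ca, bc)
    newf[4 * i, ]     <- c(ab, bc, ca)
  }
  list(vertices = verts, faces = newf)
}

#' Generate a synthetic spherical cortical mesh
#'
#' Builds a closed icosphere by repeatedly subdividing an icosahedron and
#' projecting onto the sphere. After k subdivisions the mesh has
#' 10 * 4^k + 2 vertices, 20 * 4^k faces and 30 * 4^k edges. The vertex
#' ordering is deterministic, so identical arguments always produce an
#' identical mesh.
#'
#' @param subdivision_level non-negative integer, number of subdivision
#'   passes (k).
#' @param radius_mm positive sphere radius in mm.
#' @return A [cortical_mesh].
#' @examples
#' m <- make_synthetic_mesh(2, radius_mm = 40)
#' nrow(m$vertices)  # 162
#' @export
make_synthetic_mesh <- function(subdivision_level = 3, radius_mm = 40) {
  stopifnot(subdivision_level >= 0, radius_mm > 0)
  s <- icosahedron()
  k <- as.integer(subdivision_level)
  for (i in seq_len(k)) s <- subdivide_sphere(s$vertices, s$faces)
  cortical_mesh(s$vertices * radius_mm, s$faces)
}

#' Vertex adjacency of a triangular mesh
#'
#' Extracts the undirected edge set with Euclidean edge lengths (mm). For a
#' closed triangular mesh the edge count is 3F/2.
#'
#' @param mesh a [cortical_mesh].
#' @return A list with `edges` (E x 2 integer matrix, first column < second),
#'   `lengths` (numeric, mm) and `n_vertices`.
#' @export
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  fsort <- t(apply(f, 1, sort))
  if (anyDuplicated(fsort))
    stop("non-manifold mesh: duplicate faces")
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  if (any(d == 0)) stop("mesh has zero-length edges")
  list(edges = e, lengths = d, n_vertices = nrow(mesh$vertices))
}

# Weighted igraph view of the mesh's edge graph (edge lengths as weights).
mesh_graph <- function(mesh, adj = NULL) {
  if (is.null(adj)) adj <- vertex_adjacency(mesh)
  g <- igraph::make_graph(t(adj$edges), n = adj$n_vertices, directed = FALSE)
  igraph::E(g)$weight <- adj$lengths
  g
}

#' Write a mesh as ASCII OFF
#'
#' @param mesh a [cortical_mesh].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1, function(r)
    paste(c(3L, r - 1L), collapse = " ")), con)
  invisible(path)
}

#' Read an ASCII OFF mesh
#'
#' @param path path to an OFF file (triangles only).
#' @return A [cortical_mesh].
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vl <- lines[3:(2 + nv)]
  fl <- lines[(3 + nv):(2 + nv + nf)]
  v <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
              ncol = 3, byrow = TRUE)
  fraw <- lapply(strsplit(trimws(fl), "\\s+"), as.integer)
  if (any(vapply(fraw, `[`, integer(1), 1) != 3L))
    stop("only triangular faces are supported")
  f <- do.call(rbind, lapply(fraw, function(r) r[2:4] + 1L))
  cortical_mesh(v, f)
}
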