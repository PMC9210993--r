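## Mesh geometry primitives: adjacency, areas, tangent frames, inflation,
## cross-subject coordinate averaging.

#' Vertex adjacency of a triangle mesh
#'
#' @param mesh a [TriangleMesh-class].
#' @return A list of length `nVertices(mesh)`; element `i` is the sorted
#'   integer vector of vertices sharing an edge with vertex `i`. The
#'   adjacency is symmetric and has no self-loops.
#' @export
vertexNeighbors <- function(mesh) {
    stopifnot(is(mesh, "TriangleMesh"))
    f <- meshFaces(mesh)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- rbind(e, e[, c(2, 1)])
    nb <- split(e[, 2], factor(e[, 1], levels = seq_len(nVertices(mesh))))
    lapply(nb, function(v) sort(unique(v)))
}

#' Triangle areas of a mesh
#'
#' @param mesh a [TriangleMesh-class].
#' @return numeric vector of face areas (mm^2).
#' @export
faceAreas <- function(mesh) {
    v <- meshVertices(mesh); f <- meshFaces(mesh)
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    cr <- .cross3(a, b)
    0.5 * sqrt(rowSums(cr * cr))
}

.cross3 <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-vertex surface area
#'
#' Each vertex receives one third of the summed areas of its incident
#' triangles, so the vertex areas conserve the total mesh area exactly.
#' Zero-area faces contribute nothing (with a warning).
#'
#' @param mesh a [TriangleMesh-class].
#' @return A [VertexScalarMap-class] of areas in mm^2, defined everywhere.
#' @export
vertexAreas <- function(mesh) {
    stopifnot(is(mesh, "TriangleMesh"))
    fa <- faceAreas(mesh)
    if (any(fa == 0)) warning("zero-area face(s) contribute no vertex area")
    f <- meshFaces(mesh)
    va <- numeric(nVertices(mesh))
    third <- rep(fa / 3, 3L)
    idx <- c(f[, 1], f[, 2], f[, 3])
    acc <- rowsum(third, idx)
    va[as.integer(rownames(acc))] <- acc[, 1]
    VertexScalarMap(va)
}

#' Per-vertex orthonormal tangent frames
#'
#' The vertex normal is the normalized area-weighted mean of incident face
#' normals; two unit tangents complete a right-handed frame
#' (`e1 x e2 = normal`). Every vertex must belong to at least one face.
#'
#' @param mesh a [TriangleMesh-class].
#' @return A [TangentFrame-class].
#' @export
tangentFrames <- function(mesh) {
    stopifnot(is(mesh, "TriangleMesh"))
    v <- meshVertices(mesh); f <- meshFaces(mesh)
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    cr <- .cross3(a, b)                 # |cr| = 2 * face area: area weighting
    n <- matrix(0, nVertices(mesh), 3L)
    for (k in 1:3) {
        acc <- rowsum(cr, f[, k])
        n[as.integer(rownames(acc)), ] <- n[as.integer(rownames(acc)), ] + acc
    }
    len <- sqrt(rowSums(n * n))
    if (any(len == 0))
        stop("isolated vertex (or degenerate normal) at index ",
             which(len == 0)[1])
    n <- n / len
    ## pick the global axis least aligned with each normal as the seed
    seed <- matrix(0, nrow(n), 3L)
    least <- max.col(-abs(n))
    seed[cbind(seq_len(nrow(n)), least)] <- 1
    e1 <- seed - n * rowSums(seed * n)
    e1 <- e1 / sqrt(rowSums(e1 * e1))
    e2 <- .cross3(n, e1)
    e2 <- e2 / sqrt(rowSums(e2 * e2))
    ## re-orthogonalize e1 so the validity tolerance (1e-9) holds exactly
    e1 <- .cross3(e2, n)
    e1 <- e1 / sqrt(rowSums(e1 * e1))
    new("TangentFrame", e1 = e1, e2 = e2, normal = .cross3(e1, e2))
}

#' Inflate a mesh by iterative neighbor-mean relaxation
#'
#' Each step moves every vertex toward the unweighted mean of its neighbors
#' by `stepWeight`, removing folding crinkles while leaving topology
#' unchanged. With `preserveArea = TRUE` (the default) every step rescales
#' the mesh about its centroid to conserve the total surface area, a
#' minimal stand-in for the metric-preserving terms of full inflation;
#' this is what makes the area already lost by averaging *folded* surfaces
#' observable after inflation. With `preserveArea = FALSE` the relaxation
#' is plain neighbor-mean smoothing and the total area is monotonically
#' non-increasing toward a shrinking convex limit.
#'
#' @param mesh a [TriangleMesh-class].
#' @param steps number of relaxation steps; `0` returns the mesh unchanged.
#' @param stepWeight relaxation weight in `(0, 1]`.
#' @param preserveArea rescale each step to conserve the total mesh area.
#' @return The inflated [TriangleMesh-class].
#' @export
inflateMesh <- function(mesh, steps, stepWeight = 0.5, preserveArea = TRUE) {
    stopifnot(is(mesh, "TriangleMesh"))
    steps <- as.integer(steps)
    if (steps < 0L) stop("steps must be >= 0")
    if (stepWeight <= 0 || stepWeight > 1)
        stop("stepWeight must lie in (0, 1]")
    if (steps == 0L) return(mesh)
    A <- .adjacencyMatrix(mesh, includeSelf = FALSE)
    deg <- Matrix::rowSums(A)
    v <- meshVertices(mesh)
    f <- meshFaces(mesh)
    a0 <- sum(faceAreas(mesh))
    for (s in seq_len(steps)) {
        v <- v + stepWeight * (as.matrix(A %*% v) / deg - v)
        if (preserveArea) {
            anew <- sum(faceAreas(TriangleMesh(v, f)))
            if (anew > 0) {
                ctr <- colMeans(v)
                v <- sweep(sweep(v, 2, ctr) * sqrt(a0 / anew), 2, ctr, `+`)
            }
        }
    }
    TriangleMesh(v, f)
}

.adjacencyMatrix <- function(mesh, includeSelf = FALSE) {
    f <- meshFaces(mesh)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- unique(rbind(e, e[, c(2, 1)]))
    if (includeSelf)
        e <- rbind(e, cbind(seq_len(nVertices(mesh)), seq_len(nVertices(mesh))))
    Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                         dims = rep(nVertices(mesh), 2L))
}

#' Average registered surfaces vertex-wise
#'
#' All meshes must share vertex count and an identical face list (same
#' topology, as for subjects registered to a common template). Coordinates
#' are averaged arithmetically; the face list is copied.
#'
#' @param meshes list of at least two [TriangleMesh-class] objects.
#' @return The average [TriangleMesh-class].
#' @export
averageSurfaces <- function(meshes) {
    if (!is.list(meshes) || length(meshes) < 2L)
        stop("need a list of at least two meshes")
    f0 <- meshFaces(meshes[[1]])
    n0 <- nVertices(meshes[[1]])
    for (m in meshes[-1]) {
        if (nVertices(m) != n0 || !identical(meshFaces(m), f0))
            stop("meshes differ in topology; cannot average coordinates")
    }
    v <- Reduce(`+`, lapply(meshes, meshVertices)) / length(meshes)
    TriangleMesh(v, f0)
}
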