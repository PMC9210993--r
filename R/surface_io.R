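## FreeSurfer binary triangle surface dialect: big-endian; 3-byte magic
## 0xFF 0xFF 0xFE; two newline-terminated comment lines; int32 vertex count,
## int32 face count; N x 3 float32 coordinates; M x 3 int32 0-based indices.

.SURF_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

#' Read a binary triangle surface file
#'
#' Reads the big-endian triangle-surface dialect (3-byte magic
#' `0xFF 0xFF 0xFE`, two newline-terminated comment lines, vertex and face
#' counts, float32 coordinates in mm, int32 0-based face indices). Indices
#' are converted to 1-based on read.
#'
#' @param path path to the surface file.
#' @return A [TriangleMesh-class].
#' @seealso [writeSurface()]
#' @export
readSurface <- function(path) {
    if (!file.exists(path)) stop("surface file does not exist: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", n = 3L)
    if (length(magic) < 3L || !identical(magic, .SURF_MAGIC))
        stop("not a triangle surface file (bad magic): ", path)
    for (i in 1:2) {                       # two comment lines
        repeat {
            ch <- readBin(con, "raw", n = 1L)
            if (length(ch) == 0L) stop("truncated surface file: ", path)
            if (ch == as.raw(0x0a)) break
        }
    }
    counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
    if (length(counts) < 2L) stop("truncated surface file: ", path)
    nv <- counts[1]; nf <- counts[2]
    if (nv <= 0L || nf <= 0L) stop("invalid vertex/face count in ", path)
    coords <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
    if (length(coords) < 3L * nv) stop("truncated vertex block in ", path)
    idx <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
    if (length(idx) < 3L * nf) stop("truncated face block in ", path)
    TriangleMesh(matrix(coords, nv, 3L, byrow = TRUE),
                 matrix(idx, nf, 3L, byrow = TRUE) + 1L)
}

#' Write a binary triangle surface file
#'
#' Inverse of [readSurface()]; `readSurface(writeSurface(mesh))` reproduces
#' the mesh exactly up to float32 coordinate precision.
#'
#' @param mesh a valid [TriangleMesh-class].
#' @param path output path.
#' @param comment first comment line written into the header.
#' @return `path`, invisibly.
#' @export
writeSurface <- function(mesh, path, comment = "created by topomapr") {
    stopifnot(is(mesh, "TriangleMesh"))
    validObject(mesh)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(.SURF_MAGIC, con)
    writeBin(charToRaw(paste0(comment, "\n\n")), con)
    writeBin(c(nVertices(mesh), nFaces(mesh)), con, size = 4L, endian = "big")
    writeBin(as.numeric(t(meshVertices(mesh))), con, size = 4L, endian = "big")
    writeBin(as.integer(t(meshFaces(mesh)) - 1L), con, size = 4L,
             endian = "big")
    invisible(path)
}
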