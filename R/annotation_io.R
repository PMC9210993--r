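## Binary annotation dialect (big-endian): int32 vertex count; per vertex
## int32 vertex-id (0-based) and int32 packed color; int32 colortable flag
## (1); int32 version (-2); int32 max entries; int32 filename length +
## bytes; int32 used entries; per entry: int32 structure id, int32 name
## length + bytes, int32 R, G, B, transparency (255 - A). Packed color 0 is
## the on-disk sentinel for unlabeled vertices.

#' Read a binary annotation file
#'
#' @param path path to the annotation file.
#' @param mesh the [TriangleMesh-class] the annotation belongs to; its
#'   vertex count must match the file.
#' @return An [Annotation-class]. Packed colors absent from the embedded
#'   table are read as unlabeled, with a warning.
#' @export
readAnnotation <- function(path, mesh) {
    if (!file.exists(path)) stop("annotation file does not exist: ", path)
    stopifnot(is(mesh, "TriangleMesh"))
    con <- file(path, "rb")
    on.exit(close(con))
    rdInt <- function(n = 1L) {
        v <- readBin(con, "integer", n = n, size = 4L, endian = "big")
        if (length(v) < n) stop("truncated annotation file: ", path)
        v
    }
    nv <- rdInt()
    if (nv != nVertices(mesh))
        stop("annotation has ", nv, " vertices but mesh has ",
             nVertices(mesh))
    block <- rdInt(2L * nv)
    packed <- block[seq.int(2L, 2L * nv, by = 2L)]
    flag <- rdInt()
    if (flag != 1L) stop("missing colortable block")
    version <- rdInt()
    if (version != -2L) stop("unsupported colortable version ", version)
    rdInt()                              # max entries (informational)
    fnLen <- rdInt()
    if (fnLen > 0L) readBin(con, "raw", n = fnLen)
    nUsed <- rdInt()
    rows <- vector("list", nUsed)
    for (i in seq_len(nUsed)) {
        id <- rdInt()
        nameLen <- rdInt()
        nm <- rawToChar(readBin(con, "raw", n = nameLen))
        rgba <- rdInt(4L)
        rows[[i]] <- data.frame(id = id, name = nm, R = rgba[1],
                                G = rgba[2], B = rgba[3],
                                A = 255L - rgba[4], modality = "none",
                                stringsAsFactors = FALSE)
    }
    lut <- ColorLookupTable(if (nUsed)
        do.call(rbind, rows)
    else data.frame(id = integer(), name = character(), R = integer(),
                    G = integer(), B = integer(), A = integer(),
                    modality = character()))
    known <- packedColors(lut)
    out <- packed
    out[out == 0L] <- NA_integer_
    orphan <- !is.na(out) & !(out %in% known)
    if (any(orphan)) {
        warning(sum(orphan),
                " vertex(es) carry a packed color absent from the ",
                "colortable; read as unlabeled")
        out[orphan] <- NA_integer_
    }
    Annotation(out, lut)
}

#' Write a binary annotation file
#'
#' Inverse of [readAnnotation()]; the per-vertex block round-trips
#' bit-for-bit.
#'
#' @param annot an [Annotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annot, path) {
    stopifnot(is(annot, "Annotation"))
    validObject(annot)
    e <- lutEntries(parcLut(annot))
    pk <- annotPacked(annot)
    pk[is.na(pk)] <- 0L
    con <- file(path, "wb")
    on.exit(close(con))
    wInt <- function(v) writeBin(as.integer(v), con, size = 4L,
                                 endian = "big")
    nv <- length(pk)
    wInt(nv)
    block <- integer(2L * nv)
    block[seq.int(1L, 2L * nv, by = 2L)] <- seq_len(nv) - 1L
    block[seq.int(2L, 2L * nv, by = 2L)] <- pk
    wInt(block)
    wInt(1L)                             # colortable present
    wInt(-2L)                            # version
    wInt(nrow(e))                        # max entries
    fn <- charToRaw("topomapr.ctab")
    wInt(length(fn)); writeBin(fn, con)
    wInt(nrow(e))                        # used entries
    for (i in seq_len(nrow(e))) {
        wInt(e$id[i])
        nm <- charToRaw(e$name[i])
        wInt(length(nm)); writeBin(nm, con)
        wInt(c(e$R[i], e$G[i], e$B[i], 255L - e$A[i]))
    }
    invisible(path)
}

#' Translate a parcellation to an annotation and back
#'
#' The translation label id to packed color goes through the LUT and is
#' bijective, so `annotationToParcellation(parcellationToAnnotation(p))`
#' recovers `p` exactly.
#'
#' @param parc a [Parcellation-class].
#' @return An [Annotation-class].
#' @export
parcellationToAnnotation <- function(parc) {
    stopifnot(is(parc, "Parcellation"))
    validObject(parc)
    e <- lutEntries(parcLut(parc))
    lab <- regionLabels(parc)
    packed <- rep(NA_integer_, length(lab))
    pos <- match(lab[lab > 0L], e$id)
    if (anyNA(pos)) stop("label id missing from LUT")
    packed[lab > 0L] <- packedColors(parcLut(parc))[pos]
    Annotation(packed, parcLut(parc))
}

#' @rdname parcellationToAnnotation
#' @param annot an [Annotation-class].
#' @return A [Parcellation-class].
#' @export
annotationToParcellation <- function(annot) {
    stopifnot(is(annot, "Annotation"))
    lut <- parcLut(annot)
    pk <- annotPacked(annot)
    lab <- integer(length(pk))
    pos <- match(pk[!is.na(pk)], packedColors(lut))
    if (anyNA(pos)) stop("packed color missing from LUT")
    lab[!is.na(pk)] <- lutEntries(lut)$id[pos]
    Parcellation(lab, lut)
}

#' Resample labels between registered spherical meshes
#'
#' Each destination vertex takes the label of the nearest source vertex by
#' great-circle distance on the common registration sphere (ties broken by
#' the lowest source index). The label set is preserved or reduced, never
#' invented. Both meshes must be spherical (radial deviation at most 1% of
#' the mean radius).
#'
#' @param srcAnnot the source [Annotation-class].
#' @param srcRegistered,dstRegistered registered spherical
#'   [TriangleMesh-class] objects for source and destination subjects.
#' @return An [Annotation-class] on the destination mesh.
#' @export
resampleLabels <- function(srcAnnot, srcRegistered, dstRegistered) {
    stopifnot(is(srcAnnot, "Annotation"),
              is(srcRegistered, "TriangleMesh"),
              is(dstRegistered, "TriangleMesh"))
    if (length(annotPacked(srcAnnot)) != nVertices(srcRegistered))
        stop("annotation does not match the source mesh")
    sphereCheck <- function(mesh, label) {
        v <- meshVertices(mesh)
        r <- sqrt(rowSums(v * v))
        if ((max(r) - min(r)) > 0.01 * mean(r) * 2)
            stop(label, " mesh is not spherical (radial deviation > 1%)")
        v / r
    }
    us <- sphereCheck(srcRegistered, "source")
    ud <- sphereCheck(dstRegistered, "destination")
    ## nearest on the sphere = max dot product; chunked brute force.
    ## Ties (e.g. midpoints of a subdivided mesh) go to the lowest source
    ## index; the tie comparison uses a small tolerance so that floating
    ## point noise cannot flip it.
    nd <- nrow(ud)
    nearest <- integer(nd)
    chunk <- max(1L, floor(4e6 / nrow(us)))
    for (start in seq.int(1L, nd, by = chunk)) {
        idx <- start:min(nd, start + chunk - 1L)
        dots <- ud[idx, , drop = FALSE] %*% t(us)
        best <- apply(dots, 1L, function(d)
            which(d >= max(d) - 1e-12)[1])
        nearest[idx] <- best
    }
    Annotation(annotPacked(srcAnnot)[nearest], parcLut(srcAnnot))
}

#' Export an annotation as JSON
#'
#' Writes the label content (region id, name, rgb, alpha, modality, and
#' per-vertex region ids with 0 for unlabeled) as a JSON document, the
#' package's interchange substitute for XML label formats.
#'
#' @param annot an [Annotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportLabelsJSON <- function(annot, path) {
    stopifnot(is(annot, "Annotation"))
    parc <- annotationToParcellation(annot)
    e <- lutEntries(parcLut(annot))
    doc <- list(
        regions = data.frame(id = e$id, name = e$name, R = e$R, G = e$G,
                             B = e$B, A = e$A, modality = e$modality,
                             stringsAsFactors = FALSE),
        vertex_region_id = regionLabels(parc))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
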