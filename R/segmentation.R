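## Connected-component segmentation of field-sign maps into labeled areas.

#' Segment a field-sign map into labeled areas
#'
#' Finds edge-connected components of constant nonzero field sign within
#' the significance mask. Components smaller than `minAreaMm2` or with a
#' circular phase range below `minPhaseRangeRad` (the "range of response
#' phases" an accepted map must include) are discarded. Surviving
#' components receive consecutive ids ordered by decreasing surface area,
#' ties broken by the lowest contained vertex index; an empty parcellation
#' is a valid result.
#'
#' @param fieldsign a [FieldSignMap-class].
#' @param mask logical per-vertex significance mask (or a
#'   [VertexScalarMap-class] of 0/1).
#' @param mesh the [TriangleMesh-class].
#' @param minAreaMm2 minimum component surface area (mm^2).
#' @param minPhaseRangeRad minimum circular range of response phase within
#'   a component (rad).
#' @param phase a [ComplexMapResult-class] supplying the response phases.
#' @return A [Parcellation-class] with a generated color table (one entry
#'   per area, modality `"none"`).
#' @export
segmentFieldsign <- function(fieldsign, mask, mesh, minAreaMm2 = 25,
                             minPhaseRangeRad = pi / 4, phase) {
    stopifnot(is(fieldsign, "FieldSignMap"), is(mesh, "TriangleMesh"),
              is(phase, "ComplexMapResult"))
    if (is(mask, "VertexScalarMap"))
        mask <- mapMask(mask) & !is.na(mapValues(mask)) & mapValues(mask) != 0
    mask <- as.logical(mask)
    n <- nVertices(mesh)
    s <- fieldSign(fieldsign)
    if (length(s) != n || length(mask) != n)
        stop("inputs not aligned to mesh")
    eligible <- mask & s != 0L
    ## edge-connected components among same-sign eligible vertices
    f <- meshFaces(mesh)
    e <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
                      f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)]))
    keep <- eligible[e[, 1]] & eligible[e[, 2]] & s[e[, 1]] == s[e[, 2]]
    e <- e[keep, , drop = FALSE]
    comp <- integer(n)
    nComp <- 0L
    adj <- split(e[, 2], factor(e[, 1], levels = seq_len(n)))
    for (start in which(eligible)) {
        if (comp[start] != 0L) next
        nComp <- nComp + 1L
        queue <- start
        comp[start] <- nComp
        while (length(queue)) {
            i <- queue[[1]]; queue <- queue[-1]
            js <- adj[[i]]
            js <- js[comp[js] == 0L]
            comp[js] <- nComp
            queue <- c(queue, js)
        }
    }
    va <- mapValues(vertexAreas(mesh))
    phi <- phaseRad(phase)
    survivors <- list()
    for (cid in seq_len(nComp)) {
        idx <- which(comp == cid)
        area <- sum(va[idx])
        if (area < minAreaMm2) next
        if (.circularRange(phi[idx][!is.na(phi[idx])]) < minPhaseRangeRad)
            next
        survivors[[length(survivors) + 1L]] <-
            list(idx = idx, area = area, minV = min(idx))
    }
    labels <- integer(n)
    if (length(survivors)) {
        areaV <- vapply(survivors, `[[`, numeric(1), "area")
        minV <- vapply(survivors, `[[`, numeric(1), "minV")
        ord <- order(-areaV, minV)
        for (rank in seq_along(ord))
            labels[survivors[[ord[rank]]]$idx] <- rank
    }
    Parcellation(labels, .autoLut(max(labels)))
}

## circular range: 2*pi minus the largest gap between sorted phases
.circularRange <- function(phi) {
    if (length(phi) < 2L) return(0)
    sp <- sort(.wrapPi(phi))
    gaps <- c(diff(sp), sp[1] + 2 * pi - sp[length(sp)])
    2 * pi - max(gaps)
}

## deterministic distinct colors for machine-generated parcellations
.autoLut <- function(nLabels) {
    if (nLabels == 0L)
        return(ColorLookupTable(data.frame(id = integer(), name = character(),
                                           R = integer(), G = integer(),
                                           B = integer(), A = integer(),
                                           modality = character())))
    hue <- (seq_len(nLabels) - 1) / max(nLabels, 1)
    col <- t(grDevices::col2rgb(grDevices::hsv(hue * 0.85, 0.75, 0.95)))
    ## nudge collisions (quantization) to keep packed colors unique
    repeat {
        packed <- col[, 1] + col[, 2] * 256 + col[, 3] * 65536
        dup <- duplicated(packed) | packed == 0
        if (!any(dup)) break
        col[dup, 1] <- (col[dup, 1] + seq_len(sum(dup))) %% 256L
    }
    ColorLookupTable(data.frame(
        id = seq_len(nLabels),
        name = sprintf("area_%03d", seq_len(nLabels)),
        R = col[, 1], G = col[, 2], B = col[, 3], A = 255L,
        modality = "none", stringsAsFactors = FALSE))
}

#' Area coverage of a parcellation
#'
#' @param parc a [Parcellation-class].
#' @param areas per-vertex areas from [vertexAreas()].
#' @return list with `perLabel` (named fractions of total mesh area) and
#'   `total` (labeled fraction, `sum(perLabel)`, at most 1).
#' @export
areaCoverage <- function(parc, areas) {
    stopifnot(is(parc, "Parcellation"), is(areas, "VertexScalarMap"))
    lab <- regionLabels(parc)
    va <- mapValues(areas)
    if (length(lab) != length(va)) stop("inputs not aligned")
    tot <- sum(va)
    ids <- sort(unique(lab[lab > 0L]))
    per <- vapply(ids, function(i) sum(va[lab == i]) / tot, numeric(1))
    names(per) <- as.character(ids)
    list(perLabel = per, total = sum(per))
}
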