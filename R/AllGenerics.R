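## Generics and accessors. Slots are never touched directly by user code.

#' @rdname TriangleMesh-class
#' @param object,x a `TriangleMesh`.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname TriangleMesh-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname TriangleMesh-class
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname TriangleMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname TriangleMesh-class
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname TriangleMesh-class
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))
#' @rdname TriangleMesh-class
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
#' @rdname TriangleMesh-class
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

setMethod("show", "TriangleMesh", function(object) {
    cat(sprintf("TriangleMesh: %d vertices, %d faces, total area %.3f mm^2\n",
                nVertices(object), nFaces(object),
                sum(faceAreas(object))))
})

#' @rdname VertexScalarMap-class
#' @param x a `VertexScalarMap`.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname VertexScalarMap-class
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))
#' @rdname VertexScalarMap-class
#' @export
setMethod("mapValues", "VertexScalarMap", function(x) x@values)
#' @rdname VertexScalarMap-class
#' @export
setMethod("mapMask", "VertexScalarMap", function(x) x@mask)
setMethod("length", "VertexScalarMap", function(x) length(x@values))

setMethod("show", "VertexScalarMap", function(object) {
    cat(sprintf("VertexScalarMap: %d vertices (%d defined)\n",
                length(object@values), sum(object@mask)))
})

#' @rdname TangentFrame-class
#' @param x a `TangentFrame`.
#' @param which one of `"e1"`, `"e2"`, `"normal"`.
#' @export
setGeneric("frameVectors", function(x, which = "normal")
    standardGeneric("frameVectors"))
#' @rdname TangentFrame-class
#' @export
setMethod("frameVectors", "TangentFrame", function(x, which = "normal")
    slot(x, match.arg(which, c("e1", "e2", "normal"))))

setMethod("show", "TangentFrame", function(object) {
    cat(sprintf("TangentFrame: %d vertices\n", nrow(object@e1)))
})

#' @rdname RunTimeSeries-class
#' @param x a `RunTimeSeries`.
#' @export
setGeneric("runData", function(x) standardGeneric("runData"))
#' @rdname RunTimeSeries-class
#' @export
setMethod("runData", "RunTimeSeries", function(x) x@data)
#' @rdname RunTimeSeries-class
#' @export
setGeneric("runDirection", function(x) standardGeneric("runDirection"))
#' @rdname RunTimeSeries-class
#' @export
setMethod("runDirection", "RunTimeSeries", function(x) x@direction)
#' @rdname RunTimeSeries-class
#' @export
setGeneric("runCycles", function(x) standardGeneric("runCycles"))
#' @rdname RunTimeSeries-class
#' @export
setMethod("runCycles", "RunTimeSeries", function(x) x@nCycles)
#' @rdname RunTimeSeries-class
#' @export
setGeneric("runTr", function(x) standardGeneric("runTr"))
#' @rdname RunTimeSeries-class
#' @export
setMethod("runTr", "RunTimeSeries", function(x) x@trS)

setMethod("show", "RunTimeSeries", function(object) {
    cat(sprintf(
        "RunTimeSeries: %d vertices x %d volumes, TR %.3g s, %d cycles, %s, %s\n",
        nrow(object@data), ncol(object@data), object@trS, object@nCycles,
        if (object@direction > 0) "forward" else "reversed", object@modality))
})

#' @rdname ComplexMapResult-class
#' @param x a `ComplexMapResult`.
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @rdname ComplexMapResult-class
#' @export
setMethod("amplitude", "ComplexMapResult", function(x) Mod(x@coef))
#' @rdname ComplexMapResult-class
#' @export
setGeneric("phaseRad", function(x) standardGeneric("phaseRad"))
#' @rdname ComplexMapResult-class
#' @export
setMethod("phaseRad", "ComplexMapResult", function(x) {
    ph <- Arg(x@coef)
    ## map -pi to +pi so phases live in (-pi, pi]
    ph[!is.na(ph) & ph <= -pi] <- pi
    ph
})
#' @rdname ComplexMapResult-class
#' @export
setGeneric("fStat", function(x) standardGeneric("fStat"))
#' @rdname ComplexMapResult-class
#' @export
setMethod("fStat", "ComplexMapResult", function(x) x@fStat)
#' @rdname ComplexMapResult-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname ComplexMapResult-class
#' @export
setMethod("pValues", "ComplexMapResult", function(x) x@pValue)
#' @rdname ComplexMapResult-class
#' @export
setGeneric("mapCoef", function(x) standardGeneric("mapCoef"))
#' @rdname ComplexMapResult-class
#' @export
setMethod("mapCoef", "ComplexMapResult", function(x) x@coef)
#' @rdname ComplexMapResult-class
#' @export
setGeneric("dofF", function(x) standardGeneric("dofF"))
#' @rdname ComplexMapResult-class
#' @export
setMethod("dofF", "ComplexMapResult", function(x) x@dof)
#' @rdname ComplexMapResult-class
#' @export
setMethod("mapMask", "ComplexMapResult", function(x) x@mask)

setMethod("show", "ComplexMapResult", function(object) {
    cat(sprintf(
        "ComplexMapResult: %d vertices (%d defined), dof (%g, %g), %d run(s)\n",
        length(object@coef), sum(object@mask), object@dof[1], object@dof[2],
        object@nRuns))
})

#' @rdname GradientField-class
#' @param x a `GradientField`.
#' @export
setGeneric("gradients", function(x) standardGeneric("gradients"))
#' @rdname GradientField-class
#' @export
setMethod("gradients", "GradientField", function(x) cbind(gx = x@gx, gy = x@gy))
#' @rdname GradientField-class
#' @export
setGeneric("gradientValid", function(x) standardGeneric("gradientValid"))
#' @rdname GradientField-class
#' @export
setMethod("gradientValid", "GradientField", function(x) x@valid)

setMethod("show", "GradientField", function(object) {
    cat(sprintf("GradientField: %d vertices (%d valid)\n",
                length(object@gx), sum(object@valid)))
})

#' @rdname FieldSignMap-class
#' @param x a `FieldSignMap`.
#' @export
setGeneric("fieldSign", function(x) standardGeneric("fieldSign"))
#' @rdname FieldSignMap-class
#' @export
setMethod("fieldSign", "FieldSignMap", function(x) x@sign)

setMethod("show", "FieldSignMap", function(object) {
    s <- object@sign
    cat(sprintf("FieldSignMap: %d mirror, %d non-mirror, %d undefined\n",
                sum(s == -1L), sum(s == 1L), sum(s == 0L)))
})

#' @rdname ColorLookupTable-class
#' @param x a `ColorLookupTable`.
#' @export
setGeneric("lutEntries", function(x) standardGeneric("lutEntries"))
#' @rdname ColorLookupTable-class
#' @export
setMethod("lutEntries", "ColorLookupTable", function(x) x@entries)
setMethod("length", "ColorLookupTable", function(x) nrow(x@entries))

#' Packed RGB colors of a color table
#'
#' The packing formula is `R + G*2^8 + B*2^16`.
#' @param lut a [ColorLookupTable-class].
#' @return integer vector of packed colors, one per entry.
#' @export
packedColors <- function(lut) {
    e <- lutEntries(lut)
    as.integer(e$R + e$G * 256 + e$B * 65536)
}

setMethod("show", "ColorLookupTable", function(object) {
    cat(sprintf("ColorLookupTable: %d entries\n", nrow(object@entries)))
    tab <- table(factor(object@entries$modality, levels = .lutModalities))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname Parcellation-class
#' @param x a `Parcellation`.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname Parcellation-class
#' @export
setMethod("regionLabels", "Parcellation", function(x) x@labels)
#' @rdname Parcellation-class
#' @export
setGeneric("parcLut", function(x) standardGeneric("parcLut"))
#' @rdname Parcellation-class
#' @export
setMethod("parcLut", "Parcellation", function(x) x@lut)

setMethod("show", "Parcellation", function(object) {
    lab <- object@labels
    cat(sprintf("Parcellation: %d vertices, %d labeled, %d region(s)\n",
                length(lab), sum(lab > 0L), length(unique(lab[lab > 0L]))))
})

#' @rdname Annotation-class
#' @param x an `Annotation`.
#' @export
setGeneric("annotPacked", function(x) standardGeneric("annotPacked"))
#' @rdname Annotation-class
#' @export
setMethod("annotPacked", "Annotation", function(x) x@packed)
#' @rdname Annotation-class
#' @export
setMethod("parcLut", "Annotation", function(x) x@lut)

setMethod("show", "Annotation", function(object) {
    cat(sprintf("Annotation: %d vertices (%d labeled), %d table entries\n",
                length(object@packed), sum(!is.na(object@packed)),
                nrow(object@lut@entries)))
})

#' @rdname GroundTruthMapSpec-class
#' @param x a `GroundTruthMapSpec`.
#' @param coordinate `"primary"` (polar angle / 1D coordinate) or
#'   `"secondary"` (eccentricity).
#' @export
setGeneric("truePhase", function(x, coordinate = "primary")
    standardGeneric("truePhase"))
#' @rdname GroundTruthMapSpec-class
#' @export
setMethod("truePhase", "GroundTruthMapSpec", function(x, coordinate = "primary")
    switch(match.arg(coordinate, c("primary", "secondary")),
           primary = x@phase1, secondary = x@phase2))
#' @rdname GroundTruthMapSpec-class
#' @export
setGeneric("trueAreas", function(x) standardGeneric("trueAreas"))
#' @rdname GroundTruthMapSpec-class
#' @export
setMethod("trueAreas", "GroundTruthMapSpec", function(x) x@areaId)
#' @rdname GroundTruthMapSpec-class
#' @export
setGeneric("trueFieldSign", function(x) standardGeneric("trueFieldSign"))
#' @rdname GroundTruthMapSpec-class
#' @export
setMethod("trueFieldSign", "GroundTruthMapSpec", function(x) x@fieldSign)

setMethod("show", "GroundTruthMapSpec", function(object) {
    cat(sprintf("GroundTruthMapSpec (%s): %d vertices, %d area(s)\n",
                object@kind, length(object@phase1),
                length(unique(object@areaId[object@areaId > 0L]))))
})
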