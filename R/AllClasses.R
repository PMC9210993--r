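#' @import methods
#' @importFrom stats pf optim rnorm runif sd median fft complete.cases
#' @importFrom grDevices hsv rgb2hsv
#' @importFrom utils head tail
NULL

## Central S4 classes. Vertex indices are 1-based internally (R convention)
## and converted to the 0-based on-disk convention at file boundaries.

#' TriangleMesh: a triangular surface mesh
#'
#' The geometric substrate for all per-vertex maps: `N` vertex coordinates in
#' mm and `M` consistently oriented triangles. Validity enforces in-range,
#' non-degenerate faces, edge-manifoldness (each edge shared by at most two
#' faces) and orientation consistency (adjacent faces traverse their shared
#' edge in opposite directions, so each directed edge occurs at most once).
#'
#' @slot vertices numeric `N x 3` matrix of coordinates (mm).
#' @slot faces integer `M x 3` matrix of 1-based vertex indices.
#' @export
setClass("TriangleMesh",
    representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
    v <- object@vertices; f <- object@faces
    if (!is.numeric(v) || ncol(v) != 3L)
        return("'vertices' must be a numeric N x 3 matrix")
    if (nrow(v) < 3L) return("mesh must have at least 3 vertices")
    if (!is.numeric(f) || ncol(f) != 3L)
        return("'faces' must be an integer M x 3 matrix")
    if (nrow(f) < 1L) return("mesh must have at least 1 face")
    if (anyNA(v) || anyNA(f)) return("NA in vertices or faces")
    if (any(f != round(f))) return("face indices must be integers")
    if (any(f < 1L) || any(f > nrow(v)))
        return("face index out of range [1, N]")
    deg <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(deg))
        return(sprintf("degenerate face (repeated vertex) at row %d",
                       which(deg)[1]))
    ## directed edges: orientation consistency <=> each occurs at most once;
    ## edge-manifold <=> each undirected edge occurs at most twice.
    de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- (de[, 1] - 1) * as.double(nrow(v)) + (de[, 2] - 1)
    if (anyDuplicated(key))
        return("orientation inconsistency: a directed edge occurs twice")
    ue <- cbind(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
    ukey <- (ue[, 1] - 1) * as.double(nrow(v)) + (ue[, 2] - 1)
    if (max(tabulate(match(ukey, unique(ukey)))) > 2L)
        return("non-manifold edge shared by more than two faces")
    TRUE
})

#' Construct a TriangleMesh
#'
#' @param vertices numeric `N x 3` matrix of vertex coordinates in mm.
#' @param faces `M x 3` matrix of vertex indices, 1-based, consistently
#'   oriented (counterclockwise seen from outside/above).
#' @return A [TriangleMesh-class] object.
#' @examples
#' m <- TriangleMesh(diag(3), matrix(c(1, 2, 3), 1))
#' nVertices(m)
#' @export
TriangleMesh <- function(vertices, faces) {
    vertices <- as.matrix(vertices)
    storage.mode(vertices) <- "double"
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    dimnames(vertices) <- NULL; dimnames(faces) <- NULL
    new("TriangleMesh", vertices = vertices, faces = faces)
}

#' VertexScalarMap: per-vertex scalar values with a definedness mask
#'
#' Undefined vertices carry `mask = FALSE` (their value is `NA`), never a
#' silent zero.
#'
#' @slot values numeric per-vertex values.
#' @slot mask logical; `TRUE` where the value is defined.
#' @export
setClass("VertexScalarMap",
    representation(values = "numeric", mask = "logical"))

setValidity("VertexScalarMap", function(object) {
    if (length(object@values) != length(object@mask))
        return("'values' and 'mask' lengths differ")
    if (anyNA(object@mask)) return("mask must not contain NA")
    if (any(!is.na(object@values[!object@mask])) &&
        any(!object@mask))
        return("undefined vertices must carry NA values, not numbers")
    TRUE
})

#' @rdname VertexScalarMap-class
#' @param values,mask see slots.
#' @export
VertexScalarMap <- function(values, mask = !is.na(values)) {
    values <- as.numeric(values)
    values[!mask] <- NA_real_
    new("VertexScalarMap", values = values, mask = as.logical(mask))
}

#' TangentFrame: per-vertex orthonormal tangent basis plus normal
#'
#' For each vertex, `e1`, `e2` span the tangent plane and `normal` completes
#' a right-handed orthonormal frame (`e1 x e2 = normal`).
#'
#' @slot e1,e2,normal numeric `N x 3` matrices of unit vectors.
#' @export
setClass("TangentFrame",
    representation(e1 = "matrix", e2 = "matrix", normal = "matrix"))

setValidity("TangentFrame", function(object) {
    n <- nrow(object@e1)
    if (nrow(object@e2) != n || nrow(object@normal) != n)
        return("frame component row counts differ")
    tol <- 1e-9
    unit <- function(m) abs(rowSums(m * m) - 1) < tol
    if (!all(unit(object@e1) & unit(object@e2) & unit(object@normal)))
        return("frame vectors must be unit length (1e-9)")
    if (any(abs(rowSums(object@e1 * object@e2)) > tol))
        return("e1 and e2 must be orthogonal (1e-9)")
    cr <- cbind(
        object@e1[, 2] * object@e2[, 3] - object@e1[, 3] * object@e2[, 2],
        object@e1[, 3] * object@e2[, 1] - object@e1[, 1] * object@e2[, 3],
        object@e1[, 1] * object@e2[, 2] - object@e1[, 2] * object@e2[, 1])
    if (any(abs(cr - object@normal) > 1e-9))
        return("frame must be right-handed: e1 x e2 = normal (1e-9)")
    TRUE
})

#' RunTimeSeries: one phase-encoded scan
#'
#' Per-vertex periodic response matrix for a single run, with stimulus-cycle
#' and direction metadata. `T` must be an integer multiple of `nCycles`, and
#' at least two stimulus cycles are required.
#'
#' @slot data numeric `N x T` matrix (signal units, arbitrary).
#' @slot trS sampling interval in seconds.
#' @slot nCycles integer number of stimulus cycles in the run.
#' @slot direction `+1` for forward stimulus order, `-1` for time-reversed.
#' @slot modality one of `"visual"`, `"auditory"`, `"somatomotor"`.
#' @export
setClass("RunTimeSeries",
    representation(data = "matrix", trS = "numeric", nCycles = "integer",
                   direction = "integer", modality = "character"))

setValidity("RunTimeSeries", function(object) {
    Tt <- ncol(object@data)
    if (object@trS <= 0) return("trS must be positive")
    if (object@nCycles < 2L) return("nCycles must be >= 2")
    if (Tt %% object@nCycles != 0L)
        return("T must be an integer multiple of nCycles")
    if (!(object@direction %in% c(-1L, 1L)))
        return("direction must be +1 or -1")
    if (!(object@modality %in% c("visual", "auditory", "somatomotor")))
        return("modality must be visual, auditory or somatomotor")
    TRUE
})

#' @rdname RunTimeSeries-class
#' @param data,trS,nCycles,direction,modality see slots.
#' @export
RunTimeSeries <- function(data, trS, nCycles, direction = 1L,
                          modality = "visual") {
    data <- as.matrix(data); storage.mode(data) <- "double"
    new("RunTimeSeries", data = data, trS = as.numeric(trS),
        nCycles = as.integer(nCycles), direction = as.integer(direction),
        modality = modality)
}

#' ComplexMapResult: per-vertex phase-encoded response statistics
#'
#' Holds, per vertex, the complex response at the stimulus frequency
#' (amplitude times unit phase vector -- phase is stored as a complex number
#' so that averaging never suffers wrap artifacts), the F statistic against
#' the noise band or across subjects, its degrees of freedom, and p-values.
#' `Inf` F with `p = 0` is the legitimate zero-dispersion sentinel.
#'
#' @slot coef complex per-vertex response coefficient.
#' @slot fStat non-negative per-vertex F statistics (`Inf` allowed).
#' @slot dof numeric length-2 degrees of freedom of the F statistic.
#' @slot pValue per-vertex p-values in `[0, 1]`.
#' @slot mask logical; `FALSE` where the statistic is undefined.
#' @slot nRuns number of runs (or subjects) combined into this map.
#' @export
setClass("ComplexMapResult",
    representation(coef = "complex", fStat = "numeric", dof = "numeric",
                   pValue = "numeric", mask = "logical", nRuns = "integer"))

setValidity("ComplexMapResult", function(object) {
    n <- length(object@coef)
    if (length(object@fStat) != n || length(object@pValue) != n ||
        length(object@mask) != n)
        return("per-vertex slot lengths differ")
    if (length(object@dof) != 2L) return("dof must have length 2")
    ok <- object@mask
    if (any(object@fStat[ok] < 0, na.rm = TRUE))
        return("F statistics must be non-negative")
    if (any(object@pValue[ok] < 0 | object@pValue[ok] > 1, na.rm = TRUE))
        return("p-values must lie in [0, 1]")
    TRUE
})

ComplexMapResult <- function(coef, fStat, dof, pValue, mask, nRuns = 1L) {
    coef[!mask] <- NA_complex_
    fStat[!mask] <- NA_real_
    pValue[!mask] <- NA_real_
    new("ComplexMapResult", coef = as.complex(coef),
        fStat = as.numeric(fStat), dof = as.numeric(dof),
        pValue = as.numeric(pValue), mask = as.logical(mask),
        nRuns = as.integer(nRuns))
}

#' ProtocolConfig: scanning protocol parameters
#'
#' Defaults mirror a typical multiband phase-encoded protocol: TR 1 s,
#' 512 volumes per scan, 4 scans per modality over 3 modalities, 8 stimulus
#' cycles per scan (64-s period), a 5-s shift applied when combining
#' direction-reversed runs, and a 0.05 significance level.
#'
#' @slot trS repetition time (s).
#' @slot volumesPerScan volumes acquired per scan.
#' @slot scansPerModality scans per modality (forward + reversed).
#' @slot nModalities number of mapped modalities.
#' @slot nCycles stimulus cycles per scan.
#' @slot delayShiftS seconds subtracted from every run's timing when
#'   combining reversed runs, compensating the mean hemodynamic delay.
#' @slot alpha significance level for masks.
#' @export
setClass("ProtocolConfig",
    representation(trS = "numeric", volumesPerScan = "integer",
                   scansPerModality = "integer", nModalities = "integer",
                   nCycles = "integer", delayShiftS = "numeric",
                   alpha = "numeric"))

setValidity("ProtocolConfig", function(object) {
    if (object@trS <= 0 || object@volumesPerScan <= 0 ||
        object@scansPerModality <= 0 || object@nModalities <= 0 ||
        object@nCycles <= 0 || object@delayShiftS < 0 ||
        object@alpha <= 0 || object@alpha >= 1)
        return("all protocol fields must be positive (alpha in (0,1))")
    period <- object@volumesPerScan * object@trS / object@nCycles
    if (object@delayShiftS >= period)
        return("delayShiftS must be smaller than one stimulus period")
    TRUE
})

#' @rdname ProtocolConfig-class
#' @param trS,volumesPerScan,scansPerModality,nModalities,nCycles,delayShiftS,alpha
#'   see slots.
#' @export
ProtocolConfig <- function(trS = 1, volumesPerScan = 512L,
                           scansPerModality = 4L, nModalities = 3L,
                           nCycles = 8L, delayShiftS = 5, alpha = 0.05) {
    new("ProtocolConfig", trS = as.numeric(trS),
        volumesPerScan = as.integer(volumesPerScan),
        scansPerModality = as.integer(scansPerModality),
        nModalities = as.integer(nModalities),
        nCycles = as.integer(nCycles),
        delayShiftS = as.numeric(delayShiftS), alpha = as.numeric(alpha))
}

#' CohortSpec: multi-subject simulation parameters
#'
#' @slot nSubjects number of simulated subjects.
#' @slot jitterSd s.d. (rad) of the smooth per-subject phase offset field
#'   emulating cross-subject map misalignment.
#' @slot noiseSd white innovation s.d. of the AR(1) noise (signal units).
#' @slot noiseAr1 lag-1 autocorrelation of the noise.
#' @slot delayMeanS,delaySdS hemodynamic delay mean and across-subject s.d. (s).
#' @slot amplitude response amplitude at stimulated vertices (signal units).
#' @slot seed mandatory base random seed; all run-level seeds derive from it.
#' @export
setClass("CohortSpec",
    representation(nSubjects = "integer", jitterSd = "numeric",
                   noiseSd = "numeric", noiseAr1 = "numeric",
                   delayMeanS = "numeric", delaySdS = "numeric",
                   amplitude = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
    if (object@nSubjects < 1L) return("nSubjects must be >= 1")
    if (object@jitterSd < 0 || object@noiseSd < 0 || object@delaySdS < 0)
        return("dispersions must be >= 0")
    if (abs(object@noiseAr1) >= 1) return("noiseAr1 must lie in (-1, 1)")
    if (is.na(object@seed)) return("seed is mandatory")
    TRUE
})

#' @rdname CohortSpec-class
#' @param nSubjects,jitterSd,noiseSd,noiseAr1,delayMeanS,delaySdS,amplitude,seed
#'   see slots.
#' @export
CohortSpec <- function(nSubjects = 6L, jitterSd = 0, noiseSd = 1,
                       noiseAr1 = 0.3, delayMeanS = 5, delaySdS = 0,
                       amplitude = 1, seed) {
    if (missing(seed)) stop("CohortSpec requires an explicit seed")
    new("CohortSpec", nSubjects = as.integer(nSubjects),
        jitterSd = as.numeric(jitterSd), noiseSd = as.numeric(noiseSd),
        noiseAr1 = as.numeric(noiseAr1), delayMeanS = as.numeric(delayMeanS),
        delaySdS = as.numeric(delaySdS), amplitude = as.numeric(amplitude),
        seed = as.integer(seed))
}

#' GradientField: tangential phase gradients
#'
#' Per-vertex 2D gradient of map phase, in rad/mm, expressed in each
#' vertex's [TangentFrame-class] (`gx` along `e1`, `gy` along `e2`).
#'
#' @slot gx,gy numeric per-vertex tangent components (rad/mm).
#' @slot valid logical validity mask.
#' @export
setClass("GradientField",
    representation(gx = "numeric", gy = "numeric", valid = "logical"))

setValidity("GradientField", function(object) {
    n <- length(object@gx)
    if (length(object@gy) != n || length(object@valid) != n)
        return("slot lengths differ")
    if (any(!is.finite(object@gx[object@valid])) ||
        any(!is.finite(object@gy[object@valid])))
        return("valid gradients must be finite")
    TRUE
})

#' FieldSignMap: mirror / non-mirror visual field sign
#'
#' Per-vertex value in `{-1, +1, 0}`: `-1` mirror-image, `+1`
#' non-mirror-image, `0` undefined (gradient missing or below the
#' magnitude floor).
#'
#' @slot sign integer per-vertex field sign.
#' @export
setClass("FieldSignMap", representation(sign = "integer"))

setValidity("FieldSignMap", function(object) {
    if (!all(object@sign %in% c(-1L, 0L, 1L)))
        return("field sign values must be in {-1, 0, 1}")
    TRUE
})

#' ColorLookupTable: named, colored, modality-tagged regions
#'
#' Ordered table of `(id, name, R, G, B, A, modality)` entries. Region ids,
#' names and packed colors (`R + G*2^8 + B*2^16`) must each be unique --
#' packed-color uniqueness is what makes annotation decoding well defined.
#'
#' @slot entries data.frame with columns `id`, `name`, `R`, `G`, `B`, `A`,
#'   `modality` (one of visual, auditory, somatosensory, motor, none).
#' @export
setClass("ColorLookupTable", representation(entries = "data.frame"))

.lutModalities <- c("visual", "auditory", "somatosensory", "motor", "none")

setValidity("ColorLookupTable", function(object) {
    e <- object@entries
    need <- c("id", "name", "R", "G", "B", "A", "modality")
    if (!all(need %in% names(e)))
        return(paste("entries must have columns", paste(need, collapse = ", ")))
    if (nrow(e) == 0L) return(TRUE)
    if (any(e$id <= 0)) return("region ids must be positive")
    if (anyDuplicated(e$id)) return("duplicate region id")
    if (any(!nzchar(e$name)) || any(grepl("[[:space:]]", e$name)))
        return("names must be non-empty and contain no whitespace")
    if (anyDuplicated(e$name)) return("duplicate region name")
    rng <- c(e$R, e$G, e$B, e$A)
    if (any(rng < 0 | rng > 255)) return("color components must be in 0..255")
    packed <- e$R + e$G * 256 + e$B * 65536
    if (anyDuplicated(packed)) return("duplicate packed RGB color")
    if (!all(e$modality %in% .lutModalities))
        return("unknown modality tag")
    TRUE
})

#' @rdname ColorLookupTable-class
#' @param entries see slot.
#' @export
ColorLookupTable <- function(entries) {
    entries <- as.data.frame(entries, stringsAsFactors = FALSE)
    if (nrow(entries)) {
        entries$id <- as.integer(entries$id)
        for (cc in c("R", "G", "B", "A")) entries[[cc]] <- as.integer(entries[[cc]])
        rownames(entries) <- NULL
    }
    new("ColorLookupTable", entries = entries)
}

#' Parcellation: per-vertex integer region labels
#'
#' `0` means unlabeled; every nonzero label must exist in the attached
#' [ColorLookupTable-class].
#'
#' @slot labels integer per-vertex label ids (0 = unlabeled).
#' @slot lut the color lookup table naming the labels.
#' @export
setClass("Parcellation",
    representation(labels = "integer", lut = "ColorLookupTable"))

setValidity("Parcellation", function(object) {
    lab <- object@labels
    if (any(lab < 0L)) return("labels must be non-negative")
    used <- unique(lab[lab > 0L])
    if (!all(used %in% object@lut@entries$id))
        return("parcellation uses a label id absent from its LUT")
    TRUE
})

#' @rdname Parcellation-class
#' @param labels,lut see slots.
#' @export
Parcellation <- function(labels, lut) {
    new("Parcellation", labels = as.integer(labels), lut = lut)
}

#' Annotation: per-vertex packed colors with an embedded color table
#'
#' Per-vertex packed RGB integers (`NA` = unlabeled); each non-`NA` packed
#' color must resolve to exactly one LUT entry.
#'
#' @slot packed integer per-vertex packed colors (`NA` for unlabeled).
#' @slot lut the embedded color table.
#' @export
setClass("Annotation",
    representation(packed = "integer", lut = "ColorLookupTable"))

setValidity("Annotation", function(object) {
    e <- object@lut@entries
    pk <- object@packed
    known <- e$R + e$G * 256 + e$B * 65536
    bad <- !is.na(pk) & !(pk %in% known)
    if (any(bad))
        return("annotation contains a packed color absent from its table")
    TRUE
})

#' @rdname Annotation-class
#' @param packed,lut see slots.
#' @export
Annotation <- function(packed, lut) {
    new("Annotation", packed = as.integer(packed), lut = lut)
}

#' GroundTruthMapSpec: synthetic ground truth for one modality
#'
#' Carries the true per-vertex phase coordinate(s), area ids, field signs
#' (visual specs) and per-area gradient directions of a synthetic map.
#'
#' @slot kind `"visual"`, `"1d"` or `"somato"`.
#' @slot phase1 primary phase coordinate (polar angle for visual), rad,
#'   in `(-pi, pi]`.
#' @slot phase2 secondary coordinate (eccentricity) or `NA` for 1D maps.
#' @slot areaId integer true area id per vertex (0 outside the map).
#' @slot fieldSign integer true field sign per vertex (0 where undefined).
#' @slot gradDir per-area true gradient directions (list of 2-vectors).
#' @slot jumps locations (mm along the map axis) of somatotopic
#'   discontinuities; empty otherwise.
#' @slot params generator parameters needed to re-evaluate the map's phase
#'   function at displaced cortical positions (used by the cross-subject
#'   jitter model).
#' @export
setClass("GroundTruthMapSpec",
    representation(kind = "character", phase1 = "numeric",
                   phase2 = "numeric", areaId = "integer",
                   fieldSign = "integer", gradDir = "list",
                   jumps = "numeric", params = "list"),
    prototype(params = list()))

setValidity("GroundTruthMapSpec", function(object) {
    if (!(object@kind %in% c("visual", "1d", "somato")))
        return("kind must be visual, 1d or somato")
    p <- c(object@phase1, object@phase2)
    p <- p[is.finite(p)]
    if (length(p) && (any(p <= -pi - 1e-12) || any(p > pi + 1e-12)))
        return("phases must lie in (-pi, pi]")
    n <- length(object@phase1)
    if (length(object@areaId) != n || length(object@fieldSign) != n)
        return("per-vertex slot lengths differ")
    TRUE
})
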