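## End-to-end pipeline: simulate -> analyze -> group average -> field sign
## -> parcellation -> annotation, with protocol validation and a
## reproducibility manifest.

#' PipelineConfig: full pipeline configuration
#'
#' Bundles the scanning protocol, the cohort simulation parameters, the
#' synthetic map layout and the segmentation thresholds. All component
#' invariants are validated before any stage runs.
#'
#' @slot protocol a [ProtocolConfig-class].
#' @slot cohort a [CohortSpec-class].
#' @slot scanDurationS scan duration (s); must equal
#'   `volumesPerScan * trS`.
#' @slot specKind synthetic map kind: `"visual"`, `"1d"` or `"somato"`.
#' @slot nStripes stripes (visual) or patches (somato) in the truth map.
#' @slot nRings,edgeMm hex-patch mesh size parameters.
#' @slot gains phase gains `c(polar, ecc)` in rad/mm.
#' @slot minAreaMm2,minPhaseRangeRad segmentation thresholds.
#' @slot smoothSteps nearest-neighbor smoothing steps applied to the group
#'   map before gradients are taken.
#' @export
setClass("PipelineConfig",
    representation(protocol = "ProtocolConfig", cohort = "CohortSpec",
                   scanDurationS = "numeric", specKind = "character",
                   nStripes = "integer", nRings = "integer",
                   edgeMm = "numeric", gains = "numeric",
                   minAreaMm2 = "numeric", minPhaseRangeRad = "numeric",
                   smoothSteps = "integer"))

setValidity("PipelineConfig", function(object) {
    if (!(object@specKind %in% c("visual", "1d", "somato")))
        return("specKind must be visual, 1d or somato")
    if (object@nStripes < 1L || object@nRings < 1L || object@edgeMm <= 0)
        return("mesh/map size parameters must be positive")
    if (object@minAreaMm2 < 0 || object@minPhaseRangeRad < 0)
        return("segmentation thresholds must be >= 0")
    if (object@smoothSteps < 0L) return("smoothSteps must be >= 0")
    TRUE
})

#' @rdname PipelineConfig-class
#' @param protocol,cohort,scanDurationS,specKind,nStripes,nRings,edgeMm,gains,minAreaMm2,minPhaseRangeRad,smoothSteps
#'   see slots.
#' @export
PipelineConfig <- function(protocol = ProtocolConfig(), cohort,
                           scanDurationS = NULL, specKind = "visual",
                           nStripes = 3L, nRings = 10L, edgeMm = 1,
                           gains = c(polar = 0.35, ecc = 0.2),
                           minAreaMm2 = 25, minPhaseRangeRad = pi / 4,
                           smoothSteps = 1L) {
    if (is.null(scanDurationS))
        scanDurationS <- protocol@volumesPerScan * protocol@trS
    new("PipelineConfig", protocol = protocol, cohort = cohort,
        scanDurationS = as.numeric(scanDurationS), specKind = specKind,
        nStripes = as.integer(nStripes), nRings = as.integer(nRings),
        edgeMm = as.numeric(edgeMm), gains = as.numeric(gains),
        minAreaMm2 = as.numeric(minAreaMm2),
        minPhaseRangeRad = as.numeric(minPhaseRangeRad),
        smoothSteps = as.integer(smoothSteps))
}

#' Validate a protocol and derive its summary quantities
#'
#' Checks the arithmetic consistency of the protocol -- the scan duration
#' must be an integer number of TRs matching `volumesPerScan`, and the
#' cycle length in samples must be an integer -- and reports the derived
#' quantities: volumes per scan, volumes per subject
#' (`volumesPerScan * scansPerModality * nModalities`), scan duration and
#' stimulus period.
#'
#' @param config a [PipelineConfig-class] or [ProtocolConfig-class].
#' @param scanDurationS scan duration in seconds (only when `config` is a
#'   bare protocol; defaults to `volumesPerScan * trS`).
#' @return list with `volumesPerScan`, `volumesPerSubject`,
#'   `scanDurationS`, `periodS`, `cycleLengthSamples`.
#' @export
validateProtocol <- function(config, scanDurationS = NULL) {
    if (is(config, "PipelineConfig")) {
        proto <- config@protocol
        dur <- config@scanDurationS
    } else if (is(config, "ProtocolConfig")) {
        proto <- config
        dur <- if (is.null(scanDurationS))
            proto@volumesPerScan * proto@trS else scanDurationS
    } else stop("config must be a PipelineConfig or ProtocolConfig")
    validObject(proto)
    vols <- dur / proto@trS
    if (abs(vols - round(vols)) > 1e-9)
        stop("validation error in 'scanDurationS': duration ", dur,
             " s is not an integer number of TRs (trS = ", proto@trS, ")")
    vols <- as.integer(round(vols))
    if (vols != proto@volumesPerScan)
        stop("validation error in 'volumesPerScan': duration/TR gives ",
             vols, " but protocol declares ", proto@volumesPerScan)
    if (vols %% proto@nCycles != 0L)
        stop("validation error in 'nCycles': cycle length ",
             vols / proto@nCycles, " samples is not an integer")
    list(volumesPerScan = vols,
         volumesPerSubject = vols * proto@scansPerModality *
             proto@nModalities,
         scanDurationS = dur,
         periodS = vols * proto@trS / proto@nCycles,
         cycleLengthSamples = vols %/% proto@nCycles)
}

## analyze one subject's runs for one stimulus coordinate
.subjectMap <- function(subj, config, periodS) {
    fwd <- lapply(subj$forward, fourierPhaseMap)
    rev <- lapply(subj$reversed, fourierPhaseMap)
    combineReversed(fwd, rev, config, periodS)
}

## smooth a complex map's coefficients on the mesh, keeping its statistics
.smoothMap <- function(map, mesh, steps) {
    if (steps == 0L) return(map)
    coef <- mapCoef(map)
    sm <- nnSmooth(coef, mesh, steps)
    ComplexMapResult(coef = sm, fStat = fStat(map), dof = dofF(map),
                     pValue = pValues(map), mask = mapMask(map),
                     nRuns = map@nRuns)
}

#' Run the full synthetic mapping pipeline
#'
#' Generates a synthetic cohort, analyzes every run, combines reversed
#' runs per subject, averages subjects with the bivariate F-ratio mask,
#' smooths, computes gradients and (for visual maps) the field sign,
#' segments into labeled areas, and writes the artifact directory: the
#' mesh, group maps, parcellation, annotation, color table, JSON labels
#' and a manifest with every parameter, seed and per-file checksum. All
#' outputs are a pure function of the configuration seed.
#'
#' @param config a [PipelineConfig-class].
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the in-memory stage results
#'   (`mesh`, `spec`, `groupPrimary`, `groupSecondary`, `fieldsign`,
#'   `parcellation`, `coverage`, `manifest`).
#' @export
runPipeline <- function(config, outDir) {
    stopifnot(is(config, "PipelineConfig"))
    validObject(config)
    proto <- config@protocol
    summary <- validateProtocol(config)        # aborts on inconsistency
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    mesh <- makeHexPatch(config@nRings, config@edgeMm)
    spec <- switch(config@specKind,
        visual = synthVisualSpec(mesh, config@nStripes,
                                 gains = config@gains),
        "1d" = synth1dSpec(mesh, gain = config@gains[1]),
        somato = synthSomatoSpec(mesh, config@nStripes,
                                 gain = config@gains[1]))
    coords <- if (config@specKind == "visual") c("primary", "secondary")
              else "primary"
    groups <- list()
    for (co in coords) {
        cohortCo <- config@cohort
        if (co == "secondary")    # independent noise for the second stimulus
            cohortCo@seed <- .subSeed(cohortCo@seed, 999983L)
        runs <- synthRuns(mesh, spec, co, proto, cohortCo)
        subjMaps <- lapply(runs, .subjectMap, config = proto,
                           periodS = summary$periodS)
        grp <- if (length(subjMaps) >= 3L) groupComplexFratio(subjMaps)
               else subjMaps[[1]]
        groups[[co]] <- .smoothMap(grp, mesh, config@smoothSteps)
    }
    frames <- tangentFrames(mesh)
    gradP <- phaseGradient(groups$primary, mesh, frames)
    mask <- significanceMask(groups$primary, proto@alpha)
    if (config@specKind == "visual") {
        gradE <- phaseGradient(groups$secondary, mesh, frames)
        fs <- visualFieldSign(gradP, gradE, frames)
        mask <- mask & significanceMask(groups$secondary, proto@alpha)
    } else {
        ## 1D/somato maps carry no field sign; segment the mask as one sign
        fs <- new("FieldSignMap",
                  sign = ifelse(mask, 1L, 0L))
        gradE <- NULL
    }
    parc <- segmentFieldsign(fs, mask, mesh, config@minAreaMm2,
                             config@minPhaseRangeRad, groups$primary)
    cov <- areaCoverage(parc, vertexAreas(mesh))
    ## artifacts
    paths <- list(
        surface = file.path(outDir, "patch.surf"),
        lut = file.path(outDir, "parcellation.ctab"),
        annot = file.path(outDir, "parcellation.annot"),
        labelsJson = file.path(outDir, "labels.json"),
        mapsJson = file.path(outDir, "group_maps.json"),
        manifest = file.path(outDir, "manifest.json"))
    writeSurface(mesh, paths$surface)
    writeLUT(parcLut(parc), paths$lut)
    annot <- parcellationToAnnotation(parc)
    writeAnnotation(annot, paths$annot)
    exportLabelsJSON(annot, paths$labelsJson)
    jsonlite::write_json(list(
        primary = list(phase = phaseRad(groups$primary),
                       amplitude = amplitude(groups$primary),
                       p = pValues(groups$primary)),
        secondary = if (!is.null(groups$secondary))
            list(phase = phaseRad(groups$secondary)) else NULL,
        fieldsign = fieldSign(fs)), paths$mapsJson, digits = 10,
        na = "null")
    labAreas <- as.list(cov$perLabel)
    manifest <- list(
        package = "topomapr",
        version = as.character(utils::packageVersion("topomapr")),
        seed = config@cohort@seed,
        protocol = list(trS = proto@trS,
                        volumesPerScan = proto@volumesPerScan,
                        scansPerModality = proto@scansPerModality,
                        nModalities = proto@nModalities,
                        nCycles = proto@nCycles,
                        delayShiftS = proto@delayShiftS,
                        alpha = proto@alpha),
        cohort = list(nSubjects = config@cohort@nSubjects,
                      jitterSd = config@cohort@jitterSd,
                      noiseSd = config@cohort@noiseSd,
                      noiseAr1 = config@cohort@noiseAr1,
                      delayMeanS = config@cohort@delayMeanS,
                      delaySdS = config@cohort@delaySdS,
                      amplitude = config@cohort@amplitude),
        map = list(specKind = config@specKind, nStripes = config@nStripes,
                   nRings = config@nRings, edgeMm = config@edgeMm,
                   gains = config@gains),
        segmentation = list(minAreaMm2 = config@minAreaMm2,
                            minPhaseRangeRad = config@minPhaseRangeRad,
                            smoothSteps = config@smoothSteps),
        derived = summary,
        stages = list(nVertices = nVertices(mesh), nFaces = nFaces(mesh),
                      maskedFraction = mean(!mask),
                      nLabels = length(cov$perLabel),
                      labelAreaFractions = labAreas,
                      totalCoverage = cov$total),
        checksums = as.list(tools::md5sum(unlist(paths[names(paths) !=
                                                           "manifest"]))))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    invisible(list(mesh = mesh, spec = spec, groupPrimary = groups$primary,
                   groupSecondary = groups$secondary, fieldsign = fs,
                   parcellation = parc, coverage = cov,
                   manifest = manifest, paths = paths))
}
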