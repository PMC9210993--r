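## Synthetic cortex: regular meshes, ground-truth topological maps in the
## three modalities, and periodic noisy response runs for whole cohorts.

#' Regular flat hexagonal patch mesh
#'
#' A triangulated patch of `nRings` rings of equilateral triangles around a
#' central vertex, in the z = 0 plane with upward-oriented faces. Interior
#' vertices have exactly 6 neighbors; the vertex count is
#' `1 + 3 * n * (n + 1)`.
#'
#' @param nRings number of rings (>= 1).
#' @param edgeMm edge length in mm.
#' @return A [TriangleMesh-class].
#' @export
makeHexPatch <- function(nRings, edgeMm = 1) {
    nRings <- as.integer(nRings)
    if (nRings < 1L) stop("nRings must be >= 1")
    if (edgeMm <= 0) stop("edgeMm must be positive")
    n <- nRings
    qr <- expand.grid(q = -n:n, r = -n:n)
    qr <- qr[abs(qr$q + qr$r) <= n, ]
    key <- function(q, r) paste(q, r)
    idx <- seq_len(nrow(qr))
    names(idx) <- key(qr$q, qr$r)
    x <- edgeMm * (qr$q + qr$r / 2)
    y <- edgeMm * (qr$r * sqrt(3) / 2)
    faces <- list()
    inHex <- function(q, r) abs(q) <= n && abs(r) <= n && abs(q + r) <= n
    for (q in (-n - 1L):n) for (r in (-n - 1L):n) {
        if (inHex(q, r) && inHex(q + 1, r) && inHex(q, r + 1))
            faces[[length(faces) + 1L]] <-
                c(idx[[key(q, r)]], idx[[key(q + 1, r)]],
                  idx[[key(q, r + 1)]])
        if (inHex(q + 1, r) && inHex(q + 1, r + 1) && inHex(q, r + 1))
            faces[[length(faces) + 1L]] <-
                c(idx[[key(q + 1, r)]], idx[[key(q + 1, r + 1)]],
                  idx[[key(q, r + 1)]])
    }
    TriangleMesh(cbind(x, y, 0), do.call(rbind, faces))
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to the unit sphere, with outward-facing
#' triangles; the vertex count is `10 * 4^s + 2`.
#'
#' @param subdivisions number of 1-to-4 subdivision rounds (>= 0).
#' @param radius sphere radius in mm.
#' @return A [TriangleMesh-class].
#' @export
makeSphere <- function(subdivisions = 0L, radius = 1) {
    subdivisions <- as.integer(subdivisions)
    if (subdivisions < 0L) stop("subdivisions must be >= 0")
    phi <- (1 + sqrt(5)) / 2
    v <- rbind(
        c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
        c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
        c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
    v <- v / sqrt(rowSums(v * v))
    f <- rbind(
        c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
        c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
        c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
        c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
    ## enforce outward orientation
    for (i in seq_len(nrow(f))) {
        a <- v[f[i, 2], ] - v[f[i, 1], ]
        b <- v[f[i, 3], ] - v[f[i, 1], ]
        nrm <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                 a[1] * b[2] - a[2] * b[1])
        if (sum(nrm * colMeans(v[f[i, ], ])) < 0) f[i, ] <- f[i, c(1, 3, 2)]
    }
    for (s in seq_len(subdivisions)) {
        edgeMid <- new.env(hash = TRUE)
        vlist <- v
        midpoint <- function(i, j) {
            k <- paste(min(i, j), max(i, j))
            got <- edgeMid[[k]]
            if (!is.null(got)) return(got)
            m <- (vlist[i, ] + vlist[j, ]) / 2
            m <- m / sqrt(sum(m * m))
            vlist <<- rbind(vlist, m)
            edgeMid[[k]] <- nrow(vlist)
            nrow(vlist)
        }
        nf <- matrix(0L, 0L, 3L)
        for (i in seq_len(nrow(f))) {
            a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
            ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
            nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                        c(ab, bc, ca))
        }
        v <- vlist; f <- nf
    }
    TriangleMesh(v * radius, f)
}

.patchAxes <- function(axis) {
    axis <- axis / sqrt(sum(axis^2))
    list(u = axis, w = c(-axis[2], axis[1]))
}

.centerCoord <- function(v2, axis) {
    u <- as.vector(v2 %*% axis)
    u - (max(u) + min(u)) / 2
}

#' Ground-truth visual (retinotopic) map with alternating field sign
#'
#' Eccentricity phase increases linearly along `eccAxis`; polar-angle phase
#' is a continuous triangle wave along the perpendicular axis whose slope
#' sign reverses at each of `nStripes - 1` stripe boundaries. Adjacent
#' stripes therefore carry opposite field sign, and boundary vertices have
#' identical polar phase on both sides (congruent borders), the V1/V2/V3
#' arrangement. The total phase excursion of each coordinate must stay
#' within one cycle.
#'
#' @param mesh a flat patch mesh (z = 0), e.g. [makeHexPatch()].
#' @param nStripes number of stripes (>= 2).
#' @param eccAxis in-plane unit direction of the eccentricity gradient.
#' @param gains length-2 `c(polar, ecc)` phase gains in rad/mm.
#' @return A [GroundTruthMapSpec-class].
#' @export
synthVisualSpec <- function(mesh, nStripes = 3L, eccAxis = c(1, 0),
                            gains = c(polar = 0.35, ecc = 0.2)) {
    stopifnot(is(mesh, "TriangleMesh"))
    nStripes <- as.integer(nStripes)
    if (nStripes < 2L) stop("nStripes must be >= 2")
    if (any(gains == 0)) stop("phase gains must be nonzero")
    v2 <- meshVertices(mesh)[, 1:2, drop = FALSE]
    ax <- .patchAxes(eccAxis)
    uE <- .centerCoord(v2, ax$u)         # eccentricity coordinate (mm)
    uP <- as.vector(v2 %*% ax$w)         # stripe coordinate (mm)
    uP <- uP - min(uP)
    width <- max(uP) / nStripes
    gp <- gains[[1]]; ge <- gains[[2]]
    if (abs(ge) * (max(uE) - min(uE)) >= 2 * pi ||
        abs(gp) * width >= 2 * pi)
        stop("phase gain too large: map would wrap within the patch")
    phase2 <- ge * uE
    ## continuous triangle wave: slope +gp on odd stripes, -gp on even
    tri <- function(u) gp * (width - abs(u %% (2 * width) - width))
    stripe <- pmin(pmax(ceiling(uP / width), 1L), nStripes)
    phase1 <- tri(uP)
    c1 <- (max(phase1) + min(phase1)) / 2
    phase1 <- phase1 - c1
    sgn <- ifelse(stripe %% 2L == 1L, 1, -1)
    fs <- as.integer(sign(ge * gp) * sgn)
    gradDir <- lapply(seq_len(nStripes), function(k)
        ax$w * ifelse(k %% 2L == 1L, 1, -1) * sign(gp))
    new("GroundTruthMapSpec", kind = "visual",
        phase1 = .wrapPi(phase1), phase2 = .wrapPi(phase2),
        areaId = as.integer(stripe), fieldSign = fs, gradDir = gradDir,
        jumps = numeric(),
        params = list(uP = uP, uE = uE, width = width, gp = gp, ge = ge,
                      c1 = c1))
}

#' Ground-truth 1D (tonotopic) map
#'
#' A single phase coordinate, linear along `axis` (the cochlear frequency
#' axis analog); field sign is undefined for a 1D map.
#'
#' @param mesh a flat patch mesh.
#' @param axis in-plane direction of the tonotopic gradient.
#' @param gain phase gain in rad/mm; the excursion across the patch must
#'   stay within one cycle.
#' @return A [GroundTruthMapSpec-class].
#' @export
synth1dSpec <- function(mesh, axis = c(1, 0), gain = 0.25) {
    stopifnot(is(mesh, "TriangleMesh"))
    if (gain == 0) stop("gain must be nonzero")
    v2 <- meshVertices(mesh)[, 1:2, drop = FALSE]
    ax <- .patchAxes(axis)
    u <- .centerCoord(v2, ax$u)
    if (abs(gain) * (max(u) - min(u)) >= 2 * pi)
        stop("phase gain too large: map would wrap within the patch")
    new("GroundTruthMapSpec", kind = "1d", phase1 = .wrapPi(gain * u),
        phase2 = rep(NA_real_, nrow(v2)),
        areaId = rep(1L, nrow(v2)), fieldSign = rep(0L, nrow(v2)),
        gradDir = list(ax$u * sign(gain)), jumps = numeric())
}

#' Ground-truth somatotopic map with discontinuous patch borders
#'
#' Piecewise-linear phase along `axis` over `nPatches` bands with a
#' discontinuous jump of `jumpRad` at every border -- the patchwork-quilt
#' analog of receptive fields jumping from one body part to the next.
#' Jump locations (mm along the axis) are recorded in the result.
#'
#' @param mesh a flat patch mesh.
#' @param nPatches number of body-part patches (>= 2).
#' @param axis in-plane direction of the body-part sequence.
#' @param gain within-patch phase gain (rad/mm).
#' @param jumpRad phase discontinuity at each border (rad).
#' @return A [GroundTruthMapSpec-class].
#' @export
synthSomatoSpec <- function(mesh, nPatches = 3L, axis = c(1, 0),
                            gain = 0.2, jumpRad = 0.8) {
    stopifnot(is(mesh, "TriangleMesh"))
    nPatches <- as.integer(nPatches)
    if (nPatches < 2L) stop("nPatches must be >= 2")
    if (gain == 0) stop("gain must be nonzero")
    v2 <- meshVertices(mesh)[, 1:2, drop = FALSE]
    ax <- .patchAxes(axis)
    u <- as.vector(v2 %*% ax$u)
    u <- u - min(u)
    width <- max(u) / nPatches
    patch <- pmin(pmax(ceiling(u / width), 1L), nPatches)
    phase <- gain * (u - (patch - 1L) * width) + (patch - 1L) * jumpRad
    span <- max(phase) - min(phase)
    if (span >= 2 * pi)
        stop("gain/jump too large: map would wrap within the patch")
    phase <- phase - (max(phase) + min(phase)) / 2
    new("GroundTruthMapSpec", kind = "somato", phase1 = .wrapPi(phase),
        phase2 = rep(NA_real_, nrow(v2)),
        areaId = as.integer(patch), fieldSign = rep(0L, nrow(v2)),
        gradDir = rep(list(ax$u * sign(gain)), nPatches),
        jumps = (seq_len(nPatches - 1L)) * width)
}

## Evaluate a subject's jittered phase map. The jitter field is a smooth
## per-vertex offset (rad); it is applied in the sensory (unfolded)
## coordinate by displacing cortical position through the map's own phase
## function, so that in map interiors it reduces to an additive phase
## offset while at folded (congruent) borders displaced positions reflect
## back -- the mechanism behind the phase-range compression seen in
## jittered cross-subject averages.
.jitteredPhase <- function(spec, coordinate, jitter) {
    phase <- truePhase(spec, coordinate)
    if (all(jitter == 0)) return(phase)
    p <- spec@params
    if (spec@kind == "visual" && coordinate == "primary" &&
        !is.null(p$width)) {
        tri <- function(u) p$gp * (p$width - abs(u %% (2 * p$width) -
                                                     p$width))
        return(.wrapPi(tri(p$uP + jitter / p$gp) - p$c1))
    }
    .wrapPi(phase + jitter)
}

## deterministic sub-seed (kept below 2^31)
.subSeed <- function(seed, subject, run = 0L) {
    as.integer((as.double(seed) * 7919 + subject * 104729 + run * 1299709) %%
                   2147483647)
}

## AR(1) noise, stationary start; vectorized over vertices
.ar1Noise <- function(nV, nT, sdInnov, rho) {
    if (sdInnov == 0) return(matrix(0, nV, nT))
    x <- matrix(0, nV, nT)
    x[, 1] <- rnorm(nV, sd = sdInnov / sqrt(1 - rho^2))
    innov <- matrix(rnorm(nV * (nT - 1L), sd = sdInnov), nV, nT - 1L)
    for (t in 2:nT) x[, t] <- rho * x[, t - 1L] + innov[, t - 1L]
    x
}

#' Simulate phase-encoded runs for a subject cohort
#'
#' For each subject, a smooth single-harmonic jitter field (emulating
#' registration misalignment) displaces the true map -- additively in map
#' interiors, reflecting at folded congruent borders -- a hemodynamic
#' delay is drawn, and forward and time-reversed runs are produced as
#' `amplitude * cos(2 pi nCycles t / T - phase - 2 pi delay / period)`
#' (reversed runs negate the stimulus phase before the delay is applied),
#' plus AR(1) noise. All randomness derives deterministically from
#' `cohort@seed`, the subject index and the run index, so identical specs
#' give bit-identical runs.
#'
#' @param mesh the patch mesh.
#' @param spec a [GroundTruthMapSpec-class].
#' @param coordinate which phase coordinate is being stimulated:
#'   `"primary"` or `"secondary"`.
#' @param config a [ProtocolConfig-class].
#' @param cohort a [CohortSpec-class].
#' @return list with one element per subject, each a list with `forward`
#'   and `reversed` (lists of [RunTimeSeries-class]), the subject's
#'   `delayS` and its per-vertex `jitter` field (rad).
#' @export
synthRuns <- function(mesh, spec, coordinate = "primary", config, cohort) {
    stopifnot(is(mesh, "TriangleMesh"), is(spec, "GroundTruthMapSpec"),
              is(config, "ProtocolConfig"), is(cohort, "CohortSpec"))
    validObject(config); validObject(cohort)
    phase <- truePhase(spec, coordinate)
    if (all(is.na(phase))) stop("spec has no ", coordinate, " coordinate")
    nV <- nVertices(mesh)
    if (length(phase) != nV) stop("spec does not match mesh")
    Tt <- config@volumesPerScan
    k <- config@nCycles
    if (Tt %% k != 0L) stop("volumesPerScan not divisible by nCycles")
    tr <- config@trS
    omega <- 2 * pi * k / (Tt * tr)          # rad/s
    tsec <- (seq_len(Tt) - 1L) * tr
    v2 <- meshVertices(mesh)[, 1:2, drop = FALSE]
    L <- max(max(v2[, 1]) - min(v2[, 1]), max(v2[, 2]) - min(v2[, 2]))
    nRuns <- config@scansPerModality
    nFwd <- ceiling(nRuns / 2)
    modality <- switch(spec@kind, visual = "visual", "1d" = "auditory",
                       somato = "somatomotor")
    stim <- trueAreas(spec) > 0L
    amp <- cohort@amplitude * as.numeric(stim)
    subjects <- vector("list", cohort@nSubjects)
    for (s in seq_len(cohort@nSubjects)) {
        set.seed(.subSeed(cohort@seed, s))
        if (cohort@jitterSd > 0) {
            theta <- runif(1, 0, 2 * pi)
            psi <- runif(1, 0, 2 * pi)
            proj <- (v2[, 1] * cos(theta) + v2[, 2] * sin(theta)) / L
            jitter <- cohort@jitterSd * sqrt(2) * sin(2 * pi * proj + psi)
        } else jitter <- numeric(nV)
        delayS <- cohort@delayMeanS + cohort@delaySdS * rnorm(1)
        ph <- .jitteredPhase(spec, coordinate, jitter)
        fwd <- rev <- list()
        for (r in seq_len(nRuns)) {
            set.seed(.subSeed(cohort@seed, s, r))
            forward <- r <= nFwd
            stimPhase <- if (forward) ph else -ph
            signal <- amp * cos(outer(stimPhase + omega * delayS,
                                      omega * tsec,
                                      function(p, wt) wt - p))
            noise <- .ar1Noise(nV, Tt, cohort@noiseSd, cohort@noiseAr1)
            run <- RunTimeSeries(signal + noise, trS = tr, nCycles = k,
                                 direction = if (forward) 1L else -1L,
                                 modality = modality)
            if (forward) fwd[[length(fwd) + 1L]] <- run
            else rev[[length(rev) + 1L]] <- run
        }
        subjects[[s]] <- list(forward = fwd, reversed = rev,
                              delayS = delayS, jitter = jitter)
    }
    subjects
}
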