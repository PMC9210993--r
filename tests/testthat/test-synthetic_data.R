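test_that("hex patches and icospheres have the predicted combinatorics", {
    for (n in 1:4) {
        m <- makeHexPatch(n)
        expect_identical(nVertices(m), 1L + 3L * n * (n + 1L))
        expect_identical(nFaces(m), 6L * n * n)
    }
    ## edge length scales coordinates linearly
    expect_equal(meshVertices(makeHexPatch(2, edgeMm = 2.5)),
                 meshVertices(makeHexPatch(2)) * 2.5)
    for (s in 0:2) {
        sp <- makeSphere(s)
        V <- nVertices(sp); Fc <- nFaces(sp)
        expect_identical(V, as.integer(10 * 4^s + 2))
        E <- (3L * Fc) %/% 2L
        expect_identical(V - E + Fc, 2L)      # Euler characteristic
    }
})

test_that("visual specs alternate field sign across congruent borders", {
    m <- makeHexPatch(10)
    sp <- synthVisualSpec(m, 3)
    expect_identical(sort(unique(trueAreas(sp))), 1:3)
    ## alternating sign +,-,+ (or flipped) stripe by stripe
    signs <- vapply(1:3, function(k)
        unique(trueFieldSign(sp)[trueAreas(sp) == k]), integer(1))
    expect_true(all(abs(signs) == 1L))
    expect_identical(signs[1], signs[3])
    expect_identical(signs[2], -signs[1])
    ## eccentricity gradient uniform across stripes; polar reverses
    v <- meshVertices(m)
    fr <- tangentFrames(m)
    ge <- phaseGradient(phaseMap(truePhase(sp, "secondary")), m, fr)
    int <- hexInterior(m)
    gnorm <- sqrt(rowSums(gradients(ge)^2))
    expect_equal(gnorm[int], rep(0.2, length(int)), tolerance = 1e-6)
    ## congruent borders: boundary vertices share polar phase on both sides
    nb <- vertexNeighbors(m)
    phi <- truePhase(sp)
    border <- which(vapply(seq_along(nb), function(i)
        any(trueAreas(sp)[nb[[i]]] != trueAreas(sp)[i]), logical(1)))
    ## phase is continuous at borders: neighbor differences stay small
    for (i in border[1:10]) {
        expect_lt(max(abs(phi[nb[[i]]] - phi[i])), 0.35 * 1.01)
    }
    expect_error(synthVisualSpec(m, 1), "nStripes")
    expect_error(synthVisualSpec(m, 3, gains = c(0, 0.2)), "nonzero")
    expect_error(synthVisualSpec(m, 2, gains = c(0.35, 2)), "wrap")
})

test_that("1D specs are linear with a constant perpendicular direction", {
    m <- makeHexPatch(8)
    sp <- synth1dSpec(m, axis = c(0.6, 0.8), gain = 0.25)
    fr <- tangentFrames(m)
    g <- phaseGradient(phaseMap(truePhase(sp)), m, fr)
    int <- hexInterior(m)
    gnorm <- sqrt(rowSums(gradients(g)[int, ]^2))
    expect_equal(gnorm, rep(0.25, length(int)), tolerance = 1e-6)
    expect_true(all(trueFieldSign(sp) == 0L))
    expect_error(synth1dSpec(m, gain = 0), "nonzero")
    ## gain too large for the patch wraps -> precondition
    expect_error(synth1dSpec(makeHexPatch(12), gain = 0.5), "wrap")
})

test_that("somatotopic specs jump at recorded patch borders", {
    m <- makeHexPatch(10)
    sp <- synthSomatoSpec(m, nPatches = 2L, gain = 0.15, jumpRad = 0.9)
    expect_identical(length(sp@jumps), 1L)
    ## discontinuity: gradient magnitude spikes at the border
    fr <- tangentFrames(m)
    g <- phaseGradient(phaseMap(truePhase(sp)), m, fr)
    gnorm <- sqrt(rowSums(gradients(g)^2))
    v <- meshVertices(m)
    u <- v[, 1] - min(v[, 1])
    int <- hexInterior(m)
    nearJump <- abs(u[int] - sp@jumps[1]) < 0.8     # neighborhood straddles
    clean <- abs(u[int] - sp@jumps[1]) > 1.01       # no border neighbor
    ## the discontinuity produces anomalous gradients at the border
    ## (spikes where the jump dominates the within-patch slope) while
    ## within-patch gradients are exactly the gain
    expect_gt(max(gnorm[int][nearJump]), 0.15 * 1.5)
    expect_gt(max(abs(gnorm[int][nearJump] - 0.15)), 0.05)
    expect_equal(gnorm[int][clean], rep(0.15, sum(clean)),
                 tolerance = 1e-6)
})

test_that("simulated runs close the loop on the true phase", {
    m <- makeHexPatch(6)
    sp <- synthVisualSpec(m, 3)
    cfg <- ProtocolConfig(volumesPerScan = 64L, nCycles = 8L)
    cohort <- CohortSpec(nSubjects = 1L, noiseSd = 0, noiseAr1 = 0,
                         delayMeanS = 5, seed = 7L)
    runs <- synthRuns(m, sp, "primary", cfg, cohort)
    expect_identical(length(runs[[1]]$forward), 2L)
    expect_identical(length(runs[[1]]$reversed), 2L)
    cmb <- combineReversed(lapply(runs[[1]]$forward, fourierPhaseMap),
                           lapply(runs[[1]]$reversed, fourierPhaseMap),
                           cfg, periodS = 8)
    expect_lt(max(abs(wrapPi(phaseRad(cmb) - truePhase(sp)))), 1e-6)
    ## identical seeds give bit-identical runs
    runs2 <- synthRuns(m, sp, "primary", cfg, cohort)
    expect_identical(runData(runs2[[1]]$forward[[1]]),
                     runData(runs[[1]]$forward[[1]]))
    noisy <- CohortSpec(nSubjects = 2L, noiseSd = 1, seed = 7L)
    n1 <- synthRuns(m, sp, "primary", cfg, noisy)
    n2 <- synthRuns(m, sp, "primary", cfg, noisy)
    expect_identical(runData(n1[[2]]$reversed[[2]]),
                     runData(n2[[2]]$reversed[[2]]))
    ## different runs get different noise
    expect_false(identical(runData(n1[[1]]$forward[[1]]),
                           runData(n1[[1]]$forward[[2]])))
    expect_error(synthRuns(m, sp, "primary",
                           ProtocolConfig(volumesPerScan = 65L,
                                          nCycles = 8L), cohort),
                 "divisible")
})

test_that("phase recovery error falls as SNR rises", {
    m <- makeHexPatch(5)
    sp <- synthVisualSpec(m, 3)
    cfg <- ProtocolConfig(volumesPerScan = 64L, nCycles = 8L)
    rmse <- vapply(c(0.25, 1, 4), function(a) {
        cohort <- CohortSpec(nSubjects = 1L, noiseSd = 1, amplitude = a,
                             seed = 19L)
        runs <- synthRuns(m, sp, "primary", cfg, cohort)
        cmb <- combineReversed(lapply(runs[[1]]$forward, fourierPhaseMap),
                               lapply(runs[[1]]$reversed, fourierPhaseMap),
                               cfg, 8)
        sqrt(mean(wrapPi(phaseRad(cmb) - truePhase(sp))^2))
    }, numeric(1))
    expect_true(all(diff(rmse) < 0))
})

test_that("run containers round-trip data and metadata", {
    set.seed(12)
    run <- RunTimeSeries(matrix(rnorm(20 * 32), 20), trS = 1.5,
                         nCycles = 8L, direction = -1L,
                         modality = "auditory")
    tf <- withr::local_tempfile()
    writeRun(run, tf)
    back <- readRun(tf)
    expect_equal(runData(back), runData(run), tolerance = 1e-6)
    expect_identical(runCycles(back), 8L)
    expect_identical(runDirection(back), -1L)
    expect_identical(back@modality, "auditory")
    expect_equal(runTr(back), 1.5)
    writeLines("nope", tf)
    expect_error(readRun(tf), "magic")
})
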