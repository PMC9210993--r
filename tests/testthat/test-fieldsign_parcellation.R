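worldGradients <- function(field, frames) {
    G <- gradients(field)
    G[, 1] * frameVectors(frames, "e1") + G[, 2] * frameVectors(frames, "e2")
}

test_that("phase gradients recover analytic linear fields and unwrap", {
    m <- makeHexPatch(8)
    v <- meshVertices(m)
    fr <- tangentFrames(m)
    int <- hexInterior(m)
    ## constant phase: zero vector
    g0 <- phaseGradient(phaseMap(rep(0.4, nVertices(m))), m, fr)
    expect_equal(max(abs(gradients(g0)[int, ])), 0, tolerance = 1e-12)
    ## phi = 0.3 x: gradient (0.3, 0) in world coordinates
    g <- phaseGradient(phaseMap(wrapPi(0.3 * v[, 1])), m, fr)
    gw <- worldGradients(g, fr)
    expect_equal(gw[int, 1], rep(0.3, length(int)), tolerance = 1e-6)
    expect_equal(max(abs(gw[int, 2:3])), 0, tolerance = 1e-6)
    ## adding pi (crossing the wrap boundary) changes nothing
    g2 <- phaseGradient(phaseMap(wrapPi(0.3 * v[, 1] + pi)), m, fr)
    expect_equal(gradients(g2)[int, ], gradients(g)[int, ],
                 tolerance = 1e-9)
    ## gradients are perpendicular to isophase lines: for phi = 0.2x+0.1y
    g3 <- phaseGradient(phaseMap(wrapPi(0.2 * v[, 1] + 0.1 * v[, 2])), m, fr)
    gw3 <- worldGradients(g3, fr)
    iso <- c(-0.1, 0.2, 0)          # direction along the isophase lines
    expect_equal(max(abs(gw3[int, ] %*% iso)), 0, tolerance = 1e-6)
})

test_that("mean gradient direction averages arrows and flags cancellation", {
    f <- new("GradientField", gx = c(0.3, 0.3, 1, 0, 1, -1),
             gy = c(0, 0, 0, 1, 0, 0),
             valid = rep(TRUE, 6))
    u <- meanGradientDirection(f, 1:2)
    expect_equal(u$direction, c(1, 0))
    expect_equal(u$magnitude, 0.3)
    d <- meanGradientDirection(f, 3:4)
    expect_equal(d$direction, c(sqrt(2) / 2, sqrt(2) / 2))
    opp <- meanGradientDirection(f, 5:6)
    expect_true(opp$degenerate)
    expect_error(meanGradientDirection(f, integer()), "empty")
    fInvalid <- new("GradientField", gx = 1, gy = 0, valid = FALSE)
    expect_error(meanGradientDirection(fInvalid, 1L), "no valid")
})

test_that("field sign equals the sign of the analytic Jacobian", {
    m <- makeHexPatch(8)
    v <- meshVertices(m)
    fr <- tangentFrames(m)
    int <- hexInterior(m)
    mkg <- function(phi) phaseGradient(phaseMap(wrapPi(phi)), m, fr)
    ## (ecc, polar) = (x, y): det J = +1 -> non-mirror everywhere
    fs <- visualFieldSign(mkg(0.3 * v[, 2]), mkg(0.3 * v[, 1]), fr)
    expect_true(all(fieldSign(fs)[int] == 1L))
    ## (ecc, polar) = (x, -y): mirror
    fsm <- visualFieldSign(mkg(-0.3 * v[, 2]), mkg(0.3 * v[, 1]), fr)
    expect_true(all(fieldSign(fsm)[int] == -1L))
    ## general diffeomorphism: sign(det J) with J = d(ecc,polar)/d(x,y)
    ecc <- 0.25 * v[, 1] + 0.10 * v[, 2]
    pol <- -0.05 * v[, 1] + 0.20 * v[, 2]
    detJ <- 0.25 * 0.20 - 0.10 * (-0.05)
    fsg <- visualFieldSign(mkg(pol), mkg(ecc), fr)
    agree <- fieldSign(fsg)[int] == sign(detJ)
    expect_gte(mean(agree), 0.99)
    ## zero eccentricity gradient: undefined
    fs0 <- visualFieldSign(mkg(0.3 * v[, 2]), mkg(rep(0, nrow(v))), fr)
    expect_true(all(fieldSign(fs0) == 0L))
})

test_that("field sign covaries correctly under map transformations", {
    m <- makeHexPatch(6)
    fr <- tangentFrames(m)
    sp <- synthVisualSpec(m, 3)
    mkg <- function(phi) phaseGradient(phaseMap(phi), m, fr)
    base <- visualFieldSign(mkg(truePhase(sp)),
                            mkg(truePhase(sp, "secondary")), fr)
    ## negating the polar map flips every nonzero sign
    neg <- visualFieldSign(mkg(wrapPi(-truePhase(sp))),
                           mkg(truePhase(sp, "secondary")), fr)
    nz <- fieldSign(base) != 0L & fieldSign(neg) != 0L
    expect_true(all(fieldSign(neg)[nz] == -fieldSign(base)[nz]))
    ## adding a constant to either map changes nothing
    shift <- visualFieldSign(mkg(wrapPi(truePhase(sp) + 0.8)),
                             mkg(truePhase(sp, "secondary")), fr)
    expect_identical(fieldSign(shift), fieldSign(base))
})

test_that("significance mask thresholds p-values with sentinel handling", {
    n <- 100L
    set.seed(8)
    p <- c(0, runif(n - 2L), NA)
    mask <- c(rep(TRUE, n - 1L), FALSE)
    cm <- new("ComplexMapResult", coef = as.complex(rep(1 + 0i, n)),
              fStat = rep(1, n), dof = c(2, 10), pValue = p, mask = mask,
              nRuns = 1L)
    expect_identical(sum(significanceMask(cm, 1)), n - 1L)  # all defined
    m0 <- significanceMask(cm, 0)
    expect_identical(which(m0), 1L)                         # p = 0 passes
    expect_identical(significanceMask(cm, 0.3),
                     !is.na(p) & mask & p <= 0.3)
})

test_that("three-stripe maps segment into three accurately bounded areas", {
    m <- makeHexPatch(12)
    fr <- tangentFrames(m)
    sp <- synthVisualSpec(m, 3)
    pol <- phaseMap(truePhase(sp))
    ecc <- phaseMap(truePhase(sp, "secondary"))
    fs <- visualFieldSign(phaseGradient(pol, m, fr),
                          phaseGradient(ecc, m, fr), fr)
    parc <- segmentFieldsign(fs, rep(TRUE, nVertices(m)), m,
                             minAreaMm2 = 5, minPhaseRangeRad = pi / 8,
                             phase = pol)
    lab <- regionLabels(parc)
    expect_identical(length(unique(lab[lab > 0L])), 3L)
    ## interior accuracy: recovered stripes match ground-truth stripes
    truth <- trueAreas(sp)
    int <- hexInterior(m)
    ## map each recovered label to its majority truth stripe
    ok <- lab > 0L
    conf <- table(lab[ok & seq_along(lab) %in% int],
                  truth[ok & seq_along(lab) %in% int])
    assign <- apply(conf, 1, which.max)
    expect_identical(length(unique(assign)), 3L)   # bijective
    acc <- sum(apply(conf, 1, max)) / sum(conf)
    expect_gte(acc, 0.95)
    ## boundary displacement: recovered vs true stripe borders < 2 edges
    nb <- vertexNeighbors(m)
    boundaryOf <- function(l) which(vapply(seq_along(nb), function(i)
        l[i] > 0 && any(l[nb[[i]]] != l[i] & l[nb[[i]]] > 0), logical(1)))
    bRec <- boundaryOf(lab)
    bTrue <- boundaryOf(truth)
    v <- meshVertices(m)
    dists <- vapply(bRec, function(i)
        min(sqrt(rowSums(sweep(v[bTrue, , drop = FALSE], 2, v[i, ])^2))),
        numeric(1))
    expect_lt(median(dists), 2)                    # unit edge length
})

test_that("segmentation filters by area and phase range, orders by size", {
    m <- makeHexPatch(6)
    n <- nVertices(m)
    ## uniform sign, full mask: one label covering the mesh
    fsAll <- new("FieldSignMap", sign = rep(1L, n))
    ph <- phaseMap(wrapPi(0.3 * meshVertices(m)[, 1]))
    p1 <- segmentFieldsign(fsAll, rep(TRUE, n), m, 1, 0, ph)
    expect_identical(unique(regionLabels(p1)), 1L)
    ## empty mask: empty parcellation (valid)
    p0 <- segmentFieldsign(fsAll, rep(FALSE, n), m, 1, 0, ph)
    expect_true(all(regionLabels(p0) == 0L))
    ## a tiny single-vertex component is discarded by the area threshold
    sgn <- rep(1L, n)
    corner <- which.max(meshVertices(m)[, 1])
    sgn[corner] <- -1L
    p2 <- segmentFieldsign(new("FieldSignMap", sign = sgn), rep(TRUE, n),
                           m, minAreaMm2 = 1, minPhaseRangeRad = 0,
                           phase = ph)
    expect_identical(sort(unique(regionLabels(p2))), c(0L, 1L))
    ## constant-phase component fails the phase-range criterion
    p3 <- segmentFieldsign(fsAll, rep(TRUE, n), m, 1, pi / 4,
                           phaseMap(rep(0.2, n)))
    expect_true(all(regionLabels(p3) == 0L))
    ## labels ordered by decreasing area
    sp <- synthVisualSpec(m, 2)
    fr <- tangentFrames(m)
    fs2 <- visualFieldSign(phaseGradient(phaseMap(truePhase(sp)), m, fr),
                           phaseGradient(phaseMap(truePhase(sp, "secondary")),
                                         m, fr), fr)
    p4 <- segmentFieldsign(fs2, rep(TRUE, n), m, 1, 0,
                           phaseMap(truePhase(sp)))
    va <- mapValues(vertexAreas(m))
    lab4 <- regionLabels(p4)
    ids <- sort(unique(lab4[lab4 > 0]))
    areas <- vapply(ids, function(i) sum(va[lab4 == i]), numeric(1))
    expect_true(all(diff(areas) <= 0))
})

test_that("area coverage sums per-label fractions of total mesh area", {
    m <- makeHexPatch(6)
    va <- vertexAreas(m)
    n <- nVertices(m)
    lut <- ColorLookupTable(data.frame(id = 1:2, name = c("a", "b"),
                                       R = c(10L, 20L), G = 0L, B = 0L,
                                       A = 255L, modality = "none"))
    full <- Parcellation(rep(1L, n), lut)
    expect_equal(areaCoverage(full, va)$total, 1.0)
    ## half-plane of a symmetric patch: exactly half the area
    v <- meshVertices(m)
    half <- Parcellation(ifelse(v[, 1] > 1e-9, 1L, 0L), lut)
    left <- Parcellation(ifelse(v[, 1] < -1e-9, 1L, 0L), lut)
    expect_equal(areaCoverage(half, va)$perLabel[["1"]] +
                     areaCoverage(left, va)$perLabel[["1"]],
                 1 - areaCoverage(Parcellation(
                     ifelse(abs(v[, 1]) <= 1e-9, 1L, 0L), lut), va)$total)
    expect_equal(unname(areaCoverage(half, va)$perLabel["1"]),
                 unname(areaCoverage(left, va)$perLabel["1"]))
    ## empty parcellation: zero coverage
    expect_equal(areaCoverage(Parcellation(rep(0L, n), lut), va)$total, 0)
    ## invariant under uniform rescaling
    m2 <- TriangleMesh(meshVertices(m) * 3.7, meshFaces(m))
    expect_equal(areaCoverage(half, vertexAreas(m2))$perLabel,
                 areaCoverage(half, va)$perLabel)
})
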