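# Shared fixture builders; everything is generated in code.

# ComplexMapResult directly from phases (unit amplitude, all significant)
phaseMap <- function(phi, amp = 1) {
    n <- length(phi)
    new("ComplexMapResult", coef = as.complex(amp * exp(1i * phi)),
        fStat = rep(Inf, n), dof = c(2, 20), pValue = rep(0, n),
        mask = rep(TRUE, n), nRuns = 1L)
}

# sphere with a smooth radial ripple ("crinkle"); seed controls the ripple
crinkledSphere <- function(seed, base, amplitude = 0.12, radius = 50) {
    v <- meshVertices(base)
    u <- v / sqrt(rowSums(v * v))
    set.seed(seed)
    a <- rnorm(3); b <- rnorm(3)
    r <- radius * (1 + amplitude * sin(4 * (u %*% a)) +
                       amplitude * cos(4 * (u %*% b)))
    TriangleMesh(u * as.vector(r), meshFaces(base))
}

# analytic pure-cosine run: amplitude 1, phase phi per vertex
cosineRun <- function(phi, nT = 64L, k = 8L, tr = 1, direction = 1L,
                      delayS = 0) {
    om <- 2 * pi * k / (nT * tr)
    t <- (0:(nT - 1L)) * tr
    ph <- if (direction > 0L) phi else -phi
    x <- t(vapply(ph, function(p) cos(om * t - p - om * delayS),
                  numeric(nT)))
    RunTimeSeries(x, trS = tr, nCycles = k, direction = direction)
}

wrapPi <- function(x) {
    w <- x - 2 * pi * round(x / (2 * pi))
    w[w <= -pi] <- w[w <= -pi] + 2 * pi
    w
}

# interior vertex indices of a hex patch (full 6-neighborhood)
hexInterior <- function(mesh) {
    which(lengths(vertexNeighbors(mesh)) == 6L)
}
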