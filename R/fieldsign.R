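## Tangential phase gradients, mean gradient direction, visual field sign,
## significance masking.

.wrapPi <- function(x) {
    w <- x - 2 * pi * round(x / (2 * pi))
    w[w <= -pi] <- w[w <= -pi] + 2 * pi
    w
}

#' Tangential gradient of a phase map
#'
#' For each vertex, neighbor displacements are projected into the tangent
#' plane, neighbor phases are unwrapped relative to the center phase
#' (differences mapped to `(-pi, pi]`), and the 2D gradient is the least
#' squares fit of phase difference against tangent displacement. The
#' gradient points in the steepest uphill direction in phase, in rad/mm,
#' expressed in each vertex's tangent frame. Vertices that are masked or
#' have fewer than two non-collinear defined neighbors are invalid.
#'
#' @param map a [ComplexMapResult-class] carrying the phase.
#' @param mesh the [TriangleMesh-class].
#' @param frames matching [TangentFrame-class] from [tangentFrames()].
#' @return A [GradientField-class].
#' @export
phaseGradient <- function(map, mesh, frames) {
    stopifnot(is(map, "ComplexMapResult"), is(mesh, "TriangleMesh"),
              is(frames, "TangentFrame"))
    n <- nVertices(mesh)
    if (length(mapCoef(map)) != n) stop("map does not match mesh")
    phi <- phaseRad(map)
    def <- mapMask(map)
    nbrs <- vertexNeighbors(mesh)
    v <- meshVertices(mesh)
    e1 <- frameVectors(frames, "e1"); e2 <- frameVectors(frames, "e2")
    gx <- gy <- rep(NA_real_, n)
    valid <- logical(n)
    for (i in seq_len(n)) {
        if (!def[i]) next
        j <- nbrs[[i]]
        j <- j[def[j]]
        if (length(j) < 2L) next
        d <- v[j, , drop = FALSE] - matrix(v[i, ], length(j), 3L, byrow = TRUE)
        A <- cbind(d %*% e1[i, ], d %*% e2[i, ])
        b <- .wrapPi(phi[j] - phi[i])
        AtA <- crossprod(A)
        if (abs(det(AtA)) < 1e-12 * (sum(A * A) / 2)^2) next  # collinear
        g <- solve(AtA, crossprod(A, b))
        gx[i] <- g[1]; gy[i] <- g[2]
        valid[i] <- TRUE
    }
    new("GradientField", gx = gx, gy = gy, valid = valid)
}

#' Mean gradient direction over a region
#'
#' The "white arrow" of an area: the normalized vector mean of valid
#' per-vertex gradients and the mean gradient magnitude. If opposing
#' gradients cancel, the result is flagged degenerate.
#'
#' @param field a [GradientField-class].
#' @param region integer vector of vertex indices.
#' @return list with `direction` (unit 2-vector, `NA` if degenerate),
#'   `magnitude` (mean gradient norm, rad/mm) and `degenerate` flag.
#' @export
meanGradientDirection <- function(field, region) {
    if (length(region) < 1L) stop("region is empty")
    ok <- region[gradientValid(field)[region]]
    if (length(ok) < 1L) stop("no valid gradients in region")
    G <- gradients(field)[ok, , drop = FALSE]
    vsum <- colSums(G)
    mag <- mean(sqrt(rowSums(G * G)))
    nv <- sqrt(sum(vsum^2))
    if (nv < 1e-12 * length(ok) * max(mag, 1e-300))
        return(list(direction = c(NA_real_, NA_real_), magnitude = mag,
                    degenerate = TRUE))
    list(direction = unname(vsum / nv), magnitude = mag, degenerate = FALSE)
}

#' Visual field sign from two gradient fields
#'
#' Per vertex, the sign of the component along the vertex normal of
#' `grad(ecc) x grad(polar)`: `+1` is declared non-mirror-image and `-1`
#' mirror-image. The sign is 0 (undefined) wherever either gradient is
#' invalid or its norm falls below the magnitude floor; the default floor
#' is 10% of each field's median valid gradient norm, which suppresses
#' sign noise at gradient reversals.
#'
#' @param polarGrad,eccGrad [GradientField-class] objects on the same mesh.
#' @param frames the shared [TangentFrame-class] (fixes the handedness the
#'   sign convention is defined in).
#' @param magnitudeFloor gradient-norm floor in rad/mm, or `NULL` for the
#'   default.
#' @return A [FieldSignMap-class].
#' @export
visualFieldSign <- function(polarGrad, eccGrad, frames,
                            magnitudeFloor = NULL) {
    np <- length(gradientValid(polarGrad))
    if (length(gradientValid(eccGrad)) != np)
        stop("gradient fields live on different meshes")
    if (nrow(frameVectors(frames)) != np)
        stop("frames do not match the gradient fields")
    Gp <- gradients(polarGrad); Ge <- gradients(eccGrad)
    npol <- sqrt(rowSums(Gp * Gp)); necc <- sqrt(rowSums(Ge * Ge))
    ok <- gradientValid(polarGrad) & gradientValid(eccGrad)
    if (is.null(magnitudeFloor)) {
        fp <- 0.1 * median(npol[gradientValid(polarGrad)], na.rm = TRUE)
        fe <- 0.1 * median(necc[gradientValid(eccGrad)], na.rm = TRUE)
    } else {
        fp <- fe <- magnitudeFloor
    }
    ok <- ok & !is.na(npol) & !is.na(necc) & npol >= fp & necc >= fe &
        npol > 0 & necc > 0
    cz <- Ge[, 1] * Gp[, 2] - Ge[, 2] * Gp[, 1]   # (grad ecc x grad polar) . n
    s <- integer(np)
    s[ok] <- ifelse(cz[ok] > 0, 1L, ifelse(cz[ok] < 0, -1L, 0L))
    new("FieldSignMap", sign = s)
}

#' Threshold a map's p-values into a significance mask
#'
#' @param map a [ComplexMapResult-class].
#' @param alpha significance level; vertices with `p <= alpha` are `TRUE`.
#'   The `p = 0` sentinel of noiseless vertices passes any alpha.
#' @return logical vector, `TRUE` where defined and significant.
#' @export
significanceMask <- function(map, alpha) {
    stopifnot(is(map, "ComplexMapResult"))
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
    p <- pValues(map)
    out <- !is.na(p) & mapMask(map) & p <= alpha
    out
}
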