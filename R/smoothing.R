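## Nearest-neighbor surface smoothing and FWHM estimation.

#' Nearest-neighbor surface smoothing
#'
#' Each step replaces every defined vertex value by the unweighted mean of
#' itself and its defined neighbors. The definedness mask never changes: a
#' vertex stays defined iff it started defined, and undefined neighbors are
#' simply left out of the mean. Complex values are averaged componentwise,
#' which is how phase maps must be smoothed to avoid wrap artifacts.
#'
#' @param x a [VertexScalarMap-class], or a numeric or complex vector with
#'   `NA` marking undefined vertices.
#' @param mesh the [TriangleMesh-class] the values live on.
#' @param steps non-negative number of smoothing steps.
#' @return Same type as `x`.
#' @export
nnSmooth <- function(x, mesh, steps = 1L) {
    steps <- as.integer(steps)
    if (is.na(steps) || steps < 0L) stop("steps must be >= 0")
    stopifnot(is(mesh, "TriangleMesh"))
    isMap <- is(x, "VertexScalarMap")
    vals <- if (isMap) mapValues(x) else x
    if (length(vals) != nVertices(mesh))
        stop("value length does not match mesh vertex count")
    if (steps == 0L) return(x)
    defined <- if (isMap) mapMask(x) else !is.na(vals)
    A <- .adjacencyMatrix(mesh, includeSelf = TRUE)
    d <- as.numeric(defined)
    den <- as.numeric(A %*% d)
    v <- vals
    v[!defined] <- 0
    for (s in seq_len(steps)) {
        if (is.complex(vals)) {
            num <- as.vector(A %*% Re(v)) + 1i * as.vector(A %*% Im(v))
        } else {
            num <- as.vector(A %*% v)
        }
        v <- ifelse(den > 0, num / den, 0)
        v[!defined] <- 0
    }
    v[!defined] <- NA
    if (isMap) VertexScalarMap(as.numeric(v), defined) else v
}

#' FWHM of the nearest-neighbor smoothing kernel
#'
#' Measures the impulse response of [nnSmooth()] after `steps` steps at the
#' central vertex of an approximately regular patch and fits an isotropic
#' 2D Gaussian by moment matching: the fitted `sigma^2` is half the mean
#' squared radius of the impulse response, so that repeated smoothing adds
#' kernel variances exactly as convolution does. The returned value is
#' `2 * sqrt(2 log 2) * sigma` in mm. By convention `steps = 0` gives 0.
#' The patch must be large enough that the kernel support does not reach
#' the border.
#'
#' @param mesh an approximately regular bordered patch (see
#'   [makeHexPatch()]).
#' @param steps positive number of smoothing steps.
#' @return FWHM estimate in mm.
#' @export
smoothingFwhm <- function(mesh, steps) {
    stopifnot(is(mesh, "TriangleMesh"))
    steps <- as.integer(steps)
    if (is.na(steps) || steps < 0L) stop("steps must be >= 0")
    if (steps == 0L) return(0)
    v <- meshVertices(mesh)
    ctr <- colMeans(v)
    center <- which.min(rowSums(sweep(v, 2, ctr)^2))
    imp <- numeric(nVertices(mesh))
    imp[center] <- 1
    resp <- nnSmooth(imp, mesh, steps)
    ## border = vertices on an edge used by only one face
    f <- meshFaces(mesh)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ue <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(ue[, 1], ue[, 2])
    borderV <- unique(as.vector(ue[key %in% names(which(table(key) == 1L)), ]))
    if (sum(resp[borderV]) > 1e-4 * sum(resp))
        stop("patch too small for the kernel support at ", steps, " steps")
    r2 <- rowSums(sweep(v, 2, v[center, ])^2)
    ## E[r^2] = 2 sigma^2 for an isotropic 2D Gaussian
    sigma <- sqrt(sum(resp * r2) / (2 * sum(resp)))
    2 * sqrt(2 * log(2)) * sigma
}
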