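## On-disk run container: big-endian; 4-byte magic "TMRN"; int32 version
## (1); int32 N; int32 T; float64 trS; int32 nCycles; int32 direction;
## int32 modality code (1 visual, 2 auditory, 3 somatomotor); then N x T
## float32 data, row-major.

.RUN_MAGIC <- charToRaw("TMRN")
.runModalities <- c("visual", "auditory", "somatomotor")

#' Read / write a run time-series container
#'
#' A flat binary container for one scan: per-vertex time series plus the
#' TR, cycle count, direction and modality metadata. Round trip preserves
#' everything up to float32 data precision.
#'
#' @param path file path.
#' @return [readRun()] returns a [RunTimeSeries-class].
#' @export
readRun <- function(path) {
    if (!file.exists(path)) stop("run file does not exist: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", n = 4L)
    if (!identical(magic, .RUN_MAGIC))
        stop("not a run container (bad magic): ", path)
    ver <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    if (!identical(ver, 1L)) stop("unsupported run container version ", ver)
    dims <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
    trS <- readBin(con, "numeric", n = 1L, size = 8L, endian = "big")
    meta <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    dat <- readBin(con, "numeric", n = dims[1] * dims[2], size = 4L,
                   endian = "big")
    if (length(dat) < dims[1] * dims[2]) stop("truncated run container")
    RunTimeSeries(matrix(dat, dims[1], dims[2], byrow = TRUE), trS = trS,
                  nCycles = meta[1], direction = meta[2],
                  modality = .runModalities[meta[3]])
}

#' @rdname readRun
#' @param run a [RunTimeSeries-class].
#' @export
writeRun <- function(run, path) {
    stopifnot(is(run, "RunTimeSeries"))
    validObject(run)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(.RUN_MAGIC, con)
    writeBin(1L, con, size = 4L, endian = "big")
    writeBin(dim(runData(run)), con, size = 4L, endian = "big")
    writeBin(runTr(run), con, size = 8L, endian = "big")
    writeBin(c(runCycles(run), runDirection(run),
               match(run@modality, .runModalities)), con, size = 4L,
             endian = "big")
    writeBin(as.numeric(t(runData(run))), con, size = 4L, endian = "big")
    invisible(path)
}
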