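## ASCII color lookup table I/O.
## Dialect: whitespace-separated "id name R G B A" per line; '#' starts a
## comment; writeLUT emits the modality as a trailing "# modality=..." tag,
## which readLUT parses when present.

#' Read an ASCII color lookup table
#'
#' @param path path to the LUT text file.
#' @return A [ColorLookupTable-class]. Duplicate ids, names or packed
#'   colors raise an error naming the offending line.
#' @export
readLUT <- function(path) {
    if (!file.exists(path)) stop("LUT file does not exist: ", path)
    lines <- readLines(path, warn = FALSE)
    rows <- list()
    for (ln in seq_along(lines)) {
        raw <- lines[ln]
        modality <- "none"
        hash <- regexpr("#", raw, fixed = TRUE)
        if (hash > 0) {
            comment <- substring(raw, hash + 1L)
            m <- regmatches(comment,
                            regexpr("modality=[A-Za-z]+", comment))
            if (length(m) && nzchar(m))
                modality <- sub("modality=", "", m)
            raw <- substring(raw, 1L, hash - 1L)
        }
        tok <- strsplit(trimws(raw), "[[:space:]]+")[[1]]
        tok <- tok[nzchar(tok)]
        if (length(tok) == 0L) next
        if (length(tok) != 6L)
            stop("LUT line ", ln, ": expected 'id name R G B A', got ",
                 length(tok), " fields")
        nums <- suppressWarnings(as.integer(tok[c(1, 3:6)]))
        if (anyNA(nums)) stop("LUT line ", ln, ": non-integer field")
        rows[[length(rows) + 1L]] <- data.frame(
            id = nums[1], name = tok[2], R = nums[2], G = nums[3],
            B = nums[4], A = nums[5], modality = modality,
            line = ln, stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(ColorLookupTable(data.frame(
            id = integer(), name = character(), R = integer(),
            G = integer(), B = integer(), A = integer(),
            modality = character())))
    e <- do.call(rbind, rows)
    dup <- function(x) which(duplicated(x))[1]
    if (anyDuplicated(e$id))
        stop("LUT line ", e$line[dup(e$id)], ": duplicate region id")
    if (anyDuplicated(e$name))
        stop("LUT line ", e$line[dup(e$name)], ": duplicate region name")
    packed <- e$R + e$G * 256 + e$B * 65536
    if (anyDuplicated(packed))
        stop("LUT line ", e$line[dup(packed)], ": duplicate RGB color")
    ColorLookupTable(e[, c("id", "name", "R", "G", "B", "A", "modality")])
}

#' Write an ASCII color lookup table
#'
#' Inverse of [readLUT()] (round trip modulo whitespace normalization).
#'
#' @param lut a valid [ColorLookupTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLUT <- function(lut, path) {
    stopifnot(is(lut, "ColorLookupTable"))
    validObject(lut)
    e <- lutEntries(lut)
    header <- c("# Color lookup table: id name R G B A  # modality=<tag>")
    body <- sprintf("%-4d %-14s %3d %3d %3d %3d  # modality=%s",
                    e$id, e$name, e$R, e$G, e$B, e$A, e$modality)
    writeLines(c(header, body), path)
    invisible(path)
}

#' Count LUT entries per modality
#'
#' @param lut a [ColorLookupTable-class].
#' @return named integer vector with one element per modality tag
#'   (`visual`, `auditory`, `somatosensory`, `motor`, `none`) plus `total`.
#' @export
modalityCounts <- function(lut) {
    stopifnot(is(lut, "ColorLookupTable"))
    e <- lutEntries(lut)
    tab <- table(factor(e$modality, levels = .lutModalities))
    out <- as.integer(tab)
    names(out) <- names(tab)
    c(out, total = nrow(e))
}
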