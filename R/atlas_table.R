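## The 117-region atlas color table: region abbreviations and modality
## grouping of the published cortical-map parcellation, in annotation-file
## order. The distributed files do not print RGB values, so colors here are
## synthetic: generated deterministically inside the hue family conventions
## of the atlas (visual areas blue/purple, auditory red/brown, somatomotor
## green/yellow).

.atlasVisual <- c(
    "V1-", "V1+", "V2-", "V2+", "V3", "VP",
    "DI", "V3A", "V3B", "OPA", "LO1", "LO2", "LO3", "PGp",
    "V6", "V6A", "aPOS", "POm", "ProS1", "ProS2",
    "MT-", "MT+", "MTc", "MSTd", "MSTv", "FSTd", "STV1", "STV2",
    "7b-PICv", "7b-PICv,s",
    "V4v", "hV4", "V8", "PITd", "PH", "FFC", "VVC", "VO1", "VO2",
    "V7", "cIPS", "LIP0", "LIP1", "PEc", "IPS4", "IPS5", "aPCu1", "aPCu2",
    "VIP1v", "VIP1v,s", "VIP2v", "VIP2v,s",
    "dmFEF", "FEF", "6a", "DLPFC", "DLPFCa")

.atlasAuditory <- c(
    "A1", "R", "RT",
    "MM", "RM", "CM",
    "CL", "ML", "AL", "RTL",
    "CP", "MPc", "MPr", "RP", "TA2", "TA3",
    "CA4", "MA4", "RA4",
    "CA5", "MA5", "RA5",
    "43aud",
    "PSaud1", "PSaud2",
    "3aud",
    "dmFAF", "p32aud",
    "PZa,v,s", "PZa,s", "DLPFCaud", "IFSp", "45aud", "FOPaud")

.atlasSomatosensory <- c(
    "3b-fa", "3b-ha", "3b-ft", "3a-fa", "3a-ha", "3a-ft",
    "1-fa", "1-ha", "1-ft", "2",
    "5m", "pCI", "5L", "PFt", "AIPv,s",
    "S-II", "PV", "Ig", "FOP2", "PHt")

.atlasMotor <- c("4-fa", "4-ha", "4-fo", "6d", "SMA1", "SMA2")

## hue families (hsv hue in [0,1])
.atlasHueRange <- list(
    visual        = c(0.55, 0.80),   # blue through purple
    auditory      = c(0.00, 0.08),   # red through brown/orange
    somatosensory = c(0.15, 0.40),   # yellow through green
    motor         = c(0.15, 0.40))

## small deterministic LCG so fixture colors never touch the global RNG
.lcgUnif <- function(n, seed) {
    state <- as.double(seed %% 2147483647)
    out <- numeric(n)
    for (i in seq_len(n)) {
        state <- (16807 * state) %% 2147483647
        out[i] <- state / 2147483647
    }
    out
}

#' The packaged 117-region atlas color lookup table
#'
#' Returns the atlas LUT: 117 modality-tagged regions (57 visual, 34
#' auditory, 20 somatosensory, 6 motor) in annotation-file order, with
#' deterministic synthetic colors drawn inside each modality's hue family
#' (visual blue/purple, auditory red/brown, somatomotor green/yellow).
#' The same table ships as the plain-text file
#' `extdata/CsurfColorLUT_synthetic.txt`.
#'
#' @return A [ColorLookupTable-class] with 117 entries.
#' @export
atlasLUT <- function() {
    names <- c(.atlasVisual, .atlasAuditory, .atlasSomatosensory, .atlasMotor)
    modality <- rep(c("visual", "auditory", "somatosensory", "motor"),
                    c(length(.atlasVisual), length(.atlasAuditory),
                      length(.atlasSomatosensory), length(.atlasMotor)))
    n <- length(names)
    col <- matrix(0L, n, 3L)
    for (mod in unique(modality)) {
        idx <- which(modality == mod)
        k <- length(idx)
        rng <- .atlasHueRange[[mod]]
        hue <- rng[1] + (rng[2] - rng[1]) * (seq_len(k) - 0.5) / k
        u <- .lcgUnif(2L * k, 20220527L + match(mod, names(.atlasHueRange)))
        sat <- 0.55 + 0.40 * u[seq_len(k)]
        val <- 0.55 + 0.40 * u[k + seq_len(k)]
        col[idx, ] <- t(grDevices::col2rgb(grDevices::hsv(hue, sat, val)))
    }
    ## enforce unique, nonzero packed colors
    repeat {
        packed <- col[, 1] + col[, 2] * 256 + col[, 3] * 65536
        bad <- duplicated(packed) | packed == 0
        if (!any(bad)) break
        col[bad, 2] <- (col[bad, 2] + 1L) %% 256L
    }
    ColorLookupTable(data.frame(
        id = seq_len(n), name = names,
        R = col[, 1], G = col[, 2], B = col[, 3], A = 255L,
        modality = modality, stringsAsFactors = FALSE))
}
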