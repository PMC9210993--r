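smallLut <- function() {
    ColorLookupTable(data.frame(
        id = c(1L, 2L, 3L),
        name = c("red", "green", "blue"),
        R = c(255L, 0L, 0L), G = c(0L, 255L, 0L), B = c(0L, 0L, 255L),
        A = 255L, modality = c("visual", "auditory", "motor")))
}

test_that("packed colors follow R + G*2^8 + B*2^16", {
    expect_identical(packedColors(smallLut()), c(255L, 65280L, 16711680L))
})

test_that("LUT files round-trip and validation reports line numbers", {
    lut <- smallLut()
    tf <- withr::local_tempfile()
    writeLUT(lut, tf)
    expect_identical(lutEntries(readLUT(tf)), lutEntries(lut))
    ## empty file -> empty LUT
    writeLines(character(), tf)
    expect_identical(length(readLUT(tf)), 0L)
    ## comments and blank lines ignored; missing modality tag -> none
    writeLines(c("# a comment", "", "7 solo 1 2 3 255"), tf)
    solo <- readLUT(tf)
    expect_identical(lutEntries(solo)$modality, "none")
    ## duplicate RGB is an invariant violation with a line number
    writeLines(c("1 a 9 9 9 255", "2 b 9 9 9 255"), tf)
    expect_error(readLUT(tf), "line 2.*duplicate RGB")
    writeLines(c("1 a 1 2 3 255", "1 b 4 5 6 255"), tf)
    expect_error(readLUT(tf), "duplicate region id")
})

test_that("the packaged atlas table has 117 regions in four modalities", {
    lut <- atlasLUT()
    tf <- withr::local_tempfile()
    writeLUT(lut, tf)
    counts <- modalityCounts(readLUT(tf))
    expect_identical(counts[["total"]], 117L)
    expect_identical(counts[["visual"]], 57L)
    expect_identical(counts[["auditory"]], 34L)
    expect_identical(counts[["somatosensory"]], 20L)
    expect_identical(counts[["motor"]], 6L)
    ## the shipped plain-text fixture is the same table
    shipped <- readLUT(system.file("extdata", "CsurfColorLUT_synthetic.txt",
                                   package = "topomapr"))
    expect_identical(lutEntries(shipped), lutEntries(lut))
    ## abbreviations unique, commas preserved verbatim
    e <- lutEntries(lut)
    expect_false(anyDuplicated(e$name) > 0)
    expect_true("7b-PICv,s" %in% e$name)
    expect_true("PZa,v,s" %in% e$name)
    ## hue families: visual blue/purple, auditory red/brown,
    ## somatomotor green/yellow
    h <- grDevices::rgb2hsv(t(as.matrix(e[, c("R", "G", "B")])))[1, ]
    expect_true(all(h[e$modality == "visual"] >= 0.5 &
                        h[e$modality == "visual"] <= 0.85))
    expect_true(all(h[e$modality == "auditory"] <= 0.1))
    som <- e$modality %in% c("somatosensory", "motor")
    expect_true(all(h[som] >= 0.1 & h[som] <= 0.45))
    ## modality counts on degenerate inputs
    empty <- ColorLookupTable(data.frame(id = integer(), name = character(),
                                         R = integer(), G = integer(),
                                         B = integer(), A = integer(),
                                         modality = character()))
    expect_true(all(modalityCounts(empty) == 0L))
})

test_that("annotations round-trip bit-for-bit with their color table", {
    set.seed(31)
    m <- makeHexPatch(5)
    lut <- smallLut()
    lab <- sample(c(0L, 1L, 2L, 3L), nVertices(m), replace = TRUE)
    parc <- Parcellation(lab, lut)
    annot <- parcellationToAnnotation(parc)
    expect_identical(annotPacked(annot)[lab == 1L][1], 255L)
    tf <- withr::local_tempfile()
    writeAnnotation(annot, tf)
    back <- readAnnotation(tf, m)
    expect_identical(annotPacked(back), annotPacked(annot))
    expect_identical(lutEntries(parcLut(back))[, c("id", "name", "R", "G",
                                                   "B", "A")],
                     lutEntries(lut)[, c("id", "name", "R", "G", "B", "A")])
    ## write(read(x)) is bit-identical
    tf2 <- withr::local_tempfile()
    writeAnnotation(back, tf2)
    expect_identical(readBin(tf, "raw", file.size(tf)),
                     readBin(tf2, "raw", file.size(tf2)))
    ## inverse recovers the parcellation exactly
    expect_identical(regionLabels(annotationToParcellation(back)), lab)
    ## vertex-count mismatch is an error
    expect_error(readAnnotation(tf, makeHexPatch(4)), "vertices")
})

test_that("unknown packed colors read as unlabeled with a warning", {
    m <- makeHexPatch(2)
    lut <- smallLut()
    tf <- withr::local_tempfile()
    writeAnnotation(parcellationToAnnotation(
        Parcellation(rep(1L, nVertices(m)), lut)), tf)
    ## corrupt one packed color to a value outside the table
    raw <- readBin(tf, "raw", file.size(tf))
    orphan <- writeBin(99999L, raw(), size = 4L, endian = "big")
    raw[9:12] <- orphan                 # second int32 = first packed color
    writeBin(raw, tf)
    expect_warning(back <- readAnnotation(tf, m), "absent")
    expect_true(is.na(annotPacked(back)[1]))
    expect_false(anyNA(annotPacked(back)[-1]))
})

test_that("empty parcellations translate to all-sentinel annotations", {
    lut <- smallLut()
    parc <- Parcellation(rep(0L, 10), lut)
    annot <- parcellationToAnnotation(parc)
    expect_true(all(is.na(annotPacked(annot))))
    expect_identical(regionLabels(annotationToParcellation(annot)),
                     rep(0L, 10))
})

test_that("label resampling uses nearest spherical neighbors", {
    lut <- smallLut()
    src <- makeSphere(1, radius = 100)
    set.seed(4)
    lab <- sample(c(NA_integer_, packedColors(lut)), nVertices(src),
                  replace = TRUE)
    annot <- Annotation(lab, lut)
    ## identity on identical meshes
    expect_identical(annotPacked(resampleLabels(annot, src, src)), lab)
    ## subdivided destination: each child takes a parent label;
    ## compare against a brute-force nearest-vertex oracle
    dst <- makeSphere(2, radius = 100)
    out <- resampleLabels(annot, src, dst)
    us <- meshVertices(src) / 100
    ud <- meshVertices(dst) / 100
    oracle <- vapply(seq_len(nrow(ud)), function(i) {
        d <- as.vector(us %*% ud[i, ])
        which(d >= max(d) - 1e-12)[1]        # lowest index wins ties
    }, integer(1))
    expect_identical(annotPacked(out), lab[oracle])
    ## single-label source stays single-label
    one <- Annotation(rep(255L, nVertices(src)), lut)
    expect_true(all(annotPacked(resampleLabels(one, src, dst)) == 255L))
    ## non-spherical input rejected
    expect_error(resampleLabels(annot, src, makeHexPatch(3)),
                 "not spherical")
})

test_that("JSON export carries ids, names, colors and vertex labels", {
    m <- makeHexPatch(2)
    lut <- smallLut()
    lab <- rep(c(0L, 1L, 2L), length.out = nVertices(m))
    annot <- parcellationToAnnotation(Parcellation(lab, lut))
    tf <- withr::local_tempfile(fileext = ".json")
    exportLabelsJSON(annot, tf)
    doc <- jsonlite::read_json(tf, simplifyVector = TRUE)
    expect_identical(doc$regions$name, c("red", "green", "blue"))
    expect_identical(as.integer(doc$vertex_region_id), lab)
})
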