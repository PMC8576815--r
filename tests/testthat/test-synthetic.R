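test_that("synthetic ensemble generation is a pure function of spec and seed", {
    spec <- syntheticEnsembleSpec(nFrames = 200)
    a <- makeSyntheticEnsemble(spec)
    b <- makeSyntheticEnsemble(spec)
    expect_identical(coordArray(a$ensemble), coordArray(b$ensemble))
    other <- makeSyntheticEnsemble(syntheticEnsembleSpec(nFrames = 200,
                                                         seed = 1))
    expect_false(identical(coordArray(a$ensemble),
                           coordArray(other$ensemble)))
    ## generation does not disturb the caller's RNG stream
    set.seed(123); x1 <- rnorm(1)
    set.seed(123); invisible(makeSyntheticEnsemble(spec)); x2 <- rnorm(1)
    expect_identical(x1, x2)
})

test_that("degenerate ensemble specs are rejected", {
    expect_error(syntheticEnsembleSpec(amplitude = 0), "amplitude")
    expect_error(syntheticEnsembleSpec(nFrames = 1), "nFrames")
    expect_error(syntheticEnsembleSpec(background = 0.95,
                                       plantedLevel = 0.9), "background")
    expect_error(syntheticEnsembleSpec(plantedPath = c(3, 5)), "contiguous")
    expect_error(syntheticEnsembleSpec(plantedPath = 1:8), "2..6")
})

test_that("planted-path residues are mutually within the contact cutoff and lobes connect only through them", {
    syn <- makeSyntheticEnsemble(syntheticEnsembleSpec(nFrames = 2))
    planted <- 28:33
    lay <- syn$layout
    dmat <- as.matrix(dist(lay))
    expect_lt(max(dmat[planted, planted]), 6.0)
    ## non-planted residues touching the cluster: exactly the two entries
    touching <- which(apply(dmat[, planted], 1, min) < 6.0)
    expect_setequal(setdiff(touching, planted), c(27, 34))
    ## chain is self-avoiding: non-neighbour beads keep their distance
    offDiag <- dmat[abs(row(dmat) - col(dmat)) > 1]
    expect_gt(min(offDiag[offDiag > 0]), 2.5)
})

test_that("the empirical DCCM converges to the prescribed (repaired) correlation structure", {
    syn <- makeSyntheticEnsemble(syntheticEnsembleSpec(nFrames = 5000))
    expect_lt(syn$repairDelta, 0.1)
    C <- matrixValues(computeDccm(syn$ensemble))
    expect_lt(max(abs(C - syn$truthCorrelation)), 0.1)   # ~4 sigma at n = 5000
})

test_that("sequence generation applies substitutions and the insertion with a consistent truth table", {
    sq <- makeSequences(syntheticSequenceSpec(length = 60,
        mutations = data.frame(position = c(10L, 50L), to = c("W", "W"),
                               stringsAsFactors = FALSE),
        insertionPosition = 30, insertionLength = 20, seed = 3))
    expect_equal(nchar(sq$target), 80L)
    expect_equal(sq$truth$targetPosition, c(10L, 70L))
    tgt <- strsplit(sq$target, "")[[1]]
    expect_equal(tgt[c(10, 70)], c("W", "W"))
    ## empty spec: target equals template
    sq0 <- makeSequences(syntheticSequenceSpec(length = 40,
                                               insertionLength = 0, seed = 3))
    expect_identical(sq0$template, sq0$target)
    expect_equal(nrow(sq0$truth), 0L)
})

test_that("inconsistent 'from' residues and no-op substitutions are rejected", {
    base <- makeSequences(syntheticSequenceSpec(length = 30,
                                                insertionLength = 0,
                                                seed = 6))
    res5 <- substr(base$template, 5, 5)
    wrong <- setdiff(c("A", "C", "D"), res5)[1]
    expect_error(makeSequences(syntheticSequenceSpec(length = 30,
        mutations = data.frame(position = 5L, from = wrong, to = "W"),
        insertionLength = 0, seed = 6)), "inconsistent")
    expect_error(makeSequences(syntheticSequenceSpec(length = 30,
        mutations = data.frame(position = 5L, to = res5),
        insertionLength = 0, seed = 6)), "do not change")
})

test_that("two-basin sampling is seeded and degenerate populations collapse to one basin", {
    a <- makeTwoBasinSamples(n = 500, seed = 5)
    b <- makeTwoBasinSamples(n = 500, seed = 5)
    expect_identical(a$samples, b$samples)
    one <- makeTwoBasinSamples(populations = c(1, 0), n = 300, seed = 1)
    expect_true(all(one$component == 1L))
    expect_true(all(abs(one$samples$s - 0.85) < 0.3))
    expect_error(makeTwoBasinSamples(populations = c(0.5, 0.4)), "sum to 1")
})

test_that("synthetic PDB and FASTA writers round-trip through the package readers", {
    syn <- makeSyntheticEnsemble(syntheticEnsembleSpec(nFrames = 3))
    pdb <- tempfile(fileext = ".pdb")
    writeEnsemblePdb(syn$ensemble, pdb)
    back <- readEnsemble(pdb)
    expect_equal(coordArray(back), coordArray(syn$ensemble),
                 tolerance = 1e-3)   # PDB fixed-point precision
    sq <- makeSequences(syntheticSequenceSpec(length = 25,
                                              insertionLength = 0,
                                              seed = 2))
    fa <- tempfile(fileext = ".fasta")
    writeFasta(c(template = sq$template), fa)
    expect_equal(as.character(Biostrings::readAAStringSet(fa)[[1]]),
                 sq$template)
})
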