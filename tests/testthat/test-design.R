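test_that("identical sequences align to the identity map with no gaps", {
    m <- alignPair("HEAGAWGHEE", "HEAGAWGHEE")
    expect_equal(mapPositions(m, 1:10), 1:10)
    expect_true(all(!is.na(m@columns$template)))
    expect_true(all(!is.na(m@columns$target)))
})

test_that("a 20-residue insertion shifts downstream target numbering by exactly 20", {
    sq <- makeSequences(syntheticSequenceSpec(length = 120,
        insertionPosition = 100, insertionLength = 20, seed = 1))
    m <- alignPair(sq$template, sq$target)
    up <- 1:95
    expect_equal(mapPositions(m, up), up)
    down <- 105:120     # clear of junction wobble in gap placement
    expect_equal(mapPositions(m, down), down + 20L)
})

test_that("alignment score equals an exhaustive Gotoh dynamic-programming oracle", {
    pairs <- list(c("WFAKDEGH", "WFKDEAGH"),
                  c("AKEFGHIK", "AEFGHKIK"),
                  c("HEAGAWGHEE", "PAWHEAE"))
    for (p in pairs) {
        m <- alignPair(p[1], p[2])
        expect_equal(alignmentScore(m), oracleAffineScore(p[1], p[2]),
                     tolerance = 1e-9)
    }
})

test_that("non-amino-acid characters are rejected", {
    expect_error(alignPair("ACDXJ1", "ACD"), "non-amino-acid")
})

test_that("candidate mutations appear only where aligned residues differ", {
    expect_equal(nrow(candidateMutations(c(1, 3, 5), "AKEFG", "AKEFG")), 0L)
    cm <- candidateMutations(c(2, 4), "AKEFG", "AREFG")
    expect_equal(cm$label, "R2K")
    expect_equal(cm$targetResidue, "R")
    expect_equal(cm$templateResidue, "K")
})

test_that("a fixture mirroring the design convention yields label A56E", {
    ## template has E where the target has A at target position 56
    set.seed(8)
    tpl <- paste(sample(c("G","S","T","V","L","I","F","K","R","D"),
                        60, replace = TRUE), collapse = "")
    tplChars <- strsplit(tpl, "")[[1]]
    tplChars[56] <- "E"
    tgtChars <- tplChars; tgtChars[56] <- "A"
    cm <- candidateMutations(56, paste(tplChars, collapse = ""),
                             paste(tgtChars, collapse = ""))
    expect_equal(cm$label, "A56E")
})

test_that("candidate count is bounded by the SPM position count and positions aligned to gaps are excluded", {
    sq <- makeSequences(syntheticSequenceSpec(length = 60,
        mutations = data.frame(position = c(10L, 20L), to = c("W", "W")),
        insertionPosition = 30, insertionLength = 5, seed = 2))
    pos <- c(5, 10, 20, 40, 55)
    cm <- candidateMutations(pos, sq$template, sq$target)
    expect_lte(nrow(cm), length(pos))
    expect_setequal(cm$templatePosition, c(10L, 20L))
    ## a template position aligned to a target gap is excluded, message logged
    tpl <- "ACDEFGHIKL"
    tgt <- "ACDEGHIKL"          # F deleted
    expect_message(cm2 <- candidateMutations(1:10, tpl, tgt), "gap")
    expect_equal(nrow(cm2), 0L)
})

test_that("swapping template and target reverses candidates consistently", {
    sq <- makeSequences(syntheticSequenceSpec(length = 50,
        mutations = data.frame(position = c(12L, 33L), to = c("W", "H")),
        insertionLength = 0, seed = 5))
    fwd <- candidateMutations(c(12, 33), sq$template, sq$target)
    rev <- candidateMutations(fwd$targetPosition, sq$target, sq$template)
    expect_equal(rev$targetResidue, fwd$templateResidue)
    expect_equal(rev$templateResidue, fwd$targetResidue)
    expect_equal(rev$targetPosition, fwd$templatePosition)
    ## idempotent and order-stable
    expect_identical(fwd, candidateMutations(c(33, 12), sq$template,
                                             sq$target))
})

test_that("mutation labels round-trip through parse and format", {
    labs <- c("A56E", "D62E", "S73T", "T207S", "N299A", "R300M")
    expect_equal(formatMutations(parseMutations(labs)), labs)
    expect_error(parseMutations("56E"), "malformed")
})

test_that("position overlap ignores substituted residue identity and is symmetric", {
    a <- c("N299S", "R300M")
    b <- c("A56E", "N299A", "R300M")
    expect_equal(positionOverlap(a, b)$nShared, 2L)     # N299S vs N299A share 299
    expect_equal(positionOverlap(a, b)$nShared,
                 positionOverlap(b, a)$nShared)
    expect_equal(positionOverlap(character(0), b)$nShared, 0L)
})

test_that("MSA conservation is the modal non-gap frequency with mostly-gap columns unscored", {
    prof <- msaConservation(c("KKAK", "KKA-", "KRA-", "KKA-"))
    expect_equal(prof@score[1], 1.0)            # all K
    expect_equal(prof@score[2], 0.75)           # K,K,R,K
    expect_true(is.na(prof@score[4]))           # 3/4 gaps -> unscored
    expect_equal(prof@gapFraction[4], 0.75)
    ## record order permutation leaves scores unchanged
    prof2 <- msaConservation(c("KRA-", "KKA-", "KKAK", "KKA-"))
    expect_equal(prof2@score, prof@score)
    expect_error(msaConservation(c("AB", "ABC")), "ragged")
    expect_error(msaConservation("AAAA"), "at least 2")
})

test_that("planted per-column conservation levels are recovered at depth 50", {
    levels <- c(0.95, 0.8, 0.6)
    sq <- makeSequences(syntheticSequenceSpec(length = 120,
                                              insertionLength = 0, seed = 4))
    msa <- makeMsa(sq$template, depth = 50,
                   conservation = rep(levels, length.out = 120), seed = 1)
    prof <- msaConservation(msa$msa)
    for (lev in levels) {
        idx <- which(abs(msa$truth - lev) < 1e-9)
        expect_lt(abs(mean(prof@score[idx]) - lev), 0.05)
    }
})

test_that("positions are banded high, low or intermediate by threshold", {
    prof <- new("ConservationProfile",
                score = c(0.95, 0.65, 0.80, NA), gapFraction = c(0, 0, 0, 0.8),
                high = 0.90, low = 0.70, nSequences = 10L)
    expect_equal(unname(bandPositions(prof, 1:4)),
                 c("high", "low", "intermediate", "unscored"))
    expect_error(bandPositions(prof, 5), "outside")
    expect_equal(unname(conservationBandCounts(prof)), c(1L, 1L, 1L, 1L))
})
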