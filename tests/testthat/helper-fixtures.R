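## Shared fixture builders, all constructed in code.

fixturePdb <- function() {
    system.file("extdata", "ensemble_3res_5frame.pdb", package = "alloSPM")
}

## Random small ensemble around a stretched chain.
randomEnsemble <- function(nFrames = 6, n = 5, seed = 7, amp = 0.3) {
    set.seed(seed)
    base <- cbind(3.8 * seq_len(n), 0, 0)
    coords <- array(NA_real_, c(nFrames, n, 3))
    for (f in seq_len(nFrames))
        coords[f, , ] <- base + matrix(rnorm(3 * n, 0, amp), n, 3)
    ConformationalEnsemble(coords)
}

randomRotation <- function(seed = 1) {
    set.seed(seed)
    qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

rotateEnsemble <- function(ens, R, shift = c(0, 0, 0)) {
    coords <- coordArray(ens)
    for (f in seq_len(dim(coords)[1]))
        coords[f, , ] <- coords[f, , ] %*% t(R) +
            matrix(shift, dim(coords)[2], 3, byrow = TRUE)
    ConformationalEnsemble(coords, residueLabels(ens), frameWeights(ens))
}

## Random sparse weighted graph as a CorrelationGraph (for path tests).
randomGraph <- function(n, pEdge = 0.3, seed = 1) {
    set.seed(seed)
    labels <- data.frame(chain = "A", resno = seq_len(n), resid = "ALA")
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < pEdge
    pairs <- pairs[keep, , drop = FALSE]
    corr <- runif(nrow(pairs), 0.05, 0.99)
    edges <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        dist = runif(nrow(pairs), 3, 5.9), corr = corr,
                        weight = -log(corr))
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
    new("CorrelationGraph", edges = edges, residueLabels = labels,
        cutoff = 6.0, correlationFloor = 1e-6)
}

## Minimal thresholded SpmResult holding a given position set.
spmWithPositions <- function(positions, n = max(positions, 1)) {
    labels <- data.frame(chain = "A", resno = seq_len(n), resid = "ALA")
    edges <- data.frame(i = integer(0), j = integer(0),
                        dist = numeric(0), corr = numeric(0),
                        weight = numeric(0), usage = integer(0),
                        norm = numeric(0))
    new("SpmResult", edges = edges, residueLabels = labels,
        nodeWeight = numeric(n), spmPositions = as.integer(positions),
        threshold = 0.3)
}

## Ordered linear-interpolation reference path (8 references for sharp
## path-CV endpoints under the default lambda heuristic).
linearPathRefs <- function(n = 12, nRefs = 8, seed = 3, scale = 2.5) {
    set.seed(seed)
    A <- matrix(rnorm(3 * n), n, 3) * 3
    B <- A + matrix(rnorm(3 * n), n, 3) * scale
    refs <- array(NA_real_, c(nRefs, n, 3))
    for (k in seq_len(nRefs))
        refs[k, , ] <- A + (k - 1) / (nRefs - 1) * (B - A)
    refs
}

## The planted synthetic design scenario shared by workflow tests:
## a fast (reduced-frame) ensemble plus a template/target pair with
## mutations on planted-path positions and decoys on low-usage chain
## ends, and a 20-residue insertion after position 40.
plantedScenario <- function(nFrames = 2000, seed = 0) {
    spec <- syntheticEnsembleSpec(nFrames = nFrames, seed = seed)
    syn <- makeSyntheticEnsemble(spec)
    pos <- c(2L, 29L, 31L, 50L, 59L)
    base <- makeSequences(syntheticSequenceSpec(
        length = 60L, insertionPosition = 40L, insertionLength = 20L,
        seed = seed + 1L))
    cur <- strsplit(base$template, "")[[1]][pos]
    mut <- data.frame(position = pos, to = ifelse(cur == "W", "Y", "W"))
    seqs <- makeSequences(syntheticSequenceSpec(
        length = 60L, mutations = mut, insertionPosition = 40L,
        insertionLength = 20L, seed = seed + 1L))
    list(spec = spec, syn = syn, seqs = seqs,
         plantedMutPositions = c(29L, 31L, 50L),
         decoyPositions = c(2L, 59L))
}
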