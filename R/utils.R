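## Internal geometry and bookkeeping helpers.

## Optimal rigid-body superposition of mobile (n x 3) onto fixed (n x 3),
## mass-unweighted, via bio3d's least-squares fit.  Returns the fitted
## coordinates.
.kabschFit <- function(mobile, fixed) {
    n <- nrow(fixed)
    fit <- bio3d::fit.xyz(fixed = as.numeric(t(fixed)),
                          mobile = as.numeric(t(mobile)),
                          fixed.inds = seq_len(3 * n),
                          mobile.inds = seq_len(3 * n))
    matrix(fit, ncol = 3, byrow = TRUE)
}

## Mean square deviation (A^2) between two n x 3 structures after optimal
## superposition.
.kabschMsd <- function(a, b) {
    fit <- .kabschFit(a, b)
    mean(rowSums((fit - b)^2))
}

.rmsdTo <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

## frames x (3 n) xyz matrix from a frames x n x 3 array, bio3d layout
## (x1 y1 z1 x2 ...).
.toXyzMatrix <- function(coords) {
    d <- dim(coords)
    m <- matrix(aperm(coords, c(3, 2, 1)), nrow = d[1], byrow = TRUE)
    m
}

.fromXyzMatrix <- function(m, n) {
    f <- nrow(m)
    aperm(array(t(m), dim = c(3, n, f)), c(3, 2, 1))
}

.normalizeWeights <- function(w) w / sum(w)

## frames x 3 coordinate matrix of one residue (robust to 1-frame arrays).
.residueSlice <- function(coords, i) {
    matrix(coords[, i, ], nrow = dim(coords)[1], ncol = 3)
}

.labelString <- function(labels) {
    paste0(labels$chain, ":", labels$resno)
}

.sameLabels <- function(a, b) {
    nrow(a) == nrow(b) && all(a$chain == b$chain) && all(a$resno == b$resno)
}

## Weighted mean and (population) SD.
.weightedMeanSd <- function(x, w) {
    w <- .normalizeWeights(w)
    m <- sum(w * x)
    c(mean = m, sd = sqrt(sum(w * (x - m)^2)))
}

.aaAlphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.checkAaString <- function(seq, what) {
    chars <- strsplit(toupper(seq), "")[[1]]
    bad <- setdiff(unique(chars), .aaAlphabet)
    if (length(bad))
        stop(sprintf("%s contains non-amino-acid characters: %s",
                     what, paste(bad, collapse = " ")), call. = FALSE)
    paste(chars, collapse = "")
}

## Coerce a sequence argument (character, AAString(Set), file path read
## upstream) to a plain character scalar.
.asSequence <- function(x, what) {
    if (methods::is(x, "XStringSet")) {
        if (length(x) != 1L)
            stop(sprintf("%s: expected a single sequence, got %d",
                         what, length(x)), call. = FALSE)
        x <- as.character(x[[1]])
    } else if (methods::is(x, "XString")) {
        x <- as.character(x)
    }
    if (!is.character(x) || length(x) != 1L || !nzchar(x))
        stop(sprintf("%s must be a single non-empty sequence", what),
             call. = FALSE)
    x
}
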