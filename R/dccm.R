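#' Dynamical cross-correlation matrix of residue displacements
#'
#' Computes the scalar dot-product DCCM
#' \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   \sqrt{\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle}}
#' where \eqn{\Delta r_i} is the displacement of residue i from its
#' weighted mean position.  The ensemble is expected to be superposed
#' already (see [superposeEnsemble()]); frame weights enter every average.
#'
#' @param ens a superposed [ConformationalEnsemble-class] with >= 2 frames.
#' @return a [CorrelationMatrix-class].
#' @examples
#' pdb <- system.file("extdata", "ensemble_3res_5frame.pdb",
#'                    package = "alloSPM")
#' ens <- superposeEnsemble(readEnsemble(pdb))$ensemble
#' matrixValues(computeDccm(ens))
#' @export
computeDccm <- function(ens) {
    stopifnot(is(ens, "ConformationalEnsemble"))
    if (nFrames(ens) < 2L)
        stop("correlation needs at least 2 frames")
    coords <- coordArray(ens)
    n <- nResidues(ens)
    w <- .normalizeWeights(frameWeights(ens))
    S <- matrix(0, n, n)
    for (d in 1:3) {
        X <- coords[, , d, drop = TRUE]
        if (is.null(dim(X))) X <- matrix(X, ncol = n)
        X <- sweep(X, 2, colSums(w * X))        # center on weighted mean
        S <- S + crossprod(X * sqrt(w))          # sum_f w_f dx_i dx_j
    }
    v <- diag(S)
    ## relative threshold: a residue whose variance is negligible against
    ## the most mobile one has no usable displacement signal
    zero <- which(v <= 1e-12 * max(v, 0) | !is.finite(v))
    if (length(zero)) {
        lab <- .labelString(residueLabels(ens))[zero]
        stop("zero displacement variance for residue(s): ",
             paste(lab, collapse = ", "))
    }
    C <- S / sqrt(outer(v, v))
    C <- (C + t(C)) / 2
    diag(C) <- 1
    C[C > 1] <- 1
    C[C < -1] <- -1
    new("CorrelationMatrix", values = C, residueLabels = residueLabels(ens))
}

#' Ensemble-mean residue-residue distance matrix
#'
#' Weighted mean over frames of the pairwise Euclidean C-alpha distances;
#' the contact criterion for the correlation graph edges.
#'
#' @param ens a [ConformationalEnsemble-class] (>= 1 frame).
#' @return a [MeanDistanceMatrix-class] (Angstrom).
#' @export
meanDistances <- function(ens) {
    stopifnot(is(ens, "ConformationalEnsemble"))
    coords <- coordArray(ens)
    n <- nResidues(ens)
    w <- .normalizeWeights(frameWeights(ens))
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
        di <- .residueSlice(coords, i)
        for (j in (i + 1L):n) {
            dd <- sqrt(rowSums((.residueSlice(coords, j) - di)^2))
            d[i, j] <- d[j, i] <- sum(w * dd)
        }
    }
    new("MeanDistanceMatrix", values = d, residueLabels = residueLabels(ens))
}

## Resolve a residue selector (list with chain and/or resno, or a bare
## residue number) to a single residue index.
.resolveSelector <- function(labels, sel, what) {
    if (is.numeric(sel)) sel <- list(resno = sel)
    keep <- rep(TRUE, nrow(labels))
    if (!is.null(sel$chain)) keep <- keep & labels$chain %in% sel$chain
    if (!is.null(sel$resno)) keep <- keep & labels$resno %in% sel$resno
    idx <- which(keep)
    if (length(idx) == 0L)
        stop(sprintf("%s selector matches no residue", what))
    if (length(idx) > 1L)
        stop(sprintf("%s selector is ambiguous (%d residues match)",
                     what, length(idx)))
    idx
}

#' Per-frame distance between two residues
#'
#' Geometric observable such as a catalytic proton-transfer distance:
#' the per-frame Euclidean distance between two uniquely selected
#' residues, plus its weighted mean and standard deviation.
#'
#' @param ens a [ConformationalEnsemble-class].
#' @param selA,selB residue selectors: a residue number or a list with
#'   entries \code{chain} and/or \code{resno}; each must match exactly
#'   one residue.
#' @return list with \code{distances} (numeric, one per frame, Angstrom),
#'   \code{mean} and \code{sd} (weighted).
#' @export
distanceObservable <- function(ens, selA, selB) {
    labels <- residueLabels(ens)
    ia <- .resolveSelector(labels, selA, "first")
    ib <- .resolveSelector(labels, selB, "second")
    coords <- coordArray(ens)
    dd <- sqrt(rowSums((.residueSlice(coords, ia) -
                        .residueSlice(coords, ib))^2))
    ms <- .weightedMeanSd(dd, frameWeights(ens))
    list(distances = dd, mean = unname(ms["mean"]), sd = unname(ms["sd"]))
}

#' Write a residue matrix as TSV
#'
#' Writes a [CorrelationMatrix-class] or [MeanDistanceMatrix-class] with a
#' residue-label (chain:resno) header row and column.
#'
#' @param x the matrix object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTsv <- function(x, path) {
    stopifnot(is(x, "CorrelationMatrix") || is(x, "MeanDistanceMatrix"))
    m <- matrixValues(x)
    lab <- .labelString(residueLabels(x))
    dimnames(m) <- list(lab, lab)
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    invisible(path)
}
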