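#' Accessors for alloSPM classes
#'
#' Small accessor generics: \code{nFrames} / \code{nResidues} give
#' ensemble dimensions, \code{coordArray} the raw coordinate array,
#' \code{frameWeights} the per-frame weights, \code{residueLabels} the
#' chain/resno/resid table, \code{matrixValues} the numeric matrix inside
#' a [CorrelationMatrix-class] or [MeanDistanceMatrix-class],
#' \code{edgeTable} the edge data.frame of a graph or SPM result, and
#' \code{spmPositions} the residue numbers retained in a thresholded SPM.
#'
#' @param x an alloSPM object.
#' @return the corresponding slot content; \code{spmPositions} returns a
#'   data.frame of node labels (chain, resno, resid) for the retained
#'   positions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("coordArray", function(x) standardGeneric("coordArray"))
#' @rdname accessors
#' @export
setGeneric("frameWeights", function(x) standardGeneric("frameWeights"))
#' @rdname accessors
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))
#' @rdname accessors
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("spmPositions", function(x) standardGeneric("spmPositions"))

#' @rdname accessors
setMethod("nFrames", "ConformationalEnsemble",
    function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nResidues", "ConformationalEnsemble",
    function(x) dim(x@coords)[2])
#' @rdname accessors
setMethod("coordArray", "ConformationalEnsemble", function(x) x@coords)
#' @rdname accessors
setMethod("frameWeights", "ConformationalEnsemble",
    function(x) x@frameWeights)
#' @rdname accessors
setMethod("residueLabels", "ConformationalEnsemble",
    function(x) x@residueLabels)
#' @rdname accessors
setMethod("residueLabels", "CorrelationMatrix", function(x) x@residueLabels)
#' @rdname accessors
setMethod("residueLabels", "MeanDistanceMatrix", function(x) x@residueLabels)
#' @rdname accessors
setMethod("residueLabels", "CorrelationGraph", function(x) x@residueLabels)
#' @rdname accessors
setMethod("residueLabels", "SpmResult", function(x) x@residueLabels)
#' @rdname accessors
setMethod("matrixValues", "CorrelationMatrix", function(x) x@values)
#' @rdname accessors
setMethod("matrixValues", "MeanDistanceMatrix", function(x) x@values)
#' @rdname accessors
setMethod("edgeTable", "CorrelationGraph", function(x) x@edges)
#' @rdname accessors
setMethod("edgeTable", "SpmResult", function(x) x@edges)
#' @rdname accessors
setMethod("spmPositions", "SpmResult", function(x) {
    x@residueLabels[x@spmPositions, , drop = FALSE]
})

setMethod("show", "ConformationalEnsemble", function(object) {
    d <- dim(object@coords)
    w <- object@frameWeights
    uni <- max(w) - min(w) < 1e-15 * max(w, 1)
    cat(sprintf("ConformationalEnsemble: %d frames x %d residues (%s weights)\n",
                d[1], d[2], if (uni) "uniform" else "non-uniform"))
    ch <- unique(object@residueLabels$chain)
    cat(sprintf("  chains: %s; resno %d..%d\n",
                paste(ch, collapse = ","),
                min(object@residueLabels$resno),
                max(object@residueLabels$resno)))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix: %d x %d residues, range [%.3f, %.3f]\n",
                nrow(object@values), ncol(object@values),
                min(object@values), max(object@values)))
})

setMethod("show", "MeanDistanceMatrix", function(object) {
    off <- object@values[upper.tri(object@values)]
    cat(sprintf("MeanDistanceMatrix: %d residues, off-diagonal %.2f..%.2f A\n",
                nrow(object@values), min(off), max(off)))
})

setMethod("show", "CorrelationGraph", function(object) {
    cat(sprintf(
        "CorrelationGraph: %d nodes, %d edges (cutoff %.2f A, floor %g)\n",
        nrow(object@residueLabels), nrow(object@edges),
        object@cutoff, object@correlationFloor))
})

setMethod("show", "SpmResult", function(object) {
    if (is.na(object@threshold)) {
        cat(sprintf("SpmResult (raw usage): %d edges, max usage %d\n",
                    nrow(object@edges),
                    if (nrow(object@edges)) max(object@edges$usage) else 0L))
    } else {
        cat(sprintf(
            "SpmResult: threshold %.2f, %d edges, %d SPM positions of %d residues\n",
            object@threshold, nrow(object@edges),
            length(object@spmPositions), nrow(object@residueLabels)))
    }
})

setMethod("show", "SpmComparison", function(object) {
    cat(sprintf("SpmComparison: %d of %d reference positions shared (%.1f%%)\n",
                object@nShared, object@nReference, object@percentShared))
})

setMethod("show", "AlignmentMap", function(object) {
    cl <- object@columns
    cat(sprintf(
        "AlignmentMap: %d columns (%d template, %d target residues), score %.1f\n",
        nrow(cl), sum(!is.na(cl$template)), sum(!is.na(cl$target)),
        object@score))
})

setMethod("show", "ConservationProfile", function(object) {
    s <- object@score
    cat(sprintf(
        "ConservationProfile: %d columns (%d scored), %d sequences\n",
        length(s), sum(!is.na(s)), object@nSequences))
    cat(sprintf("  bands: %d high (>= %.2f), %d low (< %.2f)\n",
                sum(s >= object@high, na.rm = TRUE), object@high,
                sum(s < object@low, na.rm = TRUE), object@low))
})

setMethod("show", "PathReference", function(object) {
    d <- dim(object@coords)
    cat(sprintf("PathReference: %d references x %d residues, lambda %.4g A^-2\n",
                d[1], d[2], object@lambda))
})

setMethod("show", "FelGrid", function(object) {
    occ <- sum(!is.na(object@fe))
    cat(sprintf(
        "FelGrid: %d x %d bins (%d occupied), kT %.3f kcal/mol, max %.2f kcal/mol\n",
        nrow(object@fe), ncol(object@fe), occ, object@kT,
        if (occ) max(object@fe, na.rm = TRUE) else NA_real_))
})
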