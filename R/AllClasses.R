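#' @import methods
NULL

## Tolerances used by validity methods; tight because these invariants are
## enforced at construction time, not approximated.
.SYM_TOL <- 1e-10
.DIAG_TOL <- 1e-10
.CORR_TOL <- 1e-12

.checkResidueLabels <- function(labels, n) {
    if (!is.data.frame(labels))
        return("residueLabels must be a data.frame")
    need <- c("chain", "resno", "resid")
    if (!all(need %in% names(labels)))
        return(sprintf("residueLabels needs columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(labels) != n)
        return(sprintf("residueLabels has %d rows but %d residues expected",
                       nrow(labels), n))
    NULL
}

#' Conformational ensemble of residue coordinates
#'
#' Holds an ensemble of conformations as a \code{frames x residues x 3}
#' coordinate array (Angstrom), together with residue labels (chain,
#' residue number as printed in the source PDB, residue name) and optional
#' per-frame weights.  Weights default to uniform and support reweighted
#' (e.g. biased-run) ensembles; all downstream moments (DCCM, mean
#' distances, observables) use normalized weights.
#'
#' @slot coords numeric array, \code{n_frames x n_residues x 3}, Angstrom.
#' @slot residueLabels data.frame with columns \code{chain}, \code{resno}
#'   (1-based numbering preserved from the input file), \code{resid}.
#' @slot frameWeights non-negative numeric vector, one value per frame,
#'   with positive sum.
#'
#' @seealso [readEnsemble()], [superposeEnsemble()], [computeDccm()]
#' @export
setClass("ConformationalEnsemble",
    representation(coords = "array",
                   residueLabels = "data.frame",
                   frameWeights = "numeric"))

setValidity("ConformationalEnsemble", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 3L)
        return("coords must be a frames x residues x 3 array")
    if (!all(is.finite(object@coords)))
        return("coords contain non-finite values")
    msg <- .checkResidueLabels(object@residueLabels, d[2])
    if (!is.null(msg)) return(msg)
    w <- object@frameWeights
    if (length(w) != d[1])
        return("frameWeights length must equal the number of frames")
    if (any(!is.finite(w)) || any(w < 0))
        return("frameWeights must be finite and non-negative")
    if (sum(w) <= 0)
        return("frameWeights must have positive sum")
    TRUE
})

#' Residue-by-residue matrix classes
#'
#' \code{CorrelationMatrix} stores a dynamical cross-correlation matrix
#' (dimensionless, symmetric, unit diagonal, entries in \eqn{[-1, 1]}).
#' \code{MeanDistanceMatrix} stores the ensemble-weighted mean Euclidean
#' C-alpha distance matrix (Angstrom, symmetric, zero diagonal,
#' non-negative).  Both carry the residue labels of the ensemble they were
#' computed from.
#'
#' @slot values numeric n x n matrix.
#' @slot residueLabels data.frame as in [ConformationalEnsemble-class].
#'
#' @aliases CorrelationMatrix-class MeanDistanceMatrix-class
#' @name ResidueMatrix-classes
#' @export
setClass("CorrelationMatrix",
    representation(values = "matrix", residueLabels = "data.frame"))

setValidity("CorrelationMatrix", function(object) {
    C <- object@values
    if (nrow(C) != ncol(C)) return("correlation matrix must be square")
    msg <- .checkResidueLabels(object@residueLabels, nrow(C))
    if (!is.null(msg)) return(msg)
    if (max(abs(C - t(C))) > .SYM_TOL)
        return("correlation matrix not symmetric within 1e-10")
    if (max(abs(diag(C) - 1)) > .DIAG_TOL)
        return("correlation matrix diagonal must be 1 within 1e-10")
    if (max(abs(C)) > 1 + .CORR_TOL)
        return("correlation entries must satisfy |C_ij| <= 1 + 1e-12")
    TRUE
})

#' @name ResidueMatrix-classes
#' @export
setClass("MeanDistanceMatrix",
    representation(values = "matrix", residueLabels = "data.frame"))

setValidity("MeanDistanceMatrix", function(object) {
    d <- object@values
    if (nrow(d) != ncol(d)) return("distance matrix must be square")
    msg <- .checkResidueLabels(object@residueLabels, nrow(d))
    if (!is.null(msg)) return(msg)
    if (max(abs(d - t(d))) > .SYM_TOL) return("distance matrix not symmetric")
    if (max(abs(diag(d))) > .DIAG_TOL) return("distance diagonal must be 0")
    if (any(d < -.DIAG_TOL)) return("distances must be non-negative")
    TRUE
})

#' Residue contact network weighted by correlated motion
#'
#' Nodes are residues; an edge joins residues whose ensemble-mean distance
#' is below \code{cutoff} (default 6 Angstrom) and whose absolute
#' correlation is at least \code{correlationFloor}.  Edge weight is
#' \eqn{w_{ij} = -\ln|C_{ij}|}, so strongly correlated contacts are cheap
#' to traverse and shortest paths trace communication pathways.
#'
#' @slot edges data.frame with columns \code{i}, \code{j} (1-based node
#'   indices, \code{i < j}), \code{dist} (Angstrom), \code{corr},
#'   \code{weight} (\eqn{-\ln|C|}, dimensionless, >= 0).
#' @slot residueLabels data.frame of node labels (chain, resno, resid).
#' @slot cutoff numeric, Angstrom.
#' @slot correlationFloor numeric in (0, 1).
#'
#' @seealso [buildGraph()], [accumulatePaths()]
#' @export
setClass("CorrelationGraph",
    representation(edges = "data.frame",
                   residueLabels = "data.frame",
                   cutoff = "numeric",
                   correlationFloor = "numeric"))

setValidity("CorrelationGraph", function(object) {
    e <- object@edges
    need <- c("i", "j", "dist", "corr", "weight")
    if (!all(need %in% names(e)))
        return(sprintf("edges needs columns %s", paste(need, collapse = ", ")))
    n <- nrow(object@residueLabels)
    if (nrow(e)) {
        if (any(e$i == e$j)) return("self-edges are not allowed")
        if (any(e$i < 1 | e$j > n)) return("edge endpoints out of range")
        if (any(e$i >= e$j)) return("edges must be stored with i < j")
        if (any(e$dist >= object@cutoff))
            return("every edge must have mean distance < cutoff")
        if (any(e$weight < 0)) return("edge weights must be non-negative")
    }
    if (object@cutoff <= 0) return("cutoff must be positive")
    if (object@correlationFloor <= 0 || object@correlationFloor >= 1)
        return("correlationFloor must lie in (0, 1)")
    TRUE
})

#' Shortest path map: edge usage over all-pairs shortest paths
#'
#' For every connected residue pair one minimum-weight path is found
#' (deterministic tie-break); each edge's \code{usage} counts how many
#' pairs route through it.  \code{norm} is usage scaled by the maximum
#' (in (0, 1] wherever usage > 0).  After thresholding, residues incident
#' to a retained edge form \code{spmPositions}: the positions within
#' allosteric pathways that contribute most to the conformational
#' dynamics.  \code{threshold = NA} marks an un-thresholded (raw usage)
#' result.
#'
#' @slot edges edge data.frame as in [CorrelationGraph-class] plus
#'   \code{usage} (integer) and \code{norm} columns.
#' @slot residueLabels node label data.frame.
#' @slot nodeWeight per-node numeric, max incident normalized edge weight.
#' @slot spmPositions integer vector of node indices (thresholded result),
#'   or integer(0) for a raw result.
#' @slot threshold numeric fraction in [0, 1], or NA.
#'
#' @seealso [accumulatePaths()], [extractSpm()], [compareSpms()]
#' @export
setClass("SpmResult",
    representation(edges = "data.frame",
                   residueLabels = "data.frame",
                   nodeWeight = "numeric",
                   spmPositions = "integer",
                   threshold = "numeric"))

setValidity("SpmResult", function(object) {
    e <- object@edges
    if (!all(c("i", "j", "weight", "usage", "norm") %in% names(e)))
        return("edges needs i, j, weight, usage, norm columns")
    n <- nrow(object@residueLabels)
    if (length(object@nodeWeight) != n)
        return("nodeWeight must have one entry per node")
    if (nrow(e) && any(e$usage > 0) &&
        abs(max(e$norm) - 1) > 1e-12)
        return("maximum normalized edge usage must be 1 when paths exist")
    if (length(object@spmPositions) &&
        (min(object@spmPositions) < 1 || max(object@spmPositions) > n))
        return("spmPositions out of node range")
    th <- object@threshold
    if (length(th) != 1 || (!is.na(th) && (th < 0 || th > 1)))
        return("threshold must be a single value in [0, 1] or NA")
    TRUE
})

#' Overlap between two shortest path maps
#'
#' Summarises how many SPM positions of a reference system are recovered
#' in the SPM of another (e.g. a homologous) system, after mapping residue
#' numbering through an alignment.  \code{percentShared} is relative to
#' the reference SPM size.
#'
#' @slot sharedPositions integer vector of reference residue numbers found
#'   in both maps.
#' @slot nShared,nReference,nOther integer counts.
#' @slot percentShared numeric, \code{100 * nShared / nReference}.
#' @export
setClass("SpmComparison",
    representation(sharedPositions = "integer",
                   nShared = "integer",
                   nReference = "integer",
                   nOther = "integer",
                   percentShared = "numeric"))

setValidity("SpmComparison", function(object) {
    if (object@nShared > min(object@nReference, object@nOther))
        return("nShared cannot exceed either SPM size")
    if (object@nReference > 0 &&
        abs(object@percentShared -
            100 * object@nShared / object@nReference) > 1e-9)
        return("percentShared inconsistent with counts")
    TRUE
})

#' Pairwise alignment position map
#'
#' Column-wise view of a global pairwise alignment between a template and
#' a target sequence.  Each row is one alignment column: the 1-based
#' template and target positions (NA at gaps) and the aligned residues
#' ("-" at gaps).  Non-gap positions appear exactly once and increase
#' strictly along each sequence.
#'
#' @slot columns data.frame with columns \code{template}, \code{target}
#'   (integer or NA), \code{templateRes}, \code{targetRes} (character).
#' @slot score numeric alignment score.
#' @seealso [alignPair()], [mapPositions()]
#' @export
setClass("AlignmentMap",
    representation(columns = "data.frame", score = "numeric"))

setValidity("AlignmentMap", function(object) {
    cl <- object@columns
    need <- c("template", "target", "templateRes", "targetRes")
    if (!all(need %in% names(cl)))
        return(sprintf("columns needs %s", paste(need, collapse = ", ")))
    for (side in c("template", "target")) {
        p <- cl[[side]][!is.na(cl[[side]])]
        if (anyDuplicated(p)) return(sprintf("%s positions repeat", side))
        if (is.unsorted(p, strictly = TRUE))
            return(sprintf("%s positions must increase strictly", side))
    }
    TRUE
})

#' Per-column conservation of a multiple sequence alignment
#'
#' Column score is the frequency of the modal residue among non-gap
#' characters (ties broken alphabetically); columns with gap fraction
#' above 0.5 are left unscored (NA).  Scores are banded as high
#' (>= \code{high}), low (< \code{low}) or intermediate.
#'
#' @slot score numeric in [0, 1], NA where unscored.
#' @slot gapFraction numeric in [0, 1].
#' @slot high,low numeric thresholds (defaults 0.90 and 0.70).
#' @slot nSequences integer, alignment depth.
#' @seealso [msaConservation()], [bandPositions()]
#' @export
setClass("ConservationProfile",
    representation(score = "numeric",
                   gapFraction = "numeric",
                   high = "numeric",
                   low = "numeric",
                   nSequences = "integer"))

setValidity("ConservationProfile", function(object) {
    s <- object@score
    if (length(s) != length(object@gapFraction))
        return("score and gapFraction lengths differ")
    if (any(s < -1e-12 | s > 1 + 1e-12, na.rm = TRUE))
        return("scores must lie in [0, 1]")
    if (object@low > object@high)
        return("low threshold must not exceed high threshold")
    TRUE
})

#' Ordered open-to-closed reference path
#'
#' An ordered series of reference structures (open first, closed last)
#' spanning a conformational transition, plus the smoothing constant
#' \eqn{\lambda} (Angstrom^-2) used by the path collective variables.
#'
#' @slot coords numeric array, \code{n_refs x n_residues x 3}, Angstrom.
#' @slot lambda positive numeric, Angstrom^-2.
#' @seealso [pathReference()], [pathCvs()]
#' @export
setClass("PathReference",
    representation(coords = "array", lambda = "numeric"))

setValidity("PathReference", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 3L)
        return("coords must be n_refs x n_residues x 3")
    if (d[1] < 2L) return("need at least two reference structures")
    if (!all(is.finite(object@coords))) return("non-finite coordinates")
    if (length(object@lambda) != 1 || !is.finite(object@lambda) ||
        object@lambda <= 0)
        return("lambda must be a single positive number")
    msd <- vapply(seq_len(d[1] - 1L), function(k)
        .kabschMsd(object@coords[k, , , drop = TRUE],
                   object@coords[k + 1L, , , drop = TRUE]), numeric(1))
    if (any(msd <= 1e-10))
        return("consecutive reference structures must differ (MSD > 0)")
    TRUE
})

#' Free-energy surface over path collective variables
#'
#' A 2-D grid over progression \code{s} (dimensionless, [0, 1]) and path
#' deviation \code{z} (Angstrom^2).  Bin free energies are
#' \eqn{-kT \ln p} from the weighted sample histogram, shifted so the
#' occupied minimum is 0; empty bins are NA (masked).  \code{stateRanges}
#' labels s-intervals as open (O), partially closed (PC) and closed (C).
#'
#' @slot fe numeric matrix, \code{n_s_bins x n_z_bins}, kcal/mol.
#' @slot sBreaks,zBreaks numeric bin edges (length nbins + 1).
#' @slot kT numeric, kcal/mol.
#' @slot stateRanges named list of \code{c(lower, upper)} s-intervals.
#' @seealso [felFromSamples()], [stateFractions()]
#' @export
setClass("FelGrid",
    representation(fe = "matrix",
                   sBreaks = "numeric",
                   zBreaks = "numeric",
                   kT = "numeric",
                   stateRanges = "list"))

setValidity("FelGrid", function(object) {
    fe <- object@fe
    if (nrow(fe) != length(object@sBreaks) - 1L ||
        ncol(fe) != length(object@zBreaks) - 1L)
        return("fe dimensions must match bin edges")
    occ <- fe[!is.na(fe)]
    if (length(occ)) {
        if (abs(min(occ)) > 1e-9)
            return("minimum over occupied bins must be 0")
        if (any(occ < -1e-9)) return("free energies must be non-negative")
    }
    if (object@kT <= 0) return("kT must be positive")
    msg <- .checkStateRanges(object@stateRanges)
    if (!is.null(msg)) return(msg)
    TRUE
})

.checkStateRanges <- function(ranges) {
    if (!length(ranges)) return(NULL)
    if (is.null(names(ranges)) || any(!nzchar(names(ranges))))
        return("state ranges must be named")
    b <- t(vapply(ranges, function(r) {
        if (length(r) != 2 || r[1] >= r[2]) c(NA_real_, NA_real_) else r
    }, numeric(2)))
    if (any(is.na(b))) return("each state range must be c(lower, upper)")
    if (any(b < -1e-12) || any(b > 1 + 1e-12))
        return("state ranges must lie within [0, 1]")
    o <- order(b[, 1])
    if (any(b[o, 1][-1] < b[o, 2][-nrow(b)] - 1e-12))
        return("state ranges must not overlap")
    NULL
}
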