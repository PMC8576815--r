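#' Build an open-to-closed reference path
#'
#' Wraps an ordered series of reference structures (open first, closed
#' last) for path collective variables.  The smoothing constant
#' \eqn{\lambda} defaults to \eqn{2.3 / \overline{MSD}_{consec}}, the
#' usual heuristic that makes the exponential kernels of adjacent
#' references overlap; \eqn{\overline{MSD}_{consec}} is the mean
#' superposed mean-square deviation between consecutive references.
#'
#' @param refs a [ConformationalEnsemble-class] whose frames are the
#'   ordered references (e.g. from an ordered multi-model PDB via
#'   [readEnsemble()]), or an \code{n_refs x n_residues x 3} array.
#' @param lambda optional positive smoothing constant, Angstrom^-2.
#' @return a [PathReference-class].
#' @export
pathReference <- function(refs, lambda = NULL) {
    coords <- if (is(refs, "ConformationalEnsemble")) coordArray(refs)
              else refs
    if (length(dim(coords)) != 3L || dim(coords)[1] < 2L)
        stop("need an ordered array of at least two reference structures")
    if (is.null(lambda)) {
        msd <- vapply(seq_len(dim(coords)[1] - 1L), function(k)
            .kabschMsd(coords[k, , , drop = TRUE],
                       coords[k + 1L, , , drop = TRUE]), numeric(1))
        lambda <- 2.3 / mean(msd)
    }
    if (lambda <= 0) stop("lambda must be positive")
    new("PathReference", coords = coords, lambda = lambda)
}

#' Project an ensemble onto path collective variables
#'
#' For every frame, the mean square deviation \eqn{MSD_i} (Angstrom^2,
#' after per-frame rigid superposition) to each of the N ordered
#' references is combined into the progression
#' \deqn{s = \frac{\sum_i \frac{i-1}{N-1} e^{-\lambda MSD_i}}
#'               {\sum_i e^{-\lambda MSD_i}} \in [0, 1]}
#' and the deviation from the path
#' \deqn{z = -\frac{1}{\lambda} \ln \sum_i e^{-\lambda MSD_i} \ge 0.}
#' s tracks where along the open-to-closed transition a frame sits; z
#' how far off the reference path it is.
#'
#' @param ens a [ConformationalEnsemble-class]; residues must correspond
#'   1:1 to the reference residues.
#' @param ref a [PathReference-class].
#' @return data.frame with one row per frame and columns \code{s}
#'   (dimensionless) and \code{z} (Angstrom^2).
#' @export
pathCvs <- function(ens, ref) {
    stopifnot(is(ens, "ConformationalEnsemble"), is(ref, "PathReference"))
    coords <- coordArray(ens)
    rc <- ref@coords
    if (dim(coords)[2] != dim(rc)[2])
        stop(sprintf("ensemble has %d residues but references have %d",
                     dim(coords)[2], dim(rc)[2]))
    nRefs <- dim(rc)[1]
    nF <- dim(coords)[1]
    lam <- ref@lambda
    msd <- matrix(NA_real_, nF, nRefs)
    m <- .toXyzMatrix(coords)
    n3 <- ncol(m)
    for (r in seq_len(nRefs)) {
        refVec <- as.numeric(t(rc[r, , , drop = TRUE]))
        fit <- bio3d::fit.xyz(fixed = refVec, mobile = m,
                              fixed.inds = seq_len(n3),
                              mobile.inds = seq_len(n3))
        if (is.null(dim(fit))) fit <- matrix(fit, nrow = 1)
        dev <- sweep(fit, 2, refVec)
        msd[, r] <- rowSums(dev^2) / (n3 / 3)
    }
    idxFrac <- (seq_len(nRefs) - 1) / (nRefs - 1)
    ## log-sum-exp guard: factor out the smallest MSD per frame
    mmin <- apply(msd, 1, min)
    ek <- exp(-lam * (msd - mmin))
    denom <- rowSums(ek)
    s <- as.numeric(ek %*% idxFrac) / denom
    z <- mmin - log(denom) / lam
    data.frame(s = s, z = pmax(z, 0))
}

#' Default open / partially-closed / closed state ranges
#'
#' Thirds of the progression axis: open (O) \eqn{s \in [0, 1/3)},
#' partially closed (PC) \eqn{[1/3, 2/3)}, closed (C) \eqn{[2/3, 1]}.
#' @return named list of \code{c(lower, upper)} intervals.
#' @export
defaultStateRanges <- function() {
    list(O = c(0, 1 / 3), PC = c(1 / 3, 2 / 3), C = c(2 / 3, 1))
}

#' Free-energy surface over (s, z) from weighted samples
#'
#' Bins the samples into a 2-D histogram (optionally weighted, e.g. by
#' reweighting factors of a biased run), normalizes it to a probability,
#' and reports \eqn{F = -kT \ln p} per bin shifted so the occupied
#' minimum is zero.  Empty bins are masked (NA).
#'
#' @param samples data.frame with columns \code{s} and \code{z} (from
#'   [pathCvs()]).
#' @param weights optional per-sample non-negative weights.
#' @param kT thermal energy in kcal/mol (default 0.596, i.e. 300 K).
#' @param bins integer vector of two bin counts (default c(100, 100)).
#' @param sRange,zRange optional axis ranges (default: sample bounding
#'   box).
#' @param stateRanges state labels for the s axis (see
#'   [defaultStateRanges()]).
#' @return a [FelGrid-class].
#' @export
felFromSamples <- function(samples, weights = NULL, kT = 0.596,
                           bins = c(100, 100), sRange = NULL,
                           zRange = NULL,
                           stateRanges = defaultStateRanges()) {
    s <- samples$s; z <- samples$z
    if (!length(s)) stop("no samples")
    if (kT <= 0) stop("kT must be positive")
    if (is.null(weights)) weights <- rep(1, length(s))
    if (length(weights) != length(s))
        stop("weights length must match samples")
    if (any(weights < 0)) stop("weights must be non-negative")
    if (sum(weights) <= 0) stop("all weights are zero")
    bins <- rep_len(as.integer(bins), 2L)
    pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
    if (is.null(sRange)) sRange <- pad(range(s))
    if (is.null(zRange)) zRange <- pad(range(z))
    sBreaks <- seq(sRange[1], sRange[2], length.out = bins[1] + 1L)
    zBreaks <- seq(zRange[1], zRange[2], length.out = bins[2] + 1L)
    bi <- findInterval(s, sBreaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    bj <- findInterval(z, zBreaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    h <- matrix(0, bins[1], bins[2])
    for (k in seq_along(s))
        h[bi[k], bj[k]] <- h[bi[k], bj[k]] + weights[k]
    p <- h / sum(h)
    fe <- matrix(NA_real_, bins[1], bins[2])
    occ <- p > 0
    fe[occ] <- -kT * log(p[occ])
    fe <- fe - min(fe, na.rm = TRUE)
    new("FelGrid", fe = fe, sBreaks = sBreaks, zBreaks = zBreaks,
        kT = kT, stateRanges = stateRanges)
}

#' Weighted state populations along the progression axis
#'
#' Fraction of (weighted) frames whose progression s falls in each state
#' interval; the closed-state fraction is the screening score for
#' whether a variant retains the catalytically competent closed
#' conformation.  Intervals are half-open \code{[lower, upper)} except
#' the one reaching s = 1, which is closed.
#'
#' @param samples data.frame with column \code{s} (and \code{z}, unused).
#' @param weights optional per-sample non-negative weights.
#' @param stateRanges named list of disjoint \code{c(lower, upper)}
#'   intervals within [0, 1] (default [defaultStateRanges()]).
#' @return named numeric vector of fractions in [0, 1]; their sum is
#'   <= 1 (frames outside all ranges are allowed).
#' @export
stateFractions <- function(samples, weights = NULL,
                           stateRanges = defaultStateRanges()) {
    msg <- .checkStateRanges(stateRanges)
    if (!is.null(msg)) stop(msg)
    s <- samples$s
    if (is.null(weights)) weights <- rep(1, length(s))
    if (sum(weights) <= 0) stop("all weights are zero")
    w <- .normalizeWeights(weights)
    out <- vapply(stateRanges, function(r) {
        inR <- if (r[2] >= 1 - 1e-12) s >= r[1] & s <= r[2]
               else s >= r[1] & s < r[2]
        sum(w[inR])
    }, numeric(1))
    out
}

#' Write a free-energy grid
#'
#' Writes both a long-format TSV (s bin center, z bin center, free
#' energy) and, if \code{matrixPath} is given, a dense matrix whose
#' header lines carry the bin edges (gnuplot / numpy loadable; empty
#' bins as NaN).
#'
#' @param fel a [FelGrid-class].
#' @param path output TSV file.
#' @param matrixPath optional dense-matrix output file.
#' @return \code{path}, invisibly.
#' @export
writeFelTsv <- function(fel, path, matrixPath = NULL) {
    stopifnot(is(fel, "FelGrid"))
    sMid <- (fel@sBreaks[-1] + fel@sBreaks[-length(fel@sBreaks)]) / 2
    zMid <- (fel@zBreaks[-1] + fel@zBreaks[-length(fel@zBreaks)]) / 2
    long <- expand.grid(s = sMid, z = zMid)
    long$free_energy <- as.numeric(fel@fe)
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(matrixPath)) {
        con <- file(matrixPath, "w")
        on.exit(close(con))
        writeLines(c(paste("# s_edges:",
                           paste(format(fel@sBreaks), collapse = " ")),
                     paste("# z_edges:",
                           paste(format(fel@zBreaks), collapse = " ")),
                     paste("# kT_kcal_mol:", fel@kT)), con)
        utils::write.table(fel@fe, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}
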