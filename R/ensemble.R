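#' Construct a conformational ensemble from coordinates
#'
#' Low-level constructor used by the readers and the synthetic generators.
#'
#' @param coords numeric array \code{n_frames x n_residues x 3} (Angstrom).
#' @param residueLabels data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}; defaults to chain "A", resno \code{1..n}, resid "ALA".
#' @param frameWeights optional non-negative per-frame weights (default
#'   uniform).
#' @return a [ConformationalEnsemble-class].
#' @export
ConformationalEnsemble <- function(coords, residueLabels = NULL,
                                   frameWeights = NULL) {
    if (length(dim(coords)) != 3L)
        stop("coords must be a frames x residues x 3 array")
    n <- dim(coords)[2]
    if (is.null(residueLabels))
        residueLabels <- data.frame(chain = "A", resno = seq_len(n),
                                    resid = "ALA")
    if (is.null(frameWeights))
        frameWeights <- rep(1, dim(coords)[1])
    new("ConformationalEnsemble", coords = coords,
        residueLabels = residueLabels, frameWeights = frameWeights)
}

## Parse ATOM records of raw PDB lines into a small table.
.parseAtomLines <- function(lines) {
    at <- lines[startsWith(lines, "ATOM")]
    data.frame(
        elety = trimws(substr(at, 13, 16)),
        resid = trimws(substr(at, 18, 20)),
        chain = substr(at, 22, 22),
        resno = as.integer(substr(at, 23, 26)),
        x = as.numeric(substr(at, 31, 38)),
        y = as.numeric(substr(at, 39, 46)),
        z = as.numeric(substr(at, 47, 54)))
}

.applySelection <- function(tab, selection) {
    keep <- rep(TRUE, nrow(tab))
    if (!is.null(selection$elety)) keep <- keep & tab$elety %in% selection$elety
    if (!is.null(selection$chain)) keep <- keep & tab$chain %in% selection$chain
    if (!is.null(selection$resno)) keep <- keep & tab$resno %in% selection$resno
    keep
}

#' Read a conformational ensemble
#'
#' Reads either a multi-model PDB (every MODEL is one frame) or a PDB
#' topology plus a plain XYZ trajectory whose atoms follow the topology's
#' atom order.  A residue selection (by atom name, chain, residue number)
#' picks one atom per residue; the default selects C-alpha atoms.  Every
#' frame must contain exactly the selected atoms; a frame with a missing
#' selected atom is an error naming the frame and residue.
#'
#' @param structureFile path to a (multi-model) PDB file.
#' @param trajectoryFile optional path to an XYZ trajectory; when given,
#'   \code{structureFile} provides only the topology.
#' @param selection list with optional entries \code{elety} (atom name,
#'   default "CA"), \code{chain}, \code{resno}.
#' @param frameWeights optional numeric weights or a path to a plain-text
#'   file with one weight per line (see [readFrameWeights()]).
#' @return a [ConformationalEnsemble-class]; residue numbering is kept as
#'   printed in the PDB (1-based).
#' @examples
#' pdb <- system.file("extdata", "ensemble_3res_5frame.pdb",
#'                    package = "alloSPM")
#' ens <- readEnsemble(pdb)
#' nFrames(ens)
#' @export
readEnsemble <- function(structureFile, trajectoryFile = NULL,
                         selection = list(elety = "CA"),
                         frameWeights = NULL) {
    if (!file.exists(structureFile))
        stop("cannot read structure file: ", structureFile)
    lines <- readLines(structureFile, warn = FALSE)
    starts <- which(startsWith(lines, "MODEL"))
    if (length(starts) == 0L) starts <- 1L
    ends <- c(starts[-1] - 1L, length(lines))
    frames <- lapply(seq_along(starts), function(k)
        .parseAtomLines(lines[starts[k]:ends[k]]))
    tab1 <- frames[[1]]
    keep1 <- .applySelection(tab1, selection)
    ref <- tab1[keep1, , drop = FALSE]
    if (nrow(ref) < 2L)
        stop("selection matches fewer than 2 residues in ", structureFile)
    refKey <- paste(ref$chain, ref$resno, ref$elety)

    labels <- data.frame(chain = ref$chain, resno = ref$resno,
                         resid = ref$resid)

    if (is.null(trajectoryFile)) {
        coords <- array(NA_real_, dim = c(length(frames), nrow(ref), 3))
        for (k in seq_along(frames)) {
            tab <- frames[[k]]
            sel <- tab[.applySelection(tab, selection), , drop = FALSE]
            key <- paste(sel$chain, sel$resno, sel$elety)
            missing <- setdiff(refKey, key)
            if (length(missing))
                stop(sprintf("frame %d is missing selected atom(s): %s",
                             k, paste(missing, collapse = ", ")))
            extra <- setdiff(key, refKey)
            if (length(extra))
                stop(sprintf("frame %d has unexpected selected atom(s): %s",
                             k, paste(extra, collapse = ", ")))
            sel <- sel[match(refKey, key), , drop = FALSE]
            coords[k, , ] <- as.matrix(sel[, c("x", "y", "z")])
        }
    } else {
        coords <- .readXyzFrames(trajectoryFile, nrow(tab1), which(keep1))
    }

    if (is.character(frameWeights))
        frameWeights <- readFrameWeights(frameWeights)
    ConformationalEnsemble(coords, labels, frameWeights)
}

## Read an XYZ trajectory (natoms / comment / atom lines per frame) and
## return frames x length(selIdx) x 3 coordinates for the selected atoms.
.readXyzFrames <- function(path, nAtomsTopology, selIdx) {
    if (!file.exists(path)) stop("cannot read trajectory file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    pos <- 1L
    out <- list()
    k <- 0L
    while (pos <= length(lines)) {
        nat <- suppressWarnings(as.integer(trimws(lines[pos])))
        k <- k + 1L
        if (is.na(nat))
            stop(sprintf("frame %d: malformed XYZ atom-count line", k))
        if (nat != nAtomsTopology)
            stop(sprintf("frame %d has %d atoms, topology has %d",
                         k, nat, nAtomsTopology))
        block <- lines[(pos + 2L):(pos + 1L + nat)]
        if (length(block) < nat || anyNA(block))
            stop(sprintf("frame %d is truncated", k))
        parts <- strsplit(trimws(block), "\\s+")
        xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
        if (anyNA(xyz))
            stop(sprintf("frame %d has unparseable coordinates", k))
        out[[k]] <- xyz[selIdx, , drop = FALSE]
        pos <- pos + 2L + nat
    }
    coords <- array(NA_real_, dim = c(length(out), length(selIdx), 3))
    for (f in seq_along(out)) coords[f, , ] <- out[[f]]
    coords
}

#' Read per-frame weights from a plain-text file
#'
#' One non-negative real per line; used to carry reweighting factors of
#' biased sampling runs into all ensemble averages.
#'
#' @param path file path.
#' @return numeric vector of weights.
#' @export
readFrameWeights <- function(path) {
    w <- scan(path, what = numeric(), quiet = TRUE)
    if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
        stop("frame weights must be finite, non-negative, with positive sum")
    w
}

#' Superpose an ensemble onto a reference structure
#'
#' Rigid-body (mass-unweighted) least-squares superposition of every frame
#' onto a reference.  With \code{reference = "mean"} the weighted mean
#' structure is used and refined by two mean/realign iterations, which
#' converges for ensembles of this kind.
#'
#' @param ens a [ConformationalEnsemble-class] with at least 3 residues.
#' @param reference \code{"mean"} or an \code{n_residues x 3} matrix.
#' @return list with \code{ensemble} (aligned), \code{rmsd} (per-frame
#'   RMSD to the reference, Angstrom) and \code{reference} (the n x 3
#'   reference actually used).
#' @export
superposeEnsemble <- function(ens, reference = "mean") {
    stopifnot(is(ens, "ConformationalEnsemble"))
    n <- nResidues(ens)
    if (n < 3L)
        stop("superposition needs at least 3 residues (rotation underdetermined)")
    coords <- coordArray(ens)
    w <- .normalizeWeights(frameWeights(ens))
    meanStructure <- function(cc) {
        apply(cc, c(2, 3), function(v) sum(w * v))
    }
    alignAll <- function(cc, ref) {
        for (f in seq_len(dim(cc)[1]))
            cc[f, , ] <- .kabschFit(cc[f, , , drop = TRUE], ref)
        cc
    }
    if (identical(reference, "mean")) {
        ref <- meanStructure(coords)
        for (it in 1:2) {
            coords <- alignAll(coords, ref)
            ref <- meanStructure(coords)
        }
    } else {
        ref <- as.matrix(reference)
        if (!all(dim(ref) == c(n, 3)))
            stop("reference must be an n_residues x 3 matrix")
        coords <- alignAll(coords, ref)
    }
    rmsd <- vapply(seq_len(dim(coords)[1]), function(f)
        .rmsdTo(coords[f, , , drop = TRUE], ref), numeric(1))
    list(ensemble = ConformationalEnsemble(coords, residueLabels(ens),
                                           frameWeights(ens)),
         rmsd = rmsd, reference = ref)
}

#' Write an ensemble as a multi-model PDB
#'
#' One MODEL per frame, one CA atom per residue, coordinates in Angstrom.
#' The synthetic generators use this writer so that fixtures pass through
#' the same reader as real data.
#'
#' @param ens a [ConformationalEnsemble-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEnsemblePdb <- function(ens, path) {
    coords <- coordArray(ens)
    lab <- residueLabels(ens)
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nFrames(ens))) {
        writeLines(sprintf("MODEL     %4d", f), con)
        writeLines(sprintf(
            "ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            seq_len(nrow(lab)), lab$resid, lab$chain, lab$resno,
            coords[f, , 1], coords[f, , 2], coords[f, , 3]), con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

#' Write an ensemble as an XYZ trajectory (plus use the PDB topology)
#'
#' @param ens a [ConformationalEnsemble-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeXyzTrajectory <- function(ens, path) {
    coords <- coordArray(ens)
    n <- nResidues(ens)
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nFrames(ens))) {
        writeLines(c(as.character(n), sprintf("frame %d", f)), con)
        writeLines(sprintf("C %12.6f %12.6f %12.6f",
                           coords[f, , 1], coords[f, , 2], coords[f, , 3]),
                   con)
    }
    invisible(path)
}
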