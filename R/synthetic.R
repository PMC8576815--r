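## Seeded synthetic generators: every stage of the workflow is testable
## against known ground truth without external trajectories or sequences.

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Specification of a synthetic correlated ensemble
#'
#' Describes a bead (C-alpha only) chain whose displacement fluctuations
#' follow a prescribed residue-residue correlation structure with a
#' planted high-correlation contact path -- a synthetic stand-in for an
#' MD ensemble with a known allosteric pathway.  Defaults are the
#' conditions used throughout the package's tests: 60 residues, a
#' 6-residue planted path, 20,000 frames.
#'
#' @param nResidues number of residues (beads).
#' @param spacing chain bead spacing, Angstrom (default 3.8, the
#'   C-alpha virtual bond length).
#' @param background background correlation level between all residue
#'   pairs (default 0.1).
#' @param plantedPath contiguous residue indices forming the planted
#'   path (default 28:33; between 2 and 6 residues, so the cluster
#'   layout keeps them mutually within contact).
#' @param plantedLevel correlation between consecutive planted-path
#'   residues, in (0, 1] (default 0.9).
#' @param offPathFactor non-consecutive planted pairs get correlation
#'   \code{plantedLevel^span * offPathFactor} (default 0.8).  Keeping
#'   this strictly below 1 makes the step-by-step route along the path
#'   strictly cheaper than any shortcut in \eqn{-\ln|C|} weight, so the
#'   planted path has a unique shortest route (exact geometric decay
#'   would make all routes tie).
#' @param nFrames number of frames (>= 2; default 20000).
#' @param amplitude displacement fluctuation amplitude per coordinate,
#'   Angstrom (default 0.5; must be positive).
#' @param seed RNG seed (default 0).
#' @return a validated spec (list of class "SyntheticEnsembleSpec").
#' @seealso [makeSyntheticEnsemble()]
#' @export
syntheticEnsembleSpec <- function(nResidues = 60L, spacing = 3.8,
                                  background = 0.1, plantedPath = 28:33,
                                  plantedLevel = 0.9, offPathFactor = 0.8,
                                  nFrames = 20000L, amplitude = 0.5,
                                  seed = 0L) {
    plantedPath <- as.integer(plantedPath)
    if (plantedLevel <= 0 || plantedLevel > 1)
        stop("plantedLevel must lie in (0, 1]")
    if (background < 0 || background >= plantedLevel)
        stop("background must be non-negative and below plantedLevel")
    if (nFrames < 2L) stop("nFrames must be >= 2")
    if (amplitude <= 0)
        stop("fluctuation amplitude must be positive")
    if (length(plantedPath) < 2L || length(plantedPath) > 6L)
        stop("plantedPath must contain 2..6 residues")
    if (any(diff(plantedPath) != 1L))
        stop("plantedPath must be contiguous residue indices")
    if (min(plantedPath) < 1L || max(plantedPath) > nResidues)
        stop("plantedPath outside 1..nResidues")
    structure(list(nResidues = as.integer(nResidues), spacing = spacing,
                   background = background, plantedPath = plantedPath,
                   plantedLevel = plantedLevel,
                   offPathFactor = offPathFactor,
                   nFrames = as.integer(nFrames), amplitude = amplitude,
                   seed = as.integer(seed)),
              class = "SyntheticEnsembleSpec")
}

## Deterministic chain layout: two arc lobes joined only through a
## compact planted-path cluster (octahedral vertex path, mutual
## distances < 6 A), so that inter-lobe communication must traverse the
## planted path.
.syntheticLayout <- function(spec) {
    n <- spec$nResidues
    planted <- spec$plantedPath
    k <- length(planted)
    rC <- 2.7
    verts <- rbind(c(-rC, 0, 0), c(0, -rC, 0), c(0, 0, -rC),
                   c(0, rC, 0), c(0, 0, rC), c(rC, 0, 0))
    cluster <- rbind(verts[seq_len(k - 1L), , drop = FALSE], verts[6, ])
    xyz <- matrix(NA_real_, n, 3)
    xyz[planted, ] <- cluster
    gap <- 5.0
    R <- 40
    delta <- spec$spacing / R
    firstP <- planted[1]; lastP <- planted[k]
    if (firstP > 1L) {
        centerA <- c(-(rC + gap), R, 0)
        for (j in seq_len(firstP - 1L)) {
            t <- firstP - 1L - j
            xyz[j, ] <- centerA + R * c(-sin(t * delta),
                                        -cos(t * delta), 0)
        }
    }
    if (lastP < n) {
        centerB <- c(rC + gap, -R, 0)
        for (j in (lastP + 1L):n) {
            t <- j - (lastP + 1L)
            xyz[j, ] <- centerB + R * c(sin(t * delta),
                                        cos(t * delta), 0)
        }
    }
    dcl <- as.matrix(stats::dist(cluster))
    stopifnot(max(dcl) < 6.0)
    xyz
}

## Prescribed correlation structure; repaired to the nearest positive
## definite correlation matrix when needed.
.syntheticCorrelation <- function(spec) {
    n <- spec$nResidues
    R <- matrix(spec$background, n, n)
    planted <- spec$plantedPath
    k <- length(planted)
    for (a in seq_len(k - 1L)) {
        for (b in (a + 1L):k) {
            span <- b - a
            r <- if (span == 1L) spec$plantedLevel
                 else max(spec$background,
                          spec$plantedLevel^span * spec$offPathFactor)
            R[planted[a], planted[b]] <- R[planted[b], planted[a]] <- r
        }
    }
    diag(R) <- 1
    repairDelta <- 0
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
        Rp <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
        repairDelta <- max(abs(Rp - R))
        if (repairDelta > 0.1)
            stop(sprintf(
                "correlation structure infeasible: nearest-PD repair moved entries by %.3f (> 0.1)",
                repairDelta))
        R <- Rp
    }
    list(R = R, repairDelta = repairDelta)
}

#' Generate a synthetic ensemble with a planted correlation path
#'
#' Residues sit on the deterministic layout of
#' [syntheticEnsembleSpec()]; per-frame displacements are drawn from a
#' correlated multivariate normal realizing the prescribed correlation
#' structure, independently and identically for x, y and z (isotropic),
#' so the ground-truth displacement DCCM equals the prescribed matrix
#' analytically.  The same seed always yields the identical ensemble.
#'
#' @param spec a spec from [syntheticEnsembleSpec()].
#' @return list with \code{ensemble}
#'   ([ConformationalEnsemble-class]), \code{truthCorrelation} (the
#'   post-repair ground-truth matrix), \code{plantedEdges} (data.frame
#'   of consecutive planted-path index pairs), \code{repairDelta}
#'   (largest entry change of the positive-definite repair, 0 if none)
#'   and \code{layout} (static n x 3 coordinates).
#' @examples
#' spec <- syntheticEnsembleSpec(nFrames = 50)
#' ens <- makeSyntheticEnsemble(spec)$ensemble
#' nFrames(ens)
#' @export
makeSyntheticEnsemble <- function(spec) {
    stopifnot(inherits(spec, "SyntheticEnsembleSpec"))
    layout <- .syntheticLayout(spec)
    corr <- .syntheticCorrelation(spec)
    n <- spec$nResidues
    Sigma <- spec$amplitude^2 * corr$R
    coords <- .withSeed(spec$seed, {
        cc <- array(NA_real_, dim = c(spec$nFrames, n, 3))
        for (d in 1:3) {
            disp <- MASS::mvrnorm(spec$nFrames, mu = rep(0, n),
                                  Sigma = Sigma)
            cc[, , d] <- sweep(disp, 2, layout[, d], `+`)
        }
        cc
    })
    planted <- spec$plantedPath
    k <- length(planted)
    ens <- ConformationalEnsemble(coords)
    list(ensemble = ens,
         truthCorrelation = corr$R,
         plantedEdges = data.frame(i = planted[-k], j = planted[-1]),
         repairDelta = corr$repairDelta,
         layout = layout)
}

#' Specification of a synthetic template/target sequence pair
#'
#' The target equals the template with a list of substitutions and one
#' insertion applied -- emulating a stand-alone template and an
#' allosterically dependent target whose numbering is shifted by the
#' insertion.
#'
#' @param length template length (default 120).
#' @param mutations data.frame with columns \code{position}, \code{to}
#'   and optionally \code{from} (which must then match the template);
#'   default none.
#' @param insertionPosition insertion goes after this template position
#'   (default 100).
#' @param insertionLength number of inserted residues (default 20;
#'   0 disables the insertion).
#' @param seed RNG seed for the template and inserted residues.
#' @return a validated spec (list of class "SyntheticSequenceSpec").
#' @seealso [makeSequences()], [makeMsa()]
#' @export
syntheticSequenceSpec <- function(length = 120L, mutations = NULL,
                                  insertionPosition = 100L,
                                  insertionLength = 20L, seed = 1L) {
    length <- as.integer(length)
    if (is.null(mutations))
        mutations <- data.frame(position = integer(0), to = character(0))
    if (!all(c("position", "to") %in% names(mutations)))
        stop("mutations needs columns position and to")
    if (nrow(mutations) &&
        (min(mutations$position) < 1 || max(mutations$position) > length))
        stop("mutation positions outside template length")
    if (insertionLength < 0L) stop("insertion length must be >= 0")
    if (insertionLength > 0L &&
        (insertionPosition < 0L || insertionPosition > length))
        stop("insertion position outside template")
    structure(list(length = length, mutations = mutations,
                   insertionPosition = as.integer(insertionPosition),
                   insertionLength = as.integer(insertionLength),
                   seed = as.integer(seed)),
              class = "SyntheticSequenceSpec")
}

#' Generate a template/target sequence pair with known differences
#'
#' @param spec a spec from [syntheticSequenceSpec()].
#' @return list with \code{template} and \code{target} (character
#'   sequences) and \code{truth}: a data.frame of planted differences
#'   with columns \code{templatePosition}, \code{templateRes},
#'   \code{targetPosition}, \code{targetRes} and \code{label} (candidate
#'   convention: target residue, target position, template residue).
#' @export
makeSequences <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSequenceSpec"))
    out <- .withSeed(spec$seed, {
        template <- sample(.aaAlphabet, spec$length, replace = TRUE)
        ins <- if (spec$insertionLength > 0L)
            sample(.aaAlphabet, spec$insertionLength, replace = TRUE)
        else character(0)
        list(template = template, ins = ins)
    })
    template <- out$template
    mut <- spec$mutations
    if (nrow(mut)) {
        if ("from" %in% names(mut)) {
            bad <- !is.na(mut$from) &
                mut$from != template[mut$position]
            if (any(bad))
                stop("mutation 'from' residue inconsistent with template at position(s): ",
                     paste(mut$position[bad], collapse = ", "))
        }
        if (any(mut$to == template[mut$position]))
            stop("substitution(s) do not change the template residue")
    }
    target <- template
    if (nrow(mut)) target[mut$position] <- mut$to
    insAt <- spec$insertionPosition
    if (spec$insertionLength > 0L) {
        target <- append(target, out$ins, after = insAt)
    }
    offset <- function(p) p + ifelse(spec$insertionLength > 0L & p > insAt,
                                     spec$insertionLength, 0L)
    truth <- if (nrow(mut)) {
        data.frame(templatePosition = mut$position,
                   templateRes = template[mut$position],
                   targetPosition = offset(mut$position),
                   targetRes = mut$to,
                   label = paste0(mut$to, offset(mut$position),
                                  template[mut$position]))
    } else {
        data.frame(templatePosition = integer(0),
                   templateRes = character(0),
                   targetPosition = integer(0),
                   targetRes = character(0), label = character(0))
    }
    truth <- truth[order(truth$templatePosition), , drop = FALSE]
    rownames(truth) <- NULL
    list(template = paste(template, collapse = ""),
         target = paste(target, collapse = ""),
         truth = truth)
}

#' Generate an alignment with planted per-column conservation
#'
#' Each column's residues equal the template residue with the planted
#' conservation probability and are otherwise drawn uniformly from the
#' remaining 19 amino acids, so the modal-residue frequency recovers the
#' planted level in expectation.
#'
#' @param template template sequence (character); its length sets the
#'   alignment width.
#' @param depth number of sequences (default 52).
#' @param conservation per-column conservation levels in (0, 1],
#'   recycled to the template length (default 0.9).
#' @param seed RNG seed.
#' @return list with \code{msa} (named character vector of aligned
#'   sequences) and \code{truth} (the planted per-column levels).
#' @export
makeMsa <- function(template, depth = 52L, conservation = 0.9,
                    seed = 1L) {
    template <- strsplit(.checkAaString(
        .asSequence(template, "template"), "template sequence"), "")[[1]]
    L <- length(template)
    p <- rep_len(conservation, L)
    if (any(p <= 0 | p > 1)) stop("conservation levels must lie in (0, 1]")
    msa <- .withSeed(seed, {
        m <- matrix("", depth, L)
        for (j in seq_len(L)) {
            keep <- stats::runif(depth) < p[j]
            m[, j] <- template[j]
            nAlt <- sum(!keep)
            if (nAlt)
                m[!keep, j] <- sample(setdiff(.aaAlphabet, template[j]),
                                      nAlt, replace = TRUE)
        }
        apply(m, 1, paste, collapse = "")
    })
    names(msa) <- sprintf("seq%03d", seq_len(depth))
    list(msa = msa, truth = p)
}

#' Draw synthetic two-basin (s, z) samples
#'
#' Mixture of Gaussian basins in path-CV space, e.g. an open and a
#' closed basin with prescribed populations, for testing free-energy
#' surfaces and state-fraction scoring.
#'
#' @param populations basin populations, summing to 1 (default
#'   c(0.7, 0.3): 70% closed, 30% open).
#' @param centers matrix with one \code{(s, z)} row per basin (default:
#'   closed at (0.85, 0.30), open at (0.15, 0.80)).
#' @param spreads matrix of per-basin (s, z) standard deviations
#'   (default 0.04 on s, 0.10 on z).
#' @param n number of samples (default 10000).
#' @param seed RNG seed.
#' @return list with \code{samples} (data.frame of s in [0, 1] and
#'   z >= 0, clipped to valid ranges) and \code{component} (true basin
#'   index per sample).
#' @export
makeTwoBasinSamples <- function(populations = c(0.7, 0.3),
                                centers = rbind(c(0.85, 0.30),
                                                c(0.15, 0.80)),
                                spreads = NULL, n = 10000L, seed = 0L) {
    if (abs(sum(populations) - 1) > 1e-9)
        stop("populations must sum to 1")
    nb <- length(populations)
    centers <- as.matrix(centers)
    if (nrow(centers) != nb) stop("one (s, z) center per basin required")
    if (is.null(spreads))
        spreads <- matrix(rep(c(0.04, 0.10), each = nb), nb, 2)
    out <- .withSeed(seed, {
        comp <- sample.int(nb, n, replace = TRUE, prob = populations)
        s <- stats::rnorm(n, centers[comp, 1], spreads[comp, 1])
        z <- stats::rnorm(n, centers[comp, 2], spreads[comp, 2])
        list(comp = comp, s = pmin(pmax(s, 0), 1), z = pmax(z, 0))
    })
    list(samples = data.frame(s = out$s, z = out$z),
         component = out$comp)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        names(seqs) <- sprintf("seq%03d", seq_along(seqs))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
    invisible(path)
}
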