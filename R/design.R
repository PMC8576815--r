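#' Candidate mutations at SPM positions
#'
#' The design filter: at every SPM position of the template (the
#' stand-alone reference), compare the aligned template and target
#' residues; positions where they differ become candidate mutations for
#' transferring the template's conformational behaviour into the target.
#' Candidates are expressed in target numbering, target residue first
#' (label \code{"<target><pos><template>"}, e.g. A56E = mutate target's
#' A56 to the template's E).  SPM positions aligned to a gap are excluded
#' with a message.
#'
#' @param spmPositions integer vector of template residue numbers
#'   (1-based), e.g. \code{residueLabels(spm)$resno[...]} from an SPM.
#' @param templateSeq,targetSeq the two sequences (as in [alignPair()]).
#' @param mapping optional [AlignmentMap-class] (computed from the
#'   sequences if omitted).
#' @return data.frame with columns \code{targetPosition},
#'   \code{targetResidue}, \code{templateResidue}, \code{templatePosition}
#'   and \code{label}, ordered by position.  Zero rows when the sequences
#'   agree at every SPM position.
#' @examples
#' candidateMutations(c(2, 4), "AKEFG", "AREFG")
#' @export
candidateMutations <- function(spmPositions, templateSeq, targetSeq,
                               mapping = NULL) {
    templateSeq <- .checkAaString(.asSequence(templateSeq, "template"),
                                  "template sequence")
    targetSeq <- .checkAaString(.asSequence(targetSeq, "target"),
                                "target sequence")
    if (length(spmPositions) &&
        (min(spmPositions) < 1 || max(spmPositions) > nchar(templateSeq)))
        stop("SPM positions outside template length")
    if (is.null(mapping))
        mapping <- alignPair(templateSeq, targetSeq)
    cl <- mapping@columns
    pos <- sort(unique(as.integer(spmPositions)))
    rows <- lapply(pos, function(p) {
        k <- match(p, cl$template)
        if (is.na(k)) return(NULL)
        if (is.na(cl$target[k])) {
            message(sprintf(
                "SPM position %d is aligned to a gap in the target; excluded", p))
            return(NULL)
        }
        tRes <- cl$templateRes[k]
        gRes <- cl$targetRes[k]
        if (tRes == gRes) return(NULL)
        data.frame(targetPosition = cl$target[k], targetResidue = gRes,
                   templateResidue = tRes, templatePosition = p,
                   label = paste0(gRes, cl$target[k], tRes))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(targetPosition = integer(0),
                          targetResidue = character(0),
                          templateResidue = character(0),
                          templatePosition = integer(0),
                          label = character(0))
    out <- out[order(out$targetPosition), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Parse and format mutation labels
#'
#' Labels follow the \code{"<current><position><proposed>"} convention
#' (e.g. \code{"A56E"}: residue A at position 56 mutated to E).
#'
#' @param labels character vector of mutation labels.
#' @return \code{parseMutations}: data.frame with \code{from},
#'   \code{position}, \code{to}; \code{formatMutations}: character vector
#'   of labels.
#' @examples
#' parseMutations(c("A56E", "R300M"))
#' @export
parseMutations <- function(labels) {
    m <- regmatches(labels,
                    regexec("^([A-Z])([0-9]+)([A-Z])$", toupper(labels)))
    bad <- lengths(m) != 4L
    if (any(bad))
        stop("malformed mutation label(s): ",
             paste(labels[bad], collapse = ", "))
    data.frame(from = vapply(m, `[`, "", 2L),
               position = as.integer(vapply(m, `[`, "", 3L)),
               to = vapply(m, `[`, "", 4L))
}

#' @rdname parseMutations
#' @param mutations data.frame as returned by \code{parseMutations}.
#' @export
formatMutations <- function(mutations) {
    paste0(mutations$from, mutations$position, mutations$to)
}

.mutationPositions <- function(x) {
    if (is.character(x)) return(parseMutations(x)$position)
    if (is.data.frame(x)) {
        if ("position" %in% names(x)) return(x$position)
        if ("targetPosition" %in% names(x)) return(x$targetPosition)
    }
    stop("expected mutation labels or a candidate-mutation data.frame")
}

#' Shared positions between two mutation sets
#'
#' Compares mutation sets by position only -- the substituted residue
#' identity is ignored, so N299S and N299A share position 299.  Both
#' sets must use the same numbering frame.
#'
#' @param setA,setB mutation label character vectors or candidate
#'   data.frames (see [candidateMutations()]).
#' @return list with \code{nShared} and \code{sharedPositions}.
#' @examples
#' spm3 <- c("S73T", "N299S", "R300M")
#' spm6 <- c("A56E", "D62E", "S73T", "T207S", "N299A", "R300M")
#' positionOverlap(spm3, spm6)$nShared
#' @export
positionOverlap <- function(setA, setB) {
    pa <- unique(.mutationPositions(setA))
    pb <- unique(.mutationPositions(setB))
    shared <- sort(intersect(pa, pb))
    list(nShared = length(shared), sharedPositions = shared)
}

#' Write candidate mutations as TSV
#'
#' @param candidates data.frame from [candidateMutations()], optionally
#'   carrying a \code{conservationBand} column (see [bandPositions()]).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCandidateTsv <- function(candidates, path) {
    utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
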