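#' Globally align a template/target sequence pair
#'
#' Needleman-Wunsch global alignment under BLOSUM62 substitution scores
#' with affine gap penalties (defaults: open 10, extend 0.5), appropriate
#' for full-length homologs.  The result is a column-wise position map
#' used to carry residue numbering between the two systems (e.g. across
#' an insertion that shifts downstream numbering).
#'
#' @param templateSeq,targetSeq amino-acid sequences (character,
#'   \code{AAString}, or single-record \code{AAStringSet}).
#' @param gapOpening,gapExtension affine gap penalties (non-negative).
#' @param substitutionMatrix substitution matrix name or matrix
#'   (default "BLOSUM62").
#' @return an [AlignmentMap-class].
#' @examples
#' m <- alignPair("HEAGAWGHEE", "HEAGAWGHEE")
#' mapPositions(m, 1:10)
#' @export
alignPair <- function(templateSeq, targetSeq, gapOpening = 10,
                      gapExtension = 0.5,
                      substitutionMatrix = "BLOSUM62") {
    templateSeq <- .checkAaString(.asSequence(templateSeq, "template"),
                                  "template sequence")
    targetSeq <- .checkAaString(.asSequence(targetSeq, "target"),
                                "target sequence")
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(templateSeq), Biostrings::AAString(targetSeq),
        substitutionMatrix = substitutionMatrix,
        gapOpening = gapOpening, gapExtension = gapExtension,
        type = "global")
    gappedT <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    gappedG <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    tpos <- cumsum(gappedT != "-")
    gpos <- cumsum(gappedG != "-")
    columns <- data.frame(
        template = ifelse(gappedT == "-", NA_integer_, tpos),
        target = ifelse(gappedG == "-", NA_integer_, gpos),
        templateRes = gappedT,
        targetRes = gappedG)
    new("AlignmentMap", columns = columns, score = Biostrings::score(pa))
}

#' Map template positions to target numbering
#'
#' @param map an [AlignmentMap-class].
#' @param templatePositions integer vector of 1-based template positions.
#' @return integer vector of target positions; NA where the template
#'   position is aligned to a gap or outside the alignment.
#' @export
mapPositions <- function(map, templatePositions) {
    stopifnot(is(map, "AlignmentMap"))
    cl <- map@columns
    idx <- match(templatePositions, cl$template)
    out <- rep(NA_integer_, length(templatePositions))
    out[!is.na(idx)] <- cl$target[idx[!is.na(idx)]]
    out
}

#' @rdname mapPositions
#' @export
alignmentScore <- function(map) {
    stopifnot(is(map, "AlignmentMap"))
    map@score
}
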