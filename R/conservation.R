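#' Per-column conservation of a multiple sequence alignment
#'
#' Scores each alignment column by the frequency of its modal residue
#' among non-gap characters (the simplest conservation definition; ties
#' for the modal residue are broken alphabetically, which does not change
#' the score).  Columns whose gap fraction exceeds 0.5 are flagged
#' unscored (NA): a mostly-gap column carries no conservation signal.
#'
#' @param msa an aligned \code{AAStringSet}, a character vector of
#'   equal-length aligned sequences, or a path to an aligned FASTA file.
#' @param high,low band thresholds (defaults 0.90 and 0.70, i.e. the
#'   conventional "highly conserved" / "poorly conserved" bands).
#' @return a [ConservationProfile-class].
#' @examples
#' msaConservation(c("KKRA", "KKKA", "KRKA", "K-KA"))
#' @export
msaConservation <- function(msa, high = 0.90, low = 0.70) {
    if (is.character(msa) && length(msa) == 1L && file.exists(msa))
        msa <- Biostrings::readAAStringSet(msa)
    if (methods::is(msa, "XStringSet"))
        msa <- as.character(msa)
    if (!is.character(msa))
        stop("msa must be aligned sequences or a FASTA path")
    if (length(msa) < 2L)
        stop("an alignment needs at least 2 sequences")
    widths <- nchar(msa)
    if (length(unique(widths)) != 1L)
        stop("ragged alignment: sequence lengths ",
             paste(sort(unique(widths)), collapse = ", "))
    mat <- do.call(rbind, strsplit(toupper(msa), ""))
    nseq <- nrow(mat)
    ncol_ <- ncol(mat)
    score <- rep(NA_real_, ncol_)
    gapFraction <- numeric(ncol_)
    for (j in seq_len(ncol_)) {
        col <- mat[, j]
        isGap <- col %in% c("-", ".")
        gapFraction[j] <- mean(isGap)
        if (gapFraction[j] > 0.5) next
        res <- col[!isGap]
        tab <- table(res)
        ## alphabetical order of table() names makes the modal pick
        ## deterministic under ties
        score[j] <- max(tab) / length(res)
    }
    new("ConservationProfile", score = score, gapFraction = gapFraction,
        high = high, low = low, nSequences = nseq)
}

#' Band alignment positions by conservation
#'
#' Assigns each position exactly one band: \code{"high"} (score >= high
#' threshold), \code{"low"} (score < low threshold),
#' \code{"intermediate"} otherwise, or \code{"unscored"} for
#' mostly-gap columns.
#'
#' @param profile a [ConservationProfile-class].
#' @param positions integer vector of 1-based column positions.
#' @return character vector of bands, named by position.
#' @export
bandPositions <- function(profile, positions) {
    stopifnot(is(profile, "ConservationProfile"))
    s <- profile@score
    if (length(positions) &&
        (min(positions) < 1 || max(positions) > length(s)))
        stop("position(s) outside the profile length of ", length(s))
    band <- vapply(positions, function(p) {
        if (is.na(s[p])) "unscored"
        else if (s[p] >= profile@high) "high"
        else if (s[p] < profile@low) "low"
        else "intermediate"
    }, character(1))
    names(band) <- positions
    band
}

#' Count columns per conservation band
#'
#' @param profile a [ConservationProfile-class].
#' @return named integer vector with counts of high, intermediate, low
#'   and unscored columns.
#' @export
conservationBandCounts <- function(profile) {
    stopifnot(is(profile, "ConservationProfile"))
    bands <- bandPositions(profile, seq_along(profile@score))
    out <- c(high = sum(bands == "high"),
             intermediate = sum(bands == "intermediate"),
             low = sum(bands == "low"),
             unscored = sum(bands == "unscored"))
    out
}
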