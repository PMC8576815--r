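#' Workflow configuration
#'
#' Bundles every tunable of the SPM design workflow with its default.
#' All values are validated against the preconditions of the stage that
#' consumes them, and the full configuration (plus its hash) is echoed
#' into the design report for provenance.
#'
#' @param cutoff contact cutoff on mean C-alpha distance, Angstrom.
#' @param correlationFloor minimum \eqn{|C|} for a graph edge.
#' @param spmThreshold SPM inclusion threshold (fraction of maximum edge
#'   usage).
#' @param excludeNeighbors drop graph edges between sequence neighbours
#'   within this offset (0 = keep).
#' @param gapOpening,gapExtension affine gap penalties for the
#'   template/target alignment.
#' @param conservationHigh,conservationLow MSA conservation band
#'   thresholds.
#' @param lambda path-CV smoothing constant (NULL = heuristic, see
#'   [pathReference()]).
#' @param kT thermal energy, kcal/mol.
#' @param bins FEL bin counts, two integers.
#' @param stateRanges state intervals on s (see [defaultStateRanges()]).
#' @param selection residue selection for [readEnsemble()].
#' @param seed optional integer seed recorded for provenance.
#' @return a list of class "SpmConfig".
#' @export
spmConfig <- function(cutoff = 6.0, correlationFloor = 1e-6,
                      spmThreshold = 0.3, excludeNeighbors = 0L,
                      gapOpening = 10, gapExtension = 0.5,
                      conservationHigh = 0.90, conservationLow = 0.70,
                      lambda = NULL, kT = 0.596, bins = c(100L, 100L),
                      stateRanges = defaultStateRanges(),
                      selection = list(elety = "CA"), seed = NULL) {
    if (cutoff <= 0) stop("cutoff must be positive")
    if (correlationFloor <= 0 || correlationFloor >= 1)
        stop("correlationFloor must lie in (0, 1)")
    if (spmThreshold < 0 || spmThreshold > 1)
        stop("spmThreshold must lie in [0, 1]")
    if (conservationLow > conservationHigh)
        stop("conservationLow must not exceed conservationHigh")
    if (kT <= 0) stop("kT must be positive")
    msg <- .checkStateRanges(stateRanges)
    if (!is.null(msg)) stop(msg)
    structure(list(cutoff = cutoff, correlationFloor = correlationFloor,
                   spmThreshold = spmThreshold,
                   excludeNeighbors = as.integer(excludeNeighbors),
                   gapOpening = gapOpening, gapExtension = gapExtension,
                   conservationHigh = conservationHigh,
                   conservationLow = conservationLow, lambda = lambda,
                   kT = kT, bins = as.integer(bins),
                   stateRanges = stateRanges, selection = selection,
                   seed = seed),
              class = "SpmConfig")
}

#' @rdname spmConfig
#' @param config an "SpmConfig" list.
#' @return \code{configHash}: md5 hex digest of the serialized
#'   configuration.
#' @export
configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(paste(deparse(config), collapse = ""), tmp)
    unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("workflow stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))
}

#' Run the full SPM-based design workflow
#'
#' Executes ensemble reading, superposition, DCCM, contact-graph
#' construction, shortest-path accumulation, SPM extraction, sequence
#' comparison at the SPM positions and (optionally) MSA conservation
#' banding, then writes a design report (JSON) plus TSV outputs.  The
#' report records the counts at each narrowing stage -- all residues,
#' SPM positions, candidate mutations -- i.e. how far the sequence
#' space was reduced.
#'
#' @param structureFile multi-model PDB of the ensemble (or topology).
#' @param templateFasta FASTA of the stand-alone template sequence
#'   (numbering must match the ensemble's residue numbering).
#' @param targetFasta FASTA of the design target sequence.
#' @param trajectoryFile optional XYZ trajectory (see [readEnsemble()]).
#' @param msaFasta optional aligned FASTA for conservation banding; its
#'   first record must be the (possibly gapped) template so that columns
#'   can be mapped to template numbering.
#' @param weightsFile optional plain-text per-frame weights.
#' @param config an [spmConfig()] list.
#' @param outDir output directory (created if missing).
#' @param prefix file-name prefix for outputs.
#' @return invisibly, the report list (also written as
#'   \code{<prefix>_report.json}).
#' @export
runWorkflow <- function(structureFile, templateFasta, targetFasta,
                        trajectoryFile = NULL, msaFasta = NULL,
                        weightsFile = NULL, config = spmConfig(),
                        outDir = ".", prefix = "allospm") {
    stopifnot(inherits(config, "SpmConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    path <- function(suffix) file.path(outDir, paste0(prefix, suffix))

    ens <- .stage("read_ensemble",
        readEnsemble(structureFile, trajectoryFile,
                     selection = config$selection,
                     frameWeights = weightsFile))
    sup <- .stage("superpose", superposeEnsemble(ens, "mean"))
    dccm <- .stage("dccm", computeDccm(sup$ensemble))
    dists <- .stage("mean_distances", meanDistances(sup$ensemble))
    graph <- .stage("build_graph",
        buildGraph(dccm, dists, cutoff = config$cutoff,
                   correlationFloor = config$correlationFloor,
                   excludeNeighbors = config$excludeNeighbors))
    raw <- .stage("accumulate_paths", accumulatePaths(graph))
    spm <- .stage("extract_spm", extractSpm(raw, config$spmThreshold))
    spmResno <- residueLabels(spm)$resno[spm@spmPositions]

    template <- .stage("read_template",
        .asSequence(Biostrings::readAAStringSet(templateFasta), "template"))
    target <- .stage("read_target",
        .asSequence(Biostrings::readAAStringSet(targetFasta), "target"))
    mapping <- .stage("align_pair",
        alignPair(template, target, gapOpening = config$gapOpening,
                  gapExtension = config$gapExtension))
    candidates <- .stage("candidate_mutations",
        candidateMutations(spmResno, template, target, mapping))

    conservation <- NULL
    if (!is.null(msaFasta)) {
        profile <- .stage("msa_conservation",
            msaConservation(msaFasta, high = config$conservationHigh,
                            low = config$conservationLow))
        ## map template positions to MSA columns through the first
        ## (template) record of the alignment
        msa <- Biostrings::readAAStringSet(msaFasta)
        refChars <- strsplit(as.character(msa[[1]]), "")[[1]]
        colOfPos <- which(!(refChars %in% c("-", ".")))
        bandOf <- function(p) {
            if (p > length(colOfPos)) return("unscored")
            unname(bandPositions(profile, colOfPos[p]))
        }
        candidates$conservationBand <-
            vapply(candidates$templatePosition, bandOf, character(1))
        conservation <- list(
            nColumns = length(profile@score),
            bandCounts = as.list(conservationBandCounts(profile)),
            thresholds = list(high = config$conservationHigh,
                              low = config$conservationLow))
    }

    writeMatrixTsv(dccm, path("_dccm.tsv"))
    writeMatrixTsv(dists, path("_distances.tsv"))
    writeEdgeTsv(graph, path("_graph.tsv"))
    writeEdgeTsv(spm, path("_spm.tsv"))
    writeCandidateTsv(candidates, path("_candidates.tsv"))

    report <- list(
        config = config[setdiff(names(config), "stateRanges")],
        configHash = configHash(config),
        funnel = list(nResidues = nResidues(ens),
                      nSpmPositions = length(spmResno),
                      nCandidates = nrow(candidates)),
        spmPositions = spmResno,
        candidates = candidates,
        conservation = if (is.null(conservation)) "skipped" else conservation,
        alignmentScore = alignmentScore(mapping))
    jsonlite::write_json(report, path("_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    invisible(report)
}
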