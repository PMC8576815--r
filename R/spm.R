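#' Build the residue correlation graph
#'
#' Joins every residue pair whose ensemble-mean distance is below
#' \code{cutoff} and whose absolute correlation is at least
#' \code{correlationFloor}; the edge weight is \eqn{-\ln|C_{ij}|}
#' (clamped at \eqn{|C| = 1} so weights stay non-negative).  Pairs with
#' \eqn{|C|} below the floor are dropped: their weight would be so large
#' that no shortest path could use them.
#'
#' @param C a [CorrelationMatrix-class].
#' @param d a [MeanDistanceMatrix-class] with the same residue labels.
#' @param cutoff contact cutoff on the mean C-alpha distance, Angstrom
#'   (default 6.0).
#' @param correlationFloor minimum \eqn{|C|} for an edge (default 1e-6).
#' @param excludeNeighbors drop edges between residues within this many
#'   sequence positions on the same chain (default 0 = keep all); useful
#'   for sensitivity analysis since chain neighbours are always in
#'   contact.
#' @return a [CorrelationGraph-class].
#' @export
buildGraph <- function(C, d, cutoff = 6.0, correlationFloor = 1e-6,
                       excludeNeighbors = 0L) {
    stopifnot(is(C, "CorrelationMatrix"), is(d, "MeanDistanceMatrix"))
    if (!.sameLabels(residueLabels(C), residueLabels(d)))
        stop("correlation and distance matrices have different residue labels")
    if (cutoff <= 0) stop("cutoff must be positive")
    if (correlationFloor <= 0 || correlationFloor >= 1)
        stop("correlationFloor must lie in (0, 1)")
    labels <- residueLabels(C)
    cm <- matrixValues(C)
    dm <- matrixValues(d)
    n <- nrow(cm)
    idx <- which(upper.tri(dm) & dm < cutoff & abs(cm) >= correlationFloor,
                 arr.ind = TRUE)
    edges <- data.frame(i = idx[, 1], j = idx[, 2],
                        dist = dm[idx], corr = cm[idx])
    if (excludeNeighbors > 0L && nrow(edges)) {
        sameChain <- labels$chain[edges$i] == labels$chain[edges$j]
        near <- abs(labels$resno[edges$i] - labels$resno[edges$j]) <=
            excludeNeighbors
        edges <- edges[!(sameChain & near), , drop = FALSE]
    }
    edges$weight <- -log(pmin(abs(edges$corr), 1))
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
    new("CorrelationGraph", edges = edges, residueLabels = labels,
        cutoff = cutoff, correlationFloor = correlationFloor)
}

## Deterministic Dijkstra from one source over an adjacency structure.
## Ties (equal distance within eps) are broken towards the predecessor
## with the smallest index; the vertex scan itself picks the smallest
## index among minimum-distance candidates.  Returns dist and pred.
.dijkstra <- function(n, adj, source) {
    dist <- rep(Inf, n)
    pred <- rep(NA_integer_, n)
    done <- rep(FALSE, n)
    dist[source] <- 0
    repeat {
        cand <- which(!done & is.finite(dist))
        if (!length(cand)) break
        u <- cand[which.min(dist[cand])]
        done[u] <- TRUE
        nb <- adj[[u]]
        if (is.null(nb)) next
        v <- nb$v
        nd <- dist[u] + nb$w
        eps <- 1e-12 * pmax(1, nd)
        for (k in seq_along(v)) {
            vk <- v[k]
            if (done[vk]) next
            if (nd[k] < dist[vk] - eps[k]) {
                dist[vk] <- nd[k]
                pred[vk] <- u
            } else if (abs(nd[k] - dist[vk]) <= eps[k] &&
                       (is.na(pred[vk]) || u < pred[vk])) {
                pred[vk] <- u
            }
        }
    }
    list(dist = dist, pred = pred)
}

.adjacency <- function(n, edges) {
    adj <- vector("list", n)
    if (!nrow(edges)) return(adj)
    for (k in seq_len(nrow(edges))) {
        i <- edges$i[k]; j <- edges$j[k]; w <- edges$weight[k]
        adj[[i]]$v <- c(adj[[i]]$v, j); adj[[i]]$w <- c(adj[[i]]$w, w)
        adj[[j]]$v <- c(adj[[j]]$v, i); adj[[j]]$w <- c(adj[[j]]$w, w)
    }
    adj
}

#' All-pairs shortest-path distances on the correlation graph
#'
#' @param g a [CorrelationGraph-class].
#' @return numeric n x n matrix of minimum total \eqn{-\ln|C|} path
#'   weights (Inf between components, 0 on the diagonal).
#' @export
shortestPathDistances <- function(g) {
    stopifnot(is(g, "CorrelationGraph"))
    n <- nrow(residueLabels(g))
    adj <- .adjacency(n, edgeTable(g))
    out <- matrix(Inf, n, n)
    for (s in seq_len(n)) out[s, ] <- .dijkstra(n, adj, s)$dist
    out
}

#' Accumulate shortest-path usage over all residue pairs
#'
#' For every unordered pair of residues in the same connected component,
#' one minimum-total-weight path is computed (deterministic tie-break:
#' lexicographically smallest predecessor index) and each traversed
#' edge's usage count is incremented.  Edge usage, normalized by its
#' maximum, measures how much each contact contributes to the enzyme's
#' internal communication; this is the quantity the SPM thresholds.
#'
#' @param g a non-empty [CorrelationGraph-class].
#' @return a raw (un-thresholded) [SpmResult-class]; pass it to
#'   [extractSpm()].
#' @export
accumulatePaths <- function(g) {
    stopifnot(is(g, "CorrelationGraph"))
    labels <- residueLabels(g)
    n <- nrow(labels)
    if (n == 0L) stop("graph has no nodes")
    edges <- edgeTable(g)
    usage <- integer(nrow(edges))
    eid <- matrix(0L, n, n)
    if (nrow(edges)) {
        eid[cbind(edges$i, edges$j)] <- seq_len(nrow(edges))
        eid[cbind(edges$j, edges$i)] <- seq_len(nrow(edges))
        adj <- .adjacency(n, edges)
        for (s in seq_len(n - 1L)) {
            sp <- .dijkstra(n, adj, s)
            for (t in (s + 1L):n) {
                if (!is.finite(sp$dist[t])) next
                v <- t
                while (v != s) {
                    u <- sp$pred[v]
                    k <- eid[u, v]
                    usage[k] <- usage[k] + 1L
                    v <- u
                }
            }
        }
    }
    edges$usage <- usage
    mx <- max(usage, 0L)
    edges$norm <- if (mx > 0) usage / mx else rep(0, length(usage))
    nodeWeight <- numeric(n)
    if (nrow(edges)) {
        for (k in seq_len(nrow(edges))) {
            nodeWeight[edges$i[k]] <- max(nodeWeight[edges$i[k]],
                                          edges$norm[k])
            nodeWeight[edges$j[k]] <- max(nodeWeight[edges$j[k]],
                                          edges$norm[k])
        }
    }
    new("SpmResult", edges = edges, residueLabels = labels,
        nodeWeight = nodeWeight, spmPositions = integer(0),
        threshold = NA_real_)
}

#' Extract the shortest path map at an inclusion threshold
#'
#' Keeps edges whose normalized usage is at least \code{threshold}; the
#' residues incident to a kept edge are the SPM positions -- the subset
#' of residues lying on the communication pathways that contribute most
#' to the conformational dynamics.
#'
#' @param spm a raw [SpmResult-class] from [accumulatePaths()].
#' @param threshold fraction of the maximum edge usage in [0, 1]
#'   (default 0.3).
#' @return a thresholded [SpmResult-class].
#' @export
extractSpm <- function(spm, threshold = 0.3) {
    stopifnot(is(spm, "SpmResult"))
    if (threshold < 0 || threshold > 1)
        stop("threshold must lie in [0, 1]")
    edges <- edgeTable(spm)
    keep <- edges$usage > 0 & edges$norm >= threshold
    kept <- edges[keep, , drop = FALSE]
    rownames(kept) <- NULL
    pos <- sort(unique(c(kept$i, kept$j)))
    new("SpmResult", edges = kept, residueLabels = residueLabels(spm),
        nodeWeight = spm@nodeWeight, spmPositions = as.integer(pos),
        threshold = threshold)
}

#' Compare two shortest path maps across homologous systems
#'
#' Counts how many SPM positions of a reference system are also detected
#' in the SPM of another system, mapping residue numbering through an
#' [AlignmentMap-class] (identity mapping when \code{mapping = NULL}).
#' Positions absent from the mapping are counted unshared with a warning.
#'
#' @param a reference thresholded [SpmResult-class].
#' @param b other thresholded [SpmResult-class].
#' @param mapping optional [AlignmentMap-class] from a's numbering
#'   (template) to b's numbering (target).
#' @return a [SpmComparison-class]; \code{percentShared} is relative to
#'   the reference SPM size.
#' @export
compareSpms <- function(a, b, mapping = NULL) {
    stopifnot(is(a, "SpmResult"), is(b, "SpmResult"))
    posA <- residueLabels(a)$resno[a@spmPositions]
    posB <- residueLabels(b)$resno[b@spmPositions]
    if (is.null(mapping)) {
        mapped <- posA
    } else {
        mapped <- mapPositions(mapping, posA)
        if (anyNA(mapped))
            warning(sum(is.na(mapped)),
                    " SPM position(s) absent from the mapping; counted unshared")
    }
    sharedMask <- !is.na(mapped) & mapped %in% posB
    shared <- sort(posA[sharedMask])
    nRef <- length(posA)
    new("SpmComparison",
        sharedPositions = as.integer(shared),
        nShared = length(shared),
        nReference = nRef,
        nOther = length(posB),
        percentShared = if (nRef) 100 * length(shared) / nRef else 0)
}

#' Write a graph or SPM edge list as TSV
#'
#' Columns: residue labels and indices of both endpoints, mean distance,
#' correlation, \eqn{-\ln|C|} weight, and (for SPM results) usage and
#' normalized usage.
#'
#' @param x a [CorrelationGraph-class] or [SpmResult-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEdgeTsv <- function(x, path) {
    edges <- edgeTable(x)
    lab <- .labelString(residueLabels(x))
    out <- cbind(data.frame(res_i = lab[edges$i], res_j = lab[edges$j]),
                 edges)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.asIgraph <- function(x) {
    edges <- edgeTable(x)
    lab <- .labelString(residueLabels(x))
    g <- igraph::graph_from_data_frame(
        data.frame(from = lab[edges$i], to = lab[edges$j],
                   weight = edges$weight, dist = edges$dist,
                   corr = edges$corr,
                   usage = if ("usage" %in% names(edges)) edges$usage else 0L,
                   norm = if ("norm" %in% names(edges)) edges$norm else 0),
        directed = FALSE,
        vertices = data.frame(name = lab))
    g
}

#' Write a graph or SPM result as GraphML
#'
#' @param x a [CorrelationGraph-class] or [SpmResult-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGraphml <- function(x, path) {
    igraph::write_graph(.asIgraph(x), path, format = "graphml")
    invisible(path)
}

#' Write a PyMOL command script rendering an SPM
#'
#' Spheres on SPM positions and cylinders (distance objects) on SPM
#' edges, sized by normalized usage, for display on the parent structure.
#'
#' @param spm a thresholded [SpmResult-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePymolScript <- function(spm, path) {
    stopifnot(is(spm, "SpmResult"))
    lab <- residueLabels(spm)
    edges <- edgeTable(spm)
    lines <- c("# SPM rendering script",
               "hide everything", "show cartoon", "color grey80")
    for (p in spm@spmPositions) {
        lines <- c(lines, sprintf(
            "show spheres, chain %s and resi %d and name CA",
            lab$chain[p], lab$resno[p]))
        lines <- c(lines, sprintf(
            "set sphere_scale, %.3f, chain %s and resi %d",
            0.3 + 0.7 * spm@nodeWeight[p], lab$chain[p], lab$resno[p]))
    }
    for (k in seq_len(nrow(edges))) {
        lines <- c(lines, sprintf(
            "distance spm_edge_%d, chain %s and resi %d and name CA, chain %s and resi %d and name CA",
            k, lab$chain[edges$i[k]], lab$resno[edges$i[k]],
            lab$chain[edges$j[k]], lab$resno[edges$j[k]]))
    }
    lines <- c(lines, "hide labels, spm_edge_*", "color black, spm_edge_*")
    writeLines(lines, path)
    invisible(path)
}
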