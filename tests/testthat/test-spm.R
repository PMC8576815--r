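.labels3 <- function(n) data.frame(chain = "A", resno = seq_len(n),
                                   resid = "ALA")

.corrOf <- function(m) new("CorrelationMatrix", values = m,
                           residueLabels = .labels3(nrow(m)))
.distOf <- function(m) new("MeanDistanceMatrix", values = m,
                           residueLabels = .labels3(nrow(m)))

test_that("graph edges follow the -ln|C| weight and contact cutoff rules", {
    C <- diag(3)
    C[1, 2] <- C[2, 1] <- 1       # perfect correlation
    C[1, 3] <- C[3, 1] <- 0.5
    C[2, 3] <- C[3, 2] <- 0.9
    d <- matrix(c(0, 4, 4, 4, 0, 7, 4, 7, 0), 3, 3)
    g <- buildGraph(.corrOf(C), .distOf(d), cutoff = 6)
    e <- edgeTable(g)
    expect_equal(nrow(e), 2L)                       # 2-3 excluded by cutoff
    expect_equal(e$weight[e$i == 1 & e$j == 2], 0)  # |C| = 1 -> weight 0
    expect_equal(e$weight[e$i == 1 & e$j == 3], log(2), tolerance = 1e-12)
    ## negative correlation uses |C|
    C[1, 3] <- C[3, 1] <- -0.5
    g2 <- buildGraph(.corrOf(C), .distOf(d))
    expect_equal(edgeTable(g2)$weight[2], log(2), tolerance = 1e-12)
})

test_that("label mismatch between correlation and distance matrices is an error", {
    C <- .corrOf(diag(3))
    d <- new("MeanDistanceMatrix", values = matrix(0, 4, 4),
             residueLabels = .labels3(4))
    expect_error(buildGraph(C, d), "different residue labels")
})

test_that("a single connected pair yields usage one on its edge; disconnected pairs none", {
    C <- diag(3); C[1, 2] <- C[2, 1] <- 0.8
    d <- matrix(8, 3, 3); diag(d) <- 0; d[1, 2] <- d[2, 1] <- 4
    raw <- accumulatePaths(buildGraph(.corrOf(C), .distOf(d)))
    e <- edgeTable(raw)
    expect_equal(nrow(e), 1L)
    expect_equal(e$usage, 1L)   # node 3 is isolated and contributes nothing
    expect_equal(e$norm, 1)
})

test_that("shortest-path distances match the Floyd-Warshall oracle on random graphs", {
    for (seed in 1:10) {
        g <- randomGraph(n = sample(5:30, 1), pEdge = 0.25, seed = seed)
        got <- shortestPathDistances(g)
        want <- oracleFloydWarshall(nrow(residueLabels(g)), edgeTable(g))
        expect_lt(max(abs(got - want), na.rm = TRUE), 1e-9)
    }
})

test_that("total edge usage equals the summed hop length of the chosen paths", {
    ## continuous random weights make shortest paths a.s. unique, so an
    ## independent igraph traversal must choose the same paths
    for (seed in c(2, 5)) {
        g <- randomGraph(n = 15, pEdge = 0.3, seed = seed)
        raw <- accumulatePaths(g)
        e <- edgeTable(g)
        ig <- igraph::graph_from_data_frame(
            data.frame(from = e$i, to = e$j, weight = e$weight),
            directed = FALSE, vertices = data.frame(name = 1:15))
        total <- 0L
        for (s in 1:14) {
            sp <- igraph::shortest_paths(ig, from = as.character(s),
                                         to = as.character((s + 1):15),
                                         weights = igraph::E(ig)$weight)
            total <- total + sum(vapply(sp$vpath, function(v)
                max(length(v) - 1L, 0L), integer(1)))
        }
        expect_equal(sum(edgeTable(raw)$usage), total)
    }
})

test_that("identical inputs give byte-identical SPM results", {
    g <- randomGraph(n = 20, seed = 3)
    r1 <- serialize(accumulatePaths(g), NULL)
    r2 <- serialize(accumulatePaths(g), NULL)
    expect_identical(r1, r2)
})

test_that("SPM thresholding keeps everything at 0, only maxima at 1, and is monotone", {
    g <- randomGraph(n = 18, seed = 6)
    raw <- accumulatePaths(g)
    used <- edgeTable(raw)[edgeTable(raw)$usage > 0, ]
    all0 <- extractSpm(raw, 0)
    expect_equal(nrow(edgeTable(all0)), nrow(used))
    only1 <- extractSpm(raw, 1)
    expect_true(all(edgeTable(only1)$usage == max(used$usage)))
    prev <- NULL
    for (t in c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
        pos <- extractSpm(raw, t)@spmPositions
        if (!is.null(prev)) expect_true(all(pos %in% prev))
        prev <- pos
    }
})

test_that("SPM comparison counts mapped shared positions", {
    a <- spmWithPositions(c(3, 5, 8, 10, 12), n = 15)
    expect_equal(compareSpms(a, a)@percentShared, 100)
    b <- spmWithPositions(c(5, 10, 12, 14), n = 15)
    cmp <- compareSpms(a, b)
    expect_equal(cmp@nShared, 3L)           # 3 of 5 shared
    expect_equal(cmp@percentShared, 60)
    expect_equal(cmp@sharedPositions, c(5L, 10L, 12L))
    disjoint <- spmWithPositions(c(1, 2), n = 15)
    expect_equal(compareSpms(a, disjoint)@nShared, 0L)
})

test_that("SPM comparison maps numbering through an alignment and warns on unmapped positions", {
    ## target numbering = template + 2 beyond an insertion after pos 4
    tpl <- "ACDEFGHIKL"
    tgt <- "ACDEWWFGHIKL"
    map <- alignPair(tpl, tgt)
    a <- spmWithPositions(c(2, 6, 9), n = 10)
    b <- spmWithPositions(c(2, 8, 10), n = 12)   # 6 -> 8, 9 -> 11
    cmp <- compareSpms(a, b, map)
    expect_equal(cmp@nShared, 2L)
    expect_equal(cmp@sharedPositions, c(2L, 6L))
})

test_that("graph writers emit parseable edge lists", {
    g <- randomGraph(n = 8, seed = 9)
    spm <- extractSpm(accumulatePaths(g), 0.3)
    tsv <- tempfile(fileext = ".tsv")
    writeEdgeTsv(spm, tsv)
    back <- read.delim(tsv)
    expect_equal(nrow(back), nrow(edgeTable(spm)))
    expect_true(all(c("res_i", "res_j", "usage", "norm") %in% names(back)))
    gml <- tempfile(fileext = ".graphml")
    writeGraphml(spm, gml)
    expect_gt(file.size(gml), 0)
    pml <- tempfile(fileext = ".pml")
    writePymolScript(spm, pml)
    expect_true(any(grepl("spheres", readLines(pml))))
})
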