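test_that("the full design workflow recovers the planted mutations and funnels monotonically", {
    sc <- plantedScenario(nFrames = 2000, seed = 0)
    dirW <- tempfile(); dir.create(dirW)
    pdb <- file.path(dirW, "ens.pdb")
    writeEnsemblePdb(sc$syn$ensemble, pdb)
    tplFa <- file.path(dirW, "template.fasta")
    tgtFa <- file.path(dirW, "target.fasta")
    writeFasta(c(template = sc$seqs$template), tplFa)
    writeFasta(c(target = sc$seqs$target), tgtFa)
    msa <- makeMsa(sc$seqs$template, depth = 30, conservation = 0.85,
                   seed = 2)
    msaFa <- file.path(dirW, "msa.fasta")
    writeFasta(c(template = sc$seqs$template, msa$msa[-1]), msaFa)

    report <- runWorkflow(pdb, tplFa, tgtFa, msaFasta = msaFa,
                          config = spmConfig(), outDir = dirW,
                          prefix = "run")
    ## candidates equal the truth-table rows at planted positions
    truthAtSpm <- sc$seqs$truth[
        sc$seqs$truth$templatePosition %in% sc$plantedMutPositions, ]
    expect_equal(report$candidates$label, truthAtSpm$label)
    expect_equal(report$candidates$targetPosition,
                 truthAtSpm$targetPosition)
    ## decoys on low-usage chain ends are filtered out by the SPM
    expect_false(any(sc$decoyPositions %in%
                     report$candidates$templatePosition))
    ## funnel: candidates <= SPM positions <= residues
    f <- report$funnel
    expect_lte(f$nCandidates, f$nSpmPositions)
    expect_lte(f$nSpmPositions, f$nResidues)
    expect_true(all(report$candidates$templatePosition %in%
                    report$spmPositions))
    ## conservation section present and every candidate banded
    expect_true(all(report$candidates$conservationBand %in%
                    c("high", "low", "intermediate", "unscored")))
    ## all declared outputs exist
    outs <- file.path(dirW, paste0("run", c("_dccm.tsv", "_distances.tsv",
                                            "_graph.tsv", "_spm.tsv",
                                            "_candidates.tsv",
                                            "_report.json")))
    expect_true(all(file.exists(outs)))
})

test_that("the workflow is deterministic and marks a missing MSA as skipped", {
    sc <- plantedScenario(nFrames = 400, seed = 3)
    dirW <- tempfile(); dir.create(dirW)
    pdb <- file.path(dirW, "ens.pdb")
    writeEnsemblePdb(sc$syn$ensemble, pdb)
    tplFa <- file.path(dirW, "t.fasta"); tgtFa <- file.path(dirW, "g.fasta")
    writeFasta(c(t = sc$seqs$template), tplFa)
    writeFasta(c(g = sc$seqs$target), tgtFa)
    r1 <- runWorkflow(pdb, tplFa, tgtFa, outDir = dirW, prefix = "a")
    r2 <- runWorkflow(pdb, tplFa, tgtFa, outDir = dirW, prefix = "b")
    expect_identical(r1$candidates, r2$candidates)
    expect_identical(r1$spmPositions, r2$spmPositions)
    expect_identical(r1$configHash, r2$configHash)
    expect_identical(r1$conservation, "skipped")
    expect_identical(readLines(file.path(dirW, "a_spm.tsv")),
                     readLines(file.path(dirW, "b_spm.tsv")))
})

test_that("workflow errors carry the failing stage name", {
    dirW <- tempfile(); dir.create(dirW)
    fa <- file.path(dirW, "x.fasta")
    writeFasta(c(x = "ACDEFG"), fa)
    expect_error(runWorkflow(file.path(dirW, "absent.pdb"), fa, fa,
                             outDir = dirW),
                 "read_ensemble")
})

test_that("configuration is validated and hashed stably", {
    expect_error(spmConfig(cutoff = -1), "cutoff")
    expect_error(spmConfig(spmThreshold = 2), "spmThreshold")
    expect_error(spmConfig(stateRanges = list(O = c(0, 0.5),
                                              C = c(0.4, 1))), "overlap")
    c1 <- spmConfig(); c2 <- spmConfig()
    expect_identical(configHash(c1), configHash(c2))
    expect_false(identical(configHash(c1),
                           configHash(spmConfig(cutoff = 7))))
})

test_that("the command-line script runs the synth and spm subcommands", {
    script <- system.file("scripts", "allospm.R", package = "alloSPM")
    expect_true(nzchar(script))
    dirW <- tempfile(); dir.create(dirW)
    rscript <- file.path(R.home("bin"), "Rscript")
    env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
    out1 <- system2(rscript, c(script, "synth", "--frames", "200",
                               "--seed", "0", "--out",
                               file.path(dirW, "syn")),
                    env = env, stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(file.path(dirW, "syn_ensemble.pdb")))
    expect_true(file.exists(file.path(dirW, "syn_template.fasta")))
    out2 <- system2(rscript, c(script, "spm", "--structure",
                               file.path(dirW, "syn_ensemble.pdb"),
                               "--out", file.path(dirW, "spm")),
                    env = env, stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(file.path(dirW, "spm_spm.tsv")))
    spmTab <- read.delim(file.path(dirW, "spm_spm.tsv"))
    expect_gt(nrow(spmTab), 0)
})
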