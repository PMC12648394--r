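# Shared end-to-end fixture: a balanced family with two modules and one
# function planted at the same ancestral node, written as pipeline inputs.

writeFixtureInputs <- function(dir, seed = 71) {
    ## balanced 8-leaf tree; two modules and the function gained at the
    ## (P1,P2) cherry, a third module at the four-leaf clade (P5..P8)
    tr <- gtree(paste0("(((P1:1,P2:1):1,(P3:1,P4:1):1):1,",
                       "((P5:1,P6:1):1,(P7:1,P8:1):1):1);"))
    target <- "g2"
    other <- "g4"
    sim <- plantModulesAndSequences(
        tr, list(list(gainNode = target, width = 16, rate = 0),
                 list(gainNode = target, width = 16, rate = 0),
                 list(gainNode = other, width = 16, rate = 0)),
        backgroundLength = 100, seed = seed + 1, disjointAlphabet = TRUE)
    pf <- plantFunctions(tr, list(list(functionId = "f1",
                                       gainNode = target)))
    fasta <- file.path(dir, "family.fasta")
    nwk <- file.path(dir, "genetree.nwk")
    annot <- file.path(dir, "annotations.csv")
    writeProteinFasta(sim$records, fasta)
    writeGeneTree(tr, nwk)
    utils::write.csv(pf$annotations, annot, row.names = FALSE, quote = FALSE)
    ids <- file.path(dir, "annotated_ids.txt")
    writeLines(sim$records$protein_id, ids)  # fully annotated family
    list(tree = tr, sim = sim, target = target, other = other,
         fasta = fasta, nwk = nwk, annot = annot, ids = ids)
}

fixtureConfig <- function(fx, outDir, ...) {
    pipelineConfig(fasta = fx$fasta, tree = fx$nwk, annotations = fx$annot,
                   outDir = outDir, annotatedIds = fx$ids, minWidth = 8,
                   nRuns = 5, baseSeed = 7, ...)
}
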