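test_that("Dollo presence matches the enumeration oracle", {
    gt <- gtree("((A:1,B:1):1,(C:1,D:1):1);")

    cases <- list(c("A", "B"), c("A"), c("A", "D"), c("A", "B", "C", "D"),
                  c("B", "C", "D"))
    for (carriers in cases) {
        dp <- dolloPresence(gt, carriers)
        best <- oracleDolloStates(gt, carriers)
        expect_equal(length(best), 1L)   # the minimum is unique
        expect_equal(presenceState(dp)[treeNodes(gt)],
                     best[[1]][treeNodes(gt)])
    }

    ## spec'd spot checks
    dp <- dolloPresence(gt, c("A", "B"))
    expect_equal(names(which(presenceState(dp))), c("g1", "A", "B"))
    dp <- dolloPresence(gt, "A")
    expect_equal(names(which(presenceState(dp))), "A")
    dp <- dolloPresence(gt, c("A", "D"))
    expect_setequal(names(which(presenceState(dp))),
                    c("g0", "g1", "A", "g2", "D"))
    expect_error(dolloPresence(gt, character(0)), "empty carrier")
})

test_that("Dollo oracle agrees on random 6-leaf fixtures", {
    for (s in 1:6) {
        gt <- randomBinaryGeneTree(6, seed = 100 + s)
        set.seed(200 + s)
        carriers <- sample(treeLeaves(gt), sample(1:5, 1))
        dp <- dolloPresence(gt, carriers)
        best <- oracleDolloStates(gt, carriers)
        expect_equal(length(best), 1L)
        expect_equal(presenceState(dp)[treeNodes(gt)],
                     best[[1]][treeNodes(gt)])
    }
})

test_that("DTL reconciliation reproduces the worked examples", {
    gt <- gtree("((A:1,B:1):1,(C:1,D:1):1);")

    ## congruent module tree: all speciations, zero cost, present everywhere
    mt <- gtree("((A:1,B:1):1,(C:1,D:1):1);")
    rec <- dtlReconcile(mt, gt)
    expect_equal(reconciliationCost(rec), 0)
    ev <- reconciliationEvents(rec)
    expect_true(all(ev[!grepl("leaf", ev)] == "speciation"))
    expect_equal(length(rec@losses), 0L)
    pm <- presenceFromReconciliation(rec, gt)
    expect_true(all(presenceState(pm)))

    ## cherry (A, C): speciation at the root plus losses above B and D
    mt2 <- gtree("(A:1,C:1);")
    rec2 <- dtlReconcile(mt2, gt)
    expect_equal(reconciliationCost(rec2), 2)
    expect_setequal(rec2@losses, c("B", "D"))
    pm2 <- presenceFromReconciliation(rec2, gt)
    expect_setequal(names(which(presenceState(pm2))),
                    c("g0", "g1", "A", "g2", "C"))

    ## degenerate single-carrier module
    rec3 <- dtlReconcile("B", gt)
    expect_equal(reconciliationCost(rec3), 0)
    pm3 <- presenceFromReconciliation(rec3, gt)
    expect_equal(names(which(presenceState(pm3))), "B")
    expect_error(dtlReconcile("Z", gt), "not a gene leaf")
})

test_that("DP cost equals the exhaustive-search minimum", {
    set.seed(424242)
    for (i in 1:30) {
        nG <- sample(4:6, 1)
        gt <- randomBinaryGeneTree(nG, seed = 1000 + i)
        carriers <- sort(sample(treeLeaves(gt), sample(2:4, 1)))
        mt <- randomModuleTopology(carriers, seed = 2000 + i)
        costs <- suppressWarnings(
            reconciliationCosts(dup = runif(1, 0.5, 4),
                                transfer = runif(1, 1, 5),
                                loss = runif(1, 0.2, 2)))
        rec <- dtlReconcile(mt, gt, costs)
        expect_equal(reconciliationCost(rec),
                     oracleDtlCost(mt, gt, costs), tolerance = 1e-9)
    }
})

test_that("reconciliation cost is monotone in each event cost", {
    gt <- randomBinaryGeneTree(6, seed = 77)
    carriers <- treeLeaves(gt)[c(1, 3, 5)]
    mt <- randomModuleTopology(carriers, seed = 78)
    base <- reconciliationCosts(dup = 2, transfer = 3, loss = 1)
    c0 <- reconciliationCost(dtlReconcile(mt, gt, base))
    for (bump in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0.5))) {
        up <- reconciliationCosts(dup = 2 + bump[1], transfer = 3 + bump[2],
                                  loss = 1 + bump[3])
        expect_gte(reconciliationCost(dtlReconcile(mt, gt, up)), c0)
    }
})

test_that("leaf fidelity holds for both presence backends", {
    gt <- randomBinaryGeneTree(7, seed = 9)
    set.seed(10)
    carriers <- sort(sample(treeLeaves(gt), 4))
    mt <- randomModuleTopology(carriers, seed = 11)

    dp <- dolloPresence(gt, carriers)
    rp <- presenceFromReconciliation(dtlReconcile(mt, gt), gt)
    for (lf in treeLeaves(gt)) {
        expect_equal(unname(presenceState(dp)[lf]), lf %in% carriers)
        expect_equal(unname(presenceState(rp)[lf]), lf %in% carriers)
    }
})

test_that("Dollo and DTL agree for congruent trees with expensive transfer", {
    gt <- randomBinaryGeneTree(8, seed = 15)
    ## congruent module tree: restriction of the gene tree to a clade
    cl <- names(gt@children)[3]
    carriers <- phyloModules:::.leavesUnder(gt, cl)
    sub <- ape::keep.tip(asPhylo(gt), carriers)
    mt <- geneTreeFromPhylo(sub)
    costs <- reconciliationCosts(dup = 2, transfer = 50, loss = 1)
    rp <- presenceFromReconciliation(dtlReconcile(mt, gt, costs), gt)
    dp <- dolloPresence(gt, carriers)
    expect_equal(presenceState(rp)[treeNodes(gt)],
                 presenceState(dp)[treeNodes(gt)])
})

test_that("consensus support is the replicate frequency", {
    ## tie-free module: supports all 0 or 1, n_runs=1 equals a single run
    gt <- gtree("((A:1,B:1):1,(C:1,D:1):1);")
    m <- makeModule("m", c("A", "B", "C"), rep(0, 3), 8, 1)
    m@segments$segment <- c("AAAAAAAA", "AAAAAACC", "CCCCAAAA")
    pm10 <- consensusPresence(m, gt, nRuns = 10, baseSeed = 3)
    expect_true(all(presenceSupport(pm10) %in% c(0, 1)))

    pm1 <- consensusPresence(m, gt, nRuns = 1, baseSeed = 3,
                             rootBy = "midpoint")
    single <- presenceFromReconciliation(
        dtlReconcile(buildModuleTree(m, seed = 3), gt), gt)
    expect_equal(presenceState(pm1),
                 presenceState(single)[names(presenceState(pm1))])

    ## cost-optimal rooting never reconciles worse than the midpoint rooting
    mt <- buildModuleTree(m, seed = 3)
    recMid <- dtlReconcile(mt, gt)
    recBest <- phyloModules:::.bestRootedReconciliation(mt, gt,
                                                        reconciliationCosts())
    expect_lte(reconciliationCost(recBest), reconciliationCost(recMid))

    ## majority state implies support >= 0.5
    expect_true(all(presenceSupport(pm10)[presenceState(pm10)] >= 0.5))
})

test_that("an engineered tie-bearing module yields fractional support", {
    gt <- gtree("((((A:1,B:1):1,C:1):1,D:1):1,(E:1,F:1):1);")
    m <- makeModule("tie", c("A", "C", "E", "F"), rep(0, 4), 8, 1)
    m@segments$segment <- rep("WWWWWWWW", 4)   # all distances zero: Q ties
    pm <- consensusPresence(m, gt, nRuns = 10, baseSeed = 1)
    s <- presenceSupport(pm)
    expect_true(any(s > 0 & s < 1))
    expect_true(all(s >= 0 & s <= 1))
})
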