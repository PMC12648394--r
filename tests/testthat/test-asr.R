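test_that("pruning likelihood matches the exhaustive enumeration oracle", {
    for (s in 1:5) {
        gt <- randomBinaryGeneTree(sample(4:6, 1), seed = 300 + s)
        set.seed(400 + s)
        lv <- treeLeaves(gt)
        st <- setNames(sample(c(0L, 1L, NA), length(lv), replace = TRUE,
                              prob = c(0.4, 0.4, 0.2)), lv)
        if (all(is.na(st))) st[1] <- 1L
        a <- runif(1, 0.1, 2); b <- runif(1, 0.1, 2)
        model <- methods::new("TwoStateModel", alpha = a, beta = b)
        orc <- oracleAsr(gt, st, a, b)
        expect_equal(pruningLikelihood(gt, st, model), orc$logLik,
                     tolerance = 1e-9)
        asr <- marginalPosteriors(gt, st, model)
        expect_equal(asrPosterior(asr)[treeNodes(gt)],
                     orc$posterior[treeNodes(gt)], tolerance = 1e-6)
    }
})

test_that("short-branch limit collapses to the stationary frequency", {
    gt <- gtree("((A:1e-9,B:1e-9):1e-9,(C:1e-9,D:1e-9):1e-9);")
    model <- methods::new("TwoStateModel", alpha = 0.7, beta = 0.3)
    st <- c(A = 1L, B = 1L, C = 1L, D = 1L)
    expect_equal(pruningLikelihood(gt, st, model), log(0.7), tolerance = 1e-4)
    asr <- marginalPosteriors(gt, st, model)
    internal <- setdiff(treeNodes(gt), treeLeaves(gt))
    expect_true(all(asrPosterior(asr)[internal] > 1 - 1e-4))
})

test_that("label flip with rate swap leaves the likelihood unchanged", {
    gt <- randomBinaryGeneTree(6, seed = 55)
    st <- setNames(c(1L, 0L, 1L, NA, 0L, 1L), treeLeaves(gt))
    m1 <- methods::new("TwoStateModel", alpha = 0.8, beta = 0.25)
    m2 <- methods::new("TwoStateModel", alpha = 0.25, beta = 0.8)
    flipped <- setNames(1L - st, names(st))
    expect_equal(pruningLikelihood(gt, st, m1),
                 pruningLikelihood(gt, flipped, m2), tolerance = 1e-12)
})

test_that("likelihood is invariant under child reordering", {
    gt1 <- gtree("((A:1,B:2):1,(C:1,D:3):2);")
    gt2 <- gtree("((D:3,C:1):2,(B:2,A:1):1);")
    st <- c(A = 1L, B = 0L, C = 1L, D = NA)
    model <- methods::new("TwoStateModel", alpha = 0.5, beta = 0.9)
    expect_equal(pruningLikelihood(gt1, st, model),
                 pruningLikelihood(gt2, st, model), tolerance = 1e-12)
})

test_that("posteriors normalize, pin observed leaves, respect symmetry", {
    gt <- gtree("((A:1,B:1):1,(C:1,D:1):1);")
    model <- methods::new("TwoStateModel", alpha = 0.5, beta = 0.5)
    st <- c(A = 1L, B = 0L, C = 0L, D = 1L)
    asr <- marginalPosteriors(gt, st, model)
    p <- asrPosterior(asr)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(p[c("A", "B", "C", "D")]), c(1, 0, 0, 1))
    ## mirror symmetry: the two cherries carry mirrored data
    expect_equal(unname(p["g1"]), unname(p["g2"]), tolerance = 1e-12)
})

test_that("distant unknown outgroup does not perturb posteriors", {
    gt1 <- gtree("((A:1,B:1):1,(C:1,D:1):1);")
    gt2 <- gtree("(((A:1,B:1):1,(C:1,D:1):1):1,OUT:1000);")
    model <- methods::new("TwoStateModel", alpha = 0.4, beta = 0.7)
    st1 <- c(A = 1L, B = 1L, C = 0L, D = NA)
    st2 <- c(st1, OUT = NA)
    a1 <- asrPosterior(marginalPosteriors(gt1, st1, model))
    a2 <- asrPosterior(marginalPosteriors(gt2, st2, model))
    ## preorder auto-labels shift by one under the extra root
    map <- c(g0 = "g1", g1 = "g2", g2 = "g3",
             setNames(names(st1), names(st1)))
    expect_equal(unname(a1[names(map)]), unname(a2[map]), tolerance = 1e-6)
})

test_that("state calls use the documented >= 0.5 tie rule", {
    asr <- methods::new("AncestralStateMap", functionId = "f",
        posterior = c(n1 = 0.7, n2 = 0.5, n3 = 0.49, n4 = 0),
        state = c(n1 = FALSE, n2 = FALSE, n3 = FALSE, n4 = FALSE),
        model = methods::new("TwoStateModel", alpha = 1, beta = 1))
    out <- mapAncestralStates(asr)
    expect_equal(unname(asrState(out)), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("all-present data drives the loss rate to the boundary", {
    gt <- randomBinaryGeneTree(8, seed = 91)
    st <- setNames(rep(1L, 8), treeLeaves(gt))
    fit <- fitTwoStateModel(gt, st)
    expect_true(fit@boundary)
    expect_lt(lossRate(fit), 1e-5)
    ## fitted likelihood at least as good as a grid of probes
    for (a in c(0.05, 0.5, 2)) for (b in c(0.05, 0.5, 2)) {
        probe <- methods::new("TwoStateModel", alpha = a, beta = b)
        expect_gte(fit@logLik + 1e-6, pruningLikelihood(gt, st, probe))
    }
})

test_that("fitted likelihood beats random probes", {
    gt <- randomBinaryGeneTree(12, seed = 17)
    sim <- simulateBinaryCharacter(gt, 0.6, 0.9, seed = 18)
    fit <- fitTwoStateModel(gt, sim$leafStates)
    set.seed(19)
    for (i in 1:100) {
        probe <- methods::new("TwoStateModel",
                              alpha = exp(runif(1, log(1e-4), log(50))),
                              beta = exp(runif(1, log(1e-4), log(50))))
        expect_gte(fit@logLik + 1e-6,
                   pruningLikelihood(gt, sim$leafStates, probe))
    }
})

test_that("rates are recovered from simulated data on a large tree", {
    ## 200-leaf tree, alpha = beta = 0.5; estimates within +/-50% in most
    ## replicates (stochastic tolerance)
    gt <- simulateYuleTree(200, seed = 61)
    ok <- 0L
    nRep <- 20L
    for (r in seq_len(nRep)) {
        sim <- simulateBinaryCharacter(gt, 0.5, 0.5, seed = 700 + r)
        fit <- fitTwoStateModel(gt, sim$leafStates)
        if (gainRate(fit) >= 0.25 && gainRate(fit) <= 0.75 &&
            lossRate(fit) >= 0.25 && lossRate(fit) <= 0.75)
            ok <- ok + 1L
    }
    expect_gte(ok, 16L)
})

test_that("degenerate inputs are rejected", {
    gt <- gtree("((A:1,B:1):1,C:1);")
    model <- methods::new("TwoStateModel", alpha = 1, beta = 1)
    expect_error(pruningLikelihood(gt, c(A = NA, B = NA, C = NA), model),
                 "all leaves unknown")
    expect_error(pruningLikelihood(gt, c(A = 1), model), "leaf without state")
})
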