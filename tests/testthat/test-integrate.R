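test_that("gain/loss events follow the parent-comparison rule", {
    gt <- gtree("((A:1,B:1):1,(C:1,D:1):1);")
    nodes <- treeNodes(gt)

    ## present everywhere: single gain at the root, no losses
    pAll <- methods::new("PresenceMap", itemId = "m", itemType = "module",
        state = setNames(rep(TRUE, 7), nodes),
        support = setNames(rep(1, 7), nodes))
    ev <- deriveGainLossEvents(pAll, gt)
    expect_equal(ev$event[ev$node_id == "g0"], "gain")
    expect_true(all(ev$event[ev$node_id != "g0"] == "none"))

    ## Dollo map for carriers {A, D}: gain at root, losses at B and C
    ev2 <- deriveGainLossEvents(dolloPresence(gt, c("A", "D")), gt)
    expect_equal(ev2$event[ev2$node_id == "g0"], "gain")
    expect_setequal(ev2$node_id[ev2$event == "loss"], c("B", "C"))

    ## gain below an absent parent
    st <- setNames(rep(FALSE, 7), nodes); st[c("g1", "A", "B")] <- TRUE
    p <- methods::new("PresenceMap", itemId = "m", itemType = "module",
        state = st, support = setNames(rep(1, 7), nodes))
    ev3 <- deriveGainLossEvents(p, gt)
    expect_equal(ev3$event[ev3$node_id == "g1"], "gain")

    pBad <- methods::new("PresenceMap", itemId = "m", itemType = "module",
        state = c(x = TRUE), support = c(x = 1))
    expect_error(deriveGainLossEvents(pBad, gt), "missing node")
})

test_that("events alternate along any root-to-leaf path", {
    for (s in 1:5) {
        gt <- randomBinaryGeneTree(8, seed = 500 + s)
        set.seed(600 + s)
        carriers <- sample(treeLeaves(gt), sample(2:6, 1))
        ev <- deriveGainLossEvents(dolloPresence(gt, carriers), gt)
        evOf <- setNames(ev$event, ev$node_id)
        paths <- lapply(treeLeaves(gt), function(lf)
            phyloModules:::.pathDown(gt, treeRoot(gt), lf))
        for (p in paths) {
            seqEv <- evOf[p]
            seqEv <- seqEv[seqEv != "none"]
            if (length(seqEv) > 1L) {
                ## no two consecutive identical events on a path
                expect_true(all(seqEv[-1] != seqEv[-length(seqEv)]))
            }
            ## a loss can only follow a gain
            if (length(seqEv)) expect_equal(unname(seqEv[1]), "gain")
        }
    }
})

test_that("co-emergence pairs function gains with same-node module gains", {
    gt <- gtree("((A:1,B:1):1,(C:1,D:1):1);")
    mkP <- function(id, type, carriers) {
        p <- dolloPresence(gt, carriers, itemId = id)
        p@itemType <- type
        p
    }
    modEv <- rbind(
        deriveGainLossEvents(mkP("m1", "module", c("A", "B")), gt),
        deriveGainLossEvents(mkP("m2", "module", c("A", "B")), gt),
        deriveGainLossEvents(mkP("m3", "module", c("C", "D")), gt))
    funEv <- deriveGainLossEvents(mkP("f", "function", c("A", "B")), gt)

    sig <- coEmergenceSignatures(modEv, funEv, gt)
    expect_equal(nrow(sig), 1L)
    expect_equal(sig$gain_node_id, "g1")
    expect_equal(sig$module_ids, "m1;m2")
    expect_equal(sig$n_modules, 2L)
    expect_equal(sig$note, "")

    ## no module gains at the function's node: flagged empty row
    funEv2 <- deriveGainLossEvents(mkP("f2", "function", c("C", "D")), gt)
    funEv2$item_id <- "f2"
    sig2 <- coEmergenceSignatures(modEv[modEv$item_id != "m3", ], funEv2, gt)
    expect_equal(nrow(sig2), 1L)
    expect_equal(sig2$module_ids, "")
    expect_equal(sig2$note, "no co-emerging module")

    ## support filter removes low-support modules
    modLow <- modEv
    modLow$support[modLow$item_id == "m2"] <- 0.3
    sig3 <- coEmergenceSignatures(modLow, funEv, gt, minSupport = 0.5)
    expect_equal(sig3$module_ids, "m1")

    ## relaxed mode also accepts parent-node gains
    modEv3 <- deriveGainLossEvents(mkP("mr", "module",
                                       c("A", "B", "C", "D")), gt)
    sigR <- coEmergenceSignatures(modEv3, funEv, gt, relaxed = TRUE)
    expect_equal(sigR$module_ids, "mr")
    sigS <- coEmergenceSignatures(modEv3, funEv, gt, relaxed = FALSE)
    expect_equal(sigS$module_ids, "")
})

test_that("signature rows reference only function gain nodes", {
    gt <- randomBinaryGeneTree(8, seed = 81)
    set.seed(82)
    mkP <- function(id, type, carriers) {
        p <- dolloPresence(gt, carriers, itemId = id)
        p@itemType <- type
        p
    }
    modEv <- do.call(rbind, lapply(1:3, function(i)
        deriveGainLossEvents(mkP(paste0("m", i), "module",
            sample(treeLeaves(gt), 3)), gt)))
    funEv <- do.call(rbind, lapply(1:2, function(i)
        deriveGainLossEvents(mkP(paste0("f", i), "function",
            sample(treeLeaves(gt), 4)), gt)))
    sig <- coEmergenceSignatures(modEv, funEv, gt)
    gainNodes <- funEv$node_id[funEv$event == "gain"]
    expect_true(all(sig$gain_node_id %in% gainNodes))
    expect_equal(nrow(sig), length(gainNodes))
})

test_that("the annotated bundle is complete, hashed and reproducible", {
    gt <- gtree("((A:1,B:1):1,C:1);")
    rec <- data.frame(protein_id = c("A", "B", "C"), taxid = 1:3,
                      sequence = strrep("M", 30))
    m <- makeModule("m1", c("A", "B"), c(0, 2), 6, 12)
    annot <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("protein_id,function_id", "A,f1", "B,f1", "C,f1"), annot)
    ft <- readFunctionTable(annot, rec)
    pres <- list(dolloPresence(gt, c("A", "B"), itemId = "m1"))
    modEv <- deriveGainLossEvents(pres[[1]], gt)
    sig <- coEmergenceSignatures(modEv, modEv[0, ], gt)

    d1 <- withr::local_tempdir()
    man <- assembleAnnotatedTree(gt, rec, list(m), pres, ft, sig, d1)
    expect_gte(nrow(man), 4L)
    expect_true(all(file.exists(file.path(d1, man$file))))
    expect_true(file.exists(file.path(d1, "manifest.csv")))

    d2 <- withr::local_tempdir()
    man2 <- assembleAnnotatedTree(gt, rec, list(m), pres, ft, sig, d2)
    expect_identical(man$md5, man2$md5)

    ## inconsistent node sets are a hard error
    pBad <- methods::new("PresenceMap", itemId = "mx", itemType = "module",
        state = c(z = TRUE), support = c(z = 1))
    expect_error(
        assembleAnnotatedTree(gt, rec, list(m), list(pBad), ft, sig, d1),
        "different node set")
})
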