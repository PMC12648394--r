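test_that("segment pair scoring matches BLOSUM62 and is symmetric", {
    ## A+C+D+E diagonal: 4 + 9 + 6 + 5
    expect_equal(scoreSegmentPair("ACDE", "ACDE"), 24)
    b62 <- phyloModules:::.substMatrix("BLOSUM62")
    expect_equal(scoreSegmentPair("A", "C"), unname(b62["A", "C"]))
    expect_equal(scoreSegmentPair("MKWV", "AQDE"),
                 scoreSegmentPair("AQDE", "MKWV"))
    ## diagonal dominance: self score >= any cross score
    set.seed(7)
    aas <- c("A","C","D","E","F","G","H","I","K","L")
    for (i in 1:20) {
        x <- paste(sample(aas, 6, replace = TRUE), collapse = "")
        y <- paste(sample(aas, 6, replace = TRUE), collapse = "")
        expect_gte(scoreSegmentPair(x, x), scoreSegmentPair(x, y))
    }
    expect_error(scoreSegmentPair("AC", "A"), "mismatch")
})

test_that("anchor pairs cover shared k-mers and respect preconditions", {
    rec <- data.frame(
        protein_id = c("A", "B"), taxid = 1:2,
        sequence = c("GGGGGWWWWWWGGGGG", "SSSSSWWWWWWSSSSS"))
    a <- findAnchorPairs(rec, detectionParams())
    expect_gt(nrow(a), 0)
    ## one merged anchor must cover the shared 6-mer after extension
    cover <- any(a$start1 <= 5 & a$start1 + a$len >= 11 &
                 a$start2 <= 5 & a$start2 + a$len >= 11)
    expect_true(cover)

    ## exhaustive scan oracle: every shared k-mer position pair is inside
    ## some anchor
    k <- 4L
    km1 <- substring(rec$sequence[1], 1:(16 - k + 1), k:16)
    km2 <- substring(rec$sequence[2], 1:(16 - k + 1), k:16)
    for (i in seq_along(km1)) for (j in seq_along(km2)) {
        if (km1[i] != km2[j]) next
        hit <- any(a$start1 <= i - 1 & a$start1 + a$len >= i - 1 + k &
                   a$start2 <= j - 1 & a$start2 + a$len >= j - 1 + k &
                   (a$start1 - a$start2) == (i - j))
        expect_true(hit)
    }

    none <- data.frame(protein_id = c("A", "B"), taxid = 1:2,
                       sequence = c("AAAAAAA", "WWWWWWW"))
    expect_equal(nrow(findAnchorPairs(none)), 0L)
    one <- none[1, ]
    expect_equal(nrow(findAnchorPairs(one)), 0L)
})

test_that("planted identical blocks are recovered as single modules", {
    tr <- simulateYuleTree(6, seed = 11)
    sim <- plantModulesAndSequences(
        tr, list(list(gainNode = treeRoot(tr), width = 12, rate = 0)),
        backgroundLength = 80, seed = 2, disjointAlphabet = TRUE)
    mods <- detectModules(sim$records)
    expect_equal(length(mods), 1L)
    seg <- moduleSegments(mods[[1]])
    expect_equal(sort(seg$protein_id), sort(treeLeaves(tr)))
    ## reported spans cover the planted spans
    for (i in seq_len(nrow(seg))) {
        truth <- sim$truth$spans[sim$truth$spans$protein_id ==
                                 seg$protein_id[i], ]
        expect_lte(seg$start[i], truth$start)
        expect_gte(seg$end[i], truth$end)
    }
})

test_that("a module shared by a subset lists exactly its carriers", {
    tr <- gtree("(((A:1,B:1):1,C:1):1,D:1);")
    sim <- plantModulesAndSequences(
        tr, list(list(gainNode = "g1", width = 12, rate = 0)),
        backgroundLength = 60, seed = 4, disjointAlphabet = TRUE)
    mods <- detectModules(sim$records)
    expect_equal(length(mods), 1L)
    expect_setequal(moduleCarriers(mods[[1]]), c("A", "B", "C"))
})

test_that("identical duplicated sequences give one near-full-length module", {
    s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
    rec <- data.frame(protein_id = c("A", "B"), taxid = 1:2, sequence = s)
    mods <- detectModules(rec)
    expect_equal(length(mods), 1L)
    expect_gte(moduleWidth(mods[[1]]), nchar(s) - 2L)
})

test_that("below-threshold clusters are filtered out", {
    rec <- data.frame(protein_id = c("A", "B"), taxid = 1:2,
                      sequence = c("GGGGPSTAGGGG", "SSSSPSTASSSS"))
    ## shared PSTA 4-mer, weakly scoring, cannot reach minWidth 6 after
    ## positive-score extension against dissimilar context
    mods <- detectModules(rec, detectionParams(minWidth = 8))
    expect_equal(length(mods), 0L)
})

test_that("compatible selection is exact on small instances", {
    ## two crossing modules: keep the higher-scoring one
    m30 <- makeModule("hi", c("A", "B"), c(0, 20), 6, 30)
    m20 <- makeModule("lo", c("A", "B"), c(20, 0), 6, 20)
    expect_false(pairCompatible(m30, m20))
    kept <- selectCompatibleBlocks(list(m20, m30))
    expect_equal(vapply(kept, moduleId, ""), "hi")
    bf <- bruteForceMaxWeight(list(m20, m30))
    expect_equal(sum(vapply(kept, moduleScore, 0)), bf$weight)

    ## non-overlapping, order-consistent pair: both kept
    m1 <- makeModule("a", c("A", "B"), c(0, 0), 6, 10)
    m2 <- makeModule("b", c("A", "B"), c(10, 10), 6, 9)
    expect_equal(length(selectCompatibleBlocks(list(m1, m2))), 2L)

    ## single module: identity
    expect_equal(length(selectCompatibleBlocks(list(m1))), 1L)
})

test_that("selection matches brute force on random instances", {
    set.seed(20240917)
    for (i in 1:25) {
        cands <- randomCandidateSet(sample(2:6, 1L))
        sel <- selectCompatibleBlocks(cands)
        bf <- bruteForceMaxWeight(cands)
        expect_true(allPairsCompatible(sel))
        expect_equal(sum(vapply(sel, moduleScore, 0)), bf$weight)
    }
})

test_that("detection output satisfies module invariants and determinism", {
    tr <- simulateYuleTree(8, seed = 5)
    sim <- plantModulesAndSequences(
        tr, list(list(gainNode = "g1", width = 14, rate = 0.02),
                 list(gainNode = "g2", width = 12, rate = 0.02)),
        backgroundLength = 100, seed = 6, disjointAlphabet = TRUE)
    mods <- detectModules(sim$records)
    for (m in mods) {
        seg <- moduleSegments(m)
        expect_gte(nrow(seg), 2L)
        expect_false(anyDuplicated(seg$protein_id) > 0)
        expect_true(all(seg$end - seg$start == moduleWidth(m)))
    }
    expect_true(allPairsCompatible(mods))

    f1 <- withr::local_tempfile(fileext = ".csv")
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeModuleTable(mods, f1)
    writeModuleTable(detectModules(sim$records), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("detection needs at least two records", {
    expect_error(detectModules(data.frame(protein_id = "A", taxid = 1L,
                                          sequence = "ACDE")),
                 ">= 2 sequences")
})
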