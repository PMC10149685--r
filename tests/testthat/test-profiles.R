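test_that("column profiles count non-gap residues and renormalize", {
    pa <- buildProfiles(tinyMsa("WA", "WA"))
    expect_equal(unname(profiles(pa)["W", 1]), 1)
    expect_equal(sum(profiles(pa)[, 1]), 1)
    ## gaps excluded, frequencies over the remainder
    pa <- buildProfiles(tinyMsa("W-", "--"))
    expect_equal(unname(profiles(pa)["W", 1]), 1)
    expect_identical(nEffective(pa), c(1L, 0L))
    expect_equal(sum(profiles(pa)[, 2]), 0)
    ## ambiguity codes carry no signal
    pa <- buildProfiles(tinyMsa("WX", "WW"))
    expect_equal(unname(profiles(pa)["W", 2]), 1)
    expect_identical(nEffective(pa)[2], 1L)
})

test_that("column frequencies match direct counting on random columns", {
    set.seed(31)
    col <- sample(ClpTyper:::AA20, 10, TRUE)
    pa <- buildProfiles(tinyMsa(setNames(col, paste0("s", 1:10))))
    tab <- table(factor(col, levels = ClpTyper:::AA20)) / 10
    expect_equal(as.numeric(profiles(pa)[, 1]), as.numeric(tab))
})

test_that("positional scores reduce to matrix entries and are linear", {
    B <- blosum62Matrix()
    pure <- setNames(numeric(20), rownames(B)); pure["W"] <- 1
    expect_equal(positionalScore("W", pure), 11)
    unif <- setNames(rep(1 / 20, 20), rownames(B))
    expect_equal(positionalScore("A", unif), mean(B["A", ]))
    expect_true(is.na(positionalScore("-", unif)))
    set.seed(32)
    p1 <- randProfile(); p2 <- randProfile(); a <- 0.3
    expect_equal(positionalScore("R", a * p1 + (1 - a) * p2),
                 a * positionalScore("R", p1) +
                     (1 - a) * positionalScore("R", p2))
})

test_that("cross scores are symmetric, reduce on pure profiles, and average on uniform", {
    B <- blosum62Matrix()
    pure <- function(x) { p <- setNames(numeric(20), rownames(B)); p[x] <- 1; p }
    expect_equal(crossScore(pure("W"), pure("W")), 11)
    expect_equal(crossScore(pure("A"), pure("W")), B["A", "W"])
    unif <- setNames(rep(1 / 20, 20), rownames(B))
    expect_equal(crossScore(unif, unif), mean(B))
    set.seed(33)
    for (i in 1:20) {
        p1 <- randProfile(); p2 <- randProfile()
        expect_equal(crossScore(p1, p2), crossScore(p2, p1))
    }
    expect_true(is.na(crossScore(numeric(20), pure("W"))))
})

test_that("cross score of a profile with itself is bounded by its best residue", {
    set.seed(34)
    B <- blosum62Matrix()
    for (i in 1:25) {
        p <- randProfile()
        best <- max(vapply(rownames(B), positionalScore, numeric(1),
                           profile = p))
        expect_lte(crossScore(p, p), best + 1e-12)
    }
    pure <- setNames(numeric(20), rownames(B)); pure["H"] <- 1
    expect_equal(crossScore(pure, pure), B["H", "H"])
})

test_that("profile-profile self-alignment is the identity", {
    set.seed(35)
    aln <- tinyMsa(randSeq(12, ClpTyper:::AA20), randSeq(12, ClpTyper:::AA20),
                   randSeq(12, ClpTyper:::AA20))
    pa <- buildProfiles(aln)
    res <- profileProfileAlign(pa, pa)
    cc <- correspondence(res)
    expect_identical(cc$top, 1:12)
    expect_identical(cc$bottom, 1:12)
    expect_false(anyNA(cc$sCross))
})

test_that("deleting one column yields exactly one gap at that position", {
    set.seed(36)
    strings <- c(randSeq(10, ClpTyper:::AA20), randSeq(10, ClpTyper:::AA20),
                 randSeq(10, ClpTyper:::AA20))
    top <- buildProfiles(tinyMsa(strings))
    k <- 6L
    bottom <- buildProfiles(tinyMsa(vapply(strings, function(s)
        paste0(substr(s, 1, k - 1), substr(s, k + 1, 10)), "")))
    cc <- correspondence(profileProfileAlign(top, bottom))
    expect_identical(sum(is.na(cc$bottom)), 1L)
    expect_identical(sum(is.na(cc$top)), 0L)
    expect_identical(cc$top[is.na(cc$bottom)], k)
})

test_that("profile-profile DP matches brute-force enumeration", {
    B <- blosum62Matrix()
    set.seed(37)
    for (rep in 1:40) {
        nt <- sample(1:5, 1); nb <- sample(1:5, 1)
        top <- c(randSeq(nt), randSeq(nt))
        bottom <- c(randSeq(nb), randSeq(nb), randSeq(nb))
        res <- profileProfileAlign(buildProfiles(tinyMsa(top)),
                                   buildProfiles(tinyMsa(bottom)))
        expect_equal(res@score,
                     oracleProfileAlign(oracleCrossMatrix(top, bottom, B), 4),
                     tolerance = 1e-9, info = paste(rep))
    }
})

test_that("bitmaps evaluate the per-cell positional-score formula", {
    ## single sequence: every cell is the self-score of its residue
    s <- "MKWV"
    bm <- renderBitmap(buildProfiles(tinyMsa(s)))
    B <- blosum62Matrix()
    expect_equal(as.numeric(bm),
                 as.numeric(B[cbind(strsplit(s, "")[[1]],
                                    strsplit(s, "")[[1]])]))
    ## perfectly conserved alignment: constant per column
    bm <- renderBitmap(buildProfiles(tinyMsa("MKW", "MKW", "MKW")))
    expect_true(all(apply(bm, 2, function(x) length(unique(x)) == 1L)))
    ## random alignment: direct recomputation, gaps as NA
    set.seed(38)
    strings <- c("MK-V", "MAWV", "-KWV")
    pa <- buildProfiles(tinyMsa(strings))
    bm <- renderBitmap(pa)
    for (i in 1:3) for (j in 1:4) {
        x <- substr(strings[i], j, j)
        if (x == "-") expect_true(is.na(bm[i, j]))
        else expect_equal(unname(bm[i, j]),
                          positionalScore(x, profiles(pa)[, j]))
    }
})

test_that("conserved ATPase modules score higher across alignments than variable NTDs", {
    fx <- fixtureCohortAnalysis()
    co <- fx$cohort
    res <- profileProfileAlign(buildProfiles(classMsa(co, "ClpB")),
                               buildProfiles(classMsa(co, "ClpC")))
    cc <- correspondence(res)
    blocks <- attr(fixtureTemplates(), "blocks")
    coreCols <- !is.na(cc$top) & !is.na(cc$bottom) &
        cc$top %in% unlist(Map(seq, blocks$start[blocks$block %in%
                                   c("D1a", "D1b", "D2a", "D2b")],
                               blocks$end[blocks$block %in%
                                   c("D1a", "D1b", "D2a", "D2b")]))
    ntdCols <- !is.na(cc$top) & !is.na(cc$bottom) &
        cc$top %in% seq(blocks$start[blocks$block == "NTD"],
                        blocks$end[blocks$block == "NTD"])
    expect_gt(mean(cc$sCross[coreCols], na.rm = TRUE),
              mean(cc$sCross[ntdCols], na.rm = TRUE) + 1)
})
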