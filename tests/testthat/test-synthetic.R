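test_that("default templates encode the class-contrastive architecture", {
    tpl <- fixtureTemplates()
    w <- function(cl, r) IRanges::width(tpl[[cl]]@regions[r])
    expect_identical(w("ClpB", "M_domain"), 90L)
    expect_identical(w("ClpC", "M_domain"), 20L)
    expect_identical(w("ClpIa", "M_domain"), 20L)
    expect_identical(w("ClpIb", "LGF_loop"), 5L)
    expect_identical(w("ClpC", "NTD"), 145L)
    lgfSeq <- function(cl) {
        r <- tpl[[cl]]@regions["LGF_loop"]
        substr(tpl[[cl]]@residues, IRanges::start(r), IRanges::end(r))
    }
    expect_true(grepl("LGF", lgfSeq("ClpC"), fixed = TRUE))
    expect_true(grepl("LGF", lgfSeq("ClpIa"), fixed = TRUE))
    expect_false(detectLgf(lgfSeq("ClpIb")))
    expect_false(detectLgf(lgfSeq("ClpB")))
    ## the strongly conserved NTD belongs to ClpC alone
    expect_lt(tpl$ClpC@subRate["NTD"], tpl$ClpB@subRate["NTD"])
    expect_lt(tpl$ClpC@subRate["NTD"], tpl$ClpIa@subRate["NTD"])
    ## deterministic under the template seed
    t2 <- defaultTemplates()
    expect_identical(vapply(t2, function(x) x@residues, ""),
                     vapply(tpl, function(x) x@residues, ""))
})

test_that("zero divergence reproduces the template exactly", {
    tpl <- fixtureTemplates()
    set.seed(71)
    s <- sampleSequence(tpl$ClpC, divergence = 0)
    expect_identical(s$residues, tpl$ClpC@residues)
    expect_identical(as.integer(IRanges::width(s$regions)),
                     as.integer(IRanges::width(
                         tpl$ClpC@regions[names(s$regions)])))
})

test_that("sampling is deterministic under a fixed RNG state", {
    tpl <- fixtureTemplates()
    set.seed(72); a <- sampleSequence(tpl$ClpIb)
    set.seed(72); b <- sampleSequence(tpl$ClpIb)
    expect_identical(a, b)
})

test_that("realized divergence matches the configured rates", {
    tpl <- fixtureTemplates()
    set.seed(73)
    rg <- tpl$ClpC@regions
    coreIdx <- unlist(lapply(c("D1a", "D1b", "D2a", "D2b"), function(r)
        IRanges::start(rg[r]):IRanges::end(rg[r])))
    tplChars <- strsplit(tpl$ClpC@residues, "")[[1]]
    mism <- replicate(30, {
        s <- sampleSequence(tpl$ClpC)
        mean(strsplit(s$residues, "")[[1]][coreIdx] != tplChars[coreIdx])
    })
    ## core substitution rate 0.04; protected motifs pull the realized
    ## value slightly below; allow binomial spread
    expect_gt(mean(mism), 0.02)
    expect_lt(mean(mism), 0.06)
    ## protected Walker motifs never mutate
    set.seed(74)
    for (i in 1:10) {
        s <- sampleSequence(tpl$ClpB)
        expect_identical(length(findWalkerMotifs(s$residues)$walkerA), 2L)
    }
})

test_that("cohorts honour configured counts, labels and determinism", {
    cfg <- cohortConfig(counts = c(ClpB = 10L, ClpC = 10L, ClpIa = 5L,
                                   ClpIb = 5L),
                        orders = c("o1", "o2"), seed = 75L)
    co <- generateCohort(cfg)
    expect_identical(length(cohortSequences(co)), 60L)
    expect_identical(sort(unique(truthLabels(co))),
                     c("ClpB", "ClpC", "ClpIa", "ClpIb"))
    tab <- buildOccurrenceTable(truthLabels(co), cohortTaxonomy(co))
    expect_identical(tab[, ], cfg$counts[rownames(tab), colnames(tab)])
    ## byte-identical output under the same seed
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeCohort(generateCohort(cfg), d1)
    writeCohort(generateCohort(cfg), d2)
    expect_identical(readLines(file.path(d1, "sequences.fasta")),
                     readLines(file.path(d2, "sequences.fasta")))
    expect_error(generateCohort(cohortConfig(counts = c(ClpB = 0L),
                                             orders = "o1")),
                 "no sequences")
})

test_that("the master-frame alignment degaps to the emitted sequences", {
    co <- fixtureSmallCohort()
    gapped <- as.character(Biostrings::unmasked(cohortAlignment(co)))
    plain <- as.character(cohortSequences(co))
    expect_identical(gsub("-", "", gapped[names(plain)]), plain)
})

test_that("truth coordinates delimit the intended domains", {
    co <- fixtureSmallCohort()
    regs <- truthRegions(co)
    lab <- truthLabels(co)
    mLen <- regs[regs$region == "M_domain", ]
    mWidth <- setNames(mLen$end - mLen$start + 1L, mLen$id)
    expect_true(all(mWidth[lab[names(mWidth)] == "ClpB"] == 90L))
    expect_true(all(mWidth[lab[names(mWidth)] == "ClpC"] == 20L))
    ib <- mWidth[lab[names(mWidth)] == "ClpIb"]
    expect_true(all(ib >= 20L & ib <= 26L))
    ## the ClpC NTD is fixed-length; ClpI NTDs vary
    ntd <- regs[regs$region == "NTD", ]
    ntdW <- setNames(ntd$end - ntd$start + 1L, ntd$id)
    expect_true(all(ntdW[lab[names(ntdW)] == "ClpC"] == 145L))
    expect_gt(max(ntdW[lab[names(ntdW)] %in% c("ClpIa", "ClpIb")]), 145L)
})

test_that("stripRegion removes exactly the truth NTD", {
    co <- fixtureSmallCohort()
    trunc <- stripRegion(co, "NTD")
    regs <- truthRegions(co)
    ntd <- regs[regs$region == "NTD", ]
    ntdW <- setNames(ntd$end - ntd$start + 1L, ntd$id)
    lenDiff <- Biostrings::width(cohortSequences(co)) -
        Biostrings::width(trunc)
    expect_identical(as.integer(lenDiff),
                     as.integer(ntdW[names(cohortSequences(co))]))
})
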