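test_that("Walker motif patterns match literally and only where present", {
    hits <- findWalkerMotifs("GESGVGKT")
    expect_identical(hits$walkerA, 1L)
    expect_identical(findWalkerMotifs(strrep("A", 50))$walkerA, integer(0))
    expect_identical(findWalkerMotifs(strrep("A", 50))$walkerB, integer(0))
    expect_identical(findWalkerMotifs("AAILLFDEAA")$walkerB, 3L)
})

test_that("synthetic class templates carry exactly two Walker A motifs", {
    tpl <- fixtureTemplates()
    for (cl in names(tpl)) {
        hits <- findWalkerMotifs(tpl[[cl]]@residues)
        expect_identical(length(hits$walkerA), 2L, info = cl)
        expect_gte(length(hits$walkerB), 2L)
    }
})

test_that("LGF-like motif detection covers conservative substitutions", {
    expect_true(detectLgf("ALGFP"))
    expect_false(detectLgf("AAAAA"))
    expect_true(detectLgf("VGY"))
    expect_false(detectLgf("LAF"))
})

test_that("region projection is the identity on the reference itself", {
    tpl <- fixtureTemplates()
    ref <- tpl$ClpC@residues
    map <- templateRegionMap(tpl$ClpC)
    mr <- mapRegions(ref, ref, map)
    rg <- map@regions
    expect_true(all(mr$present))
    expect_identical(mr$start, IRanges::start(rg)[match(mr$region, names(rg))])
    expect_identical(mr$end, IRanges::end(rg)[match(mr$region, names(rg))])
})

test_that("an NTD deletion shifts downstream regions and flags absence", {
    tpl <- fixtureTemplates()
    ref <- tpl$ClpC@residues
    map <- templateRegionMap(tpl$ClpC)
    ntdLen <- IRanges::width(map@regions["NTD"])
    query <- substring(ref, ntdLen + 1L)
    mr <- mapRegions(query, ref, map)
    expect_false(mr$present[mr$region == "NTD"])
    d1 <- mr[mr$region == "D1", ]
    expect_identical(d1$start, IRanges::start(map@regions["D1"]) - ntdLen)
    expect_identical(d1$end, IRanges::end(map@regions["D1"]) - ntdLen)
})

test_that("an insertion inside the M-domain grows its measured length", {
    tpl <- fixtureTemplates()
    ref <- tpl$ClpC@residues
    map <- templateRegionMap(tpl$ClpC)
    mMid <- IRanges::start(map@regions["M_domain"]) + 10L
    set.seed(21)
    ins <- paste(sample(ClpTyper:::AA20, 70, TRUE), collapse = "")
    query <- paste0(substring(ref, 1, mMid), ins, substring(ref, mMid + 1))
    fr <- featureReport(c(q = query), ref, map)
    expect_equal(fr$mDomainLength,
                 IRanges::width(map@regions["M_domain"]) + 70L)
})

test_that("a query unalignable to the reference frame is refused", {
    tpl <- fixtureTemplates()
    map <- templateRegionMap(tpl$ClpC)
    expect_error(mapRegions(strrep("A", 100), tpl$ClpC@residues, map),
                 "unalignable")
})

test_that("the feature decision rule reproduces the class definitions", {
    mk <- function(m, lgf, lgfLen, ntdP, ntdL)
        data.frame(id = "x", nWalkerA = 2L, nWalkerB = 2L,
                   mDomainLength = m, lgfMotifPresent = lgf,
                   lgfRegionLength = lgfLen, ntdPresent = ntdP,
                   ntdLength = ntdL)
    ## long M-domain, no LGF loop: the disaggregase
    expect_identical(classifyByFeatures(mk(90, FALSE, 8, FALSE, 0), 145),
                     "ClpB")
    ## short M-domain, LGF loop, conserved fixed-length NTD: the protease partner
    expect_identical(classifyByFeatures(mk(20, TRUE, 12, TRUE, 145), 145),
                     "ClpC")
    ## short M-domain, LGF motif, non-reference NTD
    expect_identical(classifyByFeatures(mk(20, TRUE, 12, TRUE, 175), 145),
                     "ClpIa")
    ## short M-domain, short motif-free loop region
    expect_identical(classifyByFeatures(mk(20, FALSE, 5, TRUE, 175), 145),
                     "ClpIb")
    ## boundary: the 60 aa threshold itself counts as long
    expect_identical(classifyByFeatures(mk(60, TRUE, 12, TRUE, 145), 145),
                     "ClpB")
})

test_that("NTD removal never flips the ClpIa/ClpIb sub-label", {
    tpl <- fixtureTemplates()
    refC <- tpl$ClpC@residues
    map <- templateRegionMap(tpl$ClpC)
    co <- fixtureSmallCohort()
    ids <- names(truthLabels(co))[truthLabels(co) %in% c("ClpIa", "ClpIb")]
    full <- cohortSequences(co)[ids]
    trunc <- stripRegion(co)[ids]
    lf <- classifyByFeatures(featureReport(full, refC, map), 145)
    lt <- classifyByFeatures(featureReport(trunc, refC, map), 145)
    expect_identical(lf, lt)
    expect_setequal(unique(lf), c("ClpIa", "ClpIb"))
})
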