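test_that("per-order subsampling honours quotas and small orders", {
    ids <- paste0("s", 1:23)
    tax <- setNames(c(rep("big", 20), rep("small", 3)), ids)
    keep <- subsamplePerOrder(ids, tax, k = 5, seed = 1)
    expect_identical(sum(tax[keep] == "big"), 5L)
    expect_identical(sum(tax[keep] == "small"), 3L)
    expect_identical(subsamplePerOrder(ids, tax, k = 5, seed = 9),
                     subsamplePerOrder(ids, tax, k = 5, seed = 9))
    expect_error(subsamplePerOrder(c(ids, "zz"), tax, k = 5),
                 "no taxonomy entry.*zz")
})

test_that("p-distances count mismatches over mutually ungapped columns", {
    expect_true(all(pDistanceMatrix(tinyMsa("AAAA", "AAAA", "AAAA")) == 0))
    d <- pDistanceMatrix(tinyMsa(a = "AAAA", b = "AAAT", c = "TTTT"))
    expect_equal(d["a", "b"], 0.25)
    expect_equal(d["a", "c"], 1)
    ## gapped columns are excluded pairwise
    d <- pDistanceMatrix(tinyMsa(a = "A-AA", b = "AAAT", c = "AAAA"))
    expect_equal(d["a", "b"], 1 / 3)
    set.seed(51)
    strings <- vapply(1:5, function(i) randSeq(30, ClpTyper:::AA20), "")
    d <- pDistanceMatrix(tinyMsa(strings))
    for (i in 1:4) for (j in (i + 1):5) {
        ci <- strsplit(strings[i], "")[[1]]
        cj <- strsplit(strings[j], "")[[1]]
        expect_equal(d[i, j], mean(ci != cj))
    }
    expect_error(pDistanceMatrix(tinyMsa("AA", "AA")), "at least 3")
    expect_error(pDistanceMatrix(tinyMsa("A-", "-A", "AA")),
                 "no comparable")
})

test_that("neighbor-joining solves the three-taxon system exactly", {
    d <- matrix(c(0, 0.3, 0.5,
                  0.3, 0, 0.6,
                  0.5, 0.6, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    tr <- njTree(d)
    expect_identical(ape::Ntip(tr), 3L)
    ## the three-point closed form: x = (dab + dac - dbc) / 2, etc.
    bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
    expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2)
    expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2)
    expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("neighbor-joining is exact on additive matrices", {
    set.seed(52)
    for (rep in 1:25) {
        tr <- ape::rtree(6)
        tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
        D <- ape::cophenetic.phylo(tr)
        nt <- njTree(D)
        expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr), nt)), 0)
        expect_lt(max(abs(ape::cophenetic.phylo(nt)[rownames(D),
                                                    colnames(D)] - D)),
                  1e-8)
    }
})

test_that("taxon input order does not change the inferred tree", {
    set.seed(53)
    tr <- ape::rtree(8)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    perm <- sample(8)
    expect_identical(as.numeric(ape::dist.topo(
        njTree(D), njTree(D[perm, perm]))), 0)
})

test_that("bootstrap supports are deterministic, bounded, and strong on clean data", {
    ## nested homoplasy-free signal blocks for every internal edge,
    ## plus one private column per taxon for positive terminal branches
    blockFor <- function(inGrp, yes, no, w)
        ifelse(inGrp, strrep(yes, w), strrep(no, w))
    n <- 6
    main <- blockFor(1:n <= 3, "A", "C", 20)
    s12 <- blockFor(1:n %in% 1:2, "D", "E", 10)
    s45 <- blockFor(1:n %in% 4:5, "F", "G", 10)
    priv <- vapply(1:n, function(i)
        paste(ifelse(1:n == i, "W", "Y"), collapse = ""), "")
    strings <- setNames(paste0(main, s12, s45, priv), paste0("t", 1:n))
    aln <- tinyMsa(strings)
    tr <- bootstrapSupports(aln, nReps = 50, seed = 3)
    supp <- suppressWarnings(as.numeric(tr$node.label))
    expect_true(all(supp[-1] == 100))
    expect_true(is.na(supp[1]))
    tr2 <- bootstrapSupports(aln, nReps = 50, seed = 3)
    expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
    ## single replicate: supports are 0 or 100
    tr1 <- bootstrapSupports(aln, nReps = 1, seed = 4)
    s1 <- suppressWarnings(as.numeric(tr1$node.label))
    expect_true(all(s1[-1] %in% c(0, 100)))
})

test_that("bootstrap supports ignore taxon input order", {
    set.seed(54)
    co <- fixtureSmallCohort()
    gapped <- as.character(Biostrings::unmasked(cohortAlignment(co)))
    aln1 <- Biostrings::AAMultipleAlignment(gapped)
    perm <- sample(length(gapped))
    aln2 <- Biostrings::AAMultipleAlignment(gapped[perm])
    t1 <- bootstrapSupports(aln1, nReps = 30, seed = 5)
    t2 <- bootstrapSupports(aln2, nReps = 30, seed = 5)
    lab <- truthLabels(co)
    for (cl in c("ClpB", "ClpC")) {
        S <- names(lab)[lab == cl]
        expect_identical(ClpTyper:::.bipartitionSupport(t1, S),
                         ClpTyper:::.bipartitionSupport(t2, S))
    }
})

test_that("confirmed subgroups use a strictly-greater support threshold", {
    tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
    tr$node.label <- c(NA, 50, 51)
    conf <- confirmedSubgroups(tr, 50)
    expect_identical(length(conf), 1L)
    expect_setequal(conf[[1]], c("c", "d"))
    expect_identical(length(confirmedSubgroups(tr, 100)), 0L)
    tr$node.label <- c(NA, 100, 100)
    expect_identical(length(confirmedSubgroups(tr, 99)), 2L)
})

test_that("monophyly is evaluated as unrooted bipartitions", {
    lab <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
    good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
    rep <- classMonophyly(good, lab)
    expect_true(all(rep$isMonophyletic))
    bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
    rep <- classMonophyly(bad, lab)
    expect_false(any(rep$isMonophyletic))
    expect_error(classMonophyly(good, lab[-1]), "unlabeled.*a1")
})

test_that("newick round-trip preserves topology, lengths and supports", {
    co <- fixtureSmallCohort()
    tr <- bootstrapSupports(cohortAlignment(co), nReps = 20, seed = 6)
    f <- withr::local_tempfile(fileext = ".nwk")
    writeSupportTree(tr, f)
    back <- readSupportTree(f)
    expect_identical(as.numeric(ape::dist.topo(tr, back)), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-6)
    ## node numbering may differ after parsing; compare the multiset of
    ## supports and the support attached to a specific bipartition
    expect_identical(sort(suppressWarnings(as.numeric(back$node.label))),
                     sort(suppressWarnings(as.numeric(tr$node.label))))
    lab <- truthLabels(co)
    S <- names(lab)[lab == "ClpB"]
    expect_identical(ClpTyper:::.bipartitionSupport(back, S),
                     ClpTyper:::.bipartitionSupport(tr, S))
})
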