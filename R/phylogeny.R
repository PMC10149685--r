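#' Subsample sequences per taxonomic order
#'
#' Random selection of at most `k` sequences from each taxonomic order
#' (orders with fewer than `k` representatives keep all members), the
#' standard thinning step before tree building. An optional secondary
#' grouping (`by`, e.g. class labels) applies the quota per order x group.
#'
#' @param ids character vector of sequence ids (or an
#'   [Biostrings::AAStringSet], whose names are used and which is
#'   subset on return).
#' @param taxonomy named character vector mapping every id to its order.
#' @param k per-group quota, default 5.
#' @param seed optional integer seed for reproducible selection.
#' @param by optional named character vector (e.g. labels) refining the
#'   grouping to order x value.
#' @return the selected ids (or subset `AAStringSet`), in input order.
#' @export
subsamplePerOrder <- function(ids, taxonomy, k = 5L, seed = NULL,
                              by = NULL) {
    seqs <- NULL
    if (!is.character(ids)) { seqs <- ids; ids <- names(ids) }
    miss <- setdiff(ids, names(taxonomy))
    if (length(miss))
        stop("no taxonomy entry for id: ", miss[1])
    if (!is.null(seed)) set.seed(seed)
    grp <- taxonomy[ids]
    if (!is.null(by)) grp <- paste(grp, by[ids], sep = "\r")
    keep <- unlist(lapply(split(ids, grp), function(g)
        if (length(g) <= k) g else sample(g, k)), use.names = FALSE)
    keep <- ids[ids %in% keep]
    if (is.null(seqs)) keep else seqs[keep]
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d[i, j]` is the fraction of mismatching residues over the columns where
#' neither sequence is gapped. Pairs sharing no comparable column are an
#' error.
#'
#' @param alignment an [Biostrings::AAMultipleAlignment] (or character
#'   vector of equal-length gapped strings).
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
pDistanceMatrix <- function(alignment) {
    m <- .alnMatrix(alignment)
    if (nrow(m) < 3L) stop("need at least 3 sequences")
    n <- nrow(m)
    res <- ifelse(m == "-", NA, m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        comp <- !is.na(res[i, ]) & !is.na(res[j, ])
        nc <- sum(comp)
        if (nc == 0L)
            stop("no comparable columns between '", rownames(m)[i],
                 "' and '", rownames(m)[j], "'")
        d[i, j] <- d[j, i] <- sum(res[i, comp] != res[j, comp]) / nc
    }
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining ([ape::nj()]); exact (topology and branch
#' lengths) on additive distance matrices.
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @return an unrooted [ape::phylo] tree.
#' @export
njTree <- function(d) {
    if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
    ape::nj(stats::as.dist(d))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `nReps` times, rebuilds a tree per replicate, and reports
#' for each internal edge of the full-data tree the percentage of
#' replicate trees containing the same bipartition. Resampling is seeded
#' on column indices only, so supports do not depend on taxon input order.
#'
#' @param alignment an [Biostrings::AAMultipleAlignment] (>= 3 sequences).
#' @param nReps bootstrap replicates, default 100.
#' @param seed integer seed.
#' @return an [ape::phylo] with `node.label` holding supports in
#'   \[0, 100\] (`NA` on the basal node, which subtends no internal edge).
#' @export
bootstrapSupports <- function(alignment, nReps = 100L, seed = 1L) {
    m <- .alnMatrix(alignment)
    n <- nrow(m); L <- ncol(m)
    if (n < 3L) stop("need at least 3 sequences")
    if (nReps < 1L) stop("need at least one replicate")
    res <- ifelse(m == "-", NA, m)
    ## per-pair per-column mismatch / comparability, computed once
    pairs <- utils::combn(n, 2L)
    np <- ncol(pairs)
    MM <- matrix(0, np, L); CC <- matrix(0, np, L)
    for (p in seq_len(np)) {
        i <- pairs[1L, p]; j <- pairs[2L, p]
        comp <- !is.na(res[i, ]) & !is.na(res[j, ])
        CC[p, ] <- comp
        MM[p, comp] <- res[i, comp] != res[j, comp]
    }
    toMat <- function(v) {
        d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
        d[t(pairs)] <- v; d[t(pairs)[, 2:1]] <- v
        d
    }
    main <- njTree(toMat((MM %*% rep(1, L)) / (CC %*% rep(1, L))))
    set.seed(seed)
    reps <- vector("list", nReps)
    for (r in seq_len(nReps)) {
        w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
        den <- as.numeric(CC %*% w)
        if (any(den == 0)) den[den == 0] <- 1  # degenerate resample
        reps[[r]] <- njTree(toMat(as.numeric(MM %*% w) / den))
    }
    cnt <- ape::prop.clades(main, reps, rooted = FALSE)
    supp <- 100 * cnt / nReps
    supp[is.na(supp)] <- 0
    supp[1L] <- NA  # basal node: not an internal edge
    main$node.label <- supp
    main
}

## Descendant tip-label sets for each internal node of a phylo tree.
.cladeTipSets <- function(tree) {
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    lapply(pp, function(idx) labs[idx])
}

#' Confirmed subgroups of a supported tree
#'
#' Clades whose subtending edge has bootstrap support strictly greater
#' than `threshold` (default 50, the conventional confirmed-subgroup
#' cutoff).
#'
#' @param tree an [ape::phylo] with numeric `node.label` supports.
#' @param threshold support threshold (percent), strict inequality.
#' @return list of character vectors, the tip sets of confirmed clades.
#' @export
confirmedSubgroups <- function(tree, threshold = 50) {
    if (is.null(tree$node.label)) stop("tree has no support values")
    supp <- suppressWarnings(as.numeric(tree$node.label))
    sets <- .cladeTipSets(tree)
    sets[!is.na(supp) & supp > threshold]
}

#' Per-class monophyly report
#'
#' Evaluates, on the unrooted tree, whether each class's tips form one
#' bipartition side (monophyly in the unrooted sense) and reports the
#' largest clade consisting purely of that class.
#'
#' @param tree an [ape::phylo].
#' @param labels named character vector, class per tip label; every tip
#'   must be labeled.
#' @return data.frame: `class`, `n`, `isMonophyletic`,
#'   `largestPureClade`.
#' @export
classMonophyly <- function(tree, labels) {
    tips <- tree$tip.label
    miss <- setdiff(tips, names(labels))
    if (length(miss)) stop("unlabeled leaf: ", miss[1])
    lab <- labels[tips]
    sets <- .cladeTipSets(tree)
    all <- tips
    out <- lapply(unique(lab), function(cl) {
        S <- tips[lab == cl]
        mono <- length(S) <= 1L || length(S) == length(tips) ||
            any(vapply(sets, function(x)
                setequal(x, S) || setequal(x, setdiff(all, S)), logical(1)))
        pure <- vapply(sets, function(x) all(x %in% S), logical(1))
        largest <- max(c(1L, lengths(sets)[pure]))
        data.frame(class = cl, n = length(S), isMonophyletic = mono,
                   largestPureClade = largest)
    })
    do.call(rbind, out)
}

## Support of the bipartition separating tip set S, or NA if absent.
.bipartitionSupport <- function(tree, S) {
    sets <- .cladeTipSets(tree)
    supp <- suppressWarnings(as.numeric(tree$node.label))
    all <- tree$tip.label
    for (i in seq_along(sets)) {
        if (setequal(sets[[i]], S) || setequal(sets[[i]], setdiff(all, S)))
            return(supp[i])
    }
    NA_real_
}

#' Do ClpIa and ClpIb form confirmed subgroups within a ClpI clade?
#'
#' The phylogenetic signature of the two ClpI sub-lineages: the combined
#' ClpI tips form one side of a bipartition of the tree, and within it the
#' ClpIa and ClpIb tip sets are each subtended by an edge with bootstrap
#' support above `threshold`.
#'
#' @param tree an [ape::phylo] with supports (see [bootstrapSupports()]).
#' @param labels named character vector of tip labels
#'   (`ClpIa`/`ClpIb`/others).
#' @param threshold confirmed-subgroup support cutoff, default 50 (strict).
#' @return `TRUE`/`FALSE`.
#' @export
subtypeSeparation <- function(tree, labels, threshold = 50) {
    tips <- tree$tip.label
    lab <- labels[tips]
    Sa <- tips[lab == "ClpIa"]; Sb <- tips[lab == "ClpIb"]
    if (!length(Sa) || !length(Sb)) return(FALSE)
    SI <- c(Sa, Sb)
    iClade <- length(SI) == length(tips) ||
        !is.na(.bipartitionSupport(tree, SI)) ||
        any(vapply(.cladeTipSets(tree), function(x) setequal(x, SI),
                   logical(1)))
    sa <- .bipartitionSupport(tree, Sa)
    sb <- .bipartitionSupport(tree, Sb)
    isTRUE(iClade) && !is.na(sa) && sa > threshold &&
        !is.na(sb) && sb > threshold
}

#' Write / read a supported tree in Newick format
#'
#' Supports are stored as internal-node comments (the standard Newick
#' convention of node labels).
#'
#' @param tree an [ape::phylo].
#' @param path file path.
#' @return `writeSupportTree`: `path` invisibly; `readSupportTree`: an
#'   [ape::phylo].
#' @export
writeSupportTree <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' @rdname writeSupportTree
#' @export
readSupportTree <- function(path) {
    ape::read.tree(path)
}
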