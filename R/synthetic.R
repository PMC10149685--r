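## Master coordinate frame of the synthetic Clp family: fixed-width blocks,
## every class template occupies a left-aligned prefix of each block.
MASTER_BLOCKS <- data.frame(
    block = c("NTD", "D1a", "M", "D1b", "D2a", "LGF", "D2b"),
    width = c(190L, 110L, 100L, 100L, 95L, 12L, 93L),
    rateClass = c("NTD", "core", "M_domain", "core", "core", "LGF_loop",
                  "core"))

WALKER_A1 <- "GESGVGKT"; WALKER_B1 <- "ILLFDE"
WALKER_A2 <- "GPTGVGKT"; WALKER_B2 <- "VVLFDE"

.randChars <- function(n) sample(AA20, n, replace = TRUE)

## BLOSUM-biased substitution proposal: P(y | x) ~ exp(B[x, y] / temp), y != x,
## so synthetic divergence prefers conservative exchanges like real evolution.
.blosumProposal <- function(temp = 2) {
    B <- blosum62Matrix()
    P <- exp(B / temp)
    diag(P) <- 0
    P / rowSums(P)
}

.mutateChars <- function(chars, rate, proposal, protect = integer(0)) {
    n <- length(chars)
    r <- rep_len(rate, n)
    if (length(protect)) r[protect] <- 0
    hit <- which(stats::runif(n) < r)
    for (i in hit)
        chars[i] <- sample(AA20, 1L, prob = proposal[chars[i], ])
    chars
}

## Run fn with a private RNG stream, restoring the caller's stream after.
.withSeed <- function(seed, fn) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    fn()
}

.pieceLengths <- function(className) {
    switch(className,
           ClpB = c(NTD = 150L, D1a = 110L, M = 90L, D1b = 100L,
                    D2a = 95L, LGF = 8L, D2b = 93L),
           ClpC = c(NTD = 145L, D1a = 110L, M = 20L, D1b = 100L,
                    D2a = 95L, LGF = 12L, D2b = 93L),
           ClpIa = c(NTD = 175L, D1a = 110L, M = 20L, D1b = 100L,
                     D2a = 95L, LGF = 12L, D2b = 93L),
           ClpIb = c(NTD = 175L, D1a = 110L, M = 26L, D1b = 100L,
                     D2a = 95L, LGF = 5L, D2b = 93L))
}

.assembleTemplate <- function(className, pieces, variableByPiece,
                              subRate, delProb) {
    lens <- vapply(pieces, length, integer(1))
    off <- cumsum(c(0L, lens[-length(lens)]))
    names(off) <- names(pieces)
    chars <- unlist(pieces, use.names = FALSE)
    ## canonical + sub-block regions on the ungapped template
    reg <- IRanges(
        start = c(1L, off["D1a"] + 1L, off["M"] + 1L, off["D2a"] + 1L,
                  off["LGF"] + 1L,
                  off["D1a"] + 1L, off["M"] + 1L, off["D1b"] + 1L,
                  off["D2a"] + 1L, off["D2b"] + 1L),
        end = c(lens["NTD"], off["D2a"], off["M"] + lens["M"], sum(lens),
                off["LGF"] + lens["LGF"],
                off["D1a"] + lens["D1a"], off["M"] + lens["M"],
                off["D1b"] + lens["D1b"], off["D2a"] + lens["D2a"],
                sum(lens)),
        names = c("NTD", "D1", "M_domain", "D2", "LGF_loop",
                  "D1a", "M", "D1b", "D2a", "D2b"))
    ## protected motif positions (absolute)
    prot <- integer(0)
    protFrom <- function(piece, rel) off[piece] + rel
    prot <- c(protFrom("D1a", attr(pieces$D1a, "motif")),
              protFrom("D1b", attr(pieces$D1b, "motif")),
              protFrom("D2a", attr(pieces$D2a, "motif")),
              protFrom("D2b", attr(pieces$D2b, "motif")))
    if (!is.null(attr(pieces$LGF, "motif")))
        prot <- c(prot, protFrom("LGF", attr(pieces$LGF, "motif")))
    variable <- unlist(lapply(names(variableByPiece), function(p)
        off[p] + variableByPiece[[p]]), use.names = FALSE)
    ## master string: left-aligned pieces padded to the block widths
    mb <- MASTER_BLOCKS
    masterChars <- unlist(lapply(seq_len(nrow(mb)), function(i) {
        p <- pieces[[mb$block[i]]]
        c(p, rep("-", mb$width[i] - length(p)))
    }), use.names = FALSE)
    new("ClassTemplate", className = className,
        residues = paste(chars, collapse = ""),
        master = paste(masterChars, collapse = ""),
        regions = reg, subRate = subRate,
        variable = as.integer(variable), delProb = delProb,
        protected = as.integer(prot))
}

#' Default class templates of the synthetic Clp-family generator
#'
#' Builds concrete ClpB/ClpC/ClpIa/ClpIb templates encoding the
#' class-contrastive architecture: shared (ancestrally related) D1/D2
#' ATPase cores carrying protected Walker A/B motifs; a ~90 aa ClpB
#' M-domain versus ~20 aa M-domains elsewhere, with tolerated insertions
#' only in ClpIb; an LGF-loop with a protected Leu-Gly-Phe motif in ClpC
#' and ClpIa, a ~5 aa motif-free loop in ClpIb and none in ClpB; a short,
#' strongly conserved fixed-length NTD in ClpC versus longer, variable
#' NTDs in ClpB and ClpI. ClpI cores are a balanced mosaic of the ClpB and
#' ClpC cores plus ClpI-specific divergence, so ClpI sits on the
#' equal-similarity diagonal of the reference bit-score plane by
#' construction; ClpIa and ClpIb then diverge from the common ClpI
#' ancestor.
#'
#' @param seed template seed (class-level divergence draws), default 101.
#' @param classDivergence core substitution rate from the common ancestor
#'   to ClpB/ClpC (default 0.18) .
#' @param temp softmax temperature of the BLOSUM-biased proposal.
#' @return named list of [ClassTemplate-class] (`ClpB`, `ClpC`, `ClpIa`,
#'   `ClpIb`) with the master block layout in `attr(, "blocks")`.
#' @export
defaultTemplates <- function(seed = 101L, classDivergence = 0.18,
                             temp = 2) {
    prop <- .blosumProposal(temp)
    .withSeed(seed, function() {
        plant <- function(chars, motif, at) {
            m <- strsplit(motif, "")[[1]]
            chars[at:(at + length(m) - 1L)] <- m
            attr(chars, "motif") <- at:(at + length(m) - 1L)
            chars
        }
        ## ancestor cores (identical block widths across classes)
        anc <- list(
            D1a = plant(.randChars(110L), WALKER_A1, 15L),
            D1b = plant(.randChars(100L), WALKER_B1, 41L),
            D2a = plant(.randChars(95L), WALKER_A2, 11L),
            D2b = plant(.randChars(93L), WALKER_B2, 36L))
        ## class-invariant guard flanks around the LGF block
        anc$D2a[93:95] <- c("T", "K", "E")
        attr(anc$D2a, "motif") <- c(attr(anc$D2a, "motif"), 93:95)
        anc$D2b[1:3] <- c("D", "P", "K")
        attr(anc$D2b, "motif") <- c(attr(anc$D2b, "motif"), 1:3)
        mut <- function(piece, rate) {
            out <- .mutateChars(piece, rate, prop, attr(piece, "motif"))
            attr(out, "motif") <- attr(piece, "motif")
            out
        }
        coreB <- lapply(anc, mut, rate = classDivergence)
        coreC <- lapply(anc, mut, rate = classDivergence)
        ## ClpI ancestor: balanced B/C mosaic + its own divergence
        coreI <- lapply(names(anc), function(p) {
            b <- coreB[[p]]; c0 <- coreC[[p]]
            out <- c0
            diffs <- which(b != c0)
            takeB <- diffs[seq_along(diffs) %% 2L == 0L]
            out[takeB] <- b[takeB]
            attr(out, "motif") <- attr(anc[[p]], "motif")
            mut(out, 0.08)
        })
        names(coreI) <- names(anc)
        coreIa <- lapply(coreI, mut, rate = 0.06)
        coreIb <- lapply(coreI, mut, rate = 0.06)
        ## class NTDs and M-domains
        ntdC <- .randChars(145L)
        ntdB <- .randChars(150L)
        ntdI <- .randChars(175L)
        ntdIa <- .mutateChars(ntdI, 0.15, prop)
        ntdIb <- .mutateChars(ntdI, 0.15, prop)
        mB <- .randChars(90L); mC <- .randChars(20L)
        mI <- .randChars(20L)
        mIa <- .mutateChars(mI, 0.10, prop)
        mIb20 <- .mutateChars(mI, 0.10, prop)
        mIb <- append(mIb20, .randChars(6L), after = 10L)  # tolerated inserts
        lgfC <- plant(strsplit("PVDELGFSAQTR", "")[[1]], "LGF", 5L)
        lgfIa <- plant(strsplit("TMDELGFKNEQA", "")[[1]], "LGF", 5L)
        lgfIb <- strsplit("PSNDA", "")[[1]]      # short, no LGF-like motif
        lgfB <- strsplit("SDKQTEPA", "")[[1]]    # ClpB: no docking loop
        rates <- function(ntd) c(NTD = ntd, core = 0.04, M_domain = 0.06,
                                 LGF_loop = 0.05)
        tpl <- list(
            ClpB = .assembleTemplate("ClpB",
                list(NTD = ntdB, D1a = coreB$D1a, M = mB, D1b = coreB$D1b,
                     D2a = coreB$D2a, LGF = lgfB, D2b = coreB$D2b),
                list(NTD = sort(sample(30:140, 12L))),
                rates(0.22), 0.35),
            ClpC = .assembleTemplate("ClpC",
                list(NTD = ntdC, D1a = coreC$D1a, M = mC, D1b = coreC$D1b,
                     D2a = coreC$D2a, LGF = lgfC, D2b = coreC$D2b),
                list(),
                rates(0.02), 0.35),
            ClpIa = .assembleTemplate("ClpIa",
                list(NTD = ntdIa, D1a = coreIa$D1a, M = mIa,
                     D1b = coreIa$D1b, D2a = coreIa$D2a, LGF = lgfIa,
                     D2b = coreIa$D2b),
                list(NTD = sort(sample(20:170, 20L))),
                rates(0.18), 0.35),
            ClpIb = .assembleTemplate("ClpIb",
                list(NTD = ntdIb, D1a = coreIb$D1a, M = mIb,
                     D1b = coreIb$D1b, D2a = coreIb$D2a, LGF = lgfIb,
                     D2b = coreIb$D2b),
                list(NTD = sort(sample(20:170, 20L)),
                     M = 11:16),
                rates(0.18), 0.35))
        attr(tpl, "blocks") <- {
            mb <- MASTER_BLOCKS
            mb$end <- cumsum(mb$width); mb$start <- mb$end - mb$width + 1L
            mb
        }
        tpl
    })
}

#' Sample one synthetic sequence from a class template
#'
#' Applies per-region point substitutions (BLOSUM-biased proposal) at the
#' template's rates, independent deletion of the occupancy-variable
#' positions (the generator's model of tolerated indels), never touching
#' protected motif positions, and returns the sequence together with its
#' truth domain coordinates and its gapped master-frame row. Uses the
#' caller's RNG stream; seed at the cohort level.
#'
#' @param template a [ClassTemplate-class].
#' @param divergence global multiplier on substitution rates, default 1.
#' @param temp proposal temperature.
#' @return list: `residues`, `gapped` (master frame), `regions` (named
#'   [IRanges::IRanges] of NTD/D1/M_domain/D2/LGF_loop on the sequence),
#'   `className`.
#' @export
sampleSequence <- function(template, divergence = 1, temp = 2) {
    chars <- strsplit(template@residues, "")[[1]]
    n <- length(chars)
    ## per-position substitution rate from the block rate classes
    rate <- numeric(n)
    blockRegion <- c(NTD = "NTD", D1a = "D1a", M = "M", D1b = "D1b",
                     D2a = "D2a", LGF = "LGF_loop", D2b = "D2b")
    for (i in seq_len(nrow(MASTER_BLOCKS))) {
        r <- template@regions[blockRegion[MASTER_BLOCKS$block[i]]]
        rate[start(r):end(r)] <-
            template@subRate[MASTER_BLOCKS$rateClass[i]] * divergence
    }
    prop <- .blosumProposal(temp)
    chars <- .mutateChars(chars, rate, prop, template@protected)
    keep <- rep(TRUE, n)
    if (length(template@variable))
        keep[template@variable] <-
            stats::runif(length(template@variable)) >= template@delProb
    ## master-frame row
    mchars <- strsplit(template@master, "")[[1]]
    tplCols <- which(mchars != "-")
    mchars[tplCols] <- ifelse(keep, chars, "-")
    ## truth coordinates on the retained sequence
    cum <- cumsum(keep)
    canon <- c("NTD", "D1", "M_domain", "D2", "LGF_loop")
    rg <- template@regions[canon]
    newStart <- cum[start(rg)] - keep[start(rg)] + 1L
    newEnd <- cum[end(rg)]
    reg <- IRanges(start = pmin(newStart, newEnd + 1L), end = newEnd,
                   names = canon)
    list(residues = paste(chars[keep], collapse = ""),
         gapped = paste(mchars, collapse = ""),
         regions = reg, className = template@className)
}

#' Cohort configuration for the synthetic generator
#'
#' @param counts per-order class counts: either a named vector
#'   (`c(ClpB = , ClpC = , ClpIa = , ClpIb = )`, applied to every order) or
#'   a matrix with orders as rows and classes as columns.
#' @param orders taxonomic order names.
#' @param seed cohort seed; all randomness flows from it.
#' @param divergence global divergence scale, default 1.
#' @param templateSeed seed of [defaultTemplates()].
#' @param orderJitter half-width of the per-order uniform jitter on the
#'   divergence scale (coarse emulation of lineage effects), default 0.15.
#' @return a config list.
#' @export
cohortConfig <- function(counts = c(ClpB = 22L, ClpC = 20L, ClpIa = 5L,
                                    ClpIb = 3L),
                         orders = c("Mycobacteriales", "Streptomycetales",
                                    "Micrococcales", "Pseudonocardiales"),
                         seed = 1L, divergence = 1, templateSeed = 101L,
                         orderJitter = 0.15) {
    if (is.matrix(counts)) {
        orders <- rownames(counts)
    } else {
        counts <- matrix(rep(as.integer(counts), each = length(orders)),
                         nrow = length(orders),
                         dimnames = list(orders, names(counts)))
    }
    if (any(counts < 0L)) stop("counts must be >= 0")
    list(counts = counts, orders = orders, seed = as.integer(seed),
         divergence = divergence, templateSeed = as.integer(templateSeed),
         orderJitter = orderJitter)
}

#' Generate a synthetic Clp-family cohort with ground truth
#'
#' Draws the configured number of sequences per class and taxonomic order
#' from the class templates. Output is byte-deterministic under the config
#' seed.
#'
#' @param config a [cohortConfig()].
#' @param templates optionally, a pre-built [defaultTemplates()] set.
#' @return a [ClpCohort-class].
#' @export
#' @examples
#' co <- generateCohort(cohortConfig(counts = c(ClpB = 3, ClpC = 3,
#'                                              ClpIa = 2, ClpIb = 2),
#'                                   orders = "Mycobacteriales", seed = 7))
#' table(truthLabels(co))
generateCohort <- function(config = cohortConfig(), templates = NULL) {
    if (sum(config$counts) == 0L) stop("cohort would contain no sequences")
    if (is.null(templates)) templates <- defaultTemplates(config$templateSeed)
    .withSeed(config$seed, function() {
        ids <- character(0); seqs <- character(0); gapped <- character(0)
        labs <- character(0); taxa <- character(0)
        regs <- vector("list", 0L)
        for (o in seq_along(config$orders)) {
            ord <- config$orders[o]
            jit <- 1 + stats::runif(1, -config$orderJitter,
                                    config$orderJitter)
            for (cl in colnames(config$counts)) {
                k <- config$counts[ord, cl]
                if (k == 0L) next
                for (i in seq_len(k)) {
                    s <- sampleSequence(templates[[cl]],
                                        divergence = config$divergence * jit)
                    id <- sprintf("%s_%s_%03d", tolower(cl),
                                  substr(ord, 1L, 4L), i)
                    ids <- c(ids, id); seqs <- c(seqs, s$residues)
                    gapped <- c(gapped, s$gapped)
                    labs <- c(labs, cl); taxa <- c(taxa, ord)
                    regs[[length(regs) + 1L]] <- data.frame(
                        id = id, region = names(s$regions),
                        start = start(s$regions), end = end(s$regions))
                }
            }
        }
        sset <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
        aln <- Biostrings::AAMultipleAlignment(
            stats::setNames(gapped, ids))
        new("ClpCohort", sequences = sset,
            labels = stats::setNames(labs, ids),
            taxonomy = stats::setNames(taxa, ids),
            regions = do.call(rbind, regs),
            alignment = aln, seed = config$seed, config = config)
    })
}

#' Remove a truth region from every cohort sequence
#'
#' Used for the NTD-truncation control: deletes the named region (by its
#' ground-truth coordinates) from each sequence.
#'
#' @param cohort a [ClpCohort-class].
#' @param region region name, default `"NTD"`.
#' @return an [Biostrings::AAStringSet] of truncated sequences.
#' @export
stripRegion <- function(cohort, region = "NTD") {
    regs <- cohort@regions
    seqs <- as.character(cohort@sequences)
    out <- vapply(names(seqs), function(id) {
        r <- regs[regs$id == id & regs$region == region, ]
        if (!nrow(r) || r$end < r$start) return(seqs[[id]])
        paste0(substr(seqs[[id]], 1L, r$start - 1L),
               substr(seqs[[id]], r$end + 1L, nchar(seqs[[id]])))
    }, character(1))
    Biostrings::AAStringSet(out)
}

#' Write a cohort to disk
#'
#' Emits the generator's file outputs: sequences (FASTA), taxonomy, truth
#' labels and truth region coordinates (TSV), the master-frame alignment
#' (aligned FASTA) and the config (YAML, including the seed).
#'
#' @param cohort a [ClpCohort-class].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- c(sequences = file.path(dir, "sequences.fasta"),
           taxonomy = file.path(dir, "taxonomy.tsv"),
           labels = file.path(dir, "labels.tsv"),
           regions = file.path(dir, "regions.tsv"),
           alignment = file.path(dir, "alignment.fasta"),
           config = file.path(dir, "config.yaml"))
    writeProteinFasta(cohort@sequences, p["sequences"])
    writeTaxonomy(cohort@taxonomy, p["taxonomy"])
    utils::write.table(data.frame(id = names(cohort@labels),
                                  label = cohort@labels),
                       p["labels"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cohort@regions, p["regions"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeMsa(cohort@alignment, p["alignment"])
    cfg <- cohort@config
    cfg$counts <- as.data.frame(cfg$counts)
    yaml::write_yaml(cfg, p["config"])
    invisible(p)
}

#' Canonical region map of a class template
#'
#' Convenience for using a generator template as the annotated reference
#' of the feature-annotation stage: extracts the five canonical regions
#' into a [RegionMap-class] keyed by the class name.
#'
#' @param template a [ClassTemplate-class].
#' @return a [RegionMap-class].
#' @export
templateRegionMap <- function(template) {
    rg <- template@regions[c("NTD", "D1", "M_domain", "D2", "LGF_loop")]
    new("RegionMap", referenceId = template@className, regions = rg)
}
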