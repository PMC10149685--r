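## 32-bit FNV-1a over the bytes of a string; used for config fingerprints.
.fnv1a <- function(x) {
    bytes <- as.integer(charToRaw(paste(x, collapse = "")))
    h <- 2166136261
    for (b in bytes) {
        low <- h %% 256
        h <- h - low + bitwXor(as.integer(low), b)
        h <- (h * 16777619) %% 2^32
    }
    paste0(sprintf("%04x", as.integer(h %/% 65536)),
           sprintf("%04x", as.integer(h %% 65536)))
}

.logMsg <- function(...) message("[ClpTyper] ", ...)

#' Read a pipeline run configuration
#'
#' A single YAML file holding input paths, reference ids, region
#' coordinates, scoring parameters, gate definitions and phylogeny
#' settings. Returned as a plain list; missing entries are left `NULL` and
#' stages fall back to their documented defaults.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("no such config: ", path)
    yaml::read_yaml(path)
}

.writeManifest <- function(outDir, stage, inputs, config, seed) {
    man <- list(stage = stage,
                inputs = inputs,
                configHash = .fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                     null = "null")),
                seed = seed,
                packageVersion = as.character(utils::packageVersion("ClpTyper")),
                rVersion = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(man)
}

#' Simulate stage: generate and write a synthetic cohort
#'
#' @param config a [cohortConfig()] list (or `NULL` for defaults).
#' @param outDir output directory.
#' @return the [ClpCohort-class], invisibly.
#' @export
runSimulate <- function(config = cohortConfig(), outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cohort <- generateCohort(config)
    writeCohort(cohort, outDir)
    .writeManifest(outDir, "simulate", list(), config, config$seed)
    .logMsg("simulated ", length(cohortSequences(cohort)), " sequences")
    invisible(cohort)
}

#' Classify stage: reference scoring plus gate assignment
#'
#' Scores every sequence against the ClpC and ClpB references, assigns
#' classes (explicit gates when provided, otherwise the relative
#' auto-gating rule of [autoAssignClasses()]), and writes the score/label
#' TSV, the density grid and a manifest. Numeric outputs use fixed decimal
#' formatting for diffability.
#'
#' @param sequences an [Biostrings::AAStringSet] or FASTA path.
#' @param refC,refB reference residue strings.
#' @param outDir output directory.
#' @param gates optional [gateSet()]; overlapping gates are refused by its
#'   validator before any scoring.
#' @param scheme a [ScoringScheme-class].
#' @param floorBits,relTol auto-gating parameters.
#' @param nBins density grid resolution.
#' @param plots also write a scatter plot (PDF)? Default `FALSE` so
#'   headless runs produce only text outputs.
#' @return data.frame with `id`, `label`, `scoreC`, `scoreB`, invisibly.
#' @export
runClassify <- function(sequences, refC, refB, outDir, gates = NULL,
                        scheme = scoringScheme(), floorBits = 50,
                        relTol = 0.1, nBins = 25L, plots = FALSE) {
    if (is.character(sequences) && length(sequences) == 1L &&
        file.exists(sequences))
        sequences <- readProteinFasta(sequences)
    if (!is.null(gates))
        gates <- gateSet(gates$label, gates$xmin, gates$xmax, gates$ymin,
                         gates$ymax)
    if (!nzchar(as.character(refC)) || !nzchar(as.character(refB)))
        stop("missing reference sequence")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    scores <- scoreToReferences(sequences, refC, refB, scheme)
    lab <- if (is.null(gates)) autoAssignClasses(scores, floorBits, relTol)
           else assignByGates(scores, gates)
    out <- data.frame(id = scores$id, label = lab,
                      scoreC = sprintf("%.3f", scores$scoreC),
                      scoreB = sprintf("%.3f", scores$scoreB))
    utils::write.table(out, file.path(outDir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dg <- densityGrid(scores, nBins, nBins)
    utils::write.table(dg$counts, file.path(outDir, "density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    if (plots) {
        grDevices::pdf(file.path(outDir, "scatter.pdf"))
        plotBitScores(cbind(scores, label = lab), gates)
        grDevices::dev.off()
    }
    .writeManifest(outDir, "classify",
                   list(n = length(sequences)),
                   list(floorBits = floorBits, relTol = relTol,
                        gates = gates), NA)
    invisible(data.frame(id = scores$id, label = lab,
                         scoreC = scores$scoreC, scoreB = scores$scoreB))
}

#' Profile-compare stage: cross-align two MSAs
#'
#' Builds column profiles for both alignments, cross-aligns them, and
#' writes the per-residue score bitmaps, the merged correspondence with
#' the per-column cross-comparison score strip, and a manifest.
#'
#' @param msaTop,msaBottom [Biostrings::AAMultipleAlignment] objects or
#'   alignment file paths (aligned FASTA).
#' @param outDir output directory.
#' @param gapPenalty see [profileProfileAlign()].
#' @param plots write bitmap/strip PDFs?
#' @return the [CrossAlignmentResult-class], invisibly.
#' @export
runProfileCompare <- function(msaTop, msaBottom, outDir, gapPenalty = 4,
                              plots = FALSE) {
    if (is.character(msaTop)) msaTop <- readMsa(msaTop)
    if (is.character(msaBottom)) msaBottom <- readMsa(msaBottom)
    if (!nrow(msaTop) || !nrow(msaBottom)) stop("empty alignment")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    top <- buildProfiles(msaTop)
    bottom <- buildProfiles(msaBottom)
    res <- profileProfileAlign(top, bottom, gapPenalty)
    wtsv <- function(x, f) utils::write.table(
        x, file.path(outDir, f), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    wtsv(round(renderBitmap(top), 3), "bitmap_top.tsv")
    wtsv(round(renderBitmap(bottom), 3), "bitmap_bottom.tsv")
    utils::write.table(correspondence(res),
                       file.path(outDir, "cross_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (plots) {
        grDevices::pdf(file.path(outDir, "cross_strip.pdf"))
        plotBitmap(crossScores(res), main = "cross-alignment score strip")
        grDevices::dev.off()
    }
    .writeManifest(outDir, "profile-compare",
                   list(topCols = ncol(top), bottomCols = ncol(bottom)),
                   list(gapPenalty = gapPenalty), NA)
    invisible(res)
}

#' Phylogeny stage: subsample, distances, NJ, bootstrap, reports
#'
#' Subsamples the labeled cohort per taxonomic order (and class), restricts
#' the alignment to the selected ids (dropping columns that become
#' all-gap), builds the neighbor-joining tree with bootstrap supports, and
#' writes the Newick tree plus confirmed-subgroup and monophyly reports.
#'
#' @param alignment [Biostrings::AAMultipleAlignment] (or path) covering
#'   the cohort.
#' @param labels named character vector of class labels.
#' @param taxonomy named character vector of orders.
#' @param outDir output directory.
#' @param k per order-and-class subsampling quota, default 5.
#' @param nReps bootstrap replicates, default 100.
#' @param seed seed for subsampling and bootstrap.
#' @param threshold confirmed-subgroup cutoff (strictly greater), default
#'   50.
#' @return list with `tree`, `confirmed`, `monophyly`,
#'   `subtypeSeparation`, invisibly.
#' @export
runPhylo <- function(alignment, labels, taxonomy, outDir, k = 5L,
                     nReps = 100L, seed = 1L, threshold = 50) {
    if (is.character(alignment)) alignment <- readMsa(alignment)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ids <- rownames(alignment)
    empty <- setdiff(unique(taxonomy), unique(taxonomy[ids]))
    if (length(empty))
        .logMsg("orders without sequences skipped: ",
                paste(empty, collapse = ", "))
    keep <- subsamplePerOrder(ids, taxonomy, k = k, seed = seed,
                              by = labels)
    m <- .alnMatrix(alignment)[keep, , drop = FALSE]
    m <- m[, colSums(m != "-") > 0L, drop = FALSE]
    sub <- Biostrings::AAMultipleAlignment(apply(m, 1L, paste,
                                                 collapse = ""))
    tree <- bootstrapSupports(sub, nReps = nReps, seed = seed)
    writeSupportTree(tree, file.path(outDir, "tree.nwk"))
    conf <- confirmedSubgroups(tree, threshold)
    mono <- classMonophyly(tree, labels)
    sep <- subtypeSeparation(tree, labels, threshold)
    writeLines(vapply(conf, paste, "", collapse = ","),
               file.path(outDir, "confirmed_subgroups.txt"))
    utils::write.table(mono, file.path(outDir, "monophyly.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .writeManifest(outDir, "phylo", list(n = length(keep)),
                   list(k = k, nReps = nReps, threshold = threshold), seed)
    invisible(list(tree = tree, confirmed = conf, monophyly = mono,
                   subtypeSeparation = sep))
}

#' Summarize stage: occurrence table and presence statistics
#'
#' @param labels named character vector (or data.frame id/label); may be
#'   empty.
#' @param taxonomy named character vector of orders.
#' @param outDir output directory.
#' @param scores optional data.frame from [scoreToReferences()] for
#'   per-order score distributions.
#' @return list with `table`, `stats` and optionally `distributions`,
#'   invisibly.
#' @export
runSummarize <- function(labels, taxonomy, outDir, scores = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (is.data.frame(labels))
        labels <- stats::setNames(labels$label, labels$id)
    if (!length(labels)) {
        tab <- matrix(integer(0), nrow = 0L, ncol = 4L,
                      dimnames = list(NULL, CLP_CLASSES))
    } else {
        tab <- buildOccurrenceTable(labels, taxonomy)
    }
    if (nrow(tab)) writeOccurrenceTable(tab, file.path(outDir,
                                                       "occurrence.tsv"))
    st <- orderPresenceStats(tab)
    jsonlite::write_json(st, file.path(outDir, "presence_stats.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out <- list(table = tab, stats = st)
    if (!is.null(scores)) {
        out$distributions <- perOrderScoreDistribution(scores, taxonomy,
                                                       labels)
        utils::write.table(out$distributions$summary,
                           file.path(outDir, "score_distributions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .writeManifest(outDir, "summarize", list(n = length(labels)),
                   list(), NA)
    invisible(out)
}
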