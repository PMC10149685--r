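## Shared lazily-computed fixtures for the expensive cohort analyses, so
## several test files can reuse one scored cohort.
.fixtures <- new.env(parent = emptyenv())

fixtureTemplates <- function() {
    if (is.null(.fixtures$tpl)) .fixtures$tpl <- defaultTemplates()
    .fixtures$tpl
}

## The standard 200-sequence study cohort (4 orders x 50) at default
## divergence, with reference scores, auto-gate labels and feature labels.
fixtureCohortAnalysis <- function() {
    if (!is.null(.fixtures$cohort)) return(.fixtures$cohort)
    tpl <- fixtureTemplates()
    refC <- tpl$ClpC@residues
    refB <- tpl$ClpB@residues
    cohort <- generateCohort(cohortConfig(seed = 2023L))
    scores <- scoreToReferences(cohortSequences(cohort), refC, refB)
    gateLabels <- autoAssignClasses(scores)
    report <- featureReport(cohortSequences(cohort), refC,
                            templateRegionMap(tpl$ClpC))
    featureLabels <- classifyByFeatures(
        report, refNtdLength = IRanges::width(tpl$ClpC@regions["NTD"]))
    .fixtures$cohort <- list(cohort = cohort, refC = refC, refB = refB,
                             scores = scores, gateLabels = gateLabels,
                             report = report,
                             featureLabels = featureLabels)
    .fixtures$cohort
}

## A small cohort for cheap bookkeeping / pipeline tests.
fixtureSmallCohort <- function() {
    if (is.null(.fixtures$small))
        .fixtures$small <- generateCohort(cohortConfig(
            counts = c(ClpB = 4L, ClpC = 4L, ClpIa = 3L, ClpIb = 3L),
            orders = c("Mycobacteriales", "Streptomycetales"),
            seed = 7L))
    .fixtures$small
}

classMsa <- function(cohort, class) {
    keep <- names(truthLabels(cohort))[truthLabels(cohort) == class]
    gapped <- as.character(Biostrings::unmasked(cohortAlignment(cohort)))
    Biostrings::AAMultipleAlignment(gapped[keep])
}
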