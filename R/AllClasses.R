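#' @importFrom methods new validObject is setClass setValidity setMethod setGeneric show slot
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Scoring scheme for local alignment and bit-score conversion
#'
#' Bundles a symmetric integer substitution matrix (half-bit units), affine
#' gap penalties (BLAST convention: a gap of length L costs
#' `gapOpen + gapExtend * (L - 1)`), and the Karlin-Altschul parameters
#' `lambda` (nats per raw-score unit) and `K` used to rescale raw scores to
#' bits.
#'
#' @slot matrix symmetric integer substitution matrix, rows/columns named by
#'   amino-acid letters (the 20 standard residues, optionally `X`).
#' @slot gapOpen,gapExtend positive integer gap penalties,
#'   `gapOpen >= gapExtend >= 1`.
#' @slot lambda,K positive reals of the bit-score conversion
#'   `bits = (lambda * raw - log(K)) / log(2)`.
#' @name ScoringScheme-class
#' @aliases ScoringScheme-class
#' @exportClass ScoringScheme
setClass("ScoringScheme",
         slots = c(matrix = "matrix", gapOpen = "integer",
                   gapExtend = "integer", lambda = "numeric", K = "numeric"))

setValidity("ScoringScheme", function(object) {
    m <- object@matrix
    msg <- character()
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "matrix must have identical row and column names")
    if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "substitution matrix must be symmetric")
    if (!all(AA20 %in% rownames(m)))
        msg <- c(msg, "matrix must cover the 20 standard amino acids")
    if (length(object@gapOpen) != 1L || length(object@gapExtend) != 1L ||
        object@gapExtend < 1L || object@gapOpen < object@gapExtend)
        msg <- c(msg, "need gapOpen >= gapExtend >= 1")
    if (object@lambda <= 0 || object@K <= 0)
        msg <- c(msg, "lambda and K must be positive")
    if (length(msg)) msg else TRUE
})

#' Optimal local alignment of a query against a reference
#'
#' Result of [alignLocal()]: the Smith-Waterman optimum under affine gaps,
#' its bit-score, the gapped aligned strings and the aligned spans
#' (1-based, inclusive) on query and reference.
#'
#' @slot raw numeric, optimal raw score (>= 0; 0 means the empty alignment).
#' @slot bits numeric, `raw` rescaled to bits by the scheme.
#' @slot alignedQuery,alignedRef equal-length gapped strings.
#' @slot queryStart,queryEnd,refStart,refEnd integer span bounds (0 when the
#'   optimal alignment is empty).
#' @name LocalHit-class
#' @aliases LocalHit-class
#' @exportClass LocalHit
setClass("LocalHit",
         slots = c(raw = "numeric", bits = "numeric",
                   alignedQuery = "character", alignedRef = "character",
                   queryStart = "integer", queryEnd = "integer",
                   refStart = "integer", refEnd = "integer"))

setMethod("show", "LocalHit", function(object) {
    cat("LocalHit: raw =", object@raw, "| bits =", round(object@bits, 1), "\n")
    cat("  query span [", object@queryStart, ", ", object@queryEnd,
        "]  ref span [", object@refStart, ", ", object@refEnd, "]\n", sep = "")
})

#' Named domain regions on a reference sequence
#'
#' Coordinates (1-based, inclusive [IRanges::IRanges]) of the canonical Clp
#' unfoldase architecture on a designated reference sequence: the N-terminal
#' domain (`NTD`), the first AAA+ module (`D1`) with its nested helical
#' `M_domain`, and the second AAA+ module (`D2`) containing the `LGF_loop`.
#'
#' @slot referenceId id of the reference sequence the coordinates live on.
#' @slot regions named [IRanges::IRanges] with at least
#'   `NTD`, `D1`, `M_domain`, `D2`, `LGF_loop`.
#' @name RegionMap-class
#' @aliases RegionMap-class
#' @exportClass RegionMap
setClass("RegionMap",
         slots = c(referenceId = "character", regions = "IRanges"))

setValidity("RegionMap", function(object) {
    r <- object@regions
    need <- c("NTD", "D1", "M_domain", "D2", "LGF_loop")
    msg <- character()
    if (!all(need %in% names(r)))
        return(paste("regions must include:", paste(need, collapse = ", ")))
    if (end(r["NTD"]) >= start(r["D1"]))
        msg <- c(msg, "NTD must end before D1 starts")
    if (start(r["M_domain"]) < start(r["D1"]) ||
        end(r["M_domain"]) > end(r["D1"]))
        msg <- c(msg, "M_domain must be nested in D1")
    if (start(r["LGF_loop"]) < start(r["D2"]) ||
        end(r["LGF_loop"]) > end(r["D2"]))
        msg <- c(msg, "LGF_loop must lie within D2")
    if (any(width(r) < 1L)) msg <- c(msg, "regions must be non-empty")
    if (length(msg)) msg else TRUE
})

#' @describeIn RegionMap-class constructor; `...` are named
#'   start/end pairs, e.g. `regionMap("ref", NTD = c(1, 145), ...)`.
#' @param referenceId id of the reference sequence.
#' @param ... named length-2 numeric vectors `c(start, end)`.
#' @return a `RegionMap`.
#' @export
regionMap <- function(referenceId, ...) {
    iv <- list(...)
    if (!length(iv) || is.null(names(iv)) || any(names(iv) == ""))
        stop("regions must be named c(start, end) pairs")
    st <- vapply(iv, function(x) as.integer(x[1]), integer(1))
    en <- vapply(iv, function(x) as.integer(x[2]), integer(1))
    new("RegionMap", referenceId = as.character(referenceId),
        regions = IRanges(start = st, end = en, names = names(iv)))
}

setMethod("show", "RegionMap", function(object) {
    cat("RegionMap on reference '", object@referenceId, "'\n", sep = "")
    r <- object@regions
    for (nm in names(r))
        cat(sprintf("  %-10s %5d..%d\n", nm, start(r[nm]), end(r[nm])))
})

#' Multiple sequence alignment with per-column residue profiles
#'
#' An [Biostrings::AAMultipleAlignment] together with its per-column
#' 20-member amino-acid frequency profiles (columns of `profiles` sum to 1
#' where the alignment column holds at least one unambiguous residue) and the
#' count of residues contributing to each column.
#'
#' @slot alignment the underlying [Biostrings::AAMultipleAlignment].
#' @slot profiles 20 x n_cols numeric matrix of residue frequencies.
#' @slot nEffective integer vector, per-column count of counted residues.
#' @name ProfiledAlignment-class
#' @aliases ProfiledAlignment-class
#' @exportClass ProfiledAlignment
setClass("ProfiledAlignment",
         slots = c(alignment = "ANY", profiles = "matrix",
                   nEffective = "integer"))

setValidity("ProfiledAlignment", function(object) {
    if (ncol(object@profiles) != length(object@nEffective))
        return("profiles and nEffective disagree on column count")
    if (nrow(object@profiles) != 20L)
        return("profiles must have 20 rows")
    s <- colSums(object@profiles)
    ok <- ifelse(object@nEffective > 0L, abs(s - 1) < 1e-8, s == 0)
    if (!all(ok)) return("column frequencies must sum to 1 (or 0 if all-gap)")
    TRUE
})

#' @describeIn ProfiledAlignment-class number of alignment columns.
#' @param x a `ProfiledAlignment`.
#' @export
setMethod("ncol", "ProfiledAlignment", function(x) ncol(x@profiles))

#' Accessor generics
#'
#' `profiles()` returns the 20 x n_cols frequency matrix of a
#' [ProfiledAlignment-class]; `nEffective()` its per-column residue counts;
#' `correspondence()` and `crossScores()` extract the merged column map and
#' per-column cross-alignment scores of a [CrossAlignmentResult-class].
#'
#' @param x object to access.
#' @return see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setMethod("profiles", "ProfiledAlignment", function(x) x@profiles)

#' @rdname accessors
#' @export
setGeneric("nEffective", function(x) standardGeneric("nEffective"))
#' @rdname accessors
#' @export
setMethod("nEffective", "ProfiledAlignment", function(x) x@nEffective)

setMethod("show", "ProfiledAlignment", function(object) {
    cat("ProfiledAlignment:", nrow(object@alignment), "sequences x",
        ncol(object@profiles), "columns\n")
    cat("  all-gap columns:", sum(object@nEffective == 0L), "\n")
})

#' Cross-alignment of two profiled multiple sequence alignments
#'
#' Result of [profileProfileAlign()]: a monotone merged-column
#' correspondence between a top and a bottom alignment, with the
#' BLOSUM-weighted cross-comparison score at each matched column.
#'
#' @slot topIndex,bottomIndex integer vectors over merged columns; `NA`
#'   marks a gap on that side.
#' @slot sCross numeric per merged column; `NA` wherever either side is
#'   gapped (gap columns are "no data", not "dissimilar").
#' @slot score numeric, total DP score of the correspondence.
#' @slot top,bottom the input [ProfiledAlignment-class] objects.
#' @name CrossAlignmentResult-class
#' @aliases CrossAlignmentResult-class
#' @exportClass CrossAlignmentResult
setClass("CrossAlignmentResult",
         slots = c(topIndex = "integer", bottomIndex = "integer",
                   sCross = "numeric", score = "numeric",
                   top = "ProfiledAlignment", bottom = "ProfiledAlignment"))

setValidity("CrossAlignmentResult", function(object) {
    n <- length(object@topIndex)
    if (length(object@bottomIndex) != n || length(object@sCross) != n)
        return("correspondence vectors must have equal length")
    ti <- object@topIndex[!is.na(object@topIndex)]
    bi <- object@bottomIndex[!is.na(object@bottomIndex)]
    if (is.unsorted(ti, strictly = TRUE) || is.unsorted(bi, strictly = TRUE))
        return("correspondence must be strictly monotone on both sides")
    TRUE
})

#' @rdname accessors
#' @export
setGeneric("correspondence", function(x) standardGeneric("correspondence"))
#' @rdname accessors
#' @export
setMethod("correspondence", "CrossAlignmentResult", function(x)
    data.frame(top = x@topIndex, bottom = x@bottomIndex, sCross = x@sCross))

#' @rdname accessors
#' @export
setGeneric("crossScores", function(x) standardGeneric("crossScores"))
#' @rdname accessors
#' @export
setMethod("crossScores", "CrossAlignmentResult", function(x) x@sCross)

setMethod("show", "CrossAlignmentResult", function(object) {
    n <- length(object@topIndex)
    cat("CrossAlignmentResult:", n, "merged columns (",
        sum(is.na(object@topIndex)), "top gaps,",
        sum(is.na(object@bottomIndex)), "bottom gaps )\n")
    cat("  DP score:", round(object@score, 2),
        "| mean s_cross:", round(mean(object@sCross, na.rm = TRUE), 2), "\n")
})

#' Class template of the synthetic Clp-family generator
#'
#' Encodes one unfoldase class as a concrete template sequence plus mutation
#' parameters: per-region substitution rates, occupancy-variable positions
#' (emulating tolerated indels), motif positions protected from mutation,
#' and the placement of the template on the cohort-wide master coordinate
#' frame (so ground-truth multiple alignments can be emitted exactly).
#'
#' @slot className one of `ClpB`, `ClpC`, `ClpIa`, `ClpIb`.
#' @slot residues ungapped template sequence.
#' @slot master gapped template over the shared master frame.
#' @slot regions named [IRanges::IRanges] on `residues` (NTD, D1, M_domain,
#'   D2, LGF_loop and the sub-blocks D1a/D1b/D2a/D2b).
#' @slot subRate named numeric per-region substitution rates.
#' @slot variable integer positions independently deleted per sequence.
#' @slot delProb probability that a variable position is deleted.
#' @slot protected integer positions never mutated (Walker/LGF motifs).
#' @name ClassTemplate-class
#' @aliases ClassTemplate-class
#' @exportClass ClassTemplate
setClass("ClassTemplate",
         slots = c(className = "character", residues = "character",
                   master = "character", regions = "IRanges",
                   subRate = "numeric", variable = "integer",
                   delProb = "numeric", protected = "integer"))

setMethod("show", "ClassTemplate", function(object) {
    cat("ClassTemplate", object@className, "-", nchar(object@residues),
        "aa (", length(object@variable), "variable,",
        length(object@protected), "protected positions )\n")
})

#' Synthetic Clp-family cohort with ground truth
#'
#' Output of [generateCohort()]: sequences plus everything a pipeline test
#' needs — truth class labels, taxonomy, per-sequence domain coordinates,
#' and the exact master-frame multiple alignment.
#'
#' @slot sequences [Biostrings::AAStringSet], one entry per cohort member.
#' @slot labels named character, truth class per id.
#' @slot taxonomy named character, taxonomic order per id.
#' @slot regions data.frame (id, region, start, end) of truth coordinates.
#' @slot alignment [Biostrings::AAMultipleAlignment] on the master frame.
#' @slot seed integer seed the cohort was generated from.
#' @slot config the [cohortConfig()] list used.
#' @name ClpCohort-class
#' @aliases ClpCohort-class
#' @exportClass ClpCohort
setClass("ClpCohort",
         slots = c(sequences = "ANY", labels = "character",
                   taxonomy = "character", regions = "data.frame",
                   alignment = "ANY", seed = "integer", config = "list"))

#' @rdname accessors
#' @export
setGeneric("cohortSequences", function(x) standardGeneric("cohortSequences"))
#' @rdname accessors
#' @export
setMethod("cohortSequences", "ClpCohort", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setMethod("truthLabels", "ClpCohort", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("cohortTaxonomy", function(x) standardGeneric("cohortTaxonomy"))
#' @rdname accessors
#' @export
setMethod("cohortTaxonomy", "ClpCohort", function(x) x@taxonomy)

#' @rdname accessors
#' @export
setGeneric("truthRegions", function(x) standardGeneric("truthRegions"))
#' @rdname accessors
#' @export
setMethod("truthRegions", "ClpCohort", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("cohortAlignment", function(x) standardGeneric("cohortAlignment"))
#' @rdname accessors
#' @export
setMethod("cohortAlignment", "ClpCohort", function(x) x@alignment)

setMethod("show", "ClpCohort", function(object) {
    cat("ClpCohort:", length(object@sequences), "sequences, seed",
        object@seed, "\n")
    print(table(labels = object@labels, order = object@taxonomy))
})
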