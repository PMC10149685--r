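#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix in half-bit units, restricted to the 20
#' standard amino acids. With `extended = TRUE` an `X` row/column scoring 0
#' against everything is appended, matching this package's convention that
#' ambiguous residues carry no signal.
#'
#' @param extended add the neutral `X` row/column.
#' @return integer substitution matrix.
#' @export
blosum62Matrix <- function(extended = FALSE) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA20, AA20]
    if (extended) {
        m <- rbind(cbind(m, X = 0L), X = 0L)
        m["X", "X"] <- 0L
    }
    storage.mode(m) <- "integer"
    m
}

#' Construct a scoring scheme
#'
#' Defaults follow the published gapped-BLAST protein settings: BLOSUM62,
#' gap open 11, gap extend 1, and Karlin-Altschul `lambda = 0.267`,
#' `K = 0.041` for the bit-score conversion.
#'
#' @param matrix substitution matrix (see [blosum62Matrix()]).
#' @param gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   `gapOpen + gapExtend * (L - 1)`.
#' @param lambda,K Karlin-Altschul parameters.
#' @return a [ScoringScheme-class].
#' @export
#' @examples
#' sch <- scoringScheme()
#' toBits(100, sch)
scoringScheme <- function(matrix = blosum62Matrix(extended = TRUE),
                          gapOpen = 11L, gapExtend = 1L,
                          lambda = 0.267, K = 0.041) {
    new("ScoringScheme", matrix = matrix, gapOpen = as.integer(gapOpen),
        gapExtend = as.integer(gapExtend), lambda = lambda, K = K)
}

#' Convert a raw alignment score to bits
#'
#' `bits = (lambda * raw - log(K)) / log(2)`.
#'
#' @param raw non-negative raw score(s).
#' @param scheme a [ScoringScheme-class].
#' @return numeric bit-score(s).
#' @export
toBits <- function(raw, scheme = scoringScheme()) {
    if (any(raw < 0)) stop("raw scores must be >= 0")
    (scheme@lambda * raw - log(scheme@K)) / log(2)
}

#' Optimal local alignment under affine gaps
#'
#' Smith-Waterman local alignment of `query` against `ref` with the
#' scheme's substitution matrix and BLAST-convention affine gap costs.
#' The empty alignment (score 0) is admissible, so raw scores are never
#' negative. Exact dynamic programming, no search heuristics.
#'
#' @param query,ref residue strings (or length-1 `AAStringSet` /
#'   `AAString`).
#' @param scheme a [ScoringScheme-class].
#' @return a [LocalHit-class].
#' @export
#' @examples
#' alignLocal("WW", "WW")  # raw = 2 * BLOSUM62[W, W] = 22
alignLocal <- function(query, ref, scheme = scoringScheme()) {
    query <- as.character(query); ref <- as.character(ref)
    if (!nzchar(query) || !nzchar(ref)) stop("sequences must be non-empty")
    ## Biostrings charges gapOpening + gapExtension * L for a length-L gap;
    ## shift gapOpening to reproduce open + extend * (L - 1).
    pa <- Biostrings::pairwiseAlignment(
        pattern = query, subject = ref, type = "local",
        substitutionMatrix = scheme@matrix,
        gapOpening = scheme@gapOpen - scheme@gapExtend,
        gapExtension = scheme@gapExtend)
    raw <- Biostrings::score(pa)
    if (raw <= 0) {
        return(new("LocalHit", raw = 0, bits = toBits(0, scheme),
                   alignedQuery = "", alignedRef = "",
                   queryStart = 0L, queryEnd = 0L,
                   refStart = 0L, refEnd = 0L))
    }
    new("LocalHit", raw = raw, bits = toBits(raw, scheme),
        alignedQuery = as.character(Biostrings::alignedPattern(pa)),
        alignedRef = as.character(Biostrings::alignedSubject(pa)),
        queryStart = Biostrings::start(Biostrings::pattern(pa)),
        queryEnd = Biostrings::end(Biostrings::pattern(pa)),
        refStart = Biostrings::start(Biostrings::subject(pa)),
        refEnd = Biostrings::end(Biostrings::subject(pa)))
}

#' Bit-scores of a sequence set against ClpC and ClpB references
#'
#' The 2D coordinates of the reference-partitioning scatter: each sequence
#' is locally aligned to both references and the raw optima are converted
#' to bits.
#'
#' @param records an [Biostrings::AAStringSet] (or named character vector).
#' @param refC,refB reference residue strings (ClpC-like and ClpB-like).
#' @param scheme a [ScoringScheme-class].
#' @return data.frame with columns `id`, `scoreC`, `scoreB` (bits),
#'   order-preserving.
#' @export
scoreToReferences <- function(records, refC, refB,
                              scheme = scoringScheme()) {
    if (is.character(records)) records <- Biostrings::AAStringSet(records)
    refC <- as.character(refC); refB <- as.character(refB)
    if (!nzchar(refC) || !nzchar(refB)) stop("references must be non-empty")
    n <- length(records)
    sc <- numeric(n); sb <- numeric(n)
    seqs <- as.character(records)
    for (i in seq_len(n)) {
        sc[i] <- alignLocal(seqs[i], refC, scheme)@bits
        sb[i] <- alignLocal(seqs[i], refB, scheme)@bits
    }
    data.frame(id = if (is.null(names(records)))
                        as.character(seq_len(n)) else names(records),
               scoreC = sc, scoreB = sb)
}
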