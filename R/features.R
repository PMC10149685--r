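#' Find Walker A and Walker B motifs
#'
#' Walker A (P-loop) is matched as `G..G.GK[ST]`; Walker B as two
#' hydrophobic residues followed by x-x-Asp-Glu, `[ILVFM][ILVFM]..DE`.
#' Both AAA+ modules of an intact Clp unfoldase carry one of each.
#'
#' @param residues a residue string.
#' @return list with integer vectors `walkerA` and `walkerB` of 1-based
#'   match start positions (empty when absent).
#' @export
#' @examples
#' findWalkerMotifs("AAGESGVGKTAA")$walkerA  # 3
findWalkerMotifs <- function(residues) {
    residues <- as.character(residues)
    hits <- function(pat) {
        m <- gregexpr(pat, residues, perl = TRUE)[[1]]
        if (m[1] == -1L) integer(0) else as.integer(m)
    }
    list(walkerA = hits("G..G.GK[ST]"),
         walkerB = hits("[ILVFM][ILVFM]..DE"))
}

#' Detect an LGF-like peptidase-docking motif
#'
#' The Leu-Gly-Phe motif of the ClpP-docking loop, allowing conservative
#' substitutions: default pattern `[LIVMF]G[FLY]`.
#'
#' @param regionResidues residue string of the candidate loop region.
#' @param pattern regular expression for the motif.
#' @return `TRUE` iff the region contains a match.
#' @export
#' @examples
#' detectLgf("ALGFP")  # TRUE
#' detectLgf("AAAAA")  # FALSE
detectLgf <- function(regionResidues, pattern = "[LIVMF]G[FLY]") {
    grepl(pattern, as.character(regionResidues), perl = TRUE)
}

#' Project reference regions onto a query sequence
#'
#' Aligns the query to the reference ([alignLocal()]) and maps each region
#' of the [RegionMap-class] through the alignment. A region's query span
#' runs between its flanking aligned anchor columns, so insertions inside
#' the region are counted regardless of where the aligner placed the gap.
#' Regions with no aligned reference column (and no covering anchors) are
#' reported absent, not guessed.
#'
#' @param query residue string (or `SequenceRecord`-like object coercible
#'   by `as.character`).
#' @param reference the reference residue string the map lives on.
#' @param map a [RegionMap-class].
#' @param scheme a [ScoringScheme-class].
#' @param minBits minimum alignment bit-score below which the query is
#'   declared unalignable to the reference frame.
#' @return data.frame with one row per region: `region`, `start`, `end`
#'   (query coordinates, `NA` when absent), `present`, `length`.
#' @export
mapRegions <- function(query, reference, map, scheme = scoringScheme(),
                       minBits = 50) {
    stopifnot(is(map, "RegionMap"))
    hit <- alignLocal(query, reference, scheme)
    if (hit@bits < minBits)
        stop("unalignable to reference frame (", round(hit@bits, 1),
             " bits < ", minBits, ")")
    aq <- strsplit(hit@alignedQuery, "")[[1]]
    ar <- strsplit(hit@alignedRef, "")[[1]]
    qpos <- hit@queryStart - 1L + cumsum(aq != "-")
    rpos <- hit@refStart - 1L + cumsum(ar != "-")
    both <- aq != "-" & ar != "-"
    refAligned <- rpos[both]        # strictly increasing
    qAligned <- qpos[both]
    rg <- map@regions
    out <- data.frame(region = names(rg), start = NA_integer_,
                      end = NA_integer_, present = FALSE, length = 0L)
    for (i in seq_along(rg)) {
        s <- start(rg[i]); e <- end(rg[i])
        inR <- which(refAligned >= s & refAligned <= e)
        left <- which(refAligned < s)
        right <- which(refAligned > e)
        qs <- if (length(left)) qAligned[max(left)] + 1L
              else if (length(inR)) min(qAligned[inR]) else NA_integer_
        qe <- if (length(right)) qAligned[min(right)] - 1L
              else if (length(inR)) max(qAligned[inR]) else NA_integer_
        if (!length(inR) && !(length(left) && length(right))) {
            next  # region outside the aligned span: absent
        }
        if (is.na(qs) || is.na(qe) || qe < qs) {
            out$present[i] <- FALSE; out$length[i] <- 0L
            next  # region deleted in the query
        }
        out$start[i] <- qs; out$end[i] <- qe
        out$present[i] <- length(inR) > 0L || qe >= qs
        out$length[i] <- qe - qs + 1L
    }
    out
}

#' Diagnostic feature report for a sequence set
#'
#' For each sequence: Walker A/B motif positions on the full sequence, the
#' M-domain length, presence of an LGF-like motif in the mapped LGF-loop
#' region (searched with a small `lgfPad` margin to absorb alignment
#' slop), and N-terminal-domain mapping.
#'
#' The M-domain length is inferred as the excess of the mapped D1 span
#' over the reference's D1 ATPase core length (`width(D1) -
#' width(M_domain)` on the reference): the AAA+ core is fixed-length
#' across Clp classes while the M-domain absorbs the length variation, so
#' this measure is robust to local-alignment slop around a diverged
#' M-domain (direct projection of the short reference M interval is not,
#' because unrelated residues align as mismatches into flanking core
#' columns). When D1 does not map, the direct M-domain projection is used
#' as fallback.
#'
#' @param records an [Biostrings::AAStringSet] (or named character vector).
#' @param reference reference residue string.
#' @param map a [RegionMap-class] on that reference.
#' @param scheme a [ScoringScheme-class].
#' @param lgfPattern motif pattern, see [detectLgf()].
#' @param lgfPad residues of padding around the mapped LGF region, default 3.
#' @param minBits alignability floor, see [mapRegions()].
#' @return data.frame, one row per sequence: `id`, `nWalkerA`, `nWalkerB`,
#'   `mDomainLength`, `lgfMotifPresent`, `lgfRegionLength`, `ntdPresent`,
#'   `ntdLength`.
#' @export
featureReport <- function(records, reference, map,
                          scheme = scoringScheme(),
                          lgfPattern = "[LIVMF]G[FLY]", lgfPad = 3L,
                          minBits = 50) {
    if (is.character(records)) records <- Biostrings::AAStringSet(records)
    seqs <- as.character(records)
    n <- length(seqs)
    d1Core <- width(map@regions["D1"]) - width(map@regions["M_domain"])
    rep1 <- function(i) {
        s <- seqs[i]
        mr <- mapRegions(s, reference, map, scheme, minBits)
        row <- function(nm) mr[mr$region == nm, ]
        d1 <- row("D1")
        mLen <- if (isTRUE(d1$present) && d1$length > 0L)
            max(0L, d1$length - d1Core) else row("M_domain")$length
        mot <- findWalkerMotifs(s)
        lgf <- row("LGF_loop")
        lgfSeq <- if (isTRUE(lgf$present) && !is.na(lgf$start))
            substr(s, max(1L, lgf$start - lgfPad),
                   min(nchar(s), lgf$end + lgfPad)) else ""
        ntd <- row("NTD")
        data.frame(id = names(seqs)[i] %||% as.character(i),
                   nWalkerA = length(mot$walkerA),
                   nWalkerB = length(mot$walkerB),
                   mDomainLength = mLen,
                   lgfMotifPresent = nzchar(lgfSeq) &&
                       detectLgf(lgfSeq, lgfPattern),
                   lgfRegionLength = lgf$length,
                   ntdPresent = ntd$present,
                   ntdLength = ntd$length)
    }
    do.call(rbind, lapply(seq_len(n), rep1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify sequences from diagnostic features
#'
#' Decision rule over the feature report: a long M-domain (>=
#' `longMDomain`, default 60 aa — between the ~20 aa ClpC-type and ~90 aa
#' ClpB-type M-domains) calls `ClpB`; otherwise an LGF motif plus a
#' reference-like NTD (mapped length within `ntdTol` of the reference NTD
#' length) calls `ClpC`; an LGF motif without the conserved NTD calls
#' `ClpIa`; the remainder — short M-domain, no identifiable LGF-like motif
#' — is `ClpIb`.
#'
#' @param report data.frame from [featureReport()].
#' @param refNtdLength reference NTD length in aa (take
#'   `width(map@regions["NTD"])`).
#' @param longMDomain ClpB threshold on M-domain length, default 60.
#' @param ntdTol relative tolerance for "reference-like" NTD length,
#'   default 0.1.
#' @return character vector of labels `ClpB`/`ClpC`/`ClpIa`/`ClpIb`.
#' @export
classifyByFeatures <- function(report, refNtdLength, longMDomain = 60,
                               ntdTol = 0.1) {
    ntdLike <- report$ntdPresent &
        abs(report$ntdLength - refNtdLength) <= ntdTol * refNtdLength
    ifelse(report$mDomainLength >= longMDomain, "ClpB",
    ifelse(report$lgfMotifPresent & ntdLike, "ClpC",
    ifelse(report$lgfMotifPresent, "ClpIa", "ClpIb")))
}

#' Collapse sub-type labels to top-level groups
#'
#' `ClpIa`/`ClpIb` become `ClpI`; other labels pass through.
#'
#' @param labels character vector of class labels.
#' @return character vector of `ClpB`/`ClpC`/`ClpI`/other.
#' @export
topLevelClass <- function(labels) {
    out <- ifelse(labels %in% c("ClpIa", "ClpIb", "ClpI"), "ClpI", labels)
    names(out) <- names(labels)
    out
}
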