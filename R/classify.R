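#' Rectangular gates in bit-score space
#'
#' A gate is a closed rectangle `[xmin, xmax] x [ymin, ymax]` in
#' (score-to-ClpC, score-to-ClpB) bit-score coordinates, labelled with the
#' class it captures. Gates for distinct labels must not overlap, so every
#' point belongs to at most one gate; boundary points belong to the gate
#' (closed intervals).
#'
#' @param label character vector of class labels.
#' @param xmin,xmax,ymin,ymax numeric gate bounds, recycled to `label`.
#' @return a validated `data.frame` of gates.
#' @export
#' @examples
#' gateSet(label = c("ClpC", "ClpB"),
#'         xmin = c(1800, 500), xmax = c(2400, 1400),
#'         ymin = c(1200, 1800), ymax = c(1700, 2600))
gateSet <- function(label, xmin, xmax, ymin, ymax) {
    g <- data.frame(label = as.character(label), xmin = xmin, xmax = xmax,
                    ymin = ymin, ymax = ymax)
    if (any(g$xmin > g$xmax) || any(g$ymin > g$ymax))
        stop("gate ranges must be non-empty (min <= max)")
    if (nrow(g) > 1L) {
        for (i in seq_len(nrow(g) - 1L)) for (j in (i + 1L):nrow(g)) {
            xo <- g$xmin[i] <= g$xmax[j] && g$xmin[j] <= g$xmax[i]
            yo <- g$ymin[i] <= g$ymax[j] && g$ymin[j] <= g$ymax[i]
            if (xo && yo)
                stop("gates '", g$label[i], "' and '", g$label[j],
                     "' overlap")
        }
    }
    g
}

#' Assign class labels from explicit gates
#'
#' Each point takes the label of the unique gate containing it; points
#' outside every gate are `"unassigned"`. Assignment is per-point, hence
#' permutation-invariant and idempotent.
#'
#' @param scores data.frame with `scoreC`, `scoreB` (from
#'   [scoreToReferences()]).
#' @param gates a [gateSet()].
#' @return character vector of labels, one per row of `scores`.
#' @export
assignByGates <- function(scores, gates) {
    gates <- gateSet(gates$label, gates$xmin, gates$xmax, gates$ymin,
                     gates$ymax)  # re-validate
    lab <- rep("unassigned", nrow(scores))
    for (k in seq_len(nrow(gates))) {
        hit <- scores$scoreC >= gates$xmin[k] & scores$scoreC <= gates$xmax[k] &
               scores$scoreB >= gates$ymin[k] & scores$scoreB <= gates$ymax[k]
        lab[hit] <- gates$label[k]
    }
    lab
}

#' Relative-rule class assignment (automatic gating)
#'
#' Reproducible stand-in for drawing cluster boxes by eye: a sequence whose
#' two reference scores both exceed `floorBits` and agree to within
#' `relTol` relative difference (`|scoreC - scoreB| / max < relTol`) lies on
#' the "approximately equal similarity" diagonal and is called `ClpI`;
#' otherwise the larger score decides `ClpC` vs `ClpB`. Points below the
#' floor on both axes are `"unassigned"`.
#'
#' @param scores data.frame with `scoreC`, `scoreB` in bits.
#' @param floorBits minimum credible similarity, default 50 bits.
#' @param relTol diagonal half-width as a relative difference, default 0.1.
#' @return character vector of labels (`ClpB`, `ClpC`, `ClpI`,
#'   `unassigned`).
#' @export
autoAssignClasses <- function(scores, floorBits = 50, relTol = 0.1) {
    sc <- scores$scoreC; sb <- scores$scoreB
    top <- pmax(sc, sb)
    lab <- ifelse(top < floorBits, "unassigned",
           ifelse(pmin(sc, sb) >= floorBits & abs(sc - sb) / top < relTol,
                  "ClpI", ifelse(sc > sb, "ClpC", "ClpB")))
    lab
}

#' 2D density grid of bit-score pairs
#'
#' Histogram counts over a regular grid spanning the data range, the
#' numeric backing of the scatter-density heatmap.
#'
#' @param scores data.frame with `scoreC` (x) and `scoreB` (y).
#' @param nBinsX,nBinsY bin counts.
#' @return list with `xEdges`, `yEdges` and an integer `counts` matrix
#'   (`nBinsX` rows, `nBinsY` columns); `sum(counts)` equals the number of
#'   points.
#' @export
densityGrid <- function(scores, nBinsX = 25L, nBinsY = 25L) {
    x <- scores$scoreC; y <- scores$scoreB
    if (!length(x)) stop("density grid needs at least one point")
    xe <- seq(min(x), max(x), length.out = nBinsX + 1L)
    ye <- seq(min(y), max(y), length.out = nBinsY + 1L)
    if (xe[1] == xe[nBinsX + 1L]) xe <- xe + c(-0.5, rep(0, nBinsX - 1L), 0.5)
    if (ye[1] == ye[nBinsY + 1L]) ye <- ye + c(-0.5, rep(0, nBinsY - 1L), 0.5)
    xi <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
    yi <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- matrix(0L, nBinsX, nBinsY)
    for (i in seq_along(xi))
        counts[xi[i], yi[i]] <- counts[xi[i], yi[i]] + 1L
    list(xEdges = xe, yEdges = ye, counts = counts)
}

#' Bit-score feature vectors against a reference panel
#'
#' Builds the per-sequence feature vector used for PCA embedding: the
#' bit-scores of each sequence against a panel of references (by default
#' the two class references plus up to 8 additional panel sequences drawn
#' evenly from the input, for 10 features).
#'
#' @param records an [Biostrings::AAStringSet].
#' @param refC,refB class reference sequences.
#' @param panel optional extra panel sequences (character vector); when
#'   `NULL`, up to `nExtra` members of `records` are taken at evenly spaced
#'   positions.
#' @param nExtra panel size when auto-selecting, default 8.
#' @param scheme a [ScoringScheme-class].
#' @return numeric matrix, one row per sequence, one column per panel
#'   member.
#' @export
referencePanelFeatures <- function(records, refC, refB, panel = NULL,
                                   nExtra = 8L, scheme = scoringScheme()) {
    if (is.character(records)) records <- Biostrings::AAStringSet(records)
    seqs <- as.character(records)
    if (is.null(panel)) {
        idx <- unique(round(seq(1L, length(seqs),
                                length.out = min(nExtra, length(seqs)))))
        panel <- seqs[idx]
    }
    refs <- c(refC = as.character(refC), refB = as.character(refB), panel)
    out <- matrix(0, nrow = length(seqs), ncol = length(refs))
    rownames(out) <- names(records)
    colnames(out) <- if (is.null(names(refs)))
        paste0("panel", seq_along(refs)) else names(refs)
    for (j in seq_along(refs)) for (i in seq_along(seqs))
        out[i, j] <- alignLocal(seqs[i], refs[j], scheme)@bits
    out
}

#' PCA embedding of per-sequence score vectors
#'
#' Column-centered principal component analysis of a numeric feature
#' matrix, reported as the projections onto the top `nComponents`
#' eigenvectors together with the fraction of variance each explains.
#'
#' @param featureMatrix numeric matrix, one row per sequence.
#' @param nComponents number of components, default 10 (capped at the
#'   matrix rank bound `min(ncol, nrow - 1)`).
#' @return list with `ids`, `components` (rows = sequences) and
#'   `explainedVariance` (non-increasing fractions in \[0, 1\]).
#' @export
pcaEmbed <- function(featureMatrix, nComponents = 10L) {
    if (nrow(featureMatrix) < 2L) stop("need at least 2 sequences for PCA")
    k <- min(nComponents, ncol(featureMatrix), nrow(featureMatrix) - 1L)
    p <- stats::prcomp(featureMatrix, center = TRUE, scale. = FALSE)
    ev <- p$sdev^2 / sum(p$sdev^2)
    list(ids = rownames(featureMatrix),
         components = p$x[, seq_len(k), drop = FALSE],
         explainedVariance = ev[seq_len(k)])
}

#' Scatter plot of reference bit-scores with optional gates
#'
#' @param scores data.frame with `scoreC`, `scoreB` and optionally `label`.
#' @param gates optional [gateSet()] drawn as rectangles.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotBitScores <- function(scores, gates = NULL, ...) {
    cls <- if ("label" %in% names(scores))
        as.integer(factor(scores$label)) else 1L
    graphics::plot(scores$scoreC, scores$scoreB, col = cls, pch = 16,
                   xlab = "bit-score vs ClpC reference",
                   ylab = "bit-score vs ClpB reference", ...)
    if (!is.null(gates))
        graphics::rect(gates$xmin, gates$ymin, gates$xmax, gates$ymax,
                       border = "grey40", lty = 2)
    invisible(NULL)
}
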