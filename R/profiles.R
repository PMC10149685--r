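#' Per-column amino-acid frequency profiles of an alignment
#'
#' For every alignment column a 20-member frequency array is computed over
#' the unambiguous, non-gap residues of that column and renormalized to sum
#' to 1. Gaps and `X` contribute nothing; an all-gap column carries the
#' defined zero profile with `nEffective = 0`.
#'
#' @param alignment an [Biostrings::AAMultipleAlignment] (or object
#'   accepted by [readMsa()] output).
#' @return a [ProfiledAlignment-class].
#' @export
buildProfiles <- function(alignment) {
    m <- .alnMatrix(alignment)
    if (!length(m)) stop("empty alignment")
    nc <- ncol(m)
    prof <- matrix(0, nrow = 20L, ncol = nc, dimnames = list(AA20, NULL))
    neff <- integer(nc)
    for (j in seq_len(nc)) {
        col <- m[, j]
        col <- col[col %in% AA20]
        neff[j] <- length(col)
        if (length(col)) {
            tb <- table(factor(col, levels = AA20))
            prof[, j] <- as.numeric(tb) / length(col)
        }
    }
    new("ProfiledAlignment", alignment = alignment, profiles = prof,
        nEffective = neff)
}

.alnMatrix <- function(alignment) {
    if (is(alignment, "AAMultipleAlignment"))
        return(as.matrix(alignment))
    if (is.character(alignment))
        return(do.call(rbind, strsplit(alignment, "")))
    as.matrix(alignment)
}

#' BLOSUM-weighted positional score of a residue against a profile
#'
#' `S_x = sum_y B(x, y) * P(y)`: the expected substitution score of residue
#' `x` against a column with frequency profile `P`. Gap or ambiguous
#' residues have no defined score and return `NA` (rendered as background
#' in bitmaps).
#'
#' @param x single residue character.
#' @param profile 20-member frequency vector (a column of
#'   [profiles()]).
#' @param matrix substitution matrix, default BLOSUM62.
#' @return numeric score, or `NA` for gap/ambiguous `x`.
#' @export
#' @examples
#' p <- setNames(numeric(20), ClpTyper:::AA20); p["W"] <- 1
#' positionalScore("W", p)  # BLOSUM62[W, W] = 11
positionalScore <- function(x, profile, matrix = blosum62Matrix()) {
    if (!x %in% AA20) return(NA_real_)
    sum(matrix[x, AA20] * profile[AA20])
}

#' Cross-alignment score of two column profiles
#'
#' `S_cross = sum_{x,y} B(x, y) * P_t(x) * P_b(y)`: the expected
#' substitution score between a column of the top alignment and a column of
#' the bottom alignment, each represented by its frequency profile.
#' Undefined (`NA`) when either column is all-gap.
#'
#' @param pt,pb 20-member frequency vectors.
#' @param matrix substitution matrix, default BLOSUM62.
#' @return numeric score, `NA` when a side has no residues.
#' @export
crossScore <- function(pt, pb, matrix = blosum62Matrix()) {
    if (sum(pt) == 0 || sum(pb) == 0) return(NA_real_)
    as.numeric(pt[AA20] %*% matrix[AA20, AA20] %*% pb[AA20])
}

## All-pairs cross scores between two profile matrices (20 x n each).
.crossScoreMatrix <- function(PT, PB, matrix = blosum62Matrix()) {
    t(PT[AA20, , drop = FALSE]) %*% matrix[AA20, AA20] %*%
        PB[AA20, , drop = FALSE]
}

#' Profile-profile alignment of two multiple sequence alignments
#'
#' Global dynamic programming over alignment columns, scoring a matched
#' column pair by [crossScore()] and charging a linear penalty
#' `gapPenalty` per skipped column. Ties prefer the diagonal, so aligning
#' an alignment with itself returns the identity correspondence. The
#' per-merged-column `s_cross` is reported only where both sides are
#' matched; gap columns carry `NA` ("no data", not "dissimilar").
#'
#' @param top,bottom [ProfiledAlignment-class] objects (or alignments,
#'   which are profiled on the fly).
#' @param gapPenalty linear per-column gap cost; the default 4 is the
#'   magnitude of the most negative BLOSUM62 entry, keeping gap costs on
#'   the score scale.
#' @param matrix substitution matrix.
#' @return a [CrossAlignmentResult-class].
#' @export
profileProfileAlign <- function(top, bottom, gapPenalty = 4,
                                matrix = blosum62Matrix()) {
    if (!is(top, "ProfiledAlignment")) top <- buildProfiles(top)
    if (!is(bottom, "ProfiledAlignment")) bottom <- buildProfiles(bottom)
    S <- .crossScoreMatrix(top@profiles, bottom@profiles, matrix)
    nt <- nrow(S); nb <- ncol(S)
    g <- gapPenalty
    F <- matrix(0, nt + 1L, nb + 1L)
    F[, 1L] <- -g * (0:nt)
    F[1L, ] <- -g * (0:nb)
    for (i in seq_len(nt)) {
        dg <- F[i, 1:nb] + S[i, ]
        prevRow <- F[i, ]
        row <- numeric(nb + 1L)
        row[1L] <- -g * i
        for (j in seq_len(nb)) {
            row[j + 1L] <- max(dg[j], prevRow[j + 1L] - g, row[j] - g)
        }
        F[i + 1L, ] <- row
    }
    ## traceback, diagonal preferred, then up (consume top), then left
    ti <- integer(0); bi <- integer(0)
    i <- nt; j <- nb
    while (i > 0L || j > 0L) {
        if (i > 0L && j > 0L &&
            isTRUE(all.equal(F[i + 1L, j + 1L], F[i, j] + S[i, j]))) {
            ti <- c(i, ti); bi <- c(j, bi); i <- i - 1L; j <- j - 1L
        } else if (i > 0L &&
                   isTRUE(all.equal(F[i + 1L, j + 1L], F[i, j + 1L] - g))) {
            ti <- c(i, ti); bi <- c(NA_integer_, bi); i <- i - 1L
        } else {
            ti <- c(NA_integer_, ti); bi <- c(j, bi); j <- j - 1L
        }
    }
    sc <- rep(NA_real_, length(ti))
    both <- !is.na(ti) & !is.na(bi)
    if (any(both)) {
        sc[both] <- S[cbind(ti[both], bi[both])]
        ## columns where either side is all-gap have no defined s_cross
        zt <- top@nEffective[ti[both]] == 0L
        zb <- bottom@nEffective[bi[both]] == 0L
        sc[both][zt | zb] <- NA_real_
    }
    new("CrossAlignmentResult", topIndex = as.integer(ti),
        bottomIndex = as.integer(bi), sCross = sc,
        score = F[nt + 1L, nb + 1L], top = top, bottom = bottom)
}

#' Per-residue conservation bitmap of an alignment
#'
#' `matrix[i, j]` is the positional score of sequence `i`'s residue at
#' column `j` against that column's profile; gaps and ambiguous residues
#' are `NA`. This is the numeric backing of the color-coded alignment
#' bitmaps.
#'
#' @param profiled a [ProfiledAlignment-class] (or alignment).
#' @param matrix substitution matrix.
#' @return numeric matrix (sequences x columns), row names from the
#'   alignment.
#' @export
renderBitmap <- function(profiled, matrix = blosum62Matrix()) {
    if (!is(profiled, "ProfiledAlignment")) profiled <- buildProfiles(profiled)
    m <- .alnMatrix(profiled@alignment)
    sc <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    colScores <- matrix[AA20, AA20] %*% profiled@profiles  # 20 x ncol
    for (j in seq_len(ncol(m))) {
        res <- m[, j]
        hit <- res %in% AA20
        sc[hit, j] <- colScores[res[hit], j]
    }
    sc
}

#' Plot a conservation bitmap or cross-comparison strip
#'
#' Scores are clipped to the BLOSUM62 extremes \[-4, 11\] and drawn on a
#' diverging scale, blue for strong conservation through red for low;
#' `NA` (gap) cells render as background grey.
#'
#' @param scores matrix from [renderBitmap()], or a numeric vector such as
#'   [crossScores()] (drawn as a 1-row strip).
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plotBitmap <- function(scores, main = "") {
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
    z <- pmax(pmin(scores, 11), -4)
    pal <- grDevices::colorRampPalette(c("red", "white", "blue"))(64)
    graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                    col = pal, zlim = c(-4, 11), axes = FALSE, main = main)
    invisible(NULL)
}
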