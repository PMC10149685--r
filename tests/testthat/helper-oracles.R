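## Independent brute-force oracles, deliberately naive: enumeration over
## monotone chains of matched residue pairs, never dynamic programming.

## Optimal local alignment score by exhaustive enumeration. A local
## alignment (WLOG starting and ending with a match) is a strictly
## monotone chain of matched index pairs; gaps between consecutive pairs
## cost open + ext * (L - 1) separately in each sequence.
oracleLocalAlign <- function(a, b, B, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1]]; Bb <- strsplit(b, "")[[1]]
    na <- length(A); nb <- length(Bb)
    gap <- function(L) if (L <= 0) 0 else open + ext * (L - 1)
    best <- 0  # the empty alignment
    rec <- function(i, j, score) {
        best <<- max(best, score)
        if (i < na && j < nb)
            for (ii in (i + 1):na) for (jj in (j + 1):nb)
                rec(ii, jj, score + B[A[ii], Bb[jj]] -
                        gap(ii - i - 1) - gap(jj - j - 1))
    }
    for (i in seq_len(na)) for (j in seq_len(nb))
        rec(i, j, B[A[i], Bb[j]])
    best
}

## Cross-score matrix between two tiny alignments by direct counting
## (no package profile machinery).
oracleCrossMatrix <- function(top, bottom, B) {
    aa <- rownames(B)
    freq <- function(strings, j) {
        col <- substring(strings, j, j)
        col <- col[col %in% aa]
        if (!length(col)) return(numeric(length(aa)))
        as.numeric(table(factor(col, levels = aa))) / length(col)
    }
    nt <- nchar(top[1]); nb <- nchar(bottom[1])
    S <- matrix(0, nt, nb)
    for (i in seq_len(nt)) for (j in seq_len(nb)) {
        pt <- freq(top, i); pb <- freq(bottom, j)
        s <- 0
        for (x in seq_along(aa)) for (y in seq_along(aa))
            s <- s + B[x, y] * pt[x] * pb[y]
        S[i, j] <- s
    }
    S
}

## Optimal global column-correspondence score (linear gap penalty g) by
## enumeration over monotone chains: a chain of k matches leaves
## (nt - k) + (nb - k) gapped columns.
oracleProfileAlign <- function(S, g) {
    nt <- nrow(S); nb <- ncol(S)
    best <- 0  # empty chain: everything gapped
    rec <- function(i, j, val) {
        best <<- max(best, val)
        if (i < nt && j < nb)
            for (ii in (i + 1):nt) for (jj in (j + 1):nb)
                rec(ii, jj, val + S[ii, jj] + 2 * g)
    }
    for (i in seq_len(nt)) for (j in seq_len(nb))
        rec(i, j, S[i, j] + 2 * g)
    best - g * (nt + nb)
}

## Random residue string over a restricted alphabet (small alphabets make
## gap/mismatch trade-offs and ties more likely).
randSeq <- function(n, alphabet = c("A", "W", "G", "P", "C")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

tinyMsa <- function(...) {
    x <- c(...)
    if (is.null(names(x))) names(x) <- paste0("s", seq_along(x))
    Biostrings::AAMultipleAlignment(x)
}

## Random frequency profile over the 20 standard residues.
randProfile <- function() {
    p <- stats::rexp(20)
    stats::setNames(p / sum(p), rownames(blosum62Matrix()))
}
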