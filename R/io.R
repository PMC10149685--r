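#' @import Biostrings
NULL

AMBIG <- c("B", "Z", "X", "U", "O", "J")

## Normalize raw residue text: upper-case, map ambiguity codes to X.
## Errors (with position) on anything outside 20 AA + ambiguity codes.
.sanitizeResidues <- function(x, id, allowGaps = FALSE) {
    x <- toupper(x)
    x <- chartr(".", "-", x)
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    ok <- c(AA20, AMBIG, if (allowGaps) "-")
    bad <- which(!chars %in% ok)
    if (length(bad)) {
        if (!allowGaps && chars[bad[1]] == "-")
            stop("sequence '", id, "' contains a gap character at position ",
                 bad[1], " (unaligned input must be gap-free)")
        stop("sequence '", id, "' contains non-amino-acid character '",
             chars[bad[1]], "' at position ", bad[1])
    }
    chars[chars %in% AMBIG] <- "X"
    paste(chars, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' Headers are split at the first whitespace: the leading token becomes the
#' sequence id, the remainder its description (kept in `mcols()`). Residues
#' are upper-cased, ambiguity codes (B, Z, U, O, J) are mapped to `X`, and
#' gap characters are rejected: unaligned input must be gap-free.
#'
#' @param path FASTA file.
#' @return an [Biostrings::AAStringSet] named by id, with a `description`
#'   metadata column.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a ClpC-like sequence", "MKVLAAGGKT"), f)
#' readProteinFasta(f)
readProteinFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty FASTA file: ", path)
    hdr <- grep("^>", lines)
    if (!length(hdr) || hdr[1] != 1L) stop("not FASTA-formatted: ", path)
    starts <- hdr + 1L
    ends <- c(hdr[-1] - 1L, length(lines))
    ids <- character(length(hdr)); desc <- character(length(hdr))
    seqs <- character(length(hdr))
    for (i in seq_along(hdr)) {
        h <- sub("^>", "", lines[hdr[i]])
        tok <- regmatches(h, regexpr("^\\S+", h))
        if (!length(tok) || !nzchar(tok)) stop("empty id in header: >", h)
        ids[i] <- tok
        desc[i] <- trimws(substring(h, nchar(tok) + 1L))
        if (starts[i] > ends[i]) stop("record '", tok, "' has no residues")
        raw <- paste(lines[starts[i]:ends[i]], collapse = "")
        raw <- gsub("[[:space:]]", "", raw)
        if (!nzchar(raw)) stop("record '", tok, "' has no residues")
        seqs[i] <- .sanitizeResidues(raw, tok)
    }
    dup <- ids[duplicated(ids)]
    if (length(dup)) stop("duplicate sequence id: ", dup[1])
    out <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    S4Vectors::mcols(out)$description <- desc
    out
}

#' Write protein sequences to FASTA
#'
#' @param x an [Biostrings::AAStringSet] (or named character vector).
#' @param path output file.
#' @param width line-wrap width, default 60.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path, width = 60L) {
    if (is.character(x)) x <- Biostrings::AAStringSet(x)
    desc <- S4Vectors::mcols(x)$description
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(x)) {
        d <- if (!is.null(desc) && nzchar(desc[i])) paste0(" ", desc[i]) else ""
        writeLines(paste0(">", names(x)[i], d), con)
        s <- as.character(x[[i]])
        writeLines(substring(s, seq(1L, nchar(s), width),
                             pmin(seq(1L, nchar(s), width) + width - 1L,
                                  nchar(s))), con)
    }
    invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal dialects; both yield the same alignment
#' object for the same content. Gap characters `-` and `.` are both accepted
#' and normalized to `-`; ragged inputs raise an error naming the offending
#' sequences.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return an [Biostrings::AAMultipleAlignment].
#' @export
readMsa <- function(path, format = c("fasta", "clustal")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "fasta") {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[nzchar(trimws(lines))]
        if (!length(lines)) stop("empty alignment file: ", path)
        hdr <- grep("^>", lines)
        ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
        starts <- hdr + 1L; ends <- c(hdr[-1] - 1L, length(lines))
        seqs <- vapply(seq_along(hdr), function(i)
            gsub("[[:space:]]", "",
                 paste(lines[starts[i]:ends[i]], collapse = "")), "")
    } else {
        aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
        ids <- rownames(aln)
        seqs <- as.character(Biostrings::unmasked(aln))
    }
    if (anyDuplicated(ids)) stop("duplicate sequence id: ", ids[duplicated(ids)][1])
    seqs <- vapply(seq_along(seqs), function(i)
        .sanitizeResidues(seqs[i], ids[i], allowGaps = TRUE), "")
    w <- nchar(seqs)
    if (length(unique(w)) > 1L)
        stop("ragged alignment; offending ids: ",
             paste(ids[w != stats::median(w)], collapse = ", "))
    Biostrings::AAMultipleAlignment(stats::setNames(seqs, ids))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an [Biostrings::AAMultipleAlignment].
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeMsa <- function(aln, path, width = 60L) {
    writeProteinFasta(Biostrings::AAStringSet(as.character(
        Biostrings::unmasked(aln))), path, width = width)
}

#' Read an id-to-taxonomic-order table
#'
#' Two-column TSV (id, order); a header row is recognised when its first
#' field is `id` (case-insensitive). Duplicate consistent rows are
#' deduplicated silently; conflicting duplicates are an error.
#'
#' @param path TSV file.
#' @return named character vector: order keyed by sequence id.
#' @export
readTaxonomy <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
    if (ncol(df) < 2L) stop("taxonomy table must have two columns")
    if (tolower(df[1, 1]) %in% c("id", "sequence_id", "seqid"))
        df <- df[-1, , drop = FALSE]
    df <- unique(df[, 1:2])
    dup <- df[duplicated(df[[1]]), 1]
    if (length(dup))
        stop("conflicting taxonomy for id: ", dup[1])
    stats::setNames(df[[2]], df[[1]])
}

#' Write a taxonomy table
#' @param taxonomy named character vector (order keyed by id).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(taxonomy, path) {
    utils::write.table(data.frame(id = names(taxonomy), order = taxonomy),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}
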