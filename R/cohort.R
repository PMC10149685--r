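CLP_CLASSES <- c("ClpB", "ClpC", "ClpIa", "ClpIb")

## round half up, the convention used for the printed percentage row
.roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

#' Occurrence table of Clp classes across taxonomic orders
#'
#' Counts labeled sequences per (taxonomic order, class) cell. Sequences
#' labeled `unassigned` (or any label outside `classes`) are excluded from
#' the table; their count is attached as the `"excluded"` attribute and
#' reported via `message()`.
#'
#' @param labels named character vector of class labels keyed by id (or a
#'   data.frame with columns `id` and `label`).
#' @param taxonomy named character vector, order per id.
#' @param classes table columns, default `ClpB`, `ClpC`, `ClpIa`, `ClpIb`.
#' @param sortOrders `"name"` (alphabetical) or `"appearance"`.
#' @return integer matrix orders x classes with attribute `excluded`.
#' @export
buildOccurrenceTable <- function(labels, taxonomy, classes = CLP_CLASSES,
                                 sortOrders = c("appearance", "name")) {
    sortOrders <- match.arg(sortOrders)
    if (is.data.frame(labels))
        labels <- stats::setNames(labels$label, labels$id)
    ids <- names(labels)
    miss <- setdiff(ids[labels %in% classes], names(taxonomy))
    if (length(miss)) stop("no taxonomy entry for id: ", miss[1])
    keep <- labels %in% classes
    nExcl <- sum(!keep)
    if (nExcl) message(nExcl, " sequence(s) excluded from occurrence table")
    labels <- labels[keep]; ids <- ids[keep]
    orders <- taxonomy[ids]
    lv <- if (sortOrders == "name") sort(unique(orders)) else unique(orders)
    tab <- table(factor(orders, levels = lv),
                 factor(labels, levels = classes))
    out <- matrix(as.integer(tab), nrow = length(lv),
                  dimnames = list(lv, classes))
    attr(out, "excluded") <- nExcl
    out
}

#' Column totals and percentages of an occurrence table
#'
#' @param tab matrix from [buildOccurrenceTable()].
#' @return list with `totals` (per class), `grandTotal`, and `percent`
#'   (per class, 100 * total / grandTotal, rounded half-up to 1 decimal).
#' @export
occurrenceTotals <- function(tab) {
    totals <- as.integer(colSums(tab))
    names(totals) <- colnames(tab)
    grand <- sum(totals)
    list(totals = totals, grandTotal = grand,
         percent = .roundHalfUp(100 * totals / grand, 1L))
}

#' Format an occurrence table with Total and % Total rows
#'
#' @param tab matrix from [buildOccurrenceTable()].
#' @return data.frame with an `Order` column, one row per order plus
#'   `Total` and `% Total` rows.
#' @export
formatOccurrenceTable <- function(tab) {
    tt <- occurrenceTotals(tab)
    body <- data.frame(Order = rownames(tab), tab, row.names = NULL,
                       check.names = FALSE)
    rbind(body,
          data.frame(Order = "Total", t(tt$totals), check.names = FALSE),
          data.frame(Order = "% Total", t(tt$percent), check.names = FALSE))
}

#' Write an occurrence table as TSV
#' @param tab matrix from [buildOccurrenceTable()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOccurrenceTable <- function(tab, path) {
    utils::write.table(formatOccurrenceTable(tab), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Order-presence statistics
#'
#' How many orders are observed, how many carry both ClpB and ClpC, and
#' how many carry any ClpI (ClpIa + ClpIb > 0).
#'
#' @param tab matrix from [buildOccurrenceTable()].
#' @return list `nOrders`, `nOrdersWithClpBandC`, `nOrdersWithClpI`.
#' @export
orderPresenceStats <- function(tab) {
    if (!nrow(tab))
        return(list(nOrders = 0L, nOrdersWithClpBandC = 0L,
                    nOrdersWithClpI = 0L))
    hasB <- tab[, "ClpB"] > 0L
    hasC <- tab[, "ClpC"] > 0L
    hasI <- (tab[, "ClpIa"] + tab[, "ClpIb"]) > 0L
    list(nOrders = nrow(tab),
         nOrdersWithClpBandC = sum(hasB & hasC),
         nOrdersWithClpI = sum(hasI))
}

#' Per-order bit-score distributions
#'
#' Groups single-reference bit-scores by taxonomic order (and optionally
#' class label) and summarizes each group. Grouping partitions the input:
#' group sizes sum to the number of scored sequences.
#'
#' @param scores data.frame with `id` and a score column (default the
#'   first numeric column).
#' @param taxonomy named character vector, order per id.
#' @param labels optional named character vector refining groups to
#'   order x class.
#' @param scoreColumn name of the score column.
#' @return list with `groups` (named list of raw score vectors) and
#'   `summary` (data.frame: group, n, min, median, max).
#' @export
perOrderScoreDistribution <- function(scores, taxonomy, labels = NULL,
                                      scoreColumn = NULL) {
    if (is.null(scoreColumn)) {
        num <- vapply(scores, is.numeric, logical(1))
        scoreColumn <- names(scores)[num][1]
    }
    grp <- taxonomy[scores$id]
    if (!is.null(labels)) grp <- paste(grp, labels[scores$id], sep = " / ")
    groups <- split(scores[[scoreColumn]], grp)
    summ <- data.frame(group = names(groups),
                       n = lengths(groups),
                       min = vapply(groups, min, numeric(1)),
                       median = vapply(groups, stats::median, numeric(1)),
                       max = vapply(groups, max, numeric(1)),
                       row.names = NULL)
    list(groups = groups, summary = summ)
}

#' Published order-level occurrence counts of Actinomycetota Clp classes
#'
#' The curated per-order occurrence counts of ClpB, ClpC, ClpIa and ClpIb
#' across the 20 Actinomycetota orders observed in the reference cohort,
#' shipped as a plain-text fixture. Useful as a worked example and as the
#' input for the occurrence-table arithmetic.
#'
#' @return integer matrix (20 orders x 4 classes).
#' @export
#' @examples
#' tab <- actinomycetotaClpCounts()
#' occurrenceTotals(tab)$totals
actinomycetotaClpCounts <- function() {
    path <- system.file("extdata", "actinomycetota_clp_order_counts.tsv",
                        package = "ClpTyper", mustWork = TRUE)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
    out <- as.matrix(df[, CLP_CLASSES])
    rownames(out) <- df$Order
    storage.mode(out) <- "integer"
    out
}
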