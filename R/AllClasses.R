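#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' TagCountMatrix: distinct DGE tags by library
#'
#' A \linkS4class{SummarizedExperiment} whose rows are distinct 21-bp NlaIII
#' DGE tag sequences, columns are tag libraries, and whose single
#' \code{"counts"} assay holds raw (or clean) tag counts. The column data
#' carries per-library totals: \code{totalTags} (column sums of the stored
#' matrix) and, after clean-tag filtering, \code{rawTotal} (the pre-filter
#' totals the clean matrix descends from).
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso [cleanTags()], [mapTags()], [libraryStats()]
#' @export
setClass("TagCountMatrix", contains = "SummarizedExperiment")

setValidity("TagCountMatrix", function(object) {
    m <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return("tag sequences (rownames) must be present and unique")
    if (any(m < 0)) return("tag counts must be non-negative")
    if (is.null(colnames(m))) return("library names (colnames) required")
    TRUE
})

#' Construct a TagCountMatrix
#'
#' @param counts integer matrix, rownames = tag sequences, colnames =
#'   library names.
#' @param rawTotal optional numeric vector of pre-filter library totals
#'   (one per library); defaults to the column sums of \code{counts}.
#' @return A [TagCountMatrix-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("CATGAAAAAAAAAAAAAAAAA",
#'                               "CATGCCCCCCCCCCCCCCCCC"), c("YL", "ML")))
#' TagCountMatrix(m)
#' @export
TagCountMatrix <- function(counts, rawTotal = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    cd <- S4Vectors::DataFrame(totalTags = colSums(counts),
                               row.names = colnames(counts))
    if (!is.null(rawTotal)) cd$rawTotal <- as.numeric(rawTotal)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("TagCountMatrix", se)
}

#' @describeIn TagCountMatrix tag-by-library count matrix
#' @param x,object a TagCountMatrix
#' @export
tagCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn TagCountMatrix per-library totals of the stored counts
#' @export
libTotals <- function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$totalTags, colnames(x))
}

#' @describeIn TagCountMatrix library names
#' @export
libNames <- function(x) colnames(x)

setMethod("show", "TagCountMatrix", function(object) {
    cat("TagCountMatrix:", nrow(object), "distinct tags x",
        ncol(object), "libraries\n")
    cat("libraries:", paste(colnames(object), collapse = ", "), "\n")
    cat("library totals:",
        paste(format(libTotals(object), big.mark = ","), collapse = ", "),
        "\n")
})

#' AssemblyEvaluation: sensitivity/accuracy of an assembly
#'
#' Result of [evaluateAssembly()]: the union-coverage sensitivity
#' (Sen = TP/(TP+FN), computed on gold-standard coordinates), accuracy
#' (Acc = TP/(TP+FP), computed on assembly coordinates over assembly
#' sequences with at least one qualifying HSP), and their average.
#'
#' @slot label character, assembly label.
#' @slot sensitivity,accuracy,average numeric proportions in [0, 1]
#'   (accuracy may be NA when no HSP survives filtering).
#' @slot referenceLedger,assemblyLedger data.frames of per-sequence TP/FN
#'   (reference side) and TP/FP (assembly side) base counts.
#' @export
setClass("AssemblyEvaluation",
    representation(label = "character", sensitivity = "numeric",
                   accuracy = "numeric", average = "numeric",
                   referenceLedger = "data.frame",
                   assemblyLedger = "data.frame"))

setValidity("AssemblyEvaluation", function(object) {
    ok <- function(v) length(v) == 1 && (is.na(v) || (v >= 0 && v <= 1))
    if (!ok(object@sensitivity)) return("sensitivity must be in [0,1]")
    if (!ok(object@accuracy)) return("accuracy must be in [0,1] or NA")
    TRUE
})

#' @describeIn AssemblyEvaluation sensitivity Sen = TP/(TP+FN)
#' @param x,object an AssemblyEvaluation
#' @export
sensitivity <- function(x) x@sensitivity

#' @describeIn AssemblyEvaluation accuracy Acc = TP/(TP+FP)
#' @export
accuracy <- function(x) x@accuracy

setMethod("show", "AssemblyEvaluation", function(object) {
    cat("AssemblyEvaluation [", object@label, "]\n", sep = "")
    cat(sprintf("  sensitivity: %.4f  accuracy: %s  average: %s\n",
        object@sensitivity,
        ifelse(is.na(object@accuracy), "NA",
               sprintf("%.4f", object@accuracy)),
        ifelse(is.na(object@average), "NA",
               sprintf("%.4f", object@average))))
})
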