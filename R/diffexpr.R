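## Pairwise differential and specific expression between tag libraries (or
## pooled library groups) and hypergeometric term enrichment of the
## resulting transcript sets.

#' Two-sided conditional exact test for two tag counts
#'
#' Conditional on the transcript's total count `a + b`, the count in
#' library A is hypergeometric under the null of equal relative abundance
#' (the classical exact test on the 2x2 table `[a, nA - a; b, nB - b]`).
#' The two-sided p-value sums the probabilities of all tables (with the
#' margins fixed) no more probable than the observed one.
#'
#' @param a,b tag counts in libraries A and B.
#' @param nA,nB effective library sizes.
#' @return two-sided p-value.
#' @examples
#' exactRatePValue(2, 0, 10, 10)   # 0.4737 (18/38)
#' @export
exactRatePValue <- function(a, b, nA, nB) {
    m <- a + b
    if (m == 0) return(1)
    p <- dhyper(0:m, nA, nB, m)
    pobs <- p[a + 1]
    min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

#' Flag specifically expressed transcripts
#'
#' A transcript is specific to one library when its count is zero in the
#' other and strictly greater than `minTags` in that one.
#'
#' @param a,b integer count vectors for libraries A and B.
#' @param minTags strict threshold (default 11: counts of 12 and up
#'   qualify).
#' @return character vector over `c("A", "B", "none")`.
#' @examples
#' specificExpression(c(0, 0, 3), c(12, 11, 500))  # "B" "none" "none"
#' @export
specificExpression <- function(a, b, minTags = 11L) {
    out <- rep("none", length(a))
    out[b == 0 & a > minTags] <- "A"
    out[a == 0 & b > minTags] <- "B"
    out
}

#' Pairwise differential expression between two libraries
#'
#' Per transcript, computes the two-sided conditional exact test on raw
#' counts against the effective library sizes, the log2 fold change of
#' normalized abundance (counts per effective size; a pseudo-count of 0.5
#' tags replaces zero entries for the fold change only), and the DET and
#' SET flags. A DET requires `p <= pMax` and `|log2FC| >= minLog2fc`;
#' a SET requires a zero count in one library and more than `minTags` in
#' the other.
#'
#' @param expr a `"TagExpression"` object from [quantifyTags()], or a list
#'   with `counts` (matrix) plus `mappedTotals`/`cleanTotals`.
#' @param A,B library names.
#' @param pMax,minLog2fc DET thresholds (defaults 0.05 and 1).
#' @param minTags strict SET threshold (default 11).
#' @param sizes which totals serve as effective library sizes:
#'   `"mapped"` (default) or `"clean"`.
#' @return data.frame: `id`, `countA`, `countB`, `sizeA`, `sizeB`,
#'   `log2FC` (positive = up in A), `p`, `det` (`"A"`, `"B"` or
#'   `"none"`), `set`; the pair is stored in `attr(, "pair")`.
#' @export
pairwiseDE <- function(expr, A, B, pMax = 0.05, minLog2fc = 1,
                       minTags = 11L, sizes = c("mapped", "clean")) {
    sizes <- match.arg(sizes)
    tot <- if (sizes == "mapped") expr$mappedTotals else expr$cleanTotals
    assertThat(all(c(A, B) %in% colnames(expr$counts)) &&
               all(c(A, B) %in% names(tot)),
               paste("library not found:", A, "/", B))
    a <- expr$counts[, A]
    b <- expr$counts[, B]
    nA <- tot[[A]]; nB <- tot[[B]]
    assertThat(nA > 0 && nB > 0, "effective library sizes must be > 0")
    p <- vapply(seq_along(a), function(i)
        exactRatePValue(a[i], b[i], nA, nB), numeric(1))
    aP <- ifelse(a == 0, 0.5, a)
    bP <- ifelse(b == 0, 0.5, b)
    lfc <- log2((aP / nA) / (bP / nB))
    det <- rep("none", length(a))
    det[p <= pMax & lfc >= minLog2fc] <- "A"
    det[p <= pMax & lfc <= -minLog2fc] <- "B"
    res <- data.frame(id = rownames(expr$counts), countA = a, countB = b,
                      sizeA = nA, sizeB = nB, log2FC = lfc, p = p,
                      det = det,
                      set = specificExpression(a, b, minTags),
                      row.names = NULL)
    attr(res, "pair") <- c(A, B)
    res
}

#' Compare pooled library groups
#'
#' Sums counts and effective sizes within each (disjoint) group and runs
#' [pairwiseDE()] on the pooled pair, treating member libraries as
#' replicates. Singleton groups reduce to the plain pairwise comparison.
#'
#' @inheritParams pairwiseDE
#' @param groupA,groupB disjoint non-empty character vectors of library
#'   names.
#' @param nameA,nameB labels for the pooled pair.
#' @param ... passed on to [pairwiseDE()].
#' @export
groupCompare <- function(expr, groupA, groupB, nameA = "A", nameB = "B",
                         ...) {
    assertThat(length(groupA) > 0 && length(groupB) > 0,
               "groups must be non-empty")
    assertThat(length(intersect(groupA, groupB)) == 0,
               "groups must be disjoint")
    pool <- function(g) rowSums(expr$counts[, g, drop = FALSE])
    counts <- cbind(pool(groupA), pool(groupB))
    colnames(counts) <- c(nameA, nameB)
    totals <- function(t) setNames(c(sum(t[groupA]), sum(t[groupB])),
                                   c(nameA, nameB))
    pooled <- list(counts = counts,
                   mappedTotals = totals(expr$mappedTotals),
                   cleanTotals = totals(expr$cleanTotals))
    pairwiseDE(pooled, nameA, nameB, ...)
}

#' Hypergeometric term enrichment with Bonferroni correction
#'
#' For each annotation term represented in the selected set, computes the
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of term members when sampling the selected set from the
#' background, then applies Bonferroni correction over the number of
#' tested terms. A term is enriched when its adjusted p is at most
#' `alpha`.
#'
#' @param selected character vector of selected transcript ids (subset of
#'   `background`).
#' @param termMap data.frame with columns `transcript`, `term`.
#' @param background character vector of background transcript ids.
#' @param alpha enrichment threshold on the adjusted p (default 0.05).
#' @return data.frame sorted by adjusted p: `term`, `M` (background size),
#'   `K` (term background count), `n` (selected size), `k` (term selected
#'   count), `p`, `pAdjusted`, `enriched`.
#' @export
enrichTerms <- function(selected, termMap, background, alpha = 0.05) {
    assertThat(length(background) > 0, "empty background")
    assertThat(all(selected %in% background),
               "selected must be a subset of background")
    tm <- termMap[termMap$transcript %in% background, , drop = FALSE]
    M <- length(background)
    n <- length(selected)
    K <- table(tm$term)
    k <- table(tm$term[tm$transcript %in% selected])
    tested <- names(k)[k >= 1]
    if (length(tested) == 0)
        return(data.frame(term = character(0), M = integer(0),
                          K = integer(0), n = integer(0), k = integer(0),
                          p = numeric(0), pAdjusted = numeric(0),
                          enriched = logical(0)))
    p <- vapply(tested, function(t)
        phyper(k[[t]] - 1, K[[t]], M - K[[t]], n, lower.tail = FALSE),
        numeric(1))
    padj <- p.adjust(p, method = "bonferroni")
    out <- data.frame(term = tested, M = M, K = as.integer(K[tested]),
                      n = n, k = as.integer(k[tested]), p = p,
                      pAdjusted = padj, enriched = padj <= alpha,
                      row.names = NULL)
    out[order(out$pAdjusted, out$p), ]
}

#' All pairwise comparisons of a library panel
#'
#' Runs [pairwiseDE()] for every unordered pair of the given libraries
#' (seven libraries give 21 comparisons) and tallies up-/down-regulated
#' and specifically expressed transcripts per pair.
#'
#' @inheritParams pairwiseDE
#' @param libraries ordered character vector of library names (default:
#'   all columns of `expr$counts`).
#' @param ... passed on to [pairwiseDE()].
#' @return list with `comparisons` (named list of per-pair data.frames)
#'   and `summary` (data.frame: A, B, upInA, upInB, nDET, specificA,
#'   specificB, nSET).
#' @export
comparisonMatrix <- function(expr, libraries = colnames(expr$counts),
                             ...) {
    assertThat(length(libraries) >= 2, "need at least two libraries")
    prs <- utils::combn(libraries, 2)
    comps <- list()
    summary <- NULL
    for (j in seq_len(ncol(prs))) {
        A <- prs[1, j]; B <- prs[2, j]
        r <- pairwiseDE(expr, A, B, ...)
        comps[[paste(A, B, sep = "_vs_")]] <- r
        summary <- rbind(summary, data.frame(
            A = A, B = B,
            upInA = sum(r$det == "A"), upInB = sum(r$det == "B"),
            nDET = sum(r$det != "none"),
            specificA = sum(r$set == "A"), specificB = sum(r$set == "B"),
            nSET = sum(r$set != "none")))
    }
    list(comparisons = comps, summary = summary)
}
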