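## Sequence-set bookkeeping: FASTA/FASTQ I/O, fixed-length 3' trimming,
## polymonomer filtering, length-class statistics and insert-size inference.

#' Read and write sequence sets
#'
#' Thin wrappers around Biostrings I/O so every pipeline stage reads and
#' writes through one surface. FASTQ qualities are Phred+33.
#'
#' @param path file path.
#' @return `readSequences`: a named [Biostrings::DNAStringSet].
#'   `readFastq`: a list with `seqs` (DNAStringSet) and `qual`
#'   (character vector of Phred+33 strings).
#' @export
readSequences <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname readSequences
#' @param seqs a named DNAStringSet.
#' @export
writeSequences <- function(seqs, path) {
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' @rdname readSequences
#' @export
readFastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(seqs = x, qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' @rdname readSequences
#' @param qual character vector of Phred+33 quality strings (one per read).
#' @export
writeFastq <- function(seqs, qual, path) {
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
    invisible(path)
}

#' Generate fixed-length 3'-trimmed read sets
#'
#' Removes a fixed number of bases (and quality values) from the 3' end of
#' every read, once per requested trim, reproducing the multi-length read
#' sets used to tune de novo assemblies (75 bp reads trimmed by 0-25 bp in
#' 5 bp steps give sets of 75, 70, 65, 60, 55 and 50 bp).
#'
#' @param seqs a [Biostrings::DNAStringSet] of reads.
#' @param qual optional character vector of quality strings, trimmed in step.
#' @param trims integer vector of bases to remove from the 3' end.
#' @return named list, one element per trim (named by resulting length),
#'   each a list with `seqs` and `qual`.
#' @examples
#' reads <- Biostrings::DNAStringSet(c(r1 = "ACGTACGTAC"))
#' makeTrimSets(reads, trims = 5)[["5"]]$seqs
#' @export
makeTrimSets <- function(seqs, qual = NULL,
                         trims = c(0L, 5L, 10L, 15L, 20L, 25L)) {
    w <- Biostrings::width(seqs)
    out <- list()
    for (t in trims) {
        bad <- which(t >= w)
        if (length(bad))
            stop("trim ", t, " >= length of read '",
                 names(seqs)[bad[1]], "'", call. = FALSE)
        s <- Biostrings::subseq(seqs, start = 1L, end = w - t)
        q <- if (!is.null(qual)) substr(qual, 1L, nchar(qual) - t) else NULL
        out[[as.character(w[1] - t)]] <- list(seqs = s, qual = q)
    }
    out
}

#' Filter polymonomer sequences
#'
#' Removes records whose entire sequence is a single nucleotide repeated at
#' least `minRun` times (pure homopolymer contigs, artifacts of short-read
#' assembly). The partition is exact: `kept` and `removed` together are
#' the input.
#'
#' @param seqs a named [Biostrings::DNAStringSet].
#' @param minRun minimum homopolymer length for removal (default 10 bp).
#' @return list with `kept` and `removed` DNAStringSets.
#' @examples
#' x <- Biostrings::DNAStringSet(c(a = "AAAAAAAAAA", b = "AAAAAAAAAAC"))
#' filterPolymonomers(x)$removed
#' @export
filterPolymonomers <- function(seqs, minRun = 10L) {
    assertThat(minRun >= 2, "minRun must be >= 2")
    s <- as.character(seqs)
    mono <- grepl("^(A+|C+|G+|T+|N+)$", s) & nchar(s) >= minRun
    list(kept = seqs[!mono], removed = seqs[mono])
}

## N50 by the standard definition: descending lengths, the length at which
## the cumulative sum first reaches half the total
n50 <- function(lens) {
    l <- sort(lens, decreasing = TRUE)
    l[which(cumsum(as.numeric(l)) >= sum(as.numeric(l)) / 2)[1]]
}

#' Length-class statistics of a sequence set
#'
#' For each length threshold, reports the number of sequences at or above
#' it plus N50, mean, total and maximal length of that subset — the columns
#' of a standard assembly-statistics table.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or an integer vector of
#'   lengths).
#' @param thresholds length classes in bp.
#' @return data.frame with one row per threshold: `minLength`, `n`, `n50`,
#'   `meanLength`, `totalLength`, `maxLength` (NA stats for empty classes).
#' @examples
#' lengthStats(c(6L, 5L, 4L, 3L, 2L), thresholds = 0)
#' @export
lengthStats <- function(seqs, thresholds = c(75L, 100L, 500L, 1000L)) {
    lens <- if (is.numeric(seqs)) as.integer(seqs)
            else Biostrings::width(seqs)
    assertThat(length(lens) > 0, "empty sequence set")
    do.call(rbind, lapply(thresholds, function(th) {
        l <- lens[lens >= th]
        if (length(l) == 0)
            return(data.frame(minLength = th, n = 0L, n50 = NA_integer_,
                              meanLength = NA_real_, totalLength = 0,
                              maxLength = NA_integer_))
        data.frame(minLength = th, n = length(l), n50 = n50(l),
                   meanLength = mean(l), totalLength = sum(as.numeric(l)),
                   maxLength = max(l))
    }))
}

#' Infer insert sizes from paired read alignments
#'
#' A proper pair has both mates aligned to the same subject on opposite
#' strands; its insert is the outer span between the mate extremes
#' (1-based closed coordinates: `max(end) - min(start) + 1`). Discordant
#' pairs are counted and excluded.
#'
#' @param pairs data.frame with one row per pair: columns `subject1`,
#'   `start1`, `end1`, `strand1`, `subject2`, `start2`, `end2`, `strand2`.
#' @param window numeric pair `(center, halfWidthProportion)`; the summary
#'   reports the fraction of inserts within `center * (1 +/- proportion)`.
#' @return list with `insertSizes`, `histogram` (table), `median`,
#'   `fractionWithin`, `nProper`, `nDiscordant`.
#' @examples
#' p <- data.frame(subject1 = "t", start1 = 1, end1 = 75, strand1 = "+",
#'                 subject2 = "t", start2 = 126, end2 = 200, strand2 = "-")
#' estimateInsertSizes(p)$insertSizes   # 200
#' @export
estimateInsertSizes <- function(pairs, window = c(200, 0.10)) {
    proper <- pairs$subject1 == pairs$subject2 &
        pairs$strand1 != pairs$strand2
    nd <- sum(!proper)
    p <- pairs[proper, , drop = FALSE]
    if (nrow(p) == 0) {
        warning("no proper pairs; empty insert-size summary")
        return(list(insertSizes = integer(0), histogram = table(integer(0)),
                    median = NA_real_, fractionWithin = NA_real_,
                    nProper = 0L, nDiscordant = nd))
    }
    ins <- pmax(p$end1, p$end2) - pmin(p$start1, p$start2) + 1
    lo <- window[1] * (1 - window[2])
    hi <- window[1] * (1 + window[2])
    list(insertSizes = ins, histogram = table(ins),
         median = stats::median(ins),
         fractionWithin = mean(ins >= lo & ins <= hi),
         nProper = length(ins), nDiscordant = nd)
}
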