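## Sequence characterization: six-frame ORF scanning, codon usage and
## stop-codon statistics, GC by codon position, and MISA-style perfect
## microsatellite (SSR) detection with canonical motif classes.

STOP_CODONS <- c("TAA", "TAG", "TGA")

## amino-acid property classes used for codon-usage summaries
AA_CLASSES <- list(
    nonpolar = c("G", "A", "V", "L", "I", "P", "F", "M", "W"),
    polarUncharged = c("S", "T", "C", "Y", "N", "Q"),
    acidic = c("D", "E"),
    basic = c("K", "R", "H"))

## ORFs of one character string on one strand: per frame, split at stops,
## first ATG after the previous stop up to and including the next stop
orfsOneStrand <- function(s, minNt) {
    n <- nchar(s)
    out <- NULL
    for (f in 0:2) {
        starts <- seq(1 + f, n - 2, by = 3)
        if (length(starts) == 0) next
        codons <- substring(s, starts, starts + 2)
        isStop <- codons %in% STOP_CODONS
        isAtg <- codons == "ATG"
        prevStop <- 0L  # codon index of the last stop seen
        i <- 1L
        while (i <= length(codons)) {
            if (isStop[i]) {
                seg <- which(isAtg[(prevStop + 1L):(i - 1L)])
                if (i > prevStop + 1L && length(seg)) {
                    a <- prevStop + seg[1]
                    nt <- (i - a + 1L) * 3L
                    if (nt >= minNt)
                        out <- rbind(out, c(starts[a], starts[i] + 2L, f, nt))
                }
                prevStop <- i
            }
            i <- i + 1L
        }
    }
    out
}

#' Scan open reading frames in six frames
#'
#' Finds all maximal complete ORFs (ATG through an in-frame stop, no
#' internal stop, stop included) of at least `minNt` nucleotides in all six
#' frames. Coordinates are reported on the forward strand (1-based,
#' closed). Per transcript, the longest ORF is flagged representative
#' (ties: lowest forward start, then '+' strand before '-').
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @param minNt minimum ORF length in nt, stop codon included (default 300).
#' @return data.frame: `transcript`, `strand`, `frame` (0-2 on the scanned
#'   strand), `start`, `end`, `ntLength`, `proteinLength`,
#'   `representative`.
#' @examples
#' scanORFs(Biostrings::DNAStringSet(c(t = "ATGAAATAG")), minNt = 9)
#' @export
scanORFs <- function(seqs, minNt = 300L) {
    out <- list()
    for (i in seq_along(seqs)) {
        s <- as.character(seqs[[i]])
        n <- nchar(s)
        fwd <- orfsOneStrand(s, minNt)
        if (!is.null(fwd))
            out[[length(out) + 1L]] <- data.frame(
                transcript = names(seqs)[i], strand = "+",
                frame = as.integer(fwd[, 3]), start = as.integer(fwd[, 1]),
                end = as.integer(fwd[, 2]), ntLength = as.integer(fwd[, 4]))
        rev_ <- orfsOneStrand(revcompChar(s), minNt)
        if (!is.null(rev_))
            out[[length(out) + 1L]] <- data.frame(
                transcript = names(seqs)[i], strand = "-",
                frame = as.integer(rev_[, 3]),
                start = as.integer(n - rev_[, 2] + 1L),
                end = as.integer(n - rev_[, 1] + 1L),
                ntLength = as.integer(rev_[, 4]))
    }
    if (length(out) == 0)
        return(data.frame(transcript = character(0), strand = character(0),
                          frame = integer(0), start = integer(0),
                          end = integer(0), ntLength = integer(0),
                          proteinLength = integer(0),
                          representative = logical(0)))
    orfs <- do.call(rbind, out)
    orfs$proteinLength <- orfs$ntLength %/% 3L - 1L
    ord <- order(orfs$transcript, -orfs$ntLength,
                 orfs$strand != "+", orfs$start)
    orfs <- orfs[ord, ]
    orfs$representative <- !duplicated(orfs$transcript)
    rownames(orfs) <- NULL
    orfs
}

## coding-strand sequence of each ORF row
orfSequences <- function(orfs, seqs) {
    s <- substr(as.character(seqs[orfs$transcript]), orfs$start, orfs$end)
    minus <- orfs$strand == "-"
    if (any(minus)) s[minus] <- revcompChar(s[minus])
    s
}

#' Codon usage of representative ORFs
#'
#' Tallies codons over representative ORFs. The terminal stop codon is
#' excluded from usage (and from GC accounting) but tallied in the
#' stop-codon distribution. Amino-acid property-class proportions use the
#' standard genetic code with classes non-polar \{G,A,V,L,I,P,F,M,W\},
#' polar-uncharged \{S,T,C,Y,N,Q\}, acidic \{D,E\}, basic \{K,R,H\}.
#'
#' @param orfs data.frame from [scanORFs()].
#' @param seqs the DNAStringSet the ORFs were scanned from.
#' @param representativeOnly tally only representative ORFs (default TRUE).
#' @return list with `counts` (64 codons), `frequency`, `stopDistribution`
#'   (proportions over TAA/TAG/TGA), `aaClassProportions`, `nOrfs`.
#' @export
codonUsage <- function(orfs, seqs, representativeOnly = TRUE) {
    if (representativeOnly) orfs <- orfs[orfs$representative, , drop = FALSE]
    assertThat(nrow(orfs) > 0, "no ORFs to tally")
    assertThat(all(orfs$ntLength %% 3 == 0),
               "ORF length must be divisible by 3")
    cs <- orfSequences(orfs, seqs)
    nc <- nchar(cs)
    stops <- substr(cs, nc - 2L, nc)
    body <- substr(cs, 1L, nc - 3L)
    codons <- unlist(lapply(body, function(b) {
        st <- seq(1L, nchar(b), 3L)
        substring(b, st, st + 2L)
    }), use.names = FALSE)
    counts <- table(factor(codons, levels = ALL_CODONS))
    stopDist <- table(factor(stops, levels = STOP_CODONS))
    gc <- Biostrings::GENETIC_CODE
    aa <- gc[codons]
    classCounts <- vapply(AA_CLASSES, function(cl) sum(aa %in% cl),
                          numeric(1))
    list(counts = counts,
         frequency = counts / sum(counts),
         stopDistribution = stopDist / sum(stopDist),
         aaClassProportions = classCounts / sum(classCounts),
         nOrfs = nrow(orfs))
}

#' GC content by codon position
#'
#' GC1/GC2/GC3 are the G+C proportions at the first, second and third
#' position of counted codons (terminal stop excluded); `gc` is the
#' overall G+C proportion of the counted bases.
#'
#' @inheritParams codonUsage
#' @return list with `gc`, `gc1`, `gc2`, `gc3`, `nCodons`.
#' @export
gcProfile <- function(orfs, seqs, representativeOnly = TRUE) {
    if (representativeOnly) orfs <- orfs[orfs$representative, , drop = FALSE]
    assertThat(nrow(orfs) > 0, "no ORFs to profile")
    cs <- orfSequences(orfs, seqs)
    body <- substr(cs, 1L, nchar(cs) - 3L)
    gcAt <- function(off) {
        b <- unlist(lapply(body, function(x)
            substring(x, seq(off, nchar(x), 3L),
                      seq(off, nchar(x), 3L))), use.names = FALSE)
        mean(b %in% c("G", "C"))
    }
    g1 <- gcAt(1L); g2 <- gcAt(2L); g3 <- gcAt(3L)
    nCodons <- sum(nchar(body)) / 3
    list(gc = (g1 + g2 + g3) / 3, gc1 = g1, gc2 = g2, gc3 = g3,
         nCodons = nCodons)
}

## is a motif primitive (not a repetition of a shorter motif)?
isPrimitive <- function(motif) {
    m <- nchar(motif)
    for (d in seq_len(m - 1)) {
        if (m %% d != 0) next
        if (motif == strrep(substr(motif, 1, d), m / d)) return(FALSE)
    }
    TRUE
}

#' Canonical class of a microsatellite motif
#'
#' Groups a repeat motif with all its rotations and their reverse
#' complements: the class is rendered `"X/Y"` where X is the
#' lexicographically smallest string among the motif's rotations and the
#' rotations of its reverse complement, and Y is the reverse complement of
#' X. The class is invariant under rotation and strand.
#'
#' @param motif a primitive 2-6 nt motif.
#' @return character class label, e.g. `canonicalMotif("GA")` is
#'   `"AG/CT"` and `canonicalMotif("AT")` is `"AT/AT"`.
#' @export
canonicalMotif <- function(motif) {
    m <- nchar(motif)
    assertThat(m >= 2 && m <= 6, "motif must be 2-6 nt")
    assertThat(isPrimitive(motif), "motif must be primitive")
    rot <- function(x) vapply(seq_len(nchar(x)) - 1L, function(k)
        paste0(substr(x, k + 1L, nchar(x)), substr(x, 1L, k)), character(1))
    cands <- c(rot(motif), rot(revcompChar(motif)))
    mn <- min(cands)
    paste0(mn, "/", revcompChar(mn))
}

#' Scan perfect microsatellites (SSRs)
#'
#' Finds maximal perfect tandem repeats of primitive 2-6 nt motifs with
#' total length at least `minTotal` bp (so e.g. dinucleotide repeats need
#' 9 copies, tetranucleotide repeats 5 copies to reach 18 bp with whole
#' repeats). Overlapping calls are resolved to the longest (ties: smaller
#' motif, then leftmost). Two kept SSRs at most `compoundGap` bp apart are
#' flagged compound.
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @param minTotal minimum total repeat length in bp (default 18).
#' @param motifRange integer pair of motif sizes scanned (default 2-6).
#' @param compoundGap maximum gap for the compound flag (default 100 bp).
#' @return data.frame: `transcript`, `start`, `end`, `motif`,
#'   `canonicalClass`, `repeats`, `totalLength`, `compound`,
#'   `compoundPartnerGap` (NA when not compound).
#' @examples
#' s <- Biostrings::DNAStringSet(c(t = paste0(strrep("C", 10),
#'                                            strrep("AG", 9), "TT")))
#' scanSSRs(s)
#' @export
scanSSRs <- function(seqs, minTotal = 18L, motifRange = c(2L, 6L),
                     compoundGap = 100L) {
    res <- list()
    for (i in seq_along(seqs)) {
        s <- as.character(seqs[[i]])
        n <- nchar(s)
        ch <- strsplit(s, "")[[1]]
        cand <- NULL
        for (m in seq(motifRange[1], motifRange[2])) {
            if (n < 2 * m) next
            eq <- ch[(m + 1L):n] == ch[1:(n - m)]
            r <- rle(eq)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            runs <- which(r$values & r$lengths >= m)  # >=2 whole copies
            for (k in runs) {
                j0 <- starts[k]
                regionLen <- r$lengths[k] + m
                reps <- regionLen %/% m
                tot <- reps * m
                if (tot < minTotal) next
                motif <- substr(s, j0, j0 + m - 1L)
                if (!isPrimitive(motif)) next
                cand <- rbind(cand, data.frame(
                    start = j0, end = j0 + tot - 1L, motif = motif,
                    repeats = reps, totalLength = tot))
            }
        }
        if (is.null(cand)) next
        ## resolve overlaps: longest first, then smaller motif, then leftmost
        cand <- cand[order(-cand$totalLength, nchar(cand$motif),
                           cand$start), , drop = FALSE]
        kept <- NULL
        for (k in seq_len(nrow(cand))) {
            iv <- if (is.null(kept)) NULL
                  else as.matrix(kept[, c("start", "end")])
            if (!overlapsAny1(cand$start[k], cand$end[k], iv))
                kept <- rbind(kept, cand[k, ])
        }
        kept <- kept[order(kept$start), , drop = FALSE]
        kept$transcript <- names(seqs)[i]
        res[[length(res) + 1L]] <- kept
    }
    if (length(res) == 0)
        return(data.frame(transcript = character(0), start = integer(0),
                          end = integer(0), motif = character(0),
                          canonicalClass = character(0), repeats = integer(0),
                          totalLength = integer(0), compound = logical(0),
                          compoundPartnerGap = integer(0)))
    ssrs <- do.call(rbind, res)
    ssrs$canonicalClass <- vapply(ssrs$motif, canonicalMotif, character(1),
                                  USE.NAMES = FALSE)
    ## compound flags within transcript
    ssrs <- ssrs[order(ssrs$transcript, ssrs$start), ]
    ssrs$compound <- FALSE
    ssrs$compoundPartnerGap <- NA_integer_
    if (nrow(ssrs) > 1) {
        same <- ssrs$transcript[-1] == ssrs$transcript[-nrow(ssrs)]
        gap <- ssrs$start[-1] - ssrs$end[-nrow(ssrs)] - 1L
        close <- same & gap <= compoundGap
        idx <- which(close)
        ssrs$compound[idx] <- TRUE
        ssrs$compound[idx + 1L] <- TRUE
        ssrs$compoundPartnerGap[idx] <- gap[idx]
        ssrs$compoundPartnerGap[idx + 1L] <- gap[idx]
    }
    ssrs <- ssrs[, c("transcript", "start", "end", "motif",
                     "canonicalClass", "repeats", "totalLength",
                     "compound", "compoundPartnerGap")]
    rownames(ssrs) <- NULL
    ssrs
}

#' Occurrence frequency and mean distance of SSRs
#'
#' The two headline rates of an SSR survey: occurrence frequency
#' (SSRs per hundred transcripts searched) and mean distance between SSRs
#' (total searched bases / number of SSRs).
#'
#' @param nSSRs number of SSRs found.
#' @param nTranscripts number of transcripts searched.
#' @param totalBp total searched length in bp.
#' @return list with `occurrencePct` and `meanDistanceKb`.
#' @examples
#' ssrRates(4249, 196708, 46.83e6)
#' @export
ssrRates <- function(nSSRs, nTranscripts, totalBp) {
    list(occurrencePct = 100 * nSSRs / nTranscripts,
         meanDistanceKb = totalBp / nSSRs / 1000)
}

#' MISA-style summary of an SSR scan
#'
#' @param ssrs data.frame from [scanSSRs()].
#' @param nTranscripts number of transcripts searched.
#' @param totalBp total searched length in bp.
#' @return list with per-motif-length counts, transcripts with SSRs,
#'   transcripts with more than one SSR, compound SSR count, motif-class
#'   frequency table, and the [ssrRates()] rates.
#' @export
summarizeSSRs <- function(ssrs, nTranscripts, totalBp) {
    byLen <- table(factor(nchar(ssrs$motif), levels = 2:6))
    names(byLen) <- c("di", "tri", "tetra", "penta", "hexa")
    perTx <- table(ssrs$transcript)
    classes <- sort(table(ssrs$canonicalClass), decreasing = TRUE)
    c(list(nSSRs = nrow(ssrs), byMotifLength = byLen,
           nTranscriptsWithSSR = length(perTx),
           nTranscriptsMultiSSR = sum(perTx > 1),
           nCompound = sum(ssrs$compound),
           classFrequency = classes / max(1, nrow(ssrs))),
      ssrRates(nrow(ssrs), nTranscripts, totalBp))
}
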