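## Assembly evaluation against a gold-standard reference: built-in ungapped
## seed-and-extend HSP finder, tabular-alignment ingestion, per-sequence
## interval unions, and the union-coverage sensitivity/accuracy metric
## Sen = TP/(TP+FN), Acc = TP/(TP+FP), where overlapping aligned regions are
## counted once.

emptySegs <- function() {
    data.frame(query = character(0), subject = character(0),
               qstart = integer(0), qend = integer(0),
               sstart = integer(0), send = integer(0),
               strand = character(0), identity = numeric(0),
               length = integer(0), evalue = numeric(0),
               bitscore = numeric(0))
}

#' Read 12-column tabular alignments
#'
#' Parses the standard 12-column tabular alignment format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore;
#' 1-based inclusive coordinates). Minus-strand hits (sstart > send) are
#' normalized to forward subject coordinates with `strand = "-"`.
#'
#' @param path path to the tabular file (no header).
#' @return data.frame of alignment segments with columns `query`, `subject`,
#'   `qstart`, `qend`, `sstart`, `send`, `strand`, `identity`, `length`,
#'   `evalue`, `bitscore`.
#' @export
readBlastTabular <- function(path) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
        col.names = c("query", "subject", "identity", "length",
                      "mismatch", "gapopen", "qstart", "qend",
                      "sstart", "send", "evalue", "bitscore"))
    minus <- x$sstart > x$send
    tmp <- x$sstart[minus]
    x$sstart[minus] <- x$send[minus]
    x$send[minus] <- tmp
    x$strand <- ifelse(minus, "-", "+")
    x[, c("query", "subject", "qstart", "qend", "sstart", "send",
          "strand", "identity", "length", "evalue", "bitscore")]
}

## ungapped X-drop extension on raw byte vectors; N never matches
extendSeed <- function(qr, sr, qpos, spos, w, xdrop) {
    rawN <- charToRaw("N")
    qn <- length(qr); sn <- length(sr)
    ## right
    qe <- qpos + w - 1L; se <- spos + w - 1L
    cur <- best <- w; bq <- qe
    i <- qe + 1L; j <- se + 1L
    while (i <= qn && j <= sn && best - cur <= xdrop) {
        cur <- cur + if (qr[i] == sr[j] && qr[i] != rawN) 1L else -2L
        if (cur > best) { best <- cur; bq <- i }
        i <- i + 1L; j <- j + 1L
    }
    qe <- bq; se <- spos + (bq - qpos)
    ## left
    cur <- best; bq2 <- qpos
    i <- qpos - 1L; j <- spos - 1L
    while (i >= 1L && j >= 1L && best - cur <= xdrop) {
        cur <- cur + if (qr[i] == sr[j] && qr[i] != rawN) 1L else -2L
        if (cur > best) { best <- cur; bq2 <- i }
        i <- i - 1L; j <- j - 1L
    }
    qs <- bq2; ss <- spos - (qpos - bq2)
    len <- qe - qs + 1L
    matches <- sum(qr[qs:qe] == sr[ss:se] & qr[qs:qe] != rawN)
    c(qs = qs, qe = qe, ss = ss, se = se, len = len,
      matches = matches, score = best)
}

#' Find high-scoring segment pairs by ungapped seed-and-extend
#'
#' Exact-word seeding on both strands followed by ungapped extension with
#' +1/-2 match/mismatch scoring and X-drop termination. A stand-in for a
#' full local aligner at the scale of synthetic or small real data sets;
#' for large real data, ingest external alignments with
#' [readBlastTabular()]. Minus-strand hits are reported in forward query
#' coordinates with `strand = "-"`. Emitted segments carry identity and
#' length; `evalue` is NA (the built-in finder computes no E-value, so
#' E-value filters pass it vacuously).
#'
#' @param queries,subjects named [Biostrings::DNAStringSet]s.
#' @param word seed word size (bp).
#' @param xdrop ungapped X-drop threshold.
#' @return data.frame of alignment segments (see [readBlastTabular()]).
#' @examples
#' s <- Biostrings::DNAStringSet(c(t1 = "ACGTACGTACGTACGTACGTACGT"))
#' findHSPs(s, s, word = 11)
#' @export
findHSPs <- function(queries, subjects, word = 11L, xdrop = 20L) {
    assertThat(length(queries) > 0 && length(subjects) > 0,
               "queries and subjects must be non-empty")
    w <- as.integer(word)
    schar <- as.character(subjects)
    sraw <- lapply(schar, charToRaw)
    ## global word index over all subjects
    wl <- nchar(schar) - w + 1L
    use <- wl >= 1L
    allWords <- unlist(lapply(which(use), function(j)
        substring(schar[j], 1:wl[j], w:(wl[j] + w - 1L))), use.names = FALSE)
    subjIdx <- rep(which(use), wl[use])
    posIdx <- unlist(lapply(wl[use], seq_len), use.names = FALSE)
    index <- split(seq_along(allWords), allWords)

    out <- list()
    for (i in seq_along(queries)) {
        qfwd <- as.character(queries[[i]])
        qn <- nchar(qfwd)
        if (qn < w) next
        for (strand in c("+", "-")) {
            qs <- if (strand == "+") qfwd else revcompChar(qfwd)
            qr <- charToRaw(qs)
            qwords <- substring(qs, 1:(qn - w + 1L), w:qn)
            hit <- index[qwords]
            nh <- lengths(hit)
            if (sum(nh) == 0) next
            qpos <- rep(seq_along(qwords), nh)
            loc <- unlist(hit, use.names = FALSE)
            sj <- subjIdx[loc]; sp <- posIdx[loc]
            dg <- qpos - sp
            ord <- order(sj, dg, qpos)
            qpos <- qpos[ord]; sj <- sj[ord]; sp <- sp[ord]; dg <- dg[ord]
            lastSj <- -1L; lastDg <- NA_integer_; lastEnd <- -1L
            for (k in seq_along(qpos)) {
                if (sj[k] == lastSj && identical(dg[k], lastDg) &&
                    qpos[k] <= lastEnd) next
                e <- extendSeed(qr, sraw[[sj[k]]], qpos[k], sp[k], w, xdrop)
                lastSj <- sj[k]; lastDg <- dg[k]; lastEnd <- e[["qe"]]
                qs1 <- e[["qs"]]; qe1 <- e[["qe"]]
                if (strand == "-") {
                    tmp <- qs1
                    qs1 <- qn - qe1 + 1L
                    qe1 <- qn - tmp + 1L
                }
                out[[length(out) + 1L]] <- data.frame(
                    query = names(queries)[i], subject = names(subjects)[sj[k]],
                    qstart = qs1, qend = qe1,
                    sstart = e[["ss"]], send = e[["se"]], strand = strand,
                    identity = 100 * e[["matches"]] / e[["len"]],
                    length = e[["len"]], evalue = NA_real_,
                    bitscore = e[["score"]])
            }
        }
    }
    if (length(out) == 0) return(emptySegs())
    segs <- do.call(rbind, out)
    unique(segs)
}

#' Filter HSPs on length, identity and E-value
#'
#' Keeps segments with `length >= minLen`, `identity >= minIdentity` and
#' `evalue < maxEvalue`. Segments without an E-value (the built-in finder)
#' satisfy the E-value criterion vacuously.
#'
#' @param segs alignment segments (data.frame, see [readBlastTabular()]).
#' @param minLen minimum HSP length in bp (default 50).
#' @param minIdentity minimum percent identity (default 90).
#' @param maxEvalue E-value upper bound, exclusive (default 1e-10).
#' @return the surviving segments.
#' @export
filterHSPs <- function(segs, minLen = 50, minIdentity = 90,
                       maxEvalue = 1e-10) {
    keep <- segs$length >= minLen & segs$identity >= minIdentity &
        (is.na(segs$evalue) | segs$evalue < maxEvalue)
    segs[keep, , drop = FALSE]
}

#' Union coverage of alignment segments
#'
#' Merges aligned intervals per sequence so overlapping regions are counted
#' once, then reports covered (TP) and uncovered base totals over the
#' sequence set in `seqLengths` (sequences without segments contribute
#' all-uncovered bases).
#'
#' @param segs alignment segments.
#' @param on which side to measure: `"query"` or `"subject"`.
#' @param seqLengths named integer vector of the counted sequences.
#' @return list with `perSeq` (data.frame: id, length, covered),
#'   `TP` (union bases) and `uncovered` (FN on the reference side, FP on
#'   the assembly side).
#' @examples
#' segs <- data.frame(query = "g", subject = "t", qstart = c(1, 41),
#'                    qend = c(50, 80), sstart = c(1, 41), send = c(50, 80),
#'                    strand = "+", identity = 100, length = 40,
#'                    evalue = NA, bitscore = 40)
#' unionCoverage(segs, "query", c(g = 100))$TP   # 80
#' @export
unionCoverage <- function(segs, on = c("query", "subject"), seqLengths) {
    on <- match.arg(on)
    id <- if (on == "query") segs$query else segs$subject
    s <- if (on == "query") segs$qstart else segs$sstart
    e <- if (on == "query") segs$qend else segs$send
    known <- id %in% names(seqLengths)
    assertThat(all(known), paste("segment references unknown sequence:",
                                 paste(unique(id[!known]), collapse = ", ")))
    tooLong <- e > seqLengths[id] | s < 1
    if (any(tooLong))
        stop("segment exceeds sequence bounds on ", on, ": ",
             id[which(tooLong)[1]], call. = FALSE)
    cov <- setNames(numeric(length(seqLengths)), names(seqLengths))
    if (length(id)) {
        byId <- split(seq_along(id), id)
        for (nm in names(byId)) {
            k <- byId[[nm]]
            r <- IRanges::reduce(IRanges::IRanges(start = s[k], end = e[k]))
            cov[nm] <- sum(IRanges::width(r))
        }
    }
    perSeq <- data.frame(id = names(seqLengths),
                         length = as.integer(seqLengths),
                         covered = as.numeric(cov))
    list(perSeq = perSeq, TP = sum(cov),
         uncovered = sum(as.numeric(seqLengths)) - sum(cov))
}

#' Evaluate an assembly against a gold standard
#'
#' Aligns the gold-standard sequences (queries) against the assembly
#' (subjects), filters HSPs on the given thresholds, and computes the
#' union-coverage metrics: sensitivity Sen = TP/(TP+FN) on gold-standard
#' coordinates over all gold sequences, and accuracy Acc = TP/(TP+FP) on
#' assembly coordinates over assembly sequences with at least one
#' qualifying HSP. TP counts every aligned base once per side.
#'
#' @param gold named DNAStringSet of gold-standard (known full-length)
#'   sequences.
#' @param assembly named DNAStringSet of assembled transcripts.
#' @param segs optional pre-computed alignment segments (e.g. from
#'   [readBlastTabular()]); when NULL, [findHSPs()] is used.
#' @param minLen,minIdentity,maxEvalue HSP filter thresholds.
#' @param word seed word size for the built-in finder.
#' @param label label stored in the result.
#' @return an [AssemblyEvaluation-class] object.
#' @export
evaluateAssembly <- function(gold, assembly, segs = NULL,
                             minLen = 50, minIdentity = 90,
                             maxEvalue = 1e-10, word = 11L,
                             label = "assembly") {
    assertThat(length(gold) > 0 && length(assembly) > 0,
               "gold and assembly must be non-empty")
    if (is.null(segs)) segs <- findHSPs(gold, assembly, word = word)
    segs <- filterHSPs(segs, minLen, minIdentity, maxEvalue)
    goldLens <- setNames(Biostrings::width(gold), names(gold))
    refSide <- unionCoverage(segs, "query", goldLens)
    sen <- refSide$TP / (refSide$TP + refSide$uncovered)
    hitSeqs <- unique(segs$subject)
    if (length(hitSeqs) == 0) {
        warning("no HSPs survive filtering: accuracy undefined")
        acc <- NA_real_
        asmSide <- list(perSeq = data.frame(id = character(0),
                                            length = integer(0),
                                            covered = numeric(0)),
                        TP = 0, uncovered = 0)
    } else {
        asmLens <- setNames(Biostrings::width(assembly),
                            names(assembly))[hitSeqs]
        asmSide <- unionCoverage(segs, "subject", asmLens)
        acc <- asmSide$TP / (asmSide$TP + asmSide$uncovered)
    }
    new("AssemblyEvaluation", label = label, sensitivity = sen,
        accuracy = acc,
        average = if (is.na(acc)) NA_real_ else (sen + acc) / 2,
        referenceLedger = refSide$perSeq, assemblyLedger = asmSide$perSeq)
}

#' Map reads back to transcripts (naive seed-and-verify mapper)
#'
#' Exact-matches a read prefix seed against every transcript (both
#' strands), then verifies the whole read, keeping the best placement with
#' at most `maxMismatch` substitutions. Serves synthetic-scale map-back
#' evaluation; it is not a production aligner.
#'
#' @param reads DNAStringSet of uniform-width reads.
#' @param transcripts named DNAStringSet.
#' @param maxMismatch maximum substitutions allowed (default 2).
#' @param seedLength exact-match prefix length (default 25 bp).
#' @return data.frame: `read`, `transcript`, `start` (forward 1-based),
#'   `strand`, `mismatches` — mapped reads only.
#' @export
mapReads <- function(reads, transcripts, maxMismatch = 2L,
                     seedLength = 25L) {
    RL <- unique(Biostrings::width(reads))
    assertThat(length(RL) == 1, "reads must have uniform width")
    seed <- Biostrings::subseq(reads, start = 1L, end = seedLength)
    pd <- Biostrings::PDict(seed)
    rchar <- as.character(reads)
    tchar <- as.character(transcripts)
    best <- data.frame(read = names(reads),
                       transcript = NA_character_, start = NA_integer_,
                       strand = NA_character_,
                       mismatches = rep(Inf, length(reads)))
    for (j in seq_along(transcripts)) {
        L <- nchar(tchar[j])
        for (strand in c("+", "-")) {
            subj <- if (strand == "+") tchar[j] else revcompChar(tchar[j])
            m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj))
            st <- Biostrings::startIndex(m)
            hits <- which(lengths(st) > 0)
            for (ri in hits) {
                for (p in st[[ri]]) {
                    if (p + RL - 1L > L) next
                    mm <- sum(charToRaw(rchar[ri]) !=
                              charToRaw(substr(subj, p, p + RL - 1L)))
                    if (mm < best$mismatches[ri]) {
                        fs <- if (strand == "+") p else L - (p + RL - 1L) + 1L
                        best[ri, 2:5] <- list(names(transcripts)[j],
                                              as.integer(fs), strand, mm)
                    }
                }
            }
        }
    }
    ok <- is.finite(best$mismatches) & best$mismatches <= maxMismatch
    best <- best[ok, , drop = FALSE]
    best$mismatches <- as.integer(best$mismatches)
    rownames(best) <- NULL
    best
}

#' Map-back coverage summary
#'
#' Given read-to-transcript alignments carrying mismatch counts, reports
#' the fraction of reads mapped (within the mismatch limit), the fraction
#' of transcripts hit, and the mean coverage depth
#' (total aligned bases / total transcript length), plus per-transcript
#' depths.
#'
#' @param hits data.frame as returned by [mapReads()].
#' @param nReads total number of reads attempted.
#' @param transcripts named DNAStringSet the reads were mapped to.
#' @param readLength read length in bp.
#' @param maxMismatch mismatch limit applied to `hits`.
#' @return list with `fractionReadsMapped`, `fractionTranscriptsHit`,
#'   `meanDepth`, `perTranscript` (data.frame id, alignedBases, depth).
#' @export
mapbackCoverage <- function(hits, nReads, transcripts, readLength,
                            maxMismatch = 2L) {
    hits <- hits[hits$mismatches <= maxMismatch, , drop = FALSE]
    lens <- setNames(Biostrings::width(transcripts), names(transcripts))
    ab <- setNames(numeric(length(lens)), names(lens))
    if (nrow(hits)) {
        t <- table(hits$transcript) * readLength
        ab[names(t)] <- as.numeric(t)
    }
    list(fractionReadsMapped = nrow(hits) / nReads,
         fractionTranscriptsHit = sum(ab > 0) / length(lens),
         meanDepth = sum(ab) / sum(as.numeric(lens)),
         perTranscript = data.frame(id = names(lens), length = lens,
                                    alignedBases = ab, depth = ab / lens,
                                    row.names = NULL))
}
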