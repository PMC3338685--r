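## Independent oracles used across the suite. Each is written from the
## definition, not from the implementation it checks.

## per-base bitmap union coverage
bitmapCovered <- function(starts, ends, len) {
    hit <- logical(len)
    for (k in seq_along(starts)) hit[starts[k]:ends[k]] <- TRUE
    sum(hit)
}

## brute-force six-frame ORF scan: every ATG runs to the next in-frame
## stop; maximal = longest ORF per (strand, stop)
oracleOrfsOne <- function(s, minNt) {
    n <- nchar(s)
    res <- NULL
    scan <- function(str, strand) {
        atg <- gregexpr("ATG", str, fixed = TRUE)[[1]]
        if (atg[1] == -1) return()
        for (a in atg) {
            cs <- seq(a, n - 2, by = 3)
            cod <- substring(str, cs, cs + 2)
            st <- which(cod %in% c("TAA", "TAG", "TGA"))
            if (length(st) == 0) next
            e <- cs[st[1]] + 2
            nt <- e - a + 1
            if (nt < minNt) next
            if (strand == "+")
                res <<- rbind(res, data.frame(strand = strand, start = a,
                                              end = e, ntLength = nt))
            else
                res <<- rbind(res, data.frame(strand = strand,
                                              start = n - e + 1,
                                              end = n - a + 1,
                                              ntLength = nt))
        }
    }
    scan(s, "+")
    scan(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))), "-")
    if (is.null(res)) return(res)
    ## maximality: keep the longest ORF sharing a stop
    key <- paste(res$strand, ifelse(res$strand == "+", res$end, res$start))
    keep <- unlist(lapply(split(seq_len(nrow(res)), key), function(k)
        k[which.max(res$ntLength[k])]))
    out <- res[sort(keep), ]
    out <- out[order(out$strand, out$start), ]
    out$start <- as.integer(out$start)
    out$end <- as.integer(out$end)
    out$ntLength <- as.integer(out$ntLength)
    rownames(out) <- NULL
    out
}

## regex brute-force SSR candidates over every primitive 2-6 nt motif,
## resolved with an independently coded greedy (longest, smaller motif,
## leftmost)
oracleSsrsOne <- function(s, minTotal = 18) {
    bases <- c("A", "C", "G", "T")
    prim <- function(m) {
        L <- nchar(m)
        for (d in seq_len(L - 1))
            if (L %% d == 0 &&
                m == paste(rep(substr(m, 1, d), L / d), collapse = ""))
                return(FALSE)
        TRUE
    }
    cand <- NULL
    for (m in 2:6) {
        motifs <- apply(expand.grid(rep(list(bases), m)), 1, paste,
                        collapse = "")
        motifs <- motifs[vapply(motifs, prim, logical(1))]
        for (mo in motifs) {
            g <- gregexpr(paste0("(?:", mo, "){2,}"), s, perl = TRUE)[[1]]
            if (g[1] == -1) next
            tot <- attr(g, "match.length")
            tot <- tot - tot %% m        # whole copies only
            ok <- tot >= minTotal
            if (!any(ok)) next
            cand <- rbind(cand, data.frame(start = as.integer(g)[ok],
                                           motif = mo,
                                           totalLength = tot[ok]))
        }
    }
    if (is.null(cand)) return(NULL)
    cand$totalLength <- as.integer(cand$totalLength)
    cand$end <- cand$start + cand$totalLength - 1L
    cand <- cand[order(-cand$totalLength, nchar(cand$motif), cand$start), ]
    kept <- NULL
    for (k in seq_len(nrow(cand))) {
        if (is.null(kept) ||
            !any(cand$start[k] <= kept$end & cand$end[k] >= kept$start))
            kept <- rbind(kept, cand[k, ])
    }
    kept <- kept[order(kept$start), c("start", "end", "motif",
                                      "totalLength")]
    rownames(kept) <- NULL
    kept
}

## quadratic ungapped local alignment (best-scoring segment, +1/-2),
## Kadane's rule per diagonal, both strands
oracleBestSegment <- function(q, s) {
    best <- list(score = -Inf)
    run <- function(qs, strand) {
        qr <- strsplit(qs, "")[[1]]
        sr <- strsplit(s, "")[[1]]
        nq <- length(qr); ns <- length(sr)
        for (d in (-(ns - 1)):(nq - 1)) {
            i0 <- max(1, 1 + d); j0 <- i0 - d
            len <- min(nq - i0, ns - j0) + 1
            if (len < 1) next
            cur <- 0; curStart <- 0
            for (t in 0:(len - 1)) {
                sc <- if (qr[i0 + t] == sr[j0 + t]) 1 else -2
                if (cur <= 0) { cur <- 0; curStart <- t }
                cur <- cur + sc
                if (cur > best$score)
                    best <<- list(score = cur, qstart = i0 + curStart,
                                  qend = i0 + t, sstart = j0 + curStart,
                                  send = j0 + t, strand = strand, qlen = nq)
            }
        }
    }
    run(q, "+")
    run(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(q))), "-")
    if (best$strand == "-") {
        qs <- best$qstart
        best$qstart <- best$qlen - best$qend + 1
        best$qend <- best$qlen - qs + 1
    }
    best
}

## random DNA string
randSeq <- function(n, gc = 0.5) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
}

## random DNA with no CATG site
randSeqNoCATG <- function(n) {
    s <- randSeq(n)
    while (grepl("CATG", s, fixed = TRUE))
        s <- sub("CATG", "CTTG", s, fixed = TRUE)
    s
}

## minimal TagExpression stand-in for the DE functions
makeExpr <- function(counts, sizes) {
    structure(list(counts = counts,
                   tpm = sweep(counts, 2, sizes, "/") * 1e6,
                   cleanTotals = sizes, mappedTotals = sizes),
              class = "TagExpression")
}
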