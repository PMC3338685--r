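test_that("self-alignment yields one full-length perfect HSP", {
    set.seed(3)
    s <- Biostrings::DNAStringSet(c(t1 = randSeq(500)))
    segs <- findHSPs(s, s)
    plus <- segs[segs$strand == "+", ]
    expect_identical(nrow(plus), 1L)
    expect_identical(c(plus$qstart, plus$qend, plus$sstart, plus$send),
                     c(1L, 500L, 1L, 500L))
    expect_identical(plus$identity, 100)
})

test_that("a reverse-complement query is found on the minus strand", {
    set.seed(4)
    subj <- Biostrings::DNAStringSet(c(s = randSeq(400)))
    q <- Biostrings::reverseComplement(subj)
    names(q) <- "q"
    segs <- findHSPs(q, subj)
    best <- segs[which.max(segs$length), ]
    expect_identical(best$strand, "-")
    expect_identical(c(best$qstart, best$qend, best$sstart, best$send),
                     c(1L, 400L, 1L, 400L))
})

test_that("a planted diverged block is recovered near the DP oracle", {
    set.seed(5)
    for (rep_ in 1:5) {
        block <- randSeq(60)
        ## ~95% identity copy of the block inside unrelated context
        mut <- strsplit(block, "")[[1]]
        pos <- sample(60, 3)
        for (p in pos) mut[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                mut[p]), 1)
        q <- paste0(randSeq(100), block, randSeq(100))
        s <- paste0(randSeq(80), paste(mut, collapse = ""), randSeq(120))
        segs <- findHSPs(Biostrings::DNAStringSet(c(q = q)),
                         Biostrings::DNAStringSet(c(s = s)))
        expect_gt(nrow(segs), 0)
        best <- segs[which.max(segs$bitscore), ]
        oracle <- oracleBestSegment(q, s)
        expect_lte(abs(best$qstart - oracle$qstart), 3)
        expect_lte(abs(best$qend - oracle$qend), 3)
        expect_gte(best$identity, 90)
    }
})

test_that("HSP filtering applies inclusive length/identity and exclusive E-value", {
    segs <- data.frame(query = "q", subject = "s", qstart = 1,
                       qend = c(50, 49, 50, 50), sstart = 1,
                       send = c(50, 49, 50, 50), strand = "+",
                       identity = c(90, 95, 89.9, 90),
                       length = c(50, 49, 50, 50),
                       evalue = c(1e-11, 1e-11, 1e-11, NA),
                       bitscore = 50)
    kept <- filterHSPs(segs)
    expect_identical(nrow(kept), 2L)      # rows 1 and 4
    expect_identical(nrow(filterHSPs(segs[0, ])), 0L)
    segs$evalue[1] <- 1e-10               # not < 1e-10: removed
    expect_identical(nrow(filterHSPs(segs)), 1L)
})

test_that("union coverage counts overlapping regions once", {
    segs <- data.frame(query = "g", subject = "t", qstart = c(1, 41),
                       qend = c(50, 80), sstart = c(1, 41),
                       send = c(50, 80), strand = "+", identity = 100,
                       length = c(50, 40), evalue = NA, bitscore = 1)
    u <- unionCoverage(segs, "query", c(g = 100))
    expect_identical(u$TP, 80)
    expect_identical(u$uncovered, 20)
    ## disjoint additivity
    segs2 <- transform(segs, qstart = c(1, 21), qend = c(10, 30))
    expect_identical(unionCoverage(segs2, "query", c(g = 100))$TP, 20)
    ## no segments
    u0 <- unionCoverage(segs[0, ], "query", c(g = 100))
    expect_identical(u0$TP, 0)
    expect_identical(u0$uncovered, 100)
    ## interval exceeding the sequence errors, naming the sequence
    expect_error(unionCoverage(segs, "query", c(g = 60)), "g")
})

test_that("union coverage equals the per-base bitmap oracle", {
    set.seed(6)
    for (rep_ in 1:200) {
        len <- sample(50:1000, 1)
        k <- sample(1:100, 1)
        st <- sample.int(len, k, replace = TRUE)
        en <- pmin(len, st + sample(0:80, k, replace = TRUE))
        segs <- data.frame(query = "x", subject = "y", qstart = st,
                           qend = en, sstart = st, send = en,
                           strand = "+", identity = 100,
                           length = en - st + 1, evalue = NA, bitscore = 1)
        u <- unionCoverage(segs, "query", c(x = len))
        expect_identical(u$TP, as.numeric(bitmapCovered(st, en, len)))
    }
})

test_that("evaluation metrics follow Sen = TP/(TP+FN), Acc = TP/(TP+FP)", {
    set.seed(7)
    gold <- Biostrings::DNAStringSet(setNames(
        vapply(1:5, function(i) randSeq(300), character(1)),
        paste0("g", 1:5)))
    ## identical assembly: perfect scores
    ev <- evaluateAssembly(gold, setNames(gold, paste0("a", 1:5)))
    expect_equal(sensitivity(ev), 1)
    expect_equal(accuracy(ev), 1)
    expect_equal(ev@average, 1)
    ## worked example from pre-computed segments: gold 100 bp, one 90 bp
    ## transcript aligned over its first 85 bp
    g1 <- Biostrings::DNAStringSet(c(g = randSeq(100)))
    a1 <- Biostrings::DNAStringSet(c(a = randSeq(90)))
    segs <- data.frame(query = "g", subject = "a", qstart = 1, qend = 85,
                       sstart = 1, send = 85, strand = "+", identity = 100,
                       length = 85, evalue = NA, bitscore = 85)
    ev2 <- evaluateAssembly(g1, a1, segs = segs)
    expect_equal(sensitivity(ev2), 0.85)
    expect_equal(accuracy(ev2), 85 / 90)
    expect_equal(ev2@average, (0.85 + 85 / 90) / 2)
    ## no homology: Sen 0, Acc undefined with a warning
    other <- Biostrings::DNAStringSet(c(z = randSeq(300)))
    expect_warning(ev3 <- evaluateAssembly(gold[1], other), "undefined")
    expect_equal(sensitivity(ev3), 0)
    expect_true(is.na(accuracy(ev3)))
})

test_that("metrics are invariant under segment duplication and order", {
    set.seed(8)
    g1 <- Biostrings::DNAStringSet(c(g = randSeq(200)))
    a1 <- Biostrings::DNAStringSet(c(a = randSeq(150)))
    segs <- data.frame(query = "g", subject = "a",
                       qstart = c(1, 60, 100), qend = c(80, 120, 160),
                       sstart = c(1, 60, 90), send = c(80, 120, 150),
                       strand = "+", identity = 100,
                       length = c(80, 61, 61), evalue = NA, bitscore = 1)
    base <- evaluateAssembly(g1, a1, segs = segs)
    dup <- evaluateAssembly(g1, a1, segs = rbind(segs, segs))
    shuf <- evaluateAssembly(g1, a1, segs = segs[c(3, 1, 2), ])
    expect_equal(sensitivity(dup), sensitivity(base))
    expect_equal(accuracy(dup), accuracy(base))
    expect_equal(sensitivity(shuf), sensitivity(base))
    ## adding a segment never decreases sensitivity
    extra <- rbind(segs, transform(segs[1, ], qstart = 170, qend = 200,
                                   sstart = 100, send = 130, length = 31))
    expect_gte(sensitivity(evaluateAssembly(g1, a1, segs = extra)),
               sensitivity(base))
})

test_that("map-back coverage arithmetic and thresholds", {
    tx <- Biostrings::DNAStringSet(c(t = randSeq(500)))
    hits <- data.frame(read = paste0("r", 1:10), transcript = "t",
                       start = seq(1, 451, by = 50), strand = "+",
                       mismatches = 0L)
    mb <- mapbackCoverage(hits, nReads = 10, tx, readLength = 50)
    expect_equal(mb$meanDepth, 1.0)
    expect_equal(mb$fractionReadsMapped, 1.0)
    ## a 3-mismatch alignment is excluded
    hits$mismatches[1] <- 3L
    mb2 <- mapbackCoverage(hits, nReads = 10, tx, readLength = 50)
    expect_equal(mb2$fractionReadsMapped, 0.9)
})

test_that("simulated reads map back to their source transcripts", {
    cfg <- synthConfig(nTranscripts = 15, lengthRange = c(400L, 700L),
                       nReadPairs = 300, seed = 9)
    tx <- simulateTranscriptome(cfg)
    rd <- simulateReads(tx$seqs, cfg)
    hits <- mapReads(rd$forward, tx$seqs)
    ## reads whose bases were untouched by error injection must map home
    src <- setNames(rd$truth$transcript, rd$truth$read)
    win <- substring(as.character(tx$seqs[src[rd$truth$read]]),
                     rd$truth$start, rd$truth$start + 74)
    clean <- rd$truth$read[win == as.character(rd$forward)]
    mappedClean <- hits[hits$read %in% clean, ]
    expect_gte(nrow(mappedClean) / length(clean), 0.99)
    agree <- mappedClean$transcript == src[mappedClean$read]
    expect_gte(mean(agree), 0.99)
})
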