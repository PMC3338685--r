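test_that("generator is deterministic under a fixed seed", {
    cfg <- synthConfig(nTranscripts = 100, nReadPairs = 500, seed = 42)
    a <- simulateTranscriptome(cfg)
    b <- simulateTranscriptome(cfg)
    expect_identical(as.character(a$seqs), as.character(b$seqs))
    expect_identical(a$truth, b$truth)
    ra <- simulateReads(a$seqs, cfg); rb <- simulateReads(b$seqs, cfg)
    expect_identical(as.character(ra$forward), as.character(rb$forward))
    expect_identical(ra$truth, rb$truth)
    ta <- simulateTagLibraries(a$seqs, cfg)
    tb <- simulateTagLibraries(b$seqs, cfg)
    expect_identical(tagCounts(ta$tags), tagCounts(tb$tags))
})

test_that("planted features are recorded and present in the sequence", {
    cfg <- synthConfig(nTranscripts = 40, orfFraction = 0.5,
                       ssrSpec = list(list(motif = "AG", repeats = 9,
                                           rate = 1.0)),
                       seed = 11)
    tx <- simulateTranscriptome(cfg)
    ## every transcript that received an SSR lists one (AG)9 at its offset
    expect_gt(nrow(tx$truth$ssrs), 35)  # rate 1, a few skipped collisions
    for (k in seq_len(nrow(tx$truth$ssrs))) {
        r <- tx$truth$ssrs[k, ]
        expect_identical(substr(as.character(tx$seqs[[r$id]]),
                                r$start, r$end), strrep("AG", 9))
    }
    ## ORFs start with ATG, end with a stop, and have no internal stop
    for (k in seq_len(nrow(tx$truth$orfs))) {
        o <- tx$truth$orfs[k, ]
        cds <- substr(as.character(tx$seqs[[o$id]]), o$start, o$end)
        expect_identical(substr(cds, 1, 3), "ATG")
        codons <- substring(cds, seq(1, nchar(cds), 3),
                            seq(3, nchar(cds), 3))
        expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
        expect_false(any(codons[-length(codons)] %in%
                         c("TAA", "TAG", "TGA")))
    }
    ## taggable transcripts carry a usable CATG site; untaggable none
    untag <- tx$truth$transcripts$untaggable
    for (i in seq_along(tx$seqs)) {
        s <- as.character(tx$seqs[[i]])
        sites <- gregexpr("CATG", s, fixed = TRUE)[[1]]
        if (untag[i]) expect_identical(sites[1], -1L)
        else expect_true(any(sites + 20 <= nchar(s)))
    }
})

test_that("generated GC content concentrates on the target", {
    cfg <- synthConfig(nTranscripts = 1000, lengthRange = c(400L, 800L),
                       gcTarget = 0.44, seed = 5)
    tx <- simulateTranscriptome(cfg)
    gc <- sum(Biostrings::letterFrequency(tx$seqs, "GC")) /
        sum(Biostrings::width(tx$seqs))
    expect_lt(abs(gc - 0.44), 0.02)
})

test_that("insert sizes follow the configured truncated normal law", {
    cfg <- synthConfig(nTranscripts = 60, lengthRange = c(500L, 1500L),
                       nReadPairs = 30000, insertMean = 200, insertSd = 11,
                       seed = 8)
    tx <- simulateTranscriptome(cfg)
    rd <- simulateReads(tx$seqs, cfg)
    frac <- mean(abs(rd$truth$insert - 200) <= 20)
    ## integer-rounded normal: P(round(X) in [180, 220]) with sd 11
    theo <- pnorm(20.5 / 11) - pnorm(-20.5 / 11)
    expect_lt(abs(frac - theo), 0.01)
    expect_gt(frac, 0.93)   # the headline property: >93% within +/-10%
    ## reads lie inside their source transcript
    expect_true(all(rd$truth$start >= 1))
    w <- Biostrings::width(tx$seqs)[match(rd$truth$transcript,
                                          names(tx$seqs))]
    expect_true(all(rd$truth$start + rd$truth$insert - 1 <= w))
})

test_that("median quality crosses Q30 at the configured cycles", {
    cfg <- synthConfig(nTranscripts = 10, nReadPairs = 50,
                       q30Cycle = c(61L, 56L), seed = 2)
    tx <- simulateTranscriptome(cfg)
    rd <- simulateReads(tx$seqs, cfg)
    qf <- utf8ToInt(rd$forwardQual[1]) - 33L
    qr <- utf8ToInt(rd$reverseQual[1]) - 33L
    expect_true(all(qf[1:60] >= 30))
    expect_lt(qf[61], 30)
    expect_true(all(qr[1:55] >= 30))
    expect_lt(qr[56], 30)
})

test_that("empty read request yields a valid empty FASTQ pair", {
    cfg <- synthConfig(nTranscripts = 5, nReadPairs = 0, seed = 1)
    tx <- simulateTranscriptome(cfg)
    rd <- simulateReads(tx$seqs, cfg)
    expect_length(rd$forward, 0)
    f <- tempfile(fileext = ".fastq")
    writeFastq(rd$forward, rd$forwardQual, f)
    expect_length(readFastq(f)$seqs, 0)
})

test_that("tag counts recover the negative-binomial parameters by moments", {
    cfg <- synthConfig(nTranscripts = 2000, lengthRange = c(400L, 600L),
                       nbMean = 50, nbDispersion = 0.2,
                       specificFraction = 0, untaggableFraction = 0,
                       noiseTagRate = 0, seed = 31)
    tx <- simulateTranscriptome(cfg)
    sim <- simulateTagLibraries(tx$seqs, cfg)
    cnt <- sim$truth$trueCounts[, "ML"]
    mHat <- mean(cnt)
    dHat <- (var(cnt) - mHat) / mHat^2
    expect_lt(abs(mHat - 50) / 50, 0.05)
    expect_lt(abs(dHat - 0.2) / 0.2, 0.20)
})

test_that("silencing and noise bookkeeping match the planted truth", {
    cfg <- synthConfig(nTranscripts = 200, specificFraction = 0.1,
                       specificLibraries = "YL", untaggableFraction = 0,
                       noiseTagRate = 0, seed = 13)
    tx <- simulateTranscriptome(cfg)
    sim <- simulateTagLibraries(tx$seqs, cfg)
    sil <- sim$truth$silenced$id
    expect_length(sil, 20)
    expect_true(all(sim$truth$trueCounts[sil, "YL"] == 0))
    ## no noise: every distinct tag traces to a source transcript
    expect_true(all(rownames(tagCounts(sim$tags)) %in%
                    names(sim$truth$tagToTranscript)))
    ## traceability: each tag equals its source transcript's CATG+17 window
    cat <- buildTagCatalog(tx$seqs)
    rep_ <- setNames(cat$representative$tag, cat$representative$transcript)
    tags <- rownames(tagCounts(sim$tags))
    src <- sim$truth$tagToTranscript[tags]
    expect_identical(unname(rep_[src]), tags)
})

test_that("noise tags dominate the cleaned-away mass at the planted rate", {
    cfg <- synthConfig(nTranscripts = 400, noiseTagRate = 0.05,
                       untaggableFraction = 0, seed = 17)
    tx <- simulateTranscriptome(cfg)
    sim <- simulateTagLibraries(tx$seqs, cfg)
    cl <- cleanTags(sim$tags)
    cleanFrac <- sum(tagCounts(cl$tags)) / sum(tagCounts(sim$tags))
    expect_lt(abs(cleanFrac - 0.95), 0.012)  # 2% of noise are doubletons
})

test_that("configuration invariants are enforced", {
    expect_error(synthConfig(nTranscripts = 0), "nTranscripts")
    expect_error(synthConfig(gcTarget = 1.5), "proportions")
    expect_error(synthConfig(lengthRange = c(100L, 200L)),
                 "lengthRange too small")
    expect_error(synthConfig(readLength = 500L,
                             lengthRange = c(400L, 600L)), "readLength")
})
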