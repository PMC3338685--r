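test_that("minimal ORFs and strand symmetry behave by construction", {
    one <- scanORFs(Biostrings::DNAStringSet(c(t = "ATGAAATAG")), minNt = 9)
    expect_identical(nrow(one), 1L)
    expect_identical(one$ntLength, 9L)
    expect_identical(one$proteinLength, 2L)
    expect_identical(one$strand, "+")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString("ATGAAATAG")))
    mirrored <- scanORFs(Biostrings::DNAStringSet(setNames(rc, "t")),
                         minNt = 9)
    expect_identical(nrow(mirrored), 1L)
    expect_identical(mirrored$strand, "-")
    expect_identical(mirrored$ntLength, 9L)
    expect_identical(c(mirrored$start, mirrored$end), c(1L, 9L))
})

test_that("ORF scanner equals the exhaustive oracle on random sequences", {
    set.seed(10)
    for (n in c(3000, 10000)) {
        s <- randSeq(n)
        got <- scanORFs(Biostrings::DNAStringSet(c(x = s)), minNt = 60)
        got <- got[order(got$strand, got$start),
                   c("strand", "start", "end", "ntLength")]
        rownames(got) <- NULL
        oracle <- oracleOrfsOne(s, 60)
        expect_identical(got, oracle)
    }
})

test_that("codon usage tallies codons, stops and amino-acid classes", {
    seqs <- Biostrings::DNAStringSet(c(a = "ATGGCGTAA", b = "ATGAAATGA",
                                       c = "ATGAAATGA"))
    orfs <- scanORFs(seqs, minNt = 9)
    cu <- codonUsage(orfs, seqs)
    expect_identical(as.integer(cu$counts[c("ATG", "GCG", "AAA")]),
                     c(3L, 1L, 2L))
    expect_equal(as.numeric(cu$stopDistribution[c("TAA", "TAG", "TGA")]),
                 c(1 / 3, 0, 2 / 3))
    expect_equal(sum(cu$frequency), 1, tolerance = 1e-12)
    expect_equal(sum(cu$stopDistribution), 1, tolerance = 1e-12)
    expect_equal(sum(cu$aaClassProportions), 1, tolerance = 1e-12)
    ## M and A are non-polar, K is basic
    expect_equal(as.numeric(cu$aaClassProportions["nonpolar"]), 4 / 6)
    expect_equal(as.numeric(cu$aaClassProportions["basic"]), 2 / 6)
})

test_that("uniform planted codons are recovered within Monte Carlo error", {
    set.seed(11)
    sense <- setdiff(as.vector(outer(as.vector(outer(
        c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
        c("A", "C", "G", "T"), paste0)), c("TAA", "TAG", "TGA"))
    nOrf <- 1000; nCod <- 50
    seqs <- vapply(seq_len(nOrf), function(i)
        paste0("ATG", paste(sample(sense, nCod, replace = TRUE),
                            collapse = ""), "TAA"), character(1))
    dss <- Biostrings::DNAStringSet(setNames(seqs, paste0("o", 1:nOrf)))
    orfs <- scanORFs(dss, minNt = (nCod + 2) * 3)
    cu <- codonUsage(orfs, dss)
    ## ATG is drawn like the others but also opens every ORF
    draws <- nOrf * nCod
    pUnif <- 1 / length(sense)
    se <- sqrt(pUnif * (1 - pUnif) / draws)
    freqNoStart <- (as.numeric(cu$counts[sense]) -
                    ifelse(sense == "ATG", nOrf, 0)) / draws
    expect_true(all(abs(freqNoStart - pUnif) <= 3 * se + 1e-12))
})

test_that("GC by codon position matches hand counts", {
    seqs <- Biostrings::DNAStringSet(c(a = "ATGGCGTAA"))
    orfs <- scanORFs(seqs, minNt = 9)
    gp <- gcProfile(orfs, seqs)
    expect_equal(gp$gc1, 1 / 2)
    expect_equal(gp$gc2, 1 / 2)
    expect_equal(gp$gc3, 1)
    expect_equal(gp$gc, 4 / 6)
    ## A/T-only codons apart from the obligatory ATG start
    allAT <- Biostrings::DNAStringSet(c(b = "ATGAATTTTATTTAA"))
    orfs2 <- scanORFs(allAT, minNt = 15)
    gp2 <- gcProfile(orfs2, allAT)
    expect_equal(gp2$gc1, 0)
    expect_equal(gp2$gc2, 0)
    expect_equal(gp2$gc3, 1 / 4)   # the G of the start codon
    expect_equal(gp2$gc, 1 / 12)
})

test_that("planted GC in generated ORFs is recovered", {
    cfg <- synthConfig(nTranscripts = 600, lengthRange = c(400L, 600L),
                       orfFraction = 1, gcTarget = 0.44, seed = 12)
    tx <- simulateTranscriptome(cfg)
    orfs <- scanORFs(tx$seqs, minNt = 300)
    gp <- gcProfile(orfs, tx$seqs)
    expect_lt(abs(gp$gc - 0.44), 0.02)
})

test_that("canonical motif classes match enumeration and invariances", {
    expect_identical(canonicalMotif("GA"), "AG/CT")
    expect_identical(canonicalMotif("AT"), "AT/AT")
    expect_identical(canonicalMotif("CTT"), "AAG/CTT")
    ## strand and rotation invariance on random primitive motifs
    set.seed(13)
    rc <- function(m) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(m)))
    rot1 <- function(m) paste0(substr(m, 2, nchar(m)), substr(m, 1, 1))
    for (rep_ in 1:30) {
        L <- sample(2:6, 1)
        m <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
        prim <- tryCatch({ canonicalMotif(m); TRUE },
                         error = function(e) FALSE)
        if (!prim) next
        cls <- canonicalMotif(m)
        expect_identical(canonicalMotif(rc(m)), cls)
        r1 <- rot1(m)
        if (tryCatch({ canonicalMotif(r1); TRUE },
                     error = function(e) FALSE))
            expect_identical(canonicalMotif(r1), cls)
        ## idempotence on the class representative
        expect_identical(canonicalMotif(sub("/.*", "", cls)), cls)
    }
    expect_error(canonicalMotif("ATAT"), "primitive")
})

test_that("SSR scanner finds planted repeats at the 18 bp threshold", {
    s <- Biostrings::DNAStringSet(c(
        t = paste0(strrep("C", 10), strrep("AG", 9), "TTTT")))
    r <- scanSSRs(s)
    expect_identical(nrow(r), 1L)
    expect_identical(r$motif, "AG")
    expect_identical(r$repeats, 9L)
    expect_identical(r$totalLength, 18L)
    expect_identical(r$start, 11L)
    expect_identical(r$canonicalClass, "AG/CT")
    ## 8 copies (16 bp) is below threshold
    s8 <- Biostrings::DNAStringSet(c(
        t = paste0(strrep("C", 10), strrep("AG", 8), "TTTT")))
    expect_identical(nrow(scanSSRs(s8)), 0L)
    ## tetranucleotide: 4 copies (16 bp) fails, 5 copies (20 bp) passes
    t4 <- Biostrings::DNAStringSet(c(t = paste0("CC", strrep("ATCG", 4),
                                                "TT")))
    t5 <- Biostrings::DNAStringSet(c(t = paste0("CC", strrep("ATCG", 5),
                                                "TT")))
    expect_identical(nrow(scanSSRs(t4)), 0L)
    expect_identical(scanSSRs(t5)$repeats, 5L)
})

test_that("SSR scanner equals the regex oracle on planted random sequences", {
    set.seed(14)
    for (rep_ in 1:3) {
        chunks <- c(replicate(12, randSeq(sample(500:1500, 1))),
                    strrep("AG", sample(9:14, 1)),
                    strrep("AAG", sample(6:10, 1)),
                    strrep("ATCG", 5), strrep("AATGC", 4),
                    strrep("AT", 10), strrep("ACGTAC", 4))
        s <- paste(sample(chunks), collapse = "")
        got <- scanSSRs(Biostrings::DNAStringSet(c(x = s)))
        oracle <- oracleSsrsOne(s)
        expect_identical(got[, c("start", "end", "motif", "totalLength")],
                         oracle)
        ## no two emitted SSRs overlap
        if (nrow(got) > 1) {
            o <- got[order(got$start), ]
            expect_true(all(o$start[-1] > o$end[-nrow(o)]))
        }
    }
})

test_that("compound SSRs are flagged within the gap and summarized", {
    s <- Biostrings::DNAStringSet(c(
        t = paste0(strrep("AG", 9), strrep("C", 20), strrep("AAG", 7),
                   strrep("T", 150), strrep("GA", 10))))
    r <- scanSSRs(s)
    expect_identical(nrow(r), 3L)
    expect_identical(r$compound, c(TRUE, TRUE, FALSE))
    expect_identical(r$compoundPartnerGap[1], 20L)
    sm <- summarizeSSRs(r, nTranscripts = 1, totalBp = Biostrings::width(s))
    expect_identical(sm$nSSRs, 3L)
    expect_identical(as.integer(sm$byMotifLength["di"]), 2L)
    expect_identical(as.integer(sm$byMotifLength["tri"]), 1L)
    expect_identical(sm$nCompound, 2L)
    expect_identical(sm$nTranscriptsMultiSSR, 1L)
})

test_that("SSR survey rates follow their definitions", {
    r <- ssrRates(10, 400, 1e6)
    expect_equal(r$occurrencePct, 2.5)
    expect_equal(r$meanDistanceKb, 100)
})
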