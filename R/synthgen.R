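## Synthetic transcriptome / read / tag-library generator.
##
## The generator emulates the inputs of a de novo transcriptome + DGE study:
## assembled transcripts carrying ORFs, microsatellites and NlaIII (CATG)
## sites; 75 bp paired-end reads with ~200 bp inserts and 3' quality decay;
## and seven tissue tag libraries with gamma-Poisson (marginally negative
## binomial) counts, tissue-specific silencing, and low-copy noise tags.

#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every parameter of the generator. Defaults describe
#' the emulated study design: seven tissue libraries, 75 bp paired-end reads
#' with 200 bp +/- ~10% inserts (sd 11 bp puts ~93% of inserts within 10% of
#' the mean), median Phred quality crossing 30 at cycles 61 (forward) and 56
#' (reverse), and tag counts that are marginally negative binomial.
#'
#' @param nTranscripts number of transcripts to simulate.
#' @param lengthRange integer pair, min/max transcript length (bp).
#' @param orfFraction fraction of transcripts carrying a planted complete ORF.
#' @param orfLength planted ORF length in nt, start and stop codon included
#'   (multiple of 3).
#' @param ssrSpec list of planted microsatellites; each element a list with
#'   \code{motif} (2-6 nt), \code{repeats}, and \code{rate} (fraction of
#'   transcripts receiving one).
#' @param gcTarget target GC proportion of the background sequence.
#' @param nReadPairs number of read pairs to simulate.
#' @param readLength read length in bp.
#' @param insertMean,insertSd normal law of the insert size (bp), truncated
#'   to what the source transcript can host.
#' @param q30Cycle integer pair: first cycle at which the median Phred
#'   quality falls below 30, for forward and reverse mates.
#' @param libraries character vector of tag library names.
#' @param nbMean,nbDispersion marginal negative-binomial mean and dispersion
#'   of per-transcript tag counts (variance = mean + dispersion * mean^2).
#' @param specificFraction fraction of transcripts silenced (zero count) in
#'   \code{specificLibraries}.
#' @param specificLibraries libraries in which the silenced transcripts get
#'   zero counts.
#' @param noiseTagRate fraction of the total tag mass made of random
#'   (unmappable) tags, mostly copy-number 1.
#' @param untaggableFraction fraction of transcripts stripped of CATG sites,
#'   which therefore cannot contribute tags.
#' @param effects optional list of planted expression effects; each element
#'   a list with \code{libraries}, \code{n} (transcripts affected) and
#'   \code{log2fc} (applied multiplicatively in those libraries).
#' @param seed integer seed governing all generator randomness; per-stage
#'   substreams are derived from it deterministically.
#' @return a validated list of class \code{"SynthConfig"}.
#' @examples
#' cfg <- synthConfig(nTranscripts = 50, nReadPairs = 100, seed = 1)
#' @export
synthConfig <- function(nTranscripts = 500,
                        lengthRange = c(400L, 2000L),
                        orfFraction = 0.5,
                        orfLength = 300L,
                        ssrSpec = list(list(motif = "AG", repeats = 9,
                                            rate = 0.1)),
                        gcTarget = 0.44,
                        nReadPairs = 10000L,
                        readLength = 75L,
                        insertMean = 200,
                        insertSd = 11,
                        q30Cycle = c(61L, 56L),
                        libraries = c("YL", "ML", "Stem", "FR",
                                      "ITR", "ETR", "HTR"),
                        nbMean = 50,
                        nbDispersion = 0.2,
                        specificFraction = 0.1,
                        specificLibraries = "YL",
                        noiseTagRate = 0.05,
                        untaggableFraction = 0.02,
                        effects = NULL,
                        seed = 1L) {
    cfg <- list(nTranscripts = as.integer(nTranscripts),
                lengthRange = as.integer(lengthRange),
                orfFraction = orfFraction, orfLength = as.integer(orfLength),
                ssrSpec = ssrSpec, gcTarget = gcTarget,
                nReadPairs = as.integer(nReadPairs),
                readLength = as.integer(readLength),
                insertMean = insertMean, insertSd = insertSd,
                q30Cycle = as.integer(q30Cycle), libraries = libraries,
                nbMean = nbMean, nbDispersion = nbDispersion,
                specificFraction = specificFraction,
                specificLibraries = specificLibraries,
                noiseTagRate = noiseTagRate,
                untaggableFraction = untaggableFraction,
                effects = effects, seed = as.integer(seed))
    assertThat(cfg$nTranscripts > 0, "nTranscripts must be > 0")
    assertThat(length(cfg$lengthRange) == 2 &&
               cfg$lengthRange[1] <= cfg$lengthRange[2] &&
               cfg$lengthRange[1] > 0, "invalid lengthRange")
    props <- c(cfg$orfFraction, cfg$gcTarget, cfg$specificFraction,
               cfg$noiseTagRate, cfg$untaggableFraction)
    assertThat(all(props >= 0 & props <= 1),
               "proportions must lie in [0, 1]")
    assertThat(cfg$orfLength %% 3 == 0 && cfg$orfLength >= 9,
               "orfLength must be a multiple of 3 and >= 9")
    assertThat(cfg$readLength > 0 && cfg$readLength <= cfg$lengthRange[1],
               "readLength must not exceed the minimum transcript length")
    assertThat(cfg$nReadPairs >= 0, "nReadPairs must be >= 0")
    assertThat(cfg$nbMean > 0 && cfg$nbDispersion >= 0,
               "nbMean must be > 0 and nbDispersion >= 0")
    assertThat(all(cfg$specificLibraries %in% cfg$libraries),
               "specificLibraries must be a subset of libraries")
    ssrMax <- 0
    for (s in cfg$ssrSpec) {
        assertThat(nchar(s$motif) >= 2 && nchar(s$motif) <= 6,
                   "ssrSpec motifs must be 2-6 nt")
        ssrMax <- max(ssrMax, nchar(s$motif) * s$repeats)
    }
    ## the shortest transcript must host the largest requested feature
    if (cfg$lengthRange[1] < max(cfg$orfLength, ssrMax) + 2)
        stop("lengthRange too small to host the requested ORF/SSR features",
             call. = FALSE)
    class(cfg) <- "SynthConfig"
    cfg
}

## n codons drawn base-wise at the GC target, stop codons rejected
randSenseCodons <- function(n, gc) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    draw <- function(k) {
        b <- sample(BASES, 3 * k, replace = TRUE, prob = p)
        paste0(b[seq(1, 3 * k, 3)], b[seq(2, 3 * k, 3)], b[seq(3, 3 * k, 3)])
    }
    out <- draw(n)
    repeat {
        bad <- out %in% c("TAA", "TAG", "TGA")
        if (!any(bad)) break
        out[bad] <- draw(sum(bad))
    }
    out
}

## does [s, e] overlap any interval in the two-column matrix iv (1-based)?
overlapsAny1 <- function(s, e, iv) {
    if (is.null(iv) || nrow(iv) == 0) return(FALSE)
    any(s <= iv[, 2] & e >= iv[, 1])
}

#' Simulate a transcriptome with planted ORFs, SSRs and CATG sites
#'
#' Generates \code{nTranscripts} random transcripts at the configured GC
#' content; a configured fraction carry one complete ORF (ATG ... stop, no
#' internal stop), microsatellites are planted per \code{ssrSpec}, a small
#' fraction of transcripts are stripped of CATG sites (and so can never
#' yield a DGE tag), and every other transcript is guaranteed at least one
#' CATG with 17 bases downstream. All planted feature coordinates are
#' recorded in the returned ground truth (1-based, closed).
#'
#' @param config a [synthConfig()] object.
#' @return list with \code{seqs} (named [Biostrings::DNAStringSet]) and
#'   \code{truth} (list of data.frames: \code{transcripts} with ORF span,
#'   strand and untaggable flag; \code{ssrs} with planted motif positions).
#' @examples
#' tx <- simulateTranscriptome(synthConfig(nTranscripts = 20, seed = 42))
#' tx$seqs
#' @export
simulateTranscriptome <- function(config) {
    stopifnot(inherits(config, "SynthConfig"))
    set.seed(stageSeed(config$seed, "transcriptome"))
    n <- config$nTranscripts
    gc <- config$gcTarget
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    lens <- sample(seq(config$lengthRange[1], config$lengthRange[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L)
        paste(sample(BASES, L, replace = TRUE, prob = p), collapse = ""),
        character(1))
    ids <- sprintf("TX%05d", seq_len(n))

    planted <- vector("list", n)  # per-transcript occupied intervals
    ## --- ORFs ---
    nOrf <- round(config$orfFraction * n)
    orfIdx <- if (nOrf > 0) sort(sample.int(n, nOrf)) else integer(0)
    orf <- data.frame(id = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
    for (i in orfIdx) {
        L <- config$orfLength
        s <- sample.int(lens[i] - L + 1, 1)
        body <- paste(randSenseCodons(L / 3 - 2, gc), collapse = "")
        stopc <- sample(c("TAA", "TAG", "TGA"), 1)
        substr(seqs[i], s, s + L - 1) <- paste0("ATG", body, stopc)
        ## break any in-frame ATG immediately upstream so the planted ORF is
        ## maximal in its frame: place a stop just before it when room allows
        if (s >= 4) substr(seqs[i], s - 3, s - 1) <- "TAA"
        planted[[i]] <- rbind(planted[[i]],
                              c(max(1, s - 3), s + L - 1))
        orf <- rbind(orf, data.frame(id = ids[i], start = s,
                                     end = s + L - 1, strand = "+"))
    }
    ## --- SSRs ---
    ssr <- data.frame(id = character(0), motif = character(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0))
    for (spec in config$ssrSpec) {
        tot <- nchar(spec$motif) * spec$repeats
        hit <- which(runif(n) < spec$rate)
        for (i in hit) {
            ok <- FALSE
            for (try in 1:25) {
                s <- sample.int(lens[i] - tot - 1, 1) + 1  # keep 1 bp flanks
                if (!overlapsAny1(s - 1, s + tot, planted[[i]])) {
                    ok <- TRUE; break
                }
            }
            if (!ok) next
            rep_ <- paste(rep(spec$motif, spec$repeats), collapse = "")
            substr(seqs[i], s, s + tot - 1) <- rep_
            ## flanks break the periodicity so exactly `repeats` copies exist
            m1 <- substr(spec$motif, nchar(spec$motif), nchar(spec$motif))
            m2 <- substr(spec$motif, 1, 1)
            substr(seqs[i], s - 1, s - 1) <-
                setdiff(BASES, m1)[1]
            substr(seqs[i], s + tot, s + tot) <- setdiff(BASES, m2)[1]
            planted[[i]] <- rbind(planted[[i]], c(s - 1, s + tot))
            ssr <- rbind(ssr, data.frame(id = ids[i], motif = spec$motif,
                                         repeats = spec$repeats, start = s,
                                         end = s + tot - 1))
        }
    }
    ## --- CATG handling (NlaIII site is palindromic: sense scan suffices) ---
    nUntag <- round(config$untaggableFraction * n)
    untagIdx <- if (nUntag > 0) sample.int(n, nUntag) else integer(0)
    untaggable <- logical(n)
    untaggable[untagIdx] <- TRUE
    for (i in untagIdx) {
        while (grepl("CATG", seqs[i], fixed = TRUE))
            seqs[i] <- sub("CATG", "CTTG", seqs[i], fixed = TRUE)
    }
    for (i in setdiff(seq_len(n), untagIdx)) {
        sites <- gregexpr("CATG", seqs[i], fixed = TRUE)[[1]]
        if (sites[1] != -1 && any(sites + 20 <= lens[i])) next
        for (try in 1:50) {
            s <- sample.int(lens[i] - 24, 1)
            if (!overlapsAny1(s, s + 3, planted[[i]])) {
                substr(seqs[i], s, s + 3) <- "CATG"
                break
            }
        }
    }
    dss <- Biostrings::DNAStringSet(setNames(seqs, ids))
    truth <- list(
        transcripts = data.frame(id = ids, length = lens,
                                 hasORF = seq_len(n) %in% orfIdx,
                                 untaggable = untaggable),
        orfs = orf, ssrs = ssr)
    list(seqs = dss, truth = truth)
}

## per-cycle median Phred target: linear decay crossing 30 at `cross`
cycleQuality <- function(nCycles, cross) {
    q <- 30 + 0.35 * (cross - seq_len(nCycles)) - 0.2
    as.integer(pmax(2, pmin(40, floor(q))))
}

#' Simulate paired-end reads from a transcriptome
#'
#' Draws insert sizes from a normal law (truncated to what each source
#' transcript can host), takes the two ends of each insert as the mates
#' (reverse mate on the opposite strand), assigns per-cycle Phred qualities
#' that decay linearly so the median crosses Q30 at the configured cycle,
#' and injects substitution errors at the per-cycle Phred-implied rate.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param config a [synthConfig()] object.
#' @return list with \code{forward}/\code{reverse} (DNAStringSet),
#'   \code{forwardQual}/\code{reverseQual} (Phred+33 quality strings),
#'   \code{truth} (data.frame: read id, source transcript, insert size,
#'   start) and \code{skipped} (pairs dropped because the drawn transcript
#'   was shorter than one read).
#' @examples
#' cfg <- synthConfig(nTranscripts = 10, nReadPairs = 50, seed = 3)
#' tx <- simulateTranscriptome(cfg)
#' rd <- simulateReads(tx$seqs, cfg)
#' @export
simulateReads <- function(transcripts, config) {
    stopifnot(inherits(config, "SynthConfig"))
    assertThat(length(transcripts) > 0, "transcripts must be non-empty")
    set.seed(stageSeed(config$seed, "reads"))
    n <- config$nReadPairs
    RL <- config$readLength
    lens <- Biostrings::width(transcripts)
    txt <- as.character(transcripts)
    if (n == 0) {
        empty <- Biostrings::DNAStringSet(character(0))
        return(list(forward = empty, reverse = empty,
                    forwardQual = character(0), reverseQual = character(0),
                    truth = data.frame(read = character(0),
                                       transcript = character(0),
                                       insert = integer(0),
                                       start = integer(0)),
                    skipped = 0L))
    }
    idx <- sample.int(length(transcripts), n, replace = TRUE,
                      prob = lens / sum(lens))
    skip <- lens[idx] < RL
    idx <- idx[!skip]
    m <- length(idx)
    ins <- as.integer(round(rnorm(m, config$insertMean, config$insertSd)))
    ins <- pmax(RL, pmin(ins, lens[idx]))           # truncate to bounds
    start <- vapply(lens[idx] - ins, function(r) sample.int(r + 1, 1),
                    integer(1))
    fwd <- substring(txt[idx], start, start + RL - 1)
    rev_ <- revcompChar(substring(txt[idx], start + ins - RL,
                                  start + ins - 1))
    qf <- cycleQuality(RL, config$q30Cycle[1])
    qr <- cycleQuality(RL, config$q30Cycle[2])
    fwd <- injectErrors(fwd, qf)
    rev_ <- injectErrors(rev_, qr)
    ids <- sprintf("read%06d", seq_len(m))
    list(forward = Biostrings::DNAStringSet(setNames(fwd, ids)),
         reverse = Biostrings::DNAStringSet(setNames(rev_, ids)),
         forwardQual = rep(rawToChar(as.raw(qf + 33L)), m),
         reverseQual = rep(rawToChar(as.raw(qr + 33L)), m),
         truth = data.frame(read = ids,
                            transcript = names(transcripts)[idx],
                            insert = ins, start = start),
         skipped = sum(skip))
}

## substitution errors at the Phred-implied per-cycle rate
injectErrors <- function(reads, q) {
    n <- length(reads)
    if (n == 0) return(reads)
    for (c_ in seq_along(q)) {
        e <- 10^(-q[c_] / 10)
        k <- stats::rbinom(1, n, e)
        if (k == 0) next
        rows <- sample.int(n, k)
        old <- substr(reads[rows], c_, c_)
        new <- vapply(old, function(b) sample(setdiff(BASES, b), 1),
                      character(1), USE.NAMES = FALSE)
        substr(reads[rows], c_, c_) <- new
    }
    reads
}

#' Simulate seven-tissue DGE tag libraries
#'
#' Each taggable transcript contributes its representative NlaIII tag (the
#' 3'-most sense-strand CATG + 17 nt window, see [buildTagCatalog()]). True
#' expression per transcript is one gamma draw shared across libraries with
#' Poisson library counts, so counts are marginally negative binomial
#' (mean \code{nbMean}, dispersion \code{nbDispersion}) while null
#' transcripts remain exchangeable between libraries. A configured fraction
#' of transcripts is silenced in the designated libraries; planted
#' expression \code{effects} multiply the Poisson mean; random low-copy
#' noise tags contribute \code{noiseTagRate} of the tag mass.
#'
#' @inheritParams simulateReads
#' @return list with \code{tags} (a [TagCountMatrix-class]) and
#'   \code{truth} (tag-to-transcript map, per-library true means, silenced
#'   and effect transcripts, untaggable transcripts, noise tags).
#' @examples
#' cfg <- synthConfig(nTranscripts = 30, seed = 9)
#' tx <- simulateTranscriptome(cfg)
#' sim <- simulateTagLibraries(tx$seqs, cfg)
#' sim$tags
#' @export
simulateTagLibraries <- function(transcripts, config) {
    stopifnot(inherits(config, "SynthConfig"))
    set.seed(stageSeed(config$seed, "tags"))
    catalog <- buildTagCatalog(transcripts)
    rep_ <- catalog$representative
    taggable <- !is.na(rep_$tag)
    ids <- rep_$transcript
    n <- length(ids)
    libs <- config$libraries
    L <- length(libs)

    shape <- if (config$nbDispersion > 0) 1 / config$nbDispersion else Inf
    lambda <- if (is.finite(shape))
        rgamma(n, shape = shape, rate = shape / config$nbMean)
    else rep(config$nbMean, n)
    mu <- matrix(lambda, n, L, dimnames = list(ids, libs))

    nSpec <- round(config$specificFraction * n)
    specIdx <- if (nSpec > 0) sort(sample.int(n, nSpec)) else integer(0)
    mu[specIdx, config$specificLibraries] <- 0

    effectTruth <- data.frame(id = character(0), libraries = character(0),
                              log2fc = numeric(0))
    pool <- setdiff(seq_len(n), specIdx)
    for (ef in config$effects) {
        take <- sample(pool, min(ef$n, length(pool)))
        pool <- setdiff(pool, take)
        mu[take, ef$libraries] <- mu[take, ef$libraries] * 2^ef$log2fc
        effectTruth <- rbind(effectTruth,
            data.frame(id = ids[take],
                       libraries = paste(ef$libraries, collapse = ","),
                       log2fc = ef$log2fc))
    }

    counts <- matrix(rpois(n * L, as.vector(mu)), n, L,
                     dimnames = list(ids, libs))
    counts[!taggable, ] <- 0   # no CATG site -> no tag ever observed

    ## collapse to tags (distinct transcripts can, rarely, share a tag)
    tagOf <- rep_$tag
    keep <- taggable & rowSums(counts) > 0
    tagCounts <- rowsum(counts[keep, , drop = FALSE], tagOf[keep])

    ## noise tags: random CATG+17-mers, mostly copy-number 1
    trueMass <- sum(tagCounts)
    r <- config$noiseTagRate
    noise <- NULL
    if (r > 0 && trueMass > 0) {
        mass <- r / (1 - r) * trueMass
        cnt <- integer(0)
        while (sum(cnt) < mass)
            cnt <- c(cnt, ifelse(runif(ceiling(mass)) < 0.98, 1L, 2L))
        cnt <- cnt[cumsum(cnt) <= mass + 1]
        k <- length(cnt)
        mk <- function(j) paste0("CATG", vapply(seq_len(j), function(i)
            paste(sample(BASES, 17, replace = TRUE), collapse = ""),
            character(1)))
        tg <- mk(k)
        while (any(dup <- duplicated(tg) | tg %in% rownames(tagCounts)))
            tg[dup] <- mk(sum(dup))
        nm <- matrix(0L, k, L, dimnames = list(tg, libs))
        nm[cbind(seq_len(k), sample.int(L, k, replace = TRUE))] <- cnt
        noise <- nm
    }
    full <- rbind(tagCounts, noise)
    truth <- list(
        tagToTranscript = setNames(rep_$transcript[taggable],
                                   rep_$tag[taggable]),
        mu = mu,
        trueCounts = counts,
        silenced = data.frame(
            id = ids[specIdx],
            libraries = rep(paste(config$specificLibraries,
                                  collapse = ","), length(specIdx))),
        effects = effectTruth,
        untaggable = ids[!taggable],
        noiseTags = rownames(noise))
    list(tags = TagCountMatrix(full), truth = truth)
}
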