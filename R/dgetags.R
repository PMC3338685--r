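## Tag-level digital gene expression: in-silico NlaIII/MmeI 21-bp tag
## catalogs, raw-to-clean tag filtering, mismatch-tolerant tag-to-transcript
## mapping, TPM normalization, and the full library-statistics ledger.

#' Build the NlaIII/MmeI tag catalog of a transcript set
#'
#' NlaIII cuts at CATG (a palindromic site) and MmeI releases the 17 bases
#' downstream, so every CATG site with at least 17 downstream bases yields
#' a 21-bp tag (CATG + 17 nt) — on the sense strand reading rightward from
#' the site, and on the antisense strand reading leftward (i.e. the reverse
#' complement of the 17 bases upstream plus the site). The representative
#' tag of a transcript, the one an oriented mRNA actually yields, is the
#' 3'-most sense-strand tag. Transcripts with no qualifying site are listed
#' untaggable.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @return list with `entries` (data.frame: `transcript`, `position` of the
#'   CATG site, `strand`, `tag`), `representative` (data.frame:
#'   `transcript`, `tag` — NA when no sense-strand site qualifies), and
#'   `untaggable` (transcripts with no tag on either strand).
#' @examples
#' tx <- Biostrings::DNAStringSet(c(t1 = paste0("AAACATG",
#'                                              strrep("T", 17), "GG")))
#' buildTagCatalog(tx)$representative
#' @export
buildTagCatalog <- function(transcripts) {
    ids <- names(transcripts)
    txt <- as.character(transcripts)
    lens <- nchar(txt)
    out <- list()
    repTag <- rep(NA_character_, length(ids))
    for (i in seq_along(txt)) {
        sites <- gregexpr("CATG", txt[i], fixed = TRUE)[[1]]
        if (sites[1] == -1) next
        sense <- sites[sites + 20L <= lens[i]]
        anti <- sites[sites >= 18L]
        rows <- NULL
        if (length(sense))
            rows <- data.frame(transcript = ids[i], position = sense,
                               strand = "+",
                               tag = substring(txt[i], sense, sense + 20L))
        if (length(anti))
            rows <- rbind(rows, data.frame(
                transcript = ids[i], position = anti, strand = "-",
                tag = revcompChar(substring(txt[i], anti - 17L, anti + 3L))))
        if (!is.null(rows)) out[[length(out) + 1L]] <- rows
        if (length(sense)) repTag[i] <- substring(txt[i], max(sense),
                                                  max(sense) + 20L)
    }
    entries <- if (length(out)) do.call(rbind, out)
               else data.frame(transcript = character(0),
                               position = integer(0), strand = character(0),
                               tag = character(0))
    list(entries = entries,
         representative = data.frame(transcript = ids, tag = repTag),
         untaggable = setdiff(ids, unique(entries$transcript)))
}

#' Filter raw tags into clean tags
#'
#' Applies the standard clean-tag rules: drop tags containing ambiguity
#' codes (anything outside A/C/G/T), tags matching a configured adapter
#' prefix, and tags with library-wide copy number 1 (sequencing-noise
#' singletons). Each rule can be switched off.
#'
#' @param raw a [TagCountMatrix-class] of raw tag counts.
#' @param adapters character vector of adapter prefixes (default none).
#' @param dropAmbiguous,dropAdapters,dropSingletons rule switches.
#' @return list with `tags` (clean [TagCountMatrix-class], carrying the raw
#'   library totals) and `report` (data.frame: rule, distinct tags removed,
#'   tag mass removed).
#' @export
cleanTags <- function(raw, adapters = character(0), dropAmbiguous = TRUE,
                      dropAdapters = TRUE, dropSingletons = TRUE) {
    m <- tagCounts(raw)
    tags <- rownames(m)
    assertThat(all(nchar(tags) == 21L), "tags must be 21-mers")
    rawTotal <- colSums(m)
    drop <- rep(FALSE, length(tags))
    report <- NULL
    note <- function(rule, hit) {
        new <- hit & !drop
        report <<- rbind(report, data.frame(
            rule = rule, distinctRemoved = sum(new),
            massRemoved = sum(m[new, , drop = FALSE])))
        drop <<- drop | hit
    }
    if (dropAmbiguous) note("ambiguity", grepl("[^ACGT]", tags))
    if (dropAdapters && length(adapters)) {
        hit <- Reduce(`|`, lapply(adapters, function(a)
            startsWith(tags, a)))
        note("adapter", hit)
    }
    if (dropSingletons) note("singleton", rowSums(m) == 1)
    clean <- m[!drop, , drop = FALSE]
    list(tags = TagCountMatrix(clean, rawTotal = rawTotal),
         report = report)
}

## all 1-substitution neighbors of 21-mers, vectorized over tags
oneMismatchNeighbors <- function(tags) {
    n <- length(tags)
    reps <- rep(tags, each = 21L * 3L)
    pos <- rep(rep(1:21, each = 3L), n)
    sub <- unlist(lapply(strsplit(tags, ""), function(ch)
        as.vector(vapply(1:21, function(p) setdiff(BASES, ch[p]),
                         character(3)))), use.names = FALSE)
    substr(reps, pos, pos) <- sub
    list(neighbor = reps, origin = rep(seq_len(n), each = 63L))
}

#' Map clean tags to a transcript catalog
#'
#' Assigns each clean tag to all catalog tags within the mismatch limit
#' (both strands are in the catalog, since assembled transcripts have
#' arbitrary orientation). Exact matches pre-empt 1-mismatch matches. A
#' tag is unambiguous when it maps to exactly one transcript (possibly at
#' several positions within it).
#'
#' @param clean a clean [TagCountMatrix-class].
#' @param catalog result of [buildTagCatalog()] on the same transcript set.
#' @param maxMismatch 0 or 1 (default 1).
#' @return data.frame, one row per clean tag: `tag`, `mapped`,
#'   `mismatches` (NA when unmapped), `nTranscripts`, `transcripts`
#'   (comma-collapsed ids), `unambiguous`.
#' @export
mapTags <- function(clean, catalog, maxMismatch = 1L) {
    tags <- rownames(tagCounts(clean))
    byTag <- lapply(split(catalog$entries$transcript, catalog$entries$tag),
                    unique)
    catTags <- names(byTag)
    hitTx <- vector("list", length(tags))
    mm <- rep(NA_integer_, length(tags))
    exact <- match(tags, catTags)
    found <- !is.na(exact)
    hitTx[found] <- byTag[exact[found]]
    mm[found] <- 0L
    if (maxMismatch >= 1L && any(!found)) {
        rest <- which(!found)
        nb <- oneMismatchNeighbors(tags[rest])
        hit <- match(nb$neighbor, catTags)
        ok <- !is.na(hit)
        if (any(ok)) {
            lst <- split(hit[ok], nb$origin[ok])
            for (nm in names(lst)) {
                k <- rest[as.integer(nm)]
                hitTx[[k]] <- unique(unlist(byTag[lst[[nm]]],
                                            use.names = FALSE))
                mm[k] <- 1L
            }
        }
    }
    nTx <- lengths(hitTx)
    data.frame(tag = tags, mapped = nTx > 0, mismatches = mm,
               nTranscripts = nTx,
               transcripts = vapply(hitTx, paste, character(1),
                                    collapse = ","),
               unambiguous = nTx == 1L)
}

#' Quantify transcript expression from mapped tags
#'
#' A transcript's count in a library is the sum of the counts of the
#' unambiguous clean tags assigned to it; ambiguous tags contribute to the
#' mapped totals but to no transcript. TPM (transcripts per million clean
#' tags) divides by the library's clean-tag total and scales by 1e6.
#'
#' @param assignment data.frame from [mapTags()].
#' @param clean the clean [TagCountMatrix-class].
#' @return list of class `"TagExpression"`: `counts` and `tpm`
#'   (transcript x library matrices), `cleanTotals`, `mappedTotals`
#'   (per-library totals of all mapped tags).
#' @export
quantifyTags <- function(assignment, clean) {
    m <- tagCounts(clean)
    cleanTotals <- colSums(m)
    assertThat(all(cleanTotals > 0), "zero-size library")
    ua <- assignment[assignment$unambiguous, , drop = FALSE]
    counts <- rowsum(m[ua$tag, , drop = FALSE], ua$transcripts)
    tpm <- sweep(counts, 2, cleanTotals, "/") * 1e6
    mappedTotals <- colSums(m[assignment$mapped[match(rownames(m),
                                                      assignment$tag)], ,
                              drop = FALSE])
    structure(list(counts = counts, tpm = tpm, cleanTotals = cleanTotals,
                   mappedTotals = mappedTotals),
              class = "TagExpression")
}

## Table-layout row labels of the DGE ledger
LEDGER_COUNT_ROWS <- c("rawTags", "cleanTags", "distinctRawTags",
                       "distinctCleanTags", "mappedCleanTags",
                       "mappedDistinctCleanTags", "unambiguousCleanTags",
                       "unambiguousDistinctCleanTags",
                       "tagMappedTranscripts",
                       "unambiguousTagMappedTranscripts")

#' Derive the full DGE library ledger from its count rows
#'
#' Given the ten count rows of a tag-mapping ledger (raw, clean, distinct
#' raw/clean, mapped and unambiguous clean/distinct, tag-mapped and
#' unambiguously tag-mapped transcripts; one column per library), derives
#' every percentage row (to two decimals, half-up; percentages of clean or
#' distinct-clean totals), the unknown-tag rows by the ledger identities
#' unknown = clean - mapped and distinctUnknown = distinctClean -
#' mappedDistinct, and an `Averages` column (arithmetic mean over
#' libraries; counts rounded to integers, percentages to two decimals).
#'
#' @param countRows numeric matrix or data.frame, rownames from
#'   `c("rawTags", "cleanTags", "distinctRawTags", "distinctCleanTags",
#'   "mappedCleanTags", "mappedDistinctCleanTags", "unambiguousCleanTags",
#'   "unambiguousDistinctCleanTags", "tagMappedTranscripts",
#'   "unambiguousTagMappedTranscripts")`, one column per library.
#' @return data.frame in table layout (count and percentage rows
#'   interleaved) with the `Averages` column appended.
#' @export
dgeLedger <- function(countRows) {
    m <- as.matrix(countRows)
    assertThat(all(LEDGER_COUNT_ROWS %in% rownames(m)),
               paste("countRows must contain rows:",
                     paste(LEDGER_COUNT_ROWS, collapse = ", ")))
    m <- m[LEDGER_COUNT_ROWS, , drop = FALSE]
    g <- function(r) m[r, ]
    unknown <- g("cleanTags") - g("mappedCleanTags")
    dUnknown <- g("distinctCleanTags") - g("mappedDistinctCleanTags")
    rows <- list(
        "Raw Tags" = g("rawTags"),
        "Clean Tags" = g("cleanTags"),
        "Clean Tags/Raw Tags (%)" = pct2(g("cleanTags"), g("rawTags")),
        "Distinct Raw Tags" = g("distinctRawTags"),
        "Distinct Clean Tags" = g("distinctCleanTags"),
        "Distinct Clean Tags/Clean Tags (%)" =
            pct2(g("distinctCleanTags"), g("cleanTags")),
        "Mapped Clean Tags" = g("mappedCleanTags"),
        "Mapped Clean Tags (%)" = pct2(g("mappedCleanTags"), g("cleanTags")),
        "Mapped Distinct Clean Tags" = g("mappedDistinctCleanTags"),
        "Mapped Distinct Clean Tags (%)" =
            pct2(g("mappedDistinctCleanTags"), g("distinctCleanTags")),
        "Unambiguous Clean Tags" = g("unambiguousCleanTags"),
        "Unambiguous Clean Tags (%)" =
            pct2(g("unambiguousCleanTags"), g("cleanTags")),
        "Unambiguous Distinct Clean Tags" =
            g("unambiguousDistinctCleanTags"),
        "Unambiguous Distinct Clean Tags (%)" =
            pct2(g("unambiguousDistinctCleanTags"), g("distinctCleanTags")),
        "Tag-mapped Transcripts" = g("tagMappedTranscripts"),
        "Unambiguous Tag-mapped Transcripts" =
            g("unambiguousTagMappedTranscripts"),
        "Unknown Tags" = unknown,
        "Unknown Tags (%)" = pct2(unknown, g("cleanTags")),
        "Distinct Unknown Tags" = dUnknown,
        "Distinct Unknown Tags (%)" = pct2(dUnknown, g("distinctCleanTags")))
    isPct <- grepl("%", names(rows))
    out <- do.call(rbind, rows)
    avg <- ifelse(isPct, roundHalfUp(rowMeans(out), 2),
                  round(rowMeans(out)))
    out <- cbind(as.data.frame(out), Averages = avg)
    out
}

#' Library statistics of a DGE experiment
#'
#' Computes the ten count rows of the tag-mapping ledger from the raw and
#' clean matrices and the tag assignment, then derives the full table via
#' [dgeLedger()]. Distinct counts are per library (tags with a positive
#' count in that library).
#'
#' @param raw,clean [TagCountMatrix-class] objects with identical library
#'   sets.
#' @param assignment data.frame from [mapTags()] on `clean`.
#' @return data.frame, the full ledger (see [dgeLedger()]).
#' @export
libraryStats <- function(raw, clean, assignment) {
    assertThat(identical(colnames(raw), colnames(clean)),
               "raw and clean must share the same libraries")
    rm_ <- tagCounts(raw); cm <- tagCounts(clean)
    a <- assignment[match(rownames(cm), assignment$tag), ]
    mapped <- a$mapped
    unamb <- a$unambiguous
    txHit <- function(rows, lib) {
        sel <- rows & cm[, lib] > 0
        length(unique(unlist(strsplit(a$transcripts[sel], ","))))
    }
    libs <- colnames(cm)
    counts <- rbind(
        rawTags = colSums(rm_),
        cleanTags = colSums(cm),
        distinctRawTags = colSums(rm_ > 0),
        distinctCleanTags = colSums(cm > 0),
        mappedCleanTags = colSums(cm[mapped, , drop = FALSE]),
        mappedDistinctCleanTags = colSums(cm[mapped, , drop = FALSE] > 0),
        unambiguousCleanTags = colSums(cm[unamb, , drop = FALSE]),
        unambiguousDistinctCleanTags =
            colSums(cm[unamb, , drop = FALSE] > 0),
        tagMappedTranscripts = vapply(libs, function(l) txHit(mapped, l),
                                      numeric(1)),
        unambiguousTagMappedTranscripts =
            vapply(libs, function(l) txHit(unamb, l), numeric(1)))
    dgeLedger(counts)
}

#' Read/write a tag-count matrix as TSV
#'
#' Column 1 is the tag sequence; remaining columns are per-library counts.
#'
#' @param path file path.
#' @export
readTagCounts <- function(path) {
    x <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- x[[1]]
    TagCountMatrix(m)
}

#' @rdname readTagCounts
#' @param tags a [TagCountMatrix-class].
#' @export
writeTagCounts <- function(tags, path) {
    m <- tagCounts(tags)
    df <- data.frame(tag = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
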