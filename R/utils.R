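#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement
#' @importFrom stats dhyper phyper rnorm rpois rgamma runif setNames p.adjust
#' @importFrom utils read.table write.table combn
NULL

BASES <- c("A", "C", "G", "T")

ALL_CODONS <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                              BASES, paste0))

## reverse complement on plain character vectors (keeps N)
revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## round half away from zero, matching how published tables render percentages
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

## percentage rendered to 2 decimals, half-up
pct2 <- function(num, den) roundHalfUp(100 * num / den, 2)

## deterministic per-stage RNG substream: all generator stages reseed from
## one user seed plus a fixed small offset, so stages are individually and
## jointly reproducible
stageSeed <- function(seed, stage) {
    offsets <- c(transcriptome = 11L, reads = 23L, tags = 37L,
                 pipeline = 53L)
    s <- as.integer(seed) + offsets[[stage]]
    s %% .Machine$integer.max
}

## id %in%-style stopifnot with message
assertThat <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
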