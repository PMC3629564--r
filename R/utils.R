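# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so that simulation helpers do not perturb user code.
with_local_seed <- function(seed, expr) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Hierarchical seed split: one global seed deterministically yields `n`
# independent sub-seeds (kept below 2^31 so they remain valid R integers).
split_seed <- function(seed, n) {
    with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Windowed running sum of a numeric vector with window [i - flank, i + flank]
# clipped to the vector bounds.
window_sum <- function(x, flank) {
    if (flank == 0L) return(x)
    n <- length(x)
    cs <- cumsum(x)
    lo <- pmax(seq_len(n) - flank, 1L)
    hi <- pmin(seq_len(n) + flank, n)
    cs[hi] - c(0, cs)[lo]
}

# Lengths and start offsets (1-based) of all maximal runs of `letter` in a
# character string; returns a data.frame with columns start, length.
letter_runs <- function(seq, letter = "T") {
    v <- strsplit(seq, "")[[1]] == letter
    if (!length(v) || !any(v)) {
        return(data.frame(start = integer(), length = integer()))
    }
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], length = r$lengths[keep])
}

# Reverse-complement of a plain character DNA string.
revcomp <- function(seq) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Transcript-strand sequence of a 1-based genomic interval.
transcript_seq <- function(genome_seq, start, end, strand) {
    s <- substring(genome_seq, start, end)
    if (strand == "-") s <- revcomp(s)
    s
}

rand_dna <- function(n, prob = rep(0.25, 4)) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = "")
}
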