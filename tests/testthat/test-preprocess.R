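test_that("demultiplexing routes reads by experimental barcode", {
    scheme <- barcodeScheme("NNNXXXXNN", c(GGCA = "s1", TTAA = "s2"))
    reads <- data.frame(
        name = c("r1", "r2", "r3"),
        seq = c("TTTGGCAACGATTACA",   # s1, random barcode TTT + AC
                "AAATTAAGGCCCCCCC",   # s2
                "CCCACGTAAGATTACA"),  # experimental barcode ACGT unknown
        qual = strrep("I", 16))
    out <- demultiplexReads(reads, scheme)
    expect_identical(out$tally,
                     c(assigned = 2L, unassigned = 1L, skipped = 0L))
    expect_identical(out$samples$s1$name, "r1:rbc:TTTAC")
    expect_identical(out$samples$s1$seq, "GATTACA")   # insert starts at 10
    expect_identical(out$samples$s1$qual, "IIIIIII")
    expect_identical(out$samples$s2$name, "r2:rbc:AAAGG")
    expect_identical(out$unassigned$name, "r3:rbc:CCCAA")
})

test_that("short reads are skipped with a warning and reads are conserved", {
    scheme <- barcodeScheme("NNNXXXXNN", c(GGCA = "s1"))
    reads <- data.frame(name = c("a", "b"),
                        seq = c("TTTGGCAACG", "ACGTACG"),
                        qual = c("IIIIIIIIII", "IIIIIII"))
    expect_warning(out <- demultiplexReads(reads, scheme), "skipped")
    expect_identical(sum(out$tally), nrow(reads))
    # empty input: empty outputs, zero tallies
    out0 <- demultiplexReads(reads[0, ], scheme)
    expect_identical(sum(out0$tally), 0L)
    expect_identical(nrow(out0$unassigned), 0L)
})

test_that("demultiplexing a FASTQ file equals the in-memory path", {
    fq <- tempfile(fileext = ".fastq")
    writeLines(c("@r1 extra", "TTTGGCAACGATTACA", "+", strrep("F", 16)), fq)
    scheme <- barcodeScheme("NNNXXXXNN", c(GGCA = "s1"))
    out <- demultiplexReads(fq, scheme)
    expect_identical(out$samples$s1$name, "r1:rbc:TTTAC")
    expect_identical(out$samples$s1$seq, "GATTACA")
    expect_identical(out$samples$s1$qual, strrep("F", 7))
    unlink(fq)
})

test_that("crosslink assignment takes the nucleotide 5' of the read start", {
    gr <- GRanges("chr1", IRanges(c(101, 101, 1), c(140, 140, 40)),
                  strand = c("+", "-", "+"))
    GenomeInfoDb::seqlengths(gr) <- c(chr1 = 1000L)
    xl <- assignCrosslink(gr)
    expect_identical(start(xl), c(100L, 141L))
    expect_identical(as.character(strand(xl)), c("+", "-"))
    expect_identical(S4Vectors::metadata(xl)$n_dropped, 1L)
    # minus-strand read ending at the contig end is dropped too
    gr2 <- GRanges("chr1", IRanges(901, 1000), strand = "-")
    GenomeInfoDb::seqlengths(gr2) <- c(chr1 = 1000L)
    expect_identical(length(assignCrosslink(gr2)), 0L)
})

test_that("duplicate collapsing keys on position, strand and random barcode", {
    mk <- function(pos, rbc) {
        g <- GRanges("chr1", IRanges(pos, width = 1L), strand = "+")
        mcols(g)$rbc <- rbc
        g
    }
    # same position + same barcode -> 1 event
    tr <- collapseDuplicates(mk(c(100, 100), c("TTTAC", "TTTAC")))
    expect_identical(totalEvents(tr), 1L)
    # same position, different barcodes -> 2 events at one position
    tr <- collapseDuplicates(mk(c(100, 100), c("TTTAC", "TTTAG")))
    expect_identical(totalEvents(tr), 2L)
    expect_identical(length(tr), 1L)
    # same barcode, different positions -> 2 events
    tr <- collapseDuplicates(mk(c(100, 101), c("TTTAC", "TTTAC")))
    expect_identical(totalEvents(tr), 2L)
    # missing barcode -> rejected and tallied
    tr <- collapseDuplicates(mk(c(100, 101), c("TTTAC", NA)))
    expect_identical(totalEvents(tr), 1L)
    expect_identical(S4Vectors::metadata(tr)$n_rejected, 1L)
})

test_that("full preprocessing conserves events against duplication", {
    # 2x duplicated alignments collapse to the original unique events
    set.seed(8)
    n <- 50L
    pos <- sample(100:500, n)
    rbc <- replicate(n, paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                              collapse = ""))
    g <- GRanges("chr1", IRanges(rep(pos, 2), width = 30L), strand = "+")
    mcols(g)$rbc <- rep(rbc, 2)
    tr <- collapseDuplicates(assignCrosslink(g))
    expect_lte(totalEvents(tr), length(g))
    expect_identical(totalEvents(tr),
                     length(unique(paste(pos, rbc))))
})

annotation_fixture <- function() {
    GRanges("chr1",
            IRanges(c(1000, 1000, 1100, 1900, 1500, 3000, 3000, 5000),
                    c(2000, 1099, 1200, 2000, 1600, 4000, 3100, 5100)),
            strand = c("+", "+", "+", "+", "+", "-", "-", "+"),
            type = c("gene", "five_prime_utr", "exon", "three_prime_utr",
                     "exon", "gene", "exon", "ncRNA"),
            gene_id = c("gA", "gA", "gA", "gA", "gA", "gB", "gB", "nc1"))
}

test_that("region hierarchy resolves overlapping annotations", {
    ann <- annotation_fixture()
    q <- function(pos, strand = "+")
        GRanges("chr1", IRanges(pos, width = 1L), strand = strand)
    expect_identical(as.character(annotatePositions(q(1950), ann)), "utr3")
    expect_identical(as.character(annotatePositions(q(1050), ann)), "utr5")
    expect_identical(as.character(annotatePositions(q(1150), ann)), "exon")
    expect_identical(as.character(annotatePositions(q(5050), ann)), "ncRNA")
    expect_identical(as.character(annotatePositions(q(3500, "-"), ann, 200L)),
                     "intron_deep")
    expect_identical(as.character(annotatePositions(q(3050, "+"), ann)),
                     "antisense")
    expect_identical(as.character(annotatePositions(q(9000), ann)),
                     "intergenic")
})

test_that("introns subdivide at 200 nt around splice sites", {
    ann <- GRanges("chr1", IRanges(c(1, 100, 2000), c(3000, 200, 2100)),
                   strand = "+", type = c("gene", "exon", "exon"),
                   gene_id = "g")
    q <- function(pos) GRanges("chr1", IRanges(pos, width = 1L),
                               strand = "+")
    # 150 nt downstream of an exon end -> near the 5' splice site
    expect_identical(as.character(annotatePositions(q(350), ann)),
                     "intron_near5ss")
    # 150 nt upstream of an exon start -> near the 3' splice site
    expect_identical(as.character(annotatePositions(q(1850), ann)),
                     "intron_near3ss")
    expect_identical(as.character(annotatePositions(q(1100), ann)),
                     "intron_deep")
    # exactly 200 nt away still counts as near
    expect_identical(as.character(annotatePositions(q(400), ann)),
                     "intron_near5ss")
})

test_that("every position gets exactly one category", {
    ann <- annotation_fixture()
    pos <- GRanges("chr1", IRanges(seq(900, 5200, by = 37), width = 1L),
                   strand = "+")
    cats <- annotatePositions(pos, ann)
    expect_false(any(is.na(cats)))
    expect_identical(length(cats), length(pos))
})

test_that("combining tracks sums per-position counts", {
    a <- make_track(c(10, 20), count = c(2L, 1L))
    b <- make_track(c(20, 30), count = c(3L, 4L))
    comb <- combineTracks(list(a, b))
    expect_identical(totalEvents(comb), 10L)
    expect_identical(score(comb)[start(comb) == 20], 4L)
})

test_that("alignment TSVs convert to stranded GRanges with barcodes", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("contig\tstart\tend\tstrand\tname",
                 "chr1\t100\t140\t+\tr1:rbc:TTTAC",
                 "chr1\t200\t240\t-\tr2"), tsv)
    gr <- readAlignments(tsv)
    # 0-based half-open [100,140) becomes 1-based 101..140
    expect_identical(start(gr), c(101L, 201L))
    expect_identical(end(gr), c(140L, 240L))
    expect_identical(S4Vectors::mcols(gr)$rbc[1], "TTTAC")
    expect_true(is.na(S4Vectors::mcols(gr)$rbc[2]))
    # crosslink of the first read is 0-based 99 = 1-based 100
    xl <- assignCrosslink(gr)
    expect_identical(start(xl), c(100L, 241L))
    unlink(tsv)
    expect_error(readAlignments({
        bad <- tempfile(fileext = ".tsv")
        writeLines("a\tb", bad); bad
    }), "columns")
})
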