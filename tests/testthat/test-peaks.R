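test_that("window heights sum events over the clipped window", {
    cnt <- integer(20); cnt[10] <- 3L
    expect_identical(unname(windowHeights(cnt, 1L)), 3)
    cnt <- integer(20); cnt[c(10, 12)] <- c(2L, 1L)
    h <- windowHeights(cnt, 2L)
    expect_identical(unname(h), c(3, 3))
    expect_identical(names(h), c("10", "12"))
    # flank 0 reduces to the per-position count
    expect_identical(unname(windowHeights(cnt, 0L)), c(2, 1))
    # window clipped at the gene boundary
    cnt <- integer(5); cnt[1] <- 2L; cnt[2] <- 1L
    expect_identical(unname(windowHeights(cnt, 3L)), c(3, 3))
})

test_that("a concentrated pile of events is significant, spread events are not", {
    cnt <- integer(1000); cnt[500] <- 20L
    tab <- empiricalFdr(cnt, flank = 5L, iterations = 1000L, seed = 4L)
    expect_lt(tab$fdr[tab$height == 20], 0.05)
    # events spread uniformly, one per position: heights carry no local
    # enrichment, so the maximal height is far from significant
    cnt <- rep(1L, 200)
    tab <- empiricalFdr(cnt, flank = 5L, iterations = 200L, seed = 4L)
    expect_gt(min(tab$fdr), 0.3)
    # no events -> empty FDR table
    expect_identical(nrow(empiricalFdr(integer(50), 5L)), 0L)
    expect_error(empiricalFdr(integer(0), 5L), "zero-length")
})

test_that("FDR table matches the brute-force oracle exactly", {
    set.seed(12)
    for (k in 1:8) {
        L <- sample(40:200, 1)
        cnt <- integer(L)
        idx <- sample.int(L, sample(1:15, 1), replace = TRUE)
        for (i in idx) cnt[i] <- cnt[i] + 1L
        flank <- sample(0:10, 1)
        got <- empiricalFdr(cnt, flank, iterations = 50L, seed = 100L + k)
        want <- oracle_empirical_fdr(cnt, flank, iterations = 50L,
                                     seed = 100L + k)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("site calls match the brute-force oracle on both strands", {
    set.seed(77)
    for (k in 1:10) {
        L <- sample(60:200, 1)
        strand <- sample(c("+", "-"), 1)
        gstart <- sample(1000:2000, 1)
        cnt <- integer(L)
        hot <- sample.int(L, 2)
        cnt[hot] <- sample(5:12, 2)
        idx <- sample.int(L, sample(0:8, 1), replace = TRUE)
        for (i in idx) cnt[i] <- cnt[i] + 1L
        flank <- sample(2:8, 1)
        genes <- make_genes(gstart, gstart + L - 1L, strand = strand)
        track <- make_track(gstart - 1L + which(cnt > 0),
                            count = cnt[cnt > 0], strand = strand)
        sites <- callBindingSites(track, genes, flank = flank,
                                  fdr_threshold = 0.05, iterations = 60L,
                                  seed = 200L + k)
        # oracle works in gene-local coordinates with the same per-gene seed
        want <- oracle_call_sites(cnt, flank, 0.05, 60L, 200L + k + 1L,
                                  strand = strand)
        expect_identical(length(sites), nrow(want))
        if (nrow(want)) {
            expect_identical(start(sites), gstart - 1L + want$start)
            expect_identical(end(sites), gstart - 1L + want$end)
            expect_identical(mcols(sites)$summit, gstart - 1L + want$summit)
            expect_identical(mcols(sites)$n_events, want$n_events)
            expect_equal(mcols(sites)$fdr, want$fdr, tolerance = 1e-12)
        }
    }
})

test_that("significant positions within flank distance merge into one site", {
    # plant three significant positions 4 nt apart with flank 5
    cnt <- integer(400)
    cnt[c(100, 104, 108)] <- c(10L, 12L, 9L)
    genes <- make_genes(1L, 400L)
    track <- make_track(which(cnt > 0), count = cnt[cnt > 0])
    sites <- callBindingSites(track, genes, flank = 5L, iterations = 200L,
                              seed = 9L)
    expect_identical(length(sites), 1L)
    expect_identical(start(sites), 100L)
    expect_identical(end(sites), 108L)
    expect_identical(mcols(sites)$summit, 104L)  # argmax count
    expect_identical(mcols(sites)$n_events, 31L)
})

test_that("summit ties break toward the transcript 5' end", {
    cnt <- integer(300); cnt[c(150, 153)] <- 10L
    genes_p <- make_genes(1L, 300L, strand = "+")
    genes_m <- make_genes(1L, 300L, strand = "-")
    tr_p <- make_track(c(150, 153), count = 10L, strand = "+")
    tr_m <- make_track(c(150, 153), count = 10L, strand = "-")
    sp <- callBindingSites(tr_p, genes_p, flank = 5L, iterations = 100L,
                           seed = 1L)
    sm <- callBindingSites(tr_m, genes_m, flank = 5L, iterations = 100L,
                           seed = 1L)
    expect_identical(mcols(sp)$summit, 150L)
    expect_identical(mcols(sm)$summit, 153L)
})

test_that("no significant positions yields an empty result", {
    track <- make_track(c(10, 90), count = 1L)
    genes <- make_genes(1L, 200L)
    sites <- callBindingSites(track, genes, flank = 5L, iterations = 100L,
                              seed = 2L)
    expect_identical(length(sites), 0L)
})

test_that("events on strands without a matching gene are tallied, not used", {
    track <- make_track(c(50, 60), count = c(5L, 20L), strand = "-")
    genes <- make_genes(1L, 200L, strand = "+")
    sites <- callBindingSites(track, genes, flank = 5L, iterations = 50L,
                              seed = 3L)
    expect_identical(length(sites), 0L)
    expect_identical(S4Vectors::metadata(sites)$n_ignored, 25L)
})

test_that("reported sites respect the threshold and stay disjoint per gene", {
    g <- generateGenome(simConfig(n_genes = 8L, seed = 15L))
    tr <- generateCrosslinkTracks(g)
    sites <- callBindingSites(tr$U2AF65$kd, g$genes, flank = 5L,
                              fdr_threshold = 0.05, iterations = 100L,
                              seed = 6L)
    expect_gt(length(sites), 0L)
    expect_true(all(mcols(sites)$fdr < 0.05))
    expect_true(all(mcols(sites)$summit >= start(sites) &
                    mcols(sites)$summit <= end(sites)))
    for (gid in unique(mcols(sites)$gene_id)) {
        s <- sites[mcols(sites)$gene_id == gid]
        expect_identical(length(GenomicRanges::reduce(granges(s))),
                         length(s))
    }
})

test_that("adding events at an existing summit never removes the site", {
    cnt <- integer(500); cnt[c(200, 230)] <- c(15L, 8L)
    genes <- make_genes(1L, 500L)
    t1 <- make_track(which(cnt > 0), count = cnt[cnt > 0])
    s1 <- callBindingSites(t1, genes, flank = 5L, iterations = 200L,
                           seed = 21L)
    expect_true(200 %in% mcols(s1)$summit)
    cnt[200] <- cnt[200] + 5L
    t2 <- make_track(which(cnt > 0), count = cnt[cnt > 0])
    s2 <- callBindingSites(t2, genes, flank = 5L, iterations = 200L,
                           seed = 21L)
    covering <- start(s2) <= 200 & end(s2) >= 200
    expect_true(any(covering))
    expect_true(200 %in% mcols(s2)$summit[covering])
})

test_that("the mean+SD FDR variant is conservative relative to the mean", {
    cnt <- integer(500)
    cnt[c(100, 250, 400)] <- c(8L, 3L, 5L)
    cnt[sample.int(500, 30)] <- 1L
    a <- empiricalFdr(cnt, flank = 5L, iterations = 100L, seed = 31L)
    b <- empiricalFdr(cnt, flank = 5L, iterations = 100L, seed = 31L,
                      summary = "mean_sd")
    expect_identical(a$height, b$height)
    expect_true(all(b$fdr >= a$fdr - 1e-12))
})
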