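# Small constructors shared across tests.

make_track <- function(pos, count = 1L, chrom = "chr1", strand = "+",
                       seqlen = NA_integer_) {
    tr <- CrosslinkTrack(data.frame(
        chrom = rep_len(chrom, length(pos)), pos = pos,
        strand = rep_len(strand, length(pos)),
        count = rep_len(count, length(pos))))
    if (!is.na(seqlen))
        GenomeInfoDb::seqlengths(tr) <- stats::setNames(seqlen, chrom)
    tr
}

make_genes <- function(starts, ends, strand = "+", chrom = "chr1",
                       ids = NULL) {
    if (is.null(ids)) ids <- sprintf("g%02d", seq_along(starts))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                           strand = strand, gene_id = ids)
}

# configuration whose element copies are exact consensus copies: equal
# poly(A) blocks, degenerate tract-length distribution, no mutations, no
# planted exons
exact_copy_config <- function(n_genes = 1L, n_alu = 1L, seed = 1L,
                              block = 10L) {
    cons <- makeAluConsensus(arm_length = 100L, linker_length = block,
                             tail_length = block)
    # keep the arm bases flanking the poly(A) blocks non-A so the detected
    # block lengths equal the construction lengths exactly
    v <- strsplit(cons, "")[[1]]
    v[c(1L, 100L, 111L, 210L)] <- "G"
    cons <- paste(v, collapse = "")
    simConfig(n_genes = n_genes, gene_length_range = c(2000L, 2500L),
              n_alu_per_gene = n_alu, alu_consensus = cons,
              utract_min = block, utract_mean_control = block,
              utract_mean_exonized = block, frac_exonized = 0,
              mutation_rate = 0, seed = seed)
}

# a SimTruth with hand-set exon inclusion levels, for calibration tests
psi_truth <- function(n_exons, psi_ctrl, psi_kd) {
    genes <- GenomicRanges::GRanges(
        "chrS", IRanges::IRanges(seq_len(n_exons) * 1000L, width = 500L),
        strand = "+", gene_id = sprintf("g%04d", seq_len(n_exons)))
    alu_exons <- data.frame(
        exon_id = sprintf("x%04d", seq_len(n_exons)),
        element_id = sprintf("e%04d", seq_len(n_exons)),
        gene_id = sprintf("g%04d", seq_len(n_exons)),
        start = 1L, end = 2L, strand = "+", acceptor = 1L, donor = 2L,
        upstream_tract_t = 1L,
        psi_ctrl = rep_len(psi_ctrl, n_exons),
        psi_kd = rep_len(psi_kd, n_exons))
    alu_exons$regulated <- alu_exons$psi_kd > alu_exons$psi_ctrl
    alu_exons$chrom <- "chrS"
    new("SimTruth", genes = genes, exons = GenomicRanges::GRanges(),
        elements = GenomicRanges::GRanges(),
        tracts = data.frame(), alu_exons = alu_exons)
}

sum_exon_counts <- function(counts, conds = c("ctrl", "kd1", "kd2")) {
    ec <- counts$exon_counts
    out <- list()
    for (cond in conds) {
        sub <- ec[ec$condition == cond, ]
        agg_i <- tapply(sub$inclusion, sub$exon_id, sum)
        agg_e <- tapply(sub$exclusion, sub$exon_id, sum)
        ids <- names(agg_i)
        out[[cond]] <- data.frame(exon_id = ids,
                                  inclusion = as.integer(agg_i),
                                  exclusion = as.integer(agg_e))
    }
    out
}
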