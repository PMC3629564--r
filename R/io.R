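#' Write a crosslink track as BED6
#'
#' One record per crosslink nucleotide (0-based half-open in the file), with
#' the unique-event count in the score column and the strand set.
#'
#' @param track A \code{\link{CrosslinkTrack}}.
#' @param path output file.
#' @export
writeCrosslinkTrack <- function(track, path) {
    gr <- granges(track)
    mcols(gr)$name <- "."
    mcols(gr)$score <- score(track)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read a crosslink track from BED6
#'
#' @param path BED file written by \code{\link{writeCrosslinkTrack}} (or any
#'   BED6 of width-1 stranded records with event counts as scores).
#' @return A \code{\link{CrosslinkTrack}}.
#' @export
readCrosslinkTrack <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr) <- DataFrame(score = as.integer(score(gr)))
    CrosslinkTrack(gr)
}

#' Write binding sites as a TSV table
#'
#' @param sites A \code{\link{BindingSites}}.
#' @param path output file.
#' @export
writeBindingSites <- function(sites, path) {
    df <- data.frame(chrom = as.character(seqnames(sites)),
                     start = start(sites), end = end(sites),
                     strand = as.character(strand(sites)),
                     summit = mcols(sites)$summit,
                     n_events = mcols(sites)$n_events,
                     fdr = mcols(sites)$fdr,
                     gene_id = mcols(sites)$gene_id)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the genome (FASTA), gene/exon annotation (GTF, 1-based inclusive),
#' element annotation (BED6 with strand), one BED6 crosslink track per
#' protein and condition, count tables and ground truth (TSV).
#'
#' @param sim output of \code{\link{simulateDataset}}.
#' @param dir output directory (created if missing).
#' @export
writeSimulation <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    genome <- sim$genome
    seq <- Biostrings::DNAStringSet(genome$seq)
    Biostrings::writeXStringSet(seq, file.path(dir, "genome.fa"))

    genes <- genome$genes
    mcols(genes)$type <- "gene"
    exons <- genome$exons
    mcols(exons)$type <- "exon"
    mcols(exons)$exon_rank <- NULL
    ann <- c(genes, exons)
    mcols(ann)$source <- "sim"
    rtracklayer::export(ann, file.path(dir, "annotation.gtf"),
                        format = "GTF")

    elems <- granges(genome$elements)
    mcols(elems)$name <- mcols(genome$elements)$element_id
    mcols(elems)$score <- 0L
    rtracklayer::export(elems, file.path(dir, "elements.bed"),
                        format = "BED")

    for (prot in names(sim$tracks))
        for (cond in names(sim$tracks[[prot]]))
            writeCrosslinkTrack(sim$tracks[[prot]][[cond]],
                                file.path(dir, sprintf("%s_%s.bed",
                                                       prot, cond)))

    wt <- function(x, f) utils::write.table(
        x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(sim$counts$gene_totals, "gene_totals.tsv")
    if (!is.null(sim$counts$exon_counts))
        wt(sim$counts$exon_counts, "exon_counts.tsv")
    wt(genome$truth@tracts, "truth_tracts.tsv")
    if (nrow(genome$truth@alu_exons))
        wt(genome$truth@alu_exons, "truth_alu_exons.tsv")
    invisible(dir)
}

#' Read alignments from a TSV or BAM file
#'
#' The TSV format carries one alignment per line with columns \code{contig},
#' \code{start}, \code{end} (0-based half-open span), \code{strand} and
#' \code{name}; random barcodes are recovered from \code{:rbc:<barcode>}
#' name suffixes. BAM files are read through Rsamtools when available.
#'
#' @param path alignment file (.tsv/.txt or .bam).
#' @return stranded \code{GRanges} with metadata columns \code{name} and
#'   \code{rbc}, ready for \code{\link{assignCrosslink}}.
#' @export
readAlignments <- function(path) {
    if (grepl("\\.bam$", path, ignore.case = TRUE)) {
        if (!requireNamespace("Rsamtools", quietly = TRUE))
            stop("reading BAM requires the Rsamtools package")
        p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos",
                                              "qwidth", "strand", "cigar"))
        b <- Rsamtools::scanBam(path, param = p)[[1L]]
        keep <- !is.na(b$pos)
        w <- cigar_ref_width(b$cigar[keep])
        gr <- GRanges(b$rname[keep], IRanges(b$pos[keep], width = w),
                      strand = b$strand[keep])
        nm <- b$qname[keep]
    } else {
        df <- utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        need <- c("contig", "start", "end", "strand", "name")
        if (!all(need %in% names(df)))
            stop("alignment TSV needs columns: ",
                 paste(need, collapse = ", "))
        # 0-based half-open spans in the file -> 1-based inclusive GRanges
        gr <- GRanges(df$contig, IRanges(df$start + 1L, df$end),
                      strand = df$strand)
        nm <- df$name
    }
    mcols(gr)$name <- nm
    mcols(gr)$rbc <- ifelse(grepl(":rbc:", nm), sub(".*:rbc:", "", nm),
                            NA_character_)
    gr
}

# reference-space width from CIGAR strings (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
    vapply(cigar, function(cg) {
        tok <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
        sum(vapply(tok, function(t) {
            n <- as.integer(sub("[A-Z=]$", "", t))
            if (grepl("[MDN=X]$", t)) n else 0L
        }, integer(1)))
    }, integer(1), USE.NAMES = FALSE)
}
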