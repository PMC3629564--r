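#' Barcode scheme for demultiplexing
#'
#' The iCLIP read layout is described 5' to 3' as a string over \code{N}
#' (random-barcode position) and \code{X} (experimental-barcode position).
#' The default layout \code{"NNNXXXXNN"} encodes a 4-nt experimental barcode
#' flanked by 3 + 2 random-barcode nucleotides (5 nt in total); the position
#' order within the read is an explicit, overridable assumption of this
#' package.
#'
#' @param layout string over \{N, X\}; X positions must be contiguous.
#' @param sample_table named character vector mapping experimental barcode to
#'   sample name.
#' @return A validated list with elements \code{layout}, \code{sample_table},
#'   \code{n_idx}, \code{x_idx}.
#' @examples
#' barcodeScheme("NNNXXXXNN", c(GGCA = "s1", TTAA = "s2"))
#' @export
barcodeScheme <- function(layout = "NNNXXXXNN", sample_table) {
    if (!nzchar(layout) || grepl("[^NX]", layout))
        stop("layout must be a non-empty string over {N, X}")
    chars <- strsplit(layout, "")[[1]]
    x_idx <- which(chars == "X")
    if (!length(x_idx) || any(diff(x_idx) != 1L))
        stop("experimental-barcode (X) positions must be contiguous")
    if (is.null(names(sample_table)) || any(!nzchar(names(sample_table))))
        stop("sample_table must be a named vector (barcode -> sample)")
    if (any(nchar(names(sample_table)) != length(x_idx)))
        stop("all barcodes must have length ", length(x_idx))
    list(layout = layout, sample_table = sample_table,
         n_idx = which(chars == "N"), x_idx = x_idx)
}

#' Demultiplex iCLIP reads by experimental barcode
#'
#' Splits reads by exact match of the experimental barcode against the sample
#' table, strips the whole barcode region from sequence and quality, and
#' appends the random barcode to the read identifier (as
#' \code{<name>:rbc:<barcode>}) so that PCR duplicates can be removed after
#' alignment. Reads with unknown experimental barcodes are routed to an
#' \code{unassigned} sink; reads shorter than the layout are counted and
#' skipped.
#'
#' @param reads path to a FASTQ file (gzip allowed) or a data.frame with
#'   columns \code{name}, \code{seq}, \code{qual}.
#' @param scheme A \code{\link{barcodeScheme}}.
#' @return list with \code{samples} (named list of data.frames \code{name},
#'   \code{seq}, \code{qual}), \code{unassigned} (same shape) and
#'   \code{tally} (named integer: assigned, unassigned, skipped).
#' @export
demultiplexReads <- function(reads, scheme) {
    if (is.character(reads)) {
        x <- Biostrings::readDNAStringSet(reads, format = "fastq",
                                          with.qualities = TRUE)
        reads <- data.frame(
            name = sub(" .*", "", names(x)),
            seq = as.character(x),
            qual = as.character(S4Vectors::mcols(x)$qualities),
            stringsAsFactors = FALSE)
    }
    bl <- nchar(scheme$layout)
    empty <- reads[0, , drop = FALSE]
    samples <- lapply(unique(unname(scheme$sample_table)), function(s) empty)
    names(samples) <- unique(unname(scheme$sample_table))
    unassigned <- empty
    tally <- c(assigned = 0L, unassigned = 0L, skipped = 0L)
    if (nrow(reads)) {
        short <- nchar(reads$seq) < bl + 1L
        tally["skipped"] <- sum(short)
        if (any(short))
            warning(sum(short), " read(s) shorter than the barcode layout ",
                    "were skipped")
        reads <- reads[!short, , drop = FALSE]
    }
    if (nrow(reads)) {
        bc_region <- substr(reads$seq, 1L, bl)
        split_bc <- function(idx) vapply(strsplit(bc_region, ""), function(v)
            paste(v[idx], collapse = ""), character(1))
        exp_bc <- split_bc(scheme$x_idx)
        rnd_bc <- split_bc(scheme$n_idx)
        out <- data.frame(
            name = paste0(reads$name, ":rbc:", rnd_bc),
            seq = substring(reads$seq, bl + 1L),
            qual = substring(reads$qual, bl + 1L),
            stringsAsFactors = FALSE)
        sample <- unname(scheme$sample_table[exp_bc])
        hit <- !is.na(sample)
        tally["assigned"] <- sum(hit)
        tally["unassigned"] <- sum(!hit)
        unassigned <- out[!hit, , drop = FALSE]
        for (s in names(samples))
            samples[[s]] <- out[hit & sample == s, , drop = FALSE]
    }
    list(samples = samples, unassigned = unassigned, tally = tally)
}

#' Assign the crosslink nucleotide of an aligned read
#'
#' In iCLIP, reverse transcription truncates at the crosslinked nucleotide,
#' so the crosslink site is the position immediately 5' of the read start in
#' transcript orientation: one base before the alignment start on the plus
#' strand, one base after the alignment end on the minus strand. Alignments
#' whose crosslink position would fall outside the contig are dropped and
#' tallied in \code{metadata()$n_dropped}.
#'
#' @param alignments \code{GRanges} of aligned reads (stranded); metadata
#'   columns (e.g. the random barcode \code{rbc}) are carried through.
#' @return width-1 \code{GRanges} of crosslink positions.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 140),
#'                              strand = "+")
#' assignCrosslink(gr)  # crosslink at position 100
#' @export
assignCrosslink <- function(alignments) {
    st <- as.character(strand(alignments))
    if (any(st == "*")) stop("alignments must be stranded")
    pos <- ifelse(st == "+", start(alignments) - 1L, end(alignments) + 1L)
    lens <- seqlengths(alignments)[as.character(seqnames(alignments))]
    keep <- pos >= 1L & (is.na(lens) | pos <= lens)
    out <- GRanges(seqnames(alignments)[keep],
                   IRanges(pos[keep], width = 1L), strand = st[keep])
    mcols(out) <- mcols(alignments)[keep, , drop = FALSE]
    seqlengths(out) <- seqlengths(alignments)
    metadata(out)$n_dropped <- sum(!keep)
    out
}

#' Collapse PCR duplicates into unique crosslink events
#'
#' Reads identical in (contig, strand, crosslink position, random barcode)
#' are PCR duplicates of one another and collapse to a single crosslink
#' event; all other reads are retained. The duplicate key uses the crosslink
#' position rather than the full alignment span, so trimming-length
#' differences do not split duplicates. Records without a random barcode are
#' rejected and tallied in \code{metadata()$n_rejected}.
#'
#' @param crosslinks width-1 \code{GRanges} from \code{\link{assignCrosslink}}
#'   with a random-barcode metadata column \code{rbc} (or read names carrying
#'   \code{:rbc:<barcode>} suffixes, from which \code{rbc} is recovered).
#' @return A \code{\link{CrosslinkTrack}} with \code{score} = unique events
#'   per position.
#' @export
collapseDuplicates <- function(crosslinks) {
    rbc <- mcols(crosslinks)$rbc
    if (is.null(rbc) && !is.null(mcols(crosslinks)$name) &&
        any(grepl(":rbc:", mcols(crosslinks)$name)))
        rbc <- sub(".*:rbc:", "", mcols(crosslinks)$name)
    if (is.null(rbc)) rbc <- rep(NA_character_, length(crosslinks))
    ok <- !is.na(rbc) & nzchar(rbc)
    n_rejected <- sum(!ok)
    crosslinks <- crosslinks[ok]
    rbc <- rbc[ok]
    key <- paste(seqnames(crosslinks), strand(crosslinks), start(crosslinks),
                 rbc, sep = "\r")
    uniq <- crosslinks[!duplicated(key)]
    poskey <- paste(seqnames(uniq), strand(uniq), start(uniq), sep = "\r")
    cnt <- table(poskey)
    rep1 <- uniq[!duplicated(poskey)]
    df <- data.frame(chrom = as.character(seqnames(rep1)),
                     pos = start(rep1),
                     strand = as.character(strand(rep1)),
                     count = as.integer(cnt[paste(seqnames(rep1),
                                                  strand(rep1), start(rep1),
                                                  sep = "\r")]))
    tr <- CrosslinkTrack(df)
    seqlengths(tr) <- seqlengths(crosslinks)
    metadata(tr)$n_rejected <- n_rejected
    tr
}

#' Annotate genomic positions by region category
#'
#' Assigns each position the highest-priority matching category of the
#' hierarchy ncRNA > 3'UTR > 5'UTR > exon > intron > antisense > intergenic
#' (all genic categories require the matching strand; "antisense" means
#' inside a gene on the opposite strand only). Intronic positions are further
#' subdivided into \code{intron_near3ss} (within 200 nt upstream of an exon
#' start in transcript orientation), \code{intron_near5ss} (within 200 nt
#' downstream of an exon end) and \code{intron_deep}; positions near both
#' splice sites take the closer one (ties go to the 3' splice site).
#'
#' @param positions width-1 \code{GRanges} (stranded).
#' @param annotation \code{GRanges} with metadata columns \code{type} (one of
#'   \code{gene}, \code{exon}, \code{five_prime_utr}, \code{three_prime_utr},
#'   \code{ncRNA}) and \code{gene_id}.
#' @param near_ss_dist intron subdivision distance (nt).
#' @return factor of region categories, one per position.
#' @export
annotatePositions <- function(positions, annotation, near_ss_dist = 200L) {
    if (!all(as.character(seqnames(positions)) %in%
             seqlevels(annotation)))
        stop("unknown contig in positions")
    type <- mcols(annotation)$type
    cats <- c("ncRNA", "utr3", "utr5", "exon", "intron_near3ss",
              "intron_near5ss", "intron_deep", "antisense", "intergenic")
    out <- rep(NA_character_, length(positions))

    hit_same <- function(feat) {
        overlapsAny(positions, feat, ignore.strand = FALSE)
    }
    assign_cat <- function(mask, cat) {
        sel <- is.na(out) & mask
        out[sel] <<- cat
        invisible(NULL)
    }
    assign_cat(hit_same(annotation[type == "ncRNA"]), "ncRNA")
    assign_cat(hit_same(annotation[type == "three_prime_utr"]), "utr3")
    assign_cat(hit_same(annotation[type == "five_prime_utr"]), "utr5")
    assign_cat(hit_same(annotation[type == "exon"]), "exon")

    genes <- annotation[type == "gene"]
    intronic <- is.na(out) & hit_same(genes)
    if (any(intronic)) {
        exons <- annotation[type == "exon"]
        idx <- which(intronic)
        pos <- start(positions)[idx]
        st <- as.character(strand(positions))[idx]
        # distance to the nearest exon start lying downstream (3'ss) and the
        # nearest exon end lying upstream (5'ss), in transcript orientation
        d3 <- rep(Inf, length(idx)); d5 <- rep(Inf, length(idx))
        for (i in seq_along(idx)) {
            ex <- exons[as.character(seqnames(exons)) ==
                            as.character(seqnames(positions))[idx[i]] &
                        as.character(strand(exons)) == st[i]]
            if (!length(ex)) next
            if (st[i] == "+") {
                dd3 <- start(ex) - pos[i]   # exon start downstream
                dd5 <- pos[i] - end(ex)     # exon end upstream
            } else {
                dd3 <- pos[i] - end(ex)
                dd5 <- start(ex) - pos[i]
            }
            if (any(dd3 > 0)) d3[i] <- min(dd3[dd3 > 0])
            if (any(dd5 > 0)) d5[i] <- min(dd5[dd5 > 0])
        }
        cat_i <- ifelse(d3 <= near_ss_dist & d3 <= d5, "intron_near3ss",
                 ifelse(d5 <= near_ss_dist, "intron_near5ss", "intron_deep"))
        out[idx] <- cat_i
    }
    anti <- is.na(out) & overlapsAny(positions, invertStrand(genes),
                                     ignore.strand = FALSE)
    out[is.na(out) & anti] <- "antisense"
    out[is.na(out)] <- "intergenic"
    factor(out, levels = cats)
}

#' Combine crosslink tracks by summing event counts
#'
#' @param tracks list of \code{\link{CrosslinkTrack}}s.
#' @return A \code{\link{CrosslinkTrack}} with per-position summed counts.
#' @export
combineTracks <- function(tracks) {
    all <- do.call(c, lapply(tracks, granges))
    sc <- unlist(lapply(tracks, score))
    key <- paste(seqnames(all), strand(all), start(all), sep = "\r")
    tot <- tapply(sc, key, sum)
    rep1 <- all[!duplicated(key)]
    df <- data.frame(chrom = as.character(seqnames(rep1)),
                     pos = start(rep1),
                     strand = as.character(strand(rep1)),
                     count = as.integer(tot[paste(seqnames(rep1),
                                                  strand(rep1), start(rep1),
                                                  sep = "\r")]))
    tr <- CrosslinkTrack(df)
    seqlengths(tr) <- seqlengths(tracks[[1L]])
    tr
}
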