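#' Exon splice-site coordinates in transcript orientation
#'
#' The acceptor (3' splice site) is the first exonic nucleotide and the donor
#' (5' splice site) the last, in transcript orientation.
#'
#' @param exons stranded \code{GRanges}.
#' @return data.frame with \code{acceptor} and \code{donor} genomic positions.
#' @export
spliceSiteCoords <- function(exons) {
    plus <- as.character(strand(exons)) == "+"
    data.frame(acceptor = ifelse(plus, start(exons), end(exons)),
               donor = ifelse(plus, end(exons), start(exons)))
}

junction_support <- function(chrom, pos, strand, junctions, role) {
    if (is.null(junctions) || !nrow(junctions)) return(rep(0L, length(pos)))
    key <- paste(chrom, strand, junctions_pos <- junctions[[role]], sep = "\r")
    tab <- tapply(junctions$count, paste(junctions$chrom, junctions$strand,
                                         junctions[[role]], sep = "\r"), sum)
    v <- tab[paste(chrom, strand, pos, sep = "\r")]
    v[is.na(v)] <- 0L
    as.integer(v)
}

#' Filter and merge de novo exon predictions
#'
#' Applies, in order: (a) exons must come from multi-exon transcripts, (b)
#' have at least one junction-spanning read at either splice site, and (c)
#' measure between 25 bp and 10 kb. Surviving exons that overlap and whose
#' respective starts and ends are each less than \code{merge_dist} bp apart
#' are merged (single linkage) into one exon spanning the outermost
#' boundaries, pooling transcript ids and junction support.
#'
#' @param exons \code{GRanges} of predicted exons with a
#'   \code{transcript_id} metadata column; exons of each transcript must
#'   appear in genomic order.
#' @param junctions data.frame with columns \code{chrom}, \code{acceptor},
#'   \code{donor}, \code{strand}, \code{count} (genomic splice-site
#'   positions: acceptor = first exonic nt, donor = last, in transcript
#'   orientation).
#' @param min_len,max_len exon size bounds (bp).
#' @param merge_dist merge tolerance for starts and ends (bp, exclusive).
#' @return \code{GRanges} of filtered, merged exons with metadata
#'   \code{transcript_ids}, \code{acceptor_reads}, \code{donor_reads}.
#' @export
filterExons <- function(exons, junctions, min_len = 25L, max_len = 10000L,
                        merge_dist = 25L) {
    tid <- as.character(mcols(exons)$transcript_id)
    if (is.null(tid)) stop("exons must carry a transcript_id column")
    for (tr in unique(tid)) {
        s <- start(exons)[tid == tr]
        if (is.unsorted(s) && is.unsorted(rev(s)))
            stop("unsorted exons in transcript ", tr)
    }
    # (a) multi-exon transcripts only
    multi <- tid %in% names(which(table(tid) >= 2L))
    exons <- exons[multi]; tid <- tid[multi]
    # (b) junction support at either splice site
    ss <- spliceSiteCoords(exons)
    chrom <- as.character(seqnames(exons))
    st <- as.character(strand(exons))
    acc <- junction_support(chrom, ss$acceptor, st, junctions, "acceptor")
    don <- junction_support(chrom, ss$donor, st, junctions, "donor")
    keep <- (acc + don) >= 1L
    exons <- exons[keep]; tid <- tid[keep]
    acc <- acc[keep]; don <- don[keep]
    # (c) size bounds
    keep <- width(exons) >= min_len & width(exons) <= max_len
    exons <- exons[keep]; tid <- tid[keep]
    acc <- acc[keep]; don <- don[keep]
    if (!length(exons)) {
        out <- granges(exons)
        mcols(out) <- DataFrame(transcript_ids = character(),
                                acceptor_reads = integer(),
                                donor_reads = integer())
        return(out)
    }
    # single-linkage merging of near-identical overlapping exons
    grp_key <- paste(as.character(seqnames(exons)),
                     as.character(strand(exons)))
    comp <- seq_along(exons)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    idx_by_grp <- split(seq_along(exons), grp_key)
    for (idx in idx_by_grp) {
        if (length(idx) < 2L) next
        for (a in seq_len(length(idx) - 1L)) for (b in (a + 1L):length(idx)) {
            i <- idx[a]; j <- idx[b]
            if (start(exons)[i] <= end(exons)[j] &&
                start(exons)[j] <= end(exons)[i] &&
                abs(start(exons)[i] - start(exons)[j]) < merge_dist &&
                abs(end(exons)[i] - end(exons)[j]) < merge_dist)
                comp[find(i)] <- find(j)
        }
    }
    root <- vapply(seq_along(exons), find, integer(1))
    merged <- lapply(split(seq_along(exons), root), function(members) {
        data.frame(chrom = as.character(seqnames(exons))[members[1L]],
                   start = min(start(exons)[members]),
                   end = max(end(exons)[members]),
                   strand = as.character(strand(exons))[members[1L]],
                   transcript_ids = paste(sort(unique(tid[members])),
                                          collapse = ","),
                   acceptor_reads = sum(acc[members]),
                   donor_reads = sum(don[members]))
    })
    df <- do.call(rbind, merged)
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    out <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                   transcript_ids = df$transcript_ids,
                   acceptor_reads = df$acceptor_reads,
                   donor_reads = df$donor_reads)
    seqlengths(out) <- seqlengths(exons)[seqlevels(out)]
    out
}

#' Assign exons to annotated genes
#'
#' An exon directly overlapping exactly one annotated gene (same strand) is
#' assigned to it; an exon overlapping none may inherit the gene of its
#' predicted gene model when that model overlaps exactly one annotated gene;
#' exons overlapping more than one annotated gene are discarded.
#'
#' @param exons stranded \code{GRanges}.
#' @param genes \code{GRanges} of annotated genes with \code{gene_id}.
#' @param models optional \code{GRanges} of predicted gene-model spans; exons
#'   are linked to models by overlap (same strand).
#' @return character vector of gene ids (NA = unassigned); discard reasons in
#'   \code{attr(, "reason")} (\code{"multi_gene"} where discarded).
#' @export
assignGenes <- function(exons, genes, models = NULL) {
    gid <- as.character(mcols(genes)$gene_id)
    out <- rep(NA_character_, length(exons))
    reason <- rep(NA_character_, length(exons))
    hits <- findOverlaps(exons, genes, ignore.strand = FALSE)
    n_hit <- countOverlaps(exons, genes, ignore.strand = FALSE)
    direct <- n_hit == 1L
    out[direct] <- gid[S4Vectors::subjectHits(hits)][
        match(which(direct), S4Vectors::queryHits(hits))]
    reason[n_hit > 1L] <- "multi_gene"
    if (!is.null(models)) {
        todo <- which(n_hit == 0L)
        for (i in todo) {
            mv <- which(overlapsAny(models, exons[i], ignore.strand = FALSE))
            if (!length(mv)) next
            g <- unique(gid[unique(S4Vectors::subjectHits(
                findOverlaps(models[mv], genes, ignore.strand = FALSE)))])
            if (length(g) == 1L) out[i] <- g
        }
    }
    attr(out, "reason") <- reason
    out
}

#' Classify Alu exons
#'
#' An Alu exon has at least one splice site (the boundary exonic nucleotide)
#' inside a repeat element annotated antisense to the exon's strand, with
#' that splice site supported by at least one junction-spanning read.
#'
#' @param exons stranded \code{GRanges}.
#' @param alus stranded \code{GRanges} of repeat elements.
#' @param junctions junction table as in \code{\link{filterExons}}.
#' @return data.frame with \code{acceptor_in_alu}, \code{donor_in_alu}
#'   (supported containment per site) and the combined \code{alu_exon} flag.
#' @export
classifyAluExons <- function(exons, alus, junctions) {
    ss <- spliceSiteCoords(exons)
    chrom <- as.character(seqnames(exons))
    st <- as.character(strand(exons))
    anti <- ifelse(st == "+", "-", "+")
    in_alu <- function(pos) {
        q <- GRanges(chrom, IRanges(pos, width = 1L), strand = anti)
        overlapsAny(q, alus, ignore.strand = FALSE)
    }
    acc_sup <- junction_support(chrom, ss$acceptor, st, junctions,
                                "acceptor") >= 1L
    don_sup <- junction_support(chrom, ss$donor, st, junctions,
                                "donor") >= 1L
    acc <- in_alu(ss$acceptor) & acc_sup
    don <- in_alu(ss$donor) & don_sup
    data.frame(acceptor_in_alu = acc, donor_in_alu = don,
               alu_exon = acc | don)
}

#' Predict transcript disruption by an included exon
#'
#' An exon introduces a frameshift when its length is not a multiple of 3;
#' stop codons (TAA, TAG, TGA on the transcript strand) are scanned in the
#' exon's three internal reading frames. The default disruption rule flags an
#' exon as disruptive when it introduces a frameshift or harbors a stop codon
#' in all three frames; the combination rule is explicit and logged when the
#' default is used.
#'
#' @param seq transcript-strand exon sequence(s), character vector.
#' @param rule \code{"frameshift_or_allstop"} (default) or
#'   \code{"frameshift_or_anystop"}.
#' @param quiet suppress the rule message.
#' @return data.frame with \code{frameshift}, \code{stop_frames} (0-3) and
#'   \code{disrupted}.
#' @export
predictDisruption <- function(seq, rule = c("frameshift_or_allstop",
                                            "frameshift_or_anystop"),
                              quiet = FALSE) {
    if (identical(rule, c("frameshift_or_allstop",
                          "frameshift_or_anystop")) && !quiet)
        message("predictDisruption: using default combination rule ",
                "'frameshift_or_allstop'")
    rule <- match.arg(rule)
    stops <- c("TAA", "TAG", "TGA")
    frame_has_stop <- function(s, off) {
        n <- nchar(s)
        if (1L + off > n - 2L) return(FALSE)
        starts <- seq(1L + off, n - 2L, by = 3L)
        any(substring(s, starts, starts + 2L) %in% stops)
    }
    stop_frames <- vapply(seq, function(s)
        sum(vapply(0:2, function(off) frame_has_stop(s, off), logical(1))),
        integer(1))
    frameshift <- nchar(seq) %% 3L != 0L
    disrupted <- if (rule == "frameshift_or_allstop")
        frameshift | stop_frames == 3L else frameshift | stop_frames > 0L
    data.frame(frameshift = frameshift, stop_frames = stop_frames,
               disrupted = disrupted, row.names = NULL)
}

#' Exon usage test (contingency-table stand-in)
#'
#' Tests differential exon usage between one knockdown and control with a
#' 2x2 contingency table of exon counts versus remaining gene counts:
#' Pearson's chi-square with continuity correction, or Fisher's exact test
#' when any expected cell is below 5. The fold change is the ratio of exon
#' counts normalized by gene counts (KD over control). This is an explicit
#' stand-in for a negative-binomial exon-usage fit: any per-exon p-value
#' column can be substituted downstream of it.
#'
#' @param exon_ctrl,rest_ctrl,exon_kd,rest_kd integer count vectors
#'   (replicates summed), aligned by exon.
#' @return data.frame with \code{p}, \code{fold_change}, \code{untestable}
#'   and \code{method}.
#' @export
exonUsageTest <- function(exon_ctrl, rest_ctrl, exon_kd, rest_kd) {
    n <- length(exon_ctrl)
    p <- numeric(n); fc <- numeric(n)
    untestable <- logical(n); method <- character(n)
    for (i in seq_len(n)) {
        tab <- matrix(c(exon_kd[i], rest_kd[i], exon_ctrl[i], rest_ctrl[i]),
                      nrow = 2L, byrow = TRUE)
        tot_kd <- exon_kd[i] + rest_kd[i]
        tot_ct <- exon_ctrl[i] + rest_ctrl[i]
        if (tot_kd == 0L || tot_ct == 0L) {
            p[i] <- 1; fc[i] <- NA_real_
            untestable[i] <- TRUE; method[i] <- "none"
            next
        }
        fc[i] <- (exon_kd[i] / tot_kd) / (exon_ctrl[i] / tot_ct)
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
            p[i] <- stats::fisher.test(tab)$p.value
            method[i] <- "fisher"
        } else {
            p[i] <- suppressWarnings(
                stats::chisq.test(tab, correct = TRUE)$p.value)
            method[i] <- "chisq"
        }
    }
    data.frame(p = p, fold_change = fc, untestable = untestable,
               method = method)
}

#' Conditional thresholding across two knockdowns
#'
#' A gene or exon is called reproducibly changed when it reaches p < 0.01 in
#' at least one knockdown and at least p < 0.05 in the second, with both fold
#' changes on the same side of 1.
#'
#' @param p1,p2 p-values from the two knockdowns.
#' @param fc1,fc2 optional fold changes; when supplied, concordant direction
#'   is required.
#' @return logical vector of significant calls.
#' @examples
#' conditionalThreshold(0.005, 0.03, 2, 1.5)  # TRUE
#' conditionalThreshold(0.02, 0.03)           # FALSE: neither p < 0.01
#' @export
conditionalThreshold <- function(p1, p2, fc1 = NULL, fc2 = NULL) {
    sig <- pmin(p1, p2) < 0.01 & pmax(p1, p2) < 0.05
    if (!is.null(fc1) && !is.null(fc2))
        sig <- sig & ((fc1 > 1 & fc2 > 1) | (fc1 < 1 & fc2 < 1))
    sig & !is.na(sig)
}

#' Categorize Alu-exon regulation
#'
#' Two-tier categorization of Alu exons: exons called by the conditional-
#' thresholding combiner are \code{up_called}/\code{down_called} by
#' direction; uncalled exons with a more than 2-fold change in at least one
#' knockdown are \code{up_2fold}/\code{down_2fold}; the rest are
#' \code{unchanged}. Separately, an exon is flagged \code{established} when
#' it accumulates at least \code{min_reads} reads across samples and is no
#' longer regulated: fold changes within (1/1.5, 1.5) in both knockdowns.
#'
#' @param p1,p2,fc1,fc2 per-knockdown usage-test results.
#' @param total_reads total reads over all samples per exon.
#' @param min_reads established-exon read threshold (default 50).
#' @return data.frame with \code{category} (factor) and \code{established}.
#' @export
categorizeAluRegulation <- function(p1, p2, fc1, fc2, total_reads,
                                    min_reads = 50L) {
    called <- conditionalThreshold(p1, p2, fc1, fc2)
    up <- fc1 > 1 & fc2 > 1
    category <- ifelse(called & up, "up_called",
                ifelse(called & !up, "down_called",
                ifelse(pmax(fc1, fc2, na.rm = TRUE) > 2, "up_2fold",
                ifelse(pmin(fc1, fc2, na.rm = TRUE) < 0.5, "down_2fold",
                       "unchanged"))))
    established <- total_reads >= min_reads &
        fc1 < 1.5 & fc2 < 1.5 & fc1 > 1 / 1.5 & fc2 > 1 / 1.5
    data.frame(category = factor(category, levels = c(
        "up_called", "down_called", "up_2fold", "down_2fold", "unchanged")),
        established = established & !is.na(established))
}
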