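#' Classify repeat-element orientation relative to genes
#'
#' \code{sense}: same strand as an overlapping gene; \code{antisense}:
#' opposite strand only; \code{ambiguous}: overlaps genes on both strands;
#' \code{intergenic}: overlaps no gene.
#'
#' @param alus stranded \code{GRanges} of repeat elements.
#' @param genes stranded \code{GRanges} of genes.
#' @return factor with levels sense, antisense, ambiguous, intergenic.
#' @export
classifyAluOrientation <- function(alus, genes) {
    same <- overlapsAny(alus, genes, ignore.strand = FALSE)
    opp <- overlapsAny(alus, invertStrand(genes), ignore.strand = FALSE)
    out <- ifelse(same & opp, "ambiguous",
           ifelse(same, "sense",
           ifelse(opp, "antisense", "intergenic")))
    factor(out, levels = c("sense", "antisense", "ambiguous", "intergenic"))
}

#' Map an element to consensus coordinates by global alignment
#'
#' Aligns one element copy (in consensus orientation) to the consensus with a
#' global affine-gap alignment (defaults: match +1, mismatch -1, gap open 5,
#' gap extension 1) and returns, for every element position, its aligned
#' consensus coordinate (NA at insertions relative to the consensus).
#' Elements whose length deviates from the consensus length by more than
#' \code{max_length_dev} are rejected.
#'
#' @param element_seq element sequence in consensus orientation (character).
#' @param consensus consensus sequence (character).
#' @param match,mismatch,gap_opening,gap_extension alignment scoring.
#' @param max_length_dev maximal relative length deviation (default 0.15).
#' @return integer vector of length \code{nchar(element_seq)}: consensus
#'   coordinate per element position, NA where the element base aligns to a
#'   gap; alignment score in \code{attr(, "score")}.
#' @export
alignToConsensus <- function(element_seq, consensus, match = 1,
                             mismatch = -1, gap_opening = 5,
                             gap_extension = 1, max_length_dev = 0.15) {
    if (!nzchar(element_seq)) stop("empty element sequence")
    ratio <- nchar(element_seq) / nchar(consensus)
    if (abs(ratio - 1) > max_length_dev)
        stop("element length outside +/-", max_length_dev * 100,
             "% of the consensus length")
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(element_seq), Biostrings::DNAString(consensus),
        type = "global", substitutionMatrix = mat,
        gapOpening = gap_opening, gapExtension = gap_extension)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    mapping <- integer(0)
    epos <- 0L; cpos <- 0L
    out <- rep(NA_integer_, nchar(element_seq))
    for (i in seq_along(ap)) {
        if (as_[i] != "-") cpos <- cpos + 1L
        if (ap[i] != "-") {
            epos <- epos + 1L
            out[epos] <- if (as_[i] != "-") cpos else NA_integer_
        }
    }
    attr(out, "score") <- Biostrings::score(pa)
    out
}

# genomic position -> element position in consensus orientation
g2e <- function(pos, elem_start, elem_end, elem_strand) {
    if (elem_strand == "+") pos - elem_start + 1L else elem_end - pos + 1L
}

#' Map Alu-exon splice sites onto the consensus
#'
#' Converts the acceptor and donor of each Alu exon to consensus coordinates
#' through the element's alignment mapping and accumulates per-coordinate
#' histograms. Exons lacking junction support at either splice site are
#' excluded; sites landing on alignment gaps are counted as unmapped. Each
#' acceptor is assigned an arm by its consensus coordinate relative to the
#' linker block.
#'
#' @param alu_exons data.frame with columns \code{element_id},
#'   \code{acceptor}, \code{donor} (genomic positions) and optionally
#'   \code{acceptor_reads}, \code{donor_reads} for the support filter.
#' @param elements \code{GRanges} of elements with \code{element_id}.
#' @param mappings named list (by element id) of mappings from
#'   \code{\link{alignToConsensus}}.
#' @param linker consensus-coordinate interval \code{c(start, end)} of the
#'   linker poly(A) block.
#' @return list with \code{per_exon} (consensus coordinates and \code{arm})
#'   and \code{histogram} (counts of acceptors and donors per consensus
#'   coordinate, plus an \code{unmapped} attribute).
#' @export
mapSpliceSites <- function(alu_exons, elements, mappings, linker) {
    if (!is.null(alu_exons$acceptor_reads))
        alu_exons <- alu_exons[alu_exons$acceptor_reads >= 1L &
                               alu_exons$donor_reads >= 1L, , drop = FALSE]
    eid <- as.character(mcols(elements)$element_id)
    idx <- match(alu_exons$element_id, eid)
    acc_c <- don_c <- rep(NA_integer_, nrow(alu_exons))
    for (i in seq_len(nrow(alu_exons))) {
        if (is.na(idx[i])) next
        mp <- mappings[[alu_exons$element_id[i]]]
        if (is.null(mp)) next
        es <- start(elements)[idx[i]]; ee <- end(elements)[idx[i]]
        st <- as.character(strand(elements))[idx[i]]
        for (role in c("acceptor", "donor")) {
            ep <- g2e(alu_exons[[role]][i], es, ee, st)
            val <- if (ep >= 1L && ep <= length(mp)) mp[ep] else NA_integer_
            if (role == "acceptor") acc_c[i] <- val else don_c[i] <- val
        }
    }
    arm <- ifelse(is.na(acc_c), "unmapped",
           ifelse(acc_c < linker[1L], "arm1",
           ifelse(acc_c > linker[2L], "arm2", "linker")))
    per_exon <- data.frame(alu_exons, acceptor_cons = acc_c,
                           donor_cons = don_c, arm = arm)
    coords <- sort(unique(c(acc_c[!is.na(acc_c)], don_c[!is.na(don_c)])))
    hist <- data.frame(
        coord = coords,
        acceptors = vapply(coords, function(cc)
            sum(acc_c == cc, na.rm = TRUE), integer(1)),
        donors = vapply(coords, function(cc)
            sum(don_c == cc, na.rm = TRUE), integer(1)))
    attr(hist, "unmapped") <- sum(is.na(acc_c)) + sum(is.na(don_c))
    list(per_exon = per_exon, histogram = hist)
}

#' Extract upstream and linker U-tract lengths of an element
#'
#' Measures the longest maximal A-run (uridines on the antisense transcript)
#' within the consensus-coordinate regions designated as the upstream (tail)
#' and linker poly(A) blocks, located on the element through its alignment
#' mapping. When the mapping has a gap over a region, the run is measured on
#' the element span between the flanking mapped coordinates.
#'
#' @param element_seq element sequence in consensus orientation.
#' @param mapping from \code{\link{alignToConsensus}}.
#' @param regions list with consensus intervals \code{tail} (upstream tract)
#'   and \code{linker} (see \code{\link{aluConsensusRegions}}).
#' @return named integer vector \code{c(upstream = ..., linker = ...)}.
#' @export
extractAluUtracts <- function(element_seq, mapping, regions) {
    region_span <- function(region) {
        inside <- which(!is.na(mapping) & mapping >= region[1L] &
                            mapping <= region[2L])
        if (length(inside)) return(range(inside))
        before <- which(!is.na(mapping) & mapping < region[1L])
        after <- which(!is.na(mapping) & mapping > region[2L])
        if (!length(before) || !length(after)) return(NULL)
        lo <- max(before) + 1L; hi <- min(after) - 1L
        if (lo > hi) return(NULL)
        c(lo, hi)
    }
    measure <- function(region) {
        span <- region_span(region)
        if (is.null(span)) return(0L)
        runs <- letter_runs(substring(element_seq, span[1L], span[2L]), "A")
        if (!nrow(runs)) 0L else max(runs$length)
    }
    c(upstream = measure(regions$tail), linker = measure(regions$linker))
}

#' U-tract cumulative-frequency selection statistic
#'
#' For each tract length L, the ratio between the fraction of U-tracts of at
#' least L uridines in the exonized element set and the corresponding
#' fraction in its matched control set (nonexonized antisense elements of the
#' same genes), with a p-value from Pearson's chi-square test on the 2x2
#' table (exonized/control x >=L / <L), replaced by Fisher's exact test when
#' any cell is below five. A ratio with an empty control fraction is
#' undefined and flagged.
#'
#' @param exonized,control integer vectors of tract lengths.
#' @param lengths grid of L values (default 3:12).
#' @return data.frame with \code{L}, \code{frac_exonized},
#'   \code{frac_control}, \code{ratio}, \code{p}, \code{method},
#'   \code{undefined}.
#' @export
utractRatio <- function(exonized, control, lengths = 3:12) {
    stopifnot(length(exonized) > 0L, length(control) > 0L)
    rows <- lapply(lengths, function(L) {
        a <- sum(exonized >= L); b <- sum(exonized < L)
        c_ <- sum(control >= L); d <- sum(control < L)
        fe <- a / (a + b); fc <- c_ / (c_ + d)
        undefined <- fc == 0
        ratio <- if (undefined) NA_real_ else fe / fc
        tab <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE)
        if (any(tab < 5)) {
            p <- stats::fisher.test(tab)$p.value
            method <- "fisher"
        } else {
            p <- suppressWarnings(
                stats::chisq.test(tab, correct = FALSE)$p.value)
            method <- "chisq"
        }
        data.frame(L = L, frac_exonized = fe, frac_control = fc,
                   ratio = ratio, p = p, method = method,
                   undefined = undefined)
    })
    do.call(rbind, rows)
}
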