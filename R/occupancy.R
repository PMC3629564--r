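#' Gene-normalized binding-site occupancies
#'
#' For each binding site and each supplied track (condition), counts the
#' crosslink events within the site — over the full interval (\code{mode =
#' "full"}) or an 11-nt window centered on the summit (\code{mode =
#' "summit11"}, the convention for broad binders) — and normalizes by the
#' gene total (sum of events over the gene's binding sites in that condition,
#' or over all gene positions with \code{gene_total = "gene"}) times the gene
#' length. Sites overlapping more than one annotated gene (either strand) are
#' excluded; sites on genes with zero total are flagged undefined.
#'
#' @param sites A \code{\link{BindingSites}} object.
#' @param tracks named list of \code{\link{CrosslinkTrack}}s, one per
#'   condition/sample.
#' @param genes \code{GRanges} of gene bodies with \code{gene_id}.
#' @param mode \code{"full"} or \code{"summit11"}.
#' @param gene_total \code{"sites"} (default: events within the gene's
#'   binding sites) or \code{"gene"} (all events within the gene boundaries).
#' @return data.frame with one row per retained site: site coordinates,
#'   \code{gene_id}, per-condition raw counts \code{count.<cond>}, gene
#'   totals \code{gene_total.<cond>}, occupancies \code{occ.<cond>} and an
#'   \code{undefined} flag; excluded multi-gene sites are reported in
#'   \code{attr(, "n_excluded")}.
#' @export
siteOccupancies <- function(sites, tracks, genes, mode = c("full", "summit11"),
                            gene_total = c("sites", "gene")) {
    mode <- match.arg(mode)
    gene_total <- match.arg(gene_total)
    stopifnot(is.list(tracks), !is.null(names(tracks)))
    ov <- countOverlaps(sites, genes, ignore.strand = TRUE)
    n_excluded <- sum(ov > 1L)
    sites <- sites[ov == 1L]
    m <- mcols(sites)
    glen <- width(genes)[match(m$gene_id, mcols(genes)$gene_id)]

    count_win <- if (mode == "full") granges(sites) else
        GRanges(seqnames(sites),
                IRanges(pmax(m$summit - 5L, 1L), m$summit + 5L),
                strand = strand(sites))

    out <- data.frame(site_id = seq_along(sites),
                      chrom = as.character(seqnames(sites)),
                      start = start(sites), end = end(sites),
                      strand = as.character(strand(sites)),
                      summit = m$summit, gene_id = m$gene_id,
                      gene_length = glen)
    for (cond in names(tracks)) {
        tr <- tracks[[cond]]
        hits <- findOverlaps(count_win, tr, ignore.strand = FALSE)
        k <- rep(0, length(sites))
        agg <- tapply(score(tr)[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits), sum)
        k[as.integer(names(agg))] <- agg
        if (gene_total == "sites") {
            fhits <- findOverlaps(granges(sites), tr, ignore.strand = FALSE)
            kfull <- rep(0, length(sites))
            fagg <- tapply(score(tr)[S4Vectors::subjectHits(fhits)],
                           S4Vectors::queryHits(fhits), sum)
            kfull[as.integer(names(fagg))] <- fagg
            gt_map <- tapply(kfull, m$gene_id, sum)
        } else {
            gidx <- match(unique(m$gene_id), mcols(genes)$gene_id)
            gt_map <- vapply(gidx, function(i)
                sum(score(tr)[overlapsAny(tr, genes[i],
                                          ignore.strand = FALSE)]),
                numeric(1))
            names(gt_map) <- unique(m$gene_id)
        }
        gt <- as.numeric(gt_map[m$gene_id])
        out[[paste0("count.", cond)]] <- k
        out[[paste0("gene_total.", cond)]] <- gt
        out[[paste0("occ.", cond)]] <- ifelse(gt > 0, k / (gt * glen), NA)
    }
    occ_cols <- grep("^occ\\.", names(out))
    out$undefined <- apply(is.na(out[, occ_cols, drop = FALSE]), 1L, any)
    attr(out, "n_excluded") <- n_excluded
    out
}

#' Decile ranks of binding-site occupancies
#'
#' Sorts sites by occupancy (ascending, stable so ties keep input order) and
#' splits them into 10 equal-count bins; any remainder is spread over the
#' lowest bins, so rank 10 always holds the 10% strongest sites.
#'
#' @param occupancies numeric vector (at least 10 values).
#' @return integer vector of ranks 1..10, aligned with the input.
#' @export
occupancyRanks <- function(occupancies) {
    n <- length(occupancies)
    if (n < 10L) stop("need at least 10 sites to form decile ranks")
    ord <- order(occupancies)  # stable in R
    base <- n %/% 10L
    extra <- n %% 10L
    bin_sizes <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
    ranks_sorted <- rep(1:10, times = bin_sizes)
    out <- integer(n)
    out[ord] <- ranks_sorted
    out
}

#' Median-of-ratios size factors
#'
#' The per-sample scaling constant is the median, over sites whose counts are
#' positive in every sample, of the site's count divided by its geometric
#' mean across samples — the standard median-of-ratios normalization for
#' count matrices.
#'
#' @param mat numeric matrix, sites x samples.
#' @return numeric vector of per-sample size factors.
#' @examples
#' medianRatioSizeFactors(cbind(c(1, 2, 3), c(2, 4, 6)))
#' @export
medianRatioSizeFactors <- function(mat) {
    mat <- as.matrix(mat)
    if (any(mat < 0)) stop("counts must be non-negative")
    pos <- rowSums(mat > 0) == ncol(mat)
    if (!any(pos)) stop("no site has positive counts in all samples")
    geo <- exp(rowMeans(log(mat[pos, , drop = FALSE])))
    apply(mat[pos, , drop = FALSE], 2L, function(col)
        stats::median(col / geo))
}

#' Differential binding between knockdown and control
#'
#' Computes \code{log2((occ_kd / f_kd + eps) / (occ_ctrl / f_ctrl + eps))}
#' and assigns each site a category: \code{up} for at least four-fold
#' increase (ratio >= 2), \code{down} for at least four-fold decrease (ratio
#' <= -2), \code{unchanged} for |ratio| < 0.1, and \code{other} in between.
#' The pseudocount defaults to half the smallest positive size-factor-
#' corrected occupancy, so zero-count conditions yield finite ratios.
#'
#' @param occ_ctrl,occ_kd numeric occupancy vectors (aligned by site).
#' @param factors length-2 numeric: size factors \code{c(ctrl, kd)}.
#' @param pseudocount numeric epsilon or \code{"auto"}.
#' @return data.frame with \code{log2fc} and \code{category}; the pseudocount
#'   used is attached as \code{attr(, "pseudocount")}.
#' @export
differentialBinding <- function(occ_ctrl, occ_kd, factors = c(1, 1),
                                pseudocount = "auto") {
    if (any(occ_ctrl < 0, na.rm = TRUE) || any(occ_kd < 0, na.rm = TRUE))
        stop("occupancies must be non-negative")
    c_corr <- occ_ctrl / factors[1L]
    k_corr <- occ_kd / factors[2L]
    if (identical(pseudocount, "auto")) {
        posvals <- c(c_corr[c_corr > 0], k_corr[k_corr > 0])
        pseudocount <- if (length(posvals)) min(posvals) / 2 else 1e-12
    }
    lfc <- log2((k_corr + pseudocount) / (c_corr + pseudocount))
    # the four-fold boundaries are inclusive; tolerate float noise from the
    # pseudocount at exact fold changes
    tol <- 1e-9
    category <- ifelse(lfc >= 2 - tol, "up",
                ifelse(lfc <= -2 + tol, "down",
                ifelse(abs(lfc) < 0.1, "unchanged", "other")))
    out <- data.frame(log2fc = lfc, category = factor(
        category, levels = c("up", "down", "unchanged", "other")))
    attr(out, "pseudocount") <- pseudocount
    out
}

#' Longest U-tract overlapping an interval
#'
#' Indexes all maximal uridine runs of three or more (T on the DNA
#' transcript-strand sequence) and returns the length of the longest run
#' overlapping the query interval by at least one nucleotide, or 0.
#'
#' @param start,end 1-based interval within \code{seq} (vectorized).
#' @param seq transcript-strand DNA sequence (character).
#' @param min_run minimal run length indexed (default 3).
#' @return integer vector of tract lengths.
#' @export
longestUtractOverlap <- function(start, end, seq, min_run = 3L) {
    n <- nchar(seq)
    if (any(start < 1L | end > n | start > end))
        stop("site interval outside the sequence")
    runs <- letter_runs(seq, "T")
    runs <- runs[runs$length >= min_run, , drop = FALSE]
    if (!nrow(runs)) return(integer(length(start)))
    rs <- runs$start; re <- runs$start + runs$length - 1L
    vapply(seq_along(start), function(i) {
        ov <- rs <= end[i] & re >= start[i]
        if (any(ov)) max(runs$length[ov]) else 0L
    }, integer(1))
}

#' Overlap between two binding-site sets
#'
#' @param sites_a,sites_b \code{GRanges} (or \code{BindingSites}); overlap
#'   requires at least 1 nt on the same strand.
#' @return logical vector: for each site in \code{sites_a}, whether it
#'   overlaps any site in \code{sites_b}.
#' @export
overlapSites <- function(sites_a, sites_b) {
    overlapsAny(sites_a, sites_b, ignore.strand = FALSE)
}

#' Venn-style overlap counts for two or three site sets
#'
#' Pools all site intervals, reduces them to disjoint regions (per strand)
#' and counts each region's membership pattern across the input sets.
#'
#' @param site_sets named list of 2 or 3 \code{GRanges}.
#' @return table of membership-pattern counts (e.g. \code{"A&B"}).
#' @export
siteVenn <- function(site_sets) {
    stopifnot(length(site_sets) %in% 2:3, !is.null(names(site_sets)))
    regions <- GenomicRanges::reduce(
        do.call(c, unname(lapply(site_sets, granges))),
        ignore.strand = FALSE)
    member <- vapply(site_sets, function(s)
        overlapsAny(regions, s, ignore.strand = FALSE),
        logical(length(regions)))
    member <- matrix(member, nrow = length(regions),
                     dimnames = list(NULL, names(site_sets)))
    pat <- apply(member, 1L, function(row)
        paste(names(site_sets)[row], collapse = "&"))
    table(pat)
}
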