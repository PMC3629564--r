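#' Per-exon crosslink matrix around a splice site
#'
#' Builds the positional matrix underlying RNA maps and heatmaps: one row per
#' exon, one column per offset relative to the anchor splice site, in
#' transcript orientation. Offset 0 is the first exonic nucleotide for the 3'
#' splice site anchor (the last exonic nucleotide for the 5' splice site
#' anchor); negative offsets are intronic for the 3' splice site.
#'
#' @param exons stranded \code{GRanges}.
#' @param track A \code{\link{CrosslinkTrack}}.
#' @param window integer length-2 offset range, e.g. \code{c(-50, 10)}.
#' @param anchor \code{"3ss"} (exon start in transcript orientation) or
#'   \code{"5ss"} (exon end).
#' @return numeric matrix (exons x offsets) of crosslink-event counts, with
#'   offsets as column names.
#' @export
positionalMatrix <- function(exons, track, window = c(-50L, 10L),
                             anchor = c("3ss", "5ss")) {
    anchor <- match.arg(anchor)
    offs <- seq(window[1L], window[2L])
    ss <- spliceSiteCoords(exons)
    anchor_pos <- if (anchor == "3ss") ss$acceptor else ss$donor
    plus <- as.character(strand(exons)) == "+"
    mat <- matrix(0, nrow = length(exons), ncol = length(offs),
                  dimnames = list(NULL, offs))
    if (!length(exons) || !length(track)) return(mat)
    tr_by <- split(seq_along(track),
                   paste(seqnames(track), strand(track), sep = "\r"))
    key <- paste(seqnames(exons), strand(exons), sep = "\r")
    for (i in seq_along(exons)) {
        idx <- tr_by[[key[i]]]
        if (is.null(idx)) next
        pos <- start(track)[idx]
        off <- if (plus[i]) pos - anchor_pos[i] else anchor_pos[i] - pos
        sel <- off >= window[1L] & off <= window[2L]
        if (any(sel))
            mat[i, as.character(off[sel])] <-
                mat[i, as.character(off[sel])] + score(track)[idx][sel]
    }
    mat
}

#' RNA map of crosslink events around splice sites
#'
#' Positional summary over an exon set: for each offset relative to the
#' anchor splice site, either the percentage of exons with at least one
#' crosslink event (\code{mode = "percentage"}) or the total number of
#' events, optionally corrected for library size (\code{mode = "total"}).
#'
#' @param exons stranded \code{GRanges}.
#' @param track A \code{\link{CrosslinkTrack}}.
#' @param window offset range in transcript orientation.
#' @param anchor \code{"3ss"} or \code{"5ss"}.
#' @param mode \code{"percentage"} or \code{"total"}.
#' @param size_factor library-size factor; totals are divided by it.
#' @return named numeric vector, one value per offset.
#' @export
rnaMap <- function(exons, track, window = c(-50L, 50L),
                   anchor = c("3ss", "5ss"),
                   mode = c("percentage", "total"), size_factor = 1) {
    if (!length(exons)) stop("empty exon set")
    mode <- match.arg(mode)
    mat <- positionalMatrix(exons, track, window, match.arg(anchor))
    if (mode == "percentage") 100 * colMeans(mat > 0)
    else colSums(mat) / size_factor
}

#' Splice-site heatmap matrices
#'
#' Builds one positional matrix per track over a common exon set and window,
#' keeping only exons with at least \code{min_events} crosslink events in the
#' window of the designated filter track; row order is identical across
#' matrices and follows the supplied sort key (descending).
#'
#' @param exons stranded \code{GRanges}.
#' @param tracks named list of \code{\link{CrosslinkTrack}}s.
#' @param window offset range relative to the 3' splice site (default
#'   \code{c(-50, 10)}).
#' @param min_events minimal events within the window (default 5) in the
#'   filter track.
#' @param filter_track name of the track used for the row filter (default:
#'   first track).
#' @param sort_key optional numeric vector (one per exon, e.g. inclusion fold
#'   change); retained rows are ordered by it, descending.
#' @return list with \code{matrices} (named list, filtered and ordered
#'   identically), \code{rows} (indices of retained exons in input order) and
#'   \code{sort_key} (reordered key, if supplied).
#' @export
spliceSiteHeatmap <- function(exons, tracks, window = c(-50L, 10L),
                              min_events = 5L, filter_track = names(tracks)[1L],
                              sort_key = NULL) {
    stopifnot(is.list(tracks), !is.null(names(tracks)),
              filter_track %in% names(tracks))
    mats <- lapply(tracks, function(tr)
        positionalMatrix(exons, tr, window, anchor = "3ss"))
    keep <- which(rowSums(mats[[filter_track]]) >= min_events)
    if (!is.null(sort_key)) {
        keep <- keep[order(sort_key[keep], decreasing = TRUE)]
        key_out <- sort_key[keep]
    } else key_out <- NULL
    mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
    list(matrices = mats, rows = keep, sort_key = key_out)
}

# Collapsed, weight-aware pentamer counts over windows around positions.
# Windows around position p cover all 5-mers touching [p - flank, p + flank]
# on the transcript strand. Weights group identical-count positions so the
# Biostrings counting stays a single collapsed pass per weight value.
pentamer_counts <- function(positions_by_gene, weights_by_gene, gene_tseq,
                            flank, k = 5L) {
    counts <- numeric(4^k)
    names(counts) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    all_w <- unlist(weights_by_gene, use.names = FALSE)
    if (!length(all_w)) return(counts)
    for (w in sort(unique(all_w))) {
        windows <- character(0)
        for (gid in names(positions_by_gene)) {
            pos <- positions_by_gene[[gid]]
            wt <- weights_by_gene[[gid]]
            pos <- pos[wt == w]
            if (!length(pos)) next
            seq <- gene_tseq[[gid]]
            lo <- pmax(pos - flank - (k - 1L), 1L)
            hi <- pmin(pos + flank + (k - 1L), nchar(seq))
            windows <- c(windows, substring(seq, lo, hi))
        }
        if (!length(windows)) next
        freq <- Biostrings::oligonucleotideFrequency(
            Biostrings::DNAStringSet(windows), width = k,
            simplify.as = "collapsed")
        counts <- counts + w * freq
    }
    counts
}

#' Pentamer enrichment around crosslink sites
#'
#' Compares the event-count-weighted frequency of every 5-mer covering any
#' position within \code{flank} nt of a crosslink nucleotide (on the
#' transcript strand) against the same computation on positions randomized
#' uniformly within the same genes. The expected count is floored at one
#' occurrence so that unobserved pentamers yield finite enrichment.
#'
#' @param track A \code{\link{CrosslinkTrack}}.
#' @param genes \code{GRanges} of gene bodies with \code{gene_id}.
#' @param gene_tseq named character: transcript-strand sequence per gene.
#' @param flank window half-width around the crosslink nucleotide (nt).
#' @param iterations randomization iterations for the background.
#' @param seed integer seed.
#' @return data.frame with \code{pentamer} (RNA alphabet), \code{observed},
#'   \code{expected} and \code{enrichment}, sorted by decreasing enrichment.
#' @export
pentamerEnrichment <- function(track, genes, gene_tseq, flank = 10L,
                               iterations = 20L, seed = 1L) {
    if (!length(track) || totalEvents(track) == 0L) stop("zero events")
    gid <- as.character(mcols(genes)$gene_id)
    hits <- findOverlaps(track, genes, ignore.strand = FALSE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    pos_t <- integer(length(q))
    plus <- as.character(strand(genes))[s] == "+"
    pos_t[plus] <- start(track)[q[plus]] - start(genes)[s[plus]] + 1L
    pos_t[!plus] <- end(genes)[s[!plus]] - start(track)[q[!plus]] + 1L
    positions_by_gene <- split(pos_t, gid[s])
    weights_by_gene <- split(as.numeric(score(track)[q]), gid[s])

    observed <- pentamer_counts(positions_by_gene, weights_by_gene,
                                gene_tseq, flank)
    n_by_gene <- vapply(weights_by_gene, function(w) as.integer(sum(w)),
                        integer(1))
    glen <- stats::setNames(width(genes), gid)
    expected <- numeric(length(observed))
    with_local_seed(seed, {
        for (r in seq_len(iterations)) {
            rnd_pos <- lapply(names(n_by_gene), function(g)
                sample.int(glen[[g]], n_by_gene[[g]], replace = TRUE))
            names(rnd_pos) <- names(n_by_gene)
            rnd_w <- lapply(rnd_pos, function(p) rep(1, length(p)))
            expected <- expected + pentamer_counts(rnd_pos, rnd_w, gene_tseq,
                                                   flank)
        }
    })
    expected <- pmax(expected / iterations, 1)
    obs_f <- observed / sum(observed)
    exp_f <- expected / sum(expected)
    out <- data.frame(pentamer = chartr("T", "U", names(observed)),
                      observed = as.numeric(observed),
                      expected = as.numeric(expected),
                      enrichment = as.numeric(obs_f / exp_f))
    out[order(-out$enrichment), , drop = FALSE]
}

#' Co-binding profile of another RBP around binding-site summits
#'
#' For each offset in \code{[-half_window, +half_window]} (transcript
#' orientation), the fraction of query summits covered by a site of the other
#' RBP at that offset, normalized to the mean background frequency in two
#' 10-nt windows 90 nt up- and downstream of the summit (offsets
#' \code{[-99, -90]} and \code{[+90, +99]}). A zero background leaves the
#' normalized profile undefined (flagged).
#'
#' @param sites A \code{\link{BindingSites}} (query; summits anchor the
#'   profile).
#' @param other_sites \code{GRanges} of the other RBP's binding sites.
#' @param half_window profile half-width (nt, default 100).
#' @return list with \code{offset}, \code{frequency}, \code{normalized},
#'   \code{background} and \code{undefined} flag.
#' @export
rbpOverlapProfile <- function(sites, other_sites, half_window = 100L) {
    offs <- seq(-half_window, half_window)
    summit <- mcols(sites)$summit
    plus <- as.character(strand(sites)) == "+"
    freq <- numeric(length(offs))
    if (length(sites)) {
        ob <- split(seq_along(other_sites),
                    paste(seqnames(other_sites), strand(other_sites),
                          sep = "\r"))
        key <- paste(seqnames(sites), strand(sites), sep = "\r")
        cov <- matrix(FALSE, nrow = length(sites), ncol = length(offs))
        for (i in seq_along(sites)) {
            idx <- ob[[key[i]]]
            if (is.null(idx)) next
            pos <- if (plus[i]) summit[i] + offs else summit[i] - offs
            cov[i, ] <- vapply(pos, function(p)
                any(start(other_sites)[idx] <= p & end(other_sites)[idx] >= p),
                logical(1))
        }
        freq <- colMeans(cov)
    }
    names(freq) <- offs
    bg_idx <- offs %in% c(seq(-99L, -90L), seq(90L, 99L))
    background <- mean(freq[bg_idx])
    undefined <- !is.finite(background) || background == 0
    normalized <- if (undefined) rep(NA_real_, length(offs)) else
        freq / background
    names(normalized) <- offs
    list(offset = offs, frequency = freq, normalized = normalized,
         background = background, undefined = undefined)
}
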