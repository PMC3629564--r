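#' Competition analysis of differential binding at planted tracts
#'
#' Runs the quantitative differential-binding pipeline on a synthetic
#' dataset: collapses the control and knockdown tracks of the competed
#' protein, calls binding sites on the collapsed track, computes
#' gene-normalized occupancies per condition, median-of-ratios size factors
#' and log2 knockdown/control ratios, then stratifies sites by overlap with
#' the planted competitor-bound U-tracts and by planted-affinity decile.
#'
#' @param genome output of \code{\link{generateGenome}}.
#' @param tracks output of \code{\link{generateCrosslinkTracks}} (the
#'   \code{U2AF65} control/knockdown pair is analyzed).
#' @param flank peak-calling window half-width (nt; 5 for the focused
#'   binder).
#' @param iterations randomization iterations for the peak caller.
#' @param seed integer seed.
#' @return list with \code{sites} (per-site table: occupancies, log2fc,
#'   category, \code{tract_overlap}, planted \code{affinity}),
#'   \code{mean_lfc_tract}, \code{mean_lfc_other}, \code{t_p} (one-sided
#'   t-test p that tract-overlapping sites shift more), \code{decile_means}
#'   (mean log2fc per planted-affinity decile) and \code{spearman_rho}.
#' @export
competitionAnalysis <- function(genome, tracks, flank = 5L,
                                iterations = 100L, seed = 1L) {
    combined <- combineTracks(list(tracks$U2AF65$ctrl, tracks$U2AF65$kd))
    sites <- callBindingSites(combined, genome$genes, flank = flank,
                              iterations = iterations, seed = seed)
    occ <- siteOccupancies(sites, list(ctrl = tracks$U2AF65$ctrl,
                                       kd = tracks$U2AF65$kd), genome$genes)
    occ <- occ[!occ$undefined, , drop = FALSE]
    f <- medianRatioSizeFactors(as.matrix(occ[, c("occ.ctrl", "occ.kd")]))
    db <- differentialBinding(occ$occ.ctrl, occ$occ.kd, f)
    occ$log2fc <- db$log2fc
    occ$category <- db$category

    tracts <- genome$truth@tracts
    tract_gr <- GRanges(tracts$chrom, IRanges(tracts$start, tracts$end),
                        strand = tracts$strand)
    site_gr <- GRanges(occ$chrom, IRanges(occ$start, occ$end),
                       strand = occ$strand)
    hits <- findOverlaps(site_gr, tract_gr)
    occ$tract_overlap <- seq_len(nrow(occ)) %in% S4Vectors::queryHits(hits)
    occ$affinity <- NA_real_
    agg <- tapply(tracts$lambda_c[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), max)
    occ$affinity[as.integer(names(agg))] <- agg

    lfc_t <- occ$log2fc[occ$tract_overlap]
    lfc_o <- occ$log2fc[!occ$tract_overlap]
    t_p <- stats::t.test(lfc_t, lfc_o, alternative = "greater")$p.value
    dec <- occupancyRanks(occ$affinity[occ$tract_overlap])
    decile_means <- tapply(lfc_t, dec, mean)
    rho <- stats::cor(as.numeric(names(decile_means)), decile_means,
                      method = "spearman")
    list(sites = occ, size_factors = f,
         mean_lfc_tract = mean(lfc_t), mean_lfc_other = mean(lfc_o),
         t_p = t_p, decile_means = decile_means, spearman_rho = rho)
}
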