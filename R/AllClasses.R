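#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels
#' @importFrom BiocGenerics start end width strand score
NULL

#' Crosslink-event track
#'
#' A \code{CrosslinkTrack} stores deduplicated crosslink events as a
#' strand-aware, single-nucleotide \code{GRanges}: each range has width 1 and
#' carries the number of unique crosslink events at that nucleotide in its
#' \code{score} column. This is the central quantitative object of the
#' package; one track corresponds to one protein in one condition (replicate
#' libraries are summed before or after construction).
#'
#' @slot .Data inherits the \code{GRanges} representation.
#' @export
setClass("CrosslinkTrack", contains = "GRanges")

setValidity("CrosslinkTrack", function(object) {
    msg <- character()
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "all crosslink events must have width 1")
        if (is.null(score(object)))
            msg <- c(msg, "a 'score' metadata column (event count) is required")
        else if (any(score(object) < 1))
            msg <- c(msg, "event counts must be >= 1")
        if (any(as.character(strand(object)) == "*"))
            msg <- c(msg, "crosslink events must be stranded")
        if (anyDuplicated(paste(seqnames(object), start(object),
                                strand(object))))
            msg <- c(msg, "positions must be unique per contig and strand")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CrosslinkTrack
#'
#' @param x A \code{GRanges} of width-1 stranded positions with a
#'   \code{score} column, or a data.frame with columns \code{chrom},
#'   \code{pos} (1-based), \code{strand} and \code{count}.
#' @return A \code{CrosslinkTrack}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 12), width = 1),
#'                              strand = "+", score = c(3L, 1L))
#' CrosslinkTrack(gr)
#' @export
CrosslinkTrack <- function(x) {
    if (is.data.frame(x)) {
        x <- GRanges(x$chrom, IRanges(x$pos, width = 1L),
                     strand = x$strand, score = as.integer(x$count))
    }
    x <- sort(x, ignore.strand = TRUE)
    new("CrosslinkTrack", x)
}

setMethod("show", "CrosslinkTrack", function(object) {
    cat("CrosslinkTrack with", length(object), "crosslinked positions and",
        sum(score(object)), "events\n")
    callNextMethod()
})

#' Total number of crosslink events in a track
#'
#' @param track A \code{CrosslinkTrack}.
#' @return Integer: the sum of per-position unique event counts.
#' @export
totalEvents <- function(track) {
    if (!length(track)) return(0L)
    as.integer(sum(score(track)))
}

#' Called binding sites
#'
#' A \code{BindingSites} object is a \code{GRanges} of significant
#' crosslink-event clusters. Required metadata columns: \code{summit}
#' (position with most events, 1-based), \code{n_events} (events within the
#' site), \code{fdr} (empirical FDR of the site's maximal height) and
#' \code{gene_id}.
#'
#' @export
setClass("BindingSites", contains = "GRanges")

setValidity("BindingSites", function(object) {
    msg <- character()
    need <- c("summit", "n_events", "fdr", "gene_id")
    miss <- setdiff(need, colnames(mcols(object)))
    if (length(miss))
        msg <- c(msg, paste("missing metadata column(s):",
                            paste(miss, collapse = ", ")))
    if (!length(msg) && length(object)) {
        m <- mcols(object)
        if (any(m$summit < start(object) | m$summit > end(object)))
            msg <- c(msg, "summit must lie within the site interval")
        if (any(m$n_events < 1))
            msg <- c(msg, "sites must contain at least one event")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname BindingSites-class
#' @param gr A \code{GRanges} with the required metadata columns.
#' @export
BindingSites <- function(gr) new("BindingSites", gr)

setMethod("show", "BindingSites", function(object) {
    cat("BindingSites:", length(object), "sites on",
        length(unique(mcols(object)$gene_id)), "genes\n")
    callNextMethod()
})

#' Synthetic-dataset configuration
#'
#' Holds every tunable of the synthetic-data generator: the toy genome
#' layout, the Alu-like element anatomy, U-tract length distributions for the
#' exonized and control element sets, crosslink emission rates, the
#' competition model (affinity gain \code{alpha}, pyrimidine affinity
#' \code{beta}, suppression \code{s}, occupancy saturation scale
#' \code{occ_scale}), the logistic inclusion link (\code{gamma},
#' \code{psi_threshold}), sequencing depth and the global seed.
#'
#' @slot n_genes number of genes on the toy chromosome.
#' @slot gene_length_range integer length-2, min/max gene length (nt).
#' @slot n_alu_per_gene Alu-like elements planted per gene (in introns,
#'   antisense to the gene).
#' @slot alu_consensus character, the element consensus sequence; its two
#'   poly(A) blocks become the linker and upstream U-tracts on the antisense
#'   strand.
#' @slot utract_min minimal planted tract length.
#' @slot utract_mean_control,utract_mean_exonized mean planted tract length
#'   per element set; lengths are \code{utract_min + Poisson(mean - min)}.
#' @slot frac_exonized fraction of elements assigned to the exonized set.
#' @slot mutation_rate per-nt substitution probability applied to element
#'   copies outside the poly(A) blocks.
#' @slot base_rate_c,base_rate_u background crosslink intensities (events/nt).
#' @slot alpha hnRNP C affinity gain per uridine beyond the minimal tract.
#' @slot beta U2AF65 affinity per pyrimidine-score unit.
#' @slot s suppression factor in [0,1] applied to U2AF65 at hnRNP-C-occupied
#'   tracts in the control condition.
#' @slot occ_scale saturation scale of tract occupancy,
#'   \code{P_occ = 1 - exp(-lambda_C / occ_scale)}.
#' @slot gamma logistic slope mapping U2AF65 tract occupancy to inclusion.
#' @slot psi_threshold occupancy at which inclusion is 50%.
#' @slot depth expected junction reads per gene per replicate.
#' @slot n_replicates RNA-seq replicates per condition.
#' @slot ppt_length length of the pyrimidine tract planted upstream of
#'   genuine exon acceptors (nt).
#' @slot hnrnpc_kd_background logical; emit a background-only hnRNP C track
#'   for the knockdown condition (otherwise the track is absent).
#' @slot seed integer global seed, split hierarchically per sub-generator.
#' @export
setClass("SimConfig", representation(
    n_genes = "integer",
    gene_length_range = "integer",
    n_alu_per_gene = "integer",
    alu_consensus = "character",
    utract_min = "integer",
    utract_mean_control = "numeric",
    utract_mean_exonized = "numeric",
    frac_exonized = "numeric",
    mutation_rate = "numeric",
    base_rate_c = "numeric",
    base_rate_u = "numeric",
    alpha = "numeric",
    beta = "numeric",
    s = "numeric",
    occ_scale = "numeric",
    gamma = "numeric",
    psi_threshold = "numeric",
    depth = "numeric",
    n_replicates = "integer",
    ppt_length = "integer",
    hnrnpc_kd_background = "logical",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    rates <- c(object@mutation_rate, object@base_rate_c, object@base_rate_u,
               object@alpha, object@beta, object@gamma, object@depth)
    if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
    if (object@s < 0 || object@s > 1) msg <- c(msg, "s must lie in [0, 1]")
    if (object@frac_exonized < 0 || object@frac_exonized > 1)
        msg <- c(msg, "frac_exonized must lie in [0, 1]")
    if (length(object@gene_length_range) != 2L ||
        diff(object@gene_length_range) < 0)
        msg <- c(msg, "gene_length_range must be an increasing length-2 range")
    if (object@depth <= 0) msg <- c(msg, "depth must be positive")
    if (object@n_genes < 1L) msg <- c(msg, "need at least one gene")
    if (!grepl("^[ACGT]+$", object@alu_consensus))
        msg <- c(msg, "alu_consensus must be a DNA string over ACGT")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@n_genes, "genes,",
        object@n_alu_per_gene, "antisense Alu-like element(s) per gene\n")
    cat("  competition: alpha =", object@alpha, "beta =", object@beta,
        "s =", object@s, "\n")
    cat("  tract means (control/exonized):", object@utract_mean_control, "/",
        object@utract_mean_exonized, " depth =", object@depth,
        " seed =", object@seed, "\n")
})

#' Planted ground truth of a synthetic dataset
#'
#' @slot genes \code{GRanges} of gene bodies (with \code{gene_id}).
#' @slot exons \code{GRanges} of annotated (genuine) exons per gene.
#' @slot elements \code{GRanges} of planted Alu-like elements (antisense to
#'   their gene) with the set label (\code{exonized} flag).
#' @slot tracts data.frame of planted U-tracts: genomic interval, type
#'   (upstream/linker), planted length, hnRNP C affinity \code{lambda_c},
#'   occupancy probability \code{p_occ}, expected U2AF65 events
#'   \code{lambda_u_ctrl}/\code{lambda_u_kd}, bound flag.
#' @slot alu_exons data.frame of planted Alu exons with true inclusion
#'   \code{psi_ctrl}/\code{psi_kd} and \code{regulated} flag.
#' @export
setClass("SimTruth", representation(
    genes = "GRanges",
    exons = "GRanges",
    elements = "GRanges",
    tracts = "data.frame",
    alu_exons = "data.frame"
))

setValidity("SimTruth", function(object) {
    msg <- character()
    tr <- object@tracts
    if (nrow(tr) && any(tr$lambda_u_kd < tr$lambda_u_ctrl - 1e-12))
        msg <- c(msg, "lambda_u_kd must be >= lambda_u_ctrl at every tract")
    ax <- object@alu_exons
    if (nrow(ax)) {
        bad <- ax$regulated & !(ax$psi_kd >= ax$psi_ctrl)
        if (any(bad))
            msg <- c(msg, "psi_kd must be >= psi_ctrl for regulated exons")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@genes), "genes,",
        length(object@elements), "elements,", nrow(object@tracts),
        "planted U-tracts,", nrow(object@alu_exons), "Alu exons\n")
})
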