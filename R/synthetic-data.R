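#' Default Alu-like consensus sequence
#'
#' Builds a synthetic ~300-nt element consensus with the canonical anatomy of
#' a primate SINE: two arms separated by a poly(A) linker and followed by a
#' poly(A) tail. When a copy is inserted antisense to a gene, the poly(A)
#' blocks are transcribed as the upstream (from the tail) and linker U-tracts.
#' The arm sequences are fixed pseudo-random DNA, so the consensus is a
#' package constant, not a licensed repeat-database sequence.
#'
#' @param arm_length length of each arm (nt).
#' @param linker_length,tail_length lengths of the two poly(A) blocks (nt).
#' @return A DNA character string.
#' @export
makeAluConsensus <- function(arm_length = 120L, linker_length = 12L,
                             tail_length = 18L) {
    arms <- with_local_seed(190462L, c(rand_dna(arm_length),
                                       rand_dna(arm_length)))
    paste0(arms[1], strrep("A", linker_length), arms[2],
           strrep("A", tail_length))
}

#' Locate the poly(A) blocks of an element consensus
#'
#' The first maximal A-run of at least \code{min_run} nt is taken as the
#' linker block and the last as the tail block; these consensus-coordinate
#' intervals anchor the linker and upstream U-tract regions used by
#' \code{\link{extractAluUtracts}}.
#'
#' @param consensus consensus DNA string.
#' @param min_run minimal A-run length regarded as a poly(A) block.
#' @return list with 1-based consensus intervals \code{linker} and
#'   \code{tail}, each \code{c(start, end)}.
#' @export
aluConsensusRegions <- function(consensus, min_run = 8L) {
    runs <- letter_runs(consensus, "A")
    runs <- runs[runs$length >= min_run, , drop = FALSE]
    if (nrow(runs) < 2L)
        stop("consensus must contain two poly(A) blocks of >= ", min_run,
             " nt")
    first <- runs[1L, ]
    last <- runs[nrow(runs), ]
    list(linker = c(first$start, first$start + first$length - 1L),
         tail = c(last$start, last$start + last$length - 1L))
}

#' Construct a synthetic-dataset configuration
#'
#' Returns a validated \code{\linkS4class{SimConfig}}. Defaults encode the
#' study conditions used throughout the package tests: 300 genes of 2-4 kb
#' with two intronic antisense Alu-like elements each, control tracts
#' averaging 8 uridines and exonized-set tracts two uridines longer, and a
#' planted hnRNP C / U2AF65 competition with suppression \code{s = 0.8}.
#'
#' @param n_genes,gene_length_range,n_alu_per_gene toy genome layout.
#' @param alu_consensus element consensus (see \code{\link{makeAluConsensus}}).
#' @param utract_min,utract_mean_control,utract_mean_exonized planted U-tract
#'   length distribution: \code{utract_min + Poisson(mean - utract_min)}.
#' @param frac_exonized fraction of elements labelled exonized.
#' @param mutation_rate per-nt substitution probability in element arms.
#' @param base_rate_c,base_rate_u background crosslink intensities (events/nt).
#' @param alpha,beta,s,occ_scale competition model parameters.
#' @param gamma,psi_threshold logistic inclusion link.
#' @param depth expected junction reads per gene per replicate.
#' @param n_replicates RNA-seq replicates per condition.
#' @param ppt_length planted pyrimidine-tract length at genuine acceptors.
#' @param hnrnpc_kd_background emit a background-only hnRNP C knockdown track.
#' @param seed global seed (split hierarchically per sub-generator).
#' @return A \code{SimConfig}.
#' @examples
#' cfg <- simConfig(n_genes = 5L, seed = 1L)
#' cfg
#' @export
simConfig <- function(n_genes = 300L,
                      gene_length_range = c(2000L, 4000L),
                      n_alu_per_gene = 2L,
                      alu_consensus = makeAluConsensus(),
                      utract_min = 4L,
                      utract_mean_control = 8,
                      utract_mean_exonized = 10,
                      frac_exonized = 0.5,
                      mutation_rate = 0.05,
                      base_rate_c = 0.01,
                      base_rate_u = 0.02,
                      alpha = 0.5,
                      beta = 0.5,
                      s = 0.8,
                      occ_scale = 4,
                      gamma = 2,
                      psi_threshold = 1.5,
                      depth = 200,
                      n_replicates = 2L,
                      ppt_length = 18L,
                      hnrnpc_kd_background = FALSE,
                      seed = 1L) {
    new("SimConfig",
        n_genes = as.integer(n_genes),
        gene_length_range = as.integer(gene_length_range),
        n_alu_per_gene = as.integer(n_alu_per_gene),
        alu_consensus = alu_consensus,
        utract_min = as.integer(utract_min),
        utract_mean_control = utract_mean_control,
        utract_mean_exonized = utract_mean_exonized,
        frac_exonized = frac_exonized,
        mutation_rate = mutation_rate,
        base_rate_c = base_rate_c,
        base_rate_u = base_rate_u,
        alpha = alpha,
        beta = beta,
        s = s,
        occ_scale = occ_scale,
        gamma = gamma,
        psi_threshold = psi_threshold,
        depth = depth,
        n_replicates = as.integer(n_replicates),
        ppt_length = as.integer(ppt_length),
        hnrnpc_kd_background = hnrnpc_kd_background,
        seed = as.integer(seed))
}

# Per-position pyrimidine score on a transcript-strand sequence: the number
# of pyrimidines in the centered 11-nt window in excess of 6 (0 otherwise).
# Uniform background sequence therefore scores near zero while planted
# pyrimidine tracts and U-tracts score up to 5.
pyr_scores <- function(seq) {
    v <- strsplit(seq, "")[[1]] %in% c("C", "T")
    pmax(0, window_sum(as.numeric(v), 5L) - 6)
}

# transcript coordinate (1 = 5' end) -> genomic coordinate (1-based)
t2g <- function(t, gstart, gend, strand) {
    if (strand == "+") gstart + t - 1L else gend - t + 1L
}

draw_tract_length <- function(n, min_len, mean_len) {
    min_len + stats::rpois(n, max(mean_len - min_len, 0))
}

#' Generate a toy genome with planted antisense Alu-like elements
#'
#' Lays out non-overlapping genes on a single chromosome, gives each gene
#' three genuine exons with pyrimidine tracts upstream of the internal
#' acceptors, and plants \code{n_alu_per_gene} Alu-like elements antisense to
#' the gene inside its introns. Each element carries an upstream and a linker
#' U-tract on the transcribed strand, with planted lengths drawn from the
#' configured per-set distribution (exonized vs. control) and substitutions
#' applied to the arms at \code{mutation_rate}. The returned ground truth
#' records every planted tract with its hnRNP C affinity
#' \code{lambda_c = alpha * max(0, length - 3)}, saturating occupancy
#' \code{p_occ = 1 - exp(-lambda_c / occ_scale)}, and expected U2AF65 event
#' counts in control (suppressed by \code{s * p_occ}) and knockdown.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list with elements \code{seq} (named character, the chromosome
#'   sequence), \code{genes}, \code{exons}, \code{elements} (\code{GRanges}),
#'   \code{truth} (a \code{\linkS4class{SimTruth}}) and \code{config}.
#' @export
generateGenome <- function(config) {
    validObject(config)
    seeds <- split_seed(config@seed, 4L)
    with_local_seed(seeds[1L], generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
    cons <- config@alu_consensus
    regions <- aluConsensusRegions(cons)
    arm1_end <- regions$linker[1L] - 1L
    arm2 <- c(regions$linker[2L] + 1L, regions$tail[1L] - 1L)
    arm2_len <- arm2[2L] - arm2[1L] + 1L
    cons_v <- strsplit(cons, "")[[1]]
    bases <- c("A", "C", "G", "T")
    gap <- 500L

    gene_rows <- vector("list", config@n_genes)
    exon_rows <- list()
    elem_rows <- list()
    tract_rows <- list()
    aluex_rows <- list()
    seq_pieces <- character(0)
    cur <- 300L  # leading intergenic pad
    seq_pieces <- rand_dna(cur)
    elem_counter <- 0L

    for (g in seq_len(config@n_genes)) {
        L <- sample(seq(config@gene_length_range[1L],
                        config@gene_length_range[2L]), 1L)
        strand <- if (g %% 2L == 1L) "+" else "-"
        gid <- sprintf("gene%03d", g)
        gstart <- cur + 1L
        gend <- cur + L

        # transcript-strand sequence, built as a character vector
        tv <- sample(bases, L, replace = TRUE)

        # genuine exons at the 5' end, middle and 3' end of the transcript
        m <- L %/% 2L
        ex_t <- rbind(c(1L, 150L), c(m - 74L, m + 75L), c(L - 149L, L))
        # pyrimidine tract + AG upstream of the internal acceptors
        for (k in 2:3) {
            a <- ex_t[k, 1L]
            ppt <- sample(c("C", "T"), config@ppt_length, replace = TRUE,
                          prob = c(0.4, 0.6))
            tv[(a - config@ppt_length - 2L):(a - 3L)] <- ppt
            tv[(a - 2L):(a - 1L)] <- c("A", "G")
        }
        # GT after the internal donors
        for (k in 1:2) tv[ex_t[k, 2L] + c(1L, 2L)] <- c("G", "T")

        # introns available for element insertion
        introns <- rbind(c(ex_t[1L, 2L] + 10L, ex_t[2L, 1L] - 10L),
                         c(ex_t[2L, 2L] + 10L, ex_t[3L, 1L] - 10L))
        intron_cursor <- introns[, 1L] + 40L

        # matched within-gene design: a fixed number of elements per gene is
        # labelled exonized, at random positions, so exonized and control
        # elements are paired within the same genes
        n_exo <- round(config@frac_exonized * config@n_alu_per_gene)
        exo_vec <- sample(c(rep(TRUE, n_exo),
                            rep(FALSE, config@n_alu_per_gene - n_exo)))
        for (e in seq_len(config@n_alu_per_gene)) {
            elem_counter <- elem_counter + 1L
            exonized <- exo_vec[e]
            mean_len <- if (exonized) config@utract_mean_exonized else
                config@utract_mean_control
            u_len <- draw_tract_length(1L, config@utract_min, mean_len)
            l_len <- draw_tract_length(1L, config@utract_min, mean_len)

            # element consensus instance: poly(A) blocks resized to the
            # planted tract lengths, substitutions in the arms only
            inst <- c(cons_v[1:arm1_end], rep("A", l_len),
                      cons_v[arm2[1L]:arm2[2L]], rep("A", u_len))
            arm_idx <- c(seq_len(arm1_end),
                         arm1_end + l_len + seq_len(arm2_len))
            mut <- arm_idx[stats::runif(length(arm_idx)) <
                               config@mutation_rate]
            if (length(mut))
                inst[mut] <- vapply(inst[mut], function(b)
                    sample(setdiff(bases, b), 1L), character(1))
            elen <- length(inst)

            intr <- ((e - 1L) %% 2L) + 1L
            estart_t <- intron_cursor[intr]
            if (estart_t + elen - 1L > introns[intr, 2L])
                stop("gene ", gid, " is too short to host ",
                     config@n_alu_per_gene, " element(s) of ", elen, " nt")
            intron_cursor[intr] <- estart_t + elen + 40L

            # transcript-orientation element = revcomp(instance):
            # [u_len U][arm2'][l_len U][arm1']
            inst_rc <- rev(chartr("ACGT", "TGCA", inst))
            tv[estart_t:(estart_t + elen - 1L)] <- inst_rc

            # tract positions in transcript coordinates
            up_t <- c(estart_t, estart_t + u_len - 1L)
            li_t <- c(estart_t + u_len + arm2_len,
                      estart_t + u_len + arm2_len + l_len - 1L)

            eid <- sprintf("alu%05d", elem_counter)
            eg <- sort(t2g(c(estart_t, estart_t + elen - 1L), gstart, gend,
                           strand))
            elem_rows[[elem_counter]] <- data.frame(
                gene_id = gid, element_id = eid, start = eg[1L],
                end = eg[2L], strand = if (strand == "+") "-" else "+",
                exonized = exonized)

            for (ti in list(c("upstream", up_t, u_len),
                            c("linker", li_t, l_len))) {
                tt <- as.integer(ti[2:3])
                tg <- sort(t2g(tt, gstart, gend, strand))
                tract_rows[[length(tract_rows) + 1L]] <- data.frame(
                    element_id = eid, gene_id = gid, type = ti[1L],
                    start = tg[1L], end = tg[2L], strand = strand,
                    t_start = tt[1L], t_end = tt[2L],
                    length = as.integer(ti[4L]), exonized = exonized)
            }

            if (exonized) {
                exlen <- sample(60:100, 1L)
                a_t <- estart_t + u_len + 2L   # first exonic nt (after AG)
                d_t <- a_t + exlen - 1L
                tv[(a_t - 2L):(a_t - 1L)] <- c("A", "G")
                xg <- sort(t2g(c(a_t, d_t), gstart, gend, strand))
                aluex_rows[[length(aluex_rows) + 1L]] <- data.frame(
                    exon_id = paste0(eid, "_ex"), element_id = eid,
                    gene_id = gid, start = xg[1L], end = xg[2L],
                    strand = strand,
                    acceptor = t2g(a_t, gstart, gend, strand),
                    donor = t2g(d_t, gstart, gend, strand),
                    upstream_tract_t = up_t[1L])
            }
        }

        tseq <- paste(tv, collapse = "")
        gplus <- if (strand == "+") tseq else revcomp(tseq)
        seq_pieces <- c(seq_pieces, gplus, rand_dna(gap))
        gene_rows[[g]] <- data.frame(gene_id = gid, start = gstart,
                                     end = gend, strand = strand,
                                     tseq = tseq)
        exg <- t(apply(ex_t, 1L, function(r)
            sort(t2g(r, gstart, gend, strand))))
        exon_rows[[g]] <- data.frame(gene_id = gid, start = exg[, 1L],
                                     end = exg[, 2L], strand = strand,
                                     exon_rank = 1:3)
        cur <- gend + gap
    }

    chrom <- "chrS"
    seq <- paste(seq_pieces, collapse = "")
    genes_df <- do.call(rbind, gene_rows)
    tracts <- do.call(rbind, tract_rows)
    tracts$chrom <- chrom

    # expected-event bookkeeping per tract, from the pyrimidine scores of the
    # realized sequence
    tracts$lambda_c <- config@alpha * pmax(0, tracts$length - 3L)
    tracts$p_occ <- if (config@occ_scale > 0)
        1 - exp(-tracts$lambda_c / config@occ_scale) else
        as.numeric(tracts$lambda_c > 0)
    tracts$bound <- tracts$lambda_c > 0
    lam_u <- mapply(function(gid, t1, t2, p) {
        sc <- pyr_scores(genes_df$tseq[genes_df$gene_id == gid])
        lam_kd <- sum(config@base_rate_u + config@beta * sc[t1:t2])
        lam_ct <- sum(config@base_rate_u +
                          config@beta * sc[t1:t2] * (1 - config@s * p))
        c(lam_ct, lam_kd)
    }, tracts$gene_id, tracts$t_start, tracts$t_end, tracts$p_occ)
    tracts$lambda_u_ctrl <- lam_u[1L, ]
    tracts$lambda_u_kd <- lam_u[2L, ]

    # true inclusion levels of the planted Alu exons via the logistic link on
    # mean per-nucleotide U2AF65 occupancy of the upstream tract
    alu_exons <- if (length(aluex_rows)) do.call(rbind, aluex_rows) else
        data.frame(exon_id = character(), element_id = character(),
                   gene_id = character(), start = integer(), end = integer(),
                   strand = character(), acceptor = integer(),
                   donor = integer(), upstream_tract_t = integer())
    if (nrow(alu_exons)) {
        up <- tracts[tracts$type == "upstream", ]
        idx <- match(alu_exons$element_id, up$element_id)
        occ_ct <- up$lambda_u_ctrl[idx] / up$length[idx]
        occ_kd <- up$lambda_u_kd[idx] / up$length[idx]
        alu_exons$psi_ctrl <- stats::plogis(
            config@gamma * (occ_ct - config@psi_threshold))
        alu_exons$psi_kd <- stats::plogis(
            config@gamma * (occ_kd - config@psi_threshold))
        alu_exons$regulated <- alu_exons$psi_kd > alu_exons$psi_ctrl
        alu_exons$chrom <- chrom
    }
    tracts$t_start <- NULL; tracts$t_end <- NULL

    genes <- GRanges(chrom, IRanges(genes_df$start, genes_df$end),
                     strand = genes_df$strand, gene_id = genes_df$gene_id)
    exons_df <- do.call(rbind, exon_rows)
    exons <- GRanges(chrom, IRanges(exons_df$start, exons_df$end),
                     strand = exons_df$strand, gene_id = exons_df$gene_id,
                     exon_rank = exons_df$exon_rank)
    elems_df <- do.call(rbind, elem_rows)
    elements <- GRanges(chrom, IRanges(elems_df$start, elems_df$end),
                        strand = elems_df$strand,
                        element_id = elems_df$element_id,
                        gene_id = elems_df$gene_id,
                        exonized = elems_df$exonized)
    seqlengths(genes) <- seqlengths(exons) <- seqlengths(elements) <-
        stats::setNames(nchar(seq), chrom)

    truth <- new("SimTruth", genes = genes, exons = exons,
                 elements = elements, tracts = tracts, alu_exons = alu_exons)
    out_seq <- stats::setNames(seq, chrom)
    list(seq = out_seq, genes = genes, exons = exons, elements = elements,
         truth = truth, config = config,
         gene_tseq = stats::setNames(genes_df$tseq, genes_df$gene_id))
}

#' Generate per-protein, per-condition crosslink tracks
#'
#' Draws Poisson crosslink-event counts at every transcribed position. The
#' hnRNP C rate is the background plus each planted tract's affinity
#' \code{alpha * max(0, length - 3)} spread evenly over the tract. The U2AF65
#' rate is \code{base_rate_u + beta * pyr(p)}, multiplied in the control
#' condition by \code{1 - s * p_occ} inside hnRNP-C-occupied tracts; the
#' knockdown condition drops the suppression term.
#'
#' @param genome Output of \code{\link{generateGenome}}.
#' @param truth The matching \code{\linkS4class{SimTruth}} (defaults to
#'   \code{genome$truth}); a mismatch raises a consistency error.
#' @param config The matching \code{\link{simConfig}}.
#' @return A list of \code{\link{CrosslinkTrack}} objects:
#'   \code{hnRNPC$ctrl} (and \code{hnRNPC$kd} if configured background-only),
#'   \code{U2AF65$ctrl}, \code{U2AF65$kd}.
#' @export
generateCrosslinkTracks <- function(genome, truth = genome$truth,
                                    config = genome$config) {
    if (!identical(as.character(mcols(truth@genes)$gene_id),
                   as.character(mcols(genome$genes)$gene_id)) ||
        !all(start(truth@genes) == start(genome$genes)))
        stop("truth does not match the supplied genome")
    seeds <- split_seed(config@seed, 4L)
    with_local_seed(seeds[2L], {
        genes <- as.data.frame(genome$genes)
        genes$gene_id <- mcols(genome$genes)$gene_id
        tracts <- truth@tracts
        chrom <- names(genome$seq)

        draw_track <- function(rate_fun) {
            hits <- vector("list", nrow(genes))
            for (i in seq_len(nrow(genes))) {
                gid <- genes$gene_id[i]
                L <- genes$end[i] - genes$start[i] + 1L
                rate <- rate_fun(gid, L)
                cnt <- stats::rpois(L, rate)
                pos_t <- which(cnt > 0L)
                if (!length(pos_t)) next
                pos_g <- t2g(pos_t, genes$start[i], genes$end[i],
                             genes$strand[i])
                hits[[i]] <- data.frame(chrom = chrom, pos = pos_g,
                                        strand = genes$strand[i],
                                        count = cnt[pos_t])
            }
            df <- do.call(rbind, hits)
            if (is.null(df))
                df <- data.frame(chrom = character(), pos = integer(),
                                 strand = character(), count = integer())
            tr <- CrosslinkTrack(df)
            seqlevels(tr) <- chrom
            seqlengths(tr) <- stats::setNames(nchar(genome$seq), chrom)
            tr
        }

        tract_t_coords <- function(gid, L) {
            # genomic tract intervals back to transcript coordinates
            tr <- tracts[tracts$gene_id == gid, , drop = FALSE]
            if (!nrow(tr)) return(tr)
            g <- genes[genes$gene_id == gid, ]
            if (g$strand == "+") {
                tr$t1 <- tr$start - g$start + 1L
                tr$t2 <- tr$end - g$start + 1L
            } else {
                tr$t1 <- g$end - tr$end + 1L
                tr$t2 <- g$end - tr$start + 1L
            }
            tr
        }

        rate_c <- function(gid, L) {
            rate <- rep(config@base_rate_c, L)
            tr <- tract_t_coords(gid, L)
            for (j in seq_len(nrow(tr)))
                rate[tr$t1[j]:tr$t2[j]] <- rate[tr$t1[j]:tr$t2[j]] +
                    tr$lambda_c[j] / tr$length[j]
            rate
        }
        rate_u <- function(suppressed) function(gid, L) {
            sc <- pyr_scores(genome$gene_tseq[[gid]])
            rate <- config@base_rate_u + config@beta * sc
            if (suppressed) {
                tr <- tract_t_coords(gid, L)
                for (j in seq_len(nrow(tr))) {
                    idx <- tr$t1[j]:tr$t2[j]
                    rate[idx] <- config@base_rate_u + config@beta * sc[idx] *
                        (1 - config@s * tr$p_occ[j])
                }
            }
            rate
        }

        out <- list(hnRNPC = list(ctrl = draw_track(rate_c)),
                    U2AF65 = list(ctrl = draw_track(rate_u(TRUE)),
                                  kd = draw_track(rate_u(FALSE))))
        if (config@hnrnpc_kd_background)
            out$hnRNPC$kd <- draw_track(function(gid, L)
                rep(config@base_rate_c, L))
        out
    })
}

#' Generate exon inclusion/exclusion junction counts and gene totals
#'
#' Per gene, condition (\code{ctrl}, \code{kd1}, \code{kd2}) and replicate, a
#' junction-read total is drawn as Poisson(\code{depth}); each planted Alu
#' exon's inclusion count is Binomial(total, psi) at the exon's true
#' inclusion level for that condition, and exclusion is the remainder, so
#' inclusion + exclusion reproduces the drawn gene total exactly.
#'
#' @param truth A \code{\linkS4class{SimTruth}}.
#' @param config The matching \code{\link{simConfig}}.
#' @return list with data.frames \code{gene_totals} (gene_id, condition,
#'   replicate, total) and \code{exon_counts} (exon_id, gene_id, condition,
#'   replicate, inclusion, exclusion, total, psi).
#' @export
generateExpressionCounts <- function(truth, config) {
    if (config@depth <= 0) stop("depth must be positive")
    seeds <- split_seed(config@seed, 4L)
    with_local_seed(seeds[3L], {
        gids <- as.character(mcols(truth@genes)$gene_id)
        conds <- c("ctrl", "kd1", "kd2")
        reps <- seq_len(config@n_replicates)
        gt <- expand.grid(gene_id = gids, condition = conds,
                          replicate = reps, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
        gt <- gt[order(gt$condition, gt$replicate, match(gt$gene_id, gids)), ]
        gt$total <- stats::rpois(nrow(gt), config@depth)

        ax <- truth@alu_exons
        ec <- NULL
        if (nrow(ax)) {
            ec <- merge(gt, ax[, c("exon_id", "gene_id", "psi_ctrl",
                                   "psi_kd")], by = "gene_id")
            ec <- ec[order(ec$condition, ec$replicate, ec$exon_id), ]
            ec$psi <- ifelse(ec$condition == "ctrl", ec$psi_ctrl, ec$psi_kd)
            ec$inclusion <- stats::rbinom(nrow(ec), ec$total, ec$psi)
            ec$exclusion <- ec$total - ec$inclusion
            ec <- ec[, c("exon_id", "gene_id", "condition", "replicate",
                         "inclusion", "exclusion", "total", "psi")]
            rownames(ec) <- NULL
        }
        rownames(gt) <- NULL
        list(gene_totals = gt, exon_counts = ec)
    })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper running \code{\link{generateGenome}},
#' \code{\link{generateCrosslinkTracks}} and
#' \code{\link{generateExpressionCounts}} under one configuration, optionally
#' writing all outputs to plain-text files (FASTA genome, GTF annotation,
#' BED6 elements and tracks, TSV count tables and truth).
#'
#' @param config A \code{\link{simConfig}}.
#' @param dir Optional output directory; created if missing.
#' @return list with \code{genome}, \code{tracks}, \code{counts}.
#' @export
simulateDataset <- function(config, dir = NULL) {
    genome <- generateGenome(config)
    tracks <- generateCrosslinkTracks(genome, genome$truth, config)
    counts <- generateExpressionCounts(genome$truth, config)
    sim <- list(genome = genome, tracks = tracks, counts = counts)
    if (!is.null(dir)) writeSimulation(sim, dir)
    sim
}
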