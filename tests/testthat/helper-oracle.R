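# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: naive O(L^2) window sums, explicit loops, and the
# same documented RNG contract (set.seed(seed), then `iterations` draws of
# sample.int(L, n, replace = TRUE)).

oracle_heights <- function(counts, flank) {
    L <- length(counts)
    pos <- which(counts > 0L)
    h <- numeric(length(pos))
    for (j in seq_along(pos)) {
        i <- pos[j]
        h[j] <- sum(counts[max(1L, i - flank):min(L, i + flank)])
    }
    stats::setNames(h, pos)
}

oracle_empirical_fdr <- function(counts, flank, iterations, seed) {
    L <- length(counts)
    obs_h <- oracle_heights(counts, flank)
    if (!length(obs_h))
        return(data.frame(height = numeric(0), fdr = numeric(0)))
    n <- sum(counts)
    thresholds <- sort(unique(obs_h), decreasing = TRUE)
    n_obs <- numeric(length(thresholds))
    for (j in seq_along(thresholds))
        n_obs[j] <- sum(obs_h >= thresholds[j])
    rand_tot <- numeric(length(thresholds))
    set.seed(seed)
    for (r in seq_len(iterations)) {
        draw <- sample.int(L, n, replace = TRUE)
        cnt <- integer(L)
        for (d in draw) cnt[d] <- cnt[d] + 1L
        rh <- oracle_heights(cnt, flank)
        for (j in seq_along(thresholds))
            rand_tot[j] <- rand_tot[j] + sum(rh >= thresholds[j])
    }
    fdr <- pmin(rand_tot / iterations / n_obs, 1)
    # enforce monotone non-increasing FDR with growing height
    for (j in seq_along(fdr)[-1L])         # thresholds are decreasing
        fdr[j - 1L] <- min(fdr[j - 1L], fdr[j])
    data.frame(height = thresholds, fdr = fdr)
}

oracle_call_sites <- function(counts, flank, fdr_threshold, iterations,
                              seed, strand = "+") {
    tab <- oracle_empirical_fdr(counts, flank, iterations, seed)
    obs_h <- oracle_heights(counts, flank)
    pos <- as.integer(names(obs_h))
    sig <- integer(0)
    for (j in seq_along(pos))
        if (tab$fdr[match(obs_h[j], tab$height)] < fdr_threshold)
            sig <- c(sig, pos[j])
    if (!length(sig))
        return(data.frame(start = integer(), end = integer(),
                          summit = integer(), n_events = integer(),
                          fdr = numeric()))
    sites <- list()
    cur <- c(sig[1L], sig[1L])
    flush <- function(cur) {
        inside <- cur[1L]:cur[2L]
        mx <- max(counts[inside])
        cand <- inside[counts[inside] == mx & counts[inside] > 0L]
        summit <- if (strand == "+") min(cand) else max(cand)
        hmax <- max(oracle_heights(counts, flank)[
            as.character(intersect(inside, sig))])
        data.frame(start = cur[1L], end = cur[2L], summit = summit,
                   n_events = sum(counts[inside]),
                   fdr = tab$fdr[match(hmax, tab$height)])
    }
    if (length(sig) > 1L) for (p in sig[-1L]) {
        if (p - cur[2L] <= flank) cur[2L] <- p
        else { sites[[length(sites) + 1L]] <- flush(cur); cur <- c(p, p) }
    }
    sites[[length(sites) + 1L]] <- flush(cur)
    do.call(rbind, sites)
}

oracle_size_factors <- function(mat) {
    keep <- logical(nrow(mat))
    geo <- numeric(nrow(mat))
    for (i in seq_len(nrow(mat))) {
        keep[i] <- all(mat[i, ] > 0)
        if (keep[i]) geo[i] <- prod(mat[i, ])^(1 / ncol(mat))
    }
    out <- numeric(ncol(mat))
    for (j in seq_len(ncol(mat)))
        out[j] <- stats::median(mat[keep, j] / geo[keep])
    out
}

# textbook 2x2 tests for the usage-test oracle
oracle_chisq_p <- function(tab, correct = TRUE) {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    d <- abs(tab - expected)
    if (correct) d <- pmax(d - 0.5, 0)
    stats::pchisq(sum(d^2 / expected), df = 1, lower.tail = FALSE)
}

oracle_fisher_p <- function(tab) {
    # two-sided Fisher: sum of hypergeometric probabilities <= observed
    m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n_):min(k, m)
    probs <- stats::dhyper(support, m, n_, k)
    p_obs <- stats::dhyper(tab[1, 1], m, n_, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}
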