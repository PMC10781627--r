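# Shared fixtures and independent oracles, built in code.

# uniform single-chromosome map: len_bp physical, len_cm genetic
tinyMap <- function(len_bp = 1e8, len_cm = 100, chrom = "chr1") {
    uniformGenomeMap(chrom, len_bp, len_cm)
}

# toy genome for per-base oracles: 10 kb at 0.01 cM/bp (100 cM total)
toyMap <- function(len_bp = 1e4) tinyMap(len_bp, len_bp / 100)

# quick segment constructor on a supplied map
mkseg <- function(a, b, start_bp, end_bp, map, chrom = "chr1", lod = 10) {
    IBDSegments(sample_a = a, sample_b = b, chrom = chrom,
                start_bp = start_bp, end_bp = end_bp, lod = lod, map = map)
}

# independent per-base pileup oracle: counts of qualifying segments
# (cM length strictly > long_cm) covering each base of a toy chromosome
brutePileup <- function(seg_df, len_bp, map, long_cm = 10) {
    cov <- integer(len_bp)
    for (r in seq_len(nrow(seg_df))) {
        len <- bpToCm(map, seg_df$chrom[r], seg_df$end_bp[r]) -
            bpToCm(map, seg_df$chrom[r], seg_df$start_bp[r])
        if (len > long_cm) {
            idx <- (seg_df$start_bp[r] + 1):seg_df$end_bp[r]
            cov[idx] <- cov[idx] + 1L
        }
    }
    cov
}

# fractional-mass trimmed mean/sd over an expanded per-base vector;
# written against the definition, independently of the Rle path
bruteTrimmed <- function(v, trim) {
    v <- sort(v)
    n <- length(v)
    lo <- trim * n; hi <- (1 - trim) * n
    mass <- pmax(0, pmin(seq_len(n), hi) - pmax(seq_len(n) - 1, lo))
    M <- sum(mass)
    mu <- sum(mass * v) / M
    c(mean = mu, sd = sqrt(sum(mass * (v - mu)^2) / M))
}

# 0.01-step simplex grid search oracle for 2-3 source mixture fits
gridSearchFit <- function(S, p, step = 0.01) {
    k <- ncol(S)
    best <- NULL
    grid <- seq(0, 1, by = step)
    if (k == 2) {
        for (w1 in grid) {
            w <- c(w1, 1 - w1)
            r <- sqrt(sum((S %*% w - p)^2))
            if (is.null(best) || r < best$residual)
                best <- list(w = w, residual = r)
        }
    } else if (k == 3) {
        for (w1 in grid) for (w2 in seq(0, 1 - w1, by = step)) {
            w <- c(w1, w2, 1 - w1 - w2)
            r <- sqrt(sum((S %*% w - p)^2))
            if (is.null(best) || r < best$residual)
                best <- list(w = w, residual = r)
        }
    } else stop("oracle supports 2-3 sources")
    best
}
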