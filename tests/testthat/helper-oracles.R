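# Independent brute-force oracles used across test files.

# Queue-based flood fill; returns a label matrix with components numbered
# by first pixel in row-major order (same convention as labelParticles).
bruteFloodFill <- function(mask, connectivity = 8L) {
    h <- nrow(mask); w <- ncol(mask)
    labels <- matrix(0L, h, w)
    nb <- if (connectivity == 8L)
        rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1),
              c(1,0), c(1,1))
    else rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
    id <- 0L
    for (y in seq_len(h)) for (x in seq_len(w)) {
        if (!mask[y, x] || labels[y, x] != 0L) next
        id <- id + 1L
        queue <- list(c(y, x))
        labels[y, x] <- id
        while (length(queue)) {
            p <- queue[[1]]; queue <- queue[-1]
            for (k in seq_len(nrow(nb))) {
                yy <- p[1] + nb[k, 1]; xx <- p[2] + nb[k, 2]
                if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
                    mask[yy, xx] && labels[yy, xx] == 0L) {
                    labels[yy, xx] <- id
                    queue[[length(queue) + 1L]] <- c(yy, xx)
                }
            }
        }
    }
    labels
}

# O(n^2) maximum pairwise distance over pixel centers.
bruteFeretPx <- function(coords) {
    if (nrow(coords) < 2) return(0)
    best <- 0
    for (i in seq_len(nrow(coords) - 1))
        for (j in (i + 1):nrow(coords)) {
            d2 <- sum((coords[i, ] - coords[j, ])^2)
            if (d2 > best) best <- d2
        }
    sqrt(best)
}

# Benjamini-Hochberg by its step-up definition: the largest cut-point i
# with p_(i) <= i*q/m determines the rejection set.
bhEnumerate <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    ok <- which(ps <= seq_len(m) * q / m)
    if (!length(ok)) return(integer(0))
    sort(o[seq_len(max(ok))])
}

# Small complete check table: g checks x b batches with additive genotype
# and batch effects plus residual noise.
makeCheckTable <- function(gEff, bEff, residSd = 0, seed = NULL,
                           lines = paste0("chk", seq_along(gEff))) {
    df <- expand.grid(line = lines, batch = seq_along(bEff),
                      stringsAsFactors = FALSE)
    df$is_check <- TRUE
    noise <- if (is.null(seed)) 0 else {
        set.seed(seed); rnorm(nrow(df), 0, residSd)
    }
    df$value <- gEff[match(df$line, lines)] + bEff[df$batch] + noise
    df
}

# Tiny deterministic genotype panel for scan oracles.
toyGenotypes <- function(n = 12, m = 8, seed = 7) {
    set.seed(seed)
    codes <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
    codes[1, 1] <- 1
    rownames(codes) <- sprintf("l%02d", seq_len(n))
    map <- data.frame(marker = sprintf("m%02d", seq_len(m)),
                      lg = rep(c("Mrg01", "Mrg02"), length.out = m),
                      pos_cM = rep(seq(10, 80, length.out = m / 2), 2))
    colnames(codes) <- map$marker
    genotypeData(codes, map)
}
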