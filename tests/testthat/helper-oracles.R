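# Independent oracles: deliberately naive reimplementations used only to
# check the package's fast paths.  They share no code with R/.

# Benjamini-Hochberg step-up by brute-force double loop
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, (m / j) * p[ord[j]])
    q[ord[i]] <- min(best, 1)
  }
  q
}

# naive O(n^3) agglomerative clustering of matrix columns, Euclidean
# distance, returning merge heights in merge order
oracle_hclust_heights <- function(x, linkage) {
  clusters <- lapply(seq_len(ncol(x)), identity)
  heights <- numeric(0)
  cdist <- function(a, b) {
    d <- outer(a, b, Vectorize(function(i, j) sqrt(sum((x[, i] - x[, j])^2))))
    if (linkage == "complete") max(d) else mean(d)
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- cdist(clusters[[i]], clusters[[j]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# step-by-step moderated t following the shrinkage formulas, scalar loops
oracle_moderated_t <- function(vals, a, b, d0, s0sq) {
  na <- length(a); nb <- length(b)
  dg <- na + nb - 2
  out <- data.frame(logFC = numeric(nrow(vals)), t = numeric(nrow(vals)),
                    p = numeric(nrow(vals)))
  for (g in seq_len(nrow(vals))) {
    xa <- vals[g, a]; xb <- vals[g, b]
    s2 <- ((na - 1) * var(xa) + (nb - 1) * var(xb)) / dg
    s2p <- if (is.infinite(d0)) s0sq else (d0 * s0sq + dg * s2) / (d0 + dg)
    fc <- mean(xa) - mean(xb)
    tt <- fc / sqrt(s2p * (1 / na + 1 / nb))
    out$logFC[g] <- fc
    out$t[g] <- tt
    out$p[g] <- 2 * pt(abs(tt), df = d0 + dg, lower.tail = FALSE)
  }
  out
}

# type-7 quantile by the textbook interpolation formula, then IQR
oracle_iqr <- function(x) {
  q7 <- function(v, p) {
    v <- sort(v); n <- length(v)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  q7(x, 0.75) - q7(x, 0.25)
}

# brute-force half-open interval overlap scan
oracle_region_scan <- function(ann, chrom, qs, qe) {
  hits <- character(0)
  for (i in seq_len(nrow(ann))) {
    if (ann$chromosome[i] == chrom && ann$start[i] < qe && ann$end[i] > qs)
      hits <- c(hits, ann$gene_id[i])
  }
  hits[order(ann$start[match(hits, ann$gene_id)], hits)]
}
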