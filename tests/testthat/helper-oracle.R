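# Deliberately naive direct-from-definition oracle for the four quantifiers,
# independent of every package code path: plain loops over call strings.
#
# A "raw read" is list(start = index into the position grid, calls = character
# vector over {"M","U"}).

oracle_site <- function(raw_reads, site_idx) {
  n_m <- 0L; n_u <- 0L; n_p <- 0L; A <- 0
  for (rd in raw_reads) {
    j <- site_idx - rd$start + 1L
    if (j < 1L || j > length(rd$calls)) next           # read does not cover S
    if (any(rd$calls == "M")) {
      n_m <- n_m + 1L
      cc <- length(rd$calls)
      if (rd$calls[j] == "M") {
        m <- 1L
        k <- j - 1L
        while (k >= 1L && rd$calls[k] == "M") { m <- m + 1L; k <- k - 1L }
        k <- j + 1L
        while (k <= cc && rd$calls[k] == "M") { m <- m + 1L; k <- k + 1L }
      } else {
        m <- 1L
        n_p <- n_p + 1L
      }
      A <- A + m / cc
    } else {
      n_u <- n_u + 1L
    }
  }
  tot <- n_m + n_u
  if (tot == 0L)
    return(c(wemics = NA_real_, chalm = NA_real_, camda = NA_real_,
             meanm = NA_real_))
  c(wemics = A / (A + n_u), chalm = n_m / tot, camda = n_p / tot,
    meanm = (n_m - n_p) / tot)
}

# Random raw reads over a shared position grid.
random_raw_reads <- function(n_reads, n_sites, p_m = 0.5) {
  lapply(seq_len(n_reads), function(i) {
    start <- sample.int(n_sites, 1L)
    len <- sample.int(n_sites - start + 1L, 1L)
    list(start = start,
         calls = sample(c("M", "U"), len, replace = TRUE,
                        prob = c(p_m, 1 - p_m)))
  })
}

raw_to_meth_reads <- function(raw_reads, positions, chrom = "chr1") {
  as_meth_reads(lapply(seq_along(raw_reads), function(i) {
    rd <- raw_reads[[i]]
    idx <- rd$start:(rd$start + length(rd$calls) - 1L)
    meth_read(sprintf("r%04d", i), chrom, "+", positions[idx], rd$calls)
  }))
}

# Brute-force two-sided signed-rank p-value: enumerate all 2^n sign vectors.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all) >= abs(W))
}

# Exhaustive best-segment oracle: scan all sub-intervals of a paired matrix,
# return the one with the smallest p (ties: larger |mean diff|, then longer).
exhaustive_best_segment <- function(tumor, normal, min_cpg = 3L) {
  ns <- nrow(tumor)
  best <- NULL
  for (lo in seq_len(ns)) for (hi in lo:ns) {
    if (hi - lo + 1L < min_cpg) next
    d <- round(colMeans(tumor[lo:hi, , drop = FALSE]) -
                 colMeans(normal[lo:hi, , drop = FALSE]), 10)
    res <- signed_rank_test(d)
    cand <- list(lo = lo, hi = hi, p = res$p, adiff = abs(mean(d)),
                 len = hi - lo + 1L)
    if (is.null(best) || cand$p < best$p ||
        (cand$p == best$p && cand$adiff > best$adiff) ||
        (cand$p == best$p && cand$adiff == best$adiff && cand$len > best$len))
      best <- cand
  }
  best
}

# Overlap-based confusion counts of called DMRs against a cohort truth table.
dmr_confusion <- function(dmrs, truth) {
  planted <- truth[truth$is_dmr, ]
  hit <- vapply(seq_len(nrow(planted)), function(k)
    any(dmrs$start < planted$end[k] & dmrs$end > planted$start[k] &
          dmrs$direction == planted$direction[k]), logical(1L))
  fp <- if (nrow(dmrs) == 0L) logical(0) else
    vapply(seq_len(nrow(dmrs)), function(k)
      !any(planted$start < dmrs$end[k] & planted$end > dmrs$start[k]),
      logical(1L))
  list(sensitivity = mean(hit), fdr = if (length(fp)) mean(fp) else 0)
}
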