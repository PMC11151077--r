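# Paired de-novo DMR calling.
#
# Matched tumor/normal per-site methylation is segmented by recursive binary
# segmentation within pre-windowed CpG blocks; candidate segments are scored
# with a Wilcoxon signed-rank test on per-patient segment-mean differences
# (W = sum sgn(d_i) * R_i, exact null by dynamic programming for small n
# without ties, tie-corrected normal approximation otherwise).  An unpaired
# Mann-Whitney mode is retained for comparison.

#' Paired methylation matrix
#'
#' Container for per-site methylation of N patients in two matched conditions.
#'
#' @param chrom Chromosome name.
#' @param positions Increasing integer vector of 1-based CpG positions.
#' @param tumor,normal Numeric matrices (sites x patients) of rates in
#'   `[0,1]` or `NA`; identical dimensions and column names.
#' @return An object of class `paired_meth_matrix`.
#' @export
paired_meth_matrix <- function(chrom, positions, tumor, normal) {
  tumor <- as.matrix(tumor); normal <- as.matrix(normal)
  positions <- as.integer(positions)
  if (any(diff(positions) <= 0L)) stop_param("positions must be increasing")
  if (!all(dim(tumor) == dim(normal)))
    stop_input("tumor and normal layers must share dimensions")
  if (nrow(tumor) != length(positions))
    stop_input("row count must equal the number of positions")
  if (!is.null(colnames(tumor)) && !is.null(colnames(normal)) &&
      !identical(colnames(tumor), colnames(normal)))
    stop_input("paired mode requires matched sample sets (column names differ)")
  rng <- range(c(tumor, normal), na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop_input("methylation values must lie in [0,1] or be NA")
  structure(list(chrom = chrom, positions = positions,
                 tumor = tumor, normal = normal,
                 n_patients = ncol(tumor)),
            class = "paired_meth_matrix")
}

#' @export
print.paired_meth_matrix <- function(x, ...) {
  cat(sprintf("<paired_meth_matrix %s: %d sites x %d patients>\n",
              x$chrom, length(x$positions), x$n_patients))
  invisible(x)
}

#' Read a per-site paired methylation table
#'
#' Expects TSV columns `chrom`, `pos`, then `tumor_<id>` / `normal_<id>`
#' pairs with matching id sets.
#'
#' @param path TSV file path.
#' @return A [paired_meth_matrix()] (single chromosome enforced).
#' @export
read_meth_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  dt <- fread(path, sep = "\t")
  tcols <- grep("^tumor_", names(dt), value = TRUE)
  ncols <- grep("^normal_", names(dt), value = TRUE)
  tids <- sort(sub("^tumor_", "", tcols))
  nids <- sort(sub("^normal_", "", ncols))
  if (length(tids) == 0L || !identical(tids, nids))
    stop_input("unmatched tumor_/normal_ sample sets in methylation table")
  if (length(unique(dt$chrom)) != 1L)
    stop_input("methylation table must cover a single chromosome")
  setorder(dt, pos)
  tm <- as.matrix(dt[, paste0("tumor_", tids), with = FALSE])
  nm <- as.matrix(dt[, paste0("normal_", tids), with = FALSE])
  colnames(tm) <- colnames(nm) <- tids
  paired_meth_matrix(dt$chrom[1L], dt$pos, tm, nm)
}

# == signed-rank test ==========================================================

# Exact null counts of T+ (sum of ranks with positive sign) for ranks 1..n:
# counts[k + 1] = number of sign vectors with T+ = k, k = 0..n(n+1)/2.
signed_rank_null_counts <- function(n) {
  maxs <- n * (n + 1L) / 2L
  counts <- numeric(maxs + 1L)
  counts[1L] <- 1
  for (r in seq_len(n)) {
    shifted <- c(numeric(r), counts[seq_len(maxs + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Computes `W = sum(sgn(d_i) * R_i)` with `R_i` the rank of `|d_i|` (average
#' ranks on ties) after dropping zero differences, and a two-sided p-value:
#' exact by dynamic-programming enumeration of the signed-rank null when
#' `n_eff <= exact_max` and the absolute differences are tie-free, otherwise
#' a normal approximation with tie-corrected variance `sum(R_i^2)` and a
#' continuity correction.
#'
#' @param diffs Numeric vector of paired differences (NAs dropped).
#' @param exact_max Largest tie-free `n_eff` handled exactly (default 25).
#' @return List with `W`, `n_eff`, `p`, `method` (`"exact"`,
#'   `"normal_approx"`, or `"degenerate"` when all differences are zero:
#'   `W = 0`, `p = 1`).
#' @examples
#' signed_rank_test(c(.1, .2, .3, .4, .5))  # W = 15, p = 0.0625
#' @export
signed_rank_test <- function(diffs, exact_max = 25L) {
  d <- diffs[!is.na(diffs)]
  if (length(d) == 0L) stop_param("signed_rank_test needs >= 1 non-NA difference")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W = 0, n_eff = 0L, p = 1, method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= exact_max) {
    counts <- signed_rank_null_counts(n)
    s <- n * (n + 1L) / 2L
    w_all <- 2 * (seq_along(counts) - 1L) - s    # W value per T+ level
    p <- sum(counts[abs(w_all) >= abs(W)]) / 2^n
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2))
    z <- max(0, abs(W) - 1) / sigma             # continuity correction
    p <- 2 * pnorm(-z)
    method <- "normal_approx"
  }
  list(W = W, n_eff = n, p = min(1, p), method = method)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control; input p-values must lie in (0, 1].
#'
#' @param pvalues Numeric vector.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1))
    stop_param("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Pre-segment CpG positions into contiguous blocks
#'
#' Maximal runs of consecutive sites with inter-site distance at most
#' `max_gap` base pairs.
#'
#' @param positions Sorted integer positions.
#' @param max_gap Maximum within-block gap in bp (default 300).
#' @return List of integer index vectors partitioning `seq_along(positions)`.
#' @export
presegment <- function(positions, max_gap = 300L) {
  if (length(positions) == 0L) return(list())
  if (is.unsorted(positions)) stop_param("positions must be sorted")
  brk <- c(0L, which(diff(positions) > max_gap), length(positions))
  lapply(seq_len(length(brk) - 1L),
         function(k) (brk[k] + 1L):brk[k + 1L])
}

# Score one candidate segment [lo, hi] (site indices).
.score_segment <- function(mat, lo, hi, mode, per_site) {
  idx <- lo:hi
  if (mode == "paired") {
    tseg <- colMeans(mat$tumor[idx, , drop = FALSE], na.rm = TRUE)
    nseg <- colMeans(mat$normal[idx, , drop = FALSE], na.rm = TRUE)
    if (per_site) {
      d <- as.vector(mat$tumor[idx, , drop = FALSE] -
                       mat$normal[idx, , drop = FALSE])
    } else {
      d <- tseg - nseg
    }
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(list(W = 0, p = 1, mean_diff = NA_real_))
    # collapse floating-point wobble to honest ties (1e-10 is far below any
    # meaningful methylation difference); keeps noise-free signals comparable
    # across nested segments
    res <- signed_rank_test(round(d, 10))
    list(W = res$W, p = res$p,
         mean_diff = mean(tseg - nseg, na.rm = TRUE))
  } else {
    tseg <- round(colMeans(mat$tumor[idx, , drop = FALSE], na.rm = TRUE), 10)
    nseg <- round(colMeans(mat$normal[idx, , drop = FALSE], na.rm = TRUE), 10)
    if (identical(tseg, nseg) || (sd(c(tseg, nseg), na.rm = TRUE) == 0)) {
      p <- 1; W <- 0
    } else {
      wt <- suppressWarnings(wilcox.test(tseg, nseg, exact = FALSE,
                                         correct = TRUE))
      p <- wt$p.value; W <- unname(wt$statistic)
    }
    list(W = W, p = p, mean_diff = mean(tseg - nseg, na.rm = TRUE))
  }
}

# Recursive binary segmentation within one block; collects every visited
# candidate with >= min_cpg sites.  The breakpoint maximizes the absolute
# difference of per-site mean-difference means between the two children;
# recursion descends into a child when its p does not exceed the parent's
# (non-strict, so tied discrete exact p-values still localize).
.segment_block <- function(mat, idx, min_cpg, mode, per_site) {
  dbar <- rowMeans(mat$tumor[idx, , drop = FALSE] -
                     mat$normal[idx, , drop = FALSE], na.rm = TRUE)
  dbar[is.nan(dbar)] <- 0
  acc <- list()
  recurse <- function(lo, hi, parent_p) {
    n <- hi - lo + 1L
    if (n < min_cpg) return(invisible())
    sc <- .score_segment(mat, idx[lo], idx[hi], mode, per_site)
    if (sc$p <= parent_p) {
      acc[[length(acc) + 1L]] <<- list(lo = idx[lo], hi = idx[hi],
                                       W = sc$W, p = sc$p,
                                       mean_diff = sc$mean_diff)
      if (n > min_cpg) {
        seg <- dbar[lo:hi]
        cs <- cumsum(seg)
        k <- seq_len(n - 1L)
        lmean <- cs[k] / k
        rmean <- (cs[n] - cs[k]) / (n - k)
        split <- which.max(abs(lmean - rmean))
        recurse(lo, lo + split - 1L, sc$p)
        recurse(lo + split, hi, sc$p)
      }
    }
    invisible()
  }
  recurse(1L, length(idx), Inf)
  acc
}

#' Detect differentially methylated regions
#'
#' De-novo DMR detection on a [paired_meth_matrix()]. Sites are pre-windowed
#' into blocks with inter-CpG gaps at most `max_gap`; each block is
#' recursively split at the breakpoint maximizing the difference of
#' mean-paired-difference means, and every candidate segment with at least
#' `min_cpg` sites is scored — in paired mode by [signed_rank_test()] on
#' per-patient segment-mean differences (one difference per patient; set
#' `per_site = TRUE` for the pooled site-by-patient variant), in unpaired
#' mode by a Mann-Whitney U test on per-sample segment means. Candidate
#' p-values are Benjamini-Hochberg corrected; emitted DMRs satisfy
#' `n_cpg >= min_cpg`, `|mean_diff| >= min_diff`, `q <= q_thresh` and are
#' non-overlapping (greedy selection by ascending p, ties broken by larger
#' `|mean_diff|`, then longer span, then leftmost start).
#'
#' @param mat A [paired_meth_matrix()].
#' @param mode `"paired"` (default) or `"unpaired"`.
#' @param min_cpg Minimum CpGs per DMR (default 3).
#' @param min_diff Minimum `|mean tumor - normal|` (default 0.1).
#' @param q_thresh FDR threshold (default 0.05).
#' @param max_gap Pre-windowing gap in bp (default 300).
#' @param per_site Paired mode only: pool site-by-patient differences
#'   instead of one per-patient segment mean.
#' @return data.table of DMRs sorted by coordinate, with 0-based half-open
#'   `start`/`end` spanning the CpG dinucleotides, plus `n_cpg`, `mean_diff`
#'   (tumor - normal), `W`, `p`, `q` and `direction`
#'   (`"hyper"` if tumor-higher, else `"hypo"`).
#' @export
detect_dmrs <- function(mat, mode = c("paired", "unpaired"), min_cpg = 3L,
                        min_diff = 0.1, q_thresh = 0.05, max_gap = 300L,
                        per_site = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(mat, "paired_meth_matrix"))
    stop_param("mat must be a paired_meth_matrix")
  if (mode == "paired" && mat$n_patients < 2L)
    stop_input("paired mode needs >= 2 patients")
  blocks <- presegment(mat$positions, max_gap = max_gap)
  cand <- list()
  for (b in blocks) {
    if (length(b) < min_cpg) next
    cand <- c(cand, .segment_block(mat, b, min_cpg, mode, per_site))
  }
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      n_cpg = integer(), mean_diff = numeric(), W = numeric(),
                      p = numeric(), q = numeric(), direction = character())
  if (length(cand) == 0L) return(empty)
  cd <- rbindlist(lapply(cand, as.data.table))
  cd[, q := bh_fdr(pmin(1, pmax(p, .Machine$double.xmin)))]
  cd <- cd[!is.na(cd$mean_diff) & abs(cd$mean_diff) >= min_diff &
             cd$q <= q_thresh, ]
  if (nrow(cd) == 0L) return(empty)
  cd[, len := hi - lo + 1L]
  cd[, adiff := round(abs(mean_diff), 10)]  # fp-stable tie-break
  setorder(cd, p, -adiff, -len, lo)
  taken <- logical(length(mat$positions))
  keep <- logical(nrow(cd))
  for (k in seq_len(nrow(cd))) {
    span <- cd$lo[k]:cd$hi[k]
    if (!any(taken[span])) {
      keep[k] <- TRUE
      taken[span] <- TRUE
    }
  }
  cd <- cd[keep, ]
  out <- data.table(
    chrom = mat$chrom,
    start = mat$positions[cd$lo] - 1L,
    end = mat$positions[cd$hi] + 1L,
    n_cpg = cd$len,
    mean_diff = cd$mean_diff,
    W = cd$W, p = cd$p, q = cd$q,
    direction = ifelse(cd$mean_diff > 0, "hyper", "hypo")
  )
  setorder(out, start)
  out[]
}

#' Merge nearby same-direction DMRs
#'
#' Chains of DMRs whose pairwise gap is below `max_dist` (strict) are merged
#' to their span; `n_cpg` is summed, `mean_diff` recomputed as a
#' CpG-count-weighted mean, and `W`/`p`/`q` taken from the most significant
#' member. Idempotent.
#'
#' @param dmrs DMR table as returned by [detect_dmrs()], coordinate-sorted.
#' @param max_dist Merge distance in bp (default 200).
#' @param same_direction Only merge DMRs sharing a direction (default TRUE).
#' @return Merged DMR table.
#' @export
merge_dmrs <- function(dmrs, max_dist = 200L, same_direction = TRUE) {
  dmrs <- as.data.table(dmrs)
  if (nrow(dmrs) <= 1L) return(dmrs)
  setorder(dmrs, chrom, start)
  grp <- integer(nrow(dmrs)); grp[1L] <- 1L
  for (k in 2L:nrow(dmrs)) {
    gap <- dmrs$start[k] - dmrs$end[k - 1L]
    joinable <- dmrs$chrom[k] == dmrs$chrom[k - 1L] && gap < max_dist &&
      (!same_direction || dmrs$direction[k] == dmrs$direction[k - 1L])
    grp[k] <- if (joinable) grp[k - 1L] else grp[k - 1L] + 1L
  }
  dmrs[, .grp := grp]
  out <- dmrs[, {
    best <- which.min(p)
    list(chrom = chrom[1L], start = min(start), end = max(end),
         n_cpg = sum(n_cpg),
         mean_diff = sum(mean_diff * n_cpg) / sum(n_cpg),
         W = W[best], p = p[best], q = q[best],
         direction = direction[best])
  }, by = ".grp"]
  out[, .grp := NULL]
  setorder(out, chrom, start)
  out[]
}

#' Write DMRs as BED6+
#'
#' Columns: chrom, start, end, name, score (`-10*log10(q)` capped at 1000),
#' strand (`.`), then `n_cpg`, `mean_diff`, `W`, `p`, `q`, `direction`.
#'
#' @param dmrs DMR table.
#' @param path Output path.
#' @param header Optional `#`-prefixed provenance lines.
#' @return Invisibly, the path.
#' @export
write_dmr_bed <- function(dmrs, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (nrow(dmrs) > 0L) {
    score <- pmin(1000, round(-10 * log10(pmax(dmrs$q, 1e-100))))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%d\t%s\t%s\t%s\t%s\t%s",
                       dmrs$chrom, dmrs$start, dmrs$end,
                       sprintf("DMR_%04d", seq_len(nrow(dmrs))), score,
                       dmrs$n_cpg,
                       format(dmrs$mean_diff, digits = 10, trim = TRUE),
                       format(dmrs$W, digits = 10, trim = TRUE),
                       format(dmrs$p, digits = 10, trim = TRUE),
                       format(dmrs$q, digits = 10, trim = TRUE),
                       dmrs$direction), con)
  }
  invisible(path)
}
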