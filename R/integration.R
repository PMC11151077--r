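# Methylation-expression and regulatory-annotation statistics.
#
# All interval arguments are data.frames with columns chrom, start, end in
# 0-based half-open coordinates (BED convention); gaps between intervals are
# counted in intervening base pairs, so bookended intervals are at distance 0
# and [0,5) vs [6,11) are 1 bp apart.

# bp gap between two half-open intervals on the same chromosome (0 = overlap
# or bookended).
.interval_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s2 - e1, s1 - e2))

#' Correlation between two signals
#'
#' Pearson correlation (the linear product-moment formula) or Spearman
#' correlation (Pearson applied to average ranks), with a two-sided p-value
#' from the t distribution with n - 2 degrees of freedom. Incomplete pairs
#' are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_param("correlation needs >= 3 complete pairs")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (sd(x) == 0 || sd(y) == 0)
    cometh_error("zero variance: correlation undefined",
                 "cometh_undefined_correlation")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Normalized read-count signal strength
#'
#' `log2(read_count / region_length_bp * 1000 + 1)`: reads per kilobase,
#' log-transformed with a pseudocount.
#'
#' @param read_count Non-negative count(s).
#' @param region_length_bp Region length(s) in bp, > 0.
#' @return Numeric signal value(s).
#' @examples
#' signal_strength(1000, 2000)  # log2(501)
#' @export
signal_strength <- function(read_count, region_length_bp) {
  if (any(region_length_bp <= 0)) stop_param("region length must be > 0")
  if (any(read_count < 0)) stop_param("read count must be >= 0")
  log2(read_count / region_length_bp * 1000 + 1)
}

#' Gene model
#'
#' @param gene_id Identifier.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param tss Transcription start site (0-based coordinate).
#' @param start,end Transcript span, 0-based half-open, containing `tss`.
#' @return One-row data.table of class `gene_model` compatible fields.
#' @export
gene_model <- function(gene_id, chrom, strand, tss, start, end) {
  if (!strand %in% c("+", "-")) stop_param("strand must be '+' or '-'")
  if (tss < start || tss >= end) stop_param("tss must lie inside the span")
  data.table(gene_id = gene_id, chrom = chrom, strand = strand,
             tss = as.integer(tss), start = as.integer(start),
             end = as.integer(end))
}

#' Promoter window of a gene
#'
#' Symmetric window around the TSS (`flank` bp up- and downstream,
#' irrespective of strand), clipped at zero.
#'
#' @param gene One-row gene table from [gene_model()] (or any list with
#'   `tss`).
#' @param flank Half-width in bp (default 2000).
#' @return List with `start`, `end` (0-based half-open).
#' @export
promoter_of <- function(gene, flank = 2000L) {
  tss <- as.integer(gene$tss)
  list(start = max(0L, tss - as.integer(flank)), end = tss + as.integer(flank))
}

#' Assign DMRs to their nearest gene
#'
#' Each DMR is assigned to the single nearest gene whose span is strictly
#' less than `max_dist` bp away (0 if overlapping); ties are broken by the
#' lexicographically smaller `gene_id`. Distance is measured to the gene span
#' by default; set `anchor = "tss"` to measure to the TSS.
#'
#' @param dmrs DMR table ([detect_dmrs()] output or any chrom/start/end
#'   table with a `direction` column).
#' @param genes Gene table (rows as from [gene_model()]).
#' @param max_dist Strict distance cutoff in bp (default 2000).
#' @param anchor `"span"` or `"tss"`.
#' @return data.table of pairs: DMR columns plus `gene_id`, `distance_bp`;
#'   unassigned DMRs are omitted.
#' @export
assign_dmrs_to_genes <- function(dmrs, genes, max_dist = 2000L,
                                 anchor = c("span", "tss")) {
  anchor <- match.arg(anchor)
  dmrs <- as.data.table(dmrs); genes <- as.data.table(genes)
  out <- vector("list", nrow(dmrs))
  for (k in seq_len(nrow(dmrs))) {
    g <- genes[genes$chrom == dmrs$chrom[k], ]
    if (nrow(g) == 0L) next
    # tss anchor is a zero-width point, so a DMR starting k bp past the TSS
    # is k bp away (not k - 1)
    gs <- if (anchor == "tss") g$tss else g$start
    ge <- if (anchor == "tss") g$tss else g$end
    gaps <- .interval_gap(dmrs$start[k], dmrs$end[k], gs, ge)
    best <- min(gaps)
    if (best >= max_dist) next
    hit <- g$gene_id[gaps == best]
    out[[k]] <- data.table(dmrs[k, ], gene_id = sort(hit)[1L],
                           distance_bp = as.integer(best))
  }
  rbindlist(out[!vapply(out, is.null, logical(1L))])
}

#' Classify DMR-gene pairs against a DEG table
#'
#' Five-way classification combining the DMR direction with differential
#' expression: `Hyper-Down`, `Hyper-Up`, `Hypo-Down`, `Hypo-Up`, or `NS`
#' (gene not significant at `FDR < fdr`, or absent from the table).
#'
#' @param pairs Output of [assign_dmrs_to_genes()].
#' @param deg_table data.frame with `gene_id`, `log2FC`, `FDR`.
#' @param fdr Significance gate (strict, default 0.05).
#' @return `pairs` with a `category` column added.
#' @export
classify_pairs <- function(pairs, deg_table, fdr = 0.05) {
  pairs <- as.data.table(pairs)
  deg_table <- as.data.table(deg_table)
  need <- c("gene_id", "log2FC", "FDR")
  if (!all(need %in% names(deg_table)))
    stop_input(sprintf("DEG table must have columns %s",
                       paste(need, collapse = ", ")))
  i <- match(pairs$gene_id, deg_table$gene_id)
  lfc <- deg_table$log2FC[i]; q <- deg_table$FDR[i]
  expr <- rep("NS", nrow(pairs))
  sig <- !is.na(q) & q < fdr & !is.na(lfc) & lfc != 0
  expr[sig & lfc > 0] <- "Up"
  expr[sig & lfc < 0] <- "Down"
  meth <- ifelse(pairs$direction == "hyper", "Hyper", "Hypo")
  pairs[, category := ifelse(expr == "NS", "NS", paste(meth, expr, sep = "-"))]
  pairs[]
}

#' Read and validate a DEG table
#' @param path TSV with columns `gene_id`, `log2FC`, `FDR`.
#' @return data.table.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  dt <- fread(path, sep = "\t")
  if (!all(c("gene_id", "log2FC", "FDR") %in% names(dt)))
    stop_input("DEG table must have columns gene_id, log2FC, FDR")
  dt
}

#' CpG-island context of a position
#'
#' Distance from a position to the nearest CpG-island border classifies it
#' as `CGI` (inside), `shore` (< 2 kb), `shelf` (2-4 kb inclusive) or
#' `inteCGI` (> 4 kb, including the no-island case).
#'
#' @param position 0-based coordinate(s).
#' @param cgis CGI interval table (chrom optional; `start`/`end` 0-based
#'   half-open). Pass intervals of a single chromosome.
#' @return Character vector of contexts.
#' @export
cgi_context <- function(position, cgis) {
  cgis <- as.data.table(cgis)
  vapply(position, function(p) {
    if (nrow(cgis) == 0L) return("inteCGI")
    d <- .interval_gap(p, p + 1L, cgis$start, cgis$end)
    inside <- p >= cgis$start & p < cgis$end
    dist <- if (any(inside)) 0L else min(d)
    if (dist == 0L && any(inside)) "CGI"
    else if (dist < 2000L) "shore"
    else if (dist <= 4000L) "shelf"
    else "inteCGI"
  }, character(1L))
}

#' Distance from an interval to its nearest feature
#'
#' @param interval List/row with `start`, `end` (0-based half-open).
#' @param features Interval table; `NA` returned when empty.
#' @return Minimal bp gap (0 if overlapping or bookended).
#' @export
nearest_feature_distance <- function(interval, features) {
  features <- as.data.table(features)
  if (nrow(features) == 0L) return(NA_integer_)
  min(.interval_gap(interval$start, interval$end,
                    features$start, features$end))
}

#' Merge overlapping motif intervals
#'
#' Union of overlapping or bookended intervals on one chromosome.
#'
#' @param motifs Interval table with `start`, `end` (0-based half-open).
#' @return data.table of disjoint merged intervals, sorted.
#' @export
merge_motifs <- function(motifs) {
  motifs <- as.data.table(motifs)
  if (nrow(motifs) == 0L) return(data.table(start = integer(), end = integer()))
  ir <- IRanges::IRanges(start = motifs$start + 1L, end = motifs$end)
  red <- IRanges::reduce(ir)
  data.table(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

#' Motif occupancy rate of a DMR
#'
#' The DMR is extended by `extend` bp on both flanks (clipped at zero); the
#' rate is the summed length of all individual motifs clipped to the extended
#' window — overlapping motifs counted separately, not de-overlapped —
#' divided by the extended window length. Can exceed 1 under heavy overlap.
#'
#' @param dmr List/row with `start`, `end` (0-based half-open).
#' @param motifs Motif interval table.
#' @param extend Flank extension in bp (default 200).
#' @return Occupancy rate >= 0.
#' @export
motif_occupancy <- function(dmr, motifs, extend = 200L) {
  s <- max(0L, dmr$start - as.integer(extend))
  e <- dmr$end + as.integer(extend)
  motifs <- as.data.table(motifs)
  if (nrow(motifs) == 0L) return(0)
  clip <- pmin(e, motifs$end) - pmax(s, motifs$start)
  sum(pmax(0L, clip)) / (e - s)
}

#' TF-binding-motif activity score
#'
#' For each motif, `activity = r * log2(fold change)` where `r` is the
#' Spearman correlation between TFBM methylation and target-gene expression
#' over all samples, and the fold change is the ratio of mean linear-scale
#' tumor expression to mean normal expression (expression supplied as
#' log2(FPKM+1), back-converted via `2^x - 1`; set
#' `fold_change_scale = "log"` to average log values instead). Motifs with
#' `r >= 0` are dropped (only inverse methylation-expression relations are
#' scored); the gene's score is the mean over its retained motifs, and
#' `reportable` flags `|activity| > threshold`.
#'
#' @param tfbm_methylation Numeric matrix (motifs x samples) or vector (one
#'   motif) of TFBM methylation rates.
#' @param expression Numeric vector of the target gene's expression per
#'   sample, log2(FPKM+1) scale.
#' @param tumor_mask Logical vector: `TRUE` for tumor samples. At least 3
#'   tumor and 3 normal samples required.
#' @param gene_id Optional identifier carried through.
#' @param threshold Reporting threshold on `|activity|` (default 1.2).
#' @param fold_change_scale `"linear"` (default) or `"log"`.
#' @return List with `gene_id`, `motif_activities`, `r_spearman` (per
#'   retained motif), `log2_fold_change`, `activity`, `reportable`; `NULL`
#'   activity when no motif is retained.
#' @export
activity_score <- function(tfbm_methylation, expression, tumor_mask,
                           gene_id = NA_character_, threshold = 1.2,
                           fold_change_scale = c("linear", "log")) {
  fold_change_scale <- match.arg(fold_change_scale)
  if (is.vector(tfbm_methylation))
    tfbm_methylation <- matrix(tfbm_methylation, nrow = 1L)
  if (ncol(tfbm_methylation) != length(expression) ||
      length(tumor_mask) != length(expression))
    stop_param("methylation, expression and tumor_mask must align on samples")
  if (sum(tumor_mask) < 3L || sum(!tumor_mask) < 3L)
    stop_param("need >= 3 tumor and >= 3 normal samples")
  if (fold_change_scale == "linear") {
    lin <- 2^expression - 1
    mn <- mean(lin[!tumor_mask])
    if (mn <= 0) cometh_error("zero normal-mean expression: fold change undefined",
                              "cometh_undefined_foldchange")
    fc <- mean(lin[tumor_mask]) / mn
  } else {
    mn <- mean(expression[!tumor_mask])
    if (mn <= 0) cometh_error("zero normal-mean expression: fold change undefined",
                              "cometh_undefined_foldchange")
    fc <- mean(expression[tumor_mask]) / mn
  }
  l2fc <- log2(fc)
  rs <- apply(tfbm_methylation, 1L, function(m)
    correlation(m, expression, method = "spearman")$r)
  kept <- which(rs < 0)
  acts <- rs[kept] * l2fc
  list(gene_id = gene_id,
       motif_activities = acts,
       r_spearman = rs[kept],
       log2_fold_change = l2fc,
       activity = if (length(acts)) mean(acts) else NULL,
       reportable = length(acts) > 0 && abs(mean(acts)) > threshold)
}

#' Activity-score arithmetic
#'
#' The bare `r * log2(fold change)` combination used by [activity_score()].
#'
#' @param r Spearman correlation.
#' @param fold_change Linear-scale expression fold change (tumor / normal).
#' @return Numeric activity value.
#' @examples
#' activity_value(-0.5, 4)  # -1
#' @export
activity_value <- function(r, fold_change) r * log2(fold_change)

#' Variance in target expression explained by TFBM methylation and TF
#' expression
#'
#' Fits four nested ordinary-least-squares models of the target gene's
#' expression: methylation only, TF expression only, both, and both plus
#' their interaction; reports raw and adjusted R-squared
#' (`1 - (1 - R2) (n-1)/(n-p-1)`) for each.
#'
#' @param expression_y Target-gene expression per sample.
#' @param tfbm_meth TFBM methylation per sample.
#' @param tf_expression TF expression per sample.
#' @return List of class `variance_model` with `adj_r2_meth`, `adj_r2_tf`,
#'   `adj_r2_joint`, `adj_r2_interaction`, matching `r2_*` raw values, `n`,
#'   and the fitted interaction-model coefficients.
#' @export
variance_explained <- function(expression_y, tfbm_meth, tf_expression) {
  df <- data.frame(y = expression_y, meth = tfbm_meth, tf = tf_expression)
  df <- df[complete.cases(df), ]
  n <- nrow(df)
  if (n <= 4L) stop_param("variance_explained needs > 4 complete cases")
  if (sd(df$meth) == 0 || sd(df$tf) == 0)
    cometh_error("collinear design: constant predictor", "cometh_model_error")
  fits <- list(meth = lm(y ~ meth, df), tf = lm(y ~ tf, df),
               joint = lm(y ~ meth + tf, df),
               interaction = lm(y ~ meth * tf, df))
  r2 <- vapply(fits, function(f) summary(f)$r.squared, numeric(1L))
  adj <- vapply(fits, function(f) summary(f)$adj.r.squared, numeric(1L))
  if (anyNA(coef(fits$interaction)))
    cometh_error("collinear design: rank-deficient interaction model",
                 "cometh_model_error")
  structure(list(adj_r2_meth = adj[["meth"]], adj_r2_tf = adj[["tf"]],
                 adj_r2_joint = adj[["joint"]],
                 adj_r2_interaction = adj[["interaction"]],
                 r2_meth = r2[["meth"]], r2_tf = r2[["tf"]],
                 r2_joint = r2[["joint"]],
                 r2_interaction = r2[["interaction"]],
                 n = n, coefficients = coef(fits$interaction)),
            class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf(paste0("<variance_model n=%d adjR2: meth=%.3f tf=%.3f ",
                     "joint=%.3f interaction=%.3f>\n"),
              x$n, x$adj_r2_meth, x$adj_r2_tf, x$adj_r2_joint,
              x$adj_r2_interaction))
  invisible(x)
}
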