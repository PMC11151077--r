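# Per-site methylation quantifiers.
#
# Four rates are computed from a site's covering reads, with n_m methylated
# reads (>= 1 M call on the read), n_u unmethylated reads and n_p methylated
# reads whose call at the site itself is U:
#
#   Wemics = A / (A + n_u),  A = sum over methylated reads of w_i = m_i / c_i
#   CHALM  = n_m / (n_m + n_u)
#   CAMDA  = n_p / (n_m + n_u)
#   Meanm  = (n_m - n_p) / (n_m + n_u)
#
# where c_i is the read's CpG count and m_i the length of the maximal run of
# consecutive methylated calls containing the site (m_i = 1 when the site's
# own call is U).  Two code paths exist deliberately: quantify_site() is a
# naive per-pileup loop kept close to the definitions, quantify_sites() is a
# vectorised data.table pipeline used on cohort-scale data; tests assert their
# exact agreement.

METHODS <- c("wemics", "chalm", "camda", "meanm")

#' Co-methylation run weight of a read at a site
#'
#' For a methylated read (>= 1 M call) covering `position`, returns the CpG
#' count `c`, the run length `m` (maximal run of consecutive M calls, in read
#' CpG order, containing the site; 1 if the site's call is U) and the weight
#' `w = m / c` used by the Wemics numerator.
#'
#' @param read A [meth_read()].
#' @param position 1-based forward-strand C coordinate on the read.
#' @return List with elements `c`, `m`, `w`.
#' @examples
#' r <- meth_read("r1", "chr1", "+", c(100, 105, 110, 120), "MMUM")
#' run_weight(r, 100)  # c = 4, m = 2, w = 0.5
#' run_weight(r, 110)  # site call U: m = 1, w = 0.25
#' @export
run_weight <- function(read, position) {
  if (!inherits(read, "meth_read")) stop_param("read must be a meth_read")
  j <- match(position, read$cpg_positions)
  if (is.na(j)) stop_param(sprintf("position %d not on read %s",
                                   position, read$read_id))
  if (!any(read$calls == "M"))
    stop_param("run_weight is defined for methylated reads only (route all-U reads to n_u)")
  cc <- length(read$calls)
  if (read$calls[j] == "U") {
    m <- 1L
  } else {
    lo <- j
    while (lo > 1L && read$calls[lo - 1L] == "M") lo <- lo - 1L
    hi <- j
    while (hi < cc && read$calls[hi + 1L] == "M") hi <- hi + 1L
    m <- hi - lo + 1L
  }
  list(c = cc, m = m, w = m / cc)
}

#' Quantify methylation at one site from its pileup
#'
#' Direct-from-definition implementation operating on a single
#' [build_pileups()] entry. Requires access to the full read set to recover
#' per-read call strings for the Wemics weights.
#'
#' @param pileup A `site_pileup`.
#' @param reads The `meth_reads` table the pileup was built from.
#' @param method One of `"wemics"`, `"chalm"`, `"camda"`, `"meanm"`, or
#'   `"all"`.
#' @return A single rate in `[0,1]`, or a named vector of all four when
#'   `method = "all"`. Zero coverage yields `NA` (never 0).
#' @export
quantify_site <- function(pileup, reads,
                          method = c("all", METHODS)) {
  method <- match.arg(method)
  n_m <- pileup$n_m; n_u <- pileup$n_u; n_p <- pileup$n_p
  tot <- n_m + n_u
  if (tot < 1L) {
    v <- c(wemics = NA_real_, chalm = NA_real_, camda = NA_real_,
           meanm = NA_real_)
    return(if (method == "all") v else v[[method]])
  }
  A <- 0
  if (method %in% c("all", "wemics")) {
    for (i in pileup$meth_reads)
      A <- A + run_weight(get_read(reads, i), pileup$position)$w
  }
  v <- c(wemics = A / (A + n_u),
         chalm  = n_m / tot,
         camda  = n_p / tot,
         meanm  = (n_m - n_p) / tot)
  if (method == "all") v else v[[method]]
}

# Vectorised production path: per-read run annotation, then per-site sums.
# Returns chrom, pos, coverage, n_m, n_u, n_p, A and the four rate columns.
.site_stats <- function(reads) {
  reads <- as_meth_reads(reads)
  if (nrow(reads) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      coverage = integer(), n_m = integer(), n_u = integer(),
                      n_p = integer(), A = numeric()))
  dt <- copy(reads)
  dt[, c_i := .N, by = "read"]
  dt[, has_m := any(call == "M"), by = "read"]
  # maximal run of identical consecutive calls, within each read
  dt[, runid := rleid(call), by = "read"]
  dt[, runlen := .N, by = c("read", "runid")]
  dt[, m_i := ifelse(call == "M", runlen, 1L)]
  dt[, w := ifelse(has_m, m_i / c_i, NA_real_)]
  st <- dt[, list(coverage = .N,
                  n_m = sum(has_m),
                  n_u = sum(!has_m),
                  n_p = sum(has_m & call == "U"),
                  A = sum(w[has_m])),
           by = c("chrom", "pos")]
  setorder(st, chrom, pos)
  st
}

#' Quantify methylation at every covered site
#'
#' Vectorised pipeline computing all four rates for each CpG position covered
#' by at least `min_coverage` reads.
#'
#' @param reads A `meth_reads` table (any number of chromosomes).
#' @param min_coverage Minimum covering reads for a site to be emitted.
#' @param methods Character vector of rate columns to attach (default all).
#' @return data.table with columns `chrom`, `pos`, `coverage`, `n_m`, `n_u`,
#'   `n_p` and one column per requested method.
#' @export
quantify_sites <- function(reads, min_coverage = 1L, methods = METHODS) {
  methods <- match.arg(methods, METHODS, several.ok = TRUE)
  if (min_coverage < 1L) stop_param("min_coverage must be >= 1")
  st <- .site_stats(reads)
  st <- st[st$coverage >= min_coverage, ]
  tot <- st$n_m + st$n_u
  if ("wemics" %in% methods) st[, wemics := A / (A + n_u)]
  if ("chalm" %in% methods)  st[, chalm := n_m / tot]
  if ("camda" %in% methods)  st[, camda := n_p / tot]
  if ("meanm" %in% methods)  st[, meanm := (n_m - n_p) / tot]
  st[, A := NULL]
  st[]
}

#' Quantify methylation over a region
#'
#' @param reads A `meth_reads` table.
#' @param region List or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param method One of the four rates.
#' @param aggregation `"mean_of_sites"` (unweighted mean of per-site values at
#'   coverage >= `min_site_coverage`; the default) or `"pooled_reads"`
#'   (CHALM/CAMDA only: the region is one unit over all reads overlapping it).
#' @param min_site_coverage Site filter for `mean_of_sites`.
#' @return A single rate, or `NA` if no qualifying site/read.
#' @export
quantify_region <- function(reads, region, method = METHODS,
                            aggregation = c("mean_of_sites", "pooled_reads"),
                            min_site_coverage = 5L) {
  method <- match.arg(method)
  aggregation <- match.arg(aggregation)
  reads <- as_meth_reads(reads)
  lo <- as.integer(region$start); hi <- as.integer(region$end)
  if (aggregation == "pooled_reads") {
    if (!method %in% c("chalm", "camda"))
      stop_param("pooled_reads aggregation is defined for CHALM/CAMDA only")
    sel <- reads$chrom == region$chrom & reads$pos - 1L >= lo & reads$pos - 1L < hi
    sub <- reads[sel, ]
    if (nrow(sub) == 0L) return(NA_real_)
    per <- sub[, list(any_m = any(call == "M"), any_u = any(call == "U")),
               by = "read"]
    if (method == "chalm") return(mean(per$any_m))
    mean(per$any_m & per$any_u)  # partially methylated fraction
  } else {
    st <- quantify_sites(reads, min_coverage = min_site_coverage,
                         methods = method)
    st <- st[st$chrom == region$chrom & st$pos - 1L >= lo & st$pos - 1L < hi, ]
    if (nrow(st) == 0L) return(NA_real_)
    mean(st[[method]])
  }
}

#' Sensitivity of site values to read subsampling
#'
#' Subsamples the read set without replacement and reports, per surviving
#' site, the change in each quantifier. Sites are restricted by three
#' coverage gates: pre-sampling coverage >= `pre_cov`, post-sampling
#' coverage >= `post_cov`, and a coverage drop >= `cov_diff`.
#'
#' @param reads A `meth_reads` table.
#' @param fraction Subsampling fraction, strictly inside (0, 1).
#' @param seed Integer seed (subsampling is deterministic given it).
#' @param pre_cov,post_cov,cov_diff Coverage gates (defaults 10 / 5 / 5).
#' @return data.table with `chrom`, `pos`, `cov_before`, `cov_after` and
#'   `delta_<method>` columns (value before minus value after).
#' @export
subsample_stability <- function(reads, fraction, seed = 1L,
                                pre_cov = 10L, post_cov = 5L, cov_diff = 5L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop_param("fraction must lie strictly inside (0, 1)")
  reads <- as_meth_reads(reads)
  before <- quantify_sites(reads, min_coverage = 1L)
  ids <- unique(reads$read)
  n_keep <- max(1L, floor(fraction * length(ids)))
  keep <- with_seed(seed, sample(ids, n_keep))
  after <- quantify_sites(reads[reads$read %in% keep, ], min_coverage = 1L)
  m <- merge(before, after, by = c("chrom", "pos"),
             suffixes = c("_before", "_after"))
  m <- m[m$coverage_before >= pre_cov & m$coverage_after >= post_cov &
           (m$coverage_before - m$coverage_after) >= cov_diff, ]
  out <- m[, list(chrom, pos, cov_before = coverage_before,
                  cov_after = coverage_after)]
  for (meth in METHODS)
    out[[paste0("delta_", meth)]] <-
      m[[paste0(meth, "_before")]] - m[[paste0(meth, "_after")]]
  setDT(out)[]
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}
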