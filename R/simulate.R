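# Synthetic epiallele generator.
#
# Reads are emulated as two-state (M/U) Markov chains along the CpGs of a
# region: the stationary methylation probability is theta and the persistence
# rho controls co-methylation run structure without moving the marginal,
# via P(M->M) = rho + (1-rho) theta and P(U->M) = (1-rho) theta.  A paired
# cohort layers per-patient baseline noise and planted tumor shifts (DMRs)
# on top, and an expression layer with a chosen population correlation to
# promoter methylation completes the end-to-end test bed.

#' Region specification for the read simulator
#'
#' @param chrom Chromosome name.
#' @param cpg_positions Increasing 1-based CpG positions (>= 1 site).
#' @param theta_normal Target stationary methylation level in `[0,1]`.
#' @param delta Planted tumor shift; `theta_normal + delta` must stay in
#'   `[0,1]`.
#' @param rho Within-read methylation persistence in `[0,1]`.
#' @param coverage_lambda Mean reads covering a site.
#' @param cpgs_per_read_mean Mean CpGs per read (default 5, the typical RRBS
#'   value).
#' @return Object of class `sim_region_spec`.
#' @export
sim_region_spec <- function(chrom, cpg_positions, theta_normal, delta = 0,
                            rho = 0.8, coverage_lambda = 30,
                            cpgs_per_read_mean = 5) {
  cpg_positions <- as.integer(cpg_positions)
  if (length(cpg_positions) < 1L) stop_param("region must contain >= 1 CpG")
  if (any(diff(cpg_positions) <= 0L)) stop_param("cpg_positions must increase")
  if (theta_normal < 0 || theta_normal > 1) stop_param("theta_normal outside [0,1]")
  if (theta_normal + delta < 0 || theta_normal + delta > 1)
    stop_param("theta_normal + delta outside [0,1]")
  if (rho < 0 || rho > 1) stop_param("rho outside [0,1]")
  structure(list(chrom = chrom, cpg_positions = cpg_positions,
                 theta_normal = theta_normal, delta = delta, rho = rho,
                 coverage_lambda = coverage_lambda,
                 cpgs_per_read_mean = cpgs_per_read_mean),
            class = "sim_region_spec")
}

# Vectorized Markov-chain call matrix: n reads x k sites, columns evolve
# left to right.  Returns logical matrix (TRUE = M).
.markov_calls <- function(n, k, theta, rho) {
  calls <- matrix(FALSE, n, k)
  calls[, 1L] <- runif(n) < theta
  if (k > 1L) {
    p_mm <- rho + (1 - rho) * theta
    p_um <- (1 - rho) * theta
    for (j in 2L:k) {
      p <- ifelse(calls[, j - 1L], p_mm, p_um)
      calls[, j] <- runif(n) < p
    }
  }
  calls
}

#' Simulate reads over one region
#'
#' Each read picks a uniform start CpG and a CpG count of
#' `1 + Poisson(cpgs_per_read_mean - 1)` truncated to the region, then draws
#' M/U calls from the persistence-blended Markov chain (see
#' [sim_region_spec()]). Deterministic under a fixed seed.
#'
#' @param spec A [sim_region_spec()].
#' @param condition `"normal"` or `"tumor"` (applies the planted `delta`).
#' @param n_reads Number of reads; default derives from `coverage_lambda`.
#' @param seed Integer seed or `NULL` to use the current RNG stream.
#' @param theta_override Optional explicit methylation level (bypasses
#'   `theta_normal`/`delta`; used by the cohort generator for patient noise).
#' @param read_prefix Prefix for generated read ids.
#' @return A `meth_reads` table.
#' @export
simulate_reads <- function(spec, condition = c("normal", "tumor"),
                           n_reads = NULL, seed = NULL,
                           theta_override = NULL, read_prefix = "sim") {
  condition <- match.arg(condition)
  if (!inherits(spec, "sim_region_spec")) stop_param("spec must be a sim_region_spec")
  k <- length(spec$cpg_positions)
  theta <- theta_override %||%
    (spec$theta_normal + if (condition == "tumor") spec$delta else 0)
  theta <- min(1, max(0, theta))
  if (is.null(n_reads))
    n_reads <- max(1L, ceiling(spec$coverage_lambda * k /
                                 min(spec$cpgs_per_read_mean, k)))
  with_seed(seed, {
    starts <- sample.int(k, n_reads, replace = TRUE)
    want <- 1L + rpois(n_reads, max(0, spec$cpgs_per_read_mean - 1))
    counts <- pmin(want, k - starts + 1L)
    maxc <- max(counts)
    calls <- .markov_calls(n_reads, maxc, theta, spec$rho)
    # assemble the long-format table directly (no per-read objects)
    ridx <- rep.int(seq_len(n_reads), counts)
    off <- sequence(counts) - 1L
    site <- starts[ridx] + off
    new_meth_reads(data.table(
      read = ridx,
      read_id = sprintf("%s_%05d", read_prefix, ridx),
      chrom = spec$chrom, strand = "+",
      pos = spec$cpg_positions[site],
      call = ifelse(calls[cbind(ridx, off + 1L)], "M", "U")))
  })
}

# Stable FNV-1a string hash folded below 2^31; combined with the global seed
# so per-sample streams never reshuffle when samples are added.
.stable_seed <- function(global_seed, key) {
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer((h + as.numeric(global_seed) * 2654435761) %% 2147483629 + 1)
}

#' Default paired-cohort configuration
#'
#' The stated world of the simulator: 20 patient pairs, 200 regions of 10
#' CpGs each, 10 of them planted DMRs with a tumor shift of magnitude 0.3
#' (the observed mean paired tumor-normal difference in DMRs), 30x coverage,
#' ~5 CpGs per read, persistence 0.8 (most reads fully methylated or fully
#' unmethylated), patient-level baseline noise sd 0.05.
#'
#' @param n_patients,n_regions,n_dmr,n_cpg,cpg_spacing,region_gap,delta,rho
#'   Cohort shape parameters (see description for defaults).
#' @param coverage_lambda,cpgs_per_read_mean Read generation parameters.
#' @param patient_sd Per-patient baseline methylation noise sd.
#' @param theta_range Range of per-region baseline methylation levels.
#' @param hyper_fraction Fraction of planted DMRs shifted upward in tumor.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 20L, n_regions = 200L, n_dmr = 10L,
                          n_cpg = 10L, cpg_spacing = 25L, region_gap = 2000L,
                          delta = 0.3, rho = 0.8, coverage_lambda = 30,
                          cpgs_per_read_mean = 5, patient_sd = 0.05,
                          theta_range = c(0.15, 0.55), hyper_fraction = 0.5) {
  if (n_dmr > n_regions) stop_param("n_dmr cannot exceed n_regions")
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a paired tumor/normal cohort with planted DMRs
#'
#' Lays `n_regions` CpG regions along one synthetic chromosome (separated by
#' more than any DMR-caller gap), plants `n_dmr` of them with a tumor shift
#' of `delta` (hyper) or `-delta` (hypo), draws per-patient baseline levels
#' `Normal(theta_region, patient_sd)` clipped to `[0,1]`, and generates reads
#' per patient and condition. Per-sample RNG streams are derived from the
#' global seed by stable hashing of the sample/region key, so adding samples
#' never reshuffles existing ones.
#'
#' @param config A [cohort_config()].
#' @param seed Global integer seed.
#' @return List with `reads` (nested: `reads[[patient]][[condition]]`, each a
#'   `meth_reads` table), `truth` (per-region table: `region`, `chrom`,
#'   `start`, `end`, `is_dmr`, `delta`, `direction`), `samples` (patient
#'   ids), and `config`.
#' @export
simulate_paired_cohort <- function(config = cohort_config(), seed = 1L) {
  cfg <- config
  region_span <- cfg$n_cpg * cfg$cpg_spacing
  origin <- 1000L + (seq_len(cfg$n_regions) - 1L) * (region_span + cfg$region_gap)
  region_pos <- lapply(origin, function(o)
    o + (seq_len(cfg$n_cpg) - 1L) * cfg$cpg_spacing)
  setup <- with_seed(.stable_seed(seed, "cohort-setup"), {
    theta <- runif(cfg$n_regions, cfg$theta_range[1L], cfg$theta_range[2L])
    dmr_idx <- sort(sample.int(cfg$n_regions, cfg$n_dmr))
    n_hyper <- round(cfg$n_dmr * cfg$hyper_fraction)
    hyper <- dmr_idx[seq_len(n_hyper)]
    list(theta = theta, dmr_idx = dmr_idx, hyper = hyper)
  })
  delta <- numeric(cfg$n_regions)
  delta[setup$dmr_idx] <- -cfg$delta
  delta[setup$hyper] <- cfg$delta
  # hypo regions need headroom below; raise their baseline
  theta <- setup$theta
  theta[delta < 0] <- pmin(0.95, theta[delta < 0] + cfg$delta)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  n_clip_fail <- 0L
  reads <- lapply(patients, function(pid) {
    per_cond <- lapply(c(normal = "normal", tumor = "tumor"), function(cond) {
      region_reads <- vector("list", cfg$n_regions)
      for (rg in seq_len(cfg$n_regions)) {
        base <- with_seed(.stable_seed(seed, paste0(pid, ":base:", rg)),
                          rnorm(1L, theta[rg], cfg$patient_sd))
        th <- base + if (cond == "tumor") delta[rg] else 0
        if (th < 0 || th > 1) n_clip_fail <<- n_clip_fail + 1L
        th <- min(1, max(0, th))
        spec <- sim_region_spec(
          "chrSim", region_pos[[rg]], theta[rg], delta[rg],
          rho = cfg$rho, coverage_lambda = cfg$coverage_lambda,
          cpgs_per_read_mean = cfg$cpgs_per_read_mean)
        region_reads[[rg]] <- simulate_reads(
          spec, cond, seed = .stable_seed(seed, paste0(pid, ":", cond, ":", rg)),
          theta_override = th, read_prefix = sprintf("%s_%s_r%03d", pid, cond, rg))
      }
      dt <- rbindlist(region_reads)
      dt[, read := rleid(read_id)]
      new_meth_reads(dt)
    })
    per_cond
  })
  names(reads) <- patients
  total_draws <- cfg$n_patients * cfg$n_regions * 2L
  if (n_clip_fail > 0.1 * total_draws)
    warning(sprintf("infeasible theta after clipping in %d/%d draws",
                    n_clip_fail, total_draws))
  truth <- data.table(
    region = seq_len(cfg$n_regions), chrom = "chrSim",
    start = vapply(region_pos, function(p) p[1L] - 1L, integer(1L)),
    end = vapply(region_pos, function(p) p[length(p)] + 1L, integer(1L)),
    is_dmr = delta != 0, delta = delta,
    direction = ifelse(delta > 0, "hyper", ifelse(delta < 0, "hypo", "none"))
  )
  list(reads = reads, truth = truth, samples = patients, config = cfg)
}

#' Build a paired methylation matrix from simulated cohort reads
#'
#' Quantifies every sample with the chosen method and assembles the
#' site-by-patient tumor/normal layers consumed by [detect_dmrs()].
#'
#' @param cohort Output of [simulate_paired_cohort()].
#' @param method Quantifier column to use (default `"wemics"`).
#' @param min_coverage Per-site, per-sample coverage gate.
#' @return A [paired_meth_matrix()].
#' @export
cohort_meth_matrix <- function(cohort, method = "wemics", min_coverage = 5L) {
  patients <- cohort$samples
  per <- lapply(patients, function(pid) {
    lapply(c("normal", "tumor"), function(cond) {
      st <- quantify_sites(cohort$reads[[pid]][[cond]],
                           min_coverage = min_coverage, methods = method)
      st[, list(pos, value = get(method))]
    })
  })
  pos <- sort(unique(unlist(lapply(per, function(x)
    c(x[[1L]]$pos, x[[2L]]$pos)))))
  grab <- function(tbl) {
    v <- rep(NA_real_, length(pos))
    v[match(tbl$pos, pos)] <- tbl$value
    v
  }
  normal <- vapply(per, function(x) grab(x[[1L]]), numeric(length(pos)))
  tumor <- vapply(per, function(x) grab(x[[2L]]), numeric(length(pos)))
  colnames(normal) <- colnames(tumor) <- patients
  paired_meth_matrix("chrSim", pos, tumor, normal)
}

#' Simulate an expression layer correlated with promoter methylation
#'
#' For each gene (row of `promoter_methylation`), expression is generated as
#' a linear function of the methylation values plus Gaussian noise, with the
#' coefficient and noise variance solved so the population Pearson
#' correlation equals `r_target`; output is shifted onto a non-negative
#' log2(FPKM+1)-like scale.
#'
#' @param promoter_methylation Numeric matrix (genes x samples) or vector.
#' @param r_target Target correlation, strictly inside (-1, 1).
#' @param seed Integer seed.
#' @param base_mean,base_sd Location/scale of the expression distribution
#'   (defaults 6 and 1.5 on the log2(FPKM+1) scale).
#' @return Matrix of expression values, same shape as the input.
#' @export
simulate_expression <- function(promoter_methylation, r_target, seed = 1L,
                                base_mean = 6, base_sd = 1.5) {
  if (!is.numeric(r_target) || abs(r_target) >= 1)
    stop_param("r_target must lie strictly inside (-1, 1)")
  m <- if (is.matrix(promoter_methylation)) promoter_methylation
       else matrix(promoter_methylation, nrow = 1L)
  if (any(apply(m, 1L, sd) == 0))
    stop_param("degenerate methylation variance in some gene")
  with_seed(seed, {
    out <- t(apply(m, 1L, function(g) {
      z <- (g - mean(g)) / sd(g)
      e <- r_target * z + sqrt(1 - r_target^2) * rnorm(length(g))
      pmax(0, base_mean + base_sd * e)
    }))
    dimnames(out) <- dimnames(m)
    if (!is.matrix(promoter_methylation)) out <- drop(out)
    out
  })
}
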