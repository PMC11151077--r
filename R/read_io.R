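# Read-level methylation containers and I/O.
#
# A single read is a `meth_read` (list: read_id, chrom, strand, cpg_positions,
# calls).  Collections are stored long-format as a `meth_reads` data.table with
# one row per CpG call (columns read, read_id, chrom, strand, pos, call); this
# is the shape every quantifier consumes.

#' Construct a single methylation read
#'
#' A `meth_read` records the ordered CpG calls of one sequenced read on
#' forward-strand coordinates.
#'
#' @param read_id Read name (non-empty string).
#' @param chrom Chromosome (non-empty string).
#' @param strand `"+"` or `"-"`.
#' @param cpg_positions Strictly increasing integer vector of 1-based
#'   forward-strand C coordinates.
#' @param calls Character vector over `{"M","U"}` of the same length, or a
#'   single string such as `"MMUM"`.
#' @return An object of class `meth_read`.
#' @examples
#' meth_read("r1", "chr1", "+", c(100L, 105L, 110L, 120L), "MMUM")
#' @export
meth_read <- function(read_id, chrom, strand, cpg_positions, calls) {
  if (length(calls) == 1L && nchar(calls[1L]) > 1L)
    calls <- strsplit(calls, "", fixed = TRUE)[[1L]]
  cpg_positions <- as.integer(cpg_positions)
  if (!is.character(chrom) || !nzchar(chrom))
    stop_format("chrom must be a non-empty string")
  if (!strand %in% c("+", "-"))
    stop_format(sprintf("strand must be '+' or '-', got '%s'", strand))
  if (length(cpg_positions) < 1L)
    stop_format("a read must carry at least one CpG call")
  if (length(calls) != length(cpg_positions))
    stop_format(sprintf("call length %d ≠ %d positions",
                        length(calls), length(cpg_positions)))
  if (any(diff(cpg_positions) <= 0L))
    stop_format("cpg_positions must be strictly increasing")
  if (!all(calls %in% c("M", "U")))
    stop_format(sprintf("calls restricted to {M,U}; found '%s'",
                        paste(setdiff(calls, c("M", "U")), collapse = "")))
  structure(list(read_id = as.character(read_id), chrom = chrom,
                 strand = strand, cpg_positions = cpg_positions,
                 calls = calls),
            class = "meth_read")
}

#' @export
print.meth_read <- function(x, ...) {
  cat(sprintf("<meth_read %s %s%s %s @ %s>\n", x$read_id, x$chrom, x$strand,
              paste(x$calls, collapse = ""),
              paste(x$cpg_positions, collapse = ",")))
  invisible(x)
}

#' Assemble a read collection
#'
#' Builds the long-format `meth_reads` table used by all quantifiers from a
#' list of [meth_read()] objects.
#'
#' @param reads List of `meth_read` objects (possibly empty).
#' @return A `meth_reads` data.table with one row per CpG call and columns
#'   `read` (integer read index), `read_id`, `chrom`, `strand`, `pos`, `call`.
#' @export
as_meth_reads <- function(reads) {
  if (inherits(reads, "meth_reads")) return(reads)
  if (inherits(reads, "meth_read")) reads <- list(reads)
  if (length(reads) == 0L) return(empty_meth_reads())
  ok <- vapply(reads, inherits, logical(1L), what = "meth_read")
  if (!all(ok)) stop_param("as_meth_reads expects a list of meth_read objects")
  n <- vapply(reads, function(r) length(r$cpg_positions), integer(1L))
  dt <- data.table(
    read    = rep.int(seq_along(reads), n),
    read_id = rep.int(vapply(reads, `[[`, character(1L), "read_id"), n),
    chrom   = rep.int(vapply(reads, `[[`, character(1L), "chrom"), n),
    strand  = rep.int(vapply(reads, `[[`, character(1L), "strand"), n),
    pos     = unlist(lapply(reads, `[[`, "cpg_positions"), use.names = FALSE),
    call    = unlist(lapply(reads, `[[`, "calls"), use.names = FALSE)
  )
  new_meth_reads(dt)
}

new_meth_reads <- function(dt) {
  setDT(dt)
  setattr(dt, "class", c("meth_reads", class(data.table())))
  dt
}

empty_meth_reads <- function() {
  new_meth_reads(data.table(read = integer(), read_id = character(),
                            chrom = character(), strand = character(),
                            pos = integer(), call = character()))
}

#' Number of reads in a collection
#' @param reads A `meth_reads` table.
#' @return Integer count of distinct reads.
#' @export
n_reads <- function(reads) {
  if (nrow(reads) == 0L) return(0L)
  length(unique(reads$read))
}

#' Extract one read from a collection
#' @param reads A `meth_reads` table.
#' @param i Read index (value of the `read` column).
#' @return A [meth_read()] object.
#' @export
get_read <- function(reads, i) {
  rr <- reads[reads$read == i, ]
  if (nrow(rr) == 0L) stop_param(sprintf("no read with index %d", i))
  meth_read(rr$read_id[1L], rr$chrom[1L], rr$strand[1L], rr$pos, rr$call)
}

# == READPAT fixture format ====================================================

#' Parse the READPAT plain-text read-pattern format
#'
#' READPAT is a deterministic tab-separated fixture format with one read per
#' line: `read_id  chrom  strand  pos1,pos2,...  CALLSTRING`, where the call
#' string is over `{M,U}` and aligns 1:1 with the comma-joined positions.
#' Lines starting with `#` are comments.
#'
#' @param input Path to a READPAT file, or a character vector of lines.
#' @return A `meth_reads` table, input order preserved.
#' @seealso [write_readpat()] for the inverse.
#' @export
parse_readpat <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else as.character(input)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_meth_reads())
  reads <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 5L)
      stop_format(sprintf("line %d: expected 5 tab-separated fields, got %d",
                          k, length(f)))
    pos <- suppressWarnings(as.integer(strsplit(f[4L], ",", fixed = TRUE)[[1L]]))
    if (anyNA(pos))
      stop_format(sprintf("line %d: non-integer position in '%s'", k, f[4L]))
    calls <- strsplit(f[5L], "", fixed = TRUE)[[1L]]
    if (length(calls) != length(pos))
      stop_format(sprintf("line %d: call length %d ≠ %d positions",
                          k, length(calls), length(pos)))
    if (any(diff(pos) <= 0L))
      stop_format(sprintf("line %d: positions not strictly increasing", k))
    if (!all(calls %in% c("M", "U")))
      stop_format(sprintf("line %d: calls outside {M,U}", k))
    reads[[k]] <- meth_read(f[1L], f[2L], f[3L], pos, calls)
  }
  as_meth_reads(reads)
}

#' Write reads in READPAT format
#' @param reads A `meth_reads` table.
#' @param path Output file path, or `NULL` to return the lines.
#' @return The character lines, invisibly when `path` is given.
#' @export
write_readpat <- function(reads, path = NULL) {
  reads <- as_meth_reads(reads)
  if (nrow(reads) == 0L) {
    lines <- character()
  } else {
    per <- reads[, list(read_id = read_id[1L], chrom = chrom[1L],
                        strand = strand[1L],
                        posstr = paste(pos, collapse = ","),
                        callstr = paste(call, collapse = "")),
                 by = "read"]
    lines <- sprintf("%s\t%s\t%s\t%s\t%s", per$read_id, per$chrom, per$strand,
                     per$posstr, per$callstr)
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# == SAM/BAM with Bismark-dialect XM tag ======================================

# Walk one CIGAR string, returning the reference coordinate of each query base
# (NA for soft-clipped / inserted bases).  Supported ops: M = X I D S.
.cigar_ref_positions <- function(cigar, pos, qlen) {
  ops  <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  bad <- setdiff(ops, c("M", "=", "X", "I", "D", "S"))
  if (length(bad) > 0L)
    stop_format(sprintf("unsupported CIGAR op '%s' in '%s'", bad[1L], cigar))
  refpos <- rep.int(NA_integer_, qlen)
  q <- 1L; r <- pos
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      refpos[q:(q + len - 1L)] <- r:(r + len - 1L)
      q <- q + len; r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else { # D
      r <- r + len
    }
  }
  refpos
}

#' Parse bisulfite alignments carrying a per-base methylation call tag
#'
#' Reads SAM or BAM records whose `XM` tag follows the Bismark dialect
#' (`Z` = methylated CpG, `z` = unmethylated CpG; all other characters
#' ignored) and converts them to a `meth_reads` table. Calls on
#' reverse-strand alignments sit on the G of the CpG and are shifted by -1 so
#' both strands address the forward-strand C. Unmapped, secondary,
#' supplementary and duplicate-flagged records are skipped (see
#' `keep_duplicates`); records lacking the tag are skipped with a counted
#' warning.
#'
#' @param file Path to a SAM (`.sam`) or BAM file. SAM input is converted on
#'   the fly via [Rsamtools::asBam()].
#' @param region Optional `"chrom:start-end"` (1-based, inclusive) restricting
#'   the reads returned to those overlapping the window.
#' @param strict If `TRUE`, record-level problems (tag/query length mismatch,
#'   unsupported CIGAR op) abort instead of skip-and-count.
#' @param keep_duplicates Keep duplicate-flagged records (default drops them).
#' @return A `meth_reads` table with an attribute `skipped`: a named integer
#'   vector of per-reason skip counters.
#' @export
parse_bisulfite_alignments <- function(file, region = NULL, strict = FALSE,
                                       keep_duplicates = FALSE) {
  if (!file.exists(file)) stop_input(sprintf("alignment file not found: %s", file))
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(file, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "cigar", "qwidth")
  p <- Rsamtools::ScanBamParam(what = what, tag = "XM")
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  xm <- b$tag$XM
  n <- length(b$qname)
  skipped <- c(skipped_unmapped = 0L, skipped_secondary = 0L,
               skipped_supplementary = 0L, skipped_duplicate = 0L,
               skipped_no_tag = 0L, skipped_bad_record = 0L)
  out <- vector("list", n)
  idx <- 0L
  for (k in seq_len(n)) {
    flag <- b$flag[k]
    if (bitwAnd(flag, 4L) != 0L)   { skipped["skipped_unmapped"] <- skipped["skipped_unmapped"] + 1L; next }
    if (bitwAnd(flag, 256L) != 0L) { skipped["skipped_secondary"] <- skipped["skipped_secondary"] + 1L; next }
    if (bitwAnd(flag, 2048L) != 0L){ skipped["skipped_supplementary"] <- skipped["skipped_supplementary"] + 1L; next }
    if (!keep_duplicates && bitwAnd(flag, 1024L) != 0L) {
      skipped["skipped_duplicate"] <- skipped["skipped_duplicate"] + 1L; next
    }
    tag <- if (is.null(xm)) NA_character_ else xm[k]
    if (is.na(tag)) {
      if (strict) stop_format(sprintf("record %s lacks the XM tag", b$qname[k]))
      skipped["skipped_no_tag"] <- skipped["skipped_no_tag"] + 1L; next
    }
    qlen <- b$qwidth[k]
    if (nchar(tag) != qlen) {
      msg <- sprintf("record %s: XM length %d ≠ query length %d",
                     b$qname[k], nchar(tag), qlen)
      if (strict) stop_format(msg)
      skipped["skipped_bad_record"] <- skipped["skipped_bad_record"] + 1L; next
    }
    refpos <- tryCatch(.cigar_ref_positions(b$cigar[k], b$pos[k], qlen),
                       cometh_format_error = function(e) {
                         if (strict) stop(e)
                         NULL
                       })
    if (is.null(refpos)) {
      skipped["skipped_bad_record"] <- skipped["skipped_bad_record"] + 1L; next
    }
    chars <- strsplit(tag, "", fixed = TRUE)[[1L]]
    keep <- chars %in% c("Z", "z") & !is.na(refpos)
    if (!any(keep)) next
    pos <- refpos[keep]
    if (as.character(b$strand[k]) == "-") pos <- pos - 1L
    calls <- ifelse(chars[keep] == "Z", "M", "U")
    o <- order(pos)
    pos <- pos[o]; calls <- calls[o]
    dup <- duplicated(pos)              # deletion-split CpG edge case
    pos <- pos[!dup]; calls <- calls[!dup]
    idx <- idx + 1L
    out[[idx]] <- meth_read(b$qname[k], as.character(b$rname[k]),
                            as.character(b$strand[k]), pos, calls)
  }
  out <- out[seq_len(idx)]
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4L) stop_param(sprintf("bad region '%s'", region))
    lo <- as.integer(m[3L]); hi <- as.integer(m[4L])
    out <- Filter(function(r) r$chrom == m[2L] &&
                    any(r$cpg_positions >= lo & r$cpg_positions <= hi), out)
  }
  res <- as_meth_reads(out)
  setattr(res, "skipped", skipped)
  res
}

# == pileups ===================================================================

#' Build per-site read pileups
#'
#' Collects, for every CpG position covered by at least `min_coverage` reads,
#' the reads overlapping it, partitioned into methylated reads (at least one M
#' call anywhere on the read) and unmethylated reads (all calls U). `n_p`
#' counts methylated reads whose call *at this site* is U (the partially
#' methylated group of the CAMDA numerator).
#'
#' @param reads A `meth_reads` table on a single chromosome (or list of
#'   [meth_read()]).
#' @param min_coverage Minimum covering reads per emitted site (>= 1).
#' @return Named list (`"chrom:pos"`) of `site_pileup` objects with fields
#'   `chrom`, `position`, `meth_reads`, `unmeth_reads` (integer read indices),
#'   `n_m`, `n_u`, `n_p`.
#' @export
build_pileups <- function(reads, min_coverage = 1L) {
  reads <- as_meth_reads(reads)
  if (min_coverage < 1L) stop_param("min_coverage must be >= 1")
  if (nrow(reads) == 0L) return(structure(list(), names = character()))
  if (length(unique(reads$chrom)) > 1L)
    stop_param("build_pileups expects reads on a single chromosome")
  has_m <- reads[, list(has_m = any(call == "M")), by = "read"]
  hm <- structure(has_m$has_m, names = as.character(has_m$read))
  cov <- reads[, .N, by = c("chrom", "pos")]
  keep <- cov[cov$N >= min_coverage, ]
  if (nrow(keep) == 0L) return(structure(list(), names = character()))
  setorder(keep, pos)
  out <- vector("list", nrow(keep))
  for (k in seq_len(nrow(keep))) {
    p <- keep$pos[k]
    here <- reads[reads$pos == p, ]
    meth <- hm[as.character(here$read)]
    out[[k]] <- structure(list(
      chrom = keep$chrom[k], position = p,
      meth_reads = here$read[meth], unmeth_reads = here$read[!meth],
      n_m = sum(meth), n_u = sum(!meth),
      n_p = sum(meth & here$call == "U")
    ), class = "site_pileup")
  }
  names(out) <- sprintf("%s:%d", keep$chrom, keep$pos)
  out
}

#' @export
print.site_pileup <- function(x, ...) {
  cat(sprintf("<site_pileup %s:%d n_m=%d n_u=%d n_p=%d>\n",
              x$chrom, x$position, x$n_m, x$n_u, x$n_p))
  invisible(x)
}

# == site table output =========================================================

#' Write per-site quantification results
#'
#' bedGraph output uses 0-based half-open intervals of width 2 (the CpG
#' dinucleotide: site at 1-based position p becomes `[p-1, p+1)`); TSV output
#' keeps all value columns plus `n_m`, `n_u`, `n_p`.
#'
#' @param results Per-site table as returned by [quantify_sites()] (columns
#'   `chrom`, `pos` and one or more method columns).
#' @param path Output file path.
#' @param format `"tsv"` or `"bedGraph"`.
#' @param method For bedGraph, which value column to emit.
#' @param header Optional character vector of `#`-prefixed provenance lines.
#' @return Invisibly, the path.
#' @export
write_site_table <- function(results, path, format = c("tsv", "bedGraph"),
                             method = "wemics", header = NULL) {
  format <- match.arg(format)
  results <- as.data.table(results)
  valcols <- intersect(c("wemics", "chalm", "camda", "meanm"), names(results))
  vals <- unlist(results[, valcols, with = FALSE], use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) > 0L && (min(vals) < 0 || max(vals) > 1))
    stop_param("methylation values outside [0,1]; refusing to write")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_input(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (format == "bedGraph") {
    if (!method %in% names(results))
      stop_param(sprintf("no column '%s' in results", method))
    dt <- results[!is.na(results[[method]]),
                  list(chrom = chrom, start = pos - 1L, end = pos + 1L,
                       value = get(method))]
    if (nrow(dt) > 0L)
      writeLines(sprintf("%s\t%d\t%d\t%s", dt$chrom, dt$start, dt$end,
                         format(dt$value, digits = 15, trim = TRUE,
                                scientific = FALSE)), con)
  } else {
    writeLines(paste(names(results), collapse = "\t"), con)
    if (nrow(results) > 0L) {
      body <- do.call(paste, c(lapply(results, function(col) {
        if (is.double(col)) format(col, digits = 15, trim = TRUE,
                                   scientific = FALSE) else as.character(col)
      }), sep = "\t"))
      writeLines(body, con)
    }
  }
  invisible(path)
}
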