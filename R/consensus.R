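#' @importFrom IRanges IRanges reduce disjoin findOverlaps start end width
#' @importFrom S4Vectors queryHits subjectHits
NULL

# data.frame regions (chrom/start/end, 1-based inclusive) -> list of
# IRanges per chromosome, original row indices carried in mcols.
.by_chrom <- function(regions) {
  split(seq_len(nrow(regions)), regions$chrom)
}

.ir <- function(regions, rows) {
  IRanges::IRanges(start = regions$start[rows], end = regions$end[rows])
}

#' Merge a line's regions across its comparisons
#'
#' A line is scanned against every other line; the per-line region set of
#' one method is the union of the intervals found in any of those
#' comparisons, with overlapping or adjacent intervals (gap of at most 1 bp)
#' coalesced.  Contributing comparisons are recorded per merged interval.
#'
#' @param regions region data frame with `chrom`, `start`, `end` and
#'   optionally `comparison`.
#' @param line line label to attach.
#' @param method method label to attach.
#' @return Merged region data frame with `comparisons` provenance column.
#' @export
merge_comparisons <- function(regions, line = NA_character_,
                              method = NA_character_) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), line = character(),
                      method = character(), comparisons = character(),
                      stringsAsFactors = FALSE)
  if (is.null(regions) || nrow(regions) == 0) return(empty)
  out <- list()
  for (ch in names(.by_chrom(regions))) {
    rows <- .by_chrom(regions)[[ch]]
    ir <- .ir(regions, rows)
    merged <- IRanges::reduce(ir, min.gapwidth = 2L)
    ov <- IRanges::findOverlaps(merged, ir, maxgap = 1L)
    comps <- vapply(seq_along(merged), function(k) {
      src <- rows[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]]
      if ("comparison" %in% names(regions))
        paste(sort(unique(regions$comparison[src])), collapse = ",")
      else ""
    }, character(1))
    out[[ch]] <- data.frame(
      chrom = ch, start = IRanges::start(merged), end = IRanges::end(merged),
      line = line, method = method, comparisons = comps,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Intersect the two scan methods for one line
#'
#' Keeps each XP-CLR region that overlaps (by at least 1 bp) any XP-EHH
#' region of the same line; the retained spans are the XP-CLR spans, which
#' are typically the narrower and more precise of the two.  One wide XP-EHH
#' region may support several XP-CLR regions.
#'
#' @param xpehh_regions,xpclr_regions merged per-line region data frames.
#' @param line line label to attach.
#' @return Candidate region data frame (XP-CLR spans) with an
#'   `xpehh_support` column listing the overlapping XP-EHH intervals.
#' @export
intersect_methods <- function(xpehh_regions, xpclr_regions,
                              line = NA_character_) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), line = character(),
                      xpehh_support = character(), stringsAsFactors = FALSE)
  if (is.null(xpclr_regions) || nrow(xpclr_regions) == 0 ||
      is.null(xpehh_regions) || nrow(xpehh_regions) == 0) return(empty)
  out <- list()
  for (ch in unique(xpclr_regions$chrom)) {
    crows <- which(xpclr_regions$chrom == ch)
    erows <- which(xpehh_regions$chrom == ch)
    if (length(erows) == 0) next
    ov <- IRanges::findOverlaps(.ir(xpclr_regions, crows),
                                .ir(xpehh_regions, erows))
    hit <- unique(S4Vectors::queryHits(ov))
    if (length(hit) == 0) next
    support <- vapply(hit, function(k) {
      e <- erows[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]]
      paste(sprintf("%d-%d", xpehh_regions$start[e], xpehh_regions$end[e]),
            collapse = ",")
    }, character(1))
    out[[ch]] <- data.frame(
      chrom = ch,
      start = xpclr_regions$start[crows[hit]],
      end = xpclr_regions$end[crows[hit]],
      line = line, xpehh_support = support, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cross-line consensus regions
#'
#' Finds the genomic intervals where the candidate regions of at least
#' `min_lines` lines overlap a common stretch.  The genome is cut at every
#' candidate boundary; elementary segments covered by `>= min_lines` lines
#' are kept and adjacent segments with an identical supporting line set are
#' merged, so each consensus interval is the trimmed common overlap and is
#' contained in every supporter's own candidate region.
#'
#' @param candidates candidate region data frame with `chrom`, `start`,
#'   `end`, `line`.
#' @param min_lines minimum number of supporting lines (default 2).
#' @return Consensus data frame: `chrom`, `start`, `end`, `lines`
#'   (comma-separated), `n_lines`, `provenance` (the untrimmed per-line
#'   spans).
#' @export
cross_line_consensus <- function(candidates, min_lines = 2) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), lines = character(),
                      n_lines = integer(), provenance = character(),
                      stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0) return(empty)
  out <- list()
  for (ch in unique(candidates$chrom)) {
    rows <- which(candidates$chrom == ch)
    ir <- .ir(candidates, rows)
    dj <- IRanges::disjoin(ir)
    ov <- IRanges::findOverlaps(dj, ir, type = "within")
    sets <- vapply(seq_along(dj), function(k) {
      src <- rows[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]]
      paste(sort(unique(candidates$line[src])), collapse = ",")
    }, character(1))
    nl <- vapply(strsplit(sets, ","), function(x) length(x[nzchar(x)]),
                 integer(1))
    keep <- which(nl >= min_lines)
    if (length(keep) == 0) next
    st <- IRanges::start(dj)[keep]
    en <- IRanges::end(dj)[keep]
    ss <- sets[keep]
    grp <- cumsum(c(1, !(st[-1] == en[-length(en)] + 1L &
                           ss[-1] == ss[-length(ss)])))
    for (g in unique(grp)) {
      i <- which(grp == g)
      reg_start <- min(st[i])
      reg_end <- max(en[i])
      lines <- strsplit(ss[i[1]], ",")[[1]]
      src <- rows[candidates$start[rows] <= reg_end &
                    candidates$end[rows] >= reg_start &
                    candidates$line[rows] %in% lines]
      prov <- paste(sprintf("%s:%d-%d", candidates$line[src],
                            candidates$start[src], candidates$end[src]),
                    collapse = ";")
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = reg_start, end = reg_end,
        lines = ss[i[1]], n_lines = length(lines), provenance = prov,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of the genome covered by a region set
#'
#' @param regions region data frame (`chrom`, `start`, `end`).
#' @param chrom_lengths named vector of analyzed chromosome lengths (bp);
#'   chromosomes without regions still count in the denominator.
#' @return Non-redundant covered bp divided by total genome bp.
#' @export
genome_coverage <- function(regions, chrom_lengths) {
  total <- sum(as.numeric(chrom_lengths))
  if (is.null(regions) || nrow(regions) == 0) return(0)
  bad_chr <- setdiff(unique(regions$chrom), names(chrom_lengths))
  if (length(bad_chr) > 0)
    stop("region chromosome(s) missing from chrom_lengths: ",
         paste(bad_chr, collapse = ", "))
  covered <- 0
  for (ch in unique(regions$chrom)) {
    rows <- which(regions$chrom == ch)
    if (any(regions$end[rows] > chrom_lengths[[ch]]))
      stop("region beyond the end of chromosome ", ch)
    covered <- covered +
      sum(IRanges::width(IRanges::reduce(.ir(regions, rows))))
  }
  covered / total
}

#' Write regions as BED (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; BED output converts to
#' 0-based half-open.
#'
#' @param regions region data frame.
#' @param path output path.
#' @param name_col optional column used as the BED name field.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path, name_col = NULL) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = if (!is.null(name_col)) regions[[name_col]]
                           else ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a region table as TSV (with header)
#' @param regions region data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_regions_tsv <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
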