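#' Validate a marker map
#'
#' A marker map pairs each SNP with a chromosome, a 1-based physical
#' position (bp) and, once interpolated, a genetic position (cM).  Within a
#' chromosome, bp must be strictly increasing and cM non-decreasing.
#'
#' @param map data frame with columns `chrom`, `id`, `bp` and optionally `cM`.
#' @param require_cm require a complete, valid `cM` column.
#' @return The validated map (with a `cM` column added as `NA` if absent).
#' @export
validate_marker_map <- function(map, require_cm = FALSE) {
  stopifnot(is.data.frame(map), all(c("chrom", "bp") %in% names(map)))
  if (!"id" %in% names(map))
    map$id <- paste0(map$chrom, "_", map$bp)
  if (!"cM" %in% names(map)) map$cM <- NA_real_
  map$chrom <- as.character(map$chrom)
  map$bp <- as.integer(map$bp)
  for (ch in unique(map$chrom)) {
    i <- map$chrom == ch
    bp <- map$bp[i]
    if (is.unsorted(bp, strictly = TRUE))
      stop("bp positions not strictly increasing on chromosome ", ch)
    cm <- map$cM[i]
    if (!anyNA(cm) && is.unsorted(cm))
      stop("cM positions not non-decreasing on chromosome ", ch)
  }
  if (require_cm && anyNA(map$cM))
    stop("marker map lacks cM positions; run interpolate_map() first")
  map[c("chrom", "id", "bp", "cM")]
}

#' Interpolate genetic positions from an anchor map
#'
#' Assigns a cM position to every marker by piecewise-linear interpolation
#' between anchor markers of known genetic position, i.e. assuming uniform
#' recombination within each anchor interval.  Markers before the first or
#' after the last anchor are extrapolated at the terminal interval's local
#' cM/bp rate and floored at 0 cM.
#'
#' @param anchors data frame with columns `chrom`, `bp`, `cM` (at least two
#'   anchors per chromosome, cM non-decreasing in bp).
#' @param markers data frame with columns `chrom`, `bp` (and optionally `id`).
#' @return A marker map data frame (`chrom`, `id`, `bp`, `cM`).
#' @export
interpolate_map <- function(anchors, markers) {
  stopifnot(all(c("chrom", "bp", "cM") %in% names(anchors)))
  markers <- validate_marker_map(markers, require_cm = FALSE)
  missing_chr <- setdiff(unique(markers$chrom), unique(anchors$chrom))
  if (length(missing_chr) > 0)
    stop("no anchors for chromosome(s): ", paste(missing_chr, collapse = ", "))
  out <- markers
  for (ch in unique(markers$chrom)) {
    a <- anchors[anchors$chrom == ch, ]
    a <- a[order(a$bp), ]
    if (nrow(a) < 2) stop("need >= 2 anchors on chromosome ", ch)
    if (anyDuplicated(a$bp)) stop("duplicate anchor bp on chromosome ", ch)
    if (is.unsorted(a$cM)) stop("anchor cM decreasing on chromosome ", ch)
    i <- which(markers$chrom == ch)
    bp <- markers$bp[i]
    cm <- approx(a$bp, a$cM, xout = bp, rule = 1, ties = "ordered")$y
    n <- nrow(a)
    rate_lo <- (a$cM[2] - a$cM[1]) / (a$bp[2] - a$bp[1])
    rate_hi <- (a$cM[n] - a$cM[n - 1]) / (a$bp[n] - a$bp[n - 1])
    lo <- bp < a$bp[1]
    hi <- bp > a$bp[n]
    cm[lo] <- a$cM[1] - (a$bp[1] - bp[lo]) * rate_lo
    cm[hi] <- a$cM[n] + (bp[hi] - a$bp[n]) * rate_hi
    out$cM[i] <- pmax(cm, 0)
  }
  validate_marker_map(out, require_cm = TRUE)
}

#' Read an anchor map (`chrom<TAB>bp<TAB>cM`)
#' @param path TSV path; a header row is detected and skipped.
#' @return Data frame with `chrom`, `bp`, `cM`.
#' @export
read_anchor_map <- function(path) {
  a <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                  col.names = c("chrom", "bp", "cM"))
  if (nrow(a) > 0 && a$chrom[1] == "chrom") a <- a[-1, , drop = FALSE]
  a$bp <- as.integer(a$bp)
  a$cM <- as.numeric(a$cM)
  rownames(a) <- NULL
  a
}

#' Read a marker map (`chrom<TAB>id<TAB>bp<TAB>cM`)
#' @param path TSV path; a header row is detected and skipped.
#' @return A validated marker map.
#' @export
read_marker_map <- function(path) {
  m <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                  col.names = c("chrom", "id", "bp", "cM"))
  if (nrow(m) > 0 && m$chrom[1] == "chrom") m <- m[-1, , drop = FALSE]
  m$bp <- as.integer(m$bp)
  m$cM <- suppressWarnings(as.numeric(m$cM))
  validate_marker_map(m)
}

#' Write a marker map
#' @param map marker map data frame.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_marker_map <- function(map, path) {
  write.table(map[c("chrom", "id", "bp", "cM")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
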