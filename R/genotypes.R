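#' Construct a genotype dataset
#'
#' The central container of the package: diploid genotypes for a set of
#' samples assigned to populations ("lines"), over a shared marker panel.
#' Alleles are coded `0` (REF) and `1` (ALT); `NA` marks a missing allele.
#'
#' The `phased` flag records whether genotypes carry phase (all GT separators
#' were `|` in the source VCF).  Haplotype-based scans additionally require
#' complete data; [line_haplotypes()] enforces that at extraction time.
#'
#' @param a1,a2 integer matrices (samples x markers) holding the first and
#'   second allele of each genotype; `rownames` are sample IDs.
#' @param markers data frame with columns `chrom`, `id`, `bp` and optionally
#'   `cM` (use [interpolate_map()] to fill the latter).
#' @param lines named character vector mapping every sample ID to a line label.
#' @param phased logical; whether the genotypes are phased.
#' @param alleles optional data frame with `ref`/`alt` columns (one row per
#'   marker) retaining the original allele nucleotides.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(a1, a2, markers, lines, phased = FALSE,
                             alleles = NULL) {
  stopifnot(is.matrix(a1), is.matrix(a2), all(dim(a1) == dim(a2)))
  if (is.null(rownames(a1))) stop("allele matrices need sample IDs as rownames")
  rownames(a2) <- rownames(a1)
  samples <- rownames(a1)
  markers <- validate_marker_map(markers, require_cm = FALSE)
  if (nrow(markers) != ncol(a1))
    stop("marker table has ", nrow(markers), " rows but genotypes have ",
         ncol(a1), " columns")
  missing_line <- setdiff(samples, names(lines))
  if (length(missing_line) > 0)
    stop("samples without a line assignment: ",
         paste(missing_line, collapse = ", "))
  lines <- lines[samples]
  vals <- c(a1, a2)
  if (!all(vals %in% c(0L, 1L, NA)))
    stop("alleles must be coded 0/1/NA")
  structure(
    list(a1 = a1, a2 = a2, markers = markers, lines = lines,
         phased = isTRUE(phased), alleles = alleles),
    class = "genotype_dataset"
  )
}

#' @exportS3Method base::print
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$lines), "samples x",
      nrow(x$markers), "markers\n")
  tab <- table(x$lines)
  cat("  lines:", paste(names(tab), "(", tab, ")", sep = "", collapse = " "),
      "\n")
  cat("  chromosomes:", paste(unique(x$markers$chrom), collapse = ", "), "\n")
  cat("  phased:", x$phased, " missing alleles:",
      sum(is.na(x$a1)) + sum(is.na(x$a2)), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(length(x$lines), nrow(x$markers))

#' Subset a genotype dataset
#'
#' @param ds a [genotype_dataset()].
#' @param samples character vector of sample IDs or logical/integer index.
#' @param markers logical/integer index over markers.
#' @return The subsetted `genotype_dataset`.
#' @export
gt_subset <- function(ds, samples = NULL, markers = NULL) {
  if (is.null(samples)) samples <- seq_along(ds$lines)
  if (is.character(samples)) samples <- match(samples, rownames(ds$a1))
  if (is.null(markers)) markers <- seq_len(nrow(ds$markers))
  genotype_dataset(
    a1 = ds$a1[samples, markers, drop = FALSE],
    a2 = ds$a2[samples, markers, drop = FALSE],
    markers = ds$markers[markers, , drop = FALSE],
    lines = ds$lines[samples],
    phased = ds$phased,
    alleles = if (!is.null(ds$alleles)) ds$alleles[markers, , drop = FALSE]
  )
}

#' Extract the phased haplotypes of one line
#'
#' Returns the 2n haplotypes of a line as a matrix (haplotypes x markers),
#' the substrate of every haplotype-based scan.  Requires phased, complete
#' genotypes; impute first (e.g. [naive_impute()]) if data are missing.
#'
#' @param ds a phased, complete [genotype_dataset()].
#' @param line line label.
#' @param markers optional marker index to restrict to.
#' @return Integer matrix of 0/1 alleles with 2 rows per sample.
#' @export
line_haplotypes <- function(ds, line, markers = NULL) {
  if (!ds$phased)
    stop("dataset is not phased; haplotype scans need phased input")
  idx <- which(ds$lines == line)
  if (length(idx) == 0) stop("no samples in line '", line, "'")
  if (is.null(markers)) markers <- seq_len(nrow(ds$markers))
  a1 <- ds$a1[idx, markers, drop = FALSE]
  a2 <- ds$a2[idx, markers, drop = FALSE]
  if (anyNA(a1) || anyNA(a2))
    stop("missing alleles in line '", line,
         "'; impute before extracting haplotypes (see naive_impute)")
  h <- matrix(NA_integer_, nrow = 2L * length(idx), ncol = length(markers))
  h[seq(1L, by = 2L, length.out = length(idx)), ] <- a1
  h[seq(2L, by = 2L, length.out = length(idx)), ] <- a2
  rownames(h) <- paste0(rep(rownames(ds$a1)[idx], each = 2), c("_1", "_2"))
  h
}

#' Read phased (or unphased) genotypes from a VCF file
#'
#' Reads biallelic SNP records from a VCF (v4.x) with a GT field, recodes
#' alleles to 0 = REF / 1 = ALT, and attaches a sample-to-line assignment.
#' Non-SNP and multiallelic records are skipped with a message; the dataset
#' `phased` flag is set if and only if every genotype separator is `|`.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param line_table path to a two-column TSV (`sample_id<TAB>line`) or a
#'   data frame with those columns.
#' @return A [genotype_dataset()].
#' @export
read_phased_vcf <- function(path, line_table) {
  lt <- if (is.data.frame(line_table)) line_table else read_line_table(line_table)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  snp <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message("skipped ", n_skip, " non-SNP / multiallelic record(s)")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  vcf_samples <- colnames(gt)
  unknown <- setdiff(vcf_samples, lt$sample_id)
  if (length(unknown) > 0)
    stop("VCF sample(s) absent from line table: ",
         paste(unknown, collapse = ", "))
  lines <- setNames(lt$line, lt$sample_id)[vcf_samples]

  dm <- dim(gt)
  p1 <- substr(gt, 1L, 1L)
  sp <- substr(gt, 2L, 2L)
  p2 <- substr(gt, 3L, 3L)
  a1 <- suppressWarnings(as.integer(p1))
  a2 <- suppressWarnings(as.integer(p2))
  bad <- !(a1 %in% c(0L, 1L, NA)) | !(a2 %in% c(0L, 1L, NA))
  if (any(bad)) stop("unexpected allele codes in GT field")
  # markers x samples -> samples x markers
  a1 <- t(matrix(a1, nrow = dm[1]))
  a2 <- t(matrix(a2, nrow = dm[1]))
  rownames(a1) <- rownames(a2) <- vcf_samples
  phased <- all(sp[!is.na(gt) & sp != ""] == "|") && !any(is.na(gt))

  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  markers <- data.frame(
    chrom = fix[, "CHROM"], id = id,
    bp = as.integer(fix[, "POS"]), cM = NA_real_,
    stringsAsFactors = FALSE
  )
  genotype_dataset(a1, a2, markers, lines, phased = phased,
                  alleles = data.frame(ref = fix[, "REF"], alt = fix[, "ALT"],
                                       stringsAsFactors = FALSE))
}

#' Write a genotype dataset as a minimal VCF
#'
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @param phased write `|` separators (default: the dataset's flag).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(ds, path, phased = ds$phased) {
  sep <- if (phased) "|" else "/"
  ref <- if (!is.null(ds$alleles)) ds$alleles$ref else rep("A", nrow(ds$markers))
  alt <- if (!is.null(ds$alleles)) ds$alleles$alt else rep("G", nrow(ds$markers))
  c1 <- matrix(as.character(ds$a1), nrow = nrow(ds$a1))
  c2 <- matrix(as.character(ds$a2), nrow = nrow(ds$a2))
  c1[is.na(c1)] <- "."
  c2[is.na(c2)] <- "."
  gt <- matrix(paste0(c1, sep, c2), nrow = nrow(c1))  # samples x markers
  body <- vapply(seq_len(nrow(ds$markers)), function(j) {
    paste(c(ds$markers$chrom[j], ds$markers$bp[j], ds$markers$id[j],
            ref[j], alt[j], ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(ds$a1)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-line assignment table
#'
#' @param path TSV with columns `sample_id<TAB>line`; a header row is
#'   detected and skipped.
#' @return Data frame with `sample_id` and `line` columns.
#' @export
read_line_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", col.names = c("sample_id", "line"))
  if (nrow(tab) > 0 && tab$sample_id[1] == "sample_id")
    tab <- tab[-1, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read a pedigree table
#'
#' @param path TSV with columns `child<TAB>sire<TAB>dam`; `0` denotes an
#'   unknown parent (stored as `NA`).
#' @return Data frame with `child`, `sire`, `dam` columns.
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                    col.names = c("child", "sire", "dam"))
  if (nrow(ped) > 0 && ped$child[1] == "child") ped <- ped[-1, , drop = FALSE]
  ped$sire[ped$sire == "0"] <- NA
  ped$dam[ped$dam == "0"] <- NA
  rownames(ped) <- NULL
  ped
}

#' Write a pedigree table
#' @param ped data frame with `child`, `sire`, `dam`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample-to-line table
#' @param ds a [genotype_dataset()] (or a named line vector).
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_line_table <- function(ds, path) {
  lines <- if (inherits(ds, "genotype_dataset")) ds$lines else ds
  write.table(data.frame(sample_id = names(lines), line = unname(lines)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Pooled (all-sample) alternate-allele frequency per marker; NA-aware.
pooled_freq <- function(ds) {
  n1 <- colSums(ds$a1 == 1L, na.rm = TRUE) + colSums(ds$a2 == 1L, na.rm = TRUE)
  n <- colSums(!is.na(ds$a1)) + colSums(!is.na(ds$a2))
  ifelse(n > 0, n1 / n, NA_real_)
}

# Per-line alternate-allele frequency matrix (lines x markers).
line_freqs <- function(ds) {
  labs <- unique(ds$lines)
  out <- matrix(NA_real_, nrow = length(labs), ncol = nrow(ds$markers),
                dimnames = list(labs, NULL))
  for (l in labs) {
    idx <- which(ds$lines == l)
    n1 <- colSums(ds$a1[idx, , drop = FALSE] == 1L, na.rm = TRUE) +
      colSums(ds$a2[idx, , drop = FALSE] == 1L, na.rm = TRUE)
    n <- colSums(!is.na(ds$a1[idx, , drop = FALSE])) +
      colSums(!is.na(ds$a2[idx, , drop = FALSE]))
    out[l, ] <- ifelse(n > 0, n1 / n, NA_real_)
  }
  out
}
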