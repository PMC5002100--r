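#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom GenomeInfoDb seqlevels
NULL

#' Read gene intervals from GFF3 or BED
#'
#' GFF3 input is restricted to `gene` features; gene IDs are taken from the
#' `gene_id` attribute, then `Name`, then `ID`.  BED input (4+ columns)
#' uses the name column.  Coordinates are validated up front so a malformed
#' interval is reported with its line number.
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file.
#' @return A [GenomicRanges::GRanges] with a `gene` metadata column.
#' @export
read_gene_intervals <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- readLines(path)
  body <- which(!grepl("^#", raw) & nzchar(raw))
  check_coord <- function(fields, cols, ln) {
    v <- suppressWarnings(as.numeric(fields[cols]))
    if (anyNA(v) || v[2] < v[1])
      stop("malformed interval at line ", ln, " of ", path)
  }
  if (ext %in% c("gff", "gff3")) {
    for (ln in body) {
      f <- strsplit(raw[ln], "\t", fixed = TRUE)[[1]]
      if (length(f) < 9) stop("malformed interval at line ", ln, " of ", path)
      check_coord(f, c(4, 5), ln)
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    nm <- as.character(gr$gene_id %||% rep(NA, length(gr)))
    if (all(is.na(nm)) && !is.null(gr$Name)) nm <- as.character(gr$Name)
    nm[is.na(nm)] <- as.character(gr$ID[is.na(nm)])
    gr$gene <- nm
  } else {
    for (ln in body) {
      f <- strsplit(raw[ln], "\t", fixed = TRUE)[[1]]
      if (length(f) < 4) stop("malformed interval at line ", ln, " of ", path)
      check_coord(f, c(2, 3), ln)
    }
    gr <- rtracklayer::import(path, format = "bed")
    gr$gene <- gr$name
  }
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate regions with contained and nearby genes
#'
#' Genes overlapping a region by at least 1 bp are listed as contained.  A
#' region with none is flagged as a gene desert and the genes within
#' `flank` bp of either edge are listed instead, with a signed edge-to-edge
#' distance (negative = gene left of the region); strand is ignored.
#'
#' @param regions region data frame (`chrom`, `start`, `end`).
#' @param genes a [GenomicRanges::GRanges] with a `gene` column (see
#'   [read_gene_intervals()]) or a data frame with `chrom`, `start`, `end`,
#'   `gene`.
#' @param flank search distance around gene deserts in bp (default 100 kb).
#' @return Data frame: `region`, `chrom`, `start`, `end`, `n_genes`,
#'   `contained_genes`, `desert`, `nearby_genes`, `nearby_distances`.
#' @export
annotate_regions <- function(regions, genes, flank = 100000) {
  if (is.data.frame(genes)) {
    genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end),
      gene = genes$gene)
  }
  g_chr <- as.character(GenomicRanges::seqnames(genes))
  g_start <- IRanges::start(genes)
  g_end <- IRanges::end(genes)
  g_name <- genes$gene

  rows <- lapply(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    st <- regions$start[i]
    en <- regions$end[i]
    on_chr <- which(g_chr == ch)
    contained <- on_chr[g_start[on_chr] <= en & g_end[on_chr] >= st]
    desert <- length(contained) == 0
    nearby <- integer(0)
    dists <- numeric(0)
    if (desert) {
      cand <- on_chr[g_start[on_chr] <= en + flank &
                       g_end[on_chr] >= st - flank]
      nearby <- setdiff(cand, contained)
      dists <- ifelse(g_end[nearby] < st, -(st - g_end[nearby]),
                      g_start[nearby] - en)
    }
    data.frame(
      region = sprintf("%s:%d-%d", ch, st, en),
      chrom = ch, start = st, end = en,
      n_genes = length(contained),
      contained_genes = paste(g_name[contained], collapse = ","),
      desert = desert,
      nearby_genes = paste(g_name[nearby], collapse = ","),
      nearby_distances = paste(dists, collapse = ","),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
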