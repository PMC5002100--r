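#' Haplotype-frequency profile of a candidate region
#'
#' Enumerates the phased haplotypes over a region's informative SNPs in
#' each line and reports their frequencies and the major (most frequent)
#' haplotype.  Informative SNPs are the region's markers that are
#' polymorphic in the pooled sample (configurable to per-line polymorphism);
#' a region with fewer than `min_snps` of them is skipped with a status.
#' Ties for the major haplotype are broken lexicographically, so the result
#' never depends on sample order.
#'
#' @param region list or single-row data frame with `chrom`, `start`, `end`.
#' @param ds a phased, complete [genotype_dataset()].
#' @param min_snps minimum informative SNPs (default 5).
#' @param informative `"pooled"` (default) or `"per_line"` polymorphism rule.
#' @return Object of class `haplotype_table`: list with `status`
#'   (`"ok"`/`"below_min_snps"`), `n_informative`, `snp_ids` and, when ok, a
#'   data frame `table` with `region`, `line`, `haplotype`, `count`, `freq`,
#'   `is_major`.
#' @export
region_haplotypes <- function(region, ds, min_snps = 5,
                              informative = c("pooled", "per_line")) {
  informative <- match.arg(informative)
  if (!ds$phased)
    stop("unphased input: phase or impute the dataset first ",
         "(see naive_impute)")
  if (anyNA(ds$a1) || anyNA(ds$a2))
    stop("dataset has missing alleles: impute before haplotype analysis")
  region <- as.list(region)
  label <- sprintf("%s:%d-%d", region$chrom, region$start, region$end)
  in_region <- ds$markers$chrom == region$chrom &
    ds$markers$bp >= region$start & ds$markers$bp <= region$end

  if (informative == "pooled") {
    f <- pooled_freq(ds)
    poly <- f > 0 & f < 1
  } else {
    lf <- line_freqs(ds)
    poly <- apply(lf, 2, function(p) any(p > 0 & p < 1, na.rm = TRUE))
  }
  snps <- which(in_region & poly)
  if (length(snps) < min_snps)
    return(structure(list(region = label, status = "below_min_snps",
                          n_informative = length(snps),
                          snp_ids = ds$markers$id[snps], table = NULL),
                     class = "haplotype_table"))

  rows <- list()
  for (l in unique(ds$lines)) {
    h <- line_haplotypes(ds, l, markers = snps)
    strings <- apply(h, 1, paste0, collapse = "")
    tab <- table(strings)
    freq <- as.numeric(tab) / length(strings)
    haps <- names(tab)
    ord <- order(-freq, haps)  # major first; lexicographic tie-break
    rows[[l]] <- data.frame(
      region = label, line = l, haplotype = haps[ord],
      count = as.integer(tab)[ord], freq = freq[ord],
      is_major = seq_along(ord) == 1, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(region = label, status = "ok",
                 n_informative = length(snps),
                 snp_ids = ds$markers$id[snps], table = tab),
            class = "haplotype_table")
}

#' @exportS3Method base::print
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table", x$region, "-", x$status,
      "(", x$n_informative, "informative SNPs )\n")
  if (!is.null(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Haplotype tables for a set of regions
#'
#' @param regions region data frame.
#' @param ds a phased, complete [genotype_dataset()].
#' @param min_snps minimum informative SNPs per region.
#' @return A combined data frame of all profiled regions (skipped regions
#'   contribute no rows), with the per-region status in attribute `status`.
#' @export
region_haplotype_tables <- function(regions, ds, min_snps = 5) {
  res <- lapply(seq_len(nrow(regions)), function(i)
    region_haplotypes(regions[i, ], ds, min_snps = min_snps))
  status <- vapply(res, `[[`, character(1), "status")
  tabs <- Filter(Negate(is.null), lapply(res, `[[`, "table"))
  out <- if (length(tabs) > 0) do.call(rbind, tabs) else
    data.frame(region = character(), line = character(),
               haplotype = character(), count = integer(),
               freq = numeric(), is_major = logical(),
               stringsAsFactors = FALSE)
  attr(out, "status") <- status
  out
}
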