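#' Pipeline configuration
#'
#' Collects every tunable parameter of the full scan pipeline, echoed into
#' the run manifest.  Defaults follow the standard analysis: XP-EHH
#' significance at P < 0.05 with 200 kb SNP clustering and a 0.05 combined
#' EHH floor; XP-CLR-style scoring on a 2 kb grid with 0.5 cM windows,
#' |r| >= 0.9 LD weighting, top 0.5 % of windows and 1 cM clustering; ZHp
#' over sliding 5-SNP windows; consensus across at least 2 lines;
#' annotation within +/- 100 kb of gene deserts.
#'
#' @param call_rate_min,mendel_max,excluded_chroms QC thresholds
#'   (see [apply_qc()]).
#' @param xpehh_p XP-EHH significance cutoff.
#' @param xpehh_gap XP-EHH SNP clustering distance (bp).
#' @param ehh_floor combined-EHH truncation threshold.
#' @param two_sided use two-sided XP-EHH P-values.
#' @param xpclr_spacing grid spacing (bp).
#' @param xpclr_window_cm window width (cM).
#' @param r_cutoff LD-weighting correlation cutoff.
#' @param top_fraction XP-CLR-style score threshold fraction.
#' @param cluster_gap_cm XP-CLR-style window clustering distance (cM).
#' @param scales sweep-scale grid (cM).
#' @param eps fixation-component width.
#' @param zhp_window,zhp_step,zhp_exclude_chroms ZHp window parameters.
#' @param min_lines minimum supporting lines for a consensus region.
#' @param flank annotation flank (bp).
#' @param min_region_snps minimum informative SNPs for haplotype profiling.
#' @param seed seed for any randomized step (imputation).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(call_rate_min = 0.90, mendel_max = 0.001,
                            excluded_chroms = character(),
                            xpehh_p = 0.05, xpehh_gap = 200000,
                            ehh_floor = 0.05, two_sided = FALSE,
                            xpclr_spacing = 2000, xpclr_window_cm = 0.5,
                            r_cutoff = 0.9, top_fraction = 0.005,
                            cluster_gap_cm = 1.0,
                            scales = clr_scale_grid(), eps = 0.02,
                            zhp_window = 5, zhp_step = 1,
                            zhp_exclude_chroms = c("Z", "W"),
                            min_lines = 2, flank = 100000,
                            min_region_snps = 5, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            xpehh_p > 0, xpehh_p < 1, top_fraction > 0, top_fraction < 1,
            min_lines >= 2)
  structure(cfg, class = "pipeline_config")
}

# Stable hash of a configuration: md5 of its canonical JSON.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = 15,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full selection-signature pipeline
#'
#' For every ordered pair of lines, runs the XP-EHH and XP-CLR-style scans
#' and calls per-comparison regions; merges each line's regions across its
#' comparisons, intersects the two methods (XP-CLR spans kept), and calls
#' cross-line consensus regions.  ZHp tables are computed per line, and
#' consensus regions are profiled for haplotype frequencies and (when gene
#' intervals are supplied) annotated.  All stage outputs are returned and,
#' when `out_dir` is given, written as TSV/BED together with a JSON run
#' manifest carrying the configuration hash and per-stage row counts.
#'
#' @param ds a phased, complete [genotype_dataset()] (run [apply_qc()] /
#'   [naive_impute()] beforehand if needed).
#' @param map marker map with cM positions; defaults to the dataset's.
#' @param config a [pipeline_config()].
#' @param chrom_lengths named chromosome lengths (bp); defaults to the last
#'   marker per chromosome.
#' @param genes optional gene intervals for annotation.
#' @param out_dir optional output directory.
#' @return A list of stage results (`xpehh`, `xpclr`, `xpehh_regions`,
#'   `xpclr_regions`, `candidates`, `consensus`, `coverage`, `zhp`,
#'   `haplotypes`, `annotation`, `manifest`).
#' @export
run_pipeline <- function(ds, map = NULL, config = pipeline_config(),
                         chrom_lengths = NULL, genes = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  if (is.null(map)) map <- ds$markers
  map <- validate_marker_map(map, require_cm = TRUE)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(map$bp, map$chrom, max)
  labs <- unique(ds$lines)
  if (length(labs) < 2) stop("need at least 2 lines")

  xpehh <- list()
  xpclr <- list()
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (j <= i) next
      pr <- xpehh_pair(ds, labs[i], labs[j], map = map,
                       ehh_floor = config$ehh_floor,
                       two_sided = config$two_sided)
      xpehh[[pr$forward$comparison[1]]] <- pr$forward
      xpehh[[pr$reverse$comparison[1]]] <- pr$reverse
    }
  }
  # the reference line's strong-LD adjacency is shared by the
  # comparisons that use it
  adj_cache <- lapply(setNames(labs, labs), function(l) {
    h <- line_haplotypes(ds, l)
    out <- list()
    for (ch in unique(map$chrom)) {
      i <- which(map$chrom == ch)
      out[[ch]] <- ld_adjacency(h[, i, drop = FALSE], map$cM[i],
                                r_cutoff = config$r_cutoff,
                                max_cm = config$xpclr_window_cm)
    }
    out
  })
  for (a in labs) for (b in labs) {
    if (a == b) next
    key <- paste0(a, "_vs_", b)
    xpclr[[key]] <- xpclr_scan(
      ds, a, b, map = map, chrom_lengths = chrom_lengths,
      spacing = config$xpclr_spacing, window_cm = config$xpclr_window_cm,
      r_cutoff = config$r_cutoff, scales = config$scales, eps = config$eps,
      adjacency = adj_cache[[b]])
  }

  per_comp_ehh <- lapply(xpehh, function(track) {
    sig <- track[track$pvalue < config$xpehh_p, , drop = FALSE]
    r <- cluster_snps_to_regions(sig, max_gap = config$xpehh_gap)
    if (nrow(r) > 0) r$comparison <- track$comparison[1]
    r
  })
  per_comp_clr <- lapply(xpclr, function(track) {
    r <- suppressWarnings(call_xpclr_regions(
      track, top_fraction = config$top_fraction,
      cluster_gap_cm = config$cluster_gap_cm))
    if (nrow(r) > 0) r$comparison <- track$comparison[1]
    r
  })

  xpehh_regions <- list()
  xpclr_regions <- list()
  candidates <- list()
  for (l in labs) {
    mine <- function(per_comp) {
      keys <- grep(paste0("^", l, "_vs_"), names(per_comp), value = TRUE)
      do.call(rbind, per_comp[keys])
    }
    xpehh_regions[[l]] <- merge_comparisons(mine(per_comp_ehh), line = l,
                                            method = "xpehh")
    xpclr_regions[[l]] <- merge_comparisons(mine(per_comp_clr), line = l,
                                            method = "xpclr")
    candidates[[l]] <- intersect_methods(xpehh_regions[[l]],
                                         xpclr_regions[[l]], line = l)
  }
  all_candidates <- do.call(rbind, c(candidates, make.row.names = FALSE))
  consensus <- cross_line_consensus(all_candidates,
                                    min_lines = config$min_lines)
  coverage <- vapply(labs, function(l)
    genome_coverage(candidates[[l]], chrom_lengths), numeric(1))

  zhp <- do.call(rbind, lapply(labs, function(l)
    hp_windows(ds, l, window_size = config$zhp_window,
               step = config$zhp_step,
               exclude_chroms = config$zhp_exclude_chroms)))
  zhp <- zhp_transform(zhp)

  haplotypes <- if (nrow(consensus) > 0)
    region_haplotype_tables(consensus, ds,
                            min_snps = config$min_region_snps)
  else NULL
  annotation <- if (!is.null(genes) && nrow(consensus) > 0)
    annotate_regions(consensus, genes, flank = config$flank)
  else NULL

  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    statistic_labels = c(xpehh = "XP-EHH", xpclr = "XP-CLR-style"),
    config = config[!vapply(config, is.function, logical(1))],
    config_hash = config_hash(config[!vapply(config, is.function,
                                             logical(1))]),
    n_lines = length(labs), lines = labs,
    n_comparisons = length(xpehh),
    n_snps = nrow(ds$markers), n_samples = length(ds$lines),
    rows = list(
      xpehh_regions = sum(vapply(xpehh_regions, nrow, integer(1))),
      xpclr_regions = sum(vapply(xpclr_regions, nrow, integer(1))),
      candidates = nrow(all_candidates),
      consensus = nrow(consensus),
      zhp_windows = nrow(zhp)),
    coverage = as.list(coverage),
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- list(xpehh = xpehh, xpclr = xpclr,
              xpehh_regions = xpehh_regions, xpclr_regions = xpclr_regions,
              candidates = candidates, consensus = consensus,
              coverage = coverage, zhp = zhp, haplotypes = haplotypes,
              annotation = annotation, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(xpehh))
      write.table(xpehh[[key]], file.path(out_dir,
                  paste0("xpehh_", key, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    for (key in names(xpclr))
      write.table(xpclr[[key]], file.path(out_dir,
                  paste0("xpclr_", key, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    for (l in labs) {
      if (nrow(candidates[[l]]) > 0)
        write_regions_bed(candidates[[l]],
                          file.path(out_dir, paste0("candidates_", l, ".bed")),
                          name_col = "line")
      write_regions_tsv(candidates[[l]],
                        file.path(out_dir, paste0("candidates_", l, ".tsv")))
    }
    write_regions_tsv(consensus, file.path(out_dir, "consensus.tsv"))
    if (nrow(consensus) > 0)
      write_regions_bed(consensus, file.path(out_dir, "consensus.bed"),
                        name_col = "lines")
    write.table(zhp, file.path(out_dir, "zhp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(haplotypes))
      write.table(haplotypes, file.path(out_dir, "haplotypes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(annotation))
      write.table(annotation, file.path(out_dir, "annotation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE)
  }
  res
}
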