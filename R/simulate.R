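#' Simulation configuration
#'
#' Describes a multi-line SNP-array study to forward-simulate: a common
#' base population, K reproductively isolated lines drifting (and possibly
#' sweeping) for G generations of Wright-Fisher reproduction, and an
#' array-style ascertained marker panel.  Defaults are sized so that a full
#' five-line study (3 chromosomes x 20 Mb, 3,000 SNPs, Ne = 250, G = 40)
#' simulates and scans in well under a minute on one CPU.
#'
#' @param seed integer seed governing every random draw.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param cm_per_mb constant recombination rate used to build the map.
#' @param n_snps marker count after array-style ascertainment.
#' @param n_founders founder haplotypes behind the base population.
#' @param founder_depth expected crossovers per Morgan accumulated while
#'   the base population mixed (controls baseline LD decay).
#' @param base_diploids diploid size of the base population panel.
#' @param lines line labels.
#' @param ne per-line diploid effective size (recycled).
#' @param generations generations of isolated Wright-Fisher evolution.
#' @param samples named vector: diploids sampled per line.
#' @param sweeps list of [sweep_spec()] entries.
#' @param maf_floor minimum pooled minor-allele frequency at generation 0
#'   (array ascertainment).
#' @param missing_rate genotype-wise missingness injected in the raw export.
#' @param mendel_error_rate genotype-wise Mendel-error rate in trio children.
#' @param n_trios trios appended per line for pedigree QC testing.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(`1` = 2e7, `2` = 2e7, `3` = 2e7),
                       cm_per_mb = 1,
                       n_snps = 3000,
                       n_founders = 60,
                       founder_depth = 50,
                       base_diploids = 300,
                       lines = c("ML1", "ML2", "ML3", "FL1", "FL2"),
                       ne = 250,
                       generations = 40,
                       samples = c(ML1 = 24, ML2 = 60, ML3 = 38,
                                   FL1 = 50, FL2 = 48),
                       sweeps = list(),
                       maf_floor = 0.05,
                       missing_rate = 0.02,
                       mendel_error_rate = 0,
                       n_trios = 0) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            n_snps > 0, n_founders >= 2, base_diploids >= 2,
            maf_floor >= 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate <= 1,
            mendel_error_rate >= 0, mendel_error_rate <= 1)
  ne <- rep_len(ne, length(lines))
  names(ne) <- lines
  if (is.null(names(samples))) names(samples) <- lines
  stopifnot(all(lines %in% names(samples)))
  if (any(samples[lines] > ne[lines]))
    stop("requested samples exceed the line's effective size")
  for (sw in sweeps) {
    if (!sw$chrom %in% names(chrom_lengths))
      stop("sweep on unknown chromosome ", sw$chrom)
    if (sw$bp < 1 || sw$bp > chrom_lengths[[sw$chrom]])
      stop("sweep locus outside chromosome ", sw$chrom)
    if (!all(sw$lines %in% lines))
      stop("sweep assigned to unknown line(s)")
  }
  structure(list(
    seed = seed, chrom_lengths = chrom_lengths, cm_per_mb = cm_per_mb,
    n_snps = n_snps, n_founders = n_founders, founder_depth = founder_depth,
    base_diploids = base_diploids, lines = lines, ne = ne,
    generations = generations, samples = samples[lines], sweeps = sweeps,
    maf_floor = maf_floor, missing_rate = missing_rate,
    mendel_error_rate = mendel_error_rate, n_trios = n_trios
  ), class = "sim_config")
}

#' Specify a hard selective sweep
#'
#' @param chrom chromosome label.
#' @param bp physical position of the favored locus (mapped to the nearest
#'   marker).
#' @param lines line labels in which the allele is selected.
#' @param s selection coefficient (haploid-multiplicative, weight `(1+s)`
#'   per favored-allele copy).
#' @param start_freq standing frequency of the favored allele in the base
#'   population.
#' @return A list understood by [sim_config()].
#' @export
sweep_spec <- function(chrom, bp, lines, s = 0.5, start_freq = 0.05) {
  list(chrom = as.character(chrom), bp = bp, lines = lines, s = s,
       start_freq = start_freq)
}

#' Simulate the base population panel
#'
#' Draws ancestral allele frequencies from a neutral-like spectrum
#' (density proportional to 1/p on `[maf_floor, 1 - maf_floor]`), founder
#' haplotypes per SNP independently, and builds the base panel as
#' founder mosaics (Poisson crossovers) so that nearby SNPs carry LD.
#' Array-style ascertainment then drops SNPs whose pooled minor-allele
#' frequency in the generation-0 panel falls below `maf_floor`; candidate
#' markers are oversampled so the target count survives.  Sweep loci are
#' re-seeded at their configured standing frequency in this shared panel.
#'
#' Sets the RNG seed from `config$seed`; byte-identical output is
#' guaranteed for a fixed configuration.
#'
#' @param config a [sim_config()].
#' @return List with `panel` (haplotype matrix), `markers` (marker map) and
#'   `sweep_markers` (marker index per configured sweep).
#' @export
simulate_base <- function(config) {
  set.seed(config$seed)
  oversample <- ceiling(config$n_snps * 1.4) + 50
  lens <- config$chrom_lengths
  n_per <- round(oversample * lens / sum(lens))
  # jittered regular spacing: arrays are designed for even genome coverage
  markers <- do.call(rbind, lapply(names(lens), function(ch) {
    n <- n_per[[ch]]
    step <- lens[[ch]] / n
    bp <- round((seq_len(n) - 0.5) * step + runif(n, -0.45, 0.45) * step)
    bp <- sort(unique(pmin(pmax(bp, 1), lens[[ch]])))
    data.frame(chrom = ch, bp = bp, stringsAsFactors = FALSE)
  }))
  markers$cM <- markers$bp * 1e-6 * config$cm_per_mb
  m <- nrow(markers)

  u <- runif(m)
  lo <- config$maf_floor
  p <- lo * ((1 - lo) / lo)^u  # density ~ 1/p on [lo, 1-lo]

  founders <- matrix(
    rbinom(config$n_founders * m, 1L, rep(p, each = config$n_founders)),
    nrow = config$n_founders)
  chrom_idx <- match(markers$chrom, names(lens))
  panel <- cpp_founder_mosaic(founders, 2L * config$base_diploids,
                              markers$cM, chrom_idx, config$founder_depth)

  pool <- colMeans(panel)
  maf <- pmin(pool, 1 - pool)
  keep <- which(maf >= config$maf_floor)
  if (length(keep) < config$n_snps)
    stop("SNP target exceeds what the MAF floor allows; only ",
         length(keep), " markers survived ascertainment")
  keep <- sort(sample(keep, config$n_snps))
  panel <- panel[, keep, drop = FALSE]
  markers <- markers[keep, , drop = FALSE]
  markers$id <- paste0("snp_", markers$chrom, "_", markers$bp)
  rownames(markers) <- NULL
  markers <- markers[c("chrom", "id", "bp", "cM")]

  # Hard-sweep seeding: the favored allele arose once, so every carrier
  # shares the origin's background around the locus.  The shared ancestral
  # segment decays with recombination history: each carrier copies the
  # origin over an exponential segment per side (mean 100/founder_depth cM,
  # the same historical recombination depth as the base mosaics), which
  # gives the escape gradient a sweep from standing variation really has.
  sweep_markers <- integer(length(config$sweeps))
  for (k in seq_along(config$sweeps)) {
    sw <- config$sweeps[[k]]
    on_chr <- which(markers$chrom == sw$chrom)
    j_loc <- which.min(abs(markers$bp[on_chr] - sw$bp))
    j <- on_chr[j_loc]
    cm <- markers$cM[on_chr]
    carriers <- sample.int(nrow(panel),
                           max(1L, round(sw$start_freq * nrow(panel))))
    rate <- config$founder_depth / 100  # per cM
    for (cr in carriers[-1]) {
      seg <- on_chr[cm >= cm[j_loc] - stats::rexp(1, rate) &
                      cm <= cm[j_loc] + stats::rexp(1, rate)]
      panel[cr, seg] <- panel[carriers[1], seg]
    }
    panel[, j] <- 0L
    panel[carriers, j] <- 1L
    sweep_markers[k] <- j
  }
  list(panel = panel, markers = markers, sweep_markers = sweep_markers)
}

#' Evolve the isolated lines
#'
#' Each line starts from a random sample of the base panel and reproduces
#' for G generations of Wright-Fisher mating with Poisson recombination;
#' lines carrying a sweep sample parents with fitness weight `(1+s)` per
#' favored-allele copy.  Losing the favored allele to drift is recorded in
#' the truth table, not an error.
#'
#' @param base output of [simulate_base()].
#' @param config the same [sim_config()].
#' @return List with `panels` (named list of per-line haplotype matrices)
#'   and `truth` (a `SweepTruth` data frame: locus, lines under selection,
#'   s, start frequency and the realized final frequency in every line).
#' @export
evolve_lines <- function(base, config) {
  chrom_idx <- match(base$markers$chrom, names(config$chrom_lengths))
  panels <- list()
  for (l in config$lines) {
    rows <- sample.int(nrow(base$panel), 2L * config$ne[[l]],
                       replace = nrow(base$panel) < 2L * config$ne[[l]])
    init <- base$panel[rows, , drop = FALSE]
    sw_idx <- integer(0)
    sw_s <- numeric(0)
    for (k in seq_along(config$sweeps)) {
      if (l %in% config$sweeps[[k]]$lines) {
        sw_idx <- c(sw_idx, base$sweep_markers[k] - 1L)  # 0-based
        sw_s <- c(sw_s, config$sweeps[[k]]$s)
      }
    }
    panels[[l]] <- cpp_wf_evolve(init, config$ne[[l]], config$generations,
                                 base$markers$cM, chrom_idx,
                                 as.integer(sw_idx), as.numeric(sw_s))
  }
  truth <- NULL
  if (length(config$sweeps) > 0) {
    truth <- do.call(rbind, lapply(seq_along(config$sweeps), function(k) {
      sw <- config$sweeps[[k]]
      j <- base$sweep_markers[k]
      row <- data.frame(
        chrom = sw$chrom, bp = base$markers$bp[j], cM = base$markers$cM[j],
        marker = base$markers$id[j],
        lines = paste(sw$lines, collapse = ","),
        s = sw$s, start_freq = sw$start_freq, stringsAsFactors = FALSE)
      for (l in config$lines)
        row[[paste0("freq_", l)]] <- mean(panels[[l]][, j])
      row
    }))
  }
  list(panels = panels, truth = truth)
}

# One recombined gamete in R (used only for trio children).
.gamete_r <- function(h1, h2, cm, chrom_idx) {
  out <- integer(length(cm))
  for (c_ in unique(chrom_idx)) {
    i <- which(chrom_idx == c_)
    cur <- sample(1:2, 1)
    ncx <- rpois(1, (cm[i[length(i)]] - cm[i[1]]) / 100)
    if (ncx > 0) {
      xpos <- sort(runif(ncx, cm[i[1]], cm[i[length(i)]]))
      flips <- findInterval(cm[i], c(-Inf, xpos))
      cur <- (cur - 1 + flips - 1) %% 2 + 1
    } else {
      cur <- rep(cur, length(i))
    }
    src <- rbind(h1[i], h2[i])
    out[i] <- src[cbind(cur, seq_along(i))]
  }
  out
}

#' Sample study individuals and export the dataset
#'
#' Draws the configured diploid sample from each evolved line and builds
#' two datasets: a phased, complete copy (the substrate of the haplotype
#' scans) and a raw copy with genotype-wise missingness, exported with `/`
#' separators.  Optional trios (two sampled parents plus a simulated child,
#' with forced Mendel-error injection at the configured rate) are appended
#' for pedigree QC testing.
#'
#' @param sim output of [evolve_lines()].
#' @param base output of [simulate_base()].
#' @param config the same [sim_config()].
#' @param dir optional output directory; when given, writes phased and
#'   unphased VCFs, line/marker/pedigree/truth TSVs and a config echo JSON.
#' @return List with `ds` (phased, complete), `ds_raw` (with missingness),
#'   `map`, `pedigree`, `truth` and, when written, `paths`.
#' @export
sample_and_export <- function(sim, base, config, dir = NULL) {
  markers <- base$markers
  chrom_idx <- match(markers$chrom, names(config$chrom_lengths))
  a1 <- a2 <- NULL
  ids <- character(0)
  lines <- character(0)
  for (l in config$lines) {
    n <- config$samples[[l]]
    pick <- sample.int(config$ne[[l]], n)
    h1 <- sim$panels[[l]][2L * pick - 1L, , drop = FALSE]
    h2 <- sim$panels[[l]][2L * pick, , drop = FALSE]
    a1 <- rbind(a1, h1)
    a2 <- rbind(a2, h2)
    ids <- c(ids, sprintf("%s_%03d", l, seq_len(n)))
    lines <- c(lines, rep(l, n))
  }

  pedigree <- data.frame(child = character(0), sire = character(0),
                         dam = character(0), stringsAsFactors = FALSE)
  if (config$n_trios > 0) {
    for (l in config$lines) {
      members <- which(lines == l)
      for (t in seq_len(config$n_trios)) {
        par <- sample(members, 2)
        c1 <- .gamete_r(a1[par[1], ], a2[par[1], ], markers$cM, chrom_idx)
        c2 <- .gamete_r(a1[par[2], ], a2[par[2], ], markers$cM, chrom_idx)
        if (config$mendel_error_rate > 0) {
          hit <- which(runif(ncol(a1)) < config$mendel_error_rate)
          for (j in hit) {
            gp <- c(a1[par[1], j] + a2[par[1], j],
                    a1[par[2], j] + a2[par[2], j])
            # force a detectable violation where one exists
            if (all(gp == 0)) { c1[j] <- 1L; c2[j] <- 1L }
            else if (all(gp == 2)) { c1[j] <- 0L; c2[j] <- 0L }
            else if (any(gp == 0)) { c1[j] <- 1L; c2[j] <- 1L }
            else if (any(gp == 2)) { c1[j] <- 0L; c2[j] <- 0L }
          }
        }
        cid <- sprintf("%s_trio%03d", l, t)
        a1 <- rbind(a1, c1)
        a2 <- rbind(a2, c2)
        ids <- c(ids, cid)
        lines <- c(lines, l)
        pedigree <- rbind(pedigree, data.frame(
          child = cid, sire = ids[par[1]], dam = ids[par[2]],
          stringsAsFactors = FALSE))
      }
    }
  }

  rownames(a1) <- rownames(a2) <- ids
  line_map <- setNames(lines, ids)
  ds <- genotype_dataset(a1, a2, markers, line_map, phased = TRUE)

  r1 <- a1
  r2 <- a2
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(ids) * nrow(markers)) < config$missing_rate,
                   nrow = length(ids))
    r1[miss] <- NA_integer_
    r2[miss] <- NA_integer_
  }
  ds_raw <- genotype_dataset(r1, r2, markers, line_map, phased = FALSE)

  out <- list(ds = ds, ds_raw = ds_raw, map = markers,
              pedigree = pedigree, truth = sim$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      vcf_phased = file.path(dir, "genotypes_phased.vcf"),
      vcf_raw = file.path(dir, "genotypes_raw.vcf"),
      line_table = file.path(dir, "lines.tsv"),
      marker_map = file.path(dir, "markers.tsv"),
      pedigree = file.path(dir, "pedigree.tsv"),
      truth = file.path(dir, "sweep_truth.tsv"),
      config = file.path(dir, "sim_config.json"))
    write_vcf(ds, paths$vcf_phased, phased = TRUE)
    write_vcf(ds_raw, paths$vcf_raw, phased = FALSE)
    write_line_table(ds, paths$line_table)
    write_marker_map(markers, paths$marker_map)
    write_pedigree(pedigree, paths$pedigree)
    if (!is.null(sim$truth))
      write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    jsonlite::write_json(config[setdiff(names(config), "sweeps")],
                         paths$config, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    out$paths <- paths
  }
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [simulate_base()], [evolve_lines()] and
#' [sample_and_export()] under the configuration's seed.
#'
#' @param config a [sim_config()].
#' @param dir optional export directory.
#' @return See [sample_and_export()].
#' @export
simulate_study <- function(config, dir = NULL) {
  base <- simulate_base(config)
  sim <- evolve_lines(base, config)
  sample_and_export(sim, base, config, dir = dir)
}
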