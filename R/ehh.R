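#' EHH decay curve from a core SNP
#'
#' Extended haplotype homozygosity at distance x from a core marker is the
#' probability that two haplotypes drawn at random are identical over every
#' marker between the core and x (inclusive).  This is the site version: all
#' haplotypes enter one partition, starting from the two allele classes of
#' the core SNP itself, so EHH at distance 0 equals the core-site
#' homozygosity.
#'
#' @param haps 0/1 haplotype matrix (haplotypes x markers), complete.
#' @param core core marker column index.
#' @param direction `"right"` (increasing position) or `"left"`.
#' @param cm optional vector of genetic positions (cM) for the columns of
#'   `haps`; defaults to the column index, i.e. unit marker spacing.
#' @return Data frame with one row per marker from the core outward:
#'   `marker` (column index), `cm`, `dist` (|cM from core|), `ehh`.
#' @export
ehh_site <- function(haps, core, direction = c("right", "left"), cm = NULL) {
  direction <- match.arg(direction)
  n <- nrow(haps)
  if (n < 2) stop("need at least 2 haplotypes")
  m <- ncol(haps)
  stopifnot(core >= 1, core <= m)
  if (is.null(cm)) cm <- as.numeric(seq_len(m))
  if (anyNA(haps)) stop("haplotypes must be complete (no missing alleles)")

  path <- if (direction == "right") core:m else core:1
  gid <- rep(1L, n)
  denom <- n * (n - 1) / 2
  ehh <- numeric(length(path))
  for (k in seq_along(path)) {
    key <- gid * 2L + haps[, path[k]]
    gid <- match(key, unique(key))
    cnt <- tabulate(gid)
    ehh[k] <- sum(cnt * (cnt - 1) / 2) / denom
  }
  data.frame(marker = path, cm = cm[path], dist = abs(cm[path] - cm[core]),
             ehh = ehh)
}

# Trapezoid area under y(x); x need not start at 0.
.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Truncate a curve at the first point (beyond the core) where the joint
# EHH drops below the floor; the segment reaching that point is kept.
.trunc_idx <- function(ehh_joint, floor) {
  below <- which(ehh_joint < floor)
  below <- below[below > 1]
  if (length(below) == 0) length(ehh_joint) else below[1]
}

#' Integrated EHH (iHH) for two populations with a shared boundary
#'
#' Integrates each population's EHH decay curve over genetic distance by the
#' trapezoid rule, left and right of the core, and sums the two sides.  Both
#' populations are truncated at the same boundary per direction: the first
#' marker where the EHH of the combined two-population sample drops below
#' `ehh_floor` (that segment is included), or the chromosome end.  The
#' shared boundary keeps iHH_A and iHH_B comparable.
#'
#' @param ehh_a,ehh_b,ehh_joint lists with elements `left` and `right`, each
#'   an [ehh_site()] curve for population A, population B and the pooled
#'   sample, computed at the same markers.
#' @param ehh_floor truncation threshold on the combined EHH (default 0.05).
#' @return Named vector `c(ihh_a, ihh_b)`; both are 0, with attribute
#'   `usable = FALSE`, when there is no integration support on either side.
#' @export
ihh <- function(ehh_a, ehh_b, ehh_joint, ehh_floor = 0.05) {
  one_side <- function(side) {
    j <- ehh_joint[[side]]
    k <- .trunc_idx(j$ehh, ehh_floor)
    a <- ehh_a[[side]][seq_len(k), ]
    b <- ehh_b[[side]][seq_len(k), ]
    c(.trapz(a$dist, a$ehh), .trapz(b$dist, b$ehh))
  }
  v <- one_side("left") + one_side("right")
  out <- c(ihh_a = v[1], ihh_b = v[2])
  attr(out, "usable") <- any(v > 0)
  out
}

# All three EHH curve sets (A, B, joint) around one core; helper shared by
# the R-level route and the tests that pin the compiled scan against it.
.ehh_curves <- function(hap_a, hap_b, core, cm) {
  joint <- rbind(hap_a, hap_b)
  list(
    a = list(left = ehh_site(hap_a, core, "left", cm),
             right = ehh_site(hap_a, core, "right", cm)),
    b = list(left = ehh_site(hap_b, core, "left", cm),
             right = ehh_site(hap_b, core, "right", cm)),
    joint = list(left = ehh_site(joint, core, "left", cm),
                 right = ehh_site(joint, core, "right", cm))
  )
}

#' XP-EHH scan of one ordered population comparison
#'
#' For every SNP, integrates EHH in the focal (A) and reference (B) lines
#' out to a shared combined-sample boundary and forms the unstandardized
#' statistic `ln(iHH_A / iHH_B)`.  Scores are standardized genome-wide
#' within the comparison (population sd, denominator n) and a large positive
#' value indicates extended haplotypes -- recent selection -- in the focal
#' line, so P-values are one-sided upper-tail by default.
#'
#' SNPs where either iHH is 0 cannot be scored; they are excluded from
#' standardization and counted in the `n_excluded` attribute.
#'
#' @param ds a phased, complete [genotype_dataset()].
#' @param focal,reference line labels (population A and B).
#' @param map marker map with cM positions; defaults to the dataset's map.
#'   When no cM positions are available, bp x 1e-6 is used as a fallback
#'   genetic coordinate and flagged in the `map_fallback` attribute.
#' @param ehh_floor combined-EHH truncation threshold (default 0.05).
#' @param two_sided report two-sided instead of upper-tail P-values.
#' @return A score track data frame with columns `chrom`, `id`, `bp`, `cM`,
#'   `ihh_a`, `ihh_b`, `xpehh_raw`, `xpehh_z`, `pvalue`, `comparison`.
#' @export
xpehh_scan <- function(ds, focal, reference, map = NULL, ehh_floor = 0.05,
                       two_sided = FALSE) {
  both <- xpehh_pair(ds, focal, reference, map = map, ehh_floor = ehh_floor,
                     two_sided = two_sided)
  both$forward
}

# Computes the ordered comparison focal vs reference and derives the
# reverse order from the antisymmetry of the log-ratio (the reverse raw
# score is the negation, so its z flips sign and the upper tail mirrors).
xpehh_pair <- function(ds, focal, reference, map = NULL, ehh_floor = 0.05,
                       two_sided = FALSE) {
  if (is.null(map)) map <- ds$markers
  map <- validate_marker_map(map, require_cm = FALSE)
  fallback <- anyNA(map$cM)
  hap_a <- line_haplotypes(ds, focal)
  hap_b <- line_haplotypes(ds, reference)

  res <- vector("list", 0)
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    cm <- if (fallback) map$bp[i] * 1e-6 else map$cM[i]
    hh <- cpp_xpehh_chrom(hap_a[, i, drop = FALSE], hap_b[, i, drop = FALSE],
                          as.numeric(cm), ehh_floor)
    res[[ch]] <- data.frame(
      chrom = ch, id = map$id[i], bp = map$bp[i], cM = cm,
      ihh_a = hh[, 1], ihh_b = hh[, 2], stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, res)
  rownames(track) <- NULL
  usable <- track$ihh_a > 0 & track$ihh_b > 0
  n_excluded <- sum(!usable)
  track <- track[usable, , drop = FALSE]
  if (nrow(track) < 2)
    stop("fewer than 2 scorable SNPs; cannot standardize the comparison")
  track$xpehh_raw <- log(track$ihh_a / track$ihh_b)

  finish <- function(raw, a, b, label) {
    mu <- mean(raw)
    sdev <- sqrt(mean((raw - mu)^2))
    z <- (raw - mu) / sdev
    p <- if (two_sided) 2 * pnorm(abs(z), lower.tail = FALSE)
         else pnorm(z, lower.tail = FALSE)
    out <- track
    out$ihh_a <- a
    out$ihh_b <- b
    out$xpehh_raw <- raw
    out$xpehh_z <- z
    out$pvalue <- p
    out$comparison <- label
    attr(out, "n_excluded") <- n_excluded
    attr(out, "map_fallback") <- fallback
    out
  }
  list(
    forward = finish(track$xpehh_raw, track$ihh_a, track$ihh_b,
                     paste0(focal, "_vs_", reference)),
    reverse = finish(-track$xpehh_raw, track$ihh_b, track$ihh_a,
                     paste0(reference, "_vs_", focal))
  )
}

#' Cluster significant SNPs into candidate regions
#'
#' Consecutive significant SNPs on a chromosome closer than `max_gap` bp
#' join one cluster; the region spans the member SNPs (a singleton SNP
#' yields the zero-length region `[bp, bp]`).
#'
#' @param sig data frame of significant SNPs with columns `chrom`, `bp` and
#'   optionally `pvalue`.
#' @param max_gap clustering distance in bp (default 200 kb); SNPs at a
#'   distance `>= max_gap` start a new cluster.
#' @return Region data frame: `chrom`, `start`, `end`, `n_snps`, `best_p`.
#' @export
cluster_snps_to_regions <- function(sig, max_gap = 200000) {
  if (is.null(sig) || nrow(sig) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      best_p = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$bp), , drop = FALSE]
    grp <- cumsum(c(1, diff(s$bp) >= max_gap))
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(m$bp), end = max(m$bp), n_snps = nrow(m),
        best_p = if ("pvalue" %in% names(m)) min(m$pvalue) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
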