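#' Default sweep-scale grid for the XP-CLR-style scan
#'
#' Logarithmically spaced candidate sweep scales (cM).  The scale is the
#' genetic distance over which hitchhiking is expected to distort allele
#' frequencies; the no-sweep model is always evaluated alongside, so the
#' composite likelihood ratio is never negative.
#'
#' @param n number of scales.
#' @param from,to smallest and largest scale in cM.
#' @return Numeric vector of scales.
#' @export
clr_scale_grid <- function(n = 12, from = 0.01, to = 5) {
  exp(seq(log(from), log(to), length.out = n))
}

# Normal density truncated and renormalized to [0, 1].
.tnorm <- function(x, mean, sd) {
  dnorm(x, mean, sd) / (pnorm(1, mean, sd) - pnorm(0, mean, sd))
}

# Per-SNP null and sweep-attractor mixture densities for one comparison.
# Null: focal frequency p_A drifts around the reference frequency p_B with
# variance (omega + 1/n_A) * p_B(1-p_B), truncated to [0,1].  Sweep
# component: mass near fixation of whichever allele hitchhikes, i.e. a
# p_B / (1-p_B) mixture of narrow truncated normals at 1 and 0 (width eps).
.clr_densities <- function(freq_a, freq_b, omega, n_a, eps = 0.02) {
  usable <- freq_b > 0 & freq_b < 1
  f0 <- mix <- rep(NA_real_, length(freq_a))
  sd0 <- sqrt((omega + 1 / n_a) * freq_b * (1 - freq_b))
  f0[usable] <- .tnorm(freq_a[usable], freq_b[usable], sd0[usable])
  mix[usable] <- freq_b[usable] * .tnorm(freq_a[usable], 1, eps) +
    (1 - freq_b[usable]) * .tnorm(freq_a[usable], 0, eps)
  list(f0 = f0, mix = mix, usable = usable)
}

#' Regular grid of putative selected-allele positions
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param map optional marker map used to interpolate a genetic position for
#'   each grid point (markers with cM act as anchors).
#' @param spacing grid spacing in bp (default 2 kb).
#' @return Data frame `chrom`, `bp`, `cM` (NA when no map given).
#' @export
make_grid <- function(chrom_lengths, map = NULL, spacing = 2000) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    k <- floor(chrom_lengths[[ch]] / spacing)
    if (k == 0) {
      warning("chromosome ", ch, " shorter than the grid spacing; no points")
      next
    }
    out[[ch]] <- data.frame(chrom = ch, bp = spacing * seq_len(k),
                            cM = NA_real_, stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, out)
  if (is.null(grid))
    return(data.frame(chrom = character(), bp = integer(), cM = numeric()))
  rownames(grid) <- NULL
  if (!is.null(map)) {
    anchors <- map[!is.na(map$cM), c("chrom", "bp", "cM")]
    grid <- interpolate_map(anchors, grid[c("chrom", "bp")])
    grid <- grid[c("chrom", "bp", "cM")]
  }
  grid
}

#' LD-based SNP weights for one window
#'
#' Down-weights SNPs that travel in high-LD packs: SNP i receives weight
#' 1/k_i where k_i counts the window SNPs j (including i itself) whose
#' haplotype allele correlation with i satisfies `|r| >= r_cutoff` in the
#' reference panel.  Monomorphic SNPs have undefined r; they are treated as
#' uncorrelated with everything and get weight 1.
#'
#' @param haps_ref reference-line haplotype matrix over the window SNPs.
#' @param r_cutoff correlation threshold (default 0.9).
#' @return Numeric vector of weights in (0, 1].
#' @export
ld_weights <- function(haps_ref, r_cutoff = 0.9) {
  m <- ncol(haps_ref)
  if (m == 0) stop("window contains no SNPs")
  if (m == 1) return(1)
  r <- suppressWarnings(cor(haps_ref))
  k <- rowSums(abs(r) >= r_cutoff, na.rm = TRUE)
  k[k == 0] <- 1  # monomorphic: self only
  1 / k
}

#' Method-of-moments drift-scale estimate
#'
#' Calibrates the genome-wide drift variance scale omega of the null model
#' from the raw moment `mean[(p_A - p_B)^2 / (p_B (1 - p_B))]`, with the
#' binomial sampling contribution `mean[1 / n_A]` subtracted and the result
#' floored at 0.
#'
#' @param freq_a,freq_b per-SNP allele-1 frequencies in the focal (A) and
#'   reference (B) populations.
#' @param n_a focal haplotype count(s); scalar or per-SNP vector.
#' @param n_b optional reference haplotype count (carried, not used).
#' @return Object of class `drift_params`: list with `omega`, `n_a`, `n_b`.
#' @export
estimate_omega <- function(freq_a, freq_b, n_a, n_b = NULL) {
  ok <- freq_b > 0 & freq_b < 1 & !is.na(freq_a) & !is.na(freq_b)
  if (!any(ok)) stop("no SNPs with reference frequency strictly inside (0,1)")
  if (sum(ok) < 100)
    warning("omega estimated from only ", sum(ok), " SNPs; it may be noisy")
  n_a_v <- rep_len(n_a, length(freq_a))[ok]
  m <- mean((freq_a[ok] - freq_b[ok])^2 / (freq_b[ok] * (1 - freq_b[ok])))
  corr <- mean(1 / n_a_v)
  structure(list(omega = max(0, m - corr),
                 n_a = if (length(unique(n_a)) == 1) n_a[1] else n_a,
                 n_b = n_b),
            class = "drift_params")
}

#' @exportS3Method base::print
print.drift_params <- function(x, ...) {
  cat("drift_params: omega =", format(x$omega, digits = 4),
      " n_A =", x$n_a[1], "\n")
  invisible(x)
}

#' Composite likelihood ratio of one grid window
#'
#' Contrasts a local-sweep model against genome-wide drift for the SNPs of
#' one window.  Under the null, each focal frequency follows a truncated
#' normal around the reference frequency with drift-plus-sampling variance.
#' Under a sweep of scale s, a SNP at genetic distance d from the grid point
#' escapes the sweep with probability `c = 1 - exp(-d/s)` and otherwise is
#' drawn from the near-fixation mixture.  The statistic is twice the
#' LD-weighted log-likelihood-ratio sum, maximized over the scale grid plus
#' the no-sweep model (hence always >= 0).
#'
#' @param dist_cm per-SNP genetic distance (cM) to the grid point.
#' @param freq_a,freq_b per-SNP focal and reference frequencies.
#' @param weights per-SNP LD weights (see [ld_weights()]).
#' @param drift a [estimate_omega()] result (or list with `omega`, `n_a`).
#' @param scales sweep-scale grid in cM.
#' @param eps width of the fixation components (default 0.02).
#' @return List with `clr`, `scale` (argmax scale, `NA` when the no-sweep
#'   model is optimal) and `flagged` (no scorable SNP in the window).
#' @export
clr_score <- function(dist_cm, freq_a, freq_b, weights, drift,
                      scales = clr_scale_grid(), eps = 0.02) {
  d <- .clr_densities(freq_a, freq_b, drift$omega, rep_len(drift$n_a,
                                                           length(freq_a)),
                      eps = eps)
  ok <- d$usable
  if (!any(ok))
    return(list(clr = 0, scale = NA_real_, flagged = TRUE))
  w <- weights[ok]
  lf0 <- log(d$f0[ok])
  best <- 0
  best_scale <- NA_real_
  for (s in scales) {
    cc <- 1 - exp(-dist_cm[ok] / s)
    f1 <- pmax(cc * d$f0[ok] + (1 - cc) * d$mix[ok], 1e-300)
    ll <- sum(w * (log(f1) - lf0))
    if (ll > best) {
      best <- ll
      best_scale <- s
    }
  }
  list(clr = 2 * best, scale = best_scale, flagged = FALSE)
}

#' Strong-LD adjacency of one chromosome's SNPs
#'
#' For each SNP of a reference panel, the indices of the SNPs within
#' `max_cm` cM whose haplotype allele correlation reaches `r_cutoff` in
#' absolute value.  Window weights follow by counting adjacent SNPs inside
#' a window, so the pairwise-r computation is shared across all windows
#' (and across comparisons using the same reference line).
#'
#' @param haps reference haplotype matrix (one chromosome).
#' @param cm genetic positions of the columns of `haps`.
#' @param r_cutoff correlation threshold (default 0.9).
#' @param max_cm maximum pair distance considered (the window width).
#' @return List (one element per SNP) of 1-based partner indices;
#'   monomorphic SNPs get an empty set.
#' @export
ld_adjacency <- function(haps, cm, r_cutoff = 0.9, max_cm = 0.5) {
  m <- ncol(haps)
  poly <- apply(haps, 2, function(x) length(unique(x)) > 1)
  adj <- vector("list", m)
  for (i in seq_len(m)) {
    adj[[i]] <- integer(0)
    if (!poly[i]) next
    lo <- findInterval(cm[i] - max_cm, cm, left.open = TRUE) + 1L
    hi <- findInterval(cm[i] + max_cm, cm)
    js <- setdiff(lo:hi, i)
    js <- js[poly[js]]
    if (length(js) == 0) next
    r <- suppressWarnings(
      as.vector(cor(haps[, i], haps[, js, drop = FALSE])))
    adj[[i]] <- js[!is.na(r) & abs(r) >= r_cutoff]
  }
  adj
}

#' XP-CLR-style genome scan of one ordered comparison
#'
#' Scores every grid point with [clr_score()] over the SNPs within
#' `window_cm / 2` cM on either side, using LD weights computed in the
#' reference line (the non-focal line, so the weighting is not driven by
#' sweep-distorted focal LD).  Output headers label the statistic
#' "XP-CLR-style": the composite likelihood is the package's own documented
#' drift-vs-sweep mixture, not a re-implementation of any external binary.
#'
#' @param ds a phased, complete [genotype_dataset()].
#' @param focal,reference line labels.
#' @param map marker map with cM positions.
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   last marker position per chromosome.
#' @param spacing grid spacing in bp (default 2 kb).
#' @param window_cm total window width in cM (default 0.5).
#' @param r_cutoff LD-weighting correlation cutoff (default 0.9).
#' @param scales sweep-scale grid (cM).
#' @param eps fixation-component width.
#' @param drift optional [estimate_omega()] result; estimated genome-wide
#'   from the comparison when `NULL`.
#' @param adjacency optional precomputed strong-LD adjacency for the
#'   reference line (list keyed by chromosome, as built by
#'   [ld_adjacency()]); computed on the fly when `NULL`.  Useful when the
#'   same reference line serves several comparisons.
#' @return Data frame `chrom`, `grid_bp`, `grid_cm`, `n_snps`, `clr`,
#'   `argmax_scale`, `comparison`, with the drift parameters as attribute
#'   `drift`.
#' @export
xpclr_scan <- function(ds, focal, reference, map = NULL, chrom_lengths = NULL,
                       spacing = 2000, window_cm = 0.5, r_cutoff = 0.9,
                       scales = clr_scale_grid(), eps = 0.02, drift = NULL,
                       adjacency = NULL) {
  if (is.null(map)) map <- ds$markers
  map <- validate_marker_map(map, require_cm = TRUE)
  hap_a <- line_haplotypes(ds, focal)
  hap_b <- line_haplotypes(ds, reference)
  freq_a <- colMeans(hap_a)
  freq_b <- colMeans(hap_b)
  if (is.null(drift))
    drift <- estimate_omega(freq_a, freq_b, n_a = nrow(hap_a),
                            n_b = nrow(hap_b))
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(map$bp, map$chrom, max)
  dens <- .clr_densities(freq_a, freq_b, drift$omega,
                         rep_len(drift$n_a, length(freq_a)), eps = eps)
  grid <- make_grid(chrom_lengths, map = map, spacing = spacing)

  out <- list()
  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    si <- which(map$chrom == ch)
    adj <- if (!is.null(adjacency)) adjacency[[ch]]
           else ld_adjacency(hap_b[, si, drop = FALSE], map$cM[si],
                             r_cutoff = r_cutoff, max_cm = window_cm)
    sc <- cpp_clr_chrom(
      grid_cm = grid$cM[gi], snp_cm = map$cM[si],
      logf0 = log(dens$f0[si]), f0 = dens$f0[si], mix = dens$mix[si],
      usable = dens$usable[si], adj = adj, scales = scales,
      half_width = window_cm / 2)
    out[[ch]] <- data.frame(
      chrom = ch, grid_bp = grid$bp[gi], grid_cm = grid$cM[gi],
      n_snps = sc$n_snps, clr = sc$clr,
      argmax_scale = ifelse(sc$scale_idx > 0, scales[pmax(sc$scale_idx, 1)],
                            NA_real_),
      stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  track$comparison <- paste0(focal, "_vs_", reference)
  attr(track, "drift") <- drift
  attr(track, "statistic") <- "XP-CLR-style"
  track
}

#' Call candidate regions from an XP-CLR-style score track
#'
#' Keeps windows whose score reaches the empirical upper `top_fraction`
#' quantile of the comparison (midpoint-interpolated; ties at the cutoff are
#' all kept) and clusters kept windows whose genetic distance to the
#' previous kept window on the same chromosome is below `cluster_gap_cm`.
#' Windows with no scorable SNP do not enter the threshold or the calls.
#'
#' @param scores an [xpclr_scan()] track.
#' @param top_fraction retained upper fraction of window scores (default 0.005).
#' @param cluster_gap_cm clustering distance in cM (default 1).
#' @return Region data frame: `chrom`, `start`, `end`, `n_windows`,
#'   `max_clr`.
#' @export
call_xpclr_regions <- function(scores, top_fraction = 0.005,
                               cluster_gap_cm = 1.0) {
  s <- scores[scores$n_snps > 0, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_clr = numeric(), stringsAsFactors = FALSE)
  if (nrow(s) == 0 || all(s$clr == 0)) {
    warning("no non-zero XP-CLR-style scores; no regions called")
    return(empty)
  }
  thr <- quantile(s$clr, 1 - top_fraction, type = 2, names = FALSE)
  kept <- s[s$clr >= thr, , drop = FALSE]
  out <- list()
  for (ch in unique(kept$chrom)) {
    k <- kept[kept$chrom == ch, , drop = FALSE]
    k <- k[order(k$grid_bp), , drop = FALSE]
    grp <- cumsum(c(1, diff(k$grid_cm) >= cluster_gap_cm))
    for (g in unique(grp)) {
      m <- k[grp == g, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(m$grid_bp), end = max(m$grid_bp),
        n_windows = nrow(m), max_clr = max(m$clr), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
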