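#' Pooled heterozygosity in sliding SNP windows
#'
#' For one line, slides a `window_size`-SNP window (step `step`) along each
#' chromosome and sums the major- and minor-allele counts of the member
#' SNPs (major/minor defined per SNP within the line, from called alleles
#' only).  The pooled heterozygosity of a window is
#' `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2`, which lies in \[0, 0.5\]:
#' 0 when every SNP is fixed, 0.5 when every SNP is at frequency 1/2.
#' Strongly depressed Hp marks sweeps to (near-)fixation.
#'
#' @param ds a [genotype_dataset()].
#' @param line line label.
#' @param window_size SNPs per window (default 5).
#' @param step window step in SNPs (default 1).
#' @param exclude_chroms chromosome labels to leave out (sex chromosomes;
#'   default `c("Z", "W")`).
#' @return Data frame `line`, `chrom`, `win_start_bp`, `win_end_bp`,
#'   `sum_maj`, `sum_min`, `hp`.
#' @export
hp_windows <- function(ds, line, window_size = 5, step = 1,
                       exclude_chroms = c("Z", "W")) {
  idx <- which(ds$lines == line)
  if (length(idx) == 0) stop("no samples in line '", line, "'")
  a1 <- ds$a1[idx, , drop = FALSE]
  a2 <- ds$a2[idx, , drop = FALSE]
  n1 <- colSums(a1 == 1L, na.rm = TRUE) + colSums(a2 == 1L, na.rm = TRUE)
  n <- colSums(!is.na(a1)) + colSums(!is.na(a2))
  n0 <- n - n1
  n_maj <- pmax(n0, n1)
  n_min <- pmin(n0, n1)

  out <- list()
  for (ch in setdiff(unique(ds$markers$chrom), exclude_chroms)) {
    i <- which(ds$markers$chrom == ch)
    if (length(i) < window_size) {
      warning("chromosome ", ch, " has fewer than ", window_size,
              " SNPs; skipped")
      next
    }
    starts <- seq(1L, length(i) - window_size + 1L, by = step)
    csum <- function(x) {
      s <- cumsum(c(0, x))
      s[starts + window_size] - s[starts]
    }
    smaj <- csum(n_maj[i])
    smin <- csum(n_min[i])
    tot <- smaj + smin
    out[[ch]] <- data.frame(
      line = line, chrom = ch,
      win_start_bp = ds$markers$bp[i][starts],
      win_end_bp = ds$markers$bp[i][starts + window_size - 1L],
      sum_maj = smaj, sum_min = smin,
      hp = ifelse(tot > 0, 2 * smaj * smin / tot^2, NA_real_),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no chromosome with enough SNPs")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Z-transform pooled-heterozygosity windows
#'
#' Standardizes Hp genome-wide within each line (population sd, denominator
#' n), adding a `zhp` column.  Strongly negative ZHp flags putative sweep
#' windows; no default significance cutoff is imposed.
#'
#' @param windows output of [hp_windows()] (one or several lines).
#' @return The input with a `zhp` column.
#' @export
zhp_transform <- function(windows) {
  stopifnot(all(c("line", "hp") %in% names(windows)))
  windows$zhp <- NA_real_
  for (l in unique(windows$line)) {
    i <- which(windows$line == l & !is.na(windows$hp))
    if (length(i) < 2)
      stop("line ", l, ": need at least 2 windows to standardize")
    mu <- mean(windows$hp[i])
    sdev <- sqrt(mean((windows$hp[i] - mu)^2))
    if (sdev == 0)
      stop("line ", l, ": all Hp values identical; cannot Z-transform")
    windows$zhp[i] <- (windows$hp[i] - mu) / sdev
  }
  windows
}
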