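# Shared fixture builders: everything is generated in code at test time.

# A small genotype dataset from explicit haplotype matrices (one per line).
# haps: named list of 2n x M 0/1 matrices.
make_ds <- function(haps, markers = NULL, phased = TRUE) {
  m <- ncol(haps[[1]])
  if (is.null(markers))
    markers <- data.frame(chrom = "1", id = paste0("s", seq_len(m)),
                          bp = seq_len(m) * 1000L, cM = seq_len(m) * 0.001)
  a1 <- NULL; a2 <- NULL; ids <- character(0); lines <- character(0)
  for (l in names(haps)) {
    h <- haps[[l]]
    n <- nrow(h) / 2
    a1 <- rbind(a1, h[seq(1, 2 * n, by = 2), , drop = FALSE])
    a2 <- rbind(a2, h[seq(2, 2 * n, by = 2), , drop = FALSE])
    ids <- c(ids, sprintf("%s_%02d", l, seq_len(n)))
    lines <- c(lines, rep(l, n))
  }
  rownames(a1) <- rownames(a2) <- ids
  genotype_dataset(a1, a2, markers, setNames(lines, ids), phased = phased)
}

random_haps <- function(n_hap, n_snp, p = 0.5) {
  matrix(rbinom(n_hap * n_snp, 1L, p), nrow = n_hap)
}

# Exhaustive pair-counting EHH oracle: probability that two random
# haplotypes are identical over [core..x] for every x in one direction.
ehh_oracle <- function(haps, core, direction = c("right", "left")) {
  direction <- match.arg(direction)
  n <- nrow(haps)
  path <- if (direction == "right") core:ncol(haps) else core:1
  sapply(seq_along(path), function(k) {
    span <- path[1:k]
    same <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (all(haps[i, span] == haps[j, span])) same <- same + 1L
    same / (n * (n - 1) / 2)
  })
}

# Independent trapezoid integrator over a truncated curve.
trapz_oracle <- function(x, y) {
  if (length(x) < 2) return(0)
  s <- 0
  for (k in 2:length(x))
    s <- s + (x[k] - x[k - 1]) * (y[k] + y[k - 1]) / 2
  s
}

# A tiny five-line study configuration used by simulation-backed tests.
small_sim_config <- function(seed, sweeps = list()) {
  sim_config(
    seed = seed,
    chrom_lengths = c(`1` = 6e6, `2` = 6e6),
    n_snps = 600, n_founders = 40, base_diploids = 120,
    lines = c("L1", "L2", "L3"), ne = 80, generations = 20,
    samples = c(L1 = 20, L2 = 20, L3 = 20),
    sweeps = sweeps, missing_rate = 0
  )
}
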