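test_that("make_grid counts and maps grid points", {
  g <- make_grid(c(A = 10000))
  expect_equal(nrow(g), 5)
  expect_equal(g$bp, 2000 * 1:5)
  expect_warning(make_grid(c(B = 1999)), "shorter")
  # chicken-chromosome scale: floor(len / spacing) points
  g5 <- make_grid(c(`5` = 62e6))
  expect_equal(nrow(g5), floor(62e6 / 2000))
  # grid cM interpolated through the marker map
  map <- data.frame(chrom = "A", id = c("a", "b"), bp = c(1000L, 9000L),
                    cM = c(0.1, 0.9))
  gm <- make_grid(c(A = 10000), map = map)
  expect_equal(gm$cM[gm$bp == 2000], 0.2, tolerance = 1e-12)
})

test_that("ld_weights: worked cases and brute-force agreement", {
  # all mutually uncorrelated
  set.seed(111)
  h <- cbind(rep(0:1, 10), rep(c(0, 0, 1, 1), 5), rbinom(20, 1, 0.5))
  while (any(abs(cor(h)[upper.tri(diag(3))]) >= 0.9))
    h[, 3] <- rbinom(20, 1, 0.5)
  expect_equal(ld_weights(h), c(1, 1, 1))
  # two perfect copies plus one independent -> 1/2, 1/2, 1
  h2 <- cbind(h[, 1], h[, 1], h[, 3])
  expect_equal(ld_weights(h2), c(0.5, 0.5, 1))
  # monomorphic column: weight 1, never counted as a partner
  h3 <- cbind(h[, 1], 0L, h[, 1])
  expect_equal(ld_weights(h3), c(0.5, 1, 0.5))

  for (case in 1:40) {
    m <- sample(2:10, 1)
    h <- random_haps(16, m, runif(1, 0.2, 0.8))
    w <- ld_weights(h, r_cutoff = 0.9)
    r <- suppressWarnings(cor(h))
    k_exp <- vapply(seq_len(m), function(i) {
      ri <- r[i, ]
      max(1L, sum(abs(ri) >= 0.9, na.rm = TRUE))
    }, integer(1))
    expect_equal(w, 1 / k_exp)
  }
})

test_that("estimate_omega: degenerate, arithmetic and recovery cases", {
  # identical frequencies at huge n -> omega 0
  p <- runif(200, 0.2, 0.8)
  expect_equal(estimate_omega(p, p, n_a = 1e9)$omega, 0)
  # single-SNP raw moment (sampling term ignored at huge n)
  m1 <- suppressWarnings(estimate_omega(0.6, 0.5, n_a = 1e12))
  expect_equal(m1$omega, 0.01 / 0.25, tolerance = 1e-6)
  expect_error(estimate_omega(0.5, 1, n_a = 10), "strictly inside")

  # simulation recovery: truncated-normal perturbation, 20,000 SNPs
  set.seed(121)
  omega_true <- 0.02
  p_b <- runif(20000, 0.2, 0.8)
  p_a <- rnorm(20000, p_b, sqrt(omega_true * p_b * (1 - p_b)))
  redo <- p_a <= 0 | p_a >= 1
  while (any(redo)) {
    p_a[redo] <- rnorm(sum(redo), p_b[redo],
                       sqrt(omega_true * p_b[redo] * (1 - p_b[redo])))
    redo <- p_a <= 0 | p_a >= 1
  }
  est <- estimate_omega(p_a, p_b, n_a = 1e9)
  expect_lt(abs(est$omega - omega_true) / omega_true, 0.10)
})

test_that("clr densities normalize on [0,1] and the score behaves", {
  grid <- seq(0, 1, length.out = 20001)
  for (pb in c(0.1, 0.5, 0.9)) {
    f0 <- sweepscan:::.tnorm(grid, pb, sqrt(0.05 * pb * (1 - pb)))
    expect_equal(trapz_oracle(grid, f0), 1, tolerance = 1e-6)
    mix <- pb * sweepscan:::.tnorm(grid, 1, 0.02) +
      (1 - pb) * sweepscan:::.tnorm(grid, 0, 0.02)
    expect_equal(trapz_oracle(grid, mix), 1, tolerance = 1e-6)
  }

  drift <- structure(list(omega = 0.02, n_a = 100), class = "drift_params")
  d <- runif(20, 0, 0.25)
  pb <- runif(20, 0.2, 0.8)
  w <- rep(1, 20)
  # identical frequencies -> no-sweep optimal, CLR exactly 0
  eq <- clr_score(d, pb, pb, w, drift)
  expect_equal(eq$clr, 0)
  expect_true(is.na(eq$scale))
  # frequencies pushed toward fixation -> positive CLR at a finite scale
  push <- clr_score(d, rep(0.99, 20), rep(0.5, 20), w, drift)
  expect_gt(push$clr, 0)
  expect_true(is.finite(push$scale))
  # linearity in the weights
  half <- clr_score(d, rep(0.99, 20), rep(0.5, 20), w / 2, drift)
  expect_equal(half$clr, push$clr / 2, tolerance = 1e-9)
  # allele relabeling symmetry
  flip <- clr_score(d, 1 - rep(0.99, 20), 1 - rep(0.5, 20), w, drift)
  expect_equal(flip$clr, push$clr, tolerance = 1e-6)
  # brute-force check of the maximization over the scale grid
  scales <- clr_scale_grid()
  lls <- vapply(scales, function(s) {
    cc <- 1 - exp(-d / s)
    f0 <- sweepscan:::.tnorm(rep(0.99, 20), pb,
                             sqrt((0.02 + 1 / 100) * pb * (1 - pb)))
    mix <- pb * sweepscan:::.tnorm(rep(0.99, 20), 1, 0.02) +
      (1 - pb) * sweepscan:::.tnorm(rep(0.99, 20), 0, 0.02)
    sum(log(pmax(cc * f0 + (1 - cc) * mix, 1e-300)) - log(f0))
  }, numeric(1))
  got <- clr_score(d, rep(0.99, 20), pb, w, drift)
  expect_equal(got$clr, 2 * max(0, max(lls)), tolerance = 1e-9)
})

test_that("CLR never decreases as window frequencies inflate to fixation", {
  set.seed(131)
  drift <- structure(list(omega = 0.05, n_a = 80), class = "drift_params")
  d <- runif(15, 0, 0.25)
  pb <- runif(15, 0.3, 0.7)
  pa0 <- pb
  w <- rep(1, 15)
  prev <- clr_score(d, pa0, pb, w, drift)$clr
  for (step in seq(0.2, 1, by = 0.2)) {
    pa <- pb + (0.999 - pb) * step
    cur <- clr_score(d, pa, pb, w, drift)$clr
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
})

test_that("compiled window scorer agrees with clr_score", {
  set.seed(141)
  cfg <- small_sim_config(21)
  st <- simulate_study(cfg)
  hapA <- line_haplotypes(st$ds, "L1")
  hapB <- line_haplotypes(st$ds, "L2")
  pa <- colMeans(hapA); pb <- colMeans(hapB)
  drift <- estimate_omega(pa, pb, n_a = nrow(hapA))
  track <- xpclr_scan(st$ds, "L1", "L2", map = st$map,
                      chrom_lengths = cfg$chrom_lengths, drift = drift)
  scales <- clr_scale_grid()
  probe <- track[track$n_snps > 0, ]
  probe <- probe[sample(nrow(probe), 25), ]
  for (r in seq_len(nrow(probe))) {
    ch <- probe$chrom[r]
    si <- which(st$map$chrom == ch)
    cm <- st$map$cM[si]
    inw <- si[abs(cm - probe$grid_cm[r]) <= 0.25]
    use <- inw[pb[inw] > 0 & pb[inw] < 1]
    # window weights from the reference panel restricted to the window
    w_all <- ld_weights(hapB[, inw[pb[inw] > 0 & pb[inw] < 1], drop = FALSE])
    ref <- clr_score(abs(st$map$cM[use] - probe$grid_cm[r]),
                     pa[use], pb[use], w_all, drift, scales = scales)
    expect_equal(probe$clr[r], ref$clr, tolerance = 1e-8)
    expect_equal(probe$n_snps[r], length(use))
  }
})

test_that("top-fraction thresholding keeps exactly the top windows and clusters by cM", {
  set.seed(151)
  scores <- data.frame(chrom = "1", grid_bp = 2000 * (1:1000),
                       grid_cm = 0.002 * (1:1000), n_snps = 5,
                       clr = sample(1000))
  reg <- call_xpclr_regions(scores, top_fraction = 0.005)
  expect_equal(sum(reg$n_windows), 5)
  # worked clustering: kept windows at 10.0, 10.4, 12.0 cM -> two regions
  ks <- data.frame(chrom = "9", grid_bp = c(100L, 200L, 300L),
                   grid_cm = c(10.0, 10.4, 12.0), n_snps = 2,
                   clr = c(50, 60, 70))
  reg2 <- call_xpclr_regions(ks, top_fraction = 0.999)
  expect_equal(reg2$start, c(100L, 300L))
  expect_equal(reg2$end, c(200L, 300L))
  expect_warning(call_xpclr_regions(transform(ks, clr = 0)), "no regions")

  # randomized instances against a quantile-then-partition oracle
  for (case in 1:40) {
    n <- sample(50:400, 1)
    sc <- data.frame(chrom = "1", grid_bp = 2000 * (1:n),
                     grid_cm = sort(runif(n, 0, 30)), n_snps = 1,
                     clr = rexp(n))
    tf <- sample(c(0.01, 0.05, 0.1), 1)
    reg <- call_xpclr_regions(sc, top_fraction = tf, cluster_gap_cm = 1)
    thr <- quantile(sc$clr, 1 - tf, type = 2)
    kept <- sc[sc$clr >= thr, ]
    grp <- cumsum(c(1, diff(kept$grid_cm) >= 1))
    expect_equal(reg$start, as.integer(tapply(kept$grid_bp, grp, min)),
                 ignore_attr = TRUE)
    expect_equal(reg$end, as.integer(tapply(kept$grid_bp, grp, max)),
                 ignore_attr = TRUE)
  }
})
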