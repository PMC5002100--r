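test_that("ehh_site equals exhaustive pair counting on the worked partition", {
  # 6 haplotypes splitting into groups {3,2,1} two markers out:
  # EHH = (C(3,2)+C(2,2)) / C(6,2) = 4/15
  haps <- rbind(
    c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
    c(0, 0, 1), c(0, 0, 1),
    c(0, 1, 0))
  cur <- ehh_site(haps, core = 1, direction = "right")
  expect_equal(cur$ehh[3], 4 / 15)
  expect_equal(cur$ehh, ehh_oracle(haps, 1, "right"))
})

test_that("EHH boundary cases: identical panel and all-distinct flank", {
  same <- matrix(1L, nrow = 5, ncol = 6)
  expect_true(all(ehh_site(same, 3, "right")$ehh == 1))
  expect_true(all(ehh_site(same, 3, "left")$ehh == 1))
  # biallelic flank cannot make every pair distinct, but a balanced flank
  # within each core group drives EHH down by exactly the group split
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  cur <- ehh_site(haps, 1, "right")
  expect_equal(cur$ehh, ehh_oracle(haps, 1, "right"))
  expect_error(ehh_site(haps[1, , drop = FALSE], 1), "2 haplotypes")
})

test_that("ehh_site matches the pair-counting oracle on random panels", {
  set.seed(61)
  for (case in 1:60) {
    n <- sample(2:12, 1)
    m <- sample(2:10, 1)
    haps <- random_haps(n, m, runif(1, 0.2, 0.8))
    core <- sample(m, 1)
    for (dir in c("left", "right")) {
      cur <- ehh_site(haps, core, dir)
      expect_identical(cur$ehh, ehh_oracle(haps, core, dir))
      # non-increasing away from the core
      expect_true(all(diff(cur$ehh) <= 1e-12))
    }
  }
})

test_that("iHH: rectangle area, symmetry, and brute-force agreement", {
  # EHH == 1 over 0.1 cM to each chromosome end -> iHH = 0.1 + 0.1 = 0.2;
  # identical panels give identical integrals
  cm <- c(0, 0.1, 0.2)
  hapA <- matrix(0L, 6, 3)
  curves <- sweepscan:::.ehh_curves(hapA, hapA, core = 2, cm = cm)
  v <- ihh(curves$a, curves$b, curves$joint, ehh_floor = 0.05)
  expect_equal(as.numeric(v["ihh_a"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(v["ihh_a"]), unname(v["ihh_b"]))

  set.seed(71)
  for (case in 1:40) {
    n <- 2 * sample(2:6, 1)
    m <- sample(4:20, 1)
    cm <- cumsum(runif(m, 0.01, 0.2))
    hapA <- random_haps(n, m)
    hapB <- random_haps(n, m)
    core <- sample(m, 1)
    curves <- sweepscan:::.ehh_curves(hapA, hapB, core, cm)
    got <- ihh(curves$a, curves$b, curves$joint, ehh_floor = 0.05)
    # independent integrator: truncate each direction at the first joint
    # EHH below the floor (inclusive), then trapezoid over distance
    oracle_side <- function(side) {
      j <- curves$joint[[side]]$ehh
      below <- which(j < 0.05)
      k <- if (any(below > 1)) min(below[below > 1]) else length(j)
      a <- curves$a[[side]]
      b <- curves$b[[side]]
      c(trapz_oracle(a$dist[1:k], a$ehh[1:k]),
        trapz_oracle(b$dist[1:k], b$ehh[1:k]))
    }
    exp_v <- oracle_side("left") + oracle_side("right")
    expect_equal(as.numeric(got), exp_v, tolerance = 1e-12)
  }
})

test_that("compiled pair scan equals the curve-based route", {
  set.seed(81)
  for (case in 1:15) {
    nA <- 2 * sample(2:5, 1); nB <- 2 * sample(2:5, 1)
    m <- sample(5:15, 1)
    cm <- cumsum(runif(m, 0.01, 0.3))
    hapA <- random_haps(nA, m); hapB <- random_haps(nB, m)
    hh <- sweepscan:::cpp_xpehh_chrom(hapA, hapB, cm, 0.05)
    for (core in seq_len(m)) {
      curves <- sweepscan:::.ehh_curves(hapA, hapB, core, cm)
      v <- ihh(curves$a, curves$b, curves$joint, ehh_floor = 0.05)
      expect_equal(hh[core, 1], unname(v["ihh_a"]), tolerance = 1e-12)
      expect_equal(hh[core, 2], unname(v["ihh_b"]), tolerance = 1e-12)
    }
  }
})

test_that("xpehh_scan: ratio, antisymmetry, standardization and tails", {
  # direct ratio: iHH 0.2 vs 0.1 gives ln 2
  expect_equal(log(0.2 / 0.1), 0.6931, tolerance = 1e-4)
  set.seed(91)
  cfg <- small_sim_config(13)
  st <- simulate_study(cfg)
  fwd <- xpehh_scan(st$ds, "L1", "L2", map = st$map)
  rev <- xpehh_scan(st$ds, "L2", "L1", map = st$map)
  # antisymmetry of the raw statistic under population swap
  common <- intersect(fwd$id, rev$id)
  expect_equal(fwd$xpehh_raw[match(common, fwd$id)],
               -rev$xpehh_raw[match(common, rev$id)], tolerance = 1e-12)
  # standardized scores: population mean 0, sd 1
  expect_lt(abs(mean(fwd$xpehh_z)), 1e-9)
  expect_lt(abs(sqrt(mean(fwd$xpehh_z^2)) - 1), 1e-9)
  # one-sided upper-tail P at the usual 5% quantile
  expect_equal(pnorm(1.6449, lower.tail = FALSE), 0.05, tolerance = 1e-4)
  expect_equal(fwd$pvalue, pnorm(fwd$xpehh_z, lower.tail = FALSE))
  # neutral panel: significant fraction stays loosely near its nominal rate
  expect_lt(mean(fwd$pvalue < 0.05), 0.15)
})

test_that("SNP clustering into regions matches a gap-partition oracle", {
  # threshold reading: 1.0/1.1/1.5 Mb -> [1.0-1.1] and the 1.5 singleton
  sig <- data.frame(chrom = "1", bp = c(1000000L, 1100000L, 1500000L))
  reg <- cluster_snps_to_regions(sig, max_gap = 200000)
  expect_equal(reg$start, c(1000000L, 1500000L))
  expect_equal(reg$end, c(1100000L, 1500000L))
  expect_equal(reg$n_snps, c(2L, 1L))
  # singleton -> zero-length region
  one <- cluster_snps_to_regions(data.frame(chrom = "3", bp = 42L))
  expect_equal(c(one$start, one$end), c(42L, 42L))
  expect_equal(nrow(cluster_snps_to_regions(sig[0, ])), 0L)

  set.seed(101)
  for (case in 1:40) {
    bp <- sort(sample.int(2e6, sample(2:40, 1)))
    gap <- sample(c(5e4, 2e5, 5e5), 1)
    reg <- cluster_snps_to_regions(data.frame(chrom = "1", bp = bp),
                                   max_gap = gap)
    # oracle: cut wherever the inter-SNP distance reaches the gap
    grp <- cumsum(c(1, diff(bp) >= gap))
    expect_equal(reg$start, as.integer(tapply(bp, grp, min)),
                 ignore_attr = TRUE)
    expect_equal(reg$end, as.integer(tapply(bp, grp, max)),
                 ignore_attr = TRUE)
  }
})
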