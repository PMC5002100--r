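# Brute-force per-position coverage of 1-based inclusive intervals.
coverage_vec <- function(starts, ends, limit) {
  v <- logical(limit)
  for (k in seq_along(starts)) v[starts[k]:ends[k]] <- TRUE
  v
}

test_that("merge_comparisons unions and coalesces adjacent intervals", {
  r <- data.frame(chrom = "1", start = c(1000000L, 1500000L),
                  end = c(2000000L, 3000000L),
                  comparison = c("c1", "c2"))
  m <- merge_comparisons(r, line = "L", method = "xpehh")
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1000000L, 3000000L))
  expect_equal(m$comparisons, "c1,c2")
  # disjoint inputs unchanged
  d <- data.frame(chrom = "1", start = c(10L, 100L), end = c(20L, 120L))
  expect_equal(nrow(merge_comparisons(d)), 2)
  # 1 bp gap coalesces, 2 bp gap does not
  g1 <- data.frame(chrom = "1", start = c(1L, 4L), end = c(2L, 6L))
  expect_equal(nrow(merge_comparisons(g1)), 1)
  g2 <- data.frame(chrom = "1", start = c(1L, 5L), end = c(2L, 6L))
  expect_equal(nrow(merge_comparisons(g2)), 2)

  set.seed(181)
  for (case in 1:60) {
    n <- sample(1:25, 1)
    s <- sample.int(1500, n)
    e <- pmin(s + sample(0:300, n, replace = TRUE), 1600L)
    m <- merge_comparisons(data.frame(chrom = "1", start = s, end = e))
    got <- coverage_vec(m$start, m$end, 1600L)
    want <- coverage_vec(s, e, 1600L)
    # the union must cover the same positions plus the <=1 bp bridged gaps
    bridged <- want
    gap <- which(!want)
    lone <- gap[gap > 1 & gap < 1600 &
                  c(want[pmax(gap - 1, 1)] & want[pmin(gap + 1, 1600)])]
    bridged[lone] <- TRUE
    expect_identical(got, bridged)
    # merged intervals are disjoint with gaps > 1
    if (nrow(m) > 1) expect_true(all(m$start[-1] - m$end[-nrow(m)] > 2))
  }
})

test_that("intersect_methods keeps XP-CLR spans touched by XP-EHH regions", {
  clr <- data.frame(chrom = "1", start = 10000000L, end = 11000000L)
  ehh <- data.frame(chrom = "1", start = 9000000L, end = 10200000L)
  got <- intersect_methods(ehh, clr, line = "L")
  expect_equal(c(got$start, got$end), c(10000000L, 11000000L))
  # no overlap anywhere -> empty
  none <- intersect_methods(
    data.frame(chrom = "1", start = 1L, end = 5L),
    data.frame(chrom = "1", start = 100L, end = 200L))
  expect_equal(nrow(none), 0)
  # one wide XP-EHH region may support several XP-CLR regions
  wide <- data.frame(chrom = "1", start = 1000L, end = 9000L)
  two <- data.frame(chrom = "1", start = c(2000L, 7000L),
                    end = c(3000L, 8000L))
  both <- intersect_methods(wide, two)
  expect_equal(nrow(both), 2)

  set.seed(191)
  for (case in 1:40) {
    ne <- sample(1:12, 1); nc <- sample(1:12, 1)
    es <- sample.int(900, ne); ee <- pmin(es + sample(0:150, ne, TRUE), 1000L)
    cs <- sample.int(900, nc); ce <- pmin(cs + sample(0:150, nc, TRUE), 1000L)
    got <- intersect_methods(data.frame(chrom = "1", start = es, end = ee),
                             data.frame(chrom = "1", start = cs, end = ce))
    keep <- vapply(seq_len(nc), function(k)
      any(cs[k] <= ee & ce[k] >= es), logical(1))
    expect_equal(nrow(got), sum(keep))
    expect_setequal(paste(got$start, got$end),
                    paste(cs[keep], ce[keep])[order(cs[keep])])
  }
})

test_that("cross_line_consensus trims to common overlap per line set", {
  # pairwise intersection
  two <- data.frame(chrom = "1",
                    start = c(1000000L, 1500000L), end = c(2000000L, 2500000L),
                    line = c("l1", "l2"))
  got <- cross_line_consensus(two)
  expect_equal(c(got$start, got$end), c(1500000L, 2000000L))
  expect_equal(got$lines, "l1,l2")
  # chain without a triple point: two pair regions, no 3-line region
  chain <- data.frame(chrom = "1",
                      start = c(1000000L, 1500000L, 2200000L),
                      end = c(2000000L, 2500000L, 3000000L),
                      line = c("l1", "l2", "l3"))
  got2 <- cross_line_consensus(chain)
  expect_equal(got2$start, c(1500000L, 2200000L))
  expect_equal(got2$end, c(2000000L, 2500000L))
  expect_equal(got2$lines, c("l1,l2", "l2,l3"))
  expect_true(all(got2$n_lines == 2))
  # disjoint lines -> nothing
  expect_equal(nrow(cross_line_consensus(
    data.frame(chrom = "1", start = c(1L, 100L), end = c(10L, 110L),
               line = c("a", "b")))), 0)

  set.seed(201)
  for (case in 1:40) {
    lines <- c("a", "b", "c", "d")
    n <- sample(2:16, 1)
    s <- sample.int(900, n, replace = TRUE)
    e <- pmin(s + sample(0:200, n, TRUE), 1000L)
    l <- sample(lines, n, replace = TRUE)
    cand <- data.frame(chrom = "1", start = s, end = e, line = l)
    got <- cross_line_consensus(cand, min_lines = 2)
    # oracle: per-position supporting line set; runs of equal sets >= 2
    sets <- character(1000)
    for (k in seq_len(n))
      for (pos in s[k]:e[k])
        sets[pos] <- paste(sort(unique(c(strsplit(sets[pos], ",")[[1]],
                                         l[k]))), collapse = ",")
    nl <- lengths(strsplit(sets, ","))
    nl[sets == ""] <- 0
    keep <- nl >= 2
    key <- ifelse(keep, sets, "")
    runs <- rle(key)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    exp_idx <- which(runs$values != "")
    expect_equal(got$start, starts[exp_idx], ignore_attr = TRUE)
    expect_equal(got$end, ends[exp_idx], ignore_attr = TRUE)
    expect_equal(got$lines, runs$values[exp_idx], ignore_attr = TRUE)
    # order invariance and containment in every supporter
    perm <- cand[sample(n), ]
    got_p <- cross_line_consensus(perm, min_lines = 2)
    expect_equal(got_p[c("chrom", "start", "end", "lines", "n_lines")],
                 got[c("chrom", "start", "end", "lines", "n_lines")])
    for (r in seq_len(nrow(got))) {
      for (ln in strsplit(got$lines[r], ",")[[1]]) {
        own <- cand[cand$line == ln, ]
        v <- coverage_vec(own$start, own$end, 1000L)
        expect_true(all(v[got$start[r]:got$end[r]]))
      }
    }
  }
})

test_that("genome_coverage counts non-redundant bases", {
  gl <- c(`1` = 1e8)
  one <- data.frame(chrom = "1", start = 1L, end = 1000000L)
  expect_equal(genome_coverage(one, gl), 0.01)
  dup <- rbind(one, data.frame(chrom = "1", start = 500000L, end = 1500000L))
  expect_equal(genome_coverage(dup, gl), 0.015)
  expect_equal(genome_coverage(one[0, ], gl), 0)
  expect_error(genome_coverage(
    data.frame(chrom = "1", start = 1L, end = 2e8), gl), "beyond")

  set.seed(211)
  for (case in 1:40) {
    n <- sample(1:20, 1)
    s <- sample.int(900, n, replace = TRUE)
    e <- pmin(s + sample(0:300, n, TRUE), 1000L)
    got <- genome_coverage(data.frame(chrom = "1", start = s, end = e),
                           c(`1` = 1000))
    expect_equal(got, sum(coverage_vec(s, e, 1000L)) / 1000)
  }
})
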