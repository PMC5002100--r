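test_that("region haplotype frequencies, major calls and skip rule", {
  # line of 4 haplotypes AAB, AAB, ABB, BAB (A=0, B=1), padded to 5 SNPs;
  # a second line keeps every column polymorphic in the pooled sample
  h <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, 1, 1), c(1, 0, 1))
  pad <- rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0))
  haps <- cbind(h, pad)
  other <- rbind(c(1, 1, 0, 0, 1), c(0, 0, 0, 1, 0))
  ds <- make_ds(list(A = haps, B = other))
  reg <- list(chrom = "1", start = 1000L, end = 5000L)
  ht <- region_haplotypes(reg, ds, min_snps = 5)
  expect_equal(ht$status, "ok")
  tab <- ht$table[ht$table$line == "A", ]
  expect_equal(tab$freq, c(0.5, 0.25, 0.25))
  expect_equal(tab$haplotype[tab$is_major], "00101")
  expect_equal(sum(tab$freq), 1)

  # fewer than 5 informative SNPs -> skipped with status
  small <- region_haplotypes(list(chrom = "1", start = 1000L, end = 3000L),
                             ds, min_snps = 5)
  expect_equal(small$status, "below_min_snps")
  expect_equal(small$n_informative, 3)
  expect_null(small$table)

  # unphased input is refused with guidance
  un <- ds; un$phased <- FALSE
  expect_error(region_haplotypes(reg, un, min_snps = 5), "impute")
})

test_that("haplotype frequencies sum to one and ignore sample order", {
  set.seed(221)
  for (case in 1:10) {
    haps <- list(A = random_haps(16, 8, 0.5), B = random_haps(12, 8, 0.3))
    ds <- make_ds(haps)
    reg <- list(chrom = "1", start = 1L, end = 8000L)
    ht <- region_haplotypes(reg, ds, min_snps = 2)
    if (ht$status != "ok") next
    sums <- tapply(ht$table$freq, ht$table$line, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    # permute samples: identical table after sorting
    perm <- sample(length(ds$lines))
    ds_p <- gt_subset(ds, samples = perm)
    ht_p <- region_haplotypes(reg, ds_p, min_snps = 2)
    key <- function(t) t[order(t$line, t$haplotype),
                         c("line", "haplotype", "freq", "is_major")]
    expect_equal(key(ht_p$table), key(ht$table), ignore_attr = TRUE)
  }
})

test_that("annotate_regions separates contained and nearby genes", {
  genes <- data.frame(chrom = "1",
                      start = c(120000L, 420000L, 900000L),
                      end = c(130000L, 430000L, 950000L),
                      gene = c("G1", "G2", "G3"))
  regions <- data.frame(chrom = "1",
                        start = c(100000L, 500000L, 700000L),
                        end = c(200000L, 510000L, 750000L))
  ann <- annotate_regions(regions, genes, flank = 100000)
  expect_equal(ann$contained_genes[1], "G1")
  expect_false(ann$desert[1])
  # desert region with a gene 70 kb left (signed negative distance)
  expect_true(ann$desert[2])
  expect_equal(ann$nearby_genes[2], "G2")
  expect_equal(ann$nearby_distances[2], "-70000")
  # desert with nearest gene 150 kb away -> excluded
  expect_true(ann$desert[3])
  expect_equal(ann$nearby_genes[3], "")

  set.seed(231)
  for (case in 1:30) {
    ng <- sample(1:15, 1)
    gs <- sample.int(9e5, ng)
    ge <- gs + sample(1000:50000, ng, replace = TRUE)
    genes <- data.frame(chrom = "1", start = gs, end = ge,
                        gene = paste0("g", seq_len(ng)))
    rs <- sample.int(9e5, 1)
    re <- rs + sample(1000:200000, 1)
    ann <- annotate_regions(data.frame(chrom = "1", start = rs, end = re),
                            genes, flank = 100000)
    cont <- which(gs <= re & ge >= rs)
    near <- setdiff(which(gs <= re + 1e5 & ge >= rs - 1e5), cont)
    glue <- function(i) if (length(i)) paste(paste0("g", i), collapse = ",")
                        else ""
    expect_equal(ann$n_genes, length(cont))
    expect_equal(ann$contained_genes, glue(cont))
    if (length(cont) == 0)
      expect_equal(ann$nearby_genes, glue(near))
    # contained and nearby never share a gene
    a <- strsplit(ann$contained_genes, ",")[[1]]
    b <- strsplit(ann$nearby_genes, ",")[[1]]
    expect_length(intersect(a[nzchar(a)], b[nzchar(b)]), 0)
  }
})

test_that("gene intervals load from GFF3 and BED with validation", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=gene:x1;gene_id=ABC1;Name=abc1",
    "1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=tx:x1;Parent=gene:x1",
    "2\tsrc\tgene\t5000\t9000\t.\t-\t.\tID=gene:x2;gene_id=DEF2"
  ), gff)
  g <- read_gene_intervals(gff)
  expect_length(g, 2)
  expect_setequal(g$gene, c("ABC1", "DEF2"))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tABC1", "2\t4999\t9000\tDEF2"), bed)
  b <- read_gene_intervals(bed)
  expect_equal(IRanges::start(b), c(1000L, 5000L))
  expect_setequal(b$gene, c("ABC1", "DEF2"))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tA", "1\t2000\tnope\tB"), bad)
  expect_error(read_gene_intervals(bad), "line 2")
})
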