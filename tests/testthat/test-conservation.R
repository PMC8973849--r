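gff_text <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("per-base precedence is CDS over UTR over intron across transcripts", {
  # gene 1-1000; tx1 codes 101-300; tx2 annotates 201-400 as UTR
  f <- gff_text(c(
    "chr1\ttoy\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t1000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttoy\tmRNA\t1\t1000\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\ttoy\texon\t101\t300\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\ttoy\tCDS\t101\t300\t.\t+\t0\tID=c1;Parent=t1",
    "chr1\ttoy\texon\t201\t400\t.\t+\t.\tID=e2;Parent=t2",
    "chr1\ttoy\tfive_prime_UTR\t201\t400\t.\t+\t.\tID=u1;Parent=t2",
    "chr1\ttoy\tCDS\t450\t500\t.\t+\t0\tID=c2;Parent=t2"
  ))
  reg <- classify_regions(f)
  cls_at <- function(pos0) {
    hit <- reg[reg$start <= pos0 & reg$end > pos0, ]
    hit$region_class
  }
  expect_equal(cls_at(150), "coding_exon")   # CDS only
  expect_equal(cls_at(250), "coding_exon")   # CDS in t1 beats UTR in t2
  expect_equal(cls_at(350), "utr")           # UTR only
  expect_equal(cls_at(420), "intron")        # covered by no exon
  expect_equal(cls_at(470), "coding_exon")
  # bases are partitioned: class lengths sum to the gene body
  expect_equal(sum(reg$width), 1000)
})

test_that("UTRs of non-coding transcripts do not count", {
  f <- gff_text(c(
    "chr1\ttoy\tgene\t1\t200\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttoy\tfive_prime_UTR\t51\t100\t.\t+\t.\tID=u1;Parent=t1"
  ))
  reg <- classify_regions(f)  # t1 has no CDS, so its UTR is ignored
  expect_true(all(reg$region_class == "intron"))
  expect_equal(sum(reg$width), 200)
})

test_that("identity counts matches over the full region length", {
  dir <- tempfile()
  dir.create(dir)
  maf <- file.path(dir, "t.maf")
  # 10-bp region: 5 identical aligned columns, rest mismatched
  writeLines(c(
    "##maf version=1", "",
    "a score=0",
    "s ref.chr1 0 10 + 10 ACGTACGTAC",
    "s qry.chr1 0 10 + 10 ACGTATACGT"
  ), maf)
  reg <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L,
                        region_class = "coding_exon", gene_id = "g",
                        region_id = "r1")
  out <- region_identity(maf, reg)
  expect_equal(out$aligned_matches, 5L)
  expect_equal(out$identity, 50)
  # unaligned tail contributes length but no matches
  reg2 <- dplyr::mutate(reg, end = 20L, region_id = "r2")
  out2 <- suppressWarnings(region_identity(maf, reg2))
  expect_equal(out2$identity, 25)
  # a chromosome absent from the alignment warns and scores 0
  reg3 <- dplyr::mutate(reg, chrom = "chrX")
  expect_warning(out3 <- region_identity(maf, reg3), "absent")
  expect_equal(out3$identity, 0)
})

test_that("identity is symmetric for fully aligned sequences", {
  dir <- tempfile(); dir.create(dir)
  fwd <- file.path(dir, "f.maf"); rev <- file.path(dir, "r.maf")
  s1 <- "ACGTTGCAGG"; s2 <- "ACGTACCAGG"
  writeLines(c("##maf version=1", "", "a score=0",
               sprintf("s a.chr1 0 10 + 10 %s", s1),
               sprintf("s b.chr1 0 10 + 10 %s", s2)), fwd)
  writeLines(c("##maf version=1", "", "a score=0",
               sprintf("s b.chr1 0 10 + 10 %s", s2),
               sprintf("s a.chr1 0 10 + 10 %s", s1)), rev)
  reg <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  expect_equal(region_identity(fwd, reg)$identity,
               region_identity(rev, reg)$identity)
})

test_that("soft-masked columns can be excluded from matching", {
  dir <- tempfile(); dir.create(dir)
  maf <- file.path(dir, "m.maf")
  writeLines(c("##maf version=1", "", "a score=0",
               "s ref.chr1 0 4 + 4 acGT",
               "s qry.chr1 0 4 + 4 acGT"), maf)
  reg <- tibble::tibble(chrom = "chr1", start = 0L, end = 4L)
  expect_equal(region_identity(maf, reg)$identity, 100)
  expect_equal(region_identity(maf, reg, count_softmasked = FALSE)$identity,
               50)
})

test_that("percentile of exceeding regions is a strict count", {
  expect_equal(percentile_exceeding(95, c(80, 90, 99)), 100 / 3)
  expect_equal(percentile_exceeding(99, c(80, 90, 99)), 0)  # max ties at 0
  set.seed(71)
  pop <- runif(200, 0, 100)
  f <- runif(1, 0, 100)
  expect_equal(percentile_exceeding(f, pop), 100 * sum(pop > f) / 200)
  # anti-monotone in the focal identity, bounded in [0, 100]
  vals <- vapply(c(10, 50, 90), percentile_exceeding, numeric(1),
                 population = pop)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 100))
  expect_error(percentile_exceeding(50, numeric(0)), "non-empty")
})

test_that("conservation_percentile excludes the focal region and can restrict class", {
  idt <- tibble::tibble(
    region_id = c("f", "a", "b", "c"),
    region_class = c("coding_exon", "coding_exon", "coding_exon", "utr"),
    identity = c(95, 99, 90, 99))
  out <- conservation_percentile(idt, "f", region_class = "coding_exon")
  expect_equal(out$population, 2)
  expect_equal(out$pct_exceeding, 50)
})
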