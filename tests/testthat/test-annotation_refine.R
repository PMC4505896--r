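test_that("microsatellite filter removes TEs at >= 30% union coverage", {
  te <- feature_table("c1", 100, 200, "fam")
  ms30 <- feature_table("c1", 170, 260, "ms")
  ms29 <- feature_table("c1", 171, 260, "ms")
  expect_identical(nrow(filter_microsatellite_overlap(te, ms30)), 0L)
  expect_identical(nrow(filter_microsatellite_overlap(te, ms29)), 1L)
  # no overlap: kept; union of split microsatellites counts once
  far <- feature_table("c1", 5000, 5100, "ms")
  expect_identical(nrow(filter_microsatellite_overlap(te, far)), 1L)
  two <- rbind(feature_table("c1", 100, 115, "ms"),
               feature_table("c1", 110, 125, "ms"))  # union covers 25
  expect_identical(nrow(filter_microsatellite_overlap(te, two)), 1L)
  three <- rbind(two, feature_table("c1", 190, 300, "ms"))  # union 35
  expect_identical(nrow(filter_microsatellite_overlap(te, three)), 0L)
  # different chromosome never counts
  other <- feature_table("c2", 100, 200, "ms")
  expect_identical(nrow(filter_microsatellite_overlap(te, other)), 1L)
})

test_that("same-family merging and linking follow the score rule", {
  # overlap merge
  f <- rbind(feature_table("c1", 100, 300, "fam"),
             feature_table("c1", 250, 500, "fam"))
  m <- merge_link_same_family(f)
  expect_identical(nrow(m), 1L)
  expect_identical(c(m$start, m$end), c(100L, 500L))
  # lengths 100/80 gap 20: linked (0.5*20 < 80)
  f <- rbind(feature_table("c1", 0, 100, "fam"),
             feature_table("c1", 120, 200, "fam"))
  m <- merge_link_same_family(f)
  expect_identical(nrow(m), 1L)
  expect_identical(c(m$start, m$end), c(0L, 200L))
  expect_identical(m$score, 100 + 80 - 0.5 * 20)
  # lengths 100/80 gap 200: not linked (0.5*200 > 80)
  f <- rbind(feature_table("c1", 0, 100, "fam"),
             feature_table("c1", 300, 380, "fam"))
  expect_identical(nrow(merge_link_same_family(f)), 2L)
  # different families never merge
  f <- rbind(feature_table("c1", 0, 100, "famA"),
             feature_table("c1", 50, 150, "famB"))
  expect_identical(nrow(merge_link_same_family(f)), 2L)
})

test_that("chaining agrees with exhaustive partition enumeration", {
  set.seed(11)
  for (rep in 1:60) {
    k <- sample(2:8, 1)
    lens <- sample(20:300, k, replace = TRUE)
    gaps <- sample(1:400, k - 1, replace = TRUE)
    starts <- cumsum(c(0, head(lens, -1) + gaps))
    ends <- starts + lens
    f <- feature_table("c1", starts, ends, "fam")
    got <- merge_link_same_family(f)
    want <- oracle_chain(starts, ends)
    expect_identical(got$start, as.integer(want$start))
    expect_identical(got$end, as.integer(want$end))
  }
})

test_that("cross-family resolution truncates by decreasing length", {
  # partial overlap: shorter B loses the contested region
  f <- rbind(feature_table("c1", 0, 1000, "famX"),
             feature_table("c1", 500, 1400, "famY"))
  r <- resolve_cross_family_overlaps(f)
  expect_identical(r$start[r$family == "famY"], 1000L)
  expect_identical(r$end[r$family == "famY"], 1400L)
  # nested shorter feature is dropped entirely
  f <- rbind(feature_table("c1", 0, 1000, "famX"),
             feature_table("c1", 200, 800, "famY"))
  r <- resolve_cross_family_overlaps(f)
  expect_identical(r$family, "famX")
  # disjoint features pass through
  f <- rbind(feature_table("c1", 0, 100, "famX"),
             feature_table("c1", 500, 900, "famY"))
  expect_identical(nrow(resolve_cross_family_overlaps(f)), 2L)
  # equal lengths: leftmost-first tie-break keeps the left feature whole
  f <- rbind(feature_table("c1", 100, 300, "famB"),
             feature_table("c1", 200, 400, "famA"))
  r <- resolve_cross_family_overlaps(f)
  expect_identical(r$end[r$family == "famB"], 300L)
  expect_identical(r$start[r$family == "famA"], 300L)
})

test_that("resolution output never overlaps and never grows", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    starts <- sample(0:2000, n)
    lens <- sample(50:600, n, replace = TRUE)
    f <- feature_table("c1", starts, starts + lens,
                       sample(paste0("fam", 1:4), n, replace = TRUE))
    f <- merge_link_same_family(f)
    r <- resolve_cross_family_overlaps(f)
    if (nrow(r) > 1) {
      r <- r[order(r$start), ]
      expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    }
    # covered bases cannot exceed the input union
    cov_in <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(f$start + 1L, f$end))))
    cov_out <- sum(r$end - r$start)
    expect_lte(cov_out, cov_in)
    # merge/link never shrinks a family's span; resolve never extends one
    expect_gte(max(r$end), min(f$start) + 1)
    expect_lte(max(r$end), max(f$end))
    expect_gte(min(r$start), min(f$start))
  }
})

test_that("minimum-length filter is inclusive at 100 bp", {
  f <- rbind(feature_table("c1", 0, 99, "fam"),
             feature_table("c1", 200, 300, "fam"),
             feature_table("c1", 400, 501, "fam"))
  kept <- filter_min_length(f)
  expect_identical(kept$end - kept$start, c(100L, 101L))
  expect_identical(nrow(filter_min_length(f[0, ])), 0L)
})

test_that("orthologous-block linking honours the 20-kb rule on both sides", {
  mk <- function(sA, eA, sB, eB)
    data.frame(chromA = "2L", startA = sA, endA = eA,
               chromB = "c2L", startB = sB, endB = eB)
  # gaps (15000, 18000): merged
  b <- rbind(mk(0, 10000, 0, 11000), mk(25000, 30000, 29000, 33000))
  l <- link_orthologous_blocks(b)
  expect_identical(nrow(l), 1L)
  expect_identical(c(l$startA, l$endA, l$startB, l$endB),
                   c(0, 30000, 0, 33000))
  # gaps (15000, 25000): one side exceeds, not merged
  b <- rbind(mk(0, 10000, 0, 11000), mk(25000, 30000, 36000, 40000))
  expect_identical(nrow(link_orthologous_blocks(b)), 2L)
  # single block unchanged; transitivity chains three blocks
  one <- mk(5, 10, 5, 10)
  expect_identical(link_orthologous_blocks(one), one)
  b <- rbind(mk(0, 10, 0, 10), mk(5000, 6000, 5000, 6000),
             mk(11000, 12000, 11000, 12000))
  expect_identical(nrow(link_orthologous_blocks(b)), 1L)
  # different chromosome pairs never merge
  b <- rbind(mk(0, 10, 0, 10),
             data.frame(chromA = "3R", startA = 15, endA = 20,
                        chromB = "c2L", startB = 15, endB = 20))
  expect_identical(nrow(link_orthologous_blocks(b)), 2L)
})

test_that("the full refinement pipeline is idempotent on the fixture", {
  fx <- synth_annotation_fixture()
  r1 <- refine_annotation(fx$tes, fx$microsats)
  r2 <- refine_annotation(r1, fx$microsats)
  expect_identical(r1[c("chrom", "start", "end", "family", "order")],
                   r2[c("chrom", "start", "end", "family", "order")])
  lb1 <- link_orthologous_blocks(fx$blocks)
  lb2 <- link_orthologous_blocks(lb1)
  expect_identical(lb1, lb2)
})

test_that("GFF3 and block TSV round-trips preserve coordinates and labels", {
  fx <- synth_annotation_fixture()
  gff <- tempfile(fileext = ".gff3")
  write_te_gff(fx$tes, gff)
  back <- read_te_gff(gff)
  expect_identical(back$chrom, fx$tes$chrom)
  expect_identical(back$start, fx$tes$start)
  expect_identical(back$end, fx$tes$end)
  expect_identical(back$family, fx$tes$family)
  expect_identical(back$order, fx$tes$order)
  tsv <- tempfile(fileext = ".tsv")
  write_blocks(fx$blocks, tsv)
  bb <- read_blocks(tsv)
  expect_identical(bb$startA, as.integer(fx$blocks$startA))
  expect_identical(bb$endB, as.integer(fx$blocks$endB))
})

test_that("BED round-trip preserves coordinates and family names", {
  fx <- synth_annotation_fixture()
  bed <- tempfile(fileext = ".bed")
  write_te_bed(fx$tes, bed)
  back <- read_te_bed(bed)
  expect_identical(back$chrom, fx$tes$chrom)
  expect_identical(back$start, fx$tes$start)
  expect_identical(back$end, fx$tes$end)
  expect_identical(back$family, fx$tes$family)
})
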