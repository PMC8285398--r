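# Interval I/O and set algebra.

test_that("BED reading parses 0-based half-open records and flags bad lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t10\t20", "# comment", "chr2\t0\t5\tA\t0\t-"),
             f)
  gr <- read_bed(f)
  expect_equal(df_gr(gr),
               data.frame(chrom = c("chr1", "chr2"), start = c(10L, 0L),
                          end = c(20L, 5L)))
  writeLines(character(), f)
  expect_length(read_bed(f), 0)

  writeLines("chr1\t20\t10", f)
  expect_error(read_bed(f), "line 1")

  writeLines(c("chr1\t0\t10", "chr1\tx"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("BED round-trip is exact and genome bounds are enforced", {
  set.seed(1)
  iv <- random_intervals(50, 10000)
  gr <- gr0("chrT", iv$start, iv$end, toy_genome)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, f)
  back <- read_bed(f, toy_genome)
  expect_equal(df_gr(back), df_gr(gr))
  expect_error(gr0("chrX", 0, 10, toy_genome), "absent from genome")
  expect_error(gr0("chrT", 0, 20000, toy_genome), "exceeds chromosome length")
})

test_that("intersect honours select/segment modes and half-open bookends", {
  a <- gr0("chrT", 0, 10)
  b <- gr0("chrT", 5, 20)
  expect_equal(df_gr(interval_intersect(a, b, "select")),
               data.frame(chrom = "chrT", start = 0L, end = 10L))
  expect_equal(df_gr(interval_intersect(a, b, "segment")),
               data.frame(chrom = "chrT", start = 5L, end = 10L))
  bookend <- gr0("chrT", 10, 20)
  expect_length(interval_intersect(a, bookend, "select"), 0)
  expect_length(interval_intersect(a, bookend, "segment"), 0)
})

test_that("subtract removes covered bases, splits elements, keeps metadata", {
  a <- gr0("chrT", 0, 100)
  S4Vectors::mcols(a)$name <- "E"
  out <- interval_subtract(a, gr0("chrT", 40, 60))
  expect_equal(df_gr(out),
               data.frame(chrom = c("chrT", "chrT"), start = c(0L, 60L),
                          end = c(40L, 100L)))
  expect_equal(S4Vectors::mcols(out)$name, c("E", "E"))
  expect_equal(df_gr(interval_subtract(a, GenomicRanges::GRanges())),
               df_gr(a))
  expect_length(interval_subtract(a, a), 0)
  ## element-level variant kills whole elements
  expect_length(interval_subtract(a, gr0("chrT", 40, 60), element = TRUE), 0)
})

test_that("merge collapses overlaps and bookends, honours the gap parameter", {
  a <- gr0("chrT", c(10, 15), c(20, 30))
  expect_equal(df_gr(interval_merge(a)),
               data.frame(chrom = "chrT", start = 10L, end = 30L))
  b <- gr0("chrT", c(0, 10), c(10, 20))
  expect_equal(df_gr(interval_merge(b)),
               data.frame(chrom = "chrT", start = 0L, end = 20L))
  cc <- gr0("chrT", c(0, 12), c(10, 20))
  expect_equal(nrow(df_gr(interval_merge(cc))), 2)
  expect_equal(df_gr(interval_merge(cc, gap = 2)),
               data.frame(chrom = "chrT", start = 0L, end = 20L))
  expect_error(interval_merge(a, gap = -1), "non-negative")
})

test_that("union concatenates without collapsing; extend clips to genome", {
  u <- interval_union(gr0("chrT", 0, 10), gr0("chrT", 5, 15))
  expect_length(u, 2)
  expect_equal(df_gr(interval_merge(u)),
               data.frame(chrom = "chrT", start = 0L, end = 15L))
  expect_length(interval_union(GenomicRanges::GRanges(),
                               GenomicRanges::GRanges()), 0)

  e <- interval_extend(gr0("chrT", 5000, 6000, toy_genome), 1000)
  expect_equal(df_gr(e), data.frame(chrom = "chrT", start = 4000L, end = 7000L))
  clipped <- interval_extend(gr0("chrT", 500, 600, toy_genome), 1000)
  expect_equal(df_gr(clipped),
               data.frame(chrom = "chrT", start = 0L, end = 1600L))
  expect_equal(df_gr(interval_extend(e, 0)), df_gr(e))
})

test_that("distance_to_nearest uses gap semantics and leftmost tie-break", {
  q <- gr0("chrT", 0, 10)
  expect_equal(distance_to_nearest(q, gr0("chrT", 5, 20))$distance, 0)
  expect_equal(distance_to_nearest(q, gr0("chrT", 25, 30))$distance, 15)
  ## equidistant subjects: leftmost reported
  subj <- gr0("chrT", c(30, 71), c(40, 81))
  qq <- gr0("chrT", 55, 56)  # 15 bp gap to [30,40) and to [71,81)
  res <- distance_to_nearest(qq, subj)
  expect_equal(res$distance, 15)
  expect_equal(res$nearest, 1L)
  expect_warning(res2 <- distance_to_nearest(q, GenomicRanges::GRanges()),
                 "empty subject")
  expect_true(is.na(res2$distance))
})

test_that("TSS window filter removes proximal elements, strand-ignored", {
  tss <- tss_df(6000)
  expect_length(tss_window_filter(gr0("chrT", 3000, 4000), tss, 5000), 0)
  expect_length(tss_window_filter(gr0("chrT", 20000, 21000), tss, 5000), 1)
  ## halfwidth 0: only elements containing the TSS base go
  expect_length(tss_window_filter(gr0("chrT", 5990, 6010), tss, 0), 0)
  expect_length(tss_window_filter(gr0("chrT", 6010, 6020), tss, 0), 1)
})

test_that("signal aggregation bins base-weighted means around midpoints", {
  regions <- gr0("chrT", c(1000, 5000), c(2000, 5400))
  flat <- gr0("chrT", 0, 10000)
  S4Vectors::mcols(flat)$score <- 2
  prof <- aggregate_signal(flat, regions, halfwidth = 500, nbins = 4)
  expect_equal(prof$profile, matrix(2, 2, 4))
  expect_equal(prof$means, rep(2, 4))

  empty <- gr0("chrT", numeric(), numeric())
  S4Vectors::mcols(empty)$score <- numeric()
  expect_equal(aggregate_signal(empty, regions, 500, 4)$profile,
               matrix(0, 2, 4))

  ## value 4 on the left half of the window only -> profile (4, 0)
  left <- gr0("chrT", 1000, 1500)  # window of region 1 is [1000, 2000)
  S4Vectors::mcols(left)$score <- 4
  prof2 <- aggregate_signal(left, regions[1], halfwidth = 500, nbins = 2)
  expect_equal(prof2$profile[1, ], c(4, 0))
})

test_that("set algebra matches the per-base oracle on random instances", {
  set.seed(42)
  L <- 10000
  for (rep in 1:60) {
    a <- random_intervals(sample(1:15, 1), L)
    b <- random_intervals(sample(1:15, 1), L)
    ga <- gr0("chrT", a$start, a$end)
    gb <- gr0("chrT", b$start, b$end)
    expect_equal(df_gr(interval_intersect(ga, gb, "segment"))[-1],
                 bf_segment_intersect(a, b, L), ignore_attr = TRUE)
    expect_equal(df_gr(interval_subtract(ga, gb))[-1],
                 bf_subtract_bases(a, b, L), ignore_attr = TRUE)
    gap <- sample(0:20, 1)
    expect_equal(df_gr(interval_merge(ga, gap))[-1],
                 bf_merge(a, L, gap), ignore_attr = TRUE)
  }
})

test_that("algebra invariants hold: idempotence, identity, base coverage", {
  set.seed(7)
  for (rep in 1:20) {
    a <- random_intervals(10, 10000)
    ga <- gr0("chrT", a$start, a$end)
    m1 <- interval_merge(ga)
    expect_equal(df_gr(interval_merge(m1)), df_gr(m1))
    expect_equal(df_gr(interval_subtract(ga, GenomicRanges::GRanges())),
                 df_gr(ga))
    seg <- interval_intersect(ga, ga, "segment")
    expect_equal(df_gr(seg), df_gr(m1))
  }
})
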