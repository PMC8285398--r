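# Loop lists and topology analytics.

mk_loops <- function(chrom, s1, e1, s2, e2, p = 0.001, q = p * 2, pet = 10) {
  f <- tempfile(fileext = ".bedpe")
  on.exit(unlink(f))
  writeLines(paste(chrom, s1, e1, chrom, s2, e2,
                   rep_len(pet, length(s1)), rep_len(p, length(s1)),
                   rep_len(q, length(s1)), sep = "\t"), f)
  read_bedpe(f, col_map = list(pet = 7, p = 8, q = 9))
}

test_that("BEDPE reading canonicalizes anchors, rejects trans and overlaps", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t0\t10000\tchr1\t50000\t60000\t5\t0.001\t0.002",
               "chr1\t90000\t95000\tchr1\t20000\t25000\t4\t0.2\t0.4",
               "chr1\t0\t10000\tchr2\t0\t10000\t3\t0.5\t0.9"), f)
  expect_message(loops <- read_bedpe(f, col_map = list(pet = 7, p = 8, q = 9)),
                 "1 trans pair")
  expect_equal(nrow(loops), 2)
  ## reversed anchors were swapped into canonical order
  expect_true(all(loops$start1 < loops$start2))
  expect_equal(loop_sizes(loops), c(50000, 70000))
  expect_equal(loops$pet_count, c(5, 4))
  writeLines("chr1\t0\t10000\tchr1\t5000\t15000\t1\t0.1\t0.2", f)
  expect_error(read_bedpe(f), "anchors overlap")
})

test_that("significance filtering is inclusive on the chosen column", {
  loops <- mk_loops("chr1", c(0, 0, 0), c(5000, 5000, 5000),
                    c(1e5, 2e5, 3e5), c(1e5 + 5000, 2e5 + 5000, 3e5 + 5000),
                    p = c(0.005, 0.02, 0.5), q = c(0.01, 0.2, 0.9))
  expect_equal(nrow(filter_loops(loops, max_p = 0.01)), 1)
  expect_equal(nrow(filter_loops(loops, max_q = 0.1)), 1)
  expect_equal(nrow(filter_loops(loops, max_p = 1.0)), 3)
  loops$q_value <- NA_real_
  expect_error(filter_loops(loops, max_q = 0.1), "missing column")
})

test_that("loop sizes histogram into half-open bins", {
  loops <- mk_loops("chr1", c(0, 0, 0), c(2, 2, 2),
                    c(1e5, 5e5, 2e6), c(1e5 + 2, 5e5 + 2, 2e6 + 2))
  expect_equal(unname(loop_size_distribution(loops)), c(1L, 1L, 1L))
  expect_equal(unname(loop_size_distribution(loops[0, ])), c(0L, 0L, 0L))
  ## size exactly 300 kb falls in the mid-range bin
  at_edge <- mk_loops("chr1", 0, 2, 3e5, 3e5 + 2)
  expect_equal(unname(loop_size_distribution(at_edge)), c(0L, 1L, 0L))
})

test_that("partner annotation walks the hierarchy in order", {
  ## seed PE at 100 kb; partners: a TSS+PcG locus at 400 kb (TSS wins),
  ## another seed at 700 kb, a bare locus at 1 Mb
  seeds <- gr0("chr1", c(99000, 699000), c(101000, 701000))
  tss <- tss_df(400000, "chr1")
  pcg <- gr0("chr1", 395000, 405000)
  loops <- mk_loops("chr1", rep(97500, 3), rep(102500, 3),
                    c(397500, 697500, 997500), c(402500, 702500, 1002500))
  hier <- annotation_hierarchy(tss = tss, seeds = seeds, pcg = pcg)
  ann <- annotate_partner(loops, seeds, hier, anchor_ext = 10000)
  ## loop 2 is seed-seed: one contribution per orientation
  expect_equal(unname(ann$counts),
               c(1L, 2L, 0L, 1L))
  expect_equal(ann$contributions$label,
               c("promoter", "seed_element", "seed_element", "other"))
  expect_equal(ann$seed_interacting, c(TRUE, TRUE))
  expect_equal(sum(ann$counts), nrow(ann$contributions))
  ## an anchor 9 kb from the seed is selected at 10 kb extension
  far <- mk_loops("chr1", 110000, 112000, 397500, 402500)
  ann2 <- annotate_partner(far, seeds, hier, anchor_ext = 10000)
  expect_equal(nrow(ann2$contributions), 1)
  expect_equal(ann2$contributions$label, "promoter")
  ## a seed in no loop is non-interacting
  expect_false(annotate_partner(far, seeds, hier)$seed_interacting[2])
  expect_error(annotate_partner(far, seeds, list()), "empty hierarchy")
})

test_that("TAD status follows anchor midpoints; gaps leave loops unassigned", {
  tads <- gr0("chr1", c(0, 200000), c(100000, 300000))
  loops <- mk_loops("chr1", c(5000, 5000, 5000), c(15000, 15000, 15000),
                    c(45000, 245000, 145000), c(55000, 255000, 155000))
  res <- classify_tad_status(loops, tads)
  expect_equal(res$status, c("intra", "inter", "unassigned"))
  expect_equal(unname(res$fractions), c(0.5, 0.5))
  expect_error(classify_tad_status(loops, gr0("chr1", c(0, 5e4), c(1e5, 2e5))),
               "disjoint")
  ## brute-force agreement on random layouts
  set.seed(3)
  for (rep in 1:10) {
    tads_df <- data.frame(start = seq(0, 9e5, by = 1e5) + 5000)
    tads_df$end <- tads_df$start + sample(4e4:9e4, 10)
    tgr <- gr0("chr1", tads_df$start, tads_df$end)
    m1 <- sample(0:1e6, 20); m2 <- m1 + sample(5e4:3e5, 20)
    lp <- mk_loops("chr1", m1 - 100, m1 + 100, m2 - 100, m2 + 100)
    got <- classify_tad_status(lp, tgr)$status
    tad_idx <- function(x) {
      hit <- which(tads_df$start <= x & x < tads_df$end)
      if (length(hit) == 0) NA_integer_ else hit
    }
    want <- vapply(seq_len(nrow(lp)), function(i) {
      t1 <- tad_idx(floor((lp$start1[i] + lp$end1[i]) / 2))
      t2 <- tad_idx(floor((lp$start2[i] + lp$end2[i]) / 2))
      if (is.na(t1) || is.na(t2)) "unassigned"
      else if (t1 == t2) "intra" else "inter"
    }, character(1))
    expect_equal(got, want)
    st <- classify_tad_status(lp, tgr)$status
    expect_equal(sum(st == "intra") + sum(st == "inter") +
                   sum(st == "unassigned"), nrow(lp))
  }
})

test_that("loop-set overlap requires both extended anchors to match", {
  a <- mk_loops("chr1", c(0, 5e5), c(10000, 5e5 + 1e4),
                c(2e5, 9e5), c(2e5 + 1e4, 9e5 + 1e4))
  expect_equal(loopset_overlap(a, a, 10000)$pct, 100)
  shift <- function(loops, by) {
    loops$start1 <- loops$start1 + by; loops$end1 <- loops$end1 + by
    loops$start2 <- loops$start2 + by; loops$end2 <- loops$end2 + by
    loops
  }
  expect_equal(loopset_overlap(a, shift(a, 25000), 10000)$pct, 0)
  expect_equal(loopset_overlap(a, shift(a, 5000), 10000)$pct, 100)
  ## one anchor matching is not enough
  half <- a
  half$start2 <- half$start2 + 50000; half$end2 <- half$end2 + 50000
  expect_equal(loopset_overlap(a, half, 10000)$pct, 0)
})

test_that("interaction summaries count distal PEs and promoter partners", {
  tss <- tss_df(c(500000, 800000), "chr1")
  pes <- gr0("chr1", c(99000, 505000, 300000), c(101000, 506000, 301000))
  ## PE1 loops to a promoter; PE2 is TSS-proximal (excluded); PE3 has no loop
  loops <- mk_loops("chr1", 97500, 102500, 497500, 502500)
  s <- interaction_summary(loops, pes, tss)
  expect_equal(s$n_distal, 2)
  expect_equal(s$n_interacting, 1)
  expect_equal(s$pct_interacting, 50)
  expect_equal(s$pct_promoter, 100)
  expect_equal(s$interacting_tss, "g001")
})
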