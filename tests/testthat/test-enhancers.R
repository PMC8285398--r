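# Rule-based enhancer classification.
#
# The toy locus used below places five regions on a 100 kb chromosome:
#   A at 20 kb: ATAC + K4me1 + K27me3         -> poised
#   B at 40 kb: ATAC + K4me1 + K27me3 + K27ac -> killed by subtraction
#   C at 60 kb: ATAC + K4me1 + K27ac          -> active
#   D at 80 kb: K4me1 only                    -> primed
#   E at  4 kb: ATAC + K4me1 + K27me3, 3 kb from the TSS -> TSS-filtered
toy <- local({
  g <- c(chrT = 100000)
  at <- function(pos, w = 1000) list(s = pos - w / 2, e = pos + w / 2)
  pos <- c(A = 20000, B = 40000, C = 60000, D = 80000, E = 4000)
  reg <- lapply(pos, at)
  pk <- function(which) {
    s <- vapply(reg[which], `[[`, numeric(1), "s")
    e <- vapply(reg[which], `[[`, numeric(1), "e")
    mk_peaks("chrT", s, e, fold = 10, q = 0.001, genome = g)
  }
  marks <- list(ctx1 = list(ATAC = pk(c("A", "B", "C", "E")),
                            H3K4me1 = pk(c("A", "B", "C", "D", "E")),
                            H3K27me3 = pk(c("A", "B", "E")),
                            H3K27ac = pk(c("B", "C"))))
  list(genome = g, marks = marks, tss = tss_df(1000, "chrT"), pos = pos)
})

test_that("poised calls require open chromatin with both marks, no K27ac,
          distal from TSS", {
  poised <- call_poised_invitro(toy$marks, toy$tss)
  expect_equal(df_gr(poised),
               data.frame(chrom = "chrT", start = 19500L, end = 20500L))
  expect_equal(S4Vectors::mcols(poised)$enhancer_class, "poised")
  expect_equal(S4Vectors::mcols(poised)$source_contexts, "ctx1")
  ## B is absent (H3K27ac overlap), E is absent (3 kb from the TSS)
})

test_that("active and primed rules mirror the poised rule correctly", {
  active <- call_active_invitro(toy$marks, toy$tss)
  expect_equal(df_gr(active),
               data.frame(chrom = "chrT", start = 59500L, end = 60500L))
  primed <- call_primed_invitro(toy$marks, toy$tss)
  ## D only: A/B/E carry K27me3, B/C carry K27ac (extended +/-1 kb)
  expect_equal(df_gr(primed),
               data.frame(chrom = "chrT", start = 78500L, end = 81500L))
  expect_warning(out <- call_poised_invitro(list(), toy$tss, contexts = character()),
                 "no contexts")
  expect_length(out, 0)
})

test_that("a K27ac peak in any context removes a poised call", {
  marks2 <- toy$marks
  marks2$ctx2 <- toy$marks$ctx1
  ## context 2 adds K27ac over region A
  marks2$ctx2$H3K27ac <- mk_peaks("chrT", c(39500, 59500, 19500),
                                  c(40500, 60500, 20500),
                                  fold = 10, q = 0.001, genome = toy$genome)
  poised <- call_poised_invitro(marks2, toy$tss)
  expect_length(poised, 0)
})

test_that("class overlap resolution removes poised conflicts, favors active", {
  g <- toy$genome
  poised <- gr0("chrT", c(1000, 5000), c(2000, 6000), g)
  active <- gr0("chrT", c(1500, 9000), c(2500, 9500), g)
  primed <- gr0("chrT", c(5500, 9200, 20000), c(6500, 9400, 20500), g)
  res <- resolve_class_overlaps(poised, active, primed)
  expect_length(res$poised, 0)              # both overlap active or primed
  ## active element overlapping poised is removed from both;
  ## active element overlapping only primed survives as active
  expect_equal(df_gr(res$active),
               data.frame(chrom = "chrT", start = 9000L, end = 9500L))
  expect_equal(df_gr(res$primed),
               data.frame(chrom = "chrT", start = 20000L, end = 20500L))
  ## no base covered by two classes afterwards
  expect_length(interval_intersect(res$active, res$primed, "segment"), 0)
  ## disjoint inputs pass through unchanged
  res2 <- resolve_class_overlaps(gr0("chrT", 0, 100, g),
                                 gr0("chrT", 200, 300, g),
                                 gr0("chrT", 400, 500, g))
  expect_equal(vapply(res2, length, integer(1)),
               c(poised = 1L, active = 1L, primed = 1L))
})

test_that("poiact relabeling intersects replicates before overlap", {
  poised <- call_poised_invitro(toy$marks, toy$tss)
  lateA <- mk_peaks("chrT", 19500, 20500, fold = 6, q = 0.05,
                    genome = toy$genome)
  res <- call_poiact(poised, list(list(peaks = lateA, min_fold = 5,
                                       max_q = 0.1, extension = 1000)))
  expect_length(res$poiact, 1)
  expect_equal(S4Vectors::mcols(res$poiact)$enhancer_class, "poiact")
  expect_length(res$poised, 0)
  ## the same peak in only 1 of 2 replicates does not fire
  empty_rep <- mk_peaks("chrT", 90000, 91000, fold = 6, q = 0.05,
                        genome = toy$genome)
  res2 <- call_poiact(poised, list(list(peaks = list(lateA, empty_rep),
                                        min_fold = 5, max_q = 0.1,
                                        extension = 1000)))
  expect_length(res2$poiact, 0)
  expect_length(res2$poised, 1)
  ## empty later set: all remain poised
  res3 <- call_poiact(poised, list())
  expect_length(res3$poiact, 0)
  expect_length(res3$poised, 1)
})

test_that("in vivo rule uses p-values for histones and FC >= 5 for ATAC", {
  g <- c(chrT = 100000)
  atac <- mk_peaks("chrT", 20000, 21000, fold = 6, q = 0.01, p = 0.001,
                   genome = g)
  k27me3 <- mk_peaks("chrT", 20200, 20800, fold = 3, q = 0.5, p = 0.005,
                     genome = g)  # would fail a q filter, passes p <= 0.01
  no_ac <- mk_peaks("chrT", numeric(), numeric(), genome = g)
  tss <- tss_df(90000, "chrT")
  calls <- call_poised_invivo(atac, k27me3, no_ac, no_ac, tss)
  expect_equal(df_gr(calls),
               data.frame(chrom = "chrT", start = 20000L, end = 21000L))
  ## overlapping in vitro K27ac union removes the call
  invitro_ac <- gr0("chrT", 20500, 21500, g)
  expect_length(call_poised_invivo(atac, k27me3, no_ac, invitro_ac, tss), 0)
  ## ATAC fold 4.5 fails FC >= 5
  weak <- mk_peaks("chrT", 20000, 21000, fold = 4.5, q = 0.01, genome = g)
  expect_length(call_poised_invivo(weak, k27me3, no_ac, no_ac, tss), 0)
})

test_that("de novo rule extends +/-2.5 kb and requires strictly >10 kb TSS
          distance", {
  g <- c(chrT = 100000)
  k27me3 <- mk_peaks("chrT", 52000, 53000, fold = 5, q = 0.01, genome = g)
  tss <- tss_df(39000, "chrT")
  ## element exactly 10 kb from the TSS base (start - pos = 10000): excluded
  at_10k <- mk_peaks("chrT", 49000, 50000, fold = 5, q = 0.01, genome = g)
  expect_length(suppressMessages(
    call_poised_denovo(at_10k, k27me3, NULL, tss)), 0)
  ## at 10,001 bp: included (K27me3 reaches through the 2.5 kb extension)
  at_10k1 <- mk_peaks("chrT", 49001, 50001, fold = 5, q = 0.01, genome = g)
  expect_message(out <- call_poised_denovo(at_10k1, k27me3, NULL, tss),
                 "subtraction step skipped")
  expect_equal(df_gr(out),
               data.frame(chrom = "chrT", start = 49001L, end = 50001L))
  ## with H3K27ac available the subtraction applies
  k27ac <- mk_peaks("chrT", 52000, 53000, fold = 5, q = 0.01, genome = g)
  expect_length(call_poised_denovo(at_10k1, k27me3, k27ac, tss), 0)
})

test_that("overlap reports format counts and two-decimal percentages", {
  g <- c(chrT = 1e6)
  a <- gr0("chrT", seq(0, 99000, by = 1000) * 10,
           seq(0, 99000, by = 1000) * 10 + 500, g)[1:100]
  b <- a[1:37]
  rep <- set_overlap_report(a, b)
  expect_equal(rep$label_a_in_b, "37.00% (37/100)")
  expect_equal(rep$label_b_in_a, "100.00% (37/37)")
  disj <- set_overlap_report(gr0("chrT", 0, 10, g), gr0("chrT", 100, 110, g))
  expect_equal(disj$pct_a_in_b, 0)
  same <- set_overlap_report(a, a)
  expect_equal(same$pct_a_in_b, 100)
})

test_that("classifier equals literal per-base rule evaluation on random toys", {
  set.seed(11)
  L <- 50000
  for (rep in 1:15) {
    marks_df <- random_mark_library(L, n_contexts = 2, n_peaks = 6)
    tss_pos <- sample(seq(5000, L - 5000), 2)
    marks <- marks_df_to_library(marks_df, genome = c(chrT = L))
    tss <- tss_df(tss_pos)
    for (cls in c("poised", "active")) {
      got <- if (cls == "poised") call_poised_invitro(marks, tss) else
        call_active_invitro(marks, tss)
      want <- bf_call_class(marks_df, tss_pos, L, cls)
      expect_equal(df_gr(got)[-1], want, ignore_attr = TRUE)
    }
  }
})

test_that("raising a fold threshold never increases the number of calls", {
  set.seed(23)
  L <- 50000
  marks_df <- random_mark_library(L, n_contexts = 2, n_peaks = 10)
  marks <- marks_df_to_library(marks_df, genome = c(chrT = L))
  tss <- tss_df(c(10000, 30000))
  folds <- c(1, 2, 4, 8)
  n_calls <- vapply(folds, function(f) {
    p <- calling_params()
    p$min_fold$ATAC <- f
    length(call_poised_invitro(marks, tss, p))
  }, integer(1))
  expect_true(all(diff(n_calls) <= 0))
})
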