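# Contact matrices, balancing, pileups and loopiness.

coo_file <- function(lines) {
  f <- tempfile(fileext = ".coo")
  writeLines(lines, f)
  f
}

test_that("COO reading canonicalizes symmetry and sums duplicates", {
  f <- coo_file(c("#resolution=1000", "0\t1\t5", "1\t0\t3", "2\t2\t4"))
  m <- read_coo(f, chrom_length = 10000, resolution = 5000)
  expect_equal(m$resolution, 1000)  # header wins
  expect_equal(m$n_bins, 10)
  expect_equal(as.matrix(m$mat)[1, 2], 8)
  expect_equal(as.matrix(m$mat)[2, 1], 8)
  expect_equal(as.matrix(m$mat)[3, 3], 4)
  unlink(f)
  f2 <- coo_file(character())
  m2 <- read_coo(f2, chrom_length = 10000, resolution = 1000)
  expect_equal(sum(m2$mat), 0)
  unlink(f2)
  expect_error(contact_matrix(data.frame(bin1 = 999, bin2 = 0, count = 1),
                              n_bins = 10), "out of range")
  ## write/read round trip
  ct <- contact_matrix(data.frame(bin1 = c(0, 3), bin2 = c(2, 3),
                                  count = c(7.5, 2)), n_bins = 5,
                       resolution = 2000)
  f3 <- tempfile(); write_coo(ct, f3)
  back <- read_coo(f3, chrom_length = 10000)
  expect_equal(as.matrix(back$mat), as.matrix(ct$mat))
  unlink(f3)
})

test_that("coverage normalization fixes marginals and masks empty bins", {
  ## equal marginals: matrix unchanged
  m <- contact_matrix(data.frame(bin1 = c(0, 1, 0), bin2 = c(1, 2, 2),
                                 count = c(1, 1, 1)), n_bins = 3)
  cn <- coverage_normalize(m)
  expect_equal(as.matrix(cn$mat), as.matrix(m$mat))
  ## doubling every entry doubles marginals but not the relative weights, so
  ## the normalized matrix scales by the same factor (pileup ratios unchanged)
  m2 <- m; m2$mat <- m$mat * 2
  cn2 <- coverage_normalize(m2)
  expect_equal(as.matrix(cn2$mat), 2 * as.matrix(cn$mat))
  expect_equal(cn2$weights, cn$weights)
  ## a zero-coverage bin is masked
  m3 <- contact_matrix(data.frame(bin1 = 0, bin2 = 1, count = 4), n_bins = 3)
  cn3 <- coverage_normalize(m3)
  expect_true(is.na(cn3$weights[3]))
  expect_error(coverage_normalize(
    contact_matrix(data.frame(bin1 = integer(), bin2 = integer(),
                              count = numeric()), n_bins = 3)), "all-zero")
})

test_that("KR balancing reproduces closed-form weights and unit row sums", {
  m <- contact_matrix(data.frame(bin1 = c(0, 0, 1), bin2 = c(0, 1, 1),
                                 count = c(2, 1, 2)), n_bins = 2)
  b <- kr_balance(m)
  expect_equal(b$weights, rep(1 / sqrt(3), 2), tolerance = 1e-6)
  expect_equal(Matrix::rowSums(b$mat), c(1, 1), tolerance = 1e-6)
  ## diagonal matrix diag(4, 9) -> weights (1/2, 1/3)
  d <- contact_matrix(data.frame(bin1 = c(0, 1), bin2 = c(0, 1),
                                 count = c(4, 9)), n_bins = 2)
  bd <- kr_balance(d)
  expect_equal(bd$weights, c(1 / 2, 1 / 3), tolerance = 1e-6)
  ## an isolated zero bin is masked, the rest balanced
  z <- contact_matrix(data.frame(bin1 = c(0, 0, 1), bin2 = c(0, 1, 1),
                                 count = c(2, 1, 2)), n_bins = 3)
  bz <- kr_balance(z)
  expect_true(is.na(bz$weights[3]))
  expect_equal(Matrix::rowSums(bz$mat)[1:2], c(1, 1), tolerance = 1e-6)
})

test_that("KR weights are scale-invariant and row sums converge on random
          matrices", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    A <- matrix(runif(n * n, 0.1, 5), n, n)
    A <- (A + t(A)) / 2
    idx <- which(upper.tri(A, diag = TRUE), arr.ind = TRUE)
    m <- contact_matrix(data.frame(bin1 = idx[, 1] - 1, bin2 = idx[, 2] - 1,
                                   count = A[idx]), n_bins = n)
    b <- kr_balance(m, tol = 1e-8)
    expect_lt(max(abs(Matrix::rowSums(b$mat) - 1)), 1e-8)
    ## multiplying A by a constant rescales weights by 1/sqrt(c)
    m2 <- m; m2$mat <- m$mat * 4
    b2 <- kr_balance(m2, tol = 1e-10)
    expect_equal(b2$weights * 2, b$weights, tolerance = 1e-5)
  }
})

test_that("loopiness is center over mean corners with missing handling", {
  expect_equal(loopiness(matrix(1, 5, 5)), 1.0)
  W <- matrix(2, 5, 5); W[3, 3] <- 10
  expect_equal(loopiness(W), 5.0)
  W2 <- matrix(0, 3, 3)
  W2[c(1, 3), c(1, 3)] <- c(1, 3, 2, 4)
  W2[2, 2] <- 5
  expect_equal(loopiness(W2), 2.0)
  ## rescaling the window leaves loopiness unchanged
  expect_equal(loopiness(W * 17), loopiness(W))
  ## missing corners drop out of the mean; all-missing corners -> NA
  W3 <- matrix(2, 5, 5); W3[3, 3] <- 10
  W3[1, 1] <- NA
  expect_equal(loopiness(W3), 5.0)
  W4 <- matrix(NA_real_, 5, 5); W4[3, 3] <- 1
  expect_true(is.na(loopiness(W4)))
  ## corner blocks of size 2
  W5 <- matrix(1, 5, 5); W5[3, 3] <- 4
  expect_equal(loopiness(W5, corner_size = 2), 4.0)
})

## deterministic decay matrix builder (expected counts, no noise)
decay_matrix <- function(n, alpha = 1, C = 1000, res = 5000,
                         enrich = NULL, factor = 1) {
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1] - 1; j <- idx[, 2] - 1
  x <- C / (1 + (j - i))^alpha
  if (!is.null(enrich)) {
    key <- paste(enrich$b1, enrich$b2)
    hit <- match(paste(i, j), key)
    x[!is.na(hit)] <- x[!is.na(hit)] * factor
  }
  contact_matrix(data.frame(bin1 = i, bin2 = j, count = x), n_bins = n,
                 resolution = res)
}

test_that("pileups on a pure decay matrix are flat near 1; planted centers
          are recovered", {
  n <- 240; res <- 5000; w <- 10  # 50 kb half-width windows
  set.seed(4)
  b1 <- sample(30:80, 40, replace = TRUE)
  b2 <- b1 + sample(60:120, 40, replace = TRUE)
  pairs <- data.frame(pos1 = (b1 + 0.5) * res, pos2 = (b2 + 0.5) * res)
  flat <- decay_matrix(n, C = 1000, res = res)
  pu <- pileup(flat, pairs, halfwidth = w * res, normalization = "expected")
  expect_equal(pu$n_pairs_used, 40)
  expect_lt(max(abs(pu$mean_window - 1)), 0.05)
  expect_equal(pu$loopiness, 1, tolerance = 0.05)
  ## a 5-fold planted center appears as ~5 in the pileup center
  enr <- decay_matrix(n, C = 1000, res = res,
                      enrich = data.frame(b1 = b1, b2 = b2), factor = 5)
  pu5 <- pileup(enr, pairs, halfwidth = w * res,
                normalization = "expected")
  expect_equal(pu5$loopiness, 5, tolerance = 0.15 * 5)
  ## single pair whose snippet equals the control: all-ones window
  one <- pileup(flat, pairs[1, , drop = FALSE], halfwidth = w * res,
                normalization = "expected")
  expect_lt(max(abs(one$mean_window - 1)), 0.05)
})

test_that("edge pairs are skipped and counted; zero usable pairs error", {
  n <- 100; res <- 5000
  m <- decay_matrix(n, res = res)
  pairs <- data.frame(pos1 = c(2, 50, 80) * res, pos2 = c(30, 85, 99) * res)
  pu <- pileup(m, pairs, halfwidth = 10 * res)
  expect_equal(pu$n_pairs_used, 1)
  expect_equal(pu$n_skipped, 2)
  expect_error(pileup(m, pairs[c(1, 3), ], halfwidth = 10 * res),
               "zero usable pairs")
})

test_that("shift-normalized and expected-normalized pileups agree on
          loop-free matrices", {
  n <- 240; res <- 5000
  set.seed(8)
  b1 <- sample(40:90, 30, replace = TRUE)
  b2 <- b1 + sample(60:100, 30, replace = TRUE)
  pairs <- data.frame(pos1 = (b1 + 0.5) * res, pos2 = (b2 + 0.5) * res)
  m <- decay_matrix(n, res = res)
  pe <- pileup(m, pairs, halfwidth = 10 * res, normalization = "expected")
  ps <- pileup(m, pairs, halfwidth = 10 * res, normalization = "shifts",
               n_shifts = 10, seed = 42)
  expect_equal(ps$loopiness, pe$loopiness, tolerance = 0.1)
  ## seeded shifts are reproducible
  ps2 <- pileup(m, pairs, halfwidth = 10 * res, normalization = "shifts",
                n_shifts = 10, seed = 42)
  expect_identical(ps$mean_window, ps2$mean_window)
})
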