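# Binned contact matrices: COO I/O, coverage normalization, Knight-Ruiz
# balancing (via symmetric iterative proportional fitting to the same fixed
# point), snippet pileups around anchor pairs, and the loopiness statistic
# (center pixel over mean corner intensity).

#' Construct a contact matrix
#'
#' @param entries data.frame with 0-based `bin1`, `bin2` and `count` columns;
#'   entries are canonicalized to the upper triangle and duplicates summed.
#' @param n_bins Number of bins on the chromosome.
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @return A `contact_matrix`: list with `chrom`, `resolution`, `n_bins`,
#'   `mat` (sparse symmetric), `weights` (`NULL` until balanced) and
#'   `normalized` flag.
#' @export
contact_matrix <- function(entries, n_bins, chrom = "chr1",
                           resolution = 5000) {
  stopifnot(n_bins >= 1, resolution >= 1)
  if (nrow(entries) > 0) {
    if (any(entries$bin1 < 0 | entries$bin2 < 0 |
            entries$bin1 >= n_bins | entries$bin2 >= n_bins)) {
      stop("format error: bin index out of range [0, ", n_bins - 1, "]")
    }
    if (any(entries$count < 0)) stop("negative contact count")
  }
  i <- pmin(entries$bin1, entries$bin2)
  j <- pmax(entries$bin1, entries$bin2)
  up <- Matrix::sparseMatrix(i = i + 1, j = j + 1, x = entries$count,
                             dims = c(n_bins, n_bins))
  full <- Matrix::forceSymmetric(up, uplo = "U")
  structure(list(chrom = chrom, resolution = resolution, n_bins = n_bins,
                 mat = full, weights = NULL, normalized = "raw"),
            class = "contact_matrix")
}

#' Read a sparse COO contact-matrix file
#'
#' Three tab-separated columns (bin1, bin2, count), 0-based bins; optional
#' `#resolution=<bp>` header; duplicate entries are summed.
#'
#' @param path Path to the COO file.
#' @param chrom_length Chromosome length in bp.
#' @param resolution Bin size in bp (overridden by a header line if present).
#' @param chrom Chromosome name.
#' @return A `contact_matrix`.
#' @export
read_coo <- function(path, chrom_length, resolution = 5000, chrom = "chr1") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  res_line <- grep("^#resolution=", hdr, value = TRUE)
  if (length(res_line) > 0) {
    resolution <- as.numeric(sub("^#resolution=", "", res_line[1]))
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  if (length(lines) == 0) {
    entries <- data.frame(bin1 = integer(), bin2 = integer(),
                          count = numeric())
  } else {
    x <- utils::read.table(text = lines, sep = "\t",
                           col.names = c("bin1", "bin2", "count"))
    entries <- x
  }
  contact_matrix(entries, n_bins, chrom, resolution)
}

#' Write a contact matrix as COO text
#'
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coo <- function(m, path) {
  tri <- Matrix::triu(m$mat)
  tm <- methods::as(methods::as(tri, "generalMatrix"), "TsparseMatrix")
  ord <- order(tm@i, tm@j)
  out <- c(sprintf("#resolution=%d", as.integer(m$resolution)),
           sprintf("%d\t%d\t%s", tm@i[ord], tm@j[ord],
                   format(tm@x[ord], trim = TRUE, scientific = FALSE,
                          digits = 15)))
  writeLines(out, path)
  invisible(path)
}

contact_marginals <- function(m) {
  Matrix::rowSums(m$mat)
}

#' Coverage-normalize a contact matrix
#'
#' Divides each entry by the product of its bins' relative marginals
#' (`w_i = m_i / mean(m over covered bins)`); zero-coverage bins are masked
#' (weight `NA`).
#'
#' @param m A raw `contact_matrix`.
#' @return The normalized `contact_matrix` (weights hold `1 / w_i`).
#' @export
coverage_normalize <- function(m) {
  marg <- contact_marginals(m)
  covered <- marg > 0
  if (!any(covered)) stop("all-zero contact matrix")
  w <- marg / mean(marg[covered])
  inv <- ifelse(covered, 1 / w, NA_real_)
  m$mat <- Matrix::Diagonal(x = ifelse(covered, inv, 0)) %*% m$mat %*%
    Matrix::Diagonal(x = ifelse(covered, inv, 0))
  m$weights <- inv
  m$normalized <- "coverage"
  m
}

#' Knight-Ruiz balance a contact matrix
#'
#' Finds positive weights `x` such that `diag(x) A diag(x)` has unit row sums
#' on covered bins, by symmetric iterative proportional fitting (the KR fixed
#' point for symmetric non-negative matrices). Zero-coverage bins are masked.
#'
#' @param m A `contact_matrix`.
#' @param tol Convergence tolerance on the maximum absolute deviation of
#'   covered-row sums from 1.
#' @param max_iter Iteration cap; exceeding it is an error carrying the last
#'   residual.
#' @return The balanced `contact_matrix`; `weights` holds `x` (`NA` on masked
#'   bins).
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 3000) {
  marg <- contact_marginals(m)
  covered <- which(marg > 0)
  if (length(covered) == 0) stop("all-zero contact matrix")
  A <- m$mat[covered, covered, drop = FALSE]
  x <- rep(1, length(covered))
  residual <- Inf
  for (it in seq_len(max_iter)) {
    r <- as.numeric(A %*% x) * x
    residual <- max(abs(r - 1))
    if (residual < tol) break
    x <- x / sqrt(r)
  }
  if (residual >= tol) {
    stop(sprintf("KR balancing did not converge in %d iterations (residual %g)",
                 max_iter, residual))
  }
  xf <- rep(NA_real_, m$n_bins)
  xf[covered] <- x
  D <- Matrix::Diagonal(x = ifelse(is.na(xf), 0, xf))
  m$mat <- D %*% m$mat %*% D
  m$weights <- xf
  m$normalized <- "kr"
  m
}

## dense matrix with masked rows/cols set to NA
dense_masked <- function(m) {
  A <- as.matrix(m$mat)
  bad <- contact_marginals(m) == 0
  if (!is.null(m$weights)) bad <- bad | is.na(m$weights)
  masked <- which(bad)
  if (length(masked) > 0) {
    A[masked, ] <- NA_real_
    A[, masked] <- NA_real_
  }
  A
}

## per-diagonal means over covered bins; exp_by_d[d + 1] = mean at separation d
expected_by_distance <- function(A) {
  n <- nrow(A)
  vapply(0:(n - 1), function(d) {
    idx <- seq_len(n - d)
    mean(A[cbind(idx, idx + d)], na.rm = TRUE)
  }, numeric(1))
}

#' Pileup of contact-matrix snippets around anchor pairs
#'
#' For each cis pair, extracts the `(2w+1) x (2w+1)` snippet centered on the
#' pair's bins (`w = halfwidth / resolution`; midpoints binned with ties to
#' the lower bin), divides it by a control, and averages the ratios pixel-wise
#' over pairs (missing pixels ignored). Controls: `"expected"` divides each
#' pixel by the matrix-wide per-diagonal mean at the pixel's separation;
#' `"shifts"` divides by the pixel-wise mean of `n_shifts` snippets shifted
#' along the diagonal by seeded uniform offsets in +/- [halfwidth,
#' 10 halfwidth]. Pairs closer than `halfwidth` to a chromosome edge are
#' skipped and counted.
#'
#' @param m A normalized `contact_matrix` (coverage or KR).
#' @param pairs data.frame with `pos1`, `pos2` (bp positions of the two loci,
#'   `pos1 < pos2`).
#' @param halfwidth Window half-width in bp (default 250 kb).
#' @param normalization `"expected"` or `"shifts"`.
#' @param n_shifts Number of shifted controls per pair.
#' @param seed Seed for the shift draws.
#' @return A `pileup_result`: `mean_window`, `n_pairs_used`, `n_skipped`,
#'   `loopiness` (single center pixel over mean of the four corner pixels).
#' @export
pileup <- function(m, pairs, halfwidth = 250000,
                   normalization = c("expected", "shifts"), n_shifts = 10,
                   seed = 1) {
  normalization <- match.arg(normalization)
  w <- as.integer(round(halfwidth / m$resolution))
  stopifnot(w >= 1, nrow(pairs) >= 1)
  A <- dense_masked(m)
  n <- nrow(A)
  b1 <- floor(pairs$pos1 / m$resolution)
  b2 <- floor(pairs$pos2 / m$resolution)
  iA <- pmin(b1, b2); iB <- pmax(b1, b2)
  ok <- iA - w >= 0 & iB + w <= n - 1
  n_skipped <- sum(!ok)
  iA <- iA[ok]; iB <- iB[ok]
  if (length(iA) == 0) stop("zero usable pairs")
  side <- 2 * w + 1
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  if (normalization == "expected") {
    expd <- expected_by_distance(A)
  } else {
    set.seed(seed)
  }
  for (k in seq_along(iA)) {
    ## +1: bins are 0-based, matrix rows 1-based
    S <- A[(iA[k] - w):(iA[k] + w) + 1, (iB[k] - w):(iB[k] + w) + 1]
    if (normalization == "expected") {
      sep <- abs(outer((iA[k] - w):(iA[k] + w), (iB[k] - w):(iB[k] + w),
                       function(i, j) j - i))
      C <- matrix(expd[sep + 1], side, side)
    } else {
      ssum <- matrix(0, side, side); scnt <- matrix(0, side, side)
      got <- 0; tries <- 0
      while (got < n_shifts && tries < 50 * n_shifts) {
        tries <- tries + 1
        s <- sample(c(-1, 1), 1) * sample(w:(10 * w), 1)
        if (iA[k] + s - w < 0 || iB[k] + s + w > n - 1) next
        got <- got + 1
        Sh <- A[(iA[k] + s - w):(iA[k] + s + w) + 1,
                (iB[k] + s - w):(iB[k] + s + w) + 1]
        use <- is.finite(Sh)
        ssum[use] <- ssum[use] + Sh[use]
        scnt[use] <- scnt[use] + 1
      }
      C <- ifelse(scnt > 0, ssum / scnt, NA_real_)
    }
    R <- S / C
    use <- is.finite(R)
    acc[use] <- acc[use] + R[use]
    cnt[use] <- cnt[use] + 1
  }
  mean_window <- ifelse(cnt > 0, acc / cnt, NA_real_)
  res <- structure(list(mean_window = mean_window,
                        n_pairs_used = length(iA),
                        n_skipped = n_skipped,
                        loopiness = NA_real_),
                   class = "pileup_result")
  res$loopiness <- loopiness(res)
  res
}

#' Loopiness of a pileup window
#'
#' Central pixel value divided by the mean of the four `corner_size` x
#' `corner_size` corner blocks; missing pixels are excluded from the corner
#' mean, and the value is missing when every corner pixel is.
#'
#' @param p A `pileup_result` or a square odd-sized numeric matrix.
#' @param corner_size Corner block edge length in pixels.
#' @return A dimensionless ratio (`NA` when undefined).
#' @export
loopiness <- function(p, corner_size = 1) {
  W <- if (methods::is(p, "pileup_result")) p$mean_window else p
  side <- nrow(W)
  stopifnot(is.matrix(W), side == ncol(W), side %% 2 == 1,
            corner_size >= 1, 2 * corner_size <= side)
  ctr <- W[(side + 1) / 2, (side + 1) / 2]
  k <- corner_size
  corners <- c(W[1:k, 1:k], W[1:k, (side - k + 1):side],
               W[(side - k + 1):side, 1:k],
               W[(side - k + 1):side, (side - k + 1):side])
  if (all(!is.finite(corners)) || !is.finite(ctr)) return(NA_real_)
  ctr / mean(corners[is.finite(corners)])
}
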