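# Independent brute-force oracles and small builders used across the suite.
# Everything here works on plain vectors and loops, deliberately avoiding the
# package's interval machinery.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

## ---- builders ------------------------------------------------------------

toy_genome <- c(chrT = 10000)

## GRanges from 0-based half-open coordinates
gr0 <- function(chrom, s0, e0, genome = NULL) {
  gr <- GenomicRanges::GRanges(rep_len(chrom, length(s0)),
                               IRanges::IRanges(s0 + 1, e0))
  if (!is.null(genome)) gr <- attach_genome(gr, genome)
  gr
}

df_gr <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr))
}

## peak GRanges with the metadata columns the callers expect
mk_peaks <- function(chrom, s0, e0, fold = 10, q = 0.01, p = q / 2,
                     genome = NULL) {
  n <- length(s0)
  gr <- gr0(rep_len(chrom, n), s0, e0, genome)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("pk%03d", seq_len(n)),
    fold_enrichment = rep_len(fold, n),
    p_value = rep_len(p, n),
    q_value = rep_len(q, n))
  gr
}

tss_df <- function(pos, chrom = "chrT", ids = NULL) {
  data.frame(gene_id = ids %||% sprintf("g%03d", seq_along(pos)),
             chrom = rep_len(chrom, length(pos)),
             position = pos, strand = "+", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_intervals <- function(n, L, max_w = 400) {
  s <- sample.int(L - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(start = s, end = pmin(L, s + w))
}

## ---- per-base interval-set oracle ---------------------------------------

## paint 0-based half-open intervals onto a logical base vector of length L
paint <- function(df, L) {
  v <- logical(L)
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i]) v[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  v
}

## maximal TRUE runs back to 0-based half-open intervals
runs_to_df <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

bf_segment_intersect <- function(a, b, L) runs_to_df(paint(a, L) & paint(b, L))
bf_subtract_bases <- function(a, b, L) {
  vb <- paint(b, L)
  out <- list()
  for (i in seq_len(nrow(a))) {
    v <- logical(L)
    v[(a$start[i] + 1):a$end[i]] <- TRUE
    out[[i]] <- runs_to_df(v & !vb)
  }
  do.call(rbind, out)
}
bf_merge <- function(a, L, gap = 0) {
  v <- paint(a, L)
  if (gap > 0) {  # close gaps <= gap between TRUE runs
    r <- runs_to_df(v)
    if (nrow(r) > 1) {
      for (i in 2:nrow(r)) {
        if (r$start[i] - r$end[i - 1] <= gap) {
          v[(r$end[i - 1] + 1):r$start[i]] <- TRUE
        }
      }
    }
  }
  runs_to_df(v)
}

## ---- enhancer-calling oracle --------------------------------------------

## literal per-base rule evaluation on a single toy chromosome
bf_call_class <- function(marks_df, tss_pos, L, class = "poised",
                          params = calling_params()) {
  ## marks_df: list(context -> list(mark -> data.frame(start,end,fold,q)))
  pass <- function(m, mark) {
    m[m$fold >= params$min_fold[[mark]] & m$q <= params$max_q[[mark]], ,
      drop = FALSE]
  }
  ext <- function(m, by) {
    if (nrow(m) == 0) return(m)
    data.frame(start = pmax(0, m$start - by), end = pmin(L, m$end + by))
  }
  need <- if (class == "poised") c("H3K27me3", "H3K4me1") else
    c("H3K27ac", "H3K4me1")
  excl <- if (class == "poised") "H3K27ac" else "H3K27me3"
  kept <- list()
  for (ctx in names(marks_df)) {
    ma <- paint(ext(pass(marks_df[[ctx]][[need[1]]], need[1]),
                    params$peak_extension), L)
    mb <- paint(ext(pass(marks_df[[ctx]][[need[2]]], need[2]),
                    params$peak_extension), L)
    atac <- pass(marks_df[[ctx]][["ATAC"]], "ATAC")
    for (i in seq_len(nrow(atac))) {
      idx <- (atac$start[i] + 1):atac$end[i]
      if (any(ma[idx]) && any(mb[idx])) {
        kept[[length(kept) + 1]] <- atac[i, c("start", "end")]
      }
    }
  }
  if (length(kept) == 0) return(data.frame(start = numeric(), end = numeric()))
  el <- do.call(rbind, kept)
  ## TSS filter (element overlaps any tss window base)
  vt <- logical(L)
  for (p in tss_pos) {
    lo <- max(0, p - params$tss_halfwidth)
    hi <- min(L, p + params$tss_halfwidth + 1)
    vt[(lo + 1):hi] <- TRUE
  }
  keep <- vapply(seq_len(nrow(el)), function(i) {
    !any(vt[(el$start[i] + 1):el$end[i]])
  }, logical(1))
  el <- el[keep, , drop = FALSE]
  ## element-level subtraction of the excluded mark union
  vx <- logical(L)
  for (ctx in names(marks_df)) {
    vx <- vx | paint(ext(pass(marks_df[[ctx]][[excl]], excl),
                         params$peak_extension), L)
  }
  keep <- vapply(seq_len(nrow(el)), function(i) {
    !any(vx[(el$start[i] + 1):el$end[i]])
  }, logical(1))
  el <- el[keep, , drop = FALSE]
  bf_merge(el, L)
}

## random mark library on one toy chromosome, straddling all thresholds
random_mark_library <- function(L, n_contexts = 2, n_peaks = 5) {
  marks_df <- list()
  for (ctx in paste0("ctx", seq_len(n_contexts))) {
    marks_df[[ctx]] <- list()
    for (mk in c("ATAC", "H3K4me1", "H3K27me3", "H3K27ac")) {
      iv <- random_intervals(n_peaks, L, max_w = 600)
      thr_f <- calling_params()$min_fold[[mk]]
      thr_q <- calling_params()$max_q[[mk]]
      marks_df[[ctx]][[mk]] <- data.frame(
        start = iv$start, end = iv$end,
        fold = thr_f * runif(n_peaks, 0.5, 2),
        q = thr_q * runif(n_peaks, 0.2, 2))
    }
  }
  marks_df
}

marks_df_to_library <- function(marks_df, chrom = "chrT", genome = NULL) {
  lapply(marks_df, function(ctx) {
    lapply(ctx, function(m) {
      gr <- mk_peaks(chrom, m$start, m$end, genome = genome)
      S4Vectors::mcols(gr)$fold_enrichment <- m$fold
      S4Vectors::mcols(gr)$q_value <- m$q
      S4Vectors::mcols(gr)$p_value <- m$q / 2
      gr
    })
  })
}

## ---- chain oracle --------------------------------------------------------

## chain text lines from a block spec; header spans derived from the blocks
chain_lines <- function(score, t_chrom, t_size, t_start, q_chrom, q_size,
                        q_strand, q_start, blocks, id = "1") {
  sizes <- blocks[, 1]; dt <- blocks[, 2]; dq <- blocks[, 3]
  t_end <- t_start + sum(sizes) + sum(dt)
  q_end <- q_start + sum(sizes) + sum(dq)
  hdr <- paste("chain", score, t_chrom, t_size, "+", t_start, t_end,
               q_chrom, q_size, q_strand, q_start, q_end, id)
  n <- nrow(blocks)
  body <- if (n > 1) paste(sizes[-n], dt[-n], dq[-n]) else character()
  c(hdr, body, as.character(sizes[n]), "")
}

## per-base walk: for each source base, its destination position (forward
## coords) or NA
bf_chain_basemap <- function(ch) {
  tpos <- ch$t_start; qpos <- ch$q_start
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(nrow(ch$blocks))) {
    size <- ch$blocks[i, "size"]
    src <- c(src, tpos:(tpos + size - 1))
    dst <- c(dst, qpos:(qpos + size - 1))
    tpos <- tpos + size + ch$blocks[i, "dt"]
    qpos <- qpos + size + ch$blocks[i, "dq"]
  }
  if (ch$q_strand == "-") dst <- ch$q_size - 1 - dst
  list(src = src, dst = dst)
}

bf_map_interval <- function(chains, chrom, s0, e0) {
  cand <- Filter(function(ch) ch$t_chrom == chrom && ch$t_start < e0 &&
                   ch$t_end > s0, chains$chains)
  if (length(cand) == 0) return(list(ratio = 0, lo = NA, hi = NA))
  ch <- cand[[which.max(vapply(cand, `[[`, numeric(1), "score"))]]
  bm <- bf_chain_basemap(ch)
  sel <- bm$src >= s0 & bm$src < e0
  if (!any(sel)) return(list(ratio = 0, lo = NA, hi = NA))
  list(ratio = sum(sel) / (e0 - s0),
       lo = min(bm$dst[sel]), hi = max(bm$dst[sel]) + 1)
}

random_chain_set <- function(L = 10000, n_chains = 3) {
  lines <- character()
  for (k in seq_len(n_chains)) {
    t_start <- sample(0:(L / 2), 1)
    n_blocks <- sample(1:5, 1)
    sizes <- sample(20:400, n_blocks, replace = TRUE)
    dt <- c(sample(0:300, n_blocks - 1, replace = TRUE), 0)
    dq <- c(sample(0:300, n_blocks - 1, replace = TRUE), 0)
    lines <- c(lines,
               chain_lines(score = sample(1e3:1e6, 1), "chrT", L, t_start,
                           "chrB", 2 * L, sample(c("+", "-"), 1),
                           q_start = sample(0:(L / 2), 1),
                           blocks = cbind(sizes, dt, dq), id = as.character(k)))
  }
  f <- tempfile(fileext = ".chain")
  writeLines(lines, f)
  on.exit(unlink(f))
  read_chain(f)
}

## ---- statistics oracles --------------------------------------------------

## two-sided Fisher p by explicit enumeration of fixed-margin tables
bf_fisher_p <- function(a, b, cc, d) {
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc; N <- m1 + m2
  supp <- max(0, n1 - m2):min(m1, n1)
  logpr <- lchoose(m1, supp) + lchoose(m2, n1 - supp) - lchoose(N, n1)
  pr <- exp(logpr)
  obs <- pr[supp == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

## two-sided exact rank-sum p by total enumeration of rank assignments
bf_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(n + m, n)
  ranks <- seq_len(n + m)
  ws <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- n * (n + m + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
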