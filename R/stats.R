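# Association statistics: CGI proximity, promoter chromatin states, Fisher
# enrichment, distribution comparisons, Polycomb-domain calling, nearest-gene
# assignment.

#' Distances between enhancers and CpG islands
#'
#' Per-enhancer nearest-CGI distance (gap semantics, ties to the leftmost CGI)
#' and the overlap fraction: the share of enhancers at distance 0, as a
#' percentage rounded to two decimals.
#'
#' @param enhancers,cgis `GRanges` on a shared genome.
#' @return A list with `distances` (bp, `NA` where no CGI shares a
#'   chromosome) and `overlap_pct`.
#' @export
cgi_distance_profile <- function(enhancers, cgis) {
  d <- distance_to_nearest(enhancers, cgis)$distance
  ov <- IRanges::overlapsAny(enhancers, cgis, ignore.strand = TRUE)
  pct <- if (length(enhancers) == 0) NA_real_ else round(100 * mean(ov), 2)
  list(distances = d, overlap_pct = pct)
}

#' Compare two value distributions (two-sided rank-sum)
#'
#' Exact rank-sum p for combined n <= 25 without ties, otherwise the normal
#' approximation with tie and continuity corrections. The fold change is the
#' ratio of means by default (medians selectable).
#'
#' @param x,y Numeric vectors, length >= 1, no infinities.
#' @param center `"mean"` or `"median"` for the fold change.
#' @return A list with `p` and `fc` (`NA` when the denominator is 0).
#' @export
compare_distributions <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(length(x) >= 1, length(y) >= 1, all(is.finite(c(x, y))))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 25) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))$p.value
  if (is.nan(p)) p <- 1  # degenerate case: all observations tied
  f <- if (center == "mean") mean else stats::median
  fc <- if (f(y) == 0) NA_real_ else f(x) / f(y)
  list(p = p, fc = fc)
}

#' Classify promoter chromatin states
#'
#' A TSS window overlapping both H3K4me3 and H3K27me3 regions is bivalent;
#' only H3K27me3 -> `k27me3_only`; only H3K4me3 -> `k4me3_only`; neither ->
#' `unmarked`. The four states partition the gene universe.
#'
#' @param tss TSS data.frame (unique `gene_id`; checked).
#' @param k4me3_peaks,k27me3_peaks `GRanges` of mark regions.
#' @param window_halfwidth Window half-width in bp (> 0); the window covers
#'   the TSS base +/- this many bases.
#' @return A data.frame `gene_id` / `state`.
#' @export
classify_promoter_states <- function(tss, k4me3_peaks, k27me3_peaks,
                                     window_halfwidth = 1000) {
  stopifnot(window_halfwidth > 0)
  if (anyDuplicated(tss$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(tss$gene_id[duplicated(tss$gene_id)]), collapse = ", "))
  }
  win <- tss_windows(tss, window_halfwidth)
  k4 <- IRanges::overlapsAny(win, k4me3_peaks, ignore.strand = TRUE)
  k27 <- IRanges::overlapsAny(win, k27me3_peaks, ignore.strand = TRUE)
  state <- ifelse(k4 & k27, "bivalent",
                  ifelse(k27, "k27me3_only",
                         ifelse(k4, "k4me3_only", "unmarked")))
  data.frame(gene_id = tss$gene_id, state = state, stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact enrichment on a 2x2 table
#'
#' Assembles the table a = category & hit, b = category & miss, c = other &
#' hit, d = other & miss over a shared gene universe. The odds ratio is the
#' sample cross-product (a d)/(b c); the two-sided p sums, over the
#' hypergeometric distribution with the observed margins, the probabilities of
#' all tables at most as probable as the observed one.
#'
#' @param hit_flags,category_flags Equal-length logical vectors, or directly
#'   the four counts via `counts = c(a, b, c, d)`.
#' @param counts Optional explicit counts (overrides the flag vectors).
#' @return A list of class `fisher2x2`: `a`,`b`,`c`,`d`, `odds_ratio`, `p`.
#' @export
enrichment_fisher <- function(hit_flags = NULL, category_flags = NULL,
                              counts = NULL) {
  if (is.null(counts)) {
    stopifnot(length(hit_flags) == length(category_flags))
    a <- sum(category_flags & hit_flags)
    b <- sum(category_flags & !hit_flags)
    cc <- sum(!category_flags & hit_flags)
    d <- sum(!category_flags & !hit_flags)
  } else {
    stopifnot(length(counts) == 4, all(counts >= 0))
    a <- counts[1]; b <- counts[2]; cc <- counts[3]; d <- counts[4]
  }
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc; n2 <- b + d
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0) {
    warning("degenerate 2x2 table (zero margin): OR missing, p = 1")
    return(structure(list(a = a, b = b, c = cc, d = d,
                          odds_ratio = NA_real_, p = 1),
                     class = "fisher2x2"))
  }
  or <- if (b * cc > 0) (a * d) / (b * cc) else if (a * d == 0) 0 else Inf
  ## support of a given fixed margins
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  supp <- lo:hi
  logp <- stats::dhyper(supp, m1, m2, n1, log = TRUE)
  obs <- logp[supp == a]
  rel_tol <- 1 + 1e-7
  p <- min(1, sum(exp(logp[exp(logp) <= exp(obs) * rel_tol])))
  structure(list(a = a, b = b, c = cc, d = d, odds_ratio = or, p = p),
            class = "fisher2x2")
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat(sprintf("2x2 table: a=%d b=%d c=%d d=%d\nOR = %.4g, two-sided p = %.4g\n",
              x$a, x$b, x$c, x$d, x$odds_ratio, x$p))
  invisible(x)
}

#' Call Polycomb (PcG) domains from EED and RING1B peaks
#'
#' Replicate peak collections per factor are intersected first (segment mode);
#' the two factors' replicate-intersected sets are then segment-intersected
#' and merged.
#'
#' @param eed_peaks,ring1b_peaks A `GRanges` or a list of replicate `GRanges`
#'   per factor.
#' @return A merged `GRanges` of PcG domains.
#' @export
call_pcg_domains <- function(eed_peaks, ring1b_peaks) {
  collapse <- function(pk) {
    if (methods::is(pk, "GRanges")) return(granges_bare(pk))
    acc <- granges_bare(pk[[1]])
    for (r in pk[-1]) acc <- interval_intersect(acc, granges_bare(r),
                                                mode = "segment")
    acc
  }
  dom <- interval_intersect(collapse(eed_peaks), collapse(ring1b_peaks),
                            mode = "segment")
  interval_merge(dom)
}

#' Assign each enhancer to its nearest gene
#'
#' Distance is measured from the enhancer midpoint to the TSS base; ties break
#' to the leftmost TSS by (chrom, position).
#'
#' @param enhancers A `GRanges`.
#' @param tss Non-empty TSS data.frame.
#' @return A data.frame with one row per enhancer: `gene_id` (`NA` when no TSS
#'   shares the chromosome) and `distance` (bp).
#' @export
assign_nearest_gene <- function(enhancers, tss) {
  stopifnot(nrow(tss) >= 1)
  s0 <- BiocGenerics::start(enhancers) - 1
  e0 <- BiocGenerics::end(enhancers)
  mid <- floor((s0 + e0) / 2)
  chrom <- as.character(GenomeInfoDb::seqnames(enhancers))
  ord <- order(tss$chrom, tss$position)
  tchrom <- tss$chrom[ord]; tpos <- tss$position[ord]; tid <- tss$gene_id[ord]
  gene <- rep(NA_character_, length(enhancers))
  dist <- rep(NA_real_, length(enhancers))
  for (i in seq_along(enhancers)) {
    sel <- which(tchrom == chrom[i])
    if (length(sel) == 0) next
    d <- abs(tpos[sel] - mid[i])
    j <- sel[which.min(d)]  # which.min takes the first (leftmost) minimum
    gene[i] <- tid[j]
    dist[i] <- min(d)
  }
  data.frame(gene_id = gene, distance = dist, stringsAsFactors = FALSE)
}
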