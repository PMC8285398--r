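# Chromatin-loop lists (BEDPE) and loop-level analytics.
#
# A loop_set is a data.frame (0-based half-open anchor coordinates, cis only,
# anchor1 left of anchor2) with optional significance columns (p_value,
# q_value) and PET counts. Loop size is the distance between anchor midpoints,
# which makes it invariant to anchor width.

loop_set <- function(df) {
  need <- c("chrom", "start1", "end1", "start2", "end2")
  stopifnot(all(need %in% names(df)))
  for (col in c("p_value", "q_value", "pet_count")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  class(df) <- c("loop_set", "data.frame")
  df
}

#' Anchor intervals of a loop set
#'
#' @param loops A `loop_set`.
#' @param which 1 or 2.
#' @param ext Symmetric extension in bp.
#' @return A `GRanges` (one range per loop).
#' @export
loop_anchors <- function(loops, which = 1, ext = 0) {
  s <- loops[[paste0("start", which)]]
  e <- loops[[paste0("end", which)]]
  GenomicRanges::GRanges(loops$chrom,
                         IRanges::IRanges(start = pmax(1, s + 1 - ext),
                                          end = e + ext))
}

#' Loop sizes (anchor midpoint distance)
#'
#' @param loops A `loop_set`.
#' @return Numeric vector of sizes in bp.
#' @export
loop_sizes <- function(loops) {
  mid1 <- floor((loops$start1 + loops$end1) / 2)
  mid2 <- floor((loops$start2 + loops$end2) / 2)
  mid2 - mid1
}

#' Read a BEDPE loop list
#'
#' At least six columns (chrom1, start1, end1, chrom2, start2, end2); extra
#' columns are mapped to PET counts and p/q values through `col_map` (1-based
#' column indices). Anchors are canonically ordered (left anchor first);
#' trans pairs (different chromosomes) are excluded with a logged count;
#' anchors overlapping after ordering raise a validation error.
#'
#' @param path Path to a BEDPE file.
#' @param col_map Named list, e.g. `list(pet = 7, p = 8, q = 9)`; entries
#'   optional.
#' @return A `loop_set`.
#' @export
read_bedpe <- function(path, col_map = list()) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(loop_set(data.frame(chrom = character(), start1 = numeric(),
                               end1 = numeric(), start2 = numeric(),
                               end2 = numeric())))
  }
  x <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 6) stop("BEDPE requires >= 6 columns in ", path)
  trans <- x[[1]] != x[[4]]
  if (any(trans)) {
    message(sum(trans), " trans pair(s) excluded from ", path)
    x <- x[!trans, , drop = FALSE]
  }
  grab <- function(key) {
    if (is.null(col_map[[key]])) rep(NA_real_, nrow(x))
    else as.numeric(x[[col_map[[key]]]])
  }
  df <- data.frame(chrom = x[[1]],
                   start1 = as.numeric(x[[2]]), end1 = as.numeric(x[[3]]),
                   start2 = as.numeric(x[[5]]), end2 = as.numeric(x[[6]]),
                   pet_count = grab("pet"), p_value = grab("p"),
                   q_value = grab("q"), stringsAsFactors = FALSE)
  swap <- df$start2 < df$start1
  if (any(swap)) {
    tmp_s <- df$start1[swap]; tmp_e <- df$end1[swap]
    df$start1[swap] <- df$start2[swap]; df$end1[swap] <- df$end2[swap]
    df$start2[swap] <- tmp_s; df$end2[swap] <- tmp_e
  }
  bad <- which(df$end1 > df$start2)
  if (length(bad) > 0) {
    stop("validation error: anchors overlap after ordering at record ", bad[1])
  }
  loop_set(df)
}

#' Write a loop set as BEDPE
#'
#' Columns: the six anchor fields, then PET count, p and q (`NA` as `.`).
#'
#' @param loops A `loop_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  fmt <- function(v) ifelse(is.na(v), ".",
                            format(v, trim = TRUE, scientific = FALSE,
                                   digits = 15))
  out <- paste(loops$chrom, loops$start1, loops$end1,
               loops$chrom, loops$start2, loops$end2,
               fmt(loops$pet_count), fmt(loops$p_value), fmt(loops$q_value),
               sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Filter loops by significance
#'
#' Retains loops whose chosen significance value is at most the threshold.
#'
#' @param loops A `loop_set`.
#' @param max_p,max_q Inclusive thresholds; give exactly one.
#' @return The filtered `loop_set`.
#' @export
filter_loops <- function(loops, max_p = NULL, max_q = NULL) {
  stopifnot(xor(is.null(max_p), is.null(max_q)))
  col <- if (is.null(max_p)) "q_value" else "p_value"
  thr <- max_p %||% max_q
  v <- loops[[col]]
  if (nrow(loops) > 0 && all(is.na(v))) {
    stop("configuration error: filtering on missing column ", col)
  }
  loops[!is.na(v) & v <= thr, , drop = FALSE]
}

#' Loop-size histogram
#'
#' Half-open `[lo, hi)` bins; defaults 0 / 300 kb / 1 Mb / Inf separate
#' short-, mid- and long-range loops.
#'
#' @param loops A `loop_set`.
#' @param bin_edges Strictly increasing edge vector.
#' @return Named integer vector of counts per bin.
#' @export
loop_size_distribution <- function(loops, bin_edges = c(0, 3e5, 1e6, Inf)) {
  stopifnot(all(diff(bin_edges) > 0))
  sz <- loop_sizes(loops)
  n <- length(bin_edges) - 1
  counts <- integer(n)
  for (i in seq_len(n)) {
    counts[i] <- sum(sz >= bin_edges[i] & sz < bin_edges[i + 1])
  }
  names(counts) <- paste0("[", bin_edges[-length(bin_edges)], ",",
                          bin_edges[-1], ")")
  counts
}

#' Build an annotation hierarchy for loop partners
#'
#' Ordered categories; the first whose feature set overlaps the partner anchor
#' (extended by the category's own extension) labels the loop. The default
#' order is promoter (TSS +/- 7.5 kb) > other seed element > PcG domain, with
#' an `"other"` fallback.
#'
#' @param tss TSS data.frame, or `NULL` to omit the promoter category.
#' @param seeds Seed element `GRanges` (for the "other seed element"
#'   category), or `NULL`.
#' @param pcg PcG-domain `GRanges`, or `NULL`.
#' @param tss_halfwidth Promoter window half-width in bp.
#' @return A list of categories usable by [annotate_partner()].
#' @export
annotation_hierarchy <- function(tss = NULL, seeds = NULL, pcg = NULL,
                                 tss_halfwidth = 7500) {
  h <- list()
  if (!is.null(tss)) {
    h <- c(h, list(list(label = "promoter",
                        features = tss_windows(tss, tss_halfwidth), ext = 0)))
  }
  if (!is.null(seeds)) {
    h <- c(h, list(list(label = "seed_element", features = granges_bare(seeds),
                        ext = 0)))
  }
  if (!is.null(pcg)) {
    h <- c(h, list(list(label = "pcg_domain", features = granges_bare(pcg),
                        ext = 0)))
  }
  h
}

#' Hierarchically annotate loop partners of a seed set
#'
#' Loops with at least one anchor (extended by `anchor_ext`) overlapping a
#' seed are selected; the other anchor is tested against the hierarchy
#' categories in order, and the first hit labels the contribution. When both
#' anchors overlap seeds the loop contributes once per seed-anchor
#' orientation. A seed is "interacting" when it appears in at least one
#' selected loop.
#'
#' @param loops A `loop_set`.
#' @param seeds Seed `GRanges` (e.g. poised enhancers).
#' @param hierarchy From [annotation_hierarchy()]; must be non-empty.
#' @param anchor_ext Anchor extension in bp (default 10 kb).
#' @param fallback Label for partners matching no category.
#' @return A list: `contributions` (data.frame loop / seed_anchor / label),
#'   `counts` (per label, fallback included), `seed_interacting` (logical per
#'   seed).
#' @export
annotate_partner <- function(loops, seeds, hierarchy, anchor_ext = 10000,
                             fallback = "other") {
  if (length(hierarchy) == 0) stop("configuration error: empty hierarchy")
  a1 <- loop_anchors(loops, 1, anchor_ext)
  a2 <- loop_anchors(loops, 2, anchor_ext)
  f1 <- IRanges::overlapsAny(a1, seeds, ignore.strand = TRUE)
  f2 <- IRanges::overlapsAny(a2, seeds, ignore.strand = TRUE)
  contrib <- data.frame(loop = c(which(f1), which(f2)),
                        seed_anchor = c(rep(1L, sum(f1)), rep(2L, sum(f2))))
  contrib <- contrib[order(contrib$loop, contrib$seed_anchor), , drop = FALSE]
  partner <- ifelse(contrib$seed_anchor == 1L, 2L, 1L)
  p1 <- loop_anchors(loops, 1, 0)[contrib$loop]
  p2 <- loop_anchors(loops, 2, 0)[contrib$loop]
  lab <- rep(fallback, nrow(contrib))
  open <- rep(TRUE, nrow(contrib))
  for (cat in hierarchy) {
    pa <- GenomicRanges::GRanges()
    if (nrow(contrib) > 0) {
      pa <- suppressWarnings({
        sel2 <- partner == 2L
        out <- p1
        out[sel2] <- p2[sel2]
        out
      })
      if (cat$ext > 0) pa <- interval_extend(pa, cat$ext)
    }
    hit <- open & IRanges::overlapsAny(pa, cat$features, ignore.strand = TRUE)
    lab[hit] <- cat$label
    open <- open & !hit
  }
  contrib$label <- lab
  labels_order <- c(vapply(hierarchy, `[[`, character(1), "label"), fallback)
  counts <- stats::setNames(
    vapply(labels_order, function(l) sum(lab == l), integer(1)), labels_order)
  sel_anchors <- suppressWarnings(c(a1[f1], a2[f2]))
  seed_int <- IRanges::overlapsAny(seeds, sel_anchors, ignore.strand = TRUE)
  list(contributions = contrib, counts = counts, seed_interacting = seed_int)
}

#' Classify loops as intra- or inter-TAD
#'
#' Membership is by anchor midpoint (ties never arise because TADs are
#' disjoint, which is validated). Loops with either midpoint outside every TAD
#' are `unassigned` and excluded from the intra/inter fractions.
#'
#' @param loops A `loop_set`.
#' @param tads A `GRanges` of disjoint TAD intervals.
#' @return A list: `status` (character per loop), `fractions` (intra/inter
#'   shares among assigned loops).
#' @export
classify_tad_status <- function(loops, tads) {
  if (length(tads) > 1 &&
      !IRanges::isDisjoint(granges_bare(tads))) {
    stop("TAD set must be disjoint within chromosomes")
  }
  mid_gr <- function(which) {
    s <- loops[[paste0("start", which)]]; e <- loops[[paste0("end", which)]]
    m <- floor((s + e) / 2)
    GenomicRanges::GRanges(loops$chrom, IRanges::IRanges(m + 1, m + 1))
  }
  t1 <- GenomicRanges::findOverlaps(mid_gr(1), tads, select = "first",
                                    ignore.strand = TRUE)
  t2 <- GenomicRanges::findOverlaps(mid_gr(2), tads, select = "first",
                                    ignore.strand = TRUE)
  status <- ifelse(is.na(t1) | is.na(t2), "unassigned",
                   ifelse(t1 == t2, "intra", "inter"))
  assigned <- status != "unassigned"
  fr <- if (any(assigned)) {
    c(intra = mean(status[assigned] == "intra"),
      inter = mean(status[assigned] == "inter"))
  } else c(intra = NA_real_, inter = NA_real_)
  list(status = status, fractions = fr)
}

#' Fraction of one loop set recovered in another
#'
#' A loop of `a` is matched when some loop of `b` has its anchor1 within
#' `anchor_ext` of `a`'s anchor1 AND its anchor2 within `anchor_ext` of `a`'s
#' anchor2 (extended-anchor overlap, canonical orientation). The measure is
#' directional (not symmetric).
#'
#' @param a,b `loop_set`s on a shared genome.
#' @param anchor_ext Anchor extension in bp.
#' @return A list: `matched` (logical per loop of `a`), `pct` (percentage,
#'   two decimals).
#' @export
loopset_overlap <- function(a, b, anchor_ext = 10000) {
  if (nrow(a) == 0) return(list(matched = logical(), pct = NA_real_))
  if (nrow(b) == 0) {
    return(list(matched = rep(FALSE, nrow(a)), pct = 0))
  }
  h1 <- GenomicRanges::findOverlaps(loop_anchors(a, 1, anchor_ext),
                                    loop_anchors(b, 1, 0),
                                    ignore.strand = TRUE)
  h2 <- GenomicRanges::findOverlaps(loop_anchors(a, 2, anchor_ext),
                                    loop_anchors(b, 2, 0),
                                    ignore.strand = TRUE)
  k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
  k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
  both <- intersect(k1, k2)
  matched_idx <- unique(as.integer(sub(" .*", "", both)))
  matched <- seq_len(nrow(a)) %in% matched_idx
  list(matched = matched, pct = round(100 * mean(matched), 2))
}

#' Summarize poised-enhancer interactions
#'
#' Restricts to distal PEs (gap to the nearest TSS base at least
#' `distal_min`), flags PEs appearing in at least one loop anchor (extended by
#' `anchor_ext`), and computes the share of PE interactions whose partner
#' anchor holds a promoter (TSS +/- `tss_halfwidth`). Also returns the
#' interacting TSS list for downstream promoter-state statistics.
#'
#' @param loops A significance-filtered `loop_set`.
#' @param pes Poised-enhancer `GRanges`.
#' @param tss TSS data.frame.
#' @param anchor_ext Anchor extension in bp (default 10 kb).
#' @param tss_halfwidth Promoter window half-width on the partner anchor
#'   (default 7.5 kb).
#' @param distal_min Distal threshold in bp (default 10 kb, strict in
#'   coordinate terms).
#' @return A list with `n_distal`, `n_interacting`, `pct_interacting`,
#'   `n_interactions`, `pct_promoter`, `interacting_tss` (gene ids).
#' @export
interaction_summary <- function(loops, pes, tss, anchor_ext = 10000,
                                tss_halfwidth = 7500, distal_min = 10000) {
  distal <- distal_filter(pes, tss, distal_min)
  hier <- annotation_hierarchy(tss = tss, tss_halfwidth = tss_halfwidth)
  ann <- annotate_partner(loops, distal, hier, anchor_ext = anchor_ext)
  n_int <- sum(ann$seed_interacting)
  n_contrib <- nrow(ann$contributions)
  pct_prom <- if (n_contrib == 0) NA_real_ else {
    round(100 * mean(ann$contributions$label == "promoter"), 2)
  }
  ## interacting TSS: promoter windows overlapping the partner anchors
  partner <- ann$contributions
  tssw <- tss_windows(tss, tss_halfwidth)
  pa <- c(loop_anchors(loops, 2, 0)[partner$loop[partner$seed_anchor == 1L]],
          loop_anchors(loops, 1, 0)[partner$loop[partner$seed_anchor == 2L]])
  genes <- unique(S4Vectors::mcols(tssw)$gene_id[
    IRanges::overlapsAny(tssw, pa, ignore.strand = TRUE)])
  list(n_distal = length(distal),
       n_interacting = n_int,
       pct_interacting = if (length(distal) == 0) NA_real_ else
         round(100 * n_int / length(distal), 2),
       n_interactions = n_contrib,
       pct_promoter = pct_prom,
       interacting_tss = genes)
}
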