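# Rule-based enhancer classification.
#
# Poised enhancers combine open chromatin (ATAC/p300) with H3K4me1 and
# H3K27me3 but lack H3K27ac; active enhancers swap the H3K27ac/H3K27me3 roles;
# primed enhancers carry H3K4me1 only. Calls are made per cell state
# ("context"), combined by union, filtered for TSS proximity, purged of the
# excluded mark by element-level subtraction, and merged.

#' Calling parameters
#'
#' Thresholds follow the conventions of macs2/bedtools pipelines: narrow-mode
#' marks (ATAC, p300) at q <= 0.05 with fold >= 4, broad-mode histone marks at
#' q <= 0.1 with fold >= 5 (H3K27ac) or >= 2 (H3K4me1, H3K27me3), broad peaks
#' extended +/- 1 kb before intersection, and a +/- 5 kb TSS proximity filter.
#' All fold/q comparisons are inclusive.
#'
#' @param tss_halfwidth TSS filter half-width in bp.
#' @param peak_extension Extension applied to broad histone peaks, bp.
#' @param min_fold Named list of per-mark minimum fold enrichments.
#' @param max_q Named list of per-mark inclusive q ceilings.
#' @param distal_min De novo calling: minimum gap (bp) between an element and
#'   the nearest TSS base (strictly more than 10 kb in coordinate terms).
#' @param denovo_extension Extension for de novo histone peaks, bp.
#' @param subtract_element If `TRUE` (default) the H3K27ac/H3K27me3 subtraction
#'   removes whole overlapping elements; if `FALSE`, only the covered bases.
#' @param tss_filter_first Apply the TSS filter before the subtraction step
#'   (the order in which the rules are stated); order is configurable.
#' @return A list of class `calling_params`.
#' @export
calling_params <- function(tss_halfwidth = 5000,
                           peak_extension = 1000,
                           min_fold = list(ATAC = 4, p300 = 4, H3K27ac = 5,
                                           H3K4me1 = 2, H3K27me3 = 2,
                                           H3K4me3 = 2),
                           max_q = list(ATAC = 0.05, p300 = 0.05,
                                        H3K27ac = 0.1, H3K4me1 = 0.1,
                                        H3K27me3 = 0.1, H3K4me3 = 0.1),
                           distal_min = 10000,
                           denovo_extension = 2500,
                           subtract_element = TRUE,
                           tss_filter_first = TRUE) {
  stopifnot(tss_halfwidth >= 0, peak_extension >= 0, distal_min >= 0,
            denovo_extension >= 0)
  if (any(unlist(min_fold) < 0) || any(unlist(max_q) < 0)) {
    stop("thresholds must be non-negative")
  }
  structure(list(tss_halfwidth = tss_halfwidth,
                 peak_extension = peak_extension,
                 min_fold = min_fold, max_q = max_q,
                 distal_min = distal_min,
                 denovo_extension = denovo_extension,
                 subtract_element = subtract_element,
                 tss_filter_first = tss_filter_first),
            class = "calling_params")
}

## fetch a mark for one context, filtered and optionally extended
prep_mark <- function(marks, context, mark, params, extend = FALSE) {
  pk <- marks[[context]][[mark]]
  if (is.null(pk)) {
    stop("context '", context, "' is missing required mark '", mark, "'")
  }
  if (is.null(params$min_fold[[mark]])) {
    stop("no fold threshold defined for mark '", mark, "'")
  }
  out <- suppressMessages(
    filter_peaks(pk, params$min_fold[[mark]], max_q = params$max_q[[mark]]))
  if (extend) out <- interval_extend(out, params$peak_extension)
  out
}

## open-chromatin evidence: ATAC preferred, p300 accepted
prep_open <- function(marks, context, params) {
  mk <- if (!is.null(marks[[context]][["ATAC"]])) "ATAC" else "p300"
  prep_mark(marks, context, mk, params)
}

## union of a filtered+extended mark across contexts (empty GRanges if none)
mark_union <- function(marks, contexts, mark, params) {
  pieces <- list()
  for (ctx in contexts) {
    if (!is.null(marks[[ctx]][[mark]])) {
      pieces[[ctx]] <- granges_bare(prep_mark(marks, ctx, mark, params,
                                              extend = TRUE))
    }
  }
  if (length(pieces) == 0) return(GenomicRanges::GRanges())
  do.call(c, unname(pieces))
}

## tss filter + subtraction + merge, order configurable; attaches provenance
finalize_calls <- function(calls, ctx_of, tss, subtract_set, params,
                           enhancer_class, rule) {
  steps <- character()
  do_tss <- function(x, keep_ctx) {
    ok <- !IRanges::overlapsAny(x, tss_windows(tss, params$tss_halfwidth),
                                ignore.strand = TRUE)
    steps <<- c(steps, sprintf("tss_filter(halfwidth=%d)", params$tss_halfwidth))
    list(x = x[ok], ctx = keep_ctx[ok])
  }
  do_sub <- function(x, keep_ctx) {
    if (length(subtract_set) == 0) return(list(x = x, ctx = keep_ctx))
    ok <- !IRanges::overlapsAny(x, subtract_set, ignore.strand = TRUE)
    steps <<- c(steps, "subtract(excluded_mark, element-level)")
    if (params$subtract_element) {
      list(x = x[ok], ctx = keep_ctx[ok])
    } else {
      ## base-level variant: split elements keep their context label
      y <- interval_subtract(x, subtract_set)
      hit <- GenomicRanges::findOverlaps(y, x, ignore.strand = TRUE,
                                         select = "first")
      list(x = y, ctx = keep_ctx[hit])
    }
  }
  a <- list(x = calls, ctx = ctx_of)
  if (params$tss_filter_first) {
    a <- do_tss(a$x, a$ctx)
    a <- do_sub(a$x, a$ctx)
  } else {
    a <- do_sub(a$x, a$ctx)
    a <- do_tss(a$x, a$ctx)
  }
  red <- GenomicRanges::reduce(granges_bare(a$x), with.revmap = TRUE,
                               ignore.strand = TRUE)
  ctxs <- vapply(S4Vectors::mcols(red)$revmap, function(ii) {
    paste(sort(unique(a$ctx[ii])), collapse = ",")
  }, character(1))
  S4Vectors::mcols(red) <- NULL
  S4Vectors::mcols(red)$enhancer_class <- rep(enhancer_class, length(red))
  S4Vectors::mcols(red)$source_contexts <- ctxs
  S4Vectors::mcols(red)$provenance <-
    rep(paste(c(rule, steps, "merge"), collapse = ";"), length(red))
  red
}

## per-context core rule: open-chromatin peaks overlapping both required marks
context_core_calls <- function(marks, contexts, params, mark_a, mark_b) {
  calls <- GenomicRanges::GRanges()
  ctx_of <- character()
  for (ctx in contexts) {
    open <- prep_open(marks, ctx, params)
    ma <- prep_mark(marks, ctx, mark_a, params, extend = TRUE)
    mb <- prep_mark(marks, ctx, mark_b, params, extend = TRUE)
    hit <- IRanges::overlapsAny(open, ma, ignore.strand = TRUE) &
      IRanges::overlapsAny(open, mb, ignore.strand = TRUE)
    sel <- granges_bare(open[hit])
    calls <- suppressWarnings(c(calls, sel))
    ctx_of <- c(ctx_of, rep(ctx, length(sel)))
  }
  list(calls = calls, ctx = ctx_of)
}

#' Call poised enhancers (in vitro rule)
#'
#' Per context: open-chromatin peaks (ATAC or p300) overlapping both the
#' extended H3K27me3 and H3K4me1 regions; contexts combined by union; TSS
#' proximity filter; element-level subtraction of the H3K27ac union across all
#' contexts; merge.
#'
#' @param marks Nested list `marks[[context]][[mark]]` of peak `GRanges`.
#' @param tss TSS data.frame (see [read_tss()]).
#' @param params A [calling_params()] object.
#' @param contexts Contexts to use; default all of `names(marks)`.
#' @return A `GRanges` of merged calls with `enhancer_class`,
#'   `source_contexts` and `provenance` metadata.
#' @export
call_poised_invitro <- function(marks, tss, params = calling_params(),
                                contexts = names(marks)) {
  if (length(contexts) == 0) {
    warning("no contexts provided")
    return(empty_calls("poised"))
  }
  core <- context_core_calls(marks, contexts, params, "H3K27me3", "H3K4me1")
  k27ac <- mark_union(marks, contexts, "H3K27ac", params)
  finalize_calls(core$calls, core$ctx, tss, k27ac, params, "poised",
                 "poised:=open&H3K27me3&H3K4me1 minus H3K27ac")
}

#' Call active enhancers (in vitro rule)
#'
#' Mirror of [call_poised_invitro()] with the H3K27ac/H3K27me3 roles swapped:
#' open-chromatin peaks overlapping extended H3K27ac and H3K4me1, minus the
#' H3K27me3 union.
#'
#' @inheritParams call_poised_invitro
#' @return A `GRanges` of merged calls.
#' @export
call_active_invitro <- function(marks, tss, params = calling_params(),
                                contexts = names(marks)) {
  if (length(contexts) == 0) {
    warning("no contexts provided")
    return(empty_calls("active"))
  }
  core <- context_core_calls(marks, contexts, params, "H3K27ac", "H3K4me1")
  k27me3 <- mark_union(marks, contexts, "H3K27me3", params)
  finalize_calls(core$calls, core$ctx, tss, k27me3, params, "active",
                 "active:=open&H3K27ac&H3K4me1 minus H3K27me3")
}

#' Call primed enhancers (in vitro rule)
#'
#' Union of extended H3K4me1 regions across contexts; TSS filter; subtraction
#' of both the H3K27me3 and H3K27ac unions; merge.
#'
#' @inheritParams call_poised_invitro
#' @return A `GRanges` of merged calls.
#' @export
call_primed_invitro <- function(marks, tss, params = calling_params(),
                                contexts = names(marks)) {
  if (length(contexts) == 0) {
    warning("no contexts provided")
    return(empty_calls("primed"))
  }
  calls <- GenomicRanges::GRanges()
  ctx_of <- character()
  for (ctx in contexts) {
    k4 <- granges_bare(prep_mark(marks, ctx, "H3K4me1", params, extend = TRUE))
    calls <- suppressWarnings(c(calls, k4))
    ctx_of <- c(ctx_of, rep(ctx, length(k4)))
  }
  sub <- suppressWarnings(c(mark_union(marks, contexts, "H3K27me3", params),
                            mark_union(marks, contexts, "H3K27ac", params)))
  finalize_calls(calls, ctx_of, tss, sub, params, "primed",
                 "primed:=H3K4me1 minus (H3K27me3|H3K27ac)")
}

empty_calls <- function(cls) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    enhancer_class = character(), source_contexts = character(),
    provenance = character())
  gr
}

#' Resolve overlaps between enhancer classes
#'
#' Elements overlapping between poised and active, or poised and primed, are
#' removed from both sets; elements overlapping between active and primed stay
#' and are attributed to the active class only. The returned classes are
#' pairwise disjoint by overlap.
#'
#' @param poised,active,primed Call `GRanges` from the in vitro callers.
#' @return A named list `poised`/`active`/`primed` of relabeled sets.
#' @export
resolve_class_overlaps <- function(poised, active, primed) {
  po_ac <- IRanges::overlapsAny(poised, active, ignore.strand = TRUE)
  po_pr <- IRanges::overlapsAny(poised, primed, ignore.strand = TRUE)
  ac_po <- IRanges::overlapsAny(active, poised, ignore.strand = TRUE)
  pr_po <- IRanges::overlapsAny(primed, poised, ignore.strand = TRUE)
  pr_ac <- IRanges::overlapsAny(primed, active, ignore.strand = TRUE)
  list(poised = poised[!po_ac & !po_pr],
       active = active[!ac_po],
       primed = primed[!pr_po & !pr_ac])
}

#' Relabel poised enhancers activated in a later cell state (PoiAct)
#'
#' Each later-stage H3K27ac peak set is filtered by its own fold/q thresholds
#' and extended; replicate sets are first intersected (segment mode). Poised
#' elements overlapping the processed regions are relabeled `poiact`; the rest
#' remain `poised`.
#'
#' @param poised Poised call `GRanges`.
#' @param later_k27ac_sets List of later-stage H3K27ac descriptors, each a list
#'   with `peaks` (a peak `GRanges`, or a list of replicate `GRanges`),
#'   `min_fold`, `max_q` and `extension` (bp).
#' @return A list with `poiact` and `poised` `GRanges`.
#' @export
call_poiact <- function(poised, later_k27ac_sets) {
  processed <- GenomicRanges::GRanges()
  for (s in later_k27ac_sets) {
    pk <- s$peaks
    if (methods::is(pk, "GRanges")) pk <- list(pk)
    reps <- lapply(pk, function(p) {
      granges_bare(suppressMessages(
        filter_peaks(p, s$min_fold %||% 0, max_q = s$max_q)))
    })
    acc <- reps[[1]]
    for (r in reps[-1]) acc <- interval_intersect(acc, r, mode = "segment")
    ext <- s$extension %||% 0
    processed <- suppressWarnings(c(processed, interval_extend(acc, ext)))
  }
  hit <- IRanges::overlapsAny(poised, processed, ignore.strand = TRUE)
  poiact <- poised[hit]
  if (length(poiact) > 0) {
    S4Vectors::mcols(poiact)$enhancer_class <- "poiact"
    S4Vectors::mcols(poiact)$provenance <-
      paste0(S4Vectors::mcols(poiact)$provenance, ";poiact:=later H3K27ac")
  }
  list(poiact = poiact, poised = poised[!hit])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## keep elements whose gap to the nearest TSS base is >= min_gap
## (equivalently: strictly more than min_gap in coordinate-difference terms)
distal_filter <- function(gr, tss, min_gap) {
  pts <- tss_windows(tss, 0)
  d <- suppressWarnings(distance_to_nearest(gr, pts)$distance)
  gr[is.na(d) | d >= min_gap]
}

#' Call poised enhancers in vivo (epiblast rule)
#'
#' ATAC peaks (fold >= 5, q <= 0.05) overlapping extended H3K27me3 regions
#' (fold >= 2, p <= 0.01, +/- 1 kb); subtraction of in vivo H3K27ac (fold >= 2,
#' p <= 0.01) and of the processed in vitro H3K27ac union; TSS +/- 5 kb filter.
#' No H3K4me1 requirement, and the in vivo histone filters use p-values, not
#' q-values.
#'
#' @param atac In vivo ATAC narrowPeak `GRanges`.
#' @param k27me3 In vivo H3K27me3 broadPeak `GRanges`.
#' @param k27ac_invivo In vivo H3K27ac broadPeak `GRanges`.
#' @param k27ac_invitro_union Already-processed in vitro H3K27ac regions
#'   (`GRanges`; filtered and extended).
#' @param tss TSS data.frame.
#' @param params A [calling_params()] object.
#' @param atac_min_fold,k27me3_min_fold,k27ac_min_fold,atac_max_q,hist_max_p
#'   In vivo thresholds.
#' @return A `GRanges` of in vivo poised calls.
#' @export
call_poised_invivo <- function(atac, k27me3, k27ac_invivo,
                               k27ac_invitro_union, tss,
                               params = calling_params(),
                               atac_min_fold = 5, k27me3_min_fold = 2,
                               k27ac_min_fold = 2, atac_max_q = 0.05,
                               hist_max_p = 0.01) {
  fa <- suppressMessages(filter_peaks(atac, atac_min_fold, max_q = atac_max_q))
  fk <- interval_extend(
    suppressMessages(filter_peaks(k27me3, k27me3_min_fold,
                                  max_p = hist_max_p)),
    params$peak_extension)
  calls <- granges_bare(fa[IRanges::overlapsAny(fa, fk, ignore.strand = TRUE)])
  ka <- granges_bare(suppressMessages(
    filter_peaks(k27ac_invivo, k27ac_min_fold, max_p = hist_max_p)))
  sub <- suppressWarnings(c(ka, granges_bare(k27ac_invitro_union)))
  calls <- interval_subtract(calls, sub, element = params$subtract_element)
  calls <- tss_window_filter(calls, tss, params$tss_halfwidth)
  red <- interval_merge(calls)
  S4Vectors::mcols(red)$enhancer_class <- rep("poised", length(red))
  S4Vectors::mcols(red)$source_contexts <- rep("invivo", length(red))
  S4Vectors::mcols(red)$provenance <- rep(
    "poised_invivo:=ATAC&H3K27me3 minus H3K27ac(invivo|invitro);tss_filter;merge",
    length(red))
  red
}

#' Call poised enhancers de novo (cross-species rule)
#'
#' As the in vitro poised rule but without H3K4me1: open-chromatin peaks
#' (species fold threshold, q <= 0.1) overlapping H3K27me3 peaks extended by
#' +/- 2.5 kb (species fold threshold, q <= 0.1); optional H3K27ac subtraction
#' (skipped with a notice when unavailable); only elements located distally
#' (strictly more than `distal_min` bp) from any TSS are kept.
#'
#' @param open_peaks Species ATAC/p300 narrowPeak `GRanges`.
#' @param k27me3 Species H3K27me3 broadPeak `GRanges`.
#' @param k27ac Optional species H3K27ac `GRanges` (`NULL` to skip).
#' @param tss TSS data.frame.
#' @param params A [calling_params()] object.
#' @param open_min_fold,k27me3_min_fold,k27ac_min_fold Species-specific fold
#'   thresholds.
#' @param max_q Inclusive q ceiling used throughout.
#' @return A `GRanges` of de novo poised calls.
#' @export
call_poised_denovo <- function(open_peaks, k27me3, k27ac = NULL, tss,
                               params = calling_params(),
                               open_min_fold = 3, k27me3_min_fold = 3,
                               k27ac_min_fold = 3, max_q = 0.1) {
  fo <- suppressMessages(filter_peaks(open_peaks, open_min_fold,
                                      max_q = max_q))
  fk <- interval_extend(
    suppressMessages(filter_peaks(k27me3, k27me3_min_fold, max_q = max_q)),
    params$denovo_extension)
  calls <- granges_bare(fo[IRanges::overlapsAny(fo, fk, ignore.strand = TRUE)])
  if (!is.null(k27ac)) {
    ka <- interval_extend(
      suppressMessages(filter_peaks(k27ac, k27ac_min_fold, max_q = max_q)),
      params$denovo_extension)
    calls <- interval_subtract(calls, ka, element = params$subtract_element)
  } else {
    message("no H3K27ac available: subtraction step skipped")
  }
  calls <- distal_filter(calls, tss, params$distal_min)
  red <- interval_merge(calls)
  S4Vectors::mcols(red)$enhancer_class <- rep("poised", length(red))
  S4Vectors::mcols(red)$source_contexts <- rep("denovo", length(red))
  S4Vectors::mcols(red)$provenance <- rep(
    "poised_denovo:=open&H3K27me3(+/-2.5kb) minus H3K27ac;distal>10kb;merge",
    length(red))
  red
}

#' Two-way overlap report between enhancer sets
#'
#' Counts elements of each set having at least 1 bp overlap with the other and
#' reports them as counts and percentages (two decimals).
#'
#' @param a,b Call `GRanges` on a shared genome.
#' @return A list with counts, percentages and formatted strings such as
#'   `"39.68% (1213/3057)"`.
#' @export
set_overlap_report <- function(a, b) {
  shared_genome_check(a, b)
  n_ab <- sum(IRanges::overlapsAny(a, b, ignore.strand = TRUE))
  n_ba <- sum(IRanges::overlapsAny(b, a, ignore.strand = TRUE))
  pct <- function(num, den) if (den == 0) 0 else round(100 * num / den, 2)
  p_ab <- pct(n_ab, length(a)); p_ba <- pct(n_ba, length(b))
  list(n_a = length(a), n_b = length(b),
       n_a_in_b = n_ab, n_b_in_a = n_ba,
       pct_a_in_b = p_ab, pct_b_in_a = p_ba,
       label_a_in_b = sprintf("%.2f%% (%d/%d)", p_ab, n_ab, length(a)),
       label_b_in_a = sprintf("%.2f%% (%d/%d)", p_ba, n_ba, length(b)))
}
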