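# Interval data model and set algebra.
#
# The package-internal container for genomic intervals is GRanges (1-based,
# closed). All text formats touched here (BED, bedGraph, narrowPeak/broadPeak,
# chain, COO) are 0-based half-open and are converted at the reader/writer
# boundary, so bookended BED intervals never share a base internally.

#' Read a chrom.sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  stopifnot(file.exists(path))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  if (any(x$length <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(as.integer(x$length), x$chrom)
}

#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqlevels
genome_seqinfo <- function(genome) {
  if (is.null(genome)) return(NULL)
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(genome))
}

## Construct a GRanges from 0-based half-open coordinates.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
gr_from_bed0 <- function(chrom, start0, end0, strand = "*", genome = NULL) {
  bad <- which(!(start0 >= 0 & start0 < end0))
  if (length(bad) > 0) {
    stop("invalid interval (need 0 <= start < end) at record ", bad[1],
         ": ", chrom[bad[1]], ":", start0[bad[1]], "-", end0[bad[1]])
  }
  gr <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = rep_len(strand, length(start0)))
  if (!is.null(genome)) gr <- attach_genome(gr, genome)
  gr
}

#' Attach a genome (chromosome lengths) to an interval set
#'
#' Validates that every interval lies on a known chromosome and within its
#' bounds.
#'
#' @param gr A `GRanges`.
#' @param genome Named vector of chromosome lengths (see [read_chrom_sizes()]).
#' @return `gr` with seqinfo set.
#' @export
attach_genome <- function(gr, genome) {
  unknown <- setdiff(as.character(unique(GenomeInfoDb::seqnames(gr))),
                     names(genome))
  if (length(unknown) > 0) {
    stop("chromosome(s) absent from genome: ", paste(unknown, collapse = ", "))
  }
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  ## out-of-bound ranges raise our own error below, not the GRanges warning
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome))
  over <- which(BiocGenerics::end(gr) >
                  genome[as.character(GenomeInfoDb::seqnames(gr))])
  if (length(over) > 0) {
    stop("interval ", over[1], " exceeds chromosome length")
  }
  gr
}

shared_genome_check <- function(a, b) {
  ga <- GenomeInfoDb::seqlengths(a); gb <- GenomeInfoDb::seqlengths(b)
  common <- intersect(names(ga)[!is.na(ga)], names(gb)[!is.na(gb)])
  if (length(common) > 0 && any(ga[common] != gb[common])) {
    stop("interval sets carry incompatible genomes")
  }
  invisible(TRUE)
}

#' Read a BED file into a GRanges
#'
#' BED3/BED6, tab-separated, 0-based half-open. `track`/`browser`/`#` lines are
#' skipped. Column 4 (name) and column 6 (strand) are kept when present.
#'
#' @param path Path to a BED file.
#' @param genome Optional named vector of chromosome lengths.
#' @return A `GRanges`, original record order preserved, with a `name` metadata
#'   column when the file has one.
#' @export
read_bed <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(gr_from_bed0(character(), numeric(), numeric(), genome = genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", lineno[which(nf < 3)[1]], " in ", path,
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0) {
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": non-numeric coordinates")
  }
  bad <- which(start0 >= end0)
  if (length(bad) > 0) {
    stop("invalid BED line ", lineno[bad[1]], " in ", path,
         ": start >= end")
  }
  strand <- rep("*", length(lines))
  if (all(nf >= 6)) {
    s <- vapply(fields, `[[`, character(1), 6)
    strand <- ifelse(s %in% c("+", "-"), s, "*")
  }
  gr <- gr_from_bed0(chrom, start0, end0, strand, genome)
  if (all(nf >= 4)) {
    S4Vectors::mcols(gr)$name <- vapply(fields, `[[`, character(1), 4)
  }
  gr
}

#' Write a GRanges to a BED file
#'
#' Emits BED3 (or BED6 when `name` metadata or strand information is present),
#' 0-based half-open, tab-separated.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  nm <- S4Vectors::mcols(gr)$name
  st <- as.character(BiocGenerics::strand(gr))
  if (is.null(nm) && all(st == "*")) {
    out <- paste(chrom, start0, end0, sep = "\t")
  } else {
    if (is.null(nm)) nm <- rep(".", n)
    st[st == "*"] <- "."
    out <- paste(chrom, start0, end0, nm, 0L, st, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Intersect two interval sets
#'
#' `mode = "select"` returns the elements of `a` that overlap at least one base
#' of `b`, with element identity and metadata preserved. `mode = "segment"`
#' returns the overlapping sub-intervals (disjoint, sorted).
#'
#' @param a,b `GRanges` on a shared genome.
#' @param mode `"select"` or `"segment"`.
#' @return A `GRanges`.
#' @export
interval_intersect <- function(a, b, mode = c("select", "segment")) {
  mode <- match.arg(mode)
  shared_genome_check(a, b)
  if (mode == "select") {
    return(a[IRanges::overlapsAny(a, b, ignore.strand = TRUE)])
  }
  ared <- GenomicRanges::reduce(granges_bare(a))
  bred <- GenomicRanges::reduce(granges_bare(b))
  hits <- GenomicRanges::findOverlaps(ared, bred, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  s <- pmax(BiocGenerics::start(ared)[qh], BiocGenerics::start(bred)[sh])
  e <- pmin(BiocGenerics::end(ared)[qh], BiocGenerics::end(bred)[sh])
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(ared)[qh],
                                IRanges::IRanges(s, e))
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(ared)
  sort(out)
}

## strip strand + mcols so set ops are strand-blind
granges_bare <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  BiocGenerics::strand(gr) <- "*"
  gr
}

#' Subtract one interval set from another
#'
#' Base-level by default: every base of `a` covered by `b` is removed, elements
#' fully covered vanish, split elements inherit the metadata of their parent.
#' With `element = TRUE` any element of `a` overlapping `b` is removed entirely
#' (the convention used by the enhancer-calling rules, which count whole
#' elements).
#'
#' @param a,b `GRanges` on a shared genome.
#' @param element Kill whole overlapping elements instead of removing bases.
#' @return A `GRanges`.
#' @export
interval_subtract <- function(a, b, element = FALSE) {
  shared_genome_check(a, b)
  if (element) {
    return(a[!IRanges::overlapsAny(a, b, ignore.strand = TRUE)])
  }
  if (length(b) == 0 || length(a) == 0) return(a)
  bred <- GenomicRanges::reduce(granges_bare(b))
  hits <- GenomicRanges::findOverlaps(a, bred, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  as_ <- BiocGenerics::start(a); ae <- BiocGenerics::end(a)
  ## clip each covering b interval to its a element; hits arrive sorted by
  ## query and, within a query, by position (bred is sorted)
  cs <- pmax(as_[qh], BiocGenerics::start(bred)[sh])
  ce <- pmin(ae[qh], BiocGenerics::end(bred)[sh])
  first <- !duplicated(qh)
  last <- !duplicated(qh, fromLast = TRUE)
  ## k clips inside an element leave up to k+1 complementary pieces
  p_start <- c(ifelse(first, as_[qh], c(NA, ce[-length(ce)] + 1)), ce[last] + 1)
  p_end <- c(cs - 1, ae[qh[last]])
  p_q <- c(qh, qh[last])
  ok <- p_start <= p_end
  untouched <- setdiff(seq_along(a), unique(qh))
  idx <- c(p_q[ok], untouched)
  starts <- c(p_start[ok], as_[untouched])
  ends <- c(p_end[ok], ae[untouched])
  ord <- order(idx, starts)
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(a)[idx[ord]],
                                IRanges::IRanges(starts[ord], ends[ord]))
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(a)
  S4Vectors::mcols(out) <- S4Vectors::mcols(a)[idx[ord], , drop = FALSE]
  out
}

#' Merge an interval set
#'
#' Collapses overlapping intervals, plus intervals separated by at most `gap`
#' bases. Bookended intervals (gap 0) merge, matching bedtools merge defaults.
#' Output is sorted and disjoint.
#'
#' @param a A `GRanges`.
#' @param gap Maximum gap (bp) to bridge; must be >= 0.
#' @return A `GRanges`.
#' @export
interval_merge <- function(a, gap = 0) {
  if (gap < 0) stop("gap must be non-negative")
  GenomicRanges::reduce(granges_bare(a), min.gapwidth = gap + 1,
                        ignore.strand = TRUE)
}

#' Union of two interval sets
#'
#' Concatenates the element lists without collapsing (collapsing is
#' [interval_merge()]'s job); shared metadata columns are retained.
#'
#' @param a,b `GRanges` on a shared genome.
#' @return A `GRanges` with `length(a) + length(b)` elements.
#' @export
interval_union <- function(a, b) {
  shared_genome_check(a, b)
  common <- intersect(colnames(S4Vectors::mcols(a)),
                      colnames(S4Vectors::mcols(b)))
  ga <- a; gb <- b
  S4Vectors::mcols(ga) <- S4Vectors::mcols(a)[, common, drop = FALSE]
  S4Vectors::mcols(gb) <- S4Vectors::mcols(b)[, common, drop = FALSE]
  suppressWarnings(c(ga, gb))
}

#' Extend intervals symmetrically
#'
#' Grows every interval by `flank` bases on both sides, clipped to chromosome
#' bounds when a genome is attached.
#'
#' @param a A `GRanges`.
#' @param flank Flank size in bp, >= 0.
#' @return A `GRanges`.
#' @export
interval_extend <- function(a, flank) {
  stopifnot(flank >= 0)
  if (length(a) == 0 || flank == 0) return(a)
  out <- suppressWarnings(a + flank)
  GenomicRanges::trim(out)
}

#' Distance to nearest subject interval
#'
#' Gap semantics: distance 0 when the query overlaps a subject, otherwise the
#' number of bases strictly between the closest edges (so bookended intervals
#' are at distance 0 without overlapping). Ties break to the leftmost subject
#' by (chrom, start, end). Queries on chromosomes with no subject get `NA`.
#'
#' @param query,subject `GRanges` on a shared genome.
#' @return A data.frame with one row per query: `distance` (bp or `NA`) and
#'   `nearest` (subject index or `NA`).
#' @export
distance_to_nearest <- function(query, subject) {
  if (length(subject) == 0) {
    warning("empty subject set: all distances missing")
    return(data.frame(distance = rep(NA_real_, length(query)),
                      nearest = rep(NA_integer_, length(query))))
  }
  shared_genome_check(query, subject)
  qc <- as.character(GenomeInfoDb::seqnames(query))
  sc <- as.character(GenomeInfoDb::seqnames(subject))
  qs <- BiocGenerics::start(query); qe <- BiocGenerics::end(query)
  ss <- BiocGenerics::start(subject); se <- BiocGenerics::end(subject)
  res <- data.frame(distance = rep(NA_real_, length(query)),
                    nearest = rep(NA_integer_, length(query)))
  by_chrom <- split(seq_along(subject), sc)
  for (i in seq_along(query)) {
    idx <- by_chrom[[qc[i]]]
    if (is.null(idx)) next
    ## gap between closest edges; 0 on overlap (and on bookended intervals)
    d <- pmax(0, pmax(ss[idx] - qe[i], qs[i] - se[idx]) - 1)
    dmin <- min(d)
    cand <- idx[d == dmin]
    ## leftmost tie-break by (start, end, index)
    best <- cand[order(ss[cand], se[cand], cand)][1]
    res$distance[i] <- dmin
    res$nearest[i] <- best
  }
  res
}

#' Read a TSS annotation (BED6 with gene names)
#'
#' The TSS base is the interval start for `+`/unstranded records and `end - 1`
#' for `-` records, in 0-based coordinates.
#'
#' @param path Path to a BED6 file whose name column holds gene ids.
#' @param genome Optional named vector of chromosome lengths.
#' @return A data.frame with columns `gene_id`, `chrom`, `position` (0-based),
#'   `strand`.
#' @export
read_tss <- function(path, genome = NULL) {
  gr <- read_bed(path, genome)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) stop("TSS BED file must carry gene names in column 4")
  if (anyDuplicated(nm)) {
    stop("duplicate gene_id in TSS annotation: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  st <- as.character(BiocGenerics::strand(gr))
  pos0 <- ifelse(st == "-", BiocGenerics::end(gr) - 1L,
                 BiocGenerics::start(gr) - 1L)
  data.frame(gene_id = nm,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             position = as.integer(pos0),
             strand = st,
             stringsAsFactors = FALSE)
}

#' TSS windows as intervals
#'
#' Strand-ignored windows of `halfwidth` bases on each side of the TSS base
#' (window width `2 * halfwidth + 1`).
#'
#' @param tss A TSS data.frame (see [read_tss()]).
#' @param halfwidth Half-width in bp, >= 0.
#' @param genome Optional genome for clipping.
#' @return A `GRanges` with a `gene_id` metadata column.
#' @export
tss_windows <- function(tss, halfwidth, genome = NULL) {
  stopifnot(halfwidth >= 0)
  gr <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = pmax(1L, tss$position + 1L - halfwidth),
                     end = tss$position + 1L + halfwidth))
  S4Vectors::mcols(gr)$gene_id <- tss$gene_id
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         names(genome))
    gr <- attach_genome(GenomicRanges::trim(gr), genome)
    gr <- GenomicRanges::trim(gr)
  }
  gr
}

#' Remove elements proximal to a TSS
#'
#' Drops every element of `a` overlapping any TSS +/- `halfwidth` window
#' (strand-ignored). Survivors are returned unchanged.
#'
#' @param a A `GRanges`.
#' @param tss TSS data.frame.
#' @param halfwidth Window half-width in bp.
#' @return The filtered `GRanges`.
#' @export
tss_window_filter <- function(a, tss, halfwidth) {
  win <- tss_windows(tss, halfwidth)
  a[!IRanges::overlapsAny(a, win, ignore.strand = TRUE)]
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @param genome Optional named vector of chromosome lengths.
#' @return A `GRanges` with a numeric `score` column; intervals are expected to
#'   be non-overlapping within a chromosome (checked).
#' @export
read_bedgraph <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    gr <- gr_from_bed0(character(), numeric(), numeric(), genome = genome)
    S4Vectors::mcols(gr)$score <- numeric()
    return(gr)
  }
  x <- utils::read.table(text = lines, sep = "\t",
                         col.names = c("chrom", "start", "end", "score"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  if (any(!is.finite(x$score))) stop("non-finite value in bedGraph ", path)
  gr <- gr_from_bed0(x$chrom, x$start, x$end, genome = genome)
  S4Vectors::mcols(gr)$score <- x$score
  red <- GenomicRanges::reduce(granges_bare(gr))
  if (sum(BiocGenerics::width(red)) != sum(BiocGenerics::width(gr))) {
    stop("overlapping intervals in bedGraph ", path)
  }
  gr
}

#' Aggregate a signal track around region midpoints
#'
#' Each region is represented by its midpoint +/- `halfwidth`, split into
#' `nbins` equal bins; the bin value is the base-weighted mean of the track
#' over the bin, with uncovered bases (including any part of the window falling
#' outside the chromosome) contributing 0.
#'
#' @param track A `GRanges` with a `score` column (see [read_bedgraph()]).
#' @param regions A non-empty `GRanges`.
#' @param halfwidth Window half-width in bp.
#' @param nbins Number of bins, >= 1.
#' @return A list with `profile` (regions x nbins matrix) and `means`
#'   (column means across regions).
#' @export
aggregate_signal <- function(track, regions, halfwidth, nbins) {
  stopifnot(nbins >= 1, halfwidth > 0, length(regions) > 0)
  tchrom <- as.character(GenomeInfoDb::seqnames(track))
  ts <- BiocGenerics::start(track) - 1  # 0-based
  te <- BiocGenerics::end(track)
  tv <- S4Vectors::mcols(track)$score
  if (is.null(tv)) stop("track lacks a score column")
  by_chrom <- split(seq_along(track), tchrom)

  rchrom <- as.character(GenomeInfoDb::seqnames(regions))
  rs <- BiocGenerics::start(regions) - 1
  re <- BiocGenerics::end(regions)
  mid <- floor((rs + re) / 2)
  W <- 2 * halfwidth
  prof <- matrix(0, nrow = length(regions), ncol = nbins)
  edges <- W * (0:nbins) / nbins
  for (i in seq_along(regions)) {
    idx <- by_chrom[[rchrom[i]]]
    if (is.null(idx)) next
    lo <- mid[i] - halfwidth
    s <- ts[idx]; e <- te[idx]; v <- tv[idx]
    sel <- which(e > lo & s < lo + W)
    if (length(sel) == 0) next
    s <- s[sel] - lo; e <- e[sel] - lo; v <- v[sel]
    for (j in seq_len(nbins)) {
      ov <- pmax(0, pmin(e, edges[j + 1]) - pmax(s, edges[j]))
      prof[i, j] <- sum(v * ov) / (W / nbins)
    }
  }
  list(profile = prof, means = colMeans(prof))
}
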