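# UCSC chain parsing and chain-based conservation scoring.
#
# A chain maps a source ("target" in UCSC header terms, the genome lifted
# FROM) to a destination ("query") genome through ordered aligned blocks
# separated by gaps. Conservation of an interval is scored as its mapped
# ratio: the fraction of its bases falling inside aligned blocks of the single
# highest-scoring chain overlapping it (the liftOver -minMatch semantic;
# sequence-level percent identity is not computed).

#' Read a UCSC chain file
#'
#' Header lines are
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id`, followed by `size dt dq` block triples and a bare final `size`.
#' Block sums are validated against the declared source and destination spans.
#'
#' @param path Path to a chain file.
#' @return A `chain_set`: list of chains indexed by source chromosome.
#' @export
read_chain <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^#", lines)]
  heads <- grep("^chain\\b", lines)
  chains <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    h <- strsplit(lines[heads[k]], "[ \t]+")[[1]]
    if (length(h) < 12) stop("malformed chain header at line ", heads[k])
    body <- lines[(heads[k] + 1):(bounds[k + 1] - 1)]
    body <- body[nzchar(body)]
    parts <- strsplit(body, "[ \t]+")
    sizes <- as.numeric(vapply(parts, `[[`, character(1), 1))
    dt <- dq <- numeric(length(parts))
    multi <- lengths(parts) >= 3
    dt[multi] <- as.numeric(vapply(parts[multi], `[[`, character(1), 2))
    dq[multi] <- as.numeric(vapply(parts[multi], `[[`, character(1), 3))
    if (any(sizes <= 0)) stop("non-positive block size in chain ", h[13] %||% k)
    id <- if (length(h) >= 13) h[13] else as.character(k)
    ch <- list(score = as.numeric(h[2]),
               t_chrom = h[3], t_size = as.numeric(h[4]), t_strand = h[5],
               t_start = as.numeric(h[6]), t_end = as.numeric(h[7]),
               q_chrom = h[8], q_size = as.numeric(h[9]), q_strand = h[10],
               q_start = as.numeric(h[11]), q_end = as.numeric(h[12]),
               id = id,
               blocks = cbind(size = sizes, dt = dt, dq = dq))
    if (ch$t_strand != "+") stop("chain ", id, ": source strand must be +")
    if (sum(sizes) + sum(dt) != ch$t_end - ch$t_start ||
        sum(sizes) + sum(dq) != ch$q_end - ch$q_start) {
      stop("format error: block sums do not match header span in chain ", id)
    }
    chains[[k]] <- ch
  }
  structure(list(chains = chains,
                 by_chrom = split(seq_along(chains),
                                  vapply(chains, `[[`, character(1),
                                         "t_chrom"))),
            class = "chain_set")
}

#' Write a chain set to a UCSC chain file
#'
#' @param chains A `chain_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  out <- character()
  for (ch in chains$chains) {
    out <- c(out, paste("chain", format(ch$score, scientific = FALSE),
                        ch$t_chrom, format(ch$t_size, scientific = FALSE),
                        ch$t_strand,
                        format(ch$t_start, scientific = FALSE),
                        format(ch$t_end, scientific = FALSE),
                        ch$q_chrom, format(ch$q_size, scientific = FALSE),
                        ch$q_strand,
                        format(ch$q_start, scientific = FALSE),
                        format(ch$q_end, scientific = FALSE), ch$id))
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1) {
      out <- c(out, paste(b[-n, "size"], b[-n, "dt"], b[-n, "dq"]))
    }
    out <- c(out, as.character(b[n, "size"]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Map one interval through a chain set
#'
#' Among chains overlapping the query on the source genome, only the single
#' highest-scoring chain contributes (no cross-chain stitching). The mapped
#' ratio is the fraction of query bases inside aligned blocks; the target
#' interval is the bounding span of the mapped bases on the destination genome
#' (strand-reflected for minus-strand chains). Mappings whose target span
#' exceeds `max_expansion` times the query length are rejected.
#'
#' @param chrom,start0,end0 Query interval, 0-based half-open.
#' @param chains A `chain_set`.
#' @param max_expansion Cap on target span / query length (default 10).
#' @return A one-row data.frame: `mapped_ratio`, `target_chrom`,
#'   `target_start`, `target_end` (0-based half-open, `NA` when unmapped) and
#'   `chain_id`.
#' @export
map_interval <- function(chrom, start0, end0, chains, max_expansion = 10) {
  unmapped <- data.frame(mapped_ratio = 0, target_chrom = NA_character_,
                         target_start = NA_real_, target_end = NA_real_,
                         chain_id = NA_character_,
                         stringsAsFactors = FALSE)
  idx <- chains$by_chrom[[chrom]]
  if (is.null(idx)) return(unmapped)
  cand <- idx[vapply(chains$chains[idx], function(ch) {
    ch$t_start < end0 && ch$t_end > start0
  }, logical(1))]
  if (length(cand) == 0) return(unmapped)
  scores <- vapply(chains$chains[cand], `[[`, numeric(1), "score")
  ch <- chains$chains[[cand[which.max(scores)]]]
  tpos <- ch$t_start; qpos <- ch$q_start
  covered <- 0; qmin <- Inf; qmax <- -Inf
  for (i in seq_len(nrow(ch$blocks))) {
    size <- ch$blocks[i, "size"]
    ov <- min(end0, tpos + size) - max(start0, tpos)
    if (ov > 0) {
      off <- max(start0, tpos) - tpos
      covered <- covered + ov
      qmin <- min(qmin, qpos + off)
      qmax <- max(qmax, qpos + off + ov)
    }
    tpos <- tpos + size + ch$blocks[i, "dt"]
    qpos <- qpos + size + ch$blocks[i, "dq"]
    if (tpos >= end0) break
  }
  if (covered == 0) return(unmapped)
  if (ch$q_strand == "-") {
    fwd_lo <- ch$q_size - qmax; fwd_hi <- ch$q_size - qmin
  } else {
    fwd_lo <- qmin; fwd_hi <- qmax
  }
  if ((fwd_hi - fwd_lo) / (end0 - start0) > max_expansion) {
    return(unmapped)
  }
  data.frame(mapped_ratio = covered / (end0 - start0),
             target_chrom = ch$q_chrom,
             target_start = fwd_lo, target_end = fwd_hi,
             chain_id = ch$id, stringsAsFactors = FALSE)
}

#' Map every interval of a set
#'
#' @param set A `GRanges`.
#' @param chains A `chain_set`.
#' @param max_expansion See [map_interval()].
#' @return A data.frame with one row per element (query coordinates plus the
#'   [map_interval()] columns).
#' @export
map_intervals <- function(set, chains, max_expansion = 10) {
  chrom <- as.character(GenomeInfoDb::seqnames(set))
  s0 <- BiocGenerics::start(set) - 1
  e0 <- BiocGenerics::end(set)
  if (length(set) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mapped_ratio = numeric(),
                      target_chrom = character(), target_start = numeric(),
                      target_end = numeric(), chain_id = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(set), function(i) {
    map_interval(chrom[i], s0[i], e0[i], chains, max_expansion)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cbind(data.frame(chrom = chrom, start = s0, end = e0), out)
}

#' Fraction of a set conserved at a mapping-ratio threshold
#'
#' An element counts as conserved when its mapped ratio is at least
#' `min_ratio` (inclusive).
#'
#' @param set A `GRanges`.
#' @param chains A `chain_set`.
#' @param min_ratio Threshold in (0, 1].
#' @param mapping Optional precomputed [map_intervals()] table.
#' @return A list with `fraction` (`NA` for an empty set, with a warning) and
#'   the per-element mapping `table` with a logical `conserved` column.
#' @export
conservation_fraction <- function(set, chains, min_ratio = 0.5,
                                  mapping = NULL) {
  stopifnot(min_ratio > 0, min_ratio <= 1)
  if (length(set) == 0) {
    warning("empty interval set: conservation fraction undefined")
    tab <- map_intervals(set, chains)
    tab$conserved <- logical(0)
    return(list(fraction = NA_real_, table = tab))
  }
  if (is.null(mapping)) mapping <- map_intervals(set, chains)
  mapping$conserved <- mapping$mapped_ratio >= min_ratio
  list(fraction = mean(mapping$conserved), table = mapping)
}

#' Conservation fraction over a sweep of thresholds
#'
#' @param set A `GRanges`.
#' @param chains A `chain_set`.
#' @param ratios Strictly increasing thresholds in (0, 1].
#' @return A data.frame `ratio` / `fraction`; fractions are non-increasing in
#'   the threshold by construction.
#' @export
threshold_sweep <- function(set, chains, ratios) {
  if (length(ratios) == 0) {
    return(data.frame(ratio = numeric(), fraction = numeric()))
  }
  if (any(diff(ratios) <= 0) || any(ratios <= 0) || any(ratios > 1)) {
    stop("ratios must be strictly increasing within (0, 1]")
  }
  mapping <- map_intervals(set, chains)
  frac <- vapply(ratios, function(r) {
    if (length(set) == 0) NA_real_ else mean(mapping$mapped_ratio >= r)
  }, numeric(1))
  data.frame(ratio = ratios, fraction = frac)
}
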