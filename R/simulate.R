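# Synthetic epigenome generator with planted ground truth.
#
# Emits toy genomes, multi-context peak libraries over planted enhancer
# classes, chain files with planted mapping ratios, promoter-state and loop
# annotations, and distance-decaying contact matrices with planted loop
# enrichments. Every generator is seeded deterministically from the config
# seed (fixed per-generator offsets), and every emitted record is traceable to
# the truth manifest or to declared background noise.
#
# Placement rules guarantee unambiguous recovery: planted elements keep clear
# of TSS windows and of each other by more than any extension used downstream,
# and noise peaks carry per-site mark signatures that no calling rule accepts
# (ATAC only, H3K27ac only, H3K27me3 only, or H3K4me1+H3K27me3).

#' Simulation configuration
#'
#' Defaults emulate the study conditions at desk scale: three in vitro
#' pluripotent contexts, 200 planted enhancers over four classes, broad/narrow
#' peak dialects with the pipeline's fold and q thresholds, noise peaks at
#' 5 sites per Mb per mark, 70-80% of poised elements within 3 kb of a CGI,
#' loops at 25 kb-2 Mb sizes with p-values straddling the p < 0.01 filter, and
#' contact matrices with power-law distance decay at 5 kb resolution.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param chrom_lengths Named vector of toy chromosome lengths.
#' @param n_tss Total TSS count (split across chromosomes by length).
#' @param n_poised,n_active,n_primed,n_poiact Planted counts per class.
#' @param contexts Cell-state labels for the in vitro peak library.
#' @param peak_widths Candidate element widths (bp; multiples of 20 so planted
#'   mapping ratios are exactly representable).
#' @param min_tss_dist Minimum gap between a planted element and any TSS (bp).
#' @param min_element_spacing Minimum spacing between planted elements (bp).
#' @param noise_rate Noise sites per Mb per mark.
#' @param noise_min_dist Minimum distance of a noise site from planted
#'   elements and other noise sites (bp).
#' @param cgi_fraction Fraction of poised/poiact elements given a CGI within
#'   3 kb.
#' @param cgi_overlap_fraction Share of those CGIs placed inside their element
#'   (exact overlap) rather than flanking it.
#' @param loop_max_sep Maximum anchor separation (bp); separations prefer the
#'   intra-TAD range (70% below 0.6 TAD sizes).
#' @param n_cgi_background Background CGIs unrelated to planted elements.
#' @param tad_size,tad_gap TAD tiling period and inter-TAD gap (bp).
#' @param n_pcg PcG domains (planted as EED+RING1B replicate peak support).
#' @param state_probs Promoter-state probabilities (bivalent, k27me3_only,
#'   k4me3_only, unmarked).
#' @param ratio_levels,ratio_probs Planted mapping-ratio levels and their
#'   proportions for the chain generator.
#' @param n_loops_pe_promoter,n_loops_pe_pe,n_loops_pe_pcg,n_loops_background
#'   Planted loop counts per category.
#' @param loop_bivalent_pref Probability that a PE-promoter loop targets a
#'   bivalent promoter.
#' @param anchor_width Loop anchor width (bp).
#' @param n_bins,resolution,decay_alpha,diag_intensity,loop_enrichment,
#'   n_contact_pairs Contact-matrix shape: bins per chromosome, bin size (bp),
#'   decay exponent, expected count at zero separation, planted center
#'   enrichment factor, number of planted pairs.
#' @param contact_halfwidth Pileup window half-width (bp) the planted pairs
#'   must clear from the chromosome edges.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chrS1 = 10e6, chrS2 = 10e6),
                       n_tss = 300,
                       n_poised = 60, n_active = 60, n_primed = 50,
                       n_poiact = 30,
                       contexts = c("naive", "serum", "formative"),
                       peak_widths = seq(800, 2000, by = 20),
                       min_tss_dist = 16000,
                       min_element_spacing = 14000,
                       noise_rate = 5,
                       noise_min_dist = 8000,
                       cgi_fraction = 0.75,
                       n_cgi_background = 40,
                       tad_size = 1e6, tad_gap = 50000,
                       n_pcg = 12,
                       state_probs = c(bivalent = 0.2, k27me3_only = 0.05,
                                       k4me3_only = 0.5, unmarked = 0.25),
                       ratio_levels = c(0, 0.3, 0.6, 1),
                       ratio_probs = c(0.2, 0.2, 0.25, 0.35),
                       n_loops_pe_promoter = 40, n_loops_pe_pe = 15,
                       n_loops_pe_pcg = 15, n_loops_background = 30,
                       loop_bivalent_pref = 0.7,
                       loop_max_sep = 1.8e6,
                       anchor_width = 5000,
                       cgi_overlap_fraction = 0.5,
                       n_bins = 500, resolution = 5000, decay_alpha = 1,
                       diag_intensity = 10000, loop_enrichment = 5,
                       n_contact_pairs = 100, contact_halfwidth = 250000) {
  cfg <- as.list(environment())
  stopifnot(cfg$noise_rate >= 0, cfg$decay_alpha > 0,
            abs(sum(state_probs) - 1) < 1e-9,
            abs(sum(ratio_probs) - 1) < 1e-9,
            length(ratio_levels) == length(ratio_probs))
  structure(cfg, class = "sim_config")
}

## place n points on [lo, hi] with pairwise spacing >= min_sp, avoiding
## forbidden points by >= avoid_dist (or a per-row avoid$dist); seeded by
## caller
place_spaced <- function(n, chrom_lengths, min_sp, avoid = NULL,
                         avoid_dist = 0, max_tries = 50000) {
  if (!is.null(avoid) && is.null(avoid$dist)) avoid$dist <- avoid_dist
  chroms <- names(chrom_lengths)
  placed_chrom <- character(0)
  placed_pos <- numeric(0)
  tries <- 0
  while (length(placed_pos) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("generation error: infeasible spacing (placed ",
           length(placed_pos), "/", n, ")")
    }
    ch <- sample(chroms, 1, prob = chrom_lengths / sum(chrom_lengths))
    pos <- floor(stats::runif(1, min_sp, chrom_lengths[[ch]] - min_sp))
    same <- placed_chrom == ch
    if (any(same) && min(abs(placed_pos[same] - pos)) < min_sp) next
    if (!is.null(avoid)) {
      av <- avoid$chrom == ch
      if (any(av) && any(abs(avoid$pos[av] - pos) < avoid$dist[av])) next
    }
    placed_chrom <- c(placed_chrom, ch)
    placed_pos <- c(placed_pos, pos)
  }
  data.frame(chrom = placed_chrom, pos = placed_pos,
             stringsAsFactors = FALSE)
}

#' Simulate the genome annotation
#'
#' Generates TSS (uniformly spaced with a minimum gap, with planted promoter
#' chromatin states), planted enhancer elements of the four classes placed
#' distally from every TSS, CGIs (a configurable fraction of poised elements
#' gets one within 3 kb), TADs tiling each chromosome with gaps, and PcG
#' domains clear of TSS and planted elements.
#'
#' @param cfg A [sim_config()].
#' @return A list: `genome`, `tss` (data.frame with `state`), `elements`
#'   (`GRanges` with `class`), `cgis`, `tads`, `pcg` (`GRanges`), and `truth`.
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed + 101)
  genome <- cfg$chrom_lengths
  ## TSS on a jittered grid per chromosome
  n_per <- round(cfg$n_tss * genome / sum(genome))
  tss <- do.call(rbind, lapply(names(genome), function(ch) {
    n <- n_per[[ch]]
    spacing <- genome[[ch]] / n
    if (spacing < 2 * cfg$min_tss_dist) {
      stop("generation error: infeasible TSS spacing on ", ch)
    }
    pos <- floor((seq_len(n) - 1 + 0.1 + 0.8 * stats::runif(n)) * spacing)
    data.frame(chrom = ch, position = pos, stringsAsFactors = FALSE)
  }))
  tss$gene_id <- sprintf("gene%04d", seq_len(nrow(tss)))
  tss$strand <- sample(c("+", "-"), nrow(tss), replace = TRUE)
  tss$state <- sample(names(cfg$state_probs), nrow(tss), replace = TRUE,
                      prob = cfg$state_probs)
  tss <- tss[, c("gene_id", "chrom", "position", "strand", "state")]

  ## planted elements, clear of TSS and of each other
  n_el <- cfg$n_poised + cfg$n_active + cfg$n_primed + cfg$n_poiact
  widths <- sample(cfg$peak_widths, n_el, replace = TRUE)
  mids <- place_spaced(n_el, genome,
                       min_sp = cfg$min_element_spacing,
                       avoid = data.frame(chrom = tss$chrom,
                                          pos = tss$position),
                       avoid_dist = cfg$min_tss_dist + max(cfg$peak_widths))
  classes <- sample(rep(c("poised", "active", "primed", "poiact"),
                        c(cfg$n_poised, cfg$n_active, cfg$n_primed,
                          cfg$n_poiact)))
  start0 <- mids$pos - widths %/% 2
  elements <- gr_from_bed0(mids$chrom, start0, start0 + widths,
                           genome = genome)
  S4Vectors::mcols(elements)$class <- classes
  S4Vectors::mcols(elements)$element_id <-
    sprintf("el%04d", seq_len(n_el))

  ## CGIs: near a fraction of poised/poiact elements, plus background
  pe_idx <- which(classes %in% c("poised", "poiact"))
  near <- pe_idx[stats::runif(length(pe_idx)) < cfg$cgi_fraction]
  cgi_w <- 500
  ## a configurable share of the CGIs overlaps its element (exact overlap),
  ## the rest sit within 3 kb of an edge
  inside <- stats::runif(length(near)) < cfg$cgi_overlap_fraction
  side <- sample(c(-1, 1), length(near), replace = TRUE)
  off <- floor(stats::runif(length(near), 0, 2500))
  cgi_start <- ifelse(inside,
                      start0[near] + pmax(0, widths[near] %/% 2 - cgi_w %/% 2),
                      ifelse(side < 0,
                             start0[near] - off - cgi_w,
                             start0[near] + widths[near] + off))
  cgi_chrom <- mids$chrom[near]
  bg <- place_spaced(cfg$n_cgi_background, genome, min_sp = 5000,
                     avoid = data.frame(chrom = mids$chrom, pos = mids$pos),
                     avoid_dist = cfg$min_element_spacing)
  cgis <- gr_from_bed0(c(cgi_chrom, bg$chrom),
                       c(cgi_start, bg$pos),
                       c(cgi_start + cgi_w, bg$pos + cgi_w),
                       genome = genome)
  S4Vectors::mcols(cgis)$near_pe <- c(rep(TRUE, length(near)),
                                      rep(FALSE, nrow(bg)))

  ## TADs tiling with gaps
  tads <- do.call(rbind, lapply(names(genome), function(ch) {
    starts <- seq(0, genome[[ch]] - cfg$tad_size, by = cfg$tad_size)
    data.frame(chrom = ch, start = starts,
               end = starts + cfg$tad_size - cfg$tad_gap)
  }))
  tads <- gr_from_bed0(tads$chrom, tads$start, tads$end, genome = genome)

  ## PcG domains: far enough from TSS (promoter windows + anchor extension)
  ## and planted elements (seed overlap + anchor extension) that loop anchors
  ## placed on them can only annotate as PcG
  pcg_w <- 20000
  pcg_mid <- place_spaced(cfg$n_pcg, genome, min_sp = 60000,
                          avoid = data.frame(
                            chrom = c(tss$chrom, mids$chrom),
                            pos = c(tss$position, mids$pos),
                            dist = c(rep(22000, nrow(tss)),
                                     rep(26000, nrow(mids)))))
  pcg <- gr_from_bed0(pcg_mid$chrom, pcg_mid$pos - pcg_w / 2,
                      pcg_mid$pos + pcg_w / 2, genome = genome)

  list(genome = genome, tss = tss, elements = elements, cgis = cgis,
       tads = tads, pcg = pcg,
       truth = list(classes = classes,
                    cgi_near_idx = near,
                    promoter_states = stats::setNames(tss$state, tss$gene_id)))
}

## peak GRanges with metadata drawn above (planted) / around (noise) thresholds
mk_peak_records <- function(gr, min_fold, max_q, planted = TRUE) {
  n <- length(gr)
  if (planted) {
    fold <- min_fold * stats::runif(n, 1.25, 3)
    q <- max_q * stats::runif(n, 0.005, 0.9)
  } else {
    fold <- min_fold * stats::runif(n, 0.5, 1.6)
    q <- max_q * stats::runif(n, 0.3, 1.8)
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("pk%05d", seq_len(n)),
    fold_enrichment = round(fold, 4),
    p_value = signif(q / 3, 4),
    q_value = signif(q, 4),
    summit_offset = as.integer(BiocGenerics::width(gr) %/% 2))
  gr
}

#' Simulate the multi-context peak library
#'
#' For each planted element, peaks are emitted per mark according to its class
#' signature in each context (poised/poiact: ATAC+H3K4me1+H3K27me3, no
#' H3K27ac; active: ATAC+H3K4me1+H3K27ac; primed: H3K4me1 only); poiact
#' elements additionally appear in the later-stage H3K27ac set. Promoter-state
#' H3K4me3/H3K27me3 peaks, EED/RING1B replicate peaks over PcG domains, and
#' per-mark noise peaks with non-callable signatures complete the library.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list: `marks` (context -> mark -> peak `GRanges`), `later`
#'   (later-stage H3K27ac), `promoter_marks`, `eed`/`ring1b` replicate lists,
#'   `noise` (site table).
#' @export
simulate_peak_library <- function(cfg, ann) {
  set.seed(cfg$seed + 202)
  el <- ann$elements
  cls <- S4Vectors::mcols(el)$class
  genome <- ann$genome
  params <- calling_params()

  sig <- list(poised = c("ATAC", "H3K4me1", "H3K27me3"),
              poiact = c("ATAC", "H3K4me1", "H3K27me3"),
              active = c("ATAC", "H3K4me1", "H3K27ac"),
              primed = "H3K4me1")
  all_marks <- c("ATAC", "H3K4me1", "H3K27me3", "H3K27ac")

  ## noise sites with safe signatures
  n_noise <- round(cfg$noise_rate * sum(genome) / 1e6)
  el_mid <- floor((BiocGenerics::start(el) - 1 + BiocGenerics::end(el)) / 2)
  noise_sites <- if (n_noise > 0) {
    place_spaced(n_noise, genome, min_sp = cfg$noise_min_dist,
                 avoid = data.frame(
                   chrom = as.character(GenomeInfoDb::seqnames(el)),
                   pos = el_mid),
                 avoid_dist = cfg$noise_min_dist)
  } else data.frame(chrom = character(), pos = numeric())
  safe_sigs <- list("ATAC", "H3K27ac", "H3K27me3", c("H3K4me1", "H3K27me3"))
  noise_sig <- sample(seq_along(safe_sigs), nrow(noise_sites), replace = TRUE)

  marks <- list()
  for (ctx in cfg$contexts) {
    marks[[ctx]] <- list()
    for (mk in all_marks) {
      has <- vapply(cls, function(cl) mk %in% sig[[cl]], logical(1))
      planted <- mk_peak_records(granges_bare(el[has]),
                                 params$min_fold[[mk]], params$max_q[[mk]])
      ns <- which(vapply(noise_sig, function(s) mk %in% safe_sigs[[s]],
                         logical(1)))
      if (length(ns) > 0) {
        nw <- 1000
        ngr <- gr_from_bed0(noise_sites$chrom[ns],
                            noise_sites$pos[ns] - nw / 2,
                            noise_sites$pos[ns] + nw / 2, genome = genome)
        ## the H3K27me3 companion of a K4me1-bearing noise site must clear its
        ## filter, otherwise the lone K4me1 peak would call a spurious primed
        ## enhancer; all other noise folds straddle their thresholds
        supra <- mk == "H3K27me3" &
          vapply(noise_sig[ns], function(s) {
            "H3K4me1" %in% safe_sigs[[s]]
          }, logical(1))
        noise <- mk_peak_records(ngr, params$min_fold[[mk]],
                                 params$max_q[[mk]], planted = FALSE)
        if (any(supra)) {
          sup <- mk_peak_records(ngr[supra], params$min_fold[[mk]],
                                 params$max_q[[mk]], planted = TRUE)
          noise <- suppressWarnings(c(noise[!supra], sup))
        }
        planted <- interval_union(planted, noise)
      }
      marks[[ctx]][[mk]] <- planted
    }
  }

  ## later-stage H3K27ac over poiact elements (AntNPC-like thresholds)
  po <- granges_bare(el[cls == "poiact"])
  later <- mk_peak_records(po, min_fold = 5, max_q = 0.1)

  ## promoter-state marks around the TSS
  tss <- ann$tss
  pw <- 800
  st_gr <- function(states) {
    sel <- tss$state %in% states
    gr_from_bed0(tss$chrom[sel], pmax(0, tss$position[sel] - pw),
                 tss$position[sel] + pw, genome = genome)
  }
  promoter_marks <- list(
    H3K4me3 = mk_peak_records(st_gr(c("bivalent", "k4me3_only")),
                              min_fold = 2, max_q = 0.1),
    H3K27me3 = mk_peak_records(st_gr(c("bivalent", "k27me3_only")),
                               min_fold = 2, max_q = 0.1))

  ## EED / RING1B replicates supporting the PcG domains; each replicate adds
  ## private noise peaks removed by the replicate intersection
  rep_set <- function(tag) {
    lapply(1:3, function(r) {
      priv <- place_spaced(5, genome, min_sp = cfg$noise_min_dist,
                           avoid = data.frame(
                             chrom = as.character(GenomeInfoDb::seqnames(el)),
                             pos = el_mid),
                           avoid_dist = cfg$noise_min_dist)
      pgr <- gr_from_bed0(priv$chrom, priv$pos, priv$pos + 1000,
                          genome = genome)
      mk_peak_records(suppressWarnings(c(granges_bare(ann$pcg), pgr)),
                      min_fold = 2, max_q = 0.1)
    })
  }
  list(marks = marks, later = later, promoter_marks = promoter_marks,
       eed = rep_set("eed"), ring1b = rep_set("ring1b"),
       noise = cbind(noise_sites,
                     signature = vapply(noise_sig, function(s) {
                       paste(safe_sigs[[s]], collapse = "+")
                     }, character(1))))
}

#' Simulate a pairwise alignment chain with planted mapping ratios
#'
#' Builds one whole-chromosome chain per source chromosome to a same-length
#' destination genome, with alignment gaps placed inside planted elements so
#' that each attains its prescribed mapped ratio exactly. Ratios are assigned
#' from `cfg$ratio_levels` in the prescribed proportions.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list: `chains` (a `chain_set`), `ratios` (per-element planted
#'   ratio, in element order), `dest_genome`.
#' @export
simulate_chain <- function(cfg, ann) {
  set.seed(cfg$seed + 303)
  el <- ann$elements
  genome <- ann$genome
  n <- length(el)
  counts <- floor(cfg$ratio_probs * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[length(counts)] <- counts[length(counts)] + rem
  ratios <- sample(rep(cfg$ratio_levels, counts))
  w <- BiocGenerics::width(el)
  aligned <- round(ratios * w)
  if (any(abs(aligned - ratios * w) > 1e-9)) {
    stop("generation error: prescribed ratio unreachable at base granularity")
  }
  dest <- stats::setNames(genome, paste0(names(genome), "_b"))
  chains <- list()
  for (ci in seq_along(genome)) {
    ch_name <- names(genome)[ci]
    on_ch <- which(as.character(GenomeInfoDb::seqnames(el)) == ch_name)
    on_ch <- on_ch[order(BiocGenerics::start(el)[on_ch])]
    ## run-length walk: aligned outside elements, gap for unaligned suffixes
    segs_len <- numeric(0); segs_al <- logical(0)
    pos <- 0
    for (i in on_ch) {
      s0 <- BiocGenerics::start(el)[i] - 1; e0 <- BiocGenerics::end(el)[i]
      if (s0 > pos) { segs_len <- c(segs_len, s0 - pos); segs_al <- c(segs_al, TRUE) }
      if (aligned[i] > 0) {
        segs_len <- c(segs_len, aligned[i]); segs_al <- c(segs_al, TRUE)
      }
      if (e0 - s0 - aligned[i] > 0) {
        segs_len <- c(segs_len, e0 - s0 - aligned[i])
        segs_al <- c(segs_al, FALSE)
      }
      pos <- e0
    }
    if (pos < genome[[ci]]) {
      segs_len <- c(segs_len, genome[[ci]] - pos); segs_al <- c(segs_al, TRUE)
    }
    ## collapse adjacent aligned runs, convert to (size, dt, dq) triples
    sizes <- numeric(0); dts <- numeric(0)
    i <- 1
    while (i <= length(segs_len)) {
      if (!segs_al[i]) {  # leading gap cannot start a chain: absorb minimally
        sizes <- c(sizes, 1); dts <- c(dts, segs_len[i] - 1)
        i <- i + 1
        next
      }
      run <- 0
      while (i <= length(segs_len) && segs_al[i]) {
        run <- run + segs_len[i]; i <- i + 1
      }
      gap <- 0
      while (i <= length(segs_len) && !segs_al[i]) {
        gap <- gap + segs_len[i]; i <- i + 1
      }
      sizes <- c(sizes, run); dts <- c(dts, gap)
    }
    dts[length(dts)] <- 0  # final block carries no gap
    t_end <- sum(sizes) + sum(dts)
    chains[[ci]] <- list(score = 1e6 - ci,
                         t_chrom = ch_name, t_size = genome[[ci]],
                         t_strand = "+", t_start = 0, t_end = t_end,
                         q_chrom = paste0(ch_name, "_b"),
                         q_size = genome[[ci]], q_strand = "+",
                         q_start = 0, q_end = t_end,
                         id = as.character(ci),
                         blocks = cbind(size = sizes, dt = dts, dq = dts))
  }
  cs <- structure(list(chains = chains,
                       by_chrom = split(seq_along(chains),
                                        vapply(chains, `[[`, character(1),
                                               "t_chrom"))),
                  class = "chain_set")
  list(chains = cs, ratios = ratios, dest_genome = dest)
}

#' Simulate a loop list with planted categories and TAD statuses
#'
#' Plants PE-promoter, PE-PE, PE-PcG and background loops with p/q values
#' straddling the significance filter; promoter partners prefer bivalent TSS.
#' The truth table records each loop's category, significance and TAD status
#' (computed from the generator's own interval arithmetic).
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list: `loops` (a `loop_set`), `truth` (data.frame per loop).
#' @export
simulate_loops <- function(cfg, ann) {
  set.seed(cfg$seed + 404)
  el <- ann$elements
  cls <- S4Vectors::mcols(el)$class
  pe_idx <- which(cls %in% c("poised", "poiact"))
  aw <- cfg$anchor_width
  min_sep <- 30000
  el_chrom <- as.character(GenomeInfoDb::seqnames(el))
  el_mid <- floor((BiocGenerics::start(el) - 1 + BiocGenerics::end(el)) / 2)
  tss <- ann$tss
  pcg_chrom <- as.character(GenomeInfoDb::seqnames(ann$pcg))
  pcg_mid <- floor((BiocGenerics::start(ann$pcg) - 1 +
                      BiocGenerics::end(ann$pcg)) / 2)

  ## separation drawn from a short/long mixture so that contacts prefer the
  ## intra-TAD range while still spanning the 25 kb - 1.8 Mb loop-size band
  draw_max_sep <- function() {
    if (stats::runif(1) < 0.7) cfg$tad_size * 0.6 else cfg$loop_max_sep
  }
  pick_pair <- function(c1, p1_pool, c2, p2_pool, tries = 5000) {
    max_sep <- draw_max_sep()
    for (t in seq_len(tries)) {
      i <- sample(length(p1_pool), 1)
      j <- sample(length(p2_pool), 1)
      if (c1[i] != c2[j]) next
      d <- abs(p1_pool[i] - p2_pool[j])
      if (d < min_sep || d > max_sep) next
      return(c(i, j))
    }
    stop("generation error: could not place loop pair")
  }

  rows <- list(); truth <- list()
  add_loop <- function(chrom, m1, m2, category, sig) {
    if (m1 > m2) { tmp <- m1; m1 <- m2; m2 <- tmp }
    p <- if (sig) stats::runif(1, 1e-4, 9e-3) else stats::runif(1, 0.02, 0.6)
    rows[[length(rows) + 1]] <<- data.frame(
      chrom = chrom, start1 = m1 - aw / 2, end1 = m1 + aw / 2,
      start2 = m2 - aw / 2, end2 = m2 + aw / 2,
      pet_count = 5 + stats::rpois(1, 20), p_value = signif(p, 4),
      q_value = signif(pmin(0.99, p * 2), 4), stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <<- data.frame(
      category = category, significant = sig, stringsAsFactors = FALSE)
  }

  ## PE-promoter: biased toward bivalent promoters
  for (k in seq_len(cfg$n_loops_pe_promoter)) {
    biv <- stats::runif(1) < cfg$loop_bivalent_pref
    pool <- which(if (biv) tss$state == "bivalent" else tss$state != "bivalent")
    ij <- pick_pair(el_chrom[pe_idx], el_mid[pe_idx],
                    tss$chrom[pool], tss$position[pool])
    add_loop(el_chrom[pe_idx][ij[1]], el_mid[pe_idx][ij[1]],
             tss$position[pool][ij[2]], "promoter", sig = TRUE)
  }
  for (k in seq_len(cfg$n_loops_pe_pe)) {
    repeat {
      ij <- pick_pair(el_chrom[pe_idx], el_mid[pe_idx],
                      el_chrom[pe_idx], el_mid[pe_idx])
      if (ij[1] != ij[2]) break
    }
    add_loop(el_chrom[pe_idx][ij[1]], el_mid[pe_idx][ij[1]],
             el_mid[pe_idx][ij[2]], "seed_element", sig = TRUE)
  }
  for (k in seq_len(cfg$n_loops_pe_pcg)) {
    ij <- pick_pair(el_chrom[pe_idx], el_mid[pe_idx], pcg_chrom, pcg_mid)
    add_loop(el_chrom[pe_idx][ij[1]], el_mid[pe_idx][ij[1]],
             pcg_mid[ij[2]], "pcg_domain", sig = TRUE)
  }
  ## background: anchors away from planted elements, paired within chromosome
  bg <- place_spaced(4 * cfg$n_loops_background, ann$genome, min_sp = 12000,
                     avoid = data.frame(chrom = el_chrom, pos = el_mid),
                     avoid_dist = 25000)
  used <- rep(FALSE, nrow(bg))
  for (k in seq_len(cfg$n_loops_background)) {
    placed <- FALSE
    max_sep <- draw_max_sep()
    for (t in seq_len(5000)) {
      ij <- sample(which(!used), 2)
      d <- abs(bg$pos[ij[1]] - bg$pos[ij[2]])
      if (bg$chrom[ij[1]] != bg$chrom[ij[2]] || d < min_sep ||
          d > max_sep) next
      used[ij] <- TRUE
      add_loop(bg$chrom[ij[1]], bg$pos[ij[1]], bg$pos[ij[2]], "other",
               sig = k %% 3 == 0)
      placed <- TRUE
      break
    }
    if (!placed) stop("generation error: could not place background loop")
  }

  df <- do.call(rbind, rows)
  tr <- do.call(rbind, truth)
  ## generator-side TAD status by base arithmetic (independent of the module)
  tad_chrom <- as.character(GenomeInfoDb::seqnames(ann$tads))
  tad_s <- BiocGenerics::start(ann$tads) - 1
  tad_e <- BiocGenerics::end(ann$tads)
  tad_of <- function(chrom, mid) {
    vapply(seq_along(chrom), function(i) {
      hit <- which(tad_chrom == chrom[i] & tad_s <= mid[i] & mid[i] < tad_e)
      if (length(hit) == 0) NA_integer_ else hit[1]
    }, integer(1))
  }
  m1 <- floor((df$start1 + df$end1) / 2)
  m2 <- floor((df$start2 + df$end2) / 2)
  t1 <- tad_of(df$chrom, m1); t2 <- tad_of(df$chrom, m2)
  tr$tad_status <- ifelse(is.na(t1) | is.na(t2), "unassigned",
                          ifelse(t1 == t2, "intra", "inter"))
  tr$p_value <- df$p_value
  list(loops = loop_set(df), truth = tr)
}

#' Simulate a distance-decaying contact matrix with planted loop enrichments
#'
#' Expected counts at bin separation d are `diag_intensity / (1 + d)^alpha`;
#' counts are Poisson draws, and the center bin pair of each planted pair is
#' enriched by `loop_enrichment` before drawing.
#'
#' @param cfg A [sim_config()].
#' @param pairs Optional data.frame `pos1`/`pos2` (bp); generated when `NULL`.
#' @param enrichment Planted center enrichment (defaults to
#'   `cfg$loop_enrichment`).
#' @return A list: `matrix` (a raw `contact_matrix` on a dedicated toy
#'   chromosome), `pairs`, `enrichment`.
#' @export
simulate_contacts <- function(cfg, pairs = NULL,
                              enrichment = cfg$loop_enrichment) {
  set.seed(cfg$seed + 505)
  n <- cfg$n_bins
  res <- cfg$resolution
  w <- as.integer(round(cfg$contact_halfwidth / res))
  if (is.null(pairs)) {
    sep_max <- min(7 * w, n - 2 * w - 2)
    sep_min <- 2 * w + 20
    if (sep_max < sep_min) {
      stop("generation error: n_bins too small for the contact half-width")
    }
    sep <- sample(seq(sep_min, sep_max), cfg$n_contact_pairs, replace = TRUE)
    iA <- vapply(sep, function(s) sample(w:(n - 1 - w - s), 1), numeric(1))
    pairs <- data.frame(pos1 = (iA + 0.5) * res, pos2 = (iA + sep + 0.5) * res)
  }
  b1 <- floor(pairs$pos1 / res); b2 <- floor(pairs$pos2 / res)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- ij[, 1] - 1; j <- ij[, 2] - 1
  lambda <- cfg$diag_intensity / (1 + (j - i))^cfg$decay_alpha
  planted <- paste(b1, b2)
  key <- paste(pmin(b1, b2), pmax(b1, b2))
  enr <- match(paste(i, j), key)
  lambda[!is.na(enr)] <- lambda[!is.na(enr)] * enrichment
  counts <- stats::rpois(length(lambda), lambda)
  keep <- counts > 0
  m <- contact_matrix(data.frame(bin1 = i[keep], bin2 = j[keep],
                                 count = counts[keep]),
                      n_bins = n, chrom = "chrC1", resolution = res)
  list(matrix = m, pairs = pairs, enrichment = enrichment)
}

#' Run every generator and assemble the truth manifest
#'
#' @param cfg A [sim_config()].
#' @return A list with `annotation`, `peaks`, `chain`, `loops`, `contacts`
#'   and a `manifest` (generator parameters, planted classes, ratios, loop
#'   truth, promoter states, contact enrichment).
#' @export
simulate_all <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  pk <- simulate_peak_library(cfg, ann)
  ch <- simulate_chain(cfg, ann)
  lp <- simulate_loops(cfg, ann)
  ct <- simulate_contacts(cfg)
  el <- ann$elements
  manifest <- list(
    seed = cfg$seed,
    genome = as.list(ann$genome),
    elements = data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(el)),
      start = BiocGenerics::start(el) - 1L,
      end = BiocGenerics::end(el),
      class = S4Vectors::mcols(el)$class,
      mapped_ratio = ch$ratios,
      stringsAsFactors = FALSE),
    promoter_states = ann$truth$promoter_states,
    loops = lp$truth,
    contact_enrichment = ct$enrichment,
    n_contact_pairs = nrow(ct$pairs))
  list(annotation = ann, peaks = pk, chain = ch, loops = lp, contacts = ct,
       manifest = manifest)
}
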