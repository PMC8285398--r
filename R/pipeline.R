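# Config-driven orchestration: simulate inputs, then run every analysis stage
# end to end on the emitted files, writing BED/TSV/JSON outputs and a
# machine-readable run report. Progress and per-stage timing go to stderr via
# message(); every file written is deterministic under a fixed seed.

#' Default pipeline settings
#'
#' Stage parameters mirror the pipeline's quoted conventions: TSS +/- 5 kb
#' calling filter, +/- 1 kb broad-peak extension, q <= 0.1 / 0.05 peak
#' filters, loop significance p <= 0.01, +/- 10 kb anchor extension,
#' +/- 7.5 kb TSS anchors, 0.5 mappability threshold, 250 kb pileup
#' half-width, 5 kb resolution.
#'
#' @param seed Integer seed forwarded to the generators.
#' @param overrides Named list overriding [sim_config()] fields or the stage
#'   settings `sweep_ratios`, `loop_max_p`, `anchor_ext`, `tss_anchor_halfwidth`,
#'   `mappability_threshold`, `pileup_halfwidth`, `pileup_normalization`.
#' @return A list with `sim` (a [sim_config()]) and `stages`.
#' @export
pipeline_config <- function(seed = 1, overrides = list()) {
  stages <- list(sweep_ratios = c(0.2, 0.5, 0.8),
                 mappability_threshold = 0.5,
                 loop_max_p = 0.01,
                 anchor_ext = 10000,
                 tss_anchor_halfwidth = 7500,
                 pileup_halfwidth = 250000,
                 pileup_normalization = "expected")
  sim_args <- list(seed = seed)
  for (nm in names(overrides)) {
    if (nm %in% names(stages)) stages[[nm]] <- overrides[[nm]]
    else sim_args[[nm]] <- overrides[[nm]]
  }
  list(sim = do.call(sim_config, sim_args), stages = stages)
}

#' Read a pipeline config from YAML
#'
#' Top-level keys `seed` plus any override accepted by [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A pipeline config list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  y$seed <- NULL
  if (!is.null(y$chrom_lengths)) y$chrom_lengths <- unlist(y$chrom_lengths)
  pipeline_config(seed = seed, overrides = y)
}

stage_msg <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.2fs)", stage, paste0(...),
                  as.numeric(proc.time()[3]) - t0))
}

#' Write simulated inputs to a directory
#'
#' Emits exactly the formats the pipeline reads: chrom.sizes, BED annotations,
#' narrowPeak/broadPeak libraries, a chain file, a BEDPE loop list, a COO
#' contact matrix and a JSON truth manifest.
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- sim$annotation
  p <- function(...) file.path(dir, paste0(...))
  writeLines(sprintf("%s\t%d", names(ann$genome), as.integer(ann$genome)),
             p("genome.chrom.sizes"))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ann$tss$chrom,
                     ann$tss$position, ann$tss$position + 1L,
                     ann$tss$gene_id, ann$tss$strand), p("tss.bed"))
  write_bed(ann$cgis, p("cgi.bed"))
  write_bed(ann$tads, p("tads.bed"))
  for (ctx in names(sim$peaks$marks)) {
    for (mk in names(sim$peaks$marks[[ctx]])) {
      dialect <- if (mk %in% c("ATAC", "p300")) "narrowPeak" else "broadPeak"
      write_peaks(sim$peaks$marks[[ctx]][[mk]],
                  p(ctx, "_", mk, ".", dialect), dialect)
    }
  }
  write_peaks(sim$peaks$later, p("later_H3K27ac.broadPeak"), "broadPeak")
  write_peaks(sim$peaks$promoter_marks$H3K4me3,
              p("promoter_H3K4me3.broadPeak"), "broadPeak")
  write_peaks(sim$peaks$promoter_marks$H3K27me3,
              p("promoter_H3K27me3.broadPeak"), "broadPeak")
  for (r in 1:3) {
    write_peaks(sim$peaks$eed[[r]], p("eed_rep", r, ".narrowPeak"),
                "narrowPeak")
    write_peaks(sim$peaks$ring1b[[r]], p("ring1b_rep", r, ".narrowPeak"),
                "narrowPeak")
  }
  write_chain(sim$chain$chains, p("toy.chain"))
  write_bedpe(sim$loops$loops, p("loops.bedpe"))
  write_coo(sim$contacts$matrix, p("contacts.coo"))
  manifest <- sim$manifest
  manifest$contact_pairs <- sim$contacts$pairs
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full pipeline on a simulated fixture
#'
#' Simulates inputs, writes them under `outdir/inputs`, reads them back
#' through the package's own readers, and runs every stage: enhancer calling,
#' conservation sweep, loop topology, association statistics, and contact
#' pileups. Outputs (BED/TSV/JSON plus `report.json`) are deterministic under
#' a fixed seed; progress and timings go to stderr only.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param config Optional pipeline config (list from [pipeline_config()] or a
#'   YAML path); its seed is overridden by `seed` when both are given.
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_all <- function(outdir, seed = 1, config = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config)) config <- pipeline_config(seed = seed)
  config$sim$seed <- seed
  st <- config$stages
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version =
                   as.character(utils::packageVersion("poisedR")),
                 seed = seed,
                 settings = st)
  t0 <- as.numeric(proc.time()[3])

  ## simulate + write + read back
  sim <- simulate_all(config$sim)
  indir <- file.path(outdir, "inputs")
  write_simulation(sim, indir)
  stage_msg("simulate", t0, "inputs written to ", indir)
  genome <- read_chrom_sizes(file.path(indir, "genome.chrom.sizes"))
  tss <- read_tss(file.path(indir, "tss.bed"), genome)
  cgis <- read_bed(file.path(indir, "cgi.bed"), genome)
  tads <- read_bed(file.path(indir, "tads.bed"), genome)
  marks <- list()
  for (ctx in config$sim$contexts) {
    marks[[ctx]] <- list()
    for (mk in c("ATAC", "H3K4me1", "H3K27me3", "H3K27ac")) {
      dialect <- if (mk %in% c("ATAC", "p300")) "narrowPeak" else "broadPeak"
      marks[[ctx]][[mk]] <- read_peaks(
        file.path(indir, paste0(ctx, "_", mk, ".", dialect)), dialect, genome)
    }
  }

  ## enhancer calling
  params <- calling_params()
  poised <- call_poised_invitro(marks, tss, params)
  active <- call_active_invitro(marks, tss, params)
  primed <- call_primed_invitro(marks, tss, params)
  res <- resolve_class_overlaps(poised, active, primed)
  later <- read_peaks(file.path(indir, "later_H3K27ac.broadPeak"),
                      "broadPeak", genome)
  pa <- call_poiact(res$poised, list(list(peaks = later, min_fold = 5,
                                          max_q = 0.1, extension = 1000)))
  calls <- list(poised = pa$poised, active = res$active,
                primed = res$primed, poiact = pa$poiact)
  for (cl in names(calls)) {
    gr <- calls[[cl]]
    S4Vectors::mcols(gr)$name <- rep(cl, length(gr))
    write_bed(gr, file.path(outdir, paste0("enhancers_", cl, ".bed")))
  }
  prov <- do.call(rbind, lapply(names(calls), function(cl) {
    gr <- calls[[cl]]
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               class = cl,
               contexts = S4Vectors::mcols(gr)$source_contexts,
               provenance = S4Vectors::mcols(gr)$provenance)
  }))
  utils::write.table(prov, file.path(outdir, "provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$enhancers <- lapply(calls, length)
  stage_msg("call-enhancers", t0,
            sprintf("poised=%d active=%d primed=%d poiact=%d",
                    length(calls$poised), length(calls$active),
                    length(calls$primed), length(calls$poiact)))

  ## conservation
  chains <- read_chain(file.path(indir, "toy.chain"))
  pe_all <- interval_merge(interval_union(calls$poised, calls$poiact))
  sweep <- threshold_sweep(pe_all, chains, st$sweep_ratios)
  utils::write.table(sweep, file.path(outdir, "conservation_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cons <- conservation_fraction(pe_all, chains, st$mappability_threshold)
  report$conservation <- list(
    threshold = st$mappability_threshold,
    fraction = cons$fraction,
    sweep = stats::setNames(sweep$fraction, sweep$ratio))
  stage_msg("conserve", t0, sprintf("fraction@%.2f = %.4f",
                                    st$mappability_threshold, cons$fraction))

  ## loop topology
  loops <- read_bedpe(file.path(indir, "loops.bedpe"),
                      col_map = list(pet = 7, p = 8, q = 9))
  sig <- filter_loops(loops, max_p = st$loop_max_p)
  pcg <- call_pcg_domains(
    lapply(1:3, function(r) read_peaks(
      file.path(indir, paste0("eed_rep", r, ".narrowPeak")), "narrowPeak",
      genome)),
    lapply(1:3, function(r) read_peaks(
      file.path(indir, paste0("ring1b_rep", r, ".narrowPeak")), "narrowPeak",
      genome)))
  hier <- annotation_hierarchy(tss = tss, seeds = pe_all, pcg = pcg,
                               tss_halfwidth = st$tss_anchor_halfwidth)
  ann <- annotate_partner(sig, pe_all, hier, anchor_ext = st$anchor_ext)
  tadst <- classify_tad_status(sig, tads)
  sizes <- loop_size_distribution(sig)
  summ <- interaction_summary(sig, pe_all, tss, anchor_ext = st$anchor_ext,
                              tss_halfwidth = st$tss_anchor_halfwidth)
  loop_tab <- data.frame(chrom = sig$chrom, start1 = sig$start1,
                         end1 = sig$end1, start2 = sig$start2,
                         end2 = sig$end2, p_value = sig$p_value,
                         size = loop_sizes(sig), tad_status = tadst$status)
  utils::write.table(loop_tab, file.path(outdir, "loops_annotated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$loops <- list(n_total = nrow(loops), n_significant = nrow(sig),
                       size_bins = as.list(sizes),
                       partner_counts = as.list(ann$counts),
                       tad_fractions = as.list(tadst$fractions),
                       pct_pe_interacting = summ$pct_interacting,
                       pct_promoter_interactions = summ$pct_promoter,
                       n_interacting_tss = length(summ$interacting_tss))
  stage_msg("loops", t0, sprintf("significant=%d intra=%.2f",
                                 nrow(sig), tadst$fractions[["intra"]]))

  ## association statistics
  k4me3 <- read_peaks(file.path(indir, "promoter_H3K4me3.broadPeak"),
                      "broadPeak", genome)
  k27me3p <- read_peaks(file.path(indir, "promoter_H3K27me3.broadPeak"),
                        "broadPeak", genome)
  states <- classify_promoter_states(tss, k4me3, k27me3p)
  hit <- tss$gene_id %in% summ$interacting_tss
  cat_biv <- states$state == "bivalent"
  fish <- enrichment_fisher(hit_flags = hit, category_flags = cat_biv)
  cgi_pe <- cgi_distance_profile(pe_all, cgis)
  cgi_act <- cgi_distance_profile(calls$active, cgis)
  cmp <- compare_distributions(cgi_act$distances[!is.na(cgi_act$distances)],
                               cgi_pe$distances[!is.na(cgi_pe$distances)])
  utils::write.table(states, file.path(outdir, "promoter_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$association <- list(
    state_counts = as.list(table(states$state)),
    bivalent_fisher = list(a = fish$a, b = fish$b, c = fish$c, d = fish$d,
                           odds_ratio = fish$odds_ratio, p = fish$p),
    cgi_overlap_pct_poised = cgi_pe$overlap_pct,
    cgi_overlap_pct_active = cgi_act$overlap_pct,
    cgi_distance_fc_active_vs_poised = cmp$fc,
    cgi_distance_p = cmp$p)
  stage_msg("associate", t0, sprintf("bivalent OR=%.3f p=%.3g",
                                     fish$odds_ratio, fish$p))

  ## contact pileup
  cm <- read_coo(file.path(indir, "contacts.coo"),
                 chrom_length = config$sim$n_bins * config$sim$resolution,
                 resolution = config$sim$resolution)
  pairs <- sim$contacts$pairs
  cn <- coverage_normalize(cm)
  pu <- pileup(cn, pairs, halfwidth = st$pileup_halfwidth,
               normalization = st$pileup_normalization, seed = seed)
  kr <- kr_balance(cm)
  pu_kr <- pileup(kr, pairs, halfwidth = st$pileup_halfwidth,
                  normalization = st$pileup_normalization, seed = seed)
  utils::write.table(round(pu$mean_window, 6),
                     file.path(outdir, "pileup_window.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  report$pileup <- list(n_pairs_used = pu$n_pairs_used,
                        loopiness_coverage = pu$loopiness,
                        loopiness_kr = pu_kr$loopiness,
                        planted_enrichment = sim$contacts$enrichment)
  stage_msg("pileup", t0, sprintf("loopiness=%.3f (planted %g)",
                                  pu$loopiness, sim$contacts$enrichment))

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
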