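# End-to-end pipeline orchestration and report generation.

#' Run the alternative splicing detection pipeline
#'
#' Either consumes a genome (FASTA), gene models (GFF3) and spliced EST
#' alignments (PSL), or, in simulate mode, generates them first with
#' known truth. The pipeline filters alignments, clusters them into
#' transcriptional units, detects and classifies events, calls prevalent
#' forms, and writes: events as TSV and BED, per-cluster splice graphs as
#' DOT, an event-type tally, splice-site strength tables, length/GC
#' feature contrasts, per-event ORF impact reports with a Table-style
#' summary, a run log of every threshold, and (simulate mode) a
#' truth-vs-detected confusion report.
#'
#' @param out_dir Output directory (created if needed).
#' @param genome,gff3,psl Input paths (ignored in simulate mode). `psl`
#'   is required; `genome` is needed for strand inference, splice-site
#'   strength and GC features; `gff3` for gene association and ORF
#'   impact.
#' @param sim A [sim_config()] for simulate mode, or NULL.
#' @param min_identity,min_coverage,min_intron,max_intron Alignment
#'   filters, see [filter_alignments()].
#' @param overhang,min_support Event detection parameters, see
#'   [detect_events()].
#' @param test Statistical test for strength comparisons.
#' @param short_intron_max Threshold for the short in-frame intron
#'   subgroup, see [feature_report()].
#' @param nmd_distance NMD rule distance in nt, see [assess_event()].
#' @param infer_strands Re-infer each spliced alignment's strand from the
#'   splice-site dinucleotides, overriding the PSL strand labels.
#' @param write_graphs Write per-cluster DOT splice graphs.
#' @return Invisibly, a list with all intermediate and final objects
#'   (`alignments`, `filtered`, `clusters`, `events`, `tally`,
#'   `strength`, `features`, `impact_reports`, `impact`, `confusion`,
#'   `truth`).
#' @export
run_pipeline <- function(out_dir, genome = NULL, gff3 = NULL, psl = NULL,
                         sim = NULL, min_identity = 0.95,
                         min_coverage = 0.8, min_intron = 40L,
                         max_intron = 10000L, overhang = 10L,
                         min_support = 1L, test = c("ranksum", "ttest"),
                         short_intron_max = 150L, nmd_distance = 50L,
                         infer_strands = FALSE, write_graphs = TRUE) {
  test <- match.arg(test)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    truth <- simulate_genome(sim)
    ests <- sample_ests(truth)
    paths <- write_simulation(truth, ests, file.path(out_dir, "input"))
    genome <- paths[["fasta"]]; gff3 <- paths[["gff3"]]
    psl <- paths[["psl"]]
  }
  if (is.null(psl)) {
    stop_estsplice("a PSL alignment file (or simulate mode) is required",
                   "estsplice_usage_error")
  }
  genome_ss <- if (!is.null(genome)) Biostrings::readDNAStringSet(genome)
  if (!is.null(genome_ss)) {
    names(genome_ss) <- sub("\\s.*$", "", names(genome_ss))
  }
  genes <- if (!is.null(gff3)) read_gff3(gff3)

  aln <- read_psl(psl)
  filt <- filter_alignments(aln, min_identity, min_coverage, min_intron,
                            max_intron)
  kept <- filt$kept
  if (infer_strands && !is.null(genome_ss) && nrow(kept)) {
    kept$strand <- vapply(seq_len(nrow(kept)), function(i) {
      infer_strand(kept[i, ], genome_ss)
    }, character(1))
  }
  clusters <- cluster_alignments(kept)
  if (!is.null(genes)) clusters <- associate_genes(clusters, genes)
  events <- call_prevalent(detect_events(clusters, overhang, min_support))
  tally <- tally_events(events)

  write_events_tsv(events, file.path(out_dir, "events.tsv"))
  write_events_bed(events, file.path(out_dir, "events.bed"))
  write.table(cbind(tally, total = attr(tally, "total")),
              file.path(out_dir, "tally.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(clusters$clusters[, c("cluster_id", "chrom", "strand",
                                    "start", "end", "n_ests")],
              file.path(out_dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (write_graphs && nrow(clusters$clusters)) {
    gdir <- file.path(out_dir, "graphs")
    dir.create(gdir, showWarnings = FALSE)
    for (cid in clusters$clusters$cluster_id) {
      g <- build_splice_graph(
        clusters$alignments[clusters$alignments$cluster_id == cid, ,
                            drop = FALSE])
      write_graph_dot(g, file.path(gdir, paste0(cid, ".dot")), name = cid,
                      chrom = clusters$clusters$chrom[
                        match(cid, clusters$clusters$cluster_id)])
    }
  }

  # splice-site strength vs constitutive introns
  strength <- NULL
  const_intr <- constitutive_introns(clusters, events)
  if (!is.null(genome_ss) && nrow(const_intr) >= 2L && nrow(events)) {
    strength <- strength_table(events, const_intr, genome_ss, test)
    write.table(strength$by_type, file.path(out_dir, "strength_by_type.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(strength$prevalence,
                file.path(out_dir, "strength_prevalence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_pwm(strength$pwms$donor, file.path(out_dir, "pwm_donor.tsv"))
    write_pwm(strength$pwms$acceptor, file.path(out_dir, "pwm_acceptor.tsv"))
  }

  features <- NULL
  if (!is.null(genome_ss) && nrow(events)) {
    features <- feature_report(clusters, events, genome_ss,
                               short_intron_max, "ttest")
    if (nrow(features)) {
      write.table(features, file.path(out_dir, "features.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  impact_reports <- NULL; impact <- NULL
  if (!is.null(genes) && !is.null(genome_ss) && nrow(events)) {
    elig <- eligible_events(clusters, events, genes)
    if (nrow(elig)) {
      impact_reports <- do.call(rbind, lapply(seq_len(nrow(elig)),
                                              function(i) {
        assess_event(elig[i, ], elig$prevalent_exons[[i]],
                     elig$nonprevalent_exons[[i]],
                     genes[match(elig$gene_id[i], genes$gene_id), ],
                     genome_ss, nmd_distance)
      }))
      impact <- impact_table(impact_reports)
      write.table(impact_reports, file.path(out_dir, "impact_reports.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(impact, file.path(out_dir, "impact_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  confusion <- NULL
  if (!is.null(truth)) {
    confusion <- compare_to_truth(events, truth$events)
    write.table(confusion, file.path(out_dir, "confusion.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # run log: every threshold that shaped any output
  cfg <- c(min_identity = min_identity, min_coverage = min_coverage,
           min_intron = min_intron, max_intron = max_intron,
           overhang = overhang, min_support = min_support, test = test,
           short_intron_max = short_intron_max,
           nmd_distance = nmd_distance, infer_strands = infer_strands,
           simulate = !is.null(sim),
           seed = if (!is.null(sim)) sim$seed else NA)
  writeLines(sprintf("%s=%s", names(cfg), vapply(cfg, as.character,
                                                 character(1))),
             file.path(out_dir, "run_config.txt"))

  invisible(list(alignments = aln, filtered = filt, clusters = clusters,
                 events = events, tally = tally, strength = strength,
                 features = features, impact_reports = impact_reports,
                 impact = impact, confusion = confusion, truth = truth))
}
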