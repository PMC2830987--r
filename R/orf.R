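# ORF impact of alternative splicing: premature termination codons and
# NMD candidacy.
#
# The NMD rule follows the mammalian convention: a transcript is an NMD
# candidate when its termination codon lies more than 50 nt upstream of
# its last exon-exon junction, measured on the transcript that carries
# the premature stop.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Splice an exon chain into its mRNA
#'
#' Concatenates the exonic genome sequence in transcript orientation
#' (reverse-complemented on the minus strand) and records the transcript
#' coordinate of every exon-exon junction.
#'
#' @param exons 2-column matrix of genomic exon intervals (ascending,
#'   1-based closed).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param genome A named `DNAStringSet`.
#' @return A list of class `mrna`: `seq` (character), `junctions`
#'   (transcript coordinates of the last base of each exon but the final
#'   one, in transcript order; length = exon count - 1), `exons`,
#'   `chrom`, `strand`.
#' @export
splice_to_mrna <- function(exons, chrom, strand, genome) {
  ord <- if (strand == "-") rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  pieces <- vapply(ord, function(i) {
    genome_seq(genome, chrom, exons[i, 1], exons[i, 2], strand)
  }, character(1))
  w <- exons[ord, 2] - exons[ord, 1] + 1L
  out <- list(seq = paste(pieces, collapse = ""),
              junctions = if (length(w) > 1L) cumsum(w)[-length(w)]
                          else integer(0),
              exons = exons, chrom = chrom, strand = strand)
  class(out) <- "mrna"
  out
}

#' Find the ORF from an annotated start codon
#'
#' Scans in-frame codons from an ATG at `start` (transcript coordinates)
#' to the first stop codon strictly downstream.
#'
#' @param x An `mrna` or a character mRNA sequence.
#' @param start Transcript coordinate of the A of the start codon.
#' @return A list: `stop_pos` (transcript coordinate of the last base of
#'   the stop codon, NA if none), `orf_len` (nt from the A of ATG through
#'   the stop, inclusive; NA if none), `no_stop` (TRUE when the frame
#'   runs off the transcript without a stop).
#' @export
find_orf <- function(x, start) {
  seq <- if (inherits(x, "mrna")) x$seq else x
  n <- nchar(seq)
  if (start < 1L || start + 2L > n ||
      substr(seq, start, start + 2L) != "ATG") {
    stop_estsplice("no ATG at the stated start position",
                   "estsplice_orf_error")
  }
  starts <- seq.int(start + 3L, by = 3L, length.out = (n - start - 2L) %/% 3L)
  if (length(starts)) {
    codons <- substring(seq, starts, starts + 2L)
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit)) {
      sp <- starts[hit[1]] + 2L
      return(list(stop_pos = sp, orf_len = sp - start + 1L,
                  no_stop = FALSE))
    }
  }
  list(stop_pos = NA_integer_, orf_len = NA_integer_, no_stop = TRUE)
}

# Genomic coordinate of a transcript position on an mRNA's exon chain.
tx_pos_to_genomic <- function(mrna, p) {
  b <- tx_to_genomic(mrna$exons, mrna$strand, p, p)
  b[1, 1]
}

#' Select events eligible for protein-impact analysis
#'
#' Keeps events from clusters with exactly one detected event, an
#' associated gene model with an annotated start codon, and an untied
#' prevalence call, and attaches a representative full-length exon chain
#' per form (the supporting EST with the largest aligned length). Events
#' whose representative chains do not contain the start codon in exonic
#' sequence are dropped.
#'
#' @param clusters A `tx_clusters` object, gene-associated via
#'   [associate_genes()].
#' @param events An `as_events` data frame with prevalence calls.
#' @param genes A `gene_models` data frame.
#' @return The eligible subset of `events` with list-columns
#'   `prevalent_exons` and `nonprevalent_exons` and a `gene_id` column.
#' @export
eligible_events <- function(clusters, events, genes) {
  stopifnot(!is.null(clusters$clusters$gene_ids))
  n_ev <- table(events$cluster_id)
  keep <- integer(0)
  prev_x <- list(); nonprev_x <- list(); gene_id <- character(0)
  est_chain <- function(aln, ests) {
    sub <- aln[aln$est_id %in% ests, , drop = FALSE]
    lens <- vapply(sub$blocks, function(b) sum(b[, 2] - b[, 1] + 1L),
                   integer(1))
    sub$blocks[[which.max(lens)]]
  }
  for (i in seq_len(nrow(events))) {
    cid <- events$cluster_id[i]
    if (n_ev[[cid]] != 1L) next
    if (isTRUE(events$tie[i]) || is.na(events$prevalent[i])) next
    ci <- match(cid, clusters$clusters$cluster_id)
    gids <- clusters$clusters$gene_ids[[ci]]
    gids <- gids[!is.na(genes$cds_start[match(gids, genes$gene_id)])]
    if (!length(gids)) next
    gid <- gids[1]
    cds_start <- genes$cds_start[match(gid, genes$gene_id)]
    aln <- clusters$alignments[clusters$alignments$cluster_id == cid, ,
                               drop = FALSE]
    f <- events$forms[[i]]
    pi <- events$prevalent[i]
    others <- setdiff(seq_len(nrow(f)), pi)
    ni <- others[which.max(f$n_ests[others])]
    px <- est_chain(aln, f$ests[[pi]])
    nx <- est_chain(aln, f$ests[[ni]])
    if (is.na(genomic_to_tx(px, events$strand[i], cds_start)) ||
        is.na(genomic_to_tx(nx, events$strand[i], cds_start))) next
    keep <- c(keep, i)
    prev_x <- c(prev_x, list(px))
    nonprev_x <- c(nonprev_x, list(nx))
    gene_id <- c(gene_id, gid)
  }
  out <- events[keep, , drop = FALSE]
  out$gene_id <- gene_id
  out$prevalent_exons <- prev_x
  out$nonprevalent_exons <- nonprev_x
  out
}

#' Assess the protein-level impact of one event
#'
#' Splices the prevalent and non-prevalent exon chains, finds both ORFs
#' from the annotated start codon, and reports: whether the event lies in
#' the CDS or the UTR of the prevalent form, ORF shortening in nt and
#' percent, whether the non-prevalent form terminates at a premature
#' codon (a stop genomically upstream, in transcript orientation, of the
#' prevalent stop), and NMD candidacy under the 50-nt rule applied to the
#' non-prevalent transcript's own junction map.
#'
#' @param event One row of an `as_events` data frame (the event span is
#'   taken from it).
#' @param prevalent_exons,nonprevalent_exons Genomic exon chains.
#' @param gene A one-row `gene_models` data frame (for `cds_start`).
#' @param genome A named `DNAStringSet`.
#' @param nmd_distance Minimum PTC-to-last-junction distance (nt) for NMD
#'   candidacy (default 50).
#' @return A one-row data frame (`orf_impact` report): `event_id`,
#'   `event_type`, `location`, `prevalent_orf_len`,
#'   `nonprevalent_orf_len`, `shortened_by`, `shortened_pct`,
#'   `ptc_introduced`, `nmd_candidate`,
#'   `distance_ptc_to_last_junction`, `no_stop`.
#' @export
assess_event <- function(event, prevalent_exons, nonprevalent_exons, gene,
                         genome, nmd_distance = 50L) {
  chrom <- event$chrom; strand <- event$strand
  mp <- splice_to_mrna(prevalent_exons, chrom, strand, genome)
  mn <- splice_to_mrna(nonprevalent_exons, chrom, strand, genome)
  atg_p <- genomic_to_tx(prevalent_exons, strand, gene$cds_start)
  atg_n <- genomic_to_tx(nonprevalent_exons, strand, gene$cds_start)
  orf_p <- find_orf(mp, atg_p)
  orf_n <- find_orf(mn, atg_n)
  report <- data.frame(
    event_id = sprintf("%s:%s:%d-%d", event$cluster_id, event$type,
                       event$start, event$end),
    event_type = event$type, location = NA_character_,
    prevalent_orf_len = orf_p$orf_len, nonprevalent_orf_len = orf_n$orf_len,
    shortened_by = NA_integer_, shortened_pct = NA_real_,
    ptc_introduced = FALSE, nmd_candidate = FALSE,
    distance_ptc_to_last_junction = NA_integer_,
    no_stop = orf_p$no_stop || orf_n$no_stop,
    stringsAsFactors = FALSE)
  if (orf_p$no_stop) return(report)

  # genomic CDS footprint of the prevalent form, start codon through stop;
  # introns inside it count as coding context (an event there, e.g. a
  # retained intron, interrupts the CDS)
  cds_blocks <- tx_to_genomic(prevalent_exons, strand, atg_p, orf_p$stop_pos)
  in_cds <- min(cds_blocks[, 1]) <= event$end &&
    max(cds_blocks[, 2]) >= event$start
  report$location <- if (in_cds) "CDS" else "UTR"
  if (orf_n$no_stop) return(report)

  report$shortened_by <- orf_p$orf_len - orf_n$orf_len
  report$shortened_pct <- report$shortened_by / orf_p$orf_len * 100
  g_stop_p <- tx_pos_to_genomic(mp, orf_p$stop_pos)
  g_stop_n <- tx_pos_to_genomic(mn, orf_n$stop_pos)
  upstream <- if (strand == "+") g_stop_n < g_stop_p else g_stop_n > g_stop_p
  report$ptc_introduced <- upstream
  if (length(mn$junctions)) {
    d <- mn$junctions[length(mn$junctions)] - orf_n$stop_pos
    report$distance_ptc_to_last_junction <- as.integer(d)
    report$nmd_candidate <- upstream && d > nmd_distance
  }
  report
}

#' Summarize ORF impact reports by event type
#'
#' Per event type: number of events in the coding sequence, their mean
#' ORF shortening in bp and percent, number of events in the UTR, and the
#' per-type total (CDS + UTR), with a Total/Avg row.
#'
#' @param reports Data frame of rows from [assess_event()].
#' @return Data frame with columns `event_type`, `n_cds`,
#'   `mean_shortened_bp`, `mean_shortened_pct`, `n_utr`, `n_total`.
#' @export
impact_table <- function(reports) {
  per_type <- lapply(AS_TYPES, function(ty) {
    r <- reports[!is.na(reports$event_type) & reports$event_type == ty, ,
                 drop = FALSE]
    cds <- r[!is.na(r$location) & r$location == "CDS", , drop = FALSE]
    utr <- r[!is.na(r$location) & r$location == "UTR", , drop = FALSE]
    data.frame(event_type = ty, n_cds = nrow(cds),
               mean_shortened_bp = if (nrow(cds))
                 mean(cds$shortened_by, na.rm = TRUE) else NA_real_,
               mean_shortened_pct = if (nrow(cds))
                 mean(cds$shortened_pct, na.rm = TRUE) else NA_real_,
               n_utr = nrow(utr), n_total = nrow(cds) + nrow(utr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_type)
  all_cds <- reports[!is.na(reports$location) & reports$location == "CDS", ,
                     drop = FALSE]
  total <- data.frame(
    event_type = "Total/Avg", n_cds = sum(out$n_cds),
    mean_shortened_bp = if (nrow(all_cds))
      mean(all_cds$shortened_by, na.rm = TRUE) else NA_real_,
    mean_shortened_pct = if (nrow(all_cds))
      mean(all_cds$shortened_pct, na.rm = TRUE) else NA_real_,
    n_utr = sum(out$n_utr), n_total = sum(out$n_total),
    stringsAsFactors = FALSE)
  rbind(out, total)
}
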