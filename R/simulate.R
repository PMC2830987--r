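# Synthetic genome / transcript / EST simulator with planted alternative
# splicing events of known truth.
#
# The generator emulates the compact, GC-rich gene architecture of a green
# alga: median exon 132 bp, median intron 232 bp, genome GC 64% with
# GT..AG introns whose 3' ends are C-rich in place of a polypyrimidine
# tract. Lengths are log-normal around the stated medians. Retained
# (IR-planted) introns are drawn shorter (median 127 bp) and less GC-rich
# (57%) than constitutive introns (62%), matching the contrast the
# detection pipeline is meant to recover.

#' Simulation configuration
#'
#' @param n_genes Number of genes to simulate.
#' @param exon_len_median Median exon length in bases (log-normal).
#' @param intron_len_median Median constitutive intron length in bases.
#' @param gc_content Genome-wide target GC fraction (exonic sequence).
#' @param intron_gc GC fraction of constitutive introns.
#' @param retained_intron_len_median Median length of introns chosen for
#'   intron-retention events.
#' @param retained_intron_gc GC fraction of IR-planted introns.
#' @param len_sdlog Log-scale standard deviation of the length
#'   distributions.
#' @param exons_per_gene_range Integer `[min, max]` exon count per gene;
#'   raised per-gene when a planted event needs more exons.
#' @param as_rates Named probabilities (per gene) of planting each event
#'   type: `IR`, `ES`, `Alt5`, `Alt3`, `AltB`.
#' @param ests_per_isoform_range Integer `[min, max]` ESTs sampled per
#'   isoform; the canonical isoform receives `prevalent_bias` extra ESTs
#'   so the constitutive form is the prevalent one.
#' @param est_len_range `NULL` for full-length ESTs (the default, which
#'   guarantees full junction coverage), or integer `[min, max]` EST
#'   lengths in bases.
#' @param error_rate Per-base substitution error rate of simulated ESTs.
#' @param prevalent_bias Extra ESTs given to the canonical isoform.
#' @param flip_strand_labels If TRUE, half of the PSL strand labels are
#'   flipped so that strand must be re-inferred from splice-site
#'   dinucleotides.
#' @param chrom_name Name of the single simulated chromosome.
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       exon_len_median = 132,
                       intron_len_median = 232,
                       gc_content = 0.64,
                       intron_gc = 0.62,
                       retained_intron_len_median = 127,
                       retained_intron_gc = 0.57,
                       len_sdlog = 0.4,
                       exons_per_gene_range = c(3L, 8L),
                       as_rates = c(IR = 0.18, ES = 0.04, Alt5 = 0.04,
                                    Alt3 = 0.09, AltB = 0.01),
                       ests_per_isoform_range = c(2L, 4L),
                       est_len_range = NULL,
                       error_rate = 0,
                       prevalent_bias = 1L,
                       flip_strand_labels = FALSE,
                       chrom_name = "chrS",
                       seed = 1L) {
  rates <- setNames(rep(0, length(AS_TYPES)), AS_TYPES)
  rates[names(as_rates)] <- as_rates
  if (any(rates < 0 | rates > 1)) {
    stop_estsplice("as_rates must be probabilities in [0, 1]",
                   "estsplice_config_error")
  }
  if (!is.null(est_len_range) && min(est_len_range) < 1) {
    stop_estsplice("est_len_range must be >= 1", "estsplice_config_error")
  }
  if (max(exons_per_gene_range) < 2L && any(rates > 0)) {
    stop_estsplice(
      "genes need at least 2 exons to host alternative splicing events",
      "estsplice_config_error")
  }
  if (gc_content < 0 || gc_content > 1) {
    stop_estsplice("gc_content must be in [0, 1]", "estsplice_config_error")
  }
  cfg <- list(n_genes = as.integer(n_genes),
              exon_len_median = exon_len_median,
              intron_len_median = intron_len_median,
              gc_content = gc_content,
              intron_gc = intron_gc,
              retained_intron_len_median = retained_intron_len_median,
              retained_intron_gc = retained_intron_gc,
              len_sdlog = len_sdlog,
              exons_per_gene_range = as.integer(exons_per_gene_range),
              as_rates = rates,
              ests_per_isoform_range = as.integer(ests_per_isoform_range),
              est_len_range = if (is.null(est_len_range)) NULL
                              else as.integer(est_len_range),
              error_rate = error_rate,
              prevalent_bias = as.integer(prevalent_bias),
              flip_strand_labels = isTRUE(flip_strand_labels),
              chrom_name = chrom_name,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

MIN_INTRON_SIM <- 40L   # planted introns always survive default filters
MIN_EXON_SIM <- 30L
SHIFT_RANGE <- 3:12     # Alt5'/Alt3' boundary shifts in nt

#' Plant one alternative splicing event on an exon chain
#'
#' Derives a variant exon chain from a canonical one so that the two
#' isoforms differ exactly as the event type dictates: `IR` keeps one
#' intron unspliced; `ES` drops one internal exon and merges its flanking
#' introns; `Alt5`/`Alt3` shift the donor/acceptor boundary of one intron
#' into the intron by at least 3 nt; `AltB` shifts both boundaries.
#'
#' @param exons 2-column integer matrix of genomic exon intervals
#'   (ascending, 1-based closed).
#' @param type One of `"IR"`, `"ES"`, `"Alt5"`, `"Alt3"`, `"AltB"`.
#' @param strand `"+"` or `"-"`; boundary sides are interpreted in
#'   transcript orientation.
#' @param intron Genomic index (ascending) of the target intron (all types
#'   except ES); defaults to the middle intron.
#' @param exon Genomic index of the internal exon to skip (ES only);
#'   defaults to the second exon.
#' @param shift5,shift3 Donor / acceptor boundary shifts in nt (>= 3).
#' @return A list with `iso_a` (canonical exons), `iso_b` (variant exons)
#'   and `event` (list of `type`, `start`, `end`: the genomic span of the
#'   event — the intron for IR/Alt5/Alt3/AltB, the skipped exon for ES).
#' @export
plant_event <- function(exons, type, strand = "+", intron = NULL,
                        exon = NULL, shift5 = 3L, shift3 = 3L) {
  type <- match.arg(type, AS_TYPES)
  n <- nrow(exons)
  need <- if (type == "ES") 3L else 2L
  if (n < need) {
    stop_estsplice(sprintf("%s event requires at least %d exons, gene has %d",
                           type, need, n), "estsplice_plant_error")
  }
  introns <- blocks_to_introns(exons)
  var <- exons
  if (type == "ES") {
    e <- exon %||% 2L
    if (e < 2L || e > n - 1L) {
      stop_estsplice("skipped exon must be internal", "estsplice_plant_error")
    }
    var <- exons[-e, , drop = FALSE]
    span <- exons[e, ]
  } else {
    i <- intron %||% ((n - 1L) %/% 2L + 1L)
    if (i < 1L || i > n - 1L) {
      stop_estsplice("intron index out of range", "estsplice_plant_error")
    }
    span <- introns[i, ]
    ilen <- span[2] - span[1] + 1L
    if (type == "IR") {
      var <- rbind(exons[seq_len(i - 1L), , drop = FALSE],
                   c(exons[i, 1], exons[i + 1L, 2]),
                   if (i + 2L <= n) exons[seq(i + 2L, n), , drop = FALSE])
    } else {
      d5 <- if (type %in% c("Alt5", "AltB")) as.integer(shift5) else 0L
      d3 <- if (type %in% c("Alt3", "AltB")) as.integer(shift3) else 0L
      if ((d5 > 0L && d5 < 3L) || (d3 > 0L && d3 < 3L)) {
        stop_estsplice("boundary shifts must be at least 3 nt",
                       "estsplice_plant_error")
      }
      if (ilen - d5 - d3 < MIN_INTRON_SIM) {
        stop_estsplice("intron too short for the requested boundary shifts",
                       "estsplice_plant_error")
      }
      # donor is the genomic start on "+", the genomic end on "-"
      dd <- if (strand == "+") c(d5, d3) else c(d3, d5)
      var[i, 2] <- var[i, 2] + dd[1]          # upstream-exon end moves right
      var[i + 1L, 1] <- var[i + 1L, 1] - dd[2] # downstream-exon start left
    }
  }
  storage.mode(var) <- "integer"
  colnames(var) <- c("start", "end")
  list(iso_a = exons, iso_b = var,
       event = list(type = type, start = unname(span[1]),
                    end = unname(span[2])))
}

# Build one gene in transcript-orientation local coordinates, then map to
# the genome. Returns per-gene sequence, exon layout, isoforms and events.
build_gene <- function(cfg, gid, types) {
  n_es <- sum(types == "ES")
  need_introns <- (length(types) - n_es) + 2L * n_es
  rng <- cfg$exons_per_gene_range
  n_ex <- runif_int(rng[1], rng[2])
  n_ex <- max(n_ex, need_introns + 1L, if (n_es > 0L) 3L else 2L,
              if (length(types) > 0L) 2L else 1L)
  n_in <- n_ex - 1L

  # assign each event its intron (ES: an internal exon + both flanking
  # introns), all distinct
  reserved <- logical(n_in)
  assign_intron <- rep(NA_integer_, length(types))
  assign_exon <- rep(NA_integer_, length(types))
  for (k in order(types != "ES")) {  # ES first: it needs two free introns
    if (types[k] == "ES") {
      cand <- which(!reserved[-n_in] & !reserved[-1])  # exon e -> introns e-1,e
      e <- cand[sample.int(length(cand), 1L)] + 1L
      assign_exon[k] <- e
      reserved[c(e - 1L, e)] <- TRUE
    } else {
      cand <- which(!reserved)
      i <- cand[sample.int(length(cand), 1L)]
      assign_intron[k] <- i
      reserved[i] <- TRUE
    }
  }

  shift5 <- ifelse(types %in% c("Alt5", "AltB"),
                   sample(SHIFT_RANGE, length(types), replace = TRUE), 0L)
  shift3 <- ifelse(types %in% c("Alt3", "AltB"),
                   sample(SHIFT_RANGE, length(types), replace = TRUE), 0L)

  exon_len <- pmax(MIN_EXON_SIM,
                   as.integer(round(rlnorm(n_ex, log(cfg$exon_len_median),
                                           cfg$len_sdlog))))
  intron_len <- pmax(MIN_INTRON_SIM,
                     as.integer(round(rlnorm(n_in, log(cfg$intron_len_median),
                                             cfg$len_sdlog))))
  intron_gc <- rep(cfg$intron_gc, n_in)
  ir_introns <- assign_intron[types == "IR"]
  if (length(ir_introns)) {
    intron_len[ir_introns] <- pmax(
      MIN_INTRON_SIM,
      as.integer(round(rlnorm(length(ir_introns),
                              log(cfg$retained_intron_len_median),
                              cfg$len_sdlog))))
    intron_gc[ir_introns] <- cfg$retained_intron_gc
  }
  for (k in seq_along(types)) {
    if (types[k] %in% c("Alt5", "Alt3", "AltB")) {
      i <- assign_intron[k]
      intron_len[i] <- max(intron_len[i],
                           MIN_INTRON_SIM + shift5[k] + shift3[k] + 12L)
    }
  }

  # transcript exonic sequence: 5' UTR, ATG, stop-free codons, TAA, 3' UTR
  utr5 <- 12L
  L <- sum(exon_len)
  cds_len <- L - utr5 - 15L
  cds_len <- cds_len - cds_len %% 3L
  if (cds_len < 30L) {
    exon_len[n_ex] <- exon_len[n_ex] + (30L + utr5 + 15L - L) + 3L
    L <- sum(exon_len)
    cds_len <- L - utr5 - 15L
    cds_len <- cds_len - cds_len %% 3L
  }
  tx <- paste0(random_dna(utr5, cfg$gc_content), "ATG",
               random_codons(cds_len %/% 3L - 2L, cfg$gc_content), "TAA",
               random_dna(L - utr5 - cds_len, cfg$gc_content))
  ends <- cumsum(exon_len)
  starts <- c(1L, head(ends, -1L) + 1L)
  exon_seq <- substring(tx, starts, ends)

  intron_seq <- character(n_in)
  for (i in seq_len(n_in)) {
    k <- match(i, assign_intron)
    d5 <- if (!is.na(k)) shift5[k] else 0L
    d3 <- if (!is.na(k)) shift3[k] else 0L
    intron_seq[i] <- intron_sequence(intron_len[i], intron_gc[i], d5, d3)
  }

  pieces <- character(n_ex + n_in)
  pieces[seq(1L, by = 2L, length.out = n_ex)] <- exon_seq
  if (n_in) pieces[seq(2L, by = 2L, length.out = n_in)] <- intron_seq
  local_seq <- paste(pieces, collapse = "")

  # local exon coordinates (transcript orientation = ascending local)
  glen <- nchar(local_seq)
  loc_start <- integer(n_ex); loc_end <- integer(n_ex)
  pos <- 0L
  for (e in seq_len(n_ex)) {
    loc_start[e] <- pos + 1L
    loc_end[e] <- pos + exon_len[e]
    pos <- loc_end[e] + if (e <= n_in) intron_len[e] else 0L
  }

  list(seq = local_seq, glen = glen, n_ex = n_ex,
       loc_exons = cbind(start = loc_start, end = loc_end),
       utr5 = utr5, cds_len = cds_len,
       types = types, assign_intron = assign_intron,
       assign_exon = assign_exon, shift5 = shift5, shift3 = shift3)
}

# One intron: GT..AG, C-rich tail at -10..-3 before the AG, and, when a
# boundary shift is planted, GT/AG dinucleotides at the variant boundary.
intron_sequence <- function(len, gc, d5 = 0L, d3 = 0L) {
  s <- strsplit(random_dna(len, gc), "", fixed = TRUE)[[1]]
  tail_idx <- seq(len - 11L, len - 4L)
  tail_idx <- tail_idx[tail_idx > 2L & tail_idx < len - 1L]
  s[tail_idx] <- sample(BASES, length(tail_idx), replace = TRUE,
                        prob = c(0.15, 0.45, 0.25, 0.15))
  s[1:2] <- c("G", "T")
  s[c(len - 1L, len)] <- c("A", "G")
  if (d5 > 0L) s[d5 + 1:2] <- c("G", "T")
  if (d3 > 0L) s[c(len - d3 - 1L, len - d3)] <- c("A", "G")
  paste(s, collapse = "")
}

#' Simulate a genome with genes, isoforms and planted splicing events
#'
#' Generates a single-chromosome genome of non-overlapping multi-exon
#' genes, plants alternative splicing events at the configured per-gene
#' rates, and records the full truth: gene models, isoform exon chains,
#' and every planted event with its type and genomic span. All introns
#' are GT..AG on their gene's strand by construction.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `as_truth` with elements `genome`
#'   (`DNAStringSet`), `genes`, `isoforms`, `events` (data frames) and
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (max(config$exons_per_gene_range) < 2L && any(config$as_rates > 0)) {
    stop_estsplice(
      "genes need at least 2 exons to host alternative splicing events",
      "estsplice_config_error")
  }
  set.seed(config$seed)
  genes <- list(); isoforms <- list(); events <- list()
  chrom_parts <- character(0)
  offset <- 0L

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    strand <- sample(c("+", "-"), 1L)
    types <- AS_TYPES[runif(length(AS_TYPES)) < config$as_rates]
    gb <- build_gene(config, gene_id, types)

    spacer <- random_dna(sample(100:300, 1L), config$gc_content)
    offset <- offset + nchar(spacer)
    g0 <- offset + 1L
    gene_seq <- if (strand == "-") revcomp(gb$seq) else gb$seq
    chrom_parts <- c(chrom_parts, spacer, gene_seq)
    offset <- offset + gb$glen

    # local (transcript-orientation) -> genomic exon coordinates
    if (strand == "+") {
      exons <- cbind(start = g0 + gb$loc_exons[, 1] - 1L,
                     end = g0 + gb$loc_exons[, 2] - 1L)
    } else {
      exons <- cbind(start = g0 + gb$glen - gb$loc_exons[, 2],
                     end = g0 + gb$glen - gb$loc_exons[, 1])
      exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    }
    storage.mode(exons) <- "integer"

    # start/stop codon positions are transcript coordinates; project them
    # through the canonical exon chain to the genome
    cds_start <- tx_to_genomic(exons, strand, gb$utr5 + 1L,
                               gb$utr5 + 1L)[1, 1]
    cds_end <- tx_to_genomic(exons, strand, gb$utr5 + gb$cds_len,
                             gb$utr5 + gb$cds_len)[1, 1]

    iso <- list(exons)
    iso_ids <- sprintf("%s.t1", gene_id)
    n_ex <- gb$n_ex
    for (k in seq_along(gb$types)) {
      ty <- gb$types[k]
      if (ty == "ES") {
        gx <- if (strand == "+") gb$assign_exon[k] else
          n_ex - gb$assign_exon[k] + 1L
        pl <- plant_event(exons, ty, strand, exon = gx)
      } else {
        gi <- if (strand == "+") gb$assign_intron[k] else
          (n_ex - 1L) - gb$assign_intron[k] + 1L
        pl <- plant_event(exons, ty, strand, intron = gi,
                          shift5 = gb$shift5[k], shift3 = gb$shift3[k])
      }
      iso_id <- sprintf("%s.t%d", gene_id, length(iso) + 1L)
      iso <- c(iso, list(pl$iso_b))
      iso_ids <- c(iso_ids, iso_id)
      events[[length(events) + 1L]] <- data.frame(
        gene_id = gene_id, type = ty, chrom = config$chrom_name,
        strand = strand, start = pl$event$start, end = pl$event$end,
        iso_canonical = iso_ids[1], iso_variant = iso_id,
        stringsAsFactors = FALSE)
    }

    genes[[g]] <- data.frame(
      gene_id = gene_id, chrom = config$chrom_name, strand = strand,
      start = g0, end = g0 + gb$glen - 1L,
      cds_start = cds_start, cds_end = cds_end, stringsAsFactors = FALSE)
    genes[[g]]$exons <- list(exons)
    iso_df <- data.frame(iso_id = iso_ids, gene_id = gene_id,
                         chrom = config$chrom_name, strand = strand,
                         stringsAsFactors = FALSE)
    iso_df$exons <- iso
    isoforms[[g]] <- iso_df
  }
  chrom_parts <- c(chrom_parts, random_dna(sample(100:300, 1L),
                                           config$gc_content))
  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- config$chrom_name

  truth <- list(
    genome = genome,
    genes = do.call(rbind, genes),
    isoforms = do.call(rbind, isoforms),
    events = if (length(events)) do.call(rbind, events) else data.frame(
      gene_id = character(0), type = character(0), chrom = character(0),
      strand = character(0), start = integer(0), end = integer(0),
      iso_canonical = character(0), iso_variant = character(0),
      stringsAsFactors = FALSE),
    config = config)
  class(truth) <- "as_truth"
  truth
}

#' Sample ESTs from simulated isoforms
#'
#' Draws EST fragments from each isoform's spliced transcript and projects
#' them through the isoform's exon map into spliced genomic alignments.
#' With the default full-length ESTs, every alignment's blocks equal the
#' exon pieces the EST covers and every splice junction is witnessed.
#'
#' @param truth An `as_truth` object from [simulate_genome()].
#' @param config A [sim_config()]; defaults to the one stored in `truth`.
#' @return A list with `alignments` (a `spliced_alignments` data frame)
#'   and `origins` (data frame mapping `est_id` to `iso_id` and transcript
#'   `offset`).
#' @export
sample_ests <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  tsize <- length(truth$genome[[config$chrom_name]])
  rows <- list(); origins <- list()
  warned_clamp <- FALSE
  iso <- truth$isoforms
  n_by_iso <- integer(nrow(iso))
  rng <- config$ests_per_isoform_range
  for (i in seq_len(nrow(iso))) {
    n_by_iso[i] <- runif_int(rng[1], rng[2])
  }
  # canonical isoform gets strictly more ESTs than any variant of its gene
  if (config$prevalent_bias > 0L) {
    for (gid in unique(iso$gene_id)) {
      ix <- which(iso$gene_id == gid)
      if (length(ix) > 1L) {
        n_by_iso[ix[1]] <- max(n_by_iso[ix[-1]]) + config$prevalent_bias
      }
    }
  }
  for (i in seq_len(nrow(iso))) {
    exons <- iso$exons[[i]]
    L <- sum(exons[, 2] - exons[, 1] + 1L)
    for (j in seq_len(n_by_iso[i])) {
      if (is.null(config$est_len_range)) {
        len <- L; ts <- 1L
      } else {
        len <- runif_int(config$est_len_range[1], config$est_len_range[2])
        if (len > L) {
          if (!warned_clamp) {
            warning("est_len_range exceeds isoform length; clamping")
            warned_clamp <- TRUE
          }
          len <- L
        }
        ts <- sample.int(L - len + 1L, 1L)
      }
      blocks <- tx_to_genomic(exons, iso$strand[i], ts, ts + len - 1L)
      mism <- if (config$error_rate > 0) rbinom(1L, len, config$error_rate)
              else 0L
      strand_label <- iso$strand[i]
      if (config$flip_strand_labels && runif(1) < 0.5) {
        strand_label <- if (strand_label == "+") "-" else "+"
      }
      est_id <- sprintf("%s.est%d", iso$iso_id[i], j)
      rows[[length(rows) + 1L]] <- list(
        est_id = est_id, chrom = iso$chrom[i], strand = strand_label,
        matches = len - mism, mismatches = mism, qsize = len,
        tstart = blocks[1, 1] - 1L, tend = blocks[nrow(blocks), 2],
        blockcount = nrow(blocks), blocks = blocks)
      origins[[length(origins) + 1L]] <- data.frame(
        est_id = est_id, iso_id = iso$iso_id[i], offset = ts,
        stringsAsFactors = FALSE)
    }
  }
  aln <- empty_alignments()
  if (length(rows)) {
    aln <- data.frame(
      est_id = vapply(rows, `[[`, character(1), "est_id"),
      chrom = vapply(rows, `[[`, character(1), "chrom"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      matches = vapply(rows, `[[`, integer(1), "matches"),
      mismatches = vapply(rows, `[[`, integer(1), "mismatches"),
      repmatches = 0L, ncount = 0L, qnuminsert = 0L, qbaseinsert = 0L,
      tnuminsert = vapply(rows, function(r) nrow(r$blocks) - 1L, integer(1)),
      tbaseinsert = vapply(rows, function(r) {
        g <- blocks_to_introns(r$blocks)
        as.integer(sum(g[, 2] - g[, 1] + 1L))
      }, integer(1)),
      qsize = vapply(rows, `[[`, integer(1), "qsize"),
      qstart = 0L,
      qend = vapply(rows, `[[`, integer(1), "qsize"),
      tsize = tsize,
      tstart = vapply(rows, `[[`, integer(1), "tstart"),
      tend = vapply(rows, `[[`, integer(1), "tend"),
      blockcount = vapply(rows, `[[`, integer(1), "blockcount"),
      qstarts = NA_character_,
      stringsAsFactors = FALSE)
    aln$blocks <- lapply(rows, `[[`, "blocks")
    aln$identity <- aln$matches / (aln$matches + aln$mismatches)
    aln$est_coverage <- 1
    class(aln) <- c("spliced_alignments", "data.frame")
  }
  list(alignments = aln, origins = do.call(rbind, origins))
}

#' Write a simulation to disk
#'
#' Emits the genome as 60-column FASTA, the truth gene models (all
#' isoforms, with CDS on the canonical one) as GFF3, the EST alignments as
#' PSL, and the planted events as TSV. Byte-identical across reruns with
#' the same configuration.
#'
#' @param truth An `as_truth` object.
#' @param ests Result of [sample_ests()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(truth, ests, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fasta"),
             gff3 = file.path(dir, "genes.gff3"),
             psl = file.path(dir, "ests.psl"),
             events = file.path(dir, "truth_events.tsv"))
  Biostrings::writeXStringSet(truth$genome, paths["fasta"], width = 60L)
  write_truth_gff3(truth, paths["gff3"])
  write_psl(ests$alignments, paths["psl"])
  ev <- truth$events[, c("gene_id", "type", "chrom", "strand", "start",
                         "end", "iso_canonical", "iso_variant")]
  write.table(ev, paths["events"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Simulate genes whose non-prevalent form truncates the ORF
#'
#' Builds three-exon genes with an intron-retention event planted in the
#' first intron, placing an in-frame stop codon inside the retained
#' intron so that the non-prevalent isoform's ORF is a controlled
#' fraction of the canonical one (drawn uniformly from
#' `shorten_frac_range`, centred on one half). All other in-frame stops
#' upstream of the planted one are removed, so the planted codon is the
#' premature termination codon the ORF scan finds.
#'
#' @param n_genes Number of genes.
#' @param shorten_frac_range Range of the planted ORF-shortening
#'   fraction.
#' @param gc Exonic GC fraction.
#' @param intron_gc Intronic GC fraction.
#' @param chrom_name Chromosome name.
#' @param seed Integer seed.
#' @return An `as_truth` object whose `planted` element records the
#'   planted shortening percentage per gene.
#' @export
simulate_ptc_genes <- function(n_genes = 50L, shorten_frac_range = c(0.4, 0.6),
                               gc = 0.64, intron_gc = 0.62,
                               chrom_name = "chrS", seed = 1L) {
  set.seed(seed)
  genes <- list(); isoforms <- list(); events <- list(); planted <- list()
  chrom_parts <- character(0)
  offset <- 0L
  utr5 <- 12L
  e1_len <- 330L; i1_len <- 280L; i2_len <- 150L
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("ptc%03d", g)
    strand <- sample(c("+", "-"), 1L)
    e2_len <- 300L + 3L * (sample.int(21L, 1L) - 1L)
    e3_len <- 210L + 3L * (sample.int(21L, 1L) - 1L)
    exon_len <- c(e1_len, e2_len, e3_len)
    L <- sum(exon_len)
    cds_len <- L - utr5 - 15L   # multiple of 3 by construction
    f <- runif(1L, shorten_frac_range[1], shorten_frac_range[2])
    orf_var <- 3L * as.integer(round((1 - f) * cds_len / 3))

    tx <- paste0(random_dna(utr5, gc), "ATG",
                 random_codons(cds_len %/% 3L - 2L, gc), "TAA",
                 random_dna(L - utr5 - cds_len, gc))
    ends <- cumsum(exon_len)
    starts <- c(1L, head(ends, -1L) + 1L)
    exon_seq <- substring(tx, starts, ends)

    # retained intron with the planted in-frame stop
    e1 <- strsplit(exon_seq[1], "", fixed = TRUE)[[1]]
    i1 <- strsplit(intron_sequence(i1_len, intron_gc), "", fixed = TRUE)[[1]]
    stop_start <- orf_var + 10L          # variant tx coordinate of the stop
    li <- stop_start - e1_len            # intron-local coordinate
    i1[li:(li + 2L)] <- c("T", "G", "A")
    # neutralize earlier in-frame stops in the variant reading frame
    var_char <- function(q) if (q <= e1_len) e1[q] else i1[q - e1_len]
    for (p in seq.int(utr5 + 1L, stop_start - 3L, by = 3L)) {
      cod <- paste0(var_char(p), var_char(p + 1L), var_char(p + 2L))
      if (cod %in% c("TAA", "TAG", "TGA")) {
        qs <- p:(p + 2L)
        in_intron <- qs[qs > e1_len + 2L & qs < e1_len + li]
        if (length(in_intron)) {
          i1[in_intron[1] - e1_len] <- "C"
        } else {
          # boundary codon: mutate its last exonic base (C never forms a
          # stop in either frame)
          e1[max(qs[qs <= e1_len])] <- "C"
        }
      }
    }
    exon_seq[1] <- paste(e1, collapse = "")
    i1_seq <- paste(i1, collapse = "")
    i2_seq <- intron_sequence(i2_len, intron_gc)
    local_seq <- paste0(exon_seq[1], i1_seq, exon_seq[2], i2_seq,
                        exon_seq[3])
    glen <- nchar(local_seq)

    spacer <- random_dna(sample(100:300, 1L), gc)
    offset <- offset + nchar(spacer)
    g0 <- offset + 1L
    chrom_parts <- c(chrom_parts, spacer,
                     if (strand == "-") revcomp(local_seq) else local_seq)
    offset <- offset + glen

    loc_exons <- cbind(start = starts + c(0L, i1_len, i1_len + i2_len),
                       end = ends + c(0L, i1_len, i1_len + i2_len))
    if (strand == "+") {
      exons <- cbind(start = g0 + loc_exons[, 1] - 1L,
                     end = g0 + loc_exons[, 2] - 1L)
    } else {
      exons <- cbind(start = g0 + glen - loc_exons[, 2],
                     end = g0 + glen - loc_exons[, 1])
      exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    }
    storage.mode(exons) <- "integer"
    gi <- if (strand == "+") 1L else 2L
    pl <- plant_event(exons, "IR", strand, intron = gi)

    tx2g <- function(t) tx_to_genomic(exons, strand, t, t)[1, 1]
    genes[[g]] <- data.frame(
      gene_id = gene_id, chrom = chrom_name, strand = strand,
      start = g0, end = g0 + glen - 1L,
      cds_start = tx2g(utr5 + 1L), cds_end = tx2g(utr5 + cds_len),
      stringsAsFactors = FALSE)
    genes[[g]]$exons <- list(exons)
    iso_df <- data.frame(iso_id = sprintf("%s.t%d", gene_id, 1:2),
                         gene_id = gene_id, chrom = chrom_name,
                         strand = strand, stringsAsFactors = FALSE)
    iso_df$exons <- list(pl$iso_a, pl$iso_b)
    isoforms[[g]] <- iso_df
    events[[g]] <- data.frame(
      gene_id = gene_id, type = "IR", chrom = chrom_name, strand = strand,
      start = pl$event$start, end = pl$event$end,
      iso_canonical = iso_df$iso_id[1], iso_variant = iso_df$iso_id[2],
      stringsAsFactors = FALSE)
    planted[[g]] <- data.frame(
      gene_id = gene_id, prevalent_orf_len = cds_len,
      nonprevalent_orf_len = orf_var,
      planted_shortened_pct = (cds_len - orf_var) / cds_len * 100,
      stringsAsFactors = FALSE)
  }
  chrom_parts <- c(chrom_parts, random_dna(sample(100:300, 1L), gc))
  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- chrom_name
  truth <- list(genome = genome, genes = do.call(rbind, genes),
                isoforms = do.call(rbind, isoforms),
                events = do.call(rbind, events),
                planted = do.call(rbind, planted),
                config = sim_config(n_genes = n_genes, gc_content = gc,
                                    intron_gc = intron_gc,
                                    chrom_name = chrom_name, seed = seed))
  class(truth) <- "as_truth"
  truth
}
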