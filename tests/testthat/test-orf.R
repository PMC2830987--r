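test_that("splice_to_mrna concatenates exons and maps junctions", {
  toy <- toy_genome()
  expect_equal(unname(toy$exons),
               unname(make_blocks(1, 60, 157, 216, 273, 334)))
  m <- splice_to_mrna(toy$exons, "chrT", "+", toy$genome)
  expect_equal(nchar(m$seq), 60L + 60L + 62L)
  expect_equal(m$junctions, c(60L, 120L))
  expect_equal(substr(m$seq, 10, 12), "ATG")
  # single exon: substring identity, no junctions
  m1 <- splice_to_mrna(make_blocks(157, 216), "chrT", "+", toy$genome)
  expect_equal(m1$seq,
               as.character(Biostrings::subseq(toy$genome[[1]], 157, 216)))
  expect_equal(length(m1$junctions), 0L)
})

test_that("minus-strand splicing equals the reverse complement by hand", {
  genome <- Biostrings::DNAStringSet(c(c1 = "AACCGGTTACGTACGT"))
  ex <- make_blocks(1, 4, 9, 12)
  m <- splice_to_mrna(ex, "c1", "-", genome)
  # transcript = revcomp("ACGT") then revcomp("AACC") = "ACGT" + "GGTT"
  expect_equal(m$seq, "ACGTGGTT")
  expect_equal(m$junctions, 4L)
})

test_that("find_orf matches a naive codon scan on random sequences", {
  expect_equal(find_orf("ATGTAA", 1L)$orf_len, 6L)
  expect_equal(find_orf("ATGAAATAG", 1L)$orf_len, 9L)
  expect_true(find_orf("ATGAAACCC", 1L)$no_stop)
  expect_error(find_orf("CCCTAA", 1L), class = "estsplice_orf_error")
  set.seed(55)
  for (i in 1:25) {
    seq <- paste0("ATG", paste(sample(c("A", "C", "G", "T"), 3000L, TRUE),
                               collapse = ""))
    got <- find_orf(seq, 1L)
    want <- oracle_orf(seq, 1L)
    expect_equal(got$orf_len, want$orf_len)
    expect_equal(got$stop_pos, want$stop_pos)
  }
})

test_that("the NMD boundary cases at 49 and 51 nt split on the 50-nt rule", {
  just_below <- nmd_case(49L)
  expect_true(just_below$ptc_introduced)
  expect_false(just_below$nmd_candidate)
  expect_equal(just_below$distance_ptc_to_last_junction, 49L)
  just_above <- nmd_case(51L)
  expect_true(just_above$ptc_introduced)
  expect_true(just_above$nmd_candidate)
  expect_equal(just_above$distance_ptc_to_last_junction, 51L)
})

test_that("a PTC deep in the coding region is an NMD candidate in the CDS", {
  at_rule <- nmd_case(99L)
  expect_true(at_rule$ptc_introduced)
  expect_true(at_rule$nmd_candidate)
  expect_equal(at_rule$location, "CDS")
  expect_gt(at_rule$shortened_pct, 0)
  expect_lte(at_rule$shortened_pct, 100)
})

test_that("events outside the CDS footprint are UTR with no PTC call", {
  toy <- toy_genome()
  # move the start codon downstream of intron1: the event is 5' UTR
  s <- strsplit(as.character(toy$genome[[1]]), "")[[1]]
  s[10:12] <- c("G", "G", "G")        # remove the original ATG
  s[157:159] <- c("A", "T", "G")      # new start at exon2 begin
  genome <- Biostrings::DNAStringSet(setNames(paste(s, collapse = ""),
                                              "chrT"))
  ev <- data.frame(cluster_id = "c1", chrom = "chrT", strand = "+",
                   type = "IR", start = 61L, end = 156L,
                   stringsAsFactors = FALSE)
  gene <- data.frame(gene_id = "g1", cds_start = 157L,
                     stringsAsFactors = FALSE)
  rep <- assess_event(ev, toy$exons,
                      make_blocks(1, 216, 273, 334), gene, genome)
  expect_equal(rep$location, "UTR")
  expect_false(rep$nmd_candidate)
})

test_that("assessment is invariant to the strand the gene sits on", {
  truth <- simulate_ptc_genes(n_genes = 12L, seed = 77L)
  strands <- truth$genes$strand
  expect_true(all(c("+", "-") %in% strands))  # both orientations exercised
  ests <- sample_ests(truth)
  cl <- cluster_alignments(filter_alignments(ests$alignments)$kept)
  genes <- truth$genes
  class(genes) <- c("gene_models", "data.frame")
  cl <- associate_genes(cl, genes)
  ev <- call_prevalent(detect_events(cl))
  elig <- eligible_events(cl, ev, genes)
  reps <- do.call(rbind, lapply(seq_len(nrow(elig)), function(i) {
    assess_event(elig[i, ], elig$prevalent_exons[[i]],
                 elig$nonprevalent_exons[[i]],
                 genes[match(elig$gene_id[i], genes$gene_id), ],
                 truth$genome)
  }))
  reps$strand <- elig$strand
  m <- match(elig$gene_id, truth$planted$gene_id)
  expect_equal(reps$prevalent_orf_len, truth$planted$prevalent_orf_len[m])
  expect_equal(reps$nonprevalent_orf_len,
               truth$planted$nonprevalent_orf_len[m])
  expect_true(all(reps$ptc_introduced))
  expect_true(all(reps$location == "CDS"))
  # per-strand means agree: orientation does not bias the assessment
  agg <- tapply(reps$shortened_pct - truth$planted$planted_shortened_pct[m],
                reps$strand, function(x) max(abs(x)))
  expect_true(all(agg < 1e-9))
})

test_that("multi-event clusters and unannotated genes are ineligible", {
  sm <- sim_mixed()
  cl <- cluster_alignments(sm$ests$alignments)
  genes <- sm$truth$genes
  class(genes) <- c("gene_models", "data.frame")
  cl <- associate_genes(cl, genes)
  ev <- call_prevalent(detect_events(cl))
  n_by_cluster <- table(ev$cluster_id)
  elig <- eligible_events(cl, ev, genes)
  expect_true(all(n_by_cluster[unique(elig$cluster_id)] == 1L))
  # removing the start codon annotation excludes a gene
  genes2 <- genes
  genes2$cds_start <- NA_integer_
  expect_equal(nrow(eligible_events(cl, ev, genes2)), 0L)
})

test_that("impact_table reproduces printed-table arithmetic", {
  fake_reports <- function(per_type_cds, per_type_utr) {
    rows <- list()
    for (ty in names(per_type_cds)) {
      n_c <- per_type_cds[[ty]]; n_u <- per_type_utr[[ty]]
      if (n_c + n_u == 0) next
      rows[[ty]] <- data.frame(
        event_type = ty,
        location = rep(c("CDS", "UTR"), c(n_c, n_u)),
        shortened_by = 300, shortened_pct = 50,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  # counts as printed for the coding-sequence side of the ledger
  tab <- impact_table(fake_reports(
    c(IR = 30, ES = 4, Alt5 = 6, Alt3 = 22, AltB = 0),
    c(IR = 1, ES = 0, Alt5 = 4, Alt3 = 9, AltB = 0)))
  expect_equal(tab$n_cds[tab$event_type == "Total/Avg"], 62)
  expect_equal(tab$n_utr[tab$event_type == "Total/Avg"], 14)
  # per-type totals summed over the table
  tot <- impact_table(fake_reports(
    c(IR = 31, ES = 4, Alt5 = 11, Alt3 = 31, AltB = 0),
    c(IR = 0, ES = 0, Alt5 = 0, Alt3 = 0, AltB = 0)))
  expect_equal(tot$n_total[tot$event_type == "Total/Avg"], 77)

  empty <- impact_table(data.frame(event_type = character(0),
                                   location = character(0),
                                   shortened_by = numeric(0),
                                   shortened_pct = numeric(0)))
  expect_true(all(empty$n_total == 0))
})
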