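test_that("a no-AS config yields one gene, one isoform, no events", {
  cfg <- sim_config(n_genes = 1L, exons_per_gene_range = c(2L, 2L),
                    as_rates = c(IR = 0, ES = 0, Alt5 = 0, Alt3 = 0,
                                 AltB = 0), seed = 7L)
  truth <- simulate_genome(cfg)
  expect_equal(nrow(truth$genes), 1L)
  expect_equal(nrow(truth$isoforms), 1L)
  expect_equal(nrow(truth$events), 0L)
  expect_equal(nrow(truth$isoforms$exons[[1]]), 2L)
})

test_that("genome GC tracks the configured fraction", {
  truth <- simulate_genome(sim_config(n_genes = 50L, gc_content = 0.64,
                                      seed = 1L))
  gc <- gc_fraction(as.character(truth$genome))
  expect_gte(gc, 0.61)
  expect_lte(gc, 0.67)
})

test_that("forced IR rates plant one IR event and a second isoform per gene", {
  truth <- simulate_genome(sim_config(
    n_genes = 10L, seed = 3L,
    as_rates = c(IR = 1, ES = 0, Alt5 = 0, Alt3 = 0, AltB = 0)))
  expect_gte(sum(truth$events$type == "IR"), 10L)
  n_iso <- table(truth$isoforms$gene_id)
  expect_true(all(n_iso[unique(truth$events$gene_id)] >= 2L))
})

test_that("every emitted intron is GT..AG with a C-rich 3' end", {
  truth <- sim_mixed()$truth
  donors <- character(0); acceptors <- character(0); tails <- character(0)
  for (i in seq_len(nrow(truth$isoforms))) {
    ex <- truth$isoforms$exons[[i]]
    if (nrow(ex) < 2L) next
    intr <- cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L)
    st <- truth$isoforms$strand[i]
    for (j in seq_len(nrow(intr))) {
      seq <- splice_to_mrna(matrix(intr[j, ], ncol = 2), truth$isoforms$chrom[i],
                            st, truth$genome)$seq
      donors <- c(donors, substr(seq, 1L, 2L))
      n <- nchar(seq)
      acceptors <- c(acceptors, substr(seq, n - 1L, n))
      tails <- c(tails, substr(seq, n - 11L, n - 2L))
    }
  }
  expect_true(all(donors == "GT"))
  expect_true(all(acceptors == "AG"))
  # C enrichment in the last 10 intronic nt before the AG
  tail_c <- mean(strsplit(paste(tails, collapse = ""), "")[[1]] == "C")
  expect_gt(tail_c, 0.36)
})

test_that("same config and seed reproduce byte-identical outputs", {
  run <- function(dir) {
    cfg <- sim_config(n_genes = 5L, seed = 9L)
    truth <- simulate_genome(cfg)
    write_simulation(truth, sample_ests(truth), dir)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run(d1); run(d2)
  for (f in c("genome.fasta", "genes.gff3", "ests.psl",
              "truth_events.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("plant_event builds the structure each event type dictates", {
  ex2 <- make_blocks(101, 200, 301, 400)
  ex3 <- make_blocks(101, 200, 301, 400, 501, 600)
  ir <- plant_event(ex2, "IR")
  expect_equal(unname(ir$iso_b), unname(make_blocks(101, 400)))
  expect_equal(c(ir$event$start, ir$event$end), c(201, 300))

  es <- plant_event(ex3, "ES", exon = 2L)
  expect_equal(unname(es$iso_b), unname(make_blocks(101, 200, 501, 600)))
  expect_equal(c(es$event$start, es$event$end), c(301, 400))
  expect_error(plant_event(ex2, "ES"), class = "estsplice_plant_error")

  a5 <- plant_event(ex2, "Alt5", intron = 1L, shift5 = 5L)
  expect_equal(unname(a5$iso_b), unname(make_blocks(101, 205, 301, 400)))
  # on the minus strand the donor is the genomic end of the intron
  a5m <- plant_event(ex2, "Alt5", strand = "-", intron = 1L, shift5 = 5L)
  expect_equal(unname(a5m$iso_b), unname(make_blocks(101, 200, 296, 400)))
  ab <- plant_event(ex2, "AltB", intron = 1L, shift5 = 4L, shift3 = 6L)
  expect_equal(unname(ab$iso_b), unname(make_blocks(101, 204, 295, 400)))
  expect_error(plant_event(ex2, "Alt5", shift5 = 2L),
               class = "estsplice_plant_error")
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(as_rates = c(IR = 1.5)),
               class = "estsplice_config_error")
  expect_error(sim_config(exons_per_gene_range = c(1L, 1L),
                          as_rates = c(IR = 0.5)),
               class = "estsplice_config_error")
  expect_error(sim_config(est_len_range = c(0L, 100L)),
               class = "estsplice_config_error")
})

test_that("full-length ESTs cover every exon block of their isoform", {
  sm <- sim_mixed()
  aln <- sm$ests$alignments
  origins <- sm$ests$origins
  iso <- sm$truth$isoforms
  for (i in sample(seq_len(nrow(aln)), 25L)) {
    iso_id <- origins$iso_id[origins$est_id == aln$est_id[i]]
    expect_equal(unname(aln$blocks[[i]]),
                 unname(iso$exons[[match(iso_id, iso$iso_id)]]))
  }
})

test_that("partial ESTs project through the exon map with the intron gap", {
  truth <- simulate_genome(sim_config(n_genes = 1L,
                                      exons_per_gene_range = c(2L, 2L),
                                      as_rates = c(IR = 0), seed = 11L))
  ex <- truth$isoforms$exons[[1]]
  st <- truth$isoforms$strand[1]
  w1 <- ex[1, 2] - ex[1, 1] + 1L
  # an EST overlapping the junction by 30 nt on each side
  cfg <- truth$config
  cfg$est_len_range <- c(60L, 60L)
  cfg$ests_per_isoform_range <- c(50L, 50L)
  ests <- sample_ests(truth, cfg)
  two_block <- which(vapply(ests$alignments$blocks, nrow, integer(1)) == 2L)
  expect_gt(length(two_block), 0L)
  for (i in two_block) {
    b <- ests$alignments$blocks[[i]]
    expect_equal(b[1, 2], ex[1, 2])      # first block ends at the junction
    expect_equal(b[2, 1], ex[2, 1])      # second starts after the intron
    expect_equal(sum(b[, 2] - b[, 1] + 1L), 60L)
  }
})

test_that("est lengths exceeding the isoform are clamped with a warning", {
  truth <- simulate_genome(sim_config(n_genes = 1L, seed = 2L))
  cfg <- truth$config
  cfg$est_len_range <- c(10000000L, 10000001L)
  expect_warning(ests <- sample_ests(truth, cfg), "clamp")
  L <- sum(truth$isoforms$exons[[1]][, 2] - truth$isoforms$exons[[1]][, 1] + 1L)
  expect_true(all(ests$alignments$qsize == L))
})

test_that("the PTC generator plants the exact truncated ORF it reports", {
  truth <- simulate_ptc_genes(n_genes = 8L, seed = 13L)
  genome <- truth$genome
  for (g in seq_len(nrow(truth$genes))) {
    gene <- truth$genes[g, ]
    iso <- truth$isoforms[truth$isoforms$gene_id == gene$gene_id, ]
    for (k in 1:2) {
      m <- splice_to_mrna(iso$exons[[k]], gene$chrom, gene$strand, genome)
      atg <- genomic_to_tx(iso$exons[[k]], gene$strand, gene$cds_start)
      orf <- find_orf(m, atg)
      expected <- if (k == 1L) truth$planted$prevalent_orf_len[g] else
        truth$planted$nonprevalent_orf_len[g]
      expect_equal(orf$orf_len, expected)
    }
  }
})
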