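# A hand-built single-gene genome used across the ORF tests. Layout
# (1-based, plus strand; only G/C outside the marked codons, so no stray
# stop codons can arise in any frame):
#   exon1   [1, 60]                 ATG at [10, 12]
#   intron1 [61, 156]               GTAAGT ... AG (96 nt; 96 %% 3 == 0)
#   exon2   [157, 156+e2]           e2 nt of GC-rich sequence
#   intron2 [157+e2, 212+e2]        56 nt
#   exon3   [213+e2, ...]           filler then TAA, padded so the stop
#                                   is in frame for any e2
toy_genome <- function(e2 = 60L) {
  f <- 57L + ((3L - e2 %% 3L) %% 3L)
  parts <- c(
    paste0("CCCCCCCCC", "ATG", "GCCGCC", strrep("GC", 21L)),  # exon1
    paste0("GTAAGT", strrep("C", 88L), "AG"),                 # intron1
    substr(strrep("GCC", 40L), 1L, e2),                       # exon2
    paste0("GTAAGT", strrep("C", 48L), "AG"),                 # intron2
    paste0(strrep("G", f), "TAA", "CC"))                      # exon3
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- c(1L, ends[-5L] + 1L)
  list(genome = Biostrings::DNAStringSet(c(chrT = paste(parts,
                                                        collapse = ""))),
       exons = make_blocks(starts[1], ends[1], starts[3], ends[3],
                           starts[5], ends[5]),
       intron1 = c(starts[2], ends[2]))
}


# Builds an assessment for an IR event with the PTC planted inside the
# retained intron at a controlled distance upstream of the last junction
# of the non-prevalent transcript. exon2's length is adjusted so the
# planted stop is in frame for any requested distance.
nmd_case <- function(dist) {
  e2 <- 21L + dist %% 3L
  toy <- toy_genome(e2)
  # non-prevalent mRNA merges exon1 + intron1 + exon2; its last junction
  # sits at 60 + 96 + e2, and coordinates up to it equal genome coordinates
  junction <- 156L + e2
  stop_end <- junction - dist
  stopifnot(stop_end > 66L, stop_end < 155L,        # inside the intron body
            (stop_end - 12L) %% 3L == 0L)           # in frame from the ATG
  s <- strsplit(as.character(toy$genome[[1]]), "")[[1]]
  s[(stop_end - 2L):stop_end] <- c("T", "G", "A")
  genome <- Biostrings::DNAStringSet(setNames(paste(s, collapse = ""),
                                              "chrT"))
  ev <- data.frame(cluster_id = "c1", chrom = "chrT", strand = "+",
                   type = "IR", start = 61L, end = 156L,
                   stringsAsFactors = FALSE)
  gene <- data.frame(gene_id = "g1", cds_start = 10L,
                     stringsAsFactors = FALSE)
  nonprev <- make_blocks(1, toy$exons[2, 2], toy$exons[3, 1],
                         toy$exons[3, 2])
  assess_event(ev, prevalent_exons = toy$exons,
               nonprevalent_exons = nonprev, gene = gene, genome = genome)
}

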