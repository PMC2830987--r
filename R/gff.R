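# GFF3 gene-model input/output.
#
# GFF3 is 1-based closed, which is also the internal convention, so no
# coordinate shift is applied; parsing goes through rtracklayer.

#' Read gene models from a GFF3 file
#'
#' Reads gene/mRNA/exon/CDS features. Each gene model carries the exon
#' chain of its first listed mRNA (the canonical isoform) plus all isoform
#' exon chains, and the genomic position of the annotated start codon
#' (first CDS base in transcript orientation), when CDS features are
#' present.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `cds_start` (NA when unannotated)
#'   and list-columns `exons` (canonical exon matrix) and `isoforms`
#'   (named list of exon matrices).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  # contig bounds from ##sequence-region pragmas, if present
  pragmas <- grep("^##sequence-region", readLines(path), value = TRUE)
  bounds <- NULL
  if (length(pragmas)) {
    parts <- strsplit(trimws(pragmas), "\\s+")
    bounds <- setNames(vapply(parts, function(p) as.integer(p[4]), integer(1)),
                       vapply(parts, function(p) p[2], character(1)))
  }
  type <- as.character(gr$type)
  id <- gr$ID
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[1] else NA_character_,
                   character(1))
  is_exon <- type == "exon"
  if (!is.null(bounds) && any(is_exon)) {
    ex_chrom <- as.character(GenomicRanges::seqnames(gr))[is_exon]
    ex_end <- GenomicRanges::end(gr)[is_exon]
    over <- !is.na(bounds[ex_chrom]) & ex_end > bounds[ex_chrom]
    if (any(over)) {
      stop_estsplice(
        sprintf("GFF3 exon beyond contig bounds on %s", ex_chrom[over][1]),
        "estsplice_gff_error")
    }
  }
  genes_i <- which(type == "gene")
  mrna_i <- which(type == "mRNA")
  out <- lapply(genes_i, function(gi) {
    gid <- id[gi]
    mids <- id[mrna_i][parent[mrna_i] == gid]
    isoforms <- lapply(mids, function(mid) {
      ei <- which(is_exon & parent == mid)
      ex <- cbind(start = GenomicRanges::start(gr)[ei],
                  end = GenomicRanges::end(gr)[ei])
      ex[order(ex[, 1]), , drop = FALSE]
    })
    names(isoforms) <- mids
    strand <- as.character(GenomicRanges::strand(gr))[gi]
    cds_start <- NA_integer_
    if (length(mids)) {
      ci <- which(type == "CDS" & parent == mids[1])
      if (length(ci)) {
        cds_start <- if (strand == "-") max(GenomicRanges::end(gr)[ci])
                     else min(GenomicRanges::start(gr)[ci])
      }
    }
    list(gene_id = gid,
         chrom = as.character(GenomicRanges::seqnames(gr))[gi],
         strand = strand,
         start = GenomicRanges::start(gr)[gi],
         end = GenomicRanges::end(gr)[gi],
         cds_start = cds_start,
         exons = if (length(isoforms)) isoforms[[1]] else
           matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))),
         isoforms = isoforms)
  })
  genes <- data.frame(
    gene_id = vapply(out, `[[`, character(1), "gene_id"),
    chrom = vapply(out, `[[`, character(1), "chrom"),
    strand = vapply(out, `[[`, character(1), "strand"),
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    cds_start = vapply(out, `[[`, integer(1), "cds_start"),
    stringsAsFactors = FALSE)
  genes$exons <- lapply(out, `[[`, "exons")
  genes$isoforms <- lapply(out, `[[`, "isoforms")
  class(genes) <- c("gene_models", "data.frame")
  genes
}

# Emit simulator truth as GFF3: gene, one mRNA per isoform with exon
# children, and CDS blocks on the canonical isoform.
write_truth_gff3 <- function(truth, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(truth$genome),
                     Biostrings::width(truth$genome)))
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\testsplice_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  }
  for (g in seq_len(nrow(truth$genes))) {
    ge <- truth$genes[g, ]
    lines <- c(lines, fmt(ge$chrom, "gene", ge$start, ge$end, ge$strand,
                          sprintf("ID=%s", ge$gene_id)))
    iso_rows <- which(truth$isoforms$gene_id == ge$gene_id)
    for (k in seq_along(iso_rows)) {
      iso <- truth$isoforms[iso_rows[k], ]
      ex <- iso$exons[[1]]
      lines <- c(lines,
                 fmt(ge$chrom, "mRNA", ex[1, 1], ex[nrow(ex), 2], ge$strand,
                     sprintf("ID=%s;Parent=%s", iso$iso_id, ge$gene_id)))
      for (e in seq_len(nrow(ex))) {
        lines <- c(lines,
                   fmt(ge$chrom, "exon", ex[e, 1], ex[e, 2], ge$strand,
                       sprintf("ID=%s.exon%d;Parent=%s", iso$iso_id, e,
                               iso$iso_id)))
      }
      if (k == 1L && !is.na(ge$cds_start) && !is.na(ge$cds_end)) {
        ts <- genomic_to_tx(ex, ge$strand, ge$cds_start)
        te <- genomic_to_tx(ex, ge$strand, ge$cds_end)
        cds <- tx_to_genomic(ex, ge$strand, ts, te)
        for (e in seq_len(nrow(cds))) {
          lines <- c(lines,
                     fmt(ge$chrom, "CDS", cds[e, 1], cds[e, 2], ge$strand,
                         sprintf("ID=%s.cds;Parent=%s", iso$iso_id,
                                 iso$iso_id)))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
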