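# Clustering of filtered alignments into transcriptional units.

#' Cluster alignments into transcriptional units
#'
#' Transcriptional units are the connected components of the
#' interval-overlap graph of alignment spans, computed separately per
#' (chromosome, strand); they proxy gene loci. Alignments of unknown
#' strand (single-block ESTs whose strand could not be inferred) are
#' attached to a cluster only when their span lies fully inside exactly
#' one cluster's span; otherwise they are dropped.
#'
#' @param aln A `spliced_alignments` data frame (column `strand` may
#'   contain `"unknown"`).
#' @return A list of class `tx_clusters` with `clusters` (data frame:
#'   `cluster_id`, `chrom`, `strand`, `start`, `end`, `n_ests`, and after
#'   [associate_genes()] a `gene_ids` list-column), `alignments` (the
#'   input rows that were clustered, plus a `cluster_id` column), and
#'   `dropped` (unattachable unknown-strand rows).
#' @export
cluster_alignments <- function(aln) {
  known <- aln$strand %in% c("+", "-")
  kn <- aln[known, , drop = FALSE]
  spans <- alignment_spans(kn)
  kn$cluster_id <- rep(NA_character_, nrow(kn))
  clusters <- list()
  if (nrow(kn)) {
    key <- paste(kn$chrom, kn$strand)
    cl_n <- 0L
    for (k in unique(key)) {
      ix <- which(key == k)
      ir <- IRanges::IRanges(spans[ix, 1], spans[ix, 2])
      hits <- IRanges::findOverlaps(ir, ir)  # >= 1 bp shared
      g <- igraph::graph_from_data_frame(
        data.frame(from = S4Vectors::queryHits(hits),
                   to = S4Vectors::subjectHits(hits)),
        directed = FALSE,
        vertices = data.frame(name = seq_along(ix)))
      comp <- igraph::components(g)$membership
      for (c_i in sort(unique(comp))) {
        cl_n <- cl_n + 1L
        cid <- sprintf("cluster%04d", cl_n)
        members <- ix[comp == c_i]
        kn$cluster_id[members] <- cid
        clusters[[cl_n]] <- data.frame(
          cluster_id = cid, chrom = kn$chrom[members[1]],
          strand = kn$strand[members[1]],
          start = min(spans[members, 1]), end = max(spans[members, 2]),
          n_ests = length(unique(kn$est_id[members])),
          stringsAsFactors = FALSE)
      }
    }
  }
  cl_df <- if (length(clusters)) do.call(rbind, clusters) else data.frame(
    cluster_id = character(0), chrom = character(0), strand = character(0),
    start = integer(0), end = integer(0), n_ests = integer(0),
    stringsAsFactors = FALSE)

  # unknown-strand single-block alignments: adopt by containment
  unk <- aln[!known, , drop = FALSE]
  dropped <- unk[0, , drop = FALSE]
  if (nrow(unk)) {
    uspans <- alignment_spans(unk)
    adopt <- integer(nrow(unk))
    for (i in seq_len(nrow(unk))) {
      inside <- which(cl_df$chrom == unk$chrom[i] &
                        cl_df$start <= uspans[i, 1] &
                        cl_df$end >= uspans[i, 2])
      adopt[i] <- if (length(inside) == 1L) inside else 0L
    }
    adopted <- unk[adopt > 0L, , drop = FALSE]
    if (nrow(adopted)) {
      adopted$strand <- cl_df$strand[adopt[adopt > 0L]]
      adopted$cluster_id <- cl_df$cluster_id[adopt[adopt > 0L]]
      kn <- rbind(kn, adopted)
      tab <- table(adopted$cluster_id)
      m <- match(names(tab), cl_df$cluster_id)
      cl_df$n_ests[m] <- cl_df$n_ests[m] + as.integer(tab)
    }
    dropped <- unk[adopt == 0L, , drop = FALSE]
  }
  out <- list(clusters = cl_df, alignments = kn, dropped = dropped)
  class(out) <- "tx_clusters"
  out
}

#' Associate clusters with annotated gene models
#'
#' A cluster is associated with every gene model it overlaps by at least
#' one base on the same strand.
#'
#' @param clusters A `tx_clusters` object.
#' @param genes A `gene_models` data frame from [read_gff3()] (or the
#'   `genes` element of a simulation truth).
#' @return `clusters` with a `gene_ids` list-column added to
#'   `clusters$clusters`.
#' @export
associate_genes <- function(clusters, genes) {
  cl <- clusters$clusters
  gene_ids <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    hit <- genes$chrom == cl$chrom[i] & genes$strand == cl$strand[i] &
      genes$start <= cl$end[i] & genes$end >= cl$start[i]
    gene_ids[[i]] <- genes$gene_id[hit]
  }
  cl$gene_ids <- gene_ids
  clusters$clusters <- cl
  clusters
}
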