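# Internal sequence and coordinate helpers.
#
# All internal coordinates are 1-based closed intervals (the IRanges
# convention); 0-based half-open coordinates appear only at PSL/BED file
# boundaries.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, n = 1L) x[sample.int(length(x), n, replace = FALSE)]

# uniform integer draw from [a, b]
runif_int <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

stop_estsplice <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "estsplice_error")))
}

#' Random DNA of a given GC content
#' @noRd
random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Random coding sequence of n_codons codons, none of them stop codons,
# drawn base-wise at the given GC content.
random_codons <- function(n_codons, gc) {
  if (n_codons <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  b <- sample(BASES, 3 * n_codons, replace = TRUE, prob = p)
  cod <- paste0(b[c(TRUE, FALSE, FALSE)], b[c(FALSE, TRUE, FALSE)],
                b[c(FALSE, FALSE, TRUE)])
  bad <- which(cod %in% c("TAA", "TAG", "TGA"))
  while (length(bad)) {
    for (i in bad) {
      cod[i] <- paste(sample(BASES, 3, replace = TRUE, prob = p),
                      collapse = "")
    }
    bad <- which(cod %in% c("TAA", "TAG", "TGA"))
  }
  paste(cod, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract genome sequence for a 1-based closed interval
#'
#' Returns the sequence in transcript orientation: reverse-complemented
#' when `strand` is "-".
#' @noRd
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop_estsplice(sprintf("chromosome '%s' not in genome", chrom),
                   "estsplice_coord_error")
  }
  len <- length(genome[[chrom]])
  if (start < 1L || end > len || start > end) {
    stop_estsplice(
      sprintf("interval %s:%d-%d outside contig bounds [1,%d]",
              chrom, start, end, len),
      "estsplice_coord_error")
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  if (strand == "-") revcomp(s) else s
}

#' Map a transcript interval to genomic blocks
#'
#' Projects a 1-based interval `[ts, te]` on the spliced transcript back
#' through an exon chain into genomic blocks.
#'
#' @param exons Ascending 2-column matrix of genomic exon intervals
#'   (1-based closed).
#' @param strand `"+"` or `"-"` (transcript order is reversed on `"-"`).
#' @param ts,te Transcript coordinates (1-based, closed).
#' @return 2-column integer matrix of genomic blocks, ascending.
#' @export
tx_to_genomic <- function(exons, strand, ts, te) {
  w <- exons[, 2] - exons[, 1] + 1L
  ord <- if (strand == "-") rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  offs <- cumsum(c(0L, w[ord]))  # transcript offset before each exon
  blocks <- NULL
  for (k in seq_along(ord)) {
    e_ts <- offs[k] + 1L
    e_te <- offs[k + 1L]
    lo <- max(ts, e_ts); hi <- min(te, e_te)
    if (lo > hi) next
    i <- ord[k]
    if (strand == "+") {
      gs <- exons[i, 1] + (lo - e_ts)
      ge <- exons[i, 1] + (hi - e_ts)
    } else {
      ge <- exons[i, 2] - (lo - e_ts)
      gs <- exons[i, 2] - (hi - e_ts)
    }
    blocks <- rbind(blocks, c(gs, ge))
  }
  blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  storage.mode(blocks) <- "integer"
  colnames(blocks) <- c("start", "end")
  blocks
}

#' Map a genomic position to its transcript coordinate
#'
#' Inverse of [tx_to_genomic()] for a single position; returns NA when
#' the position is intronic or outside the exon chain.
#'
#' @inheritParams tx_to_genomic
#' @param gpos Genomic position (1-based).
#' @return Transcript coordinate, or NA.
#' @export
genomic_to_tx <- function(exons, strand, gpos) {
  w <- exons[, 2] - exons[, 1] + 1L
  ord <- if (strand == "-") rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  off <- 0L
  for (i in ord) {
    if (gpos >= exons[i, 1] && gpos <= exons[i, 2]) {
      d <- if (strand == "+") gpos - exons[i, 1] else exons[i, 2] - gpos
      return(as.integer(unname(off + d + 1L)))
    }
    off <- off + w[i]
  }
  NA_integer_
}

# Introns implied by an exon chain / block matrix (ascending genomic order).
blocks_to_introns <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = blocks[-n, 2] + 1L, end = blocks[-1, 1] - 1L)
}
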