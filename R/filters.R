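# Alignment quality filtering and strand inference.

#' Filter spliced alignments on quality criteria
#'
#' Keeps alignments with identity and EST coverage above the given
#' thresholds and with every inter-block gap (putative intron) inside
#' `[min_intron, max_intron]`. After the quality filters, an EST that
#' still has several alignments keeps only its single best one (by
#' matches); ESTs whose best alignments are exactly tied are dropped
#' entirely as ambiguous, which guards against paralog cross-mapping
#' creating false splice variants.
#'
#' @param aln A `spliced_alignments` data frame.
#' @param min_identity Minimum identity, matches/(matches+mismatches).
#' @param min_coverage Minimum fraction of the EST length aligned.
#' @param min_intron,max_intron Allowed inter-block gap range in nt.
#' @return A list with elements `kept` (a `spliced_alignments` data frame)
#'   and `rejected` (the rejected rows plus a machine-readable `reason`
#'   column: `low_identity`, `low_coverage`, `short_intron`, `long_intron`,
#'   `ambiguous`, or `secondary_alignment`).
#' @export
filter_alignments <- function(aln, min_identity = 0.95, min_coverage = 0.8,
                              min_intron = 40L, max_intron = 10000L) {
  reason <- rep(NA_character_, nrow(aln))
  gaps <- lapply(aln$blocks, blocks_to_introns)
  gap_min <- vapply(gaps, function(g) if (nrow(g)) min(g[, 2] - g[, 1] + 1L)
                    else NA_integer_, integer(1))
  gap_max <- vapply(gaps, function(g) if (nrow(g)) max(g[, 2] - g[, 1] + 1L)
                    else NA_integer_, integer(1))
  reason[is.na(reason) & aln$identity < min_identity] <- "low_identity"
  reason[is.na(reason) & aln$est_coverage < min_coverage] <- "low_coverage"
  reason[is.na(reason) & !is.na(gap_min) & gap_min < min_intron] <-
    "short_intron"
  reason[is.na(reason) & !is.na(gap_max) & gap_max > max_intron] <-
    "long_intron"
  # ambiguity among surviving alignments of the same EST
  ok <- which(is.na(reason))
  if (length(ok)) {
    for (ids in split(ok, aln$est_id[ok])) {
      if (length(ids) < 2L) next
      best <- max(aln$matches[ids])
      top <- ids[aln$matches[ids] == best]
      if (length(top) > 1L) {
        reason[ids] <- "ambiguous"
      } else {
        reason[setdiff(ids, top)] <- "secondary_alignment"
      }
    }
  }
  keep <- is.na(reason)
  rejected <- aln[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = aln[keep, , drop = FALSE], rejected = rejected)
}

#' Infer transcription strand from splice-site dinucleotides
#'
#' A spliced alignment's gaps are read from the genome: if every gap starts
#' GT and ends AG the transcript is on the forward strand; if every gap
#' reads CT..AC (the reverse complement) it is on the reverse strand.
#' Conflicting gaps, non-canonical gaps, or a single-block alignment give
#' `"unknown"`.
#'
#' @param aln A single-row `spliced_alignments` data frame (or a row index
#'   into a larger one via `aln[i, ]`).
#' @param genome A named `DNAStringSet`.
#' @return `"+"`, `"-"`, or `"unknown"`.
#' @export
infer_strand <- function(aln, genome) {
  stopifnot(nrow(aln) == 1L)
  g <- blocks_to_introns(aln$blocks[[1]])
  if (!nrow(g)) return("unknown")
  verdict <- apply(g, 1, function(iv) {
    left <- genome_seq(genome, aln$chrom, iv[1], iv[1] + 1L)
    right <- genome_seq(genome, aln$chrom, iv[2] - 1L, iv[2])
    if (left == "GT" && right == "AG") "+"
    else if (left == "CT" && right == "AC") "-"
    else "unknown"
  })
  u <- unique(verdict)
  if (length(u) == 1L && u != "unknown") u else "unknown"
}
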