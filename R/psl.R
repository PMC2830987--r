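# PSL (BLAT 21-column) input/output.
#
# PSL uses 0-based half-open block coordinates; they are converted to the
# package-internal 1-based closed convention on read and back on write.

PSL_HEADER <- c(
  "psLayout version 3", "",
  paste0("match\tmis- \trep. \tN's\tQ gap\tQ gap\tT gap\tT gap\tstrand\tQ",
         "        \tQ   \tQ    \tQ  \tT        \tT   \tT    \tT  \tblock",
         "\tblockSizes \tqStarts\t tStarts"),
  paste0("     \tmatch\tmatch\t   \tcount\tbases\tcount\tbases\t      \tname",
         "     \tsize\tstart\tend\tname     \tsize\tstart\tend\tcount"),
  strrep("-", 159))

#' Read spliced alignments from a PSL file
#'
#' Parses the 21-column tab-separated alignment format produced by BLAT,
#' with or without its 5-line header. Block coordinates are converted to
#' 1-based closed genomic intervals; per-alignment identity is computed as
#' matches/(matches + mismatches) and EST coverage as aligned bases / EST
#' length.
#'
#' @param path Path to a PSL file.
#' @return A data frame of class `spliced_alignments` with one row per
#'   alignment and a `blocks` list-column of 2-column integer matrices
#'   (columns `start`, `end`, 1-based closed, ascending).
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  line0 <- 0L
  if (length(lines) && startsWith(lines[1], "psLayout")) {
    lines <- lines[-seq_len(5L)]
    line0 <- 5L
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    bad <- which(nf != 21L)[1]
    stop_estsplice(
      sprintf("malformed PSL line %d: %d columns, expected 21",
              bad + line0, nf[bad]),
      "estsplice_psl_error")
  }
  m <- do.call(rbind, fields)
  int <- function(j) as.integer(m[, j])
  blocks <- lapply(seq_len(nrow(m)), function(i) {
    sizes <- as.integer(strsplit(m[i, 19], ",", fixed = TRUE)[[1]])
    tst <- as.integer(strsplit(m[i, 21], ",", fixed = TRUE)[[1]])
    b <- cbind(start = tst + 1L, end = tst + sizes)
    b[order(b[, 1]), , drop = FALSE]
  })
  aln <- data.frame(
    est_id = m[, 10], chrom = m[, 14],
    strand = substr(m[, 9], 1L, 1L),
    matches = int(1), mismatches = int(2), repmatches = int(3),
    ncount = int(4), qnuminsert = int(5), qbaseinsert = int(6),
    tnuminsert = int(7), tbaseinsert = int(8),
    qsize = int(11), qstart = int(12), qend = int(13),
    tsize = int(15), tstart = int(16), tend = int(17),
    blockcount = int(18),
    qstarts = m[, 20],
    stringsAsFactors = FALSE)
  aln$blocks <- blocks
  aln$identity <- ifelse(aln$matches + aln$mismatches > 0,
                         aln$matches / (aln$matches + aln$mismatches), 0)
  aln$est_coverage <- vapply(blocks, function(b) sum(b[, 2] - b[, 1] + 1L),
                             numeric(1)) / aln$qsize
  class(aln) <- c("spliced_alignments", "data.frame")
  aln
}

empty_alignments <- function() {
  aln <- data.frame(
    est_id = character(0), chrom = character(0), strand = character(0),
    matches = integer(0), mismatches = integer(0), repmatches = integer(0),
    ncount = integer(0), qnuminsert = integer(0), qbaseinsert = integer(0),
    tnuminsert = integer(0), tbaseinsert = integer(0),
    qsize = integer(0), qstart = integer(0), qend = integer(0),
    tsize = integer(0), tstart = integer(0), tend = integer(0),
    blockcount = integer(0), qstarts = character(0),
    stringsAsFactors = FALSE)
  aln$blocks <- list()
  aln$identity <- numeric(0)
  aln$est_coverage <- numeric(0)
  class(aln) <- c("spliced_alignments", "data.frame")
  aln
}

#' Write spliced alignments to a PSL file
#'
#' Inverse of [read_psl()]; emits BLAT's 21-column format with the standard
#' 5-line header. For minus-strand alignments, `qStarts` follow the BLAT
#' convention of coordinates on the reverse-complemented query.
#'
#' @param aln A `spliced_alignments` data frame.
#' @param path Output path.
#' @param header Write the 5-line psLayout header (default TRUE).
#' @export
write_psl <- function(aln, path, header = TRUE) {
  rows <- vapply(seq_len(nrow(aln)), function(i) {
    b <- aln$blocks[[i]]
    sizes <- b[, 2] - b[, 1] + 1L
    tstarts <- b[, 1] - 1L
    qst <- aln$qstarts[i]
    if (is.na(qst) || !nzchar(qst)) {
      # reconstruct gapless query starts from block sizes
      if (aln$strand[i] == "-") {
        qends_rc <- aln$qsize[i] - aln$qstart[i] - c(0L, cumsum(rev(sizes)))
        qs <- rev(qends_rc[-1])
      } else {
        qs <- aln$qstart[i] + cumsum(c(0L, sizes[-length(sizes)]))
      }
      qst <- paste0(paste(qs, collapse = ","), ",")
    }
    paste(aln$matches[i], aln$mismatches[i], aln$repmatches[i],
          aln$ncount[i], aln$qnuminsert[i], aln$qbaseinsert[i],
          aln$tnuminsert[i], aln$tbaseinsert[i], aln$strand[i],
          aln$est_id[i], aln$qsize[i], aln$qstart[i], aln$qend[i],
          aln$chrom[i], aln$tsize[i], aln$tstart[i], aln$tend[i],
          nrow(b),
          paste0(paste(sizes, collapse = ","), ","),
          qst,
          paste0(paste(tstarts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  out <- c(if (header) PSL_HEADER, rows)
  writeLines(out, path)
  invisible(path)
}

#' Genomic span of each alignment
#' @noRd
alignment_spans <- function(aln) {
  cbind(start = vapply(aln$blocks, function(b) b[1, 1], integer(1)),
        end = vapply(aln$blocks, function(b) b[nrow(b), 2], integer(1)))
}

#' Introns implied by spliced alignments
#'
#' One row per inter-block gap of each alignment: the putative intron in
#' 1-based closed genomic coordinates, with the supporting EST.
#'
#' @param aln A `spliced_alignments` data frame.
#' @return Data frame with columns `est_id`, `chrom`, `strand`, `start`,
#'   `end`.
#' @export
alignment_introns <- function(aln) {
  out <- lapply(seq_len(nrow(aln)), function(i) {
    g <- blocks_to_introns(aln$blocks[[i]])
    if (!nrow(g)) return(NULL)
    data.frame(est_id = aln$est_id[i], chrom = aln$chrom[i],
               strand = aln$strand[i], start = g[, 1], end = g[, 2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(est_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  out
}
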