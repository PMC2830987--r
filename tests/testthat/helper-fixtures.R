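# Shared fixtures: toy alignment constructor and cached simulations.

make_blocks <- function(...) {
  m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# Minimal spliced_alignments data frame from a list of block matrices.
make_aln <- function(blocks, strand = "+", chrom = "chrS", ids = NULL,
                     qsize = NULL, matches = NULL, mismatches = 0L) {
  n <- length(blocks)
  if (is.null(ids)) ids <- sprintf("est%02d", seq_len(n))
  widths <- vapply(blocks, function(b) sum(b[, 2] - b[, 1] + 1L), integer(1))
  if (is.null(qsize)) qsize <- widths
  if (is.null(matches)) matches <- widths - mismatches
  aln <- data.frame(
    est_id = ids, chrom = chrom,
    strand = rep(strand, length.out = n),
    matches = as.integer(matches),
    mismatches = as.integer(rep(mismatches, length.out = n)),
    repmatches = 0L, ncount = 0L, qnuminsert = 0L, qbaseinsert = 0L,
    tnuminsert = vapply(blocks, nrow, integer(1)) - 1L,
    tbaseinsert = 0L,
    qsize = as.integer(qsize), qstart = 0L, qend = as.integer(qsize),
    tsize = 100000L,
    tstart = vapply(blocks, function(b) b[1, 1] - 1L, integer(1)),
    tend = vapply(blocks, function(b) b[nrow(b), 2], integer(1)),
    blockcount = vapply(blocks, nrow, integer(1)),
    qstarts = NA_character_,
    stringsAsFactors = FALSE)
  aln$blocks <- blocks
  aln$identity <- aln$matches / (aln$matches + aln$mismatches)
  aln$est_coverage <- widths / aln$qsize
  class(aln) <- c("spliced_alignments", "data.frame")
  aln
}

# Simulations reused across test files (built once per session).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, fn(), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

sim_mixed <- function() {
  cached("sim_mixed", function() {
    truth <- simulate_genome(sim_config(
      n_genes = 30L, seed = 42L,
      as_rates = c(IR = 0.3, ES = 0.2, Alt5 = 0.2, Alt3 = 0.2, AltB = 0.1)))
    ests <- sample_ests(truth)
    list(truth = truth, ests = ests)
  })
}

# Canonical string form of an event list for set comparison.
event_key <- function(events) {
  if (!nrow(events)) return(character(0))
  sort(vapply(seq_len(nrow(events)), function(i) {
    f <- events$forms[[i]]
    forms <- sort(vapply(seq_len(nrow(f)), function(j) {
      paste0(paste(sort(f$ests[[j]]), collapse = ","))
    }, character(1)))
    paste(events$type[i], events$start[i], events$end[i],
          paste(forms, collapse = "/"))
  }, character(1)))
}
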