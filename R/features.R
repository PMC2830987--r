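# Length and GC statistics contrasting alternative and constitutive
# introns / exons.

#' GC fraction of sequences
#'
#' (#G + #C) / (#A + #C + #G + #T), case-insensitive; non-ACGT bases are
#' excluded from both numerator and denominator. Sequences that are empty
#' or contain no ACGT base are undefined and yield NA with a warning.
#'
#' @param x Character vector of sequences (or a `DNAStringSet`).
#' @return Numeric vector of GC fractions.
#' @export
gc_fraction <- function(x) {
  x <- toupper(as.character(x))
  counts <- vapply(strsplit(x, "", fixed = TRUE), function(b) {
    c(gc = sum(b %in% c("G", "C")), acgt = sum(b %in% BASES))
  }, numeric(2))
  bad <- counts["acgt", ] == 0
  if (any(bad)) {
    warning(sprintf("%d sequence(s) with no ACGT bases: GC undefined",
                    sum(bad)))
  }
  unname(ifelse(bad, NA_real_, counts["gc", ] / counts["acgt", ]))
}

#' Length distribution summary
#'
#' @param x Numeric lengths, or a 2-column matrix / data frame of 1-based
#'   closed intervals (lengths are `end - start + 1`).
#' @return A list with `n`, `median` (even n: mean of the central pair),
#'   `q1`, `q3`, `mean`, `min`, `max`.
#' @export
length_summary <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.numeric(x[, 2]) - as.numeric(x[, 1]) + 1
  }
  stopifnot(length(x) >= 1L)
  q <- unname(quantile(x, c(0.25, 0.75)))
  list(n = length(x), median = median(x), q1 = q[1], q3 = q[2],
       mean = mean(x), min = min(x), max = max(x))
}

#' Contrast a feature between two groups
#'
#' Two-sided two-sample test on a per-element feature (GC fraction or
#' length), Welch t-test by default as is conventional for these
#' composition contrasts. Identical zero-variance groups give p = 1.
#'
#' @param a,b Numeric feature vectors (each n >= 2; NAs dropped).
#' @param feature Label carried into the result row.
#' @param test `"ttest"` (default) or `"ranksum"`.
#' @return One-row data frame: `feature`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `mean_a`, `mean_b`, `test`, `p_value`.
#' @export
feature_contrast <- function(a, b, feature = "feature",
                             test = c("ttest", "ranksum")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (sd(c(a, b)) == 0) {
    p <- 1
  } else if (test == "ttest") {
    p <- t.test(a, b)$p.value
  } else {
    p <- wilcox.test(a, b, exact = FALSE)$p.value
  }
  data.frame(feature = feature, n_a = length(a), n_b = length(b),
             median_a = median(a), median_b = median(b),
             mean_a = mean(a), mean_b = mean(b),
             test = if (test == "ttest") "Welch t-test"
                    else "Wilcoxon rank-sum",
             p_value = p, stringsAsFactors = FALSE)
}

# Unique internal exons (blocks that are neither first nor last in their
# alignment) of a set of alignments.
internal_exons <- function(aln) {
  out <- lapply(seq_len(nrow(aln)), function(i) {
    b <- aln$blocks[[i]]
    if (nrow(b) < 3L) return(NULL)
    data.frame(chrom = aln$chrom[i], strand = aln$strand[i],
               start = b[-c(1L, nrow(b)), 1], end = b[-c(1L, nrow(b)), 2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(chrom = character(0),
                                      strand = character(0),
                                      start = integer(0), end = integer(0),
                                      stringsAsFactors = FALSE))
  unique(out)
}

# Unique introns of the alignments in clusters without any detected event
# ("constitutive", i.e. EST-confirmed but never alternatively spliced).
constitutive_introns <- function(clusters, events) {
  as_clusters <- unique(events$cluster_id)
  aln <- clusters$alignments[!clusters$alignments$cluster_id %in%
                               as_clusters, , drop = FALSE]
  unique(alignment_introns(aln)[, c("chrom", "strand", "start", "end")])
}

#' Length and GC contrasts of alternative vs constitutive features
#'
#' Builds the feature sets from a clustering and its detected events:
#' retained introns (IR event spans) and skipped exons (ES event spans)
#' are contrasted against the introns and internal exons of clusters
#' without any detected event. Exons and introns of alternatively spliced
#' clusters that are outside event spans contribute to neither side, to
#' avoid contaminating the constitutive baseline. Short in-frame retained
#' introns (length a multiple of 3 below the threshold) are additionally
#' contrasted on GC.
#'
#' @param clusters A `tx_clusters` object.
#' @param events An `as_events` data frame.
#' @param genome A named `DNAStringSet`.
#' @param short_intron_max Length threshold (nt) for the short in-frame
#'   intron subgroup.
#' @param test `"ttest"` or `"ranksum"`.
#' @return Data frame with one row per contrast (see [feature_contrast()])
#'   and attribute `sets` holding the underlying feature tables.
#' @export
feature_report <- function(clusters, events, genome, short_intron_max = 150L,
                           test = c("ttest", "ranksum")) {
  test <- match.arg(test)
  const_intr <- constitutive_introns(clusters, events)
  as_clusters <- unique(events$cluster_id)
  const_ex <- internal_exons(
    clusters$alignments[!clusters$alignments$cluster_id %in% as_clusters, ,
                        drop = FALSE])
  retained <- events[events$type == "IR", c("chrom", "strand", "start",
                                            "end"), drop = FALSE]
  skipped <- events[events$type == "ES", c("chrom", "strand", "start",
                                           "end"), drop = FALSE]
  seq_of <- function(d) {
    vapply(seq_len(nrow(d)), function(i) {
      genome_seq(genome, d$chrom[i], d$start[i], d$end[i], d$strand[i])
    }, character(1))
  }
  len_of <- function(d) d$end - d$start + 1
  rows <- list()
  if (nrow(retained) >= 2L && nrow(const_intr) >= 2L) {
    rows$ril <- feature_contrast(len_of(retained), len_of(const_intr),
                                 "intron_length_retained_vs_constitutive",
                                 test)
    rows$rig <- feature_contrast(gc_fraction(seq_of(retained)),
                                 gc_fraction(seq_of(const_intr)),
                                 "intron_gc_retained_vs_constitutive", test)
    short <- retained[len_of(retained) %% 3 == 0 &
                        len_of(retained) < short_intron_max, , drop = FALSE]
    if (nrow(short) >= 2L) {
      rows$sig <- feature_contrast(
        gc_fraction(seq_of(short)), gc_fraction(seq_of(const_intr)),
        "intron_gc_short_inframe_retained_vs_constitutive", test)
    }
  }
  if (nrow(skipped) >= 2L && nrow(const_ex) >= 2L) {
    rows$sel <- feature_contrast(len_of(skipped), len_of(const_ex),
                                 "exon_length_skipped_vs_constitutive", test)
    rows$seg <- feature_contrast(gc_fraction(seq_of(skipped)),
                                 gc_fraction(seq_of(const_ex)),
                                 "exon_gc_skipped_vs_constitutive", test)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  attr(out, "sets") <- list(retained = retained, skipped = skipped,
                            constitutive_introns = const_intr,
                            constitutive_exons = const_ex)
  out
}
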