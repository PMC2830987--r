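# Splice-site strength: log-odds position weight matrices trained on
# constitutive introns, and group comparisons of site scores.
#
# Windows follow the common convention of 3 exonic + 6 intronic nt around
# the donor and 14 intronic + 3 exonic nt around the acceptor, covering
# the invariant GT / AG dinucleotides; both are configurable. Scores are
# in bits (log2). The background base distribution is estimated from the
# training windows themselves rather than assumed uniform, because the
# genomes this targets are strongly GC-rich.

DONOR_EXONIC <- 3L
DONOR_INTRONIC <- 6L
ACCEPTOR_INTRONIC <- 14L
ACCEPTOR_EXONIC <- 3L

#' Extract splice-site window sequences
#'
#' Reads donor or acceptor windows for a set of introns from the genome,
#' in transcript orientation (reverse-complemented on the minus strand).
#' Sites whose window runs off the contig are skipped with a warning.
#'
#' @param introns Data frame with columns `chrom`, `strand`, `start`,
#'   `end` (1-based closed genomic intron intervals).
#' @param genome A named `DNAStringSet`.
#' @param site `"donor"` or `"acceptor"`.
#' @param exonic,intronic Number of exonic / intronic nt in the window.
#' @return Character vector of window sequences (invariant dinucleotide
#'   included); skipped sites are dropped, and the number skipped is
#'   attached as attribute `n_skipped`.
#' @export
splice_site_seqs <- function(introns, genome, site = c("donor", "acceptor"),
                             exonic = NULL, intronic = NULL) {
  site <- match.arg(site)
  exonic <- exonic %||% if (site == "donor") DONOR_EXONIC else ACCEPTOR_EXONIC
  intronic <- intronic %||%
    if (site == "donor") DONOR_INTRONIC else ACCEPTOR_INTRONIC
  out <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(introns))) {
    st <- introns$strand[i]
    at_start <- (site == "donor") == (st == "+")
    if (at_start) {
      lo <- introns$start[i] - (if (st == "+") exonic else intronic)
      hi <- introns$start[i] + (if (st == "+") intronic else exonic) - 1L
    } else {
      lo <- introns$end[i] - (if (st == "+") intronic else exonic) + 1L
      hi <- introns$end[i] + (if (st == "+") exonic else intronic)
    }
    seq <- tryCatch(genome_seq(genome, introns$chrom[i], lo, hi, st),
                    estsplice_coord_error = function(e) NULL)
    if (is.null(seq)) skipped <- skipped + 1L else out <- c(out, seq)
  }
  if (skipped > 0L) {
    warning(sprintf("%d site window(s) ran off a contig and were skipped",
                    skipped))
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Train a splice-site position weight matrix
#'
#' Builds a per-position log-odds matrix in bits:
#' `log2(((count + pseudocount) / (N + 4 * pseudocount)) / background)`,
#' with the background base frequencies estimated from all bases of all
#' training windows unless supplied.
#'
#' @param x Either a character vector of equal-length site window
#'   sequences, or an intron data frame as for [splice_site_seqs()] (in
#'   which case `genome` must be given and windows are extracted first).
#' @param genome A named `DNAStringSet` (only when `x` is an intron table).
#' @param site `"donor"` or `"acceptor"`.
#' @param exonic,intronic Window composition, as in [splice_site_seqs()].
#' @param pseudocount Added to every base count (default 0.5).
#' @param background Optional length-4 named base frequency vector.
#' @return An object of class `splice_pwm`: list with `site`, `mat` (4 x
#'   width log-odds matrix in bits), `background`, `pseudocount`, `n`
#'   (training sites), `exonic`, `intronic`.
#' @export
train_pwm <- function(x, genome = NULL, site = c("donor", "acceptor"),
                      exonic = NULL, intronic = NULL, pseudocount = 0.5,
                      background = NULL) {
  site <- match.arg(site)
  seqs <- if (is.character(x)) x else {
    stopifnot(!is.null(genome))
    splice_site_seqs(x, genome, site, exonic, intronic)
  }
  if (length(seqs) < 2L) {
    stop_estsplice("PWM training requires at least 2 sites",
                   "estsplice_pwm_error")
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    stop_estsplice("training windows must have equal length",
                   "estsplice_pwm_error")
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(p) {
    tabulate(factor(m[, p], levels = BASES), nbins = 4L)
  }, integer(4))
  rownames(counts) <- BASES
  if (is.null(background)) {
    tot <- rowSums(counts)
    background <- tot / sum(tot)
  } else {
    background <- background[BASES] / sum(background[BASES])
  }
  n <- length(seqs)
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  mat <- log2(freq / as.vector(background))
  exonic <- exonic %||% if (site == "donor") DONOR_EXONIC else ACCEPTOR_EXONIC
  intronic <- intronic %||%
    if (site == "donor") DONOR_INTRONIC else ACCEPTOR_INTRONIC
  out <- list(site = site, mat = mat, background = background,
              pseudocount = pseudocount, n = n, exonic = exonic,
              intronic = intronic)
  class(out) <- "splice_pwm"
  out
}

#' Score site windows against a PWM
#'
#' The motif score of a window is the sum of its per-position log-odds,
#' in bits. Non-ACGT bases contribute 0 (background-neutral).
#'
#' @param pwm A `splice_pwm`.
#' @param seqs Character vector of windows matching the PWM width.
#' @return Numeric vector of scores.
#' @export
score_site <- function(pwm, seqs) {
  w <- ncol(pwm$mat)
  if (any(nchar(seqs) != w)) {
    stop_estsplice("window length does not match PWM width",
                   "estsplice_pwm_error")
  }
  vapply(strsplit(seqs, "", fixed = TRUE), function(b) {
    ix <- match(b, BASES)
    sum(pwm$mat[cbind(ix[!is.na(ix)], which(!is.na(ix)))])
  }, numeric(1))
}

#' Compare splice-site strength between two groups
#'
#' Reports group means and a two-sided p-value, by default from the
#' Wilcoxon rank-sum test (Welch t-test optional). Two degenerate
#' identical groups give p = 1.
#'
#' @param scores_a,scores_b Numeric score vectors (each n >= 2).
#' @param test `"ranksum"` (default) or `"ttest"`.
#' @param group_a,group_b Labels carried into the result.
#' @return A list of class `strength_comparison`: `group_a`, `group_b`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `p_value`, `test_name`.
#' @export
compare_strength <- function(scores_a, scores_b, test = c("ranksum", "ttest"),
                             group_a = "a", group_b = "b") {
  test <- match.arg(test)
  stopifnot(length(scores_a) >= 2L, length(scores_b) >= 2L)
  if (sd(c(scores_a, scores_b)) == 0) {
    p <- 1
  } else if (test == "ranksum") {
    p <- wilcox.test(scores_a, scores_b, exact = FALSE)$p.value
  } else {
    p <- t.test(scores_a, scores_b)$p.value
  }
  out <- list(group_a = group_a, group_b = group_b,
              mean_a = mean(scores_a), mean_b = mean(scores_b),
              n_a = length(scores_a), n_b = length(scores_b),
              p_value = p,
              test_name = if (test == "ranksum") "Wilcoxon rank-sum"
                          else "Welch t-test")
  class(out) <- "strength_comparison"
  out
}

# Distinct introns participating in an event's splice forms.
event_introns <- function(events) {
  out <- lapply(seq_len(nrow(events)), function(i) {
    f <- events$forms[[i]]
    f <- f[!is.na(f$start), , drop = FALSE]
    if (!nrow(f)) return(NULL)
    data.frame(type = events$type[i], chrom = events$chrom[i],
               strand = events$strand[i], start = f$start, end = f$end,
               form_idx = seq_len(nrow(events$forms[[i]]))[!is.na(
                 events$forms[[i]]$start)],
               event_idx = i, prevalent = events$prevalent[i],
               tie = events$tie[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(type = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), form_idx = integer(0),
                      event_idx = integer(0), prevalent = integer(0),
                      tie = logical(0), stringsAsFactors = FALSE)
  }
  out
}

#' Splice-site strength report by event type and prevalence
#'
#' Trains donor and acceptor PWMs on constitutive introns, then reports,
#' per event type, the mean motif score of the introns participating in
#' that type's events at both sites, each compared with the constitutive
#' scores. For Alt5 (donor) and Alt3 (acceptor) events with an untied
#' prevalence call, the varying site is additionally contrasted between
#' non-prevalent and prevalent forms and between prevalent and
#' constitutive sites.
#'
#' @param events An `as_events` data frame with prevalence calls.
#' @param constitutive Data frame of constitutive introns (`chrom`,
#'   `strand`, `start`, `end`), the PWM training set.
#' @param genome A named `DNAStringSet`.
#' @param test `"ranksum"` or `"ttest"`.
#' @param pseudocount PWM pseudocount.
#' @return A list of class `strength_table` with `by_type` (per type and
#'   site: n, mean score, constitutive mean, p-value), `prevalence` (the
#'   Alt5/Alt3 three-way contrast), `pwms`, and attribute `omitted`
#'   naming event types with no qualifying sites.
#' @export
strength_table <- function(events, constitutive, genome,
                           test = c("ranksum", "ttest"), pseudocount = 0.5) {
  test <- match.arg(test)
  pwm_d <- train_pwm(constitutive, genome, "donor", pseudocount = pseudocount)
  pwm_a <- train_pwm(constitutive, genome, "acceptor",
                     pseudocount = pseudocount)
  const_d <- score_site(pwm_d, splice_site_seqs(constitutive, genome, "donor"))
  const_a <- score_site(pwm_a,
                        splice_site_seqs(constitutive, genome, "acceptor"))
  ei <- event_introns(events)
  rows <- list(); omitted <- character(0)
  for (ty in AS_TYPES) {
    sub <- unique(ei[ei$type == ty, c("chrom", "strand", "start", "end")])
    if (!nrow(sub)) { omitted <- c(omitted, ty); next }
    for (site in c("donor", "acceptor")) {
      pwm <- if (site == "donor") pwm_d else pwm_a
      const <- if (site == "donor") const_d else const_a
      sc <- score_site(pwm, splice_site_seqs(sub, genome, site))
      if (length(sc) < 2L) next
      cmp <- compare_strength(sc, const, test, ty, "constitutive")
      rows[[length(rows) + 1L]] <- data.frame(
        type = ty, site = site, n = length(sc), mean_score = cmp$mean_a,
        constitutive_mean = cmp$mean_b, p_value = cmp$p_value,
        stringsAsFactors = FALSE)
    }
  }
  by_type <- if (length(rows)) do.call(rbind, rows) else data.frame(
    type = character(0), site = character(0), n = integer(0),
    mean_score = numeric(0), constitutive_mean = numeric(0),
    p_value = numeric(0), stringsAsFactors = FALSE)

  # prevalent vs non-prevalent on the varying site of Alt5/Alt3
  prows <- list()
  for (ty in c("Alt5", "Alt3")) {
    site <- if (ty == "Alt5") "donor" else "acceptor"
    pwm <- if (ty == "Alt5") pwm_d else pwm_a
    const <- if (ty == "Alt5") const_d else const_a
    sub <- ei[ei$type == ty & !is.na(ei$prevalent) & !ei$tie, , drop = FALSE]
    if (!nrow(sub)) next
    prev <- sub[sub$form_idx == sub$prevalent, , drop = FALSE]
    nonprev <- sub[sub$form_idx != sub$prevalent, , drop = FALSE]
    if (nrow(prev) < 2L || nrow(nonprev) < 2L) next
    sc_p <- score_site(pwm, splice_site_seqs(prev, genome, site))
    sc_n <- score_site(pwm, splice_site_seqs(nonprev, genome, site))
    c1 <- compare_strength(sc_n, sc_p, test, "non-prevalent", "prevalent")
    c2 <- compare_strength(sc_p, const, test, "prevalent", "constitutive")
    prows[[length(prows) + 1L]] <- data.frame(
      type = ty, site = site,
      nonprevalent_mean = c1$mean_a, p_nonprev_vs_prev = c1$p_value,
      prevalent_mean = c1$mean_b, p_prev_vs_const = c2$p_value,
      constitutive_mean = c2$mean_b, stringsAsFactors = FALSE)
  }
  prevalence <- if (length(prows)) do.call(rbind, prows) else data.frame(
    type = character(0), site = character(0), nonprevalent_mean = numeric(0),
    p_nonprev_vs_prev = numeric(0), prevalent_mean = numeric(0),
    p_prev_vs_const = numeric(0), constitutive_mean = numeric(0),
    stringsAsFactors = FALSE)
  out <- list(by_type = by_type, prevalence = prevalence,
              pwms = list(donor = pwm_d, acceptor = pwm_a))
  attr(out, "omitted") <- omitted
  class(out) <- "strength_table"
  out
}

#' Write a PWM as a tab-separated matrix
#'
#' Header lines carry the site kind, window composition, pseudocount,
#' training size, and background frequencies; the body is the 4 x width
#' log-odds matrix. [read_pwm()] inverts this.
#'
#' @param pwm A `splice_pwm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pwm <- function(pwm, path) {
  hdr <- c(sprintf("# site\t%s", pwm$site),
           sprintf("# exonic\t%d", pwm$exonic),
           sprintf("# intronic\t%d", pwm$intronic),
           sprintf("# pseudocount\t%g", pwm$pseudocount),
           sprintf("# n\t%d", pwm$n),
           sprintf("# background\t%s",
                   paste(sprintf("%s=%.10g", BASES, pwm$background),
                         collapse = ",")))
  body <- vapply(seq_len(4L), function(r) {
    paste(c(BASES[r], sprintf("%.10g", pwm$mat[r, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, paste(c("base", sprintf("p%d", seq_len(ncol(pwm$mat)))),
                          collapse = "\t"), body), path)
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#' @param path Path to a PWM file.
#' @return A `splice_pwm`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(k) {
    x <- hdr[startsWith(hdr, paste0("# ", k, "\t"))]
    sub(paste0("^# ", k, "\t"), "", x)
  }
  bg <- strsplit(get("background"), ",", fixed = TRUE)[[1]]
  background <- setNames(as.numeric(sub("^.=", "", bg)),
                         substr(bg, 1L, 1L))
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1L]  # column header
  mat <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]][-1])
  }))
  rownames(mat) <- vapply(body, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  out <- list(site = get("site"), mat = mat[BASES, , drop = FALSE],
              background = background[BASES],
              pseudocount = as.numeric(get("pseudocount")),
              n = as.integer(get("n")),
              exonic = as.integer(get("exonic")),
              intronic = as.integer(get("intronic")))
  class(out) <- "splice_pwm"
  out
}

#' Simulate constitutive, prevalent, and degraded non-prevalent sites
#'
#' Draws splice-site windows from a fixed donor (or acceptor) motif.
#' Constitutive sites come from the motif itself; prevalent and
#' non-prevalent sites are degraded by replacing each non-invariant
#' position, with the given probability, by a draw from the GC-rich
#' background. This plants the ordering non-prevalent < prevalent <
#' constitutive in expected motif score, with default degradations sized
#' to yield score gaps of roughly one to two bits between adjacent
#' groups.
#'
#' @param n Sites per group.
#' @param site `"donor"` or `"acceptor"`.
#' @param degrade_prevalent,degrade_nonprevalent Per-position replacement
#'   probabilities.
#' @param gc Background GC fraction.
#' @param seed Integer seed.
#' @return List with character vectors `constitutive`, `prevalent`,
#'   `nonprevalent`.
#' @export
simulate_site_set <- function(n = 200L, site = c("donor", "acceptor"),
                              degrade_prevalent = 0.3,
                              degrade_nonprevalent = 0.6,
                              gc = 0.64, seed = 1L) {
  site <- match.arg(site)
  set.seed(seed)
  motif <- if (site == "donor") {
    # CAG | GTAAGT, with the GT invariant
    rbind(A = c(0.30, 0.60, 0.10, 0, 0, 0.55, 0.60, 0.10, 0.15),
          C = c(0.40, 0.15, 0.05, 0, 0, 0.05, 0.10, 0.10, 0.15),
          G = c(0.20, 0.15, 0.80, 1, 0, 0.30, 0.15, 0.70, 0.20),
          T = c(0.10, 0.10, 0.05, 0, 1, 0.10, 0.15, 0.10, 0.50))
  } else {
    # C-rich tail .. CAG | exon
    w <- 17L
    m <- matrix(c(0.15, 0.45, 0.20, 0.20), nrow = 4, ncol = w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[, 13:14] <- cbind(c(1, 0, 0, 0), c(0, 0, 1, 0))  # invariant AG
    m[, 12] <- c(0.10, 0.60, 0.20, 0.10)
    m[, 15:17] <- c(0.25, 0.30, 0.30, 0.15)
    m
  }
  invariant <- which(apply(motif, 2, max) == 1)
  bg <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(n, degrade) {
    vapply(seq_len(n), function(i) {
      b <- vapply(seq_len(ncol(motif)), function(p) {
        use_bg <- degrade > 0 && !(p %in% invariant) && runif(1) < degrade
        sample(BASES, 1L, prob = if (use_bg) bg else motif[, p])
      }, character(1))
      paste(b, collapse = "")
    }, character(1))
  }
  list(constitutive = draw(n, 0),
       prevalent = draw(n, degrade_prevalent),
       nonprevalent = draw(n, degrade_nonprevalent))
}
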