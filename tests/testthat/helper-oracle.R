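# Independent brute-force oracles for the classifier, the clustering, and
# the ORF scan. These re-derive results by direct enumeration over intron
# pairs and exon containment, sharing no code with the package internals.

# Event classification by exhaustive pair testing. Returns a data frame
# in the same shape as detect_events() output (cluster_id omitted).
oracle_detect <- function(aln, overhang = 10L, min_support = 1L) {
  strand <- aln$strand[1]
  # per-EST introns and blocks
  est_introns <- lapply(seq_len(nrow(aln)), function(i) {
    b <- aln$blocks[[i]]
    if (nrow(b) < 2L) return(matrix(integer(0), ncol = 2))
    cbind(b[-nrow(b), 2] + 1L, b[-1, 1] - 1L)
  })
  intr <- do.call(rbind, lapply(seq_len(nrow(aln)), function(i) {
    g <- est_introns[[i]]
    if (!nrow(g)) return(NULL)
    data.frame(est = aln$est_id[i], s = g[, 1], e = g[, 2])
  }))
  events <- list()
  push <- function(type, start, end, ests_by_form) {
    ests_by_form <- lapply(ests_by_form, function(x) sort(unique(x)))
    ests_by_form <- ests_by_form[vapply(ests_by_form, length, integer(1)) >=
                                   min_support]
    if (length(ests_by_form) < 2L) return()
    events[[length(events) + 1L]] <<- list(type = type, start = start,
                                           end = end, forms = ests_by_form)
  }
  if (is.null(intr) || !nrow(intr)) intr <- data.frame(est = character(0),
                                                       s = integer(0),
                                                       e = integer(0))
  u <- unique(intr[c("s", "e")])
  supp <- function(s, e) unique(intr$est[intr$s == s & intr$e == e])

  # --- exon skipping: chains of an EST bridged by a single long intron
  excl <- character(0)
  es_found <- list()
  for (i in seq_len(nrow(aln))) {
    g <- est_introns[[i]]
    if (nrow(g) < 2L) next
    for (k in seq_len(nrow(g) - 1L)) for (m in seq(k + 1L, nrow(g))) {
      if (any(u$s == g[k, 1] & u$e == g[m, 2])) {
        rk <- paste(g[k, 1], g[m, 2], g[k, 2] + 1L, g[m, 1] - 1L)
        es_found[[rk]] <- list(
          L = c(g[k, 1], g[m, 2]), run = c(g[k, 2] + 1L, g[m, 1] - 1L),
          incl = c(es_found[[rk]]$incl, aln$est_id[i]))
        # pairs explained by this skip: (L, first) and (L, last)
        for (p in list(c(g[k, 1], g[k, 2]), c(g[m, 1], g[m, 2]))) {
          excl <- c(excl, paste(g[k, 1], g[m, 2], p[1], p[2]),
                    paste(p[1], p[2], g[k, 1], g[m, 2]))
        }
      }
    }
  }
  for (e in es_found) {
    push("ES", e$run[1], e$run[2],
         list(supp(e$L[1], e$L[2]), e$incl))
  }
  pair_excluded <- function(a, b) {
    paste(u$s[a], u$e[a], u$s[b], u$e[b]) %in% excl
  }

  # --- intron retention: a block covering intron +/- overhang
  for (i in seq_len(nrow(u))) {
    spliced <- supp(u$s[i], u$e[i])
    retained <- character(0)
    for (j in seq_len(nrow(aln))) {
      b <- aln$blocks[[j]]
      for (r in seq_len(nrow(b))) {
        if (b[r, 1] <= u$s[i] - overhang && b[r, 2] >= u$e[i] + overhang) {
          retained <- c(retained, aln$est_id[j])
        }
      }
    }
    retained <- setdiff(retained, spliced)
    if (length(retained)) {
      push("IR", u$s[i], u$e[i], list(spliced, retained))
    }
  }

  # --- grouped events over unexcluded pairs, via adjacency closure
  components <- function(idx, joined) {
    comps <- list()
    left <- idx
    while (length(left)) {
      cc <- left[1]; left <- left[-1]
      repeat {
        add <- left[vapply(left, function(j) any(vapply(cc, function(i)
          joined(i, j), logical(1))), logical(1))]
        if (!length(add)) break
        cc <- c(cc, add); left <- setdiff(left, add)
      }
      comps[[length(comps) + 1L]] <- cc
    }
    comps
  }
  donor <- if (strand == "-") u$e else u$s
  acceptor <- if (strand == "-") u$s else u$e
  for (ty in c("Alt5", "Alt3")) {
    shared <- if (ty == "Alt5") acceptor else donor
    for (v in unique(shared)) {
      idx <- which(shared == v)
      if (length(idx) < 2L) next
      for (cc in components(idx, function(i, j) !pair_excluded(i, j))) {
        if (length(cc) < 2L) next
        push(ty, min(u$s[cc]), max(u$e[cc]),
             lapply(cc, function(i) supp(u$s[i], u$e[i])))
      }
    }
  }
  # AltB: overlapping introns differing at both ends, minus skip-like pairs
  exon_between <- function(lo, hi) {
    for (j in seq_len(nrow(aln))) {
      b <- aln$blocks[[j]]
      for (r in seq_len(nrow(b))) {
        if (b[r, 1] > lo && b[r, 2] < hi) return(TRUE)
      }
    }
    FALSE
  }
  altb_pair <- function(i, j) {
    if (u$s[i] == u$s[j] || u$e[i] == u$e[j]) return(FALSE)
    if (max(u$s[i], u$s[j]) > min(u$e[i], u$e[j])) return(FALSE)
    if (pair_excluded(i, j)) return(FALSE)
    !(exon_between(min(u$s[i], u$s[j]), max(u$s[i], u$s[j])) &&
        exon_between(min(u$e[i], u$e[j]), max(u$e[i], u$e[j])))
  }
  if (nrow(u) >= 2L) {
    for (cc in components(seq_len(nrow(u)), altb_pair)) {
      if (length(cc) < 2L) next
      push("AltB", min(u$s[cc]), max(u$e[cc]),
           lapply(cc, function(i) supp(u$s[i], u$e[i])))
    }
  }
  events
}

oracle_event_key <- function(events) {
  sort(vapply(events, function(e) {
    forms <- sort(vapply(e$forms, paste, character(1), collapse = ","))
    paste(e$type, e$start, e$end, paste(forms, collapse = "/"))
  }, character(1)))
}

# O(n^2) union-find clustering over strict interval overlap.
oracle_cluster <- function(chrom, strand, start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (chrom[i] == chrom[j] && strand[i] == strand[j] &&
        start[i] <= end[j] && start[j] <= end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Naive codon-by-codon ORF scan.
oracle_orf <- function(seq, start) {
  p <- start + 3L
  while (p + 2L <= nchar(seq)) {
    if (substr(seq, p, p + 2L) %in% c("TAA", "TAG", "TGA")) {
      return(list(stop_pos = p + 2L, orf_len = p + 2L - start + 1L,
                  no_stop = FALSE))
    }
    p <- p + 3L
  }
  list(stop_pos = NA_integer_, orf_len = NA_integer_, no_stop = TRUE)
}

# Random small cluster: 2-3 ESTs of up to 4 blocks over a shared boundary
# pool, so shared donors/acceptors and containment patterns arise often.
random_cluster <- function(seed) {
  set.seed(seed)
  n_est <- sample(2:3, 1)
  strand <- sample(c("+", "-"), 1)
  pool <- sort(sample(seq(20L, 600L, by = 20L), 12L))
  blocks <- lapply(seq_len(n_est), function(i) {
    k <- sample(1:4, 1)
    cuts <- sort(sample(pool, 2L * k))
    m <- cbind(start = cuts[c(TRUE, FALSE)], end = cuts[c(FALSE, TRUE)] - 5L)
    storage.mode(m) <- "integer"
    m
  })
  make_aln(blocks, strand = strand)
}
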