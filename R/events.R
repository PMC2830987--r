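# Detection and classification of alternative splicing events.
#
# Five event types are recognized from the intron/exon structure of a
# transcriptional unit's EST alignments, in transcript orientation:
#   IR    an intron spliced by some ESTs and covered read-through, with
#         overhang on both sides, by a single block of another EST
#   ES    an internal exon present in some ESTs while another intron
#         spans it together with both flanking introns
#   Alt5  introns sharing their acceptor but differing at the donor
#   Alt3  introns sharing their donor but differing at the acceptor
#   AltB  overlapping introns differing at both boundaries, not explained
#         by exon skipping
# Intron pairs that constitute a detected ES event are excluded from the
# Alt5/Alt3/AltB groupings, so each event is reported under exactly one
# type (precedence: ES first).

#' Detect alternative splicing events
#'
#' @param x A `tx_clusters` object from [cluster_alignments()], or a
#'   `spliced_alignments` data frame holding one cluster.
#' @param overhang Read-through evidence for intron retention must extend
#'   at least this many nt beyond both intron boundaries (guards against
#'   truncated alignments mimicking retention).
#' @param min_support Minimum number of distinct ESTs per splice form.
#' @return A data frame of class `as_events`: `cluster_id`, `chrom`,
#'   `strand`, `type`, `start`, `end`, a `forms` list-column (per-form
#'   data frames with `form`, `start`, `end`, `n_ests`, `ests`), and
#'   `prevalent`/`tie` columns filled by [call_prevalent()].
#' @export
detect_events <- function(x, overhang = 10L, min_support = 1L) {
  if (inherits(x, "tx_clusters")) {
    parts <- lapply(x$clusters$cluster_id, function(cid) {
      detect_events_one(
        x$alignments[x$alignments$cluster_id == cid, , drop = FALSE],
        cid, overhang, min_support)
    })
    ev <- do.call(rbind, parts)
  } else {
    ev <- detect_events_one(x, x$cluster_id[1] %||% "cluster0001",
                            overhang, min_support)
  }
  if (is.null(ev)) ev <- empty_events()
  class(ev) <- c("as_events", "data.frame")
  ev
}

empty_events <- function() {
  ev <- data.frame(cluster_id = character(0), chrom = character(0),
                   strand = character(0), type = character(0),
                   start = integer(0), end = integer(0),
                   stringsAsFactors = FALSE)
  ev$forms <- list()
  ev$prevalent <- integer(0)
  ev$tie <- logical(0)
  class(ev) <- c("as_events", "data.frame")
  ev
}

# Classify one cluster. `aln` rows must share chrom and strand.
detect_events_one <- function(aln, cluster_id, overhang = 10L,
                              min_support = 1L) {
  if (nrow(aln) < 2L) return(NULL)
  chrom <- aln$chrom[1]
  strand <- aln$strand[1]
  intr <- alignment_introns(aln)
  ev <- list()
  add_event <- function(type, start, end, forms) {
    forms <- forms[vapply(forms$ests, length, integer(1)) >= min_support, ,
                   drop = FALSE]
    if (nrow(forms) < 2L) return(invisible(NULL))
    ev[[length(ev) + 1L]] <<- list(type = type, start = start, end = end,
                                   forms = forms)
    invisible(NULL)
  }
  make_forms <- function(labels, starts, ends, ests) {
    data.frame(form = labels, start = starts, end = ends,
               n_ests = vapply(ests, length, integer(1)),
               ests = I(ests), stringsAsFactors = FALSE)
  }

  # unique introns with EST support
  if (nrow(intr)) {
    key <- paste(intr$start, intr$end)
    uk <- !duplicated(key)
    u <- data.frame(start = intr$start[uk], end = intr$end[uk])
    u <- u[order(u$start, u$end), , drop = FALSE]
    support <- lapply(seq_len(nrow(u)), function(i) {
      sort(unique(intr$est_id[intr$start == u$start[i] &
                                intr$end == u$end[i]]))
    })
  } else {
    u <- data.frame(start = integer(0), end = integer(0))
    support <- list()
  }
  nu <- nrow(u)
  ukey <- paste(u$start, u$end)

  # --- exon skipping, and the intron pairs it explains ------------------
  excluded <- character(0)  # "i|j" with i < j, indices into u
  pair_key <- function(i, j) paste(min(i, j), max(i, j), sep = "|")
  es_events <- list()
  for (a in seq_len(nrow(aln))) {
    g <- blocks_to_introns(aln$blocks[[a]])
    p <- nrow(g)
    if (p < 2L) next
    my_idx <- match(paste(g[, 1], g[, 2]), ukey)
    for (k in seq_len(p - 1L)) {
      for (m in seq(k + 1L, p)) {
        li <- match(paste(g[k, 1], g[m, 2]), ukey)
        if (is.na(li)) next
        run <- c(g[k, 2] + 1L, g[m, 1] - 1L)
        ekey <- paste(li, run[1], run[2])
        es_events[[ekey]] <- list(
          skip = li, run = run,
          inclusion = c(es_events[[ekey]]$inclusion, aln$est_id[a]))
        excluded <- union(excluded, c(pair_key(li, my_idx[k]),
                                      pair_key(li, my_idx[m])))
      }
    }
  }
  for (e in es_events) {
    add_event("ES", e$run[1], e$run[2],
              make_forms(c("skip", "inclusion"),
                         c(u$start[e$skip], NA_integer_),
                         c(u$end[e$skip], NA_integer_),
                         list(support[[e$skip]],
                              sort(unique(e$inclusion)))))
  }

  # --- intron retention -------------------------------------------------
  if (nu) {
    all_blocks <- do.call(rbind, lapply(seq_len(nrow(aln)), function(i) {
      b <- aln$blocks[[i]]
      cbind(i = i, start = b[, 1], end = b[, 2])
    }))
    for (i in seq_len(nu)) {
      spanning <- all_blocks[, "start"] <= u$start[i] - overhang &
        all_blocks[, "end"] >= u$end[i] + overhang
      retained <- sort(unique(aln$est_id[all_blocks[spanning, "i"]]))
      retained <- setdiff(retained, support[[i]])
      if (length(retained)) {
        add_event("IR", u$start[i], u$end[i],
                  make_forms(c("spliced", "retained"),
                             c(u$start[i], NA_integer_),
                             c(u$end[i], NA_integer_),
                             list(support[[i]], retained)))
      }
    }
  }

  # --- alternative donor/acceptor groups --------------------------------
  donor <- if (strand == "-") u$end else u$start
  acceptor <- if (strand == "-") u$start else u$end
  group_events <- function(shared, type) {
    for (val in unique(shared)) {
      members <- which(shared == val)
      if (length(members) < 2L) next
      comps <- pair_components(members, function(i, j) {
        !(pair_key(i, j) %in% excluded)
      })
      for (cc in comps) {
        if (length(cc) < 2L) next
        add_event(type, min(u$start[cc]), max(u$end[cc]),
                  make_forms(sprintf("intron:%d-%d", u$start[cc], u$end[cc]),
                             u$start[cc], u$end[cc], support[cc]))
      }
    }
  }
  group_events(acceptor, "Alt5")  # shared acceptor, donors differ
  group_events(donor, "Alt3")     # shared donor, acceptors differ

  # --- AltB: overlap, both boundaries differ, not exon skipping ---------
  if (nu >= 2L) {
    has_block_within <- function(lo, hi) {
      if (hi - lo < 2L) return(FALSE)
      any(vapply(aln$blocks, function(b) {
        any(b[, 1] > lo & b[, 2] < hi)
      }, logical(1)))
    }
    altb_edge <- function(i, j) {
      if (u$start[i] == u$start[j] || u$end[i] == u$end[j]) return(FALSE)
      if (u$start[i] > u$end[j] || u$start[j] > u$end[i]) return(FALSE)
      if (pair_key(i, j) %in% excluded) return(FALSE)
      es_like <- has_block_within(min(u$start[i], u$start[j]),
                                  max(u$start[i], u$start[j])) &&
        has_block_within(min(u$end[i], u$end[j]),
                         max(u$end[i], u$end[j]))
      !es_like
    }
    comps <- pair_components(seq_len(nu), altb_edge)
    for (cc in comps) {
      if (length(cc) < 2L) next
      add_event("AltB", min(u$start[cc]), max(u$end[cc]),
                make_forms(sprintf("intron:%d-%d", u$start[cc], u$end[cc]),
                           u$start[cc], u$end[cc], support[cc]))
    }
  }

  if (!length(ev)) return(NULL)
  out <- data.frame(
    cluster_id = cluster_id, chrom = chrom, strand = strand,
    type = vapply(ev, `[[`, character(1), "type"),
    start = vapply(ev, function(e) as.integer(e$start), integer(1)),
    end = vapply(ev, function(e) as.integer(e$end), integer(1)),
    stringsAsFactors = FALSE)
  out$forms <- lapply(ev, `[[`, "forms")
  out$prevalent <- NA_integer_
  out$tie <- NA
  out[order(out$start, out$end, out$type), , drop = FALSE]
}

# Connected components of the graph on `members` whose edges are the
# pairs for which edge_fun(i, j) is TRUE. Isolated vertices are returned
# as singleton components.
pair_components <- function(members, edge_fun) {
  n <- length(members)
  if (n == 1L) return(list(members))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      if (edge_fun(members[a], members[b])) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(members, roots), identity))
}

#' Call the prevalent splice form of each event
#'
#' The prevalent form is the one supported by the strictly largest number
#' of distinct ESTs. Exact ties set the `tie` flag and leave `prevalent`
#' as NA; tied events are excluded from prevalent/non-prevalent
#' comparisons.
#'
#' @param events An `as_events` data frame.
#' @return The events with `prevalent` and `tie` columns filled.
#' @export
call_prevalent <- function(events) {
  for (i in seq_len(nrow(events))) {
    n <- events$forms[[i]]$n_ests
    top <- max(n)
    if (sum(n == top) == 1L) {
      events$prevalent[i] <- which.max(n)
      events$tie[i] <- FALSE
    } else {
      events$prevalent[i] <- NA_integer_
      events$tie[i] <- TRUE
    }
  }
  events
}

#' Tally events by type
#'
#' @param x An `as_events` data frame, or a named vector of per-type
#'   counts.
#' @return Data frame with columns `type`, `n`, `pct` (percentage of the
#'   total, rounded to 1 decimal), one row per event type in canonical
#'   order, with the total count as attribute `total`.
#' @export
tally_events <- function(x) {
  if (is.numeric(x)) {
    counts <- setNames(rep(0L, length(AS_TYPES)), AS_TYPES)
    counts[names(x)] <- x
  } else {
    counts <- vapply(AS_TYPES, function(t) sum(x$type == t), numeric(1))
  }
  total <- sum(counts)
  pct <- if (total > 0) round(counts / total * 100, 1) else counts * 0
  out <- data.frame(type = AS_TYPES, n = as.vector(counts),
                    pct = as.vector(pct), stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Compare detected events with a planted truth set
#'
#' Events match when type, chromosome, strand, and genomic span agree
#' exactly.
#'
#' @param events An `as_events` data frame.
#' @param truth_events The `events` element of an `as_truth` object.
#' @return Data frame with one row per event type plus an `overall` row:
#'   `n_truth`, `n_detected`, `n_matched`, `recall`, `precision`.
#' @export
compare_to_truth <- function(events, truth_events) {
  key <- function(d) paste(d$type, d$chrom, d$strand, d$start, d$end)
  dk <- key(events); tk <- key(truth_events)
  per_type <- lapply(c(AS_TYPES, "overall"), function(t) {
    di <- if (t == "overall") seq_along(dk) else which(events$type == t)
    ti <- if (t == "overall") seq_along(tk) else which(truth_events$type == t)
    matched_t <- sum(tk[ti] %in% dk[di])
    matched_d <- sum(dk[di] %in% tk[ti])
    data.frame(type = t, n_truth = length(ti), n_detected = length(di),
               n_matched = matched_t,
               recall = if (length(ti)) matched_t / length(ti) else NA_real_,
               precision = if (length(di)) matched_d / length(di)
                           else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per_type)
}

#' Write events as TSV
#'
#' One row per event with per-form support serialized as
#' `form=est1|est2;...`.
#'
#' @param events An `as_events` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events_tsv <- function(events, path) {
  forms_str <- vapply(seq_len(nrow(events)), function(i) {
    f <- events$forms[[i]]
    paste(sprintf("%s=%s", f$form,
                  vapply(f$ests, paste, character(1), collapse = "|")),
          collapse = ";")
  }, character(1))
  prev_str <- vapply(seq_len(nrow(events)), function(i) {
    if (isTRUE(events$tie[i])) "tie"
    else if (is.na(events$prevalent[i])) "."
    else events$forms[[i]]$form[events$prevalent[i]]
  }, character(1))
  out <- data.frame(cluster_id = events$cluster_id, chrom = events$chrom,
                    strand = events$strand, type = events$type,
                    start = events$start, end = events$end,
                    prevalent = prev_str, forms = forms_str,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write event spans as BED6
#'
#' Converts the internal 1-based closed spans to BED's 0-based half-open
#' convention.
#'
#' @param events An `as_events` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events_bed <- function(events, path) {
  out <- data.frame(chrom = events$chrom, start = events$start - 1L,
                    end = events$end,
                    name = sprintf("%s_%s", events$type, events$cluster_id),
                    score = rep(0L, nrow(events)), strand = events$strand,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
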