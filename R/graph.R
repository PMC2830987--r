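# Splice graphs: exonic segments connected by adjacency and splice edges.

#' Build the splice graph of a transcriptional unit
#'
#' Node boundaries are the sorted set of all block boundaries in the
#' cluster; each maximal sub-segment covered by at least one EST block
#' becomes a node. Consecutive segments traversed contiguously within one
#' EST block are linked by `adjacency` edges; each distinct intron adds a
#' `splice` edge between the segments flanking it. Every EST's path
#' through the graph is recorded.
#'
#' @param aln A `spliced_alignments` data frame holding one cluster's
#'   alignments (same chromosome and strand).
#' @return A list of class `splice_graph` with `nodes` (data frame `node`,
#'   `start`, `end`), `edges` (data frame `from`, `to`, `type`), and
#'   `est_paths` (named list of node index vectors).
#' @export
build_splice_graph <- function(aln) {
  stopifnot(nrow(aln) >= 1L)
  blocks <- aln$blocks
  bstart <- unlist(lapply(blocks, function(b) b[, 1]))
  bend <- unlist(lapply(blocks, function(b) b[, 2]))
  # candidate segment cut points: all starts and all end+1
  cuts <- sort(unique(c(bstart, bend + 1L)))
  seg <- cbind(start = cuts[-length(cuts)], end = cuts[-1] - 1L)
  covered <- vapply(seq_len(nrow(seg)), function(i) {
    any(bstart <= seg[i, 1] & bend >= seg[i, 2])
  }, logical(1))
  seg <- seg[covered, , drop = FALSE]
  nodes <- data.frame(node = seq_len(nrow(seg)), start = seg[, 1],
                      end = seg[, 2])

  seg_of <- function(pos_start, pos_end) {
    which(nodes$start >= pos_start & nodes$end <= pos_end)
  }
  edges <- list()
  est_paths <- list()
  for (i in seq_len(nrow(aln))) {
    b <- blocks[[i]]
    path <- integer(0)
    for (j in seq_len(nrow(b))) {
      segs <- seg_of(b[j, 1], b[j, 2])
      segs <- segs[order(nodes$start[segs])]
      if (length(segs) > 1L) {
        edges[[length(edges) + 1L]] <- cbind(from = segs[-length(segs)],
                                             to = segs[-1],
                                             type = "adjacency")
      }
      path <- c(path, segs)
    }
    g <- blocks_to_introns(b)
    for (j in seq_len(nrow(g))) {
      from <- which(nodes$end == g[j, 1] - 1L)
      to <- which(nodes$start == g[j, 2] + 1L)
      edges[[length(edges) + 1L]] <- cbind(from = from, to = to,
                                           type = "splice")
    }
    est_paths[[aln$est_id[i]]] <- path
  }
  ed <- if (length(edges)) {
    e <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    e$from <- as.integer(e$from); e$to <- as.integer(e$to)
    unique(e)
  } else {
    data.frame(from = integer(0), to = integer(0), type = character(0),
               stringsAsFactors = FALSE)
  }
  out <- list(nodes = nodes, edges = ed[order(ed$from, ed$to), ,
                                        drop = FALSE],
              est_paths = est_paths)
  class(out) <- "splice_graph"
  out
}

#' Intron set encoded by a splice graph
#'
#' The genomic intervals spanned by the graph's splice edges; equals the
#' intron set of the alignments the graph was built from.
#'
#' @param graph A `splice_graph`.
#' @return Data frame with columns `start`, `end`.
#' @export
graph_introns <- function(graph) {
  sp <- graph$edges[graph$edges$type == "splice", , drop = FALSE]
  data.frame(start = graph$nodes$end[sp$from] + 1L,
             end = graph$nodes$start[sp$to] - 1L)
}

#' Export splice graphs as DOT
#'
#' One directed graph per cluster; nodes are labeled with their genomic
#' span, adjacency edges are solid and splice (intron) edges dashed.
#'
#' @param graph A `splice_graph`.
#' @param path Output path.
#' @param name Graph name used in the DOT header.
#' @param chrom Optional chromosome name for node labels.
#' @return Invisibly, `path`.
#' @export
write_graph_dot <- function(graph, path, name = "cluster", chrom = NULL) {
  lab <- function(i) {
    pos <- sprintf("%d-%d", graph$nodes$start[i], graph$nodes$end[i])
    if (is.null(chrom)) pos else sprintf("%s:%s", chrom, pos)
  }
  lines <- c(sprintf("digraph %s {", gsub("[^A-Za-z0-9_]", "_", name)),
             "  rankdir=LR;",
             "  node [shape=box];",
             sprintf('  n%d [label="%s"];', graph$nodes$node,
                     vapply(graph$nodes$node, lab, character(1))))
  if (nrow(graph$edges)) {
    style <- ifelse(graph$edges$type == "splice",
                    ' [style=dashed, label="intron"]', "")
    lines <- c(lines, sprintf("  n%d -> n%d%s;", graph$edges$from,
                              graph$edges$to, style))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
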