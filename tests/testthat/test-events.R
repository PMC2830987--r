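# Shared-boundary toy clusters use two ESTs whose introns differ at one
# or both boundaries; coordinates are chosen so all gaps are >= 40 nt.

test_that("shared donors and acceptors classify by transcript orientation", {
  # introns (201,300) and (201,350): shared genomic start
  aln <- make_aln(list(make_blocks(1, 200, 301, 500),
                       make_blocks(1, 200, 351, 500)))
  ev <- detect_events(aln)
  expect_equal(ev$type, "Alt3")   # on +, shared start = shared donor
  expect_equal(c(ev$start, ev$end), c(201L, 350L))

  ev <- detect_events(make_aln(list(make_blocks(1, 200, 301, 500),
                                    make_blocks(1, 200, 351, 500)),
                               strand = "-"))
  expect_equal(ev$type, "Alt5")   # same coordinates, minus strand

  # introns (201,300) and (151,300): shared genomic end
  ev <- detect_events(make_aln(list(make_blocks(1, 200, 301, 500),
                                    make_blocks(1, 150, 301, 500))))
  expect_equal(ev$type, "Alt5")
  ev <- detect_events(make_aln(list(make_blocks(1, 200, 301, 500),
                                    make_blocks(1, 150, 301, 500)),
                               strand = "-"))
  expect_equal(ev$type, "Alt3")
})

test_that("exon skipping wins over Alt5/Alt3/AltB for its intron pairs", {
  aln <- make_aln(list(make_blocks(1, 100, 201, 300, 401, 500),
                       make_blocks(1, 100, 401, 500)),
                  ids = c("incl", "skip"))
  ev <- detect_events(aln)
  expect_equal(ev$type, "ES")
  expect_equal(c(ev$start, ev$end), c(201L, 300L))
  f <- ev$forms[[1]]
  expect_setequal(f$ests[[match("skip", f$form)]], "skip")
  expect_setequal(f$ests[[match("inclusion", f$form)]], "incl")
})

test_that("intron retention needs read-through with enough overhang", {
  spliced <- make_blocks(1, 100, 201, 300)
  ev <- detect_events(make_aln(list(spliced, make_blocks(51, 250)),
                               ids = c("s", "r")))
  expect_equal(ev$type, "IR")
  expect_equal(c(ev$start, ev$end), c(101L, 200L))
  # overhang short by one base on the right: no event
  ev <- detect_events(make_aln(list(spliced, make_blocks(51, 209)),
                               ids = c("s", "r")))
  expect_equal(nrow(ev), 0L)
  # custom overhang honoured
  ev <- detect_events(make_aln(list(spliced, make_blocks(51, 209)),
                               ids = c("s", "r")), overhang = 5L)
  expect_equal(ev$type, "IR")
})

test_that("overlapping introns differing at both ends are AltB", {
  aln <- make_aln(list(make_blocks(1, 200, 301, 500),
                       make_blocks(1, 205, 296, 500)))
  ev <- detect_events(aln)
  expect_equal(ev$type, "AltB")
  expect_equal(c(ev$start, ev$end), c(201L, 300L))
})

test_that("prevalence needs a strict majority of distinct ESTs", {
  two_forms <- function(n1, n2) {
    b1 <- make_blocks(1, 200, 301, 500)
    b2 <- make_blocks(1, 200, 351, 500)
    make_aln(c(replicate(n1, b1, simplify = FALSE),
               replicate(n2, b2, simplify = FALSE)),
             ids = sprintf("e%02d", seq_len(n1 + n2)))
  }
  ev <- call_prevalent(detect_events(two_forms(5L, 2L)))
  expect_false(ev$tie)
  expect_equal(ev$forms[[1]]$n_ests[ev$prevalent], 5L)
  ev <- call_prevalent(detect_events(two_forms(3L, 3L)))
  expect_true(ev$tie)
  expect_true(is.na(ev$prevalent))
})

test_that("a three-form group with tied top support is flagged as a tie", {
  b <- list(make_blocks(1, 200, 301, 500),
            make_blocks(1, 200, 351, 500), make_blocks(1, 200, 351, 500),
            make_blocks(1, 200, 421, 500), make_blocks(1, 200, 421, 500))
  ev <- call_prevalent(detect_events(
    make_aln(b, ids = sprintf("e%d", 1:5))))
  expect_equal(ev$type, "Alt3")
  expect_equal(nrow(ev$forms[[1]]), 3L)
  expect_true(ev$tie)
})

test_that("duplicating an EST never removes events nor flips prevalence away", {
  sm <- sim_mixed()
  cl <- cluster_alignments(sm$ests$alignments)
  as_cids <- unique(detect_events(cl)$cluster_id)
  for (cid in head(as_cids, 8L)) {
    sub <- cl$alignments[cl$alignments$cluster_id == cid, , drop = FALSE]
    before <- call_prevalent(detect_events(sub))
    dup <- sub[1, , drop = FALSE]
    dup$est_id <- "dup_est"
    after <- call_prevalent(detect_events(rbind(sub, dup)))
    key <- function(e) paste(e$type, e$start, e$end)
    expect_true(all(key(before) %in% key(after)))
    for (i in seq_len(nrow(before))) {
      j <- match(key(before)[i], key(after))
      fb <- before$forms[[i]]; fa <- after$forms[[j]]
      supported <- which(vapply(fa$ests, function(x) sub$est_id[1] %in% x,
                                logical(1)))
      if (!length(supported)) next
      if (!is.na(before$prevalent[i]) &&
          before$prevalent[i] %in% supported) {
        # the duplicated EST's form can only be reinforced
        expect_equal(after$prevalent[j], before$prevalent[i])
      }
    }
  }
})

test_that("event tally reproduces printed-table arithmetic", {
  t <- tally_events(c(IR = 305, ES = 73, Alt5 = 71, Alt3 = 158, AltB = 4))
  expect_equal(attr(t, "total"), 611)
  expect_equal(t$pct[t$type == "ES"], 11.9)
  expect_equal(t$pct[t$type == "Alt5"], 11.6)
  expect_equal(t$pct[t$type == "AltB"], 0.7)
  # intron retention accounts for half of all events
  expect_equal(t$pct[t$type == "IR"], 49.9, tolerance = 0.005)
  expect_equal(sum(t$n), attr(t, "total"))

  empty <- tally_events(detect_events(make_aln(list(make_blocks(1, 100)))))
  expect_equal(attr(empty, "total"), 0)
  expect_true(all(empty$pct == 0))
})

test_that("each event carries exactly one type and counts are conserved", {
  sm <- sim_mixed()
  ev <- detect_events(cluster_alignments(sm$ests$alignments))
  t <- tally_events(ev)
  expect_equal(sum(t$n), nrow(ev))
  expect_true(all(ev$type %in% c("IR", "ES", "Alt5", "Alt3", "AltB")))
  # no duplicated (cluster, type, span)
  expect_false(any(duplicated(ev[, c("cluster_id", "type", "start", "end")])))
})

test_that("random small clusters match the brute-force classifier", {
  for (seed in 1:200) {
    aln <- random_cluster(seed)
    got <- event_key(detect_events(aln))
    want <- oracle_event_key(oracle_detect(aln))
    expect_identical(got, want, label = sprintf("seed %d", seed))
  }
})
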