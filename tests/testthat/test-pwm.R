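test_that("uniform training data against a uniform background scores zero", {
  seqs <- c("ACGT", "CGTA", "GTAC", "TACG")  # every base once per position
  pwm <- train_pwm(seqs, site = "donor")
  expect_true(all(abs(pwm$mat) < 1e-12))
  expect_equal(score_site(pwm, "AAAA"), 0)
})

test_that("identical training sites give the closed-form per-position score", {
  seqs <- rep("CAGGTAAGT", 10L)
  pwm <- train_pwm(seqs, site = "donor", pseudocount = 0.5,
                   background = c(A = 1, C = 1, G = 1, T = 1))
  expected <- 9 * log2((10.5 / 12) / 0.25)
  expect_equal(score_site(pwm, "CAGGTAAGT"), expected)
})

test_that("the per-position argmax sequence achieves the maximum score", {
  s <- simulate_site_set(n = 50L, seed = 3L)
  pwm <- train_pwm(s$constitutive, site = "donor")
  consensus <- paste(rownames(pwm$mat)[apply(pwm$mat, 2, which.max)],
                     collapse = "")
  max_score <- score_site(pwm, consensus)
  expect_true(all(score_site(pwm, s$constitutive) <= max_score + 1e-12))
  expect_equal(max_score, sum(apply(pwm$mat, 2, max)))
})

test_that("non-ACGT bases are background-neutral and widths are checked", {
  pwm <- train_pwm(c("CAGGTAAGT", "CAGGTAAGA", "CAGGTAAGC"), site = "donor")
  with_n <- score_site(pwm, "NAGGTAAGT")
  without_first <- sum(pwm$mat[cbind(match(strsplit("AGGTAAGT", "")[[1]],
                                           c("A", "C", "G", "T")), 2:9)])
  expect_equal(with_n, without_first)
  expect_error(score_site(pwm, "CAG"), class = "estsplice_pwm_error")
  expect_error(train_pwm("CAGGTAAGT", site = "donor"),
               class = "estsplice_pwm_error")
})

test_that("background-distributed random windows score near zero on average", {
  set.seed(99)
  gc <- 0.64
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rand_win <- function(n, w) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), w, TRUE, p), collapse = "")
    }, character(1))
  }
  pwm <- train_pwm(rand_win(500L, 9L), site = "donor")
  scores <- score_site(pwm, rand_win(10000L, 9L))
  expect_lt(abs(mean(scores)), 0.1)
})

test_that("adding counts uniformly preserves per-position base ranking", {
  # the per-position log-odds is monotone in the base count, so raising
  # the pseudocount (a constant added to every count) cannot reorder the
  # four bases at any position
  s <- simulate_site_set(n = 60L, seed = 8L)
  p1 <- train_pwm(s$constitutive, site = "donor", pseudocount = 0.5)
  p2 <- train_pwm(s$constitutive, site = "donor", pseudocount = 5)
  for (pos in seq_len(ncol(p1$mat))) {
    expect_equal(order(p1$mat[, pos]), order(p2$mat[, pos]),
                 label = sprintf("position %d", pos))
  }
})

test_that("strength comparison detects shifts and handles degeneracy", {
  same <- rep(c(1, 2, 3), 5L)
  cmp <- compare_strength(same, same)
  expect_equal(cmp$mean_a - cmp$mean_b, 0)
  cmp <- compare_strength(rep(2, 10), rep(2, 10))
  expect_equal(cmp$p_value, 1)

  set.seed(4)
  a <- rnorm(100)
  cmp <- compare_strength(a, a - 1.5)
  expect_gt(cmp$mean_a, cmp$mean_b)
  expect_lt(cmp$p_value, 1e-6)
  cmp_t <- compare_strength(a, a - 1.5, test = "ttest")
  expect_lt(cmp_t$p_value, 1e-6)
  expect_equal(cmp_t$test_name, "Welch t-test")
})

test_that("degraded non-prevalent sites reproduce the strength ordering", {
  s <- simulate_site_set(n = 200L, seed = 21L)
  pwm <- train_pwm(s$constitutive, site = "donor")
  m_c <- mean(score_site(pwm, s$constitutive))
  m_p <- mean(score_site(pwm, s$prevalent))
  m_n <- mean(score_site(pwm, s$nonprevalent))
  expect_lt(m_n, m_p)
  expect_lt(m_p, m_c)
})

test_that("PWMs survive a save/load round trip", {
  s <- simulate_site_set(n = 30L, site = "acceptor", seed = 5L)
  pwm <- train_pwm(s$constitutive, site = "acceptor")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, p)
  back <- read_pwm(p)
  expect_equal(back$site, "acceptor")
  expect_equal(back$mat, pwm$mat, tolerance = 1e-9)
  expect_equal(unname(back$background), unname(pwm$background),
               tolerance = 1e-9)
  expect_equal(back$n, pwm$n)
  expect_equal(score_site(back, s$prevalent), score_site(pwm, s$prevalent),
               tolerance = 1e-7)
})

test_that("the strength table reports per-type rows backed by event introns", {
  sm <- sim_mixed()
  cl <- cluster_alignments(sm$ests$alignments)
  ev <- call_prevalent(detect_events(cl))
  const <- unique(alignment_introns(
    cl$alignments[!cl$alignments$cluster_id %in% ev$cluster_id, ,
                  drop = FALSE])[, c("chrom", "strand", "start", "end")])
  st <- strength_table(ev, const, sm$truth$genome)
  expect_true(all(st$by_type$type %in% unique(ev$type)))
  expect_true(all(st$by_type$n >= 1))
  expect_true(all(st$by_type$p_value >= 0 & st$by_type$p_value <= 1))
  # donor PWM consensus must contain the invariant GT at the boundary
  cons <- paste(rownames(st$pwms$donor$mat)[
    apply(st$pwms$donor$mat, 2, which.max)], collapse = "")
  expect_equal(substr(cons, 4, 5), "GT")
  cons_a <- paste(rownames(st$pwms$acceptor$mat)[
    apply(st$pwms$acceptor$mat, 2, which.max)], collapse = "")
  expect_equal(substr(cons_a, 13, 14), "AG")
})
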