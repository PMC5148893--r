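test_that("signature assembly computes gaps, regex and span", {
  pat <- make_patterns(c(39L, 129L), c("GTCTTGGAATAGG", "TTCTCATGT"))
  sig <- assemble_signature("Croton gratissimus", pat, "EU214230.1")
  expect_equal(sig$gaps, 77L)  # 129 - (39 + 13)
  expect_equal(sig$regex, "GTCTTGGAATAGG.{77}TTCTCATGT")
  expect_equal(sig$span$start, 39L)
  expect_equal(sig$span$end, 137L)
  single <- assemble_signature("X y", make_patterns(5L, "ACGTACG"))
  expect_length(single$gaps, 0)
  expect_equal(single$regex, "ACGTACG")
})

test_that("a signature spanning positions 39 to 742 covers 704 bp", {
  # eight patterns at the printed start positions of the exemplar
  starts <- c(39L, 129L, 188L, 294L, 365L, 531L, 639L, 735L)
  lens <- c(13L, 9L, rep(6L, 5L), 8L)   # last pattern ends at 742
  set.seed(7)
  lits <- vapply(lens, function(l) random_dna(l), character(1))
  sig <- assemble_signature("Croton gratissimus",
                            make_patterns(starts, lits))
  expect_equal(sig$span$start, 39L)
  expect_equal(sig$span$end, 742L)
  expect_equal(sig$span$length, 704L)
  expect_equal(length(sig$gaps), 7L)
})

test_that("overlapping patterns error and unsorted input is sorted", {
  bad <- make_patterns(c(10L, 15L), c("ACGTACGTAC", "ACGT"))
  expect_error(assemble_signature("X y", bad), "overlap")
  unsorted <- make_patterns(c(50L, 10L), c("ACGT", "GGCC"))
  expect_warning(sig <- assemble_signature("X y", unsorted), "sort")
  expect_equal(sig$patterns$start, c(10L, 50L))
})

test_that("sig text round trip reproduces the signature exactly", {
  set.seed(12)
  for (i in 1:20) {
    txt <- random_sig_text()
    sig <- read_sig(txt)
    expect_identical(write_sig(sig), txt)
    f <- withr::local_tempfile(fileext = ".sig")
    write_sig(sig, f)
    back <- read_sig(f)
    expect_equal(back$patterns$start, sig$patterns$start)
    expect_equal(back$patterns$literal, sig$patterns$literal)
    expect_equal(back$gaps, sig$gaps)
    expect_equal(back$species, sig$species)
  }
  expect_error(read_sig("not a signature"), "signature")
})

test_that("category boundaries are closed on the left", {
  expect_equal(categorize_f(0.75), "A")
  expect_equal(categorize_f(1.0), "A")
  expect_equal(categorize_f(0.5), "B")
  expect_equal(categorize_f(0.4999), "C")
  expect_equal(categorize_f(0.25), "C")
  expect_equal(categorize_f(0.0), "D")
  expect_error(categorize_f(1.1), "0, 1")
  # exhaustive grid against the interval definition
  grid <- seq(0, 1, by = 0.005)
  manual <- cut(grid, c(-Inf, 0.25, 0.5, 0.75, Inf),
                labels = c("D", "C", "B", "A"), right = FALSE)
  expect_equal(categorize_f(grid), as.character(manual))
})

test_that("evaluation implements recall, precision, F1 and conventions", {
  ev <- evaluation_report(tp = 3L, fp = 0L, fn = 1L)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$f_measure, 6 / 7)
  expect_equal(ev$category, "A")
  zero <- evaluation_report(tp = 0L, fp = 0L, fn = 4L)
  expect_equal(zero$precision, 0)
  expect_equal(zero$f_measure, 0)
  expect_equal(zero$category, "D")
})

test_that("a signature matching all targets and no others is perfect", {
  set.seed(13)
  target <- random_dna(300)
  sig <- assemble_signature("X y", build_patterns(c(50L, 150L), target))
  others <- vapply(1:5, function(i) random_dna(300), character(1))
  ev <- evaluate_signature(sig, rep(target, 3), others)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$f_measure, 1)
})

test_that("candidate selection follows the stated tie-break order", {
  mk <- function(f, recall, npat, span_len, regex) {
    lits <- rep("ACGT", npat)
    starts <- seq(1L, by = span_len %/% npat, length.out = npat)
    sig <- assemble_signature("X y", make_patterns(starts, lits))
    sig$regex <- regex
    sig$span$length <- span_len
    tp <- round(recall * 10)
    ev <- evaluation_report(tp, 0L, 10L - tp)
    ev$f_measure <- f
    ev$recall <- recall
    list(signature = sig, evaluation = ev)
  }
  a <- mk(0.9, 1.0, 2L, 100L, "AA")
  b <- mk(0.8, 1.0, 2L, 100L, "BB")
  expect_identical(select_candidate(list(b, a)), a)
  c1 <- mk(0.9, 1.0, 2L, 100L, "AA")
  c2 <- mk(0.9, 0.9, 2L, 100L, "BB")
  expect_identical(select_candidate(list(c2, c1)), c1)
  d1 <- mk(0.9, 1.0, 2L, 100L, "AA")
  d2 <- mk(0.9, 1.0, 3L, 100L, "BB")
  expect_identical(select_candidate(list(d2, d1)), d1)
  single <- mk(0.5, 0.5, 1L, 10L, "CC")
  expect_identical(select_candidate(list(single)), single)
  expect_error(select_candidate(list()), "no candidate")
})

test_that("refinement adds the site that eliminates false positives", {
  # Poa-like: two species identical except one G/C site
  set.seed(14)
  base <- random_dna(200)
  target <- base
  substr(target, 150, 150) <- "G"
  decoy <- base
  substr(decoy, 150, 150) <- "C"
  # initial signature from a site both species share
  init <- assemble_signature("Poa annua",
                             build_patterns(50L, target), "ex1")
  ev0 <- evaluate_signature(init, rep(target, 2), rep(decoy, 2))
  expect_equal(ev0$FP, 2L)
  out <- refine_signature(init, rep(target, 2), rep(decoy, 2),
                          site_pool = c(50L, 150L),
                          aligned_target = target)
  expect_equal(out$evaluation$FP, 0L)
  expect_equal(out$evaluation$TP, 2L)
  expect_equal(length(out$trajectory), 2L)
  # FP already 0: unchanged fixpoint
  out2 <- refine_signature(out$signature, rep(target, 2), rep(decoy, 2),
                           site_pool = c(50L, 150L),
                           aligned_target = target)
  expect_identical(out2$signature$regex, out$signature$regex)
  expect_length(out2$trajectory, 1L)
})

test_that("greedy refinement matches the exhaustive subset oracle", {
  # 1 target species + 2 decoys; 3 spare planted sites
  set.seed(15)
  base <- random_dna(300)
  sites <- c(60L, 140L, 220L)
  mutate_at <- function(s, pos) {
    old <- substr(s, pos, pos)
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    s
  }
  target <- base
  decoy1 <- mutate_at(base, sites[1])
  decoy2 <- mutate_at(mutate_at(base, sites[2]), sites[3])
  t_seqs <- rep(target, 3)
  o_seqs <- c(rep(decoy1, 2), rep(decoy2, 2))
  anchor <- 20L   # shared, non-discriminating anchor site
  init <- assemble_signature("X y", build_patterns(anchor, target), "e")
  out <- refine_signature(init, t_seqs, o_seqs,
                          site_pool = c(anchor, sites),
                          aligned_target = target)
  expect_equal(out$evaluation$FP, 0L)
  # FP monotonically non-increasing, TP non-decreasing along the way
  fps <- vapply(out$trajectory, function(x) x$evaluation$FP, integer(1))
  tps <- vapply(out$trajectory, function(x) x$evaluation$TP, integer(1))
  expect_true(all(diff(fps) <= 0))
  expect_true(all(diff(tps) >= 0))
  # exhaustive subset oracle: smallest site subset achieving FP = 0
  best_size <- Inf
  for (k in 1:3) {
    for (comb in utils::combn(sites, k, simplify = FALSE)) {
      sig <- assemble_signature(
        "X y", build_patterns(c(anchor, comb), target), "e")
      ev <- evaluate_signature(sig, t_seqs, o_seqs)
      if (ev$FP == 0 && ev$TP == 3) best_size <- min(best_size, k)
    }
  }
  added <- length(out$trajectory) - 1L
  expect_equal(added, best_size)
})
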