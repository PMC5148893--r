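sig_from <- function(literals, gaps, species = "X y") {
  starts <- cumsum(c(1L, utils::head(nchar(literals), -1) + gaps))
  assemble_signature(species, make_patterns(starts, literals), "ex")
}

test_that("exact inter-pattern distances are enforced", {
  sig <- sig_from(c("GTCTTGGAATAGG", "TTCTCATGT"), 77L)
  set.seed(31)
  q_good <- paste0("GTCTTGGAATAGG", random_dna(77), "TTCTCATGT")
  q_off <- paste0("GTCTTGGAATAGG", random_dna(76), "TTCTCATGT")
  queries <- barcode_records(c("good", "off"), c(q_good, q_off))
  res <- search_signature(sig, queries)
  expect_equal(res$matched, c(TRUE, FALSE))
  expect_equal(res$match_start[1], 1L)
  expect_equal(res$match_end[1], nchar(q_good))
  expect_true(all(is.na(res$match_start[2])))
})

test_that("N in a literal position is a hard mismatch", {
  sig <- sig_from(c("ACGTACGT", "GGCCGGCC"), 10L)
  set.seed(32)
  mid <- random_dna(10)
  hit <- paste0("TT", "ACGTACGT", mid, "GGCCGGCC", "TT")
  n_in_lit <- sub("ACGTACGT", "ACGNACGT", hit)
  n_in_gap <- paste0("TT", "ACGTACGT", paste0("NN", substr(mid, 3, 10)),
                     "GGCCGGCC", "TT")
  queries <- barcode_records(c("hit", "nlit", "ngap"),
                             c(hit, n_in_lit, n_in_gap))
  res <- search_signature(sig, queries)
  expect_equal(res$matched, c(TRUE, FALSE, TRUE))
  expect_equal(res$match_start[1], 3L)
})

test_that("search equals the brute-force all-offsets oracle", {
  set.seed(33)
  for (rep in 1:25) {
    n_pat <- sample(1:3, 1)
    lits <- vapply(seq_len(n_pat), function(i) random_dna(sample(3:6, 1)),
                   character(1))
    gaps <- if (n_pat > 1) sample(0:8, n_pat - 1, replace = TRUE) else integer()
    sig <- sig_from(lits, gaps)
    queries <- barcode_records(
      paste0("q", 1:20),
      vapply(1:20, function(i) random_dna(sample(30:80, 1)), character(1)))
    # plant positives in a few queries
    for (k in sample(20, 5)) {
      ins <- paste0(lits[1],
                    if (n_pat > 1) {
                      paste(vapply(2:n_pat, function(j) {
                        paste0(random_dna(gaps[j - 1]), lits[j])
                      }, character(1)), collapse = "")
                    } else "")
      at <- sample(nchar(queries$seq[k]) - 1L, 1)
      queries$seq[k] <- paste0(substr(queries$seq[k], 1, at), ins,
                               substr(queries$seq[k], at + 1,
                                      nchar(queries$seq[k])))
    }
    res <- search_signature(sig, queries)
    oracle <- vapply(queries$seq, function(s) match_oracle(lits, gaps, s),
                     integer(1), USE.NAMES = FALSE)
    expect_equal(res$matched, !is.na(oracle))
    expect_equal(res$match_start, oracle)
  }
})

test_that("multi-signature classification assigns, abstains or flags", {
  set.seed(34)
  sig_x <- sig_from(c("AAAAGGGG", "CCCCTTTT"), 5L, species = "Gen x")
  sig_y <- sig_from(c("TTTTCCCC", "GGGGAAAA"), 5L, species = "Gen y")
  q_x <- paste0(random_dna(10), "AAAAGGGG", random_dna(5), "CCCCTTTT")
  q_none <- random_dna(40)
  # adversarial: concatenates both signatures' layouts
  q_both <- paste0(q_x, "TTTTCCCC", random_dna(5), "GGGGAAAA")
  queries <- barcode_records(c("qx", "qn", "qb"), c(q_x, q_none, q_both))
  res <- classify_queries(list(sig_x, sig_y), queries)
  expect_equal(res$matched_species, c("Gen x", NA, NA))
  expect_equal(res$ambiguous, c(FALSE, FALSE, TRUE))
  expect_equal(res$signature_used[3], "Gen x;Gen y")
  # positions only when a single species is assigned
  expect_false(is.na(res$match_start[1]))
  expect_true(all(is.na(res$match_start[2:3])))
  expect_error(classify_queries(list(sig_x, sig_x), queries), "duplicate")
})

test_that("classification order does not change assignments", {
  set.seed(35)
  sig_x <- sig_from(c("AAAAGGGG", "CCCCTTTT"), 5L, species = "Gen x")
  sig_y <- sig_from(c("TTTTCCCC", "GGGGAAAA"), 5L, species = "Gen y")
  queries <- barcode_records(
    paste0("r", 1:6),
    c(paste0(random_dna(4), "AAAAGGGG", random_dna(5), "CCCCTTTT"),
      vapply(1:5, function(i) random_dna(50), character(1))))
  r1 <- classify_queries(list(sig_x, sig_y), queries)
  r2 <- classify_queries(list(sig_y, sig_x), queries)
  expect_equal(r1$matched_species, r2$matched_species)
  expect_equal(r1$ambiguous, r2$ambiguous)
})

test_that("summaries count every query exactly once", {
  set.seed(36)
  sig <- sig_from(c("AAAAGGGG", "CCCCTTTT"), 5L, species = "Gen x")
  queries <- barcode_records(
    paste0("s", 1:30),
    vapply(1:30, function(i) random_dna(60), character(1)))
  planted <- sample(30, 8)
  queries$seq[planted] <- paste0(
    "AAAAGGGG", vapply(planted, function(i) random_dna(5), character(1)),
    "CCCCTTTT")
  res <- classify_queries(list(sig), queries)
  s <- summarize_classification(res)
  expect_equal(s$n_identified + s$n_unidentified + s$n_ambiguous,
               s$n_queries)
  expect_equal(s$n_identified, 8L)
  expect_equal(unname(s$per_species["Gen x"]), 8L)
  empty <- summarize_classification(
    classify_queries(list(sig), queries[0, , drop = FALSE]))
  expect_equal(empty$n_queries, 0L)
  expect_equal(empty$n_identified, 0L)
})
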