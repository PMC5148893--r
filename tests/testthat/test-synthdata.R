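test_that("noise-free generation is deterministic with identical species", {
  sd1 <- generate_barcodes(synth_spec(seed = 42L))
  sd2 <- generate_barcodes(synth_spec(seed = 42L))
  expect_identical(sd1$alignment$records$seq, sd2$alignment$records$seq)
  expect_identical(sd1$truth, sd2$truth)
  rec <- sd1$alignment$records
  for (sp in unique(rec$species)) {
    expect_length(unique(rec$seq[rec$species == sp]), 1L)
  }
  # within-species probability-vector distances are exactly zero
  m <- compute_ppm(compute_pfm(sd1$alignment))
  d <- pairwise_distances(probability_vectors(sd1$alignment, m))
  for (sp in unique(rec$species)) {
    i <- which(rec$species == sp)
    expect_true(all(d[i, i] == 0))
  }
})

test_that("different seeds give different datasets", {
  sd1 <- generate_barcodes(synth_spec(seed = 1L))
  sd2 <- generate_barcodes(synth_spec(seed = 2L))
  expect_false(identical(sd1$alignment$records$seq,
                         sd2$alignment$records$seq))
})

test_that("planted alleles differ from the backbone at planted sites only", {
  sd <- generate_barcodes(synth_spec(seed = 7L))
  for (sp in names(sd$truth)) {
    t <- sd$truth[[sp]]
    expect_true(all(t$alleles != t$backbone_base))
    expect_equal(anyDuplicated(t$sites), 0L)
  }
  # sites are unique within each genus (no collisions across species)
  by_genus <- split(sd$truth, vapply(sd$truth, `[[`, "", "genus"))
  for (g in by_genus) {
    all_sites <- unlist(lapply(g, `[[`, "sites"))
    expect_equal(anyDuplicated(all_sites), 0L)
  }
})

test_that("empirical noise frequency is within 3 sigma of the rate", {
  rate <- 0.02
  sd <- generate_barcodes(synth_spec(seq_len = 2000L, seqs_per_species = 4L,
                                     noise_rate = rate, seed = 99L))
  rec <- sd$alignment$records
  mism <- 0L
  total <- 0L
  for (sp in names(sd$truth)) {
    tmpl <- strsplit(sd$truth[[sp]]$template, "")[[1]]
    for (s in rec$seq[rec$species == sp]) {
      chars <- strsplit(s, "")[[1]]
      mism <- mism + sum(chars != tmpl)
      total <- total + length(chars)
    }
  }
  p_hat <- mism / total
  se <- sqrt(rate * (1 - rate) / total)
  expect_lt(abs(p_hat - rate), 3 * se)
})

test_that("indels are emitted as alignment gaps, keeping records aligned", {
  sd <- generate_barcodes(synth_spec(indel_rate = 0.01, seed = 5L))
  expect_true(any(grepl("-", sd$alignment$records$seq)))
  expect_length(unique(nchar(sd$alignment$records$seq)), 1L)
  degapped <- degap_records(sd$alignment)
  expect_false(any(grepl("-", degapped$seq)))
})

test_that("infeasible site requests are rejected", {
  expect_error(generate_barcodes(synth_spec(seq_len = 30L,
                                            planted_sites_per_species = 20L)),
               "too short")
})

test_that("corruption at rate zero is the identity", {
  sd <- generate_barcodes(synth_spec())
  rec <- degap_records(sd$alignment)
  expect_identical(corrupt_barcodes(rec, 0), rec)
})

test_that("truncation that removes a pattern causes a false negative", {
  set.seed(61)
  target <- random_dna(400)
  sig <- assemble_signature("X y",
                            build_patterns(c(100L, 350L), target), "e")
  truncated <- substr(target, 1, 300)   # second pattern gone
  ev <- evaluate_signature(sig, c(target, truncated), character())
  expect_equal(ev$TP, 1L)
  expect_equal(ev$FN, 1L)
})

test_that("a gap-region indel breaks exact distances but not tolerant ones", {
  set.seed(62)
  target <- random_dna(400)
  sig <- assemble_signature("X y",
                            build_patterns(c(100L, 300L), target), "e")
  # delete one base strictly between the two patterns
  mutated <- paste0(substr(target, 1, 200), substr(target, 202, 400))
  ev_exact <- evaluate_signature(sig, mutated, character(), tolerance = 0L)
  expect_equal(ev_exact$FN, 1L)
  ev_tol <- evaluate_signature(sig, mutated, character(), tolerance = 1L)
  expect_equal(ev_tol$TP, 1L)
  diag <- diagnose_miss(sig, mutated)
  expect_equal(diag$reason, "gap_mismatch")
  expect_equal(diag$observed, diag$expected - 1L)
})

test_that("recall under corruption is non-increasing in the noise rate", {
  sd <- generate_barcodes(synth_spec(seed = 8L))
  fit <- barcode_signatures(sd$alignment)
  rec <- degap_records(sd$alignment)
  recalls <- vapply(c(0, 0.05, 0.15, 0.4), function(rate) {
    noisy <- corrupt_barcodes(rec, rate, seed = 123L)
    evs <- vapply(names(fit$signatures), function(sp) {
      evaluate_signature(fit$signatures[[sp]],
                         noisy$seq[noisy$species == sp],
                         character())$recall
    }, numeric(1))
    mean(evs)
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-9))
  expect_equal(recalls[1], 1)
})
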