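test_that("probability vectors look up each base's column probability", {
  a <- toy_alignment()
  m <- compute_ppm(compute_pfm(a))
  v <- probability_vectors(a, m)
  expect_equal(unname(v["s1", ]), c(0.75, 0.5, 1.0))   # ACG
  # ACG and ATG collide: equal column-2 frequencies (known degeneracy)
  expect_equal(v["s1", ], v["s3", ])
  # identical sequences give all-ones vectors
  same <- barcode_alignment(barcode_records(c("a", "b"), c("AC", "AC")))
  vs <- probability_vectors(same, compute_ppm(compute_pfm(same)))
  expect_true(all(vs == 1))
  # c mismatch is an error
  expect_error(probability_vectors(same, m), "columns")
})

test_that("gap positions contribute zero to the probability vector", {
  a <- barcode_alignment(barcode_records(c("a", "b"), c("A-", "AC")))
  v <- probability_vectors(a, compute_ppm(compute_pfm(a)))
  expect_equal(unname(v["a", ]), c(1, 0))
})

test_that("pairwise distances equal the naive double-loop oracle", {
  a <- toy_alignment()
  m <- compute_ppm(compute_pfm(a))
  v <- probability_vectors(a, m)
  d <- pairwise_distances(v)
  expect_equal(d["s1", "s4"], 0.5)  # sqrt((0.75-0.25)^2)
  set.seed(33)
  vs <- matrix(runif(5 * 7), nrow = 5,
               dimnames = list(paste0("q", 1:5), NULL))
  dm <- pairwise_distances(vs)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(dm[i, j], sqrt(sum((vs[i, ] - vs[j, ])^2)),
                 tolerance = 1e-12)
  }
})

test_that("distance matrices satisfy the metric axioms", {
  set.seed(44)
  for (rep in 1:5) {
    vs <- matrix(runif(6 * 10), nrow = 6,
                 dimnames = list(paste0("r", 1:6), NULL))
    d <- pairwise_distances(vs)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("the barcoding-gap rule needs inter > intra and nonzero", {
  # P = two copies of ACG, Q = two copies of TTG, scored under the
  # toy alignment's PPM: intra = 0 for both, inter = 0.5 > 0
  m <- compute_ppm(compute_pfm(toy_alignment()))
  a <- barcode_alignment(barcode_records(
    paste0("x", 1:4), c("ACG", "ACG", "TTG", "TTG"),
    genus = "G", species = c("G p", "G p", "G q", "G q")))
  d <- pairwise_distances(probability_vectors(a, m))
  rep <- discriminate_species(d, setNames(a$records$species, a$records$id))
  expect_true(all(rep$pair_table$discriminated))
  expect_equal(rep$n_discriminated, 2L)
  # sequences collapsing to identical probability vectors: min_inter = 0
  b <- barcode_alignment(barcode_records(
    paste0("y", 1:4), c("ACG", "ACG", "ATG", "ATG"),
    genus = "G", species = c("G p", "G p", "G q", "G q")))
  mb <- compute_ppm(compute_pfm(b))
  db <- pairwise_distances(probability_vectors(b, mb))
  repb <- discriminate_species(db, setNames(b$records$species,
                                            b$records$id))
  expect_false(any(repb$pair_table$discriminated))
  expect_equal(repb$n_discriminated, 0L)
})

test_that("singleton species reduce the rule to min_inter > 0", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
              dimnames = list(c("a1", "b1"), c("a1", "b1")))
  rep <- discriminate_species(d, c(a1 = "G a", b1 = "G b"))
  expect_true(rep$pair_table$discriminated)
  expect_equal(rep$pair_table$max_intra_a, 0)
})

test_that("ties at min_inter == max_intra are not discriminated", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.5   # intra equals inter
  d["b1", "b2"] <- d["b2", "b1"] <- 0.1
  rep <- discriminate_species(d, setNames(c("G a", "G a", "G b", "G b"),
                                          ids))
  expect_false(rep$pair_table$discriminated)
})

test_that("discrimination is invariant to id relabelling and row order", {
  set.seed(55)
  vs <- matrix(runif(8 * 12), nrow = 8,
               dimnames = list(paste0("s", 1:8), NULL))
  labels <- setNames(rep(c("G a", "G b", "G c", "G d"), each = 2),
                     paste0("s", 1:8))
  d1 <- pairwise_distances(vs)
  r1 <- discriminate_species(d1, labels)
  perm <- sample(8)
  vs2 <- vs[perm, ]
  rownames(vs2) <- paste0("t", 1:8)
  labels2 <- setNames(labels[perm], paste0("t", 1:8))
  r2 <- discriminate_species(pairwise_distances(vs2), labels2)
  expect_equal(r1$n_discriminated, r2$n_discriminated)
  expect_equal(r1$species_table$discriminated_overall,
               r2$species_table$discriminated_overall)
})

test_that("locus comparison handles identity, dominance and tiny n", {
  expect_warning(res <- compare_loci(1:5 / 10, 1:5 / 10), "zero")
  expect_equal(res$p, 1)
  set.seed(66)
  b <- runif(20)
  res2 <- compare_loci(b + runif(20, 0.05, 0.15), b)
  expect_lt(res2$p, 0.05)
  # n = 3: exact signed-rank distribution by enumerating 2^3 signs
  a3 <- c(0.30, 0.10, 0.25)
  b3 <- c(0.10, 0.18, 0.10)  # distinct |differences|, so ranks are exact
  d <- a3 - b3
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 3))
  v_all <- as.matrix(signs) %*% r
  p_exact <- mean(abs(v_all - sum(r) / 2) >= abs(v_obs - sum(r) / 2))
  res3 <- compare_loci(a3, b3)
  expect_equal(res3$p, p_exact)
})
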