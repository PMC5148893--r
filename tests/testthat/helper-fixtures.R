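# shared fixtures and independent oracles, built in code

# the 4-sequence, 3-column toy alignment used throughout
toy_alignment <- function() {
  barcode_alignment(barcode_records(
    paste0("s", 1:4), c("ACG", "ACG", "ATG", "TTG"),
    genus = "Toy", species = "Toy example"))
}

# build a signature_patterns data frame by hand
make_patterns <- function(starts, literals, sites = NULL) {
  df <- data.frame(start = as.integer(starts),
                   end = as.integer(starts + nchar(literals) - 1L))
  df$literal <- literals
  df$sites_covered <- I(if (is.null(sites)) {
    rep(list(integer()), nrow(df))
  } else {
    sites
  })
  class(df) <- c("signature_patterns", "data.frame")
  df
}

# brute-force all-offsets matcher for ordered literals with exact gaps;
# returns the leftmost 1-based match start or NA. Literals must match
# exactly; gap positions match any character.
match_oracle <- function(literals, gaps, seq) {
  total <- sum(nchar(literals)) + sum(gaps)
  n <- nchar(seq)
  if (total > n) return(NA_integer_)
  for (s in 1:(n - total + 1L)) {
    pos <- s
    ok <- TRUE
    for (i in seq_along(literals)) {
      if (substring(seq, pos, pos + nchar(literals[i]) - 1L) != literals[i]) {
        ok <- FALSE
        break
      }
      pos <- pos + nchar(literals[i])
      if (i < length(literals)) pos <- pos + gaps[i]
    }
    if (ok) return(s)
  }
  NA_integer_
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random but syntactically valid signature payload string
random_sig_text <- function(n_pat = NULL) {
  if (is.null(n_pat)) n_pat <- sample(2:6, 1)
  lits <- vapply(seq_len(n_pat), function(i) random_dna(sample(5:15, 1)),
                 character(1))
  gaps <- sample(0:200, n_pat - 1, replace = TRUE)
  starts <- cumsum(c(sample(1:50, 1),
                     utils::head(nchar(lits), -1) + gaps))
  sig <- assemble_signature(
    paste("Genus", paste0("sp", sample(letters, 1))),
    make_patterns(starts, lits), exemplar_id = "EX1")
  write_sig(sig)
}
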