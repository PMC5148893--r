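# QR model-2 symbol construction (encoder side). All coordinates in
# this file are 1-based matrix indices [row, col]; the standard's
# 0-based (row, column) positions are offset by one.

# function-module layout: returns list(mod = 0/1 matrix with function
# patterns placed, fun = logical mask of reserved modules)
qr_function_modules <- function(version) {
  n <- qr_size(version)
  mod <- matrix(0L, n, n)
  fun <- matrix(FALSE, n, n)

  place_finder <- function(r, c) {
    for (dr in -1:7) for (dc in -1:7) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1L || rr > n || cc < 1L || cc > n) next
      dark <- (dr >= 0 && dr <= 6 && dc >= 0 && dc <= 6) &&
        (dr %in% c(0, 6) || dc %in% c(0, 6) ||
           (dr >= 2 && dr <= 4 && dc >= 2 && dc <= 4))
      mod[rr, cc] <<- as.integer(dark)
      fun[rr, cc] <<- TRUE
    }
  }
  place_finder(1L, 1L)
  place_finder(1L, n - 6L)
  place_finder(n - 6L, 1L)

  # timing patterns (row/col 7 in 1-based terms)
  for (i in 9:(n - 8L)) {
    mod[7L, i] <- as.integer(i %% 2L == 1L)
    mod[i, 7L] <- as.integer(i %% 2L == 1L)
    fun[7L, i] <- TRUE
    fun[i, 7L] <- TRUE
  }

  # alignment patterns
  centres <- qr_alignment_centres(version)
  for (r in centres) for (c in centres) {
    # skip where overlapping a finder
    if ((r <= 8L && c <= 8L) || (r <= 8L && c >= n - 7L) ||
        (r >= n - 7L && c <= 8L)) next
    for (dr in -2:2) for (dc in -2:2) {
      dark <- max(abs(dr), abs(dc)) != 1L
      mod[r + dr, c + dc] <- as.integer(dark)
      fun[r + dr, c + dc] <- TRUE
    }
  }

  # reserve format info areas
  fun[9L, c(1:9, (n - 7L):n)] <- TRUE
  fun[c(1:9, (n - 7L):n), 9L] <- TRUE
  # dark module
  mod[n - 7L, 9L] <- 1L
  fun[n - 7L, 9L] <- TRUE

  if (version >= 7L) {
    fun[(n - 10L):(n - 8L), 1:6] <- TRUE
    fun[1:6, (n - 10L):(n - 8L)] <- TRUE
  }
  list(mod = mod, fun = fun)
}

# total codewords available in the symbol (geometry-derived)
qr_total_codewords <- function(version) {
  fun <- qr_function_modules(version)$fun
  sum(!fun) %/% 8L
}

# zigzag order of data-module positions: 2 x n matrix (row; col)
qr_data_positions <- function(fun) {
  n <- nrow(fun)
  rows <- integer(); cols <- integer()
  col <- n
  upward <- TRUE
  while (col >= 1L) {
    if (col == 7L) col <- 6L  # skip the timing column entirely
    rseq <- if (upward) n:1 else 1:n
    for (r in rseq) {
      for (c in c(col, col - 1L)) {
        if (c >= 1L && !fun[r, c]) {
          rows <- c(rows, r); cols <- c(cols, c)
        }
      }
    }
    col <- col - 2L
    upward <- !upward
  }
  rbind(rows, cols)
}

qr_mask_matrix <- function(mask, n) {
  r <- matrix(0:(n - 1L), n, n)          # 0-based row index
  c <- matrix(0:(n - 1L), n, n, byrow = TRUE)
  keep <- switch(as.character(mask),
    "0" = (r + c) %% 2L == 0L,
    "1" = r %% 2L == 0L,
    "2" = c %% 3L == 0L,
    "3" = (r + c) %% 3L == 0L,
    "4" = (r %/% 2L + c %/% 3L) %% 2L == 0L,
    "5" = (r * c) %% 2L + (r * c) %% 3L == 0L,
    "6" = ((r * c) %% 2L + (r * c) %% 3L) %% 2L == 0L,
    "7" = ((r + c) %% 2L + (r * c) %% 3L) %% 2L == 0L,
    stop("mask must be 0..7"))
  keep
}

# BCH-protected 15-bit format information for EC level M and a mask id
qr_format_bits <- function(mask, ec_bits = 0L) {  # M level indicator = 00
  value <- bitwOr(bitwShiftL(ec_bits, 3L), mask)
  bch <- bitwShiftL(value, 10L)
  gen <- 1335L  # 0b10100110111
  for (i in 14:10) {
    if (bitwAnd(bch, bitwShiftL(1L, i)) != 0L) {
      bch <- bitwXor(bch, bitwShiftL(gen, i - 10L))
    }
  }
  fmt <- bitwXor(bitwOr(bitwShiftL(value, 10L), bch), 21522L)  # 0x5412
  as.integer(bitwAnd(bitwShiftR(fmt, 0:14), 1L))  # bit 0 (LSB) first
}

# 18-bit version information (versions >= 7); bit 0 first
qr_version_bits <- function(version) {
  bch <- bitwShiftL(version, 12L)
  gen <- 7973L  # 0b1111100100101
  for (i in 17:12) {
    if (bitwAnd(bch, bitwShiftL(1L, i)) != 0L) {
      bch <- bitwXor(bch, bitwShiftL(gen, i - 12L))
    }
  }
  v <- bitwOr(bitwShiftL(version, 12L), bch)
  as.integer(bitwAnd(bitwShiftR(v, 0:17), 1L))
}

# format info placement: 15 x 2 matrices of [row, col] for both copies,
# index i holds bit i-1 (LSB first)
qr_format_positions <- function(n) {
  copy1 <- rbind(
    cbind(9L, c(1:6, 8L)),        # bits 0-6
    cbind(c(9L, 8L), 9L),         # bits 7-8
    cbind(6:1, 9L))               # bits 9-14
  copy2 <- rbind(
    cbind(n:(n - 6L), 9L),        # bits 0-6
    cbind(9L, (n - 7L):n))        # bits 7-14
  list(copy1 = copy1, copy2 = copy2)
}

qr_place_format <- function(mod, mask) {
  n <- nrow(mod)
  fb <- qr_format_bits(mask)
  pos <- qr_format_positions(n)
  mod[pos$copy1] <- fb
  mod[pos$copy2] <- fb
  mod
}

qr_place_version <- function(mod, version) {
  if (version < 7L) return(mod)
  n <- nrow(mod)
  vb <- qr_version_bits(version)
  i <- 0:17
  # bottom-left copy: 3 rows x 6 cols
  mod[cbind(n - 10L + (i %% 3L), 1L + i %/% 3L)] <- vb
  # top-right copy: transpose
  mod[cbind(1L + i %/% 3L, n - 10L + (i %% 3L))] <- vb
  mod
}

# mask evaluation penalty (ISO rules N1-N4)
qr_penalty <- function(mod) {
  n <- nrow(mod)
  p <- 0L
  run_penalty <- function(v) {
    r <- rle(v)
    sum(ifelse(r$lengths >= 5L, 3L + (r$lengths - 5L), 0L))
  }
  for (i in seq_len(n)) {
    p <- p + run_penalty(mod[i, ]) + run_penalty(mod[, i])
  }
  blk <- mod[-n, -n] + mod[-1L, -n] + mod[-n, -1L] + mod[-1L, -1L]
  p <- p + 3L * sum(blk == 0L | blk == 4L)
  pat1 <- c(1, 0, 1, 1, 1, 0, 1, 0, 0, 0, 0)
  pat2 <- rev(pat1)
  count_pat <- function(v) {
    if (length(v) < 11L) return(0L)
    hits <- 0L
    for (s in 1:(length(v) - 10L)) {
      w <- v[s:(s + 10L)]
      if (all(w == pat1) || all(w == pat2)) hits <- hits + 1L
    }
    hits
  }
  n3 <- 0L
  for (i in seq_len(n)) {
    n3 <- n3 + count_pat(mod[i, ]) + count_pat(mod[, i])
  }
  p <- p + 40L * n3
  dark_pct <- 100 * sum(mod) / (n * n)
  lo <- as.integer(dark_pct %/% 5) * 5L
  p + 10L * (min(abs(lo - 50L), abs(lo + 5L - 50L)) %/% 5L)
}

# build the bit payload (byte mode) and final interleaved codewords
qr_codewords <- function(bytes, version) {
  dc <- qr_data_codewords(version)
  cci_bits <- if (version <= 9L) 8L else 16L
  nbits <- 4L + cci_bits + 8L * length(bytes)
  if (nbits > 8L * dc) stop("payload does not fit version ", version)
  int_bits <- function(x, width) as.integer(bitwAnd(bitwShiftR(x, (width - 1L):0), 1L))
  bits <- c(int_bits(4L, 4L),                       # byte mode 0100
            int_bits(length(bytes), cci_bits),
            unlist(lapply(bytes, int_bits, width = 8L), use.names = FALSE))
  bits <- c(bits, integer(min(4L, 8L * dc - length(bits))))  # terminator
  if (length(bits) %% 8L != 0L) {
    bits <- c(bits, integer(8L - length(bits) %% 8L))
  }
  data_cw <- vapply(seq_len(length(bits) / 8L), function(i) {
    sum(bits[(8L * i - 7L):(8L * i)] * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
  }, integer(1))
  pad <- c(236L, 17L)
  while (length(data_cw) < dc) {
    data_cw <- c(data_cw, pad[(length(data_cw) - length(bits) / 8L) %% 2L + 1L])
  }
  # split into blocks
  tab <- qr_block_table_M[[version]]
  blocks <- list()
  off <- 0L
  for (g in seq_len(nrow(tab$g))) {
    for (b in seq_len(tab$g[g, 1L])) {
      sz <- tab$g[g, 2L]
      blocks[[length(blocks) + 1L]] <- data_cw[(off + 1L):(off + sz)]
      off <- off + sz
    }
  }
  ec_blocks <- lapply(blocks, rs_encode, n_ec = tab$ec)
  interleave <- function(bl) {
    maxlen <- max(lengths(bl))
    out <- integer()
    for (i in seq_len(maxlen)) {
      for (b in bl) if (length(b) >= i) out <- c(out, b[i])
    }
    out
  }
  c(interleave(blocks), interleave(ec_blocks))
}

# full symbol matrix (0/1) for a UTF-8 text payload
qr_matrix <- function(text, version = NULL, mask = NULL) {
  bytes <- as.integer(charToRaw(enc2utf8(text)))
  if (length(bytes) == 0L) stop("empty QR payload")
  if (is.null(version)) {
    fits <- function(v) {
      cci <- if (v <= 9L) 8L else 16L
      4L + cci + 8L * length(bytes) <= 8L * qr_data_codewords(v)
    }
    version <- NA_integer_
    for (v in seq_len(QR_MAX_VERSION)) if (fits(v)) { version <- v; break }
    if (is.na(version)) {
      stop("payload too long for QR version ", QR_MAX_VERSION,
           " at EC level M (", length(bytes),
           " bytes); split the payload")
    }
  }
  cw <- qr_codewords(bytes, version)
  layout <- qr_function_modules(version)
  pos <- qr_data_positions(layout$fun)
  bits <- unlist(lapply(cw, function(x) {
    as.integer(bitwAnd(bitwShiftR(x, 7:0), 1L))
  }), use.names = FALSE)
  bits <- c(bits, integer(ncol(pos) - length(bits)))  # remainder bits
  mod <- layout$mod
  mod[t(pos)] <- bits
  masks <- if (is.null(mask)) 0:7 else mask
  best <- NULL
  for (m in masks) {
    mm <- qr_mask_matrix(m, nrow(mod))
    cand <- mod
    flip <- mm & !layout$fun
    cand[flip] <- 1L - cand[flip]
    cand <- qr_place_format(cand, m)
    cand <- qr_place_version(cand, version)
    pen <- qr_penalty(cand)
    if (is.null(best) || pen < best$pen) best <- list(mat = cand, pen = pen,
                                                     mask = m)
  }
  structure(best$mat, version = version, mask = best$mask)
}
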