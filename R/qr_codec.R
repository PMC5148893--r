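# QR decoding: module-grid extraction from clean upright PNG renderings,
# format recovery, unmasking, codeword deinterleaving and Reed-Solomon
# error correction.

#' Encode a text payload as a QR code PNG
#'
#' Produces a standard model-2 QR symbol, byte mode, error-correction
#' level M, automatic version selection (1-20), standard mask-penalty
#' selection, with a 4-module quiet zone. The payload is typically a
#' serialized signature ([write_sig()]) or a FASTA entry.
#'
#' @param text non-empty character payload (UTF-8).
#' @param path output PNG path.
#' @param scale pixels per module (default 4).
#' @return the path, invisibly; attributes \code{version} and
#'   \code{mask} report the chosen symbol parameters.
#' @export
encode_qr <- function(text, path, scale = 4L) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("QR payload must be a single non-empty string")
  }
  mat <- qr_matrix(text)
  n <- nrow(mat)
  quiet <- 4L
  full <- matrix(0L, n + 2L * quiet, n + 2L * quiet)
  full[quiet + seq_len(n), quiet + seq_len(n)] <- mat
  img <- 1 - full[rep(seq_len(nrow(full)), each = scale),
                  rep(seq_len(ncol(full)), each = scale)]
  png::writePNG(img, path)
  out <- path
  attr(out, "version") <- attr(mat, "version")
  attr(out, "mask") <- attr(mat, "mask")
  invisible(out)
}

#' Decode a QR code PNG back to its text payload
#'
#' Reads a clean, upright rendering of a single QR symbol (as produced
#' by [encode_qr()] or any renderer emitting an axis-aligned symbol
#' with a quiet zone), recovers the module grid, reads format
#' information, unmasks, deinterleaves codewords and applies
#' Reed-Solomon error correction. The recovered payload is byte-exact.
#'
#' @param path PNG file containing exactly one QR symbol.
#' @return list of class \code{qr_payload}: \code{text} and
#'   \code{kind}, inferred as \code{"signature"} when the text starts
#'   with \code{#species=}, \code{"fasta"} when it starts with
#'   \code{>}, else \code{"other"}.
#' @export
decode_qr <- function(path) {
  mat <- qr_read_modules(path)
  text <- qr_decode_matrix(mat)
  kind <- if (startsWith(text, "#species=")) "signature"
          else if (startsWith(text, ">")) "fasta"
          else "other"
  structure(list(text = text, kind = kind), class = "qr_payload")
}

#' @export
print.qr_payload <- function(x, ...) {
  cat(sprintf("qr_payload (%s, %d bytes)\n", x$kind,
              length(charToRaw(x$text))))
  invisible(x)
}

# --- module-grid extraction ------------------------------------------

qr_read_modules <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  }
  dark <- img < 0.5
  if (!any(dark)) stop("no QR symbol found in image")
  rows <- range(which(rowSums(dark) > 0L))
  cols <- range(which(colSums(dark) > 0L))
  h <- rows[2L] - rows[1L] + 1L
  w <- cols[2L] - cols[1L] + 1L
  if (h != w) stop("no QR symbol found: dark region is not square")
  # the top-left finder's top edge is a run of 7 dark modules
  top <- dark[rows[1L], cols[1L]:cols[2L]]
  run <- which(!top)[1L] - 1L
  if (is.na(run)) run <- w
  if (run %% 7L != 0L) stop("cannot infer module size (not a QR symbol?)")
  scale <- run %/% 7L
  if (w %% scale != 0L) stop("image width is not a whole number of modules")
  n <- w %/% scale
  if (n < 21L || (n - 17L) %% 4L != 0L) {
    stop("module count ", n, " does not correspond to a QR version")
  }
  centre <- as.integer((seq_len(n) - 0.5) * scale)
  mat <- matrix(as.integer(dark[rows[1L] - 1L + centre,
                                cols[1L] - 1L + centre]), n, n)
  finder_ok <- function(r, c) {
    all(mat[r:(r + 6L), c] == c(1L, 1L, 1L, 1L, 1L, 1L, 1L)) &&
      all(mat[r, c:(c + 6L)] == 1L) &&
      all(mat[r + 1L, c + 1L:5L] == c(0L, 0L, 0L, 0L, 0L)) &&
      all(mat[r + 2L:4L, c + 2L] == c(1L, 1L, 1L))
  }
  if (!finder_ok(1L, 1L) || !finder_ok(1L, n - 6L) || !finder_ok(n - 6L, 1L)) {
    stop("finder patterns not found; not a single upright QR symbol")
  }
  mat
}

# --- symbol decoding --------------------------------------------------

qr_decode_matrix <- function(mat) {
  n <- nrow(mat)
  version <- (n - 17L) %/% 4L
  if (version > QR_MAX_VERSION) {
    stop("QR version ", version, " exceeds supported range")
  }
  fmt <- qr_decode_format(mat)
  if (fmt$ec_bits != 0L) {
    stop("unsupported error-correction level (only level M is handled)")
  }
  layout <- qr_function_modules(version)
  mm <- qr_mask_matrix(fmt$mask, n)
  unmasked <- mat
  flip <- mm & !layout$fun
  unmasked[flip] <- 1L - unmasked[flip]
  pos <- qr_data_positions(layout$fun)
  bits <- unmasked[t(pos)]
  total_cw <- length(bits) %/% 8L
  cw <- vapply(seq_len(total_cw), function(i) {
    sum(bits[(8L * i - 7L):(8L * i)] * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
  }, integer(1))
  data_cw <- qr_deinterleave(cw, version)
  qr_parse_bitstream(data_cw, version)
}

qr_decode_format <- function(mat) {
  n <- nrow(mat)
  pos <- qr_format_positions(n)
  read_copy <- function(p) as.integer(mat[p])
  candidates <- lapply(0:31, function(v) {
    ec <- bitwShiftR(v, 3L); mask <- bitwAnd(v, 7L)
    list(ec = ec, mask = mask, bits = qr_format_bits(mask, ec))
  })
  best_for <- function(bits) {
    dists <- vapply(candidates, function(cand) sum(cand$bits != bits),
                    integer(1))
    i <- which.min(dists)
    list(cand = candidates[[i]], dist = dists[i])
  }
  b1 <- best_for(read_copy(pos$copy1))
  b2 <- best_for(read_copy(pos$copy2))
  best <- if (b1$dist <= b2$dist) b1 else b2
  if (best$dist > 3L) stop("format information unreadable")
  list(ec_bits = best$cand$ec, mask = best$cand$mask)
}

# undo block interleaving and correct each block
qr_deinterleave <- function(cw, version) {
  tab <- qr_block_table_M[[version]]
  sizes <- rep(tab$g[, 2L], tab$g[, 1L])
  nb <- length(sizes)
  dc_total <- sum(sizes)
  data_part <- cw[seq_len(dc_total)]
  ec_part <- cw[(dc_total + 1L):length(cw)]
  blocks <- lapply(sizes, function(s) integer(0))
  i <- 1L
  for (round in seq_len(max(sizes))) {
    for (b in seq_len(nb)) {
      if (sizes[b] >= round) {
        blocks[[b]] <- c(blocks[[b]], data_part[i]); i <- i + 1L
      }
    }
  }
  ecs <- lapply(seq_len(nb), function(b) integer(0))
  i <- 1L
  for (round in seq_len(tab$ec)) {
    for (b in seq_len(nb)) {
      ecs[[b]] <- c(ecs[[b]], ec_part[i]); i <- i + 1L
    }
  }
  corrected <- mapply(function(d, e) rs_correct(c(d, e), tab$ec)[seq_along(d)],
                      blocks, ecs, SIMPLIFY = FALSE)
  unlist(corrected, use.names = FALSE)
}

qr_parse_bitstream <- function(data_cw, version) {
  bits <- unlist(lapply(data_cw, function(x) {
    as.integer(bitwAnd(bitwShiftR(x, 7:0), 1L))
  }), use.names = FALSE)
  take <- function(k) {
    v <- sum(bits[seq_len(k)] * 2L^((k - 1L):0))
    bits <<- bits[-seq_len(k)]
    v
  }
  mode <- take(4L)
  if (mode != 4L) stop("unsupported QR mode indicator: ", mode)
  cci <- if (version <= 9L) 8L else 16L
  count <- take(cci)
  if (8L * count > length(bits)) stop("corrupt QR bitstream: short payload")
  bytes <- vapply(seq_len(count), function(i) take(8L), numeric(1))
  txt <- rawToChar(as.raw(bytes))
  Encoding(txt) <- "UTF-8"
  txt
}

# --- Reed-Solomon error correction -----------------------------------

# evaluate polynomial (highest degree first) at x in GF(256)
gf_poly_eval <- function(p, x) {
  y <- 0L
  for (coef in p) y <- bitwXor(gf_mul(y, x), coef)
  y
}

# evaluate a low-degree-first polynomial at x in GF(256)
gf_poly_eval_low <- function(p, x) {
  y <- 0L
  xp <- 1L
  for (coef in p) {
    y <- bitwXor(y, gf_mul(coef, xp))
    xp <- gf_mul(xp, x)
  }
  y
}

# XOR two low-degree-first polynomials, padding to equal length
gf_poly_add_low <- function(p, q) {
  len <- max(length(p), length(q))
  bitwXor(c(p, integer(len - length(p))), c(q, integer(len - length(q))))
}

# correct a received codeword block (data + EC) of a Reed-Solomon code
# with n_ec check symbols: errors-only Berlekamp-Massey; error
# magnitudes from the syndrome linear system by Gaussian elimination
# over GF(256). Up to floor(n_ec/2) byte errors are corrected.
rs_correct <- function(received, n_ec) {
  synd <- vapply(0:(n_ec - 1L),
                 function(i) gf_poly_eval(received, gf_pow(i)),
                 integer(1))
  if (all(synd == 0L)) return(received)
  # Berlekamp-Massey; C is the error locator, low-degree first
  C <- 1L; B <- 1L
  L <- 0L; m <- 1L; b <- 1L
  for (step in 0:(n_ec - 1L)) {
    d <- synd[step + 1L]
    if (L > 0L) {
      for (i in seq_len(min(L, step))) {
        d <- bitwXor(d, gf_mul(C[i + 1L], synd[step - i + 1L]))
      }
    }
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= step) {
      Told <- C
      coef <- gf_mul(d, gf_inv(b))
      C <- gf_poly_add_low(C, gf_mul(coef, c(integer(m), B)))
      L <- step + 1L - L
      B <- Told
      b <- d
      m <- 1L
    } else {
      coef <- gf_mul(d, gf_inv(b))
      C <- gf_poly_add_low(C, gf_mul(coef, c(integer(m), B)))
      m <- m + 1L
    }
  }
  while (length(C) > 1L && C[length(C)] == 0L) C <- C[-length(C)]
  nerr <- length(C) - 1L
  if (nerr == 0L || nerr > n_ec %/% 2L) {
    stop("too many errors to correct in QR block")
  }
  # zeros of the locator mark error-term degrees d: C(alpha^-d) = 0
  nn <- length(received)
  err_deg <- Filter(function(d) gf_poly_eval_low(C, gf_pow(-d)) == 0L,
                    0:(nn - 1L))
  if (length(err_deg) != nerr) stop("Reed-Solomon correction failed")
  # solve S_j = sum_k e_k * alpha^(j * d_k) for the magnitudes e_k
  A <- outer(0:(nerr - 1L), err_deg,
             function(j, d) gf_pow(j * d))
  e <- gf_solve(A, synd[seq_len(nerr)])
  idx <- nn - err_deg  # degree d sits at 1-based index nn - d
  received[idx] <- bitwXor(received[idx], e)
  synd2 <- vapply(0:(n_ec - 1L),
                  function(i) gf_poly_eval(received, gf_pow(i)),
                  integer(1))
  if (any(synd2 != 0L)) stop("Reed-Solomon correction failed")
  received
}

# Gaussian elimination over GF(256): solve A x = y
gf_solve <- function(A, y) {
  n <- nrow(A)
  M <- cbind(A, y)
  for (col in seq_len(n)) {
    piv <- which(M[col:n, col] != 0L)[1L]
    if (is.na(piv)) stop("Reed-Solomon correction failed")
    piv <- piv + col - 1L
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    M[col, ] <- gf_mul(M[col, ], gf_inv(M[col, col]))
    for (r in seq_len(n)) {
      if (r != col && M[r, col] != 0L) {
        M[r, ] <- bitwXor(M[r, ], gf_mul(M[r, col], M[col, ]))
      }
    }
  }
  as.integer(M[, n + 1L])
}
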