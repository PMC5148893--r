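# QR model-2 constants for error-correction level M, versions 1-20.
#
# Block structure per version: EC codewords per block, then
# (number of blocks, data codewords per block) for group 1 and the
# optional group 2. Internal consistency with symbol geometry (total
# codewords derived from the module count) is asserted by the test
# suite, so a transcription slip here cannot pass silently.

qr_block_table_M <- list(
  list(ec = 10L, g = rbind(c(1L, 16L))),
  list(ec = 16L, g = rbind(c(1L, 28L))),
  list(ec = 26L, g = rbind(c(1L, 44L))),
  list(ec = 18L, g = rbind(c(2L, 32L))),
  list(ec = 24L, g = rbind(c(2L, 43L))),
  list(ec = 16L, g = rbind(c(4L, 27L))),
  list(ec = 18L, g = rbind(c(4L, 31L))),
  list(ec = 22L, g = rbind(c(2L, 38L), c(2L, 39L))),
  list(ec = 22L, g = rbind(c(3L, 36L), c(2L, 37L))),
  list(ec = 26L, g = rbind(c(4L, 43L), c(1L, 44L))),
  list(ec = 30L, g = rbind(c(1L, 50L), c(4L, 51L))),
  list(ec = 22L, g = rbind(c(6L, 36L), c(2L, 37L))),
  list(ec = 22L, g = rbind(c(8L, 37L), c(1L, 38L))),
  list(ec = 24L, g = rbind(c(4L, 40L), c(5L, 41L))),
  list(ec = 24L, g = rbind(c(5L, 41L), c(5L, 42L))),
  list(ec = 28L, g = rbind(c(7L, 45L), c(3L, 46L))),
  list(ec = 28L, g = rbind(c(10L, 46L), c(1L, 47L))),
  list(ec = 26L, g = rbind(c(9L, 43L), c(4L, 44L))),
  list(ec = 26L, g = rbind(c(3L, 44L), c(11L, 45L))),
  list(ec = 26L, g = rbind(c(3L, 41L), c(13L, 42L)))
)

QR_MAX_VERSION <- length(qr_block_table_M)

qr_size <- function(version) 17L + 4L * version

# data codeword capacity at level M
qr_data_codewords <- function(version) {
  b <- qr_block_table_M[[version]]
  sum(b$g[, 1L] * b$g[, 2L])
}

# alignment pattern centre coordinates (1-based), standard even-spacing
# rule (exact for versions < 32; we support up to 20)
qr_alignment_centres <- function(version) {
  if (version == 1L) return(integer())
  n <- qr_size(version)
  count <- version %/% 7L + 2L
  last <- n - 7L
  step <- 2L * as.integer(ceiling((last - 6L) / (2L * (count - 1L))))
  centres <- c(6L, last - step * rev(seq_len(count - 2L)), last)
  centres + 1L
}

# --- GF(256) arithmetic, primitive polynomial x^8+x^4+x^3+x^2+1 (0x11D)

gf_tables <- local({
  exp <- integer(512L)
  log <- integer(256L)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 285L)
  }
  exp[256:510] <- exp[1:255]
  list(exp = exp, log = log)
})

gf_mul <- function(a, b) {
  out <- integer(length(a) * 0L + max(length(a), length(b)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- gf_tables$exp[gf_tables$log[a[nz] + 1L] +
                             gf_tables$log[b[nz] + 1L] + 1L]
  out
}

gf_inv <- function(a) {
  if (any(a == 0L)) stop("division by zero in GF(256)")
  gf_tables$exp[255L - gf_tables$log[a + 1L] + 1L]
}

gf_pow <- function(exponent) gf_tables$exp[(exponent %% 255L) + 1L]

# polynomial product over GF(256); coefficients highest degree first
gf_poly_mul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    out[i:(i + length(q) - 1L)] <- bitwXor(out[i:(i + length(q) - 1L)],
                                           gf_mul(p[i], q))
  }
  out
}

# Reed-Solomon generator polynomial for n EC codewords
rs_generator <- function(n) {
  g <- 1L
  for (i in 0:(n - 1L)) g <- gf_poly_mul(g, c(1L, gf_pow(i)))
  g
}

# RS systematic encoding: returns the n EC codewords for a data block
rs_encode <- function(data, n_ec) {
  gen <- rs_generator(n_ec)[-1L]  # monic; drop leading 1
  rem <- integer(n_ec)
  for (d in data) {
    factor <- bitwXor(d, rem[1L])
    rem <- c(rem[-1L], 0L)
    if (factor != 0L) rem <- bitwXor(rem, gf_mul(factor, gen))
  }
  rem
}
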