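#' Trim gap-rich columns from an alignment
#'
#' Removes every column whose gap fraction exceeds \code{max_gap_frac}.
#' The default 0 drops any column containing a gap, yielding the
#' equal-length, gap-free alignment the PSSM stage expects. The returned
#' alignment's \code{col_map} maps surviving columns back to original
#' 1-based columns so downstream sites can be reported in original
#' coordinates.
#'
#' @param a a \code{barcode_alignment}.
#' @param max_gap_frac maximum tolerated gap fraction per column, in
#'   \code{[0, 1]}.
#' @return a trimmed \code{barcode_alignment}.
#' @export
trim_gap_columns <- function(a, max_gap_frac = 0) {
  stopifnot(inherits(a, "barcode_alignment"),
            max_gap_frac >= 0, max_gap_frac <= 1)
  m <- aln_matrix(a)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_frac
  if (!any(keep)) stop("gap trimming removed every column")
  r <- a$records
  r$seq <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  barcode_alignment(r, col_map = a$col_map[keep])
}

#' Position frequency matrix of an alignment
#'
#' Counts the occurrence of each nucleotide at each column. Gaps and N
#' contribute no count, so column sums can fall below N where gaps
#' remain.
#'
#' @param a a \code{barcode_alignment}.
#' @return an object of class \code{pssm} with fields \code{counts}
#'   (4 x c integer matrix, rows A,C,G,T), \code{probs} (NULL until
#'   [compute_ppm()]), \code{N} and \code{c}.
#' @export
compute_pfm <- function(a) {
  stopifnot(inherits(a, "barcode_alignment"))
  m <- aln_matrix(a)
  counts <- vapply(BASES,
                   function(b) colSums(m == b),
                   numeric(a$c))
  counts <- t(matrix(counts, nrow = a$c, ncol = 4L,
                     dimnames = list(NULL, BASES)))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, probs = NULL, N = a$N, c = a$c),
            class = "pssm")
}

#' Position probability matrix from a frequency matrix
#'
#' \code{probs[k, j] = counts[k, j] / N}: the relative frequency of
#' nucleotide k at column j. On gap-free columns each column sums to 1;
#' residual gaps leave visible probability mass below 1 (no
#' renormalization).
#'
#' @param pfm a \code{pssm} with counts filled (from [compute_pfm()]).
#' @return the same \code{pssm} with \code{probs} filled.
#' @export
compute_ppm <- function(pfm) {
  stopifnot(inherits(pfm, "pssm"), !is.null(pfm$counts))
  if (pfm$N <= 0L) stop("N must be positive")
  pfm$probs <- pfm$counts / pfm$N
  pfm
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm: %d columns from %d sequences (%s filled)\n",
              x$c, x$N,
              if (is.null(x$probs)) "counts" else "counts+probs"))
  invisible(x)
}

#' Export a PSSM as TSV
#'
#' Writes \code{<prefix>.pfm.tsv} and, when probabilities are filled,
#' \code{<prefix>.ppm.tsv}; rows A,C,G,T, one column per alignment
#' position.
#'
#' @param x a \code{pssm}.
#' @param prefix output path prefix.
#' @export
write_pssm <- function(x, prefix) {
  utils::write.table(x$counts, paste0(prefix, ".pfm.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  if (!is.null(x$probs)) {
    utils::write.table(x$probs, paste0(prefix, ".ppm.tsv"),
                       sep = "\t", quote = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}

#' Majority-rule consensus sequence
#'
#' Per column, the most frequent base among A,C,G,T; ties are broken by
#' the fixed order A < C < G < T and recorded in \code{tie_columns}.
#' Gaps are never emitted: an all-gap column is an error (trim first).
#'
#' @param a a \code{barcode_alignment}.
#' @param group optional group label carried on the result.
#' @return list of class \code{consensus_seq}: \code{group}, \code{seq},
#'   \code{tie_columns} (1-based, in current alignment coordinates).
#' @export
consensus <- function(a, group = "") {
  pfm <- compute_pfm(a)
  cs <- pfm$counts
  tot <- colSums(cs)
  if (any(tot == 0L)) {
    stop("all-gap column(s) at ", paste(which(tot == 0L), collapse = ", "),
         "; trim gap columns first")
  }
  top <- apply(cs, 2L, max)
  idx <- apply(cs, 2L, which.max)  # which.max takes the first -> A<C<G<T
  ties <- which(colSums(cs == rep(top, each = 4L)) > 1L)
  structure(list(group = group,
                 seq = paste(BASES[idx], collapse = ""),
                 tie_columns = as.integer(ties)),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("consensus_seq%s: %d bp, %d tied column(s)\n",
              if (nzchar(x$group)) paste0(" [", x$group, "]") else "",
              nchar(x$seq), length(x$tie_columns)))
  invisible(x)
}
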