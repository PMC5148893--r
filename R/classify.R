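#' Search one signature against query sequences
#'
#' Forward-strand regex search; the leftmost occurrence is reported and
#' a query counts at most once however many times the signature occurs.
#' Query \code{N}s never match a literal (literals are pure A/C/G/T) but
#' may fall inside an inter-pattern run.
#'
#' @param sig a \code{barcode_signature}.
#' @param queries a \code{barcode_records} data frame of ungapped query
#'   sequences.
#' @param tolerance gap tolerance (see [signature_regex()]).
#' @param both_strands also search the reverse complement of each query
#'   (default FALSE: barcode amplicons are assumed canonically
#'   oriented).
#' @return data frame: query_id, length, matched (logical),
#'   match_start, match_end (1-based inclusive, NA when unmatched; for
#'   reverse-strand hits the positions refer to the reverse-complemented
#'   query), strand ("+" or "-").
#' @export
search_signature <- function(sig, queries, tolerance = 0L,
                             both_strands = FALSE) {
  rx <- signature_regex(sig$patterns$literal, sig$gaps, tolerance)
  n <- nrow(queries)
  out <- data.frame(query_id = queries$id,
                    length = nchar(queries$seq),
                    matched = logical(n),
                    match_start = rep(NA_integer_, n),
                    match_end = rep(NA_integer_, n),
                    strand = rep("+", n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  hit <- regexpr(rx, queries$seq, perl = TRUE)
  ok <- hit > 0L
  out$matched[ok] <- TRUE
  out$match_start[ok] <- as.integer(hit[ok])
  out$match_end[ok] <- as.integer(hit[ok]) +
    attr(hit, "match.length")[ok] - 1L
  if (both_strands && any(!ok)) {
    rc <- revcomp(queries$seq[!ok])
    hit2 <- regexpr(rx, rc, perl = TRUE)
    ok2 <- hit2 > 0L
    idx <- which(!ok)[ok2]
    out$matched[idx] <- TRUE
    out$match_start[idx] <- as.integer(hit2[ok2])
    out$match_end[idx] <- as.integer(hit2[ok2]) +
      attr(hit2, "match.length")[ok2] - 1L
    out$strand[idx] <- "-"
  }
  out
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    gsub("[^ACGTN]", "N", seqs))))
}

#' Classify queries against a set of species signatures
#'
#' Each query is tested against every signature. Exactly one match
#' assigns that species; zero matches leaves the query unidentified;
#' two or more set \code{ambiguous = TRUE} with all matching species
#' semicolon-joined in \code{signature_used}.
#'
#' @param sig_set list of \code{barcode_signature} with distinct
#'   species.
#' @param queries a \code{barcode_records} data frame.
#' @param tolerance,both_strands passed to [search_signature()].
#' @return data frame of class \code{classification_results}: query_id,
#'   length, matched_species (NA when unidentified), match_start,
#'   match_end, signature_used, ambiguous.
#' @export
classify_queries <- function(sig_set, queries, tolerance = 0L,
                             both_strands = FALSE) {
  sp <- vapply(sig_set, `[[`, character(1), "species")
  if (anyDuplicated(sp)) {
    stop("duplicate species among signatures: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "))
  }
  per_sig <- lapply(sig_set, search_signature, queries = queries,
                    tolerance = tolerance, both_strands = both_strands)
  n <- nrow(queries)
  out <- data.frame(query_id = queries$id,
                    length = nchar(queries$seq),
                    matched_species = rep(NA_character_, n),
                    match_start = rep(NA_integer_, n),
                    match_end = rep(NA_integer_, n),
                    signature_used = rep(NA_character_, n),
                    ambiguous = logical(n),
                    stringsAsFactors = FALSE)
  if (n == 0L) {
    class(out) <- c("classification_results", "data.frame")
    return(out)
  }
  matched <- vapply(per_sig, `[[`, logical(n), "matched")
  matched <- matrix(matched, nrow = n)
  for (q in seq_len(n)) {
    hits <- which(matched[q, ])
    if (length(hits) == 1L) {
      out$matched_species[q] <- sp[hits]
      out$signature_used[q] <- sp[hits]
      out$match_start[q] <- per_sig[[hits]]$match_start[q]
      out$match_end[q] <- per_sig[[hits]]$match_end[q]
    } else if (length(hits) >= 2L) {
      # ambiguous: no single species is assigned, so no positions either
      out$ambiguous[q] <- TRUE
      out$signature_used[q] <- paste(sp[hits], collapse = ";")
    }
  }
  class(out) <- c("classification_results", "data.frame")
  out
}

#' Summarize classification results
#'
#' @param results a \code{classification_results} data frame.
#' @return list: n_queries, n_identified (exactly one species),
#'   n_unidentified, n_ambiguous, per_species (named counts of
#'   unambiguous assignments).
#' @export
summarize_classification <- function(results) {
  ident <- !is.na(results$matched_species) & !results$ambiguous
  per <- table(results$matched_species[ident])
  list(n_queries = nrow(results),
       n_identified = sum(ident),
       n_unidentified = sum(is.na(results$matched_species) &
                              !results$ambiguous),
       n_ambiguous = sum(results$ambiguous),
       per_species = stats::setNames(as.integer(per), names(per)))
}
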