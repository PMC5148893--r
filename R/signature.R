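#' Assemble an ordered-pattern signature
#'
#' A signature is an ordered series of literal patterns separated by
#' exact base-pair distances in the target species' ungapped sequence.
#' Its regex form is \code{literal1.{g1}literal2.{g2}...}, where
#' \code{gi} is the number of bases strictly between consecutive
#' patterns.
#'
#' @param species binomial of the target species.
#' @param patterns a \code{signature_patterns} data frame
#'   ([build_patterns()]); must be non-overlapping.
#' @param exemplar_id id of the sequence the coordinates refer to.
#' @return list of class \code{barcode_signature}: \code{species},
#'   \code{exemplar_id}, \code{patterns}, \code{gaps}, \code{regex},
#'   \code{span} (start, end, length; 1-based inclusive).
#' @export
assemble_signature <- function(species, patterns, exemplar_id = "") {
  if (nrow(patterns) < 1L) stop("signature needs at least one pattern")
  if (is.unsorted(patterns$start)) {
    warning("patterns were not sorted by start; sorting")
    patterns <- patterns[order(patterns$start), , drop = FALSE]
  }
  n <- nrow(patterns)
  if (n > 1L && any(patterns$start[-1L] <= patterns$end[-n])) {
    stop("overlapping patterns")
  }
  gaps <- if (n > 1L) patterns$start[-1L] - patterns$end[-n] - 1L else integer()
  span <- list(start = patterns$start[1L], end = patterns$end[n])
  span$length <- span$end - span$start + 1L
  structure(list(species = species, exemplar_id = exemplar_id,
                 patterns = patterns, gaps = as.integer(gaps),
                 regex = signature_regex(patterns$literal, gaps),
                 span = span),
            class = "barcode_signature")
}

#' Regex string for literals and exact gaps
#'
#' @param literals character vector of patterns in order.
#' @param gaps integer vector of exact distances (length
#'   \code{length(literals) - 1}).
#' @param tolerance non-negative integer; when positive, each gap
#'   \code{d} is matched as \code{.{max(0, d - t), d + t}}.
#' @return the regex string.
#' @export
signature_regex <- function(literals, gaps, tolerance = 0L) {
  stopifnot(length(gaps) == length(literals) - 1L || length(literals) == 1L)
  if (length(literals) == 1L) return(literals)
  runs <- if (tolerance > 0L) {
    sprintf(".{%d,%d}", pmax(0L, gaps - tolerance), gaps + tolerance)
  } else {
    sprintf(".{%d}", gaps)
  }
  paste0(paste0(literals[-length(literals)], runs, collapse = ""),
         literals[length(literals)])
}

#' @export
print.barcode_signature <- function(x, ...) {
  cat(sprintf("barcode_signature for %s (exemplar %s)\n", x$species,
              if (nzchar(x$exemplar_id)) x$exemplar_id else "<none>"))
  cat(sprintf("  %d pattern(s), span %d-%d (%d bp)\n",
              nrow(x$patterns), x$span$start, x$span$end, x$span$length))
  cat("  ", x$regex, "\n", sep = "")
  invisible(x)
}

#' Serialize a signature to the two-line .sig text format
#'
#' Line 1: \code{#species=<binomial>\\t#exemplar=<id>\\t#span=<start>-<end>};
#' line 2: the regex (uppercase A/C/G/T literals and \code{.{d}} runs).
#' This string is byte-identical to the QR payload body.
#'
#' @param sig a \code{barcode_signature}.
#' @param path optional file to write; when NULL the string is returned.
#' @return the serialized string, invisibly when written to file.
#' @export
write_sig <- function(sig, path = NULL) {
  txt <- paste0(sprintf("#species=%s\t#exemplar=%s\t#span=%d-%d",
                        sig$species, sig$exemplar_id,
                        sig$span$start, sig$span$end),
                "\n", sig$regex)
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "\n")
  invisible(txt)
}

#' Parse a .sig file or string back into a signature
#'
#' Inverse of [write_sig()]: pattern starts and ends are reconstructed
#' from the span start and the literal/gap lengths, so
#' \code{read_sig(write_sig(sig))} reproduces the signature.
#'
#' @param x path to a .sig file, or the two-line signature string
#'   itself.
#' @return a \code{barcode_signature}.
#' @export
read_sig <- function(x) {
  lines <- if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n")[[1]]
  } else if (length(x) == 1L && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    x
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) != 2L || !startsWith(lines[1L], "#species=")) {
    stop("not a signature: expected '#species=' header plus regex line")
  }
  fields <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  get <- function(key) {
    hit <- fields[startsWith(fields, paste0("#", key, "="))]
    if (length(hit) != 1L) stop("missing #", key, " in signature header")
    sub(paste0("^#", key, "="), "", hit)
  }
  span <- as.integer(strsplit(get("span"), "-", fixed = TRUE)[[1]])
  parsed <- parse_signature_regex(lines[2L])
  starts <- span[1L] + c(0L, cumsum(nchar(parsed$literals[-length(parsed$literals)]) +
                                      parsed$gaps))
  pat <- data.frame(start = starts,
                    end = starts + nchar(parsed$literals) - 1L)
  pat$literal <- parsed$literals
  pat$sites_covered <- I(rep(list(integer()), nrow(pat)))
  class(pat) <- c("signature_patterns", "data.frame")
  sig <- assemble_signature(get("species"), pat, get("exemplar"))
  if (sig$span$end != span[2L]) {
    stop("signature span header inconsistent with patterns")
  }
  sig
}

# split "LIT.{d}LIT..." into literals and exact gap lengths
parse_signature_regex <- function(regex) {
  if (!grepl("^[ACGT]+(\\.\\{[0-9]+\\}[ACGT]+)*$", regex)) {
    stop("malformed signature regex: ", regex)
  }
  literals <- strsplit(regex, "\\.\\{[0-9]+\\}")[[1]]
  gaps <- as.integer(regmatches(regex,
                                gregexpr("(?<=\\.\\{)[0-9]+(?=\\})", regex,
                                         perl = TRUE))[[1]])
  list(literals = literals, gaps = gaps)
}

#' Assign the A-D performance category from an F-measure
#'
#' Categories bin F into A = [0.75, 1], B = [0.50, 0.75),
#' C = [0.25, 0.50), D = [0, 0.25) (closed on the left).
#'
#' @param f F-measure in \code{[0, 1]} (vectorized).
#' @return character vector of categories.
#' @export
categorize_f <- function(f) {
  if (any(f < 0 | f > 1)) stop("F-measure must lie in [0, 1]")
  ifelse(f >= 0.75, "A", ifelse(f >= 0.5, "B", ifelse(f >= 0.25, "C", "D")))
}

#' Evaluate a signature against target and other sequences
#'
#' TP = target sequences matched, FN = target sequences unmatched,
#' FP = other-species sequences matched (a sequence counts at most
#' once). Recall = TP/(TP+FN); precision = TP/(TP+FP), 0 by convention
#' when TP+FP = 0; F is the balanced F1.
#'
#' @param sig a \code{barcode_signature}.
#' @param target_seqs character vector of ungapped target-species
#'   sequences.
#' @param other_seqs character vector of ungapped other-species
#'   sequences.
#' @param tolerance gap tolerance passed to [signature_regex()].
#' @return list of class \code{signature_evaluation}: TP, FP, FN,
#'   recall, precision, f_measure, category.
#' @export
evaluate_signature <- function(sig, target_seqs, other_seqs, tolerance = 0L) {
  rx <- signature_regex(sig$patterns$literal, sig$gaps, tolerance)
  tp <- sum(grepl(rx, target_seqs, perl = TRUE))
  fn <- length(target_seqs) - tp
  fp <- sum(grepl(rx, other_seqs, perl = TRUE))
  evaluation_report(tp, fp, fn)
}

#' Build an evaluation report from raw counts
#' @param tp,fp,fn true positives, false positives, false negatives.
#' @return a \code{signature_evaluation} list (see
#'   [evaluate_signature()]).
#' @export
evaluation_report <- function(tp, fp, fn) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(TP = tp, FP = fp, FN = fn, recall = recall,
                 precision = precision, f_measure = f,
                 category = categorize_f(f)),
            class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  cat(sprintf(
    "TP=%d FP=%d FN=%d | recall %.3f precision %.3f F %.3f (category %s)\n",
    x$TP, x$FP, x$FN, x$recall, x$precision, x$f_measure, x$category))
  invisible(x)
}

#' Greedy false-positive refinement of a signature
#'
#' While the signature still matches other-species sequences and unused
#' discriminating sites remain, add the site (expanded to a flanked
#' pattern on the exemplar and merged into the pattern series) that
#' maximally reduces FP without reducing TP. Stops at FP = 0 or when no
#' remaining site helps. FP never increases and TP never decreases
#' across steps.
#'
#' @param sig a \code{barcode_signature} built on \code{aligned_target}.
#' @param target_seqs,other_seqs ungapped sequence sets as in
#'   [evaluate_signature()].
#' @param site_pool integer vector of candidate alignment columns not
#'   yet used by the signature.
#' @param aligned_target the exemplar's aligned sequence.
#' @param flank window half-width for new patterns.
#' @param tolerance gap tolerance for evaluation.
#' @return list: \code{signature} (refined), \code{evaluation}, and
#'   \code{trajectory}, the list of (signature, evaluation) pairs after
#'   each accepted addition (starting state included).
#' @export
refine_signature <- function(sig, target_seqs, other_seqs, site_pool,
                             aligned_target, flank = 6L, tolerance = 0L) {
  used <- sort(unique(unlist(sig$patterns$sites_covered)))
  pool <- setdiff(sort(unique(as.integer(site_pool))), used)
  ev <- evaluate_signature(sig, target_seqs, other_seqs, tolerance)
  trajectory <- list(list(signature = sig, evaluation = ev))
  while (ev$FP > 0L && length(pool) > 0L) {
    best <- NULL
    for (col in pool) {
      pat <- tryCatch(
        suppressWarnings(build_patterns(c(used, col), aligned_target, flank)),
        error = function(e) NULL)
      if (is.null(pat) || nrow(pat) == 0L) next
      cand <- assemble_signature(sig$species, pat, sig$exemplar_id)
      cev <- evaluate_signature(cand, target_seqs, other_seqs, tolerance)
      if (cev$TP < ev$TP) next
      if (is.null(best) || cev$FP < best$ev$FP) {
        best <- list(col = col, sig = cand, ev = cev)
      }
    }
    if (is.null(best) || best$ev$FP >= ev$FP) break
    used <- sort(c(used, best$col))
    pool <- setdiff(pool, best$col)
    sig <- best$sig
    ev <- best$ev
    trajectory[[length(trajectory) + 1L]] <-
      list(signature = sig, evaluation = ev)
  }
  list(signature = sig, evaluation = ev, trajectory = trajectory)
}

#' Select the candidate signature for a species
#'
#' Argmax by F-measure; ties broken by higher recall, then fewer
#' patterns, then shorter span, then lexicographically smaller regex,
#' giving a deterministic total order.
#'
#' @param evaluated list of \code{list(signature =, evaluation =)}
#'   pairs.
#' @return the selected element (signature + evaluation).
#' @export
select_candidate <- function(evaluated) {
  if (length(evaluated) == 0L) stop("no candidate signatures to select from")
  key <- vapply(evaluated, function(e) {
    s <- e$signature; v <- e$evaluation
    sprintf("%012.9f|%012.9f|%06d|%09d|%s",
            1 - v$f_measure, 1 - v$recall, nrow(s$patterns),
            s$span$length, s$regex)
  }, character(1))
  evaluated[[order(key)[1L]]]
}

#' Explain why a sequence misses a signature
#'
#' Walks the pattern series left to right in the given ungapped
#' sequence: reports the first pattern that cannot be found, or the
#' first inter-pattern gap whose observed distance differs from the
#' signature's exact distance (greedy leftmost anchoring).
#'
#' @param sig a \code{barcode_signature}.
#' @param seq one ungapped sequence string.
#' @return NULL when the sequence matches; otherwise a list with
#'   \code{reason} ("pattern_missing" or "gap_mismatch"),
#'   \code{pattern_index}, and for gap mismatches \code{expected} and
#'   \code{observed} distances.
#' @export
diagnose_miss <- function(sig, seq) {
  if (grepl(sig$regex, seq, perl = TRUE)) return(NULL)
  lits <- sig$patterns$literal
  at <- regexpr(lits[1L], seq, fixed = TRUE)
  if (at < 0L) {
    return(list(reason = "pattern_missing", pattern_index = 1L))
  }
  pos <- as.integer(at)
  for (i in seq_along(lits)[-1L]) {
    prev_end <- pos + nchar(lits[i - 1L]) - 1L
    nxt <- regexpr(lits[i], substring(seq, prev_end + 1L), fixed = TRUE)
    if (nxt < 0L) {
      return(list(reason = "pattern_missing", pattern_index = i))
    }
    observed <- as.integer(nxt) - 1L
    if (observed != sig$gaps[i - 1L]) {
      return(list(reason = "gap_mismatch", pattern_index = i,
                  expected = sig$gaps[i - 1L], observed = observed))
    }
    pos <- prev_end + as.integer(nxt)
  }
  list(reason = "pattern_missing", pattern_index = NA_integer_)
}
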