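BASES <- c("A", "C", "G", "T")
SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a set of labelled barcode records
#'
#' A barcode record set is a plain \code{data.frame} with columns
#' \code{id}, \code{genus}, \code{species}, \code{locus} and \code{seq},
#' one row per sequence. \code{species} is the full binomial
#' ("Genus epithet"); its first token must equal \code{genus} when both
#' are set.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of DNA sequences over \code{A,C,G,T,N,-}
#'   (upper-cased on construction).
#' @param genus,species,locus taxonomy labels; empty strings mean
#'   "unlabelled".
#' @return a \code{data.frame} of class \code{barcode_records}.
#' @export
barcode_records <- function(id, seq, genus = "", species = "", locus = "other") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seq))) stop("sequences must be non-empty")
  bad <- grepl(sprintf("[^%s]", paste(SEQ_ALPHABET, collapse = "")), seq)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N,-}: ",
         paste(id[bad], collapse = ", "))
  }
  df <- data.frame(id = id,
                   genus = rep_len(as.character(genus), length(id)),
                   species = rep_len(as.character(species), length(id)),
                   locus = rep_len(as.character(locus), length(id)),
                   seq = seq,
                   stringsAsFactors = FALSE)
  mismatch <- nzchar(df$genus) & nzchar(df$species) &
    vapply(strsplit(df$species, " +"), `[`, "", 1L) != df$genus
  if (any(mismatch)) {
    stop("species binomial does not start with the genus for: ",
         paste(df$id[mismatch], collapse = ", "))
  }
  class(df) <- c("barcode_records", "data.frame")
  df
}

#' Read barcode sequences from FASTA
#'
#' Headers are parsed by the GenBank convention: token 1 is the accession
#' (record id), tokens 2--3 are genus and specific epithet. An explicit
#' taxonomy TSV (\code{id<TAB>genus<TAB>species<TAB>locus}, no header)
#' always overrides header parsing.
#'
#' @param path FASTA file.
#' @param taxonomy optional taxonomy TSV path.
#' @return a \code{barcode_records} data frame.
#' @export
read_fasta <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(barcode_records(character(), character())[0, , drop = FALSE])
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA at line ", first, ": expected '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genus <- species <- character(length(ids))
  toks <- strsplit(headers, "[ \t]+")
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) >= 3L && grepl("^[A-Za-z]+$", tk[2L]) &&
        grepl("^[a-z-]+$", tk[3L])) {
      genus[i] <- tk[2L]
      species[i] <- paste(tk[2L], tk[3L])
    }
  }
  rec <- barcode_records(ids, seqs, genus = genus, species = species)
  if (!is.null(taxonomy)) {
    tax <- utils::read.delim(taxonomy, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("id", "genus", "species", "locus"),
                             colClasses = "character")
    hit <- match(rec$id, tax$id)
    miss <- is.na(hit)
    if (any(miss)) {
      warning("no taxonomy entry for: ", paste(rec$id[miss], collapse = ", "),
              " (kept unlabelled)")
    }
    rec$genus[!miss] <- tax$genus[hit[!miss]]
    rec$species[!miss] <- tax$species[hit[!miss]]
    rec$locus[!miss] <- tax$locus[hit[!miss]]
    rec <- barcode_records(rec$id, rec$seq, rec$genus, rec$species, rec$locus)
  }
  rec
}

#' Write barcode records to FASTA
#'
#' Headers are \code{id genus epithet} when the record is labelled,
#' bare \code{id} otherwise.
#'
#' @param records a \code{barcode_records} data frame.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(nzchar(records$species),
                paste(records$id, records$species), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write a taxonomy TSV for a record set
#' @param records a \code{barcode_records} data frame.
#' @param path output path.
#' @export
write_taxonomy <- function(records, path) {
  utils::write.table(records[, c("id", "genus", "species", "locus")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Apply the dataset-inclusion filters
#'
#' Keeps records of the requested locus, drops every sequence containing
#' an ambiguous base \code{N}, then drops species left with fewer than
#' two sequences. N-removal happens before the per-species count, so a
#' species reduced to one clean sequence is excluded.
#'
#' @param records a \code{barcode_records} data frame with species and
#'   locus labels.
#' @param locus locus to keep ("matK", "rbcL", ...); \code{NULL} keeps all.
#' @param min_per_species minimum surviving sequences per species
#'   (default 2).
#' @return the filtered \code{barcode_records}, with an attribute
#'   \code{filter_counts} reporting removals per rule.
#' @export
filter_dataset <- function(records, locus = NULL, min_per_species = 2L) {
  n0 <- nrow(records)
  kept <- records
  if (!is.null(locus)) kept <- kept[kept$locus == locus, , drop = FALSE]
  n_locus <- n0 - nrow(kept)
  has_n <- grepl("N", kept$seq, fixed = TRUE)
  kept <- kept[!has_n, , drop = FALSE]
  n_ambig <- sum(has_n)
  tab <- table(kept$species[nzchar(kept$species)])
  ok_sp <- names(tab)[tab >= min_per_species]
  small <- !(kept$species %in% ok_sp)
  kept <- kept[!small, , drop = FALSE]
  n_small <- sum(small)
  if (nrow(kept) == 0L) warning("no records survive the dataset filters")
  attr(kept, "filter_counts") <- c(wrong_locus = n_locus,
                                   contains_N = n_ambig,
                                   species_below_min = n_small)
  kept
}

#' Construct an alignment of barcode records
#'
#' @param records a \code{barcode_records} data frame whose sequences all
#'   have equal length.
#' @param col_map optional integer map from current columns to original
#'   1-based alignment columns (used after gap trimming); defaults to
#'   \code{1:c}.
#' @return list of class \code{barcode_alignment} with fields
#'   \code{records}, \code{c} (columns), \code{N} (rows), \code{col_map}.
#' @export
barcode_alignment <- function(records, col_map = NULL) {
  if (nrow(records) < 1L) stop("alignment needs at least one sequence")
  len <- nchar(records$seq)
  if (length(unique(len)) != 1L) {
    bad <- records$id[len != stats::median(len)]
    stop("ragged alignment; offending id(s): ", paste(bad, collapse = ", "))
  }
  c_ <- len[1L]
  if (c_ < 1L) stop("alignment length must be >= 1")
  if (is.null(col_map)) col_map <- seq_len(c_)
  stopifnot(length(col_map) == c_)
  structure(list(records = records, c = c_, N = nrow(records),
                 col_map = as.integer(col_map)),
            class = "barcode_alignment")
}

#' Read an aligned FASTA file
#' @param path aligned FASTA; all entries must have equal length.
#' @param taxonomy optional taxonomy TSV (see [read_fasta()]).
#' @return a \code{barcode_alignment}.
#' @export
read_alignment <- function(path, taxonomy = NULL) {
  barcode_alignment(read_fasta(path, taxonomy))
}

#' Write an alignment to FASTA
#' @param a a \code{barcode_alignment}.
#' @param path output path.
#' @export
write_alignment <- function(a, path) {
  write_fasta(a$records, path)
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("barcode_alignment: %d sequences x %d columns\n", x$N, x$c))
  sp <- unique(x$records$species[nzchar(x$records$species)])
  if (length(sp)) cat(sprintf("  %d species, %d genera\n", length(sp),
                              length(unique(x$records$genus[nzchar(x$records$genus)]))))
  invisible(x)
}

# character matrix view of an alignment (rows = sequences)
aln_matrix <- function(a) {
  m <- matrix(unlist(strsplit(a$records$seq, ""), use.names = FALSE),
              nrow = a$N, ncol = a$c, byrow = TRUE)
  rownames(m) <- a$records$id
  m
}

# drop gaps from a sequence string
degap <- function(seq) gsub("-", "", seq, fixed = TRUE)

#' Export the ungapped sequences of an alignment
#'
#' Gap characters are removed per record; this is the form consumed by
#' signature search and classification.
#'
#' @param a a \code{barcode_alignment}.
#' @return a \code{barcode_records} data frame with ungapped sequences.
#' @export
degap_records <- function(a) {
  r <- a$records
  r$seq <- degap(r$seq)
  r
}
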