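#' Discriminating sites among genus consensus sequences
#'
#' Every alignment column where at least two genus consensuses carry
#' different bases becomes a genus-level discriminating site with its
#' per-genus allele map.
#'
#' @param consensuses list of \code{consensus_seq} objects of equal
#'   length, one per genus, each with a non-empty \code{group}.
#' @return data frame of class \code{discriminating_sites}: columns
#'   \code{column} (1-based), \code{level}, and one allele column per
#'   group, plus attribute \code{groups}.
#' @export
genus_level_sites <- function(consensuses) {
  if (length(consensuses) < 2L) {
    stop("need at least two genus consensuses to compare")
  }
  lens <- vapply(consensuses, function(x) nchar(x$seq), integer(1))
  if (length(unique(lens)) != 1L) stop("consensuses must have equal length")
  groups <- vapply(consensuses, function(x) x$group, character(1))
  if (any(!nzchar(groups)) || anyDuplicated(groups)) {
    stop("each consensus needs a unique non-empty group label")
  }
  m <- do.call(rbind, lapply(consensuses, function(x) strsplit(x$seq, "")[[1]]))
  rownames(m) <- groups
  var_cols <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  new_sites(var_cols, "genus", m)
}

#' Discriminating sites among species within one genus
#'
#' Columns where the within-species consensus bases differ between
#' species are species-level discriminating sites. A column that is
#' polymorphic inside any species (including gap/base mixtures) is not
#' species-diagnostic and is excluded, as are columns fixed to a gap in
#' any species.
#'
#' @param genus_alignment a \code{barcode_alignment} whose records all
#'   belong to one genus.
#' @param labels named character vector id -> species; defaults to the
#'   alignment's own species labels.
#' @return a \code{discriminating_sites} data frame (see
#'   [genus_level_sites()]).
#' @export
species_level_sites <- function(genus_alignment, labels = NULL) {
  a <- genus_alignment
  if (is.null(labels)) {
    labels <- stats::setNames(a$records$species, a$records$id)
  }
  sp <- labels[a$records$id]
  if (any(is.na(sp) | !nzchar(sp))) stop("every record needs a species label")
  species <- sort(unique(sp))
  if (length(species) < 2L) {
    stop("need at least two species within the genus")
  }
  m <- aln_matrix(a)
  fixed <- vapply(species, function(s) {
    rows <- m[sp == s, , drop = FALSE]
    apply(rows, 2L, function(col) {
      u <- unique(col)
      if (length(u) == 1L) u else NA_character_
    })
  }, character(a$c))
  fixed <- matrix(fixed, nrow = a$c, dimnames = list(NULL, species))
  usable <- apply(fixed, 1L, function(row) {
    all(!is.na(row)) && all(row %in% BASES) && length(unique(row)) > 1L
  })
  new_sites(which(usable), "species", t(fixed))
}

# shared constructor: cols = site columns, allele matrix rows = groups
new_sites <- function(cols, level, allele_matrix) {
  groups <- rownames(allele_matrix)
  df <- data.frame(column = as.integer(cols),
                   level = rep(level, length(cols)),
                   stringsAsFactors = FALSE)
  for (g in groups) df[[g]] <- allele_matrix[g, cols]
  attr(df, "groups") <- groups
  class(df) <- c("discriminating_sites", "data.frame")
  df
}

#' Combine genus- and species-level sites for one target species
#'
#' Concatenates both site sets and deduplicates by column (a column
#' found at both levels is kept once, at species level).
#'
#' @param genus_sites,species_sites \code{discriminating_sites} (either
#'   may be NULL or empty).
#' @return integer vector of unique site columns, sorted.
#' @export
combine_sites <- function(genus_sites, species_sites) {
  cols <- c(if (!is.null(species_sites)) species_sites$column,
            if (!is.null(genus_sites)) genus_sites$column)
  sort(unique(as.integer(cols)))
}

# Map alignment columns to ungapped positions of one aligned sequence.
# Returns NA where the sequence has a gap at that column.
column_to_position <- function(aligned_seq, columns) {
  chars <- strsplit(aligned_seq, "")[[1]]
  cum <- cumsum(chars != "-")
  pos <- cum[columns]
  pos[chars[columns] == "-"] <- NA_integer_
  as.integer(pos)
}

#' Expand discriminating sites into literal patterns on a target
#' sequence
#'
#' Each site column is mapped to the ungapped coordinate of the target
#' (exemplar) sequence and expanded to a window of \code{flank}
#' conserved bases on each side, clipped at the sequence ends.
#' Overlapping or adjacent windows merge into a single pattern. Literals
#' are read off the ungapped target, so every pattern matches its
#' exemplar at its stated start by construction. Sites falling on a gap
#' in the target are skipped with a warning.
#'
#' @param site_columns integer vector of alignment columns (in the
#'   coordinates of \code{aligned_target}).
#' @param aligned_target the target's aligned sequence (string).
#' @param flank non-negative integer window half-width (default 6; a
#'   single site yields a \code{2*flank + 1}-mer away from the ends).
#' @return data frame of class \code{signature_patterns}: \code{start},
#'   \code{end} (1-based, ungapped target coordinates), \code{literal},
#'   and list-column \code{sites_covered} (alignment columns).
#' @export
build_patterns <- function(site_columns, aligned_target, flank = 6L) {
  stopifnot(flank >= 0L)
  site_columns <- sort(unique(as.integer(site_columns)))
  target <- degap(aligned_target)
  len <- nchar(target)
  pos <- column_to_position(aligned_target, site_columns)
  if (anyNA(pos)) {
    warning("site(s) at alignment column(s) ",
            paste(site_columns[is.na(pos)], collapse = ", "),
            " fall on a gap in the target; skipped")
    site_columns <- site_columns[!is.na(pos)]
    pos <- pos[!is.na(pos)]
  }
  if (length(pos) == 0L) {
    return(empty_patterns())
  }
  win <- data.frame(start = pmax(1L, pos - flank),
                    end = pmin(len, pos + flank))
  # merge overlapping or adjacent windows, carrying covered sites
  merged <- list()
  cur <- list(start = win$start[1L], end = win$end[1L],
              sites = site_columns[1L])
  for (i in seq_along(pos)[-1L]) {
    if (win$start[i] <= cur$end + 1L) {
      cur$end <- max(cur$end, win$end[i])
      cur$sites <- c(cur$sites, site_columns[i])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- list(start = win$start[i], end = win$end[i],
                  sites = site_columns[i])
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- data.frame(
    start = vapply(merged, `[[`, integer(1), "start"),
    end = vapply(merged, `[[`, integer(1), "end"))
  out$literal <- substring(target, out$start, out$end)
  out$sites_covered <- I(lapply(merged, `[[`, "sites"))
  class(out) <- c("signature_patterns", "data.frame")
  out
}

empty_patterns <- function() {
  out <- data.frame(start = integer(), end = integer(),
                    literal = character())
  out$sites_covered <- I(list())
  class(out) <- c("signature_patterns", "data.frame")
  out
}
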