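#' Per-sequence probability vectors under a PSSM
#'
#' For sequence i, \code{v[j]} is the alignment-wide probability of the
#' base sequence i carries at column j (\code{probs[base, j]}); gap and
#' N positions contribute 0. These vectors are the representation whose
#' pairwise Euclidean distances drive species discrimination.
#'
#' @param a a \code{barcode_alignment}.
#' @param m a \code{pssm} with probabilities, computed from \code{a}.
#' @return numeric matrix, one row per sequence (rownames = ids), c
#'   columns.
#' @export
probability_vectors <- function(a, m) {
  stopifnot(inherits(a, "barcode_alignment"), inherits(m, "pssm"))
  if (is.null(m$probs)) stop("pssm has no probabilities; run compute_ppm()")
  if (m$c != a$c) stop("pssm has ", m$c, " columns but alignment has ", a$c)
  chars <- aln_matrix(a)
  v <- matrix(0, nrow = a$N, ncol = a$c, dimnames = list(a$records$id, NULL))
  for (k in seq_along(BASES)) {
    hit <- chars == BASES[k]
    v[hit] <- rep(m$probs[k, ], each = a$N)[hit]
  }
  v
}

#' Pairwise Euclidean distance matrix
#'
#' @param vs numeric matrix of probability vectors (rows = sequences),
#'   as returned by [probability_vectors()].
#' @return a symmetric matrix with zero diagonal, dimnames = ids.
#' @export
pairwise_distances <- function(vs) {
  if (is.null(dim(vs))) stop("vs must be a matrix with one row per sequence")
  d <- as.matrix(stats::dist(vs, method = "euclidean"))
  dimnames(d) <- list(rownames(vs), rownames(vs))
  d
}

#' Score species discrimination from a distance matrix
#'
#' A species pair is discriminated when its smallest between-species
#' distance strictly exceeds the largest within-species distance of both
#' species and is nonzero (the barcoding-gap rule). A species with no
#' intra-species pair contributes \code{max_intra = 0}. A species counts
#' as discriminated overall according to \code{pair_policy}: in all of
#' its pairs (default, strictest), in at least one, or in a majority.
#'
#' @param dm distance matrix from [pairwise_distances()].
#' @param labels named character vector mapping sequence id to species.
#' @param pair_policy one of \code{"all"}, \code{"any"},
#'   \code{"majority"}.
#' @return list of class \code{discrimination_report}: \code{pair_table}
#'   (data frame with min_inter, max_intra of each species,
#'   discriminated), \code{species_table}, \code{n_discriminated},
#'   \code{n_not}.
#' @export
discriminate_species <- function(dm, labels,
                                 pair_policy = c("all", "any", "majority")) {
  pair_policy <- match.arg(pair_policy)
  ids <- rownames(dm)
  if (is.null(ids)) stop("distance matrix must carry ids as dimnames")
  sp <- labels[ids]
  if (any(is.na(sp) | !nzchar(sp))) {
    stop("unlabelled id(s): ", paste(ids[is.na(sp) | !nzchar(sp)],
                                     collapse = ", "))
  }
  species <- sort(unique(sp))
  max_intra <- vapply(species, function(s) {
    i <- which(sp == s)
    if (length(i) < 2L) 0 else max(dm[i, i])
  }, numeric(1))
  pairs <- utils::combn(species, 2L)
  pt <- data.frame(species_a = pairs[1L, ], species_b = pairs[2L, ],
                   min_inter = NA_real_, max_intra_a = NA_real_,
                   max_intra_b = NA_real_, discriminated = NA,
                   stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pt))) {
    ia <- which(sp == pt$species_a[r]); ib <- which(sp == pt$species_b[r])
    mi <- min(dm[ia, ib])
    ma <- max_intra[[pt$species_a[r]]]; mb <- max_intra[[pt$species_b[r]]]
    pt$min_inter[r] <- mi
    pt$max_intra_a[r] <- ma
    pt$max_intra_b[r] <- mb
    pt$discriminated[r] <- (mi > max(ma, mb)) && (mi > 0)
  }
  ok <- vapply(species, function(s) {
    rows <- pt$discriminated[pt$species_a == s | pt$species_b == s]
    switch(pair_policy,
           all = all(rows),
           any = any(rows),
           majority = mean(rows) > 0.5)
  }, logical(1))
  st <- data.frame(species = species, max_intra = unname(max_intra),
                   discriminated_overall = unname(ok),
                   stringsAsFactors = FALSE)
  structure(list(pair_table = pt, species_table = st,
                 n_discriminated = sum(ok), n_not = sum(!ok),
                 pair_policy = pair_policy),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf(
    "discrimination_report: %d of %d species discriminated (policy '%s')\n",
    x$n_discriminated, x$n_discriminated + x$n_not, x$pair_policy))
  invisible(x)
}

#' Compare per-pair divergence between two loci
#'
#' Two-sided Wilcoxon signed-rank test on paired per-species-pair
#' divergences from two loci (same pairs, same order). All-zero
#' differences return p = 1 with a warning.
#'
#' @param div_a,div_b equal-length numeric vectors of paired
#'   divergences.
#' @return list with \code{statistic} and \code{p}.
#' @export
compare_loci <- function(div_a, div_b) {
  if (length(div_a) != length(div_b)) {
    stop("paired divergence lists must have equal length")
  }
  d <- div_a - div_b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1 by convention")
    return(list(statistic = 0, p = 1))
  }
  wt <- stats::wilcox.test(div_a, div_b, paired = TRUE, exact = NULL)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
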