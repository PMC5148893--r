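sub_alignment <- function(a, idx) {
  barcode_alignment(a$records[idx, , drop = FALSE], col_map = a$col_map)
}

#' Fit species signatures to a labelled barcode alignment
#'
#' Runs the full discrimination-and-signature workflow: gap-column
#' trimming, PFM/PPM computation, per-sequence probability vectors and
#' their Euclidean distance matrix, the barcoding-gap discrimination
#' rule, two-level (genus, then species-within-genus) discriminating
#' site discovery, pattern assembly on each species' exemplar sequence,
#' greedy false-positive refinement, candidate selection, and
#' evaluation (recall/precision/F, categories A-D) of every species'
#' signature against all other sequences.
#'
#' Site columns are discovered on the trimmed alignment and mapped back
#' to original alignment columns, so pattern coordinates refer to each
#' exemplar's raw ungapped sequence.
#'
#' @param alignment a \code{barcode_alignment} with genus and species
#'   labels (see [read_alignment()]).
#' @param flank conserved bases kept on each side of a discriminating
#'   site (default 6, giving 13-mers around isolated sites).
#' @param max_gap_frac gap-column trim threshold (default 0: drop any
#'   column containing a gap).
#' @param pair_policy species-level discrimination tally rule (see
#'   [discriminate_species()]).
#' @param tolerance inter-pattern distance tolerance used in matching
#'   (default 0: exact distances).
#' @param min_per_species dataset filter threshold (see
#'   [filter_dataset()]).
#' @return an object of class \code{barcode_sig_fit} with components
#'   \code{signatures} (named list of \code{barcode_signature}),
#'   \code{evaluations} (one row per species with signature metrics),
#'   \code{discrimination}, \code{pssm}, \code{distances},
#'   \code{genus_sites}, \code{species_sites}, \code{failures},
#'   \code{recall_misses}, \code{params}. Methods: \code{print},
#'   \code{summary}, \code{predict} (classify query sequences),
#'   \code{plot}.
#' @export
barcode_signatures <- function(alignment, flank = 6L, max_gap_frac = 0,
                               pair_policy = "all", tolerance = 0L,
                               min_per_species = 2L) {
  stopifnot(inherits(alignment, "barcode_alignment"))
  cl <- match.call()
  rec <- alignment$records
  if (any(!nzchar(rec$species)) || any(!nzchar(rec$genus))) {
    stop("every record needs genus and species labels")
  }
  trimmed <- trim_gap_columns(alignment, max_gap_frac)
  pssm <- compute_ppm(compute_pfm(trimmed))
  vecs <- probability_vectors(trimmed, pssm)
  dm <- pairwise_distances(vecs)
  labels <- stats::setNames(rec$species, rec$id)
  discrim <- discriminate_species(dm, labels, pair_policy = pair_policy)

  genera <- sort(unique(rec$genus))
  genus_idx <- lapply(genera, function(g) which(trimmed$records$genus == g))
  names(genus_idx) <- genera
  consensuses <- lapply(genera, function(g) {
    consensus(sub_alignment(trimmed, genus_idx[[g]]), group = g)
  })
  genus_sites <- if (length(genera) >= 2L) {
    genus_level_sites(consensuses)
  } else NULL
  species_sites <- list()
  for (g in genera) {
    sub <- sub_alignment(trimmed, genus_idx[[g]])
    if (length(unique(sub$records$species)) >= 2L) {
      species_sites[[g]] <- species_level_sites(sub)
    }
  }

  ungapped <- degap_records(alignment)
  species <- sort(unique(rec$species))
  signatures <- list()
  evaluations <- list()
  failures <- list()
  recall_misses <- list()
  for (sp in species) {
    g <- rec$genus[rec$species == sp][1L]
    res <- fit_species_signature(
      sp, g, alignment, trimmed, genus_sites, species_sites[[g]],
      ungapped, flank, tolerance)
    if (!is.null(res$failure)) {
      failures[[sp]] <- res$failure
      next
    }
    signatures[[sp]] <- res$signature
    ev <- res$evaluation
    evaluations[[sp]] <- data.frame(
      species = sp, genus = g, exemplar = res$signature$exemplar_id,
      n_patterns = nrow(res$signature$patterns),
      span_start = res$signature$span$start,
      span_end = res$signature$span$end,
      span_length = res$signature$span$length,
      TP = ev$TP, FP = ev$FP, FN = ev$FN,
      recall = ev$recall, precision = ev$precision,
      f_measure = ev$f_measure, category = ev$category,
      stringsAsFactors = FALSE)
    if (!is.null(res$misses)) recall_misses[[sp]] <- res$misses
  }
  evaluations <- if (length(evaluations)) {
    do.call(rbind, c(evaluations, make.row.names = FALSE))
  } else NULL
  structure(list(call = cl,
                 alignment = alignment, trimmed = trimmed,
                 pssm = pssm, distances = dm,
                 discrimination = discrim,
                 genus_sites = genus_sites,
                 species_sites = species_sites,
                 signatures = signatures,
                 evaluations = evaluations,
                 failures = failures,
                 recall_misses = recall_misses,
                 params = list(flank = flank, max_gap_frac = max_gap_frac,
                               pair_policy = pair_policy,
                               tolerance = tolerance,
                               min_per_species = min_per_species)),
            class = "barcode_sig_fit")
}

# candidate generation + refinement + selection for one species
fit_species_signature <- function(sp, g, alignment, trimmed, genus_sites,
                                  sp_sites, ungapped, flank, tolerance) {
  rec <- alignment$records
  # genus-level columns where this genus' consensus allele differs
  # from at least one other genus
  g_cols <- integer()
  if (!is.null(genus_sites) && nrow(genus_sites)) {
    groups <- attr(genus_sites, "groups")
    others <- setdiff(groups, g)
    differs <- vapply(seq_len(nrow(genus_sites)), function(i) {
      any(genus_sites[[g]][i] != unlist(genus_sites[i, others]))
    }, logical(1))
    g_cols <- genus_sites$column[differs]
  }
  s_cols <- if (!is.null(sp_sites)) sp_sites$column else integer()
  all_cols <- sort(unique(c(g_cols, s_cols)))
  if (length(all_cols) == 0L) {
    return(list(failure = "no_discriminating_sites"))
  }
  exemplar_i <- which(rec$species == sp)[1L]
  aligned_target <- rec$seq[exemplar_i]
  to_orig <- function(cols) trimmed$col_map[cols]
  target_seqs <- ungapped$seq[ungapped$species == sp]
  other_seqs <- ungapped$seq[ungapped$species != sp]

  init_cols <- if (length(s_cols)) s_cols else all_cols
  init_pat <- suppressWarnings(
    build_patterns(to_orig(init_cols), aligned_target, flank))
  full_pat <- suppressWarnings(
    build_patterns(to_orig(all_cols), aligned_target, flank))
  if (nrow(full_pat) == 0L) {
    return(list(failure = "sites_on_exemplar_gaps"))
  }
  candidates <- list()
  if (nrow(init_pat) > 0L) {
    init_sig <- assemble_signature(sp, init_pat, rec$id[exemplar_i])
    refined <- refine_signature(init_sig, target_seqs, other_seqs,
                                site_pool = to_orig(all_cols),
                                aligned_target = aligned_target,
                                flank = flank, tolerance = tolerance)
    candidates <- refined$trajectory
  }
  full_sig <- assemble_signature(sp, full_pat, rec$id[exemplar_i])
  candidates[[length(candidates) + 1L]] <- list(
    signature = full_sig,
    evaluation = evaluate_signature(full_sig, target_seqs, other_seqs,
                                    tolerance))
  best <- select_candidate(candidates)
  misses <- NULL
  if (best$evaluation$FN > 0L) {
    miss_idx <- which(ungapped$species == sp &
                        !grepl(best$signature$regex, ungapped$seq,
                               perl = TRUE))
    misses <- lapply(stats::setNames(miss_idx, ungapped$id[miss_idx]),
                     function(i) diagnose_miss(best$signature,
                                               ungapped$seq[i]))
  }
  list(signature = best$signature, evaluation = best$evaluation,
       misses = misses)
}

#' @export
print.barcode_sig_fit <- function(x, ...) {
  cat("barcode signature fit\n")
  cat(sprintf("  alignment: %d sequences, %d columns (%d after trim)\n",
              x$alignment$N, x$alignment$c, x$trimmed$c))
  d <- x$discrimination
  cat(sprintf("  discrimination: %d of %d species (pair policy '%s')\n",
              d$n_discriminated, d$n_discriminated + d$n_not,
              x$params$pair_policy))
  cat(sprintf("  signatures: %d generated, %d failed\n",
              length(x$signatures), length(x$failures)))
  if (!is.null(x$evaluations)) {
    tab <- table(factor(x$evaluations$category, levels = c("A", "B", "C", "D")))
    cat(sprintf("  categories: A=%d B=%d C=%d D=%d\n",
                tab["A"], tab["B"], tab["C"], tab["D"]))
  }
  invisible(x)
}

#' @export
summary.barcode_sig_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.barcode_sig_fit")
}

#' @export
print.summary.barcode_sig_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$evaluations)) {
    cat("\nPer-species signature evaluation:\n")
    print(x$fit$evaluations[, c("species", "n_patterns", "span_length",
                                "TP", "FP", "FN", "recall", "precision",
                                "f_measure", "category")],
          row.names = FALSE, digits = 3)
  }
  if (length(x$fit$failures)) {
    cat("\nSpecies without a signature:\n")
    for (sp in names(x$fit$failures)) {
      cat(sprintf("  %s: %s\n", sp, x$fit$failures[[sp]]))
    }
  }
  invisible(x)
}

#' Classify query sequences with a fitted signature set
#'
#' @param object a \code{barcode_sig_fit}.
#' @param newdata a \code{barcode_records} data frame of ungapped
#'   queries, or a FASTA path.
#' @param summarize also return the summary counts.
#' @param tolerance,both_strands see [search_signature()]; tolerance
#'   defaults to the fit's own setting.
#' @param ... unused.
#' @return a \code{classification_results} data frame; when
#'   \code{summarize = TRUE}, a list with \code{results} and
#'   \code{summary}.
#' @export
predict.barcode_sig_fit <- function(object, newdata, summarize = FALSE,
                                    tolerance = NULL, both_strands = FALSE,
                                    ...) {
  if (is.character(newdata) && length(newdata) == 1L) {
    newdata <- read_fasta(newdata)
  }
  if (is.null(tolerance)) tolerance <- object$params$tolerance
  res <- classify_queries(unname(object$signatures), newdata,
                          tolerance = tolerance,
                          both_strands = both_strands)
  if (summarize) {
    list(results = res, summary = summarize_classification(res))
  } else {
    res
  }
}

#' @export
plot.barcode_sig_fit <- function(x, ...) {
  if (is.null(x$evaluations)) stop("no signatures to plot")
  tab <- table(factor(x$evaluations$category, levels = c("A", "B", "C", "D")))
  graphics::barplot(tab, xlab = "F-measure category",
                    ylab = "species", col = "grey40",
                    main = "Signature performance categories", ...)
  invisible(x)
}
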