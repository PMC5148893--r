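#' Run the end-to-end signature pipeline and write its artifacts
#'
#' Executes filter -> trim -> PSSM -> distances -> discrimination ->
#' site discovery -> signature assembly/refinement -> evaluation ->
#' signature and QR export, writing every stage's output to
#' \code{out_dir} in re-loadable form plus a machine-readable run
#' manifest (inputs, parameters, per-stage counts).
#'
#' @param alignment_path aligned FASTA of labelled barcode sequences.
#' @param out_dir output directory (created if absent).
#' @param taxonomy optional taxonomy TSV (see [read_fasta()]).
#' @param locus locus filter applied before fitting (NULL keeps all).
#' @param flank,max_gap_frac,pair_policy,tolerance,min_per_species
#'   passed to [barcode_signatures()].
#' @param qr also export each signature as a QR PNG.
#' @return the \code{barcode_sig_fit}, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(alignment_path, out_dir, taxonomy = NULL,
                         locus = NULL, flank = 6L, max_gap_frac = 0,
                         pair_policy = "all", tolerance = 0L,
                         min_per_species = 2L, qr = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  records <- stage("read", read_fasta(alignment_path, taxonomy))
  kept <- stage("filter", filter_dataset(records, locus = locus,
                                         min_per_species = min_per_species))
  if (nrow(kept) == 0L) stop("pipeline stage 'filter' removed every record")
  write_fasta(kept, file.path(out_dir, "filtered.fasta"))
  aln <- stage("align", barcode_alignment(kept))
  fit <- stage("fit", barcode_signatures(
    aln, flank = flank, max_gap_frac = max_gap_frac,
    pair_policy = pair_policy, tolerance = tolerance,
    min_per_species = min_per_species))

  write_pssm(fit$pssm, file.path(out_dir, "pssm"))
  utils::write.table(fit$distances, file.path(out_dir, "distances.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(fit$discrimination$pair_table,
                     file.path(out_dir, "discrimination_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$discrimination$species_table,
                     file.path(out_dir, "discrimination_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fit$evaluations)) {
    utils::write.table(fit$evaluations,
                       file.path(out_dir, "signature_evaluations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sig_dir <- file.path(out_dir, "signatures")
  dir.create(sig_dir, showWarnings = FALSE)
  for (sp in names(fit$signatures)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", sp)
    write_sig(fit$signatures[[sp]], file.path(sig_dir, paste0(slug, ".sig")))
    if (qr) {
      encode_qr(write_sig(fit$signatures[[sp]]),
                file.path(sig_dir, paste0(slug, ".png")))
    }
  }
  manifest <- list(
    input = basename(alignment_path),
    parameters = fit$params,
    counts = list(
      records_in = nrow(records),
      records_kept = nrow(kept),
      filter = as.list(attr(kept, "filter_counts")),
      columns = fit$alignment$c,
      columns_after_trim = fit$trimmed$c,
      species = length(unique(kept$species)),
      genera = length(unique(kept$genus)),
      species_discriminated = fit$discrimination$n_discriminated,
      signatures_generated = length(fit$signatures),
      signatures_failed = length(fit$failures),
      categories = as.list(table(factor(
        if (is.null(fit$evaluations)) character() else
          fit$evaluations$category, levels = c("A", "B", "C", "D"))))
    ))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}

#' Write a synthetic dataset fixture to disk
#'
#' Aligned FASTA + taxonomy TSV + truth JSON, the on-disk form of
#' [generate_barcodes()].
#'
#' @param data a \code{synth_data}.
#' @param out_dir output directory.
#' @return out_dir, invisibly.
#' @export
write_synth_fixture <- function(data, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(data$alignment, file.path(out_dir, "aligned.fasta"))
  write_taxonomy(data$alignment$records, file.path(out_dir, "taxonomy.tsv"))
  jsonlite::write_json(
    lapply(data$truth, function(t) {
      list(genus = t$genus, sites = t$sites,
           alleles = as.list(t$alleles))
    }),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
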