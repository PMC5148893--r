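#' Specification for a synthetic barcode dataset
#'
#' The generator emulates the structure of a multi-genus barcode
#' compilation: one conserved backbone per genus, species defined by a
#' small number of fixed diagnostic substitutions planted on the
#' backbone, two or more sequences per species, optional iid
#' sequencing noise and gap-coded indels. Defaults give 3 genera x 2
#' species x 3 sequences of 700 bp with 2 planted sites per species
#' and no noise.
#'
#' @param n_genera number of genera.
#' @param species_per_genus species per genus.
#' @param seqs_per_species sequences per species (>= 2, matching the
#'   dataset-inclusion filter).
#' @param seq_len alignment length in bp.
#' @param genus_divergence per-site substitution probability between
#'   genus backbones (default 0.05, a matK-like inter-genus scale).
#' @param planted_sites_per_species diagnostic substitutions per
#'   species.
#' @param noise_rate per-site per-sequence substitution error
#'   probability.
#' @param indel_rate per-site per-sequence probability of a gap-coded
#'   single-base deletion.
#' @param seed RNG seed; the output is fully reproducible from it.
#' @return list of class \code{synth_spec}.
#' @export
synth_spec <- function(n_genera = 3L, species_per_genus = 2L,
                       seqs_per_species = 3L, seq_len = 700L,
                       genus_divergence = 0.05,
                       planted_sites_per_species = 2L,
                       noise_rate = 0, indel_rate = 0, seed = 42L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L,
            seqs_per_species >= 2L, seq_len >= 1L,
            genus_divergence >= 0, genus_divergence <= 1,
            planted_sites_per_species >= 0L,
            noise_rate >= 0, noise_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  structure(as.list(environment()), class = "synth_spec")
}

mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Generate a labelled synthetic barcode dataset with planted structure
#'
#' Each genus gets a random backbone; backbones differ from the first
#' at approximately \code{genus_divergence * seq_len} sites. Each
#' species is its genus backbone plus its planted diagnostic
#' substitutions (fixed within the species, at positions unique within
#' the genus). Each sequence is the species template plus iid noise
#' and gap-coded deletions, so the output is a valid pre-aligned set.
#'
#' @param spec a [synth_spec()].
#' @return list of class \code{synth_data}: \code{alignment} (a
#'   \code{barcode_alignment}), \code{truth} (per-species planted site
#'   positions, alleles, backbone base and template sequence), and
#'   \code{spec}.
#' @export
generate_barcodes <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  margin <- 10L
  usable <- if (spec$seq_len > 2L * margin) {
    (margin + 1L):(spec$seq_len - margin)
  } else {
    seq_len(spec$seq_len)
  }
  n_sites_genus <- spec$species_per_genus * spec$planted_sites_per_species
  if (n_sites_genus > length(usable)) {
    stop("sequence too short for the requested planted sites")
  }
  backbone1 <- sample(BASES, spec$seq_len, replace = TRUE)
  ids <- genus <- species <- seqs <- character()
  truth <- list()
  for (g in seq_len(spec$n_genera)) {
    gname <- paste0("Genus", LETTERS[((g - 1L) %% 26L) + 1L],
                    if (g > 26L) g else "")
    backbone <- backbone1
    if (g > 1L) {
      flip <- stats::runif(spec$seq_len) < spec$genus_divergence
      backbone[flip] <- mutate_base(backbone[flip])
    }
    site_pool <- sample(usable, n_sites_genus)
    for (s in seq_len(spec$species_per_genus)) {
      epithet <- paste0("sp", letters[((s - 1L) %% 26L) + 1L],
                        if (s > 26L) s else "")
      sp_name <- paste(gname, epithet)
      take <- seq_len(spec$planted_sites_per_species) +
        (s - 1L) * spec$planted_sites_per_species
      sites <- sort(site_pool[take])
      template <- backbone
      alleles <- mutate_base(template[sites])
      template[sites] <- alleles
      for (r in seq_len(spec$seqs_per_species)) {
        seq_chars <- template
        if (spec$noise_rate > 0) {
          noisy <- stats::runif(spec$seq_len) < spec$noise_rate
          seq_chars[noisy] <- mutate_base(seq_chars[noisy])
        }
        if (spec$indel_rate > 0) {
          gaps <- stats::runif(spec$seq_len) < spec$indel_rate
          seq_chars[gaps] <- "-"
        }
        ids <- c(ids, sprintf("%s_%s_%d", gname, epithet, r))
        genus <- c(genus, gname)
        species <- c(species, sp_name)
        seqs <- c(seqs, paste(seq_chars, collapse = ""))
      }
      truth[[sp_name]] <- list(genus = gname, sites = sites,
                               alleles = stats::setNames(alleles,
                                                         as.character(sites)),
                               backbone_base = stats::setNames(
                                 backbone[sites], as.character(sites)),
                               template = paste(template, collapse = ""))
    }
  }
  rec <- barcode_records(ids, seqs, genus = genus, species = species,
                         locus = "matK")
  structure(list(alignment = barcode_alignment(rec), truth = truth,
                 spec = spec),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "synth_data: %d genera x %d species x %d seqs, %d bp (seed %d)\n",
    s$n_genera, s$species_per_genus, s$seqs_per_species, s$seq_len,
    s$seed))
  invisible(x)
}

#' Corrupt barcode records with truncations, Ns and indels
#'
#' A stress fixture for the failure modes of exact-distance
#' signatures: 3' truncation (partial sequence length), ambiguous
#' bases, and single-base insertions/deletions that shift
#' inter-pattern distances. Operates on ungapped sequences;
#' deterministic for a given seed.
#'
#' @param records a \code{barcode_records} data frame (ungapped).
#' @param extra_noise per-sequence corruption intensity in [0, 1]: the
#'   probability that each of the three corruption types hits a given
#'   sequence; N substitution also uses it as the per-site rate.
#' @param seed RNG seed.
#' @return corrupted \code{barcode_records}.
#' @export
corrupt_barcodes <- function(records, extra_noise, seed = 1L) {
  stopifnot(extra_noise >= 0, extra_noise <= 1)
  if (extra_noise == 0) return(records)
  set.seed(seed)
  out <- records
  # each sequence consumes a fixed set of random draws, so for a given
  # seed the corruption events at a lower rate are a subset of those at
  # a higher rate (common-random-numbers coupling across rate grids)
  for (i in seq_len(nrow(out))) {
    s <- strsplit(out$seq[i], "")[[1]]
    len0 <- length(s)
    u_indel <- stats::runif(1)
    u_type <- stats::runif(1)
    at <- 1L + as.integer(stats::runif(1) * (len0 - 2L))
    ins <- sample(BASES, 1L)
    u_trunc <- stats::runif(1)
    frac <- stats::runif(1, 0.3, 0.9)
    u_site <- stats::runif(len0 + 1L)  # +1 covers a possible insertion
    if (u_indel < extra_noise && len0 > 2L) {   # single indel
      if (u_type < 0.5) s <- s[-at] else s <- append(s, ins, after = at)
    }
    if (u_trunc < extra_noise) {                # 3' truncation
      s <- s[seq_len(max(1L, floor(length(s) * frac)))]
    }
    hit_n <- u_site[seq_along(s)] < extra_noise # ambiguous bases
    s[hit_n] <- "N"
    out$seq[i] <- paste(s, collapse = "")
  }
  out
}
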