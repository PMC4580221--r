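#' Genome specification for the synthetic di-tag generator
#'
#' Describes one species-like genome at the level the downstream analyses
#' need: chromosome lengths, the restriction fragment length distribution,
#' and a per-fragment-end GC model. No sequence is stored; fragment length
#' and GC heterogeneity are what the bias analyses consume.
#'
#' @param species_label Short label, e.g. `"mm"` or `"hs"`. Chromosome names
#'   are prefixed with it so that multi-species pools have unique chromosomes.
#' @param chromosome_lengths Numeric vector of chromosome lengths in bp
#'   (all > 0). Names optional; defaults to `chr1..chrN`.
#' @param mean_fragment_length Mean restriction fragment length in bp
#'   (>= 100). Fragment lengths are drawn as 100 + Exponential(mean - 100)
#'   so the mean is exact and no fragment is shorter than 100 bp.
#' @param gc_mean,gc_sd Mean and SD of the per-fragment-end GC fraction
#'   (Gaussian, clipped to \[0, 1\]).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(species_label, chromosome_lengths,
                        mean_fragment_length = 4000,
                        gc_mean = 0.45, gc_sd = 0.07) {
  stopifnot(is.character(species_label), length(species_label) == 1L,
            nzchar(species_label))
  chromosome_lengths <- as.numeric(chromosome_lengths)
  if (length(chromosome_lengths) == 0L || any(!is.finite(chromosome_lengths)) ||
      any(chromosome_lengths <= 0))
    stop("chromosome_lengths must all be positive")
  if (!is.numeric(mean_fragment_length) || mean_fragment_length < 100)
    stop("mean_fragment_length must be >= 100 bp")
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  structure(list(
    species_label = species_label,
    chromosome_lengths = chromosome_lengths,
    mean_fragment_length = as.numeric(mean_fragment_length),
    gc_mean = gc_mean, gc_sd = gc_sd
  ), class = "genome_spec")
}

#' Ground-truth contact model for the synthetic generator
#'
#' Parameterizes the intra-complex contact structure (distance decay, planted
#' TADs, planted A/B compartments, trans background) and the contamination
#' process (random-ligation fraction, optional injected fragment-end biases).
#'
#' Intra-complex cis contacts decay with genomic distance as
#' `s^(-decay_exponent)`; pairs falling inside one planted TAD are boosted
#' `tad_enrichment`-fold, and pairs whose planted compartment labels agree
#' are boosted `checkerboard_enrichment`-fold. A fraction
#' `trans_background_weight` of intra-complex contacts is trans-chromosomal.
#' With probability `random_ligation_fraction` a di-tag is instead spurious:
#' both fragment ends drawn uniformly from the pooled fragment-end library of
#' all cells of all species.
#'
#' @param decay_exponent Positive cis distance-decay exponent (default 1,
#'   the canonical Hi-C powerlaw regime).
#' @param min_distance Minimum cis contact distance in bp.
#' @param tad_boundaries Named list (by chromosome) of internal TAD boundary
#'   positions in bp, or `NULL` for no planted TADs.
#' @param tad_enrichment Fold enrichment (>= 1) of intra-TAD pairs.
#' @param compartment_binsize Bin size in bp at which compartment truth is
#'   laid out (default 1 Mb).
#' @param compartment_block_bins Number of consecutive bins sharing a
#'   compartment label in the alternating A/B block layout.
#' @param checkerboard_enrichment Fold enrichment (>= 1) of same-compartment
#'   cis pairs.
#' @param trans_background_weight Probability in \[0, 1\] that an
#'   intra-complex contact is trans-chromosomal.
#' @param random_ligation_fraction Fraction `f_random` in \[0, 1\] of di-tags
#'   arising from spurious cross-complex ligation.
#' @param bias_injection Optional list with 20x20 positive matrices
#'   `length` and/or `gc`: true acceptance biases over fragment-end feature
#'   quantile bins (see [fend_features()]). Candidate di-tags are accepted
#'   with probability proportional to the product of the matrix entries of
#'   their two ends.
#' @return An object of class `contact_model`.
#' @export
contact_model <- function(decay_exponent = 1,
                          min_distance = 1000,
                          tad_boundaries = NULL,
                          tad_enrichment = 1,
                          compartment_binsize = 1e6,
                          compartment_block_bins = 5,
                          checkerboard_enrichment = 1,
                          trans_background_weight = 0.12,
                          random_ligation_fraction = 0,
                          bias_injection = NULL) {
  stopifnot(decay_exponent > 0,
            tad_enrichment >= 1, checkerboard_enrichment >= 1,
            trans_background_weight >= 0, trans_background_weight <= 1,
            random_ligation_fraction >= 0, random_ligation_fraction <= 1)
  if (!is.null(bias_injection)) {
    for (nm in names(bias_injection)) {
      b <- bias_injection[[nm]]
      stopifnot(nm %in% c("length", "gc"), is.matrix(b),
                nrow(b) == ncol(b), all(b > 0))
    }
  }
  structure(list(
    decay_exponent = decay_exponent, min_distance = min_distance,
    tad_boundaries = tad_boundaries, tad_enrichment = tad_enrichment,
    compartment_binsize = compartment_binsize,
    compartment_block_bins = compartment_block_bins,
    checkerboard_enrichment = checkerboard_enrichment,
    trans_background_weight = trans_background_weight,
    random_ligation_fraction = random_ligation_fraction,
    bias_injection = bias_injection
  ), class = "contact_model")
}

#' Species mixture specification
#'
#' @param cells Named integer vector of cell counts per species; names must
#'   match the `species_label` of the corresponding genome spec. All >= 0,
#'   at least one > 0.
#' @param specs List of [genome_spec()] objects, one per species.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(cells, specs) {
  if (inherits(specs, "genome_spec")) specs <- list(specs)
  labs <- vapply(specs, function(s) s$species_label, character(1))
  names(specs) <- labs
  cells <- as.integer(cells)
  if (is.null(names(cells))) names(cells) <- labs
  stopifnot(all(names(cells) %in% labs), all(cells >= 0))
  if (sum(cells) == 0L) stop("at least one species must have > 0 cells")
  structure(list(cells = cells[labs], specs = specs), class = "mixture_spec")
}

#' Planted compartment truth labels
#'
#' Lays out alternating A/B blocks over fixed-size bins on each chromosome:
#' `block_bins` consecutive bins get label A, the next `block_bins` get B,
#' and so on.
#'
#' @param chromosome_lengths Named numeric vector of chromosome lengths (bp).
#' @param binsize Bin size in bp.
#' @param block_bins Bins per alternating block.
#' @return `data.table` with columns chrom, start, end, label ("A"/"B").
#' @export
compartment_truth <- function(chromosome_lengths, binsize = 1e6,
                              block_bins = 5) {
  out <- lapply(names(chromosome_lengths), function(ch) {
    L <- chromosome_lengths[[ch]]
    starts <- seq(0, L - 1, by = binsize)
    idx <- seq_along(starts) - 1L
    data.table::data.table(
      chrom = ch, start = starts, end = pmin(starts + binsize, L),
      label = ifelse((idx %/% block_bins) %% 2L == 0L, "A", "B"))
  })
  data.table::rbindlist(out)
}

# deterministic sub-stream seeds derived from one master seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% 2147483629)
}
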