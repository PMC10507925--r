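#' Parameters for the synthetic-data generators
#'
#' Bundles every knob the seeded generators understand. The synthetic genome is
#' a single linear coordinate space of `genome_length` bases partitioned into
#' eight named pseudo-chromosomes (`pc1`..`pc8`), which avoids shipping any
#' reference sequence. All generator outputs are deterministic functions of
#' `seed` and the remaining parameters: the same `GeneratorParams` always
#' yields byte-identical tables.
#'
#' @param seed integer RNG seed.
#' @param n_small_variants number of small-variant records to emit.
#' @param n_sv_per_caller number of SV/CNV records per caller.
#' @param n_genes number of genes on the synthetic panel.
#' @param n_exclusion_regions number of exclusionary (blacklist) intervals.
#' @param fraction_common proportion of variants given a population allele
#'   frequency above the filtering thresholds (1\% for small variants, 5\% for
#'   SV/CNV).
#' @param fraction_clinvar_lp_p proportion of small variants annotated as
#'   ClinVar likely-pathogenic/pathogenic.
#' @param vaf_noise_sd standard deviation of heterozygous variant allele
#'   fraction noise around 0.5.
#' @param genome_length total length of the synthetic genome in bp.
#' @return an object of class `generator_params` (a validated list).
#' @examples
#' p <- generator_params(seed = 1, n_small_variants = 10)
#' @export
generator_params <- function(seed = 1L,
                             n_small_variants = 1000L,
                             n_sv_per_caller = 200L,
                             n_genes = 120L,
                             n_exclusion_regions = 50L,
                             fraction_common = 0.3,
                             fraction_clinvar_lp_p = 0.05,
                             vaf_noise_sd = 0.05,
                             genome_length = 8e6) {
  counts <- c(n_small_variants = n_small_variants,
              n_sv_per_caller = n_sv_per_caller,
              n_genes = n_genes,
              n_exclusion_regions = n_exclusion_regions)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_data("all generator counts must be non-negative integers")
  }
  assert_prop(fraction_common, "fraction_common")
  assert_prop(fraction_clinvar_lp_p, "fraction_clinvar_lp_p")
  if (vaf_noise_sd < 0) stop_data("vaf_noise_sd must be >= 0")
  if (genome_length < 1e4) stop_data("genome_length must be at least 10 kb")
  structure(
    list(seed = as.integer(seed),
         n_small_variants = as.integer(n_small_variants),
         n_sv_per_caller = as.integer(n_sv_per_caller),
         n_genes = as.integer(n_genes),
         n_exclusion_regions = as.integer(n_exclusion_regions),
         fraction_common = fraction_common,
         fraction_clinvar_lp_p = fraction_clinvar_lp_p,
         vaf_noise_sd = vaf_noise_sd,
         genome_length = genome_length),
    class = "generator_params"
  )
}

#' Layout of the synthetic genome
#'
#' Partitions the linear coordinate space into eight pseudo-chromosomes with
#' fixed relative sizes. Coordinates within each pseudo-chromosome are 0-based.
#'
#' @param params a [generator_params()] object.
#' @return tibble with columns `chrom`, `length`.
#' @export
genome_layout <- function(params) {
  rel <- c(0.20, 0.17, 0.15, 0.13, 0.11, 0.10, 0.08, 0.06)
  len <- floor(params$genome_length * rel)
  tibble::tibble(chrom = paste0("pc", seq_along(rel)), length = len)
}

#' Synthetic cancer gene panel
#'
#' Deterministic panel of `n_genes` symbols. The first seven are named after
#' well-known cancer predisposition genes (APC, ATM, MUTYH, MSH6, PALB2,
#' BRCA2, BAP1) so that the cohort fixture can tally findings by familiar
#' symbols; the remainder are `G008`, `G009`, ....
#'
#' @param n_genes number of panel genes (>= 1).
#' @return character vector of gene symbols.
#' @export
synthetic_panel <- function(n_genes = 120L) {
  named <- c("APC", "ATM", "MUTYH", "MSH6", "PALB2", "BRCA2", "BAP1")
  if (n_genes <= length(named)) return(named[seq_len(n_genes)])
  c(named, sprintf("G%03d", seq.int(length(named) + 1L, n_genes)))
}

#' Default gnomAD-style subpopulation resource
#'
#' Seven subpopulation labels with an eligibility flag representing the
#' "n >= 2000 individuals" condition for the allele-frequency filter. The flag
#' is carried as data rather than recomputed from sample sizes.
#'
#' @return tibble with columns `pop`, `eligible`.
#' @export
default_subpops <- function() {
  tibble::tibble(
    pop = c("afr", "amr", "asj", "eas", "fin", "nfe", "sas"),
    eligible = TRUE
  )
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
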