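#' ClinVar rescue for a small variant
#'
#' A variant present in ClinVar with a likely-pathogenic or pathogenic
#' classification bypasses the population-frequency filters. The rescue does
#' not waive the VAF filter, which is a call-quality criterion applied
#' unconditionally.
#'
#' @param clinvar_status character vector with values in
#'   `none`, `B`, `LB`, `VUS`, `LP`, `P`.
#' @return logical vector.
#' @export
clinvar_rescue <- function(clinvar_status) {
  clinvar_status %in% c("LP", "P")
}

#' Population-frequency gate for one small variant
#'
#' Drops a variant whose allele frequency exceeds 1\% (strictly) in any
#' eligible gnomAD subpopulation — exome- and genome-derived frequencies
#' considered separately — or in the study cohort or the in-house germline
#' dataset, unless it is ClinVar-rescued (see [clinvar_rescue()]). A frequency
#' of exactly 1\% passes. Frequencies missing from a resource are treated as
#' zero (absence implies rarity).
#'
#' @param v one small-variant record (one-row data frame or list) carrying
#'   `gnex_<pop>` / `gnge_<pop>` columns plus `cohort_af`, `inhouse_af` and
#'   `clinvar_status`.
#' @param eligible_subpops character vector of subpopulation labels that meet
#'   the sample-size condition (n >= 2000 individuals).
#' @param max_af frequency threshold (default 0.01, strict).
#' @return list with `keep` (logical) and `reasons` (ordered character vector
#'   of rule identifiers; non-empty whenever `keep` is `FALSE`).
#' @export
passes_frequency_gate <- function(v, eligible_subpops, max_af = 0.01) {
  hits <- character(0)
  check <- function(af, reason) {
    if (is.null(af) || length(af) == 0 || is.na(af)) return(invisible(NULL))
    if (af < 0 || af > 1) stop_data("allele frequency outside [0, 1]: %s", reason)
    if (af > max_af) hits <<- c(hits, reason)
    invisible(NULL)
  }
  for (p in eligible_subpops) check(v[[paste0("gnex_", p)]],
                                    paste0("AF_GNOMAD_EXOME_", toupper(p)))
  for (p in eligible_subpops) check(v[[paste0("gnge_", p)]],
                                    paste0("AF_GNOMAD_GENOME_", toupper(p)))
  check(v[["cohort_af"]], "COHORT_AF")
  check(v[["inhouse_af"]], "INHOUSE_AF")
  if (length(hits) == 0) {
    list(keep = TRUE, reasons = character(0))
  } else if (clinvar_rescue(v[["clinvar_status"]])) {
    list(keep = TRUE, reasons = "CLINVAR_RESCUE")
  } else {
    list(keep = FALSE, reasons = hits)
  }
}

#' Variant-allele-fraction gate for one small variant
#'
#' SNVs (and dinucleotide substitutions) are dropped when their VAF is below
#' 30\%; indels when below 20\%. Boundary values are retained. The gate is a
#' call-quality criterion and is never waived by ClinVar rescue.
#'
#' @param v one small-variant record with `variant_class` (`snv`, `dnv`,
#'   `indel`) and `vaf`.
#' @return list with `keep` and `reasons` as in [passes_frequency_gate()].
#' @export
passes_vaf_gate <- function(v) {
  if (is.na(v[["vaf"]])) stop_data("missing VAF for variant %s",
                                   v[["id"]] %||% "<unknown>")
  cls <- v[["variant_class"]]
  if (cls %in% c("snv", "dnv")) {
    if (v[["vaf"]] < 0.30) return(list(keep = FALSE, reasons = "VAF_SNV"))
  } else if (cls == "indel") {
    if (v[["vaf"]] < 0.20) return(list(keep = FALSE, reasons = "VAF_INDEL"))
  } else {
    stop_data("unknown variant_class '%s'", cls)
  }
  list(keep = TRUE, reasons = character(0))
}

#' Run the small-variant prioritisation cascade
#'
#' Applies, per variant and in order: restriction to the virtual gene panel,
#' the population-frequency gate with ClinVar rescue, and the VAF gate. Emits
#' the kept table together with an audit table holding one row per input
#' variant with the final decision and the ordered rule identifiers that
#' fired.
#'
#' @param variants small-variant table (as from [gen_small_variants()] or
#'   [read_small_variants_tsv()]).
#' @param subpops subpopulation resource (`pop`, `eligible` columns).
#' @param panel character vector of panel gene symbols (non-empty).
#' @return list with `kept` (subset of `variants`) and `audit`
#'   (tibble `id`, `keep`, `reasons`).
#' @export
run_small_variant_cascade <- function(variants, subpops = default_subpops(),
                                      panel) {
  if (length(panel) == 0) stop_data("panel must be non-empty")
  assert_cols(variants, c("id", "gene", "variant_class", "vaf",
                          "clinvar_status", "cohort_af", "inhouse_af"),
              "small-variant table")
  bad_cls <- setdiff(unique(variants$variant_class), c("snv", "dnv", "indel"))
  if (length(bad_cls) > 0) {
    stop_data("unknown variant_class '%s'", bad_cls[1])
  }
  eligible <- subpops$pop[subpops$eligible]
  n <- nrow(variants)
  keep <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    r <- character(0)
    ok <- TRUE
    if (!(v$gene %in% panel)) {
      r <- c(r, "PANEL")
      ok <- FALSE
    }
    fq <- passes_frequency_gate(v, eligible)
    r <- c(r, fq$reasons)
    ok <- ok && fq$keep
    vg <- passes_vaf_gate(v)
    r <- c(r, vg$reasons)
    ok <- ok && vg$keep
    keep[i] <- ok
    reasons[i] <- collapse_reasons(r)
  }
  list(
    kept = variants[keep, , drop = FALSE],
    audit = tibble::tibble(id = variants$id, keep = keep, reasons = reasons)
  )
}
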