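#' Percentage with half-up rounding to one decimal
#'
#' The rounding convention used for every reported cohort percentage:
#' `100 * numerator / denominator`, rounded half-up to one decimal place.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return numeric percentage.
#' @examples
#' pct(10, 195)  # 5.1
#' @export
pct <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop_data("pct: denominator must be > 0")
  round_half_up(100 * numerator / denominator, 1)
}

count_by <- function(x) {
  tb <- table(x)
  stats::setNames(as.integer(tb), names(tb))
}

#' Cohort-level tallies and percentages
#'
#' Computes every study-level summary from the case, report and
#' classified-variant tables: counts and percentages of cases with causal and
#' secondary LP/P findings, risk-management changes and uninformative LP/P
#' findings; returned-variant counts by ACMG class, VUS tier, variant type
#' and gene; report multiplicities; eligibility-criterion, sex, age-group,
#' prior-testing and recruitment-site counts; and the multi-phenotype
#' fraction among reported cases. Only variants with a `return` verdict are
#' counted as returned.
#'
#' @param cases index-case tibble (see [gen_cohort_fixture()]).
#' @param variants classified-variant tibble with verdicts applied.
#' @param reports case reports; defaults to [build_reports()] on the inputs.
#' @return object of class `cohort_summary`: a named list of counts and
#'   one-decimal percentages.
#' @export
summarise_cohort <- function(cases, variants,
                             reports = build_reports(cases, variants)) {
  assert_cols(cases, "case_id", "case table")
  unknown_pheno <- setdiff(
    unlist(strsplit(cases$phenotypes, ",", fixed = TRUE)),
    phenotype_vocabulary())
  if (length(unknown_pheno) > 0) {
    stop_data("unknown phenotype category: %s", unknown_pheno[1])
  }
  n_cases <- nrow(cases)
  returned <- variants[variants$mdt_verdict == "return", , drop = FALSE]
  lp_p <- returned[returned$acmg_class %in% c("LP", "P"), , drop = FALSE]
  vus <- returned[returned$acmg_class == "VUS", , drop = FALSE]

  causal_cases <- unique(lp_p$case_id[lp_p$causal_for_phenotype])
  lp_p_cases <- unique(lp_p$case_id)
  secondary_cases <- setdiff(lp_p_cases, causal_cases)
  risk_cases <- unique(lp_p$case_id[lp_p$risk_management_changed])
  uninformative_cases <- setdiff(lp_p_cases, risk_cases)

  elig_cols <- grep("^elig_", names(cases), value = TRUE)
  elig_counts <- vapply(cases[elig_cols], sum, integer(1))

  age <- cases$age_at_first_diagnosis
  age_group <- cut(age, c(-Inf, 18, 49, Inf),
                   labels = c("18_and_under", "19_49", "50_plus"))

  rep_cases <- cases[cases$case_id %in% reports$case_id, , drop = FALSE]
  multi <- vapply(strsplit(rep_cases$phenotypes, ",", fixed = TRUE),
                  function(p) length(p) > 1, logical(1))

  out <- list(
    n_cases = n_cases,
    returned_variants = nrow(returned),
    lp_p_variants = nrow(lp_p),
    vus_variants = nrow(vus),
    vus_tier_counts = count_by(vus$vus_tier),
    causal_cases = length(causal_cases),
    causal_pct = pct(length(causal_cases), n_cases),
    secondary_cases = length(secondary_cases),
    secondary_pct = pct(length(secondary_cases), n_cases),
    risk_management_cases = length(risk_cases),
    risk_management_pct = pct(length(risk_cases), n_cases),
    lp_p_uninformative_cases = length(uninformative_cases),
    lp_p_uninformative_pct = pct(length(uninformative_cases), n_cases),
    reported_cases = nrow(reports),
    report_multiplicity = count_by(reports$n_variants),
    variants_by_type = count_by(returned$variant_type),
    variants_by_gene = count_by(returned$gene),
    eligibility_counts = elig_counts,
    eligibility_pcts = vapply(elig_counts, pct, numeric(1),
                              denominator = n_cases),
    sex_counts = count_by(cases$sex),
    age_group_counts = count_by(age_group),
    prior_testing_counts = count_by(cases$prior_testing),
    site_counts = count_by(cases$recruitment_site),
    multi_phenotype_reported = sum(multi),
    multi_phenotype_reported_pct = if (nrow(rep_cases) > 0) {
      pct(sum(multi), nrow(rep_cases))
    } else NA_real_
  )
  # class tallies must partition the returned set
  stopifnot(out$lp_p_variants + out$vus_variants == out$returned_variants)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  index cases:        %d\n", x$n_cases))
  cat(sprintf("  returned variants:  %d (%d LP/P + %d VUS [A:%s B:%s C:%s])\n",
              x$returned_variants, x$lp_p_variants, x$vus_variants,
              x$vus_tier_counts[["A"]], x$vus_tier_counts[["B"]],
              x$vus_tier_counts[["C"]]))
  cat(sprintf("  causal LP/P:        %d cases (%.1f%%)\n",
              x$causal_cases, x$causal_pct))
  cat(sprintf("  secondary LP/P:     %d cases (%.1f%%)\n",
              x$secondary_cases, x$secondary_pct))
  cat(sprintf("  risk mgmt changed:  %d cases (%.1f%%)\n",
              x$risk_management_cases, x$risk_management_pct))
  cat(sprintf("  reported cases:     %d (multiplicity %s)\n",
              x$reported_cases,
              paste(sprintf("%sx%s", names(x$report_multiplicity),
                            x$report_multiplicity), collapse = ", ")))
  invisible(x)
}
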