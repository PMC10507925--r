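#' Reportability gate for a curated variant
#'
#' Decides whether a curated variant enters the preliminary report for
#' multidisciplinary-team (MDT) review. LP/P variants always report.
#' Benign/likely-benign variants never reach this gate (calling it with one is
#' an error). For the remaining variants, three exclusionary conditions
#' suppress: a missense variant with REVEL below 0.5; a synonymous variant
#' with no predicted splicing impact; or an in-frame indel with PROVEAN above
#' -2.5. None of these applies when a rescue condition holds: an apparent
#' gene-phenotype association, an alternative deleteriousness predictor
#' (CADD above `cadd_rescue`), or a ClinVar LP/P classification from at least
#' one submitter.
#'
#' @param v one classified-variant record (one-row data frame or list) with
#'   `acmg_class`, `consequence`, `revel`, `provean`,
#'   `splice_impact_predicted`, `cadd`, `gene_phenotype_match`,
#'   `clinvar_lp_p_any_submitter`.
#' @param cadd_rescue CADD threshold for the alternative-predictor rescue
#'   (default 20, strict).
#' @return list with `decision` (`"report"` or `"suppress"`) and `reason`.
#' @export
reportability_gate <- function(v, cadd_rescue = 20) {
  cls <- v[["acmg_class"]]
  if (cls %in% c("B", "LB")) {
    stop_data("reportability_gate: B/LB variants are never presented")
  }
  if (cls %in% c("LP", "P")) {
    return(list(decision = "report", reason = "LP_P_ALWAYS_REPORTED"))
  }
  csq <- v[["consequence"]]
  exclusionary <- NULL
  if (identical(csq, "missense")) {
    if (is.na(v[["revel"]])) stop_data("missing REVEL score for a missense variant")
    if (v[["revel"]] < 0.5) exclusionary <- "MISSENSE_LOW_REVEL"
  } else if (identical(csq, "synonymous")) {
    if (is.na(v[["splice_impact_predicted"]])) {
      stop_data("missing splice-impact prediction for a synonymous variant")
    }
    if (!v[["splice_impact_predicted"]]) exclusionary <- "SYNONYMOUS_NO_SPLICE"
  } else if (identical(csq, "inframe_indel")) {
    if (is.na(v[["provean"]])) stop_data("missing PROVEAN score for an in-frame indel")
    if (v[["provean"]] > -2.5) exclusionary <- "INFRAME_HIGH_PROVEAN"
  }
  if (is.null(exclusionary)) {
    return(list(decision = "report", reason = "NO_EXCLUSIONARY_CATEGORY"))
  }
  rescue <- c(
    if (isTRUE(v[["gene_phenotype_match"]])) "GENE_PHENOTYPE",
    if (!is.null(v[["cadd"]]) && !is.na(v[["cadd"]]) && v[["cadd"]] > cadd_rescue)
      "CADD",
    if (isTRUE(v[["clinvar_lp_p_any_submitter"]])) "CLINVAR_SUBMITTER"
  )
  if (length(rescue) > 0) {
    list(decision = "report",
         reason = paste0(exclusionary, ";RESCUE_", paste(rescue, collapse = "+")))
  } else {
    list(decision = "suppress", reason = exclusionary)
  }
}

#' Apply MDT verdicts to a classified-variant table
#'
#' MDT judgement is an input, not computed: `exclude` and `downgrade_B_LB`
#' verdicts remove a variant from reporting; `return` verdicts mark it
#' returnable and may set the post-MDT VUS tier and the finding flags.
#' Variants with no verdict remain `pending`.
#'
#' @param variants classified-variant tibble with a `variant_id` column.
#' @param verdicts tibble with `variant_id`, `verdict` and optional `tier`,
#'   `causal`, `secondary`, `somatic`, `risk_changed`, `direct_return`.
#' @return `variants` with `mdt_verdict` (and any supplied fields) updated.
#' @export
apply_mdt_verdicts <- function(variants, verdicts) {
  assert_cols(variants, "variant_id", "classified-variant table")
  if (nrow(verdicts) == 0) {
    if (!"mdt_verdict" %in% names(variants)) variants$mdt_verdict <- "pending"
    return(variants)
  }
  assert_cols(verdicts, c("variant_id", "verdict"), "verdict table")
  unknown <- setdiff(verdicts$variant_id, variants$variant_id)
  if (length(unknown) > 0) {
    stop_data("verdict for unknown variant id(s): %s",
              paste(utils::head(unknown, 3), collapse = ", "))
  }
  bad <- setdiff(verdicts$verdict, c("return", "exclude", "downgrade_B_LB"))
  if (length(bad) > 0) stop_data("unknown verdict '%s'", bad[1])
  if (!"mdt_verdict" %in% names(variants)) variants$mdt_verdict <- "pending"
  idx <- match(verdicts$variant_id, variants$variant_id)
  variants$mdt_verdict[idx] <- verdicts$verdict
  opt <- c(tier = "vus_tier", causal = "causal_for_phenotype",
           secondary = "secondary_finding", somatic = "somatic_origin",
           risk_changed = "risk_management_changed",
           direct_return = "direct_return")
  for (from in names(opt)) {
    if (from %in% names(verdicts)) {
      to <- opt[[from]]
      if (!to %in% names(variants)) {
        variants[[to]] <- if (from == "tier") NA_character_ else NA
      }
      has <- !is.na(verdicts[[from]])
      variants[[to]][idx[has]] <- verdicts[[from]][has]
    }
  }
  variants
}

finding_category_of <- function(v) {
  if (!(v$acmg_class %in% c("LP", "P"))) return(NA_character_)
  if (!is.null(v$finding_category) && !is.na(v$finding_category)) {
    return(v$finding_category)
  }
  if (isTRUE(v$somatic_origin)) return("somatic")
  if (isTRUE(v$causal_for_phenotype)) return("causal")
  "new_diagnosis"
}

#' Assemble post-MDT case reports
#'
#' One report per case with at least one returned variant
#' (`mdt_verdict == "return"`). Cases whose variants were all suppressed,
#' excluded or downgraded receive no report. A safety invariant guarantees no
#' benign/likely-benign variant ever appears in a report.
#'
#' @param cases index-case tibble with `case_id`.
#' @param variants classified-variant tibble with verdicts applied.
#' @return tibble with one row per reported case: `case_id`, `n_variants`,
#'   `n_lp_p`, list-columns `variant_ids`, `classes`, `vus_tiers`,
#'   `finding_categories`.
#' @export
build_reports <- function(cases, variants) {
  assert_cols(variants, c("variant_id", "case_id", "acmg_class", "mdt_verdict"),
              "classified-variant table")
  dangling <- setdiff(variants$case_id, cases$case_id)
  if (length(dangling) > 0) {
    stop_data("variant refers to unknown case id(s): %s",
              paste(utils::head(dangling, 3), collapse = ", "))
  }
  returned <- variants[variants$mdt_verdict == "return", , drop = FALSE]
  if (any(returned$acmg_class %in% c("B", "LB"))) {
    stop_data("safety invariant violated: B/LB variant marked for return")
  }
  if (nrow(returned) == 0) {
    return(tibble::tibble(case_id = character(0), n_variants = integer(0),
                          n_lp_p = integer(0), variant_ids = list(),
                          classes = list(), vus_tiers = list(),
                          finding_categories = list()))
  }
  split_idx <- split(seq_len(nrow(returned)), returned$case_id)
  rows <- lapply(names(split_idx), function(cid) {
    ix <- split_idx[[cid]]
    sub <- returned[ix, , drop = FALSE]
    cats <- vapply(seq_len(nrow(sub)),
                   function(k) finding_category_of(sub[k, ]) %||% NA_character_,
                   character(1))
    tibble::tibble(
      case_id = cid,
      n_variants = nrow(sub),
      n_lp_p = sum(sub$acmg_class %in% c("LP", "P")),
      variant_ids = list(sub$variant_id),
      classes = list(sub$acmg_class),
      vus_tiers = list(sub$vus_tier),
      finding_categories = list(cats)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$case_id)
}
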