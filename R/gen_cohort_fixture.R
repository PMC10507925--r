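#' Broad tumour-phenotype vocabulary used by the cohort fixture
#' @return character vector of category labels.
#' @export
phenotype_vocabulary <- function() {
  c("gynaecological_breast", "urogenital", "neuroendocrine", "polyposis",
    "gastrointestinal", "skin", "sarcoma", "respiratory", "head_and_neck",
    "brain", "lymphoma", "pancreatic", "unknown_primary", "neurological",
    "other")
}

#' Deterministic cohort fixture
#'
#' Code-generated (no RNG) tables of 195 index cases and 155 classified
#' variants reproducing the study-level tallies the cohort summary reports:
#' 119 returned variants (31 LP/P and 88 VUS split 7/54/27 across tiers A/B/C)
#' across 92 participants with report multiplicities 67/23/2; 10 cases with a
#' causal LP/P finding, 19 with a secondary LP/P finding, 20 with a change in
#' risk management and 9 where the LP/P finding was uninformative; eligibility
#' flags counting 28/83/52/29/42; 141 female / 54 male; prior testing
#' 140 uninformative / 55 none. Two cases (I148, I176) carry two LP/P
#' variants each; two pathogenic PALB2 variants (I129, I134) are returned
#' directly without formal MDT review; one LP/P structural variant (I079) is
#' of somatic origin. Thirty-six additional variants were presented to the
#' MDT but excluded (24) or downgraded to B/LB (12), so 153 variants faced
#' formal review and 153 - 36 + 2 = 119 were returned.
#'
#' @return list with `cases` and `variants` tibbles.
#' @export
gen_cohort_fixture <- function() {
  n <- 195L
  id <- sprintf("I%03d", seq_len(n))
  vocab <- phenotype_vocabulary()
  panel <- synthetic_panel(120L)

  sex <- c(rep("F", 141), rep("M", 54))
  age <- c(8 + (seq_len(16) %% 9),              # 16 cases aged <= 18
           19 + ((seq_len(125) * 7) %% 31),     # 125 cases aged 19-49
           50 + ((seq_len(54) * 3) %% 25))      # 54 cases aged 50+
  prior_testing <- c(rep("uninformative", 140), rep("none", 55))
  site <- rep(c("QLD", "VIC", "TAS", "SA", "NSW", "WA"),
              times = c(46, 58, 14, 21, 29, 27))

  i <- seq_len(n)
  elig_syndrome <- i %in% 1:28
  elig_two_primaries <- i %in% 29:111
  elig_three_primaries <- i %in% 112:163
  elig_polyposis <- i %in% 164:192
  elig_multi_criteria <- i %in% c(193:195, 1:39)

  reported <- c(sprintf("I%03d", 1:88), "I129", "I134", "I148", "I176")
  multi_pheno <- id %in% reported[1:63]   # 63/92 reported cases multi-phenotype
  pheno1 <- vocab[(i - 1) %% length(vocab) + 1]
  pheno2 <- vocab[i %% length(vocab) + 1]
  phenotypes <- ifelse(multi_pheno, paste(pheno1, pheno2, sep = ","), pheno1)

  cases <- tibble::tibble(
    case_id = id, sex = sex, age_at_first_diagnosis = age,
    prior_testing = prior_testing, recruitment_site = site,
    elig_syndrome = elig_syndrome, elig_two_primaries = elig_two_primaries,
    elig_three_primaries = elig_three_primaries,
    elig_polyposis = elig_polyposis, elig_multi_criteria = elig_multi_criteria,
    phenotypes = phenotypes
  )

  # ---- classified variants ------------------------------------------------
  single_lp_cases <- c(sprintf("I%03d", 24:40), "I079")
  causal_cases <- sprintf("I%03d", 24:33)
  risk_changed_cases <- c(sprintf("I%03d", 24:40), "I129", "I134", "I003")
  lp_genes <- rep(c("APC", "ATM", "MUTYH", "MSH6", "BRCA2", "BAP1", "G015"),
                  length.out = 40)
  gi <- 0L

  rows <- list()
  add <- function(case_id, acmg_class, vus_tier = NA_character_,
                  variant_type = "SNV", consequence = "missense",
                  gene = NULL, mdt_verdict = "return", direct_return = FALSE,
                  causal = FALSE, secondary = FALSE, somatic = FALSE,
                  risk_changed = FALSE, finding_category = NA_character_) {
    if (is.null(gene)) {
      gi <<- gi + 1L
      gene <- lp_genes[gi]
    }
    k <- length(rows) + 1L
    rows[[k]] <<- tibble::tibble(
      variant_id = sprintf("V%03d", k), case_id = case_id, gene = gene,
      variant_type = variant_type, consequence = consequence,
      acmg_class = acmg_class, vus_tier = vus_tier,
      revel = if (consequence == "missense") 0.65 else NA_real_,
      provean = if (consequence == "inframe_indel") -3.5 else NA_real_,
      cadd = 22, splice_impact_predicted = consequence == "synonymous",
      gene_phenotype_match = isTRUE(causal),
      clinvar_lp_p_any_submitter = acmg_class %in% c("LP", "P"),
      mdt_verdict = mdt_verdict, direct_return = direct_return,
      causal_for_phenotype = causal, secondary_finding = secondary,
      somatic_origin = somatic, risk_management_changed = risk_changed,
      finding_category = finding_category
    )
  }

  vus_consequence <- function(k) {
    if (k %% 10 == 0) "synonymous" else if (k %% 10 == 5) "inframe_indel" else "missense"
  }
  vus_count <- 0L
  add_vus <- function(case_id, variant_type = "SNV") {
    vus_count <<- vus_count + 1L
    add(case_id, "VUS", vus_tier = "pendingtier",
        variant_type = variant_type,
        consequence = vus_consequence(vus_count),
        gene = panel[(vus_count * 3) %% length(panel) + 1])
  }
  add_lp <- function(case_id, ...) {
    cls <- if (length(rows) %% 2 == 0) "P" else "LP"
    add(case_id, cls, consequence = "frameshift", ...)
  }

  for (cid in c("I001", "I002")) for (k in 1:3) add_vus(cid)   # 3-variant cases
  for (cid in sprintf("I%03d", 3:9)) {                         # LP/P + VUS
    add_lp(cid, secondary = TRUE,
           risk_changed = cid %in% risk_changed_cases,
           finding_category = "carrier_recessive")
    add_vus(cid)
  }
  for (cid in sprintf("I%03d", 10:23)) { add_vus(cid); add_vus(cid) }  # 2 VUS
  for (cid in c("I148", "I176")) {                             # two LP/P each
    add_lp(cid, secondary = TRUE, finding_category = "carrier_recessive")
    add_lp(cid, secondary = TRUE, finding_category = "carrier_recessive")
  }
  for (cid in single_lp_cases) {                               # single LP/P
    causal <- cid %in% causal_cases
    somatic <- cid == "I079"
    add_lp(cid,
           variant_type = if (somatic) "SV" else if (cid == "I024") "CNV" else "SNV",
           causal = causal, secondary = !causal, somatic = somatic,
           risk_changed = cid %in% risk_changed_cases,
           finding_category = if (somatic) "somatic"
                              else if (causal) "causal"
                              else if (cid %in% sprintf("I%03d", 39:40)) "partial_diagnosis"
                              else "new_diagnosis")
  }
  for (cid in c("I129", "I134")) {                             # direct-return PALB2
    add(cid, "P", variant_type = "SNV", consequence = "frameshift",
        gene = "PALB2", direct_return = TRUE, secondary = TRUE,
        risk_changed = TRUE, finding_category = "new_diagnosis")
  }
  single_vus_cases <- setdiff(sprintf("I%03d", 24:88),
                              c(sprintf("I%03d", 24:40), "I079"))
  for (k in seq_along(single_vus_cases)) {                     # single VUS
    add_vus(single_vus_cases[k],
            variant_type = if (k <= 3) "CNV" else if (k <= 5) "SV" else "SNV")
  }
  for (k in 1:36) {                                            # MDT-rejected
    add(sprintf("I%03d", 88 + k), "VUS",
        mdt_verdict = if (k <= 24) "exclude" else "downgrade_B_LB",
        consequence = "missense")
  }

  variants <- dplyr::bind_rows(rows)

  # post-MDT VUS tiers for returned VUS, in variant order: 7 A, 54 B, 27 C
  ret_vus <- which(variants$acmg_class == "VUS" &
                   variants$mdt_verdict == "return")
  stopifnot(length(ret_vus) == 88)
  variants$vus_tier <- NA_character_
  variants$vus_tier[ret_vus] <- rep(c("A", "B", "C"), times = c(7, 54, 27))
  variants$revel[variants$consequence != "missense"] <- NA_real_

  list(cases = cases, variants = variants)
}
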