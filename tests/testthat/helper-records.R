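# single-record constructors with sensible defaults, for gate-level tests

make_small_variant <- function(id = "v1", gene = "APC", variant_class = "snv",
                               consequence = "missense", vaf = 0.5,
                               clinvar_status = "none", cohort_af = 0,
                               inhouse_af = 0, revel = NA_real_,
                               provean = NA_real_, cadd = NA_real_,
                               splice_impact_predicted = FALSE, ...) {
  afs <- list(...)
  base <- tibble::tibble(
    id = id, chrom = "pc1", pos = 1000L, ref = "A", alt = "G",
    variant_class = variant_class, consequence = consequence, gene = gene,
    clinvar_status = clinvar_status, vaf = vaf, cohort_af = cohort_af,
    inhouse_af = inhouse_af, revel = revel, provean = provean, cadd = cadd,
    splice_impact_predicted = splice_impact_predicted
  )
  for (p in default_subpops()$pop) {
    for (pre in c("gnex_", "gnge_")) {
      col <- paste0(pre, p)
      base[[col]] <- afs[[col]] %||% NA_real_
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_sv_record <- function(id = "A0001", sv_type = "DEL", chrom1 = "pc1",
                           pos1 = 0, chrom2 = chrom1, pos2 = 1000,
                           caller = "A", q0 = NA_real_,
                           genotype_score = NA_real_) {
  tibble::tibble(id = id, sv_type = sv_type, chrom1 = chrom1, pos1 = pos1,
                 chrom2 = chrom2, pos2 = pos2, caller = caller, q0 = q0,
                 genotype_score = genotype_score)
}

make_freq_resource <- function(type = "DEL", chrom1 = "pc1", pos1 = 0,
                               chrom2 = chrom1, pos2 = 1000, af = 0.1) {
  tibble::tibble(type = type, chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
                 pos2 = pos2, af = af)
}

make_classified <- function(variant_id = "V1", case_id = "I001",
                            acmg_class = "VUS", consequence = "missense",
                            revel = NA_real_, provean = NA_real_,
                            cadd = NA_real_, splice_impact_predicted = FALSE,
                            gene_phenotype_match = FALSE,
                            clinvar_lp_p_any_submitter = FALSE,
                            mdt_verdict = "pending", vus_tier = NA_character_,
                            causal_for_phenotype = FALSE,
                            secondary_finding = FALSE, somatic_origin = FALSE,
                            risk_management_changed = FALSE, gene = "APC") {
  tibble::tibble(
    variant_id = variant_id, case_id = case_id, gene = gene,
    acmg_class = acmg_class, consequence = consequence, revel = revel,
    provean = provean, cadd = cadd,
    splice_impact_predicted = splice_impact_predicted,
    gene_phenotype_match = gene_phenotype_match,
    clinvar_lp_p_any_submitter = clinvar_lp_p_any_submitter,
    mdt_verdict = mdt_verdict, vus_tier = vus_tier,
    causal_for_phenotype = causal_for_phenotype,
    secondary_finding = secondary_finding, somatic_origin = somatic_origin,
    risk_management_changed = risk_management_changed
  )
}

# literal per-base coverage scan: the O(n * m) oracle for region coverage
brute_coverage <- function(s, e, regions) {
  if (e <= s) stop("bad span")
  pos <- s:(e - 1)
  covered <- vapply(pos, function(p) {
    any(p >= regions$start & p < regions$end)
  }, logical(1))
  mean(covered)
}

# brute-force reciprocal overlap by interval arithmetic written independently
brute_ro <- function(a1, a2, b1, b2) {
  ov <- min(a2, b2) - max(a1, b1)
  if (ov <= 0) return(0)
  min(ov / (a2 - a1), ov / (b2 - b1))
}
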