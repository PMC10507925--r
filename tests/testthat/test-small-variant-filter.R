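eligible <- default_subpops()$pop

test_that("ClinVar rescue applies to LP/P classifications only", {
  expect_true(clinvar_rescue("P"))
  expect_true(clinvar_rescue("LP"))
  expect_false(clinvar_rescue("VUS"))
  expect_false(clinvar_rescue("none"))
  expect_false(clinvar_rescue("B"))
})

test_that("frequency gate drops common variants unless ClinVar-rescued", {
  v <- make_small_variant(gnex_nfe = 0.02)
  d <- passes_frequency_gate(v, eligible)
  expect_false(d$keep)
  expect_equal(d$reasons, "AF_GNOMAD_EXOME_NFE")

  vr <- make_small_variant(gnex_nfe = 0.02, clinvar_status = "P")
  dr <- passes_frequency_gate(vr, eligible)
  expect_true(dr$keep)
  expect_equal(dr$reasons, "CLINVAR_RESCUE")

  # genome-derived frequencies are considered separately
  vg <- make_small_variant(gnge_afr = 0.05)
  expect_equal(passes_frequency_gate(vg, eligible)$reasons,
               "AF_GNOMAD_GENOME_AFR")

  # cohort and in-house thresholds
  expect_false(passes_frequency_gate(make_small_variant(cohort_af = 0.02),
                                     eligible)$keep)
  expect_false(passes_frequency_gate(make_small_variant(inhouse_af = 0.02),
                                     eligible)$keep)
})

test_that("a frequency of exactly 1 percent is retained (strict inequality)", {
  v <- make_small_variant(gnex_nfe = 0.01, gnge_nfe = 0.01,
                          cohort_af = 0.01, inhouse_af = 0.01)
  d <- passes_frequency_gate(v, eligible)
  expect_true(d$keep)
  expect_length(d$reasons, 0)
})

test_that("ineligible subpopulations and missing frequencies are ignored", {
  v <- make_small_variant(gnex_fin = 0.2)
  expect_false(passes_frequency_gate(v, eligible)$keep)
  expect_true(passes_frequency_gate(v, setdiff(eligible, "fin"))$keep)
  expect_true(passes_frequency_gate(make_small_variant(), eligible)$keep)
  expect_error(passes_frequency_gate(make_small_variant(gnex_nfe = 1.2),
                                     eligible), "outside")
})

test_that("VAF gate uses 30% for substitutions and 20% for indels", {
  expect_false(passes_vaf_gate(make_small_variant(vaf = 0.25))$keep)
  expect_true(passes_vaf_gate(make_small_variant(variant_class = "indel",
                                                 vaf = 0.25))$keep)
  expect_true(passes_vaf_gate(make_small_variant(vaf = 0.30))$keep)
  expect_true(passes_vaf_gate(make_small_variant(variant_class = "indel",
                                                 vaf = 0.20))$keep)
  expect_false(passes_vaf_gate(make_small_variant(variant_class = "indel",
                                                  vaf = 0.19))$keep)
  # dinucleotide substitutions take the SNV threshold
  expect_false(passes_vaf_gate(make_small_variant(variant_class = "dnv",
                                                  vaf = 0.25))$keep)
  expect_error(passes_vaf_gate(make_small_variant(vaf = NA_real_)), "missing VAF")
})

test_that("ClinVar rescue does not waive the VAF filter", {
  v <- make_small_variant(gnex_nfe = 0.05, clinvar_status = "P", vaf = 0.25)
  res <- run_small_variant_cascade(v, panel = "APC")
  expect_equal(nrow(res$kept), 0)
  expect_match(res$audit$reasons, "VAF_SNV")
  expect_match(res$audit$reasons, "CLINVAR_RESCUE")
})

test_that("the cascade restricts to the virtual panel and audits every row", {
  tbl <- dplyr::bind_rows(
    make_small_variant(id = "v1", gene = "APC"),
    make_small_variant(id = "v2", gene = "NOT_ON_PANEL")
  )
  res <- run_small_variant_cascade(tbl, panel = c("APC", "ATM"))
  expect_equal(res$kept$id, "v1")
  expect_equal(nrow(res$audit), 2)
  expect_equal(res$audit$reasons[2], "PANEL")

  empty <- gen_small_variants(generator_params(seed = 1, n_small_variants = 0))
  res0 <- run_small_variant_cascade(empty, panel = "APC")
  expect_equal(nrow(res0$kept), 0)
  expect_equal(nrow(res0$audit), 0)
  expect_error(run_small_variant_cascade(tbl, panel = character(0)), "non-empty")
  expect_error(
    run_small_variant_cascade(make_small_variant(variant_class = "mnv"),
                              panel = "APC"),
    "variant_class")
})

test_that("cascade output matches the generator's ground-truth labels", {
  p <- generator_params(seed = 7, n_small_variants = 1000, fraction_common = 0.3)
  tbl <- gen_small_variants(p)
  res <- run_small_variant_cascade(tbl, panel = synthetic_panel(p$n_genes))
  expect_identical(res$audit$keep, tbl$truth_keep)
  expect_identical(res$audit$reasons, tbl$truth_reasons)
  expect_identical(res$kept$id, tbl$id[tbl$truth_keep])
})

test_that("the cascade is order-invariant and idempotent", {
  p <- generator_params(seed = 21, n_small_variants = 300)
  tbl <- gen_small_variants(p)
  panel <- synthetic_panel(p$n_genes)
  res <- run_small_variant_cascade(tbl, panel = panel)

  set.seed(42)
  perm <- sample.int(nrow(tbl))
  res_p <- run_small_variant_cascade(tbl[perm, ], panel = panel)
  expect_identical(res_p$audit$keep, res$audit$keep[perm])
  expect_setequal(res_p$kept$id, res$kept$id)

  res2 <- run_small_variant_cascade(res$kept, panel = panel)
  expect_identical(res2$kept, res$kept)
})

test_that("upgrading ClinVar status to P never shrinks the kept set", {
  p <- generator_params(seed = 33, n_small_variants = 300,
                        fraction_common = 0.5)
  tbl <- gen_small_variants(p)
  panel <- synthetic_panel(p$n_genes)
  before <- run_small_variant_cascade(tbl, panel = panel)$kept$id
  tbl$clinvar_status <- "P"
  after <- run_small_variant_cascade(tbl, panel = panel)$kept$id
  expect_true(all(before %in% after))
})
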