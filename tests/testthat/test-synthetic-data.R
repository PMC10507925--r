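test_that("generator parameters are validated", {
  expect_error(generator_params(n_small_variants = -1), "non-negative")
  expect_error(generator_params(fraction_common = 1.5), "\\[0, 1\\]")
  expect_error(generator_params(vaf_noise_sd = -0.1), ">= 0")
})

test_that("small-variant generator handles the empty case with a full header", {
  p <- generator_params(seed = 1, n_small_variants = 0)
  tbl <- gen_small_variants(p)
  expect_equal(nrow(tbl), 0)
  expect_true(all(c("id", "chrom", "pos", "vaf", "clinvar_status", "cohort_af",
                    "inhouse_af", "gnex_nfe", "gnge_nfe", "truth_keep") %in%
                    names(tbl)))
})

test_that("generators are byte-identical under a fixed seed", {
  p <- generator_params(seed = 11, n_small_variants = 200, n_sv_per_caller = 50)
  expect_identical(gen_small_variants(p), gen_small_variants(p))
  expect_identical(gen_sv_cnv(p), gen_sv_cnv(p))
  expect_identical(gen_region_resources(p), gen_region_resources(p))
})

test_that("all-common, no-rescue variants are all labelled drop", {
  p <- generator_params(seed = 7, n_small_variants = 1000,
                        fraction_common = 1.0, fraction_clinvar_lp_p = 0.0)
  tbl <- gen_small_variants(p)
  expect_equal(nrow(tbl), 1000)
  expect_false(any(tbl$truth_keep))
})

test_that("small-variant annotations respect their ranges", {
  p <- generator_params(seed = 3, n_small_variants = 500)
  tbl <- gen_small_variants(p)
  expect_true(all(tbl$vaf >= 0 & tbl$vaf <= 1))
  afs <- unlist(tbl[, grep("^(gnex|gnge)_|_af$", names(tbl))])
  expect_true(all(is.na(afs) | (afs >= 0 & afs <= 1)))
  expect_true(all(tbl$pos >= 1))
  expect_true(all(tbl$ref != tbl$alt))
  expect_true(all(tbl$clinvar_status %in% c("none", "B", "LB", "VUS", "LP", "P")))
})

test_that("SV generator handles the empty case and emits valid coordinates", {
  p0 <- generator_params(seed = 1, n_sv_per_caller = 0)
  sc0 <- gen_sv_cnv(p0)
  expect_equal(nrow(sc0$calls_a), 0)
  expect_equal(nrow(sc0$calls_b), 0)

  p <- generator_params(seed = 5, n_sv_per_caller = 100)
  sc <- gen_sv_cnv(p)
  expect_equal(nrow(sc$calls_a), 100)
  expect_equal(nrow(sc$calls_b), 100)
  expect_true(all(sc$calls_b$sv_type %in% c("DEL", "DUP")))
  expect_false(any(is.na(sc$calls_b$q0)))
  same <- sc$calls_a$chrom1 == sc$calls_a$chrom2
  expect_true(all(sc$calls_a$pos1[same] <= sc$calls_a$pos2[same]))
  layout <- genome_layout(p)
  lim <- setNames(layout$length, layout$chrom)
  expect_true(all(sc$calls_a$pos2 <= lim[sc$calls_a$chrom1] |
                    sc$calls_a$chrom1 != sc$calls_a$chrom2))
  expect_true(all(sc$calls_b$pos2 <= lim[sc$calls_b$chrom1]))
})

test_that("generated concordant CNV pairs overlap as constructed", {
  # a shrink-only partner always keeps reciprocal overlap above 0.84
  p <- generator_params(seed = 9, n_sv_per_caller = 80)
  sc <- gen_sv_cnv(p)
  m <- match_cnv_calls(sc$calls_a[sc$calls_a$sv_type %in% c("DEL", "DUP"), ],
                       sc$calls_b)
  conc <- m[m$concordant, ]
  expect_gt(nrow(conc), 0)
  expect_true(all(conc$overlap >= 0.8))
})

test_that("region resources fit in the genome and yield valid footprints", {
  p <- generator_params(seed = 2, n_genes = 101, n_exclusion_regions = 40)
  res <- gen_region_resources(p)
  layout <- genome_layout(p)
  lim <- setNames(layout$length, layout$chrom)
  expect_equal(nrow(res$genes), 101)
  expect_true(all(res$genes$end > res$genes$start))
  expect_true(all(res$genes$end <= lim[res$genes$chrom]))
  expect_true(all(res$exclusion_regions$start < res$exclusion_regions$end))
  expect_true(all(res$exclusion_regions$end <= lim[res$exclusion_regions$chrom]))
  fp <- gene_footprint(res$genes, chrom_lengths = layout)
  expect_equal(nrow(fp), 101)
  expect_true(all(fp$end > fp$start))
  expect_true(all(fp$start >= 0 & fp$end <= lim[fp$chrom]))

  p0 <- generator_params(seed = 2, n_exclusion_regions = 0)
  expect_equal(nrow(gen_region_resources(p0)$exclusion_regions), 0)
})

test_that("the cohort fixture reproduces every pinned tally", {
  fx <- gen_cohort_fixture()
  expect_equal(nrow(fx$cases), 195)

  ret <- fx$variants[fx$variants$mdt_verdict == "return", ]
  expect_equal(nrow(ret), 119)
  expect_equal(sum(ret$acmg_class %in% c("LP", "P")), 31)
  vus <- ret[ret$acmg_class == "VUS", ]
  expect_equal(nrow(vus), 88)
  expect_equal(as.vector(table(vus$vus_tier)[c("A", "B", "C")]), c(7, 54, 27))
  expect_equal(length(unique(ret$case_id)), 92)

  expect_equal(sum(fx$cases$elig_syndrome), 28)
  expect_equal(sum(fx$cases$elig_two_primaries), 83)
  expect_equal(sum(fx$cases$elig_three_primaries), 52)
  expect_equal(sum(fx$cases$elig_polyposis), 29)
  expect_equal(sum(fx$cases$elig_multi_criteria), 42)
  expect_equal(as.vector(table(fx$cases$prior_testing)[c("uninformative", "none")]),
               c(140, 55))
  expect_equal(as.vector(table(fx$cases$sex)[c("F", "M")]), c(141, 54))

  # the two direct-return pathogenic variants bypass formal MDT review
  direct <- fx$variants[fx$variants$direct_return, ]
  expect_equal(sort(direct$case_id), c("I129", "I134"))
  expect_true(all(direct$acmg_class == "P"))
  # 153 variants faced formal MDT review, 36 were not returned
  expect_equal(sum(!fx$variants$direct_return), 153)
  expect_equal(sum(fx$variants$mdt_verdict != "return"), 36)
})

test_that("the base-case economic configuration carries the study parameters", {
  cfg <- gen_econ_config()
  expect_equal(cfg$referred_national, 13230)
  expect_equal(cfg$offered_targeted_proportion, 0.3504)
  expect_equal(cfg$wgs_uptake_s2, 0.796)
  expect_equal(cfg$wgs_uptake_s3, 0.968)
  expect_equal(cfg$wgs_yield_s3, 0.384)
  expect_equal(cfg$costs$wgs_price, 1750)
})
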