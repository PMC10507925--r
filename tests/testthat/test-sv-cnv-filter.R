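test_that("reciprocal overlap follows the min-of-fractions definition", {
  expect_equal(reciprocal_overlap(100, 200, 100, 200), 1.0)
  expect_equal(reciprocal_overlap(0, 100, 20, 100), 0.8)
  expect_equal(reciprocal_overlap(1000, 2000, 1100, 2000), 0.9)
  expect_equal(reciprocal_overlap(0, 100, 200, 300), 0.0)
  expect_error(reciprocal_overlap(5, 5, 0, 10), "zero")
})

test_that("reciprocal overlap is symmetric, bounded and maximal at identity", {
  set.seed(101)
  for (k in 1:200) {
    a <- sort(sample.int(1000, 2)); b <- sort(sample.int(1000, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    ro <- reciprocal_overlap(a[1], a[2], b[1], b[2])
    expect_equal(ro, reciprocal_overlap(b[1], b[2], a[1], a[2]))
    expect_gte(ro, 0); expect_lte(ro, 1)
    expect_equal(ro, brute_ro(a[1], a[2], b[1], b[2]))
    expect_equal(ro == 1, identical(a, b))
  }
})

test_that("q0 rule flags extreme values unless the genotype score is low", {
  expect_true(q0_flag(0.6, 0.3))
  expect_false(q0_flag(0.6, 0.2))
  expect_false(q0_flag(0.4, 0.9))
  expect_true(q0_flag(-1, 0.9))
  expect_false(q0_flag(0, 0.9))    # boundary: q0 of exactly 0 is acceptable
  expect_false(q0_flag(0.5, 0.9))  # boundary: q0 of exactly 0.5 is acceptable
  expect_error(q0_flag(NA_real_), "missing q0")
})

test_that("CNV matching requires same type and 80% reciprocal overlap", {
  a <- make_sv_record("A1", "DEL", pos1 = 1000, pos2 = 2000)
  b <- make_sv_record("B1", "DEL", pos1 = 1100, pos2 = 2000, caller = "B")
  m <- match_cnv_calls(a, b)
  expect_true(all(m$concordant))
  expect_equal(unique(m$overlap), 0.9)

  b_dup <- make_sv_record("B1", "DUP", pos1 = 1000, pos2 = 2000, caller = "B")
  m2 <- match_cnv_calls(a, b_dup)
  expect_false(any(m2$concordant))
  expect_true(all(grepl("SINGLE_CALLER", m2$flags)))
  expect_true(all(grepl("MANUAL_REVIEW", m2$flags)))

  m3 <- match_cnv_calls(a, a[0, ])
  expect_false(any(m3$concordant))

  expect_error(match_cnv_calls(make_sv_record(sv_type = "INV"), b), "DEL/DUP")
})

test_that("greedy matching assigns at most one partner per call", {
  set.seed(7)
  n <- 40
  mk <- function(caller, prefix) {
    s <- sort(sample.int(50000, n))
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_sv_record(sprintf("%s%02d", prefix, i), "DEL", pos1 = s[i],
                     pos2 = s[i] + sample(500:2000, 1), caller = caller)
    }))
  }
  a <- mk("A", "A"); b <- mk("B", "B")
  m <- match_cnv_calls(a, b)
  ma <- m$matched_id[m$caller == "A"]
  mb <- m$matched_id[m$caller == "B"]
  expect_false(any(duplicated(stats::na.omit(ma))))
  expect_false(any(duplicated(stats::na.omit(mb))))
  expect_lte(sum(m$concordant) / 2, min(nrow(a), nrow(b)))
  # the match relation is mutual
  for (i in which(!is.na(ma))) {
    j <- which(b$id == ma[i])
    expect_equal(mb[j], a$id[i])
  }
})

test_that("region exclusion uses 80% union coverage for spans, any hit for breakpoints", {
  regions <- tibble::tibble(chrom = "pc1", start = 0, end = 800)
  del <- make_sv_record(sv_type = "DEL", pos1 = 0, pos2 = 1000)
  expect_true(region_exclusion_flag(del, regions))          # exactly 0.8
  expect_false(region_exclusion_flag(del, regions[0, ]))

  tra <- make_sv_record(sv_type = "TRA", pos1 = 500, chrom2 = "pc2",
                        pos2 = 999999)
  expect_true(region_exclusion_flag(tra, tibble::tibble(
    chrom = "pc1", start = 400, end = 600)))
  expect_false(region_exclusion_flag(tra, tibble::tibble(
    chrom = "pc3", start = 400, end = 600)))

  # coverage counts the union: two half-covering regions together exclude
  two <- tibble::tibble(chrom = "pc1", start = c(0, 400), end = c(500, 900))
  expect_true(region_exclusion_flag(del, two))
  # overlapping regions are not double-counted
  dup_regions <- tibble::tibble(chrom = "pc1", start = c(0, 0), end = c(500, 500))
  expect_false(region_exclusion_flag(del, dup_regions))
})

test_that("union coverage agrees with a per-base brute-force scan", {
  set.seed(55)
  for (k in 1:100) {
    nreg <- sample(1:200, 1)
    start <- sample.int(1800, nreg, replace = TRUE)
    regions <- tibble::tibble(chrom = "pc1", start = start,
                              end = start + sample.int(150, nreg, replace = TRUE))
    s <- sample.int(1500, 1); e <- s + sample(50:400, 1)
    v <- make_sv_record(sv_type = "DEL", pos1 = s, pos2 = e)
    expect_equal(region_exclusion_flag(v, regions),
                 brute_coverage(s, e, regions) >= 0.80)
  }
})

test_that("frequency assignment needs 80% overlap (spans) or 100 bp windows", {
  del <- make_sv_record(sv_type = "DEL", pos1 = 1000, pos2 = 2000)
  res <- make_freq_resource("DEL", pos1 = 1100, pos2 = 2000, af = 0.10)
  expect_true(frequency_flag(del, gnomadsv = res))
  expect_false(frequency_flag(del, gnomadsv = make_freq_resource(
    "DEL", pos1 = 1100, pos2 = 2000, af = 0.05)))  # exactly 5% retained
  expect_false(frequency_flag(del, gnomadsv = make_freq_resource(
    "DUP", pos1 = 1100, pos2 = 2000, af = 0.10)))  # type must match
  expect_false(frequency_flag(del, gnomadsv = make_freq_resource(
    "DEL", pos1 = 1600, pos2 = 2600, af = 0.10)))  # overlap below 80%

  ins <- make_sv_record(sv_type = "INS", pos1 = 5000, pos2 = 5000)
  near <- make_freq_resource("INS", pos1 = 5100, pos2 = 5100, af = 0.2)
  far <- make_freq_resource("INS", pos1 = 5150, pos2 = 5150, af = 0.2)
  expect_true(frequency_flag(ins, inhouse = near))   # within the 100-bp window
  expect_false(frequency_flag(ins, inhouse = far))   # 150 bp away: no assignment
  # any of the three resources can trigger the flag
  expect_true(frequency_flag(del, cohort = res))
})

test_that("gene footprints extend 2000 bp upstream, strand-aware, clipped", {
  genes <- tibble::tibble(
    gene = c("P1", "M1", "C1"), chrom = "pc1",
    start = c(10000, 10000, 500), end = c(15000, 15000, 900),
    strand = c("+", "-", "+"))
  fp <- gene_footprint(genes)
  expect_equal(fp$start, c(8000, 10000, 0))
  expect_equal(fp$end, c(15000, 17000, 900))

  fp2 <- gene_footprint(genes, stranded = FALSE)
  expect_equal(fp2$start, c(8000, 8000, 0))
  expect_equal(fp2$end, c(15000, 15000, 900))

  lim <- tibble::tibble(chrom = "pc1", length = 16000)
  fp3 <- gene_footprint(genes, chrom_lengths = lim)
  expect_equal(fp3$end, c(15000, 16000, 900))
})

test_that("gene association: any overlap for CNVs, breakpoints only for SVs", {
  fp <- tibble::tibble(gene = "APC", chrom = "pc1", start = 9, end = 100,
                       strand = "+")
  del <- make_sv_record(sv_type = "DEL", pos1 = 0, pos2 = 10)
  expect_equal(associate_genes(del, fp), "APC")

  # an inversion spanning the footprint with both breakpoints outside it
  inv <- make_sv_record(sv_type = "INV", pos1 = 0, pos2 = 500)
  expect_length(associate_genes(inv, fp), 0)
  inv2 <- make_sv_record(sv_type = "INV", pos1 = 50, pos2 = 500)
  expect_equal(associate_genes(inv2, fp), "APC")

  expect_length(associate_genes(del, fp[0, ]), 0)
})

test_that("the SV cascade matches the generator's ground-truth labels", {
  p <- generator_params(seed = 13, n_sv_per_caller = 200)
  sc <- gen_sv_cnv(p)
  res <- run_sv_cascade(sc$calls_a, sc$calls_b, sc$regions, sc$freqs,
                        sc$footprints, sc$panel)
  truth <- dplyr::bind_rows(sc$calls_a, sc$calls_b)
  m <- merge(truth[, c("id", "truth_keep")],
             res$audit[, c("id", "kept")], by = "id")
  expect_equal(nrow(m), nrow(truth))
  expect_identical(m$kept, m$truth_keep)
  expect_setequal(res$kept$id, truth$id[truth$truth_keep])
})

test_that("empty inputs produce empty outputs and flags accumulate in the audit", {
  p <- generator_params(seed = 1, n_sv_per_caller = 0)
  sc <- gen_sv_cnv(p)
  res <- run_sv_cascade(sc$calls_a, sc$calls_b, sc$regions, sc$freqs,
                        sc$footprints, sc$panel)
  expect_equal(nrow(res$kept), 0)
  expect_equal(nrow(res$audit), 0)

  # a call inside a blacklist region that is also common: both flags recorded
  regions <- tibble::tibble(chrom = "pc1", start = 0, end = 2000)
  freqs <- list(gnomadsv = make_freq_resource("DEL", pos1 = 100, pos2 = 1100,
                                              af = 0.3),
                inhouse = NULL, cohort = NULL)
  fp <- tibble::tibble(gene = "APC", chrom = "pc1", start = 0, end = 5000,
                       strand = "+")
  del <- make_sv_record(sv_type = "DEL", pos1 = 100, pos2 = 1100)
  res2 <- run_sv_cascade(del, del[0, ], regions, freqs, fp, panel = "APC")
  expect_equal(nrow(res2$kept), 0)
  expect_match(res2$audit$flags, "EXCLUDED_REGION")
  expect_match(res2$audit$flags, "COMMON")
})

test_that("q0-flagged caller-B calls are removed before matching", {
  a <- make_sv_record("A1", "DEL", pos1 = 1000, pos2 = 2000)
  b <- make_sv_record("B1", "DEL", pos1 = 1000, pos2 = 2000, caller = "B",
                      q0 = 0.9, genotype_score = 0.9)
  fp <- tibble::tibble(gene = "APC", chrom = "pc1", start = 0, end = 5000,
                       strand = "+")
  no_regions <- tibble::tibble(chrom = character(0), start = numeric(0),
                               end = numeric(0))
  res <- run_sv_cascade(a, b, no_regions, list(), fp, panel = "APC")
  expect_match(res$audit$flags[res$audit$id == "B1"], "Q0_FLAG")
  expect_false(res$audit$kept[res$audit$id == "B1"])
  # its partner loses dual-caller support and is flagged for review
  expect_match(res$audit$flags[res$audit$id == "A1"], "SINGLE_CALLER")
  expect_true(res$audit$kept[res$audit$id == "A1"])
})

test_that("single-caller CNVs are retained but marked for manual review", {
  a <- make_sv_record("A1", "DEL", pos1 = 1000, pos2 = 2000)
  fp <- tibble::tibble(gene = "APC", chrom = "pc1", start = 500, end = 3000,
                       strand = "+")
  res <- run_sv_cascade(a, a[0, ],
                        tibble::tibble(chrom = character(0), start = numeric(0),
                                       end = numeric(0)),
                        list(), fp, panel = "APC")
  expect_true(res$audit$kept)
  expect_match(res$audit$flags, "MANUAL_REVIEW")
})

test_that("BED coordinates round-trip through write and read", {
  skip_if_not_installed("rtracklayer")
  regions <- tibble::tibble(chrom = c("pc1", "pc2"), start = c(0, 12345),
                            end = c(1000, 67890))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions, path)
  back <- read_bed(path)
  expect_equal(back$chrom, regions$chrom)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
})
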