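#' Generate an annotated small-variant table
#'
#' Emits `n_small_variants` synthetic SNV/indel/DNV records with the annotation
#' columns the prioritisation cascade consumes: per-subpopulation gnomAD exome
#' (`gnex_*`) and genome (`gnge_*`) allele frequencies, cohort and in-house
#' frequencies, ClinVar status, molecular consequence, VAF and in-silico scores
#' (REVEL, PROVEAN, CADD). A proportion `fraction_common` of records is forced
#' above the 1\% frequency threshold in one randomly chosen resource; the rest
#' stay strictly below it (the exact 1\% boundary is exercised by unit tests,
#' not by random data). Roughly 10\% of records are assigned off-panel gene
#' symbols to exercise the panel restriction, and 15\% receive a low VAF.
#'
#' Each record carries a ground-truth `truth_keep` label (plus ordered
#' `truth_reasons`) computed at generation time by a direct, per-record
#' application of the filtering rules — panel membership, the strict >1\%
#' frequency gate with ClinVar LP/P rescue, and the VAF gate (<30\% for
#' SNV/DNV, <20\% for indels, never waived by rescue). This label is the
#' oracle against which [run_small_variant_cascade()] is tested.
#'
#' @param params a [generator_params()] object.
#' @param subpops subpopulation resource as from [default_subpops()].
#' @return tibble of small-variant records; zero rows (full header) when
#'   `n_small_variants = 0`.
#' @seealso [run_small_variant_cascade()]
#' @export
gen_small_variants <- function(params, subpops = default_subpops()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_small_variants
  pops <- subpops$pop
  layout <- genome_layout(params)
  panel <- synthetic_panel(params$n_genes)

  empty <- small_variant_header(pops)
  if (n == 0) return(empty)

  set.seed(params$seed)
  bases <- c("A", "C", "G", "T")

  chrom_idx <- sample.int(nrow(layout), n, replace = TRUE,
                          prob = layout$length / sum(layout$length))
  chrom <- layout$chrom[chrom_idx]
  pos <- floor(stats::runif(n, min = 1, max = layout$length[chrom_idx])) # 1-based

  consequence <- sample(c("missense", "synonymous", "inframe_indel",
                          "frameshift", "splice", "other"),
                        n, replace = TRUE,
                        prob = c(0.45, 0.20, 0.08, 0.10, 0.07, 0.10))
  variant_class <- ifelse(consequence %in% c("inframe_indel", "frameshift"),
                          "indel",
                          ifelse(stats::runif(n) < 0.05, "dnv", "snv"))

  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    if (variant_class[i] == "snv") {
      ref[i] <- sample(bases, 1)
      alt[i] <- sample(setdiff(bases, ref[i]), 1)
    } else if (variant_class[i] == "dnv") {
      ref[i] <- paste(sample(bases, 2, replace = TRUE), collapse = "")
      repeat {
        alt[i] <- paste(sample(bases, 2, replace = TRUE), collapse = "")
        if (alt[i] != ref[i]) break
      }
    } else if (consequence[i] == "inframe_indel") {
      ref[i] <- paste(sample(bases, 4, replace = TRUE), collapse = "")
      alt[i] <- substr(ref[i], 1, 1)
    } else {
      ref[i] <- sample(bases, 1)
      alt[i] <- paste(c(ref[i], sample(bases, 2, replace = TRUE)), collapse = "")
    }
  }

  off_panel <- stats::runif(n) < 0.10
  gene <- ifelse(off_panel,
                 sprintf("OFFP%03d", sample.int(50, n, replace = TRUE)),
                 sample(panel, n, replace = TRUE))

  clinvar_lp_p <- stats::runif(n) < params$fraction_clinvar_lp_p
  clinvar_status <- ifelse(
    clinvar_lp_p,
    sample(c("LP", "P"), n, replace = TRUE),
    sample(c("none", "B", "LB", "VUS"), n, replace = TRUE,
           prob = c(0.55, 0.10, 0.10, 0.25))
  )

  # heterozygous VAF around 0.5, with a low-VAF artefact fraction
  vaf <- pmin(pmax(stats::rnorm(n, 0.5, params$vaf_noise_sd), 0.01), 1)
  low <- stats::runif(n) < 0.15
  vaf[low] <- stats::runif(sum(low), 0.01, 0.28)

  # frequency annotations: common records exceed 1% in one random venue;
  # everything else sits strictly below 1% (or is absent from the resource)
  common <- stats::runif(n) < params$fraction_common
  n_venue <- 2 * length(pops) + 2   # exome pops, genome pops, cohort, in-house
  venue <- sample.int(n_venue, n, replace = TRUE)

  rare_af <- function(k) {
    x <- stats::runif(k, 0, 0.0099)
    x[stats::runif(k) < 0.5] <- NA_real_   # absent from the resource
    x
  }
  af_cols <- list()
  for (j in seq_along(pops)) {
    af_cols[[paste0("gnex_", pops[j])]] <- rare_af(n)
    af_cols[[paste0("gnge_", pops[j])]] <- rare_af(n)
  }
  cohort_af <- stats::runif(n, 0, 0.0099)
  inhouse_af <- stats::runif(n, 0, 0.0099)
  hot <- stats::runif(n, 0.0105, 0.25)
  for (i in which(common)) {
    v <- venue[i]
    if (v <= length(pops)) {
      af_cols[[paste0("gnex_", pops[v])]][i] <- hot[i]
    } else if (v <= 2 * length(pops)) {
      af_cols[[paste0("gnge_", pops[v - length(pops)])]][i] <- hot[i]
    } else if (v == 2 * length(pops) + 1) {
      cohort_af[i] <- hot[i]
    } else {
      inhouse_af[i] <- hot[i]
    }
  }

  revel <- ifelse(consequence == "missense", stats::runif(n), NA_real_)
  provean <- ifelse(consequence == "inframe_indel",
                    stats::rnorm(n, -1.5, 2), NA_real_)
  cadd <- stats::runif(n, 0, 40)
  cadd[stats::runif(n) < 0.1] <- NA_real_
  splice_impact_predicted <- stats::runif(n) < 0.1

  out <- tibble::tibble(
    id = sprintf("SV%05d", seq_len(n)),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    variant_class = variant_class, consequence = consequence, gene = gene,
    clinvar_status = clinvar_status, vaf = vaf
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(af_cols))
  out$cohort_af <- cohort_af
  out$inhouse_af <- inhouse_af
  out$revel <- revel
  out$provean <- provean
  out$cadd <- cadd
  out$splice_impact_predicted <- splice_impact_predicted

  truth <- label_small_variants(out, subpops, panel)
  out$truth_keep <- truth$keep
  out$truth_reasons <- truth$reasons
  out
}

small_variant_header <- function(pops) {
  af_cols <- stats::setNames(
    rep(list(numeric(0)), 2 * length(pops)),
    c(paste0("gnex_", pops), paste0("gnge_", pops))
  )
  dplyr::bind_cols(
    tibble::tibble(
      id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), variant_class = character(0),
      consequence = character(0), gene = character(0),
      clinvar_status = character(0), vaf = numeric(0)
    ),
    tibble::as_tibble(af_cols),
    tibble::tibble(
      cohort_af = numeric(0), inhouse_af = numeric(0), revel = numeric(0),
      provean = numeric(0), cadd = numeric(0),
      splice_impact_predicted = logical(0),
      truth_keep = logical(0), truth_reasons = character(0)
    )
  )
}

# Ground-truth labeller: a deliberately plain per-record loop applying the
# filtering rules directly. Kept free of any code shared with the cascade
# implementation so the two routes stay independent.
label_small_variants <- function(tbl, subpops, panel) {
  eligible <- subpops$pop[subpops$eligible]
  n <- nrow(tbl)
  keep <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character(0)
    if (!(tbl$gene[i] %in% panel)) r <- c(r, "PANEL")
    rescued <- tbl$clinvar_status[i] %in% c("LP", "P")
    freq_hit <- character(0)
    for (p in eligible) {
      a <- tbl[[paste0("gnex_", p)]][i]
      if (!is.na(a) && a > 0.01) freq_hit <- c(freq_hit, paste0("AF_GNOMAD_EXOME_", toupper(p)))
    }
    for (p in eligible) {
      a <- tbl[[paste0("gnge_", p)]][i]
      if (!is.na(a) && a > 0.01) freq_hit <- c(freq_hit, paste0("AF_GNOMAD_GENOME_", toupper(p)))
    }
    if (!is.na(tbl$cohort_af[i]) && tbl$cohort_af[i] > 0.01) freq_hit <- c(freq_hit, "COHORT_AF")
    if (!is.na(tbl$inhouse_af[i]) && tbl$inhouse_af[i] > 0.01) freq_hit <- c(freq_hit, "INHOUSE_AF")
    if (length(freq_hit) > 0) {
      if (rescued) r <- c(r, "CLINVAR_RESCUE") else r <- c(r, freq_hit)
    }
    drop_freq <- length(freq_hit) > 0 && !rescued
    vaf_fail <- if (tbl$variant_class[i] %in% c("snv", "dnv")) {
      tbl$vaf[i] < 0.30
    } else {
      tbl$vaf[i] < 0.20
    }
    if (vaf_fail) {
      r <- c(r, if (tbl$variant_class[i] == "indel") "VAF_INDEL" else "VAF_SNV")
    }
    keep[i] <- (tbl$gene[i] %in% panel) && !drop_freq && !vaf_fail
    reasons[i] <- collapse_reasons(r)
  }
  list(keep = keep, reasons = reasons)
}
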