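#' Generate exclusion regions and a gene table
#'
#' Deterministic resources for the SV/CNV cascade: `n_exclusion_regions`
#' blacklist intervals (1-50 kb, BED-writable, 0-based half-open) and a
#' non-overlapping gene table with transcription coordinates and strand.
#' Genes are distributed over the pseudo-chromosomes proportionally to length
#' and placed in evenly spaced slots so that footprints never collide and
#' always fit inside the genome.
#'
#' @param params a [generator_params()] object.
#' @return list with `exclusion_regions` (tibble `chrom`, `start`, `end`) and
#'   `genes` (tibble `gene`, `chrom`, `start`, `end`, `strand`).
#' @export
gen_region_resources <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  layout <- genome_layout(params)
  if (params$genome_length < params$n_genes * 5e4) {
    stop_data("genome_length too small to place %d genes", params$n_genes)
  }
  set.seed(params$seed)

  nr <- params$n_exclusion_regions
  if (nr > 0) {
    ci <- sample.int(nrow(layout), nr, replace = TRUE,
                     prob = layout$length / sum(layout$length))
    len <- floor(stats::runif(nr, 1000, 50000))
    start <- floor(stats::runif(nr, 0, layout$length[ci] - len))
    regions <- tibble::tibble(chrom = layout$chrom[ci], start = start,
                              end = start + len)
  } else {
    regions <- tibble::tibble(chrom = character(0), start = numeric(0),
                              end = numeric(0))
  }

  ng <- params$n_genes
  panel <- synthetic_panel(ng)
  if (ng > 0) {
    per_chrom <- floor(ng * layout$length / sum(layout$length))
    rem <- ng - sum(per_chrom)
    if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L
    chrom <- rep(layout$chrom, per_chrom)
    chromlen <- rep(layout$length, per_chrom)
    slot_n <- rep(per_chrom, per_chrom)
    slot_i <- unlist(lapply(per_chrom, seq_len)) - 1L
    slot_w <- floor(chromlen / pmax(slot_n, 1))
    start <- slot_i * slot_w +
      floor(stats::runif(ng, 2500, pmax(3000, slot_w * 0.3)))
    width <- floor(stats::runif(ng, 3000, pmin(30000, pmax(4000, slot_w * 0.5))))
    genes <- tibble::tibble(
      gene = panel, chrom = chrom, start = start, end = start + width,
      strand = sample(c("+", "-"), ng, replace = TRUE)
    )
  } else {
    genes <- tibble::tibble(gene = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            strand = character(0))
  }
  list(exclusion_regions = regions, genes = genes)
}

sv_header <- function() {
  tibble::tibble(
    id = character(0), sv_type = character(0), chrom1 = character(0),
    pos1 = numeric(0), chrom2 = character(0), pos2 = numeric(0),
    caller = character(0), q0 = numeric(0), genotype_score = numeric(0),
    af_gnomadsv = numeric(0), af_inhouse = numeric(0), af_cohort = numeric(0),
    truth_keep = logical(0), truth_flags = character(0)
  )
}

freq_header <- function() {
  tibble::tibble(type = character(0), chrom1 = character(0), pos1 = numeric(0),
                 chrom2 = character(0), pos2 = numeric(0), af = numeric(0))
}

#' Generate paired-caller SV/CNV call tables
#'
#' Emits a complete scenario for the SV/CNV cascade: caller A (split-read SV
#' caller; DEL, DUP, INV, INS, TRA) and caller B (read-depth CNV caller; DEL
#' and DUP only, carrying `q0` and `genotype_score`), the exclusion regions
#' and gene table from [gen_region_resources()], three population-frequency
#' resources and the panel. About 60\% of caller-A CNVs receive a caller-B
#' partner with reciprocal overlap above 0.84, 15\% a poor partner (overlap
#' 0.2-0.5), and the remainder none; caller B is padded with B-only calls so
#' both tables hold `n_sv_per_caller` records. A `fraction_common` share of
#' calls gains a matching high-frequency resource record (> 5\% AF); 10\% of
#' calls are placed wholly inside a blacklist region; 70\% are anchored on a
#' gene footprint.
#'
#' Each record carries `truth_keep` and `truth_flags` computed at generation
#' time by plain per-record loops applying the stated rules (q0, merged-region
#' coverage, resource-frequency assignment, footprint association) without any
#' of the interval machinery the cascade itself uses.
#'
#' @param params a [generator_params()] object.
#' @return list with `calls_a`, `calls_b`, `regions`, `freqs` (list of three
#'   resource tibbles), `genes`, `footprints`, `panel`.
#' @seealso [run_sv_cascade()]
#' @export
gen_sv_cnv <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  res <- gen_region_resources(params)
  layout <- genome_layout(params)
  panel <- synthetic_panel(params$n_genes)
  footprints <- gene_footprint(res$genes, chrom_lengths = layout)
  n <- params$n_sv_per_caller

  out <- list(calls_a = sv_header(), calls_b = sv_header(),
              regions = res$exclusion_regions,
              freqs = list(gnomadsv = freq_header(), inhouse = freq_header(),
                           cohort = freq_header()),
              genes = res$genes, footprints = footprints, panel = panel)
  if (n == 0) return(out)

  set.seed(params$seed + 1L)
  chrom_len <- stats::setNames(layout$length, layout$chrom)

  place_span <- function(len) {
    mode <- stats::runif(1)
    if (mode < 0.70 && nrow(footprints) > 0) {        # gene-anchored
      g <- footprints[sample.int(nrow(footprints), 1), ]
      lo <- max(0, g$start - floor(len / 2))
      hi <- max(lo + 1, min(g$end - 100, chrom_len[[g$chrom]] - len))
      s <- floor(stats::runif(1, lo, hi))
      list(chrom = g$chrom, start = s, end = s + len)
    } else if (mode < 0.80 && nrow(res$exclusion_regions) > 0) {  # blacklisted
      r <- res$exclusion_regions[sample.int(nrow(res$exclusion_regions), 1), ]
      list(chrom = r$chrom, start = r$start,
           end = min(r$end, r$start + len))
    } else {                                           # uniform
      ch <- sample(layout$chrom, 1, prob = layout$length)
      s <- floor(stats::runif(1, 0, max(1, chrom_len[[ch]] - len)))
      list(chrom = ch, start = s, end = s + len)
    }
  }
  place_point <- function() {
    if (stats::runif(1) < 0.70 && nrow(footprints) > 0) {
      g <- footprints[sample.int(nrow(footprints), 1), ]
      list(chrom = g$chrom, pos = floor(stats::runif(1, g$start, g$end)))
    } else {
      ch <- sample(layout$chrom, 1, prob = layout$length)
      list(chrom = ch, pos = floor(stats::runif(1, 0, chrom_len[[ch]])))
    }
  }

  rows_a <- list(); rows_b <- list(); freq_rows <- list()
  add_freq <- function(resource, type, chrom1, pos1, chrom2, pos2, af) {
    freq_rows[[length(freq_rows) + 1]] <<- tibble::tibble(
      resource = resource, type = type, chrom1 = chrom1, pos1 = pos1,
      chrom2 = chrom2, pos2 = pos2, af = af)
  }
  maybe_add_freq <- function(type, chrom1, pos1, chrom2, pos2) {
    resource <- sample(c("gnomadsv", "inhouse", "cohort"), 1)
    if (stats::runif(1) < params$fraction_common) {
      af <- stats::runif(1, 0.055, 0.4)
      if (type %in% c("DEL", "DUP", "INV")) {
        len <- pos2 - pos1
        j1 <- floor(stats::runif(1, 0, 0.04 * len))
        j2 <- floor(stats::runif(1, 0, 0.04 * len))
        add_freq(resource, type, chrom1, pos1 + j1, chrom2, pos2 - j2, af)
      } else {
        d1 <- floor(stats::runif(1, -50, 50))
        d2 <- floor(stats::runif(1, -50, 50))
        add_freq(resource, type, chrom1, pos1 + d1, chrom2, pos2 + d2, af)
      }
    } else if (stats::runif(1) < 0.3) {
      add_freq(resource, type, chrom1, pos1, chrom2, pos2,
               stats::runif(1, 0, 0.045))
    }
  }

  n_cnv_a <- ceiling(0.6 * n)
  ib <- 0L
  for (i in seq_len(n_cnv_a)) {
    type <- sample(c("DEL", "DUP"), 1)
    len <- floor(stats::runif(1, 2000, 150000))
    sp <- place_span(len)
    len <- sp$end - sp$start
    rows_a[[length(rows_a) + 1]] <- tibble::tibble(
      id = sprintf("A%04d", i), sv_type = type, chrom1 = sp$chrom,
      pos1 = sp$start, chrom2 = sp$chrom, pos2 = sp$end, caller = "A",
      q0 = NA_real_, genotype_score = NA_real_)
    maybe_add_freq(type, sp$chrom, sp$start, sp$chrom, sp$end)
    u <- stats::runif(1)
    if (ib < n && u < 0.60) {            # concordant partner (RO >= 0.84)
      f1 <- stats::runif(1, 0, 0.08); f2 <- stats::runif(1, 0, 0.08)
      ib <- ib + 1L
      rows_b[[length(rows_b) + 1]] <- tibble::tibble(
        id = sprintf("B%04d", ib), sv_type = type, chrom1 = sp$chrom,
        pos1 = sp$start + floor(f1 * len), chrom2 = sp$chrom,
        pos2 = sp$end - floor(f2 * len), caller = "B",
        q0 = NA_real_, genotype_score = NA_real_)
    } else if (ib < n && u < 0.75) {     # discordant partner (RO 0.2-0.5)
      d <- floor(stats::runif(1, 0.5, 0.8) * len)
      ib <- ib + 1L
      rows_b[[length(rows_b) + 1]] <- tibble::tibble(
        id = sprintf("B%04d", ib), sv_type = type, chrom1 = sp$chrom,
        pos1 = min(sp$start + d, chrom_len[[sp$chrom]] - len),
        chrom2 = sp$chrom,
        pos2 = min(sp$end + d, chrom_len[[sp$chrom]]), caller = "B",
        q0 = NA_real_, genotype_score = NA_real_)
    }
  }
  for (i in seq.int(n_cnv_a + 1L, length.out = n - n_cnv_a)) {
    type <- sample(c("INV", "INS", "TRA"), 1)
    if (type == "INV") {
      len <- floor(stats::runif(1, 2000, 100000))
      sp <- place_span(len)
      row <- tibble::tibble(id = sprintf("A%04d", i), sv_type = type,
                            chrom1 = sp$chrom, pos1 = sp$start,
                            chrom2 = sp$chrom, pos2 = sp$end, caller = "A",
                            q0 = NA_real_, genotype_score = NA_real_)
    } else if (type == "INS") {
      pt <- place_point()
      row <- tibble::tibble(id = sprintf("A%04d", i), sv_type = type,
                            chrom1 = pt$chrom, pos1 = pt$pos,
                            chrom2 = pt$chrom, pos2 = pt$pos, caller = "A",
                            q0 = NA_real_, genotype_score = NA_real_)
    } else {
      p1 <- place_point(); p2 <- place_point()
      row <- tibble::tibble(id = sprintf("A%04d", i), sv_type = type,
                            chrom1 = p1$chrom, pos1 = p1$pos,
                            chrom2 = p2$chrom, pos2 = p2$pos, caller = "A",
                            q0 = NA_real_, genotype_score = NA_real_)
    }
    rows_a[[length(rows_a) + 1]] <- row
    maybe_add_freq(type, row$chrom1, row$pos1, row$chrom2, row$pos2)
  }
  while (ib < n) {                        # B-only CNVs
    ib <- ib + 1L
    type <- sample(c("DEL", "DUP"), 1)
    len <- floor(stats::runif(1, 2000, 150000))
    sp <- place_span(len)
    rows_b[[length(rows_b) + 1]] <- tibble::tibble(
      id = sprintf("B%04d", ib), sv_type = type, chrom1 = sp$chrom,
      pos1 = sp$start, chrom2 = sp$chrom, pos2 = sp$end, caller = "B",
      q0 = NA_real_, genotype_score = NA_real_)
    maybe_add_freq(type, sp$chrom, sp$start, sp$chrom, sp$end)
  }

  calls_a <- dplyr::bind_rows(rows_a)
  calls_b <- dplyr::bind_rows(rows_b)

  # caller-B quality fields: mixture of clean, q0-flagged, waived and q0 = -1
  nb <- nrow(calls_b)
  w <- stats::runif(nb)
  calls_b$q0 <- stats::runif(nb, 0, 0.5)
  calls_b$genotype_score <- stats::runif(nb, 0.25, 1)
  hi <- w >= 0.65 & w < 0.80
  calls_b$q0[hi] <- stats::runif(sum(hi), 0.51, 0.95)
  waived <- w >= 0.80 & w < 0.90
  calls_b$q0[waived] <- stats::runif(sum(waived), 0.51, 0.95)
  calls_b$genotype_score[waived] <- stats::runif(sum(waived), 0, 0.249)
  neg <- w >= 0.90
  calls_b$q0[neg] <- -1

  freq_all <- if (length(freq_rows) > 0) dplyr::bind_rows(freq_rows) else NULL
  freqs <- lapply(c(gnomadsv = "gnomadsv", inhouse = "inhouse",
                    cohort = "cohort"), function(rs) {
    if (is.null(freq_all)) return(freq_header())
    f <- freq_all[freq_all$resource == rs,
                  c("type", "chrom1", "pos1", "chrom2", "pos2", "af")]
    if (nrow(f) == 0) freq_header() else f
  })

  calls_a <- annotate_record_afs(calls_a, freqs)
  calls_b <- annotate_record_afs(calls_b, freqs)
  calls_a <- label_sv_calls(calls_a, res$exclusion_regions, freqs, footprints,
                            panel)
  calls_b <- label_sv_calls(calls_b, res$exclusion_regions, freqs, footprints,
                            panel)

  out$calls_a <- calls_a
  out$calls_b <- calls_b
  out$freqs <- freqs
  out
}

# record-level AF annotation columns (informational; the cascade performs its
# own resource lookup)
annotate_record_afs <- function(calls, freqs) {
  n <- nrow(calls)
  rows <- lapply(seq_len(n), function(i) {
    list(sv_type = calls$sv_type[i], chrom1 = calls$chrom1[i],
         pos1 = calls$pos1[i], chrom2 = calls$chrom2[i], pos2 = calls$pos2[i])
  })
  for (nm in c("gnomadsv", "inhouse", "cohort")) {
    res <- freqs[[nm]]
    res_df <- if (is.null(res)) NULL else as.data.frame(res)
    calls[[paste0("af_", nm)]] <- vapply(rows, bf_assigned_af, numeric(1),
                                         resource = res_df)
  }
  calls
}

# ---- brute-force ground-truth helpers (plain arithmetic, no IRanges) --------
# O(n * m) scans over the raw columns; deliberately free of the interval
# machinery the cascade uses.

bf_assigned_af <- function(v, resource) {
  if (is.null(resource) || nrow(resource) == 0) return(0)
  if (v$sv_type %in% c("DEL", "DUP", "INV")) {
    sel <- resource$type == v$sv_type & resource$chrom1 == v$chrom1
    if (!any(sel)) return(0)
    p1 <- resource$pos1[sel]; p2 <- resource$pos2[sel]
    ov <- pmax(0, pmin(v$pos2, p2) - pmax(v$pos1, p1))
    ro <- pmin(ov / (v$pos2 - v$pos1), ov / (p2 - p1))
    hit <- ro >= 0.80
  } else {
    sel <- resource$type == v$sv_type & resource$chrom1 == v$chrom1 &
      resource$chrom2 == v$chrom2
    if (!any(sel)) return(0)
    hit <- abs(resource$pos1[sel] - v$pos1) <= 100 &
      abs(resource$pos2[sel] - v$pos2) <= 100
  }
  if (!any(hit)) 0 else max(resource$af[sel][hit])
}

bf_region_coverage <- function(chrom, s, e, regions) {
  if (nrow(regions) == 0) return(0)
  seg <- regions[regions$chrom == chrom & regions$end > s & regions$start < e, ,
                 drop = FALSE]
  if (nrow(seg) == 0) return(0)
  a <- pmax(seg$start, s); b <- pmin(seg$end, e)
  o <- order(a)
  a <- a[o]; b <- b[o]
  covered <- 0; cur_a <- a[1]; cur_b <- b[1]
  for (k in seq_along(a)[-1]) {
    if (a[k] <= cur_b) {
      cur_b <- max(cur_b, b[k])
    } else {
      covered <- covered + (cur_b - cur_a)
      cur_a <- a[k]; cur_b <- b[k]
    }
  }
  covered <- covered + (cur_b - cur_a)
  covered / (e - s)
}

bf_point_in_regions <- function(chrom, pos, regions) {
  any(regions$chrom == chrom & pos >= regions$start & pos < regions$end)
}

label_sv_calls <- function(calls, regions, freqs, footprints, panel) {
  n <- nrow(calls)
  keep <- logical(n); flags <- character(n)
  fp <- as.data.frame(footprints[footprints$gene %in% panel, , drop = FALSE])
  reg <- as.data.frame(regions)
  freq_dfs <- lapply(freqs, function(r) if (is.null(r)) NULL else as.data.frame(r))
  for (i in seq_len(n)) {
    v <- list(sv_type = calls$sv_type[i], chrom1 = calls$chrom1[i],
              pos1 = calls$pos1[i], chrom2 = calls$chrom2[i],
              pos2 = calls$pos2[i], caller = calls$caller[i],
              q0 = calls$q0[i], genotype_score = calls$genotype_score[i])
    f <- character(0)
    if (v$caller == "B" && !is.na(v$q0) &&
        (v$q0 < 0 || v$q0 > 0.5) &&
        !(!is.na(v$genotype_score) && v$genotype_score < 0.25)) {
      f <- c(f, "Q0_FLAG")
    }
    span_type <- v$sv_type %in% c("DEL", "DUP", "INV")
    excl <- if (span_type) {
      bf_region_coverage(v$chrom1, v$pos1, v$pos2, reg) >= 0.80
    } else {
      bf_point_in_regions(v$chrom1, v$pos1, reg) ||
        bf_point_in_regions(v$chrom2, v$pos2, reg)
    }
    if (excl) f <- c(f, "EXCLUDED_REGION")
    afs <- vapply(freq_dfs, function(r) bf_assigned_af(v, r), numeric(1))
    if (any(afs > 0.05)) f <- c(f, "COMMON")
    hit <- if (v$sv_type %in% c("DEL", "DUP")) {
      fp$chrom == v$chrom1 & fp$start < v$pos2 & fp$end > v$pos1
    } else {
      (fp$chrom == v$chrom1 & v$pos1 >= fp$start & v$pos1 < fp$end) |
        (fp$chrom == v$chrom2 & v$pos2 >= fp$start & v$pos2 < fp$end)
    }
    if (!any(hit)) f <- c(f, "NO_PANEL_GENE")
    keep[i] <- length(f) == 0
    flags[i] <- collapse_reasons(f)
  }
  calls$truth_keep <- keep
  calls$truth_flags <- flags
  calls
}
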