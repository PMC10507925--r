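#' Reciprocal overlap between two half-open intervals
#'
#' The concordance criterion used to decide whether two CNV calls describe the
#' same event: `min(|a-and-b| / |a|, |a-and-b| / |b|)`. Both intervals must be
#' 0-based half-open and lie on the same chromosome (callers must check the
#' chromosome before calling). Vectorised over all four arguments.
#'
#' @param a_start,a_end first interval, 0-based half-open.
#' @param b_start,b_end second interval, 0-based half-open.
#' @return numeric fraction in \[0, 1\]; 0 when disjoint.
#' @examples
#' reciprocal_overlap(1000, 2000, 1100, 2000)  # 0.9
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  if (any(a_end <= a_start) || any(b_end <= b_start)) {
    stop_data("reciprocal_overlap: zero- or negative-length interval")
  }
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  pmin(ov / (a_end - a_start), ov / (b_end - b_start))
}

#' Read-quality flag for copy-number calls (caller B)
#'
#' A CNV from the read-depth caller is flagged for removal when its fraction
#' of zero-mapping-quality reads (`q0`) is below 0 or above 0.5, unless the
#' genotype score is below 0.25 (low genotype scores mark calls where q0 is
#' not trusted and the call is kept for downstream review).
#'
#' @param q0 numeric q0 value(s); must be present for caller-B records.
#' @param genotype_score numeric genotype score(s); `NA` treated as not < 0.25.
#' @return logical: `TRUE` when the call is flagged for removal.
#' @export
q0_flag <- function(q0, genotype_score = NA_real_) {
  if (any(is.na(q0))) stop_data("q0_flag: missing q0 for a caller-B record")
  extreme <- q0 < 0 | q0 > 0.5
  waived <- !is.na(genotype_score) & genotype_score < 0.25
  extreme & !waived
}

#' Match CNV calls between two callers by reciprocal overlap
#'
#' Pairs deletion/duplication calls from caller A with same-type calls from
#' caller B whose reciprocal overlap is at least 0.80, greedily by descending
#' overlap (ties broken by the lexicographically smaller id pair), each call
#' matched at most once. Matched calls are marked concordant; every other call
#' is flagged `SINGLE_CALLER` and `MANUAL_REVIEW`.
#'
#' @param calls_a,calls_b tibbles of DEL/DUP records with columns `id`,
#'   `sv_type`, `chrom1`, `pos1`, `pos2`.
#' @param min_overlap concordance threshold (default 0.80, inclusive).
#' @return the row-bound calls annotated with `matched_id`, `overlap`,
#'   `concordant` and a `flags` string column.
#' @export
match_cnv_calls <- function(calls_a, calls_b, min_overlap = 0.80) {
  for (tb in list(calls_a, calls_b)) {
    assert_cols(tb, c("id", "sv_type", "chrom1", "pos1", "pos2"), "CNV call table")
    if (nrow(tb) > 0 && !all(tb$sv_type %in% c("DEL", "DUP"))) {
      stop_data("match_cnv_calls accepts DEL/DUP records only")
    }
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(calls_a, caller = "A"),
    dplyr::mutate(calls_b, caller = "B")
  )
  out$matched_id <- NA_character_
  out$overlap <- NA_real_

  if (nrow(calls_a) > 0 && nrow(calls_b) > 0) {
    # candidate pairs: same type, same chromosome, reciprocal overlap >= cutoff
    cand <- NULL
    for (i in seq_len(nrow(calls_a))) {
      same <- which(calls_b$sv_type == calls_a$sv_type[i] &
                    calls_b$chrom1 == calls_a$chrom1[i])
      if (length(same) == 0) next
      ro <- reciprocal_overlap(calls_a$pos1[i], calls_a$pos2[i],
                               calls_b$pos1[same], calls_b$pos2[same])
      hit <- ro >= min_overlap
      if (any(hit)) {
        cand <- rbind(cand, data.frame(ia = i, ib = same[hit], ro = ro[hit]))
      }
    }
    if (!is.null(cand)) {
      cand <- cand[order(-cand$ro, calls_a$id[cand$ia], calls_b$id[cand$ib]), ,
                   drop = FALSE]
      used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
      for (k in seq_len(nrow(cand))) {
        ia <- cand$ia[k]; ib <- cand$ib[k]
        if (used_a[ia] || used_b[ib]) next
        used_a[ia] <- TRUE; used_b[ib] <- TRUE
        ra <- which(out$caller == "A")[ia]
        rb <- which(out$caller == "B")[ib]
        out$matched_id[ra] <- calls_b$id[ib]
        out$matched_id[rb] <- calls_a$id[ia]
        out$overlap[c(ra, rb)] <- cand$ro[k]
      }
    }
  }
  out$concordant <- !is.na(out$matched_id)
  out$flags <- ifelse(out$concordant, "", "SINGLE_CALLER,MANUAL_REVIEW")
  out
}

# vectorised region flags for a whole call table against reduced regions;
# agrees with region_exclusion_flag() record by record
cascade_region_flags <- function(calls, red, min_coverage = 0.80) {
  n <- nrow(calls)
  excl <- logical(n)
  if (n == 0 || length(red) == 0) return(excl)
  span <- calls$sv_type %in% c("DEL", "DUP", "INV")
  if (any(span)) {
    spans <- GenomicRanges::GRanges(
      calls$chrom1[span],
      IRanges::IRanges(calls$pos1[span] + 1L, calls$pos2[span]))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(spans, red))
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      ints <- GenomicRanges::pintersect(spans[q],
                                        red[S4Vectors::subjectHits(hits)])
      cov <- tapply(GenomicRanges::width(ints), q, sum)
      frac <- rep(0, sum(span))
      frac[as.integer(names(cov))] <- cov
      excl[span] <- frac / (calls$pos2[span] - calls$pos1[span]) >= min_coverage
    }
  }
  if (any(!span)) {
    bp_in <- function(chrom, pos) {
      suppressWarnings(IRanges::overlapsAny(GenomicRanges::GRanges(
        chrom, IRanges::IRanges(pos + 1L, pos + 1L)), red))
    }
    excl[!span] <- bp_in(calls$chrom1[!span], calls$pos1[!span]) |
      bp_in(calls$chrom2[!span], calls$pos2[!span])
  }
  excl
}

# vectorised panel-gene association; agrees with associate_genes() per record
cascade_gene_lists <- function(calls, fp) {
  n <- nrow(calls)
  genes <- rep(list(character(0)), n)
  if (n == 0 || nrow(fp) == 0) return(genes)
  fp_gr <- GenomicRanges::GRanges(fp$chrom,
                                  IRanges::IRanges(fp$start + 1, fp$end))
  cnv <- which(calls$sv_type %in% c("DEL", "DUP"))
  if (length(cnv) > 0) {
    spans <- GenomicRanges::GRanges(
      calls$chrom1[cnv],
      IRanges::IRanges(calls$pos1[cnv] + 1L, calls$pos2[cnv]))
    h <- suppressWarnings(GenomicRanges::findOverlaps(spans, fp_gr))
    byq <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    for (qi in names(byq)) {
      genes[[cnv[as.integer(qi)]]] <- fp$gene[byq[[qi]]]
    }
  }
  oth <- which(!(calls$sv_type %in% c("DEL", "DUP")))
  if (length(oth) > 0) {
    for (side in 1:2) {
      ch <- if (side == 1) calls$chrom1[oth] else calls$chrom2[oth]
      po <- if (side == 1) calls$pos1[oth] else calls$pos2[oth]
      pts <- GenomicRanges::GRanges(ch, IRanges::IRanges(po + 1L, po + 1L))
      h <- suppressWarnings(GenomicRanges::findOverlaps(pts, fp_gr))
      byq <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
      for (qi in names(byq)) {
        i <- oth[as.integer(qi)]
        genes[[i]] <- unique(c(genes[[i]], fp$gene[byq[[qi]]]))
      }
    }
  }
  genes
}

# union of exclusion regions as a reduced GRanges (internal 0-based half-open
# intervals are converted to the 1-based closed convention IRanges uses)
regions_as_granges <- function(regions) {
  if (nrow(regions) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  ))
}

#' Blacklist-region exclusion flag for one SV/CNV record
#'
#' Deletions, duplications and inversions are flagged when at least 80\% of
#' their span is covered by the union of exclusionary regions (merged-region
#' coverage, the BEDTools `-f 0.80` semantics). Translocations and insertions
#' are flagged when either breakpoint falls inside any region.
#'
#' @param v one SV/CNV record (one-row data frame or list) with `sv_type`,
#'   `chrom1`, `pos1`, `chrom2`, `pos2` in 0-based half-open coordinates.
#' @param regions tibble of exclusion intervals (`chrom`, `start`, `end`),
#'   0-based half-open.
#' @param min_coverage coverage threshold for span types (default 0.80).
#' @return logical.
#' @export
region_exclusion_flag <- function(v, regions, min_coverage = 0.80) {
  red <- if (inherits(regions, "GRanges")) regions else regions_as_granges(regions)
  if (length(red) == 0) return(FALSE)
  if (v$sv_type %in% c("DEL", "DUP", "INV")) {
    span <- GenomicRanges::GRanges(v$chrom1,
                                   IRanges::IRanges(v$pos1 + 1L, v$pos2))
    covered <- sum(GenomicRanges::width(GenomicRanges::intersect(
      red, span, ignore.strand = TRUE)))
    covered / (v$pos2 - v$pos1) >= min_coverage
  } else {
    bp <- GenomicRanges::GRanges(
      c(v$chrom1, v$chrom2),
      IRanges::IRanges(c(v$pos1, v$pos2) + 1L, c(v$pos1, v$pos2) + 1L))
    # disjoint seqlevels (breakpoint chromosome absent from the region set)
    # are a legitimate no-overlap outcome, not a condition worth warning about
    any(suppressWarnings(IRanges::overlapsAny(bp, red)))
  }
}

# assigned population AF for one record against one frequency resource table
assigned_af <- function(v, resource, min_overlap = 0.80, window = 100L) {
  if (is.null(resource) || nrow(resource) == 0) return(0)
  same <- resource[resource$type == v$sv_type, , drop = FALSE]
  if (nrow(same) == 0) return(0)
  if (v$sv_type %in% c("DEL", "DUP", "INV")) {
    same <- same[same$chrom1 == v$chrom1, , drop = FALSE]
    if (nrow(same) == 0) return(0)
    ro <- reciprocal_overlap(v$pos1, v$pos2, same$pos1, same$pos2)
    hit <- ro >= min_overlap
  } else {
    hit <- same$chrom1 == v$chrom1 & same$chrom2 == v$chrom2 &
      abs(same$pos1 - v$pos1) <= window & abs(same$pos2 - v$pos2) <= window
  }
  if (!any(hit)) 0 else max(same$af[hit])
}

#' Population-frequency exclusion flag for one SV/CNV record
#'
#' Assigns the record an allele frequency from each of three resources
#' (gnomAD-SV-like, in-house, within-cohort) and flags it when any assigned
#' frequency is strictly above 5\%. For DEL/DUP/INV the assigned AF is the
#' maximum over same-type resource records with reciprocal overlap >= 0.80;
#' for TRA/INS, over resource records whose two breakpoints each lie within
#' 100 bp of the call's.
#'
#' @param v one SV/CNV record (see [region_exclusion_flag()]).
#' @param gnomadsv,inhouse,cohort frequency resource tibbles with columns
#'   `type`, `chrom1`, `pos1`, `chrom2`, `pos2`, `af`.
#' @param max_af frequency threshold (default 0.05, strict).
#' @return logical.
#' @export
frequency_flag <- function(v, gnomadsv = NULL, inhouse = NULL, cohort = NULL,
                           max_af = 0.05) {
  afs <- c(assigned_af(v, gnomadsv), assigned_af(v, inhouse),
           assigned_af(v, cohort))
  any(afs > max_af)
}

#' Gene footprints from a transcription-coordinate table
#'
#' Extends each gene's transcribed interval 2000 bp upstream of the
#' transcription start: on the + strand the footprint is
#' `[start - 2000, end)`, on the - strand `[start, end + 2000)`. With
#' `stranded = FALSE` the extension is always applied on the left, matching a
#' strandless annotation convention. Footprints are clipped at 0 and at the
#' chromosome length when `chrom_lengths` is supplied.
#'
#' @param genes tibble with `gene`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open transcription coordinates).
#' @param upstream extension in bp (default 2000).
#' @param chrom_lengths optional tibble (`chrom`, `length`) for clipping.
#' @param stranded apply the extension on the strand-aware side (default).
#' @return tibble with `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
gene_footprint <- function(genes, upstream = 2000L, chrom_lengths = NULL,
                           stranded = TRUE) {
  assert_cols(genes, c("gene", "chrom", "start", "end", "strand"), "gene table")
  if (nrow(genes) > 0 && any(genes$end <= genes$start)) {
    stop_data("gene table has end <= start")
  }
  start <- genes$start
  end <- genes$end
  if (stranded) {
    plus <- genes$strand == "+"
    start[plus] <- start[plus] - upstream
    end[!plus] <- end[!plus] + upstream
  } else {
    start <- start - upstream
  }
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths$length[match(genes$chrom, chrom_lengths$chrom)]
    end <- pmin(end, lim)
  }
  tibble::tibble(gene = genes$gene, chrom = genes$chrom,
                 start = as.numeric(start), end = as.numeric(end),
                 strand = genes$strand)
}

#' Genes associated with one SV/CNV record
#'
#' Copy-number events (DEL/DUP) are associated with every gene footprint they
#' overlap by at least one base. Other SV types (INV/INS/TRA) are associated
#' only with footprints containing one or both breakpoints.
#'
#' @param v one SV/CNV record.
#' @param footprints footprint tibble as from [gene_footprint()].
#' @return character vector of gene symbols (possibly empty).
#' @export
associate_genes <- function(v, footprints) {
  if (nrow(footprints) == 0) return(character(0))
  if (v$sv_type %in% c("DEL", "DUP")) {
    hit <- footprints$chrom == v$chrom1 &
      footprints$start < v$pos2 & footprints$end > v$pos1
  } else {
    in_fp <- function(chrom, pos) {
      footprints$chrom == chrom & pos >= footprints$start & pos < footprints$end
    }
    hit <- in_fp(v$chrom1, v$pos1) | in_fp(v$chrom2, v$pos2)
  }
  footprints$gene[hit]
}

#' Run the full SV/CNV prioritisation cascade
#'
#' Applies, in order: the q0 quality rule (flagged caller-B calls are removed
#' before concordance matching), dual-caller CNV concordance by reciprocal
#' overlap, blacklist-region exclusion, population-frequency exclusion, and
#' gene association against panel-gene footprints. A record is retained when
#' it carries no exclusion flag and is associated with at least one panel
#' gene; single-caller CNVs are retained but flagged `MANUAL_REVIEW`.
#' Non-CNV types from caller A are not subject to the dual-caller requirement.
#'
#' @param calls_a,calls_b call tables (caller A: SV caller, may contain all
#'   types; caller B: CNV caller, DEL/DUP with `q0`/`genotype_score`).
#' @param regions exclusion-region tibble (`chrom`, `start`, `end`).
#' @param freqs named list of frequency resources `gnomadsv`, `inhouse`,
#'   `cohort` (each may be `NULL`).
#' @param footprints gene footprints as from [gene_footprint()].
#' @param panel character vector of panel gene symbols.
#' @return list with `kept` (retained records, with a `genes` list-column and
#'   flags) and `audit` (one row per input record with every flag).
#' @export
run_sv_cascade <- function(calls_a, calls_b, regions, freqs, footprints,
                           panel) {
  cnv_a <- calls_a[calls_a$sv_type %in% c("DEL", "DUP"), , drop = FALSE]
  oth_a <- calls_a[!(calls_a$sv_type %in% c("DEL", "DUP")), , drop = FALSE]
  if (nrow(calls_b) > 0) {
    b_q0 <- q0_flag(calls_b$q0, calls_b$genotype_score)
  } else {
    b_q0 <- logical(0)
  }
  b_removed <- calls_b[b_q0, , drop = FALSE]
  b_live <- calls_b[!b_q0, , drop = FALSE]

  matched <- match_cnv_calls(cnv_a, b_live)
  all_calls <- dplyr::bind_rows(
    matched,
    if (nrow(oth_a) > 0) dplyr::mutate(oth_a, caller = "A", flags = "")
  )

  fp_panel <- footprints[footprints$gene %in% panel, , drop = FALSE]
  red <- regions_as_granges(regions)

  n <- nrow(all_calls)
  excl <- cascade_region_flags(all_calls, red)
  genes <- cascade_gene_lists(all_calls, fp_panel)
  freq_dfs <- lapply(freqs[c("gnomadsv", "inhouse", "cohort")],
                     function(r) if (is.null(r) || nrow(r) == 0) NULL
                                 else as.data.frame(r))
  kept <- logical(n)
  flags <- all_calls$flags %||% rep("", n)
  for (i in seq_len(n)) {
    v <- list(sv_type = all_calls$sv_type[i], chrom1 = all_calls$chrom1[i],
              pos1 = all_calls$pos1[i], chrom2 = all_calls$chrom2[i],
              pos2 = all_calls$pos2[i])
    f <- if (nzchar(flags[i])) strsplit(flags[i], ",")[[1]] else character(0)
    if (excl[i]) f <- c(f, "EXCLUDED_REGION")
    if (frequency_flag(v, freq_dfs$gnomadsv, freq_dfs$inhouse,
                       freq_dfs$cohort)) {
      f <- c(f, "COMMON")
    }
    if (length(genes[[i]]) == 0) f <- c(f, "NO_PANEL_GENE")
    drop_flags <- c("EXCLUDED_REGION", "COMMON", "NO_PANEL_GENE")
    kept[i] <- !any(f %in% drop_flags)
    flags[i] <- collapse_reasons(f)
  }
  all_calls$flags <- flags
  all_calls$genes <- genes
  all_calls$kept <- kept

  audit_removed <- if (nrow(b_removed) > 0) {
    tibble::tibble(id = b_removed$id, caller = "B", flags = "Q0_FLAG",
                   genes = "", kept = FALSE)
  }
  audit <- dplyr::bind_rows(
    tibble::tibble(
      id = all_calls$id, caller = all_calls$caller, flags = all_calls$flags,
      genes = vapply(genes, function(g) paste(g, collapse = ","), character(1)),
      kept = kept
    ),
    audit_removed
  )
  list(kept = all_calls[kept, , drop = FALSE], audit = audit)
}
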