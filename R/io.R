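# Readers and writers for the plain-text interchange formats. Internal SV/CNV
# and BED coordinates are 0-based half-open; small-variant positions are
# 1-based (the VCF convention).

#' Write small variants as TSV
#' @param variants small-variant tibble.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_small_variants_tsv <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Read small variants from TSV
#' @param path input file written by [write_small_variants_tsv()].
#' @return tibble.
#' @export
read_small_variants_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}

vcf_info_value <- function(x) {
  ifelse(is.na(x), ".", as.character(x))
}

#' Write small variants as VCF v4.2
#'
#' Annotations travel in INFO under the keys `VAF`, `GNEX_<POP>`,
#' `GNGE_<POP>`, `COHORT_AF`, `INHOUSE_AF`, `CLINVAR`, `CSQ`, `REVEL`,
#' `PROVEAN`, `CADD`, `GENE`. Missing values are omitted from INFO.
#'
#' @param variants small-variant tibble.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_small_variants_vcf <- function(variants, path) {
  pops <- toupper(sub("^gnex_", "", grep("^gnex_", names(variants), value = TRUE)))
  keys <- c("VAF", paste0("GNEX_", pops), paste0("GNGE_", pops),
            "COHORT_AF", "INHOUSE_AF", "REVEL", "PROVEAN", "CADD")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varcascade",
    vapply(keys, function(k) sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k),
      character(1)),
    "##INFO=<ID=CLINVAR,Number=1,Type=String,Description=\"ClinVar status\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Variant class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    fields <- c(VAF = v$vaf)
    for (p in tolower(pops)) {
      fields[paste0("GNEX_", toupper(p))] <- v[[paste0("gnex_", p)]]
      fields[paste0("GNGE_", toupper(p))] <- v[[paste0("gnge_", p)]]
    }
    fields <- c(fields, COHORT_AF = v$cohort_af, INHOUSE_AF = v$inhouse_af,
                REVEL = v$revel, PROVEAN = v$provean, CADD = v$cadd)
    num <- fields[!is.na(fields)]
    parts <- c(sprintf("%s=%g", names(num), num),
               sprintf("CLINVAR=%s", v$clinvar_status),
               sprintf("CSQ=%s", v$consequence),
               sprintf("GENE=%s", v$gene),
               sprintf("VCLASS=%s", v$variant_class))
    paste(parts, collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  variants$chrom, variants$pos, variants$id,
                  variants$ref, variants$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read small variants from a VCF written by [write_small_variants_vcf()]
#'
#' Parsing is delegated to the vcfR package.
#'
#' @param path VCF file.
#' @return tibble in the layout of [gen_small_variants()] (without the
#'   ground-truth columns).
#' @export
read_small_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_data("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  get_info <- function(key, numeric = TRUE) {
    x <- vcfR::extract.info(v, element = key, as.numeric = numeric)
    if (numeric) as.numeric(x) else as.character(x)
  }
  out <- tibble::tibble(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    variant_class = get_info("VCLASS", numeric = FALSE),
    consequence = get_info("CSQ", numeric = FALSE),
    gene = get_info("GENE", numeric = FALSE),
    clinvar_status = get_info("CLINVAR", numeric = FALSE),
    vaf = get_info("VAF")
  )
  info_keys <- regmatches(v@meta, regexpr("(?<=ID=)[A-Z_]+", v@meta, perl = TRUE))
  for (k in grep("^GNEX_|^GNGE_", info_keys, value = TRUE)) {
    out[[tolower(sub("^(GNEX|GNGE)_", "\\L\\1_", k, perl = TRUE))]] <- get_info(k)
  }
  out$cohort_af <- get_info("COHORT_AF")
  out$inhouse_af <- get_info("INHOUSE_AF")
  out$revel <- get_info("REVEL")
  out$provean <- get_info("PROVEAN")
  out$cadd <- get_info("CADD")
  out
}

#' Write intervals as BED (0-based half-open)
#' @param regions tibble with `chrom`, `start`, `end`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 0-based half-open intervals
#'
#' Import is delegated to rtracklayer, whose 1-based closed ranges are
#' converted back to the BED convention.
#'
#' @param path BED file.
#' @return tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_data("reading BED requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Write a gene table as 6-column BED-like TSV
#' @param genes tibble with `gene`, `chrom`, `start`, `end`, `strand`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom,
               format(genes$start, scientific = FALSE, trim = TRUE),
               format(genes$end, scientific = FALSE, trim = TRUE),
               genes$gene, 0L, genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED-like gene table
#' @param path file written by [write_gene_bed()].
#' @return tibble with `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(gene = df$V4, chrom = df$V1, start = df$V2, end = df$V3,
                 strand = df$V6)
}

#' Write SV/CNV calls as TSV
#' @param calls SV/CNV tibble.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_sv_tsv <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' Read SV/CNV calls from TSV
#' @param path file written by [write_sv_tsv()].
#' @return tibble.
#' @export
read_sv_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write the economic configuration as YAML
#' @param cfg an `econ_config`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_econ_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read and validate an economic configuration from YAML
#' @param path file written by [write_econ_config()].
#' @return validated `econ_config`.
#' @export
read_econ_config <- function(path) {
  validate_econ_config(yaml::read_yaml(path))
}

#' Write case reports as JSON lines
#' @param reports report tibble from [build_reports()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_reports_json <- function(reports, path) {
  lines <- vapply(seq_len(nrow(reports)), function(i) {
    jsonlite::toJSON(as.list(reports[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort summary as JSON
#' @param summary a `cohort_summary`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
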