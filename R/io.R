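#' Write a variant table as minimal VCF v4.2
#'
#' Emits per-sample GT plus the INFO keys [read_variants()] consumes
#' (`GENE`, `CSQ_CLASS`, `MAF`, `PP2_CAT`, `PP2_SCORE`, `SIFT_CAT`,
#' `SIFT_SCORE`); dbSNP ids go in the ID column.
#'
#' @param vt a [variant_table()].
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vt, path) {
  s <- vt$sites
  samples <- colnames(vt$genotypes)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=famvarscan",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency">',
    '##INFO=<ID=PP2_CAT,Number=1,Type=String,Description="PolyPhen-2 category">',
    '##INFO=<ID=PP2_SCORE,Number=1,Type=Float,Description="PolyPhen-2 score">',
    '##INFO=<ID=SIFT_CAT,Number=1,Type=String,Description="SIFT category">',
    '##INFO=<ID=SIFT_SCORE,Number=1,Type=Float,Description="SIFT score">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  info_field <- function(i) {
    kv <- c(
      if (!is.na(s$gene[i])) paste0("GENE=", gsub(" ", "_", s$gene[i])),
      paste0("CSQ_CLASS=", s$consequence[i]),
      if (!is.na(s$maf[i])) paste0("MAF=", format(s$maf[i], scientific = FALSE)),
      if (!is.na(s$polyphen_cat[i]))
        paste0("PP2_CAT=", gsub(" ", "_", s$polyphen_cat[i])),
      if (!is.na(s$polyphen_score[i]))
        paste0("PP2_SCORE=", s$polyphen_score[i]),
      if (!is.na(s$sift_cat[i])) paste0("SIFT_CAT=", gsub(" ", "_", s$sift_cat[i])),
      if (!is.na(s$sift_score[i])) paste0("SIFT_SCORE=", s$sift_score[i]))
    paste(kv, collapse = ";")
  }
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
              missing = "./.")
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i],
            if (is.na(s$dbsnp_id[i])) "." else s$dbsnp_id[i],
            s$ref[i], s$alt[i], ".", "PASS", info_field(i), "GT",
            gt_map[vt$genotypes[i, ]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a long qPCR Ct table from CSV
#'
#' Columns: `sample_id`, `gene`, `ct` (empty = undetected), and
#' optionally `mycn_status`.
#'
#' @param path CSV path.
#' @return data.frame with `ct` numeric (`NA` where undetected).
#' @export
read_ct_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(tab)))
  tab$ct <- suppressWarnings(as.numeric(tab$ct))
  if (any(!is.na(tab$ct) & (tab$ct <= 0 | tab$ct > 45)))
    stop("Ct values must lie in (0, 45]")
  tab
}

#' Write a long qPCR Ct table to CSV
#' @param ct_table data.frame as read by [read_ct_csv()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a survival table from CSV
#'
#' Columns: `sample_id`, `time_months`, `event` (0/1 or TRUE/FALSE),
#' `expression`, and optional strata tags `mycn_status`, `stage`
#' (1-4 or `localized`/`metastatic`), `relapse_or_progression`.
#'
#' @param path CSV path.
#' @return data.frame with `time`, `event` (logical), `expression`,
#'   `stage_class` derived from `stage` when numeric (1-3 localized,
#'   4 metastatic).
#' @export
read_survival_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time_months", "event") %in% names(tab)))
  out <- data.frame(sample_id = tab$sample_id,
                    time = as.numeric(tab$time_months),
                    event = as.logical(tab$event),
                    stringsAsFactors = FALSE)
  if ("expression" %in% names(tab)) out$expression <- as.numeric(tab$expression)
  if ("mycn_status" %in% names(tab)) out$mycn_status <- tab$mycn_status
  if ("stage_class" %in% names(tab)) {
    out$stage_class <- tab$stage_class
  } else if ("stage" %in% names(tab)) {
    st <- suppressWarnings(as.integer(tab$stage))
    out$stage_class <- ifelse(!is.na(st) & st <= 3, "localized",
                              "metastatic")
  }
  if ("relapse_or_progression" %in% names(tab))
    out$relapse_or_progression <- as.logical(tab$relapse_or_progression)
  .check_survival_records(out)
}

#' Write a survival table to CSV
#' @param records survival data.frame (columns as produced by
#'   [simulate_survival_cohort()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(records, path) {
  out <- data.frame(sample_id = records$sample_id,
                    time_months = records$time,
                    event = as.integer(records$event),
                    expression = records$expression,
                    mycn_status = records$mycn_status,
                    stage_class = records$stage_class,
                    relapse_or_progression =
                      as.integer(records$relapse_or_progression))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
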