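REPORT_SCHEMA_VERSION <- "1.0"

.stage_log <- function(log, stage, n_in, n_out, verbose) {
  if (verbose) message(sprintf("[%s] %d -> %d", stage, n_in, n_out))
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                        stringsAsFactors = FALSE))
}

#' Run the variant discovery cascade end to end
#'
#' Executes read (or takes an in-memory table) -> shared-by-affected ->
#' absent-in-unaffected -> rarity -> consequence -> segregation, logging
#' every stage's input and output counts, and writes a cascade summary
#' (whole-exome statistics layout), a candidate table (chromosome,
#' position, reference base, IUPAC heterozygote code, gene, PolyPhen-2,
#' SIFT), a segregation report and a machine-readable JSON result.
#'
#' @param config list with elements: `vcf` (path) or `table` (a
#'   [variant_table()]); `ped` (path to PED) or `pedigree`;
#'   `affected_ids`, `unaffected_ids` (required, non-empty);
#'   `maf_threshold` (default 0.01); `consequence_keep` (default
#'   `"missense"`); `out_dir` (optional; no files written when absent).
#' @param verbose log stage counts via `message()` (default TRUE).
#' @return list of class `discovery_report`: `stages` (count log),
#'   `summary`, `candidates`, `segregation`, `candidate_table`,
#'   `n_genes`, `result` (the JSON-serializable payload).
#' @export
run_discovery <- function(config, verbose = TRUE) {
  if (is.null(config$affected_ids) || length(config$affected_ids) == 0)
    stop("config must list non-empty affected_ids")
  if (is.null(config$unaffected_ids) || length(config$unaffected_ids) == 0)
    stop("config must list non-empty unaffected_ids")
  maf_thr <- if (is.null(config$maf_threshold)) 0.01 else config$maf_threshold
  keep <- if (is.null(config$consequence_keep)) "missense" else config$consequence_keep

  vt <- if (!is.null(config$table)) config$table
        else if (!is.null(config$vcf)) read_variants(config$vcf)
        else stop("config must provide either a VCF path or a variant table")
  ped <- if (!is.null(config$pedigree)) config$pedigree
         else if (!is.null(config$ped)) read_ped(config$ped)
         else NULL

  log <- NULL
  n0 <- n_variants(vt)
  shared <- shared_by_affected(vt, config$affected_ids)
  log <- .stage_log(log, "shared_by_affected", n0, n_variants(shared), verbose)
  priv <- absent_in_unaffected(shared, config$unaffected_ids)
  log <- .stage_log(log, "absent_in_unaffected", n_variants(shared),
                    n_variants(priv), verbose)
  rar <- rarity_filter(priv, maf_thr)
  log <- .stage_log(log, "rarity_filter", n_variants(priv),
                    n_variants(rar$novel_or_rare), verbose)
  cons <- consequence_filter(rar$novel_or_rare, keep)
  log <- .stage_log(log, "consequence_filter", n_variants(rar$novel_or_rare),
                    n_variants(cons$variants), verbose)

  summary_tab <- cascade_summary(vt, shared = shared)
  seg <- if (!is.null(ped) && n_variants(cons$variants) > 0)
    segregation_analysis(cons$variants, ped) else NULL
  cand_tab <- if (n_variants(cons$variants) > 0)
    candidate_table(cons$variants) else NULL

  result <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    parameters = list(maf_threshold = maf_thr, consequence_keep = keep,
                      affected_ids = config$affected_ids,
                      unaffected_ids = config$unaffected_ids),
    stages = log,
    n_candidate_variants = n_variants(cons$variants),
    n_candidate_genes = cons$n_genes,
    candidate_keys = cons$variants$key,
    n_segregating = if (is.null(seg)) NA_integer_ else sum(seg$segregates))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(config$out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    w(summary_tab, "cascade_summary.tsv")
    w(cand_tab, "candidates.tsv")
    w(seg, "segregation.tsv")
    jsonlite::write_json(result, file.path(config$out_dir, "discovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(stages = log, summary = summary_tab,
                 candidates = cons$variants, candidate_table = cand_tab,
                 segregation = seg, n_genes = cons$n_genes,
                 result = result),
            class = "discovery_report")
}

#' Run the expression and survival follow-up analyses
#'
#' With qPCR input: geNorm reference ranking -> calibrated relative
#' quantities -> positivity -> MYCN association tests. With survival
#' input: the stratified overall-survival cutoff scans, each stamped
#' with a multiplicity warning. Either input may be omitted and its
#' stage is skipped cleanly.
#'
#' @param config list with elements: `ct_csv` (path) or `ct_table`
#'   (data.frame); `survival_csv` (path) or `survival_table`;
#'   `target_gene` (default `"GALNT14"`), `reference_candidates`
#'   (default all non-target genes), `n_references` (default 3),
#'   `max_ct` (default 40), `min_group_size` (default 8),
#'   `log2_transform` (default FALSE), `out_dir` (optional).
#' @param verbose log via `message()`.
#' @return list of class `followup_report`: `stability`, `profiles`,
#'   `positivity`, `association`, `os_report`, `result`.
#' @export
run_followup <- function(config, verbose = TRUE) {
  ct <- if (!is.null(config$ct_table)) config$ct_table
        else if (!is.null(config$ct_csv)) read_ct_csv(config$ct_csv)
        else NULL
  surv <- if (!is.null(config$survival_table)) config$survival_table
          else if (!is.null(config$survival_csv))
            read_survival_csv(config$survival_csv)
          else NULL
  if (is.null(ct) && is.null(surv))
    stop("config must provide qPCR and/or survival inputs")

  stability <- profiles <- positivity <- assoc <- NULL
  if (!is.null(ct)) {
    target <- if (is.null(config$target_gene)) "GALNT14" else config$target_gene
    cands <- if (is.null(config$reference_candidates))
      setdiff(unique(ct$gene), target) else config$reference_candidates
    n_ref <- if (is.null(config$n_references)) 3 else config$n_references
    max_ct <- if (is.null(config$max_ct)) 40 else config$max_ct
    stability <- genorm_stability(ct[ct$gene %in% cands, ], n_keep = n_ref)
    refs <- stability$retained_references
    if (verbose) message("[genorm] retained references: ",
                         paste(refs, collapse = ", "))
    profiles <- relative_quantity(ct, target, refs, max_ct = max_ct)
    positivity <- positivity_summary(profiles)
    if (verbose) message(sprintf("[positivity] %d/%d (%.1f%%)",
                                 positivity$n_expressed,
                                 positivity$n_total, positivity$percent))
    if (!all(is.na(profiles$mycn_status)))
      assoc <- mycn_association(profiles,
                                log2_transform = isTRUE(config$log2_transform))
  }
  os_report <- NULL
  if (!is.null(surv)) {
    floor <- if (is.null(config$min_group_size)) 8 else config$min_group_size
    os_report <- stratified_os_report(surv, min_group_size = floor)
    if (verbose) message("[os_scan] ", sum(os_report$evaluable), " of ",
                         nrow(os_report), " strata evaluable")
  }
  result <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    references = if (is.null(stability)) NULL else stability$retained_references,
    positivity = positivity,
    association = assoc,
    os_scan = if (is.null(os_report)) NULL else
      os_report[, c("stratum", "n", "evaluable", "chosen_cutoff",
                    "min_p", "n_high", "n_low", "high_group_worse")],
    multiplicity_warning = if (is.null(os_report)) NULL else
      "scan minimum p-values are not adjusted for the multiplicity of scanned cutoffs")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(config$out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    w(profiles, "expression_profiles.tsv")
    w(assoc, "mycn_association.tsv")
    w(os_report, "os_scan.tsv")
    jsonlite::write_json(result, file.path(config$out_dir, "followup.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(stability = stability, profiles = profiles,
                 positivity = positivity, association = assoc,
                 os_report = os_report, result = result),
            class = "followup_report")
}

#' Check a pipeline JSON result against the shipped schema
#'
#' A lightweight structural validation: the report must carry the
#' current `schema_version` and the keys the schema file lists for its
#' kind.
#'
#' @param result a parsed report list (or path to a JSON file).
#' @param kind `"discovery"` or `"followup"`.
#' @return TRUE, or an error naming the missing keys.
#' @export
validate_report <- function(result, kind = c("discovery", "followup")) {
  kind <- match.arg(kind)
  if (is.character(result)) result <- jsonlite::read_json(result)
  schema_path <- system.file("extdata", "report-schema.json",
                             package = "famvarscan")
  schema <- jsonlite::read_json(schema_path)
  if (!identical(as.character(result$schema_version), schema$version))
    stop("schema version mismatch: report has ", result$schema_version,
         ", package ships ", schema$version)
  need <- unlist(schema$required[[kind]])
  missing_keys <- setdiff(need, names(result))
  if (length(missing_keys))
    stop("report is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  TRUE
}
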