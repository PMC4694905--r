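CONSEQUENCE_CLASSES <- c("missense", "synonymous", "nonsense",
                         "splice_site", "utr", "intronic", "intergenic")
CODING_CLASSES <- c("missense", "synonymous", "nonsense")
GENOTYPE_CODES <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a variant table
#'
#' The container used throughout the filtering cascade: one row per
#' biallelic site (multiallelic sites are decomposed upstream), with
#' per-sample genotype classes held in a parallel character matrix.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `consequence` (one of the seven classes), `gene` (`NA`
#'   allowed for non-coding classes), `dbsnp_id` (`NA` = not in dbSNP),
#'   `maf` (`NA` = unannotated), and optional `polyphen_cat`,
#'   `polyphen_score`, `sift_cat`, `sift_score`.
#' @param genotypes character matrix, rows = variants, columns = samples,
#'   values in `hom_ref`, `het`, `hom_alt`, `missing`.
#' @return object of class `variant_table` (list with `$sites`,
#'   `$genotypes`).
#' @export
variant_table <- function(sites, genotypes) {
  stopifnot(is.data.frame(sites), is.matrix(genotypes),
            nrow(sites) == nrow(genotypes))
  bad <- !(sites$consequence %in% CONSEQUENCE_CLASSES)
  if (any(bad))
    stop("unknown consequence term(s): ",
         paste(unique(sites$consequence[bad]), collapse = ", "))
  if (any(sites$ref == sites$alt))
    stop("alt allele equals ref allele at some sites")
  coding <- sites$consequence %in% CODING_CLASSES
  if (any(coding & is.na(sites$gene)))
    stop("coding variants must carry a gene symbol")
  bad_gt <- !(genotypes %in% GENOTYPE_CODES)
  if (any(bad_gt))
    stop("invalid genotype code(s): ",
         paste(unique(genotypes[bad_gt]), collapse = ", "))
  for (opt in c("polyphen_cat", "polyphen_score", "sift_cat", "sift_score"))
    if (is.null(sites[[opt]])) sites[[opt]] <- rep(NA, nrow(sites))
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  structure(list(sites = sites, genotypes = genotypes, key = key),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "variants x",
      ncol(x$genotypes), "samples\n")
  print(utils::head(x$sites), ...)
  invisible(x)
}

#' Number of variants in a variant table
#' @param vt a [variant_table()].
#' @return integer count.
#' @export
n_variants <- function(vt) nrow(vt$sites)

#' Subset a variant table by row index
#' @param vt a [variant_table()].
#' @param i logical or integer row index.
#' @return the subsetted [variant_table()].
#' @export
vt_subset <- function(vt, i) {
  variant_table(vt$sites[i, , drop = FALSE],
                vt$genotypes[i, , drop = FALSE])
}

.carries_alt <- function(gt) gt == "het" | gt == "hom_alt"

#' Read annotated variants from a multi-sample VCF
#'
#' Expects per-sample GT and INFO keys `CSQ_CLASS` (one of the seven
#' consequence terms), `GENE`, `MAF`, and optionally `PP2_CAT`,
#' `PP2_SCORE`, `SIFT_CAT`, `SIFT_SCORE`. The ID column supplies dbSNP
#' membership (`.` = absent). Multiallelic sites are decomposed into one
#' record per alternate allele; a genotype carrying the k-th alternate
#' counts as carrying only in the k-th record.
#'
#' @param path path to a VCF (v4.2, plain text or gzipped).
#' @return a [variant_table()].
#' @export
read_variants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- setdiff(colnames(vcf@gt), "FORMAT")
    return(variant_table(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), consequence = character(0),
                 gene = character(0), dbsnp_id = character(0),
                 maf = numeric(0), stringsAsFactors = FALSE),
      matrix(character(0), nrow = 0, ncol = length(samples),
             dimnames = list(NULL, samples))))
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw))
    stop("VCF has no GT field; per-sample genotypes are required")
  samples <- colnames(gt_raw)
  info_get <- function(key) vcfR::extract.info(vcf, element = key)
  csq <- info_get("CSQ_CLASS")
  gene <- info_get("GENE")
  maf <- suppressWarnings(as.numeric(info_get("MAF")))
  unesc <- function(x) if (is.null(x)) x else gsub("_", " ", x, fixed = TRUE)
  pp2c <- unesc(info_get("PP2_CAT"))
  pp2s <- suppressWarnings(as.numeric(info_get("PP2_SCORE")))
  sifc <- unesc(info_get("SIFT_CAT"))
  sifs <- suppressWarnings(as.numeric(info_get("SIFT_SCORE")))
  bad_csq <- !is.na(csq) & !(csq %in% CONSEQUENCE_CLASSES)
  if (any(bad_csq))
    stop("unknown consequence term(s) in CSQ_CLASS: ",
         paste(unique(csq[bad_csq]), collapse = ", "))

  rows <- list(); gts <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      cls <- .classify_gt(gt_raw[i, ], k)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        consequence = if (is.na(csq[i])) "intergenic" else csq[i],
        gene = if (is.null(gene)) NA_character_ else gene[i],
        dbsnp_id = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_ else fix$ID[i],
        maf = if (is.null(maf)) NA_real_ else maf[i],
        polyphen_cat = if (is.null(pp2c)) NA_character_ else pp2c[i],
        polyphen_score = if (is.null(pp2s)) NA_real_ else pp2s[i],
        sift_cat = if (is.null(sifc)) NA_character_ else sifc[i],
        sift_score = if (is.null(sifs)) NA_real_ else sifs[i],
        stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- cls
    }
  }
  geno <- do.call(rbind, gts)
  colnames(geno) <- samples
  variant_table(do.call(rbind, rows), geno)
}

# Classify a vector of raw GT strings with respect to alt allele index k.
.classify_gt <- function(gt, k) {
  out <- vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return("missing")
    n_alt <- sum(al == as.character(k))
    if (n_alt == 0) "hom_ref" else if (n_alt == length(al)) "hom_alt" else "het"
  }, character(1))
  unname(out)
}

#' Keep variants shared by every affected sample
#'
#' A variant is retained only if every listed affected sample carries at
#' least one alternate allele. A missing genotype in an affected sample
#' excludes the variant: a candidate is never promoted on absent evidence.
#'
#' @param vt a [variant_table()].
#' @param affected_ids character vector of sample ids (non-empty).
#' @return the filtered [variant_table()].
#' @export
shared_by_affected <- function(vt, affected_ids) {
  if (length(affected_ids) == 0)
    stop("affected_ids must be non-empty")
  missing_s <- setdiff(affected_ids, colnames(vt$genotypes))
  if (length(missing_s))
    stop("samples absent from genotypes: ", paste(missing_s, collapse = ", "))
  g <- vt$genotypes[, affected_ids, drop = FALSE]
  keep <- rowSums(.carries_alt(g)) == length(affected_ids)
  vt_subset(vt, keep)
}

#' Drop variants seen in any unaffected sample
#'
#' A variant is removed if any listed unaffected sample carries an
#' alternate allele. Missing genotypes in unaffected samples do not
#' trigger exclusion: a candidate is never discarded on absent evidence.
#'
#' @param vt a [variant_table()].
#' @param unaffected_ids character vector of sample ids (non-empty).
#' @return the filtered [variant_table()].
#' @export
absent_in_unaffected <- function(vt, unaffected_ids) {
  if (length(unaffected_ids) == 0)
    stop("unaffected_ids must be non-empty")
  missing_s <- setdiff(unaffected_ids, colnames(vt$genotypes))
  if (length(missing_s))
    stop("samples absent from genotypes: ", paste(missing_s, collapse = ", "))
  g <- vt$genotypes[, unaffected_ids, drop = FALSE]
  drop <- rowSums(.carries_alt(g)) > 0
  vt_subset(vt, !drop)
}

#' Partition variants into known-common and novel-or-rare
#'
#' Novel-or-rare: no dbSNP id, or an annotated minor allele frequency
#' strictly below the threshold (so a documented-rare dbSNP variant such
#' as one at MAF 0.004 is retained). A variant with a dbSNP id but no MAF
#' annotation is classed known-common: presence in dbSNP counts as
#' "already described" unless rarity is documented.
#'
#' @param vt a [variant_table()].
#' @param maf_threshold strict upper MAF bound, default 0.01.
#' @return list with `$known_common` and `$novel_or_rare`, both
#'   [variant_table()]s; the two partitions are disjoint and exhaustive.
#' @export
rarity_filter <- function(vt, maf_threshold = 0.01) {
  stopifnot(maf_threshold > 0, maf_threshold < 1)
  s <- vt$sites
  rare <- is.na(s$dbsnp_id) | (!is.na(s$maf) & s$maf < maf_threshold)
  list(known_common = vt_subset(vt, !rare),
       novel_or_rare = vt_subset(vt, rare))
}

#' Keep variants of selected consequence classes
#'
#' @param vt a [variant_table()].
#' @param keep consequence classes to retain (default missense only).
#' @return list with `$variants` (filtered [variant_table()]),
#'   `$n_genes` (distinct gene symbols among survivors), `$genes`.
#' @export
consequence_filter <- function(vt, keep = "missense") {
  if (length(keep) == 0) stop("keep set must be non-empty")
  bad <- setdiff(keep, CONSEQUENCE_CLASSES)
  if (length(bad))
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  out <- vt_subset(vt, vt$sites$consequence %in% keep)
  genes <- unique(stats::na.omit(out$sites$gene))
  list(variants = out, n_genes = length(genes), genes = genes)
}

#' Per-sample and shared-set filtering summary
#'
#' A whole-exome statistics table in the conventional layout: one column
#' per sample (variants that sample carries) plus one for the shared set,
#' with rows for the seven consequence classes, dbSNP membership, and
#' the total.
#'
#' @param vt the full [variant_table()].
#' @param sample_ids columns to report (default: all samples).
#' @param shared a [variant_table()] holding the shared-by-affected set,
#'   or `NULL` to omit the column.
#' @return data.frame, rows = categories, columns = samples (+ `shared`).
#' @export
cascade_summary <- function(vt, sample_ids = colnames(vt$genotypes),
                            shared = NULL) {
  count_col <- function(tab, carried) {
    s <- tab$sites[carried, , drop = FALSE]
    cons <- vapply(CONSEQUENCE_CLASSES,
                   function(cl) sum(s$consequence == cl), numeric(1))
    c(cons,
      in_dbsnp = sum(!is.na(s$dbsnp_id)),
      not_in_dbsnp = sum(is.na(s$dbsnp_id)),
      total = nrow(s))
  }
  cols <- lapply(sample_ids, function(sid)
    count_col(vt, .carries_alt(vt$genotypes[, sid])))
  names(cols) <- sample_ids
  if (!is.null(shared))
    cols$shared <- count_col(shared, rep(TRUE, n_variants(shared)))
  out <- as.data.frame(cols, check.names = FALSE)
  out <- cbind(category = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Segregation analysis over a pedigree
#'
#' For each variant, counts alternate-allele carriers among the sampled
#' affected members (non-missing genotypes) and flags `segregates` when
#' all of them carry it; also reports carriers among sampled unaffected
#' members and the penetrance over all sampled carriers. Variants that
#' fail segregation are flagged, never dropped.
#'
#' @param vt a [variant_table()] whose genotype columns cover the sampled
#'   pedigree members.
#' @param ped a [pedigree()].
#' @return data.frame, one row per variant: `key`, `affected_carriers`,
#'   `affected_total`, `unaffected_carriers`, `segregates`,
#'   `carriers_total`, `penetrance_f`, `penetrance_percent`.
#' @export
segregation_analysis <- function(vt, ped) {
  samples <- colnames(vt$genotypes)
  aff <- intersect(ped$id[ped$affection == "affected" & ped$sampled], samples)
  unaff <- intersect(ped$id[ped$affection == "unaffected" & ped$sampled], samples)
  if (length(aff) == 0)
    stop("no sampled affected individuals with genotypes")
  res <- lapply(seq_len(n_variants(vt)), function(i) {
    ga <- vt$genotypes[i, aff]
    gu <- vt$genotypes[i, unaff]
    aff_nonmiss <- sum(ga != "missing")
    aff_car <- sum(.carries_alt(ga))
    unaff_car <- sum(.carries_alt(gu))
    carriers <- aff_car + unaff_car
    f <- if (carriers > 0) aff_car / carriers else NA_real_
    data.frame(key = vt$key[i],
               affected_carriers = aff_car,
               affected_total = aff_nonmiss,
               unaffected_carriers = unaff_car,
               segregates = aff_nonmiss == length(aff) && aff_car == aff_nonmiss,
               carriers_total = carriers,
               penetrance_f = f,
               penetrance_percent = if (is.na(f)) NA_real_ else round(100 * f),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' IUPAC one-letter code for a heterozygous genotype
#'
#' @param ref,alt single reference and alternate bases.
#' @return string such as `"R(G/A)"`.
#' @export
iupac_het <- function(ref, alt) {
  codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  key <- paste(sort(c(ref, alt)), collapse = "")
  code <- unname(codes[key])
  if (is.na(code)) stop("not a heterozygous base pair: ", ref, "/", alt)
  sprintf("%s(%s/%s)", code, ref, alt)
}

#' Candidate-variant report table
#'
#' One row per candidate with chromosome, position, reference base, the
#' IUPAC heterozygote code of a representative carrier genotype, gene,
#' and pass-through PolyPhen-2 / SIFT annotations formatted as
#' `"Category (score)"`.
#'
#' @param vt a [variant_table()] of candidates.
#' @return data.frame in the candidate-table layout.
#' @export
candidate_table <- function(vt) {
  s <- vt$sites
  fmt <- function(cat, score, digits) ifelse(
    is.na(cat), NA_character_,
    sprintf("%s (%.*f)", cat, digits, score))
  data.frame(chrom = s$chrom, position = s$pos, ref_base = s$ref,
             sample_genotype = unname(mapply(iupac_het, s$ref, s$alt)),
             gene = s$gene,
             polyphen2 = fmt(s$polyphen_cat, s$polyphen_score, 3),
             sift = fmt(s$sift_cat, s$sift_score, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}
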