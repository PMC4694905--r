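#' Pivot a long qPCR table to a samples-by-genes Ct matrix
#'
#' @param ct_table data.frame with columns `sample_id`, `gene`, `ct`
#'   (`NA` = undetected).
#' @return numeric matrix, rows = samples, columns = genes.
#' @export
ct_matrix <- function(ct_table) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct_table)))
  samples <- unique(ct_table$sample_id)
  genes <- unique(ct_table$gene)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(ct_table$sample_id, samples),
          match(ct_table$gene, genes))] <- ct_table$ct
  m
}

#' geNorm-style reference-gene stability ranking
#'
#' For each candidate reference gene j, the stability measure M_j is the
#' mean, over every other candidate k, of the standard deviation across
#' samples of the pairwise difference Ct_k - Ct_j (the log2 expression
#' ratio under 100% amplification efficiency). The least stable gene
#' (highest M) is dropped and M recomputed, iterating until `n_keep`
#' genes remain. A gene tracking the common expression profile has low
#' M; a gene fluctuating independently has high M.
#'
#' @param ct_table long qPCR table ([ct_matrix()] input) or a numeric
#'   samples-by-genes matrix, restricted to candidate reference genes.
#' @param n_keep number of reference genes to retain (default 3).
#' @return list of class `stability_ranking`: `m_values` (initial M per
#'   gene), `exclusion_order` (first-dropped first),
#'   `retained_references` (ranked, most stable first by final M).
#' @export
genorm_stability <- function(ct_table, n_keep = 3) {
  m <- if (is.matrix(ct_table)) ct_table else ct_matrix(ct_table)
  if (ncol(m) < 3)
    stop("geNorm stability needs at least 3 candidate reference genes")
  if (nrow(m) < 2)
    stop("geNorm stability needs at least 2 samples")
  if (anyNA(m))
    stop("undetected Ct among candidate reference genes")
  if (n_keep < 2) stop("at least 2 reference genes must be retained")
  m_of <- function(mat) {
    vapply(colnames(mat), function(j) {
      others <- setdiff(colnames(mat), j)
      mean(vapply(others,
                  function(k) stats::sd(mat[, k] - mat[, j]),
                  numeric(1)))
    }, numeric(1))
  }
  m_init <- m_of(m)
  cur <- m
  dropped <- character(0)
  while (ncol(cur) > n_keep) {
    mm <- m_of(cur)
    worst <- names(which.max(mm))
    dropped <- c(dropped, worst)
    cur <- cur[, setdiff(colnames(cur), worst), drop = FALSE]
  }
  final_m <- if (ncol(cur) >= 3) m_of(cur) else m_init[colnames(cur)]
  structure(list(m_values = m_init,
                 exclusion_order = dropped,
                 retained_references = names(sort(final_m))),
            class = "stability_ranking")
}

#' Calibrated relative quantification (delta-delta-Ct)
#'
#' For each sample s, dCt_s = Ct_target,s - mean(Ct_reference,s); the
#' relative quantity is 2^-(dCt_s - dCt_cal) where the calibrator is the
#' least-expressed sample with a detected target, so quantities are in
#' arbitrary units relative to the least expressed sample and the
#' minimum over expressed samples is exactly 1. Samples whose target Ct
#' is missing or above `max_ct` are flagged not expressed and get no
#' quantity.
#'
#' @param ct_table long qPCR table with columns `sample_id`, `gene`,
#'   `ct`, optionally `mycn_status`.
#' @param target_gene gene symbol to quantify.
#' @param reference_genes character vector of reference gene symbols
#'   (must be detected in every sample).
#' @param max_ct detection threshold in cycles (default 40); a target Ct
#'   above it counts as not expressed.
#' @return data.frame: `sample_id`, `delta_ct`, `relative_quantity`,
#'   `expressed`, `mycn_status` (`NA` when absent from input). When no
#'   sample expresses the target the frame has zero expressed rows and a
#'   warning is issued.
#' @export
relative_quantity <- function(ct_table, target_gene, reference_genes,
                              max_ct = 40) {
  m <- ct_matrix(ct_table)
  if (!target_gene %in% colnames(m))
    stop("target gene ", target_gene, " absent from Ct table")
  miss_ref <- setdiff(reference_genes, colnames(m))
  if (length(miss_ref))
    stop("reference gene(s) absent: ", paste(miss_ref, collapse = ", "))
  refs <- m[, reference_genes, drop = FALSE]
  if (anyNA(refs))
    stop("reference genes must be detected in all samples")
  tgt <- m[, target_gene]
  expressed <- !is.na(tgt) & tgt <= max_ct
  dct <- tgt - rowMeans(refs)
  status <- rep(NA_character_, nrow(m))
  if ("mycn_status" %in% names(ct_table)) {
    st <- unique(ct_table[, c("sample_id", "mycn_status")])
    status <- st$mycn_status[match(rownames(m), st$sample_id)]
  }
  rq <- rep(NA_real_, nrow(m))
  if (any(expressed)) {
    dct_cal <- max(dct[expressed])  # least expressed detected sample
    rq[expressed] <- 2^(-(dct[expressed] - dct_cal))
  } else {
    warning("no sample expresses ", target_gene,
            "; returning an empty profile")
  }
  data.frame(sample_id = rownames(m), delta_ct = dct,
             relative_quantity = rq, expressed = expressed,
             mycn_status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression positivity summary
#'
#' @param profiles output of [relative_quantity()].
#' @return list with `n_expressed`, `n_total`, `percent` (one decimal),
#'   e.g. 11 of 15 gives 73.3 and 18 of 76 gives 23.7.
#' @export
positivity_summary <- function(profiles) {
  if (nrow(profiles) == 0) stop("profiles must be non-empty")
  n <- nrow(profiles)
  k <- sum(profiles$expressed)
  list(n_expressed = k, n_total = n, percent = round(100 * k / n, 1))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value obtained by summing the hypergeometric
#' probabilities of all tables (at fixed margins) no more probable than
#' the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return data.frame row: `test_name`, `statistic` (the odds-ratio
#'   estimate), `p_value`, `n1`, `n2` (row sums).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: a margin is zero")
  ft <- stats::fisher.test(tab)
  data.frame(test_name = "fisher_exact",
             statistic = unname(ft$estimate),
             p_value = ft$p.value,
             n1 = sum(tab[1, ]), n2 = sum(tab[2, ]),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney and Welch t tests between two expression groups
#'
#' The Mann-Whitney U test uses exact enumeration when the combined
#' sample size is at most 10 and there are no ties, and the tie-corrected
#' normal approximation otherwise; the location test is Welch's
#' unequal-variance t. Both are two-sided. When both groups are constant
#' with equal means the t statistic is defined as 0 with p = 1 (and as
#' infinite with p = 0 for unequal constant means).
#'
#' @param group_a,group_b numeric vectors of relative quantities.
#' @param log2_transform apply log2 before the t test (quantities must
#'   then be positive); the rank test is unaffected by monotone
#'   transforms.
#' @return data.frame with one row per test: `test_name` (`mann_whitney`,
#'   `welch_t`), `statistic`, `p_value`, `n1`, `n2`.
#' @export
rank_and_location_tests <- function(group_a, group_b,
                                    log2_transform = FALSE) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b,
                       exact = (n <= 10) && !ties, correct = TRUE))
  ta <- if (log2_transform) log2(group_a) else group_a
  tb <- if (log2_transform) log2(group_b) else group_b
  tt <- tryCatch(stats::t.test(ta, tb, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {  # essentially constant data
    if (isTRUE(all.equal(mean(ta), mean(tb)))) {
      t_stat <- 0; t_p <- 1
    } else {
      t_stat <- sign(mean(ta) - mean(tb)) * Inf; t_p <- 0
    }
  } else {
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
  }
  data.frame(
    test_name = c("mann_whitney", "welch_t"),
    statistic = c(unname(wt$statistic), t_stat),
    p_value = c(wt$p.value, t_p),
    n1 = length(group_a), n2 = length(group_b),
    stringsAsFactors = FALSE)
}

#' Association of expression with MYCN status
#'
#' Runs the three tests the expression analysis reports: a Fisher exact
#' test of positivity (expressed yes/no) between MYCN-amplified and
#' MYCN-single-copy samples, and Mann-Whitney plus Welch t tests on the
#' relative quantities of the expressed samples in the two groups. The
#' three-way status (amplified / gain / single copy) is kept in the
#' profiles, but inference contrasts amplified vs single copy only.
#'
#' @param profiles output of [relative_quantity()] with `mycn_status`.
#' @param log2_transform passed to [rank_and_location_tests()].
#' @return data.frame of test rows (see the individual tests); Fisher is
#'   omitted with a warning when a margin is zero, the quantity tests
#'   when either group has no expressed samples.
#' @export
mycn_association <- function(profiles, log2_transform = FALSE) {
  amp <- profiles[profiles$mycn_status == "amplified", ]
  sc <- profiles[profiles$mycn_status == "single_copy", ]
  out <- list()
  tab <- matrix(c(sum(amp$expressed), sum(!amp$expressed),
                  sum(sc$expressed), sum(!sc$expressed)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("amplified", "single_copy"),
                                c("expressed", "not_expressed")))
  ok_fisher <- !any(rowSums(tab) == 0) && !any(colSums(tab) == 0)
  if (ok_fisher) out$fisher <- fisher_exact_2x2(tab)
  else warning("degenerate positivity table; Fisher test skipped")
  qa <- amp$relative_quantity[amp$expressed]
  qs <- sc$relative_quantity[sc$expressed]
  if (length(qa) >= 1 && length(qs) >= 1)
    out$quant <- rank_and_location_tests(qa, qs, log2_transform)
  else warning("a MYCN group has no expressed samples; quantity tests skipped")
  do.call(rbind, out)
}
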