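#' Simulation configuration with study-shaped defaults
#'
#' Bundles every tunable of the synthetic-cohort generators. The
#' defaults emulate the structure of the study this pipeline is built
#' around: a 22-member four-generation family with a rare causal
#' missense variant planted heterozygously in one founding
#' great-grandparent under incomplete penetrance (f = 0.3125, the 5/16
#' figure reported for familial ALK carriers); a background of unlinked
#' annotated SNPs whose consequence-class mix follows the shared-by-NB
#' column of the published whole-exome statistics table; a 76-sample
#' expression cohort whose MYCN-status-dependent detection rates give
#' roughly 24% overall positivity with amplified samples averaging two
#' log2 units above single-copy samples; and an 88-sample survival
#' cohort with bimodal (expressed / not expressed) marker levels and a
#' hazard ratio of 3 above the true expression threshold.
#'
#' @param seed integer seed used by every generator drawing from this
#'   config.
#' @param pedigree a [pedigree()]; default [family_pedigree()].
#' @param n_background_snps background variant count (default 2000; a
#'   desk-scale stand-in for an exome).
#' @param consequence_probabilities named fractions over the seven
#'   consequence classes (must sum to 1).
#' @param dbsnp_rate_common fraction of background SNPs that are common,
#'   catalogued variants (default 6744/6999).
#' @param rare_known_rate fraction of the non-common background that is
#'   catalogued with a documented MAF below 0.01 (rather than novel).
#' @param causal list: `founder_carrier`, `penetrance` (f), `phenocopy`.
#' @param expression list: cohort size, MYCN proportions, per-status
#'   detection probabilities and log2-quantity means, shared sd, Ct
#'   noise levels.
#' @param survival list: cohort size, monthly baseline event rate,
#'   hazard ratio above threshold, monthly censoring rate, expression
#'   mixture (`p_high`, log2 means/sd) and `true_threshold`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    pedigree = family_pedigree(),
    n_background_snps = 2000,
    consequence_probabilities = prop.table(c(
      missense = 662, synonymous = 739, nonsense = 9, splice_site = 3,
      utr = 284, intronic = 4404, intergenic = 808)),
    dbsnp_rate_common = 6744 / 6999,
    rare_known_rate = 0.2,
    causal = list(founder_carrier = "E1", penetrance = 0.3125,
                  phenocopy = 0),
    expression = list(
      n = 76,
      mycn_probs = c(amplified = 0.20, gain = 0.15, single_copy = 0.65),
      detection_prob = c(amplified = 0.60, gain = 0.30, single_copy = 0.12),
      log2_mean = c(amplified = 3.5, gain = 2.5, single_copy = 1.5),
      log2_sd = 0.8,
      reference_base_ct = c(RNA18S = 12, GAPDH = 20, UBC = 24),
      target_base_ct = 30, loading_sd = 0.6, ref_noise_sd = 0.15,
      decoy_noise_sd = 1.5, target_noise_sd = 0.2),
    survival = list(
      n = 88, base_rate = 0.008, hazard_ratio = 3,
      censor_rate = 0.004, p_high = 0.45,
      log2_mean_low = 0, log2_mean_high = 3, log2_sd = 0.7,
      true_threshold = 2^1.5,
      p_localized = 0.5, p_relapse = 0.45,
      mycn_probs = c(amplified = 0.20, gain = 0.15, single_copy = 0.65))) {
  stopifnot(abs(sum(consequence_probabilities) - 1) < 1e-8,
            causal$penetrance > 0, causal$penetrance <= 1,
            causal$phenocopy >= 0, causal$phenocopy <= 1,
            survival$hazard_ratio >= 1)
  structure(list(seed = as.integer(seed), pedigree = pedigree,
                 n_background_snps = n_background_snps,
                 consequence_probabilities = consequence_probabilities,
                 dbsnp_rate_common = dbsnp_rate_common,
                 rare_known_rate = rare_known_rate,
                 causal = causal, expression = expression,
                 survival = survival),
            class = "sim_config")
}

#' Gene-dropping simulation
#'
#' Drops founder alleles down the pedigree: each child receives one
#' allele from each parent, chosen with probability 1/2 independently
#' across meioses and replicates. Two statistics are reported per pair:
#'
#' * `joint_carriage` — the probability that both individuals carry the
#'   specific allele planted heterozygously in `founder_carrier` (a
#'   six-meiosis chain for second cousins, so 1/64);
#' * `ibd_share` — the expected fraction of alleles shared identical by
#'   descent, estimated by labelling every founder allele uniquely; its
#'   expectation is the relatedness coefficient r = 2 phi, the quantity
#'   behind the familiar "second cousins share ~3% of their genome".
#'
#' Monte-Carlo standard errors accompany both.
#'
#' @param ped a [pedigree()].
#' @param founder_carrier id of a founder, planted heterozygous.
#' @param n_replicates Monte-Carlo replicates (independent loci).
#' @param seed RNG seed.
#' @param pairs list of id pairs to report; default: all pairs.
#' @return list with `pairs` (data.frame: `id_a`, `id_b`,
#'   `joint_carriage`, `se_joint`, `ibd_share`, `se_ibd`) and
#'   `carriage` (data.frame: per-individual carriage frequency of the
#'   planted allele).
#' @export
gene_drop <- function(ped, founder_carrier, n_replicates = 2e5,
                      seed = 1L, pairs = NULL) {
  is_founder <- is.na(ped$father_id)
  if (!founder_carrier %in% ped$id[is_founder])
    stop(founder_carrier, " is not a founder of the pedigree")
  set.seed(seed)
  ord <- ped_topological_order(ped)
  n <- length(ped$id)
  father <- stats::setNames(ped$father_id, ped$id)
  mother <- stats::setNames(ped$mother_id, ped$id)
  # allele-label matrices: one row per individual, one column per replicate
  a1 <- matrix(0L, n, n_replicates, dimnames = list(ped$id, NULL))
  a2 <- a1
  next_label <- 1L
  for (id in ord) {
    if (is.na(father[[id]])) {
      a1[id, ] <- next_label
      a2[id, ] <- next_label + 1L
      next_label <- next_label + 2L
    } else {
      pick_f <- stats::runif(n_replicates) < 0.5
      pick_m <- stats::runif(n_replicates) < 0.5
      a1[id, ] <- ifelse(pick_f, a1[father[[id]], ], a2[father[[id]], ])
      a2[id, ] <- ifelse(pick_m, a1[mother[[id]], ], a2[mother[[id]], ])
    }
  }
  planted <- a1[founder_carrier, 1]  # founder's first allele label
  carries <- (a1 == planted) | (a2 == planted)
  carriage <- data.frame(id = ped$id,
                         carriage_freq = rowMeans(carries),
                         stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(pairs)) {
    idx <- utils::combn(ped$id, 2, simplify = FALSE)
  } else idx <- pairs
  mc_se <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(idx, function(p) {
    joint <- carries[p[1], ] & carries[p[2], ]
    share <- ((a1[p[1], ] == a1[p[2], ]) + (a1[p[1], ] == a2[p[2], ]) +
              (a2[p[1], ] == a1[p[2], ]) + (a2[p[1], ] == a2[p[2], ])) / 2
    data.frame(id_a = p[1], id_b = p[2],
               joint_carriage = mean(joint), se_joint = mc_se(joint),
               ibd_share = mean(share), se_ibd = mc_se(share),
               stringsAsFactors = FALSE)
  })
  list(pairs = do.call(rbind, rows), carriage = carriage,
       n_replicates = n_replicates)
}

# Drop one biallelic locus (alt-allele counts) down the pedigree.
# founder_counts: named integer vector (0/1/2) over founders; returns
# counts for every individual. Vectorized over loci (matrix input).
.drop_counts <- function(ped, founder_counts) {
  ord <- ped_topological_order(ped)
  father <- stats::setNames(ped$father_id, ped$id)
  m <- ncol(founder_counts)
  counts <- matrix(0L, length(ped$id), m, dimnames = list(ped$id, NULL))
  for (id in ord) {
    f <- father[[id]]
    if (is.na(f)) {
      counts[id, ] <- founder_counts[id, ]
    } else {
      mo <- ped$mother_id[ped$id == id]
      counts[id, ] <- stats::rbinom(m, 1, counts[f, ] / 2) +
                      stats::rbinom(m, 1, counts[mo, ] / 2)
    }
  }
  counts
}

.count_to_code <- function(counts) {
  codes <- c("hom_ref", "het", "hom_alt")
  matrix(codes[counts + 1L], nrow = nrow(counts),
         dimnames = dimnames(counts))
}

#' Simulate an annotated multi-sample variant table
#'
#' Background SNPs receive founder genotypes by binomial sampling at
#' their (minor) allele frequency and are gene-dropped to every
#' descendant; consequence classes, dbSNP membership and MAF annotations
#' are drawn per the configuration. One causal rare missense variant is
#' planted heterozygously in the configured founder and dropped through
#' the family; affection status is then reassigned as
#' carrier-and-Bernoulli(f) plus phenocopies, so the causal variant is
#' carried by every simulated affected member whenever the phenocopy
#' rate is zero.
#'
#' @param config a [sim_config()].
#' @return list: `table` (a [variant_table()] over all sampled members),
#'   `pedigree` (the input pedigree with simulated affection),
#'   `truth` (planted key, carrier ids, affected ids, config echo).
#' @export
simulate_variant_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- config$pedigree
  n_bg <- config$n_background_snps
  founders <- ped$id[is.na(ped$father_id)]

  sites <- NULL; geno_counts <- NULL
  if (n_bg > 0) {
    cons <- sample(names(config$consequence_probabilities), n_bg,
                   replace = TRUE, prob = config$consequence_probabilities)
    common <- stats::runif(n_bg) < config$dbsnp_rate_common
    rare_known <- !common & stats::runif(n_bg) < config$rare_known_rate
    maf <- ifelse(common, stats::runif(n_bg, 0.05, 0.5),
           ifelse(rare_known, stats::runif(n_bg, 5e-4, 0.0099), NA))
    dbsnp <- ifelse(common | rare_known,
                    sprintf("rs%08d", sample.int(9e7, n_bg)), NA)
    q <- ifelse(is.na(maf), 0.005, maf)  # founder alt-allele frequency
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_bg, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    coding <- cons %in% CODING_CLASSES
    gene <- ifelse(coding | cons == "utr",
                   sprintf("GENE%04d", sample.int(5000, n_bg, replace = TRUE)),
                   NA)
    sites <- data.frame(
      chrom = as.character(sample.int(22, n_bg, replace = TRUE)),
      pos = sample.int(2.4e8, n_bg), ref = ref, alt = unname(alt),
      consequence = cons, gene = gene, dbsnp_id = dbsnp, maf = maf,
      stringsAsFactors = FALSE)
    fc <- matrix(0L, length(ped$id), n_bg, dimnames = list(ped$id, NULL))
    for (f in founders) fc[f, ] <- stats::rbinom(n_bg, 2, q)
    geno_counts <- .drop_counts(ped, fc)
  }

  # planted causal variant: rare missense, catalogued at MAF < 0.01
  fc1 <- matrix(0L, length(ped$id), 1, dimnames = list(ped$id, NULL))
  fc1[config$causal$founder_carrier, 1] <- 1L
  causal_counts <- .drop_counts(ped, fc1)
  causal_site <- data.frame(
    chrom = "2", pos = 31167749L, ref = "G", alt = "A",
    consequence = "missense", gene = "GALNT14",
    dbsnp_id = "rs143143842", maf = 4e-4,
    polyphen_cat = "Probably Damaging", polyphen_score = 1.000,
    sift_cat = "Damaging", sift_score = 0.00,
    stringsAsFactors = FALSE)

  if (is.null(sites)) {
    all_sites <- causal_site
    all_counts <- causal_counts
  } else {
    sites$polyphen_cat <- NA_character_; sites$polyphen_score <- NA_real_
    sites$sift_cat <- NA_character_; sites$sift_score <- NA_real_
    all_sites <- rbind(sites, causal_site)
    all_counts <- cbind(geno_counts, causal_counts)
  }
  ord <- order(as.integer(all_sites$chrom), all_sites$pos)
  all_sites <- all_sites[ord, , drop = FALSE]
  all_counts <- all_counts[, ord, drop = FALSE]

  carriers <- ped$id[causal_counts[, 1] > 0]
  affected <- ped$id[ifelse(causal_counts[, 1] > 0,
                            stats::runif(length(ped$id)) < config$causal$penetrance,
                            stats::runif(length(ped$id)) < config$causal$phenocopy)]
  ped$affection <- ifelse(ped$id %in% affected, "affected", "unaffected")

  sampled <- ped$id[ped$sampled]
  # all_counts is individuals x variants; genotypes are variants x samples
  geno <- .count_to_code(t(all_counts[sampled, , drop = FALSE]))
  dimnames(geno) <- list(NULL, sampled)

  vt <- variant_table(all_sites, geno)
  key <- paste(causal_site$chrom, causal_site$pos, causal_site$ref,
               causal_site$alt, sep = ":")
  list(table = vt, pedigree = ped,
       truth = list(planted_key = key, carriers = carriers,
                    affected = affected, seed = config$seed,
                    penetrance = config$causal$penetrance))
}

#' Simulate a qPCR expression cohort
#'
#' Draws a MYCN status per sample, a Bernoulli detection flag with a
#' status-specific probability, and for detected samples a log2 quantity
#' from the status-specific normal. Ct values are emitted for the target
#' plus three stable reference genes (shared per-sample loading shift,
#' small independent noise) and one deliberately unstable decoy
#' reference whose large independent noise should earn it the worst
#' geNorm M.
#'
#' @param config a [sim_config()].
#' @param n cohort size; default from the config.
#' @return list: `ct_table` (long data.frame `sample_id`, `gene`, `ct`,
#'   `mycn_status`; target gene `GALNT14`, references `RNA18S`,
#'   `GAPDH`, `UBC`, decoy `DECOY`), `truth` (status, detected flag and
#'   log2 quantity per sample).
#' @export
simulate_expression_cohort <- function(config, n = config$expression$n) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  e <- config$expression
  ids <- sprintf("S%03d", seq_len(n))
  status <- sample(names(e$mycn_probs), n, replace = TRUE,
                   prob = e$mycn_probs)
  detected <- stats::runif(n) < e$detection_prob[status]
  log2q <- ifelse(detected,
                  stats::rnorm(n, e$log2_mean[status], e$log2_sd), NA)
  shift <- stats::rnorm(n, 0, e$loading_sd)
  rows <- list()
  for (g in names(e$reference_base_ct)) {
    rows[[g]] <- data.frame(
      sample_id = ids, gene = g,
      ct = e$reference_base_ct[[g]] + shift +
        stats::rnorm(n, 0, e$ref_noise_sd),
      mycn_status = status, stringsAsFactors = FALSE)
  }
  rows$DECOY <- data.frame(
    sample_id = ids, gene = "DECOY",
    ct = 22 + shift + stats::rnorm(n, 0, e$decoy_noise_sd),
    mycn_status = status, stringsAsFactors = FALSE)
  rows$target <- data.frame(
    sample_id = ids, gene = "GALNT14",
    ct = ifelse(detected,
                e$target_base_ct + shift - log2q +
                  stats::rnorm(n, 0, e$target_noise_sd),
                NA),
    mycn_status = status, stringsAsFactors = FALSE)
  ct_table <- do.call(rbind, rows)
  rownames(ct_table) <- NULL
  list(ct_table = ct_table,
       truth = data.frame(sample_id = ids, mycn_status = status,
                          detected = detected, log2_quantity = log2q,
                          stringsAsFactors = FALSE))
}

#' Simulate a survival cohort with expression-dependent hazard
#'
#' Expression is drawn from a two-component log2-normal mixture (an
#' expressed and a not-expressed mode); event times are exponential with
#' the baseline monthly rate multiplied by the hazard ratio for samples
#' whose expression is at or above the true threshold; censoring times
#' are independent exponentials (censoring rate 0 means no censoring).
#' Stage class, relapse/progression and MYCN status tags are drawn from
#' configured proportions, independent of survival.
#'
#' @param config a [sim_config()].
#' @param n cohort size; default from the config.
#' @return data.frame `sample_id`, `time` (months), `event` (logical),
#'   `expression`, `mycn_status`, `stage_class`,
#'   `relapse_or_progression`, with `attr(, "truth")` carrying the
#'   generative threshold and hazard ratio.
#' @export
simulate_survival_cohort <- function(config, n = config$survival$n) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  s <- config$survival
  high <- stats::runif(n) < s$p_high
  log2e <- stats::rnorm(n, ifelse(high, s$log2_mean_high, s$log2_mean_low),
                        s$log2_sd)
  expression <- 2^log2e
  rate <- s$base_rate * ifelse(expression >= s$true_threshold,
                               s$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (s$censor_rate > 0) stats::rexp(n, s$censor_rate) else Inf
  out <- data.frame(
    sample_id = sprintf("P%03d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    expression = expression,
    mycn_status = sample(names(s$mycn_probs), n, replace = TRUE,
                         prob = s$mycn_probs),
    stage_class = ifelse(stats::runif(n) < s$p_localized,
                         "localized", "metastatic"),
    relapse_or_progression = stats::runif(n) < s$p_relapse,
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(true_threshold = s$true_threshold,
                             hazard_ratio = s$hazard_ratio)
  out
}
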