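test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 99, n_background_snps = 150)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_variant_vcf(simulate_variant_table(cfg)$table, f1)
  write_variant_vcf(simulate_variant_table(cfg)$table, f2)
  expect_identical(readLines(f1), readLines(f2))
  e1 <- simulate_expression_cohort(cfg)
  e2 <- simulate_expression_cohort(cfg)
  expect_identical(e1, e2)
  s1 <- simulate_survival_cohort(cfg)
  s2 <- simulate_survival_cohort(cfg)
  expect_identical(s1, s2)
})

test_that("every simulated genotype is Mendelian-consistent with its parents", {
  sim <- simulate_variant_table(sim_config(seed = 12, n_background_snps = 250))
  ped <- sim$pedigree
  counts <- matrix(match(sim$table$genotypes, c("hom_ref", "het", "hom_alt")) - 1L,
                   nrow = n_variants(sim$table),
                   dimnames = dimnames(sim$table$genotypes))
  allowed <- function(p) if (p == 0) 0L else if (p == 2) 1L else c(0L, 1L)
  for (i in which(!is.na(ped$father_id))) {
    id <- ped$id[i]; f <- ped$father_id[i]; m <- ped$mother_id[i]
    feasible <- mapply(function(cc, fc, mc)
      any(outer(allowed(fc), allowed(mc), "+") == cc),
      counts[, id], counts[, f], counts[, m])
    expect_true(all(feasible), info = id)
  }
})

test_that("gene-drop carriage frequencies follow Mendelian expectations", {
  trio_plus <- pedigree(id = c("f", "m", "c1", "c2"),
                        father_id = c(NA, NA, "f", "f"),
                        mother_id = c(NA, NA, "m", "m"))
  gd <- gene_drop(trio_plus, "f", n_replicates = 4e4, seed = 2)
  carr <- gd$carriage
  for (child in c("c1", "c2"))
    expect_equal(carr$carriage_freq[carr$id == child], 0.5, tolerance = 0.05)
  sibs <- gd$pairs[gd$pairs$id_a == "c1" & gd$pairs$id_b == "c2", ]
  expect_equal(sibs$joint_carriage, 0.25, tolerance = 0.05)
  expect_error(gene_drop(trio_plus, "c1", 10, 1), "not a founder")
})

test_that("gene-drop IBD sharing matches pedigree relatedness within 3 SE", {
  ped <- family_pedigree()
  phi <- kinship_matrix(ped)
  gd <- gene_drop(ped, "E1", n_replicates = 5e4, seed = 3,
                  pairs = list(c("E5", "E10"), c("E5", "E17"),
                               c("E1", "E5"), c("E2", "E19")))
  for (i in seq_len(nrow(gd$pairs))) {
    row <- gd$pairs[i, ]
    r <- 2 * phi[row$id_a, row$id_b]
    expect_lt(abs(row$ibd_share - r), 3 * max(row$se_ibd, 1e-4),
              label = paste(row$id_a, row$id_b, "ibd vs r"))
  }
  # and the planted-allele joint carriage for second cousins is the
  # six-meiosis chain, (1/2)^6
  sc <- gd$pairs[gd$pairs$id_a == "E5" & gd$pairs$id_b == "E10", ]
  expect_lt(abs(sc$joint_carriage - 1 / 64), 3 * max(sc$se_joint, 1e-4))
})

test_that("founder genotypes are in Hardy-Weinberg proportions", {
  n_f <- 4000
  ids <- sprintf("F%04d", seq_len(n_f))
  big <- pedigree(id = ids, father_id = NA, mother_id = NA)
  cfg <- sim_config(seed = 41, pedigree = big, n_background_snps = 12,
                    dbsnp_rate_common = 1,
                    causal = list(founder_carrier = ids[1],
                                  penetrance = 1, phenocopy = 0))
  sim <- simulate_variant_table(cfg)
  vt <- sim$table
  bg <- which(vt$sites$pos != 31167749L)
  for (i in bg[1:8]) {
    q <- vt$sites$maf[i]
    counts <- table(factor(vt$genotypes[i, ],
                           levels = c("hom_ref", "het", "hom_alt")))
    expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    for (k in 1:3) {
      se <- sqrt(expected[k] * (1 - expected[k]) / n_f)
      expect_lt(abs(counts[k] / n_f - expected[k]), 3 * se + 1e-3,
                label = paste("variant", i, "class", k))
    }
  }
})

test_that("the planted variant is carried by every simulated affected member", {
  for (seed in 1:10) {
    sim <- simulate_variant_table(sim_config(seed = seed,
                                             n_background_snps = 0))
    expect_equal(n_variants(sim$table), 1)  # only the planted site
    ped <- sim$pedigree
    carriers <- sim$truth$carriers
    expect_true(all(sim$truth$affected %in% carriers))  # phenocopy rate 0
    expect_setequal(ped$id[ped$affection == "affected"], sim$truth$affected)
  }
})

test_that("expression cohort recovers its built-in MYCN ordering", {
  hits <- 0; decoy_worst <- 0
  for (i in 1:100) {
    cfg <- sim_config(seed = 3000 + i)
    ex <- simulate_expression_cohort(cfg)
    rk <- genorm_stability(
      ex$ct_table[ex$ct_table$gene != "GALNT14", ], n_keep = 3)
    if (names(which.max(rk$m_values)) == "DECOY") decoy_worst <- decoy_worst + 1
    prof <- relative_quantity(ex$ct_table, "GALNT14",
                              rk$retained_references)
    qa <- prof$relative_quantity[prof$expressed &
                                   prof$mycn_status == "amplified"]
    qs <- prof$relative_quantity[prof$expressed &
                                   prof$mycn_status == "single_copy"]
    if (length(qa) && length(qs) && mean(qa) > mean(qs)) hits <- hits + 1
  }
  expect_gte(hits, 95)
  expect_gte(decoy_worst, 95)
})

test_that("zero detection probability yields an all-negative cohort", {
  cfg <- sim_config(seed = 6)
  cfg$expression$detection_prob[] <- 0
  ex <- simulate_expression_cohort(cfg)
  prof <- suppressWarnings(
    relative_quantity(ex$ct_table, "GALNT14", c("RNA18S", "GAPDH", "UBC")))
  expect_equal(sum(prof$expressed), 0)
})

test_that("zero censoring rate yields events only", {
  cfg <- sim_config(seed = 7)
  cfg$survival$censor_rate <- 0
  sv <- simulate_survival_cohort(cfg)
  expect_true(all(sv$event))
})

test_that("the scan calls the high-expression group worse almost surely at HR 3", {
  correct <- 0
  for (i in 1:100) {
    sv <- simulate_survival_cohort(sim_config(seed = 4000 + i))
    sc <- scan_cutoff(sv)
    if (sc$high_group_worse) correct <- correct + 1
  }
  expect_gte(correct, 95)
})

test_that("the scan's chosen cutoff sits within a few sample ranks of the truth", {
  dists <- integer(60)
  for (i in seq_along(dists)) {
    sv <- simulate_survival_cohort(sim_config(seed = 5000 + i))
    thr <- attr(sv, "truth")$true_threshold
    sc <- scan_cutoff(sv)
    cand <- sc$scan$cutoff
    dists[i] <- abs(which(cand == sc$chosen_cutoff) -
                      which.min(abs(cand - thr)))
  }
  # the argmin of a maximally selected log-rank statistic concentrates
  # near the generative threshold but keeps a sampling spread of a few
  # candidate ranks at this sample size and effect
  expect_lte(median(dists), 3)
})

test_that("the log-rank at the true threshold holds its nominal size under the null", {
  rej <- 0; n_runs <- 200
  for (i in seq_len(n_runs)) {
    cfg <- sim_config(seed = 7000 + i)
    cfg$survival$hazard_ratio <- 1
    sv <- simulate_survival_cohort(cfg)
    thr <- attr(sv, "truth")$true_threshold
    hi <- sv$expression >= thr
    p <- logrank_test(sv[hi, ], sv[!hi, ])$p_value
    if (p < 0.05) rej <- rej + 1
  }
  # 3 binomial SEs around 5% of 200
  expect_gte(rej, 1)
  expect_lte(rej, 20)
})
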