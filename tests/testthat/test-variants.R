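vcf_fixture <- function() {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="c">',
    '##INFO=<ID=MAF,Number=1,Type=Float,Description="m">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("2", "31167749", "rs143143842", "G", "A", ".", "PASS",
          "GENE=GALNT14;CSQ_CLASS=missense;MAF=0.0004", "GT",
          "0/1", "0/1", "0/0", sep = "\t"),
    paste("3", "500", ".", "A", "C,T", ".", "PASS",
          "GENE=GX;CSQ_CLASS=synonymous", "GT",
          "1/2", "0/2", "./.", sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

test_that("VCF reading decomposes multiallelics and keeps annotations", {
  vt <- read_variants(vcf_fixture())
  expect_equal(n_variants(vt), 3)  # 1 biallelic + 2 from the A->C,T site
  expect_equal(vt$sites$dbsnp_id[1], "rs143143842")
  expect_equal(vt$sites$maf[1], 4e-4)
  expect_equal(vt$sites$consequence[1], "missense")
  expect_equal(unname(vt$genotypes[1, ]), c("het", "het", "hom_ref"))
  # the 1/2 genotype is het for both decomposed records
  expect_equal(unname(vt$genotypes[2, ]), c("het", "hom_ref", "missing"))
  expect_equal(unname(vt$genotypes[3, ]), c("het", "het", "missing"))
  expect_equal(vt$sites$alt[2:3], c("C", "T"))
})

test_that("unknown consequence terms are rejected by name", {
  expect_error(make_vt(matrix("het", 1, 1, dimnames = list(NULL, "S1")),
                       consequence = "frameshiftish"),
               "frameshiftish")
})

test_that("sharing filter keeps only variants carried by all affected", {
  geno <- rbind(c("het", "het"),       # kept
                c("het", "hom_ref"),   # dropped
                c("hom_alt", "het"),   # kept
                c("het", "missing"))   # dropped: missing fails sharing
  colnames(geno) <- c("A1", "A2")
  vt <- make_vt(geno)
  out <- shared_by_affected(vt, c("A1", "A2"))
  expect_equal(out$key, vt$key[c(1, 3)])
  expect_error(shared_by_affected(vt, character(0)), "non-empty")
})

test_that("unaffected filter drops on evidence, not on missingness", {
  geno <- rbind(c("het", "het", "hom_ref", "hom_ref"),
                c("het", "het", "het", "hom_ref"),     # alt in healthy
                c("het", "het", "missing", "missing")) # missing: kept
  colnames(geno) <- c("A1", "A2", "U1", "U2")
  vt <- make_vt(geno)
  out <- absent_in_unaffected(vt, c("U1", "U2"))
  expect_equal(out$key, vt$key[c(1, 3)])
})

test_that("composed sharing filters match hand enumeration on a toy set", {
  set.seed(42)
  geno <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                        12 * 4, replace = TRUE),
                 nrow = 12, dimnames = list(NULL, c("A1", "A2", "U1", "U2")))
  vt <- make_vt(geno)
  got <- absent_in_unaffected(shared_by_affected(vt, c("A1", "A2")),
                              c("U1", "U2"))
  want <- vapply(seq_len(12), function(i)
    filter_oracle_keep(geno[i, ], c("A1", "A2"), c("U1", "U2")),
    logical(1))
  expect_equal(got$key, vt$key[want])
})

test_that("rarity filter partitions exactly with a strict MAF bound", {
  vt <- make_vt(matrix("het", 5, 1, dimnames = list(NULL, "S")),
                dbsnp_id = c("rs1", NA, "rs143143842", "rs2", NA),
                maf = c(0.30, NA, 0.004, NA, 0.02))
  parts <- rarity_filter(vt)
  # dbSNP + common MAF -> common; catalogued but documented-rare -> rare;
  # dbSNP with no MAF -> common; novel -> rare regardless of MAF column
  expect_equal(parts$known_common$key, vt$key[c(1, 4)])
  expect_equal(parts$novel_or_rare$key, vt$key[c(2, 3, 5)])
  expect_equal(sort(c(parts$known_common$key, parts$novel_or_rare$key)),
               sort(vt$key))
  # threshold is strict: maf exactly at the bound is not rare
  vt2 <- make_vt(matrix("het", 1, 1, dimnames = list(NULL, "S")),
                 dbsnp_id = "rs9", maf = 0.01)
  expect_equal(n_variants(rarity_filter(vt2)$novel_or_rare), 0)
})

test_that("consequence filter counts distinct genes", {
  cons <- c("missense", "missense", "missense", "synonymous", "intronic",
            "utr", "nonsense")
  vt <- make_vt(matrix("het", 7, 1, dimnames = list(NULL, "S")),
                consequence = cons,
                gene = c("GA", "GA", "GB", "GC", NA, NA, "GD"))
  out <- consequence_filter(vt, "missense")
  expect_equal(n_variants(out$variants), 3)
  expect_equal(out$n_genes, 2)  # two missense hit the same gene
  expect_error(consequence_filter(vt, character(0)), "non-empty")
  expect_error(consequence_filter(vt, "weird"), "weird")
})

test_that("cascade summary conserves counts by category", {
  sim <- simulate_variant_table(sim_config(seed = 2, n_background_snps = 300))
  vt <- sim$table
  shared <- shared_by_affected(vt, c("E5", "E10"))
  tab <- cascade_summary(vt, shared = shared)
  cons_rows <- tab$category %in% c("missense", "synonymous", "nonsense",
                                   "splice_site", "utr", "intronic",
                                   "intergenic")
  for (col in setdiff(names(tab), "category")) {
    expect_equal(sum(tab[[col]][cons_rows]), tab[[col]][tab$category == "total"])
    expect_equal(tab[[col]][tab$category == "in_dbsnp"] +
                   tab[[col]][tab$category == "not_in_dbsnp"],
                 tab[[col]][tab$category == "total"])
  }
  expect_lt(tab$shared[tab$category == "total"],
            tab$E5[tab$category == "total"])
})

test_that("filter stages are monotone and predicate order is immaterial", {
  for (seed in 1:5) {
    vt <- random_vt(80, c("A1", "A2", "U1", "U2"), seed)
    s1 <- shared_by_affected(vt, c("A1", "A2"))
    s2 <- absent_in_unaffected(s1, c("U1", "U2"))
    s3 <- rarity_filter(s2)$novel_or_rare
    s4 <- consequence_filter(s3, "missense")$variants
    ns <- c(n_variants(vt), n_variants(s1), n_variants(s2),
            n_variants(s3), n_variants(s4))
    expect_true(all(diff(ns) <= 0))
    expect_true(all(s4$key %in% vt$key))
    # reorder the pure-predicate stages: rarity & consequence first
    r1 <- consequence_filter(rarity_filter(vt)$novel_or_rare,
                             "missense")$variants
    r2 <- absent_in_unaffected(shared_by_affected(r1, c("A1", "A2")),
                               c("U1", "U2"))
    expect_equal(sort(r2$key), sort(s4$key))
  }
})

test_that("sharing filters agree with the truth-table oracle up to 6 samples", {
  for (k in c(2, 4, 6)) {
    n_aff <- k / 2
    samples <- c(paste0("A", seq_len(n_aff)),
                 paste0("U", seq_len(k - n_aff)))
    codes <- c("hom_ref", "het", "missing")
    patterns <- as.matrix(expand.grid(rep(list(codes), k),
                                      stringsAsFactors = FALSE))
    colnames(patterns) <- samples
    vt <- make_vt(patterns)
    got <- absent_in_unaffected(
      shared_by_affected(vt, samples[seq_len(n_aff)]),
      samples[-seq_len(n_aff)])
    want <- vapply(seq_len(nrow(patterns)), function(i)
      filter_oracle_keep(patterns[i, ], samples[seq_len(n_aff)],
                         samples[-seq_len(n_aff)]),
      logical(1))
    expect_equal(got$key, vt$key[want], info = paste("k =", k))
  }
})

test_that("segregation flags full co-occurrence and reports penetrance", {
  ped <- family_pedigree()
  aff <- ped$id[ped$affection == "affected"]      # 5 members
  unaff <- ped$id[ped$affection == "unaffected"]  # 17 members
  geno <- matrix("hom_ref", 3, 22, dimnames = list(NULL, ped$id))
  # variant 1: all 5 affected + 11 unaffected carry -> segregates, 5/16
  geno[1, aff] <- "het"
  geno[1, unaff[1:11]] <- "het"
  # variant 2: one affected not a carrier
  geno[2, aff[-1]] <- "het"
  # variant 3: one affected genotype missing
  geno[3, aff] <- "het"; geno[3, aff[1]] <- "missing"
  vt <- make_vt(geno)
  seg <- segregation_analysis(vt, ped)
  expect_equal(seg$segregates, c(TRUE, FALSE, FALSE))
  expect_equal(seg$carriers_total[1], 16)
  expect_equal(seg$penetrance_f[1], 5 / 16)
  expect_equal(seg$penetrance_percent[1], 31)
})

test_that("a 4-of-18 segregation pattern is recovered from a toy set", {
  ped <- family_pedigree()
  aff <- ped$id[ped$affection == "affected"]
  set.seed(9)
  geno <- matrix(sample(c("hom_ref", "het"), 18 * 22, replace = TRUE,
                        prob = c(0.7, 0.3)),
                 nrow = 18, dimnames = list(NULL, ped$id))
  geno[, aff] <- "hom_ref"
  segregating <- c(2, 7, 11, 17)
  geno[segregating, aff] <- "het"
  vt <- make_vt(geno)
  seg <- segregation_analysis(vt, ped)
  expect_equal(which(seg$segregates), segregating)
  expect_equal(sum(seg$segregates), 4)
})

test_that("candidate table formats IUPAC codes and annotation scores", {
  expect_equal(iupac_het("G", "A"), "R(G/A)")
  expect_equal(iupac_het("A", "C"), "M(A/C)")
  expect_error(iupac_het("A", "A"), "not a heterozygous")
  sites <- data.frame(chrom = "2", pos = 31167749L, ref = "G", alt = "A",
                      consequence = "missense", gene = "GALNT14",
                      dbsnp_id = "rs143143842", maf = 4e-4,
                      polyphen_cat = "Probably Damaging",
                      polyphen_score = 1, sift_cat = "Damaging",
                      sift_score = 0, stringsAsFactors = FALSE)
  vt <- variant_table(sites, matrix("het", 1, 1, dimnames = list(NULL, "E5")))
  tab <- candidate_table(vt)
  expect_equal(tab$sample_genotype, "R(G/A)")
  expect_equal(tab$polyphen2, "Probably Damaging (1.000)")
  expect_equal(tab$sift, "Damaging (0.00)")
})
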