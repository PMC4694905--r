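#!/usr/bin/env Rscript

# Generates every input the downstream analyses read, from one seeded
# configuration: the family pedigree (PED), an annotated multi-sample
# variant table (VCF) with one planted causal missense variant under
# incomplete penetrance, a qPCR expression cohort (CSV) and a survival
# cohort (CSV), plus a truth file for later comparison.
#
# The variant table is drawn under ascertainment: families enter a
# hereditary-cancer study because they present multiple cases, so seeded
# replicates are screened until the simulated family carries at least
# two affected members (the replicate count is reported).

suppressPackageStartupMessages(library(famvarscan))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)

# --- family with ascertainment ------------------------------------------
tries <- 0
repeat {
  tries <- tries + 1
  cfg$seed <- as.integer(seed + tries - 1)
  sim <- simulate_variant_table(cfg)
  if (length(sim$truth$affected) >= 2) break
}
message(sprintf(
  "ascertained a multi-case family after %d replicate(s): %d affected (%s), %d carriers",
  tries, length(sim$truth$affected),
  paste(sim$truth$affected, collapse = ", "), length(sim$truth$carriers)))

write_ped(sim$pedigree, file.path(out, "family.ped"))
write_variant_vcf(sim$table, file.path(out, "family_variants.vcf"))
jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# --- expression and survival cohorts ------------------------------------
ex <- simulate_expression_cohort(cfg)
write_ct_csv(ex$ct_table, file.path(out, "qpcr_ct.csv"))
message(sprintf("qPCR cohort: %d samples x %d genes",
                length(unique(ex$ct_table$sample_id)),
                length(unique(ex$ct_table$gene))))

sv <- simulate_survival_cohort(cfg)
write_survival_csv(sv, file.path(out, "survival.csv"))
message(sprintf("survival cohort: %d samples, %d events, %d censored",
                nrow(sv), sum(sv$event), sum(!sv$event)))

message("inputs written under ", out)
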