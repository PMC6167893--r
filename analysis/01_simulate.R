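#!/usr/bin/env Rscript
# Stage 1: generate the reference synthetic cohort.
#
# Emulates a two-stage stratified household survey of Hispanic/Latino
# adults (strata with unequal PSU sampling fractions, oversampling of ages
# 45+), a biallelic T2D risk variant in Hardy-Weinberg proportions at
# allele frequency 0.255, and the recursive life-course system linking
# genotype, BMI at ages 21/45/65 and period-specific first T2D diagnoses.
# Quality-control artifacts (lb/kg unit confusion, pre-adult diagnosis
# ages, close-kin pairs) are injected on top so stage 2 has work to do.
#
# Writes: results/cohort.csv, results/kinship.tsv, results/scenario.json

suppressPackageStartupMessages(library(svypath))
dir.create("results", showWarnings = FALSE)

seed <- 20260930L
cfg <- scenario_config(seed = seed)   # 10 strata x 4 PSUs x 226 = 9040
print(cfg)

cohort <- simulate_cohort(cfg)
cohort <- inject_artifacts(cohort,
                           rates = list(unit_confusion = 0.01,
                                        early_diagnosis = 0.003,
                                        pregnancy = 0.01,
                                        bmi_out_of_range = 0.002,
                                        related_pairs = 0.02),
                           seed = seed)

cat(sprintf("simulated %d participants (%.0f%% aged 45+, %.0f%% aged 65+)\n",
            nrow(cohort), 100 * mean(cohort$age_exam >= 45),
            100 * mean(cohort$age_exam >= 65)))
cat(sprintf("risk-allele frequency in sample: %.3f\n", mean(cohort$G) / 2))
cat(sprintf("injected artifacts: %d (see artifact_truth attribute)\n",
            nrow(attr(cohort, "artifact_truth"))))

write_cohort(cohort, "results/cohort.csv")
write_kinship(attr(cohort, "kinship"), "results/kinship.tsv")
write_scenario_config(cfg, "results/scenario.json")
# hidden truth kept alongside for later scoring
write.csv(attr(cohort, "artifact_truth"), "results/artifact_truth.csv",
          row.names = FALSE)
cat("wrote results/cohort.csv, results/kinship.tsv, results/scenario.json\n")
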