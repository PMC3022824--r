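#!/usr/bin/env Rscript
# Step 1: generate the default synthetic two-cohort case-control study.
#
# The generator emulates the design of a large psoriasis GWAS: a training
# cohort of 941 cases / 686 controls and an independent test cohort of
# 443 cases / 728 controls, here at a desk scale of 500 SNPs with two
# common causal variants (per-allele log-odds 1.1, MAF 0.3) acting through
# a logistic liability under Hardy-Weinberg equilibrium, plus 1% missing
# calls. Genotype matrices go to scratch/ (they are large and fully
# reproducible from the seed); the ground truth goes to results/.

suppressPackageStartupMessages(library(sibsnp))

master_seed <- 1L
data_dir <- "scratch/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = master_seed)
sim <- simulate_cohorts(cfg)

write_cohort(sim$train$G, sim$train$labels, file.path(data_dir, "train"), "tsv")
write_cohort(sim$test$G, sim$test$labels, file.path(data_dir, "test"), "tsv")
# PLINK text mirror of the training cohort, for interoperability checks
write_cohort(sim$train$G, sim$train$labels, file.path(data_dir, "train"), "ped_map")

jsonlite::write_json(
  list(seed = master_seed,
       n_snps = cfg$n_snps,
       causal_snp_ids = sim$truth$causal_snp_ids,
       causal_log_odds = sim$truth$causal_log_odds,
       causal_maf = cfg$causal_maf,
       intercept = sim$truth$intercept,
       realized_prevalence_train = sim$truth$realized_prevalence_train,
       realized_prevalence_test = sim$truth$realized_prevalence_test),
  "results/simulation_truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("training cohort: %d cases / %d controls, %d SNPs\n",
            sum(sim$train$labels == 1), sum(sim$train$labels == 0),
            cfg$n_snps))
cat(sprintf("test cohort:     %d cases / %d controls\n",
            sum(sim$test$labels == 1), sum(sim$test$labels == 0)))
cat(sprintf("causal SNPs: %s (per-allele log-odds %s)\n",
            paste(sim$truth$causal_snp_ids, collapse = ", "),
            paste(sim$truth$causal_log_odds, collapse = ", ")))
cat(sprintf("realized population prevalence: train %.3f, test %.3f\n",
            sim$truth$realized_prevalence_train,
            sim$truth$realized_prevalence_test))
cat("wrote scratch/data/{train,test}.tsv, train.{ped,map}, results/simulation_truth.json\n")
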