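#!/usr/bin/env Rscript
# Step 1: generate the two synthetic SHI samples the study emulates.
#
# Two claims databases with disjoint patient populations are drawn from the
# same generator configuration (years 2013-2019, ages 2-15 at the 2018
# anchor, stratum prevalences at the study's printed 2018 stratified rates)
# but different seeds, so all between-sample differences are sampling noise.
# Writes the four claims tables per sample plus the ground-truth table under
# results/claims_S1 and results/claims_S2.

suppressPackageStartupMessages(library(jiaclaims))

out_root <- "results"
dir.create(out_root, showWarnings = FALSE)

cfg <- generator_config(n_patients = 100000, years = 2013:2019,
                        anchor_year = 2018, seed = 20180101)
sims <- simulate_claims_pair(cfg, second_seed = 20180202)

for (sim in sims) {
  dir <- file.path(out_root, paste0("claims_", sim$db$label))
  write_claims(sim$db, dir)
  data.table::fwrite(sim$truth, file.path(dir, "truth.csv"))
  cat(sprintf("sample %s: %d patients, %d diagnoses, %d true case-years -> %s\n",
              sim$db$label, nrow(sim$db$patients), nrow(sim$db$diagnoses),
              nrow(sim$truth), dir))
}
cat("done: every downstream step reads these tables from disk.\n")
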