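#!/usr/bin/env Rscript
# Stage 1 — simulate the study-scale claims cohort and split it.
#
# Generates a 1727-record cohort with the study's structure (71.5/28.5
# DOAC/VKA split, 20 correlated comorbidity flags, rare death and
# major-bleeding events), then partitions it into the train split (feeds
# protected-data generation), the control split (feeds control attacks) and
# the attacker pool (feeds shadow-model reference sampling).

suppressPackageStartupMessages(library(privcohort))
seed <- 1L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
splits <- split_cohort(cohort, c(0.5, 0.25, 0.25), seed = seed)

write_cohort_csv(cohort, file.path(out, "cohort_full.csv"))
for (nm in names(splits)) {
  write_cohort_csv(splits[[nm]], file.path(out, paste0(nm, ".csv")))
}
write_schema_yaml(cfg$schema, file.path(out, "schema.yaml"))

cat("cohort:", nrow(cohort), "records,", ncol(cohort), "attributes\n")
cat("DOAC share:", round(mean(cohort$treatment_group == "DOAC"), 3), "\n")
cat("events (death):", sum(cohort$death_flag),
    "| events (major bleeding):", sum(cohort$major_bleeding_flag), "\n")
cat("splits:", paste(names(splits), vapply(splits, nrow, 0L),
                     collapse = ", "), "\n")
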