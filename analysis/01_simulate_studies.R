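#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic preclinical studies the analysis
# chain runs on — a cynomolgus-monkey PK study (single-dose arm, n = 6,
# 10/30/100 mg/kg IV, rich sampling to 1007 h; plus the first week of the
# repeat-dose arm, n = 22) and a JIMT-1 xenograft efficacy study (vehicle /
# 2.5 / 25 mg/kg weekly i.p. x4, n = 10 per arm, twice-weekly calipering,
# euthanasia at 800 mm^3).  No animal data are deposited with the original
# analysis, so everything downstream runs on these study-shaped datasets.
suppressPackageStartupMessages(library(transpkpd))

seed <- 20260101
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
set.seed(seed)

truth <- human_default_params()
d1 <- generate_monkey_pk_study(truth, design = monkey_single_dose_design())
d2 <- generate_monkey_pk_study(truth, design = monkey_repeat_dose_design())
d2$ID <- d2$ID + max(d1$ID)
monkey <- rbind(d1, d2)
write_dataset(monkey, "results/data/monkey_pk.csv")
message(sprintf("monkey PK study: %d animals, %d observations (%d below LLOQ)",
                length(unique(monkey$ID)), sum(monkey$EVID == 0),
                sum(monkey$BLQ == 1)))

xeno <- generate_xenograft_study(pd_params(), mouse_default_params())
write_dataset(xeno, "results/data/xenograft.csv")
obs <- xeno[xeno$EVID == 0, ]
last_day <- max(xenograft_rules()$measurement_days)
censored <- tapply(obs$TIME, obs$ID, max) / 24 < last_day
message(sprintf("xenograft study: %d mice, %d tumor measurements, %d mice censored at 800 mm^3",
                length(unique(xeno$ID)), nrow(obs), sum(censored)))
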