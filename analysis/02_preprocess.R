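#!/usr/bin/env Rscript
# Stage 2: clean the raw diary responses.
#
# After-midnight responses are recoded to the previous day, same-day
# duplicates averaged, the four items scored into the SRBAI, interior
# singleton gaps imputed by the neighbour mean, and participants retained if
# they have >= 6 observed values and engaged past the decay-phase midpoint.

suppressPackageStartupMessages(library(habitdecay))

responses <- read.csv("results/raw_responses.csv")
cfg <- cohort_config(seed = 20260926L)  # same study design as stage 1

pre <- preprocess_diary(responses, start_date = cfg$start_date,
                        n_days = cfg$n_days, day_offset = cfg$day_offset)

write.csv(pre$occasions, "results/occasions.csv", row.names = FALSE)
write.csv(pre$exclusions, "results/exclusions.csv", row.names = FALSE)
write.csv(pre$missingness$per_participant, "results/missingness.csv",
          row.names = FALSE)

ov <- pre$missingness$overall
cat(sprintf("retained %d participants (%d excluded)\n",
            ov$n_participants, nrow(pre$exclusions)))
cat(sprintf("missing %d of %d values (%.1f%%), %d imputed (mean %.1f per person)\n",
            ov$n_missing, ov$denominator, 100 * ov$missing_fraction,
            ov$n_imputed, ov$n_imputed / ov$n_participants))
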