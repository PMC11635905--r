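#!/usr/bin/env Rscript
# Stage 3: person-specific trajectory models.
#
# Fits the six families (constant, linear, quadratic, cubic, asymptotic,
# logistic) to every retained participant, selects the best by BIC, and
# applies the 4-step validity gate: decreasing fitted trajectory,
# leave-one-out selection stability, RMSE <= 0.33, longest gap <= 21 days.

suppressPackageStartupMessages(library(habitdecay))

responses <- read.csv("results/raw_responses.csv")
cfg <- cohort_config(seed = 20260926L)
pre <- preprocess_diary(responses, start_date = cfg$start_date,
                        n_days = cfg$n_days, day_offset = cfg$day_offset)

fits <- lapply(pre$series, fit_all_families)
verdicts <- classify_cohort(pre$series, fits)

write.csv(fit_table(fits), "results/fits.csv", row.names = FALSE)
write.csv(verdicts, "results/verdicts.csv", row.names = FALSE)

cat("best-fitting family frequencies:\n")
print(table(verdicts$best_family))
cat(sprintf("\nvalid trajectories: %d of %d (+%d stable-habit constant fits)\n",
            sum(verdicts$overall_valid), nrow(verdicts),
            sum(verdicts$stable_habit_valid)))
cat("validity by family:\n")
print(aggregate(overall_valid ~ best_family, data = verdicts, FUN = sum))
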