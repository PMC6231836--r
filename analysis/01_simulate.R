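#!/usr/bin/env Rscript
# Step 1 — generate the synthetic cohort.
#
# Draws a population of 5,000 step diaries under the default generator
# calibration (lognormal latent steps, centred gender/province offsets,
# engagement-scaled incentive response with week-9 decay onset, 40%/day
# non-wear) and writes the analysis-stage files. The latent engagement
# propensity stays out of the written files by construction.

suppressMessages(library(stepincentives))

out_dir <- "results/run"
seed <- 20260924L
dir.create("scratch", showWarnings = FALSE)

params <- population_params(n_participants = 5000L, seed = seed)
tl <- program_timeline()
pop <- generate_population(params, tl)
write_diaries(pop, out_dir)

wk <- weekly_means(pop$diaries)
base <- wk$mean_steps[wk$study_week == 0 & wk$valid]
cat(sprintf("generated %d participants; %d (%.1f%%) have a valid baseline\n",
            params$n_participants, length(base),
            100 * length(base) / params$n_participants))
cat(sprintf("baseline mean %.1f steps/day; %.1f%% below 5000 (inactive)\n",
            mean(base), 100 * mean(base < 5000)))
saveRDS(pop, "scratch/pop.rds")  # scratch only; re-derivable from the seed
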