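#!/usr/bin/env Rscript
# Step 1 — synthesize the study cohort.
#
# Ten synthetic subjects with the interleaved visual/vestibular/combined
# design. Each subject's bounds are the endpoint of a prematurely
# stopped ("deep" preset) gradient ascent on that subject's own
# reward-rate surface, so the cohort embodies incomplete gradient
# learning by construction. Writes one trial CSV and one truth JSON per
# subject under results/cohort/.

suppressPackageStartupMessages(library(msddm))
seed <- 1
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- experiment_design()        # 100 trials/cell, 3 coherences
spec <- reward_spec()                # 6 s ITI, no accumulation cost

message("simulating 10 truncated-learner subjects (seed ", seed, ") ...")
cohort <- generate_cohort(10, base_variability = 0.15, seed = seed,
                          design = design, truncated = TRUE, spec = spec,
                          truncation = "deep", n_restarts = 3)

for (s in cohort) {
  id <- s$truth$subject_id
  write_trial_table(s$trials, file.path(out_dir, paste0(id, ".csv")))
  p <- s$truth$params
  jsonlite::write_json(
    list(subject = id, seed = s$truth$seed,
         k_vest = p$k_vest, k_vis = as.list(p$k_vis),
         bounds = as.list(p$bounds$theta),
         theta_opt = as.list(bound_coords(s$learner$opt$theta_opt)),
         rr_opt = s$learner$opt$rr_opt,
         t_nd = as.list(p$t_nd), bias = p$bias,
         learning = s$learner$config[c("alpha", "n_steps", "mode")]),
    file.path(out_dir, paste0(id, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  message("  ", id, ": ", nrow(s$trials), " trials; rr_opt ",
          signif(s$learner$opt$rr_opt, 4))
}
message("cohort written to ", out_dir)
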