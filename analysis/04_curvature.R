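#!/usr/bin/env Rscript
# Step 4 — incomplete-learning diagnostics.
#
# The curvature-versus-distance diagnostic is only faithful where the
# reward surface is locally quadratic (see the methods vignette), so
# this step builds, for each subject, a gradient learner truncated
# inside that neighbourhood of the stored optimum (the "quadratic"
# preset) and reports, per Hessian eigendimension, the |curvature| /
# |distance-to-optimum| pairs, their rank correlation, and the
# quadratic-loss check. The deeply truncated bounds that generated the
# cohort's trial data sit below that neighbourhood; their position on
# the optimal-bound line is step 3's s-projection.
# Writes results/curvature_pairs.csv and results/curvature_summary.csv.

suppressPackageStartupMessages(library(msddm))
design <- experiment_design()
spec <- reward_spec()
profile <- make_stimulus_profile(design$duration_s, 0.005)
truths <- list.files("results/cohort", pattern = "_truth\\.json$",
                     full.names = TRUE)
stopifnot(length(truths) > 0)

pairs_rows <- sum_rows <- list()
for (f in truths) {
  j <- jsonlite::read_json(f)
  id <- j$subject
  params <- subject_params(
    k_vest = j$k_vest, k_vis = unlist(j$k_vis),
    bounds = bound_vector(theta = unlist(j$bounds)),
    t_nd = unlist(j$t_nd), bias = j$bias)
  opt <- structure(list(theta_opt = bound_vector(theta = unlist(j$theta_opt)),
                        rr_opt = j$rr_opt, variant = "free"),
                   class = "optimization_result")
  lq <- make_truncated_learner(params, design, spec, opt = opt,
                               seed = 40 + match(f, truths),
                               profile = profile)
  rep <- reward_rate_hessian(lq$params, design, spec, richardson = FALSE,
                             profile = profile)
  pr <- curvature_distance_analysis(rep, lq$params$bounds, opt$theta_opt)
  pr$subject <- id
  pairs_rows[[id]] <- pr
  rr_hat <- model_reward_rate(lq$params, design, spec, profile, 100)
  ql <- quadratic_loss_check(rep, lq$params$bounds, opt$theta_opt,
                             rr_hat, opt$rr_opt)
  keep <- !pr$degenerate
  rho <- cor(pr$abs_curvature[keep], pr$abs_distance[keep],
             method = "spearman")
  sum_rows[[id]] <- tibble::tibble(
    subject = id, spearman = rho,
    model_loss = ql[["model_loss"]],
    quadratic_loss = ql[["quadratic_loss"]])
  message(sprintf("  %s: spearman %+.3f, model loss %.2e, quad loss %.2e",
                  id, rho, ql[["model_loss"]], ql[["quadratic_loss"]]))
}
utils::write.csv(do.call(rbind, pairs_rows),
                 "results/curvature_pairs.csv", row.names = FALSE)
utils::write.csv(do.call(rbind, sum_rows),
                 "results/curvature_summary.csv", row.names = FALSE)
message("wrote results/curvature_pairs.csv, results/curvature_summary.csv")
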