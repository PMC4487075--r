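test_that("reward rate reduces to arithmetic at zero bounds and is linear in cost", {
  des <- fx_design()
  p <- default_subject_params(des)
  th <- theta_by_cell(p$bounds, des)
  p0 <- p
  p0$bounds <- bound_vector(theta = setNames(rep(0, length(th)), names(th)))
  p0$t_nd[] <- 0.3
  expect_equal(model_reward_rate(p0, des, reward_spec(iti_s = 6)),
               0.5 / 6.3, tolerance = 1e-9)
  expect_equal(random_choice_rr(p0, des, reward_spec()), 0.5 / 6.3,
               tolerance = 1e-12)
  # f(cost) = f(0) - cost * E[DT] / (E[RT] + iti), exactly
  pr <- fx_profile(0.005)
  cs <- msddm:::cell_summaries(p, des, pr, 100)
  f0 <- msddm:::.rr_from_stats(cs$p_correct, cs$mean_dt, cs$mean_rt,
                               cs$weight, reward_spec(cost_per_s = 0))
  f2 <- msddm:::.rr_from_stats(cs$p_correct, cs$mean_dt, cs$mean_rt,
                               cs$weight, reward_spec(cost_per_s = 0.2))
  edt <- sum(cs$weight * cs$mean_dt)
  ert <- sum(cs$weight * cs$mean_rt)
  expect_equal(f2, f0 - 0.2 * edt / (ert + 6), tolerance = 1e-12)
})

test_that("pipeline reward rate matches the constant-drift closed form", {
  # single condition with flat drift: p and E[DT] have closed forms
  pr <- fx_long_profile()
  mu <- 1; th <- 1; tnd <- 0.3
  d <- fpt_solve(rep(mu, length(pr$t)), th, 0, pr)
  cs <- condition_summary(d, tnd, +1)
  f_pipe <- cs[["p_correct"]] / (cs[["mean_rt"]] + 6)
  p_cf <- 1 / (1 + exp(-2 * mu * th))
  dt_cf <- (th / mu) * tanh(mu * th)
  f_cf <- p_cf / (dt_cf + tnd + 6)
  expect_equal(f_pipe, f_cf, tolerance = 0.01)
})

test_that("empirical reward rate matches its arithmetic and the model", {
  tab <- tibble::tibble(subject = "s", modality = "visual",
                        coherence = 0.5, heading_deg = 8,
                        choice = 1, rt_s = 1)[rep(1, 40), ]
  expect_equal(empirical_reward_rate(tab, reward_spec()), 1 / 7)
  tab2 <- tab
  tab2$choice <- rep(c(1, -1), 20)
  tab2$rt_s <- 0.3
  expect_equal(
    empirical_reward_rate(tab2, reward_spec(),
                          t_nd = c(vestibular = 0.3, visual = 0.3,
                                   combined = 0.3)),
    0.5 / 6.3)
  expect_error(empirical_reward_rate(tab[0, ]), "empty")
  # simulation consistency against the model value
  gs <- fx_trials400()
  p <- gs$truth$params
  rr_m <- model_reward_rate(p, gs$truth$design, reward_spec(),
                            fx_profile(0.005), 100)
  rr_e <- empirical_reward_rate(gs$trials, reward_spec(), p$t_nd)
  ci <- bootstrap_rr_ci(gs$trials, reward_spec(), p$t_nd,
                        n_boot = 1000, seed = 2)
  se <- (ci[["high"]] - ci[["low"]]) / (2 * 1.96)
  expect_lt(abs(rr_e - rr_m), 3 * se)
})

test_that("bound optimization matches a one-dimensional grid search", {
  # all design weight on one visual cell makes the objective 1-D
  des <- experiment_design(n_per_cell = 10)
  w <- ifelse(des$cells$cell == "visual_c0.7", 1, 0)
  des1 <- experiment_design(weights = w)
  p <- default_subject_params(des1)
  opt <- optimize_bounds(p, des1, reward_spec(), n_restarts = 3,
                         seed = 1, max_iter = 300)
  obj <- msddm:::rr_objective(p, des1, reward_spec())
  co <- bound_coords(p$bounds)
  grid <- seq(0.05, 3, by = 0.01)
  fg <- vapply(grid, function(v) {
    x <- co; x["visual_c0.7"] <- v; obj$f(x)
  }, numeric(1))
  th_grid <- grid[which.max(fg)]
  th_opt <- bound_coords(opt$theta_opt)[["visual_c0.7"]]
  expect_lt(abs(th_opt - th_grid) / th_grid, 0.05)
  expect_gte(opt$rr_opt, max(fg) - 1e-6)
})

test_that("the tuned optimum dominates fitted bounds and rises when cost falls", {
  h <- fx_harness(1)
  expect_gte(h$opt$rr_opt, h$opt$rr_start - 1e-10)
  expect_gte(h$opt$rr_opt, h$rr_random)
  des <- fx_design()
  opt_cost <- optimize_bounds(h$params, des, reward_spec(cost_per_s = 0.2),
                              n_restarts = 2, seed = 1,
                              profile = h$profile, max_iter = 200)
  expect_lte(opt_cost$rr_opt, h$opt$rr_opt)
})

test_that("relative reward rate behaves as a fraction of optimum", {
  h <- fx_harness(1)
  expect_equal(relative_rr(h$opt$rr_opt, h$opt), 1)
  expect_equal(relative_rr(0, h$opt), 0)
  expect_gt(relative_rr(h$rr_deep, h$opt), 0.8)
  expect_lt(relative_rr(h$rr_deep, h$opt), 1)
  fake <- h$opt; fake$rr_opt <- 0
  expect_error(relative_rr(0.05, fake), "positive")
})

test_that("the bound-scaling curve starts at the random baseline and peaks at one", {
  h <- fx_harness(1)
  des <- fx_design()
  curve <- bound_scaling_curve(h$params, h$opt, des, h$spec,
                               s_grid = seq(0, 1.6, by = 0.05),
                               profile = h$profile)
  at <- function(s) curve$rr[which.min(abs(curve$s - s))]
  expect_equal(at(0), h$rr_random, tolerance = 1e-9)
  s_peak <- curve$s[which.max(curve$rr)]
  expect_lte(abs(s_peak - 1), 0.05 + 1e-9)
  # reward falls off faster below than above the optimum
  expect_lt(at(0.7), at(1.3))
})

test_that("iso-reward projection solves its defining equation on the correct branch", {
  h <- fx_harness(1)
  des <- fx_design()
  th_hat <- h$learner_deep$params$bounds
  s <- project_to_bound_line(th_hat, h$opt, h$params, des, h$spec,
                             profile = h$profile)
  sv <- project_to_bound_line(th_hat, h$opt, h$params, des, h$spec,
                              mode = "vector", profile = h$profile)
  expect_lt(s, 1)
  expect_lt(sv, 1)       # both projections agree on the side
  obj <- msddm:::rr_objective(h$params, des, h$spec, h$profile)
  resid <- obj$f(s * bound_coords(h$opt$theta_opt)) -
    obj$f(bound_coords(th_hat))
  expect_lt(abs(resid), 1e-6)
  # the optimum itself projects to one
  s1 <- project_to_bound_line(h$opt$theta_opt, h$opt, h$params, des,
                              h$spec, profile = h$profile)
  expect_equal(s1, 1, tolerance = 0.02)
})

test_that("combined-condition trials earn more reward than unimodal ones", {
  gs <- fx_trials400()
  p <- gs$truth$params
  sg <- compare_subgroups(gs$trials, reward_spec(), p$t_nd,
                          n_boot = 1000, seed = 3)
  rr_comb <- sg$rr[sg$subgroup == "combined"]
  expect_gt(rr_comb, sg$rr[sg$subgroup == "visual"])
  expect_gt(rr_comb, sg$rr[sg$subgroup == "vestibular"])
  expect_gt(rr_comb, sg$ci_high[sg$subgroup == "unimodal"])
})
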