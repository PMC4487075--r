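# Shared fixtures, built lazily and cached for the whole test run.
# The expensive end-to-end harness (bound optimization + truncated
# learners + curvature reports) is reused across reward, curvature,
# synthdata and acceptance tests.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

fx_design <- function() fx_cache("design", function() experiment_design())

fx_profile <- function(dt = 0.001) {
  fx_cache(paste0("prof_", dt), function() make_stimulus_profile(2, dt))
}

# long flat-drift window for constant-drift closed-form oracles
fx_long_profile <- function() {
  fx_cache("prof_long", function() make_stimulus_profile(12, 0.002))
}

# one cohort-drawn synthetic subject (truth parameters only)
fx_subject <- function(seed) {
  fx_cache(paste0("subj_", seed), function() {
    des <- fx_design()
    set.seed(seed)
    p <- default_subject_params(des)
    p$k_vest <- p$k_vest * exp(rnorm(1, 0, 0.15))
    p$k_vis <- p$k_vis * exp(rnorm(length(p$k_vis), 0, 0.15))
    co <- bound_coords(p$bounds)
    p$bounds <- msddm:::set_bound_coords(
      p$bounds, co * exp(rnorm(length(co), 0, 0.15)))
    p
  })
}

# full reward/curvature harness for one synthetic subject:
# optimization, quadratic-regime learner + curvature report, deep
# learner for the bound-line analyses
fx_harness <- function(seed) {
  fx_cache(paste0("harness_", seed), function() {
    des <- fx_design()
    spec <- reward_spec()
    prof <- make_stimulus_profile(des$duration_s, 0.005)
    p <- fx_subject(seed)
    opt <- optimize_bounds(p, des, spec, n_restarts = 3, seed = seed,
                           profile = prof, max_iter = 300)
    lq <- make_truncated_learner(p, des, spec, opt = opt, seed = seed,
                                 profile = prof)
    ld <- make_truncated_learner(p, des, spec, truncation = "deep",
                                 opt = opt, seed = seed, profile = prof)
    rr_q <- model_reward_rate(lq$params, des, spec, prof, 100)
    rr_d <- model_reward_rate(ld$params, des, spec, prof, 100)
    rep_q <- reward_rate_hessian(lq$params, des, spec,
                                 richardson = FALSE, profile = prof)
    pairs_q <- curvature_distance_analysis(rep_q, lq$params$bounds,
                                           opt$theta_opt)
    list(params = p, spec = spec, profile = prof, opt = opt,
         learner_quad = lq, learner_deep = ld,
         rr_quad = rr_q, rr_deep = rr_d,
         rr_random = random_choice_rr(p, des, spec),
         report_quad = rep_q, pairs_quad = pairs_q)
  })
}

# a well-sampled trial table from the template subject (for empirical
# reward-rate and subgroup checks)
fx_trials400 <- function() {
  fx_cache("trials400", function() {
    des <- experiment_design(n_per_cell = 400)
    generate_subject(default_subject_params(des), des, seed = 11)
  })
}

# reduced-cost settings used for maximum-likelihood fits in the tests
fx_fit_settings <- function(seed = 1, ...) {
  modifyList(list(n_restarts = 1, maxit = 60, solver_dt = 0.01, nx = 60,
                  seed = seed), list(...))
}
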