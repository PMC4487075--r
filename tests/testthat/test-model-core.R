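# drift construction ------------------------------------------------------

test_that("drift vanishes at heading zero and obeys the combination rule", {
  des <- fx_design()
  p <- default_subject_params(des)
  pr <- fx_profile()
  for (m in c("vestibular", "visual", "combined")) {
    coh <- if (m == "vestibular") NA else 0.37
    expect_true(all(drift_timecourse(p, m, coh, 0, pr) == 0))
  }
  # k_vest = 0 makes the combined stream identical to the visual one
  p0 <- p; p0$k_vest <- 0
  expect_equal(drift_timecourse(p0, "combined", 0.7, 8, pr),
               drift_timecourse(p0, "visual", 0.7, 8, pr))
  # root-sum-square combination, pointwise
  mv <- drift_timecourse(p, "visual", 0.25, -12, pr)
  ma <- drift_timecourse(p, "vestibular", NA, -12, pr)
  mc <- drift_timecourse(p, "combined", 0.25, -12, pr)
  expect_equal(mc^2, mv^2 + ma^2, tolerance = 1e-12)
})

test_that("coherence bookkeeping is enforced", {
  des <- fx_design()
  p <- default_subject_params(des)
  pr <- fx_profile()
  expect_error(drift_timecourse(p, "visual", NA, 5, pr), "coherence")
  expect_error(drift_timecourse(p, "vestibular", 0.5, 5, pr),
               "no coherence")
  expect_error(drift_timecourse(p, "visual", 0.5, 95, pr), "heading")
})

# first-passage solver -----------------------------------------------------

test_that("solver matches constant-drift closed forms", {
  pr <- fx_long_profile()
  mu <- rep(1, length(pr$t))
  d <- fpt_solve(mu, 1, 0, pr)
  expect_equal(d$p_up + d$forced_up, 1 / (1 + exp(-2)), tolerance = 0.005)
  expect_equal(d$mean_dt, tanh(1), tolerance = 0.01)
})

test_that("probability mass is conserved across parameter draws", {
  pr <- fx_profile(0.002)
  des <- fx_design()
  set.seed(101)
  for (i in 1:8) {
    p <- default_subject_params(des)
    p$k_vest <- runif(1, 1, 12)
    cell <- des$cells[sample.int(7, 1), ]
    mu <- drift_timecourse(p, cell$modality,
                           if (cell$modality == "vestibular") NA
                           else cell$coherence,
                           runif(1, -20, 20), pr)
    d <- fpt_solve(mu, runif(1, 0.1, 2.5), runif(1, -0.5, 0.5), pr)
    total <- d$p_up + d$p_lo + d$forced_up + d$forced_lo
    expect_lt(abs(total - 1), 1e-4)
  }
})

test_that("zero bound gives an immediate even split", {
  pr <- fx_profile(0.002)
  d <- fpt_solve(rep(1, length(pr$t)), 0, 0, pr)
  expect_equal(d$p0_up, 0.5)
  expect_equal(d$p0_lo, 0.5)
  expect_equal(d$mean_dt, 0)
  expect_equal(condition_summary(d, 0.3, 0),
               c(p_correct = 0.5, mean_rt = 0.3, mean_dt = 0))
})

test_that("flipping heading and bias signs swaps the boundary densities", {
  des <- fx_design()
  p <- default_subject_params(des)
  pr <- fx_profile(0.002)
  mu <- drift_timecourse(p, "combined", 0.37, 8, pr)
  d1 <- fpt_solve(mu, 1.2, 0.3, pr)
  d2 <- fpt_solve(-mu, 1.2, -0.3, pr)
  expect_equal(d1$g_up, d2$g_lo, tolerance = 1e-10)
  expect_equal(d1$g_lo, d2$g_up, tolerance = 1e-10)
  expect_equal(d1$forced_up, d2$forced_lo, tolerance = 1e-12)
})

test_that("accuracy and decision time are monotone in the bound (constant drift)", {
  pr <- fx_long_profile()
  mu <- rep(1, length(pr$t))
  thetas <- c(0.3, 0.6, 1, 1.5, 2)
  res <- vapply(thetas, function(th) {
    d <- fpt_solve(mu, th, 0, pr)
    c(p = d$p_up + d$forced_up, dt = d$mean_dt)
  }, numeric(2))
  expect_true(all(diff(res["p", ]) > -1e-10))
  expect_true(all(diff(res["dt", ]) > -1e-10))
})

test_that("condition_summary separates decision and non-decision time", {
  pr <- fx_profile(0.002)
  des <- fx_design()
  p <- default_subject_params(des)
  mu <- drift_timecourse(p, "visual", 0.7, 8, pr)
  d <- fpt_solve(mu, 1.1, p$bias, pr)
  cs <- condition_summary(d, 0.35, +1)
  expect_equal(cs[["mean_rt"]] - cs[["mean_dt"]], 0.35)
  expect_equal(cs[["p_correct"]], d$p_up + d$forced_up)
  cs_neg <- condition_summary(d, 0.35, -1)
  expect_equal(cs_neg[["p_correct"]], d$p_lo + d$forced_lo)
})

# simulation ---------------------------------------------------------------

test_that("simulated choices are unbiased at heading zero", {
  des <- experiment_design(headings_deg = c(-4, 0, 4), n_per_cell = 900)
  p <- default_subject_params(des)
  p$bias <- 0
  tab <- simulate_trials(p, des, seed = 5)
  h0 <- tab[tab$heading_deg == 0, ]
  pr_right <- mean(h0$choice == 1)
  expect_lt(abs(pr_right - 0.5), 3 * sqrt(0.25 / nrow(h0)))
})

test_that("zero bounds collapse reaction times onto the non-decision window", {
  des <- fx_design()
  p <- default_subject_params(des)
  th <- theta_by_cell(p$bounds, des)
  p$bounds <- bound_vector(theta = setNames(rep(0, length(th)), names(th)))
  tab <- simulate_trials(p, des, n_per_cell = 20, seed = 3)
  tnd <- p$t_nd[tab$modality]
  expect_true(all(abs(tab$rt_s - tnd) <= 0.05 + 1e-12))
})

test_that("simulator agrees with the solver under constant drift", {
  pr <- fx_long_profile()
  mu <- rep(0.8, length(pr$t))
  d <- fpt_solve(mu, 1.2, 0, pr)
  set.seed(77)
  sim <- msddm:::sim_paths_cpp(mu, pr$dt_s, 1.2, 0, 10000)
  p_sol <- d$p_up + d$forced_up
  p_sim <- mean(sim$choice == 1)
  expect_lt(abs(p_sim - p_sol), 3 * sqrt(p_sol * (1 - p_sol) / 10000))
})

test_that("simulation is reproducible from its seed", {
  des <- fx_design()
  p <- default_subject_params(des)
  t1 <- simulate_trials(p, des, n_per_cell = 10, seed = 21)
  t2 <- simulate_trials(p, des, n_per_cell = 10, seed = 21)
  expect_identical(t1, t2)
})
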