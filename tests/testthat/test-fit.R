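test_that("zero-bound trials carry the forced even-split density", {
  des <- fx_design()
  p <- default_subject_params(des)
  th <- theta_by_cell(p$bounds, des)
  p$bounds <- bound_vector(theta = setNames(rep(0, length(th)), names(th)))
  pr <- fx_profile(0.005)
  trial <- tibble::tibble(subject = "s", modality = "visual",
                          coherence = 0.7, heading_deg = 8, choice = 1,
                          rt_s = unname(p$t_nd["visual"]))
  ll <- trial_loglik(p, trial, pr, des)
  # point mass 1/2 smeared over the 100 ms jitter window
  expect_equal(ll, log(0.5 / 0.1), tolerance = 1e-9)
})

test_that("the RT likelihood integrates to one over choices and times", {
  des <- fx_design()
  pr <- fx_profile(0.002)
  set.seed(31)
  for (i in 1:2) {
    p <- default_subject_params(des)
    p$k_vest <- runif(1, 3, 8)
    p$bias <- runif(1, -0.3, 0.3)
    mu <- drift_timecourse(p, "combined", 0.37, 6, pr)
    th <- unname(theta_by_cell(p$bounds, des)["combined_c0.37"])
    d <- fpt_solve(mu, th, p$bias, pr)
    u <- seq(-0.06, 2.06, by = 0.002)
    dens <- msddm:::.jittered_density(msddm:::.cdf_knots(d, "up"), u, 0.05) +
      msddm:::.jittered_density(msddm:::.cdf_knots(d, "lo"), u, 0.05)
    total <- sum((dens[-1] + dens[-length(dens)]) / 2) * 0.002
    expect_equal(total, 1, tolerance = 1e-3)
  }
})

test_that("the lapse mixture combines model and uniform components", {
  des <- fx_design()
  pr <- fx_profile(0.005)
  p0 <- default_subject_params(des)
  trial <- tibble::tibble(subject = "s", modality = "vestibular",
                          coherence = NA, heading_deg = -8, choice = -1,
                          rt_s = 0.9)
  p1 <- p0; p1$lapse <- 0.1
  d0 <- exp(trial_loglik(p0, trial, pr, des))
  d1 <- exp(trial_loglik(p1, trial, pr, des))
  u <- trial$rt_s - unname(p0$t_nd["vestibular"])
  expect_equal(d1, 0.9 * d0 + 0.1 * 0.5 / des$duration_s,
               tolerance = 1e-10)
  # an impossible reaction time has zero density without lapse
  trial$rt_s <- 5
  expect_identical(trial_loglik(p0, trial, pr, des), -Inf)
})

test_that("maximum-likelihood recovery stays within tolerance across subjects", {
  des <- fx_design()   # 100 trials per cell
  errs_b <- errs_k <- errs_bias <- NULL
  for (sd in 1:5) {
    co <- generate_cohort(1, 0.15, seed = sd, design = des)[[1]]
    truth <- co$truth$params
    fit <- fit_subject(co$trials, des, "free", fx_fit_settings(seed = sd))
    tb <- theta_by_cell(truth$bounds, des)
    fb <- theta_by_cell(fit$params$bounds, des)
    errs_b <- c(errs_b, abs(fb - tb) / tb)
    kt <- c(truth$k_vest, truth$k_vis)
    kf <- c(fit$params$k_vest, fit$params$k_vis)
    errs_k <- c(errs_k, abs(kf - kt) / kt)
    errs_bias <- c(errs_bias, abs(fit$params$bias - truth$bias))
  }
  expect_lte(median(errs_b), 0.10)
  expect_lte(median(errs_k), 0.15)
  expect_true(all(errs_bias <= 0.05))
})

test_that("recovery improves with more trials on average", {
  rmse_for <- function(n, sd) {
    des <- experiment_design(n_per_cell = n)
    co <- generate_cohort(1, 0.15, seed = sd, design = des)[[1]]
    fit <- fit_subject(co$trials, des, "free", fx_fit_settings(seed = sd))
    tb <- theta_by_cell(co$truth$params$bounds, des)
    fb <- theta_by_cell(fit$params$bounds, des)
    sqrt(mean((fb - tb)^2))
  }
  r100 <- vapply(1:3, function(sd) rmse_for(100, sd), numeric(1))
  r400 <- vapply(1:3, function(sd) rmse_for(400, sd), numeric(1))
  expect_lte(mean(r400), mean(r100))
})

test_that("the parametric bound variant can be fitted directly", {
  des <- fx_design()
  truth <- default_subject_params(des)
  truth$bounds <- bound_vector(variant = "parametric",
                               theta_modality = c(vestibular = 1.1,
                                                  visual = 1.25,
                                                  combined = 1.15),
                               slope = 0.25)
  gs <- generate_subject(truth, des, seed = 13)
  fit <- fit_subject(gs$trials, des, "parametric",
                     fx_fit_settings(seed = 2, maxit = 50))
  expect_s3_class(fit$params$bounds, "bound_vector")
  expect_identical(fit$params$bounds$variant, "parametric")
  tb <- theta_by_cell(truth$bounds, des)
  fb <- theta_by_cell(fit$params$bounds, des)
  expect_lte(median(abs(fb - tb) / tb), 0.15)
})

test_that("model psychometrics hit their degenerate and simulated anchors", {
  des <- fx_design()
  p <- default_subject_params(des)
  th <- theta_by_cell(p$bounds, des)
  p0 <- p
  p0$bounds <- bound_vector(theta = setNames(rep(0, length(th)), names(th)))
  tab0 <- predicted_psychometric(p0, des, fx_profile(0.005), nx = 60)
  expect_equal(tab0$p_correct, rep(0.5, 7))
  expect_equal(tab0$mean_rt, unname(p0$t_nd[tab0$modality]))
  # an unbiased subject can never fall below chance
  p$bias <- 0
  tab <- predicted_psychometric(p, des, fx_profile(0.005), nx = 100)
  expect_true(all(tab$p_correct >= 0.5 - 1e-9))
  expect_true(all(tab$p_correct <= 1))
  # one cell against direct simulation
  sim <- simulate_trials(p, des, n_per_cell = 3000, seed = 17)
  cell <- sim[sim$modality == "combined" & sim$coherence == 0.7, ]
  p_emp <- mean(sign(cell$choice) == sign(cell$heading_deg))
  p_mod <- tab$p_correct[tab$cell == "combined_c0.7"]
  expect_lt(abs(p_emp - p_mod), 3 * sqrt(p_mod * (1 - p_mod) / nrow(cell)))
})

test_that("fit results serialize to JSON", {
  des <- fx_design()
  gs <- generate_subject(default_subject_params(des),
                         experiment_design(n_per_cell = 30), seed = 5)
  fit <- fit_subject(gs$trials, des, "free",
                     fx_fit_settings(seed = 3, maxit = 5))
  path <- tempfile(fileext = ".json")
  write_fit_result(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$loglik, fit$loglik)
  expect_equal(back$n_trials, fit$n_trials)
  expect_named(back$bounds, names(fit$params$bounds$theta),
               ignore.order = TRUE)
})
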