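quad_surface <- function(lam, center = c(0, 0)) {
  function(x) -0.5 * sum(lam * (x - center)^2)
}

test_that("finite-difference Hessian recovers analytic second derivatives", {
  f <- function(x) -(x[1]^2 + 4 * x[2]^2)
  H <- fd_hessian(f, c(0.3, -0.2), step = 1e-3)
  expect_equal(max(abs(H - t(H))), 0, tolerance = 1e-6)
  rep <- msddm:::.curvature_report(H, 1e-3)
  expect_equal(rep$H, diag(c(-2, -8)), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(sort(rep$eigenvalues), c(-8, -2), tolerance = 1e-4)
  expect_equal(sort(abs(rep$eigenvalues)), c(2, 8), tolerance = 1e-4)
})

test_that("fd Hessian matches analytic Hessians on polynomial surfaces", {
  f <- function(x) -x[1]^2 - 3 * x[2]^2 + 0.5 * x[1] * x[2] + x[1]^3 / 10
  x0 <- c(0.4, 0.1)
  H_true <- matrix(c(-2 + 6 * x0[1] / 10, 0.5, 0.5, -6), 2, 2)
  H <- fd_hessian(f, x0, step = 1e-3)
  expect_equal(max(abs(H - H_true)) / max(abs(H_true)), 0,
               tolerance = 1e-3)
})

test_that("eigenspace distances reduce to coordinate distances for diagonal Hessians", {
  rep <- msddm:::.curvature_report(diag(c(-2, -8)), 1e-2)
  pr <- curvature_distance_analysis(rep, c(0, 0), c(0.3, 0.7))
  # eigenvectors are coordinate axes; sorted by |lambda| descending
  expect_equal(sort(pr$abs_distance), c(0.3, 0.7))
  expect_equal(pr$abs_curvature, c(8, 2))
  pr0 <- curvature_distance_analysis(rep, c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(pr0$abs_distance, c(0, 0))
  expect_error(curvature_distance_analysis(rep, c(1, 2, 3), c(0, 0, 0)),
               "dimension")
})

test_that("quadratic loss equals model loss exactly on quadratic surfaces", {
  lam <- c(3, 0.5)
  f <- quad_surface(lam, center = c(1, 2))
  th_hat <- c(0.6, 1.1)
  H <- fd_hessian(f, th_hat, step = 1e-4)
  rep <- msddm:::.curvature_report(H, 1e-4)
  ql <- quadratic_loss_check(rep, th_hat, c(1, 2), f(th_hat), f(c(1, 2)))
  expect_equal(ql[["model_loss"]], ql[["quadratic_loss"]],
               tolerance = 1e-8)
  ql0 <- quadratic_loss_check(rep, c(1, 2), c(1, 2), 0, 0)
  expect_equal(unname(ql0), c(0, 0))
})

test_that("deterministic learning decays geometrically on quadratic surfaces", {
  lam <- c(8, 0.5)
  f <- quad_surface(lam)
  cfg <- learning_config(alpha = 0.1, n_steps = 10, fd_step = 1e-5)
  traj <- simulate_learning(f, c(1, 1), cfg)
  resid <- abs(traj$theta[11, ])
  expect_equal(resid[1], (1 - 0.1 * 8)^10, tolerance = 1e-6)
  expect_equal(resid[2], (1 - 0.1 * 0.5)^10, tolerance = 1e-6)
  expect_equal(resid[2], 0.95^10, tolerance = 1e-6)
  # objective is nondecreasing at a stable step size
  expect_true(all(diff(traj$f) > -1e-12))
})

test_that("a vanishing step size freezes the trajectory", {
  f <- quad_surface(c(2, 2))
  traj <- simulate_learning(f, c(1, -1),
                            learning_config(alpha = 1e-12, n_steps = 5))
  expect_equal(traj$theta[6, ], c(1, -1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("unstable step sizes raise an instability error", {
  f <- quad_surface(c(50, 50))
  expect_error(
    simulate_learning(f, c(1, 1),
                      learning_config(alpha = 1, n_steps = 50)),
    "alpha")
})

test_that("truncated learning ends nearer the optimum along steep eigendirections", {
  lam <- c(5, 0.2)   # 25x curvature spread
  f <- quad_surface(lam)
  for (seed in 1:5) {
    tr <- simulate_learning(f, c(1, 1),
                            learning_config(alpha = 0.1, n_steps = 10,
                                            seed = seed))
    resid <- abs(tr$theta[11, ])
    expect_lt(resid[1], resid[2])
  }
  # stochastic single-coordinate acceptance shows the same signature
  # (acceptance noise comparable to the shallow dimension's improvements
  # turns that dimension into a random walk while the steep one ratchets)
  f2 <- quad_surface(c(5, 0.05))
  for (seed in 1:3) {
    tr <- simulate_learning(f2, c(1, 1),
                            learning_config(alpha = 0.2, n_steps = 150,
                                            mode = "stochastic",
                                            eps_sd = 0.1, seed = seed))
    resid <- abs(tr$theta[151, ])
    expect_lt(resid[1], resid[2])
  }
})

test_that("stochastic acceptance without noise never decreases the objective", {
  f <- quad_surface(c(2, 1))
  tr <- simulate_learning(f, c(1.5, -0.5),
                          learning_config(alpha = 0.2, n_steps = 100,
                                          mode = "stochastic",
                                          eps_sd = 0, seed = 2))
  expect_true(all(diff(tr$f) > -1e-12))
})

test_that("reward-rate Hessian is symmetric with near-nonpositive spectrum at the optimum", {
  h <- fx_harness(1)
  des <- fx_design()
  rep <- suppressWarnings(
    reward_rate_hessian(h$params, des, h$spec,
                        theta_hat = h$opt$theta_opt,
                        richardson = TRUE, profile = h$profile))
  expect_equal(max(abs(rep$H - t(rep$H))), 0, tolerance = 1e-8)
  expect_true(all(rep$eigenvalues < 1e-4))
  expect_true(is.finite(rep$richardson_rel))
  expect_equal(nrow(curvature_distance_analysis(rep, h$opt$theta_opt,
                                                h$opt$theta_opt)), 7)
  path <- tempfile(fileext = ".json")
  write_curvature_report(rep, path, h$pairs_quad)
  back <- jsonlite::read_json(path)
  expect_length(back$eigenvalues, 7)
  expect_equal(length(back$pairs), 7)
})
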