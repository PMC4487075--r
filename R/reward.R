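#' Model-predicted reward rate
#'
#' Reward rate of the model at its current parameters: expected correct
#' fraction (net of the evidence-accumulation cost times expected
#' decision time) divided by the average time between trial onsets,
#' \deqn{f = \frac{\sum_i w_i p_i - c \sum_i w_i \bar t_{D,i}}
#'            {\sum_i w_i \bar t_{R,i} + t_{iti}},}
#' with cell weights \eqn{w_i}, per-cell accuracy \eqn{p_i}, mean
#' decision time \eqn{\bar t_D} and mean reaction time \eqn{\bar t_R},
#' all marginalized over the design's headings.
#'
#' @param params a [subject_params()].
#' @param design an [experiment_design()].
#' @param spec a [reward_spec()].
#' @param profile optional stimulus profile (default 1 ms grid).
#' @param nx solver space intervals.
#' @return Reward rate in reward units per second.
#' @export
model_reward_rate <- function(params, design, spec = reward_spec(),
                              profile = NULL, nx = 200) {
  if (is.null(profile))
    profile <- make_stimulus_profile(design$duration_s, 0.001)
  cs <- cell_summaries(params, design, profile, nx)
  .rr_from_stats(cs$p_correct, cs$mean_dt, cs$mean_rt, cs$weight, spec)
}

.rr_from_stats <- function(p, md, mr, w, spec) {
  (spec$reward_correct * sum(w * p) - spec$cost_per_s * sum(w * md)) /
    (sum(w * mr) + spec$iti_s)
}

#' Empirical reward rate of a trial (sub)table
#'
#' Fraction of correct choices (heading-0 trials credited 0.5), net of
#' the accumulation cost times the mean decision time, divided by the
#' mean trial-onset-to-onset time.
#'
#' @param trials trial table (any subgroup).
#' @param spec a [reward_spec()].
#' @param t_nd per-modality non-decision times used to strip decision
#'   time out of the reaction time, named vestibular/visual/combined.
#' @return Reward rate in reward units per second.
#' @export
empirical_reward_rate <- function(trials, spec = reward_spec(),
                                  t_nd = c(vestibular = 0.3, visual = 0.3,
                                           combined = 0.3)) {
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  correct <- ifelse(trials$heading_deg == 0, 0.5,
                    (sign(trials$choice) == sign(trials$heading_deg)) * 1)
  dt <- pmax(trials$rt_s - unname(t_nd[trials$modality]), 0)
  (spec$reward_correct * mean(correct) - spec$cost_per_s * mean(dt)) /
    (mean(trials$rt_s) + spec$iti_s)
}

# --- reward-rate objective over bound coordinates ------------------------
#
# Precomputes the drift time courses (which do not depend on the bounds)
# so that evaluating the reward rate for new bounds only re-runs the
# first-passage solver, and exploits the cell structure: perturbing one
# bound coordinate only invalidates the cells it feeds, which makes
# finite-difference gradients and Hessians cost a couple of full
# evaluations instead of tens.

rr_objective <- function(params, design, spec = reward_spec(),
                         profile = NULL, nx = 100, bias = params$bias) {
  if (is.null(profile))
    profile <- make_stimulus_profile(design$duration_s, 0.005)
  cells <- design$cells
  hs <- design$headings_deg
  nh <- length(hs)
  w <- cells$weight
  tnd_cell <- unname(params$t_nd[cells$modality])
  mu_list <- lapply(seq_len(nrow(cells)), function(i)
    drift_matrix_cell(params, cells$modality[i], cells$coherence[i],
                      hs, profile))
  hsign <- sign(hs)
  bounds0 <- params$bounds
  coord_cells <- if (bounds0$variant == "free") {
    setNames(as.list(seq_len(nrow(cells))), cells$cell)
  } else {
    lapply(setNames(nm = c("vestibular", "visual", "combined")),
           function(m) which(cells$modality == m))
  }

  # per-cell stats (rows: p_correct, mean_dt, mean_rt) for cells `idx`
  # at scaled bounds th (one per entry of idx)
  stats_cells <- function(idx, th) {
    out <- matrix(0, 3, length(idx))
    tiny <- th < 1e-8
    out[1, tiny] <- 0.5
    out[3, tiny] <- tnd_cell[idx[tiny]]
    if (any(!tiny)) {
      ii <- idx[!tiny]
      mu <- do.call(cbind, mu_list[ii])
      res <- fpt_batch_cpp(mu, rep(th[!tiny], each = nh),
                           rep(bias, length(ii) * nh), profile$dt_s,
                           as.integer(nx), FALSE)
      up <- res$p_up + res$forced_up
      lo <- res$p_lo + res$forced_lo
      hsg <- rep(hsign, length(ii))
      pc <- ifelse(hsg > 0, up, ifelse(hsg < 0, lo, 0.5))
      out[1, !tiny] <- colMeans(matrix(pc, nrow = nh))
      out[2, !tiny] <- colMeans(matrix(res$mean_dt, nrow = nh))
      out[3, !tiny] <- out[2, !tiny] + tnd_cell[ii]
    }
    out
  }

  theta_cells_of <- function(coords) {
    if (is.null(names(coords)))
      names(coords) <- names(bound_coords(bounds0))
    b <- set_bound_coords(bounds0, coords)
    unname(theta_by_cell(b, design))
  }
  f_stats <- function(S) .rr_from_stats(S[1, ], S[2, ], S[3, ], w, spec)

  eval_full <- function(coords) {
    th <- theta_cells_of(coords)
    S <- stats_cells(seq_len(nrow(cells)), th)
    list(f = f_stats(S), stats = S, theta_cells = th)
  }

  # reward rate when only the cells tied to coordinate `j` change
  f_perturbed <- function(state, coords, j) {
    idx <- coord_cells[[j]]
    th <- theta_cells_of(coords)
    S <- state$stats
    S[, idx] <- stats_cells(idx, th[idx])
    f_stats(S)
  }

  # central-difference gradient wrt log-coordinates
  grad_log <- function(coords, state = eval_full(coords), step = 1e-3) {
    g <- numeric(length(coords))
    for (j in seq_along(coords)) {
      cp <- coords; cp[j] <- coords[j] * exp(step)
      cm <- coords; cm[j] <- coords[j] * exp(-step)
      g[j] <- (f_perturbed(state, cp, j) - f_perturbed(state, cm, j)) /
        (2 * step)
    }
    names(g) <- names(coords)
    g
  }

  # central-difference Hessian wrt the coordinates themselves (bound units)
  hessian <- function(coords, step = 1e-2, state = eval_full(coords)) {
    n <- length(coords)
    H <- matrix(NA_real_, n, n, dimnames = list(names(coords),
                                                names(coords)))
    f0 <- state$f
    fd1 <- function(j, h) {
      cp <- coords; cp[j] <- max(coords[j] + h, 0)
      f_perturbed(state, cp, j)
    }
    for (j in seq_len(n))
      H[j, j] <- (fd1(j, step) - 2 * f0 + fd1(j, -step)) / step^2
    if (n > 1) {
      fd2 <- function(j, k, hj, hk) {
        cp <- coords
        cp[j] <- max(coords[j] + hj, 0)
        cp[k] <- max(coords[k] + hk, 0)
        idx <- union(coord_cells[[j]], coord_cells[[k]])
        th <- theta_cells_of(cp)
        S <- state$stats
        S[, idx] <- stats_cells(idx, th[idx])
        f_stats(S)
      }
      for (j in 1:(n - 1)) for (k in (j + 1):n) {
        H[j, k] <- H[k, j] <-
          (fd2(j, k, step, step) - fd2(j, k, step, -step) -
             fd2(j, k, -step, step) + fd2(j, k, -step, -step)) /
          (4 * step^2)
      }
    }
    H
  }

  list(f = function(coords) eval_full(coords)$f,
       eval_full = eval_full, grad_log = grad_log, hessian = hessian,
       coord_names = names(bound_coords(bounds0)),
       profile = profile, nx = nx)
}

#' Reward rate of immediate random choices
#'
#' The model's reward rate with every bound forced to zero: decisions at
#' stimulus onset, accuracy 1/2, decision time 0.
#'
#' @inheritParams model_reward_rate
#' @return Reward rate in reward units per second.
#' @export
random_choice_rr <- function(params, design, spec = reward_spec()) {
  w <- design$cells$weight
  tnd <- unname(params$t_nd[design$cells$modality])
  (0.5 * spec$reward_correct * sum(w)) / (sum(w * tnd) + spec$iti_s)
}

#' Tune the decision bounds to maximize reward rate
#'
#' Gradient ascent on the model's reward rate over the bound
#' coordinates (quasi-Newton steps in log-bound space on a central
#' finite-difference gradient, box-constrained to keep bounds positive
#' and below the diffusion's reachable range), all other parameters
#' held at their fitted values; run from multiple random restarts
#' (log-uniform in `[theta/5, 5 theta]` around the current bounds, plus
#' the current bounds themselves) and the best endpoint returned.
#'
#' @param params fitted [subject_params()]; its bound variant
#'   (`free` or `parametric`) defines the optimization space.
#' @param design an [experiment_design()].
#' @param spec a [reward_spec()].
#' @param n_restarts number of starts (default 50).
#' @param seed RNG seed for the restart draws.
#' @param profile,nx solver settings for the objective (default 5 ms
#'   grid, 100 space intervals; the returned optimum is insensitive to
#'   moderate refinement).
#' @param max_iter ascent iteration cap per restart.
#' @param grad_tol convergence threshold on the log-space gradient norm.
#' @param step0 initial ascent step.
#' @return Object of class `optimization_result`: `theta_opt` (a
#'   [bound_vector()]), `rr_opt`, `rr_start` (reward rate at the fitted
#'   bounds), `restarts` tibble, `seed`.
#' @export
optimize_bounds <- function(params, design, spec = reward_spec(),
                            n_restarts = 50, seed = 1, profile = NULL,
                            nx = 100, max_iter = 500, grad_tol = 1e-6,
                            step0 = 0.2) {
  obj <- rr_objective(params, design, spec, profile, nx)
  coords0 <- bound_coords(params$bounds)
  coords0 <- pmax(coords0, 1e-3)   # log-space ascent needs positive start
  set.seed(seed)
  starts <- c(list(coords0),
              lapply(seq_len(max(n_restarts - 1, 0)), function(i)
                coords0 * exp(runif(length(coords0), log(1 / 5), log(5)))))
  recs <- vector("list", length(starts))
  best <- NULL
  for (r in seq_along(starts)) {
    res <- .ascend(obj, starts[[r]], max_iter, grad_tol, step0)
    recs[[r]] <- tibble::tibble(
      restart = r, rr_start = obj$f(starts[[r]]), rr_end = res$f,
      converged = res$converged, iters = res$iters)
    if (is.null(best) || res$f > best$f) best <- res
  }
  recs <- do.call(rbind, recs)
  if (!any(recs$converged))
    stop("no reward-rate ascent restart converged", call. = FALSE)
  structure(
    list(theta_opt = set_bound_coords(params$bounds, best$coords),
         rr_opt = best$f, rr_start = recs$rr_start[1],
         restarts = recs, seed = seed, variant = params$bounds$variant),
    class = "optimization_result"
  )
}

# one ascent run: quasi-Newton (L-BFGS-B) ascent in z = log(coords) with
# the cell-partial central-difference gradient, box-constrained to
# [1e-4, theta_max] (bounds beyond the diffusion's reachable range are
# behaviorally equivalent; the reward surface is flat there). The
# last-evaluated state is cached so the gradient call reuses the
# objective evaluation at the same point.
.ascend <- function(obj, coords, max_iter, grad_tol, step0,
                    theta_max = 10) {
  z0 <- pmin(pmax(log(pmax(coords, 1e-8)), log(1e-4)), log(theta_max))
  cache <- new.env(parent = emptyenv())
  fn <- function(z) {
    st <- obj$eval_full(exp(z))
    assign("z", z, envir = cache)
    assign("state", st, envir = cache)
    -st$f
  }
  gr <- function(z) {
    st <- if (!is.null(cache$z) && isTRUE(all.equal(z, cache$z)))
      cache$state else obj$eval_full(exp(z))
    -obj$grad_log(exp(z), st)
  }
  res <- try(optim(z0, fn, gr, method = "L-BFGS-B",
                   lower = log(1e-4), upper = log(theta_max),
                   control = list(maxit = max_iter, factr = 1e6,
                                  pgtol = grad_tol)),
             silent = TRUE)
  if (inherits(res, "try-error"))
    return(list(coords = setNames(coords, names(coords)), f = -Inf,
                converged = FALSE, iters = 0))
  list(coords = setNames(exp(res$par), names(coords)), f = -res$value,
       converged = res$convergence == 0,
       iters = res$counts[["function"]])
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>", x$variant, "bounds; rr_opt =",
      signif(x$rr_opt, 5), "(from", signif(x$rr_start, 5), "at start);",
      sum(x$restarts$converged), "of", nrow(x$restarts),
      "restarts converged\n")
  invisible(x)
}

#' Reward rate as a fraction of the optimum
#'
#' @param subject_rr the subject's reward rate (model or empirical).
#' @param opt an [optimize_bounds()] result.
#' @return `subject_rr / rr_opt`.
#' @export
relative_rr <- function(subject_rr, opt) {
  if (opt$rr_opt <= 0)
    stop("optimal reward rate must be positive", call. = FALSE)
  subject_rr / opt$rr_opt
}

#' Reward rate along a simultaneous linear scaling of all bounds
#'
#' Evaluates the reward rate along the ray `s * theta_opt` from the
#' origin (all bounds zero: immediate random choices) through the
#' optimal bounds (`s = 1`) and beyond.
#'
#' @param params fitted [subject_params()].
#' @param opt an [optimize_bounds()] result.
#' @param design,spec,profile,nx as in [optimize_bounds()].
#' @param s_grid scaling factors (nonnegative).
#' @return Tibble with `s` and `rr`.
#' @export
bound_scaling_curve <- function(params, opt, design,
                                spec = reward_spec(),
                                s_grid = seq(0, 2, by = 0.05),
                                profile = NULL, nx = 100) {
  if (any(s_grid < 0)) stop("s_grid must be nonnegative", call. = FALSE)
  obj <- rr_objective(params, design, spec, profile, nx)
  co <- bound_coords(opt$theta_opt)
  rr <- vapply(s_grid, function(s) obj$f(s * co), numeric(1))
  tibble::tibble(s = s_grid, rr = rr)
}

#' Project fitted bounds onto the optimal-bound line
#'
#' Finds where the subject's fitted bounds sit relative to the ray
#' through the optimal bounds. In `"contour"` mode (default) it follows
#' the iso-reward-rate contour: the returned `s` solves
#' `f(s * theta_opt) = f(theta_hat)`, on the below-optimum branch iff the
#' scalar projection of the fitted bounds onto the ray is below 1. In
#' `"vector"` mode it returns that plain scalar projection.
#'
#' @param theta_hat fitted [bound_vector()] (same variant as the
#'   optimum).
#' @param opt an [optimize_bounds()] result.
#' @param params fitted [subject_params()].
#' @param design,spec,profile,nx as in [optimize_bounds()].
#' @param mode `"contour"` or `"vector"`.
#' @param s_max search limit on the above-optimum branch.
#' @return The position `s` on the line (fraction of the optimal
#'   bounds).
#' @export
project_to_bound_line <- function(theta_hat, opt, params, design,
                                  spec = reward_spec(),
                                  mode = c("contour", "vector"),
                                  s_max = 3, profile = NULL, nx = 100) {
  mode <- match.arg(mode)
  th <- bound_coords(theta_hat)
  to <- bound_coords(opt$theta_opt)
  sp <- sum(th * to) / sum(to^2)
  if (mode == "vector") return(sp)
  obj <- rr_objective(params, design, spec, profile, nx)
  f_hat <- obj$f(th)
  if (f_hat > opt$rr_opt + 1e-8)
    stop("fitted bounds outperform the supplied optimum", call. = FALSE)
  g <- function(s) obj$f(s * to) - f_hat
  if (sp < 1) {
    lo <- 0; hi <- 1
  } else {
    lo <- 1; hi <- s_max
    if (g(hi) > 0)
      stop("no iso-reward intersection on the above-optimum branch ",
           "within s_max", call. = FALSE)
  }
  uniroot(g, c(lo, hi), tol = 1e-10, extendInt = "no")$root
}
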