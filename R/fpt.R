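#' First-passage-time solve for one condition
#'
#' Solves the Fokker-Planck equation of the scaled diffusion (unit
#' variance, time-varying drift `mu`, absorbing bounds at ±`theta`,
#' start point `bias * theta`) with a Crank-Nicolson scheme and returns
#' the defective first-passage densities at both bounds plus the
#' forced-choice masses: probability still unabsorbed at stimulus offset,
#' split by the sign of the surviving density (ties split evenly).
#'
#' `theta = 0` is the immediate-decision limit: all mass sits at t = 0,
#' split evenly between the two choices.
#'
#' @param mu drift samples (1/s) on the profile time grid.
#' @param theta scaled bound, nonnegative.
#' @param bias start-point offset as a fraction of the bound, in (-1, 1).
#' @param profile the [make_stimulus_profile()] whose grid `mu` lives on.
#' @param nx number of spatial grid intervals between the bounds
#'   (even; default 200, i.e. 201 grid points).
#' @return Object of class `rt_distribution`: `t_mid` (interval
#'   midpoints), `g_up`/`g_lo` (defective densities), `p_up`/`p_lo`
#'   (their integrals), `p0_up`/`p0_lo` (point masses at t = 0, nonzero
#'   only for `theta = 0`), `forced_up`/`forced_lo` (masses at
#'   `duration_s`), `mean_dt`, `duration_s`, `dt_s`.
#' @export
fpt_solve <- function(mu, theta, bias = 0, profile, nx = 200) {
  stopifnot(length(mu) == length(profile$t))
  if (theta < 0) stop("theta must be nonnegative", call. = FALSE)
  if (abs(bias) >= 1) stop("|bias| must be < 1", call. = FALSE)
  K <- length(mu) - 1
  if (theta < 1e-8) {
    d <- list(t_mid = (seq_len(K) - 0.5) * profile$dt_s,
              g_up = numeric(K), g_lo = numeric(K),
              p_up = 0, p_lo = 0, p0_up = 0.5, p0_lo = 0.5,
              forced_up = 0, forced_lo = 0, mean_dt = 0,
              duration_s = profile$duration_s, dt_s = profile$dt_s)
    return(structure(d, class = "rt_distribution"))
  }
  res <- fpt_batch_cpp(matrix(mu, ncol = 1), theta, bias, profile$dt_s,
                       as.integer(nx), TRUE)
  total <- res$p_up[1] + res$p_lo[1] + res$forced_up[1] + res$forced_lo[1]
  if (abs(total - 1) > 1e-3)
    stop(sprintf("first-passage solve lost probability mass (defect %.2e)",
                 abs(total - 1)), call. = FALSE)
  structure(
    list(t_mid = (seq_len(K) - 0.5) * profile$dt_s,
         g_up = res$g_up[, 1], g_lo = res$g_lo[, 1],
         p_up = res$p_up[1], p_lo = res$p_lo[1], p0_up = 0, p0_lo = 0,
         forced_up = res$forced_up[1], forced_lo = res$forced_lo[1],
         mean_dt = res$mean_dt[1],
         duration_s = profile$duration_s, dt_s = profile$dt_s),
    class = "rt_distribution"
  )
}

#' @export
print.rt_distribution <- function(x, ...) {
  cat("<rt_distribution> P(up) =", signif(total_up(x), 4),
      " P(lo) =", signif(total_lo(x), 4),
      " forced =", signif(x$forced_up + x$forced_lo, 4),
      " mean DT =", signif(x$mean_dt, 4), "s\n")
  invisible(x)
}

# total choice probabilities including forced and t=0 masses
total_up <- function(d) d$p_up + d$forced_up + d$p0_up
total_lo <- function(d) d$p_lo + d$forced_lo + d$p0_lo

#' Choice accuracy and mean timing implied by an RT distribution
#'
#' @param dist an [fpt_solve()] result.
#' @param t_nd non-decision time (s) of the condition's modality.
#' @param heading_sign +1 (rightward), -1 (leftward) or 0; the correct
#'   boundary is the one matching the heading sign, and heading 0 counts
#'   as accuracy 0.5 by convention.
#' @return Named numeric vector `(p_correct, mean_rt, mean_dt)`.
#' @export
condition_summary <- function(dist, t_nd, heading_sign) {
  p_correct <- if (heading_sign > 0) total_up(dist)
  else if (heading_sign < 0) total_lo(dist)
  else 0.5
  c(p_correct = unname(p_correct), mean_rt = dist$mean_dt + t_nd,
    mean_dt = dist$mean_dt)
}

# per-cell summaries (p_correct, mean_dt, mean_rt) marginalized over the
# design's headings with equal weight; the workhorse behind reward rates
# and predicted psychometrics. `theta` may override the params' bounds
# (named per-cell vector) so bound optimization can reuse drift matrices.
cell_summaries <- function(params, design, profile, nx = 200,
                           theta = NULL, bias = params$bias) {
  cells <- design$cells
  hs <- design$headings_deg
  if (is.null(theta)) theta <- theta_by_cell(params$bounds, design)
  mu_list <- lapply(seq_len(nrow(cells)), function(i)
    drift_matrix_cell(params, cells$modality[i], cells$coherence[i],
                      hs, profile))
  summarize_cells_from_mu(mu_list, cells, hs, theta, bias, params$t_nd,
                          profile, nx)
}

# shared implementation: mu_list[[i]] is the (time x heading) drift matrix
# of cell i. Returns a tibble in design cell order.
summarize_cells_from_mu <- function(mu_list, cells, hs, theta, bias, t_nd,
                                    profile, nx) {
  nh <- length(hs)
  nc <- nrow(cells)
  mu_all <- do.call(cbind, mu_list)
  th_all <- rep(theta[cells$cell], each = nh)
  tiny <- th_all < 1e-8
  p_cor <- mean_dt <- numeric(nc * nh)
  if (any(!tiny)) {
    res <- fpt_batch_cpp(mu_all[, !tiny, drop = FALSE], th_all[!tiny],
                         rep(bias, sum(!tiny)), profile$dt_s,
                         as.integer(nx), FALSE)
    up <- res$p_up + res$forced_up
    lo <- res$p_lo + res$forced_lo
    hsign <- sign(rep(hs, nc))[!tiny]
    p_cor[!tiny] <- ifelse(hsign > 0, up, ifelse(hsign < 0, lo, 0.5))
    mean_dt[!tiny] <- res$mean_dt
  }
  p_cor[tiny] <- 0.5
  mean_dt[tiny] <- 0
  pc <- colMeans(matrix(p_cor, nrow = nh))
  md <- colMeans(matrix(mean_dt, nrow = nh))
  tibble::tibble(
    cell = cells$cell, modality = cells$modality,
    coherence = cells$coherence, weight = cells$weight,
    p_correct = pc, mean_dt = md,
    mean_rt = md + unname(t_nd[cells$modality])
  )
}

#' Simulate trials from the model
#'
#' Monte-Carlo twin of [fpt_solve()]: Euler-Maruyama sample paths (with a
#' Brownian-bridge within-step crossing correction), forced choices at
#' stimulus offset, per-modality non-decision times with uniform ±`jitter`
#' response jitter, and lapse trials (fair coin, uniform RT over the
#' response window).
#'
#' @param params a [subject_params()].
#' @param design an [experiment_design()]; `n_per_cell` trials per cell
#'   are spread as evenly as possible over its headings.
#' @param n_per_cell trials per modality-by-coherence cell (defaults to
#'   the design's).
#' @param seed integer RNG seed; the output is reproducible given it.
#' @param profile stimulus profile (defaults to a 1 ms grid over the
#'   design duration).
#' @param jitter half-width (s) of the uniform non-decision jitter.
#' @return A tibble with columns `subject`, `modality`, `coherence`,
#'   `heading_deg`, `choice` (-1 left / +1 right), `rt_s`.
#' @export
simulate_trials <- function(params, design, n_per_cell = design$n_per_cell,
                            seed = 1, profile = NULL, jitter = 0.05) {
  if (n_per_cell < 1) stop("n_per_cell must be >= 1", call. = FALSE)
  if (is.null(profile))
    profile <- make_stimulus_profile(design$duration_s, 0.001)
  set.seed(seed)
  cells <- design$cells
  hs <- design$headings_deg
  nh <- length(hs)
  n_h <- rep(n_per_cell %/% nh, nh) +
    c(rep(1, n_per_cell %% nh), rep(0, nh - n_per_cell %% nh))
  theta <- theta_by_cell(params$bounds, design)
  out <- vector("list", nrow(cells) * nh)
  idx <- 0
  for (i in seq_len(nrow(cells))) {
    mu_m <- drift_matrix_cell(params, cells$modality[i], cells$coherence[i],
                              hs, profile)
    tnd <- unname(params$t_nd[cells$modality[i]])
    for (j in seq_len(nh)) {
      n <- n_h[j]
      if (n == 0) next
      idx <- idx + 1
      th <- unname(theta[cells$cell[i]])
      if (th < 1e-8) {
        choice <- sample(c(-1L, 1L), n, replace = TRUE)
        dt_dec <- rep(0, n)
      } else {
        sim <- sim_paths_cpp(mu_m[, j], profile$dt_s, th, params$bias, n)
        choice <- as.integer(sim$choice)
        dt_dec <- sim$dt_dec
      }
      rt <- dt_dec + tnd + runif(n, -jitter, jitter)
      if (params$lapse > 0) {
        lp <- runif(n) < params$lapse
        nl <- sum(lp)
        if (nl > 0) {
          choice[lp] <- sample(c(-1L, 1L), nl, replace = TRUE)
          rt[lp] <- tnd + runif(nl, 0, design$duration_s)
        }
      }
      out[[idx]] <- tibble::tibble(
        modality = cells$modality[i], coherence = cells$coherence[i],
        heading_deg = hs[j], choice = choice, rt_s = pmax(rt, 0)
      )
    }
  }
  tab <- do.call(rbind, out[seq_len(idx)])
  tab <- tab[sample.int(nrow(tab)), ]   # interleaved trial order
  tab <- tibble::add_column(tab, subject = "sim", .before = 1)
  tab
}
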