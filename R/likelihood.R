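# --- likelihood assembly -------------------------------------------------
#
# The RT likelihood of a trial is the defective first-passage density of
# the chosen boundary at decision time rt - t_nd(modality), convolved
# with the uniform ±jitter non-decision jitter. Because the jitter is
# uniform, the convolution is a difference of the decision-time CDF
# (which includes the forced-choice step at stimulus offset) across the
# jitter window. Lapse trials mix in a fair coin with uniform RT density
# over the response window.

# decision-time CDF knots for one boundary of an rt_distribution;
# returns list(x, y) usable with approx(); right limit includes the
# forced mass as a (numerically steep) step at t = duration.
.cdf_knots <- function(dist, boundary = c("up", "lo")) {
  boundary <- match.arg(boundary)
  g <- if (boundary == "up") dist$g_up else dist$g_lo
  p0 <- if (boundary == "up") dist$p0_up else dist$p0_lo
  forced <- if (boundary == "up") dist$forced_up else dist$forced_lo
  Tdur <- dist$duration_s
  tk <- c(0, dist$t_mid + dist$dt_s / 2)
  Fk <- p0 + c(0, cumsum(g * dist$dt_s))
  x <- c(-1e-9, tk, Tdur + 1e-9, Tdur + 10)
  y <- c(0, Fk, Fk[length(Fk)] + forced, Fk[length(Fk)] + forced)
  list(x = x, y = y)
}

# vectorized jittered density at decision-time offsets u for one boundary
.jittered_density <- function(knots, u, jitter) {
  Fb <- stats::approx(knots$x, knots$y, pmin(u + jitter, knots$x[length(knots$x)]),
                      rule = 2)$y
  Fa <- stats::approx(knots$x, knots$y, pmax(u - jitter, knots$x[1]),
                      rule = 2)$y
  (Fb - Fa) / (2 * jitter)
}

#' Log-likelihood of one trial
#'
#' @param params a [subject_params()].
#' @param trial one-row data frame with `modality`, `coherence`,
#'   `heading_deg`, `choice`, `rt_s`.
#' @param profile stimulus profile.
#' @param design design the trial belongs to (for bound lookup).
#' @param jitter non-decision jitter half-width (s).
#' @param nx solver space intervals.
#' @return Log density; `-Inf` when the trial is impossible under the
#'   parameters (reaction time outside the response window with no lapse).
#' @export
trial_loglik <- function(params, trial, profile,
                         design = experiment_design(), jitter = 0.05,
                         nx = 200) {
  ll <- loglik_table(params, trial, design, profile, jitter, nx,
                     floor = 0)
  ll
}

# static trial-grouping structure shared by every likelihood evaluation:
# one group per (design cell x heading) with the member trials' reaction
# times and choices
.build_lik_data <- function(trials, design) {
  stopifnot(all(trials$rt_s > 0))
  cells <- design$cells
  cellv <- cell_id(trials$modality, trials$coherence)
  bad <- !(cellv %in% cells$cell)
  if (any(bad))
    stop("trial conditions not in the design: ",
         paste(unique(cellv[bad]), collapse = ", "), call. = FALSE)
  key <- paste(cellv, trials$heading_deg)
  groups <- split(seq_len(nrow(trials)), key)
  g <- lapply(groups, function(ix) {
    list(cell_row = match(cellv[ix[1]], cells$cell),
         modality = trials$modality[ix[1]],
         heading = trials$heading_deg[ix[1]],
         rt = trials$rt_s[ix], up = trials$choice[ix] > 0)
  })
  list(groups = g, n = nrow(trials), cells = cells)
}

# fast path: all first-passage solves in one batch call
.loglik_fast <- function(params, ld, design, profile, jitter, nx,
                         floor = 0) {
  theta <- unname(theta_by_cell(params$bounds, design))
  cells <- ld$cells
  Tdur <- profile$duration_s
  ng <- length(ld$groups)
  mu <- vapply(ld$groups, function(g)
    drift_timecourse(params, g$modality,
                     if (g$modality == "vestibular") NA
                     else cells$coherence[g$cell_row],
                     g$heading, profile),
    numeric(length(profile$t)))
  th_g <- theta[vapply(ld$groups, `[[`, integer(1), "cell_row")]
  tiny <- th_g < 1e-8
  K <- length(profile$t) - 1
  res <- NULL
  if (any(!tiny))
    res <- fpt_batch_cpp(mu[, !tiny, drop = FALSE], th_g[!tiny],
                         rep(params$bias, sum(!tiny)), profile$dt_s,
                         as.integer(nx), TRUE)
  col_of <- cumsum(!tiny)
  ll <- 0
  tk <- c(0, (seq_len(K) - 0.5) * profile$dt_s + profile$dt_s / 2)
  for (gi in seq_len(ng)) {
    g <- ld$groups[[gi]]
    tnd <- unname(params$t_nd[g$modality])
    u <- g$rt - tnd
    dens <- numeric(length(u))
    if (tiny[gi]) {
      d0 <- list(t_mid = (seq_len(K) - 0.5) * profile$dt_s,
                 g_up = numeric(K), g_lo = numeric(K), p0_up = 0.5,
                 p0_lo = 0.5, forced_up = 0, forced_lo = 0,
                 duration_s = Tdur, dt_s = profile$dt_s)
      if (any(g$up))
        dens[g$up] <- .jittered_density(.cdf_knots(d0, "up"), u[g$up],
                                        jitter)
      if (any(!g$up))
        dens[!g$up] <- .jittered_density(.cdf_knots(d0, "lo"), u[!g$up],
                                         jitter)
    } else {
      j <- col_of[gi]
      d <- list(t_mid = (seq_len(K) - 0.5) * profile$dt_s,
                g_up = res$g_up[, j], g_lo = res$g_lo[, j],
                p0_up = 0, p0_lo = 0,
                forced_up = res$forced_up[j], forced_lo = res$forced_lo[j],
                duration_s = Tdur, dt_s = profile$dt_s)
      if (any(g$up))
        dens[g$up] <- .jittered_density(.cdf_knots(d, "up"), u[g$up],
                                        jitter)
      if (any(!g$up))
        dens[!g$up] <- .jittered_density(.cdf_knots(d, "lo"), u[!g$up],
                                         jitter)
    }
    if (params$lapse > 0) {
      lap <- ifelse(u >= 0 & u <= Tdur, 0.5 / Tdur, 0)
      dens <- (1 - params$lapse) * dens + params$lapse * lap
    }
    ll <- ll + sum(log(pmax(dens, floor)))
  }
  ll
}

# total log-likelihood of a trial table; floor > 0 replaces zero
# densities with `floor` (used for optimization smoothness)
loglik_table <- function(params, trials, design, profile, jitter = 0.05,
                         nx = 200, floor = 0) {
  ld <- .build_lik_data(trials, design)
  .loglik_fast(params, ld, design, profile, jitter, nx, floor)
}

# --- parameter packing ---------------------------------------------------

.pack <- function(params, design) {
  b <- params$bounds
  if (b$variant == "free") {
    th <- log(pmax(theta_by_cell(b, design), 1e-6))
    extra <- NULL
  } else {
    th <- log(pmax(b$theta_modality, 1e-6))
    extra <- qlogis(min(max(b$slope, 0.02), 0.9))
  }
  c(log(max(params$k_vest, 1e-6)), log(pmax(params$k_vis, 1e-6)),
    th, extra, log(pmax(params$t_nd, 1e-3)), atanh(params$bias))
}

.unpack <- function(par, design, variant, lapse = 0) {
  ex <- function(x) pmin(exp(x), 1e4)   # keep the optimizer on the map
  coh <- design$coherences
  C <- length(coh)
  i <- 1
  k_vest <- ex(par[i]); i <- i + 1
  k_vis <- setNames(ex(par[i:(i + C - 1)]), coh_key(coh))
  i <- i + C
  if (variant == "free") {
    nth <- nrow(design$cells)
    th <- setNames(ex(par[i:(i + nth - 1)]), design$cells$cell)
    i <- i + nth
    bounds <- bound_vector(theta = th)
  } else {
    thm <- setNames(ex(par[i:(i + 2)]),
                    c("vestibular", "visual", "combined"))
    i <- i + 3
    slope <- plogis(par[i]); i <- i + 1
    bounds <- bound_vector(variant = "parametric", theta_modality = thm,
                           slope = min(slope, 0.95))
  }
  t_nd <- setNames(ex(par[i:(i + 2)]),
                   c("vestibular", "visual", "combined"))
  i <- i + 3
  bias <- max(min(tanh(par[i]), 0.999), -0.999)
  subject_params(k_vest, k_vis, bounds, t_nd, bias, lapse)
}

# method-of-moments starting point: non-decision time from the fastest
# responses, bound and sensitivity per cell from accuracy and mean RT at
# the largest heading via the constant-drift closed forms
.init_params <- function(trials, design, profile, variant, jitter) {
  mods <- c("vestibular", "visual", "combined")
  tnd <- vapply(mods, function(m) {
    rt <- trials$rt_s[trials$modality == m]
    max(0.05, min(rt) - 0.1)
  }, numeric(1))
  hmax <- max(abs(trials$heading_deg))
  shx <- sin(hmax * pi / 180)
  vbar <- mean(profile$v)                       # effective profile scale
  cells <- design$cells
  th <- k <- setNames(numeric(nrow(cells)), cells$cell)
  cellv <- cell_id(trials$modality, trials$coherence)
  for (i in seq_len(nrow(cells))) {
    sel <- cellv == cells$cell[i] & abs(trials$heading_deg) == hmax
    if (!any(sel)) sel <- cellv == cells$cell[i]  # sparse cell fallback
    p <- mean(sign(trials$choice[sel]) == sign(trials$heading_deg[sel]))
    p <- min(max(p, 0.55), 0.95)
    edt <- max(mean(trials$rt_s[sel]) - tnd[cells$modality[i]], 0.05)
    L <- log(p / (1 - p))
    th[i] <- sqrt(edt * (L / 2) / tanh(L / 2))
    k[i] <- L / (2 * th[i]) / (shx * vbar)
  }
  coh <- design$coherences
  k_vis <- setNames(pmax(k[cells$modality == "visual"], 0.5),
                    coh_key(coh))
  k_vest <- max(k[cells$cell == "vestibular"], 0.5)
  if (variant == "free") {
    bounds <- bound_vector(theta = pmax(th, 0.05))
  } else {
    thm <- vapply(mods, function(m) mean(th[cells$modality == m]),
                  numeric(1))
    bounds <- bound_vector(variant = "parametric",
                           theta_modality = pmax(thm, 0.05), slope = 0.1)
  }
  subject_params(k_vest, k_vis, bounds, tnd, bias = 0)
}

#' Fit the diffusion model to one subject's trials
#'
#' Maximum-likelihood estimation of all subject parameters
#' (sensitivities, scaled bounds, per-modality non-decision times, start
#' bias) by multi-start quasi-Newton optimization on transformed
#' parameters (log for positive quantities, atanh for the bias). The
#' first start is a method-of-moments point; further restarts perturb it.
#'
#' @param trials trial table (see [simulate_trials()] for the schema).
#' @param design the [experiment_design()].
#' @param variant `"free"` (per-modality-per-coherence bounds) or
#'   `"parametric"` (per-modality bounds with a coherence-to-sigma map).
#' @param settings list overriding any of: `n_restarts` (10), `maxit`
#'   (150), `solver_dt` (0.005 s), `nx` (100), `jitter` (0.05 s),
#'   `lapse` (0, held fixed), `seed` (1), `perturb_sd` (0.25).
#' @return Object of class `fit_result`: `params`, `loglik`, `n_trials`,
#'   `restarts` tibble, `settings`.
#' @export
fit_subject <- function(trials, design = experiment_design(),
                        variant = c("free", "parametric"),
                        settings = list()) {
  variant <- match.arg(variant)
  for (m in unique(design$cells$modality))
    if (!any(trials$modality == m))
      stop("no trials for modality ", m, call. = FALSE)
  s <- modifyList(list(n_restarts = 10, maxit = 150, solver_dt = 0.005,
                       nx = 100, jitter = 0.05, lapse = 0, seed = 1,
                       perturb_sd = 0.25), settings)
  profile <- make_stimulus_profile(design$duration_s, s$solver_dt)
  init <- .init_params(trials, design, profile, variant, s$jitter)
  par0 <- .pack(init, design)
  ld <- .build_lik_data(trials, design)
  nll <- function(par) {
    v <- try({
      p <- .unpack(par, design, variant, s$lapse)
      -.loglik_fast(p, ld, design, profile, s$jitter, s$nx,
                    floor = 1e-12)
    }, silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  set.seed(s$seed)
  best <- NULL
  recs <- vector("list", s$n_restarts)
  for (r in seq_len(s$n_restarts)) {
    start <- if (r == 1) par0 else par0 + rnorm(length(par0), 0, s$perturb_sd)
    fit <- try(optim(start, nll, method = "BFGS",
                     control = list(maxit = s$maxit, reltol = 1e-8)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      recs[[r]] <- tibble::tibble(restart = r, loglik = NA_real_,
                                  converged = FALSE)
      next
    }
    recs[[r]] <- tibble::tibble(restart = r, loglik = -fit$value,
                                converged = fit$convergence == 0)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all restarts failed; check the trial table and settings",
         call. = FALSE)
  structure(
    list(params = .unpack(best$par, design, variant, s$lapse),
         loglik = -best$value, n_trials = nrow(trials),
         restarts = do.call(rbind, recs), settings = s,
         variant = variant),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$variant, "variant, loglik", signif(x$loglik, 6),
      "on", x$n_trials, "trials;",
      sum(x$restarts$converged, na.rm = TRUE), "of",
      nrow(x$restarts), "restarts converged\n")
  print(x$params)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit a [fit_subject()] result.
#' @param path file to write.
#' @export
write_fit_result <- function(fit, path) {
  b <- fit$params$bounds
  jsonlite::write_json(
    list(variant = fit$variant, loglik = fit$loglik,
         n_trials = fit$n_trials,
         k_vest = fit$params$k_vest, k_vis = as.list(fit$params$k_vis),
         bounds = if (b$variant == "free") as.list(b$theta)
                  else list(theta_modality = as.list(b$theta_modality),
                            sigma0 = b$sigma0, slope = b$slope),
         t_nd = as.list(fit$params$t_nd), bias = fit$params$bias,
         lapse = fit$params$lapse, settings = fit$settings),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Model-predicted psychometric/chronometric table
#'
#' Per design cell: probability correct and mean reaction time,
#' marginalized over the design's headings.
#'
#' @param params a [subject_params()].
#' @param design an [experiment_design()].
#' @param profile optional stimulus profile (default 1 ms grid).
#' @param nx solver space intervals.
#' @return Tibble with `cell`, `modality`, `coherence`, `p_correct`,
#'   `mean_rt`, `mean_dt`.
#' @export
predicted_psychometric <- function(params, design, profile = NULL,
                                   nx = 200) {
  if (is.null(profile))
    profile <- make_stimulus_profile(design$duration_s, 0.001)
  cs <- cell_summaries(params, design, profile, nx)
  cs[, c("cell", "modality", "coherence", "p_correct", "mean_rt",
         "mean_dt")]
}
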