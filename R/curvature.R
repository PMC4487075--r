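# --- curvature diagnostics of incomplete gradient learning ---------------

#' Finite-difference Hessian of a scalar function
#'
#' Central-difference Hessian built by differencing central-difference
#' gradients; the raw estimate is not exactly symmetric, which gives a
#' useful numerical diagnostic before symmetrization.
#'
#' @param f scalar function of a numeric vector.
#' @param x evaluation point.
#' @param step finite-difference step (same units as `x`).
#' @return The raw (possibly asymmetric) Hessian matrix.
#' @export
fd_hessian <- function(f, x, step = 1e-2) {
  n <- length(x)
  grad <- function(y) {
    vapply(seq_len(n), function(j) {
      yp <- y; yp[j] <- y[j] + step
      ym <- y; ym[j] <- y[j] - step
      (f(yp) - f(ym)) / (2 * step)
    }, numeric(1))
  }
  H <- matrix(NA_real_, n, n)
  for (k in seq_len(n)) {
    xp <- x; xp[k] <- x[k] + step
    xm <- x; xm[k] <- x[k] - step
    H[, k] <- (grad(xp) - grad(xm)) / (2 * step)
  }
  dimnames(H) <- list(names(x), names(x))
  H
}

# package a raw Hessian into a curvature report
.curvature_report <- function(H_raw, fd_step, richardson_rel = NA_real_) {
  if (any(!is.finite(H_raw))) {
    bad <- which(!is.finite(H_raw), arr.ind = TRUE)
    stop("non-finite Hessian entries at coordinates (",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "),
         ")", call. = FALSE)
  }
  sym_defect <- max(abs(H_raw - t(H_raw)))
  H <- (H_raw + t(H_raw)) / 2
  ei <- eigen(H, symmetric = TRUE)
  ord <- order(abs(ei$values), decreasing = TRUE)
  flagged <- is.finite(richardson_rel) && richardson_rel > 0.10
  structure(
    list(H = H, H_raw = H_raw, eigenvalues = ei$values[ord],
         V = ei$vectors[, ord, drop = FALSE],
         coord_names = colnames(H_raw), fd_step = fd_step,
         sym_defect = sym_defect, richardson_rel = richardson_rel,
         step_flagged = flagged),
    class = "curvature_report"
  )
}

#' Hessian of the reward rate at fitted bounds
#'
#' Curvature of the reward-rate surface with respect to the (free,
#' per-modality-per-coherence) bound coordinates, estimated by central
#' finite differences at the fitted bounds, symmetrized, and
#' eigen-decomposed. A Richardson check re-estimates at half the step;
#' a relative mismatch above 10% flags the report.
#'
#' @param params fitted [subject_params()] whose bounds (or `theta_hat`)
#'   give the evaluation point; free variant required.
#' @param design,spec,profile,nx as in [model_reward_rate()].
#' @param theta_hat optional [bound_vector()] overriding the params'.
#' @param fd_step finite-difference step in bound units (default 1e-2).
#' @param richardson logical: run the half-step consistency check.
#' @return Object of class `curvature_report`: `H` (symmetrized),
#'   `H_raw`, signed `eigenvalues` (sorted by magnitude), eigenvector
#'   matrix `V` (the absolute overlap with the original bound axes is
#'   `abs(V)`), `sym_defect`, `richardson_rel`, `step_flagged`.
#' @export
reward_rate_hessian <- function(params, design, spec = reward_spec(),
                                theta_hat = NULL, fd_step = 1e-2,
                                richardson = TRUE, profile = NULL,
                                nx = 100) {
  if (!is.null(theta_hat)) params$bounds <- theta_hat
  if (params$bounds$variant != "free")
    stop("curvature analysis uses the free (per-cell) bound variant",
         call. = FALSE)
  obj <- rr_objective(params, design, spec, profile, nx)
  coords <- bound_coords(params$bounds)
  H1 <- obj$hessian(coords, step = fd_step)
  rich <- NA_real_
  if (richardson) {
    H2 <- obj$hessian(coords, step = fd_step / 2)
    rich <- max(abs(H1 - H2)) / max(abs(H2))
    if (rich > 0.10)
      warning("Hessian finite-difference step check mismatch ",
              signif(100 * rich, 3), "% — consider a different fd_step",
              call. = FALSE)
  }
  .curvature_report(H1, fd_step, rich)
}

#' @export
print.curvature_report <- function(x, ...) {
  cat("<curvature_report>", length(x$eigenvalues), "dimensions; |lambda|",
      "range", signif(min(abs(x$eigenvalues)), 3), "-",
      signif(max(abs(x$eigenvalues)), 3),
      if (isTRUE(x$step_flagged)) " [fd step flagged]" else "", "\n")
  invisible(x)
}

#' Curvature-versus-distance pairs in the Hessian eigenspace
#'
#' Projects the bound mis-tuning `theta_opt - theta_hat` into the
#' eigenspace of the reward-rate Hessian and pairs each eigendimension's
#' absolute curvature `|lambda_i|` with its absolute projected distance
#' `|delta'_i|`. Under incomplete gradient learning, steeper dimensions
#' should be closer to optimal (a negative association).
#'
#' @param report a [reward_rate_hessian()] result.
#' @param theta_hat,theta_opt fitted and optimal bounds
#'   ([bound_vector()] or named numeric in the report's coordinate
#'   order).
#' @return Tibble sorted by `abs_curvature` (descending) with columns
#'   `dimension`, `lambda`, `abs_curvature`, `abs_distance`,
#'   `dominant_coord` (bound coordinate with the largest eigenvector
#'   loading), `degenerate` (`|lambda| < 1e-8`: distance relation not
#'   testable).
#' @export
curvature_distance_analysis <- function(report, theta_hat, theta_opt) {
  th <- if (inherits(theta_hat, "bound_vector")) bound_coords(theta_hat)
        else theta_hat
  to <- if (inherits(theta_opt, "bound_vector")) bound_coords(theta_opt)
        else theta_opt
  if (length(th) != length(report$eigenvalues) ||
      length(to) != length(report$eigenvalues))
    stop("bound vectors do not match the Hessian dimension",
         call. = FALSE)
  if (!is.null(report$coord_names)) {
    th <- th[report$coord_names]
    to <- to[report$coord_names]
  }
  delta <- unname(to - th)
  dprime <- drop(t(report$V) %*% delta)
  dom <- apply(abs(report$V), 2, which.max)
  tibble::tibble(
    dimension = seq_along(dprime),
    lambda = report$eigenvalues,
    abs_curvature = abs(report$eigenvalues),
    abs_distance = abs(dprime),
    dominant_coord = if (is.null(report$coord_names))
      as.character(dom) else report$coord_names[dom],
    degenerate = abs(report$eigenvalues) < 1e-8
  )
}

#' Quadratic approximation check of the reward-rate loss
#'
#' Compares the model's reward-rate loss `rr_opt - rr_hat` with the loss
#' predicted by the quadratic (Hessian) approximation
#' `0.5 |delta' H delta|` at the fitted bounds. Agreement validates the
#' curvature-based analysis.
#'
#' @param report a [reward_rate_hessian()] result.
#' @param theta_hat,theta_opt fitted and optimal bounds.
#' @param rr_hat,rr_opt reward rate at the fitted and optimal bounds.
#' @return Named numeric `(model_loss, quadratic_loss)`.
#' @export
quadratic_loss_check <- function(report, theta_hat, theta_opt, rr_hat,
                                 rr_opt) {
  if (rr_opt < rr_hat - 1e-12)
    stop("rr_opt must be at least rr_hat", call. = FALSE)
  th <- if (inherits(theta_hat, "bound_vector")) bound_coords(theta_hat)
        else theta_hat
  to <- if (inherits(theta_opt, "bound_vector")) bound_coords(theta_opt)
        else theta_opt
  if (!is.null(report$coord_names)) {
    th <- th[report$coord_names]
    to <- to[report$coord_names]
  }
  delta <- unname(to - th)
  c(model_loss = rr_opt - rr_hat,
    quadratic_loss = 0.5 * abs(drop(t(delta) %*% report$H %*% delta)))
}

#' Serialize a curvature report (and optional distance pairs) to JSON
#'
#' @param report a [reward_rate_hessian()] result.
#' @param path file to write.
#' @param pairs optional [curvature_distance_analysis()] tibble to embed.
#' @export
write_curvature_report <- function(report, path, pairs = NULL) {
  jsonlite::write_json(
    list(H = report$H, eigenvalues = report$eigenvalues,
         eigenvectors = report$V, coord_names = report$coord_names,
         fd_step = report$fd_step, sym_defect = report$sym_defect,
         richardson_rel = report$richardson_rel,
         step_flagged = report$step_flagged, pairs = pairs),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Learning-rule configuration
#'
#' @param alpha gradient-ascent step size (deterministic mode) or
#'   proposal standard deviation (stochastic mode).
#' @param n_steps number of update steps.
#' @param mode `"deterministic"` (full finite-difference gradient step
#'   `theta <- theta + alpha * grad f`) or `"stochastic"`
#'   (single-coordinate proposal accepted iff
#'   `f(new) > f(old) + eps`, `eps ~ N(0, eps_sd)`).
#' @param eps_sd standard deviation of the zero-mean acceptance noise.
#' @param seed RNG seed (stochastic mode).
#' @param fd_step step for the finite-difference gradient when the
#'   surface is a plain function.
#' @export
learning_config <- function(alpha, n_steps, mode = c("deterministic",
                                                     "stochastic"),
                            eps_sd = 0, seed = 1, fd_step = 1e-4) {
  mode <- match.arg(mode)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  if (eps_sd < 0) stop("eps_sd must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, n_steps = n_steps, mode = mode,
                 eps_sd = eps_sd, seed = seed, fd_step = fd_step),
            class = "learning_config")
}

#' Simulate gradient-based bound learning
#'
#' Runs the bound-update rule `theta_n = theta_{n-1} + alpha grad
#' f(theta_{n-1})` (deterministic mode) or the stochastic
#' single-coordinate acceptance rule (see [learning_config()]) on an
#' objective surface.
#'
#' @param surface either a plain function of the bound vector, or an
#'   objective object with fields `f` and `grad_log` (as built
#'   internally for reward-rate surfaces, whose cell structure makes the
#'   gradient cheap).
#' @param theta0 starting bound vector.
#' @param config a [learning_config()].
#' @return Object of class `learning_trajectory`: `theta` (matrix,
#'   one row per step including the start), `f` (objective values),
#'   `config`.
#' @export
simulate_learning <- function(surface, theta0, config) {
  if (is.list(surface) && !is.null(surface$grad_log)) {
    f <- surface$f
    grad <- function(x) surface$grad_log(x) / x   # d/dtheta from d/dlog
  } else {
    f <- surface
    grad <- function(x) vapply(seq_along(x), function(j) {
      xp <- x; xp[j] <- x[j] + config$fd_step
      xm <- x; xm[j] <- x[j] - config$fd_step
      (f(xp) - f(xm)) / (2 * config$fd_step)
    }, numeric(1))
  }
  d <- length(theta0)
  th <- matrix(NA_real_, config$n_steps + 1, d)
  colnames(th) <- names(theta0)
  fv <- numeric(config$n_steps + 1)
  th[1, ] <- theta0
  fv[1] <- f(theta0)
  lim <- 1e3 * max(sqrt(sum(theta0^2)), 1)
  set.seed(config$seed)
  x <- theta0
  for (n in seq_len(config$n_steps)) {
    if (config$mode == "deterministic") {
      x <- x + config$alpha * grad(x)
      fx <- f(x)
    } else {
      j <- sample.int(d, 1)
      prop <- x
      prop[j] <- prop[j] + rnorm(1, 0, config$alpha)
      eps <- if (config$eps_sd > 0) rnorm(1, 0, config$eps_sd) else 0
      fp <- f(prop)
      if (fp > fv[n] + eps) { x <- prop; fx <- fp } else fx <- fv[n]
    }
    if (sqrt(sum(x^2)) > lim)
      stop("learning trajectory diverged; use a smaller alpha",
           call. = FALSE)
    th[n + 1, ] <- x
    fv[n + 1] <- fx
  }
  structure(list(theta = th, f = fv, config = config),
            class = "learning_trajectory")
}

#' @export
print.learning_trajectory <- function(x, ...) {
  n <- nrow(x$theta) - 1
  cat("<learning_trajectory>", n, "steps (", x$config$mode, "); f:",
      signif(x$f[1], 5), "->", signif(x$f[n + 1], 5), "\n")
  invisible(x)
}
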