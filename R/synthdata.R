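# --- synthetic subjects and cohorts --------------------------------------

#' Generate one synthetic subject's trial table
#'
#' Simulation front-end around [simulate_trials()] that also returns a
#' truth record sufficient to regenerate the table bit-exactly.
#'
#' @param truth generating [subject_params()].
#' @param design an [experiment_design()].
#' @param seed integer seed.
#' @param subject_id label stored in the table.
#' @return List with `trials` (tibble) and `truth` (list with `params`,
#'   `design`, `seed`).
#' @export
generate_subject <- function(truth, design = experiment_design(),
                             seed = 1, subject_id = "S1") {
  trials <- simulate_trials(truth, design, design$n_per_cell, seed)
  trials$subject <- subject_id
  list(trials = trials,
       truth = list(params = truth, design = design, seed = seed,
                    subject_id = subject_id))
}

#' Build a truncated-learner subject
#'
#' Constructs a subject whose bounds are the endpoint of a prematurely
#' stopped gradient ascent on the reward-rate surface, started below the
#' optimum (default at `start_frac` times the optimal bounds). Such a
#' subject embodies incomplete gradient learning: near-optimal bounds
#' along steep (high-curvature) directions, larger deviations along
#' shallow ones, and an overall reward rate below — but close to — the
#' optimum.
#'
#' If no [learning_config()] is given, a deterministic rule is used with
#' the step size set to `0.5 / max |lambda|` of the reward-rate Hessian
#' at the optimum (stable for the steepest eigendirection, slower along
#' shallow ones) and 5 steps — a truncation that leaves
#' curvature-ordered residual mistuning. The default start is at 0.6
#' times the optimal bounds: with a bell-shaped stimulus, evidence is
#' absent at stimulus onset, so very low bounds amount to immediate
#' guessing and the reward surface has a guessing basin below roughly
#' half the optimal bounds; the start must sit above that separatrix
#' for gradient learning to flow toward the optimum. Two presets are
#' available when no explicit config is given: `"quadratic"` (the
#' default: endpoint inside the locally quadratic neighbourhood of the
#' optimum, where the curvature diagnostic is valid) and `"deep"`
#' (`alpha = 0.3/max|lambda|`, 2 steps: bounds well below the optimum,
#' as in the bound-line analyses).
#'
#' @param base base [subject_params()] (all non-bound parameters are
#'   kept).
#' @param design an [experiment_design()].
#' @param spec a [reward_spec()].
#' @param config optional [learning_config()] overriding the presets.
#' @param truncation preset used when `config` is `NULL`: `"quadratic"`
#'   or `"deep"`.
#' @param opt optional precomputed [optimize_bounds()] result for
#'   `base` (computed with `n_restarts` restarts otherwise).
#' @param start_frac starting bounds as a fraction of the optimal ones.
#' @param n_restarts restarts for the internal bound optimization.
#' @param seed seed for the internal optimization and learning rule.
#' @param profile,nx solver settings.
#' @return List with `params` (the learner), `opt`, `trajectory`,
#'   `config`.
#' @export
make_truncated_learner <- function(base, design = experiment_design(),
                                   spec = reward_spec(), config = NULL,
                                   truncation = c("quadratic", "deep"),
                                   opt = NULL, start_frac = 0.6,
                                   n_restarts = 5, seed = 1,
                                   profile = NULL, nx = 100) {
  truncation <- match.arg(truncation)
  if (is.null(opt))
    opt <- optimize_bounds(base, design, spec, n_restarts = n_restarts,
                           seed = seed, profile = profile, nx = nx)
  obj <- rr_objective(base, design, spec, profile, nx)
  theta_star <- bound_coords(opt$theta_opt)
  if (is.null(config)) {
    H <- obj$hessian(theta_star)
    lam_max <- max(abs(eigen((H + t(H)) / 2, symmetric = TRUE,
                             only.values = TRUE)$values))
    config <- if (truncation == "quadratic")
      learning_config(alpha = 0.5 / lam_max, n_steps = 5,
                      mode = "deterministic", seed = seed)
    else
      learning_config(alpha = 0.3 / lam_max, n_steps = 2,
                      mode = "deterministic", seed = seed)
  }
  traj <- simulate_learning(obj, start_frac * theta_star, config)
  endpoint <- traj$theta[nrow(traj$theta), ]
  learner <- base
  learner$bounds <- set_bound_coords(base$bounds, pmax(endpoint, 0))
  list(params = learner, opt = opt, trajectory = traj, config = config)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject truths are drawn by perturbing a template subject
#' (log-normal jitter with standard deviation `base_variability` on the
#' sensitivities and bounds, small additive jitter on non-decision times
#' and bias); optionally each subject's bounds are then replaced by a
#' truncated-learner endpoint.
#'
#' @param n_subjects cohort size.
#' @param base_variability log-normal standard deviation of the
#'   between-subject parameter jitter.
#' @param seed cohort seed; subject `i` uses `seed * 1000 + i` for its
#'   trials.
#' @param template template [subject_params()].
#' @param design an [experiment_design()].
#' @param truncated logical: make each subject a truncated learner.
#' @param spec reward spec used for the learners.
#' @param ... passed to [make_truncated_learner()].
#' @return List of [generate_subject()] results; for truncated cohorts
#'   each element also carries `learner` (the
#'   [make_truncated_learner()] record).
#' @export
generate_cohort <- function(n_subjects, base_variability = 0.15, seed = 1,
                            template = NULL,
                            design = experiment_design(),
                            truncated = FALSE, spec = reward_spec(),
                            ...) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (is.null(template)) template <- default_subject_params(design)
  set.seed(seed)
  cohort <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- template
    p$k_vest <- p$k_vest * exp(rnorm(1, 0, base_variability))
    p$k_vis <- p$k_vis * exp(rnorm(length(p$k_vis), 0, base_variability))
    co <- bound_coords(p$bounds)
    p$bounds <- set_bound_coords(
      p$bounds, co * exp(rnorm(length(co), 0, base_variability)))
    p$t_nd <- pmax(p$t_nd + rnorm(3, 0, 0.02), 0.1)
    p$bias <- max(min(p$bias + rnorm(1, 0, 0.02), 0.5), -0.5)
    learner <- NULL
    if (truncated) {
      learner <- make_truncated_learner(p, design, spec,
                                        seed = seed * 100 + i, ...)
      p <- learner$params
    }
    cohort[[i]] <- generate_subject(p, design, seed = seed * 1000 + i,
                                    subject_id = sprintf("S%02d", i))
    cohort[[i]]$learner <- learner
  }
  cohort
}

#' Write / read a trial table CSV
#'
#' Schema: columns `subject`, `modality`
#' (`vestibular|visual|combined`), `coherence` (empty for vestibular),
#' `heading_deg`, `choice` (-1/+1), `rt_s`, with a header row.
#'
#' @param trials trial tibble.
#' @param path CSV file path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(
    trials[, c("subject", "modality", "coherence", "heading_deg",
               "choice", "rt_s")],
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @param check validate the schema after reading.
#' @return `read_trial_table()` returns the trial tibble.
#' @export
read_trial_table <- function(path, check = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject = "character"))
  tab <- tibble::as_tibble(df)
  need <- c("subject", "modality", "coherence", "heading_deg",
            "choice", "rt_s")
  if (check) {
    if (!all(need %in% names(tab)))
      stop("trial table must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    if (!all(tab$modality %in% c("vestibular", "visual", "combined")))
      stop("unknown modality strings in trial table", call. = FALSE)
    if (!all(tab$choice %in% c(-1, 1)))
      stop("choice must be coded -1 (left) / +1 (right)", call. = FALSE)
  }
  tab[, need]
}
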