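# --- full-analysis orchestration -----------------------------------------

#' The standard reward-rate variant set
#'
#' The variants along which the optimality conclusion is probed:
#' no accumulation cost, costs of 0.1 and 0.2 reward units/s, parametric
#' (per-modality) bounds, and the two bias-removed ("unbiased")
#' optimizations. Each variant is a (cost, bound-variant, bias-handling)
#' triple.
#'
#' @return Named list of variant descriptors.
#' @export
default_variants <- function() {
  list(
    no_cost    = list(cost = 0,   bounds = "free",       unbiased = FALSE),
    cost_0.1   = list(cost = 0.1, bounds = "free",       unbiased = FALSE),
    cost_0.2   = list(cost = 0.2, bounds = "free",       unbiased = FALSE),
    parametric = list(cost = 0,   bounds = "parametric", unbiased = FALSE),
    unbiased_free = list(cost = 0, bounds = "free",      unbiased = TRUE),
    unbiased_parametric = list(cost = 0, bounds = "parametric",
                               unbiased = TRUE)
  )
}

#' Analysis configuration
#'
#' @param design an [experiment_design()].
#' @param variants subset of [default_variants()] (or compatible list).
#' @param n_subjects cohort size when synthesizing data.
#' @param truncated synthesize truncated-learner subjects.
#' @param base_variability between-subject parameter spread.
#' @param fit_settings passed to [fit_subject()].
#' @param opt_restarts restarts for each bound optimization.
#' @param solver_nx,solver_dt solver resolution for the reward-rate
#'   objective.
#' @param curvature run the Hessian / eigenspace diagnostics (on the
#'   no-cost free variant).
#' @param n_boot bootstrap resamples for subgroup intervals.
#' @param seed master seed.
#' @export
analysis_config <- function(design = experiment_design(),
                            variants = default_variants(),
                            n_subjects = 10, truncated = TRUE,
                            base_variability = 0.15,
                            fit_settings = list(),
                            opt_restarts = 10, solver_nx = 100,
                            solver_dt = 0.005, curvature = TRUE,
                            n_boot = 2000, seed = 1) {
  stopifnot(all(vapply(variants, function(v)
    all(c("cost", "bounds", "unbiased") %in% names(v)), logical(1))))
  structure(list(design = design, variants = variants,
                 n_subjects = n_subjects, truncated = truncated,
                 base_variability = base_variability,
                 fit_settings = fit_settings, opt_restarts = opt_restarts,
                 solver_nx = solver_nx, solver_dt = solver_dt,
                 curvature = curvature, n_boot = n_boot, seed = seed),
            class = "analysis_config")
}

# least-squares conversion of free per-cell bounds to the parametric
# (per-modality bound, coherence->sigma slope) space
parametric_from_free <- function(theta_free, design) {
  cells <- design$cells
  th <- theta_free[cells$cell]
  vis <- cells$modality != "vestibular"
  sse <- function(s) {
    adj <- log(pmax(th[vis], 1e-8)) + log(1 - s * cells$coherence[vis])
    sum(unlist(lapply(split(adj, cells$modality[vis]),
                      function(v) sum((v - mean(v))^2))))
  }
  s <- stats::optimize(sse, c(0, 0.9))$minimum
  thm <- c(vestibular = unname(th[cells$cell == "vestibular"]),
           vapply(c(visual = "visual", combined = "combined"), function(m) {
             sel <- cells$modality == m
             exp(mean(log(pmax(th[sel], 1e-8)) +
                        log(1 - s * cells$coherence[sel])))
           }, numeric(1)))
  bound_vector(variant = "parametric", theta_modality = thm, slope = s)
}

#' Run the full simulate-fit-optimize-diagnose analysis
#'
#' For each subject (synthesized unless a `cohort` is supplied): fit the
#' model, then for each variant compute the subject's model reward rate,
#' the optimal reward rate from tuned bounds, the random-choice
#' baseline, the relative reward rate and the bound-line projection;
#' optionally the curvature diagnostics. Cohort level: Wilcoxon
#' signed-rank tests (subject vs random) and box-plot summaries of the
#' relative reward rates per variant. Per-subject failures are isolated
#' and recorded; the run continues.
#'
#' @param config an [analysis_config()].
#' @param cohort optional precomputed list of [generate_subject()]
#'   results (overrides synthesis).
#' @return A report bundle (list) with `subjects` (per-subject records),
#'   `by_variant` tibble, `box_stats`, `wilcoxon`, `errors`, and the
#'   echoed `config`.
#' @export
run_full_analysis <- function(config, cohort = NULL) {
  design <- config$design
  profile <- make_stimulus_profile(design$duration_s, config$solver_dt)
  if (is.null(cohort))
    cohort <- generate_cohort(config$n_subjects,
                              config$base_variability, config$seed,
                              design = design,
                              truncated = config$truncated,
                              nx = config$solver_nx)
  subjects <- vector("list", length(cohort))
  errors <- list()
  for (i in seq_along(cohort)) {
    id <- cohort[[i]]$truth$subject_id
    rec <- try({
      trials <- cohort[[i]]$trials
      fit <- fit_subject(trials, design, "free",
                         modifyList(list(seed = config$seed * 10 + i),
                                    config$fit_settings))
      per_variant <- list()
      curv <- NULL
      for (vn in names(config$variants)) {
        v <- config$variants[[vn]]
        spec <- reward_spec(cost_per_s = v$cost)
        pop <- fit$params            # parameters used for optimization
        if (v$unbiased) pop$bias <- 0
        if (v$bounds == "parametric")
          pop$bounds <- parametric_from_free(fit$params$bounds$theta,
                                             design)
        opt <- optimize_bounds(pop, design, spec,
                               n_restarts = config$opt_restarts,
                               seed = config$seed * 100 + i,
                               profile = profile, nx = config$solver_nx)
        rr_subj <- model_reward_rate(fit$params, design, spec,
                                     profile = profile,
                                     nx = config$solver_nx)
        rr_rand <- random_choice_rr(fit$params, design, spec)
        s_proj <- try(
          project_to_bound_line(pop$bounds, opt, pop, design, spec,
                                profile = profile,
                                nx = config$solver_nx),
          silent = TRUE)
        per_variant[[vn]] <- list(
          variant = vn, rr_subject = rr_subj, rr_opt = opt$rr_opt,
          rr_random = rr_rand,
          relative_rr = relative_rr(rr_subj, opt),
          theta_hat = bound_coords(pop$bounds),
          theta_opt = bound_coords(opt$theta_opt),
          s_projection = if (inherits(s_proj, "try-error")) NA_real_
                         else s_proj)
        if (config$curvature && vn == "no_cost" && v$bounds == "free") {
          rep <- reward_rate_hessian(fit$params, design, spec,
                                     richardson = FALSE,
                                     profile = profile,
                                     nx = config$solver_nx)
          curv <- list(
            report = rep,
            pairs = curvature_distance_analysis(rep, fit$params$bounds,
                                                opt$theta_opt),
            loss = quadratic_loss_check(rep, fit$params$bounds,
                                        opt$theta_opt, rr_subj,
                                        opt$rr_opt))
        }
      }
      subgroups <- compare_subgroups(trials, reward_spec(),
                                     fit$params$t_nd,
                                     n_boot = config$n_boot,
                                     seed = config$seed * 7 + i)
      list(subject = id, fit = fit, variants = per_variant,
           curvature = curv, subgroups = subgroups)
    }, silent = TRUE)
    if (inherits(rec, "try-error")) {
      errors[[id]] <- attr(rec, "condition")$message
      subjects[[i]] <- list(subject = id, error = errors[[id]])
    } else subjects[[i]] <- rec
  }
  ok <- !vapply(subjects, function(s) !is.null(s$error), logical(1))
  by_variant <- do.call(rbind, unlist(lapply(subjects[ok], function(s)
    lapply(s$variants, function(v)
      tibble::tibble(subject = s$subject, variant = v$variant,
                     rr_subject = v$rr_subject, rr_opt = v$rr_opt,
                     rr_random = v$rr_random,
                     relative_rr = v$relative_rr,
                     s_projection = v$s_projection))),
    recursive = FALSE))
  box_stats <- NULL
  wilcoxon <- list()
  if (!is.null(by_variant) && nrow(by_variant) > 0) {
    box_stats <- do.call(rbind, lapply(split(by_variant,
                                             by_variant$variant),
                                       function(d) {
      q <- quantile(d$relative_rr, c(0, 0.25, 0.5, 0.75, 1))
      tibble::tibble(variant = d$variant[1], min = q[1], q25 = q[2],
                     median = q[3], q75 = q[4], max = q[5])
    }))
    wilcoxon <- lapply(split(by_variant, by_variant$variant),
                       function(d) {
      if (nrow(d) < 2) return(NULL)
      wilcoxon_signed_rank_exact(d$rr_subject - d$rr_random)
    })
  }
  list(subjects = subjects, by_variant = by_variant,
       box_stats = box_stats, wilcoxon = wilcoxon, errors = errors,
       config = config)
}

#' Subgroup reward rates with bootstrap intervals
#'
#' Empirical reward rate (with percentile bootstrap interval) for the
#' combined-condition trials, each unimodal condition, and the pooled
#' unimodal trials of one trial table.
#'
#' @param trials trial table with at least two modalities.
#' @param spec a [reward_spec()].
#' @param t_nd per-modality non-decision times.
#' @param n_boot,level,seed bootstrap settings.
#' @return Tibble with `subgroup`, `n_trials`, `rr`, `ci_low`,
#'   `ci_high`; subgroups missing from the table are omitted.
#' @export
compare_subgroups <- function(trials, spec = reward_spec(),
                              t_nd = c(vestibular = 0.3, visual = 0.3,
                                       combined = 0.3),
                              n_boot = 2000, level = 0.95, seed = 1) {
  if (length(unique(trials$modality)) < 2)
    stop("need at least two modalities for subgroup comparison",
         call. = FALSE)
  subsets <- list(
    combined = trials[trials$modality == "combined", ],
    visual = trials[trials$modality == "visual", ],
    vestibular = trials[trials$modality == "vestibular", ],
    unimodal = trials[trials$modality != "combined", ])
  out <- lapply(names(subsets), function(nm) {
    d <- subsets[[nm]]
    if (nrow(d) == 0) return(NULL)
    ci <- bootstrap_rr_ci(d, spec, t_nd, n_boot = max(n_boot, 1000),
                          level = level, seed = seed)
    tibble::tibble(subgroup = nm, n_trials = nrow(d),
                   rr = empirical_reward_rate(d, spec, t_nd),
                   ci_low = ci["low"], ci_high = ci["high"])
  })
  do.call(rbind, out)
}

#' Write the long-format report twin of a full analysis
#'
#' @param report a [run_full_analysis()] bundle.
#' @param csv_path,json_path output files (either may be `NULL`).
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path) && !is.null(report$by_variant))
    utils::write.csv(report$by_variant, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    slim <- list(
      by_variant = report$by_variant, box_stats = report$box_stats,
      wilcoxon = lapply(report$wilcoxon, function(w)
        if (is.null(w)) NULL else w[c("W", "n", "p_one_tailed",
                                      "p_two_tailed", "exact")]),
      errors = report$errors,
      seed = report$config$seed, n_subjects = report$config$n_subjects)
    jsonlite::write_json(slim, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
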