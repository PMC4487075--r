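#' Scaled decision-bound vector
#'
#' In the scaled model the diffusion variance is normalized to 1 and all
#' stimulus-reliability dependence lives in the drift sensitivities, so
#' the fitted bound is the actual bound divided by the diffusion standard
#' deviation. Two parameterizations are supported:
#'
#' * `"free"`: one nonnegative scaled bound per modality-by-coherence
#'   cell (2C + 1 values for C coherences: visual x C, combined x C,
#'   vestibular x 1).
#' * `"parametric"`: one actual bound per modality plus a linear
#'   coherence-to-standard-deviation map `sigma(c) = sigma0 * (1 - slope * c)`
#'   (must stay positive); the scaled bound of a visual/combined cell is
#'   `theta_modality / sigma(c)`. `sigma0` is fixed at 1 during fitting
#'   (it is collinear with the per-modality bounds).
#'
#' @param theta for `"free"`: named numeric vector of scaled bounds, one
#'   per cell id of the design (see [experiment_design()]); for
#'   `"parametric"`: ignored.
#' @param variant `"free"` or `"parametric"`.
#' @param theta_modality for `"parametric"`: named bounds
#'   `c(vestibular=, visual=, combined=)`.
#' @param sigma0,slope parametric variance map parameters;
#'   `1 - slope * c` must stay positive for all design coherences.
#' @return Object of class `bound_vector`.
#' @export
bound_vector <- function(theta = NULL, variant = c("free", "parametric"),
                         theta_modality = NULL, sigma0 = 1, slope = 0) {
  variant <- match.arg(variant)
  if (variant == "free") {
    if (is.null(theta) || is.null(names(theta)) || any(theta < 0) ||
        any(!is.finite(theta)))
      stop("free bounds need a named, nonnegative `theta`", call. = FALSE)
    structure(list(variant = "free", theta = theta), class = "bound_vector")
  } else {
    if (is.null(theta_modality) ||
        !setequal(names(theta_modality),
                  c("vestibular", "visual", "combined")) ||
        any(theta_modality < 0))
      stop("parametric bounds need nonnegative `theta_modality` named ",
           "vestibular/visual/combined", call. = FALSE)
    if (sigma0 <= 0 || slope < 0 || slope >= 1)
      stop("need sigma0 > 0 and slope in [0, 1)", call. = FALSE)
    structure(list(variant = "parametric",
                   theta_modality = theta_modality[c("vestibular", "visual",
                                                     "combined")],
                   sigma0 = sigma0, slope = slope),
              class = "bound_vector")
  }
}

#' Scaled bound per design cell
#'
#' Expands a [bound_vector()] to one scaled bound per design cell (in
#' design cell order); for the parametric variant this applies the
#' coherence-to-sigma map.
#'
#' @param bounds a [bound_vector()].
#' @param design an [experiment_design()].
#' @return Named numeric vector of scaled bounds.
#' @export
theta_by_cell <- function(bounds, design) {
  cells <- design$cells
  if (bounds$variant == "free") {
    th <- bounds$theta[cells$cell]
    if (any(is.na(th)))
      stop("free bound vector is missing cells: ",
           paste(cells$cell[is.na(th)], collapse = ", "), call. = FALSE)
    names(th) <- cells$cell
    return(th)
  }
  sig <- ifelse(cells$modality == "vestibular", bounds$sigma0,
                bounds$sigma0 * (1 - bounds$slope * cells$coherence))
  if (any(sig <= 0)) stop("parametric sigma(c) must stay positive",
                          call. = FALSE)
  th <- bounds$theta_modality[cells$modality] / sig
  names(th) <- cells$cell
  th
}

# rebuild a bound_vector of the same variant from a per-coordinate vector
# (free: per-cell theta; parametric: per-modality theta, map unchanged)
set_bound_coords <- function(bounds, coords) {
  if (bounds$variant == "free") {
    bounds$theta[names(coords)] <- coords
  } else {
    bounds$theta_modality[names(coords)] <- coords
  }
  bounds
}

#' The optimizable coordinates of a bound vector
#'
#' Free variant: the per-cell scaled bounds; parametric variant: the
#' three per-modality bounds (the sigma map is held fixed during
#' optimization).
#'
#' @param bounds a [bound_vector()].
#' @return Named numeric vector.
#' @export
bound_coords <- function(bounds) {
  if (bounds$variant == "free") bounds$theta else bounds$theta_modality
}

#' Subject-level diffusion-model parameters
#'
#' @param k_vest vestibular drift sensitivity (1/s per unit sine of
#'   heading).
#' @param k_vis visual drift sensitivities, one per coherence level,
#'   named by coherence (as formatted in the design cell ids).
#' @param bounds a [bound_vector()].
#' @param t_nd non-decision times (s), named
#'   `c(vestibular=, visual=, combined=)`.
#' @param bias start-point offset in units of the scaled bound, in
#'   (-1, 1); shared across modalities.
#' @param lapse probability of a stimulus-independent random choice with
#'   uniform reaction time, in `[0, 0.1]`.
#' @return Object of class `subject_params`.
#' @export
subject_params <- function(k_vest, k_vis, bounds, t_nd, bias = 0,
                           lapse = 0) {
  if (k_vest < 0 || any(k_vis < 0))
    stop("drift sensitivities must be nonnegative", call. = FALSE)
  if (is.null(names(k_vis)))
    stop("`k_vis` must be named by coherence", call. = FALSE)
  if (!inherits(bounds, "bound_vector"))
    stop("`bounds` must be a bound_vector", call. = FALSE)
  if (!setequal(names(t_nd), c("vestibular", "visual", "combined")) ||
      any(t_nd < 0))
    stop("`t_nd` must be nonnegative and named ",
         "vestibular/visual/combined", call. = FALSE)
  if (abs(bias) >= 1) stop("|bias| must be < 1", call. = FALSE)
  if (lapse < 0 || lapse > 0.1)
    stop("lapse must be in [0, 0.1]", call. = FALSE)
  structure(list(k_vest = k_vest, k_vis = k_vis, bounds = bounds,
                 t_nd = t_nd[c("vestibular", "visual", "combined")],
                 bias = bias, lapse = lapse),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params>\n")
  cat("  k_vest:", signif(x$k_vest, 4), "  k_vis:",
      paste(names(x$k_vis), signif(x$k_vis, 4), sep = "=", collapse = " "),
      "\n")
  cat("  bounds (", x$bounds$variant, "):",
      paste(signif(bound_coords(x$bounds), 4), collapse = " "), "\n")
  cat("  t_nd:", paste(names(x$t_nd), signif(x$t_nd, 3), sep = "=",
                       collapse = " "),
      " bias:", signif(x$bias, 3), " lapse:", x$lapse, "\n")
  invisible(x)
}

#' A plausible template subject for the default design
#'
#' Sensitivities give near-chance performance at the smallest headings
#' and near-ceiling at the largest, bounds of order one, ~300 ms
#' non-decision times and a small choice bias — a generic well-practised
#' observer in this task.
#'
#' @param design an [experiment_design()].
#' @return A [subject_params()] object.
#' @export
default_subject_params <- function(design = experiment_design()) {
  coh <- design$coherences
  kv <- setNames(4 + 9 * coh, coh_key(coh))  # reliability grows with coherence
  cells <- design$cells
  th <- setNames(numeric(nrow(cells)), cells$cell)
  th[cells$modality == "vestibular"] <- 1.1
  th[cells$modality == "visual"] <- seq(1.4, 1.1, length.out = length(coh))
  th[cells$modality == "combined"] <- seq(1.3, 1.0, length.out = length(coh))
  subject_params(
    k_vest = 5,
    k_vis = kv,
    bounds = bound_vector(theta = th),
    t_nd = c(vestibular = 0.30, visual = 0.35, combined = 0.32),
    bias = 0.03
  )
}
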