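#' Experiment design: interleaved modality/coherence/heading conditions
#'
#' Describes the structure of one heading-discrimination session:
#' a vestibular-only condition plus visual and combined (visual +
#' vestibular) conditions at each motion coherence, with signed heading
#' angles interleaved across trials.
#'
#' The default coherence set \{0.25, 0.37, 0.70\} and heading set
#' ±\{1, 2, 4, 8, 16\}° are plausible task settings (only the highest
#' coherence is pinned down by the task description); both are
#' configurable.
#'
#' @param coherences visual motion coherences, fractions in (0, 1].
#' @param headings_deg signed heading angles (degrees); must be symmetric
#'   about 0 (a 0 entry is allowed).
#' @param n_per_cell trials per modality-by-coherence cell, spread evenly
#'   over headings.
#' @param duration_s maximum stimulus duration (seconds).
#' @param weights per-cell weights used when averaging over cells
#'   (default equal).
#' @return Object of class `experiment_design` with a `cells` tibble
#'   (`cell`, `modality`, `coherence`, `weight`).
#' @export
experiment_design <- function(coherences = c(0.25, 0.37, 0.70),
                              headings_deg = c(-16, -8, -4, -2, -1,
                                               1, 2, 4, 8, 16),
                              n_per_cell = 100,
                              duration_s = 2,
                              weights = NULL) {
  if (any(coherences <= 0 | coherences > 1))
    stop("coherences must be in (0, 1]", call. = FALSE)
  hs <- sort(headings_deg)
  if (!all(vapply(hs, function(h) any(abs(hs + h) < 1e-9), logical(1))))
    stop("headings_deg must be symmetric about 0", call. = FALSE)
  if (any(abs(headings_deg) > 90))
    stop("headings must lie within +/-90 degrees", call. = FALSE)
  coherences <- sort(coherences)
  cells <- tibble::tibble(
    modality = c("vestibular", rep("visual", length(coherences)),
                 rep("combined", length(coherences))),
    coherence = c(NA_real_, coherences, coherences)
  )
  cells$cell <- cell_id(cells$modality, cells$coherence)
  if (is.null(weights)) weights <- rep(1 / nrow(cells), nrow(cells))
  if (length(weights) != nrow(cells) || any(weights < 0))
    stop("weights must be one nonnegative value per cell", call. = FALSE)
  cells$weight <- weights / sum(weights)
  structure(
    list(coherences = coherences, headings_deg = headings_deg,
         n_per_cell = n_per_cell, duration_s = duration_s,
         cells = cells[, c("cell", "modality", "coherence", "weight")]),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>", nrow(x$cells), "cells (",
      length(x$coherences), "coherences ),",
      length(x$headings_deg), "headings,", x$n_per_cell, "trials/cell\n")
  invisible(x)
}

# canonical coherence key: element-wise, no padding ("0.7", not "0.70")
coh_key <- function(x) as.character(signif(x, 8))

# canonical cell identifier, e.g. "vestibular", "visual_c0.37"
cell_id <- function(modality, coherence) {
  ifelse(modality == "vestibular", "vestibular",
         paste0(modality, "_c", coh_key(coherence)))
}

#' Reward-rate bookkeeping
#'
#' @param iti_s mean inter-trial interval in seconds (default 6).
#' @param cost_per_s evidence-accumulation cost in reward units per
#'   second of decision time (default 0; typical alternatives 0.1, 0.2).
#' @param reward_correct reward units per correct choice (default 1).
#' @return Object of class `reward_spec`.
#' @export
reward_spec <- function(iti_s = 6, cost_per_s = 0, reward_correct = 1) {
  if (iti_s <= 0) stop("iti_s must be positive", call. = FALSE)
  if (cost_per_s < 0) stop("cost_per_s must be nonnegative", call. = FALSE)
  structure(list(iti_s = iti_s, cost_per_s = cost_per_s,
                 reward_correct = reward_correct),
            class = "reward_spec")
}
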