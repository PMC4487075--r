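#' Drift-rate time course for one condition
#'
#' Maps a stimulus profile to the instantaneous drift rate of the scaled
#' (unit-variance) diffusion. The visual stream follows the velocity
#' profile with a coherence-dependent sensitivity, the vestibular stream
#' follows the rectified (peak-normalized magnitude) acceleration
#' profile, and the combined stream is their reliability-weighted optimal
#' combination — in the unit-variance reduction, the root-sum-square of
#' the two modality drifts:
#' \deqn{\mu_{comb}(t) = \sin h \sqrt{k_{vis}(c)^2 v(t)^2 + k_{vest}^2 \hat a(t)^2}.}
#'
#' @param params a [subject_params()].
#' @param modality `"vestibular"`, `"visual"` or `"combined"`.
#' @param coherence visual coherence (required for visual/combined,
#'   must be absent/NA for vestibular).
#' @param heading_deg signed heading angle in degrees, within ±90.
#' @param profile a [make_stimulus_profile()].
#' @return Numeric vector of drift samples (1/s) on the profile grid.
#' @export
drift_timecourse <- function(params, modality, coherence = NA,
                             heading_deg, profile) {
  if (abs(heading_deg) > 90)
    stop("heading must be within +/-90 degrees", call. = FALSE)
  s <- sin(heading_deg * pi / 180)
  ahat <- abs(profile$a)
  if (modality == "vestibular") {
    if (!is.na(coherence))
      stop("vestibular conditions carry no coherence", call. = FALSE)
    return(params$k_vest * s * ahat)
  }
  if (is.na(coherence))
    stop("coherence is required for visual/combined conditions",
         call. = FALSE)
  kv <- params$k_vis[coh_key(coherence)]
  if (is.na(kv))
    stop("no visual sensitivity for coherence ", coherence, call. = FALSE)
  kv <- unname(kv)
  if (modality == "visual") return(kv * s * profile$v)
  if (modality == "combined")
    return(s * sqrt(kv^2 * profile$v^2 + params$k_vest^2 * ahat^2))
  stop("unknown modality: ", modality, call. = FALSE)
}

# drift matrix for one design cell across all headings:
# (length(profile$t) x n_headings), columns named by heading
drift_matrix_cell <- function(params, modality, coherence, headings_deg,
                              profile) {
  s <- sin(headings_deg * pi / 180)
  ahat <- abs(profile$a)
  base <- if (modality == "vestibular") {
    params$k_vest * ahat
  } else {
    kv <- unname(params$k_vis[coh_key(coherence)])
    if (is.na(kv))
      stop("no visual sensitivity for coherence ", coherence,
           call. = FALSE)
    if (modality == "visual") kv * profile$v
    else sqrt(kv^2 * profile$v^2 + params$k_vest^2 * ahat^2)
  }
  m <- outer(base, s)
  colnames(m) <- format(headings_deg, trim = TRUE)
  m
}
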