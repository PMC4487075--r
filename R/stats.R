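#' Exact Wilcoxon signed-rank test
#'
#' Signed-rank statistic `W` (sum of the ranks of the positive
#' differences) with exact tail probabilities from the full null
#' distribution over all `2^n` sign assignments. Without ties in the
#' absolute differences the standard exact signed-rank distribution is
#' used; with ties, mid-ranks are used and the (conditional) exact
#' distribution is computed by dynamic programming over the doubled
#' ranks, and the result is flagged as approximate. Zero differences are
#' dropped with a warning.
#'
#' @param diffs paired differences.
#' @return Object of class `wilcoxon_result`: `W`, `n`, `p_one_tailed`
#'   (`P(W >= w)`, the "greater" direction), `p_two_tailed` (doubled
#'   smaller tail, capped at 1), `exact`, `tail_note`.
#' @examples
#' wilcoxon_signed_rank_exact(1:10)$W # 55
#' @export
wilcoxon_signed_rank_exact <- function(diffs) {
  if (any(diffs == 0)) {
    warning("dropping ", sum(diffs == 0), " zero difference(s)",
            call. = FALSE)
    diffs <- diffs[diffs != 0]
  }
  n <- length(diffs)
  if (n == 0) stop("no nonzero differences", call. = FALSE)
  r <- rank(abs(diffs))
  W <- sum(r[diffs > 0])
  ties <- anyDuplicated(abs(diffs)) > 0
  if (!ties) {
    p_ge <- psignrank(W - 1, n, lower.tail = FALSE)  # P(W >= w)
    p_le <- psignrank(W, n)                          # P(W <= w)
  } else {
    # exact conditional null over doubled mid-ranks by convolution
    r2 <- as.integer(round(2 * r))
    maxw <- sum(r2)
    cnt <- numeric(maxw + 1)
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(maxw + 1 - ri)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(probs[(w2 + 1):(maxw + 1)])
    p_le <- sum(probs[1:(w2 + 1)])
  }
  structure(
    list(W = W, n = n, p_one_tailed = p_ge,
         p_two_tailed = min(1, 2 * min(p_ge, p_le)),
         exact = !ties,
         tail_note = paste("one-tailed = P(W >= w) under H0, i.e. the",
                           "'differences greater than zero' direction;",
                           "two-tailed = doubled smaller tail")),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("<wilcoxon_result> W =", x$W, " n =", x$n,
      " p(one-tailed) =", signif(x$p_one_tailed, 4),
      " p(two-tailed) =", signif(x$p_two_tailed, 4),
      if (!x$exact) " [mid-ranks, conditional]" else "", "\n")
  invisible(x)
}

#' Bootstrap confidence interval for an empirical reward rate
#'
#' Percentile interval of [empirical_reward_rate()] over trial
#' resamples with replacement.
#'
#' @param trials trial table.
#' @param spec a [reward_spec()].
#' @param t_nd per-modality non-decision times (see
#'   [empirical_reward_rate()]).
#' @param n_boot number of bootstrap resamples (at least 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return Named numeric `(low, high)`.
#' @export
bootstrap_rr_ci <- function(trials, spec = reward_spec(),
                            t_nd = c(vestibular = 0.3, visual = 0.3,
                                     combined = 0.3),
                            n_boot = 2000, level = 0.95, seed = 1) {
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  if (n_boot < 1000) stop("n_boot must be at least 1000", call. = FALSE)
  n <- nrow(trials)
  correct <- ifelse(trials$heading_deg == 0, 0.5,
                    (sign(trials$choice) == sign(trials$heading_deg)) * 1)
  dtv <- pmax(trials$rt_s - unname(t_nd[trials$modality]), 0)
  rt <- trials$rt_s
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  num <- spec$reward_correct * colMeans(matrix(correct[idx], nrow = n)) -
    spec$cost_per_s * colMeans(matrix(dtv[idx], nrow = n))
  den <- colMeans(matrix(rt[idx], nrow = n)) + spec$iti_s
  rr <- num / den
  ci <- unname(quantile(rr, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 6))
  c(low = ci[1], high = ci[2])
}
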