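#' Threshold configuration for the reject option
#'
#' @param alpha significance level of the adaptive margin test
#'   (confidence level `1 - alpha`).
#' @param use_t use the Student-t quantile with `T - 1` degrees of
#'   freedom instead of the standard-normal quantile (the published
#'   scheme uses the normal quantile; the t-variant is the exact
#'   small-sample test).
#' @param grid_lo,grid_hi,grid_step sweep grid for the exhaustive
#'   baseline over normalized predictive entropy.
#' @return a `threshold_config` object.
#' @export
threshold_config <- function(alpha = 0.05, use_t = FALSE, grid_lo = 0.05,
                             grid_hi = 1.0, grid_step = 0.01) {
  stopifnot(alpha > 0, alpha < 1, grid_lo < grid_hi, grid_step > 0)
  structure(list(alpha = alpha, use_t = isTRUE(use_t), grid_lo = grid_lo,
                 grid_hi = grid_hi, grid_step = grid_step,
                 sweep_measure = "normalized_entropy"),
            class = "threshold_config")
}

#' Closed-form adaptive abstention threshold
#'
#' `T_M = sigma_d * z_(1-alpha) / sqrt(T)`: the critical mean margin of
#' a one-sided test of whether the expected per-pass margin exceeds
#' zero.  Inputs whose passes agree perfectly (`sigma_d = 0`) get a
#' zero threshold and are never rejected on dispersion grounds.
#'
#' @param sigma_d sample standard deviation of the per-pass margins
#'   (vectorized).
#' @param T number of forward passes (>= 2).
#' @param alpha significance level in (0, 1).
#' @param use_t use the Student-t quantile (`T - 1` df).
#' @return the threshold(s), same length as `sigma_d`.
#' @export
adaptive_threshold <- function(sigma_d, T, alpha = 0.05, use_t = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(all(sigma_d >= 0), T >= 2)
  q <- if (use_t) qt(1 - alpha, df = T - 1) else qnorm(1 - alpha)
  sigma_d * q / sqrt(T)
}

#' Accept/reject decision for a prediction
#'
#' A prediction is certain iff its mean margin strictly exceeds the
#' adaptive threshold, `M > T_M`; equivalently (for `sigma_d > 0`)
#' `zeta > z_(1-alpha)`.  At the boundary `M = T_M` (including the
#' degenerate `M = sigma_d = 0`) the prediction is rejected, so a stack
#' whose passes all agree is accepted only when its margin is positive.
#'
#' @param M mean margin (vectorized).
#' @param sigma_d margin sample standard deviation.
#' @param T number of passes.
#' @param alpha significance level.
#' @param use_t use the Student-t quantile.
#' @return logical vector: `TRUE` = certain (accepted).
#' @export
decide_certain <- function(M, sigma_d, T, alpha = 0.05, use_t = FALSE) {
  M > adaptive_threshold(sigma_d, T, alpha, use_t = use_t)
}

#' Exhaustive threshold sweep maximizing uncertainty accuracy
#'
#' The baseline scheme: a fixed threshold `Th` on normalized predictive
#' entropy is swept over a grid; predictions with `Hn > Th` are
#' uncertain.  For each grid point the uncertainty accuracy
#' `UA = (Ncc + Niu) / N` is evaluated and the smallest maximizing
#' threshold is returned together with the full curve.
#'
#' @param Hn per-input normalized predictive entropy in `[0, 1]`.
#' @param correct per-input logical correctness.
#' @param config a [threshold_config()].
#' @return list with `best_th`, `best_ua`, and `curve`
#'   (data frame `th`, `ua`).
#' @export
sweep_threshold <- function(Hn, correct, config = threshold_config()) {
  stopifnot(length(Hn) == length(correct), length(Hn) > 0,
            all(Hn >= 0), all(Hn <= 1 + 1e-9))
  grid <- seq(config$grid_lo, config$grid_hi, by = config$grid_step)
  ua <- vapply(grid, function(th) {
    reject_metrics(categorize(correct, Hn <= th))$UA
  }, 1.0)
  best <- which.max(ua)  # which.max returns the first (smallest) maximizer
  list(best_th = grid[best], best_ua = ua[best],
       curve = data.frame(th = grid, ua = ua))
}
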