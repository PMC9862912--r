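#' Mean prediction of a predictive stack
#'
#' The model's final prediction is the column mean of the `T x C` stack
#' of stochastic forward passes; the predicted class is its argmax,
#' with ties broken by the lowest class index (flagged via the `tie`
#' attribute).
#'
#' @param stack `T x C` matrix of simplex rows.
#' @return list with `y_star` (length-C simplex vector) and `class`.
#' @export
mean_prediction <- function(stack) {
  stopifnot(is.matrix(stack), nrow(stack) >= 1)
  check_simplex_rows(stack)
  y_star <- colMeans(stack)
  mx <- max(y_star)
  hits <- which(abs(y_star - mx) < 1e-12)
  cls <- hits[1]
  out <- list(y_star = y_star, class = cls)
  attr(out, "tie") <- length(hits) > 1
  out
}

check_simplex_rows <- function(stack, tol = 1e-6) {
  if (any(stack < -tol) || any(abs(rowSums(stack) - 1) > tol))
    stop("stack rows must lie on the probability simplex (nonnegative, sum 1)")
  invisible(TRUE)
}

entropy_bits <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1)
  -sum(ifelse(p > 1e-12, p * log2(p), 0))
}

#' Predictive entropy (bits) and its normalized form
#'
#' Base-2 entropy of the mean prediction, with `0 * log 0 := 0`; maximal
#' (`log2 C`) for the uniform vector, zero for a one-hot vector.
#' `Hn = H / log2(C)` lies in `[0, 1]`.
#'
#' @param y_star length-C mean prediction (simplex vector).
#' @return list with `H` (bits) and `Hn`.
#' @export
predictive_entropy <- function(y_star) {
  if (any(y_star < -1e-6) || abs(sum(y_star) - 1) > 1e-6)
    stop("y_star must lie on the probability simplex")
  H <- entropy_bits(y_star)
  list(H = H, Hn = H / log2(length(y_star)))
}

#' Mutual information between prediction and posterior draw
#'
#' The epistemic part of the predictive uncertainty: entropy of the
#' mean prediction minus the mean per-pass entropy.  Zero when all
#' passes agree; bounded above by the predictive entropy.
#'
#' @param stack `T x C` matrix of simplex rows.
#' @return mutual information in bits.
#' @export
mutual_information <- function(stack) {
  check_simplex_rows(stack)
  H <- entropy_bits(colMeans(stack))
  mean_pass <- mean(apply(stack, 1, entropy_bits))
  H - mean_pass
}

#' Margin-of-confidence statistics of a stack
#'
#' With `c` the argmax of the mean prediction, each pass contributes
#' `d_t = y_c^t - max_{j != c} y_j^t` (which may be negative when
#' another class wins that pass).  Returns the per-pass margins, their
#' mean `M`, and their sample (n-1) standard deviation `sigma_d`.
#'
#' @param stack `T x C` matrix of simplex rows (`T >= 2`).
#' @return list with `d`, `M`, `sigma_d`, and the reference class `class`.
#' @export
margin_stats <- function(stack) {
  stopifnot(is.matrix(stack))
  if (nrow(stack) < 2) stop("need at least two passes for the sample sd")
  check_simplex_rows(stack)
  cls <- mean_prediction(stack)$class
  other <- apply(stack[, -cls, drop = FALSE], 1, max)
  d <- stack[, cls] - other
  list(d = d, M = mean(d), sigma_d = stats::sd(d), class = cls)
}

#' Full uncertainty summary of one predictive stack
#'
#' Combines the mean prediction, entropy measures, mutual information,
#' margin statistics, the test statistic `zeta = M / (sigma_d / sqrt(T))`,
#' the adaptive threshold `T_M`, and the accept/reject decision.
#'
#' @param stack `T x C` matrix of simplex rows.
#' @param alpha significance level of the margin test.
#' @param use_t use the Student-t quantile (T-1 df) instead of the
#'   normal quantile.
#' @return list of class `uncertainty_summary`.
#' @export
uncertainty_summary <- function(stack, alpha = 0.05, use_t = FALSE) {
  mp <- mean_prediction(stack)
  ent <- predictive_entropy(mp$y_star)
  I <- mutual_information(stack)
  ms <- margin_stats(stack)
  Tn <- nrow(stack)
  T_M <- adaptive_threshold(ms$sigma_d, Tn, alpha, use_t = use_t)
  zeta <- if (ms$sigma_d > 0) ms$M / (ms$sigma_d / sqrt(Tn)) else
    ifelse(ms$M > 0, Inf, ifelse(ms$M < 0, -Inf, 0))
  structure(list(y_star = mp$y_star, class = mp$class, H = ent$H,
                 Hn = ent$Hn, I = I, d = ms$d, M = ms$M,
                 sigma_d = ms$sigma_d, zeta = zeta, T_M = T_M,
                 certain = decide_certain(ms$M, ms$sigma_d, Tn, alpha,
                                          use_t = use_t)),
            class = "uncertainty_summary")
}

#' Summarize a collection of stacks into a data frame
#'
#' @param stacks array `T x C x n` (as returned by [mc_predict()] or
#'   [generate_stacks()]).
#' @param alpha significance level of the margin test.
#' @param use_t use the Student-t quantile.
#' @return data frame with one row per input: `input_id`, `class`, `H`,
#'   `Hn`, `I`, `M`, `sigma_d`, `zeta`, `T_M`, `certain`.
#' @export
summarize_stacks <- function(stacks, alpha = 0.05, use_t = FALSE) {
  stopifnot(length(dim(stacks)) == 3)
  n <- dim(stacks)[3]
  rows <- lapply(seq_len(n), function(i) {
    s <- uncertainty_summary(stacks[, , i], alpha, use_t)
    data.frame(input_id = i, class = s$class, H = s$H, Hn = s$Hn, I = s$I,
               M = s$M, sigma_d = s$sigma_d, zeta = s$zeta, T_M = s$T_M,
               certain = s$certain)
  })
  do.call(rbind, rows)
}
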