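#' Four-way categorization of predictions
#'
#' Crosses correctness (prediction vs ground truth) with the
#' accept/reject decision into the four counts: correct-certain,
#' incorrect-certain, correct-uncertain, incorrect-uncertain.
#'
#' @param correct logical vector.
#' @param certain logical vector of equal length.
#' @return a `reject_counts` object with fields `Ncc`, `Nic`, `Ncu`,
#'   `Niu`, `N`.
#' @export
categorize <- function(correct, certain) {
  if (length(correct) != length(certain))
    stop("correct and certain must have equal length")
  stopifnot(is.logical(correct), is.logical(certain))
  structure(list(Ncc = sum(correct & certain),
                 Nic = sum(!correct & certain),
                 Ncu = sum(correct & !certain),
                 Niu = sum(!correct & !certain),
                 N = length(correct)),
            class = "reject_counts")
}

#' Reject-option quality criteria
#'
#' From the four-way counts: coverage `Rc = (Ncc + Nic) / N`, selective
#' accuracy `Rcc = Ncc / (Ncc + Nic)`, accuracy on rejected predictions
#' `Rcu = Ncu / (Ncu + Niu)`, and uncertainty accuracy
#' `UA = (Ncc + Niu) / N`.  A ratio with a zero denominator is
#' returned as `NA` (undefined, not zero).  `accuracy_all` is the plain
#' accuracy ignoring the reject decision.
#'
#' @param counts a `reject_counts` object (or list with the four
#'   fields).
#' @return a `reject_metrics` object: `Rc`, `Rcc`, `Rcu`, `UA`,
#'   `accuracy_all`.
#' @export
reject_metrics <- function(counts) {
  N <- counts$Ncc + counts$Nic + counts$Ncu + counts$Niu
  if (N == 0) stop("no predictions to evaluate")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(Rc = (counts$Ncc + counts$Nic) / N,
                 Rcc = ratio(counts$Ncc, counts$Ncc + counts$Nic),
                 Rcu = ratio(counts$Ncu, counts$Ncu + counts$Niu),
                 UA = (counts$Ncc + counts$Niu) / N,
                 accuracy_all = (counts$Ncc + counts$Ncu) / N),
            class = "reject_metrics")
}

#' Experiment plan for repeated holdout validation
#'
#' @param n_repetitions number of train/validation re-splits evaluated
#'   against the same fixed test set.
#' @param val_fraction fraction of the training pool used for
#'   validation in each repetition (class-stratified at trial level).
#' @param test_fraction fraction of all trials held out once, before
#'   any repetition, as the test set.
#' @param seed seed controlling all splits.
#' @return an `experiment_plan` object.
#' @export
experiment_plan <- function(n_repetitions = 16, val_fraction = 0.2,
                            test_fraction = 0.25, seed = 1L) {
  stopifnot(n_repetitions >= 1, val_fraction > 0, val_fraction < 1,
            test_fraction > 0, test_fraction < 1)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 val_fraction = val_fraction, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

# class-stratified sample of round(frac * n_k) trials per class;
# deterministic for a given seed
stratified_pick <- function(labels, frac, seed) {
  with_seed(seed, {
    picked <- integer(0)
    for (k in sort(unique(labels))) {
      idx <- which(labels == k)
      n_k <- round(frac * length(idx))
      if (n_k < 1)
        stop(sprintf("class %d has too few trials for stratification", k))
      picked <- c(picked, sample(idx, n_k))
    }
    sort(picked)
  })
}

#' Stratified train/validation holdout split
#'
#' Picks `val_fraction` of the pool's trials per class (identical class
#' ratios) for validation; the rest train.  Splitting is at trial
#' level so all crops of a trial fall on the same side, and is
#' deterministic per `(seed, repetition)`.
#'
#' @param labels per-trial class labels of the training pool.
#' @param plan an [experiment_plan()].
#' @param repetition repetition index i (>= 1).
#' @return list with `train_idx` and `val_idx` (trial indices).
#' @export
holdout_split <- function(labels, plan, repetition = 1L) {
  stopifnot(inherits(plan, "experiment_plan"), repetition >= 1)
  sub_seed <- (plan$seed + 7919L * as.integer(repetition)) %% .Machine$integer.max
  val_idx <- stratified_pick(labels, plan$val_fraction, sub_seed)
  list(train_idx = setdiff(seq_along(labels), val_idx), val_idx = val_idx)
}

#' Mean uncertainty per crop position
#'
#' Averages normalized predictive entropy across trials at each crop
#' position, producing the per-position uncertainty profile used to
#' locate the most reliable segment of a trial.
#'
#' @param Hn per-crop normalized entropy.
#' @param crop_position per-crop position ordinal.
#' @return data frame with `position` and `mean_Hn`, ordered by
#'   position.
#' @export
crop_uncertainty_profile <- function(Hn, crop_position) {
  stopifnot(length(Hn) == length(crop_position))
  tab <- table(crop_position)
  if (length(unique(as.integer(tab))) != 1)
    stop("ragged crop positions: every position must occur equally often")
  agg <- tapply(Hn, crop_position, mean)
  data.frame(position = as.integer(names(agg)), mean_Hn = as.numeric(agg),
             row.names = NULL)
}

#' Central crop positions of a trial
#'
#' The `k` positions centred on the middle of `n` crops; for even
#' leftovers the window is biased one position toward the start.
#'
#' @param n crops per trial.
#' @param k crops to select.
#' @return integer vector of k consecutive positions.
#' @export
central_crop_positions <- function(n, k = 5) {
  stopifnot(k >= 1, k <= n)
  start <- floor((n - k) / 2) + 1
  seq.int(start, start + k - 1)
}

#' Trial-level prediction from the central crops
#'
#' Averages the mean predictions of the `k` central crops of one trial
#' and takes the argmax as the trial label; the pooled stack (all
#' passes of the selected crops) supports an optional reject decision.
#'
#' @param stacks array `T x C x n_crops`, all crops of one trial in
#'   position order.
#' @param k number of central crops (default 5).
#' @param alpha significance level for the pooled reject decision.
#' @return list with `y_star`, `class`, `positions`, and `summary` (the
#'   [uncertainty_summary()] of the pooled stack).
#' @export
central_crop_predict <- function(stacks, k = 5, alpha = 0.05) {
  stopifnot(length(dim(stacks)) == 3)
  n <- dim(stacks)[3]
  if (k > n) stop("k exceeds the number of crops per trial")
  pos <- central_crop_positions(n, k)
  pooled <- do.call(rbind, lapply(pos, function(p) stacks[, , p]))
  y_star <- colMeans(pooled)
  list(y_star = y_star, class = which.max(y_star), positions = pos,
       summary = uncertainty_summary(pooled, alpha))
}

#' Repeated-holdout experiment with reject option
#'
#' Full orchestration on one data set: a fixed stratified test split,
#' then for each repetition a fresh train/validation split, model
#' training (deterministic pretraining when a MOPED prior is
#' requested), Monte-Carlo prediction on validation and test crops,
#' uncertainty summaries, the adaptive reject decision, the
#' exhaustive-search threshold calibrated on the validation set and
#' applied to the test set, and the full metric set.  Accuracy is
#' crop-wise.
#'
#' @param trials a raw [trial_set()].
#' @param plan an [experiment_plan()].
#' @param prep a [preprocess_config()].
#' @param tconf a [training_config()].
#' @param thconf a [threshold_config()].
#' @param model_kind `"moped"`, `"standard"` or `"deterministic"`
#'   (the deterministic baseline has no reject option and reports
#'   accuracy only).
#' @param arch optional [architecture_spec()]; defaults to the standard
#'   architecture for the data's channel/class counts.
#' @param verbose print progress.
#' @return list with `per_repetition` (data frame) and `mean` (named
#'   vector of averaged metrics).
#' @export
run_experiment <- function(trials, plan = experiment_plan(),
                           prep = preprocess_config(),
                           tconf = training_config(),
                           thconf = threshold_config(),
                           model_kind = c("moped", "standard", "deterministic"),
                           arch = NULL, verbose = FALSE) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(trials, "trial_set"))

  # preprocessing is causal and per-trial, so it is applied once up front
  prepped <- exp_moving_standardize(bandpass(trials, prep), prep)
  crops <- crop_trials(prepped, prep)

  n_trials <- dim(trials$data)[1]
  test_idx <- stratified_pick(trials$labels, plan$test_fraction, plan$seed)
  pool_idx <- setdiff(seq_len(n_trials), test_idx)
  crops_of <- function(trial_ids)
    crop_subset(crops, which(crops$trial_index %in% trial_ids))
  test_crops <- crops_of(test_idx)

  if (is.null(arch))
    arch <- architecture_spec(dim(trials$data)[2],
                              length(unique(trials$labels)),
                              input_len = round(prep$crop_len_s * trials$fs))

  rows <- list()
  for (i in seq_len(plan$n_repetitions)) {
    sp <- holdout_split(trials$labels[pool_idx], plan, i)
    tr_ids <- pool_idx[sp$train_idx]; va_ids <- pool_idx[sp$val_idx]
    stopifnot(length(intersect(tr_ids, test_idx)) == 0,
              length(intersect(va_ids, test_idx)) == 0,
              length(intersect(tr_ids, va_ids)) == 0)
    tr <- crops_of(tr_ids); va <- crops_of(va_ids)

    seed_i <- (tconf$seed + 104729L * i) %% .Machine$integer.max
    tconf_i <- tconf; tconf_i$seed <- seed_i
    det <- build_deterministic(arch, seed = seed_i)
    if (model_kind != "standard")
      det <- train_model(det, tr, va, tconf_i, verbose = verbose)

    if (model_kind == "deterministic") {
      probs <- forward_probs(det, crops_to_cube(test_crops$crops))
      acc <- mean(max.col(probs) == test_crops$labels)
      rows[[i]] <- data.frame(repetition = i, accuracy = acc, Rc = NA,
                              Rcc = NA, Rcu = NA, UA_adaptive = NA,
                              best_th = NA, UA_swept = NA)
      next
    }

    prior <- if (model_kind == "moped") moped_prior(det) else standard_prior()
    bnn <- to_bayesian(det, prior, seed = seed_i)
    bnn <- train_model(bnn, tr, va, tconf_i, verbose = verbose)

    st_test <- mc_predict(bnn, test_crops, T = tconf$T_predict,
                          seed = seed_i + 1L)
    sm_test <- summarize_stacks(st_test, thconf$alpha, thconf$use_t)
    correct <- sm_test$class == test_crops$labels
    m_adapt <- reject_metrics(categorize(correct, sm_test$certain))

    st_val <- mc_predict(bnn, va, T = tconf$T_predict, seed = seed_i + 2L)
    sm_val <- summarize_stacks(st_val, thconf$alpha, thconf$use_t)
    sw <- sweep_threshold(sm_val$Hn, sm_val$class == va$labels, thconf)
    m_swept <- reject_metrics(categorize(correct, sm_test$Hn <= sw$best_th))

    rows[[i]] <- data.frame(repetition = i, accuracy = m_adapt$accuracy_all,
                            Rc = m_adapt$Rc, Rcc = m_adapt$Rcc,
                            Rcu = m_adapt$Rcu, UA_adaptive = m_adapt$UA,
                            best_th = sw$best_th, UA_swept = m_swept$UA)
    if (verbose)
      message(sprintf("repetition %d: acc %.3f  UA(adaptive) %.3f  UA(swept) %.3f",
                      i, m_adapt$accuracy_all, m_adapt$UA, m_swept$UA))
  }
  per_rep <- do.call(rbind, rows)
  means <- colMeans(per_rep[, -1, drop = FALSE], na.rm = TRUE)
  list(per_repetition = per_rep, mean = means)
}
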