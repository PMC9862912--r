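#' Training configuration
#'
#' Optimizer and schedule settings shared by the deterministic baseline
#' and the variational models: Adam, early stopping on validation loss,
#' and learning-rate decay on plateau.  The divergence term of the
#' variational objective is weighted by `kl_weight` (defaulting to
#' `1 / N_train`, the conventional mean-field scaling when the
#' cross-entropy is averaged per example).
#'
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr_patience plateau length triggering a learning-rate decay.
#' @param lr_factor multiplicative decay factor.
#' @param min_lr lower bound for the decayed rate.
#' @param kl_weight divergence weight; `NULL` means `1 / N_train`.
#' @param T_predict default number of stochastic forward passes.
#' @param val_passes weight draws used to form the Monte-Carlo mean
#'   prediction when validating a variational model (validation measures
#'   the model as it predicts, not its plug-in means).
#' @param seed seed controlling shuffling, weight sampling and dropout.
#' @return a `training_config` object.
#' @export
training_config <- function(lr = 1e-3, batch_size = 64, max_epochs = 50,
                            patience = 20, lr_patience = 10, lr_factor = 0.5,
                            min_lr = 1e-5, kl_weight = NULL, T_predict = 50,
                            val_passes = 10, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1,
            T_predict >= 2, val_passes >= 1,
            is.null(kl_weight) || kl_weight > 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor, min_lr = min_lr,
                 kl_weight = kl_weight, T_predict = as.integer(T_predict),
                 val_passes = as.integer(val_passes),
                 seed = as.integer(seed)),
            class = "training_config")
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

train_step_raw <- function(model, w, cube, labels, drop_mask = numeric(0)) {
  sp <- model$spec
  scnn_train_step_cpp(cube, labels, w$Wt, w$Ws, model$gamma, model$beta,
                      w$Wd, w$bd, model$bn_mean, model$bn_var, drop_mask,
                      sp$temporal_stride, sp$avg_pool_len, sp$max_pool_len,
                      sp$max_pool_stride, 1e-5, 1e-6, 0.1)
}

eval_loss_acc <- function(model, crops, labels, n_passes = 1L, batch = 256L) {
  n <- dim(crops)[1]
  mc <- model$kind == "bayesian" && n_passes > 1L
  probs <- matrix(0, n, model$spec$n_classes)
  reps <- if (mc) n_passes else 1L
  for (r in seq_len(reps)) {
    w <- if (mc) sample_weights(model)$w else NULL
    for (start in seq(1L, n, by = batch)) {
      idx <- start:min(start + batch - 1L, n)
      probs[idx, ] <- probs[idx, ] +
        forward_probs(model, crops_to_cube(crops, idx), w)
    }
  }
  probs <- probs / reps
  p <- pmax(probs[cbind(seq_len(n), labels)], 1e-300)
  c(loss = -mean(log(p)), acc = mean(max.col(probs) == labels))
}

#' Train a shallow ConvNet (deterministic or variational)
#'
#' Minibatch Adam with early stopping on validation loss and
#' learning-rate decay on plateau.  For a Bayesian model each minibatch
#' uses one reparameterization sample `w = mu + softplus(rho) * eps`
#' shared across the batch (an unbiased single-sample ELBO gradient
#' estimator), and the loss adds `kl_weight` times the closed-form
#' Gaussian KL.  Validation loss is the cross-entropy of the model's
#' actual prediction: the Monte-Carlo mean over `val_passes` weight
#' draws for a variational model, the single forward pass for the
#' deterministic baseline.  The epoch achieving the best validation
#' loss is restored on return.
#'
#' @param model an `scnn_model` from [build_deterministic()] or
#'   [to_bayesian()].
#' @param train,val `crop_set` objects (or lists with `crops` and
#'   `labels`).
#' @param config a [training_config()].
#' @param verbose print per-epoch progress.
#' @return the trained model with a `history` data frame (epoch,
#'   train_loss, train_acc, val_loss, val_acc, lr) and `best_epoch`
#'   attached.
#' @export
train_model <- function(model, train, val, config = training_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "scnn_model"))
  n <- dim(train$crops)[1]
  if (n == 0 || dim(val$crops)[1] == 0)
    stop("empty training or validation set")
  stopifnot(length(train$labels) == n)
  bayes <- model$kind == "bayesian"
  klw <- if (is.null(config$kl_weight)) 1 / n else config$kl_weight
  dropout <- if (!bayes) model$spec$dropout else 0

  with_seed(config$seed, {
    params <- if (bayes) c(stats::setNames(model$mu, paste0("mu.", names(model$mu))),
                           stats::setNames(model$rho, paste0("rho.", names(model$rho))),
                           list(gamma = model$gamma, beta = model$beta))
              else c(model$weights, list(gamma = model$gamma, beta = model$beta))
    opt <- adam_init(params)
    lr <- config$lr
    hist <- list()
    best_loss <- Inf; best_epoch <- 0L; best_params <- params
    best_bn <- list(mean = model$bn_mean, var = model$bn_var)
    wait <- 0L; lr_wait <- 0L

    put_params <- function(m, p) {
      if (bayes) {
        for (nm in names(m$mu)) {
          m$mu[[nm]] <- p[[paste0("mu.", nm)]]
          m$rho[[nm]] <- p[[paste0("rho.", nm)]]
        }
      } else m$weights <- p[names(m$weights)]
      m$gamma <- p$gamma; m$beta <- p$beta
      m
    }

    for (epoch in seq_len(config$max_epochs)) {
      model <- put_params(model, params)
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        cube <- crops_to_cube(train$crops, idx)
        y <- train$labels[idx]
        mask <- if (dropout > 0)
          (runif(model$spec$dense_in) >= dropout) / (1 - dropout)
        else numeric(0)

        if (bayes) {
          sw <- sample_weights(model)
          res <- train_step_raw(model, sw$w, cube, y, mask)
          sig <- lapply(model$rho, softplus)
          grads <- params
          for (nm in names(model$mu)) {
            pr <- prior_moments(model, nm)
            gw <- res[[paste0("d", nm)]]
            dkl_dmu <- (model$mu[[nm]] - pr$mu) / pr$sigma^2
            dkl_dsig <- -1 / sig[[nm]] + sig[[nm]] / pr$sigma^2
            dsig_drho <- 1 / (1 + exp(-model$rho[[nm]]))
            grads[[paste0("mu.", nm)]] <- gw + klw * dkl_dmu
            grads[[paste0("rho.", nm)]] <-
              gw * sw$eps[[nm]] * dsig_drho + klw * dkl_dsig * dsig_drho
          }
          grads$gamma <- res$dgamma; grads$beta <- res$dbeta
          batch_loss <- res$loss + klw * model_kl(model)
        } else {
          res <- train_step_raw(model, model$weights, cube, y, mask)
          grads <- params
          for (nm in names(model$weights)) grads[[nm]] <- res[[paste0("d", nm)]]
          grads$gamma <- res$dgamma; grads$beta <- res$dbeta
          batch_loss <- res$loss
        }
        model$bn_mean <- as.numeric(res$bn_mean)
        model$bn_var <- as.numeric(res$bn_var)
        upd <- adam_step(opt, params, grads, lr)
        opt <- upd$state; params <- upd$params
        model <- put_params(model, params)
        ep_loss <- ep_loss + batch_loss * length(idx)
        ep_correct <- ep_correct + res$n_correct
      }
      va <- eval_loss_acc(model, val$crops, val$labels,
                          n_passes = config$val_passes)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                  train_acc = ep_correct / n,
                                  val_loss = va["loss"], val_acc = va["acc"],
                                  lr = lr, row.names = NULL)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f (acc %.3f)  val %.4f (acc %.3f)",
                        epoch, ep_loss / n, ep_correct / n, va["loss"], va["acc"]))
      if (va["loss"] < best_loss - 1e-6) {
        best_loss <- va["loss"]; best_epoch <- epoch
        best_params <- params
        best_bn <- list(mean = model$bn_mean, var = model$bn_var)
        wait <- 0L; lr_wait <- 0L
      } else {
        wait <- wait + 1L; lr_wait <- lr_wait + 1L
        if (lr_wait >= config$lr_patience && lr > config$min_lr) {
          lr <- max(lr * config$lr_factor, config$min_lr)
          lr_wait <- 0L
        }
        if (wait >= config$patience) break
      }
    }
    model <- put_params(model, best_params)
    model$bn_mean <- best_bn$mean; model$bn_var <- best_bn$var
    model$history <- do.call(rbind, hist)
    model$best_epoch <- best_epoch
    model
  })
}

#' Monte-Carlo prediction
#'
#' Performs `T` stochastic forward passes (fresh posterior weight sample
#' per pass, batch norm in inference mode so stochasticity comes only
#' from the weights) and returns the predictive stacks.  For a
#' deterministic model all rows of each stack are identical.
#'
#' @param model an `scnn_model`.
#' @param crops a `crop_set` or an `n x c x L` array.
#' @param T number of forward passes (>= 2).
#' @param seed seed for the weight draws.
#' @return array `T x C x n`: one `T x C` simplex-row stack per input,
#'   rows in draw order.
#' @export
mc_predict <- function(model, crops, T = 50, seed = 1L) {
  if (T < 2) stop("need at least two forward passes (dispersion undefined)")
  arr <- if (inherits(crops, "crop_set")) crops$crops else crops
  n <- dim(arr)[1]
  out <- array(0, dim = c(T, model$spec$n_classes, n))
  with_seed(seed, {
    batch <- 256L
    for (t in seq_len(T)) {
      w <- if (model$kind == "bayesian") sample_weights(model)$w else NULL
      for (start in seq(1L, n, by = batch)) {
        idx <- start:min(start + batch - 1L, n)
        out[t, , idx] <- t(forward_probs(model, crops_to_cube(arr, idx), w))
      }
    }
  })
  out
}
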