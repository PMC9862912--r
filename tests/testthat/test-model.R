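test_that("shape chain reproduces the printed architecture arithmetic", {
  for (c_ in c(3, 22)) {
    spec <- architecture_spec(n_channels = c_, n_classes = 4)
    expect_equal(spec$conv_out_len, 478L)
    expect_equal(spec$avg_out_len, 434L)
    expect_equal(spec$max_out_len, 54L)
    expect_equal(spec$dense_in, 2160L)  # independent of channel count
  }
  m <- build_deterministic(architecture_spec(22, 4), seed = 1)
  expect_equal(dim(m$weights$Wt), c(45, 40))
  expect_equal(dim(m$weights$Ws), c(22 * 40, 40))
  expect_equal(dim(m$weights$Wd), c(2160, 4))
  expect_error(architecture_spec(3, 2, input_len = 50), "too short")
})

test_that("forward pass emits simplex rows of the right width", {
  spec <- tiny_arch(n_classes = 3)
  m <- build_deterministic(spec, seed = 2)
  x <- array(rnorm(4 * 2 * 60), dim = c(4, 2, 60))
  p <- bayesmi:::forward_probs(m, bayesmi:::crops_to_cube(x))
  expect_equal(dim(p), c(4, 3))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9) && all(p >= 0))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  spec <- tiny_arch(n_classes = 3)
  m <- build_deterministic(spec, seed = 7)
  x <- array(rnorm(4 * 2 * 60), dim = c(4, 2, 60))
  y <- sample(1:3, 4, replace = TRUE)
  cube <- bayesmi:::crops_to_cube(x)
  step <- function(w, gamma, beta)
    bayesmi:::scnn_train_step_cpp(cube, y, w$Wt, w$Ws, gamma, beta, w$Wd,
                                  w$bd, m$bn_mean, m$bn_var, numeric(0),
                                  spec$temporal_stride, spec$avg_pool_len,
                                  spec$max_pool_len, spec$max_pool_stride,
                                  1e-5, 1e-6, 0.1)
  res <- step(m$weights, m$gamma, m$beta)
  h <- 1e-5
  for (field in c("Wt", "Ws", "Wd", "bd", "gamma", "beta")) {
    g_an <- as.numeric(res[[paste0("d", field)]])
    for (i in seq_len(min(4, length(g_an)))) {
      perturb <- function(eps) {
        w <- m$weights; gamma <- m$gamma; beta <- m$beta
        if (field %in% names(w)) w[[field]][i] <- w[[field]][i] + eps
        else if (field == "gamma") gamma[i] <- gamma[i] + eps
        else beta[i] <- beta[i] + eps
        step(w, gamma, beta)$loss
      }
      g_fd <- (perturb(h) - perturb(-h)) / (2 * h)
      expect_lt(abs(g_fd - g_an[i]), 1e-6)
    }
  }
})

test_that("MOPED prior follows the empirical scale rule", {
  m <- build_deterministic(tiny_arch(), seed = 3)
  m$weights$Wt[1, 1] <- 0.5
  m$weights$Wt[2, 1] <- 0
  m$weights$Wt[3, 1] <- -2.0
  pr <- moped_prior(m, delta = 0.1, eps = 1e-6)
  expect_equal(pr$sigma$Wt[1, 1], 0.05)
  expect_equal(pr$sigma$Wt[2, 1], 1e-6)   # floored at eps
  expect_equal(pr$sigma$Wt[3, 1], 0.2)    # |w_d| handles the sign
  expect_equal(pr$mu$Wt[3, 1], -2.0)
  expect_error(moped_prior(m, delta = 0), "positive")
})

test_that("Bayesian conversion doubles the weight count and is stochastic", {
  det <- build_deterministic(tiny_arch(), seed = 4)
  bnn <- to_bayesian(det, standard_prior(), seed = 5)
  np_det <- n_parameters(det); np_b <- n_parameters(bnn)
  expect_equal(np_b[["weights"]], 2L * np_det[["weights"]])
  x <- array(rnorm(2 * 2 * 60), dim = c(2, 2, 60))
  st <- mc_predict(bnn, x, T = 2, seed = 8)
  expect_false(isTRUE(all.equal(st[1, , ], st[2, , ])))
})

test_that("near-zero posterior scales collapse to the deterministic model", {
  det <- build_deterministic(tiny_arch(), seed = 6)
  bnn <- to_bayesian(det, moped_prior(det, delta = 1e-9, eps = 1e-9), seed = 1)
  x <- array(rnorm(3 * 2 * 60), dim = c(3, 2, 60))
  p_det <- bayesmi:::forward_probs(det, bayesmi:::crops_to_cube(x))
  st <- mc_predict(bnn, x, T = 3, seed = 2)
  for (t in 1:3) expect_lt(max(abs(t(st[t, , ]) - p_det)), 1e-5)
})

test_that("MOPED conversion requires pretrained weights", {
  det <- build_deterministic(tiny_arch(), seed = 1)
  pr <- moped_prior(det)
  pr$mu <- NULL
  expect_error(to_bayesian(det, pr), "pretrained")
})

test_that("Gaussian KL matches the closed form and vanishes at the prior", {
  expect_equal(kl_gaussian(0.3, 0.7, 0.3, 0.7), 0)
  expect_equal(kl_gaussian(1, 0.5, 0, 1),
               log(1 / 0.5) + (0.25 + 1) / 2 - 0.5)  # 0.8181...
  det <- build_deterministic(tiny_arch(), seed = 2)
  # posterior exactly at a MOPED prior => total KL 0
  bnn <- to_bayesian(det, moped_prior(det), seed = 3)
  expect_equal(model_kl(bnn), 0)
  expect_gte(model_kl(to_bayesian(det, standard_prior(), seed = 3)), 0)
})

test_that("ELBO loss is cross-entropy plus weighted KL", {
  det <- build_deterministic(tiny_arch(), seed = 2)
  bnn <- to_bayesian(det, standard_prior(), seed = 3)
  probs <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  labels <- c(1L, 2L)
  ce <- -mean(log(c(0.8, 0.7)))
  expect_equal(elbo_loss(probs, labels, bnn, kl_weight = 0.01),
               ce + 0.01 * model_kl(bnn))
  expect_error(elbo_loss(probs, c(1L, 2L, 1L), bnn, 0.01))
})

test_that("mc_predict rows are simplex draws whose mean is the estimator", {
  det <- build_deterministic(tiny_arch(), seed = 9)
  x <- array(rnorm(2 * 2 * 60), dim = c(2, 2, 60))
  expect_error(mc_predict(det, x, T = 1), "two forward passes")
  st <- mc_predict(det, x, T = 4, seed = 1)
  # deterministic model: all rows identical
  for (i in 1:2) expect_lt(max(abs(sweep(st[, , i], 2, st[1, , i]))), 1e-12)
  expect_equal(colMeans(st[, , 1]), mean_prediction(st[, , 1])$y_star)
})

test_that("training learns a separable toy task and early-stops", {
  dat <- tiny_crop_data(n_per_class = 30, seed = 11)
  n <- length(dat$labels)
  set.seed(12); ord <- sample(n)
  tr_i <- ord[1:45]; va_i <- ord[46:60]
  tr <- list(crops = dat$crops[tr_i, , , drop = FALSE], labels = dat$labels[tr_i])
  va <- list(crops = dat$crops[va_i, , , drop = FALSE], labels = dat$labels[va_i])
  m <- build_deterministic(tiny_arch(), seed = 13)
  fit <- train_model(m, tr, va, training_config(max_epochs = 30, patience = 8,
                                                batch_size = 16, seed = 14))
  expect_gt(max(fit$history$val_acc), 0.75)
  expect_true(fit$best_epoch >= 1)
  # loss trend decreases
  expect_lt(mean(tail(fit$history$train_loss, 3)),
            mean(head(fit$history$train_loss, 3)))
  expect_error(train_model(m, list(crops = dat$crops[0, , , drop = FALSE],
                                   labels = integer(0)), va,
                           training_config()), "empty")
})

test_that("variational training reduces the ELBO loss on the toy task", {
  dat <- tiny_crop_data(n_per_class = 25, seed = 21)
  set.seed(22); ord <- sample(length(dat$labels))
  tr_i <- ord[1:38]; va_i <- ord[39:50]
  tr <- list(crops = dat$crops[tr_i, , , drop = FALSE], labels = dat$labels[tr_i])
  va <- list(crops = dat$crops[va_i, , , drop = FALSE], labels = dat$labels[va_i])
  det <- build_deterministic(tiny_arch(), seed = 23)
  bnn <- to_bayesian(det, standard_prior(), seed = 24)
  fit <- train_model(bnn, tr, va, training_config(max_epochs = 25, patience = 8,
                                                  batch_size = 16, seed = 25))
  expect_lt(mean(tail(fit$history$train_loss, 3)),
            mean(head(fit$history$train_loss, 3)))
  expect_gte(model_kl(fit), 0)
})
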