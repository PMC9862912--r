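test_that("categorization counts the four outcomes", {
  ct <- categorize(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ct$Ncc, 1); expect_equal(ct$Ncu, 1)
  expect_equal(ct$Nic, 1); expect_equal(ct$Niu, 1)

  all_cc <- categorize(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(all_cc$Ncc, 5)
  expect_equal(all_cc$Nic + all_cc$Ncu + all_cc$Niu, 0)

  expect_error(categorize(c(TRUE), c(TRUE, FALSE)), "equal length")

  set.seed(21)
  correct <- runif(1000) < 0.5; certain <- runif(1000) < 0.5
  ct2 <- categorize(correct, certain)
  # brute-force pairwise counter
  cnt <- c(0, 0, 0, 0)
  for (i in 1:1000) {
    k <- if (correct[i] && certain[i]) 1 else if (!correct[i] && certain[i]) 2
         else if (correct[i]) 3 else 4
    cnt[k] <- cnt[k] + 1
  }
  expect_equal(c(ct2$Ncc, ct2$Nic, ct2$Ncu, ct2$Niu), cnt)
})

test_that("reject metrics evaluate the worked count vector", {
  m <- reject_metrics(list(Ncc = 80, Nic = 10, Ncu = 5, Niu = 5))
  expect_equal(m$Rc, 0.90)
  expect_equal(m$Rcc, 80 / 90)       # 0.8889
  expect_equal(m$Rcu, 0.50)
  expect_equal(m$UA, 0.85)
  expect_equal(m$accuracy_all, 0.85)

  perfect <- reject_metrics(list(Ncc = 7, Nic = 0, Ncu = 0, Niu = 3))
  expect_equal(perfect$UA, 1)

  und <- reject_metrics(list(Ncc = 0, Nic = 0, Ncu = 2, Niu = 3))
  expect_true(is.na(und$Rcc))        # undefined, not zero
  expect_error(reject_metrics(list(Ncc = 0, Nic = 0, Ncu = 0, Niu = 0)),
               "no predictions")
})

test_that("metric identities hold for arbitrary counts", {
  set.seed(22)
  for (i in 1:200) {
    cts <- list(Ncc = sample(1:50, 1), Nic = sample(1:50, 1),
                Ncu = sample(1:50, 1), Niu = sample(1:50, 1))
    m <- reject_metrics(cts)
    expect_equal(m$UA, m$Rc * m$Rcc + (1 - m$Rc) * (1 - m$Rcu))
    expect_equal(m$accuracy_all, m$Rc * m$Rcc + (1 - m$Rc) * m$Rcu)
  }
})

test_that("holdout splits are stratified, deterministic and disjoint", {
  labels <- rep(1:4, each = 25)
  plan <- experiment_plan(val_fraction = 0.2, seed = 30)
  sp <- holdout_split(labels, plan, 1)
  expect_length(sp$val_idx, 20)
  expect_equal(as.integer(table(labels[sp$val_idx])), rep(5L, 4))
  expect_length(intersect(sp$train_idx, sp$val_idx), 0)
  expect_setequal(c(sp$train_idx, sp$val_idx), seq_along(labels))
  sp2 <- holdout_split(labels, plan, 1)
  expect_identical(sp, sp2)
  sp3 <- holdout_split(labels, plan, 2)
  expect_false(identical(sp$val_idx, sp3$val_idx))
  expect_error(holdout_split(c(1, 1, 2), experiment_plan(val_fraction = 0.1),
                             1), "too few")
})

test_that("crop uncertainty profile averages by position", {
  # constant uncertainty => flat profile
  flat <- crop_uncertainty_profile(rep(0.4, 30), rep(1:10, 3))
  expect_equal(nrow(flat), 10)
  expect_true(all(flat$mean_Hn == 0.4))

  # U-shaped uncertainty over positions: interior minimum
  pos <- rep(1:11, 4)
  Hn <- 0.5 + 0.4 * ((pos - 6) / 5)^2 + 0  # parabola, min at 6
  prof <- crop_uncertainty_profile(Hn, pos)
  expect_equal(prof$position[which.min(prof$mean_Hn)], 6L)
  expect_gt(prof$mean_Hn[1], min(prof$mean_Hn))
  expect_gt(prof$mean_Hn[11], min(prof$mean_Hn))

  expect_error(crop_uncertainty_profile(rep(0.1, 5), c(1, 1, 2, 2, 2)),
               "ragged")
})

test_that("central-crop selection lands on the stated positions", {
  expect_equal(central_crop_positions(563, 5), 280:284)
  cfg <- preprocess_config()
  starts <- cfg$crop_start_s + (280:284 - 1) * cfg$crop_stride_s
  expect_equal(starts, seq(1.732, 1.764, by = 0.008))
  expect_equal(central_crop_positions(10, 3), 4:6)  # even count biased left
  expect_error(central_crop_positions(4, 5))
})

test_that("central-crop prediction pools stacks and degenerates to the mean", {
  set.seed(31)
  stacks <- array(0, dim = c(6, 3, 9))
  for (i in 1:9) stacks[, , i] <- random_stack(T = 6, C = 3)
  out <- central_crop_predict(stacks, k = 5)
  expect_equal(out$positions, 3:7)
  expect_equal(sum(out$y_star), 1, tolerance = 1e-9)
  # k = all crops equals the whole-trial average prediction
  all_out <- central_crop_predict(stacks, k = 9)
  expect_equal(all_out$y_star, apply(stacks, 2, mean))
  expect_error(central_crop_predict(stacks, k = 10), "exceeds")
})

test_that("uniform random guessing attains the 1/C floor", {
  set.seed(32)
  n <- 20000; C <- 4
  labels <- rep(1:C, n / C)
  preds <- sample(1:C, n, replace = TRUE)
  acc <- mean(preds == labels)
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("informative uncertainty raises Rcc as confidence grows", {
  # stacks whose dispersion tracks correctness by construction
  set.seed(33)
  n <- 400
  correct <- runif(n) < 0.7
  M <- ifelse(correct, rnorm(n, 0.5, 0.1), rnorm(n, 0.05, 0.1))
  s <- ifelse(correct, runif(n, 0.05, 0.2), runif(n, 0.3, 0.6))
  rcc <- function(alpha)
    reject_metrics(categorize(correct, decide_certain(M, s, 50, alpha)))$Rcc
  expect_gte(rcc(0.01), rcc(0.10) - 1e-9)

  # independent noise: no such monotonicity guarantee (values may tie or
  # invert); only check the metrics stay defined and bounded
  M2 <- rnorm(n, 0.3, 0.2); s2 <- runif(n, 0.05, 0.5)
  r <- reject_metrics(categorize(correct, decide_certain(M2, s2, 50, 0.05)))
  expect_true(r$Rc >= 0 && r$Rc <= 1)
})
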