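one_hotish <- function(labels, conf = 0.9, k = 3) {
  p <- matrix((1 - conf) / (k - 1), length(labels), k)
  p[cbind(seq_along(labels), labels + 1L)] <- conf
  p
}

test_that("perfectly confident correct predictions fill the diagonal", {
  labels <- rep(0:2, each = 20)
  joint <- estimate_confident_joint(one_hotish(labels, 0.98), labels)
  expect_equal(sum(joint$counts) - sum(diag(joint$counts)), 0)
  expect_equal(unname(diag(joint$counts)), c(20, 20, 20))
  expect_equal(joint$noise_estimate, 0)
})

test_that("a never-confident class has an empty column", {
  labels <- rep(0:2, each = 10)
  # the model never favours class 2: its own samples look like class 0
  p <- one_hotish(ifelse(labels == 2L, 0L, labels), 0.9)
  joint <- estimate_confident_joint(p, labels)
  expect_equal(sum(joint$counts[, 3]), 0)
})

test_that("uniform flips put the expected mass off the diagonal", {
  n <- 1500
  true <- withr::with_seed(1, sample(0:2, n, replace = TRUE))
  observed <- withr::with_seed(2, {
    flip <- stats::runif(n) < 0.2
    ifelse(flip, (true + sample(1:2, n, replace = TRUE)) %% 3, true)
  })
  # well-calibrated probabilities reflect the *true* class
  joint <- estimate_confident_joint(one_hotish(true, 0.85), observed)
  off <- (sum(joint$counts) - sum(diag(joint$counts))) / sum(joint$counts)
  expect_lt(abs(off - 0.2), 0.03)
  expect_lt(abs(joint$noise_estimate - 0.2), 0.03)
})

test_that("pruning removes planted flips and reweights by class size", {
  d <- toy_three_class(60, seed = 3, centers = c(0, 5, 10))
  flip_idx <- withr::with_seed(4, sample(nrow(d), 10))
  d$label[flip_idx] <- (d$label[flip_idx] + 1L) %% 3L
  probs <- cv_probabilities(as.matrix(d[, 1:2]), d$label, k = 3,
                            folds = 5, config = classifier_config(),
                            seed = 5)
  joint <- estimate_confident_joint(probs, d$label)
  res <- prune_and_reweight(d, joint)
  dropped <- joint$assigned[joint$predicted != d$label[joint$assigned]]
  expect_gte(length(intersect(flip_idx, dropped)), 8)
  expect_identical(nrow(res$data) + nrow(res$pruned), nrow(d))

  # inverse-frequency weights, mean-normalized
  d2 <- toy_three_class(10, seed = 6)
  d2 <- d2[c(1:10, 11:15, 21:25), ]    # class sizes 10 / 5 / 5
  joint0 <- estimate_confident_joint(one_hotish(d2$label, 0.95), d2$label)
  res2 <- prune_and_reweight(d2, joint0)
  w <- res2$class_weights
  expect_equal(unname(w / w[1]), c(1, 2, 2))
  expect_equal(nrow(res2$pruned), 0L)
  expect_equal(mean(res2$data$.weight), 1, tolerance = 0.35)
})

test_that("co-teaching keeps everything during warm-up and is deterministic", {
  d <- toy_three_class(30, seed = 7)
  cfg <- classifier_config(epochs = 20, warmup_epochs = 5,
                           architecture = "linear")
  fit <- coteach_train(d, cfg, seed = 1)
  expect_true(all(fit$keep_schedule[1:5] == 1))
  expect_true(all(diff(fit$keep_schedule[6:20]) <= 0))
  expect_equal(min(fit$keep_schedule), 1 - cfg$forget_rate)

  fit2 <- coteach_train(d, cfg, seed = 1)
  expect_identical(fit$model_a$par, fit2$model_a$par)

  d1 <- d; d1$label <- 0L
  expect_error(coteach_train(d1, cfg, seed = 1))
})

test_that("co-teaching matches plain training without noise and beats it with noise", {
  clean_gap <- vapply(1:3, function(s) {
    train <- toy_three_class(60, seed = s, centers = c(0, 5, 10))
    test <- toy_three_class(60, seed = 50 + s, centers = c(0, 5, 10))
    cfg <- classifier_config(epochs = 60, architecture = "linear")
    ct <- coteach_train(train, cfg, seed = s)
    plain <- fit_net(as.matrix(train[, 1:2]), train$label, k = 3,
                     config = `$<-`(cfg, "small_loss", FALSE), seed = s)
    acc_ct <- mean(predict_final(ct, test) == test$label)
    acc_pl <- mean(predict_net(plain, as.matrix(test[, 1:2]),
                               type = "class") == test$label)
    acc_ct - acc_pl
  }, numeric(1))
  expect_gte(mean(clean_gap), -0.02)

  noisy_gap <- vapply(1:5, function(s) {
    train <- toy_three_class(80, seed = 10 + s, centers = c(0, 4, 8))
    train$label <- withr::with_seed(30 + s, {
      flip <- stats::runif(nrow(train)) < 0.2
      ifelse(flip, (train$label + 1L) %% 3L, train$label)
    })
    test <- toy_three_class(80, seed = 70 + s, centers = c(0, 4, 8))
    cfg <- classifier_config(epochs = 60, architecture = "linear")
    ct <- coteach_train(train, cfg, seed = s)
    plain <- fit_net(as.matrix(train[, 1:2]), train$label, k = 3,
                     config = `$<-`(cfg, "small_loss", FALSE), seed = s)
    mean(predict_final(ct, test) == test$label) -
      mean(predict_net(plain, as.matrix(test[, 1:2]),
                       type = "class") == test$label)
  }, numeric(1))
  expect_gte(mean(noisy_gap), 0)
})

test_that("final prediction averages the peers and breaks ties low", {
  d <- toy_three_class(40, seed = 8, centers = c(0, 5, 10))
  fit <- coteach_train(d, classifier_config(epochs = 120,
                                            architecture = "linear"),
                       seed = 2, noise_estimate = 0)
  test <- toy_three_class(50, seed = 9, centers = c(0, 5, 10))
  acc <- mean(predict_final(fit, test) == test$label)
  expect_gte(acc, 0.95)

  p <- coteach_probs(fit, test)
  expect_equal(rowSums(p), rep(1, nrow(p)))
  expect_identical(predict_final(fit, test),
                   max.col(p, ties.method = "first") - 1L)

  # explicit tie: equal averaged probabilities pick the lowest index
  tied <- matrix(c(0.4, 0.4, 0.2), 1)
  expect_identical(max.col(tied, ties.method = "first") - 1L, 0L)
})
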