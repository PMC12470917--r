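test_that("standardizer round-trips and rejects constant columns", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  s <- fit_standardizer(X)
  expect_lt(max(abs(std_inverse(s, std_transform(s, X)) - X)), 1e-12)
  Z <- std_transform(s, X)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  X[, 2] <- 5
  expect_error(fit_standardizer(X), "zero/undefined spread.*b")
})

test_that("forward pass reproduces a hand-computed single-hidden-layer case", {
  net <- surrogate_net(2, hidden = 2, n_outputs = 1, dropout = 0, seed = 1)
  net$W[[1]] <- matrix(c(1, -1, 0.5, 2), 2, 2)   # inputs x hidden
  net$b[[1]] <- c(0.1, -0.2)
  net$W[[2]] <- matrix(c(1, -2), 2, 1)
  net$b[[2]] <- 0.3
  x <- matrix(c(0.4, -0.3), 1, 2)
  # by hand: h = relu(c(0.4*1 - 0.3*(-1) + 0.1, 0.4*0.5 - 0.3*2 - 0.2))
  h <- pmax(c(0.4 + 0.3 + 0.1, 0.2 - 0.6 - 0.2), 0)
  y_hand <- sum(h * c(1, -2)) + 0.3
  y_net <- drop(net_forward_test(net, x))
  expect_equal(y_net, y_hand, tolerance = 1e-12)
})

test_that("an untrained zero net predicts its bias everywhere", {
  net <- surrogate_net(3, hidden = c(4, 4), n_outputs = 2, seed = 1)
  net$W <- lapply(net$W, function(w) w * 0)
  net$b[[length(net$b)]] <- c(1.5, -2.5)
  X <- matrix(rnorm(15), 5, 3)
  pred <- net_forward_test(net, X)
  expect_true(all(abs(sweep(pred, 2, c(1.5, -2.5))) < 1e-14))
})

test_that("the analytic gradient matches finite differences", {
  set.seed(4)
  net <- surrogate_net(2, hidden = c(3), n_outputs = 2, dropout = 0,
                       weight_decay = 0, seed = 4)
  X <- matrix(rnorm(10), 5, 2)
  Y <- matrix(rnorm(10), 5, 2)
  cfg <- train_config(loss = "huber", huber_delta = 0.7, seed = 1)
  loss_of <- function(net) {
    R <- net_forward_test(net, X) - Y
    d <- 0.7
    q <- abs(R) <= d
    sum(ifelse(q, 0.5 * R^2, d * (abs(R) - 0.5 * d))) / nrow(R)
  }
  g <- net_gradient_test(net, X, Y, cfg)
  h <- 1e-6
  for (l in 1:2) {
    for (idx in c(1, length(net$W[[l]]))) {
      np <- net; np$W[[l]][idx] <- np$W[[l]][idx] + h
      nm <- net; nm$W[[l]][idx] <- nm$W[[l]][idx] - h
      fd <- (loss_of(np) - loss_of(nm)) / (2 * h)
      expect_equal(g$W[[l]][idx], fd, tolerance = 1e-5)
    }
  }
})

test_that("training recovers a linearly representable target", {
  df <- linear_toy(200)
  sp <- toy_splits(df)
  fit <- fit_surrogate(sp, inputs = c("x", "z"), targets = "y",
                       hidden = c(16, 8), dropout = 0, config = fast_config())
  rep <- evaluate_surrogate(fit, sp$test)
  expect_gte(rep$r2, 0.999)
  # repeated prediction is deterministic
  p1 <- predict_surrogate(fit, sp$test)
  p2 <- predict_surrogate(fit, sp$test)
  expect_identical(p1, p2)
  expect_error(predict_surrogate(fit, sp$test["x"]), "lacks input column")
})

test_that("training is bit-reproducible under a fixed seed", {
  df <- linear_toy(120)
  sp <- toy_splits(df)
  cfg <- train_config(max_epochs = 60, patience = 30, seed = 99)
  f1 <- fit_surrogate(sp, inputs = c("x", "z"), targets = "y",
                      hidden = c(8), config = cfg)
  f2 <- fit_surrogate(sp, inputs = c("x", "z"), targets = "y",
                      hidden = c(8), config = cfg)
  expect_identical(f1$net$W, f2$net$W)
  expect_identical(f1$history, f2$history)
})

test_that("early stopping fires at patience epochs after the best epoch", {
  df <- linear_toy(80)
  sp <- toy_splits(df)
  # a zero learning rate freezes validation MAE: epoch 1 is the best forever
  cfg <- train_config(lr = 1e-30, patience = 12, max_epochs = 200, seed = 5)
  fit <- fit_surrogate(sp, inputs = c("x", "z"), targets = "y",
                       hidden = c(4), dropout = 0, config = cfg)
  expect_identical(fit$best_epoch, 1L)
  expect_identical(nrow(fit$history), 13L)   # best + patience epochs
})

test_that("stratified split honours the fractions and strata", {
  ds <- full_factorial()
  ds$sigma_vm_max <- 1; ds$delta_max <- 1; ds$sigma_screw_max <- 1
  sp <- split_stratified(ds, seed = 1)
  expect_identical(vapply(sp, nrow, integer(1)),
                   c(train = 336L, val = 72L, test = 72L))
  # disjoint and exhaustive
  key <- function(d) paste(d$d, d$a, d$t_lat, d$t_plate, d$P)
  all_keys <- unlist(lapply(sp, key))
  expect_identical(sort(unname(all_keys)), sort(key(ds)))
  expect_identical(anyDuplicated(all_keys), 0L)
  # per-stratum proportions within one row of the target in every split
  for (part in names(sp)) {
    tab <- table(sp[[part]]$P, sp[[part]]$t_plate)
    expect_lte(max(abs(tab - mean(tab))), 1)
  }
  # 100 rows -> exactly 70/15/15
  sp100 <- split_stratified(ds[1:100, ], seed = 2, strata_cols = character(0))
  expect_identical(vapply(sp100, nrow, integer(1)),
                   c(train = 70L, val = 15L, test = 15L))
  expect_warning(split_stratified(ds[c(1:3, 241), ], seed = 1), "merged")
})

test_that("evaluation metrics match a hand-computed five-row fixture", {
  Y <- matrix(c(10, 12, 14, 16, 18), 5, 1)
  Yhat <- matrix(c(11, 11, 15, 15, 19), 5, 1)
  rep <- latticeplate:::eval_report(Y, Yhat, "t")
  expect_equal(rep$mae, mean(abs(Yhat - Y)), tolerance = 1e-12)
  expect_equal(rep$rmse, sqrt(mean((Yhat - Y)^2)), tolerance = 1e-12)
  expect_equal(rep$r2, 1 - sum((Yhat - Y)^2) / sum((Y - mean(Y))^2),
               tolerance = 1e-12)
  expect_equal(rep$mae_pct, 100 * rep$mae / mean(Y), tolerance = 1e-12)
  # perfect predictions and the mean predictor
  perfect <- latticeplate:::eval_report(Y, Y, "t")
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  mean_pred <- latticeplate:::eval_report(Y, matrix(mean(Y), 5, 1), "t")
  expect_equal(mean_pred$r2, 0)
  expect_lte(rep$mae, rep$rmse)
})

test_that("residual sigma equals the test RMSE and guards degeneracy", {
  df <- linear_toy(150)
  sp <- toy_splits(df)
  fit <- fit_surrogate(sp, inputs = c("x", "z"), targets = "y",
                       hidden = c(16, 8), dropout = 0, config = fast_config())
  rm <- fit_residual_model(fit, sp$test)
  rep <- evaluate_surrogate(fit, sp$test)
  expect_equal(unname(rm$sigma), rep$rmse, tolerance = 1e-12)
  # residuals drawn from N(0, 2): sigma recovers 2 within sampling error
  noisy <- sp$test
  set.seed(8)
  noisy$y <- noisy$y + rnorm(nrow(noisy), 0, 2)
  rm2 <- fit_residual_model(fit, noisy)
  expect_equal(unname(rm2$sigma), 2, tolerance = 0.5)
})

test_that("cross-validation recovers a linear fixture with small error", {
  set.seed(10)
  df <- tibble::tibble(x = runif(24, -1, 1), z = runif(24, -1, 1))
  df$y <- 3 * df$x + 1 + 0.5 * df$z
  cfg <- train_config(lr = 5e-3, max_epochs = 2000, patience = 500, seed = 2)
  cv <- crossvalidate_surrogate(df, k = 6, inputs = c("x", "z"),
                                targets = "y", hidden = c(16, 8),
                                dropout = 0, config = cfg, seed = 2)
  expect_lt(cv$mean$mae, 0.3)       # ~4% of the response range
  expect_gt(cv$mean$r2, 0.9)
  # fold partition and metrics reproducible under seed
  cheap <- train_config(max_epochs = 50, patience = 20, seed = 2)
  cv1 <- crossvalidate_surrogate(df, k = 3, inputs = c("x", "z"),
                                 targets = "y", hidden = c(4), dropout = 0,
                                 config = cheap, seed = 5)
  cv2 <- crossvalidate_surrogate(df, k = 3, inputs = c("x", "z"),
                                 targets = "y", hidden = c(4), dropout = 0,
                                 config = cheap, seed = 5)
  expect_equal(cv1$mean, cv2$mean)
  expect_error(crossvalidate_surrogate(df, k = 1), "k must be >= 2")
})

test_that("polynomial baseline reproduces representable targets exactly", {
  set.seed(3)
  df <- tibble::tibble(x = runif(40, -1, 1), z = runif(40, -1, 1))
  df$y <- 1 + 2 * df$x - df$z + 0.5 * df$x * df$z + df$x^2
  sp <- toy_splits(df, c(0.6, 0.2, 0.2))
  pb <- poly_baseline(sp, degree = 2, inputs = c("x", "z"), targets = "y")
  expect_gt(pb$report$r2, 1 - 1e-10)
  # degree 1 on a purely linear target
  df$y <- 2 * df$x + 1
  pb1 <- poly_baseline(toy_splits(df, c(0.6, 0.2, 0.2)), degree = 1,
                       inputs = c("x", "z"), targets = "y")
  expect_equal(pb1$report$r2, 1, tolerance = 1e-10)
})

test_that("checkpoints round-trip through the portable JSON format", {
  df <- linear_toy(100)
  sp <- toy_splits(df)
  fit <- fit_surrogate(sp, inputs = c("x", "z"), targets = "y",
                       hidden = c(8, 4), config = fast_config())
  path <- withr::local_tempfile(fileext = ".json")
  save_surrogate(fit, path)
  back <- load_surrogate(path)
  p1 <- predict_surrogate(fit, sp$test)
  p2 <- predict_surrogate(back, sp$test)
  expect_equal(p1$y, p2$y, tolerance = 1e-12)
})

test_that("test-set permutation cannot leak into training", {
  df <- linear_toy(120)
  sp <- toy_splits(df)
  cfg <- train_config(max_epochs = 40, patience = 20, seed = 7)
  f1 <- fit_surrogate(sp, inputs = c("x", "z"), targets = "y",
                      hidden = c(8), config = cfg)
  sp$test <- sp$test[sample(nrow(sp$test)), ]
  f2 <- fit_surrogate(sp, inputs = c("x", "z"), targets = "y",
                      hidden = c(8), config = cfg)
  expect_identical(f1$net$W, f2$net$W)
})
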