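#' Z-score standardizer
#'
#' Per-column mean/sd computed on the training split only; transform then
#' inverse-transform is the identity to round-off.
#'
#' @param X Numeric matrix or data frame.
#' @return An object of class `standardizer`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    bad <- colnames(X)[!is.finite(sd) | sd <= 0]
    stop("standardizer: zero/undefined spread in column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sd), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param s A `standardizer`.
#' @export
std_transform <- function(s, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, s$mean, "-"), 2, s$sd, "/")
}

#' @rdname fit_standardizer
#' @param Z Standardized matrix.
#' @export
std_inverse <- function(s, Z) {
  sweep(sweep(as.matrix(Z), 2, s$sd, "*"), 2, s$mean, "+")
}

#' Multi-output feed-forward surrogate network
#'
#' A multilayer perceptron `a^l = f(W^l a^(l-1) + b^l)` with rectifier
#' hidden activations and a linear output layer, He-initialised. Dropout
#' (inverted, training only) is applied after the first two hidden layers;
#' L2 weight decay acts on weights, not biases.
#'
#' @param n_inputs Input width.
#' @param hidden Hidden-layer widths (default 64, 32, 16).
#' @param n_outputs Output width (default 3 mechanical targets).
#' @param dropout Dropout rate after hidden layers 1-2.
#' @param weight_decay L2 coefficient.
#' @param seed Seed for the He initialisation.
#' @return An object of class `surrogate_net`.
#' @export
surrogate_net <- function(n_inputs, hidden = c(64, 32, 16), n_outputs = 3,
                          dropout = 0.10, weight_decay = 1e-4, seed = 2025) {
  set.seed(seed)
  sizes <- c(n_inputs, hidden, n_outputs)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(
    list(W = W, b = b, sizes = sizes, dropout = dropout,
         weight_decay = weight_decay,
         dropout_layers = seq_len(min(2, length(hidden)))),
    class = "surrogate_net"
  )
}

#' Training protocol configuration
#'
#' Adam with the stated moment parameters, minibatches, Huber loss (delta 1,
#' switchable to mean-squared error), early stopping on validation MAE with
#' best-checkpoint restore.
#'
#' @param lr Initial step size.
#' @param beta1,beta2,eps Adam moment decays and stabiliser.
#' @param batch_size Minibatch size.
#' @param loss `"huber"` or `"mse"`.
#' @param huber_delta Huber transition point (on the standardized target
#'   scale).
#' @param patience Early-stop patience, epochs.
#' @param max_epochs Epoch cap.
#' @param seed Seed for shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         batch_size = 64, loss = c("huber", "mse"),
                         huber_delta = 1.0, patience = 80, max_epochs = 2000,
                         seed = 2025) {
  loss <- match.arg(loss)
  stopifnot(lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            patience < max_epochs)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 batch_size = batch_size, loss = loss,
                 huber_delta = huber_delta, patience = patience,
                 max_epochs = max_epochs, seed = seed),
            class = "train_config")
}

relu <- function(x) pmax(x, 0)

# forward pass; when training=TRUE applies inverted dropout and returns caches
net_forward <- function(net, X, training = FALSE) {
  L <- length(net$W)
  A <- list(X)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      Z <- relu(Z)
      if (training && net$dropout > 0 && l %in% net$dropout_layers) {
        m <- matrix(stats::runif(length(Z)) >= net$dropout, nrow(Z), ncol(Z))
        Z <- Z * m / (1 - net$dropout)
        masks[[l]] <- m
      }
    }
    A[[l + 1]] <- Z
  }
  list(A = A, masks = masks)
}

loss_grad <- function(R, config) {
  n <- nrow(R)
  if (config$loss == "mse") {
    list(loss = sum(R^2) / n, grad = 2 * R / n)
  } else {
    d <- config$huber_delta
    absR <- abs(R)
    q <- absR <= d
    list(loss = sum(ifelse(q, 0.5 * R^2, d * (absR - 0.5 * d))) / n,
         grad = ifelse(q, R, d * sign(R)) / n)
  }
}

# backpropagation: gradients of the (loss + L2) objective for a minibatch
net_backward <- function(net, X, Y, config, training = FALSE) {
  fw <- net_forward(net, X, training = training)
  L <- length(net$W)
  lg <- loss_grad(fw$A[[L + 1]] - Y, config)
  G <- lg$grad
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], G) + net$weight_decay * net$W[[l]]
    gb[[l]] <- colSums(G)
    if (l > 1) {
      G <- G %*% t(net$W[[l]])
      G <- G * (fw$A[[l]] > 0)
      if (!is.null(fw$masks[[l - 1]])) {
        G <- G * fw$masks[[l - 1]] / (1 - net$dropout)
      }
    }
  }
  list(W = gW, b = gb, loss = lg$loss)
}

# one Adam step over a minibatch; state carries moments and step counter
net_step <- function(net, X, Y, config, state) {
  bk <- net_backward(net, X, Y, config, training = TRUE)
  L <- length(net$W)
  state$t <- state$t + 1
  for (l in seq_len(L)) {
    for (par in c("W", "b")) {
      g <- bk[[par]][[l]]
      state$m[[par]][[l]] <- config$beta1 * state$m[[par]][[l]] +
        (1 - config$beta1) * g
      state$v[[par]][[l]] <- config$beta2 * state$v[[par]][[l]] +
        (1 - config$beta2) * g^2
      mhat <- state$m[[par]][[l]] / (1 - config$beta1^state$t)
      vhat <- state$v[[par]][[l]] / (1 - config$beta2^state$t)
      net[[par]][[l]] <- net[[par]][[l]] -
        config$lr * mhat / (sqrt(vhat) + config$eps)
    }
  }
  list(net = net, state = state, loss = bk$loss)
}

#' Train the surrogate on standardized data
#'
#' Minibatch Adam on the configured loss with early stopping on validation
#' MAE (standardized scale, averaged over outputs); the best-validation
#' checkpoint is restored. Deterministic under the config seed.
#'
#' @param net A [surrogate_net()].
#' @param config A [train_config()].
#' @param X_train,Y_train Standardized training matrices.
#' @param X_val,Y_val Standardized validation matrices.
#' @return List with `net` (best checkpoint), `history` tibble
#'   (`epoch`, `train_loss`, `val_mae`), `best_epoch`, `stopped_epoch`.
#' @export
train_net <- function(net, config, X_train, Y_train, X_val, Y_val) {
  set.seed(config$seed)
  n <- nrow(X_train)
  L <- length(net$W)
  zeros_like <- function(par) lapply(net[[par]], function(x) x * 0)
  state <- list(t = 0,
                m = list(W = zeros_like("W"), b = zeros_like("b")),
                v = list(W = zeros_like("W"), b = zeros_like("b")))
  best <- list(mae = Inf, net = net, epoch = 0)
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_mae <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      st <- net_step(net, X_train[idx, , drop = FALSE],
                     Y_train[idx, , drop = FALSE], config, state)
      net <- st$net; state <- st$state
      ep_loss <- ep_loss + st$loss * length(idx)
    }
    ep_loss <- ep_loss / n
    if (!is.finite(ep_loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
    pred_val <- net_forward(net, X_val)$A[[L + 1]]
    val_mae <- mean(abs(pred_val - Y_val))
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, ep_loss)
    hist_mae <- c(hist_mae, val_mae)
    if (val_mae < best$mae) {
      best <- list(mae = val_mae, net = net, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  list(net = best$net,
       history = tibble::tibble(epoch = hist_epoch, train_loss = hist_loss,
                                val_mae = hist_mae),
       best_epoch = best$epoch, stopped_epoch = epoch)
}

#' Stratified train/validation/test split
#'
#' Splits the dataset 70/15/15 (configurable) with stratification over the
#' load level and the plate-thickness level; within each stratum row counts
#' follow the target fractions by largest remainder, so per-stratum
#' proportions match the global ones within one row. Strata smaller than 3
#' rows are merged into a single pooled stratum with a warning.
#'
#' @param dataset A tibble (e.g. QC-filtered `fe_dataset`).
#' @param fractions Length-3 split fractions summing to 1.
#' @param seed Integer seed.
#' @param strata_cols Columns defining the strata.
#' @return Named list of tibbles `train`, `val`, `test`.
#' @export
split_stratified <- function(dataset, fractions = c(0.70, 0.15, 0.15),
                             seed = 2025,
                             strata_cols = intersect(c("P", "t_plate"),
                                                     names(dataset))) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  dataset <- tibble::as_tibble(dataset)
  strat <- if (length(strata_cols) > 0) {
    interaction(dataset[strata_cols], drop = TRUE)
  } else factor(rep(1, nrow(dataset)))
  tab <- table(strat)
  if (any(tab < 3)) {
    warning("strata smaller than 3 rows merged into one pooled stratum")
    small <- names(tab)[tab < 3]
    strat <- as.character(strat)
    strat[strat %in% small] <- ".pooled"
    strat <- factor(strat)
  }
  set.seed(seed)
  assign <- integer(nrow(dataset))
  for (s in levels(strat)) {
    idx <- sample(which(strat == s))
    n <- length(idx)
    base <- floor(fractions * n)
    rem <- fractions * n - base
    extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
    counts <- base
    counts[extra] <- counts[extra] + 1
    lab <- rep(1:3, times = counts)
    assign[idx] <- lab
  }
  list(train = dataset[assign == 1, ],
       val = dataset[assign == 2, ],
       test = dataset[assign == 3, ])
}

#' Fit the FE surrogate to a dataset
#'
#' End-to-end convenience: standardizes inputs and targets on the training
#' split, trains the network, and returns a fitted object usable with
#' [predict_surrogate()], [evaluate_surrogate()] and
#' [fit_residual_model()].
#'
#' @param splits List with `train`, `val` (and usually `test`) tibbles, as
#'   returned by [split_stratified()].
#' @param inputs Input column names.
#' @param targets Target column names.
#' @param hidden Hidden widths.
#' @param dropout,weight_decay Regularisation settings.
#' @param config A [train_config()].
#' @return An object of class `surrogate_fit`.
#' @export
fit_surrogate <- function(splits,
                          inputs = c("d", "a", "t_lat", "t_plate", "P"),
                          targets = c("sigma_vm_max", "delta_max",
                                      "sigma_screw_max"),
                          hidden = c(64, 32, 16), dropout = 0.10,
                          weight_decay = 1e-4, config = train_config()) {
  tr <- splits$train; va <- splits$val
  # inputs with no spread in the training split carry no information and
  # cannot be z-scored; they are dropped from the retained input set
  spread <- vapply(tr[inputs], stats::sd, numeric(1))
  if (any(spread == 0)) {
    message("dropping constant input(s): ",
            paste(inputs[spread == 0], collapse = ", "))
    inputs <- inputs[spread > 0]
  }
  xs <- fit_standardizer(tr[inputs])
  ys <- fit_standardizer(tr[targets])
  net <- surrogate_net(length(inputs), hidden = hidden,
                       n_outputs = length(targets), dropout = dropout,
                       weight_decay = weight_decay, seed = config$seed)
  fitted <- train_net(net, config,
                      std_transform(xs, tr[inputs]),
                      std_transform(ys, tr[targets]),
                      std_transform(xs, va[inputs]),
                      std_transform(ys, va[targets]))
  structure(
    list(net = fitted$net, x_std = xs, y_std = ys, inputs = inputs,
         targets = targets, history = fitted$history,
         best_epoch = fitted$best_epoch, config = config,
         train_ranges = lapply(tr[inputs], range)),
    class = "surrogate_fit"
  )
}

#' @exportS3Method base::print
print.surrogate_fit <- function(x, ...) {
  cat(sprintf(
    "<surrogate_fit> %s -> %s; layers %s; best epoch %d (val MAE %.4g)\n",
    paste(x$inputs, collapse = ","), paste(x$targets, collapse = ","),
    paste(x$net$sizes, collapse = "-"), x$best_epoch,
    min(x$history$val_mae)))
  invisible(x)
}

#' Predict mechanical targets with a fitted surrogate
#'
#' Deterministic forward pass (dropout off) on native-unit inputs; targets
#' are returned in native units. Inputs outside the training hull are
#' allowed but counted in the `extrapolated` attribute.
#'
#' @param fit A `surrogate_fit`.
#' @param newdata Tibble/data frame with the fit's input columns.
#' @return Tibble of predictions (one column per target).
#' @export
predict_surrogate <- function(fit, newdata) {
  newdata <- tibble::as_tibble(newdata)
  if (!all(fit$inputs %in% names(newdata))) {
    stop("newdata lacks input column(s): ",
         paste(setdiff(fit$inputs, names(newdata)), collapse = ", "))
  }
  X <- std_transform(fit$x_std, newdata[fit$inputs])
  n_out <- 0
  for (v in fit$inputs) {
    r <- fit$train_ranges[[v]]
    n_out <- n_out + sum(newdata[[v]] < r[1] | newdata[[v]] > r[2])
  }
  Z <- net_forward(fit$net, X)$A[[length(fit$net$W) + 1]]
  out <- tibble::as_tibble(as.data.frame(std_inverse(fit$y_std, Z)))
  names(out) <- fit$targets
  attr(out, "extrapolated") <- n_out
  out
}

#' Evaluate a surrogate on a data split
#'
#' Per-output MAE (native units and percent of the split's target mean),
#' RMSE and R-squared.
#'
#' @param fit A `surrogate_fit`.
#' @param split Tibble with input and target columns.
#' @return An `eval_report` tibble: columns `target`, `mae`, `mae_pct`,
#'   `rmse`, `r2`; attribute `n`.
#' @export
evaluate_surrogate <- function(fit, split) {
  if (nrow(split) == 0) stop("empty evaluation split")
  pred <- predict_surrogate(fit, split)
  eval_report(as.matrix(split[fit$targets]), as.matrix(pred), fit$targets)
}

eval_report <- function(Y, Yhat, targets) {
  res <- Yhat - Y
  out <- tibble::tibble(
    target = targets,
    mae = unname(colMeans(abs(res))),
    mae_pct = unname(100 * colMeans(abs(res)) / colMeans(abs(Y))),
    rmse = unname(sqrt(colMeans(res^2))),
    r2 = unname(1 - colSums(res^2) /
                  colSums(sweep(Y, 2, colMeans(Y), "-")^2))
  )
  attr(out, "n") <- nrow(Y)
  structure(out, class = c("eval_report", class(out)))
}

#' K-fold cross-validation of the surrogate
#'
#' Disjoint seeded folds; each fold is held out in turn while the rest is
#' re-split into train/validation for early stopping. Reports per-fold and
#' fold-averaged metrics.
#'
#' @param dataset QC-filtered dataset.
#' @param k Number of folds (>= 2).
#' @param inputs,targets Column names.
#' @param config A [train_config()].
#' @param hidden,dropout,weight_decay Architecture settings.
#' @param seed Fold-assignment seed.
#' @return List with `folds` (per-fold `eval_report`s), `mean` (fold-averaged
#'   tibble), `sd`.
#' @export
crossvalidate_surrogate <- function(dataset, k = 5,
                                    inputs = c("d", "a", "t_lat", "t_plate",
                                               "P"),
                                    targets = c("sigma_vm_max", "delta_max",
                                                "sigma_screw_max"),
                                    config = train_config(),
                                    hidden = c(64, 32, 16), dropout = 0.10,
                                    weight_decay = 1e-4, seed = 2025) {
  if (k < 2) stop("k must be >= 2")
  dataset <- tibble::as_tibble(dataset)
  n <- nrow(dataset)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- dataset[fold == f, ]
    rest <- dataset[fold != f, ]
    # carve a validation slice out of the training folds for early stopping
    idx <- seq_len(nrow(rest))
    set.seed(seed + f)
    val_idx <- sample(idx, size = max(1, round(0.15 * nrow(rest))))
    splits <- list(train = rest[-val_idx, ], val = rest[val_idx, ])
    fit <- fit_surrogate(splits, inputs = inputs, targets = targets,
                         hidden = hidden, dropout = dropout,
                         weight_decay = weight_decay, config = config)
    reports[[f]] <- evaluate_surrogate(fit, hold)
  }
  all <- dplyr::bind_rows(reports, .id = "fold")
  agg <- dplyr::summarise(
    dplyr::group_by(all, .data$target),
    dplyr::across(c("mae", "mae_pct", "rmse", "r2"), mean),
    .groups = "drop")
  sds <- dplyr::summarise(
    dplyr::group_by(all, .data$target),
    dplyr::across(c("mae", "mae_pct", "rmse", "r2"), stats::sd),
    .groups = "drop")
  list(folds = reports, mean = agg, sd = sds)
}

#' Gaussian residual model from the untouched test split
#'
#' Zero-mean Gaussian per output with sigma equal to the test-set RMSE,
#' floored at a machine-scaled epsilon so downstream sampling never
#' degenerates.
#'
#' @param fit A `surrogate_fit`.
#' @param test Test tibble (must not have been used in training).
#' @return An object of class `residual_model`: named sigma vector.
#' @export
fit_residual_model <- function(fit, test) {
  rep <- evaluate_surrogate(fit, test)
  floor_ <- vapply(fit$targets,
                   function(t) max(1e-12, 1e-9 * abs(fit$y_std$mean[[t]])),
                   numeric(1))
  sigma <- pmax(rep$rmse, floor_)
  if (any(rep$rmse <= 0)) {
    warning("zero test residuals: sigma floored at machine-scaled epsilon")
  }
  structure(list(sigma = stats::setNames(sigma, fit$targets),
                 n_test = attr(rep, "n")),
            class = "residual_model")
}

#' Quadratic response-surface baseline
#'
#' Least-squares polynomial fit (total degree `degree`, raw terms) on
#' standardized inputs, one linear model per target; evaluated with the
#' same report contract as the network.
#'
#' @param splits List with `train` and `test` tibbles.
#' @param degree Polynomial total degree.
#' @param inputs,targets Column names.
#' @return List with `models` (per-target `lm`), `report` (`eval_report` on
#'   the test split), `predict(newdata)` closure.
#' @export
poly_baseline <- function(splits, degree = 2,
                          inputs = c("d", "a", "t_lat", "t_plate", "P"),
                          targets = c("sigma_vm_max", "delta_max",
                                      "sigma_screw_max")) {
  tr <- splits$train
  xs <- fit_standardizer(tr[inputs])
  basis <- function(data) {
    Z <- std_transform(xs, data[inputs])
    as.data.frame(do.call(
      stats::polym,
      c(lapply(seq_len(ncol(Z)), function(j) Z[, j]),
        list(degree = degree, raw = TRUE))))
  }
  n_terms <- ncol(basis(tr[1, , drop = FALSE]))
  if (nrow(tr) < n_terms + 1) {
    stop("dataset too small for a degree-", degree, " response surface (",
         n_terms, " terms)")
  }
  Btr <- basis(tr)
  models <- lapply(targets, function(tg) {
    stats::lm(y ~ ., data = cbind(y = tr[[tg]], Btr))
  })
  names(models) <- targets
  predict_fn <- function(newdata) {
    B <- basis(tibble::as_tibble(newdata))
    out <- lapply(models, function(m) unname(stats::predict(m, newdata = B)))
    tibble::as_tibble(out)
  }
  report <- if (!is.null(splits$test) && nrow(splits$test) > 0) {
    pred <- predict_fn(splits$test)
    eval_report(as.matrix(splits$test[targets]), as.matrix(pred), targets)
  } else NULL
  list(models = models, report = report, predict = predict_fn,
       degree = degree)
}

#' Save/load a surrogate checkpoint as portable JSON
#'
#' Single JSON file: header (layer sizes, input/target names, standardizer
#' statistics, config) plus flat weight arrays.
#'
#' @param fit A `surrogate_fit`.
#' @param path Output path.
#' @return The loader returns a `surrogate_fit` (without history).
#' @export
save_surrogate <- function(fit, path) {
  obj <- list(
    sizes = fit$net$sizes, dropout = fit$net$dropout,
    weight_decay = fit$net$weight_decay,
    dropout_layers = fit$net$dropout_layers,
    inputs = fit$inputs, targets = fit$targets,
    x_mean = fit$x_std$mean, x_sd = fit$x_std$sd,
    y_mean = fit$y_std$mean, y_sd = fit$y_std$sd,
    train_ranges = fit$train_ranges,
    W = lapply(fit$net$W, as.vector), b = fit$net$b
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- obj$sizes
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l) {
    matrix(obj$W[[l]], sizes[l], sizes[l + 1])
  })
  net <- structure(
    list(W = W, b = lapply(obj$b, as.numeric), sizes = sizes,
         dropout = obj$dropout, weight_decay = obj$weight_decay,
         dropout_layers = obj$dropout_layers),
    class = "surrogate_net")
  structure(
    list(net = net,
         x_std = structure(list(mean = unlist(obj$x_mean),
                                sd = unlist(obj$x_sd)),
                           class = "standardizer"),
         y_std = structure(list(mean = unlist(obj$y_mean),
                                sd = unlist(obj$y_sd)),
                           class = "standardizer"),
         inputs = obj$inputs, targets = obj$targets,
         history = NULL, best_epoch = NA,
         config = NULL,
         train_ranges = lapply(obj$train_ranges, as.numeric)),
    class = "surrogate_fit")
}

#' Summarise a fitted surrogate in one row
#'
#' @param x A `surrogate_fit`.
#' @param ... Unused.
#' @return A one-row tibble: layer layout, parameter count, best epoch,
#'   best validation MAE (standardized scale).
#' @export
glance.surrogate_fit <- function(x, ...) {
  n_par <- sum(vapply(x$net$W, length, numeric(1))) +
    sum(vapply(x$net$b, length, numeric(1)))
  tibble::tibble(
    layers = paste(x$net$sizes, collapse = "-"),
    n_parameters = n_par,
    best_epoch = x$best_epoch,
    best_val_mae = if (is.null(x$history)) NA_real_ else min(x$history$val_mae)
  )
}

#' Plot a surrogate training history
#'
#' Training loss and validation MAE against the epoch, with the restored
#' best-validation checkpoint marked.
#'
#' @param object A `surrogate_fit` (with history).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surrogate_fit <- function(object, ...) {
  if (is.null(object$history)) stop("fit carries no training history")
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_mae"),
                           names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
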