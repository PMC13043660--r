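#' Hyperparameter search grids
#'
#' Returns the full discrete hyperparameter grid for a model kind as a list
#' of configuration lists. Grids: ridge / elastic net penalty alpha in
#' \{1e-4, 1e-3, 1e-2, 0.1, 1, 10, 100, 1000\}, elastic-net L1 ratio in
#' \{0.1, 0.3, 0.5, 0.7, 0.9\}; random forest (500 trees) depth in
#' \{2,4,6,8,12,unlimited\}, feature fraction per split \{1/3, 2/3, 1\},
#' sample fraction \{0.632, 0.8, 1\}; gradient boosted trees n in
#' \{50,100,250\}, learning rate \{0.01,0.05,0.1\}, depth \{2,4,6\},
#' feature fraction \{1/3,2/3,1\}; multilayer perceptron layers \{1,2,3\},
#' width \{20,50,100,200\}, batch \{1,32,64\}, learning rate
#' \{1e-4,5e-3,1e-3\}, L1/L2 \{0,1e-4,1e-6\}.
#'
#' @param model_kind one of "ols", "ridge", "en", "rf", "gbt", "ann", "ct".
#' @return list of configuration lists (length 1 for "ols" and "ct").
#' @export
hyper_grid <- function(model_kind) {
  alphas <- c(1e-4, 1e-3, 1e-2, 0.1, 1, 10, 100, 1000)
  cross <- function(...) {
    df <- expand.grid(..., KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  switch(model_kind,
    ols = list(list()),
    ct = list(list()),
    ridge = cross(alpha = alphas),
    en = cross(alpha = alphas, l1_ratio = c(0.1, 0.3, 0.5, 0.7, 0.9)),
    rf = cross(max_depth = c(2, 4, 6, 8, 12, 0),  # 0 = unlimited
               mtry_frac = c(1 / 3, 2 / 3, 1),
               sample_frac = c(0.632, 0.8, 1)),
    gbt = cross(n_trees = c(50, 100, 250), learning_rate = c(0.01, 0.05, 0.1),
                max_depth = c(2, 4, 6), colsample = c(1 / 3, 2 / 3, 1)),
    ann = cross(layers = c(1, 2, 3), width = c(20, 50, 100, 200),
                batch = c(1, 32, 64), learning_rate = c(1e-4, 5e-3, 1e-3),
                l1 = c(0, 1e-4, 1e-6), l2 = c(0, 1e-4, 1e-6)),
    stop("unknown model kind: ", model_kind, call. = FALSE))
}

#' Default configuration of each model kind
#'
#' A fixed configuration drawn from \code{\link{hyper_grid}}, used when
#' hyperparameter search is disabled.
#' @param model_kind model kind.
#' @return configuration list.
#' @export
default_config <- function(model_kind) {
  switch(model_kind,
    ols = list(), ct = list(),
    ridge = list(alpha = 1),
    en = list(alpha = 0.01, l1_ratio = 0.5),
    rf = list(max_depth = 0, mtry_frac = 1 / 3, sample_frac = 0.8),
    gbt = list(n_trees = 100, learning_rate = 0.1, max_depth = 4,
               colsample = 2 / 3),
    ann = list(layers = 1, width = 20, batch = 32, learning_rate = 5e-3,
               l1 = 0, l2 = 1e-4),
    stop("unknown model kind: ", model_kind, call. = FALSE))
}

#' Fit a supervised regressor
#'
#' Trains one of the benchmark model kinds on a numeric feature matrix.
#' All learners are deterministic given \code{seed}, tolerate p > n, and
#' never see test targets. The "ct" kind carries a clumping+thresholding
#' score model and bypasses fitting entirely.
#'
#' @param model_kind one of "ols", "ridge", "en", "rf", "gbt", "ann", "ct".
#' @param config configuration list (see \code{\link{hyper_grid}}); for
#'   "ct", must contain \code{ct_model}.
#' @param X numeric feature matrix (individuals x features).
#' @param y numeric target vector.
#' @param seed integer seed for any stochastic learner.
#' @return object of class \code{ml_model}.
#' @export
fit_model <- function(model_kind, config, X, y, seed = 1L) {
  X <- as.matrix(X)
  if (model_kind != "ct") {
    if (!nrow(X) || !ncol(X)) stop("empty feature matrix", call. = FALSE)
    if (any(!is.finite(X)) || any(!is.finite(y)))
      stop("non-finite features or targets", call. = FALSE)
  }
  fit <- switch(model_kind,
    ct = config$ct_model,
    ols = {
      Xd <- cbind(1, X)
      co <- qr.coef(qr(Xd), y)
      co[is.na(co)] <- 0
      co
    },
    ridge = .fit_ridge(X, y, config$alpha),
    en = {
      withr::with_seed(seed,
        glmnet::glmnet(.pad2(X), y, alpha = config$l1_ratio,
                       lambda = config$alpha, standardize = FALSE))
    },
    rf = ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = 500,
      max.depth = config$max_depth,
      mtry = max(1L, ceiling(config$mtry_frac * ncol(X))),
      sample.fraction = config$sample_frac, replace = TRUE,
      seed = seed, num.threads = 1),
    gbt = xgboost::xgb.train(
      params = list(eta = config$learning_rate, max_depth = config$max_depth,
                    colsample_bytree = config$colsample,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = config$n_trees, verbose = 0),
    ann = .fit_mlp(X, y, config, seed),
    stop("unknown model kind: ", model_kind, call. = FALSE))
  structure(list(kind = model_kind, fit = fit, config = config,
                 x_names = colnames(X), y_mean = mean(y)),
            class = "ml_model")
}

#' @export
predict.ml_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  switch(object$kind,
    ct = stop("ct models are scored with ct_score(), not predict()",
              call. = FALSE),
    ols = as.numeric(cbind(1, X) %*% object$fit),
    ridge = as.numeric(cbind(1, X) %*% object$fit),
    en = as.numeric(stats::predict(object$fit, newx = .pad2(X))),
    rf = stats::predict(object$fit, data = as.data.frame(X),
                        num.threads = 1)$predictions,
    gbt = stats::predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    ann = .predict_mlp(object$fit, X))
}

#' Fit a model and predict a test set
#'
#' @inheritParams fit_model
#' @param train,test lists with elements \code{X} (matrix) and, for train,
#'   \code{y}.
#' @return numeric vector of test-set predictions.
#' @export
fit_predict <- function(model_kind, config, train, test, seed = 1L) {
  m <- fit_model(model_kind, config, train$X, train$y, seed = seed)
  predict(m, test$X)
}

# closed-form ridge matching the sklearn objective ||y-Xb||^2 + alpha||b||^2,
# intercept unpenalized (fit on centered data); handles p > n
.fit_ridge <- function(X, y, alpha) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-")
  A <- crossprod(Xc) + diag(alpha, ncol(X))
  b <- solve(A, crossprod(Xc, y - ym))
  c(ym - sum(xm * b), b)
}

# glmnet refuses single-column x; pad with an all-zero dummy
.pad2 <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, .dummy_zero_col = 0)
}

# ---- minimal multilayer perceptron (Adam, L1/L2 penalty, early stopping on
# a 10% validation split, ReLU hidden units, linear output) ----

.fit_mlp <- function(X, y, config, seed, max_epochs = 200L, patience = 10L) {
  withr::with_seed(seed, {
    n <- nrow(X)
    n_val <- max(1L, floor(0.1 * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (!length(tr_idx)) { tr_idx <- seq_len(n); val_idx <- seq_len(n) }
    sizes <- c(ncol(X), rep(config$width, config$layers), 1L)
    W <- lapply(seq_len(length(sizes) - 1), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(length(sizes) - 1), function(l) rep(0, sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
    lr <- config$learning_rate
    best <- list(W = W, b = b, loss = Inf); wait <- 0L
    batch <- min(config$batch, length(tr_idx))

    forward <- function(W, b, Xb) {
      acts <- list(Xb)
      L <- length(W)
      for (l in seq_len(L)) {
        z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
        acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      acts
    }

    for (epoch in seq_len(max_epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1, length(ord), by = batch)) {
        idx <- ord[start:min(start + batch - 1, length(ord))]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        acts <- forward(W, b, Xb)
        L <- length(W)
        delta <- (acts[[L + 1]] - yb) * (2 / length(idx))
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], delta) +
            config$l2 * 2 * W[[l]] + config$l1 * sign(W[[l]])
          gb <- colSums(delta)
          t_step <- t_step + 1
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^t_step); vhW <- vW[[l]] / (1 - beta2^t_step)
          mhb <- mb[[l]] / (1 - beta1^t_step); vhb <- vb[[l]] / (1 - beta2^t_step)
          if (l > 1) delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
          W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      val_pred <- forward(W, b, X[val_idx, , drop = FALSE])[[length(W) + 1]]
      val_loss <- mean((val_pred - y[val_idx])^2)
      if (is.finite(val_loss) && val_loss < best$loss - 1e-8) {
        best <- list(W = W, b = b, loss = val_loss); wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    list(W = best$W, b = best$b)
  })
}

.predict_mlp <- function(fit, X) {
  a <- X
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  as.numeric(a)
}
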