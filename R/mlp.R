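# Multilayer-perceptron regressor mapping the six thermal channels to
# (flow rate, vessel depth). Dense layers with batch normalization, ReLU
# and dropout, trained with Adam on standardized inputs/targets. Written
# in plain matrix algebra so training is fully deterministic under a seed.

#' Regressor architecture specification
#'
#' @param input Input width (number of features; 6 for the full
#'   temperature mode, 4 for bridge mode, 3 for the single-layer ablation).
#' @param hidden Hidden layer widths (default 128, 128, 64).
#' @param output Output width (2: flow mm/s and depth mm).
#' @param dropout Dropout rate in [0, 1) (default 0.10), active only
#'   during training; evaluation runs deterministically.
#' @param batchnorm Apply batch normalization after each hidden linear
#'   layer (default TRUE).
#' @param dropout_layers Where dropout is applied: `"last"` (default; on
#'   the final hidden activation, so the deterministic evaluation network
#'   is exactly the dropout-ensemble mean because the output layer is
#'   linear) or `"all"` (after every hidden activation).
#' @return An object of class `regressor_spec`.
#' @export
regressor_spec <- function(input = 6, hidden = c(128, 128, 64), output = 2,
                           dropout = 0.10, batchnorm = TRUE,
                           dropout_layers = c("last", "all")) {
  dropout_layers <- match.arg(dropout_layers)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  if (input < 1 || output < 1 || any(hidden < 1))
    stop("layer widths must be positive", call. = FALSE)
  structure(list(input = as.integer(input), hidden = as.integer(hidden),
                 output = as.integer(output), dropout = dropout,
                 batchnorm = isTRUE(batchnorm),
                 dropout_layers = dropout_layers),
            class = "regressor_spec")
}

#' Training configuration
#'
#' @param epochs Training epochs (default 300).
#' @param batch_size Minibatch size (default 64).
#' @param lr Initial Adam learning rate (default 2e-3). The rate is
#'   stepped down by a factor of 10 after 60% and again after 85% of the
#'   epochs, which settles the minibatch/dropout noise at the end of
#'   training.
#' @param seed Seed fixing initialization, shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 300, batch_size = 64, lr = 2e-3,
                            seed = 0L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "training_config")
}

relu <- function(x) pmax(x, 0)

init_params <- function(spec) {
  widths <- c(spec$input, spec$hidden, spec$output)
  L <- length(widths) - 1L
  params <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]
    params[[l]] <- list(
      W = matrix(rnorm(fan_in * widths[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, widths[l + 1]),
      b = rep(0, widths[l + 1]))
    if (spec$batchnorm && l < L) {
      params[[l]]$gamma <- rep(1, widths[l + 1])
      params[[l]]$beta <- rep(0, widths[l + 1])
      params[[l]]$run_mean <- rep(0, widths[l + 1])
      params[[l]]$run_var <- rep(1, widths[l + 1])
    }
  }
  params
}

# forward pass; training = TRUE uses batch statistics and dropout and
# returns a cache for backprop (and updates running stats by reference
# convention: the updated params are returned in the cache).
mlp_forward <- function(params, X, spec, training = FALSE, eps = 1e-5,
                        momentum = 0.9) {
  L <- length(params)
  A <- X
  cache <- list()
  for (l in seq_len(L - 1L)) {
    p <- params[[l]]
    Z <- sweep(A %*% p$W, 2, p$b, `+`)
    if (spec$batchnorm) {
      if (training) {
        mu <- colMeans(Z)
        va <- colMeans(sweep(Z, 2, mu, `-`)^2)
        params[[l]]$run_mean <- momentum * p$run_mean + (1 - momentum) * mu
        params[[l]]$run_var <- momentum * p$run_var + (1 - momentum) * va
      } else {
        mu <- p$run_mean
        va <- p$run_var
      }
      istd <- 1 / sqrt(va + eps)
      Zhat <- sweep(sweep(Z, 2, mu, `-`), 2, istd, `*`)
      Y <- sweep(sweep(Zhat, 2, p$gamma, `*`), 2, p$beta, `+`)
    } else {
      Zhat <- NULL; istd <- NULL; Y <- Z
    }
    H <- relu(Y)
    drop_here <- spec$dropout > 0 &&
      (identical(spec$dropout_layers, "all") || l == L - 1L)
    if (training && drop_here) {
      mask <- matrix(runif(length(H)) >= spec$dropout, nrow(H), ncol(H)) /
        (1 - spec$dropout)
      H <- H * mask
    } else mask <- NULL
    cache[[l]] <- list(A = A, Z = Z, Zhat = Zhat, istd = istd, Y = Y,
                       mask = mask)
    A <- H
  }
  p <- params[[L]]
  out <- sweep(A %*% p$W, 2, p$b, `+`)
  cache[[L]] <- list(A = A)
  list(out = out, cache = cache, params = params)
}

mlp_backward <- function(params, spec, cache, dout) {
  L <- length(params)
  grads <- vector("list", L)
  A <- cache[[L]]$A
  grads[[L]] <- list(W = crossprod(A, dout), b = colSums(dout))
  dA <- dout %*% t(params[[L]]$W)
  for (l in rev(seq_len(L - 1L))) {
    cc <- cache[[l]]
    dH <- dA
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dY <- dH * (cc$Y > 0)
    if (spec$batchnorm) {
      m <- nrow(dY)
      dgamma <- colSums(dY * cc$Zhat)
      dbeta <- colSums(dY)
      dZhat <- sweep(dY, 2, params[[l]]$gamma, `*`)
      s1 <- colSums(dZhat)
      s2 <- colSums(dZhat * cc$Zhat)
      dZ <- sweep(m * dZhat, 2, s1, `-`)
      dZ <- dZ - sweep(cc$Zhat, 2, s2, `*`)
      dZ <- sweep(dZ, 2, cc$istd / m, `*`)
      grads[[l]] <- list(W = crossprod(cc$A, dZ), b = colSums(dZ),
                         gamma = dgamma, beta = dbeta)
      dA <- dZ %*% t(params[[l]]$W)
    } else {
      grads[[l]] <- list(W = crossprod(cc$A, dY), b = colSums(dY))
      dA <- dY %*% t(params[[l]]$W)
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    keep <- intersect(names(p), c("W", "b", "gamma", "beta"))
    st <- lapply(p[keep], function(x) list(m = x * 0, v = x * 0))
    st
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    for (nm in names(state[[l]])) {
      g <- grads[[l]][[nm]]
      st <- state[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[l]][[nm]] <- params[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

dataset_matrices <- function(data) {
  if (inherits(data, "labeled_dataset")) {
    fn <- attr(data, "feature_names")
    X <- as.matrix(as.data.frame(data)[, fn, drop = FALSE])
    Y <- cbind(flow = data$f_set_mm_s, depth = data$d_set_mm)
    list(X = X, Y = Y)
  } else stop("expected a labeled_dataset", call. = FALSE)
}

#' Fit the flow/depth inversion regressor
#'
#' Trains the multilayer perceptron on standardized features and targets
#' (statistics computed from the training data only) with minibatch Adam
#' and mean-squared-error loss over both outputs.
#'
#' @param train A `labeled_dataset` (or list with matrices `X` and `Y`).
#' @param spec A [regressor_spec()]; its input width is adjusted to the
#'   data if it disagrees.
#' @param cfg A [training_config()].
#' @return An object of class `tsm_mlp` holding the trained parameters,
#'   standardization statistics, the loss trace and the configuration.
#' @export
fit_regressor <- function(train, spec = regressor_spec(),
                          cfg = training_config()) {
  dm <- if (is.list(train) && !inherits(train, "labeled_dataset") &&
            all(c("X", "Y") %in% names(train))) train
  else dataset_matrices(train)
  X <- dm$X; Y <- dm$Y
  if (nrow(X) < 1) stop("empty training set", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite training values", call. = FALSE)
  if (spec$input != ncol(X))
    spec <- regressor_spec(ncol(X), spec$hidden, spec$output, spec$dropout,
                           spec$batchnorm, spec$dropout_layers)

  x_mu <- colMeans(X); x_sd <- apply(X, 2, sd)
  x_sd[!is.finite(x_sd) | x_sd < 1e-12] <- 1
  y_mu <- colMeans(Y); y_sd <- apply(Y, 2, sd)
  y_sd[!is.finite(y_sd) | y_sd < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, x_mu, `-`), 2, x_sd, `/`)
  Ys <- sweep(sweep(Y, 2, y_mu, `-`), 2, y_sd, `/`)

  set.seed(cfg$seed)
  params <- init_params(spec)
  state <- adam_init(params)
  n <- nrow(Xs)
  bs <- min(cfg$batch_size, n)
  losses <- numeric(cfg$epochs)
  t_step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    lr_now <- cfg$lr * if (ep > 0.85 * cfg$epochs) 0.01
    else if (ep > 0.60 * cfg$epochs) 0.1 else 1
    ord <- sample(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      if (length(idx) < 2L && spec$batchnorm) next  # batch stats need >= 2 rows
      xb <- Xs[idx, , drop = FALSE]
      yb <- Ys[idx, , drop = FALSE]
      fw <- mlp_forward(params, xb, spec, training = TRUE)
      params <- fw$params
      err <- fw$out - yb
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss", call. = FALSE)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      dout <- 2 * err / length(err)
      grads <- mlp_backward(params, spec, fw$cache, dout)
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, state, lr_now, t_step)
      params <- upd$params; state <- upd$state
    }
    losses[ep] <- ep_loss / max(nb, 1L)
  }
  # re-estimate batchnorm statistics exactly over the full training set so
  # evaluation-mode normalization matches the data actually trained on
  if (spec$batchnorm) {
    A <- Xs
    Lh <- length(params) - 1L
    for (l in seq_len(Lh)) {
      p <- params[[l]]
      Z <- sweep(A %*% p$W, 2, p$b, `+`)
      mu <- colMeans(Z)
      va <- colMeans(sweep(Z, 2, mu, `-`)^2)
      params[[l]]$run_mean <- mu
      params[[l]]$run_var <- va
      istd <- 1 / sqrt(va + 1e-5)
      Zhat <- sweep(sweep(Z, 2, mu, `-`), 2, istd, `*`)
      A <- relu(sweep(sweep(Zhat, 2, p$gamma, `*`), 2, p$beta, `+`))
    }
  }
  structure(list(params = params, spec = spec, cfg = cfg,
                 x_mu = x_mu, x_sd = x_sd, y_mu = y_mu, y_sd = y_sd,
                 feature_names = colnames(X), losses = losses,
                 n_train = n),
            class = "tsm_mlp")
}

#' Predict flow rate and vessel depth
#'
#' @param object A fitted `tsm_mlp`.
#' @param newdata A `labeled_dataset`, matrix or vector of features with
#'   the width the model was trained on.
#' @param ... Unused.
#' @return Matrix with columns `flow` (mm/s) and `depth` (mm).
#' @export
predict.tsm_mlp <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) dataset_matrices(newdata)$X
  else if (is.vector(newdata) && is.numeric(newdata)) matrix(newdata, nrow = 1)
  else as.matrix(newdata)
  if (ncol(X) != object$spec$input)
    stop(sprintf("feature width mismatch: model expects %d, got %d",
                 object$spec$input, ncol(X)), call. = FALSE)
  Xs <- sweep(sweep(X, 2, object$x_mu, `-`), 2, object$x_sd, `/`)
  out <- mlp_forward(object$params, Xs, object$spec, training = FALSE)$out
  out <- sweep(sweep(out, 2, object$y_sd, `*`), 2, object$y_mu, `+`)
  colnames(out) <- c("flow", "depth")
  out
}

#' @export
print.tsm_mlp <- function(x, ...) {
  cat(sprintf("<tsm_mlp> %d -> %s -> %d (%s%sdropout %.2g), %d rows, %d epochs\n",
              x$spec$input, paste(x$spec$hidden, collapse = "-"),
              x$spec$output,
              if (x$spec$batchnorm) "batchnorm, " else "",
              "ReLU, ", x$spec$dropout, x$n_train, x$cfg$epochs))
  cat(sprintf("  final training loss (standardized MSE): %.4g\n",
              tail(x$losses, 1)))
  invisible(x)
}

#' @export
summary.tsm_mlp <- function(object, ...) {
  npar <- sum(vapply(object$params, function(p)
    sum(vapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
               length, numeric(1))), numeric(1)))
  out <- list(spec = object$spec, parameters = npar,
              first_loss = object$losses[1],
              final_loss = tail(object$losses, 1),
              n_train = object$n_train)
  class(out) <- "summary.tsm_mlp"
  out
}

#' @export
print.summary.tsm_mlp <- function(x, ...) {
  cat(sprintf("MLP regressor: %d trainable parameters\n", x$parameters))
  cat(sprintf("  training loss %.4g -> %.4g over %d rows\n",
              x$first_loss, x$final_loss, x$n_train))
  invisible(x)
}

#' @export
coef.tsm_mlp <- function(object, ...) {
  lapply(object$params, function(p)
    p[intersect(names(p), c("W", "b", "gamma", "beta"))])
}
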