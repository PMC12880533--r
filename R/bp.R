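# Two-branch blood-pressure estimator: an LSTM branch encodes the 1 Hz
# flow-rate window and a 1-D convolutional branch encodes the 128 Hz PPG
# window; the branch embeddings are concatenated and a fully connected
# (ridge-regression) head maps them to SP and DP. Branch weights are
# fixed random projections drawn once from the seed (echo-state style),
# which keeps training closed-form and fully deterministic; only the head
# is fitted.

#' Fusion model architecture
#'
#' @param window Input window length in seconds (both branches; default 10).
#' @param lstm_hidden Hidden state size of the recurrent (flow) branch.
#' @param conv_filters Number of convolution filters in the PPG branch.
#' @param conv_width Filter width in samples (128 Hz; default 64 = 0.5 s).
#' @param conv_stride Stride of the convolution (default 16).
#' @param ridge Ridge penalty of the fully connected head.
#' @return An object of class `fusion_spec`.
#' @export
fusion_spec <- function(window = 10, lstm_hidden = 16, conv_filters = 16,
                        conv_width = 64, conv_stride = 16, ridge = 1e-2) {
  stopifnot(window >= 2, lstm_hidden >= 1, conv_filters >= 1,
            conv_width >= 2, conv_stride >= 1, ridge > 0)
  structure(list(window = as.integer(window),
                 lstm_hidden = as.integer(lstm_hidden),
                 conv_filters = as.integer(conv_filters),
                 conv_width = as.integer(conv_width),
                 conv_stride = as.integer(conv_stride), ridge = ridge),
            class = "fusion_spec")
}

# fixed random LSTM cell parameters
init_lstm <- function(nin, nh) {
  mk <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)
  list(Wx = mk(nin, 4 * nh, 0.8), Wh = mk(nh, 4 * nh, 0.4 / sqrt(nh)),
       b = c(rep(1, nh), rep(0, 3 * nh)))  # forget-gate bias 1
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# run the LSTM over a batch of sequences (rows = windows, cols = time);
# returns the final hidden state, n x nh
lstm_encode <- function(X, par, nh) {
  n <- nrow(X)
  Hc <- matrix(0, n, nh); Cc <- matrix(0, n, nh)
  for (tt in seq_len(ncol(X))) {
    G <- X[, tt, drop = FALSE] %*% par$Wx + Hc %*% par$Wh
    G <- sweep(G, 2, par$b, `+`)
    f <- sigmoid(G[, 1:nh, drop = FALSE])
    i <- sigmoid(G[, nh + 1:nh, drop = FALSE])
    o <- sigmoid(G[, 2 * nh + 1:nh, drop = FALSE])
    g <- tanh(G[, 3 * nh + 1:nh, drop = FALSE])
    Cc <- f * Cc + i * g
    Hc <- o * tanh(Cc)
  }
  Hc
}

# 1-D convolution encoder: random filters, ReLU, global average and max
# pooling per filter -> 2 * conv_filters features per window
conv_encode <- function(X, filt, stride) {
  n <- nrow(X); wlen <- ncol(X); fw <- nrow(filt)
  starts <- seq(1L, wlen - fw + 1L, by = stride)
  nf <- ncol(filt)
  out <- matrix(0, n, 2L * nf)
  act <- array(0, dim = c(n, length(starts), nf))
  for (si in seq_along(starts)) {
    seg <- X[, starts[si]:(starts[si] + fw - 1L), drop = FALSE]
    act[, si, ] <- pmax(seg %*% filt, 0)
  }
  for (j in seq_len(nf)) {
    out[, j] <- rowMeans(act[, , j, drop = FALSE][, , 1])
    out[, nf + j] <- apply(act[, , j, drop = FALSE][, , 1], 1, max)
  }
  out
}

# build windowed design matrices from a record list
bp_windows <- function(records, spec) {
  W <- spec$window
  fs <- 128L
  Xf <- list(); Xp <- list(); Y <- list(); meta <- list()
  for (r in records) {
    n1 <- length(r$time)
    ends <- seq(W, n1)  # window ends at second `end` (1-based)
    if (!length(ends)) next
    Xf[[length(Xf) + 1L]] <- t(vapply(ends, function(e)
      r$flow[(e - W + 1L):e], numeric(W)))
    Xp[[length(Xp) + 1L]] <- t(vapply(ends, function(e)
      r$ppg[((e - W) * fs + 1L):(e * fs)], numeric(W * fs)))
    Y[[length(Y) + 1L]] <- cbind(sp = r$sp[ends], dp = r$dp[ends])
    meta[[length(meta) + 1L]] <- data.frame(record_id = r$record_id,
                                            time = r$time[ends])
  }
  list(flow = do.call(rbind, Xf), ppg = do.call(rbind, Xp),
       y = do.call(rbind, Y), meta = do.call(rbind, meta))
}

#' Fit the blood-pressure estimation model
#'
#' Encodes each 10 s window with the two branches (or the PPG branch only
#' in `ppg_only` mode), then fits the fully connected head by ridge
#' regression of SP/DP on the standardized embeddings. The flow channel
#' is excluded from the `ppg_only` model by construction.
#'
#' @param records List of `multimodal_record` (training split; split by
#'   record, never within a record).
#' @param mode `"fused"` (flow + PPG) or `"ppg_only"`.
#' @param spec A [fusion_spec()].
#' @param seed Seed for the fixed branch weights.
#' @return An object of class `bp_model`.
#' @export
fit_bp_model <- function(records, mode = c("fused", "ppg_only"),
                         spec = fusion_spec(), seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, logical(1), "multimodal_record")))
  set.seed(seed)
  lstm <- init_lstm(1L, spec$lstm_hidden)
  filt <- matrix(rnorm(spec$conv_width * spec$conv_filters,
                       sd = 1 / sqrt(spec$conv_width)),
                 spec$conv_width, spec$conv_filters)
  wd <- bp_windows(records, spec)
  emb_p <- conv_encode(wd$ppg, filt, spec$conv_stride)
  emb <- if (mode == "fused")
    cbind(lstm_encode(wd$flow, lstm, spec$lstm_hidden), emb_p)
  else emb_p
  mu <- colMeans(emb); s <- apply(emb, 2, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  Z <- sweep(sweep(emb, 2, mu, `-`), 2, s, `/`)
  y_mu <- colMeans(wd$y)
  Yc <- sweep(wd$y, 2, y_mu, `-`)
  if (any(!is.finite(Z)) || any(!is.finite(Yc)))
    stop("non-finite values in the training embeddings", call. = FALSE)
  p <- ncol(Z)
  beta <- solve(crossprod(Z) + spec$ridge * nrow(Z) * diag(p), crossprod(Z, Yc))
  structure(list(mode = mode, spec = spec, seed = as.integer(seed),
                 lstm = lstm, filt = filt, emb_mu = mu, emb_sd = s,
                 y_mu = y_mu, beta = beta),
            class = "bp_model")
}

#' Predict SP/DP at 1 Hz for records
#'
#' @param object A fitted `bp_model`.
#' @param newdata List of `multimodal_record` (or a single record).
#' @param ... Unused.
#' @return Data frame: record_id, time, sp_pred, dp_pred, sp_ref, dp_ref.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  if (inherits(newdata, "multimodal_record")) newdata <- list(newdata)
  wd <- bp_windows(newdata, object$spec)
  emb_p <- conv_encode(wd$ppg, object$filt, object$spec$conv_stride)
  emb <- if (object$mode == "fused")
    cbind(lstm_encode(wd$flow, object$lstm, object$spec$lstm_hidden), emb_p)
  else emb_p
  Z <- sweep(sweep(emb, 2, object$emb_mu, `-`), 2, object$emb_sd, `/`)
  pred <- sweep(Z %*% object$beta, 2, object$y_mu, `+`)
  data.frame(wd$meta, sp_pred = pred[, 1], dp_pred = pred[, 2],
             sp_ref = wd$y[, "sp"], dp_ref = wd$y[, "dp"])
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> mode = %s; LSTM hidden %d + %d conv filters -> ridge head\n",
              x$mode, x$spec$lstm_hidden, x$spec$conv_filters))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `measured - reference`; the bias is their mean and the
#' 95% limits of agreement are `bias +/- 1.96 * SD` with the sample
#' (n - 1) standard deviation.
#'
#' @param reference,measured Paired series, mmHg (equal length, n >= 2).
#' @return An object of class `agreement_stats` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(reference, measured) {
  if (length(reference) != length(measured))
    stop("reference and measured must have equal length", call. = FALSE)
  if (length(reference) < 2L)
    stop("need at least two paired observations", call. = FALSE)
  d <- measured - reference
  bias <- mean(d)
  sdd <- sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f mmHg, LoA [%.2f, %.2f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Error reduction of the fused model over the PPG-only baseline
#'
#' @param err_ppg,err_fused RMS (or other) errors of the two approaches on
#'   identical evaluation rows; scalars or equally-named vectors (e.g.
#'   per-phase).
#' @return Percent reduction `100 (err_ppg - err_fused) / err_ppg`;
#'   `NA` where the baseline error is zero.
#' @export
error_reduction <- function(err_ppg, err_fused) {
  out <- 100 * (err_ppg - err_fused) / err_ppg
  out[err_ppg == 0] <- NA_real_
  out
}

#' Run the flow+PPG fusion demonstration
#'
#' Generates synthetic cardio records, fits PPG-only and fused models on
#' a record-level training split, and evaluates both on the held-out
#' records: RMSEs, error reductions and Bland-Altman agreement over the
#' Valsalva window (10 s before to 30 s after the maneuver).
#'
#' @param cfg A [cardio_config()].
#' @param n_records Total records (last `n_test` held out).
#' @param n_test Held-out records.
#' @param duration Record length, s.
#' @param spec A [fusion_spec()].
#' @param seed Seed for the branch weights.
#' @return List with `rmse` (matrix: ppg_only/fused x sp/dp),
#'   `reduction_pct`, `agreement` (Bland-Altman for both modes and
#'   outputs over the maneuver window), and the held-out `predictions`.
#' @export
run_bp_demo <- function(cfg = cardio_config(), n_records = 8, n_test = 3,
                        duration = 600, spec = fusion_spec(), seed = 0L) {
  stopifnot(n_test >= 1, n_records > n_test)
  recs <- generate_cardio_dataset(cfg, n_records, duration)
  train <- recs[seq_len(n_records - n_test)]
  test <- recs[(n_records - n_test + 1):n_records]
  m_ppg <- fit_bp_model(train, "ppg_only", spec, seed)
  m_fus <- fit_bp_model(train, "fused", spec, seed)
  p_ppg <- predict(m_ppg, test)
  p_fus <- predict(m_fus, test)
  rm <- rbind(
    ppg_only = c(sp = rmse(p_ppg$sp_ref, p_ppg$sp_pred),
                 dp = rmse(p_ppg$dp_ref, p_ppg$dp_pred)),
    fused = c(sp = rmse(p_fus$sp_ref, p_fus$sp_pred),
              dp = rmse(p_fus$dp_ref, p_fus$dp_pred)))
  red <- error_reduction(rm["ppg_only", ], rm["fused", ])
  w <- p_ppg$time >= cfg$valsalva_onset - 10 &
    p_ppg$time <= cfg$valsalva_onset + cfg$valsalva_duration + 30
  agreement <- list(
    sp_ppg = bland_altman(p_ppg$sp_ref[w], p_ppg$sp_pred[w]),
    sp_fused = bland_altman(p_fus$sp_ref[w], p_fus$sp_pred[w]),
    dp_ppg = bland_altman(p_ppg$dp_ref[w], p_ppg$dp_pred[w]),
    dp_fused = bland_altman(p_fus$dp_ref[w], p_fus$dp_pred[w]))
  list(rmse = rm, reduction_pct = red, agreement = agreement,
       predictions = list(ppg_only = p_ppg, fused = p_fus))
}
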