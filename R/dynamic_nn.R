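# Lagged-feedback (NARX-style) neural network ---------------------------
#
# One calcium-calculator unit: a single-hidden-layer network whose inputs
# are the current agonist dose channels plus its own output (the F/F0
# trace) at a fixed set of past lags. It is trained teacher-forced (the
# measured trace fills the lag slots) and evaluated closed-loop (its own
# predictions are fed back).

#' Network specification
#'
#' @param n_inputs number of agonist input channels (panel size).
#' @param lags_s feedback lags in seconds; must be positive, strictly
#'   increasing, integer multiples of `dt_s`.
#' @param hidden_nodes hidden layer width.
#' @param max_epochs training epoch cap.
#' @param patience early stopping: halt when the validation MSE has not
#'   improved for this many consecutive epochs.
#' @param val_fraction fraction of *conditions* held out for validation.
#' @param dt_s model grid sampling interval, seconds.
#' @param floor lower clip applied to closed-loop predictions (F/F0 cannot
#'   go below 0).
#' @return A list of class `nn_spec`.
#' @export
nn_spec <- function(n_inputs, lags_s = c(1, 2, 4, 8, 16, 32, 64, 128),
                    hidden_nodes = 12, max_epochs = 1000, patience = 5,
                    val_fraction = 0.10, dt_s = 1, floor = 0) {
  lags_s <- as.numeric(lags_s)
  if (any(lags_s <= 0) || is.unsorted(lags_s, strictly = TRUE))
    stop("nn_spec: lags must be positive and strictly increasing")
  steps <- lags_s / dt_s
  if (max(abs(steps - round(steps))) > 1e-9)
    stop("nn_spec: lags must be integer multiples of dt_s")
  stopifnot(n_inputs >= 1, hidden_nodes >= 1,
            val_fraction > 0, val_fraction < 1, max_epochs >= 1,
            patience >= 1)
  structure(list(n_inputs = as.integer(n_inputs), lags_s = lags_s,
                 lag_steps = as.integer(round(steps)),
                 hidden_nodes = as.integer(hidden_nodes),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, dt_s = dt_s, floor = floor),
            class = "nn_spec")
}

# dose encoding: log10(1 + d) rescaled so the design range d in [0, 10]
# maps to [0, 1]; keeps the three dose decades separable for the sigmoid
encode_dose <- function(d) log10(1 + d) / log10(11)

#' Initialize network weights
#'
#' Weights are drawn from a symmetric uniform distribution scaled by fan-in
#' so an untrained network's closed-loop output stays near baseline.
#' Feature/output scaling starts at neutral values (center 1, scale 0.5 on
#' the F/F0 axis) and is refit from the data during training.
#'
#' @param spec an [nn_spec()].
#' @param seed integer seed; weights are deterministic given the seed.
#' @return A list of class `pas_nn`.
#' @export
nn_build <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "nn_spec"))
  p <- spec$n_inputs + length(spec$lags_s)
  h <- spec$hidden_nodes
  w <- local_seed(seed, {
    list(W1 = matrix(stats::runif(h * p, -1, 1) / sqrt(p), h, p),
         b1 = stats::runif(h, -0.5, 0.5),
         w2 = stats::runif(h, -1, 1) / (2 * sqrt(h)),
         b2 = 0)
  })
  x_center <- c(rep(0, spec$n_inputs), rep(1, length(spec$lags_s)))
  x_scale <- c(rep(1, spec$n_inputs), rep(0.5, length(spec$lags_s)))
  structure(list(spec = spec, W1 = w$W1, b1 = w$b1, w2 = w$w2, b2 = w$b2,
                 x_center = x_center, x_scale = x_scale,
                 y_center = 1, y_scale = 0.5, seed = as.integer(seed)),
            class = "pas_nn")
}

# scaled-space forward pass; X raw feature matrix (rows = samples)
nn_forward_raw <- function(nn, X) {
  Xs <- sweep(sweep(X, 2, nn$x_center), 2, nn$x_scale, "/")
  Z <- tanh(Xs %*% t(nn$W1) + rep(nn$b1, each = nrow(Xs)))
  drop(Z %*% nn$w2 + nn$b2) * nn$y_scale + nn$y_center
}

#' Build teacher-forced training pairs from an experiment set
#'
#' For every condition and every grid point with `t > 0`, the feature
#' vector is the encoded agonist input at `t` plus the *measured* F/F0 at
#' `t - lag` for each lag (history before the grid start is padded with
#' baseline 1.0); the target is the measured F/F0 at `t`.
#'
#' @param experiment an averaged `pas_experiment` on the model grid.
#' @param spec an [nn_spec()].
#' @return A list with `X` (features), `y` (targets), `condition` (integer
#'   condition id per row) and `labels`.
#' @export
make_training_pairs <- function(experiment, spec) {
  time_s <- experiment$time_s
  if (abs((time_s[2] - time_s[1]) - spec$dt_s) > 1e-9)
    stop("make_training_pairs: experiment grid does not match spec dt_s")
  if (length(time_s) <= max(spec$lag_steps))
    stop("make_training_pairs: trace shorter than the maximum lag")
  tr <- experiment$traces
  if (length(dim(tr)) == 3) stop("make_training_pairs: average replicates first")
  targets <- which(time_s > 0)
  nc <- ncol(tr)
  nL <- length(spec$lag_steps)
  Xs <- vector("list", nc); ys <- vector("list", nc)
  for (j in seq_len(nc)) {
    U <- encode_dose(condition_input_series(experiment$schedules[[j]], time_s))
    lagm <- matrix(1, length(targets), nL)
    for (l in seq_len(nL)) {
      idx <- targets - spec$lag_steps[l]
      ok <- idx >= 1
      lagm[ok, l] <- tr[idx[ok], j]
    }
    Xs[[j]] <- cbind(U[targets, , drop = FALSE], lagm)
    ys[[j]] <- tr[targets, j]
  }
  X <- do.call(rbind, Xs)
  colnames(X) <- c(colnames(Xs[[1]])[seq_len(spec$n_inputs)],
                   paste0("lag", spec$lags_s))
  list(X = X, y = unlist(ys),
       condition = rep(seq_len(nc), each = length(targets)),
       labels = experiment$labels)
}

# one Rprop- epoch over flattened parameters; returns updated state
rprop_step <- function(par, grad, state,
                       eta_plus = 1.2, eta_minus = 0.7,
                       d_max = 1, d_min = 1e-9) {
  s <- sign(grad) * sign(state$g_prev)
  state$delta[s > 0] <- pmin(state$delta[s > 0] * eta_plus, d_max)
  state$delta[s < 0] <- pmax(state$delta[s < 0] * eta_minus, d_min)
  grad[s < 0] <- 0
  par <- par - sign(grad) * state$delta
  state$g_prev <- grad
  list(par = par, state = state)
}

#' Train a network on teacher-forced pairs
#'
#' Conditions (not single time points) are split 90/10 into training and
#' validation sets, the mean-squared one-step error is minimized by
#' full-batch resilient backpropagation, training stops early when the
#' validation MSE has not improved for `patience` epochs, and the weights
#' with the best validation MSE are returned.
#'
#' @param nn a [nn_build()] network.
#' @param pairs output of [make_training_pairs()].
#' @param split_seed integer seed for the condition-level split.
#' @return The trained `pas_nn`, with fields `history` (per-epoch train/val
#'   MSE, F/F0 units), `train_mse`, `val_mse`, `epochs_run`.
#' @export
nn_train <- function(nn, pairs, split_seed = 1L) {
  spec <- nn$spec
  stopifnot(nrow(pairs$X) > 0)
  conds <- unique(pairs$condition)
  n_val <- max(1L, round(spec$val_fraction * length(conds)))
  if (n_val >= length(conds)) n_val <- length(conds) - 1L
  val_conds <- local_seed(split_seed, sample(conds, n_val))
  is_val <- pairs$condition %in% val_conds
  Xtr <- pairs$X[!is_val, , drop = FALSE]; ytr <- pairs$y[!is_val]
  Xva <- pairs$X[is_val, , drop = FALSE];  yva <- pairs$y[is_val]

  # data-driven affine scaling from the training rows
  nn$x_center <- colMeans(Xtr)
  sds <- apply(Xtr, 2, stats::sd)
  nn$x_scale <- ifelse(sds > 1e-12, sds, 1)
  nn$y_center <- mean(ytr)
  nn$y_scale <- if (stats::sd(ytr) > 1e-12) stats::sd(ytr) else 1

  Xs <- sweep(sweep(Xtr, 2, nn$x_center), 2, nn$x_scale, "/")
  ys <- (ytr - nn$y_center) / nn$y_scale
  n <- nrow(Xs)
  par <- c(as.vector(nn$W1), nn$b1, nn$w2, nn$b2)
  h <- spec$hidden_nodes; p <- ncol(Xs)
  unpack <- function(par) {
    W1 <- matrix(par[1:(h * p)], h, p)
    b1 <- par[(h * p + 1):(h * p + h)]
    w2 <- par[(h * p + h + 1):(h * p + 2 * h)]
    b2 <- par[h * p + 2 * h + 1]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  state <- list(delta = rep(0.01, length(par)), g_prev = rep(0, length(par)))
  val_mse_of <- function(par) {
    w <- unpack(par)
    tmp <- nn; tmp$W1 <- w$W1; tmp$b1 <- w$b1; tmp$w2 <- w$w2; tmp$b2 <- w$b2
    mean((nn_forward_raw(tmp, Xva) - yva)^2)
  }
  best_par <- par; best_val <- val_mse_of(par)
  since_best <- 0L
  hist_tr <- numeric(0); hist_va <- numeric(0)
  for (epoch in seq_len(spec$max_epochs)) {
    w <- unpack(par)
    Z <- tanh(Xs %*% t(w$W1) + rep(w$b1, each = n))
    pred <- drop(Z %*% w$w2 + w$b2)
    err <- pred - ys
    loss <- mean(err^2)
    if (!is.finite(loss)) stop("training-failure: non-finite loss")
    e <- 2 * err / n
    g_w2 <- drop(crossprod(Z, e)); g_b2 <- sum(e)
    dZ <- (e %o% w$w2) * (1 - Z^2)
    g_W1 <- crossprod(dZ, Xs); g_b1 <- colSums(dZ)
    grad <- c(as.vector(g_W1), g_b1, g_w2, g_b2)
    upd <- rprop_step(par, grad, state)
    par <- upd$par; state <- upd$state
    va <- val_mse_of(par)
    hist_tr <- c(hist_tr, loss * nn$y_scale^2); hist_va <- c(hist_va, va)
    if (va < best_val) {
      best_val <- va; best_par <- par; since_best <- 0L
    } else since_best <- since_best + 1L
    if (since_best >= spec$patience) break
  }
  w <- unpack(best_par)
  nn$W1 <- w$W1; nn$b1 <- w$b1; nn$w2 <- w$w2; nn$b2 <- w$b2
  nn$history <- data.frame(epoch = seq_along(hist_tr),
                           train_mse = hist_tr, val_mse = hist_va)
  nn$val_mse <- best_val
  nn$train_mse <- mean((nn_forward_raw(nn, Xtr) - ytr)^2)
  nn$val_conditions <- pairs$labels[val_conds]
  nn$epochs_run <- length(hist_tr)
  nn
}

#' One-step prediction on teacher-forced pairs
#'
#' @param nn a trained `pas_nn`.
#' @param pairs output of [make_training_pairs()].
#' @return Numeric vector of one-step predictions (F/F0 units).
#' @export
nn_one_step <- function(nn, pairs) nn_forward_raw(nn, pairs$X)

#' Closed-loop prediction for a batch of input series
#'
#' Iterates the one-step map, feeding the network's own past predictions
#' into the lag slots. History before `t = 0` is fixed at baseline 1.0 and
#' the output is clipped at `spec$floor`.
#'
#' @param nn a `pas_nn`.
#' @param inputs a single time x agonist dose-multiplier matrix, or a list
#'   of them (one per condition, shared grid).
#' @param time_s uniform time grid matching the rows of `inputs`.
#' @return A matrix time x condition of predicted F/F0.
#' @export
nn_predict_closed_loop <- function(nn, inputs, time_s) {
  if (is.matrix(inputs)) inputs <- list(inputs)
  nc <- length(inputs)
  nt <- length(time_s)
  for (u in inputs) stopifnot(nrow(u) == nt)
  spec <- nn$spec
  nL <- length(spec$lag_steps)
  # encoded inputs: nc x n_inputs per time point
  U <- lapply(inputs, encode_dose)
  Fm <- matrix(1, nt, nc)
  steps <- which(time_s > 0)
  for (idx in steps) {
    doses <- t(vapply(U, function(u) u[idx, ], numeric(spec$n_inputs)))
    if (spec$n_inputs == 1) doses <- matrix(doses, nc, 1)
    lags <- matrix(1, nc, nL)
    for (l in seq_len(nL)) {
      k <- idx - spec$lag_steps[l]
      if (k >= 1) lags[, l] <- Fm[k, ]
    }
    X <- cbind(doses, lags)
    yhat <- nn_forward_raw(nn, X)
    if (any(!is.finite(yhat))) stop("prediction-failure: non-finite state")
    Fm[idx, ] <- pmax(yhat, spec$floor)
  }
  Fm
}

#' Closed-loop prediction for one dispense schedule
#'
#' @param nn a `pas_nn`.
#' @param schedule a [dispense_schedule()].
#' @param time_s uniform time grid covering the schedule.
#' @return A [calcium_trace()].
#' @export
predict_closed_loop <- function(nn, schedule, time_s) {
  u <- condition_input_series(schedule, time_s)
  calcium_trace(time_s, nn_predict_closed_loop(nn, u, time_s)[, 1])
}

# Weight serialization ---------------------------------------------------

#' Serialize / restore a network as versioned JSON
#'
#' Numbers are written at full precision, so a save/load round trip is
#' bit-exact.
#'
#' @param nn a `pas_nn`.
#' @param path JSON file path.
#' @export
nn_save_json <- function(nn, path) {
  obj <- list(format = "pascalc-nn", version = 1L,
              spec = unclass(nn$spec),
              W1 = nn$W1, b1 = nn$b1, w2 = nn$w2, b2 = nn$b2,
              x_center = nn$x_center, x_scale = nn$x_scale,
              y_center = nn$y_center, y_scale = nn$y_scale,
              seed = nn$seed)
  # 17 significant digits: lossless for IEEE doubles, so the round trip
  # is bit-exact
  writeLines(as.character(jsonlite::toJSON(obj, digits = I(17),
                                           auto_unbox = TRUE)), path)
  invisible(path)
}

#' @rdname nn_save_json
#' @export
nn_load_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pascalc-nn"))
    stop("nn_load_json: not a pascalc network file")
  sp <- obj$spec
  spec <- nn_spec(n_inputs = sp$n_inputs, lags_s = sp$lags_s,
                  hidden_nodes = sp$hidden_nodes, max_epochs = sp$max_epochs,
                  patience = sp$patience, val_fraction = sp$val_fraction,
                  dt_s = sp$dt_s, floor = sp$floor)
  W1 <- matrix(as.numeric(obj$W1), nrow(obj$W1), ncol(obj$W1))
  structure(list(spec = spec, W1 = W1,
                 b1 = as.numeric(obj$b1), w2 = as.numeric(obj$w2),
                 b2 = as.numeric(obj$b2),
                 x_center = as.numeric(obj$x_center),
                 x_scale = as.numeric(obj$x_scale),
                 y_center = as.numeric(obj$y_center),
                 y_scale = as.numeric(obj$y_scale),
                 seed = as.integer(obj$seed)),
            class = "pas_nn")
}
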