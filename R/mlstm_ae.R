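# Multilabel LSTM autoencoder (MLSTM-AE): a recurrent encoder whose final
# hidden state feeds (a) an input-free LSTM decoder trained to reproduce the
# time-flipped input and (b) a per-label sigmoid classification head. The two
# heads are trained jointly on L = L_cls + gamma * L_rec.
#
# Everything here is vectorised over the batch dimension; the only explicit
# loop is over the T time steps. Gradients are exact backpropagation-through-
# time, checked against finite differences in the unit tests.

#' Initialise MLSTM-AE parameters
#'
#' Weights are drawn uniformly in `[-scale, scale]`; forget-gate biases start
#' at 1 (the usual LSTM trick that keeps early memory open). The decoder has
#' the same cell shape as the encoder but no input weights: it unrolls from the
#' encoder's final hidden state alone.
#'
#' @param d Input feature width per time step.
#' @param H Hidden state size.
#' @param C Number of labels.
#' @param seed Integer seed for the initialisation stream.
#' @param scale Uniform init half-width. Default 0.08.
#' @return Object of class `mlstm_params`.
#' @export
mlstm_init <- function(d, H, C, seed = 1L, scale = 0.08) {
  stopifnot(is_count(d), is_count(H), is_count(C), d >= 1, H >= 1, C >= 1)
  with_seed(seed, {
    ru <- function(nr, nc) matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
    fb <- function(H) { b <- rep(0, 4L * H); b[(H + 1L):(2L * H)] <- 1; b }
    structure(list(
      enc = list(Wx = ru(d, 4L * H), Wh = ru(H, 4L * H), b = fb(H)),
      dec = list(Wh = ru(H, 4L * H), b = fb(H), Wy = ru(H, d), by = rep(0, d)),
      cls = list(Wc = ru(H, C), bc = rep(0, C)),
      d = d, H = H, C = C
    ), class = "mlstm_params")
  })
}

# Extract time slice t of an N x T x d array as an N x d matrix, robust to
# N == 1 or d == 1 (plain `[` would drop to a vector).
slice_t <- function(x, t) matrix(x[, t, ], nrow = dim(x)[1L])

# One LSTM step for a batch. xt may be NULL (input-free decoder cell).
# Gate order inside the 4H block: input, forget, cell candidate, output.
lstm_step <- function(xt, hprev, cprev, Wx, Wh, b) {
  H <- ncol(Wh) / 4L
  z <- hprev %*% Wh + matrix(b, nrow(hprev), 4L * H, byrow = TRUE)
  if (!is.null(xt)) z <- z + xt %*% Wx
  i <- sigmoid(z[, 1:H, drop = FALSE])
  f <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
  g <- tanh(z[, (2L * H + 1L):(3L * H), drop = FALSE])
  o <- sigmoid(z[, (3L * H + 1L):(4L * H), drop = FALSE])
  c <- f * cprev + i * g
  tc <- tanh(c)
  h <- o * tc
  list(h = h, c = c, cache = list(i = i, f = f, g = g, o = o, tc = tc,
                                  hprev = hprev, cprev = cprev, xt = xt))
}

# Backward through one LSTM step. Returns gradients w.r.t. the step inputs and
# accumulable weight gradients.
lstm_step_backward <- function(cache, Wx, Wh, dh, dc) {
  i <- cache$i; f <- cache$f; g <- cache$g; o <- cache$o; tc <- cache$tc
  do <- dh * tc
  dc <- dc + dh * o * (1 - tc^2)
  di <- dc * g
  dg <- dc * i
  df <- dc * cache$cprev
  dcprev <- dc * f
  dz <- cbind(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2),
              do * o * (1 - o))
  list(
    dhprev = dz %*% t(Wh),
    dcprev = dcprev,
    dWx = if (is.null(cache$xt)) NULL else crossprod(cache$xt, dz),
    dWh = crossprod(cache$hprev, dz),
    db = colSums(dz)
  )
}

#' Encode a batch of sequences
#'
#' Runs the encoder LSTM over the `N x T x d` input and returns all hidden
#' states plus the final hidden/cell state. The final state equals the T-th
#' hidden state and is the sequence representation used downstream.
#'
#' @param params An `mlstm_params` object.
#' @param x Numeric array `N x T x d`.
#' @return List with `h_all` (`N x T x H`), `h_T` (`N x H`), `c_T` (`N x H`)
#'   and an internal cache used for backpropagation.
#' @export
mlstm_encode <- function(params, x) {
  check_batch_dims(params, x)
  N <- dim(x)[1L]; T <- dim(x)[2L]; H <- params$H
  h <- matrix(0, N, H); c <- matrix(0, N, H)
  h_all <- array(0, c(N, T, H))
  caches <- vector("list", T)
  for (t in seq_len(T)) {
    st <- lstm_step(slice_t(x, t), h, c,
                    params$enc$Wx, params$enc$Wh, params$enc$b)
    h <- st$h; c <- st$c
    h_all[, t, ] <- h
    caches[[t]] <- st$cache
  }
  list(h_all = h_all, h_T = h, c_T = c, caches = caches)
}

check_batch_dims <- function(params, x) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop_input("x must be an N x T x d array")
  }
  if (dim(x)[3L] != params$d) {
    stop_input("input feature width ", dim(x)[3L],
               " does not match model d = ", params$d)
  }
  invisible(TRUE)
}

#' Decode a reconstruction from the encoder's final state
#'
#' The decoder is an LSTM of the same hidden size whose initial hidden state is
#' the encoder's final hidden state (cell state starts at zero) and whose steps
#' take no input; each hidden state is projected to feature space. The training
#' target for an input `(x1, ..., xT)` is its time-flipped copy
#' `(xT, ..., x1)` — see [flip_time()].
#'
#' @param params An `mlstm_params` object.
#' @param final_state `N x H` matrix (encoder final hidden state).
#' @param T Number of steps to unroll (>= 1).
#' @return List with `x_hat` (`N x T x d`) and an internal cache.
#' @export
mlstm_decode <- function(params, final_state, T) {
  if (!is_count(T) || T < 1) stop_input("T must be a positive integer")
  stopifnot(is.matrix(final_state), ncol(final_state) == params$H)
  N <- nrow(final_state); H <- params$H; d <- params$d
  h <- final_state
  c <- matrix(0, N, H)
  x_hat <- array(0, c(N, T, d))
  caches <- vector("list", T)
  hs <- vector("list", T)
  for (t in seq_len(T)) {
    st <- lstm_step(NULL, h, c, NULL, params$dec$Wh, params$dec$b)
    h <- st$h; c <- st$c
    hs[[t]] <- h
    x_hat[, t, ] <- h %*% params$dec$Wy +
      matrix(params$dec$by, N, d, byrow = TRUE)
    caches[[t]] <- st$cache
  }
  list(x_hat = x_hat, caches = caches, hs = hs)
}

#' Time-flip a sequence batch
#'
#' @param x Numeric array `N x T x d`.
#' @return The array with the time axis reversed — the decoder's
#'   reconstruction target.
#' @export
flip_time <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
}

#' Multilabel classification head
#'
#' Applies the fully connected layer and a per-label sigmoid to the encoder's
#' final hidden state, giving independent label probabilities in `[0, 1]`.
#'
#' @param params An `mlstm_params` object.
#' @param final_state `N x H` matrix.
#' @return `N x C` probability matrix.
#' @export
mlstm_classify <- function(params, final_state) {
  if (!is.matrix(final_state) || ncol(final_state) != params$H) {
    stop_input("final_state must be an N x H matrix with H = ", params$H)
  }
  sigmoid(final_state %*% params$cls$Wc +
            matrix(params$cls$bc, nrow(final_state), params$C, byrow = TRUE))
}

#' Reconstruction loss
#'
#' Squared reconstruction error summed over time steps and features and
#' averaged over samples only: `(1/N) sum_i sum_t ||x_it - x_hat_it||^2`.
#'
#' @param x,x_hat Numeric arrays `N x T x d` of equal shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat))) {
    stop_input("x and x_hat must have identical shape")
  }
  sum((x - x_hat)^2) / dim(x)[1L]
}

# Row-normalise a binary label matrix into ground-truth probability vectors
# p_hat_i = y_i / ||y_i||_1. Rows with no positive label return NA rows.
label_prob_targets <- function(y) {
  s <- rowSums(y)
  p_hat <- y / ifelse(s == 0, NA_real_, s)
  p_hat
}

#' Multilabel classification loss
#'
#' Mean squared error between predicted probability vectors and the L1-
#' normalised label rows `p_hat_i = y_i / ||y_i||_1`:
#' `(1/N) sum_i sum_c (p_ic - p_hat_ic)^2`. Rows whose labels are all zero
#' have no defined probability target; they are excluded from the average with
#' a warning.
#'
#' @param p `N x C` predicted probability matrix.
#' @param y `N x C` binary label matrix.
#' @return Non-negative scalar.
#' @export
classification_loss <- function(p, y) {
  if (!is.matrix(p) || !is.matrix(y) || !identical(dim(p), dim(y))) {
    stop_input("p and y must be matrices of identical shape")
  }
  if (!all(y %in% c(0, 1))) stop_input("y must be binary")
  keep <- rowSums(y) > 0
  if (!all(keep)) {
    warning(sum(!keep), " all-zero label row(s) excluded from the ",
            "classification loss", call. = FALSE)
  }
  if (!any(keep)) return(0)
  p_hat <- label_prob_targets(y[keep, , drop = FALSE])
  sum((p[keep, , drop = FALSE] - p_hat)^2) / sum(keep)
}

#' Joint training loss
#'
#' @param l_cls Classification loss.
#' @param l_rec Reconstruction loss.
#' @param gamma Non-negative reconstruction weight.
#' @return `l_cls + gamma * l_rec`.
#' @export
total_loss <- function(l_cls, l_rec, gamma) {
  stopifnot(is.finite(l_cls), is.finite(l_rec))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    stop_input("gamma must be a single non-negative finite number")
  }
  l_cls + gamma * l_rec
}

# Forward + exact BPTT gradients of L = L_cls + gamma * L_rec on one batch.
# `drop_mask` (N x H, already inverted-scaled) is applied to the classifier
# input only. Rows of y that are all zero are assumed filtered upstream.
mlstm_loss_grads <- function(params, x, y, gamma, drop_mask = NULL) {
  N <- dim(x)[1L]; T <- dim(x)[2L]; d <- params$d; H <- params$H
  enc <- mlstm_encode(params, x)
  h_cls <- if (is.null(drop_mask)) enc$h_T else enc$h_T * drop_mask
  p <- sigmoid(h_cls %*% params$cls$Wc +
                 matrix(params$cls$bc, N, params$C, byrow = TRUE))
  p_hat <- label_prob_targets(y)
  l_cls <- sum((p - p_hat)^2) / N
  dec <- mlstm_decode(params, enc$h_T, T)
  target <- flip_time(x)
  l_rec <- sum((target - dec$x_hat)^2) / N
  loss <- l_cls + gamma * l_rec

  # classifier head
  dp <- 2 * (p - p_hat) / N
  dscore <- dp * p * (1 - p)
  g_cls <- list(Wc = crossprod(h_cls, dscore), bc = colSums(dscore))
  dhT <- (dscore %*% t(params$cls$Wc)) *
    (if (is.null(drop_mask)) 1 else drop_mask)

  # decoder BPTT (gradient flows into the encoder final hidden state)
  g_dec <- list(Wh = 0 * params$dec$Wh, b = 0 * params$dec$b,
                Wy = 0 * params$dec$Wy, by = 0 * params$dec$by)
  dh_next <- matrix(0, N, H); dc_next <- matrix(0, N, H)
  for (t in rev(seq_len(T))) {
    dxhat <- gamma * 2 * (slice_t(dec$x_hat, t) - slice_t(target, t)) / N
    g_dec$Wy <- g_dec$Wy + crossprod(dec$hs[[t]], dxhat)
    g_dec$by <- g_dec$by + colSums(dxhat)
    dh <- dh_next + dxhat %*% t(params$dec$Wy)
    bk <- lstm_step_backward(dec$caches[[t]], NULL, params$dec$Wh, dh, dc_next)
    g_dec$Wh <- g_dec$Wh + bk$dWh
    g_dec$b <- g_dec$b + bk$db
    dh_next <- bk$dhprev
    dc_next <- bk$dcprev
  }
  dhT <- dhT + dh_next # decoder h0 is the encoder final hidden state

  # encoder BPTT
  g_enc <- list(Wx = 0 * params$enc$Wx, Wh = 0 * params$enc$Wh,
                b = 0 * params$enc$b)
  dh <- dhT; dc <- matrix(0, N, H)
  for (t in rev(seq_len(T))) {
    bk <- lstm_step_backward(enc$caches[[t]], params$enc$Wx, params$enc$Wh,
                             dh, dc)
    g_enc$Wx <- g_enc$Wx + bk$dWx
    g_enc$Wh <- g_enc$Wh + bk$dWh
    g_enc$b <- g_enc$b + bk$db
    dh <- bk$dhprev
    dc <- bk$dcprev
  }

  list(loss = loss, l_cls = l_cls, l_rec = l_rec,
       grads = list(enc = g_enc, dec = g_dec, cls = g_cls))
}

adam_init <- function(params) {
  zero_like <- function(grp) lapply(grp, function(w) 0 * w)
  list(m = list(enc = zero_like(params$enc), dec = zero_like(params$dec),
                cls = zero_like(params$cls)),
       v = list(enc = zero_like(params$enc), dec = zero_like(params$dec),
                cls = zero_like(params$cls)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (grp in c("enc", "dec", "cls")) {
    for (nm in names(grads[[grp]])) {
      g <- grads[[grp]][[nm]]
      state$m[[grp]][[nm]] <- beta1 * state$m[[grp]][[nm]] + (1 - beta1) * g
      state$v[[grp]][[nm]] <- beta2 * state$v[[grp]][[nm]] + (1 - beta2) * g * g
      mhat <- state$m[[grp]][[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[grp]][[nm]] / (1 - beta2^state$t)
      params[[grp]][[nm]] <- params[[grp]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Default MLSTM-AE training hyperparameters
#'
#' @param hidden Hidden size H. Default 24.
#' @param lr Adam learning rate. Default 0.02.
#' @param epochs Training epochs. Default 12.
#' @param batch_size Minibatch size. Default 32.
#' @param gamma Reconstruction-loss weight (joint loss). Default 1.
#' @param dropout Dropout rate on the classifier input in `[0, 1)`. Default 0.
#' @param val_frac Fraction held out for validation checkpointing. Default 0.2.
#' @return Named list of hyperparameters.
#' @export
mlstm_control <- function(hidden = 24L, lr = 0.02, epochs = 12L,
                          batch_size = 32L, gamma = 1, dropout = 0,
                          val_frac = 0.2) {
  stopifnot(hidden >= 1, lr > 0, epochs >= 0, batch_size >= 1,
            gamma >= 0, dropout >= 0, dropout < 1,
            val_frac >= 0, val_frac < 1)
  list(hidden = as.integer(round(hidden)), lr = lr,
       epochs = as.integer(epochs), batch_size = as.integer(round(batch_size)),
       gamma = gamma, dropout = dropout, val_frac = val_frac)
}

#' Train the multilabel LSTM autoencoder
#'
#' Joint minimisation of the classification and reconstruction losses with
#' Adam. One master seed governs the train/validation split, weight
#' initialisation, minibatch shuffling and dropout masks, so identical
#' `(data, hyper, seed)` triples give bitwise-identical loss histories. The
#' parameters achieving the best validation loss are checkpointed and returned.
#' Samples whose label rows are all zero are dropped from training (their
#' probability target is undefined) with a single warning.
#'
#' @param x Numeric array `N x T x d` of input sequences.
#' @param y `N x C` binary label matrix.
#' @param hyper Hyperparameters from [mlstm_control()].
#' @param seed Integer master seed.
#' @param quiet Suppress progress messages. Default `TRUE`.
#' @return Object of class `mlstm_ae`: fields `params` (best checkpoint),
#'   `history` (per-epoch data frame of train/validation losses), `hyper`,
#'   `seed`, `val_idx` (row indices of the validation split).
#' @export
mlstm_train <- function(x, y, hyper = mlstm_control(), seed = 1L,
                        quiet = TRUE) {
  check_xy(x, y)
  keep <- rowSums(y) > 0
  if (!all(keep)) {
    warning(sum(!keep), " all-zero label row(s) dropped from training",
            call. = FALSE)
    x <- x[keep, , , drop = FALSE]
    y <- y[keep, , drop = FALSE]
  }
  N <- dim(x)[1L]; T <- dim(x)[2L]; d <- dim(x)[3L]; C <- ncol(y)
  n_val <- floor(hyper$val_frac * N)
  perm <- with_seed(derive_seed(seed, "split"), sample.int(N))
  val_idx <- sort(utils::head(perm, n_val))
  tr_idx <- sort(utils::tail(perm, N - n_val))
  params <- mlstm_init(d, hyper$hidden, C, seed = derive_seed(seed, "init"))
  state <- adam_init(params)
  best <- params
  best_val <- Inf
  hist <- vector("list", hyper$epochs)
  xv <- x[val_idx, , , drop = FALSE]; yv <- y[val_idx, , drop = FALSE]
  for (ep in seq_len(hyper$epochs)) {
    ep_seed <- derive_seed(seed, paste0("epoch", ep))
    order_tr <- with_seed(ep_seed, sample(tr_idx))
    batches <- split(order_tr, ceiling(seq_along(order_tr) / hyper$batch_size))
    tr_loss <- 0; tr_cls <- 0; tr_rec <- 0; n_seen <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      xb <- x[idx, , , drop = FALSE]; yb <- y[idx, , drop = FALSE]
      mask <- NULL
      if (hyper$dropout > 0) {
        mask <- with_seed(derive_seed(ep_seed, paste0("drop", bi)), {
          matrix(stats::rbinom(length(idx) * hyper$hidden, 1L,
                               1 - hyper$dropout),
                 length(idx), hyper$hidden) / (1 - hyper$dropout)
        })
      }
      res <- mlstm_loss_grads(params, xb, yb, hyper$gamma, mask)
      if (!is.finite(res$loss)) {
        stop("training diverged: non-finite loss at epoch ", ep, ", batch ",
             bi, " (lr = ", hyper$lr, ", hidden = ", hyper$hidden, ")")
      }
      up <- adam_step(params, res$grads, state, hyper$lr)
      params <- up$params; state <- up$state
      w <- length(idx)
      tr_loss <- tr_loss + res$loss * w
      tr_cls <- tr_cls + res$l_cls * w
      tr_rec <- tr_rec + res$l_rec * w
      n_seen <- n_seen + w
    }
    val_loss <- NA_real_
    if (n_val > 0) {
      ev <- mlstm_evaluate_loss(params, xv, yv, hyper$gamma)
      val_loss <- ev$loss
      if (val_loss < best_val) {
        best_val <- val_loss
        best <- params
      }
    } else {
      best <- params
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = tr_loss / n_seen,
                             train_cls = tr_cls / n_seen,
                             train_rec = tr_rec / n_seen,
                             val_loss = val_loss)
    if (!quiet) {
      message(sprintf("epoch %d  train %.5f  val %.5f", ep,
                      tr_loss / n_seen, val_loss))
    }
  }
  history <- if (hyper$epochs > 0) do.call(rbind, hist) else
    data.frame(epoch = integer(), train_loss = numeric(),
               train_cls = numeric(), train_rec = numeric(),
               val_loss = numeric())
  structure(list(params = best, history = history, hyper = hyper, seed = seed,
                 val_idx = val_idx, train_idx = tr_idx),
            class = "mlstm_ae")
}

check_xy <- function(x, y) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop_input("x must be an N x T x d array")
  }
  if (!is.matrix(y) || nrow(y) != dim(x)[1L]) {
    stop_input("y must be an N x C matrix aligned with x")
  }
  if (!all(y %in% c(0, 1))) stop_input("y must be binary")
  invisible(TRUE)
}

# Joint loss on a fixed set (no dropout), used for validation checkpointing.
mlstm_evaluate_loss <- function(params, x, y, gamma) {
  enc <- mlstm_encode(params, x)
  p <- mlstm_classify(params, enc$h_T)
  p_hat <- label_prob_targets(y)
  l_cls <- sum((p - p_hat)^2, na.rm = TRUE) / sum(rowSums(y) > 0)
  dec <- mlstm_decode(params, enc$h_T, dim(x)[2L])
  l_rec <- sum((flip_time(x) - dec$x_hat)^2) / dim(x)[1L]
  list(loss = l_cls + gamma * l_rec, l_cls = l_cls, l_rec = l_rec)
}

#' Predict multilabel scores for new sequences
#'
#' @param object A fitted [mlstm_train()] model (or bare `mlstm_params`).
#' @param x Numeric array `N x T x d`.
#' @param ... Unused.
#' @return `N x C` score matrix in `[0, 1]`, rows aligned with `x`.
#' @export
predict_scores <- function(object, x, ...) {
  params <- if (inherits(object, "mlstm_ae")) object$params else object
  stopifnot(inherits(params, "mlstm_params"))
  enc <- mlstm_encode(params, x)
  mlstm_classify(params, enc$h_T)
}

#' @rdname predict_scores
#' @export
predict.mlstm_ae <- function(object, x, ...) predict_scores(object, x, ...)

#' @export
print.mlstm_ae <- function(x, ...) {
  cat("Multilabel LSTM autoencoder\n")
  cat(sprintf("  d = %d, H = %d, C = %d, gamma = %g\n", x$params$d,
              x$params$H, x$params$C, x$hyper$gamma))
  if (nrow(x$history) > 0) {
    cat(sprintf("  %d epochs; final train loss %.5f, best val loss %.5f\n",
                nrow(x$history), utils::tail(x$history$train_loss, 1L),
                min(x$history$val_loss, na.rm = TRUE)))
  } else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single binary RDS file holding the parameters, with a
#' JSON sidecar (`<path>.json`) recording hyperparameters, seed and the loss
#' history for inspection without loading R objects.
#'
#' @param model A fitted `mlstm_ae`.
#' @param path Checkpoint file path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mlstm_ae"))
  saveRDS(model, path)
  side <- list(hyper = model$hyper, seed = model$seed,
               history = model$history)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mlstm_ae"))
  model
}
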