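#' Control parameters for the rotation-attention forecaster
#'
#' @param d_model Hidden width; must be divisible by `2 * n_heads` so every
#'   attention head has an even width (whole rotation planes).
#' @param n_heads Number of attention heads.
#' @param enc_layers,dec_layers Encoder / decoder depth.
#' @param memory_len Number of global-memory slots `c` used by the decoupled
#'   attention.
#' @param lambda1,lambda2 Weights of the frequency-smoothness and
#'   phase-sparsity regularizers in the training loss.
#' @param input_len Observed steps fed to the encoder.
#' @param horizon Steps to predict.
#' @param label_len Trailing observed steps replayed to the decoder ahead of
#'   the zero placeholders for the horizon.
#' @param epochs Maximum training epochs.
#' @param learning_rate Initial Adam step size.
#' @param lr_decay Multiplicative learning-rate decay applied after every
#'   epoch.
#' @param weight_decay Decoupled L2 weight decay applied to the shared
#'   weight matrices (not to rotation/normalization parameters).
#' @param batch_size Mini-batch size (capped at the training-set size).
#' @param patience Early-stopping patience on validation prediction loss.
#' @param clip Global gradient-norm clip.
#' @param d_ff Position-wise feed-forward width.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `quatformer_control`.
#' @export
quatformer_control <- function(d_model = 32, n_heads = 4, enc_layers = 1,
                               dec_layers = 1, memory_len = 8,
                               lambda1 = 0.01, lambda2 = 0.01,
                               input_len = 7, horizon = 1, label_len = 3,
                               epochs = 100, learning_rate = 1e-3,
                               lr_decay = 1, weight_decay = 0,
                               batch_size = 32, patience = 10, clip = 1,
                               d_ff = 2 * d_model, seed = 1) {
  if (d_model %% (2L * n_heads) != 0L)
    stop("d_model must be divisible by 2 * n_heads")
  if (horizon < 1) stop("horizon must be >= 1")
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")
  if (memory_len < 1) stop("memory_len must be >= 1")
  if (label_len < 1) stop("label_len must be >= 1")
  if (label_len + horizon < 2) stop("decoder needs at least 2 positions")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 enc_layers = as.integer(enc_layers),
                 dec_layers = as.integer(dec_layers),
                 memory_len = as.integer(memory_len),
                 lambda1 = lambda1, lambda2 = lambda2,
                 input_len = as.integer(input_len),
                 horizon = as.integer(horizon),
                 label_len = as.integer(label_len),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 lr_decay = lr_decay, weight_decay = weight_decay,
                 batch_size = batch_size, patience = as.integer(patience),
                 clip = clip, d_ff = as.integer(d_ff),
                 seed = as.integer(seed)),
            class = "quatformer_control")
}

## parameter initialization -------------------------------------------------

qf_init_attn <- function(d, dh, c_mem, prefix) {
  P <- dh %/% 2L
  g <- function(nr, nc, sc) matrix(stats::rnorm(nr * nc, 0, sc), nr, nc)
  conv_set <- function(nm) {
    out <- list()
    # stacked kernel-3 convolution weight: rows = (previous, centre, next)
    out[[paste0(nm, "_A")]] <- g(3 * dh, 2 * P, 0.05)
    out[[paste0(nm, "_b")]] <- array(0, c(1L, 2L * P, 1L))
    out
  }
  sc <- 1 / sqrt(d)
  out <- list()
  out[[paste0(prefix, "_Wq")]] <- g(d, d, sc)
  out[[paste0(prefix, "_Wk")]] <- g(d, d, sc)
  out[[paste0(prefix, "_Wv")]] <- g(d, d, sc)
  out[[paste0(prefix, "_Wo")]] <- g(d, d, sc)
  out[[paste0(prefix, "_mem")]] <- g(c_mem, d, 0.2)
  c(out,
    conv_set(paste0(prefix, "_rs1q")), conv_set(paste0(prefix, "_rs1k")),
    conv_set(paste0(prefix, "_rs2q")), conv_set(paste0(prefix, "_rs2k")))
}

qf_init_tn <- function(d, prefix) {
  out <- list()
  out[[paste0(prefix, "_gamma")]] <- array(1, c(1L, d, 1L))
  out[[paste0(prefix, "_beta")]] <- array(0, c(1L, d, 1L))
  out[[paste0(prefix, "_rho")]] <- array(1, c(1L, 1L, 1L))
  out
}

qf_init_ffn <- function(d, dff, prefix) {
  out <- list()
  out[[paste0(prefix, "_W1")]] <- matrix(stats::rnorm(d * dff, 0, 1 / sqrt(d)), d, dff)
  out[[paste0(prefix, "_b1")]] <- array(0, c(1L, dff, 1L))
  out[[paste0(prefix, "_W2")]] <- matrix(stats::rnorm(dff * d, 0, 1 / sqrt(dff)), dff, d)
  out[[paste0(prefix, "_b2")]] <- array(0, c(1L, d, 1L))
  out
}

qf_init_params <- function(control, n_features = 3L) {
  d <- control$d_model
  dh <- d %/% control$n_heads
  cm <- control$memory_len
  params <- list(
    enc_emb = matrix(stats::rnorm(n_features * d, 0, 1 / sqrt(n_features)),
                     n_features, d),
    enc_emb_b = array(0, c(1L, d, 1L)),
    dec_emb = matrix(stats::rnorm(n_features * d, 0, 1 / sqrt(n_features)),
                     n_features, d),
    dec_emb_b = array(0, c(1L, d, 1L)),
    Wout = matrix(stats::rnorm(d, 0, 1 / sqrt(d)), d, 1),
    bout = array(0, c(1L, 1L, 1L))
  )
  for (i in seq_len(control$enc_layers)) {
    pre <- paste0("enc", i)
    params <- c(params,
                qf_init_attn(d, dh, cm, paste0(pre, "_sa")),
                qf_init_tn(d, paste0(pre, "_tn1")),
                qf_init_ffn(d, control$d_ff, paste0(pre, "_ffn")),
                qf_init_tn(d, paste0(pre, "_tn2")))
  }
  for (i in seq_len(control$dec_layers)) {
    pre <- paste0("dec", i)
    params <- c(params,
                qf_init_attn(d, dh, cm, paste0(pre, "_sa")),
                qf_init_tn(d, paste0(pre, "_tn1")),
                qf_init_attn(d, dh, cm, paste0(pre, "_ca")),
                qf_init_tn(d, paste0(pre, "_tn2")),
                qf_init_ffn(d, control$d_ff, paste0(pre, "_ffn")),
                qf_init_tn(d, paste0(pre, "_tn3")))
  }
  params
}

## tape building blocks -----------------------------------------------------

# Kernel-3 replicate-padded convolution mapping x (N, dh, Bh) to latent
# frequencies (Nyquist-squashed) and phases.
tp_conv_rot <- function(tape, pn, set, x) {
  d <- dim3(x$value)
  n <- d[1]
  im <- if (n == 1L) 1L else c(1L, 1L:(n - 1L))
  ip <- if (n == 1L) 1L else c(2L:n, n)
  raw <- tp_add(tape,
                tp_rmm(tape, tp_shift_cat(tape, x, im, ip),
                       pn[[paste0(set, "_A")]]),
                pn[[paste0(set, "_b")]])
  tp_freq_phase_f(tape, raw)
}

# Decoupled multi-head rotation attention. xq (N, d, B), xkv (L, d, B).
tp_attn_block <- function(tape, pn, prefix, xq, xkv, control, regs) {
  h <- control$n_heads
  B <- dim3(xq$value)[3]
  q <- tp_head_split(tape, tp_rmm(tape, xq, pn[[paste0(prefix, "_Wq")]]), h)
  k <- tp_head_split(tape, tp_rmm(tape, xkv, pn[[paste0(prefix, "_Wk")]]), h)
  v <- tp_head_split(tape, tp_rmm(tape, xkv, pn[[paste0(prefix, "_Wv")]]), h)
  mem <- tp_head_split(tape,
                       tp_bcastB(tape, pn[[paste0(prefix, "_mem")]], B), h)

  rp_m <- tp_conv_rot(tape, pn, paste0(prefix, "_rs1q"), mem)
  rp_k <- tp_conv_rot(tape, pn, paste0(prefix, "_rs1k"), k)
  m_prime <- tp_kernel_attention_f(tape,
                                   tp_rotate_f(tape, mem, rp_m$omega, rp_m$theta),
                                   tp_rotate_f(tape, k, rp_k$omega, rp_k$theta),
                                   v)

  rp_q <- tp_conv_rot(tape, pn, paste0(prefix, "_rs2q"), q)
  rp_mp <- tp_conv_rot(tape, pn, paste0(prefix, "_rs2k"), m_prime)
  hh <- tp_kernel_attention_f(tape,
                              tp_rotate_f(tape, q, rp_q$omega, rp_q$theta),
                              tp_rotate_f(tape, m_prime, rp_mp$omega, rp_mp$theta),
                              m_prime)

  for (rp in list(rp_m, rp_k, rp_q, rp_mp)) {
    regs$omegas[[length(regs$omegas) + 1L]] <- rp$omega
    regs$thetas[[length(regs$thetas) + 1L]] <- rp$theta
  }
  tp_rmm(tape, tp_head_merge(tape, hh, h), pn[[paste0(prefix, "_Wo")]])
}

tp_trend_norm <- function(tape, pn, prefix, x, eps = 1e-5) {
  n <- dim3(x$value)[1]
  proj <- tp_node(tape, trend_projector(n))  # plain matrix const for lmm
  tr <- tp_lmm(tape, proj, x)
  tp_trend_norm_f(tape, x, tr, pn[[paste0(prefix, "_gamma")]],
                  pn[[paste0(prefix, "_beta")]],
                  pn[[paste0(prefix, "_rho")]], eps = eps)
}

tp_ffn <- function(tape, pn, prefix, x) {
  hidden <- tp_relu(tape, tp_add(tape,
                                 tp_rmm(tape, x, pn[[paste0(prefix, "_W1")]]),
                                 pn[[paste0(prefix, "_b1")]]))
  tp_add(tape, tp_rmm(tape, hidden, pn[[paste0(prefix, "_W2")]]),
         pn[[paste0(prefix, "_b2")]])
}

# Full forward pass. xenc (input_len, F, B), xdec (label_len+horizon, F, B).
# Returns the standardized horizon predictions and regularizer node lists.
qf_forward <- function(tape, pn, xenc, xdec, control) {
  regs <- new.env(parent = emptyenv())
  regs$omegas <- list(); regs$thetas <- list()

  enc <- tp_add(tape, tp_rmm(tape, xenc, pn$enc_emb), pn$enc_emb_b)
  for (i in seq_len(control$enc_layers)) {
    pre <- paste0("enc", i)
    a <- tp_attn_block(tape, pn, paste0(pre, "_sa"), enc, enc, control, regs)
    enc <- tp_trend_norm(tape, pn, paste0(pre, "_tn1"),
                         tp_add(tape, enc, a))
    f <- tp_ffn(tape, pn, paste0(pre, "_ffn"), enc)
    enc <- tp_trend_norm(tape, pn, paste0(pre, "_tn2"),
                         tp_add(tape, enc, f))
  }

  dec <- tp_add(tape, tp_rmm(tape, xdec, pn$dec_emb), pn$dec_emb_b)
  for (i in seq_len(control$dec_layers)) {
    pre <- paste0("dec", i)
    a <- tp_attn_block(tape, pn, paste0(pre, "_sa"), dec, dec, control, regs)
    dec <- tp_trend_norm(tape, pn, paste0(pre, "_tn1"),
                         tp_add(tape, dec, a))
    x <- tp_attn_block(tape, pn, paste0(pre, "_ca"), dec, enc, control, regs)
    dec <- tp_trend_norm(tape, pn, paste0(pre, "_tn2"),
                         tp_add(tape, dec, x))
    f <- tp_ffn(tape, pn, paste0(pre, "_ffn"), dec)
    dec <- tp_trend_norm(tape, pn, paste0(pre, "_tn3"),
                         tp_add(tape, dec, f))
  }

  idx <- control$label_len + seq_len(control$horizon)
  pred <- tp_add(tape, tp_rmm(tape, tp_slice1(tape, dec, idx), pn$Wout),
                 pn$bout)
  list(pred = pred, omegas = regs$omegas, thetas = regs$thetas)
}

# Loss node: L_pred + lambda1 * mean(L_omega) + lambda2 * mean(L_theta).
qf_loss <- function(tape, fw, target, control) {
  tgt <- tp_const(tape, target)
  l_pred <- tp_mean_all(tape, tp_square(tape, tp_sub(tape, fw$pred, tgt)))
  loss <- l_pred
  l_om_val <- 0; l_th_val <- 0
  oms <- Filter(function(x) dim3(x$value)[1] >= 2L, fw$omegas)
  if (control$lambda1 > 0 && length(oms)) {
    acc <- NULL
    for (om in oms) {
      n <- dim3(om$value)[1]
      d <- tp_sub(tape, tp_slice1(tape, om, 2:n),
                  tp_slice1(tape, om, 1:(n - 1)))
      t <- tp_mean_all(tape, tp_square(tape, d))
      acc <- if (is.null(acc)) t else tp_add(tape, acc, t)
    }
    l_om <- tp_scale(tape, acc, 1 / length(oms))
    l_om_val <- as.numeric(l_om$value)
    loss <- tp_add(tape, loss, tp_scale(tape, l_om, control$lambda1))
  }
  if (control$lambda2 > 0 && length(fw$thetas)) {
    acc <- NULL
    for (th in fw$thetas) {
      t <- tp_mean_all(tape, tp_abs(tape, th))
      acc <- if (is.null(acc)) t else tp_add(tape, acc, t)
    }
    l_th <- tp_scale(tape, acc, 1 / length(fw$thetas))
    l_th_val <- as.numeric(l_th$value)
    loss <- tp_add(tape, loss, tp_scale(tape, l_th, control$lambda2))
  }
  list(loss = loss, l_pred = as.numeric(l_pred$value),
       l_omega = l_om_val, l_theta = l_th_val)
}

## batch assembly -----------------------------------------------------------

qf_batch <- function(windows, scaler, control) {
  B <- length(windows)
  nf <- 3L
  xenc <- array(0, c(control$input_len, nf, B))
  ld <- control$label_len + control$horizon
  xdec <- array(0, c(ld, nf, B))
  tgt <- array(0, c(control$horizon, 1L, B))
  for (b in seq_len(B)) {
    sw <- standardize_window(windows[[b]], scaler)
    xenc[, , b] <- sw$x
    lab <- sw$x[(control$input_len - control$label_len + 1L):control$input_len, ,
                drop = FALSE]
    xdec[seq_len(control$label_len), , b] <- lab
    # horizon placeholders: zero concentration, known covariates
    xdec[(control$label_len + 1L):ld, 2L, b] <- sw$x[1L, 2L]
    xdec[(control$label_len + 1L):ld, 3L, b] <- sw$x[1L, 3L]
    tgt[, , b] <- sw$y
  }
  list(xenc = xenc, xdec = xdec, target = tgt)
}

## optimizer ----------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim3(p))),
       v = lapply(params, function(p) array(0, dim3(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, clip, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  sc <- if (is.finite(gn) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  decayed <- if (weight_decay > 0) grepl("_W|emb$|Wout", names(params)) else NULL
  for (i in seq_along(params)) {
    nm <- names(params)[i]
    g <- grads[[nm]] * sc
    dim(g) <- dim3(params[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    dim(upd) <- dim(params[[nm]])
    params[[nm]] <- params[[nm]] - upd
    if (!is.null(decayed) && decayed[i])
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
  }
  list(params = params, state = state)
}

## training -----------------------------------------------------------------

qf_eval_lpred <- function(params, batch, control) {
  tape <- tape_new()
  pn <- lapply(params, function(p) tp_param(tape, p))
  fw <- qf_forward(tape, pn, tp_const(tape, batch$xenc),
                   tp_const(tape, batch$xdec), control)
  mean((as_cube(fw$pred$value) - batch$target)^2)
}

#' Train a rotation-attention forecaster on split windows
#'
#' Minimizes the prediction loss plus the frequency/phase regularizers by
#' mini-batch Adam with gradient clipping, early-stopping on validation
#' prediction loss. All randomness (initialization, shuffling) derives from
#' `control$seed`, so a fixed seed reproduces the loss history exactly.
#'
#' @param split A [split_windows()] result.
#' @param control A [quatformer_control()].
#' @return An object of class `quatformer` with elements `params`, `control`,
#'   `scaler`, `history` (per-epoch data frame with `l_pred`, `l_omega`,
#'   `l_theta`, `total`, `val_pred`), `best_epoch` and `trained`.
#' @export
train_quatformer <- function(split, control = quatformer_control()) {
  stopifnot(inherits(split, "window_split"))
  if (length(split$train) == 0L || length(split$val) == 0L)
    stop("training and validation partitions must be non-empty")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(control$seed)

  params <- qf_init_params(control)
  opt <- adam_new(params)
  val_batch <- qf_batch(split$val, split$scaler, control)
  train_all <- qf_batch(split$train, split$scaler, control)
  n_tr <- length(split$train)
  bs <- min(control$batch_size, n_tr)

  history <- vector("list", control$epochs)
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L
  lr_now <- control$learning_rate

  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(n_tr)
    ep_pred <- ep_om <- ep_th <- ep_tot <- 0
    n_batches <- 0L
    for (start in seq(1L, n_tr, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n_tr)]
      batch <- list(xenc = train_all$xenc[, , idx, drop = FALSE],
                    xdec = train_all$xdec[, , idx, drop = FALSE],
                    target = train_all$target[, , idx, drop = FALSE])
      tape <- tape_new()
      pn <- lapply(params, function(p) tp_param(tape, p))
      fw <- qf_forward(tape, pn, tp_const(tape, batch$xenc),
                       tp_const(tape, batch$xdec), control)
      ls <- qf_loss(tape, fw, batch$target, control)
      tot <- as.numeric(ls$loss$value)
      if (!is.finite(tot))
        stop("training loss diverged (non-finite) at epoch ", epoch)
      tape_backward(tape, ls$loss)
      grads <- lapply(pn, function(nd) {
        if (is.null(nd$grad)) array(0, dim3(nd$value)) else nd$grad
      })
      stepped <- adam_step(params, grads, opt, lr_now, control$clip,
                           control$weight_decay)
      params <- stepped$params
      opt <- stepped$state
      ep_pred <- ep_pred + ls$l_pred * length(idx)
      ep_om <- ep_om + ls$l_omega * length(idx)
      ep_th <- ep_th + ls$l_theta * length(idx)
      ep_tot <- ep_tot + tot * length(idx)
      n_batches <- n_batches + 1L
    }
    lr_now <- lr_now * control$lr_decay
    val_pred <- qf_eval_lpred(params, val_batch, control)
    history[[epoch]] <- data.frame(
      epoch = epoch, l_pred = ep_pred / n_tr, l_omega = ep_om / n_tr,
      l_theta = ep_th / n_tr, total = ep_tot / n_tr, val_pred = val_pred)
    if (is.finite(val_pred) && val_pred < best$val - 1e-12) {
      best <- list(val = val_pred, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }

  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  structure(list(params = if (best$epoch > 0L) best$params else params,
                 control = control, scaler = split$scaler,
                 history = history, best_epoch = best$epoch,
                 trained = control$epochs > 0L,
                 n_train = length(split$train), n_val = length(split$val),
                 n_test = length(split$test)),
            class = "quatformer")
}

#' Fit a rotation-attention residue forecaster
#'
#' High-level interface: windows the residue series, splits them
#' chronologically, and trains the forecaster. One model is normally fitted
#' per pesticide.
#'
#' @param series A `residue_series`, a list of them, or a long residue data
#'   frame (see [split_series()]).
#' @param control A [quatformer_control()].
#' @param fractions Train/validation/test fractions for [split_windows()].
#' @return A fitted `quatformer` object; the window split is attached as
#'   `$split`.
#' @examples
#' \donttest{
#' prof <- default_profiles(noise_sd = 0)[[1]]
#' s <- lapply(c(25, 30, 35, 40), function(tc)
#'   simulate_series(prof, storage_condition(tc, 65), seed = 1))
#' fit <- quatformer(s, quatformer_control(epochs = 2))
#' predict(fit)
#' }
#' @export
quatformer <- function(series, control = quatformer_control(),
                       fractions = c(0.7, 0.1, 0.2)) {
  if (is.data.frame(series)) series <- split_series(series)
  windows <- make_windows(series, control$input_len, control$horizon)
  split <- split_windows(windows, fractions)
  fit <- train_quatformer(split, control)
  fit$split <- split
  fit
}

#' Forecast residues with a fitted model
#'
#' Runs the encoder over each window's observed block and the decoder over
#' the replayed label steps plus zero placeholders with known covariates,
#' returning predictions de-standardized to mg/kg.
#'
#' @param object A fitted `quatformer`.
#' @param newdata A list of forecast windows, a single window, a
#'   `residue_series` (its trailing `input_len` observations are used), or
#'   `NULL` for the model's own test windows.
#' @param ... Unused.
#' @return A numeric matrix, one row per window, `horizon` columns, mg/kg.
#' @export
predict.quatformer <- function(object, newdata = NULL, ...) {
  if (!isTRUE(object$trained))
    warning("model has not been trained; predictions are arbitrary")
  windows <- newdata
  if (is.null(windows)) {
    if (is.null(object$split)) stop("no newdata and no stored test windows")
    windows <- object$split$test
  }
  if (inherits(windows, "residue_series")) {
    n <- length(windows$conc)
    il <- object$control$input_len
    if (n < il) stop("series shorter than input_len")
    windows <- list(structure(
      list(series_id = windows$pesticide, anchor = windows$days[n - il + 1L],
           conc = windows$conc[(n - il + 1L):n],
           temperature_C = windows$temperature_C, rh_pct = windows$rh_pct,
           target = rep(NA_real_, object$control$horizon)),
      class = "forecast_window"))
  }
  if (inherits(windows, "forecast_window")) windows <- list(windows)
  batch <- qf_batch(windows, object$scaler, object$control)
  tape <- tape_new()
  pn <- lapply(object$params, function(p) tp_param(tape, p))
  fw <- qf_forward(tape, pn, tp_const(tape, batch$xenc),
                   tp_const(tape, batch$xdec), object$control)
  z <- as_cube(fw$pred$value)
  out <- t(apply(z, 3L, function(m) m[, 1L]))
  if (object$control$horizon == 1L) out <- matrix(z[1L, 1L, ], ncol = 1L)
  destandardize_conc(out, object$scaler)
}

#' @export
print.quatformer <- function(x, ...) {
  cat(sprintf("<quatformer> d_model=%d heads=%d enc=%d dec=%d memory=%d\n",
              x$control$d_model, x$control$n_heads, x$control$enc_layers,
              x$control$dec_layers, x$control$memory_len))
  cat(sprintf("  windows: %d train / %d val / %d test; input_len=%d horizon=%d\n",
              x$n_train, x$n_val, x$n_test, x$control$input_len,
              x$control$horizon))
  if (!is.null(x$history) && nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs run, best epoch %d; final train L_pred=%.4g, val L_pred=%.4g\n",
                nrow(x$history), x$best_epoch, last$l_pred, last$val_pred))
  }
  invisible(x)
}

#' @export
summary.quatformer <- function(object, ...) {
  res <- NULL
  if (!is.null(object$split)) {
    y <- unlist(lapply(object$split$test, function(w) w$target))
    p <- as.vector(t(predict(object)))
    res <- evaluate_metrics(y, p)
  }
  out <- list(control = object$control, history = object$history,
              best_epoch = object$best_epoch, test_metrics = res)
  class(out) <- "summary.quatformer"
  out
}

#' @export
print.summary.quatformer <- function(x, ...) {
  cat("Rotation-attention residue forecaster\n")
  cat(sprintf("  best epoch: %d of %d run\n", x$best_epoch,
              if (is.null(x$history)) 0L else nrow(x$history)))
  if (!is.null(x$test_metrics)) {
    cat("  test-set accuracy (mg/kg):\n")
    print(x$test_metrics)
  }
  invisible(x)
}

#' @export
plot.quatformer <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history to plot")
  graphics::matplot(h$epoch, cbind(h$l_pred, h$val_pred), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "prediction loss (standardized)",
                    ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.quatformer <- function(object, ...) {
  if (is.null(object$split)) stop("model was not fitted through quatformer()")
  y <- unlist(lapply(object$split$train, function(w) w$target))
  p <- as.vector(t(predict(object, object$split$train)))
  y - p
}
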