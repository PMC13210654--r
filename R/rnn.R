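# Gated recurrent unit (GRU) sequence regressor with a linear multi-output
# head, trained by backpropagation through time with Adam. Written directly
# on base-R matrix algebra: batches are processed as (n x d) matrices, so one
# time step of one layer is a handful of matrix products regardless of batch
# size. Used to learn the STL remainder from lagged component + environment
# features.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
.gru_init <- function(input_dim, units, horizon) {
  layers <- vector("list", length(units))
  d <- input_dim
  for (l in seq_along(units)) {
    h <- units[l]
    s <- 1 / sqrt(h)
    layers[[l]] <- list(
      W = matrix(stats::runif(d * 3L * h, -s, s), d, 3L * h),
      U = matrix(stats::runif(h * 3L * h, -s, s), h, 3L * h),
      b = numeric(3L * h))
    d <- h
  }
  so <- 1 / sqrt(d)
  list(layers = layers,
       Wo = matrix(stats::runif(d * horizon, -so, so), d, horizon),
       bo = numeric(horizon),
       input_dim = input_dim, units = units, horizon = horizon)
}

# Forward pass. X: array (n, T, F). Returns yhat and, if cache, per-layer
# per-step activations needed for BPTT. masks: optional list of (n x H)
# inverted-dropout masks, one per layer (applied to that layer's output,
# constant across time).
#' @noRd
.gru_forward <- function(p, X, masks = NULL, cache = FALSE) {
  n <- dim(X)[1L]; Tn <- dim(X)[2L]
  caches <- if (cache) vector("list", length(p$layers))
  inp <- lapply(seq_len(Tn), function(t) matrix(X[, t, ], nrow = n))
  for (l in seq_along(p$layers)) {
    ly <- p$layers[[l]]
    H <- ncol(ly$U)
    h <- H / 3L
    zi <- seq_len(h); ri <- h + zi; ni <- 2L * h + zi
    hs <- matrix(0, n, h)
    out <- vector("list", Tn)
    cc <- if (cache) list(x = inp, z = vector("list", Tn), r = vector("list", Tn),
                          nn = vector("list", Tn), hprev = vector("list", Tn),
                          un = vector("list", Tn))
    for (t in seq_len(Tn)) {
      a <- inp[[t]] %*% ly$W
      a <- sweep(a, 2L, ly$b, "+")
      u <- hs %*% ly$U
      z <- .sigmoid(a[, zi, drop = FALSE] + u[, zi, drop = FALSE])
      r <- .sigmoid(a[, ri, drop = FALSE] + u[, ri, drop = FALSE])
      un <- u[, ni, drop = FALSE]
      nn <- tanh(a[, ni, drop = FALSE] + r * un)
      hnew <- (1 - z) * nn + z * hs
      if (cache) {
        cc$z[[t]] <- z; cc$r[[t]] <- r; cc$nn[[t]] <- nn
        cc$hprev[[t]] <- hs; cc$un[[t]] <- un
      }
      hs <- hnew
      out[[t]] <- hs
    }
    if (!is.null(masks)) {
      out <- lapply(out, function(o) o * masks[[l]])
      hs <- hs * masks[[l]]
    }
    if (cache) { cc$out <- out; caches[[l]] <- cc }
    inp <- out
  }
  yhat <- sweep(hs %*% p$Wo, 2L, p$bo, "+")
  list(yhat = yhat, caches = caches, h_last = hs)
}

# Backward pass for mean-squared-error loss. Returns gradients with the same
# structure as the parameter list.
#' @noRd
.gru_backward <- function(p, X, y, fwd, masks = NULL) {
  n <- dim(X)[1L]; Tn <- dim(X)[2L]
  g <- list(layers = vector("list", length(p$layers)))
  dY <- 2 * (fwd$yhat - y) / length(y)
  g$Wo <- crossprod(fwd$h_last, dY)
  g$bo <- colSums(dY)
  # dh on the (possibly dropout-masked) output of the top layer, last step
  dtop <- dY %*% t(p$Wo)
  nlay <- length(p$layers)
  # dh_out[[t]] for the current layer being processed (top first)
  dh_out <- vector("list", Tn)
  for (t in seq_len(Tn)) dh_out[[t]] <- matrix(0, n, ncol(dtop))
  dh_out[[Tn]] <- dtop
  for (l in rev(seq_len(nlay))) {
    ly <- p$layers[[l]]
    cc <- fwd$caches[[l]]
    h <- length(ly$b) / 3L
    zi <- seq_len(h); ri <- h + zi; ni <- 2L * h + zi
    dW <- matrix(0, nrow(ly$W), ncol(ly$W))
    dU <- matrix(0, h, 3L * h)
    db <- numeric(3L * h)
    dx_out <- vector("list", Tn)
    dh_carry <- matrix(0, n, h)
    for (t in rev(seq_len(Tn))) {
      dh <- dh_carry
      d_ext <- dh_out[[t]]
      if (!is.null(masks)) d_ext <- d_ext * masks[[l]]
      dh <- dh + d_ext
      z <- cc$z[[t]]; r <- cc$r[[t]]; nn <- cc$nn[[t]]
      hprev <- cc$hprev[[t]]; un <- cc$un[[t]]
      dz <- dh * (hprev - nn)
      dnn <- dh * (1 - z)
      dn_pre <- dnn * (1 - nn^2)
      dr <- dn_pre * un
      dz_pre <- dz * z * (1 - z)
      dr_pre <- dr * r * (1 - r)
      dA <- cbind(dz_pre, dr_pre, dn_pre)
      dUmat <- cbind(dz_pre, dr_pre, dn_pre * r)
      x_t <- cc$x[[t]]
      dW <- dW + crossprod(x_t, dA)
      dU <- dU + crossprod(hprev, dUmat)
      db <- db + colSums(dA)
      dx_out[[t]] <- dA %*% t(ly$W)
      dh_carry <- dh * z + dUmat %*% t(ly$U)
    }
    g$layers[[l]] <- list(W = dW, U = dU, b = db)
    dh_out <- dx_out
  }
  g
}

#' @noRd
.adam_state <- function(p) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(m = rapply(p[c("layers", "Wo", "bo")], zero_like, how = "replace"),
       v = rapply(p[c("layers", "Wo", "bo")], zero_like, how = "replace"),
       t = 0L)
}

#' @noRd
.adam_update <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  upd <- function(par, grad, m, v) {
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    mh <- m / (1 - beta1^st$t)
    vh <- v / (1 - beta2^st$t)
    list(par = par - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(p$layers)) {
    for (nm in c("W", "U", "b")) {
      u <- upd(p$layers[[l]][[nm]], g$layers[[l]][[nm]],
               st$m$layers[[l]][[nm]], st$v$layers[[l]][[nm]])
      p$layers[[l]][[nm]] <- u$par
      st$m$layers[[l]][[nm]] <- u$m; st$v$layers[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("Wo", "bo")) {
    u <- upd(p[[nm]], g[[nm]], st$m[[nm]], st$v[[nm]])
    p[[nm]] <- u$par
    st$m[[nm]] <- u$m; st$v[[nm]] <- u$v
  }
  list(p = p, st = st)
}

# Training loop: minibatch Adam on MSE with validation-based early stopping.
# x/y are normalized arrays; returns params, per-epoch log and best epoch.
#' @noRd
.gru_train <- function(x_train, y_train, x_val, y_val, units, horizon,
                       dropout = 0.2, lr = 1e-3, batch_size = 32L,
                       max_epochs = 100L, patience = 10L, seed = 42L) {
  set.seed(seed)
  n <- dim(x_train)[1L]
  p <- .gru_init(dim(x_train)[3L], units, horizon)
  st <- .adam_state(p)
  best <- list(val = Inf, p = p, epoch = 0L)
  log <- data.frame(epoch = integer(), train_mse = numeric(), val_mse = numeric())
  wait <- 0L
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0; seen <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      xb <- x_train[idx, , , drop = FALSE]
      yb <- y_train[idx, , drop = FALSE]
      masks <- NULL
      if (dropout > 0) {
        masks <- lapply(units, function(h)
          matrix(stats::rbinom(length(idx) * h, 1L, 1 - dropout) / (1 - dropout),
                 length(idx), h))
      }
      fwd <- .gru_forward(p, xb, masks = masks, cache = TRUE)
      loss <- mean((fwd$yhat - yb)^2)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep,
             " (learning rate too high or degenerate inputs)", call. = FALSE)
      g <- .gru_backward(p, xb, yb, fwd, masks = masks)
      au <- .adam_update(p, g, st, lr)
      p <- au$p; st <- au$st
      tr_loss <- tr_loss + loss * length(idx); seen <- seen + length(idx)
    }
    val_mse <- if (is.null(x_val) || dim(x_val)[1L] == 0L) NA_real_ else
      mean((.gru_forward(p, x_val)$yhat - y_val)^2)
    log <- rbind(log, data.frame(epoch = ep, train_mse = tr_loss / seen,
                                 val_mse = val_mse))
    if (!is.na(val_mse) && val_mse < best$val - 1e-12) {
      best <- list(val = val_mse, p = p, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (!is.na(val_mse) && wait >= patience) break
    }
  }
  if (is.finite(best$val)) p <- best$p else best$epoch <- nrow(log)
  list(params = p, log = log, best_epoch = best$epoch, seed = seed)
}
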