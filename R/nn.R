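# Internal neural-network engine for the CNN-LSTM quality classifier.
#
# Batches are held time-major: a (B, T, F) tensor is a (B*T) x F matrix whose
# rows for time slice t are ((t-1)*B + 1):(t*B). Every layer then reduces to
# BLAS matrix products, which keeps single-CPU training fast in plain R.
# Gradients are exact analytic backprop, verified against finite differences
# in the test suite.

time_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Shift the time axis by `offset` slices, zero-filling (for "same" padding).
shift_time <- function(H, B, Tn, offset) {
  if (offset == 0L) return(H)
  C <- ncol(H)
  out <- matrix(0, nrow(H), C)
  if (offset > 0L) {         # contributions from earlier slices
    out[(offset * B + 1L):(Tn * B), ] <- H[seq_len((Tn - offset) * B), ]
  } else {
    k <- -offset
    out[seq_len((Tn - k) * B), ] <- H[(k * B + 1L):(Tn * B), ]
  }
  out
}

glorot <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter initialization --------------------------------------------

nn_init_params <- function(config) {
  cb <- config$conv_blocks
  in_ch <- config$input_shape[2]
  par <- list(conv = list(), norm = list(mu = rep(0, in_ch), sd = rep(1, in_ch)))
  for (i in seq_along(cb)) {
    filters <- cb[[i]][1]
    kernel <- cb[[i]][2]
    par$conv[[i]] <- list(W = glorot(kernel * in_ch, filters),
                          b = rep(0, filters))
    in_ch <- filters
  }
  par$dense <- list(W = glorot(in_ch, config$dense_units),
                    b = rep(0, config$dense_units))
  u <- config$lstm_units
  par$lstm <- list(Wx = glorot(config$dense_units, 4L * u,
                               nrow = config$dense_units, ncol = 4L * u),
                   Wh = glorot(u, 4L * u, nrow = u, ncol = 4L * u),
                   b = rep(c(0, 1, 0, 0), each = u))  # forget-gate bias 1
  par$head <- list(W = glorot(u, config$head_units), b = rep(0, config$head_units))
  par$out <- list(W = glorot(config$head_units, config$output_units),
                  b = rep(0, config$output_units))
  par
}

nn_param_count <- function(par) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  cnt(par$conv) + cnt(par$dense) + cnt(par$lstm) + cnt(par$head) + cnt(par$out)
}

# ---- forward pass ---------------------------------------------------------

# X: (B*T) x F time-major matrix. Returns list(prob, loss?, cache).
nn_forward <- function(par, X, B, config, training = FALSE, y = NULL) {
  Tn <- nrow(X) / B
  stopifnot(Tn == round(Tn))
  Tn <- as.integer(Tn)
  cache <- list(B = B)

  H <- sweep(sweep(X, 2L, par$norm$mu), 2L, par$norm$sd, "/")
  cache$conv <- list()
  drop_rate <- if (training) config$dropout_rate else 0

  for (i in seq_along(par$conv)) {
    kernel <- config$conv_blocks[[i]][2]
    half <- (kernel - 1L) %/% 2L
    offs <- seq.int(-half, half)
    U <- do.call(cbind, lapply(offs, function(o) shift_time(H, B, Tn, o)))
    Z <- U %*% par$conv[[i]]$W
    Z <- sweep(Z, 2L, par$conv[[i]]$b, "+")
    A <- pmax(Z, 0)
    # max-pool over time (stride = width = pool_size), dropping the remainder
    p <- config$pool_size
    Tp <- Tn %/% p
    P <- matrix(-Inf, B * Tp, ncol(A))
    amax <- matrix(0L, B * Tp, ncol(A))
    for (j in seq_len(p)) {
      src <- A[as.vector(vapply(seq_len(Tp), function(tt) time_rows((tt - 1L) * p + j, B),
                                integer(B))), , drop = FALSE]
      upd <- src > P
      amax[upd] <- j
      P[upd] <- src[upd]
    }
    mask <- NULL
    if (drop_rate > 0) {
      mask <- matrix(stats::rbinom(length(P), 1L, 1 - drop_rate), nrow(P)) / (1 - drop_rate)
      P <- P * mask
    }
    cache$conv[[i]] <- list(U = U, Z = Z, amax = amax, Tin = Tn, Tp = Tp,
                            mask = mask, H_in_cols = ncol(H))
    H <- P
    Tn <- Tp
  }

  Zd <- sweep(H %*% par$dense$W, 2L, par$dense$b, "+")
  Ad <- pmax(Zd, 0)
  cache$dense <- list(H = H, Zd = Zd)

  # LSTM over the Tn remaining slices; final hidden state is the summary.
  u <- config$lstm_units
  h <- matrix(0, B, u)
  cc <- matrix(0, B, u)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- Ad[time_rows(t, B), , drop = FALSE]
    G <- Xt %*% par$lstm$Wx + h %*% par$lstm$Wh
    G <- sweep(G, 2L, par$lstm$b, "+")
    i_g <- sigmoid(G[, 1:u, drop = FALSE])
    f_g <- sigmoid(G[, (u + 1):(2 * u), drop = FALSE])
    g_g <- tanh(G[, (2 * u + 1):(3 * u), drop = FALSE])
    o_g <- sigmoid(G[, (3 * u + 1):(4 * u), drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    tc <- tanh(c_new)
    steps[[t]] <- list(Xt = Xt, h_prev = h, c_prev = cc, i = i_g, f = f_g,
                       g = g_g, o = o_g, tc = tc)
    cc <- c_new
    h <- o_g * tc
  }
  cache$lstm <- list(steps = steps, Tn = Tn)

  mask_h <- NULL
  hd <- h
  if (drop_rate > 0) {
    mask_h <- matrix(stats::rbinom(length(h), 1L, 1 - drop_rate), nrow(h)) / (1 - drop_rate)
    hd <- h * mask_h
  }
  Zh <- sweep(hd %*% par$head$W, 2L, par$head$b, "+")
  Ah <- pmax(Zh, 0)
  logits <- sweep(Ah %*% par$out$W, 2L, par$out$b, "+")
  cache$head <- list(hd = hd, mask_h = mask_h, Zh = Zh, Ah = Ah, logits = logits)

  if (config$output_units == 2L) {
    m <- apply(logits, 1L, max)
    e <- exp(logits - m)
    prob <- e / rowSums(e)            # column 2 = acceptable
    p_acc <- prob[, 2L]
  } else {
    prob <- sigmoid(logits)
    p_acc <- prob[, 1L]
  }
  loss <- NULL
  if (!is.null(y)) {                  # y in {0 unacceptable, 1 acceptable}
    eps <- 1e-12
    loss <- if (config$output_units == 2L) {
      -mean(log(pmax(prob[cbind(seq_len(B), y + 1L)], eps)))
    } else {
      -mean(y * log(pmax(p_acc, eps)) + (1 - y) * log(pmax(1 - p_acc, eps)))
    }
  }
  list(prob = prob, p_acceptable = p_acc, loss = loss, cache = cache)
}

# ---- backward pass --------------------------------------------------------

nn_backward <- function(par, fwd, y, config) {
  cache <- fwd$cache
  B <- cache$B
  grads <- list()

  if (config$output_units == 2L) {
    dlogits <- fwd$prob
    dlogits[cbind(seq_len(B), y + 1L)] <- dlogits[cbind(seq_len(B), y + 1L)] - 1
    dlogits <- dlogits / B
  } else {
    dlogits <- (fwd$prob - y) / B
  }
  hc <- cache$head
  grads$out <- list(W = t(hc$Ah) %*% dlogits, b = colSums(dlogits))
  dAh <- dlogits %*% t(par$out$W)
  dZh <- dAh * (hc$Zh > 0)
  grads$head <- list(W = t(hc$hd) %*% dZh, b = colSums(dZh))
  dh <- dZh %*% t(par$head$W)
  if (!is.null(hc$mask_h)) dh <- dh * hc$mask_h

  # LSTM BPTT from the final hidden state only.
  lc <- cache$lstm
  u <- config$lstm_units
  dWx <- matrix(0, nrow(par$lstm$Wx), 4L * u)
  dWh <- matrix(0, u, 4L * u)
  dbl <- rep(0, 4L * u)
  dc <- matrix(0, B, u)
  dAd <- matrix(0, B * lc$Tn, nrow(par$lstm$Wx))
  for (t in rev(seq_len(lc$Tn))) {
    st <- lc$steps[[t]]
    do_g <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dG <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_g * st$o * (1 - st$o))
    dWx <- dWx + t(st$Xt) %*% dG
    dWh <- dWh + t(st$h_prev) %*% dG
    dbl <- dbl + colSums(dG)
    dAd[time_rows(t, B), ] <- dG %*% t(par$lstm$Wx)
    dh <- dG %*% t(par$lstm$Wh)
    dc <- dc * st$f
  }
  grads$lstm <- list(Wx = dWx, Wh = dWh, b = dbl)

  dc_ <- cache$dense
  dZd <- dAd * (dc_$Zd > 0)
  grads$dense <- list(W = t(dc_$H) %*% dZd, b = colSums(dZd))
  dP <- dZd %*% t(par$dense$W)

  grads$conv <- vector("list", length(par$conv))
  for (i in rev(seq_along(par$conv))) {
    cv <- cache$conv[[i]]
    if (!is.null(cv$mask)) dP <- dP * cv$mask
    # un-pool: route gradient to the argmax slice
    dA <- matrix(0, B * cv$Tin, ncol(dP))
    for (j in seq_len(config$pool_size)) {
      rows_out <- which(cv$amax == j, arr.ind = TRUE)
      if (nrow(rows_out) == 0L) next
      tt <- (rows_out[, 1L] - 1L) %/% B + 1L       # pooled slice
      bb <- (rows_out[, 1L] - 1L) %% B + 1L
      src_row <- ((tt - 1L) * config$pool_size + j - 1L) * B + bb
      dA[cbind(src_row, rows_out[, 2L])] <-
        dA[cbind(src_row, rows_out[, 2L])] + dP[rows_out]
    }
    dZ <- dA * (cv$Z > 0)
    grads$conv[[i]] <- list(W = t(cv$U) %*% dZ, b = colSums(dZ))
    dU <- dZ %*% t(par$conv[[i]]$W)
    kernel <- config$conv_blocks[[i]][2]
    half <- (kernel - 1L) %/% 2L
    offs <- seq.int(-half, half)
    Cin <- cv$H_in_cols
    dH <- matrix(0, B * cv$Tin, Cin)
    for (k in seq_along(offs)) {
      block <- dU[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
      dH <- dH + shift_time(block, B, cv$Tin, -offs[k])
    }
    dP <- dH
  }
  grads$norm_input <- dP  # d loss / d normalized input (unused; norm is frozen)
  grads
}

# ---- Adam optimizer -------------------------------------------------------

adam_state <- function(par) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  trainable <- par[c("conv", "dense", "lstm", "head", "out")]
  list(m = zero_like(trainable), v = zero_like(trainable), t = 0L)
}

adam_update <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p) %||% seq_along(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (blk in c("conv", "dense", "lstm", "head", "out")) {
    r <- upd(par[[blk]], grads[[blk]], state$m[[blk]], state$v[[blk]])
    par[[blk]] <- r$p
    state$m[[blk]] <- r$m
    state$v[[blk]] <- r$v
  }
  list(par = par, state = state)
}
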