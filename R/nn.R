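# Minimal neural-network engine: 1x1 channel-mixing convolution, sigmoid,
# global max-pooling over time, dropout, (bi)LSTM (Rcpp kernel), ReLU and a
# linear read-out, with analytic gradients and an Adam optimiser. All
# forward/backward passes are deterministic given the R RNG state.

uinit <- function(nr, nc, fan_in) {
  k <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -k, k), nr, nc)
}

lstm_params <- function(input_size, hidden, prefix) {
  out <- list(
    uinit(input_size, 4L * hidden, hidden),
    uinit(hidden, 4L * hidden, hidden),
    matrix(runif(4L * hidden, -1 / sqrt(hidden), 1 / sqrt(hidden)), 1L))
  names(out) <- paste0(prefix, c("_Wx", "_Wh", "_b"))
  out
}

lstm_fwd <- function(X, params, prefix) {
  .lstm_forward_cpp(X, params[[paste0(prefix, "_Wx")]],
                    params[[paste0(prefix, "_Wh")]],
                    params[[paste0(prefix, "_b")]])
}

lstm_bwd <- function(X, params, prefix, cache, dH) {
  g <- .lstm_backward_cpp(X, params[[paste0(prefix, "_Wx")]],
                          params[[paste0(prefix, "_Wh")]],
                          cache$gates, cache$c, cache$h, dH)
  grads <- list(g$dWx, g$dWh, matrix(g$db, 1L))
  names(grads) <- paste0(prefix, c("_Wx", "_Wh", "_b"))
  list(grads = grads, dX = g$dX)
}

# conv 1x1 over channels + sigmoid + global max-pool over time.
# X: array N x C x T. Returns pooled N x F plus caches.
conv_pool_fwd <- function(X, Wc, bc) {
  d <- dim(X); N <- d[1]; C <- d[2]; T <- d[3]
  F <- nrow(Wc)
  Xp <- matrix(aperm(X, c(2, 3, 1)), C, T * N)     # C x (T*N)
  Y <- Wc %*% Xp + as.vector(bc)                   # F x (T*N)
  S <- 1 / (1 + exp(-Y))
  # layout (T, F*N) so each column is one (feature, sample) time course
  Sm <- matrix(aperm(array(S, c(F, T, N)), c(2, 1, 3)), T, F * N)
  Tm <- t(Sm)                                      # (F*N) x T
  am <- max.col(Tm, ties.method = "first")
  vals <- Tm[cbind(seq_len(F * N), am)]
  P <- t(matrix(vals, F, N))                       # N x F
  list(P = P, Xp = Xp, am = am, vals = vals, dims = c(N = N, C = C, T = T, F = F))
}

conv_pool_bwd <- function(cache, dP) {
  N <- cache$dims[["N"]]; C <- cache$dims[["C"]]
  T <- cache$dims[["T"]]; F <- cache$dims[["F"]]
  dvals <- as.vector(t(dP))                        # length F*N, f fastest
  dvals <- dvals * cache$vals * (1 - cache$vals)   # through the sigmoid
  dYm <- matrix(0, T, F * N)
  dYm[cbind(cache$am, seq_len(F * N))] <- dvals
  dY <- matrix(aperm(array(dYm, c(T, F, N)), c(2, 1, 3)), F, T * N)
  list(dWc = dY %*% t(cache$Xp), dbc = matrix(rowSums(dY), ncol = 1))
}

dropout_fwd <- function(P, p, train) {
  if (!train || p <= 0) return(list(out = P, mask = NULL))
  mask <- matrix(rbinom(length(P), 1L, 1 - p), nrow(P)) / (1 - p)
  list(out = P * mask, mask = mask)
}

relu <- function(x) pmax(x, 0)

softmax_xent <- function(logits, y) {
  # y: integer class ids 1..K
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  pr <- ez / rowSums(ez)
  n <- nrow(logits)
  loss <- -mean(log(pmax(pr[cbind(seq_len(n), y)], 1e-12)))
  dlogits <- pr
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n, prob = pr)
}

nn_init_params <- function(kind, spec) {
  C <- spec$input_channels; F <- spec$n_filters; H <- spec$hidden_units
  K <- spec$n_classes
  p <- list()
  if (kind %in% c("cnn_lstm", "cnn_only", "cnn_lstm_seq")) {
    p$Wc <- uinit(F, C, C)
    p$bc <- matrix(runif(F, -1 / sqrt(C), 1 / sqrt(C)), ncol = 1)
  }
  if (kind == "cnn_lstm") {
    p <- c(p, lstm_params(F, H, "fw"), lstm_params(F, H, "bw"))
    p$Wfc <- uinit(2L * H, K, 2L * H)
    p$bfc <- matrix(runif(K, -1 / sqrt(2 * H), 1 / sqrt(2 * H)), 1L)
  } else if (kind == "cnn_lstm_seq") {
    p <- c(p, lstm_params(F, H, "fw"), lstm_params(F, H, "bw"))
    p$Wfc <- uinit(2L * H, K, 2L * H)
    p$bfc <- matrix(runif(K, -1 / sqrt(2 * H), 1 / sqrt(2 * H)), 1L)
  } else if (kind == "cnn_only") {
    p$Wfc <- uinit(F, K, F)
    p$bfc <- matrix(runif(K, -1 / sqrt(F), 1 / sqrt(F)), 1L)
  } else if (kind == "lstm_only") {
    p <- c(p, lstm_params(C, H, "fw"), lstm_params(C, H, "bw"))
    p$Wfc <- uinit(2L * H, K, 2L * H)
    p$bfc <- matrix(runif(K, -1 / sqrt(2 * H), 1 / sqrt(2 * H)), 1L)
  } else {
    abort(sprintf("Unknown model kind '%s'.", kind))
  }
  p
}

nn_forward <- function(kind, params, X, spec, train = FALSE) {
  N <- dim(X)[1]
  cache <- list(kind = kind, train = train)
  if (kind %in% c("cnn_lstm", "cnn_only", "cnn_lstm_seq")) {
    if (dim(X)[3] != spec$time_steps) {
      abort(sprintf("Input has %d time steps but the pooling kernel expects %d.",
                    dim(X)[3], spec$time_steps))
    }
  }
  if (kind == "cnn_lstm") {
    cp <- conv_pool_fwd(X, params$Wc, params$bc)
    dp <- dropout_fwd(cp$P, spec$dropout_p, train)
    V <- array(dp$out, c(N, ncol(dp$out), 1L))     # length-1 sequence
    lf <- lstm_fwd(V, params, "fw")
    lb <- lstm_fwd(V, params, "bw")
    Hcat <- cbind(lf$h_last, lb$h_last)
    Z <- relu(Hcat)
    logits <- Z %*% params$Wfc + matrix(params$bfc, N, spec$n_classes, byrow = TRUE)
    cache <- c(cache, list(cp = cp, dp = dp, V = V, lf = lf, lb = lb,
                           Hcat = Hcat, Z = Z))
  } else if (kind == "cnn_lstm_seq") {
    # ablation variant: pooling after the LSTM instead of before it
    d <- dim(X); T <- d[3]
    cp <- conv_seq_fwd(X, params$Wc, params$bc)
    dp <- dropout_fwd(matrix(cp$S, N), spec$dropout_p, train)
    V <- array(dp$out, c(N, dim(cp$S)[2], T))
    lf <- lstm_fwd(V, params, "fw")
    lb <- lstm_fwd(Vrev <- V[, , T:1, drop = FALSE], params, "bw")
    Hall <- abind_h(lf$h, lb$h)                    # N x 2H x T
    mp <- time_maxpool_fwd(Hall)
    Z <- relu(mp$P)
    logits <- Z %*% params$Wfc + matrix(params$bfc, N, spec$n_classes, byrow = TRUE)
    cache <- c(cache, list(cp = cp, dp = dp, V = V, Vrev = Vrev, lf = lf,
                           lb = lb, mp = mp, Z = Z, T = T))
  } else if (kind == "cnn_only") {
    cp <- conv_pool_fwd(X, params$Wc, params$bc)
    dp <- dropout_fwd(cp$P, spec$dropout_p, train)
    Z <- dp$out
    logits <- Z %*% params$Wfc + matrix(params$bfc, N, spec$n_classes, byrow = TRUE)
    cache <- c(cache, list(cp = cp, dp = dp, Z = Z))
  } else if (kind == "lstm_only") {
    T <- dim(X)[3]
    lf <- lstm_fwd(X, params, "fw")
    lb <- lstm_fwd(Xrev <- X[, , T:1, drop = FALSE], params, "bw")
    Hcat <- cbind(lf$h_last, lb$h_last)
    Z <- relu(Hcat)
    logits <- Z %*% params$Wfc + matrix(params$bfc, N, spec$n_classes, byrow = TRUE)
    cache <- c(cache, list(X = X, Xrev = Xrev, lf = lf, lb = lb,
                           Hcat = Hcat, Z = Z, T = T))
  }
  cache$logits <- logits
  cache
}

nn_backward <- function(kind, params, X, cache, dlogits) {
  g <- list()
  N <- nrow(dlogits)
  g$Wfc <- t(cache$Z) %*% dlogits
  g$bfc <- matrix(colSums(dlogits), 1L)
  dZ <- dlogits %*% t(params$Wfc)
  if (kind == "cnn_lstm") {
    dH <- dZ * (cache$Hcat > 0)
    Hn <- ncol(dH) / 2L
    dHf <- array(dH[, seq_len(Hn)], c(N, Hn, 1L))
    dHb <- array(dH[, Hn + seq_len(Hn)], c(N, Hn, 1L))
    bf <- lstm_bwd(cache$V, params, "fw", cache$lf, dHf)
    bb <- lstm_bwd(cache$V, params, "bw", cache$lb, dHb)
    g <- c(g, bf$grads, bb$grads)
    dP <- matrix(bf$dX + bb$dX, N)
    if (!is.null(cache$dp$mask)) dP <- dP * cache$dp$mask
    g <- c(g, conv_pool_bwd(cache$cp, dP))
    names(g)[match(c("dWc", "dbc"), names(g))] <- c("Wc", "bc")
  } else if (kind == "cnn_lstm_seq") {
    dP <- dZ * (cache$mp$P > 0)
    dHall <- time_maxpool_bwd(cache$mp, dP)
    Hn <- dim(cache$lf$h)[2]
    # Hall holds the backward direction's states in its own processing
    # order, so its gradient slices need no re-reversal here.
    dHf <- dHall[, seq_len(Hn), , drop = FALSE]
    dHb <- dHall[, Hn + seq_len(Hn), , drop = FALSE]
    bf <- lstm_bwd(cache$V, params, "fw", cache$lf, dHf)
    bb <- lstm_bwd(cache$Vrev, params, "bw", cache$lb, dHb)
    g <- c(g, bf$grads, bb$grads)
    dV <- bf$dX + bb$dX[, , dim(bb$dX)[3]:1, drop = FALSE]
    dVm <- matrix(dV, N)
    if (!is.null(cache$dp$mask)) dVm <- dVm * cache$dp$mask
    g <- c(g, conv_seq_bwd(cache$cp, array(dVm, dim(dV))))
    names(g)[match(c("dWc", "dbc"), names(g))] <- c("Wc", "bc")
  } else if (kind == "cnn_only") {
    dP <- dZ
    if (!is.null(cache$dp$mask)) dP <- dP * cache$dp$mask
    g <- c(g, conv_pool_bwd(cache$cp, dP))
    names(g)[match(c("dWc", "dbc"), names(g))] <- c("Wc", "bc")
  } else if (kind == "lstm_only") {
    dH <- dZ * (cache$Hcat > 0)
    Hn <- ncol(dH) / 2L
    T <- cache$T
    dHf <- array(0, c(N, Hn, T)); dHf[, , T] <- dH[, seq_len(Hn)]
    dHb <- array(0, c(N, Hn, T)); dHb[, , T] <- dH[, Hn + seq_len(Hn)]
    bf <- lstm_bwd(cache$X, params, "fw", cache$lf, dHf)
    bb <- lstm_bwd(cache$Xrev, params, "bw", cache$lb, dHb)
    g <- c(g, bf$grads, bb$grads)
  }
  g
}

# conv 1x1 + sigmoid keeping the full time axis (for the pool-after-LSTM
# ablation). Returns S as array N x F x T.
conv_seq_fwd <- function(X, Wc, bc) {
  d <- dim(X); N <- d[1]; C <- d[2]; T <- d[3]
  F <- nrow(Wc)
  Xp <- matrix(aperm(X, c(2, 3, 1)), C, T * N)
  Y <- Wc %*% Xp + as.vector(bc)
  S <- 1 / (1 + exp(-Y))                    # F x (T*N)
  Sarr <- aperm(array(S, c(F, T, N)), c(3, 1, 2))
  list(S = Sarr, Sflat = S, Xp = Xp, dims = c(N = N, C = C, T = T, F = F))
}

conv_seq_bwd <- function(cache, dS) {
  # dS: N x F x T
  d <- cache$dims
  dSf <- matrix(aperm(dS, c(2, 3, 1)), d[["F"]], d[["T"]] * d[["N"]])
  dY <- dSf * cache$Sflat * (1 - cache$Sflat)
  list(dWc = dY %*% t(cache$Xp), dbc = matrix(rowSums(dY), ncol = 1))
}

abind_h <- function(a, b) {
  # bind two N x H x T cubes along the unit axis -> N x 2H x T
  d <- dim(a)
  out <- array(0, c(d[1], 2L * d[2], d[3]))
  out[, seq_len(d[2]), ] <- a
  out[, d[2] + seq_len(d[2]), ] <- b
  out
}

time_maxpool_fwd <- function(Hall) {
  d <- dim(Hall)                             # N x U x T
  M <- matrix(Hall, d[1] * d[2], d[3])
  am <- max.col(M, ties.method = "first")
  vals <- M[cbind(seq_len(nrow(M)), am)]
  list(P = matrix(vals, d[1], d[2]), am = am, dims = d)
}

time_maxpool_bwd <- function(cache, dP) {
  d <- cache$dims
  dM <- matrix(0, d[1] * d[2], d[3])
  dM[cbind(seq_len(nrow(dM)), cache$am)] <- as.vector(dP)
  array(dM, d)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

n_params <- function(params) sum(vapply(params, length, integer(1)))
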