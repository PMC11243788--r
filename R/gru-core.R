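# Internal numerical core: batched GRU encoder/decoder with Bahdanau
# attention, backpropagation through time, and ADAM. Everything is plain
# matrix algebra, vectorized over the batch so a full-batch epoch is a few
# hundred BLAS calls.
#
# GRU convention (Cho et al.):
#   z = sigma(Wz x + Uz h + bz); r = sigma(Wr x + Ur h + br)
#   n = tanh(Wn x + Un (r*h) + bn); h' = (1 - z)*h + z*n
# Decoder input at step t is [y_{t-1}; c_t] where c_t is the attention context
# (or the final encoder state for the attention-free baseline).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# parameter list; attention weights only when use_attention
init_params <- function(in_enc, hidden, use_attention) {
  in_dec <- 1L + hidden
  p <- list(
    enc_Wz = glorot(in_enc, hidden), enc_Wr = glorot(in_enc, hidden),
    enc_Wn = glorot(in_enc, hidden),
    enc_Uz = glorot(hidden, hidden), enc_Ur = glorot(hidden, hidden),
    enc_Un = glorot(hidden, hidden),
    enc_bz = numeric(hidden), enc_br = numeric(hidden), enc_bn = numeric(hidden),
    dec_Wz = glorot(in_dec, hidden), dec_Wr = glorot(in_dec, hidden),
    dec_Wn = glorot(in_dec, hidden),
    dec_Uz = glorot(hidden, hidden), dec_Ur = glorot(hidden, hidden),
    dec_Un = glorot(hidden, hidden),
    dec_bz = numeric(hidden), dec_br = numeric(hidden), dec_bn = numeric(hidden),
    out_w = glorot(hidden, 1L)[, 1L], out_b = 0
  )
  if (use_attention) {
    p$att_Ua <- glorot(hidden, hidden)
    p$att_Wa <- glorot(hidden, hidden)
    p$att_Va <- glorot(hidden, 1L)[, 1L]
  }
  p
}

n_parameters <- function(params) sum(vapply(params, length, integer(1)))

# weight/bias views for one GRU; bias rows are pre-expanded to batch matrices
gru_views <- function(p, prefix, B, H) {
  g <- function(nm) p[[paste0(prefix, nm)]]
  list(Wz = g("Wz"), Wr = g("Wr"), Wn = g("Wn"),
       Uz = g("Uz"), Ur = g("Ur"), Un = g("Un"),
       Bz = matrix(g("bz"), B, H, byrow = TRUE),
       Br = matrix(g("br"), B, H, byrow = TRUE),
       Bn = matrix(g("bn"), B, H, byrow = TRUE),
       nm = paste0(prefix, c("Wz", "Wr", "Wn", "Uz", "Ur", "Un",
                             "bz", "br", "bn")))
}

# one batched GRU step; returns new hidden plus the gate cache for backprop
gru_step <- function(x, h, v) {
  z <- sigmoid(x %*% v$Wz + h %*% v$Uz + v$Bz)
  r <- sigmoid(x %*% v$Wr + h %*% v$Ur + v$Br)
  rh <- r * h
  nt <- tanh(x %*% v$Wn + rh %*% v$Un + v$Bn)
  h_new <- (1 - z) * h + z * nt
  list(h = h_new, z = z, r = r, nt = nt, rh = rh, h_prev = h, x = x)
}

# backward through one GRU step. dh: gradient wrt the step's output hidden.
# Accumulates into grads (an environment); returns dh_prev and dx.
gru_back <- function(cache, dh, v, grads) {
  z <- cache$z; r <- cache$r; nt <- cache$nt
  h_prev <- cache$h_prev; x <- cache$x; rh <- cache$rh
  dz <- dh * (nt - h_prev)
  dnt <- dh * z
  dh_prev <- dh * (1 - z)
  dan <- dnt * (1 - nt^2)
  drh <- dan %*% t(v$Un)
  dr <- drh * h_prev
  dh_prev <- dh_prev + drh * r
  dar <- dr * r * (1 - r)
  daz <- dz * z * (1 - z)
  nm <- v$nm
  grads[[nm[1]]] <- grads[[nm[1]]] + crossprod(x, daz)
  grads[[nm[2]]] <- grads[[nm[2]]] + crossprod(x, dar)
  grads[[nm[3]]] <- grads[[nm[3]]] + crossprod(x, dan)
  grads[[nm[4]]] <- grads[[nm[4]]] + crossprod(h_prev, daz)
  grads[[nm[5]]] <- grads[[nm[5]]] + crossprod(h_prev, dar)
  grads[[nm[6]]] <- grads[[nm[6]]] + crossprod(rh, dan)
  grads[[nm[7]]] <- grads[[nm[7]]] + colSums(daz)
  grads[[nm[8]]] <- grads[[nm[8]]] + colSums(dar)
  grads[[nm[9]]] <- grads[[nm[9]]] + colSums(dan)
  dh_prev <- dh_prev + daz %*% t(v$Uz) + dar %*% t(v$Ur)
  dx <- daz %*% t(v$Wz) + dar %*% t(v$Wr) + dan %*% t(v$Wn)
  list(dh_prev = dh_prev, dx = dx)
}

row_max <- function(e) {
  m <- e[, 1L]
  for (j in seq_len(ncol(e))[-1L]) m <- pmax(m, e[, j])
  m
}

# Full forward pass.
# X: list over encoder steps j = 1..M of B x in_enc matrices.
# Y: B x L matrix of normalized targets (needed when teacher = TRUE).
# Returns predictions (B x L, normalized scale) and, when keep = TRUE, the
# caches required by net_backward.
net_forward <- function(params, X, L, Y = NULL, teacher = FALSE,
                        use_attention = TRUE, keep = FALSE) {
  M <- length(X)
  B <- nrow(X[[1]])
  H <- length(params$out_w)
  ev <- gru_views(params, "enc_", B, H)
  dv <- gru_views(params, "dec_", B, H)

  h <- matrix(0, B, H)
  enc_cache <- if (keep) vector("list", M) else NULL
  Hs <- vector("list", M)
  for (j in seq_len(M)) {
    st <- gru_step(X[[j]], h, ev)
    h <- st$h
    Hs[[j]] <- h
    if (keep) enc_cache[[j]] <- st
  }

  if (use_attention) {
    Hmat <- do.call(rbind, Hs)            # (M*B) x H, j-major blocks
    WaH <- Hmat %*% params$att_Wa
    repidx <- rep(seq_len(B), times = M)
  }

  s <- Hs[[M]]
  y_prev <- numeric(B)
  Yhat <- matrix(0, B, L)
  dec_cache <- if (keep) vector("list", L) else NULL
  alph <- if (keep && use_attention) vector("list", L) else NULL
  us <- if (keep && use_attention) vector("list", L) else NULL
  for (t in seq_len(L)) {
    if (use_attention) {
      u <- s %*% params$att_Ua
      A <- tanh(u[repidx, , drop = FALSE] + WaH)
      e <- matrix(A %*% params$att_Va, B, M)
      alpha <- exp(e - row_max(e))
      alpha <- alpha / .rowSums(alpha, B, M)
      ctx <- matrix(0, B, H)
      for (j in seq_len(M)) ctx <- ctx + alpha[, j] * Hs[[j]]
      if (keep) { alph[[t]] <- alpha; us[[t]] <- u }
    } else {
      ctx <- Hs[[M]]
    }
    xin <- cbind(y_prev, ctx)
    st <- gru_step(xin, s, dv)
    s <- st$h
    o <- as.numeric(s %*% params$out_w) + params$out_b
    yhat <- sigmoid(o)
    Yhat[, t] <- yhat
    if (keep) dec_cache[[t]] <- st
    y_prev <- if (teacher) Y[, t] else yhat
  }
  out <- list(Yhat = Yhat, M = M, B = B)
  if (keep) {
    out$enc_cache <- enc_cache
    out$dec_cache <- dec_cache
    out$Hs <- Hs
    out$alpha <- alph
    out$u <- us
    if (use_attention) { out$Hmat <- Hmat; out$WaH <- WaH; out$repidx <- repidx }
  }
  out
}

# loss value and gradient wrt the output pre-activation (logit)
loss_grad <- function(Yhat, Y, loss) {
  N <- length(Y)
  if (loss == "bce") {
    P <- pmin(pmax(Yhat, 1e-7), 1 - 1e-7)
    val <- -mean(Y * log(P) + (1 - Y) * log(1 - P))
    dO <- (Yhat - Y) / N
  } else {
    val <- mean((Yhat - Y)^2)
    dO <- 2 * (Yhat - Y) * Yhat * (1 - Yhat) / N
  }
  list(value = val, dO = dO)
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

# Backward pass for the full network. fw is net_forward(..., keep = TRUE)
# output; dO is the B x L gradient wrt the output logits. Under teacher
# forcing no gradient flows through y_prev (it was ground truth); in
# free-running mode y_prev = sigmoid(o_{t-1}) and the gradient is carried
# back through it.
net_backward <- function(params, fw, X, dO, use_attention = TRUE,
                         teacher = TRUE) {
  M <- fw$M; B <- fw$B; L <- ncol(dO)
  H <- length(params$out_w)
  ev <- gru_views(params, "enc_", B, H)
  dv <- gru_views(params, "dec_", B, H)
  grads <- list2env(zeros_like(params))

  MB <- M * B
  dHflat <- matrix(0, if (use_attention) MB else B, H)
  if (use_attention) dWaH <- matrix(0, MB, H)
  ds_next <- matrix(0, B, H)
  dy_carry <- numeric(B)
  for (t in rev(seq_len(L))) {
    st <- fw$dec_cache[[t]]
    do_t <- dO[, t]
    if (!teacher) {
      yh <- fw$Yhat[, t]
      do_t <- do_t + dy_carry * yh * (1 - yh)
    }
    grads$out_w <- grads$out_w + as.numeric(crossprod(st$h, do_t))
    grads$out_b <- grads$out_b + sum(do_t)
    ds <- ds_next + tcrossprod(do_t, params$out_w)
    bk <- gru_back(st, ds, dv, grads)
    dy_carry <- bk$dx[, 1L]
    dctx <- bk$dx[, -1L, drop = FALSE]
    if (use_attention) {
      alpha <- fw$alpha[[t]]
      avec <- as.vector(alpha)                      # j-major, matches Hmat
      Drep <- dctx[fw$repidx, , drop = FALSE]
      dalpha <- matrix(.rowSums(Drep * fw$Hmat, MB, H), B, M)
      dHflat <- dHflat + avec * Drep
      de <- alpha * (dalpha - .rowSums(alpha * dalpha, B, M))
      devec <- as.vector(de)
      A <- tanh(fw$u[[t]][fw$repidx, , drop = FALSE] + fw$WaH)
      grads$att_Va <- grads$att_Va + as.numeric(crossprod(A, devec))
      dAct <- tcrossprod(devec, params$att_Va) * (1 - A^2)
      du <- rowsum(dAct, group = fw$repidx)
      grads$att_Ua <- grads$att_Ua + crossprod(st$h_prev, du)
      bk$dh_prev <- bk$dh_prev + du %*% t(params$att_Ua)
      dWaH <- dWaH + dAct
    } else {
      dHflat <- dHflat + dctx
    }
    ds_next <- bk$dh_prev
  }

  if (use_attention) {
    grads$att_Wa <- grads$att_Wa + crossprod(fw$Hmat, dWaH)
    dHflat <- dHflat + dWaH %*% t(params$att_Wa)
    block <- function(j) dHflat[((j - 1L) * B + 1L):(j * B), , drop = FALSE]
  } else {
    block <- function(j) if (j == M) dHflat else matrix(0, B, H)
  }

  # decoder initial state was the final encoder hidden state
  dh_next <- ds_next
  for (j in rev(seq_len(M))) {
    dh <- block(j) + dh_next
    bk <- gru_back(fw$enc_cache[[j]], dh, ev, grads)
    dh_next <- bk$dh_prev
  }
  as.list(grads)[names(params)]
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# --- dataset <-> tensors ----------------------------------------------------

norm_channel <- function(x, mn, mx) {
  d <- mx - mn
  d[d == 0] <- 1
  (x - mn) / d
}

# build encoder input list and normalized target matrix from cycles
cycles_tensors <- function(cycles, stats, window = 20) {
  B <- length(cycles)
  L <- cycles[[1]]$L
  C <- length(cycles[[1]]$channels)
  n_win <- L %/% window
  M <- n_win * C
  X <- vector("list", M)
  for (m in seq_len(M)) X[[m]] <- matrix(0, B, window)
  Y <- matrix(0, B, L)
  arng <- stats$angle_max - stats$angle_min
  if (arng == 0) arng <- 1
  for (b in seq_len(B)) {
    cy <- cycles[[b]]
    emg <- cy$emg
    for (ch in seq_len(C))
      emg[, ch] <- norm_channel(emg[, ch], stats$emg_min[ch], stats$emg_max[ch])
    for (w in seq_len(n_win)) {
      rows <- ((w - 1L) * window + 1L):(w * window)
      for (ch in seq_len(C))
        X[[(w - 1L) * C + ch]][b, ] <- emg[rows, ch]
    }
    Y[b, ] <- (cy$angle - stats$angle_min) / arng
  }
  list(X = X, Y = Y, B = B, M = M, L = L)
}

denorm_angle <- function(Yhat, stats) {
  stats$angle_min + Yhat * (stats$angle_max - stats$angle_min)
}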