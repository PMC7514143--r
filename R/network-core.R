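# Batched forward pass (with cache) and backpropagation. All operations work
# on a mini-batch of fixed-length encoded instances; sequences are stored as
# lists over time of (B x dim) matrices, and convolution inputs as a
# (B*n x channels) matrix whose row block t holds timestep t.

#' Stack encoded instances into a mini-batch
#'
#' @param enc_list list of `ddi_encoded` objects sharing one `max_len`.
#' @return List with integer matrices `tok`, `d1`, `d2` (B x max_len),
#'   `label` (integer vector, may contain NA for unlabeled input), `B`, `n`.
#' @export
stack_instances <- function(enc_list) {
  B <- length(enc_list)
  stopifnot(B >= 1)
  n <- length(enc_list[[1]]$token_ids)
  list(tok = do.call(rbind, lapply(enc_list, `[[`, "token_ids")),
       d1 = do.call(rbind, lapply(enc_list, `[[`, "dist1")),
       d2 = do.call(rbind, lapply(enc_list, `[[`, "dist2")),
       label = vapply(enc_list, function(e) e$label_id %||% NA_integer_,
                      integer(1)),
       B = B, n = n)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# ---- recurrent cells --------------------------------------------------------

lstm_forward <- function(Wx, Wh, b, X, ord, B, H) {
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  Hout <- vector("list", length(X))
  cache <- vector("list", length(X))
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  i4 <- (3 * H + 1):(4 * H)
  for (t in ord) {
    z <- add_bias(X[[t]] %*% Wx + h %*% Wh, b)
    ig <- sigmoid(z[, i1, drop = FALSE])
    fg <- sigmoid(z[, i2, drop = FALSE])
    og <- sigmoid(z[, i3, drop = FALSE])
    gg <- tanh(z[, i4, drop = FALSE])
    c_new <- fg * cst + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    cache[[t]] <- list(x = X[[t]], h_prev = h, c_prev = cst,
                       i = ig, f = fg, o = og, g = gg, tc = tc)
    h <- h_new; cst <- c_new
    Hout[[t]] <- h_new
  }
  list(H = Hout, cache = cache)
}

lstm_backward <- function(Wx, Wh, cache, dH_ext, ord, B, H) {
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * H)
  dX <- vector("list", length(cache))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(ord)) {
    cc <- cache[[t]]
    dh <- dH_ext[[t]] + dh_next
    dog <- dh * cc$tc * cc$o * (1 - cc$o)
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    dig <- dc * cc$g * cc$i * (1 - cc$i)
    dfg <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dgg <- dc * cc$i * (1 - cc$g^2)
    dz <- cbind(dig, dfg, dog, dgg)
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
    dc_next <- dc * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

rnn_forward <- function(Wx, Wh, b, X, ord, B, H) {
  h <- matrix(0, B, H)
  Hout <- vector("list", length(X))
  cache <- vector("list", length(X))
  for (t in ord) {
    h_new <- tanh(add_bias(X[[t]] %*% Wx + h %*% Wh, b))
    cache[[t]] <- list(x = X[[t]], h_prev = h, h = h_new)
    h <- h_new
    Hout[[t]] <- h_new
  }
  list(H = Hout, cache = cache)
}

rnn_backward <- function(Wx, Wh, cache, dH_ext, ord, B, H) {
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(H)
  dX <- vector("list", length(cache))
  dh_next <- matrix(0, B, H)
  for (t in rev(ord)) {
    cc <- cache[[t]]
    dz <- (dH_ext[[t]] + dh_next) * (1 - cc$h^2)
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

cell_forward <- function(params, nm, cell_type, X, ord, B, H) {
  fn <- if (cell_type == "lstm") lstm_forward else rnn_forward
  fn(params[[paste0(nm, "_Wx")]], params[[paste0(nm, "_Wh")]],
     params[[paste0(nm, "_b")]], X, ord, B, H)
}

cell_backward <- function(params, nm, cell_type, cache, dH_ext, ord, B, H) {
  fn <- if (cell_type == "lstm") lstm_backward else rnn_backward
  fn(params[[paste0(nm, "_Wx")]], params[[paste0(nm, "_Wh")]],
     cache, dH_ext, ord, B, H)
}

# ---- context encoding -------------------------------------------------------

zero_like_list <- function(n, B, d) {
  z <- matrix(0, B, d)
  rep(list(z), n)
}

context_forward <- function(params, cfg, X, B) {
  n <- length(X)
  H <- cfg$hidden
  z <- matrix(0, B, cfg$n_w)
  if (cfg$context_mode == "causal") {
    XL <- c(list(z), X[-n])          # position i sees word i-1
    XR <- c(X[-1], list(z))          # position i sees word i+1
    l1 <- cell_forward(params, "cl1", cfg$cell_type, XL, 1:n, B, H)
    l2 <- cell_forward(params, "cl2", cfg$cell_type, XL, 1:n, B, H)
    r1 <- cell_forward(params, "cr1", cfg$cell_type, XR, n:1, B, H)
    r2 <- cell_forward(params, "cr2", cfg$cell_type, XR, n:1, B, H)
    el <- lapply(1:n, function(t) cbind(l1$H[[t]], l2$H[[t]]))
    er <- lapply(1:n, function(t) cbind(r1$H[[t]], r2$H[[t]]))
    list(el = el, er = er,
         cache = list(mode = "causal", l1 = l1$cache, l2 = l2$cache,
                      r1 = r1$cache, r2 = r2$cache))
  } else {
    f <- cell_forward(params, "cf", cfg$cell_type, X, 1:n, B, H)
    b <- cell_forward(params, "cb", cfg$cell_type, X, n:1, B, H)
    zh <- matrix(0, B, H)
    el <- lapply(1:n, function(t) {
      if (t == 1) cbind(zh, zh) else cbind(f$H[[t - 1]], b$H[[t - 1]])
    })
    er <- lapply(1:n, function(t) {
      if (t == n) cbind(zh, zh) else cbind(f$H[[t + 1]], b$H[[t + 1]])
    })
    list(el = el, er = er,
         cache = list(mode = "bilstm", f = f$cache, b = b$cache))
  }
}

context_backward <- function(params, cfg, cache, del, der, B) {
  n <- length(del)
  H <- cfg$hidden
  i1 <- 1:H; i2 <- (H + 1):(2 * H)
  col <- function(lst, idx) lapply(lst, function(m) m[, idx, drop = FALSE])
  grads <- list()
  dX <- zero_like_list(n, B, cfg$n_w)
  if (cache$mode == "causal") {
    for (spec in list(list(nm = "cl1", cc = cache$l1, d = col(del, i1),
                           ord = 1:n, shift = -1L),
                      list(nm = "cl2", cc = cache$l2, d = col(del, i2),
                           ord = 1:n, shift = -1L),
                      list(nm = "cr1", cc = cache$r1, d = col(der, i1),
                           ord = n:1, shift = +1L),
                      list(nm = "cr2", cc = cache$r2, d = col(der, i2),
                           ord = n:1, shift = +1L))) {
      bk <- cell_backward(params, spec$nm, cfg$cell_type, spec$cc, spec$d,
                          spec$ord, B, H)
      grads[[paste0(spec$nm, "_Wx")]] <- bk$dWx
      grads[[paste0(spec$nm, "_Wh")]] <- bk$dWh
      grads[[paste0(spec$nm, "_b")]] <- bk$db
      for (t in 1:n) {
        src <- t + spec$shift  # cell input at t is word embedding at src
        if (src >= 1 && src <= n) dX[[src]] <- dX[[src]] + bk$dX[[t]]
      }
    }
  } else {
    zh <- matrix(0, B, H)
    dHf <- rep(list(zh), n)
    dHb <- rep(list(zh), n)
    for (t in 1:n) {
      if (t + 1 <= n) {  # el[[t+1]] uses states at t
        dHf[[t]] <- dHf[[t]] + del[[t + 1]][, i1, drop = FALSE]
        dHb[[t]] <- dHb[[t]] + del[[t + 1]][, i2, drop = FALSE]
      }
      if (t - 1 >= 1) {  # er[[t-1]] uses states at t
        dHf[[t]] <- dHf[[t]] + der[[t - 1]][, i1, drop = FALSE]
        dHb[[t]] <- dHb[[t]] + der[[t - 1]][, i2, drop = FALSE]
      }
    }
    bf <- cell_backward(params, "cf", cfg$cell_type, cache$f, dHf, 1:n, B, H)
    bb <- cell_backward(params, "cb", cfg$cell_type, cache$b, dHb, n:1, B, H)
    grads$cf_Wx <- bf$dWx; grads$cf_Wh <- bf$dWh; grads$cf_b <- bf$db
    grads$cb_Wx <- bb$dWx; grads$cb_Wh <- bb$dWh; grads$cb_b <- bb$db
    for (t in 1:n) dX[[t]] <- bf$dX[[t]] + bb$dX[[t]]
  }
  list(grads = grads, dX = dX)
}

# ---- convolution towers -----------------------------------------------------

# Row block of timestep t inside a (B*n x channels) matrix.
blk <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Valid dilated window: output position i taps inputs i, i+d, ..., i+(k-1)d.
conv_out_len <- function(n, k, d) n - (k - 1L) * d

# Stride-w max pooling with argmax bookkeeping. A: (B, L, F) array.
pool_forward <- function(A, w) {
  B <- dim(A)[1]; L <- dim(A)[2]; F <- dim(A)[3]
  Lp <- as.integer(ceiling(L / w))
  out <- array(0, c(B, Lp, F))
  amax <- array(0L, c(B, Lp, F))
  for (j in seq_len(Lp)) {
    idxs <- ((j - 1L) * w + 1L):min(j * w, L)
    cur <- A[, idxs[1], , drop = FALSE]
    pos <- array(idxs[1], c(B, 1, F))
    for (q in idxs[-1]) {
      cand <- A[, q, , drop = FALSE]
      upd <- cand > cur           # ties keep the earliest position
      cur[upd] <- cand[upd]
      pos[upd] <- q
    }
    out[, j, ] <- cur
    amax[, j, ] <- pos
  }
  list(out = out, amax = amax, L = L)
}

pool_backward <- function(pool, dOut) {
  B <- dim(dOut)[1]; Lp <- dim(dOut)[2]; F <- dim(dOut)[3]
  dA <- array(0, c(B, pool$L, F))
  bb <- rep(seq_len(B), times = F)
  ff <- rep(seq_len(F), each = B)
  for (j in seq_len(Lp)) {
    dA[cbind(bb, as.vector(pool$amax[, j, ]), ff)] <-
      dA[cbind(bb, as.vector(pool$amax[, j, ]), ff)] + as.vector(dOut[, j, ])
  }
  dA
}

tower_forward <- function(params, cfg, tw, Ebig, B, n) {
  F <- cfg$n_filters
  W1 <- params[[paste0(tw$name, "_W1")]]
  b1 <- params[[paste0(tw$name, "_b1")]]
  W2 <- params[[paste0(tw$name, "_W2")]]
  b2 <- params[[paste0(tw$name, "_b2")]]
  k <- tw$k; d <- tw$d
  L1 <- conv_out_len(n, k, d)
  if (L1 < 1) stopf("sequence of length %d too short for filter %d, dilation %d",
                    n, k, d)
  # layer 1: valid dilated convolution + ReLU
  A1 <- array(0, c(B, L1, F))
  for (i in seq_len(L1)) {
    Wn <- do.call(cbind, lapply(0:(k - 1L),
                                function(j) Ebig[blk(i + j * d, B), , drop = FALSE]))
    A1[, i, ] <- pmax(add_bias(Wn %*% W1, b1), 0)
  }
  p1 <- pool_forward(A1, cfg$pool_w)
  Lp1 <- dim(p1$out)[2]
  # layer 2: same-padding dilated convolution + ReLU
  span <- (k - 1L) * d
  padL <- span %/% 2L
  A2 <- array(0, c(B, Lp1, F))
  for (i in seq_len(Lp1)) {
    Z <- matrix(rep(b2, each = B), B, F)
    for (j in 0:(k - 1L)) {
      src <- i + j * d - padL
      if (src >= 1 && src <= Lp1) {
        Z <- Z + matrix(p1$out[, src, ], B, F) %*%
          W2[(j * F + 1L):((j + 1L) * F), , drop = FALSE]
      }
    }
    A2[, i, ] <- pmax(Z, 0)
  }
  p2 <- pool_forward(A2, cfg$pool_w)
  Lp2 <- dim(p2$out)[2]
  # global max pool over the remaining positions
  g <- matrix(p2$out[, 1, ], B, F)
  gpos <- matrix(1L, B, F)
  if (Lp2 > 1) {
    for (q in 2:Lp2) {
      cand <- matrix(p2$out[, q, ], B, F)
      upd <- cand > g
      g[upd] <- cand[upd]
      gpos[upd] <- q
    }
  }
  list(g = g, cache = list(A1 = A1, p1 = p1, A2 = A2, p2 = p2, gpos = gpos,
                           L1 = L1, Lp1 = Lp1, Lp2 = Lp2, k = k, d = d,
                           padL = padL))
}

tower_backward <- function(params, cfg, tw, cache, dg, Ebig, B, n) {
  F <- cfg$n_filters
  W1 <- params[[paste0(tw$name, "_W1")]]
  W2 <- params[[paste0(tw$name, "_W2")]]
  k <- cache$k; d <- cache$d; padL <- cache$padL
  # global max pool
  dP2 <- array(0, c(B, cache$Lp2, F))
  bb <- rep(seq_len(B), times = F)
  ff <- rep(seq_len(F), each = B)
  dP2[cbind(bb, as.vector(cache$gpos), ff)] <- as.vector(dg)
  dA2 <- pool_backward(cache$p2, dP2)
  # layer 2
  dA2 <- dA2 * (cache$A2 > 0)
  dW2 <- matrix(0, nrow(W2), ncol(W2))
  db2 <- numeric(F)
  dP1out <- array(0, c(B, cache$Lp1, F))
  for (i in seq_len(cache$Lp1)) {
    dz <- matrix(dA2[, i, ], B, F)
    db2 <- db2 + colSums(dz)
    for (j in 0:(k - 1L)) {
      src <- i + j * d - padL
      if (src >= 1 && src <= cache$Lp1) {
        rows <- (j * F + 1L):((j + 1L) * F)
        dW2[rows, ] <- dW2[rows, ] +
          crossprod(matrix(cache$p1$out[, src, ], B, F), dz)
        dP1out[, src, ] <- dP1out[, src, ] +
          dz %*% t(W2[rows, , drop = FALSE])
      }
    }
  }
  dA1 <- pool_backward(cache$p1, dP1out)
  # layer 1
  dA1 <- dA1 * (cache$A1 > 0)
  dW1 <- matrix(0, nrow(W1), ncol(W1))
  db1 <- numeric(F)
  dE <- matrix(0, B * n, ncol(Ebig))
  for (i in seq_len(cache$L1)) {
    dz <- matrix(dA1[, i, ], B, F)
    db1 <- db1 + colSums(dz)
    Wn <- do.call(cbind, lapply(0:(k - 1L),
                                function(j) Ebig[blk(i + j * d, B), , drop = FALSE]))
    dW1 <- dW1 + crossprod(Wn, dz)
    dWn <- dz %*% t(W1)
    ne <- ncol(Ebig)
    for (j in 0:(k - 1L)) {
      dE[blk(i + j * d, B), ] <- dE[blk(i + j * d, B), ] +
        dWn[, (j * ne + 1L):((j + 1L) * ne), drop = FALSE]
    }
  }
  g <- list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
  names(g) <- paste0(tw$name, c("_W1", "_b1", "_W2", "_b2"))
  list(grads = g, dE = dE)
}

# ---- full network -----------------------------------------------------------

# Forward pass over a stacked batch. Returns class probabilities and, when
# keep_cache, everything backward() needs.
net_forward <- function(model, batch, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  params <- model$params
  d <- config_dims(cfg)
  B <- batch$B; n <- batch$n
  X <- lapply(seq_len(n), function(t)
    params$Ew[batch$tok[, t] + 1L, , drop = FALSE])
  ctx <- context_forward(params, cfg, X, B)
  bigS <- do.call(rbind, lapply(seq_len(n), function(t)
    cbind(ctx$el[[t]], X[[t]], ctx$er[[t]])))
  Es <- if (cfg$fusion) add_bias(bigS %*% params$Ws, params$bs) else bigS
  idx1 <- as.vector(batch$d1) + 1L
  idx2 <- as.vector(batch$d2) + 1L
  Ebig <- cbind(Es, params$Ep1[idx1, , drop = FALSE],
                params$Ep2[idx2, , drop = FALSE])
  towers <- lapply(d$towers, function(tw) tower_forward(params, cfg, tw,
                                                        Ebig, B, n))
  s <- do.call(cbind, lapply(towers, `[[`, "g"))
  mask <- NULL
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix((stats::runif(length(s)) < keep) / keep, nrow(s), ncol(s))
    s_used <- s * mask
  } else {
    s_used <- s
  }
  logits <- add_bias(s_used %*% params$Wo, params$bo)
  zmax <- apply(logits, 1, max)
  ez <- exp(logits - zmax)
  probs <- ez / rowSums(ez)
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(X = X, ctx = ctx, bigS = bigS, Ebig = Ebig,
                      towers = towers, s = s, s_used = s_used, mask = mask,
                      idx1 = idx1, idx2 = idx2, B = B, n = n)
  }
  out
}

# Backward pass from the gradient w.r.t. the logits; returns a flat named
# list of parameter gradients matching model$params.
net_backward <- function(model, batch, cache, dlogits) {
  cfg <- model$config
  params <- model$params
  d <- config_dims(cfg)
  B <- cache$B; n <- cache$n
  grads <- list()
  grads$Wo <- crossprod(cache$s_used, dlogits)
  grads$bo <- colSums(dlogits)
  ds <- dlogits %*% t(params$Wo)
  if (!is.null(cache$mask)) ds <- ds * cache$mask
  dEbig <- matrix(0, B * n, ncol(cache$Ebig))
  F <- cfg$n_filters
  for (ti in seq_along(d$towers)) {
    tw <- d$towers[[ti]]
    cols <- ((ti - 1L) * F + 1L):(ti * F)
    tb <- tower_backward(params, cfg, tw, cache$towers[[ti]]$cache,
                         ds[, cols, drop = FALSE], cache$Ebig, B, n)
    grads <- c(grads, tb$grads)
    dEbig <- dEbig + tb$dE
  }
  n_sem <- d$n_sem
  dEs <- dEbig[, 1:n_sem, drop = FALSE]
  dP1 <- dEbig[, (n_sem + 1L):(n_sem + cfg$n_d), drop = FALSE]
  dP2 <- dEbig[, (n_sem + cfg$n_d + 1L):(n_sem + 2L * cfg$n_d), drop = FALSE]
  grads$Ep1 <- scatter_rows(dP1, cache$idx1, nrow(params$Ep1))
  grads$Ep2 <- scatter_rows(dP2, cache$idx2, nrow(params$Ep2))
  if (cfg$fusion) {
    grads$Ws <- crossprod(cache$bigS, dEs)
    grads$bs <- colSums(dEs)
    dbigS <- dEs %*% t(params$Ws)
  } else {
    dbigS <- dEs
  }
  n_l <- d$n_l
  del <- lapply(seq_len(n), function(t)
    dbigS[blk(t, B), 1:n_l, drop = FALSE])
  dXf <- lapply(seq_len(n), function(t)
    dbigS[blk(t, B), (n_l + 1L):(n_l + cfg$n_w), drop = FALSE])
  der <- lapply(seq_len(n), function(t)
    dbigS[blk(t, B), (n_l + cfg$n_w + 1L):(2L * n_l + cfg$n_w), drop = FALSE])
  cb <- context_backward(params, cfg, cache$ctx$cache, del, der, B)
  grads <- c(grads, cb$grads)
  dX <- lapply(seq_len(n), function(t) dXf[[t]] + cb$dX[[t]])
  dXbig <- do.call(rbind, dX)
  grads$Ew <- scatter_rows(dXbig, as.vector(batch$tok) + 1L, nrow(params$Ew))
  grads
}

# Mean improved focal loss and its parameter gradients for a stacked batch.
net_loss_grads <- function(model, batch, loss_cfg, train = TRUE) {
  fw <- net_forward(model, batch, train = train, keep_cache = TRUE)
  loss <- mean(improved_focal_loss(fw$probs, batch$label, loss_cfg))
  dlogits <- focal_grad_logits(fw$probs, batch$label, loss_cfg)
  grads <- net_backward(model, batch, fw$cache, dlogits)
  list(loss = loss, grads = grads, probs = fw$probs)
}
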