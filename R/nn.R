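# Minimal CPU neural-network primitives.
#
# Feature maps for a single image are arrays of shape (C, H, W); batches are
# arrays of shape (B, C, H, W). Convolutions are evaluated as im2col gathers
# followed by a BLAS matrix multiply; the gather index is computed once per
# geometry and cached. Backward passes are analytic and are checked against
# finite differences in the test suite.

.plan_cache <- new.env(parent = emptyenv())

# Precomputed transpose of the im2col gather: for each touched position of
# the padded input, the (at most maxc) entries of the column matrix that
# accumulate into it. Turns the backward scatter-add into a vectorized
# gather + rowSums.
make_scatter <- function(idx_vec) {
  o <- order(idx_vec)
  r <- rle(idx_vec[o])
  maxc <- max(r$lengths)
  n_u <- length(r$values)
  M <- matrix(length(idx_vec) + 1L, n_u, maxc)
  M[cbind(rep.int(seq_len(n_u), r$lengths), sequence(r$lengths))] <- o
  list(targets = r$values, index = M)
}

col2im <- function(dcol, plan, total) {
  v <- c(dcol, 0)
  dxp <- numeric(total)
  sc <- plan$scatter
  dxp[sc$targets] <- rowSums(matrix(v[sc$index], nrow(sc$index)))
  dxp
}

conv2d_plan <- function(Cin, H, W, K, stride, pad) {
  key <- paste("c2", Cin, H, W, K, stride, pad, sep = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  stopifnot(Hp >= K, Wp >= K)
  Hout <- (Hp - K) %/% stride + 1L
  Wout <- (Wp - K) %/% stride + 1L
  off <- expand.grid(ci = seq_len(Cin), ky = seq_len(K), kx = seq_len(K))
  out <- expand.grid(oy = seq_len(Hout), ox = seq_len(Wout))
  Y <- outer(off$ky, (out$oy - 1L) * stride, "+")
  X <- outer(off$kx, (out$ox - 1L) * stride, "+")
  idx <- off$ci + Cin * ((Y - 1L) + Hp * (X - 1L))
  plan <- list(idx = idx, R = nrow(off), P = nrow(out), Hp = Hp, Wp = Wp,
               Hout = Hout, Wout = Wout, Cin = Cin, H = H, W = W, pad = pad,
               scatter = make_scatter(c(idx)))
  .plan_cache[[key]] <- plan
  plan
}

conv3d_plan <- function(Cin, D, H, W, Kd, Kh, Kw, stride, pad) {
  key <- paste("c3", Cin, D, H, W, Kd, Kh, Kw,
               paste(stride, collapse = "."), paste(pad, collapse = "."), sep = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  Dp <- D + 2L * pad[1L]; Hp <- H + 2L * pad[2L]; Wp <- W + 2L * pad[3L]
  stopifnot(Dp >= Kd, Hp >= Kh, Wp >= Kw)
  Dout <- (Dp - Kd) %/% stride[1L] + 1L
  Hout <- (Hp - Kh) %/% stride[2L] + 1L
  Wout <- (Wp - Kw) %/% stride[3L] + 1L
  off <- expand.grid(ci = seq_len(Cin), kd = seq_len(Kd),
                     ky = seq_len(Kh), kx = seq_len(Kw))
  out <- expand.grid(od = seq_len(Dout), oy = seq_len(Hout), ox = seq_len(Wout))
  Dd <- outer(off$kd, (out$od - 1L) * stride[1L], "+")
  Y <- outer(off$ky, (out$oy - 1L) * stride[2L], "+")
  X <- outer(off$kx, (out$ox - 1L) * stride[3L], "+")
  idx <- off$ci + Cin * ((Dd - 1L) + Dp * ((Y - 1L) + Hp * (X - 1L)))
  plan <- list(idx = idx, R = nrow(off), P = nrow(out), Dp = Dp, Hp = Hp, Wp = Wp,
               Dout = Dout, Hout = Hout, Wout = Wout,
               Cin = Cin, D = D, H = H, W = W, pad = pad,
               scatter = make_scatter(c(idx)))
  .plan_cache[[key]] <- plan
  plan
}

# x: (Cin, H, W); W_: (Cout, Cin, K, K); returns list(out, col, plan) with
# out: (Cout, Hout, Wout)
conv2d_fwd <- function(x, W_, b, stride = 2L, pad = 1L) {
  dW <- dim(W_)
  plan <- conv2d_plan(dW[2L], dim(x)[2L], dim(x)[3L], dW[3L], stride, pad)
  xp <- array(0, c(plan$Cin, plan$Hp, plan$Wp))
  xp[, plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W)] <- x
  col <- matrix(xp[plan$idx], plan$R, plan$P)
  y <- matrix(W_, dW[1L], plan$R) %*% col + b
  list(out = array(y, c(dW[1L], plan$Hout, plan$Wout)), col = col, plan = plan)
}

conv2d_bwd <- function(dy, fwd, W_, need_dx = TRUE) {
  dW <- dim(W_)
  plan <- fwd$plan
  dyM <- matrix(dy, dW[1L], plan$P)
  gW <- array(dyM %*% t(fwd$col), dW)
  gb <- rowSums(dyM)
  if (!need_dx) return(list(dx = NULL, gW = gW, gb = gb))
  dcol <- t(matrix(W_, dW[1L], plan$R)) %*% dyM
  dxp <- col2im(dcol, plan, plan$Cin * plan$Hp * plan$Wp)
  dxp <- array(dxp, c(plan$Cin, plan$Hp, plan$Wp))
  dx <- dxp[, plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), drop = FALSE]
  list(dx = array(dx, c(plan$Cin, plan$H, plan$W)), gW = gW, gb = gb)
}

# x: (Cin, D, H, W); W_: (Cout, Cin, Kd, Kh, Kw); stride (sd, sh, sw);
# default padding keeps each dimension's "same" geometry before striding
conv3d_fwd <- function(x, W_, b, stride = c(1L, 2L, 2L), pad = NULL) {
  dW <- dim(W_)
  if (is.null(pad)) pad <- (dW[3:5] - 1L) %/% 2L
  dx <- dim(x)
  plan <- conv3d_plan(dW[2L], dx[2L], dx[3L], dx[4L], dW[3L], dW[4L], dW[5L],
                      as.integer(stride), as.integer(pad))
  xp <- array(0, c(plan$Cin, plan$Dp, plan$Hp, plan$Wp))
  xp[, plan$pad[1L] + seq_len(plan$D), plan$pad[2L] + seq_len(plan$H),
     plan$pad[3L] + seq_len(plan$W)] <- x
  col <- matrix(xp[plan$idx], plan$R, plan$P)
  y <- matrix(W_, dW[1L], plan$R) %*% col + b
  list(out = array(y, c(dW[1L], plan$Dout, plan$Hout, plan$Wout)),
       col = col, plan = plan)
}

conv3d_bwd <- function(dy, fwd, W_, need_dx = TRUE) {
  dW <- dim(W_)
  plan <- fwd$plan
  dyM <- matrix(dy, dW[1L], plan$P)
  gW <- array(dyM %*% t(fwd$col), dW)
  gb <- rowSums(dyM)
  if (!need_dx) return(list(dx = NULL, gW = gW, gb = gb))
  dcol <- t(matrix(W_, dW[1L], plan$R)) %*% dyM
  dxp <- col2im(dcol, plan, plan$Cin * plan$Dp * plan$Hp * plan$Wp)
  dxp <- array(dxp, c(plan$Cin, plan$Dp, plan$Hp, plan$Wp))
  dx <- dxp[, plan$pad[1L] + seq_len(plan$D), plan$pad[2L] + seq_len(plan$H),
            plan$pad[3L] + seq_len(plan$W), drop = FALSE]
  list(dx = array(dx, c(plan$Cin, plan$D, plan$H, plan$W)), gW = gW, gb = gb)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_bwd <- function(x, dy) {
  s <- sigmoid(x)
  dy * (s * (1 + x * (1 - s)))
}

# softmax over the channel axis (axis = "channel") or over all spatial
# positions within each channel (axis = "spatial") of a (C, H, W) array
softmax3 <- function(x, axis = "channel") {
  d <- dim(x)
  xm <- matrix(x, d[1L])
  if (axis == "channel") {
    mx <- do.call(pmax, asplit(xm, 1L))
    e <- exp(xm - rep(mx, each = d[1L]))
    s <- e / rep(colSums(e), each = d[1L])
  } else {
    mx <- apply(xm, 1L, max)
    e <- exp(xm - mx)
    s <- e / rowSums(e)
  }
  array(s, d)
}

softmax3_bwd <- function(s, dy, axis = "channel") {
  d <- dim(s)
  sm <- matrix(s, d[1L]); dm <- matrix(dy, d[1L])
  if (axis == "channel") {
    dot <- colSums(sm * dm)
    dx <- sm * (dm - rep(dot, each = d[1L]))
  } else {
    dot <- rowSums(sm * dm)
    dx <- sm * (dm - dot)
  }
  array(dx, d)
}

# max pool over the depth axis of a (C, D, H, W) array
depth_maxpool_fwd <- function(x) {
  d <- dim(x)
  out <- array(x[, 1L, , ], c(d[1L], d[3L], d[4L]))
  arg <- array(1L, c(d[1L], d[3L], d[4L]))
  if (d[2L] > 1L) {
    for (k in 2:d[2L]) {
      xi <- array(x[, k, , ], c(d[1L], d[3L], d[4L]))
      upd <- xi > out
      out[upd] <- xi[upd]
      arg[upd] <- k
    }
  }
  list(out = out, arg = arg, d = d)
}

depth_maxpool_bwd <- function(dy, fwd) {
  dx <- array(0, fwd$d)
  for (k in seq_len(fwd$d[2L])) {
    sel <- fwd$arg == k
    slice <- array(0, fwd$d[c(1L, 3L, 4L)])
    slice[sel] <- dy[sel]
    dx[, k, , ] <- slice
  }
  dx
}

# 2x2 stride-2 spatial max pooling on a (C, H, W) array (H, W even)
maxpool2_fwd <- function(x) {
  d <- dim(x)
  h2 <- d[2L] %/% 2L; w2 <- d[3L] %/% 2L
  out <- array(-Inf, c(d[1L], h2, w2))
  arg <- array(1L, c(d[1L], h2, w2))
  k <- 0L
  for (dxo in 0:1) for (dyo in 0:1) {
    k <- k + 1L
    ck <- array(x[, seq_len(h2) * 2L - 1L + dyo, seq_len(w2) * 2L - 1L + dxo],
                c(d[1L], h2, w2))
    upd <- ck > out
    out[upd] <- ck[upd]
    arg[upd] <- k
  }
  list(out = out, arg = arg, d = d)
}

maxpool2_bwd <- function(dy, fwd) {
  d <- fwd$d
  h2 <- d[2L] %/% 2L; w2 <- d[3L] %/% 2L
  dx <- array(0, d)
  k <- 0L
  for (dxo in 0:1) for (dyo in 0:1) {
    k <- k + 1L
    sel <- fwd$arg == k
    slice <- array(0, c(d[1L], h2, w2))
    slice[sel] <- dy[sel]
    cur <- array(dx[, seq_len(h2) * 2L - 1L + dyo, seq_len(w2) * 2L - 1L + dxo],
                 c(d[1L], h2, w2))
    dx[, seq_len(h2) * 2L - 1L + dyo, seq_len(w2) * 2L - 1L + dxo] <- cur + slice
  }
  dx
}

he_init <- function(dims) {
  fan_in <- prod(dims[-1L])
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# Adam over a flat named list of parameter arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
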