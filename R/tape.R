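# Minimal reverse-mode autodiff over 3-D arrays (position x channel x batch),
# enough to train the rotation-attention forecaster. Values are "cubes";
# shared weights are plain matrices. Internal; not part of the package API.

dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) c(1L, 1L, length(x))
  else if (length(d) == 2L) c(d, 1L)
  else d
}

as_cube <- function(x) {
  if (length(dim(x)) == 3L) x else array(x, dim = dim3(x))
}

# Broadcast x (dims all equal to d or 1) up to dims d.
bcast_to <- function(x, d) {
  x <- as_cube(x)
  dx <- dim(x)
  if (all(dx == d)) return(x)
  ix <- lapply(1:3, function(i) {
    if (dx[i] == d[i]) seq_len(d[i])
    else if (dx[i] == 1L) rep(1L, d[i])
    else stop("cannot broadcast dim ", i, ": ", dx[i], " -> ", d[i])
  })
  x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# Sum over dim i, keeping it as length 1.
sum_keepdim <- function(g, i) {
  d <- dim(g)
  perm <- c(i, setdiff(1:3, i))
  m <- aperm(g, perm)
  dim(m) <- c(d[i], prod(d[-i]))
  out <- array(colSums(m), dim = c(1L, d[-i]))
  aperm(out, order(perm))
}

# Reduce a broadcasted gradient back to the original dims d.
reduce_to <- function(g, d) {
  for (i in 1:3) if (d[i] == 1L && dim(g)[i] > 1L) g <- sum_keepdim(g, i)
  g
}

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

tp_const <- function(tape, value) tp_node(tape, as_cube(value))
tp_param <- function(tape, value) tp_node(tape, value)  # matrix or cube leaf

tape_backward <- function(tape, loss) {
  loss$grad <- array(1, dim = dim3(loss$value))
  for (i in tape$n:1L) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (is.null(gs[[j]])) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(NULL)
}

## elementwise binary ops with broadcasting ---------------------------------

tp_add <- function(tape, a, b) {
  da <- dim3(a$value); db <- dim3(b$value)
  d <- pmax(da, db)
  tp_node(tape, bcast_to(a$value, d) + bcast_to(b$value, d), list(a, b),
          function(g) list(reduce_to(g, da), reduce_to(g, db)))
}

tp_sub <- function(tape, a, b) {
  da <- dim3(a$value); db <- dim3(b$value)
  d <- pmax(da, db)
  tp_node(tape, bcast_to(a$value, d) - bcast_to(b$value, d), list(a, b),
          function(g) list(reduce_to(g, da), reduce_to(-g, db)))
}

tp_scale <- function(tape, a, s) {
  tp_node(tape, a$value * s, list(a), function(g) list(g * s))
}

## unary ops ----------------------------------------------------------------

tp_relu <- function(tape, a) {
  m <- a$value > 0
  tp_node(tape, a$value * m, list(a), function(g) list(g * m))
}

tp_square <- function(tape, a) {
  av <- a$value
  tp_node(tape, av^2, list(a), function(g) list(2 * g * av))
}

tp_abs <- function(tape, a) {
  s <- sign(a$value)
  tp_node(tape, abs(a$value), list(a), function(g) list(g * s))
}

## matrix products ----------------------------------------------------------

# x: (N,K,B) cube node; w: (K,M) matrix param node.
tp_rmm <- function(tape, x, w) {
  xv <- as_cube(x$value); wv <- w$value
  tp_node(tape, rmm_cpp(xv, wv, FALSE), list(x, w),
          function(g) list(rmm_cpp(g, wv, TRUE), rmm_grad_cpp(xv, g)))
}

# p: (M,N) matrix node (param or const); x: (N,D,B) cube node.
tp_lmm <- function(tape, p, x) {
  pv <- p$value; xv <- as_cube(x$value)
  tp_node(tape, lmm_cpp(pv, xv, FALSE), list(p, x),
          function(g) list(lmm_grad_cpp(g, xv), lmm_cpp(pv, g, TRUE)))
}

## structural ops -----------------------------------------------------------

tp_slice1 <- function(tape, x, idx) {
  d <- dim3(x$value)
  tp_node(tape, as_cube(x$value)[idx, , , drop = FALSE], list(x),
          function(g) {
            g0 <- array(0, d)
            for (j in seq_along(idx))
              g0[idx[j], , ] <- g0[idx[j], , ] + g[j, , ]
            list(g0)
          })
}

tp_mean_all <- function(tape, x) {
  d <- dim3(x$value)
  n <- prod(d)
  tp_node(tape, array(sum(x$value) / n, c(1L, 1L, 1L)), list(x),
          function(g) list(array(as.numeric(g) / n, d)))
}

# Replicate a (c,d) matrix param across B batch slices.
tp_bcastB <- function(tape, w, B) {
  dw <- dim(w$value)
  tp_node(tape, array(w$value, c(dw, B)), list(w),
          function(g) list(apply(g, c(1, 2), sum)))
}

# Fold h heads into the batch dimension: (N, d, B) -> (N, d/h, B*h).
# Head hh of batch slice b lands in slice (hh-1)*B + b; realized as a
# permuted reshape, since (channel, head) and (batch, head) both flatten
# column-major.
tp_head_split <- function(tape, x, h) {
  d <- dim3(x$value)
  dh <- d[2] %/% h
  v <- as_cube(x$value)
  dim(v) <- c(d[1], dh, h, d[3])
  out <- aperm(v, c(1L, 2L, 4L, 3L))
  dim(out) <- c(d[1], dh, d[3] * h)
  tp_node(tape, out, list(x), function(g) {
    dim(g) <- c(d[1], dh, d[3], h)
    g0 <- aperm(g, c(1L, 2L, 4L, 3L))
    dim(g0) <- d
    list(g0)
  })
}

# Inverse of tp_head_split: (N, dh, B*h) -> (N, dh*h, B).
tp_head_merge <- function(tape, x, h) {
  d <- dim3(x$value)
  B <- d[3] %/% h
  v <- as_cube(x$value)
  dim(v) <- c(d[1], d[2], B, h)
  out <- aperm(v, c(1L, 2L, 4L, 3L))
  dim(out) <- c(d[1], d[2] * h, B)
  tp_node(tape, out, list(x), function(g) {
    dim(g) <- c(d[1], d[2], h, B)
    g0 <- aperm(g, c(1L, 2L, 4L, 3L))
    dim(g0) <- d
    list(g0)
  })
}

# Concatenate x with its replicate-padded shifts along channels:
# out = [x[im,,], x, x[ip,,]] with width 3*D, feeding one stacked
# convolution weight.
tp_shift_cat <- function(tape, x, im, ip) {
  v <- as_cube(x$value)
  d <- dim(v)
  out <- array(0, c(d[1], 3L * d[2], d[3]))
  out[, seq_len(d[2]), ] <- v[im, , , drop = FALSE]
  out[, d[2] + seq_len(d[2]), ] <- v
  out[, 2L * d[2] + seq_len(d[2]), ] <- v[ip, , , drop = FALSE]
  tp_node(tape, out, list(x), function(g) {
    g0 <- g[, d[2] + seq_len(d[2]), , drop = FALSE]
    gm <- g[, seq_len(d[2]), , drop = FALSE]
    gp <- g[, 2L * d[2] + seq_len(d[2]), , drop = FALSE]
    for (j in seq_along(im)) g0[im[j], , ] <- g0[im[j], , ] + gm[j, , ]
    for (j in seq_along(ip)) g0[ip[j], , ] <- g0[ip[j], , ] + gp[j, , ]
    list(g0)
  })
}

## fused composite ops ------------------------------------------------------
## Hand-derived backward passes for the hot paths of the forecaster; each
## replaces a chain of elementary nodes.

# Rotate channel pairs of x (N, 2P, Bh) by angle 2*pi*omega*m + theta,
# omega/theta (N, P, Bh), m = 0-based position.
tp_rotate_f <- function(tape, x, omega, theta) {
  xv <- as_cube(x$value)
  d <- dim(xv); n <- d[1]; P <- d[2] %/% 2L
  ov <- as_cube(omega$value); tv <- as_cube(theta$value)
  m <- array(0:(n - 1), dim(ov))
  ang <- 2 * pi * ov * m + tv
  ca <- cos(ang); sa <- sin(ang)
  ev <- seq(1L, d[2], by = 2L); od <- ev + 1L
  xe <- xv[, ev, , drop = FALSE]; xo <- xv[, od, , drop = FALSE]
  out <- array(0, d)
  oe <- xe * ca - xo * sa
  oo <- xe * sa + xo * ca
  out[, ev, ] <- oe
  out[, od, ] <- oo
  tp_node(tape, out, list(x, omega, theta), function(g) {
    ge <- g[, ev, , drop = FALSE]; go <- g[, od, , drop = FALSE]
    gx <- array(0, d)
    gx[, ev, ] <- ge * ca + go * sa
    gx[, od, ] <- -ge * sa + go * ca
    dang <- -ge * oo + go * oe
    list(gx, dang * 2 * pi * m, dang)
  })
}

# Softmax-kernel attention on rotated inputs: out = W v with
# W = S / rowsum(S), S = exp(qr kr^T / sqrt(dh)).
tp_kernel_attention_f <- function(tape, qr, kr, v) {
  qv <- as_cube(qr$value); kv <- as_cube(kr$value); vv <- as_cube(v$value)
  dh <- dim(qv)[2]
  s <- exp(bmm_cpp(qv, kv, FALSE, TRUE) / sqrt(dh))
  r <- sum_keepdim(s, 2L)
  w <- s / bcast_to(r, dim(s))
  out <- bmm_cpp(w, vv, FALSE, FALSE)
  tp_node(tape, out, list(qr, kr, v), function(g) {
    gv <- bmm_cpp(w, g, TRUE, FALSE)
    gw <- bmm_cpp(g, vv, FALSE, TRUE)
    inner <- sum_keepdim(gw * w, 2L)
    # dA = (dW - rowsum(dW o W)) o W / sqrt(dh), A = qr kr^T / sqrt(dh)
    ga <- (gw - bcast_to(inner, dim(s))) * w / sqrt(dh)
    list(bmm_cpp(ga, kv, FALSE, FALSE), bmm_cpp(ga, qv, TRUE, FALSE), gv)
  })
}

# Squash the convolution output into frequencies and phases:
# omega = 0.5 * sigmoid(raw[, 1:P, ]), theta = pi * tanh(raw[, P+1:2P, ]).
tp_freq_phase_f <- function(tape, raw) {
  rv <- as_cube(raw$value)
  P <- dim(rv)[2] %/% 2L
  i1 <- seq_len(P); i2 <- P + i1
  sig <- 1 / (1 + exp(-rv[, i1, , drop = FALSE]))
  th <- tanh(rv[, i2, , drop = FALSE])
  omega <- tp_node(tape, 0.5 * sig, list(raw), function(g) {
    g0 <- array(0, dim(rv))
    g0[, i1, ] <- g * 0.5 * sig * (1 - sig)
    list(g0)
  })
  theta <- tp_node(tape, pi * th, list(raw), function(g) {
    g0 <- array(0, dim(rv))
    g0[, i2, ] <- g * pi * (1 - th^2)
    list(g0)
  })
  list(omega = omega, theta = theta)
}

# Trend normalization given the fitted trend: out = gamma * z + beta +
# rho * tr with z = (x - tr) / (s + eps), s = sqrt(mean_pos((x-tr)^2) + f).
tp_trend_norm_f <- function(tape, x, tr, gamma, beta, rho, eps = 1e-5,
                            floor = 1e-12) {
  xv <- as_cube(x$value); trv <- as_cube(tr$value)
  d <- dim(xv); n <- d[1]
  r <- xv - trv
  s <- sqrt(sum_keepdim(r^2, 1L) / n + floor)
  den <- bcast_to(s + eps, d)
  z <- r / den
  gv <- as_cube(gamma$value); bv <- as_cube(beta$value)
  rv <- as_cube(rho$value)
  gb <- bcast_to(gv, d)
  out <- gb * z + bcast_to(bv, d) + bcast_to(rv, d) * trv
  tp_node(tape, out, list(x, tr, gamma, beta, rho), function(g) {
    dgamma <- reduce_to(g * z, dim3(gamma$value))
    dbeta <- reduce_to(g, dim3(beta$value))
    drho <- reduce_to(g * trv, dim3(rho$value))
    dz <- g * gb
    dr <- dz / den
    ds <- sum_keepdim(dz * (-r) / den^2, 1L)   # d/ds with den = s + eps
    dr <- dr + bcast_to(ds / s, d) * r / n
    list(dr, -dr + g * bcast_to(rv, d), dgamma, dbeta, drho)
  })
}
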