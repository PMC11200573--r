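# Minimal reverse-mode automatic differentiation over 4-d arrays
# (H, W, C, N layout).  A tape records nodes in forward order; backward walks
# the tape in reverse, accumulating gradients into parent nodes.  Trainable
# parameters are environments ("pm") wrapped into leaf nodes once per tape so
# that repeated use of a network within one loss accumulates into one grad.
#
# This core exists because the degradation-enhancement / super-resolution
# architecture, its losses, and its staged training ARE the substance of the
# package; everything is sized for CPU-scale experiments.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t$pcache <- new.env(parent = emptyenv())
  t
}

ag_node <- function(tape, value, parents = list(), backfn = NULL, pm = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  nd$pm <- pm
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_const <- function(tape, x) ag_node(tape, x)

# trainable parameter: value plus optimizer state, group tag and identity
new_param <- function(value, group = "main", name = "") {
  pm <- new.env(parent = emptyenv())
  pm$value <- value
  pm$group <- group
  pm$name <- name
  pm$m <- NULL        # AdamW first moment
  pm$v <- NULL        # AdamW second moment
  pm$t <- 0L          # AdamW step counter
  .uwf_state$param_uid <- .uwf_state$param_uid + 1L
  pm$uid <- sprintf("p%08d@%s", .uwf_state$param_uid, .uwf_state$session)
  pm
}

# wrap a parameter as a leaf node, cached per tape
ag_wrap <- function(tape, pm) {
  nd <- tape$pcache[[pm$uid]]
  if (!is.null(nd)) return(nd)
  nd <- ag_node(tape, pm$value, pm = pm)
  tape$pcache[[pm$uid]] <- nd
  nd
}

# run backward from a scalar loss node; afterwards parameter-node grads are
# available via ag_param_grads()
ag_backward <- function(loss) {
  tape <- loss$tape
  loss$grad <- 1
  for (i in seq(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      if (is.null(gs[[k]])) next
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(NULL)
}

# gradients of all parameters touched by the tape, named by pm uid
ag_param_grads <- function(tape) {
  out <- list()
  for (uid in ls(tape$pcache)) {
    nd <- tape$pcache[[uid]]
    if (!is.null(nd$grad)) out[[uid]] <- list(pm = nd$pm, grad = nd$grad)
  }
  out
}

## ---- elementwise and reduction ops ----------------------------------------

ag_add <- function(a, b) {
  ag_node(a$tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$tape, a$value - b$value, list(a, b),
          function(g) list(g, -g))
}

ag_scale <- function(a, s) {
  ag_node(a$tape, a$value * s, list(a), function(g) list(g * s))
}

ag_lrelu <- function(a, slope = 0.2) {
  x <- a$value
  y <- ifelse(x > 0, x, slope * x)
  ag_node(a$tape, y, list(a),
          function(g) list(g * ifelse(x > 0, 1, slope)))
}

# PReLU with one learnable slope per channel (dim 3 of H,W,C,N)
ag_prelu <- function(a, alpha_pm) {
  tape <- a$tape
  an <- ag_wrap(tape, alpha_pm)
  x <- a$value
  d <- dim(x)
  aarr <- array(rep(an$value, each = d[1L] * d[2L]), dim = d)
  y <- ifelse(x > 0, x, aarr * x)
  ag_node(tape, y, list(a, an), function(g) {
    dx <- g * ifelse(x > 0, 1, aarr)
    neg <- g * x * (x <= 0)
    dim(neg) <- c(d[1L] * d[2L], d[3L], d[4L])
    da <- rowSums(colSums(neg))          # sum over H*W then N -> length C
    list(dx, da)
  })
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  ag_node(a$tape, y, list(a), function(g) list(g * y * (1 - y)))
}

# log with lower clamp; positions at the clamp get zero gradient
ag_log <- function(a, eps = 1e-7) {
  x <- pmax(a$value, eps)
  ag_node(a$tape, log(x), list(a),
          function(g) list(g / x * (a$value > eps)))
}

ag_one_minus <- function(a) {
  ag_node(a$tape, 1 - a$value, list(a), function(g) list(-g))
}

ag_mean <- function(a) {
  n <- length(a$value)
  ag_node(a$tape, mean(a$value), list(a),
          function(g) list(array(g / n, dim = dim(a$value) %||% n)))
}

# mean |a - b| (L1)
ag_mean_abs_diff <- function(a, b) {
  d <- a$value - b$value
  n <- length(d)
  ag_node(a$tape, mean(abs(d)), list(a, b), function(g) {
    s <- sign(d) * (g / n)
    list(s, -s)
  })
}

# mean (a - b)^2 (L2 / MSE)
ag_mean_sq_diff <- function(a, b) {
  d <- a$value - b$value
  n <- length(d)
  ag_node(a$tape, mean(d * d), list(a, b), function(g) {
    s <- 2 * d * (g / n)
    list(s, -s)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## ---- shape ops -------------------------------------------------------------

# zero-pad the bottom/right spatial borders (used to make sizes divisible)
ag_pad_br <- function(a, pb, pr) {
  if (pb == 0L && pr == 0L) return(a)
  d <- dim(a$value)
  out <- array(0, dim = c(d[1L] + pb, d[2L] + pr, d[3L], d[4L]))
  out[seq_len(d[1L]), seq_len(d[2L]), , ] <- a$value
  ag_node(a$tape, out, list(a), function(g) {
    list(g[seq_len(d[1L]), seq_len(d[2L]), , , drop = FALSE])
  })
}

ag_crop <- function(a, H, W) {
  d <- dim(a$value)
  if (d[1L] == H && d[2L] == W) return(a)
  ag_node(a$tape, a$value[seq_len(H), seq_len(W), , , drop = FALSE], list(a),
          function(g) {
            out <- array(0, dim = d)
            out[seq_len(H), seq_len(W), , ] <- g
            list(out)
          })
}

# embed x on the even-index grid of a (2H+2) x (2W+2) zero canvas; a stride-1
# valid 3x3 convolution of the result realises a stride-2 transposed
# convolution with padding 1 and output padding 1 (output exactly 2H x 2W)
ag_zero_embed2 <- function(a) {
  d <- dim(a$value)
  H <- d[1L]; W <- d[2L]
  ri <- seq(2L, 2L * H, by = 2L)
  ci <- seq(2L, 2L * W, by = 2L)
  out <- array(0, dim = c(2L * H + 2L, 2L * W + 2L, d[3L], d[4L]))
  out[ri, ci, , ] <- a$value
  ag_node(a$tape, out, list(a),
          function(g) list(g[ri, ci, , , drop = FALSE]))
}

## ---- convolution -----------------------------------------------------------

# cached gather indices for im2col: linear indices into an Hp x Wp plane,
# one row per output position (oy fastest), one column per kernel offset
# (ky fastest, then kx)
conv_indices <- function(Hp, Wp, k, stride, Ho, Wo, dil = 1L) {
  key <- paste(Hp, Wp, k, stride, Ho, Wo, dil, sep = "_")
  idx <- .uwf_state$im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  top <- (oy - 1L) * stride
  left <- (ox - 1L) * stride
  idx <- matrix(0L, Ho * Wo, k * k)
  col <- 0L
  for (kx in seq_len(k)) {
    for (ky in seq_len(k)) {
      col <- col + 1L
      idx[, col] <- (top + (ky - 1L) * dil + 1L) +
        (left + (kx - 1L) * dil) * Hp
    }
  }
  .uwf_state$im2col_cache[[key]] <- idx
  idx
}

# 2-d convolution; w_pm$value is a (k*k*Cin) x Cout matrix with rows ordered
# (ky, kx, cin), b_pm$value a length-Cout vector (or NULL for no bias)
ag_conv2d <- function(a, w_pm, b_pm = NULL, stride = 1L, pad = 0L,
                      dil = 1L) {
  tape <- a$tape
  wn <- ag_wrap(tape, w_pm)
  bn <- if (!is.null(b_pm)) ag_wrap(tape, b_pm)
  x <- a$value
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  k <- attr(w_pm$value, "k")
  Cout <- ncol(w_pm$value)
  ke <- (k - 1L) * dil + 1L                          # dilated kernel extent
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - ke) %/% stride + 1L
  Wo <- (Wp - ke) %/% stride + 1L
  if (Ho < 1L || Wo < 1L)
    stop("conv2d: input ", H, "x", W, " too small for kernel ", k,
         call. = FALSE)
  if (pad > 0L) {
    xp <- array(0, dim = c(Hp, Wp, C, N))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  } else xp <- x
  dim(xp) <- c(Hp * Wp, C, N)
  idx <- conv_indices(Hp, Wp, k, stride, Ho, Wo, dil)
  K <- k * k
  L <- Ho * Wo
  colv <- xp[as.vector(idx), , , drop = FALSE]       # (L*K, C, N)
  dim(colv) <- c(L, K, C, N)
  colv <- aperm(colv, c(1L, 4L, 2L, 3L))             # (L, N, K, C)
  dim(colv) <- c(L * N, K * C)
  y <- colv %*% w_pm$value                           # (L*N, Cout)
  if (!is.null(b_pm))
    y <- y + matrix(b_pm$value, nrow = L * N, ncol = Cout, byrow = TRUE)
  dim(y) <- c(Ho, Wo, N, Cout)
  y <- aperm(y, c(1L, 2L, 4L, 3L))                   # (Ho, Wo, Cout, N)
  parents <- if (is.null(b_pm)) list(a, wn) else list(a, wn, bn)
  ag_node(tape, y, parents, function(g) {
    gm <- aperm(g, c(1L, 2L, 4L, 3L))                # (Ho, Wo, N, Cout)
    dim(gm) <- c(L * N, Cout)
    dW <- crossprod(colv, gm)
    dcol <- gm %*% t(w_pm$value)                     # (L*N, K*C)
    dim(dcol) <- c(L, N, K, C)
    dcol <- aperm(dcol, c(1L, 3L, 4L, 2L))           # (L, K, C, N)
    dxp <- array(0, dim = c(Hp * Wp, C, N))
    for (kk in seq_len(K)) {
      dck <- dcol[, kk, , , drop = FALSE]
      dim(dck) <- c(L, C, N)
      dxp[idx[, kk], , ] <- dxp[idx[, kk], , , drop = FALSE] + dck
    }
    dim(dxp) <- c(Hp, Wp, C, N)
    dx <- if (pad > 0L)
      dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
    else dxp
    if (is.null(b_pm)) list(dx, dW) else list(dx, dW, colSums(gm))
  })
}

# stride-2 3x3 transposed convolution (output 2H x 2W): zero-embed + conv
ag_deconv2d <- function(a, w_pm, b_pm = NULL) {
  ag_conv2d(ag_zero_embed2(a), w_pm, b_pm, stride = 1L, pad = 0L)
}

# pixel shuffle, factor r: (H, W, C*r^2, N) -> (rH, rW, C, N); a fixed
# channel-to-space bijection, its backward is the inverse rearrangement
ag_pixel_shuffle <- function(a, r = 2L) {
  d <- dim(a$value)
  H <- d[1L]; W <- d[2L]; C4 <- d[3L]; N <- d[4L]
  if (C4 %% (r * r) != 0L)
    stop("pixel_shuffle: channels not divisible by r^2", call. = FALSE)
  C <- C4 %/% (r * r)
  tmp <- a$value
  dim(tmp) <- c(H, W, r, r, C, N)
  out <- aperm(tmp, c(4L, 1L, 3L, 2L, 5L, 6L))
  dim(out) <- c(r * H, r * W, C, N)
  ag_node(a$tape, out, list(a), function(g) {
    dim(g) <- c(r, H, r, W, C, N)
    gt <- aperm(g, c(2L, 4L, 3L, 1L, 5L, 6L))
    dim(gt) <- c(H, W, C4, N)
    list(gt)
  })
}

## ---- batch normalisation ---------------------------------------------------

# layer: env with running_mean, running_var (length C), momentum, eps
ag_batchnorm <- function(a, gamma_pm, beta_pm, layer, training = TRUE) {
  tape <- a$tape
  gn <- ag_wrap(tape, gamma_pm)
  bn <- ag_wrap(tape, beta_pm)
  x <- a$value
  d <- dim(x)
  C <- d[3L]
  m <- d[1L] * d[2L] * d[4L]
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(m, C)
  if (training && m > 1L) {
    mu <- colMeans(xm)
    xc <- xm - matrix(mu, m, C, byrow = TRUE)
    va <- colMeans(xc * xc)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * va * m / max(1, m - 1)
  } else {
    mu <- layer$running_mean
    xc <- xm - matrix(mu, m, C, byrow = TRUE)
    va <- layer$running_var
  }
  istd <- 1 / sqrt(va + layer$eps)
  xhat <- xc * matrix(istd, m, C, byrow = TRUE)
  ym <- xhat * matrix(gamma_pm$value, m, C, byrow = TRUE) +
    matrix(beta_pm$value, m, C, byrow = TRUE)
  y <- array(ym, dim = c(d[1L], d[2L], d[4L], C))
  y <- aperm(y, c(1L, 2L, 4L, 3L))
  batch_stats <- training && m > 1L
  ag_node(tape, y, list(a, gn, bn), function(g) {
    gmat <- aperm(g, c(1L, 2L, 4L, 3L))
    dim(gmat) <- c(m, C)
    dgamma <- colSums(gmat * xhat)
    dbeta <- colSums(gmat)
    gw <- matrix(gamma_pm$value * istd, m, C, byrow = TRUE)
    if (batch_stats) {
      mg <- matrix(colMeans(gmat), m, C, byrow = TRUE)
      mgx <- matrix(colMeans(gmat * xhat), m, C, byrow = TRUE)
      dxm <- gw * (gmat - mg - xhat * mgx)
    } else {
      dxm <- gw * gmat
    }
    dx <- array(dxm, dim = c(d[1L], d[2L], d[4L], C))
    dx <- aperm(dx, c(1L, 2L, 4L, 3L))
    list(dx, dgamma, dbeta)
  })
}

## ---- pooling, dense, softmax ----------------------------------------------

# 3x3 average pooling, stride 1, zero-padded (fixed 1/9 weights); its adjoint
# is itself, so backward reuses the forward kernel
pool3_apply <- function(x) {
  d <- dim(x)
  Hp <- d[1L] + 2L; Wp <- d[2L] + 2L
  xp <- array(0, dim = c(Hp, Wp, d[3L], d[4L]))
  xp[1L + seq_len(d[1L]), 1L + seq_len(d[2L]), , ] <- x
  out <- array(0, dim = d)
  for (dy in 0:2) for (dx in 0:2)
    out <- out + xp[dy + seq_len(d[1L]), dx + seq_len(d[2L]), , ,
                    drop = FALSE]
  out / 9
}

ag_avg_pool3 <- function(a) {
  ag_node(a$tape, pool3_apply(a$value), list(a),
          function(g) list(pool3_apply(g)))
}

# global average pooling: (H, W, C, N) -> (C, N)
ag_gap <- function(a) {
  d <- dim(a$value)
  hw <- d[1L] * d[2L]
  x <- a$value
  dim(x) <- c(hw, d[3L] * d[4L])
  y <- matrix(colMeans(x), d[3L], d[4L])
  ag_node(a$tape, y, list(a), function(g) {
    gx <- array(rep(as.vector(g), each = hw) / hw, dim = d)
    list(gx)
  })
}

# dense layer on (F, N) features: y = t(W) x + b, W is (F, O)
ag_dense <- function(a, w_pm, b_pm) {
  tape <- a$tape
  wn <- ag_wrap(tape, w_pm)
  bn <- ag_wrap(tape, b_pm)
  x <- a$value
  y <- crossprod(w_pm$value, x) + b_pm$value
  ag_node(tape, y, list(a, wn, bn), function(g) {
    list(w_pm$value %*% g, x %*% t(g), rowSums(g))
  })
}

# column-wise softmax on (K, N)
ag_softmax_cols <- function(a) {
  x <- a$value
  xs <- sweep(x, 2L, apply(x, 2L, max))
  e <- exp(xs)
  y <- sweep(e, 2L, colSums(e), `/`)
  ag_node(a$tape, y, list(a), function(g) {
    dot <- colSums(g * y)
    list(y * sweep(g, 2L, dot))
  })
}

# attention-weighted sum of K candidate-operation outputs:
# out = sum_k ops[[k]] * w[k, n]  (weights broadcast over H, W, C)
ag_attention_mix <- function(op_nodes, w_node) {
  K <- length(op_nodes)
  d <- dim(op_nodes[[1L]]$value)
  hwc <- d[1L] * d[2L] * d[3L]
  w <- w_node$value                       # (K, N)
  out <- array(0, dim = d)
  for (k in seq_len(K))
    out <- out + op_nodes[[k]]$value *
      array(rep(w[k, ], each = hwc), dim = d)
  ag_node(op_nodes[[1L]]$tape, out, c(op_nodes, list(w_node)), function(g) {
    gs <- vector("list", K + 1L)
    dw <- matrix(0, K, d[4L])
    for (k in seq_len(K)) {
      gs[[k]] <- g * array(rep(w[k, ], each = hwc), dim = d)
      prod <- g * op_nodes[[k]]$value
      dim(prod) <- c(hwc, d[4L])
      dw[k, ] <- colSums(prod)
    }
    gs[[K + 1L]] <- dw
    gs
  })
}

# weight-anchor regulariser: mean squared deviation of parameters from a
# stored snapshot, over all anchored scalars
ag_anchor <- function(tape, pms, anchors) {
  total_n <- sum(vapply(pms, function(p) length(p$value), numeric(1)))
  nodes <- lapply(pms, function(p) ag_wrap(tape, p))
  val <- 0
  for (i in seq_along(pms))
    val <- val + sum((pms[[i]]$value - anchors[[i]])^2)
  val <- val / total_n
  ag_node(tape, val, nodes, function(g) {
    lapply(seq_along(pms), function(i)
      g * 2 * (pms[[i]]$value - anchors[[i]]) / total_n)
  })
}

## ---- parameter init + optimizer -------------------------------------------

# conv weight as (k*k*Cin, Cout) matrix, He-normal init
init_conv_w <- function(k, cin, cout, group, name) {
  fan_in <- k * k * cin
  w <- matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  attr(w, "k") <- as.integer(k)
  new_param(w, group, name)
}

init_bias <- function(cout, group, name) new_param(numeric(cout), group, name)

init_dense_w <- function(fin, fout, group, name) {
  new_param(matrix(stats::rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout),
            group, name)
}

new_bn_layer <- function(C, group, name, momentum = 0.1, eps = 1e-5) {
  layer <- new.env(parent = emptyenv())
  layer$running_mean <- numeric(C)
  layer$running_var <- rep(1, C)
  layer$momentum <- momentum
  layer$eps <- eps
  layer$gamma <- new_param(rep(1, C), group, paste0(name, ".gamma"))
  layer$beta <- new_param(numeric(C), group, paste0(name, ".beta"))
  layer
}

# one decoupled-weight-decay Adam step over the parameters touched by `tape`,
# skipping groups named in `frozen`
adamw_step <- function(tape, lr, betas = c(0.9, 0.999), eps = 1e-8,
                       weight_decay = 1e-2, frozen = character(0)) {
  for (entry in ag_param_grads(tape)) {
    pm <- entry$pm
    if (pm$group %in% frozen) next
    g <- entry$grad
    if (is.null(pm$m)) {
      pm$m <- g * 0
      pm$v <- g * 0
    }
    pm$t <- pm$t + 1L
    pm$m <- betas[1L] * pm$m + (1 - betas[1L]) * g
    pm$v <- betas[2L] * pm$v + (1 - betas[2L]) * g * g
    mhat <- pm$m / (1 - betas[1L]^pm$t)
    vhat <- pm$v / (1 - betas[2L]^pm$t)
    k_attr <- attr(pm$value, "k")
    pm$value <- pm$value - lr * (mhat / (sqrt(vhat) + eps) +
                                   weight_decay * pm$value)
    if (!is.null(k_attr)) attr(pm$value, "k") <- k_attr
  }
  invisible(NULL)
}
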