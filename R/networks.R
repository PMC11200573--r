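# Architecture builders: the attention U-Net degradation enhancer (GDE), the
# x4 residual pixel-shuffle upscaler (GSR), and the shared-shape adversarial
# critics (DDE / DSR).  Builders are pure functions of (config, seed); all
# trainable state lives in parameter environments grouped by name so that
# stage-wise freezing can be enforced and audited.

#' Network size configuration
#'
#' `tiny_mode = TRUE` selects reduced widths sized for CPU-scale experiments;
#' the full-mode defaults follow the conventions of the cited base
#' architectures (4 U-Net levels, 16 residual blocks, 64 base channels,
#' 7-block critic ladder).  Any field can be overridden explicitly.
#'
#' @param base_channels first-layer width.
#' @param depth number of Conv/Deconv levels in the enhancer.
#' @param n_residual_blocks residual blocks in the upscaler.
#' @param n_attention_ops parallel candidate operations per attention module
#'   (2..6; the last candidate is always average pooling).
#' @param scale super-resolution factor; a power of 2, achieved by scale/2
#'   pixel-shuffle stages.
#' @param n_disc_blocks Conv blocks in the critic ladder after the feature
#'   extractor.
#' @param tiny_mode reduced-size preset for desk-scale runs.
#' @return an object of class `net_config`.
#' @export
net_config <- function(base_channels = NULL, depth = NULL,
                       n_residual_blocks = NULL, n_attention_ops = NULL,
                       scale = 4L, n_disc_blocks = NULL, tiny_mode = FALSE) {
  d <- if (tiny_mode)
    list(base_channels = 8L, depth = 2L, n_residual_blocks = 4L,
         n_attention_ops = 4L, n_disc_blocks = 4L)
  else
    list(base_channels = 64L, depth = 4L, n_residual_blocks = 16L,
         n_attention_ops = 6L, n_disc_blocks = 7L)
  cfg <- list(
    base_channels = as.integer(base_channels %||% d$base_channels),
    depth = as.integer(depth %||% d$depth),
    n_residual_blocks = as.integer(n_residual_blocks %||%
                                     d$n_residual_blocks),
    n_attention_ops = as.integer(n_attention_ops %||% d$n_attention_ops),
    scale = as.integer(scale),
    n_disc_blocks = as.integer(n_disc_blocks %||% d$n_disc_blocks),
    tiny_mode = isTRUE(tiny_mode))
  if (cfg$depth < 1L) stop("net_config: depth must be >= 1", call. = FALSE)
  if (cfg$base_channels < 4L)
    stop("net_config: base_channels must be >= 4", call. = FALSE)
  if (cfg$scale < 2L || bitwAnd(cfg$scale, cfg$scale - 1L) != 0L)
    stop("net_config: scale must be a power of 2 (>= 2)", call. = FALSE)
  if (cfg$n_attention_ops < 2L || cfg$n_attention_ops > 6L)
    stop("net_config: n_attention_ops must be in 2..6", call. = FALSE)
  structure(cfg, class = "net_config")
}

new_net <- function(kind, cfg, seed) {
  net <- new.env(parent = emptyenv())
  net$kind <- kind
  net$cfg <- cfg
  net$seed <- as.integer(seed)
  net$params <- list()
  net$bn <- list()
  class(net) <- "uwf_net"
  net
}

#' @export
print.uwf_net <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat("<uwf_net:", x$kind, "> ", length(x$params), " tensors, ",
      np, " parameters, groups: ",
      paste(sort(unique(vapply(x$params, function(p) p$group, ""))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

reg_param <- function(net, name, pm) {
  net$params[[name]] <- pm
  pm
}

reg_bn <- function(net, name, C, group) {
  layer <- new_bn_layer(C, group, name)
  net$bn[[name]] <- layer
  net$params[[paste0(name, ".gamma")]] <- layer$gamma
  net$params[[paste0(name, ".beta")]] <- layer$beta
  layer
}

## ---- operation-wise attention ---------------------------------------------

# candidate-operation catalog: (kernel, dilation) convs plus average pooling;
# the final candidate is always the pooling op
attention_catalog <- function(n_ops) {
  convs <- list(c(1L, 1L), c(3L, 1L), c(3L, 2L), c(5L, 1L), c(5L, 2L))
  c(lapply(convs[seq_len(n_ops - 1L)], function(kd)
    list(type = "conv", k = kd[1L], dil = kd[2L])),
    list(list(type = "avgpool")))
}

#' Create an operation-wise attention module
#'
#' `n_ops` parallel channel-preserving candidate operations (convolutions of
#' kernel size 1/3/5 with dilation 1/2, plus 3x3 average pooling) are applied
#' to the feature; per-operation weights are computed by global average
#' pooling, a two-layer bottleneck and a softmax over operations, and the
#' output is the attention-weighted sum.  The 1x1 convolution is initialised
#' to the identity and the gate's final layer near zero, so a freshly built
#' module starts close to uniform mixing (zeroing the final gate layer
#' forces exactly uniform weights).
#'
#' @param channels feature channel count.
#' @param n_ops number of candidate operations (2..6).
#' @param group parameter-group tag.
#' @param name name prefix for parameters.
#' @param net optionally, a network to register parameters into.
#' @return attention module state (list of parameter environments).
#' @export
attention_module <- function(channels, n_ops = 4L, group = "attention",
                             name = "att", net = NULL) {
  C <- as.integer(channels)
  cat_ops <- attention_catalog(n_ops)
  ops <- vector("list", length(cat_ops))
  for (i in seq_along(cat_ops)) {
    op <- cat_ops[[i]]
    if (op$type == "conv") {
      w <- init_conv_w(op$k, C, C, group, sprintf("%s.op%d.w", name, i))
      if (op$k == 1L) {
        wi <- diag(C)                 # identity-initialised 1x1 conv
        attr(wi, "k") <- 1L
        w$value <- wi
      }
      b <- init_bias(C, group, sprintf("%s.op%d.b", name, i))
      ops[[i]] <- list(type = "conv", k = op$k, dil = op$dil, w = w, b = b)
    } else {
      ops[[i]] <- list(type = "avgpool")
    }
  }
  hid <- max(4L, C %/% 2L)
  gate_w1 <- init_dense_w(C, hid, group, paste0(name, ".gate1.w"))
  gate_b1 <- init_bias(hid, group, paste0(name, ".gate1.b"))
  # near-zero final gate: starts close to uniform mixing without cutting
  # the gradient path to the first gate layer
  gate_w2 <- new_param(matrix(stats::rnorm(hid * n_ops, 0, 0.01), hid,
                              n_ops), group, paste0(name, ".gate2.w"))
  gate_b2 <- init_bias(n_ops, group, paste0(name, ".gate2.b"))
  mod <- list(C = C, K = n_ops, ops = ops, gate_w1 = gate_w1,
              gate_b1 = gate_b1, gate_w2 = gate_w2, gate_b2 = gate_b2)
  if (!is.null(net)) {
    for (i in seq_along(ops)) {
      if (ops[[i]]$type == "conv") {
        reg_param(net, sprintf("%s.op%d.w", name, i), ops[[i]]$w)
        reg_param(net, sprintf("%s.op%d.b", name, i), ops[[i]]$b)
      }
    }
    reg_param(net, paste0(name, ".gate1.w"), gate_w1)
    reg_param(net, paste0(name, ".gate1.b"), gate_b1)
    reg_param(net, paste0(name, ".gate2.w"), gate_w2)
    reg_param(net, paste0(name, ".gate2.b"), gate_b2)
  }
  mod
}

# tape-level attention forward; returns (feature node, weights node)
att_apply <- function(mod, nd) {
  op_nodes <- lapply(mod$ops, function(op) {
    if (op$type == "conv") {
      pad <- as.integer((op$k - 1L) * op$dil / 2L)
      ag_conv2d(nd, op$w, op$b, stride = 1L, pad = pad, dil = op$dil)
    } else {
      ag_avg_pool3(nd)
    }
  })
  g <- ag_gap(nd)
  g <- ag_lrelu(ag_dense(g, mod$gate_w1, mod$gate_b1))
  w <- ag_softmax_cols(ag_dense(g, mod$gate_w2, mod$gate_b2))
  list(out = ag_attention_mix(op_nodes, w), weights = w)
}

#' Apply an operation-wise attention module to a numeric feature
#'
#' @param feature H x W x C x N numeric array (a single H x W x C feature is
#'   promoted to a batch of one).
#' @param module_state a module created by [attention_module()].
#' @return list with `out` (same shape as `feature`) and `weights`
#'   (`n_ops` x N matrix of softmax attention weights).
#' @export
op_attention_forward <- function(feature, module_state) {
  single <- length(dim(feature)) == 3L
  if (single) dim(feature) <- c(dim(feature), 1L)
  tape <- ag_tape()
  res <- att_apply(module_state, ag_const(tape, feature))
  out <- res$out$value
  if (single) out <- out[, , , 1L]
  list(out = out, weights = res$weights$value)
}

## ---- GDE: attention U-Net enhancer -----------------------------------------

#' Build the degradation-enhancement generator (attention U-Net)
#'
#' Encoder: `depth` Conv boxes (3x3, stride 2; spatial halved, channels
#' doubled), each followed by an Att box (batch norm, activation,
#' operation-wise attention, activation).  Decoder: `depth` Deconv boxes (3x3
#' transposed convolution; spatial doubled, channels halved), each followed
#' by an Att box, with additive U-Net skip connections between matching
#' levels, and a final 3x3 convolution back to 3 channels.  Parameters are
#' grouped as `encoder`, `decoder` and `attention` to support stage-wise
#' freezing.  Inputs whose sides are not divisible by `2^depth` are zero-
#' padded and cropped back.
#'
#' @param cfg a [net_config()].
#' @param seed integer seed for the parameter initialisation.
#' @return a `uwf_net` of kind `"gde"`.
#' @export
build_gde <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  net <- new_net("gde", cfg, seed)
  with_seed(seed, {
    ch <- c(3L, cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L))
    net$enc <- vector("list", cfg$depth)
    for (l in seq_len(cfg$depth)) {
      w <- reg_param(net, sprintf("enc%d.w", l),
                     init_conv_w(3L, ch[l], ch[l + 1L], "encoder",
                                 sprintf("enc%d.w", l)))
      b <- reg_param(net, sprintf("enc%d.b", l),
                     init_bias(ch[l + 1L], "encoder", sprintf("enc%d.b", l)))
      bn <- reg_bn(net, sprintf("enc%d.bn", l), ch[l + 1L], "attention")
      att <- attention_module(ch[l + 1L], cfg$n_attention_ops, "attention",
                              sprintf("enc%d.att", l), net)
      net$enc[[l]] <- list(w = w, b = b, bn = bn, att = att)
    }
    out_ch <- max(4L, cfg$base_channels %/% 2L)
    dch <- c(out_ch, ch[-1L])        # dch[l+1] -> dch[l] at decoder level l
    net$dec <- vector("list", cfg$depth)
    for (l in rev(seq_len(cfg$depth))) {
      w <- reg_param(net, sprintf("dec%d.w", l),
                     init_conv_w(3L, dch[l + 1L], dch[l], "decoder",
                                 sprintf("dec%d.w", l)))
      b <- reg_param(net, sprintf("dec%d.b", l),
                     init_bias(dch[l], "decoder", sprintf("dec%d.b", l)))
      bn <- reg_bn(net, sprintf("dec%d.bn", l), dch[l], "attention")
      att <- attention_module(dch[l], cfg$n_attention_ops, "attention",
                              sprintf("dec%d.att", l), net)
      net$dec[[l]] <- list(w = w, b = b, bn = bn, att = att)
    }
    net$out_w <- reg_param(net, "out.w",
                           init_conv_w(3L, out_ch, 3L, "decoder", "out.w"))
    net$out_b <- reg_param(net, "out.b", init_bias(3L, "decoder", "out.b"))
  })
  net
}

# Att box: BN -> activation -> operation-wise attention -> activation
att_box <- function(box, nd, training) {
  h <- ag_batchnorm(nd, box$bn$gamma, box$bn$beta, box$bn, training)
  h <- ag_lrelu(h)
  h <- att_apply(box$att, h)$out
  ag_lrelu(h)
}

gde_forward <- function(net, nd, training = FALSE) {
  d <- dim(nd$value)
  H <- d[1L]; W <- d[2L]
  div <- 2L^net$cfg$depth
  pb <- (div - H %% div) %% div
  pr <- (div - W %% div) %% div
  h <- ag_pad_br(nd, pb, pr)
  skips <- vector("list", net$cfg$depth)
  for (l in seq_len(net$cfg$depth)) {
    box <- net$enc[[l]]
    h <- ag_conv2d(h, box$w, box$b, stride = 2L, pad = 1L)
    h <- att_box(box, h, training)
    skips[[l]] <- h
  }
  for (l in rev(seq_len(net$cfg$depth))) {
    box <- net$dec[[l]]
    h <- ag_deconv2d(h, box$w, box$b)
    h <- att_box(box, h, training)
    if (l > 1L) h <- ag_add(h, skips[[l - 1L]])   # additive U-Net skip
  }
  h <- ag_conv2d(h, net$out_w, net$out_b, stride = 1L, pad = 1L)
  ag_crop(h, H, W)
}

## ---- GSR: residual pixel-shuffle upscaler ----------------------------------

#' Build the super-resolution generator
#'
#' FeatureExtractor (3x3 conv + PReLU), `n_residual_blocks` residual blocks
#' (Conv+BN, PReLU, Conv+BN, elementwise sum), a Conv+BN with a global skip
#' from the extractor output, `log2(scale)` Conv+Shuffle stages (3x3 conv,
#' x2 pixel shuffle, PReLU) and a channel-calibration 3x3 convolution to 3
#' channels.  Maps H x W x 3 to (scale H) x (scale W) x 3.
#'
#' @inheritParams build_gde
#' @return a `uwf_net` of kind `"gsr"`.
#' @export
build_gsr <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  net <- new_net("gsr", cfg, seed)
  C <- cfg$base_channels
  with_seed(seed, {
    net$fe_w <- reg_param(net, "fe.w", init_conv_w(3L, 3L, C, "gsr", "fe.w"))
    net$fe_b <- reg_param(net, "fe.b", init_bias(C, "gsr", "fe.b"))
    net$fe_a <- reg_param(net, "fe.alpha",
                          new_param(rep(0.25, C), "gsr", "fe.alpha"))
    net$res <- vector("list", cfg$n_residual_blocks)
    for (i in seq_len(cfg$n_residual_blocks)) {
      net$res[[i]] <- list(
        w1 = reg_param(net, sprintf("res%d.w1", i),
                       init_conv_w(3L, C, C, "gsr", sprintf("res%d.w1", i))),
        bn1 = reg_bn(net, sprintf("res%d.bn1", i), C, "gsr"),
        a = reg_param(net, sprintf("res%d.alpha", i),
                      new_param(rep(0.25, C), "gsr",
                                sprintf("res%d.alpha", i))),
        w2 = reg_param(net, sprintf("res%d.w2", i),
                       init_conv_w(3L, C, C, "gsr", sprintf("res%d.w2", i))),
        bn2 = reg_bn(net, sprintf("res%d.bn2", i), C, "gsr"))
    }
    net$post_w <- reg_param(net, "post.w",
                            init_conv_w(3L, C, C, "gsr", "post.w"))
    net$post_bn <- reg_bn(net, "post.bn", C, "gsr")
    n_up <- as.integer(log2(cfg$scale))
    net$up <- vector("list", n_up)
    for (s in seq_len(n_up)) {
      net$up[[s]] <- list(
        w = reg_param(net, sprintf("up%d.w", s),
                      init_conv_w(3L, C, 4L * C, "gsr",
                                  sprintf("up%d.w", s))),
        b = reg_param(net, sprintf("up%d.b", s),
                      init_bias(4L * C, "gsr", sprintf("up%d.b", s))),
        a = reg_param(net, sprintf("up%d.alpha", s),
                      new_param(rep(0.25, C), "gsr",
                                sprintf("up%d.alpha", s))))
    }
    net$out_w <- reg_param(net, "out.w", init_conv_w(3L, C, 3L, "gsr",
                                                     "out.w"))
    net$out_b <- reg_param(net, "out.b", init_bias(3L, "gsr", "out.b"))
  })
  net
}

gsr_forward <- function(net, nd, training = FALSE) {
  fe <- ag_prelu(ag_conv2d(nd, net$fe_w, net$fe_b, stride = 1L, pad = 1L),
                 net$fe_a)
  h <- fe
  for (blk in net$res) {
    r <- ag_batchnorm(ag_conv2d(h, blk$w1, NULL, stride = 1L, pad = 1L),
                      blk$bn1$gamma, blk$bn1$beta, blk$bn1, training)
    r <- ag_prelu(r, blk$a)
    r <- ag_batchnorm(ag_conv2d(r, blk$w2, NULL, stride = 1L, pad = 1L),
                      blk$bn2$gamma, blk$bn2$beta, blk$bn2, training)
    h <- ag_add(h, r)
  }
  h <- ag_batchnorm(ag_conv2d(h, net$post_w, NULL, stride = 1L, pad = 1L),
                    net$post_bn$gamma, net$post_bn$beta, net$post_bn,
                    training)
  h <- ag_add(h, fe)                 # global skip from the extractor
  for (up in net$up) {
    h <- ag_conv2d(h, up$w, up$b, stride = 1L, pad = 1L)
    h <- ag_pixel_shuffle(h, 2L)
    h <- ag_prelu(h, up$a)
  }
  ag_conv2d(h, net$out_w, net$out_b, stride = 1L, pad = 1L)
}

## ---- discriminator ----------------------------------------------------------

#' Build an adversarial critic
#'
#' FeatureExtractor (3x3 conv + activation) followed by `n_disc_blocks` Conv
#' blocks (3x3 Conv+BN + leaky activation, strides alternating 2/1, channels
#' doubling on each stride-1 block), global average pooling and a Dense layer
#' reducing the feature to a single scalar score per image, mapped through a
#' sigmoid to (0, 1).  Two critics built from the same config never share
#' parameter storage.
#'
#' @inheritParams build_gde
#' @return a `uwf_net` of kind `"critic"`.
#' @export
build_discriminator <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  net <- new_net("critic", cfg, seed)
  C <- cfg$base_channels
  # [15]-style ladder after the extractor: (C,2),(2C,1),(2C,2),(4C,1),...
  chans <- C * 2L^(seq_len(cfg$n_disc_blocks) %/% 2L)
  strides <- rep(c(2L, 1L), length.out = cfg$n_disc_blocks)
  with_seed(seed, {
    net$fe_w <- reg_param(net, "fe.w",
                          init_conv_w(3L, 3L, C, "critic", "fe.w"))
    net$fe_b <- reg_param(net, "fe.b", init_bias(C, "critic", "fe.b"))
    net$blocks <- vector("list", cfg$n_disc_blocks)
    cin <- C
    for (i in seq_len(cfg$n_disc_blocks)) {
      net$blocks[[i]] <- list(
        w = reg_param(net, sprintf("blk%d.w", i),
                      init_conv_w(3L, cin, chans[i], "critic",
                                  sprintf("blk%d.w", i))),
        bn = reg_bn(net, sprintf("blk%d.bn", i), chans[i], "critic"),
        stride = strides[i])
      cin <- chans[i]
    }
    net$dense_w <- reg_param(net, "dense.w",
                             init_dense_w(cin, 1L, "critic", "dense.w"))
    net$dense_b <- reg_param(net, "dense.b",
                             init_bias(1L, "critic", "dense.b"))
  })
  net$min_input <- 2L^sum(strides == 2L)
  net
}

disc_forward <- function(net, nd, training = FALSE) {
  d <- dim(nd$value)
  if (min(d[1L], d[2L]) < net$min_input)
    stop("discriminator: input ", d[1L], "x", d[2L],
         " is below the minimum size ", net$min_input, call. = FALSE)
  h <- ag_lrelu(ag_conv2d(nd, net$fe_w, net$fe_b, stride = 1L, pad = 1L))
  for (blk in net$blocks) {
    h <- ag_conv2d(h, blk$w, NULL, stride = blk$stride, pad = 1L)
    h <- ag_batchnorm(h, blk$bn$gamma, blk$bn$beta, blk$bn, training)
    h <- ag_lrelu(h)
  }
  s <- ag_dense(ag_gap(h), net$dense_w, net$dense_b)   # (1, N)
  ag_sigmoid(s)
}

## ---- numeric-level forward helpers ------------------------------------------

# stack a list of H x W x 3 images into an (H, W, 3, N) batch
stack_images <- function(imgs) {
  if (is.array(imgs) && length(dim(imgs)) == 4L) return(imgs)
  if (is.array(imgs) && length(dim(imgs)) == 3L)
    return(array(imgs, dim = c(dim(imgs), 1L)))
  d <- dim(imgs[[1L]])
  out <- array(0, dim = c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

#' Run a network forward on a numeric image batch
#'
#' Generator outputs are clipped to \[0, 1\] when `clip = TRUE` (inference
#' convention); critics return a vector of scores in (0, 1).
#'
#' @param net a `uwf_net`.
#' @param x an H x W x 3 image, an (H, W, 3, N) batch, or a list of images.
#' @param training use batch statistics in the normalisation layers.
#' @param clip clip generator output into \[0, 1\].
#' @return numeric array (generators) or numeric vector of scores (critics).
#' @export
net_forward <- function(net, x, training = FALSE, clip = TRUE) {
  xb <- stack_images(x)
  single <- is.array(x) && length(dim(x)) == 3L
  tape <- ag_tape()
  nd <- ag_const(tape, xb)
  out <- switch(net$kind,
    gde = gde_forward(net, nd, training),
    gsr = gsr_forward(net, nd, training),
    critic = disc_forward(net, nd, training))
  v <- out$value
  if (net$kind == "critic") return(as.vector(v))
  if (clip) v <- clip01(v)
  if (single) v <- v[, , , 1L]
  v
}

## ---- parameter bookkeeping ---------------------------------------------------

#' Parameters of a network, optionally restricted to groups
#' @param net a `uwf_net`.
#' @param groups character vector of group names, or NULL for all.
#' @return named list of parameter environments.
#' @export
net_params <- function(net, groups = NULL) {
  ps <- net$params
  if (is.null(groups)) return(ps)
  ps[vapply(ps, function(p) p$group %in% groups, logical(1))]
}

#' Deep-copy the parameter values of a network
#' @inheritParams net_params
#' @return named list of numeric arrays.
#' @export
param_snapshot <- function(net, groups = NULL) {
  lapply(net_params(net, groups), function(p) p$value)
}

#' Restore parameter values from a snapshot
#' @param net a `uwf_net`.
#' @param snapshot a [param_snapshot()] result.
#' @export
load_snapshot <- function(net, snapshot) {
  for (nm in names(snapshot)) {
    if (is.null(net$params[[nm]]))
      stop("load_snapshot: unknown parameter ", nm, call. = FALSE)
    net$params[[nm]]$value <- snapshot[[nm]]
  }
  invisible(net)
}

# exact fingerprint for freezing audits
param_checksum <- function(net, groups = NULL) {
  vapply(net_params(net, groups), function(p) sum(p$value) + sum(p$value^2),
         numeric(1))
}
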