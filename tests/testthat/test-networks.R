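test_that("shape contracts hold across random sizes in tiny mode", {
  cfg <- net_config(tiny_mode = TRUE)
  gde <- build_gde(cfg, seed = 2)
  gsr <- build_gsr(cfg, seed = 3)
  dde <- build_discriminator(cfg, seed = 4)
  set.seed(10)
  for (sz in c(12L, 16L, 24L)) {
    x <- rand_batch(sz, sz, n = 2L, seed = sz)
    e <- net_forward(gde, x, clip = FALSE)
    expect_identical(dim(e), dim(x))                 # GDE preserves H x W
    s <- net_forward(gsr, x)
    expect_identical(dim(s), c(4L * sz, 4L * sz, 3L, 2L))  # GSR is x4
    sc <- net_forward(dde, x)
    expect_length(sc, 2L)
    expect_true(all(sc > 0 & sc < 1))                # one sigmoid scalar each
  }
  # non-divisible sizes are padded and cropped back, never an error
  odd <- rand_batch(13L, 17L, n = 1L, seed = 1)
  expect_identical(dim(net_forward(gde, odd)), dim(odd))
})

test_that("builders are seed-deterministic and critics never share storage", {
  cfg <- tiny_cfg()
  g1 <- build_gde(cfg, seed = 5)
  g2 <- build_gde(cfg, seed = 5)
  expect_equal(param_snapshot(g1), param_snapshot(g2))
  g3 <- build_gde(cfg, seed = 6)
  expect_false(isTRUE(all.equal(param_snapshot(g1), param_snapshot(g3))))

  d1 <- build_discriminator(cfg, seed = 7)
  d2 <- build_discriminator(cfg, seed = 8)
  x <- rand_batch(8L, n = 2L, seed = 2)
  expect_false(isTRUE(all.equal(net_forward(d1, x), net_forward(d2, x))))
  uids1 <- vapply(net_params(d1), function(p) p$uid, "")
  uids2 <- vapply(net_params(d2), function(p) p$uid, "")
  expect_length(intersect(uids1, uids2), 0L)
  # even same-seed builds are distinct parameter sets
  d3 <- build_discriminator(cfg, seed = 7)
  expect_length(intersect(uids1, vapply(net_params(d3),
                                        function(p) p$uid, "")), 0L)
})

test_that("encoder feature halves spatial dims and doubles channels", {
  cfg <- net_config(base_channels = 8L, depth = 2L, tiny_mode = TRUE)
  gde <- build_gde(cfg, seed = 1)
  x <- rand_batch(64L, n = 1L, seed = 3)
  tape <- uwfenhance:::ag_tape()
  h <- uwfenhance:::ag_conv2d(uwfenhance:::ag_const(tape, x),
                              gde$enc[[1]]$w, gde$enc[[1]]$b,
                              stride = 2L, pad = 1L)
  expect_identical(dim(h$value), c(32L, 32L, 8L, 1L))
  h2 <- uwfenhance:::ag_conv2d(h, gde$enc[[2]]$w, gde$enc[[2]]$b,
                               stride = 2L, pad = 1L)
  expect_identical(dim(h2$value), c(16L, 16L, 16L, 1L))
})

test_that("a zeroed gate mixes candidates uniformly", {
  set.seed(20)
  mod <- attention_module(channels = 4L, n_ops = 3L)
  mod$gate_w2$value[] <- 0           # softmax of zeros -> uniform weights
  mod$gate_b2$value[] <- 0
  feat <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4))
  res <- op_attention_forward(feat, mod)
  expect_equal(colSums(res$weights), 1, tolerance = 1e-12)
  expect_equal(as.vector(res$weights), rep(1 / 3, 3), tolerance = 1e-12)
  # zero-initialised gate => output is the mean of the candidate outputs
  tape <- uwfenhance:::ag_tape()
  nd <- uwfenhance:::ag_const(tape, array(feat, dim = c(6, 6, 4, 1)))
  ops <- lapply(mod$ops, function(op) {
    if (op$type == "conv") {
      pad <- as.integer((op$k - 1L) * op$dil / 2L)
      uwfenhance:::ag_conv2d(nd, op$w, op$b, stride = 1L, pad = pad,
                             dil = op$dil)$value
    } else uwfenhance:::pool3_apply(nd$value)
  })
  expect_equal(res$out, (ops[[1]] + ops[[2]] + ops[[3]])[, , , 1] / 3,
               tolerance = 1e-10)
})

test_that("a one-hot gate on the identity-initialised 1x1 conv passes input", {
  set.seed(21)
  mod <- attention_module(channels = 4L, n_ops = 3L)
  # force the gate to put all mass on op 1 (the identity-initialised 1x1)
  mod$gate_w2$value[] <- 0
  mod$gate_b2$value <- c(50, -50, -50)
  feat <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4))
  res <- op_attention_forward(feat, mod)
  expect_equal(res$out, feat, tolerance = 1e-8)
})

test_that("pixel shuffle rearranges 4C channels into a x2 grid exactly", {
  x <- array(seq_len(2 * 2 * 4), dim = c(2, 2, 4, 1))
  tape <- uwfenhance:::ag_tape()
  y <- uwfenhance:::ag_pixel_shuffle(uwfenhance:::ag_const(tape, x), 2L)
  expect_identical(dim(y$value), c(4L, 4L, 1L, 1L))
  # channels fill the 2x2 sub-grid column-offset fastest:
  # channel c = j + (i-1)*2 lands at out[(h-1)*2+i, (w-1)*2+j]
  expect_equal(y$value[1, 1, 1, 1], x[1, 1, 1, 1])
  expect_equal(y$value[1, 2, 1, 1], x[1, 1, 2, 1])
  expect_equal(y$value[2, 1, 1, 1], x[1, 1, 3, 1])
  expect_equal(y$value[2, 2, 1, 1], x[1, 1, 4, 1])
  expect_setequal(as.vector(y$value), as.vector(x))
})

test_that("zeroing the final calibration conv zeroes the upscaler output", {
  gsr <- zero_gsr()
  x <- rand_batch(8L, n = 1L, seed = 5)
  out <- net_forward(gsr, x, clip = FALSE)
  expect_identical(dim(out), c(32L, 32L, 3L, 1L))
  expect_equal(max(abs(out)), 0)
})

test_that("every trainable parameter receives gradient from a generic loss", {
  cfg <- tiny_cfg()
  for (build in list(build_gde, build_gsr)) {
    net <- build(cfg, seed = 9)
    x <- rand_batch(8L, n = 2L, seed = 7)
    tape <- uwfenhance:::ag_tape()
    fwd <- if (net$kind == "gde") uwfenhance:::gde_forward
           else uwfenhance:::gsr_forward
    out <- fwd(net, uwfenhance:::ag_const(tape, x), TRUE)
    loss <- uwfenhance:::ag_mean_sq_diff(
      out, uwfenhance:::ag_const(tape, out$value + 1))
    uwfenhance:::ag_backward(loss)
    grads <- uwfenhance:::ag_param_grads(tape)
    uids <- vapply(net_params(net), function(p) p$uid, "")
    missing <- setdiff(uids, names(grads))
    expect_length(missing, 0L)
    nonzero <- vapply(grads, function(g) any(g$grad != 0), logical(1))
    expect_true(all(nonzero))
  }
})

test_that("discriminator rejects inputs below its receptive minimum", {
  cfg <- net_config(base_channels = 4L, n_disc_blocks = 6L,
                    tiny_mode = TRUE)
  d <- build_discriminator(cfg, seed = 3)
  tiny <- rand_batch(4L, n = 1L, seed = 1)
  expect_error(net_forward(d, tiny), "minimum size")
})
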