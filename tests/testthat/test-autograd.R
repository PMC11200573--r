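# The autograd core backs every network; its gradients are verified against
# central finite differences on small composite graphs.

test_that("conv/deconv/prelu/pixel-shuffle gradients match finite differences", {
  set.seed(31)
  w <- uwfenhance:::init_conv_w(3L, 2L, 4L, "g", "w")
  b <- uwfenhance:::init_bias(4L, "g", "b")
  wd <- uwfenhance:::init_conv_w(3L, 4L, 8L, "g", "wd")
  al <- uwfenhance:::new_param(rep(0.25, 2L), "g", "alpha")
  x <- array(rnorm(6 * 6 * 2 * 2), dim = c(6, 6, 2, 2))
  tgt <- array(rnorm(24 * 24 * 2 * 2), dim = c(24, 24, 2, 2))
  fwd <- function() {
    tape <- uwfenhance:::ag_tape()
    h <- uwfenhance:::ag_conv2d(uwfenhance:::ag_const(tape, x), w, b,
                                stride = 1L, pad = 1L)
    h <- uwfenhance:::ag_deconv2d(h, wd)      # 4 -> 8 ch, x2 spatial
    h <- uwfenhance:::ag_pixel_shuffle(h, 2L) # 8 -> 2 ch, x2 spatial
    h <- uwfenhance:::ag_prelu(h, al)
    list(tape = tape,
         loss = uwfenhance:::ag_mean_sq_diff(
           h, uwfenhance:::ag_const(tape, tgt)))
  }
  r <- fwd()
  uwfenhance:::ag_backward(r$loss)
  for (pm in list(w, b, wd, al)) {
    nd <- r$tape$pcache[[pm$uid]]
    ng <- numeric_grad(function() fwd()$loss$value, pm)
    expect_lt(max(abs(as.vector(nd$grad) - ng)) / (max(abs(ng)) + 1e-8),
              1e-5)
  }
})

test_that("strided and dilated convolutions have exact adjoints", {
  set.seed(32)
  for (spec in list(list(stride = 2L, pad = 1L, dil = 1L),
                    list(stride = 1L, pad = 2L, dil = 2L))) {
    w <- uwfenhance:::init_conv_w(3L, 2L, 3L, "g", "w")
    x <- array(rnorm(8 * 8 * 2 * 1), dim = c(8, 8, 2, 1))
    fwd <- function() {
      tape <- uwfenhance:::ag_tape()
      xn <- uwfenhance:::ag_const(tape, x)
      h <- uwfenhance:::ag_conv2d(xn, w, NULL, stride = spec$stride,
                                  pad = spec$pad, dil = spec$dil)
      list(tape = tape, xn = xn,
           loss = uwfenhance:::ag_mean_sq_diff(
             h, uwfenhance:::ag_const(tape, h$value * 0)))
    }
    r <- fwd()
    uwfenhance:::ag_backward(r$loss)
    ng <- numeric_grad(function() fwd()$loss$value, w)
    nd <- r$tape$pcache[[w$uid]]
    expect_lt(max(abs(as.vector(nd$grad) - ng)) / (max(abs(ng)) + 1e-8),
              1e-5)
    # input gradient at a probe pixel
    i <- 13L
    f_at <- function(v) {
      x2 <- x; x2[i] <- v
      tape <- uwfenhance:::ag_tape()
      h <- uwfenhance:::ag_conv2d(uwfenhance:::ag_const(tape, x2), w, NULL,
                                  stride = spec$stride, pad = spec$pad,
                                  dil = spec$dil)
      uwfenhance:::ag_mean_sq_diff(
        h, uwfenhance:::ag_const(tape, h$value * 0))$value
    }
    ngx <- (f_at(x[i] + 1e-5) - f_at(x[i] - 1e-5)) / 2e-5
    expect_lt(abs(r$xn$grad[i] - ngx) / (abs(ngx) + 1e-8), 1e-5)
  }
})

test_that("softmax, dense and attention-mix gradients are exact", {
  set.seed(33)
  w1 <- uwfenhance:::init_dense_w(3L, 4L, "g", "w1")
  b1 <- uwfenhance:::init_bias(4L, "g", "b1")
  x <- array(rnorm(5 * 5 * 3 * 2), dim = c(5, 5, 3, 2))
  fwd <- function() {
    tape <- uwfenhance:::ag_tape()
    xn <- uwfenhance:::ag_const(tape, x)
    ops <- list(uwfenhance:::ag_avg_pool3(xn), uwfenhance:::ag_lrelu(xn),
                uwfenhance:::ag_scale(xn, 0.5),
                uwfenhance:::ag_sigmoid(xn))
    wgt <- uwfenhance:::ag_softmax_cols(
      uwfenhance:::ag_dense(uwfenhance:::ag_gap(xn), w1, b1))
    out <- uwfenhance:::ag_attention_mix(ops, wgt)
    list(tape = tape, loss = uwfenhance:::ag_mean_sq_diff(
      out, uwfenhance:::ag_const(tape, x * 0)))
  }
  r <- fwd()
  uwfenhance:::ag_backward(r$loss)
  for (pm in list(w1, b1)) {
    ng <- numeric_grad(function() fwd()$loss$value, pm)
    nd <- r$tape$pcache[[pm$uid]]
    expect_lt(max(abs(as.vector(nd$grad) - ng)) / (max(abs(ng)) + 1e-8),
              1e-5)
  }
})

test_that("a parameter reused twice on one tape accumulates both paths", {
  w <- uwfenhance:::new_param(matrix(2, 1, 1), "g", "w")
  attr(w$value, "k") <- 1L
  x <- array(1, dim = c(1, 1, 1, 1))
  tape <- uwfenhance:::ag_tape()
  xn <- uwfenhance:::ag_const(tape, x)
  h1 <- uwfenhance:::ag_conv2d(xn, w, NULL, stride = 1L, pad = 0L)
  h2 <- uwfenhance:::ag_conv2d(h1, w, NULL, stride = 1L, pad = 0L)
  loss <- uwfenhance:::ag_mean(h2)     # loss = w^2 -> d/dw = 2w = 4
  uwfenhance:::ag_backward(loss)
  expect_equal(as.numeric(tape$pcache[[w$uid]]$grad), 4)
})

test_that("AdamW skips frozen groups and decays unfrozen weights", {
  w_a <- uwfenhance:::new_param(matrix(1, 2, 2), "groupA", "a")
  w_b <- uwfenhance:::new_param(matrix(1, 2, 2), "groupB", "b")
  tape <- uwfenhance:::ag_tape()
  na <- uwfenhance:::ag_wrap(tape, w_a)
  nb <- uwfenhance:::ag_wrap(tape, w_b)
  loss <- uwfenhance:::ag_add(uwfenhance:::ag_mean(na),
                              uwfenhance:::ag_mean(nb))
  uwfenhance:::ag_backward(loss)
  uwfenhance:::adamw_step(tape, lr = 0.1, frozen = "groupA")
  expect_identical(w_a$value, matrix(1, 2, 2))
  expect_true(all(w_b$value < 1))
})
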