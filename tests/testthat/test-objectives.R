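test_that("adversarial losses match the closed form at D = 0.5", {
  critic <- half_critic()
  real <- rand_batch(8L, n = 3L, seed = 1)
  fake <- rand_batch(8L, n = 3L, seed = 2)
  l <- adversarial_loss(critic, real, fake)
  expect_equal(l$d_loss, -2 * log(0.5), tolerance = 1e-6)
  expect_equal(l$g_loss, -log(0.5), tolerance = 1e-6)
  expect_error(adversarial_loss(critic, real[, , , 0, drop = FALSE], fake),
               "empty")
})

test_that("adversarial losses stay finite at extreme critic scores", {
  critic <- half_critic()
  critic$dense_b$value[] <- 100        # sigmoid -> 1 - eps
  real <- rand_batch(8L, n = 2L, seed = 3)
  fake <- rand_batch(8L, n = 2L, seed = 4)
  l_hi <- adversarial_loss(critic, real, fake)
  critic$dense_b$value[] <- -100       # sigmoid -> eps
  l_lo <- adversarial_loss(critic, real, fake)
  expect_true(all(is.finite(unlist(l_hi))))
  expect_true(all(is.finite(unlist(l_lo))))
  # perfect critic: D(real) -> 1, D(fake) -> 0 gives near-zero d_loss
  critic2 <- half_critic()
  expect_gt(l_lo$g_loss, l_hi$g_loss)  # generator punished when D(fake) -> 0
})

test_that("identity loss matches the elementwise oracle", {
  gde_half <- const_gde(0.5)
  zeros <- array(0, dim = c(8, 8, 3, 2))
  expect_equal(identity_loss(gde_half, zeros), 0.5, tolerance = 1e-9)
  # batch-order invariance
  b1 <- rand_batch(8L, n = 3L, seed = 5)
  b2 <- b1[, , , c(3, 1, 2)]
  expect_equal(identity_loss(gde_half, b1), identity_loss(gde_half, b2),
               tolerance = 1e-12)
})

test_that("weight anchor loss is a mean squared deviation", {
  expect_equal(weight_anchor_loss(list(a = 0.3), list(a = 0.1)), 0.04,
               tolerance = 1e-12)
  snap <- list(a = matrix(1, 2, 2), b = rep(0.5, 3))
  expect_equal(weight_anchor_loss(snap, snap), 0)
  moved <- snap; moved$a[1, 1] <- 1.5
  v1 <- weight_anchor_loss(moved, snap)
  moved$a[1, 1] <- 2
  expect_gt(weight_anchor_loss(moved, snap), v1)   # monotone in deviation
  expect_error(weight_anchor_loss(list(a = 1), list(b = 1)), "match")
})

test_that("stage composites are the stated weighted sums", {
  w <- loss_weights()                      # 0.5 / 0.1 / 0.5
  de <- total_de_loss(list(adv_g = 1.0, identity = 0.2, anchor = 0.0), w)
  expect_equal(de$total, 1.1, tolerance = 1e-12)
  expect_identical(de$stage, "DE")
  sr <- total_sr_loss(list(adv_g = 0.8, cycle = 0.4), w)
  expect_equal(sr$total, 1.0, tolerance = 1e-12)
  ft <- total_finetune_loss(de, sr)
  expect_equal(ft$total, 2.1, tolerance = 1e-12)
  expect_identical(ft$stage, "FT")
  # degenerate weights reduce to the adversarial term alone
  w0 <- loss_weights(0, 0, 0)
  expect_equal(total_de_loss(list(adv_g = 0.7, identity = 9, anchor = 9),
                             w0)$total, 0.7)
  expect_equal(total_sr_loss(list(adv_g = 0.7, cycle = 9), w0)$total, 0.7)
})

test_that("composites are exactly linear in their components", {
  set.seed(40)
  for (rep in 1:20) {
    w <- loss_weights(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
    cmp <- list(adv_g = rnorm(1), identity = abs(rnorm(1)),
                anchor = abs(rnorm(1)), cycle = abs(rnorm(1)))
    de <- total_de_loss(cmp, w)
    expect_equal(de$total,
                 cmp$adv_g + w$lambda_I * cmp$identity +
                   w$lambda_R * cmp$anchor, tolerance = 1e-12)
    sr <- total_sr_loss(cmp, w)
    expect_equal(sr$total, cmp$adv_g + w$lambda_C * cmp$cycle,
                 tolerance = 1e-12)
    expect_equal(total_finetune_loss(de, sr)$total, de$total + sr$total,
                 tolerance = 1e-12)
  }
})

test_that("cycle loss implements the one-way downsample/upscale round trip", {
  gsr0 <- zero_gsr()
  batch <- array(0.5, dim = c(32, 32, 3, 2))
  expect_equal(cycle_loss(gsr0, batch), 0.5, tolerance = 1e-9)
  expect_gte(cycle_loss(gsr0, rand_batch(32L, n = 2L, seed = 6)), 0)
  # indivisible sizes are cropped to a multiple of 4, then processed
  odd <- array(0.5, dim = c(34, 39, 3, 1))
  expect_equal(cycle_loss(gsr0, odd), 0.5, tolerance = 1e-9)
})

test_that("one generator step on a fixed critic raises D(fake)", {
  set.seed(41)
  cfg <- tiny_cfg()
  gde <- build_gde(cfg, seed = 12)
  critic <- build_discriminator(cfg, seed = 13)
  z <- rand_batch(8L, n = 2L, seed = 7)
  before <- mean(net_forward(critic, net_forward(gde, z, clip = FALSE)))
  tape <- uwfenhance:::ag_tape()
  fake <- uwfenhance:::gde_forward(gde, uwfenhance:::ag_const(tape, z),
                                   FALSE)
  gl <- uwfenhance:::adv_g_node(critic, fake, training = FALSE)
  uwfenhance:::ag_backward(gl)
  uwfenhance:::adamw_step(tape, lr = 5e-3, weight_decay = 0,
                          frozen = "critic")
  after <- mean(net_forward(critic, net_forward(gde, z, clip = FALSE)))
  expect_gt(after, before)
})
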