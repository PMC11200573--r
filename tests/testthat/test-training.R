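# Stage orchestration: freezing contracts, schedule, patching, resumability.
# Training runs here are deliberately short; the full miniature experiment
# lives in test-acceptance.R.

make_tiny_dataset <- function(dir, n = 4L, size = 32L, seed = 3L) {
  params <- phantom_params(size = size, n_drusen = 2)
  build_unpaired_dataset(params, n, file.path(dir, "clean"),
                         file.path(dir, "uwf"), seed = seed)
  params
}

test_that("learning-rate schedule halves at the stated period", {
  expect_equal(lr_at(0, 1e-3, 200000), 1e-3)
  expect_equal(lr_at(200000, 1e-3, 200000), 5e-4)
  expect_equal(lr_at(450000, 1e-3, 200000), 2.5e-4)
  expect_equal(lr_at(199999, 1e-3, 200000), 1e-3)
  expect_error(lr_at(-1, 1e-3, 200000), ">= 0")
})

test_that("stage defaults freeze the groups the scheme prescribes", {
  expect_identical(stage_config("DE")$frozen_groups, "encoder")
  expect_setequal(stage_config("SR")$frozen_groups,
                  c("encoder", "decoder", "attention"))
  expect_length(stage_config("FT")$frozen_groups, 0L)
  expect_length(stage_config("PRETRAIN")$frozen_groups, 0L)
  expect_error(stage_config("DE", patch_size = 30), "divisible")
})

test_that("random crops stay in bounds and honour the macular region", {
  img <- rand_img(256, seed = 1)
  ps <- extract_patches(img, 128, n = 20, seed = 5)
  for (p in ps) expect_identical(dim(p), c(128L, 128L, 3L))
  # region-restricted crops: audit 1000 seeded draws via the crop log
  mc <- c(128, 128); r <- 40
  crops <- extract_patches(img, 64, n = 1000,
                           region = list(center = mc, radius = r),
                           seed = 77)
  dists <- vapply(crops, function(p) {
    ctr <- attr(p, "corner") + (64 - 1) / 2
    sqrt(sum((ctr - mc)^2))
  }, numeric(1))
  expect_true(all(dists <= r + 1e-9))
  expect_error(extract_patches(img, 512), "smaller")
})

test_that("180-degree rotation applied twice restores the patch", {
  p <- rand_img(16, seed = 9)
  r180 <- uwfenhance:::rot90cw(uwfenhance:::rot90cw(p))
  expect_equal(uwfenhance:::rot90cw(uwfenhance:::rot90cw(r180)), p,
               tolerance = 1e-15)
  # four quarter turns are the identity
  r <- p
  for (i in 1:4) r <- uwfenhance:::rot90cw(r)
  expect_equal(r, p, tolerance = 1e-15)
})

test_that("pretraining lowers reconstruction error and anchors exactly", {
  cfg <- tiny_cfg()
  gde <- build_gde(cfg, seed = 30)
  params <- phantom_params(size = 32, n_drusen = 2)
  pre <- build_pretrain_set(params, 4, seed = 17)
  held <- build_pretrain_set(params, 4, seed = 18)
  err0 <- mean(vapply(seq_along(held$input), function(i)
    mean(abs(net_forward(gde, held$input[[i]]) - held$target[[i]])),
    numeric(1)))
  st <- pretrain_gde(pre, gde,
                     stage_config("PRETRAIN", iterations = 120,
                                  batch_size = 4, patch_size = 32,
                                  seed = 2))
  err1 <- mean(vapply(seq_along(held$input), function(i)
    mean(abs(net_forward(gde, held$input[[i]]) - held$target[[i]])),
    numeric(1)))
  expect_lt(err1, err0)
  # anchor snapshot equals post-pretraining parameters exactly
  expect_equal(weight_anchor_loss(net_params(gde), st$anchor), 0)
  expect_error(pretrain_gde(list(input = list(), target = list()), gde,
                            stage_config("PRETRAIN")), "empty")
})

test_that("zero pretraining iterations leave the network untouched", {
  cfg <- tiny_cfg()
  gde <- build_gde(cfg, seed = 31)
  before <- param_snapshot(gde)
  params <- phantom_params(size = 32, n_drusen = 0)
  pretrain_gde(build_pretrain_set(params, 2, seed = 1), gde,
               stage_config("PRETRAIN", iterations = 0, batch_size = 2,
                            patch_size = 32, seed = 3))
  expect_equal(param_snapshot(gde), before, tolerance = 0)
})

test_that("stage DE freezes the encoder bit-for-bit and trains the rest", {
  d <- withr::local_tempdir()
  make_tiny_dataset(d)
  cfg <- tiny_cfg()
  gde <- build_gde(cfg, seed = 32)
  anchor <- param_snapshot(gde)
  enc_before <- param_snapshot(gde, "encoder")
  dec_before <- param_snapshot(gde, c("decoder", "attention"))
  st <- train_stage_de(file.path(d, "uwf"), file.path(d, "clean"), gde,
                       anchor,
                       stage_config("DE", iterations = 25, batch_size = 2,
                                    patch_size = 32, seed = 4))
  expect_identical(param_snapshot(gde, "encoder"), enc_before)
  expect_false(isTRUE(all.equal(param_snapshot(gde,
                                               c("decoder", "attention")),
                                dec_before)))
  expect_s3_class(st, "train_state")
  expect_identical(nrow(st$history), 25L)
  expect_true(all(c("adv_g", "adv_d", "identity", "anchor", "total") %in%
                    names(st$history)))
})

test_that("a strong identity weight constrains enhancer drift", {
  d <- withr::local_tempdir()
  make_tiny_dataset(d)
  cfg <- tiny_cfg()
  run_with_li <- function(li) {
    gde <- build_gde(cfg, seed = 33)
    anchor <- param_snapshot(gde)
    sc <- stage_config("DE", iterations = 40, batch_size = 2,
                       patch_size = 32, seed = 6,
                       weights = loss_weights(lambda_I = li))
    train_stage_de(file.path(d, "uwf"), file.path(d, "clean"), gde, anchor,
                   sc)
    z <- rand_batch(8L, n = 4L, seed = 11)
    mean(abs(net_forward(gde, z, clip = FALSE) - z))
  }
  expect_lt(run_with_li(100), run_with_li(0))
})

test_that("stage SR leaves every enhancer parameter identical", {
  d <- withr::local_tempdir()
  make_tiny_dataset(d)
  cfg <- tiny_cfg()
  gde <- build_gde(cfg, seed = 34)
  gde$stage_trained <- "DE"          # staged via a completed DE pass
  gsr <- build_gsr(cfg, seed = 35)
  gde_before <- param_snapshot(gde)
  st <- train_stage_sr(file.path(d, "uwf"), file.path(d, "clean"), gde, gsr,
                       stage_config("SR", iterations = 8, batch_size = 2,
                                    patch_size = 32, seed = 7))
  expect_identical(param_snapshot(gde), gde_before)
  expect_false(isTRUE(all.equal(param_snapshot(gsr),
                                param_snapshot(build_gsr(cfg, seed = 35)))))
  # x4 contract after training
  out <- net_forward(gsr, rand_img(8, seed = 2))
  expect_identical(dim(out), c(32L, 32L, 3L))
})

test_that("stage SR demands a staged enhancer", {
  d <- withr::local_tempdir()
  make_tiny_dataset(d)
  cfg <- tiny_cfg()
  fresh <- build_gde(cfg, seed = 36)
  expect_error(train_stage_sr(file.path(d, "uwf"), file.path(d, "clean"),
                              fresh, build_gsr(cfg, seed = 37),
                              stage_config("SR", iterations = 2,
                                           batch_size = 2,
                                           patch_size = 32, seed = 8)),
               "DE stage")
})

test_that("fine-tuning updates all groups and logs LM = LE + LSR", {
  d <- withr::local_tempdir()
  make_tiny_dataset(d)
  cfg <- tiny_cfg()
  gde <- build_gde(cfg, seed = 38); gde$stage_trained <- "DE"
  gsr <- build_gsr(cfg, seed = 39); gsr$stage_trained <- "SR"
  anchor <- param_snapshot(gde)
  before <- list(enc = param_snapshot(gde, "encoder"),
                 dec = param_snapshot(gde, "decoder"),
                 att = param_snapshot(gde, "attention"),
                 gsr = param_snapshot(gsr))
  st <- finetune_macular(file.path(d, "uwf"), file.path(d, "clean"), gde,
                         gsr, anchor,
                         stage_config("FT", iterations = 6, batch_size = 2,
                                      patch_size = 32, seed = 9))
  expect_false(isTRUE(all.equal(param_snapshot(gde, "encoder"),
                                before$enc)))
  expect_false(isTRUE(all.equal(param_snapshot(gde, "decoder"),
                                before$dec)))
  expect_false(isTRUE(all.equal(param_snapshot(gde, "attention"),
                                before$att)))
  expect_false(isTRUE(all.equal(param_snapshot(gsr), before$gsr)))
  expect_equal(st$history$total, st$history$le + st$history$lsr,
               tolerance = 1e-6)
  expect_error(finetune_macular(file.path(d, "uwf"), file.path(d, "clean"),
                                build_gde(cfg, seed = 40), gsr, anchor,
                                stage_config("FT", iterations = 1,
                                             batch_size = 2,
                                             patch_size = 32, seed = 9)),
               "trained first")
})

test_that("checkpoint save/load/continue reproduces an uninterrupted run", {
  cfg <- tiny_cfg()
  params <- phantom_params(size = 32, n_drusen = 1)
  pre <- build_pretrain_set(params, 3, seed = 21)
  sc6 <- stage_config("PRETRAIN", iterations = 6, batch_size = 2,
                      patch_size = 32, seed = 13)
  # uninterrupted reference run
  gde_a <- build_gde(cfg, seed = 50)
  hist_a <- pretrain_gde(pre, gde_a, sc6)$history
  # interrupted run: 3 iterations, serialize, restore, continue to 6
  gde_b <- build_gde(cfg, seed = 50)
  sc3 <- stage_config("PRETRAIN", iterations = 3, batch_size = 2,
                      patch_size = 32, seed = 13)
  st3 <- pretrain_gde(pre, gde_b, sc3)
  ck <- withr::local_tempdir()
  save_checkpoint(st3, ck)
  restored <- load_checkpoint(ck)
  hist_b <- pretrain_gde(pre, restored$nets$enhancer, sc6,
                         resume_state = restored)$history
  expect_equal(hist_b, hist_a, tolerance = 1e-12)
  expect_equal(param_snapshot(restored$nets$enhancer),
               param_snapshot(gde_a), tolerance = 1e-12)
})

test_that("enhance composes DE then SR and exposes the interim image", {
  cfg <- tiny_cfg()
  gde <- build_gde(cfg, seed = 60)
  gsr <- build_gsr(cfg, seed = 61)
  img <- rand_img(16, seed = 3)
  res <- enhance(img, gde, gsr, return_intermediate = TRUE)
  expect_identical(dim(res$output), c(64L, 64L, 3L))
  expect_identical(dim(res$intermediate), dim(img))
  expect_true(min(res$output) >= 0 && max(res$output) <= 1)
  # the reversed-order ablation is a distinct composition
  abl <- enhance(img, gde, gsr, order = "sr_de")
  expect_identical(dim(abl), c(64L, 64L, 3L))
  expect_false(isTRUE(all.equal(abl, res$output)))
})
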