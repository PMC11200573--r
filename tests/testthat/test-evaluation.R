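test_that("sharpness score is monotone in blur strength", {
  ph <- test_phantom(size = 64, seed = 13)
  s0 <- sharpness_score(ph$clean)
  s3 <- sharpness_score(gaussian_blur(ph$clean, 3))
  s5 <- sharpness_score(gaussian_blur(ph$clean, 5))
  s7 <- sharpness_score(gaussian_blur(ph$clean, 7))
  expect_lt(s0, s3)
  expect_lt(s3, s5)
  expect_lt(s5, s7)
  expect_true(all(c(s0, s3, s5, s7) >= 0 & c(s0, s3, s5, s7) <= 1))
})

test_that("sharpness score matches the direct-formula oracle", {
  expect_equal(sharpness_score(array(0.5, dim = c(16, 16, 3))), 1.0)
  # checkerboard: maximal variation survives re-blurring poorly normalised
  cb <- array(rep_len(c(0, 1), 24 * 24), dim = c(24, 24, 3))
  expect_lt(sharpness_score(cb), 0.5)
  expect_equal(sharpness_score(cb), sharpness_oracle(cb), tolerance = 1e-10)
  img <- rand_img(20, seed = 8)
  expect_equal(sharpness_score(img), sharpness_oracle(img),
               tolerance = 1e-10)
  expect_error(sharpness_score(rand_img(8, seed = 1)), "16x16")
})

test_that("IoU equals brute-force pixel counting on random masks", {
  set.seed(50)
  for (i in 1:25) {
    a <- matrix(runif(16 * 16) < runif(1), 16, 16)
    b <- matrix(runif(16 * 16) < runif(1), 16, 16)
    expect_equal(iou(a, b), iou_oracle(a, b), tolerance = 1e-12)
    expect_equal(iou(a, b), iou(b, a))               # symmetry
    expect_true(iou(a, b) >= 0 && iou(a, b) <= 1)
  }
  m <- matrix(TRUE, 2, 2)
  expect_equal(iou(m, m), 1.0)
  expect_equal(iou(matrix(c(TRUE, FALSE), 2, 2),
                   matrix(c(FALSE, TRUE), 2, 2)), 0.0)
  left <- matrix(FALSE, 2, 2); left[, 1] <- TRUE
  expect_equal(iou(m, left), 0.5)
  expect_equal(iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1.0)
  expect_error(iou(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes")
})

test_that("mAP is the mean IoU in percent, order-invariant", {
  m1 <- matrix(TRUE, 4, 4); m0 <- matrix(FALSE, 4, 4)
  half <- m0; half[1:2, ] <- TRUE
  pairs <- list(list(m1, m1), list(m1, m0))
  expect_equal(map_score(pairs), 50.0)
  expect_equal(map_score(rev(pairs)), 50.0)
  expect_equal(map_score(list(list(m1, m1), list(half, half))), 100.0)
  expect_error(map_score(list()), "nonempty")
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  set.seed(51)
  for (i in 1:15) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1),
                                                   mean = runif(1, 0, 2)))
    got <- anova_oneway(groups)
    ora <- anova_oracle(groups)
    expect_equal(got$F, ora$F, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
    expect_false(got$degenerate)
  }
  expect_equal(anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))$F, 1.5,
               tolerance = 1e-12)
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0); expect_equal(same$p, 1)
  dg <- anova_oneway(list(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  expect_identical(dg$F, Inf)
  expect_equal(dg$p, 0)
  expect_true(dg$degenerate)
  expect_error(anova_oneway(list(1, c(1, 2))), "at least 2 samples")
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
})

test_that("Bonferroni correction caps and counts comparisons", {
  set.seed(52)
  g2 <- list(a = rnorm(5), b = rnorm(5))
  pw2 <- bonferroni_pairwise(g2)
  expect_identical(nrow(pw2), 1L)
  expect_equal(pw2$p_adjusted, pw2$p_raw)            # m = 1
  g4 <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5), d = rnorm(5))
  pw4 <- bonferroni_pairwise(g4)
  expect_identical(nrow(pw4), 6L)                    # 4 choose 2
  expect_equal(pw4$p_adjusted, pmin(1, pw4$p_raw * 6), tolerance = 1e-12)
  # capping: p_raw = 0.3 with m = 6 -> 1.0
  expect_true(all(pw4$p_adjusted[pw4$p_raw >= 1 / 6] == 1.0))
  expect_equal(min(1, 0.3 * 6), 1.0)
})

test_that("metric adapters degrade gracefully and accept backends", {
  expect_message(v <- lpips_adapter(rand_img(16), rand_img(16)),
                 "no LPIPS backend")
  expect_identical(v, NA_real_)
  expect_message(f <- fid_adapter("a", "b"), "no FID backend")
  expect_identical(f, NA_real_)
  # registry contract with a stub backend
  register_metric_backend("lpips", function(a, b) mean((a - b)^2))
  withr::defer(register_metric_backend("lpips", NULL))
  img <- rand_img(16, seed = 2)
  expect_lte(lpips_adapter(img, img), 1e-6)
  expect_gt(lpips_adapter(img, 1 - img), 0)
})

test_that("evaluate_dirs produces a full report with group statistics", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "pred")); dir.create(file.path(d, "ref"))
  for (i in 1:3) {
    ph <- test_phantom(size = 32, seed = i)
    save_image(gaussian_blur(ph$clean, 5),
               file.path(d, "pred", sprintf("p%d.png", i)))
    save_image(ph$clean, file.path(d, "ref", sprintf("r%d.png", i)))
  }
  out <- file.path(d, "report.json")
  rep <- suppressMessages(evaluate_dirs(file.path(d, "pred"),
                                        file.path(d, "ref"), out = out))
  expect_s3_class(rep, "metric_report")
  expect_identical(nrow(rep$per_image), 3L)
  expect_true(all(rep$per_image$gamma >= 0 & rep$per_image$gamma <= 1))
  expect_gt(rep$aggregate$gamma_mean, rep$aggregate$ref_gamma_mean)
  expect_true(rep$stats$anova_p >= 0 && rep$stats$anova_p <= 1)
  expect_true(file.exists(out))
  parsed <- jsonlite::read_json(out)
  expect_true(!is.null(parsed$aggregate$gamma_mean))
})

test_that("drusen detector recovers phantom lesions on clean images", {
  ph <- generate_phantom(phantom_params(size = 64, n_drusen = 4), seed = 44)
  det <- detect_drusen(ph$clean, ph$macula_center, 64 / 6 + 2)
  expect_gt(iou(det, ph$drusen_mask), 0.2)
  # no false positives far from the macula
  far <- det
  far[abs(row(far) - ph$macula_center[1]) < 20 &
        abs(col(far) - ph$macula_center[2]) < 20] <- FALSE
  expect_equal(sum(far), 0L)
})
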