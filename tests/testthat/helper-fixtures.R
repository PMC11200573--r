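# Shared fixtures and independent oracles, built in code at test time.

tiny_cfg <- function(...) {
  net_config(base_channels = 4L, depth = 1L, n_residual_blocks = 1L,
             n_attention_ops = 3L, n_disc_blocks = 2L, tiny_mode = TRUE, ...)
}

test_phantom <- function(size = 64L, n_drusen = 3L, seed = 7L) {
  generate_phantom(phantom_params(size = size, n_drusen = n_drusen), seed)
}

# a critic whose score is exactly 0.5 for every input: zero final dense layer
half_critic <- function(cfg = tiny_cfg(), seed = 1L) {
  d <- build_discriminator(cfg, seed)
  d$dense_w$value[] <- 0
  d$dense_b$value[] <- 0
  d
}

# an enhancer that outputs a constant value regardless of input
const_gde <- function(value, cfg = tiny_cfg(), seed = 1L) {
  g <- build_gde(cfg, seed)
  g$out_w$value[] <- 0
  g$out_b$value[] <- value
  g
}

# an upscaler that outputs the zero image
zero_gsr <- function(cfg = tiny_cfg(), seed = 1L) {
  g <- build_gsr(cfg, seed)
  g$out_w$value[] <- 0
  g$out_b$value[] <- 0
  g
}

rand_img <- function(H, W = H, seed = 1L) {
  set.seed(seed)
  array(runif(H * W * 3), dim = c(H, W, 3L))
}

rand_batch <- function(H, W = H, n = 2L, seed = 1L) {
  set.seed(seed)
  array(runif(H * W * 3 * n), dim = c(H, W, 3L, n))
}

# independent one-way ANOVA oracle: explicit sums of squares
anova_oracle <- function(groups) {
  x <- unlist(groups)
  k <- length(groups)
  N <- length(x)
  grand <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# independent brute-force IoU by explicit pixel counting
iou_oracle <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] && b[i, j]) inter <- inter + 1L
    if (a[i, j] || b[i, j]) uni <- uni + 1L
  }
  if (uni == 0L) 1.0 else inter / uni
}

# independent re-blur gradient-ratio oracle (direct formula, loops)
sharpness_oracle <- function(img) {
  f <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  H <- nrow(f); W <- ncol(f)
  reflect <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  blur_dir <- function(vertical) {
    b <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      s <- 0
      for (t in -4:4) {
        ii <- if (vertical) reflect(i + t, H) else i
        jj <- if (vertical) j else reflect(j + t, W)
        s <- s + f[ii, jj]
      }
      b[i, j] <- s / 9
    }
    b
  }
  bv <- blur_dir(TRUE); bh <- blur_dir(FALSE)
  dfv <- abs(diff(f)); dbv <- abs(diff(bv))
  dfh <- abs(t(diff(t(f)))); dbh <- abs(t(diff(t(bh))))
  sv <- sum(dfv); sh <- sum(dfh)
  if (sv < 1e-300 && sh < 1e-300) return(1.0)
  rv <- if (sv < 1e-300) 0 else (sv - sum(pmax(0, dfv - dbv))) / sv
  rh <- if (sh < 1e-300) 0 else (sh - sum(pmax(0, dfh - dbh))) / sh
  max(rv, rh)
}

# central-difference gradient of a scalar function of one parameter env
numeric_grad <- function(fn, pm, eps = 1e-5) {
  g <- numeric(length(pm$value))
  for (i in seq_along(pm$value)) {
    v0 <- pm$value[i]
    pm$value[i] <- v0 + eps; fp <- fn()
    pm$value[i] <- v0 - eps; fm <- fn()
    pm$value[i] <- v0
    g[i] <- (fp - fm) / (2 * eps)
  }
  g
}
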