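# Parametrized degradation operators used both for robustness experiments and
# for synthesising the UWF-like domain from clean phantoms.  All operators map
# [0,1] images to [0,1] images of deterministic shape.

#' Describe one degradation operator
#'
#' A `degradation_spec` is a typed description of a single operator; chains
#' (lists) of specs define the synthesis of UWF-like images.  Exactly the
#' parameter matching `kind` is consulted; the defaults are the canonical
#' severe-degradation settings (sigma = 7, gamma = 0.75, rate = 0.25,
#' scale = 0.25).
#'
#' @param kind one of `"gaussian_blur"`, `"illumination"`, `"jpeg"`,
#'   `"bicubic"`.
#' @param sigma blur kernel support in pixels (kernel sd = sigma/3).
#' @param gamma corner gamma of the uneven-illumination field.
#' @param rate JPEG quality fraction in (0, 1].
#' @param scale bicubic resampling factor in (0, 1] for degradation use.
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(kind = c("gaussian_blur", "illumination",
                                      "jpeg", "bicubic"),
                             sigma = 7, gamma = 0.75, rate = 0.25,
                             scale = 0.25) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    gaussian_blur = {
      if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 1)
        stop("degradation_spec: 'sigma' must be a single number >= 1",
             call. = FALSE)
      list(kind = kind, sigma = sigma)
    },
    illumination = {
      if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
        stop("degradation_spec: 'gamma' must be a single positive number",
             call. = FALSE)
      list(kind = kind, gamma = gamma)
    },
    jpeg = {
      if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate > 1)
        stop("degradation_spec: 'rate' must be in (0, 1]", call. = FALSE)
      list(kind = kind, rate = rate)
    },
    bicubic = {
      if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
        stop("degradation_spec: 'scale' must be positive", call. = FALSE)
      list(kind = kind, scale = scale)
    })
  structure(spec, class = "degradation_spec")
}

#' @export
print.degradation_spec <- function(x, ...) {
  p <- setdiff(names(x), "kind")
  cat("<degradation_spec> ", x$kind, " (", p, " = ", x[[p]], ")\n", sep = "")
  invisible(x)
}

# reflect-pad a matrix by r rows/cols on each side
reflect_pad <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  if (r >= H || r >= W)
    stop("blur support exceeds image size", call. = FALSE)
  ri <- c(rev(seq_len(r) + 1L), seq_len(H), H - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(W), W - seq_len(r))
  m[ri, ci, drop = FALSE]
}

#' Gaussian blur with a sigma-by-sigma kernel
#'
#' Convolves each channel with a normalised 2-D Gaussian whose support is
#' `sigma` x `sigma` pixels (`sigma` rounded up to odd) and whose standard
#' deviation is `sigma/3`, so the kernel decays close to zero at the support
#' border.  Borders are handled by reflection.
#'
#' @param img image array (see [as_image()]).
#' @param sigma kernel support in pixels, >= 1.
#' @return blurred image, same shape, values in \[0, 1\].
#' @export
gaussian_blur <- function(img, sigma = 7) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("gaussian_blur: 'sigma' must be a positive number", call. = FALSE)
  if (sigma < 1)
    stop("gaussian_blur: 'sigma' must be >= 1", call. = FALSE)
  img <- as_image(img)
  k <- as.integer(ceiling(sigma))
  if (k %% 2L == 0L) k <- k + 1L
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(img)
  w1 <- stats::dnorm(seq(-r, r), sd = sigma / 3)
  w1 <- w1 / sum(w1)                  # separable => outer(w1, w1) sums to 1
  out <- img
  for (ch in 1:3) {
    m <- reflect_pad(img[, , ch], r)
    H <- dim(img)[1L]; W <- dim(img)[2L]
    # separable convolution via shifted accumulation
    tmp <- matrix(0, H, W + 2L * r)
    for (i in seq_len(k)) tmp <- tmp + w1[i] * m[(i - 1L) + seq_len(H), ]
    res <- matrix(0, H, W)
    for (j in seq_len(k)) res <- res + w1[j] * tmp[, (j - 1L) + seq_len(W)]
    out[, , ch] <- res
  }
  clip01(out)
}

#' Uneven illumination by spatially varying gamma correction
#'
#' Applies `out(p) = img(p)^(g(p))` where the exponent field `g` is a smooth
#' radial cosine ramp interpolating from 1 at the image centre to `gamma` at
#' the corners, producing an uneven (vignetting-like) illumination change.
#' `gamma = 1` is the exact identity; the centre pixel value is unchanged for
#' any `gamma`.
#'
#' @param img image array.
#' @param gamma positive corner gamma.
#' @return image of the same shape in \[0, 1\].
#' @export
gamma_illumination <- function(img, gamma = 0.75) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma_illumination: 'gamma' must be a single positive number",
         call. = FALSE)
  img <- as_image(img)
  if (gamma == 1) return(img)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ry <- (seq_len(H) - cy); rx <- (seq_len(W) - cx)
  d <- sqrt(outer(ry^2, rx^2, `+`))
  dmax <- sqrt((1 - cy)^2 + (1 - cx)^2)   # distance centre -> corner pixel
  wgt <- (1 - cos(pi * pmin(d / dmax, 1))) / 2     # 0 at centre, 1 at corners
  g <- 1 + (gamma - 1) * wgt
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch]^g
  clip01(out)
}

#' JPEG compression round-trip
#'
#' Encodes the image as JPEG at quality `rate` (the libjpeg quality percent
#' is `round(100 * rate)`) and decodes it again.  Shape is preserved.
#'
#' @param img image array.
#' @param rate quality fraction in (0, 1].
#' @return decoded image, same shape, values in \[0, 1\].
#' @export
jpeg_compress <- function(img, rate = 0.25) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate > 1)
    stop("jpeg_compress: 'rate' must be in (0, 1]", call. = FALSE)
  img <- as_image(img)
  raw_jpeg <- jpeg::writeJPEG(img, raw(), quality = rate)
  as_image(jpeg::readJPEG(raw_jpeg))
}

# cubic convolution kernel (Keys, a = -0.5)
cubic_kernel <- function(x) {
  a <- -0.5
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

# dense resampling matrix mapping n_in samples to n_out samples, half-pixel
# centres, edge clamping, kernel widened by 1/scale when minifying (antialias)
resample_matrix <- function(n_in, n_out, scale) {
  filt <- max(1, 1 / scale)            # kernel widening factor for minification
  support <- 2 * filt
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / scale + 0.5     # 1-based continuous source coordinate
    lo <- floor(src - support); hi <- ceiling(src + support)
    taps <- lo:hi
    w <- cubic_kernel((src - taps) / filt)
    keep <- w != 0
    taps <- pmin(pmax(taps[keep], 1L), n_in)   # clamp-to-edge
    w <- w[keep]
    for (t in seq_along(taps)) M[i, taps[t]] <- M[i, taps[t]] + w[t]
  }
  M / rowSums(M)
}

#' Bicubic resampling
#'
#' Separable cubic-convolution interpolation (a = -0.5) with half-pixel
#' centres and clamp-to-edge borders; when minifying, the kernel support is
#' widened by 1/scale (antialiasing).  `scale = 1` is the exact identity.
#'
#' @param img image array.
#' @param scale positive resampling factor; output dims are
#'   `round(dim * scale)` and must be at least 8.
#' @return resampled image in \[0, 1\].
#' @export
bicubic_resample <- function(img, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("bicubic_resample: 'scale' must be positive", call. = FALSE)
  img <- as_image(img)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  Ho <- as.integer(round(H * scale)); Wo <- as.integer(round(W * scale))
  if (Ho < 8L || Wo < 8L)
    stop("bicubic_resample: output size ", Ho, "x", Wo,
         " is degenerate (< 8 pixels)", call. = FALSE)
  if (scale == 1) return(img)
  Mr <- resample_matrix(H, Ho, scale)
  Mc <- resample_matrix(W, Wo, scale)
  out <- array(0, dim = c(Ho, Wo, 3L))
  for (ch in 1:3) out[, , ch] <- Mr %*% img[, , ch] %*% t(Mc)
  clip01(out)
}

#' Apply a degradation operator or chain
#'
#' @param img image array.
#' @param chain a `degradation_spec` or a nonempty list of them, applied in
#'   order.
#' @return degraded image.
#' @export
apply_degradations <- function(img, chain) {
  if (inherits(chain, "degradation_spec")) chain <- list(chain)
  if (!is.list(chain) || length(chain) == 0L)
    stop("apply_degradations: 'chain' must be a nonempty list of ",
         "degradation_spec objects", call. = FALSE)
  for (spec in chain) {
    if (!inherits(spec, "degradation_spec"))
      stop("apply_degradations: chain elements must be degradation_spec ",
           "objects", call. = FALSE)
    img <- switch(spec$kind,
      gaussian_blur = gaussian_blur(img, spec$sigma),
      illumination  = gamma_illumination(img, spec$gamma),
      jpeg          = jpeg_compress(img, spec$rate),
      bicubic       = bicubic_resample(img, spec$scale))
  }
  img
}

#' The default severe-degradation chain
#'
#' Gaussian blur (sigma = 7), uneven gamma illumination (gamma = 0.75), JPEG
#' compression (rate = 0.25) and bicubic downsampling (scale = 0.25), applied
#' jointly in that order — the four canonical synthetic degradations used to
#' turn clean fundus-quality images into UWF-like counterparts.
#'
#' @return list of `degradation_spec` objects.
#' @export
default_uwf_chain <- function() {
  list(degradation_spec("gaussian_blur", sigma = 7),
       degradation_spec("illumination", gamma = 0.75),
       degradation_spec("jpeg", rate = 0.25),
       degradation_spec("bicubic", scale = 0.25))
}

# serialize/deserialize chains as JSON (CLI chain files)
chain_to_json <- function(chain, path) {
  if (inherits(chain, "degradation_spec")) chain <- list(chain)
  jsonlite::write_json(lapply(chain, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

chain_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) do.call(degradation_spec, s))
}
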