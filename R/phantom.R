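# Synthetic retinal phantom generator.  Produces unpaired "fundus-quality"
# and "UWF-like" image sets with known ground truth (drusen masks, macula
# centres, hidden pairings), so that the whole pipeline can be exercised and
# evaluated without any clinical data.

# evaluate code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(abs(seed) %% 2147483647))
  force(code)
}

#' Parameters of the synthetic retinal phantom
#'
#' @param size square image side in pixels (>= 32).
#' @param n_vessels number of vessel paths grown from the optic-disc region.
#' @param n_drusen number of bright macular drusen blobs.
#' @param background_tint RGB triple in \[0, 1\]; base fundus colour.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   applied (seeded) at UWF synthesis time.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(size = 128L, n_vessels = 7L, n_drusen = 5L,
                           background_tint = c(0.82, 0.42, 0.22),
                           noise_sd = 0.01) {
  if (!is.numeric(size) || length(size) != 1L || size < 32)
    stop("phantom_params: 'size' must be a single integer >= 32",
         call. = FALSE)
  if (!is.numeric(n_vessels) || length(n_vessels) != 1L || n_vessels < 0)
    stop("phantom_params: 'n_vessels' must be >= 0", call. = FALSE)
  if (!is.numeric(n_drusen) || length(n_drusen) != 1L || n_drusen < 0)
    stop("phantom_params: 'n_drusen' must be >= 0", call. = FALSE)
  if (!is.numeric(background_tint) || length(background_tint) != 3L ||
      any(background_tint < 0) || any(background_tint > 1))
    stop("phantom_params: 'background_tint' must be an RGB triple in [0, 1]",
         call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("phantom_params: 'noise_sd' must be a nonnegative number",
         call. = FALSE)
  structure(list(size = as.integer(size), n_vessels = as.integer(n_vessels),
                 n_drusen = as.integer(n_drusen),
                 background_tint = as.numeric(background_tint),
                 noise_sd = noise_sd),
            class = "phantom_params")
}

# smooth low-frequency texture field in [-1, 1], seeded by the caller's RNG
smooth_texture <- function(H, W, n_waves = 6L) {
  yy <- matrix(seq_len(H) / H, H, W)
  xx <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
  t <- matrix(0, H, W)
  for (k in seq_len(n_waves)) {
    f <- stats::runif(2, 1.5, 6)
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::runif(1, 0.3, 1)
    t <- t + a * sin(2 * pi * (f[1] * yy + f[2] * xx) + ph)
  }
  t / max(abs(t))
}

# grow one vessel as a second-order random walk and stamp a Gaussian
# cross-section into the accumulator map
stamp_vessel <- function(V, start, theta0, n_steps, width) {
  H <- nrow(V); W <- ncol(V)
  pos <- start
  theta <- theta0
  dtheta <- 0
  r <- 2L
  off <- expand.grid(dy = -r:r, dx = -r:r)
  for (s in seq_len(n_steps)) {
    dtheta <- 0.75 * dtheta + stats::rnorm(1, 0, 0.12)
    theta <- theta + dtheta
    pos <- pos + c(sin(theta), cos(theta))
    iy <- round(pos[1]); ix <- round(pos[2])
    if (iy < 1 + r || iy > H - r || ix < 1 + r || ix > W - r) break
    d2 <- (off$dy + (pos[1] - iy))^2 + (off$dx + (pos[2] - ix))^2
    g <- exp(-d2 / (2 * width^2))
    idx <- cbind(iy + off$dy, ix + off$dx)
    V[idx] <- pmax(V[idx], g)
  }
  V
}

#' Generate a synthetic clean retinal phantom
#'
#' Builds a fundus-quality image containing a radial-gradient orange/red
#' textured background, a bright optic disc ellipse, seeded curvilinear dark
#' vessels grown from the disc region by a second-order random walk, a darker
#' macular disc, and optional small bright drusen blobs confined to the
#' macular region (their union is returned as the ground-truth mask).
#' Identical `(params, seed)` reproduce a bit-identical phantom.
#'
#' @param params a [phantom_params()] object.
#' @param seed integer seed.
#' @return an object of class `phantom` with fields `clean` (H x W x 3 array
#'   in \[0, 1\]), `drusen_mask` (logical H x W), `macula_center`
#'   (row, col), `seed`, and `params`.
#' @export
generate_phantom <- function(params, seed) {
  if (!inherits(params, "phantom_params"))
    params <- do.call(phantom_params, as.list(params))
  n <- params$size
  with_seed(seed, {
    yy <- matrix(seq_len(n), n, n)
    xx <- matrix(seq_len(n), n, n, byrow = TRUE)
    cy <- (n + 1) / 2; cx <- (n + 1) / 2
    rad <- sqrt((yy - cy)^2 + (xx - cx)^2) / (n / 2)

    img <- array(0, dim = c(n, n, 3L))
    tex <- smooth_texture(n, n)
    shade <- 1 - 0.35 * pmin(rad, 1.2)^2        # radial fall-off
    for (ch in 1:3)
      img[, , ch] <- params$background_tint[ch] * shade * (1 + 0.08 * tex)

    # optic disc: bright ellipse, nasal side
    dc <- c(0.5 * n, 0.24 * n)
    da <- 0.085 * n; db <- 0.07 * n
    dd <- sqrt(((yy - dc[1]) / da)^2 + ((xx - dc[2]) / db)^2)
    disc <- 1 / (1 + exp(8 * (dd - 1)))         # soft ellipse edge
    lift <- c(0.95, 0.85, 0.55)
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - disc) + lift[ch] * disc

    # vessels: seeded second-order random walks from the disc region
    V <- matrix(0, n, n)
    if (params$n_vessels > 0) {
      for (v in seq_len(params$n_vessels)) {
        theta0 <- stats::runif(1, -pi, pi)
        start <- dc + c(stats::rnorm(1, 0, 0.02 * n),
                        stats::rnorm(1, 0, 0.02 * n))
        width <- stats::runif(1, 0.55, 1.1)
        V <- stamp_vessel(V, start, theta0, n_steps = round(1.6 * n), width)
      }
    }
    vdark <- c(0.38, 0.52, 0.45)                # vessels darker in G/B
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - vdark[ch] * V)

    # macula: darker disc, temporal side
    mc <- c(round(0.52 * n), round(0.64 * n))
    md <- sqrt((yy - mc[1])^2 + (xx - mc[2])^2)
    mac <- exp(-(md / (n / 5))^2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.25 * mac)

    # drusen: small bright disks inside the macular radius n/6
    mask <- matrix(FALSE, n, n)
    if (params$n_drusen > 0) {
      for (k in seq_len(params$n_drusen)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rr <- sqrt(stats::runif(1)) * (n / 6 - 3)
        ctr <- mc + rr * c(sin(ang), cos(ang))
        radius <- stats::runif(1, 1, 3)
        bright <- stats::runif(1, 0.2, 0.4)
        dd2 <- sqrt((yy - ctr[1])^2 + (xx - ctr[2])^2)
        blob <- dd2 <= radius
        mask <- mask | blob
        prof <- exp(-(dd2 / radius)^2)
        gain <- c(1, 0.9, 0.55)                 # yellowish-white deposits
        for (ch in 1:3)
          img[, , ch] <- img[, , ch] + bright * gain[ch] * prof * (dd2 <= radius + 1)
      }
    }

    structure(list(clean = clip01(img), drusen_mask = mask,
                   macula_center = as.integer(mc), seed = as.integer(seed),
                   params = params),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$params$size, "x", x$params$size,
      ", vessels=", x$params$n_vessels,
      ", drusen px=", sum(x$drusen_mask),
      ", macula=(", x$macula_center[1], ",", x$macula_center[2],
      "), seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Synthesise a UWF-like image from a clean phantom
#'
#' Applies each degradation of `chain` in order to the clean phantom image,
#' then adds seeded Gaussian pixel noise with the phantom's `noise_sd`.
#' Output size follows the chain (a x0.25 bicubic step yields size/4).
#'
#' @param phantom a [generate_phantom()] result.
#' @param chain nonempty list of [degradation_spec()] objects.
#' @param seed integer seed for the pixel noise.
#' @return degraded image in \[0, 1\].
#' @export
synthesize_uwf <- function(phantom, chain = default_uwf_chain(), seed = 0L) {
  if (!inherits(phantom, "phantom"))
    stop("synthesize_uwf: 'phantom' must be a phantom object", call. = FALSE)
  img <- apply_degradations(phantom$clean, chain)
  sd <- phantom$params$noise_sd
  if (sd > 0) {
    img <- with_seed(seed, img + array(stats::rnorm(length(img), 0, sd),
                                       dim = dim(img)))
  }
  clip01(img)
}

#' Write an unpaired two-domain phantom dataset to disk
#'
#' Generates `n` phantoms, writes their clean images (plus drusen masks) to
#' `out_clean_dir` and UWF-like degraded counterparts to `out_uwf_dir`.  The
#' two sets are unpaired by construction: the UWF image at position `i` is
#' synthesised from the phantom underlying clean image `pairing[i]`, where
#' `pairing` is a seeded non-identity permutation.  The manifest records the
#' hidden pairing, per-phantom seeds and macula centres so that tests can run
#' paired oracles even though training never sees the pairing.
#'
#' @param params a [phantom_params()] object.
#' @param n number of images per domain (>= 1).
#' @param out_clean_dir,out_uwf_dir output directories (created if needed).
#' @param seed integer master seed.
#' @param chain degradation chain for UWF synthesis.
#' @return the manifest, invisibly (also written as `manifest.json` in
#'   `out_uwf_dir`).
#' @export
build_unpaired_dataset <- function(params, n, out_clean_dir, out_uwf_dir,
                                   seed = 1L, chain = default_uwf_chain()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("build_unpaired_dataset: 'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  for (d in c(out_clean_dir, out_uwf_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(d))
      stop("build_unpaired_dataset: cannot create directory ", d,
           call. = FALSE)
  }
  phantom_seeds <- vapply(seq_len(n),
                          function(i) derive_seed(seed, paste0("phantom", i)),
                          numeric(1))
  # unpairing permutation: UWF slot i <- phantom pairing[i]
  pairing <- with_seed(derive_seed(seed, "pairing"), sample.int(n))
  if (n >= 2L && all(pairing == seq_len(n)))
    pairing <- c(pairing[-1L], pairing[1L])

  phantoms <- lapply(phantom_seeds, function(s) generate_phantom(params, s))
  clean_files <- file.path(out_clean_dir, sprintf("clean_%03d.png", seq_len(n)))
  mask_files <- file.path(out_clean_dir, sprintf("mask_%03d.png", seq_len(n)))
  uwf_files <- file.path(out_uwf_dir, sprintf("uwf_%03d.png", seq_len(n)))
  for (i in seq_len(n)) {
    save_image(phantoms[[i]]$clean, clean_files[i])
    save_mask(phantoms[[i]]$drusen_mask, mask_files[i])
    uwf <- synthesize_uwf(phantoms[[pairing[i]]], chain,
                          seed = derive_seed(seed, paste0("noise", i)))
    save_image(uwf, uwf_files[i])
  }
  manifest <- list(
    clean_files = basename(clean_files),
    uwf_files = basename(uwf_files),
    masks = basename(mask_files),
    seeds = phantom_seeds,
    pairing = pairing,
    macula_centers = lapply(phantoms, function(p) p$macula_center),
    params = unclass(params),
    chain = lapply(chain, unclass),
    master_seed = seed)
  jsonlite::write_json(manifest, file.path(out_uwf_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset manifest written by [build_unpaired_dataset()]
#' @param uwf_dir the UWF output directory containing `manifest.json`.
#' @return the manifest list.
#' @export
read_manifest <- function(uwf_dir) {
  p <- file.path(uwf_dir, "manifest.json")
  if (!file.exists(p)) stop("no manifest.json in ", uwf_dir, call. = FALSE)
  jsonlite::read_json(p, simplifyVector = TRUE)
}
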