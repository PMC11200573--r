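# Evaluation battery: no-reference sharpness (re-blur gradient ratio),
# lesion-mask IoU and mean average precision, one-way ANOVA with
# Bonferroni-corrected pairwise comparisons, and optional adapters for
# learned perceptual metrics (LPIPS/FID) when an external backend is
# registered.

#' No-reference sharpness (blur) score
#'
#' Re-blur gradient-ratio blur estimate in \[0, 1\]: the luminance channel is
#' re-blurred with a fixed 9-tap separable averaging filter and the loss of
#' neighbouring-pixel variation caused by re-blurring is measured along both
#' axes; the maximum of the two normalised ratios is returned.  An already
#' blurry image changes little under re-blurring, giving a HIGH score;
#' lower = sharper.  A constant image returns 1 (maximal blur) by
#' convention.
#'
#' @param img image array, at least 16 x 16.
#' @return blur score in \[0, 1\].
#' @export
sharpness_score <- function(img) {
  img <- as_image(img)
  if (any(dim(img)[1:2] < 16L))
    stop("sharpness_score: image must be at least 16x16", call. = FALSE)
  f <- luminance(img)
  H <- nrow(f); W <- ncol(f)
  taps <- rep(1 / 9, 9L)
  pad <- 4L
  fp <- reflect_pad(f, pad)
  bver <- matrix(0, H, W + 2L * pad)
  for (i in 1:9) bver <- bver + taps[i] * fp[(i - 1L) + seq_len(H), ]
  bver <- bver[, pad + seq_len(W)]
  bhor <- matrix(0, H + 2L * pad, W)
  for (j in 1:9) bhor <- bhor + taps[j] * fp[, (j - 1L) + seq_len(W)]
  bhor <- bhor[pad + seq_len(H), ]

  d_f_ver <- abs(f[-1L, ] - f[-H, ])
  d_b_ver <- abs(bver[-1L, ] - bver[-H, ])
  d_f_hor <- abs(f[, -1L] - f[, -W])
  d_b_hor <- abs(bhor[, -1L] - bhor[, -W])
  s_ver <- sum(d_f_ver)
  s_hor <- sum(d_f_hor)
  if (s_ver <= .Machine$double.eps && s_hor <= .Machine$double.eps)
    return(1.0)                       # degenerate constant image
  ratio <- function(d_f, d_b, s) {
    if (s <= .Machine$double.eps) return(0)
    v <- pmax(0, d_f - d_b)
    (s - sum(v)) / s
  }
  max(ratio(d_f_ver, d_b_ver, s_ver), ratio(d_f_hor, d_b_hor, s_hor))
}

#' Intersection over union of two binary masks
#'
#' `|A ∩ B| / |A ∪ B|`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b logical (or 0/1) matrices of identical shape.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(mask_a, mask_b) {
  a <- as.matrix(mask_a) != 0
  b <- as.matrix(mask_b) != 0
  if (!identical(dim(a), dim(b)))
    stop("iou: mask shapes differ", call. = FALSE)
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}

#' Mean average precision over lesion-mask pairs
#'
#' Defined as the IoU averaged across images, in percent: the mask-overlap
#' mAP used to compare lesion visibility before and after enhancement.
#'
#' @param pairs nonempty list; each element a list/pair `(mask_pred,
#'   mask_gt)` of equal-shaped binary masks.
#' @return mAP in \[0, 100\].
#' @export
map_score <- function(pairs) {
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("map_score: 'pairs' must be a nonempty list", call. = FALSE)
  100 * mean(vapply(pairs, function(p) iou(p[[1L]], p[[2L]]), numeric(1)))
}

#' One-way fixed-effects ANOVA
#'
#' Classical F statistic with (k-1, N-k) degrees of freedom and its
#' upper-tail p-value.  Degenerate inputs with zero within-group variance
#' return `F = Inf, p = 0` (flagged) when group means differ, and
#' `F = 0, p = 1` when they do not.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return list with `F`, `p`, and `degenerate` flag.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("anova_oneway: need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("anova_oneway: every group needs at least 2 samples", call. = FALSE)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  grand <- mean(x)
  ssb <- sum(tapply(x, g, length) * (tapply(x, g, mean) - grand)^2)
  ssw <- sum((x - ave(x, g))^2)
  if (ssw <= .Machine$double.eps * sum(x^2 + 1)) {
    if (ssb <= .Machine$double.eps * sum(x^2 + 1))
      return(list(F = 0, p = 1, degenerate = TRUE))
    return(list(F = Inf, p = 0, degenerate = TRUE))
  }
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value), degenerate = FALSE)
}

#' Bonferroni-corrected pairwise Welch t tests
#'
#' All `k(k-1)/2` two-sided two-sample (Welch) comparisons;
#' `p_adjusted = min(1, p_raw * m)` with `m` the number of comparisons.
#'
#' @param groups list of >= 2 numeric vectors (>= 2 values each).
#' @param alpha significance level applied to the adjusted p-values.
#' @return data.frame with columns `group_a`, `group_b`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("bonferroni_pairwise: need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("bonferroni_pairwise: every group needs at least 2 samples",
         call. = FALSE)
  k <- length(groups)
  nm <- names(groups) %||% paste0("group", seq_len(k))
  combs <- utils::combn(k, 2L)
  p_raw <- apply(combs, 2L, function(ij) {
    a <- groups[[ij[1L]]]; b <- groups[[ij[2L]]]
    tryCatch(stats::t.test(a, b)$p.value,
             error = function(e) if (isTRUE(all.equal(mean(a), mean(b))))
               1 else 0)
  })
  data.frame(group_a = nm[combs[1L, ]], group_b = nm[combs[2L, ]],
             p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = "bonferroni"),
             significant = stats::p.adjust(p_raw, "bonferroni") < alpha,
             stringsAsFactors = FALSE)
}

## ---- optional learned-metric adapters ---------------------------------------

#' Register an external metric backend
#'
#' The learned perceptual metrics (LPIPS, FID) are defined by fixed
#' pretrained feature extractors and are exposed only as adapters: when a
#' backend function is registered under the metric's name it is delegated
#' to, otherwise the adapters return `NA` (never a fabricated number).
#'
#' @param name `"lpips"` (called as `fn(img_a, img_b)`) or `"fid"` (called
#'   as `fn(dir_a, dir_b)`).
#' @param fn backend function, or NULL to unregister.
#' @export
register_metric_backend <- function(name, fn) {
  stopifnot(name %in% c("lpips", "fid"))
  .uwf_state$metric_backends[[name]] <- fn
  invisible(NULL)
}

#' Learned perceptual image distance (adapter)
#'
#' Smaller = perceptually closer.  Returns `NA` with a notice when no
#' backend is registered.
#'
#' @param img_a,img_b images of identical shape.
#' @return numeric distance or `NA`.
#' @export
lpips_adapter <- function(img_a, img_b) {
  fn <- .uwf_state$metric_backends[["lpips"]]
  if (is.null(fn)) {
    message("lpips_adapter: no LPIPS backend registered; returning NA")
    return(NA_real_)
  }
  fn(as_image(img_a), as_image(img_b))
}

#' Frechet inception distance between two image directories (adapter)
#'
#' Smaller = closer distributions.  Returns `NA` with a notice when no
#' backend is registered.
#'
#' @param dir_a,dir_b image directories.
#' @return numeric distance or `NA`.
#' @export
fid_adapter <- function(dir_a, dir_b) {
  fn <- .uwf_state$metric_backends[["fid"]]
  if (is.null(fn)) {
    message("fid_adapter: no FID backend registered; returning NA")
    return(NA_real_)
  }
  fn(dir_a, dir_b)
}

## ---- drusen detection and reports -------------------------------------------

#' Threshold-based bright-blob drusen detector
#'
#' Subtracts a heavily blurred background from the luminance channel and
#' thresholds the residual, optionally restricted to a macular disk.  A
#' deliberately simple, deterministic detector used to compare lesion
#' visibility before and after enhancement.
#'
#' @param img image array.
#' @param center optional macula centre (row, col).
#' @param radius optional macular radius in pixels.
#' @param threshold residual brightness threshold.
#' @return logical detection mask.
#' @export
detect_drusen <- function(img, center = NULL, radius = NULL,
                          threshold = 0.08) {
  img <- as_image(img)
  lum <- luminance(img)
  sigma <- max(7L, 2L * (min(dim(lum)) %/% 16L) + 1L)
  bg <- luminance(gaussian_blur(img, sigma))
  mask <- (lum - bg) > threshold
  if (!is.null(center)) {
    H <- nrow(lum); W <- ncol(lum)
    if (is.null(radius)) radius <- min(H, W) / 4
    d <- sqrt(outer((seq_len(H) - center[1L])^2,
                    (seq_len(W) - center[2L])^2, `+`))
    mask <- mask & (d <= radius)
  }
  mask
}

#' Evaluate a directory of generated images against a reference domain
#'
#' Computes the per-image sharpness score for both directories, one-way
#' ANOVA plus Bonferroni-corrected pairwise comparison between the two
#' sharpness groups, optional mask mAP, and the optional learned-metric
#' adapters; returns (and optionally writes) a structured report.
#'
#' @param pred_dir directory of generated/enhanced images.
#' @param ref_dir directory of reference-domain images.
#' @param masks_pred,masks_gt optional equal-length lists/directories of
#'   binary mask PNGs for the mAP computation.
#' @param out optional JSON output path.
#' @return an object of class `metric_report`.
#' @export
evaluate_dirs <- function(pred_dir, ref_dir, masks_pred = NULL,
                          masks_gt = NULL, out = NULL) {
  pred <- load_domain_dir(pred_dir)
  ref <- load_domain_dir(ref_dir)
  g_pred <- vapply(pred, sharpness_score, numeric(1))
  g_ref <- vapply(ref, sharpness_score, numeric(1))
  per_image <- data.frame(file = names(pred), gamma = unname(g_pred),
                          stringsAsFactors = FALSE)
  map <- NULL
  if (!is.null(masks_pred) && !is.null(masks_gt)) {
    if (is.character(masks_pred) && length(masks_pred) == 1L &&
        dir.exists(masks_pred))
      masks_pred <- lapply(sort(list.files(masks_pred, "\\.png$",
                                           full.names = TRUE)), load_mask)
    if (is.character(masks_gt) && length(masks_gt) == 1L &&
        dir.exists(masks_gt))
      masks_gt <- lapply(sort(list.files(masks_gt, "\\.png$",
                                         full.names = TRUE)), load_mask)
    map <- map_score(Map(list, masks_pred, masks_gt))
  }
  groups <- list(pred = unname(g_pred), ref = unname(g_ref))
  av <- anova_oneway(groups)
  pw <- bonferroni_pairwise(groups)
  fid <- suppressMessages(fid_adapter(pred_dir, ref_dir))
  report <- structure(list(
    per_image = per_image,
    aggregate = list(gamma_mean = mean(g_pred), gamma_sd = stats::sd(g_pred),
                     ref_gamma_mean = mean(g_ref),
                     fid = fid, map = map),
    stats = list(anova_F = av$F, anova_p = av$p, degenerate = av$degenerate,
                 pairwise = pw)), class = "metric_report")
  if (!is.null(out)) {
    rep_json <- report
    rep_json$stats$pairwise <- as.list(pw)
    jsonlite::write_json(unclass(rep_json), out, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> n =", nrow(x$per_image),
      " gamma:", format(x$aggregate$gamma_mean, digits = 4),
      "+/-", format(x$aggregate$gamma_sd, digits = 4),
      " (ref:", format(x$aggregate$ref_gamma_mean, digits = 4), ")\n")
  if (!is.null(x$aggregate$map)) cat("  mAP:", x$aggregate$map, "%\n")
  cat("  ANOVA F =", format(x$stats$anova_F, digits = 5),
      ", p =", format(x$stats$anova_p, digits = 4), "\n")
  invisible(x)
}
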