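# The complete loss suite of the two-stage adversarial pipeline: adversarial
# losses for both generator/critic pairs, the identity mapping loss, the
# weight-anchor L2 regulariser tying adapted parameters to their pretrained
# snapshot, the one-way cycle constraint, and the stage composites.
#
# Convention: the critic objective is the standard cross-entropy form
#   d_loss = -E[log D(real)] - E[log(1 - D(fake))]
# and the generator uses the non-saturating form  g_loss = -E[log D(fake)].
# Critic outputs are clamped away from {0, 1} by 1e-7 so every loss is finite.

#' Loss weights of the stage composites
#'
#' Defaults are the canonical settings: identity 0.5, weight anchor 0.1,
#' cycle 0.5.
#'
#' @param lambda_I identity-loss weight (degradation-enhancement stage).
#' @param lambda_R weight-anchor weight (degradation-enhancement stage).
#' @param lambda_C one-way cycle weight (super-resolution stage).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_I = 0.5, lambda_R = 0.1, lambda_C = 0.5) {
  for (v in c(lambda_I, lambda_R, lambda_C))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("loss_weights: weights must be single nonnegative numbers",
           call. = FALSE)
  structure(list(lambda_I = lambda_I, lambda_R = lambda_R,
                 lambda_C = lambda_C), class = "loss_weights")
}

new_breakdown <- function(stage, adv_g = NA_real_, adv_d = NA_real_,
                          identity = NA_real_, anchor = NA_real_,
                          cycle = NA_real_, total) {
  structure(list(stage = stage, adv_g = adv_g, adv_d = adv_d,
                 identity = identity, anchor = anchor, cycle = cycle,
                 total = total), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  comp <- unlist(x[c("adv_g", "adv_d", "identity", "anchor", "cycle")])
  comp <- comp[!is.na(comp)]
  cat("<loss_breakdown:", x$stage, "> total = ", format(x$total), " (",
      paste(names(comp), format(comp, digits = 4), sep = "=",
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# tape-level critic loss on given real/fake nodes
adv_d_node <- function(critic, real_nd, fake_nd, training = TRUE) {
  dr <- disc_forward(critic, real_nd, training)
  df <- disc_forward(critic, fake_nd, training)
  term_r <- ag_mean(ag_log(dr))
  term_f <- ag_mean(ag_log(ag_one_minus(df)))
  ag_scale(ag_add(term_r, term_f), -1)
}

# tape-level non-saturating generator loss
adv_g_node <- function(critic, fake_nd, training = TRUE) {
  df <- disc_forward(critic, fake_nd, training)
  ag_scale(ag_mean(ag_log(df)), -1)
}

#' Adversarial losses for a critic and a real/fake image pair
#'
#' Computes the critic loss `-mean(log D(real)) - mean(log(1 - D(fake)))`
#' and the non-saturating generator loss `-mean(log D(fake))`.  The fake
#' batch is treated as constant for the critic loss and as the generator
#' output for the generator loss.  Serves both adversarial pairs of the
#' pipeline (low-resolution enhanced-vs-downsampled and full-resolution
#' super-resolved-vs-fundus).
#'
#' @param critic a critic built with [build_discriminator()].
#' @param real_batch,fake_batch image batches (list of images or 4-d array).
#' @return list with `d_loss` and `g_loss`.
#' @export
adversarial_loss <- function(critic, real_batch, fake_batch) {
  real <- stack_images(real_batch)
  fake <- stack_images(fake_batch)
  if (dim(real)[4L] < 1L || dim(fake)[4L] < 1L)
    stop("adversarial_loss: empty batch", call. = FALSE)
  tape <- ag_tape()
  rn <- ag_const(tape, real)
  fn <- ag_const(tape, fake)
  d <- adv_d_node(critic, rn, fn, training = FALSE)
  g <- adv_g_node(critic, fn, training = FALSE)
  list(d_loss = d$value, g_loss = g$value)
}

#' Identity mapping loss of the enhancer
#'
#' Mean absolute difference between the enhancer's output and its input,
#' averaged over pixels, channels and batch.  Keeps the enhancer from
#' altering the style (colour, structure) of its source domain more than the
#' adversarial signal requires.
#'
#' @param enhancer a `uwf_net` built with [build_gde()].
#' @param batch image batch.
#' @return nonnegative scalar.
#' @export
identity_loss <- function(enhancer, batch) {
  xb <- stack_images(batch)
  if (dim(xb)[4L] < 1L) stop("identity_loss: empty batch", call. = FALSE)
  tape <- ag_tape()
  nd <- ag_const(tape, xb)
  out <- gde_forward(enhancer, nd, training = FALSE)
  ag_mean_abs_diff(out, nd)$value
}

#' Weight-anchor L2 regulariser
#'
#' Mean squared deviation of the current (non-frozen) enhancer parameters
#' from their pretrained snapshot, over all anchored scalars; prevents
#' catastrophic drift away from the pretrained initialisation during
#' adversarial adaptation.
#'
#' @param current_params named list of numeric arrays (or of parameter
#'   environments as returned by [net_params()]).
#' @param anchor_params snapshot with identical structure
#'   (see [param_snapshot()]).
#' @return nonnegative scalar.
#' @export
weight_anchor_loss <- function(current_params, anchor_params) {
  vals <- lapply(current_params, function(p)
    if (is.environment(p)) p$value else p)
  if (!identical(sort(names(vals)), sort(names(anchor_params))))
    stop("weight_anchor_loss: parameter structures do not match",
         call. = FALSE)
  tot <- 0; n <- 0
  for (nm in names(vals)) {
    if (length(vals[[nm]]) != length(anchor_params[[nm]]))
      stop("weight_anchor_loss: shape mismatch for ", nm, call. = FALSE)
    tot <- tot + sum((as.numeric(vals[[nm]]) -
                        as.numeric(anchor_params[[nm]]))^2)
    n <- n + length(vals[[nm]])
  }
  tot / n
}

#' Composite degradation-enhancement loss
#'
#' `total = adv_g + lambda_I * identity + lambda_R * anchor`.
#'
#' @param components list carrying `adv_g`, `identity`, `anchor` (and
#'   optionally `adv_d`, recorded but not part of the generator total).
#' @param weights a [loss_weights()].
#' @return a `loss_breakdown` with `stage = "DE"`.
#' @export
total_de_loss <- function(components, weights = loss_weights()) {
  total <- components$adv_g + weights$lambda_I * components$identity +
    weights$lambda_R * components$anchor
  new_breakdown("DE", adv_g = components$adv_g,
                adv_d = components$adv_d %||% NA_real_,
                identity = components$identity, anchor = components$anchor,
                total = total)
}

#' One-way cycle-consistency loss
#'
#' Downsamples each fundus-domain image by the pipeline's factor (bicubic,
#' scale 1/4), super-resolves it with the upscaler, and returns the mean
#' absolute difference to the original (L1).  The cycle runs one way only —
#' there is no reverse generator.  Images whose sides are not divisible by 4
#' are cropped to the largest multiple of 4 first.
#'
#' @param upscaler a `uwf_net` built with [build_gsr()].
#' @param fundus_batch image batch.
#' @return nonnegative scalar.
#' @export
cycle_loss <- function(upscaler, fundus_batch) {
  xb <- stack_images(fundus_batch)
  d <- dim(xb)
  H4 <- (d[1L] %/% 4L) * 4L; W4 <- (d[2L] %/% 4L) * 4L
  xb <- xb[seq_len(H4), seq_len(W4), , , drop = FALSE]
  ds <- array(0, dim = c(H4 %/% 4L, W4 %/% 4L, 3L, d[4L]))
  for (i in seq_len(d[4L]))
    ds[, , , i] <- bicubic_resample(xb[, , , i], 0.25)
  tape <- ag_tape()
  up <- gsr_forward(upscaler, ag_const(tape, ds), training = FALSE)
  ag_mean_abs_diff(up, ag_const(tape, xb))$value
}

#' Composite super-resolution loss
#'
#' `total = adv_g + lambda_C * cycle`.
#'
#' @param components list carrying `adv_g` and `cycle` (optionally `adv_d`).
#' @param weights a [loss_weights()].
#' @return a `loss_breakdown` with `stage = "SR"`.
#' @export
total_sr_loss <- function(components, weights = loss_weights()) {
  total <- components$adv_g + weights$lambda_C * components$cycle
  new_breakdown("SR", adv_g = components$adv_g,
                adv_d = components$adv_d %||% NA_real_,
                cycle = components$cycle, total = total)
}

#' Macular fine-tuning loss
#'
#' The fine-tuning objective is the sum of the two stage composites,
#' evaluated on the same macular-patch batch: `total = LE + LSR`.
#'
#' @param de_breakdown a `loss_breakdown` from [total_de_loss()].
#' @param sr_breakdown a `loss_breakdown` from [total_sr_loss()].
#' @return a `loss_breakdown` with `stage = "FT"`.
#' @export
total_finetune_loss <- function(de_breakdown, sr_breakdown) {
  new_breakdown("FT", adv_g = de_breakdown$adv_g + sr_breakdown$adv_g,
                adv_d = de_breakdown$adv_d + sr_breakdown$adv_d,
                identity = de_breakdown$identity,
                anchor = de_breakdown$anchor, cycle = sr_breakdown$cycle,
                total = de_breakdown$total + sr_breakdown$total)
}
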