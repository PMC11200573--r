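# Three-stage training scheme: (i) supervised pretraining of the enhancer on
# synthetic phantom pairs followed by adversarial adaptation with a frozen
# encoder, (ii) super-resolution training with the whole enhancer frozen and
# a one-way cycle constraint, (iii) joint fine-tuning on macular patches.
# AdamW with a halving learning-rate schedule throughout.

#' Stage configuration
#'
#' Canonical full-scale defaults: batch 16, 128-pixel fundus patches,
#' learning rate 1e-3 halved every 200000 iterations, AdamW betas
#' (0.9, 0.999), eps 1e-8, decoupled weight decay 1e-2.  `patch_size` refers
#' to the fundus-domain patch; the UWF-domain patch is `patch_size/scale`
#' since UWF-domain images are natively 1/scale the linear size.  Default
#' frozen groups per stage: DE freezes the encoder, SR freezes the whole
#' enhancer, PRETRAIN and FT freeze nothing.
#'
#' @param stage one of `"PRETRAIN"`, `"DE"`, `"SR"`, `"FT"`.
#' @param iterations number of optimisation iterations.
#' @param batch_size patches per step.
#' @param patch_size fundus-domain patch side; divisible by 4 and by
#'   `2^depth * 4` for enhancer padding-free operation.
#' @param lr base learning rate.
#' @param betas,eps,weight_decay AdamW settings.
#' @param critic_lr critic learning rate; defaults to `lr`.  The critics
#'   are fresh networks even when the generator is only fine-tuned, so
#'   their rate is configurable independently.
#' @param critic_lr_scale multiplier applied to `critic_lr` after the
#'   warm-up phase (two-timescale balancing knob).
#' @param critic_warmup iterations at the start of an adversarial stage
#'   during which only the critic updates (generator losses are still
#'   computed and logged); gives the adversary a calibrated starting point
#'   before the generator begins chasing it.
#' @param lr_halving_period iterations between learning-rate halvings.
#' @param seed stage seed.
#' @param frozen_groups parameter groups excluded from updates; `NULL` means
#'   the stage default.
#' @param weights a [loss_weights()].
#' @param log_file optional JSON-lines loss log path.
#' @param checkpoint_every iterations between checkpoints when
#'   `checkpoint_dir` is set.
#' @param checkpoint_dir optional checkpoint directory.
#' @return an object of class `stage_config`.
#' @export
stage_config <- function(stage = c("PRETRAIN", "DE", "SR", "FT"),
                         iterations = 500L, batch_size = 16L,
                         patch_size = 128L, lr = 1e-3,
                         betas = c(0.9, 0.999), eps = 1e-8,
                         weight_decay = 1e-2, critic_lr = NULL,
                         critic_lr_scale = 1,
                         critic_warmup = 0L, lr_halving_period = 200000L,
                         seed = 1L, frozen_groups = NULL,
                         weights = loss_weights(), log_file = NULL,
                         checkpoint_every = Inf, checkpoint_dir = NULL) {
  stage <- match.arg(stage)
  if (is.null(frozen_groups))
    frozen_groups <- switch(stage,
      PRETRAIN = character(0),
      DE = "encoder",
      SR = c("encoder", "decoder", "attention"),
      FT = character(0))
  if (patch_size %% 4L != 0L)
    stop("stage_config: patch_size must be divisible by 4", call. = FALSE)
  structure(list(stage = stage, iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size), lr = lr, betas = betas,
                 eps = eps, weight_decay = weight_decay,
                 critic_lr = critic_lr %||% lr,
                 critic_lr_scale = critic_lr_scale,
                 critic_warmup = as.integer(critic_warmup),
                 lr_halving_period = as.integer(lr_halving_period),
                 seed = as.integer(seed), frozen_groups = frozen_groups,
                 weights = weights, log_file = log_file,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "stage_config")
}

#' Learning rate at a given iteration
#'
#' `base_lr * 0.5 ^ floor(iteration / halving_period)`.
#'
#' @param iteration iteration counter (0-based).
#' @param base_lr base learning rate.
#' @param halving_period iterations between halvings.
#' @return the scheduled learning rate.
#' @export
lr_at <- function(iteration, base_lr, halving_period) {
  if (iteration < 0) stop("lr_at: iteration must be >= 0", call. = FALSE)
  base_lr * 0.5^floor(iteration / halving_period)
}

rot90cw <- function(img) {
  H <- dim(img)[1L]
  aperm(img[H:1, , , drop = FALSE], c(2L, 1L, 3L))
}

augment_patch <- function(patch) {
  k <- sample.int(4L, 1L) - 1L
  if (k > 0L) for (i in seq_len(k)) patch <- rot90cw(patch)
  if (sample.int(2L, 1L) == 2L)
    patch <- patch[, rev(seq_len(dim(patch)[2L])), , drop = FALSE]
  if (sample.int(2L, 1L) == 2L)
    patch <- patch[rev(seq_len(dim(patch)[1L])), , , drop = FALSE]
  patch
}

#' Extract random patches from an image
#'
#' Seeded uniform-random square crops, optionally restricted so that patch
#' centres lie within `region$radius` of `region$center`, with optional
#' rotation (0/90/180/270 degrees) and horizontal/vertical flip
#' augmentation.
#'
#' @param img image array.
#' @param patch_size square patch side; must not exceed the image.
#' @param n number of patches.
#' @param region optional `list(center = c(row, col), radius = r)`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param augment apply random rotation/flip augmentation.
#' @return list of patch arrays.
#' @export
extract_patches <- function(img, patch_size, n = 1L, region = NULL,
                            seed = NULL, augment = FALSE) {
  img <- as_image(img)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  p <- as.integer(patch_size)
  if (p > H || p > W)
    stop("extract_patches: image ", H, "x", W, " smaller than patch ", p,
         call. = FALSE)
  draw <- function() {
    lo_y <- 1L; hi_y <- H - p + 1L
    lo_x <- 1L; hi_x <- W - p + 1L
    if (!is.null(region)) {
      mc <- region$center; r <- region$radius
      half <- (p - 1) / 2
      lo_y <- max(lo_y, ceiling(mc[1L] - r - half))
      hi_y <- min(hi_y, floor(mc[1L] + r - half))
      lo_x <- max(lo_x, ceiling(mc[2L] - r - half))
      hi_x <- min(hi_x, floor(mc[2L] + r - half))
      if (lo_y > hi_y) lo_y <- hi_y <- min(max(round(mc[1L] - half), 1L),
                                           H - p + 1L)
      if (lo_x > hi_x) lo_x <- hi_x <- min(max(round(mc[2L] - half), 1L),
                                           W - p + 1L)
      for (try in 1:50) {
        ty <- sample(lo_y:hi_y, 1L)
        tx <- sample(lo_x:hi_x, 1L)
        cy <- ty + half; cx <- tx + half
        if ((cy - mc[1L])^2 + (cx - mc[2L])^2 <= r^2)
          return(c(ty, tx))
      }
      # fall back to the in-range corner closest to the region centre
      ty <- min(max(round(mc[1L] - half), lo_y), hi_y)
      tx <- min(max(round(mc[2L] - half), lo_x), hi_x)
      return(c(ty, tx))
    }
    c(sample(lo_y:hi_y, 1L), sample(lo_x:hi_x, 1L))
  }
  go <- function() {
    lapply(seq_len(n), function(i) {
      t <- draw()
      patch <- img[t[1L] + seq_len(p) - 1L, t[2L] + seq_len(p) - 1L, ,
                   drop = FALSE]
      if (augment) patch <- augment_patch(patch)
      attr(patch, "corner") <- t          # crop-log for region audits
      patch
    })
  }
  if (is.null(seed)) go() else with_seed(seed, go())
}

# read all PNG/JPEG/TIFF images of a directory, sorted by name
load_domain_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|jpe?g|tiff?)$",
                           ignore.case = TRUE, full.names = TRUE))
  files <- files[!grepl("^mask_", basename(files))]
  if (length(files) == 0L)
    stop("no images found in ", dir, call. = FALSE)
  imgs <- lapply(files, load_image)
  names(imgs) <- basename(files)
  imgs
}

# sample a batch of patches across a pool of images (uses current RNG)
sample_patch_batch <- function(imgs, patch_size, batch_size, regions = NULL,
                               augment = TRUE) {
  idx <- sample.int(length(imgs), batch_size, replace = TRUE)
  patches <- lapply(idx, function(i)
    extract_patches(imgs[[i]], patch_size, n = 1L,
                    region = if (!is.null(regions)) regions[[i]],
                    augment = augment)[[1L]])
  stack_images(patches)
}

append_log <- function(cfg, rec) {
  if (is.null(cfg$log_file)) return(invisible(NULL))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = cfg$log_file, append = TRUE)
  invisible(NULL)
}

new_train_state <- function(stage, iteration, nets, anchor, history, cfg,
                            rng_state = NULL) {
  if (is.null(rng_state)) {
    rng_state <- attr(history, "rng_state")
    if (is.null(rng_state))
      rng_state <- get(".Random.seed", envir = globalenv())
  }
  structure(list(stage = stage, iteration = iteration, nets = nets,
                 anchor = anchor, history = history, cfg = cfg,
                 rng_state = rng_state),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat("<train_state:", x$stage, "> iteration ", x$iteration, ", nets: ",
      paste(names(x$nets), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Save / load a training checkpoint
#'
#' The checkpoint is a serialized `train_state` (parameters, optimizer
#' moments, normalisation statistics, anchor snapshot, RNG state, loss
#' history) plus a small JSON sidecar describing stage, iteration and seed.
#'
#' @param state a `train_state`.
#' @param dir checkpoint directory (created if needed).
#' @return the checkpoint path (`save_checkpoint`) or the restored
#'   `train_state` (`load_checkpoint`).
#' @export
save_checkpoint <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, sprintf("%s_%06d.ckpt", state$stage,
                                 state$iteration))
  saveRDS(state, path)
  jsonlite::write_json(list(stage = state$stage,
                            iteration = state$iteration,
                            seed = state$cfg$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path a checkpoint file written by [save_checkpoint()] (or a
#'   directory, in which case the latest checkpoint is used).
#' @export
load_checkpoint <- function(path) {
  if (dir.exists(path)) {
    cks <- sort(list.files(path, pattern = "\\.ckpt$", full.names = TRUE))
    if (length(cks) == 0L) stop("no checkpoints in ", path, call. = FALSE)
    path <- cks[length(cks)]
  }
  readRDS(path)
}

# run `body(iter)` for the remaining iterations of a stage under the stage's
# (or resumed) RNG state, restoring the caller's RNG afterwards
run_stage_loop <- function(cfg, resume_state, history_init, body) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  })
  first <- 1L
  history <- history_init
  if (!is.null(resume_state)) {
    assign(".Random.seed", resume_state$rng_state, envir = globalenv())
    first <- resume_state$iteration + 1L
    history <- resume_state$history
  } else {
    set.seed(as.integer(derive_seed(cfg$seed, cfg$stage) %% 2147483647))
  }
  for (it in seq(first, length.out = max(0L, cfg$iterations - first + 1L)))
    history <- body(it, history)
  # stash the loop's final RNG state so checkpoints can resume exactly
  attr(history, "rng_state") <- get(".Random.seed", envir = globalenv())
  history
}

#' Build a paired pretraining set of degraded/clean phantom patches
#'
#' Generates `n` phantoms and pairs each UWF-like synthesis with the x4
#' bicubic downsample of its own clean image (the enhancer preserves size,
#' so the supervision target lives at the UWF resolution).
#'
#' @param params a [phantom_params()].
#' @param n number of pairs.
#' @param seed integer seed.
#' @param chain degradation chain for the inputs.
#' @return list with `input` and `target` image lists.
#' @export
build_pretrain_set <- function(params, n, seed = 1L,
                               chain = default_uwf_chain()) {
  inputs <- vector("list", n)
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(params, derive_seed(seed, paste0("pre", i)))
    inputs[[i]] <- synthesize_uwf(ph, chain,
                                  seed = derive_seed(seed,
                                                     paste0("prenoise", i)))
    targets[[i]] <- bicubic_resample(ph$clean, 0.25)
  }
  list(input = inputs, target = targets)
}

#' Supervised pretraining of the enhancer
#'
#' Trains the enhancer with a mean-absolute-error reconstruction loss on
#' paired (degraded, clean) phantom data and returns both the trained
#' network and a deep-copied parameter snapshot, which later serves as the
#' anchor of the weight-anchor regulariser.
#'
#' @param dataset a list with `input` and `target` image lists of identical
#'   sizes (e.g. from [build_pretrain_set()]).
#' @param enhancer a `uwf_net` from [build_gde()].
#' @param cfg a [stage_config()] with `stage = "PRETRAIN"`.
#' @param resume_state optional `train_state` to continue from.
#' @return a `train_state` whose `nets$enhancer` is the trained network and
#'   whose `anchor` is the post-pretraining snapshot.
#' @export
pretrain_gde <- function(dataset, enhancer, cfg, resume_state = NULL) {
  if (length(dataset$input) == 0L)
    stop("pretrain_gde: empty dataset", call. = FALSE)
  stopifnot(cfg$stage == "PRETRAIN")
  p_uwf <- cfg$patch_size %/% 4L
  history <- run_stage_loop(cfg, resume_state, data.frame(), function(it, h) {
    idx <- sample.int(length(dataset$input), cfg$batch_size, replace = TRUE)
    xs <- vector("list", cfg$batch_size)
    ys <- vector("list", cfg$batch_size)
    for (j in seq_along(idx)) {
      H <- dim(dataset$input[[idx[j]]])[1L]
      p <- min(p_uwf, H)
      ty <- sample.int(H - p + 1L, 1L)
      tx <- sample.int(dim(dataset$input[[idx[j]]])[2L] - p + 1L, 1L)
      xs[[j]] <- dataset$input[[idx[j]]][ty:(ty + p - 1L),
                                         tx:(tx + p - 1L), , drop = FALSE]
      ys[[j]] <- dataset$target[[idx[j]]][ty:(ty + p - 1L),
                                          tx:(tx + p - 1L), , drop = FALSE]
    }
    tape <- ag_tape()
    out <- gde_forward(enhancer, ag_const(tape, stack_images(xs)),
                       training = TRUE)
    loss <- ag_mean_abs_diff(out, ag_const(tape, stack_images(ys)))
    ag_backward(loss)
    adamw_step(tape, lr_at(it - 1L, cfg$lr, cfg$lr_halving_period),
               cfg$betas, cfg$eps, cfg$weight_decay, cfg$frozen_groups)
    rec <- list(iter = it, stage = "PRETRAIN", recon = loss$value)
    append_log(cfg, rec)
    rbind(h, as.data.frame(rec))
  })
  enhancer$stage_trained <- "PRETRAIN"
  state <- new_train_state("PRETRAIN", cfg$iterations,
                           list(enhancer = enhancer),
                           anchor = param_snapshot(enhancer), history, cfg)
  if (!is.null(cfg$checkpoint_dir)) save_checkpoint(state, cfg$checkpoint_dir)
  state
}

#' Adversarial adaptation of the enhancer (stage DE)
#'
#' Alternating critic/generator steps: the critic sees bicubic x4
#' downsamples of fundus patches as real and enhancer outputs on UWF patches
#' as fake; the generator minimises the composite of the non-saturating
#' adversarial loss, the identity loss and the weight-anchor regulariser.
#' The encoder group stays frozen (bit-identical before/after).
#'
#' @param uwf_dir,fundus_dir directories of the two unpaired domains.
#' @param enhancer a pretrained `uwf_net` from [build_gde()].
#' @param anchor parameter snapshot anchoring the regulariser (typically the
#'   `anchor` of the pretraining state).
#' @param cfg a [stage_config()] with `stage = "DE"`.
#' @param critic optional critic (built fresh when NULL).
#' @param resume_state optional `train_state` to continue from.
#' @return a `train_state` with nets `enhancer` and `critic_de`.
#' @export
train_stage_de <- function(uwf_dir, fundus_dir, enhancer, anchor, cfg,
                           critic = NULL, resume_state = NULL) {
  stopifnot(cfg$stage == "DE")
  uwf <- load_domain_dir(uwf_dir)
  fundus <- load_domain_dir(fundus_dir)
  if (!is.null(resume_state)) critic <- resume_state$nets$critic_de
  if (is.null(critic))
    critic <- build_discriminator(enhancer$cfg,
                                  seed = derive_seed(cfg$seed, "dde"))
  anchored <- net_params(enhancer, c("decoder", "attention"))
  anchor_vals <- anchor[names(anchored)]
  p_uwf <- cfg$patch_size %/% 4L
  gen_frozen <- union(cfg$frozen_groups, "critic")
  crit_frozen <- c("encoder", "decoder", "attention", "gsr")
  history <- run_stage_loop(cfg, resume_state, data.frame(), function(it, h) {
    lr <- lr_at(it - 1L, cfg$lr, cfg$lr_halving_period)
    fpatch <- sample_patch_batch(fundus, cfg$patch_size, cfg$batch_size)
    real <- array(0, dim = c(p_uwf, p_uwf, 3L, cfg$batch_size))
    for (i in seq_len(cfg$batch_size))
      real[, , , i] <- bicubic_resample(fpatch[, , , i], 0.25)
    z <- sample_patch_batch(uwf, p_uwf, cfg$batch_size)

    # generator step (encoder frozen; critic untouched)
    tape_g <- ag_tape()
    zn <- ag_const(tape_g, z)
    fake_nd <- gde_forward(enhancer, zn, training = TRUE)
    g_adv <- adv_g_node(critic, fake_nd, training = TRUE)
    ident <- ag_mean_abs_diff(fake_nd, zn)
    anch <- ag_anchor(tape_g, anchored, anchor_vals)
    total <- ag_add(g_adv,
                    ag_add(ag_scale(ident, cfg$weights$lambda_I),
                           ag_scale(anch, cfg$weights$lambda_R)))
    ag_backward(total)
    if (it > cfg$critic_warmup)
      adamw_step(tape_g, lr, cfg$betas, cfg$eps, cfg$weight_decay,
                 gen_frozen)

    # critic step on the same fake batch, detached
    tape_d <- ag_tape()
    d_loss <- adv_d_node(critic, ag_const(tape_d, real),
                         ag_const(tape_d, fake_nd$value), training = TRUE)
    ag_backward(d_loss)
    d_lr <- if (it <= cfg$critic_warmup) cfg$critic_lr
            else cfg$critic_lr * cfg$critic_lr_scale
    adamw_step(tape_d, d_lr, cfg$betas, cfg$eps,
               cfg$weight_decay, crit_frozen)

    rec <- list(iter = it, stage = "DE", adv_g = g_adv$value,
                adv_d = d_loss$value, identity = ident$value,
                anchor = anch$value, total = total$value)
    append_log(cfg, rec)
    h <- rbind(h, as.data.frame(rec))
    if (is.finite(cfg$checkpoint_every) && !is.null(cfg$checkpoint_dir) &&
        it %% cfg$checkpoint_every == 0L)
      save_checkpoint(new_train_state("DE", it,
                                      list(enhancer = enhancer,
                                           critic_de = critic),
                                      anchor, h, cfg), cfg$checkpoint_dir)
    h
  })
  enhancer$stage_trained <- "DE"
  state <- new_train_state("DE", cfg$iterations,
                           list(enhancer = enhancer, critic_de = critic),
                           anchor, history, cfg)
  if (!is.null(cfg$checkpoint_dir)) save_checkpoint(state, cfg$checkpoint_dir)
  state
}

#' Super-resolution training (stage SR)
#'
#' The enhancer is frozen (all groups) and run in inference mode to produce
#' enhanced low-resolution images; the upscaler is trained with the
#' non-saturating adversarial loss against full-resolution fundus patches
#' plus the weighted one-way cycle loss.
#'
#' @inheritParams train_stage_de
#' @param upscaler a `uwf_net` from [build_gsr()].
#' @param cfg a [stage_config()] with `stage = "SR"`.
#' @return a `train_state` with nets `enhancer`, `upscaler`, `critic_sr`.
#' @export
train_stage_sr <- function(uwf_dir, fundus_dir, enhancer, upscaler, cfg,
                           critic = NULL, resume_state = NULL) {
  stopifnot(cfg$stage == "SR")
  if (is.null(enhancer$stage_trained))
    stop("train_stage_sr: the enhancer has not been through the DE stage; ",
         "run pretraining and train_stage_de first", call. = FALSE)
  uwf <- load_domain_dir(uwf_dir)
  fundus <- load_domain_dir(fundus_dir)
  if (!is.null(resume_state)) critic <- resume_state$nets$critic_sr
  if (is.null(critic))
    critic <- build_discriminator(upscaler$cfg,
                                  seed = derive_seed(cfg$seed, "dsr"))
  p_uwf <- cfg$patch_size %/% 4L
  gen_frozen <- union(cfg$frozen_groups, "critic")
  crit_frozen <- c("encoder", "decoder", "attention", "gsr")
  history <- run_stage_loop(cfg, resume_state, data.frame(), function(it, h) {
    lr <- lr_at(it - 1L, cfg$lr, cfg$lr_halving_period)
    fpatch <- sample_patch_batch(fundus, cfg$patch_size, cfg$batch_size)
    z <- sample_patch_batch(uwf, p_uwf, cfg$batch_size)
    # frozen enhancer in inference mode produces the SR inputs
    e_uwf <- net_forward(enhancer, z, training = FALSE, clip = TRUE)
    ds <- array(0, dim = c(p_uwf, p_uwf, 3L, cfg$batch_size))
    for (i in seq_len(cfg$batch_size))
      ds[, , , i] <- bicubic_resample(fpatch[, , , i], 0.25)

    tape_g <- ag_tape()
    fake_nd <- gsr_forward(upscaler, ag_const(tape_g, e_uwf),
                           training = TRUE)
    g_adv <- adv_g_node(critic, fake_nd, training = TRUE)
    cyc_nd <- gsr_forward(upscaler, ag_const(tape_g, ds), training = TRUE)
    cyc <- ag_mean_abs_diff(cyc_nd, ag_const(tape_g, fpatch))
    total <- ag_add(g_adv, ag_scale(cyc, cfg$weights$lambda_C))
    ag_backward(total)
    if (it > cfg$critic_warmup)
      adamw_step(tape_g, lr, cfg$betas, cfg$eps, cfg$weight_decay,
                 gen_frozen)

    tape_d <- ag_tape()
    d_loss <- adv_d_node(critic, ag_const(tape_d, fpatch),
                         ag_const(tape_d, fake_nd$value), training = TRUE)
    ag_backward(d_loss)
    d_lr <- if (it <= cfg$critic_warmup) cfg$critic_lr
            else cfg$critic_lr * cfg$critic_lr_scale
    adamw_step(tape_d, d_lr, cfg$betas, cfg$eps,
               cfg$weight_decay, crit_frozen)

    rec <- list(iter = it, stage = "SR", adv_g = g_adv$value,
                adv_d = d_loss$value, cycle = cyc$value,
                total = total$value)
    append_log(cfg, rec)
    h <- rbind(h, as.data.frame(rec))
    if (is.finite(cfg$checkpoint_every) && !is.null(cfg$checkpoint_dir) &&
        it %% cfg$checkpoint_every == 0L)
      save_checkpoint(new_train_state("SR", it,
                                      list(enhancer = enhancer,
                                           upscaler = upscaler,
                                           critic_sr = critic),
                                      NULL, h, cfg), cfg$checkpoint_dir)
    h
  })
  upscaler$stage_trained <- "SR"
  state <- new_train_state("SR", cfg$iterations,
                           list(enhancer = enhancer, upscaler = upscaler,
                                critic_sr = critic),
                           NULL, history, cfg)
  if (!is.null(cfg$checkpoint_dir)) save_checkpoint(state, cfg$checkpoint_dir)
  state
}

#' Whole-model macular fine-tuning (stage FT)
#'
#' Joint optimisation of enhancer and upscaler (nothing frozen) with the sum
#' of the two stage composites, using only patches whose centres lie in the
#' macular region.  Macula centres are taken from the phantom manifest when
#' present, from the `macula_centers` argument, or default to the image
#' centre with radius `0.25 * min(H, W)`.
#'
#' @inheritParams train_stage_sr
#' @param anchor anchor snapshot for the weight-anchor term.
#' @param cfg a [stage_config()] with `stage = "FT"`.
#' @param macula_centers optional list of (row, col) centres, one per image
#'   of each domain, at that domain's own pixel scale: a list with elements
#'   `uwf` and `fundus`.
#' @param critics optional list with `de` and `sr` critics to continue with.
#' @return a `train_state` with all four networks.
#' @export
finetune_macular <- function(uwf_dir, fundus_dir, enhancer, upscaler, anchor,
                             cfg, macula_centers = NULL, critics = NULL,
                             resume_state = NULL) {
  stopifnot(cfg$stage == "FT")
  if (is.null(enhancer$stage_trained) || is.null(upscaler$stage_trained))
    stop("finetune_macular: DE and SR stages must be trained first",
         call. = FALSE)
  uwf <- load_domain_dir(uwf_dir)
  fundus <- load_domain_dir(fundus_dir)
  regions <- macular_regions(uwf_dir, uwf, fundus, macula_centers)
  if (!is.null(resume_state)) critics <- resume_state$nets[c("critic_de",
                                                             "critic_sr")]
  if (is.null(critics) || is.null(critics[[1L]]))
    critics <- list(critic_de = build_discriminator(
                      enhancer$cfg, seed = derive_seed(cfg$seed, "ft_dde")),
                    critic_sr = build_discriminator(
                      upscaler$cfg, seed = derive_seed(cfg$seed, "ft_dsr")))
  anchored <- net_params(enhancer, c("decoder", "attention"))
  anchor_vals <- anchor[names(anchored)]
  p_uwf <- cfg$patch_size %/% 4L
  gen_frozen <- "critic"
  crit_frozen <- c("encoder", "decoder", "attention", "gsr")
  history <- run_stage_loop(cfg, resume_state, data.frame(), function(it, h) {
    lr <- lr_at(it - 1L, cfg$lr, cfg$lr_halving_period)
    fpatch <- sample_patch_batch(fundus, cfg$patch_size, cfg$batch_size,
                                 regions = regions$fundus)
    z <- sample_patch_batch(uwf, p_uwf, cfg$batch_size,
                            regions = regions$uwf)
    real_lr <- array(0, dim = c(p_uwf, p_uwf, 3L, cfg$batch_size))
    for (i in seq_len(cfg$batch_size))
      real_lr[, , , i] <- bicubic_resample(fpatch[, , , i], 0.25)

    tape_g <- ag_tape()
    zn <- ag_const(tape_g, z)
    e_nd <- gde_forward(enhancer, zn, training = TRUE)
    de_adv <- adv_g_node(critics$critic_de, e_nd, training = TRUE)
    ident <- ag_mean_abs_diff(e_nd, zn)
    anch <- ag_anchor(tape_g, anchored, anchor_vals)
    le <- ag_add(de_adv, ag_add(ag_scale(ident, cfg$weights$lambda_I),
                                ag_scale(anch, cfg$weights$lambda_R)))
    sr_nd <- gsr_forward(upscaler, e_nd, training = TRUE)
    sr_adv <- adv_g_node(critics$critic_sr, sr_nd, training = TRUE)
    cyc_nd <- gsr_forward(upscaler, ag_const(tape_g, real_lr),
                          training = TRUE)
    cyc <- ag_mean_abs_diff(cyc_nd, ag_const(tape_g, fpatch))
    lsr <- ag_add(sr_adv, ag_scale(cyc, cfg$weights$lambda_C))
    lm <- ag_add(le, lsr)
    ag_backward(lm)
    if (it > cfg$critic_warmup)
      adamw_step(tape_g, lr, cfg$betas, cfg$eps, cfg$weight_decay,
                 gen_frozen)

    tape_d <- ag_tape()
    dde_loss <- adv_d_node(critics$critic_de, ag_const(tape_d, real_lr),
                           ag_const(tape_d, e_nd$value), training = TRUE)
    dsr_loss <- adv_d_node(critics$critic_sr, ag_const(tape_d, fpatch),
                           ag_const(tape_d, sr_nd$value), training = TRUE)
    ag_backward(ag_add(dde_loss, dsr_loss))
    d_lr <- if (it <= cfg$critic_warmup) cfg$critic_lr
            else cfg$critic_lr * cfg$critic_lr_scale
    adamw_step(tape_d, d_lr, cfg$betas, cfg$eps,
               cfg$weight_decay, crit_frozen)

    rec <- list(iter = it, stage = "FT", le = le$value, lsr = lsr$value,
                adv_g = de_adv$value + sr_adv$value,
                adv_d = dde_loss$value + dsr_loss$value,
                identity = ident$value, anchor = anch$value,
                cycle = cyc$value, total = lm$value)
    append_log(cfg, rec)
    rbind(h, as.data.frame(rec))
  })
  enhancer$stage_trained <- "FT"
  upscaler$stage_trained <- "FT"
  state <- new_train_state("FT", cfg$iterations,
                           c(list(enhancer = enhancer, upscaler = upscaler),
                             critics),
                           anchor, history, cfg)
  if (!is.null(cfg$checkpoint_dir)) save_checkpoint(state, cfg$checkpoint_dir)
  state
}

# resolve macular regions per image for both domains; manifest coordinates
# are at the clean (fundus) scale, UWF images live at 1/4 that scale
macular_regions <- function(uwf_dir, uwf, fundus, macula_centers) {
  if (!is.null(macula_centers))
    return(list(
      uwf = lapply(seq_along(uwf), function(i)
        list(center = macula_centers$uwf[[i]],
             radius = 0.25 * min(dim(uwf[[i]])[1:2]))),
      fundus = lapply(seq_along(fundus), function(i)
        list(center = macula_centers$fundus[[i]],
             radius = 0.25 * min(dim(fundus[[i]])[1:2])))))
  man_path <- file.path(uwf_dir, "manifest.json")
  if (file.exists(man_path)) {
    man <- read_manifest(uwf_dir)
    centers <- man$macula_centers
    if (is.matrix(centers)) centers <- asplit(centers, 1L)
    return(list(
      uwf = lapply(seq_along(uwf), function(i) {
        mc <- unlist(centers[[man$pairing[i]]]) / 4
        list(center = mc, radius = 0.25 * min(dim(uwf[[i]])[1:2]))
      }),
      fundus = lapply(seq_along(fundus), function(i)
        list(center = unlist(centers[[i]]),
             radius = 0.25 * min(dim(fundus[[i]])[1:2])))))
  }
  # centre-fraction heuristic
  list(
    uwf = lapply(uwf, function(im)
      list(center = (dim(im)[1:2] + 1) / 2,
           radius = 0.25 * min(dim(im)[1:2]))),
    fundus = lapply(fundus, function(im)
      list(center = (dim(im)[1:2] + 1) / 2,
           radius = 0.25 * min(dim(im)[1:2]))))
}

#' Enhance and super-resolve an image
#'
#' The full inference pass: degradation enhancement followed by x4
#' super-resolution (`GSR(GDE(x))`), output clipped to \[0, 1\].  The
#' reversed composition (`order = "sr_de"`) is the order-ablation entry
#' point and applies the upscaler first, then the enhancer at high
#' resolution.
#'
#' @param image input image array.
#' @param enhancer,upscaler trained networks.
#' @param order `"de_sr"` (canonical) or `"sr_de"` (ablation).
#' @param return_intermediate also return the enhanced low-resolution
#'   intermediate.
#' @return the enhanced x4 image, or a list with `output` and
#'   `intermediate` when `return_intermediate = TRUE`.
#' @export
enhance <- function(image, enhancer, upscaler,
                    order = c("de_sr", "sr_de"),
                    return_intermediate = FALSE) {
  order <- match.arg(order)
  image <- as_image(image)
  if (order == "de_sr") {
    mid <- net_forward(enhancer, image, training = FALSE, clip = TRUE)
    out <- net_forward(upscaler, mid, training = FALSE, clip = TRUE)
  } else {
    mid <- net_forward(upscaler, image, training = FALSE, clip = TRUE)
    out <- net_forward(enhancer, mid, training = FALSE, clip = TRUE)
  }
  if (return_intermediate) list(output = out, intermediate = mid) else out
}
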