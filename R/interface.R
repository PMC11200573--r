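# Shared configuration and the command-line surface.  The CLI is a thin
# dispatcher over the package's functions; every run writes a provenance
# block (config hash, seed, package version) to its output root.

.run_config_keys <- c("phantom", "chain", "stages", "evaluation",
                      "output_root", "seed")

#' Load / save a run configuration
#'
#' A run configuration is a single YAML document with (optional) blocks
#' `phantom` (phantom parameters), `chain` (degradation chain), `stages`
#' (per-stage overrides of [stage_config()] fields, keyed by stage name),
#' `evaluation`, `output_root` and `seed`.  Unknown top-level keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return the validated configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .run_config_keys)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_root <- cfg$output_root %||% "."
  cfg
}

#' @rdname load_run_config
#' @param cfg configuration list.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# small deterministic polynomial rolling hash of a deparsed object, for the
# provenance block (not cryptographic)
config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_provenance <- function(root, cfg, seed) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config_hash = config_hash(cfg), seed = seed,
         package_version = as.character(utils::packageVersion("uwfenhance")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(root, "provenance.json"), auto_unbox = TRUE)
  invisible(NULL)
}

arg_value <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0L) return(default)
  if (i[1L] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1L] + 1L]
}

cli_usage <- function() {
  cat("usage: uwfenhance <command> [options]\n",
      "commands:\n",
      "  synth    --n N --seed S --out DIR [--size PX --n-drusen K]\n",
      "  degrade  --kind KIND [--sigma S|--gamma G|--rate R|--scale F]",
      " IN OUT\n",
      "  train    --stage {pretrain,de,sr,ft,all} --config cfg.yaml\n",
      "  enhance  IN OUT --ckpt DIR [--order de_sr|sr_de]\n",
      "  evaluate --pred-dir D --ref-dir D [--masks-pred D --masks-gt D]",
      " --out report.json\n", sep = "")
}

known_flags <- function(cmd) {
  switch(cmd,
    synth = c("--n", "--seed", "--out", "--size", "--n-drusen",
              "--n-vessels"),
    degrade = c("--kind", "--sigma", "--gamma", "--rate", "--scale",
                "--chain"),
    train = c("--stage", "--config"),
    enhance = c("--ckpt", "--order"),
    evaluate = c("--pred-dir", "--ref-dir", "--masks-pred", "--masks-gt",
                 "--out"))
}

cli_synth <- function(args) {
  n <- as.integer(arg_value(args, "--n", "4"))
  seed <- as.integer(arg_value(args, "--seed", "1"))
  out <- arg_value(args, "--out")
  if (is.null(out)) stop("usage: synth requires --out", call. = FALSE)
  params <- phantom_params(
    size = as.integer(arg_value(args, "--size", "128")),
    n_drusen = as.integer(arg_value(args, "--n-drusen", "5")),
    n_vessels = as.integer(arg_value(args, "--n-vessels", "7")))
  build_unpaired_dataset(params, n, file.path(out, "clean"),
                         file.path(out, "uwf"), seed = seed)
  write_provenance(out, list(cmd = "synth", params = unclass(params), n = n),
                   seed)
  0L
}

cli_degrade <- function(args) {
  pos <- args[!grepl("^--", args) &
                !args %in% args[which(grepl("^--", args)) + 1L]]
  if (length(pos) != 2L)
    stop("usage: degrade needs input and output paths", call. = FALSE)
  chain_file <- arg_value(args, "--chain")
  chain <- if (!is.null(chain_file)) chain_from_json(chain_file)
  else {
    kind <- arg_value(args, "--kind")
    if (is.null(kind)) stop("usage: degrade requires --kind or --chain",
                            call. = FALSE)
    list(degradation_spec(kind,
           sigma = as.numeric(arg_value(args, "--sigma", "7")),
           gamma = as.numeric(arg_value(args, "--gamma", "0.75")),
           rate = as.numeric(arg_value(args, "--rate", "0.25")),
           scale = as.numeric(arg_value(args, "--scale", "0.25"))))
  }
  save_image(apply_degradations(load_image(pos[1L]), chain), pos[2L])
  0L
}

cli_train <- function(args) {
  cfg_path <- arg_value(args, "--config")
  stage <- tolower(arg_value(args, "--stage", "all"))
  if (is.null(cfg_path)) stop("usage: train requires --config", call. = FALSE)
  if (!stage %in% c("pretrain", "de", "sr", "ft", "all"))
    stop("usage: unknown stage '", stage, "'", call. = FALSE)
  rc <- load_run_config(cfg_path)
  root <- rc$output_root
  write_provenance(root, rc, rc$seed)
  params <- do.call(phantom_params, as.list(rc$phantom %||% list()))
  st <- rc$stages %||% list()
  iters <- c(pretrain = as.integer(st$pretrain$iterations %||% 500L),
             de = as.integer(st$de$iterations %||% 500L),
             sr = as.integer(st$sr$iterations %||% 500L),
             ft = as.integer(st$ft$iterations %||% 200L))
  res <- run_experiment(params,
                        n_train = as.integer(rc$phantom$n_train %||% 12L),
                        cfg = net_config(tiny_mode = TRUE),
                        iters = iters,
                        batch_size = as.integer(st$de$batch_size %||% 4L),
                        patch_size = as.integer(st$de$patch_size %||% 64L),
                        seed = rc$seed, dir = file.path(root, "data"))
  save_checkpoint(res$states$ft, file.path(root, "checkpoints"))
  jsonlite::write_json(res$metrics, file.path(root, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_enhance <- function(args) {
  pos <- args[!grepl("^--", args) &
                !args %in% args[which(grepl("^--", args)) + 1L]]
  if (length(pos) != 2L)
    stop("usage: enhance needs input and output paths", call. = FALSE)
  ckpt <- arg_value(args, "--ckpt")
  if (is.null(ckpt) || (!dir.exists(ckpt) && !file.exists(ckpt)))
    stop("runtime: enhance requires a trained checkpoint (--ckpt); ",
         "no checkpoint found", call. = FALSE)
  state <- load_checkpoint(ckpt)
  if (is.null(state$nets$upscaler))
    stop("runtime: checkpoint has no trained upscaler; complete the SR ",
         "stage first", call. = FALSE)
  out <- enhance(load_image(pos[1L]), state$nets$enhancer,
                 state$nets$upscaler,
                 order = arg_value(args, "--order", "de_sr"))
  save_image(out, pos[2L])
  0L
}

cli_evaluate <- function(args) {
  pred <- arg_value(args, "--pred-dir")
  ref <- arg_value(args, "--ref-dir")
  if (is.null(pred) || is.null(ref))
    stop("usage: evaluate requires --pred-dir and --ref-dir", call. = FALSE)
  evaluate_dirs(pred, ref,
                masks_pred = arg_value(args, "--masks-pred"),
                masks_gt = arg_value(args, "--masks-gt"),
                out = arg_value(args, "--out", "report.json"))
  0L
}

#' Command-line entry point
#'
#' Dispatches the subcommands `synth`, `degrade`, `train`, `enhance`,
#' `evaluate`.  Returns 0 on success, 2 on a usage error (unknown command,
#' unknown flag, missing required argument), 1 on a runtime error.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    cli_usage()
    return(2L)
  }
  cmd <- argv[1L]
  args <- argv[-1L]
  if (!cmd %in% c("synth", "degrade", "train", "enhance", "evaluate")) {
    cli_usage()
    return(2L)
  }
  bad <- setdiff(grep("^--", args, value = TRUE), known_flags(cmd))
  if (length(bad) > 0L) {
    message("unknown flag(s): ", paste(bad, collapse = ", "))
    cli_usage()
    return(2L)
  }
  handler <- switch(cmd, synth = cli_synth, degrade = cli_degrade,
                    train = cli_train, enhance = cli_enhance,
                    evaluate = cli_evaluate)
  tryCatch(handler(args), error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("^usage:", conditionMessage(e))) 2L else 1L
  })
}
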