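default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "hypnoseeg_run",
    simulate = list(duration = 602, fs = 500, event_spacing = 1,
                    state_block_s = 20, noise_sd = 0.5, artifact_rate = 12,
                    theta_alpha_mult = 1.5),
    preprocess = list(lowpass = 30, highpass = 0.1, notch = 40,
                      notch_half_width = 2, lowpass_order = 500,
                      highpass_order = 3000, notch_order = 500,
                      ref = c("M1", "M2")),
    ica = list(n_components = 8, g = "tanh", tol = 1e-4, max_iter = 200,
               exclude = "auto", threshold = 1),
    features = list(window = c(0.2, 1.0), psd = "periodogram"),
    model = list(type = "eegnet", representation = "time",
                 split = c(0.6, 0.2, 0.2), lr = 1e-3, batch_size = 32,
                 max_epochs = 30, patience = 5)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and applies cross-field checks
#' (filter cutoffs against the Nyquist limit, epoch window ordering,
#' split ratios).
#'
#' @param config Path to a YAML file, or a (possibly partial) named list.
#'   An empty file or \code{NULL} yields the full default configuration.
#' @return Normalized configuration list of class \code{pipeline_config}.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  def <- default_pipeline_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (blk in intersect(names(config), names(def))) {
    if (is.list(def[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad)) stop("unknown key(s) in '", blk, "': ",
                            paste(bad, collapse = ", "), call. = FALSE)
      def[[blk]][names(config[[blk]])] <- config[[blk]]
    } else {
      def[[blk]] <- config[[blk]]
    }
  }
  cfg <- def
  fs <- cfg$simulate$fs
  ny <- nyquist(fs)
  for (f in c("lowpass", "highpass", "notch")) {
    if (cfg$preprocess[[f]] >= ny) {
      stop("preprocess.", f, " = ", cfg$preprocess[[f]],
           " Hz violates the Nyquist limit ", ny, " Hz at fs = ", fs,
           call. = FALSE)
    }
  }
  w <- as.numeric(cfg$features$window)
  if (length(w) != 2 || w[2] <= w[1]) {
    stop("features.window must be (start, end) with end > start",
         call. = FALSE)
  }
  cfg$features$window <- w
  if (abs(sum(cfg$model$split) - 1) > 1e-8) {
    stop("model.split ratios must sum to 1", call. = FALSE)
  }
  if (!cfg$model$type %in% c("eegnet", "rnn", "lstm")) {
    stop("model.type must be eegnet, rnn or lstm", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

stage_path <- function(dir, stage) file.path(dir, paste0(stage, ".rds"))

run_stage <- function(name, dir, resume, manifest, fun) {
  path <- stage_path(dir, name)
  t0 <- Sys.time()
  if (resume && file.exists(path)) {
    value <- readRDS(path)
    cached <- TRUE
  } else {
    value <- fun()
    saveRDS(value, path, version = 2)
    cached <- FALSE
  }
  manifest$stages[[name]] <- list(
    file = basename(path),
    md5 = unname(tools::md5sum(path)),
    cached = cached,
    seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
  list(value = value, manifest = manifest)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: electrode location (montage validation) ->
#' re-referencing -> filtering -> ICA -> epoch processing -> feature
#' extraction -> model training -> evaluation. Each stage's output is
#' saved under \code{out_dir} and hashed into \code{manifest.json};
#' rerunning with \code{resume = TRUE} loads existing stage outputs and
#' recomputes only what is missing.
#'
#' @param config A \code{\link{validate_config}} result (or anything it
#'   accepts).
#' @param resume Reuse existing stage outputs in \code{out_dir}.
#' @param verbose Print stage progress.
#' @return List: \code{report} (the test-set \code{\link{metrics}}),
#'   \code{manifest}, \code{out_dir}, plus the trained model and splits.
#' @export
run_pipeline <- function(config = NULL, resume = FALSE, verbose = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir <- cfg$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(stage_order = c("electrode_location", "rereference",
                                   "filtering", "ica", "epoching",
                                   "features", "model", "evaluation"),
                   seed = cfg$seed, stages = list())
  say <- function(...) if (verbose) message(...)
  fail <- function(stage, e) {
    manifest$partial <- stage
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  dirty <- FALSE   # once a stage recomputes, downstream caches are stale
  wrap <- function(name, fun) {
    say("stage: ", name)
    out <- tryCatch(run_stage(name, dir, resume && !dirty, manifest, fun),
                    error = function(e) fail(name, e))
    manifest <<- out$manifest
    if (!manifest$stages[[name]]$cached) dirty <<- TRUE
    out$value
  }

  mult <- cfg$simulate$theta_alpha_mult
  scfg <- synth_config(
    fs = cfg$simulate$fs, duration = cfg$simulate$duration,
    event_spacing = cfg$simulate$event_spacing,
    state_block_s = cfg$simulate$state_block_s,
    noise_sd = cfg$simulate$noise_sd,
    artifact_rate = cfg$simulate$artifact_rate,
    class_band_power = list(
      RH = c(delta = 1, theta = mult, alpha = mult, beta = 1, gamma = 1),
      ND = c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1)),
    seed = cfg$seed)

  sim <- wrap("electrode_location", function() {
    s <- simulate_recording(scfg)
    stopifnot(all(c(scfg$channel_names, scfg$mastoid_names) %in%
                    s$recording$channel_names))
    s
  })
  rec <- wrap("rereference", function() {
    rereference(sim$recording, cfg$preprocess$ref)
  })
  filt <- wrap("filtering", function() {
    p <- cfg$preprocess
    r <- apply_filter(rec, design_fir(
      filter_spec("high-pass", p$highpass, order = p$highpass_order),
      rec$fs))
    r <- apply_filter(r, design_fir(
      filter_spec("low-pass", p$lowpass, order = p$lowpass_order), rec$fs))
    apply_filter(r, design_fir(
      filter_spec("notch", p$notch, half_width = p$notch_half_width,
                  order = p$notch_order), rec$fs))
  })
  clean <- wrap("ica", function() {
    ic <- cfg$ica
    model <- ica_fit(filt, n_components = ic$n_components, g = ic$g,
                     tol = ic$tol, max_iter = ic$max_iter,
                     seed = cfg$seed + 10L)
    S <- ica_sources(model, filt)
    scores <- identify_artifact_components(model, S,
                                           threshold = ic$threshold,
                                           fs = filt$fs)
    excl <- if (identical(ic$exclude, "auto")) {
      scores$component[scores$flagged]
    } else as.integer(ic$exclude)
    list(recording = remove_components(filt, model, excl),
         model = model, scores = scores, excluded = excl)
  })
  epochs <- wrap("epoching", function() {
    extract_epochs(clean$recording, sim$events, cfg$features$window)
  })
  feats <- wrap("features", function() {
    compute_psd(epochs, method = cfg$features$psd)
  })
  fit <- wrap("model", function() {
    repr <- cfg$model$representation
    ds <- model_dataset(if (repr == "time") epochs else feats)
    sp <- split_dataset(ds$y, cfg$model$split, seed = cfg$seed + 20L)
    width <- dim(ds$x)[3]
    mcfg <- if (cfg$model$type == "eegnet") {
      eegnet_config(n_channels = dim(ds$x)[2], n_samples = width)
    } else {
      recurrent_config(cfg$model$type)
    }
    take <- function(i) list(x = ds$x[i, , , drop = FALSE], y = ds$y[i],
                             representation = ds$representation)
    model <- train_model(mcfg, take(sp$train), take(sp$val),
                         lr = cfg$model$lr,
                         batch_size = cfg$model$batch_size,
                         max_epochs = cfg$model$max_epochs,
                         patience = cfg$model$patience,
                         seed = cfg$seed + 30L)
    list(model = model, split = sp, dataset_labels = ds$y)
  })
  report <- wrap("evaluation", function() {
    repr <- cfg$model$representation
    ds <- model_dataset(if (repr == "time") epochs else feats)
    te <- fit$split$test
    pred <- predict(fit$model,
                    list(x = ds$x[te, , , drop = FALSE],
                         representation = ds$representation))
    metrics(confusion(ds$y[te], pred$labels))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say(sprintf("test ACC %.3f", report$ACC))
  list(report = report, manifest = manifest, out_dir = dir,
       model = fit$model, split = fit$split, config = cfg)
}
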