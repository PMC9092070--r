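#' Full pipeline configuration
#'
#' Nested configuration for the five pipeline stages (synth, train, evaluate,
#' quantify, compare). Every stage derives its randomness from the global
#' `seed`; rerunning an identical configuration reproduces every artifact
#' byte for byte.
#'
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @param pixel_size_um physical pixel size, or `NA` for pixel units.
#' @param synth list: `n_per_group`, `jitter_cv`, `image_format`, plus any
#'   [phantom_spec()] argument for the control spec.
#' @param segnet list of [seg_model_config()] arguments.
#' @param training list of [train_config()] arguments plus `train_n`/`test_n`
#'   (defaults: 80/20 split of the cohort).
#' @param morphometry list of [morpho_config()] arguments plus `source`
#'   (`"predicted"` quantifies model segmentations; `"labels"` the ground
#'   truth).
#' @param stats list: `control_group`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = "retseg_out",
                            pixel_size_um = NA_real_,
                            synth = list(),
                            segnet = list(),
                            training = list(),
                            morphometry = list(),
                            stats = list()) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, pixel_size_um = pixel_size_um,
    synth = modifyList(list(
      n_per_group = 6L, jitter_cv = 0.08, image_format = "png",
      width_px = 64L, height_px = 64L,
      layer_thickness_px = list(RNFL = 8, IPL = 12, INL = 9, OPL = 5),
      curvature_amplitude_px = 2, curvature_period_px = 60,
      cell_count = 3L, cell_radius_px = 3, cell_clump_fraction = 0,
      vacuole_density = 0.5, noise_sigma = 6, blur_sigma = 0.8), synth),
    segnet = modifyList(list(
      encoder_widths = c(8L, 8L, 16L, 16L, 16L), sge_groups = 4L,
      sge_enabled = TRUE, convs_per_stage = 1L), segnet),
    training = modifyList(list(
      epochs = 2L, batch_size = 4L, learning_rate = 0.001,
      lr_decay_step = 1L, lr_decay_factor = 0.92,
      train_n = NULL, test_n = NULL), training),
    morphometry = modifyList(list(
      erosion_iters = 1L, min_layer_area_frac = 0.001,
      adherence_ratio = 1.8, max_split = 6L, source = "predicted"), morphometry),
    stats = modifyList(list(control_group = "control"), stats)
  )
  # keep the thickness map a named list so YAML round-trips preserve names
  cfg$synth$layer_thickness_px <- as.list(cfg$synth$layer_thickness_px)
  structure(cfg, class = "pipeline_config")
}

phantom_from_config <- function(cfg, condition) {
  s <- cfg$synth
  phantom_spec(
    width_px = s$width_px, height_px = s$height_px,
    pixel_size_um = cfg$pixel_size_um,
    layer_thickness_px = unlist(s$layer_thickness_px),
    curvature_amplitude_px = s$curvature_amplitude_px,
    curvature_period_px = s$curvature_period_px,
    cell_count = s$cell_count, cell_radius_px = s$cell_radius_px,
    cell_clump_fraction = s$cell_clump_fraction,
    vacuole_density = s$vacuole_density,
    noise_sigma = s$noise_sigma, blur_sigma = s$blur_sigma,
    condition = condition, seed = cfg$seed
  )
}

morpho_from_config <- function(cfg) {
  m <- cfg$morphometry
  morpho_config(erosion_iters = m$erosion_iters,
                min_layer_area_frac = m$min_layer_area_frac,
                adherence_ratio = m$adherence_ratio, max_split = m$max_split)
}

log_stage <- function(stage, cfg, hash, msg) {
  message(sprintf("[retseg:%s] seed=%d config=%s %s", stage, cfg$seed, hash, msg))
}

#' Run the end-to-end pipeline
#'
#' Stages: `synth` (generate and write a two-group cohort), `train` (fit the
#' SGE U-Net on a train split), `evaluate` (segmentation metrics on the test
#' split), `quantify` (morphometric profiles of every section) and `compare`
#' (percent-of-control ANOVA across groups). Stages communicate through
#' files under `out_dir`, so any stage can be rerun standalone against an
#' existing directory. All outputs embed the configuration hash.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("synth", "train", "evaluate", "quantify", "compare")`, in order.
#' @param verbose print stage log lines.
#' @return invisible list of artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "train", "evaluate", "quantify", "compare"),
                         verbose = TRUE) {
  cfg <- config
  # hash the scientific configuration only, so relocating out_dir does not
  # change the recorded identity of a run
  hash <- config_hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stopf("cannot create output directory %s", out)
  write_config(cfg, file.path(out, "config.yaml"))
  say <- function(stage, msg) if (verbose) log_stage(stage, cfg, hash, msg)
  paths <- list(config = file.path(out, "config.yaml"))

  synth_dir <- file.path(out, "synth")
  manifest_path <- file.path(synth_dir, "manifest.csv")

  if ("synth" %in% stages) {
    ctrl <- phantom_from_config(cfg, "control")
    cohort <- generate_cohort(cfg$synth$n_per_group, ctrl,
                              seed = cfg$seed, jitter_cv = cfg$synth$jitter_cv)
    dir.create(synth_dir, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(cohort, function(sec) {
      p <- write_section(sec, synth_dir, sec$section_id, cfg$synth$image_format)
      cbind(data.frame(section_id = sec$section_id, group = sec$group,
                       image = basename(p[["image"]]),
                       labels = basename(p[["labels"]]),
                       config_hash = hash),
            as.data.frame(sec$truth_profile))
    })
    manifest <- do.call(rbind, rows)
    write.csv(manifest, manifest_path, row.names = FALSE)
    paths$manifest <- manifest_path
    say("synth", sprintf("wrote %d sections to %s", length(cohort), synth_dir))
  }

  load_cohort <- function() {
    manifest <- read.csv(manifest_path)
    secs <- lapply(seq_len(nrow(manifest)), function(i) {
      sec <- read_section(file.path(synth_dir, manifest$image[i]),
                          file.path(synth_dir, manifest$labels[i]),
                          cfg$pixel_size_um)
      sec$section_id <- manifest$section_id[i]
      sec$group <- manifest$group[i]
      sec
    })
    secs
  }

  train_dir <- file.path(out, "train")
  ckpt_path <- file.path(train_dir, "model.rds")
  split_path <- file.path(train_dir, "split.csv")

  if ("train" %in% stages) {
    cohort <- load_cohort()
    n <- length(cohort)
    tr_n <- cfg$training$train_n %||% max(1L, floor(0.8 * n))
    te_n <- cfg$training$test_n %||% (n - (cfg$training$train_n %||% max(1L, floor(0.8 * n))))
    sp <- split_dataset(cohort, tr_n, te_n, seed = derive_seeds(cfg$seed, 1, salt = 11L))
    scfg <- seg_model_config(
      encoder_widths = unlist(cfg$segnet$encoder_widths),
      sge_groups = cfg$segnet$sge_groups,
      sge_enabled = cfg$segnet$sge_enabled,
      convs_per_stage = unlist(cfg$segnet$convs_per_stage))
    model <- seg_model(scfg, seed = derive_seeds(cfg$seed, 1, salt = 13L))
    tcfg <- train_config(epochs = cfg$training$epochs,
                         batch_size = cfg$training$batch_size,
                         learning_rate = cfg$training$learning_rate,
                         lr_decay_step = cfg$training$lr_decay_step,
                         lr_decay_factor = cfg$training$lr_decay_factor,
                         seed = derive_seeds(cfg$seed, 1, salt = 17L))
    res <- train_model(model, sp$train, sp$test, tcfg, verbose = FALSE)
    dir.create(train_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(res$best, ckpt_path)
    hist <- res$history
    hist$config_hash <- hash
    write.csv(hist, file.path(train_dir, "history.csv"), row.names = FALSE)
    write.csv(data.frame(
      section_id = c(vapply(sp$train, `[[`, "", "section_id"),
                     vapply(sp$test, `[[`, "", "section_id")),
      role = rep(c("train", "test"), c(length(sp$train), length(sp$test)))),
      split_path, row.names = FALSE)
    paths$checkpoint <- ckpt_path
    paths$history <- file.path(train_dir, "history.csv")
    say("train", sprintf("trained %d epochs; best MIOU %.3f",
                         cfg$training$epochs, max(hist$test_MIOU)))
  }

  eval_dir <- file.path(out, "evaluate")
  if ("evaluate" %in% stages) {
    cohort <- load_cohort()
    model <- load_model(ckpt_path)
    split <- read.csv(split_path)
    test_ids <- split$section_id[split$role == "test"]
    test <- Filter(function(s) s$section_id %in% test_ids, cohort)
    dir.create(eval_dir, recursive = TRUE, showWarnings = FALSE)
    reports <- lapply(test, function(sec) {
      metrics_report(predict_labels(sec$image, model), sec$labels)
    })
    per <- do.call(rbind, lapply(seq_along(test), function(i) {
      data.frame(section_id = test[[i]]$section_id, group = test[[i]]$group,
                 PA = reports[[i]]$PA, MPA = reports[[i]]$MPA,
                 MIOU = reports[[i]]$MIOU, config_hash = hash)
    }))
    write.csv(per, file.path(eval_dir, "metrics.csv"), row.names = FALSE)
    # per-class accuracy/recall/IoU table averaged over the test sections
    percls <- do.call(rbind, lapply(reports, `[[`, "per_class"))
    percls_mean <- aggregate(percls[c("recall", "accuracy_ovr", "IOU")],
                             by = percls[c("class", "id")], FUN = mean,
                             na.rm = TRUE)
    percls_mean <- percls_mean[order(percls_mean$id), ]
    percls_mean$config_hash <- hash
    write.csv(percls_mean, file.path(eval_dir, "per_class.csv"),
              row.names = FALSE)
    agg <- as.list(colMeans(per[, c("PA", "MPA", "MIOU")]))
    agg$n_sections <- nrow(per)
    agg$config_hash <- hash
    jsonlite::write_json(agg, file.path(eval_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$metrics <- file.path(eval_dir, "metrics.csv")
    say("evaluate", sprintf("test PA %.3f MIOU %.3f over %d sections",
                            agg$PA, agg$MIOU, agg$n_sections))
  }

  quant_dir <- file.path(out, "quantify")
  profiles_path <- file.path(quant_dir, "profiles.csv")
  if ("quantify" %in% stages) {
    cohort <- load_cohort()
    mcfg <- morpho_from_config(cfg)
    source <- cfg$morphometry$source
    src <- if (identical(source, "predicted")) {
      model <- load_model(ckpt_path)
      function(sec) predict_labels(sec$image, model)
    } else {
      "labels"
    }
    profs <- profile_cohort(cohort, mcfg, src)
    profs$config_hash <- hash
    dir.create(quant_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(profs, profiles_path, row.names = FALSE)
    paths$profiles <- profiles_path
    say("quantify", sprintf("profiled %d sections (source: %s)", nrow(profs), source))
  }

  if ("compare" %in% stages) {
    profs <- read.csv(profiles_path)
    cmp_dir <- file.path(out, "compare")
    dir.create(cmp_dir, recursive = TRUE, showWarnings = FALSE)
    cmp <- compare_profiles(profs, cfg$stats$control_group)
    cmp$config_hash <- hash
    write.csv(cmp, file.path(cmp_dir, "comparison.csv"), row.names = FALSE)
    jsonlite::write_json(cmp, file.path(cmp_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    paths$comparison <- file.path(cmp_dir, "comparison.csv")
    say("compare", sprintf("compared %d parameters across groups",
                           length(unique(cmp$parameter))))
  }
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `train`, `evaluate`, `quantify`, `compare`,
#' `run-all`. Common flags: `--config` (YAML pipeline configuration),
#' `--seed`, `--out`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status, invisibly.
#' @export
retseg_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: retseg <synth|train|evaluate|quantify|compare|run-all> [--config F] [--seed N] [--out DIR]"
  if (length(args) < 1) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  known <- c("synth", "train", "evaluate", "quantify", "compare", "run-all")
  if (!sub %in% known) {
    message(usage)
    return(invisible(1L))
  }
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL)
  ))
  opts <- optparse::parse_args(parser, args = args[-1])
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else pipeline_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  stages <- if (sub == "run-all") {
    c("synth", "train", "evaluate", "quantify", "compare")
  } else {
    sub
  }
  run_pipeline(cfg, stages)
  invisible(0L)
}
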