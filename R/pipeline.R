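#' Assemble and validate a full run configuration
#'
#' A run configuration binds the stage configs (scene simulation,
#' segmentation, network, training, evaluation, optional time-lapse) with
#' an output directory and one master seed. It serializes to/from a single
#' YAML file; unknown keys are rejected so typos fail before any
#' computation.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param simulate List: `n_train`, `n_eval` frame counts and `scene`
#'   (fields of [scene_spec()], marker links as plain lists).
#' @param segmentation Fields of [segmentation_config()].
#' @param network Fields of [network_config()].
#' @param train Fields of [train_config()].
#' @param timelapse Optional list: `n_frames`, `motion_sd`,
#'   `density_growth`, `frame_interval`, `rupture_lag`.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `run_config` object.
#' @export
run_config <- function(out_dir = "cellbright-run", seed = 1L,
                       simulate = list(n_train = 8L, n_eval = 3L,
                                       scene = list()),
                       segmentation = list(), network = list(),
                       train = list(), timelapse = NULL,
                       log_level = "info") {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = simulate, segmentation = segmentation,
              network = network, train = train, timelapse = timelapse,
              log_level = log_level)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

run_config_schema <- list(
  top = c("out_dir", "seed", "simulate", "segmentation", "network",
          "train", "timelapse", "log_level"),
  simulate = c("n_train", "n_eval", "scene"),
  scene = c("width", "height", "n_cells", "cell_radius_mean",
            "cell_radius_sd", "elongation_range", "texture_amplitude",
            "marker_links", "noise_sd", "background_level", "seed"),
  marker_link = c("marker_name", "weights", "intercept", "noise_sd",
                  "dynamics", "density_gain", "half_life", "spike"),
  segmentation = c("threshold_method", "fixed_threshold", "min_area",
                   "connectivity", "fill_holes", "border_policy",
                   "opening_radius"),
  network = c("input_size", "depth", "base_channels", "norm", "refine"),
  train = c("optimizer_name", "learning_rate", "batch_size", "epochs",
            "crops_per_image", "crop_sampling", "adam_beta2", "lr_schedule",
            "seed", "validation_fraction"),
  timelapse = c("n_frames", "frame_interval", "motion_sd",
                "density_growth", "rupture_lag")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

validate_run_config <- function(cfg) {
  sch <- run_config_schema
  check_keys(cfg, sch$top, "run config")
  check_keys(cfg$simulate, sch$simulate, "simulate")
  check_keys(cfg$simulate$scene, sch$scene, "simulate$scene")
  for (ml in cfg$simulate$scene$marker_links %||% list()) {
    check_keys(ml, sch$marker_link, "marker link")
  }
  check_keys(cfg$segmentation, sch$segmentation, "segmentation")
  check_keys(cfg$network, sch$network, "network")
  check_keys(cfg$train, sch$train, "train")
  if (!is.null(cfg$timelapse)) {
    check_keys(cfg$timelapse, sch$timelapse, "timelapse")
  }
  cfg
}

#' Read / write a run configuration as YAML
#' @param path Path to a `.yaml` file.
#' @return For `read_run_config`, a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$timelapse <- cfg$timelapse %||% NULL
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

cfg_scene_spec <- function(cfg, seed) {
  sc <- cfg$simulate$scene
  links <- lapply(sc$marker_links %||% list(list()), function(ml) {
    do.call(marker_link, ml)
  })
  args <- sc[setdiff(names(sc), c("marker_links", "seed"))]
  args$marker_links <- links
  args$seed <- seed
  do.call(scene_spec, args)
}

stage_log <- function(cfg, stage, t0) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[cellbright] %-14s %6.1f s", stage,
                  as.numeric(proc.time()[3] - t0)))
}

run_stage <- function(cfg, stage, expr) {
  t0 <- proc.time()[3]
  out <- tryCatch(force(expr), error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         "\nreproduce with: run_pipeline(read_run_config(\"<config>\"))",
         call. = FALSE)
  })
  stage_log(cfg, stage, t0)
  out
}

#' Run the end-to-end workflow
#'
#' simulate -> segment -> build-targets -> train -> evaluate
#' (-> time-lapse, if configured), all under one output directory with a
#' JSON manifest listing every artifact with its MD5 hash, the config
#' hash, seed and package version. Given the same configuration and seed
#' the manifest hashes are identical across reruns.
#'
#' @param cfg A [run_config()].
#' @return A `result_bundle`: manifest (tibble of files and hashes),
#'   per-marker evaluation `correlation_result`s, trained model paths, and
#'   provenance.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seg <- do.call(segmentation_config, cfg$segmentation)
  net_cfg <- do.call(network_config, cfg$network)
  tr_cfg <- do.call(train_config, c(cfg$train,
                                    if (is.null(cfg$train$seed))
                                      list(seed = cfg$seed)))

  n_train <- cfg$simulate$n_train %||% 8L
  n_eval <- cfg$simulate$n_eval %||% 3L

  frames <- run_stage(cfg, "simulate", {
    lapply(seq_len(n_train + n_eval), function(i) {
      generate_frame(cfg_scene_spec(cfg,
                                    seed = (cfg$seed %% 2000000L) * 1000L + i))
    })
  })
  train_frames <- frames[seq_len(n_train)]
  eval_frames <- frames[n_train + seq_len(n_eval)]

  seg_dir <- file.path(out, "segmentation")
  eval_labels <- run_stage(cfg, "segment", {
    dir.create(seg_dir, showWarnings = FALSE)
    purrr::imap(eval_frames, function(fr, i) {
      lab <- binarize_and_label(fr$membrane, seg)
      write_labelmap(lab, file.path(seg_dir, sprintf("eval_%02d.tif", i)))
      lab
    })
  })

  markers <- names(frames[[1]]$markers)
  tgt_dir <- file.path(out, "targets")
  pairs_by_marker <- run_stage(cfg, "build-targets", {
    dir.create(tgt_dir, showWarnings = FALSE)
    cell_rows <- list()
    pbm <- lapply(markers, function(mk) {
      purrr::imap(train_frames, function(fr, i) {
        lab <- binarize_and_label(fr$membrane, seg)
        tg <- build_target(fr$markers[[mk]], lab)
        write_image(tg$values,
                    file.path(tgt_dir, sprintf("%s_train_%02d.tif", mk, i)))
        cell_rows[[length(cell_rows) + 1L]] <<- dplyr::mutate(
          dplyr::inner_join(regions_from_labelmap(lab),
                            measure_cell_means(fr$markers[[mk]], lab),
                            by = "cell_id"),
          frame = i, marker = mk)
        pair_for_training(fr$phase, tg)
      })
    })
    names(pbm) <- markers
    readr::write_csv(
      dplyr::bind_rows(cell_rows)[, c("frame", "marker", "cell_id", "area",
                                      "row", "col", "mean")],
      file.path(tgt_dir, "per_cell.csv"))
    pbm
  })

  model_dir <- file.path(out, "models")
  models <- run_stage(cfg, "train", {
    dir.create(model_dir, showWarnings = FALSE)
    ms <- lapply(markers, function(mk) {
      m <- train_model(pairs_by_marker[[mk]], net_cfg, tr_cfg,
                       marker_name = mk)
      save_model(m, file.path(model_dir, paste0(mk, ".json")))
      m
    })
    names(ms) <- markers
    ms
  })

  eval_dir <- file.path(out, "evaluation")
  results <- run_stage(cfg, "evaluate", {
    dir.create(eval_dir, showWarnings = FALSE)
    res <- lapply(markers, function(mk) {
      pooled <- purrr::imap_dfr(eval_frames, function(fr, i) {
        lab <- eval_labels[[i]]
        meas <- measure_cell_means(fr$markers[[mk]], lab)
        est <- estimate_cell_levels(models[[mk]], fr$phase, lab)
        dplyr::mutate(dplyr::inner_join(meas, est, by = "cell_id"),
                      frame = i)
      })
      r <- pearson(pooled$mean, pooled$estimate, mk)
      attr(r, "pairs") <- dplyr::rename(pooled, measured = "mean")[
        , c("cell_id", "measured", "estimate")]
      export_scatter(r, file.path(eval_dir, paste0(mk, "_scatter.csv")))
      r
    })
    names(res) <- markers
    res
  })

  tl_out <- NULL
  if (!is.null(cfg$timelapse)) {
    tl_dir <- file.path(out, "timelapse")
    tl_out <- run_stage(cfg, "timelapse", {
      dir.create(tl_dir, showWarnings = FALSE)
      tsp_args <- cfg$timelapse
      tsp <- do.call(timelapse_spec,
                     c(list(base = cfg_scene_spec(cfg, cfg$seed)), tsp_args))
      tl <- generate_timelapse(tsp)
      tab <- run_timelapse(tl$frames, models, seg)
      readr::write_csv(tab, file.path(tl_dir, "per_frame.csv"))
      traj <- link_trajectories(tab)
      readr::write_csv(traj, file.path(tl_dir, "trajectories.csv"))
      dens <- lapply(markers, function(mk) density_analysis(tab, mk))
      readr::write_csv(
        purrr::map_dfr(dens, function(d) tidy(d$result)),
        file.path(tl_dir, "density_report.csv"))
      list(table = tab, trajectories = traj, density = dens)
    })
  }

  cfg_path <- file.path(out, "config.yaml")
  cfg_copy <- cfg
  cfg_copy$out_dir <- "."  # the bundle is relocatable; hashes must not
                           # depend on where it was written
  write_run_config(cfg_copy, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  files <- sort(setdiff(list.files(out, recursive = TRUE, full.names = TRUE),
                        file.path(out, "manifest.json")))
  manifest <- tibble::tibble(file = sub(paste0("^", out, "/?"), "", files),
                             md5 = unname(tools::md5sum(files)))
  provenance <- list(config_hash = config_hash, seed = cfg$seed,
                     package_version =
                       as.character(utils::packageVersion("cellbright")))
  jsonlite::write_json(list(provenance = provenance, files = manifest),
                       file.path(out, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  structure(list(manifest = manifest, provenance = provenance,
                 results = results, models = models, timelapse = tl_out,
                 out_dir = out),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle> ", nrow(x$manifest), " artifacts under ", x$out_dir,
      "\n", sep = "")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %s: r = %.3f, p = %.3g, n = %d\n", nm, r$r, r$p, r$n))
  }
  invisible(x)
}

#' @export
glance.result_bundle <- function(x, ...) {
  purrr::map_dfr(x$results, tidy)
}
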