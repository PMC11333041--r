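# Orchestration: configuration, a staged simulate -> analyze runner with
# provenance, and the deterministic fixture generator used by the tests.

#' Read / write a pipeline configuration
#'
#' The YAML configuration mirrors the generator, imaging-model and analysis
#' parameters; [pipeline_config()] fills defaults so a partial file is
#' enough. Configurations round-trip unchanged through serialization.
#'
#' @param overrides named list overriding defaults (possibly nested).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  base <- list(
    seed = 1L,
    n_scenes = 5L,
    channels = c("Cx35.5", "Cx34.1", "ZO1", "GluR2", "NCad"),
    generator = contact_config(),
    expansion = list(k = 3.9, r = 1.0),
    imaging = unclass(imaging_model()),
    analysis = list(
      threshold_method = "otsu",
      min_punctum_area_um2 = 0.05,
      split_touching = TRUE,
      projection = "sum",
      connexon_density = 12000,
      areal_expansion_factor = 13.4,
      peak_window_um = 0.3,
      n_linescan = 30L
    )
  )
  cfg <- utils::modifyList(base, overrides)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config: '%s'", path),
                                "cequant_error_missing_file")
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

cfg_model <- function(cfg) do.call(imaging_model, cfg$imaging)
cfg_transform <- function(cfg) expansion_transform(cfg$expansion$k, cfg$expansion$r)

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order over synthetic scenes
#' and writes one CSV per stage plus a provenance JSON (seed, stage list,
#' config hash and copy) into `out_dir`. Deterministic stages are
#' bit-identical across reruns with the same configuration.
#'
#' Stages: `simulate` (required upstream of everything), `morphometry`,
#' `puncta`, `coloc`, `partition`, `occupancy`, `linescan`, `report`.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stage names (default: all).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the per-stage result tables.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "morphometry", "puncta", "coloc",
                                    "partition", "occupancy", "linescan", "report"),
                         out_dir = tempfile("cequant_run_")) {
  known <- c("simulate", "morphometry", "puncta", "coloc", "partition",
             "occupancy", "linescan", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")),
                         "cequant_error_stage")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  analysis_stages <- setdiff(stages, "simulate")
  if (length(analysis_stages) && !("simulate" %in% stages))
    abort("missing upstream output: stages require 'simulate' (no input scenes)",
          "cequant_error_missing_input")

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  model <- cfg_model(config)
  results <- list()

  ds <- generate_dataset(config$generator, n_scenes = config$n_scenes,
                         seed = config$seed, transform = cfg_transform(config),
                         model = model, channels = config$channels)
  man <- result_table(ds$manifest[, setdiff(names(ds$manifest), "path")],
                      units = c(scene = "", seed = "", n_puncta = "count",
                                contact_area = "um2", sl_ratio = "",
                                occupancy_gj = "", occupancy_aj = "",
                                occupancy_glur2 = "", occupancy_unlabeled = ""))
  write_table(man, file.path(out_dir, "simulate_manifest.csv"))
  results$simulate <- man

  projector <- if (identical(config$analysis$projection, "max"))
    max_project else sum_project
  proj <- lapply(ds$scenes, function(s) projector(s$stack))
  fits <- lapply(proj, function(p)
    fit_contact_outline(p$channels[["Cx35.5"]], p$pixel_size_xy,
                        channel = "Cx35.5"))

  if ("morphometry" %in% stages) {
    df <- do.call(rbind, lapply(seq_along(fits), function(i) {
      m <- fits[[i]]$measure
      data.frame(scene = i, L = m$L, S = m$S, area = m$area,
                 sl_ratio = m$sl_ratio,
                 true_L = ds$scenes[[i]]$truth$long_diameter_post,
                 true_sl = ds$scenes[[i]]$truth$sl_ratio)
    }))
    tb <- result_table(df, units = c(scene = "", L = "um", S = "um",
                                     area = "um2", sl_ratio = "",
                                     true_L = "um", true_sl = ""))
    write_table(tb, file.path(out_dir, "morphometry.csv"))
    results$morphometry <- tb
  }

  if ("puncta" %in% stages) {
    df <- do.call(rbind, lapply(seq_along(proj), function(i) {
      lab <- segment_puncta(proj[[i]]$channels[["Cx35.5"]], fits[[i]]$mask,
                            config$imaging$pixel_size_xy,
                            min_area_um2 = config$analysis$min_punctum_area_um2,
                            split_touching = config$analysis$split_touching)
      rec <- measure_puncta(lab, config$imaging$pixel_size_xy,
                            config$analysis$areal_expansion_factor,
                            config$analysis$connexon_density)
      sm <- contact_summary(rec)
      data.frame(scene = i, n_detected = sm$n,
                 n_true = ds$scenes[[i]]$truth$n_puncta,
                 total_area = sm$total_area_um2,
                 total_connexons = sm$total_connexons)
    }))
    tb <- result_table(df, units = c(scene = "", n_detected = "count",
                                     n_true = "count", total_area = "um2",
                                     total_connexons = "count"))
    write_table(tb, file.path(out_dir, "puncta.csv"))
    results$puncta <- tb
  }

  if ("coloc" %in% stages) {
    pairs <- lapply(seq_along(proj), function(i)
      list(imgA = proj[[i]]$channels[["Cx35.5"]],
           imgB = proj[[i]]$channels[["Cx34.1"]],
           roi = fits[[i]]$mask))
    cb <- coloc_batch(pairs, method = config$analysis$threshold_method)
    write_table(cb$table, file.path(out_dir, "coloc.csv"))
    results$coloc <- cb$table
  }

  if (any(c("partition", "occupancy") %in% stages)) {
    partitions <- lapply(seq_along(fits), function(i)
      partition_center_periphery(fits[[i]]$mask, fits[[i]]$measure))
    if ("partition" %in% stages) {
      contacts <- lapply(seq_along(proj), function(i)
        list(chA = proj[[i]]$channels[["Cx35.5"]],
             chB = proj[[i]]$channels[["GluR2"]],
             partition = partitions[[i]],
             background_roi = default_background_roi(
               proj[[i]]$channels[["Cx35.5"]], fits[[i]]$mask)))
      cp <- center_periphery_analysis(contacts)
      write_table(cp$table, file.path(out_dir, "partition.csv"))
      results$partition <- cp$table
    }
    if ("occupancy" %in% stages) {
      df <- do.call(rbind, lapply(seq_along(proj), function(i) {
        oc <- occupancy(proj[[i]]$channels[c("Cx35.5", "GluR2", "NCad")],
                        fits[[i]]$mask)
        data.frame(scene = i, t(oc$fractions), unlabeled = oc$unlabeled)
      }))
      tb <- result_table(df, units = setNames(rep("", ncol(df)), names(df)))
      write_table(tb, file.path(out_dir, "occupancy.csv"))
      results$occupancy <- tb
    }
  }

  if ("linescan" %in% stages) {
    d_zo1 <- measure_sideview_offsets(config$analysis$n_linescan,
                                      model$offset_zo1, model,
                                      channel_names = c("Cx35.5", "ZO1"),
                                      window = config$analysis$peak_window_um)
    d_cx <- measure_sideview_offsets(config$analysis$n_linescan,
                                     model$offset_cx, model,
                                     channel_names = c("Cx35.5", "Cx34.1"),
                                     window = config$analysis$peak_window_um)
    st <- offset_stats(list(cx_cx = abs(d_cx), cx_zo1 = abs(d_zo1)))
    write_table(st$table, file.path(out_dir, "linescan.csv"))
    results$linescan <- st$table
  }

  if ("report" %in% stages) {
    rpt <- data.frame(stage = names(results),
                      rows = vapply(results, nrow, 0L))
    write_table(result_table(rpt, units = c(stage = "", rows = "count")),
                file.path(out_dir, "report.csv"))
  }

  prov <- list(seed = config$seed, stages = stages, config_hash = cfg_hash,
               config_file = "config.yaml",
               thresholds = list(method = config$analysis$threshold_method),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(results)
}

#' Deterministic test fixtures
#'
#' A small bundle of tiny scenes regenerated deterministically from a seed;
#' used by the unit tests. Scenes use a reduced field and fewer puncta so
#' the bundle stays small and fast.
#'
#' @param seed integer seed.
#' @param n_scenes number of fixture scenes.
#' @return list as from [generate_dataset()].
#' @export
make_fixtures <- function(seed = 7L, n_scenes = 2L) {
  cfg <- contact_config()
  cfg$puncta_count_mean <- 12
  cfg$puncta_count_sd <- 2
  generate_dataset(cfg, n_scenes = n_scenes, seed = seed,
                   channels = c("Cx35.5", "GluR2", "NCad"))
}
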