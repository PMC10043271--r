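#' Pipeline orchestration
#'
#' The `run_*` functions tie the modules into the standard analyses. Each
#' takes a configuration (a named list, or a path to a YAML file with one
#' section per stage), writes its outputs under `out_dir`, and writes a JSON
#' run manifest (`manifest_<stage>.json`) recording the configuration, seed,
#' package version and every output file, sufficient to reproduce the run.
#'
#' @param config named list or YAML path.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for stages with randomness.
#' @return list with `outputs` (file paths) and `results` (in-memory
#'   results), invisibly for the file side.
#' @name pipeline
NULL

.load_config <- function(config, section = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  if (!is.null(section) && !is.null(config[[section]]))
    config <- utils::modifyList(config[setdiff(names(config),
                                               c("simulate", "fields", "fit",
                                                 "lengths", "quantify",
                                                 "synth"))],
                                config[[section]])
  config
}

.write_manifest <- function(stage, config, outputs, seed, out_dir) {
  manifest <- list(stage = stage,
                   package_version =
                     as.character(utils::packageVersion("actopore")),
                   seed = seed,
                   config = config[setdiff(names(config),
                                           "pore_trajectory")],
                   outputs = outputs)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  path
}

.params_from_config <- function(config) {
  if (!is.null(config[["condition"]]))
    return(liposome_params(config[["condition"]]))
  if (!is.null(config[["params_file"]]))
    return(read_gel_params(config[["params_file"]]))
  if (!is.null(config[["params"]]))
    return(validate_gel_params(lapply(config[["params"]], as.numeric)))
  stop("config must provide 'condition', 'params' or 'params_file'")
}

#' @rdname pipeline
#' @export
run_simulate <- function(config = list(), out_dir = tempfile("simulate_"),
                         seed = 1) {
  config <- .load_config(config, "simulate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- tryCatch(.params_from_config(config), error = function(e) NULL)
  R_init <- config[["R_init"]] %||% 5e-7
  conditions <- config[["conditions"]] %||% config[["condition"]]

  outputs <- character(0)
  results <- list()

  if (!is.null(conditions)) {
    tab <- data.frame(condition = character(0), tau_s = numeric(0),
                      tau_over_tau_BL = numeric(0))
    tau_bl <- NA_real_
    for (cond in unique(c("bare", conditions))) {
      pt <- pore_timescale(liposome_params(cond), R_init = R_init)
      if (cond == "bare") tau_bl <- pt$tau
      if (cond %in% conditions || cond == "bare") {
        f <- file.path(out_dir, paste0("trajectory_", cond, ".csv"))
        write_time_series(pt$trace, f)
        outputs <- c(outputs, f)
        tab <- rbind(tab, data.frame(condition = cond, tau_s = pt$tau,
                                     tau_over_tau_BL = pt$tau / tau_bl))
        results[[cond]] <- pt
      }
    }
    f <- file.path(out_dir, "timescales.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    outputs <- c(outputs, f)
    results$timescales <- tab
  } else {
    if (is.null(params))
      stop("config must provide 'condition', 'conditions', 'params' or 'params_file'")
    traj <- simulate_pore(params, R_init,
                          seq(0, config[["t_end"]] %||% 1000,
                              length.out = config[["n_out"]] %||% 401))
    f <- file.path(out_dir, "trajectory.csv")
    write_pore_trajectory(traj, f)
    outputs <- c(outputs, f)
    results$trajectory <- traj
  }

  if (isTRUE(config[["phase_diagram"]])) {
    if (is.null(params)) params <- liposome_params(conditions[1])
    pd <- phase_diagram(params,
                        f_adh_grid = config[["f_adh_grid"]] %||%
                          seq(0, 2e7, length.out = 21),
                        R_grid = config[["R_grid"]] %||%
                          seq(1e-7, params$R_L * 0.99, length.out = 21))
    f <- file.path(out_dir, "phase_diagram.csv")
    utils::write.csv(
      data.frame(f_adh = rep(pd$f_adh_grid, each = length(pd$R_grid)),
                 R = rep(pd$R_grid, length(pd$f_adh_grid)),
                 regime = as.vector(pd$regime)),
      f, row.names = FALSE)
    outputs <- c(outputs, f)
    results$phase_diagram <- pd
  }

  manifest <- .write_manifest("simulate", config, outputs, seed, out_dir)
  invisible(list(outputs = c(outputs, manifest), results = results,
                 manifest = manifest))
}

#' @rdname pipeline
#' @export
run_fields <- function(config = list(), out_dir = tempfile("fields_"),
                       seed = 1) {
  config <- .load_config(config, "fields")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- .params_from_config(config)
  ft <- simulate_fields(params,
                        R_init = config[["R_init"]] %||% 5e-7,
                        t_end = config[["t_end"]] %||% 300,
                        n = config[["n"]] %||% 200,
                        n_out = config[["n_out"]] %||% 40,
                        store_fields = isTRUE(config[["store_fields"]]))
  f <- file.path(out_dir, "field_summary.csv")
  write_field_summary(ft, f)
  manifest <- .write_manifest("fields", config, f, seed, out_dir)
  invisible(list(outputs = c(f, manifest), results = list(fields = ft),
                 manifest = manifest))
}

#' @rdname pipeline
#' @export
run_fit <- function(config = list(), out_dir = tempfile("fit_"), seed = 1) {
  config <- .load_config(config, "fit")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- config[["traces"]]
  if (is.null(files) || length(files) == 0)
    stop("no input traces: the config 'traces' entry must list CSV files")
  missing <- files[!file.exists(files)]
  if (length(missing) > 0)
    stop("trace files not found: ", paste(missing, collapse = ", "))
  kind <- config[["kind"]] %||% "pore_radius"
  groups <- config[["groups"]] %||% rep("all", length(files))
  if (length(groups) != length(files))
    stop("groups must have one entry per trace file")

  rows <- lapply(seq_along(files), function(i) {
    ts <- read_time_series(files[i])
    fit <- if (kind == "pore_radius") fit_pore_radius(ts)
           else fit_center_depletion(ts)
    tau_name <- if (kind == "pore_radius") "tau" else "tau_a"
    data.frame(file = files[i], group = groups[i],
               tau_s = unname(fit$estimates[[tau_name]]),
               se_s = unname(fit$se[[tau_name]]),
               rms = fit$residual_rms, converged = fit$converged)
  })
  report <- do.call(rbind, rows)

  bl_group <- config[["baseline_group"]]
  if (!is.null(bl_group) && bl_group %in% report$group) {
    tau_bl <- mean(report$tau_s[report$group == bl_group])
    report$tau_over_tau_BL <- normalize_tau(report$tau_s, tau_bl)
  }
  f <- file.path(out_dir, "fit_report.csv")
  utils::write.csv(report, f, row.names = FALSE)

  summ <- do.call(rbind, lapply(split(report, report$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean_tau = mean(g$tau_s),
               sd_tau = stats::sd(g$tau_s))
  }))
  tests <- list()
  gs <- unique(report$group)
  if (length(gs) >= 2) {
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (i < j) {
        gc <- group_compare(report$tau_s[report$group == gs[i]],
                            report$tau_s[report$group == gs[j]])
        tests[[paste(gs[i], "vs", gs[j])]] <-
          list(p_value = gc$p_value, stars = gc$stars)
      }
    }
  }
  f2 <- file.path(out_dir, "group_summary.json")
  jsonlite::write_json(list(summary = summ, tests = tests), f2,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- .write_manifest("fit", config, c(f, f2), seed, out_dir)
  invisible(list(outputs = c(f, f2, manifest),
                 results = list(report = report, summary = summ,
                                tests = tests),
                 manifest = manifest))
}

#' @rdname pipeline
#' @export
run_lengths <- function(config = list(), out_dir = tempfile("lengths_"),
                        seed = 1) {
  config <- .load_config(config, "lengths")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config[["k_b"]])) stop("missing parameter: k_b (bending stiffness, J)")
  gamma <- config[["gamma"]] %||% c(0.3e-3, 5.0e-3)
  td <- thiele_defaults()
  D <- config[["D"]] %||% td$D
  k <- config[["k"]] %||% td$k
  L_obs <- config[["L_obs"]] %||% 2e-6

  L_b <- bendocapillary_length(config[["k_b"]], unlist(gamma))
  L_Th <- thiele_length(unlist(D), unlist(k))
  rep_ <- hypothesis_report(max(L_b), L_Th, L_obs)
  out <- list(L_b_m = as.list(L_b), L_Th_m = as.list(L_Th), L_obs_m = L_obs,
              mechanosensing_supported = rep_$mechanosensing_supported,
              reaction_diffusion_supported = rep_$reaction_diffusion_supported)
  f <- file.path(out_dir, "length_scales.json")
  jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
  tab <- data.frame(
    quantity = c("L_b_min", "L_b_max", "L_Th_min", "L_Th_max", "L_obs"),
    value_m = c(min(L_b), max(L_b), min(L_Th), max(L_Th), L_obs))
  f2 <- file.path(out_dir, "length_scales.csv")
  utils::write.csv(tab, f2, row.names = FALSE)
  manifest <- .write_manifest("lengths", config, c(f, f2), seed, out_dir)
  invisible(list(outputs = c(f, f2, manifest),
                 results = c(out, list(table = tab)), manifest = manifest))
}

#' @rdname pipeline
#' @export
run_quantify <- function(config = list(), out_dir = tempfile("quantify_"),
                         seed = 1) {
  config <- .load_config(config, "quantify")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  results <- list()

  if (!is.null(config[["actin_stack"]])) {
    frames <- read_image_stack(config[["actin_stack"]])
    spots <- detect_spots(frames[[length(frames)]])
    f <- file.path(out_dir, "spots.csv")
    utils::write.csv(spots, f, row.names = FALSE)
    outputs <- c(outputs, f)
    results$spots <- spots
    if (!is.null(config[["center"]]) && !is.null(config[["R_liposome"]])) {
      prof <- radial_profile(frames[[length(frames)]],
                             unlist(config[["center"]]))
      f <- file.path(out_dir, "radial_profile.csv")
      utils::write.csv(prof, f, row.names = FALSE)
      outputs <- c(outputs, f)
      results$radial_profile <- prof
    }
  }
  if (!is.null(config[["brightfield_stack"]])) {
    frames <- read_image_stack(config[["brightfield_stack"]])
    bl <- lapply(frames, detect_blisters)
    tab <- do.call(rbind, lapply(seq_along(bl), function(k) {
      if (nrow(bl[[k]]) == 0) return(NULL)
      cbind(frame = k, time_s = frames[[k]]$time, bl[[k]])
    }))
    if (is.null(tab))
      tab <- data.frame(frame = integer(0), time_s = numeric(0),
                        x_m = numeric(0), y_m = numeric(0),
                        radius_m = numeric(0), area_m2 = numeric(0))
    f <- file.path(out_dir, "blisters.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    outputs <- c(outputs, f)
    results$blisters <- tab
  }
  if (!is.null(config[["traction_stack"]])) {
    stop("traction input must be provided in-memory as the config 'tmap' entry ",
         "(TFM inversion is out of scope)")
  }
  if (!is.null(config[["tmap"]])) {
    tension <- rim_tension(config[["tmap"]],
                           w_rim = config[["w_rim"]] %||% 2e-6)
    f <- file.path(out_dir, "rim_tension.json")
    jsonlite::write_json(list(rim_tension_N_per_m = tension), f,
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
    results$rim_tension <- tension
  }
  if (length(outputs) == 0)
    stop("nothing to quantify: provide actin_stack, brightfield_stack ",
         "or tmap")
  manifest <- .write_manifest("quantify",
                              config[setdiff(names(config), "tmap")],
                              outputs, seed, out_dir)
  invisible(list(outputs = c(outputs, manifest), results = results,
                 manifest = manifest))
}

#' @rdname pipeline
#' @export
run_synth <- function(config = list(), out_dir = tempfile("synth_"),
                      seed = 1) {
  config <- .load_config(config, "synth")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scene_config(seed = config[["seed"]] %||% seed,
                      n_frames = config[["n_frames"]] %||% 12,
                      n_spots = config[["n_spots"]] %||% 10,
                      n_blisters = config[["n_blisters"]] %||% 3,
                      noise_sd = config[["noise_sd"]] %||% 0.05)
  movie <- gen_liposome_movie(cfg)
  f1 <- file.path(out_dir, "actin.tif")
  write_image_stack(movie$actin, f1)
  f2 <- file.path(out_dir, "brightfield.tif")
  write_image_stack(movie$brightfield, f2)
  f3 <- file.path(out_dir, "truth_spots.csv")
  utils::write.csv(movie$truth$spots, f3, row.names = FALSE)
  f4 <- file.path(out_dir, "truth_blisters.csv")
  utils::write.csv(movie$truth$blisters, f4, row.names = FALSE)
  f5 <- file.path(out_dir, "scene_config.json")
  jsonlite::write_json(unclass(cfg)[setdiff(names(cfg), "pore_trajectory")],
                       f5, auto_unbox = TRUE, digits = NA)
  outputs <- c(f1, paste0(f1, ".json"), f2, paste0(f2, ".json"), f3, f4, f5)
  manifest <- .write_manifest("synth", config, outputs, cfg$seed, out_dir)
  invisible(list(outputs = c(outputs, manifest),
                 results = list(movie = movie, cfg = cfg),
                 manifest = manifest))
}
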